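#' Render pseudo-atom coordinate frames from a simulation
#'
#' Reconstructs a long-format "track table" (one row per particle per frame)
#' from the exact event log of [simulate_pore()].  Ions and the blocker are
#' placed at the midpoint of their current compartment (wide compartments --
#' CTD, G-loop, cavity -- additionally receive one uniform per-dwell axial
#' offset so they are not rendered as a stack), with isotropic Gaussian
#' positional jitter.  Optional components: gate Calpha pseudo-atoms (four
#' per gate residue, diagonals drawn per frame from the open/closed
#' distance Gaussians), CTD/SF/D173 center-of-mass landmarks, co-permeating
#' water markers (short synthetic crossing tracks at each logged
#' co-permeation), and cavity hydration waters (per-frame counts from the
#' open/closed hydration Gaussians, placed uniformly inside the cavity
#' cylinder).
#'
#' Particles in the bulk reservoirs are rendered only for a short tail
#' around their pore entry/exit, at the bulk anchor positions.
#'
#' @param sim a `kir_sim` from [simulate_pore()].
#' @param dt_ns frame interval, ns.
#' @param t_range time window to render, us (default whole run).
#' @param jitter_sd positional jitter standard deviation, A; must be smaller
#'   than half the narrowest site width so site assignment remains
#'   recoverable.  Use 0 for jitter-free rendering.
#' @param include character subset of `c("ions", "spm", "gate", "landmarks",
#'   "coperm_waters", "cavity_waters")`.
#' @param tail_us bulk-anchor tail rendered before entry/after exit, us.
#' @param seed optional RNG seed for rendering noise (defaults to the
#'   continuing RNG stream).
#' @return a `data.table` (class `kir_tracks`) with columns `frame`,
#'   `time_ns`, `particle_id`, `role`, `x`, `y`, `z`; attributes `geometry`
#'   and `dt_ns`.
#' @export
render_frames <- function(sim, dt_ns = 2,
                          t_range = NULL,
                          jitter_sd = 0.4,
                          include = c("ions", "spm", "gate", "landmarks",
                                      "coperm_waters"),
                          tail_us = 0.02,
                          seed = NULL) {
  stopifnot(inherits(sim, "kir_sim"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  geom <- sim$model$geometry
  sb <- geom$site_bounds
  min_width <- min(sb$z_hi - sb$z_lo)
  if (jitter_sd >= min_width / 2)
    stop("jitter_sd must be below half the narrowest site width (",
         min_width / 2, " A)")
  if (is.null(t_range)) t_range <- c(0, sim$duration)
  t_range <- c(max(0, t_range[1]), min(sim$duration, t_range[2]))
  dt_us <- dt_ns / 1000
  ft <- seq(t_range[1], t_range[2], by = dt_us)
  nf <- length(ft)
  frames <- seq_len(nf)
  jit <- function(n) if (jitter_sd > 0) stats::rnorm(n, 0, jitter_sd)
         else numeric(n)

  chain <- sim$model$chain
  anchors <- vapply(chain, function(s) .site_anchor(geom, s), 1)
  wide <- intersect(c("CTD", "G_loop", "cavity"), chain)
  halfband <- setNames(numeric(length(chain)), chain)
  for (s in wide) {
    i <- match(s, sb$site)
    halfband[s] <- 0.3 * (sb$z_hi[i] - sb$z_lo[i])
  }
  closure <- if (is.na(sim$closure_time)) Inf else sim$closure_time
  open_at <- ft < closure

  out <- list()

  ## ---- ions --------------------------------------------------------------
  if ("ions" %in% include) {
    hops <- sim$log[kind == "hop" & particle > 0L]
    ion_ids <- sort(unique(c(sim$init$particle, hops$particle)))
    ion_ids <- ion_ids[vapply(ion_ids, function(p)
      sim$particle_roles[p] == "ion", TRUE)]
    hsplit <- if (nrow(hops)) split(hops, hops$particle) else list()
    seeded <- setNames(sim$init$site, sim$init$particle)
    pieces <- vector("list", length(ion_ids))
    for (k in seq_along(ion_ids)) {
      p <- ion_ids[k]
      hp <- hsplit[[as.character(p)]]
      if (is.null(hp)) {
        sites <- unname(seeded[as.character(p)])
        times <- 0
        win <- c(0, sim$duration)
      } else {
        first_from <- hp$from[1]
        s0 <- if (as.character(p) %in% names(seeded))
          unname(seeded[as.character(p)]) else first_from
        sites <- c(s0, hp$to)
        times <- c(0, hp$time)
        entered <- !(as.character(p) %in% names(seeded))
        w0 <- if (entered) max(0, hp$time[1] - tail_us) else 0
        last_site <- sites[length(sites)]
        exited <- last_site %in% c("bulk_in", "bulk_out")
        w1 <- if (exited) min(sim$duration,
                              hp$time[nrow(hp)] + tail_us) else sim$duration
        win <- c(w0, w1)
      }
      sel <- which(ft >= win[1] & ft <= win[2])
      if (!length(sel)) next
      idx <- findInterval(ft[sel], times)
      site_i <- match(sites[idx], chain)
      z <- anchors[site_i]
      hb <- halfband[site_i]
      if (any(hb > 0)) {
        ## one offset per dwell (= per run of constant idx)
        off <- stats::runif(length(sites), -1, 1)
        z <- z + hb * off[idx]
      }
      pieces[[k]] <- data.table::data.table(
        frame = frames[sel], time_ns = ft[sel] * 1000,
        particle_id = paste0("ion", p), role = "ion",
        x = jit(length(sel)), y = jit(length(sel)),
        z = z + jit(length(sel)))
    }
    out$ions <- data.table::rbindlist(pieces)
  }

  ## ---- co-permeating water markers ---------------------------------------
  if ("coperm_waters" %in% include) {
    wev <- sim$log[kind == "water_coperm"]
    if (nrow(wev)) {
      w_win <- max(10 * dt_us, 0.04)          # crossing window, us
      z_in <- anchors["bulk_in"]; z_out <- anchors["bulk_out"]
      pieces <- vector("list", nrow(wev))
      for (k in seq_len(nrow(wev))) {
        tc <- min(max(wev$time[k], t_range[1] + w_win / 2),
                  t_range[2] - w_win / 2)
        sel <- which(ft >= tc - w_win / 2 & ft <= tc + w_win / 2)
        if (!length(sel)) next
        u <- (ft[sel] - (tc - w_win / 2)) / w_win    # 0..1
        ## dwell at bulk anchors for the first/last third, cross in between
        v <- pmin(1, pmax(0, (u - 1 / 3) * 3))
        z <- z_in + v * (z_out - z_in)
        pieces[[k]] <- data.table::data.table(
          frame = frames[sel], time_ns = ft[sel] * 1000,
          particle_id = paste0("wat", wev$particle[k]), role = "water",
          x = jit(length(sel)), y = jit(length(sel)), z = z + jit(length(sel)))
      }
      out$coperm <- data.table::rbindlist(pieces)
    }
  }

  ## ---- blocker -----------------------------------------------------------
  if ("spm" %in% include && !is.null(sim$blocker)) {
    smoves <- sim$log[kind == "hop" & particle == 0L]
    stz <- setNames(sim$blocker$stations$z, sim$blocker$stations$station)
    s0 <- sim$blocker$start_station
    sites <- c(s0, smoves$to)
    times <- c(0, smoves$time)
    idx <- findInterval(ft, times)
    out$spm <- data.table::data.table(
      frame = frames, time_ns = ft * 1000,
      particle_id = "SPM", role = "blocker",
      x = jit(nf), y = jit(nf),
      z = unname(stz[sites[idx]]) + jit(nf))
  }

  ## ---- gate pseudo-atoms -------------------------------------------------
  if ("gate" %in% include) {
    g <- sim$gate
    mk_gate <- function(resname, zg) {
      mu <- ifelse(open_at, g$open_gate_distance$mean,
                   g$closed_gate_distance$mean)
      sdv <- ifelse(open_at, g$open_gate_distance$sd,
                    g$closed_gate_distance$sd)
      d1 <- stats::rnorm(nf, mu, sdv)
      d2 <- stats::rnorm(nf, mu, sdv)
      data.table::rbindlist(list(
        data.table::data.table(frame = frames, time_ns = ft * 1000,
          particle_id = paste0(resname, "_A"), role = "gate",
          x = d1 / 2, y = 0, z = zg),
        data.table::data.table(frame = frames, time_ns = ft * 1000,
          particle_id = paste0(resname, "_B"), role = "gate",
          x = 0, y = d2 / 2, z = zg),
        data.table::data.table(frame = frames, time_ns = ft * 1000,
          particle_id = paste0(resname, "_C"), role = "gate",
          x = -d1 / 2, y = 0, z = zg),
        data.table::data.table(frame = frames, time_ns = ft * 1000,
          particle_id = paste0(resname, "_D"), role = "gate",
          x = 0, y = -d2 / 2, z = zg)))
    }
    out$gate <- data.table::rbindlist(list(mk_gate("I177", -20.5),
                                           mk_gate("M181", -23.5)))
  }

  ## ---- landmarks ---------------------------------------------------------
  if ("landmarks" %in% include) {
    g <- sim$gate
    sep <- stats::rnorm(nf,
                        ifelse(open_at, g$open_ctd_sf$mean,
                               g$closed_ctd_sf$mean),
                        ifelse(open_at, g$open_ctd_sf$sd, g$closed_ctd_sf$sd))
    z_sf <- 5
    out$landmarks <- data.table::rbindlist(list(
      data.table::data.table(frame = frames, time_ns = ft * 1000,
        particle_id = "SF_COM", role = "landmark", x = 0, y = 0, z = z_sf),
      data.table::data.table(frame = frames, time_ns = ft * 1000,
        particle_id = "CTD_COM", role = "landmark", x = 0, y = 0,
        z = z_sf - sep),
      data.table::data.table(frame = frames, time_ns = ft * 1000,
        particle_id = "D173_COM", role = "landmark", x = 0, y = 0, z = -10)))
  }

  ## ---- cavity hydration waters -------------------------------------------
  if ("cavity_waters" %in% include) {
    g <- sim$gate
    cyl <- geom$cavity_cylinder
    counts <- pmax(0L, as.integer(round(stats::rnorm(
      nf,
      ifelse(open_at, g$open_hydration$mean, g$closed_hydration$mean),
      ifelse(open_at, g$open_hydration$sd, g$closed_hydration$sd)))))
    K <- max(counts, 1L)
    total <- sum(counts)
    ## in-cylinder placements
    rr <- cyl$radius * sqrt(stats::runif(total))
    th <- stats::runif(total, 0, 2 * pi)
    zz <- stats::runif(total, cyl$z_lo, cyl$z_hi)
    wat_id <- sequence(counts)
    fr_rep <- rep.int(frames, counts)
    inside <- data.table::data.table(
      frame = fr_rep, time_ns = ft[fr_rep] * 1000,
      particle_id = paste0("hw", wat_id), role = "water",
      x = rr * cos(th), y = rr * sin(th), z = zz)
    ## parked (outside the cylinder, in intracellular bulk)
    n_park <- K - counts
    fr_rep2 <- rep.int(frames, n_park)
    park_id <- unlist(lapply(seq_len(nf), function(i)
      if (n_park[i] > 0) seq.int(counts[i] + 1L, K) else integer(0)),
      use.names = FALSE)
    parked <- data.table::data.table(
      frame = fr_rep2, time_ns = ft[fr_rep2] * 1000,
      particle_id = paste0("hw", park_id), role = "water",
      x = 25, y = 0, z = anchors[["bulk_in"]])
    out$cavity_waters <- data.table::rbindlist(list(inside, parked))
  }

  tracks <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setorder(tracks, frame, particle_id)
  data.table::setattr(tracks, "geometry", geom)
  data.table::setattr(tracks, "dt_ns", dt_ns)
  data.table::setattr(tracks, "duration_us", diff(t_range))
  data.table::setattr(tracks, "class",
                      c("kir_tracks", class(tracks)))
  tracks[]
}
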