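#' Exact-jump stochastic simulation of the extended-pore kinetic model
#'
#' Runs a Gillespie (next-event) simulation of voltage-biased, single-file
#' ion hopping through the compartment chain defined by the
#' [kinetic_model()], together with an optional two-state gate
#' ([gate_model()]) and an optional spermine blocker ([blocker_model()]).
#' The returned object carries the exact, complete event log (the ground
#' truth against which trajectory analyzers are validated) from which
#' pseudo-atom coordinate frames can be rendered with [render_frames()].
#'
#' Mechanics:
#' \itemize{
#'   \item Ion hops between adjacent compartments honor per-compartment
#'     capacities (site exclusion) and a symmetric Eyring voltage bias
#'     `exp(+-z_q * delta * u / 2)` per edge (z_q = +1 for K+, +4 for the
#'     blocker).
#'   \item A permeation event (`permeation_out`/`permeation_in`) is logged
#'     when a particle whose last extreme position was on one bulk side of
#'     the pore reaches the opposite side; transient excursions produce no
#'     event, mirroring the hysteresis rule used by the analyzers.
#'   \item Each completed outward ion permeation triggers, with probability
#'     `water_coperm_prob`, one co-permeating water marker
#'     (`water_coperm`).
#'   \item The gate closes with hazard `closure_rate` (absorbing); hops
#'     across the G_loop/cavity edge then stop.
#'   \item The blocker walks its station graph; entering `deep_site` logs
#'     `spm_bind`, optionally evicts the cavity/SF ions in the direction of
#'     the field (logged as hops, plus permeation events when the eviction
#'     completes a crossing) and blocks TM-pore ion hops while bound;
#'     leaving logs `spm_unbind`.
#'   \item With `mechanism_constrained = TRUE`, SF transitions follow the
#'     concerted four-state knock-on cycle
#'     `S6[S4,S2],S1 -> S5[S4,S2],S1 -> S5[S3,S2],S0 -> S4[S2,S1],S_ext`
#'     (each arrow firing its constituent single-ion hops atomically)
#'     instead of free single-ion hops.
#' }
#'
#' A state with zero total propensity ends the replicate early (the state is
#' absorbing); this raises a deadlock error naming the state only when ion
#' dynamics were requested (some base rate > 0), particles remain inside the
#' pore, and neither gate closure nor a deep-bound blocker explains the
#' standstill.
#'
#' @param model a [kinetic_model()].
#' @param gate a [gate_model()].
#' @param blocker a [blocker_model()] or `NULL`.
#' @param duration simulated time, us.
#' @param seed integer RNG seed (one stream per replicate; derive replicate
#'   seeds as `master_seed + replicate_index`).
#' @param init named integer vector of initial compartment occupancies
#'   (ions); default seeds CTD 3, cavity 3, and SF sites S5/S3/S1 (or the
#'   knock-on state `S6,S4,S2,S1` when mechanism-constrained).
#' @param max_events safety cap on the number of logged events.
#' @return object of class `kir_sim`: list with `log` (data.table: `time`
#'   us, `kind`, `particle`, `from`, `to`), `init` (initial placements),
#'   `duration`, `voltage`, `closure_time` (`NA` if the pore never closed),
#'   `model`, `gate`, `blocker`, `seed`.
#' @seealso [render_frames()], [log_occupancy()], [log_permeation_counts()]
#' @export
simulate_pore <- function(model, gate = gate_model(), blocker = NULL,
                          duration, seed = 1L, init = NULL,
                          max_events = 5e6) {
  stopifnot(inherits(model, "kinetic_model"), inherits(gate, "gate_model"))
  if (!is.null(blocker)) stopifnot(inherits(blocker, "blocker_model"))
  if (duration <= 0) stop("'duration' must be positive (us)")
  if (model$mechanism_constrained && !is.null(blocker) &&
      blocker$displace_on_deep_bind)
    stop("mechanism_constrained mode cannot be combined with an ",
         "ion-displacing blocker")
  set.seed(as.integer(seed))

  chain <- model$chain
  M <- length(chain)
  capv <- ifelse(is.na(model$capacities), .Machine$integer.max,
                 model$capacities)
  i_bin <- 1L; i_bout <- M
  i_cav <- match("cavity", chain)
  i_gloop <- match("G_loop", chain)
  i_sext <- match("S_ext", chain)
  i_s0 <- match("S0", chain)

  V <- model$voltage; Temp <- model$temperature
  ed <- model$edges
  nE <- nrow(ed)                       # edge e joins chain[e] -> chain[e+1]
  bias <- .bias_exponent(1, ed$delta, V, Temp)
  kf <- ed$k_fwd0 * exp(bias)
  kb <- ed$k_bwd0 * exp(-bias)
  gate_edge <- if (!is.na(i_gloop) && !is.na(i_cav)) i_gloop else NA_integer_
  block_edges <- if (!is.na(i_cav) && !is.na(i_sext))
    seq.int(i_gloop, i_sext) else integer(0)   # G_loop->cavity .. S0->S_ext

  ## --- mechanism-constrained knock-on cycle -------------------------------
  constrained <- model$mechanism_constrained
  if (constrained) {
    need <- c("cavity", paste0("S", 6:0), "S_ext")
    if (!all(need %in% chain))
      stop("mechanism_constrained requires the full cavity-SF-S_ext chain")
    ii <- function(s) match(s, chain)
    ## transition -> list of constituent (from, to) single-ion hops
    kn_moves <- list(
      AB = list(c(ii("S6"), ii("S5"))),
      BC = list(c(ii("S4"), ii("S3")), c(ii("S1"), ii("S0"))),
      CD = list(c(ii("S0"), ii("S_ext")), c(ii("S2"), ii("S1")),
                c(ii("S3"), ii("S2")), c(ii("S5"), ii("S4"))),
      DA = list(c(ii("S_ext"), i_bout), c(i_cav, ii("S6"))))
    kn_k <- kn_delta <- numeric(4)
    for (j in 1:4) {
      e_idx <- vapply(kn_moves[[j]], function(m) min(m), 1L)
      kn_k[j] <- mean(ed$k_fwd0[e_idx])
      kn_delta[j] <- sum(ed$delta[e_idx])
    }
    kn_fwd <- kn_k * exp(.bias_exponent(1, kn_delta, V, Temp))
    kn_bwd_k <- vapply(1:4, function(j)
      mean(ed$k_bwd0[vapply(kn_moves[[j]], function(m) min(m), 1L)]), 1)
    kn_bwd <- kn_bwd_k * exp(-.bias_exponent(1, kn_delta, V, Temp))
    kn_bwd[4] <- 0                 # the completed permeation is not undone
    ## single-ion SF edges are replaced by the cycle
    disabled_edges <- seq.int(i_cav, nE)
    kf[disabled_edges] <- 0
    kb[disabled_edges] <- 0
    sf_state <- 1L                 # A
  }

  ## --- blocker setup ------------------------------------------------------
  has_blk <- !is.null(blocker)
  if (has_blk) {
    stn <- blocker$stations$station
    nS <- length(stn)
    bed <- blocker$edges
    bbias <- .bias_exponent(blocker$charge, bed$delta, V, Temp)
    bkf <- bed$k_fwd0 * exp(bbias)
    bkb <- bed$k_bwd0 * exp(-bbias)
    b_at <- match(blocker$start_station, stn)
    i_deep <- match("deep_site", stn)       # NA if absent (e.g. ROMK-like)
    i_sfst <- match("SF", stn)
    nBE <- nrow(bed)
  } else {
    nBE <- 0L; b_at <- NA_integer_; i_deep <- NA_integer_
    i_sfst <- NA_integer_
  }
  deep_bound <- has_blk && !is.na(i_deep) && b_at == i_deep

  ## --- particle state -----------------------------------------------------
  cap0 <- 1024L
  p_site <- integer(cap0); p_zone <- integer(cap0); p_role <- integer(cap0)
  n_part <- 0L
  new_particle <- function(site, zone, role) {
    n_part <<- n_part + 1L
    if (n_part > length(p_site)) {
      length(p_site) <<- 2L * length(p_site)
      length(p_zone) <<- 2L * length(p_zone)
      length(p_role) <<- 2L * length(p_role)
    }
    p_site[n_part] <<- site; p_zone[n_part] <<- zone; p_role[n_part] <<- role
    n_part
  }
  slots <- vector("list", M)
  for (i in seq_len(M)) slots[[i]] <- integer(0)
  occ <- integer(M)

  ## zone of a compartment: -1 intracellular side (<= cavity), +1
  ## extracellular side (>= S_ext), 0 inside the SF
  comp_zone <- integer(M)
  comp_zone[seq_len(if (is.na(i_cav)) 1L else i_cav)] <- -1L
  if (!is.na(i_sext)) comp_zone[i_sext:M] <- 1L else comp_zone[M] <- 1L

  ## --- event log ----------------------------------------------------------
  lcap <- 4096L
  l_time <- numeric(lcap); l_kind <- integer(lcap)
  l_part <- integer(lcap); l_from <- integer(lcap); l_to <- integer(lcap)
  n_ev <- 0L
  KIND <- c("hop", "permeation_out", "permeation_in", "water_coperm",
            "spm_bind", "spm_unbind", "closure")
  push <- function(t, kind, part, from, to) {
    n_ev <<- n_ev + 1L
    if (n_ev > length(l_time)) {
      length(l_time) <<- 2L * length(l_time)
      length(l_kind) <<- 2L * length(l_kind)
      length(l_part) <<- 2L * length(l_part)
      length(l_from) <<- 2L * length(l_from)
      length(l_to) <<- 2L * length(l_to)
    }
    l_time[n_ev] <<- t; l_kind[n_ev] <<- kind
    l_part[n_ev] <<- part; l_from[n_ev] <<- from; l_to[n_ev] <<- to
  }

  ## move one ion between compartments, with permeation/zone bookkeeping;
  ## a move out of a bulk reservoir creates a fresh particle
  move_ion <- function(from, to, t) {
    if (from == i_bin || from == i_bout) {
      p <- new_particle(from, comp_zone[from], 1L)
    } else {
      s <- slots[[from]]
      if (to > from) { p <- s[length(s)]; slots[[from]] <<- s[-length(s)] }
      else           { p <- s[1L];        slots[[from]] <<- s[-1L] }
      occ[from] <<- occ[from] - 1L
    }
    if (to != i_bin && to != i_bout) {
      if (to > from) slots[[to]] <<- c(p, slots[[to]])
      else           slots[[to]] <<- c(slots[[to]], p)
      occ[to] <<- occ[to] + 1L
    }
    p_site[p] <<- to
    push(t, 1L, p, from, to)
    z <- comp_zone[to]
    if (z != 0L) {
      lastz <- p_zone[p]
      if (lastz != 0L && z != lastz) {
        if (z == 1L) {
          push(t, 2L, p, i_bin, i_bout)              # permeation_out
          if (p_role[p] == 1L &&
              stats::runif(1) < model$water_coperm_prob) {
            w <- new_particle(i_bout, 1L, 2L)
            push(t, 4L, w, i_bin, i_bout)            # water_coperm
          }
        } else {
          push(t, 3L, p, i_bout, i_bin)              # permeation_in
        }
      }
      p_zone[p] <<- z
    }
    invisible(p)
  }

  ## specific-particle move used by eviction / constrained cycle
  move_specific <- function(p, to, t) {
    from <- p_site[p]
    s <- slots[[from]]
    slots[[from]] <<- s[s != p]
    occ[from] <<- occ[from] - 1L
    if (to != i_bin && to != i_bout) {
      if (to > from) slots[[to]] <<- c(p, slots[[to]])
      else           slots[[to]] <<- c(slots[[to]], p)
      occ[to] <<- occ[to] + 1L
    }
    p_site[p] <<- to
    push(t, 1L, p, from, to)
    z <- comp_zone[to]
    if (z != 0L) {
      lastz <- p_zone[p]
      if (lastz != 0L && z != lastz) {
        if (z == 1L) push(t, 2L, p, i_bin, i_bout)
        else push(t, 3L, p, i_bout, i_bin)
      }
      p_zone[p] <<- z
    }
    invisible(NULL)
  }

  ## --- initial occupancy --------------------------------------------------
  if (is.null(init)) {
    init <- integer(0)
    if ("CTD" %in% chain) init["CTD"] <- min(3L, capv[match("CTD", chain)])
    if ("cavity" %in% chain) init["cavity"] <- min(3L, capv[i_cav])
    sf_seed <- if (constrained) c("S6", "S4", "S2", "S1")
               else c("S5", "S3", "S1")
    for (s in intersect(sf_seed, chain)) init[s] <- 1L
  }
  init_rows <- list()
  for (s in names(init)) {
    i <- match(s, chain)
    if (is.na(i)) stop("init names unknown compartment: ", s)
    if (init[[s]] > capv[i]) stop("init exceeds capacity at ", s)
    for (k in seq_len(init[[s]])) {
      p <- new_particle(i, comp_zone[i], 1L)
      slots[[i]] <- c(slots[[i]], p)
      occ[i] <- occ[i] + 1L
      init_rows[[length(init_rows) + 1L]] <- c(p, i)
    }
  }

  ## --- main loop ----------------------------------------------------------
  t <- 0
  gate_open <- TRUE
  closure_time <- NA_real_
  lam_c <- gate$closure_rate
  any_ion_rates <- any(ed$k_fwd0 > 0 | ed$k_bwd0 > 0)

  repeat {
    ## ion edge propensities: per-particle rates (source-count scaled),
    ## capacity-limited targets; bulk reservoirs contribute unit weight
    n_src_f <- c(1L, occ[2:(M - 1)])                  # source of fwd edge e
    dst_ok_f <- c(occ[2:(M - 1)] < capv[2:(M - 1)], TRUE)
    a_f <- kf * n_src_f * dst_ok_f
    n_src_b <- c(occ[2:(M - 1)], 1L)                  # source of bwd edge e
    dst_ok_b <- c(TRUE, occ[2:(M - 1)] < capv[2:(M - 1)])
    a_b <- kb * n_src_b * dst_ok_b
    if (!gate_open && !is.na(gate_edge)) {
      a_f[gate_edge] <- 0; a_b[gate_edge] <- 0
    }
    if (deep_bound && blocker$block_on_deep_bind && length(block_edges)) {
      a_f[block_edges] <- 0; a_b[block_edges] <- 0
    }

    ## knock-on cycle propensities
    if (constrained) {
      a_kf <- numeric(4); a_kb <- numeric(4)
      blocked_sf <- deep_bound && has_blk && blocker$block_on_deep_bind
      if (!blocked_sf) {
        a_kf[sf_state] <- kn_fwd[sf_state]
        if (sf_state == 4L && occ[i_cav] == 0L) a_kf[4L] <- 0
        if (sf_state > 1L) a_kb[sf_state - 1L] <- kn_bwd[sf_state - 1L]
      }
    } else a_kf <- a_kb <- numeric(0)

    a_gate <- if (gate_open && lam_c > 0) lam_c else 0

    if (has_blk) {
      ab_f <- bkf * (seq_len(nBE) == b_at)
      ab_b <- bkb * (seq_len(nBE) + 1L == b_at)
    } else ab_f <- ab_b <- numeric(0)

    a_all <- c(a_f, a_b, a_kf, a_kb, a_gate, ab_f, ab_b)
    a_tot <- sum(a_all)

    if (a_tot <= 0) {
      interior <- sum(occ[2:(M - 1)])
      stuck_by_design <- !any_ion_rates || !gate_open ||
        (deep_bound && has_blk && blocker$block_on_deep_bind)
      if (interior > 0L && !stuck_by_design)
        stop("kinetic deadlock: no escape from state {",
             paste(sprintf("%s:%d", chain[2:(M - 1)], occ[2:(M - 1)]),
                   collapse = ", "), "} at t = ", signif(t, 6), " us")
      break
    }

    t <- t + stats::rexp(1, a_tot)
    if (t >= duration) { t <- duration; break }
    if (n_ev >= max_events) {
      warning("max_events reached at t = ", signif(t, 6), " us; truncating")
      break
    }

    r <- stats::runif(1) * a_tot
    cum <- 0; j <- 0L
    for (jj in seq_along(a_all)) {      # small vector (~40), linear scan
      cum <- cum + a_all[jj]
      if (r <= cum) { j <- jj; break }
    }
    if (j == 0L) j <- length(a_all)

    off1 <- nE; off2 <- 2L * nE
    off3 <- off2 + length(a_kf); off4 <- off3 + length(a_kb)
    off5 <- off4 + 1L
    if (j <= off1) {                                   # ion fwd hop
      move_ion(j, j + 1L, t)
    } else if (j <= off2) {                            # ion bwd hop
      e <- j - off1
      move_ion(e + 1L, e, t)
    } else if (j <= off3) {                            # knock-on forward
      tr <- j - off2
      for (mv in kn_moves[[tr]]) {
        s <- slots[[mv[1]]]
        pm <- if (mv[2] > mv[1]) s[length(s)] else s[1L]  # single-file order
        move_specific(pm, mv[2], t)
      }
      sf_state <- if (tr == 4L) 1L else tr + 1L
    } else if (j <= off4) {                            # knock-on backward
      tr <- j - off3
      for (mv in rev(kn_moves[[tr]])) {
        s <- slots[[mv[2]]]
        pm <- if (mv[1] < mv[2]) s[1L] else s[length(s)]
        move_specific(pm, mv[1], t)
      }
      sf_state <- tr
    } else if (j == off5) {                            # gate closure
      gate_open <- FALSE
      closure_time <- t
      push(t, 7L, 0L, 0L, 0L)
    } else {                                           # blocker move
      jj <- j - off5
      if (jj <= nBE) { b_from <- jj; b_to <- jj + 1L }
      else { b_from <- jj - nBE + 1L; b_to <- jj - nBE }
      was_deep <- !is.na(i_deep) && b_from == i_deep
      b_at <- b_to
      push(t, 1L, 0L, -b_from, -b_to)
      if (!is.na(i_deep) && b_to == i_deep) {
        push(t, 5L, 0L, -b_from, -b_to)                # spm_bind
        deep_bound <- TRUE
        if (blocker$displace_on_deep_bind && !is.na(i_cav) && !is.na(i_s0)) {
          dest <- if (V >= 0) i_bout else i_bin
          for (ci in seq.int(i_cav, i_s0)) {
            for (pm in rev(slots[[ci]])) move_specific(pm, dest, t)
          }
        }
      } else if (was_deep) {
        push(t, 6L, 0L, -b_from, -b_to)                # spm_unbind
        deep_bound <- !is.na(i_sfst) && b_to == i_sfst &&
          blocker$block_on_deep_bind
        ## block persists while the blocker occupies the SF station
      } else if (deep_bound && !is.na(i_sfst) && b_from == i_sfst &&
                 b_to != i_deep) {
        deep_bound <- FALSE                            # translocated onward
      }
    }
  }

  ## --- assemble -----------------------------------------------------------
  comp_name <- function(i) {
    ifelse(i > 0, chain[pmax(i, 1L)],
           ifelse(i < 0, if (has_blk) stn[-i] else NA_character_, ""))
  }
  idx <- seq_len(n_ev)
  log_dt <- data.table::data.table(
    time = l_time[idx],
    kind = KIND[l_kind[idx]],
    particle = l_part[idx],
    from = vapply(l_from[idx], comp_name, ""),
    to = vapply(l_to[idx], comp_name, ""))
  init_dt <- if (length(init_rows)) {
    m <- do.call(rbind, init_rows)
    data.table::data.table(particle = m[, 1], site = chain[m[, 2]],
                           role = "ion")
  } else data.table::data.table(particle = integer(0), site = character(0),
                                role = character(0))
  roles <- c("ion", "water")[p_role[seq_len(n_part)]]
  structure(list(log = log_dt, init = init_dt, duration = duration,
                 voltage = V, closure_time = closure_time,
                 model = model, gate = gate, blocker = blocker,
                 seed = seed, n_particles = n_part, particle_roles = roles),
            class = "kir_sim")
}

#' @export
print.kir_sim <- function(x, ...) {
  cnt <- table(x$log$kind)
  cat(sprintf("kir_sim: %.3g us at %g mV, %d particles, %d events\n",
              x$duration, x$voltage, x$n_particles, nrow(x$log)))
  if (length(cnt)) print(cnt)
  if (!is.na(x$closure_time))
    cat(sprintf("pore closed at %.3g us\n", x$closure_time))
  invisible(x)
}

#' Time-averaged occupancy of a region from the ground-truth log
#'
#' Reconstructs the per-compartment occupancy trajectory exactly from the
#' initial placements and logged hops, and returns the time-weighted mean
#' ion count over the sites of `region`.
#'
#' @param sim a `kir_sim`.
#' @param region region name resolvable by [region_range()] (site name or
#'   composite group such as `"SF"`).
#' @param from_time average from this time (us), e.g. to discard
#'   equilibration.
#' @return time-averaged occupancy (count).
#' @export
log_occupancy <- function(sim, region, from_time = 0) {
  stopifnot(inherits(sim, "kir_sim"))
  geom <- sim$model$geometry
  sites <- if (region %in% names(geom$region_groups))
    geom$region_groups[[region]] else region
  lg <- sim$log[kind == "hop" & particle > 0L]
  occ0 <- sum(sim$init$site %in% sites)
  if (nrow(lg) == 0L) return(occ0)
  dset <- as.integer(lg$to %in% sites) - as.integer(lg$from %in% sites)
  keep <- dset != 0L
  breaks <- c(0, lg$time[keep], sim$duration)
  vals <- c(occ0, occ0 + cumsum(dset[keep]))  # value on [breaks[i], breaks[i+1])
  lo <- pmax(breaks[-length(breaks)], from_time)
  hi <- pmax(breaks[-1], from_time)
  w <- hi - lo
  if (sum(w) <= 0) stop("'from_time' is beyond the simulated duration")
  sum(vals * w) / sum(w)
}

#' Permeation and water co-permeation counts from the ground-truth log
#'
#' @param sim a `kir_sim`.
#' @return list with `n_out`, `n_in`, `n_water`.
#' @export
log_permeation_counts <- function(sim) {
  stopifnot(inherits(sim, "kir_sim"))
  list(n_out = sum(sim$log$kind == "permeation_out"),
       n_in = sum(sim$log$kind == "permeation_in"),
       n_water = sum(sim$log$kind == "water_coperm"))
}

#' Blocker bind/unbind times from the ground-truth log
#'
#' @param sim a `kir_sim`.
#' @return list with vectors `bind` and `unbind` (us).
#' @export
log_spm_times <- function(sim) {
  stopifnot(inherits(sim, "kir_sim"))
  list(bind = sim$log$time[sim$log$kind == "spm_bind"],
       unbind = sim$log$time[sim$log$kind == "spm_unbind"])
}
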