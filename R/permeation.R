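## Permeation analysis: event detection, currents, occupancies, densities,
## residence times, knock-on configuration histograms.

.tracks_geom <- function(tracks, geometry) {
  if (is.null(geometry)) geometry <- attr(tracks, "geometry")
  if (is.null(geometry))
    stop("no geometry: pass one or use tracks from render_frames()")
  stopifnot(inherits(geometry, "pore_geometry"))
  geometry
}

.tracks_dt_us <- function(tracks) {
  dt_ns <- attr(tracks, "dt_ns")
  if (is.null(dt_ns)) {
    tt <- sort(unique(tracks$time_ns))
    if (length(tt) < 2) stop("cannot infer frame interval from tracks")
    dt_ns <- min(diff(tt))
  }
  dt_ns / 1000
}

#' Detect ion permeation events with hysteresis thresholds
#'
#' Two-threshold state machine per particle: an outward event is committed
#' only when a particle whose last extreme position was below the inner
#' threshold (below S6) rises above the outer threshold (above S0); inward
#' events are symmetric.  Excursions that retreat before crossing the far
#' threshold produce no event, so ions transiently interacting with the SF
#' from either side are not counted.
#'
#' @param tracks a track table ([render_frames()] output or equivalent
#'   long-format data with `frame`, `time_ns`, `particle_id`, `role`, `z`).
#' @param geometry a [pore_geometry()] (default: the tracks attribute).
#' @param hysteresis threshold offset, A: inner = `z_lo(S6) - hysteresis`,
#'   outer = `z_hi(S0) + hysteresis`.  Must exceed the rendering jitter sd.
#' @param particle_role role to analyse (`"ion"`, or `"water"` for
#'   co-permeating water markers).
#' @return data.table with `particle_id`, `direction`
#'   (`"outward"`/`"inward"`), `t_enter`, `t_exit` (us).
#' @export
detect_permeation_events <- function(tracks, geometry = NULL, hysteresis = 2,
                                     particle_role = "ion") {
  geometry <- .tracks_geom(tracks, geometry)
  sfr <- region_range(geometry, "SF")
  inner <- sfr[1] - hysteresis
  outer <- sfr[2] + hysteresis
  tr <- data.table::as.data.table(tracks)[role == particle_role]
  if (nrow(tr) == 0)
    return(data.table::data.table(particle_id = character(0),
                                  direction = character(0),
                                  t_enter = numeric(0), t_exit = numeric(0)))
  ev <- tr[, {
    if (is.unsorted(time_ns)) stop("unsorted frames for particle ",
                                   particle_id[1])
    zone <- (z > outer) - (z < inner)
    nzi <- which(zone != 0L)
    if (length(nzi) < 2L) {
      list(direction = character(0), t_enter = numeric(0),
           t_exit = numeric(0))
    } else {
      zs <- zone[nzi]
      flip <- which(zs[-1] != zs[-length(zs)]) + 1L
      list(direction = c("inward", "outward")[(zs[flip] > 0) + 1L],
           t_enter = time_ns[nzi[flip - 1L]] / 1000,
           t_exit = time_ns[nzi[flip]] / 1000)
    }
  }, by = particle_id]
  data.table::setorder(ev, t_exit)
  ev[]
}

#' Single-channel current and conductance from permeation events
#'
#' `I = (N_out - N_in) * e / T` with `e` the elementary charge; with `T` in
#' us and counts per event this gives pA directly.  `g = I / V` (pA/V = pS).
#'
#' @param events event table from [detect_permeation_events()], or `NULL`
#'   when passing counts directly.
#' @param duration trajectory duration, us.
#' @param voltage membrane voltage, mV; conductance is flagged undefined at
#'   0 mV.
#' @param n_out,n_in event counts (used when `events` is `NULL`).
#' @return object of class `current_result`: `n_out`, `n_in`, `duration`,
#'   `voltage`, `current_pA`, `conductance_pS`, `conductance_defined`.
#' @examples
#' ## printed worked example: 929 + 1461 outward events over two 48-us runs
#' current_and_conductance(NULL, duration = 96, voltage = 310,
#'                         n_out = 929 + 1461, n_in = 0)
#' @export
current_and_conductance <- function(events, duration, voltage,
                                    n_out = NULL, n_in = NULL) {
  if (duration <= 0) stop("'duration' must be positive (us)")
  if (!is.null(events)) {
    n_out <- sum(events$direction == "outward")
    n_in <- sum(events$direction == "inward")
  }
  if (is.null(n_out) || is.null(n_in))
    stop("provide 'events' or both 'n_out' and 'n_in'")
  ## e / 1 us = 1.602...e-19 C / 1e-6 s = 1.602...e-13 A = 0.1602... pA
  current <- (n_out - n_in) * (.E_CHARGE * 1e18) / duration  # pA
  defined <- voltage != 0
  g <- if (defined) current / (voltage / 1000) else NA_real_  # pA/V = pS
  structure(list(n_out = n_out, n_in = n_in, duration = duration,
                 voltage = voltage, current_pA = current,
                 conductance_pS = g, conductance_defined = defined),
            class = "current_result")
}

#' @export
print.current_result <- function(x, ...) {
  cat(sprintf("%d out / %d in over %g us at %g mV: I = %.3f pA",
              x$n_out, x$n_in, x$duration, x$voltage, x$current_pA))
  if (x$conductance_defined) cat(sprintf(", g = %.2f pS", x$conductance_pS))
  else cat(" (conductance undefined at 0 mV)")
  cat("\n")
  invisible(x)
}

#' Kinetic (time-averaged) ion occupancy of a pore region
#'
#' Time average of the per-frame count of ions inside the region's axial
#' extent.  Under `rule = "intracellular_entry_only"` an ion's frames are
#' counted only while its current visit to the region began by crossing the
#' region's intracellular (lower-z) boundary -- the "kinetic" occupancy of
#' outwardly permeating ions, excluding ions transiently interacting with
#' the SF from the extracellular side.  The standard error is estimated by
#' block averaging (autocorrelated series).
#'
#' @param tracks a track table.
#' @param geometry a [pore_geometry()] (default: tracks attribute).
#' @param region region name (site or composite group, e.g. `"SF"`).
#' @param rule `"all"` or `"intracellular_entry_only"`.
#' @param n_blocks number of blocks for the block-averaged standard error.
#' @param particle_role role to count.
#' @return object of class `occupancy_result`: `region`, `mean`, `se`,
#'   `rule`, `n_frames`.
#' @export
kinetic_occupancy <- function(tracks, geometry = NULL, region = "SF",
                              rule = c("all", "intracellular_entry_only"),
                              n_blocks = 5, particle_role = "ion") {
  rule <- match.arg(rule)
  geometry <- .tracks_geom(tracks, geometry)
  rng <- region_range(geometry, region)
  tr <- data.table::as.data.table(tracks)[role == particle_role]
  all_frames <- seq(min(tracks$frame), max(tracks$frame))
  if (nrow(tr) == 0 || !any(tr$z >= rng[1] & tr$z < rng[2])) {
    warning("no ", particle_role, " frames overlap region '", region, "'")
    return(structure(list(region = region, mean = 0, se = 0, rule = rule,
                          n_frames = length(all_frames)),
                     class = "occupancy_result"))
  }
  if (rule == "all") {
    inreg <- tr[z >= rng[1] & z < rng[2]]
  } else {
    inreg <- tr[, {
      inside <- z >= rng[1] & z < rng[2]
      r <- rle(inside)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      ok_run <- r$values & starts > 1L            # entry observed
      ok_run[which(ok_run)] <-
        z[starts[ok_run] - 1L] < rng[1]           # entered from below
      keep <- rep.int(ok_run, r$lengths)
      list(frame = frame[keep])
    }, by = particle_id]
  }
  cnt <- inreg[, .N, by = frame]
  counts <- integer(length(all_frames))
  counts[match(cnt$frame, all_frames)] <- cnt$N
  blocks <- cut(seq_along(counts), breaks = n_blocks, labels = FALSE)
  bm <- tapply(counts, blocks, mean)
  structure(list(region = region, mean = mean(counts),
                 se = stats::sd(bm) / sqrt(length(bm)), rule = rule,
                 n_frames = length(counts)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy(%s, %s) = %.3f +- %.3f (n = %d frames)\n",
              x$region, x$rule, x$mean, x$se, x$n_frames))
  invisible(x)
}

#' Water-to-ion co-permeation ratio with Wilson confidence interval
#'
#' Each ion permeation is treated as a Bernoulli trial for an accompanying
#' water co-permeation, giving a Wilson score interval for the ratio.
#'
#' @param water_events water permeation events (table from
#'   [detect_permeation_events()]) or a count.
#' @param ion_events ion permeation events (table) or a count; must be > 0.
#' @param conf confidence level.
#' @return list with `ratio`, `ci_lo`, `ci_hi`, `n_water`, `n_ion`.
#' @export
water_ion_ratio <- function(water_events, ion_events, conf = 0.95) {
  n_w <- if (is.data.frame(water_events)) nrow(water_events)
         else as.numeric(water_events)
  n_i <- if (is.data.frame(ion_events)) nrow(ion_events)
         else as.numeric(ion_events)
  if (n_i <= 0) stop("water-to-ion ratio undefined: zero ion events")
  p <- n_w / n_i
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + zq^2 / n_i
  ctr <- (p + zq^2 / (2 * n_i)) / den
  hw <- zq * sqrt(p * (1 - p) / n_i + zq^2 / (4 * n_i^2)) / den
  list(ratio = p, ci_lo = max(0, ctr - hw), ci_hi = ctr + hw,
       n_water = n_w, n_ion = n_i)
}

#' Axial number-density profile
#'
#' Histogram of per-frame axial positions.  In normalized mode the profile
#' peaks at 1 (profiles "each normalized to 1"); unnormalized, the profile
#' is a per-frame count density whose integral (sum x bin width) over a
#' range equals the mean occupancy of that range.
#'
#' @param tracks a track table.
#' @param geometry a [pore_geometry()] (default: tracks attribute).
#' @param bin_width bin width, A.
#' @param normalize logical.
#' @param particle_role role to histogram.
#' @param z_range numeric `c(lo, hi)`; default covers all sites.
#' @return data.frame with `z_mid` and `density`.
#' @export
axial_density <- function(tracks, geometry = NULL, bin_width = 0.5,
                          normalize = TRUE, particle_role = "ion",
                          z_range = NULL) {
  if (bin_width <= 0) stop("'bin_width' must be positive")
  geometry <- .tracks_geom(tracks, geometry)
  sb <- geometry$site_bounds
  if (is.null(z_range)) z_range <- c(sb$z_lo[1], sb$z_hi[nrow(sb)])
  tr <- data.table::as.data.table(tracks)[role == particle_role]
  n_frames <- length(unique(tracks$frame))
  breaks <- seq(z_range[1], z_range[2] + bin_width, by = bin_width)
  zz <- tr$z[tr$z >= breaks[1] & tr$z < breaks[length(breaks)]]
  cnt <- tabulate(findInterval(zz, breaks), nbins = length(breaks) - 1)
  dens <- if (normalize) {
    if (max(cnt) > 0) cnt / max(cnt) else cnt
  } else cnt / (n_frames * bin_width)
  data.frame(z_mid = breaks[-length(breaks)] + bin_width / 2,
             density = dens)
}

#' Ion residence times within a region
#'
#' One duration per maximal contiguous visit of a particle to the region's
#' axial extent; visits truncated by the trajectory ends are flagged
#' censored and excluded from the summary statistics.
#'
#' @param tracks a track table.
#' @param geometry a [pore_geometry()] (default: tracks attribute).
#' @param region region name.
#' @param particle_role role to analyse.
#' @return list with `visits` (data.table: `particle_id`, `t_start`,
#'   `t_end`, `duration`, `censored`), `mean`, `median` (us, uncensored
#'   visits).
#' @export
residence_times <- function(tracks, geometry = NULL, region,
                            particle_role = "ion") {
  geometry <- .tracks_geom(tracks, geometry)
  rng <- region_range(geometry, region)
  dt_us <- .tracks_dt_us(tracks)
  tr <- data.table::as.data.table(tracks)[role == particle_role]
  t_lo <- min(tracks$time_ns) / 1000
  t_hi <- max(tracks$time_ns) / 1000
  visits <- tr[, {
    inside <- z >= rng[1] & z < rng[2]
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    w <- which(r$values)
    list(t_start = time_ns[starts[w]] / 1000,
         t_end = time_ns[ends[w]] / 1000)
  }, by = particle_id]
  if (nrow(visits)) {
    visits[, `:=`(duration = t_end - t_start + dt_us,
                  censored = t_start <= t_lo + dt_us / 2 |
                             t_end >= t_hi - dt_us / 2)]
  } else {
    visits <- data.table::data.table(particle_id = character(0),
                                     t_start = numeric(0),
                                     t_end = numeric(0),
                                     duration = numeric(0),
                                     censored = logical(0))
  }
  ok <- visits$duration[!visits$censored]
  list(visits = visits[],
       mean = if (length(ok)) mean(ok) else NA_real_,
       median = if (length(ok)) stats::median(ok) else NA_real_)
}

#' Canonical knock-on configuration label
#'
#' Labels a selectivity-filter occupancy pattern in the standard knock-on
#' notation `A[B,C],D`: `A` is the lowest occupied site (incoming ion), `D`
#' the highest (outgoing), and `B,C` the two between, written in descending
#' site number (ascending z).  Reduced forms are used with fewer ions
#' (`"A[B],C"`, `"A,B"`, `"A"`), and the empty pattern is `"∅"`.
#'
#' @param occupied character vector of occupied site names among
#'   `S6...S0, S_ext` (each at most once), or a named 0/1 vector over those
#'   sites.
#' @return configuration string.
#' @examples
#' label_configuration(c("S6", "S4", "S2", "S1"))   # "S6[S4,S2],S1"
#' @export
label_configuration <- function(occupied) {
  site_order <- c(paste0("S", 6:0), "S_ext")   # ascending z
  if (!is.null(names(occupied)) && is.numeric(occupied)) {
    if (any(occupied > 1)) stop("invalid state: >1 ion in one SF site")
    occupied <- names(occupied)[occupied >= 1]
  }
  occupied <- as.character(occupied)
  if (anyDuplicated(occupied)) stop("invalid state: >1 ion in one SF site")
  unknown <- setdiff(occupied, site_order)
  if (length(unknown)) stop("unknown SF sites: ",
                            paste(unknown, collapse = ", "))
  s <- occupied[order(match(occupied, site_order))]  # ascending z
  n <- length(s)
  if (n == 0) return("∅")
  if (n == 1) return(s)
  if (n == 2) return(paste0(s[1], ",", s[2]))
  if (n == 3) return(sprintf("%s[%s],%s", s[1], s[2], s[3]))
  if (n == 4) return(sprintf("%s[%s,%s],%s", s[1], s[2], s[3], s[4]))
  sprintf("%s[%s],%s", s[1], paste(s[2:(n - 1)], collapse = ","), s[n])
}

#' Knock-on position histograms and configuration dwell fractions
#'
#' Per frame, ions inside the SF axial range are sorted by z.  The left
#' grid bins (z of the lowest ion, mean z of the two ions directly above
#' it); the right grid bins (z of the highest ion, mean z of the two ions
#' directly below it).  Frames with fewer than three SF-range ions are
#' skipped.  Per-frame configuration labels (over `S6...S0, S_ext`) with
#' dwell fractions are attached; frames where jitter makes site assignment
#' ambiguous (two ions in one site) are dropped from the dwell table.
#'
#' @param tracks a track table.
#' @param geometry a [pore_geometry()] (default: tracks attribute).
#' @param bin_width grid bin width, A.
#' @param particle_role role to analyse.
#' @return object of class `knockon_histogram`: list with `left`, `right`
#'   (count matrices, dimnames = bin lower edges), `bin_width`,
#'   `n_frames` (contributing frames per grid), `dwell` (data.frame:
#'   `label`, `fraction`, sorted descending).
#' @export
knockon_histogram <- function(tracks, geometry = NULL, bin_width = 0.5,
                              particle_role = "ion") {
  geometry <- .tracks_geom(tracks, geometry)
  sfr <- region_range(geometry, "SF")
  ext <- region_range(geometry, "S_ext")
  tr <- data.table::as.data.table(tracks)[role == particle_role]
  sf <- tr[z >= sfr[1] & z < sfr[2]]
  data.table::setorder(sf, frame, z)
  pts <- sf[, if (.N >= 3L)
    list(xl = z[1L], yl = (z[2L] + z[3L]) / 2,
         xr = z[.N], yr = (z[.N - 1L] + z[.N - 2L]) / 2),
    by = frame]
  grid_breaks <- seq(sfr[1], sfr[2] + bin_width, by = bin_width)
  bin2d <- function(x, y) {
    nb <- length(grid_breaks) - 1L
    m <- matrix(0L, nb, nb,
                dimnames = list(x = grid_breaks[-length(grid_breaks)],
                                y = grid_breaks[-length(grid_breaks)]))
    ix <- findInterval(x, grid_breaks, rightmost.closed = TRUE)
    iy <- findInterval(y, grid_breaks, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nb & iy >= 1 & iy <= nb
    for (k in which(ok)) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1L
    m
  }
  ## dwell labels from ions across SF + S_ext
  lab_tr <- tr[z >= sfr[1] & z < ext[2]]
  labs <- lab_tr[, {
    sites <- assign_site(z, geometry)
    if (anyDuplicated(sites)) list(label = NA_character_)
    else list(label = label_configuration(sites))
  }, by = frame]
  labs <- labs[!is.na(labs$label)]
  dwell <- if (nrow(labs)) {
    tb <- sort(table(labs$label), decreasing = TRUE)
    data.frame(label = names(tb), fraction = as.numeric(tb) / sum(tb))
  } else data.frame(label = character(0), fraction = numeric(0))
  structure(list(left = bin2d(pts$xl, pts$yl),
                 right = bin2d(pts$xr, pts$yr),
                 bin_width = bin_width, n_frames = nrow(pts),
                 dwell = dwell),
            class = "knockon_histogram")
}

#' @export
print.knockon_histogram <- function(x, ...) {
  cat(sprintf("knock-on histogram: %d contributing frames, %g-A bins\n",
              x$n_frames, x$bin_width))
  cat("top configurations:\n")
  print(utils::head(x$dwell, 6), row.names = FALSE)
  invisible(x)
}
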