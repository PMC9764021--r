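## Spermine blocker analysis: running-median smoothing, bind/unbind
## detection with hysteresis, censored exponential tau estimation, station
## classification, displaced-ion counts, block-modulated currents.

#' Blocker detection configuration
#'
#' Distance criteria for blocker binding and unbinding relative to the
#' rectification-controller landmark (D173 Calpha center of mass): bound
#' when the smoothed distance is at or below `d_on` (10 A), unbound when it
#' exceeds `d_off` (20 A), with a 30-ns running median.  The gap between the
#' two thresholds provides hysteresis, so no event fires while the smoothed
#' distance sits between them.
#'
#' @param d_on bind threshold, A.
#' @param d_off unbind threshold, A; must exceed `d_on`.
#' @param window_ns running-median window, ns.
#' @param landmark_id reference landmark particle id.
#' @return object of class `blocker_config`.
#' @export
blocker_config <- function(d_on = 10, d_off = 20, window_ns = 30,
                           landmark_id = "D173_COM") {
  if (!(d_off > d_on && d_on > 0)) stop("need d_off > d_on > 0")
  if (window_ns <= 0) stop("'window_ns' must be positive")
  structure(list(d_on = d_on, d_off = d_off, window_ns = window_ns,
                 landmark_id = landmark_id), class = "blocker_config")
}

#' Centered running median with truncated edge windows
#'
#' Interior points use a centered odd-length window of `round(w/dt) | 1`
#' frames; near the edges the window is truncated to the available samples
#' (no reflection -- no invented data at the boundaries).
#'
#' @param series numeric vector.
#' @param window_ns window width, ns; must be >= `dt_ns`.
#' @param dt_ns frame interval, ns.
#' @return smoothed numeric vector of the same length.
#' @export
running_median <- function(series, window_ns = 30, dt_ns = 1) {
  if (window_ns < dt_ns) stop("window must be at least one frame interval")
  k <- round(window_ns / dt_ns)
  if (k %% 2 == 0) k <- k + 1L
  n <- length(series)
  if (n == 0) return(series)
  if (k <= 1 || n == 1) return(series)
  if (k >= 2 * n) k <- (2 * (n %/% 2)) - 1L  # largest usable odd window
  if (k <= 1) return(series)
  h <- (k - 1L) %/% 2L
  out <- if (n >= k) stats::runmed(series, k, endrule = "keep")
         else series
  edge <- unique(c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n)))
  for (i in edge)
    out[i] <- stats::median(series[max(1L, i - h):min(n, i + h)])
  as.numeric(out)
}

#' Blocker-landmark distance series from tracks
#'
#' Smoothed 3-D distance between the blocker bead and the reference
#' landmark, ready for [detect_binding()] / [detect_unbinding()].
#'
#' @param tracks a track table containing the blocker (role `"blocker"`)
#'   and the landmark.
#' @param config a [blocker_config()].
#' @param blocker_id blocker particle id.
#' @return data.table with `frame`, `time_ns`, `distance` (raw, A),
#'   `smoothed` (running-median, A).
#' @export
blocker_distance_series <- function(tracks, config = blocker_config(),
                                    blocker_id = "SPM") {
  tr <- data.table::as.data.table(tracks)
  s <- tr[particle_id == blocker_id]
  l <- tr[particle_id == config$landmark_id]
  if (nrow(s) == 0) stop("blocker '", blocker_id, "' not in tracks")
  if (nrow(l) == 0) stop("landmark '", config$landmark_id,
                         "' not in tracks")
  m <- merge(s, l, by = "frame", suffixes = c("_s", "_l"))
  data.table::setorder(m, frame)
  d <- sqrt((m$x_s - m$x_l)^2 + (m$y_s - m$y_l)^2 + (m$z_s - m$z_l)^2)
  dt_ns <- attr(tracks, "dt_ns")
  if (is.null(dt_ns)) dt_ns <- min(diff(sort(unique(m$time_ns_s))))
  data.table::data.table(frame = m$frame, time_ns = m$time_ns_s,
                         distance = d,
                         smoothed = running_median(d, config$window_ns,
                                                   dt_ns))
}

#' First blocker binding time
#'
#' `t_on` is the first time the smoothed blocker-landmark distance is at or
#' below the bind threshold; censored at the series end if never.
#'
#' @param dist a series from [blocker_distance_series()] (or any table with
#'   `time_ns` and `smoothed`).
#' @param config a [blocker_config()].
#' @return list with `t_on` (us), `censored`, `censor_time` (us).
#' @export
detect_binding <- function(dist, config = blocker_config()) {
  i <- which(dist$smoothed <= config$d_on)
  if (length(i))
    list(t_on = dist$time_ns[i[1]] / 1000, censored = FALSE,
         censor_time = NA_real_)
  else
    list(t_on = NA_real_, censored = TRUE,
         censor_time = dist$time_ns[NROW(dist)] / 1000)
}

#' Blocker unbinding time measured from a block start
#'
#' `t_off` is the first time after `block_start` at which the smoothed
#' distance exceeds the unbind threshold, measured from `block_start`;
#' censored at the series end if never.  Excursions between `d_on` and
#' `d_off` produce no event (hysteresis).
#'
#' @param dist a series from [blocker_distance_series()].
#' @param config a [blocker_config()].
#' @param block_start block start time, us; must lie within the series.
#' @return list with `t_off` (us, from `block_start`), `censored`,
#'   `censor_time` (us from `block_start`).
#' @export
detect_unbinding <- function(dist, config = blocker_config(),
                             block_start = 0) {
  t_us <- dist$time_ns / 1000
  if (block_start > t_us[length(t_us)])
    stop("block start beyond series end")
  sel <- which(t_us >= block_start & dist$smoothed > config$d_off)
  if (length(sel))
    list(t_off = t_us[sel[1]] - block_start, censored = FALSE,
         censor_time = NA_real_)
  else
    list(t_off = NA_real_, censored = TRUE,
         censor_time = t_us[length(t_us)] - block_start)
}

#' Censored exponential maximum-likelihood time-constant estimate
#'
#' For exponentially distributed waiting times with right censoring the MLE
#' is total observed time (events plus censored durations) divided by the
#' number of uncensored events; the confidence interval follows from
#' `2 * n * tau_hat / tau ~ chi-squared(2 n)`.
#'
#' @param times observed (uncensored) event times, us.
#' @param censored censoring durations of replicates that never showed the
#'   event, us.
#' @param conf confidence level.
#' @return object of class `tau_estimate`: `tau`, `ci_lo`, `ci_hi`,
#'   `n_events`, `n_censored`; with zero uncensored events only a lower
#'   bound is returned (`tau = NA`, `lower_bound`).
#' @examples
#' estimate_tau(c(3, 5), censored = 10)   # (3+5+10)/2 = 9
#' @export
estimate_tau <- function(times, censored = numeric(0), conf = 0.95) {
  times <- times[!is.na(times)]
  censored <- censored[!is.na(censored)]
  total <- sum(times) + sum(censored)
  n <- length(times)
  if (n == 0) {
    return(structure(list(tau = NA_real_, ci_lo = NA_real_, ci_hi = Inf,
                          lower_bound = total /
                            (-log((1 - conf))),  # from P(no event)
                          n_events = 0L, n_censored = length(censored)),
                     class = "tau_estimate"))
  }
  tau <- total / n
  a <- (1 - conf) / 2
  structure(list(tau = tau,
                 ci_lo = 2 * total / stats::qchisq(1 - a, 2 * n),
                 ci_hi = 2 * total / stats::qchisq(a, 2 * n),
                 lower_bound = NA_real_,
                 n_events = n, n_censored = length(censored)),
            class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  if (is.na(x$tau))
    cat(sprintf("tau: no uncensored events (n_cens = %d); lower bound %.3g us\n",
                x$n_censored, x$lower_bound))
  else
    cat(sprintf("tau = %.3g us [%.3g, %.3g] (%d events, %d censored)\n",
                x$tau, x$ci_lo, x$ci_hi, x$n_events, x$n_censored))
  invisible(x)
}

#' Classify an axial blocker position into a binding station
#'
#' Band lookup along the axis with the same half-open convention as
#' [assign_site()].  The `above_D173` band lies between the D173 plane and
#' the bottom of the SF (the deep binding site above the rectification
#' controller); `SF` covers the filter itself; positions beyond the filter
#' are `translocated`; positions below the CTD are `bulk`.
#'
#' @param z axial position(s), A.
#' @param geometry a [pore_geometry()].
#' @param d173_z axial position of the D173 plane, A.
#' @return character vector of stations among `bulk`, `CTD`, `G_loop`,
#'   `cavity`, `above_D173`, `SF`, `translocated`.
#' @export
classify_station <- function(z, geometry = default_geometry(),
                             d173_z = -10) {
  ctd <- region_range(geometry, "CTD")
  gl <- region_range(geometry, "G_loop")
  sf <- region_range(geometry, "SF")
  breaks <- c(ctd[1], gl[1], gl[2], d173_z, sf[1], sf[2])
  bands <- c("bulk", "CTD", "G_loop", "cavity", "above_D173", "SF",
             "translocated")
  bands[findInterval(z, breaks) + 1L]
}

#' Ions displaced from the TM pore by deep blocker binding
#'
#' Count of ions inside the TM-pore region (cavity + SF by default) in the
#' frame just before the deep-binding time, minus the count at
#' `bind_time + window`, floored at zero.
#'
#' @param tracks a track table.
#' @param bind_time deep-binding time, us (e.g. from [detect_binding()]);
#'   `NA` raises an error (no binding, count undefined).
#' @param geometry a [pore_geometry()] (default: tracks attribute).
#' @param window settle window after binding, us.
#' @param pre_margin pre-binding margin, us: the "before" count is taken at
#'   `bind_time - pre_margin` so that the running-median detection lag
#'   (about half the smoothing window) cannot place the reference frame
#'   after the eviction itself.
#' @param region TM-pore region name.
#' @return list with `displaced`, `n_before`, `n_after`.
#' @export
displaced_ions <- function(tracks, bind_time, geometry = NULL,
                           window = 0.5, pre_margin = 0.05,
                           region = "TM_pore") {
  if (is.na(bind_time)) stop("displaced-ion count undefined: no binding")
  geometry <- .tracks_geom(tracks, geometry)
  rng <- region_range(geometry, region)
  tr <- data.table::as.data.table(tracks)[role == "ion"]
  t_us <- tr$time_ns / 1000
  t_max <- max(tracks$time_ns) / 1000
  t_after <- bind_time + window
  if (t_after > t_max) {
    warning("window extends past trajectory end; truncated")
    t_after <- t_max
  }
  count_at <- function(tt) {
    ft <- t_us[t_us <= tt]
    if (!length(ft)) return(0L)
    f <- max(ft)
    sum(abs(t_us - f) < 1e-9 & tr$z >= rng[1] & tr$z < rng[2])
  }
  before <- count_at(bind_time - pre_margin)
  after <- count_at(t_after)
  list(displaced = max(0L, before - after), n_before = before,
       n_after = after)
}

#' Currents over blocked and unblocked trajectory segments
#'
#' Splits the trajectory at the blocker bind/unbind times and computes the
#' current separately over bound and unbound time, attributing each
#' permeation event (by its exit time) to the segment it falls in.
#'
#' @param events ion permeation events ([detect_permeation_events()]).
#' @param bound_intervals two-column matrix or data.frame of
#'   (start, end) times, us, during which the blocker is bound; may be
#'   empty.
#' @param duration trajectory duration, us.
#' @param voltage voltage, mV.
#' @return list with `blocked` and `unblocked` `current_result`s (`NULL`
#'   when the corresponding time is zero) and `t_blocked`/`t_unblocked`
#'   (us).
#' @export
block_modulated_current <- function(events, bound_intervals, duration,
                                    voltage) {
  bi <- if (NROW(bound_intervals)) {
    m <- as.matrix(bound_intervals)[, 1:2, drop = FALSE]
    m[, 2] <- pmin(m[, 2], duration)
    m[m[, 1] < m[, 2], , drop = FALSE]
  } else matrix(numeric(0), ncol = 2)
  t_blocked <- sum(bi[, 2] - bi[, 1])
  t_unblocked <- duration - t_blocked
  in_block <- function(t) {
    if (nrow(bi) == 0) return(rep(FALSE, length(t)))
    rowSums(outer(t, bi[, 1], ">=") & outer(t, bi[, 2], "<")) > 0
  }
  isb <- in_block(events$t_exit)
  res <- function(ev, tt) {
    if (tt <= 0) return(NULL)
    current_and_conductance(ev, tt, voltage)
  }
  if (t_unblocked <= 0)
    warning("zero unbound time: unblocked current undefined")
  list(blocked = res(events[isb, ], t_blocked),
       unblocked = res(events[!isb, ], t_unblocked),
       t_blocked = t_blocked, t_unblocked = t_unblocked)
}
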