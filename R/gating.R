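## Gating analysis: gate geometry, cavity hydration, closure detection,
## survival statistics over replicates.

#' Activation-gate diagonal distance series
#'
#' Mean of the two subunit-diagonal Calpha-Calpha distances (pairing fixed
#' by subunit order: A-C and B-D) for one gate residue, per frame.
#'
#' @param tracks a track table containing four pseudo-atoms named
#'   `<residue>_A` ... `<residue>_D` (role `"gate"`).
#' @param residue residue label, e.g. `"I177"`.
#' @return data.table with `frame`, `time_ns`, `distance` (A).
#' @export
gate_diagonal_distance <- function(tracks, residue = "I177") {
  tr <- data.table::as.data.table(tracks)
  ids <- paste0(residue, "_", c("A", "B", "C", "D"))
  g <- tr[particle_id %in% ids]
  found <- unique(g$particle_id)
  if (length(found) != 4L)
    stop("invalid topology: expected 4 subunit copies ",
         paste(ids, collapse = ", "), ", found ", length(found))
  w <- data.table::dcast(g, frame + time_ns ~ particle_id,
                         value.var = c("x", "y", "z"))
  d2 <- function(a, b) {
    sqrt((w[[paste0("x_", a)]] - w[[paste0("x_", b)]])^2 +
         (w[[paste0("y_", a)]] - w[[paste0("y_", b)]])^2 +
         (w[[paste0("z_", a)]] - w[[paste0("z_", b)]])^2)
  }
  dAC <- d2(ids[1], ids[3])
  dBD <- d2(ids[2], ids[4])
  data.table::data.table(frame = w$frame, time_ns = w$time_ns,
                         distance = (dAC + dBD) / 2)
}

#' Cavity hydration series
#'
#' Per-frame count of water particles inside the cavity cylinder
#' (axial range and radius from the geometry).
#'
#' @param tracks a track table with water particles (role `"water"`).
#' @param geometry a [pore_geometry()] (default: tracks attribute).
#' @return data.table with `frame`, `time_ns`, `count`.
#' @export
cavity_hydration <- function(tracks, geometry = NULL) {
  geometry <- .tracks_geom(tracks, geometry)
  cyl <- geometry$cavity_cylinder
  tr <- data.table::as.data.table(tracks)
  wat <- tr[role == "water" & z >= cyl$z_lo & z < cyl$z_hi &
              (x^2 + y^2) <= cyl$radius^2]
  frames <- tr[, list(time_ns = time_ns[1]), by = frame]
  cnt <- wat[, .N, by = frame]
  out <- merge(frames, cnt, by = "frame", all.x = TRUE)
  out[is.na(out$N), "N"] <- 0L
  data.table::setnames(out, "N", "count")
  data.table::setorder(out, frame)
  out[]
}

#' Detect pore closure from a hydration series
#'
#' Closure is called at the first frame from which the cavity water count
#' stays at or below `threshold` for at least `persistence` consecutive
#' frames; otherwise the outcome is censored at the trajectory end.  With
#' `persistence = 1` this reduces to the first touch of the criterion.
#'
#' @param hydration data.table from [cavity_hydration()] (or any table with
#'   `time_ns` and `count`).
#' @param threshold closure criterion, waters (closure when the count is
#'   at or below this value; default 35).
#' @param persistence minimum run length below threshold, frames (>= 1).
#' @return object of class `closure_outcome`: `closed` (logical), `time`
#'   (closure time, us, or the censoring time), `censored`, `threshold`,
#'   `persistence`.
#' @export
detect_closure <- function(hydration, threshold = 35, persistence = 1) {
  if (NROW(hydration) == 0) stop("empty hydration series")
  if (persistence < 1) stop("'persistence' must be >= 1 frame")
  below <- hydration$count <= threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit)) {
    i <- starts[hit[1]]
    structure(list(closed = TRUE, time = hydration$time_ns[i] / 1000,
                   censored = FALSE, threshold = threshold,
                   persistence = persistence), class = "closure_outcome")
  } else {
    structure(list(closed = FALSE,
                   time = hydration$time_ns[NROW(hydration)] / 1000,
                   censored = TRUE, threshold = threshold,
                   persistence = persistence), class = "closure_outcome")
  }
}

#' @export
print.closure_outcome <- function(x, ...) {
  if (x$closed)
    cat(sprintf("pore closed at %.3g us (<=%g waters, %d-frame persistence)\n",
                x$time, x$threshold, x$persistence))
  else cat(sprintf("no closure; censored at %.3g us\n", x$time))
  invisible(x)
}

#' Closure statistics across replicates
#'
#' Kaplan-Meier survival handling of censored replicates.  The median
#' closure time is read from the survival estimate; when the estimate never
#' reaches 0.5 the median is reported as a lower bound (`> T_max`).  Also
#' returns the fraction-closed-vs-time curve.
#'
#' @param outcomes list of `closure_outcome` objects (or a data.frame with
#'   `time` and `censored`).
#' @return list with `median` (us, `NA` when undefined), `median_lower_bound`
#'   (us; equals the largest observation when the median is undefined),
#'   `median_defined`, `n`, `n_closed`, and `curve` (data.frame: `time`,
#'   `fraction_closed`).
#' @export
closure_statistics <- function(outcomes) {
  if (inherits(outcomes, "closure_outcome")) outcomes <- list(outcomes)
  if (is.data.frame(outcomes)) {
    times <- outcomes$time; cens <- outcomes$censored
  } else {
    if (length(outcomes) < 1) stop("need at least one closure outcome")
    times <- vapply(outcomes, `[[`, 1, "time")
    cens <- vapply(outcomes, `[[`, TRUE, "censored")
  }
  fit <- survival::survfit(survival::Surv(times, !cens) ~ 1)
  med <- unname(summary(fit)$table["median"])
  curve <- data.frame(time = fit$time, fraction_closed = 1 - fit$surv)
  list(median = med,
       median_lower_bound = if (is.na(med)) max(times) else med,
       median_defined = !is.na(med),
       n = length(times), n_closed = sum(!cens), curve = curve)
}

#' CTD-SF center-of-mass separation series
#'
#' Euclidean distance between two landmark pseudo-atoms per frame.
#'
#' @param tracks a track table.
#' @param ctd_id,sf_id landmark particle ids.
#' @return data.table with `frame`, `time_ns`, `distance` (A).
#' @export
ctd_sf_separation <- function(tracks, ctd_id = "CTD_COM", sf_id = "SF_COM") {
  tr <- data.table::as.data.table(tracks)
  a <- tr[particle_id == ctd_id]
  b <- tr[particle_id == sf_id]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("landmark(s) not found: ", ctd_id, " / ", sf_id)
  m <- merge(a, b, by = "frame", suffixes = c("_a", "_b"))
  data.table::data.table(frame = m$frame, time_ns = m$time_ns_a,
                         distance = sqrt((m$x_a - m$x_b)^2 +
                                         (m$y_a - m$y_b)^2 +
                                         (m$z_a - m$z_b)^2))
}

#' Per-frame minimum cross-pair distance between two selections
#'
#' For each frame, the minimum over all cross pairs of the two particle
#' selections (e.g. closest approach between R/K-region residues and an
#' acidic partner).
#'
#' @param tracks a track table.
#' @param sel_a,sel_b character vectors of particle ids; must be non-empty
#'   and present in the tracks.
#' @return data.table with `frame`, `time_ns`, `distance` (A).
#' @export
contact_distances <- function(tracks, sel_a, sel_b) {
  if (length(sel_a) == 0 || length(sel_b) == 0)
    stop("empty selection")
  tr <- data.table::as.data.table(tracks)
  a <- tr[particle_id %in% sel_a]
  b <- tr[particle_id %in% sel_b]
  if (nrow(a) == 0 || nrow(b) == 0) stop("selection matches no particles")
  m <- merge(a[, list(frame, time_ns, particle_id, x, y, z)],
             b[, list(frame, particle_id, x, y, z)],
             by = "frame", allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  d <- m[, list(time_ns = time_ns[1],
                distance = min(sqrt((x_a - x_b)^2 + (y_a - y_b)^2 +
                                    (z_a - z_b)^2))),
         by = frame]
  data.table::setorder(d, frame)
  d[]
}
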