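## Trajectory and log I/O: track tables (TSV), ground-truth event logs
## (JSON lines), and PDB topology / multi-model coordinate interop via
## bio3d (which also reads DCD coordinate series for real trajectories).

.role_resid <- c(ion = "POT", water = "HOH", blocker = "SPM",
                 gate = "GAT", landmark = "LMK")

#' Write / read a track table
#'
#' The track table is the canonical text trajectory format: one row per
#' particle per frame with columns `frame`, `time_ns`, `particle_id`,
#' `role`, `x`, `y`, `z` (tab-separated).
#'
#' @param tracks a track table.
#' @param path file path.
#' @return `write_track_table`: the path, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  if (NROW(tracks) == 0) stop("empty track table")
  cols <- c("frame", "time_ns", "particle_id", "role", "x", "y", "z")
  stopifnot(all(cols %in% names(tracks)))
  data.table::fwrite(data.table::as.data.table(tracks)[, cols, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_track_table
#' @param geometry a [pore_geometry()] to attach (default:
#'   [default_geometry()]).
#' @return `read_track_table`: a track table (`kir_tracks`).
#' @export
read_track_table <- function(path, geometry = default_geometry()) {
  tr <- data.table::fread(path, sep = "\t")
  cols <- c("frame", "time_ns", "particle_id", "role", "x", "y", "z")
  if (!all(cols %in% names(tr)))
    stop("not a track table: need columns ", paste(cols, collapse = ", "))
  data.table::setorder(tr, frame, particle_id)
  tt <- sort(unique(tr$time_ns))
  data.table::setattr(tr, "dt_ns",
                      if (length(tt) > 1) min(diff(tt)) else NA_real_)
  data.table::setattr(tr, "geometry", geometry)
  data.table::setattr(tr, "class", c("kir_tracks", class(tr)))
  tr[]
}

#' Write / read a ground-truth event log (JSON lines)
#'
#' One JSON object per line.  The first line is a `meta` record (duration,
#' voltage, seed, closure time); `init` records give the initial particle
#' placements; the remaining records are the simulation events in time
#' order.
#'
#' @param sim a `kir_sim`.
#' @param path file path.
#' @return `write_event_log`: the path, invisibly.
#' @export
write_event_log <- function(sim, path) {
  stopifnot(inherits(sim, "kir_sim"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(record = "meta", duration = sim$duration,
               voltage = sim$voltage, seed = sim$seed,
               closure_time = sim$closure_time)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"), con)
  if (nrow(sim$init))
    jsonlite::stream_out(cbind(record = "init", as.data.frame(sim$init)),
                         con, digits = NA, verbose = FALSE)
  if (nrow(sim$log))
    jsonlite::stream_out(cbind(record = "event", as.data.frame(sim$log)),
                         con, digits = NA, verbose = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @return `read_event_log`: list with `meta`, `init` (data.table), `log`
#'   (data.table).
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  rest <- if (length(lines) > 1) {
    jsonlite::stream_in(textConnection(lines[-1]), verbose = FALSE)
  } else data.frame(record = character(0))
  init <- rest[rest$record == "init",
               intersect(c("particle", "site", "role"), names(rest))]
  log <- rest[rest$record == "event",
              intersect(c("time", "kind", "particle", "from", "to"),
                        names(rest))]
  list(meta = meta, init = data.table::as.data.table(init),
       log = data.table::as.data.table(log))
}

## wide per-particle coordinate matrices (frames x particles), carrying
## positions forward/backward over frames where a particle is not rendered
.tracks_wide <- function(tracks) {
  tr <- data.table::as.data.table(tracks)
  info <- tr[, list(role = role[1]), by = particle_id]
  frames <- sort(unique(tr$frame))
  fill <- function(v) data.table::nafill(data.table::nafill(v, "locf"),
                                         "nocb")
  wide <- lapply(c("x", "y", "z"), function(cc) {
    w <- data.table::dcast(tr, frame ~ particle_id, value.var = cc)
    data.table::setcolorder(w, c("frame", info$particle_id))
    m <- as.matrix(w[, -1])
    apply(m, 2, fill)
  })
  names(wide) <- c("x", "y", "z")
  list(info = info, frames = frames, wide = wide)
}

#' Write a trajectory bundle to disk
#'
#' Emits the full text bundle for a rendered trajectory: a PDB topology
#' (one pseudo-atom per particle, role encoded in the residue name), a
#' multi-model PDB coordinate series, the track table (TSV) and the
#' ground-truth event log (JSON lines).  PDB output uses bio3d.
#'
#' @param sim a `kir_sim` (for the event log; pass `NULL` to skip).
#' @param tracks a rendered track table with at least one frame.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param coordinates write the (potentially large) multi-model coordinate
#'   PDB.
#' @return named character vector of the paths written.
#' @export
write_trajectory <- function(sim, tracks, dir, prefix = "traj",
                             coordinates = TRUE) {
  if (NROW(tracks) == 0) stop("empty trajectory bundle (0 frames)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracks = file.path(dir, paste0(prefix, "_tracks.tsv")))
  write_track_table(tracks, paths[["tracks"]])
  if (!is.null(sim)) {
    paths[["events"]] <- file.path(dir, paste0(prefix, "_events.jsonl"))
    write_event_log(sim, paths[["events"]])
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    warning("bio3d not available: skipping PDB topology/coordinates")
    return(paths)
  }
  tw <- .tracks_wide(tracks)
  n_at <- nrow(tw$info)
  resid <- unname(.role_resid[tw$info$role])
  resid[is.na(resid)] <- "UNK"
  elety <- c(POT = "K", HOH = "O", SPM = "N", GAT = "CA", LMK = "CA",
             UNK = "C")[resid]
  paths[["topology"]] <- file.path(dir, paste0(prefix, "_top.pdb"))
  xyz1 <- as.numeric(rbind(tw$wide$x[1, ], tw$wide$y[1, ], tw$wide$z[1, ]))
  bio3d::write.pdb(file = paths[["topology"]], xyz = xyz1,
                   resno = seq_len(n_at), resid = resid,
                   elety = unname(elety), chain = rep("A", n_at))
  if (coordinates) {
    nf <- length(tw$frames)
    xyz <- matrix(0, nrow = nf, ncol = 3 * n_at)
    xyz[, seq(1, 3 * n_at, 3)] <- tw$wide$x
    xyz[, seq(2, 3 * n_at, 3)] <- tw$wide$y
    xyz[, seq(3, 3 * n_at, 3)] <- tw$wide$z
    paths[["coordinates"]] <- file.path(dir, paste0(prefix, "_coords.pdb"))
    bio3d::write.pdb(file = paths[["coordinates"]], xyz = xyz,
                     resno = seq_len(n_at), resid = resid,
                     elety = unname(elety), chain = rep("A", n_at))
  }
  paths
}

#' Read a molecular trajectory into a track table
#'
#' Reads a PDB topology plus a coordinate series (multi-model PDB or DCD,
#' via bio3d) and converts it to the long-format track table used by all
#' analyzers.  Particle roles are decoded from residue names
#' (`POT` ion, `HOH` water, `SPM` blocker, `GAT` gate, `LMK` landmark;
#' anything else `"other"`).
#'
#' @param topology PDB topology path.
#' @param coordinates coordinate series path (`.pdb` multi-model or
#'   `.dcd`); `NULL` uses the topology's own model(s).
#' @param geometry a [pore_geometry()] attached to the result.
#' @param dt_ns frame interval, ns.
#' @return a track table (`kir_tracks`).
#' @export
read_trajectory <- function(topology, coordinates = NULL,
                            geometry = default_geometry(), dt_ns = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("bio3d is required to read PDB/DCD trajectories")
  top <- bio3d::read.pdb(topology, multi = TRUE)
  xyz <- if (is.null(coordinates)) {
    top$xyz
  } else if (grepl("\\.dcd$", coordinates, ignore.case = TRUE)) {
    bio3d::read.dcd(coordinates)
  } else {
    bio3d::read.pdb(coordinates, multi = TRUE)$xyz
  }
  xyz <- as.matrix(xyz)
  n_at <- nrow(top$atom)
  if (ncol(xyz) != 3 * n_at)
    stop("coordinate/topology atom-count mismatch")
  rev_role <- c(POT = "ion", HOH = "water", SPM = "blocker",
                GAT = "gate", LMK = "landmark")
  roles <- rev_role[top$atom$resid]
  roles[is.na(roles)] <- "other"
  pid <- paste0(tolower(top$atom$resid), top$atom$resno)
  pid[roles == "blocker"] <- "SPM"
  nf <- nrow(xyz)
  xs <- xyz[, seq(1, 3 * n_at, 3), drop = FALSE]
  ys <- xyz[, seq(2, 3 * n_at, 3), drop = FALSE]
  zs <- xyz[, seq(3, 3 * n_at, 3), drop = FALSE]
  tr <- data.table::data.table(
    frame = rep(seq_len(nf), each = n_at),
    time_ns = rep((seq_len(nf) - 1) * dt_ns, each = n_at),
    particle_id = rep(pid, nf),
    role = rep(unname(roles), nf),
    x = as.numeric(t(xs)), y = as.numeric(t(ys)), z = as.numeric(t(zs)))
  ## project onto the pore axis (z column holds the axial coordinate)
  proj <- project_to_axis(as.matrix(tr[, c("x", "y", "z")]), geometry)
  tr$z <- proj
  data.table::setorder(tr, frame, particle_id)
  data.table::setattr(tr, "dt_ns", dt_ns)
  data.table::setattr(tr, "geometry", geometry)
  data.table::setattr(tr, "class", c("kir_tracks", class(tr)))
  tr[]
}
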