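#' Backbone torsional correction for selectivity-filter stabilization
#'
#' Long unbiased simulations of K+ channels can show unphysical backbone
#' rotations in the selectivity filter (SF).  A CMAP-style per-dihedral
#' additive correction counteracts this by lowering the backbone torsional
#' potential at the crystallographic minimum theta0 by a depth `A`
#' (kcal/mol), relative to its value at theta0 + 180 deg.  The correction
#' used here is a single cosine well,
#' \deqn{\Delta E(\theta) = -\frac{A}{2}\,(1 + \cos(\theta - \theta_0)),}
#' which satisfies \eqn{\Delta E(\theta_0) - \Delta E(\theta_0+180) = -A}
#' exactly, is periodic (360 deg), even about theta0, and bounded in
#' `[-A, 0]`.
#'
#' @param theta dihedral angle(s), degrees.
#' @param theta0 reference (crystallographic minimum) angle, degrees.
#' @param A well depth, kcal/mol; must be > 0.
#' @return correction energy, kcal/mol.
#' @examples
#' correction_energy(-60, -60, 4.6)   # -4.6
#' correction_energy(120, -60, 4.6)   #  0
#' @export
correction_energy <- function(theta, theta0, A = 4.6) {
  if (A <= 0) stop("'A' must be positive (kcal/mol)")
  -(A / 2) * (1 + cos((theta - theta0) * pi / 180))
}

#' Torsional-correction specification
#'
#' Describes which residues and dihedral kinds receive the correction.  The
#' full variant applies phi and psi corrections to the five SF residues
#' (default 143-147); the reduced variant applies phi-only corrections to
#' the two SF glycines (145 and 147).
#'
#' @param residues integer residue ids.
#' @param dihedrals character vector, subset of `c("phi", "psi")`, applied to
#'   every residue.
#' @param theta0 named numeric vector of reference angles (degrees) with
#'   names `"<residue>_<dihedral>"` (e.g. `"145_phi"`), one per table; angles
#'   must lie in `[-180, 180)`.
#' @param depth well depth A, kcal/mol.
#' @param grid_spacing grid spacing, degrees; must divide 360.
#' @param variant `"full"` (phi+psi on `residues`) or `"reduced"` (phi-only
#'   on glycines 145/147); when given, `residues`/`dihedrals` defaults are
#'   set accordingly.
#' @return object of class `torsional_correction`.
#' @export
torsional_correction <- function(residues = 143:147,
                                 dihedrals = c("phi", "psi"),
                                 theta0 = NULL,
                                 depth = 4.6,
                                 grid_spacing = 15,
                                 variant = c("full", "reduced")) {
  variant <- match.arg(variant)
  if (variant == "reduced") {
    residues <- c(145L, 147L)
    dihedrals <- "phi"
  }
  if (depth <= 0) stop("'depth' must be positive")
  if (!all(dihedrals %in% c("phi", "psi"))) stop("dihedrals must be phi/psi")
  if (360 %% grid_spacing != 0)
    stop("'grid_spacing' must divide 360 degrees")
  keys <- as.vector(outer(residues, dihedrals, paste, sep = "_"))
  if (!is.null(theta0)) {
    if (any(theta0 < -180 | theta0 >= 180))
      stop("theta0 angles must lie in [-180, 180)")
  }
  structure(list(residues = residues, dihedrals = dihedrals, keys = keys,
                 theta0 = theta0, depth = depth,
                 grid_spacing = grid_spacing, variant = variant),
            class = "torsional_correction")
}

#' Build per-dihedral correction grid tables
#'
#' Tabulates the correction energy on a periodic grid covering
#' `[-180, 180)` for every residue/dihedral in the specification.
#'
#' @param spec a [torsional_correction()]; `spec$theta0` must supply a
#'   reference angle for every required dihedral (names like `"145_phi"`).
#' @return named list of data.frames with columns `theta` (deg) and
#'   `dE` (kcal/mol), one per dihedral.
#' @export
build_correction_tables <- function(spec) {
  stopifnot(inherits(spec, "torsional_correction"))
  th0 <- spec$theta0
  missing <- setdiff(spec$keys, names(th0))
  if (length(missing))
    stop("missing theta0 for: ", paste(missing, collapse = ", "))
  grid <- seq(-180, 180 - spec$grid_spacing, by = spec$grid_spacing)
  out <- lapply(spec$keys, function(k) {
    data.frame(theta = grid,
               dE = correction_energy(grid, th0[[k]], spec$depth))
  })
  names(out) <- spec$keys
  out
}

#' Write correction tables as a CHARMM-stream-style patch and CSV grid
#'
#' @param tables output of [build_correction_tables()].
#' @param stream_path path for the stream-style text patch (or `NULL` to
#'   skip).
#' @param csv_path path for a long-format CSV grid (or `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_correction_patch <- function(tables, stream_path = NULL,
                                   csv_path = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1)
  written <- character(0)
  if (!is.null(stream_path)) {
    con <- file(stream_path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("* Backbone torsional correction patch",
                 "* One block per residue/dihedral; energies in kcal/mol",
                 "*"), con)
    for (k in names(tables)) {
      tb <- tables[[k]]
      writeLines(sprintf("DIHEDRAL_CORRECTION %s  npoints %d  spacing %g",
                         k, nrow(tb), tb$theta[2] - tb$theta[1]), con)
      writeLines(sprintf("%10.3f %12.6f", tb$theta, tb$dE), con)
      writeLines("END", con)
    }
    written <- c(written, stream_path)
  }
  if (!is.null(csv_path)) {
    long <- do.call(rbind, lapply(names(tables), function(k) {
      cbind(data.frame(dihedral = k), tables[[k]])
    }))
    utils::write.csv(long, csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}
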