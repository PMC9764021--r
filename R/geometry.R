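#' Pore geometry: axis convention, site intervals, and named regions
#'
#' Defines the shared coordinate frame of the extended pore.  Axial position
#' z increases from the intracellular side (cytoplasmic domain, CTD) toward
#' the extracellular bulk.  Sites occupy contiguous half-open intervals
#' `[z_lo, z_hi)`; at an interval boundary the upper site wins, so assignment
#' is deterministic with no double counting.
#'
#' The default synthetic geometry anchors selectivity-filter (SF) site S4 at
#' z = 0 with 3.3-A site spacing (canonical K+ channel site spacing): S6 at
#' -6.6, S0 at +13.2 (interval lower bounds), preceded by the cavity
#' `[-20, -6.6)`, G-loop `[-30, -20)` and CTD `[-55, -30)`, and followed by
#' S_ext `[16.5, 25)`.  z below/above all sites is bulk_in/bulk_out.
#'
#' @param site_bounds data.frame with columns `site`, `z_lo`, `z_hi` (A),
#'   ordered and contiguous in z.
#' @param axis_origin 3-vector, A.
#' @param axis_direction unit 3-vector pointing intracellular to
#'   extracellular.
#' @param cavity_cylinder list `(z_lo, z_hi, radius)` in A, the cylinder used
#'   for cavity-hydration counting.
#' @param region_groups named list mapping composite region names to site
#'   vectors (e.g. `SF = c("S6", ..., "S0")`).  Every individual site is also
#'   addressable as its own region.
#' @return object of class `pore_geometry`.
#' @seealso [default_geometry()], [assign_site()], [project_to_axis()]
#' @export
pore_geometry <- function(site_bounds,
                          axis_origin = c(0, 0, 0),
                          axis_direction = c(0, 0, 1),
                          cavity_cylinder = list(z_lo = -20, z_hi = 0, radius = 8),
                          region_groups = NULL) {
  sb <- as.data.frame(site_bounds, stringsAsFactors = FALSE)
  stopifnot(all(c("site", "z_lo", "z_hi") %in% names(sb)))
  if (nrow(sb) < 1) stop("need at least one site")
  if (anyDuplicated(sb$site)) stop("duplicate site names")
  if (any(sb$z_hi <= sb$z_lo)) stop("each site needs z_hi > z_lo")
  if (nrow(sb) > 1) {
    gaps <- sb$z_lo[-1] - sb$z_hi[-nrow(sb)]
    if (any(abs(gaps) > 1e-9))
      stop("site_bounds must be contiguous and strictly increasing in z")
  }
  if (abs(sqrt(sum(axis_direction^2)) - 1) > 1e-9)
    stop("axis_direction must have unit norm (within 1e-9)")
  if (length(axis_origin) != 3 || length(axis_direction) != 3)
    stop("axis_origin and axis_direction must be 3-vectors")
  groups <- region_groups
  if (is.null(groups)) {
    groups <- list()
    if (all(c("S6", "S0") %in% sb$site))
      groups$SF <- sb$site[match("S6", sb$site):match("S0", sb$site)]
    if (!is.null(groups$SF) && "cavity" %in% sb$site)
      groups$TM_pore <- c("cavity", groups$SF)
    groups$extended_pore <- sb$site
  }
  for (g in names(groups)) {
    miss <- setdiff(groups[[g]], sb$site)
    if (length(miss))
      stop("region group '", g, "' names unknown sites: ",
           paste(miss, collapse = ", "))
    idx <- match(groups[[g]], sb$site)
    if (length(idx) > 1 && any(diff(sort(idx)) != 1))
      stop("region group '", g, "' must be a contiguous run of sites")
  }
  structure(list(site_bounds = sb,
                 axis_origin = as.numeric(axis_origin),
                 axis_direction = as.numeric(axis_direction),
                 cavity_cylinder = cavity_cylinder,
                 region_groups = groups),
            class = "pore_geometry")
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat("Pore geometry:", nrow(x$site_bounds), "sites, z in [",
      x$site_bounds$z_lo[1], ",", x$site_bounds$z_hi[nrow(x$site_bounds)],
      ") A\n")
  print(x$site_bounds, row.names = FALSE)
  invisible(x)
}

#' Default synthetic pore geometry
#'
#' @param site_spacing SF site width, A.
#' @return a `pore_geometry`.
#' @export
default_geometry <- function(site_spacing = 3.3) {
  s <- site_spacing
  sf_lo <- -2 * s  # S6 lower bound at -6.6 for spacing 3.3
  sf_sites <- paste0("S", 6:0)
  sb <- rbind(
    data.frame(site = "CTD",    z_lo = -55, z_hi = -30),
    data.frame(site = "G_loop", z_lo = -30, z_hi = -20),
    data.frame(site = "cavity", z_lo = -20, z_hi = sf_lo),
    data.frame(site = sf_sites,
               z_lo = sf_lo + s * (0:6),
               z_hi = sf_lo + s * (1:7)),
    data.frame(site = "S_ext",  z_lo = sf_lo + 7 * s, z_hi = 25)
  )
  pore_geometry(sb)
}

#' Project Cartesian coordinates onto the pore axis
#'
#' z = (coords - axis_origin) . axis_direction, increasing toward the
#' extracellular side.
#'
#' @param coords numeric 3-vector or n x 3 matrix, A.
#' @param geometry a [pore_geometry()].
#' @return numeric vector of axial positions, A.
#' @export
project_to_axis <- function(coords, geometry) {
  stopifnot(inherits(geometry, "pore_geometry"))
  m <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  if (ncol(m) != 3) stop("coords must be a 3-vector or n x 3 matrix")
  drop(sweep(m, 2, geometry$axis_origin) %*% geometry$axis_direction)
}

#' Assign axial positions to pore sites
#'
#' Half-open interval lookup `[z_lo, z_hi)`: at a shared boundary the upper
#' site wins.  Positions below the first site map to `"bulk_in"`, at or above
#' the last boundary to `"bulk_out"`.
#'
#' @param z numeric vector of axial positions, A.
#' @param geometry a [pore_geometry()].
#' @return character vector of site names.
#' @export
assign_site <- function(z, geometry) {
  stopifnot(inherits(geometry, "pore_geometry"))
  sb <- geometry$site_bounds
  breaks <- c(sb$z_lo, sb$z_hi[nrow(sb)])
  idx <- findInterval(z, breaks, left.open = FALSE, rightmost.closed = FALSE)
  out <- character(length(z))
  out[idx == 0] <- "bulk_in"
  out[idx == length(breaks)] <- "bulk_out"
  inside <- idx >= 1 & idx < length(breaks)
  out[inside] <- sb$site[idx[inside]]
  out
}

#' Axial extent of a named region
#'
#' A region is a single site, one of the composite groups defined in the
#' geometry (e.g. `"SF"`, `"TM_pore"`), or `"bulk_in"`/`"bulk_out"`.
#'
#' @param geometry a [pore_geometry()].
#' @param region region name.
#' @return numeric `c(z_lo, z_hi)`; half-open, bulk regions are unbounded on
#'   one side.
#' @export
region_range <- function(geometry, region) {
  stopifnot(inherits(geometry, "pore_geometry"))
  sb <- geometry$site_bounds
  if (region %in% names(geometry$region_groups)) {
    sites <- geometry$region_groups[[region]]
    idx <- match(sites, sb$site)
    return(c(min(sb$z_lo[idx]), max(sb$z_hi[idx])))
  }
  if (region %in% sb$site) {
    i <- match(region, sb$site)
    return(c(sb$z_lo[i], sb$z_hi[i]))
  }
  if (region == "bulk_in") return(c(-Inf, sb$z_lo[1]))
  if (region == "bulk_out") return(c(sb$z_hi[nrow(sb)], Inf))
  stop("unknown region: ", region)
}

## Site interval midpoint (anchor used when rendering frames)
.site_anchor <- function(geometry, site) {
  sb <- geometry$site_bounds
  i <- match(site, sb$site)
  if (is.na(i)) {
    if (site == "bulk_in") return(sb$z_lo[1] - 5)
    if (site == "bulk_out") return(sb$z_hi[nrow(sb)] + 5)
    stop("unknown site: ", site)
  }
  (sb$z_lo[i] + sb$z_hi[i]) / 2
}

#' Default residue selections for real-trajectory analysis of cKir2.2
#'
#' Label -> residue-number selections for the landmarks used by the
#' analyzers: activation-gate residues, the rectification controller, the SF
#' backbone, the CTD ring, interfacial-helix acidic residues, the R/K-rich
#' region, and the CTD reference residues.  In tetramer mode each label is
#' expected to resolve to exactly four subunit copies.
#'
#' @return named list of integer residue-number vectors.
#' @export
residue_map <- function() {
  list(gate         = c(I177 = 177L, M181 = 181L, S174 = 174L),
       rect_controller = c(D173 = 173L),
       sf_backbone  = 144:148,
       ctd_ring     = c(E225 = 225L, E300 = 300L, R261 = 261L, E304 = 304L),
       ih           = c(D69 = 69L, D76 = 76L),
       rk_region    = c(R78 = 78L, R80 = 80L, K183 = 183L, R186 = 186L,
                        K188 = 188L, K189 = 189L),
       ctd_reference = c(R219 = 219L, K220 = 220L))
}
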