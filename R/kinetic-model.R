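#' Kinetic model of single-file ion transport through the extended pore
#'
#' Generative specification for the synthetic-trajectory simulator: a
#' continuous-time Markov hopping model over the compartment chain
#' `bulk_in - CTD - G_loop - cavity - S6 ... S0 - S_ext - bulk_out` with site
#' exclusion (per-compartment capacities), voltage-biased rates, and
#' stochastic water co-permeation.
#'
#' Each edge carries base rates `k_fwd0`/`k_bwd0` (us^-1, at V = 0) and a
#' voltage coupling `delta`, the fraction of the total membrane voltage that
#' drops across the edge; the couplings over the intracellular-to-
#' extracellular path must sum to 1.  At voltage V the rates become
#' `k_fwd0 * exp(+z_q*delta*u/2)` and `k_bwd0 * exp(-z_q*delta*u/2)` with
#' `u = (V/43.3641)/(R*T)` (a symmetric Eyring barrier; z_q = +1 for K+).
#'
#' @param geometry a [pore_geometry()]; the compartment chain is its site
#'   sequence plus the two bulk reservoirs.
#' @param capacities named integer vector of per-compartment maximum
#'   occupancies; defaults: SF sites and S_ext 1, cavity 4, CTD 4, G_loop 1.
#' @param edges data.frame with columns `from`, `to`, `k_fwd0`, `k_bwd0`,
#'   `delta` for every adjacent compartment pair (in chain order).  If
#'   `NULL`, a uniform template with zero rates is built (useful as a
#'   skeleton).
#' @param voltage membrane voltage, mV.
#' @param temperature temperature, K.
#' @param water_coperm_prob probability that one water marker co-permeates
#'   per completed outward ion permeation (Bernoulli per event).
#' @param mechanism_constrained if `TRUE`, SF dynamics follow the concerted
#'   four-state knock-on cycle instead of free single-ion hops (see
#'   [simulate_pore()]).
#' @return object of class `kinetic_model`.
#' @export
kinetic_model <- function(geometry = default_geometry(),
                          capacities = NULL,
                          edges = NULL,
                          voltage = 0,
                          temperature = 310,
                          water_coperm_prob = 0.22,
                          mechanism_constrained = FALSE) {
  stopifnot(inherits(geometry, "pore_geometry"))
  chain <- c("bulk_in", geometry$site_bounds$site, "bulk_out")
  caps <- setNames(rep(1L, length(chain)), chain)
  caps[c("bulk_in", "bulk_out")] <- NA_integer_  # unbounded reservoirs
  if ("CTD" %in% chain) caps["CTD"] <- 4L
  if ("cavity" %in% chain) caps["cavity"] <- 4L
  if (!is.null(capacities)) {
    unknown <- setdiff(names(capacities), chain)
    if (length(unknown)) stop("unknown compartments: ",
                              paste(unknown, collapse = ", "))
    caps[names(capacities)] <- as.integer(capacities)
  }
  if (any(caps[!is.na(caps)] < 1L)) stop("all capacities must be >= 1")
  if (is.null(edges)) {
    edges <- data.frame(from = chain[-length(chain)], to = chain[-1],
                        k_fwd0 = 0, k_bwd0 = 0,
                        delta = 0, stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "k_fwd0", "k_bwd0", "delta") %in% names(edges)))
  want <- paste(chain[-length(chain)], chain[-1], sep = "->")
  got <- paste(edges$from, edges$to, sep = "->")
  if (!identical(sort(want), sort(got)))
    stop("edges must cover every adjacent compartment pair exactly once")
  edges <- edges[match(want, got), ]
  rownames(edges) <- NULL
  if (any(edges$k_fwd0 < 0 | edges$k_bwd0 < 0)) stop("rates must be >= 0")
  if (abs(sum(edges$delta) - 1) > 1e-9 && any(edges$k_fwd0 > 0))
    stop("voltage couplings must sum to 1 over the transmembrane path ",
         "(got ", sum(edges$delta), ")")
  if (water_coperm_prob < 0 || water_coperm_prob > 1)
    stop("'water_coperm_prob' must be in [0, 1]")
  structure(list(geometry = geometry, chain = chain, capacities = caps,
                 edges = edges, voltage = voltage, temperature = temperature,
                 water_coperm_prob = water_coperm_prob,
                 mechanism_constrained = isTRUE(mechanism_constrained)),
            class = "kinetic_model")
}

#' Two-state gate model
#'
#' Open/closed pore gate with an absorbing closure hazard.  While open, the
#' per-frame cavity hydration is drawn from the open Gaussian and gate
#' diagonal distances from the open-distance Gaussian; after the (exponential
#' with rate `closure_rate`) closure event, the closed distributions apply
#' and hops across the gate edge (G_loop <-> cavity) stop.  Closure is
#' absorbing within a replicate (no reopening).
#'
#' Defaults follow the open-state statistics of a stably conducting pore:
#' hydration 56 +- 8 waters, I177 Ca-Ca diagonal 16.5 +- 0.8 A; the closed
#' pore dehydrates (mean 20 waters) and the gate collapses to ~10 A.
#'
#' @param closure_rate absorbing open->closed hazard, us^-1 (0 = never
#'   closes).
#' @param open_hydration,closed_hydration lists `(mean, sd)`, waters/frame.
#' @param open_gate_distance,closed_gate_distance lists `(mean, sd)`, A, for
#'   the per-residue Ca-Ca diagonal.
#' @param open_ctd_sf,closed_ctd_sf lists `(mean, sd)`, A, CTD-SF
#'   center-of-mass separation (the CTD sits closer to the pore domain while
#'   open).
#' @return object of class `gate_model`.
#' @export
gate_model <- function(closure_rate = 0,
                       open_hydration = list(mean = 56, sd = 8),
                       closed_hydration = list(mean = 20, sd = 5),
                       open_gate_distance = list(mean = 16.5, sd = 0.8),
                       closed_gate_distance = list(mean = 10, sd = 0.6),
                       open_ctd_sf = list(mean = 47.5, sd = 0.5),
                       closed_ctd_sf = list(mean = 50.5, sd = 0.5)) {
  if (closure_rate < 0) stop("'closure_rate' must be >= 0")
  if (open_hydration$mean <= closed_hydration$mean)
    stop("open hydration mean must exceed closed hydration mean")
  structure(list(closure_rate = closure_rate,
                 open_hydration = open_hydration,
                 closed_hydration = closed_hydration,
                 open_gate_distance = open_gate_distance,
                 closed_gate_distance = closed_gate_distance,
                 open_ctd_sf = open_ctd_sf,
                 closed_ctd_sf = closed_ctd_sf),
            class = "gate_model")
}

#' Spermine blocker model
#'
#' A single tetravalent blocker walks a station graph along the extended
#' pore: `bulk - CTD - G_loop - cavity - deep_site - SF - translocated`,
#' with voltage-biased rates (effective charge +4, fully protonated at
#' pH 7).  Entering `deep_site` (the binding site above the rectification
#' controller, extending into the lower SF) optionally evicts the K+ ions in
#' the TM pore in the direction of the field and blocks ion hops through the
#' TM pore while bound.
#'
#' @param stations data.frame with columns `station`, `z` (axial anchor, A),
#'   strictly increasing in z.  Default spans the extended pore of the
#'   default geometry.
#' @param edges data.frame `from`, `to`, `k_fwd0`, `k_bwd0`, `delta` for
#'   adjacent station pairs (in order).
#' @param charge blocker effective charge (elementary charges).
#' @param displace_on_deep_bind evict TM-pore (cavity + SF) ions on deep
#'   binding.
#' @param block_on_deep_bind suppress ion hops into/through the TM pore
#'   while deep-bound.
#' @param start_station station occupied at t = 0.
#' @return object of class `blocker_model`.
#' @export
blocker_model <- function(stations = NULL, edges = NULL, charge = 4,
                          displace_on_deep_bind = TRUE,
                          block_on_deep_bind = TRUE,
                          start_station = "bulk") {
  if (is.null(stations)) {
    stations <- data.frame(
      station = c("bulk", "CTD", "G_loop", "cavity", "deep_site", "SF",
                  "translocated"),
      z = c(-70, -42, -25, -14, -8, 2, 30),
      stringsAsFactors = FALSE)
  }
  stations <- as.data.frame(stations, stringsAsFactors = FALSE)
  stopifnot(all(c("station", "z") %in% names(stations)))
  if (any(diff(stations$z) <= 0))
    stop("station z anchors must be strictly increasing along the axis")
  if (is.null(edges)) {
    edges <- data.frame(from = stations$station[-nrow(stations)],
                        to = stations$station[-1],
                        k_fwd0 = 0, k_bwd0 = 0, delta = 0,
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "k_fwd0", "k_bwd0", "delta") %in% names(edges)))
  want <- paste(stations$station[-nrow(stations)], stations$station[-1],
                sep = "->")
  got <- paste(edges$from, edges$to, sep = "->")
  if (!identical(sort(want), sort(got)))
    stop("blocker edges must cover adjacent station pairs exactly once")
  edges <- edges[match(want, got), ]
  rownames(edges) <- NULL
  if (any(edges$k_fwd0 < 0 | edges$k_bwd0 < 0)) stop("rates must be >= 0")
  if (!start_station %in% stations$station)
    stop("unknown start_station: ", start_station)
  structure(list(stations = stations, edges = edges, charge = charge,
                 displace_on_deep_bind = isTRUE(displace_on_deep_bind),
                 block_on_deep_bind = isTRUE(block_on_deep_bind),
                 start_station = start_station),
            class = "blocker_model")
}

#' Calibrate the voltage dependence of blocker unbinding
#'
#' Fits the two-parameter exponential law
#' \deqn{\tau(V) = (1/k_0)\,\exp(-|V|/V_s)}
#' exactly through two (voltage, mean unbinding time) anchors.  Equal
#' anchor times at distinct voltages give a voltage-independent law
#' (`Vs = Inf`); equal anchor voltages are degenerate and raise an error.
#'
#' @param anchors 2 x 2 numeric matrix or list of two `c(voltage_mV,
#'   tau_us)` pairs.
#' @return object of class `blocker_rate_law`: list with `k0` (us^-1), `Vs`
#'   (mV), `voltage_independent` flag, and `tau(V)` prediction function.
#' @examples
#' law <- calibrate_blocker_rates(rbind(c(-185, 8.1), c(-310, 0.33)))
#' law$Vs                    # 125 / log(8.1/0.33) ~ 39.1 mV
#' law$tau(-215)             # ~3.8 us
#' @export
calibrate_blocker_rates <- function(anchors) {
  a <- if (is.list(anchors)) do.call(rbind, anchors) else as.matrix(anchors)
  if (!all(dim(a) == c(2, 2))) stop("need exactly two (voltage, tau) anchors")
  V <- abs(a[, 1]); tau <- a[, 2]
  if (any(tau <= 0)) stop("anchor times must be positive")
  if (abs(V[1] - V[2]) < 1e-12)
    stop("degenerate fit: anchors must be at distinct voltages")
  if (abs(tau[1] - tau[2]) < 1e-12) {
    Vs <- Inf
    k0 <- 1 / tau[1]
  } else {
    Vs <- (V[2] - V[1]) / (log(tau[1]) - log(tau[2]))
    k0 <- exp(-V[1] / Vs) / tau[1]
  }
  law <- list(k0 = k0, Vs = Vs, voltage_independent = !is.finite(Vs),
              anchors = a)
  law$tau <- function(voltage) (1 / k0) * exp(-abs(voltage) / Vs)
  class(law) <- "blocker_rate_law"
  law
}

#' @export
print.blocker_rate_law <- function(x, ...) {
  cat(sprintf("Blocker unbinding law: tau(V) = (1/%.4g) * exp(-|V|/%.4g mV)%s\n",
              x$k0, x$Vs,
              if (x$voltage_independent) " [voltage-independent]" else ""))
  invisible(x)
}

## Convert a tau(V) law to a (k0_edge, delta_edge) pair for the deep-site
## escape edge, so that the simulated escape rate reproduces the law at
## hyperpolarizing voltages: exp(z*delta*|u|/2) == exp(|V|/Vs).
.law_to_edge <- function(law, charge = 4, temperature = 310) {
  delta <- if (is.finite(law$Vs)) {
    2 * .R_KCAL * temperature * .KCALMOL_PER_E_TO_MV / (charge * law$Vs)
  } else 0
  list(k0 = law$k0, delta = delta)
}
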