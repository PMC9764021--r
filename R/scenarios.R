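## Scenario presets: WT and mutant parameterizations of the kinetic model.
##
## The printed observables the presets are tuned to (per-region kinetic
## occupancies, current magnitude, closure medians, blocker kinetics) come
## from the study conditions; absolute hop rates are free parameters chosen
## to reproduce those observables and are documented in the methods
## vignette, not asserted as physical.

## WT ion-hopping rate table (us^-1 at V = 0; delta = fraction of the
## membrane voltage dropped across the edge, summing to 1 over the
## intracellular -> extracellular path).
.wt_ion_edges <- function() {
  data.frame(
    from  = c("bulk_in", "CTD", "G_loop", "cavity",
              "S6", "S5", "S4", "S3", "S2", "S1", "S0", "S_ext"),
    to    = c("CTD", "G_loop", "cavity", "S6",
              "S5", "S4", "S3", "S2", "S1", "S0", "S_ext", "bulk_out"),
    ## graded SF forward rates (fast at the bottom, slower toward S0) give
    ## the density profile its S1-S3/S4 preference while the entry/exit
    ## rates set the total SF occupancy
    k_fwd0 = c(170, 40, 40, 5.4, 110, 95, 80, 65, 55, 48, 51, 120),
    k_bwd0 = c(30, 25, 30, 40, 60, 60, 60, 60, 60, 60, 30, 5),
    delta = c(0, 0.02, 0.08, 0.15, rep(0.10, 7), 0.05),
    stringsAsFactors = FALSE)
}

## WT blocker station rate table (z_q = +4).  The cavity<->deep_site edge
## carries the unbinding law calibrated through the printed
## (voltage, unbinding-time) anchors; the remaining couplings complete the
## transmembrane voltage drop.
.wt_blocker <- function() {
  law <- calibrate_blocker_rates(rbind(c(-185, 8.1), c(-310, 0.33)))
  eg <- .law_to_edge(law, charge = 4)
  delta_rest <- 1 - eg$delta - 0.05 - 0.10 - 0.20
  edges <- data.frame(
    from = c("bulk", "CTD", "G_loop", "cavity", "deep_site", "SF"),
    to = c("CTD", "G_loop", "cavity", "deep_site", "SF", "translocated"),
    k_fwd0 = c(2.0, 0.8, 1.5, 150, 0.004, 5),
    k_bwd0 = c(2.0, 30, 30, eg$k0, 0.01, 0.001),
    delta = c(0, 0.05, 0.10, eg$delta, 0.20, delta_rest),
    stringsAsFactors = FALSE)
  blocker_model(edges = edges, charge = 4)
}

#' Scenario presets for synthetic trajectory generation
#'
#' Returns the kinetic model, gate model, and blocker model for a named
#' study scenario:
#' \describe{
#'   \item{WT}{PIP2-bound wild type: conducting pore, closure hazard
#'     `ln(2)/120` us^-1, blocker with the calibrated voltage-dependent
#'     deep-site kinetics.}
#'   \item{E225A_E300A}{CTD charge-neutralized double mutant: CTD exit
#'     rates / 10, cavity exit rates / 2, blocker CTD-entry rate ~ 0 (the
#'     CTD ring no longer recruits the polyamine).}
#'   \item{E225A_R261Q}{charge-compensated double mutant: WT-like rates.}
#'   \item{ROMK_like}{weak rectifier lacking the cavity rectification
#'     controller: no deep blocker site; the blocker is confined to the
#'     CTD side.}
#'   \item{PIP2_depleted}{agonist lipid removed: closure hazard
#'     `ln(2)/58` us^-1 (median closure 58 us).}
#'   \item{D69A_D76A}{interfacial-helix double mutant, stable without
#'     PIP2: closure hazard `ln(2)/110` us^-1.}
#' }
#'
#' @param name scenario name.
#' @param voltage membrane voltage, mV.
#' @param water_coperm_prob water co-permeation probability per outward ion
#'   permeation.
#' @param mechanism_constrained restrict SF dynamics to the concerted
#'   knock-on cycle.
#' @return list with elements `model` ([kinetic_model()]), `gate`
#'   ([gate_model()]), `blocker` ([blocker_model()]).
#' @export
scenario_preset <- function(name = c("WT", "E225A_E300A", "E225A_R261Q",
                                     "ROMK_like", "PIP2_depleted",
                                     "D69A_D76A"),
                            voltage = 310,
                            water_coperm_prob = 0.22,
                            mechanism_constrained = FALSE) {
  if (!is.character(name) || !name[1] %in% c("WT", "E225A_E300A",
                                             "E225A_R261Q", "ROMK_like",
                                             "PIP2_depleted", "D69A_D76A"))
    stop("unknown scenario: ", name[1])
  name <- name[1]
  edges <- .wt_ion_edges()
  closure <- log(2) / 120            # PIP2-bound WT median closure
  blocker <- .wt_blocker()

  if (name == "E225A_E300A") {
    ## Exit-rate divisors calibrated so the *realized* per-visit residence
    ## times of generated tracks increase ~10-fold (CTD) and ~2-fold
    ## (cavity) relative to WT; the raw divisors exceed those factors
    ## because single-file exclusion at the G-loop bottleneck partially
    ## compensates when the flux drops.
    edges$k_fwd0[edges$from == "CTD"] <-
      edges$k_fwd0[edges$from == "CTD"] / 18
    edges$k_bwd0[edges$from == "bulk_in"] <-
      edges$k_bwd0[edges$from == "bulk_in"] / 18
    edges$k_fwd0[edges$from == "cavity"] <-
      edges$k_fwd0[edges$from == "cavity"] / 4.5
    edges$k_bwd0[edges$from == "G_loop"] <-
      edges$k_bwd0[edges$from == "G_loop"] / 4.5
    blocker$edges$k_fwd0[blocker$edges$from == "bulk"] <- 1e-4
  } else if (name == "ROMK_like") {
    st <- blocker$stations[blocker$stations$station != "deep_site", ]
    ed <- data.frame(from = st$station[-nrow(st)], to = st$station[-1],
                     k_fwd0 = c(2.0, 0.8, 0, 0, 0),
                     k_bwd0 = c(2.0, 30, 0, 0, 0),
                     delta = c(0, 0.05, 0.15, 0.40, 0.40),
                     stringsAsFactors = FALSE)
    blocker <- blocker_model(stations = st, edges = ed, charge = 4)
  } else if (name == "PIP2_depleted") {
    closure <- log(2) / 58
  } else if (name == "D69A_D76A") {
    closure <- log(2) / 110
  }

  model <- kinetic_model(edges = edges, voltage = voltage,
                         water_coperm_prob = water_coperm_prob,
                         mechanism_constrained = mechanism_constrained)
  gate <- gate_model(closure_rate = closure)
  list(model = model, gate = gate, blocker = blocker)
}

#' Blocked-start unbinding scenario
#'
#' Convenience configuration for voltage-dependent unbinding studies: the
#' blocker starts deep-bound (pore blocked), ion hopping is switched off
#' (the analyzers only need the blocker-landmark distance), and the gate
#' never closes.  Replicated at hyperpolarizing voltages this reproduces
#' the calibrated unbinding law.
#'
#' @param voltage membrane voltage, mV (hyperpolarizing, < 0, for
#'   unbinding).
#' @return list with `model`, `gate`, `blocker`.
#' @export
spm_unbinding_scenario <- function(voltage) {
  sc <- scenario_preset("WT", voltage = voltage)
  sc$model$edges$k_fwd0 <- 0
  sc$model$edges$k_bwd0 <- 0
  sc$gate <- gate_model(closure_rate = 0)
  sc$blocker$start_station <- "deep_site"
  sc$blocker$displace_on_deep_bind <- FALSE
  sc
}
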