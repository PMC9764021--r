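## Shared fixtures, built lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

## 10-us WT conducting run at +310 mV with its rendered tracks
fixture_wt_sim <- function() {
  if (is.null(.fix$wt)) {
    sc <- scenario_preset("WT", voltage = 310)
    .fix$wt <- simulate_pore(sc$model, sc$gate, duration = 10, seed = 101)
  }
  .fix$wt
}

fixture_wt_tracks <- function() {
  if (is.null(.fix$wt_tracks))
    .fix$wt_tracks <- render_frames(fixture_wt_sim(), dt_ns = 2, seed = 102)
  .fix$wt_tracks
}

## Hand-made track table from per-particle axial series (x = y = 0).
## zlist: named list particle_id -> numeric vector (NA = particle absent).
tracks_from_z <- function(zlist, roles = NULL, dt_ns = 10,
                          geometry = default_geometry()) {
  nf <- max(vapply(zlist, length, 1L))
  rows <- lapply(names(zlist), function(id) {
    z <- zlist[[id]]
    keep <- which(!is.na(z))
    data.table::data.table(
      frame = keep, time_ns = (keep - 1) * dt_ns,
      particle_id = id,
      role = if (is.null(roles)) "ion" else roles[[id]],
      x = 0, y = 0, z = z[keep])
  })
  tr <- data.table::rbindlist(rows)
  data.table::setorder(tr, frame, particle_id)
  data.table::setattr(tr, "dt_ns", dt_ns)
  data.table::setattr(tr, "geometry", geometry)
  data.table::setattr(tr, "class", c("kir_tracks", class(tr)))
  tr[]
}

## site-anchor z for hand-made configurations
site_z <- function(sites, geometry = default_geometry()) {
  sb <- geometry$site_bounds
  i <- match(sites, sb$site)
  (sb$z_lo[i] + sb$z_hi[i]) / 2
}

## independent net-crossing count from a ground-truth log (reimplements the
## zone walk: last-extreme-side bookkeeping per particle)
net_crossings_from_hops <- function(sim) {
  geom <- sim$model$geometry
  chain <- sim$model$chain
  zone_of <- function(site) {
    i <- match(site, chain)
    i_cav <- match("cavity", chain)
    i_sext <- match("S_ext", chain)
    if (i <= i_cav) -1L else if (i >= i_sext) 1L else 0L
  }
  hops <- sim$log[sim$log$kind == "hop" & sim$log$particle > 0L, ]
  seeded <- stats::setNames(sim$init$site, sim$init$particle)
  net <- 0L
  for (p in unique(c(hops$particle, sim$init$particle))) {
    hp <- hops[hops$particle == p, ]
    s0 <- if (as.character(p) %in% names(seeded))
      unname(seeded[as.character(p)]) else hp$from[1]
    sites <- c(s0, hp$to)
    last <- 0L
    for (s in sites) {
      zz <- zone_of(s)
      if (zz != 0L) {
        if (last != 0L && zz != last) net <- net + zz
        last <- zz
      }
    }
  }
  net
}
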