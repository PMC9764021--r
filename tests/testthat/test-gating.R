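## gate pseudo-atoms at the corners of a square of side a, subunit order
## A, B, C, D around the square (diagonals A-C and B-D)
square_gate_tracks <- function(a, nf = 5) {
  ids <- paste0("I177_", c("A", "B", "C", "D"))
  xy <- rbind(c(0, 0), c(a, 0), c(a, a), c(0, a))
  rows <- lapply(1:4, function(i)
    data.table::data.table(frame = 1:nf, time_ns = (0:(nf - 1)) * 10,
                           particle_id = ids[i], role = "gate",
                           x = xy[i, 1], y = xy[i, 2], z = -20))
  tr <- data.table::rbindlist(rows)
  data.table::setattr(tr, "dt_ns", 10)
  tr
}

test_that("gate diagonal distance recovers square geometry", {
  tr <- square_gate_tracks(a = 7)
  d <- gate_diagonal_distance(tr, "I177")
  expect_equal(d$distance, rep(7 * sqrt(2), 5))
  ## missing subunit copies -> invalid topology
  tr3 <- tr[tr$particle_id != "I177_D", ]
  expect_error(gate_diagonal_distance(tr3, "I177"), "4 subunit copies")
})

test_that("gate series from the generator match the configured Gaussians", {
  sim <- fixture_wt_sim()
  tr <- render_frames(sim, dt_ns = 10, include = c("gate", "landmarks"),
                      seed = 104)
  gI <- gate_diagonal_distance(tr, "I177")
  expect_equal(mean(gI$distance), 16.5, tolerance = 0.02)
  gM <- gate_diagonal_distance(tr, "M181")
  expect_equal(mean(gM$distance), 16.5, tolerance = 0.02)
  ## closed-state generator
  gate_c <- gate_model(closure_rate = 1e6)   # closes immediately
  simc <- simulate_pore(kinetic_model(), gate_c, duration = 5, seed = 51)
  trc <- render_frames(simc, dt_ns = 10, include = "gate", seed = 52)
  expect_equal(mean(gate_diagonal_distance(trc, "I177")$distance), 10,
               tolerance = 0.02)
})

test_that("cavity hydration counting matches a brute-force cylinder scan", {
  sim <- fixture_wt_sim()
  tr <- render_frames(sim, dt_ns = 20, include = "cavity_waters",
                      seed = 105)
  hyd <- cavity_hydration(tr)
  expect_equal(mean(hyd$count), 56, tolerance = 0.02)
  ## brute-force oracle over a subset of frames
  geom <- attr(tr, "geometry")
  cyl <- geom$cavity_cylinder
  for (f in unique(tr$frame)[1:20]) {
    w <- tr[tr$frame == f & tr$role == "water", ]
    manual <- sum(w$z >= cyl$z_lo & w$z < cyl$z_hi &
                    w$x^2 + w$y^2 <= cyl$radius^2)
    expect_identical(hyd$count[hyd$frame == f], manual)
  }
  ## permutation invariance in particle order
  shuf <- tr[sample(nrow(tr)), ]
  data.table::setattr(shuf, "geometry", geom)
  hyd2 <- cavity_hydration(shuf)
  expect_equal(hyd2$count, hyd$count)
  ## no waters -> all zeros
  tri <- render_frames(sim, dt_ns = 50, include = "ions", seed = 106)
  expect_true(all(cavity_hydration(tri)$count == 0))
})

test_that("closure detection applies threshold and persistence rules", {
  mk <- function(counts) data.table::data.table(
    frame = seq_along(counts), time_ns = (seq_along(counts) - 1) * 100,
    count = counts)
  ## drops to 30 at frame 121 (12 us) and stays
  s1 <- mk(c(rep(56, 120), rep(30, 80)))
  out <- detect_closure(s1, threshold = 35, persistence = 10)
  expect_true(out$closed)
  expect_equal(out$time, 12)
  ## never below: censored at the end
  s2 <- mk(rep(50, 100))
  out2 <- detect_closure(s2, threshold = 35, persistence = 1)
  expect_true(out2$censored)
  expect_equal(out2$time, 9.9)
  ## single-frame dip with a long persistence window: censored
  s3 <- mk(c(rep(56, 50), 34, rep(56, 149)))
  expect_true(detect_closure(s3, threshold = 35,
                             persistence = 40)$censored)
  ## but first-touch mode (persistence = 1) calls it
  expect_equal(detect_closure(s3, threshold = 35, persistence = 1)$time, 5)
  expect_error(detect_closure(mk(integer(0))), "empty")
  expect_error(detect_closure(s1, persistence = 0), ">= 1")
})

test_that("closure detection is monotone in the threshold", {
  set.seed(61)
  for (rep in 1:20) {
    counts <- round(stats::filter(rnorm(300, 45, 12), rep(1 / 5, 5),
                                  circular = TRUE))
    s <- data.table::data.table(frame = 1:300, time_ns = (0:299) * 100,
                                count = as.integer(counts))
    t_lo <- detect_closure(s, threshold = 35, persistence = 5)
    t_hi <- detect_closure(s, threshold = 45, persistence = 5)
    v <- function(o) if (o$censored) Inf else o$time
    expect_lte(v(t_hi), v(t_lo))
  }
})

test_that("closure statistics handle censoring by survival analysis", {
  mk <- function(t, cens) structure(list(closed = !cens, time = t,
                                         censored = cens,
                                         threshold = 35, persistence = 1),
                                    class = "closure_outcome")
  ## no censoring: plain median
  s <- closure_statistics(list(mk(2, FALSE), mk(4, FALSE), mk(6, FALSE)))
  expect_equal(s$median, 4)
  ## {3, 5, censored-at-10}: survival crosses 0.5 at the 2nd ordered event
  s2 <- closure_statistics(list(mk(3, FALSE), mk(5, FALSE), mk(10, TRUE)))
  expect_equal(s2$median, 5)
  ## all censored: lower bound only
  s3 <- closure_statistics(list(mk(10, TRUE), mk(12, TRUE)))
  expect_false(s3$median_defined)
  expect_equal(s3$median_lower_bound, 12)
  ## fraction-closed curve is non-decreasing
  expect_true(all(diff(s2$curve$fraction_closed) >= 0))
})

test_that("survival median converges to ln(2)/lambda on exponential samples", {
  set.seed(62)
  lam <- 1 / 20
  t <- rexp(500, lam)
  outs <- data.frame(time = t, censored = FALSE)
  s <- closure_statistics(outs)
  expect_equal(s$median, log(2) / lam, tolerance = 0.1)
})

test_that("CTD-SF separation and contact distances are exact geometry", {
  tr <- data.table::rbindlist(list(
    data.table::data.table(frame = 1:3, time_ns = (0:2) * 10,
                           particle_id = "CTD_COM", role = "landmark",
                           x = 0, y = 0, z = c(0, 0, 1)),
    data.table::data.table(frame = 1:3, time_ns = (0:2) * 10,
                           particle_id = "SF_COM", role = "landmark",
                           x = 0, y = c(0, 2.5, 0), z = c(0, 0, 3))))
  d <- ctd_sf_separation(tr)
  expect_equal(d$distance, c(0, 2.5, 2))
  expect_error(ctd_sf_separation(tr, ctd_id = "missing"), "not found")
  ## opening decreases the separation by ~3 A relative to the closed state
  simc <- simulate_pore(kinetic_model(), gate_model(closure_rate = 1e6),
                        duration = 2, seed = 63)
  simo <- simulate_pore(kinetic_model(), gate_model(closure_rate = 0),
                        duration = 2, seed = 63)
  trc <- render_frames(simc, dt_ns = 10, include = "landmarks", seed = 64)
  tro <- render_frames(simo, dt_ns = 10, include = "landmarks", seed = 64)
  drop_on_open <- mean(ctd_sf_separation(trc)$distance) -
    mean(ctd_sf_separation(tro)$distance)
  expect_gt(drop_on_open, 2)
  expect_lt(drop_on_open, 4)
})

test_that("contact distances equal the brute-force pair minimum", {
  set.seed(65)
  nf <- 6
  ids_a <- paste0("a", 1:10); ids_b <- paste0("b", 1:10)
  mk <- function(ids) data.table::rbindlist(lapply(ids, function(id)
    data.table::data.table(frame = 1:nf, time_ns = (0:(nf - 1)) * 10,
                           particle_id = id, role = "other",
                           x = rnorm(nf), y = rnorm(nf), z = rnorm(nf))))
  tr <- data.table::rbindlist(list(mk(ids_a), mk(ids_b)))
  d <- contact_distances(tr, ids_a, ids_b)
  for (f in 1:nf) {
    A <- as.matrix(tr[tr$frame == f & tr$particle_id %in% ids_a,
                      c("x", "y", "z")])
    B <- as.matrix(tr[tr$frame == f & tr$particle_id %in% ids_b,
                      c("x", "y", "z")])
    manual <- min(sqrt(outer(rowSums(A^2), rowSums(B^2), "+") -
                         2 * A %*% t(B)))
    expect_equal(d$distance[d$frame == f], manual, tolerance = 1e-9)
  }
  ## singleton selections give the plain distance
  d1 <- contact_distances(tr, "a1", "b1")
  expect_equal(nrow(d1), nf)
  expect_error(contact_distances(tr, character(0), "b1"), "empty")
})
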