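test_that("burst search groups photons by interphoton time", {
  ts <- c(0, 50, 120, 400, 460) * 1e-6
  st <- photon_stream(ts, rep("donor", 5), rep("donor", 5))
  b <- identify_bursts(st, max_interphoton = 100e-6, min_photons = 1)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_photons, c(3L, 2L))
  expect_equal(b$start, c(1L, 4L))
  ## min_photons drops short runs
  b2 <- identify_bursts(st, max_interphoton = 100e-6, min_photons = 3)
  expect_equal(nrow(b2), 1)
  ## empty stream
  e <- photon_stream(numeric(), character(), character())
  expect_equal(nrow(identify_bursts(e)), 0)
  expect_error(photon_stream(c(2, 1) * 1e-3, rep("donor", 2),
                             rep("donor", 2)), "sorted")
})

test_that("a sparse Poisson stream yields mostly singleton runs", {
  set.seed(42)
  n <- 1e4
  thr <- 100e-6
  ts <- cumsum(stats::rexp(n, rate = 1 / (10 * thr)))
  st <- photon_stream(ts, rep("donor", n), rep("donor", n))
  b <- identify_bursts(st, max_interphoton = thr, min_photons = 1)
  ## P(gap < thr) = 1 - exp(-0.1) ~ 0.095; expected number of runs =
  ## n * exp(-0.1)
  expect_equal(nrow(b), n * exp(-0.1), tolerance = 0.02)
})

test_that("burst observables implement corrected E and PIE stoichiometry", {
  ## hand-built burst: 40 donor + 60 acceptor (donor excitation),
  ## 50 acceptor-excitation photons
  n <- 150
  ch <- c(rep("donor", 40), rep("acceptor", 60), rep("acceptor", 50))
  ex <- c(rep("donor", 100), rep("acceptor", 50))
  ts <- seq(0, 1e-3, length.out = n)
  st <- photon_stream(ts, ch, ex, microtime = rep(1.5, n))
  b <- data.frame(start = 1L, end = as.integer(n), n_photons = n,
                  t_start = 0, t_end = 1e-3, duration_ms = 1)
  ob <- burst_observables(st, b)
  expect_equal(ob$E, 0.6)
  expect_equal(ob$S, 100 / 150)
  expect_equal(ob$mean_donor_microtime, 1.5)
  ## donor-only molecule: S = 1
  st2 <- photon_stream(ts[1:40], rep("donor", 40), rep("donor", 40))
  b2 <- data.frame(start = 1L, end = 40L, n_photons = 40L,
                   t_start = 0, t_end = ts[40], duration_ms = 1)
  expect_equal(burst_observables(st2, b2)$S, 1)
  ## null corrections leave raw counts untouched; gamma rescales
  ob_g <- burst_observables(st, b, correction_set(gamma = 2))
  expect_equal(ob_g$E, 60 / (60 + 80))
})

test_that("stoichiometry window removes donor-only bursts with high purity", {
  spec <- photon_generator_spec(
    E_true = c(0.43, 0), fractions = c(0.7, 0.3),
    donor_only = c(FALSE, TRUE), n_bursts = 600, seed = 21)
  g <- generate_photon_stream(spec)
  bursts <- identify_bursts(g$stream, min_photons = 30)
  ob <- burst_observables(g$stream, bursts)
  kept <- filter_bursts(ob, g$stream)
  ## match kept bursts back to their generating molecule by start time
  lab <- g$labels$donor_only[findInterval(kept$t_start,
                                          g$labels$t_start)]
  expect_gt(nrow(kept), 100)
  expect_lt(mean(lab), 0.02)
  ## all-pass settings are the identity
  allp <- filter_bursts(ob, g$stream, S_window = c(0, 1),
                        aggregate_rule = FALSE, bleach_rule = FALSE)
  expect_equal(nrow(allp), sum(!ob$flagged & !is.na(ob$S)))
  ## filtering is idempotent
  twice <- filter_bursts(kept, g$stream)
  expect_equal(nrow(twice), nrow(kept))
})

test_that("aggregate rule removes bursts in overloaded 1-s bins", {
  set.seed(8)
  ## quiet stream plus one very hot second
  t_quiet <- sort(stats::runif(2000, 0, 20))
  t_hot <- sort(stats::runif(3000, 5.2, 5.4))
  ts <- sort(c(t_quiet, t_hot))
  n <- length(ts)
  st <- photon_stream(ts, rep("donor", n), rep("donor", n))
  bursts <- data.frame(start = c(1L, 1L), end = c(2L, 2L),
                       n_photons = c(2L, 2L),
                       t_start = c(2.0, 5.3), t_end = c(2.0001, 5.3001),
                       duration_ms = c(0.1, 0.1))
  bursts$S <- 0.5; bursts$flagged <- FALSE
  bursts$E_drift <- 0; bursts$n_photons <- c(2L, 2L)
  kept <- filter_bursts(bursts, st, bleach_rule = FALSE)
  expect_equal(kept$t_start, 2.0)
})

test_that("bleach filter rejects bursts whose efficiency drifts", {
  ## acceptor photons only in the first half: E drifts 1 -> 0
  n <- 60
  ch <- c(rep("acceptor", 30), rep("donor", 30))
  ts <- seq(0, 1e-3, length.out = n)
  st <- photon_stream(ts, ch, rep("donor", n))
  b <- data.frame(start = 1L, end = as.integer(n), n_photons = n,
                  t_start = 0, t_end = 1e-3, duration_ms = 1)
  ob <- burst_observables(st, b)
  expect_equal(ob$E_drift, 1)
  ob$S <- 0.5
  expect_equal(nrow(filter_bursts(ob, st, aggregate_rule = FALSE)), 0)
})

test_that("histogram fitting recovers component parameters and areas", {
  set.seed(5)
  E1 <- stats::rnorm(5000, 0.43, 0.05)
  fit <- fit_histogram(E1, components = 1)
  expect_equal(fit$components$mean, 0.43, tolerance = 0.025)
  expect_equal(sum(fit$components$area), 5000, tolerance = 0.05)
  ## two equal-area components
  E2 <- c(stats::rnorm(2500, 0.4, 0.04), stats::rnorm(2500, 0.6, 0.04))
  fit2 <- fit_histogram(E2, components = 2,
                        start = list(mean = c(0.35, 0.65),
                                     width = c(0.05, 0.05)))
  fr <- sort(fit2$components$area) / sum(fit2$components$area)
  expect_equal(fr[1], 0.5, tolerance = 0.1)
  expect_equal(sort(fit2$components$mean), c(0.4, 0.6),
               tolerance = 0.05)
  ## degenerate input
  expect_error(fit_histogram(rep(0.4, 100)), "zero variance")
  expect_error(fit_histogram(E1[1:20]), "at least 50")
})

test_that("global histogram fits share means across histograms", {
  set.seed(6)
  h1 <- c(stats::rnorm(1500, 0.3, 0.05), stats::rnorm(500, 0.7, 0.05))
  h2 <- c(stats::rnorm(500, 0.3, 0.05), stats::rnorm(1500, 0.7, 0.05))
  fit <- fit_histogram(list(h1, h2), components = 2,
                       shared = c("mean", "width"),
                       start = list(mean = c(0.3, 0.7),
                                    width = c(0.05, 0.05)))
  cm <- fit$components
  ## shared means identical across histograms
  m1 <- cm$mean[cm$histogram == 1]
  m2 <- cm$mean[cm$histogram == 2]
  expect_equal(m1, m2)
  ## mixing fractions recovered per histogram
  a1 <- cm$area[cm$histogram == 1]
  expect_equal(a1[1] / sum(a1), 0.75, tolerance = 0.1)
  ## theta via histogram areas
  th <- fraction_bound_from_histogram(
    c(bound = a1[2], unbound = a1[1]))
  expect_equal(th, 0.25, tolerance = 0.05)
})
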