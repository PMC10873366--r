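test_that("correlator is flat for independent Poisson streams", {
  set.seed(3)
  t1 <- cumsum(stats::rexp(2e5, 1e6)) # 1 MHz
  t2 <- cumsum(stats::rexp(2e5, 1e6))
  g <- correlate(t1, t2, bin_width = 10e-9, max_lag = 1e-6,
                 denominator = "geometric")
  ## fluctuation band: relative sd per bin is 1/sqrt(expected pairs)
  T <- max(t1, t2) - min(t1, t2)
  band <- 1 / sqrt(as.numeric(length(t1)) * length(t2) * 10e-9 / T)
  expect_lt(max(abs(g$G)), 5 * band)
  expect_lt(abs(mean(g$G)), band)
  expect_error(correlate(numeric(), t2), "empty")
})

test_that("correlation of a periodic stream peaks at multiples of the period", {
  tt <- seq(0, 1e-3, by = 1e-6) # 1 us period
  g <- correlate(tt, tt, bin_width = 0.05e-6, max_lag = 3.4e-6,
                 symmetric = FALSE, denominator = "geometric")
  pk <- g$lag[g$G > 0.5 * max(g$G)]
  expect_true(all(abs((pk %% 1e-6 + 0.5e-6) %% 1e-6 - 0.5e-6) <
                    0.06e-6))
})

test_that("correlation is invariant under a time-origin shift", {
  set.seed(4)
  ph <- generate_telegraph_photons(k_switch = 1 / (2 * 200e-9),
                                   rate = 2e6, t_total = 0.02, seed = 4)
  dur <- max(ph$t_donor, ph$t_acceptor) - min(ph$t_donor, ph$t_acceptor)
  g1 <- correlate(ph$t_donor, ph$t_acceptor, bin_width = 20e-9,
                  max_lag = 1e-6, duration = dur)
  g2 <- correlate(ph$t_donor + 5, ph$t_acceptor + 5,
                  bin_width = 20e-9, max_lag = 1e-6, duration = dur)
  expect_equal(g1$G, g2$G, tolerance = 1e-6)
})

test_that("nsFCS fit recovers parameters from a noiseless model curve", {
  lag <- seq(-1e-6, 1e-6, by = 1e-9)
  pars <- list(a = 1.5, c_ab = 0.8, tau_ab = 3e-9, c_cd = -0.35,
               tau_cd = 100e-9)
  G <- pars$a * (1 - pars$c_ab * exp(-abs(lag) / pars$tau_ab)) *
    (1 + pars$c_cd * exp(-abs(lag) / pars$tau_cd))
  curve <- structure(data.frame(lag = lag, G = G),
                     class = c("correlation_curve", "data.frame"))
  fit <- fit_nsfcs(curve)
  expect_equal(unname(coef_of(fit, "tau_cd")), 100e-9,
               tolerance = 0.01)
  expect_equal(unname(coef_of(fit, "c_cd")), -0.35, tolerance = 0.02)
  expect_equal(unname(coef_of(fit, "tau_ab")), 3e-9, tolerance = 0.01)
  ## nested model without antibunching reproduces pure chain dynamics
  G2 <- pars$a * (1 + pars$c_cd * exp(-abs(lag) / pars$tau_cd))
  curve2 <- structure(data.frame(lag = lag, G = G2),
                      class = c("correlation_curve", "data.frame"))
  fit2 <- fit_nsfcs(curve2, antibunching = FALSE)
  expect_equal(unname(coef_of(fit2, "tau_cd")), 100e-9,
               tolerance = 0.01)
})

test_that("telegraph photons give an anti-correlated decay at the telegraph time", {
  tau_true <- 150e-9
  ph <- generate_telegraph_photons(E_states = c(0.2, 0.8),
                                   k_switch = 1 / (2 * tau_true),
                                   rate = 8e6, t_total = 0.1, seed = 9)
  g <- correlate(ph$t_donor, ph$t_acceptor, bin_width = 5e-9,
                 max_lag = 1e-6, denominator = "geometric",
                 mean_subtract = FALSE)
  ## anti-correlated dip at small lags
  expect_lt(mean(g$G[abs(g$lag) < 30e-9]),
            mean(g$G[abs(g$lag) > 0.8e-6]))
  fit <- fit_nsfcs(g, antibunching = FALSE)
  expect_lt(unname(coef_of(fit, "c_cd")), 0)
  expect_equal(unname(coef_of(fit, "tau_cd")), tau_true,
               tolerance = 0.15)
})

test_that("reconfiguration time matches the Ornstein-Uhlenbeck oracle", {
  ## Gaussian P(r): diffusion in a harmonic PMF relaxes <r(0)r(t)> on
  ## tau = sigma^2 / D exactly
  sig <- 0.8; mu <- 6
  r <- seq(mu - 5 * sig, mu + 5 * sig, length.out = 400)
  p <- stats::dnorm(r, mu, sig)
  tau_r1 <- cgfret:::.smoluchowski_relaxation(p, r[2] - r[1], r, D = 1)
  expect_equal(tau_r1, sig^2, tolerance = 0.02)
})

test_that("reconfiguration time scales inversely with diffusion", {
  d <- saw_distribution(5.5, 0.55)
  out1 <- reconfiguration_time(100, d)
  ## doubling the matched diffusion coefficient (i.e. halving tau_cd)
  ## halves tau_r
  out2 <- reconfiguration_time(50, d)
  expect_equal(out2$tau_r, out1$tau_r / 2, tolerance = 1e-10)
  expect_gt(out1$tau_r, 0)
})

test_that("full nsFCS chain recovers the model reconfiguration time", {
  ## generate photons by diffusive dynamics on the SAW-nu PMF, then
  ## correlate -> fit -> convert and compare to the operator prediction
  d <- saw_distribution(5.5, 0.55)
  D_true <- 0.2 # nm^2/ns
  conv0 <- reconfiguration_time(1, d) # unit-D relaxation times
  tau_r_true <- conv0$tau_r_unitD / D_true
  tau_E_true <- conv0$tau_E_unitD / D_true
  ph <- generate_diffusive_photons(d, D_true, rate = 1e7,
                                   t_total = 0.05, dt = 0.5, seed = 12)
  g <- correlate(ph$t_donor, ph$t_acceptor, bin_width = 5e-9,
                 max_lag = 1e-6, denominator = "geometric",
                 mean_subtract = FALSE)
  fit <- fit_nsfcs(g, antibunching = FALSE)
  tau_cd <- unname(coef_of(fit, "tau_cd")) * 1e9 # ns
  out <- reconfiguration_time(tau_cd, d)
  expect_equal(out$tau_r, tau_r_true, tolerance = 0.2)
})
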