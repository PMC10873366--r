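test_that("ensemble efficiency averages the Foerster curve over frames", {
  ## single frame at r = R0 -> 0.5
  fr <- array(0, c(1, 2, 3)); fr[1, 2, 1] <- 6.0
  tr <- fake_trajectory(fr)
  expect_equal(ensemble_efficiency(tr, c(1, 2),
                                   min_frames = 1)$E_mean, 0.5)
  ## two frames at 0.1 R0 and 10 R0 -> ~(1 + 0)/2
  fr2 <- array(0, c(2, 2, 3)); fr2[1, 2, 1] <- 0.6; fr2[2, 2, 1] <- 60
  tr2 <- fake_trajectory(fr2)
  expect_equal(ensemble_efficiency(tr2, c(1, 2),
                                   min_frames = 1)$E_mean, 0.5,
               tolerance = 1e-5)
  expect_warning(ensemble_efficiency(tr2, c(1, 2)), "frames")
})

test_that("frames drawn from a SAW-nu distribution reproduce the quadrature mean", {
  set.seed(13)
  d <- saw_distribution(7.5, 0.5)
  ## sample r by inverse-CDF on a fine grid, place beads along x
  r_grid <- seq(1e-4, 5 * d$R, length.out = 4000)
  cdf <- cumsum(saw_pdf(r_grid, d)); cdf <- cdf / cdf[length(cdf)]
  r_smp <- stats::approx(cdf, r_grid, stats::runif(20000),
                         rule = 2, ties = "ordered")$y
  fr <- array(0, c(length(r_smp), 2, 3)); fr[, 2, 1] <- r_smp
  tr <- fake_trajectory(fr)
  E_emp <- ensemble_efficiency(tr, c(1, 2))$E_mean
  expect_equal(E_emp, mean_efficiency(d), tolerance = 0.01)
})

test_that("Lin's concordance penalises offsets and matches hand evaluation", {
  x <- c(0.2, 0.5, 0.8)
  expect_equal(concordance(x, x), 1)
  ## frozen hand evaluation: sxy = 0.04, sx2 = 0.06, sy2 = 0.0267
  expect_equal(concordance(x, c(0.3, 0.5, 0.7)), 0.923077,
               tolerance = 1e-5)
  ## offset penalty: rho_c < Pearson r
  y_off <- x + 0.2
  expect_lt(concordance(x, y_off), stats::cor(x, y_off))
  ## rho_c <= |r| over random pairs
  set.seed(3)
  for (k in 1:20) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    expect_lte(concordance(a, b), abs(stats::cor(a, b)) + 1e-12)
  }
  expect_error(concordance(x, rep(0.5, 3)), "variance")
})

test_that("contact maps count frame fractions and subtract cleanly", {
  ## beads 1-2 in contact in 37 of 100 frames, 1-3 never
  fr <- array(0, c(100, 3, 3))
  fr[, 2, 1] <- ifelse(seq_len(100) <= 37, 0.5, 3.0)
  fr[, 3, 2] <- 5
  tr <- fake_trajectory(fr)
  cm <- contact_fraction_map(tr, cutoff = 1.0)
  expect_equal(cm[1, 2], 0.37)
  expect_equal(cm[1, 3], 0)
  expect_equal(diag(unclass(cm)), rep(0, 3))
  expect_true(isSymmetric(unclass(cm)))
  ## frame permutation leaves fractions unchanged
  trp <- tr; trp$frames <- fr[sample(100), , ]
  expect_equal(unclass(contact_fraction_map(trp, cutoff = 1.0)),
               unclass(cm))
  ## signed difference and antisymmetry (same cutoff, other trajectory)
  fr3 <- fr; fr3[, 2, 1] <- ifelse(seq_len(100) <= 60, 0.5, 3.0)
  cm2 <- contact_fraction_map(fake_trajectory(fr3), cutoff = 1.0)
  dd <- contact_difference(cm, cm2)
  expect_equal(unclass(dd), unclass(cm) - unclass(cm2))
  expect_equal(unclass(contact_difference(cm2, cm)), -unclass(dd))
  expect_equal(unclass(contact_difference(cm, cm)),
               matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("domain contact autocorrelation recovers telegraph kinetics", {
  set.seed(17)
  nf <- 50000
  ## two-state telegraph distance: switch probability per frame
  tau_frames <- 25 # => autocorrelation time tau = 25 frames
  p_sw <- 1 / (2 * tau_frames)
  state <- integer(nf); s <- 0
  for (i in seq_len(nf)) {
    if (stats::runif(1) < p_sw) s <- 1 - s
    state[i] <- s
  }
  fr <- array(0, c(nf, 2, 3))
  fr[, 2, 1] <- ifelse(state == 1, 0.5, 3.0)
  tr <- fake_trajectory(fr)
  ck <- contact_autocorrelation(tr, list(1, 2), cutoff = 1.0,
                                max_lag_frac = 0.01,
                                double_exponential = FALSE)
  expect_equal(ck$tau1, tau_frames, tolerance = 0.15)
  expect_equal(ck$acf[1], 1)
  ## constant indicator raises
  fr0 <- array(0, c(200, 2, 3)); fr0[, 2, 1] <- 0.2
  expect_error(contact_autocorrelation(fake_trajectory(fr0),
                                       list(1, 2)),
               "constant")
})

test_that("double-exponential fit separates two telegraph timescales", {
  set.seed(23)
  nf <- 100000
  mk_tele <- function(tau) {
    p <- 1 / (2 * tau); s <- 0
    vapply(seq_len(nf), function(i) {
      if (stats::runif(1) < p) s <<- 1 - s
      s
    }, numeric(1))
  }
  ## additive indicator from two processes with tau = 10 and 100
  ind <- mk_tele(10) + mk_tele(100)
  ac <- stats::acf(ind, lag.max = 600, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  d <- data.frame(t = 0:600, y = ac)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-t / t1) + B * exp(-t / t2), d,
                           start = list(A = 0.5, t1 = 5, B = 0.5,
                                        t2 = 150),
                           lower = c(0, 0.5, 0, 0.5))
  cf <- stats::coef(fit)
  expect_equal(unname(cf["t1"]), 10, tolerance = 0.25)
  expect_equal(unname(cf["t2"]), 100, tolerance = 0.25)
})

test_that("persistence length recovers a discrete worm-like chain", {
  set.seed(31)
  Lp_true <- 50; ell <- 0.34
  n_seg <- 120; n_ch <- 400
  ## WLC sampling: successive tangents tilted by Gaussian angles with
  ## <theta^2> = 2 ell / Lp
  axis <- array(0, c(n_ch, n_seg + 1, 3))
  for (c in seq_len(n_ch)) {
    t_vec <- c(0, 0, 1)
    pos <- matrix(0, n_seg + 1, 3)
    for (s in seq_len(n_seg)) {
      ## random perpendicular tilt
      phi <- stats::runif(1, 0, 2 * pi)
      th <- stats::rnorm(1, 0, sqrt(2 * ell / Lp_true))
      ## build orthonormal frame around t_vec
      a <- if (abs(t_vec[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1 <- a - sum(a * t_vec) * t_vec
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(t_vec[2] * e1[3] - t_vec[3] * e1[2],
              t_vec[3] * e1[1] - t_vec[1] * e1[3],
              t_vec[1] * e1[2] - t_vec[2] * e1[1])
      t_vec <- cos(th) * t_vec +
        sin(th) * (cos(phi) * e1 + sin(phi) * e2)
      t_vec <- t_vec / sqrt(sum(t_vec^2))
      pos[s + 1, ] <- pos[s, ] + ell * t_vec
    }
    axis[c, , ] <- pos
  }
  out <- persistence_length(axis, max_n = 40, trim = 0)
  expect_equal(out$L_p, Lp_true, tolerance = 0.1)
  ## rigid rod reports a lower bound
  rod <- array(0, c(3, 50, 3))
  rod[, , 3] <- matrix(rep(seq_len(50) * 0.34, each = 3), 3)
  out_rod <- persistence_length(rod, trim = 0)
  expect_true(is.infinite(out_rod$L_p))
  ## freely jointed chain decorrelates within one segment
  fjc <- array(0, c(1, 200, 3))
  step <- matrix(stats::rnorm(199 * 3), 199, 3)
  step <- step / sqrt(rowSums(step^2))
  fjc[1, , ] <- rbind(0, apply(step, 2, cumsum))
  out_fjc <- persistence_length(fjc, max_n = 10, trim = 0)
  expect_lt(out_fjc$L_p, 1)
})
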