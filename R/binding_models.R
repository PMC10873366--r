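## Closed-form titration and spectroscopy estimators.
##
## All fits are (weighted) nonlinear least squares via minpack.lm, with
## standard errors from the Jacobian-based covariance and t-based 95%
## confidence intervals on n - p degrees of freedom.

#' Titration series container
#'
#' @param concentration Titrant concentrations (M), non-negative.
#' @param observable Measured quantity (efficiency, fraction bound, or
#'   chemical-shift change), same length.
#' @param sd Optional per-point standard deviations for weighting.
#' @param kind Label for the observable kind.
#' @return Object of class `titration_series` (a data frame).
#' @export
titration_series <- function(concentration, observable, sd = NULL,
                             kind = c("efficiency", "fraction_bound",
                                      "shift")) {
  kind <- match.arg(kind)
  stopifnot(length(concentration) == length(observable),
            all(concentration >= 0))
  o <- order(concentration)
  out <- data.frame(concentration = concentration[o],
                    observable = observable[o])
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(concentration), all(sd > 0))
    out$sd <- sd[o]
  }
  structure(out, kind = kind, class = c("titration_series", "data.frame"))
}

## shared machinery: weighted nls fit + tidy result
.fit_nls <- function(formula, data, start, lower = NULL, upper = NULL,
                     weights = NULL) {
  args <- list(formula = formula, data = data, start = start,
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(lower)) args$lower <- lower
  if (!is.null(upper)) args$upper <- upper
  if (!is.null(weights)) args$weights <- weights
  fit <- try(do.call(minpack.lm::nlsLM, args), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("nonlinear fit did not converge: ", attr(fit, "condition")$message)
  fit
}

.fit_result <- function(fit, n) {
  est <- summary(fit)$coefficients
  p <- nrow(est)
  dfree <- max(n - p, 1)
  tq <- stats::qt(0.975, dfree)
  params <- data.frame(
    parameter = rownames(est),
    estimate  = est[, "Estimate"],
    se        = est[, "Std. Error"],
    ci_lower  = est[, "Estimate"] - tq * est[, "Std. Error"],
    ci_upper  = est[, "Estimate"] + tq * est[, "Std. Error"],
    row.names = NULL
  )
  structure(list(parameters = params,
                 covariance = stats::vcov(fit),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Nonlinear least-squares fit\n")
  print(x$parameters, digits = 4)
  cat("residual norm:", signif(x$residual_norm, 4), "\n")
  invisible(x)
}

#' Extract a parameter estimate from a fit result
#' @param x A `fit_result`.
#' @param name Parameter name.
#' @return Named numeric of length one.
#' @export
coef_of <- function(x, name) {
  stopifnot(inherits(x, "fit_result"))
  i <- match(name, x$parameters$parameter)
  if (is.na(i)) stop("no parameter named ", name)
  stats::setNames(x$parameters$estimate[i], name)
}

#' Weak denaturant-binding model fit
#'
#' Fits \eqn{E(c_D) = (E_0 + \Delta E K_a c_D)/(1 + K_a c_D)}, where
#' \eqn{E_0} is the observable at zero denaturant and \eqn{\Delta E} the
#' saturating value as \eqn{c_D \to \infty} (asymptote convention, as
#' the model is written).
#'
#' @param series A [titration_series()] of efficiency vs denaturant
#'   concentration (M), at least 4 points.
#' @return A `fit_result` with parameters `Ka`, `E0`, `dE`.
#' @export
fit_denaturant_binding <- function(series) {
  stopifnot(inherits(series, "titration_series"),
            nrow(series) >= 4)
  d <- as.data.frame(series)
  w <- if (!is.null(d$sd)) 1 / d$sd^2 else NULL
  start <- list(E0 = d$observable[1],
                dE = d$observable[nrow(d)],
                Ka = 1 / max(d$concentration[d$concentration > 0], 1e-3))
  fit <- .fit_nls(observable ~ (E0 + dE * Ka * concentration) /
                    (1 + Ka * concentration),
                  d, start, lower = c(-Inf, -Inf, 1e-12),
                  upper = c(Inf, Inf, Inf), weights = w)
  res <- .fit_result(fit, nrow(d))
  ka <- coef_of(res, "Ka")
  if (ka < 1e-10) warning("Ka hit its lower bound; data may be flat")
  res
}

#' Exact 1:1 binding isotherm (fraction bound)
#'
#' Physical root of the quadratic mass-action equation for the bound
#' fraction of species Y (the labelled species at fixed total
#' concentration \eqn{c_Y}) when titrated with X:
#' \deqn{\theta = \frac{c_X + K_D + c_Y -
#'   \sqrt{(c_X + K_D + c_Y)^2 - 4 c_X c_Y}}{2 c_Y}.}
#' The minus root is the physical branch with \eqn{\theta \in [0,1]}.
#'
#' @param cX_tot Titrant total concentration(s), M.
#' @param KD Dissociation constant, M.
#' @param cY_tot Fixed-species total concentration, M.
#' @return Fraction bound in \[0, 1\], vectorised over `cX_tot`.
#' @export
isotherm_theta <- function(cX_tot, KD, cY_tot) {
  s <- cX_tot + KD + cY_tot
  theta <- (s - sqrt(pmax(s^2 - 4 * cX_tot * cY_tot, 0))) / (2 * cY_tot)
  pmin(pmax(theta, 0), 1)
}

#' Fit a 1:1 binding isotherm to fraction-bound data
#'
#' @param series A [titration_series()] of fraction bound vs titrant
#'   concentration (M).
#' @param fixed_conc Total concentration of the species held constant (M).
#' @param theta_tol Tolerance for observables outside \[0, 1\].
#' @return A `fit_result` with parameter `KD` (M).
#' @export
fit_binding_isotherm <- function(series, fixed_conc, theta_tol = 0.05) {
  stopifnot(inherits(series, "titration_series"), fixed_conc > 0)
  d <- as.data.frame(series)
  if (any(d$observable < -theta_tol | d$observable > 1 + theta_tol))
    stop("fraction-bound observations outside [0, 1] beyond tolerance")
  w <- if (!is.null(d$sd)) 1 / d$sd^2 else NULL
  ## half-saturation concentration as the KD seed
  i <- which.min(abs(d$observable - 0.5))
  start <- list(KD = max(d$concentration[i], 1e-15))
  fit <- .fit_nls(observable ~ isotherm_theta(concentration, KD, fixed_conc),
                  d, start, lower = 1e-18, upper = Inf, weights = w)
  .fit_result(fit, nrow(d))
}

#' Fraction bound from histogram component areas
#'
#' @param areas Named numeric with elements `bound` and `unbound` (the
#'   two non-donor-only components of a transfer-efficiency histogram
#'   fit), or a `histogram_fit` from [fit_histogram()] together with
#'   `bound`/`unbound` component indices.
#' @param bound,unbound Component indices when `areas` is a
#'   `histogram_fit`.
#' @return Fraction bound \eqn{\theta = a_b/(a_b + a_u)}.
#' @export
fraction_bound_from_histogram <- function(areas, bound = NULL,
                                          unbound = NULL) {
  if (inherits(areas, "histogram_fit")) {
    if (is.null(bound) || is.null(unbound))
      stop("bound and unbound component indices must be designated")
    a <- areas$components$area
    areas <- c(bound = a[bound], unbound = a[unbound])
  }
  if (!all(c("bound", "unbound") %in% names(areas)))
    stop("areas must designate 'bound' and 'unbound' components")
  unname(areas["bound"] / (areas["bound"] + areas["unbound"]))
}

#' Weighted amide chemical-shift perturbation
#'
#' \eqn{CSP = \sqrt{((\Delta\delta_H)^2 + (0.154\,\Delta\delta_N)^2)/2}}.
#'
#' @param delta_H Amide proton shift difference (ppm).
#' @param delta_N Amide nitrogen shift difference (ppm).
#' @return CSP in ppm, vectorised.
#' @export
csp <- function(delta_H, delta_N) {
  sqrt(0.5 * (delta_H^2 + (0.154 * delta_N)^2))
}

#' Chemical-shift titration model
#'
#' \deqn{\Delta\delta_{obs} = \Delta\delta_{max}\,
#'  \{(P_t + L_t + K_D) - [(P_t + L_t + K_D)^2 - 4 P_t L_t]^{1/2}\}/2 P_t}
#'
#' @param L_tot Total ligand concentration(s), M.
#' @param KD Dissociation constant, M.
#' @param ddmax Maximum shift change (ppm).
#' @param P_tot Total observed-species concentration, M.
#' @return Predicted shift changes, vectorised over `L_tot`.
#' @export
shift_titration_model <- function(L_tot, KD, ddmax, P_tot) {
  s <- P_tot + L_tot + KD
  ddmax * (s - sqrt(pmax(s^2 - 4 * P_tot * L_tot, 0))) / (2 * P_tot)
}

#' Fit a chemical-shift titration for K_D
#'
#' Fits the exact quadratic-root shift-titration model.  With a list of
#' series (one per residue) a global fit shares `KD` across residues
#' while each residue keeps its own `ddmax`.
#'
#' @param series A [titration_series()] of observed shift change vs total
#'   ligand concentration (M), or a list of such series for a global fit.
#' @param P_tot Total concentration of the observed species (M).
#' @return A `fit_result` with parameters `KD` and `ddmax` (one `ddmax`
#'   per residue in the global case).
#' @export
fit_shift_titration <- function(series, P_tot) {
  stopifnot(P_tot > 0)
  if (inherits(series, "titration_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, TRUE, "titration_series")),
            all(vapply(series, nrow, 1L) >= 5))
  nser <- length(series)
  d <- do.call(rbind, lapply(seq_len(nser), function(i) {
    x <- as.data.frame(series[[i]]); x$residue <- i; x
  }))
  start <- c(list(KD = max(stats::median(d$concentration), 1e-12)),
             stats::setNames(
               lapply(series, function(s) max(abs(s$observable))),
               paste0("ddmax", seq_len(nser))))
  rhs <- paste0(
    "shift_titration_model(concentration, KD, ",
    "c(", paste0("ddmax", seq_len(nser), collapse = ", "), ")[residue], ",
    deparse(P_tot), ")")
  fit <- .fit_nls(stats::as.formula(paste("observable ~", rhs)), d, start,
                  lower = c(1e-15, rep(-Inf, nser)),
                  upper = rep(Inf, nser + 1),
                  weights = if (!is.null(d$sd)) 1 / d$sd^2 else NULL)
  res <- .fit_result(fit, nrow(d))
  if (nser == 1)
    res$parameters$parameter[res$parameters$parameter == "ddmax1"] <- "ddmax"
  res
}

#' Mean residue ellipticity
#'
#' \eqn{MRE = mdeg / (10\,L\,C\,N)} in deg cm\eqn{^2} dmol\eqn{^{-1}}.
#'
#' @param mdeg Measured ellipticity in millidegrees.
#' @param L Path length in cm.
#' @param C Protein concentration in M.
#' @param N Number of peptide bonds.
#' @return Mean residue ellipticity, vectorised over `mdeg`.
#' @export
mean_residue_ellipticity <- function(mdeg, L, C, N) {
  if (L <= 0 || C <= 0 || N <= 0)
    stop("path length, concentration and peptide-bond count must be positive")
  mdeg / (10 * L * C * N)
}

#' Single-exponential relaxation fit (T1/T2-style decays)
#'
#' Fits \eqn{I(t) = I_0 \exp(-t/T)} to intensity-vs-delay data and
#' reports the relaxation time with a 95% confidence interval.
#'
#' @param delay Relaxation delays (s), at least 4.
#' @param intensity Measured intensities.
#' @return A `fit_result` with parameters `I0` and `T` (s).
#' @export
fit_exponential_relaxation <- function(delay, intensity) {
  stopifnot(length(delay) == length(intensity), length(delay) >= 4)
  if (stats::sd(intensity) == 0 ||
      stats::cor(delay, intensity) >= 0)
    stop("intensities do not decay with delay; nothing to fit")
  d <- data.frame(delay = delay, intensity = intensity)
  ## log-linear seed on the positive part
  pos <- d$intensity > 0
  sl <- stats::coef(stats::lm(log(intensity) ~ delay, d[pos, ]))
  start <- list(I0 = exp(sl[[1]]), T = -1 / min(sl[[2]], -1e-9))
  fit <- .fit_nls(intensity ~ I0 * exp(-delay / T), d, start,
                  lower = c(1e-12, 1e-12), upper = c(Inf, Inf))
  .fit_result(fit, nrow(d))
}
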