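## Fluorescence correlation spectroscopy: photon-pair correlators,
## nsFCS model fitting, and conversion of the chain-dynamics decay time
## to the chain reconfiguration time via 1-D Smoluchowski dynamics on
## the SAW-nu potential of mean force.

#' Correlate two photon streams
#'
#' Computes the intensity correlation
#' \eqn{G_{ij}(\tau) = \langle\delta n_i(0)\,\delta n_j(\tau)\rangle /
#' \langle n_i\rangle^2} from photon timestamps by direct pair counting
#' on a uniform lag grid.  For nsFCS use a symmetric grid at 1 ns
#' binning over \eqn{\pm 1\,\mu s} and cross-correlate photons from
#' distinct detectors.
#'
#' @param t_i,t_j Sorted photon arrival times (seconds) of channels i
#'   and j.
#' @param bin_width Lag bin width in seconds (default 1 ns).
#' @param max_lag Maximum |lag| in seconds (default 1 us).
#' @param symmetric Use a symmetric lag grid over `[-max_lag, max_lag]`?
#' @param denominator `"i2"` for the \eqn{\langle n_i\rangle^2} form, or
#'   `"geometric"` for \eqn{\langle n_i\rangle\langle n_j\rangle}.
#' @param mean_subtract Subtract the uncorrelated baseline (the
#'   \eqn{\delta n} form, baseline 0)?  With `FALSE` the raw intensity
#'   ratio \eqn{\langle n_i(0) n_j(\tau)\rangle} over the denominator is
#'   returned (baseline ~1), which is the form the multiplicative
#'   antibunching/chain-dynamics model of [fit_nsfcs()] describes.
#' @param duration Total acquisition time (s); defaults to the observed
#'   span of the two streams.
#' @return Object of class `correlation_curve`: data frame with `lag`
#'   (seconds, bin centres) and `G`.
#' @export
correlate <- function(t_i, t_j, bin_width = 1e-9, max_lag = 1e-6,
                      symmetric = TRUE,
                      denominator = c("i2", "geometric"),
                      mean_subtract = TRUE, duration = NULL) {
  denominator <- match.arg(denominator)
  if (length(t_i) == 0 || length(t_j) == 0)
    stop("empty photon stream")
  if (is.unsorted(t_i) || is.unsorted(t_j))
    stop("photon timestamps must be sorted")
  lag_min <- if (symmetric) -max_lag else 0
  counts <- .photon_pair_counts(t_i, t_j, lag_min, max_lag, bin_width)
  nbin <- length(counts)
  lag <- lag_min + (seq_len(nbin) - 0.5) * bin_width
  if (is.null(duration))
    duration <- max(t_i[length(t_i)], t_j[length(t_j)]) -
      min(t_i[1], t_j[1])
  Ni <- length(t_i); Nj <- length(t_j)
  norm <- counts * duration / (bin_width * Ni * Nj)
  base <- if (mean_subtract) 1 else 0
  G <- if (denominator == "geometric") norm - base
       else (norm - base) * (Nj / Ni)
  structure(data.frame(lag = lag, G = G),
            class = c("correlation_curve", "data.frame"))
}

#' Normalize a correlation curve to its value at a reference lag
#'
#' Display convention: curves normalised to 1 at `|lag| = ref_lag`
#' (default 0.5 us).
#'
#' @param curve A `correlation_curve`.
#' @param ref_lag Reference |lag| in seconds.
#' @return The curve with `G` rescaled.
#' @export
normalize_curve <- function(curve, ref_lag = 0.5e-6) {
  i <- which.min(abs(abs(curve$lag) - ref_lag))
  curve$G <- curve$G / curve$G[i]
  curve
}

#' Fit the nsFCS antibunching/chain-dynamics model
#'
#' Fits \deqn{g(\tau) = a\,(1 - c_{ab} e^{-|\tau|/\tau_{ab}})
#'   (1 + c_{cd} e^{-|\tau|/\tau_{cd}})} over a symmetric lag window.
#' For donor-acceptor cross-correlations the chain-dynamics term is
#' anti-correlated (`c_cd < 0`).  With `antibunching = FALSE` the ab
#' term is dropped (nested model, `c_ab = 0`).
#'
#' @param curve A `correlation_curve` on a symmetric lag grid.
#' @param antibunching Include the antibunching term?
#' @param start Optional named list of starting values
#'   (`a`, `c_ab`, `tau_ab`, `c_cd`, `tau_cd`; times in seconds).
#' @return A `fit_result` with parameters `a`, `c_cd`, `tau_cd` (s) and,
#'   when fitted, `c_ab`, `tau_ab` (s).
#' @export
fit_nsfcs <- function(curve, antibunching = TRUE, start = NULL) {
  stopifnot(inherits(curve, "correlation_curve"))
  d <- data.frame(alag = abs(curve$lag), G = curve$G)
  a0 <- mean(d$G[d$alag > 0.8 * max(d$alag)])
  g0 <- mean(d$G[d$alag < 5 * min(d$alag[d$alag > 0])])
  if (is.null(start))
    start <- list(a = a0, c_ab = 0.5, tau_ab = 3e-9,
                  c_cd = (g0 - a0) / max(a0, 1e-12) * 1.2,
                  tau_cd = 100e-9)
  if (antibunching) {
    fit <- .fit_nls(G ~ a * (1 - c_ab * exp(-alag / tau_ab)) *
                      (1 + c_cd * exp(-alag / tau_cd)),
                    d, start[c("a", "c_ab", "tau_ab", "c_cd", "tau_cd")],
                    lower = c(1e-12, 0, 1e-10, -1, 1e-10),
                    upper = c(Inf, 1, 1e-5, 10, 1e-5))
  } else {
    fit <- .fit_nls(G ~ a * (1 + c_cd * exp(-alag / tau_cd)),
                    d, start[c("a", "c_cd", "tau_cd")],
                    lower = c(1e-12, -1, 1e-10),
                    upper = c(Inf, 10, 1e-5))
  }
  res <- .fit_result(fit, nrow(d))
  if (antibunching) {
    tab <- coef_of(res, "tau_ab"); tcd <- coef_of(res, "tau_cd")
    if (max(tab, tcd) / min(tab, tcd) < 2)
      warning("tau_ab and tau_cd are nearly degenerate (ratio < 2); ",
              "amplitudes are poorly determined")
  }
  res
}

## Discretized 1-D Smoluchowski operator on a potential of mean force
## U(r) = -kT log P(r).  Nearest-neighbour hopping rates obey detailed
## balance: w(i -> i+1) = (D/h^2) sqrt(P_{i+1}/P_i).  The integral
## relaxation time of observable f is
##   tau_f = sum_k (a_k^2/lambda_k) / sum_k a_k^2
## over the nonzero eigenmodes of the symmetrized generator.
.smoluchowski_relaxation <- function(p, h, fvals, D = 1) {
  n <- length(p)
  p <- p / sum(p)
  w_up <- (D / h^2) * sqrt(p[-1] / p[-n])      # i -> i+1
  w_dn <- (D / h^2) * sqrt(p[-n] / p[-1])      # i+1 -> i
  ## symmetrized generator Ls = P^{-1/2} L P^{1/2} (tridiagonal, symmetric)
  off <- sqrt(w_up * w_dn)
  diag_el <- numeric(n)
  diag_el[-n] <- diag_el[-n] - w_up
  diag_el[-1] <- diag_el[-1] - w_dn
  Ls <- diag(diag_el)
  for (i in seq_len(n - 1)) {
    Ls[i, i + 1] <- off[i]
    Ls[i + 1, i] <- off[i]
  }
  eig <- eigen(Ls, symmetric = TRUE)
  ## amplitudes of f in the eigenbasis, weighted by sqrt(pi)
  g <- sqrt(p) * fvals
  amp <- drop(crossprod(eig$vectors, g))
  lam <- -eig$values
  keep <- lam > 1e-12 * max(lam)
  sum(amp[keep]^2 / lam[keep]) / sum(amp[keep]^2)
}

#' Convert the nsFCS chain-dynamics time to the reconfiguration time
#'
#' Models the inter-dye distance as diffusing on the potential of mean
#' force \eqn{-k_BT \ln P(r)} of the SAW-nu distribution.  The measured
#' \eqn{\tau_{cd}} is identified with the integral relaxation time of
#' the FRET-efficiency autocorrelation; the diffusion coefficient is
#' matched accordingly (relaxation times scale as 1/D, so the match is
#' exact and closed-form), and the reconfiguration time \eqn{\tau_r} is
#' the relaxation time of the distance autocorrelation
#' \eqn{\langle\delta r(0)\,\delta r(\tau)\rangle} at the matched
#' diffusion coefficient.
#'
#' @param tau_cd Fitted chain-dynamics decay time (seconds or ns; the
#'   result has the same units).
#' @param dist A [saw_distribution()] for the labelled construct.
#' @param model A [forster_model()].
#' @param n_grid Number of grid points for the discretized operator.
#' @return List with `tau_r` (same units as `tau_cd`), the matched
#'   relative diffusion coefficient `D` (nm^2 per unit of `tau_cd`), and
#'   the unit-D relaxation times `tau_E_unitD`, `tau_r_unitD`.
#' @export
reconfiguration_time <- function(tau_cd, dist, model = forster_model(),
                                 n_grid = 300) {
  stopifnot(inherits(dist, "saw_distribution"), tau_cd > 0)
  r <- seq(1e-3 * dist$R, 4 * dist$R, length.out = n_grid)
  h <- r[2] - r[1]
  p <- saw_pdf(r, dist)
  Evals <- forster_efficiency(r, model)
  tau_E1 <- .smoluchowski_relaxation(p, h, Evals, D = 1)
  tau_r1 <- .smoluchowski_relaxation(p, h, r, D = 1)
  D <- tau_E1 / tau_cd
  list(tau_r = tau_r1 / D, D = D,
       tau_E_unitD = tau_E1, tau_r_unitD = tau_r1)
}
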