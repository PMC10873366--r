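## Foerster theory and the SAW-nu end-to-end distance model.
##
## The SAW-nu density describes the inter-dye distance r of a disordered
## chain segment:
##   P(r) = A (4 pi / R) (r/R)^(2 + (gamma-1)/nu) exp(-alpha (r/R)^(1/(1-nu)))
## with A and alpha fixed by normalisation and <r^2> = R^2.  Both constants
## have closed forms in terms of gamma functions (see saw_distribution).

#' Foerster model for a dye pair
#'
#' Container for the Foerster radius of a donor/acceptor dye pair.  The
#' default of 6.0 nm corresponds to the Cy3B/CF660R pair.  `R00` and
#' `n_ref` are the zero-denaturant Foerster radius and refractive index
#' used by [corrected_forster_radius()].
#'
#' @param R0 Foerster radius in nm (distance at which E = 0.5).
#' @param R00 Zero-denaturant Foerster radius in nm (defaults to `R0`).
#' @param n_ref Refractive index of the zero-denaturant sample.
#' @return An object of class `forster_model`.
#' @export
forster_model <- function(R0 = 6.0, R00 = R0, n_ref = 1.333) {
  stopifnot(R0 > 0, R00 > 0, n_ref > 0)
  structure(list(R0 = R0, R00 = R00, n_ref = n_ref),
            class = "forster_model")
}

#' Foerster transfer efficiency at a fixed inter-dye distance
#'
#' \eqn{E(r) = 1 / (1 + r^6 / R_0^6)}.
#'
#' @param r Inter-dye distance(s) in nm, non-negative.
#' @param model A [forster_model()] (or a single numeric R0 in nm).
#' @return Transfer efficiency in \[0, 1\], vectorised over `r`.
#' @export
forster_efficiency <- function(r, model = forster_model()) {
  if (is.numeric(model)) model <- forster_model(R0 = model)
  if (any(r < 0)) stop("inter-dye distance r must be non-negative")
  1 / (1 + (r / model$R0)^6)
}

#' SAW-nu inter-dye distance distribution
#'
#' Constructs the self-avoiding-walk density with variable scaling
#' exponent `nu` and critical exponent `gamma`.  The decay constant
#' `alpha` and the normalisation `A` follow in closed form from the two
#' defining constraints: with \eqn{p = 2 + (\gamma-1)/\nu} and
#' \eqn{q = 1/(1-\nu)},
#' \deqn{\alpha = [\Gamma((p+3)/q)/\Gamma((p+1)/q)]^{q/2},\quad
#'       A = q\,\alpha^{(p+1)/q} / (4\pi\,\Gamma((p+1)/q)).}
#'
#' @param R Root-mean-square inter-dye distance in nm.
#' @param nu Scaling exponent, in (0, 1).
#' @param gamma Critical exponent (default 1.1615).
#' @return Object of class `saw_distribution` with fields `R`, `nu`,
#'   `gamma`, `alpha`, `A`.
#' @export
saw_distribution <- function(R, nu, gamma = 1.1615) {
  stopifnot(R > 0)
  if (nu <= 0 || nu >= 1)
    stop("scaling exponent nu must lie in (0, 1), got ", nu)
  p <- 2 + (gamma - 1) / nu
  q <- 1 / (1 - nu)
  lg1 <- lgamma((p + 1) / q)
  lg3 <- lgamma((p + 3) / q)
  alpha <- exp((lg3 - lg1) * q / 2)
  A <- q * alpha^((p + 1) / q) / (4 * pi * exp(lg1))
  structure(list(R = R, nu = nu, gamma = gamma, alpha = alpha, A = A),
            class = "saw_distribution")
}

#' SAW-nu probability density
#'
#' @param r Distance(s) in nm.
#' @param dist A [saw_distribution()].
#' @return Density values (1/nm); zero at r = 0 and for r < 0.
#' @export
saw_pdf <- function(r, dist) {
  stopifnot(inherits(dist, "saw_distribution"))
  p <- 2 + (dist$gamma - 1) / dist$nu
  q <- 1 / (1 - dist$nu)
  x <- r / dist$R
  out <- numeric(length(r))
  ok <- r > 0
  out[ok] <- dist$A * (4 * pi / dist$R) * x[ok]^p *
    exp(-dist$alpha * x[ok]^q)
  out
}

#' Mean transfer efficiency of a SAW-nu chain
#'
#' Evaluates \eqn{\langle E\rangle = \int_0^\infty E(r) P(r)\,dr} by
#' adaptive quadrature.
#'
#' @param dist A [saw_distribution()].
#' @param model A [forster_model()].
#' @param abs_tol Absolute quadrature tolerance.
#' @return Mean efficiency in (0, 1).
#' @export
mean_efficiency <- function(dist, model = forster_model(),
                            abs_tol = 1e-8) {
  stopifnot(inherits(dist, "saw_distribution"))
  f <- function(r) forster_efficiency(r, model) * saw_pdf(r, dist)
  ## split at R to help the quadrature across the density peak
  i1 <- stats::integrate(f, 0, dist$R, abs.tol = abs_tol / 2,
                         rel.tol = 1e-10, subdivisions = 400L)
  i2 <- stats::integrate(f, dist$R, Inf, abs.tol = abs_tol / 2,
                         rel.tol = 1e-10, subdivisions = 400L)
  if (i1$message != "OK" || i2$message != "OK")
    stop("quadrature did not converge; achieved error ",
         signif(i1$abs.error + i2$abs.error, 3))
  i1$value + i2$value
}

#' Scaling-law closure relating R, b and N
#'
#' The closure \eqn{R = b N^\nu} removes the free exponent:
#' \eqn{\nu(R) = \ln(R/b)/\ln N}.  `N` is the number of monomers between
#' the fluorophores (no linker correction); `b` is the monomer prefactor,
#' approximately 0.55 nm for polypeptides.
#'
#' @param b Monomer length prefactor in nm.
#' @param N Number of monomers between the fluorophores (>= 2).
#' @return Object of class `scaling_closure`.
#' @export
scaling_closure <- function(b = 0.55, N = 195) {
  stopifnot(b > 0, N >= 2)
  structure(list(b = b, N = N), class = "scaling_closure")
}

#' Invert a mean transfer efficiency to (R, nu) under the scaling closure
#'
#' Solves the transcendental equation
#' \eqn{\langle E\rangle = \int E(r) P_{R,\nu(R)}(r)\,dr} for the
#' root-mean-square distance R, substituting
#' \eqn{\nu = \ln(R/b)/\ln N}.  The mean efficiency is strictly
#' decreasing in R, so the root is unique; it is bracketed on
#' (b, bN) and located with [stats::uniroot()].
#'
#' @param E_mean Measured mean transfer efficiency, in (0, 1).
#' @param model A [forster_model()].
#' @param closure A [scaling_closure()].
#' @param gamma Critical exponent passed to [saw_distribution()].
#' @param tol Root tolerance on R (nm).
#' @return List with `R` (nm), `nu`, and the achieved `E_mean`.
#' @export
invert_efficiency <- function(E_mean, model = forster_model(),
                              closure = scaling_closure(),
                              gamma = 1.1615, tol = 1e-9) {
  stopifnot(E_mean > 0, E_mean < 1)
  b <- closure$b; N <- closure$N
  f <- function(R) {
    nu <- log(R / b) / log(N)
    mean_efficiency(saw_distribution(R, nu, gamma), model) - E_mean
  }
  lo <- b * N^0.02
  hi <- b * N^0.98
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop("mean efficiency ", E_mean, " has no root in the bracket [",
         signif(lo, 4), ", ", signif(hi, 4), "] nm")
  root <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = tol)
  R <- root$root
  list(R = R, nu = log(R / b) / log(N), E_mean = E_mean)
}

#' Radius of gyration of a SAW-nu chain
#'
#' \deqn{R_g \approx R \sqrt{\gamma(\gamma+1) /
#'   (2(\gamma+2\nu)(\gamma+2\nu+1))}.}
#'
#' @param dist A [saw_distribution()].
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(dist) {
  stopifnot(inherits(dist, "saw_distribution"))
  g <- dist$gamma; nu <- dist$nu
  dist$R * sqrt(g * (g + 1) / (2 * (g + 2 * nu) * (g + 2 * nu + 1)))
}

#' Relative donor lifetime for a fluctuating distance distribution
#'
#' For a chain rapidly sampling P(r), the mean donor lifetime in the
#' presence of the acceptor satisfies
#' \deqn{\langle\tau_{DA}\rangle/\tau_D = 1 - \langle E\rangle +
#'   \sigma^2 / (1 - \langle E\rangle)}
#' where \eqn{\sigma^2 = \int (E(r) - \langle E\rangle)^2 P(r)\,dr}.
#' A static distance has \eqn{\sigma^2 = 0} and falls on the diagonal
#' \eqn{1 - E}.
#'
#' @param dist A [saw_distribution()].
#' @param model A [forster_model()].
#' @return List with `E_mean`, `sigma2` and `tau_ratio`.
#' @export
lifetime_ratio <- function(dist, model = forster_model()) {
  E_mean <- mean_efficiency(dist, model)
  f <- function(r)
    (forster_efficiency(r, model) - E_mean)^2 * saw_pdf(r, dist)
  s1 <- stats::integrate(f, 0, dist$R, rel.tol = 1e-10,
                         subdivisions = 400L)$value
  s2 <- stats::integrate(f, dist$R, Inf, rel.tol = 1e-10,
                         subdivisions = 400L)$value
  sigma2 <- s1 + s2
  list(E_mean = E_mean, sigma2 = sigma2,
       tau_ratio = 1 - E_mean + sigma2 / (1 - E_mean))
}

#' Denaturant-corrected Foerster radius
#'
#' Corrects the Foerster radius for the refractive-index change of a
#' denaturant-containing sample:
#' \eqn{R_0^6(c_D) = R_{0,0}^6\,(n_{ref}/n(c_D))^4}, returned as the
#' sixth root.
#'
#' @param model A [forster_model()] carrying `R00` and `n_ref`.
#' @param n_cD Refractive index at the denaturant concentration.
#' @return Corrected Foerster radius in nm.
#' @export
corrected_forster_radius <- function(model, n_cD) {
  stopifnot(inherits(model, "forster_model"))
  if (n_cD <= 0) stop("refractive index must be positive")
  model$R00 * (model$n_ref / n_cD)^(4 / 6)
}
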