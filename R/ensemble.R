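## Ensemble observables from trajectories: back-calculated FRET
## efficiencies, concordance-based eps_pp refinement, contact maps and
## kinetics, DNA persistence length.

#' Back-calculate a mean FRET efficiency from a trajectory
#'
#' Computes the bead-bead distance between two labelled positions in
#' every equilibrated frame and averages the Foerster efficiency over
#' the resulting distance distribution (dye linkers are ignored).
#'
#' @param traj A `cg_trajectory`.
#' @param pair Integer vector of two bead indices (labelled residues).
#' @param model A [forster_model()] (R0 = 6.0 nm default).
#' @param min_frames Minimum number of usable frames.
#' @return List with `E_mean`, the per-frame `distances` (nm) and
#'   `n_frames`.
#' @export
ensemble_efficiency <- function(traj, pair, model = forster_model(),
                                min_frames = 100) {
  stopifnot(inherits(traj, "cg_trajectory"), length(pair) == 2)
  fr <- equilibrated_frames(traj)
  if (dim(fr)[1] < min_frames)
    warning("only ", dim(fr)[1], " equilibrated frames (< ", min_frames,
            "); efficiency estimate may be unreliable")
  x1 <- matrix(fr[, pair[1], ], ncol = 3)
  x2 <- matrix(fr[, pair[2], ], ncol = 3)
  d <- sqrt(rowSums((x1 - x2)^2))
  list(E_mean = mean(forster_efficiency(d, model)), distances = d,
       n_frames = length(d))
}

#' Back-calculate efficiencies for a set of labelled pairs
#'
#' @param traj A `cg_trajectory`.
#' @param pairs Two-column matrix or data frame of bead index pairs.
#' @param model A [forster_model()].
#' @return Data frame with columns `i`, `j`, `E_sim`.
#' @export
pair_efficiencies <- function(traj, pairs, model = forster_model()) {
  pairs <- as.matrix(pairs)
  data.frame(
    i = pairs[, 1], j = pairs[, 2],
    E_sim = apply(pairs, 1, function(p)
      ensemble_efficiency(traj, p, model, min_frames = 1)$E_mean))
}

#' Lin's concordance correlation coefficient
#'
#' \deqn{\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)}
#' with population (1/n) variances.  Penalises both scatter and
#' systematic offset; \eqn{\rho_c \le |r|} with equality only for mean-
#' and scale-matched vectors.
#'
#' @param E_sim,E_exp Paired numeric vectors (length >= 3).
#' @return Concordance coefficient in \[-1, 1\].
#' @export
concordance <- function(E_sim, E_exp) {
  stopifnot(length(E_sim) == length(E_exp), length(E_sim) >= 3)
  n <- length(E_sim)
  sx <- stats::var(E_sim) * (n - 1) / n
  sy <- stats::var(E_exp) * (n - 1) / n
  if (sx == 0 || sy == 0) stop("zero variance in input vector")
  sxy <- stats::cov(E_sim, E_exp) * (n - 1) / n
  2 * sxy / (sx + sy + (mean(E_sim) - mean(E_exp))^2)
}

#' Refine the disordered-region interaction strength eps_pp
#'
#' Runs unrestrained simulations over a grid of the uniform
#' disordered-bead interaction strength \eqn{\varepsilon_{pp}},
#' back-calculates FRET efficiencies for the labelled pairs at each
#' grid point, and scores the agreement with the experimental
#' efficiencies by Lin's concordance coefficient.  The refined value is
#' the grid argmax.
#'
#' @param topology A protein (or complex) `cg_topology`.
#' @param protocol A [simulation_protocol()].
#' @param E_exp Data frame with columns `i`, `j`, `E` of experimental
#'   mean efficiencies for labelled bead pairs.
#' @param grid Grid of eps_pp values in units of \eqn{k_B T}.
#' @param electrostatics An [electrostatics_model()].
#' @param model A [forster_model()].
#' @param trajectories Optional precomputed list of `cg_trajectory`
#'   objects, one per grid point (reuse instead of re-running).
#' @return List with `best_eps_pp`, `rho_c` (per grid point), `grid`,
#'   `efficiencies` (list of per-pair tables) and `trajectories`.
#' @export
refine_epsilon_pp <- function(topology, protocol, E_exp,
                              grid = c(0.05, 0.1, 0.16, 0.25, 0.4),
                              electrostatics = electrostatics_model(),
                              model = forster_model(),
                              trajectories = NULL) {
  stopifnot(all(c("i", "j", "E") %in% names(E_exp)), nrow(E_exp) >= 3)
  effs <- list(); rho <- numeric(length(grid)); trajs <- list()
  for (g in seq_along(grid)) {
    if (!is.null(trajectories)) {
      tr <- trajectories[[g]]
    } else {
      topo_g <- topology
      topo_g$params$eps_pp_kT <- grid[g]
      tr <- run_simulation(topo_g, protocol, electrostatics)
    }
    eff <- pair_efficiencies(tr, E_exp[, c("i", "j")], model)
    effs[[g]] <- eff
    rho[g] <- concordance(eff$E_sim, E_exp$E)
    trajs[[g]] <- tr
  }
  contrast <- diff(range(rho))
  if (contrast < 0.02)
    warning("concordance varies by < 0.02 across the grid; ",
            "sampling noise may exceed the grid contrast")
  list(best_eps_pp = grid[which.max(rho)], rho_c = rho, grid = grid,
       efficiencies = effs, trajectories = trajs)
}

## mass-weighted centre of mass of a bead set, per frame (nf x 3)
.dom_com <- function(fr, ii, mass) {
  w <- mass[ii] / sum(mass[ii])
  out <- matrix(0, dim(fr)[1], 3)
  for (k in 1:3)
    out[, k] <- matrix(fr[, ii, k], ncol = length(ii)) %*% w
  out
}

#' Contact fraction map
#'
#' Fraction of equilibrated frames in which two units are in contact.
#' At `"domain"` granularity a contact means the centre-of-mass
#' distance of two declared domains is below the cutoff (1.0 nm); at
#' `"residue"` granularity the bead-bead distance is used.
#'
#' @param traj A `cg_trajectory`.
#' @param cutoff Contact cutoff in nm.
#' @param granularity `"residue"` or `"domain"`.
#' @param domains Named list of bead index vectors (for `"domain"`).
#' @return Object of class `contact_map`: symmetric matrix of contact
#'   fractions with zero diagonal, with attributes `cutoff` and
#'   `granularity`.
#' @export
contact_fraction_map <- function(traj, cutoff = 1.0,
                                 granularity = c("residue", "domain"),
                                 domains = NULL) {
  granularity <- match.arg(granularity)
  fr <- equilibrated_frames(traj)
  nf <- dim(fr)[1]
  if (granularity == "domain") {
    if (is.null(domains)) stop("domain granularity requires 'domains'")
    nd <- length(domains)
    com <- array(0, c(nf, nd, 3))
    m <- traj$topology$beads$mass
    for (d in seq_len(nd))
      com[, d, ] <- .dom_com(fr, domains[[d]], m)
    pos <- com; nu <- nd
    labs <- names(domains)
  } else {
    pos <- fr; nu <- dim(fr)[2]
    labs <- NULL
  }
  cm <- matrix(0, nu, nu, dimnames = list(labs, labs))
  for (a in seq_len(nu - 1)) {
    for (b in (a + 1):nu) {
      d2 <- (pos[, a, 1] - pos[, b, 1])^2 + (pos[, a, 2] - pos[, b, 2])^2 +
        (pos[, a, 3] - pos[, b, 3])^2
      cm[a, b] <- cm[b, a] <- mean(d2 < cutoff^2)
    }
  }
  structure(cm, cutoff = cutoff, granularity = granularity,
            class = c("contact_map", "matrix"))
}

#' Signed difference of two contact maps
#'
#' Elementwise `map_a - map_b`; with the bound-state map first, positive
#' values report contacts gained on binding.
#'
#' @param map_a,map_b `contact_map` objects with matching granularity
#'   and cutoff.
#' @return A signed `contact_map`.
#' @export
contact_difference <- function(map_a, map_b) {
  if (!identical(dim(map_a), dim(map_b)))
    stop("contact maps have different shapes")
  if (!identical(attr(map_a, "granularity"), attr(map_b, "granularity")) ||
      !identical(attr(map_a, "cutoff"), attr(map_b, "cutoff")))
    stop("contact maps were computed with different settings")
  out <- unclass(map_a) - unclass(map_b)
  structure(out, cutoff = attr(map_a, "cutoff"),
            granularity = attr(map_a, "granularity"),
            class = c("contact_map", "matrix"))
}

#' Autocorrelation and double-exponential lifetimes of a domain contact
#'
#' Computes the normalised autocorrelation of the binary
#' contact-formation indicator between two domains (centre-of-mass
#' distance below the cutoff) and fits
#' \eqn{A e^{-t/\tau_1} + B e^{-t/\tau_2}} (with \eqn{\tau_1 \le \tau_2}
#' by convention).  Lags up to `max_lag_frac` of the trajectory length
#' enter the fit, weighted by the number of contributing frame pairs.
#'
#' @param traj A `cg_trajectory`.
#' @param domain_pair List of two bead index vectors.
#' @param cutoff Contact cutoff in nm.
#' @param max_lag_frac Longest fitted lag as a fraction of the
#'   trajectory length.
#' @param double_exponential Fit two components? (`FALSE` fits a single
#'   exponential; B is reported as 0.)
#' @return Object of class `contact_kinetics`: list with `lag` (ps),
#'   `acf`, fitted `A`, `B`, `tau1`, `tau2` (ps) and the `fit_result`.
#' @export
contact_autocorrelation <- function(traj, domain_pair, cutoff = 1.0,
                                    max_lag_frac = 0.2,
                                    double_exponential = TRUE) {
  fr <- equilibrated_frames(traj)
  nf <- dim(fr)[1]
  m <- traj$topology$beads$mass
  com <- lapply(domain_pair, function(ii) .dom_com(fr, ii, m))
  d2 <- rowSums((com[[1]] - com[[2]])^2)
  ind <- as.numeric(d2 < cutoff^2)
  if (stats::var(ind) == 0)
    stop("contact indicator is constant over the trajectory ",
         "(no transitions)")
  dt_frame <- mean(diff(traj$times[traj$equilibrated][1:2]))
  max_lag <- max(floor(nf * max_lag_frac), 4)
  ac <- stats::acf(ind, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lag_t <- (seq_along(ac) - 1) * dt_frame
  w <- nf - (seq_along(ac) - 1)
  d <- data.frame(t = lag_t, y = ac, w = w)
  if (double_exponential) {
    t_half <- lag_t[which(ac < 0.5)[1]]
    if (is.na(t_half)) t_half <- lag_t[length(lag_t)] / 4
    start <- list(A = 0.6, tau1 = max(t_half, dt_frame),
                  B = 0.4, tau2 = max(4 * t_half, 2 * dt_frame))
    fit <- .fit_nls(y ~ A * exp(-t / tau1) + B * exp(-t / tau2), d,
                    start, lower = c(0, dt_frame / 10, 0, dt_frame / 10),
                    upper = c(2, Inf, 2, Inf), weights = d$w)
    res <- .fit_result(fit, nrow(d))
    A <- coef_of(res, "A"); B <- coef_of(res, "B")
    t1 <- coef_of(res, "tau1"); t2 <- coef_of(res, "tau2")
    if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp
                   tmp <- A; A <- B; B <- tmp }
  } else {
    start <- list(A = 1, tau1 = lag_t[max(which(ac > exp(-1))[1], 2)])
    fit <- .fit_nls(y ~ A * exp(-t / tau1), d, start,
                    lower = c(0, dt_frame / 10), upper = c(2, Inf),
                    weights = d$w)
    res <- .fit_result(fit, nrow(d))
    A <- coef_of(res, "A"); B <- 0
    t1 <- coef_of(res, "tau1"); t2 <- NA_real_
  }
  structure(list(lag = lag_t, acf = ac, A = unname(A), B = unname(B),
                 tau1 = unname(t1), tau2 = unname(t2), fit = res),
            class = "contact_kinetics")
}

#' Tangent-correlation persistence length
#'
#' Fits \eqn{\langle \hat t_i \cdot \hat t_{i+n}\rangle =
#' \exp(-n\,\ell/L_p)} to the tangent-vector correlations of a polymer
#' axis, averaged over frames and positions.  For a duplex trajectory
#' the axis is the sequence of base-pair midpoints (mean of the two
#' paired C4' beads).
#'
#' @param traj A `cg_trajectory` of a DNA duplex (its topology must
#'   carry the Watson-Crick `pair_id` annotation), or a 3-d array
#'   (frames x points x 3) of axis coordinates.
#' @param smooth_window Running-mean window (in points) applied to the
#'   axis before tangents are taken.  Defaults to one helical turn
#'   (11 bp) for duplex trajectories -- base-pair midpoints trace a
#'   small helix around the true axis, which otherwise imprints a
#'   10.5-bp oscillation on the tangent correlations -- and to 1 (no
#'   smoothing) for plain axis arrays.
#' @param max_n Longest tangent separation used in the fit (defaults to
#'   a third of the axis length, capped at 25; moderate separations
#'   relax orders of magnitude faster than the filament's longest
#'   bending modes, so they equilibrate and average far better in
#'   finite trajectories).
#' @param trim Number of terminal base pairs dropped from each end
#'   (fraying).
#' @return List with `L_p` (nm; `Inf` reported as a lower bound when
#'   correlations do not decay), `ell` (mean segment length, nm),
#'   `n` (separations), `corr` (mean tangent correlations).
#' @export
persistence_length <- function(traj, max_n = NULL, trim = 3,
                               smooth_window = NULL) {
  if (inherits(traj, "cg_trajectory")) {
    if (is.null(smooth_window)) smooth_window <- 11
    pair_id <- attr(traj$topology, "pair_id")
    if (is.null(pair_id))
      stop("topology lacks Watson-Crick pair annotation")
    fr <- equilibrated_frames(traj)
    beads <- traj$topology$beads
    nt_key <- paste(beads$chain, beads$resid)
    nts <- unique(nt_key)
    iC4 <- vapply(nts, function(k)
      which(nt_key == k & beads$atom == "C4'"), 1L)
    wc <- .wc_partners(pair_id)
    nbp <- nrow(wc)
    if (nbp < 10) stop("duplex too short for a persistence length fit")
    axis <- array(0, c(dim(fr)[1], nbp, 3))
    for (b in seq_len(nbp))
      axis[, b, ] <- (fr[, iC4[wc[b, 1]], ] + fr[, iC4[wc[b, 2]], ]) / 2
  } else {
    axis <- traj
    stopifnot(length(dim(axis)) == 3)
    if (is.null(smooth_window)) smooth_window <- 1
  }
  npt <- dim(axis)[2]
  if (trim > 0 && npt - 2 * trim >= 10)
    axis <- axis[, (trim + 1):(npt - trim), , drop = FALSE]
  npt <- dim(axis)[2]
  if (smooth_window > 1) {
    w <- smooth_window
    ns <- npt - w + 1
    if (ns < 12) stop("axis too short for the smoothing window")
    sm <- array(0, c(dim(axis)[1], ns, 3))
    for (b in seq_len(ns))
      sm[, b, ] <- apply(axis[, b:(b + w - 1), , drop = FALSE],
                         c(1, 3), mean)
    axis <- sm
    npt <- ns
  }
  tan <- axis[, -1, , drop = FALSE] - axis[, -npt, , drop = FALSE]
  len <- sqrt(tan[, , 1]^2 + tan[, , 2]^2 + tan[, , 3]^2)
  for (k in 1:3) tan[, , k] <- tan[, , k] / len
  ell <- mean(len)
  nt <- dim(tan)[2]
  if (is.null(max_n)) max_n <- min(30, nt - 2)
  corr <- vapply(seq_len(max_n), function(s) {
    i1 <- seq_len(nt - s)
    mean(tan[, i1, 1] * tan[, i1 + s, 1] +
           tan[, i1, 2] * tan[, i1 + s, 2] +
           tan[, i1, 3] * tan[, i1 + s, 3])
  }, 0)
  ns <- seq_len(max_n)
  pos <- corr > 0.05
  if (all(corr > 0.9)) {
    ## rigid rod: no measurable decay
    return(list(L_p = Inf, ell = ell, n = ns, corr = corr,
                lower_bound = TRUE))
  }
  ## free intercept absorbs uncorrelated per-point axis noise, which
  ## otherwise deflates the apparent persistence length at small n
  use <- pos & ns <= max(which(pos)) & ns >= 2
  if (sum(use) < 3) {
    ## correlations die within a segment or two: slope through n = 1
    lp <- -ell / log(max(corr[1], 1e-6))
    return(list(L_p = lp, ell = ell, n = ns, corr = corr,
                lower_bound = FALSE))
  }
  fit <- stats::lm(log(corr[use]) ~ ns[use])
  slope <- stats::coef(fit)[[2]]
  list(L_p = -ell / slope, ell = ell, n = ns, corr = corr,
       lower_bound = FALSE)
}
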