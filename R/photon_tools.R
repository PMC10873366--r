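## Photon-stream processing: burst search, corrected transfer efficiency
## and PIE stoichiometry, burst filtering, histogram fitting, FCS/nsFCS.

#' Photon stream container
#'
#' Timestamped, channel-tagged photons from a confocal single-molecule
#' experiment with pulsed interleaved excitation (PIE).
#'
#' @param time Arrival times in seconds, sorted non-decreasing.
#' @param channel Detection channel, `"donor"` or `"acceptor"`.
#' @param excitation Which laser pulse excited the molecule, `"donor"`
#'   or `"acceptor"` (PIE).
#' @param microtime Detection delay after the excitation pulse (ns);
#'   must be below the excitation period.
#' @param polarization Optional `"par"`/`"perp"` detector tag.
#' @param period Excitation period in ns (25 ns at 40 MHz).
#' @return Object of class `photon_stream` (a data frame).
#' @export
photon_stream <- function(time, channel, excitation,
                          microtime = rep(0, length(time)),
                          polarization = NULL, period = 25) {
  n <- length(time)
  stopifnot(length(channel) == n, length(excitation) == n,
            length(microtime) == n)
  if (is.unsorted(time)) stop("photon timestamps must be sorted")
  if (any(microtime < 0 | microtime >= period))
    stop("microtimes must lie in [0, excitation period)")
  stopifnot(all(channel %in% c("donor", "acceptor")),
            all(excitation %in% c("donor", "acceptor")))
  out <- data.frame(time = time, channel = channel,
                    excitation = excitation, microtime = microtime)
  if (!is.null(polarization)) out$polarization <- polarization
  structure(out, period = period,
            class = c("photon_stream", "data.frame"))
}

#' Correction factors for burst observables
#'
#' @param bg_donor,bg_acceptor Background count rates (Hz) in the donor
#'   and acceptor channels under donor excitation.
#' @param bg_acceptor_aex Background rate (Hz) in the acceptor channel
#'   under acceptor excitation.
#' @param crosstalk Fraction of donor photons detected in the acceptor
#'   channel.
#' @param direct_excitation Fraction of acceptor-excitation signal that
#'   leaks into the donor-excitation acceptor counts.
#' @param gamma Detection-efficiency/quantum-yield correction factor
#'   applied to donor counts.
#' @return Object of class `correction_set`.
#' @export
correction_set <- function(bg_donor = 0, bg_acceptor = 0,
                           bg_acceptor_aex = 0, crosstalk = 0,
                           direct_excitation = 0, gamma = 1) {
  stopifnot(crosstalk >= 0, crosstalk < 1,
            direct_excitation >= 0, direct_excitation < 1, gamma > 0)
  structure(list(bg_donor = bg_donor, bg_acceptor = bg_acceptor,
                 bg_acceptor_aex = bg_acceptor_aex, crosstalk = crosstalk,
                 direct_excitation = direct_excitation, gamma = gamma),
            class = "correction_set")
}

#' Identify fluorescence bursts in a photon stream
#'
#' Combines runs of consecutive photons separated by less than
#' `max_interphoton` into bursts and drops runs with fewer than
#' `min_photons` photons.
#'
#' @param stream A [photon_stream()].
#' @param max_interphoton Maximum interphoton time within a burst,
#'   seconds (default 100 us).
#' @param min_photons Minimum number of photons per burst.
#' @return Data frame with one row per burst: `start`, `end` (photon
#'   indices into the stream), `n_photons`, `t_start`, `t_end`,
#'   `duration_ms`.
#' @export
identify_bursts <- function(stream, max_interphoton = 100e-6,
                            min_photons = 50) {
  stopifnot(inherits(stream, "photon_stream"))
  n <- nrow(stream)
  if (n == 0)
    return(data.frame(start = integer(), end = integer(),
                      n_photons = integer(), t_start = numeric(),
                      t_end = numeric(), duration_ms = numeric()))
  gap <- diff(stream$time) >= max_interphoton
  start <- c(1L, which(gap) + 1L)
  end <- c(which(gap), n)
  keep <- (end - start + 1L) >= min_photons
  data.frame(start = start[keep], end = end[keep],
             n_photons = (end - start + 1L)[keep],
             t_start = stream$time[start[keep]],
             t_end = stream$time[end[keep]],
             duration_ms = (stream$time[end[keep]] -
                              stream$time[start[keep]]) * 1e3)
}

#' Per-burst corrected observables: E, S and mean donor microtime
#'
#' Computes raw counts per (channel, excitation) combination, applies
#' background, crosstalk, direct-excitation and gamma corrections, and
#' returns per-burst transfer efficiency `E = n'_A / (n'_A + n'_D)`, PIE
#' stoichiometry
#' `S = (n_D^D + n_A^D) / (n_D^D + n_A^D + n_A^A)` (background-corrected
#' counts, no gamma), the mean donor microtime, and the within-burst
#' half-by-half efficiency drift used by the acceptor-bleach filter.
#'
#' @param stream A [photon_stream()].
#' @param bursts Burst table from [identify_bursts()].
#' @param corrections A [correction_set()].
#' @return The burst table with columns `nDD`, `nAD`, `nAA`, `nA_corr`,
#'   `nD_corr`, `E`, `S`, `mean_donor_microtime`, `E_drift`, `flagged`.
#' @export
burst_observables <- function(stream, bursts,
                              corrections = correction_set()) {
  stopifnot(inherits(stream, "photon_stream"))
  nb <- nrow(bursts)
  out <- bursts
  out$nDD <- out$nAD <- out$nAA <- integer(nb)
  out$E <- out$S <- out$mean_donor_microtime <- out$E_drift <- NA_real_
  out$nA_corr <- out$nD_corr <- NA_real_
  out$flagged <- FALSE
  for (k in seq_len(nb)) {
    idx <- bursts$start[k]:bursts$end[k]
    ch <- stream$channel[idx]; ex <- stream$excitation[idx]
    dex <- ex == "donor"
    nDD <- sum(dex & ch == "donor")
    nAD <- sum(dex & ch == "acceptor")
    nAA <- sum(!dex & ch == "acceptor")
    dur <- max(stream$time[idx[length(idx)]] - stream$time[idx[1]], 0)
    bDD <- nDD - corrections$bg_donor * dur
    bAD <- nAD - corrections$bg_acceptor * dur
    bAA <- nAA - corrections$bg_acceptor_aex * dur
    nD_corr <- corrections$gamma * bDD
    nA_corr <- bAD - corrections$crosstalk * bDD -
      corrections$direct_excitation * bAA
    tot <- nA_corr + nD_corr
    out$nDD[k] <- nDD; out$nAD[k] <- nAD; out$nAA[k] <- nAA
    out$nA_corr[k] <- nA_corr; out$nD_corr[k] <- nD_corr
    if (tot <= 0) {
      out$flagged[k] <- TRUE
    } else {
      out$E[k] <- nA_corr / tot
    }
    stot <- bDD + bAD + bAA
    out$S[k] <- if (stot > 0) (bDD + bAD) / stot else NA_real_
    dph <- dex & ch == "donor"
    if (any(dph))
      out$mean_donor_microtime[k] <- mean(stream$microtime[idx][dph])
    ## acceptor-bleach proxy: raw acceptor fraction, first vs second half
    half <- seq_along(idx) <= length(idx) / 2
    e_half <- function(sel) {
      nd <- sum(dex & sel & ch == "donor")
      na <- sum(dex & sel & ch == "acceptor")
      if (nd + na == 0) NA_real_ else na / (na + nd)
    }
    out$E_drift[k] <- e_half(half) - e_half(!half)
  }
  out
}

#' Filter bursts by stoichiometry, aggregates and acceptor bleaching
#'
#' Applies three filters: (i) keep bursts with PIE stoichiometry inside
#' `S_window` (removes donor-only and acceptor-only molecules); (ii)
#' remove bursts overlapping 1-s bins whose total photon count exceeds
#' three times the mean binned signal (aggregates); (iii) remove bursts
#' whose within-burst efficiency drifts by more than `bleach_threshold`
#' between its first and second half (acceptor bleaching during transit;
#' applied to bursts with at least `bleach_min_photons` photons).
#'
#' @param bursts Burst table from [burst_observables()].
#' @param stream The originating [photon_stream()] (needed for the
#'   aggregate rule); may be `NULL` to skip it.
#' @param S_window Stoichiometry window, default `c(0.3, 0.7)`.
#' @param aggregate_rule Apply the 3x-mean 1-s bin rule?
#' @param bleach_rule Apply the efficiency-drift bleach filter?
#' @param bleach_threshold Maximum |E drift| between burst halves.
#' @param bleach_min_photons Minimum photons for the bleach test.
#' @return Filtered burst table.
#' @export
filter_bursts <- function(bursts, stream = NULL, S_window = c(0.3, 0.7),
                          aggregate_rule = TRUE, bleach_rule = TRUE,
                          bleach_threshold = 0.3,
                          bleach_min_photons = 20) {
  keep <- !is.na(bursts$S) &
    bursts$S >= S_window[1] & bursts$S <= S_window[2] &
    !bursts$flagged
  if (aggregate_rule && !is.null(stream) && nrow(stream) > 0) {
    bin <- floor(stream$time)
    cnt <- table(bin)
    hot <- as.numeric(names(cnt))[cnt > 3 * mean(cnt)]
    if (length(hot))
      keep <- keep & !(floor(bursts$t_start) %in% hot |
                         floor(bursts$t_end) %in% hot)
  }
  if (bleach_rule) {
    drift <- abs(bursts$E_drift)
    keep <- keep & !(bursts$n_photons >= bleach_min_photons &
                       !is.na(drift) & drift > bleach_threshold)
  }
  bursts[keep, , drop = FALSE]
}

## component density on the E axis
.comp_density <- function(x, mean, width, model) {
  if (model == "gaussian") {
    stats::dnorm(x, mean, width)
  } else {
    ## lognormal parameterised by its own mean and sd on the E axis
    s2 <- log(1 + (width / mean)^2)
    stats::dlnorm(pmax(x, .Machine$double.eps),
                  meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  }
}

#' Fit Gaussian or log-normal components to transfer-efficiency values
#'
#' Bins the per-burst efficiencies and fits a sum of `components` peak
#' functions by least squares.  When `E` is a list of vectors the
#' histograms are fitted globally with the parameters named in `shared`
#' ("mean" and/or "width") common to all histograms while areas stay
#' per-histogram.
#'
#' @param E Numeric vector of burst efficiencies, or a list of vectors
#'   for a global fit.
#' @param components Number of peak components.
#' @param model `"gaussian"` or `"lognormal"`.
#' @param shared Character vector of parameter families shared across
#'   histograms in a global fit.
#' @param bins Number of histogram bins.
#' @param range Histogram range on the E axis.
#' @param start Optional list with numeric vectors `mean` and `width`
#'   (length `components`) of starting values.
#' @return Object of class `histogram_fit`: a list with `components`
#'   (data frame of mean, width, area; one row per component, with a
#'   `histogram` column in global fits), `fitted`, `breaks`, and the
#'   underlying `fit_result`.
#' @export
fit_histogram <- function(E, components = 1,
                          model = c("gaussian", "lognormal"),
                          shared = c("mean", "width"),
                          bins = 40, range = c(-0.1, 1.1),
                          start = NULL) {
  model <- match.arg(model)
  elist <- if (is.list(E)) E else list(E)
  nh <- length(elist)
  for (e in elist) {
    if (length(e) < 50)
      stop("at least 50 bursts per histogram are required")
    if (stats::sd(e) < 1e-12)
      stop("degenerate input: efficiencies have zero variance")
  }
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  bw <- diff(breaks)[1]
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  counts <- lapply(elist, function(e)
    graphics::hist(pmin(pmax(e, range[1]), range[2]), breaks = breaks,
                   plot = FALSE)$counts)
  if (is.null(start)) {
    ## evenly spaced quantile seeds
    qs <- stats::quantile(unlist(elist),
                          probs = (seq_len(components) - 0.5) / components)
    start <- list(mean = as.numeric(qs),
                  width = rep(stats::sd(unlist(elist)) /
                                sqrt(components), components))
  }
  ## parameter vector layout: means (k), widths (k) [shared or per-hist],
  ## areas (k per histogram)
  share_mean <- "mean" %in% shared || nh == 1
  share_width <- "width" %in% shared || nh == 1
  nm <- if (share_mean) components else components * nh
  nw <- if (share_width) components else components * nh
  p0 <- c(rep(start$mean, length.out = nm),
          rep(start$width, length.out = nw),
          rep(vapply(counts, sum, 1) / components, each = components))
  lower <- c(rep(range[1], nm), rep(1e-4, nw),
             rep(0, components * nh))
  unpack <- function(p) {
    m <- matrix(p[seq_len(nm)], nrow = components,
                ncol = nh)
    w <- matrix(p[nm + seq_len(nw)], nrow = components, ncol = nh)
    a <- matrix(p[nm + nw + seq_len(components * nh)],
                nrow = components, ncol = nh)
    list(mean = m, width = w, area = a)
  }
  predict_counts <- function(p) {
    u <- unpack(p)
    lapply(seq_len(nh), function(h) {
      y <- numeric(length(mids))
      for (k in seq_len(components))
        y <- y + u$area[k, h] * bw *
          .comp_density(mids, u$mean[k, h], u$width[k, h], model)
      y
    })
  }
  resid_fn <- function(p)
    unlist(predict_counts(p)) - unlist(counts)
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 400))
  if (fit$info %in% c(0, 5))
    stop("histogram fit did not converge; residual norm ",
         signif(sqrt(sum(fit$fvec^2)), 4))
  u <- unpack(fit$par)
  comp <- do.call(rbind, lapply(seq_len(nh), function(h)
    data.frame(histogram = h, component = seq_len(components),
               mean = u$mean[, h], width = u$width[, h],
               area = u$area[, h])))
  if (nh == 1) comp$histogram <- NULL
  structure(list(components = comp, breaks = breaks, mids = mids,
                 counts = counts, fitted = predict_counts(fit$par),
                 residual_norm = sqrt(sum(fit$fvec^2)), model = model),
            class = "histogram_fit")
}

#' @export
print.histogram_fit <- function(x, ...) {
  cat("Transfer-efficiency histogram fit (", x$model, ")\n", sep = "")
  print(x$components, digits = 4)
  invisible(x)
}
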