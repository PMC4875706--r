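#' Moving-average smoothed spike densities
#'
#' Moving average of each neuron's spike train, the preprocessing step before
#' extracting common-input components. The default window is centered at each
#' bin; `align = "trailing"` averages the `window` bins strictly before the
#' current one, which makes the smoothed signal usable as a causal GLM
#' regressor (the current and future spikes of a neuron never enter it).
#' Edges are truncated (the window shrinks near the boundaries), so interior
#' mass is preserved.
#'
#' @param sm a [spike_matrix()].
#' @param window window size in bins (`1 <= window <= T`).
#' @param align `"centered"` (default) or `"trailing"`.
#' @return object of class `smoothed_density`: `densities` (`C x T`),
#'   `window`, `align`.
#' @export
smooth_spikes <- function(sm, window, align = c("centered", "trailing")) {
  stopifnot(inherits(sm, "spike_matrix"))
  align <- match.arg(align)
  T <- ncol(sm$counts)
  if (!is.numeric(window) || window < 1L) stop("window must be a positive integer")
  if (window > T) stop("window cannot exceed the number of bins")
  window <- as.integer(window)
  if (align == "centered") {
    half_lo <- (window - 1L) %/% 2L
    half_hi <- window - 1L - half_lo
    lo <- pmax(seq_len(T) - half_lo, 1L)
    hi <- pmin(seq_len(T) + half_hi, T)
  } else {
    lo <- pmax(seq_len(T) - window, 1L)
    hi <- pmax(seq_len(T) - 1L, 1L)
  }
  dens <- t(apply(sm$counts, 1L, function(x) {
    cs <- cumsum(x)
    (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  }))
  if (align == "trailing") dens[, 1L] <- 0
  structure(list(densities = dens, window = window, align = align),
            class = "smoothed_density")
}

#' Estimate common external-input channels by PCA of smoothed activity
#'
#' Computes the leading principal components of the neurons' smoothed spike
#' densities (eigen-decomposition of the `C x C` covariance matrix over time)
#' and returns their time courses as candidate external-input channels,
#' ordered by decreasing eigenvalue. A strong shared slow drive shows up as a
#' dominant component; independent neurons yield no dominant component.
#' Channel signs are flipped so each correlates nonnegatively with the mean
#' population density, and the scores are z-scored so downstream GLM
#' coefficients share a common scale.
#'
#' The channels are built from trailing (causal) moving averages so that a
#' neuron's own current and future spikes never enter the regressors used to
#' predict it; a centered window would leak the response into the predictor
#' and grossly inflate the apparent explanatory power of every channel.
#'
#' @param sm a [spike_matrix()] (real neurons only are used).
#' @param window moving-average window in bins (default 20).
#' @param L_max number of channels to return (`<= C`).
#' @return an [external_inputs()] with up to `L_max` channels (fewer if the
#'   covariance is degenerate, with a warning) and eigenvalues attached.
#' @export
estimate_external_inputs <- function(sm, window = 20L, L_max = 1L) {
  C <- sm$n_real
  if (L_max > C) stop("L_max cannot exceed the number of real neurons")
  smd <- smooth_spikes(sm, window, align = "trailing")
  dens <- smd$densities[seq_len(C), , drop = FALSE]
  dc <- dens - rowMeans(dens)
  S <- tcrossprod(dc) / (ncol(dc) - 1L)
  eg <- eigen(S, symmetric = TRUE)
  keep <- which(eg$values > 1e-12 * max(eg$values, 0))
  if (length(keep) < L_max) {
    warning(sprintf("covariance is degenerate: returning %d of %d channels",
                    length(keep), L_max))
  }
  L <- min(L_max, length(keep))
  scores <- crossprod(dc, eg$vectors[, seq_len(L), drop = FALSE])  # T x L
  popmean <- colMeans(dens)
  for (l in seq_len(L)) {
    if (cor(scores[, l], popmean) < 0) scores[, l] <- -scores[, l]
    s <- sd(scores[, l])
    scores[, l] <- (scores[, l] - mean(scores[, l])) / if (s > 0) s else 1
  }
  external_inputs(t(scores), source = "estimated",
                  eigenvalues = eg$values[seq_len(L)])
}

#' Select the number of external-input channels by AIC
#'
#' Fits the population GLM with the leading `0, 1, ..., L_max` candidate
#' channels and computes `AIC(l) = sum_i loglik_i - #free parameters` (the
#' sign convention in which larger is better). Returns the argmax; the AIC
#' values, normalized so that the no-input model is zero, are attached as
#' attribute `"aic"`.
#'
#' @param sm a [spike_matrix()].
#' @param basis basis set for the fits.
#' @param candidates an [external_inputs()] holding at least `L_max` channels.
#' @param L_max largest number of channels to consider.
#' @param eta,link fit settings (a small `eta` keeps the unregularized fits
#'   numerically stable).
#' @return integer in `0..L_max`.
#' @export
select_num_inputs_by_aic <- function(sm, basis, candidates, L_max,
                                     eta = 0.001, link = "logistic") {
  if (nrow(candidates$signals) < L_max)
    stop("candidates hold fewer than L_max channels")
  aic <- rep(NA_real_, L_max + 1L)
  for (l in 0:L_max) {
    ext_l <- if (l == 0L) NULL else
      external_inputs(candidates$signals[seq_len(l), , drop = FALSE],
                      source = candidates$source)
    fits <- fit_population(sm, basis, ext_l, eta = eta, reg_kind = "L2",
                           link = link, control = list(hessian = FALSE))
    bad <- !vapply(fits, `[[`, TRUE, "converged")
    if (any(bad)) {
      warning(sprintf("%d fit(s) did not converge for l=%d; excluded", sum(bad), l))
      next
    }
    ll <- sum(vapply(fits, `[[`, 0, "loglik"))
    npar <- sm$n_real * (1L + l + nrow(sm$counts) * basis$K)
    aic[l + 1L] <- ll - npar
  }
  aic <- aic - aic[1L]
  best <- which.max(aic) - 1L
  structure(as.integer(best), aic = aic)
}
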