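#' Likelihood-ratio (Granger) statistic for one directed pair
#'
#' `LR = -2 (ln L0 - ln L)`, where `ln L` is the unpenalized log-likelihood of
#' the full (alternative) fit and `ln L0` that of the null refit in which the
#' source neuron's spike response is constrained to zero at every lag, both
#' evaluated at their respective (possibly penalized) optima. For nested
#' unregularized fits the statistic is nonnegative by construction; with
#' regularization, tiny negative values (optimizer tolerance) are floored at
#' zero.
#'
#' @param fit_alt full fit of the target neuron.
#' @param fit_null refit with the source's loadings row constrained to zero;
#'   must share target, data size, link, penalty and `eta` with `fit_alt`.
#' @return scalar `LR >= 0`.
#' @export
lr_statistic <- function(fit_alt, fit_null) {
  same <- fit_alt$target == fit_null$target &&
    fit_alt$eta == fit_null$eta && fit_alt$link == fit_null$link &&
    fit_alt$reg_kind == fit_null$reg_kind && fit_alt$n_bins == fit_null$n_bins
  if (!same) stop("fit_alt and fit_null must share target, data, link and eta")
  lr <- -2 * (fit_null$loglik - fit_alt$loglik)
  if (lr < 0) {
    if (lr < -1e-6)
      warning(sprintf("negative LR (%.3g) floored at 0 (regularized fits)", lr))
    lr <- 0
  }
  lr
}

#' Likelihood-ratio statistics of one target against many sources
#'
#' Refits the target's null model once per requested source (loadings row of
#' that source removed) and returns all LR statistics. Refits are warm-started
#' from the alternative optimum and solved by a fixed-metric Newton method
#' using the alternative fit's information matrix (the problem is convex, so
#' the optimum is the same; a full Newton fallback guards convergence).
#'
#' @param fit alternative fit (from [fit_glm()] with `reg_kind = "L2"`).
#' @param sm,basis,ext data used for `fit`.
#' @param sources integer vector of source rows (default: all rows except the
#'   target itself).
#' @param design optional precomputed [build_design()].
#' @return data.frame with columns `source`, `lr`, `loglik_null`.
#' @export
lr_statistics <- function(fit, sm, basis, ext = NULL, sources = NULL,
                          design = NULL) {
  if (fit$reg_kind != "L2")
    stop("likelihood-ratio refits are defined for the smooth (L2) objective")
  if (is.null(design)) design <- build_design(sm, basis, ext)
  if (is.null(sources)) sources <- setdiff(seq_len(design$C_total), fit$target)
  y <- response_vector(sm, design, fit$target)
  beta <- fit$beta
  lc <- link_code(fit$link)
  H <- cpp_info_matrix(design$X, y, beta, lc)
  pen_full <- penalty_mask(design)
  if (fit$eta > 0) diag(H) <- diag(H) + fit$eta * pen_full
  out <- data.frame(source = sources, lr = NA_real_, loglik_null = NA_real_)
  for (j in seq_along(sources)) {
    drop <- loading_cols(design, sources[j])
    keep <- setdiff(seq_len(ncol(design$X)), drop)
    Xs <- design$X[, keep, drop = FALSE]
    res <- cpp_refit_frozen(Xs, y, fit$eta, pen_full[keep], lc,
                            beta[keep], H[keep, keep, drop = FALSE],
                            1e-10, 100L)
    if (!isTRUE(res$converged)) {
      res <- cpp_newton_fit(Xs, y, fit$eta, pen_full[keep], lc,
                            as.numeric(res$beta), 1e-10, 200L, FALSE)
    }
    out$loglik_null[j] <- res$loglik
    out$lr[j] <- max(0, -2 * (res$loglik - fit$loglik))
  }
  out
}

#' Shape statistics of a spike response function
#'
#' `stat_surface` is the summed absolute response `sum_s |R(s)|`;
#' `stat_peak` the maximum absolute response `max_s |R(s)|`; `stat_delay`
#' the lag attaining the peak (smallest lag on ties -- used to describe a
#' detected connection rather than to test it). All are invariant to a sign
#' flip of the SRF and `peak <= surface` always.
#'
#' @param srf numeric SRF over lags `1..M` (see [reconstruct_srf()]).
#' @return scalar statistic (`stat_delay`: integer lag).
#' @export
stat_surface <- function(srf) sum(abs(srf))

#' @rdname stat_surface
#' @export
stat_peak <- function(srf) max(abs(srf))

#' @rdname stat_surface
#' @export
stat_delay <- function(srf) which.max(abs(srf))

#' Regularized inverse covariance metric of null loadings
#'
#' Estimates the covariance `S0` of loading vectors over known-null pairs
#' (count-normalized sum of outer products) and returns its ridge-regularized
#' inverse `Sigma = (S0 + ridge_frac * tr(S0)/K * I)^-1`, the metric used by
#' the Mahalanobis-type `MD` statistic. The null set used here is the
#' surrogate null-pair set, which is guaranteed null and avoids the
#' circularity of pruning real pairs by the test itself.
#'
#' @param null_loadings matrix with one null `K`-vector per row (or list of
#'   vectors).
#' @param ridge_frac ridge fraction (default 0.05).
#' @return `K x K` symmetric positive definite matrix.
#' @export
null_metric <- function(null_loadings, ridge_frac = 0.05) {
  A <- if (is.list(null_loadings)) do.call(rbind, null_loadings)
       else as.matrix(null_loadings)
  K <- ncol(A)
  if (nrow(A) < K)
    warning(sprintf("only %d null vectors for a %d-dim metric; estimate is weak",
                    nrow(A), K))
  S0 <- crossprod(A) / nrow(A)
  tr <- sum(diag(S0))
  if (tr <= 0) {
    warning("all-zero null loadings; falling back to identity metric")
    return(diag(K))
  }
  solve(S0 + diag(ridge_frac * tr / K, K))
}

#' Metric-weighted loading norm (MD statistic)
#'
#' `sqrt(a' Sigma a)` for a loadings row `a` and the [null_metric()]
#' `Sigma`; reduces to the Euclidean norm when `Sigma` is the identity.
#'
#' @param loadings_row numeric `K`-vector.
#' @param Sigma positive definite `K x K` metric.
#' @export
stat_md <- function(loadings_row, Sigma) {
  ok <- tryCatch({ chol(Sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("Sigma must be positive definite")
  sqrt(max(0, as.numeric(loadings_row %*% Sigma %*% loadings_row)))
}

#' MaxZ statistic and Wald confidence intervals of one source's loadings
#'
#' Per-loading Z-scores `Z_k = |w_k| / sigma_kk` (asymptotic sds from the
#' observed information) are combined into a lag profile
#' `Z(s) = sum_k Z_k B_k(s)`; `stat_maxz` is its maximum over lags. The
#' detection rule `MaxZ > z*` with `z* = qnorm(0.975) ~ 1.96` is equivalent to
#' declaring a connection when any pointwise 95% Wald CI `w_k +/- z* sigma_kk`
#' excludes zero, because the bases are nonnegative with positive maxima.
#'
#' @param fit a `neuron_glm` with curvature available.
#' @param basis basis set.
#' @param source source row index.
#' @param level CI coverage for [wald_ci()] (default 0.95).
#' @return `stat_maxz`: scalar. `wald_ci`: data.frame with `k`, `estimate`,
#'   `lower`, `upper`.
#' @export
stat_maxz <- function(fit, basis, source) {
  se <- fit$se_loadings[source, ]
  if (any(!is.finite(se)) || any(se <= 0))
    stop("asymptotic standard deviations unavailable for this fit")
  z <- abs(fit$loadings[source, ]) / se
  max(as.numeric(z %*% basis$values))
}

#' @rdname stat_maxz
#' @export
wald_ci <- function(fit, source, level = 0.95) {
  se <- fit$se_loadings[source, ]
  if (any(!is.finite(se)) || any(se <= 0))
    stop("asymptotic standard deviations unavailable for this fit")
  zq <- qnorm(1 - (1 - level) / 2)
  w <- fit$loadings[source, ]
  data.frame(k = seq_along(w), estimate = w,
             lower = w - zq * se, upper = w + zq * se)
}
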