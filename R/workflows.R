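#' AUC of a connection statistic across a regularization path
#'
#' Fits the population GLM at each hyperparameter value (warm-started along
#' the path from strong to weak regularization), scores every ordered real
#' pair with a shape statistic of its reconstructed spike response function,
#' and evaluates the AUC against the simulation's ground truth. This is the
#' sweep used to study how detection accuracy depends on the regularization
#' strength for non-sparse (L2) versus sparse (group lasso) estimation.
#'
#' @param sim a [simulate_network()] result.
#' @param basis basis set.
#' @param etas hyperparameter grid (sorted internally in decreasing order).
#' @param reg_kind `"L2"`, `"L1"` or `"group_lasso"`.
#' @param link fit link.
#' @param stat `"peak"` (default) or `"surface"`.
#' @return data.frame `eta`, `auc`, in the order of the supplied grid.
#' @export
sweep_eta_auc <- function(sim, basis, etas, reg_kind = "L2",
                          link = "logistic", stat = c("peak", "surface")) {
  stat <- match.arg(stat)
  sm <- sim$spikes
  design <- build_design(sm, basis)
  truth_df <- pair_truth(sim)
  ord <- order(etas, decreasing = TRUE)
  p <- ncol(design$X)
  warm <- replicate(sm$n_real, numeric(p), simplify = FALSE)
  auc <- numeric(length(etas))
  statfun <- if (stat == "peak") stat_peak else stat_surface
  for (j in ord) {
    scores <- numeric(nrow(truth_df))
    for (i in seq_len(sm$n_real)) {
      fit <- fit_glm(sm, i, basis, eta = etas[j], reg_kind = reg_kind,
                     link = link, design = design, init = warm[[i]],
                     control = list(hessian = FALSE))
      warm[[i]] <- fit$beta
      srfs <- srf_matrix(fit, basis)
      sel <- truth_df$dest == i
      scores[sel] <- apply(abs(srfs[truth_df$source[sel], , drop = FALSE]),
                           1L, max)
      if (stat == "surface")
        scores[sel] <- rowSums(abs(srfs[truth_df$source[sel], , drop = FALSE]))
    }
    auc[j] <- roc_auc(scores, truth_df$connected)$auc
  }
  data.frame(eta = etas, auc = auc)
}

#' Default hyperparameter grid for regularization sweeps
#'
#' Log-spaced grid spanning effectively unregularized to strongly
#' regularized fits.
#'
#' @param n grid size.
#' @export
default_eta_grid <- function(n = 7L) {
  exp(seq(log(0.01), log(30), length.out = n))
}
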