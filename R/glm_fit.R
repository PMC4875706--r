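#' Build the basis-convolved GLM design matrix
#'
#' Convolves every neuron's spike train with every basis filter and assembles
#' the regression design used by [fit_glm()]. Rows correspond to bins
#' `t = M+1, ..., T` (the likelihood is evaluated only where a full history
#' window exists); columns are the intercept, the external-input channels and
#' one block of `K` convolution features per candidate source neuron,
#' `X[t, (c,k)] = sum_s B_k(s) N_c(t - s)`.
#'
#' Building the design once and passing it to repeated fits of different
#' target neurons or hyperparameters avoids recomputing the convolutions.
#'
#' @param sm a [spike_matrix()].
#' @param basis a [make_gamma_basis()] / [make_identity_basis()] basis set.
#' @param ext optional [external_inputs()] (signals must span the same bins).
#' @return object of class `glm_design`.
#' @export
build_design <- function(sm, basis, ext = NULL) {
  stopifnot(inherits(sm, "spike_matrix"), inherits(basis, "basis_set"))
  T <- ncol(sm$counts)
  if (T <= basis$M) stop("T must exceed the basis lag window M")
  L <- 0L
  sig <- matrix(0, 0L, T)
  if (!is.null(ext) && nrow(ext$signals) > 0L) {
    if (ncol(ext$signals) != T)
      stop("external input length does not match the spike matrix")
    sig <- ext$signals
    L <- nrow(sig)
  }
  X <- cpp_design_matrix(sm$counts, basis$values, sig)
  structure(list(X = X, T = T, M = basis$M, K = basis$K, L = L,
                 C_total = nrow(sm$counts), n_real = sm$n_real,
                 neuron_ids = sm$neuron_ids),
            class = "glm_design")
}

loading_cols <- function(design, c) {
  1L + design$L + (c - 1L) * design$K + seq_len(design$K)
}

response_vector <- function(sm, design, target) {
  as.integer(sm$counts[target, (design$M + 1L):design$T])
}

penalty_mask <- function(design) {
  # baseline and external-input coefficients are never penalized
  c(rep(0, 1L + design$L), rep(1, design$C_total * design$K))
}

reg_value <- function(loadings, reg_kind) {
  switch(reg_kind,
         L2 = 0.5 * sum(loadings^2),
         L1 = sum(abs(loadings)),
         group_lasso = sum(sqrt(rowSums(loadings^2))))
}

#' Fit the regularized spike-response GLM for one target neuron
#'
#' Maximizes the regularized Bernoulli log-likelihood
#' `sum_t L_t - eta * Reg` over the baseline, external-input coefficients and
#' basis loadings of one postsynaptic (target) neuron, where `L_t` is the
#' per-bin log-likelihood under the chosen link and `Reg` is the L2
#' (`0.5 * sum A^2`), L1 (`sum |A|`) or group-lasso (sum over source neurons
#' of the Euclidean norm of their `K` loadings) penalty over loadings only.
#' The smooth L2 objective is maximized by a damped Newton method; the
#' nonsmooth penalties use FISTA (proximal gradient with momentum,
#' backtracking and adaptive restart). Both problems are convex, so the
#' optimum is unique and independent of initialization.
#'
#' Per-parameter asymptotic standard deviations are derived from the diagonal
#' of the inverse observed information of the smooth part of the objective at
#' the optimum (the Wald construction used for confidence intervals and the
#' MaxZ statistic).
#'
#' @param sm a [spike_matrix()]; surrogate rows, if present, enter as
#'   candidate sources exactly like real neurons.
#' @param target index of the target neuron (must be a real neuron).
#' @param basis basis set shared by all fits.
#' @param ext optional [external_inputs()].
#' @param eta regularization strength (`>= 0`).
#' @param reg_kind `"L2"`, `"L1"` or `"group_lasso"`.
#' @param link `"logistic"` (default) or `"cloglog"`.
#' @param design optionally, a precomputed [build_design()] result.
#' @param init optional warm-start coefficient vector (full length).
#' @param control list: `tol` (relative objective change, default `1e-8`),
#'   `maxit` (default 200 Newton / 5000 FISTA), `hessian` (compute curvature,
#'   default `TRUE`).
#' @return object of class `neuron_glm`: `baseline`, `ext_coef`, `loadings`
#'   (`C_total x K`, one row per candidate source including self-history and
#'   surrogates), `se_loadings` (asymptotic sds, same shape), `objective_value`
#'   (penalized), `loglik` (unpenalized, at the optimum), `converged`, plus
#'   bookkeeping fields.
#' @export
fit_glm <- function(sm, target, basis, ext = NULL, eta = 0,
                    reg_kind = c("L2", "L1", "group_lasso"),
                    link = c("logistic", "cloglog"),
                    design = NULL, init = NULL, control = list()) {
  reg_kind <- match.arg(reg_kind)
  link <- match.arg(link)
  if (is.null(design)) design <- build_design(sm, basis, ext)
  if (target < 1L || target > design$n_real)
    stop("target must be a real (non-surrogate) neuron")
  if (eta < 0) stop("eta must be non-negative")
  tol <- control$tol %||% 1e-8
  want_h <- control$hessian %||% TRUE
  y <- response_vector(sm, design, target)
  p <- ncol(design$X)
  beta0 <- if (is.null(init)) numeric(p) else init
  pen <- penalty_mask(design)
  if (reg_kind == "L2" || eta == 0) {
    maxit <- control$maxit %||% 200L
    res <- cpp_newton_fit(design$X, y, eta, pen, link_code(link), beta0,
                          tol, maxit, want_h)
    H <- if (want_h) res$hessian else NULL
  } else {
    maxit <- control$maxit %||% 5000L
    groups <- rep(-1L, p)
    idx <- which(pen == 1)
    groups[idx] <- if (reg_kind == "L1") seq_along(idx) - 1L
                   else rep(seq_len(design$C_total) - 1L, each = design$K)
    L0 <- 0.25 * max(colSums(design$X^2))
    res <- cpp_fista_fit(design$X, y, eta, groups, link_code(link), beta0,
                         tol, maxit, L0)
    H <- if (want_h) cpp_info_matrix(design$X, y, res$beta, link_code(link))
         else NULL
  }
  if (!isTRUE(res$converged))
    warning(sprintf("fit for target %d did not converge in %d iterations",
                    target, res$iterations))
  beta <- as.numeric(res$beta)
  se <- rep(NA_real_, p)
  if (!is.null(H)) {
    if (reg_kind == "L2") diag(H) <- diag(H) + 0  # eta already in Newton's H
    Hi <- tryCatch(chol2inv(chol(H)), error = function(e) {
      diag(H) <- diag(H) + 1e-8 * (sum(diag(H)) / p + 1)
      chol2inv(chol(H))
    })
    se <- sqrt(pmax(diag(Hi), 0))
  }
  lo_idx <- (1L + design$L + 1L):p
  loadings <- matrix(beta[lo_idx], design$C_total, design$K, byrow = TRUE)
  se_load <- matrix(se[lo_idx], design$C_total, design$K, byrow = TRUE)
  rownames(loadings) <- rownames(se_load) <- design$neuron_ids
  structure(list(
    baseline = beta[1L],
    ext_coef = if (design$L > 0L) beta[1L + seq_len(design$L)] else numeric(0),
    loadings = loadings,
    link = link, eta = eta, reg_kind = reg_kind,
    objective_value = res$objective, loglik = res$loglik,
    se_baseline = se[1L],
    se_ext = if (design$L > 0L) se[1L + seq_len(design$L)] else numeric(0),
    se_loadings = se_load,
    converged = isTRUE(res$converged), iterations = res$iterations,
    target = as.integer(target), target_id = design$neuron_ids[target],
    K = design$K, M = design$M, L = design$L,
    n_real = design$n_real, C_total = design$C_total,
    n_bins = length(y),
    beta = beta), class = "neuron_glm")
}

#' @export
print.neuron_glm <- function(x, ...) {
  cat(sprintf(
    "<neuron_glm> target '%s': %s link, %s penalty (eta=%g), K=%d, M=%d\n",
    x$target_id, x$link, x$reg_kind, x$eta, x$K, x$M))
  cat(sprintf("  objective %.4f, loglik %.4f, %s in %d iterations\n",
              x$objective_value, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Fit all real neurons of a population
#'
#' Convenience loop over targets sharing one design matrix.
#'
#' @inheritParams fit_glm
#' @return list of [fit_glm()] results, one per real neuron.
#' @export
fit_population <- function(sm, basis, ext = NULL, eta = 0,
                           reg_kind = "L2", link = "logistic",
                           design = NULL, control = list()) {
  if (is.null(design)) design <- build_design(sm, basis, ext)
  lapply(seq_len(sm$n_real), function(i)
    fit_glm(sm, i, basis, ext, eta, reg_kind, link,
            design = design, control = control))
}

#' Evaluate the regularized objective of a fitted (or hand-built) model
#'
#' Recomputes `sum_t L_t - eta * Reg` from the data; useful for checking fits
#' and for constructing likelihood ratios.
#'
#' @param fit a `neuron_glm`.
#' @param sm,basis,ext the data the fit was (or is to be) evaluated on.
#' @param design optional precomputed design.
#' @return list with `objective`, `loglik`, `penalty`.
#' @export
glm_objective <- function(fit, sm, basis, ext = NULL, design = NULL) {
  if (is.null(design)) design <- build_design(sm, basis, ext)
  y <- response_vector(sm, design, fit$target)
  beta <- c(fit$baseline, fit$ext_coef, as.numeric(t(fit$loadings)))
  ll <- cpp_loglik(design$X, y, beta, link_code(fit$link))
  pen <- reg_value(fit$loadings, fit$reg_kind)
  list(objective = ll - fit$eta * pen, loglik = ll, penalty = pen)
}

#' Total spike response of a target neuron at given bins
#'
#' Evaluates `lambda_i(t) = R_i0 + sum_l R^E_il E_l(t) +
#' sum_c sum_k sum_s A_ick B_k(s) N_c(t - s)` for 1-based bins
#' `t in (M, T]` (a full history window is required).
#'
#' @param fit a `neuron_glm`.
#' @param sm,basis,ext data.
#' @param t integer vector of bins, each `> M`.
#' @return numeric vector of total responses (linear predictor scale).
#' @export
total_response <- function(fit, sm, basis, ext = NULL, t) {
  design <- build_design(sm, basis, ext)
  if (any(t <= design$M) || any(t > design$T))
    stop("bins t must satisfy M < t <= T")
  beta <- c(fit$baseline, fit$ext_coef, as.numeric(t(fit$loadings)))
  lam <- as.numeric(design$X %*% beta)
  lam[t - design$M]
}

#' Reconstruct a spike response function from basis loadings
#'
#' `R_ic(s) = sum_k A_ick B_k(s)`, the lag profile of the increment that a
#' spike of the source neuron adds to the target's total response.
#'
#' @param fit a `neuron_glm`.
#' @param basis the basis set used for the fit.
#' @param source source-neuron row index.
#' @return numeric vector over lags `1..M`.
#' @export
reconstruct_srf <- function(fit, basis, source) {
  if (source < 1L || source > nrow(fit$loadings))
    stop("source is not a valid loadings row")
  as.numeric(fit$loadings[source, ] %*% basis$values)
}

#' Spike response functions of all candidate sources
#'
#' @param fit a `neuron_glm`.
#' @param basis basis set.
#' @return `C_total x M` matrix, one SRF per row.
#' @export
srf_matrix <- function(fit, basis) {
  out <- fit$loadings %*% basis$values
  rownames(out) <- rownames(fit$loadings)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fitted spike-response model to JSON
#'
#' Writes the baseline, external-input coefficients, loadings, penalty
#' settings and fit diagnostics as a structured JSON document; the inverse
#' reconstructs a `neuron_glm` usable by [reconstruct_srf()] and the
#' statistic functions.
#'
#' @param fit a `neuron_glm`.
#' @param path file path.
#' @export
write_neuron_glm <- function(fit, path) {
  stopifnot(inherits(fit, "neuron_glm"))
  doc <- fit[c("baseline", "ext_coef", "link", "eta", "reg_kind",
               "objective_value", "loglik", "converged", "iterations",
               "target", "target_id", "K", "M", "L", "n_real", "C_total",
               "n_bins")]
  doc$loadings <- unname(as.matrix(fit$loadings))
  doc$se_loadings <- unname(as.matrix(fit$se_loadings))
  doc$neuron_ids <- rownames(fit$loadings)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_neuron_glm
#' @export
read_neuron_glm <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$loadings <- matrix(doc$loadings, ncol = doc$K)
  doc$se_loadings <- matrix(doc$se_loadings, ncol = doc$K)
  rownames(doc$loadings) <- rownames(doc$se_loadings) <- doc$neuron_ids
  doc$ext_coef <- as.numeric(doc$ext_coef %||% numeric(0))
  doc$beta <- c(doc$baseline, doc$ext_coef, as.numeric(t(doc$loadings)))
  structure(doc, class = "neuron_glm")
}
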