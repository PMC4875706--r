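#' Chi-square p-values for likelihood-ratio statistics
#'
#' Upper-tail probabilities of the chi-square distribution. For the raw-lag
#' (identity basis) model the likelihood ratio for one directed pair
#' constrains `M` parameters, so its large-sample null distribution is
#' chi-square with `M` degrees of freedom; with `K` smooth bases the
#' constraint count, hence the dof, is `K`.
#'
#' @param lr nonnegative statistic(s).
#' @param dof degrees of freedom (`> 0`; need not be integer, see
#'   [fit_null_dof()]).
#' @return p-values, same shape as `lr`.
#' @export
chi2_pvalues <- function(lr, dof) {
  if (!is.numeric(dof) || dof <= 0) stop("dof must be positive")
  if (any(lr < 0)) stop("LR statistics must be nonnegative")
  p <- pchisq(lr, df = dof, lower.tail = FALSE)
  attributes(p) <- attributes(lr)
  p
}

#' Fit effective degrees of freedom to an empirical null
#'
#' Calibrates the chi-square reference distribution against likelihood-ratio
#' statistics observed on known-null (surrogate) pairs. Method of moments
#' (default) uses the chi-square mean identity `E[LR] = dof`; `"mle"`
#' maximizes the chi-square likelihood numerically.
#'
#' @param null_lr numeric vector of null LR statistics (warns below 20).
#' @param method `"moments"` or `"mle"`.
#' @return scalar dof estimate.
#' @export
fit_null_dof <- function(null_lr, method = c("moments", "mle")) {
  method <- match.arg(method)
  if (length(null_lr) == 0L) stop("no null samples")
  if (length(null_lr) < 20L)
    warning("fewer than 20 null samples; dof estimate will be noisy")
  if (method == "moments") return(mean(null_lr))
  opt <- optimize(function(v) sum(dchisq(pmax(null_lr, 1e-12), df = v, log = TRUE)),
                  interval = c(1e-3, max(mean(null_lr) * 10, 1)), maximum = TRUE)
  opt$maximum
}

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values `q(i) = min_{j >= i} p(j) * m / j` (sorted), capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @export
bh_qvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

eb_pi0 <- function(real_stats, null_stats) {
  # observed-to-null mass ratio in the null-dominated left part of the
  # distribution, capped at 1. The ratio is evaluated on a grid of lower
  # null quantiles and summarized by its median, which is much less noisy
  # than a single cutoff at the null median.
  qs <- quantile(null_stats, seq(0.2, 0.7, by = 0.05), names = FALSE,
                 type = 8)
  ratios <- vapply(qs, function(s0) {
    f0 <- mean(null_stats <= s0)
    if (f0 <= 0) return(NA_real_)
    mean(real_stats <= s0) / f0
  }, 0)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L) return(1)
  min(1, median(ratios))
}

#' Empirical Bayesian q-values and local false discovery rates
#'
#' Direct q-value estimation from empirical null samples (no p-values): for
#' each observed statistic `s` (larger = more significant), the null tail is
#' estimated with an add-one correction
#' `F0(s) = (1 + #\{null >= s\}) / (n_null + 1)` and the observed tail as
#' `F(s) = #\{real >= s\} / n_real`; then
#' `q(s) = min(1, pi0 * F0(s) / F(s))`, made monotone nonincreasing in the
#' statistic by a running minimum from the largest statistic downward. The
#' null proportion `pi0` defaults to the observed-to-null mass ratio below
#' the null median, capped at 1. Local false discovery rates
#' `min(1, pi0 * f0(s) / f(s))` use Gaussian kernel density estimates with a
#' shared Silverman bandwidth.
#'
#' Because the construction uses only tail counts, the q-values are invariant
#' to strictly monotone transforms of the statistic.
#'
#' @param real_stats statistics of the hypotheses under test.
#' @param null_stats statistics of known-null (surrogate) pairs.
#' @param pi0 optional fixed null proportion in `[0, 1]`; default: estimated.
#' @return object of class `eb_significance`: data.frame `table` with
#'   `stat`, `q`, `local_fdr` (row order matching `real_stats`), plus `pi0`
#'   and `n_null`.
#' @export
eb_qvalues <- function(real_stats, null_stats, pi0 = NULL) {
  n_null <- length(null_stats)
  if (n_null == 0L) stop("empirical Bayesian testing requires null samples")
  n_real <- length(real_stats)
  if (is.null(pi0)) pi0 <- eb_pi0(real_stats, null_stats)
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]")
  ord <- order(real_stats, decreasing = TRUE)
  s_sorted <- real_stats[ord]
  # tail counts; ties share the count of the whole tied block
  F0 <- (1 + vapply(s_sorted, function(s) sum(null_stats >= s), 0)) / (n_null + 1)
  Fr <- vapply(s_sorted, function(s) sum(real_stats >= s), 0) / n_real
  q_raw <- pmin(1, pi0 * F0 / Fr)
  # a hypothesis is rejected at every threshold at or below its own statistic,
  # so its q is the minimum tail ratio over those weaker thresholds
  q_sorted <- rev(cummin(rev(q_raw)))
  q <- numeric(n_real)
  q[ord] <- q_sorted
  # local fdr via kernel densities on a shared bandwidth
  bw <- stats::bw.nrd0(c(real_stats, null_stats))
  if (!is.finite(bw) || bw <= 0) bw <- 1e-6
  rng <- range(c(real_stats, null_stats))
  d0 <- density(null_stats, bw = bw, from = rng[1] - 3 * bw,
                to = rng[2] + 3 * bw, n = 512)
  d1 <- density(real_stats, bw = bw, from = rng[1] - 3 * bw,
                to = rng[2] + 3 * bw, n = 512)
  f0 <- approx(d0$x, d0$y, xout = real_stats, rule = 2)$y
  f1 <- approx(d1$x, d1$y, xout = real_stats, rule = 2)$y
  local_fdr <- pmin(1, pi0 * f0 / pmax(f1, 1e-300))
  structure(list(table = data.frame(stat = real_stats, q = q,
                                    local_fdr = local_fdr),
                 pi0 = pi0, n_null = n_null),
            class = "eb_significance")
}

#' @export
print.eb_significance <- function(x, ...) {
  cat(sprintf("<eb_significance> %d hypotheses, %d null samples, pi0 = %.3f\n",
              nrow(x$table), x$n_null, x$pi0))
  cat(sprintf("  discoveries at q<0.05: %d, q<0.2: %d\n",
              sum(x$table$q < 0.05), sum(x$table$q < 0.2)))
  invisible(x)
}

#' Configuration for a full connectivity analysis
#'
#' @param procedure one of `"CHI2"`, `"DOF"`, `"EB-LR"`,
#'   `"EB-regularized-LR"`, `"EB-peak"`, `"EB-surface"`, `"EB-md"`,
#'   `"EB-maxz"`. The two chi-square procedures use the raw-lag (identity)
#'   basis convention and a near-zero `eta`; the EB procedures estimate the
#'   null from surrogate pairs.
#' @param eta regularization strength; default 0.001 for CHI2/DOF/EB-LR and
#'   3.0 for the regularized EB procedures.
#' @param link,reg_kind fit settings.
#' @param null_target approximate number of surrogate null pairs.
#' @param q_threshold reporting threshold (stored with results).
#' @param ridge_frac ridge fraction of the MD metric.
#' @param seed RNG seed for surrogate construction.
#' @param estimate_inputs if `TRUE`, estimate external inputs by
#'   [estimate_external_inputs()] + [select_num_inputs_by_aic()] first.
#' @param window,L_max external-input estimation settings.
#' @export
fc_config <- function(procedure = "EB-regularized-LR", eta = NULL,
                      link = "logistic", reg_kind = "L2",
                      null_target = 300L, q_threshold = 0.2,
                      ridge_frac = 0.05, seed = 1L,
                      estimate_inputs = FALSE, window = 20L, L_max = 3L) {
  procedures <- c("CHI2", "DOF", "EB-LR", "EB-regularized-LR",
                  "EB-peak", "EB-surface", "EB-md", "EB-maxz")
  procedure <- match.arg(procedure, procedures)
  if (is.null(eta))
    eta <- if (procedure %in% c("CHI2", "DOF", "EB-LR")) 0.001 else 3.0
  list(procedure = procedure, eta = eta, link = link, reg_kind = reg_kind,
       null_target = as.integer(null_target), q_threshold = q_threshold,
       ridge_frac = ridge_frac, seed = as.integer(seed),
       estimate_inputs = isTRUE(estimate_inputs),
       window = as.integer(window), L_max = as.integer(L_max))
}

stat_for_pairs <- function(stat_name, fits, sm, basis, ext, design, pairs,
                           Sigma = NULL) {
  vapply(seq_len(nrow(pairs)), function(r) {
    fit <- fits[[pairs$dest[r]]]
    src <- pairs$source[r]
    switch(stat_name,
           peak = stat_peak(reconstruct_srf(fit, basis, src)),
           surface = stat_surface(reconstruct_srf(fit, basis, src)),
           md = stat_md(fit$loadings[src, ], Sigma),
           maxz = stat_maxz(fit, basis, src))
  }, 0)
}

#' Run a full functional-connectivity test suite
#'
#' Orchestrates one complete analysis: optional external-input estimation,
#' surrogate construction (for the empirical procedures), per-neuron GLM
#' fits, per-pair statistics, and the selected significance procedure.
#'
#' * `CHI2`: likelihood-ratio statistics referred to the chi-square with dof
#'   equal to the constraint count `K` (equals `M` for the identity basis);
#'   BH q-values.
#' * `DOF`: as CHI2, but the dof is refitted to surrogate-null LR statistics.
#' * `EB-LR` / `EB-regularized-LR`: empirical Bayesian q-values of the LR
#'   statistic with small (`0.001`) / larger (`3.0`) L2 regularization.
#' * `EB-peak`, `EB-surface`, `EB-md`, `EB-maxz`: empirical Bayesian q-values
#'   of the corresponding shape statistic (no null refits needed).
#'
#' @param sm a [spike_matrix()] of real neurons (surrogates are added here
#'   when the procedure needs them).
#' @param ext optional [external_inputs()]; ignored when
#'   `config$estimate_inputs` is set.
#' @param basis basis set for the fits.
#' @param config a [fc_config()] list.
#' @return object of class `connection_table`: data.frame with one row per
#'   ordered real pair (`dest`, `source`, labels, `stat_name`, `stat_value`,
#'   `lr`, `peak`, `surface`, `delay`, `md`, `maxz`, `p`, `q`, `local_fdr`),
#'   with attributes `procedure`, `eta`, `pi0`, `dof`, `null_stats`, `config`.
#' @export
run_test_suite <- function(sm, ext = NULL, basis, config = fc_config()) {
  stopifnot(inherits(sm, "spike_matrix"))
  if (sm$n_surrogate > 0L) stop("pass a spike matrix without surrogate rows")
  proc <- config$procedure
  needs_sur <- proc != "CHI2"
  needs_lr <- proc %in% c("CHI2", "DOF", "EB-LR", "EB-regularized-LR")
  if (config$estimate_inputs) {
    cand <- estimate_external_inputs(sm, config$window, config$L_max)
    lsel <- select_num_inputs_by_aic(sm, basis, cand, nrow(cand$signals),
                                     eta = min(config$eta, 0.001),
                                     link = config$link)
    ext <- if (lsel > 0L)
      external_inputs(cand$signals[seq_len(lsel), , drop = FALSE], "estimated")
    else NULL
  }
  sm_fit <- sm
  if (needs_sur) {
    plan <- plan_surrogates(sm$n_real, basis$M, ncol(sm$counts),
                            config$null_target, seed = config$seed)
    sm_fit <- make_surrogates(sm, plan)
  }
  design <- build_design(sm_fit, basis, ext)
  fits <- fit_population(sm_fit, basis, ext, eta = config$eta,
                         reg_kind = config$reg_kind, link = config$link,
                         design = design)
  C <- sm$n_real
  pairs <- expand.grid(source = seq_len(C), dest = seq_len(C))[, 2:1]
  pairs <- pairs[pairs$dest != pairs$source, ]
  rownames(pairs) <- NULL
  nullp <- if (needs_sur) null_pair_index(sm_fit) else
    data.frame(dest = integer(0), source = integer(0))

  # shape statistics for every real pair (always reported)
  tab <- data.frame(dest = pairs$dest, source = pairs$source,
                    dest_id = sm$neuron_ids[pairs$dest],
                    source_id = sm$neuron_ids[pairs$source])
  tab$peak <- stat_for_pairs("peak", fits, sm_fit, basis, ext, design, pairs)
  tab$surface <- stat_for_pairs("surface", fits, sm_fit, basis, ext, design, pairs)
  tab$delay <- vapply(seq_len(nrow(pairs)), function(r)
    stat_delay(reconstruct_srf(fits[[pairs$dest[r]]], basis, pairs$source[r])), 0L)
  Sigma <- NULL
  if (needs_sur) {
    null_load <- do.call(rbind, lapply(seq_len(nrow(nullp)), function(r)
      fits[[nullp$dest[r]]]$loadings[nullp$source[r], ]))
    Sigma <- null_metric(null_load, config$ridge_frac)
    tab$md <- stat_for_pairs("md", fits, sm_fit, basis, ext, design, pairs,
                             Sigma = Sigma)
  } else tab$md <- NA_real_
  have_se <- all(vapply(fits, function(f)
    all(is.finite(f$se_loadings)) && all(f$se_loadings > 0), TRUE))
  tab$maxz <- if (have_se)
    stat_for_pairs("maxz", fits, sm_fit, basis, ext, design, pairs)
  else NA_real_

  lr_real <- rep(NA_real_, nrow(pairs))
  lr_null <- NULL
  if (needs_lr) {
    for (i in seq_len(C)) {
      want <- c(pairs$source[pairs$dest == i],
                if (needs_sur) nullp$source[nullp$dest == i])
      lrs <- lr_statistics(fits[[i]], sm_fit, basis, ext,
                           sources = want, design = design)
      sel <- pairs$dest == i
      lr_real[sel] <- lrs$lr[match(pairs$source[sel], lrs$source)]
      if (needs_sur) {
        seln <- nullp$dest == i
        lr_null <- c(lr_null, lrs$lr[match(nullp$source[seln], lrs$source)])
      }
    }
  }
  tab$lr <- lr_real

  stat_name <- switch(proc,
                      "CHI2" = , "DOF" = , "EB-LR" = ,
                      "EB-regularized-LR" = "lr",
                      "EB-peak" = "peak", "EB-surface" = "surface",
                      "EB-md" = "md", "EB-maxz" = "maxz")
  tab$stat_name <- stat_name
  tab$stat_value <- tab[[stat_name]]
  pi0 <- NA_real_; dof <- NA_real_; null_stats <- NULL
  if (proc == "CHI2") {
    dof <- basis$K
    tab$p <- chi2_pvalues(tab$lr, dof)
    tab$q <- bh_qvalues(tab$p)
    tab$local_fdr <- NA_real_
  } else if (proc == "DOF") {
    null_stats <- lr_null
    dof <- fit_null_dof(lr_null)
    tab$p <- chi2_pvalues(tab$lr, dof)
    tab$q <- bh_qvalues(tab$p)
    tab$local_fdr <- NA_real_
  } else {
    null_stats <- if (stat_name == "lr") lr_null else
      stat_for_pairs(stat_name, fits, sm_fit, basis, ext, design, nullp,
                     Sigma = Sigma)
    eb <- eb_qvalues(tab$stat_value, null_stats)
    tab$p <- NA_real_
    tab$q <- eb$table$q
    tab$local_fdr <- eb$table$local_fdr
    pi0 <- eb$pi0
  }
  structure(tab, class = c("connection_table", "data.frame"),
            procedure = proc, eta = config$eta, pi0 = pi0, dof = dof,
            K = basis$K, M = basis$M, seed = config$seed,
            null_stats = null_stats, config = config)
}

#' Write / read a connection table as annotated TSV
#'
#' Header comments record the procedure, hyperparameters and the estimated
#' null proportion so a saved table is self-describing and downstream
#' evaluation (e.g. [fdp_curve()]) is reproducible bit-wise.
#'
#' @param tab a `connection_table`.
#' @param path file path.
#' @export
write_connection_table <- function(tab, path) {
  stopifnot(inherits(tab, "connection_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# procedure=%s eta=%g K=%d M=%d pi0=%s dof=%s seed=%d",
                     attr(tab, "procedure"), attr(tab, "eta"),
                     attr(tab, "K"), attr(tab, "M"),
                     format(attr(tab, "pi0"), digits = 17),
                     format(attr(tab, "dof"), digits = 17),
                     attr(tab, "seed")), con)
  df <- as.data.frame(tab)
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], format, digits = 17)
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(do.call(paste, c(df, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_connection_table
#' @export
read_connection_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[[1L]]
  df <- utils::read.delim(text = lines[-1L], check.names = FALSE)
  getv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    v <- sub(paste0(key, "="), "", m)
    if (identical(v, "NA")) NA else v
  }
  structure(df, class = c("connection_table", "data.frame"),
            procedure = getv("procedure"), eta = as.numeric(getv("eta")),
            K = as.integer(getv("K")), M = as.integer(getv("M")),
            pi0 = as.numeric(getv("pi0")), dof = as.numeric(getv("dof")),
            seed = as.integer(getv("seed")))
}

#' @export
print.connection_table <- function(x, ...) {
  cat(sprintf("<connection_table> %s: %d directed pairs (eta=%g, K=%d, M=%d)\n",
              attr(x, "procedure"), nrow(x), attr(x, "eta"),
              attr(x, "K"), attr(x, "M")))
  if (is.finite(attr(x, "pi0") %||% NA))
    cat(sprintf("  estimated null proportion pi0 = %.3f\n", attr(x, "pi0")))
  cat(sprintf("  discoveries at q<0.2: %d of %d\n", sum(x$q < 0.2), nrow(x)))
  invisible(x)
}
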