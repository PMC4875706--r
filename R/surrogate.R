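#' Plan time-shifted surrogate neurons
#'
#' Surrogate neurons are circularly time-shifted copies of real spike trains.
#' Shifted by more than the lag window `M`, a surrogate is independent of
#' every real neuron at the lags the model can see, so statistics of
#' (real destination, surrogate source) pairs furnish empirical null samples.
#' The number of surrogates is chosen so that the number of null pairs is
#' about `null_target` (around 300 is typically sufficient); sources are
#' assigned round-robin over the real neurons and shifts are drawn uniformly
#' from `[2M, T - 2M]`, keeping them well clear of the window at both ends of
#' the recording.
#'
#' @param C number of real neurons.
#' @param M lag window in bins.
#' @param T number of bins (must exceed `4 * M`).
#' @param null_target desired number of null pairs (default 300).
#' @param seed optional RNG seed for the shifts.
#' @return object of class `surrogate_plan`: `n_surrogate`, `source_map`,
#'   `shifts`.
#' @export
plan_surrogates <- function(C, M, T, null_target = 300L, seed = NULL) {
  if (T <= 4L * M) stop("T must exceed 4*M to leave room for admissible shifts")
  if (!is.null(seed)) set.seed(seed)
  C_S <- as.integer(ceiling(null_target / C))
  source_map <- rep_len(seq_len(C), C_S)
  lo <- 2L * M
  hi <- T - 2L * M
  if (hi < lo) stop("T too short for any admissible shift")
  shifts <- as.integer(floor(runif(C_S, lo, hi + 1)))
  shifts <- pmin(shifts, hi)
  structure(list(n_surrogate = C_S, source_map = source_map, shifts = shifts,
                 M = as.integer(M), null_target = as.integer(null_target)),
            class = "surrogate_plan")
}

#' Append surrogate neurons to a spike matrix
#'
#' Row `j` of the appended block is the circular shift of its source row by
#' `shifts[j]` bins: surrogate spike train `N*(t) = N(source, t + shift)`
#' (wrapping around the end of the recording, which preserves length and
#' spike count). Real rows are untouched. The plan is stored on the result so
#' [null_pair_index()] can exclude shifted copies of a pair's own destination.
#'
#' @param sm a [spike_matrix()] without surrogates.
#' @param plan a [plan_surrogates()] result.
#' @return a [spike_matrix()] with `plan$n_surrogate` appended rows.
#' @export
make_surrogates <- function(sm, plan) {
  stopifnot(inherits(sm, "spike_matrix"), inherits(plan, "surrogate_plan"))
  if (sm$n_surrogate > 0L) stop("spike matrix already has surrogate rows")
  if (any(plan$shifts <= plan$M))
    stop("all surrogate shifts must exceed the lag window M")
  T <- ncol(sm$counts)
  rows <- matrix(0L, plan$n_surrogate, T)
  ids <- character(plan$n_surrogate)
  for (j in seq_len(plan$n_surrogate)) {
    src <- plan$source_map[j]
    sh <- plan$shifts[j] %% T
    x <- sm$counts[src, ]
    rows[j, ] <- c(x[(sh + 1L):T], if (sh > 0L) x[1L:sh] else integer(0))
    ids[j] <- sprintf("%s*s%d", sm$neuron_ids[src], j)
  }
  out <- spike_matrix(rbind(sm$counts, rows), bin_width = sm$bin_width,
                      neuron_ids = c(sm$neuron_ids, ids),
                      n_surrogate = plan$n_surrogate)
  out$surrogate_plan <- plan
  out
}

#' Null directed pairs furnished by the surrogates
#'
#' All (real destination, surrogate source) pairs, except those where the
#' surrogate is a shifted copy of the destination itself (slow
#' autocorrelation could otherwise contaminate the null).
#'
#' @param sm a spike matrix produced by [make_surrogates()].
#' @return data.frame with columns `dest` (real neuron index) and `source`
#'   (surrogate row index, `> n_real`).
#' @export
null_pair_index <- function(sm) {
  stopifnot(inherits(sm, "spike_matrix"))
  if (sm$n_surrogate == 0L)
    return(data.frame(dest = integer(0), source = integer(0)))
  plan <- sm$surrogate_plan
  dest <- rep(seq_len(sm$n_real), each = sm$n_surrogate)
  sur <- rep(seq_len(sm$n_surrogate), times = sm$n_real)
  keep <- if (!is.null(plan)) plan$source_map[sur] != dest else TRUE
  data.frame(dest = dest[keep], source = (sm$n_real + sur)[keep])
}
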