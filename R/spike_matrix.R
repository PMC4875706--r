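#' Binned spike trains for a population of neurons
#'
#' A `spike_matrix` holds binned binary spike trains: one row per neuron
#' (real neurons first, then any appended surrogate neurons), one column per
#' time bin. The bin width is assumed short enough that at most one spike
#' falls in a bin, so entries are 0/1.
#'
#' In memory, neurons and bins are indexed 1-based as usual in R; the on-disk
#' event-list format uses 0-based, half-open bin indices `[0, T)`.
#'
#' @param counts integer matrix `[C_total x T]`, entries 0/1 (or counts if
#'   `clip = TRUE`).
#' @param bin_width bin width in seconds (`> 0`).
#' @param neuron_ids character labels, one per row. Default `"0", "1", ...`.
#' @param n_surrogate number of trailing rows that are surrogate neurons.
#' @param clip if `TRUE`, counts greater than 1 (e.g. un-split bursts) are
#'   clipped to 1 with a warning; if `FALSE` they are an error.
#' @return an object of class `spike_matrix` with fields `counts`,
#'   `bin_width`, `neuron_ids`, `n_real`, `n_surrogate`.
#' @export
spike_matrix <- function(counts, bin_width = 0.005, neuron_ids = NULL,
                         n_surrogate = 0L, clip = FALSE) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  C_total <- nrow(counts)
  T <- ncol(counts)
  if (T < 1L) stop("spike matrix must have at least one time bin")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a positive scalar (seconds)")
  if (any(is.na(counts)) || any(counts < 0L))
    stop("spike counts must be non-negative integers")
  if (any(counts > 1L)) {
    if (clip) {
      nclip <- sum(counts > 1L)
      warning(sprintf("%d bins held more than one spike; clipped to 1", nclip))
      counts[counts > 1L] <- 1L
    } else {
      stop("spike counts greater than 1 found; use clip = TRUE to treat them as single spikes")
    }
  }
  n_surrogate <- as.integer(n_surrogate)
  if (n_surrogate < 0L || n_surrogate > C_total)
    stop("n_surrogate must be between 0 and the number of rows")
  if (is.null(neuron_ids)) neuron_ids <- as.character(seq_len(C_total) - 1L)
  if (length(neuron_ids) != C_total) stop("neuron_ids length must match rows")
  if (anyDuplicated(neuron_ids)) stop("neuron_ids must be unique")
  structure(
    list(counts = counts, bin_width = bin_width,
         neuron_ids = as.character(neuron_ids),
         n_real = C_total - n_surrogate, n_surrogate = n_surrogate),
    class = "spike_matrix")
}

#' @export
print.spike_matrix <- function(x, ...) {
  cat(sprintf(
    "<spike_matrix> %d neurons (%d real + %d surrogate) x %d bins, bin width %g s\n",
    nrow(x$counts), x$n_real, x$n_surrogate, ncol(x$counts), x$bin_width))
  cat(sprintf("  total spikes: %d (mean rate %.3g spikes/s)\n",
              sum(x$counts),
              mean(rowSums(x$counts)) / (ncol(x$counts) * x$bin_width)))
  invisible(x)
}

#' @export
dim.spike_matrix <- function(x) dim(x$counts)

parse_header <- function(line, path) {
  if (!startsWith(line, "#"))
    stop(sprintf("%s: first line must be a '#C=... T=... bin_width=... n_surrogate=...' header", path))
  get <- function(key, conv) {
    m <- regmatches(line, regexpr(paste0(key, "=[^ \t]+"), line))
    if (length(m) == 0L) stop(sprintf("%s: header is missing '%s='", path, key))
    conv(sub(paste0(key, "="), "", m))
  }
  list(C = get("C", as.integer), T = get("T", as.integer),
       bin_width = get("bin_width", as.numeric),
       n_surrogate = get("n_surrogate", as.integer))
}

#' Read binned spike trains from disk
#'
#' Two plain-text formats are supported. `event_list` (canonical; sparse) has
#' a header line `#C=<int> T=<int> bin_width=<float> n_surrogate=<int>`, an
#' optional `#ids=<tab-separated labels>` line, and one
#' `<neuron_label>\t<bin_index>` line per spike with 0-based bin indices in
#' `[0, T)`. `dense` is a `C x T` tab-separated integer matrix preceded by the
#' same header comments.
#'
#' @param path file path.
#' @param format `"event_list"` or `"dense"`.
#' @param clip passed to [spike_matrix()]: clip duplicate events to one spike.
#' @return a [spike_matrix()].
#' @export
read_spikes <- function(path, format = c("event_list", "dense"), clip = TRUE) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (length(lines) == 0L) stop(sprintf("%s: empty file", path))
  hd <- parse_header(lines[[1L]], path)
  body_start <- 2L
  ids <- as.character(seq_len(hd$C) - 1L)
  if (length(lines) >= 2L && startsWith(lines[[2L]], "#ids=")) {
    ids <- strsplit(sub("^#ids=", "", lines[[2L]]), "\t", fixed = TRUE)[[1L]]
    if (length(ids) != hd$C)
      stop(sprintf("%s: #ids line has %d labels, header says C=%d",
                   path, length(ids), hd$C))
    body_start <- 3L
  }
  counts <- matrix(0L, hd$C, hd$T)
  if (format == "event_list") {
    body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1L)]
    body <- body[nzchar(body)]
    for (j in seq_along(body)) {
      parts <- strsplit(body[[j]], "\t", fixed = TRUE)[[1L]]
      lineno <- body_start - 1L + j
      if (length(parts) != 2L)
        stop(sprintf("%s:%d: expected '<label>\\t<bin>', got '%s'",
                     path, lineno, body[[j]]))
      row <- match(parts[[1L]], ids)
      if (is.na(row))
        stop(sprintf("%s:%d: unknown neuron label '%s'", path, lineno, parts[[1L]]))
      bin <- suppressWarnings(as.integer(parts[[2L]]))
      if (is.na(bin))
        stop(sprintf("%s:%d: malformed bin index '%s'", path, lineno, parts[[2L]]))
      if (bin < 0L || bin >= hd$T)
        stop(sprintf("%s:%d: bin index %d outside [0, %d)", path, lineno, bin, hd$T))
      counts[row, bin + 1L] <- counts[row, bin + 1L] + 1L
    }
  } else {
    body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1L)]
    body <- body[nzchar(body) & !startsWith(body, "#")]
    if (length(body) != hd$C)
      stop(sprintf("%s: dense body has %d rows, header says C=%d",
                   path, length(body), hd$C))
    for (r in seq_len(hd$C)) {
      vals <- suppressWarnings(as.integer(strsplit(body[[r]], "\t", fixed = TRUE)[[1L]]))
      if (length(vals) != hd$T || any(is.na(vals)))
        stop(sprintf("%s: malformed dense row %d", path, r))
      counts[r, ] <- vals
    }
  }
  spike_matrix(counts, bin_width = hd$bin_width, neuron_ids = ids,
               n_surrogate = hd$n_surrogate, clip = clip)
}

#' Write binned spike trains to disk
#'
#' Inverse of [read_spikes()]: `read_spikes(write_spikes(sm, f))` reproduces
#' `sm` exactly, including surrogate metadata.
#'
#' @param sm a [spike_matrix()].
#' @param path output file path.
#' @param format `"event_list"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(sm, path, format = c("event_list", "dense")) {
  format <- match.arg(format)
  stopifnot(inherits(sm, "spike_matrix"))
  C <- nrow(sm$counts); T <- ncol(sm$counts)
  header <- sprintf("#C=%d T=%d bin_width=%s n_surrogate=%d",
                    C, T, format(sm$bin_width, digits = 17), sm$n_surrogate)
  idline <- paste0("#ids=", paste(sm$neuron_ids, collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, idline), con)
  if (format == "event_list") {
    ev <- which(sm$counts == 1L, arr.ind = TRUE)
    if (nrow(ev) > 0L) {
      ev <- ev[order(ev[, 1L], ev[, 2L]), , drop = FALSE]
      writeLines(paste(sm$neuron_ids[ev[, 1L]], ev[, 2L] - 1L, sep = "\t"), con)
    }
  } else {
    writeLines(apply(sm$counts, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' External input channels
#'
#' Real-valued signals assumed shared across neurons (e.g. slow common drive),
#' either supplied by the user or estimated from population activity by
#' [estimate_external_inputs()].
#'
#' @param signals real matrix `[L x T]` (0 rows allowed).
#' @param source `"given"` or `"estimated"`.
#' @param eigenvalues optional eigenvalue per channel (estimation metadata).
#' @export
external_inputs <- function(signals, source = c("given", "estimated"),
                            eigenvalues = NULL) {
  source <- match.arg(source)
  signals <- as.matrix(signals)
  structure(list(signals = signals, source = source, eigenvalues = eigenvalues),
            class = "external_inputs")
}

#' @export
print.external_inputs <- function(x, ...) {
  cat(sprintf("<external_inputs> %d channel(s) x %d bins (%s)\n",
              nrow(x$signals), ncol(x$signals), x$source))
  invisible(x)
}

#' Write / read external-input channels as annotated TSV
#'
#' One row per channel; header comments record the source and any
#' eigenvalues from estimation.
#'
#' @param ext an [external_inputs()].
#' @param path file path.
#' @export
write_external_inputs <- function(ext, path) {
  stopifnot(inherits(ext, "external_inputs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#L=%d T=%d source=%s", nrow(ext$signals),
                     ncol(ext$signals), ext$source), con)
  if (!is.null(ext$eigenvalues))
    writeLines(paste0("#eigenvalues=", paste(format(ext$eigenvalues,
                                                    digits = 17),
                                             collapse = "\t")), con)
  if (nrow(ext$signals) > 0L)
    writeLines(apply(format(ext$signals, digits = 17), 1L, paste,
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_external_inputs
#' @export
read_external_inputs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[[1L]]
  src <- sub(".*source=", "", hdr)
  ev <- NULL
  body_start <- 2L
  if (length(lines) >= 2L && startsWith(lines[[2L]], "#eigenvalues=")) {
    ev <- as.numeric(strsplit(sub("^#eigenvalues=", "", lines[[2L]]),
                              "\t")[[1L]])
    body_start <- 3L
  }
  body <- lines[seq.int(body_start, length.out = length(lines) - body_start + 1L)]
  sig <- if (length(body) > 0L)
    do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  else matrix(0, 0L, 0L)
  external_inputs(sig, source = src, eigenvalues = ev)
}
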