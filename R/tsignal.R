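#' Channel normalization factors
#'
#' Per-channel mean read-1 intensity observed when reading that base; used
#' to put the four fluorescence channels on a common scale before the
#' T-signal is formed.
#'
#' @param A,C,G,T positive scalars.
#' @return named numeric vector of class `channel_norms`.
#' @export
channel_norms <- function(A = 1, C = 1, G = 1, T = 1) {
  v <- c(A = A, C = C, G = G, T = T)
  if (any(!is.finite(v)) || any(v <= 0)) stop("channel norms must be positive")
  structure(v, class = "channel_norms")
}

#' Compute per-cycle log T-signal traces
#'
#' For each cycle, every channel is divided by its normalization factor and
#' the T-signal is the normalized thymidine intensity divided by the sum of
#' the other three channels; the stored value is its natural logarithm.
#' Positions at which all four channels are zero (or at which the T-signal
#' is not positive) are imputed as the mean of the five valid signal values
#' upstream and the five downstream (10 neighbors; fewer at trace edges).
#' A trace with more than `max_zero` such positions is discarded.
#'
#' @param A,C,G,T numeric matrices of raw intensities (tags x cycles).
#' @param norms a [channel_norms()] object.
#' @param max_zero maximum tolerated zero-valued positions per trace.
#' @return list with `values` (tags x cycles matrix of log T-signal, rows of
#'   discarded traces set to `NA`), `imputed` (logical matrix), and
#'   `discarded` (logical vector).
#' @export
compute_t_signal <- function(A, C, G, T, norms = channel_norms(),
                             max_zero = 5L) {
  A <- rbind(A); C <- rbind(C); G <- rbind(G); T <- rbind(T)
  stopifnot(all(dim(A) == dim(C)), all(dim(A) == dim(G)), all(dim(A) == dim(T)))
  if (ncol(A) < 1) stop("traces must have at least one cycle")
  tsig <- (T / norms[["T"]]) /
    (A / norms[["A"]] + C / norms[["C"]] + G / norms[["G"]])
  bad <- (A == 0 & C == 0 & G == 0 & T == 0) | !is.finite(tsig) | tsig <= 0
  vals <- suppressWarnings(log(tsig))
  rm(tsig)
  vals[bad] <- NA_real_
  nbad <- rowSums(bad)
  discarded <- nbad > max_zero
  impute_rows <- which(!discarded & nbad > 0)
  for (i in impute_rows) {
    v <- vals[i, ]
    for (j in which(bad[i, ])) {
      up <- which(!bad[i, ] & seq_along(v) < j)
      dn <- which(!bad[i, ] & seq_along(v) > j)
      nb <- c(utils::tail(up, 5L), utils::head(dn, 5L))
      vals[i, j] <- mean(v[nb])
    }
  }
  vals[discarded, ] <- NA_real_
  list(values = vals, imputed = bad & !discarded, discarded = discarded)
}

#' Screen read-2 sequences for GHMM analysis
#'
#' A tag is routed to the GHMM when its read-2 base calls contain a stretch
#' of >= `min_t` T residues (the reverse complement of the tail) within an
#' 11-nt window starting in the first `first_nt` nt of the read. Sequences
#' shorter than the scan region are scanned over their full length.
#'
#' @param seqs character vector of read-2 sequences.
#' @param window window width in nt.
#' @param min_t minimum T count within one window.
#' @param first_nt number of leading window start positions scanned.
#' @return logical vector: `TRUE` = analyze with the GHMM.
#' @export
screen_for_ghmm <- function(seqs, window = 11L, min_t = 10L, first_nt = 30L) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < min_t) return(FALSE)
    x <- strsplit(toupper(s), "")[[1]] == "T"
    lastStart <- min(first_nt, max(1L, n - window + 1L))
    cs <- cumsum(x)
    starts <- seq_len(lastStart)
    ends <- pmin(starts + window - 1L, n)
    counts <- cs[ends] - c(0, cs)[starts]
    any(counts >= min_t)
  }, logical(1), USE.NAMES = FALSE)
}

#' Direct tail calls for short-tailed tags
#'
#' For tags that failed the GHMM screen: if read 2 begins with >= `min_run`
#' contiguous T residues, the tail length is the length of that leading run
#' (by construction < 10 nt for tags failing the screen); otherwise the tag
#' is discarded.
#'
#' @param seqs character vector of read-2 sequences.
#' @param min_run minimum leading-T run for a direct call.
#' @return data.frame with columns `tail_length` (NA when discarded) and
#'   `route` ("direct" or "discarded").
#' @export
call_short_tail <- function(seqs, min_run = 4L) {
  runs <- vapply(seqs, function(s) {
    x <- strsplit(toupper(s), "")[[1]] == "T"
    if (!length(x) || !x[1]) return(0L)
    w <- which(!x)
    if (!length(w)) length(x) else w[1] - 1L
  }, integer(1), USE.NAMES = FALSE)
  ok <- runs >= min_run
  data.frame(tail_length = ifelse(ok, runs, NA_integer_),
             route = ifelse(ok, "direct", "discarded"),
             stringsAsFactors = FALSE)
}

#' Call poly(A)-tail lengths for a set of tags
#'
#' Full tail-calling pipeline for one sample: screens read-2 base calls,
#' calls short tails directly from leading-T runs, converts the remaining
#' tags' intensities to log T-signal traces (discarding traces with more
#' than five unrecoverable positions), and decodes tail lengths with the
#' GHMM.
#'
#' @param traces list with elements `tag_id` (character) and `A`, `C`, `G`,
#'   `T` (tags x cycles intensity matrices), as produced by
#'   [simulate_intensity_tags()] or [read_traces_tsv()].
#' @param seqs character vector of read-2 sequences, parallel to `tag_id`.
#' @param params a trained [ghmm_params()] object.
#' @param norms a [channel_norms()] object.
#' @param genes optional character vector of gene assignments per tag.
#' @param polyA_state poly(A)-state index passed to [decode_tail_length()].
#' @return data.frame: `tag_id`, `gene`, `tail_length`, `route`
#'   ("ghmm", "direct", or "discarded").
#' @export
call_tails <- function(traces, seqs, params, norms = channel_norms(),
                       genes = NULL, polyA_state = 2L) {
  n <- length(traces$tag_id)
  stopifnot(length(seqs) == n)
  if (is.null(genes)) genes <- rep(NA_character_, n)
  route <- rep("discarded", n)
  tail_length <- rep(NA_integer_, n)

  ghmm_idx <- screen_for_ghmm(seqs)
  if (any(!ghmm_idx)) {
    st <- call_short_tail(seqs[!ghmm_idx])
    route[!ghmm_idx] <- st$route
    tail_length[!ghmm_idx] <- st$tail_length
  }
  ## decode GHMM-routed tags in blocks to bound peak memory
  gi <- which(ghmm_idx)
  block <- 20000L
  for (st in if (length(gi)) seq(1L, length(gi), by = block) else integer(0)) {
    idx <- gi[st:min(st + block - 1L, length(gi))]
    ts <- compute_t_signal(traces$A[idx, , drop = FALSE],
                           traces$C[idx, , drop = FALSE],
                           traces$G[idx, , drop = FALSE],
                           traces$T[idx, , drop = FALSE], norms)
    keep <- !ts$discarded
    if (any(keep)) {
      calls <- decode_tail_length(ts$values[keep, , drop = FALSE], params,
                                  polyA_state = polyA_state)
      tail_length[idx[keep]] <- calls
      route[idx[keep]] <- "ghmm"
    }
    rm(ts)
  }
  data.frame(tag_id = traces$tag_id, gene = genes,
             tail_length = tail_length, route = route,
             stringsAsFactors = FALSE)
}

#' Mean tail length per gene
#'
#' Arithmetic mean of tail-length calls per gene; genes with fewer than
#' `min_tags` measurements are excluded from all mean-tail analyses.
#'
#' @param calls data.frame with columns `gene` and `tail_length`.
#' @param min_tags minimum tail-length measurements per gene (default 50).
#' @return data.frame: `gene`, `n_tags`, `mean_tail`.
#' @export
aggregate_gene_tails <- function(calls, min_tags = 50L) {
  ok <- !is.na(calls$tail_length) & !is.na(calls$gene)
  calls <- calls[ok, , drop = FALSE]
  dt <- data.table::as.data.table(calls)
  agg <- dt[, list(n_tags = .N, mean_tail = mean(tail_length)), by = "gene"]
  agg <- agg[agg$n_tags >= min_tags, ]
  as.data.frame(agg[order(agg$gene), ])
}

#' Spike-in standard recovery and accuracy
#'
#' Compares tail calls for spike-in standards of known length against their
#' input fractions: recovered fraction of tags per standard relative to its
#' input fraction, plus mean/median called length against truth.
#'
#' @param calls data.frame of tail calls for spike-in tags.
#' @param standard_map data.frame mapping `tag_id` to `standard`.
#' @param truth data.frame with `standard`, `length`, `input_fraction`.
#' @return data.frame per standard: `standard`, `true_length`, `n_tags`,
#'   `recovered_fraction`, `input_fraction`, `recovery_ratio`, `mean_call`,
#'   `median_call`.
#' @export
standards_report <- function(calls, standard_map, truth) {
  m <- merge(calls, standard_map, by = "tag_id")
  if (any(!m$standard %in% truth$standard)) stop("unknown standard id")
  kept <- m[!is.na(m$tail_length), , drop = FALSE]
  total <- nrow(kept)
  out <- lapply(seq_len(nrow(truth)), function(i) {
    sub <- kept[kept$standard == truth$standard[i], , drop = FALSE]
    rec <- nrow(sub) / total
    data.frame(standard = truth$standard[i],
               true_length = truth$length[i],
               n_tags = nrow(sub),
               recovered_fraction = rec,
               input_fraction = truth$input_fraction[i],
               recovery_ratio = rec / truth$input_fraction[i],
               mean_call = if (nrow(sub)) mean(sub$tail_length) else NA_real_,
               median_call = if (nrow(sub)) stats::median(sub$tail_length) else NA_real_)
  })
  do.call(rbind, out)
}
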