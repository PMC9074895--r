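#' Annotate mRNA 3' ends from a tag pileup
#'
#' Iterative greedy peak assignment on the pileup of tag 3' coordinates for
#' one gene. At each iteration the coordinate carrying the most tags is
#' annotated as a 3' end; all tags within `window_halfwidth` nt of it (a
#' 21-nt window by default) are assigned to that end and removed; the
#' process repeats until no tags remain. Ends are then retained if they
#' account for at least `min_fraction` of all the gene's 3'-UTR-mapping
#' tags. Ties on the maximal count are broken toward the 5'-most coordinate
#' in transcript orientation.
#'
#' Coordinates are expected in transcript orientation (increasing towards
#' the 3' end); only tags with tails >= 11 nt should enter the pileup.
#'
#' @param pileup named numeric vector or data.frame (`coord`, `count`) of
#'   tag counts by 3'-coordinate.
#' @param window_halfwidth half-width of the assignment window (nt).
#' @param min_fraction minimum fraction of the gene's tags for a retained end.
#' @return data.frame of all discovered ends in assignment order:
#'   `coord`, `count`, `fraction`, `retained`.
#' @export
annotate_ends <- function(pileup, window_halfwidth = 10L, min_fraction = 0.10) {
  if (is.data.frame(pileup)) {
    coords <- as.numeric(pileup$coord); counts <- as.numeric(pileup$count)
  } else {
    coords <- as.numeric(names(pileup)); counts <- as.numeric(pileup)
  }
  keep <- !is.na(coords) & is.finite(coords) & !is.na(counts) & counts > 0
  coords <- coords[keep]; counts <- counts[keep]
  if (!length(coords)) {
    return(data.frame(coord = numeric(0), count = numeric(0),
                      fraction = numeric(0), retained = logical(0)))
  }
  o <- order(coords)
  coords <- coords[o]; counts <- counts[o]
  total <- sum(counts)
  ends <- list()
  active <- rep(TRUE, length(coords))
  while (any(active)) {
    cand <- which(active)
    best <- cand[which.max(counts[cand])]  # which.max takes the first (5'-most) on ties
    inwin <- active & abs(coords - coords[best]) <= window_halfwidth
    assigned <- sum(counts[inwin])
    ends[[length(ends) + 1L]] <- c(coord = coords[best], count = assigned)
    active[inwin] <- FALSE
  }
  out <- as.data.frame(do.call(rbind, ends))
  out$fraction <- out$count / total
  out$retained <- out$fraction >= min_fraction
  out
}

#' Annotate 3' ends for every gene in a tag table
#'
#' Applies [annotate_ends()] gene by gene to a BED-like table of tag 3'
#' coordinates, first dropping tags with tails shorter than `min_tail`
#' (short-tailed tags are not used for end annotation).
#'
#' @param tags data.frame with columns `gene`, `coord`, `tail_length`
#'   (coordinates in transcript orientation).
#' @param min_tail minimum tail length for a tag to enter the pileup.
#' @param window_halfwidth,min_fraction passed to [annotate_ends()].
#' @param retained_only if `TRUE` (default) return only retained ends.
#' @return data.frame: `gene`, `coord`, `count`, `fraction`, `retained`.
#' @export
annotate_ends_by_gene <- function(tags, min_tail = 11L, window_halfwidth = 10L,
                                  min_fraction = 0.10, retained_only = TRUE) {
  tags <- tags[!is.na(tags$tail_length) & tags$tail_length >= min_tail &
                 !is.na(tags$gene) & !is.na(tags$coord), , drop = FALSE]
  dt <- data.table::as.data.table(tags)
  pil <- dt[, list(count = .N), by = c("gene", "coord")]
  res <- lapply(split(pil, pil$gene), function(g) {
    e <- annotate_ends(data.frame(coord = g$coord, count = g$count),
                       window_halfwidth, min_fraction)
    if (nrow(e)) cbind(gene = g$gene[1], e) else NULL
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (retained_only && !is.null(out)) out <- out[out$retained, , drop = FALSE]
  if (is.null(out)) out <- data.frame(gene = character(0), coord = numeric(0),
                                      count = numeric(0), fraction = numeric(0),
                                      retained = logical(0))
  out
}
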