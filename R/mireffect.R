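#' Classify canonical miRNA seed-match site types
#'
#' Scans a 3'-UTR for canonical seed matches to a miRNA and reports the
#' strongest site class present, using the standard hierarchy
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer > none. Matches are defined on the mRNA
#' sense strand as the reverse complement of miRNA positions 2-7 (6mer core)
#' or 2-8 (7mer-m8 core), with an A opposite miRNA position 1 defining the
#' A1 feature (8mer = 2-8 match + A1; 7mer-A1 = 2-7 match + A1). A gene is
#' "none" only if no 6mer core match occurs anywhere in the full transcript
#' (when `transcript` is supplied; otherwise the UTR is used).
#' Ambiguous bases are treated as mismatches.
#'
#' @param utr3 character vector of 3'-UTR sequences (DNA alphabet).
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet, >= 8 nt).
#' @param transcript optional character vector of full transcript sequences
#'   used for the no-site definition.
#' @return factor of site types with levels
#'   `none < 6mer < 7mer-A1 < 7mer-m8 < 8mer`.
#' @export
classify_sites <- function(utr3, mirna, transcript = NULL) {
  if (nchar(mirna) < 8) stop("miRNA sequence must be >= 8 nt")
  mir <- chartr("Uu", "Tt", toupper(mirna))
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  seed6 <- rc(substr(mir, 2, 7))           # matches miRNA 2-7
  seed7m8 <- rc(substr(mir, 2, 8))         # matches miRNA 2-8
  m8mer <- paste0(seed7m8, "A")            # 2-8 match plus A opposite position 1
  m7a1 <- paste0(seed6, "A")               # 2-7 match plus A opposite position 1
  utr3 <- toupper(utr3)
  has <- function(seqs, motif) vapply(seqs, grepl, logical(1),
                                      pattern = motif, fixed = TRUE,
                                      USE.NAMES = FALSE)
  site <- rep("none", length(utr3))
  site[has(utr3, seed6)] <- "6mer"
  site[has(utr3, m7a1)] <- "7mer-A1"
  site[has(utr3, seed7m8)] <- "7mer-m8"
  site[has(utr3, m8mer)] <- "8mer"
  ## the no-site class requires no 6mer core anywhere in the transcript
  bg <- if (is.null(transcript)) utr3 else toupper(transcript)
  site[site == "none" & has(bg, seed6)] <- NA
  factor(site, levels = c("none", "6mer", "7mer-A1", "7mer-m8", "8mer"),
         ordered = TRUE)
}

#' Normalize fold changes for the 3'-UTR-length confound
#'
#' Longer 3'-UTRs accrue larger secondary effects of a miRNA perturbation.
#' The relationship between log2 fold-change and log10(3'-UTR length) is
#' fitted by OLS on the no-site genes only, and the fitted slope component
#' (centered on the no-site mean log-length, so the no-site intercept is
#' preserved) is subtracted from every gene's fold change. After
#' normalization the refitted no-site slope is zero to numerical precision,
#' and the operation is idempotent.
#'
#' @param fc numeric vector of log2 fold changes (all genes).
#' @param utr3_length numeric vector of 3'-UTR lengths (nt).
#' @param no_site logical vector flagging no-site genes (>= 30 required).
#' @return numeric vector of normalized log2 fold changes, with the fitted
#'   slope as attribute `slope`.
#' @export
normalize_fold_changes <- function(fc, utr3_length, no_site) {
  stopifnot(length(fc) == length(utr3_length), length(fc) == length(no_site))
  if (sum(no_site) < 30) stop("need >= 30 no-site genes for normalization")
  lx <- log10(utr3_length)
  if (stats::sd(lx[no_site]) == 0) {
    out <- fc
    attr(out, "slope") <- 0
    return(out)
  }
  fit <- stats::lm(fc[no_site] ~ lx[no_site])
  slope <- stats::coef(fit)[[2]]
  out <- fc - slope * (lx - mean(lx[no_site]))
  attr(out, "slope") <- slope
  out
}

#' Cohort repression statistics
#'
#' The repressive effect of the miRNA on a cohort of predicted targets is
#' the mean normalized fold-change of the cohort minus the median
#' normalized fold-change of the no-site genes. Significance of repression
#' is a one-tailed Welch t-test (alternative: cohort < no-site); RNA vs
#' RPF responses are compared with an unpaired two-tailed t-test on the
#' cohort's normalized fold changes.
#'
#' @param normalized named list of per-measure normalized fold-change
#'   vectors over all genes, e.g. `list(rna = ..., rpf = ..., tail = ...)`.
#' @param cohort integer/logical index of cohort genes.
#' @param no_site integer/logical index of no-site genes (disjoint from
#'   `cohort`).
#' @param min_cohort below this size effects are reported without tests.
#' @return data.frame, one row per measure: `measure`, `effect`, `p_value`
#'   (one-tailed, vs no-site), `n_cohort`, `n_no_site`; attribute
#'   `rna_vs_rpf_p` when both measures are present.
#' @export
cohort_repression <- function(normalized, cohort, no_site, min_cohort = 5L) {
  if (is.logical(cohort)) cohort <- which(cohort)
  if (is.logical(no_site)) no_site <- which(no_site)
  if (length(intersect(cohort, no_site))) {
    stop("cohort and no-site sets must be disjoint")
  }
  small <- length(cohort) < min_cohort
  if (small) warning("cohort has fewer than ", min_cohort,
                     " genes; effects reported without tests")
  rows <- lapply(names(normalized), function(m) {
    x <- normalized[[m]][cohort]
    y <- normalized[[m]][no_site]
    eff <- mean(x, na.rm = TRUE) - stats::median(y, na.rm = TRUE)
    p <- if (small) NA_real_ else
      stats::t.test(x, y, alternative = "less")$p.value
    data.frame(measure = m, effect = eff, p_value = p,
               n_cohort = length(cohort), n_no_site = length(no_site),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (all(c("rna", "rpf") %in% names(normalized)) && !small) {
    attr(out, "rna_vs_rpf_p") <- stats::t.test(
      normalized$rna[cohort], normalized$rpf[cohort],
      alternative = "two.sided", paired = FALSE)$p.value
  }
  out
}

#' Select top-repressed predicted targets
#'
#' Restricts a set of predicted targets to those whose expression in a
#' reference miRNA-induction experiment decreased to at most
#' `max_fraction` (default 75%) of its original level. Targets missing a
#' reference value are excluded.
#'
#' @param targets character vector of predicted-target gene ids.
#' @param reference data.frame with columns `gene` and `fraction`
#'   (expression after induction / before).
#' @param max_fraction inclusive threshold.
#' @return character vector of top-target gene ids.
#' @export
select_top_targets <- function(targets, reference, max_fraction = 0.75) {
  fr <- reference$fraction[match(targets, reference$gene)]
  targets[!is.na(fr) & fr <= max_fraction]
}
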