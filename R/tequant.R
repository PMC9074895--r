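#' Translational efficiency from RPF and RNA-seq counts
#'
#' TE = log2(RPF RPM / RNA RPM), where RPM is reads per million mapped
#' reads. The expression cutoff (>= `rpm_cutoff` RPM) applies to the
#' RNA-seq measurement of each gene; retained genes additionally require a
#' nonzero RPF count (zero-RPF genes are dropped with a warning, their TE
#' being undefined). Counts are expected over the ORF excluding its first
#' 50 nt, per the counting rules of the profiling protocol.
#'
#' @param counts data.frame with columns `gene`, `rpf`, `rna`.
#' @param rpf_lib,rna_lib library sizes (total mapped reads) for the RPF and
#'   RNA-seq samples.
#' @param rpm_cutoff minimum RNA-seq RPM for a gene to be retained.
#' @return data.frame: `gene`, `rpf_rpm`, `rna_rpm`, `te` (log2).
#' @export
compute_te <- function(counts, rpf_lib = sum(counts$rpf),
                       rna_lib = sum(counts$rna), rpm_cutoff = 10) {
  stopifnot(rpf_lib > 0, rna_lib > 0)
  rpf_rpm <- counts$rpf * 1e6 / rpf_lib
  rna_rpm <- counts$rna * 1e6 / rna_lib
  keep <- rna_rpm >= rpm_cutoff
  zero_rpf <- keep & counts$rpf == 0
  if (any(zero_rpf)) {
    warning(sum(zero_rpf), " gene(s) passed the RNA cutoff with zero RPF ",
            "counts; TE undefined, dropped")
    keep <- keep & !zero_rpf
  }
  data.frame(gene = counts$gene[keep], rpf_rpm = rpf_rpm[keep],
             rna_rpm = rna_rpm[keep],
             te = log2(rpf_rpm[keep] / rna_rpm[keep]),
             stringsAsFactors = FALSE)
}

#' Fold range of TE values between outer percentiles
#'
#' Median-centers log2 TE values and reports the fold range spanned between
#' the `lo` and `hi` percentiles (default 1st-99th), i.e.
#' `2^(P_hi - P_lo)`. Percentiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param te numeric vector of log2 TE values (>= 100 genes).
#' @param lo,hi percentile bounds, in percent.
#' @return scalar fold range.
#' @export
percentile_range <- function(te, lo = 1, hi = 99) {
  te <- te[is.finite(te)]
  if (length(te) < 100) stop("need >= 100 genes for a percentile range")
  te <- te - stats::median(te)
  q <- stats::quantile(te, c(lo, hi) / 100, names = FALSE, type = 7)
  2^(q[2] - q[1])
}

#' Per-gene codon frequencies
#'
#' Counts codons across each CDS (which must begin ATG, end with a stop,
#' and have length divisible by 3) and returns per-gene frequencies over
#' the 61 sense codons (stop codons excluded from both counts and total).
#'
#' @param cds a [Biostrings::DNAStringSet] of coding sequences.
#' @return numeric matrix, genes x 61 sense codons.
#' @export
codon_frequencies <- function(cds) {
  if (any(Biostrings::width(cds) %% 3 != 0)) {
    stop("CDS lengths must be divisible by 3")
  }
  counts <- Biostrings::trinucleotideFrequency(cds, step = 3)
  stops <- c("TAA", "TAG", "TGA")
  counts <- counts[, setdiff(colnames(counts), stops), drop = FALSE]
  counts / pmax(rowSums(counts), 1)
}

## codon -> amino acid map over the 61 sense codons
.codon_to_aa <- function(codons) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(codons)))
}

#' Correlation of codon (or amino-acid) frequency with TE
#'
#' For each sense codon, the Pearson correlation between its per-gene
#' frequency and the per-gene TE is computed in every sample, then
#' aggregated as mean and standard deviation across samples and sorted in
#' descending order of the mean. With `level = "aa"`, frequencies are first
#' pooled over synonymous codons.
#'
#' @param freqs genes x codons frequency matrix from [codon_frequencies()].
#' @param te_samples data.frame or matrix of log2 TE values, genes in rows
#'   (aligned with `freqs`), one column per sample.
#' @param level `"codon"` or `"aa"`.
#' @return data.frame: `feature`, `mean_r`, `sd_r`, `n_samples`, sorted by
#'   decreasing `mean_r`; features with zero variance are reported with NA.
#' @export
codon_te_correlation <- function(freqs, te_samples, level = c("codon", "aa")) {
  level <- match.arg(level)
  te_samples <- as.matrix(te_samples)
  stopifnot(nrow(freqs) == nrow(te_samples))
  if (level == "aa") {
    aa <- .codon_to_aa(colnames(freqs))
    freqs <- t(rowsum(t(freqs), aa))
  }
  rs <- sapply(colnames(freqs), function(cd) {
    f <- freqs[, cd]
    apply(te_samples, 2, function(te) {
      ok <- is.finite(te) & is.finite(f)
      if (stats::sd(f[ok]) == 0 || stats::sd(te[ok]) == 0) return(NA_real_)
      stats::cor(f[ok], te[ok])
    })
  })
  rs <- matrix(rs, ncol = ncol(freqs),
               dimnames = list(NULL, colnames(freqs)))
  out <- data.frame(feature = colnames(freqs),
                    mean_r = colMeans(rs),
                    sd_r = apply(rs, 2, stats::sd),
                    n_samples = ncol(te_samples),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_r, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Ribosomal A-site codon occupancy
#'
#' Enrichment of each codon at the RPF position corresponding to the
#' ribosomal A site (5' end + `offset` nt by field convention for 29-31-nt
#' footprints), relative to the background codon frequency of the
#' transcriptome. Optionally regresses an external per-codon statistic
#' (e.g. the codon's TE correlation) on the enrichments.
#'
#' @param rpf data.frame of footprints with columns `gene` and `pos`
#'   (0-based 5'-end offset into the CDS).
#' @param cds [Biostrings::DNAStringSet] of coding sequences (genes named).
#' @param offset A-site offset from the 5' end, nt.
#' @param te_correlation optional named vector of per-codon values to
#'   regress on enrichment (names = codons).
#' @param min_reads minimum number of usable in-frame reads.
#' @return list: `enrichment` (data.frame `codon`, `observed`, `background`,
#'   `enrichment`) and, when `te_correlation` is given, `r_squared` of the
#'   OLS of that statistic on enrichment.
#' @export
asite_occupancy <- function(rpf, cds, offset = 15L, te_correlation = NULL,
                            min_reads = 100L) {
  seqs <- as.character(cds)
  asite <- rpf$pos + offset
  inframe <- asite %% 3 == 0
  rpf <- rpf[inframe, , drop = FALSE]
  asite <- asite[inframe]
  lens <- nchar(seqs)[match(rpf$gene, names(seqs))]
  ok <- !is.na(lens) & asite + 3 <= lens
  rpf <- rpf[ok, , drop = FALSE]; asite <- asite[ok]
  if (nrow(rpf) < min_reads) stop("insufficient in-frame reads for A-site analysis")
  codons <- substr(seqs[match(rpf$gene, names(seqs))], asite + 1L, asite + 3L)
  stops <- c("TAA", "TAG", "TGA")
  codons <- codons[!codons %in% stops]
  obs <- table(codons)
  bg_counts <- colSums(Biostrings::trinucleotideFrequency(cds, step = 3))
  bg_counts <- bg_counts[setdiff(names(bg_counts), stops)]
  bg <- bg_counts / sum(bg_counts)
  all_codons <- names(bg)
  obs_f <- as.numeric(obs[all_codons]); obs_f[is.na(obs_f)] <- 0
  obs_f <- obs_f / sum(obs_f)
  enr <- data.frame(codon = all_codons, observed = obs_f,
                    background = as.numeric(bg),
                    enrichment = obs_f / as.numeric(bg),
                    stringsAsFactors = FALSE)
  out <- list(enrichment = enr)
  if (!is.null(te_correlation)) {
    y <- te_correlation[enr$codon]
    fit <- stats::lm(y ~ enr$enrichment)
    out$r_squared <- summary(fit)$r.squared
  }
  out
}

#' Reading-frame periodicity of RPF 5' ends
#'
#' Fraction of CDS-mapped footprint 5' ends falling in each of the three
#' reading frames; a quality-control statistic for ribosome profiling.
#'
#' @param pos integer vector of 5'-end offsets into the CDS (0-based).
#' @param min_reads minimum number of reads required.
#' @return numeric vector of length 3 (frames 0, 1, 2), summing to 1.
#' @export
rpf_periodicity <- function(pos, min_reads = 1000L) {
  if (length(pos) < min_reads) {
    stop("need >= ", min_reads, " CDS-mapped reads for periodicity QC")
  }
  tab <- tabulate(pos %% 3 + 1L, nbins = 3L)
  stats::setNames(tab / sum(tab), c("frame0", "frame1", "frame2"))
}

#' Spearman correlation between mean tail length and TE
#'
#' @param tail numeric vector of per-gene mean tail lengths.
#' @param te numeric vector of per-gene log2 TE values (same genes).
#' @return list: `rho`, `p_value`, `n`.
#' @export
tail_te_correlation <- function(tail, te) {
  ok <- is.finite(tail) & is.finite(te)
  if (sum(ok) < 10) stop("need >= 10 genes for the tail-TE correlation")
  ct <- suppressWarnings(stats::cor.test(tail[ok], te[ok], method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Permutation test for a gene subset's tail-TE correlation
#'
#' Tests whether the tail-TE Spearman correlation within a gene subset
#' exceeds what same-sized random subsets achieve: the null distribution is
#' the correlation of `n_perm` random subsets of identical size, and the
#' empirical p-value is the fraction of null correlations at least as large
#' as the observed one (add-one correction).
#'
#' @param tail,te per-gene vectors as in [tail_te_correlation()].
#' @param subset logical or integer index of the subset (size >= 50).
#' @param n_perm number of random subsets (> 0).
#' @param seed RNG seed.
#' @return list: `observed_rho`, `p_value`, `null_rho` (vector), `n_subset`.
#' @export
subset_correlation_test <- function(tail, te, subset, n_perm = 1000L,
                                    seed = NULL) {
  if (n_perm < 1) stop("n_perm must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.logical(subset)) subset <- which(subset)
  k <- length(subset)
  if (k < 50) stop("subset must contain >= 50 genes")
  obs <- stats::cor(tail[subset], te[subset], method = "spearman")
  null_rho <- replicate(n_perm, {
    idx <- sample.int(length(tail), k)
    stats::cor(tail[idx], te[idx], method = "spearman")
  })
  list(observed_rho = obs,
       p_value = (1 + sum(null_rho >= obs)) / (n_perm + 1),
       null_rho = null_rho, n_subset = k)
}
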