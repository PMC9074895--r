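#' Differential tail length between stimulated and control cohorts
#'
#' Per-gene Welch (unequal-variance) t-test on per-replicate mean tail
#' lengths, stimulated vs control; Delta = stimulated mean - control mean.
#' Genes should already have passed the 50-tag expression cutoff in each
#' sample. If both cohorts have zero within-cohort variance the test
#' degenerates: p = 1 when the means are equal, p = 0 (flagged) otherwise.
#'
#' @param control,stimulated numeric matrices of per-replicate gene mean
#'   tail lengths (genes x replicates, >= 2 replicates each).
#' @return data.frame: `delta_tail`, `p_value`, `degenerate` (logical), one
#'   row per gene (rownames preserved from `control`).
#' @export
differential_tail <- function(control, stimulated) {
  control <- rbind(control); stimulated <- rbind(stimulated)
  stopifnot(nrow(control) == nrow(stimulated))
  n0 <- ncol(control); n1 <- ncol(stimulated)
  if (n0 < 2 || n1 < 2) stop("need >= 2 replicates per cohort")
  m0 <- rowMeans(control); m1 <- rowMeans(stimulated)
  v0 <- apply(control, 1, stats::var); v1 <- apply(stimulated, 1, stats::var)
  delta <- m1 - m0
  se2 <- v0 / n0 + v1 / n1
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  tstat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- v0 == 0 & v1 == 0
  p[degen] <- ifelse(delta[degen] == 0, 1, 0)
  data.frame(delta_tail = delta, p_value = p, degenerate = degen,
             row.names = rownames(control))
}

## DESeq-style median-of-ratios size factors
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- rowMeans(lg)
  use <- is.finite(geo)
  apply(counts, 2, function(cj) {
    exp(stats::median(log(cj[use]) - geo[use], na.rm = TRUE))
  })
}

#' Negative-binomial differential expression across replicate cohorts
#'
#' A self-contained NB test for per-gene tag counts across two replicate
#' cohorts (the package's defined substitute for an external
#' differential-expression caller, so the pipeline has no dependencies
#' beyond base statistics). Counts are normalized with median-of-ratios
#' size factors; per-gene dispersions are estimated by the method of
#' moments (Var = mu + alpha mu^2) within cohorts and then replaced by a
#' mean-dispersion trend alpha(mu) = a0 + a1/mu fitted across genes; the
#' cohort contrast is a Wald test on the log2 ratio of normalized cohort
#' means, with a t reference on the within-cohort degrees of freedom and
#' Benjamini-Hochberg adjustment.
#'
#' @param counts integer matrix of tag counts, genes x samples.
#' @param condition factor/character of length ncol(counts) with two
#'   levels; the second level is the "stimulated" cohort.
#' @param pseudocount added to normalized cohort means for the fold change.
#' @return data.frame: `gene`, `base_mean`, `log2fc`, `p_value`, `padj`.
#'   All-zero genes are excluded.
#' @export
differential_expression <- function(counts, condition, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2, length(condition) == ncol(counts))
  if (min(table(condition)) < 2) stop("need >= 2 replicates per cohort")
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  g0 <- condition == levels(condition)[1]
  g1 <- condition == levels(condition)[2]
  n0 <- sum(g0); n1 <- sum(g1)
  mu0 <- rowMeans(norm[, g0, drop = FALSE])
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  v0 <- apply(norm[, g0, drop = FALSE], 1, stats::var)
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  ## per-gene method-of-moments dispersion, pooled across cohorts
  a_raw <- ((v0 - mu0) + (v1 - mu1)) / (mu0^2 + mu1^2)
  mu_bar <- (mu0 + mu1) / 2
  fit_rows <- is.finite(a_raw) & a_raw > 0 & mu_bar > 1
  if (sum(fit_rows) >= 10) {
    co <- stats::coef(stats::lm(a_raw[fit_rows] ~ I(1 / mu_bar[fit_rows])))
    a0 <- max(co[1], 0); a1 <- max(co[2], 0)
  } else {
    a0 <- max(mean(a_raw[is.finite(a_raw)]), 0.01); a1 <- 0
  }
  alpha <- pmax(a0 + a1 / mu_bar, 1e-8)
  log2fc <- log2((mu1 + pseudocount) / (mu0 + pseudocount))
  se2 <- ((1 / pmax(mu0, pseudocount) + alpha) / n0 +
          (1 / pmax(mu1, pseudocount) + alpha) / n1) / log(2)^2
  tstat <- log2fc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df = n0 + n1 - 2)
  data.frame(gene = rownames(counts), base_mean = mu_bar, log2fc = log2fc,
             p_value = p, padj = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify the mechanism behind a stimulation-induced tail change
#'
#' Pure function of the two per-gene test outcomes. A significant tail
#' increase accompanied by a significant expression increase indicates a
#' transcriptional burst of young, long-tailed mRNAs; with a significant
#' expression decrease it indicates preferential decay of short-tailed
#' isoforms; with no significant expression change it indicates
#' cytoplasmic polyadenylation; anything else is "none".
#'
#' @param delta_tail,tail_p per-gene tail change (nt) and t-test p.
#' @param log2fc,expr_padj per-gene expression log2 fold-change and
#'   BH-adjusted NB-test p.
#' @param alpha_tail,alpha_expr significance thresholds (defaults 0.05).
#' @return factor with levels `none`, `burst`, `short-tail-decay`,
#'   `cytoplasmic-polyadenylation`.
#' @export
classify_mechanism <- function(delta_tail, tail_p, log2fc, expr_padj,
                               alpha_tail = 0.05, alpha_expr = 0.05) {
  tail_up <- delta_tail > 0 & tail_p < alpha_tail
  expr_sig <- expr_padj < alpha_expr
  out <- rep("none", length(delta_tail))
  out[tail_up & expr_sig & log2fc > 0] <- "burst"
  out[tail_up & expr_sig & log2fc < 0] <- "short-tail-decay"
  out[tail_up & !expr_sig] <- "cytoplasmic-polyadenylation"
  factor(out, levels = c("none", "burst", "short-tail-decay",
                         "cytoplasmic-polyadenylation"))
}

#' Detect cytoplasmic polyadenylation elements in 3' UTRs
#'
#' Scans for U-rich CPE motifs (supplied as DNA-alphabet patterns; the
#' defaults, TTTTAT and TTTTAAT, are the canonical CPE classes described in
#' oocytes and striatum and are configurable reconstructions).
#'
#' @param utr3 character vector of 3'-UTR sequences.
#' @param patterns character vector of motif patterns.
#' @return logical vector: gene has at least one CPE.
#' @export
has_cpe <- function(utr3, patterns = c("TTTTAT", "TTTTAAT")) {
  utr3 <- chartr("Uu", "Tt", toupper(utr3))
  Reduce(`|`, lapply(patterns, function(p) grepl(p, utr3, fixed = TRUE)))
}

#' Association between a motif and tail-length increases
#'
#' Fisher's exact test on the 2x2 table of tail-increased vs not against
#' motif presence vs absence; reports the odds ratio. An empty margin
#' yields p = 1 with a warning.
#'
#' @param tail_increased logical vector per gene.
#' @param motif_present logical vector per gene.
#' @return list: `table`, `odds_ratio`, `p_value`.
#' @export
motif_association <- function(tail_increased, motif_present) {
  tab <- table(factor(tail_increased, c(TRUE, FALSE)),
               factor(motif_present, c(TRUE, FALSE)),
               dnn = c("tail_increased", "motif"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in the association table; p = 1")
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Short-tailed-isoform depletion check
#'
#' Tests whether stimulation depleted a gene's short-tailed isoforms:
#' the short-tail boundary is the `q` quantile of the control cohort's tag
#' tail lengths, and the fraction of tags below that boundary is compared
#' between cohorts with a two-proportion test.
#'
#' @param control_tails,stim_tails numeric vectors of per-tag tail lengths
#'   for one gene.
#' @param q quantile defining "short-tailed" on the control distribution.
#' @return list: `cutoff_nt`, `control_fraction`, `stim_fraction`,
#'   `p_value` (two-sided).
#' @export
short_tail_depletion <- function(control_tails, stim_tails, q = 0.25) {
  cutoff <- stats::quantile(control_tails, q, names = FALSE)
  f0 <- mean(control_tails < cutoff)
  f1 <- mean(stim_tails < cutoff)
  pt <- stats::prop.test(c(sum(control_tails < cutoff),
                           sum(stim_tails < cutoff)),
                         c(length(control_tails), length(stim_tails)))
  list(cutoff_nt = cutoff, control_fraction = f0, stim_fraction = f1,
       p_value = pt$p.value)
}

#' Global tail-length distribution summary across cohorts
#'
#' Per-sample tail-length histograms (2-nt bins), per-sample mean tails,
#' and a one-way ANOVA of sample mean tail length on treatment, testing
#' whether stimulation shifted the global distribution.
#'
#' @param tails named list of numeric vectors (one per sample) of per-tag
#'   tail lengths.
#' @param treatment factor/character per sample.
#' @param binwidth histogram bin width, nt.
#' @return list: `sample_means`, `anova_p`, `histograms` (list of
#'   data.frames `mid`, `count`).
#' @export
global_tail_summary <- function(tails, treatment, binwidth = 2) {
  stopifnot(length(tails) == length(treatment))
  if (length(unique(treatment)) < 2) stop("need >= 2 cohorts")
  means <- vapply(tails, mean, numeric(1))
  fit <- stats::aov(means ~ factor(treatment))
  an <- summary(fit)[[1]]
  anova_p <- an[["Pr(>F)"]][1]
  if (is.na(anova_p) || an[["F value"]][1] == 0) anova_p <- 1
  top <- max(vapply(tails, max, numeric(1)))
  breaks <- seq(0, ceiling(top / binwidth) * binwidth + binwidth, by = binwidth)
  hists <- lapply(tails, function(x) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  })
  list(sample_means = means, anova_p = anova_p, histograms = hists)
}
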