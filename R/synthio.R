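#' Configuration for the synthetic-data generators
#'
#' Central configuration for all synthetic inputs, with planted ground
#' truth written alongside every output. Defaults describe a typical
#' neuronal tail-profiling / ribosome-profiling experiment: gamma-
#' distributed tail lengths with mean 90 nt, 250-cycle intensity reads,
#' log-normal gene expression, negative-binomial counts with dispersion
#' 0.05, 4-vs-4 replicate stimulation cohorts with replicate tail SD
#' 4.5 nt, and spike-in tail standards of 10-160 nt.
#'
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @param n_genes number of genes.
#' @param mean_tags_per_gene expected tags per gene (allocated
#'   proportionally to expression).
#' @param trace_len read-2 length in cycles.
#' @param tail_length_law list: `dist` ("gamma"), `mean` (nt), `shape`.
#' @param length_laws list of log-normal length laws for `utr5`,
#'   `cds_codons`, `utr3` (each `meanlog`, `sdlog`, `min`).
#' @param ghmm_truth `ghmm_params` generating the intensity traces.
#' @param te_effects named numeric vector: log2-TE coefficient per feature
#'   column.
#' @param noise_sd residual SD of log2 TE.
#' @param nb_dispersion NB dispersion alpha (Var = mu + alpha mu^2).
#' @param library_size reads per count library.
#' @param confound_slope log2FC per log10-nt of 3'-UTR length planted in
#'   the miRNA experiment.
#' @param repression_by_site named log2FC repression per site type.
#' @param fc_noise_sd,te_fc_noise_sd,tail_fc_noise_sd per-gene noise SDs of
#'   the miRNA fold-change measures (log2, log2, nt).
#' @param n_replicates replicates per stimulation cohort.
#' @param replicate_tail_sd between-replicate SD of gene mean tails (nt).
#' @param stim_delta_tail planted tail increase for responsive genes (nt).
#' @param stim_fold planted expression fold change for burst/decay genes.
#' @param mechanism_fractions named fractions of genes per mechanism.
#' @param standards data.frame `standard`, `length`, `input_fraction`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 500L,
                         mean_tags_per_gene = 200,
                         trace_len = 250L,
                         tail_length_law = list(dist = "gamma", mean = 90, shape = 4),
                         length_laws = list(
                           utr5 = list(meanlog = log(150), sdlog = 0.5, min = 30),
                           cds_codons = list(meanlog = log(400), sdlog = 0.5, min = 40),
                           utr3 = list(meanlog = log(800), sdlog = 0.7, min = 60)),
                         ghmm_truth = NULL,
                         te_effects = c(gc_cds = 4, log_len_cds = 0.8,
                                        utr3_mfe_per_nt = 3),
                         noise_sd = 0.8,
                         nb_dispersion = 0.05,
                         library_size = 2e7,
                         confound_slope = 0,
                         repression_by_site = c("6mer" = -0.1, "7mer-A1" = -0.2,
                                                "7mer-m8" = -0.3, "8mer" = -0.4),
                         fc_noise_sd = 0.3,
                         te_fc_noise_sd = 0.15,
                         tail_fc_noise_sd = 2,
                         n_replicates = 4L,
                         replicate_tail_sd = 4.5,
                         stim_delta_tail = 20,
                         stim_fold = 8,
                         mechanism_fractions = c(burst = 0.05,
                                                 `short-tail-decay` = 0.05,
                                                 `cytoplasmic-polyadenylation` = 0.05,
                                                 none = 0.85),
                         standards = data.frame(
                           standard = c("std10", "std50", "std100", "std160"),
                           length = c(10L, 50L, 100L, 160L),
                           input_fraction = c(0.25, 0.25, 0.25, 0.25))) {
  if (tail_length_law$dist != "gamma" || tail_length_law$mean <= 0 ||
      tail_length_law$shape <= 0) {
    stop("invalid tail-length law")
  }
  if (is.null(ghmm_truth)) {
    A <- matrix(c(0.8, 0.2, 0,
                  0, 1 - 1 / tail_length_law$mean, 1 / tail_length_law$mean,
                  0, 0, 1), 3, 3, byrow = TRUE)
    ghmm_truth <- ghmm_params(pi = c(0.998, 0.001, 0.001), A = A,
                              mu = c(100, 1, -1), sigma2 = c(1, 0.25, 0.25))
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              mean_tags_per_gene = mean_tags_per_gene,
              trace_len = as.integer(trace_len),
              tail_length_law = tail_length_law, length_laws = length_laws,
              ghmm_truth = ghmm_truth, te_effects = te_effects,
              noise_sd = noise_sd, nb_dispersion = nb_dispersion,
              library_size = library_size, confound_slope = confound_slope,
              repression_by_site = repression_by_site,
              fc_noise_sd = fc_noise_sd, te_fc_noise_sd = te_fc_noise_sd,
              tail_fc_noise_sd = tail_fc_noise_sd,
              n_replicates = as.integer(n_replicates),
              replicate_tail_sd = replicate_tail_sd,
              stim_delta_tail = stim_delta_tail, stim_fold = stim_fold,
              mechanism_fractions = mechanism_fractions,
              standards = standards)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @param cfg a configuration list.
#' @export
validate_synth_config <- function(cfg) {
  if (cfg$n_genes < 1) stop("n_genes must be >= 1")
  if (cfg$trace_len < 1) stop("trace length must be >= 1")
  if (cfg$nb_dispersion < 0) stop("negative NB dispersion")
  if (cfg$tail_length_law$dist != "gamma" ||
      cfg$tail_length_law$mean <= 0 || cfg$tail_length_law$shape <= 0) {
    stop("invalid tail-length law")
  }
  for (nm in c("utr5", "cds_codons", "utr3")) {
    l <- cfg$length_laws[[nm]]
    if (is.null(l$meanlog) || is.null(l$sdlog) || l$sdlog < 0 || l$min < 1) {
      stop("invalid length law for ", nm)
    }
  }
  if (sum(cfg$standards$input_fraction) > 1 + 1e-9) {
    stop("standard input fractions must sum to <= 1")
  }
  if (abs(sum(cfg$mechanism_fractions) - 1) > 1e-9) {
    stop("mechanism fractions must sum to 1")
  }
  invisible(cfg)
}

## draw integer lengths from a log-normal law
.draw_len <- function(n, law) {
  pmax(round(stats::rlnorm(n, law$meanlog, law$sdlog)), law$min)
}

.SENSE_CODONS <- setdiff(
  apply(expand.grid(B1 = c("A", "C", "G", "T"), B2 = c("A", "C", "G", "T"),
                    B3 = c("A", "C", "G", "T"))[, 3:1], 1,
        function(r) paste0(r[3], r[2], r[1])),
  c("TAA", "TAG", "TGA"))

## random DNA with a given GC fraction
.rand_dna <- function(len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

## random CDS: ATG + sense codons biased by GC + stop
.rand_cds <- function(n_codons, gc) {
  gcw <- vapply(strsplit(.SENSE_CODONS, ""), function(x) sum(x %in% c("G", "C")),
                numeric(1))
  w <- gc^gcw * (1 - gc)^(3 - gcw)
  body <- sample(.SENSE_CODONS, n_codons - 2L, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
}

#' Generate a synthetic transcriptome with planted gene models
#'
#' Draws per-gene UTR and CDS lengths from the configured log-normal laws
#' and a per-gene GC bias from a beta distribution, then builds sequences:
#' a 5' UTR, a CDS that begins with ATG, ends with a stop codon and has
#' length divisible by 3, and a 3' UTR. Each gene receives one or two
#' 3'-end isoforms (a fraction of genes get a second, shorter 3' end at a
#' planted position and usage fraction).
#'
#' @param config a [synth_config()].
#' @return list: `seqs` (list of DNAStringSets `utr5`, `cds`, `utr3`),
#'   `genes` (data.frame of planted per-gene values), `isoforms`
#'   (data.frame `gene`, `end_offset` from the UTR3 start, `fraction`).
#' @export
make_transcriptome <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  gene <- sprintf("gene%04d", seq_len(n))
  gc_bias <- stats::rbeta(n, 10, 10)  # centered on 0.5, sd ~0.11
  len5 <- .draw_len(n, config$length_laws$utr5)
  ncod <- .draw_len(n, config$length_laws$cds_codons)
  len3 <- .draw_len(n, config$length_laws$utr3)
  utr5 <- vapply(seq_len(n), function(i) .rand_dna(len5[i], gc_bias[i]), "")
  cds <- vapply(seq_len(n), function(i) .rand_cds(ncod[i], gc_bias[i]), "")
  utr3 <- vapply(seq_len(n), function(i) .rand_dna(len3[i], gc_bias[i]), "")
  seqs <- list(utr5 = Biostrings::DNAStringSet(stats::setNames(utr5, gene)),
               cds = Biostrings::DNAStringSet(stats::setNames(cds, gene)),
               utr3 = Biostrings::DNAStringSet(stats::setNames(utr3, gene)))
  ## 3'-end isoforms: 30% of genes carry a second, proximal end
  second <- stats::runif(n) < 0.3 & len3 >= 200
  prox_off <- pmax(60L, round(len3 * stats::runif(n, 0.3, 0.6)))
  prox_frac <- stats::runif(n, 0.15, 0.45)
  iso <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (second[i]) {
      data.frame(gene = gene[i], end_offset = c(prox_off[i], len3[i]),
                 fraction = c(prox_frac[i], 1 - prox_frac[i]))
    } else {
      data.frame(gene = gene[i], end_offset = len3[i], fraction = 1)
    }
  }))
  genes <- data.frame(gene = gene, gc_bias = gc_bias, len_utr5 = len5,
                      len_cds = ncod * 3L, len_utr3 = len3,
                      stringsAsFactors = FALSE)
  list(seqs = seqs, genes = genes, isoforms = iso)
}

#' Simulate per-tag intensity traces with planted tail lengths
#'
#' Each tag draws a true tail length L from the configured gamma law (or a
#' spike-in standard length), dwells geometrically in the initiation state
#' (following the generating HMM's own a11), spends exactly L cycles in the
#' poly(A) state (truncated at the trace length), and the remainder in the
#' non-poly(A) state. Per-cycle log T-signals are drawn from the state
#' Gaussians and back-computed into raw 4-channel intensities (the three
#' non-T channels fixed at 1.0 and the T channel at 3 exp(logT), with unit
#' channel norms) so that [compute_t_signal()] round-trips the sampled
#' values exactly. Read-2 base calls consistent with each tag's route are
#' generated alongside.
#'
#' @param config a [synth_config()].
#' @param transcriptome optional output of [make_transcriptome()]; used to
#'   attach tag 3'-coordinates at the planted isoform ends.
#' @param n_tags total mRNA tags (default `n_genes * mean_tags_per_gene`).
#' @param n_standard_tags spike-in tags to add (default 2000).
#' @return list: `traces` (list `tag_id`, `A`, `C`, `G`, `T` matrices),
#'   `seqs` (read-2 base calls), `truth` (data.frame `tag_id`, `gene`,
#'   `true_tail`, `planted_state2`, `coord`), `standard_map`.
#' @export
simulate_intensity_tags <- function(config, transcriptome = NULL,
                                    n_tags = NULL, n_standard_tags = 2000L) {
  set.seed(config$seed + 1L)
  if (config$trace_len < 1) stop("trace length must be >= 1")
  n_genes <- config$n_genes
  if (is.null(n_tags)) n_tags <- n_genes * config$mean_tags_per_gene
  expr_w <- stats::rlnorm(n_genes, 0, 1)
  gene_names <- sprintf("gene%04d", seq_len(n_genes))
  gene_of <- sample(gene_names, n_tags, replace = TRUE, prob = expr_w)
  law <- config$tail_length_law
  L <- round(stats::rgamma(n_tags, shape = law$shape,
                           scale = law$mean / law$shape))
  ## spike-in standards at fixed lengths
  std <- config$standards
  n_std <- round(n_standard_tags * std$input_fraction / sum(std$input_fraction))
  std_id <- rep(std$standard, n_std)
  L <- c(L, rep(std$length, n_std))
  gene_of <- c(gene_of, std_id)
  is_std <- c(rep(FALSE, n_tags), rep(TRUE, sum(n_std)))
  ntot <- length(L)
  tag_id <- sprintf("tag%06d", seq_len(ntot))

  p <- config$ghmm_truth
  dwell <- stats::rgeom(ntot, 1 - p$A[1, 1]) + 1L
  Tn <- config$trace_len
  s2_run <- pmin(pmax(Tn - dwell, 0L), L)
  ## build the state matrix
  states <- matrix(3L, ntot, Tn)
  col <- matrix(rep(seq_len(Tn), each = ntot), ntot, Tn)
  states[col <= dwell] <- 1L
  states[col > dwell & col <= dwell + L] <- 2L
  rm(col)
  logT <- matrix(stats::rnorm(ntot * Tn, p$mu[states],
                              sqrt(p$sigma2)[states]), ntot, Tn)
  rm(states)
  ones <- matrix(1, ntot, Tn)
  traces <- list(tag_id = tag_id, A = ones, C = ones, G = ones,
                 T = 3 * exp(logT))
  rm(logT)
  ## read-2 base calls: leading T run of the planted tail, then A/C/G
  seqs <- vapply(seq_len(ntot), function(i) {
    lead <- min(L[i], 40L)
    rest <- paste(sample(c("A", "C", "G"), 60 - lead, replace = TRUE),
                  collapse = "")
    paste0(strrep("T", lead), rest)
  }, "")
  ## 3'-end coordinate: planted isoform end +- 1 nt of jitter
  coord <- rep(NA_real_, ntot)
  if (!is.null(transcriptome)) {
    iso <- transcriptome$isoforms
    mrna_idx <- which(!is_std)
    for (g in unique(gene_of[mrna_idx])) {
      gi <- iso[iso$gene == g, , drop = FALSE]
      idx <- mrna_idx[gene_of[mrna_idx] == g]
      pick <- sample.int(nrow(gi), length(idx), replace = TRUE,
                         prob = gi$fraction)
      coord[idx] <- gi$end_offset[pick] +
        sample(-1:1, length(idx), replace = TRUE, prob = c(0.15, 0.7, 0.15))
    }
  }
  truth <- data.frame(tag_id = tag_id,
                      gene = ifelse(is_std, NA_character_, gene_of),
                      true_tail = as.integer(L),
                      planted_state2 = as.integer(s2_run), coord = coord,
                      stringsAsFactors = FALSE)
  list(traces = traces, seqs = seqs, truth = truth,
       standard_map = data.frame(tag_id = tag_id[is_std],
                                 standard = gene_of[is_std],
                                 stringsAsFactors = FALSE))
}

#' Simulate RPF and RNA-seq counts with a planted linear TE
#'
#' True log2 TE is a planted linear function of feature columns
#' (`te_effects`) plus Gaussian noise. RNA counts are negative binomial
#' with mean proportional to a log-normal expression level; RPF counts are
#' negative binomial with mean proportional to expression x 2^TE.
#' Dispersion below 1e-12 switches to the Poisson limit.
#'
#' @param config a [synth_config()].
#' @param features data.frame with a `gene` column and every column named
#'   in `config$te_effects`.
#' @param te_true optional externally supplied true log2 TE vector
#'   (overrides the linear construction).
#' @return list: `counts` (data.frame `gene`, `rna`, `rpf`), `te_true`,
#'   `expression`, `rna_lib`, `rpf_lib`.
#' @export
simulate_counts <- function(config, features, te_true = NULL) {
  set.seed(config$seed + 2L)
  if (config$nb_dispersion < 0) stop("negative NB dispersion")
  eff <- config$te_effects
  if (is.null(te_true)) {
    missing_cols <- setdiff(names(eff), colnames(features))
    if (length(missing_cols)) {
      stop("te_effects name columns absent from features: ",
           paste(missing_cols, collapse = ", "))
    }
    X <- as.matrix(features[, names(eff), drop = FALSE])
    te_true <- as.numeric(X %*% eff) +
      stats::rnorm(nrow(features), 0, config$noise_sd)
  }
  n <- nrow(features)
  expr <- stats::rlnorm(n, 0, 1.2)
  rna_mu <- expr / sum(expr) * config$library_size
  rpf_w <- expr * 2^te_true
  rpf_mu <- rpf_w / sum(rpf_w) * config$library_size
  draw <- function(mu) {
    if (config$nb_dispersion < 1e-12) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }
  counts <- data.frame(gene = features$gene, rna = draw(rna_mu),
                       rpf = draw(rpf_mu), stringsAsFactors = FALSE)
  list(counts = counts, te_true = te_true, expression = expr,
       rna_lib = config$library_size, rpf_lib = config$library_size)
}

#' Simulate a miRNA-induction fold-change experiment
#'
#' Every gene's baseline log2 fold change carries the planted 3'-UTR-length
#' confound (`confound_slope` x log10 length) plus noise; genes with a
#' seed-match site additionally receive the planted site-type repression on
#' both RNA and RPF (the default scenario plants repression at the mRNA
#' level with no independent TE effect, so RPF changes mirror RNA changes).
#' The planted tail change is zero for all genes unless `tail_effect` is
#' supplied.
#'
#' @param config a [synth_config()].
#' @param site_labels character/factor of site types per gene (levels of
#'   [classify_sites()]).
#' @param utr3_length numeric vector of 3'-UTR lengths per gene.
#' @param tail_effect optional named vector of tail changes (nt) per site
#'   type; default all zero.
#' @return data.frame: `gene`, `site`, `utr3_length`, `rna_fc`, `rpf_fc`,
#'   `tail_change`; planted effects in attribute `truth`.
#' @export
simulate_mirna_experiment <- function(config, site_labels, utr3_length,
                                      tail_effect = NULL) {
  set.seed(config$seed + 3L)
  site_labels <- as.character(site_labels)
  known <- c("none", names(config$repression_by_site))
  if (any(!site_labels %in% known)) {
    stop("unknown site label(s): ",
         paste(setdiff(unique(site_labels), known), collapse = ", "))
  }
  n <- length(site_labels)
  stopifnot(length(utr3_length) == n)
  base <- config$confound_slope * log10(utr3_length) +
    stats::rnorm(n, 0, config$fc_noise_sd)
  repr <- ifelse(site_labels == "none", 0,
                 config$repression_by_site[site_labels])
  rna_fc <- base + repr
  rpf_fc <- rna_fc + stats::rnorm(n, 0, config$te_fc_noise_sd)
  tail_mu <- if (is.null(tail_effect)) rep(0, n) else
    ifelse(site_labels == "none", 0, tail_effect[site_labels])
  tail_change <- tail_mu + stats::rnorm(n, 0, config$tail_fc_noise_sd)
  out <- data.frame(gene = sprintf("gene%04d", seq_len(n)), site = site_labels,
                    utr3_length = utr3_length, rna_fc = rna_fc,
                    rpf_fc = rpf_fc, tail_change = tail_change,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(repression = config$repression_by_site,
                             confound_slope = config$confound_slope,
                             tail_effect = tail_mu)
  out
}

#' Simulate a replicated stimulation experiment
#'
#' Plants one of three tail-increase mechanisms (or none) per gene and
#' generates per-replicate gene mean tail lengths and poly(A)-tag counts
#' for a control and a stimulated cohort. Burst genes gain tail and
#' expression, short-tail-decay genes gain tail and lose expression,
#' cytoplasmic-polyadenylation genes gain tail at flat expression, and
#' "none" genes are flat in both.
#'
#' @param config a [synth_config()] (`n_replicates` >= 2).
#' @param n_genes optional override of the gene count.
#' @return list: `tail_control`, `tail_stim` (genes x replicates),
#'   `counts` (genes x 2*n_replicates), `condition`, `mechanism` (factor of
#'   planted labels), `baseline_tail`, `baseline_expr`.
#' @export
simulate_stimulation <- function(config, n_genes = NULL) {
  set.seed(config$seed + 4L)
  if (config$n_replicates < 2) stop("need >= 2 replicates per cohort")
  n <- if (is.null(n_genes)) config$n_genes else n_genes
  mech <- sample(names(config$mechanism_fractions), n, replace = TRUE,
                 prob = config$mechanism_fractions)
  law <- config$tail_length_law
  base_tail <- stats::rgamma(n, shape = law$shape, scale = law$mean / law$shape)
  base_expr <- stats::rlnorm(n, log(500), 1)
  dT <- ifelse(mech == "none", 0, config$stim_delta_tail)
  fold <- ifelse(mech == "burst", config$stim_fold,
                 ifelse(mech == "short-tail-decay", 1 / config$stim_fold, 1))
  R <- config$n_replicates
  rep_noise <- function() matrix(stats::rnorm(n * R, 0, config$replicate_tail_sd),
                                 n, R)
  tail_control <- base_tail + rep_noise()
  tail_stim <- base_tail + dT + rep_noise()
  draw <- function(mu) {
    m <- matrix(mu, n, R)
    if (config$nb_dispersion < 1e-12) matrix(stats::rpois(n * R, m), n, R)
    else matrix(stats::rnbinom(n * R, mu = m, size = 1 / config$nb_dispersion),
                n, R)
  }
  counts <- cbind(draw(base_expr), draw(base_expr * fold))
  gene <- sprintf("gene%04d", seq_len(n))
  rownames(tail_control) <- rownames(tail_stim) <- rownames(counts) <- gene
  colnames(counts) <- c(paste0("ctrl", seq_len(R)), paste0("stim", seq_len(R)))
  list(tail_control = tail_control, tail_stim = tail_stim, counts = counts,
       condition = factor(rep(c("control", "stimulated"), each = R),
                          levels = c("control", "stimulated")),
       mechanism = factor(mech, levels = c("none", "burst", "short-tail-decay",
                                           "cytoplasmic-polyadenylation")),
       baseline_tail = base_tail, baseline_expr = base_expr)
}
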