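test_that("configuration is validated", {
  expect_error(synth_config(n_genes = 0), "n_genes")
  expect_error(synth_config(nb_dispersion = -1), "dispersion")
  expect_error(synth_config(tail_length_law = list(dist = "gamma", mean = -5,
                                                   shape = 2)), "tail-length")
  expect_error(synth_config(length_laws = list(
    utr5 = list(meanlog = 1, sdlog = -1, min = 10),
    cds_codons = list(meanlog = 1, sdlog = 1, min = 10),
    utr3 = list(meanlog = 1, sdlog = 1, min = 10))), "length law")
  expect_error(synth_config(mechanism_fractions = c(none = 0.5)), "sum to 1")
})

test_that("transcriptome generation is deterministic and structurally valid", {
  cfg <- synth_config(seed = 91, n_genes = 500)
  tx <- make_transcriptome(cfg)
  expect_equal(length(tx$seqs$cds), 500)
  cds <- as.character(tx$seqs$cds)
  expect_true(all(substr(cds, 1, 3) == "ATG"))
  expect_true(all(nchar(cds) %% 3 == 0))
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  # no internal stops (sense-codon construction)
  f <- codon_frequencies(tx$seqs$cds)
  expect_equal(rowSums(f), rep(1, 500))
  # byte determinism
  tx2 <- make_transcriptome(cfg)
  expect_identical(as.character(tx$seqs$utr3), as.character(tx2$seqs$utr3))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_transcriptome_fasta(tx, f1); write_transcriptome_fasta(tx2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # isoform fractions sum to 1 per gene
  fr <- tapply(tx$isoforms$fraction, tx$isoforms$gene, sum)
  expect_equal(as.numeric(fr), rep(1, 500), tolerance = 1e-12)
})

test_that("planted tail lengths follow the configured gamma law", {
  cfg <- synth_config(seed = 92, n_genes = 50)
  tags <- simulate_intensity_tags(cfg, n_tags = 10000, n_standard_tags = 0)
  expect_equal(mean(tags$truth$true_tail), 90, tolerance = 3 / 90)
  expect_true(all(tags$truth$true_tail >= 0))
  # standards appear at their exact planted lengths
  tags2 <- simulate_intensity_tags(cfg, n_tags = 100, n_standard_tags = 400)
  stds <- merge(tags2$truth, tags2$standard_map)
  expect_setequal(unique(stds$true_tail), cfg$standards$length)
  expect_error(simulate_intensity_tags(synth_config(trace_len = 0)),
               "trace length")
})

test_that("counts follow the planted TE in the Poisson limit", {
  set.seed(93)
  feats <- data.frame(gene = sprintf("g%03d", 1:300),
                      gc_cds = rbeta(300, 10, 10),
                      log_len_cds = rnorm(300, 3, 0.2),
                      utr3_mfe_per_nt = rnorm(300, -0.2, 0.05))
  cfg <- synth_config(seed = 93, noise_sd = 0, nb_dispersion = 0,
                      library_size = 5e7)
  sim <- simulate_counts(cfg, feats)
  # noise_sd = 0: TE_true is exactly the linear predictor
  X <- as.matrix(feats[, names(cfg$te_effects)])
  expect_equal(sim$te_true, as.numeric(X %*% cfg$te_effects))
  # NB -> Poisson limit: observed log2 RPF/RNA ratio tracks TE_true
  ok <- sim$counts$rna > 500 & sim$counts$rpf > 500
  ratio <- log2(sim$counts$rpf[ok] / sim$counts$rna[ok])
  centered <- ratio - mean(ratio)
  expect_gt(cor(centered, sim$te_true[ok]), 0.99)
  # seed determinism
  sim2 <- simulate_counts(cfg, feats)
  expect_identical(sim$counts, sim2$counts)
  expect_error(simulate_counts(synth_config(nb_dispersion = -0.1), feats),
               "dispersion")
  expect_error(simulate_counts(cfg, feats[, 1:2, drop = FALSE]), "absent")
})

test_that("miRNA simulation plants repression, confound, and null tail change", {
  cfg <- synth_config(seed = 94, confound_slope = -0.1)
  n <- 2000
  set.seed(94)
  site <- sample(c("none", "8mer"), n, TRUE, prob = c(0.7, 0.3))
  len <- round(10^runif(n, 2, 3.5))
  sim <- simulate_mirna_experiment(cfg, site, len)
  ns <- sim$site == "none"
  # OLS on no-site genes recovers the planted confound slope
  sl <- coef(lm(sim$rna_fc[ns] ~ log10(len[ns])))[2]
  expect_lt(abs(unname(sl) + 0.1), 0.035)
  # planted repression appears on top of the confound
  m8 <- mean(sim$rna_fc[!ns]) -
    mean(-0.1 * log10(len[!ns]))
  expect_lt(abs(m8 + 0.4), 0.05)
  expect_lt(abs(mean(sim$tail_change)), 0.2)
  # all-none cohort carries no effect beyond the confound at its length
  sim0 <- simulate_mirna_experiment(cfg, rep("none", 500),
                                    rep(1000, 500))
  expect_lt(abs(mean(sim0$rna_fc) + 0.3), 0.05)  # slope*log10(1000)
  expect_error(simulate_mirna_experiment(cfg, c("none", "9mer"), c(100, 100)),
               "unknown site")
})

test_that("stimulation simulation plants the three mechanisms", {
  cfg <- synth_config(seed = 95, n_genes = 600)
  sim <- simulate_stimulation(cfg)
  cyto <- sim$mechanism == "cytoplasmic-polyadenylation"
  dmeans <- rowMeans(sim$tail_stim) - rowMeans(sim$tail_control)
  expect_equal(mean(dmeans[cyto]), cfg$stim_delta_tail, tolerance = 1)
  none <- sim$mechanism == "none"
  expect_equal(mean(dmeans[none]), 0, tolerance = 0.5)
  burst <- sim$mechanism == "burst"
  r <- rowMeans(sim$counts[burst, 5:8]) / rowMeans(sim$counts[burst, 1:4])
  expect_equal(median(r), cfg$stim_fold, tolerance = 0.1 * cfg$stim_fold)
  expect_error(simulate_stimulation(synth_config(n_replicates = 1)),
               ">= 2 replicates")
})

test_that("under a null stimulation the tail-test p-values are uniform", {
  cfg0 <- synth_config(seed = 96, n_genes = 1500,
                       mechanism_fractions = c(burst = 0, `short-tail-decay` = 0,
                                               `cytoplasmic-polyadenylation` = 0,
                                               none = 1))
  sim <- simulate_stimulation(cfg0)
  dt <- differential_tail(sim$tail_control, sim$tail_stim)
  ks <- ks.test(dt$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("trace, config, and parameter files round-trip", {
  cfg <- synth_config(seed = 97, n_genes = 3, trace_len = 40)
  tags <- simulate_intensity_tags(cfg, n_tags = 12, n_standard_tags = 0)
  f <- tempfile(fileext = ".tsv.gz")
  write_traces_tsv(tags$traces, f)
  back <- read_traces_tsv(f)
  ord <- match(tags$traces$tag_id, back$tag_id)
  expect_equal(back$T[ord, ], tags$traces$T, tolerance = 1e-9,
               ignore_attr = TRUE)
  # config YAML round trip preserves the generating parameters
  fy <- tempfile(fileext = ".yaml")
  write_synth_config(cfg, fy)
  cfg2 <- read_synth_config(fy)
  expect_equal(cfg2$ghmm_truth$A, cfg$ghmm_truth$A)
  expect_equal(cfg2$te_effects, cfg$te_effects)
  expect_equal(cfg2$seed, cfg$seed)
  # GHMM params JSON round trip
  fj <- tempfile(fileext = ".json")
  write_ghmm_json(cfg$ghmm_truth, fj)
  p2 <- read_ghmm_json(fj)
  expect_equal(p2$A, cfg$ghmm_truth$A)
  expect_equal(p2$mu, cfg$ghmm_truth$mu)
  # GTF and FASTA writers produce parseable files
  tx <- make_transcriptome(cfg)
  fg <- tempfile(fileext = ".gtf")
  write_transcriptome_gtf(tx, fg)
  gtf <- rtracklayer::import(fg)
  expect_true(all(c("exon", "CDS") %in% as.character(gtf$type)))
})
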