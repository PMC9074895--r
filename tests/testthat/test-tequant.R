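test_that("TE is log2 of RPF RPM over RNA RPM with the RNA RPM cutoff", {
  counts <- data.frame(gene = c("a", "b", "c", "d"),
                       rpf = c(200, 100, 50, 0),
                       rna = c(100, 100, 99, 200))
  te <- suppressWarnings(
    compute_te(counts, rpf_lib = 1e7, rna_lib = 1e7, rpm_cutoff = 10))
  expect_equal(te$te[te$gene == "a"], 1)      # RPF 20 RPM / RNA 10 RPM
  expect_equal(te$te[te$gene == "b"], 0)      # equal RPMs
  expect_false("c" %in% te$gene)              # RNA 9.9 RPM < 10
  expect_false("d" %in% te$gene)              # zero RPF -> undefined TE
  expect_warning(compute_te(counts, 1e7, 1e7), "zero RPF")
  # RPM conservation: sum(RPM) * lib/1e6 returns the total counts
  rpm <- counts$rna * 1e6 / 1e7
  expect_equal(sum(rpm) * 1e7 / 1e6, sum(counts$rna))
})

test_that("percentile range is median-centered and scale-invariant", {
  te <- rep(2.5, 150)
  expect_equal(percentile_range(te), 1)       # no spread -> 1-fold
  set.seed(51)
  te2 <- rnorm(500)
  expect_equal(percentile_range(te2), percentile_range(te2 + 7))
  expect_error(percentile_range(rnorm(50)), ">= 100")
  # constructed spread: P1..P99 spanning exactly 4 log2 units -> 16-fold
  te3 <- seq(-2, 2, length.out = 101)  # P1 = -1.96, P99 = 1.96 by interpolation
  q <- quantile(te3 - median(te3), c(0.01, 0.99), type = 7)
  expect_equal(percentile_range(te3), 2^(q[[2]] - q[[1]]))
})

test_that("lognormal TE with analytic 37-fold P99/P01 range is recovered", {
  # choose sigma so that the normal 1-99 percentile spread is log2(37)
  sigma <- log2(37) / (2 * qnorm(0.99))
  set.seed(52)
  est <- replicate(5, percentile_range(rnorm(5000, sd = sigma)))
  expect_equal(mean(est), 37, tolerance = 0.05)
})

test_that("codon frequencies count sense codons only", {
  cds <- Biostrings::DNAStringSet(c(g1 = "ATGGCCGCCTAA"))
  f <- codon_frequencies(cds)
  expect_equal(unname(f[1, "GCC"]), 2 / 3)    # stops excluded from the total
  expect_equal(unname(f[1, "ATG"]), 1 / 3)
  expect_equal(ncol(f), 61)
  expect_equal(sum(f[1, ]), 1)
  expect_error(codon_frequencies(Biostrings::DNAStringSet("ATGC")),
               "divisible by 3")
})

test_that("a planted codon-TE effect puts that codon at the top", {
  set.seed(53)
  cfg <- synth_config(seed = 53, n_genes = 300)
  tx <- make_transcriptome(cfg)
  f <- codon_frequencies(tx$seqs$cds)
  te1 <- 40 * f[, "GCC"] + rnorm(300, 0, 0.1)
  te2 <- 40 * f[, "GCC"] + rnorm(300, 0, 0.1)
  res <- codon_te_correlation(f, cbind(te1, te2))
  expect_equal(res$feature[1], "GCC")
  expect_gt(res$mean_r[1], 0.5)
  # constant TE: all defined correlations are NA/0-like
  res0 <- codon_te_correlation(f, matrix(rep(1, 300)))
  expect_true(all(is.na(res0$mean_r)))
  # amino-acid pooling keeps the contract
  resaa <- codon_te_correlation(f, cbind(te1, te2), level = "aa")
  expect_equal(resaa$feature[1], "A")         # GCC encodes alanine
})

test_that("RPF frame fractions sum to one and recover planted periodicity", {
  expect_equal(unname(rpf_periodicity(seq(0, 3000, by = 3))),
               c(1, 0, 0))
  set.seed(54)
  pos <- sample(0:2, 30000, replace = TRUE, prob = c(0.7, 0.2, 0.1)) +
    3 * sample(0:200, 30000, replace = TRUE)
  fr <- rpf_periodicity(pos)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr), c(0.7, 0.2, 0.1), tolerance = 0.02)
  expect_error(rpf_periodicity(1:10), ">= 1000")
})

test_that("A-site enrichment is flat under uniform occupancy and recovers planted dwell", {
  set.seed(55)
  cfg <- synth_config(seed = 55, n_genes = 80)
  tx <- make_transcriptome(cfg)
  cds <- tx$seqs$cds
  lens <- Biostrings::width(cds)
  # uniform codon positions
  n_reads <- 40000
  gidx <- sample(length(cds), n_reads, replace = TRUE)
  cpos <- floor(runif(n_reads) * (lens[gidx] / 3 - 1)) * 3
  rpf <- data.frame(gene = names(cds)[gidx], pos = cpos - 15)
  res <- asite_occupancy(rpf, cds)
  expect_equal(mean(res$enrichment$enrichment), 1, tolerance = 0.05)
  expect_true(max(abs(res$enrichment$enrichment - 1)) < 0.5)
  # planted 3x dwell at AGA
  codon_at <- substr(as.character(cds)[gidx], cpos + 1, cpos + 3)
  w <- ifelse(codon_at == "AGA", 3, 1)
  keep <- runif(n_reads) < w / 3
  res3 <- asite_occupancy(rpf[keep, ], cds)
  aga <- res3$enrichment$enrichment[res3$enrichment$codon == "AGA"]
  other <- mean(res3$enrichment$enrichment[res3$enrichment$codon != "AGA"])
  expect_equal(aga / other, 3, tolerance = 0.15)
  expect_error(asite_occupancy(rpf[1:5, ], cds), "insufficient")
})

test_that("tail-TE Spearman matches rank-then-Pearson and closed forms", {
  set.seed(56)
  tail <- runif(200); te <- tail^3  # perfectly monotone
  expect_equal(tail_te_correlation(tail, te)$rho, 1)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(tail_te_correlation(x, y)$rho,
               cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(tail_te_correlation(1:5, 1:5), ">= 10")
  # bivariate normal with rho = 0.2: population Spearman = 6/pi asin(rho/2)
  rho <- 0.2
  n <- 40000
  z <- matrix(rnorm(2 * n), ncol = 2)
  xy <- cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
  expected <- 6 / pi * asin(rho / 2)
  expect_lt(abs(tail_te_correlation(xy[, 1], xy[, 2])$rho - expected), 0.015)
})

test_that("subset permutation test is calibrated and detects coupled subsets", {
  set.seed(57)
  n <- 600
  z <- rnorm(n)
  tail <- z + rnorm(n, 0, 2)
  te <- z + rnorm(n, 0, 2)
  # null: random subsets give roughly uniform p
  ps <- replicate(40, {
    subset_correlation_test(tail, te, sample.int(n, 80), n_perm = 99)$p_value
  })
  expect_gt(mean(ps > 0.1), 0.5)
  expect_gt(min(ps), 0)
  # powered: pick the genes whose tail and TE ranks agree most
  agree <- -abs(rank(tail) - rank(te))
  coupled <- order(agree, decreasing = TRUE)[1:80]
  res <- subset_correlation_test(tail, te, coupled, n_perm = 199, seed = 3)
  expect_lt(res$p_value, 0.02)
  expect_error(subset_correlation_test(tail, te, 1:80, n_perm = 0), "positive")
  expect_error(subset_correlation_test(tail, te, 1:10), ">= 50")
})
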