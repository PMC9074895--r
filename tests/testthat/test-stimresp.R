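test_that("differential tail handles identical and degenerate cohorts", {
  ctrl <- matrix(c(80, 82, 79, 81), 1)
  res <- differential_tail(ctrl, ctrl)
  expect_equal(res$delta_tail, 0)
  expect_gt(res$p_value, 0.99)
  # both cohorts variance-free: exact-equality shortcut
  flat <- matrix(90, 2, 4)
  shifted <- flat + c(0, 5)
  res2 <- differential_tail(flat, shifted)
  expect_true(all(res2$degenerate))
  expect_equal(res2$p_value, c(1, 0))
  expect_equal(res2$delta_tail, c(0, 5))
  expect_error(differential_tail(matrix(1, 1, 1), matrix(1, 1, 4)),
               ">= 2 replicates")
})

test_that("Welch test has near-nominal type-I error and high power at the large planted effect", {
  set.seed(81)
  n <- 4000
  # null genes: same mean, replicate SD 4.5, n = 4 per cohort
  ctrl <- matrix(rnorm(n * 4, 90, 4.5), n)
  stim <- matrix(rnorm(n * 4, 90, 4.5), n)
  res <- differential_tail(ctrl, stim)
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.015)
  # planted +47.5 nt shift: essentially always detected
  stim2 <- matrix(rnorm(n * 4, 90 + 47.5, 4.5), n)
  res2 <- differential_tail(ctrl, stim2)
  expect_gte(mean(res2$p_value < 0.05 & res2$delta_tail > 0), 0.99)
})

test_that("NB stand-in reports exact-zero fold change for duplicated cohorts", {
  set.seed(82)
  counts <- matrix(rnbinom(200 * 4, mu = 300, size = 20), 200, 4)
  counts <- cbind(counts, counts)
  rownames(counts) <- sprintf("g%03d", 1:200)
  res <- differential_expression(counts, rep(c("a", "b"), each = 4))
  expect_equal(res$log2fc, rep(0, nrow(res)))
  expect_true(all(res$padj > 0.99))
})

test_that("NB stand-in detects a planted 16-fold induction", {
  set.seed(83)
  n <- 500
  mu <- rlnorm(n, log(300), 0.7)
  induced <- seq_len(n) <= 25
  fold <- ifelse(induced, 16, 1)
  c0 <- matrix(rnbinom(n * 4, mu = mu, size = 1 / 0.05), n)
  c1 <- matrix(rnbinom(n * 4, mu = mu * fold, size = 1 / 0.05), n)
  counts <- cbind(c0, c1); rownames(counts) <- sprintf("g%03d", 1:n)
  res <- differential_expression(counts, rep(c("ctrl", "stim"), each = 4))
  ind <- res$gene %in% rownames(counts)[induced]
  expect_equal(mean(res$log2fc[ind]), 4, tolerance = 0.15)
  expect_true(all(res$padj[ind] < 0.05))
})

test_that("NB stand-in keeps false discoveries at or below the nominal FDR on nulls", {
  set.seed(84)
  fdrs <- replicate(10, {
    n <- 800
    mu <- rlnorm(n, log(200), 0.8)
    counts <- matrix(rnbinom(n * 8, mu = mu, size = 1 / 0.05), n)
    rownames(counts) <- sprintf("g%03d", 1:n)
    res <- differential_expression(counts, rep(c("a", "b"), each = 4))
    mean(res$padj < 0.05)
  })
  expect_lte(mean(fdrs), 0.05)
})

test_that("mechanism classification is a pure rule over the two tests", {
  d <- classify_mechanism(
    delta_tail = c(20, 20, 20, -5, 20, 0),
    tail_p = c(0.01, 0.01, 0.01, 0.01, 0.2, 0.9),
    log2fc = c(3, -2, 0.1, 2, 3, 0),
    expr_padj = c(0.001, 0.001, 0.6, 0.001, 0.001, 0.9))
  expect_equal(as.character(d),
               c("burst", "short-tail-decay", "cytoplasmic-polyadenylation",
                 "none", "none", "none"))
  # purity: identical inputs give identical labels
  expect_identical(d, classify_mechanism(c(20, 20, 20, -5, 20, 0),
                                         c(0.01, 0.01, 0.01, 0.01, 0.2, 0.9),
                                         c(3, -2, 0.1, 2, 3, 0),
                                         c(0.001, 0.001, 0.6, 0.001, 0.001, 0.9)))
})

test_that("CPE-association uses Fisher's exact test with hypergeometric tails", {
  sym <- motif_association(rep(c(TRUE, FALSE), each = 20),
                           rep(c(TRUE, FALSE), 20))
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(sym$p_value, 1)
  # perfectly separated 5/5 table: p = 2/choose(10,5) = 2/252
  sep <- motif_association(rep(c(TRUE, FALSE), each = 5),
                           rep(c(TRUE, FALSE), each = 5))
  expect_equal(sep$p_value, 2 / 252, tolerance = 1e-12)
  # planted enrichment at n = 400: odds 1 vs 0.2, i.e. OR = 5
  set.seed(85)
  inc <- rep(c(TRUE, FALSE), each = 200)
  cpe <- runif(400) < ifelse(inc, 0.5, 1 / 6)
  res <- motif_association(inc, cpe)
  expect_gt(res$odds_ratio, 2)
  expect_lt(res$p_value, 0.05)
  expect_warning(motif_association(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
                 "empty margin")
})

test_that("CPE motifs are found in U-rich 3' UTRs", {
  utrs <- c("GGGTTTTATGGG", "GGGTTTTAATGGG", "GGGGGGG", "cccuuuuauccc")
  expect_equal(has_cpe(utrs), c(TRUE, TRUE, FALSE, TRUE))
})

test_that("short-tail depletion check flags a missing short-tail mode", {
  set.seed(88)
  ctrl <- c(rgamma(3000, 4, scale = 22.5))
  # stimulated: short-tailed isoforms removed below the control Q25
  cutoff <- quantile(ctrl, 0.25)
  stim <- ctrl[ctrl >= cutoff]
  res <- short_tail_depletion(ctrl, stim)
  expect_lt(res$stim_fraction, res$control_fraction)
  expect_lt(res$p_value, 1e-6)
  # identical cohorts show no depletion
  res0 <- short_tail_depletion(ctrl, ctrl)
  expect_equal(res0$control_fraction, res0$stim_fraction)
  expect_gt(res0$p_value, 0.99)
})

test_that("global tail summary bins at 2 nt, conserves tags, and tests cohorts", {
  set.seed(86)
  tails <- c(lapply(1:4, function(i) rgamma(2000, 4, scale = 22.5)),
             lapply(1:4, function(i) rgamma(2000, 4, scale = 22.5)))
  names(tails) <- c(paste0("c", 1:4), paste0("s", 1:4))
  treat <- rep(c("control", "stim"), each = 4)
  gs <- global_tail_summary(tails, treat)
  expect_gt(gs$anova_p, 0.05)
  expect_equal(sum(gs$histograms[[1]]$count), 2000)
  expect_equal(diff(gs$histograms[[1]]$mid[1:2]), 2)
  # planted +15 nt global shift is detected across 4 + 4 samples
  tails2 <- tails
  tails2[5:8] <- lapply(tails2[5:8], function(x) x + 15)
  gs2 <- global_tail_summary(tails2, treat)
  expect_lt(gs2$anova_p, 0.05)
  # identical cohorts: F = 0 handled as p = 1
  same <- tails[c(1:4, 1:4)]
  gs3 <- global_tail_summary(same, treat)
  expect_equal(gs3$anova_p, 1)
  expect_error(global_tail_summary(tails, rep("x", 8)), ">= 2 cohorts")
})

test_that("planted stimulation mechanisms are recovered end to end", {
  cfg <- synth_config(seed = 87, n_genes = 400)
  sim <- simulate_stimulation(cfg)
  dt <- differential_tail(sim$tail_control, sim$tail_stim)
  de <- differential_expression(sim$counts, sim$condition)
  ord <- match(rownames(sim$counts), de$gene)
  mech <- classify_mechanism(dt$delta_tail, dt$p_value,
                             de$log2fc[ord], de$padj[ord])
  acc <- mean(as.character(mech) == as.character(sim$mechanism))
  expect_gte(acc, 0.95)
  # directional checks on the planted classes
  cyto <- sim$mechanism == "cytoplasmic-polyadenylation"
  expect_equal(mean(dt$delta_tail[cyto]), cfg$stim_delta_tail, tolerance = 1)
  burst <- sim$mechanism == "burst"
  expect_equal(mean(de$log2fc[ord][burst]), log2(cfg$stim_fold),
               tolerance = 0.3)
})
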