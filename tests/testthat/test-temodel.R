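make_features <- function(n, seed = 71) {
  set.seed(seed)
  data.frame(
    tail_length = rgamma(n, 4, scale = 22.5),
    log_expression = rnorm(n, 1, 0.8),
    log_len_cds = rnorm(n, 3, 0.25),
    log_len_utr3 = rnorm(n, 2.8, 0.3),
    gc_cds = rbeta(n, 10, 10),
    region5_fe = rnorm(n, -30, 8))
}

test_that("feature table computes weighted means and per-nt energies", {
  seqs <- list(
    utr5 = Biostrings::DNAStringSet(c(g1 = strrep("A", 50))),
    cds = Biostrings::DNAStringSet(c(g1 = paste0("ATG", strrep("GCC", 98), "TAA"))),
    utr3 = Biostrings::DNAStringSet(c(g1 = strrep("AT", 200))))
  tails <- data.frame(gene = "g1", mean_tail = 85)
  expr <- data.frame(gene = "g1", expression = 100)
  fold <- data.frame(gene = "g1", utr3_mfe = -50, region5_fe = -20)
  iso <- data.frame(gene = "g1", utr3_length = c(200, 400),
                    utr3_mfe = c(-40, -80), expression = c(3, 1))
  ft <- build_feature_table(seqs, tails, expr, fold, isoforms = iso)
  # 3:1 expression weighting of 200/400-nt isoforms -> 250 nt
  expect_equal(10^ft$log_len_utr3, 250)
  expect_equal(ft$utr3_mfe_per_nt, 0.75 * (-40 / 200) + 0.25 * (-80 / 400))
  # single-isoform fallback: -50 kcal/mol over 400 nt = -0.125/nt
  ft2 <- build_feature_table(seqs, tails, expr, fold)
  expect_equal(ft2$utr3_mfe_per_nt, -50 / 400)
  expect_equal(ft2$gc_cds, (98 * 3 + 1) / 300)  # GCC contributes 3 G/C each
})

test_that("sub-feature model is perfect in the noiseless limit and null otherwise", {
  set.seed(72)
  n <- 400
  X <- matrix(rnorm(n * 20), n, 20)
  beta <- rnorm(20)
  te <- as.numeric(X %*% beta) + 2
  tr <- sample.int(n, 300)
  pred <- fit_subfeature_model(X, te, tr)
  heldout <- setdiff(seq_len(n), tr)
  r2 <- 1 - sum((te[heldout] - pred[heldout])^2) / sum((te[heldout] - mean(te[heldout]))^2)
  expect_equal(r2, 1, tolerance = 1e-9)
  # TE independent of the sub-features: held-out R^2 near zero
  te0 <- rnorm(n)
  pred0 <- fit_subfeature_model(X, te0, tr)
  r20 <- 1 - sum((te0[heldout] - pred0[heldout])^2) /
    sum((te0[heldout] - mean(te0[heldout]))^2)
  expect_lt(abs(r20), 0.35)
  # permuted training labels destroy the fit
  predp <- fit_subfeature_model(X, sample(te), tr)
  r2p <- 1 - sum((te[heldout] - predp[heldout])^2) /
    sum((te[heldout] - mean(te[heldout]))^2)
  expect_lt(r2p, 0.3)
  # rank deficiency falls back to ridge
  Xdup <- cbind(X, X[, 1])
  expect_message(fit_subfeature_model(Xdup, te, tr), "rank deficient")
})

test_that("forward AIC selection finds the informative feature and stops on noise", {
  set.seed(73)
  n <- 2000
  feats <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  colnames(feats) <- c("signal", paste0("noise", 1:9))
  te <- 2 * feats$signal + rnorm(n)
  sel <- stepwise_select(feats, te)
  expect_equal(sel[1], "signal")
  expect_lt(length(sel), 9)
  # pure noise: the AIC guard stops almost immediately
  sel0 <- stepwise_select(feats, rnorm(n))
  expect_lte(length(sel0), 2)
  # duplicated feature enters only once
  feats$signal_copy <- feats$signal
  sel2 <- stepwise_select(feats, te)
  expect_equal(sum(sel2 %in% c("signal", "signal_copy")), 1)
  expect_error(stepwise_select(feats[, 1, drop = FALSE], te), ">= 2")
})

test_that("selection order agrees with MASS::stepAIC forward selection", {
  skip_if_not_installed("MASS")
  set.seed(74)
  n <- 500
  feats <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  te <- 1.5 * feats$a + 0.8 * feats$c + rnorm(n)
  sel <- stepwise_select(feats, te)
  df <- data.frame(te = te, feats)
  ms <- MASS::stepAIC(lm(te ~ 1, data = df), direction = "forward",
                      scope = list(upper = ~ a + b + c + d), trace = 0)
  expect_setequal(sel, attr(terms(ms), "term.labels"))
})

test_that("round-2 filter drops weak features but always keeps the forced one", {
  set.seed(75)
  n <- 3000
  feats <- make_features(n, seed = 75)
  feats$weak <- rnorm(n)
  te <- 1.2 * feats$gc_cds * 10 + 0.5 * feats$log_len_cds +
    0.02 * feats$weak + rnorm(n, 0, 1)
  r1 <- stepwise_select(feats, te)
  final <- filter_and_refit(feats, te, r1, delta_r2 = 0.003,
                            forced = "tail_length")
  expect_true("tail_length" %in% final)
  dt <- attr(final, "delta_table")
  expected_menu <- union(dt$feature[dt$delta_adj_r2 >= 0.003], "tail_length")
  expect_setequal(attr(final, "menu"), expected_menu)
  expect_error(filter_and_refit(feats, te, r1, forced = "absent_feature"),
               "missing")
  # delta_r2 = 0 keeps the whole round-1 list in the menu
  final0 <- filter_and_refit(feats, te, r1, delta_r2 = 0)
  expect_setequal(setdiff(attr(final0, "menu"), "tail_length"),
                  as.character(r1))
})

test_that("bootstrap evaluation is near-perfect for noiseless linear TE and deterministic", {
  set.seed(76)
  n <- 600
  feats <- make_features(n, seed = 76)
  te <- 0.3 * feats$tail_length / 20 + 0.8 * feats$gc_cds * 5 - 0.1 * feats$region5_fe
  sel <- c("gc_cds", "region5_fe", "tail_length")
  fit <- evaluate_model(feats, te, sel, n_boot = 20, seed = 7)
  expect_equal(fit$mean_r2, 1, tolerance = 1e-9)
  expect_true(all(diff(fit$cumulative$mean_cum_r2) >= -1e-9))
  fit2 <- evaluate_model(feats, te, sel, n_boot = 20, seed = 7)
  expect_identical(fit$cumulative, fit2$cumulative)
  expect_error(evaluate_model(feats, te, sel, n_boot = 1), ">= 2")
  expect_error(evaluate_model(feats, te, sel, n_boot = 5, split_fraction = 1),
               "degenerate")
})

test_that("feature correlation matrix is symmetric with unit diagonal", {
  set.seed(77)
  n <- 5000
  f <- data.frame(a = rnorm(n), b = rnorm(n))
  f$c_cor <- f$a * 0.7 + rnorm(n, 0, 0.7)  # planted positive correlation
  f$const <- 1
  r <- feature_correlation_matrix(f)
  expect_equal(r["a", "a"], 1)
  expect_equal(r, t(r))
  expect_lt(abs(r["a", "b"]), 0.05)        # independent features
  expect_gt(r["a", "c_cor"], 0.5)          # planted sign recovered
  expect_true(all(is.na(r["const", ])))
  expect_error(feature_correlation_matrix(f[, 1, drop = FALSE]), ">= 2")
})

test_that("training-set cumulative R^2 is monotone along the stepwise path", {
  set.seed(78)
  n <- 1000
  feats <- make_features(n, seed = 78)
  te <- 3 * feats$gc_cds + 0.4 * feats$log_len_utr3 + rnorm(n, 0, 0.5)
  sel <- stepwise_select(feats, te)
  tr <- attr(sel, "trace")
  expect_true(all(diff(tr$cum_r2) >= -1e-12))
})
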