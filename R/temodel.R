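#' Build the per-gene feature table for TE modeling
#'
#' Assembles simple sequence features per gene: log10 lengths of the 5'
#' UTR, CDS, and 3' UTR; log10 mRNA expression; GC content of each region;
#' mean poly(A)-tail length; 3'-UTR minimum free energy normalized per nt;
#' and the predicted folding energy of the 5' region (5' UTR plus first
#' 35 nt of CDS), which is supplied precomputed. For genes with multiple
#' 3'-end isoforms, 3'-UTR length and folding energy are expression-weighted
#' means across isoforms.
#'
#' @param seqs list of [Biostrings::DNAStringSet]s named `utr5`, `cds`,
#'   `utr3`, each named by gene.
#' @param tail_means data.frame `gene`, `mean_tail` (e.g. from
#'   [aggregate_gene_tails()]).
#' @param expression data.frame `gene`, `expression` (linear scale).
#' @param folding data.frame `gene`, `utr3_mfe` (kcal/mol, whole UTR),
#'   `region5_fe` (kcal/mol, precomputed 5'-region folding energy).
#' @param isoforms optional data.frame `gene`, `utr3_length`, `utr3_mfe`,
#'   `expression` giving per-isoform values; when present, per-gene 3'-UTR
#'   length and MFE-per-nt override the single-isoform values.
#' @return data.frame, one row per gene present in all inputs, with columns
#'   `gene`, `tail_length`, `log_expression`, `log_len_utr5`, `log_len_cds`,
#'   `log_len_utr3`, `gc_utr5`, `gc_cds`, `gc_utr3`, `utr3_mfe_per_nt`,
#'   `region5_fe`.
#' @export
build_feature_table <- function(seqs, tail_means, expression, folding,
                                isoforms = NULL) {
  genes <- Reduce(intersect, list(names(seqs$utr5), names(seqs$cds),
                                  names(seqs$utr3), tail_means$gene,
                                  expression$gene, folding$gene))
  gc <- function(ss) {
    f <- Biostrings::letterFrequency(ss, c("G", "C"))
    rowSums(f) / pmax(Biostrings::width(ss), 1)
  }
  len_utr3 <- Biostrings::width(seqs$utr3)[match(genes, names(seqs$utr3))]
  mfe <- folding$utr3_mfe[match(genes, folding$gene)]
  mfe_per_nt <- mfe / len_utr3
  if (!is.null(isoforms)) {
    agg <- do.call(rbind, lapply(split(isoforms, isoforms$gene), function(g) {
      w <- g$expression / sum(g$expression)
      data.frame(gene = g$gene[1],
                 utr3_length = sum(w * g$utr3_length),
                 utr3_mfe_per_nt = sum(w * g$utr3_mfe / g$utr3_length))
    }))
    hit <- match(genes, agg$gene)
    repl <- !is.na(hit)
    len_utr3[repl] <- agg$utr3_length[hit[repl]]
    mfe_per_nt[repl] <- agg$utr3_mfe_per_nt[hit[repl]]
  }
  data.frame(
    gene = genes,
    tail_length = tail_means$mean_tail[match(genes, tail_means$gene)],
    log_expression = log10(expression$expression[match(genes, expression$gene)]),
    log_len_utr5 = log10(Biostrings::width(seqs$utr5)[match(genes, names(seqs$utr5))]),
    log_len_cds = log10(Biostrings::width(seqs$cds)[match(genes, names(seqs$cds))]),
    log_len_utr3 = log10(len_utr3),
    gc_utr5 = gc(seqs$utr5[match(genes, names(seqs$utr5))]),
    gc_cds = gc(seqs$cds[match(genes, names(seqs$cds))]),
    gc_utr3 = gc(seqs$utr3[match(genes, names(seqs$utr3))]),
    utr3_mfe_per_nt = mfe_per_nt,
    region5_fe = folding$region5_fe[match(genes, folding$gene)],
    stringsAsFactors = FALSE)
}

#' Fit a complex sub-feature model
#'
#' Trains a linear model of TE on a matrix of sub-features (e.g. the 61
#' codon frequencies, or 5'-UTR 6-mer counts) using training rows only, and
#' returns its predictions for all genes as a single scalar column for use
#' in the full model. Rank-deficient or wide (p >= n) designs fall back to
#' ridge regression with the penalty chosen by 5-fold cross-validation on
#' the training rows, so the complex feature cannot interpolate its own
#' training data; a fixed penalty can be supplied instead.
#'
#' @param X numeric matrix of sub-features (genes x sub-features).
#' @param te numeric vector of log2 TE values.
#' @param train integer/logical index of training genes.
#' @param ridge ridge penalty; 0 = OLS, with automatic CV-ridge fallback
#'   for rank-deficient or wide designs.
#' @return numeric vector of predictions for all genes, with attributes
#'   `coef` and `ridge_used`.
#' @export
fit_subfeature_model <- function(X, te, train, ridge = 0, crossfit = TRUE,
                                 n_folds = 5L) {
  X <- as.matrix(X)
  if (is.logical(train)) train <- which(train)
  n <- length(train)
  p <- ncol(X)

  ## fit a (ridge) linear model on the given rows; dual form when wide
  fit_once <- function(rows, lambda) {
    Xtr <- X[rows, , drop = FALSE]
    ctr <- colMeans(Xtr)
    Xc <- sweep(Xtr, 2, ctr)
    yc <- te[rows] - mean(te[rows])
    m <- nrow(Xc)
    if (lambda > 0 && p > m) {
      beta <- crossprod(Xc, solve(tcrossprod(Xc) + diag(lambda * m, m), yc))
    } else {
      XtX <- crossprod(Xc)
      if (lambda > 0) diag(XtX) <- diag(XtX) + lambda * m
      beta <- solve(XtX, crossprod(Xc, yc))
    }
    list(beta = beta, ctr = ctr, mu = mean(te[rows]))
  }
  predict_once <- function(fit, rows) {
    as.numeric(sweep(X[rows, , drop = FALSE], 2, fit$ctr) %*% fit$beta) +
      fit$mu
  }

  folds <- rep_len(seq_len(n_folds), n)[sample.int(n)]
  oof <- function(lambda) {
    out <- numeric(n)
    for (f in seq_len(n_folds)) {
      fit <- fit_once(train[folds != f], lambda)
      out[folds == f] <- predict_once(fit, train[folds == f])
    }
    out
  }

  ridge_used <- ridge
  need_ridge <- ridge == 0 &&
    (p >= floor(n * (n_folds - 1) / n_folds) ||
       qr(sweep(X[train, , drop = FALSE], 2,
                colMeans(X[train, , drop = FALSE])))$rank < p)
  if (need_ridge) {
    message("sub-feature design is rank deficient or wide; ",
            "selecting a ridge penalty by cross-validation")
    scale0 <- mean(scale(X[train, , drop = FALSE], scale = FALSE)^2) * p
    grid <- scale0 / n * 10^seq(-4, 4, by = 0.5)
    cv <- vapply(grid, function(l) sum((te[train] - oof(l))^2), numeric(1))
    ridge_used <- grid[which.min(cv)]
  }

  full <- fit_once(train, ridge_used)
  pred <- predict_once(full, seq_len(nrow(X)))
  if (crossfit) {
    ## training rows carry out-of-fold predictions so the downstream
    ## stepwise selection never sees the sub-feature model's own
    ## training optimism (standard stacking practice)
    pred[train] <- oof(ridge_used)
  }
  attr(pred, "coef") <- as.numeric(full$beta)
  attr(pred, "ridge_used") <- ridge_used
  pred
}

## R^2 of an lm-style fit evaluated on given rows
.r2 <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

.fit_lm <- function(features, cols, te, rows) {
  df <- data.frame(te = te, features[, cols, drop = FALSE])[rows, , drop = FALSE]
  stats::lm(te ~ ., data = df)
}

.predict_lm <- function(fit, features, cols) {
  stats::predict(fit, newdata = features[, cols, drop = FALSE])
}

#' Forward stepwise feature selection by AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' feature whose inclusion most decreases the AIC of the Gaussian linear
#' model, stopping when no addition decreases it.
#'
#' @param features data.frame of candidate feature columns (>= 2).
#' @param te numeric vector of log2 TE values.
#' @param rows optional training-row index (default: all rows).
#' @return character vector of selected features in selection order, with
#'   attribute `trace` (data.frame `feature`, `aic`, `cum_r2` on the
#'   training rows).
#' @export
stepwise_select <- function(features, te, rows = seq_along(te)) {
  candidates <- colnames(features)
  if (length(candidates) < 2) stop("need >= 2 candidate features")
  if (is.logical(rows)) rows <- which(rows)
  selected <- character(0)
  df <- data.frame(te = te, features)[rows, , drop = FALSE]
  cur <- stats::lm(te ~ 1, data = df)
  cur_aic <- stats::AIC(cur)
  trace <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(f) {
      stats::AIC(stats::lm(stats::reformulate(c(selected, f), "te"), data = df))
    }, numeric(1))
    best <- names(which.min(aics))
    if (aics[best] >= cur_aic) break
    selected <- c(selected, best)
    cur_aic <- aics[best]
    fit <- stats::lm(stats::reformulate(selected, "te"), data = df)
    trace[[length(trace) + 1L]] <- data.frame(
      feature = best, aic = cur_aic, cum_r2 = summary(fit)$r.squared,
      stringsAsFactors = FALSE)
  }
  attr(selected, "trace") <- do.call(rbind, trace)
  selected
}

#' Filter round-1 features by incremental adjusted R-squared and refit
#'
#' Drops features whose sequential inclusion (in round-1 order) added less
#' than `delta_r2` to the adjusted R-squared, always retaining the features
#' in `forced` (kept for reporting interest even when uninformative), and
#' reruns stepwise selection on the reduced menu. Forced features absent
#' from the second-round AIC selection are appended at the end.
#'
#' @param features data.frame of candidate features.
#' @param te numeric vector of log2 TE values.
#' @param round1 character vector from [stepwise_select()].
#' @param delta_r2 minimum incremental adjusted R-squared (default 0.003).
#' @param forced character vector of always-retained features (default
#'   `"tail_length"`).
#' @param rows optional training-row index.
#' @return character vector: final selected features in round-2 order, with
#'   attributes `menu` (the reduced menu), `delta_table` (per-feature
#'   incremental adjusted R-squared from round 1) and `trace` from the
#'   second stepwise run.
#' @export
filter_and_refit <- function(features, te, round1, delta_r2 = 0.003,
                             forced = "tail_length", rows = seq_along(te)) {
  if (length(forced) && !all(forced %in% colnames(features))) {
    stop("forced feature(s) missing from the feature table: ",
         paste(setdiff(forced, colnames(features)), collapse = ", "))
  }
  if (is.logical(rows)) rows <- which(rows)
  df <- data.frame(te = te, features)[rows, , drop = FALSE]
  adj <- function(sel) {
    if (!length(sel)) return(0)
    summary(stats::lm(stats::reformulate(sel, "te"), data = df))$adj.r.squared
  }
  deltas <- numeric(length(round1))
  prev <- 0
  for (i in seq_along(round1)) {
    cur <- adj(round1[seq_len(i)])
    deltas[i] <- cur - prev
    prev <- cur
  }
  keep <- round1[deltas >= delta_r2]
  menu <- union(keep, intersect(forced, colnames(features)))
  if (length(menu) < 2) menu <- union(menu, round1[seq_len(min(2, length(round1)))])
  final <- stepwise_select(features[, menu, drop = FALSE], te, rows)
  tr <- attr(final, "trace")
  missing_forced <- setdiff(intersect(forced, menu), final)
  out <- c(as.character(final), missing_forced)
  attr(out, "menu") <- menu
  attr(out, "delta_table") <- data.frame(feature = round1, delta_adj_r2 = deltas,
                                         stringsAsFactors = FALSE)
  attr(out, "trace") <- tr
  out
}

#' Bootstrap evaluation of the final TE model
#'
#' Trains and evaluates the final model `n_boot` times, each time with a
#' fresh random assignment of genes to training and test sets. Complex
#' sub-feature columns listed in `subfeatures` are refit within each
#' resample's training split only, so the held-out R-squared is free of
#' leakage. Reports the mean and percentile confidence interval of the
#' held-out cumulative R-squared at each model step, per-feature standalone
#' held-out R-squared, and the sign of each feature's correlation with TE.
#'
#' @param features data.frame of feature columns (complex columns included).
#' @param te numeric vector of log2 TE values.
#' @param selected character vector of final features in model order.
#' @param subfeatures optional named list of sub-feature matrices; names
#'   must match columns of `features` that should be refit per resample.
#' @param n_boot number of resamples (>= 2).
#' @param split_fraction fraction of genes assigned to training.
#' @param seed RNG seed.
#' @param ridge named numeric vector of ridge penalties per sub-feature
#'   model (default 0 = OLS with fallback).
#' @return list of class `te_model_fit`: `selected`, `mean_r2` (final
#'   held-out mean), `train_r2` (mean training R-squared), `cumulative`
#'   (data.frame `feature`, `mean_cum_r2`, `ci_lo`, `ci_hi`), `standalone`
#'   (data.frame `feature`, `r2`, `sign`), `n_boot`.
#' @export
evaluate_model <- function(features, te, selected, subfeatures = NULL,
                           n_boot = 100L, split_fraction = 0.8, seed = NULL,
                           ridge = NULL) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- length(te)
  n_train <- round(split_fraction * n)
  if (n_train < 2 || n_train >= n) stop("degenerate train/test split")
  k <- length(selected)
  cum_r2 <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, selected))
  alone_r2 <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, selected))
  train_r2 <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    tr <- sample.int(n, n_train)
    te_idx <- setdiff(seq_len(n), tr)
    feats <- features
    for (nm in names(subfeatures)) {
      pen <- if (!is.null(ridge) && nm %in% names(ridge)) ridge[[nm]] else 0
      feats[[nm]] <- as.numeric(fit_subfeature_model(subfeatures[[nm]], te,
                                                     tr, ridge = pen))
    }
    for (j in seq_len(k)) {
      fit <- .fit_lm(feats, selected[seq_len(j)], te, tr)
      cum_r2[b, j] <- .r2(te[te_idx], .predict_lm(fit, feats[te_idx, , drop = FALSE],
                                                  selected[seq_len(j)]))
      fit1 <- .fit_lm(feats, selected[j], te, tr)
      alone_r2[b, j] <- .r2(te[te_idx], .predict_lm(fit1, feats[te_idx, , drop = FALSE],
                                                    selected[j]))
    }
    full <- .fit_lm(feats, selected, te, tr)
    train_r2[b] <- summary(full)$r.squared
  }
  signs <- vapply(selected, function(f) {
    sign(stats::cor(features[[f]], te, use = "complete.obs"))
  }, numeric(1))
  structure(list(
    selected = selected,
    mean_r2 = mean(cum_r2[, k]),
    train_r2 = mean(train_r2),
    cumulative = data.frame(
      feature = selected,
      mean_cum_r2 = colMeans(cum_r2),
      ci_lo = apply(cum_r2, 2, stats::quantile, 0.025),
      ci_hi = apply(cum_r2, 2, stats::quantile, 0.975),
      row.names = NULL, stringsAsFactors = FALSE),
    standalone = data.frame(
      feature = selected,
      r2 = colMeans(alone_r2),
      sign = signs,
      row.names = NULL, stringsAsFactors = FALSE),
    n_boot = n_boot), class = "te_model_fit")
}

#' @export
print.te_model_fit <- function(x, ...) {
  cat(sprintf("TE linear model: %d features, mean held-out R^2 = %.3f (%d resamples)\n",
              length(x$selected), x$mean_r2, x$n_boot))
  print(x$cumulative, digits = 3)
  invisible(x)
}

#' Pairwise Pearson correlations between selected features
#'
#' @param features data.frame or matrix of feature columns.
#' @return symmetric correlation matrix with unit diagonal; rows for
#'   constant features are `NA`.
#' @export
feature_correlation_matrix <- function(features) {
  m <- as.matrix(features)
  if (ncol(m) < 2) stop("need >= 2 features")
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r) <- ifelse(sds == 0, NA, 1)
  r
}

#' Two-round stepwise TE model, end to end
#'
#' Convenience driver: fits sub-feature models on a seeded training split,
#' runs round-1 stepwise AIC selection over the full menu, applies the
#' incremental adjusted-R-squared filter with forced retention of tail
#' length, reruns stepwise selection on the reduced menu, and bootstraps
#' the final model.
#'
#' @param features data.frame of simple feature columns (incl. `tail_length`).
#' @param te numeric vector of log2 TE values.
#' @param subfeatures named list of sub-feature matrices to be summarized
#'   into complex scalar features (entries become columns named by the
#'   list names).
#' @param delta_r2,forced,n_boot,split_fraction,seed,ridge see the
#'   individual operations.
#' @return a `te_model_fit` (see [evaluate_model()]) with extra elements
#'   `round1` and `final_menu`.
#' @export
fit_te_model <- function(features, te, subfeatures = NULL, delta_r2 = 0.003,
                         forced = "tail_length", n_boot = 100L,
                         split_fraction = 0.8, seed = 1L, ridge = NULL) {
  set.seed(seed)
  n <- length(te)
  tr <- sample.int(n, round(split_fraction * n))
  feats <- features
  for (nm in names(subfeatures)) {
    pen <- if (!is.null(ridge) && nm %in% names(ridge)) ridge[[nm]] else 0
    feats[[nm]] <- as.numeric(fit_subfeature_model(subfeatures[[nm]], te, tr,
                                                   ridge = pen))
  }
  round1 <- stepwise_select(feats[, setdiff(colnames(feats), "gene"),
                                  drop = FALSE], te, tr)
  final <- filter_and_refit(feats[, setdiff(colnames(feats), "gene"),
                                  drop = FALSE], te, round1,
                            delta_r2 = delta_r2, forced = forced, rows = tr)
  fit <- evaluate_model(feats, te, as.character(final),
                        subfeatures = subfeatures, n_boot = n_boot,
                        split_fraction = split_fraction, seed = seed + 1L,
                        ridge = ridge)
  fit$round1 <- as.character(round1)
  fit$final_menu <- attr(final, "menu")
  fit
}
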