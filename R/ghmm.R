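#' Gaussian hidden Markov model parameters
#'
#' Container for the left-to-right Gaussian HMM used to decode poly(A)-tail
#' segments from per-cycle log T-signal traces. The canonical 3-state
#' topology comprises an initiation state (1), a poly(A) state (2), and a
#' non-poly(A) state (3); the 5-state variant inserts transition states on
#' either side of the poly(A) segment. Transitions with probability zero are
#' structural: they encode the left-to-right topology and are preserved
#' exactly through training.
#'
#' @param pi numeric vector of initial-state probabilities (simplex).
#' @param A  row-stochastic transition matrix; zeros are structural.
#' @param mu numeric vector of per-state Gaussian emission means
#'   (log T-signal units).
#' @param sigma2 numeric vector of per-state emission variances (> 0).
#' @return An object of class `ghmm_params`.
#' @export
ghmm_params <- function(pi, A, mu, sigma2) {
  S <- length(pi)
  stopifnot(is.matrix(A), nrow(A) == S, ncol(A) == S,
            length(mu) == S, length(sigma2) == S)
  if (abs(sum(pi) - 1) > 1e-9) stop("initial-state probabilities must sum to 1")
  if (any(pi < 0) || any(A < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(A) - 1) > 1e-9)) stop("transition rows must sum to 1")
  if (any(sigma2 <= 0)) stop("emission variances must be positive")
  structure(list(n_states = S, pi = as.numeric(pi), A = unname(A),
                 mu = as.numeric(mu), sigma2 = as.numeric(sigma2)),
            class = "ghmm_params")
}

#' @export
print.ghmm_params <- function(x, ...) {
  cat(sprintf("Gaussian HMM with %d states\n", x$n_states))
  cat("pi:", signif(x$pi, 4), "\n")
  cat("transition matrix:\n"); print(signif(x$A, 4))
  cat("emission means:", signif(x$mu, 4), "\n")
  cat("emission variances:", signif(x$sigma2, 4), "\n")
  invisible(x)
}

#' Default GHMM initialization parameters
#'
#' Packaged initialization used before unsupervised training. The 3-state
#' emission means (100, 1, -1), variances (1, 0.25, 0.25) and initial-state
#' probabilities (0.998, 0.001, 0.001) follow the published protocol for
#' splinted-ligation tail profiling; the numeric transition entries are
#' package defaults chosen to give a short initiation dwell and tail dwells
#' of order 100 cycles. The 5-state variant (for the alternative sequencing
#' mode) uses an analogous left-to-right topology with transition states
#' flanking the poly(A) segment.
#'
#' @param mode `"palseq3"` for the 3-state model, `"tailseq5"` for 5 states.
#' @return A `ghmm_params` object.
#' @export
ghmm_params_default <- function(mode = c("palseq3", "tailseq5")) {
  mode <- match.arg(mode)
  if (mode == "palseq3") {
    A <- matrix(c(0.99, 0.01, 0,
                  0,    0.99, 0.01,
                  0,    0,    1), 3, 3, byrow = TRUE)
    ghmm_params(pi = c(0.998, 0.001, 0.001), A = A,
                mu = c(100, 1, -1), sigma2 = c(1, 0.25, 0.25))
  } else {
    A <- matrix(0, 5, 5)
    diag(A) <- c(0.99, 0.99, 0.5, 0.5, 1)
    A[cbind(1:4, 2:5)] <- 1 - diag(A)[1:4]
    ghmm_params(pi = c(0.996, 0.001, 0.001, 0.001, 0.001), A = A,
                mu = c(100, 1, 0.5, -0.5, -1),
                sigma2 = c(1, 0.25, 0.25, 0.25, 0.25))
  }
}

## row-wise log-sum-exp of an n x k matrix, guarding -Inf rows
.row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = FALSE))
  out <- mx + log(rowSums(exp(m - mx)))
  out[is.infinite(mx) & mx < 0] <- -Inf
  out
}

## n x S matrix of log emission densities for one cycle
.ghmm_log_emission <- function(x, params) {
  m <- vapply(seq_len(params$n_states), function(s) {
    stats::dnorm(x, params$mu[s], sqrt(params$sigma2[s]), log = TRUE)
  }, numeric(length(x)))
  matrix(m, ncol = params$n_states)
}

#' Simulate traces from the GHMM's own generative law
#'
#' Draws state paths from the Markov chain defined by `params` and emissions
#' from the per-state Gaussians. Used for parameter-recovery checks of
#' Baum-Welch training; the planted-tail simulator
#' ([simulate_intensity_tags()]) instead fixes the poly(A) dwell to a drawn
#' tail length.
#'
#' @param params a `ghmm_params` object.
#' @param n number of traces.
#' @param len trace length in cycles.
#' @param seed optional RNG seed.
#' @return list with `obs` (n x len matrix of log T-signal values) and
#'   `states` (n x len integer matrix).
#' @export
ghmm_simulate <- function(params, n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (len < 1) stop("trace length must be >= 1")
  S <- params$n_states
  states <- matrix(0L, n, len)
  states[, 1] <- sample.int(S, n, replace = TRUE, prob = params$pi)
  for (t in seq_len(len - 1L)) {
    cur <- states[, t]
    u <- stats::runif(n)
    cum <- t(apply(params$A, 1, cumsum))
    nxt <- integer(n)
    for (s in seq_len(S)) {
      idx <- cur == s
      if (any(idx)) nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    states[, t + 1L] <- nxt
  }
  obs <- matrix(stats::rnorm(n * len, mean = params$mu[states],
                             sd = sqrt(params$sigma2)[states]), n, len)
  list(obs = obs, states = states)
}

#' Forward-algorithm log-likelihood
#'
#' Computes per-trace log-likelihoods under the GHMM with the forward
#' algorithm in log space, vectorized across traces.
#'
#' @param obs numeric matrix, traces in rows, cycles in columns.
#' @param params a `ghmm_params` object.
#' @param details if `TRUE`, also return the full log-alpha array (n x S x T).
#' @return numeric vector of per-trace log-likelihoods, or a list with
#'   `loglik` and `logalpha` when `details = TRUE`.
#' @export
ghmm_forward <- function(obs, params, details = FALSE) {
  obs <- rbind(obs)
  if (any(!is.finite(obs))) stop("non-finite emission values in traces")
  n <- nrow(obs); Tn <- ncol(obs); S <- params$n_states
  logA <- log(params$A)
  la <- log(matrix(params$pi, n, S, byrow = TRUE)) + .ghmm_log_emission(obs[, 1], params)
  logalpha <- if (details) array(NA_real_, c(n, S, Tn)) else NULL
  if (details) logalpha[, , 1] <- la
  if (Tn > 1) for (t in 2:Tn) {
    e <- .ghmm_log_emission(obs[, t], params)
    la <- vapply(seq_len(S), function(s) {
      .row_logsumexp(la + matrix(logA[, s], n, S, byrow = TRUE))
    }, numeric(n)) + e
    la <- rbind(la)  # keep matrix shape at n = 1
    if (details) logalpha[, , t] <- la
  }
  ll <- .row_logsumexp(la)
  if (details) list(loglik = ll, logalpha = logalpha) else ll
}

## backward pass: n x S x T array of log-beta values
.ghmm_backward <- function(obs, params) {
  n <- nrow(obs); Tn <- ncol(obs); S <- params$n_states
  logA <- log(params$A)
  logbeta <- array(NA_real_, c(n, S, Tn))
  logbeta[, , Tn] <- 0
  if (Tn > 1) for (t in (Tn - 1L):1L) {
    e <- .ghmm_log_emission(obs[, t + 1L], params)
    nb <- rbind(logbeta[, , t + 1L])
    logbeta[, , t] <- vapply(seq_len(S), function(k) {
      .row_logsumexp(nb + e + matrix(logA[k, ], n, S, byrow = TRUE))
    }, numeric(n))
  }
  logbeta
}

#' Viterbi decoding of state paths
#'
#' Most-probable state path per trace, computed in log space and vectorized
#' across traces; traces are processed in chunks to bound the backpointer
#' memory. Ties in path score are broken toward the lower-numbered
#' (more 5') state, which is deterministic under the left-to-right topology.
#'
#' @param obs numeric matrix, traces in rows, cycles in columns.
#' @param params a `ghmm_params` object.
#' @param chunk_size traces decoded per block.
#' @return integer matrix of decoded states (same shape as `obs`).
#' @export
ghmm_viterbi <- function(obs, params, chunk_size = 20000L) {
  obs <- rbind(obs)
  if (any(!is.finite(obs))) stop("non-finite emission values in traces")
  n <- nrow(obs)
  out <- matrix(0L, n, ncol(obs))
  starts <- seq(1L, n, by = chunk_size)
  for (st in starts) {
    idx <- st:min(st + chunk_size - 1L, n)
    out[idx, ] <- .viterbi_block(obs[idx, , drop = FALSE], params)
  }
  out
}

.viterbi_block <- function(obs, params) {
  n <- nrow(obs); Tn <- ncol(obs); S <- params$n_states
  logA <- log(params$A)
  delta <- log(matrix(params$pi, n, S, byrow = TRUE)) +
    .ghmm_log_emission(obs[, 1], params)
  psi <- array(1L, c(n, S, Tn))
  if (Tn > 1) for (t in 2:Tn) {
    e <- .ghmm_log_emission(obs[, t], params)
    newdelta <- matrix(-Inf, n, S)
    for (s in seq_len(S)) {
      cand <- delta + matrix(logA[, s], n, S, byrow = TRUE)
      best <- max.col(cand, ties.method = "first")
      newdelta[, s] <- cand[cbind(seq_len(n), best)] + e[, s]
      psi[, s, t] <- best
    }
    delta <- newdelta
  }
  path <- matrix(0L, n, Tn)
  path[, Tn] <- max.col(delta, ties.method = "first")
  if (Tn > 1) for (t in (Tn - 1L):1L) {
    path[, t] <- psi[cbind(seq_len(n), path[, t + 1L], t + 1L)]
  }
  path
}

#' Baum-Welch training of the GHMM
#'
#' Unsupervised maximum-likelihood estimation of initial, transition, and
#' Gaussian emission parameters by expectation-maximization. Structural
#' zeros of the transition matrix are preserved exactly (a zero expected
#' transition count keeps the entry at zero), rows remain stochastic, and
#' the total log-likelihood is non-decreasing across iterations. Training
#' tags are subsampled uniformly without replacement when more than
#' `n_train` traces are supplied.
#'
#' @param obs numeric matrix of log T-signal traces (rows = tags).
#' @param init a `ghmm_params` object used as the starting point.
#' @param n_train number of randomly selected tags to train on (default
#'   10000); all tags are used if fewer are available.
#' @param max_iter maximum EM iterations.
#' @param tol convergence tolerance on the change in total log-likelihood.
#' @param var_floor lower clamp for emission variances.
#' @param seed RNG seed for the training-tag subsample.
#' @return A `ghmm_params` object with attributes `loglik_trace` (per
#'   iteration) and `n_train`.
#' @export
ghmm_train <- function(obs, init, n_train = 10000L, max_iter = 100L,
                       tol = 1e-4, var_floor = 1e-6, seed = NULL) {
  obs <- rbind(obs)
  if (nrow(obs) == 0) stop("no traces supplied for training")
  if (!is.null(seed)) set.seed(seed)
  if (nrow(obs) > n_train) {
    obs <- obs[sample.int(nrow(obs), n_train), , drop = FALSE]
  }
  n <- nrow(obs); Tn <- ncol(obs); S <- init$n_states
  params <- init
  ll_trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    logA <- log(params$A)
    emis <- array(NA_real_, c(n, S, Tn))
    for (t in seq_len(Tn)) emis[, , t] <- .ghmm_log_emission(obs[, t], params)
    fwd <- ghmm_forward(obs, params, details = TRUE)
    logalpha <- fwd$logalpha
    logbeta <- .ghmm_backward(obs, params)
    ll <- sum(fwd$loglik)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(prev_ll) && ll + 1e-8 < prev_ll) {
      warning("log-likelihood decreased during Baum-Welch; stopping")
      break
    }
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol) break
    prev_ll <- ll

    ## posteriors
    gamma <- array(NA_real_, c(n, S, Tn))
    for (t in seq_len(Tn)) {
      g <- rbind(logalpha[, , t]) + rbind(logbeta[, , t]) - fwd$loglik
      gamma[, , t] <- exp(g)
    }
    pi_new <- colMeans(rbind(gamma[, , 1]))

    A_num <- matrix(0, S, S)
    if (Tn > 1) for (k in seq_len(S)) for (s in seq_len(S)) {
      if (params$A[k, s] == 0) next  # structural zero stays zero
      acc <- 0
      for (t in seq_len(Tn - 1L)) {
        acc <- acc + sum(exp(rbind(logalpha[, , t])[, k] + logA[k, s] +
                             rbind(emis[, , t + 1L])[, s] +
                             rbind(logbeta[, , t + 1L])[, s] - fwd$loglik))
      }
      A_num[k, s] <- acc
    }
    A_new <- A_num / pmax(rowSums(A_num), .Machine$double.xmin)
    ## absorbing rows with no outgoing mass keep their previous values
    empty <- rowSums(A_num) == 0
    A_new[empty, ] <- params$A[empty, ]

    mu_new <- numeric(S); s2_new <- numeric(S)
    for (s in seq_len(S)) {
      w <- rbind(gamma[, s, ])
      tot <- sum(w)
      mu_new[s] <- sum(w * obs) / tot
      s2_new[s] <- sum(w * (obs - mu_new[s])^2) / tot
    }
    clamped <- s2_new < var_floor
    if (any(clamped)) {
      warning("emission variance clamped to floor for state(s) ",
              paste(which(clamped), collapse = ", "))
      s2_new[clamped] <- var_floor
    }
    params <- ghmm_params(pi_new / sum(pi_new),
                          A_new / rowSums(A_new), mu_new, s2_new)
  }
  attr(params, "loglik_trace") <- ll_trace
  attr(params, "n_train") <- n
  params
}

#' Decode poly(A)-tail lengths from traces
#'
#' Viterbi-decodes each trace and reports the number of cycles spent in the
#' poly(A) state, which is the tail-length call for the tag. Posterior
#' decoding (per-cycle argmax of the state posterior) is available as an
#' alternative.
#'
#' @param obs numeric matrix of log T-signal traces.
#' @param params a trained `ghmm_params` object.
#' @param polyA_state index of the poly(A) state (2 in both topologies; in
#'   the 5-state variant only the pure poly(A) state is counted, the
#'   transition states absorb boundary blur).
#' @param method `"viterbi"` (default) or `"posterior"`.
#' @return integer vector of tail lengths (nt), one per trace.
#' @export
decode_tail_length <- function(obs, params, polyA_state = 2L,
                               method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  obs <- rbind(obs)
  if (method == "viterbi") {
    path <- ghmm_viterbi(obs, params)
    return(as.integer(rowSums(path == polyA_state)))
  }
  ## posterior decoding, chunked like Viterbi
  n <- nrow(obs)
  out <- integer(n)
  starts <- seq(1L, n, by = 20000L)
  for (st in starts) {
    idx <- st:min(st + 20000L - 1L, n)
    o <- obs[idx, , drop = FALSE]
    fwd <- ghmm_forward(o, params, details = TRUE)
    lb <- .ghmm_backward(o, params)
    Tn <- ncol(o)
    cnt <- integer(length(idx))
    for (t in seq_len(Tn)) {
      g <- rbind(fwd$logalpha[, , t]) + rbind(lb[, , t])
      cnt <- cnt + (max.col(g, ties.method = "first") == polyA_state)
    }
    out[idx] <- cnt
  }
  out
}
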