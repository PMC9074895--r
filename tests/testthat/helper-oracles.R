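# Independent brute-force oracles used to validate the implementations.
# These deliberately share no code with the package internals.

# Enumerate every state path with nonzero probability and return the total
# likelihood and the single best path (exhaustive alternative to the
# forward algorithm and Viterbi).
enumerate_paths <- function(obs, params) {
  S <- params$n_states
  Tn <- length(obs)
  emis <- function(s, t) dnorm(obs[t], params$mu[s], sqrt(params$sigma2[s]))
  best <- list(logp = -Inf, path = NULL)
  total <- 0
  recurse <- function(path, logp) {
    t <- length(path)
    if (t == Tn) {
      total <<- total + exp(logp)
      if (logp > best$logp) best <<- list(logp = logp, path = path)
      return(invisible())
    }
    for (s in seq_len(S)) {
      a <- params$A[path[t], s]
      if (a > 0) recurse(c(path, s), logp + log(a) + log(emis(s, t + 1)))
    }
  }
  for (s in seq_len(S)) {
    if (params$pi[s] > 0) {
      recurse(s, log(params$pi[s]) + log(emis(s, 1)))
    }
  }
  list(loglik = log(total), best_path = best$path, best_logp = best$logp)
}

# Reference greedy 3'-end caller written independently of annotate_ends().
brute_force_ends <- function(coord, count, halfwidth = 10, min_fraction = 0.10) {
  total <- sum(count)
  res <- NULL
  while (length(coord) > 0) {
    mx <- max(count)
    peak <- min(coord[count == mx])  # 5'-most on ties
    sel <- abs(coord - peak) <= halfwidth
    res <- rbind(res, data.frame(coord = peak, count = sum(count[sel])))
    coord <- coord[!sel]; count <- count[!sel]
  }
  res$fraction <- res$count / total
  res$retained <- res$fraction >= min_fraction
  res
}

# Reference seed-match scanner: checks every UTR position explicitly.
brute_force_site <- function(utr, mirna) {
  mir <- chartr("Uu", "Tt", toupper(mirna))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  s6 <- rc(substr(mir, 2, 7)); s7 <- rc(substr(mir, 2, 8))
  found <- c("8mer" = FALSE, "7mer-m8" = FALSE, "7mer-A1" = FALSE,
             "6mer" = FALSE)
  n <- nchar(utr)
  for (i in seq_len(max(0, n - 5))) {
    w6 <- substr(utr, i, i + 5)
    if (w6 == s6) {
      found["6mer"] <- TRUE
      if (substr(utr, i + 6, i + 6) == "A") found["7mer-A1"] <- TRUE
    }
    w7 <- substr(utr, i, i + 6)
    if (w7 == s7) {
      found["7mer-m8"] <- TRUE
      if (substr(utr, i + 7, i + 7) == "A") found["8mer"] <- TRUE
    }
  }
  hier <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
  hit <- hier[found[hier]]
  if (length(hit)) hit[1] else "none"
}
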