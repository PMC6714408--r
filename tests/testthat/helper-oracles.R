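# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by enumeration or naive definitions, never by calling
# the code paths they check.

# Exhaustive enumeration of all 5^n state paths: returns the maximum joint
# log probability. Paths are tracked explicitly; the HMM recursions of
# viterbi_decode() are not used.
enumerate_best_logp <- function(signals, model) {
  n <- nrow(signals)
  emis <- matrix(0, n, 5)
  for (i in seq_len(n))
    for (s in 0:4)
      emis[i, s + 1L] <- emission_loglik(signals$lrr[i], signals$baf[i],
                                         signals$pfb[i], s, model)
  p0 <- rep((1 - model$start_cn2_prob) / 4, 5); p0[3] <- model$start_cn2_prob
  scores <- log(p0) + emis[1, ]
  last <- 1:5
  if (n > 1) {
    for (t in 2:n) {
      d <- signals$position[t] - signals$position[t - 1L]
      off <- model$base_transition_prob * (1 - exp(-d / model$distance_scale_d))
      lt <- matrix(off / 4, 5, 5); diag(lt) <- 1 - off; lt <- log(lt)
      m <- scores + lt[last, , drop = FALSE] +
        matrix(emis[t, ], nrow = length(scores), ncol = 5, byrow = TRUE)
      scores <- as.vector(t(m))
      last <- rep(1:5, times = nrow(m))
    }
  }
  max(scores)
}

# Random probe signals for small HMM instances.
random_signals <- function(n) {
  data.frame(name = paste0("p", seq_len(n)),
             position = cumsum(sample(500:50000, n, replace = TRUE)),
             lrr = stats::rnorm(n, 0, 1),
             baf = stats::runif(n),
             pfb = stats::runif(n))
}

# Exact HWE by direct enumeration with choose() products (no log-gamma):
# unnormalized weight of h heterozygotes given n genotypes and na minor
# alleles is choose(n, h) * choose(n - h, (na - h) / 2) * 2^h.
hwe_enum_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  na <- nAa + 2 * naa
  if (na > n) return(hwe_enum_p(naa, nAa, nAA))
  if (n == 0 || na == 0) return(1)
  hets <- seq(na %% 2, na, by = 2)
  w <- vapply(hets, function(h) {
    choose(n, h) * choose(n - h, (na - h) / 2) * 2^h
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Benjamini-Hochberg by naive definition: largest rank i with
# p_(i) <= q i / m declares all p up to p_(i) significant; adjusted value
# is min over j >= i of m p_(j) / j.
bh_brute <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thr <- q * seq_len(m) / m
  k <- suppressWarnings(max(which(ps <= thr)))
  sig <- if (is.finite(k)) p <= ps[k] else rep(FALSE, m)
  adj_sorted <- vapply(seq_len(m), function(i)
    min(m * ps[i:m] / (i:m)), numeric(1))
  adj <- numeric(m); adj[o] <- pmin(adj_sorted, 1)
  list(significant = sig, adjusted = adj)
}

# Reference Newton-Raphson IRLS for logistic regression, written from the
# likelihood equations.
irls_reference <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    delta <- solve(crossprod(X * W, X), crossprod(X, y - mu))
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  beta
}

# Small deterministic probe map on one chromosome.
test_probe_map <- function(n = 60, chromosome = "2", start = 1e6,
                           spacing = 1000, pfb = NULL) {
  if (is.null(pfb)) { set.seed(424242); pfb <- stats::runif(n, 0.2, 0.8) }
  data.frame(name = sprintf("rs%04d", seq_len(n)), chromosome = chromosome,
             position = seq(start, by = spacing, length.out = n), pfb = pfb,
             stringsAsFactors = FALSE)
}

# Simulated carrier copy-number column under Hardy-Weinberg at carrier
# frequency f.
random_cn_column <- function(n, f = 0.056) {
  q <- 1 - sqrt(1 - f)
  a <- stats::rbinom(n, 2, q)
  ifelse(a >= 1, 2L - pmin(a, 2L), 2L)
}

empty_calls_for_test <- function() {
  data.frame(sample_id = character(0), chromosome = character(0),
             start = numeric(0), end = numeric(0),
             copy_number = integer(0), num_snps = integer(0),
             start_probe = character(0), end_probe = character(0),
             stringsAsFactors = FALSE)
}
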