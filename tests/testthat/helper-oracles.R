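# Independent brute-force oracles: explicit loops, no shared code with the
# package implementation. Used to freeze expected values and in equivalence
# tests.

random_cm <- function(G = 50, m = 4, seed = 1, max_count = 400) {
  set.seed(seed)
  k <- matrix(rnbinom(G * m, size = 2, mu = runif(G, 5, max_count)), G, m)
  rownames(k) <- paste0("g", seq_len(G))
  colnames(k) <- paste0("s", seq_len(m))
  count_matrix(k, group = rep(c("A", "B"), length.out = m))
}

# tie-averaged rank of x[i] computed by counting, not by rank()
loop_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; ties <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) ties <- ties + 1
    }
    r[i] <- less + (ties + 1) / 2
  }
  r
}

# direct evaluation of the TMM formula: per-sample weighted trimmed mean of
# log ratios against reference r (reference chosen externally)
oracle_tmm <- function(K, r, trim_M = 0.30, trim_A = 0.05,
                       inverse_variance = FALSE) {
  m <- ncol(K)
  N <- colSums(K)
  log2d <- numeric(m)
  for (j in seq_len(m)) {
    if (j == r) next
    Ms <- c(); As <- c(); ws <- c()
    for (g in seq_len(nrow(K))) {
      kj <- K[g, j]; kr <- K[g, r]
      if (kj > 0 && kr > 0) {
        Ms <- c(Ms, log2((kj / N[j]) / (kr / N[r])))
        As <- c(As, 0.5 * log2((kj / N[j]) * (kr / N[r])))
        ws <- c(ws, (N[j] - kj) / (N[j] * kj) + (N[r] - kr) / (N[r] * kr))
      }
    }
    n <- length(Ms)
    rkM <- loop_rank(Ms); rkA <- loop_rank(As)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    num <- 0; den <- 0
    for (g in seq_len(n)) {
      if (rkM[g] >= loM && rkM[g] <= hiM && rkA[g] >= loA && rkA[g] <= hiA) {
        wt <- if (inverse_variance) 1 / ws[g] else ws[g]
        num <- num + wt * Ms[g]
        den <- den + wt
      }
    }
    log2d[j] <- num / den
  }
  2 ^ log2d
}

# direct evaluation of the median-of-ratios formula
oracle_median_ratio <- function(K) {
  G <- nrow(K); m <- ncol(K)
  d <- numeric(m)
  for (j in seq_len(m)) {
    ratios <- c()
    for (g in seq_len(G)) {
      gm <- prod(K[g, ]) ^ (1 / m)
      if (all(K[g, ] > 0)) ratios <- c(ratios, K[g, j] / gm)
    }
    d[j] <- median(ratios)
  }
  d
}

# direct evaluation of the upper-quartile depth formula
oracle_quantile <- function(K) {
  m <- ncol(K)
  Q <- numeric(m)
  for (j in seq_len(m)) Q[j] <- unname(quantile(K[, j], 0.75, type = 7))
  d <- numeric(m)
  for (j in seq_len(m)) d[j] <- 10 ^ (log10(Q[j]) - mean(log10(Q)))
  d
}

# direct evaluation of the goodness-of-fit depth estimator
oracle_poissonseq <- function(K, window = c(0.25, 0.75)) {
  G <- nrow(K); m <- ncol(K)
  total <- sum(K)
  d_tc <- numeric(m)
  for (j in seq_len(m)) d_tc[j] <- sum(K[, j]) / total
  gof <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    tg <- sum(K[g, ])
    if (tg == 0) next
    s <- 0
    for (j in seq_len(m)) s <- s + (K[g, j] - d_tc[j] * tg) ^ 2 / (d_tc[j] * tg)
    gof[g] <- s
  }
  b <- quantile(gof, window, na.rm = TRUE, type = 7)
  sel <- which(!is.na(gof) & gof >= b[1] & gof <= b[2])
  d <- numeric(m)
  denom <- sum(K[sel, ])
  for (j in seq_len(m)) d[j] <- sum(K[sel, j]) / denom
  list(d = d, selected = sel, gof = gof, d_tc = d_tc)
}

# two-sided binomial test of s1 against Binomial(s1+s2, n1/(n1+n2)) by
# explicit enumeration of outcome probabilities
oracle_binom_two_sided <- function(s1, s2, n1, n2) {
  tot <- s1 + s2
  if (tot == 0) return(1)
  p0 <- n1 / (n1 + n2)
  probs <- dbinom(0:tot, tot, p0)
  obs <- probs[s1 + 1]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# hand-stepped Benjamini-Hochberg adjustment
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}
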