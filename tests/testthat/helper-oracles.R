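# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (loops, exhaustive
# enumeration) rather than touching the package's vectorized implementations.

# exhaustive Otsu scan: between-class variance at every cut, computed with
# plain loops and bin centres; returns the smallest maximizing threshold
oracle_otsu <- function(bin_edges, counts) {
  B <- length(counts)
  mids <- (bin_edges[-1] + bin_edges[-(B + 1)]) / 2
  total <- sum(counts)
  best_sigma <- -Inf
  best_t <- NA_real_
  for (k in 1:(B - 1)) {
    n0 <- sum(counts[1:k]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):B] * mids[(k + 1):B]) / n1
    sigma <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (sigma > best_sigma + 1e-15) {
      best_sigma <- sigma
      best_t <- bin_edges[k + 1]
    }
  }
  best_t
}

# within-class variance at every cut (for the sigma_total decomposition check)
oracle_within_variance <- function(bin_edges, counts) {
  B <- length(counts)
  mids <- (bin_edges[-1] + bin_edges[-(B + 1)]) / 2
  total <- sum(counts)
  out <- rep(NA_real_, B - 1)
  for (k in 1:(B - 1)) {
    n0 <- sum(counts[1:k]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):B] * mids[(k + 1):B]) / n1
    v0 <- sum(counts[1:k] * (mids[1:k] - mu0)^2) / n0
    v1 <- sum(counts[(k + 1):B] * (mids[(k + 1):B] - mu1)^2) / n1
    out[k] <- (n0 / total) * v0 + (n1 / total) * v1
  }
  out
}

# pairwise concordance AUC with half credit for ties, double loop
oracle_auc <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg) {
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# exhaustive Youden search over observed scores under the package's stated
# conventions: rule "> c" (greater positive) or "<= c" (lesser positive),
# ties toward higher specificity
oracle_youden <- function(scores, y, direction) {
  best <- NULL
  for (c0 in sort(unique(scores))) {
    pred <- if (direction == "greater_is_positive") scores > c0 else scores <= c0
    sens <- mean(pred[y]); spec <- mean(!pred[!y])
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(cutoff = c0, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data only), using the same two-sided convention as wilcox.test
oracle_mw_p <- function(x, y) {
  m <- length(x); n <- length(y)
  v <- c(x, y)
  u_of <- function(ix) sum(outer(v[ix], v[-ix], ">"))
  u_obs <- sum(outer(x, y, ">"))
  us <- apply(utils::combn(m + n, m), 2, u_of)
  if (u_obs > m * n / 2) min(1, 2 * mean(us >= u_obs)) else min(1, 2 * mean(us <= u_obs))
}

# random histogram on a random grid; guarantees at least two non-empty bins
random_histogram <- function(max_bins = 256) {
  B <- sample(2:max_bins, 1)
  lo <- stats::runif(1, -50, 50)
  width <- stats::runif(1, 0.01, 10)
  counts <- stats::rpois(B, lambda = stats::runif(1, 0.2, 20))
  if (sum(counts > 0) < 2) {
    ix <- sample(B, 2)
    counts[ix] <- counts[ix] + 1
  }
  intensity_histogram(lo + width * (0:B), counts)
}

# symmetric Dirichlet draw for random-but-balanced class fractions
rdirichlet_sample <- function(alpha = c(2, 2, 2, 2)) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

# tiny in-memory volume/mask builders
make_vol <- function(values, dim = c(4, 4, 2), spacing = c(1, 1, 3), origin = c(0, 0, 0)) {
  scalar_volume(array(values, dim = dim), spacing, origin)
}

make_mask <- function(values, dim = c(4, 4, 2), spacing = c(1, 1, 3), origin = c(0, 0, 0)) {
  seg_mask(array(values, dim = dim), spacing, origin)
}
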