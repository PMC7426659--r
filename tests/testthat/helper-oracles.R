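# Independent brute-force oracles used to validate the statistical operations.
# These deliberately share no code with the implementation paths they check.

# Kendall tau-b by explicit pair counting: (C - D) / sqrt((C+D+Tx)(C+D+Ty))
# with Tx/Ty the pairs tied only in x / only in y.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- Tx <- Ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      else if (dx == 0) Tx <- Tx + 1
      else if (dy == 0) Ty <- Ty + 1
      else if (dx == dy) C <- C + 1
      else D <- D + 1
    }
  }
  (C - D) / sqrt((C + D + Tx) * (C + D + Ty))
}

# Exact two-sided paired Wilcoxon signed-rank p-value by enumerating all 2^n
# sign assignments (zeros dropped; assumes no ties among |d|).
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_null <- as.matrix(signs) %*% r
  p_low <- mean(v_null <= v_obs)
  p_high <- mean(v_null >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# Exact two-sided Mann-Whitney p-value by enumerating all group-1 rank subsets.
oracle_mann_whitney_p <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  u_null <- apply(idx, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p_low <- mean(u_null <= u_obs)
  p_high <- mean(u_null >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Benjamini-Hochberg step-up by direct arithmetic.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Exact multivariate hypergeometric pmf over the support of a 2- or 3-taxon
# row rarefied to depth n; returns a named vector keyed by "c1,c2[,c3]".
oracle_mvhyper_pmf <- function(row, n) {
  total <- sum(row)
  if (length(row) == 2) {
    support <- max(0, n - row[2]):min(row[1], n)
    p <- stats::dhyper(support, row[1], row[2], n)
    names(p) <- paste(support, n - support, sep = ",")
    return(p)
  }
  stopifnot(length(row) == 3)
  out <- c()
  for (a in 0:min(row[1], n)) {
    for (b in 0:min(row[2], n - a)) {
      cc <- n - a - b
      if (cc > row[3]) next
      lp <- lchoose(row[1], a) + lchoose(row[2], b) + lchoose(row[3], cc) -
        lchoose(total, n)
      out[paste(a, b, cc, sep = ",")] <- exp(lp)
    }
  }
  out
}

# Draw Dirichlet-multinomial counts with known parameters (oracle generator
# for single-component recovery tests).
oracle_rdm <- function(n, alpha, depth) {
  t(vapply(seq_len(n), function(i) {
    p <- rgamma(length(alpha), alpha, 1)
    p <- p / sum(p)
    stats::rmultinom(1, depth, p)[, 1]
  }, integer(length(alpha))))
}

# Small synthetic cohort used by several test files.
small_study <- function(seed = 42, n_subjects = 6, n_taxa = 20,
                        depth = c(4000, 6000), ...) {
  simulate_study(qmp_sim_config(n_subjects = n_subjects, n_taxa = n_taxa,
                                depth_range = depth, seed = seed, ...))
}
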