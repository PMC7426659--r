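# Concordance statistics against closed forms and brute-force oracles.

test_that("observed richness counts positive taxa and is scale invariant", {
  m <- matrix(c(1, 0, 2, 0, 0, 0, 5, 1, 3), 3, 3,
              dimnames = list(paste0("T", 1:3), paste0("S", 1:3)))
  expect_equal(unname(observed_richness(m)), c(2, 0, 3))
  expect_equal(observed_richness(m * 7.3), observed_richness(m))
  expect_error(observed_richness(-m), "non-negative")
})

test_that("Bray-Curtis matches its definition", {
  m <- matrix(c(2, 1, 1, 1), 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  d <- bray_curtis_matrix(m)
  expect_equal(d["x", "y"], 0.2)          # (1+0)/(3+2)
  expect_equal(diag(d), c(x = 0, y = 0))
  expect_equal(d, t(d))

  same <- matrix(c(3, 4, 3, 4), 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(bray_curtis_matrix(same)["x", "y"], 0)

  disjoint <- matrix(c(5, 0, 0, 7), 2, 2,
                     dimnames = list(c("A", "B"), c("x", "y")))
  expect_equal(bray_curtis_matrix(disjoint)["x", "y"], 1)

  # matches the definition on random data, and normalization is compositional
  set.seed(8)
  r <- matrix(rexp(30), 5, 6, dimnames = list(paste0("T", 1:5), paste0("S", 1:6)))
  d2 <- bray_curtis_matrix(r)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d2[i, j], sum(abs(r[, i] - r[, j])) / sum(r[, i] + r[, j]))
  }
  dn <- bray_curtis_matrix(r, normalize = TRUE)
  expect_equal(dn, bray_curtis_matrix(sweep(r, 2, colSums(r), "/")))
  expect_true(all(d2 >= 0 & d2 <= 1))
})

test_that("PCoA reproduces Euclidean-embeddable distances", {
  # three collinear points at 0, 1, 2
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  res <- pcoa_ordination(d)
  pos <- res$eigenvalues[res$eigenvalues > 1e-9]
  expect_equal(length(pos), 1)
  expect_equal(as.matrix(dist(res$coordinates)), unname(d) + 0,
               ignore_attr = TRUE, tolerance = 1e-9)

  # a general Euclidean configuration round-trips
  set.seed(12)
  pts <- matrix(rnorm(40), 10, 4)
  dd <- as.matrix(dist(pts))
  res2 <- pcoa_ordination(dd)
  expect_equal(as.matrix(dist(res2$coordinates)), dd,
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(sum(res2$variance_explained), 1, tolerance = 1e-9)

  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("identical points give an all-zero ordination", {
  d <- matrix(0, 4, 4)
  res <- pcoa_ordination(d)
  expect_true(all(abs(res$coordinates) < 1e-12))
})

test_that("Kendall tau-b agrees with brute-force pair counting", {
  expect_equal(oracle_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4)), 2 / 3)
  a <- c(1, 2, 3, 4); b <- c(1, 3, 2, 4)
  expect_equal(cor(a, b, method = "kendall"), 2 / 3)

  set.seed(3)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    x <- sample(1:5, n, replace = TRUE)  # ties included
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(cor(x, y, method = "kendall"), oracle_tau_b(x, y),
                 tolerance = 1e-12)
  }
})

test_that("top-genus concordance ranks by the reference and handles ties", {
  set.seed(21)
  a <- matrix(rexp(60, rate = 1 / (6:1)), 6, 10,
              dimnames = list(paste0("G", 1:6), paste0("S", 1:10)))
  mono <- a^2 * 3        # per-genus monotone transform
  res <- top_genus_rank_concordance(a, mono, n_top = 4)
  expect_equal(res$genus, names(sort(rowMeans(a), decreasing = TRUE))[1:4])
  expect_equal(res$tau, rep(1, 4))

  rev_ranks <- -a
  rev_ranks <- rev_ranks - min(rev_ranks)
  res2 <- top_genus_rank_concordance(a, rev_ranks, n_top = 3)
  expect_equal(res2$tau, rep(-1, 3))

  const <- a; const["G1", ] <- 5
  res3 <- top_genus_rank_concordance(a, const, reference = a, n_top = 6)
  expect_true(is.na(res3$tau[res3$genus == "G1"]))
  expect_error(top_genus_rank_concordance(a, mono, n_top = 10), "n_top")
})

test_that("correlations match closed forms", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$estimate, 1)
  mono <- correlate(x, exp(x), method = "spearman")
  expect_equal(mono$estimate, 1)
  expect_lt(correlate(x, exp(x))$estimate, 1)
  expect_equal(correlate(c(1, 2, 3), c(3, 1, 2), method = "spearman")$estimate,
               -0.5)
  expect_error(correlate(1:5, rep(1, 5)), "zero variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("paired Wilcoxon matches exact enumeration", {
  x <- c(1.2, 2.1, 3.7, 4.4, 5.9, 6.3)
  y <- x + 1
  res <- paired_wilcoxon(y, x)
  expect_true(res$exact)
  expect_equal(res$p.value, 2 / 2^6)      # = 0.03125
  expect_equal(res$p.value, oracle_signed_rank_p(y, x))

  # symmetry under exchanging x and y
  expect_equal(paired_wilcoxon(x, y)$p.value, res$p.value)

  # random tie-free cases, n <= 10, against full enumeration
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(paired_wilcoxon(a, b)$p.value, oracle_signed_rank_p(a, b),
                 tolerance = 1e-12)
  }

  # the large-sample approximation is close to the exact answer
  set.seed(6)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  exact_p <- oracle_signed_rank_p(a, b)
  d <- a - b
  approx_p <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(approx_p - exact_p), 0.01)

  expect_error(paired_wilcoxon(c(1, 2), c(1, 2)), "zero")
})

test_that("Mann-Whitney U matches exact enumeration", {
  g1 <- c(1, 2, 3, 4); g2 <- c(10, 11, 12, 13)
  res <- mann_whitney_u(g1, g2)
  expect_equal(unname(res$U), 0)
  expect_equal(res$p.value, 2 / choose(8, 4))   # 0.02857...
  expect_equal(res$p.value, oracle_mann_whitney_p(g1, g2))

  # label swap maps U to n1*n2 - U
  expect_equal(unname(mann_whitney_u(g2, g1)$U), 16)

  # identical groups: approximate p near 1
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p.value, 0.9)

  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney_u(a, b)$p.value, oracle_mann_whitney_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("BH adjustment matches step-up arithmetic", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(9)
  p <- runif(25)^2
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p))
  expect_true(all(adj >= p))
  expect_equal(order(adj[order(p)]), seq_along(p))  # order preserving
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("replicate dissimilarity analysis: structure and invariances", {
  st <- small_study(seed = 51)
  loads <- st$truth$load[sub("_r\\d+$", "", colnames(st$counts_untreated))]
  names(loads) <- colnames(st$counts_untreated)
  k <- st$truth$copy_numbers
  qmp <- qmp_profile(st$counts_untreated, k, loads, seed = 1)
  rep_report <- replicate_dissimilarity_analysis(list(QMP = qmp, COPY = qmp))

  # an exact copy of a method gives all-zero between-method distances
  expect_true(all(rep_report$between$distance == 0))
  expect_equal(rep_report$medians[["QMP"]], rep_report$medians[["COPY"]])

  # permuting sample order leaves the medians unchanged
  perm <- qmp$abundance[, sample(ncol(qmp$abundance))]
  rep2 <- replicate_dissimilarity_analysis(list(QMP = qmp$abundance, P = perm))
  expect_equal(sort(unname(rep2$medians[c("QMP", "P")])),
               sort(unname(rep_report$medians[c("QMP", "COPY")])))

  # missing replicate is an error
  broken <- qmp$abundance[, -1]
  expect_error(replicate_dissimilarity_analysis(list(A = broken, B = broken)),
               "missing a replicate")
  expect_error(
    replicate_dissimilarity_analysis(list(A = qmp$abundance,
                                          B = qmp$abundance[, -1])),
    "share the same sample ids")
})

test_that("noise confined to one method raises its between-method distance", {
  st <- small_study(seed = 53, n_subjects = 8)
  samples <- colnames(st$counts_untreated)
  loads <- st$truth$load[sub("_r\\d+$", "", samples)]
  names(loads) <- samples
  k <- st$truth$copy_numbers
  qmp <- qmp_profile(st$counts_untreated, k, loads, seed = 1)
  # corrupt the anchor loads of a second method with strong per-sample noise
  set.seed(99)
  noisy_loads <- loads * exp(rnorm(length(loads), 0, 0.6))
  noisy <- qmp_profile(st$counts_untreated, k, noisy_loads, seed = 1,
                       method_tag = "NOISY")
  rep_report <- replicate_dissimilarity_analysis(list(QMP = qmp, NOISY = noisy))
  expect_gt(rep_report$medians[["QMP vs NOISY"]], rep_report$medians[["QMP"]])
})
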