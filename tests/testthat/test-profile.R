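# Copy-number correction, rarefaction, and the RMP/QMP normalizations.

mk_counts <- function(m, taxa = NULL, samples = NULL) {
  taxa <- taxa %||% paste0("T", seq_len(nrow(m)))
  samples <- samples %||% paste0("S", seq_len(ncol(m)), "_r1")
  dimnames(m) <- list(taxa, samples)
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("copy-number correction rounds half away from zero", {
  x <- mk_counts(matrix(c(10L, 9L), 2, 1))
  cc <- copy_number_correct(x, c(T1 = 2, T2 = 3))
  expect_equal(unname(cc$counts[, 1]), c(5, 3))
  expect_equal(unname(cc$depths), 8)

  # unit copy numbers are the identity
  idm <- copy_number_correct(x, c(T1 = 1, T2 = 1))
  expect_equal(idm$counts, x)

  # a count of 1 with k = 3 rounds to zero, with a warning
  y <- mk_counts(matrix(c(1L, 30L), 2, 1))
  expect_warning(cc2 <- copy_number_correct(y, c(T1 = 3, T2 = 1)),
                 "rounded to zero")
  expect_equal(unname(cc2$counts[, 1]), c(0, 30))

  # floor and probabilistic modes
  expect_equal(unname(copy_number_correct(x, c(T1 = 2, T2 = 3),
                                          rounding = "floor")$counts[, 1]),
               c(5, 3))
  pr <- replicate(400, sum(copy_number_correct(
    mk_counts(matrix(c(0L, 9L), 2, 1)), c(T1 = 2, T2 = 2),
    rounding = "probabilistic", seed = sample.int(1e6, 1))$counts))
  expect_equal(mean(pr), 4.5, tolerance = 0.1)  # expectation-preserving

  # missing taxa: default fills in, NA default errors
  expect_message(copy_number_correct(x, c(T1 = 2)), "default copy number")
  expect_error(copy_number_correct(x, c(T1 = 2)[0],
                                   default_copy_number = NA), "missing")
})

test_that("rarefaction is an exact hypergeometric subsample", {
  x <- c(A = 50, B = 50)
  expect_equal(rarefy_counts(x, 100), x)          # n = total: identity
  expect_equal(unname(rarefy_counts(x, 0)), c(0, 0))
  expect_error(rarefy_counts(x, 101), "target depth")
  r <- rarefy_counts(x, 10, seed = 1)
  expect_equal(sum(r), 10)
  expect_true(all(r <= x))

  # expectation: 10,000 seeded draws of (50,50) -> 10 average 5 per taxon
  draws <- vapply(seq_len(10000), function(i) rarefy_counts(x, 10, seed = i)[1], 0)
  p <- 0.5
  se <- sqrt(10 * p * (1 - p) * (100 - 10) / 99 / 10000)
  expect_lt(abs(mean(draws) - 5), 3 * se)
})

test_that("RMP rarefies to the minimum depth and scales to proportions", {
  set.seed(4)
  counts <- mk_counts(matrix(rpois(40, 50), 8, 5))
  prof <- rmp_profile(counts, seed = 2)
  expect_s3_class(prof, "quant_profile")
  expect_equal(unname(prof$target_depths),
               rep(min(colSums(counts)), 5))
  expect_equal(unname(colSums(prof$abundance)), rep(1, 5), tolerance = 1e-9)

  # one sample: proportions = counts / total
  one <- counts[, 1, drop = FALSE]
  expect_equal(rmp_profile(one, seed = 1)$abundance[, 1], one[, 1] / sum(one))

  # identical samples under the same sub-seed handling give identical rows
  two <- mk_counts(cbind(counts[, 1], counts[, 1]),
                   samples = c("A_r1", "A_r2"))
  # depths equal so both columns rarefy to the full depth: identical by identity
  pr <- rmp_profile(two, seed = 9)
  expect_equal(pr$abundance[, 1], pr$abundance[, 2], ignore_attr = TRUE)

  # shallow samples: error listing offenders, or dropped on request
  counts2 <- counts
  counts2[, 3] <- 0L
  counts2[1, 3] <- 5L
  expect_error(rmp_profile(counts2, target_depth = 100), "S3_r1")
  expect_warning(p2 <- rmp_profile(counts2, target_depth = 100,
                                   drop_below = TRUE), "dropping")
  expect_equal(ncol(p2$abundance), 4)
})

test_that("QMP equalizes sampling depth and conserves loads", {
  # worked two-sample case: D = (100, 300), L = (1e10, 2e10)
  # SD = (1e-8, 1.5e-8) -> SD_min = 1e-8 -> targets (100, 200)
  counts <- mk_counts(matrix(c(60L, 40L, 120L, 180L), 2, 2),
                      samples = c("S1_r1", "S2_r1"))
  loads <- c(S1_r1 = 1e10, S2_r1 = 2e10)
  prof <- qmp_profile(counts, c(T1 = 1, T2 = 1), loads, seed = 5)
  expect_equal(unname(prof$target_depths), c(100, 200))
  expect_equal(prof$sd_min, 1e-8)
  expect_equal(colSums(prof$abundance), loads, tolerance = 1e-9)
  # even realized sampling depth: |n_s/L_s - SD_min| <= 1/L_s
  expect_true(all(abs(prof$target_depths / loads - prof$sd_min) <= 1 / loads))

  # equal loads and equal depths: QMP = RMP * L (same rarefaction targets)
  eq_counts <- mk_counts(matrix(c(60L, 40L, 30L, 70L), 2, 2),
                         samples = c("S1_r1", "S2_r1"))
  L <- c(S1_r1 = 5e9, S2_r1 = 5e9)
  q <- qmp_profile(eq_counts, c(T1 = 1, T2 = 1), L, seed = 3)
  r <- rmp_profile(eq_counts, seed = 3)
  # both rarefy to the full (equal) depth, so no randomness is involved
  expect_equal(q$abundance, r$abundance * 5e9)
})

test_that("QMP input validation catches unusable anchors", {
  counts <- mk_counts(matrix(c(6L, 4L), 2, 1))
  expect_error(qmp_profile(counts, c(T1 = 1, T2 = 1), c(S1_r1 = -1)), "> 0")
  expect_error(qmp_profile(counts, c(T1 = 1, T2 = 1),
                           c(other = 1e10)), "missing loads")
  # a sampling-depth target of zero is an error
  big <- mk_counts(matrix(c(6L, 4L), 2, 1))
  expect_error(
    suppressWarnings(qmp_profile(cbind(big, mk_counts(matrix(c(60000L, 40000L), 2, 1),
                                                      samples = "S2_r1")),
                                 c(T1 = 1, T2 = 1),
                                 c(S1_r1 = 1e12, S2_r1 = 1e2))),
    "target is zero")
})

test_that("average copies per cell and the qPCR load conversion", {
  x <- mk_counts(matrix(c(10L, 9L), 2, 1))
  a <- avg_copies_per_cell(x, c(T1 = 2, T2 = 3))
  expect_equal(unname(a), 19 / 8)   # R/D from the worked correction example

  one <- mk_counts(matrix(100L, 1, 1))
  expect_equal(unname(avg_copies_per_cell(one, c(T1 = 5))), 5)
  expect_equal(unname(avg_copies_per_cell(x, c(T1 = 1, T2 = 1))), 1)

  expect_equal(unname(qpcr_copies_to_load(6.435e10, 6.435)), 1e10)
  expect_equal(unname(qpcr_copies_to_load(42, 1)), 42)
  # inverse consistency
  L_true <- c(S1_r1 = 3e10)
  expect_equal(qpcr_copies_to_load(L_true * unname(a), unname(a)), L_true)
  expect_error(qpcr_copies_to_load(10, 0), "> 0")
})

test_that("qPCR-anchored QMP equals standard QMP when loads agree", {
  st <- small_study(seed = 31)
  counts <- st$counts_untreated
  loads <- st$truth$load[sub("_r\\d+$", "", colnames(counts))]
  names(loads) <- colnames(counts)

  # unit copy numbers: A_s = 1, so Q = L exactly and the two routes are
  # bit-identical
  k1 <- stats::setNames(rep(1, nrow(counts)), rownames(counts))
  q_equiv <- qmp_qpcr_profile(counts, k1, loads, seed = 77)
  q_std <- qmp_profile(counts, k1, loads, seed = 77)
  expect_identical(q_equiv$abundance, q_std$abundance)
  expect_identical(q_equiv$target_depths, q_std$target_depths)
  expect_equal(q_equiv$method, "QMP-qPCR")

  # general copy numbers: Q = L * A recovers the same rarefied counts; the
  # abundances agree to floating-point round-off of the load division
  k <- st$truth$copy_numbers
  a <- avg_copies_per_cell(counts, k)
  g_equiv <- qmp_qpcr_profile(counts, k, loads * a, seed = 77)
  g_std <- qmp_profile(counts, k, loads, seed = 77)
  expect_identical(g_equiv$target_depths, g_std$target_depths)
  expect_equal(g_equiv$abundance, g_std$abundance, tolerance = 1e-12)
})

test_that("noiseless QMP preserves within-sample rank order", {
  st <- small_study(seed = 37, depth = c(20000, 20000))
  counts <- st$counts_untreated
  k <- st$truth$copy_numbers
  loads <- st$truth$load[sub("_r\\d+$", "", colnames(counts))]
  names(loads) <- colnames(counts)
  cc <- suppressWarnings(copy_number_correct(counts, k))
  prof <- qmp_profile(counts, k, loads, seed = 7)
  for (j in c(1, 4)) {
    present <- cc$counts[, j] > 0 & prof$abundance[, j] > 0
    rho <- suppressWarnings(
      cor(cc$counts[present, j], prof$abundance[present, j], method = "spearman"))
    expect_gt(rho, 0.97)
  }
})
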