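# Statistical comparison layer: richness, Bray-Curtis dissimilarity + PCoA,
# replicate/method dissimilarity testing, per-genus rank concordance,
# correlations, paired and unpaired rank tests, and FDR control. Standard
# tests are delegated to stats/vegan; this module defines the comparison
# protocol around them.

#' Observed richness: taxa with non-zero abundance per sample
#'
#' @param x abundance matrix (taxa x samples) or a `quant_profile`.
#' @return named integer vector of per-sample richness.
#' @export
observed_richness <- function(x) {
  if (inherits(x, "quant_profile")) x <- x$abundance
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  r <- colSums(x > 0)
  storage.mode(r) <- "integer"
  r
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `BC(x, y) = sum |x_t - y_t| / sum (x_t + y_t)`, computed between sample
#' columns. For quantitative (cells/gram) profiles the dissimilarity is taken
#' on the absolute abundances as supplied; `normalize = TRUE` rescales each
#' sample to proportions first, making the comparison purely compositional.
#' Bray-Curtis is bounded in \[0, 1\] and symmetric but not a metric (no
#' triangle inequality). A pair of all-zero samples is returned as 0 with a
#' warning.
#'
#' @param x abundance matrix (taxa x samples) or a `quant_profile`.
#' @param normalize scale each sample to sum 1 before computing distances.
#' @return symmetric matrix with zero diagonal and sample dimnames.
#' @export
bray_curtis_matrix <- function(x, normalize = FALSE) {
  if (inherits(x, "quant_profile")) x <- x$abundance
  if (any(x < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (normalize) {
    sums <- colSums(x)
    x <- sweep(x, 2, ifelse(sums > 0, sums, 1), "/")
  }
  zero <- colSums(x) == 0
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  if (any(zero)) {
    warning("all-zero samples present; their mutual Bray-Curtis set to 0")
    d[zero, zero] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes; coordinates come from the
#' positive eigenvalues. Negative eigenvalues (Bray-Curtis matrices are rarely
#' Euclidean-embeddable) are reported, not corrected.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all, in
#'   decreasing order), `variance_explained` (share of the positive
#'   eigenvalue total per retained axis).
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(d)
  res <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = max(1L, n - 1L), eig = TRUE))
  eig <- res$eig
  pos <- which(eig > max(eig, 0) * 1e-12 & eig > 0)
  coords <- res$points
  if (length(pos) && ncol(coords) > length(pos)) {
    coords <- coords[, seq_along(pos), drop = FALSE]
  }
  if (!is.null(coords) && ncol(coords)) {
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  }
  list(
    coordinates = coords,
    eigenvalues = eig,
    variance_explained = if (length(pos)) eig[pos][seq_len(ncol(coords))] / sum(eig[pos])
                         else numeric(0)
  )
}

parse_sample_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_r(\\d+)$", ids))
  bad <- vapply(m, length, 1L) != 3
  if (any(bad)) {
    stop("sample ids must look like '<subject>_r<replicate>': ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(sample_id = ids,
             subject = vapply(m, `[`, "", 2),
             replicate = as.integer(vapply(m, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Within- and between-method dissimilarity analysis
#'
#' For each profiling method, the within-method dissimilarity of a subject is
#' the Bray-Curtis distance between that subject's two replicate profiles; for
#' each method pair, the between-method dissimilarity is the distance between
#' the same subject's profiles under the two methods, replicate-matched
#' (replicate 1 vs 1, 2 vs 2) by default, or all replicate crosses with
#' `pairing = "cross"`. Every within-vs-within, within-vs-between and
#' between-vs-between contrast is tested with a two-sided paired Wilcoxon
#' signed-rank test across subjects and corrected with Benjamini-Hochberg.
#'
#' @param profiles named list of `quant_profile` objects or abundance matrices
#'   sharing sample columns named `<subject>_r<replicate>`.
#' @param normalize passed to [bray_curtis_matrix()].
#' @param pairing `"matched"` (default) or `"cross"` for between-method pairs.
#' @return object of class `concordance_report`: list with `within` (long
#'   data.frame: method, subject, distance), `between` (comparison, subject,
#'   replicate, distance), `medians`, `tests` (contrast, statistic, p, p_adj).
#' @export
replicate_dissimilarity_analysis <- function(profiles, normalize = FALSE,
                                             pairing = c("matched", "cross")) {
  pairing <- match.arg(pairing)
  if (is.null(names(profiles)) || anyDuplicated(names(profiles))) {
    stop("profiles must be a uniquely named list", call. = FALSE)
  }
  mats <- lapply(profiles, function(p) if (inherits(p, "quant_profile")) p$abundance else p)
  ids <- colnames(mats[[1]])
  for (m in mats) {
    if (!identical(sort(colnames(m)), sort(ids))) {
      stop("all profiles must share the same sample ids", call. = FALSE)
    }
  }
  info <- parse_sample_ids(ids)
  subjects <- unique(info$subject)
  reps <- sort(unique(info$replicate))
  if (length(reps) < 2) stop("each subject needs at least 2 replicates", call. = FALSE)
  for (s in subjects) {
    if (!all(reps %in% info$replicate[info$subject == s])) {
      stop("subject ", s, " is missing a replicate", call. = FALSE)
    }
  }
  methods <- names(mats)

  within <- do.call(rbind, lapply(methods, function(me) {
    d <- bray_curtis_matrix(mats[[me]], normalize = normalize)
    data.frame(method = me, subject = subjects,
               distance = vapply(subjects, function(s) {
                 d[paste0(s, "_r", reps[1]), paste0(s, "_r", reps[2])]
               }, 0), stringsAsFactors = FALSE, row.names = NULL)
  }))

  pairs <- if (length(methods) >= 2) utils::combn(methods, 2, simplify = FALSE) else list()
  between <- do.call(rbind, lapply(pairs, function(pr) {
    a <- mats[[pr[1]]]; b <- mats[[pr[2]]]
    rows <- expand.grid(subject = subjects,
                        r1 = reps, r2 = reps,
                        stringsAsFactors = FALSE)
    rows <- if (pairing == "matched") rows[rows$r1 == rows$r2, ] else rows
    d <- vapply(seq_len(nrow(rows)), function(i) {
      x <- a[, paste0(rows$subject[i], "_r", rows$r1[i])]
      y <- b[, paste0(rows$subject[i], "_r", rows$r2[i])]
      bray_curtis_pair(x, y, normalize = normalize)
    }, 0)
    data.frame(comparison = paste(pr[1], pr[2], sep = " vs "),
               subject = rows$subject, replicate = rows$r1,
               distance = d, stringsAsFactors = FALSE)
  }))

  medians <- vapply(c(split(within$distance, within$method),
                      if (!is.null(between)) split(between$distance, between$comparison)),
                    stats::median, 0)
  # test on one value per subject per group (between-method distances averaged
  # over replicates) so every contrast is a paired comparison across subjects
  per_subject <- function(df) {
    agg <- tapply(df$distance, df$subject, mean)
    agg[subjects]
  }
  groups <- c(lapply(split(within, within$method), per_subject),
              if (!is.null(between)) lapply(split(between, between$comparison),
                                            per_subject))
  contrasts <- if (length(groups) >= 2) utils::combn(names(groups), 2, simplify = FALSE) else list()
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    g1 <- groups[[ct[1]]]; g2 <- groups[[ct[2]]]
    res <- tryCatch(paired_wilcoxon(g1, g2),
                    error = function(e) list(statistic = NA_real_,
                                             p.value = NA_real_))
    data.frame(contrast = paste(ct[1], "|", ct[2]),
               statistic = res$statistic, p = res$p.value,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(tests) && nrow(tests)) tests$p_adj <- bh_adjust(tests$p)

  structure(list(within = within, between = between,
                 medians = medians, tests = tests,
                 pairing = pairing, normalize = normalize),
            class = "concordance_report")
}

# Bray-Curtis between two single samples; both-zero pair -> 0 with warning.
bray_curtis_pair <- function(x, y, normalize = FALSE) {
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (normalize) {
    if (sum(x) > 0) x <- x / sum(x)
    if (sum(y) > 0) y <- y / sum(y)
  }
  tot <- sum(x) + sum(y)
  if (tot == 0) {
    warning("Bray-Curtis between two all-zero samples set to 0")
    return(0)
  }
  sum(abs(x - y)) / tot
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Replicate/method dissimilarity analysis (Bray-Curtis,",
      x$pairing, "pairing)\n")
  cat("  medians:\n")
  for (nm in names(x$medians)) cat(sprintf("    %-28s %.4f\n", nm, x$medians[nm]))
  if (!is.null(x$tests) && nrow(x$tests)) {
    sig <- sum(x$tests$p_adj < 0.05)
    cat(sprintf("  %d contrasts tested (paired Wilcoxon, BH); %d with FDR < 0.05\n",
                nrow(x$tests), sig))
  }
  invisible(x)
}

#' Rank concordance of the most abundant genera between two profiles
#'
#' Selects the `n_top` genera by mean abundance in a reference profile
#' (typically RMP) and, for each genus, computes the Kendall tau-b rank
#' correlation between its across-sample abundance vectors in two profiling
#' methods. tau-b corrects for ties; a genus constant in either method has
#' undefined concordance and is reported as `NA`.
#'
#' @param a,b abundance matrices or `quant_profile`s sharing samples.
#' @param reference profile used to rank genera (defaults to `a`).
#' @param n_top number of genera (default 15).
#' @return data.frame with columns `genus`, `tau`.
#' @export
top_genus_rank_concordance <- function(a, b, reference = NULL, n_top = 15) {
  ma <- if (inherits(a, "quant_profile")) a$abundance else a
  mb <- if (inherits(b, "quant_profile")) b$abundance else b
  mr <- if (is.null(reference)) ma else
    if (inherits(reference, "quant_profile")) reference$abundance else reference
  common <- intersect(colnames(ma), colnames(mb))
  if (!length(common)) stop("profiles share no samples", call. = FALSE)
  ma <- ma[, common, drop = FALSE]
  mb <- mb[, common, drop = FALSE]
  if (n_top > nrow(mr)) stop("n_top exceeds the number of taxa", call. = FALSE)
  top <- names(sort(rowMeans(mr), decreasing = TRUE))[seq_len(n_top)]
  tau <- vapply(top, function(g) {
    x <- ma[g, ]; y <- mb[g, ]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    stats::cor(x, y, method = "kendall")  # tau-b (tie-corrected)
  }, 0)
  data.frame(genus = top, tau = unname(tau), stringsAsFactors = FALSE)
}

#' Pearson or Spearman correlation with p-value
#'
#' @param x,y numeric vectors, length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `estimate`, `p.value`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  res <- suppressWarnings(stats::cor.test(x, y, method = method,
                                          exact = method == "spearman" && length(x) <= 9))
  list(estimate = unname(res$estimate), p.value = res$p.value, method = method)
}

#' Paired Wilcoxon signed-rank test (two-sided)
#'
#' Zero differences are dropped. For up to 20 non-zero differences the exact
#' two-sided p-value is computed by enumerating the null distribution of the
#' signed-rank sum over all sign assignments (ties among the absolute
#' differences are handled with midranks, so the enumeration remains valid);
#' larger samples use the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y paired numeric vectors.
#' @return list with `statistic` (V, sum of positive-difference ranks),
#'   `p.value`, `exact`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (length(d) <= 20) {
    p <- signed_rank_exact_p(r, v)
    return(list(statistic = v, p.value = p, exact = TRUE))
  }
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  )
  list(statistic = v, p.value = res$p.value, exact = FALSE)
}

# Exact two-sided signed-rank p by dynamic programming over the distribution
# of V = sum of a random subset of the ranks (all 2^n sign assignments
# equally likely under the null). Ranks are doubled so midranks from ties
# become integers.
signed_rank_exact_p <- function(ranks, v_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # counts[s + 1] = number of sign assignments with doubled rank-sum s
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (w in r2) {
    shifted <- c(numeric(w), counts[seq_len(total + 1 - w)])
    counts <- counts + shifted
  }
  probs <- counts / sum(counts)
  v2 <- as.integer(round(2 * v_obs))
  p_low <- sum(probs[seq_len(v2 + 1)])
  p_high <- sum(probs[seq(v2 + 1, total + 1)])
  min(1, 2 * min(p_low, p_high))
}

#' Mann-Whitney U test (two-sided)
#'
#' The exact two-sided p-value is computed by full enumeration of group-1 rank
#' subsets when that enumeration is small (at most 50,000 subsets; ties are
#' handled with midranks), otherwise the normal approximation with tie and
#' continuity correction is used. The returned U counts the pairs where a
#' `group1` value exceeds a `group2` value.
#'
#' @param group1,group2 numeric vectors.
#' @return list with `U`, `p.value`, `exact`.
#' @export
mann_whitney_u <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (!n1 || !n2) stop("empty group", call. = FALSE)
  r <- rank(c(group1, group2))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= 50000) {
    idx <- utils::combn(n1 + n2, n1)
    u_null <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p_low <- mean(u_null <= u + eps)
    p_high <- mean(u_null >= u - eps)
    return(list(U = u, p.value = min(1, 2 * min(p_low, p_high)), exact = TRUE))
  }
  if (length(unique(c(group1, group2))) == 1) {
    return(list(U = u, p.value = 1, exact = FALSE))  # fully tied: no evidence
  }
  res <- suppressWarnings(
    stats::wilcox.test(group1, group2, exact = FALSE, correct = TRUE)
  )
  list(U = u, p.value = res$p.value, exact = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p vector of p-values in \[0, 1\] (`NA`s allowed and preserved).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
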