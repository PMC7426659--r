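# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded operations do not disturb the
#' caller's RNG stream. A `NULL` seed evaluates the expression as-is.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed from a master seed and an operation tag
#'
#' All stochastic operations in the package draw their randomness from
#' sub-seeds derived this way, so one master seed reproduces a whole run while
#' individual stages remain independently re-runnable. Result is in
#' [0, 2^31 - 2].
#' @noRd
derive_seed <- function(seed, tag, index = 0L) {
  if (is.null(seed)) return(NULL)
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  val <- (as.numeric(seed) %% m) * 48271 + h * 1009 + as.numeric(index) * 7919
  as.integer(val %% m)
}

#' Log-normal multiplicative noise with mean 1 and a given coefficient of
#' variation. cv = 0 returns exact ones (the zero-noise limit is exact).
#' @noRd
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("coefficient of variation must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' One Dirichlet draw via gamma normalization.
#' @noRd
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1  # guard against underflow at tiny alpha
  x / sum(x)
}

#' Validate a taxon-by-sample count matrix (taxa in rows).
#' @noRd
check_count_matrix <- function(x, what = "count table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (taxa in rows, samples in columns)",
         call. = FALSE)
  }
  if (any(x < 0)) stop(what, " contains negative counts", call. = FALSE)
  if (any(abs(x - round(x)) > 1e-8)) {
    stop(what, " contains non-integer counts", call. = FALSE)
  }
  if (is.null(rownames(x))) stop(what, " must have taxon rownames", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop(what, " has duplicate taxon ids", call. = FALSE)
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) {
    stop(what, " has duplicate sample ids", call. = FALSE)
  }
  invisible(x)
}

#' Deterministic 32-bit hash of a configuration object (FNV-1a over its
#' deparsed form), recorded in run outputs so reruns are verifiable.
#' @noRd
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#' Used to score recovery of simulated enterotype structure.
#'
#' @param a,b factors or vectors of cluster labels, same length.
#' @return numeric scalar in \[-1, 1\].
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}
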