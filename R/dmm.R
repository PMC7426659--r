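# Dirichlet-multinomial mixture (DMM) enterotyping. The mixture likelihood,
# the EM algorithm and the model-evidence approximation are implemented here;
# only k-means initialization is delegated to stats::kmeans.

# Per-sample log density of counts under one DM component (multinomial
# coefficient omitted: it is constant across components and K, so it affects
# neither responsibilities nor model comparison).
dm_component_logdens <- function(X, alpha) {
  # X: samples x taxa; alpha: taxa vector
  A <- sum(alpha)
  N <- rowSums(X)
  am <- matrix(alpha, nrow(X), ncol(X), byrow = TRUE)
  lgamma(A) - lgamma(N + A) + rowSums(lgamma(X + am) - lgamma(am))
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# Minka's fixed-point update for the alpha of one DM component under sample
# weights w (an MM step: each iteration cannot decrease the weighted
# likelihood). Returns the updated alpha.
dm_alpha_fixed_point <- function(X, w, alpha, inner_iter = 25, tol = 1e-8,
                                 alpha_floor = 1e-10) {
  N <- rowSums(X)
  for (it in seq_len(inner_iter)) {
    A <- sum(alpha)
    am <- matrix(alpha, nrow(X), ncol(X), byrow = TRUE)
    num <- colSums(w * (digamma(X + am) - digamma(am)))
    den <- sum(w * (digamma(N + A) - digamma(A)))
    if (den <= 0) break
    new_alpha <- pmax(alpha * num / den, alpha_floor)
    if (max(abs(new_alpha - alpha)) < tol * max(1, max(alpha))) {
      alpha <- new_alpha
      break
    }
    alpha <- new_alpha
  }
  alpha
}

fit_dmm_single <- function(X, K, init_seed, max_iter, tol, alpha_floor) {
  S <- nrow(X); Tt <- ncol(X)
  props <- X / pmax(rowSums(X), 1)
  # k-means initialization on proportion rows -> soft responsibilities
  resp <- with_seed(init_seed, {
    cl <- if (K == 1) rep(1L, S) else {
      km <- tryCatch(stats::kmeans(props, centers = K, nstart = 5),
                     error = function(e) NULL)
      if (is.null(km)) sample(rep_len(seq_len(K), S)) else km$cluster
    }
    r <- matrix(0.05 / max(K - 1, 1), S, K)
    r[cbind(seq_len(S), cl)] <- if (K == 1) 1 else 0.95
    r
  })
  alpha <- matrix(0, Tt, K)
  pi_k <- colMeans(resp)
  for (k in seq_len(K)) {
    m <- colSums(resp[, k] * props) / sum(resp[, k])
    alpha[, k] <- pmax(m, 1e-6) * 30  # moderate initial concentration
  }
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step
    logdens <- vapply(seq_len(K), function(k) dm_component_logdens(X, alpha[, k]),
                      numeric(S))
    logw <- sweep(matrix(logdens, S, K), 2, log(pi_k), "+")
    lse <- logsumexp_rows(logw)
    new_loglik <- sum(lse)
    resp <- exp(logw - lse)
    trace <- c(trace, new_loglik)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) < tol * (abs(loglik) + 1e-3)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
    # M-step
    pi_k <- pmax(colMeans(resp), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      alpha[, k] <- dm_alpha_fixed_point(X, resp[, k], alpha[, k],
                                         alpha_floor = alpha_floor)
    }
  }
  list(K = K, weights = pi_k, alpha = alpha, responsibilities = resp,
       logLik = loglik, trace = trace, converged = converged)
}

# Laplace approximation to the log model evidence:
# logL + (p/2) log(2*pi) - (1/2) log det(-H), with the curvature -H evaluated
# blockwise at the optimum. Each component's alpha block has the analytic
# structure diag(-D_t) - c 11', so its determinant comes from the matrix
# determinant lemma; the mixture-weight block uses the multinomial
# information. Note the approximation is anticonservative when an extra
# component duplicates an existing one (the likelihood surface is then locally
# singular and det(-H) collapses toward zero), which is why BIC is the default
# selection rule.
dmm_laplace_evidence <- function(X, fit) {
  S <- nrow(X)
  N <- rowSums(X)
  logdet <- 0
  p <- 0
  for (k in seq_len(fit$K)) {
    alpha <- fit$alpha[, k]
    w <- fit$responsibilities[, k]
    A <- sum(alpha)
    am <- matrix(alpha, S, ncol(X), byrow = TRUE)
    d_t <- colSums(w * (trigamma(X + am) - trigamma(am)))   # <= 0
    cc <- sum(w * (trigamma(A) - trigamma(N + A)))          # >= 0
    a_diag <- pmax(-d_t, 1e-12)
    corr <- max(1 - cc * sum(1 / a_diag), 1e-12)
    logdet <- logdet + sum(log(a_diag)) + log(corr)
    p <- p + length(alpha)
  }
  if (fit$K > 1) {
    n_k <- colSums(fit$responsibilities)
    logdet <- logdet + sum(log(pmax(n_k[-fit$K] / fit$weights[-fit$K]^2, 1e-10)))
    p <- p + fit$K - 1
  }
  fit$logLik + p / 2 * log(2 * pi) - logdet / 2
}

#' Fit a Dirichlet-multinomial mixture to a count table
#'
#' Enterotyping model: each sample's taxon counts follow a Dirichlet-
#' multinomial distribution whose parameter vector comes from one of K latent
#' community types. Fitting is by EM with Minka fixed-point M-steps (both are
#' minorize-maximize steps, so the log-likelihood is non-decreasing), multiple
#' k-means-seeded restarts per K, and model selection across `K_range` by
#' BIC (default) or a Laplace approximation to the model evidence
#' (`selection = "laplace"`; anticonservative for overlapping components, see
#' the methods vignette).
#'
#' @param counts integer matrix, taxa x samples.
#' @param K_range candidate numbers of components (each < number of samples).
#' @param n_starts random restarts per K (>= 3 recommended).
#' @param seed integer seed controlling initialization.
#' @param selection `"bic"` (default) or `"laplace"`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param alpha_floor lower bound on Dirichlet parameters, guarding against
#'   boundary collapse.
#' @return object of class `dmm_fit`: the best model (`K`, `weights`, `alpha`
#'   taxa x K, `responsibilities` samples x K, `logLik`, `trace`, `converged`)
#'   plus `model_selection` (data.frame over K: logLik, n_param, laplace, bic)
#'   and `selection`.
#' @export
#' @examples
#' cfg <- qmp_sim_config(n_subjects = 8, n_taxa = 12, depth_range = c(2000, 2000),
#'                       seed = 7)
#' counts <- simulate_sequencing(generate_truth(cfg), "untreated")
#' fit <- fit_dmm(counts, K_range = 1:2, n_starts = 2, seed = 1)
fit_dmm <- function(counts, K_range = 1:3, n_starts = 3, seed = NULL,
                    selection = c("bic", "laplace"),
                    max_iter = 500, tol = 1e-6, alpha_floor = 1e-10) {
  selection <- match.arg(selection)
  check_count_matrix(counts)
  X <- t(counts)  # samples x taxa internally
  if (any(rowSums(X) == 0)) stop("empty samples (zero total counts)", call. = FALSE)
  if (any(K_range < 1) || max(K_range) >= nrow(X)) {
    stop("K_range must be >= 1 and below the number of samples", call. = FALSE)
  }
  fits <- lapply(K_range, function(K) {
    best <- NULL
    for (s in seq_len(n_starts)) {
      f <- fit_dmm_single(X, K, init_seed = derive_seed(seed, "dmm", K * 1000 + s),
                          max_iter = max_iter, tol = tol,
                          alpha_floor = alpha_floor)
      if (is.null(best) || f$logLik > best$logLik) best <- f
    }
    best
  })
  sel <- data.frame(
    K = K_range,
    logLik = vapply(fits, `[[`, 0, "logLik"),
    n_param = K_range * ncol(X) + (K_range - 1),
    laplace = vapply(fits, function(f) dmm_laplace_evidence(X, f), 0),
    bic = vapply(seq_along(fits), function(i) {
      -2 * fits[[i]]$logLik + (K_range[i] * ncol(X) + K_range[i] - 1) * log(nrow(X))
    }, 0)
  )
  best_i <- if (selection == "laplace") which.max(sel$laplace) else which.min(sel$bic)
  best <- fits[[best_i]]
  rownames(best$alpha) <- colnames(X)
  rownames(best$responsibilities) <- rownames(X)
  structure(c(best, list(model_selection = sel, selection = selection,
                         seed = seed, taxa = colnames(X),
                         samples = rownames(X))),
            class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat(sprintf("Dirichlet-multinomial mixture: K = %d (%s selection)\n",
              x$K, x$selection))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations%s\n",
              x$logLik, length(x$trace),
              if (x$converged) "" else " (iteration cap reached)"))
  cat("  mixture weights:", paste(sprintf("%.3f", x$weights), collapse = ", "), "\n")
  sizes <- table(factor(dmm_assign(x), levels = seq_len(x$K)))
  cat("  hard assignment sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dmm_fit <- function(object, n_top = 5, ...) {
  print(object)
  cat("\nModel selection:\n")
  print(object$model_selection, row.names = FALSE)
  cat("\nTop taxa per component (by expected proportion):\n")
  for (k in seq_len(object$K)) {
    p <- object$alpha[, k] / sum(object$alpha[, k])
    top <- sort(p, decreasing = TRUE)[seq_len(min(n_top, length(p)))]
    cat(sprintf("  component %d: %s\n", k,
                paste(sprintf("%s (%.2f)", names(top), top), collapse = ", ")))
  }
  invisible(object)
}

#' @export
logLik.dmm_fit <- function(object, ...) {
  structure(object$logLik, df = object$K * length(object$taxa) + object$K - 1,
            class = "logLik")
}

#' Hard cluster assignment from a fitted DMM
#'
#' Assigns each sample to the component with the highest responsibility. Exact
#' ties are broken toward the lowest component index with a warning.
#'
#' @param model a [fit_dmm()] object.
#' @param counts optional new taxa x samples count matrix (taxa must match the
#'   training taxa); defaults to the training responsibilities.
#' @return named integer vector of component labels.
#' @export
dmm_assign <- function(model, counts = NULL) {
  if (!inherits(model, "dmm_fit")) stop("model must be a dmm_fit", call. = FALSE)
  resp <- if (is.null(counts)) {
    model$responsibilities
  } else {
    check_count_matrix(counts)
    if (!setequal(rownames(counts), model$taxa)) {
      stop("count table taxa do not match the fitted model", call. = FALSE)
    }
    X <- t(counts[model$taxa, , drop = FALSE])
    logdens <- vapply(seq_len(model$K),
                      function(k) dm_component_logdens(X, model$alpha[, k]),
                      numeric(nrow(X)))
    logw <- sweep(matrix(logdens, nrow(X), model$K), 2, log(model$weights), "+")
    r <- exp(logw - logsumexp_rows(logw))
    rownames(r) <- rownames(X)
    r
  }
  ties <- apply(resp, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) {
    warning("responsibility ties for ", sum(ties),
            " sample(s); assigned to the lowest component index")
  }
  labels <- apply(resp, 1, which.max)
  stats::setNames(as.integer(labels), rownames(resp))
}

#' @export
predict.dmm_fit <- function(object, counts = NULL,
                            type = c("class", "responsibility"), ...) {
  type <- match.arg(type)
  if (type == "class") return(dmm_assign(object, counts))
  if (is.null(counts)) return(object$responsibilities)
  X <- t(counts[object$taxa, , drop = FALSE])
  logdens <- vapply(seq_len(object$K),
                    function(k) dm_component_logdens(X, object$alpha[, k]),
                    numeric(nrow(X)))
  logw <- sweep(matrix(logdens, nrow(X), object$K), 2, log(object$weights), "+")
  r <- exp(logw - logsumexp_rows(logw))
  rownames(r) <- rownames(X)
  r
}

#' Compare microbial loads between two enterotype clusters
#'
#' Reports per-cluster median loads and a two-sided Mann-Whitney U test of the
#' load difference.
#'
#' @param labels cluster labels (exactly 2 distinct values represented).
#' @param loads per-sample loads, aligned with `labels` (by names when both
#'   are named).
#' @return list with `medians`, `U`, `p.value`, `n`.
#' @export
loads_by_cluster_test <- function(labels, loads) {
  if (!is.null(names(labels)) && !is.null(names(loads))) {
    common <- intersect(names(labels), names(loads))
    if (!length(common)) stop("labels and loads share no names", call. = FALSE)
    labels <- labels[common]; loads <- loads[common]
  } else if (length(labels) != length(loads)) {
    stop("labels and loads must align", call. = FALSE)
  }
  lv <- unique(labels)
  if (length(lv) != 2) {
    stop("exactly 2 clusters must be represented (got ", length(lv), ")",
         call. = FALSE)
  }
  g1 <- loads[labels == lv[1]]; g2 <- loads[labels == lv[2]]
  if (!length(g1) || !length(g2)) stop("a cluster has no members", call. = FALSE)
  mw <- mann_whitney_u(g1, g2)
  list(medians = stats::setNames(c(stats::median(g1), stats::median(g2)),
                                 as.character(lv)),
       U = mw$U, p.value = mw$p.value,
       n = stats::setNames(c(length(g1), length(g2)), as.character(lv)))
}
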