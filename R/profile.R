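# The four profiling normalizations: relative microbiome profiling (RMP) by
# rarefaction, cell-count-anchored quantitative profiling (QMP), its PMA
# variant (same algorithm on PMA-treated counts) and the qPCR-anchored variant.

#' Correct read counts for 16S rRNA gene copy number
#'
#' Divides each taxon's counts by its copies-per-genome so that corrected
#' counts approximate cell-proportional sampling. Corrected values are rounded
#' back to integers (default: half away from zero) so they remain valid input
#' for rarefaction; low counts of high-copy taxa can round to zero, which is
#' reported with a warning.
#'
#' @param counts integer matrix, taxa x samples.
#' @param copy_numbers named vector of copies/genome (>= 1) keyed by taxon.
#' @param default_copy_number value for taxa missing from `copy_numbers`;
#'   default is the mean of the supplied table. `NULL` makes missing taxa an
#'   error.
#' @param rounding `"half_away"` (default), `"floor"`, or `"probabilistic"`
#'   (stochastic rounding, expectation-preserving; honors `seed`).
#' @param seed used only for probabilistic rounding.
#' @return list with `counts` (corrected integer matrix) and `depths` (named
#'   per-sample corrected depths D_s).
#' @export
#' @examples
#' x <- matrix(c(10, 9), 2, 1, dimnames = list(c("A", "B"), "s1"))
#' copy_number_correct(x, c(A = 2, B = 3))
copy_number_correct <- function(counts, copy_numbers,
                                default_copy_number = NULL,
                                rounding = c("half_away", "floor", "probabilistic"),
                                seed = NULL) {
  rounding <- match.arg(rounding)
  check_count_matrix(counts)
  if (any(copy_numbers < 1)) stop("copy numbers must be >= 1", call. = FALSE)
  missing <- setdiff(rownames(counts), names(copy_numbers))
  if (length(missing)) {
    if (is.null(default_copy_number)) default_copy_number <- mean(copy_numbers)
    if (is.na(default_copy_number)) {
      stop("taxa missing from the copy-number table and no default available: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    message("using default copy number ", signif(default_copy_number, 4),
            " for ", length(missing), " taxa: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "")
    copy_numbers <- c(copy_numbers,
                      stats::setNames(rep(default_copy_number, length(missing)),
                                      missing))
  }
  k <- copy_numbers[rownames(counts)]
  raw <- counts / k
  corrected <- switch(rounding,
    half_away = floor(raw + 0.5),     # round half away from zero (all values >= 0)
    floor = floor(raw),
    probabilistic = with_seed(seed, {
      fl <- floor(raw)
      fl + (stats::runif(length(raw)) < (raw - fl))
    })
  )
  storage.mode(corrected) <- "integer"
  dimnames(corrected) <- dimnames(counts)
  lost <- counts > 0 & corrected == 0
  if (any(lost)) {
    warning(sum(lost), " taxon-sample cells with nonzero reads rounded to zero ",
            "by copy-number correction")
  }
  list(counts = corrected, depths = colSums(corrected))
}

#' Rarefy a count vector to a target depth
#'
#' Subsamples reads without replacement (multivariate hypergeometric), the
#' operation behind both RMP downsizing and the QMP even-sampling-depth step.
#' Implemented by sequential univariate hypergeometric draws, which samples
#' the exact joint distribution.
#'
#' @param x non-negative integer vector of counts.
#' @param n target depth, `0 <= n <= sum(x)`.
#' @param seed optional seed.
#' @return integer vector, same length and names as `x`, summing to `n`, with
#'   `out[t] <= x[t]` for every taxon.
#' @export
#' @examples
#' rarefy_counts(c(A = 50, B = 50), 10, seed = 1)
rarefy_counts <- function(x, n, seed = NULL) {
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  nm <- names(x)
  x <- as.integer(round(x))
  names(x) <- nm
  n <- as.integer(round(n))
  total <- sum(x)
  if (n < 0 || n > total) {
    stop("target depth n must be in [0, sum(x)] (requested ", n,
         " from ", total, ")", call. = FALSE)
  }
  with_seed(seed, {
    out <- integer(length(x))
    remaining_total <- total
    remaining_n <- n
    for (t in seq_along(x)) {
      if (remaining_n == 0L) break
      other <- remaining_total - x[t]
      if (other == 0L) {
        out[t] <- remaining_n
        remaining_n <- 0L
        break
      }
      draw <- stats::rhyper(1, x[t], other, remaining_n)
      out[t] <- draw
      remaining_n <- remaining_n - draw
      remaining_total <- other
    }
    names(out) <- names(x)
    out
  })
}

new_quant_profile <- function(abundance, method, target_depths, loads,
                              sd_min = NA_real_, seed = NULL) {
  structure(list(
    abundance = abundance, method = method,
    target_depths = target_depths, loads = loads,
    sd_min = sd_min, seed = seed
  ), class = "quant_profile")
}

#' @export
print.quant_profile <- function(x, ...) {
  unit <- if (x$method == "RMP") "proportions" else "cells/gram"
  cat(sprintf("%s profile: %d taxa x %d samples (%s)\n", x$method,
              nrow(x$abundance), ncol(x$abundance), unit))
  if (!is.na(x$sd_min)) {
    cat(sprintf("  minimum sampling depth: %.4g reads per cell/gram\n", x$sd_min))
  }
  cat(sprintf("  rarefied depths: %d - %d reads\n",
              min(x$target_depths), max(x$target_depths)))
  invisible(x)
}

#' Relative microbiome profiling: rarefy and convert to proportions
#'
#' Downsizes every sample to a common read depth by random subsampling, then
#' scales to proportions (rows of the sample dimension sum to 1).
#'
#' @param counts integer matrix, taxa x samples.
#' @param target_depth common depth; default is the minimum column sum.
#' @param seed master seed; each sample is rarefied under a derived sub-seed.
#' @param drop_below logical: drop samples shallower than `target_depth`
#'   (default `FALSE`: such samples are an error).
#' @return a `quant_profile` with method `"RMP"` (proportions).
#' @export
rmp_profile <- function(counts, target_depth = NULL, seed = NULL,
                        drop_below = FALSE) {
  check_count_matrix(counts)
  depths <- colSums(counts)
  target_depth <- as.integer(target_depth %||% min(depths))
  if (target_depth < 1) stop("target_depth must be >= 1", call. = FALSE)
  shallow <- names(depths)[depths < target_depth]
  if (length(shallow)) {
    if (!drop_below) {
      stop("samples below the target depth of ", target_depth, ": ",
           paste(shallow, collapse = ", "),
           " (set drop_below = TRUE to drop them)", call. = FALSE)
    }
    warning("dropping ", length(shallow), " samples below target depth: ",
            paste(shallow, collapse = ", "))
    counts <- counts[, !(colnames(counts) %in% shallow), drop = FALSE]
  }
  rarefied <- vapply(seq_len(ncol(counts)), function(j) {
    rarefy_counts(counts[, j], target_depth,
                  seed = derive_seed(seed, "rmp", j))
  }, integer(nrow(counts)))
  dimnames(rarefied) <- dimnames(counts)
  new_quant_profile(rarefied / target_depth, "RMP",
                    target_depths = stats::setNames(rep(target_depth, ncol(counts)),
                                                    colnames(counts)),
                    loads = NULL, seed = seed)
}

#' Quantitative microbiome profiling anchored to measured loads
#'
#' Implements rarefaction to even sampling depth: (1) correct counts for 16S
#' copy number; (2) compute each sample's sampling depth
#' `SD_s = D_s / L_s` (corrected reads per cell/gram of microbial load) and
#' find the cohort minimum `SD_min`; (3) rarefy every sample to
#' `n_s = floor(SD_min * L_s)` reads, which equalizes reads-per-cell across
#' samples; (4) scale the rarefied composition by the load, giving taxon
#' abundances in cells/gram whose per-sample sum equals the measured load.
#'
#' @param counts integer matrix, taxa x samples.
#' @param copy_numbers named copies/genome vector (see
#'   [copy_number_correct()]).
#' @param loads named per-sample microbial loads, cells/gram (> 0); names must
#'   cover the sample columns.
#' @param seed master seed (per-sample sub-seeds derived from it).
#' @param method_tag label stored on the result (`"QMP"` by default;
#'   the PMA variant passes `"QMP-PMA"`).
#' @param min_sampling_depth optional floor on SD_s: samples below it are
#'   dropped with a warning instead of dragging `SD_min` down (default `NULL`,
#'   keep all).
#' @param ... passed to [copy_number_correct()] (rounding mode, default copy
#'   number).
#' @return a `quant_profile` with abundances in cells/gram; row sums equal
#'   `loads`.
#' @export
qmp_profile <- function(counts, copy_numbers, loads, seed = NULL,
                        method_tag = "QMP", min_sampling_depth = NULL, ...) {
  check_count_matrix(counts)
  samples <- colnames(counts)
  if (is.null(names(loads))) {
    if (length(loads) != length(samples)) {
      stop("loads must be named by sample or match the number of samples",
           call. = FALSE)
    }
    names(loads) <- samples
  }
  missing_load <- setdiff(samples, names(loads))
  if (length(missing_load)) {
    stop("missing loads for samples: ", paste(missing_load, collapse = ", "),
         call. = FALSE)
  }
  loads <- loads[samples]
  if (any(loads <= 0)) stop("loads must be > 0", call. = FALSE)

  cc <- copy_number_correct(counts, copy_numbers, seed = derive_seed(seed, "cnc"), ...)
  depths <- cc$depths
  if (any(depths == 0)) {
    stop("zero copy-number-corrected depth for samples: ",
         paste(samples[depths == 0], collapse = ", "), call. = FALSE)
  }
  sd_s <- depths / loads
  if (!is.null(min_sampling_depth)) {
    low <- samples[sd_s < min_sampling_depth]
    if (length(low)) {
      warning("dropping ", length(low), " samples below the minimum sampling ",
              "depth: ", paste(low, collapse = ", "))
      keep <- setdiff(samples, low)
      return(qmp_profile(counts[, keep, drop = FALSE], copy_numbers,
                         loads[keep], seed = seed, method_tag = method_tag,
                         min_sampling_depth = NULL, ...))
    }
  }
  sd_min <- min(sd_s)
  # floor guarantees feasibility (n_s <= D_s); the tiny nudge keeps exact
  # integers (notably the SD_min-defining sample itself) from losing a read
  # to floating-point round-off
  targets <- pmin(floor(sd_min * loads * (1 + 1e-12) + 1e-9), depths)
  if (any(targets == 0)) {
    stop("even-depth rarefaction target is zero for samples: ",
         paste(samples[targets == 0], collapse = ", "),
         " (sampling depth too low)", call. = FALSE)
  }
  abundance <- vapply(seq_along(samples), function(j) {
    r <- rarefy_counts(cc$counts[, j], targets[j],
                       seed = derive_seed(seed, "qmp", j))
    r / targets[j] * loads[j]
  }, numeric(nrow(counts)))
  dimnames(abundance) <- dimnames(counts)
  new_quant_profile(abundance, method_tag,
                    target_depths = stats::setNames(as.integer(targets), samples),
                    loads = loads, sd_min = sd_min, seed = seed)
}

#' Per-sample average 16S copies per cell implied by the sequencing data
#'
#' The ratio of a sample's raw read count to its copy-number-corrected read
#' count estimates the average 16S rRNA gene copy number per bacterium in that
#' sample, used to convert qPCR copies/gram into cells/gram.
#'
#' @inheritParams qmp_profile
#' @param ... passed to [copy_number_correct()].
#' @return named numeric vector `A_s` (copies/cell per sample).
#' @export
avg_copies_per_cell <- function(counts, copy_numbers, ...) {
  check_count_matrix(counts)
  cc <- copy_number_correct(counts, copy_numbers, ...)
  if (any(cc$depths == 0)) {
    stop("zero copy-number-corrected depth for samples: ",
         paste(colnames(counts)[cc$depths == 0], collapse = ", "), call. = FALSE)
  }
  colSums(counts) / cc$depths
}

#' Convert qPCR 16S copies/gram into cells/gram
#'
#' @param copies_per_gram named per-sample qPCR loads (copies/gram).
#' @param avg_copies per-sample average copies per cell from
#'   [avg_copies_per_cell()].
#' @return named per-sample loads in cells/gram.
#' @export
qpcr_copies_to_load <- function(copies_per_gram, avg_copies) {
  if (!is.null(names(copies_per_gram)) && !is.null(names(avg_copies))) {
    common <- intersect(names(copies_per_gram), names(avg_copies))
    if (!length(common)) stop("no shared sample names", call. = FALSE)
    copies_per_gram <- copies_per_gram[common]
    avg_copies <- avg_copies[common]
  } else if (length(copies_per_gram) != length(avg_copies)) {
    stop("copies_per_gram and avg_copies must pair up", call. = FALSE)
  }
  if (any(avg_copies <= 0)) stop("average copies per cell must be > 0", call. = FALSE)
  copies_per_gram / avg_copies
}

#' qPCR-anchored quantitative microbiome profiling
#'
#' Derives each sample's microbial load from its qPCR 16S copies/gram divided
#' by the sequencing-derived average copy number per cell, then applies the
#' standard QMP normalization with those loads.
#'
#' @inheritParams qmp_profile
#' @param qpcr_copies named per-sample qPCR loads, copies/gram.
#' @return a `quant_profile` with method `"QMP-qPCR"`.
#' @export
qmp_qpcr_profile <- function(counts, copy_numbers, qpcr_copies, seed = NULL, ...) {
  a <- avg_copies_per_cell(counts, copy_numbers, ...)
  loads <- qpcr_copies_to_load(qpcr_copies, a)
  qmp_profile(counts, copy_numbers, loads, seed = seed,
              method_tag = "QMP-qPCR", ...)
}
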