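# Conversion of raw instrument readouts into microbial loads: flow-cytometry
# event counts, qPCR standard curves, ddPCR Poisson statistics, fixed
# copy-number conversion, paired PMA differencing and Ct-difference arithmetic.

#' Convert flow-cytometry gate events to a cell concentration
#'
#' The acquired sample volume is determined gravimetrically (tube weighed
#' before and after acquisition); concentration is events per consumed volume
#' times the dilution factor. Given the mass of input feces per ml of
#' suspension, the result can also be expressed per gram.
#'
#' @param events_in_gate number of events in the cell gate.
#' @param tube_mass_before,tube_mass_after tube mass (g) before/after
#'   acquisition; the difference is the consumed suspension mass.
#' @param dilution_factor fold-dilution of the suspension (>= 1).
#' @param fluid_density suspension density in g/ml (default 1.0).
#' @param feces_g_per_ml optional grams of feces per ml of (undiluted)
#'   suspension; when given, `cells_per_gram` is also returned.
#' @return list with `cells_per_ml` and, if requested, `cells_per_gram`.
#' @export
#' @examples
#' events_to_concentration(2e6, 10.05, 10.00, dilution_factor = 1000)$cells_per_ml
events_to_concentration <- function(events_in_gate, tube_mass_before,
                                    tube_mass_after, dilution_factor = 1,
                                    fluid_density = 1.0,
                                    feces_g_per_ml = NULL) {
  if (events_in_gate < 0) stop("events_in_gate must be >= 0", call. = FALSE)
  if (tube_mass_before <= tube_mass_after) {
    stop("non-positive consumed volume: tube_mass_before must exceed tube_mass_after",
         call. = FALSE)
  }
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  if (fluid_density <= 0) stop("fluid_density must be > 0", call. = FALSE)
  volume_ml <- (tube_mass_before - tube_mass_after) / fluid_density
  cells_per_ml <- events_in_gate / volume_ml * dilution_factor
  out <- list(cells_per_ml = cells_per_ml)
  if (!is.null(feces_g_per_ml)) {
    if (feces_g_per_ml <= 0) stop("feces_g_per_ml must be > 0", call. = FALSE)
    out$cells_per_gram <- cells_per_ml / feces_g_per_ml
  }
  out
}

#' Fit a qPCR standard quantification curve
#'
#' Ordinary least squares of cycle-threshold (Ct) values on log10 template
#' copies. A valid dilution series gives a negative slope near -3.32 (one Ct
#' per doubling); amplification efficiency is `10^(-1/slope) - 1`.
#'
#' @param ct_values observed Ct values.
#' @param log10_copies log10 of known template copies per reaction.
#' @return object of class `standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n`.
#' @export
#' @examples
#' fit_standard_curve(c(30, 26.7, 23.3, 20), 3:6)
fit_standard_curve <- function(ct_values, log10_copies) {
  if (length(ct_values) != length(log10_copies)) {
    stop("ct_values and log10_copies must have equal length", call. = FALSE)
  }
  if (length(unique(log10_copies)) < 3) {
    stop("a standard curve needs at least 3 distinct standards", call. = FALSE)
  }
  if (stats::var(ct_values) == 0) {
    stop("degenerate standards: Ct identical at all concentrations", call. = FALSE)
  }
  fit <- stats::lm(ct_values ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    efficiency = 10^(-1 / slope) - 1,
    n = length(ct_values)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve (n = %d standards)\n", x$n))
  cat(sprintf("  Ct = %.4f + %.4f * log10(copies)   R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  amplification efficiency: %.1f%%\n", 100 * x$efficiency))
  invisible(x)
}

#' Convert Ct values to copies per gram via a standard curve
#'
#' Inverts the standard curve to copies per reaction, then scales by the
#' template dilution and the reaction-to-gram factor (elution volume over
#' template volume over input mass), which depend on the extraction protocol
#' and are supplied by the user.
#'
#' @param curve a [fit_standard_curve()] object (slope must be negative).
#' @param ct Ct value(s).
#' @param template_dilution fold-dilution of the template DNA (e.g. 1000 for a
#'   1:1000 dilution).
#' @param reaction_to_gram_factor multiplier taking copies/reaction to
#'   copies/gram feces.
#' @return copies per gram (same length as `ct`).
#' @export
ct_to_copies <- function(curve, ct, template_dilution = 1,
                         reaction_to_gram_factor = 1) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve",
                                               call. = FALSE)
  if (curve$slope >= 0) stop("invalid standard curve: slope must be negative",
                             call. = FALSE)
  copies_reaction <- 10^((curve$intercept - ct) / abs(curve$slope))
  copies_reaction * template_dilution * reaction_to_gram_factor
}

#' Invert a standard curve: copies per reaction to expected Ct
#'
#' @param curve a [fit_standard_curve()] object.
#' @param copies copies per reaction.
#' @return expected Ct value(s).
#' @export
copies_to_ct <- function(curve, copies) {
  if (!inherits(curve, "standard_curve")) stop("curve must be a standard_curve",
                                               call. = FALSE)
  if (any(copies <= 0)) stop("copies must be > 0", call. = FALSE)
  curve$intercept + curve$slope * log10(copies)
}

#' ddPCR concentration from droplet counts (Poisson statistics)
#'
#' With droplets of volume v and a positive fraction p, the mean copies per
#' droplet is `lambda = -ln(1 - p)` and the concentration is `lambda / v`.
#' A well with zero positive droplets is below the detection limit and returns
#' 0 flagged `below_detection`; a saturated well (all droplets positive) is an
#' error because lambda is unbounded.
#'
#' @param droplets_positive,droplets_total droplet counts.
#' @param droplet_volume droplet volume in microliters (default 0.00085, the
#'   standard for this instrument class).
#' @param scale_to_gram optional multiplier taking copies/microliter to
#'   copies/gram.
#' @return list with `copies_per_ul`, `lambda`, `below_detection`, and
#'   optionally `copies_per_gram`.
#' @export
#' @examples
#' ddpcr_concentration(2000, 10000)$copies_per_ul
ddpcr_concentration <- function(droplets_positive, droplets_total,
                                droplet_volume = 0.00085,
                                scale_to_gram = NULL) {
  if (droplet_volume <= 0) stop("droplet_volume must be > 0", call. = FALSE)
  if (droplets_positive < 0 || droplets_positive > droplets_total) {
    stop("droplets_positive must be in [0, droplets_total]", call. = FALSE)
  }
  if (droplets_total < 1) stop("droplets_total must be >= 1", call. = FALSE)
  if (droplets_positive == droplets_total) {
    stop("saturated ddPCR well (all droplets positive): concentration not quantifiable",
         call. = FALSE)
  }
  p <- droplets_positive / droplets_total
  lambda <- -log1p(-p)
  out <- list(copies_per_ul = lambda / droplet_volume, lambda = lambda,
              below_detection = droplets_positive == 0)
  if (!is.null(scale_to_gram)) out$copies_per_gram <- out$copies_per_ul * scale_to_gram
  out
}

#' Convert 16S copies to cells with a fixed average copy number
#'
#' Used for defined communities where the average 16S rRNA gene copy number per
#' genome is known (6.435 for the 12-species gut mock community shipped with
#' the package).
#'
#' @param copies copies (any per-volume or per-mass unit).
#' @param average_copy_number copies per genome (> 0).
#' @return cells in the same unit as `copies`.
#' @export
copies_to_cells_fixed <- function(copies, average_copy_number) {
  if (average_copy_number <= 0) {
    stop("average_copy_number must be > 0", call. = FALSE)
  }
  if (any(copies < 0)) stop("copies must be >= 0", call. = FALSE)
  copies / average_copy_number
}

#' Synthetic 12-species gut mock community specification
#'
#' A stand-in for a commercial whole-cell gut standard: 12 species in even cell
#' proportions with per-species 16S copy numbers whose mean is 6.435
#' copies/genome (the value used throughout the package's copy-based
#' conversions). The species list and copy numbers are synthetic — plausible
#' values, not the certified composition of any real product.
#'
#' @param expected_cells_per_ml expected concentration of the undiluted mix.
#' @param n_dilutions number of serial 2-fold dilutions.
#' @return list with `species` (data.frame: species, copy_number),
#'   `average_copy_number`, `expected_cells_per_ml` (vector over the dilution
#'   series), `dilution_factors`.
#' @export
mock_community <- function(expected_cells_per_ml = 3.3e6, n_dilutions = 6) {
  species <- data.frame(
    species = c("Bacteroides fragilis", "Bacteroides vulgatus",
                "Bifidobacterium adolescentis", "Clostridioides difficile",
                "Enterobacter cloacae", "Escherichia coli",
                "Fusobacterium nucleatum", "Lactobacillus plantarum",
                "Enterococcus faecalis", "Salmonella enterica",
                "Yersinia enterocolitica", "Helicobacter pylori"),
    copy_number = c(6, 7, 5, 12, 8, 7, 5, 5, 4, 7, 7, 4.22),
    stringsAsFactors = FALSE
  )
  dilution_factors <- 2^(seq_len(n_dilutions) - 1)
  list(
    species = species,
    average_copy_number = mean(species$copy_number),
    expected_cells_per_ml = expected_cells_per_ml / dilution_factors,
    dilution_factors = dilution_factors
  )
}

#' Estimate the extracellular DNA fraction by paired PMA differencing
#'
#' For each sample measured with and without viability-dye (PMA) treatment on
#' the same DNA extract, the fraction of signal removed by treatment estimates
#' the share of metagenomic DNA that was extracellular or from dead /
#' membrane-compromised cells: `f_s = (untreated_s - treated_s) / untreated_s`.
#' Because both measurements share the aliquot's extraction yield, the yield
#' factor cancels in the ratio. Significance of the paired decrease is assessed
#' with a two-sided paired Wilcoxon signed-rank test.
#'
#' @param untreated,treated positive load values (copies/gram), paired by
#'   position or by names when both are named.
#' @return object of class `pma_differencing`: list with `fractions`,
#'   `mean_fraction`, `mean_decrease`, `p_value`, `n`.
#' @export
#' @examples
#' estimate_extracellular_fraction(c(1e10, 2e10), c(6e9, 1.2e10))
estimate_extracellular_fraction <- function(untreated, treated) {
  if (!is.null(names(untreated)) && !is.null(names(treated))) {
    if (!setequal(names(untreated), names(treated))) {
      stop("mismatched pairing keys between untreated and treated", call. = FALSE)
    }
    treated <- treated[names(untreated)]
  } else if (length(untreated) != length(treated)) {
    stop("untreated and treated must pair up (equal length or shared names)",
         call. = FALSE)
  }
  if (length(untreated) < 1) stop("at least one complete pair required", call. = FALSE)
  if (any(untreated <= 0) || any(treated <= 0)) {
    stop("load values must be > 0", call. = FALSE)
  }
  fractions <- (untreated - treated) / untreated
  p <- if (length(untreated) >= 2 && any(untreated != treated)) {
    paired_wilcoxon(untreated, treated)$p.value
  } else {
    NA_real_
  }
  structure(list(
    fractions = fractions,
    mean_fraction = mean(fractions),
    mean_decrease = mean(untreated - treated),
    p_value = p,
    n = length(untreated)
  ), class = "pma_differencing")
}

#' @export
print.pma_differencing <- function(x, ...) {
  cat(sprintf("PMA differencing on %d paired samples\n", x$n))
  cat(sprintf("  mean extracellular fraction: %.3f (%.1f%% of metagenomic DNA)\n",
              x$mean_fraction, 100 * x$mean_fraction))
  cat(sprintf("  mean absolute decrease: %.4g copies/gram\n", x$mean_decrease))
  if (!is.na(x$p_value)) cat(sprintf("  paired Wilcoxon p = %.2g\n", x$p_value))
  invisible(x)
}

#' Percent signal reduction implied by a Ct increase
#'
#' At amplification efficiency E, one cycle multiplies signal by (1 + E), so a
#' Ct increase of dCt corresponds to a fractional signal reduction of
#' `1 - (1 + E)^(-dCt)`. With a vector of per-sample Ct increases, the default
#' mode computes the reduction from the mean dCt; `mode = "per_sample"`
#' averages per-sample reductions instead (the two differ by Jensen's
#' inequality).
#'
#' @param delta_ct Ct increase(s); negative values are allowed (signal gain)
#'   but flagged with a warning.
#' @param efficiency amplification efficiency in (0, 1]; default 1 (perfect
#'   doubling).
#' @param mode `"mean_ct"` (default) or `"per_sample"`.
#' @return percent reduction (scalar).
#' @export
#' @examples
#' delta_ct_signal_reduction(11.6)        # ~99.97 %
#' delta_ct_signal_reduction(1)           # 50 %
delta_ct_signal_reduction <- function(delta_ct, efficiency = 1,
                                      mode = c("mean_ct", "per_sample")) {
  mode <- match.arg(mode)
  if (efficiency <= 0 || efficiency > 1) {
    stop("efficiency must be in (0, 1]", call. = FALSE)
  }
  if (any(delta_ct < 0)) {
    warning("negative delta Ct: reported reduction is negative (signal gain)")
  }
  reduction <- function(d) (1 - (1 + efficiency)^(-d)) * 100
  if (mode == "mean_ct") reduction(mean(delta_ct)) else mean(reduction(delta_ct))
}

#' Evaluate a mock-community dilution series measured by two methods
#'
#' Computes per-dilution accuracy ratios (measured / expected) for each method
#' and the Pearson correlation between the two methods across the series, on
#' the scale supplied (raw concentrations give r near +1 for concordant
#' methods; a Ct-scale channel is linear in -log2 concentration, so its
#' correlation against a raw channel is negative — the sign is preserved, not
#' normalized away).
#'
#' @param measured_a,measured_b measurements of the same dilution series by two
#'   methods (any scale).
#' @param expected expected concentrations, same length.
#' @return list with `ratios_a`, `ratios_b` (NULL when a channel is not on the
#'   concentration scale, see `ratio_scale`), `pearson_r`, `p_value`.
#' @param ratio_scale logical length 2: whether each channel is on the
#'   concentration scale (ratios meaningful). Default both TRUE.
#' @export
evaluate_mock_series <- function(measured_a, measured_b, expected,
                                 ratio_scale = c(TRUE, TRUE)) {
  n <- length(expected)
  if (length(measured_a) != n || length(measured_b) != n) {
    stop("measured series and expected concentrations differ in length",
         call. = FALSE)
  }
  if (n < 3) stop("at least 3 dilutions required", call. = FALSE)
  ct <- stats::cor.test(measured_a, measured_b, method = "pearson")
  list(
    ratios_a = if (ratio_scale[1]) measured_a / expected else NULL,
    ratios_b = if (ratio_scale[2]) measured_b / expected else NULL,
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value
  )
}
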