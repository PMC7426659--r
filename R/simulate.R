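# Synthetic fecal-community generator and its three measurement channels:
# amplicon sequencing, flow-cytometry cell counting, and molecular (qPCR/ddPCR)
# load quantification, with or without viability-dye (PMA) pre-treatment.

# Common human gut genera used to label synthetic taxa. The first two anchor the
# two enterotype templates.
gut_genera <- c(
  "Bacteroides", "Prevotella", "Faecalibacterium", "Blautia", "Bifidobacterium",
  "Roseburia", "Ruminococcus", "Alistipes", "Akkermansia", "Dorea",
  "Coprococcus", "Lachnospira", "Oscillibacter", "Parabacteroides", "Dialister",
  "Phascolarctobacterium", "Streptococcus", "Collinsella", "Eubacterium",
  "Subdoligranulum", "Anaerostipes", "Butyrivibrio", "Christensenella",
  "Clostridium", "Desulfovibrio", "Enterococcus", "Escherichia",
  "Fusicatenibacter", "Gemmiger", "Haemophilus", "Holdemanella", "Intestinibacter",
  "Lactobacillus", "Megamonas", "Megasphaera", "Methanobrevibacter",
  "Mitsuokella", "Odoribacter", "Paraprevotella", "Peptostreptococcus",
  "Romboutsia", "Sarcina", "Slackia", "Sutterella", "Terrisporobacter",
  "Turicibacter", "Veillonella", "Victivallis", "Weissella", "Acidaminococcus",
  "Adlercreutzia", "Anaerotruncus", "Barnesiella", "Bilophila", "Butyricimonas",
  "Catenibacterium", "Cloacibacillus", "Coprobacter", "Dielma", "Eggerthella",
  "Enterorhabdus", "Erysipelatoclostridium", "Flavonifractor", "Gordonibacter",
  "Hespellia", "Hungatella", "Intestinimonas", "Lachnoclostridium",
  "Marvinbryantia", "Mogibacterium", "Moryella", "Negativibacillus",
  "Oxalobacter", "Papillibacter", "Parasutterella", "Prevotellamassilia",
  "Pseudoflavonifractor", "Sellimonas", "Senegalimassilia", "Shuttleworthia",
  "Solobacterium", "Sporobacter", "Succinivibrio", "Tyzzerella", "Vampirovibrio"
)

#' Simulation configuration for the synthetic fecal cohort
#'
#' Bundles every tunable of the synthetic-community generator. Defaults emulate
#' the study design the package is built around: 16 subjects sampled in
#' duplicate, genus-level communities following one of two enterotype templates
#' (*Bacteroides*- or *Prevotella*-dominant), total microbial loads between
#' 1.2e10 and 5.3e10 cells/gram, an extracellular/dead-cell DNA compartment
#' averaging 39% of metagenomic DNA, sequencing depths between 153,527 and
#' 282,297 reads, and multiplicative measurement noise on the flow-cytometry
#' and molecular channels.
#'
#' @param n_subjects number of subjects (biological samples).
#' @param n_replicates technical replicates per subject (aliquots profiled
#'   independently).
#' @param n_taxa number of genera in the community pool.
#' @param enterotype_mix proportion of subjects assigned to the
#'   *Bacteroides*-dominant template (the rest follow the *Prevotella* one).
#' @param load_range numeric length-2: min/max total intact microbial load,
#'   cells/gram. Loads are drawn uniformly on the log scale within this range
#'   (the underlying study reports only the min/max/median, not a distribution).
#' @param extracellular_mean expected fraction of metagenomic DNA that is
#'   extracellular or from dead cells, in (0, 1).
#' @param extracellular_precision precision (a + b) of the Beta distribution the
#'   per-sample fraction is drawn from; larger = tighter around the mean.
#' @param death_bias `"proportional"` (default) kills cells evenly across taxa,
#'   so the dead compartment mirrors the intact composition; `"biased"` draws a
#'   per-taxon death propensity so that PMA treatment changes composition, for
#'   testing detection of taxon-specific death.
#' @param copy_number_range integer range of 16S rRNA gene copies per genome.
#' @param depth_range integer range of per-sample sequencing depths (reads).
#' @param facs_cv coefficient of variation of flow-cytometry counting noise.
#' @param extraction_yield_cv coefficient of variation of the per-aliquot DNA
#'   extraction yield factor (the dominant source of molecular-load error).
#' @param qpcr_tech_cv coefficient of variation of per-measurement technical
#'   noise in qPCR/ddPCR quantification.
#' @param moisture_range stool moisture range, percent mass.
#' @param seed integer master seed; all stages derive sub-seeds from it.
#' @return an object of class `qmp_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- qmp_sim_config(n_subjects = 4, n_taxa = 20, seed = 1)
#' truth <- generate_truth(cfg)
qmp_sim_config <- function(n_subjects = 16L,
                           n_replicates = 2L,
                           n_taxa = 80L,
                           enterotype_mix = 0.5,
                           load_range = c(1.2e10, 5.3e10),
                           extracellular_mean = 0.39,
                           extracellular_precision = 150,
                           death_bias = c("proportional", "biased"),
                           copy_number_range = c(1L, 10L),
                           depth_range = c(153527L, 282297L),
                           facs_cv = 0.05,
                           extraction_yield_cv = 0.5,
                           qpcr_tech_cv = 0.1,
                           moisture_range = c(10, 40),
                           seed = 1L) {
  death_bias <- match.arg(death_bias)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_replicates = as.integer(n_replicates),
    n_taxa = as.integer(n_taxa), enterotype_mix = enterotype_mix,
    load_range = as.numeric(load_range),
    extracellular_mean = extracellular_mean,
    extracellular_precision = extracellular_precision,
    death_bias = death_bias,
    copy_number_range = as.integer(copy_number_range),
    depth_range = as.integer(depth_range),
    facs_cv = facs_cv, extraction_yield_cv = extraction_yield_cv,
    qpcr_tech_cv = qpcr_tech_cv,
    moisture_range = as.numeric(moisture_range),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "qmp_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop("invalid simulation config: ",
                                                   msg, call. = FALSE)
  stopifnot_cfg(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  stopifnot_cfg(cfg$n_replicates >= 1, "n_replicates must be >= 1")
  stopifnot_cfg(cfg$n_taxa >= 1, "n_taxa must be >= 1")
  stopifnot_cfg(cfg$enterotype_mix >= 0 && cfg$enterotype_mix <= 1,
                "enterotype_mix must be in [0, 1]")
  stopifnot_cfg(length(cfg$load_range) == 2 && all(cfg$load_range > 0) &&
                  diff(cfg$load_range) >= 0, "load_range must be positive, increasing")
  stopifnot_cfg(cfg$extracellular_mean > 0 && cfg$extracellular_mean < 1,
                "extracellular_mean must be in (0, 1)")
  stopifnot_cfg(cfg$extracellular_precision > 0, "extracellular_precision must be > 0")
  stopifnot_cfg(all(cfg$copy_number_range >= 1) && diff(cfg$copy_number_range) >= 0,
                "copy_number_range must be integers >= 1, increasing")
  stopifnot_cfg(all(cfg$depth_range >= 1) && diff(cfg$depth_range) >= 0,
                "depth_range minimum must be >= 1")
  stopifnot_cfg(cfg$facs_cv >= 0 && cfg$extraction_yield_cv >= 0 &&
                  cfg$qpcr_tech_cv >= 0, "all CVs must be >= 0")
  invisible(cfg)
}

# Enterotype base compositions: geometric rank-abundance decay with the
# dominant genus boosted. Deterministic in n_taxa.
enterotype_templates <- function(n_taxa) {
  decay <- exp(-0.07 * (seq_len(n_taxa) - 1))
  bact <- decay
  prev <- decay
  if (n_taxa >= 2) {
    # template 1: Bacteroides-dominant, Prevotella nearly absent
    bact[1] <- sum(decay) * 0.45
    bact[2] <- decay[2] * 0.02
    # template 2: Prevotella-dominant, Bacteroides reduced
    prev[2] <- sum(decay) * 0.55
    prev[1] <- decay[1] * 0.25
  }
  list(Bacteroides = bact / sum(bact), Prevotella = prev / sum(prev))
}

#' Generate synthetic community ground truth
#'
#' Draws a cohort of subject-level communities with fully known composition:
#' per-taxon intact-cell absolute abundances (cells/gram), a per-taxon
#' extracellular/dead-DNA compartment (genome-equivalents/gram), per-taxon 16S
#' copy numbers, total loads, enterotype labels and stool moisture. Each
#' subject follows one of two enterotype templates via a Dirichlet draw with
#' additional per-taxon log-normal variation; higher stool moisture is linked
#' to lower genus richness through noisy monotone thinning of the rarest taxa.
#'
#' @param config a [qmp_sim_config()] object.
#' @return an object of class `community_truth`: list with elements `taxa`,
#'   `copy_numbers` (named, copies/genome), `intact` and `extracellular`
#'   (taxa x subject matrices), `load` (cells/gram, = column sums of `intact`),
#'   `enterotype`, `moisture`, `richness`, `config`, `seed`.
#' @export
generate_truth <- function(config) {
  if (!inherits(config, "qmp_sim_config")) {
    stop("config must be created by qmp_sim_config()", call. = FALSE)
  }
  validate_sim_config(config)
  n_taxa <- config$n_taxa
  n_sub <- config$n_subjects
  taxa <- if (n_taxa <= length(gut_genera)) gut_genera[seq_len(n_taxa)] else
    c(gut_genera, sprintf("Genus%03d", seq_len(n_taxa - length(gut_genera))))
  subjects <- sprintf("S%02d", seq_len(n_sub))

  with_seed(derive_seed(config$seed, "truth"), {
    k <- config$copy_number_range[1] +
      sample.int(diff(config$copy_number_range) + 1L, n_taxa, replace = TRUE) - 1L
    names(k) <- taxa

    templates <- enterotype_templates(n_taxa)
    n_bact <- round(config$enterotype_mix * n_sub)
    labels <- c(rep("Bacteroides", n_bact), rep("Prevotella", n_sub - n_bact))
    labels <- sample(labels)
    if (n_taxa == 1) labels <- rep("Bacteroides", n_sub)  # templates degenerate

    # moisture -> richness link: monotone thinning with noise, targeting a rank
    # correlation magnitude around 0.7
    moisture <- config$moisture_range[1] +
      diff(config$moisture_range) * stats::rbeta(n_sub, 2, 2)
    m_scaled <- (moisture - config$moisture_range[1]) / max(diff(config$moisture_range), 1e-12)
    frac_kept <- pmin(1, pmax(0.3, 1 - 0.45 * m_scaled + stats::rnorm(n_sub, 0, 0.09)))
    n_kept <- pmax(1L, pmin(n_taxa, as.integer(round(frac_kept * n_taxa))))

    load <- exp(stats::runif(n_sub, log(config$load_range[1]),
                             log(config$load_range[2])))

    concentration <- 120  # Dirichlet precision around the template
    intact <- matrix(0, n_taxa, n_sub, dimnames = list(taxa, subjects))
    for (s in seq_len(n_sub)) {
      base <- templates[[labels[s]]]
      comp <- rdirichlet1(base * concentration)
      comp <- comp * rlnorm_cv(n_taxa, 0.3)
      if (n_kept[s] < n_taxa) {
        drop <- order(comp)[seq_len(n_taxa - n_kept[s])]
        comp[drop] <- 0
      }
      comp <- comp / sum(comp)
      intact[, s] <- comp * load[s]
    }

    # extracellular/dead compartment: per-sample DNA fraction drawn from a Beta
    # around the configured mean; "proportional" death mirrors the intact
    # composition, "biased" draws per-taxon death propensities
    f <- stats::rbeta(n_sub, config$extracellular_mean * config$extracellular_precision,
                      (1 - config$extracellular_mean) * config$extracellular_precision)
    extracellular <- matrix(0, n_taxa, n_sub, dimnames = list(taxa, subjects))
    bias <- if (config$death_bias == "biased") rlnorm_cv(n_taxa, 1) else rep(1, n_taxa)
    for (s in seq_len(n_sub)) {
      w <- intact[, s] * bias
      dna_intact <- sum(k * intact[, s])
      dna_w <- sum(k * w)
      if (dna_w > 0) {
        # scale so that k-weighted (DNA-mass) extracellular fraction equals f_s
        scale <- f[s] / (1 - f[s]) * dna_intact / dna_w
        extracellular[, s] <- w * scale
      }
    }

    structure(list(
      taxa = taxa, copy_numbers = k, intact = intact,
      extracellular = extracellular, load = colSums(intact),
      enterotype = stats::setNames(labels, subjects),
      moisture = stats::setNames(moisture, subjects),
      richness = colSums(intact > 0),
      config = config, seed = config$seed
    ), class = "community_truth")
  })
}

#' @export
print.community_truth <- function(x, ...) {
  cat("Synthetic community truth\n")
  cat(sprintf("  %d taxa x %d subjects (%d replicates/subject when measured)\n",
              length(x$taxa), ncol(x$intact), x$config$n_replicates))
  cat(sprintf("  loads: %.3g - %.3g cells/g; enterotypes: %s\n",
              min(x$load), max(x$load),
              paste(names(table(x$enterotype)), table(x$enterotype),
                    sep = "=", collapse = ", ")))
  dna_i <- colSums(x$copy_numbers * x$intact)
  dna_e <- colSums(x$copy_numbers * x$extracellular)
  cat(sprintf("  mean extracellular DNA fraction: %.3f\n",
              mean(dna_e / (dna_i + dna_e))))
  invisible(x)
}

sample_grid <- function(truth) {
  n_rep <- truth$config$n_replicates
  subjects <- colnames(truth$intact)
  data.frame(
    subject = rep(subjects, each = n_rep),
    replicate = rep(seq_len(n_rep), times = length(subjects)),
    sample_id = paste0(rep(subjects, each = n_rep), "_r",
                       rep(seq_len(n_rep), times = length(subjects))),
    stringsAsFactors = FALSE
  )
}

#' Simulate 16S amplicon sequencing of the synthetic cohort
#'
#' Draws multinomial read counts for every subject x replicate. Without PMA
#' treatment, a taxon's sampling probability is proportional to
#' `k_t * (intact_t + extracellular_t)` (sequencing sees all DNA, weighted by
#' 16S copy number); with PMA treatment the extracellular compartment is
#' excluded and probabilities are proportional to `k_t * intact_t`.
#'
#' @param truth a [generate_truth()] object.
#' @param treatment `"untreated"` or `"pma"`.
#' @param depths optional per-sample read depths (scalar or vector, recycled);
#'   defaults to uniform draws within the configured depth range.
#' @param seed integer seed; defaults to a sub-seed of the truth seed.
#' @return integer matrix, taxa x (subject x replicate) with column names like
#'   `"S01_r1"`; column sums equal the requested depths. Depths are attached as
#'   attribute `"depths"`.
#' @export
simulate_sequencing <- function(truth, treatment = c("untreated", "pma"),
                                depths = NULL, seed = NULL) {
  treatment <- match.arg(treatment)
  grid <- sample_grid(truth)
  k <- truth$copy_numbers
  seed <- seed %||% derive_seed(truth$seed, paste0("seq_", treatment))
  with_seed(seed, {
    if (is.null(depths)) {
      lo <- truth$config$depth_range[1]
      hi <- truth$config$depth_range[2]
      depths <- lo + sample.int(hi - lo + 1L, nrow(grid), replace = TRUE) - 1L
    }
    depths <- as.integer(rep_len(depths, nrow(grid)))
    if (any(depths < 1)) stop("sequencing depths must be >= 1", call. = FALSE)
    counts <- matrix(0L, length(truth$taxa), nrow(grid),
                     dimnames = list(truth$taxa, grid$sample_id))
    for (i in seq_len(nrow(grid))) {
      s <- grid$subject[i]
      w <- if (treatment == "untreated") {
        k * (truth$intact[, s] + truth$extracellular[, s])
      } else {
        k * truth$intact[, s]
      }
      if (sum(w) <= 0) stop("sample ", s, " has zero sequencable material", call. = FALSE)
      counts[, i] <- stats::rmultinom(1, depths[i], prob = w / sum(w))[, 1]
    }
    attr(counts, "depths") <- stats::setNames(depths, grid$sample_id)
    attr(counts, "treatment") <- treatment
    counts
  })
}

#' Simulate flow-cytometry cell counts
#'
#' Flow cytometry counts only intact cells: each subject x replicate
#' measurement is the true intact load times log-normal counting noise with the
#' given coefficient of variation. The extracellular compartment contributes
#' nothing.
#'
#' @param truth a [generate_truth()] object.
#' @param facs_cv coefficient of variation; defaults to the configured value.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id` (subject), `replicate`,
#'   `method` (`"facs"`), `treatment` (`"untreated"`), `value` (cells/gram),
#'   `units`.
#' @export
simulate_cell_counts <- function(truth, facs_cv = NULL, seed = NULL) {
  facs_cv <- facs_cv %||% truth$config$facs_cv
  if (facs_cv < 0) stop("facs_cv must be >= 0", call. = FALSE)
  grid <- sample_grid(truth)
  seed <- seed %||% derive_seed(truth$seed, "facs")
  with_seed(seed, {
    noise <- rlnorm_cv(nrow(grid), facs_cv)
    data.frame(
      sample_id = grid$subject, replicate = grid$replicate,
      method = "facs", treatment = "untreated",
      value = truth$load[grid$subject] * noise,
      units = "cells_per_gram",
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate molecular (qPCR/ddPCR) load quantification
#'
#' Models the measurement chain from feces to copies/gram: a per-aliquot DNA
#' extraction yield factor (log-normal, mean 1) multiplies the true 16S copy
#' content, and independent per-measurement technical noise is applied on top.
#' The yield factor is drawn once per subject x replicate aliquot and shared
#' between the untreated and PMA-treated halves of that aliquot (and between
#' qPCR and ddPCR runs on the same extract, via `yield_factors`), which is what
#' makes paired PMA differencing cancel extraction bias.
#'
#' Untreated measurements see `sum_t k_t (intact_t + extracellular_t)`;
#' PMA-treated measurements see `sum_t k_t intact_t`.
#'
#' @param truth a [generate_truth()] object.
#' @param method `"qpcr"` or `"ddpcr"`.
#' @param treatment `"untreated"`, `"pma"`, or `"both"` (paired on shared
#'   yield).
#' @param extraction_yield_cv,tech_cv noise levels; default to configured
#'   values.
#' @param seed integer seed.
#' @param yield_factors optional subject x replicate matrix of yield factors to
#'   reuse (e.g. to share an extract between qPCR and ddPCR); drawn if `NULL`
#'   and returned as attribute `"yield_factors"`.
#' @return data.frame with columns `sample_id`, `replicate`, `method`,
#'   `treatment`, `value` (copies/gram), `units`.
#' @export
simulate_molecular_load <- function(truth, method = c("qpcr", "ddpcr"),
                                    treatment = c("untreated", "pma", "both"),
                                    extraction_yield_cv = NULL, tech_cv = NULL,
                                    seed = NULL, yield_factors = NULL) {
  method <- match.arg(method)
  treatment <- match.arg(treatment)
  extraction_yield_cv <- extraction_yield_cv %||% truth$config$extraction_yield_cv
  tech_cv <- tech_cv %||% truth$config$qpcr_tech_cv
  grid <- sample_grid(truth)
  k <- truth$copy_numbers
  dna_untreated <- colSums(k * (truth$intact + truth$extracellular))
  dna_pma <- colSums(k * truth$intact)
  seed <- seed %||% derive_seed(truth$seed, paste0("mol_", method))
  with_seed(seed, {
    if (is.null(yield_factors)) {
      subjects <- unique(grid$subject)
      n_rep <- truth$config$n_replicates
      yield_factors <- matrix(
        rlnorm_cv(length(subjects) * n_rep, extraction_yield_cv),
        nrow = length(subjects), ncol = n_rep,
        dimnames = list(subjects, as.character(seq_len(n_rep)))
      )
    }
    one <- function(trt) {
      expected <- if (trt == "untreated") dna_untreated else dna_pma
      y <- yield_factors[cbind(grid$subject, as.character(grid$replicate))]
      data.frame(
        sample_id = grid$subject, replicate = grid$replicate,
        method = method, treatment = trt,
        value = y * expected[grid$subject] * rlnorm_cv(nrow(grid), tech_cv),
        units = "copies_per_gram",
        stringsAsFactors = FALSE
      )
    }
    out <- if (treatment == "both") {
      rbind(one("untreated"), one("pma"))
    } else {
      one(treatment)
    }
    attr(out, "yield_factors") <- yield_factors
    out
  })
}

#' Simulate a full study: truth plus every measurement channel
#'
#' Convenience wrapper running [generate_truth()] and all measurement
#' simulators with sub-seeds derived from the config seed: untreated and
#' PMA-treated sequencing, flow-cytometry counts, and paired qPCR/ddPCR loads
#' sharing per-aliquot extraction yields.
#'
#' @param config a [qmp_sim_config()] object.
#' @return list with elements `truth`, `counts_untreated`, `counts_pma`,
#'   `facs`, `qpcr` (untreated + pma, paired), `ddpcr`.
#' @export
simulate_study <- function(config = qmp_sim_config()) {
  truth <- generate_truth(config)
  counts_u <- simulate_sequencing(truth, "untreated")
  counts_p <- simulate_sequencing(truth, "pma")
  facs <- simulate_cell_counts(truth)
  qpcr <- simulate_molecular_load(truth, "qpcr", "both")
  ddpcr <- simulate_molecular_load(truth, "ddpcr", "both",
                                   yield_factors = attr(qpcr, "yield_factors"))
  list(truth = truth, counts_untreated = counts_u, counts_pma = counts_p,
       facs = facs, qpcr = qpcr, ddpcr = ddpcr)
}
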