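# TSV input/output for count tables, copy-number tables and load measurements,
# plus the end-to-end study orchestrator. All files are plain tab-separated
# UTF-8 with '.' decimal separators; simulated and real data use the same
# formats and are interchangeable.

#' Read a taxon-by-sample count table from TSV
#'
#' First column: taxon id; remaining columns: integer counts per sample.
#'
#' @param path file path.
#' @return integer matrix, taxa x samples.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || nrow(df) < 1) stop("empty or malformed count table", call. = FALSE)
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon ids in ", path, ": ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path, call. = FALSE)
  bad <- which(m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid count at taxon '", taxa[bad[1, 1]], "', sample '",
         colnames(m)[bad[1, 2]], "' in ", path, call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- taxa
  m
}

#' Write a taxon-by-sample table to TSV
#'
#' @param x matrix with taxon rownames (counts or abundances).
#' @param path output path.
#' @param id_column header for the taxon-id column.
#' @export
write_count_table <- function(x, path, id_column = "taxon") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column taxon copy-number table from TSV
#'
#' Columns: taxon id, 16S copies per genome (>= 1).
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
read_copy_number_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("copy-number table needs 2 columns", call. = FALSE)
  k <- as.numeric(df[[2]])
  if (any(is.na(k)) || any(k < 1)) {
    stop("copy numbers must be numeric and >= 1", call. = FALSE)
  }
  if (anyDuplicated(df[[1]])) stop("duplicate taxon ids", call. = FALSE)
  stats::setNames(k, as.character(df[[1]]))
}

#' Read/write a load-measurement table
#'
#' Long format with columns `sample_id`, `replicate`, `method`
#' (`facs`/`qpcr`/`ddpcr`), `treatment` (`untreated`/`pma`), `value`, `units`
#' (`cells_per_gram`/`copies_per_gram`).
#'
#' @param path file path.
#' @return data.frame with the columns above.
#' @export
read_load_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "replicate", "method", "treatment", "value", "units")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("load table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(df$method %in% c("facs", "qpcr", "ddpcr"))) {
    stop("unknown method in load table", call. = FALSE)
  }
  if (!all(df$treatment %in% c("untreated", "pma"))) {
    stop("unknown treatment in load table", call. = FALSE)
  }
  if (any(df$value < 0)) stop("negative load values", call. = FALSE)
  df[needed]
}

#' @rdname read_load_table
#' @param x a load-measurement data.frame.
#' @export
write_load_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Subject-level loads from a measurement table: mean over a subject's
# replicate measurements, expanded to the subject's sequencing samples.
subject_loads <- function(measurements, sample_ids, per_replicate = FALSE) {
  info <- parse_sample_ids(sample_ids)
  if (per_replicate) {
    key <- paste0(measurements$sample_id, "_r", measurements$replicate)
    v <- tapply(measurements$value, key, mean)
    missing <- setdiff(sample_ids, names(v))
    if (length(missing)) {
      stop("missing per-replicate loads for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    return(v[sample_ids])
  }
  by_subject <- tapply(measurements$value, measurements$sample_id, mean)
  missing <- setdiff(info$subject, names(by_subject))
  if (length(missing)) {
    stop("missing loads for subjects: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(as.numeric(by_subject[info$subject]), sample_ids)
}

#' Run the full quantitative-profiling comparison on a simulated cohort
#'
#' Orchestrates the end-to-end analysis: simulate a cohort (or accept a
#' pre-simulated one), build the four profiles (RMP; QMP and QMP-PMA anchored
#' to subject-averaged flow-cytometry loads; QMP-qPCR anchored to qPCR
#' copies/gram), then compute per-sample richness, the within/between-method
#' Bray-Curtis dissimilarity analysis, per-genus rank concordance against RMP,
#' the paired PMA differencing estimate of the extracellular DNA fraction, and
#' DMM enterotyping with a load comparison between the two clusters.
#'
#' @param config a [qmp_sim_config()]; its seed drives every stage.
#' @param study optional pre-built [simulate_study()] result (overrides
#'   `config`).
#' @param methods subset of `c("RMP", "QMP", "QMP-PMA", "QMP-qPCR")`.
#' @param per_replicate_loads anchor QMP to per-replicate instead of
#'   subject-averaged cell counts.
#' @param normalize_bc compute Bray-Curtis on renormalized rows (see
#'   [bray_curtis_matrix()]).
#' @param K_range,enterotype_depth DMM candidate K and the even depth counts
#'   are rarefied to before clustering.
#' @param out_dir optional directory; when given, all tables are written as
#'   TSV alongside a `run_info.txt` recording seed and configuration.
#' @return list with `profiles`, `richness`, `dissimilarity`, `concordance`
#'   (per-genus tau vs RMP), `extracellular`, `enterotypes` (selected fit and
#'   labels, the two-component labels `labels_k2`, and the between-cluster
#'   load test), `truth`, `seed`.
#' @export
run_qmp_study <- function(config = qmp_sim_config(),
                          study = NULL,
                          methods = c("RMP", "QMP", "QMP-PMA", "QMP-qPCR"),
                          per_replicate_loads = FALSE,
                          normalize_bc = FALSE,
                          K_range = 1:3,
                          enterotype_depth = 10000,
                          out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  study <- study %||% simulate_study(config)
  truth <- study$truth
  seed <- truth$config$seed
  k <- truth$copy_numbers
  samples <- colnames(study$counts_untreated)

  facs_loads <- subject_loads(study$facs, samples, per_replicate_loads)
  qpcr_untreated <- study$qpcr[study$qpcr$treatment == "untreated", ]
  qpcr_loads_cpg <- subject_loads(qpcr_untreated, samples, per_replicate_loads)

  profiles <- list()
  if ("RMP" %in% methods) {
    profiles$RMP <- rmp_profile(study$counts_untreated,
                                seed = derive_seed(seed, "profile_rmp"))
  }
  if ("QMP" %in% methods) {
    profiles$QMP <- qmp_profile(study$counts_untreated, k, facs_loads,
                                seed = derive_seed(seed, "profile_qmp"))
  }
  if ("QMP-PMA" %in% methods) {
    profiles[["QMP-PMA"]] <- qmp_profile(study$counts_pma, k, facs_loads,
                                         seed = derive_seed(seed, "profile_pma"),
                                         method_tag = "QMP-PMA")
  }
  if ("QMP-qPCR" %in% methods) {
    profiles[["QMP-qPCR"]] <- qmp_qpcr_profile(study$counts_untreated, k,
                                               qpcr_loads_cpg,
                                               seed = derive_seed(seed, "profile_qpcr"))
  }

  richness <- vapply(profiles, function(p) observed_richness(p), integer(length(samples)))

  dissimilarity <- if (length(profiles) >= 2) {
    replicate_dissimilarity_analysis(profiles, normalize = normalize_bc)
  } else NULL

  concordance <- NULL
  if ("RMP" %in% names(profiles) && length(profiles) >= 2) {
    others <- setdiff(names(profiles), "RMP")
    concordance <- do.call(rbind, lapply(others, function(me) {
      tc <- top_genus_rank_concordance(profiles$RMP, profiles[[me]],
                                       reference = profiles$RMP,
                                       n_top = min(15, length(truth$taxa)))
      tc$comparison <- paste("RMP vs", me)
      tc
    }))
  }

  # paired PMA differencing on the qPCR channel (shared extraction yield)
  qu <- study$qpcr[study$qpcr$treatment == "untreated", ]
  qp <- study$qpcr[study$qpcr$treatment == "pma", ]
  key <- function(d) paste0(d$sample_id, "_r", d$replicate)
  extracellular <- estimate_extracellular_fraction(
    stats::setNames(qu$value, key(qu)),
    stats::setNames(qp$value, key(qp))
  )

  # enterotyping on counts rarefied to a common moderate depth
  ent_counts <- vapply(seq_along(samples), function(j) {
    col <- study$counts_untreated[, j]
    rarefy_counts(col, min(enterotype_depth, sum(col)),
                  seed = derive_seed(seed, "ent", j))
  }, integer(length(truth$taxa)))
  dimnames(ent_counts) <- dimnames(study$counts_untreated)
  fit <- fit_dmm(ent_counts, K_range = K_range, seed = derive_seed(seed, "dmm"))
  labels <- dmm_assign(fit)
  # the two-component solution is always kept for the binary enterotype
  # comparison (load shift between the two community types), regardless of
  # which K the evidence criterion selects
  fit_k2 <- if (fit$K == 2) fit else
    fit_dmm(ent_counts, K_range = 2, seed = derive_seed(seed, "dmm"))
  labels_k2 <- dmm_assign(fit_k2)
  load_test <- if (length(unique(labels_k2)) == 2) {
    loads_by_cluster_test(labels_k2, facs_loads[names(labels_k2)])
  } else NULL

  out <- list(profiles = profiles, richness = richness,
              dissimilarity = dissimilarity, concordance = concordance,
              extracellular = extracellular,
              enterotypes = list(fit = fit, labels = labels,
                                 labels_k2 = labels_k2,
                                 load_test = load_test),
              truth = truth, seed = seed)

  if (!is.null(out_dir)) write_study_outputs(out, study, out_dir)
  out
}

write_study_outputs <- function(result, study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (me in names(result$profiles)) {
    p <- result$profiles[[me]]
    write_count_table(p$abundance,
                      file.path(out_dir, paste0("profile_", gsub("-", "_", me), ".tsv")))
  }
  utils::write.table(data.frame(sample_id = rownames(result$richness),
                                result$richness, check.names = FALSE),
                     file.path(out_dir, "richness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$dissimilarity)) {
    utils::write.table(result$dissimilarity$within,
                       file.path(out_dir, "within_method_bc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$dissimilarity$between,
                       file.path(out_dir, "between_method_bc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$concordance)) {
    utils::write.table(result$concordance,
                       file.path(out_dir, "rank_concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(sample_id = names(result$enterotypes$labels),
                                cluster = result$enterotypes$labels),
                     file.path(out_dir, "enterotype_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$enterotypes$fit$model_selection,
                     file.path(out_dir, "enterotype_model_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_load_table(rbind(study$facs, study$qpcr, study$ddpcr),
                   file.path(out_dir, "load_measurements.tsv"))
  cfg <- result$truth$config
  writeLines(c(
    sprintf("qmprofiler run  seed=%d", result$seed),
    sprintf("config_hash=%08x", config_hash(cfg)),
    utils::capture.output(utils::str(unclass(cfg)))
  ), file.path(out_dir, "run_info.txt"))
  invisible(out_dir)
}
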