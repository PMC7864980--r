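# End-to-end orchestration: read -> decontaminate -> diagnostics ->
# diversity -> core contaminants -> (optional) spike-in scoring, with all
# tabular outputs and a run log. Stage order is fixed; correlation
# diagnostics are always computed before removal by construction.

kit_pairs <- function(kits) {
  if (length(kits) < 2L) return(NULL)
  utils::combn(sort(kits), 2L, simplify = FALSE)
}

alpha_kit_tests <- function(table, alpha_div) {
  m <- table$meta
  rows <- list()
  for (type in c("cancerous", "healthy")) {
    for (pair in kit_pairs(unique(m$extraction_kit))) {
      pa <- m[m$sample_type == type & m$extraction_kit == pair[1L], ]
      pb <- m[m$sample_type == type & m$extraction_kit == pair[2L], ]
      common <- intersect(pa$patient_id, pb$patient_id)
      if (length(common) < 3L) next
      a <- alpha_div[pa$sample_id[match(common, pa$patient_id)]]
      b <- alpha_div[pb$sample_id[match(common, pb$patient_id)]]
      t_p <- tryCatch(paired_ttest(a, b)$p_value,
                      error = function(e) NA_real_)
      w_p <- tryCatch(paired_wilcoxon(a, b)$p_value,
                      error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue_type = type, kit_a = pair[1L], kit_b = pair[2L],
        n_pairs = length(common), mean_diff = mean(a - b),
        paired_t_p = t_p, paired_wilcoxon_p = w_p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Run the full decontamination workflow
#'
#' Fixed stage order: load (when file paths are given), per-patient
#' ratio-based decontamination with pre-removal control diagnostics,
#' Shannon alpha diversity with paired kit comparisons per tissue type
#' (paired on patient), Bray-Curtis (weighted and unweighted) with PCoA
#' and one-way permutation ADONIS on the controls grouped by extraction
#' kit, core-contaminant profiling, and optional mock-community spike-in
#' scoring. All results are written as TSVs under `out_dir` together with
#' a run log naming package version, seed and parameters.
#'
#' @param table An [otu_table()]; alternatively give the three file paths.
#' @param shared,taxonomy,metadata Paths to the `.shared`,
#'   `.cons.taxonomy` and metadata TSV files (used when `table` is NULL).
#' @param qc Optional path to an extraction-QC TSV (see [read_qc()]).
#' @param panel Optional [mock_panel()] (or path to a panel TSV).
#' @param spike_samples Sample ids of spiked replicates to score against
#'   `panel`; spike-in scoring is skipped (and logged) when missing.
#' @param out_dir Output directory.
#' @param params A [lungdecon_params()].
#' @param seed Integer seed for the ADONIS permutations.
#' @return Invisibly, a list with the stage results (`decontam`, `alpha`,
#'   `alpha_tests`, `adonis`, `pcoa`, `core`, `spikein`, `qc`) and
#'   `files`, the paths written.
#' @export
run_pipeline <- function(table = NULL, shared = NULL, taxonomy = NULL,
                         metadata = NULL, qc = NULL, panel = NULL,
                         spike_samples = NULL, out_dir,
                         params = lungdecon_params(), seed = 1L) {
  log <- character(0L)
  say <- function(...) log <<- c(log, sprintf(...))
  say("lungdecon %s", as.character(utils::packageVersion("lungdecon")))
  say("seed: %d", as.integer(seed))
  say(paste0("parameters: ratio_threshold=%g core_abundance_cutoff=%g ",
             "core_frequency_cutoff=%g permutations=%d alpha=%g"),
      params$ratio_threshold, params$core_abundance_cutoff,
      params$core_frequency_cutoff, params$permutations, params$alpha)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0L)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_report(df, path)
    files <<- c(files, path)
  }

  if (is.null(table)) {
    say("stage load: %s", paste(basename(c(shared, taxonomy, metadata)),
                                collapse = ", "))
    table <- load_study(shared, taxonomy, metadata)
  } else {
    say("stage load: in-memory table")
  }
  say("table: %d samples x %d OTUs", nrow(table$counts),
      ncol(table$counts))

  trips <- patient_triplets(table, require_complete = FALSE)
  has_triplets <- nrow(trips) > 0L &&
    any(!is.na(trips$cancerous) & !is.na(trips$healthy) &
          !is.na(trips$control))
  dec <- NULL
  if (has_triplets) {
    say("stage decontam: ratio threshold %g", params$ratio_threshold)
    dec <- decontaminate(table, params)
    write_shared(dec$filtered_table, file.path(out_dir, "filtered.shared"))
    files <- c(files, file.path(out_dir, "filtered.shared"))
    emit(dec$diagnostics, "decontam_diagnostics.tsv")
    removal <- do.call(rbind, lapply(dec$patients, function(p)
      cbind(patient_id = p$patient_id, extraction_kit = p$extraction_kit,
            p$decisions)))
    emit(removal, "removal_report.tsv")
  } else {
    say("stage decontam skipped: no complete patient triplet")
  }

  say("stage diversity: Shannon + paired kit tests")
  tissues <- subset_samples(table, sample_type != "control")
  alpha <- shannon_diversity(tissues)
  emit(data.frame(sample_id = names(alpha), shannon = unname(alpha),
                  stringsAsFactors = FALSE), "alpha_diversity.tsv")
  atests <- alpha_kit_tests(tissues, alpha)
  if (!is.null(atests)) emit(atests, "alpha_kit_tests.tsv")
  else say("  paired kit tests skipped: fewer than 3 complete pairs")

  controls <- subset_samples(table, sample_type == "control")
  adonis_res <- NULL; pcoa_res <- NULL
  if (nrow(controls$counts) >= 3L &&
      length(unique(controls$meta$extraction_kit)) >= 2L) {
    say("stage beta: Bray-Curtis + PCoA + ADONIS on %d controls (%d perms)",
        nrow(controls$counts), params$permutations)
    adonis_res <- list(); pcoa_res <- list()
    for (w in c(TRUE, FALSE)) {
      tag <- if (w) "weighted" else "unweighted"
      d <- bray_curtis(controls, weighted = w)
      emit(cbind(sample_id = attr(d, "Labels"),
                 as.data.frame(as.matrix(d))),
           sprintf("braycurtis_%s.tsv", tag))
      pc <- pcoa(d)
      pcoa_res[[tag]] <- pc
      emit(cbind(sample_id = rownames(pc$coordinates),
                 as.data.frame(pc$coordinates)),
           sprintf("pcoa_%s.tsv", tag))
      ad <- permanova(d, controls$meta$extraction_kit,
                      permutations = params$permutations, seed = seed)
      adonis_res[[tag]] <- ad
      emit(data.frame(metric = tag, pseudo_F = ad$pseudo_F,
                      r_squared = ad$r_squared, p_value = ad$p_value,
                      permutations = ad$permutations_used,
                      stringsAsFactors = FALSE),
           sprintf("adonis_%s.tsv", tag))
    }
  } else {
    say("stage beta skipped: need >= 3 controls over >= 2 kits")
  }

  core <- NULL
  if (nrow(controls$counts) > 0L) {
    say("stage core: abundance cutoff %g, frequency cutoff %g",
        params$core_abundance_cutoff, params$core_frequency_cutoff)
    core <- core_contaminants(table, params)
  } else {
    say("stage core skipped: no control samples")
  }
  if (!is.null(core) && !is.null(core$regions)) {
    emit(core$regions, "core_regions.tsv")
    emit(core$non_core, "core_non_core.tsv")
    emit(core$membership, "core_membership.tsv")
    center <- core$membership$otu_id[
      core$membership$region == region_name(names(core$core_sets))]
    emit(genus_profile(center, core$controls_table),
         "core_genus_profile.tsv")
  }

  spike <- NULL
  if (!is.null(panel) && !is.null(spike_samples)) {
    if (is.character(panel)) panel <- mock_panel(panel)
    say("stage spikein: %d replicate(s) against %d-strain panel",
        length(spike_samples), nrow(panel))
    spiked <- subset_samples(table, sample_id %in% spike_samples)
    spike <- detect_spikein(spiked, panel)
    emit(data.frame(replicate = rownames(spike$detection),
                    percent = spike$percent, stringsAsFactors = FALSE),
         "spikein_report.tsv")
  } else {
    say("stage spikein skipped: no panel/spiked samples given")
  }

  qc_df <- NULL
  if (!is.null(qc)) {
    say("stage qc: DNA yield per gram")
    qc_df <- read_qc(qc)
    emit(qc_df, "qc_yield.tsv")
  }

  writeLines(log, file.path(out_dir, "run_log.txt"))
  files <- c(files, file.path(out_dir, "run_log.txt"))
  invisible(list(decontam = dec, alpha = alpha, alpha_tests = atests,
                 adonis = adonis_res, pcoa = pcoa_res, core = core,
                 spikein = spike, qc = qc_df, files = files, log = log))
}
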