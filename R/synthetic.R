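# Synthetic study generator: patient triplets with kit-specific
# contaminant profiles, endogenous tissue communities, multinomial
# sequencing at fixed depth, and ground-truth contaminant labels — so the
# whole pipeline is testable without any sequencing download.

CONTAM_GENERA <- c("Brevundimonas", "Cutibacterium", "Micrococcus",
                   "Nitrobacter", "Ralstonia", "Staphylococcus",
                   "Xanthobacteraceae_unclassified", "Pelomonas",
                   "Sphingomonas", "Methylobacterium", "Bradyrhizobium",
                   "Acinetobacter", "Burkholderia", "Delftia",
                   "Comamonas", "Herbaspirillum")

ENDO_GENERA <- c("Streptococcus", "Prevotella", "Veillonella",
                 "Haemophilus", "Neisseria", "Fusobacterium",
                 "Rothia", "Porphyromonas", "Gemella", "Actinomyces",
                 "Leptotrichia", "Granulicatella", "Campylobacter",
                 "Capnocytophaga", "Megasphaera", "Selenomonas")

#' Configuration of a synthetic study
#'
#' Defaults echo the emulated study design: 5 patients, each contributing a
#' cancerous/healthy/control triplet under all three extraction kits;
#' 20,000 reads per sample; 10 core contaminant taxa shared by every kit
#' plus 30 kit-specific contaminant taxa per kit; an endogenous tissue
#' community of 40 taxa of which a `contaminant_fraction_in_tissue` = 0.05
#' expected read share is replaced by the kit's contaminant profile.
#' Controls contain contaminant reads only (an empty tube accumulates
#' exactly the method's contaminants) unless `leakage > 0`.
#'
#' @param n_patients Number of patients (default 5).
#' @param kits Subset of [EXTRACTION_KITS] (default all three).
#' @param depth Reads per sample (default 20000).
#' @param n_endogenous_taxa Endogenous community size (default 40).
#' @param n_core_contaminants Contaminant taxa shared across kits
#'   (default 10).
#' @param n_kit_specific_contaminants Contaminant taxa private to each kit
#'   (default 30).
#' @param contaminant_fraction_in_tissue Expected fraction of a tissue's
#'   reads coming from the contaminant profile (default 0.05).
#' @param tissue_dirichlet_alpha Dirichlet concentration of the endogenous
#'   profile (default 0.5; < 1 gives the skewed abundance distributions
#'   typical of amplicon data).
#' @param cancer_vs_healthy_perturbation Log-scale s.d. of the
#'   patient-level cancerous-vs-healthy perturbation (default 0.5).
#' @param leakage Fraction of control reads drawn from the patient's
#'   endogenous profile (default 0; for cross-contamination stress tests).
#' @param seed Integer seed (required; identical seeds give bit-identical
#'   studies).
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_patients = 5, kits = EXTRACTION_KITS,
                         depth = 20000, n_endogenous_taxa = 40,
                         n_core_contaminants = 10,
                         n_kit_specific_contaminants = 30,
                         contaminant_fraction_in_tissue = 0.05,
                         tissue_dirichlet_alpha = 0.5,
                         cancer_vs_healthy_perturbation = 0.5,
                         leakage = 0, seed) {
  if (missing(seed)) stop("`seed` is required")
  kits <- match.arg(kits, EXTRACTION_KITS, several.ok = TRUE)
  stopifnot(n_patients >= 1, depth > 0, n_endogenous_taxa >= 1,
            n_core_contaminants >= 0, n_kit_specific_contaminants >= 0,
            n_core_contaminants + n_kit_specific_contaminants >= 1,
            contaminant_fraction_in_tissue >= 0,
            contaminant_fraction_in_tissue < 1,
            tissue_dirichlet_alpha > 0,
            cancer_vs_healthy_perturbation >= 0,
            leakage >= 0, leakage < 1)
  structure(list(n_patients = as.integer(n_patients), kits = kits,
                 depth = as.integer(depth),
                 n_endogenous_taxa = as.integer(n_endogenous_taxa),
                 n_core_contaminants = as.integer(n_core_contaminants),
                 n_kit_specific_contaminants =
                   as.integer(n_kit_specific_contaminants),
                 contaminant_fraction_in_tissue =
                   contaminant_fraction_in_tissue,
                 tissue_dirichlet_alpha = tissue_dirichlet_alpha,
                 cancer_vs_healthy_perturbation =
                   cancer_vs_healthy_perturbation,
                 leakage = leakage, seed = as.integer(seed)),
            class = "synth_config")
}

rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)   # degenerate draw guard
  g / sum(g)
}

# recycle a base-name pool into unique labels (Ralstonia, Ralstonia_2, ...)
label_pool <- function(pool, n) {
  reps <- ceiling(n / length(pool))
  lab <- unlist(lapply(seq_len(reps), function(r)
    if (r == 1L) pool else paste0(pool, "_", r)))
  lab[seq_len(n)]
}

synth_taxonomy <- function(otu_ids, genera) {
  tax <- data.frame(otu_id = otu_ids, domain = "Bacteria",
                    phylum = "Bacteria_unclassified",
                    class = "Bacteria_unclassified",
                    order = "Bacteria_unclassified",
                    family = "Bacteria_unclassified",
                    genus = genera, stringsAsFactors = FALSE)
  tax
}

#' Simulate a complete synthetic study
#'
#' Per kit, one contaminant profile is drawn from a Dirichlet over the
#' union of core and kit-specific contaminant taxa. Per patient, one
#' endogenous profile is drawn over the endogenous taxa, then perturbed
#' log-normally (independently per tissue) into cancerous and healthy
#' variants. Control reads are multinomial draws at `depth` from the kit's
#' contaminant profile; tissue reads from the mixture
#' `(1 - f) * endogenous + f * contaminant` with
#' `f = contaminant_fraction_in_tissue`. Every sample row totals exactly
#' `depth`; identical seeds give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A list of class `"synth_study"`: `table` (an [otu_table()]),
#'   `truth` (`data.frame` `otu_id`, `label` in
#'   `{endogenous, core_contaminant, kit_contaminant:<kit>}`),
#'   `mixture_weights` (per-sample contaminant fraction),
#'   `profiles` (the generating probability vectors), `config`.
#' @examples
#' study <- simulate_study(synth_config(n_patients = 2, seed = 42))
#' study$table
#' head(study$truth)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cg <- config

  endo_ids <- sprintf("Otu%04d", seq_len(cg$n_endogenous_taxa))
  core_ids <- if (cg$n_core_contaminants)
    sprintf("Ctm%04d", seq_len(cg$n_core_contaminants)) else character(0L)
  kit_ids <- stats::setNames(lapply(seq_along(cg$kits), function(i)
    if (cg$n_kit_specific_contaminants)
      sprintf("Ctm%s%03d", substr(cg$kits[i], 1L, 2L),
              seq_len(cg$n_kit_specific_contaminants)) else character(0L)),
    cg$kits)
  taxa <- c(endo_ids, core_ids, unlist(kit_ids, use.names = FALSE))

  genera <- c(label_pool(ENDO_GENERA, length(endo_ids)),
              label_pool(CONTAM_GENERA,
                         length(taxa) - length(endo_ids)))
  taxonomy <- synth_taxonomy(taxa, genera)

  truth <- data.frame(otu_id = taxa,
                      label = c(rep("endogenous", length(endo_ids)),
                                rep("core_contaminant", length(core_ids)),
                                unlist(lapply(cg$kits, function(k)
                                  rep(paste0("kit_contaminant:", k),
                                      length(kit_ids[[k]]))),
                                  use.names = FALSE)),
                      stringsAsFactors = FALSE)

  p <- length(taxa)
  idx <- stats::setNames(seq_len(p), taxa)

  contam_profile <- list()
  for (k in cg$kits) {
    support <- c(core_ids, kit_ids[[k]])
    prof <- numeric(p)
    prof[idx[support]] <- rdirichlet1(length(support), 1)
    contam_profile[[k]] <- prof
  }

  samples <- list(); meta <- list(); weights <- list()
  endo_profiles <- list()
  for (pt in seq_len(cg$n_patients)) {
    pid <- sprintf("P%02d", pt)
    base <- numeric(p)
    base[idx[endo_ids]] <- rdirichlet1(length(endo_ids),
                                       cg$tissue_dirichlet_alpha)
    endo_profiles[[pid]] <- base
    variant <- function() {
      v <- base
      nz <- v > 0
      v[nz] <- v[nz] * exp(stats::rnorm(sum(nz), 0,
                                        cg$cancer_vs_healthy_perturbation))
      v / sum(v)
    }
    endo_c <- variant()
    endo_h <- variant()
    for (k in cg$kits) {
      f <- cg$contaminant_fraction_in_tissue
      probs <- list(
        cancerous = (1 - f) * endo_c + f * contam_profile[[k]],
        healthy = (1 - f) * endo_h + f * contam_profile[[k]],
        control = (1 - cg$leakage) * contam_profile[[k]] +
          cg$leakage * base)
      for (type in names(probs)) {
        sid <- sprintf("%s_%s_%s", pid, k,
                       c(cancerous = "can", healthy = "hea",
                         control = "ctl")[[type]])
        samples[[sid]] <- as.integer(
          stats::rmultinom(1L, cg$depth, probs[[type]]))
        meta[[sid]] <- data.frame(sample_id = sid, patient_id = pid,
                                  sample_type = type, extraction_kit = k,
                                  replicate = 1L,
                                  stringsAsFactors = FALSE)
        weights[[sid]] <- if (type == "control") 1 - cg$leakage else f
      }
    }
  }
  counts <- do.call(rbind, samples)
  rownames(counts) <- names(samples)
  colnames(counts) <- taxa
  table <- otu_table(counts, taxonomy, do.call(rbind, meta))
  structure(list(table = table, truth = truth,
                 mixture_weights = unlist(weights),
                 profiles = list(contaminant = contam_profile,
                                 endogenous = endo_profiles),
                 config = cg),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cg <- x$config
  cat(sprintf(
    "synth_study: %d patients x %d kit(s), depth %d, seed %d\n",
    cg$n_patients, length(cg$kits), cg$depth, cg$seed))
  cat(sprintf("  taxa: %d endogenous, %d core + %d/kit contaminants\n",
              cg$n_endogenous_taxa, cg$n_core_contaminants,
              cg$n_kit_specific_contaminants))
  print(x$table)
  invisible(x)
}

#' Score decontamination against the generator's ground truth
#'
#' Micro-averaged over all patient triplets: sensitivity is the fraction
#' of contaminant-labelled OTUs observed in a triplet's tissues that the
#' rule removed; specificity the fraction of endogenous OTUs observed in
#' the tissues that it kept. An empty denominator yields `NA` (undefined),
#' not an error.
#'
#' @param result A `"decontam_result"` from [decontaminate()].
#' @param study The `"synth_study"` the result was computed from (or a
#'   truth `data.frame` plus `table`).
#' @param table Original (unfiltered) [otu_table()]; defaults to
#'   `study$table` when `study` is a `"synth_study"`.
#' @return A list: `sensitivity`, `specificity`, and the four underlying
#'   counts.
#' @export
evaluate_decontam <- function(result, study, table = NULL) {
  stopifnot(inherits(result, "decontam_result"))
  if (inherits(study, "synth_study")) {
    truth <- study$truth
    if (is.null(table)) table <- study$table
  } else {
    truth <- study
    if (is.null(table)) stop("`table` required when `study` is a truth table")
  }
  lab <- stats::setNames(truth$label, truth$otu_id)
  tp <- fn <- tn <- fp <- 0L
  for (pres in result$patients) {
    tissues <- rownames(pres$filtered_counts)
    observed <- colnames(table$counts)[
      colSums(table$counts[tissues, , drop = FALSE] > 0L) > 0L]
    contam <- observed[lab[observed] != "endogenous"]
    endo <- observed[lab[observed] == "endogenous"]
    rem <- pres$removed_otus
    tp <- tp + sum(contam %in% rem)
    fn <- fn + sum(!(contam %in% rem))
    fp <- fp + sum(endo %in% rem)
    tn <- tn + sum(!(endo %in% rem))
  }
  list(sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
       true_positives = tp, false_negatives = fn,
       true_negatives = tn, false_positives = fp)
}

#' Write a synthetic study to disk
#'
#' Emits the mothur-dialect `.shared` and `.cons.taxonomy` files, the
#' metadata TSV and the ground-truth TSV, all readable back through the
#' package's readers; a fixed seed gives byte-identical files.
#'
#' @param study A `"synth_study"`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix (default `"study"`).
#' @return Named character vector of the paths written.
#' @export
write_study <- function(study, out_dir, prefix = "study") {
  stopifnot(inherits(study, "synth_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(shared = file.path(out_dir, paste0(prefix, ".shared")),
             taxonomy = file.path(out_dir,
                                  paste0(prefix, ".cons.taxonomy")),
             metadata = file.path(out_dir,
                                  paste0(prefix, ".metadata.tsv")),
             truth = file.path(out_dir, paste0(prefix, ".truth.tsv")))
  write_shared(study$table, paths[["shared"]])
  tax <- study$table$taxonomy
  tax$size <- colSums(study$table$counts)
  write_cons_taxonomy(tax, paths[["taxonomy"]])
  write_sample_metadata(study$table$meta, paths[["metadata"]])
  write_report(study$truth, paths[["truth"]])
  paths
}
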