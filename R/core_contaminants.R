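# "Methodological core microbiota" of the negative controls: per-kit core
# OTU sets under a joint abundance/frequency rule, and their Venn partition
# across extraction kits with summed mean relative abundances.

#' Presence call at the core abundance cutoff
#'
#' An OTU counts as present in a control when its relative abundance is at
#' least the cutoff (default `1e-5`, i.e. 0.001 percent); inclusive at the
#' boundary.
#'
#' @param rel_abundance Relative abundance(s) in \[0,1\].
#' @param cutoff Presence cutoff (default `1e-5`).
#' @return Logical vector.
#' @export
abundance_present <- function(rel_abundance, cutoff = 1e-5) {
  stopifnot(all(rel_abundance >= 0 & rel_abundance <= 1))
  rel_abundance >= cutoff
}

#' Core contaminant OTUs of one extraction kit
#'
#' Within the controls of one kit, an OTU is "core" when it is present (at
#' least `core_abundance_cutoff` relative abundance) in at least
#' `ceiling(core_frequency_cutoff * n_controls)` of the controls — with the
#' defaults and five controls per kit, at least two of five. Mean relative
#' abundance is averaged across *all* the kit's controls, zeros included.
#' OTUs passing the abundance rule in at least one control but failing the
#' frequency rule form the "non-core" complement.
#'
#' Singletons should be removed from the pooled control table before
#' calling (see [core_contaminants()], which enforces the order).
#'
#' @param controls_table An [otu_table()] of negative controls.
#' @param kit One of [EXTRACTION_KITS].
#' @param params A [lungdecon_params()].
#' @return A list of class `"core_set"`: `kit`, `otu_ids`,
#'   `mean_abundance` (named, core OTUs), `non_core_otu_ids`,
#'   `non_core_mean_abundance`, `n_controls`, `min_controls`.
#' @export
core_set <- function(controls_table, kit, params = lungdecon_params()) {
  stopifnot(inherits(controls_table, "otu_table"))
  kit <- match.arg(kit, EXTRACTION_KITS)
  sub <- subset_samples(controls_table,
                        sample_type == "control" & extraction_kit == kit)
  n <- nrow(sub$counts)
  if (n == 0L) stop("no controls for kit ", kit)
  rel <- relative_abundances(sub)
  pres <- abundance_present(rel, params$core_abundance_cutoff)
  dim(pres) <- dim(rel)
  n_present <- colSums(pres)
  min_controls <- ceiling(params$core_frequency_cutoff * n)
  mean_ab <- colMeans(rel)
  core <- n_present >= min_controls
  non_core <- n_present >= 1L & !core
  otus <- colnames(sub$counts)
  structure(list(kit = kit, otu_ids = otus[core],
                 mean_abundance = mean_ab[core],
                 non_core_otu_ids = otus[non_core],
                 non_core_mean_abundance = mean_ab[non_core],
                 n_controls = n, min_controls = min_controls),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf(
    "core_set (%s): %d core OTU(s) in >= %d of %d controls; %d non-core\n",
    x$kit, length(x$otu_ids), x$min_controls, x$n_controls,
    length(x$non_core_otu_ids)))
  invisible(x)
}

region_name <- function(kits) paste(kits, collapse = "+")

#' Venn partition of per-kit core sets
#'
#' Classifies every OTU that is core for at least one kit by its exact kit
#' membership subset (7 possible regions for three kits). For each region
#' the OTU count and, per member kit, the summed mean relative abundance of
#' the region's OTUs in that kit's controls are reported — sums of means,
#' so they need not add up to 100 percent. Per-kit non-core totals are
#' attached.
#'
#' @param core_sets List of [core_set()] objects (>= 2 kits).
#' @return A list of class `"core_venn"`: `membership` (`data.frame`
#'   otu_id/region), `regions` (`data.frame` region/n_otus plus one summed
#'   abundance column per kit), `non_core` (`data.frame` per kit),
#'   `core_sets`.
#' @export
venn_partition <- function(core_sets) {
  stopifnot(length(core_sets) >= 2L,
            all(vapply(core_sets, inherits, logical(1L), "core_set")))
  kits <- vapply(core_sets, `[[`, character(1L), "kit")
  if (anyDuplicated(kits)) stop("duplicate kit in core_sets")
  names(core_sets) <- kits
  all_otus <- sort(unique(unlist(lapply(core_sets, `[[`, "otu_ids"))))
  member <- vapply(core_sets, function(cs) all_otus %in% cs$otu_ids,
                   logical(length(all_otus)))
  if (length(all_otus) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, kits))
  region <- apply(member, 1L, function(row) region_name(kits[row]))
  membership <- data.frame(otu_id = all_otus, region = region,
                           stringsAsFactors = FALSE)

  subsets <- unlist(lapply(seq_along(kits), function(k)
    utils::combn(kits, k, simplify = FALSE)), recursive = FALSE)
  regions <- data.frame(region = vapply(subsets, region_name,
                                        character(1L)),
                        n_otus = 0L, stringsAsFactors = FALSE)
  for (kit in kits) regions[[paste0("abundance_", kit)]] <- NA_real_
  for (i in seq_along(subsets)) {
    rkits <- subsets[[i]]
    rname <- region_name(rkits)
    otus <- membership$otu_id[membership$region == rname]
    regions$n_otus[i] <- length(otus)
    for (kit in rkits) {
      regions[[paste0("abundance_", kit)]][i] <-
        sum(core_sets[[kit]]$mean_abundance[otus])
    }
  }
  non_core <- data.frame(
    kit = kits,
    n_otus = vapply(core_sets, function(cs)
      length(cs$non_core_otu_ids), integer(1L)),
    abundance = vapply(core_sets, function(cs)
      sum(cs$non_core_mean_abundance), numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(non_core) <- NULL
  structure(list(membership = membership, regions = regions,
                 non_core = non_core, core_sets = core_sets),
            class = "core_venn")
}

#' @export
print.core_venn <- function(x, ...) {
  cat("Core-contaminant Venn partition\n")
  df <- x$regions
  ab <- grep("^abundance_", names(df))
  df[ab] <- lapply(df[ab], function(v) ifelse(is.na(v), "",
                                              sprintf("%.3g%%", 100 * v)))
  print(df, row.names = FALSE)
  cat("non-core (present but below the frequency cutoff):\n")
  nc <- x$non_core
  nc$abundance <- sprintf("%.3g%%", 100 * nc$abundance)
  print(nc, row.names = FALSE)
  invisible(x)
}

#' Per-genus abundance profile of an OTU set
#'
#' Agglomerates the member OTUs by genus and reports the per-kit mean
#' relative abundance of each genus in the kit's controls (sum of the
#' member OTUs' mean relative abundances). Genera are ordered by
#' decreasing overall abundance, ties broken alphabetically.
#'
#' @param otu_ids Character vector of OTU ids (e.g. one Venn region or a
#'   core set).
#' @param controls_table The controls [otu_table()] the core sets were
#'   computed from.
#' @return `data.frame` with `genus` and one mean-abundance column per
#'   kit present in `controls_table`.
#' @export
genus_profile <- function(otu_ids, controls_table) {
  stopifnot(inherits(controls_table, "otu_table"))
  kits <- sort(unique(controls_table$meta$extraction_kit))
  if (!length(otu_ids)) {
    out <- data.frame(genus = character(0L), stringsAsFactors = FALSE)
    for (kit in kits) out[[paste0("abundance_", kit)]] <- numeric(0L)
    return(out)
  }
  genus <- otu_genus(controls_table)[otu_ids]
  rel <- relative_abundances(controls_table)
  out <- data.frame(genus = sort(unique(genus)), stringsAsFactors = FALSE)
  for (kit in kits) {
    rows <- controls_table$meta$sample_id[
      controls_table$meta$extraction_kit == kit]
    mean_ab <- colMeans(rel[rows, otu_ids, drop = FALSE])
    out[[paste0("abundance_", kit)]] <- vapply(out$genus, function(g)
      sum(mean_ab[genus == g]), numeric(1L))
  }
  overall <- rowSums(as.matrix(out[, -1L, drop = FALSE]))
  out <- out[order(-overall, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full core-contaminant analysis of a study
#'
#' Pools all negative controls, removes singleton OTUs from that pooled
#' control table (in that order: the order changes totals), computes one
#' [core_set()] per extraction kit present and their [venn_partition()].
#'
#' @param table The full study [otu_table()].
#' @param params A [lungdecon_params()].
#' @return A `"core_venn"` object whose `controls_table` element holds the
#'   singleton-free pooled control table used.
#' @examples
#' study <- simulate_study(synth_config(n_patients = 3, seed = 1))
#' cv <- core_contaminants(study$table)
#' cv$regions
#' @export
core_contaminants <- function(table, params = lungdecon_params()) {
  controls <- subset_samples(table, sample_type == "control")
  if (!nrow(controls$counts)) stop("no control samples in table")
  controls <- remove_singletons(controls)
  kits <- sort(unique(controls$meta$extraction_kit))
  sets <- lapply(kits, function(k) core_set(controls, k, params))
  if (length(sets) >= 2L) {
    out <- venn_partition(sets)
  } else {
    out <- structure(list(membership = data.frame(
      otu_id = sets[[1L]]$otu_ids, region = kits,
      stringsAsFactors = FALSE),
      regions = NULL, non_core = NULL,
      core_sets = stats::setNames(sets, kits)), class = "core_venn")
  }
  out$controls_table <- controls
  out$params <- params
  out
}
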