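# Core data model: sample x OTU count matrix with consensus taxonomy and
# sample metadata. Counts stay integer; relative abundances are derived
# views, never stored back.

#' Taxonomic ranks used throughout the package
#'
#' The six-rank lineage (domain to genus) that mothur emits when classifying
#' against SILVA. Deeper input lineages are truncated, shallower ones padded
#' with `"<parent>_unclassified"`.
#'
#' @format Character vector of length 6.
#' @export
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Allowed sample types and extraction kits
#'
#' Study design vocabulary: every patient contributes a cancerous tissue, a
#' healthy tissue and a single negative (empty-tube) control, each processed
#' with one of three commercial DNA extraction kits.
#'
#' @name design-vocabulary
#' @format Character vectors.
#' @export
SAMPLE_TYPES <- c("cancerous", "healthy", "control")

#' @rdname design-vocabulary
#' @export
EXTRACTION_KITS <- c("Blood", "Microbial", "Powersoil")

#' Analysis parameters
#'
#' Bundles the tunable thresholds of the workflow with their defaults:
#' the tissue/control relative-abundance ratio above which a control-present
#' OTU is kept (`ratio_threshold`, 1000), the relative-abundance cutoff for
#' an OTU to count as present in a control (`core_abundance_cutoff`,
#' `1e-5`, i.e. 0.001 percent), the fraction of a kit's controls an OTU must
#' be present in to be "core" (`core_frequency_cutoff`, 0.40), the number of
#' ADONIS permutations (`permutations`, 5000) and the significance level
#' (`alpha`, 0.05).
#'
#' @param ratio_threshold Positive real; keep a control-present OTU only when
#'   its relative abundance in both tissues is strictly greater than
#'   `ratio_threshold` times its relative abundance in the control.
#' @param core_abundance_cutoff Fraction in (0,1); presence cutoff on
#'   relative abundance.
#' @param core_frequency_cutoff Fraction in (0,1]; minimum fraction of a
#'   kit's controls in which a core OTU must be present.
#' @param permutations Positive integer; ADONIS permutation count.
#' @param alpha Significance level in (0,1).
#' @return A list with class `"lungdecon_params"`.
#' @examples
#' p <- lungdecon_params()
#' p$ratio_threshold
#' @export
lungdecon_params <- function(ratio_threshold = 1000,
                             core_abundance_cutoff = 1e-5,
                             core_frequency_cutoff = 0.40,
                             permutations = 5000,
                             alpha = 0.05) {
  stopifnot(is.numeric(ratio_threshold), length(ratio_threshold) == 1L,
            ratio_threshold > 0)
  stopifnot(is.numeric(core_abundance_cutoff), core_abundance_cutoff > 0,
            core_abundance_cutoff < 1)
  stopifnot(is.numeric(core_frequency_cutoff), core_frequency_cutoff > 0,
            core_frequency_cutoff <= 1)
  stopifnot(is.numeric(permutations), permutations >= 1,
            permutations == round(permutations))
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(ratio_threshold = ratio_threshold,
                 core_abundance_cutoff = core_abundance_cutoff,
                 core_frequency_cutoff = core_frequency_cutoff,
                 permutations = as.integer(permutations),
                 alpha = alpha),
            class = "lungdecon_params")
}

#' Normalise a lineage to the fixed six-rank scheme
#'
#' Truncates lineages deeper than genus and pads shallower ones following the
#' mothur convention: each missing rank gets the deepest assigned label
#' suffixed with `"_unclassified"` (the suffix is not doubled when already
#' present).
#'
#' @param lineage Character vector of taxon labels, outermost rank first.
#' @return Character vector of length 6, named by [TAX_RANKS].
#' @examples
#' pad_lineage(c("Bacteria", "Proteobacteria"))
#' @export
pad_lineage <- function(lineage) {
  lineage <- as.character(lineage)
  lineage <- lineage[nzchar(lineage)]
  if (length(lineage) > 6L) lineage <- lineage[seq_len(6L)]
  if (length(lineage) < 6L) {
    base <- if (length(lineage)) lineage[length(lineage)] else "unclassified"
    pad <- if (base == "unclassified" || grepl("_unclassified$", base)) {
      base
    } else {
      paste0(base, "_unclassified")
    }
    lineage <- c(lineage, rep(pad, 6L - length(lineage)))
  }
  names(lineage) <- TAX_RANKS
  lineage
}

#' Build an OTU table
#'
#' The universal currency of the workflow: a samples x OTUs matrix of
#' nonnegative integer read counts joined, by name and never by position, to
#' a taxonomy table and a sample metadata table.
#'
#' @param counts Numeric matrix, rows = samples, columns = OTUs, with
#'   dimnames; nonnegative integers.
#' @param taxonomy `data.frame` with column `otu_id` plus the six rank
#'   columns of [TAX_RANKS]; every column of `counts` must appear.
#'   Alternatively a character vector of semicolon-delimited lineages named
#'   by OTU id.
#' @param meta `data.frame` with columns `sample_id`, `patient_id`,
#'   `sample_type` (one of [SAMPLE_TYPES]), `extraction_kit` (one of
#'   [EXTRACTION_KITS]) and `replicate`; every row of `counts` must appear.
#' @return An object of class `"otu_table"`: a list with elements `counts`,
#'   `taxonomy`, `meta`.
#' @examples
#' counts <- matrix(c(5L, 3L, 0L, 2L), nrow = 2, byrow = TRUE,
#'                  dimnames = list(c("S1", "S2"), c("Otu001", "Otu002")))
#' tax <- data.frame(otu_id = c("Otu001", "Otu002"),
#'                   t(sapply(list(c("Bacteria", "Firmicutes", "Bacilli",
#'                                   "Bacillales", "Staphylococcaceae",
#'                                   "Staphylococcus"),
#'                                 "Bacteria"), pad_lineage)))
#' meta <- data.frame(sample_id = c("S1", "S2"), patient_id = "P1",
#'                    sample_type = c("cancerous", "healthy"),
#'                    extraction_kit = "Blood", replicate = 1L)
#' tab <- otu_table(counts, tax, meta)
#' tab
#' @export
otu_table <- function(counts, taxonomy, meta) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in `counts`")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in `counts`")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"

  if (is.character(taxonomy)) {
    lins <- strsplit(taxonomy, ";", fixed = TRUE)
    taxonomy <- data.frame(otu_id = names(taxonomy),
                           t(vapply(lins, pad_lineage, character(6L))),
                           stringsAsFactors = FALSE)
  }
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  need <- c("otu_id", TAX_RANKS)
  if (!all(need %in% names(taxonomy)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  taxonomy <- taxonomy[, need]
  if (anyDuplicated(taxonomy$otu_id)) stop("duplicate otu_id in taxonomy")
  missing_tax <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(missing_tax))
    stop("OTUs without taxonomy: ", paste(missing_tax, collapse = ", "))
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), ,
                       drop = FALSE]
  rownames(taxonomy) <- NULL

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needm <- c("sample_id", "patient_id", "sample_type", "extraction_kit",
             "replicate")
  if (!all(needm %in% names(meta)))
    stop("meta must have columns: ", paste(needm, collapse = ", "))
  meta <- meta[, needm]
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in meta")
  missing_meta <- setdiff(rownames(counts), meta$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  bad_type <- setdiff(unique(meta$sample_type), SAMPLE_TYPES)
  if (length(bad_type))
    stop("unknown sample_type ", paste(sQuote(bad_type), collapse = ", "),
         "; allowed: ", paste(SAMPLE_TYPES, collapse = ", "))
  bad_kit <- setdiff(unique(meta$extraction_kit), EXTRACTION_KITS)
  if (length(bad_kit))
    stop("unknown extraction_kit ", paste(sQuote(bad_kit), collapse = ", "),
         "; allowed: ", paste(EXTRACTION_KITS, collapse = ", "))
  if (any(meta$replicate < 0)) stop("replicate must be nonnegative")
  meta$replicate <- as.integer(meta$replicate)
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  structure(list(counts = counts, taxonomy = taxonomy, meta = meta),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  tt <- table(factor(x$meta$sample_type, levels = SAMPLE_TYPES))
  cat("  sample types:",
      paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  kk <- table(factor(x$meta$extraction_kit, levels = EXTRACTION_KITS))
  cat("  extraction kits:",
      paste(sprintf("%s=%d", names(kk), kk), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Per-sample relative abundances
#'
#' Divides each sample row by its total read count. Rows with zero total are
#' rejected: an empty sample signals an upstream failure and must not
#' silently become `NaN`.
#'
#' @param table An [otu_table()], or a plain counts matrix with row names.
#' @return Numeric matrix of the same shape; every row sums to 1.
#' @examples
#' m <- matrix(c(10, 10), 1, dimnames = list("S1", c("a", "b")))
#' relative_abundances(m)
#' @export
relative_abundances <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- rownames(counts)[totals == 0]
    stop("sample(s) with zero total reads: ", paste(bad, collapse = ", "))
  }
  counts / totals
}

#' Agglomerate OTUs at a taxonomic rank
#'
#' Sums the counts of all OTUs sharing the same taxon label at `rank`
#' (mothur/phyloseq "tax_glom" behaviour). Sample totals are conserved. The
#' resulting table is keyed by taxon label; ranks deeper than `rank` are
#' refilled with the `"_unclassified"` padding convention.
#'
#' @param table An [otu_table()].
#' @param rank One of [TAX_RANKS], typically `"genus"`.
#' @return An [otu_table()] whose columns are the distinct labels at `rank`.
#' @export
agglomerate_by_rank <- function(table, rank = "genus") {
  stopifnot(inherits(table, "otu_table"))
  rank <- match.arg(rank, TAX_RANKS)
  labels <- table$taxonomy[[rank]]
  uniq <- unique(labels)
  idx <- match(labels, uniq)
  counts <- matrix(0L, nrow(table$counts), length(uniq),
                   dimnames = list(rownames(table$counts), uniq))
  for (j in seq_along(labels)) {
    counts[, idx[j]] <- counts[, idx[j]] + table$counts[, j]
  }
  r <- match(rank, TAX_RANKS)
  first <- match(uniq, labels)
  tax <- table$taxonomy[first, , drop = FALSE]
  tax$otu_id <- uniq
  if (r < 6L) {
    for (k in seq(r + 1L, 6L)) {
      tax[[TAX_RANKS[k]]] <- ifelse(
        grepl("_unclassified$", uniq) | uniq == "unclassified",
        uniq, paste0(uniq, "_unclassified"))
    }
  }
  otu_table(counts, tax, table$meta)
}

#' Drop singleton OTUs
#'
#' Removes OTUs whose total read count across all samples of the table
#' equals 1, the conventional pre-filter before core-microbiota computation.
#'
#' @param table An [otu_table()].
#' @return An [otu_table()] without the singleton columns.
#' @export
remove_singletons <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  keep <- colSums(table$counts) != 1L
  tab <- table
  tab$counts <- table$counts[, keep, drop = FALSE]
  tab$taxonomy <- table$taxonomy[keep, , drop = FALSE]
  rownames(tab$taxonomy) <- NULL
  tab
}

#' Subset samples by a metadata predicate
#'
#' @param table An [otu_table()].
#' @param subset Logical expression over the metadata columns (`sample_id`,
#'   `patient_id`, `sample_type`, `extraction_kit`, `replicate`), evaluated
#'   non-standardly like [base::subset()]; or a logical/character vector of
#'   samples to keep.
#' @param drop_zero_otus Drop OTUs that have zero counts in every retained
#'   sample (default `FALSE`: the OTU universe is kept stable).
#' @return An [otu_table()]; possibly with zero samples (no error).
#' @examples
#' # controls only:
#' # subset_samples(tab, sample_type == "control")
#' @export
subset_samples <- function(table, subset, drop_zero_otus = FALSE) {
  stopifnot(inherits(table, "otu_table"))
  e <- substitute(subset)
  keep <- eval(e, table$meta, parent.frame())
  if (is.character(keep)) keep <- table$meta$sample_id %in% keep
  if (is.logical(keep) && length(keep) == 1L)
    keep <- rep(keep, nrow(table$meta))
  if (!is.logical(keep) || length(keep) != nrow(table$meta))
    stop("`subset` must evaluate to a logical vector over the samples")
  keep[is.na(keep)] <- FALSE
  tab <- table
  tab$counts <- table$counts[keep, , drop = FALSE]
  tab$meta <- table$meta[keep, , drop = FALSE]
  rownames(tab$meta) <- NULL
  if (drop_zero_otus) {
    nz <- colSums(tab$counts) > 0L
    tab$counts <- tab$counts[, nz, drop = FALSE]
    tab$taxonomy <- tab$taxonomy[nz, , drop = FALSE]
    rownames(tab$taxonomy) <- NULL
  }
  tab
}

#' Genus label of each OTU
#'
#' @param table An [otu_table()].
#' @return Named character vector, OTU id -> genus label.
#' @export
otu_genus <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  stats::setNames(table$taxonomy$genus, table$taxonomy$otu_id)
}
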