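# Mock-community spike-in recovery: score how many of the panel's distinct
# genera are recovered in each sequencing replicate of a spiked sample,
# after agglomerating the OTU table at the genus rank.

#' Load a mock-community panel
#'
#' A panel is a TSV with columns `strain`, `genus`, `proportion`. The
#' packaged default is the ATCC MSA-1002 20-strain even mix (5 percent per
#' strain): 20 strains collapsing to 18 distinct genera, since it carries
#' two *Staphylococcus* and two *Streptococcus* species. Ship your own TSV
#' to use a different community.
#'
#' @param path Path to a panel TSV; defaults to the packaged MSA-1002
#'   composition.
#' @return A `data.frame` of class `"mock_panel"` with columns `strain`,
#'   `genus`, `proportion`.
#' @examples
#' panel <- mock_panel()
#' nrow(panel)                       # 20 strains
#' length(collapse_to_genera(panel)) # 18 distinct genera
#' @export
mock_panel <- function(path = system.file("extdata",
                                          "mock_panel_msa1002.tsv",
                                          package = "lungdecon")) {
  df <- read_tsv_strict(path, c("strain", "genus", "proportion"))
  df$proportion <- as.numeric(df$proportion)
  if (anyDuplicated(df$strain))
    stop(basename(path), ": duplicate strain names")
  if (nrow(df) && abs(sum(df$proportion) - 1) > 1e-6)
    stop(basename(path), ": strain proportions must sum to 1")
  class(df) <- c("mock_panel", "data.frame")
  df
}

#' Distinct genera of a mock panel
#'
#' Collapses congeneric strains to a single genus label — detection is
#' scored at the genus rank, so congeneric strains are indistinguishable.
#' Idempotent.
#'
#' @param panel A [mock_panel()].
#' @return Sorted character vector of distinct genus labels.
#' @export
collapse_to_genera <- function(panel) {
  sort(unique(as.character(panel$genus)))
}

#' Score mock-community recovery at the genus rank
#'
#' Agglomerates the spiked replicates at the genus rank and calls a panel
#' genus detected in a replicate when its read count is at least
#' `min_reads` (default 1: any read is a detection). The per-replicate
#' percentage is `detected / n_distinct_genera * 100` and the headline
#' number is the arithmetic mean over replicates. When a matched unspiked
#' `background` table is supplied, genera observed in it are flagged as
#' naturally occurring; they still earn credit unless
#' `exclude_natural = TRUE`, which withdraws them from a replicate's
#' detected set.
#'
#' @param table An [otu_table()] whose rows are the spiked replicates.
#' @param panel A [mock_panel()].
#' @param background Optional [otu_table()] of matched unspiked samples.
#' @param min_reads Minimum agglomerated read count for a detection
#'   (default 1).
#' @param exclude_natural Withdraw credit for genera found in
#'   `background` (default `FALSE`).
#' @return A list of class `"spikein_report"`: `detection` (logical
#'   replicates x genera matrix), `percent` (per replicate),
#'   `mean_percent`, `mean_percent_strains` (same mean on the
#'   20-strain denominator), `n_genera`, `n_strains`, `never_detected`,
#'   `partially_detected`, `natural_genera`.
#' @export
detect_spikein <- function(table, panel, background = NULL, min_reads = 1L,
                           exclude_natural = FALSE) {
  stopifnot(inherits(table, "otu_table"), min_reads >= 1L)
  genera <- collapse_to_genera(panel)
  if (!length(genera)) stop("empty mock panel")
  totals <- rowSums(table$counts)
  if (any(totals == 0))
    stop("replicate(s) with zero total reads: ",
         paste(rownames(table$counts)[totals == 0], collapse = ", "))
  glom <- agglomerate_by_rank(table, "genus")
  counts <- matrix(0L, nrow(glom$counts), length(genera),
                   dimnames = list(rownames(glom$counts), genera))
  found <- intersect(genera, colnames(glom$counts))
  counts[, found] <- glom$counts[, found, drop = FALSE]
  detection <- counts >= min_reads

  natural <- character(0L)
  if (!is.null(background)) {
    bg <- agglomerate_by_rank(background, "genus")
    natural <- intersect(genera,
                         colnames(bg$counts)[colSums(bg$counts) > 0L])
    if (exclude_natural) detection[, natural] <- FALSE
  }

  percent <- 100 * rowSums(detection) / length(genera)
  per_genus <- colSums(detection)
  structure(list(detection = detection,
                 percent = percent,
                 mean_percent = mean(percent),
                 mean_percent_strains = mean(
                   100 * rowSums(detection) / nrow(panel)),
                 n_genera = length(genera), n_strains = nrow(panel),
                 never_detected = genera[per_genus == 0L],
                 partially_detected = genera[per_genus > 0L &
                                               per_genus < nrow(detection)],
                 natural_genera = natural),
            class = "spikein_report")
}

#' @export
print.spikein_report <- function(x, ...) {
  cat(sprintf(
    "spikein_report: %d replicate(s), %d panel genera (%d strains)\n",
    nrow(x$detection), x$n_genera, x$n_strains))
  cat(sprintf("  per-replicate detection: %s%%\n",
              paste(sprintf("%.1f", x$percent), collapse = ", ")))
  cat(sprintf("  mean detection: %.1f%% of genera (%.1f%% of strains)\n",
              x$mean_percent, x$mean_percent_strains))
  if (length(x$never_detected))
    cat("  never detected:", paste(x$never_detected, collapse = ", "), "\n")
  if (length(x$partially_detected))
    cat("  partially detected:",
        paste(x$partially_detected, collapse = ", "), "\n")
  if (length(x$natural_genera))
    cat("  naturally occurring in background:",
        paste(x$natural_genera, collapse = ", "), "\n")
  invisible(x)
}

#' Expected spike load
#'
#' Whole-cell communities are spiked at 2.5e3 bacteria per gram of tissue
#' (so the expectation scales with mass); genomic communities contribute a
#' per-sample constant of 1.25e3 genome copies.
#'
#' @param kind `"whole_cell"` or `"genomic"`.
#' @param tissue_mass_g Tissue mass in grams (> 0).
#' @return Expected number of organisms (whole_cell) or genome copies
#'   (genomic).
#' @examples
#' spike_load("whole_cell", 1)  # 2500
#' spike_load("genomic", 1)     # 1250
#' @export
spike_load <- function(kind = c("whole_cell", "genomic"),
                       tissue_mass_g = 1) {
  kind <- match.arg(kind)
  if (any(tissue_mass_g <= 0)) stop("tissue mass must be positive")
  if (kind == "whole_cell") 2.5e3 * tissue_mass_g
  else rep(1.25e3, length(tissue_mass_g))
}
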