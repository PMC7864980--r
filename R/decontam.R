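# Ratio-based contaminant removal against a single per-patient negative
# control, applied jointly to the patient's paired tissues, plus the two
# published diagnostics (percent of OTUs remaining, Pearson correlation to
# the control).

#' Keep-or-remove decision for one control-present OTU
#'
#' The core predicate of the workflow. An OTU found in a patient's negative
#' control is kept only when its relative abundance in *both* the cancerous
#' and healthy tissue is strictly greater than `ratio` times its relative
#' abundance in the control; otherwise it is removed from both tissues.
#' Strict inequality means a single-OTU sample (relative abundance 1)
#' tolerates a control relative abundance strictly below `1/ratio`: with a
#' 20,000-read control and ratio 1000, up to 19 control reads.
#'
#' @param c_rel,h_rel Relative abundance of the OTU in the cancerous and
#'   healthy tissue (values in \[0,1\]; vectorised).
#' @param k_rel Relative abundance of the OTU in the control; must be > 0
#'   (only control-present OTUs are tested).
#' @param ratio Positive ratio threshold (default 1000).
#' @return Logical vector: `TRUE` = keep, `FALSE` = remove.
#' @examples
#' keep_decision(1, 1, 20 / 20000, ratio = 1000)  # FALSE: removed
#' keep_decision(1, 1, 19 / 20000, ratio = 1000)  # TRUE: kept
#' @export
keep_decision <- function(c_rel, h_rel, k_rel, ratio = 1000) {
  stopifnot(all(c_rel >= 0 & c_rel <= 1), all(h_rel >= 0 & h_rel <= 1),
            all(k_rel > 0), ratio > 0)
  (c_rel > ratio * k_rel) & (h_rel > ratio * k_rel)
}

#' Enumerate patient triplets
#'
#' A triplet is the (cancerous, healthy, control) trio of one patient
#' processed with one extraction kit. Incomplete trios are reported.
#'
#' @param table An [otu_table()].
#' @param require_complete Error on incomplete triplets (default `TRUE`).
#' @return `data.frame` with columns `patient_id`, `extraction_kit`,
#'   `cancerous`, `healthy`, `control` (sample ids).
#' @export
patient_triplets <- function(table, require_complete = TRUE) {
  m <- table$meta
  key <- interaction(m$patient_id, m$extraction_kit, drop = TRUE)
  out <- do.call(rbind, lapply(split(m, key), function(g) {
    pick <- function(type) {
      id <- g$sample_id[g$sample_type == type]
      if (length(id) == 1L) id else NA_character_
    }
    data.frame(patient_id = g$patient_id[1L],
               extraction_kit = g$extraction_kit[1L],
               cancerous = pick("cancerous"), healthy = pick("healthy"),
               control = pick("control"), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  bad <- is.na(out$cancerous) | is.na(out$healthy) | is.na(out$control)
  if (any(bad) && require_complete)
    stop("incomplete patient triplet(s): ",
         paste(paste(out$patient_id[bad], out$extraction_kit[bad],
                     sep = "/"), collapse = ", "))
  out[!bad | !require_complete, , drop = FALSE]
}

#' Decontaminate one patient triplet
#'
#' Applies [keep_decision()] to every OTU with a positive count in the
#' patient's control. Removed OTUs are zeroed in *both* tissue rows (joint
#' removal: never in one tissue only); the control row is never modified.
#' Relative abundances are computed per sample, independently, before any
#' removal.
#'
#' @param table An [otu_table()] containing the triplet's three samples.
#' @param triplet One row of [patient_triplets()] (or a list with
#'   `patient_id`, `cancerous`, `healthy`, `control`).
#' @param params A [lungdecon_params()].
#' @return A list of class `"decontam_patient"`: `patient_id`,
#'   `extraction_kit`, `removed_otus`, `kept_control_otus`, `decisions`
#'   (per control-present OTU: the three relative abundances and the
#'   decision), `filtered_counts` (the two tissue rows after zeroing) and
#'   `percent_remaining` (named by the tissue sample ids).
#' @export
decontaminate_patient <- function(table, triplet,
                                  params = lungdecon_params()) {
  stopifnot(inherits(table, "otu_table"))
  ids <- c(triplet$cancerous, triplet$healthy, triplet$control)
  miss <- setdiff(ids, rownames(table$counts))
  if (length(miss))
    stop("triplet sample(s) not in table: ", paste(miss, collapse = ", "))
  cvec <- table$counts[triplet$cancerous, ]
  hvec <- table$counts[triplet$healthy, ]
  kvec <- table$counts[triplet$control, ]
  for (id in ids) {
    if (sum(table$counts[id, ]) == 0L)
      stop("sample ", id, " has zero total reads; the ratio rule is ",
           "undefined on empty samples")
  }
  c_rel <- cvec / sum(cvec)
  h_rel <- hvec / sum(hvec)
  k_rel <- kvec / sum(kvec)

  tested <- which(kvec > 0L)
  keep <- keep_decision(c_rel[tested], h_rel[tested], k_rel[tested],
                        ratio = params$ratio_threshold)
  otus <- colnames(table$counts)
  removed <- otus[tested][!keep]
  kept <- otus[tested][keep]

  filtered <- table$counts[c(triplet$cancerous, triplet$healthy), ,
                           drop = FALSE]
  filtered[, removed] <- 0L

  pr <- c(percent_remaining_otus(cvec, filtered[triplet$cancerous, ]),
          percent_remaining_otus(hvec, filtered[triplet$healthy, ]))
  names(pr) <- c(triplet$cancerous, triplet$healthy)

  decisions <- data.frame(
    otu_id = otus[tested],
    genus = table$taxonomy$genus[tested],
    c_rel = unname(c_rel[tested]), h_rel = unname(h_rel[tested]),
    k_rel = unname(k_rel[tested]),
    decision = ifelse(keep, "keep", "remove"),
    stringsAsFactors = FALSE)
  rownames(decisions) <- NULL

  structure(list(patient_id = triplet$patient_id,
                 extraction_kit = triplet$extraction_kit,
                 removed_otus = removed, kept_control_otus = kept,
                 decisions = decisions, filtered_counts = filtered,
                 percent_remaining = pr),
            class = "decontam_patient")
}

#' Percent of observed OTUs remaining after removal
#'
#' `100 * (OTUs with count > 0 after) / (OTUs with count > 0 before)` for
#' one sample row; the published per-sample diagnostic of how much of a
#' tissue's richness the control-based filter preserves.
#'
#' @param before,after Count vectors over the same OTU universe.
#' @return A percentage in \[0, 100\].
#' @export
percent_remaining_otus <- function(before, after) {
  stopifnot(length(before) == length(after))
  n_before <- sum(before > 0)
  if (n_before == 0L)
    stop("no observed OTUs before removal; percent remaining undefined")
  100 * sum(after > 0) / n_before
}

#' Pearson correlation between a sample and its control
#'
#' Computed on relative abundances over the full OTU universe (zeros
#' included), *before* any removal — a diagnostic of how strongly the
#' method's contaminant background shapes the tissue profile. Shapiro-Wilk
#' normality p-values for both vectors are reported alongside (diagnostics
#' only; the correlation is reported regardless).
#'
#' @param table An [otu_table()] (pre-removal counts).
#' @param sample_id,control_id Sample ids of the tissue and its control.
#' @param relative Correlate relative abundances (default) or raw counts.
#' @return A list: `pearson_r`, `shapiro_p_sample`, `shapiro_p_control`.
#' @export
control_correlation <- function(table, sample_id, control_id,
                                relative = TRUE) {
  stopifnot(inherits(table, "otu_table"))
  rel <- if (relative) relative_abundances(table) else table$counts
  x <- rel[sample_id, ]
  y <- rel[control_id, ]
  if (stats::sd(x) == 0)
    stop("sample ", sample_id, " has constant abundances; ",
         "correlation undefined")
  if (stats::sd(y) == 0)
    stop("sample ", control_id, " has constant abundances; ",
         "correlation undefined")
  sw <- function(v) {
    if (length(v) < 3L || length(unique(v)) == 1L) return(NA_real_)
    if (length(v) > 5000L) v <- v[seq_len(5000L)]
    stats::shapiro.test(v)$p.value
  }
  list(pearson_r = unname(stats::cor(x, y, method = "pearson")),
       shapiro_p_sample = sw(x), shapiro_p_control = sw(y))
}

#' Decontaminate a whole study
#'
#' Runs [decontaminate_patient()] over every complete (patient, kit)
#' triplet of the table and assembles the filtered table (tissue rows
#' zeroed where OTUs were removed, control rows untouched) together with
#' the per-sample diagnostics.
#'
#' @param table An [otu_table()].
#' @param params A [lungdecon_params()].
#' @param drop_empty_otus Drop OTUs that end up all-zero in the filtered
#'   table (default `FALSE`; keeps the OTU universe stable).
#' @return An object of class `"decontam_result"`: `filtered_table`
#'   (an [otu_table()]), `patients` (list of `"decontam_patient"`),
#'   `diagnostics` (`data.frame`: sample_id, patient_id, extraction_kit,
#'   sample_type, percent_remaining, pearson_r, shapiro_p), and `params`.
#' @examples
#' study <- simulate_study(synth_config(n_patients = 2, seed = 1))
#' res <- decontaminate(study$table)
#' res
#' @export
decontaminate <- function(table, params = lungdecon_params(),
                          drop_empty_otus = FALSE) {
  trips <- patient_triplets(table, require_complete = FALSE)
  complete <- !is.na(trips$cancerous) & !is.na(trips$healthy) &
    !is.na(trips$control)
  if (!any(complete))
    stop("no complete (cancerous, healthy, control) patient triplet")
  if (any(!complete))
    warning("skipping incomplete triplet(s): ",
            paste(paste(trips$patient_id[!complete],
                        trips$extraction_kit[!complete], sep = "/"),
                  collapse = ", "))
  trips <- trips[complete, , drop = FALSE]
  counts <- table$counts
  patients <- vector("list", nrow(trips))
  diag_rows <- vector("list", nrow(trips))
  for (i in seq_len(nrow(trips))) {
    tr <- trips[i, ]
    res <- decontaminate_patient(table, tr, params)
    patients[[i]] <- res
    counts[rownames(res$filtered_counts), ] <- res$filtered_counts
    corr <- lapply(c(tr$cancerous, tr$healthy), function(sid)
      control_correlation(table, sid, tr$control))
    diag_rows[[i]] <- data.frame(
      sample_id = c(tr$cancerous, tr$healthy),
      patient_id = tr$patient_id, extraction_kit = tr$extraction_kit,
      sample_type = c("cancerous", "healthy"),
      percent_remaining = unname(res$percent_remaining),
      pearson_r = vapply(corr, `[[`, numeric(1L), "pearson_r"),
      shapiro_p = vapply(corr, `[[`, numeric(1L), "shapiro_p_sample"),
      stringsAsFactors = FALSE)
  }
  filtered <- table
  filtered$counts <- counts
  if (drop_empty_otus) {
    nz <- colSums(counts) > 0L
    filtered$counts <- counts[, nz, drop = FALSE]
    filtered$taxonomy <- filtered$taxonomy[nz, , drop = FALSE]
    rownames(filtered$taxonomy) <- NULL
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  structure(list(filtered_table = filtered, patients = patients,
                 diagnostics = diagnostics, params = params),
            class = "decontam_result")
}

#' @export
print.decontam_result <- function(x, ...) {
  n_rem <- vapply(x$patients, function(p) length(p$removed_otus),
                  integer(1L))
  cat(sprintf(
    "decontam_result: %d patient triplet(s), ratio threshold %g\n",
    length(x$patients), x$params$ratio_threshold))
  cat(sprintf("  removed OTUs per triplet: %s\n",
              paste(n_rem, collapse = ", ")))
  cat(sprintf("  percent remaining: %.2f-%.2f%%\n",
              min(x$diagnostics$percent_remaining),
              max(x$diagnostics$percent_remaining)))
  invisible(x)
}

#' @export
summary.decontam_result <- function(object, ...) {
  d <- object$diagnostics
  agg <- do.call(rbind, lapply(split(d, d$extraction_kit), function(g)
    data.frame(extraction_kit = g$extraction_kit[1L],
               n_samples = nrow(g),
               mean_percent_remaining = mean(g$percent_remaining),
               min_percent_remaining = min(g$percent_remaining),
               max_percent_remaining = max(g$percent_remaining),
               mean_pearson_r = mean(g$pearson_r),
               stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(by_kit = agg, params = object$params),
            class = "summary.decontam_result")
}

#' @export
print.summary.decontam_result <- function(x, ...) {
  cat("Decontamination diagnostics by extraction kit\n")
  print(x$by_kit, row.names = FALSE)
  invisible(x)
}
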