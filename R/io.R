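# Readers/writers for the mothur table dialects and the study's TSV
# side-tables. Readers reject malformed input rather than coerce; writers
# emit UTF-8, tab-delimited, LF files that their paired reader accepts.

read_tsv_strict <- function(path, required) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(basename(path), ": missing column(s) ", paste(miss, collapse = ", "))
  df
}

write_tsv_strict <- function(df, path, digits = 6L) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n",
             useBytes = TRUE)
  if (nrow(df)) {
    body <- do.call(paste, c(lapply(df, function(x) {
      if (is.numeric(x))
        vapply(x, format, character(1L), trim = TRUE,
               scientific = FALSE, digits = 15L)
      else as.character(x)
    }), sep = "\t"))
    writeLines(body, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a mothur `.shared` OTU count table
#'
#' Parses the tab-delimited shared format whose header starts with
#' `label`, `Group`, `numOtus` followed by the OTU ids. Only a single
#' clustering label is supported unless `label` selects one.
#'
#' @param path Path to the `.shared` file.
#' @param label Clustering label (e.g. `"0.03"`) to select when the file
#'   contains several; an error is raised for multi-label files when `NULL`.
#' @return A list with `counts` (integer matrix, samples x OTUs), `otu_ids`
#'   and `label`; attach metadata with [otu_table()].
#' @export
read_shared <- function(path, label = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(basename(path), ": empty shared file")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L ||
      tolower(header[1L]) != "label" || header[2L] != "Group" ||
      tolower(header[3L]) != "numotus")
    stop(basename(path),
         ": malformed shared header (expected label, Group, numOtus)")
  otu_ids <- header[-(1:3)]
  if (anyDuplicated(otu_ids))
    stop(basename(path), ": duplicate OTU ids in header")
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ragged <- lengths(rows) != length(header)
  if (any(ragged))
    stop(basename(path), ": ragged row(s) at line(s) ",
         paste(which(ragged) + 1L, collapse = ", "))
  labs <- vapply(rows, `[[`, character(1L), 1L)
  if (is.null(label)) {
    if (length(unique(labs)) > 1L)
      stop(basename(path), ": multiple clustering labels (",
           paste(unique(labs), collapse = ", "),
           "); pass `label` to select one")
  } else {
    rows <- rows[labs == label]
    if (!length(rows))
      stop(basename(path), ": no rows with label ", sQuote(label))
    labs <- rep(label, length(rows))
  }
  groups <- vapply(rows, `[[`, character(1L), 2L)
  if (anyDuplicated(groups))
    stop(basename(path), ": duplicate Group ",
         paste(unique(groups[duplicated(groups)]), collapse = ", "))
  num_otus <- suppressWarnings(
    as.integer(vapply(rows, `[[`, character(1L), 3L)))
  if (any(is.na(num_otus)) || any(num_otus != length(otu_ids)))
    stop(basename(path), ": numOtus disagrees with the ", length(otu_ids),
         " count columns")
  counts <- matrix(NA_integer_, length(rows), length(otu_ids),
                   dimnames = list(groups, otu_ids))
  for (i in seq_along(rows)) {
    v <- rows[[i]][-(1:3)]
    x <- suppressWarnings(as.numeric(v))
    if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
      stop(basename(path), ": non-integer or negative count in Group ",
           groups[i])
    counts[i, ] <- as.integer(x)
  }
  list(counts = counts, otu_ids = otu_ids, label = unique(labs))
}

#' Write a mothur `.shared` file
#'
#' @param counts Integer matrix (samples x OTUs) or an [otu_table()].
#' @param path Output path.
#' @param label Clustering label written in the first column.
#' @export
write_shared <- function(counts, path, label = "0.03") {
  if (inherits(counts, "otu_table")) counts <- counts$counts
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("label", "Group", "numOtus", colnames(counts)),
                   collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  for (i in seq_len(nrow(counts))) {
    writeLines(paste(c(label, rownames(counts)[i], ncol(counts),
                       counts[i, ]), collapse = "\t"),
               con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a mothur `.cons.taxonomy` consensus taxonomy file
#'
#' Expects header columns `OTU`, `Size`, `Taxonomy`. Bootstrap percentages
#' in parentheses are stripped (they are not used downstream), lineages are
#' split on `";"` and normalised to the six-rank scheme with
#' [pad_lineage()].
#'
#' @param path Path to the `.cons.taxonomy` file.
#' @return `data.frame` with columns `otu_id`, `size` and the six
#'   [TAX_RANKS] columns.
#' @export
read_cons_taxonomy <- function(path) {
  df <- read_tsv_strict(path, c("OTU", "Size", "Taxonomy"))
  if (anyDuplicated(df$OTU))
    stop(basename(path), ": duplicate OTU ids")
  bad_tax <- is.na(df$Taxonomy) | !nzchar(trimws(df$Taxonomy))
  if (any(bad_tax))
    stop(basename(path), ": empty taxonomy string for ",
         paste(df$OTU[bad_tax], collapse = ", "))
  clean <- gsub("\\([0-9.]+\\)", "", df$Taxonomy)
  lins <- strsplit(clean, ";", fixed = TRUE)
  ranks <- t(vapply(lins, pad_lineage, character(6L)))
  colnames(ranks) <- TAX_RANKS
  data.frame(otu_id = df$OTU, size = as.integer(df$Size), ranks,
             stringsAsFactors = FALSE)
}

#' Write a `.cons.taxonomy` file
#'
#' @param taxonomy `data.frame` with `otu_id` and the six rank columns
#'   (e.g. the `taxonomy` element of an [otu_table()]); an optional `size`
#'   column is used for `Size`, otherwise 0.
#' @param path Output path.
#' @export
write_cons_taxonomy <- function(taxonomy, path) {
  size <- if ("size" %in% names(taxonomy)) taxonomy$size else
    rep(0L, nrow(taxonomy))
  tax_str <- apply(taxonomy[, TAX_RANKS, drop = FALSE], 1L,
                   function(r) paste0(paste(r, collapse = ";"), ";"))
  write_tsv_strict(data.frame(OTU = taxonomy$otu_id, Size = size,
                              Taxonomy = tax_str,
                              stringsAsFactors = FALSE), path)
}

#' Read the sample metadata table
#'
#' Tab-separated with columns `sample_id`, `patient_id`, `sample_type`,
#' `extraction_kit`, `replicate`. Enum fields are validated against
#' [SAMPLE_TYPES] and [EXTRACTION_KITS].
#'
#' @param path Path to the metadata TSV.
#' @return Validated metadata `data.frame`.
#' @export
read_sample_metadata <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "patient_id", "sample_type",
                                "extraction_kit", "replicate"))
  if (anyDuplicated(df$sample_id))
    stop(basename(path), ": duplicate sample_id ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
  if (length(bad))
    stop(basename(path), ": unknown sample_type ",
         paste(sQuote(bad), collapse = ", "), "; allowed: ",
         paste(SAMPLE_TYPES, collapse = ", "))
  badk <- setdiff(unique(df$extraction_kit), EXTRACTION_KITS)
  if (length(badk))
    stop(basename(path), ": unknown extraction_kit ",
         paste(sQuote(badk), collapse = ", "), "; allowed: ",
         paste(EXTRACTION_KITS, collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df
}

#' Write the sample metadata table
#'
#' @param meta Metadata `data.frame` (see [read_sample_metadata()]).
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  cols <- c("sample_id", "patient_id", "sample_type", "extraction_kit",
            "replicate")
  write_tsv_strict(meta[, cols], path)
}

#' Read the extraction-QC table
#'
#' Tab-separated with columns `sample_id`, `dna_ng_per_ul`, `eluate_ul`,
#' `tissue_g`, `a260_280`, `a260_230`; feeds [dna_yield_per_gram()].
#'
#' @param path Path to the QC TSV.
#' @return `data.frame` with the columns above plus `yield_ng_per_g`.
#' @export
read_qc <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "dna_ng_per_ul", "eluate_ul",
                                "tissue_g", "a260_280", "a260_230"))
  if (anyDuplicated(df$sample_id))
    stop(basename(path), ": duplicate sample_id")
  for (col in c("dna_ng_per_ul", "eluate_ul", "tissue_g", "a260_280",
                "a260_230")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$yield_ng_per_g <- dna_yield_per_gram(df$dna_ng_per_ul, df$eluate_ul,
                                          df$tissue_g)
  df
}

#' Write a generic report TSV
#'
#' Deterministic column order (as given) and six significant digits for
#' floating-point columns.
#'
#' @param df `data.frame` to write.
#' @param path Output path.
#' @export
write_report <- function(df, path) {
  write_tsv_strict(as.data.frame(df), path)
}

#' Load a complete study from its three files
#'
#' Joins a `.shared` count table, a `.cons.taxonomy` file and a metadata
#' TSV into one [otu_table()], by sample and OTU id (never by position).
#'
#' @param shared_path,taxonomy_path,metadata_path File paths.
#' @param label Optional clustering label for multi-label shared files.
#' @return An [otu_table()].
#' @export
load_study <- function(shared_path, taxonomy_path, metadata_path,
                       label = NULL) {
  sh <- read_shared(shared_path, label = label)
  tax <- read_cons_taxonomy(taxonomy_path)
  meta <- read_sample_metadata(metadata_path)
  otu_table(sh$counts, tax, meta)
}
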