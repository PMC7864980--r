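# Fixtures built in code plus the independent brute-force oracles the
# suites check the implementation against.

# minimal taxonomy frame: one genus label per OTU
toy_taxonomy <- function(otu_ids, genus = otu_ids) {
  data.frame(otu_id = otu_ids, domain = "Bacteria",
             phylum = "Bacteria_unclassified",
             class = "Bacteria_unclassified",
             order = "Bacteria_unclassified",
             family = "Bacteria_unclassified",
             genus = genus, stringsAsFactors = FALSE)
}

# one patient triplet as an otu_table: rows C (cancerous), H (healthy),
# K (control)
triplet_table <- function(c_counts, h_counts, k_counts,
                          otu_ids = sprintf("Otu%03d", seq_along(c_counts)),
                          genus = otu_ids, kit = "Blood") {
  counts <- rbind(C = as.integer(c_counts), H = as.integer(h_counts),
                  K = as.integer(k_counts))
  colnames(counts) <- otu_ids
  meta <- data.frame(sample_id = c("C", "H", "K"), patient_id = "P1",
                     sample_type = c("cancerous", "healthy", "control"),
                     extraction_kit = kit, replicate = 1L,
                     stringsAsFactors = FALSE)
  otu_table(counts, toy_taxonomy(otu_ids, genus), meta)
}

toy_triplet <- function(kit = "Blood") {
  data.frame(patient_id = "P1", extraction_kit = kit, cancerous = "C",
             healthy = "H", control = "K", stringsAsFactors = FALSE)
}

# independent scalar brute-force oracle for the ratio rule: loops OTU by
# OTU over raw counts, never touching the package's vectorised path
oracle_removed_otus <- function(counts, c_id, h_id, k_id, ratio = 1000) {
  removed <- character(0L)
  for (otu in colnames(counts)) {
    if (counts[k_id, otu] > 0) {
      c_rel <- counts[c_id, otu] / sum(counts[c_id, ])
      h_rel <- counts[h_id, otu] / sum(counts[h_id, ])
      k_rel <- counts[k_id, otu] / sum(counts[k_id, ])
      keep <- (c_rel > ratio * k_rel) && (h_rel > ratio * k_rel)
      if (!keep) removed <- c(removed, otu)
    }
  }
  removed
}

# random small study table (<= 20 OTUs, <= 6 patients, one kit each),
# every sample guaranteed a positive total
random_small_table <- function(n_patients = 3L, n_otus = 12L,
                               max_count = 30L) {
  ids <- sprintf("Otu%03d", seq_len(n_otus))
  rows <- list(); meta <- list()
  for (p in seq_len(n_patients)) {
    kit <- sample(EXTRACTION_KITS, 1L)
    for (type in c("cancerous", "healthy", "control")) {
      sid <- sprintf("P%d_%s", p, substr(type, 1L, 3L))
      x <- rpois(n_otus, lambda = runif(1L, 0.3, 4)) *
        rbinom(n_otus, 1L, 0.6)
      x <- pmin(x, max_count)
      if (sum(x) == 0L) x[sample.int(n_otus, 1L)] <- 1L
      rows[[sid]] <- as.integer(x)
      meta[[sid]] <- data.frame(sample_id = sid,
                                patient_id = sprintf("P%d", p),
                                sample_type = type, extraction_kit = kit,
                                replicate = 1L, stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  colnames(counts) <- ids
  otu_table(counts, toy_taxonomy(ids), do.call(rbind, meta))
}

# three spiked replicates over the mock panel: `detections` maps a genus
# to the number of replicates (0..3) carrying its reads; unnamed genera
# are present in all three
spike_scenario <- function(panel, detections = c(), reads = 100L,
                           kit = "Blood") {
  otus <- panel$strain
  counts <- matrix(0L, 3L, length(otus),
                   dimnames = list(paste0(kit, "_rep", 1:3), otus))
  for (i in seq_along(otus)) {
    g <- panel$genus[i]
    k <- if (g %in% names(detections)) detections[[g]] else 3L
    if (k > 0L) counts[seq_len(k), i] <- reads
  }
  meta <- data.frame(sample_id = rownames(counts), patient_id = "mock",
                     sample_type = "cancerous", extraction_kit = kit,
                     replicate = 1:3, stringsAsFactors = FALSE)
  otu_table(counts, toy_taxonomy(otus, panel$genus), meta)
}
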