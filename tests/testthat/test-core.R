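# five controls of one kit as an otu_table
controls_5 <- function(counts, kit = "Blood", genus = NULL,
                       otu_ids = sprintf("Otu%03d", ncol(counts))) {
  otu_ids <- sprintf("Otu%03d", seq_len(ncol(counts)))
  colnames(counts) <- otu_ids
  rownames(counts) <- sprintf("%s_K%d", kit, seq_len(nrow(counts)))
  if (is.null(genus)) genus <- otu_ids
  meta <- data.frame(sample_id = rownames(counts),
                     patient_id = sprintf("P%d", seq_len(nrow(counts))),
                     sample_type = "control", extraction_kit = kit,
                     replicate = 1L, stringsAsFactors = FALSE)
  otu_table(counts, toy_taxonomy(otu_ids, genus), meta)
}

test_that("presence rule is inclusive at the abundance cutoff", {
  expect_true(abundance_present(1e-5))
  expect_false(abundance_present(0))
  expect_false(abundance_present(9.9e-6))
  expect_true(abundance_present(2e-5))
})

test_that("core set applies the 2-of-5 rule and averages over all controls", {
  depth <- 100000L
  hit <- as.integer(0.01 * depth)                 # 1% when present
  counts <- matrix(0L, 5L, 3L)
  counts[, 1L] <- depth                           # filler OTU, ubiquitous
  counts[1:2, 1L] <- depth - hit                  # keep totals at depth
  counts[1:2, 2L] <- hit                          # 1% in 2 of 5 -> core
  counts[3L, 3L] <- as.integer(0.5 * depth)       # 50% in 1 of 5 -> not core
  tab <- controls_5(counts)
  cs <- core_set(tab, "Blood")
  expect_true("Otu002" %in% cs$otu_ids)
  expect_false("Otu003" %in% cs$otu_ids)
  expect_equal(cs$min_controls, 2L)
  # mean abundance across ALL five controls, zeros included: ~0.4%
  rel <- relative_abundances(tab)
  expect_equal(unname(cs$mean_abundance["Otu002"]),
               mean(rel[, "Otu002"]))
  expect_equal(unname(cs$mean_abundance["Otu002"]), 0.004,
               tolerance = 1e-3)
  # Otu003 passed abundance once -> non-core
  expect_true("Otu003" %in% cs$non_core_otu_ids)
})

test_that("an OTU below the abundance cutoff everywhere is never core", {
  depth <- 1000000L
  counts <- matrix(0L, 5L, 2L)
  counts[, 1L] <- depth
  counts[, 2L] <- 5L          # 5e-6 in all five controls
  cs <- core_set(controls_5(counts), "Blood")
  expect_false("Otu002" %in% cs$otu_ids)
  expect_false("Otu002" %in% cs$non_core_otu_ids)
})

test_that("raising either cutoff never grows a core set", {
  set.seed(55)
  study <- simulate_study(synth_config(n_patients = 5, seed = 19))
  controls <- remove_singletons(
    subset_samples(study$table, sample_type == "control"))
  prev <- NULL
  for (cut_a in c(1e-6, 1e-5, 1e-4, 1e-3)) {
    cs <- core_set(controls, "Blood",
                   lungdecon_params(core_abundance_cutoff = cut_a))
    if (!is.null(prev)) expect_true(all(cs$otu_ids %in% prev))
    prev <- cs$otu_ids
  }
  prev <- NULL
  for (cut_f in c(0.2, 0.4, 0.6, 0.9)) {
    cs <- core_set(controls, "Blood",
                   lungdecon_params(core_frequency_cutoff = cut_f))
    if (!is.null(prev)) expect_true(all(cs$otu_ids %in% prev))
    prev <- cs$otu_ids
  }
})

test_that("Venn partition classifies hand-planted memberships exactly", {
  # 3 kits x 5 controls; Otu001 core everywhere, Otu002 Blood+Microbial,
  # Otu003 Blood only, Otu004 core nowhere
  depth <- 10000L
  make_kit <- function(kit, present) {
    counts <- matrix(0L, 5L, 5L)
    counts[, 5L] <- depth
    for (j in present) counts[1:3, j] <- 100L
    controls_5(counts, kit = kit)
  }
  tabs <- list(make_kit("Blood", c(1L, 2L, 3L)),
               make_kit("Microbial", c(1L, 2L)),
               make_kit("Powersoil", 1L))
  counts <- do.call(rbind, lapply(tabs, `[[`, "counts"))
  meta <- do.call(rbind, lapply(tabs, `[[`, "meta"))
  all_tab <- otu_table(counts, tabs[[1L]]$taxonomy, meta)
  sets <- lapply(EXTRACTION_KITS, function(k) core_set(all_tab, k))
  vp <- venn_partition(sets)
  reg <- setNames(vp$membership$region, vp$membership$otu_id)
  expect_equal(unname(reg["Otu001"]), "Blood+Microbial+Powersoil")
  expect_equal(unname(reg["Otu002"]), "Blood+Microbial")
  expect_equal(unname(reg["Otu003"]), "Blood")
  expect_false("Otu004" %in% names(reg))
  # every OTU in exactly one region; per-kit region counts sum to the
  # kit's core-set size
  expect_equal(anyDuplicated(vp$membership$otu_id), 0L)
  for (cs in sets) {
    in_regions <- sum(vp$regions$n_otus[
      vapply(strsplit(vp$regions$region, "+", fixed = TRUE),
             function(ks) cs$kit %in% ks, logical(1L))])
    expect_equal(in_regions, length(cs$otu_ids))
  }
})

test_that("identical control profiles put every core OTU in the center", {
  depth <- 10000L
  counts <- matrix(0L, 5L, 4L)
  counts[, 1L] <- depth - 300L
  counts[, 2:4] <- 100L
  tabs <- lapply(EXTRACTION_KITS, function(k) controls_5(counts, kit = k))
  all_tab <- otu_table(do.call(rbind, lapply(tabs, `[[`, "counts")),
                       tabs[[1L]]$taxonomy,
                       do.call(rbind, lapply(tabs, `[[`, "meta")))
  vp <- venn_partition(lapply(EXTRACTION_KITS, function(k)
    core_set(all_tab, k)))
  expect_true(all(vp$membership$region == "Blood+Microbial+Powersoil"))
})

test_that("genus profile sums congeneric members and orders by abundance", {
  depth <- 10000L
  counts <- matrix(0L, 5L, 4L)
  counts[, 1L] <- depth - 600L
  counts[, 2L] <- 400L
  counts[, 3L] <- 100L
  counts[, 4L] <- 100L
  tab <- controls_5(counts, genus = c("Filler", "Ralstonia",
                                      "Staphylococcus", "Staphylococcus"))
  gp <- genus_profile(c("Otu002", "Otu003", "Otu004"), tab)
  expect_equal(gp$genus, c("Ralstonia", "Staphylococcus"))
  rel <- relative_abundances(tab)
  expect_equal(gp$abundance_Blood[gp$genus == "Staphylococcus"],
               mean(rel[, "Otu003"]) + mean(rel[, "Otu004"]),
               tolerance = 1e-12)
  empty <- genus_profile(character(0L), tab)
  expect_equal(nrow(empty), 0L)
})

test_that("full core analysis removes pooled singletons first", {
  study <- simulate_study(synth_config(n_patients = 3, seed = 23))
  cv <- core_contaminants(study$table)
  # singleton columns of the pooled control table are gone
  ctl <- subset_samples(study$table, sample_type == "control")
  singles <- colnames(ctl$counts)[colSums(ctl$counts) == 1L]
  expect_false(any(singles %in% colnames(cv$controls_table$counts)))
  # core sets only ever contain contaminant-labelled taxa
  lab <- setNames(study$truth$label, study$truth$otu_id)
  for (cs in cv$core_sets)
    expect_true(all(lab[cs$otu_ids] != "endogenous"))
})
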