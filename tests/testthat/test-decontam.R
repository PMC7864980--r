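test_that("keep decision matches a brute-force scan over control counts", {
  # single-OTU tissues (relative abundance 1) against a 20,000-read
  # control: the rule tolerates 19 control reads and removes at 20
  for (k in 1:25) {
    keep <- keep_decision(1, 1, k / 20000, ratio = 1000)
    expect_identical(keep, 1 > 1000 * k / 20000 && 1 > 1000 * k / 20000)
    expect_identical(keep, k <= 19L)
  }
  # healthy side failing alone removes the OTU
  expect_false(keep_decision(0.30, 0.001, 0.01, ratio = 1000))
  # boundary is strict: equality is a removal
  expect_false(keep_decision(1, 1, 0.001, ratio = 1000))
})

test_that("toy patient reproduces the hand-evaluated removal set", {
  # totals C=1000, H=1000, K=100
  tab <- triplet_table(c(500L, 300L, 150L, 50L),
                       c(400L, 1L, 500L, 99L),
                       c(0L, 1L, 0L, 99L))
  res <- decontaminate_patient(tab, toy_triplet())
  expect_setequal(res$removed_otus, c("Otu002", "Otu004"))
  expect_setequal(res$kept_control_otus, character(0L))
  expect_equal(unname(res$filtered_counts["C", ]), c(500L, 0L, 150L, 0L))
  expect_equal(unname(res$filtered_counts["H", ]), c(400L, 0L, 500L, 0L))
  # brute-force oracle agrees OTU by OTU
  expect_setequal(res$removed_otus,
                  oracle_removed_otus(tab$counts, "C", "H", "K"))
})

test_that("disjoint control support leaves tissues untouched at 100%", {
  tab <- triplet_table(c(10L, 20L, 0L, 0L), c(5L, 25L, 0L, 0L),
                       c(0L, 0L, 7L, 3L))
  res <- decontaminate_patient(tab, toy_triplet())
  expect_setequal(res$removed_otus, c("Otu003", "Otu004"))
  expect_equal(res$filtered_counts, tab$counts[c("C", "H"), ])
  expect_equal(unname(res$percent_remaining), c(100, 100))
})

test_that("ratio near zero removes nothing present in both tissues", {
  tab <- triplet_table(c(10L, 20L, 30L), c(5L, 25L, 40L), c(1L, 1L, 1L))
  res <- decontaminate_patient(tab, toy_triplet(),
                               lungdecon_params(ratio_threshold = 1e-9))
  expect_length(res$removed_otus, 0L)
})

test_that("empty tissue or control is surfaced, not silently tolerated", {
  tab <- triplet_table(c(1L, 1L), c(0L, 0L), c(1L, 0L))
  expect_error(decontaminate_patient(tab, toy_triplet()), "H")
})

test_that("decontaminate matches the brute-force oracle on random tables", {
  set.seed(77)
  for (i in 1:40) {
    tab <- random_small_table(n_patients = sample(1:3, 1L),
                              n_otus = sample(4:20, 1L))
    trips <- patient_triplets(tab)
    res <- decontaminate(tab)
    for (j in seq_len(nrow(trips))) {
      tr <- trips[j, ]
      expect_setequal(
        res$patients[[j]]$removed_otus,
        oracle_removed_otus(tab$counts, tr$cancerous, tr$healthy,
                            tr$control))
    }
  }
})

test_that("joint removal: identical zero-pattern over removed OTUs; control untouched", {
  set.seed(8)
  tab <- random_small_table(n_patients = 2L, n_otus = 15L)
  res <- decontaminate(tab)
  for (p in res$patients) {
    filt <- p$filtered_counts
    expect_true(all(filt[, p$removed_otus] == 0L))
    # an OTU removed from one tissue is removed from the other
    expect_equal(filt[1L, p$removed_otus] == 0L,
                 filt[2L, p$removed_otus] == 0L)
  }
  ctl_ids <- tab$meta$sample_id[tab$meta$sample_type == "control"]
  expect_identical(res$filtered_table$counts[ctl_ids, ],
                   tab$counts[ctl_ids, ])
})

test_that("raising the ratio threshold never shrinks the removed set", {
  set.seed(9)
  for (i in 1:10) {
    tab <- random_small_table(n_patients = 1L, n_otus = 15L)
    tr <- patient_triplets(tab)[1L, ]
    prev <- character(0L)
    for (ratio in c(0.5, 5, 50, 500, 5000)) {
      rem <- decontaminate_patient(
        tab, tr, lungdecon_params(ratio_threshold = ratio))$removed_otus
      expect_true(all(prev %in% rem))
      prev <- rem
    }
  }
})

test_that("OTUs absent from the control are bit-identical before/after", {
  set.seed(10)
  tab <- random_small_table(n_patients = 2L, n_otus = 18L)
  res <- decontaminate(tab)
  for (p in res$patients) {
    ctl <- tab$meta$sample_id[tab$meta$patient_id == p$patient_id &
                                tab$meta$extraction_kit ==
                                  p$extraction_kit &
                                tab$meta$sample_type == "control"]
    absent <- colnames(tab$counts)[tab$counts[ctl, ] == 0L]
    expect_identical(p$filtered_counts[, absent],
                     tab$counts[rownames(p$filtered_counts), absent])
  }
})

test_that("percent remaining counts observed OTUs before vs after", {
  before <- c(3L, 1L, 0L, 2L, 5L, 1L, 1L, 4L, 9L, 8L, 2L)  # 10 observed
  after <- before
  after[c(2L, 6L)] <- 0L                                    # 2 removed
  expect_equal(percent_remaining_otus(before, after), 80)
  expect_equal(percent_remaining_otus(before, before), 100)
  expect_error(percent_remaining_otus(c(0L, 0L), c(0L, 0L)), "undefined")
})

test_that("control correlation follows the product-moment formula", {
  tab <- triplet_table(c(5L, 5L, 0L, 0L), c(7L, 2L, 1L, 0L),
                       c(5L, 5L, 0L, 0L))
  expect_equal(control_correlation(tab, "C", "K")$pearson_r, 1.0)

  tab2 <- triplet_table(c(5L, 5L, 0L, 0L), c(1L, 1L, 1L, 1L),
                        c(0L, 0L, 5L, 5L))
  expect_equal(control_correlation(tab2, "C", "K")$pearson_r, -1.0)

  x <- c(0.7, 0.2, 0.1, 0)
  y <- c(0.1, 0.1, 0.1, 0.7)
  tab3 <- triplet_table(as.integer(x * 10), c(1L, 1L, 1L, 1L),
                        as.integer(y * 10))
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(control_correlation(tab3, "C", "K")$pearson_r, r_hand,
               tolerance = 1e-12)
  # constant vector is an error naming the sample
  expect_error(control_correlation(tab3, "H", "K"), "H")
})
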