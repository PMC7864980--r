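test_that("Shannon index: zero for single OTU, log(k) for uniform, formula", {
  expect_equal(unname(shannon_diversity(c(0, 9, 0))), 0)
  expect_equal(unname(shannon_diversity(rep(5, 4))), log(4))
  p <- (1:3) / 6
  expect_equal(unname(shannon_diversity(c(1, 2, 3))), -sum(p * log(p)))
  expect_error(shannon_diversity(rbind(S1 = c(0, 0))), "S1")
  # maximal for uniform rows among same-richness rows
  expect_lt(unname(shannon_diversity(c(1, 1, 18))),
            unname(shannon_diversity(c(1, 1, 1))))
})

test_that("Bray-Curtis matches the hand formula, weighted and unweighted", {
  m <- rbind(A = c(2L, 0L, 1L), B = c(1L, 1L, 0L))
  colnames(m) <- paste0("o", 1:3)
  # unweighted: presence vectors [1,0,1] vs [1,1,0] -> 2/4
  expect_equal(as.numeric(bray_curtis(m, weighted = FALSE)), 0.5)
  # weighted on relative abundances
  x <- m["A", ] / sum(m["A", ]); y <- m["B", ] / sum(m["B", ])
  expect_equal(as.numeric(bray_curtis(m, weighted = TRUE)),
               sum(abs(x - y)) / sum(x + y))
  # identical and disjoint rows
  same <- rbind(A = c(3L, 1L), B = c(3L, 1L)); colnames(same) <- c("a", "b")
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disj <- rbind(A = c(3L, 0L), B = c(0L, 7L)); colnames(disj) <- c("a", "b")
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  expect_equal(as.numeric(bray_curtis(disj, weighted = FALSE)), 1)
})

test_that("unweighted Bray-Curtis equals weighted on indicator matrices", {
  set.seed(21)
  m <- matrix(rbinom(60, 8, 0.3), 5L,
              dimnames = list(paste0("S", 1:5), paste0("o", 1:12)))
  m[rowSums(m) == 0, 1L] <- 1L
  ind <- (m > 0) * 1L
  expect_equal(as.numeric(bray_curtis(m, weighted = FALSE)),
               as.numeric(bray_curtis(ind, weighted = TRUE,
                                      relative = FALSE)),
               tolerance = 1e-12)
})

test_that("PCoA embeds two points at +/- d/2 and recovers Euclidean inputs", {
  d2 <- matrix(c(0, 3, 3, 0), 2L, dimnames = list(c("a", "b"),
                                                  c("a", "b")))
  pc <- pcoa(d2)
  expect_equal(sort(pc$coordinates[, 1L]), c(a = -1.5, b = 1.5),
               ignore_attr = TRUE)

  # equilateral three-point configuration: two equal positive eigenvalues
  d3 <- matrix(1, 3L, 3L) - diag(3L)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  pc3 <- pcoa(d3)
  pos <- pc3$eigenvalues[pc3$eigenvalues > 1e-12]
  expect_length(pos, 2L)
  expect_equal(pos[1L], pos[2L], tolerance = 1e-9)

  # reconstruction oracle on genuinely Euclidean distances
  set.seed(5)
  pts <- matrix(rnorm(20), 5L)
  d <- dist(pts)
  rec <- dist(pcoa(d)$coordinates)
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-9)
})

test_that("PERMANOVA matches vegan and the exhaustive toy oracle", {
  # 4 samples, two clean blocks: R^2 = 1, exhaustive p = 2/6
  m <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1, 0, 0), 4L)
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(as.dist(m), c("g1", "g1", "g2", "g2"),
                   exhaustive = TRUE)
  expect_equal(res$r_squared, 1)
  expect_equal(res$p_value, 2 / 6)

  # F and R^2 equal adonis2 on a real dissimilarity matrix
  set.seed(31)
  tab <- random_small_table(n_patients = 3L, n_otus = 14L)
  d <- bray_curtis(tab)
  grp <- tab$meta$sample_type
  mine <- permanova(d, grp, permutations = 99, seed = 4)
  va <- vegan::adonis2(d ~ grp, data = data.frame(grp = grp),
                       permutations = 99)
  expect_equal(mine$pseudo_F, va$F[1L], tolerance = 1e-10)
  expect_equal(mine$r_squared, va$R2[1L], tolerance = 1e-10)
})

test_that("PERMANOVA permutation p is seeded, bounded and label-invariant", {
  set.seed(32)
  tab <- random_small_table(n_patients = 3L, n_otus = 10L)
  d <- bray_curtis(tab)
  grp <- tab$meta$sample_type
  r1 <- permanova(d, grp, permutations = 199, seed = 11)
  r2 <- permanova(d, grp, permutations = 199, seed = 11)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 200)
  expect_true(r1$r_squared >= 0 && r1$r_squared <= 1)

  # permuting samples consistently leaves F and R^2 unchanged
  perm <- sample(nrow(as.matrix(d)))
  dm <- as.matrix(d)[perm, perm]
  r3 <- permanova(as.dist(dm), grp[perm], permutations = 49, seed = 1)
  expect_equal(r3$pseudo_F, r1$pseudo_F, tolerance = 1e-10)
  expect_equal(r3$r_squared, r1$r_squared, tolerance = 1e-10)
})

test_that("exact paired Wilcoxon reproduces small-sample closed forms", {
  # n = 5, all differences one sign: 2/32
  expect_equal(paired_wilcoxon(6:10, 1:5)$p_value, 0.0625)
  expect_equal(paired_wilcoxon(1:5, 6:10)$p_value, 0.0625)  # symmetry
  # all-but-one pair equal: p = 1 under sign symmetry
  expect_equal(paired_wilcoxon(c(1, 2, 3, 4, 5),
                               c(1, 2, 3, 4, 9))$p_value, 1)
  expect_error(paired_wilcoxon(1:4, 1:4), "zero")
})

test_that("exact Wilcoxon agrees with wilcox.test in the tie-free case", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(4:15, 1L)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(paired_wilcoxon(a, b)$p_value,
                 wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("paired t-test matches the closed-form statistic", {
  a <- c(3.1, 4.2, 5.0, 6.3, 7.7)
  b <- c(2.0, 4.8, 4.1, 5.0, 6.9)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  res <- paired_ttest(a, b)
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$p_value,
               2 * pt(-abs(t_hand), df = length(d) - 1), tolerance = 1e-9)
  expect_error(paired_ttest(a, a), "zero variance")
  # power grows with a constant shift
  set.seed(6)
  base <- rnorm(8)
  noise <- rnorm(8, sd = 0.05)
  p_small <- paired_ttest(base + 0.2 + noise, base)$p_value
  p_big <- paired_ttest(base + 2 + noise, base)$p_value
  expect_lt(p_big, p_small)
})

test_that("DNA yield arithmetic is exact and homogeneous in mass", {
  expect_equal(dna_yield_per_gram(50, 600, 1.0), 30000)
  expect_equal(dna_yield_per_gram(50, 600, 2.0),
               dna_yield_per_gram(50, 600, 1.0) / 2)
  expect_error(dna_yield_per_gram(0, 600, 1), "positive")
})
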