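# Diversity and hypothesis-testing layer: Shannon alpha diversity,
# weighted/unweighted Bray-Curtis, classical PCoA, one-way permutation
# ADONIS, exact paired Wilcoxon signed-rank, paired t, and the
# extraction-QC yield arithmetic.

as_count_matrix <- function(table) {
  if (inherits(table, "otu_table")) return(table$counts)
  m <- as.matrix(table)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  m
}

#' Shannon alpha diversity (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over an individual sample's nonzero relative
#' abundances, in nats. Zero for a single-OTU sample; `log(k)` for `k`
#' equally abundant OTUs.
#'
#' @param table An [otu_table()], a counts matrix, or a single count
#'   vector.
#' @return Named numeric vector of per-sample Shannon indices.
#' @examples
#' shannon_diversity(c(1, 2, 3))
#' @export
shannon_diversity <- function(table) {
  m <- if (is.null(dim(table)) && !inherits(table, "otu_table"))
    matrix(table, nrow = 1L, dimnames = list("sample", NULL)) else
      as_count_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("sample(s) with zero total reads: ",
         paste(rownames(m)[totals == 0], collapse = ", "))
  h <- vegan::diversity(m, index = "shannon", MARGIN = 1)
  stats::setNames(as.numeric(h), rownames(m))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`. The weighted variant is
#' computed on per-sample relative abundances (so sequencing depth cancels);
#' the unweighted variant on presence/absence indicators (count > 0).
#'
#' @param table An [otu_table()] or counts matrix.
#' @param weighted Use abundances (`TRUE`, default) or presence/absence.
#' @param relative For the weighted variant, transform rows to relative
#'   abundances first (default `TRUE`); set `FALSE` for raw-count
#'   Bray-Curtis.
#' @return A [stats::dist] object labelled by sample id; values in \[0,1\].
#' @export
bray_curtis <- function(table, weighted = TRUE, relative = TRUE) {
  m <- as_count_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("sample(s) with zero total reads: ",
         paste(rownames(m)[totals == 0], collapse = ", "))
  if (weighted) {
    x <- if (relative) m / totals else m
    vegan::vegdist(x, method = "bray", binary = FALSE)
  } else {
    vegan::vegdist(m, method = "bray", binary = TRUE)
  }
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres `-D^2/2` and eigendecomposes it. Axes with positive
#' eigenvalues are kept, sorted by decreasing eigenvalue; negative
#' eigenvalues (from non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported, not corrected. Proportion explained is taken over the sum of
#' positive eigenvalues.
#'
#' @param d A [stats::dist] or symmetric distance matrix.
#' @return A list of class `"pcoa_result"`: `coordinates` (samples x
#'   axes), `eigenvalues` (all, decreasing), `proportion_explained`
#'   (per positive axis), `negative_eigenvalues` (logical flag).
#' @export
pcoa <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 2L) stop("PCoA needs at least 2 samples")
  sc <- suppressWarnings(
    stats::cmdscale(d, k = n - 1L, eig = TRUE, add = FALSE))
  eig <- sc$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  coords <- sc$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_along(pos))
  rownames(coords) <- attr(d, "Labels")
  structure(list(coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 proportion_explained = pos / sum(pos),
                 negative_eigenvalues = any(eig < -sqrt(
                   .Machine$double.eps) * max(abs(eig)))),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  pe <- utils::head(x$proportion_explained, 3L)
  cat("  proportion explained:",
      paste(sprintf("%s %.1f%%", names(pe) <- paste0("PCo", seq_along(pe)),
                    100 * pe), collapse = ", "), "\n")
  if (x$negative_eigenvalues)
    cat("  note: negative eigenvalues present (non-Euclidean input)\n")
  invisible(x)
}

permanova_f <- function(d2, groups, n) {
  sst <- sum(d2[lower.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      ssw <- ssw + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  ssb <- sst - ssw
  g <- length(unique(groups))
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  c(f = f, r2 = ssb / sst)
}

#' One-way PERMANOVA (ADONIS) on a distance matrix
#'
#' Partitions the total sum of squared dissimilarities
#' (`SST = sum_{i<j} d_ij^2 / n`) into between- and within-group parts and
#' forms the pseudo-F statistic `F = (SSB/(g-1)) / (SSW/(n-g))`,
#' `R^2 = SSB/SST`. The p-value counts label permutations whose pseudo-F
#' is at least the observed one, with the conservative `(B+1)` correction:
#' `p = (exceedances + 1) / (permutations + 1)`, so `p >= 1/(B+1)`. With
#' `exhaustive = TRUE` all `n!` relabelings are enumerated and
#' `p = exceedances / n!` (the identity counts as an exceedance), which is
#' exact on small designs. A degenerate within-group sum of squares of zero
#' yields `pseudo_F = Inf`; the p-value remains valid through exceedance
#' counting.
#'
#' @param d A [stats::dist] or symmetric distance matrix.
#' @param groups Group labels, one per sample (>= 2 nonempty groups).
#' @param permutations Number of random permutations (default 5000).
#' @param seed Optional integer; makes the permutation p reproducible.
#' @param exhaustive Enumerate all label permutations instead (requires
#'   n <= 9).
#' @return A list of class `"permanova"`: `pseudo_F`, `r_squared`,
#'   `p_value`, `permutations_used`, `groups`.
#' @examples
#' m <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1, 1, 1, 0, 0, 1, 1, 0, 0), 4)
#' permanova(as.dist(m), c("a", "a", "b", "b"), exhaustive = TRUE)
#' @export
permanova <- function(d, groups, permutations = 5000, seed = NULL,
                      exhaustive = FALSE) {
  dm <- as.matrix(stats::as.dist(d))
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n)
    stop("`groups` must have one label per sample")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  d2 <- dm^2
  obs <- permanova_f(d2, groups, n)
  if (exhaustive) {
    if (n > 9L) stop("exhaustive enumeration limited to n <= 9")
    perms <- all_permutations(n)
    fs <- apply(perms, 1L, function(p) permanova_f(d2, groups[p], n)["f"])
    p_value <- sum(fs >= obs["f"] - 1e-12) / nrow(perms)
    used <- nrow(perms)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    }
    fs <- replicate(permutations,
                    permanova_f(d2, groups[sample.int(n)], n)["f"])
    p_value <- (sum(fs >= obs["f"] - 1e-12) + 1) / (permutations + 1)
    used <- as.integer(permutations)
  }
  structure(list(pseudo_F = unname(obs["f"]),
                 r_squared = unname(obs["r2"]), p_value = p_value,
                 permutations_used = used, groups = groups),
            class = "permanova")
}

# all n! permutations of 1..n, one per row (n kept tiny by the caller)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.permanova <- function(x, ...) {
  cat("One-way PERMANOVA (ADONIS)\n")
  cat(sprintf("  pseudo-F = %.4g, R^2 = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$permutations_used))
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test (two-sided)
#'
#' Differences equal to zero are dropped (Wilcoxon's convention); the
#' remaining absolute differences are ranked with midranks for ties, and
#' the exact null distribution of the signed-rank sum is built by dynamic
#' programming over all `2^m` sign assignments (doubled midranks keep the
#' convolution integer-valued, so ties are handled exactly). The two-sided
#' p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`. With five pairs all
#' differing in the same direction this gives `2/32 = 0.0625`.
#'
#' @param a,b Paired numeric vectors of equal length (>= 3 informative
#'   pairs recommended; at least one nonzero difference required).
#' @param max_exact Largest number of nonzero differences for which the
#'   exact distribution is used (default 50); beyond it the normal
#'   approximation with continuity correction is applied.
#' @return A list of class `"paired_wilcoxon"`: `statistic` (signed-rank
#'   sum W+ on the original ranks), `p_value`, `n_used`, `exact`.
#' @examples
#' paired_wilcoxon(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))$p_value  # 0.0625
#' @export
paired_wilcoxon <- function(a, b, max_exact = 50L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) stop("all paired differences are zero")
  r <- rank(abs(d))
  w2 <- as.integer(round(2 * r))   # doubled midranks are integers
  w2_obs <- sum(w2[d > 0])
  if (m <= max_exact) {
    total <- sum(w2)
    f <- numeric(total + 1L)       # f[s+1] = #sign vectors with sum s
    f[1L] <- 1
    for (v in w2) {
      shifted <- c(rep(0, v), f[seq_len(total + 1L - v)])
      f <- f + shifted
    }
    cdf <- cumsum(f) / 2^m
    p_le <- cdf[w2_obs + 1L]
    p_ge <- 1 - (if (w2_obs == 0L) 0 else cdf[w2_obs])
    p <- min(1, 2 * min(p_le, p_ge))
    exact <- TRUE
  } else {
    mu <- sum(w2) / 2
    sigma <- sqrt(sum(w2^2)) / 2
    z <- (w2_obs - mu)
    z <- (abs(z) - 1) / sigma      # continuity correction on doubled scale
    p <- min(1, 2 * stats::pnorm(-z))
    exact <- FALSE
  }
  structure(list(statistic = w2_obs / 2, p_value = p, n_used = m,
                 exact = exact),
            class = "paired_wilcoxon")
}

#' @export
print.paired_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Paired Wilcoxon signed-rank: W+ = %g, n = %d, %s two-sided p = %.4g\n",
    x$statistic, x$n_used, if (x$exact) "exact" else "approximate",
    x$p_value))
  invisible(x)
}

#' Two-sided paired t-test
#'
#' Thin wrapper over [stats::t.test()] that rejects zero-variance
#' differences explicitly instead of returning `NaN`.
#'
#' @param a,b Paired numeric vectors of equal length, n >= 3.
#' @return A list: `statistic`, `df`, `p_value`, `mean_difference`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("paired differences have zero variance; t-test undefined")
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = unname(tt$estimate))
}

#' Shapiro-Wilk normality p-value
#'
#' @param x Numeric vector (3 to 5000 values, not all identical).
#' @return The Shapiro-Wilk p-value in (0, 1\].
#' @export
shapiro_wilk <- function(x) {
  stats::shapiro.test(x)$p.value
}

#' DNA yield per gram of tissue
#'
#' Concentration of DNA in the extraction eluate times eluate volume,
#' divided by the mass of tissue processed: ng DNA per g tissue.
#'
#' @param concentration_ng_per_ul DNA concentration, ng/uL (> 0).
#' @param eluate_volume_ul Eluate volume, uL (> 0).
#' @param tissue_mass_g Tissue mass, g (> 0).
#' @return Yield in ng DNA / g tissue (vectorised).
#' @examples
#' dna_yield_per_gram(50, 600, 1)  # 30000
#' @export
dna_yield_per_gram <- function(concentration_ng_per_ul, eluate_volume_ul,
                               tissue_mass_g) {
  if (any(concentration_ng_per_ul <= 0) || any(eluate_volume_ul <= 0) ||
      any(tissue_mass_g <= 0))
    stop("concentration, volume and mass must all be positive")
  concentration_ng_per_ul * eluate_volume_ul / tissue_mass_g
}
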