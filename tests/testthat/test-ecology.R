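test_that("rarefaction draws a multivariate hypergeometric subsample", {
  x <- c(a = 10L, b = 0L, c = 0L)
  expect_equal(rarefy_counts(x, 5), c(a = 5L, b = 0L, c = 0L))
  expect_equal(rarefy_counts(x, 10), x)
  expect_error(rarefy_counts(x, 11), "depth")
  set.seed(1)
  v <- rpois(40, 20)
  sums <- replicate(500, sum(rarefy_counts(v, 100)))
  expect_true(all(sums == 100))
  # never exceeds the original counts
  r <- rarefy_counts(v, 100, seed = 3)
  expect_true(all(r <= v))
  # distribution agrees with a sequential-hypergeometric oracle
  set.seed(2)
  x2 <- c(50L, 30L, 20L)
  mine <- rowMeans(replicate(3000, rarefy_counts(x2, 10)))
  orac <- rowMeans(replicate(3000, oracle_rarefy(x2, 10)))
  expect_equal(mine, orac, tolerance = 0.05)
  expect_equal(mine, c(5, 3, 2), tolerance = 0.05)
})

test_that("Shannon index closed forms (base 2)", {
  expect_equal(shannon_index(rep(5, 4)), 2.0)
  expect_equal(shannon_index(c(10, 0, 0)), 0.0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  # converges to log2(k) for a rarefied uniform community
  set.seed(4)
  big <- rep(50000L, 16)
  r <- rarefy_counts(big, 1e5)
  expect_equal(shannon_index(r), log2(16), tolerance = 0.02)
})

test_that("alpha diversity medians behave on degenerate and planted matrices", {
  # every sample concentrated on one contig
  m <- matrix(0L, 5, 4, dimnames = list(paste0("c", 1:5), paste0("s", 1:4)))
  m[cbind(1:4, 1:4)] <- 100L
  a <- alpha_diversity(m, n_rarefactions = 20, seed = 1)
  expect_equal(a$median_value[a$metric == "observed_contigs"], rep(1, 4))
  expect_equal(a$median_value[a$metric == "shannon"], rep(0, 4))
  # k equally abundant contigs, depth >> k
  m2 <- matrix(rep(c(500L, 0L), c(6, 4)), 10, 3,
               dimnames = list(paste0("c", 1:10), paste0("s", 1:3)))
  a2 <- alpha_diversity(m2, n_rarefactions = 20, depth = 2000, seed = 2)
  expect_equal(a2$median_value[a2$metric == "observed_contigs"], rep(6, 3))
  expect_error(alpha_diversity(m2, 5, depth = 4000), "smallest")
  # reproducible under seed
  expect_identical(alpha_diversity(m2, 10, seed = 9),
                   alpha_diversity(m2, 10, seed = 9))
})

test_that("planted richness inflation orders group medians", {
  hits <- 0
  for (seed in 1:10) {
    tr <- synth_community(seed = seed)
    groups <- sample_groups(tr)
    a <- alpha_diversity(tr$counts, n_rarefactions = 20, seed = seed + 500)
    a <- a[a$metric == "observed_contigs", ]
    med <- tapply(a$median_value, groups[a$sample_id], median)
    hits <- hits + (med[["NW"]] < med[["O"]] && med[["NW"]] < med[["OMS"]])
  }
  expect_gte(hits, 9)
})

test_that("dominant set counts the smallest prefix reaching the share", {
  expect_equal(dominant_set(c(70, 10, 10, 10))$n_dominant, 1L)
  expect_equal(dominant_set(rep(1, 10))$n_dominant, 7L)
  d <- dominant_set(c(rep(10, 7), rep(1, 3)))
  expect_equal(d$percent_of_phageome, 100 * d$n_dominant / 10)
  expect_error(dominant_set(c(0, 0)), "positive")
})

test_that("Bray-Curtis closed forms and guards", {
  m <- matrix(c(1, 1, 0,
                0, 1, 1,
                1, 1, 0), 3, 3,
              dimnames = list(paste0("c", 1:3), paste0("s", 1:3)))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s2"], 0.5)    # 1 - 2*1/4... shared min sum = 1
  disjoint <- matrix(c(5, 0, 0, 7), 2, 2,
                     dimnames = list(c("c1", "c2"), c("s1", "s2")))
  expect_equal(as.matrix(bray_curtis(disjoint))["s1", "s2"], 1)
  zero <- matrix(c(1, 0, 0, 0), 2, 2,
                 dimnames = list(c("c1", "c2"), c("s1", "s2")))
  expect_error(bray_curtis(zero), "s2")
})

test_that("PCoA reproduces an exact Euclidean configuration", {
  set.seed(7)
  pts <- matrix(rnorm(8 * 3), 8, 3,
                dimnames = list(paste0("s", 1:8), NULL))
  d <- dist(pts)
  ord <- pcoa_ordination(d)
  wide <- tidyr::pivot_wider(ord$coordinates, names_from = "axis",
                             values_from = "value")
  coords <- as.matrix(wide[, -1])
  rownames(coords) <- wide$sample_id
  d2 <- dist(coords[labels(d), ])
  expect_equal(as.vector(d2), as.vector(d), tolerance = 1e-6)
  expect_true(all(diff(ord$eigenvalues) <= 1e-8))   # sorted descending
})

test_that("CLR transform: zero mean, scale invariance, equal-abundance zero", {
  m <- matrix(c(5, 5, 5, 1, 2, 4), 3, 2,
              dimnames = list(paste0("c", 1:3), c("s1", "s2")))
  clr <- clr_transform(m)
  expect_equal(unname(clr[, "s1"]), c(0, 0, 0))
  expect_true(all(abs(colSums(clr)) < 1e-9))
  # doubling a sample leaves its CLR unchanged (offset is negligible here)
  clr2 <- clr_transform(m * 2)
  expect_equal(clr2[, "s2"], clr[, "s2"], tolerance = 1e-6)
  # closed form for one sample
  x <- c(1, 2, 4) + 1e-7
  expect_equal(unname(clr[, "s2"]), log(x) - mean(log(x)))
  # Aitchison = Euclidean on CLR
  expect_equal(as.vector(aitchison_distance(m)),
               as.vector(dist(t(clr_transform(m)))))
})

test_that("permutation group tests: separation, determinism, label invariance", {
  set.seed(31)
  pat_a <- rep(c(100, 0), each = 4)
  pat_b <- rep(c(0, 100), each = 4)
  m <- vapply(1:16, function(i) (if (i <= 8) pat_a else pat_b) + rpois(8, 2),
              numeric(8))
  dimnames(m) <- list(paste0("c", 1:8), sprintf("s%02d", 1:16))
  d <- bray_curtis(m)
  g <- setNames(rep(c("A", "B"), each = 8), colnames(m))
  res <- permutation_group_test(d, g, n_perm = 99, seed = 1)
  # maximal separation: no sampled permutation reaches the observed statistic
  expect_equal(res$p_value, rep(1 / (1 + 99), 2), tolerance = 1e-12)
  res2 <- permutation_group_test(d, g, n_perm = 99, seed = 1)
  expect_equal(res, res2)
  # relabeling the groups (A<->B) leaves the statistic unchanged
  g2 <- setNames(rep(c("B", "A"), each = 8), colnames(m))
  res3 <- permutation_group_test(d, g2, n_perm = 99, seed = 1)
  expect_equal(res3$statistic, res$statistic)
  expect_error(permutation_group_test(d, g, n_perm = 0), "n_perm")
  expect_error(permutation_group_test(d, setNames(rep("A", 16), colnames(m))),
               "groups")
})

test_that("group comparison: exact Mann-Whitney, ties, monotone invariance", {
  df <- tibble::tibble(value = c(1, 2, 3, 10, 11, 12),
                       group = rep(c("a", "b"), each = 3))
  gc <- group_compare(df)
  expect_equal(gc$tests$statistic, 0)
  expect_equal(gc$tests$p_value, 0.1)   # 2/20 rank splits as extreme
  expect_true(gc$tests$exact)
  # identical pooled values: normal approximation gives p = 1
  same <- tibble::tibble(value = rep(c(1, 2, 3), 2),
                         group = rep(c("a", "b"), each = 3))
  gc2 <- suppressWarnings(group_compare(same))
  expect_equal(gc2$tests$p_value, 1)
  expect_false(gc2$tests$exact)
  # strictly monotone transform leaves the statistic unchanged
  df2 <- dplyr::mutate(df, value = exp(value))
  expect_equal(group_compare(df2)$tests$statistic, gc$tests$statistic)
  expect_equal(group_compare(df2)$tests$p_value, gc$tests$p_value)
  # normality is reported per group when computable
  set.seed(11)
  big <- tibble::tibble(value = rnorm(40), group = rep(c("a", "b"), 20))
  expect_equal(nrow(group_compare(big)$normality), 2L)
  expect_false(anyNA(group_compare(big)$normality$shapiro_p))
  tiny <- tibble::tibble(value = c(1, 1, 5), group = c("a", "a", "b"))
  w <- testthat::capture_warnings(group_compare(tiny))
  expect_true(all(grepl("skipped", w)) && length(w) == 2)
})
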