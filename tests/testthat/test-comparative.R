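test_that("presence criteria: coverage threshold inclusive, nonzero counts", {
  cov <- tibble::tibble(
    contig_id = c("c1", "c1", "c2", "c2"),
    sample_id = c("s1", "s2", "s1", "s2"),
    covered_fraction = c(0.80, 0.79, 0.10, 0.95),
    mapped_read_count = c(40L, 500L, 3L, 60L)
  )
  p <- presence_matrix(cov, "coverage", contigs = c("c1", "c2"),
                       samples = c("s1", "s2"))
  expect_true(p["c1", "s1"])       # boundary inclusive
  expect_false(p["c1", "s2"])      # 0.79 with 500 reads: absent
  counts <- matrix(c(0L, 5L, 1L, 0L), 2, 2,
                   dimnames = list(c("c1", "c2"), c("s1", "s2")))
  p2 <- presence_matrix(counts, "nonzero_count")
  expect_identical(unname(p2), unname(counts > 0))
  expect_error(presence_matrix(cov, "typo"), "arg")
})

test_that("prevalence classes partition contigs with the stated boundaries", {
  pres <- matrix(FALSE, 5, 28,
                 dimnames = list(paste0("c", 1:5), paste0("s", 1:28)))
  pres["c1", 1:24] <- TRUE   # 85.7% -> core
  pres["c2", 1:28] <- TRUE   # 100%  -> core
  pres["c3", 1:14] <- TRUE   # exactly 50% -> individual (boundary policy)
  pres["c4", 1:20] <- TRUE   # 71.4% -> common
  cl <- classify_prevalence(pres)
  expect_equal(cl$class, c("core", "core", "individual", "common", "individual"))
  expect_equal(sum(table(cl$class)), nrow(pres))
  # exactly 80% is common under the (50, 80] rule
  pres10 <- matrix(FALSE, 1, 10, dimnames = list("x", paste0("s", 1:10)))
  pres10["x", 1:8] <- TRUE
  expect_equal(classify_prevalence(pres10)$class, "common")
})

test_that("unique sweep: group-exclusive presence, monotone counts, recommended cutoff", {
  groups <- setNames(rep(c("NW", "O", "OMS"), c(10, 10, 8)),
                     sprintf("s%02d", 1:28))
  pres <- matrix(FALSE, 4, 28, dimnames = list(paste0("c", 1:4), names(groups)))
  pres["c1", 1:3] <- TRUE            # 3/10 NW, absent elsewhere
  pres["c2", c(1, 11, 21)] <- TRUE   # one sample in each group
  pres["c3", 11:18] <- TRUE          # 8/10 O only
  sw <- unique_sweep(pres, groups)
  at30 <- sw[abs(sw$cutoff - 0.3) < 1e-9, ]
  expect_equal(at30$n_unique[at30$group == "NW"], 1L)
  expect_true("c1" %in% at30$contig_ids[at30$group == "NW"][[1]])
  expect_equal(sum(sw$n_unique[sw$group == "OMS"]), 0L)
  # c2 is unique to no group at any cutoff
  expect_false(any(vapply(sw$contig_ids, function(x) "c2" %in% x, logical(1))))
  # monotone in cutoff for every group
  for (g in c("NW", "O", "OMS")) {
    ng <- sw$n_unique[sw$group == g][order(sw$cutoff[sw$group == g])]
    expect_true(all(diff(ng) <= 0))
  }
  # totals tie from 0.2 to 0.3 (c1 at 30%, c3 at 80%); recommendation is the
  # most stringent cutoff attaining the maximum
  expect_equal(attr(sw, "recommended_cutoff"), 0.3)
  expect_error(unique_sweep(pres, groups[-(1:28)]), "labeled")
})

test_that("unique sweep monotonicity holds on random presence matrices", {
  set.seed(15)
  groups <- setNames(rep(c("NW", "O", "OMS"), c(10, 10, 8)),
                     sprintf("s%02d", 1:28))
  for (rep in 1:5) {
    pres <- matrix(runif(40 * 28) < 0.25, 40, 28,
                   dimnames = list(paste0("c", 1:40), names(groups)))
    sw <- unique_sweep(pres, groups)
    for (g in unique(groups)) {
      ng <- sw$n_unique[sw$group == g][order(sw$cutoff[sw$group == g])]
      expect_true(all(diff(ng) <= 0))
    }
  }
})

test_that("prevalence shift reproduces the weighted-mean construction", {
  # 52 contigs prevalent in NW: 8 present in 10/10, 44 in 9/10
  groups <- setNames(rep(c("NW", "O"), c(10, 10)), sprintf("s%02d", 1:20))
  pres <- matrix(FALSE, 52, 20, dimnames = list(sprintf("c%02d", 1:52),
                                                names(groups)))
  pres[1:8, 1:10] <- TRUE
  for (i in 9:52) pres[i, 1:9] <- TRUE
  # O group: all selected contigs present in 6/10
  pres[, 11:16] <- TRUE
  ps <- prevalence_shift(pres, groups, reference = "NW")
  expect_equal(ps$summary$n_contigs, c(52L, 52L))
  nw_mean <- ps$summary$mean_prevalence[ps$summary$group == "NW"]
  expect_equal(nw_mean, (8 * 100 + 44 * 90) / 52)
  expect_equal(round(nw_mean, 2), 91.54)
  expect_equal(ps$summary$mean_prevalence[ps$summary$group == "O"], 60)
  expect_lt(ps$tests$p_value, 1e-6)
  # locality: removing one group's presences lowers only that group's mean
  pres2 <- pres
  pres2[, 11:16] <- FALSE
  pres2[1:20, 11:13] <- TRUE
  ps2 <- prevalence_shift(pres2, groups, reference = "NW")
  expect_equal(ps2$summary$mean_prevalence[ps2$summary$group == "NW"], nw_mean)
  expect_lt(ps2$summary$mean_prevalence[ps2$summary$group == "O"], 60)
  # all contigs everywhere: means 100, test p = 1
  all_p <- matrix(TRUE, 5, 20, dimnames = list(paste0("c", 1:5), names(groups)))
  ps3 <- suppressWarnings(prevalence_shift(all_p, groups, reference = "NW"))
  expect_true(all(ps3$summary$mean_prevalence == 100))
  expect_equal(ps3$tests$p_value, 1)
  # empty selection warns
  none <- matrix(FALSE, 3, 20, dimnames = list(paste0("c", 1:3), names(groups)))
  expect_warning(prevalence_shift(none, groups, reference = "NW"), "threshold")
})

test_that("size factors: identity, doubling, reorder invariance, DESeq2 agreement", {
  set.seed(21)
  counts <- matrix(rnbinom(200, mu = 50, size = 5) + 1L, 20, 10,
                   dimnames = list(paste0("c", 1:20), paste0("s", 1:10)))
  sf0 <- size_factors(cbind(s1 = counts[, 1], s2 = counts[, 1]))
  expect_equal(unname(sf0), c(1, 1))
  doubled <- cbind(counts, sX = 2L * counts[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf["sX"] / sf["s1"]), 2)
  perm <- sample(nrow(counts))
  expect_equal(size_factors(counts[perm, ]), size_factors(counts))
  # matches the reference implementation on an all-positive matrix
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(size_factors(counts), ref, tolerance = 1e-12)
  # sparse fallback: no all-positive contig
  sparse <- counts
  for (j in 1:10) sparse[sample(20, 8), j] <- 0L
  keep <- rowSums(sparse > 0) < 10 & rowSums(sparse > 0) > 0
  expect_true(all(size_factors(sparse[keep, , drop = FALSE]) > 0))
  expect_error(size_factors(sparse[keep, , drop = FALSE], fallback = FALSE),
               "all-positive|positive counts")
})

test_that("NB differential flags planted effects and honors the prevalence gate", {
  set.seed(31)
  n <- 10
  groups <- setNames(rep(c("T", "R"), each = n), sprintf("s%02d", 1:(2 * n)))
  mu <- matrix(60, 120, 2 * n, dimnames = list(sprintf("c%03d", 1:120),
                                               names(groups)))
  mu[1:10, groups == "T"] <- 60 * 8       # planted log2FC = 3
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), nrow(mu), ncol(mu),
                   dimnames = dimnames(mu))
  # a planted 8-fold contig detected in only 2/10 target samples
  counts[11, ] <- 0L
  counts[11, which(groups == "T")[1:2]] <- 500L
  d <- nb_differential(counts, groups, target = "T", reference = "R")
  expect_s3_class(d, "phg_diff")
  expect_true(all(d$flagged[1:10]))
  expect_false(d$flagged[11])
  expect_lt(d$prevalence_in_target[11], 0.3)
  expect_equal(sum(d$flagged[-(1:11)]), 0L)
  expect_true(all(abs(d$log2_fold_change[1:10] - 3) < 1))
  # invariant: flag rule
  expect_equal(d$flagged,
               !is.na(d$bh_adjusted_p) & d$log2_fold_change >= 2 &
                 d$bh_adjusted_p <= 0.05 & d$prevalence_in_target >= 0.3)
  expect_error(nb_differential(counts / 3, groups, "T", "R"), "integer")
  g2 <- setNames(rep(c("T", "R"), c(2, 18)), names(groups))
  expect_error(nb_differential(counts, g2, "T", "R"), ">= 3")
  # glance/tidy
  gl <- glance(d)
  expect_equal(gl$n_flagged, 10L)
  expect_false(inherits(tidy(d), "phg_diff"))
})

test_that("NB differential log2FC agrees with DESeq2 on a dense fixture", {
  set.seed(41)
  groups <- setNames(rep(c("T", "R"), each = 8), sprintf("s%02d", 1:16))
  mu <- matrix(rep(c(200, 50, 120), length.out = 60 * 16), 60, 16,
               dimnames = list(sprintf("c%03d", 1:60), names(groups)))
  mu[1:12, groups == "T"] <- mu[1:12, groups == "T"] * 6
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), 60, 16,
                   dimnames = dimnames(mu))
  d <- nb_differential(counts, groups, "T", "R")
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    countData = counts,
    colData = data.frame(group = factor(unname(groups), levels = c("R", "T"))),
    design = ~group))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  ok <- !is.na(res$log2FoldChange)
  expect_gt(cor(d$log2_fold_change[ok], res$log2FoldChange[ok]), 0.98)
  expect_equal(unname(d$log2_fold_change[1:12]), res$log2FoldChange[1:12],
               tolerance = 0.15)
})

test_that("venn partition reproduces the printed arithmetic", {
  o <- sprintf("c%03d", 1:82)
  oms <- sprintf("c%03d", 64:130)   # overlap of 19? set up |shared| = 48
  oms <- c(sprintf("c%03d", 35:82), sprintf("x%02d", 1:19))
  v <- venn_partition(o, oms, names = c("O", "OMS"))
  expect_equal(v$n[v$region == "shared"], 48L)
  expect_equal(v$n[v$region == "only_O"], 34L)
  expect_equal(v$n[v$region == "only_OMS"], 19L)
  expect_equal(venn_partition(c("a"), c("b"))$n, c(1L, 1L, 0L))
  same <- venn_partition(c("a", "b"), c("a", "b"))
  expect_equal(same$n, c(0L, 0L, 2L))
})

test_that("correlation screen: selection rule, ties, oracle agreement", {
  set.seed(51)
  n <- 28
  x <- matrix(rlnorm(3 * n), 3, n,
              dimnames = list(c("up", "down", "null"), sprintf("s%02d", 1:n)))
  covs <- tibble::tibble(
    sample_id = colnames(x),
    mono_up = rank(x["up", ]) + 0.0,         # perfectly monotone
    mono_down = -(x["down", ])^3,
    noise = rnorm(n)
  )
  cs <- correlation_screen(x, covs)
  up <- cs[cs$contig_id == "up" & cs$covariate == "mono_up", ]
  expect_equal(up$spearman_rho, 1)
  expect_true(up$selected)
  dn <- cs[cs$contig_id == "down" & cs$covariate == "mono_down", ]
  expect_equal(dn$spearman_rho, -1)
  expect_true(dn$selected)   # r^2 = 1 regardless of sign
  # rho = 0.5 gives r^2 = 0.25 <= 0.3: never selected
  expect_true(all(!cs$selected[cs$r_squared <= 0.3]))
  # rho equals a rank-then-Pearson oracle to 1e-12
  for (i in 1:3) {
    xx <- x[i, ]
    yy <- covs$noise
    rk <- function(v) {
      o <- order(v)
      r <- numeric(length(v)); r[o] <- seq_along(v)
      ave(r, v, FUN = mean)   # average ties
    }
    a <- rk(xx) - mean(rk(xx)); b <- rk(yy) - mean(rk(yy))
    oracle_rho <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    got <- cs$spearman_rho[cs$contig_id == rownames(x)[i] &
                             cs$covariate == "noise"]
    expect_equal(got, oracle_rho, tolerance = 1e-12)
  }
  # constant covariate skipped with a warning
  covs$flat <- 1
  expect_warning(correlation_screen(x, covs), "skipped")
  # exact p for small tie-free samples matches cor.test
  x5 <- matrix(c(3.2, 1.1, 4.8, 2.5, 5.9, 0.7, 6.3), 1, 7,
               dimnames = list("c", sprintf("s%d", 1:7)))
  cv5 <- tibble::tibble(sample_id = colnames(x5),
                        v = c(2.1, 0.4, 3.3, 5.0, 4.2, 1.7, 6.6))
  got5 <- correlation_screen(x5, cv5)
  ref5 <- cor.test(x5[1, ], cv5$v, method = "spearman", exact = TRUE)
  expect_equal(got5$p_unadjusted, ref5$p.value)
  expect_equal(got5$spearman_rho, unname(ref5$estimate))
})

test_that("planted copula correlations at rho 0.8 are recovered across seeds", {
  tr <- synth_community(seed = 1)
  rpkm <- sweep(sweep(tr$counts, 1,
                      setNames(tr$catalog$length, tr$catalog$contig_id) / 1e3,
                      "/"), 2, tr$sample_totals / 1e6, "/")
  anchor <- tr$core_set[1]
  hits <- 0
  for (seed in 1:10) {
    targets <- tibble::tibble(contig_id = anchor, covariate = "BMI", rho = 0.8)
    cov <- synth_covariates(tr, targets = targets, seed = seed + 100)
    cs <- correlation_screen(rpkm[anchor, , drop = FALSE],
                             cov$clinical[, c("sample_id", "BMI")])
    hits <- hits + as.integer(cs$selected && abs(cs$spearman_rho) >= 0.6)
  }
  expect_gte(hits, 9)
})
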