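test_that("synthetic community plants disjoint sets with exact prevalence", {
  tr <- synth_community(seed = 3)
  planted <- c(tr$core_set, unlist(tr$unique_sets), tr$diff$contig_id)
  expect_equal(anyDuplicated(planted), 0L)
  groups <- sample_groups(tr)
  pres <- tr$counts > 0
  # core: planted mean >= 100 in every sample; zero draws are practically
  # impossible at dispersion 0.1, so realized prevalence is 1
  expect_true(all(rowMeans(pres[tr$core_set, ]) == 1))
  # unique contigs: exactly half their group present, absent elsewhere
  for (g in names(tr$unique_sets)) {
    ids <- tr$unique_sets[[g]]
    own <- pres[ids, groups == g, drop = FALSE]
    other <- tr$mu[ids, groups != g, drop = FALSE]
    expect_true(all(rowSums(own > 0) <= sum(groups == g)))
    expect_true(all(other == 0))
    expect_true(all(rowSums(tr$mu[ids, groups == g, drop = FALSE] > 0) ==
                      round(0.5 * sum(groups == g))))
  }
  # differential contigs: planted mean carries the fold change
  for (j in seq_len(nrow(tr$diff))) {
    cid <- tr$diff$contig_id[j]
    tg <- if (tr$diff$target[j] == "both") c("O", "OMS") else tr$diff$target[j]
    mu_t <- tr$mu[cid, groups %in% tg]
    mu_r <- tr$mu[cid, groups == "NW"]
    ratio <- mean(mu_t[mu_t > 0]) / mean(mu_r[mu_r > 0])
    expect_equal(log2(ratio), tr$diff$log2fc[j], tolerance = 0.2)
  }
  # richness block: absent from NW, present in disease groups
  expect_true(all(tr$mu[tr$extra_set, groups == "NW"] == 0))
  expect_true(all(rowSums(tr$mu[tr$extra_set, groups != "NW"] > 0) > 0))
  # catalog lengths within the configured range
  expect_true(all(tr$catalog$length >= 4000))
  expect_true(all(tr$catalog$length <= 176210))
  expect_error(synth_community(n_contigs = 10, n_core = 20),
               "inconsistent")
})

test_that("synthetic community is reproducible and respects chimera/short flags", {
  a <- synth_community(seed = 5, chimera_fraction = 0.1, short_fraction = 0.1)
  b <- synth_community(seed = 5, chimera_fraction = 0.1, short_fraction = 0.1)
  expect_identical(a$counts, b$counts)
  expect_identical(a$diff, b$diff)
  expect_equal(length(a$chimera_set), round(0.1 * a$params$n_contigs))
  expect_true(all(a$catalog$length[a$catalog$contig_id %in% a$short_set] < 4000))
  # planted roles never overlap the chimera/short decoys
  planted <- c(a$core_set, unlist(a$unique_sets), a$diff$contig_id)
  expect_length(intersect(planted, c(a$chimera_set, a$short_set)), 0)
})

test_that("emitted alignments realize planted counts and decoy structure", {
  tr <- synth_community(n_per_group = c(NW = 2, O = 2), n_contigs = 8,
                        n_core = 2, n_unique = c(NW = 1, O = 1), n_diff = 2,
                        mean_reads = 400, mu_floor = 20,
                        length_range = c(4000, 5000), seed = 7)
  dir <- withr::local_tempdir()
  al <- synth_alignments(tr, dir, seed = 8)
  expect_true(all(file.exists(al$sam_paths)))
  s <- colnames(tr$counts)[2]
  aln <- parse_alignments(al$sam_paths[[s]], al$catalog, sample_id = s)
  flt <- filter_alignments(aln)
  # passing reads exactly match the planted counts
  got <- table(factor(flt$contig_id, levels = rownames(tr$counts)))
  expect_equal(as.integer(got), unname(tr$counts[, s]))
  # decoys fail for the planted reason
  decoy <- aln[!aln$read_id %in% flt$read_id, ]
  id_fail <- grepl("_i\\d+$", decoy$read_id)
  expect_true(all(decoy$identity[id_fail] < 0.9))
  expect_true(all(decoy$aligned_fraction[!id_fail] < 0.8))
  # zero mutation rate: every emitted read passes
  al0 <- synth_alignments(tr, withr::local_tempdir(),
                          fail_identity_fraction = 0,
                          fail_length_fraction = 0, max_pass_edits = 0,
                          seed = 9)
  aln0 <- parse_alignments(al0$sam_paths[[s]], al0$catalog, sample_id = s)
  expect_equal(nrow(aln0), nrow(filter_alignments(aln0)))
  expect_true(all(aln0$identity == 1))
})

test_that("chimera-like contigs never reach 80% coverage in any sample", {
  tr <- synth_community(n_per_group = c(NW = 3, O = 3), n_contigs = 12,
                        n_core = 2, n_unique = c(NW = 1, O = 1), n_diff = 2,
                        mean_reads = 2500, mu_floor = 150,
                        length_range = c(4000, 5000),
                        chimera_fraction = 0.25, seed = 17)
  dir <- withr::local_tempdir()
  al <- synth_alignments(tr, dir, seed = 18)
  aln <- purrr::imap_dfr(as.list(al$sam_paths), function(p, s)
    parse_alignments(p, al$catalog, sample_id = s))
  cov <- coverage_profiles(filter_alignments(aln), al$catalog)
  chim_cov <- cov$covered_fraction[cov$contig_id %in% tr$chimera_set]
  expect_true(all(chim_cov <= 0.5))
  keep <- chimera_filter(cov, al$catalog)
  expect_length(intersect(keep, tr$chimera_set), 0)
})

test_that("synthetic reads for clustering respect divergence contracts", {
  r <- synth_reads(6, 5, divergence = 0.02, length = 150, seed = 2)
  expect_length(r$reads, 30)
  expect_equal(r$true_k, 6)
  # within-template identity >= 98%, between-template far below 80%
  for (t in 1:6) {
    members <- r$reads[r$read_template == t]
    expect_true(all(vapply(members, pairwise_identity,
                           numeric(1), seq_b = r$templates[t]) >= 0.98))
  }
  cross <- pairwise_identity(r$templates[1], r$templates[2])
  expect_lt(cross, 0.8)
  expect_error(synth_reads(3, 3, divergence = 0.06), "5%")
})

test_that("covariate tables close taxa to 1 and plant rank correlations", {
  tr <- synth_community(seed = 9)
  cov <- synth_covariates(tr, seed = 10)
  taxa_mat <- as.matrix(cov$taxa[, -1])
  expect_true(all(abs(rowSums(taxa_mat) - 1) < 1e-9))
  expect_equal(nrow(cov$taxa), ncol(tr$counts))
  expect_named(cov$clinical,
               c("sample_id", "BMI", "HDL", "triglycerides", "glucose",
                 "waist", "weight"))
  # a planted clinical pair shows the right sign and magnitude of rank
  # correlation in this realization
  rpkm <- sweep(sweep(tr$counts, 1,
                      setNames(tr$catalog$length, tr$catalog$contig_id) / 1e3,
                      "/"), 2, tr$sample_totals / 1e6, "/")
  tg <- cov$targets[cov$targets$covariate == "triglycerides", ]
  rho <- cor(rank(rpkm[tg$contig_id, cov$clinical$sample_id]),
             rank(cov$clinical$triglycerides))
  expect_gt(rho * sign(tg$rho), 0.4)
  # HDL is planted negative
  expect_lt(cov$targets$rho[cov$targets$covariate == "HDL"], 0)
})

test_that("planted null covariates select at the false-positive rate only", {
  tr <- synth_community(seed = 12)
  targets <- tibble::tibble(contig_id = character(), covariate = character(),
                            rho = numeric())
  cov <- synth_covariates(tr, targets = targets, seed = 13)
  rpkm <- sweep(sweep(tr$counts, 1,
                      setNames(tr$catalog$length, tr$catalog$contig_id) / 1e3,
                      "/"), 2, tr$sample_totals / 1e6, "/")
  use <- rownames(rpkm)[rowSums(rpkm > 0) == ncol(rpkm)]
  cs <- suppressWarnings(correlation_screen(rpkm[use, , drop = FALSE],
                                            cov$clinical))
  expect_lt(mean(cs$selected), 0.05)
})

test_that("synthetic hit generator covers all planted roles", {
  tree <- synth_taxonomy()
  sh <- synth_hits(sprintf("q%03d", 1:80), tree, seed = 4)
  expect_setequal(unique(sh$expected$category),
                  c("prokaryotic_virus", "eukaryotic_virus", "ambiguous",
                    "unknown"))
  expect_true(any(sh$expected$evidence == "protein"))
  # every expected taxon exists in the tree
  tax <- sh$expected$taxon[!is.na(sh$expected$taxon)]
  expect_true(all(tax %in% tree$node))
})
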