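#' Generate a synthetic phageome community with planted ground truth
#'
#' Emulates the structure of a three-group VLP metagenome cohort
#' (normal-weight, obese, obese with metabolic syndrome): a contig catalog
#' with log-uniform lengths, sparse contig-by-sample counts with
#' gamma-Poisson (negative binomial) noise, a planted core set present in
#' every sample, group-unique contigs, contigs with planted fold changes in
#' the disease groups, extra low-abundance contigs inflating richness in the
#' disease groups, and optional chimera-like / short contigs exercising the
#' assembly filters.
#'
#' @param n_per_group Named group sizes (default 10 NW / 10 O / 8 OMS).
#' @param n_contigs Baseline catalog size (before the richness block).
#' @param n_core Planted core contigs (present in all samples).
#' @param n_unique Named per-group counts of group-unique contigs.
#' @param unique_prevalence Within-group prevalence of unique contigs.
#' @param n_diff Planted differential contigs, split 1/3 over-abundant in O
#'   only, 1/3 in OMS only, 1/3 in both.
#' @param lfc_range Planted log2 fold changes drawn uniformly from this range
#'   (default 2-3, i.e. 4- to 8-fold).
#' @param common_fraction Fraction of baseline contigs drawn with >50%
#'   prevalence (the rest are individual-specific).
#' @param richness_inflation Fraction of extra low-abundance contigs present
#'   only in the disease groups (default 0.15).
#' @param dispersion Gamma-Poisson dispersion of the count noise.
#' @param baseline_sigma Log-normal sigma of baseline contig abundances.
#' @param mean_reads Target expected per-sample total counts.
#' @param length_range Contig length range (log-uniform draw), default
#'   4 kb to 176,210 nt.
#' @param mu_floor Minimum planted per-sample mean for core/differential
#'   contigs, so detection is not the limiting factor for those analyses.
#' @param chimera_fraction Fraction of baseline contigs marked chimera-like
#'   (their reads are later confined to half the contig by
#'   [synth_alignments()]).
#' @param short_fraction Fraction of baseline contigs drawn shorter than 4 kb
#'   (removed by the length filter).
#' @param seed Master seed; all randomness flows from it.
#' @return A `phg_truth` list: `metadata` (tibble `sample_id`, `group`),
#'   `catalog`, `counts` (realized matrix), `mu` (planted means),
#'   `core_set`, `unique_sets`, `diff` (tibble `contig_id`, `target`,
#'   `log2fc`), `extra_set`, `chimera_set`, `short_set`, `sample_totals`,
#'   `params`.
#' @export
synth_community <- function(n_per_group = c(NW = 10, O = 10, OMS = 8),
                            n_contigs = 400, n_core = 16,
                            n_unique = c(NW = 10, O = 7, OMS = 2),
                            unique_prevalence = 0.5,
                            n_diff = 24, lfc_range = c(2, 3),
                            common_fraction = 0.25,
                            richness_inflation = 0.15,
                            dispersion = 0.1, baseline_sigma = 1.2,
                            mean_reads = 2e4, mu_floor = 100,
                            length_range = c(4000, 176210),
                            chimera_fraction = 0, short_fraction = 0,
                            seed = 1) {
  groups <- rep(names(n_per_group), n_per_group)
  sample_id <- unname(unlist(purrr::imap(as.list(n_per_group), function(n, g)
    sprintf("%s_%02d", g, seq_len(n)))))
  meta <- tibble::tibble(sample_id = sample_id, group = groups)

  n_roles <- n_core + sum(n_unique) + n_diff
  if (n_roles > n_contigs)
    abort("planted sets exceed the catalog size (inconsistent config)")

  with_seed_(seed, {
    n_extra <- round(richness_inflation * n_contigs)
    n_total <- n_contigs + n_extra
    ids <- sprintf("contig_%04d", seq_len(n_total))
    lengths <- round(10^runif(n_total, log10(length_range[1]),
                              log10(length_range[2])))

    # planted roles are drawn from the baseline block and kept disjoint
    pool <- sample(ids[seq_len(n_contigs)])
    take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
    core_set <- take(n_core)
    unique_sets <- purrr::map(as.list(n_unique), take)
    # O-only / OMS-only / shared split mirrors the 34/19/48 structure of
    # over-abundant contigs reported in childhood-obesity phageomes
    n_o <- round(0.34 * n_diff); n_oms <- round(0.19 * n_diff)
    diff_ids <- take(n_diff)
    diff <- tibble::tibble(
      contig_id = diff_ids,
      target = rep(c("O", "OMS", "both"), c(n_o, n_oms, n_diff - n_o - n_oms)),
      log2fc = runif(n_diff, lfc_range[1], lfc_range[2])
    )
    # chimera-like and short contigs come from the unplanted remainder
    chimera_set <- pool[seq_len(round(chimera_fraction * n_contigs))]
    pool <- setdiff(pool, chimera_set)
    short_set <- pool[seq_len(round(short_fraction * n_contigs))]
    lengths[match(short_set, ids)] <- round(runif(length(short_set), 500, 3999))
    extra_set <- ids[n_contigs + seq_len(n_extra)]

    catalog <- tibble::tibble(contig_id = ids, length = lengths)

    # baseline log-normal compositional weights; recruited read counts scale
    # with contig length (RPKM then reflects the weight); richness-block
    # contigs are low-abundance
    w <- stats::rlnorm(n_total, meanlog = 0, sdlog = baseline_sigma)
    names(w) <- ids
    w <- w * lengths / exp(mean(log(lengths)))
    w[extra_set] <- w[extra_set] * 0.15

    # Background presence: most contigs individual-specific (< 50%
    # prevalence), about a quarter common — mirroring the cohort's observed
    # prevalence structure — drawn iid per sample.
    n_samples <- nrow(meta)
    is_common <- runif(n_total) < common_fraction
    pi_contig <- ifelse(is_common, runif(n_total, 0.55, 0.95),
                        runif(n_total, 0.05, 0.50))
    pi_mat <- matrix(pi_contig, n_total, n_samples,
                     dimnames = list(ids, meta$sample_id))
    present <- matrix(stats::rbinom(length(pi_mat), 1, pi_mat),
                      n_total, n_samples, dimnames = dimnames(pi_mat))

    # Planted features use balanced presence: exactly the target number of
    # positive samples per group, so the planted prevalence is exact rather
    # than in expectation. Differential contigs sit at 90% within-group
    # prevalence — prevalent, but with at least one zero per group so the
    # all-positive reference set of the size-factor estimator stays free of
    # planted fold changes.
    plant_exact <- function(cids, group_prev) {
      for (g in names(group_prev)) {
        cols <- which(meta$group == g)
        k <- round(group_prev[[g]] * length(cols))
        for (cid in cids) {
          present[cid, cols] <<- 0L
          if (k > 0) present[cid, sample(cols, k)] <<- 1L
        }
      }
    }
    all_groups <- unique(meta$group)
    plant_exact(core_set, setNames(rep(1, length(all_groups)), all_groups))
    plant_exact(diff$contig_id,
                setNames(rep(0.9, length(all_groups)), all_groups))
    for (g in names(unique_sets)) {
      prev <- setNames(rep(0, length(all_groups)), all_groups)
      prev[g] <- unique_prevalence
      plant_exact(unique_sets[[g]], prev)
    }
    extra_prev <- setNames(rep(0.7, length(all_groups)), all_groups)
    extra_prev[all_groups[1]] <- 0  # richness block absent from the reference group
    plant_exact(extra_set, extra_prev)

    # planted fold changes in the disease groups
    fold <- matrix(1, n_total, n_samples, dimnames = dimnames(pi_mat))
    for (j in seq_len(nrow(diff))) {
      tg <- if (diff$target[j] == "both") c("O", "OMS") else diff$target[j]
      fold[diff$contig_id[j], meta$group %in% tg] <- 2^diff$log2fc[j]
    }

    lib <- exp(rnorm(n_samples, 0, 0.15))
    mu <- w * present * fold * rep(lib, each = n_total)
    mu <- mu * (mean_reads / mean(colSums(mu)))
    # keep core/differential contigs comfortably detectable: floor the
    # baseline (pre-fold) mean over the samples where they are present
    anchor <- union(core_set, diff$contig_id)
    base <- mu[anchor, , drop = FALSE] / fold[anchor, , drop = FALSE]
    base_min <- apply(base, 1, function(r) min(r[r > 0]))
    mu[anchor, ] <- mu[anchor, ] * pmax(1, mu_floor / base_min)

    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     n_total, n_samples, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"

    structure(list(
      metadata = meta, catalog = catalog, counts = counts, mu = mu,
      core_set = core_set, unique_sets = unique_sets, diff = diff,
      extra_set = extra_set, chimera_set = chimera_set, short_set = short_set,
      sample_totals = colSums(counts),
      params = list(n_per_group = n_per_group, n_contigs = n_contigs,
                    n_core = n_core, n_unique = n_unique,
                    unique_prevalence = unique_prevalence, n_diff = n_diff,
                    lfc_range = lfc_range,
                    richness_inflation = richness_inflation,
                    dispersion = dispersion, baseline_sigma = baseline_sigma,
                    mean_reads = mean_reads, mu_floor = mu_floor,
                    chimera_fraction = chimera_fraction,
                    short_fraction = short_fraction, seed = seed)
    ), class = "phg_truth")
  })
}

#' @export
print.phg_truth <- function(x, ...) {
  cat("<phg_truth> ", nrow(x$counts), " contigs x ", ncol(x$counts),
      " samples (", paste(names(x$params$n_per_group),
                          x$params$n_per_group, sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  planted: ", length(x$core_set), " core, ",
      sum(lengths(x$unique_sets)), " unique, ", nrow(x$diff),
      " differential, ", length(x$extra_set), " richness-block contigs\n",
      sep = "")
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(bases), n_mut)
  bases[pos] <- vapply(bases[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(bases, collapse = "")
}

#' Emit per-sample SAM alignments realizing planted counts
#'
#' Writes one SAM file per sample. Each planted count becomes a read that
#' passes the default recruitment filters (identity >= 0.9 over the full
#' read); a configurable fraction of additional decoy reads is planted to
#' fail either the identity filter (15% edits) or the aligned-fraction
#' filter (25% soft-clipped). Reads of chimera-like contigs are confined to
#' the first half of the contig in every sample, so those contigs can never
#' reach 80% coverage.
#'
#' For every other contig-sample pair with at least `ceil(L/read_length) + 1`
#' planted reads, that many reads are placed as a deterministic tile covering
#' the whole contig (guaranteeing the coverage filter is a function of the
#' planted structure, not of placement luck); remaining reads are placed
#' uniformly. Substitutions matching the NM tag are applied to each read
#' sequence.
#'
#' @param truth A `phg_truth` from [synth_community()].
#' @param dir Output directory for `<sample>.sam` files.
#' @param read_length Read length in nt (default 100).
#' @param fail_identity_fraction,fail_length_fraction Decoy read fractions
#'   relative to the planted count (defaults 0.1 each).
#' @param max_pass_edits Passing reads carry `Binomial(read_length, 0.02)`
#'   edits capped at `floor(0.1 * read_length)` so they stay at or above 90%
#'   identity.
#' @param seed Seed.
#' @return List: `sam_paths` (named by sample), `sample_totals` (reads
#'   emitted per sample), `planted_counts` (= `truth$counts`), `catalog`
#'   (with sequences).
#' @export
synth_alignments <- function(truth, dir, read_length = 100,
                             fail_identity_fraction = 0.1,
                             fail_length_fraction = 0.1,
                             max_pass_edits = NULL, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(max_pass_edits)) max_pass_edits <- floor(0.1 * read_length)
  catalog <- truth$catalog
  counts <- truth$counts
  rl <- read_length
  with_seed_(seed, {
    catalog$sequence <- vapply(catalog$length, random_dna, character(1))
    seqs <- setNames(catalog$sequence, catalog$contig_id)
    lens <- setNames(catalog$length, catalog$contig_id)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", catalog$contig_id, catalog$length))
    chim <- truth$chimera_set

    totals <- setNames(integer(ncol(counts)), colnames(counts))
    paths <- setNames(file.path(dir, paste0(colnames(counts), ".sam")),
                      colnames(counts))
    for (s in colnames(counts)) {
      per_contig <- vector("list", nrow(counts))
      for (ci in seq_len(nrow(counts))) {
        cid <- rownames(counts)[ci]
        n_pass <- counts[cid, s]
        if (n_pass == 0) next
        n_fid <- round(fail_identity_fraction * n_pass)
        n_flen <- round(fail_length_fraction * n_pass)
        L <- lens[[cid]]
        chimeric <- cid %in% chim
        max_start <- if (chimeric) max(0L, floor(L / 2) - rl) else L - rl

        # pass-read start positions: deterministic full tile when the
        # planted count allows it, uniform otherwise
        n_tile <- ceiling(L / rl) + 1L
        starts <- if (!chimeric && n_pass >= n_tile) {
          c(floor(seq(0, L - rl, length.out = n_tile)),
            sample.int(max_start + 1L, n_pass - n_tile, replace = TRUE) - 1L)
        } else {
          sample.int(max_start + 1L, n_pass, replace = TRUE) - 1L
        }
        nm_pass <- pmin(rbinom(n_pass, rl, 0.02), max_pass_edits)
        sq_pass <- substring(seqs[[cid]], starts + 1, starts + rl)
        mut <- which(nm_pass > 0)
        sq_pass[mut] <- mapply(mutate_dna, sq_pass[mut], nm_pass[mut])
        rows <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                        paste0(s, "_", cid, "_p", seq_len(n_pass)),
                        cid, starts + 1L, rl, sq_pass, nm_pass)
        if (n_fid > 0) {
          st <- sample.int(max_start + 1L, n_fid, replace = TRUE) - 1L
          nm <- as.integer(ceiling(0.15 * rl))
          sq <- vapply(substring(seqs[[cid]], st + 1, st + rl), mutate_dna,
                       character(1), n_mut = nm, USE.NAMES = FALSE)
          rows <- c(rows, sprintf(
            "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
            paste0(s, "_", cid, "_i", seq_len(n_fid)),
            cid, st + 1L, rl, sq, nm))
        }
        if (n_flen > 0) {
          st <- sample.int(max_start + 1L, n_flen, replace = TRUE) - 1L
          alen <- floor(0.75 * rl)
          sq <- paste0(substring(seqs[[cid]], st + 1, st + alen),
                       vapply(seq_len(n_flen), function(i)
                         random_dna(rl - alen), character(1)))
          rows <- c(rows, sprintf(
            "%s\t0\t%s\t%d\t60\t%dM%dS\t*\t0\t0\t%s\t*\tNM:i:0",
            paste0(s, "_", cid, "_l", seq_len(n_flen)),
            cid, st + 1L, alen, rl - alen, sq))
        }
        per_contig[[ci]] <- rows
      }
      recs <- unlist(per_contig)
      writeLines(c(header, recs), paths[[s]])
      totals[[s]] <- length(recs)
    }
    list(sam_paths = paths, sample_totals = totals,
         planted_counts = counts,
         catalog = catalog)
  })
}

#' Emit reads with a known cluster structure
#'
#' Generates `k_templates` random templates (mutually far below any
#' clustering threshold of interest) and `copies` reads per template, each
#' mutated at at most `divergence` of its positions, so the true
#' 95%-identity cluster count is exactly `k_templates`.
#'
#' @param k_templates Number of planted templates.
#' @param copies Reads per template.
#' @param divergence Maximum within-template substitution fraction
#'   (default 0.02; must stay below 0.05).
#' @param length Read length (default 150).
#' @param seed Seed.
#' @return List: `reads` (named character vector), `templates`,
#'   `true_k` (= `k_templates`), `read_template` (named template index).
#' @export
synth_reads <- function(k_templates, copies, divergence = 0.02,
                        length = 150, seed = 1) {
  if (divergence >= 0.05) abort("within-template divergence must be < 5%")
  with_seed_(seed, {
    templates <- vapply(seq_len(k_templates), function(i) random_dna(length),
                        character(1))
    reads <- character(0)
    origin <- integer(0)
    for (t in seq_len(k_templates)) {
      for (cpy in seq_len(copies)) {
        nm <- sample.int(max(1, floor(divergence * length)), 1)
        reads <- c(reads, mutate_dna(templates[t], nm))
        origin <- c(origin, t)
      }
    }
    names(reads) <- sprintf("read_t%02d_c%03d", origin,
                            stats::ave(origin, origin, FUN = seq_along))
    names(origin) <- names(reads)
    list(reads = reads, templates = templates, true_k = k_templates,
         read_template = origin)
  })
}

#' Emit covariate tables with planted rank correlations
#'
#' Draws bacterial-taxa relative abundances and a clinical panel (BMI, HDL,
#' triglycerides, glucose, waist, weight) for the community's samples via a
#' Gaussian copula against chosen contig abundances: for each planted pair
#' the covariate's normal score is correlated with the contig RPKM's normal
#' score at `2*sin(pi*rho/6)`, which targets a Spearman correlation of `rho`.
#' Taxa rows are closed to sum 1 per sample.
#'
#' @param truth `phg_truth`.
#' @param targets Tibble `contig_id`, `covariate`, `rho`; default plants
#'   |rho| 0.6-0.8 between four differential/core contigs and four clinical
#'   variables (HDL negative) and between three contigs and three taxa.
#' @param n_taxa Number of bacterial taxa columns (default 41).
#' @param seed Seed.
#' @return List: `taxa` (tibble, closed compositions), `clinical` (tibble),
#'   `targets` (the planted pairs).
#' @export
synth_covariates <- function(truth, targets = NULL, n_taxa = 41, seed = 1) {
  rpkm <- sweep(sweep(truth$counts, 1,
                      setNames(truth$catalog$length,
                               truth$catalog$contig_id)[rownames(truth$counts)] / 1e3,
                      "/"),
                2, truth$sample_totals / 1e6, "/")
  samples <- colnames(rpkm)
  n <- length(samples)
  clin_vars <- c("BMI", "HDL", "triglycerides", "glucose", "waist", "weight")
  taxa_vars <- sprintf("taxon_%02d", seq_len(n_taxa))
  with_seed_(seed, {
    if (is.null(targets)) {
      anchors <- c(truth$diff$contig_id, truth$core_set)
      picks <- sample(anchors, 7)
      targets <- tibble::tibble(
        contig_id = picks,
        covariate = c("BMI", "HDL", "triglycerides", "glucose",
                      taxa_vars[1:3]),
        rho = runif(7, 0.6, 0.8) * c(1, -1, 1, 1, 1, -1, 1)
      )
    }
    normscore <- function(x) stats::qnorm((rank(x) - 0.5) / length(x))
    draw_for <- function(cov) {
      hit <- targets[targets$covariate == cov, ]
      if (nrow(hit)) {
        rho_s <- hit$rho[1]
        r <- 2 * sin(pi * rho_s / 6)
        z0 <- normscore(rpkm[hit$contig_id[1], samples])
        r * z0 + sqrt(1 - r^2) * rnorm(n)
      } else {
        rnorm(n)
      }
    }
    clinical_marginals <- list(
      BMI = function(z) 18 + 4 * exp(0.4 * z),
      HDL = function(z) 50 + 12 * z,
      triglycerides = function(z) 90 * exp(0.5 * z),
      glucose = function(z) 90 + 8 * z,
      waist = function(z) 65 + 10 * exp(0.3 * z),
      weight = function(z) 40 + 12 * exp(0.35 * z)
    )
    clinical <- tibble::as_tibble(
      c(list(sample_id = samples),
        purrr::imap(clinical_marginals, function(f, v) f(draw_for(v))))
    )
    taxa_raw <- vapply(taxa_vars, function(v) exp(0.8 * draw_for(v) +
                                                    rnorm(1, 0, 0.5)),
                       numeric(n))
    taxa_rel <- taxa_raw / rowSums(taxa_raw)
    taxa <- tibble::as_tibble(cbind(
      tibble::tibble(sample_id = samples),
      as.data.frame(taxa_rel)
    ))
    list(taxa = taxa, clinical = clinical, targets = targets)
  })
}

#' A small curated viral taxonomy
#'
#' Fixed tree used by the synthetic hit generator and examples: Caudovirales
#' (tagged prokaryotic viruses) with three phage families down to species,
#' and two eukaryotic-virus families.
#'
#' @return A `phg_taxonomy` tibble.
#' @export
synth_taxonomy <- function() {
  rows <- list(
    c("1", "1", "root", "Viruses", "other"),
    c("10", "1", "order", "Caudovirales", "prokaryotic_virus"),
    c("11", "10", "family", "Siphoviridae", "other"),
    c("12", "10", "family", "Myoviridae", "other"),
    c("13", "10", "family", "Podoviridae", "other"),
    c("111", "11", "genus", "Lambdavirus", "other"),
    c("1111", "111", "species", "Lambdavirus lambda", "other"),
    c("1112", "111", "species", "Lambdavirus ursula", "other"),
    c("112", "11", "genus", "Tequatrovirus_like", "other"),
    c("1121", "112", "species", "Sipho species B", "other"),
    c("121", "12", "genus", "Tequatrovirus", "other"),
    c("1211", "121", "species", "Tequatrovirus T4", "other"),
    c("1212", "121", "species", "Tequatrovirus T2", "other"),
    c("131", "13", "genus", "Teseptimavirus", "other"),
    c("1311", "131", "species", "Teseptimavirus T7", "other"),
    c("20", "1", "family", "Anelloviridae", "eukaryotic_virus"),
    c("201", "20", "genus", "Alphatorquevirus", "other"),
    c("2011", "201", "species", "Torque teno virus 1", "other"),
    c("21", "1", "family", "Adenoviridae", "eukaryotic_virus"),
    c("211", "21", "genus", "Mastadenovirus", "other"),
    c("2111", "211", "species", "Human adenovirus C", "other")
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("node", "parent", "rank", "name", "category")
  read_taxonomy(df)
}

#' Emit homology hit tables with known expected assignments
#'
#' For each contig a role is drawn: nucleotide-classified prokaryotic virus,
#' protein-only prokaryotic virus (its nucleotide hits fall below the score
#' filter), eukaryotic virus, ambiguous (retained hits in both virus
#' categories), or unknown (no hits passing the filters). Hits are generated
#' so the expected LCA and category are known by construction.
#'
#' @param contig_ids Contigs to cover.
#' @param tree Taxonomy from [synth_taxonomy()] (default).
#' @param probs Role probabilities, in the order
#'   `c(nt, protein_only, eukaryotic, ambiguous, unknown)`.
#' @param seed Seed.
#' @return List: `nt_hits`, `prot_hits` (hit tibbles as from [read_hits()]),
#'   `expected` (tibble `contig_id`, `taxon`, `category`, `evidence`).
#' @export
synth_hits <- function(contig_ids, tree = synth_taxonomy(),
                       probs = c(nt = 0.35, protein_only = 0.25,
                                 eukaryotic = 0.15, ambiguous = 0.15,
                                 unknown = 0.10),
                       seed = 1) {
  species <- tree$node[tree$rank == "species"]
  parent_of <- setNames(tree$parent, tree$node)
  prok_species <- species[vapply(species, function(s)
    node_category(s, tree) == "prokaryotic_virus", logical(1))]
  euk_species <- species[vapply(species, function(s)
    node_category(s, tree) == "eukaryotic_virus", logical(1))]
  with_seed_(seed, {
    roles <- sample(names(probs), length(contig_ids), replace = TRUE,
                    prob = probs)
    nt <- list(); pr <- list(); exp <- list()
    mk_hit <- function(q, taxon, bitscore, evalue, source) {
      tibble::tibble(query_id = q, subject_taxon = taxon, pident = 95,
                     length = 500L, evalue = evalue, bitscore = bitscore,
                     source = source)
    }
    for (i in seq_along(contig_ids)) {
      cid <- contig_ids[i]
      role <- roles[i]
      if (role == "nt") {
        # two species of one genus, near-equal scores -> LCA = genus
        sp <- sample(prok_species, 1)
        sib <- setdiff(species[parent_of[species] == parent_of[[sp]]], sp)
        if (length(sib)) {
          nt[[cid]] <- rbind(mk_hit(cid, sp, 100, 1e-20, "nucleotide"),
                             mk_hit(cid, sib[1], 95, 1e-18, "nucleotide"))
          expected_taxon <- parent_of[[sp]]
        } else {
          nt[[cid]] <- mk_hit(cid, sp, 100, 1e-20, "nucleotide")
          expected_taxon <- sp
        }
        exp[[cid]] <- tibble::tibble(contig_id = cid, taxon = expected_taxon,
                                     category = "prokaryotic_virus",
                                     evidence = "nucleotide")
      } else if (role == "protein_only") {
        sp <- sample(prok_species, 1)
        # nucleotide evidence exists but falls below the score filter
        nt[[cid]] <- mk_hit(cid, sp, 30, 1e-3, "nucleotide")
        pr[[cid]] <- mk_hit(cid, sp, 120, 1e-30, "protein")
        exp[[cid]] <- tibble::tibble(contig_id = cid, taxon = sp,
                                     category = "prokaryotic_virus",
                                     evidence = "protein")
      } else if (role == "eukaryotic") {
        sp <- sample(euk_species, 1)
        nt[[cid]] <- mk_hit(cid, sp, 90, 1e-15, "nucleotide")
        exp[[cid]] <- tibble::tibble(contig_id = cid, taxon = sp,
                                     category = "eukaryotic_virus",
                                     evidence = "nucleotide")
      } else if (role == "ambiguous") {
        nt[[cid]] <- rbind(mk_hit(cid, sample(prok_species, 1), 100, 1e-20,
                                  "nucleotide"),
                           mk_hit(cid, sample(euk_species, 1), 98, 1e-19,
                                  "nucleotide"))
        exp[[cid]] <- tibble::tibble(contig_id = cid, taxon = "1",
                                     category = "ambiguous",
                                     evidence = "nucleotide")
      } else {
        # hits exist but fail the e-value / score filters -> unknown
        nt[[cid]] <- mk_hit(cid, sample(species, 1), 39, 0.02, "nucleotide")
        exp[[cid]] <- tibble::tibble(contig_id = cid, taxon = NA_character_,
                                     category = "unknown", evidence = "none")
      }
    }
    empty_hits <- tibble::tibble(query_id = character(),
                                 subject_taxon = character(),
                                 pident = double(), length = integer(),
                                 evalue = double(), bitscore = double(),
                                 source = character())
    list(
      nt_hits = if (length(nt)) dplyr::bind_rows(nt) else empty_hits,
      prot_hits = if (length(pr)) dplyr::bind_rows(pr) else empty_hits,
      expected = dplyr::bind_rows(exp)
    )
  })
}
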