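#' Pipeline configuration with field-standard defaults
#'
#' All thresholds of the analysis in one validated list: recruitment filters
#' (90% identity / 80% aligned fraction), assembly filters (80% single-sample
#' coverage, 4 kb length), 95% clustering identity, LCA filter settings
#' (min score 40, max e-value 0.01, top percent 10, min support 1),
#' differential thresholds (log2FC >= 2, BH alpha 0.05, 30% target
#' prevalence), correlation thresholds (r^2 > 0.3, p <= 0.05), core threshold
#' 80%, unique-contig cutoffs 20-80%, dominance fraction 70%, CLR offset
#' 1e-7, and the rarefaction count.
#'
#' @param ... Overrides of the defaults.
#' @return A named list of settings (class `phg_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_identity = 0.90, min_aligned_fraction = 0.80,
    min_covered_fraction = 0.80, min_contig_length = 4000,
    cluster_identity = 0.95,
    rarefactions = 100, rarefaction_depth = NULL,
    lca = list(min_score = 40.0, max_evalue = 0.01, top_percent = 10.0,
               min_support = 1),
    diff = list(lfc_min = 2.0, alpha = 0.05, prevalence_min = 0.30),
    corr = list(r2_min = 0.3, p_max = 0.05),
    core_threshold = 0.80, unique_cutoffs = seq(0.2, 0.8, by = 0.1),
    dominance_fraction = 0.70, clr_offset = 1e-7,
    reference_group = "NW", n_perm = 999, seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort(paste0("unknown config field: ", bad[1]))
  cfg[names(over)] <- over
  with(cfg, stopifnot(
    min_identity >= 0, min_identity <= 1,
    min_aligned_fraction >= 0, min_aligned_fraction <= 1,
    min_covered_fraction >= 0, min_covered_fraction <= 1,
    min_contig_length >= 0, cluster_identity > 0, cluster_identity <= 1,
    rarefactions >= 1, dominance_fraction > 0, dominance_fraction <= 1,
    core_threshold >= 0, core_threshold <= 1, clr_offset > 0, n_perm >= 1
  ))
  structure(cfg, class = c("phg_config", "list"))
}

#' Run the phageome pipeline end to end
#'
#' Stages, in order: alignment parsing, identity/length filtering, coverage +
#' chimera + length contig filters, abundance matrix, taxonomy (when hit
#' tables are supplied), alpha/beta diversity with group tests, and
#' comparative analyses (prevalence classes, unique sweep, prevalence shift,
#' NB differential abundance per disease group vs the reference, Venn
#' partition, correlation screens). Inputs may be per-sample SAM files plus a
#' catalog, or a precomputed count matrix (then the coverage-based stages are
#' skipped and detection falls back to nonzero counts).
#'
#' @param inputs List with either `sam` (named sample -> path) + `catalog` +
#'   `sample_totals`, or `counts` (+ `catalog`, `sample_totals` optional —
#'   defaults to column sums). Optional: `groups` (named sample -> group),
#'   `nt_hits`, `prot_hits`, `taxonomy`, `taxa`, `clinical` (covariate
#'   tibbles with `sample_id`).
#' @param config From [pipeline_config()].
#' @return A `phg_report` list with the per-stage outputs, the funnel table
#'   and the echoed config. All randomness flows from `config$seed`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  funnel <- list()
  note <- function(stage, items_in, items_out, rule) {
    funnel[[length(funnel) + 1]] <<- tibble::tibble(
      stage = stage, items_in = as.numeric(items_in),
      items_out = as.numeric(items_out), rule = rule)
  }
  report <- list(config = config)

  if (!is.null(inputs[["sam"]])) {
    catalog <- inputs[["catalog"]]
    missing <- names(inputs[["sam"]])[!file.exists(unlist(inputs[["sam"]]))]
    if (length(missing))
      abort(paste0("stage parse: missing SAM for sample ", missing[1]))
    aln <- purrr::imap_dfr(inputs[["sam"]], function(p, s)
      parse_alignments(p, catalog, sample_id = s))
    flt <- filter_alignments(aln, config$min_identity,
                             config$min_aligned_fraction)
    note("read_filter", nrow(aln), nrow(flt),
         sprintf("identity >= %.2f & aligned fraction >= %.2f",
                 config$min_identity, config$min_aligned_fraction))
    cov <- coverage_profiles(flt, catalog)
    keep_cov <- chimera_filter(cov, catalog, config$min_covered_fraction)
    note("chimera_filter", nrow(catalog), length(keep_cov),
         sprintf("covered fraction >= %.2f in >= 1 sample",
                 config$min_covered_fraction))
    keep_len <- intersect(keep_cov, length_filter(catalog, config$min_contig_length))
    note("length_filter", length(keep_cov), length(keep_len),
         sprintf("length >= %d nt", config$min_contig_length))
    totals <- unlist(inputs[["sample_totals"]])
    abundance <- build_abundance(flt, keep_len, catalog, totals)
    report$coverage <- cov
    presence <- presence_matrix(cov, "coverage", config$min_covered_fraction,
                                contigs = keep_len,
                                samples = colnames(abundance$counts))
  } else if (!is.null(inputs[["counts"]])) {
    counts <- inputs[["counts"]]
    catalog <- inputs[["catalog"]]
    if (is.null(catalog))
      catalog <- tibble::tibble(contig_id = rownames(counts),
                                length = rep(10000L, nrow(counts)))
    keep_len <- length_filter(catalog, config$min_contig_length)
    keep_len <- intersect(rownames(counts), keep_len)
    note("length_filter", nrow(counts), length(keep_len),
         sprintf("length >= %d nt", config$min_contig_length))
    totals <- inputs[["sample_totals"]]
    if (is.null(totals)) totals <- colSums(counts)
    lengths <- setNames(catalog$length, catalog$contig_id)
    abundance <- new_abundance(counts[keep_len, , drop = FALSE],
                               lengths, totals)
    presence <- presence_matrix(abundance, "nonzero_count")
  } else {
    abort("inputs must provide either `sam` or `counts`")
  }
  report$abundance <- abundance
  report$retained_contigs <- rownames(abundance$counts)

  groups <- inputs[["groups"]]

  if (!is.null(inputs[["nt_hits"]]) || !is.null(inputs[["prot_hits"]])) {
    tree <- inputs[["taxonomy"]]
    if (is.null(tree)) abort("stage taxonomy: hit tables given without a taxonomy")
    empty <- tibble::tibble(query_id = character(), subject_taxon = character(),
                            pident = double(), length = integer(),
                            evalue = double(), bitscore = double(),
                            source = character())
    assignments <- classify_contigs(
      inputs[["nt_hits"]] %||% empty, inputs[["prot_hits"]] %||% empty, tree,
      contig_ids = report$retained_contigs,
      min_score = config$lca$min_score, max_evalue = config$lca$max_evalue,
      top_percent = config$lca$top_percent)
    report$assignments <- assignments
    phage_ids <- assignments$contig_id[assignments$category == "prokaryotic_virus"]
    note("taxonomy", length(report$retained_contigs), length(phage_ids),
         "category == prokaryotic_virus (LCA over nt-then-protein hits)")
    if (length(phage_ids) >= 2) {
      report$phageome <- subset_abundance(abundance, phage_ids)
      presence <- presence[phage_ids, , drop = FALSE]
    } else {
      warn("fewer than 2 prokaryotic-virus contigs; keeping all contigs")
      report$phageome <- abundance
    }
    if (!is.null(groups))
      report$family_profile <- family_profile(assignments, report$phageome,
                                              groups, tree)
  } else {
    report$phageome <- abundance
  }

  ph <- report$phageome
  report$alpha <- alpha_diversity(ph, n_rarefactions = config$rarefactions,
                                  depth = config$rarefaction_depth,
                                  seed = config$seed)
  bc <- bray_curtis(ph)
  report$bray_curtis <- bc
  report$pcoa <- pcoa_ordination(bc)
  report$aitchison <- aitchison_distance(ph, offset = config$clr_offset)

  if (!is.null(groups)) {
    g <- groups[colnames(ph$counts)]
    report$group_tests <- dplyr::bind_rows(
      dplyr::mutate(permutation_group_test(bc, g, n_perm = config$n_perm,
                                           seed = config$seed),
                    distance = "bray_curtis"),
      dplyr::mutate(permutation_group_test(report$aitchison, g,
                                           n_perm = config$n_perm,
                                           seed = config$seed + 1L),
                    distance = "aitchison"))
    report$dominance <- dominant_set(ph, config$dominance_fraction, groups = g)
    report$prevalence_classes <- classify_prevalence(presence)
    report$unique_sweep <- unique_sweep(presence, groups,
                                        cutoffs = config$unique_cutoffs)
    report$prevalence_shift <- prevalence_shift(presence, groups,
                                                config$reference_group,
                                                config$core_threshold)
    targets <- setdiff(unique(g), config$reference_group)
    sizes <- table(g)
    too_small <- targets[sizes[targets] < 3]
    if (sizes[[config$reference_group]] < 3) {
      warn("reference group has < 3 samples; differential stage skipped")
      targets <- character(0)
    } else if (length(too_small)) {
      warn(paste0("differential stage skipped for group(s) with < 3 samples: ",
                  paste(too_small, collapse = ", ")))
      targets <- setdiff(targets, too_small)
    }
    diffs <- purrr::map(setNames(targets, targets), function(tg)
      nb_differential(ph$counts, groups, target = tg,
                      reference = config$reference_group,
                      lfc_min = config$diff$lfc_min,
                      alpha = config$diff$alpha,
                      prevalence_min = config$diff$prevalence_min))
    report$differential <- diffs
    if (length(diffs) == 2) {
      sets <- purrr::map(diffs, function(d) d$contig_id[d$flagged])
      report$venn <- venn_partition(sets[[1]], sets[[2]], names = names(sets))
    }
    flagged <- unique(unlist(purrr::map(diffs, function(d)
      d$contig_id[d$flagged])))
    for (cv in c("taxa", "clinical")) {
      if (!is.null(inputs[[cv]]) && length(flagged)) {
        report[[paste0("corr_", cv)]] <- correlation_screen(
          ph$rpkm[flagged, , drop = FALSE], inputs[[cv]],
          r2_min = config$corr$r2_min, p_max = config$corr$p_max)
      }
    }
  }
  report$funnel <- dplyr::bind_rows(funnel)
  class(report) <- "phg_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stage-by-stage retention table
#'
#' @param report A `phg_report` from [run_pipeline()].
#' @return Tibble `stage`, `items_in`, `items_out`, `rule`.
#' @export
funnel_summary <- function(report) {
  report$funnel
}

#' @export
print.phg_report <- function(x, ...) {
  cat("<phg_report>\n")
  print(x$funnel)
  cat("phageome: ", nrow(x$phageome$counts), " contigs x ",
      ncol(x$phageome$counts), " samples\n", sep = "")
  invisible(x)
}

#' Serialize the numeric content of a report to JSON
#'
#' @param report `phg_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    config = unclass(report$config),
    funnel = report$funnel,
    alpha = report$alpha,
    group_tests = report$group_tests,
    dominance = report$dominance,
    n_core = if (!is.null(report$prevalence_classes))
      sum(report$prevalence_classes$class == "core"),
    venn = report$venn[, c("region", "n")]
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
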