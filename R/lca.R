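#' MEGAN-style hit filtering
#'
#' Drops hits below the minimum bitscore or above the maximum e-value, then,
#' within each query, keeps only hits whose bitscore is within `top_percent`
#' of the best remaining hit (bitscore >= (1 - top_percent/100) x best).
#' Idempotent: filtering a filtered table changes nothing.
#'
#' @param hits Hit tibble from [read_hits()].
#' @param min_score Minimum bitscore (default 40.0).
#' @param max_evalue Maximum e-value (default 0.01).
#' @param top_percent Top-percent band (default 10.0), in `[0, 100]`.
#' @return The retained hits.
#' @export
filter_hits <- function(hits, min_score = 40.0, max_evalue = 0.01,
                        top_percent = 10.0) {
  if (top_percent < 0 || top_percent > 100)
    abort("top_percent must be in [0, 100]")
  hits |>
    dplyr::filter(.data$bitscore >= min_score, .data$evalue <= max_evalue) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$bitscore >=
                    (1 - top_percent / 100) * max(.data$bitscore, -Inf)) |>
    dplyr::ungroup()
}

# path from a node up to the root, node first
root_path <- function(node, parent_of) {
  path <- character(0)
  while (TRUE) {
    path <- c(path, node)
    p <- parent_of[[node]]
    if (p == node) break
    node <- p
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every taxon in the set.
#' With a single taxon the answer is that taxon itself (minimum support 1:
#' one retained hit suffices for an assignment).
#'
#' @param taxa Character vector of taxonomy node ids (retained hits of one
#'   query). Empty input yields `NA`.
#' @param tree `phg_taxonomy` from [read_taxonomy()].
#' @return A node id, or `NA_character_` if `taxa` is empty.
#' @export
assign_lca <- function(taxa, tree) {
  taxa <- unique(taxa)
  if (!length(taxa)) return(NA_character_)
  unknown <- setdiff(taxa, tree$node)
  if (length(unknown)) abort(paste0("unknown taxon: ", unknown[1]))
  parent_of <- setNames(tree$parent, tree$node)
  depth_of <- setNames(tree$depth, tree$node)
  lca <- taxa[1]
  for (t in taxa[-1]) {
    a <- lca; b <- t
    while (depth_of[[a]] > depth_of[[b]]) a <- parent_of[[a]]
    while (depth_of[[b]] > depth_of[[a]]) b <- parent_of[[b]]
    while (a != b) { a <- parent_of[[a]]; b <- parent_of[[b]] }
    lca <- a
  }
  lca
}

# category of the subtree a node sits under: a node is prokaryotic_virus if
# itself or any ancestor carries that label (labels are placed at the
# highest node of each curated clade)
node_category <- function(node, tree) {
  parent_of <- setNames(tree$parent, tree$node)
  cat_of <- setNames(tree$category, tree$node)
  for (n in root_path(node, parent_of)) {
    if (cat_of[[n]] != "other") return(cat_of[[n]])
  }
  "other"
}

#' Classify contigs by nucleotide-then-protein LCA
#'
#' Runs [filter_hits()] + [assign_lca()] on the nucleotide hits of each
#' contig; contigs without a nucleotide assignment are retried with their
#' protein hits. The category is `prokaryotic_virus` or `eukaryotic_virus`
#' when the assigned taxon lies under the corresponding curated clade,
#' `ambiguous` when the retained hits span both virus categories (the LCA
#' then sits above both), and `unknown` when no hits survive filtering.
#'
#' @param nt_hits,prot_hits Hit tibbles (either may be empty); `contig_ids`
#'   defaults to the union of query ids seen in the two tables.
#' @param tree `phg_taxonomy`.
#' @param contig_ids Contigs to classify (so hit-less contigs appear as
#'   `unknown`).
#' @param min_score,max_evalue,top_percent Passed to [filter_hits()].
#' @return Tibble: `contig_id`, `taxon` (node id or `NA`), `rank`,
#'   `category`, `evidence` (`nucleotide`/`protein`/`none`).
#' @export
classify_contigs <- function(nt_hits, prot_hits, tree, contig_ids = NULL,
                             min_score = 40.0, max_evalue = 0.01,
                             top_percent = 10.0) {
  if (is.null(contig_ids))
    contig_ids <- union(unique(nt_hits$query_id), unique(prot_hits$query_id))
  fnt <- filter_hits(nt_hits, min_score, max_evalue, top_percent)
  fpr <- filter_hits(prot_hits, min_score, max_evalue, top_percent)
  rank_of <- setNames(tree$rank, tree$node)
  cat_of_memo <- new.env(parent = emptyenv())
  node_cat <- function(n) {
    if (is.null(cat_of_memo[[n]])) cat_of_memo[[n]] <- node_category(n, tree)
    cat_of_memo[[n]]
  }
  one <- function(cid) {
    for (src in c("nucleotide", "protein")) {
      h <- if (src == "nucleotide") fnt else fpr
      taxa <- h$subject_taxon[h$query_id == cid]
      if (!length(taxa)) next
      lca <- assign_lca(taxa, tree)
      hit_cats <- unique(vapply(unique(taxa), node_cat, character(1)))
      virus_cats <- intersect(hit_cats, c("prokaryotic_virus", "eukaryotic_virus"))
      lca_cat <- node_cat(lca)
      category <- if (lca_cat %in% c("prokaryotic_virus", "eukaryotic_virus")) {
        lca_cat
      } else if (length(virus_cats) == 2L) {
        "ambiguous"
      } else if (length(virus_cats) == 1L) {
        # hits confined to one category but LCA above the curated clade:
        # still a within-category call at a high rank
        virus_cats
      } else {
        "ambiguous"
      }
      return(tibble::tibble(contig_id = cid, taxon = lca,
                            rank = unname(rank_of[lca]),
                            category = category, evidence = src))
    }
    tibble::tibble(contig_id = cid, taxon = NA_character_,
                   rank = NA_character_, category = "unknown",
                   evidence = "none")
  }
  purrr::map_dfr(contig_ids, one)
}

# step-down Sidak adjustment (Holm's sequential variant of the Sidak
# correction); p.adjust() offers holm but not holm-sidak
holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' Family-level relative abundance profile with group tests
#'
#' Rolls contig RPKM up to viral families (the family-rank ancestor of each
#' assigned taxon; assignments above family rank are pooled as
#' `"unclassified"`), converts to per-sample relative abundance over all
#' assigned contigs, and tests each family across groups with Kruskal-Wallis
#' under a step-down Sidak correction.
#'
#' @param assignments Tibble from [classify_contigs()].
#' @param abundance `phg_abundance` covering the assigned contigs.
#' @param groups Named character vector: sample id -> group label.
#' @param tree `phg_taxonomy`.
#' @param alpha Significance level for the corrected tests (default 0.01).
#' @return List with `profile` (tibble `family`, `sample_id`, `group`,
#'   `rel_abundance`) and `tests` (tibble `family`, `kw_statistic`, `p_value`,
#'   `p_holm_sidak`, `significant`).
#' @export
family_profile <- function(assignments, abundance, groups, tree, alpha = 0.01) {
  assigned <- assignments[!is.na(assignments$taxon), ]
  assigned <- assigned[assigned$contig_id %in% rownames(abundance$rpkm), ]
  if (!nrow(assigned)) abort("no assigned contigs overlap the matrix")
  parent_of <- setNames(tree$parent, tree$node)
  rank_of <- setNames(tree$rank, tree$node)
  name_of <- setNames(tree$name, tree$node)
  family_of <- vapply(assigned$taxon, function(n) {
    for (p in root_path(n, parent_of)) {
      if (rank_of[[p]] == "family") return(name_of[[p]])
    }
    "unclassified"
  }, character(1))

  rp <- abundance$rpkm[assigned$contig_id, , drop = FALSE]
  totals <- colSums(rp)
  if (any(totals == 0))
    abort(paste0("sample with all-zero RPKM over assigned contigs: ",
                 colnames(rp)[which(totals == 0)[1]]))
  fam_mat <- rowsum(rp, group = family_of)
  rel <- sweep(fam_mat, 2, totals, "/")

  profile <- tibble::tibble(
    family = rep(rownames(rel), times = ncol(rel)),
    sample_id = rep(colnames(rel), each = nrow(rel)),
    rel_abundance = as.vector(rel)
  )
  profile$group <- unname(groups[profile$sample_id])

  kw_one <- function(x, g) {
    # numerically constant profiles (single family) carry no information
    if (diff(range(x)) < 1e-10) return(c(NA_real_, NA_real_))
    kw <- kruskal.test(x, factor(g))
    c(unname(kw$statistic), kw$p.value)
  }
  tests <- profile |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      kw_statistic = kw_one(.data$rel_abundance, .data$group)[1],
      p_value = kw_one(.data$rel_abundance, .data$group)[2],
      .groups = "drop"
    )
  ok <- !is.na(tests$p_value)
  tests$p_holm_sidak <- NA_real_
  tests$p_holm_sidak[ok] <- holm_sidak(tests$p_value[ok])
  tests$significant <- !is.na(tests$p_holm_sidak) & tests$p_holm_sidak <= alpha
  list(profile = profile, tests = tests)
}
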