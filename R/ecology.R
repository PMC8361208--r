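#' Rarefy a count vector (multivariate hypergeometric subsample)
#'
#' Draws `depth` reads without replacement from the pooled reads of `x`;
#' the result always sums to `depth`.
#'
#' @param x Non-negative integer counts.
#' @param depth Subsample size; must not exceed `sum(x)`.
#' @param seed Optional seed.
#' @return Integer vector of the same length (and names) as `x`.
#' @export
rarefy_counts <- function(x, depth, seed = NULL) {
  if (any(x < 0)) abort("counts must be non-negative")
  total <- sum(x)
  if (depth > total) abort("depth exceeds the total count")
  if (depth == total) return(x)
  with_seed_(seed, {
    draw <- sample.int(total, depth)
    # read index r belongs to category i iff cum[i-1] < r <= cum[i]
    idx <- findInterval(draw, cumsum(x), left.open = TRUE) + 1L
    out <- tabulate(idx, nbins = length(x))
    names(out) <- names(x)
    out
  })
}

#' Shannon diversity (base-2)
#'
#' `H = -sum(p_i * log2(p_i))` over the nonzero proportions of the vector.
#'
#' @param x Non-negative abundances with a positive sum.
#' @param base Logarithm base (default 2, giving bits).
#' @return Shannon entropy.
#' @export
shannon_index <- function(x, base = 2) {
  if (any(x < 0)) abort("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) abort("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Rarefaction-based alpha diversity
#'
#' For each sample, draws `n_rarefactions` rarefied count vectors at a common
#' depth (default: the smallest sample sum) and reports the median observed
#' contig count and median Shannon diversity across draws.
#'
#' @param x `phg_abundance` or an integer contig-by-sample count matrix.
#' @param n_rarefactions Number of rarefaction draws per sample.
#' @param depth Even depth; `NULL` uses the minimum sample sum.
#' @param seed Seed for reproducibility.
#' @return Tibble: `sample_id`, `metric` (`observed_contigs` / `shannon`),
#'   `median_value`, `rarefaction_depth`, `n_rarefactions`.
#' @export
alpha_diversity <- function(x, n_rarefactions = 100, depth = NULL, seed = NULL) {
  counts <- if (inherits(x, "phg_abundance")) x$counts else x
  sums <- colSums(counts)
  if (is.null(depth)) depth <- min(sums)
  if (depth > min(sums))
    abort(paste0("depth exceeds the smallest sample (",
                 colnames(counts)[which.min(sums)], ": ", min(sums), ")"))
  with_seed_(seed, {
    purrr::map_dfr(colnames(counts), function(sid) {
      v <- counts[, sid]
      obs <- numeric(n_rarefactions)
      sh <- numeric(n_rarefactions)
      for (b in seq_len(n_rarefactions)) {
        r <- rarefy_counts(v, depth)
        obs[b] <- sum(r > 0)
        sh[b] <- shannon_index(r)
      }
      tibble::tibble(
        sample_id = sid,
        metric = c("observed_contigs", "shannon"),
        median_value = c(median(obs), median(sh)),
        rarefaction_depth = as.integer(depth),
        n_rarefactions = as.integer(n_rarefactions)
      )
    })
  })
}

#' Dominant contig set
#'
#' The smallest set of contigs whose summed normalized abundance reaches a
#' given fraction of a group's total, and its share of the phageome.
#'
#' @param totals Per-contig summed RPKM within a group (non-negative, positive
#'   sum), or a `phg_abundance` plus `groups` to compute one row per group.
#' @param fraction Target share (default 0.70).
#' @param groups Optional named sample->group vector when `totals` is a
#'   `phg_abundance`.
#' @return Tibble: `group` (or `"all"`), `n_dominant`, `percent_of_phageome`,
#'   `n_contigs`.
#' @export
dominant_set <- function(totals, fraction = 0.70, groups = NULL) {
  if (inherits(totals, "phg_abundance")) {
    ab <- totals
    if (is.null(groups)) groups <- setNames(rep("all", ncol(ab$rpkm)), colnames(ab$rpkm))
    return(purrr::map_dfr(unique(groups), function(g) {
      tot <- rowSums(ab$rpkm[, names(groups)[groups == g], drop = FALSE])
      dplyr::mutate(dominant_set(tot, fraction), group = g, .before = 1)
    }))
  }
  if (sum(totals) <= 0) abort("group total abundance must be positive")
  share <- cumsum(sort(totals, decreasing = TRUE)) / sum(totals)
  n <- which(share >= fraction)[1]
  tibble::tibble(n_dominant = as.integer(n),
                 percent_of_phageome = 100 * n / length(totals),
                 n_contigs = length(totals))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(u, v) = 1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v))` over the
#' contig abundances of two samples (delegated to vegan).
#'
#' @param x `phg_abundance` (RPKM is used) or a contig-by-sample matrix.
#' @return A `dist` over samples.
#' @export
bray_curtis <- function(x) {
  mat <- if (inherits(x, "phg_abundance")) x$rpkm else x
  if (ncol(mat) < 2) abort("need at least 2 samples")
  if (any(colSums(mat) == 0))
    abort(paste0("sample with zero total abundance: ",
                 colnames(mat)[which(colSums(mat) == 0)[1]]))
  vegan::vegdist(t(mat), method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical PCoA (double-centered Gower matrix eigendecomposition, via ape).
#' Coordinates are reported for non-negative-eigenvalue axes only; all
#' eigenvalues, including negative ones, are returned.
#'
#' @param d A `dist` (e.g. from [bray_curtis()] or [aitchison_distance()]).
#' @return List with `coordinates` (tibble: `sample_id`, `axis`, `value`),
#'   `eigenvalues` (numeric), `relative_eig` (shares over positive
#'   eigenvalues).
#' @export
pcoa_ordination <- function(d) {
  res <- ape::pcoa(d)
  vec <- res$vectors
  coords <- tibble::tibble(
    sample_id = rep(rownames(vec), times = ncol(vec)),
    axis = rep(seq_len(ncol(vec)), each = nrow(vec)),
    value = as.vector(vec)
  )
  eig <- res$values$Eigenvalues
  list(coordinates = coords, eigenvalues = eig,
       relative_eig = pmax(eig, 0) / sum(pmax(eig, 0)))
}

#' Centered log-ratio transform
#'
#' Adds a small offset to every entry (so zeros are defined), then per sample
#' subtracts the mean log: `clr_i = ln(x_i + offset) - mean_j ln(x_j +
#' offset)`. Each transformed sample sums to zero.
#'
#' @param x `phg_abundance` (RPKM) or contig-by-sample matrix.
#' @param offset Pseudo-value added before logs (default 1e-7).
#' @return Matrix of CLR coordinates, same shape as the input.
#' @export
clr_transform <- function(x, offset = 1e-7) {
  mat <- if (inherits(x, "phg_abundance")) x$rpkm else x
  lg <- log(mat + offset)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Aitchison distance
#'
#' Euclidean distance between CLR-transformed samples.
#'
#' @inheritParams clr_transform
#' @return A `dist` over samples.
#' @export
aitchison_distance <- function(x, offset = 1e-7) {
  stats::dist(t(clr_transform(x, offset)))
}

#' Permutation tests of group structure on a distance matrix
#'
#' ANOSIM (rank-based R statistic) and PERMANOVA (adonis pseudo-F), both via
#' vegan, with permutation p-values `(1 + #{permuted >= observed}) /
#' (1 + n_perm)`.
#'
#' @param d `dist` over samples.
#' @param groups Named (or ordered like `labels(d)`) group labels.
#' @param method `"anosim"`, `"permanova"`, or both.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for reproducibility.
#' @return Tibble: `method`, `statistic`, `p_value`, `n_perm`.
#' @export
permutation_group_test <- function(d, groups,
                                   method = c("anosim", "permanova"),
                                   n_perm = 999, seed = NULL) {
  method <- match.arg(method, several.ok = TRUE)
  if (n_perm < 1) abort("n_perm must be >= 1")
  ids <- labels(d)
  g <- if (!is.null(names(groups)) && !is.null(ids)) groups[ids] else groups
  g <- factor(g)
  if (nlevels(g) < 2 || any(table(g) < 2))
    abort("need >= 2 groups with >= 2 samples each")
  with_seed_(seed, {
    purrr::map_dfr(method, function(m) {
      if (m == "anosim") {
        fit <- vegan::anosim(d, g, permutations = n_perm)
        tibble::tibble(method = "anosim", statistic = unname(fit$statistic),
                       p_value = fit$signif, n_perm = as.integer(n_perm))
      } else {
        fit <- vegan::adonis2(d ~ g, permutations = n_perm)
        tibble::tibble(method = "permanova", statistic = fit$F[1],
                       p_value = fit$`Pr(>F)`[1], n_perm = as.integer(n_perm))
      }
    })
  })
}

#' Group comparison: normality check + pairwise Mann-Whitney
#'
#' Shapiro-Wilk normality per group (reported, n >= 3 and non-constant
#' required), then two-sided Mann-Whitney tests for every pair of groups:
#' exact when both groups have n <= 8 and the pooled values are tie-free,
#' otherwise the tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param data Tibble with a value column and a group column.
#' @param value,group Column names (strings).
#' @param pairwise Run all pairwise tests (default `TRUE`).
#' @return List with `normality` (tibble `group`, `n`, `shapiro_w`,
#'   `shapiro_p`) and `tests` (tibble `group_a`, `group_b`, `statistic`,
#'   `p_value`, `exact`).
#' @export
group_compare <- function(data, value = "value", group = "group",
                          pairwise = TRUE) {
  v <- data[[value]]
  g <- factor(data[[group]])
  normality <- purrr::map_dfr(levels(g), function(lev) {
    x <- v[g == lev]
    if (length(x) >= 3 && length(x) <= 5000 && var(x) > 0) {
      sw <- shapiro.test(x)
      tibble::tibble(group = lev, n = length(x),
                     shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value)
    } else {
      if (length(x) < 3 || var(x) == 0)
        warn(paste0("normality check skipped for group ", lev,
                    " (too few values or zero variance)"))
      tibble::tibble(group = lev, n = length(x),
                     shapiro_w = NA_real_, shapiro_p = NA_real_)
    }
  })
  tests <- NULL
  if (pairwise && nlevels(g) >= 2) {
    pairs <- utils::combn(levels(g), 2, simplify = FALSE)
    tests <- purrr::map_dfr(pairs, function(p) {
      x <- v[g == p[1]]; y <- v[g == p[2]]
      if (length(unique(c(x, y))) == 1L) {
        # fully tied data: no evidence of a shift
        return(tibble::tibble(group_a = p[1], group_b = p[2],
                              statistic = length(x) * length(y) / 2,
                              p_value = 1, exact = FALSE))
      }
      ties <- anyDuplicated(c(x, y)) > 0
      exact <- length(x) <= 8 && length(y) <= 8 && !ties
      wt <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = FALSE)
      )
      tibble::tibble(group_a = p[1], group_b = p[2],
                     statistic = unname(wt$statistic),
                     p_value = wt$p.value, exact = exact)
    })
  }
  list(normality = normality, tests = tests)
}
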