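#' Presence/absence matrix under an explicit detection criterion
#'
#' Detection is either coverage-based (`covered_fraction >= threshold`, the
#' stringent criterion of at least 80% of the contig covered at >= 1x) or a
#' simple nonzero-count rule.
#'
#' @param x For `criterion = "coverage"`: a coverage tibble from
#'   [coverage_profiles()]; for `"nonzero_count"`: a `phg_abundance` or a
#'   count matrix.
#' @param criterion `"coverage"` or `"nonzero_count"`.
#' @param threshold Coverage threshold (default 0.80, inclusive).
#' @param contigs,samples Row/column universe (needed with the coverage
#'   criterion when some contig-sample pairs have no reads at all); default:
#'   the ids observed in `x`.
#' @return Logical contig-by-sample matrix.
#' @export
presence_matrix <- function(x, criterion = c("coverage", "nonzero_count"),
                            threshold = 0.80, contigs = NULL, samples = NULL) {
  criterion <- match.arg(criterion)
  if (criterion == "nonzero_count") {
    counts <- if (inherits(x, "phg_abundance")) x$counts else x
    pres <- counts > 0
    if (!is.null(contigs)) pres <- pres[contigs, , drop = FALSE]
    if (!is.null(samples)) pres <- pres[, samples, drop = FALSE]
    return(pres)
  }
  stopifnot(is.data.frame(x))
  if (is.null(contigs)) contigs <- unique(x$contig_id)
  if (is.null(samples)) samples <- unique(x$sample_id)
  pres <- matrix(FALSE, length(contigs), length(samples),
                 dimnames = list(contigs, samples))
  hit <- x[x$covered_fraction >= threshold &
             x$contig_id %in% contigs & x$sample_id %in% samples, ]
  pres[cbind(hit$contig_id, hit$sample_id)] <- TRUE
  pres
}

#' Core / common / individual prevalence classes
#'
#' Prevalence is the fraction of all samples in which a contig is detected.
#' Classes: core (> 80%), common (> 50% and <= 80%), individual (<= 50%).
#' The boundary assignment at exactly 50%/80% makes the classes a partition;
#' it is immaterial for cohort sizes where those fractions are non-integer.
#'
#' @param presence Logical contig-by-sample matrix.
#' @return Tibble: `contig_id`, `n_present`, `prevalence`, `class`.
#' @export
classify_prevalence <- function(presence) {
  if (ncol(presence) < 1) abort("need at least one sample")
  n <- rowSums(presence)
  prev <- n / ncol(presence)
  tibble::tibble(
    contig_id = rownames(presence),
    n_present = as.integer(n),
    prevalence = prev,
    class = dplyr::case_when(
      prev > 0.8 ~ "core",
      prev > 0.5 ~ "common",
      TRUE ~ "individual"
    )
  )
}

#' Group-unique contig sweep over prevalence cutoffs
#'
#' A contig is unique to group `g` at cutoff `c` if it is present in at least
#' a fraction `c` of `g`'s samples and in zero samples of every other group.
#' Counts are non-increasing in the cutoff; the recommended cutoff is the
#' most stringent one that still attains the maximum total number of unique
#' contigs across groups.
#'
#' @param presence Logical contig-by-sample matrix.
#' @param groups Named sample -> group vector covering all columns.
#' @param cutoffs Fractions to sweep (default 0.20 to 0.80 by 0.10).
#' @return Tibble `cutoff`, `group`, `n_unique`, list-column `contig_ids`;
#'   attribute `recommended_cutoff`.
#' @export
unique_sweep <- function(presence, groups,
                         cutoffs = seq(0.2, 0.8, by = 0.1)) {
  g <- unname(groups[colnames(presence)])
  if (anyNA(g)) abort("every sample must be labeled with a group")
  levs <- unique(g)
  sizes <- table(factor(g, levels = levs))
  if (any(sizes == 0)) abort("group with zero samples")
  within <- vapply(levs, function(lev)
    rowSums(presence[, g == lev, drop = FALSE]), numeric(nrow(presence)))
  out <- purrr::map_dfr(cutoffs, function(co) {
    purrr::map_dfr(levs, function(lev) {
      others <- setdiff(levs, lev)
      uniq <- within[, lev] >= co * sizes[[lev]] - 1e-9 &
        rowSums(within[, others, drop = FALSE]) == 0
      tibble::tibble(cutoff = co, group = lev,
                     n_unique = sum(uniq),
                     contig_ids = list(rownames(presence)[uniq]))
    })
  })
  totals <- out |>
    dplyr::group_by(.data$cutoff) |>
    dplyr::summarise(total = sum(.data$n_unique), .groups = "drop")
  best <- max(totals$total)
  attr(out, "recommended_cutoff") <- max(totals$cutoff[totals$total == best])
  out
}

#' Prevalence shift of reference-prevalent contigs across groups
#'
#' Selects the contigs present in more than `ref_threshold` of the reference
#' group's samples, computes each contig's within-group prevalence in every
#' group, and compares groups by pairwise Mann-Whitney tests on the
#' per-contig prevalences.
#'
#' @param presence Logical contig-by-sample matrix.
#' @param groups Named sample -> group vector.
#' @param reference Reference group label.
#' @param ref_threshold Selection threshold in the reference group (strict
#'   `>`, default 0.80).
#' @return List: `summary` (tibble `group`, `mean_prevalence` in percent,
#'   `n_contigs`), `per_contig` (tibble `contig_id`, `group`, `prevalence`),
#'   `tests` (pairwise Mann-Whitney tibble, `NULL` if < 2 contigs selected).
#' @export
prevalence_shift <- function(presence, groups, reference,
                             ref_threshold = 0.80) {
  g <- unname(groups[colnames(presence)])
  if (!reference %in% g) abort("reference group has no samples")
  if (sum(g == reference) < 2) abort("reference group needs >= 2 samples")
  ref_prev <- rowMeans(presence[, g == reference, drop = FALSE])
  sel <- rownames(presence)[ref_prev > ref_threshold]
  if (!length(sel)) {
    warn("no contig exceeds the reference prevalence threshold")
    return(list(summary = tibble::tibble(group = character(),
                                         mean_prevalence = double(),
                                         n_contigs = integer()),
                per_contig = tibble::tibble(contig_id = character(),
                                            group = character(),
                                            prevalence = double()),
                tests = NULL))
  }
  levs <- unique(g)
  per_contig <- purrr::map_dfr(levs, function(lev) {
    tibble::tibble(
      contig_id = sel, group = lev,
      prevalence = 100 * rowMeans(presence[sel, g == lev, drop = FALSE])
    )
  })
  summary <- per_contig |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(mean_prevalence = mean(.data$prevalence),
                     n_contigs = length(sel), .groups = "drop")
  tests <- if (length(sel) >= 2) {
    # fully tied per-contig prevalences are routine here; the normality
    # column is NA in that case rather than a warning
    suppressWarnings(
      group_compare(per_contig, value = "prevalence", group = "group")$tests)
  }
  list(summary = summary, per_contig = per_contig, tests = tests)
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over reference contigs of the ratio of its count to
#' the contig's geometric mean across samples. Reference contigs are those
#' with strictly positive counts in every sample; when none exists (common in
#' sparse virome matrices) and `fallback = TRUE`, geometric means are taken
#' over positive counts only and each sample's median over its nonzero
#' contigs.
#'
#' @param counts Integer contig-by-sample count matrix.
#' @param fallback Use the positive-counts fallback when no contig is
#'   all-positive (default `TRUE`).
#' @return Named positive numeric vector, one per sample.
#' @export
size_factors <- function(counts, fallback = TRUE) {
  lc <- log(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    loggeo <- rowMeans(lc[all_pos, , drop = FALSE])
    sf <- apply(lc[all_pos, , drop = FALSE], 2,
                function(col) exp(median(col - loggeo)))
  } else {
    if (!fallback) abort("no contig has positive counts in every sample")
    pos <- counts > 0
    loggeo <- rowSums(ifelse(pos, lc, 0)) / pmax(rowSums(pos), 1)
    sf <- vapply(seq_len(ncol(counts)), function(s) {
      use <- pos[, s] & rowSums(pos) > 0
      if (!any(use)) abort(paste0("sample has no nonzero counts: ",
                                  colnames(counts)[s]))
      exp(median(lc[use, s] - loggeo[use]))
    }, numeric(1))
  }
  setNames(sf, colnames(counts))
}

# method-of-moments gamma-Poisson dispersion, pooled across the two groups
moments_dispersion <- function(yt, yr, floor = 1e-8) {
  disp_g <- function(y) {
    m <- rowMeans(y)
    v <- apply(y, 1, var)
    ifelse(m > 0, (v - m) / m^2, NA_real_)
  }
  at <- disp_g(yt); ar <- disp_g(yr)
  wt <- ncol(yt) - 1; wr <- ncol(yr) - 1
  pooled <- dplyr::case_when(
    !is.na(at) & !is.na(ar) ~ (wt * at + wr * ar) / (wt + wr),
    !is.na(at) ~ at,
    !is.na(ar) ~ ar,
    TRUE ~ 0
  )
  pmax(pooled, floor)
}

#' Negative-binomial differential abundance
#'
#' Raw counts are normalized by median-of-ratios size factors; a per-contig
#' gamma-Poisson dispersion is estimated by moments (floored at 1e-8); a
#' two-group log-link negative-binomial mean model is fit by iteratively
#' reweighted least squares; the group coefficient is tested with a Wald test
#' on the log2 scale and p-values are Benjamini-Hochberg adjusted across
#' contigs. A contig is flagged over-abundant when its estimated log2 fold
#' change is at least `lfc_min`, its adjusted p-value at most `alpha`, and it
#' is detected (nonzero raw count) in at least `prevalence_min` of the target
#' group's samples — the last rule removes individual-specific contigs.
#'
#' @param counts Integer contig-by-sample raw count matrix (RPKM is
#'   rejected: the model needs counts).
#' @param groups Named sample -> group vector.
#' @param target,reference Group labels to contrast (fold change is
#'   target / reference).
#' @param lfc_min Minimum estimated log2 fold change (default 2).
#' @param alpha BH-adjusted p-value threshold (default 0.05).
#' @param prevalence_min Minimum detection fraction in the target group
#'   (default 0.30).
#' @return A `phg_diff` tibble: `contig_id`, `base_mean`, `log2_fold_change`,
#'   `wald_p`, `bh_adjusted_p`, `prevalence_in_target`, `flagged`; attributes
#'   record the contrast, size factors and dispersions.
#' @export
nb_differential <- function(counts, groups, target, reference,
                            lfc_min = 2.0, alpha = 0.05,
                            prevalence_min = 0.30) {
  if (any(counts != round(counts)))
    abort("differential abundance needs raw integer counts, not RPKM")
  g <- unname(groups[colnames(counts)])
  ti <- which(g == target); ri <- which(g == reference)
  if (length(ti) < 3 || length(ri) < 3)
    abort("target and reference groups each need >= 3 samples")
  sub <- counts[, c(ti, ri), drop = FALSE]
  sf <- size_factors(sub)
  norm <- sweep(sub, 2, sf, "/")
  yt <- norm[, seq_along(ti), drop = FALSE]
  yr <- norm[, length(ti) + seq_along(ri), drop = FALSE]

  disp <- moments_dispersion(yt, yr)
  eps <- 1e-8
  # IRLS on the log link; for the saturated two-group design the update
  # eta <- eta + (ybar/mu - 1) converges to the group means
  irls_mean <- function(y) {
    ybar <- rowMeans(y)
    mu <- pmax(ybar, eps)
    eta <- log(pmax(ybar, 0.5))
    for (i in 1:50) {
      mu <- exp(eta)
      step <- ybar / mu - 1
      eta_new <- eta + step
      if (max(abs(eta_new - eta)) < 1e-12) { eta <- eta_new; break }
      eta <- eta_new
    }
    pmax(exp(eta), eps)
  }
  mu_t <- irls_mean(yt)
  mu_r <- irls_mean(yr)

  lfc <- log2(mu_t / mu_r)
  se <- sqrt((1 / mu_t + disp) / ncol(yt) + (1 / mu_r + disp) / ncol(yr))
  z <- (log(mu_t) - log(mu_r)) / se
  p <- 2 * pnorm(-abs(z))
  informative <- rowSums(sub) > 0
  p[!informative] <- NA_real_
  padj <- p.adjust(p, method = "BH")
  prev_t <- rowMeans(counts[, ti, drop = FALSE] > 0)

  out <- tibble::tibble(
    contig_id = rownames(counts),
    base_mean = rowMeans(norm),
    log2_fold_change = lfc,
    wald_p = p,
    bh_adjusted_p = padj,
    prevalence_in_target = prev_t,
    flagged = !is.na(padj) & lfc >= lfc_min & padj <= alpha &
      prev_t >= prevalence_min
  )
  attr(out, "contrast") <- c(target = target, reference = reference)
  attr(out, "size_factors") <- sf
  attr(out, "dispersion") <- setNames(disp, rownames(counts))
  attr(out, "params") <- list(lfc_min = lfc_min, alpha = alpha,
                              prevalence_min = prevalence_min)
  class(out) <- c("phg_diff", class(out))
  out
}

#' @export
tidy.phg_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "phg_diff")
  attr(out, "contrast") <- NULL
  attr(out, "size_factors") <- NULL
  attr(out, "dispersion") <- NULL
  attr(out, "params") <- NULL
  out
}

#' @export
glance.phg_diff <- function(x, ...) {
  ct <- attr(x, "contrast")
  tibble::tibble(
    target = ct[["target"]], reference = ct[["reference"]],
    n_contigs = nrow(x),
    n_tested = sum(!is.na(x$wald_p)),
    n_flagged = sum(x$flagged)
  )
}

#' Venn partition of two flagged contig sets
#'
#' @param set_a,set_b Character vectors of contig ids.
#' @param names Labels for the two sets.
#' @return Tibble `region`, `n`, list-column `contig_ids` with rows
#'   `only_<a>`, `only_<b>`, `shared`.
#' @export
venn_partition <- function(set_a, set_b, names = c("a", "b")) {
  tibble::tibble(
    region = c(paste0("only_", names[1]), paste0("only_", names[2]), "shared"),
    n = c(length(setdiff(set_a, set_b)), length(setdiff(set_b, set_a)),
          length(intersect(set_a, set_b))),
    contig_ids = list(setdiff(set_a, set_b), setdiff(set_b, set_a),
                      intersect(set_a, set_b))
  )
}

# Spearman rho with average ranks; p exact (via cor.test) for n < 10 without
# ties, t-approximation with df = n - 2 otherwise
spearman_one <- function(x, y) {
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- if (n < 10 && !ties) {
    stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else {
    if (abs(rho) >= 1) {
      0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
  }
  c(rho = rho, p = p)
}

#' Spearman correlation screen of contig abundance against covariates
#'
#' Correlates each contig's RPKM with each covariate (bacterial taxa relative
#' abundances or clinical variables) across samples. A pair is selected when
#' `rho^2 > r2_min` and the unadjusted p-value is at most `p_max`;
#' BH-adjusted p-values are reported alongside.
#'
#' @param rpkm Contig-by-sample RPKM matrix (e.g. `x$rpkm[flagged, ]`), or a
#'   `phg_abundance`.
#' @param covariates Tibble with a `sample_id` column and one numeric column
#'   per covariate.
#' @param r2_min Squared-correlation threshold (strict `>`, default 0.3).
#' @param p_max Unadjusted p-value threshold (default 0.05).
#' @return Tibble: `contig_id`, `covariate`, `n`, `spearman_rho`, `r_squared`,
#'   `p_unadjusted`, `p_bh`, `selected`. Constant pairs are skipped with a
#'   warning.
#' @export
correlation_screen <- function(rpkm, covariates, r2_min = 0.3, p_max = 0.05) {
  mat <- if (inherits(rpkm, "phg_abundance")) rpkm$rpkm else rpkm
  stopifnot("sample_id" %in% names(covariates))
  covs <- setdiff(names(covariates), "sample_id")
  samples <- intersect(colnames(mat), covariates$sample_id)
  if (length(samples) < 4) abort("need >= 4 paired samples")
  cv <- covariates[match(samples, covariates$sample_id), ]
  skipped <- character(0)
  out <- purrr::map_dfr(rownames(mat), function(cid) {
    x <- mat[cid, samples]
    purrr::map_dfr(covs, function(cname) {
      y <- cv[[cname]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 4 || var(x[ok]) == 0 || var(y[ok]) == 0) {
        skipped <<- c(skipped, paste0(cid, "/", cname))
        return(NULL)
      }
      sp <- spearman_one(x[ok], y[ok])
      tibble::tibble(contig_id = cid, covariate = cname, n = sum(ok),
                     spearman_rho = unname(sp["rho"]),
                     r_squared = unname(sp["rho"])^2,
                     p_unadjusted = unname(sp["p"]))
    })
  })
  if (length(skipped))
    warn(paste0(length(skipped), " constant/short pair(s) skipped, e.g. ",
                skipped[1]))
  if (!nrow(out)) return(out)
  out$p_bh <- p.adjust(out$p_unadjusted, method = "BH")
  out$selected <- out$r_squared > r2_min & out$p_unadjusted <= p_max
  out
}
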