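# Independent reference implementations used as oracles.

# Fit-alignment via Biostrings (global in the shorter sequence, local in the
# longer), same scoring as the package kernel: match +1, mismatch -1, gap -2
# per position. Returns list(score, matches).
bs_fit_alignment <- function(a, b) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  one <- function(shorter, longer) {
    pwa <- Biostrings::pairwiseAlignment(pattern = shorter, subject = longer,
                                         substitutionMatrix = sm,
                                         gapOpening = 0, gapExtension = 2,
                                         type = "global-local")
    list(score = unname(Biostrings::score(pwa)),
         matches = unname(Biostrings::nmatch(pwa)),
         identity = unname(Biostrings::nmatch(pwa) / nchar(shorter)))
  }
  if (nchar(a) == nchar(b)) {
    # same equal-length symmetry rule as the package kernel
    r1 <- one(a, b); r2 <- one(b, a)
    if (r2$identity > r1$identity) r2 else r1
  } else if (nchar(a) < nchar(b)) {
    one(a, b)
  } else {
    one(b, a)
  }
}

# Brute-force greedy clustering: no prescreen, identities from the Biostrings
# oracle. Same ordering and tie-break contract as greedy_cluster().
oracle_greedy_cluster <- function(seqs, threshold = 0.95) {
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    found <- 0L
    for (ci in seq_along(reps)) {
      if (bs_fit_alignment(seqs[i], seqs[reps[ci]])$identity >= threshold) {
        found <- ci; break
      }
    }
    if (found == 0L) { reps <- c(reps, i); found <- length(reps) }
    assign[i] <- found
  }
  setNames(assign, names(seqs))
}

random_seqs <- function(n, len_range = c(30, 200)) {
  lens <- len_range[1] +
    sample.int(len_range[2] - len_range[1] + 1L, n, replace = TRUE) - 1L
  setNames(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)), sprintf("s%03d", seq_len(n)))
}

# point-mutate a sequence at exactly k positions
mutate_at <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(b), k)
  b[pos] <- vapply(b[pos], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  paste(b, collapse = "")
}

# LCA by intersecting root paths: deepest node common to every taxon's path
oracle_lca <- function(taxa, tree) {
  parent_of <- setNames(tree$parent, tree$node)
  depth_of <- setNames(tree$depth, tree$node)
  path <- function(n) {
    out <- n
    while (parent_of[[n]] != n) { n <- parent_of[[n]]; out <- c(out, n) }
    out
  }
  common <- Reduce(intersect, lapply(unique(taxa), path))
  common[which.max(depth_of[common])]
}

# random taxonomy: node i's parent drawn among nodes 1..(i-1)
random_tree <- function(n_nodes) {
  node <- as.character(seq_len(n_nodes))
  parent <- c("1", as.character(vapply(2:n_nodes, function(i)
    sample.int(i - 1L, 1L), integer(1))))
  read_taxonomy(data.frame(node = node, parent = parent,
                           rank = "clade", name = paste0("n", node),
                           category = "other"))
}

# multivariate hypergeometric by sequential rhyper draws
oracle_rarefy <- function(x, depth) {
  remaining <- sum(x)
  out <- integer(length(x))
  for (i in seq_along(x)) {
    remaining <- remaining - x[i]
    out[i] <- rhyper(1, x[i], remaining, depth)
    depth <- depth - out[i]
  }
  out
}

# minimal SAM writer for round-trip checks
write_sam_lines <- function(records, catalog) {
  header <- sprintf("@SQ\tSN:%s\tLN:%d", catalog$contig_id, catalog$length)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  records$read_id, records$flag, records$contig_id,
                  records$pos, records$cigar, records$seq, records$nm)
  c(header, body)
}

sample_groups <- function(truth) {
  setNames(truth$metadata$group, truth$metadata$sample_id)
}
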