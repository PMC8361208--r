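#' Read a contig catalog
#'
#' A contig catalog maps contig ids to lengths (and optionally sequences).
#' It can be built from a FASTA file, a two-column TSV (`contig_id`, `length`),
#' or a named vector / `DNAStringSet`.
#'
#' @param x Path to a FASTA (`.fa`, `.fasta`, `.fna`) or TSV file, a named
#'   integer vector of lengths, or a `Biostrings::DNAStringSet`.
#' @return A tibble with columns `contig_id`, `length` and, when sequences are
#'   available, `sequence` (character).
#' @export
read_contig_catalog <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    cat <- tibble::tibble(
      contig_id = names(x),
      length = Biostrings::width(x),
      sequence = unname(as.character(x))
    )
  } else if (is.numeric(x) && !is.null(names(x))) {
    cat <- tibble::tibble(contig_id = names(x), length = as.integer(x))
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (grepl("\\.(fa|fasta|fna)$", x, ignore.case = TRUE)) {
      return(read_contig_catalog(Biostrings::readDNAStringSet(x)))
    }
    cat <- readr::read_tsv(x, show_col_types = FALSE)
    names(cat)[1:2] <- c("contig_id", "length")
    cat <- tibble::as_tibble(cat)
  } else {
    abort("cannot interpret `x` as a contig catalog")
  }
  validate_catalog(cat)
  cat
}

validate_catalog <- function(catalog) {
  stopifnot(all(c("contig_id", "length") %in% names(catalog)))
  if (anyDuplicated(catalog$contig_id))
    abort("duplicate contig ids in catalog")
  if (nrow(catalog) && any(catalog$length < 1))
    abort("contig lengths must be positive")
  invisible(catalog)
}

# CIGAR operation sums needed for identity / aligned-fraction arithmetic.
# aligned query bases = M + '=' + X + I (soft clips excluded)
# alignment span      = aligned query bases + D (aligned columns incl. indels)
# reference span      = M + '=' + X + D + N
cigar_stats <- function(cigar) {
  ops <- GenomicAlignments::cigarOpTable(cigar)
  mx <- ops[, "M", drop = TRUE] + ops[, "=", drop = TRUE] + ops[, "X", drop = TRUE]
  ins <- ops[, "I", drop = TRUE]
  del <- ops[, "D", drop = TRUE]
  tibble::tibble(
    aligned_query_bases = mx + ins,
    alignment_span = mx + ins + del,
    reference_span = mx + del + ops[, "N", drop = TRUE],
    query_length = mx + ins + ops[, "S", drop = TRUE]
  )
}

#' Parse read-to-contig alignments from a SAM file
#'
#' Reads mapped primary alignments from SAM and derives, per record, the
#' NM-based percent identity and the aligned fraction of the read. Unmapped,
#' secondary (0x100) and supplementary (0x800) records are skipped so each
#' read contributes at most once.
#'
#' Identity is `(alignment_span - NM) / alignment_span`, where the span counts
#' aligned columns including indels; the aligned fraction is aligned query
#' bases (matches plus insertions, soft clips excluded) over read length.
#' Coordinates are converted to 0-based half-open.
#'
#' @param sam Path to a SAM file, or a character vector of SAM lines.
#' @param catalog Contig catalog tibble (see [read_contig_catalog()]); every
#'   reference name in the SAM must appear in it.
#' @param sample_id Optional sample label attached to every record.
#' @param missing_nm `"warn"` (drop the record with a warning) or `"error"`.
#' @return A tibble of alignment records: `read_id`, `contig_id`,
#'   `contig_start`, `contig_end`, `read_length`, `aligned_query_bases`,
#'   `alignment_span`, `edit_distance`, `identity`, `aligned_fraction`
#'   (plus `sample_id` when given).
#' @export
parse_alignments <- function(sam, catalog, sample_id = NULL,
                             missing_nm = c("warn", "error")) {
  missing_nm <- match.arg(missing_nm)
  validate_catalog(catalog)
  lines <- if (length(sam) == 1L && !grepl("\t", sam) && file.exists(sam)) {
    readLines(sam)
  } else {
    sam
  }
  lines <- lines[!startsWith(lines, "@")]
  empty <- tibble::tibble(
    read_id = character(), contig_id = character(),
    contig_start = integer(), contig_end = integer(),
    read_length = integer(), aligned_query_bases = integer(),
    alignment_span = integer(), edit_distance = integer(),
    identity = double(), aligned_fraction = double()
  )
  if (!is.null(sample_id)) empty$sample_id <- character()
  if (!length(lines)) return(empty)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11)) abort(paste0("malformed SAM record at line ", which(nf < 11)[1]))
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  fields <- fields[keep]
  if (!length(fields)) return(empty)

  read_id <- vapply(fields, `[[`, "", 1L)
  contig_id <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  cigar <- vapply(fields, `[[`, "", 6L)
  seqs <- vapply(fields, `[[`, "", 10L)
  nm <- vapply(fields, function(f) {
    tags <- f[-(1:11)]
    hit <- grep("^NM:i:", tags, value = TRUE)
    if (!length(hit)) return(NA_integer_)
    as.integer(sub("^NM:i:", "", hit[1]))
  }, integer(1))

  unknown <- setdiff(unique(contig_id), catalog$contig_id)
  if (length(unknown))
    abort(paste0("alignment references contig absent from catalog: ", unknown[1]))

  if (anyNA(nm)) {
    bad <- which(is.na(nm))
    msg <- paste0(length(bad), " mapped record(s) missing the NM tag")
    if (missing_nm == "error") abort(msg)
    warn(paste0(msg, "; dropped"))
    read_id <- read_id[-bad]; contig_id <- contig_id[-bad]; pos <- pos[-bad]
    cigar <- cigar[-bad]; seqs <- seqs[-bad]; nm <- nm[-bad]
    if (!length(read_id)) return(empty)
  }

  cs <- cigar_stats(cigar)
  read_length <- ifelse(seqs == "*", cs$query_length, nchar(seqs))
  out <- tibble::tibble(
    read_id = read_id,
    contig_id = contig_id,
    contig_start = pos - 1L,
    contig_end = pos - 1L + cs$reference_span,
    read_length = as.integer(read_length),
    aligned_query_bases = cs$aligned_query_bases,
    alignment_span = cs$alignment_span,
    edit_distance = nm,
    identity = (cs$alignment_span - nm) / cs$alignment_span,
    aligned_fraction = cs$aligned_query_bases / read_length
  )
  if (!is.null(sample_id)) out$sample_id <- sample_id
  out
}

#' Read a BLAST outfmt-6 hit table
#'
#' Parses the 12-column tabular hit format and maps subject ids to taxonomy
#' nodes. No filtering is applied here; see [filter_hits()].
#'
#' @param tsv Path to a TSV file or a character vector of lines (no header).
#' @param tree Taxonomy tibble from [read_taxonomy()].
#' @param source `"nucleotide"` or `"protein"` — evidence class of the search.
#' @param subject_taxon Optional named character vector mapping subject ids to
#'   taxonomy node ids. If `NULL`, subject ids are taken to be node ids.
#' @return Tibble of hits: `query_id`, `subject_taxon`, `pident`, `length`,
#'   `evalue`, `bitscore`, `source`.
#' @export
read_hits <- function(tsv, tree, source = c("nucleotide", "protein"),
                      subject_taxon = NULL) {
  source <- match.arg(source)
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(tsv) == 1L && !grepl("\t|\n", tsv) && file.exists(tsv)) {
    lines <- readLines(tsv)
  } else {
    lines <- tsv
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble::tibble(query_id = character(), subject_taxon = character(),
                          pident = double(), length = integer(),
                          evalue = double(), bitscore = double(),
                          source = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad)) abort(paste0("malformed hit row at line ", bad[1]))
  m <- do.call(rbind, parts)
  df <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12])
  )
  if (anyNA(df$evalue) || anyNA(df$bitscore))
    abort(paste0("non-numeric evalue/bitscore at line ",
                 which(is.na(df$evalue) | is.na(df$bitscore))[1]))
  taxon <- if (is.null(subject_taxon)) df$subject_id else unname(subject_taxon[df$subject_id])
  unknown <- unique(taxon[is.na(taxon) | !(taxon %in% tree$node)])
  if (length(unknown))
    abort(paste0("hit subject maps to unknown taxon: ",
                 paste(utils::head(unknown, 3), collapse = ", ")))
  tibble::tibble(
    query_id = df$query_id, subject_taxon = taxon,
    pident = df$pident, length = df$length,
    evalue = df$evalue, bitscore = df$bitscore, source = source
  )
}

#' Read and validate a taxonomy tree
#'
#' The taxonomy is a TSV of `node`, `parent`, `rank`, `name`, `category`
#' where the single root has `parent` equal to itself and `category` is one of
#' `prokaryotic_virus`, `eukaryotic_virus`, `other`. Category labels are
#' curated node attributes (e.g. tagging Caudovirales as prokaryotic viruses),
#' not inferred from names.
#'
#' @param tsv Path to the TSV (with header) or a data frame with those columns.
#' @return A validated `phg_taxonomy` tibble with a `depth` column added
#'   (root depth 0).
#' @export
read_taxonomy <- function(tsv) {
  tree <- if (is.data.frame(tsv)) {
    tibble::as_tibble(tsv)
  } else {
    readr::read_tsv(tsv, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  stopifnot(all(c("node", "parent", "rank", "name", "category") %in% names(tree)))
  tree$node <- as.character(tree$node)
  tree$parent <- as.character(tree$parent)
  if (anyDuplicated(tree$node)) abort("duplicate taxonomy node ids")
  roots <- tree$node[tree$node == tree$parent]
  if (length(roots) != 1L)
    abort(paste0("taxonomy must have exactly one root (parent = self); found ",
                 length(roots)))
  missing_parent <- setdiff(tree$parent, tree$node)
  if (length(missing_parent))
    abort(paste0("undefined parent node: ", missing_parent[1]))
  bad_cat <- setdiff(unique(tree$category),
                     c("prokaryotic_virus", "eukaryotic_virus", "other"))
  if (length(bad_cat)) abort(paste0("unknown category: ", bad_cat[1]))

  # depth by repeated parent hops; a node that never reaches the root in
  # nrow(tree) hops sits on a cycle
  parent_of <- setNames(tree$parent, tree$node)
  depth <- setNames(rep(NA_integer_, nrow(tree)), tree$node)
  depth[roots] <- 0L
  for (i in seq_len(nrow(tree))) {
    todo <- names(depth)[is.na(depth)]
    if (!length(todo)) break
    ready <- todo[!is.na(depth[parent_of[todo]])]
    if (!length(ready)) {
      abort(paste0("cycle in taxonomy involving: ",
                   paste(utils::head(todo, 5), collapse = ", ")))
    }
    depth[ready] <- depth[parent_of[ready]] + 1L
  }
  tree$depth <- unname(depth[tree$node])
  class(tree) <- c("phg_taxonomy", class(tree))
  tree
}

#' Write / read abundance or presence matrices as TSV
#'
#' Contig-by-sample matrices round-trip through a TSV with a `contig_id`
#' column followed by one column per sample; values survive to at least 10
#' significant digits and row/column order is preserved.
#'
#' @param mat Numeric (or logical, for presence) matrix with rownames =
#'   contig ids and colnames = sample ids.
#' @param path File path.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (is.logical(mat)) storage.mode(mat) <- "integer"
  df <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE),
                          rownames = "contig_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param logical Read as a logical presence matrix.
#' @export
read_matrix_tsv <- function(path, logical = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          contig_id = readr::col_character(),
                          .default = readr::col_double()))
  if (anyDuplicated(df$contig_id)) abort("duplicate contig ids in matrix TSV")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$contig_id
  if (anyNA(mat)) abort("non-numeric cell in matrix TSV")
  if (logical) return(mat > 0)
  if (nrow(mat) && any(mat < 0)) abort("abundance matrices must be non-negative")
  mat
}
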