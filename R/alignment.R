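#' Alignments of equal-length nucleotide sequences
#'
#' An alignment is represented as a named character vector of uppercase
#' sequences (alphabet `A,C,G,T,N,-`), all of the same length, with unique
#' names (the sample ids). `alignment()` validates and normalizes; most
#' other sequence functions accept anything `alignment()` accepts.
#'
#' @param seqs named character vector of sequences.
#' @return validated named character vector of class `dna_alignment`.
#' @export
alignment <- function(seqs) {
  if (inherits(seqs, "dna_alignment")) return(seqs)
  if (length(seqs) == 0) stop("empty alignment", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("sequences must be named by sample id", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  seqs <- toupper(as.character(seqs))
  names(seqs) <- ids
  L <- unique(nchar(seqs))
  if (length(L) != 1) {
    stop("ragged alignment: sequence lengths differ (", paste(L, collapse = ", "),
         ")", call. = FALSE)
  }
  structure(seqs, class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", length(x), "sequences x", nchar(x[[1]]), "sites\n")
  invisible(x)
}

# alignment as an integer matrix (rows = samples): A=1 C=2 G=3 T=4, NA for N/-
aln_matrix <- function(a) {
  a <- alignment(a)
  chars <- matrix(unlist(strsplit(unname(a), "", fixed = TRUE), use.names = FALSE),
                  nrow = length(a), byrow = TRUE)
  code <- match(chars, c("A", "C", "G", "T"))
  dim(code) <- dim(chars)
  rownames(code) <- names(a)
  code
}

#' Read an alignment from a FASTA file
#'
#' @param path FASTA file with equal-length records.
#' @return a `dna_alignment` (named uppercase character vector).
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  alignment(seqs)
}

#' Write an alignment to a FASTA file
#'
#' @param a alignment.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  a <- alignment(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(a), "\n", unname(a)), con)
  invisible(path)
}

#' Concatenate two alignments over the same samples
#'
#' Joins the fragments end to end per sample (e.g. a cytochrome-b fragment
#' followed by a D-loop fragment). The id order of `a` is kept.
#'
#' @param a,b alignments with identical id sets.
#' @return alignment of length `L_a + L_b`.
#' @export
concat_alignments <- function(a, b) {
  a <- alignment(a); b <- alignment(b)
  if (!setequal(names(a), names(b))) {
    stop("alignments have different id sets; cannot concatenate", call. = FALSE)
  }
  alignment(stats::setNames(paste0(unname(a), unname(b[names(a)])), names(a)))
}

#' Collapse an alignment into haplotypes
#'
#' Two samples share a haplotype iff their sequences are strictly identical
#' strings (after uppercasing; `N` and `-` are ordinary characters).
#' Haplotype indices are assigned in order of first appearance.
#'
#' @param a alignment.
#' @return list with `assignment` (named integer vector, sample id ->
#'   haplotype index) and `n_haplotypes`.
#' @export
find_haplotypes <- function(a) {
  a <- alignment(a)
  idx <- match(unname(a), unique(unname(a)))
  list(assignment = stats::setNames(idx, names(a)),
       n_haplotypes = length(unique(idx)))
}

#' Pairwise p-distances with pairwise deletion
#'
#' For each pair, the per-site proportion of differences over the sites
#' where both sequences carry an unambiguous base (`A,C,G,T`); sites with
#' `N` or `-` in either sequence are dropped for that pair only.
#'
#' @param a alignment with at least 2 sequences.
#' @return distance matrix of proportions in `[0, 1]`.
#' @export
pairwise_p_distances <- function(a) {
  a <- alignment(a)
  if (length(a) < 2) stop("need at least 2 sequences", call. = FALSE)
  code <- aln_matrix(a)
  n <- nrow(code)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(code[i, ]) & !is.na(code[j, ])
      n_ok <- sum(ok)
      if (n_ok == 0) {
        stop("no comparable sites between '", rownames(code)[i], "' and '",
             rownames(code)[j], "'", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- sum(code[i, ok] != code[j, ok]) / n_ok
    }
  }
  dist_matrix(d, ids = names(a))
}

#' Nucleotide diversity
#'
#' Mean per-site difference over all unordered pairs of sequences, i.e. the
#' mean of the off-diagonal upper triangle of [pairwise_p_distances()]
#' (pairwise deletion of `N`/`-` sites by default). `deletion =
#' "complete"` instead drops every site that is ambiguous in any sequence
#' before comparing.
#'
#' @param a alignment with at least 2 sequences.
#' @param deletion `"pairwise"` (default) or `"complete"` handling of
#'   ambiguous sites.
#' @return scalar diversity (per site, dimensionless).
#' @export
nucleotide_diversity <- function(a, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  a <- alignment(a)
  if (length(a) < 2) stop("nucleotide diversity needs at least 2 sequences", call. = FALSE)
  if (deletion == "complete") {
    code <- aln_matrix(a)
    keep <- colSums(is.na(code)) == 0
    if (!any(keep)) stop("no unambiguous sites under complete deletion", call. = FALSE)
    sub <- code[, keep, drop = FALSE]
    a <- alignment(stats::setNames(
      apply(sub, 1, function(r) paste(c("A", "C", "G", "T")[r], collapse = "")),
      rownames(code)))
  }
  mean(upper_pairs(pairwise_p_distances(a)))
}
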