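# Global pairwise alignment and the percent-identity convention used
# throughout the package.
#
# Identity convention: Needleman-Wunsch global alignment (affine gaps;
# BLOSUM62 for proteins, +2/-3 for nucleotides); identity = identical
# columns / aligned columns, where terminal gap columns (overhangs of the
# shorter sequence) are excluded from the denominator and internal gap
# columns count as mismatches. This makes identity robust to comparing a
# partial-length amplicon against a full-length reference while still
# penalising genuine indels.

.masdiv_env <- new.env(parent = emptyenv())

protein_submat <- function() {
  if (is.null(.masdiv_env$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .masdiv_env$BLOSUM62 <- e$BLOSUM62
  }
  .masdiv_env$BLOSUM62
}

nucleotide_submat <- function() {
  if (is.null(.masdiv_env$NUCMAT)) {
    .masdiv_env$NUCMAT <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE)
  }
  .masdiv_env$NUCMAT
}

# Align many patterns against one subject; returns aligned strings.
align_to_subject <- function(patterns, subject,
                             alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "protein") {
    pat <- Biostrings::AAStringSet(patterns)
    sub <- Biostrings::AAString(subject)
    mat <- protein_submat()
    go <- 10; ge <- 0.5
  } else {
    pat <- Biostrings::DNAStringSet(patterns)
    sub <- Biostrings::DNAString(subject)
    mat <- nucleotide_submat()
    go <- 5; ge <- 2
  }
  aln <- Biostrings::pairwiseAlignment(
    pat, sub, substitutionMatrix = mat,
    gapOpening = go, gapExtension = ge, type = "global")
  # pattern()/subject() give the per-pair aligned rows (gaps as "-") far
  # faster than the set-padded alignedPattern(), but drop the terminal
  # overhang columns; re-pad them so every row covers both sequences
  ap <- as.character(Biostrings::pattern(aln))
  as_ <- as.character(Biostrings::subject(aln))
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  np <- nchar(patterns)
  ns <- nchar(subject)
  list(
    pattern = paste0(substring(patterns, 1, ps - 1), strrep("-", ss - 1), ap,
                     substring(patterns, pe + 1, np), strrep("-", ns - se)),
    subject = paste0(strrep("-", ps - 1), substring(subject, 1, ss - 1), as_,
                     strrep("-", np - pe), substring(subject, se + 1, ns)))
}

# Identity (percent) from a pair of equal-length aligned strings.
aligned_identity <- function(ap, as_) {
  p <- strsplit(ap, "")[[1]]
  s <- strsplit(as_, "")[[1]]
  pg <- p != "-"
  sg <- s != "-"
  # terminal gap columns: outside the overlap of both sequences' spans
  start <- max(which(pg)[1], which(sg)[1])
  end <- min(which(pg)[length(which(pg))], which(sg)[length(which(sg))])
  if (!is.finite(start) || !is.finite(end) || end < start) return(0)
  idx <- start:end
  100 * sum(p[idx] == s[idx]) / length(idx)
}

#' Percent identity between two sequences
#'
#' Global alignment identity with the package convention: terminal gap
#' columns are excluded from the denominator, internal gaps count as
#' mismatches. Symmetric in its arguments.
#'
#' @param a,b Character scalars (sequences).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return Percent identity in \[0, 100\].
#' @examples
#' pairwise_identity("ACDEFG", "ACDEFA")  # 5/6 = 83.33
#' @export
pairwise_identity <- function(a, b, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (identical(a, b)) return(100)
  # canonical argument order: alignment tie-breaks depend on which
  # sequence is the pattern, so fix the order to guarantee symmetry
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  if (nchar(a) == nchar(b)) {
    # equal-length pair: at moderate divergence the optimal global
    # alignment under affine gap costs is gapless, so the position-wise
    # identity is the alignment identity
    h <- hamming_identity(a, b)
    if (h >= 50) return(h)
  }
  aln <- align_to_subject(a, b, alphabet)
  aligned_identity(aln$pattern[1], aln$subject[1])
}

# Hamming identity for equal-length ungapped sequences (percent).
hamming_identity <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  100 * sum(av == bv) / length(av)
}

# For each anchor column (1-based position in the ungapped anchor), the
# query character aligned to it ("-" where the query has a gap).
map_to_anchor_columns <- function(aligned_query, aligned_anchor) {
  q <- strsplit(aligned_query, "")[[1]]
  a <- strsplit(aligned_anchor, "")[[1]]
  keep <- a != "-"
  q[keep]
}
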