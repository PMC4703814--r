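# Translation and MasD screening: three-frame translation (forward strand
# only; amplicons are orientation-fixed by the forward primer), diagnostic
# motif search, catalytic-cysteine check against the anchor, and gene
# family classification against a labelled reference panel.

#' Translate a nucleotide sequence in the three forward frames
#'
#' Standard genetic code; internal stops are rendered as `*`, the trailing
#' partial codon is dropped, and ambiguous codons translate to `X` (or to
#' the residue when the ambiguity is synonymous).
#'
#' @param nt DNA string of length >= 3.
#' @return Character vector of three proteins (frames 0, 1, 2).
#' @examples
#' translate_frames("TTTGAATGCATTCGT")[1]  # "FECIR"
#' @export
translate_frames <- function(nt) {
  if (nchar(nt) < 3) stop("sequence must be >= 3 nt")
  vapply(0:2, function(f) {
    sub <- substr(nt, f + 1L, f + 3L * ((nchar(nt) - f) %/% 3L))
    if (nchar(sub) < 3) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }, "")
}

# Vectorised three-frame translation of many reads; returns an
# n x 3 character matrix.
translate_frames_many <- function(nts) {
  out <- matrix("", length(nts), 3)
  for (f in 0:2) {
    sub <- substr(nts, f + 1L, f + 3L * ((nchar(nts) - f) %/% 3L))
    ok <- nchar(sub) >= 3
    if (any(ok)) {
      tr <- Biostrings::translate(Biostrings::DNAStringSet(sub[ok]),
                                  if.fuzzy.codon = "solve", no.init.codon = TRUE)
      out[ok, f + 1L] <- as.character(tr)
    }
  }
  out
}

#' Find the leftmost diagnostic motif in a protein
#'
#' Exact substring search over the motif set; the leftmost hit wins, and
#' among hits at the same position the motif earlier in the set wins.
#'
#' @param protein Protein string.
#' @param motifs Motif set (defaults to [masd_motifs()]).
#' @return `NULL` if no motif is found, else a list with `motif` and
#'   1-based `position`.
#' @export
find_motif <- function(protein, motifs = masd_motifs()) {
  if (!nzchar(protein)) stop("'protein' must be non-empty")
  best <- NULL
  for (m in motifs) {
    p <- regexpr(m, protein, fixed = TRUE)[1]
    if (p > 0 && (is.null(best) || p < best$position))
      best <- list(motif = m, position = as.integer(p))
  }
  best
}

has_internal_stop <- function(protein) grepl("*", protein, fixed = TRUE)

#' Select the reading frame of a translated read
#'
#' Priority: a frame containing a motif and no internal stop, then a frame
#' containing a motif, then a frame without internal stop, then frame 0;
#' ties go to the lowest frame index.
#'
#' @param candidates Character vector of the three frame translations.
#' @param motifs Motif set.
#' @return Selected frame offset (0, 1 or 2).
#' @export
select_frame <- function(candidates, motifs = masd_motifs()) {
  stopifnot(length(candidates) == 3)
  has_m <- vapply(candidates, function(p)
    nzchar(p) && !is.null(find_motif(p, motifs)), TRUE, USE.NAMES = FALSE)
  has_s <- vapply(candidates, has_internal_stop, TRUE, USE.NAMES = FALSE)
  pick <- function(ok) if (any(ok)) which(ok)[1] - 1L else NA_integer_
  for (rule in list(has_m & !has_s, has_m, !has_s)) {
    f <- pick(rule)
    if (!is.na(f)) return(f)
  }
  0L
}

#' Check the catalytic cysteine against the anchor
#'
#' Globally aligns the protein to the anchor and inspects the residue
#' aligned to the anchor's annotated catalytic column: `C` gives
#' `"present"`, a gap or any other residue `"absent"`; an alignment
#' identity below `min_identity` percent gives `"unalignable"`.
#'
#' @param protein Protein string (or vector of proteins).
#' @param anchor A `masd_anchor`.
#' @param min_identity Percent identity below which the alignment is
#'   considered uninformative.
#' @return Character vector of `"present"`, `"absent"` or `"unalignable"`.
#' @export
check_catalytic_cysteine <- function(protein, anchor = default_anchor(),
                                     min_identity = 25) {
  anchor <- as_anchor(anchor)
  ok <- nzchar(protein)
  out <- rep("absent", length(protein))
  if (!any(ok)) return(out)
  idx <- which(ok)
  need <- logical(length(idx))
  res <- character(length(idx))
  for (k in seq_along(idx)) {
    p <- protein[idx[k]]
    # gapless fast path: length-matched protein at moderate divergence
    if (nchar(p) == nchar(anchor$protein) &&
        hamming_identity(p, anchor$protein) >= 50) {
      res[k] <- if (substr(p, anchor$cys_pos, anchor$cys_pos) == "C")
        "present" else "absent"
    } else need[k] <- TRUE
  }
  if (any(need)) {
    aln <- align_to_subject(protein[idx[need]], anchor$protein, "protein")
    res[need] <- vapply(seq_along(aln$pattern), function(i) {
      idn <- aligned_identity(aln$pattern[i], aln$subject[i])
      if (idn < min_identity) return("unalignable")
      cols <- map_to_anchor_columns(aln$pattern[i], aln$subject[i])
      if (cols[anchor$cys_pos] == "C") "present" else "absent"
    }, "")
  }
  out[idx] <- res
  out
}

#' Classify a protein into a gene family by best panel hit
#'
#' Best global-alignment identity against the labelled panel; the family
#' of the best hit is returned when identity reaches `min_identity`
#' (fraction), else `"unclassified"`. Ties resolve in the order
#' MasD > NmsA > BssA > Pfl.
#'
#' @param protein Protein string (or vector).
#' @param panel Reference panel data frame (see [synthetic_panel()]).
#' @param min_identity Minimum fractional identity for a family call.
#' @return Character vector of family calls.
#' @export
classify_family <- function(protein, panel = synthetic_panel(),
                            min_identity = 0.40) {
  if (nrow(panel) == 0) stop("'panel' must be non-empty")
  fam_order <- c("MasD", "NmsA", "BssA", "Pfl")
  ok <- nzchar(protein)
  out <- rep("unclassified", length(protein))
  if (!any(ok)) return(out)
  res <- vapply(which(ok), function(i) {
    p <- protein[i]
    # length-matched members first (exact gapless identity); members below
    # the gapless regime are aligned only when no member reaches it --
    # a sub-50% hit cannot out-rank a confident best hit
    ids <- vapply(panel$protein, function(ref) {
      if (nchar(p) == nchar(ref)) hamming_identity(p, ref) else NA_real_
    }, 0, USE.NAMES = FALSE)
    if (all(is.na(ids)) || max(ids, na.rm = TRUE) < 50) {
      need <- is.na(ids) | ids < 50
      ids[need] <- vapply(which(need), function(k)
        pairwise_identity(p, panel$protein[k], "protein"), 0)
    }
    best <- max(ids, na.rm = TRUE)
    if (best / 100 < min_identity) return("unclassified")
    fams <- panel$family[!is.na(ids) & ids == best]
    fams[order(match(fams, fam_order))][1]
  }, "")
  out[ok] <- res
  out
}

#' Screen quality reads for MasD
#'
#' Translates each read (three forward frames), selects a frame, and
#' accepts a read iff a diagnostic motif is found, the frame has no
#' internal stop, the catalytic cysteine is present, and the family call
#' is MasD. The ledger accounts for every read under its first failing
#' rule, in that order.
#'
#' @param reads Data frame of QC-passed reads with columns `id`,
#'   `sequence` and optionally `site`.
#' @param panel Reference panel (see [synthetic_panel()]).
#' @param anchor A `masd_anchor`.
#' @param motifs Motif set.
#' @param min_family_identity Minimum fractional identity for the family
#'   call.
#' @return List of class `screen_result` with `accepted` (data frame:
#'   id, site, frame, protein, motif, motif_pos), `verdicts` and `counts`.
#' @export
screen_reads <- function(reads, panel = synthetic_panel(),
                         anchor = default_anchor(), motifs = masd_motifs(),
                         min_family_identity = 0.40) {
  n <- nrow(reads)
  trs <- translate_frames_many(reads$sequence)
  frame <- integer(n)
  protein <- character(n)
  for (i in seq_len(n)) {
    frame[i] <- select_frame(trs[i, ], motifs)
    protein[i] <- trs[i, frame[i] + 1L]
  }
  motif <- rep(NA_character_, n)
  motif_pos <- rep(NA_integer_, n)
  verdict <- rep("pass", n)
  for (i in seq_len(n)) {
    hit <- if (nzchar(protein[i])) find_motif(protein[i], motifs) else NULL
    if (is.null(hit)) { verdict[i] <- "fail_no_motif"; next }
    motif[i] <- hit$motif
    motif_pos[i] <- hit$position
    if (has_internal_stop(protein[i])) verdict[i] <- "fail_stop_codon"
  }
  todo <- verdict == "pass"
  if (any(todo)) {
    cys <- check_catalytic_cysteine(protein[todo], anchor)
    verdict[todo][cys != "present"] <- "fail_no_cysteine"
  }
  todo <- verdict == "pass"
  if (any(todo)) {
    fam <- classify_family(protein[todo], panel, min_family_identity)
    verdict[todo][fam != "MasD"] <- "fail_family"
  }
  kept <- which(verdict == "pass")
  accepted <- data.frame(id = reads$id[kept],
                         site = if ("site" %in% names(reads))
                           reads$site[kept] else NA_character_,
                         frame = frame[kept], protein = protein[kept],
                         motif = motif[kept], motif_pos = motif_pos[kept],
                         stringsAsFactors = FALSE)
  levels_all <- c("pass", "fail_no_motif", "fail_stop_codon",
                  "fail_no_cysteine", "fail_family")
  counts <- table(factor(verdict, levels = levels_all))
  structure(list(accepted = accepted,
                 verdicts = data.frame(id = reads$id, verdict = verdict,
                                       stringsAsFactors = FALSE),
                 counts = stats::setNames(as.integer(counts), levels_all)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("ORF screen:", sum(x$counts), "reads in,",
      x$counts[["pass"]], "MasD accepted\n")
  rej <- x$counts[x$counts > 0 & names(x$counts) != "pass"]
  if (length(rej))
    cat(paste0("  ", names(rej), ": ", rej, collapse = "\n"), "\n")
  invisible(x)
}
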