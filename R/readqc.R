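# Read-level quality control: primer matching, length / homopolymer /
# mean-quality / ambiguity filters, and a simplified de novo chimera
# screen. Rules are applied in a fixed order (primer -> length ->
# homopolymer -> quality -> ambiguity -> chimera); a read failing several
# rules is counted once, under the first.

#' Quality-control parameters
#'
#' Defaults reproduce the stringent amplicon filters of the original
#' survey: no forward-primer mismatch, minimum 200 bp after trimming,
#' maximum homopolymer run of 8, mean Phred >= 20, no ambiguity codes.
#' "Maximum homopolymer 8" is read as the longest single-base run (the
#' established amplicon-QC convention), and the mean-quality rule applies
#' the prose ("average quality score") over the post-trim read.
#'
#' @param max_primer_mismatch Maximum tolerated forward-primer mismatches.
#' @param min_length Minimum post-trim read length (bp).
#' @param max_homopolymer Longest tolerated homopolymer run (bp).
#' @param min_avg_quality Minimum mean Phred score.
#' @param allow_ambiguities Keep reads containing IUPAC ambiguity codes?
#' @param chimera_score_threshold Chimera score above which a dereplicated
#'   sequence is flagged (see [detect_chimeras()]).
#' @param min_segment_identity Minimum identity of both chimera segments to
#'   their putative parents; the chimeric model must explain the query.
#' @param check_chimeras Run the chimera stage in [filter_reads()]?
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(max_primer_mismatch = 0L, min_length = 200L,
                      max_homopolymer = 8L, min_avg_quality = 20,
                      allow_ambiguities = FALSE,
                      chimera_score_threshold = 0.05,
                      min_segment_identity = 0.90,
                      check_chimeras = TRUE) {
  if (any(c(max_primer_mismatch, min_length, max_homopolymer,
            min_avg_quality, chimera_score_threshold) < 0))
    stop("all thresholds must be >= 0")
  structure(list(max_primer_mismatch = as.integer(max_primer_mismatch),
                 min_length = as.integer(min_length),
                 max_homopolymer = as.integer(max_homopolymer),
                 min_avg_quality = min_avg_quality,
                 allow_ambiguities = isTRUE(allow_ambiguities),
                 chimera_score_threshold = chimera_score_threshold,
                 min_segment_identity = min_segment_identity,
                 check_chimeras = isTRUE(check_chimeras)),
            class = "qc_params")
}

#' Longest homopolymer run in a sequence
#'
#' @param seq Non-empty character scalar.
#' @return Integer length of the longest run of one repeated character.
#' @examples
#' max_homopolymer_run("AAAAAAAAAT")  # 9
#' @export
max_homopolymer_run <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("'seq' must be a non-empty string")
  max(rle(strsplit(seq, "")[[1]])$lengths)
}

# IUPAC-aware per-position mismatch count of a primer against the 5' end
# of a read; a read position matches iff its expansion is covered by the
# primer's degeneracy. A read shorter than the primer counts every primer
# position as a mismatch.
primer_mismatch_count <- function(seq, primer, sets = iupac_sets()) {
  pl <- nchar(primer)
  if (nchar(seq) < pl) return(pl)
  sc <- strsplit(substr(seq, 1, pl), "")[[1]]
  pc <- strsplit(primer, "")[[1]]
  mm <- 0L
  for (i in seq_len(pl)) {
    rs <- sets[[sc[i]]]
    ps <- sets[[pc[i]]]
    if (is.null(rs) || is.null(ps) || !all(rs %in% ps)) mm <- mm + 1L
  }
  mm
}

#' Match a read against a set of degenerate forward primers
#'
#' Position-wise IUPAC-aware comparison at the read 5' end: primer
#' degeneracy (M, Y, R, N, ...) matches its expansion; a read ambiguity
#' counts as a mismatch unless covered by the primer degeneracy. The best
#' primer is the one with fewest mismatches, ties resolved to the lowest
#' index.
#'
#' @param seq Read sequence (barcode already removed).
#' @param primers Character vector of IUPAC primer sequences.
#' @param max_mismatch Maximum tolerated mismatches.
#' @return List with `matched` (flag), `primer_index`, `mismatches`.
#' @export
match_primer <- function(seq, primers = masd_primers()$forward,
                         max_mismatch = 0L) {
  if (length(primers) == 0) stop("'primers' must be non-empty")
  sets <- iupac_sets()
  mm <- vapply(primers, primer_mismatch_count, 0L, seq = seq, sets = sets,
               USE.NAMES = FALSE)
  best <- which.min(mm)
  list(matched = mm[best] <= max_mismatch, primer_index = best,
       mismatches = mm[best])
}

#' Assign reads to sites by exact barcode prefix
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @param barcode_map Data frame with columns `barcode`, `site`.
#' @return The reads with `site` filled in and barcodes stripped; reads
#'   with an unknown barcode keep `site = NA` and their full sequence.
#' @export
demultiplex_reads <- function(reads, barcode_map) {
  site <- rep(NA_character_, nrow(reads))
  seqs <- reads$sequence
  qual <- reads$quality
  for (k in seq_len(nrow(barcode_map))) {
    bc <- barcode_map$barcode[k]
    hit <- startsWith(seqs, bc) & is.na(site)
    site[hit] <- barcode_map$site[k]
    seqs[hit] <- substring(seqs[hit], nchar(bc) + 1L)
    qual[hit] <- substring(qual[hit], nchar(bc) + 1L)
  }
  out <- reads
  out$site <- site
  out$sequence <- seqs
  out$quality <- qual
  out
}

#' Dereplicate sequences with abundances
#'
#' @param seqs Character vector of sequences.
#' @param ids Optional read ids; the representative id of each unique
#'   sequence is its lexicographically first member.
#' @return Data frame `id`, `sequence`, `abundance`, plus a `map` column
#'   attribute giving, for each input, its row in the table.
#' @export
dereplicate_sequences <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("seq%06d", seq_along(seqs))
  key <- factor(seqs, levels = unique(seqs))
  ab <- as.integer(table(key))
  rep_id <- vapply(split(ids, key), function(x) sort(x)[1], "")
  out <- data.frame(id = unname(rep_id), sequence = levels(key),
                    abundance = ab, stringsAsFactors = FALSE)
  attr(out, "map") <- as.integer(key)
  out
}

# Full-length and left/right segment identities (fractions) of a query
# against one parent, for every crossover cut in `cuts` (query
# coordinates). Length-matched pairs use position-wise comparison with
# cumulative match counts; length-mismatched pairs derive all segment
# identities from a single global alignment (internal gap columns count
# as mismatches, terminal gaps are excluded).
chimera_profile_eq <- function(q, p, cuts) {
  nq <- nchar(q)
  m <- utf8ToInt(q) == utf8ToInt(p)
  cum <- cumsum(m)
  tot <- cum[nq]
  list(full = tot / nq,
       left = cum[cuts] / cuts,
       right = (tot - cum[cuts]) / (nq - cuts))
}

# profile from one pair of aligned strings (query as pattern)
chimera_profile_aln <- function(ap, as_, cuts) {
  a <- utf8ToInt(ap)
  b <- utf8ToInt(as_)
  gap <- utf8ToInt("-")
  qpos <- cumsum(a != gap)
  ng_a <- which(a != gap); ng_b <- which(b != gap)
  span <- seq(max(ng_a[1], ng_b[1]),
              min(ng_a[length(ng_a)], ng_b[length(ng_b)]))
  match <- (a == b)[span]
  qp <- qpos[span]
  list(full = mean(match),
       left = vapply(cuts, function(k) {
         sel <- qp <= k
         if (!any(sel)) 0 else mean(match[sel])
       }, 0),
       right = vapply(cuts, function(k) {
         sel <- qp > k
         if (!any(sel)) 0 else mean(match[sel])
       }, 0))
}

# Full-length and left/right segment identities (fractions) of a query
# against each candidate parent, for every crossover cut in `cuts`
# (query coordinates). Length-matched pairs use position-wise comparison
# with cumulative match counts; length-mismatched pairs derive all
# segment identities from a single batched global alignment (internal
# gap columns count as mismatches, terminal gaps are excluded).
chimera_profiles <- function(q, parents, cuts) {
  eq <- nchar(parents) == nchar(q)
  prof <- vector("list", length(parents))
  prof[eq] <- lapply(parents[eq], chimera_profile_eq, q = q, cuts = cuts)
  if (any(!eq)) {
    # batched: all mismatched parents aligned against the query at once
    aln <- align_to_subject(parents[!eq], q, "nucleotide")
    prof[!eq] <- lapply(seq_along(aln$pattern), function(k)
      chimera_profile_aln(aln$subject[k], aln$pattern[k], cuts))
  }
  prof
}

#' Simplified de novo chimera screen
#'
#' Dereplicated sequences are processed in decreasing abundance
#' (id-lexicographic tie-break). For each query, candidate parents are the
#' previously processed, unflagged sequences with abundance at least twice
#' the query's. The query is split at a grid of crossover points; at each
#' split the best distinct parent pair (left parent != right parent)
#' maximizing the smaller segment identity is found. The chimera score is
#' that segment identity minus the best full-length identity to any single
#' parent (both as fractions). A query is flagged when the score exceeds
#' `score_threshold`, the parents are distinct, and both segments match
#' their parents at `min_segment_identity` or better.
#'
#' This is a deliberately simplified three-way comparison of
#' query/parent segments, not a reimplementation of a k-mer chunked
#' chimera search; the stage is pluggable.
#'
#' @param derep Data frame with columns `id`, `sequence`, `abundance`
#'   (see [dereplicate_sequences()]).
#' @param score_threshold Flagging threshold on the score.
#' @param min_segment_identity Minimum fractional segment identity.
#' @param crossover_grid Crossover points as fractions of query length.
#' @return `derep` with added columns `is_chimera`, `score`,
#'   `parent_left`, `parent_right`, in the original row order.
#' @export
detect_chimeras <- function(derep, score_threshold = 0.05,
                            min_segment_identity = 0.90,
                            crossover_grid = seq(0.25, 0.75, by = 0.05)) {
  n <- nrow(derep)
  out <- derep
  out$is_chimera <- rep(FALSE, n)
  out$score <- rep(NA_real_, n)
  out$parent_left <- rep(NA_character_, n)
  out$parent_right <- rep(NA_character_, n)
  if (n < 3) return(out)
  ord <- order(-derep$abundance, derep$id)
  accepted <- integer(0)
  for (qi in ord) {
    q <- derep$sequence[qi]
    cand <- accepted[derep$abundance[accepted] >= 2 * derep$abundance[qi]]
    if (length(cand) >= 2) {
      cuts <- unique(pmax(1L, pmin(nchar(q) - 1L,
                                   round(crossover_grid * nchar(q)))))
      prof <- chimera_profiles(q, derep$sequence[cand], cuts)
      full_best <- max(vapply(prof, `[[`, 0, "full"))
      lid <- do.call(rbind, lapply(prof, `[[`, "left"))   # cand x cuts
      rid <- do.call(rbind, lapply(prof, `[[`, "right"))
      best_score <- -Inf
      best_minseg <- -Inf
      best_pair <- c(NA_integer_, NA_integer_)
      for (ci in seq_along(cuts)) {
        M <- outer(lid[, ci], rid[, ci], pmin)
        diag(M) <- -Inf  # parents must be distinct
        hit <- which(M == max(M), arr.ind = TRUE)[1, ]
        sc <- M[hit[1], hit[2]] - full_best
        if (sc > best_score) {
          best_score <- sc
          best_pair <- cand[hit]
          best_minseg <- M[hit[1], hit[2]]
        }
      }
      out$score[qi] <- best_score
      if (best_score > score_threshold &&
          best_minseg >= min_segment_identity) {
        out$is_chimera[qi] <- TRUE
        out$parent_left[qi] <- derep$id[best_pair[1]]
        out$parent_right[qi] <- derep$id[best_pair[2]]
      }
    }
    if (!out$is_chimera[qi]) accepted <- c(accepted, qi)
  }
  out
}

#' Filter reads through the fixed quality-control cascade
#'
#' A read passes iff its forward-primer mismatches are within
#' `max_primer_mismatch`, its post-trim length reaches `min_length`, its
#' longest homopolymer run does not exceed `max_homopolymer`, its mean
#' Phred score reaches `min_avg_quality`, it contains no ambiguity codes
#' (unless allowed), and it is not flagged by the chimera screen. Kept
#' reads are primer-trimmed; when the reverse primer is found it and any
#' trailing bases are trimmed before the length check. The report accounts
#' for every input read under its first failing rule.
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`
#'   (barcode already stripped, e.g. by [demultiplex_reads()]); an
#'   optional `site` column is carried through.
#' @param params A [qc_params()].
#' @param primers Forward primers (IUPAC), tried in order.
#' @param reverse_primer Reverse primer (IUPAC) or `NULL` to skip
#'   reverse-primer trimming.
#' @return List of class `qc_result` with `reads` (kept, trimmed),
#'   `verdicts` (per-read data frame) and `counts` (named vector whose sum
#'   equals the input read count).
#' @export
filter_reads <- function(reads, params = qc_params(),
                         primers = masd_primers()$forward,
                         reverse_primer = masd_primers()$reverse) {
  n <- nrow(reads)
  verdict <- rep("pass", n)
  note <- rep(NA_character_, n)
  seqs <- reads$sequence
  qual <- if ("quality" %in% names(reads)) reads$quality
          else rep(NA_character_, n)
  sets <- iupac_sets()
  rc_rev <- if (is.null(reverse_primer)) NULL else
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(reverse_primer)))

  for (i in seq_len(n)) {
    m <- match_primer(seqs[i], primers, params$max_primer_mismatch)
    if (!m$matched) { verdict[i] <- "fail_primer"; next }
    pl <- nchar(primers[m$primer_index])
    s <- substring(seqs[i], pl + 1L)
    q <- if (is.na(qual[i])) NA_character_ else substring(qual[i], pl + 1L)
    if (!is.null(rc_rev) && nzchar(s)) {
      hit <- Biostrings::matchPattern(rc_rev, Biostrings::DNAString(s),
                                      fixed = FALSE)
      if (length(hit) > 0) {
        cut <- Biostrings::start(hit)[length(hit)] - 1L
        s <- substr(s, 1L, cut)
        if (!is.na(q)) q <- substr(q, 1L, cut)
      }
    }
    seqs[i] <- s
    qual[i] <- q
    if (nchar(s) < params$min_length) { verdict[i] <- "fail_length"; next }
    if (max_homopolymer_run(s) > params$max_homopolymer) {
      verdict[i] <- "fail_homopolymer"; next
    }
    if (params$min_avg_quality > 0) {
      if (is.na(q) || !nzchar(q)) {
        verdict[i] <- "fail_quality"
        note[i] <- "missing qualities"
        next
      }
      if (mean_phred(q) < params$min_avg_quality) {
        verdict[i] <- "fail_quality"; next
      }
    }
    if (!params$allow_ambiguities && grepl("[^ACGT]", s)) {
      verdict[i] <- "fail_ambiguity"; next
    }
  }

  if (params$check_chimeras && sum(verdict == "pass") >= 3) {
    keep <- which(verdict == "pass")
    derep <- dereplicate_sequences(seqs[keep], reads$id[keep])
    flags <- detect_chimeras(derep,
                             score_threshold = params$chimera_score_threshold,
                             min_segment_identity = params$min_segment_identity)
    chim_seqs <- flags$sequence[flags$is_chimera]
    if (length(chim_seqs))
      verdict[keep[seqs[keep] %in% chim_seqs]] <- "fail_chimera"
  }

  kept <- which(verdict == "pass")
  out_reads <- data.frame(id = reads$id[kept], sequence = seqs[kept],
                          quality = qual[kept], stringsAsFactors = FALSE)
  if ("site" %in% names(reads)) out_reads$site <- reads$site[kept]
  levels_all <- c("pass", "fail_primer", "fail_length", "fail_homopolymer",
                  "fail_quality", "fail_ambiguity", "fail_chimera")
  counts <- table(factor(verdict, levels = levels_all))
  structure(list(reads = out_reads,
                 verdicts = data.frame(id = reads$id, verdict = verdict,
                                       note = note, stringsAsFactors = FALSE),
                 counts = stats::setNames(as.integer(counts), levels_all)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Read QC:", sum(x$counts), "reads in,", x$counts[["pass"]], "kept\n")
  rej <- x$counts[x$counts > 0 & names(x$counts) != "pass"]
  if (length(rej))
    cat(paste0("  ", names(rej), ": ", rej, collapse = "\n"), "\n")
  invisible(x)
}
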