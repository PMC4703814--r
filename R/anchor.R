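# Reference material: diagnostic motifs, PCR primers, and the synthetic
# anchor / reference panel shipped with the package.
#
# The real survey anchors its coordinate system on the MasD protein of
# strain HxN1 (motif around column 435, catalytic cysteine at column 477;
# amplified region covering roughly columns 395-657). Those database
# sequences cannot be bundled here, so the package ships a SYNTHETIC
# anchor: a deterministically generated 180-residue protein carrying the
# FECIR motif at column 41 and the catalytic cysteine at column 83, with a
# 120-column analysis region (columns 31-150) mirroring the 120-position
# window the survey clustered on. All anchor coordinates are parameters,
# so a real anchor can be substituted.

#' Diagnostic MasD motifs
#'
#' The six amino-acid motifs used to recognise MasD/AssA reads
#' (FECIR, FECIK, FECQR, FECVR, FDCIR, FDNIA).
#' @return Character vector of six motifs.
#' @export
masd_motifs <- function() {
  c("FECIR", "FECIK", "FECQR", "FECVR", "FDCIR", "FDNIA")
}

#' MasD amplification primers
#'
#' Degenerate primer sequences used for masD/assA amplicon generation:
#' forward 7757f (`TCGGACGCGTGCAACGMYCTGA`) and reverse 8543r
#' (`TCGTCRTTGCCCCAYTTNGG`), plus the alternative forward primer 7766f.
#'
#' @return List with elements `forward` (character vector of forward
#'   primers, IUPAC degenerate) and `reverse` (reverse primer).
#' @export
masd_primers <- function() {
  list(forward = c("TCGGACGCGTGCAACGMYCTGA", "TGTAACGGCATGACCATTGCGCT"),
       reverse = "TCGTCRTTGCCCCAYTTNGG")
}

# Concrete (non-degenerate) primer instances used by the simulator; they
# match the degenerate primers with zero mismatches.
concrete_primers <- function() {
  list(forward = "TCGGACGCGTGCAACGACCTGA",   # M->A, Y->C
       reverse = "TCGTCATTGCCCCATTTAGG")     # R->A, Y->T, N->A
}

# Frozen synthetic anchor protein (generated once, seeded; FECIR at 41-45,
# catalytic C at 83, no triple-residue runs so back-translations stay clear
# of the >8 homopolymer QC rule).
.ANCHOR_PROTEIN <- paste0(
  "YIGFAVETRLIRNKPWQHCNIYFGHWTFVRATRGWSSVNGFECIRCRWWGPHAPRFFIHY",
  "TVHTRECITSKLLISMLCSPMECTTPTFATNKEWMNGTEWPHSPEMCSEMRGSNPYMMVH",
  "FSEKGFGTMDWTAADWTHYNPGKPPENNVSCTVFTMSCNYCPLMFMFKAKINLYTCVTWP")

#' Synthetic MasD anchor
#'
#' The bundled synthetic anchor protein with its annotations: motif
#' position, catalytic cysteine column, and the default analysis region
#' used for OTU clustering (120 anchor columns).
#'
#' @return An object of class `masd_anchor`: a list with `id`, `protein`,
#'   `motif`, `motif_pos`, `cys_pos` and `region` (inclusive 1-based
#'   anchor column interval).
#' @export
default_anchor <- function() {
  structure(list(
    id = "MasD_anchor_synthetic",
    protein = .ANCHOR_PROTEIN,
    motif = "FECIR",
    motif_pos = 41L,
    cys_pos = 83L,
    region = c(31L, 150L)
  ), class = "masd_anchor")
}

#' @export
print.masd_anchor <- function(x, ...) {
  cat("Synthetic MasD anchor (", nchar(x$protein), " aa)\n", sep = "")
  cat("  motif ", x$motif, " at column ", x$motif_pos,
      "; catalytic Cys at column ", x$cys_pos, "\n", sep = "")
  cat("  analysis region: columns ", x$region[1], "-", x$region[2],
      " (", x$region[2] - x$region[1] + 1L, " columns)\n", sep = "")
  invisible(x)
}

as_anchor <- function(x) {
  if (inherits(x, "masd_anchor")) return(x)
  stop("'anchor' must be a 'masd_anchor' object (see default_anchor())")
}

#' Synthetic glycyl-radical-enzyme reference panel
#'
#' A small labelled protein panel for family classification: the MasD
#' anchor plus one diverged MasD relative, and synthetic, motif-free
#' NmsA-, BssA- and Pfl-like decoys (off-target families amplified by
#' unspecific primer binding). All non-anchor members are synthetic.
#'
#' @param seed Integer seed for the deterministic decoy generation.
#' @return A `data.frame` with columns `id`, `family`, `protein`, carrying
#'   the anchor annotations as attribute `anchor`.
#' @export
synthetic_panel <- function(seed = 101L) {
  anchor <- default_anchor()
  with_seed(seed, {
    masd2 <- evolve_protein_family(anchor, divergences = 0.25,
                                   seed = derive_seed(seed, 1))[[1]]
    decoys <- replicate(4, random_protein(180, avoid = masd_motifs()))
  })
  panel <- data.frame(
    id = c("MasD_anchor_synthetic", "MasD_rel_synthetic",
           "NmsA_syn1", "NmsA_syn2", "BssA_syn1", "Pfl_syn1"),
    family = c("MasD", "MasD", "NmsA", "NmsA", "BssA", "Pfl"),
    protein = c(anchor$protein, masd2, decoys),
    stringsAsFactors = FALSE)
  attr(panel, "anchor") <- anchor
  panel
}

# Synthetic 16S-like nucleotide anchor (1200 nt), deterministic.
default_16s_anchor <- function() {
  with_seed(424243L,
            paste(sample(DNA_BASES, 1200, replace = TRUE), collapse = ""))
}

#' Synthetic full-length strain reference protein
#'
#' A deterministic 600-residue MasD-like protein (the bundled anchor
#' extended with a synthetic tail) used as the default ancestor for
#' strain-pair simulation: strain-level identity comparisons are made on
#' full-length proteins, and the longer sequence keeps substitution-count
#' quantization negligible.
#'
#' @return A protein string of length 600 containing the diagnostic
#'   motif and catalytic cysteine of the anchor.
#' @export
strain_reference_protein <- function() {
  if (is.null(.masdiv_env$STRAIN_REF)) {
    tail <- with_seed(87431L, random_protein(420, avoid = masd_motifs()))
    .masdiv_env$STRAIN_REF <- paste0(.ANCHOR_PROTEIN, tail)
  }
  .masdiv_env$STRAIN_REF
}

#' Read or write a reference panel FASTA
#'
#' Panel FASTA headers carry `family=` and (optionally) `anchor=`,
#' `motif_pos=`, `cys_pos=`, `region=` key-value tags.
#'
#' @param path File path.
#' @return `read_panel_fasta()` returns a panel `data.frame` as produced
#'   by [synthetic_panel()].
#' @export
read_panel_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  parse_tag <- function(h, tag) {
    m <- regmatches(h, regexpr(paste0(tag, "=\\S+"), h))
    if (length(m) == 0) NA_character_ else sub(paste0(tag, "="), "", m)
  }
  fam <- vapply(hdr, parse_tag, "", tag = "family")
  id <- vapply(strsplit(hdr, "\\s+"), `[`, "", 1)
  panel <- data.frame(id = id, family = unname(fam),
                      protein = as.character(seqs), stringsAsFactors = FALSE)
  anch_i <- which(vapply(hdr, function(h) !is.na(parse_tag(h, "anchor")), TRUE))
  if (length(anch_i) == 1) {
    h <- hdr[anch_i]
    region <- as.integer(strsplit(parse_tag(h, "region"), ",")[[1]])
    anchor <- structure(list(
      id = id[anch_i], protein = panel$protein[anch_i],
      motif = find_motif(panel$protein[anch_i])$motif,
      motif_pos = as.integer(parse_tag(h, "motif_pos")),
      cys_pos = as.integer(parse_tag(h, "cys_pos")),
      region = region), class = "masd_anchor")
    attr(panel, "anchor") <- anchor
  }
  panel
}

#' @rdname read_panel_fasta
#' @param panel Panel `data.frame` (see [synthetic_panel()]).
#' @export
write_panel_fasta <- function(panel, path) {
  anchor <- attr(panel, "anchor")
  hdr <- paste0(panel$id, " family=", panel$family)
  if (!is.null(anchor)) {
    i <- match(anchor$id, panel$id)
    if (!is.na(i))
      hdr[i] <- paste0(hdr[i], " anchor=true motif_pos=", anchor$motif_pos,
                       " cys_pos=", anchor$cys_pos,
                       " region=", anchor$region[1], ",", anchor$region[2])
  }
  x <- Biostrings::AAStringSet(panel$protein)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
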