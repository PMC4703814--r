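# Synthetic amplicon data with known ground truth.
#
# The generator emulates the statistical structure of a multi-site
# functional-gene amplicon survey: a community of motif-bearing
# protein-coding OTUs with lognormal abundances spread over sites, reads
# built as barcode + forward primer + back-translated coding sequence +
# reverse-complemented reverse primer, 454-style substitution/indel errors
# (indels boosted inside homopolymer runs), PCR chimeras, and off-target
# (NmsA/BssA-like) spikes. Every emitted read has exactly one truth record.

#' Community specification for the amplicon simulator
#'
#' Defaults mirror the structure of the original 12-site survey:
#' 12 sites, 420 species-level OTUs, 428 reads per site (about 5100 quality
#' reads total), lognormal OTU abundances, about 0.5% cosmopolitan OTUs and
#' a site-overlap parameter tuned so that roughly 60% of OTUs occupy a
#' single site.
#'
#' @param n_sites Number of sites (>= 1).
#' @param n_otus Number of OTUs (>= 1).
#' @param abundance_model `"lognormal"`, `"uniform"` or `"geometric"`.
#' @param abundance_params Parameters of the abundance model
#'   (`meanlog`/`sdlog` for lognormal, `ratio` for geometric).
#' @param reads_per_site Reads emitted per site (>= 1).
#' @param cosmopolitan_fraction Fraction of OTUs present at every site.
#' @param site_overlap Per-extra-site occupancy probability for the
#'   remaining OTUs (occupancy = 1 + Binomial(n_sites - 1, site_overlap)).
#' @param seed Integer seed; all outputs are pure functions of (spec, seed).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_sites = 12L, n_otus = 420L,
                           abundance_model = c("lognormal", "uniform", "geometric"),
                           abundance_params = list(meanlog = 0, sdlog = 2, ratio = 0.9),
                           reads_per_site = 428L,
                           cosmopolitan_fraction = 0.005,
                           site_overlap = 0.05,
                           seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot_count(n_sites, "n_sites")
  stopifnot_count(n_otus, "n_otus")
  stopifnot_count(reads_per_site, "reads_per_site")
  stopifnot_scalar_fraction(cosmopolitan_fraction, "cosmopolitan_fraction")
  stopifnot_scalar_fraction(site_overlap, "site_overlap")
  structure(list(n_sites = as.integer(n_sites), n_otus = as.integer(n_otus),
                 abundance_model = abundance_model,
                 abundance_params = abundance_params,
                 reads_per_site = as.integer(reads_per_site),
                 cosmopolitan_fraction = cosmopolitan_fraction,
                 site_overlap = site_overlap, seed = as.integer(seed)),
            class = "community_spec")
}

#' Sequencing error model
#'
#' Defaults emulate 454 pyrosequencing behaviour: low substitution rate,
#' indels concentrated in homopolymer runs (the chemistry that motivates
#' the >8-homopolymer quality filter), a few percent chimeras, and an
#' off-target spike comparable to the share of non-target (NmsA/BssA)
#' amplicons in the original survey. Quality scores are drawn per base
#' from a truncated normal clamped to \[2, 40\], independent of errors
#' (a documented simplification).
#'
#' @param substitution_rate Per-base substitution probability.
#' @param indel_rate Per-base indel probability outside homopolymers.
#' @param homopolymer_indel_multiplier Factor (>= 1) applied to
#'   `indel_rate` for bases inside a homopolymer run of length >= 3.
#' @param chimera_fraction Fraction of reads per site turned into chimeras.
#' @param offtarget_fraction Fraction of reads per site replaced by
#'   off-target (motif-free) amplicons.
#' @param quality_mean,quality_sd Phred-scale parameters of the per-base
#'   quality distribution.
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.001, indel_rate = 5e-4,
                        homopolymer_indel_multiplier = 10,
                        chimera_fraction = 0.05, offtarget_fraction = 0.10,
                        quality_mean = 33, quality_sd = 4) {
  for (nm in c("substitution_rate", "indel_rate", "chimera_fraction",
               "offtarget_fraction"))
    stopifnot_scalar_fraction(get(nm), nm)
  if (homopolymer_indel_multiplier < 1)
    stop("'homopolymer_indel_multiplier' must be >= 1")
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 homopolymer_indel_multiplier = homopolymer_indel_multiplier,
                 chimera_fraction = chimera_fraction,
                 offtarget_fraction = offtarget_fraction,
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "error_model")
}

#' Error model with all error processes switched off
#' @return An `error_model` with all rates zero and high quality.
#' @export
error_model_clean <- function() {
  error_model(substitution_rate = 0, indel_rate = 0,
              homopolymer_indel_multiplier = 1,
              chimera_fraction = 0, offtarget_fraction = 0,
              quality_mean = 38, quality_sd = 1)
}

# ---- protein evolution ------------------------------------------------

codon_choices <- function() {
  if (is.null(.masdiv_env$CODONS)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[gc != "*"]
    .masdiv_env$CODONS <- split(names(gc), unname(gc))
  }
  .masdiv_env$CODONS
}

# Substitute n_sub random non-protected positions, each to a different
# residue; assumes the current RNG stream.
mutate_protein <- function(protein, n_sub, protected = integer(0)) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ch <- strsplit(protein, "")[[1]]
  free <- setdiff(seq_along(ch), protected)
  if (n_sub > length(free))
    stop("requested divergence exceeds the number of substitutable columns")
  pos <- sample(free, n_sub)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(aa, b), 1), "")
  paste(ch, collapse = "")
}

#' Evolve a family of OTU reference proteins from an ancestor
#'
#' Each requested divergence yields one descendant with exactly
#' `round(d * L)` substituted positions, drawn outside the protected
#' columns (the diagnostic motif and the catalytic cysteine), so every
#' descendant still screens as MasD.
#'
#' @param ancestor A `masd_anchor` or a protein string containing one of
#'   the six diagnostic motifs and a cysteine downstream of it.
#' @param divergences Numeric vector of divergences in \[0, 0.6\].
#' @param seed Integer seed.
#' @return Named character vector of descendant proteins (`OTU001`, ...),
#'   with realized per-sequence divergence in attribute `divergence`.
#' @export
evolve_protein_family <- function(ancestor, divergences, seed = 1L) {
  if (inherits(ancestor, "masd_anchor")) {
    prot <- ancestor$protein
    motif_pos <- ancestor$motif_pos
    cys_pos <- ancestor$cys_pos
  } else {
    prot <- as.character(ancestor)
    hit <- find_motif(prot)
    if (is.null(hit))
      stop("ancestor lacks a diagnostic MasD motif (one of ",
           paste(masd_motifs(), collapse = ", "), ")")
    motif_pos <- hit$position
    downstream <- gregexpr("C", substr(prot, motif_pos + 5L, nchar(prot)),
                           fixed = TRUE)[[1]]
    if (downstream[1] == -1)
      stop("ancestor lacks a catalytic cysteine downstream of the motif")
    cys_pos <- motif_pos + 4L + downstream[1]
  }
  if (any(divergences < 0 | divergences > 0.6))
    stop("divergences must lie in [0, 0.6]")
  protected <- c(motif_pos:(motif_pos + 4L), cys_pos)
  L <- nchar(prot)
  with_seed(seed, {
    out <- vapply(divergences, function(d)
      mutate_protein(prot, round(d * L), protected), "")
  })
  names(out) <- sprintf("OTU%03d", seq_along(out))
  realized <- vapply(out, function(s)
    sum(utf8ToInt(s) != utf8ToInt(prot)) / L, 0)
  attr(out, "divergence") <- realized
  out
}

#' Default reference OTU set for simulations
#'
#' Evolves `n` reference proteins from the synthetic anchor at divergences
#' evenly spaced in \[0.05, `max_divergence`\]; any two references then
#' differ by more than the species-level clustering threshold, so a clean
#' simulation recovers exactly `n` OTUs.
#'
#' @param n Number of reference OTUs.
#' @param seed Integer seed.
#' @param max_divergence Largest divergence from the anchor.
#' @return Named character vector of reference proteins.
#' @export
masd_reference_set <- function(n = 20L, seed = 7L, max_divergence = 0.5) {
  d <- if (n == 1L) 0.05 else seq(0.05, max_divergence, length.out = n)
  evolve_protein_family(default_anchor(), d, seed = seed)
}

#' Back-translate a protein to a coding sequence
#'
#' Uses the standard genetic code with seeded uniform synonymous codon
#' choice (optionally weighted). Codon realizations containing a
#' homopolymer run longer than `max_homopolymer` are resampled, so the
#' generator emits template molecules that the homopolymer quality filter
#' (aimed at sequencing artefacts) does not reject.
#'
#' @param protein Protein string (no stop characters).
#' @param seed Integer seed or `NULL` to use the current RNG stream.
#' @param codon_weights Optional named numeric vector of per-codon weights.
#' @param max_homopolymer Longest tolerated homopolymer run.
#' @return A DNA string of length `3 * nchar(protein)`.
#' @export
back_translate <- function(protein, seed = NULL, codon_weights = NULL,
                           max_homopolymer = 8L) {
  tab <- codon_choices()
  aa <- strsplit(protein, "")[[1]]
  if (any(!aa %in% names(tab)))
    stop("protein contains characters outside the 20 standard residues")
  with_seed(seed, {
    for (attempt in 1:100) {
      cds <- paste(vapply(aa, function(a) {
        cods <- tab[[a]]
        w <- if (is.null(codon_weights)) NULL else codon_weights[cods]
        sample(cods, 1L, prob = w)
      }, ""), collapse = "")
      if (max_homopolymer_run(cds) <= max_homopolymer) return(cds)
    }
    stop("could not realize a homopolymer-safe coding sequence")
  })
}

# ---- read-level error machinery ---------------------------------------

apply_read_errors <- function(seq, sub_rate, indel_rate, homop_mult) {
  if (sub_rate <= 0 && indel_rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hit <- which(stats::runif(n) < sub_rate)
  if (length(hit))
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1), "")
  if (indel_rate > 0) {
    r <- rle(ch)
    in_long_run <- rep(r$lengths >= 3L, r$lengths)
    rate <- ifelse(in_long_run, pmin(1, indel_rate * homop_mult), indel_rate)
    hit <- which(stats::runif(n) < rate)
    for (i in rev(hit)) {
      if (stats::runif(1) < 0.5) ch <- ch[-i]
      else ch <- append(ch, sample(DNA_BASES, 1), after = i)
    }
  }
  paste(ch, collapse = "")
}

draw_quality_string <- function(len, mean, sd) {
  q <- round(pmin(40, pmax(2, stats::rnorm(len, mean, sd))))
  paste(phred_to_chars(q), collapse = "")
}

# ---- dataset generation ------------------------------------------------

#' Generate a synthetic amplicon dataset with ground truth
#'
#' Per site, OTU read counts are drawn from the abundance model and
#' multinomially sampled to `reads_per_site` (sampling with replacement:
#' counts may exceed unique molecules). Each read is assembled as
#' barcode + forward primer + back-translated coding sequence +
#' reverse-complemented reverse primer, then passed through the error
#' model. A fixed fraction of reads per site is replaced by off-target
#' amplicons and another fixed fraction by chimeras joining two parent
#' reads at a uniform crossover in the central 60% of the read. A fixed
#' seed yields byte-identical output.
#'
#' @param spec A [community_spec()].
#' @param error An [error_model()].
#' @param references Named character vector of reference OTU proteins.
#' @param offtarget_refs Optional named character vector of off-target
#'   proteins; defaults to the non-MasD members of [synthetic_panel()].
#' @return An object of class `amplicon_dataset`: a list with `reads`
#'   (data.frame: id, site, sequence, quality), `truth` (data.frame:
#'   read_id, site, otu, is_chimera, is_offtarget, frame), `barcode_map`,
#'   `references` (protein and nucleotide), and the spec/error used.
#' @export
generate_dataset <- function(spec, error = error_model(),
                             references = masd_reference_set(spec$n_otus),
                             offtarget_refs = NULL) {
  stopifnot(inherits(spec, "community_spec"), inherits(error, "error_model"))
  if (length(references) == 0) stop("'references' must be non-empty")
  if (is.null(names(references)))
    names(references) <- sprintf("OTU%03d", seq_along(references))
  if (length(references) != spec$n_otus)
    stop("length(references) must equal spec$n_otus")
  if (is.null(offtarget_refs) && error$offtarget_fraction > 0) {
    pan <- synthetic_panel()
    offtarget_refs <- stats::setNames(pan$protein[pan$family != "MasD"],
                                      paste0("OFF_", pan$id[pan$family != "MasD"]))
  }
  prm <- concrete_primers()
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(prm$reverse)))

  with_seed(spec$seed, {
    sites <- sprintf("S%02d", seq_len(spec$n_sites))
    barcodes <- make_barcodes(spec$n_sites)
    n_otus <- spec$n_otus

    # global OTU abundance weights
    w <- switch(spec$abundance_model,
      lognormal = stats::rlnorm(n_otus,
                                spec$abundance_params$meanlog %||% 0,
                                spec$abundance_params$sdlog %||% 2),
      uniform = stats::runif(n_otus, 0.5, 1.5),
      geometric = (spec$abundance_params$ratio %||% 0.9)^(seq_len(n_otus) - 1))

    # occupancy: cosmopolitan OTUs at all sites, others at 1 + Binom extra
    n_cosmo <- round(spec$cosmopolitan_fraction * n_otus)
    cosmo <- if (n_cosmo > 0) sample(n_otus, n_cosmo) else integer(0)
    present <- matrix(FALSE, spec$n_sites, n_otus,
                      dimnames = list(sites, names(references)))
    present[, cosmo] <- TRUE
    for (o in setdiff(seq_len(n_otus), cosmo)) {
      k <- 1L + stats::rbinom(1, spec$n_sites - 1L, spec$site_overlap)
      present[sample(spec$n_sites, k), o] <- TRUE
    }

    # one deterministic coding sequence per reference
    cds <- vapply(references, function(p) back_translate(p), "")
    off_cds <- if (length(offtarget_refs))
      vapply(offtarget_refs, function(p) back_translate(p), "") else character(0)

    reads <- vector("list", spec$n_sites)
    truth <- vector("list", spec$n_sites)
    for (si in seq_len(spec$n_sites)) {
      pres <- which(present[si, ])
      if (length(pres) == 0) pres <- seq_len(n_otus)  # degenerate guard
      cnt <- as.vector(stats::rmultinom(1, spec$reads_per_site, w[pres]))
      otu_idx <- rep(pres, cnt)
      nr <- length(otu_idx)
      otu <- names(references)[otu_idx]
      is_off <- rep(FALSE, nr)
      n_off <- round(error$offtarget_fraction * nr)
      if (n_off > 0 && length(off_cds)) {
        oi <- sample(nr, n_off)
        is_off[oi] <- TRUE
        otu[oi] <- names(off_cds)[sample(length(off_cds), n_off, replace = TRUE)]
      }
      core <- ifelse(is_off, off_cds[otu], cds[otu])
      base <- paste0(barcodes[si], prm$forward, core, rc_rev)
      seqs <- vapply(base, apply_read_errors, "",
                     sub_rate = error$substitution_rate,
                     indel_rate = error$indel_rate,
                     homop_mult = error$homopolymer_indel_multiplier,
                     USE.NAMES = FALSE)
      is_chim <- rep(FALSE, nr)
      n_chim <- round(error$chimera_fraction * nr)
      if (n_chim > 0 && nr >= 2) {
        ci <- sample(which(!is_off), min(n_chim, sum(!is_off)))
        for (i in ci) {
          partners <- which(otu != otu[i] & seq_len(nr) != i)
          if (length(partners) == 0) partners <- setdiff(seq_len(nr), i)
          j <- if (length(partners) == 1) partners else sample(partners, 1)
          len <- min(nchar(seqs[i]), nchar(seqs[j]))
          cut <- round(stats::runif(1, 0.2, 0.8) * len)
          seqs[i] <- paste0(substr(seqs[i], 1, cut),
                            substr(seqs[j], cut + 1, nchar(seqs[j])))
          is_chim[i] <- TRUE
        }
      }
      qual <- vapply(nchar(seqs), draw_quality_string, "",
                     mean = error$quality_mean, sd = error$quality_sd)
      id <- sprintf("%s_r%04d", sites[si], seq_len(nr))
      reads[[si]] <- data.frame(id = id, site = sites[si], sequence = seqs,
                                quality = qual, stringsAsFactors = FALSE)
      truth[[si]] <- data.frame(read_id = id, site = sites[si], otu = otu,
                                is_chimera = is_chim, is_offtarget = is_off,
                                frame = 0L, stringsAsFactors = FALSE)
    }
    structure(list(
      reads = do.call(rbind, reads),
      truth = do.call(rbind, truth),
      barcode_map = data.frame(barcode = barcodes, site = sites,
                               stringsAsFactors = FALSE),
      references = list(protein = references, cds = cds,
                        offtarget = offtarget_refs),
      spec = spec, error = error), class = "amplicon_dataset")
  })
}

#' @export
print.amplicon_dataset <- function(x, ...) {
  cat("Synthetic amplicon dataset:", nrow(x$reads), "reads,",
      x$spec$n_sites, "sites,", x$spec$n_otus, "reference OTUs\n")
  cat("  chimeras:", sum(x$truth$is_chimera),
      " off-target:", sum(x$truth$is_offtarget), "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `reads.fastq` (Sanger Phred+33), `truth.tsv`, `barcodes.tsv`
#' and `references.fasta` into `dir`.
#'
#' @param dataset An `amplicon_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fastq = file.path(dir, "reads.fastq"),
             truth = file.path(dir, "truth.tsv"),
             barcodes = file.path(dir, "barcodes.tsv"),
             refs = file.path(dir, "references.fasta"))
  write_fastq(dataset$reads, paths[["fastq"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$barcode_map, paths[["barcodes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  refs <- Biostrings::AAStringSet(dataset$references$protein)
  Biostrings::writeXStringSet(refs, paths[["refs"]])
  invisible(paths)
}

# ---- strain-pair simulation -------------------------------------------

#' Specification for paired 16S/protein strain simulation
#'
#' Defaults place strains on the published coupling between MasD protein
#' identity and 16S rRNA identity: the line through (98.7, 96) and
#' (86.5, 72) percent, i.e. slope ~1.967, intercept ~-98.16.
#'
#' @param n_strains Number of strains (>= 3).
#' @param slope,intercept Linear coupling of protein identity (percent)
#'   to 16S identity (percent); `slope` must be positive.
#' @param noise_sd Standard deviation (identity percent) of pairwise
#'   protein-identity noise around the line.
#' @param seed Integer seed.
#' @return An object of class `strain_pair_spec`.
#' @export
strain_pair_spec <- function(n_strains = 15L, slope = 24 / 12.2,
                             intercept = 96 - (24 / 12.2) * 98.7,
                             noise_sd = 2, seed = 1L) {
  stopifnot_count(n_strains, "n_strains", min = 3L)
  if (slope <= 0) stop("'slope' must be positive (the model assumes positive coupling)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(n_strains = as.integer(n_strains), slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "strain_pair_spec")
}

#' Simulate strains with coupled 16S and marker-protein divergence
#'
#' Strains are placed on a star phylogeny such that expected pairwise
#' protein identity follows `intercept + slope * s16` with Gaussian noise.
#' Substitutions in the protein avoid the diagnostic motif and catalytic
#' cysteine.
#'
#' @param spec A [strain_pair_spec()].
#' @param anchor_protein Ancestor protein (a `masd_anchor` or a string of
#'   length >= 100 containing a diagnostic motif); defaults to the
#'   synthetic full-length [strain_reference_protein()].
#' @param anchor_16s Ancestor 16S-like nucleotide string (length >= 300).
#' @return A `data.frame` (class `strain_set`) with columns `strain_id`,
#'   `protein`, `s16`; the generating line is kept in attribute `truth`.
#' @export
simulate_strain_pairs <- function(spec,
                                  anchor_protein = strain_reference_protein(),
                                  anchor_16s = default_16s_anchor()) {
  stopifnot(inherits(spec, "strain_pair_spec"))
  anchor <- if (inherits(anchor_protein, "masd_anchor")) anchor_protein
            else NULL
  prot <- if (is.null(anchor)) as.character(anchor_protein) else anchor$protein
  if (nchar(prot) < 100) stop("anchor protein must be >= 100 aa")
  if (nchar(anchor_16s) < 300) stop("anchor 16S must be >= 300 nt")
  if (is.null(anchor)) {
    hit <- find_motif(prot)
    if (is.null(hit)) stop("anchor protein lacks a diagnostic motif")
    motif_pos <- hit$position
    cpos <- gregexpr("C", substr(prot, motif_pos + 5L, nchar(prot)))[[1]][1]
    if (cpos == -1) stop("anchor protein lacks a downstream cysteine")
    cys_pos <- motif_pos + 4L + cpos
  } else {
    motif_pos <- anchor$motif_pos; cys_pos <- anchor$cys_pos
  }
  protected <- c(motif_pos:(motif_pos + 4L), cys_pos)
  Lp <- nchar(prot); Ln <- nchar(anchor_16s)
  n <- spec$n_strains
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  with_seed(spec$seed, {
    # Star decomposition: with disjoint per-strain substitution sets the
    # realized pairwise divergence is exactly d_i + d_j, so pairwise
    # protein identity falls exactly on intercept + slope * s16 (up to
    # count rounding). Per-strain jitter sd noise_sd/sqrt(2) gives the
    # requested pairwise noise sd.
    c0 <- (100 - spec$intercept - 100 * spec$slope) / 100
    free_p <- setdiff(seq_len(Lp), protected)
    # shrink the 16S divergence range until the protein substitution
    # budget fits the disjoint-assignment constraint
    dn_max <- 0.068
    repeat {
      dn <- seq(0, dn_max, length.out = n)
      dp0 <- c0 / 2 + spec$slope * dn
      if (sum(round(dp0 * Lp)) <= length(free_p) - 3L * n || dn_max < 1e-4)
        break
      dn_max <- dn_max * 0.9
    }
    kn <- round(dn * Ln)
    if (sum(kn) > Ln) stop("16S divergence budget exceeded")
    # protein counts follow the line evaluated at the *realized* 16S
    # divergence; randomized rounding keeps the count quantization
    # unbiased instead of tilting the fitted slope
    dp <- c0 / 2 + spec$slope * (kn / Ln) +
      stats::rnorm(n, 0, spec$noise_sd / (100 * sqrt(2)))
    dp <- pmin(pmax(dp, 0), 0.6)
    v <- dp * Lp
    kp <- floor(v) + stats::rbinom(n, 1L, v - floor(v))
    perm_p <- sample(free_p)
    perm_n <- sample(Ln)
    mutate_at <- function(seq_chars, pos, choices) {
      seq_chars[pos] <- vapply(seq_chars[pos], function(b)
        sample(setdiff(choices, b), 1), "")
      paste(seq_chars, collapse = "")
    }
    prot_chars <- strsplit(prot, "")[[1]]
    s16_chars <- strsplit(anchor_16s, "")[[1]]
    proteins <- character(n)
    s16 <- character(n)
    off_p <- 0L; off_n <- 0L
    for (i in seq_len(n)) {
      pos_p <- if (kp[i] > 0) {
        if (off_p + kp[i] <= length(perm_p)) {
          perm_p[(off_p + 1L):(off_p + kp[i])]
        } else sample(free_p, kp[i])  # budget overflow: allow collisions
      } else integer(0)
      off_p <- min(off_p + kp[i], length(perm_p))
      pos_n <- if (kn[i] > 0) perm_n[(off_n + 1L):(off_n + kn[i])] else integer(0)
      off_n <- off_n + kn[i]
      proteins[i] <- mutate_at(prot_chars, pos_p, aa)
      s16[i] <- mutate_at(s16_chars, pos_n, DNA_BASES)
    }
  })
  out <- data.frame(strain_id = sprintf("strain%02d", seq_len(n)),
                    protein = proteins, s16 = s16, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(slope = spec$slope, intercept = spec$intercept,
                             noise_sd = spec$noise_sd)
  class(out) <- c("strain_set", "data.frame")
  out
}
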