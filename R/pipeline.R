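# Pipeline orchestration: simulate (or ingest) -> demultiplex/QC ->
# ORF screen -> region extraction and OTU clustering -> per-site
# diversity -> community structure, with a manifest whose counts
# reconcile at every stage. Fixed seeds make reruns bit-identical.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with their survey defaults
#' (minimum length 200 bp, maximum homopolymer 8, mean quality 20,
#' species/genus/family clustering distances 0.04/0.14/0.28,
#' cosmopolitan occupancy >= 10 sites, 20 NMDS starts).
#'
#' @param spec [community_spec()] used when reads are simulated.
#' @param error [error_model()] used when reads are simulated.
#' @param references Reference OTU proteins for the simulator.
#' @param reads,barcode_map Optional pre-existing reads (data frame or
#'   FASTQ path) and barcode map; when given, the simulator is skipped.
#' @param qc [qc_params()].
#' @param panel,anchor Reference panel and anchor for screening.
#' @param species_threshold Clustering distance for species-level OTUs,
#'   or `"calibrate"` to derive it from `strains`.
#' @param strains Optional strain set for threshold calibration.
#' @param linkage Clustering linkage.
#' @param min_sites_cosmopolitan Occupancy rule for cosmopolitan OTUs.
#' @param nmds_starts NMDS random starts.
#' @param subsample_depth Depth for the rarefied richness column
#'   (`NULL` = smallest site total).
#' @param seed Master seed for the seeded stages.
#' @param outdir Optional directory for stage outputs (TSV/FASTA/Newick);
#'   when set, the manifest carries md5 checksums of every file written.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = community_spec(),
                            error = error_model(),
                            references = NULL,
                            reads = NULL, barcode_map = NULL,
                            qc = qc_params(),
                            panel = synthetic_panel(),
                            anchor = default_anchor(),
                            species_threshold = 0.04,
                            strains = NULL,
                            linkage = "furthest",
                            min_sites_cosmopolitan = 10L,
                            nmds_starts = 20L,
                            subsample_depth = NULL,
                            seed = 1L,
                            outdir = NULL) {
  structure(list(spec = spec, error = error, references = references,
                 reads = reads, barcode_map = barcode_map, qc = qc,
                 panel = panel, anchor = anchor,
                 species_threshold = species_threshold, strains = strains,
                 linkage = linkage,
                 min_sites_cosmopolitan = min_sites_cosmopolitan,
                 nmds_starts = nmds_starts,
                 subsample_depth = subsample_depth,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Run the full MasD diversity pipeline
#'
#' Executes the stages in order, keeping a ledger at each stage so that
#' raw read counts reconcile (`raw = pass + rejects` everywhere). A rerun
#' with the same configuration and seeds reproduces identical results
#' (and identical file checksums when `outdir` is set).
#'
#' @param config A [pipeline_config()].
#' @return List of class `masd_pipeline` with `manifest` (per-stage
#'   counts, parameters, checksums), `dataset`, `qc`, `screen`,
#'   `otu_table`, `diversity`, `occupancy` and (for >= 3 sites)
#'   `community`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(stages = list())

  # stage 1: reads
  dataset <- NULL
  if (is.null(config$reads)) {
    refs <- config$references %||% masd_reference_set(config$spec$n_otus)
    dataset <- generate_dataset(config$spec, config$error, refs)
    reads <- dataset$reads
    barcode_map <- dataset$barcode_map
  } else {
    reads <- if (is.character(config$reads)) read_fastq(config$reads)
             else config$reads
    barcode_map <- if (is.character(config$barcode_map))
      read_barcode_map(config$barcode_map) else config$barcode_map
  }
  manifest$stages$input <- list(reads = nrow(reads))

  # stage 2: demultiplex + QC (simulated reads carry a site label but
  # still start with their barcode, so demultiplex whenever a map exists)
  if (!is.null(barcode_map))
    reads <- demultiplex_reads(reads, barcode_map)
  qc <- filter_reads(reads, config$qc)
  if (sum(qc$counts) != nrow(reads))
    stop("QC ledger does not reconcile")
  manifest$stages$qc <- as.list(qc$counts)

  # stage 3: ORF screen
  scr <- screen_reads(qc$reads, config$panel, config$anchor)
  if (sum(scr$counts) != nrow(qc$reads))
    stop("screen ledger does not reconcile")
  manifest$stages$screen <- as.list(scr$counts)

  # stage 4: threshold, region, clustering
  threshold <- config$species_threshold
  calibration <- NULL
  if (identical(threshold, "calibrate")) {
    if (is.null(config$strains))
      stop("species_threshold = 'calibrate' needs a strain set")
    calibration <- fit_threshold_model(build_pairs(config$strains))
    threshold <- 1 - map_threshold(calibration, 98.7) / 100
  }
  regions <- extract_region(scr$accepted$protein, config$anchor)
  dm <- otu_distance_matrix(regions, scr$accepted$id)
  assignment <- cluster_otus(dm, threshold, config$linkage)
  table <- build_otu_table(assignment, scr$accepted$site)
  manifest$stages$cluster <- list(
    accepted = nrow(scr$accepted),
    region_dropped = length(attr(regions, "dropped")),
    unique_sequences = nrow(dm$derep),
    otus = ncol(table), threshold = threshold)
  if (sum(table) + length(attr(regions, "dropped")) != nrow(scr$accepted))
    stop("clustering ledger does not reconcile")

  # stage 5: diversity
  div <- diversity_report(table, config$subsample_depth,
                          seed = derive_seed(config$seed, 5L))
  occupancy <- if (nrow(table) >= 2)
    classify_occupancy(table, config$min_sites_cosmopolitan) else NULL
  manifest$stages$diversity <- list(
    sites = nrow(table), total_reads = sum(table),
    subsample_depth = attr(div, "subsample_depth"))

  # stage 6: community structure
  community <- NULL
  if (nrow(table) >= 3) {
    bc <- bray_curtis(table)
    community <- list(
      bray_curtis = bc,
      nmds = nmds_ordination(bc, n_starts = config$nmds_starts,
                             seed = derive_seed(config$seed, 6L)),
      ward = ward_cluster(bc),
      cooccurrence = cooccurrence(table),
      network = layout_network(table, seed = derive_seed(config$seed, 7L)))
    manifest$stages$community <- list(
      sites = nrow(bc), nmds_stress = community$nmds$stress)
  }

  out <- structure(list(manifest = manifest, dataset = dataset, qc = qc,
                        screen = scr, calibration = calibration,
                        otu_table = table, diversity = div,
                        occupancy = occupancy, community = community),
                   class = "masd_pipeline")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (!is.null(dataset))
      paths <- c(paths, unlist(write_dataset(dataset,
                                             file.path(config$outdir, "sim"))))
    p <- file.path(config$outdir, "otu_table.tsv")
    write_otu_table(table, p); paths <- c(paths, p)
    p <- file.path(config$outdir, "diversity.tsv")
    utils::write.table(div, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(community)) {
      p <- file.path(config$outdir, "ward.nwk")
      write_dendrogram_newick(community$ward, p); paths <- c(paths, p)
      p <- file.path(config$outdir, "nmds.tsv")
      utils::write.table(data.frame(site = rownames(community$nmds$points),
                                    community$nmds$points),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    out$manifest$checksums <- tools::md5sum(paths)
  }
  out
}

#' @export
print.masd_pipeline <- function(x, ...) {
  m <- x$manifest$stages
  cat("MasD diversity pipeline\n")
  cat("  reads in:        ", m$input$reads, "\n")
  cat("  QC pass:         ", m$qc$pass, "\n")
  cat("  MasD accepted:   ", m$screen$pass, "\n")
  cat("  OTUs (species):  ", m$cluster$otus,
      sprintf(" (threshold %.2f)", m$cluster$threshold), "\n")
  if (!is.null(m$community))
    cat("  NMDS stress:     ", sprintf("%.4f", m$community$nmds_stress), "\n")
  invisible(x)
}
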