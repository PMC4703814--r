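# Per-site diversity statistics: single-sequence OTU (SSO) taxonomy,
# Good's coverage, inverse Simpson, closed-form rarefaction, seeded
# subsampling, and occupancy classification.

check_otu_table <- function(table) {
  if (!is.matrix(table) || is.null(rownames(table)))
    stop("'table' must be a sites x OTUs matrix with site rownames")
  if (any(table < 0) || any(table != round(table)))
    stop("'table' must hold non-negative integer counts")
  invisible(table)
}

#' Count single-sequence OTUs at a site
#'
#' An absolute single-sequence OTU (SSO_abs) has exactly one read at this
#' site and none elsewhere (permanently rare); a relative SSO (SSO_rel)
#' has one read here but more at other sites (conditionally rare).
#'
#' @param table Sites x OTUs count matrix.
#' @param site Site name.
#' @return Named integer vector `c(sso_abs, sso_rel)`.
#' @export
count_sso <- function(table, site) {
  check_otu_table(table)
  if (!site %in% rownames(table)) stop("unknown site: ", site)
  here <- table[site, ]
  elsewhere <- colSums(table) - here
  c(sso_abs = sum(here == 1L & elsewhere == 0L),
    sso_rel = sum(here == 1L & elsewhere >= 1L))
}

#' Good's coverage
#'
#' `C = (1 - n/N) * 100`, with `n` the number of singletons
#' (SSO_abs + SSO_rel) and `N` the number of sequences analysed.
#'
#' @param N Total reads at the site (> 0).
#' @param n_singletons Singleton count (0 <= n <= N).
#' @param digits Rounding of the reported percentage (default integer).
#' @return Coverage percentage.
#' @examples
#' goods_coverage(430, 46)  # 89
#' @export
goods_coverage <- function(N, n_singletons, digits = 0) {
  if (any(N <= 0)) stop("N must be > 0")
  if (any(n_singletons < 0) || any(n_singletons > N))
    stop("n_singletons must lie in [0, N]")
  round((1 - n_singletons / N) * 100, digits)
}

#' Inverse Simpson diversity index
#'
#' Default plug-in form `1 / sum(p_i^2)` (bounded by \[1, S\]); the
#' small-sample (unbiased) form `1 / (sum n_i (n_i - 1) / (N (N - 1)))`
#' is available as `method = "unbiased"` and is undefined (NA) for a
#' site with a single read.
#'
#' @param counts Per-OTU read counts at one site.
#' @param method `"plugin"` or `"unbiased"`.
#' @return The inverse Simpson index 1/D.
#' @export
inverse_simpson <- function(counts, method = c("plugin", "unbiased")) {
  method <- match.arg(method)
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N <= 0) stop("total count must be > 0")
  if (method == "plugin") {
    1 / sum((counts / N)^2)
  } else {
    if (N < 2) return(NA_real_)
    D <- sum(counts * (counts - 1)) / (N * (N - 1))
    if (D == 0) NA_real_ else 1 / D
  }
}

#' Closed-form rarefaction curve
#'
#' Hypergeometric expectation of richness at depth m:
#' `E[S_m] = S - sum_i C(N - n_i, m) / C(N, m)`, computed in log space.
#'
#' @param counts Per-OTU read counts.
#' @param depths Subsampling depths (each <= sum(counts)).
#' @return Numeric vector of expected richness, one per depth.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths > N)) stop("depth exceeds total count")
  if (any(depths < 0)) stop("depths must be >= 0")
  S <- length(counts)
  vapply(depths, function(m) {
    S - sum(exp(lchoose(N - counts, m) - lchoose(N, m)))
  }, 0)
}

#' Rarefy an OTU table to a common depth
#'
#' Per site, draws `depth` reads without replacement (seeded); OTUs with
#' zero post-draw count contribute nothing to that site's richness.
#'
#' @param table Sites x OTUs count matrix.
#' @param depth Common depth; defaults to the smallest site total.
#' @param seed Integer seed.
#' @return Rarefied count matrix of the same shape.
#' @export
subsample_table <- function(table, depth = NULL, seed = 1L) {
  check_otu_table(table)
  totals <- rowSums(table)
  depth <- depth %||% min(totals)
  bad <- totals < depth
  if (any(bad))
    stop("subsampling depth ", depth, " exceeds the read count of site(s): ",
         paste(rownames(table)[bad], collapse = ", "))
  out <- table * 0L
  with_seed(seed, {
    for (s in rownames(table)) {
      pool <- rep(seq_len(ncol(table)), table[s, ])
      draw <- if (length(pool) == depth) pool else sample(pool, depth)
      cnt <- tabulate(draw, nbins = ncol(table))
      out[s, ] <- as.integer(cnt)
    }
  })
  out
}

#' Classify OTUs by site occupancy
#'
#' Occupancy is the number of sites where an OTU is present; OTUs at
#' `min_sites_cosmopolitan` or more sites are cosmopolitan, OTUs at
#' exactly one site are locally restricted, the rest intermediate.
#'
#' @param table Sites x OTUs count matrix (>= 2 sites).
#' @param min_sites_cosmopolitan Occupancy needed for the cosmopolitan
#'   class (default 10, for a 12-site survey).
#' @return Factor (one level per OTU) with attribute `occupancy`.
#' @export
classify_occupancy <- function(table, min_sites_cosmopolitan = 10L) {
  check_otu_table(table)
  if (nrow(table) < 2) stop("need at least 2 sites")
  occ <- colSums(table > 0)
  cls <- ifelse(occ >= min_sites_cosmopolitan, "cosmopolitan",
                ifelse(occ == 1L, "locally_restricted", "intermediate"))
  out <- factor(cls, levels = c("cosmopolitan", "intermediate",
                                "locally_restricted"))
  names(out) <- colnames(table)
  attr(out, "occupancy") <- occ
  out
}

#' Per-site diversity report
#'
#' Assembles reads analysed (N), observed richness, SSO counts, Good's
#' coverage (with n = SSO_abs + SSO_rel), inverse Simpson, and richness
#' after subsampling to a common depth.
#'
#' @param table Sites x OTUs count matrix.
#' @param site Site name.
#' @param subsample_depth Common subsampling depth (defaults to the
#'   smallest site total); `NA` skips the subsampled column.
#' @param seed Seed for the subsampling draw.
#' @param simpson_method Passed to [inverse_simpson()].
#' @return One-row data frame with columns `site`, `N`, `S_obs`,
#'   `sso_abs`, `sso_rel`, `coverage`, `inv_simpson`, `S_subsampled`.
#' @export
site_report <- function(table, site, subsample_depth = NULL, seed = 1L,
                        simpson_method = "plugin") {
  check_otu_table(table)
  counts <- table[site, ]
  sso <- count_sso(table, site)
  N <- sum(counts)
  depth <- subsample_depth %||% min(rowSums(table))
  S_sub <- if (is.na(depth)) NA_integer_ else {
    sub <- subsample_table(table, depth, seed)
    sum(sub[site, ] > 0)
  }
  data.frame(site = site, N = N, S_obs = sum(counts > 0),
             sso_abs = unname(sso["sso_abs"]),
             sso_rel = unname(sso["sso_rel"]),
             coverage = goods_coverage(N, sum(sso)),
             inv_simpson = inverse_simpson(counts, simpson_method),
             S_subsampled = S_sub,
             stringsAsFactors = FALSE)
}

#' Diversity report for all sites
#'
#' @inheritParams site_report
#' @return Data frame with one [site_report()] row per site; the
#'   subsampling draw is shared across rows (single rarefied table).
#' @export
diversity_report <- function(table, subsample_depth = NULL, seed = 1L,
                             simpson_method = "plugin") {
  check_otu_table(table)
  depth <- subsample_depth %||% min(rowSums(table))
  sub <- subsample_table(table, depth, seed)
  out <- do.call(rbind, lapply(rownames(table), function(s)
    site_report(table, s, subsample_depth = NA, seed = seed,
                simpson_method = simpson_method)))
  out$S_subsampled <- rowSums(sub > 0)[out$site]
  attr(out, "subsample_depth") <- depth
  out
}

#' Published seep-site survey statistics
#'
#' Per-site summary statistics of the original 12-site MasD seep survey
#' (raw and quality read counts, observed species-level OTU richness,
#' relative/absolute SSO percentages, Good's coverage, subsampled
#' richness and inverse Simpson), shipped as plain TSV. Useful for
#' consistency checks of the coverage arithmetic and the subsampled
#' diversity spread.
#'
#' @return Data frame with columns `site`, `raw_reads`, `quality_reads`,
#'   `otu96`, `sso_rel_pct`, `sso_abs_pct`, `coverage_pct`,
#'   `otu96_subsampled`, `inv_simpson`.
#' @export
seep_survey_stats <- function() {
  path <- system.file("extdata", "seep_site_stats.tsv", package = "masdiv",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
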