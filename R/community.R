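# Between-site community structure: Bray-Curtis dissimilarity, non-metric
# multidimensional scaling (best of n seeded starts), Ward hierarchical
# clustering, shared-OTU fractions, co-occurrence counts, and a
# force-directed layout of the presence-absence bipartite network.

#' Bray-Curtis dissimilarity between sites
#'
#' `d(a, b) = 1 - 2 * sum(min(x_a, x_b)) / (sum(x_a) + sum(x_b))`.
#'
#' @param table Sites x OTUs count matrix (>= 2 sites, no all-zero site).
#' @return Symmetric site x site distance matrix in \[0, 1\].
#' @export
bray_curtis <- function(table) {
  check_otu_table(table)
  if (nrow(table) < 2) stop("need at least 2 sites")
  if (any(rowSums(table) == 0)) stop("all-zero site in table")
  as.matrix(vegan::vegdist(table, method = "bray"))
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS (monotone-regression engine), run from
#' `n_starts` seeded initializations (the first start is the metric
#' scaling solution, the rest random); the lowest-stress configuration is
#' returned, centred at the origin. Orientation is arbitrary (rotation /
#' reflection indeterminacy). More starts can only lower the reported
#' stress.
#'
#' @param dm Square distance matrix or `dist` over >= 3 sites.
#' @param k Ordination dimensions (default 2).
#' @param n_starts Number of starts (default 20).
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed.
#' @return Object of class `masd_nmds`: `points` (sites x k), `stress`
#'   (in \[0, 1\]), `n_starts`, `best_start`, `converged`.
#' @export
nmds_ordination <- function(dm, k = 2, n_starts = 20, max_iter = 200,
                            seed = 42L) {
  d <- stats::as.dist(as_square_dist(dm))
  n <- attr(d, "Size")
  if (n < 3) stop("need at least 3 sites")
  with_seed(seed, {
    init0 <- tryCatch(stats::cmdscale(d, k = k), error = function(e) NULL)
    if (is.null(init0) || ncol(init0) < k) {
      init0 <- matrix(stats::rnorm(n * k), n, k)
    }
    best <- NULL
    best_start <- NA_integer_
    for (s in seq_len(n_starts)) {
      init <- if (s == 1) init0 else matrix(stats::runif(n * k, -1, 1), n, k)
      fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                            maxit = max_iter)
      if (is.null(best) || fit$stress < best$stress) {
        best <- fit
        best_start <- s
      }
    }
  })
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  rownames(pts) <- labels(d)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts[, , drop = FALSE], stress = best$stress,
                 n_starts = n_starts, best_start = best_start,
                 converged = best$maxits >= best$iters),
            class = "masd_nmds")
}

#' @export
print.masd_nmds <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d sites, stress = %.4f (best of %d starts)\n",
              nrow(x$points), x$stress, x$n_starts))
  invisible(x)
}

#' Ward hierarchical clustering of sites
#'
#' Agglomerative clustering with the Ward criterion (default `ward.D2`,
#' i.e. squared input dissimilarities, the convention that minimizes
#' total within-cluster variance; `ward.D` available as a switch).
#' Accepts either a Bray-Curtis matrix or a co-occurrence-derived
#' distance.
#'
#' @param dm Square distance matrix or `dist`.
#' @param method `"ward.D2"` or `"ward.D"`.
#' @return An `hclust` object.
#' @export
ward_cluster <- function(dm, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  stats::hclust(stats::as.dist(as_square_dist(dm)), method = method)
}

#' Write a dendrogram as Newick with branch heights
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Percentage of OTUs shared between two sites
#'
#' `100 * |present at both| / |present at either|` (Jaccard convention);
#' `denominator = "min"` uses the smaller site richness instead.
#'
#' @param table Sites x OTUs count matrix.
#' @param site_a,site_b Distinct site names.
#' @param denominator `"union"` (Jaccard) or `"min"`.
#' @return Percentage, or `NA` when both sites are empty.
#' @export
shared_fraction <- function(table, site_a, site_b,
                            denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  check_otu_table(table)
  if (identical(site_a, site_b)) stop("sites must be distinct")
  a <- table[site_a, ] > 0
  b <- table[site_b, ] > 0
  den <- if (denominator == "union") sum(a | b) else min(sum(a), sum(b))
  if (den == 0) return(NA_real_)
  100 * sum(a & b) / den
}

#' Site x site co-occurrence counts
#'
#' Entry (a, b) is the number of OTUs present at both sites; the diagonal
#' is per-site richness.
#'
#' @param table Sites x OTUs count matrix (>= 2 sites).
#' @return Symmetric integer matrix.
#' @export
cooccurrence <- function(table) {
  check_otu_table(table)
  if (nrow(table) < 2) stop("need at least 2 sites")
  P <- (table > 0) * 1L
  M <- P %*% t(P)
  storage.mode(M) <- "integer"
  M
}

#' Force-directed layout of the presence-absence network
#'
#' Builds the bipartite graph with site nodes and OTU nodes (an edge iff
#' the OTU is present at the site) and lays it out with seeded
#' Fruchterman-Reingold iterations; sites sharing many OTUs are pulled
#' together through their shared OTU nodes.
#'
#' @param table Sites x OTUs count matrix.
#' @param iterations Layout iterations.
#' @param seed Integer seed.
#' @return List of class `masd_network`: `graph` (igraph), `coords`
#'   (data frame: node, type, x, y), `iterations`, `seed`.
#' @export
layout_network <- function(table, iterations = 500L, seed = 7L) {
  check_otu_table(table)
  P <- table > 0
  g <- igraph::graph_from_biadjacency_matrix(P)
  coords <- with_seed(seed, igraph::layout_with_fr(g, niter = iterations))
  df <- data.frame(node = igraph::V(g)$name,
                   type = ifelse(igraph::V(g)$type, "otu", "site"),
                   x = coords[, 1], y = coords[, 2],
                   stringsAsFactors = FALSE)
  structure(list(graph = g, coords = df, iterations = iterations,
                 seed = seed), class = "masd_network")
}

#' @export
print.masd_network <- function(x, ...) {
  cat("Presence-absence network:",
      sum(x$coords$type == "site"), "sites,",
      sum(x$coords$type == "otu"), "OTUs,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}
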