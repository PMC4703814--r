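# Independent brute-force oracles used to cross-check the package
# implementations, plus small fixture builders. Everything here is
# deliberately naive and kept separate from the code paths it checks.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
random_aa <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV",
                                               "")[[1]], n, TRUE),
                               collapse = "")

# O(n^2) scan for the longest homopolymer run
oracle_max_homopolymer <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  best <- 1L
  for (i in seq_along(ch)) {
    j <- i
    while (j < length(ch) && ch[j + 1] == ch[i]) j <- j + 1L
    best <- max(best, j - i + 1L)
  }
  best
}

# two-pass closed-form OLS
oracle_ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(intercept = my - slope * mx, slope = slope)
}

# naive agglomerative clustering at a distance threshold; clusters as a
# membership vector (arbitrary labels)
oracle_agglomerative <- function(d, threshold, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  link <- function(a, b) {
    v <- d[a, b, drop = FALSE]
    switch(linkage, furthest = max(v), average = mean(v), nearest = min(v))
  }
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dv <- link(clusters[[i]], clusters[[j]])
        if (dv < bestd) { bestd <- dv; best <- c(i, j) }
      }
    }
    if (bestd > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# partitions equal up to relabeling
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# naive Ward (ward.D2 convention): Lance-Williams on squared
# dissimilarities; returns sorted merge heights
oracle_ward_heights <- function(d) {
  d2 <- d^2
  n <- nrow(d2)
  active <- seq_len(n)
  size <- rep(1, n)
  heights <- numeric(0)
  repeat {
    if (length(active) == 1) break
    bestd <- Inf; best <- c(NA, NA)
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < bestd) { bestd <- d2[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestd))
    for (k in setdiff(active, c(i, j))) {
      v <- ((size[i] + size[k]) * d2[i, k] + (size[j] + size[k]) * d2[j, k] -
              size[k] * d2[i, j]) / (size[i] + size[j] + size[k])
      d2[i, k] <- d2[k, i] <- v
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

# Monte-Carlo rarefaction: mean and SE of richness at depth m
oracle_rarefaction_mc <- function(counts, m, draws = 2000) {
  pool <- rep(seq_along(counts), counts)
  s <- replicate(draws, length(unique(sample(pool, m))))
  c(mean = mean(s), se = stats::sd(s) / sqrt(draws))
}

oracle_bray <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# random symmetric distance matrix in [0,1] with zero diagonal
random_dist_matrix <- function(n) {
  d <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# small random OTU table
random_otu_table <- function(n_sites, n_otus, lambda = 2) {
  m <- matrix(stats::rpois(n_sites * n_otus, lambda), n_sites, n_otus,
              dimnames = list(sprintf("S%02d", 1:n_sites),
                              paste0("OTU", 1:n_otus)))
  m[rowSums(m) == 0, 1] <- 1L
  storage.mode(m) <- "integer"
  m
}

# a small clean simulated dataset shared by several tests
clean_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- community_spec(n_sites = 3, n_otus = 10, reads_per_site = 60,
                             abundance_model = "uniform",
                             cosmopolitan_fraction = 1, seed = 42)
      cache <<- list(spec = spec,
                     ds = generate_dataset(spec, error_model_clean(),
                                           masd_reference_set(10)))
    }
    cache
  }
})
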