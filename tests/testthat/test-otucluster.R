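# Region extraction, distance matrices, threshold clustering and the
# site x OTU table.

test_that("region extraction returns anchor-column residues", {
  a <- default_anchor()
  reg <- extract_region(a$protein, a)
  expect_equal(reg[1], substr(a$protein, a$region[1], a$region[2]))

  # an internal 3-residue deletion inside the region shortens it by 3
  del_at <- a$region[1] + 40
  deleted <- paste0(substr(a$protein, 1, del_at - 1),
                    substr(a$protein, del_at + 3, nchar(a$protein)))
  reg2 <- extract_region(deleted, a)
  expect_equal(nchar(reg2[1]), (a$region[2] - a$region[1] + 1) - 3)

  # a cleanly simulated protein carries exactly its reference's region
  refs <- masd_reference_set(5)
  reg3 <- extract_region(unname(refs), a)
  expect_equal(unname(reg3[3]), substr(refs[[3]], a$region[1], a$region[2]))

  # fragments covering too little of the region are dropped and logged
  frag <- substr(a$protein, 1, a$region[1] + 49)  # 50 of 120 columns
  reg4 <- extract_region(c(a$protein, frag), a)
  expect_true(is.na(reg4[2]))
  expect_equal(attr(reg4, "dropped"), 2L)
})

test_that("distance matrix dereplicates and matches direct recomputation", {
  set.seed(131)
  base <- random_aa(100)
  ch <- strsplit(base, "")[[1]]
  pos <- sample(100, 4)
  for (i in pos) ch[i] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV",
                                                  "")[[1]], ch[i]), 1)
  variant <- paste(ch, collapse = "")
  dm <- otu_distance_matrix(c(base, variant, base))
  expect_equal(nrow(dm$d), 2)  # duplicates collapse
  expect_equal(unname(dm$d[1, 2]), 0.04, tolerance = 1e-9)
  expect_equal(dm$map, c(1L, 2L, 1L))

  seqs <- vapply(1:8, function(i) random_aa(60), "")
  dm2 <- otu_distance_matrix(seqs)
  expect_equal(dm2$d, t(dm2$d))
  expect_true(all(diag(dm2$d) == 0))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(unname(dm2$d[i, j]),
                 1 - pairwise_identity(seqs[i], seqs[j]) / 100,
                 tolerance = 1e-9)
})

test_that("threshold clustering matches a naive agglomerative oracle", {
  # degenerate thresholds
  d <- random_dist_matrix(6)
  expect_equal(length(unique(cluster_otus(d, 0))), 6)
  expect_equal(length(unique(cluster_otus(d, 1))), 1)

  set.seed(141)
  for (rep in 1:5) {
    d <- random_dist_matrix(10)
    for (lk in c("furthest", "average", "nearest")) {
      got <- cluster_otus(d, threshold = 0.5, linkage = lk)
      want <- oracle_agglomerative(d, 0.5, lk)
      expect_true(same_partition(unname(got), want),
                  info = paste(lk, "rep", rep))
    }
  }
})

test_that("clustering is monotone in threshold and ordered across linkages", {
  set.seed(151)
  for (rep in 1:3) {
    d <- random_dist_matrix(12)
    n_at <- vapply(c(0.1, 0.3, 0.5, 0.7),
                   function(h) length(unique(cluster_otus(d, h))), 0)
    expect_true(all(diff(n_at) <= 0))
    counts <- vapply(c("nearest", "average", "furthest"),
                     function(lk) length(unique(cluster_otus(d, 0.4, lk))), 0)
    expect_true(counts[["nearest"]] <= counts[["average"]])
    expect_true(counts[["average"]] <= counts[["furthest"]])
  }
})

test_that("the partition is invariant to input order", {
  set.seed(161)
  seqs <- unname(masd_reference_set(8))
  dm <- otu_distance_matrix(seqs)
  base <- cluster_otus(dm, 0.1)
  perm <- sample(8)
  dm_p <- otu_distance_matrix(seqs[perm])
  got <- cluster_otus(dm_p, 0.1)
  expect_true(same_partition(unname(base)[perm], unname(got)))
})

test_that("the OTU table accumulates multiplicities and orders by abundance", {
  tab <- build_otu_table(c(1L, 1L, 1L), rep("siteA", 3))
  expect_equal(dim(tab), c(1L, 1L))
  expect_equal(unname(tab[1, 1]), 3L)

  asg <- c(1L, 1L, 2L, 2L, 2L, 3L, NA)
  sites <- c("A", "A", "A", "B", "B", "B", "B")
  tab2 <- build_otu_table(asg, sites)
  # OTU1 is the most abundant overall
  expect_equal(colnames(tab2), c("OTU1", "OTU2", "OTU3"))
  expect_equal(unname(colSums(tab2)), c(3L, 2L, 1L))
  # row sums equal per-site assigned (non-dropped) read counts
  expect_equal(unname(rowSums(tab2)), c(3L, 3L))

  # zero-error simulation: table equals the truth aggregation
  sim <- clean_sim()
  qc <- filter_reads(demultiplex_reads(sim$ds$reads, sim$ds$barcode_map))
  scr <- screen_reads(qc$reads)
  reg <- extract_region(scr$accepted$protein)
  asg2 <- cluster_otus(otu_distance_matrix(reg, scr$accepted$id), 0.04)
  tab3 <- build_otu_table(asg2, scr$accepted$site)
  truth_tab <- table(sim$ds$truth$site, sim$ds$truth$otu)
  expect_equal(ncol(tab3), length(unique(sim$ds$truth$otu)))
  expect_equal(sort(as.integer(colSums(tab3))),
               sort(as.integer(colSums(truth_tab))))
  expect_equal(unname(rowSums(tab3)), unname(as.integer(rowSums(truth_tab))))
})
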