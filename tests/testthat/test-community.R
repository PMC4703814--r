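# Bray-Curtis, NMDS, Ward clustering, shared OTUs, co-occurrence and the
# presence-absence network layout.

test_that("Bray-Curtis follows the definition with bounds and symmetry", {
  tab <- rbind(A = c(3L, 1L, 0L), B = c(1L, 1L, 2L))
  colnames(tab) <- paste0("OTU", 1:3)
  d <- bray_curtis(tab)
  # shared minima 1 + 1 + 0 = 2 over totals 4 + 4
  expect_equal(unname(d["A", "B"]), 1 - 2 * 2 / 8, tolerance = 1e-9)

  same <- rbind(A = c(2L, 3L), B = c(2L, 3L))
  colnames(same) <- c("OTU1", "OTU2")
  expect_equal(unname(bray_curtis(same)["A", "B"]), 0)

  disj <- rbind(A = c(4L, 0L), B = c(0L, 7L))
  colnames(disj) <- c("OTU1", "OTU2")
  expect_equal(unname(bray_curtis(disj)["A", "B"]), 1)

  set.seed(231)
  for (i in 1:50) {
    tab <- random_otu_table(4, 12)
    d <- bray_curtis(tab)
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(unname(d[2, 4]), oracle_bray(tab[2, ], tab[4, ]),
                 tolerance = 1e-9)
  }
  allzero <- rbind(A = c(1L, 0L), B = c(0L, 0L))
  colnames(allzero) <- c("OTU1", "OTU2")
  expect_error(bray_curtis(allzero), "all-zero")
})

test_that("NMDS embeds planar data with near-zero stress, reproducibly", {
  set.seed(241)
  xy <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(xy))
  dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
  ord <- nmds_ordination(d, n_starts = 5, seed = 17)
  expect_lt(ord$stress, 0.01)
  expect_equal(unname(colMeans(ord$points)), c(0, 0), tolerance = 1e-8)

  ord2 <- nmds_ordination(d, n_starts = 5, seed = 17)
  expect_identical(ord$points, ord2$points)

  # best-of-n starts: stress cannot increase with more starts
  s1 <- nmds_ordination(d, n_starts = 1, seed = 17)$stress
  s5 <- nmds_ordination(d, n_starts = 5, seed = 17)$stress
  s10 <- nmds_ordination(d, n_starts = 10, seed = 17)$stress
  expect_gte(s1, s5)
  expect_gte(s5, s10)
})

test_that("Ward clustering matches a Lance-Williams oracle", {
  # two tight triplets: the first merges happen within the triplets
  centers <- rbind(c(0, 0), c(10, 10))
  set.seed(251)
  pts <- rbind(centers[1, ] + matrix(rnorm(6, sd = 0.1), 3, 2),
               centers[2, ] + matrix(rnorm(6, sd = 0.1), 3, 2))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  hc <- ward_cluster(d)
  first_two <- hc$merge[1:2, ]
  expect_true(all(abs(first_two) %in% 1:6))
  grp <- cutree(hc, k = 2)
  expect_equal(length(unique(grp[1:3])), 1L)
  expect_equal(length(unique(grp[4:6])), 1L)
  # heights non-decreasing
  expect_true(all(diff(hc$height) >= -1e-12))

  for (rep in 1:3) {
    d <- random_dist_matrix(6)
    hc <- ward_cluster(d)
    expect_equal(hc$height, oracle_ward_heights(d), tolerance = 1e-9)
  }
})

test_that("shared-OTU fractions follow the Jaccard convention", {
  tab <- rbind(A = c(1L, 1L, 1L, 0L), B = c(0L, 1L, 1L, 1L),
               C = c(1L, 1L, 1L, 0L), D = c(0L, 0L, 0L, 1L))
  colnames(tab) <- paste0("OTU", 1:4)
  expect_equal(shared_fraction(tab, "A", "B"), 50)  # 2 of 4
  expect_equal(shared_fraction(tab, "A", "C"), 100)
  expect_equal(shared_fraction(tab, "A", "D"), 0)
  expect_equal(shared_fraction(tab, "A", "B"),
               shared_fraction(tab, "B", "A"))
  expect_equal(shared_fraction(tab, "A", "B", denominator = "min"),
               100 * 2 / 3)
  expect_error(shared_fraction(tab, "A", "A"), "distinct")
})

test_that("co-occurrence counts equal brute-force set intersections", {
  set.seed(261)
  tab <- random_otu_table(6, 40, lambda = 0.4)
  M <- cooccurrence(tab)
  expect_equal(unname(diag(M)), unname(rowSums(tab > 0)))
  for (a in 1:5) for (b in (a + 1):6)
    expect_equal(M[a, b], sum(tab[a, ] > 0 & tab[b, ] > 0))

  disj <- rbind(A = c(1L, 1L, 0L, 0L), B = c(0L, 0L, 1L, 1L))
  colnames(disj) <- paste0("OTU", 1:4)
  expect_true(all(cooccurrence(disj)[1, 2] == 0))
})

test_that("the network layout is seeded and respects the edge rule", {
  tab <- rbind(A = c(1L, 1L, 0L), B = c(1L, 0L, 1L), C = c(0L, 0L, 1L))
  colnames(tab) <- paste0("OTU", 1:3)
  net1 <- layout_network(tab, iterations = 100, seed = 3)
  net2 <- layout_network(tab, iterations = 100, seed = 3)
  expect_identical(net1$coords, net2$coords)
  # OTU1 present at two sites has degree 2
  deg <- igraph::degree(net1$graph)
  expect_equal(unname(deg[["OTU1"]]), 2)
  expect_equal(unname(deg[["OTU2"]]), 1)

  # sites sharing most OTUs end up closer than sites sharing none
  set.seed(271)
  shared <- matrix(0L, 4, 12,
                   dimnames = list(c("A", "B", "C", "D"), paste0("OTU", 1:12)))
  shared[c("A", "B"), 1:10] <- 1L   # A and B share 10 OTUs
  shared["A", 11] <- 1L
  shared["C", 11] <- 1L             # C touches the rest only via OTU11
  shared["D", 12] <- 1L             # D is isolated from A
  wins <- 0
  for (s in 1:100) {
    net <- layout_network(shared, iterations = 200, seed = s)
    xy <- net$coords[match(c("A", "B", "D"), net$coords$node), c("x", "y")]
    d_ab <- dist(xy[1:2, ])
    d_ad <- dist(xy[c(1, 3), ])
    if (d_ab < d_ad) wins <- wins + 1
  }
  expect_gte(wins, 95)
})
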