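# Singleton taxonomy, coverage, inverse Simpson, rarefaction,
# subsampling and occupancy classes.

test_that("single-sequence OTU taxonomy distinguishes absolute and relative", {
  one_site <- matrix(1L, 1, 5, dimnames = list("A", paste0("OTU", 1:5)))
  expect_equal(unname(count_sso(one_site, "A")), c(5L, 0L))

  two <- matrix(c(1L, 5L, 0L, 2L), 2, 2,
                dimnames = list(c("A", "B"), c("OTU1", "OTU2")))
  # OTU1: one read at A, five at B -> relative SSO at A, nothing at B
  expect_equal(unname(count_sso(two, "A")), c(0L, 1L))
  expect_equal(unname(count_sso(two, "B")), c(0L, 0L))

  # brute-force oracle over a random table
  set.seed(171)
  tab <- random_otu_table(12, 200, lambda = 0.3)
  for (s in sample(rownames(tab), 4)) {
    got <- count_sso(tab, s)
    abs_ <- 0L; rel_ <- 0L
    for (o in seq_len(ncol(tab))) {
      if (tab[s, o] == 1L) {
        if (sum(tab[, o]) == 1L) abs_ <- abs_ + 1L else rel_ <- rel_ + 1L
      }
    }
    expect_equal(unname(got), c(abs_, rel_))
  }
})

test_that("Good's coverage is the exact formula", {
  expect_equal(goods_coverage(430, 46), 89)
  expect_equal(goods_coverage(100, 0), 100)
  expect_equal(goods_coverage(100, 100), 0)
  expect_equal(goods_coverage(154, 40), 74)
  expect_error(goods_coverage(0, 0), "N")
  expect_error(goods_coverage(10, 11), "n_singletons")
  # exact arithmetic over a grid
  for (N in c(7, 65, 989)) {
    n <- 0:N
    expect_equal(goods_coverage(N, n, digits = 6),
                 round((1 - n / N) * 100, 6))
  }
})

test_that("inverse Simpson has the documented forms and bounds", {
  expect_equal(inverse_simpson(rep(10, 7)), 7)
  expect_equal(inverse_simpson(c(9, 1)), 1 / 0.82, tolerance = 1e-4)
  set.seed(181)
  for (i in 1:50) {
    cnt <- rpois(sample(2:30, 1), 3) + 1
    v <- inverse_simpson(cnt)
    expect_gte(v, 1)
    expect_lte(v, length(cnt) + 1e-9)
  }
  # small-sample form: undefined for a single read
  expect_true(is.na(inverse_simpson(1, method = "unbiased")))
  expect_equal(inverse_simpson(c(5, 5), method = "unbiased"),
               1 / (2 * 5 * 4 / (10 * 9)))
})

test_that("closed-form rarefaction matches Monte-Carlo subsampling", {
  counts <- c(50, 30, 10, 5, 3, 1, 1)
  N <- sum(counts)
  expect_equal(rarefaction_curve(counts, N), 7)
  expect_equal(rarefaction_curve(counts, 1), 1)
  expect_error(rarefaction_curve(counts, N + 1), "depth")

  set.seed(191)
  for (m in c(10, 40, 80)) {
    mc <- oracle_rarefaction_mc(counts, m, draws = 4000)
    expect_lt(abs(rarefaction_curve(counts, m) - mc["mean"]), 3 * mc["se"])
  }
})

test_that("subsampling is seeded, bounded and consistent with rarefaction", {
  set.seed(201)
  tab <- random_otu_table(4, 30)
  depth <- min(rowSums(tab))
  s1 <- subsample_table(tab, depth, seed = 5)
  s2 <- subsample_table(tab, depth, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(rowSums(s1) == depth))
  expect_true(all(rowSums(s1 > 0) <= rowSums(tab > 0)))

  # depth equal to a site total reproduces that site's counts
  full <- subsample_table(tab, depth = min(rowSums(tab)), seed = 1)
  smallest <- which.min(rowSums(tab))
  expect_equal(full[smallest, ], tab[smallest, ])

  expect_error(subsample_table(tab, depth = max(rowSums(tab)) + 1), "depth")

  # mean subsampled richness tracks the closed-form expectation
  site <- rownames(tab)[2]
  expectation <- rarefaction_curve(tab[site, ], depth)
  rich <- vapply(1:300, function(s)
    sum(subsample_table(tab, depth, seed = s)[site, ] > 0), 0)
  se <- sd(rich) / sqrt(length(rich))
  expect_lt(abs(mean(rich) - expectation), 4 * se + 1e-6)
})

test_that("occupancy classes partition OTUs and ignore column order", {
  set.seed(211)
  tab <- random_otu_table(12, 50, lambda = 0.15)
  tab[, 1] <- 1L  # everywhere
  cls <- classify_occupancy(tab, min_sites_cosmopolitan = 10)
  occ <- colSums(tab > 0)
  expect_equal(unname(cls[1]), factor("cosmopolitan",
                                      levels = levels(cls)))
  expect_true(all(cls[occ == 1] == "locally_restricted"))
  expect_true(all(cls[occ > 1 & occ < 10] == "intermediate"))
  expect_equal(length(cls), ncol(tab))
  expect_false(anyNA(cls))

  perm <- sample(ncol(tab))
  cls_p <- classify_occupancy(tab[, perm], min_sites_cosmopolitan = 10)
  expect_equal(as.character(cls_p), as.character(cls)[perm])
})

test_that("the per-site report composes the statistics consistently", {
  single <- matrix(100L, 1, 1, dimnames = list("A", "OTU1"))
  rep1 <- site_report(single, "A")
  expect_equal(rep1$S_obs, 1)
  expect_equal(rep1$sso_abs + rep1$sso_rel, 0)
  expect_equal(rep1$coverage, 100)
  expect_equal(rep1$inv_simpson, 1)

  set.seed(221)
  tab <- random_otu_table(5, 40)
  rep_all <- diversity_report(tab, seed = 3)
  expect_equal(nrow(rep_all), 5)
  expect_true(all(rep_all$sso_abs + rep_all$sso_rel <= rep_all$S_obs))
  expect_true(all(rep_all$coverage >= 0 & rep_all$coverage <= 100))
  expect_true(all(rep_all$inv_simpson >= 1 &
                    rep_all$inv_simpson <= rep_all$S_obs + 1e-9))
  expect_true(all(rep_all$S_subsampled <= rep_all$S_obs))
  expect_equal(rep_all$N, unname(rowSums(tab)))
})
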