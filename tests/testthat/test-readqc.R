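# Read quality control: primer matching, homopolymer scan, the fixed
# filter cascade, and the chimera screen.

test_that("primer matching is IUPAC-aware with fewest-mismatch tie-break", {
  primer <- "TCGGACGCGTGCAACGMYCTGA"
  # degenerate positions M (A/C) and Y (C/T) match their expansions
  read <- paste0("TCGGACGCGTGCAACGACCTGA", "GGGAAATTT")
  m <- match_primer(read, primer)
  expect_true(m$matched)
  expect_equal(m$mismatches, 0L)

  # one substitution with zero tolerance fails
  bad <- paste0("ACGGACGCGTGCAACGACCTGA", "GGG")
  expect_false(match_primer(bad, primer, max_mismatch = 0)$matched)
  expect_true(match_primer(bad, primer, max_mismatch = 1)$matched)

  # N matches anything
  expect_equal(match_primer("GATC", "NNNN")$mismatches, 0L)

  # a read shorter than the primer counts every position as a mismatch
  expect_equal(match_primer("TCG", primer)$mismatches, nchar(primer))

  # read ambiguity only matches when covered by primer degeneracy
  expect_equal(match_primer("AM", "AM")$mismatches, 0L)  # M within M
  expect_equal(match_primer("AN", "AM")$mismatches, 1L)  # N not within M
})

test_that("homopolymer run length matches a brute-force scan", {
  expect_equal(max_homopolymer_run("AAAAAAAAAT"), 9L)
  expect_equal(max_homopolymer_run("ACGT"), 1L)
  expect_error(max_homopolymer_run(""), "non-empty")
  set.seed(21)
  for (i in 1:200) {
    s <- random_dna(sample(10:200, 1))
    expect_equal(max_homopolymer_run(s), oracle_max_homopolymer(s))
  }
})

test_that("the filter cascade applies rules in fixed order and conserves the ledger", {
  set.seed(31)
  fwd <- "TCGGACGCGTGCAACGACCTGA"  # concrete instance of the primer
  params <- qc_params(check_chimeras = FALSE)
  good_core <- gsub("[^ACGT]", "A", random_dna(300))
  q40 <- function(n) paste(rep("I", n), collapse = "")  # Phred 40
  q10 <- function(n) paste(rep("+", n), collapse = "")  # Phred 10
  mk <- function(core, qual) data.frame(
    id = "r", sequence = paste0(fwd, core), quality = qual,
    stringsAsFactors = FALSE)

  reads <- rbind(
    data.frame(id = "ok", sequence = paste0(fwd, good_core),
               quality = q40(nchar(fwd) + 300)),
    data.frame(id = "primer", sequence = paste0("AAAA", good_core),
               quality = q40(304)),
    data.frame(id = "short", sequence = paste0(fwd, substr(good_core, 1, 199)),
               quality = q40(nchar(fwd) + 199)),
    data.frame(id = "homop",
               sequence = paste0(fwd, substr(good_core, 1, 150),
                                 "CCCCCCCCC", substr(good_core, 1, 150)),
               quality = q40(nchar(fwd) + 309)),
    data.frame(id = "lowq", sequence = paste0(fwd, good_core),
               quality = q10(nchar(fwd) + 300)),
    data.frame(id = "ambig",
               sequence = paste0(fwd, substr(good_core, 1, 150), "N",
                                 substr(good_core, 1, 150)),
               quality = q40(nchar(fwd) + 301)),
    data.frame(id = "noqual", sequence = paste0(fwd, good_core),
               quality = NA_character_))
  res <- filter_reads(reads, params, primers = fwd, reverse_primer = NULL)
  v <- setNames(res$verdicts$verdict, res$verdicts$id)
  expect_equal(unname(v[c("ok", "primer", "short", "homop", "lowq",
                          "ambig", "noqual")]),
               c("pass", "fail_primer", "fail_length", "fail_homopolymer",
                 "fail_quality", "fail_ambiguity", "fail_quality"))
  expect_equal(res$verdicts$note[res$verdicts$id == "noqual"],
               "missing qualities")
  # ledger conservation and primer trimming
  expect_equal(sum(res$counts), nrow(reads))
  expect_equal(res$reads$sequence[res$reads$id == "ok"], good_core)

  # a read failing several rules lands under the first rule only
  multi <- data.frame(id = "multi", sequence = paste0("AAAA", "CCCCCCCCCC"),
                      quality = q10(14))
  r2 <- filter_reads(multi, params, primers = fwd, reverse_primer = NULL)
  expect_equal(r2$verdicts$verdict, "fail_primer")

  # pass set is independent of input order
  perm <- sample(nrow(reads))
  res_perm <- filter_reads(reads[perm, ], params, primers = fwd,
                           reverse_primer = NULL)
  expect_setequal(res_perm$reads$id, res$reads$id)
})

test_that("reverse primer and trailing bases are trimmed before the length check", {
  fwd <- "TCGGACGCGTGCAACGACCTGA"
  rev_rc <- "CCTAAATGGGGCAATGACGA"  # revcomp of a concrete reverse primer
  set.seed(41)
  core <- gsub("[^ACGT]", "A", random_dna(250))
  read <- data.frame(id = "r1",
                     sequence = paste0(fwd, core, rev_rc, "ACGTACGT"),
                     quality = paste(rep("I", nchar(fwd) + 250 + 28),
                                     collapse = ""))
  res <- filter_reads(read, qc_params(check_chimeras = FALSE), primers = fwd)
  expect_equal(res$reads$sequence, core)
  expect_equal(nchar(res$reads$quality), 250)
})

test_that("a clean simulated dataset passes quality control completely", {
  sim <- clean_sim()
  dem <- demultiplex_reads(sim$ds$reads, sim$ds$barcode_map)
  expect_setequal(unique(dem$site), unique(sim$ds$truth$site))
  res <- filter_reads(dem)
  expect_equal(res$counts[["pass"]], nrow(sim$ds$reads))
})

test_that("the chimera screen flags constructed joins and spares parents", {
  set.seed(51)
  a <- random_dna(300)
  bc <- strsplit(a, "")[[1]]
  swap <- sample(300, 60)  # parents 80% identical
  for (i in swap) bc[i] <- sample(setdiff(c("A", "C", "G", "T"), bc[i]), 1)
  b <- paste(bc, collapse = "")
  chim <- paste0(substr(a, 1, 150), substr(b, 151, 300))
  derep <- data.frame(id = c("parentA", "parentB", "chimera1"),
                      sequence = c(a, b, chim),
                      abundance = c(10L, 10L, 1L), stringsAsFactors = FALSE)
  res <- detect_chimeras(derep, score_threshold = 0.05)
  flagged <- setNames(res$is_chimera, res$id)
  expect_true(flagged[["chimera1"]])
  # perfect 50/50 join of 80%-identical parents scores ~ 1.0 - 0.9
  expect_gt(res$score[res$id == "chimera1"], 0.05)
  expect_lt(res$score[res$id == "chimera1"], 0.15)
  expect_false(flagged[["parentA"]])
  expect_false(flagged[["parentB"]])
  expect_setequal(na.omit(c(res$parent_left[3], res$parent_right[3])),
                  c("parentA", "parentB"))

  # a query identical to one parent scores <= 0
  derep2 <- rbind(derep[1:2, ],
                  data.frame(id = "copy", sequence = a, abundance = 1L))
  res2 <- detect_chimeras(derep2, score_threshold = 0.05)
  expect_false(res2$is_chimera[res2$id == "copy"])
  expect_lte(res2$score[res2$id == "copy"], 0)

  # the most abundant sequence has no eligible parents
  expect_true(is.na(res$score[res$id == "parentA"]) ||
                !res$is_chimera[res$id == "parentA"])
})

test_that("chimera recall and false-positive rate hold on simulated data", {
  spec <- community_spec(n_sites = 2, n_otus = 15, reads_per_site = 150,
                         abundance_model = "uniform",
                         cosmopolitan_fraction = 1, seed = 61)
  err <- error_model(substitution_rate = 0.001, indel_rate = 5e-4,
                     homopolymer_indel_multiplier = 10,
                     chimera_fraction = 0.1, offtarget_fraction = 0)
  ds <- generate_dataset(spec, err, masd_reference_set(15))
  qc <- filter_reads(demultiplex_reads(ds$reads, ds$barcode_map))
  v <- merge(qc$verdicts, ds$truth, by.x = "id", by.y = "read_id")
  recall <- with(v, sum(verdict == "fail_chimera" & is_chimera) /
                   sum(is_chimera))
  fpr <- with(v, sum(verdict == "fail_chimera" & !is_chimera) /
                sum(!is_chimera))
  expect_gte(recall, 0.6)
  expect_lte(fpr, 0.02)
})
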