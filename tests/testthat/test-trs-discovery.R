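test_that("maximal exact repeats are found with canonical tandem handling", {
  lib <- find_perfect_repeats(genome_record("ACGTACGT"))
  strs <- repeat_library_as_strings(lib)
  expect_true("ACGT@1,5" %in% strs)

  # a 6-nt homopolymer has no two non-overlapping unit-4 copies
  expect_length(find_perfect_repeats(genome_record("AAAAAACG")), 0L)
  # an 8-nt run does
  lib8 <- find_perfect_repeats(genome_record("AAAAAAAACG"))
  expect_true("AAAA@1,5" %in% repeat_library_as_strings(lib8))
})

test_that("repeat finder agrees with the all-substring oracle", {
  set.seed(77)
  for (n in c(200, 400, 800)) {
    s <- random_seq(n)
    got <- repeat_library_as_strings(
      find_perfect_repeats(genome_record(s)))
    want <- oracle_repeats(s)
    expect_identical(got, want, info = paste("n =", n))
  }
  # sequences with N: windows containing N never match
  s <- paste0("ACGTACGTAC", "N", "ACGTACGTAC")
  gotN <- repeat_library_as_strings(find_perfect_repeats(genome_record(s)))
  expect_identical(gotN, oracle_repeats(s))
  expect_false(any(grepl("N", gotN)))
})

test_that("positional filtering keeps planted TRS repeats and drops decoys", {
  sim <- generate_genome(genome_spec(seed = 21, n_decoys = 2))
  lib <- find_perfect_repeats(sim$record)
  flib <- filter_positional(lib, sim$truth$orfs)
  units <- vapply(flib, `[[`, character(1), "unit")
  # decoy repeats (both copies inside ORF1a) must not survive
  expect_true(all(vapply(sim$truth$decoys$unit, function(d) {
    !d %in% units
  }, logical(1))))
  # every surviving repeat has a leader and a body occurrence
  for (r in flib) {
    expect_true(any(r$regions$region == "leader", na.rm = TRUE))
    expect_true(any(startsWith(stats::na.omit(r$regions$region), "body:")))
  }
  expect_error(filter_positional(lib, data.frame(label = "x", start = 1,
                                                 end = 9)),
               "ORF1a")
})

test_that("near-perfect pairing finds exact and mismatched copies", {
  set.seed(55)
  unit <- random_seq(15)
  lead_flank <- random_seq(40); mid <- random_seq(200)
  body_flank <- random_seq(30)
  s <- paste0(lead_flank, unit, random_seq(40), mid, body_flank, unit,
              random_seq(30))
  r <- genome_record(s)
  leader_region <- c(1L, 95L)
  body_region <- c(296L, r$length)
  pc <- pair_near_perfect(r, leader_region, body_region)
  top <- pc[1L, ]
  expect_gte(top$identities, 15L)
  expect_equal(top$mismatches, 0L)
  # the planted copy is recovered (possibly extended by chance matches)
  expect_lte(top$leader_start, 41L)
  expect_gte(top$leader_end, 55L)

  # with zero mismatch tolerance, pairing reduces to exact matching
  cfg0 <- trs_config(max_mismatch_fraction = 0)
  pc0 <- pair_near_perfect(r, leader_region, body_region, cfg0)
  expect_true(all(pc0$mismatches == 0L))
  expect_error(pair_near_perfect(r, c(1, 100), c(50, 200)), "disjoint")
})

test_that("flanked alignment scores match an independent aligner", {
  # identical flanked regions: 100% identity, no gaps
  set.seed(66)
  block <- random_seq(35)  # 15-nt core plus 10-nt flanks on each side
  s <- paste0(random_seq(25), block, random_seq(120), block, random_seq(25))
  r <- genome_record(s)
  cand <- data.frame(leader_start = 36, leader_end = 50,
                     body_start = 191, body_end = 205)
  al <- align_flanked(r, cand, trs_config(flank = 10))
  expect_equal(al$gap_columns, 0L)
  expect_equal(al$identity_all_percent, 100)

  # a single internal deletion yields exactly one gap column
  a <- "ACGTACGTTACGGACTACGT"
  b <- paste0(substr(a, 1, 9), substr(a, 11, 20))
  al2 <- nw_align(a, b)
  expect_equal(al2$gap_columns, 1L)
  expect_equal(al2$score, oracle_nw_score(a, b))

  # random pairs: score equals the quadratic-DP oracle
  for (i in 1:15) {
    x <- random_seq(sample(20:60, 1))
    y <- random_seq(sample(20:60, 1))
    expect_equal(nw_align(x, y)$score, oracle_nw_score(x, y),
                 info = paste("pair", i))
  }
  # identity conventions
  al3 <- nw_align("ACGT", "ACGT")
  expect_equal(al3$identity_nongap_percent, 100)
  expect_equal(al3$identity_all_percent, 100)
})

test_that("sg mRNA sizes follow from 3'-coterminality", {
  r <- genome_record("ACGT"); r$length <- 20192L  # coordinate-only
  sg <- predict_sg_mrnas(r, c(ORF3 = 18402, ORF2a = 15660))
  expect_equal(sg$body_segment_len, c(1791L, 4533L))
  expect_equal(sg$kb, c(1.8, 4.5))
  expect_equal(predict_sg_mrnas(r, 1)$body_segment_len, 20192L)

  # monotone decreasing in junction position
  j <- sort(sample.int(20192, 20))
  lens <- predict_sg_mrnas(r, j)$body_segment_len
  expect_true(all(diff(lens) < 0))

  # leader-included length adds the leader contribution
  expect_equal(predict_sg_mrnas(r, 18402, leader_end = 40)$leader_included_len,
               1831L)
})

test_that("the full TRS pipeline reports planted pairs and honest absences", {
  sim <- generate_genome(genome_spec(seed = 31))
  res <- discover_trs(sim$record, sim$truth$orfs)
  cc <- res$candidates
  for (i in seq_len(nrow(sim$truth$trs))) {
    t <- sim$truth$trs[i, ]
    hit <- which(cc$leader_start == t$leader_start &
                 cc$leader_end == t$leader_end &
                 cc$body_start == t$body_start &
                 cc$body_end == t$body_end)
    expect_length(hit, 1L)
    expect_equal(cc$identities[hit], t$unit_len - t$mismatches)
    expect_equal(cc$downstream_orf[hit], t$downstream_orf)
    # flanked alignment reported for each candidate
    expect_true(is.finite(cc$flank_identity_all[hit]))
  }
  # an ORF with no planted (or chance) TRS can be reported as absent;
  # the field always exists and is a character vector
  expect_type(res$no_trs_orfs, "character")
})
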