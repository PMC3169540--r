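test_that("generation is deterministic under a seed", {
  a <- generate_genome(genome_spec(seed = 5))
  b <- generate_genome(genome_spec(seed = 5))
  expect_identical(a$record$seq, b$record$seq)
  expect_identical(a$truth, b$truth)
  c <- generate_genome(genome_spec(seed = 6))
  expect_false(identical(a$record$seq, c$record$seq))

  # byte-identical FASTA files
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(a$record, f1); write_fasta(b$record, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted ORFs are recovered exactly by the ORF finder", {
  # a layout without TRS pairs still carries the ORF skeleton
  sp <- genome_spec(seed = 9, trs = data.frame(leader_pos = integer(),
                                               unit_len = integer(),
                                               mismatches = integer(),
                                               body_orf = character()))
  sim <- generate_genome(sp)
  aug <- find_orfs(sim$record, 150, "aug")
  open <- find_orfs(sim$record, 150, "open")
  truth <- sim$truth$orfs
  for (i in seq_len(nrow(truth))) {
    pool <- if (truth$mode[i] == "aug") aug else open
    hit <- pool$start == truth$start[i] & pool$end == truth$end[i]
    expect_true(any(hit), info = truth$label[i])
    expect_equal(pool$frame[hit], truth$frame[i])
  }
})

test_that("every truth feature is recoverable by exact sequence comparison", {
  sim <- generate_genome(genome_spec(seed = 14))
  r <- sim$record
  truth <- sim$truth

  # heptamer at its stated coordinates
  expect_equal(subsequence(r, truth$rfs$heptamer_start,
                           truth$rfs$heptamer_end),
               truth$rfs$motif)

  # TRS body copies differ from leader copies at exactly the planted
  # number of interior positions
  for (i in seq_len(nrow(truth$trs))) {
    t <- truth$trs[i, ]
    lead <- strsplit(subsequence(r, t$leader_start, t$leader_end), "")[[1L]]
    body <- strsplit(subsequence(r, t$body_start, t$body_end), "")[[1L]]
    diffs <- which(lead != body)
    expect_length(diffs, t$mismatches)
    expect_true(all(diffs >= 3L & diffs <= t$unit_len - 2L))
  }

  # hairpin: 3' arm is the reverse complement of the 5' arm
  hp <- truth$hairpin
  stem5 <- subsequence(r, hp$start, hp$start + hp$stem_len - 1L)
  stem3 <- subsequence(r, hp$end - hp$stem_len + 1L, hp$end)
  expect_equal(stem3, revcomp(stem5))

  # poly(A) tail
  expect_equal(subsequence(r, truth$polyA[1L], truth$polyA[2L]),
               strrep("A", truth$polyA[2L] - truth$polyA[1L] + 1L))

  # no internal stops in any planted ORF reading frame
  for (i in seq_len(nrow(truth$orfs))) {
    cds <- subsequence(r, truth$orfs$start[i], truth$orfs$end[i])
    tr <- translate_cds(cds)
    expect_true(tr$stop_included, info = truth$orfs$label[i])
  }
})

test_that("inconsistent genome specifications fail with named constraints", {
  expect_error(genome_spec(overlap_len = 39), "overlap_len")
  expect_error(genome_spec(orf1a_len = 100), "orf1a_len")
  expect_error(genome_spec(rfs_offset = 36), "heptamer does not fit")
  expect_error(genome_spec(rfs_offset = 17), "rfs_offset")
  expect_error(genome_spec(total_len = 7100), "total_len too small")
  expect_error(genome_spec(trs = data.frame(leader_pos = 5, unit_len = 15,
                                            mismatches = 1,
                                            body_orf = "ORF3")),
               "5'-UTR")
  expect_error(genome_spec(trs = data.frame(leader_pos = 26, unit_len = 15,
                                            mismatches = 14,
                                            body_orf = "ORF3")),
               "mismatches")
  expect_error(genome_spec(hairpin_stem = 1500), "hairpin")
})

test_that("lineage generation respects counts, boundaries and modes", {
  tb <- generate_lineage_table(43, 4, seed = 2)
  expect_equal(attr(tb, "n"), 43L)
  expect_equal(attr(tb, "k"), 4L)
  expect_equal(length(unique(tb$genome_size)), 43L)
  expect_equal(max(tb$genome_size[!tb$trait]), 19600)
  expect_equal(min(tb$genome_size[tb$trait]), 20192)

  # separable construction puts the scan argmin at the known boundary
  s <- scan_thresholds(tb)
  expect_gt(s$argmin_threshold, 19600)
  expect_lt(s$argmin_threshold, 20192)

  # k = 0 builds a table but the test itself refuses p = 0
  tb0 <- generate_lineage_table(10, 0, seed = 2)
  expect_error(scan_thresholds(tb0), "0 < p < 1")
  expect_error(generate_lineage_table(5, 6), "\\[0, n\\]")

  # determinism
  expect_identical(generate_lineage_table(43, 4, seed = 8),
                   generate_lineage_table(43, 4, seed = 8))
})
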