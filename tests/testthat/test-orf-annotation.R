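test_that("aug-mode ORFs run from the 5'-most AUG to the stop", {
  r <- genome_record("AAATGAAATAAGG")
  orfs <- find_orfs(r, min_len_nt = 9, mode = "aug")
  expect_equal(nrow(orfs), 1L)
  expect_equal(c(orfs$start, orfs$end), c(3L, 11L))
  expect_equal(subsequence(r, orfs$start, orfs$end), "ATGAAATAA")
  # truncated stretches (no terminating stop) are excluded by default
  r2 <- genome_record("ATGAAAAAAAAA")
  expect_equal(nrow(find_orfs(r2, 9, "aug")), 0L)
  expect_equal(nrow(find_orfs(r2, 9, "aug", include_truncated = TRUE)), 1L)
})

test_that("both ORF modes agree with a frame-scan oracle on random sequences", {
  set.seed(101)
  for (i in 1:10) {
    s <- random_seq(300)
    r <- genome_record(s)
    for (mode in c("aug", "open")) {
      got <- find_orfs(r, min_len_nt = 30, mode = mode)
      want <- oracle_find_orfs(s, 30, mode)
      expect_equal(got$start, want$start,
                   info = sprintf("seed-case %d mode %s", i, mode))
      expect_equal(got$end, want$end)
    }
  }
})

test_that("every aug ORF is contained in an open-mode stretch", {
  set.seed(202)
  for (i in 1:5) {
    r <- genome_record(random_seq(500))
    aug <- find_orfs(r, 30, "aug")
    open <- find_orfs(r, 30, "open")
    for (j in seq_len(nrow(aug))) {
      containing <- open$start <= aug$start[j] & open$end >= aug$end[j] &
        (open$start - 1L) %% 3L == (aug$start[j] - 1L) %% 3L
      expect_true(any(containing))
    }
  }
})

test_that("overlap length and relative frame reproduce the replicase arrangement", {
  ov <- overlap_and_frame(c(361, 7869), c(7830, 15635))
  expect_equal(ov$overlap_len, 40L)
  expect_equal(ov$relative_frame, -1L)
  expect_equal(overlap_and_frame(c(1, 9), c(10, 18)),
               list(overlap_len = 0L, relative_frame = 0L))
})

test_that("overlap arithmetic matches a position-set oracle and is antisymmetric", {
  set.seed(303)
  for (i in 1:50) {
    a <- sort(sample.int(200, 2)); b <- sort(sample.int(200, 2))
    got <- overlap_and_frame(a, b)
    expect_equal(got$overlap_len,
                 length(intersect(a[1]:a[2], b[1]:b[2])))
    rev <- overlap_and_frame(b, a)
    expect_equal(got$overlap_len, rev$overlap_len)
    expect_equal(got$relative_frame, -rev$relative_frame)
  }
})

test_that("UTRs flank the outermost ORFs, with zero-length markers", {
  r <- genome_record(strrep("A", 100))
  r20k <- r; r20k$length <- 20192L  # coordinate-only check
  orfs <- data.frame(start = c(361, 7830, 18754), end = c(7869, 15635, 19101))
  utrs <- delineate_utrs(r20k, orfs)
  expect_equal(unname(utrs$five_prime), c(1L, 360L))
  expect_equal(unname(utrs$three_prime), c(19102L, 20192L))

  u2 <- delineate_utrs(r, data.frame(start = 1, end = 99))
  expect_equal(unname(u2$five_prime), c(1L, 0L))   # empty 5'-UTR
  expect_equal(unname(u2$three_prime), c(100L, 100L))
})

test_that("UTRs on synthetic genomes equal the planted truth", {
  sim <- generate_genome(genome_spec(seed = 8))
  orfs <- find_orfs(sim$record, 300, "aug")
  utrs <- delineate_utrs(sim$record, orfs)
  expect_equal(unname(utrs$five_prime), unname(sim$truth$utr5))
  expect_equal(unname(utrs$three_prime), unname(sim$truth$utr3))
})

test_that("sequon detection honours the proline rule and its toggle", {
  expect_equal(protein_features("NPS")$nxst_sites, integer(0))
  expect_equal(protein_features("NAS")$nxst_sites, 1L)
  expect_equal(protein_features("NPS",
                                sequon_excludes_proline = FALSE)$nxst_sites,
               1L)
  pf <- protein_features("MNASANVTKNLT")
  expect_equal(pf$nxst_sites, c(2L, 6L, 10L))
})

test_that("composition and cysteine counts are correct and permutation-invariant", {
  pf <- protein_features("CCAC")
  expect_equal(pf$cys_count, 3L)
  expect_equal(unname(pf$composition["C"]), 75)
  expect_equal(sum(pf$composition), 100, tolerance = 0.1)

  set.seed(404)
  aa <- paste(sample(names(nidoscan:::KD_SCALE), 60, replace = TRUE),
              collapse = "")
  perm <- paste(sample(strsplit(aa, "")[[1L]]), collapse = "")
  expect_equal(protein_features(aa)$composition,
               protein_features(perm)$composition)
  expect_error(protein_features("AC*G"), "invalid residue")
})

test_that("hydrophobic stretches are found by windowed Kyte-Doolittle means", {
  aa <- paste0(strrep("D", 15), strrep("I", 25), strrep("D", 15))
  st <- protein_features(aa)$hydrophobic_stretches
  expect_equal(nrow(st), 1L)
  # the stretch must cover the hydrophobic core
  expect_lte(st$start[1L], 25L)
  expect_gte(st$end[1L], 31L)
  expect_equal(nrow(protein_features(strrep("D", 60))$hydrophobic_stretches),
               0L)
})
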