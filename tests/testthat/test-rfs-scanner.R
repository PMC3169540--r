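# construct a small record with a -1 frame ORF overlap and a motif
# planted at a frame-valid doubly-read position
make_overlap_record <- function(window7, e = 72L) {
  set.seed(9000 + e)
  chars <- strsplit(random_seq(200), "", fixed = TRUE)[[1L]]
  chars[(e - 6L):e] <- strsplit(window7, "", fixed = TRUE)[[1L]]
  list(record = genome_record(paste(chars, collapse = "")),
       orf1a = c(1L, 99L), orf1b = c(60L, 158L), overlap = c(60L, 99L))
}

test_that("heptamer scanning scores library motifs by Hamming distance", {
  x <- make_overlap_record("GGATTTT")
  sites <- scan_slippery(x$record, x$overlap, x$orf1a, x$orf1b)
  hit <- sites[sites$heptamer_start == 66L, ]
  expect_equal(hit$window, "GGATTTT")
  expect_equal(hit$lib_motif, "ronivirus")  # AAAUUUU
  expect_equal(hit$lib_hamming, 2L)

  y <- make_overlap_record("AAATTTT")
  sy <- scan_slippery(y$record, y$overlap, y$orf1a, y$orf1b)
  expect_equal(sy$lib_hamming[sy$heptamer_start == 66L], 0L)

  # non -1 arrangements are rejected
  expect_error(scan_slippery(x$record, x$overlap, c(1, 99), c(61, 159)),
               "-1")
})

test_that("every reported site satisfies both doubly-read frame identities", {
  set.seed(12)
  for (s in 1:5) {
    sim <- generate_genome(genome_spec(seed = 1200 + s))
    a <- unlist(sim$truth$orfs[1, c("start", "end")])
    b <- unlist(sim$truth$orfs[2, c("start", "end")])
    sites <- scan_slippery(sim$record, sim$truth$rfs$overlap, a, b)
    pos <- sites$doubly_read_pos
    expect_true(all((pos - a[["start"]] + 1L) %% 3L == 0L))
    expect_true(all((pos - b[["start"]]) %% 3L == 0L))
    expect_true(all(sites$heptamer_start >= sim$truth$rfs$overlap[1L]))
    expect_true(all(sites$heptamer_end <= sim$truth$rfs$overlap[2L]))
  }
})

test_that("a planted exact motif is the best library match across seeds", {
  for (s in 1:20) {
    sim <- generate_genome(genome_spec(seed = 3000 + s))
    a <- unlist(sim$truth$orfs[1, c("start", "end")])
    b <- unlist(sim$truth$orfs[2, c("start", "end")])
    sites <- scan_slippery(sim$record, sim$truth$rfs$overlap, a, b)
    best <- sites[which.min(sites$lib_hamming), ]
    expect_equal(best$lib_hamming, 0L, info = paste("seed", s))
    expect_equal(best$doubly_read_pos, sim$truth$rfs$doubly_read_pos)
  }
})

test_that("stop distances follow from the printed coordinate arithmetic", {
  d <- stop_distances(7851, c(361, 7869), c(7830, 15635))
  expect_equal(d$d_down_1a, 18L)
  expect_equal(d$d_up_1b, 21L)
  # exact identity: the two distances always sum to overlap_len - 1
  sim <- generate_genome(genome_spec(seed = 44))
  a <- unlist(sim$truth$orfs[1, c("start", "end")])
  b <- unlist(sim$truth$orfs[2, c("start", "end")])
  sites <- scan_slippery(sim$record, sim$truth$rfs$overlap, a, b)
  ov_len <- a[["end"]] - b[["start"]] + 1L
  expect_true(all(sites$dist_to_orf1a_stop +
                    sites$dist_to_orf1b_upstream_stop == ov_len - 1L))
  expect_true(all(sites$dist_to_orf1a_stop >= 0L))
})

test_that("base-pair maximization solves canonical examples", {
  allA <- nussinov(strrep("A", 20))
  expect_equal(allA$bp_count, 0L)
  expect_equal(allA$dotbracket, strrep(".", 20))

  hp <- nussinov("GGGAAAACCC", min_loop = 3)
  expect_equal(hp$bp_count, 3L)
  expect_equal(hp$dotbracket, "(((....)))")
})

test_that("Nussinov equals exhaustive enumeration on short windows", {
  set.seed(500)
  for (i in 1:25) {
    s <- random_seq(sample(8:12, 1))
    for (gu in c(TRUE, FALSE)) {
      expect_equal(nussinov(s, min_loop = 3, allow_GU = gu)$bp_count,
                   oracle_nussinov_max(s, min_loop = 3, allow_GU = gu),
                   info = paste(s, "GU", gu))
    }
  }
})

test_that("structures are nested, respect min_loop, and grow as min_loop shrinks", {
  set.seed(600)
  for (i in 1:10) {
    s <- random_seq(30)
    prev <- -1L
    for (ml in c(4L, 3L, 2L, 1L, 0L)) {
      res <- nussinov(s, min_loop = ml)
      expect_gte(res$bp_count, prev)
      prev <- res$bp_count
      if (nrow(res$pairs) > 0L) {
        expect_true(all(res$pairs[, 2L] - res$pairs[, 1L] - 1L >= ml))
        # nestedness: no crossing pairs
        for (a in seq_len(nrow(res$pairs))) for (b in seq_len(nrow(res$pairs))) {
          if (a == b) next
          i1 <- res$pairs[a, 1L]; j1 <- res$pairs[a, 2L]
          i2 <- res$pairs[b, 1L]; j2 <- res$pairs[b, 2L]
          crossing <- i1 < i2 && i2 < j1 && j1 < j2
          expect_false(crossing)
        }
        # only admissible pairs
        ch <- strsplit(chartr("U", "T", s), "")[[1L]]
        pr <- paste0(ch[res$pairs[, 1L]], ch[res$pairs[, 2L]])
        expect_true(all(pr %in% c("AT", "TA", "CG", "GC", "GT", "TG")))
      }
    }
  }
})

test_that("a planted hairpin is detected downstream of the slippery site", {
  sim <- generate_genome(genome_spec(seed = 71))
  fold <- fold_downstream(sim$record, sim$truth$rfs$doubly_read_pos,
                          rfs_config(fold_window = 60))
  expect_gte(fold$bp_count, sim$truth$hairpin$stem_len)
  expect_equal(fold$window_start, sim$truth$rfs$doubly_read_pos + 1L)

  # truncation at the genome 3' end warns but still folds
  expect_warning(
    f2 <- fold_downstream(sim$record, sim$record$length - 50L,
                          rfs_config(fold_window = 190)),
    "truncated")
  expect_equal(f2$window_end, sim$record$length)
})
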