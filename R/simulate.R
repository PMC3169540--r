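#' Specification of a synthetic nidovirus-like genome
#'
#' Describes a polycistronic genome with the architectural features the
#' annotation pipeline targets: a 5'-UTR carrying one or two leader TRS
#' copies, two large ORFs overlapping in the -1 frame with a slippery
#' heptamer (and a downstream hairpin) inside/after the overlap, 3'
#' -proximal ORFs each preceded by a near-perfect body copy of a leader
#' TRS, a 3'-UTR and a poly(A) tail. Defaults mirror the printed NDiV
#' proportions (5'-UTR 360 nt, 40-nt ORF1a/ORF1b overlap, ~1-kb 3'-UTR)
#' at a reduced 8-kb total length for fast simulation.
#'
#' All planted features are mutually consistency-checked; an
#' inconsistent specification raises an error naming the violated
#' constraint.
#'
#' @param total_len Total genome length (nt).
#' @param utr5_len 5'-UTR length; ORF1a starts at `utr5_len + 1`.
#' @param orf1a_len,orf1b_len ORF lengths in nt including the stop codon
#'   (multiples of 3).
#' @param overlap_len ORF1a/ORF1b overlap (nt); must be `1 (mod 3)` so
#'   the overlap is in the -1 relative frame.
#' @param orf3p_lens Named integer vector of downstream aug-ORF lengths
#'   (nt, multiples of 3), in genome order.
#' @param orf3p_gaps Intergenic gaps (nt) preceding each downstream ORF.
#' @param trs `data.frame` with columns `leader_pos`, `unit_len`,
#'   `mismatches`, `body_orf` (a name from `orf3p_lens`); the body copy
#'   is planted ending 21 nt upstream of its ORF start.
#' @param heptamer 7-nt slippery motif to plant (RNA or DNA alphabet).
#' @param rfs_offset Distance from the doubly-read nucleotide to the
#'   ORF1a stop-codon end (`orf1a_end - doubly_read_pos`; multiple of 3).
#' @param hairpin_stem,hairpin_loop Stem and loop lengths of the planted
#'   hairpin, which starts immediately after the ORF1a stop codon.
#' @param polyA_len Poly(A) tail length.
#' @param n_decoys Number of decoy 12-nt repeats planted (both copies)
#'   inside ORF1a, to exercise the positional TRS filters.
#' @param seed Integer seed; the same seed yields a byte-identical
#'   genome.
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(total_len = 8000L, utr5_len = 360L,
                        orf1a_len = 3000L, orf1b_len = 2880L,
                        overlap_len = 40L,
                        orf3p_lens = c(ORF2 = 420L, ORF3 = 330L),
                        orf3p_gaps = c(80L, 100L),
                        trs = data.frame(
                          leader_pos = c(26L, 125L),
                          unit_len = c(15L, 13L),
                          mismatches = c(1L, 1L),
                          body_orf = c("ORF3", "ORF2"),
                          stringsAsFactors = FALSE),
                        heptamer = "AAAUUUU", rfs_offset = 18L,
                        hairpin_stem = 8L, hairpin_loop = 4L,
                        polyA_len = 25L, n_decoys = 0L, seed = 1L) {
  spec <- structure(
    list(total_len = as.integer(total_len), utr5_len = as.integer(utr5_len),
         orf1a_len = as.integer(orf1a_len),
         orf1b_len = as.integer(orf1b_len),
         overlap_len = as.integer(overlap_len),
         orf3p_lens = orf3p_lens, orf3p_gaps = as.integer(orf3p_gaps),
         trs = trs, heptamer = chartr("U", "T", toupper(heptamer)),
         rfs_offset = as.integer(rfs_offset),
         hairpin_stem = as.integer(hairpin_stem),
         hairpin_loop = as.integer(hairpin_loop),
         polyA_len = as.integer(polyA_len),
         n_decoys = as.integer(n_decoys), seed = as.integer(seed)),
    class = "genome_spec"
  )
  validate_genome_spec(spec)
  spec
}

# derive all planted coordinates from a spec
spec_layout <- function(spec) {
  orf1a_start <- spec$utr5_len + 1L
  orf1a_end <- orf1a_start + spec$orf1a_len - 1L
  orf1b_start <- orf1a_end - spec$overlap_len + 1L
  orf1b_end <- orf1b_start + spec$orf1b_len - 1L
  labels <- names(spec$orf3p_lens)
  starts <- integer(length(labels)); ends <- integer(length(labels))
  prev_end <- orf1b_end
  for (i in seq_along(labels)) {
    starts[i] <- prev_end + spec$orf3p_gaps[i] + 1L
    ends[i] <- starts[i] + spec$orf3p_lens[i] - 1L
    prev_end <- ends[i]
  }
  e <- orf1a_end - spec$rfs_offset           # doubly-read nucleotide
  hp_start <- orf1a_end + 1L
  hp_end <- hp_start + 2L * spec$hairpin_stem + spec$hairpin_loop - 1L
  body_start <- body_end <- integer(nrow(spec$trs))
  for (i in seq_len(nrow(spec$trs))) {
    orf_i <- match(spec$trs$body_orf[i], labels)
    body_end[i] <- starts[orf_i] - 21L
    body_start[i] <- body_end[i] - spec$trs$unit_len[i] + 1L
  }
  list(orf1a = c(orf1a_start, orf1a_end),
       orf1b = c(orf1b_start, orf1b_end),
       orf3p = data.frame(label = labels, start = starts, end = ends,
                          stringsAsFactors = FALSE),
       doubly_read_pos = e, hairpin = c(hp_start, hp_end),
       body_start = body_start, body_end = body_end)
}

validate_genome_spec <- function(spec) {
  fail <- function(...) stop("inconsistent genome_spec: ", sprintf(...))
  if (spec$overlap_len %% 3L != 1L) {
    fail("overlap_len %% 3 must be 1 for a -1 frame overlap (got %d)",
         spec$overlap_len)
  }
  for (f in c("orf1a_len", "orf1b_len")) {
    if (spec[[f]] %% 3L != 0L || spec[[f]] < 90L) {
      fail("%s must be a multiple of 3 and >= 90", f)
    }
  }
  if (is.null(names(spec$orf3p_lens)) ||
      any(spec$orf3p_lens %% 3L != 0L)) {
    fail("orf3p_lens must be named multiples of 3")
  }
  if (length(spec$orf3p_gaps) != length(spec$orf3p_lens)) {
    fail("orf3p_gaps and orf3p_lens lengths differ")
  }
  if (nchar(spec$heptamer) != 7L) fail("heptamer must be 7 nt")
  if (spec$rfs_offset %% 3L != 0L) {
    fail("rfs_offset must be a multiple of 3 to land on the doubly-read frame")
  }
  if (spec$rfs_offset > spec$overlap_len - 7L) {
    fail("heptamer does not fit inside the overlap (rfs_offset too large)")
  }
  lay <- spec_layout(spec)
  if (lay$hairpin[2L] >= lay$orf1b[2L] - 2L) {
    fail("hairpin collides with the ORF1b stop codon")
  }
  tr <- spec$trs
  if (nrow(tr) > 0L) {
    if (!all(tr$body_orf %in% names(spec$orf3p_lens))) {
      fail("trs$body_orf must name entries of orf3p_lens")
    }
    if (any(tr$leader_pos < 9L) ||
        any(tr$leader_pos + tr$unit_len - 1L > spec$utr5_len - 11L)) {
      fail("leader TRS copies (with flank guards) must lie inside the 5'-UTR")
    }
    if (any(tr$mismatches < 0L) ||
        any(tr$mismatches > pmax(0L, tr$unit_len - 4L))) {
      fail("mismatches must fit interior positions (0..unit_len-4)")
    }
    prev_ends <- c(lay$orf1b[2L], utils::head(lay$orf3p$end, -1L))
    for (i in seq_len(nrow(tr))) {
      orf_i <- match(tr$body_orf[i], lay$orf3p$label)
      if (lay$body_start[i] - 8L <= prev_ends[orf_i]) {
        fail("body TRS for %s (with flank guards) does not fit in its intergenic gap",
             tr$body_orf[i])
      }
    }
    # leader copies (with guards) must not overlap each other
    if (nrow(tr) > 1L) {
      o <- order(tr$leader_pos)
      le <- tr$leader_pos[o] + tr$unit_len[o] - 1L
      if (any(tr$leader_pos[o][-1L] - 8L <= le[-length(le)] + 8L)) {
        fail("leader TRS copies overlap (flank guards included)")
      }
    }
  }
  tail_end <- max(lay$orf3p$end)
  if (tail_end + spec$polyA_len + 20L > spec$total_len) {
    fail("total_len too small for the 3'-UTR and poly(A) tail")
  }
  invisible(spec)
}

BASES <- c("A", "C", "G", "T")

# depth (nt) of the mismatching flank guards planted around TRS copies;
# matches the default discovery length cap (max_unit + 8 vs planted
# lengths >= 10) so planted windows dominate any extension
TRS_GUARD <- 8L

#' Generate a synthetic genome with known ground truth
#'
#' Produces a [genome_record()] realizing a [genome_spec()]: uniform
#' random background with all specified features planted at exact
#' coordinates, in-frame stop codons inside planted ORFs removed by
#' codon resampling (the only non-uniform background element), and
#' single-base flank guards around each TRS copy so the planted repeats
#' are maximal by construction. The truth set records every planted
#' feature so pipeline output can be checked by exact comparison.
#'
#' @param spec A [genome_spec()].
#' @return A list with `record` (the genome) and `truth` (list of
#'   planted ORFs, UTRs, TRS pairs, slippery site, hairpin and expected
#'   sg mRNA lengths).
#' @export
generate_genome <- function(spec = genome_spec()) {
  validate_genome_spec(spec)
  set.seed(spec$seed)
  lay <- spec_layout(spec)
  n <- spec$total_len
  chars <- sample(BASES, n, replace = TRUE)
  lock <- logical(n)

  plant <- function(pos, s) {
    sv <- strsplit(s, "", fixed = TRUE)[[1L]]
    idx <- pos:(pos + length(sv) - 1L)
    if (any(lock[idx])) {
      stop("inconsistent genome_spec: planted features overlap at ",
           idx[lock[idx]][1L])
    }
    chars[idx] <<- sv
    lock[idx] <<- TRUE
  }

  # poly(A) tail
  plant(n - spec$polyA_len + 1L, strrep("A", spec$polyA_len))

  # ORF boundary codons: a stop immediately 5' of every planted start
  # makes the planted AUG/first codon the 5'-most of its open stretch
  a <- lay$orf1a; b <- lay$orf1b
  plant(a[1L] - 3L, "TAA")
  plant(a[1L], "ATG")
  plant(a[2L] - 2L, "TAA")
  plant(b[1L] - 3L, "TAA")            # ORF1b-frame stop inside ORF1a
  plant(b[2L] - 2L, "TAA")
  for (i in seq_len(nrow(lay$orf3p))) {
    plant(lay$orf3p$start[i] - 3L, "TAA")
    plant(lay$orf3p$start[i], "ATG")
    plant(lay$orf3p$end[i] - 2L, "TAA")
  }

  # TRS pairs: leader copy random, body copy = leader with `mismatches`
  # interior substitutions; one-base flank guards enforce maximality
  trs_truth <- list()
  for (i in seq_len(nrow(spec$trs))) {
    L <- spec$trs$unit_len[i]
    lp <- spec$trs$leader_pos[i]
    unit <- sample(BASES, L, replace = TRUE)
    body <- unit
    mm <- spec$trs$mismatches[i]
    if (mm > 0L) {
      # mismatches sit away from the copy edges (positions 3..L-2) so
      # trimming edge columns can never raise the alignment score and
      # the planted extent is the unique dominant candidate
      at <- sample(3:(L - 2L), mm)
      for (p in at) body[p] <- sample(setdiff(BASES, unit[p]), 1L)
    }
    bp <- lay$body_start[i]
    plant(lp, paste(unit, collapse = ""))
    plant(bp, paste(body, collapse = ""))
    # anti-flank guards: for TRS_GUARD positions on each side the two
    # copies are forced to disagree, so any extension of the planted
    # window (up to the discovery length cap) only accumulates
    # mismatches and the planted extent is the dominant candidate
    for (g in c(-seq_len(TRS_GUARD), L - 1L + seq_len(TRS_GUARD))) {
      gl <- lp + g; gb <- bp + g
      if (gl >= 1L && gb >= 1L && !lock[gl] && !lock[gb]) {
        x <- sample(BASES, 1L)
        chars[gl] <- x
        chars[gb] <- sample(setdiff(BASES, x), 1L)
        lock[c(gl, gb)] <- TRUE
      }
    }
    trs_truth[[i]] <- data.frame(
      leader_start = lp, leader_end = lp + L - 1L,
      body_start = bp, body_end = bp + L - 1L,
      unit_len = L, mismatches = mm,
      downstream_orf = spec$trs$body_orf[i], stringsAsFactors = FALSE
    )
  }

  # slippery heptamer (ends on the doubly-read nucleotide)
  e <- lay$doubly_read_pos
  plant(e - 6L, spec$heptamer)

  # hairpin just 3' of the ORF1a stop, inside the ORF1b coding region:
  # rejection-sample a stem that introduces no ORF1b-frame stop codon
  # among the fully planted codons
  hp <- lay$hairpin
  hp_len <- hp[2L] - hp[1L] + 1L
  for (try in 1:500) {
    stem <- sample(BASES, spec$hairpin_stem, replace = TRUE)
    loop <- sample(BASES, spec$hairpin_loop, replace = TRUE)
    hp_seq <- c(stem, loop,
                strsplit(revcomp(paste(stem, collapse = "")), "",
                         fixed = TRUE)[[1L]])
    cod_starts <- seq.int(b[1L], b[2L] - 3L, by = 3L)
    inside <- cod_starts >= hp[1L] & cod_starts + 2L <= hp[2L]
    cods <- vapply(cod_starts[inside], function(cs) {
      paste(hp_seq[(cs - hp[1L] + 1L):(cs - hp[1L] + 3L)], collapse = "")
    }, character(1))
    if (!any(cods %in% STOP_CODONS)) {
      plant(hp[1L], paste(hp_seq, collapse = ""))
      break
    }
    if (try == 500L) stop("could not plant a stop-free hairpin")
  }

  # decoy repeats: both copies inside ORF1a (so positional TRS filters
  # must reject them)
  decoys <- list()
  if (spec$n_decoys > 0L) {
    for (i in seq_len(spec$n_decoys)) {
      p1 <- a[1L] + 200L + (i - 1L) * 400L
      p2 <- p1 + 150L
      for (try in 1:200) {
        unit <- sample(BASES, 12L, replace = TRUE)
        u <- paste(unit, collapse = "")
        # avoid units that would read as a stop in any phase of ORF1a
        safe <- !any(vapply(seq_len(10L), function(s)
          substr(u, s, s + 2L) %in% STOP_CODONS, logical(1)))
        if (safe) break
        if (try == 200L) stop("could not draw a stop-free decoy unit")
      }
      plant(p1, u); plant(p2, u)
      decoys[[i]] <- data.frame(unit = u, pos1 = p1, pos2 = p2,
                                stringsAsFactors = FALSE)
    }
  }

  # scrub in-frame stop codons inside every planted ORF by resampling
  # free (unlocked) codon positions; iterate until all frames are clean
  orf_frames <- c(
    list(c(a[1L], a[2L] - 3L), c(b[1L], b[2L] - 3L)),
    lapply(seq_len(nrow(lay$orf3p)), function(i) {
      c(lay$orf3p$start[i], lay$orf3p$end[i] - 3L)
    })
  )
  for (pass in 1:100) {
    dirty <- FALSE
    s_now <- paste(chars, collapse = "")
    for (fr in orf_frames) {
      cod_starts <- seq.int(fr[1L], fr[2L], by = 3L)
      cods <- substring(s_now, cod_starts, cod_starts + 2L)
      for (cs in cod_starts[cods %in% STOP_CODONS]) {
        idx <- cs:(cs + 2L)
        free <- idx[!lock[idx]]
        if (length(free) == 0L) {
          stop("inconsistent genome_spec: fully planted stop codon at ", cs)
        }
        repeat {
          chars[free] <- sample(BASES, length(free), replace = TRUE)
          if (!paste(chars[idx], collapse = "") %in% STOP_CODONS) break
        }
        dirty <- TRUE
      }
    }
    if (!dirty) break
    if (pass == 100L) stop("stop-codon scrubbing did not converge")
  }

  record <- genome_record(paste(chars, collapse = ""),
                          id = sprintf("synthetic_seed%d", spec$seed))
  orfs <- rbind(
    data.frame(label = "ORF1a", start = a[1L], end = a[2L],
               mode = "aug", stringsAsFactors = FALSE),
    data.frame(label = "ORF1b", start = b[1L], end = b[2L],
               mode = "open", stringsAsFactors = FALSE),
    data.frame(label = lay$orf3p$label, start = lay$orf3p$start,
               end = lay$orf3p$end, mode = "aug", stringsAsFactors = FALSE)
  )
  orfs$frame <- (orfs$start - 1L) %% 3L
  sg <- predict_sg_mrnas(record,
                         stats::setNames(lay$orf3p$start, lay$orf3p$label))
  truth <- list(
    orfs = orfs,
    utr5 = c(1L, a[1L] - 1L),
    utr3 = c(max(lay$orf3p$end) + 1L, n),
    trs = if (length(trs_truth)) do.call(rbind, trs_truth) else NULL,
    rfs = list(heptamer_start = e - 6L, heptamer_end = e,
               doubly_read_pos = e, motif = spec$heptamer,
               overlap = c(b[1L], a[2L])),
    hairpin = list(start = hp[1L], end = hp[2L],
                   stem_len = spec$hairpin_stem,
                   loop_len = spec$hairpin_loop),
    decoys = if (length(decoys)) do.call(rbind, decoys) else NULL,
    sg_mrnas = sg,
    polyA = c(n - spec$polyA_len + 1L, n)
  )
  list(record = record, truth = truth)
}

#' Generate a synthetic lineage table
#'
#' Draws `n` lineages with `k` trait-positives. In `"separable"` mode
#' the trait-negative sizes are confined to `neg_size_range` (forcing
#' the range maximum to be realized) and positives to `pos_size_range`
#' (forcing the minimum), so the trait separates perfectly at the known
#' boundary; in `"mixed"` mode sizes are drawn from the union range and
#' the trait is assigned at random. All sizes are distinct.
#'
#' @param n,k Lineage count and trait-positive count.
#' @param neg_size_range,pos_size_range Size ranges in nt.
#' @param mode `"separable"` or `"mixed"`.
#' @param seed Optional integer seed.
#' @return A [lineage_table()].
#' @export
generate_lineage_table <- function(n = 43L, k = 4L,
                                   neg_size_range = c(3500L, 19600L),
                                   pos_size_range = c(20192L, 31700L),
                                   mode = c("separable", "mixed"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (k < 0L || k > n) stop("k must lie in [0, n]")
  if (!is.null(seed)) set.seed(seed)
  if (mode == "separable") {
    if (pos_size_range[1L] <= neg_size_range[2L] && k > 0L && k < n) {
      stop("separable mode requires disjoint size ranges")
    }
    neg <- if (n - k > 0L) {
      c(sample(seq.int(neg_size_range[1L], neg_size_range[2L] - 1L),
               n - k - 1L), neg_size_range[2L])
    } else numeric(0)
    pos <- if (k > 0L) {
      c(pos_size_range[1L],
        sample(seq.int(pos_size_range[1L] + 1L, pos_size_range[2L]),
               k - 1L))
    } else numeric(0)
    sizes <- c(neg, pos)
    trait <- c(rep(FALSE, length(neg)), rep(TRUE, length(pos)))
  } else {
    sizes <- sample(seq.int(min(neg_size_range[1L], pos_size_range[1L]),
                            max(neg_size_range[2L], pos_size_range[2L])),
                    n)
    trait <- rep(FALSE, n)
    trait[sample.int(n, k)] <- TRUE
  }
  lineage_table(sprintf("lineage_%02d", seq_len(n)), sizes, trait)
}
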