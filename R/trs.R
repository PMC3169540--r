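#' Pair near-perfect leader/body repeat copies
#'
#' Compares every window of the leader region against every equally long
#' window of the body region under ungapped comparison (near-perfect TRS
#' pairs are length-preserving; gaps only enter the flanked conservation
#' alignment). Candidates are windows with mismatch fraction at most
#' `cfg$max_mismatch_fraction`. On each alignment diagonal, overlapping
#' candidates are reduced to the dominant one (highest
#' `identities - mismatches`, ties to the longer window, then the
#' 5'-most body start), so a strong pair is reported once, at its exact
#' extent, rather than as a cloud of shifted sub-windows.
#'
#' With `max_mismatch_fraction = 0` this reduces to exact repeat
#' matching.
#'
#' @param record A [genome_record()].
#' @param leader_region,body_region Each `c(start, end)` in genome
#'   coordinates; the regions must be disjoint.
#' @param cfg A [trs_config()].
#' @param min_len,max_len Window lengths considered (defaults 10 and
#'   `cfg$max_unit + 8`, allowing a near-perfect pair to extend past the
#'   longest perfect unit).
#' @return A `data.frame` with columns `leader_start`, `leader_end`,
#'   `body_start`, `body_end`, `matched_len`, `identities`, `mismatches`,
#'   `score`, sorted by score (desc), then length (desc), then body
#'   start. `N` never matches.
#' @export
pair_near_perfect <- function(record, leader_region, body_region,
                              cfg = trs_config(), min_len = 10L,
                              max_len = cfg$max_unit + 8L) {
  stopifnot(inherits(record, "genome_record"))
  lr <- as.integer(leader_region[1:2]); br <- as.integer(body_region[1:2])
  if (max(lr[1L], br[1L]) <= min(lr[2L], br[2L])) {
    stop("leader and body regions must be disjoint")
  }
  lch <- strsplit(subsequence(record, lr[1L], lr[2L]), "", fixed = TRUE)[[1L]]
  bch <- strsplit(subsequence(record, br[1L], br[2L]), "", fixed = TRUE)[[1L]]
  nl <- length(lch); nb <- length(bch)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  rows <- list()
  for (d in seq.int(1L - nl, nb - 1L)) {
    t0 <- max(1L, 1L - d); t1 <- min(nl, nb - d)
    if (t1 - t0 + 1L < min_len) next
    t <- t0:t1
    m <- (lch[t] == bch[t + d]) & lch[t] != "N" & bch[t + d] != "N"
    cs <- c(0L, cumsum(m))
    cand_li <- integer(0); cand_L <- integer(0); cand_id <- integer(0)
    for (L in min_len:min(max_len, length(t))) {
      s <- seq_len(length(t) - L + 1L)
      ident <- cs[s + L] - cs[s]
      ok <- (L - ident) <= cfg$max_mismatch_fraction * L
      if (!any(ok)) next
      cand_li <- c(cand_li, t0 + s[ok] - 1L)
      cand_L <- c(cand_L, rep(L, sum(ok)))
      cand_id <- c(cand_id, ident[ok])
    }
    if (length(cand_li) == 0L) next
    score <- 2L * cand_id - cand_L
    o <- order(-score, -cand_L, cand_li)
    # greedy dominance within the diagonal: accept best, drop overlaps
    acc_s <- integer(0); acc_e <- integer(0)
    for (i in o) {
      s0 <- cand_li[i]; e0 <- s0 + cand_L[i] - 1L
      if (any(s0 <= acc_e & e0 >= acc_s)) next
      acc_s <- c(acc_s, s0); acc_e <- c(acc_e, e0)
      rows[[length(rows) + 1L]] <-
        c(s0, e0, s0 + d, e0 + d, cand_L[i], cand_id[i], score[i])
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(leader_start = integer(), leader_end = integer(),
                      body_start = integer(), body_end = integer(),
                      matched_len = integer(), identities = integer(),
                      mismatches = integer(), score = integer()))
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(
    leader_start = lr[1L] + mat[, 1L] - 1L,
    leader_end = lr[1L] + mat[, 2L] - 1L,
    body_start = br[1L] + mat[, 3L] - 1L,
    body_end = br[1L] + mat[, 4L] - 1L,
    matched_len = mat[, 5L],
    identities = mat[, 6L],
    mismatches = mat[, 5L] - mat[, 6L],
    score = mat[, 7L]
  )
  out <- out[order(-out$score, -out$matched_len, out$body_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global alignment of a candidate pair with flanking context
#'
#' Aligns the leader copy plus `cfg$flank` nt on each side against the
#' body copy plus flanks, by global (Needleman-Wunsch/Gotoh) alignment
#' with match +1, mismatch -1, and affine gaps costing 2 for the first
#' gap position and 1 for each extension. Flanks are truncated at the
#' genome boundaries.
#'
#' Percent identity is reported both over non-gap columns and over all
#' alignment columns, since published identity figures do not always
#' state which convention they use.
#'
#' @param record A [genome_record()].
#' @param cand One row of the table returned by [pair_near_perfect()].
#' @param cfg A [trs_config()].
#' @return A list with `aligned_leader`, `aligned_body`, `score`,
#'   `gap_columns`, `identity_nongap_percent`, `identity_all_percent`,
#'   and the flanked coordinate ranges.
#' @export
align_flanked <- function(record, cand, cfg = trs_config()) {
  ls <- max(1L, cand$leader_start - cfg$flank)
  le <- min(record$length, cand$leader_end + cfg$flank)
  bs <- max(1L, cand$body_start - cfg$flank)
  be <- min(record$length, cand$body_end + cfg$flank)
  a <- subsequence(record, ls, le)
  b <- subsequence(record, bs, be)
  al <- nw_align(a, b)
  c(al, list(leader_range = c(ls, le), body_range = c(bs, be)))
}

#' Needleman-Wunsch global alignment with affine gaps
#'
#' Scoring: match +1, mismatch -1; a gap of length g costs
#' `2 + (g - 1)` (open -2 on the first gap position, -1 per extension).
#' Ties in the traceback prefer diagonal moves, then gaps in the second
#' sequence.
#'
#' @param a,b Nucleotide strings.
#' @return List with `aligned_a`, `aligned_b`, `score`, `gap_columns`,
#'   `identity_nongap_percent`, `identity_all_percent`.
#' @export
nw_align <- function(a, b) {
  ac <- strsplit(a, "", fixed = TRUE)[[1L]]
  bc <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  gap_first <- 2; gap_ext <- 1
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in a (consumes b)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) {
    X[i + 1L, 1L] <- -gap_first - gap_ext * (i - 1L)
  }
  for (j in seq_len(m)) {
    Y[1L, j + 1L] <- -gap_first - gap_ext * (j - 1L)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (ac[i] == bc[j] && ac[i] != "N") 1 else -1
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_first,
                               X[i, j + 1L] - gap_ext,
                               Y[i, j + 1L] - gap_first)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_first,
                               X[i + 1L, j] - gap_first,
                               Y[i + 1L, j] - gap_ext)
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback
  state <- which.max(c(M[n + 1L, m + 1L], X[n + 1L, m + 1L],
                       Y[n + 1L, m + 1L]))
  i <- n; j <- m
  out_a <- character(0); out_b <- character(0)
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      sub <- if (ac[i] == bc[j] && ac[i] != "N") 1 else -1
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state_next <- which.max(prev)
      stopifnot(abs(prev[state_next] + sub - M[i + 1L, j + 1L]) < 1e-9)
      out_a <- c(ac[i], out_a); out_b <- c(bc[j], out_b)
      i <- i - 1L; j <- j - 1L
      state <- state_next
    } else if (state == 2L) {
      prev <- c(M[i, j + 1L] - gap_first, X[i, j + 1L] - gap_ext,
                Y[i, j + 1L] - gap_first)
      state_next <- which.max(prev)
      out_a <- c(ac[i], out_a); out_b <- c("-", out_b)
      i <- i - 1L
      state <- state_next
    } else {
      prev <- c(M[i + 1L, j] - gap_first, X[i + 1L, j] - gap_first,
                Y[i + 1L, j] - gap_ext)
      state_next <- which.max(prev)
      out_a <- c("-", out_a); out_b <- c(bc[j], out_b)
      j <- j - 1L
      state <- state_next
    }
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  ncol_al <- length(out_a)
  gap_col <- out_a == "-" | out_b == "-"
  ident <- out_a == out_b & !gap_col & out_a != "N"
  nongap <- sum(!gap_col)
  list(
    aligned_a = paste(out_a, collapse = ""),
    aligned_b = paste(out_b, collapse = ""),
    score = score,
    gap_columns = sum(gap_col),
    identity_nongap_percent = if (nongap > 0L) 100 * sum(ident) / nongap
                              else NA_real_,
    identity_all_percent = 100 * sum(ident) / ncol_al
  )
}

#' Predict subgenomic mRNA sizes from TRS candidates
#'
#' Nidovirus sg mRNAs are 3'-coterminal: each runs from its leader/body
#' junction to the genome 3' end. The body segment length is
#' `genome_length - junction + 1`, with the junction taken at the
#' downstream ORF start (default) or at the body-TRS start. The
#' leader-included length adds the 5'-leader contribution (the leader
#' TRS end position) to approximate the full mRNA.
#'
#' @param record A [genome_record()].
#' @param junctions Integer vector of junction positions (one per
#'   predicted mRNA), with optional names used as labels.
#' @param leader_end Leader length added for the leader-included
#'   estimate (default 0 = body segment only).
#' @return A `data.frame` with `label`, `junction`, `body_segment_len`,
#'   `leader_included_len`, `kb` (body segment, rounded to 0.1 kb).
#' @examples
#' r <- genome_record(strrep("A", 100))
#' r$length <- 20192L  # coordinates-only example
#' @export
predict_sg_mrnas <- function(record, junctions, leader_end = 0L) {
  stopifnot(inherits(record, "genome_record"), all(junctions >= 1L),
            all(junctions <= record$length))
  labs <- names(junctions)
  if (is.null(labs)) labs <- sprintf("mRNA_%d", seq_along(junctions))
  body <- record$length - as.integer(junctions) + 1L
  data.frame(
    label = labs,
    junction = as.integer(junctions),
    body_segment_len = body,
    leader_included_len = body + as.integer(leader_end),
    kb = round(body / 1000, 1),
    stringsAsFactors = FALSE
  )
}

#' Discover TRS candidates for a genome with labelled ORFs
#'
#' Runs the full TRS-candidate procedure: a maximal exact repeat library
#' is built and filtered by the leader/body positional constraints, and
#' independently each downstream ORF's upstream window is paired against
#' the leader region by near-perfect ungapped comparison
#' ([pair_near_perfect()]). Candidates carry their flanked conservation
#' alignment and predicted sg mRNA size. Downstream ORFs for which no
#' window passes the mismatch threshold are reported as having no
#' candidate TRS (absence is a result, not an error).
#'
#' @param record A [genome_record()].
#' @param orfs ORF table with `label`, `start`, `end`; `"ORF1a"` (and
#'   optionally `"ORF1b"`) plus downstream ORFs.
#' @param cfg A [trs_config()].
#' @param min_len,max_len Passed to [pair_near_perfect()].
#' @return A list of class `trs_result` with `candidates` (data.frame
#'   incl. `downstream_orf`, alignment stats, `sg_mrna_kb`),
#'   `no_trs_orfs` (labels without a candidate), and `repeat_library`
#'   (the positionally filtered perfect-repeat library).
#' @export
discover_trs <- function(record, orfs, cfg = trs_config(), min_len = 10L,
                         max_len = cfg$max_unit + 8L) {
  stopifnot("ORF1a" %in% orfs$label)
  orf1a_start <- orfs$start[orfs$label == "ORF1a"][1L]
  if (orf1a_start < 2L) stop("no leader region 5' of ORF1a")
  leader_region <- c(1L, orf1a_start - 1L)
  down <- orfs[!orfs$label %in% c("ORF1a", "ORF1b"), , drop = FALSE]
  if (nrow(down) == 0L) stop("no downstream ORFs in table")

  lib <- find_perfect_repeats(record, cfg)
  flib <- tryCatch(filter_positional(lib, orfs, cfg),
                   error = function(e) structure(list(),
                                                 class = "repeat_library"))
  cands <- list()
  absent <- character(0)
  for (i in seq_len(nrow(down))) {
    w_start <- max(1L, down$start[i] - cfg$upstream_window)
    w_end <- down$start[i] - 1L
    if (w_end <= leader_region[2L]) { absent <- c(absent, down$label[i]); next }
    w_start <- max(w_start, leader_region[2L] + 1L)
    pc <- pair_near_perfect(record, leader_region, c(w_start, w_end), cfg,
                            min_len = min_len, max_len = max_len)
    if (nrow(pc) == 0L) {
      absent <- c(absent, down$label[i])
      next
    }
    pc$downstream_orf <- down$label[i]
    al <- lapply(seq_len(nrow(pc)), function(j) {
      align_flanked(record, pc[j, ], cfg)
    })
    pc$flank_identity_nongap <- vapply(al, `[[`, numeric(1),
                                       "identity_nongap_percent")
    pc$flank_identity_all <- vapply(al, `[[`, numeric(1),
                                    "identity_all_percent")
    pc$flank_gap_columns <- vapply(al, `[[`, numeric(1), "gap_columns")
    sg <- predict_sg_mrnas(record, stats::setNames(down$start[i],
                                                   down$label[i]))
    pc$sg_mrna_body_len <- sg$body_segment_len
    pc$sg_mrna_kb <- sg$kb
    cands[[length(cands) + 1L]] <- pc
  }
  candidates <- if (length(cands)) do.call(rbind, cands) else
    data.frame()
  if (nrow(candidates) > 0L) {
    candidates <- candidates[order(-candidates$score,
                                   -candidates$matched_len,
                                   candidates$body_start), , drop = FALSE]
    rownames(candidates) <- NULL
  }
  structure(list(candidates = candidates, no_trs_orfs = absent,
                 repeat_library = flib),
            class = "trs_result")
}

#' @export
print.trs_result <- function(x, ...) {
  cat(sprintf("trs_result: %d candidate(s)\n",
              if (is.data.frame(x$candidates)) nrow(x$candidates) else 0L))
  if (is.data.frame(x$candidates) && nrow(x$candidates) > 0L) {
    print(utils::head(x$candidates[, c("downstream_orf", "leader_start",
                                       "leader_end", "body_start",
                                       "body_end", "matched_len",
                                       "identities", "sg_mrna_kb")], 10L))
  }
  if (length(x$no_trs_orfs) > 0L) {
    cat("no candidate TRS upstream of:", paste(x$no_trs_orfs,
                                               collapse = ", "), "\n")
  }
  invisible(x)
}
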