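#' Configuration for -1 frameshift signal scanning
#'
#' The heptamer library defaults to the invertebrate-nidovirus
#' (ronivirus) slippery sequence AAAUUUU plus common coronavirus- and
#' arterivirus-type heptamers; motifs may be given on the RNA or DNA
#' alphabet. Independently of the library, windows can be scored
#' against the generic slippery pattern XXXYYYZ (X, Y, Z free bases with
#' X != Y and Z != Y).
#'
#' @param heptamers Named character vector of 7-nt motifs.
#' @param use_xxxyyyz Also score the XXXYYYZ pattern class.
#' @param fold_window Length (nt) of the window folded downstream of the
#'   slippery site (default 190).
#' @param fold_offset Offset of the fold window start relative to the
#'   first position after the heptamer (default 0).
#' @param min_loop Minimum hairpin loop length for base pairing.
#' @param allow_GU Permit G-U wobble pairs.
#' @return A list of class `rfs_config`.
#' @export
rfs_config <- function(heptamers = c(ronivirus = "AAAUUUU",
                                     corona = "UUUAAAC",
                                     arteri = "GUUAAAC"),
                       use_xxxyyyz = TRUE, fold_window = 190L,
                       fold_offset = 0L, min_loop = 3L, allow_GU = TRUE) {
  heptamers <- vapply(heptamers, function(m) chartr("U", "T", toupper(m)),
                      character(1))
  if (any(nchar(heptamers) != 7L)) stop("heptamer motifs must be 7 nt")
  if (fold_window < 30L) stop("fold_window must be >= 30 nt")
  structure(
    list(heptamers = heptamers, use_xxxyyyz = isTRUE(use_xxxyyyz),
         fold_window = as.integer(fold_window),
         fold_offset = as.integer(fold_offset),
         min_loop = as.integer(min_loop), allow_GU = isTRUE(allow_GU)),
    class = "rfs_config"
  )
}

hamming7 <- function(win_chars, motif_chars) {
  # N never matches
  sum(win_chars != motif_chars | win_chars == "N" | motif_chars == "N")
}

xxxyyyz_hamming <- function(w) {
  # minimum substitutions to any XXXYYYZ instance with X != Y, Z != Y
  best <- 7L
  bases <- c("A", "C", "G", "T")
  for (x in bases) {
    mx <- 3L - sum(w[1:3] == x)
    for (y in bases[bases != x]) {
      my <- 3L - sum(w[4:6] == y)
      mz <- if (w[7L] != y && w[7L] != "N") 0L else 1L
      best <- min(best, mx + my + mz)
    }
  }
  best
}

#' Scan an ORF1a/ORF1b overlap for slippery heptamers
#'
#' Every 7-nt window inside the overlap is scored by Hamming distance
#' against each library motif and (optionally) against the generic
#' XXXYYYZ slippery pattern. Only windows compatible with the
#' frameshift geometry are kept: the window's last nucleotide is the
#' doubly-read nucleotide, decoded both as the third position of an
#' ORF1a-frame codon and as the first position of the first
#' ORF1b-frame codon, so its position must satisfy both frame
#' congruences. Sites are returned sorted by best Hamming distance,
#' then 5'-most position.
#'
#' @param record A [genome_record()].
#' @param overlap `c(start, end)` of the ORF1a/ORF1b intersection.
#' @param orf1a,orf1b Each `c(start, end)` (ORF1b in open mode: start =
#'   first in-frame position after the upstream stop). Their relative
#'   frame must be -1.
#' @param cfg An [rfs_config()].
#' @return A `data.frame` with `heptamer_start`, `heptamer_end`,
#'   `window`, `motif_matched` and `hamming` (best over both motif
#'   classes), `lib_motif`/`lib_hamming` (best library heptamer only),
#'   `xxxyyyz_hamming`, `doubly_read_pos`, `dist_to_orf1a_stop`,
#'   `dist_to_orf1b_upstream_stop`.
#' @export
scan_slippery <- function(record, overlap, orf1a, orf1b,
                          cfg = rfs_config()) {
  stopifnot(inherits(record, "genome_record"))
  a <- as_startend(orf1a); b <- as_startend(orf1b)
  ov <- as.integer(overlap[1:2])
  if (overlap_and_frame(a, b)$relative_frame != -1L) {
    stop("ORF1a/ORF1b overlap is not in the -1 relative frame")
  }
  if (ov[2L] - ov[1L] + 1L < 7L) stop("overlap shorter than 7 nt")
  ends <- seq.int(ov[1L] + 6L, ov[2L])
  # doubly-read nucleotide: 3rd position of an ORF1a codon AND 1st
  # position of an ORF1b-frame codon
  ok <- ((ends - a[1L] + 1L) %% 3L == 0L) & ((ends - b[1L]) %% 3L == 0L)
  ends <- ends[ok]
  if (length(ends) == 0L) {
    stop("no frame-compatible heptamer windows in the overlap")
  }
  motif_chars <- lapply(cfg$heptamers, function(m)
    strsplit(m, "", fixed = TRUE)[[1L]])
  rows <- lapply(ends, function(e) {
    w <- strsplit(subsequence(record, e - 6L, e), "", fixed = TRUE)[[1L]]
    hd <- vapply(motif_chars, function(mc) hamming7(w, mc), integer(1))
    xh <- if (cfg$use_xxxyyyz) xxxyyyz_hamming(w) else NA_integer_
    best_lib <- which.min(hd)
    if (!is.na(xh) && xh < hd[best_lib]) {
      motif <- "XXXYYYZ"; h <- xh
    } else {
      motif <- names(cfg$heptamers)[best_lib]; h <- hd[best_lib]
    }
    d <- stop_distances(e, a, b)
    data.frame(
      heptamer_start = e - 6L, heptamer_end = e,
      window = paste(w, collapse = ""),
      motif_matched = motif, hamming = h,
      lib_motif = names(cfg$heptamers)[best_lib],
      lib_hamming = hd[best_lib], xxxyyyz_hamming = xh,
      doubly_read_pos = e,
      dist_to_orf1a_stop = d$d_down_1a,
      dist_to_orf1b_upstream_stop = d$d_up_1b,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$hamming, out$heptamer_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distances from a frameshift site to the flanking stop codons
#'
#' @param doubly_read_pos 1-based genome position of the doubly-read
#'   nucleotide.
#' @param orf1a,orf1b Each `c(start, end)`.
#' @return List with `d_down_1a` (nt to the ORF1a stop downstream,
#'   `orf1a_end - pos`) and `d_up_1b` (nt from the upstream ORF1b-frame
#'   stop, `pos - orf1b_start`).
#' @export
stop_distances <- function(doubly_read_pos, orf1a, orf1b) {
  a <- as_startend(orf1a); b <- as_startend(orf1b)
  list(d_down_1a = a[2L] - as.integer(doubly_read_pos),
       d_up_1b = as.integer(doubly_read_pos) - b[1L])
}

#' Fold the window downstream of a slippery site
#'
#' Applies Nussinov base-pair maximization to the `fold_window`-nt
#' window starting immediately after the heptamer (plus
#' `cfg$fold_offset`); the window is truncated at the genome 3' end with
#' a warning. Only the nested-structure topology (pairs, stem count,
#' dot-bracket) is reported; no free-energy model is used, so the result
#' indicates stem-loop presence and shape, not thermodynamic stability.
#'
#' @param record A [genome_record()].
#' @param doubly_read_pos Position of the doubly-read nucleotide (the
#'   heptamer end).
#' @param cfg An [rfs_config()].
#' @return The [nussinov()] result plus `window_start`, `window_end`.
#' @export
fold_downstream <- function(record, doubly_read_pos, cfg = rfs_config()) {
  w_start <- as.integer(doubly_read_pos) + 1L + cfg$fold_offset
  w_end <- w_start + cfg$fold_window - 1L
  if (w_end > record$length) {
    warning("fold window truncated at the genome 3' end")
    w_end <- record$length
  }
  if (w_start > w_end) stop("fold window is empty")
  res <- nussinov(subsequence(record, w_start, w_end),
                  min_loop = cfg$min_loop, allow_GU = cfg$allow_GU)
  c(res, list(window_start = w_start, window_end = w_end))
}

#' Maximize base pairing in an RNA window (Nussinov algorithm)
#'
#' Dynamic-programming maximization of the number of nested
#' Watson-Crick (and optionally G-U wobble) base pairs, subject to a
#' minimum hairpin loop length. Pseudoknots are outside the model by
#' construction. The traceback prefers pairing the 5' base, then the
#' leftmost admissible partner, giving a deterministic structure among
#' co-optimal ones.
#'
#' @param seq Nucleotide string (DNA or RNA alphabet; `N` never pairs).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (`j - i - 1 >= min_loop`).
#' @param allow_GU Permit G-U (G-T) wobble pairs.
#' @return A list with `bp_count`, `pairs` (two-column matrix of 1-based
#'   indices, i < j), and `dotbracket`.
#' @examples
#' nussinov("GGGAAAACCC")$dotbracket  # "(((....)))"
#' @export
nussinov <- function(seq, min_loop = 3L, allow_GU = TRUE) {
  s <- chartr("U", "T", toupper(seq))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  pairs_ok <- function(x, y) {
    (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "C" & y == "G") | (x == "G" & y == "C") |
    (allow_GU & ((x == "G" & y == "T") | (x == "T" & y == "G")))
  }
  if (n == 0L) {
    return(list(bp_count = 0L, pairs = matrix(integer(0), ncol = 2L,
                                              dimnames = list(NULL,
                                                              c("i", "j"))),
                dotbracket = ""))
  }
  # DP over an (n+1) x (n+1) zero matrix so out-of-span lookups read 0
  Nmat <- matrix(0L, n + 1L, n + 1L)
  min_span <- min_loop + 1L  # j - i >= min_span  <=>  j - i - 1 >= min_loop
  if (n - 1L >= min_span) {
    for (span in seq.int(min_span, n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- Nmat[i + 1L, j]
        ks <- seq.int(i + min_span, j)
        can <- pairs_ok(ch[i], ch[ks])
        if (any(can)) {
          kk <- ks[can]
          cand <- 1L + Nmat[i + 1L, kk - 1L] + Nmat[kk + 1L, j]
          best <- max(best, max(cand))
        }
        Nmat[i, j] <- best
      }
    }
  }
  # traceback: prefer pairing the 5' base, then the leftmost partner
  pair_of <- integer(n)
  segments <- list(c(1L, n))
  while (length(segments) > 0L) {
    seg <- segments[[length(segments)]]
    segments[[length(segments)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    while (i < j && j - i >= min_span) {
      ks <- seq.int(i + min_span, j)
      can <- pairs_ok(ch[i], ch[ks])
      k_found <- 0L
      if (any(can)) {
        for (k in ks[can]) {
          if (1L + Nmat[i + 1L, k - 1L] + Nmat[k + 1L, j] == Nmat[i, j]) {
            k_found <- k
            break
          }
        }
      }
      if (k_found > 0L) {
        pair_of[i] <- k_found
        pair_of[k_found] <- i
        if (k_found + 1L <= j) {
          segments[[length(segments) + 1L]] <- c(k_found + 1L, j)
        }
        j <- k_found - 1L
        i <- i + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  idx <- which(pair_of > seq_len(n))
  pairs <- cbind(i = idx, j = pair_of[idx])
  db <- rep(".", n)
  db[pairs[, 1L]] <- "("
  db[pairs[, 2L]] <- ")"
  list(bp_count = Nmat[1L, n], pairs = pairs,
       dotbracket = paste(db, collapse = ""))
}
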