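# Independent brute-force oracles used to validate the package's
# dynamic-programming and scanning implementations on small inputs.

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# position-by-position ORF scan: walk codons in each frame
oracle_find_orfs <- function(seq, min_len, mode) {
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (f in 0:2) {
    pos <- 1L + f
    seg_start <- pos
    while (pos + 2L <= n) {
      codon <- substr(seq, pos, pos + 2L)
      if (codon %in% stops) {
        st <- NA_integer_
        if (mode == "open") {
          st <- seg_start
        } else {
          p <- seg_start
          while (p <= pos) {
            if (substr(seq, p, p + 2L) == "ATG") { st <- p; break }
            p <- p + 3L
          }
        }
        if (!is.na(st) && (pos + 2L - st + 1L) >= min_len) {
          res[[length(res) + 1L]] <- c(st, pos + 2L)
        }
        seg_start <- pos + 3L
      }
      pos <- pos + 3L
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("start", "end")
  out[order(out$start, out$end), , drop = FALSE]
}

# all-substring repeat oracle built on a character matrix; returns a
# canonical string set "unit@pos1,pos2,..."
oracle_repeats <- function(seq, min_unit = 4L, max_unit = 16L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  out <- character(0)
  for (L in min_unit:max_unit) {
    if (n - L + 1L < 2L) break
    starts <- seq_len(n - L + 1L)
    M <- vapply(0:(L - 1L), function(k) ch[starts + k],
                character(length(starts)))
    units <- apply(M, 1L, paste, collapse = "")
    tab <- table(units)
    for (u in names(tab)[tab >= 2L]) {
      if (grepl("N", u, fixed = TRUE)) next
      pos <- starts[units == u]
      if (L < max_unit) {
        left_ext <- pos[1L] > 1L &&
          length(unique(ch[pos - 1L])) == 1L && ch[pos[1L] - 1L] != "N"
        right_ext <- pos[length(pos)] + L <= n &&
          length(unique(ch[pos + L])) == 1L && ch[pos[1L] + L] != "N"
        if (left_ext || right_ext) next
      }
      # greedy 5' non-overlapping canonicalization
      keep <- integer(0); last_end <- -1L
      for (p in pos) {
        if (p > last_end) { keep <- c(keep, p); last_end <- p + L - 1L }
      }
      if (length(keep) >= 2L) {
        out <- c(out, paste0(u, "@", paste(keep, collapse = ",")))
      }
    }
  }
  sort(out)
}

repeat_library_as_strings <- function(lib) {
  sort(vapply(lib, function(r) {
    paste0(r$unit, "@", paste(r$positions, collapse = ","))
  }, character(1)))
}

# exhaustive enumeration of all nested structures (disjoint recursion:
# base i unpaired, or paired with each admissible k)
oracle_nussinov_max <- function(seq, min_loop = 3L, allow_GU = TRUE) {
  ch <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1L]]
  can <- function(x, y) {
    p <- paste0(x, y)
    p %in% c("AT", "TA", "CG", "GC") ||
      (allow_GU && p %in% c("GT", "TG"))
  }
  enum <- function(i, j) {
    if (i >= j || j - i < min_loop + 1L) return(0L)
    best <- enum(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (can(ch[i], ch[k])) {
        best <- max(best, 1L + enum(i + 1L, k - 1L) + enum(k + 1L, j))
      }
    }
    best
  }
  if (length(ch) < 2L) return(0L)
  enum(1L, length(ch))
}

# direct (non-log) evaluation of the product-of-binomials scan minimum
oracle_scan_min <- function(sizes, trait, p = mean(trait)) {
  u <- sort(unique(sizes))
  thr <- (u[-1L] + u[-length(u)]) / 2
  probs <- vapply(thr, function(t) {
    b <- sizes < t
    dbinom(sum(trait[b]), sum(b), p) * dbinom(sum(trait[!b]), sum(!b), p)
  }, numeric(1))
  list(min = min(probs),
       argmin = thr[which(probs <= min(probs) * (1 + 1e-9))[1L]],
       probs = probs)
}

# global alignment score oracle (same scoring scheme: match +1,
# mismatch -1, gap of length g costs 1 + g)
oracle_nw_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                  mismatch = -1)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 1, gapExtension = 1,
                                scoreOnly = TRUE)
}
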