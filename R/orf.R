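STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames on the forward strand
#'
#' Two ORF definitions are supported, reflecting the two ways large
#' nidovirus ORFs are expressed. In `"aug"` mode an ORF runs from the
#' 5'-most AUG of a stop-bounded open stretch to the last nucleotide of
#' its terminating stop codon. In `"open"` mode the whole stop-to-stop
#' open stretch is reported (start = first in-frame position after the
#' upstream stop, end = last nucleotide of the terminating stop); this is
#' the natural annotation for ORFs expressed by ribosomal frameshifting,
#' which need not begin with AUG.
#'
#' Stretches truncated by the sequence end (no terminating stop) are
#' excluded unless `include_truncated = TRUE`, in which case they appear
#' with `truncated = TRUE` and end at the last complete codon.
#'
#' @param record A [genome_record()].
#' @param min_len_nt Minimum ORF length in nucleotides (stop codon
#'   included); must be a positive multiple of 3.
#' @param mode `"aug"` or `"open"`.
#' @param include_truncated Include stretches without a terminating stop.
#' @return A `data.frame` with columns `label`, `start`, `end`,
#'   `length_nt`, `frame` (`(start - 1) %% 3`), `mode`, `truncated`,
#'   sorted by `start`.
#' @examples
#' r <- genome_record("AAATGAAATAAGG")
#' find_orfs(r, min_len_nt = 9, mode = "aug")  # one ORF at (3, 11)
#' @export
find_orfs <- function(record, min_len_nt = 300L,
                      mode = c("aug", "open"), include_truncated = FALSE) {
  stopifnot(inherits(record, "genome_record"))
  mode <- match.arg(mode)
  if (min_len_nt < 3L || min_len_nt %% 3L != 0L) {
    stop("min_len_nt must be a positive multiple of 3")
  }
  n <- record$length
  rows <- list()
  for (f in 0:2) {
    if (n - f < 3L) next
    codon_starts <- seq.int(1L + f, n - 2L, by = 3L)
    codons <- substring(record$seq, codon_starts, codon_starts + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)
    bounds <- c(0L, stop_idx)
    n_seg <- length(stop_idx) + if (include_truncated) 1L else 0L
    for (b in seq_len(n_seg)) {
      truncated <- b > length(stop_idx)
      first <- bounds[b] + 1L
      last <- if (truncated) length(codons) else stop_idx[b]
      if (last < first) next
      if (mode == "open") {
        start_pos <- codon_starts[first]
      } else {
        hit <- which(codons[first:last] == "ATG")
        if (length(hit) == 0L) next
        start_pos <- codon_starts[first + hit[1L] - 1L]
      }
      end_pos <- codon_starts[last] + 2L
      len <- end_pos - start_pos + 1L
      if (len < min_len_nt) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = start_pos, end = end_pos, length_nt = len,
        frame = (start_pos - 1L) %% 3L, mode = mode,
        truncated = truncated, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(label = character(), start = integer(),
                      end = integer(), length_nt = integer(),
                      frame = integer(), mode = character(),
                      truncated = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  cbind(label = sprintf("orf_%02d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Overlap length and relative reading frame of two ORFs
#'
#' The relative frame of `b` with respect to `a` is derived from
#' `(b_start - a_start) mod 3` and mapped onto the conventional
#' \{-1, 0, +1\} classes (`0 -> 0`, `1 -> +1`, `2 -> -1`), so that an
#' ORF1b-style overlap decoded by a -1 ribosomal frameshift reports
#' `relative_frame = -1`.
#'
#' @param a,b Each a numeric vector `c(start, end)` or a one-row
#'   `data.frame` with `start`/`end` columns.
#' @return A list with `overlap_len` (nt, 0 if disjoint) and
#'   `relative_frame`.
#' @examples
#' overlap_and_frame(c(361, 7869), c(7830, 15635))  # 40 nt, -1
#' @export
overlap_and_frame <- function(a, b) {
  a <- as_startend(a); b <- as_startend(b)
  ov <- max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]) + 1L)
  r <- (b[1L] - a[1L]) %% 3L
  list(overlap_len = as.integer(ov),
       relative_frame = c(0L, 1L, -1L)[r + 1L])
}

as_startend <- function(x) {
  if (is.data.frame(x)) c(as.integer(x$start[1L]), as.integer(x$end[1L]))
  else as.integer(x[1:2])
}

#' Delineate the untranslated regions flanking an ORF set
#'
#' The 5'-UTR spans from position 1 to one nucleotide before the 5'-most
#' ORF start; the 3'-UTR from one nucleotide after the 3'-most ORF end to
#' the genome end. A degenerate (empty) UTR is returned as a zero-length
#' marker with `end == start - 1`.
#'
#' @param record A [genome_record()].
#' @param orfs ORF table from [find_orfs()] (at least one row).
#' @return A list with `five_prime` and `three_prime`, each
#'   `c(start, end)`.
#' @export
delineate_utrs <- function(record, orfs) {
  stopifnot(inherits(record, "genome_record"), nrow(orfs) >= 1L)
  first_start <- min(orfs$start)
  last_end <- max(orfs$end)
  list(
    five_prime = c(start = 1L, end = as.integer(first_start - 1L)),
    three_prime = c(start = as.integer(last_end + 1L),
                    end = record$length)
  )
}

interval_length <- function(iv) max(0L, iv[["end"]] - iv[["start"]] + 1L)
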