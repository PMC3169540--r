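#' Configuration for TRS discovery
#'
#' Defaults follow the constrained-repeat procedure used for nidovirus
#' TRS candidates: perfect-repeat unit sizes from 4 up to 16 nt, a 300-nt
#' window immediately upstream of each downstream ORF for body copies,
#' and 20-nt flanks in the conservation alignment.
#'
#' @param min_unit Minimum perfect-repeat unit size (nt).
#' @param max_unit Maximum unit size (nt).
#' @param upstream_window Width of the body-TRS search window immediately
#'   upstream of a downstream ORF start (nt).
#' @param flank Flank width added on each side in the conservation
#'   alignment (nt).
#' @param max_mismatch_fraction Maximum mismatch fraction for a
#'   near-perfect leader/body pair.
#' @return A list with class `trs_config`.
#' @export
trs_config <- function(min_unit = 4L, max_unit = 16L,
                       upstream_window = 300L, flank = 20L,
                       max_mismatch_fraction = 0.15) {
  stopifnot(min_unit >= 2L, max_unit >= min_unit, flank >= 0L,
            upstream_window >= max_unit,
            max_mismatch_fraction >= 0, max_mismatch_fraction < 1)
  structure(
    list(min_unit = as.integer(min_unit), max_unit = as.integer(max_unit),
         upstream_window = as.integer(upstream_window),
         flank = as.integer(flank),
         max_mismatch_fraction = max_mismatch_fraction),
    class = "trs_config"
  )
}

#' Find maximal exact direct repeats
#'
#' Enumerates all same-strand exact repeats with unit length in
#' `[min_unit, max_unit]` and at least two occurrences. A unit is kept
#' only if it is *maximal*: its occurrence set cannot be extended with
#' identity on the left nor on the right (a sequence boundary blocks
#' extension; units already at `max_unit` are kept regardless, since the
#' library is capped at that size). Windows containing `N` never match.
#'
#' Tandem runs (e.g. poly-A) are canonicalized to the greedy 5'-most
#' non-self-overlapping occurrence set; units left with fewer than two
#' occurrences after canonicalization are dropped.
#'
#' @param record A [genome_record()].
#' @param cfg A [trs_config()].
#' @return A list of class `repeat_library`; each element has `unit`,
#'   `length` and `positions` (1-based starts). Elements are ordered by
#'   unit length (descending), then 5'-most occurrence.
#' @examples
#' lib <- find_perfect_repeats(genome_record("ACGTACGT"))
#' lib[[1]]$unit       # "ACGT"
#' lib[[1]]$positions  # 1 5
#' @export
find_perfect_repeats <- function(record, cfg = trs_config()) {
  stopifnot(inherits(record, "genome_record"))
  n <- record$length
  if (n < 2L * cfg$min_unit) stop("sequence shorter than 2 * min_unit")
  chars <- strsplit(record$seq, "", fixed = TRUE)[[1L]]
  out <- list()
  for (L in seq(cfg$max_unit, cfg$min_unit)) {
    if (n < L) next
    starts <- seq_len(n - L + 1L)
    units <- substring(record$seq, starts, starts + L - 1L)
    ok <- !grepl("N", units, fixed = TRUE)
    # restrict to units seen at least twice before grouping
    dup <- unique(units[ok][duplicated(units[ok])])
    sel <- ok & units %in% dup
    grp <- split(starts[sel], units[sel])
    if (length(grp) == 0L) next
    for (u in names(grp)) {
      pos <- grp[[u]]
      if (L < cfg$max_unit) {
        # extendable with identity on a side only if all occurrences share
        # a real (non-boundary, non-N) flanking base on that side
        left_ext <- if (pos[1L] > 1L) {
          lb <- chars[pos - 1L]
          all(lb == lb[1L]) && lb[1L] != "N"
        } else FALSE
        right_ext <- if (pos[length(pos)] + L <= n) {
          rb <- chars[pos + L]
          all(rb == rb[1L]) && rb[1L] != "N"
        } else FALSE
        if (left_ext || right_ext) next
      }
      pos <- greedy_nonoverlap(pos, L)
      if (length(pos) < 2L) next
      out[[length(out) + 1L]] <- list(unit = u, length = L, positions = pos)
    }
  }
  # deterministic ordering: unit length desc, then 5'-most occurrence
  if (length(out) > 1L) {
    first_pos <- vapply(out, function(x) x$positions[1L], numeric(1))
    lens <- vapply(out, function(x) x$length, numeric(1))
    out <- out[order(-lens, first_pos)]
  }
  structure(out, class = "repeat_library")
}

greedy_nonoverlap <- function(pos, L) {
  pos <- sort(pos)
  kept <- integer(0)
  last_end <- -1L
  for (p in pos) {
    if (p > last_end) {
      kept <- c(kept, p)
      last_end <- p + L - 1L
    }
  }
  kept
}

#' @export
print.repeat_library <- function(x, ...) {
  cat(sprintf("repeat_library: %d maximal repeat unit(s)\n", length(x)))
  for (r in utils::head(x, 10L)) {
    cat(sprintf("  %-18s len %2d  at %s\n", r$unit, r$length,
                paste(r$positions, collapse = ", ")))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Filter a repeat library by TRS positional constraints
#'
#' Retains repeats satisfying the leader/body arrangement of a
#' candidate TRS: at least one occurrence entirely 5' of the ORF1a start
#' (the leader region) and at least one occurrence entirely inside the
#' `upstream_window`-nt region immediately upstream of a downstream
#' ORF start. Retained occurrences are tagged with their region.
#'
#' @param lib A `repeat_library`.
#' @param orfs ORF table with columns `label`, `start`, `end`; must
#'   contain a row labelled `"ORF1a"` and at least one downstream ORF
#'   (any label other than `"ORF1a"`/`"ORF1b"`).
#' @param cfg A [trs_config()].
#' @return A `repeat_library` whose elements carry an extra `regions`
#'   data.frame (`position`, `region`).
#' @export
filter_positional <- function(lib, orfs, cfg = trs_config()) {
  stopifnot(inherits(lib, "repeat_library"), is.data.frame(orfs))
  if (!"ORF1a" %in% orfs$label) {
    stop("orfs must contain a row labelled 'ORF1a'")
  }
  orf1a_start <- orfs$start[orfs$label == "ORF1a"][1L]
  down <- orfs[!orfs$label %in% c("ORF1a", "ORF1b"), , drop = FALSE]
  if (nrow(down) == 0L) stop("no downstream ORFs in table")
  kept <- list()
  for (r in lib) {
    L <- r$length
    ends <- r$positions + L - 1L
    region <- rep(NA_character_, length(r$positions))
    region[ends < orf1a_start] <- "leader"
    for (i in seq_len(nrow(down))) {
      w_start <- down$start[i] - cfg$upstream_window
      w_end <- down$start[i] - 1L
      inside <- r$positions >= w_start & ends <= w_end
      region[inside] <- paste0("body:", down$label[i])
    }
    if (any(region == "leader", na.rm = TRUE) &&
        any(startsWith(region[!is.na(region)], "body:"))) {
      r$regions <- data.frame(position = r$positions, region = region,
                              stringsAsFactors = FALSE)
      kept[[length(kept) + 1L]] <- r
    }
  }
  structure(kept, class = "repeat_library")
}
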