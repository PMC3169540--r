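# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Protein-level features of a translated ORF
#'
#' Computes the residue-level statistics reported for virion proteins:
#' amino-acid composition (percentages), cysteine count, candidate
#' N-linked glycosylation sequons (N-X-S/T), and hydrophobic stretches
#' suggestive of transmembrane segments, detected as maximal runs of
#' sliding-window Kyte-Doolittle means above a threshold.
#'
#' The sequon definition excludes X = P by default (proline blocks
#' glycosylation); set `sequon_excludes_proline = FALSE` for the
#' unrestricted N-X-S/T motif.
#'
#' Because basic-residue percentages are sometimes quoted with and
#' sometimes without histidine, both `basic_kr_percent` (K+R) and
#' `basic_krh_percent` (K+R+H) are reported.
#'
#' @param aa Amino-acid string (no stop symbol).
#' @param hydro_window Sliding-window width for hydropathy (odd; default
#'   19, a typical transmembrane-helix span).
#' @param hydro_threshold Mean-hydropathy threshold (default 1.6).
#' @param sequon_excludes_proline Disallow proline at the sequon X
#'   position (default `TRUE`).
#' @return A list with `length_aa`, `composition` (named percent vector),
#'   `acidic_percent` (D+E), `basic_kr_percent`, `basic_krh_percent`,
#'   `cys_count`, `nxst_sites` (1-based positions of the N), and
#'   `hydrophobic_stretches` (data.frame of aa intervals).
#' @examples
#' protein_features("CCAC")$cys_count  # 3
#' @export
protein_features <- function(aa, hydro_window = 19L, hydro_threshold = 1.6,
                             sequon_excludes_proline = TRUE) {
  stopifnot(is.character(aa), length(aa) == 1L, nchar(aa) > 0L)
  chars <- strsplit(toupper(aa), "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(KD_SCALE))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue '%s' at position %d", chars[bad[1L]],
                 bad[1L]))
  }
  n <- length(chars)
  comp <- table(factor(chars, levels = names(KD_SCALE)))
  comp_pct <- 100 * as.vector(comp) / n
  names(comp_pct) <- names(KD_SCALE)

  # N-X-S/T sequons
  idx <- seq_len(max(0L, n - 2L))
  is_sequon <- chars[idx] == "N" & chars[idx + 2L] %in% c("S", "T")
  if (sequon_excludes_proline) {
    is_sequon <- is_sequon & chars[idx + 1L] != "P"
  }
  nxst <- idx[is_sequon]

  # hydrophobic stretches: maximal runs of above-threshold window means,
  # reported as the aa span covered by the qualifying windows
  stretches <- data.frame(start = integer(), end = integer(),
                          mean_kd = numeric())
  if (n >= hydro_window) {
    kd <- KD_SCALE[chars]
    cs <- c(0, cumsum(kd))
    win_starts <- seq_len(n - hydro_window + 1L)
    means <- (cs[win_starts + hydro_window] - cs[win_starts]) / hydro_window
    hot <- means > hydro_threshold
    if (any(hot)) {
      r <- rle(hot)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      keep <- which(r$values)
      stretches <- data.frame(
        start = win_starts[starts_i[keep]],
        end = win_starts[ends_i[keep]] + hydro_window - 1L,
        mean_kd = vapply(keep, function(k) {
          max(means[starts_i[k]:ends_i[k]])
        }, numeric(1))
      )
    }
  }

  list(
    length_aa = n,
    composition = comp_pct,
    acidic_percent = sum(comp_pct[c("D", "E")]),
    basic_kr_percent = sum(comp_pct[c("K", "R")]),
    basic_krh_percent = sum(comp_pct[c("K", "R", "H")]),
    cys_count = sum(chars == "C"),
    nxst_sites = nxst,
    hydrophobic_stretches = stretches
  )
}
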