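#' Annotate a nidovirus-like genome end to end
#'
#' Runs the full analysis in the natural order: ORF finding (AUG mode
#' plus open mode for frameshift-expressed ORFs), ORF labelling and UTR
#' delineation, TRS candidate discovery, -1 frameshift signal scanning
#' in the ORF1a/ORF1b overlap with downstream stem-loop folding, and
#' subgenomic mRNA size prediction.
#'
#' ORF labelling: ORF1a is the longest AUG-mode ORF; ORF1b is the
#' longest open-mode ORF that overlaps ORF1a in the -1 relative frame
#' and extends 3' of it; remaining AUG-mode ORFs 3' of ORF1b (or ORF1a
#' if there is no ORF1b) are labelled ORF2, ORF3, ... in genome order.
#' If the genome has no -1 frame overlap the frameshift section reports
#' "not applicable" and the run still succeeds.
#'
#' @param input Path to a FASTA file or a [genome_record()].
#' @param out_dir Optional output directory; when given, writes
#'   `annotation.gff3`, `orfs.tsv`, `trs_candidates.tsv`,
#'   `rfs_sites.tsv` and `summary.json`.
#' @param min_orf_nt Minimum ORF length (nt) for reported ORFs.
#' @param trs Optional [trs_config()].
#' @param rfs Optional [rfs_config()].
#' @return A list of class `nido_annotation` with elements `record_id`,
#'   `orfs`, `utrs`, `trs`, `rfs`, `sg_mrnas`, `proteins`, `log`.
#' @export
annotate <- function(input, out_dir = NULL, min_orf_nt = 300L,
                     trs = trs_config(), rfs = rfs_config()) {
  record <- if (inherits(input, "genome_record")) input else
    read_fasta(input)
  aug <- find_orfs(record, min_len_nt = min_orf_nt, mode = "aug")
  if (nrow(aug) == 0L) stop("no ORFs found at min_orf_nt = ", min_orf_nt)
  open <- find_orfs(record, min_len_nt = min_orf_nt, mode = "open")

  # label ORFs
  i1a <- which.max(aug$length_nt)
  orf1a <- aug[i1a, ]
  orf1b <- NULL
  if (nrow(open) > 0L) {
    cand <- open[open$start > orf1a$start & open$start <= orf1a$end &
                   open$end > orf1a$end, , drop = FALSE]
    if (nrow(cand) > 0L) {
      rel <- vapply(seq_len(nrow(cand)), function(i) {
        overlap_and_frame(orf1a, cand[i, ])$relative_frame
      }, integer(1))
      cand <- cand[rel == -1L, , drop = FALSE]
      if (nrow(cand) > 0L) orf1b <- cand[which.max(cand$length_nt), ]
    }
  }
  tail_from <- if (!is.null(orf1b)) orf1b$end else orf1a$end
  down <- aug[aug$start > tail_from, , drop = FALSE]
  orfs <- rbind(
    cbind(label = "ORF1a", orf1a[, c("start", "end", "length_nt",
                                     "frame", "mode")]),
    if (!is.null(orf1b)) {
      cbind(label = "ORF1b", orf1b[, c("start", "end", "length_nt",
                                       "frame", "mode")])
    },
    if (nrow(down) > 0L) {
      cbind(label = sprintf("ORF%d", 1L + seq_len(nrow(down))),
            down[, c("start", "end", "length_nt", "frame", "mode")])
    }
  )
  rownames(orfs) <- NULL
  utrs <- delineate_utrs(record, orfs)

  # protein-level features per ORF (sense codons only)
  proteins <- lapply(seq_len(nrow(orfs)), function(i) {
    cds <- subsequence(record, orfs$start[i], orfs$end[i])
    tr <- tryCatch(translate_cds(cds), error = function(e) NULL)
    if (is.null(tr) || nchar(tr$aa) == 0L) return(NULL)
    pf <- protein_features(tr$aa)
    pf$orf <- orfs$label[i]
    pf
  })
  proteins <- Filter(Negate(is.null), proteins)

  # TRS discovery needs a leader region and downstream ORFs
  trs_res <- if (orfs$start[1L] > 1L &&
                 any(!orfs$label %in% c("ORF1a", "ORF1b"))) {
    discover_trs(record, orfs, trs)
  } else {
    structure(list(candidates = data.frame(), no_trs_orfs = character(0),
                   repeat_library = structure(list(),
                                              class = "repeat_library")),
              class = "trs_result")
  }

  # frameshift signal
  rfs_res <- list(applicable = FALSE)
  if (!is.null(orf1b)) {
    ov <- c(orf1b$start, orf1a$end)
    sites <- scan_slippery(record, ov, orf1a, orf1b, rfs)
    best <- sites[1L, ]
    fold <- fold_downstream(record, best$doubly_read_pos, rfs)
    rfs_res <- list(applicable = TRUE, overlap = ov, sites = sites,
                    best = best, fold = fold)
  }

  sg <- if (any(!orfs$label %in% c("ORF1a", "ORF1b"))) {
    dn <- orfs[!orfs$label %in% c("ORF1a", "ORF1b"), ]
    predict_sg_mrnas(record, stats::setNames(dn$start, dn$label))
  } else NULL

  res <- structure(
    list(record_id = record$id, genome_length = record$length,
         orfs = orfs, utrs = utrs, trs = trs_res, rfs = rfs_res,
         sg_mrnas = sg, proteins = proteins,
         log = list(package_version =
                      as.character(utils::packageVersion("nidoscan")),
                    config_hash = rlang::hash(list(min_orf_nt, trs, rfs)),
                    input_checksum =
                      if (is.character(input)) unname(tools::md5sum(input))
                      else rlang::hash(record$seq))),
    class = "nido_annotation"
  )
  if (!is.null(out_dir)) write_annotation(res, record, out_dir)
  res
}

#' @export
print.nido_annotation <- function(x, ...) {
  cat(sprintf("annotation of '%s' (%d nt)\n", x$record_id,
              x$genome_length))
  print(x$orfs)
  cat(sprintf("5'-UTR (%d-%d), 3'-UTR (%d-%d)\n",
              x$utrs$five_prime[1L], x$utrs$five_prime[2L],
              x$utrs$three_prime[1L], x$utrs$three_prime[2L]))
  if (isTRUE(x$rfs$applicable)) {
    cat(sprintf("RFS: best heptamer %s (%s, hamming %d), doubly-read nt %d\n",
                x$rfs$best$window, x$rfs$best$motif_matched,
                x$rfs$best$hamming, x$rfs$best$doubly_read_pos))
  } else {
    cat("RFS: not applicable (no -1 frame ORF overlap)\n")
  }
  if (!is.null(x$sg_mrnas)) {
    cat("predicted sg mRNA body segments (kb):",
        paste(sprintf("%s=%.1f", x$sg_mrnas$label, x$sg_mrnas$kb),
              collapse = ", "), "\n")
  }
  invisible(x)
}

write_annotation <- function(res, record, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ft <- feature_table(
    seqid = record$id, type = "ORF",
    start = res$orfs$start, end = res$orfs$end,
    label = res$orfs$label
  )
  utr_rows <- feature_table(
    seqid = record$id, type = c("five_prime_UTR", "three_prime_UTR"),
    start = c(res$utrs$five_prime[1L], res$utrs$three_prime[1L]),
    end = c(res$utrs$five_prime[2L], res$utrs$three_prime[2L]),
    label = c("5UTR", "3UTR")
  )
  utr_rows <- utr_rows[utr_rows$start <= utr_rows$end, , drop = FALSE]
  ft <- rbind(ft, utr_rows)
  if (is.data.frame(res$trs$candidates) && nrow(res$trs$candidates) > 0L) {
    cc <- res$trs$candidates
    ft <- rbind(
      ft,
      feature_table(record$id, "TRS_leader", cc$leader_start,
                    cc$leader_end, label = cc$downstream_orf),
      feature_table(record$id, "TRS_body", cc$body_start, cc$body_end,
                    label = cc$downstream_orf)
    )
  }
  write_gff3(ft, file.path(out_dir, "annotation.gff3"))
  utils::write.table(res$orfs, file.path(out_dir, "orfs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.data.frame(res$trs$candidates) && nrow(res$trs$candidates) > 0L) {
    utils::write.table(res$trs$candidates,
                       file.path(out_dir, "trs_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (isTRUE(res$rfs$applicable)) {
    utils::write.table(res$rfs$sites, file.path(out_dir, "rfs_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(res$rfs$fold$dotbracket,
               file.path(out_dir, "rfs_fold.txt"))
  }
  summary <- list(
    record_id = res$record_id, genome_length = res$genome_length,
    orfs = res$orfs, utrs = res$utrs,
    trs_candidates = res$trs$candidates,
    no_trs_orfs = res$trs$no_trs_orfs,
    rfs = if (isTRUE(res$rfs$applicable)) {
      list(best = res$rfs$best, dotbracket = res$rfs$fold$dotbracket,
           bp_count = res$rfs$fold$bp_count)
    } else "not applicable",
    sg_mrnas = res$sg_mrnas, log = res$log
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the genome-size association test
#'
#' @param table A [lineage_table()] or path to a lineage TSV (columns
#'   `name`, `size_nt`, `trait`).
#' @param p Fixed success probability (default `k/n`).
#' @param permutations Number of trait-label permutations for the
#'   companion null (0 = none).
#' @param seed Seed for the permutation null.
#' @param out Optional path for a JSON report.
#' @return A list with the [scan_thresholds()] result and, if
#'   requested, the permutation p-value.
#' @export
sizetest <- function(table, p = NULL, permutations = 0L, seed = NULL,
                     out = NULL) {
  if (is.character(table)) table <- read_lineage_tsv(table)
  scan <- scan_thresholds(table, p)
  res <- list(
    n = scan$n, k = scan$k, p = scan$p,
    n_thresholds = length(scan$thresholds),
    thresholds = scan$thresholds, probs = scan$probs,
    min_prob = scan$min_prob,
    argmin_threshold = scan$argmin_threshold,
    argmin_interval = as.list(scan$argmin_interval),
    power_of_ten = scan$power_of_ten
  )
  if (permutations > 0L) {
    pn <- permutation_null(table, n_perm = permutations, seed = seed)
    res$permutation_p_value <- pn$p_value
    res$permutations <- permutations
  }
  if (!is.null(out)) {
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  res
}
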