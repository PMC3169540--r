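#' A named nucleotide sequence with a fixed coordinate contract
#'
#' `genome_record()` wraps a single nucleotide sequence together with its
#' identifier and records which alphabet it arrived in. Internally the
#' sequence is always stored on the DNA alphabet (`U` is mapped to `T`),
#' so repeat and motif comparisons downstream operate on a single alphabet
#' regardless of whether the input was written as DNA or RNA. All public
#' coordinates throughout the package are 1-based and inclusive, matching
#' the GenBank convention, so printed genome coordinates can be used
#' verbatim.
#'
#' IUPAC ambiguity codes other than `N` are collapsed to `N` (with a
#' warning); `N` never matches in repeat or heptamer comparisons. Any
#' character outside the IUPAC nucleotide set is an error.
#'
#' @param seq Character scalar, the nucleotide sequence (case-insensitive).
#' @param id Sequence identifier.
#' @return An object of class `genome_record` with fields `id`, `seq`
#'   (normalized, `A/C/G/T/N`), `length` and `source_alphabet`
#'   (`"DNA"` or `"RNA"`).
#' @examples
#' gr <- genome_record("AUGC", id = "x")
#' gr$seq             # "ATGC"
#' gr$source_alphabet # "RNA"
#' @export
genome_record <- function(seq, id = "genome") {
  stopifnot(is.character(seq), length(seq) == 1L, is.character(id))
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  iupac <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  bad <- which(!chars %in% iupac)
  if (length(bad) > 0L) {
    stop(sprintf("non-IUPAC nucleotide character '%s' at position %d of '%s'",
                 chars[bad[1L]], bad[1L], id))
  }
  alphabet <- if (any(chars == "U")) "RNA" else "DNA"
  ambig <- chars %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  if (any(ambig)) {
    warning(sprintf("%d ambiguity code(s) collapsed to N in '%s'",
                    sum(ambig), id))
    chars[ambig] <- "N"
  }
  chars[chars == "U"] <- "T"
  s <- paste(chars, collapse = "")
  structure(
    list(id = id, seq = s, length = nchar(s), source_alphabet = alphabet),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record '%s': %d nt (%s input)\n",
              x$id, x$length, x$source_alphabet))
  head <- substr(x$seq, 1L, min(60L, x$length))
  cat(" ", head, if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Render a genome record back on its source alphabet
#'
#' @param record A [genome_record()].
#' @return The sequence as a character scalar; `T` is rendered as `U`
#'   when the record was read from RNA.
#' @export
as_source_alphabet <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  if (identical(record$source_alphabet, "RNA")) {
    chartr("T", "U", record$seq)
  } else {
    record$seq
  }
}

#' Read a genome from a FASTA file
#'
#' Reads a (single- or multi-record) FASTA file and returns one record as
#' a [genome_record()]. For multi-record files the record is selected by
#' `id`; with `id = NULL` the first record is used and a warning is
#' emitted. The record id is the first whitespace-delimited token of the
#' FASTA header.
#'
#' @param path Path to a FASTA file.
#' @param id Optional record id to select from a multi-record file.
#' @return A [genome_record()].
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (is.null(id)) {
    if (length(set) > 1L) {
      warning(sprintf("multi-record FASTA; using first record '%s'", ids[1L]))
    }
    idx <- 1L
  } else {
    idx <- match(id, ids)
    if (is.na(idx)) stop(sprintf("record '%s' not found in %s", id, path))
  }
  genome_record(as.character(set[[idx]]), id = ids[idx])
}

#' Write a genome record to a FASTA file
#'
#' @param record A [genome_record()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @param alphabet `"internal"` writes the normalized DNA-alphabet
#'   sequence; `"source"` renders the record on its input alphabet.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(record, path, width = 70L,
                        alphabet = c("internal", "source")) {
  stopifnot(inherits(record, "genome_record"))
  alphabet <- match.arg(alphabet)
  s <- if (alphabet == "source") as_source_alphabet(record) else record$seq
  starts <- seq.int(1L, nchar(s), by = width)
  lines <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
  writeLines(c(paste0(">", record$id), lines), con = path)
  invisible(path)
}

#' Extract a subsequence by 1-based inclusive coordinates
#'
#' @param record A [genome_record()].
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` returns the forward sequence; `"-"` its reverse
#'   complement.
#' @return A nucleotide string of length `end - start + 1`.
#' @examples
#' r <- genome_record("ACGTAC")
#' subsequence(r, 2, 4)        # "CGT"
#' subsequence(r, 2, 4, "-")   # "ACG"
#' @export
subsequence <- function(record, start, end, strand = "+") {
  stopifnot(inherits(record, "genome_record"))
  if (!(start >= 1L && start <= end && end <= record$length)) {
    stop(sprintf("interval (%d,%d) out of range for '%s' (1..%d)",
                 start, end, record$id, record$length))
  }
  s <- substr(record$seq, start, end)
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

#' Reverse-complement a nucleotide string
#'
#' @param seq Nucleotide string on the `A/C/G/T/N` (or RNA) alphabet.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTUN", "TGCAAN", toupper(seq))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a coding sequence under the standard genetic code
#'
#' Translates an in-frame CDS. A terminal stop codon is excluded from the
#' returned amino-acid string and reported through the `stop_included`
#' flag; an internal stop codon is an error, as is a length not divisible
#' by three.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return A list with `aa` (amino-acid string, no stop symbol) and
#'   `stop_included` (logical).
#' @examples
#' translate_cds("ATGAAATAG")  # aa = "MK", stop_included = TRUE
#' @export
translate_cds <- function(cds) {
  cds <- chartr("U", "T", toupper(cds))
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3, got ", n)
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  if (anyNA(aa)) {
    # codons containing N or other non-ACGT letters are untranslatable
    bad <- which(is.na(aa))[1L]
    stop(sprintf("untranslatable codon '%s' at codon %d", codons[bad], bad))
  }
  internal_stop <- which(aa[-length(aa)] == "*")
  if (length(internal_stop) > 0L) {
    stop(sprintf("internal stop codon at codon %d", internal_stop[1L]))
  }
  stop_included <- aa[length(aa)] == "*"
  if (stop_included) aa <- aa[-length(aa)]
  list(aa = paste(aa, collapse = ""), stop_included = stop_included)
}
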