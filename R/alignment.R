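#' Multiple alignments
#'
#' An alignment is an ordered set of equal-length gapped amino-acid
#' sequences with unique identifiers. Gap characters `'.'` and `'-'` are
#' accepted on input and normalized to `'-'`.
#'
#' @param seqs named character vector of gapped sequences, in row order.
#' @return An object of class `alignment`: the named character vector with a
#'   `width` attribute.
#' @export
alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) {
    stop_archnet(sprintf("duplicate sequence id(s): %s",
                         paste(unique(names(seqs)[duplicated(names(seqs))]),
                               collapse = ", ")),
                 "archnet_format_error")
  }
  seqs <- chartr(".", "-", toupper(seqs))
  w <- unique(nchar(seqs))
  if (length(seqs) > 0L && length(w) != 1L) {
    off <- names(seqs)[nchar(seqs) != nchar(seqs)[1]][1]
    stop_archnet(
      sprintf("sequences are not all the same length (first offender: %s)",
              off),
      "archnet_format_error"
    )
  }
  structure(seqs, width = if (length(seqs)) w else 0L, class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d sequence(s) x %d column(s)\n",
              length(x), attr(x, "width")))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[i]
    shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
    cat(sprintf("  %-20s %s\n", names(x)[i], shown))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' Read a multiple alignment (aligned FASTA or Stockholm)
#'
#' The format is taken from `format`, or guessed from the first
#' non-blank line (`# STOCKHOLM` header vs FASTA `>`). Parsing is done with
#' Biostrings; rows keep file order, `'.'` gaps are normalized to `'-'`, and
#' unequal sequence lengths raise an error naming the offending record.
#'
#' @param path path to the alignment file.
#' @param format `"auto"`, `"fasta"` or `"stockholm"`.
#' @return An [alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    format <- if (length(first) > 0L && grepl("^#\\s*STOCKHOLM", first[1])) {
      "stockholm"
    } else {
      "fasta"
    }
  }
  if (format == "fasta") {
    aa <- Biostrings::readBStringSet(path, format = "fasta")
    seqs <- as.character(aa)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    seqs <- as.character(Biostrings::unmasked(aln))
  }
  alignment(seqs)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an [alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", names(aln)), unclass(aln)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
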