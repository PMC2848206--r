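#' Residue-class schemes for consensus annotation
#'
#' A scheme is an ordered list of (symbol, residue set) classes plus a
#' consensus threshold. A column is annotated with a single uppercase
#' residue if one residue reaches the threshold, otherwise with the symbol
#' of the first class (in stored order) whose members jointly reach it,
#' otherwise with `'.'`. Gaps always count in the denominator, so a mostly
#' gapped column cannot reach consensus.
#'
#' The default classes follow the convention used for annotating protein
#' superfamily alignments: `h` hydrophobic, `l` aliphatic, `s` small,
#' `p` polar, evaluated most-specific first (`l`, `s`, `p`, then the broad
#' `h`).
#'
#' @param classes named list mapping class symbol -> character vector of
#'   residues, in evaluation order.
#' @param threshold consensus threshold, a proportion in (0.5, 1].
#' @return An object of class `residue_scheme`.
#' @export
residue_scheme <- function(classes = list(
                             l = c("I", "L", "V"),
                             s = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
                             p = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T"),
                             h = c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
                           ),
                           threshold = 0.7) {
  stopifnot(is.list(classes), !is.null(names(classes)),
            !anyDuplicated(names(classes)),
            threshold > 0.5, threshold <= 1)
  classes <- lapply(classes, function(x) toupper(as.character(x)))
  structure(list(classes = classes, threshold = threshold,
                 gap_symbol = "."),
            class = "residue_scheme")
}

#' @export
print.residue_scheme <- function(x, ...) {
  cat(sprintf("Residue-class scheme (threshold %.2f):\n", x$threshold))
  for (s in names(x$classes)) {
    cat(sprintf("  %s = {%s}\n", s, paste(x$classes[[s]], collapse = "")))
  }
  invisible(x)
}

#' Read a residue-class scheme from YAML
#'
#' The file maps each class symbol to a string of residues and may carry
#' `order` (evaluation order of the symbols) and `threshold` keys:
#' ```yaml
#' threshold: 0.7
#' order: [l, s, p, h]
#' classes:
#'   h: ACFILMVWY
#'   l: ILV
#'   s: ACDGNPSTV
#'   p: CDEHKNQRST
#' ```
#'
#' @param path path to the YAML file.
#' @return A [residue_scheme()].
#' @export
read_residue_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$classes)) {
    stop_archnet("scheme file has no 'classes' mapping",
                 "archnet_format_error")
  }
  cls <- lapply(y$classes, function(s) strsplit(toupper(s), "")[[1]])
  ord <- y$order %||% names(cls)
  missing <- setdiff(ord, names(cls))
  if (length(missing) > 0L) {
    stop_archnet(sprintf("order refers to undefined class(es): %s",
                         paste(missing, collapse = ", ")),
                 "archnet_format_error")
  }
  residue_scheme(cls[ord], threshold = y$threshold %||% 0.7)
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Consensus symbol of one alignment column
#'
#' With `n` rows (gaps included in the count): a residue occurring in at
#' least `threshold * n` rows gives that residue, uppercase; otherwise the
#' first class in scheme order whose members jointly occur in at least
#' `threshold * n` rows gives its lowercase symbol; otherwise `'.'`.
#'
#' @param column character vector of single residues/gaps, one per row.
#' @param scheme a [residue_scheme()].
#' @return A single consensus symbol.
#' @examples
#' column_consensus(strsplit("LIVLIVLAGC", "")[[1]])  # aliphatic -> "l"
#' @export
column_consensus <- function(column, scheme = residue_scheme()) {
  stopifnot(length(column) >= 1L)
  column <- chartr(".", "-", toupper(column))
  bad <- setdiff(unique(column), c(AA_ALPHABET, "-"))
  if (length(bad) > 0L) {
    stop_archnet(sprintf("non-amino-acid character '%s' in column", bad[1]),
                 "archnet_bad_residue")
  }
  n <- length(column)
  need <- scheme$threshold * n - 1e-9
  counts <- table(column[column != "-"])
  if (length(counts) > 0L) {
    top <- names(counts)[which.max(counts)]
    if (max(counts) >= need) return(top)
    for (sym in names(scheme$classes)) {
      members <- intersect(scheme$classes[[sym]], names(counts))
      if (sum(counts[members]) >= need) return(sym)
    }
  }
  scheme$gap_symbol
}

#' Residue-class consensus line of an alignment
#'
#' Applies [column_consensus()] to every column, producing the annotation
#' string printed beneath superfamily alignments: uppercase letters mark
#' columns conserving a single residue, lowercase class symbols (`h`, `l`,
#' `s`, `p` by default) mark columns conserving a residue class, and `'.'`
#' marks unconserved or gap-dominated columns.
#'
#' @param aln an [alignment()], non-empty.
#' @param scheme a [residue_scheme()].
#' @return A single string of length equal to the alignment width, with
#'   class `consensus_line`.
#' @export
consensus_line <- function(aln, scheme = residue_scheme()) {
  stopifnot(inherits(aln, "alignment"), length(aln) >= 1L)
  mat <- do.call(rbind, strsplit(unclass(aln), ""))
  syms <- vapply(seq_len(ncol(mat)), function(j) {
    tryCatch(column_consensus(mat[, j], scheme),
             archnet_bad_residue = function(e) {
               stop_archnet(sprintf("column %d: %s", j, conditionMessage(e)),
                            "archnet_bad_residue")
             })
  }, character(1))
  structure(paste(syms, collapse = ""), class = "consensus_line")
}

#' @export
print.consensus_line <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}
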