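#' Architecture sets: ordered domain architectures with metadata
#'
#' An architecture is one protein's ordered (N-terminal to C-terminal) list
#' of globular domain names, together with a protein identifier, an organism
#' abbreviation and a lineage label. Non-globular linkers between domains are
#' not represented: positional distance along an architecture is counted over
#' domain tokens only. An architecture set is a collection of such records;
#' it may contain duplicates (the same ordered domain tuple observed in
#' different proteins) and is never deduplicated implicitly --
#' [distinct_architectures()] is the explicit operation.
#'
#' @param protein_id character vector of protein identifiers.
#' @param organism character vector of organism abbreviations (e.g. "Dmel").
#' @param lineage character vector of lineage labels (e.g. "Bacteria",
#'   "Metazoa").
#' @param domains list of character vectors, each the ordered domain names of
#'   one protein, or a single character vector for a one-record set.
#' @param provenance free-text label describing where the set came from.
#'
#' @return An object of class `arch_set`: a data frame with columns
#'   `protein_id`, `organism`, `lineage` and a list-column `domains`, plus a
#'   `provenance` attribute.
#' @examples
#' archs <- arch_set(
#'   protein_id = c("Oskar", "TDRD7"),
#'   organism   = c("Dmel", "Hsap"),
#'   lineage    = c("Metazoa", "Metazoa"),
#'   domains    = list(c("OST-HTH", "SGNH"), c("Tudor", "OST-HTH"))
#' )
#' archs
#' @export
arch_set <- function(protein_id, organism, lineage, domains,
                     provenance = "in-memory") {
  if (is.character(domains)) domains <- list(domains)
  stopifnot(length(protein_id) == length(domains))
  organism <- rep_len(as.character(organism), length(protein_id))
  lineage <- rep_len(as.character(lineage), length(protein_id))
  for (i in seq_along(domains)) {
    toks <- domains[[i]]
    if (length(toks) == 0L || any(!nzchar(toks))) {
      stop_archnet(
        sprintf("record %d (%s): empty domain list or empty domain token",
                i, protein_id[i]),
        "archnet_row_error"
      )
    }
    if (any(grepl(";", toks, fixed = TRUE))) {
      stop_archnet(
        sprintf("record %d (%s): ';' is reserved as the domain separator",
                i, protein_id[i]),
        "archnet_row_error"
      )
    }
  }
  out <- data.frame(
    protein_id = as.character(protein_id),
    organism   = as.character(organism),
    lineage    = as.character(lineage),
    stringsAsFactors = FALSE
  )
  out$domains <- domains
  attr(out, "provenance") <- provenance
  class(out) <- c("arch_set", class(out))
  out
}

#' @export
print.arch_set <- function(x, ...) {
  cat(sprintf("Architecture set: %d record(s), %d distinct architecture(s)\n",
              nrow(x), length(unique(vapply(x$domains, arch_signature, "")))))
  cat(sprintf("provenance: %s\n", attr(x, "provenance") %||% "unknown"))
  n <- min(nrow(x), 8L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s [%s/%s]  %s\n", x$protein_id[i], x$organism[i],
                x$lineage[i], arch_signature(x$domains[[i]])))
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Read a domain-architecture table
#'
#' Reads a tab-separated architecture table with header columns
#' `protein_id`, `organism`, `lineage`, `domains`. The `domains` cell is the
#' semicolon-separated ordered domain list, N-terminal first. Blank lines and
#' lines starting with `#` are skipped. Extra columns (e.g. optional
#' start-end coordinate annotations) are accepted and ignored. Row order and
#' domain order are preserved exactly; duplicate architectures are kept.
#'
#' @param path path to a TSV file (UTF-8).
#' @return An [arch_set()] with one record per data row.
#' @seealso [write_architectures()] for the inverse operation.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\torganism\tlineage\tdomains",
#'              "Oskar\tDmel\tMetazoa\tOST-HTH;SGNH"), tsv)
#' read_architectures(tsv)
#' @export
read_architectures <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", blank.lines.skip = TRUE,
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8",
                           check.names = FALSE)
  required <- c("protein_id", "organism", "lineage", "domains")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop_archnet(
      sprintf("architecture table %s is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "archnet_format_error"
    )
  }
  doms <- strsplit(tab$domains, ";", fixed = TRUE)
  bad <- which(!nzchar(tab$domains) |
                 vapply(doms, function(d) any(!nzchar(d)) || length(d) == 0L,
                        logical(1)))
  if (length(bad) > 0L) {
    stop_archnet(
      sprintf("row %d of %s: empty domain list", bad[1], path),
      "archnet_row_error"
    )
  }
  arch_set(tab$protein_id, tab$organism, tab$lineage, doms,
           provenance = path)
}

#' Write a domain-architecture table
#'
#' Writes an architecture set as the canonical TSV understood by
#' [read_architectures()]: tab-separated columns `protein_id`, `organism`,
#' `lineage`, `domains` (semicolon-joined), one row per record in input
#' order. `read_architectures(write_architectures(x))` reproduces `x`.
#'
#' @param archs an [arch_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_architectures <- function(archs, path) {
  lines <- c(
    "protein_id\torganism\tlineage\tdomains",
    if (nrow(archs) > 0L) {
      paste(archs$protein_id, archs$organism, archs$lineage,
            vapply(archs$domains, arch_signature, ""), sep = "\t")
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
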