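#' Phyletic presence matrix of architecture families across lineages
#'
#' Tallies how many records of each architecture family occur in each
#' lineage. By default a family is the exact architecture signature
#' (semicolon-joined ordered domain list); a `families` mapping can merge
#' signatures into named families (e.g. grouping every LK-nuclease+OST-HTH
#' variant into one family to ask whether it occurs in both bacteria and
#' eukaryotes).
#'
#' @param archs an [arch_set()].
#' @param families optional named character vector mapping architecture
#'   signature -> family label. Signatures not named fall back to
#'   themselves if `strict = FALSE`; with `strict = TRUE` an unmapped record
#'   is an error naming its protein_id.
#' @param strict require every record's signature to be mapped?
#' @return An integer matrix of class `phyletic_matrix` with one row per
#'   family and one column per lineage, both sorted alphabetically for
#'   determinism. The cells sum to the record count.
#' @export
phyletic_matrix <- function(archs, families = NULL, strict = !is.null(families)) {
  sigs <- vapply(archs$domains, arch_signature, "")
  fam <- sigs
  if (!is.null(families)) {
    hit <- sigs %in% names(families)
    if (isTRUE(strict) && any(!hit)) {
      stop_archnet(
        sprintf("record(s) with unmapped architecture: %s",
                paste(archs$protein_id[!hit], collapse = ", ")),
        "archnet_unmapped_family"
      )
    }
    fam[hit] <- unname(families[sigs[hit]])
  }
  if (length(fam) == 0L) {
    m <- matrix(integer(), 0L, 0L)
  } else {
    m <- table(family = fam, lineage = archs$lineage)
    m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
    m <- m[order(rownames(m), method = "radix"),
           order(colnames(m), method = "radix"), drop = FALSE]
  }
  structure(m, class = c("phyletic_matrix", class(m)))
}

#' Compact presence/absence pattern of one family
#'
#' @param m a [phyletic_matrix()].
#' @param family a family (row) label present in the matrix.
#' @return A string of `'+'`/`'-'` over the matrix's lineage order.
#' @examples
#' archs <- arch_set(c("a", "b"), "?", c("Bacteria", "Metazoa"),
#'                   list(c("LK-nuclease", "OST-HTH"),
#'                        c("LK-nuclease", "OST-HTH")))
#' m <- phyletic_matrix(archs)
#' pattern_string(m, "LK-nuclease;OST-HTH")
#' @export
pattern_string <- function(m, family) {
  stopifnot(inherits(m, "phyletic_matrix"))
  if (!family %in% rownames(m)) {
    stop_archnet(sprintf("unknown family '%s'", family),
                 "archnet_unknown_family")
  }
  paste(ifelse(m[family, ] > 0L, "+", "-"), collapse = "")
}
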