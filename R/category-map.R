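#' Functional-category maps for partner domains
#'
#' A category map assigns each domain name one or more functional-category
#' labels. The default vocabulary mirrors the three recurring themes in
#' OST-HTH domain architectures: `"RNA-binding"` (single- and double-stranded
#' RNA-binding partners such as RRM, KH, CCCH, the S1/cold-shock OB fold,
#' dsRBD and Zn-knuckles), `"anchoring"` (protein-protein or lipid
#' interaction modules that could tether the protein to cytoskeletal
#' structures, modified RNP proteins or membranes: Tudor, WW, Ankyrin, MORN,
#' the inactive SGNH hydrolase, Sfi1), and `"Ub-system"` (ubiquitin E3 ligase
#' folds, Ub-binding Zn-ribbons and ubiquitin-like domains). Any domain not
#' listed falls in the residual category `"other"`.
#'
#' @param entries named list: domain name -> character vector of categories.
#' @param categories the label vocabulary. Labels used in `entries` but not
#'   declared here are kept with a warning (open vocabulary).
#' @return An object of class `category_map`.
#' @seealso [read_category_map()], [default_category_map()],
#'   [domain_categories()].
#' @export
category_map <- function(entries,
                         categories = c("RNA-binding", "anchoring",
                                        "Ub-system", "other")) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  used <- unique(unlist(entries, use.names = FALSE))
  extra <- setdiff(used, categories)
  if (length(extra) > 0L) {
    warning(sprintf("category label(s) outside the declared vocabulary kept: %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
    categories <- c(categories, extra)
  }
  structure(list(entries = entries, categories = categories),
            class = "category_map")
}

#' @export
print.category_map <- function(x, ...) {
  cat(sprintf("Category map: %d domain(s), vocabulary {%s}\n",
              length(x$entries), paste(x$categories, collapse = ", ")))
  invisible(x)
}

#' Read a domain-to-category table
#'
#' Reads a two-column TSV (`domain`, `category`), one row per
#' (domain, category) pair; a domain listed under several categories carries
#' all of them. Lines starting with `#` are skipped.
#'
#' @param path path to the TSV file.
#' @param categories declared label vocabulary; see [category_map()].
#' @return A `category_map`.
#' @export
read_category_map <- function(path,
                              categories = c("RNA-binding", "anchoring",
                                             "Ub-system", "other")) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", colClasses = "character",
                           quote = "", fileEncoding = "UTF-8")
  missing <- setdiff(c("domain", "category"), names(tab))
  if (length(missing) > 0L) {
    stop_archnet(
      sprintf("category table %s is missing required column(s): %s",
              path, paste(missing, collapse = ", ")),
      "archnet_format_error"
    )
  }
  entries <- lapply(split(tab$category, tab$domain), unique)
  category_map(entries, categories = categories)
}

#' Look up the categories of a domain
#'
#' @param cmap a [category_map()].
#' @param domain a single domain name.
#' @return Character vector of category labels; `"other"` for any domain the
#'   map does not list.
#' @examples
#' cm <- default_category_map()
#' domain_categories(cm, "RRM")
#' domain_categories(cm, "DUF2384")  # unlisted -> "other"
#' @export
domain_categories <- function(cmap, domain) {
  stopifnot(inherits(cmap, "category_map"), length(domain) == 1L)
  cmap$entries[[domain]] %||% "other"
}

#' The packaged default category map
#'
#' Loads the domain grouping shipped with the package
#' (`inst/extdata/category_map.tsv`), which assigns the OST-HTH partner
#' domains to the three functional themes described in
#' [category_map()].
#'
#' @return A `category_map`.
#' @export
default_category_map <- function() {
  read_category_map(system.file("extdata", "category_map.tsv",
                                package = "archnet", mustWork = TRUE))
}
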