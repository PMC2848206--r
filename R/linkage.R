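#' Domains within a positional distance of a focal domain
#'
#' Along one architecture (an ordered domain tuple), returns the set of
#' domain names found within `max_sep` positions of any occurrence of the
#' focal domain. Distance 1 is an immediate neighbor; distance 2 a neighbor
#' one removed (one intervening domain). Both the N- and C-terminal sides
#' count. Occurrences of the focal domain itself are never reported as
#' neighbors, so tandem focal repeats do not self-link.
#'
#' @param domains character vector, one architecture's ordered domain names.
#' @param focal the focal domain name; must occur in `domains`.
#' @param max_sep maximum positional distance (>= 1).
#' @return Character vector of neighboring domain names (unique, sorted).
#' @examples
#' neighbors_within(c("RRM", "Tudor", "OST-HTH"), "OST-HTH", 2)
#' @export
neighbors_within <- function(domains, focal, max_sep = 2L) {
  stopifnot(length(focal) == 1L, max_sep >= 1L)
  occ <- which(domains == focal)
  if (length(occ) == 0L) {
    stop_archnet(
      sprintf("focal domain '%s' does not occur in architecture '%s'",
              focal, arch_signature(domains)),
      "archnet_focal_absent"
    )
  }
  idx <- unique(as.vector(outer(occ, c(-(seq_len(max_sep)), seq_len(max_sep)),
                                `+`)))
  idx <- idx[idx >= 1L & idx <= length(domains)]
  sort(setdiff(unique(domains[idx]), focal), method = "radix")
}

#' Neighborhood-linkage fraction of a focal domain for one category
#'
#' The central statistic of the package: among the distinct architectures
#' that contain the focal domain, the fraction in which at least one domain
#' of the given functional category lies within `max_sep` positions of some
#' focal occurrence. With the OST-HTH corpus and the default category map
#' this is the quantity reported as "70% of the distinct architectures have
#' an RNA-binding immediate neighbor or neighbor-one-removed".
#'
#' @param archs an [arch_set()].
#' @param focal focal domain name; must occur in at least one architecture.
#' @param cmap a [category_map()].
#' @param category one label from the map's vocabulary.
#' @param max_sep maximum positional distance (default 2: immediate neighbor
#'   or neighbor one removed).
#' @param distinct if `TRUE` (default) the unit of analysis is the distinct
#'   architecture; if `FALSE`, every record counts, so the fraction is the
#'   per-record (per-protein) linkage probability. The per-record form is the
#'   one whose estimate is binomially distributed under the synthetic
#'   generator.
#' @param collapse_repeats passed to [distinct_architectures()].
#' @return An object of class `linkage_result`: list with `focal`,
#'   `category`, `max_sep`, `n_distinct` (architectures containing focal),
#'   `n_linked` and `fraction = n_linked / n_distinct`.
#' @examples
#' archs <- arch_set(c("a", "b"), "?", "?",
#'                   list(c("RRM", "OST-HTH"), c("OST-HTH", "Tudor")))
#' linkage_fraction(archs, "OST-HTH", default_category_map(), "RNA-binding")
#' @export
linkage_fraction <- function(archs, focal, cmap, category, max_sep = 2L,
                             distinct = TRUE, collapse_repeats = FALSE) {
  stopifnot(inherits(cmap, "category_map"))
  if (!category %in% cmap$categories) {
    stop_archnet(
      sprintf("unknown category '%s'; known labels: %s", category,
              paste(cmap$categories, collapse = ", ")),
      "archnet_unknown_category"
    )
  }
  if (isTRUE(distinct)) {
    units <- distinct_architectures(archs,
                                    collapse_repeats = collapse_repeats)$domains
  } else {
    units <- archs$domains
    if (isTRUE(collapse_repeats)) units <- lapply(units, function(d) rle(d)$values)
  }
  units <- units[vapply(units, function(d) focal %in% d, logical(1))]
  if (length(units) == 0L) {
    stop_archnet(
      sprintf("focal domain '%s' occurs in no architecture", focal),
      "archnet_focal_absent"
    )
  }
  linked <- vapply(units, function(d) {
    nb <- neighbors_within(d, focal, max_sep)
    any(vapply(nb, function(x) category %in% domain_categories(cmap, x),
               logical(1)))
  }, logical(1))
  structure(list(focal = focal, category = category,
                 max_sep = as.integer(max_sep),
                 n_distinct = length(units),
                 n_linked = sum(linked),
                 fraction = sum(linked) / length(units)),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf(
    "%s ~ %s (distance <= %d): %d/%d architectures linked (%.1f%%)\n",
    x$focal, x$category, x$max_sep, x$n_linked, x$n_distinct,
    100 * x$fraction))
  invisible(x)
}

#' Linkage profile of a focal domain across all categories
#'
#' Applies [linkage_fraction()] once per category in the map's vocabulary,
#' by default excluding the residual `"other"` label. The profile does not
#' depend on the order in which categories are stored; results are returned
#' in vocabulary order.
#'
#' @inheritParams linkage_fraction
#' @param include_other include the residual `"other"` category?
#' @return A data frame of class `linkage_profile` with one row per
#'   category: `focal`, `category`, `max_sep`, `n_distinct`, `n_linked`,
#'   `fraction`, `percent` (fraction rounded to the nearest integer
#'   percent, the granularity at which such statistics are reported).
#' @export
linkage_profile <- function(archs, focal, cmap, max_sep = 2L,
                            include_other = FALSE, distinct = TRUE,
                            collapse_repeats = FALSE) {
  cats <- cmap$categories
  if (!include_other) cats <- setdiff(cats, "other")
  rows <- lapply(cats, function(cc) {
    r <- linkage_fraction(archs, focal, cmap, cc, max_sep = max_sep,
                          distinct = distinct,
                          collapse_repeats = collapse_repeats)
    data.frame(focal = r$focal, category = r$category, max_sep = r$max_sep,
               n_distinct = r$n_distinct, n_linked = r$n_linked,
               fraction = r$fraction,
               percent = round(100 * r$fraction),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("linkage_profile", class(out))
  out
}
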