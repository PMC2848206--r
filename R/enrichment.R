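#' Background linkage fractions for a set of background focal domains
#'
#' Computes [linkage_fraction()] for each of several background domains over
#' a background architecture corpus (e.g. a sample network of eukaryotic
#' RNA-binding proteins), yielding the distribution of "equivalent linkages"
#' against which a focal domain's fraction is compared.
#'
#' @param bg_archs background [arch_set()].
#' @param bg_focals character vector of background focal domain names.
#'   Domains absent from the corpus are skipped with a warning.
#' @param cmap a [category_map()].
#' @param category category label to score.
#' @param max_sep maximum positional distance.
#' @param distinct passed to [linkage_fraction()].
#' @return Named numeric vector of linkage fractions, one per usable
#'   background focal, in input order.
#' @export
background_fractions <- function(bg_archs, bg_focals, cmap, category,
                                 max_sep = 2L, distinct = TRUE) {
  present <- vapply(bg_focals, function(f) {
    any(vapply(bg_archs$domains, function(d) f %in% d, logical(1)))
  }, logical(1))
  if (any(!present)) {
    warning(sprintf("background focal(s) absent from corpus, skipped: %s",
                    paste(bg_focals[!present], collapse = ", ")),
            call. = FALSE)
  }
  usable <- bg_focals[present]
  if (length(usable) == 0L) {
    stop_archnet("no usable background focal domain occurs in the corpus",
                 "archnet_empty_background")
  }
  vapply(usable, function(f) {
    linkage_fraction(bg_archs, f, cmap, category, max_sep = max_sep,
                     distinct = distinct)$fraction
  }, numeric(1))
}

#' Test a focal linkage fraction against a background
#'
#' Tests whether the focal domain's category-linkage fraction is higher than
#' equivalent linkages in a background corpus (one-sided). Two
#' reconstructions of the comparison are available, since the original
#' analysis reports only a significance level:
#'
#' * `"percentile"` (default) treats background *domains* as the
#'   exchangeable units: `p = (1 + #\{b >= f\}) / (1 + n_background)` where
#'   `b` ranges over the background domains' fractions.
#' * `"label-permutation"` treats *distinct architectures* as the units:
#'   the focal corpus's linked/unlinked indicators are pooled with a
#'   background corpus's, corpus labels are reshuffled `n_perm` times, the
#'   statistic is the linked fraction of the relabelled focal group, and
#'   `p = (1 + #\{perm >= observed\}) / (1 + n_perm)`.
#'
#' Both use add-one empirical p-values, so `p` is never exactly 0 and lies
#' in (0, 1].
#'
#' @param focal_result a [linkage_fraction()] result for the focal domain
#'   (or, for the percentile method only, a bare fraction in `[0, 1]`).
#' @param background for `"percentile"`, a numeric vector of background
#'   fractions (see [background_fractions()]); for `"label-permutation"`, a
#'   `linkage_result` for the background corpus (its `n_linked` and
#'   `n_distinct` supply the background indicators).
#' @param method `"percentile"` or `"label-permutation"`.
#' @param n_perm number of permutations (>= 99; p-resolution guard).
#' @param seed RNG seed; mandatory for the permutation method.
#' @return An object of class `enrichment_result`: list with
#'   `focal_fraction`, `background_fractions` (percentile method),
#'   `method`, `n_perm`, `p_value`, `seed`.
#' @examples
#' p <- enrichment_test(0.9, background = c(0.1, 0.2, 0.3, 0.4))
#' p$p_value  # (1 + 0) / (1 + 4) = 0.2
#' @export
enrichment_test <- function(focal_result, background,
                            method = c("percentile", "label-permutation"),
                            n_perm = 999L, seed = NULL) {
  method <- match.arg(method)
  f <- if (inherits(focal_result, "linkage_result")) {
    focal_result$fraction
  } else {
    stopifnot(is.numeric(focal_result), length(focal_result) == 1L)
    focal_result
  }
  if (method == "percentile") {
    stopifnot(is.numeric(background))
    if (length(background) == 0L) {
      stop_archnet("empty background", "archnet_empty_background")
    }
    p <- (1 + sum(background >= f)) / (1 + length(background))
    res <- list(focal_fraction = f,
                background_fractions = as.numeric(background),
                method = method, n_perm = NA_integer_, p_value = p,
                seed = seed %||% NA_integer_)
  } else {
    if (!inherits(focal_result, "linkage_result") ||
        !inherits(background, "linkage_result")) {
      stop_archnet(
        "label-permutation requires linkage_result objects for both focal and background",
        "archnet_bad_input"
      )
    }
    if (is.null(seed)) {
      stop_archnet("label-permutation requires an explicit seed",
                   "archnet_seed_required")
    }
    if (n_perm < 99L) {
      stop_archnet("n_perm must be >= 99 for a usable p-value resolution",
                   "archnet_bad_input")
    }
    ind <- c(rep(1L, focal_result$n_linked),
             rep(0L, focal_result$n_distinct - focal_result$n_linked),
             rep(1L, background$n_linked),
             rep(0L, background$n_distinct - background$n_linked))
    nf <- focal_result$n_distinct
    obs <- focal_result$fraction
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) mean(ind[sample.int(length(ind), nf)]),
             numeric(1))
    })
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    res <- list(focal_fraction = f,
                background_fractions = background$fraction,
                method = method, n_perm = as.integer(n_perm), p_value = p,
                seed = seed)
  }
  structure(res, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment test (%s): focal fraction %.3f, p = %.4g%s\n",
              x$method, x$focal_fraction, x$p_value,
              if (!is.na(x$n_perm)) sprintf(" (%d permutations, seed %s)",
                                            x$n_perm, x$seed) else ""))
  invisible(x)
}
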