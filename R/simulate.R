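#' Simulate an architecture corpus with controlled category linkage
#'
#' Generates an architecture set in which every record carries exactly one
#' occurrence of the focal domain (or a tandem pair, see `tandem_rate`) and,
#' independently for each functional category, carries a domain of that
#' category within distance `max_sep` of the focal with probability
#' `p_link[category]`. A linked category domain is placed at distance 1 with
#' probability `p_distance1`, otherwise at distance 2 with a decoy filling
#' the intervening slot. Remaining slots out to `max_sep + 1` positions on
#' either side are filled with decoys or trimmed at random, giving short
#' architectures (2-7 domains) like real OST-HTH proteins. With
#' probability `dup_rate` a record is a verbatim copy of a previously
#' generated one, emulating the same architecture recovered from several
#' proteins.
#'
#' By default every decoy slot receives a *fresh* domain name
#' (`DUF00001`, `DUF00002`, ...): filler domains in real corpora are
#' essentially never shared between unrelated proteins, so any two records
#' containing a decoy are distinct, and deduplication at `dup_rate = 0` is
#' near-trivial (only minimal architectures pairing the focal directly with
#' the same category partner can coincide). Pass a finite `decoy_pool` to
#' allow heavier accidental collisions instead.
#'
#' Category insertions are independent across categories, so one record may
#' be linked to several categories and per-category linkage probabilities
#' need not sum to 1.
#'
#' @param n_records number of records to generate.
#' @param p_link named numeric vector, category -> probability that a record
#'   is linked to that category within `max_sep`.
#' @param focal focal domain name.
#' @param max_sep linkage distance the probabilities refer to (>= 1).
#' @param p_distance1 probability a linked domain sits at distance 1.
#' @param category_pools named list, category -> candidate domain names;
#'   must be non-empty for every category with `p_link > 0`.
#' @param decoy_pool domain names used for unlinked filler slots, or `NULL`
#'   (default) to draw a fresh unique name per slot. A supplied pool must
#'   not contain domains belonging to any category in `p_link`.
#' @param dup_rate probability a record duplicates an earlier one.
#' @param tandem_rate probability the focal occurs as a tandem pair, for
#'   exercising the rule that focal copies are not their own neighbors.
#' @param lineages lineage labels sampled uniformly per record.
#' @param seed RNG seed (required: the corpus is fully determined by it).
#' @return An [arch_set()] of `n_records` records.
#' @examples
#' archs <- simulate_architectures(5, p_link = c("RNA-binding" = 1), seed = 1)
#' archs
#' @export
simulate_architectures <- function(n_records,
                                   p_link = c("RNA-binding" = 0.70,
                                              "anchoring"   = 0.58,
                                              "Ub-system"   = 0.25),
                                   focal = "OST-HTH",
                                   max_sep = 2L,
                                   p_distance1 = 0.5,
                                   category_pools = list(
                                     "RNA-binding" = c("RRM", "KH", "CCCH",
                                                       "S1/CSD-OB", "dsRBD",
                                                       "Zn-knuckle"),
                                     "anchoring"   = c("Tudor", "WW", "Ankyrin",
                                                       "MORN", "SGNH", "Sfi1"),
                                     "Ub-system"   = c("RING", "U-box", "B-Box",
                                                       "Little-finger", "Ubl")
                                   ),
                                   decoy_pool = NULL,
                                   dup_rate = 0,
                                   tandem_rate = 0,
                                   lineages = c("Bacteria", "Metazoa",
                                                "Plants", "Ciliates",
                                                "Stramenopiles"),
                                   seed) {
  if (max_sep < 1L) {
    stop_archnet("max_sep must be >= 1: no placement is possible otherwise",
                 "archnet_config_error")
  }
  stopifnot(all(p_link >= 0), all(p_link <= 1), !is.null(names(p_link)),
            dup_rate >= 0, dup_rate <= 1, p_distance1 >= 0, p_distance1 <= 1)
  active <- names(p_link)[p_link > 0]
  for (cat in active) {
    if (length(category_pools[[cat]] %||% character()) == 0L) {
      stop_archnet(sprintf("category '%s' has p_link > 0 but an empty pool",
                           cat),
                   "archnet_config_error")
    }
  }
  cats <- names(p_link)
  decoy_counter <- 0L
  next_decoys <- function(k) {
    if (k == 0L) return(character())
    if (!is.null(decoy_pool)) return(sample(decoy_pool, k, replace = TRUE))
    decoy_counter <<- decoy_counter + k
    sprintf("DUF%05d", (decoy_counter - k + 1L):decoy_counter)
  }
  with_seed(seed, {
    doms <- vector("list", n_records)
    lins <- character(n_records)
    for (i in seq_len(n_records)) {
      if (i > 1L && stats::runif(1) < dup_rate) {
        j <- sample.int(i - 1L, 1L)
        doms[[i]] <- doms[[j]]
        lins[i] <- lins[j]
        next
      }
      # slots at offsets -max_sep-1 ... -1, focal, +1 ... +max_sep+1
      left <- rep(NA_character_, max_sep + 1L)
      right <- rep(NA_character_, max_sep + 1L)
      sides <- list(left = left, right = right)
      for (cat in cats) {
        if (stats::runif(1) >= p_link[[cat]]) next
        d <- if (stats::runif(1) < p_distance1) 1L else min(2L, max_sep)
        side <- if (stats::runif(1) < 0.5) "left" else "right"
        # find a free slot at distance d, trying the other side, then other
        # distances, so independent categories never displace one another
        placed <- FALSE
        for (dd in unique(c(d, seq_len(max_sep)))) {
          for (ss in unique(c(side, c("left", "right")))) {
            if (is.na(sides[[ss]][dd])) {
              sides[[ss]][dd] <- sample(category_pools[[cat]], 1L)
              placed <- TRUE
              break
            }
          }
          if (placed) break
        }
      }
      # intervening slots inside the outermost placed domain get decoys
      for (ss in c("left", "right")) {
        v <- sides[[ss]]
        outer <- max(c(0L, which(!is.na(v))))
        if (outer > 0L) {
          fill <- which(is.na(v[seq_len(outer)]))
          v[fill] <- next_decoys(length(fill))
        }
        # optionally extend with decoy tails beyond the linked region
        ext <- which(is.na(v))
        for (k in ext) {
          if (stats::runif(1) < 0.5) v[k] <- next_decoys(1L) else break
        }
        sides[[ss]] <- v
      }
      # architectures are at least two domains long (single-domain proteins
      # do not occur in such corpora): pad a bare focal with one decoy
      if (all(is.na(unlist(sides)))) {
        ss <- if (stats::runif(1) < 0.5) "left" else "right"
        sides[[ss]][1L] <- next_decoys(1L)
      }
      focal_block <- if (stats::runif(1) < tandem_rate) c(focal, focal) else focal
      arch <- c(rev(sides$left[!is.na(sides$left)]), focal_block,
                sides$right[!is.na(sides$right)])
      doms[[i]] <- arch
      lins[i] <- sample(lineages, 1L)
    }
    arch_set(sprintf("sim%05d", seq_len(n_records)),
             organism = "Synt", lineage = lins, domains = doms,
             provenance = sprintf("simulate_architectures(seed=%s)", seed))
  })
}

#' Simulate an alignment with controlled per-column class purity
#'
#' Each column has a target residue class; each cell is a gap with
#' probability `gap_rate`, otherwise a residue drawn from the target class
#' with probability `purity` and uniformly from the remaining amino-acid
#' alphabet otherwise.
#'
#' @param n_rows,width alignment dimensions (>= 1).
#' @param target_class a single class symbol from `scheme`, or a vector of
#'   length `width` giving each column's target.
#' @param purity probability a non-gap cell comes from the target class,
#'   in (0, 1]; a scalar or one value per column.
#' @param gap_rate per-cell gap probability; a scalar or one value per
#'   column.
#' @param scheme a [residue_scheme()] supplying the class memberships.
#' @param seed RNG seed (required).
#' @return An [alignment()].
#' @export
simulate_alignment <- function(n_rows, width, target_class = "l",
                               purity = 0.9, gap_rate = 0.05,
                               scheme = residue_scheme(), seed) {
  stopifnot(n_rows >= 1L, width >= 1L, all(purity > 0), all(purity <= 1),
            all(gap_rate >= 0), all(gap_rate < 1))
  target_class <- rep_len(target_class, width)
  purity <- rep_len(purity, width)
  gap_rate <- rep_len(gap_rate, width)
  unknown <- setdiff(unique(target_class), names(scheme$classes))
  if (length(unknown) > 0L) {
    stop_archnet(sprintf("unknown target class(es): %s",
                         paste(unknown, collapse = ", ")),
                 "archnet_config_error")
  }
  with_seed(seed, {
    cols <- lapply(seq_len(width), function(j) {
      members <- scheme$classes[[target_class[j]]]
      rest <- setdiff(AA_ALPHABET, members)
      cell <- character(n_rows)
      gap <- stats::runif(n_rows) < gap_rate[j]
      from_class <- stats::runif(n_rows) < purity[j]
      cell[gap] <- "-"
      n_in <- sum(!gap & from_class)
      n_out <- sum(!gap & !from_class)
      cell[!gap & from_class] <- sample(members, n_in, replace = TRUE)
      cell[!gap & !from_class] <- sample(rest, n_out, replace = TRUE)
      cell
    })
    mat <- do.call(cbind, cols)
    seqs <- apply(mat, 1L, paste, collapse = "")
    names(seqs) <- sprintf("row%04d", seq_len(n_rows))
    alignment(seqs)
  })
}
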