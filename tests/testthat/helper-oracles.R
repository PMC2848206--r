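# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Is `focal` linked to any domain in `category_domains` within max_sep,
# by a flat scan over every (position, offset) pair?
oracle_linked <- function(domains, focal, category_domains, max_sep) {
  for (p in seq_along(domains)) {
    if (domains[p] != focal) next
    for (off in c(-(max_sep:1), 1:max_sep)) {
      q <- p + off
      if (q < 1 || q > length(domains)) next
      if (domains[q] == focal) next
      if (domains[q] %in% category_domains) return(TRUE)
    }
  }
  FALSE
}

# Linkage fraction over a list of tuples, deduplicating by exact signature.
oracle_fraction <- function(tuples, focal, category_domains, max_sep) {
  sigs <- vapply(tuples, paste, "", collapse = ";")
  tuples <- tuples[!duplicated(sigs)]
  tuples <- tuples[vapply(tuples, function(d) focal %in% d, logical(1))]
  linked <- vapply(tuples, oracle_linked, logical(1),
                   focal = focal, category_domains = category_domains,
                   max_sep = max_sep)
  sum(linked) / length(linked)
}

# Per-column consensus recount: tabulates by explicit equality sums.
oracle_column_consensus <- function(column, classes, threshold) {
  n <- length(column)
  residues <- setdiff(unique(column), c("-", "."))
  counts <- vapply(residues, function(r) sum(column == r), integer(1))
  if (length(counts) > 0 && max(counts) >= threshold * n - 1e-9) {
    return(residues[which.max(counts)])
  }
  for (sym in names(classes)) {
    tot <- sum(column %in% classes[[sym]])
    if (tot >= threshold * n - 1e-9) return(sym)
  }
  "."
}

# Exact one-sided tail probability of the label-permutation null by full
# enumeration of all ways to choose the focal group from the pooled
# indicators.
oracle_exact_perm_p <- function(f_linked, f_unlinked, b_linked, b_unlinked) {
  ind <- c(rep(1, f_linked), rep(0, f_unlinked),
           rep(1, b_linked), rep(0, b_unlinked))
  nf <- f_linked + f_unlinked
  obs <- f_linked / nf
  picks <- utils::combn(length(ind), nf)
  stats <- apply(picks, 2, function(ix) mean(ind[ix]))
  mean(stats >= obs - 1e-12)
}

# Random architecture set over a small alphabet (may contain duplicates).
random_arch_set <- function(n, alphabet = c("F", "R", "T", "D"),
                            max_len = 5) {
  doms <- lapply(seq_len(n), function(i) {
    sample(alphabet, sample.int(max_len, 1), replace = TRUE)
  })
  arch_set(sprintf("p%03d", seq_len(n)),
           organism = sample(c("Dmel", "Hsap", "Neur"), n, replace = TRUE),
           lineage = sample(c("Bacteria", "Metazoa"), n, replace = TRUE),
           domains = doms)
}

# Small category map over the 4-letter oracle alphabet: F is the focal,
# R RNA-binding, T anchoring, D stays "other".
toy_cmap <- function() {
  category_map(list(R = "RNA-binding", T = "anchoring"))
}

random_alignment <- function(n_rows, width, gap_rate = 0.1) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n_rows), function(i) {
    cell <- sample(letters20, width, replace = TRUE)
    cell[runif(width) < gap_rate] <- "-"
    paste(cell, collapse = "")
  }, "")
  names(seqs) <- sprintf("s%03d", seq_len(n_rows))
  alignment(seqs)
}
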