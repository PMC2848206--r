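# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All seeded operations in the package go through this so that a call never
# perturbs the global random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Signature string of a domain tuple; ";" is reserved as the separator and
# forbidden inside domain tokens by the readers.
arch_signature <- function(domains) paste(domains, collapse = ";")

stop_archnet <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "archnet_error")))
}
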