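test_that("percentile p-values follow the add-one rule", {
  r <- enrichment_test(0.7, background = c(0.7, 0.7, 0.7))
  expect_equal(r$p_value, 1.0)
  r2 <- enrichment_test(0.9, background = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(r2$p_value, 0.2)  # (1 + 0) / (1 + 4)
  expect_error(enrichment_test(0.5, background = numeric()),
               class = "archnet_empty_background")
})

test_that("background fractions match manual counts and warn on absent focals", {
  cm <- category_map(list(R = "RNA-binding", S = "RNA-binding",
                          T = "anchoring"))
  bg <- arch_set(paste0("p", 1:4), "x", "y",
                 list(c("R", "A1"), c("A1", "R"), c("A2", "S", "T"),
                      c("A2", "D")))
  # A1: distinct archs containing A1 = {R;A1, A1;R, A2;D? no} -> 2, both
  # have R adjacent -> 1.0.  A2: {A2;S;T, A2;D} -> S at distance 1 in one
  # of two -> 0.5.
  fr <- background_fractions(bg, c("A1", "A2"), cm, "RNA-binding",
                             max_sep = 2)
  expect_equal(unname(fr), c(1.0, 0.5))
  expect_warning(
    fr2 <- background_fractions(bg, c("A1", "ZZZ"), cm, "RNA-binding"),
    "ZZZ"
  )
  expect_equal(unname(fr2), 1.0)
  expect_error(
    suppressWarnings(background_fractions(bg, "ZZZ", cm, "RNA-binding")),
    class = "archnet_empty_background"
  )
})

test_that("using the focal corpus as its own background recovers the focal fraction", {
  cm <- default_category_map()
  archs <- osthth_architectures()
  f <- linkage_fraction(archs, "OST-HTH", cm, "RNA-binding")
  bgf <- background_fractions(archs, "OST-HTH", cm, "RNA-binding")
  expect_equal(unname(bgf), f$fraction)
  expect_equal(enrichment_test(f, background = bgf)$p_value, 1.0)
})

test_that("permutation p agrees with exhaustive enumeration of the 8-architecture pool", {
  # focal corpus: 3 linked / 1 unlinked; background: 1 linked / 3 unlinked.
  # Exact tail over all C(8,4) label assignments is 17/70 (frozen from the
  # enumeration oracle).
  exact <- oracle_exact_perm_p(3, 1, 1, 3)
  expect_equal(exact, 17 / 70)
  f <- structure(list(focal = "F", category = "c", max_sep = 2L,
                      n_distinct = 4L, n_linked = 3L, fraction = 0.75),
                 class = "linkage_result")
  b <- structure(list(focal = "F", category = "c", max_sep = 2L,
                      n_distinct = 4L, n_linked = 1L, fraction = 0.25),
                 class = "linkage_result")
  r <- enrichment_test(f, b, method = "label-permutation",
                       n_perm = 9999, seed = 5)
  expect_lt(abs(r$p_value - exact), 0.02)
})

test_that("permutation method enforces its preconditions", {
  f <- structure(list(n_distinct = 4L, n_linked = 3L, fraction = 0.75),
                 class = "linkage_result")
  b <- structure(list(n_distinct = 4L, n_linked = 1L, fraction = 0.25),
                 class = "linkage_result")
  expect_error(enrichment_test(f, b, method = "label-permutation",
                               n_perm = 999),
               class = "archnet_seed_required")
  expect_error(enrichment_test(f, b, method = "label-permutation",
                               n_perm = 50, seed = 1),
               class = "archnet_bad_input")
  expect_error(enrichment_test(0.9, b, method = "label-permutation",
                               n_perm = 999, seed = 1),
               class = "archnet_bad_input")
})

test_that("identical seeds reproduce identical permutation p-values", {
  f <- structure(list(n_distinct = 30L, n_linked = 21L, fraction = 0.7),
                 class = "linkage_result")
  b <- structure(list(n_distinct = 30L, n_linked = 9L, fraction = 0.3),
                 class = "linkage_result")
  p1 <- enrichment_test(f, b, "label-permutation", n_perm = 199, seed = 42)
  p2 <- enrichment_test(f, b, "label-permutation", n_perm = 199, seed = 42)
  p3 <- enrichment_test(f, b, "label-permutation", n_perm = 199, seed = 43)
  expect_identical(p1$p_value, p2$p_value)
  expect_gt(p1$p_value, 0)  # add-one: never exactly zero
  # a different seed is allowed to differ (and here does not change the
  # qualitative call)
  expect_lt(p3$p_value, 0.05)
})
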