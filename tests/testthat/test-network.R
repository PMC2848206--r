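test_that("distinct architectures are order-sensitive exact tuples", {
  archs <- arch_set(c("p1", "p2", "p3"), "x", "y",
                    list(c("A", "B"), c("A", "B"), c("B", "A")))
  d <- distinct_architectures(archs)
  expect_equal(d$signature, c("A;B", "B;A"))
  expect_equal(d$multiplicity, c(2L, 1L))

  # repeat counts distinguish architectures unless collapse_repeats
  archs2 <- arch_set(c("p1", "p2"), "x", "y",
                     list(c("OST", "OST", "Tudor"), c("OST", "Tudor")))
  expect_equal(nrow(distinct_architectures(archs2)), 2L)
  expect_equal(nrow(distinct_architectures(archs2, collapse_repeats = TRUE)),
               1L)

  empty <- arch_set(character(), character(), character(), list())
  expect_equal(nrow(distinct_architectures(empty)), 0L)
})

test_that("multiplicities sum to the record count on random sets", {
  set.seed(7)
  for (rep in 1:10) {
    archs <- random_arch_set(sample(1:40, 1))
    d <- distinct_architectures(archs)
    expect_equal(sum(d$multiplicity), nrow(archs))
    expect_false(is.unsorted(d$signature))
  }
})

test_that("network construction counts adjacencies once per distinct architecture", {
  net <- build_network(arch_set("p", "x", "y", list(c("A", "B"))))
  el <- write_network(net)
  expect_equal(sort(igraph::V(net$graph)$name), c("A", "B"))
  expect_equal(el, data.frame(source = "A", target = "B", weight = 1L))

  # walking A;B;A gives both directions, two nodes
  net2 <- build_network(arch_set("p", "x", "y", list(c("A", "B", "A"))))
  el2 <- write_network(net2)
  expect_equal(igraph::vcount(net2$graph), 2L)
  expect_equal(el2$weight, c(1L, 1L))
  expect_setequal(paste(el2$source, el2$target), c("A B", "B A"))

  # a repeated adjacency within one architecture still counts once
  net3 <- build_network(arch_set("p", "x", "y", list(c("A", "B", "A", "B"))))
  el3 <- write_network(net3)
  expect_equal(el3$weight[el3$source == "A" & el3$target == "B"], 1L)
})

test_that("duplicate records never change the network; weights bounded by n_distinct", {
  set.seed(11)
  archs <- random_arch_set(30)
  dup <- arch_set(c(archs$protein_id, "dup1", "dup2"),
                  c(archs$organism, "x", "x"),
                  c(archs$lineage, "y", "y"),
                  c(archs$domains, archs$domains[c(1, 2)]))
  el_a <- write_network(build_network(archs))
  el_b <- write_network(build_network(dup))
  expect_identical(el_a, el_b)
  net <- build_network(archs)
  if (nrow(el_a) > 0) expect_true(all(el_a$weight <= net$n_distinct))
  expect_true(all(el_a$weight >= 1L))
})

test_that("neighbors_within follows positional distance with self-exclusion", {
  expect_equal(neighbors_within(c("X", "F", "Y"), "F", 1), c("X", "Y"))
  expect_equal(neighbors_within(c("R", "T", "F"), "F", 2), c("R", "T"))
  # tandem focal copies are not their own neighbors
  expect_equal(neighbors_within(c("F", "F", "T"), "F", 2), "T")
  expect_error(neighbors_within(c("A", "B"), "F", 2),
               class = "archnet_focal_absent")
})

test_that("linkage_fraction matches hand-enumerated cases", {
  cm <- default_category_map()
  one <- arch_set("p", "x", "y", list(c("RRM", "OST-HTH")))
  r <- linkage_fraction(one, "OST-HTH", cm, "RNA-binding")
  expect_equal(r$fraction, 1.0)
  expect_equal(r$n_distinct, 1L)

  # 4 records, 3 distinct; linked: OST;Tudor;RRM (RRM one removed) and
  # LK-nuclease;OST (with LK declared RNA-binding) -> 2/3
  cm2 <- category_map(list(RRM = "RNA-binding", "LK" = "RNA-binding",
                           Tudor = "anchoring"))
  archs <- arch_set(paste0("p", 1:4), "x", "y",
                    list(c("OST", "Tudor"), c("OST", "Tudor", "RRM"),
                         c("LK", "OST"), c("OST", "Tudor")))
  r2 <- linkage_fraction(archs, "OST", cm2, "RNA-binding", max_sep = 2)
  expect_equal(r2$n_distinct, 3L)
  expect_equal(r2$n_linked, 2L)
  expect_equal(r2$fraction, 2 / 3)

  expect_error(linkage_fraction(archs, "absent", cm2, "RNA-binding"),
               class = "archnet_focal_absent")
  expect_error(linkage_fraction(archs, "OST", cm2, "lipidic"),
               "RNA-binding", class = "archnet_unknown_category")
})

test_that("linkage fraction is monotone in max_sep and bounded", {
  set.seed(23)
  cm <- toy_cmap()
  for (rep in 1:20) {
    archs <- random_arch_set(25)
    has_focal <- any(vapply(archs$domains, function(d) "F" %in% d,
                            logical(1)))
    if (!has_focal) next
    fr <- vapply(1:4, function(ms) {
      linkage_fraction(archs, "F", cm, "RNA-binding",
                       max_sep = ms)$fraction
    }, numeric(1))
    expect_true(all(diff(fr) >= 0))
    expect_true(all(fr >= 0 & fr <= 1))
  }
})

test_that("linkage profile covers the vocabulary and ignores category order", {
  cm1 <- category_map(list(R = "RNA-binding", T = "anchoring"))
  cm2 <- category_map(list(T = "anchoring", R = "RNA-binding"))
  archs <- arch_set(paste0("p", 1:3), "x", "y",
                    list(c("R", "F"), c("F", "T"), c("F", "D")))
  p1 <- linkage_profile(archs, "F", cm1)
  p2 <- linkage_profile(archs, "F", cm2)
  expect_equal(p1$category, c("RNA-binding", "anchoring", "Ub-system"))
  expect_equal(p1[order(p1$category), ], p2[order(p2$category), ],
               ignore_attr = TRUE)
  # single-category map gives a singleton profile
  cm3 <- category_map(list(R = "RNA-binding"), categories = c("RNA-binding",
                                                              "other"))
  expect_equal(nrow(linkage_profile(archs, "F", cm3)), 1L)
})
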