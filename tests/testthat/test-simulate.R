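test_that("simulated corpora are seed-deterministic and leave the RNG alone", {
  a1 <- simulate_architectures(40, seed = 9)
  a2 <- simulate_architectures(40, seed = 9)
  expect_identical(a1$domains, a2$domains)
  expect_identical(a1$lineage, a2$lineage)
  a3 <- simulate_architectures(40, seed = 10)
  expect_false(identical(a1$domains, a3$domains))

  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_architectures(10, seed = 1))
  after <- runif(3)
  expect_identical(before, after)  # global RNG stream untouched

  expect_equal(nrow(simulate_architectures(0, seed = 1)), 0L)
  expect_error(simulate_architectures(5, max_sep = 0, seed = 1),
               class = "archnet_config_error")
  expect_error(
    simulate_architectures(5, p_link = c("RNA-binding" = 0.5),
                           category_pools = list(), seed = 1),
    class = "archnet_config_error"
  )
})

test_that("every simulated record carries exactly one focal block", {
  archs <- simulate_architectures(200, seed = 2)
  counts <- vapply(archs$domains, function(d) sum(d == "OST-HTH"),
                   integer(1))
  expect_true(all(counts == 1L))
  tand <- simulate_architectures(200, tandem_rate = 1, seed = 2)
  counts2 <- vapply(tand$domains, function(d) sum(d == "OST-HTH"),
                    integer(1))
  expect_true(all(counts2 == 2L))
})

test_that("p_link = 1 forces linkage and p_link = 0 forbids it", {
  cm <- default_category_map()
  forced <- simulate_architectures(
    50, p_link = c("RNA-binding" = 1, "anchoring" = 0), seed = 3
  )
  r <- linkage_fraction(forced, "OST-HTH", cm, "RNA-binding", max_sep = 2)
  expect_equal(r$fraction, 1.0)
  r0 <- linkage_fraction(forced, "OST-HTH", cm, "anchoring", max_sep = 2,
                         distinct = FALSE)
  expect_equal(r0$fraction, 0.0)
})

test_that("per-record linkage recovers the configured probability", {
  # binomial sampling check: the per-record linked indicator is
  # Bernoulli(p_link) by construction
  archs <- simulate_architectures(10000, p_link = c("RNA-binding" = 0.5),
                                  dup_rate = 0, seed = 4)
  r <- linkage_fraction(archs, "OST-HTH", default_category_map(),
                        "RNA-binding", max_sep = 2, distinct = FALSE)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(r$fraction - 0.5), 3 * se)
})

test_that("duplicates change multiplicities but not distinct-level statistics", {
  base <- simulate_architectures(80, dup_rate = 0, seed = 6)
  dup <- arch_set(c(base$protein_id, paste0("copy", 1:40)),
                  "Synt",
                  c(base$lineage, base$lineage[1:40]),
                  c(base$domains, base$domains[1:40]))
  cm <- default_category_map()
  r1 <- linkage_fraction(base, "OST-HTH", cm, "RNA-binding")
  r2 <- linkage_fraction(dup, "OST-HTH", cm, "RNA-binding")
  expect_identical(r1$fraction, r2$fraction)
  expect_identical(write_network(build_network(base)),
                   write_network(build_network(dup)))
  # dup_rate > 0 produces genuine duplicates
  dd <- simulate_architectures(100, dup_rate = 0.5, seed = 7)
  expect_lt(nrow(distinct_architectures(dd)), nrow(dd))
})

test_that("simulated alignments honor purity, dimensions, and the seed", {
  a1 <- simulate_alignment(8, 30, target_class = "l", purity = 1,
                           gap_rate = 0, seed = 11)
  a2 <- simulate_alignment(8, 30, target_class = "l", purity = 1,
                           gap_rate = 0, seed = 11)
  expect_identical(unclass(a1), unclass(a2))
  expect_equal(attr(a1, "width"), 30L)
  # purity 1, no gaps: every column is pure aliphatic, so the consensus is
  # 'l' or an uppercase aliphatic residue at every position
  cons <- strsplit(unclass(consensus_line(a1)), "")[[1]]
  expect_true(all(cons %in% c("l", "I", "L", "V")))

  one <- simulate_alignment(1, 15, gap_rate = 0.3, seed = 12)
  # single row: consensus is the sequence itself, '.' where gapped
  expected <- chartr("-", ".", unclass(one)[[1]])
  expect_identical(unclass(consensus_line(one)), expected)

  expect_error(simulate_alignment(5, 10, target_class = "z", seed = 1),
               class = "archnet_config_error")
})
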