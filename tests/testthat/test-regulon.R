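# Frozen from the exhaustive oracle: a universe of 20 genes with 5 up genes,
# a 4-member regulon overlapping 3 of them. Enumerating all C(20,4) = 4845
# draws gives 155 with >= 3 successes, so P(X >= 3) = 155/4845.
test_that("regulon enrichment matches the exhaustive worked example", {
  oracle <- enumTailProbs(N = 20, K = 5, n = 4, k = 3)
  expect_equal(oracle[["upper"]], 155 / 4845, tolerance = 1e-12)

  universe <- sprintf("G%02d", 1:20)
  up <- universe[1:5]
  regulon <- universe[c(1, 2, 3, 10)]     # 3 of 4 members up
  db <- InteractionDB(rep("TFX", 4), regulon)
  de <- mkDE(universe, up = up)
  sc <- scoreRegulon(db, "TFX", de)
  expect_equal(sc$p_up, 155 / 4845, tolerance = 1e-12)
  expect_equal(sc$k_up, 3L)
  expect_identical(sc$direction, "up")
})

test_that("tail probabilities match a permutation oracle on random instances", {
  withr::with_seed(99, {
    cases <- lapply(1:3, function(i) {
      N <- sample(20:50, 1)
      list(N = N, K = sample(3:(N %/% 2), 1), n = sample(3:(N %/% 2), 1))
    })
  })
  for (cs in cases) {
    k <- min(cs$K, cs$n) %/% 2
    perm <- permTailProbs(cs$N, cs$K, cs$n, k, nPerm = 5000, seed = cs$N)
    universe <- sprintf("G%03d", seq_len(cs$N))
    db <- InteractionDB(rep("TFX", cs$n), universe[seq_len(cs$n)])
    de <- mkDE(universe, up = universe[cs$N - cs$K + seq_len(cs$K)])
    sc <- scoreRegulon(db, "TFX", de)
    kUp <- sc$k_up
    permK <- permTailProbs(cs$N, cs$K, cs$n, kUp, nPerm = 5000,
                           seed = cs$N + 1)
    se <- sqrt(sc$p_up * (1 - sc$p_up) / 5000)
    expect_lt(abs(permK[["upper"]] - sc$p_up), 3 * se + 1e-6)
  }
})

test_that("degenerate universes and null contrasts score as defined", {
  # regulon == up set == universe: the overlap is forced, P(X >= k) = 1
  universe <- sprintf("G%02d", 1:6)
  db <- InteractionDB(rep("TFX", 6), universe)
  de <- mkDE(universe, up = universe)
  sc <- scoreRegulon(db, "TFX", de)
  expect_equal(sc$p_up, 1)
  expect_equal(sc$k_up, 6L)

  # no DE genes at all: direction none, signed score 0
  deNull <- mkDE(universe)
  sc <- scoreContrast(db, deNull)
  expect_identical(sc$direction, "none")
  expect_equal(sc$signed_score, 0)
  expect_false(any(sc$selected))
})

test_that("scoring ignores gene order and out-of-universe members", {
  universe <- sprintf("G%02d", 1:30)
  up <- universe[c(3, 9, 12, 20, 25)]
  members <- universe[c(3, 9, 14, 21)]
  db1 <- InteractionDB(rep("TFX", 4), members)
  db2 <- InteractionDB(rep("TFX", 6),
                       c(rev(members), "ZZZ1", "ZZZ2"))  # extra, outside
  de1 <- mkDE(universe, up = up)
  de2 <- mkDE(rev(universe), up = rev(up))
  a <- scoreRegulon(db1, "TFX", de1)
  b <- scoreRegulon(db2, "TFX", de2)
  cols <- c("n_regulon", "k_up", "k_down", "p_up", "p_down", "p_depletion")
  expect_equal(a[cols], b[cols])
})

test_that("small regulons are skipped, not scored", {
  universe <- sprintf("G%02d", 1:10)
  db <- InteractionDB(c("TFX", "TFX"), c("G01", "G02"))
  de <- mkDE(universe, up = universe[1:3])
  expect_message(sc <- scoreRegulon(db, "TFX", de), "skipped")
  expect_null(sc)
})

test_that("a fully responsive regulon dominates its contrast", {
  r <- simRecoveryContrast(1)
  sc <- scoreContrast(r$db, r$de)
  expect_true(sc$tf[1] %in% r$activeTfs)   # smallest q is an active TF
  expect_true(all(r$activeTfs %in% sc$tf[sc$selected]))
  top <- sc[sc$tf %in% r$activeTfs, ]
  expect_true(all(top$direction == "up"))
  expect_true(all(top$q_value <= sort(sc$q_value)[5]))
  # deterministic ordering by q then tf
  expect_false(is.unsorted(sc$q_value))
})

test_that("signed scores follow the sign convention", {
  r <- simRecoveryContrast(2)
  sc <- scoreContrast(r$db, r$de)
  scored <- sc[sc$direction != "none" & sc$q_value < 1, ]
  expect_true(all((scored$signed_score > 0) == (scored$direction == "up")))
  expect_true(all(sc$signed_score[sc$direction %in%
                                    c("down", "depleted")] <= 0))
  expect_true(all(sc$signed_score[sc$direction == "none"] == 0))
})

test_that("ties and depletion resolve by the documented rules", {
  # symmetric up/down overlap: tie broken toward up
  universe <- sprintf("G%02d", 1:20)
  db <- InteractionDB(rep("TFX", 4), universe[c(1, 2, 6, 7)])
  de <- mkDE(universe, up = universe[1:5], down = universe[6:10])
  sc <- scoreRegulon(db, "TFX", de)
  expect_equal(sc$p_up, sc$p_down)
  expect_identical(sc$direction, "up")

  # a regulon avoiding a large DE set is reported depleted, negative score
  universeB <- sprintf("H%02d", 1:24)
  dbB <- InteractionDB(rep("TFY", 8), universeB[17:24])
  deB <- mkDE(universeB, up = universeB[1:8], down = universeB[9:16])
  scB <- scoreContrast(dbB, deB)
  expect_identical(scB$direction, "depleted")
  expect_lte(scB$signed_score, 0)
  expect_false(any(scB$selected))
})

test_that("network assembly restricts edges and annotates nodes", {
  universe <- c("KLF1", "NFE2", "GFI1B", "GATA2", sprintf("G%02d", 1:16))
  db <- InteractionDB(
    regulator = c("GATA2", "GATA2", "GATA2", "KLF1", "KLF1", "KLF1",
                  "NFE2", "NFE2", "NFE2", "GFI1B", "GFI1B", "GFI1B"),
    target = c("KLF1", "NFE2", "G01", "G01", "G02", "G03",
               "G01", "G02", "G04", "G02", "G03", "G05"))
  de <- mkDE(universe, up = c("KLF1", "NFE2", "GFI1B", "G01", "G02", "G03"),
             lfc = c(2, 2, 2, 0, rep(0, 16)))
  sc <- scoreContrast(db, de, kMin = 2)
  sel <- sc$tf[sc$selected]
  net <- buildNetwork(db, sc, de, anchors = "GATA2")
  expect_setequal(net@nodes$gene, union(sel, "GATA2"))
  e <- net@edgeTable
  expect_true(all(e$regulator %in% net@nodes$gene))
  expect_true(all(e$target %in% net@nodes$gene))
  # GATA2 -> KLF1 retained iff both in node set; edges to excluded genes gone
  if (all(c("GATA2", "KLF1") %in% net@nodes$gene))
    expect_true(any(e$regulator == "GATA2" & e$target == "KLF1"))
  expect_false(any(!e$target %in% net@nodes$gene))
  # log2fc 0 maps to NC
  expect_identical(net@nodes$size_category[net@nodes$gene == "GATA2"], "NC")

  expect_warning(buildNetwork(db, sc, de, anchors = c("GATA2", "NOSUCH")),
                 "NOSUCH")
})
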