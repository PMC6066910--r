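mkAnn <- function(...) {
  pairs <- list(...)
  data.frame(gene = unlist(lapply(pairs, `[[`, 2)),
             category = rep(sapply(pairs, `[[`, 1),
                            lengths(lapply(pairs, `[[`, 2))),
             stringsAsFactors = FALSE)
}

test_that("annotation readers deduplicate and filter by aspect", {
  f <- tempfile()
  writeLines(c("gene\tcategory", "g1\tGO:0009986", "G1\tGO:0009986",
               "g2\tGO:0009986"), f)
  a <- readAnnotations(f, "two_column_tsv")
  expect_equal(nrow(a$annotations), 2L)
  expect_setequal(a$annotations$gene, c("G1", "G2"))

  gaf <- tempfile()
  gl <- function(sym, go, aspect)
    paste(c("DB", "ID", sym, "", go, "REF", "IEA", "", aspect), collapse = "\t")
  writeLines(c("!gaf-version: 2.1",
               gl("KLF1", "GO:0005856", "C"),
               gl("KLF1", "GO:0003700", "F"),   # molecular function: skipped
               gl("NFE2", "GO:0005886", "C")), gaf)
  b <- readAnnotations(gaf, "gaf_subset")
  expect_equal(nrow(b$annotations), 2L)
  expect_setequal(b$annotations$category, c("GO:0005856", "GO:0005886"))

  writeLines(character(), f)
  expect_warning(e <- readAnnotations(f, "two_column_tsv"), "empty")
  expect_equal(nrow(e$annotations), 0L)

  writeLines(c("g1\tGO:1", "justonefield"), f)
  expect_error(readAnnotations(f, "two_column_tsv"), "line 2")
})

test_that("category scoring shares the regulon statistical core", {
  universe <- sprintf("G%02d", 1:20)
  deSet <- universe[1:5]
  ann <- mkAnn(list("GO:X", universe[c(1, 2, 3, 10)]))
  cs <- scoreCategory("GO:X", deSet, ann, universe)
  expect_equal(cs$p_enrich, 155 / 4845, tolerance = 1e-12)

  db <- InteractionDB(rep("TFX", 4), universe[c(1, 2, 3, 10)])
  de <- mkDE(universe, up = deSet)
  sr <- scoreRegulon(db, "TFX", de)
  expect_identical(cs$p_enrich, sr$p_up)   # same machinery, same number
})

test_that("depleted categories get the lower tail and a negative score", {
  # 10-gene toy, by hand: DE set 5, category 4, overlap 0.
  # P(X <= 0) = C(5,4)/C(10,4) = 5/210.
  universe <- sprintf("G%02d", 1:10)
  ann <- mkAnn(list("GO:D", universe[6:9]), list("GO:E", universe[1:4]))
  cs <- scoreCategory("GO:D", universe[1:5], ann, universe)
  expect_equal(cs$p_deplete, 5 / 210, tolerance = 1e-12)
  expect_identical(cs$direction, "depleted")
  expect_equal(enumTailProbs(10, 5, 4, 0)[["lower"]], 5 / 210,
               tolerance = 1e-12)

  all <- scoreCategories(ann, universe[1:5], universe)
  expect_lte(all$signed_score[all$category == "GO:D"], 0)
  expect_gt(all$signed_score[all$category == "GO:E"], 0)

  # empty DE set: p 1, no signal
  nul <- scoreCategories(ann, character(), universe)
  expect_true(all(nul$p_value == 1))
  expect_true(all(nul$signed_score == 0))

  expect_error(scoreCategory("GO:NOPE", universe[1:5], ann, universe),
               "unknown category")
})

test_that("partitioned categories conserve the DE overlap", {
  universe <- sprintf("G%02d", 1:12)
  ann <- mkAnn(list("GO:A", universe[1:4]), list("GO:B", universe[5:8]),
               list("GO:C", universe[9:12]))
  deSet <- universe[c(1, 2, 6, 11)]
  sc <- scoreCategories(ann, deSet, universe)
  expect_equal(sum(sc$k), length(intersect(deSet, unique(ann$gene))))
})

test_that("category graphs carry brute-force shared-gene weights", {
  universe <- sprintf("G%02d", 1:15)
  ann <- mkAnn(list("GO:A", universe[1:3]),
               list("GO:B", universe[c(2, 3, 9)]),
               list("GO:C", universe[10:12]))
  sc <- scoreCategories(ann, universe[1:4], universe)
  g <- buildCategoryGraph(sc, ann, universe, qThreshold = 1)
  e <- g@edgeTable
  ab <- e[(e$cat1 == "GO:A" & e$cat2 == "GO:B") |
            (e$cat1 == "GO:B" & e$cat2 == "GO:A"), ]
  expect_equal(ab$shared_genes, 2L)               # {G02, G03}
  expect_false(any((e$cat1 == "GO:A" & e$cat2 == "GO:C") |
                     (e$cat1 == "GO:C" & e$cat2 == "GO:A")))  # disjoint
  # weights equal brute-force intersections for every edge
  memb <- split(ann$gene, ann$category)
  for (i in seq_len(nrow(e)))
    expect_equal(e$shared_genes[i],
                 length(intersect(intersect(memb[[e$cat1[i]]], universe),
                                  intersect(memb[[e$cat2[i]]], universe))))
  # empty input: valid empty graph
  empty <- buildCategoryGraph(sc[0, ], ann, universe)
  expect_equal(nrow(empty@nodes), 0L)
  expect_equal(nrow(empty@edgeTable), 0L)
})

test_that("supercategories come from the keyword map", {
  got <- assignSupercategories(
    c("GO:1", "GO:2", "GO:3"),
    names = c("integral component of plasma membrane",
              "actin cytoskeleton organization thing", "ribosome"))
  expect_identical(got, c("cell_surface", "cytoskeleton", "other"))
  # exact-ID mapping also works (synthetic annotation route)
  map <- data.frame(pattern = "GO:SYN0001", supercategory = "cytoskeleton")
  expect_identical(assignSupercategories("GO:SYN0001", map = map),
                   "cytoskeleton")
})
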