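test_that("median-of-ratios size factors match hand calculations", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  expect_equal(unname(computeSizeFactors(m)), c(1, 1), tolerance = 1e-12)

  # sample 2 = 2 x sample 1 elementwise: geometric-mean rescaling puts the
  # factors at 1/sqrt(2) and sqrt(2)
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- c("A", "B", "C")
  expect_equal(unname(computeSizeFactors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)

  # a gene with any zero is excluded from every sample's median: here gene C
  # would otherwise drag sample 2's ratio median away from 2
  m3 <- cbind(s1 = c(10, 20, 5), s2 = c(20, 40, 0))
  rownames(m3) <- c("A", "B", "C")
  expect_equal(unname(computeSizeFactors(m3)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)

  m4 <- cbind(s1 = c(10, 0), s2 = c(0, 10))
  expect_error(computeSizeFactors(m4), "normalization impossible")
})

test_that("size factors agree with the DESeq2 implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(1)
  m <- matrix(rnbinom(5000, mu = 100, size = 10), ncol = 10)
  rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  ours <- computeSizeFactors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("Welch test reproduces the closed-form worked example", {
  # counts chosen so log2(count + 1) equals the target log2 values
  a <- 2^c(4.9, 5.0, 5.1) - 1
  b <- 2^c(6.9, 7.0, 7.1) - 1
  m <- rbind(G1 = c(a, b))
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  de <- deTest(m, paste0("a", 1:3), paste0("b", 1:3),
               sizeFactors = rep(1, 6))
  tb <- deTable(de)
  expect_equal(tb$log2fc, 2, tolerance = 1e-9)
  # t = 2 / sqrt(0.01/3 + 0.01/3) = 24.4949, df = 4
  expect_equal(tb$p_value, 2 * pt(-2 / sqrt(0.02 / 3), 4),
               tolerance = 1e-12)
  expect_equal(tb$p_value, 1.648309e-05, tolerance = 1e-6)
})

test_that("vectorised Welch agrees with stats::t.test gene by gene", {
  set.seed(7)
  m <- matrix(rnbinom(50 * 8, mu = 300, size = 10), nrow = 50,
              dimnames = list(sprintf("G%02d", 1:50),
                              c(paste0("a", 1:4), paste0("b", 1:4))))
  sf <- rep(1, 8)
  de <- deTest(m, paste0("a", 1:4), paste0("b", 1:4), sizeFactors = sf)
  tb <- deTable(de)
  lg <- log2(m + 1)
  for (g in rownames(m)) {
    ref <- t.test(lg[g, 5:8], lg[g, 1:4])
    i <- match(g, tb$gene)
    expect_equal(tb$p_value[i], ref$p.value, tolerance = 1e-9)
    expect_equal(tb$log2fc[i], unname(diff(rev(ref$estimate))),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and error cases behave as specified", {
  m <- rbind(G1 = c(5, 5, 5, 5, 5, 5),     # identical in both groups
             G2 = c(3, 4, 5, 9, 10, 11),
             G3 = c(0, 0, 0, 0, 0, 0))     # never observed
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  de <- deTest(m, paste0("a", 1:3), paste0("b", 1:3),
               sizeFactors = rep(1, 6))
  tb <- deTable(de)
  expect_equal(tb$p_value[tb$gene == "G1"], 1)
  expect_equal(tb$log2fc[tb$gene == "G1"], 0)
  expect_identical(de@untested, "G3")
  expect_false("G3" %in% tb$gene)

  expect_error(deTest(m, "a1", paste0("b", 1:3), sizeFactors = rep(1, 6)),
               "insufficient replication")
  expect_error(deTest(m, paste0("a", 1:3), c("a1", "b2", "b3")),
               "invalid contrast")
})

test_that("swapping the groups negates log2fc and keeps p", {
  set.seed(11)
  m <- matrix(rnbinom(200 * 6, mu = 200, size = 8), nrow = 200,
              dimnames = list(sprintf("G%03d", 1:200),
                              c(paste0("a", 1:3), paste0("b", 1:3))))
  fwd <- deTable(deTest(m, paste0("a", 1:3), paste0("b", 1:3)))
  rev <- deTable(deTest(m, paste0("b", 1:3), paste0("a", 1:3)))
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
})

test_that("BH adjustment matches hand results and its step-up properties", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.05), 0.05)
  expect_error(bhAdjust(c(0.1, 1.2)), "invalid p")

  set.seed(3)
  p <- runif(100)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  ord <- sample(100)
  expect_equal(bhAdjust(p[ord]), q[ord])  # order invariance
})

test_that("classification partitions genes by the FDR and LFC gates", {
  universe <- sprintf("G%02d", 1:20)
  tb <- data.frame(gene = universe,
                   log2fc = c(2, -0.5, -2, rep(0, 17)),
                   p_value = c(1e-5, 1e-6, 0.15, runif(17, 0.3, 1)),
                   q_value = NA_real_, direction = "nc",
                   stringsAsFactors = FALSE)
  de <- new("DEResult", table = tb, contrast = "t",
            groupA = character(), groupB = character(),
            fdrThreshold = NA_real_, lfcThreshold = NA_real_,
            untested = character())
  de <- classifyDE(de, 0.05, 1)
  tb <- deTable(de)
  expect_identical(tb$direction[1], "up")     # passes both gates
  expect_identical(tb$direction[2], "nc")     # fails the LFC gate
  expect_identical(tb$direction[3], "nc")     # fails the FDR gate
  sets <- deSets(de)
  expect_identical(sort(unlist(sets, use.names = FALSE)), sort(universe))
  expect_equal(length(sets$up) + length(sets$down) + length(sets$nc),
               nrow(tb))
  expect_true(all(tb$q_value >= tb$p_value))
  expect_error(classifyDE(de, -0.05, 1), "invalid config")
})
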