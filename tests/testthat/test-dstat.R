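test_that("triad enumeration matches displayed triples", {
  t1 <- ape::read.tree(text = "(((A,B),C),O);")
  tri <- enumerateTriads(t1, "O")
  expect_equal(tri, data.frame(P1 = "A", P2 = "B", P3 = "C"))

  # balanced 4-ingroup tree: the pairs {A,B} and {C,D} each accept both
  # far-side species as P3
  bal <- ape::read.tree(text = "(((A,B),(C,D)),O);")
  tb <- enumerateTriads(bal, "O")
  expect_equal(nrow(tb), 4)
  expect_setequal(paste(tb$P1, tb$P2, tb$P3),
                  c("A B C", "A B D", "C D A", "C D B"))
  expect_error(enumerateTriads(bal, "X"), "not in tree")
})

test_that("triad enumeration agrees with the pruned-triple oracle", {
  set.seed(61)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    og <- tr$tip.label[1]
    a <- enumerateTriads(tr, og)
    b <- oracle_enumerate_triads(tr, og)
    expect_equal(paste(a$P1, a$P2, a$P3), paste(b$P1, b$P2, b$P3))
  }
})

test_that("site-pattern weights follow the Durand formula", {
  w <- sitePatternWeights(0, 1, 1, 0)
  expect_equal(c(w$abba, w$baba), c(1, 0))
  w2 <- sitePatternWeights(0.4, 0.4, 0.7, 0.1)
  expect_equal(w2$abba, w2$baba)  # p1 == p2 contributes nothing to D
  # (1-0.2)*0.8*0.5 = 0.32 ; 0.2*(1-0.8)*0.5 = 0.02
  w3 <- sitePatternWeights(0.2, 0.8, 0.5, 0)
  expect_equal(c(w3$abba, w3$baba), c(0.32, 0.02))
  expect_error(sitePatternWeights(1.2, 0, 0, 0), "frequencies")
})

test_that("Patterson's D matches a per-site summation oracle to 12 dp", {
  # fixed 6-site genotype table: 2 inds per population, cols P1 P1 P2 P2 P3 P3 O O
  cm <- rbind(
    c(0L, 0L, 2L, 2L, 2L, 2L, 0L, 0L),   # canonical ABBA
    c(2L, 2L, 0L, 0L, 2L, 2L, 0L, 0L),   # canonical BABA
    c(0L, 1L, 1L, 2L, 1L, 1L, 0L, 0L),   # mixed frequencies
    c(2L, 2L, 2L, 2L, 0L, 0L, 2L, 2L),   # polarisation flip (outgroup alt)
    c(0L, 0L, 0L, 0L, 2L, 2L, 0L, 0L),   # p1 = p2 = 0
    c(1L, 0L, 2L, 1L, 2L, 0L, 0L, 0L))
  gm <- genotypeMatrix(cm, chrom = "chr1", pos = 1:6 * 1000,
                       ref = rep("A", 6), alt = rep("G", 6),
                       individuals = c("p1a", "p1b", "p2a", "p2b", "p3a",
                                       "p3b", "oa", "ob"))
  pm <- populationMap(individuals(gm),
                      species = rep(c("S1", "S2", "S3", "SO"), each = 2),
                      role = rep(c("P1", "P2", "P3", "O"), each = 2))
  r <- pattersonD(gm, pm, c("S1", "S2", "S3"), "SO", blockSize = 1e6)
  dOracle <- oracle_patterson_d(cm, 1:2, 3:4, 5:6, 7:8)
  expect_equal(r@D, dOracle, tolerance = 1e-12)
  expect_equal(r@D, (r@nABBA - r@nBABA) / (r@nABBA + r@nBABA),
               tolerance = 1e-14)
  expect_true(is.na(r@z))  # single 1-Mb block: Z undefined, not 0

  # swapping P1 and P2 negates D and swaps the counts
  r2 <- pattersonD(gm, pm, c("S2", "S1", "S3"), "SO")
  expect_equal(r2@D, -r@D, tolerance = 1e-14)
  expect_equal(r2@nABBA, r@nBABA)
  expect_equal(r2@nBABA, r@nABBA)
})

test_that("boundary cases: pure ABBA gives D = 1; no signal errors", {
  cm <- rbind(c(0L, 2L, 2L, 0L), c(0L, 2L, 2L, 0L))
  gm <- genotypeMatrix(cm, chrom = "c", pos = c(1, 2), ref = "A", alt = "T",
                       individuals = c("a", "b", "c", "o"))
  pm <- populationMap(c("a", "b", "c", "o"), c("A", "B", "C", "O"),
                      role = c("P1", "P2", "P3", "O"))
  r <- pattersonD(gm, pm, c("A", "B", "C"), "O")
  expect_equal(r@D, 1)
  # monomorphic-in-P3 table has no informative sites
  cm0 <- rbind(c(0L, 2L, 0L, 0L), c(2L, 0L, 0L, 0L))
  gm0 <- genotypeMatrix(cm0, chrom = "c", pos = c(1, 2), ref = "A",
                        alt = "T", individuals = c("a", "b", "c", "o"))
  expect_error(pattersonD(gm0, pm, c("A", "B", "C"), "O"),
               "no informative sites")
})

test_that("D is near zero with Z well calibrated under the ILS-only null", {
  set.seed(71)
  ok <- 0
  for (i in 1:10) {
    sim <- synthesizeGenotypes(simulationConfig(
      chromTable = data.frame(chrom = paste0("c", 1:5), length = 5e6,
                              is_z = FALSE)))
    r <- pattersonD(sim$gm, sim$pm, c("P1", "P2", "P3"), "O")
    if (!is.na(r@z) && abs(r@z) < 3) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("jackknife SE shrinks roughly as 1/sqrt(data size)", {
  set.seed(81)
  seFor <- function(nc) {
    sim <- synthesizeGenotypes(simulationConfig(
      chromTable = data.frame(chrom = paste0("c", seq_len(nc)),
                              length = 5e6, is_z = FALSE)))
    pattersonD(sim$gm, sim$pm, c("P1", "P2", "P3"), "O")@se
  }
  seSmall <- seFor(2)
  seBig <- seFor(18)   # 9x the genome
  expect_lt(seBig, seSmall)
  expect_lt(seBig / seSmall, 0.75)
})

test_that("heatmap layout mirrors D with a sign flip", {
  res <- data.frame(P1 = c("A", "A", "B"), P2 = c("B", "C", "C"),
                    P3 = "X", D = c(0.1, -0.2, 0.05))
  M <- dHeatmapTable(res, "X")
  expect_equal(M["A", "B"], 0.1)
  expect_equal(M["B", "A"], -0.1)
  expect_equal(M["A", "C"], -0.2)
  expect_equal(M["C", "A"], 0.2)
  expect_equal(M["B", "C"], 0.05)
  expect_true(all(is.na(diag(M))))
  one <- dHeatmapTable(data.frame(P1 = "A", P2 = "B", P3 = "X", D = 0.3), "X")
  expect_equal(dim(one), c(2, 2))
  expect_equal(one["B", "A"], -0.3)
  zero <- dHeatmapTable(data.frame(P1 = "A", P2 = "B", P3 = "X", D = 0), "X")
  expect_true(all(zero[!is.na(zero)] == 0))
})
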