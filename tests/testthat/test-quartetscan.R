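make_pm <- function(sizes) {
  roles <- rep(c("P1", "P2", "P3", "O"), sizes)
  populationMap(paste0(tolower(roles), "_", unlist(lapply(sizes, seq_len))),
                species = roles, role = roles)
}

test_that("Cartesian combination counts equal the product of role sizes", {
  expect_equal(nrow(cartesianCombinations(make_pm(c(5, 2, 7, 2)))), 140)
  expect_equal(nrow(cartesianCombinations(make_pm(c(1, 1, 1, 1)))), 1)
  co <- cartesianCombinations(make_pm(c(2, 2, 2, 2)))
  expect_equal(nrow(co), 16)
  # brute-force nested-loop enumeration
  brute <- list()
  for (o in 1:2) for (p3 in 1:2) for (p2 in 1:2) for (p1 in 1:2)
    brute[[length(brute) + 1]] <-
      paste0("p1_", p1, "|p2_", p2, "|p3_", p3, "|o_", o)
  expect_setequal(paste(co$P1, co$P2, co$P3, co$O, sep = "|"),
                  unlist(brute))
  # deterministic order
  co2 <- cartesianCombinations(make_pm(c(2, 2, 2, 2)))
  expect_identical(co, co2)
  pmEmpty <- populationMap(c("a", "b", "c"), c("x", "y", "z"),
                           role = c("P1", "P2", "P3"))
  expect_error(cartesianCombinations(pmEmpty), "without individuals")
})

test_that("outgroup-pair mode enumerates only the ingroup product", {
  co <- cartesianCombinations(make_pm(c(2, 3, 2, 2)), outgroupPair = TRUE)
  expect_equal(nrow(co), 12)
  expect_true(all(c("O", "O2") %in% colnames(co)))
})

test_that("quartet scoring follows the stated label convention", {
  expect_equal(scoreQuartet(ape::read.tree(text = "((p1,p2),(p3,o));"),
                            "p1", "p2", "p3", "o"), "BBAA")
  expect_equal(scoreQuartet(ape::read.tree(text = "((p2,p3),(p1,o));"),
                            "p1", "p2", "p3", "o"), "ABBA")
  expect_equal(scoreQuartet(ape::read.tree(text = "((p1,p3),(p2,o));"),
                            "p1", "p2", "p3", "o"), "BABA")
  expect_equal(scoreQuartet(ape::read.tree(text = "(p1,p2,p3,o);"),
                            "p1", "p2", "p3", "o"), "UNRESOLVED")
  expect_true(is.na(scoreQuartet(ape::read.tree(text = "((p1,p2),(p3,o));"),
                                 "p1", "p2", "p3", "missing")))
})

test_that("scoring on larger trees agrees with the four-point oracle", {
  set.seed(131)
  for (i in 1:300) {
    tr <- ape::rtree(12)
    tips <- sample(tr$tip.label, 4)
    got <- scoreQuartet(tr, tips[1], tips[2], tips[3], tips[4])
    expect_identical(got, oracle_quartet_label(tr, tips[1], tips[2],
                                               tips[3], tips[4]))
  }
})

test_that("two-individual outgroups root on their MRCA edge", {
  tr <- ape::read.tree(text = "((p2,p3),(p1,(o1,o2)));")
  expect_equal(scoreQuartet(tr, "p1", "p2", "p3", c("o1", "o2")), "ABBA")
  # outgroup pair not monophyletic after pruning -> UNRESOLVED
  tr2 <- ape::read.tree(text = "(((p1,o1),p2),(p3,o2));")
  expect_equal(scoreQuartet(tr2, "p1", "p2", "p3", c("o1", "o2")),
               "UNRESOLVED")
})

test_that("folded scaled bins index centre 1 to telomere 20", {
  sc <- binScheme("SCALED_FOLDED")
  expect_equal(assignBin(500, 1000, sc), 1L)
  expect_equal(assignBin(0, 1000, sc), 20L)
  expect_equal(assignBin(250, 1000, sc), 10L)
  expect_equal(assignBin(999, 1000, sc), 20L)
  expect_error(assignBin(1000, 1000, sc), "out of range")
  # bins partition [0, L): every position maps to exactly one bin, and
  # each bin holds 5% of positions up to midpoint/boundary rounding
  L <- 4000
  b <- assignBin(0:(L - 1), L, sc)
  expect_true(all(b %in% 1:20))
  expect_equal(length(b), L)
  expect_true(all(abs(table(b) - L / 20) <= 2))
  # megabase bins are 0-based floor(position / width)
  mb <- binScheme("MEGABASE", width = 1e6)
  expect_equal(assignBin(c(0, 999999, 1e6, 2.5e6), 5e6, mb),
               c(0L, 0L, 1L, 2L))
})

test_that("tallies conserve window counts and match hand counts", {
  # hand-built: 12 windows x 3 combos worth of labels on two chromosomes
  labs <- cbind(rep(c("BBAA", "ABBA", "BABA", "UNRESOLVED"), 3),
                rep("BBAA", 12),
                rep(c("ABBA", "BABA"), 6))
  colnames(labs) <- c("c1", "c2", "c3")
  win <- data.frame(chrom = rep(c("a1", "zZ"), c(8, 4)),
                    start = c(seq(0, 7e5, 1e5), seq(0, 3e5, 1e5)),
                    end = c(seq(0, 7e5, 1e5), seq(0, 3e5, 1e5)) + 1e4)
  ct <- data.frame(chrom = c("a1", "zZ"), length = c(1e6, 5e5),
                   is_z = c(FALSE, TRUE))
  tl <- tallyQuartetLabels(labs, win, ct, macro = "a1")
  expect_equal(sum(tl$pooled["AUTOSOME", ]), 8 * 3)
  expect_equal(sum(tl$pooled["Z", ]), 4 * 3)
  # hand count: autosome rows 1-8
  expect_equal(unname(tl$pooled["AUTOSOME", "BBAA"]),
               sum(labs[1:8, ] == "BBAA"))
  expect_equal(unname(tl$pooled["Z", "ABBA"]), sum(labs[9:12, ] == "ABBA"))
  # per-bin counts cover exactly the macro-chromosome windows
  expect_equal(sum(tl$perBin[, c("BBAA", "ABBA", "BABA", "UNRESOLVED")]),
               8 * 3)
  # per-combo conservation
  expect_true(all(rowSums(tl$perCombo[, c("BBAA", "ABBA", "BABA",
                                          "UNRESOLVED")]) %in% c(4, 8)))
})

test_that("all-BBAA input gives relative frequency (1, 0, 0)", {
  labs <- matrix("BBAA", 10, 2)
  win <- data.frame(chrom = "a1", start = seq(0, 9e5, 1e5),
                    end = seq(0, 9e5, 1e5) + 1e4)
  ct <- data.frame(chrom = "a1", length = 1e6, is_z = FALSE)
  tl <- tallyQuartetLabels(labs, win, ct, macro = "a1")
  pb <- tl$perBin[rowSums(tl$perBin[, 2:5]) > 0, ]
  expect_true(all(pb$freq_BBAA == 1))
  expect_true(all(pb$freq_ABBA == 0))
  expect_equal(sum(tl$pooled["AUTOSOME", "UNRESOLVED"]), 0)
})

test_that("windows beyond the chromosome are a coordinate error", {
  labs <- matrix("BBAA", 1, 1)
  win <- data.frame(chrom = "a1", start = 2e6, end = 2e6 + 1e4)
  ct <- data.frame(chrom = "a1", length = 1e6, is_z = FALSE)
  expect_error(tallyQuartetLabels(labs, win, ct, macro = "a1"), "beyond")
})

test_that("telomere skew contrasts and sentinels", {
  perBin <- data.frame(bin = 1:20, BBAA = 50, ABBA = 10, BABA = 10,
                       UNRESOLVED = 0)
  sk <- telomereSkew(perBin)
  expect_equal(sk$telomericRatio, sk$interiorRatio)  # uniform tallies
  expect_equal(sk$perBin$discordance, rep(20 / 70, 20))

  pb2 <- perBin
  pb2$ABBA[1:16] <- 0; pb2$BABA[1:16] <- 0
  sk2 <- telomereSkew(pb2)
  expect_true(is.nan(sk2$interiorRatio))  # undefined sentinel
  pb3 <- perBin
  pb3$BABA <- 0
  expect_equal(telomereSkew(pb3)$telomericRatio, Inf)
})

test_that("tree-route tally equals the label-route tally on simulated data", {
  set.seed(141)
  cfg <- simulationConfig(samplesPerSpecies = 1L,
                          chromTable = data.frame(chrom = c("a1", "a2"),
                                                  length = 2e6,
                                                  is_z = FALSE))
  sim <- synthesizeGenotypes(cfg)
  combos <- cartesianCombinations(sim$pm)
  trees <- windowTrees(sim$truth$batch)
  viaTrees <- tallyQuartets(trees, sim$truth$windows, combos,
                            cfg@chromTable, macro = c("a1", "a2"))
  viaTimes <- tallyQuartetLabels(
    scoreGenealogyQuartets(sim$truth$batch, combos),
    sim$truth$windows, cfg@chromTable, macro = c("a1", "a2"))
  expect_equal(viaTrees$pooled, viaTimes$pooled)
  expect_equal(viaTrees$perBin, viaTimes$perBin)
})
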