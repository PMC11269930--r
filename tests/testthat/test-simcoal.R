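quartet_cfg <- function(t_internal, ...) {
  h1 <- 1; h2 <- 1 + t_internal; h3 <- h2 + 2
  nwk <- sprintf("(((P1:%g,P2:%g):%g,P3:%g):%g,O:%g);",
                 h1, h1, t_internal, h2, h3 - h2, h3)
  simulationConfig(speciesTree = nwk, samplesPerSpecies = 1L, ...)
}

one_combo <- data.frame(P1 = "P1_1", P2 = "P2_1", P3 = "P3_1", O = "O_1")

test_that("retention landscape follows the folded-power formula", {
  expect_equal(retentionProbability(5e5, 1e6, FALSE, alpha = 1, rMin = 0,
                                    gamma = 0.3), 0)           # centre
  expect_equal(retentionProbability(0, 1e6, FALSE, alpha = 1, rMin = 0,
                                    gamma = 0.3), 0.3)         # telomere
  expect_equal(retentionProbability(999999, 1e6, FALSE, alpha = 1,
                                    rMin = 0, gamma = 0.3), 0.3,
               tolerance = 1e-4)
  expect_equal(retentionProbability(25e4, 1e6, FALSE, alpha = 1, rMin = 0,
                                    gamma = 0.4), 0.2)         # L/4 -> g/2
  expect_equal(retentionProbability(1e5, 1e6, TRUE, alpha = 2, rMin = 0.1,
                                    gamma = 0.5), 0.5 * 0.1 * 0.1)  # Z
  expect_error(retentionProbability(0, 1e6, FALSE, alpha = -1, rMin = 0,
                                    gamma = 0.1), "alpha")
  # monotone non-decreasing from centre to either end
  g <- retentionProbability(seq(5e5, 1e6 - 1, length.out = 50), 1e6, FALSE,
                            alpha = 2, rMin = 0.05, gamma = 1)
  expect_true(all(diff(g) >= -1e-12))
})

test_that("complete lineage sorting at long internal branches", {
  set.seed(1)
  b <- simulateGenealogies(quartet_cfg(50), nWindows = 200,
                           mutations = FALSE)
  lab <- scoreGenealogyQuartets(b, one_combo)
  expect_true(all(lab == "BBAA"))
})

test_that("a star tree gives each resolved topology at 1/3", {
  set.seed(2)
  # internal branch ~0: discordance ~2/3, split evenly
  b <- simulateGenealogies(quartet_cfg(1e-9), nWindows = 6000,
                           mutations = FALSE)
  tab <- table(scoreGenealogyQuartets(b, one_combo))
  se3 <- 3 * sqrt(6000 * (1 / 3) * (2 / 3))
  for (lv in c("BBAA", "ABBA", "BABA"))
    expect_lt(abs(tab[[lv]] - 2000), se3)
})

test_that("quartet discordance matches (1/3)exp(-t) across t (property)", {
  set.seed(3)
  for (t in c(0.5, 1, 2)) {
    b <- simulateGenealogies(quartet_cfg(t), nWindows = 6000,
                             mutations = FALSE)
    lab <- scoreGenealogyQuartets(b, one_combo)
    p <- exp(-t) / 3
    se3 <- 3 * sqrt(p * (1 - p) / 6000)
    expect_lt(abs(mean(lab == "ABBA") - p), se3)
    expect_lt(abs(mean(lab == "BABA") - p), se3)
  }
})

test_that("coalescent-time scoring agrees with tree-based scoring", {
  set.seed(4)
  cfg <- simulationConfig(samplesPerSpecies = 2L)
  b <- simulateGenealogies(cfg, nWindows = 150, mutations = FALSE)
  combos <- data.frame(P1 = c("P1_1", "P1_2"), P2 = "P2_1",
                       P3 = c("P3_2", "P3_1"), O = c("O_1", "O_2"))
  fast <- scoreGenealogyQuartets(b, combos)
  # tree-based scoring of the same haploid lineages must agree exactly
  for (w in seq(1, 150, by = 7)) {
    tr <- genealogyTree(b, w)
    for (k in 1:2) {
      slow <- scoreQuartet(tr, paste0(combos$P1[k], "_a"),
                           paste0(combos$P2[k], "_a"),
                           paste0(combos$P3[k], "_a"),
                           paste0(combos$O[k], "_a"))
      expect_identical(slow, unname(fast[w, k]))
    }
  }
})

test_that("pulse-free runs flag no windows and satisfy the ILS null", {
  set.seed(5)
  sim <- synthesizeGenotypes(simulationConfig(
    chromTable = data.frame(chrom = paste0("c", 1:4), length = 5e6,
                            is_z = FALSE)))
  expect_equal(sum(sim$truth$windows$introgressed), 0)
  lab <- scoreGenealogyQuartets(sim$truth$batch,
                                cartesianCombinations(sim$pm))
  nA <- sum(lab == "ABBA"); nB <- sum(lab == "BABA")
  expect_lt(abs(nA - nB), 3 * sqrt(nA + nB))
})

test_that("zero mutation rate yields an empty site list", {
  set.seed(6)
  cfg <- simulationConfig(speciesTree = "(A:2,B:2);",
                          samplesPerSpecies = 1L, mutRate = 0)
  sim <- synthesizeGenotypes(cfg, nWindows = 3)
  expect_equal(nSites(sim$gm), 0)
})

test_that("deep-split fixed differences match brute-force tabulation", {
  set.seed(7)
  sim <- synthesizeGenotypes(deep_split_cfg(nDip = 2, nChrom = 2))
  hap <- sim$truth$haplotypes
  spc <- sim$truth$hapInfo$species
  hA <- hap[, spc == "A", drop = FALSE]
  hB <- hap[, spc == "B", drop = FALSE]
  # brute force: per-site loop over haplotype columns
  fixed <- vapply(seq_len(nrow(hap)), function(s) {
    a <- hA[s, ]; b <- hB[s, ]
    length(unique(a)) == 1 && length(unique(b)) == 1 && a[1] != b[1]
  }, logical(1))
  cm <- calls(sim$gm)
  iA <- groupIndividuals(sim$pm, "A")
  iB <- groupIndividuals(sim$pm, "B")
  w <- coalscan:::.wcComponents(cm[, iA, drop = FALSE],
                                cm[, iB, drop = FALSE])
  expect_identical(w$fixed, fixed)
  expect_true(all(w$theta[fixed] == 1))
})

test_that("sequence evolution honours the JC closed form and the seed", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  m <- simulateSequences(tr, 200, 0.1)
  expect_identical(m["a", ], m["b", ])

  d <- 0.4
  tr2 <- ape::read.tree(text = sprintf("(a:%g,b:%g);", d / 2, d / 2))
  set.seed(8)
  m2 <- simulateSequences(tr2, 10000, 1)
  p <- mean(m2["a", ] != m2["b", ])
  pExp <- 0.75 * (1 - exp(-4 * d / 3))
  expect_lt(abs(p - pExp), 3 * sqrt(pExp * (1 - pExp) / 10000))

  set.seed(99); s1 <- simulateSequences(tr2, 500, 1)
  set.seed(99); s2 <- simulateSequences(tr2, 500, 1)
  expect_identical(s1, s2)
})

test_that("hybrid construction follows F1 and backcross expectations", {
  nA <- 6; nB <- 6; S <- 2000
  poolA <- matrix(0L, S, nA)  # fixed differences at every site
  poolB <- matrix(1L, S, nB)
  f1 <- makeHybrid(poolA, poolB, "F1")
  expect_true(all(f1$genotype == 1L))
  mono <- makeHybrid(matrix(1L, 5, 2), matrix(1L, 5, 2), "F1")
  expect_true(all(mono$genotype == 2L))
  set.seed(10)
  bc <- makeHybrid(poolA, poolB, "BC1_A")
  hetFrac <- mean(bc$genotype == 1L)
  expect_lt(abs(hetFrac - 0.5), 3 * sqrt(0.25 / S))
  expect_true(all(bc$genotype %in% c(0L, 1L)))  # never hom for the B allele
  expect_error(makeHybrid(poolA, poolB, "F2"), "arg")
  expect_error(makeHybrid(poolA[, 0, drop = FALSE], poolB, "F1"),
               "nonempty")
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- simulationConfig(pulses = data.frame(time = 0.5, donor = "P3",
                                              recipient = "P2",
                                              gamma = 0.2))
  set.seed(123); a <- synthesizeGenotypes(cfg, nWindows = 80)
  set.seed(123); b <- synthesizeGenotypes(cfg, nWindows = 80)
  expect_identical(calls(a$gm), calls(b$gm))
  expect_identical(a$truth$windows$introgressed, b$truth$windows$introgressed)
  expect_identical(a$truth$batch$parents, b$truth$batch$parents)
})

test_that("pulse validation rejects times outside branch lifetimes", {
  expect_error(simulationConfig(pulses = data.frame(
    time = 1.5, donor = "P3", recipient = "P2", gamma = 0.1)),
    "outside lifetime")
  expect_error(simulationConfig(pulses = data.frame(
    time = 0.5, donor = "P3", recipient = "P2", gamma = 1.2)),
    "gamma")
  expect_error(simulationConfig(pulses = data.frame(
    time = 0.5, donor = "XX", recipient = "P2", gamma = 0.1)),
    "unknown branch")
})
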