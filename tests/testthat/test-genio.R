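test_that("VCF write-then-read is the identity for random matrices", {
  gm <- toy_gm(20, 5, seed = 11, withDepth = TRUE)
  p <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypeVcf(gm, p)
  gm2 <- readGenotypeVcf(p)
  expect_identical(unname(calls(gm2)), unname(calls(gm)))
  expect_identical(individuals(gm2), individuals(gm))
  expect_equal(GenomicRanges::start(sites(gm2)),
               GenomicRanges::start(sites(gm)))
  expect_equal(S4Vectors::mcols(sites(gm2))$ref,
               S4Vectors::mcols(sites(gm))$ref)
  expect_equal(unname(callDepth(gm2)), unname(callDepth(gm)))
})

test_that("multiallelic records are dropped with a count; ./. is missing", {
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"),
           "1\t100\t.\tA\tG\t50\t.\t.\tGT\t0/0\t0|1\t1/1",
           "1\t200\t.\tC\tT,G\t50\t.\t.\tGT\t0/0\t0/1\t0/2",
           "1\t300\t.\tG\tA\t50\t.\t.\tGT\t./.\t0/0\t1/1")
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, p)
  suppressMessages(gm <- readGenotypeVcf(p))
  expect_equal(nSites(gm), 2)
  expect_equal(attr(gm, "dropped")[["multiallelic"]], 1)
  expect_identical(unname(calls(gm)[2, ]), c(NA, 0L, 2L))
  expect_identical(unname(calls(gm)[1, ]), c(0L, 1L, 2L))  # phased == unphased
})

test_that("sample subsetting works and absent samples are an error", {
  gm <- toy_gm(10, 4, seed = 3)
  p <- withr::local_tempfile(fileext = ".vcf")
  writeGenotypeVcf(gm, p)
  sub <- readGenotypeVcf(p, samples = c("ind2", "ind4"))
  expect_identical(individuals(sub), c("ind2", "ind4"))
  expect_identical(unname(calls(sub)), unname(calls(gm)[, c(2, 4)]))
  expect_error(readGenotypeVcf(p, samples = "nope"), "not in VCF header")
})

test_that("site filter applies each rule and accounts for every site", {
  # 10 individuals x 6 sites with a constructed MAF/missingness pattern:
  # s1 monomorphic, s2 ok, s3 2/10 missing, s4 monomorphic with one
  # missing call (fails MAF, passes missingness), s5 ok, s6 ok
  cm <- rbind(rep(0L, 10),
              c(1L, 1L, rep(0L, 8)),
              c(NA, NA, 1L, 1L, rep(0L, 6)),
              c(NA, rep(0L, 9)),
              c(rep(2L, 5), rep(0L, 5)),
              c(rep(1L, 10)))
  gm <- genotypeMatrix(cm, chrom = "chr1", pos = 1:6 * 10,
                       ref = rep("A", 6), alt = rep("C", 6),
                       individuals = paste0("i", 1:10))
  out <- filterSites(gm, siteFilterConfig())
  expect_equal(nSites(out), 3)
  expect_equal(GenomicRanges::start(sites(out)), c(20, 50, 60))
  rem <- attr(out, "removed")
  expect_equal(unname(rem[["maf"]]), 2)          # s1 (monomorphic) and s4
  expect_equal(unname(rem[["missingness"]]), 1)  # s3
  expect_equal(nSites(out) + sum(rem[c("qual", "missingness", "maf",
                                       "mean_depth")]), nSites(gm))
})

test_that("disabling all thresholds returns the input unchanged", {
  gm <- toy_gm(15, 6, seed = 9, withDepth = TRUE, missingRate = 0.3)
  cfg <- siteFilterConfig(minMaf = NA, maxMissing = NA, minDepth = NA,
                          maxDepth = NA, minMeanDepth = NA,
                          maxMeanDepth = NA, minQual = NA)
  out <- filterSites(gm, cfg)
  expect_identical(unname(calls(out)), unname(calls(gm)))
  expect_equal(sum(attr(out, "removed")), 0)
})

test_that("filter accounting holds on random matrices (property)", {
  for (seed in 1:5) {
    gm <- toy_gm(40, 8, seed = seed, withDepth = TRUE, missingRate = 0.15)
    out <- filterSites(gm, siteFilterConfig(minDepth = 8, maxDepth = 35,
                                            minMeanDepth = 15,
                                            maxMeanDepth = 30))
    rem <- attr(out, "removed")
    expect_equal(nSites(out) + sum(rem[setdiff(names(rem), "masked_calls")]),
                 nSites(gm))
  }
})

test_that("invalid filter config is rejected", {
  expect_error(siteFilterConfig(minDepth = 10, maxDepth = 2), "exceeds")
  expect_error(filterSites(toy_gm(5, 3),
                           siteFilterConfig(minMeanDepth = 50,
                                            maxMeanDepth = 10)), "exceeds")
})

test_that("population map round-trips and validates roles", {
  pm <- populationMap(
    individual = paste0("i", 1:16),
    species = rep(c("a", "b", "c", "d"), c(5, 2, 7, 2)),
    role = rep(c("P1", "P2", "P3", "O"), c(5, 2, 7, 2)))
  p <- withr::local_tempfile(fileext = ".tsv")
  writePopulationMap(pm, p)
  pm2 <- readPopulationMap(p)
  expect_equal(popTable(pm2)[, 1:5], popTable(pm)[, 1:5])
  expect_length(roleIndividuals(pm2, "P1"), 5)
  expect_length(roleIndividuals(pm2, "P2"), 2)
  expect_length(roleIndividuals(pm2, "P3"), 7)
  expect_length(roleIndividuals(pm2, "O"), 2)

  bad <- popTable(pm)
  bad$role[1] <- "P9"
  pb <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, pb, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readPopulationMap(pb), "unknown role")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("individual\tspecies\tgenus\trole\tis_hybrid", empty)
  expect_error(readPopulationMap(empty), "empty")
  expect_error(populationMap(c("a", "a"), c("x", "x")), "duplicate")
})

test_that("hybrids cannot carry quartet roles", {
  expect_error(populationMap("h1", "sp", role = "P1", is_hybrid = TRUE),
               "role NONE")
})

test_that("Newick and chromosome-table readers validate their input", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a,b),(c,d));", p)
  tr <- readTrees(p)
  expect_length(tr, 1)
  expect_equal(ape::Ntip(tr[[1]]), 4)
  writeLines(c("((a,b),(c,d));", "((a,b,;"), p)
  expect_error(readTrees(p), "line 2")

  ct <- data.frame(chrom = c("1", "Z"), length = c(1e6, 5e5),
                   is_z = c(FALSE, TRUE))
  pc <- withr::local_tempfile(fileext = ".tsv")
  writeChromTable(ct, pc)
  expect_equal(readChromTable(pc), ct)
})

test_that("FASTA alignments round-trip", {
  aln <- random_alignment(4, 30)
  p <- withr::local_tempfile(fileext = ".fa")
  writeFastaAlignment(aln, p)
  expect_identical(readFastaAlignment(p), aln)
})
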