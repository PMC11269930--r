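# Weir & Cockerham (1984) theta for one biallelic site, two populations,
# plus a fixed-difference flag. Vectorised internals feed findAims.

.wcComponents <- function(gA, gB) {
  # gA, gB: matrices sites x individuals of 0/1/2/NA
  n1 <- rowSums(!is.na(gA)); n2 <- rowSums(!is.na(gB))
  p1 <- rowSums(gA, na.rm = TRUE) / (2 * pmax(n1, 1L))
  p2 <- rowSums(gB, na.rm = TRUE) / (2 * pmax(n2, 1L))
  h1 <- rowSums(gA == 1L, na.rm = TRUE) / pmax(n1, 1L)
  h2 <- rowSums(gB == 1L, na.rm = TRUE) / pmax(n2, 1L)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  theta[n1 == 0 | n2 == 0] <- NA_real_
  fixed <- n1 > 0 & n2 > 0 &
    ((p1 == 0 & p2 == 1) | (p1 == 1 & p2 == 0)) & h1 == 0 & h2 == 0
  list(theta = theta, fixed = fixed, n1 = n1, n2 = n2, p1 = p1, p2 = p2)
}

#' Per-site Weir & Cockerham Fst between two groups
#'
#' Computes the two-population Weir & Cockerham (1984) theta estimator for
#' one biallelic site from diploid genotype calls, together with a
#' fixed-difference flag (all non-missing group-A individuals homozygous
#' for one allele, all group-B individuals homozygous for the other).
#' Theta is reported as computed and may be negative or undefined (0/0)
#' when there is no differentiation.
#'
#' @param gA,gB genotype vectors (0/1/2/NA) for the two groups at one site.
#' @return List: \code{fst}, \code{fixed}.
#' @examples
#' perSiteFst(c(0, 0, 0), c(2, 2, 2))  # fst 1, fixed TRUE
#' @export
perSiteFst <- function(gA, gB) {
  if (all(is.na(gA)) || all(is.na(gB)))
    stop("Fst undefined: a group has no non-missing calls")
  w <- .wcComponents(matrix(gA, 1), matrix(gB, 1))
  list(fst = w$theta[1], fixed = w$fixed[1])
}

#' Discover ancestry-informative markers between two groups
#'
#' AIMs are autosomal sites with a fixed allelic difference between the
#' two discovery groups: every non-missing group-A individual homozygous
#' for one allele and every group-B individual homozygous for the other.
#' Flagged hybrids are always excluded from discovery (preventing
#' circularity), as are Z-flagged chromosomes. Discovery groups are
#' arbitrary individual sets, so proxy parents can stand in for unsampled
#' species.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param pm a \linkS4class{PopulationMap}.
#' @param groupA,groupB genus labels (default) or explicit individual IDs
#'   when \code{byIndividual = TRUE}.
#' @param minPerGroup minimum non-missing individuals per group at a site
#'   (default 2).
#' @param maxMissing maximum missing fraction within each group at a site
#'   (default 0.5).
#' @param zChroms chromosome IDs to exclude as sex-linked.
#' @param byIndividual treat groupA/groupB as individual IDs.
#' @return data.frame(chrom, pos, alleleA, alleleB, nA, nB, fst): the AIM
#'   set, BED-like, ordered as in \code{gm}. alleleA/alleleB are the bases
#'   fixed in each group.
#' @export
findAims <- function(gm, pm, groupA, groupB, minPerGroup = 2,
                     maxMissing = 0.5, zChroms = character(),
                     byIndividual = FALSE) {
  tb <- popTable(pm)
  pick <- function(g) {
    ids <- if (byIndividual) g else tb$individual[tb$genus %in% g]
    ids <- setdiff(ids, c(tb$individual[tb$is_hybrid]))
    ids <- intersect(ids, individuals(gm))
    if (!length(ids)) stop("group has no usable individuals: ",
                           paste(g, collapse = ","))
    ids
  }
  idsA <- pick(groupA); idsB <- pick(groupB)
  cm <- calls(gm)
  gA <- cm[, idsA, drop = FALSE]; gB <- cm[, idsB, drop = FALSE]
  w <- .wcComponents(gA, gB)
  missA <- rowMeans(is.na(gA)); missB <- rowMeans(is.na(gB))
  gr <- sites(gm)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  keep <- w$fixed & w$n1 >= minPerGroup & w$n2 >= minPerGroup &
    missA <= maxMissing & missB <= maxMissing & !(chrom %in% zChroms)
  mc <- S4Vectors::mcols(gr)
  aA <- ifelse(w$p1 == 0, mc$ref, mc$alt)  # allele fixed in group A
  aB <- ifelse(w$p1 == 0, mc$alt, mc$ref)
  out <- data.frame(chrom = chrom[keep],
                    pos = GenomicRanges::start(gr)[keep],
                    alleleA = aA[keep], alleleB = aB[keep],
                    nA = w$n1[keep], nB = w$n2[keep],
                    fst = w$theta[keep], stringsAsFactors = FALSE)
  attr(out, "groups") <- list(A = idsA, B = idsB)
  out
}

#' Genotype profile of a putative hybrid at AIM sites
#'
#' Tabulates the hybrid's genotype class at every AIM: heterozygous,
#' homozygous for the group-A allele, homozygous for the group-B allele,
#' or missing. The four fractions (over all AIMs) sum to one; the
#' classification uses the heterozygous fraction among non-missing AIMs.
#'
#' @param gm a \linkS4class{GenotypeMatrix} containing the hybrid.
#' @param hybridId individual ID to profile.
#' @param aims AIM set from \code{\link{findAims}}.
#' @param ... forwarded to \code{\link{classifyHybrid}}.
#' @return List: \code{individual}, \code{nAims}, \code{nGenotyped},
#'   \code{fractions} (het/homA/homB/missing over all AIMs),
#'   \code{hetFraction} (over non-missing AIMs), \code{classification}.
#' @export
profileHybrid <- function(gm, hybridId, aims, ...) {
  if (!nrow(aims)) stop("empty AIM set")
  if (!hybridId %in% individuals(gm))
    stop("individual not in genotype matrix: ", hybridId)
  gr <- sites(gm)
  key <- paste(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  idx <- match(paste(aims$chrom, aims$pos), key)
  if (anyNA(idx)) stop("AIM site(s) absent from genotype matrix")
  g <- calls(gm)[idx, hybridId]
  mc <- S4Vectors::mcols(gr)[idx, ]
  homAcall <- ifelse(aims$alleleA == mc$ref, 0L, 2L)
  nA <- sum(!is.na(g) & g == homAcall)
  nB <- sum(!is.na(g) & g == (2L - homAcall))
  nH <- sum(!is.na(g) & g == 1L)
  nM <- sum(is.na(g))
  tot <- length(g)
  gen <- tot - nM
  hetFrac <- if (gen > 0) nH / gen else NA_real_
  cls <- if (gen == 0) "UNRESOLVED"
         else classifyHybrid(hetFrac, nGenotyped = gen, ...)
  list(individual = hybridId, nAims = tot, nGenotyped = gen,
       fractions = c(het = nH / tot, homA = nA / tot, homB = nB / tot,
                     missing = nM / tot),
       hetFraction = hetFrac, classification = cls)
}

#' Classify a hybrid from its AIM heterozygosity
#'
#' F1 hybrids carry one haplotype from each parental lineage and are
#' (near-)completely heterozygous at AIMs; any backcrossing skews the
#' profile toward one parent, with a first-generation backcross expected
#' at 50\% heterozygosity.
#'
#' @param hetFraction heterozygous fraction over non-missing AIMs.
#' @param f1Threshold classify F1 when hetFraction >= this (default 0.9).
#' @param backcrossBand numeric length-2 interval for BACKCROSS (default
#'   c(0.25, 0.75), inclusive).
#' @param minAims minimum genotyped AIMs required (default 100).
#' @param nGenotyped number of non-missing AIMs behind hetFraction.
#' @return "F1", "BACKCROSS" or "UNRESOLVED".
#' @export
classifyHybrid <- function(hetFraction, f1Threshold = 0.9,
                           backcrossBand = c(0.25, 0.75), minAims = 100,
                           nGenotyped = Inf) {
  if (is.na(hetFraction) || nGenotyped < minAims) return("UNRESOLVED")
  if (hetFraction >= f1Threshold) return("F1")
  if (hetFraction >= backcrossBand[1] && hetFraction <= backcrossBand[2])
    return("BACKCROSS")
  "UNRESOLVED"
}

#' Write an AIM set as BED-like TSV
#' @param aims data.frame from \code{\link{findAims}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAims <- function(aims, path) {
  out <- cbind(chrom = aims$chrom, start = aims$pos - 1, end = aims$pos,
               aims[, setdiff(colnames(aims), c("chrom", "pos"))])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
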