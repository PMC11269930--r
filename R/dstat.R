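#' Enumerate species-tree-compatible triads
#'
#' Returns every unordered pair {P1, P2} with a third species P3 such that
#' the rooted triple ((P1,P2),P3) is displayed by the species tree, i.e.
#' the tree restricted to the three species has P1 and P2 as sisters. Each
#' triad is emitted once with P1 < P2 lexicographically.
#'
#' @param tree rooted species tree (\link[ape]{phylo}).
#' @param outgroup outgroup tip label(s), excluded from triad membership.
#' @return data.frame(P1, P2, P3).
#' @examples
#' tr <- ape::read.tree(text = "(((A,B),(C,D)),O);")
#' enumerateTriads(tr, "O")
#' @export
enumerateTriads <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label))
    stop("outgroup not in tree: ", paste(setdiff(outgroup, tree$tip.label),
                                         collapse = ", "))
  ing <- setdiff(tree$tip.label, outgroup)
  if (length(ing) < 3) return(data.frame(P1 = character(),
                                         P2 = character(),
                                         P3 = character()))
  M <- ape::mrca(tree)
  res <- list()
  for (co in utils::combn(sort(ing), 3, simplify = FALSE)) {
    a <- co[1]; b <- co[2]; c <- co[3]
    mab <- M[a, b]; mac <- M[a, c]; mbc <- M[b, c]
    # the pair whose MRCA is strictly below the triple's MRCA is sister
    if (mac == mbc && mab != mac) {
      res[[length(res) + 1]] <- c(a, b, c)
    } else if (mab == mbc && mac != mab) {
      res[[length(res) + 1]] <- c(a, c, b)
    } else if (mab == mac && mbc != mab) {
      res[[length(res) + 1]] <- c(b, c, a)
    }
  }
  out <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  if (!nrow(out)) return(data.frame(P1 = character(), P2 = character(),
                                    P3 = character()))
  colnames(out) <- c("P1", "P2", "P3")
  out[order(out$P1, out$P2, out$P3), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' ABBA and BABA site-pattern weights from derived-allele frequencies
#'
#' Frequency-weighted (Durand-style) pattern counting:
#' abba = (1-p1) p2 p3 (1-p4), baba = p1 (1-p2) p3 (1-p4), with p4 the
#' outgroup derived-allele frequency (alleles polarised so the
#' outgroup-major allele is ancestral).
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in [0, 1] (vectorised).
#' @return List with numeric vectors \code{abba} and \code{baba}.
#' @examples
#' sitePatternWeights(0, 1, 1, 0)            # canonical ABBA
#' sitePatternWeights(0.2, 0.8, 0.5, 0)      # (0.32, 0.08)
#' @export
sitePatternWeights <- function(p1, p2, p3, p4) {
  for (p in list(p1, p2, p3, p4))
    if (any(p < 0 | p > 1, na.rm = TRUE))
      stop("frequencies must lie in [0, 1]")
  list(abba = (1 - p1) * p2 * p3 * (1 - p4),
       baba = p1 * (1 - p2) * p3 * (1 - p4))
}

# per-population derived-allele frequencies with outgroup polarisation;
# returns NULL rows excluded (all-missing population or unstable outgroup)
.derivedFreqs <- function(gm, pop1, pop2, pop3, popO, maxOutgroupMinor = 0.2) {
  cm <- calls(gm)
  fr <- function(ids) {
    sub <- cm[, ids, drop = FALSE]
    n <- rowSums(!is.na(sub))
    p <- rowSums(sub, na.rm = TRUE) / (2 * pmax(n, 1L))
    p[n == 0] <- NA
    p
  }
  p1 <- fr(pop1); p2 <- fr(pop2); p3 <- fr(pop3); p4 <- fr(popO)
  flip <- !is.na(p4) & p4 > 0.5
  p1[flip] <- 1 - p1[flip]; p2[flip] <- 1 - p2[flip]
  p3[flip] <- 1 - p3[flip]; p4[flip] <- 1 - p4[flip]
  ok <- !is.na(p1) & !is.na(p2) & !is.na(p3) & !is.na(p4) &
    pmin(p4, 1 - p4) <= maxOutgroupMinor
  list(p1 = p1, p2 = p2, p3 = p3, p4 = p4, ok = ok)
}

#' Patterson's D for one triad with block-jackknife significance
#'
#' Derived-allele frequencies are population means of genotype calls over
#' non-missing individuals; the outgroup-major allele defines the ancestral
#' state, and sites where the outgroup minor-allele frequency exceeds
#' \code{maxOutgroupMinor} are excluded as unstably polarised. D =
#' (sum ABBA - sum BABA) / (sum ABBA + sum BABA) over
#' \code{\link{sitePatternWeights}}; the standard error comes from a
#' delete-one block jackknife over contiguous genomic blocks.
#'
#' @param gm a \linkS4class{GenotypeMatrix} (already site-filtered).
#' @param pm a \linkS4class{PopulationMap}.
#' @param triad character vector c(P1, P2, P3) of species labels, or a
#'   one-row data.frame from \code{\link{enumerateTriads}}.
#' @param outgroup outgroup species label.
#' @param blockSize jackknife block size in bp (default 1 Mb).
#' @param maxOutgroupMinor polarisation stability bound (default 0.2).
#' @return A \linkS4class{TriadDResult}. Z is NA with fewer than two
#'   jackknife blocks; zero informative sites is an error.
#' @export
pattersonD <- function(gm, pm, triad, outgroup, blockSize = 1e6,
                       maxOutgroupMinor = 0.2) {
  if (is.data.frame(triad)) triad <- unlist(triad[1, c("P1", "P2", "P3")])
  triad <- as.character(triad)
  ids <- lapply(c(triad, outgroup), function(s)
    groupIndividuals(pm, s, by = "species"))
  if (any(lengths(ids) == 0))
    stop("triad member without non-hybrid individuals: ",
         paste(c(triad, outgroup)[lengths(ids) == 0], collapse = ", "))
  f <- .derivedFreqs(gm, ids[[1]], ids[[2]], ids[[3]], ids[[4]],
                     maxOutgroupMinor)
  w <- sitePatternWeights(f$p1[f$ok], f$p2[f$ok], f$p3[f$ok], f$p4[f$ok])
  informative <- w$abba + w$baba > 0
  if (!any(f$ok) || !any(informative))
    stop("no informative sites: D undefined for triad ",
         paste(triad, collapse = ","))
  sumA <- sum(w$abba); sumB <- sum(w$baba)
  D <- (sumA - sumB) / (sumA + sumB)

  gr <- sites(gm)[f$ok]
  block <- paste0(as.character(GenomicRanges::seqnames(gr)), ":",
                  (GenomicRanges::start(gr) - 1) %/% blockSize)
  ub <- unique(block)
  B <- length(ub)
  if (B >= 2) {
    aB <- tapply(w$abba, block, sum)[ub]
    bB <- tapply(w$baba, block, sum)[ub]
    keepB <- (sumA - aB) + (sumB - bB) > 0
    Dj <- ((sumA - aB) - (sumB - bB)) / ((sumA - aB) + (sumB - bB))
    Dj <- Dj[keepB]
    m <- length(Dj)
    se <- if (m >= 2) sqrt((m - 1) / m * sum((Dj - mean(Dj))^2)) else NA_real_
  } else se <- NA_real_
  z <- if (!is.na(se) && se > 0) D / se else NA_real_
  new("TriadDResult", P1 = triad[1], P2 = triad[2], P3 = triad[3],
      outgroup = as.character(outgroup), nABBA = sumA, nBABA = sumB, D = D,
      se = se, z = z, nBlocks = as.integer(B),
      nSites = as.integer(sum(informative)))
}

#' Patterson's D over all species-tree-compatible triads
#'
#' @param gm,pm,outgroup,blockSize,maxOutgroupMinor see
#'   \code{\link{pattersonD}}.
#' @param tree rooted species tree used to enumerate triads.
#' @return data.frame with one row per triad (long format: P1, P2, P3,
#'   outgroup, nABBA, nBABA, D, se, z, nBlocks, nSites).
#' @export
pattersonDAll <- function(gm, pm, tree, outgroup, blockSize = 1e6,
                          maxOutgroupMinor = 0.2) {
  tri <- enumerateTriads(tree, outgroup)
  out <- lapply(seq_len(nrow(tri)), function(i)
    as.data.frame(pattersonD(gm, pm, tri[i, ], outgroup, blockSize,
                             maxOutgroupMinor)))
  do.call(rbind, out)
}

#' Heatmap matrix of D values for a focal P3
#'
#' Lays out D for every (P1, P2) pair tested against the focal P3 as a
#' square matrix with both orientations populated: cell [P1, P2] holds D
#' and cell [P2, P1] holds -D (swapping P1 and P2 negates the statistic).
#'
#' @param results data.frame with columns P1, P2, P3, D (e.g. from
#'   \code{\link{pattersonDAll}}).
#' @param focalP3 the P3 species the matrix is drawn for.
#' @return Numeric matrix (species x species), NA where untested.
#' @export
dHeatmapTable <- function(results, focalP3) {
  res <- results[results$P3 == focalP3, , drop = FALSE]
  sp <- sort(unique(c(res$P1, res$P2)))
  M <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_len(nrow(res))) {
    M[res$P1[i], res$P2[i]] <- res$D[i]
    M[res$P2[i], res$P1[i]] <- -res$D[i]
  }
  M
}
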