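#' Cartesian four-taxon combinations of individuals
#'
#' Builds the full Cartesian product of the individuals assigned to roles
#' P1, P2, P3 and O in the population map (hybrids never carry roles).
#' Order is deterministic: IDs are sorted within each role and the P1
#' index varies fastest.
#'
#' @param pm a \linkS4class{PopulationMap}.
#' @param outgroupPair use the two outgroup individuals jointly for
#'   rooting instead of enumerating them (requires exactly two O
#'   individuals).
#' @return data.frame with columns P1, P2, P3, O (plus O2 when
#'   \code{outgroupPair}); \code{nrow} equals the product of role sizes.
#' @examples
#' pm <- populationMap(paste0("i", 1:4), paste0("s", 1:4),
#'                     role = c("P1", "P2", "P3", "O"))
#' cartesianCombinations(pm)
#' @export
cartesianCombinations <- function(pm, outgroupPair = FALSE) {
  rl <- lapply(c("P1", "P2", "P3", "O"), function(r)
    sort(roleIndividuals(pm, r)))
  names(rl) <- c("P1", "P2", "P3", "O")
  if (any(lengths(rl) == 0))
    stop("role(s) without individuals: ",
         paste(names(rl)[lengths(rl) == 0], collapse = ", "))
  if (outgroupPair) {
    if (length(rl$O) != 2)
      stop("outgroupPair requires exactly two O individuals")
    out <- expand.grid(P1 = rl$P1, P2 = rl$P2, P3 = rl$P3,
                       stringsAsFactors = FALSE)
    out$O <- rl$O[1]; out$O2 <- rl$O[2]
  } else {
    out <- expand.grid(P1 = rl$P1, P2 = rl$P2, P3 = rl$P3, O = rl$O,
                       stringsAsFactors = FALSE)
  }
  bad <- apply(out, 1, anyDuplicated) > 0
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score the rooted four-taxon topology of a window tree
#'
#' Prunes the tree to the four sampled tips, roots it on the outgroup
#' (on the MRCA edge of an outgroup pair, which must be monophyletic after
#' pruning), and reports which ingroup pair is sister: BBAA when P1+P2,
#' ABBA when P2+P3, BABA when P1+P3. Polytomies and unresolvable rootings
#' give UNRESOLVED; a missing tip gives NA (window skipped upstream).
#'
#' Label convention (stated in every output header): BBAA = P1P2 sisters,
#' ABBA = P2P3 sisters, BABA = P1P3 sisters.
#'
#' @param tree a \link[ape]{phylo} containing (at least) the four tips.
#' @param p1,p2,p3 ingroup individual IDs.
#' @param o outgroup individual ID (length 1 or 2).
#' @return "BBAA", "ABBA", "BABA", "UNRESOLVED", or NA if a tip is absent.
#' @examples
#' scoreQuartet(ape::read.tree(text = "((a,b),(c,o));"), "a", "b", "c", "o")
#' @export
scoreQuartet <- function(tree, p1, p2, p3, o) {
  tips <- c(p1, p2, p3, o)
  if (!all(tips %in% tree$tip.label)) return(NA_character_)
  pr <- ape::keep.tip(tree, tips)
  rt <- tryCatch(ape::root(pr, outgroup = o, resolve.root = TRUE),
                 error = function(e) NULL)
  if (is.null(rt)) return("UNRESOLVED")  # e.g. outgroup pair not monophyletic
  M <- ape::mrca(rt)
  m12 <- M[p1, p2]; m13 <- M[p1, p3]; m23 <- M[p2, p3]
  if (m13 == m23 && m12 != m13) return("BBAA")
  if (m12 == m13 && m23 != m12) return("ABBA")
  if (m12 == m23 && m13 != m12) return("BABA")
  "UNRESOLVED"
}

#' Score quartet topologies from coalescence times (fast route)
#'
#' For ultrametric genealogies the rooted quartet topology is determined
#' by which ingroup pair coalesces first: the pair with the smallest MRCA
#' time is sister. This vectorised route consumes the pairwise coalescence
#' times recorded by \code{\link{simulateGenealogies}} and agrees exactly
#' with the tree-based \code{\link{scoreQuartet}} on binary ultrametric
#' trees (a property the test suite asserts).
#'
#' @param batch a \code{GenealogyBatch} with \code{pairTimes}.
#' @param combos data.frame(P1, P2, P3, O) of individual IDs
#'   (\code{\link{cartesianCombinations}}); the first haplotype of each
#'   individual represents it.
#' @return Character matrix windows x combos of topology labels.
#' @export
scoreGenealogyQuartets <- function(batch, combos) {
  hi <- batch$hapInfo
  n <- nrow(hi)
  hap1 <- function(ind) match(paste0(ind, "_a"), hi$haploid)
  W <- nrow(batch$windows)
  out <- matrix(NA_character_, W, nrow(combos))
  pcol <- function(i, j) .pairCol(pmin(i, j), pmax(i, j), n)
  for (k in seq_len(nrow(combos))) {
    i1 <- hap1(combos$P1[k]); i2 <- hap1(combos$P2[k])
    i3 <- hap1(combos$P3[k])
    if (anyNA(c(i1, i2, i3))) stop("combo individual lacks a haplotype")
    t12 <- batch$pairTimes[, pcol(i1, i2)]
    t13 <- batch$pairTimes[, pcol(i1, i3)]
    t23 <- batch$pairTimes[, pcol(i2, i3)]
    lab <- rep("UNRESOLVED", W)
    lab[t12 < t13 & t12 < t23] <- "BBAA"
    lab[t23 < t12 & t23 < t13] <- "ABBA"
    lab[t13 < t12 & t13 < t23] <- "BABA"
    out[, k] <- lab
  }
  colnames(out) <- apply(combos[, c("P1", "P2", "P3", "O")], 1, paste,
                         collapse = "|")
  out
}

#' Bin scheme for chromosome-position stratification
#'
#' MEGABASE bins are fixed-width (default 1 Mb), indexed 0, 1, ... from the
#' chromosome start. SCALED_FOLDED bins normalise by chromosome length and
#' fold around the midpoint: 20 bins, each the union of two mirror-image
#' 2.5\%-length segments, indexed 1 (centre) to 20 (telomere) — a proxy for
#' the telomere-elevated avian recombination landscape.
#'
#' @param mode "MEGABASE" or "SCALED_FOLDED".
#' @param width MEGABASE bin width in bp.
#' @param nBins number of folded bins (default 20, i.e. 5\% of L each).
#' @return A \code{BinScheme} list.
#' @export
binScheme <- function(mode = c("SCALED_FOLDED", "MEGABASE"), width = 1e6,
                      nBins = 20L) {
  structure(list(mode = match.arg(mode), width = width,
                 nBins = as.integer(nBins)), class = "BinScheme")
}

#' Assign a position to a chromosome bin
#'
#' @param position 0-based position(s), 0 <= position < length.
#' @param length chromosome length in bp.
#' @param scheme a \code{\link{binScheme}}.
#' @return Integer bin index (0-based for MEGABASE; 1 = centre to
#'   \code{nBins} = telomere for SCALED_FOLDED).
#' @examples
#' sc <- binScheme("SCALED_FOLDED")
#' assignBin(c(500, 0, 250), 1000, sc)  # centre -> 1, tip -> 20, 250 -> 10
#' @export
assignBin <- function(position, length, scheme) {
  if (any(position < 0 | position >= length))
    stop("position out of range [0, length)")
  if (scheme$mode == "MEGABASE") return(as.integer(position %/% scheme$width))
  d <- abs(position - length / 2)
  half <- length / (2 * scheme$nBins)
  as.integer(pmax(1, pmin(scheme$nBins, ceiling(d / half))))
}

#' The n largest autosomes (macrochromosomes)
#' @param chromTable data.frame(chrom, length, is_z).
#' @param n how many to keep (default 10).
#' @return Character vector of chromosome IDs.
#' @export
macroChromosomes <- function(chromTable, n = 10) {
  aut <- chromTable[!chromTable$is_z, , drop = FALSE]
  aut$chrom[order(-aut$length)][seq_len(min(n, nrow(aut)))]
}

# internal: count labels into a named vector
.countLabels <- function(lab) {
  lv <- c("BBAA", "ABBA", "BABA", "UNRESOLVED")
  tab <- table(factor(lab, levels = lv))
  setNames(as.integer(tab), lv)
}

#' Tally quartet topology labels across strata and bins
#'
#' Pools per-window topology labels (one column per Cartesian combination)
#' into autosome and Z strata — scored independently — per-combination
#' counts, and per-bin counts pooled across all combinations. Only
#' macrochromosomes enter the folded-bin analysis. Windows are assigned to
#' bins by their midpoint.
#'
#' @param labels character matrix windows x combos (from
#'   \code{\link{scoreGenealogyQuartets}} or repeated
#'   \code{\link{scoreQuartet}} calls); NA entries are skipped windows.
#' @param windows data.frame(chrom, start, end) aligned with rows.
#' @param chromTable data.frame(chrom, length, is_z).
#' @param scheme a \code{\link{binScheme}} (default folded 5\% bins).
#' @param macro chromosomes admitted to the bin analysis (default the 10
#'   largest autosomes).
#' @return List: \code{pooled} (stratum x counts), \code{perCombo},
#'   \code{perBin} (bin x counts with relative frequencies), and
#'   \code{convention} (the label-to-role-pair key, printed in every
#'   output header).
#' @export
tallyQuartetLabels <- function(labels, windows, chromTable,
                               scheme = binScheme("SCALED_FOLDED"),
                               macro = macroChromosomes(chromTable)) {
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1)
  stopifnot(nrow(labels) == nrow(windows))
  chrLen <- chromTable$length[match(windows$chrom, chromTable$chrom)]
  if (anyNA(chrLen)) stop("window on unknown chromosome")
  mid <- (windows$start + windows$end) / 2
  if (any(mid >= chrLen)) stop("window midpoint beyond chromosome length")
  isZ <- chromTable$is_z[match(windows$chrom, chromTable$chrom)]

  strat <- function(rows) .countLabels(labels[rows, , drop = FALSE])
  pooled <- rbind(AUTOSOME = strat(which(!isZ)), Z = strat(which(isZ)))
  perCombo <- do.call(rbind, lapply(seq_len(ncol(labels)), function(k) {
    data.frame(combo = colnames(labels)[k] %||% as.character(k),
               stratum = c("AUTOSOME", "Z"),
               rbind(.countLabels(labels[!isZ, k]),
                     .countLabels(labels[isZ, k])))
  }))
  inBin <- which(windows$chrom %in% macro & !isZ)
  bins <- assignBin(mid[inBin], chrLen[inBin], scheme)
  binLevels <- if (scheme$mode == "SCALED_FOLDED") seq_len(scheme$nBins)
               else sort(unique(bins))
  perBin <- do.call(rbind, lapply(binLevels, function(b) {
    cnt <- .countLabels(labels[inBin[bins == b], , drop = FALSE])
    data.frame(bin = b, t(cnt))
  }))
  tot <- rowSums(perBin[, c("BBAA", "ABBA", "BABA", "UNRESOLVED")])
  for (lv in c("BBAA", "ABBA", "BABA"))
    perBin[[paste0("freq_", lv)]] <- ifelse(tot > 0, perBin[[lv]] / tot, NA)
  list(pooled = pooled, perCombo = perCombo, perBin = perBin,
       convention = c(BBAA = "P1+P2 sister", ABBA = "P2+P3 sister",
                      BABA = "P1+P3 sister"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tally window-tree topologies over Cartesian combinations
#'
#' The tree-based route: every window tree is scored with
#' \code{\link{scoreQuartet}} for every combination, then pooled with
#' \code{\link{tallyQuartetLabels}}.
#'
#' @param trees list of window trees (tips are individual IDs).
#' @param windows data.frame(chrom, start, end) aligned with \code{trees}.
#' @param combos data.frame(P1, P2, P3, O[, O2]).
#' @param chromTable data.frame(chrom, length, is_z).
#' @param scheme,macro see \code{\link{tallyQuartetLabels}}.
#' @return As \code{\link{tallyQuartetLabels}}, plus the label matrix.
#' @export
tallyQuartets <- function(trees, windows, combos, chromTable,
                          scheme = binScheme("SCALED_FOLDED"),
                          macro = macroChromosomes(chromTable)) {
  W <- length(trees)
  stopifnot(W == nrow(windows))
  labels <- matrix(NA_character_, W, nrow(combos))
  for (k in seq_len(nrow(combos))) {
    o <- if ("O2" %in% colnames(combos)) c(combos$O[k], combos$O2[k])
         else combos$O[k]
    for (w in seq_len(W))
      labels[w, k] <- scoreQuartet(trees[[w]], combos$P1[k], combos$P2[k],
                                   combos$P3[k], o)
  }
  colnames(labels) <- apply(combos[, c("P1", "P2", "P3", "O")], 1, paste,
                            collapse = "|")
  res <- tallyQuartetLabels(labels, windows, chromTable, scheme, macro)
  res$labels <- labels
  res
}

#' Telomere skew of introgression-supporting topologies
#'
#' Contrasts the pooled ABBA:BABA ratio in the telomeric bins (the outer
#' 20\% of each chromosome: folded bins 17-20 by default) against the
#' interior bins, and reports the per-bin discordance profile
#' (ABBA+BABA)/total as the ILS-magnitude proxy along the chromosome.
#' Ratios with a zero denominator are +Inf sentinels (NaN when both counts
#' are zero), never an error.
#'
#' @param perBin per-bin counts from \code{\link{tallyQuartetLabels}}.
#' @param telomereBins bin indices defining the telomeric stratum
#'   (default 17:20 of the 20 folded bins).
#' @return List: \code{telomericRatio}, \code{interiorRatio},
#'   \code{perBin} with added columns \code{abba_minus_baba} and
#'   \code{discordance}.
#' @export
telomereSkew <- function(perBin, telomereBins = 17:20) {
  tel <- perBin$bin %in% telomereBins
  rat <- function(rows) {
    a <- sum(perBin$ABBA[rows]); b <- sum(perBin$BABA[rows])
    if (a == 0 && b == 0) NaN else if (b == 0) Inf else a / b
  }
  tot <- rowSums(perBin[, c("BBAA", "ABBA", "BABA", "UNRESOLVED")])
  perBin$abba_minus_baba <- perBin$ABBA - perBin$BABA
  perBin$discordance <- ifelse(tot > 0,
                               (perBin$ABBA + perBin$BABA) / tot, NA)
  list(telomericRatio = rat(tel), interiorRatio = rat(!tel),
       perBin = perBin)
}
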