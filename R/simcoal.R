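# Multispecies-coalescent simulation with introgression pulses.
# Branch bookkeeping: every node of the species tree identifies the branch
# directly above it; the root node identifies the (infinite) root branch.
# Times are node heights in coalescent units of the reference diploid Ne.

.nodeHeights <- function(phy) {
  d <- ape::node.depth.edgelength(phy)       # distance from root
  h <- max(d[seq_len(ape::Ntip(phy))]) - d   # height above the tips
  tipH <- h[seq_len(ape::Ntip(phy))]
  if (any(abs(tipH) > 1e-6 * max(h)))
    stop("species tree must be ultrametric (all tips at time 0)")
  h[seq_len(ape::Ntip(phy))] <- 0
  h
}

.branchLabels <- function(phy) {
  nt <- ape::Ntip(phy)
  lab <- c(phy$tip.label,
           if (!is.null(phy$node.label) && any(nzchar(phy$node.label)))
             phy$node.label else paste0("node", nt + seq_len(phy$Nnode)))
  lab[!nzchar(lab)] <- paste0("node", which(!nzchar(lab)))
  lab
}

# interval [start, end) during which each branch exists; rownames are labels
.branchIntervals <- function(phy) {
  h <- .nodeHeights(phy)
  nn <- length(h)
  par <- integer(nn)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  tend <- ifelse(par == 0, Inf, h[pmax(par, 1)])
  tend[par == 0] <- Inf
  out <- cbind(start = h, end = tend)
  rownames(out) <- .branchLabels(phy)
  out
}

.branchTable <- function(cfg, neScale = 1) {
  phy <- cfg@speciesTree
  h <- .nodeHeights(phy)
  nn <- length(h)
  par <- integer(nn)
  par[phy$edge[, 2]] <- phy$edge[, 1]
  lab <- .branchLabels(phy)
  ne <- rep(1, nn)
  if (length(cfg@ne)) {
    idx <- match(names(cfg@ne), lab)
    if (anyNA(idx)) stop("unknown branch label(s) in ne: ",
                         paste(names(cfg@ne)[is.na(idx)], collapse = ", "))
    ne[idx] <- cfg@ne
  }
  tend <- ifelse(par == 0, Inf, h[pmax(par, 1L)])
  list(parent = as.integer(par), tend = as.numeric(tend),
       ne = ne * neScale, labels = lab, heights = h, ntip = ape::Ntip(phy))
}

# 1-based column of pair (i < j) among choose(n, 2) pairs in combn order
.pairCol <- function(i, j, n) (i - 1) * n - (i - 1) * i / 2 + (j - i)

#' Window-scaled introgression retention probability
#'
#' Encodes the telomere-weighted retention landscape: introgressed
#' genealogies are retained with a probability that rises from the
#' chromosome centre toward either telomere (a stand-in for post-hybrid
#' purging in low-recombination interiors), and is strongly suppressed on
#' the Z chromosome. For autosomes
#' \deqn{\gamma_w = \gamma \max(r_{min}, (2|pos - L/2|/L)^\alpha)}
#' and for the Z \eqn{\gamma_w = \gamma\, r_{min}\, z_{scale}}.
#'
#' @param position 0-based position(s) in [0, length).
#' @param length chromosome length in bp.
#' @param isZ logical: Z chromosome?
#' @param alpha landscape exponent (>= 0); 0 gives a flat landscape.
#' @param rMin floor in [0, 1].
#' @param gamma base admixture fraction of the pulse.
#' @param zScale extra Z suppression factor (default 0.1).
#' @return Effective per-window admixture probability gamma_w.
#' @examples
#' retentionProbability(0, 1e6, FALSE, alpha = 1, rMin = 0, gamma = 0.2)
#' retentionProbability(25e4, 1e6, FALSE, alpha = 1, rMin = 0, gamma = 0.2)
#' @export
retentionProbability <- function(position, length, isZ, alpha, rMin, gamma,
                                 zScale = 0.1) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (any(position < 0 | position >= length)) stop("position out of range")
  fold <- (2 * abs(position - length / 2) / length)^alpha
  ifelse(isZ, gamma * rMin * zScale, gamma * pmax(rMin, fold))
}

# haploid sample bookkeeping: two haplotypes per diploid, species-grouped
.hapInfo <- function(cfg) {
  sp <- names(cfg@samplesPerSpecies)
  ind <- unlist(lapply(sp, function(s)
    paste0(s, "_", seq_len(cfg@samplesPerSpecies[[s]]))))
  data.frame(haploid = paste0(rep(ind, each = 2), c("_a", "_b")),
             individual = rep(ind, each = 2),
             species = rep(rep(sp, cfg@samplesPerSpecies), each = 2),
             stringsAsFactors = FALSE)
}

#' Simulate gene genealogies under the multispecies coalescent
#'
#' Draws one genealogy per genome window. Within each species-tree branch,
#' k lineages coalesce with exponential waiting times at rate k(k-1)/2
#' divided by the branch's relative Ne; at each introgression pulse every
#' recipient-branch lineage independently relocates to the donor branch
#' with the window-scaled probability from
#' \code{\link{retentionProbability}}. Mutations are dropped on the
#' genealogy under the infinite-sites model at \code{mutRate * windowLength}
#' expected mutations per unit of total branch length.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param windows optional data.frame(chrom, start, end) of 0-based
#'   half-open windows; defaults to the layout implied by the config's
#'   chromosome table, window length and spacing.
#' @param nWindows shortcut: simulate this many windows on one synthetic
#'   autosome (ignores the chromosome table).
#' @param mutations logical: drop infinite-sites mutations?
#' @param pairTimes logical: record pairwise coalescence times (needed for
#'   coalescent-time quartet scoring)?
#' @return A \code{GenealogyBatch} list: \code{windows} (with per-window
#'   \code{introgressed} flags), \code{hapInfo}, \code{parents} and
#'   \code{heights} (node matrices, one column per window), \code{pairTimes}
#'   (windows x haploid pairs), and \code{snp} (window index + derived-allele
#'   carrier matrix). Driven entirely by R's RNG: call \code{set.seed}
#'   first for reproducibility.
#' @export
simulateGenealogies <- function(cfg, windows = NULL, nWindows = NULL,
                                mutations = TRUE, pairTimes = TRUE) {
  validObject(cfg)
  if (!is.null(nWindows)) {
    windows <- data.frame(chrom = "sim", start = (seq_len(nWindows) - 1) *
                            cfg@windowSpacing)
    windows$end <- windows$start + cfg@windowLength
    windows$is_z <- FALSE
    chromLen <- max(windows$end)
    windows$chrom_length <- chromLen
  } else if (is.null(windows)) {
    windows <- sampleWindows(cfg@chromTable, cfg@windowLength,
                             cfg@windowSpacing)
    windows$is_z <- cfg@chromTable$is_z[match(windows$chrom,
                                              cfg@chromTable$chrom)]
    windows$chrom_length <- cfg@chromTable$length[match(windows$chrom,
                                                        cfg@chromTable$chrom)]
  } else {
    if (is.null(windows$is_z)) windows$is_z <- FALSE
    if (is.null(windows$chrom_length))
      windows$chrom_length <- max(windows$end)
  }
  windows$mid <- (windows$start + windows$end) / 2
  hi <- .hapInfo(cfg)
  W <- nrow(windows)
  n <- nrow(hi)
  mu <- if (mutations) cfg@mutRate * cfg@windowLength else 0

  runStratum <- function(idx, neScale) {
    bt <- .branchTable(cfg, neScale)
    sampleBranch <- match(hi$species, bt$labels)
    np <- nrow(cfg@pulses)
    if (np) {
      donor <- match(cfg@pulses$donor, bt$labels)
      recip <- match(cfg@pulses$recipient, bt$labels)
      g <- vapply(idx, function(w)
        retentionProbability(windows$mid[w], windows$chrom_length[w],
                             windows$is_z[w], cfg@alpha, cfg@rMin,
                             1, cfg@zScale), numeric(1))
      gmat <- outer(cfg@pulses$gamma, g)  # np x |idx|
    } else {
      donor <- recip <- integer()
      gmat <- matrix(0, 1, length(idx))
    }
    .sim_msc_batch(bt$parent, bt$tend, bt$ne, sampleBranch,
                   as.numeric(cfg@pulses$time), as.integer(donor),
                   as.integer(recip), gmat, length(idx), mu, pairTimes)
  }

  az <- which(!windows$is_z)
  zz <- which(windows$is_z)
  nNodes <- 2 * n - 1
  parents <- matrix(0L, nNodes, W)
  heights <- matrix(0, nNodes, W)
  introgressed <- logical(W)
  pt <- if (pairTimes) matrix(0, W, n * (n - 1) / 2) else NULL
  snpW <- integer(0)
  snpC <- matrix(0L, 0, n)
  for (grp in list(az, zz)) {
    if (!length(grp)) next
    res <- runStratum(grp, if (windows$is_z[grp[1]]) cfg@zNeScale else 1)
    parents[, grp] <- res$parents
    heights[, grp] <- res$heights
    introgressed[grp] <- res$introgressed
    if (pairTimes) pt[grp, ] <- res$pair_times
    if (length(res$snp_window)) {
      snpW <- c(snpW, grp[res$snp_window])
      snpC <- rbind(snpC, res$snp_carriers)
    }
  }
  windows$introgressed <- introgressed
  structure(list(windows = windows, hapInfo = hi, parents = parents,
                 heights = heights, pairTimes = pt,
                 snp = list(window = snpW, carriers = snpC), cfg = cfg),
            class = "GenealogyBatch")
}

#' @exportS3Method base::print
print.GenealogyBatch <- function(x, ...) {
  cat("GenealogyBatch:", nrow(x$windows), "windows,", nrow(x$hapInfo),
      "haploid lineages,", length(x$snp$window), "segregating mutations\n")
  cat("  introgressed windows:", sum(x$windows$introgressed), "\n")
  invisible(x)
}

#' Extract one window genealogy as a phylo tree
#'
#' @param batch a \code{GenealogyBatch} from \code{\link{simulateGenealogies}}.
#' @param w window index.
#' @return A rooted ultrametric \link[ape]{phylo} with haploid tip labels,
#'   branch lengths in coalescent units.
#' @export
genealogyTree <- function(batch, w) {
  n <- nrow(batch$hapInfo)
  par <- batch$parents[, w]
  h <- batch$heights[, w]
  internal <- (n + 1):(2 * n - 1)
  ord <- internal[order(-h[internal])]  # root (max height) first
  newid <- integer(2 * n - 1)
  newid[seq_len(n)] <- seq_len(n)
  newid[ord] <- n + seq_along(ord)
  child <- which(par > 0)
  edge <- cbind(newid[par[child]], newid[child])
  tr <- structure(list(edge = edge,
                       edge.length = h[par[child]] - h[child],
                       tip.label = batch$hapInfo$haploid,
                       Nnode = n - 1L),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a single window genealogy
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param window optional one-row data.frame(chrom, start, end); defaults
#'   to the first window of the config layout.
#' @return A \code{GeneGenealogy} list: \code{tree} (phylo), \code{window},
#'   and \code{introgressed} (did any recipient lineage take a pulse path?).
#' @export
simulateGenealogy <- function(cfg, window = NULL) {
  b <- if (is.null(window)) simulateGenealogies(cfg, nWindows = 1)
       else simulateGenealogies(cfg, windows = window)
  structure(list(tree = genealogyTree(b, 1), window = b$windows[1, ],
                 introgressed = b$windows$introgressed[1]),
            class = "GeneGenealogy")
}

#' Evolve sequences along a genealogy under Jukes-Cantor
#'
#' @param tree a \link[ape]{phylo} with branch lengths in coalescent units.
#' @param lengthBp number of sites.
#' @param mutRate substitutions per site per coalescent unit.
#' @return Character matrix (tips x sites) of uppercase bases.
#' @export
simulateSequences <- function(tree, lengthBp, mutRate) {
  stopifnot(lengthBp > 0, mutRate >= 0)
  sim <- phangorn::simSeq(tree, l = lengthBp, rate = mutRate)
  m <- toupper(as.character(sim))
  rownames(m) <- names(sim)
  m[tree$tip.label, , drop = FALSE]
}

#' Synthesize a diploid genotype matrix from the coalescent simulator
#'
#' Pairs consecutive haploid lineages into diploid individuals, places
#' infinite-sites mutations on the window genealogies, assigns each SNP a
#' unique position inside its window, and returns hard-called genotypes
#' with full truth tracking.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param windows,nWindows forwarded to \code{\link{simulateGenealogies}}.
#' @return List: \code{gm} (\linkS4class{GenotypeMatrix}), \code{pm}
#'   (\linkS4class{PopulationMap}; species named P1/P2/P3/O get the matching
#'   quartet role), \code{truth} (window table with introgressed flags, the
#'   haploid 0/1 derived-allele matrix, hapInfo, and the simulated batch).
#' @export
synthesizeGenotypes <- function(cfg, windows = NULL, nWindows = NULL) {
  batch <- simulateGenealogies(cfg, windows = windows, nWindows = nWindows,
                               mutations = TRUE, pairTimes = TRUE)
  hi <- batch$hapInfo
  S <- length(batch$snp$window)
  win <- batch$windows
  # assign unique positions per window, sorted; drop overflow beyond window
  pos <- integer(S)
  keep <- rep(TRUE, S)
  for (w in unique(batch$snp$window)) {
    ii <- which(batch$snp$window == w)
    L <- win$end[w] - win$start[w]
    if (length(ii) > L) { keep[ii[-seq_len(L)]] <- FALSE; ii <- ii[seq_len(L)] }
    pos[ii] <- win$start[w] + sort(sample.int(L, length(ii)))  # 1-based
  }
  carriers <- batch$snp$carriers[keep, , drop = FALSE]
  posK <- pos[keep]
  winK <- batch$snp$window[keep]
  chromK <- win$chrom[winK]
  ord <- order(match(chromK, unique(win$chrom)), posK)
  carriers <- carriers[ord, , drop = FALSE]
  posK <- posK[ord]; chromK <- chromK[ord]; winK <- winK[ord]

  inds <- unique(hi$individual)
  hapA <- match(paste0(inds, "_a"), hi$haploid)
  hapB <- match(paste0(inds, "_b"), hi$haploid)
  cm <- carriers[, hapA, drop = FALSE] + carriers[, hapB, drop = FALSE]
  colnames(cm) <- inds
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(posK), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  gm <- genotypeMatrix(cm, chrom = chromK, pos = posK, ref = ref, alt = alt,
                       individuals = inds)
  spOf <- hi$species[match(inds, hi$individual)]
  pm <- populationMap(inds, species = spOf, genus = spOf,
                      role = ifelse(spOf %in% c("P1", "P2", "P3", "O"),
                                    spOf, "NONE"))
  colnames(carriers) <- hi$haploid
  truth <- list(windows = win, haplotypes = carriers,
                siteWindow = winK, hapInfo = hi, batch = batch)
  list(gm = gm, pm = pm, truth = truth)
}

#' Construct a hybrid individual from parental haplotype pools
#'
#' F1: one haplotype drawn from each parental pool. BC1_A / BC1_B: a gamete
#' from an F1 (each site drawn independently from either parental-origin
#' haplotype, i.e. free recombination) plus a fresh haplotype from the
#' named parental pool.
#'
#' @param poolA,poolB sites x haplotypes 0/1 matrices for the two parents.
#' @param generation one of "F1", "BC1_A", "BC1_B".
#' @return List: \code{genotype} (0/1/2 vector) and the two haplotypes.
#' @export
makeHybrid <- function(poolA, poolB, generation = c("F1", "BC1_A", "BC1_B")) {
  if (!is.matrix(poolA) || !is.matrix(poolB) || ncol(poolA) == 0 ||
      ncol(poolB) == 0)
    stop("parental haplotype pools must be nonempty matrices")
  generation <- match.arg(generation)
  a <- poolA[, sample.int(ncol(poolA), 1)]
  b <- poolB[, sample.int(ncol(poolB), 1)]
  if (generation == "F1") {
    h1 <- a; h2 <- b
  } else {
    gamete <- ifelse(runif(length(a)) < 0.5, a, b)
    h1 <- gamete
    h2 <- if (generation == "BC1_A") poolA[, sample.int(ncol(poolA), 1)]
          else poolB[, sample.int(ncol(poolB), 1)]
  }
  list(genotype = as.integer(h1 + h2), hap1 = h1, hap2 = h2)
}

#' Apply symmetric genotype error
#'
#' Each call is replaced, with the given probability, by one of the other
#' two genotype classes (uniformly). Missing calls are untouched.
#'
#' @param genotype 0/1/2/NA vector.
#' @param rate per-call error probability.
#' @return The perturbed genotype vector.
#' @export
applyGenotypeError <- function(genotype, rate) {
  if (rate <= 0) return(genotype)
  hit <- which(!is.na(genotype) & runif(length(genotype)) < rate)
  for (i in hit)
    genotype[i] <- sample(setdiff(0:2, genotype[i]), 1)
  genotype
}

#' Append simulated hybrid individuals to a synthesized data set
#'
#' @param sim result of \code{\link{synthesizeGenotypes}}.
#' @param speciesA,speciesB parental species labels.
#' @param generation hybrid generation, see \code{\link{makeHybrid}}.
#' @param n number of hybrids to add.
#' @param errorRate symmetric genotype error applied to hybrid calls only.
#' @param prefix ID prefix for the new individuals.
#' @return The updated \code{sim} list (gm/pm extended; truth untouched).
#' @export
addHybrids <- function(sim, speciesA, speciesB, generation = "F1", n = 1,
                       errorRate = 0, prefix = generation) {
  hi <- sim$truth$hapInfo
  poolA <- sim$truth$haplotypes[, hi$species == speciesA, drop = FALSE]
  poolB <- sim$truth$haplotypes[, hi$species == speciesB, drop = FALSE]
  cm <- calls(sim$gm)
  newCols <- matrix(NA_integer_, nrow(cm), n)
  ids <- paste0(prefix, "_", speciesA, "x", speciesB, "_", seq_len(n))
  for (i in seq_len(n)) {
    hy <- makeHybrid(poolA, poolB, generation)
    newCols[, i] <- applyGenotypeError(hy$genotype, errorRate)
  }
  gr <- sites(sim$gm)
  mc <- S4Vectors::mcols(gr)
  cm2 <- cbind(cm, newCols)
  colnames(cm2) <- c(individuals(sim$gm), ids)
  sim$gm <- genotypeMatrix(cm2, chrom = as.character(GenomicRanges::seqnames(gr)),
                           pos = GenomicRanges::start(gr), ref = mc$ref,
                           alt = mc$alt, individuals = colnames(cm2))
  tb <- popTable(sim$pm)
  tb2 <- rbind(tb, data.frame(individual = ids,
                              species = paste0(speciesA, "x", speciesB),
                              genus = paste0(speciesA, "x", speciesB),
                              role = "NONE", is_hybrid = TRUE, sex = NA,
                              stringsAsFactors = FALSE))
  sim$pm <- new("PopulationMap", tab = tb2)
  sim
}

#' Per-window trees with one tip per individual
#'
#' Restricts each window genealogy to the first haplotype of every diploid
#' and relabels tips with individual IDs — the simulator's stand-in for
#' per-window trees inferred from consensus sequences.
#'
#' @param batch a \code{GenealogyBatch}.
#' @param windows window indices (default all).
#' @return \code{multiPhylo} list of trees.
#' @export
windowTrees <- function(batch, windows = seq_len(nrow(batch$windows))) {
  hi <- batch$hapInfo
  keepHap <- hi$haploid[grepl("_a$", hi$haploid)]
  indOf <- hi$individual[match(keepHap, hi$haploid)]
  out <- vector("list", length(windows))
  for (k in seq_along(windows)) {
    tr <- genealogyTree(batch, windows[k])
    tr <- ape::keep.tip(tr, keepHap)
    tr$tip.label <- indOf[match(tr$tip.label, keepHap)]
    out[[k]] <- tr
  }
  class(out) <- "multiPhylo"
  out
}
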