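#' GenotypeMatrix: diploid biallelic genotypes with genomic coordinates
#'
#' Holds hard-called genotypes for a set of individuals at biallelic SNPs.
#' Calls are coded 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate) and NA (missing); the matrix is sites x individuals. Site
#' coordinates live in a \link[GenomicRanges]{GRanges} with metadata columns
#' \code{ref}, \code{alt} and (optionally) \code{qual}. Per-call sequencing
#' depth may be attached as a second matrix of the same shape.
#'
#' Positions are 1-based (VCF convention) in the GRanges; all internal window
#' and bin arithmetic elsewhere in the package uses 0-based half-open
#' intervals, converting only at I/O boundaries.
#'
#' @slot calls integer matrix, sites x individuals, values 0/1/2/NA.
#' @slot sites GRanges of length nrow(calls) with mcols ref, alt.
#' @slot individuals character vector of column IDs.
#' @slot depth NULL or a numeric matrix matching \code{calls}.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", sites = "GRanges",
                 individuals = "character", depth = "ANY"),
  prototype(depth = NULL))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@calls) != length(object@sites))
    msg <- c(msg, "nrow(calls) must equal length(sites)")
  if (ncol(object@calls) != length(object@individuals))
    msg <- c(msg, "ncol(calls) must equal length(individuals)")
  if (anyDuplicated(object@individuals))
    msg <- c(msg, "duplicate individual IDs")
  bad <- object@calls[!is.na(object@calls)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "calls must be 0, 1, 2 or NA")
  mc <- S4Vectors::mcols(object@sites)
  if (!all(c("ref", "alt") %in% colnames(mc))) {
    msg <- c(msg, "sites must carry mcols ref and alt")
  } else {
    if (any(nchar(mc$ref) != 1L) || any(nchar(mc$alt) != 1L) ||
        any(mc$ref == mc$alt))
      msg <- c(msg, "sites must be biallelic SNPs (one ref, one distinct alt)")
  }
  if (length(object@sites) > 1) {
    ch <- as.character(GenomicRanges::seqnames(object@sites))
    po <- GenomicRanges::start(object@sites)
    ok <- tapply(po, ch, function(p) all(diff(p) > 0))
    if (!all(unlist(ok)))
      msg <- c(msg, "positions must be strictly increasing within chromosomes")
  }
  if (!is.null(object@depth) &&
      !identical(dim(object@depth), dim(object@calls)))
    msg <- c(msg, "depth matrix must match calls in shape")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls sites x individuals matrix of 0/1/2/NA genotype codes.
#' @param chrom,pos site chromosome IDs and 1-based positions.
#' @param ref,alt single-character reference and alternate alleles.
#' @param individuals column IDs (defaults to colnames(calls)).
#' @param depth optional per-call depth matrix.
#' @param qual optional per-site quality scores.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- genotypeMatrix(matrix(c(0, 1, 2, NA), 2, 2), chrom = c("1", "1"),
#'                      pos = c(100, 200), ref = c("A", "C"),
#'                      alt = c("G", "T"), individuals = c("x", "y"))
#' nSites(gm)
#' @export
genotypeMatrix <- function(calls, chrom, pos, ref, alt,
                           individuals = colnames(calls), depth = NULL,
                           qual = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  gr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(pos, width = 1L))
  S4Vectors::mcols(gr)$ref <- as.character(ref)
  S4Vectors::mcols(gr)$alt <- as.character(alt)
  if (!is.null(qual)) S4Vectors::mcols(gr)$qual <- as.numeric(qual)
  if (is.null(individuals))
    individuals <- paste0("ind", seq_len(ncol(calls)))
  colnames(calls) <- individuals
  new("GenotypeMatrix", calls = calls, sites = gr,
      individuals = as.character(individuals), depth = depth)
}

#' PopulationMap: individual-to-group assignments and quartet roles
#'
#' Maps each individual to a species and genus, an optional quartet role
#' (P1, P2, P3, O or NONE), a hybrid flag and an optional sex. Roles drive
#' Cartesian four-taxon enumeration; hybrids are excluded from discovery
#' analyses and never carry a quartet role.
#'
#' @slot tab data.frame with columns individual, species, genus, role,
#'   is_hybrid, sex.
#' @export
setClass("PopulationMap", representation(tab = "data.frame"))

.ROLES <- c("P1", "P2", "P3", "O", "NONE")

setValidity("PopulationMap", function(object) {
  tb <- object@tab
  msg <- character()
  need <- c("individual", "species", "genus", "role", "is_hybrid")
  if (!all(need %in% colnames(tb)))
    return(paste("population map needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$individual)) msg <- c(msg, "duplicate individual IDs")
  if (!all(tb$role %in% .ROLES))
    msg <- c(msg, paste("unknown role token(s):",
                        paste(setdiff(unique(tb$role), .ROLES), collapse = ", ")))
  if (any(tb$is_hybrid & tb$role != "NONE"))
    msg <- c(msg, "hybrid individuals must have role NONE")
  if (length(msg)) msg else TRUE
})

#' Construct a PopulationMap
#'
#' @param individual,species,genus character vectors of equal length.
#' @param role quartet roles, one of P1, P2, P3, O, NONE (default NONE).
#' @param is_hybrid logical flags (default FALSE).
#' @param sex optional sex labels.
#' @return A \linkS4class{PopulationMap}.
#' @export
populationMap <- function(individual, species, genus = species,
                          role = "NONE", is_hybrid = FALSE, sex = NA) {
  tb <- data.frame(individual = as.character(individual),
                   species = as.character(species),
                   genus = as.character(genus),
                   role = rep_len(as.character(role), length(individual)),
                   is_hybrid = rep_len(as.logical(is_hybrid), length(individual)),
                   sex = rep_len(as.character(sex), length(individual)),
                   stringsAsFactors = FALSE)
  new("PopulationMap", tab = tb)
}

#' SiteFilterConfig: thresholds applied to sites before every statistic
#'
#' Defaults follow common hard-call practice for SNP matrices in
#' phylogenomic scans: minor allele frequency at least 0.03, at most 10%
#' missing individuals per site (0.9 completeness), per-call depth within
#' [2, 160] and site mean depth within [10, 50] when depth is available, a
#' minimum site QUAL of 20 when QUAL is available, and biallelic sites only.
#' Set any threshold to NA to disable it.
#'
#' @slot minMaf minimum minor allele frequency.
#' @slot maxMissing maximum fraction of missing individuals per site.
#' @slot minDepth,maxDepth per-call depth bounds (calls outside are masked
#'   to missing before the missingness/MAF rules are applied).
#' @slot minMeanDepth,maxMeanDepth bounds on the site mean depth.
#' @slot minQual minimum VCF QUAL (skipped when QUAL is absent).
#' @slot biallelicOnly always TRUE; kept for transparency.
#' @export
setClass("SiteFilterConfig",
  representation(minMaf = "numeric", maxMissing = "numeric",
                 minDepth = "numeric", maxDepth = "numeric",
                 minMeanDepth = "numeric", maxMeanDepth = "numeric",
                 minQual = "numeric", biallelicOnly = "logical"))

setValidity("SiteFilterConfig", function(object) {
  msg <- character()
  chk <- function(lo, hi, what)
    if (!is.na(lo) && !is.na(hi) && lo > hi)
      paste0(what, ": min (", lo, ") exceeds max (", hi, ")") else NULL
  msg <- c(msg, chk(object@minDepth, object@maxDepth, "depth"),
           chk(object@minMeanDepth, object@maxMeanDepth, "mean depth"))
  for (s in c("minMaf", "maxMissing", "minDepth", "maxDepth",
              "minMeanDepth", "maxMeanDepth"))
    if (!is.na(slot(object, s)) && slot(object, s) < 0)
      msg <- c(msg, paste(s, "must be non-negative"))
  if (length(msg)) msg else TRUE
})

#' @rdname SiteFilterConfig-class
#' @param minMaf,maxMissing,minDepth,maxDepth,minMeanDepth,maxMeanDepth,minQual
#'   thresholds; NA disables a rule.
#' @param biallelicOnly logical, kept TRUE.
#' @return A \linkS4class{SiteFilterConfig}.
#' @export
siteFilterConfig <- function(minMaf = 0.03, maxMissing = 0.10, minDepth = 2,
                             maxDepth = 160, minMeanDepth = 10,
                             maxMeanDepth = 50, minQual = 20,
                             biallelicOnly = TRUE) {
  num <- function(x) as.numeric(x)  # NA (logical) disables a rule
  new("SiteFilterConfig", minMaf = num(minMaf), maxMissing = num(maxMissing),
      minDepth = num(minDepth), maxDepth = num(maxDepth),
      minMeanDepth = num(minMeanDepth), maxMeanDepth = num(maxMeanDepth),
      minQual = num(minQual), biallelicOnly = biallelicOnly)
}

#' SimulationConfig: the multispecies-coalescent study design
#'
#' Describes a dated species tree (branch lengths in coalescent units of a
#' reference diploid Ne), per-branch relative population sizes, directional
#' introgression pulses, the mutation process, the genome window layout and
#' the telomere-weighted retention landscape that modulates how likely an
#' introgressed genealogy is retained at a given chromosomal position.
#'
#' @slot speciesTree rooted ultrametric \link[ape]{phylo}; node times in
#'   coalescent units (2 Nref generations).
#' @slot ne named numeric: relative diploid Ne per branch, keyed by tip or
#'   node label; unnamed branches default to 1.
#' @slot pulses data.frame(time, donor, recipient, gamma): each pulse moves
#'   every recipient-branch lineage to the donor branch with probability
#'   gamma (scaled per window by the retention landscape).
#' @slot samplesPerSpecies named integer: diploid individuals per tip.
#' @slot mutRate expected mutations per site per coalescent unit of branch
#'   length (infinite-sites SNPs for genotype synthesis).
#' @slot windowLength,windowSpacing window layout in bp.
#' @slot chromTable data.frame(chrom, length, is_z).
#' @slot alpha,rMin,zScale retention landscape: exponent, floor, and the
#'   extra suppression applied on the Z chromosome.
#' @slot zNeScale Ne multiplier applied to every branch on Z windows
#'   (default 0.75, the neutral Z:autosome ratio).
#' @export
setClass("SimulationConfig",
  representation(speciesTree = "ANY", ne = "numeric", pulses = "data.frame",
                 samplesPerSpecies = "integer", mutRate = "numeric",
                 windowLength = "numeric", windowSpacing = "numeric",
                 chromTable = "data.frame", alpha = "numeric",
                 rMin = "numeric", zScale = "numeric", zNeScale = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  phy <- object@speciesTree
  if (!inherits(phy, "phylo")) return("speciesTree must be a phylo object")
  if (!ape::is.rooted(phy)) msg <- c(msg, "speciesTree must be rooted")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@rMin < 0 || object@rMin > 1) msg <- c(msg, "rMin must be in [0,1]")
  if (nrow(object@pulses)) {
    p <- object@pulses
    if (any(p$gamma < 0 | p$gamma > 1)) msg <- c(msg, "gamma must be in [0,1]")
    iv <- .branchIntervals(phy)
    for (i in seq_len(nrow(p))) {
      for (side in c("donor", "recipient")) {
        b <- p[[side]][i]
        if (!b %in% rownames(iv)) {
          msg <- c(msg, paste0("unknown branch label '", b, "' in pulse ", i))
        } else if (p$time[i] <= iv[b, 1] || p$time[i] >= iv[b, 2]) {
          msg <- c(msg, paste0("pulse ", i, " time ", p$time[i],
                               " outside lifetime of branch '", b, "'"))
        }
      }
    }
  }
  missing_sp <- setdiff(phy$tip.label, names(object@samplesPerSpecies))
  if (length(missing_sp))
    msg <- c(msg, paste("no sample count for species:",
                        paste(missing_sp, collapse = ", ")))
  if (!all(c("chrom", "length", "is_z") %in% colnames(object@chromTable)))
    msg <- c(msg, "chromTable needs columns chrom, length, is_z")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' The defaults encode a four-species design, \code{(((P1,P2),P3),O)}, with
#' splits at 1, 2 and 4 coalescent units, two diploid individuals per
#' species, ten 5-Mb autosomes plus one 5-Mb Z chromosome, 10-kb windows
#' every 100 kb, and no introgression. Pulses are specified as
#' \code{data.frame(time, donor, recipient, gamma)} with branches named by
#' tip (or node) label.
#'
#' @param speciesTree rooted ultrametric phylo or a Newick string.
#' @param samplesPerSpecies named diploid sample sizes (recycled scalar OK).
#' @param ne named per-branch relative Ne (default all 1).
#' @param pulses introgression pulses (default none).
#' @param mutRate per-site per-coalescent-unit mutation rate.
#' @param windowLength,windowSpacing window layout in bp.
#' @param chromTable data.frame(chrom, length, is_z).
#' @param alpha,rMin,zScale retention landscape parameters.
#' @param zNeScale Ne multiplier on Z windows.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig()
#' cfg
#' @export
simulationConfig <- function(speciesTree = "(((P1:1,P2:1):1,P3:2):2,O:4);",
                             samplesPerSpecies = 2L, ne = numeric(),
                             pulses = NULL, mutRate = 2e-5,
                             windowLength = 1e4, windowSpacing = 1e5,
                             chromTable = NULL, alpha = 0, rMin = 0.1,
                             zScale = 0.1, zNeScale = 0.75) {
  if (is.character(speciesTree))
    speciesTree <- ape::read.tree(text = speciesTree)
  if (is.null(chromTable))
    chromTable <- data.frame(
      chrom = c(paste0("chr", 1:10), "chrZ"),
      length = rep(5e6, 11),
      is_z = c(rep(FALSE, 10), TRUE))
  if (is.null(pulses))
    pulses <- data.frame(time = numeric(), donor = character(),
                         recipient = character(), gamma = numeric())
  sps <- samplesPerSpecies
  if (is.null(names(sps)))
    sps <- setNames(rep_len(as.integer(sps), length(speciesTree$tip.label)),
                    speciesTree$tip.label)
  new("SimulationConfig", speciesTree = speciesTree, ne = ne, pulses = pulses,
      samplesPerSpecies = as.integer(round(sps)) |> setNames(names(sps)),
      mutRate = mutRate, windowLength = windowLength,
      windowSpacing = windowSpacing, chromTable = chromTable, alpha = alpha,
      rMin = rMin, zScale = zScale, zNeScale = zNeScale)
}

#' TriadDResult: Patterson's D for one species-tree-compatible triad
#'
#' @slot P1,P2,P3,outgroup population labels.
#' @slot nABBA,nBABA frequency-weighted site-pattern sums.
#' @slot D the statistic (nABBA - nBABA) / (nABBA + nBABA).
#' @slot se,z block-jackknife standard error and Z-score (NA when fewer
#'   than two blocks are available).
#' @slot nBlocks,nSites block count and number of sites used.
#' @export
setClass("TriadDResult",
  representation(P1 = "character", P2 = "character", P3 = "character",
                 outgroup = "character", nABBA = "numeric", nBABA = "numeric",
                 D = "numeric", se = "numeric", z = "numeric",
                 nBlocks = "integer", nSites = "integer"))

setValidity("TriadDResult", function(object) {
  if (!is.na(object@D) && abs(object@D) > 1 + 1e-12)
    "D must lie in [-1, 1]" else TRUE
})
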