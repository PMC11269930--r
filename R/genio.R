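#' Read hard-called genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a
#' \linkS4class{GenotypeMatrix}. Only biallelic SNP records are kept:
#' multiallelic records and indels are dropped and their counts reported via
#' a message and the \code{"dropped"} attribute. Phased and unphased GT
#' separators are treated identically; \code{./.} (or \code{.}) is missing.
#' Per-call DP is attached when present in FORMAT; site QUAL is attached
#' when numeric.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param samples optional character vector restricting the sample set;
#'   requesting an absent sample is an error.
#' @return A \linkS4class{GenotypeMatrix} with attribute \code{dropped}
#'   (named counts of multiallelic and non-SNP records removed).
#' @export
readGenotypeVcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) stop("VCF '", path, "' has no records")
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- !multi & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  dropped <- c(multiallelic = sum(multi), non_snp = sum(!snp & !multi))
  if (any(dropped > 0))
    message("readGenotypeVcf: dropped ", dropped[["multiallelic"]],
            " multiallelic and ", dropped[["non_snp"]], " non-SNP record(s)")
  if (!any(snp)) stop("VCF '", path, "' contains no biallelic SNPs")
  v <- v[snp, ]
  fix <- v@fix

  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) {
    samples <- all_samples
  } else {
    miss <- setdiff(samples, all_samples)
    if (length(miss)) stop("sample(s) not in VCF header: ",
                           paste(miss, collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[, samples, drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0")] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% c("1/1")] <- 2L

  depth <- NULL
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    depth <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- depth[, samples, drop = FALSE]
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  gm <- genotypeMatrix(code, chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                       alt = fix[, "ALT"], individuals = samples,
                       depth = depth, qual = qual)
  attr(gm, "dropped") <- dropped
  gm
}

#' Write a GenotypeMatrix as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT (and DP when depth is present). Inverse
#' of \code{\link{readGenotypeVcf}} up to header boilerplate.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeVcf <- function(gm, path) {
  gr <- sites(gm)
  mc <- S4Vectors::mcols(gr)
  qual <- if ("qual" %in% colnames(mc)) {
    ifelse(is.na(mc$qual), ".", format(mc$qual, trim = TRUE))
  } else rep(".", length(gr))
  cmat <- calls(gm)
  gt <- matrix("./.", nrow(cmat), ncol(cmat))
  gt[!is.na(cmat) & cmat == 0L] <- "0/0"
  gt[!is.na(cmat) & cmat == 1L] <- "0/1"
  gt[!is.na(cmat) & cmat == 2L] <- "1/1"
  dp <- callDepth(gm)
  if (!is.null(dp)) {
    fmt <- "GT:DP"
    dpc <- ifelse(is.na(dp), ".", format(dp, trim = TRUE, scientific = FALSE))
    gt <- matrix(paste(gt, dpc, sep = ":"), nrow(cmat), ncol(cmat))
  } else fmt <- "GT"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=coalscan",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (!is.null(dp))
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individuals(gm)), collapse = "\t"))
  body <- cbind(as.character(GenomicRanges::seqnames(gr)),
                GenomicRanges::start(gr), ".", mc$ref, mc$alt, qual, ".",
                ".", fmt, gt)
  writeLines(c(hdr, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Filter sites of a GenotypeMatrix
#'
#' Applies the site-level thresholds of a \linkS4class{SiteFilterConfig} in
#' a fixed order: (1) QUAL, (2) per-call depth masking (out-of-range calls
#' become missing), (3) per-site missingness, (4) minor allele frequency
#' (recomputed after masking), (5) site mean depth. Site order is preserved.
#' Removal counts attribute each removed site to the first rule it failed,
#' so the retained count plus the per-rule removals always equals the input
#' site count.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param cfg a \linkS4class{SiteFilterConfig}.
#' @return The filtered \linkS4class{GenotypeMatrix} with attribute
#'   \code{removed}: named integer counts per rule (plus \code{masked_calls},
#'   the number of genotypes set missing by the depth mask).
#' @examples
#' gm <- genotypeMatrix(matrix(c(0, 0, 0, 1), 2, 2), chrom = c("1", "1"),
#'                      pos = c(1, 2), ref = "A", alt = "T",
#'                      individuals = c("a", "b"))
#' filterSites(gm, siteFilterConfig())  # monomorphic site removed
#' @export
filterSites <- function(gm, cfg = siteFilterConfig()) {
  stopifnot(is(gm, "GenotypeMatrix"), is(cfg, "SiteFilterConfig"))
  validObject(cfg)
  if (nSites(gm) == 0) stop("empty GenotypeMatrix")
  cmat <- calls(gm)
  dp <- callDepth(gm)
  n <- nrow(cmat)
  fail <- rep(NA_character_, n)
  masked <- 0L

  mc <- S4Vectors::mcols(sites(gm))
  if (!is.na(cfg@minQual) && "qual" %in% colnames(mc)) {
    q <- mc$qual
    bad <- !is.na(q) & q < cfg@minQual
    fail[is.na(fail) & bad] <- "qual"
  }
  if (!is.null(dp) && (!is.na(cfg@minDepth) || !is.na(cfg@maxDepth))) {
    out <- !is.na(dp) &
      ((!is.na(cfg@minDepth) & dp < cfg@minDepth) |
       (!is.na(cfg@maxDepth) & dp > cfg@maxDepth))
    masked <- sum(out & !is.na(cmat))
    cmat[out] <- NA_integer_
  }
  missFrac <- rowMeans(is.na(cmat))
  if (!is.na(cfg@maxMissing))
    fail[is.na(fail) & missFrac > cfg@maxMissing] <- "missingness"
  if (!is.na(cfg@minMaf)) {
    nonmiss <- rowSums(!is.na(cmat))
    p <- rowSums(cmat, na.rm = TRUE) / (2 * pmax(nonmiss, 1L))
    maf <- pmin(p, 1 - p)
    fail[is.na(fail) & (nonmiss == 0 | maf < cfg@minMaf)] <- "maf"
  }
  if (!is.null(dp) && (!is.na(cfg@minMeanDepth) || !is.na(cfg@maxMeanDepth))) {
    md <- rowMeans(dp, na.rm = TRUE)
    bad <- (!is.na(cfg@minMeanDepth) & md < cfg@minMeanDepth) |
      (!is.na(cfg@maxMeanDepth) & md > cfg@maxMeanDepth)
    bad[is.na(bad)] <- FALSE
    fail[is.na(fail) & bad] <- "mean_depth"
  }

  keep <- is.na(fail)
  removed <- table(factor(fail[!keep],
                          levels = c("qual", "missingness", "maf",
                                     "mean_depth")))
  out <- new("GenotypeMatrix", calls = cmat[keep, , drop = FALSE],
             sites = sites(gm)[keep], individuals = individuals(gm),
             depth = if (is.null(dp)) NULL else dp[keep, , drop = FALSE])
  attr(out, "removed") <- c(as.vector(removed) |>
                              setNames(names(removed)),
                            masked_calls = masked)
  out
}

#' Read a population map from TSV
#'
#' Expects a header line with columns \code{individual}, \code{species},
#' \code{genus}, \code{role}, \code{is_hybrid} (optional \code{sex}).
#' Lines starting with \code{#} are comments.
#'
#' @param path TSV file path.
#' @return A \linkS4class{PopulationMap}.
#' @export
readPopulationMap <- function(path) {
  tb <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tb) == 0) stop("empty population map: ", path)
  need <- c("individual", "species", "genus", "role", "is_hybrid")
  miss <- setdiff(need, colnames(tb))
  if (length(miss)) stop("population map missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(tb$role), .ROLES)
  if (length(bad)) stop("unknown role token(s): ", paste(bad, collapse = ", "))
  populationMap(tb$individual, tb$species, tb$genus, tb$role,
                as.logical(tb$is_hybrid),
                if ("sex" %in% colnames(tb)) tb$sex else NA)
}

#' Write a population map as TSV
#' @param pm a \linkS4class{PopulationMap}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePopulationMap <- function(pm, path) {
  write.table(popTable(pm), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a chromosome length table from TSV
#'
#' Columns: \code{chrom}, \code{length}, \code{is_sex_chromosome} (or
#' \code{is_z}).
#'
#' @param path TSV file path.
#' @return data.frame(chrom, length, is_z).
#' @export
readChromTable <- function(path) {
  tb <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tb) == 0) stop("empty chromosome table: ", path)
  if ("is_sex_chromosome" %in% colnames(tb) && !"is_z" %in% colnames(tb))
    tb$is_z <- as.logical(tb$is_sex_chromosome)
  need <- c("chrom", "length", "is_z")
  miss <- setdiff(need, colnames(tb))
  if (length(miss)) stop("chromosome table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tb$length <= 0)) stop("chromosome lengths must be positive")
  tb[, need]
}

#' Write a chromosome table as TSV
#' @param chromTable data.frame(chrom, length, is_z).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeChromTable <- function(chromTable, path) {
  out <- data.frame(chrom = chromTable$chrom, length = chromTable$length,
                    is_sex_chromosome = chromTable$is_z)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read trees from a Newick file (one per line)
#'
#' @param path Newick file; blank and \code{#} lines are skipped.
#' @return A list of \link[ape]{phylo} objects (class \code{multiPhylo}).
#' @export
readTrees <- function(path) {
  ln <- readLines(path)
  keep <- which(nzchar(trimws(ln)) & !startsWith(trimws(ln), "#"))
  if (!length(keep)) stop("no trees in ", path)
  trees <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    tr <- tryCatch(ape::read.tree(text = ln[keep[k]]), error = function(e) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
      stop("unparsable Newick at line ", keep[k], " of ", path)
    trees[[k]] <- tr
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Write trees to a Newick file (one per line)
#' @param trees a phylo or list of phylo objects.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTrees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ape::write.tree(structure(trees, class = "multiPhylo"), file = path)
  invisible(path)
}

#' Read a FASTA alignment into a character matrix
#'
#' Rows are sequences (uppercase), columns alignment positions. Both 'N'
#' and '-' are treated as missing data throughout the package.
#'
#' @param path FASTA file path.
#' @return Character matrix with rownames from FASTA headers.
#' @export
readFastaAlignment <- function(path) {
  x <- ape::read.FASTA(path)
  if (length(unique(lengths(x))) != 1)
    stop("alignment rows differ in length: ", path)
  m <- toupper(as.character(as.matrix(x)))
  rownames(m) <- names(x)
  m
}

#' Write a character-matrix alignment as FASTA
#' @param aln character matrix with rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaAlignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

# shared missing-data predicate for alignment characters
.isMissingChar <- function(x) x %in% c("N", "-", "?", "n")
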