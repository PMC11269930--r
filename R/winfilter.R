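#' Enumerate candidate genome windows
#'
#' Candidate windows of length \code{x} start at 0, s, 2s, ... on each
#' chromosome, subject to start + x <= chromosome length. Coordinates are
#' 0-based half-open.
#'
#' @param chromTable data.frame(chrom, length) (extra columns ignored) or a
#'   named numeric vector of chromosome lengths.
#' @param x window length in bp.
#' @param s sampling interval in bp (x <= s).
#' @return data.frame(chrom, start, end).
#' @examples
#' sampleWindows(c(chr1 = 250000), x = 10000, s = 100000)  # 3 candidates
#' @export
sampleWindows <- function(chromTable, x, s) {
  if (x > s) stop("window length x must not exceed the sampling interval s")
  if (is.numeric(chromTable))
    chromTable <- data.frame(chrom = names(chromTable),
                             length = as.numeric(chromTable))
  if (any(chromTable$length <= 0)) stop("chromosome lengths must be positive")
  out <- lapply(seq_len(nrow(chromTable)), function(i) {
    L <- chromTable$length[i]
    if (L < x) return(NULL)
    st <- seq(0, L - x, by = s)
    data.frame(chrom = chromTable$chrom[i], start = st, end = st + x)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  rownames(out) <- NULL
  out
}

#' Alignment completeness filter for one window
#'
#' A window alignment passes iff strictly more than 50\% of its columns
#' have at least 50\% of the individuals non-missing, and at least 80\% of
#' its rows have a missing fraction strictly below 40\%. 'N' and '-' count
#' as missing.
#'
#' @param aln character matrix (individuals x columns).
#' @param minColCoverage fraction of individuals required per column (0.5).
#' @param minColFrac fraction of columns that must reach it (0.5, strict >).
#' @param maxRowMissing per-row missing-fraction bound (0.4, strict <).
#' @param minRowFrac fraction of rows that must satisfy it (0.8, >=).
#' @return List: \code{pass} (logical), \code{colFracOK}, \code{rowFracOK}.
#' @export
filterAlignment <- function(aln, minColCoverage = 0.5, minColFrac = 0.5,
                            maxRowMissing = 0.4, minRowFrac = 0.8) {
  if (!is.matrix(aln) || nrow(aln) == 0 || ncol(aln) == 0)
    stop("nonempty alignment matrix required")
  miss <- matrix(.isMissingChar(aln), nrow(aln), ncol(aln))
  colFracOK <- mean(colMeans(!miss) >= minColCoverage)
  rowFracOK <- mean(rowMeans(miss) < maxRowMissing)
  list(pass = (colFracOK > minColFrac) && (rowFracOK >= minRowFrac),
       colFracOK = colFracOK, rowFracOK = rowFracOK)
}

#' Sample windows with completeness filtering and adjacent-window fallback
#'
#' Scans each chromosome left to right. A candidate window that fails the
#' completeness filter is slid rightward in steps of the window length
#' until it passes or the next scheduled candidate start is reached. After
#' a pass, scanning resumes one sampling interval beyond the accepted
#' window's start, so accepted windows never overlap.
#'
#' @param chromTable data.frame(chrom, length).
#' @param alignmentSource function(chrom, start, length) returning the
#'   window alignment as a character matrix (individuals x columns).
#' @param x window length in bp.
#' @param s sampling interval in bp.
#' @param ... forwarded to \code{\link{filterAlignment}}.
#' @return data.frame(chrom, start, end, status, offset): status PASS for a
#'   first-try acceptance, FALLBACK_PASS when one or more slides were
#'   needed; offset counts the slides. Chromosomes yielding no window are
#'   reported via a message.
#' @export
sampleAndFilter <- function(chromTable, alignmentSource, x, s, ...) {
  if (x > s) stop("window length x must not exceed the sampling interval s")
  res <- list()
  for (i in seq_len(nrow(chromTable))) {
    chrom <- chromTable$chrom[i]
    L <- chromTable$length[i]
    cand <- 0
    got <- 0L
    while (cand + x <= L) {
      limit <- min(cand + s, L)
      start <- cand
      accepted <- NA
      off <- 0L
      while (start + x <= limit) {
        f <- filterAlignment(alignmentSource(chrom, start, x), ...)
        if (f$pass) { accepted <- start; break }
        start <- start + x
        off <- off + 1L
      }
      if (!is.na(accepted)) {
        res[[length(res) + 1]] <-
          data.frame(chrom = chrom, start = accepted, end = accepted + x,
                     status = if (off > 0) "FALLBACK_PASS" else "PASS",
                     offset = off)
        got <- got + 1L
        cand <- accepted + s
      } else {
        cand <- cand + s
      }
    }
    if (got == 0L)
      message("sampleAndFilter: no accepted windows on chromosome ", chrom)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), status = character(),
                      offset = integer())
  rownames(out) <- NULL
  out
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' Computed over jointly non-missing columns ('N', '-' and '?' are
#' missing): p = mismatch fraction, d = -(3/4) log(1 - 4p/3). A saturated
#' pair (p >= 3/4) yields NaN with a warning — the flagged error value.
#'
#' @param a,b character vectors of equal length.
#' @return JC distance (NaN when saturated).
#' @examples
#' jcDistance(c("A", "C", "G"), c("A", "C", "T"))
#' @export
jcDistance <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- !.isMissingChar(a) & !.isMissingChar(b)
  if (!any(ok)) stop("no jointly non-missing columns: distance undefined")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.75) {
    warning("JC distance saturated (p >= 3/4)")
    return(NaN)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise JC distance matrix for an alignment
#'
#' @param aln character matrix (individuals x columns) with rownames.
#' @return Symmetric numeric matrix of JC distances.
#' @export
jcDistanceMatrix <- function(aln) {
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- jcDistance(aln[i, ], aln[j, ])
  D
}

#' Neighbor-joining window tree with deterministic tie-breaking
#'
#' Canonical NJ (via \pkg{ape}) over a distance matrix whose taxa are first
#' sorted lexicographically, which fixes the agglomeration order for tied
#' distances. Negative branch lengths are clamped to zero with the deficit
#' moved to the sibling branch, preserving path lengths through the parent.
#'
#' @param D symmetric distance matrix with zero diagonal and >= 3 taxa.
#' @return Unrooted \link[ape]{phylo}.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (any(is.na(D))) stop("distance matrix contains NA/NaN entries")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-9 || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  ord <- order(rownames(D))
  tr <- ape::nj(D[ord, ord])
  # clamp negative edges; move the deficit onto the sibling edge
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sib))
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    else break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write windows as a BED file (0-based half-open)
#' @param windows data.frame(chrom, start, end, ...).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWindowsBed <- function(windows, path) {
  write.table(windows[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
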