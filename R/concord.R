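# Branch contexts for concordance factors: every internal branch of a
# binary rooted species tree, with the four tip groups adjacent to it in
# the unrooted sense (the two child clades and the two far-side subtrees).

.branchContexts <- function(tree) {
  nt <- ape::Ntip(tree)
  if (!ape::is.binary.phylo(tree)) stop("species tree must be binary")
  pp <- ape::prop.part(tree)  # clades per internal node, in node order
  tipsOf <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    tree$tip.label[pp[[node - nt]]]
  }
  root <- nt + 1L
  allTips <- tree$tip.label
  childrenOf <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  parentOf <- function(node) tree$edge[tree$edge[, 2] == node, 1]
  out <- list()
  for (v in (nt + 1L):(nt + tree$Nnode)) {
    if (v == root) next
    kids <- childrenOf(v)
    A <- tipsOf(kids[1]); B <- tipsOf(kids[2])
    u <- parentOf(v)
    if (u == root) {
      sib <- setdiff(childrenOf(root), v)
      if (sib <= nt) next               # pendant edge in the unrooted tree
      if (sib < v) next                 # same unrooted edge, already done
      sk <- childrenOf(sib)
      C <- tipsOf(sk[1]); D <- tipsOf(sk[2])
    } else {
      sib <- setdiff(childrenOf(u), v)
      C <- tipsOf(sib)
      D <- setdiff(allTips, tipsOf(u))
      if (!length(D)) next
    }
    side1 <- sort(c(A, B))
    out[[length(out) + 1]] <- list(node = v, A = A, B = B, C = C, D = D,
                                   side1 = side1,
                                   id = paste(side1, collapse = ","))
  }
  out
}

# does `tree` (restricted to `shared`) display the split side1 | rest?
.displaysSplit <- function(tree, shared, side1) {
  pr <- ape::keep.tip(tree, shared)
  s1 <- sort(intersect(side1, shared))
  s2 <- sort(setdiff(shared, s1))
  for (cl in ape::prop.part(pr)) {
    tl <- sort(pr$tip.label[cl])
    if (identical(tl, s1) || identical(tl, s2)) return(TRUE)
  }
  FALSE
}

#' Window concordance factors
#'
#' For each internal branch of the species tree, the percentage of
#' decisive window trees whose restriction to the shared taxa contains the
#' branch's bipartition. A window tree is decisive for a branch when it
#' carries at least one taxon from each of the four subtrees adjacent to
#' that branch; trees missing whole groups reduce the denominator rather
#' than scoring against the branch.
#'
#' @param speciesTree rooted binary \link[ape]{phylo}.
#' @param windowTrees list of window trees (may miss taxa).
#' @return data.frame(branch, node, wCF, concordant, decisive); wCF is NA
#'   (undefined sentinel) when no window tree is decisive.
#' @export
windowConcordance <- function(speciesTree, windowTrees) {
  ctx <- .branchContexts(speciesTree)
  rows <- lapply(ctx, function(cx) {
    dec <- 0L; con <- 0L
    for (tr in windowTrees) {
      shared <- intersect(tr$tip.label, speciesTree$tip.label)
      if (!length(intersect(shared, cx$A)) ||
          !length(intersect(shared, cx$B)) ||
          !length(intersect(shared, cx$C)) ||
          !length(intersect(shared, cx$D))) next
      dec <- dec + 1L
      if (.displaysSplit(tr, shared, cx$side1)) con <- con + 1L
    }
    data.frame(branch = cx$id, node = cx$node,
               wCF = if (dec > 0) 100 * con / dec else NA_real_,
               concordant = con, decisive = dec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Site concordance factors
#'
#' For each internal branch, samples quartets of taxa (one from each
#' adjacent subtree group), counts decisive alignment sites — all four
#' taxa called A/C/G/T, exactly two states in a 2+2 pattern — and reports
#' 100 times the mean, over quartets with at least one decisive site, of
#' the fraction of decisive sites supporting the species-tree pairing.
#' Sampling uses R's RNG; set a seed for reproducibility, or pass
#' \code{quartets = Inf} for deterministic exhaustive enumeration.
#'
#' @param speciesTree rooted binary \link[ape]{phylo}.
#' @param aln character matrix (taxa x sites) — e.g. concatenated window
#'   alignments — or a list of such matrices (columns are concatenated,
#'   rows matched by name).
#' @param quartets quartets sampled per branch (default 100; Inf = all).
#' @return data.frame(branch, node, sCF, quartetsUsed, meanDecisiveSites);
#'   sCF is NA when no sampled quartet has a decisive site.
#' @export
siteConcordance <- function(speciesTree, aln, quartets = 100) {
  if (is.list(aln) && !is.matrix(aln)) {
    taxa <- Reduce(union, lapply(aln, rownames))
    aln <- do.call(cbind, lapply(aln, function(m) {
      out <- matrix("N", length(taxa), ncol(m),
                    dimnames = list(taxa, NULL))
      out[rownames(m), ] <- m
      out
    }))
  }
  ctx <- .branchContexts(speciesTree)
  taxa <- rownames(aln)
  rows <- lapply(ctx, function(cx) {
    gr <- lapply(list(cx$A, cx$B, cx$C, cx$D), intersect, x = taxa)
    if (any(lengths(gr) == 0))
      return(data.frame(branch = cx$id, node = cx$node, sCF = NA_real_,
                        quartetsUsed = 0L, meanDecisiveSites = NA_real_))
    qs <- if (is.finite(quartets)) {
      cbind(sample(gr[[1]], quartets, replace = TRUE),
            sample(gr[[2]], quartets, replace = TRUE),
            sample(gr[[3]], quartets, replace = TRUE),
            sample(gr[[4]], quartets, replace = TRUE))
    } else as.matrix(expand.grid(gr[[1]], gr[[2]], gr[[3]], gr[[4]],
                                 stringsAsFactors = FALSE))
    fr <- numeric(0); nd <- integer(0)
    for (q in seq_len(nrow(qs))) {
      a <- aln[qs[q, 1], ]; b <- aln[qs[q, 2], ]
      c_ <- aln[qs[q, 3], ]; d <- aln[qs[q, 4], ]
      good <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T") &
        c_ %in% c("A", "C", "G", "T") & d %in% c("A", "C", "G", "T")
      sAB <- good & a == b & c_ == d & a != c_
      sAC <- good & a == c_ & b == d & a != b
      sAD <- good & a == d & b == c_ & a != b
      tot <- sum(sAB) + sum(sAC) + sum(sAD)
      if (tot > 0) { fr <- c(fr, sum(sAB) / tot); nd <- c(nd, tot) }
    }
    data.frame(branch = cx$id, node = cx$node,
               sCF = if (length(fr)) 100 * mean(fr) else NA_real_,
               quartetsUsed = length(fr),
               meanDecisiveSites = if (length(nd)) mean(nd) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Combined concordance-factor table and annotated tree
#'
#' @param speciesTree rooted binary \link[ape]{phylo}.
#' @param windowTrees list of window trees (or NULL to skip wCF).
#' @param aln alignment input for \code{\link{siteConcordance}} (or NULL).
#' @param quartets quartets per branch for sCF.
#' @return List: \code{table} (per-branch wCF/sCF) and \code{tree} (the
#'   species tree with "wCF/sCF" node labels, writable with
#'   \code{\link{writeTrees}}).
#' @export
concordanceFactors <- function(speciesTree, windowTrees = NULL, aln = NULL,
                               quartets = 100) {
  w <- if (!is.null(windowTrees)) windowConcordance(speciesTree, windowTrees)
  s <- if (!is.null(aln)) siteConcordance(speciesTree, aln, quartets)
  tab <- if (!is.null(w) && !is.null(s))
    merge(w, s[, c("branch", "sCF", "quartetsUsed", "meanDecisiveSites")],
          by = "branch")
  else if (!is.null(w)) w else s
  tr <- speciesTree
  nt <- ape::Ntip(tr)
  lab <- rep("", tr$Nnode)
  if (!is.null(tab) && "node" %in% colnames(tab))
    for (i in seq_len(nrow(tab)))
      lab[tab$node[i] - nt] <- paste0(
        if ("wCF" %in% colnames(tab)) sprintf("%.1f", tab$wCF[i]) else "",
        if (all(c("wCF", "sCF") %in% colnames(tab))) "/" else "",
        if ("sCF" %in% colnames(tab)) sprintf("%.1f", tab$sCF[i]) else "")
  tr$node.label <- lab
  list(table = tab, tree = tr)
}
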