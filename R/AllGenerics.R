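#' @name coalscan-accessors
#' @title Accessors for coalscan data classes
#' @description Slot access for \linkS4class{GenotypeMatrix},
#'   \linkS4class{PopulationMap} and \linkS4class{TriadDResult} goes through
#'   these generics; user code should never reach into slots directly.
#' @param x,object a coalscan object.
#' @param role a quartet role, one of "P1", "P2", "P3", "O".
#' @param ... unused.
NULL

#' @rdname coalscan-accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname coalscan-accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname coalscan-accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname coalscan-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @rdname coalscan-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname coalscan-accessors
#' @export
setGeneric("callDepth", function(x) standardGeneric("callDepth"))
#' @rdname coalscan-accessors
#' @export
setGeneric("popTable", function(x) standardGeneric("popTable"))
#' @rdname coalscan-accessors
#' @export
setGeneric("roleIndividuals", function(x, role) standardGeneric("roleIndividuals"))
#' @rdname coalscan-accessors
#' @export
setGeneric("hybridIndividuals", function(x) standardGeneric("hybridIndividuals"))

#' @rdname coalscan-accessors
#' @export
setMethod("calls", "GenotypeMatrix", function(x) x@calls)
#' @rdname coalscan-accessors
#' @export
setMethod("sites", "GenotypeMatrix", function(x) x@sites)
#' @rdname coalscan-accessors
#' @export
setMethod("individuals", "GenotypeMatrix", function(x) x@individuals)
#' @rdname coalscan-accessors
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) nrow(x@calls))
#' @rdname coalscan-accessors
#' @export
setMethod("nIndividuals", "GenotypeMatrix", function(x) ncol(x@calls))
#' @rdname coalscan-accessors
#' @export
setMethod("callDepth", "GenotypeMatrix", function(x) x@depth)

#' @rdname coalscan-accessors
#' @export
setMethod("popTable", "PopulationMap", function(x) x@tab)
#' @rdname coalscan-accessors
#' @export
setMethod("individuals", "PopulationMap", function(x) x@tab$individual)
#' @rdname coalscan-accessors
#' @export
setMethod("roleIndividuals", "PopulationMap", function(x, role) {
  stopifnot(role %in% c("P1", "P2", "P3", "O"))
  x@tab$individual[x@tab$role == role & !x@tab$is_hybrid]
})
#' @rdname coalscan-accessors
#' @export
setMethod("hybridIndividuals", "PopulationMap",
          function(x) x@tab$individual[x@tab$is_hybrid])

#' Individuals belonging to a species or genus
#'
#' @param pm a \linkS4class{PopulationMap}.
#' @param label species or genus label.
#' @param by match on "species" or "genus".
#' @param includeHybrids keep flagged hybrids (default FALSE).
#' @return Character vector of individual IDs.
#' @export
groupIndividuals <- function(pm, label, by = c("species", "genus"),
                             includeHybrids = FALSE) {
  by <- match.arg(by)
  tb <- popTable(pm)
  ids <- tb$individual[tb[[by]] %in% label]
  if (!includeHybrids)
    ids <- setdiff(ids, tb$individual[tb$is_hybrid])
  ids
}

#' Subset a GenotypeMatrix by individuals and/or sites
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param i site indices (logical or integer).
#' @param j individual IDs or indices.
#' @param ... unused.
#' @param drop ignored.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  if (is.character(j)) {
    jj <- match(j, x@individuals)
    if (anyNA(jj)) stop("unknown individual(s): ",
                        paste(j[is.na(jj)], collapse = ", "))
    j <- jj
  }
  new("GenotypeMatrix", calls = x@calls[i, j, drop = FALSE],
      sites = x@sites[i], individuals = x@individuals[j],
      depth = if (is.null(x@depth)) NULL else x@depth[i, j, drop = FALSE])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "sites x",
      ncol(object@calls), "individuals\n")
  ch <- unique(as.character(GenomicRanges::seqnames(object@sites)))
  cat("  chromosomes:", paste(head(ch, 8), collapse = ", "),
      if (length(ch) > 8) "..." else "", "\n")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(object@calls))), "\n")
  cat("  depth:", if (is.null(object@depth)) "absent" else "present", "\n")
})

setMethod("show", "PopulationMap", function(object) {
  tb <- object@tab
  cat("PopulationMap:", nrow(tb), "individuals,",
      length(unique(tb$species)), "species,",
      length(unique(tb$genus)), "genera\n")
  rl <- table(factor(tb$role, levels = .ROLES))
  cat("  roles:", paste(names(rl), rl, sep = "=", collapse = " "), "\n")
  cat("  hybrids:", sum(tb$is_hybrid), "\n")
})

setMethod("show", "SiteFilterConfig", function(object) {
  cat("SiteFilterConfig:\n")
  for (s in slotNames(object))
    cat("  ", s, ": ", format(slot(object, s)), "\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  phy <- object@speciesTree
  cat("SimulationConfig:", length(phy$tip.label), "species (",
      paste(phy$tip.label, collapse = ", "), ")\n")
  cat("  diploids/species:",
      paste(names(object@samplesPerSpecies), object@samplesPerSpecies,
            sep = "=", collapse = " "), "\n")
  cat("  pulses:", nrow(object@pulses),
      "| mutRate:", object@mutRate,
      "| window:", object@windowLength, "bp every",
      object@windowSpacing, "bp\n")
  cat("  chromosomes:", nrow(object@chromTable),
      sprintf("(%d Z)", sum(object@chromTable$is_z)),
      "| retention alpha:", object@alpha, "rMin:", object@rMin, "\n")
})

setMethod("show", "TriadDResult", function(object) {
  cat(sprintf("TriadDResult ((%s,%s),%s) outgroup %s\n", object@P1,
              object@P2, object@P3, object@outgroup))
  cat(sprintf("  D = %.5f (ABBA %.3f, BABA %.3f), Z = %s over %d blocks, %d sites\n",
              object@D, object@nABBA, object@nBABA,
              ifelse(is.na(object@z), "NA", sprintf("%.2f", object@z)),
              object@nBlocks, object@nSites))
})

#' Coerce a TriadDResult to a one-row data.frame
#'
#' @param x a \linkS4class{TriadDResult}.
#' @param ... unused.
#' @exportS3Method base::as.data.frame
as.data.frame.TriadDResult <- function(x, ...) {
  data.frame(P1 = x@P1, P2 = x@P2, P3 = x@P3, outgroup = x@outgroup,
             nABBA = x@nABBA, nBABA = x@nBABA, D = x@D, se = x@se, z = x@z,
             nBlocks = x@nBlocks, nSites = x@nSites,
             stringsAsFactors = FALSE)
}
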