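#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> site filter -> window trees -> Patterson's D +
#' AIM profiling + quartet tallies + concordance factors from a single
#' YAML configuration, writing every stage output as TSV (plus VCF, BED
#' and Newick) under \code{outdir} together with a JSON manifest of
#' parameters, seed and output MD5 hashes. Identical config and seed give
#' byte-identical outputs and manifests.
#'
#' Config keys (all optional, shown with defaults in the shipped demo
#' config): \code{seed}; \code{simulate} (species tree, samples per
#' species, pulses, mutation rate, window layout, chromosomes, retention
#' landscape, hybrids); \code{filter} (site thresholds); \code{dstat}
#' (outgroup, block size); \code{aims} (discovery groups, thresholds);
#' \code{quartets} (bin scheme); \code{concord} (quartets per branch).
#'
#' @param config path to a YAML file or an equivalent named list.
#' @param outdir output directory (created if needed).
#' @param seed integer seed overriding the config's (optional).
#' @return The manifest, invisibly (also written to
#'   \code{outdir/manifest.json}).
#' @export
runPipeline <- function(config, outdir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML path or a list")
  if (is.null(seed)) seed <- cfg$seed %||% 1L
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    paths[[length(paths) + 1]] <<- p
    names(paths)[length(paths)] <<- name
    paths <<- paths
    p
  }
  tsv <- function(df, comment = NULL) function(p) {
    con <- file(p, "w"); on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  }

  ## --- simulate -----------------------------------------------------
  sc <- cfg$simulate %||% list()
  simcfg <- simulationConfig(
    speciesTree = sc$species_tree %||% "(((P1:1,P2:1):1,P3:2):2,O:4);",
    samplesPerSpecies = unlist(sc$samples_per_species) %||% 2L,
    pulses = if (!is.null(sc$pulses))
      do.call(rbind, lapply(sc$pulses, as.data.frame))
    else NULL,
    mutRate = sc$mut_rate %||% 2e-5,
    windowLength = sc$window_length %||% 1e4,
    windowSpacing = sc$window_spacing %||% 1e5,
    chromTable = if (!is.null(sc$chromosomes))
      do.call(rbind, lapply(sc$chromosomes, as.data.frame)) else NULL,
    alpha = sc$alpha %||% 0, rMin = sc$r_min %||% 0.1,
    zScale = sc$z_scale %||% 0.1, zNeScale = sc$z_ne_scale %||% 0.75)
  sim <- synthesizeGenotypes(simcfg)
  for (h in sc$hybrids %||% list())
    sim <- addHybrids(sim, h$parent_a, h$parent_b,
                      h$generation %||% "F1", h$count %||% 1,
                      h$error_rate %||% 0)
  emit("genotypes.vcf", function(p) writeGenotypeVcf(sim$gm, p))
  emit("popmap.tsv", function(p) writePopulationMap(sim$pm, p))
  emit("chromosomes.tsv",
       function(p) writeChromTable(simcfg@chromTable, p))
  emit("truth_windows.tsv", tsv(sim$truth$windows))

  ## --- site filter --------------------------------------------------
  fl <- cfg$filter %||% list()
  fcfg <- siteFilterConfig(minMaf = fl$min_maf %||% 0.03,
                           maxMissing = fl$max_missing %||% 0.10)
  gmF <- filterSites(sim$gm, fcfg)
  emit("filtered_genotypes.vcf", function(p) writeGenotypeVcf(gmF, p))
  emit("filter_report.tsv",
       tsv(data.frame(rule = names(attr(gmF, "removed")),
                      removed = as.integer(attr(gmF, "removed")))))

  ## --- window trees -------------------------------------------------
  trees <- windowTrees(sim$truth$batch)
  emit("window_trees.nwk", function(p) writeTrees(trees, p))
  emit("windows.bed", function(p) writeWindowsBed(sim$truth$windows, p))

  ## --- Patterson's D ------------------------------------------------
  ds <- cfg$dstat %||% list()
  outg <- ds$outgroup %||% "O"
  dres <- pattersonDAll(gmF, sim$pm, simcfg@speciesTree, outg,
                        blockSize = ds$block_size %||% 1e6)
  emit("dstat_triads.tsv",
       tsv(dres, "Patterson's D; D>0 = excess P2-P3 allele sharing"))
  for (p3 in unique(dres$P3)) {
    hm <- dHeatmapTable(dres, p3)
    emit(paste0("dstat_heatmap_", p3, ".tsv"),
         function(p) write.table(hm, p, sep = "\t", quote = FALSE,
                                 col.names = NA))
  }

  ## --- AIMs ---------------------------------------------------------
  am <- cfg$aims %||% list()
  aimTab <- NULL
  if (!is.null(am$group_a)) {
    zc <- simcfg@chromTable$chrom[simcfg@chromTable$is_z]
    aimTab <- findAims(sim$gm, sim$pm, am$group_a, am$group_b,
                       minPerGroup = am$min_per_group %||% 2,
                       zChroms = zc)
    emit("aims.tsv", function(p) writeAims(aimTab, p))
    hy <- hybridIndividuals(sim$pm)
    if (length(hy) && nrow(aimTab)) {
      prof <- do.call(rbind, lapply(hy, function(h) {
        pr <- profileHybrid(sim$gm, h, aimTab,
                            minAims = am$min_aims %||% 100)
        data.frame(individual = h, nAims = pr$nAims,
                   nGenotyped = pr$nGenotyped, t(pr$fractions),
                   hetFraction = pr$hetFraction,
                   classification = pr$classification)
      }))
      emit("hybrid_profiles.tsv", tsv(prof))
    }
  }

  ## --- quartet tallies ----------------------------------------------
  qt <- cfg$quartets %||% list()
  combos <- cartesianCombinations(sim$pm)
  labels <- scoreGenealogyQuartets(sim$truth$batch, combos)
  tl <- tallyQuartetLabels(labels, sim$truth$windows, simcfg@chromTable,
                           binScheme(qt$mode %||% "SCALED_FOLDED",
                                     qt$width %||% 1e6))
  conv <- paste(names(tl$convention), tl$convention, sep = "=",
                collapse = "; ")
  emit("quartet_pooled.tsv",
       tsv(data.frame(stratum = rownames(tl$pooled), tl$pooled), conv))
  emit("quartet_per_combo.tsv", tsv(tl$perCombo, conv))
  emit("quartet_per_bin.tsv", tsv(tl$perBin, conv))
  sk <- telomereSkew(tl$perBin)
  emit("quartet_summary.tsv",
       tsv(data.frame(telomeric_abba_baba = sk$telomericRatio,
                      interior_abba_baba = sk$interiorRatio), conv))

  ## --- concordance factors ------------------------------------------
  cc <- cfg$concord %||% list()
  nCF <- min(length(trees), cc$max_trees %||% 200)
  cf <- concordanceFactors(simcfg@speciesTree, trees[seq_len(nCF)],
                           aln = NULL)
  emit("concordance.tsv", tsv(cf$table))
  emit("species_tree_annotated.nwk",
       function(p) writeTrees(cf$tree, p))

  manifest <- list(package = "coalscan",
                   version = as.character(utils::packageVersion("coalscan")),
                   seed = as.integer(seed), config = cfg,
                   outputs = lapply(seq_along(paths), function(i)
                     list(name = names(paths)[i],
                          md5 = unname(tools::md5sum(paths[[i]])))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Aggregate pipeline outputs into summary tables
#'
#' Reads a manifest written by \code{\link{runPipeline}} and loads every
#' stage's TSV outputs; missing outputs produce a warning and a partial
#' report rather than an error. Regenerating the report from the same
#' manifest is a pure function of the files on disk.
#'
#' @param manifestPath path to \code{manifest.json}.
#' @return Named list of data.frames plus \code{rowCounts}.
#' @export
pipelineReport <- function(manifestPath) {
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  outdir <- dirname(manifestPath)
  if (length(man$outputs) == 0) {
    warning("empty manifest: nothing to report")
    return(list(rowCounts = integer(0)))
  }
  nm <- man$outputs$name
  tabs <- list()
  for (f in nm[grepl("\\.tsv$", nm)]) {
    p <- file.path(outdir, f)
    if (!file.exists(p)) {
      warning("missing stage output: ", f)
      next
    }
    tabs[[sub("\\.tsv$", "", f)]] <-
      read.delim(p, comment.char = "#", stringsAsFactors = FALSE)
  }
  tabs$rowCounts <- vapply(tabs, nrow, integer(1))
  tabs
}
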