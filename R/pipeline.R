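# Pipeline orchestration: run whichever stages are configured, write one
# TSV per stage plus a machine-readable summary and a run log. Every output
# is re-derivable from config + inputs alone.

.PIPELINE_KEYS <- list(
  top = c("outdir", "seed", "catalog", "scan", "phylo", "ortho",
          "promoters", "expression"),
  catalog = c("locus_table", "max_gap", "min_size", "gff"),
  scan = c("proteins", "zipper_alphabet", "gas_strict"),
  phylo = c("alignment", "reps", "collapse_below", "min_support",
            "min_coverage", "reference", "model"),
  ortho = c("vitis", "species", "e_max", "identity_min"),
  promoters = c("targets", "background", "motifs", "alpha", "k_range",
                "top_n"),
  expression = c("matrix", "sample_meta", "distance_threshold",
                 "threshold_abs"))

.checkKeys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  }
}

.stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the configured characterization pipeline
#'
#' Executes, for whichever inputs are configured, the stages scan ->
#' catalog -> phylo -> ortho -> promoters -> expression; writes one TSV per
#' stage into the output directory, a machine-readable `summary.json`
#' (catalog census, chromosome distribution, class calls, orthology
#' counts), and `run.log` with package version, seed and parameters.
#' Re-running with an identical config and inputs reproduces the summary
#' byte for byte.
#'
#' @param config a named list or the path to a YAML file. Top-level keys:
#'   `outdir` (required), `seed`, and optional blocks `catalog`
#'   (`locus_table`, `max_gap`, `min_size`, `gff`), `scan` (`proteins`
#'   FASTA), `phylo` (`alignment` aligned FASTA, `reps`, `collapse_below`,
#'   `min_support`, `min_coverage`, `reference` named list gene ->
#'   subclass), `ortho` (`vitis` FASTA, `species` named list of FASTAs,
#'   thresholds), `promoters` (`targets`, `background` FASTAs, `motifs`
#'   TSV, `alpha`), `expression` (`matrix` TSV genes x samples,
#'   `sample_meta` TSV, `distance_threshold`, `threshold_abs`). Unknown
#'   keys are rejected.
#' @return (invisibly) the summary list.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  .checkKeys(config, .PIPELINE_KEYS$top, "top level")
  if (is.null(config$outdir)) stop("config needs an outdir")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  summary <- list(seed = seed)
  logline <- character(0)
  log <- function(...) logline <<- c(logline, paste0(...))
  log("lbdfam pipeline, package version ", as.character(packageVersion("lbdfam")))
  log("seed: ", seed)

  for (blk in intersect(names(config), names(.PIPELINE_KEYS)[-1])) {
    .checkKeys(config[[blk]], .PIPELINE_KEYS[[blk]], blk)
  }

  if (!is.null(config$scan)) {
    .stage("scan", log, {
      cfg <- config$scan
      prot <- Biostrings::readAAStringSet(cfg$proteins)
      gr <- motifGrammar(
        zipper_alphabet = if (is.null(cfg$zipper_alphabet)) "LVI" else
          cfg$zipper_alphabet,
        gas_strict = if (is.null(cfg$gas_strict)) TRUE else cfg$gas_strict)
      ann <- annotateProteome(prot, gr)
      write.table(ann, file.path(outdir, "scan_annotations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$scan <- list(n_sequences = nrow(ann),
                           class_calls = as.list(table(ann$class)))
      log("scan: ", nrow(ann), " sequences annotated")
    })
  }

  if (!is.null(config$catalog)) {
    .stage("catalog", log, {
      cfg <- config$catalog
      cat_df <- parseLocusTable(cfg$locus_table)
      max_gap <- if (is.null(cfg$max_gap)) 100000 else cfg$max_gap
      min_size <- if (is.null(cfg$min_size)) 2L else cfg$min_size
      fam <- familySummary(cat_df)
      dist <- chromosomeDistribution(cat_df)
      arrays <- detectTandemArrays(cat_df, max_gap = max_gap,
                                   min_size = min_size)
      write.table(cat_df, file.path(outdir, "catalog.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(arrays, file.path(outdir, "tandem_arrays.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summary$catalog <- list(
        n_loci = fam$total,
        by_class = as.list(fam$by_class),
        chromosome_distribution = as.list(dist),
        n_tandem_arrays = nrow(arrays))
      if (!is.null(cfg$gff)) {
        ex <- exonStructureSummary(cfg$gff)
        write.table(ex$structures, file.path(outdir, "exon_structure.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        summary$catalog$exon_histogram <- as.list(ex$histogram)
      }
      log("catalog: ", fam$total, " loci, ", nrow(arrays), " tandem arrays")
    })
  }

  if (!is.null(config$phylo)) {
    .stage("phylo", log, {
      cfg <- config$phylo
      msa <- Biostrings::readAAStringSet(cfg$alignment)
      min_cov <- if (is.null(cfg$min_coverage)) 0.95 else cfg$min_coverage
      msa <- filterColumns(msa, min_coverage = min_cov)
      st <- bootstrapTree(
        msa,
        n_reps = if (is.null(cfg$reps)) 100L else as.integer(cfg$reps),
        seed = seed,
        collapse_below = if (is.null(cfg$collapse_below)) 30 else
          cfg$collapse_below,
        model = if (is.null(cfg$model)) "poisson" else cfg$model)
      ape::write.tree(treeOf(st), file.path(outdir, "tree_full.nwk"))
      ape::write.tree(collapsedTree(st), file.path(outdir, "tree_collapsed.nwk"))
      summary$phylo <- list(n_taxa = ape::Ntip(treeOf(st)),
                            median_support = stats::median(
                              supportValues(st), na.rm = TRUE))
      if (!is.null(cfg$reference)) {
        ref <- unlist(cfg$reference)
        asg <- assignSubclasses(st, ref,
                                min_support = if (is.null(cfg$min_support))
                                  70 else cfg$min_support)
        write.table(asg, file.path(outdir, "subclass_assignments.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        summary$phylo$assignments <- as.list(table(asg$status))
      }
      log("phylo: ", ape::Ntip(treeOf(st)), " taxa")
    })
  }

  if (!is.null(config$ortho)) {
    .stage("ortho", log, {
      cfg <- config$ortho
      vitis <- Biostrings::readAAStringSet(cfg$vitis)
      species <- lapply(cfg$species, Biostrings::readAAStringSet)
      e_max <- if (is.null(cfg$e_max)) 1e-20 else cfg$e_max
      id_min <- if (is.null(cfg$identity_min)) 0.40 else cfg$identity_min
      om <- orthologPresenceMatrix(vitis, species, e_max = e_max,
                                   identity_min = id_min)
      write.table(om$results, file.path(outdir, "orthology.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summary$ortho <- list(categories = as.list(table(om$results$category)),
                            n_genes_no_ortholog = length(om$no_ortholog_genes))
      log("ortho: ", length(vitis), " genes x ", length(species), " species")
    })
  }

  if (!is.null(config$promoters)) {
    .stage("promoters", log, {
      cfg <- config$promoters
      targets <- Biostrings::readDNAStringSet(cfg$targets)
      background <- Biostrings::readDNAStringSet(cfg$background)
      motifs <- loadMotifDictionary(cfg$motifs)
      alpha <- if (is.null(cfg$alpha)) 0.01 else cfg$alpha
      enr <- motifEnrichment(targets, background, motifs, alpha = alpha)
      write.table(enr, file.path(outdir, "motif_enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      summary$promoters <- list(n_motifs = nrow(enr),
                                n_enriched = sum(enr$enriched))
      log("promoters: ", sum(enr$enriched), "/", nrow(enr),
          " motifs enriched at alpha ", alpha)
    })
  }

  if (!is.null(config$expression)) {
    .stage("expression", log, {
      cfg <- config$expression
      vals <- as.matrix(read.delim(cfg$matrix, row.names = 1,
                                   check.names = FALSE))
      meta <- read.delim(cfg$sample_meta, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
      se <- expressionMatrix(vals, meta)
      thr <- if (is.null(cfg$threshold_abs)) 256 else cfg$threshold_abs
      dthr <- if (is.null(cfg$distance_threshold)) 0.2 else
        cfg$distance_threshold
      calls <- assignTissueOntology(se, threshold_abs = thr)
      cl <- coexpressionClusters(se, distance_threshold = dthr)
      write.table(calls, file.path(outdir, "tissue_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cl_df <- if (length(cl)) {
        do.call(rbind, lapply(seq_along(cl), function(i) {
          data.frame(cluster = i, gene = cl[[i]]$members,
                     max_internal_distance = cl[[i]]$max_internal_distance,
                     stringsAsFactors = FALSE)
        }))
      } else data.frame(cluster = integer(0), gene = character(0),
                        max_internal_distance = numeric(0))
      write.table(cl_df, file.path(outdir, "coexpression_clusters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$expression <- list(n_genes = nrow(vals),
                                 n_tissue_calls = nrow(calls),
                                 n_clusters = length(cl))
      log("expression: ", nrow(vals), " genes, ", length(cl), " clusters")
    })
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(logline, paste0("finished: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(outdir, "run.log"))
  invisible(summary)
}
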