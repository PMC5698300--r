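#' Simulation configuration for the synthetic-data generators
#'
#' A validated container for every knob of the synthetic-data module. One
#' `SimConfig` drives all five generators; the same seed always reproduces
#' byte-identical outputs.
#'
#' @slot seed integer RNG seed.
#' @slot n_class1,n_class2,n_decoys counts of generated Class I / Class II /
#'   decoy proteins.
#' @slot protein_len integer range (min, max) of generated protein lengths.
#' @slot n_chromosomes number of chromosomes in generated gene catalogs.
#' @slot chromosome_length chromosome length in bp.
#' @slot n_background_genes number of non-array genes per generated catalog.
#' @slot tandem_array_spec list of planted arrays, each
#'   `list(chromosome=, n_genes=, max_gap_bp=)`.
#' @slot n_genes number of ancestral genes in ortholog-family simulations.
#' @slot n_species number of non-grapevine species.
#' @slot loss_prob,dup_prob per gene-per species probabilities of gene loss
#'   and of a reciprocity-breaking duplication.
#' @slot mutation_rate per-site amino-acid substitution probability between
#'   the ancestral and each species copy.
#' @slot motif_pattern planted promoter motif (DNA string).
#' @slot motif_freq_target,motif_freq_background per-sequence planting
#'   probabilities in target and background promoter sets.
#' @slot n_targets,n_background_promoters promoter set sizes.
#' @slot promoter_len promoter length in bp.
#' @slot n_modules,module_size planted co-expression modules.
#' @slot module_pcc target expected pairwise Pearson correlation within a
#'   module, in [0, 1].
#' @slot noise_sd independent log2-intensity noise sd for expression values.
#' @slot n_tissues,n_reps tissues and replicates per tissue in the simulated
#'   atlas.
#' @slot n_tissue_specific,n_noise_genes planted tissue-specific genes and
#'   unstructured background genes.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  n_class1 = "integer", n_class2 = "integer", n_decoys = "integer",
  protein_len = "integer",
  n_chromosomes = "integer", chromosome_length = "numeric",
  n_background_genes = "integer", tandem_array_spec = "list",
  n_genes = "integer", n_species = "integer",
  loss_prob = "numeric", dup_prob = "numeric", mutation_rate = "numeric",
  motif_pattern = "character",
  motif_freq_target = "numeric", motif_freq_background = "numeric",
  n_targets = "integer", n_background_promoters = "integer",
  promoter_len = "integer",
  n_modules = "integer", module_size = "integer", module_pcc = "numeric",
  noise_sd = "numeric",
  n_tissues = "integer", n_reps = "integer",
  n_tissue_specific = "integer", n_noise_genes = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  probs <- c(loss_prob = object@loss_prob, dup_prob = object@dup_prob,
             mutation_rate = object@mutation_rate,
             motif_freq_target = object@motif_freq_target,
             motif_freq_background = object@motif_freq_background,
             module_pcc = object@module_pcc)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    msg <- c(msg, paste0("probabilities must lie in [0, 1]: ",
                         paste(names(probs)[bad], collapse = ", ")))
  }
  counts <- c(object@n_class1, object@n_class2, object@n_decoys,
              object@n_chromosomes, object@n_background_genes,
              object@n_genes, object@n_species, object@n_targets,
              object@n_background_promoters, object@n_modules,
              object@module_size, object@n_tissues, object@n_reps,
              object@n_tissue_specific, object@n_noise_genes)
  if (any(counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (length(object@protein_len) != 2L || diff(object@protein_len) < 0L) {
    msg <- c(msg, "protein_len must be an ascending (min, max) pair")
  }
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  for (arr in object@tandem_array_spec) {
    if (!all(c("chromosome", "n_genes", "max_gap_bp") %in% names(arr))) {
      msg <- c(msg, "each tandem_array_spec entry needs chromosome, n_genes, max_gap_bp")
    } else if (as.integer(arr$chromosome) > object@n_chromosomes) {
      msg <- c(msg, "tandem_array_spec chromosome exceeds n_chromosomes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults are the study conditions of the packaged recovery analyses:
#' 100/100/200 Class I / Class II / decoy proteins; 20 ancestral genes over
#' 3 species with loss and duplication probabilities 0.1 and a 5% per-site
#' substitution rate; 20 + 20 promoters of 500 bp with the planted motif at
#' frequency 1 in targets and 0 in background; three 6-gene co-expression
#' modules at expected pairwise PCC 0.95 over a 6-tissue, 4-replicate atlas.
#'
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @param n_class1,n_class2,n_decoys protein counts.
#' @param protein_len length-2 integer range of protein lengths.
#' @param n_chromosomes,chromosome_length,n_background_genes,tandem_array_spec
#'   gene-catalog layout.
#' @param n_genes,n_species,loss_prob,dup_prob,mutation_rate ortholog-family
#'   parameters.
#' @param motif_pattern,motif_freq_target,motif_freq_background,n_targets,n_background_promoters,promoter_len
#'   promoter parameters.
#' @param n_modules,module_size,module_pcc,noise_sd,n_tissues,n_reps,n_tissue_specific,n_noise_genes
#'   expression parameters.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, n_class1 = 5, n_class2 = 3, n_decoys = 10)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      n_class1 = 100L, n_class2 = 100L, n_decoys = 200L,
                      protein_len = c(150L, 250L),
                      n_chromosomes = 19L, chromosome_length = 3e7,
                      n_background_genes = 20L,
                      tandem_array_spec = list(),
                      n_genes = 20L, n_species = 3L,
                      loss_prob = 0.1, dup_prob = 0.1, mutation_rate = 0.05,
                      motif_pattern = "GGTTGAATACAC",
                      motif_freq_target = 1, motif_freq_background = 0,
                      n_targets = 20L, n_background_promoters = 20L,
                      promoter_len = 500L,
                      n_modules = 3L, module_size = 6L, module_pcc = 0.95,
                      noise_sd = 0.5,
                      n_tissues = 6L, n_reps = 4L,
                      n_tissue_specific = 5L, n_noise_genes = 20L) {
  new("SimConfig",
      seed = as.integer(seed),
      n_class1 = as.integer(n_class1), n_class2 = as.integer(n_class2),
      n_decoys = as.integer(n_decoys),
      protein_len = as.integer(protein_len),
      n_chromosomes = as.integer(n_chromosomes),
      chromosome_length = as.numeric(chromosome_length),
      n_background_genes = as.integer(n_background_genes),
      tandem_array_spec = tandem_array_spec,
      n_genes = as.integer(n_genes), n_species = as.integer(n_species),
      loss_prob = loss_prob, dup_prob = dup_prob,
      mutation_rate = mutation_rate,
      motif_pattern = as.character(motif_pattern),
      motif_freq_target = motif_freq_target,
      motif_freq_background = motif_freq_background,
      n_targets = as.integer(n_targets),
      n_background_promoters = as.integer(n_background_promoters),
      promoter_len = as.integer(promoter_len),
      n_modules = as.integer(n_modules), module_size = as.integer(module_size),
      module_pcc = module_pcc, noise_sd = noise_sd,
      n_tissues = as.integer(n_tissues), n_reps = as.integer(n_reps),
      n_tissue_specific = as.integer(n_tissue_specific),
      n_noise_genes = as.integer(n_noise_genes))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  proteome: ", object@n_class1, " class I / ", object@n_class2,
      " class II / ", object@n_decoys, " decoys, length ",
      object@protein_len[1], "-", object@protein_len[2], "\n", sep = "")
  cat("  orthology: ", object@n_genes, " genes x ", object@n_species,
      " species (loss ", object@loss_prob, ", dup ", object@dup_prob,
      ", mut ", object@mutation_rate, ")\n", sep = "")
  cat("  promoters: ", object@n_targets, "+", object@n_background_promoters,
      " x ", object@promoter_len, " bp, motif ", object@motif_pattern,
      " at ", object@motif_freq_target, "/", object@motif_freq_background,
      "\n", sep = "")
  cat("  expression: ", object@n_modules, " modules x ", object@module_size,
      " genes at PCC ", object@module_pcc, "\n", sep = "")
})

#' LOB-domain motif grammar
#'
#' Describes the three-block grammar used by the scanner: the C-block
#' (C X2 C X6 C X3 C), the GAS block (anchor1 F X2 [VA] H, anchor2
#' D P [VI] Y G with P and G always required), and the leucine-zipper-like
#' block with hydrophobic anchors spaced X6/X3/X6.
#'
#' @slot zipper_alphabet residues accepted as zipper anchors ("LVI" default;
#'   "L" for a strict-leucine mode).
#' @slot n_zipper_anchors number of zipper anchors (4 matches the printed
#'   LX6LX3LX6L pattern).
#' @slot min_partial_anchors minimum matched anchors for a reported
#'   incomplete zipper frame.
#' @slot gas_strict if TRUE the D and Y of anchor2 and its [VI] class are
#'   required; if FALSE only the invariant P and G are required.
#' @slot max_gap_cblock_to_gas,max_gap_gas_to_zipper residue gap limits
#'   between consecutive blocks.
#' @seealso [motifGrammar()]
#' @export
setClass("MotifGrammar", representation(
  zipper_alphabet = "character",
  n_zipper_anchors = "integer",
  min_partial_anchors = "integer",
  gas_strict = "logical",
  max_gap_cblock_to_gas = "integer",
  max_gap_gas_to_zipper = "integer"
))

setValidity("MotifGrammar", function(object) {
  msg <- character()
  if (!nzchar(object@zipper_alphabet)) msg <- c(msg, "empty zipper alphabet")
  if (object@n_zipper_anchors < 2L) msg <- c(msg, "need >= 2 zipper anchors")
  if (object@min_partial_anchors < 1L ||
      object@min_partial_anchors > object@n_zipper_anchors) {
    msg <- c(msg, "min_partial_anchors must lie in [1, n_zipper_anchors]")
  }
  if (object@max_gap_cblock_to_gas < 0L || object@max_gap_gas_to_zipper < 0L) {
    msg <- c(msg, "gap limits must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LOB-domain motif grammar
#'
#' @param zipper_alphabet anchor residues for the zipper; the default "LVI"
#'   reflects that the hydrophobic anchor positions accept valine and
#'   isoleucine as well as leucine. Use "L" for a strict-leucine mode.
#' @param n_zipper_anchors anchors in the zipper frame (default 4, i.e.
#'   LX6LX3LX6L).
#' @param min_partial_anchors matched anchors required to report an
#'   incomplete frame (default 2).
#' @param gas_strict require the full D P [VI] Y G anchor2 (default TRUE);
#'   FALSE relaxes all but the invariant P and G.
#' @param max_gap_cblock_to_gas,max_gap_gas_to_zipper maximum residues
#'   between the end of one block and the start of the next (defaults 120
#'   and 80).
#' @return A [MotifGrammar-class] object.
#' @examples
#' motifGrammar()
#' @export
motifGrammar <- function(zipper_alphabet = "LVI",
                         n_zipper_anchors = 4L,
                         min_partial_anchors = 2L,
                         gas_strict = TRUE,
                         max_gap_cblock_to_gas = 120L,
                         max_gap_gas_to_zipper = 80L) {
  new("MotifGrammar",
      zipper_alphabet = zipper_alphabet,
      n_zipper_anchors = as.integer(n_zipper_anchors),
      min_partial_anchors = as.integer(min_partial_anchors),
      gas_strict = gas_strict,
      max_gap_cblock_to_gas = as.integer(max_gap_cblock_to_gas),
      max_gap_gas_to_zipper = as.integer(max_gap_gas_to_zipper))
}

setMethod("show", "MotifGrammar", function(object) {
  cat("MotifGrammar: C-X2-C-X6-C-X3-C | F-X2-[VA]-H ... D-P-[VI]-Y-G",
      if (!object@gas_strict) " (relaxed)" else "", " | ",
      object@n_zipper_anchors, " x [", object@zipper_alphabet,
      "] anchors (X6/X3 spacing)\n", sep = "")
  cat("  gaps: C-block->GAS <= ", object@max_gap_cblock_to_gas,
      ", GAS->zipper <= ", object@max_gap_gas_to_zipper, " residues\n",
      sep = "")
})

#' Per-protein LOB-domain annotation
#'
#' Result of [classifyProtein()]: located block spans (1-based inclusive
#' residue intervals, NA when absent), zipper completeness, and the Class
#' call ("I", "II" or "none").
#'
#' @slot c_block_span,gas_span,zipper_span integer (start, end) pairs,
#'   NA when the block was not found.
#' @slot zipper_complete logical; all anchors hydrophobic.
#' @slot zipper_anchors number of matched anchors in the reported frame.
#' @slot gas_anchor1_strict,gas_anchor2_strict logical flags for strict
#'   anchor matches (NA when the GAS block is absent).
#' @slot class_call factor-like character: "I", "II" or "none".
#' @export
setClass("LobDomainAnnotation", representation(
  c_block_span = "integer",
  gas_span = "integer",
  zipper_span = "integer",
  zipper_complete = "logical",
  zipper_anchors = "integer",
  gas_anchor1_strict = "logical",
  gas_anchor2_strict = "logical",
  class_call = "character"
))

setValidity("LobDomainAnnotation", function(object) {
  msg <- character()
  if (!object@class_call %in% c("I", "II", "none")) {
    msg <- c(msg, "class_call must be one of I, II, none")
  }
  if (object@class_call %in% c("I", "II") && anyNA(object@c_block_span)) {
    msg <- c(msg, "a class call requires a located C-block")
  }
  if (object@class_call == "I" && !isTRUE(object@zipper_complete)) {
    msg <- c(msg, "class I requires a complete zipper")
  }
  spans <- list(object@c_block_span, object@gas_span, object@zipper_span)
  starts <- vapply(spans, function(s) s[1], integer(1))
  ok <- !is.na(starts)
  if (sum(ok) > 1L && is.unsorted(starts[ok], strictly = TRUE)) {
    msg <- c(msg, "present blocks must be ordered C-block < GAS < zipper")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LobDomainAnnotation the Class call ("I", "II" or "none").
#' @param x a `LobDomainAnnotation`.
#' @export
classCall <- function(x) x@class_call

#' @describeIn LobDomainAnnotation named list of the three block spans.
#' @export
blockSpans <- function(x) {
  list(c_block = x@c_block_span, gas = x@gas_span, zipper = x@zipper_span)
}

setMethod("show", "LobDomainAnnotation", function(object) {
  fmt <- function(s) if (anyNA(s)) "absent" else paste0("[", s[1], ", ", s[2], "]")
  cat("LobDomainAnnotation: class ", object@class_call, "\n", sep = "")
  cat("  C-block ", fmt(object@c_block_span),
      "  GAS ", fmt(object@gas_span),
      "  zipper ", fmt(object@zipper_span),
      if (!anyNA(object@zipper_span)) {
        paste0(" (", object@zipper_anchors, " anchors, ",
               if (isTRUE(object@zipper_complete)) "complete" else "incomplete",
               ")")
      } else "",
      "\n", sep = "")
})

#' Unrooted tree with bootstrap supports
#'
#' Wraps an `ape::phylo` tree with per-internal-edge bootstrap supports
#' (percentages of replicates reproducing each non-trivial bipartition of
#' the full-data tree) and, when branch collapsing was requested, the
#' collapsed polytomous tree. Pre-collapse supports are always retained.
#'
#' @slot tree full-data binary `phylo` tree (supports stored as node labels).
#' @slot supports numeric vector, one entry per internal node of `tree`
#'   (NA for the root, whose bipartition is trivial).
#' @slot collapsed `phylo` tree with edges below the collapse threshold
#'   contracted to polytomies (equal to `tree` when no collapsing applied).
#' @slot collapse_below the collapse threshold used (percent).
#' @export
setClass("SupportTree", representation(
  tree = "ANY",
  supports = "numeric",
  collapsed = "ANY",
  collapse_below = "numeric"
))

setValidity("SupportTree", function(object) {
  msg <- character()
  if (!inherits(object@tree, "phylo")) msg <- c(msg, "tree must be a phylo")
  s <- object@supports[!is.na(object@supports)]
  if (length(s) && (any(s < 0) || any(s > 100))) {
    msg <- c(msg, "supports must lie in [0, 100]")
  }
  if (inherits(object@tree, "phylo") &&
      length(object@supports) != object@tree$Nnode) {
    msg <- c(msg, "one support entry per internal node required")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SupportTree from a phylo object
#'
#' Internal node labels, when numeric, are read as bootstrap supports.
#'
#' @param tree an `ape::phylo` tree (e.g. from [ape::read.tree()] on Newick
#'   with supports as internal node labels).
#' @param supports optional numeric vector overriding node-label supports.
#' @return A [SupportTree-class].
#' @examples
#' tr <- ape::read.tree(text = "((q:1,r1:1)85:1,(r2:1,r3:1)90:1,o:1);")
#' supportTree(tr)
#' @export
supportTree <- function(tree, supports = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(supports)) {
    lab <- tree$node.label
    supports <- if (is.null(lab)) rep(NA_real_, tree$Nnode) else
      suppressWarnings(as.numeric(lab))
    if (is.null(lab)) supports <- rep(NA_real_, tree$Nnode)
  }
  new("SupportTree", tree = tree, supports = as.numeric(supports),
      collapsed = tree, collapse_below = 0)
}

#' @describeIn SupportTree the underlying full-data `phylo` tree.
#' @param x a `SupportTree`.
#' @export
treeOf <- function(x) x@tree

#' @describeIn SupportTree per-internal-node supports (NA at the root).
#' @export
supportValues <- function(x) x@supports

#' @describeIn SupportTree the collapsed (polytomous) tree.
#' @export
collapsedTree <- function(x) x@collapsed

setMethod("show", "SupportTree", function(object) {
  cat("SupportTree: ", ape::Ntip(object@tree), " tips, ",
      object@tree$Nnode, " internal nodes\n", sep = "")
  s <- object@supports[!is.na(object@supports)]
  if (length(s)) {
    cat("  supports: ", paste(round(sort(s)), collapse = " "), "\n", sep = "")
  }
  if (object@collapse_below > 0) {
    cat("  collapsed below ", object@collapse_below, "% (",
        object@collapsed$Nnode, " internal nodes retained)\n", sep = "")
  }
})
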