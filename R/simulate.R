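# Synthetic-data generators. Every generator is a pure function of
# (SimConfig, seed): a fixed seed reproduces byte-identical outputs, and all
# planted signals are returned as ground truth so downstream operations have
# closed-loop recovery tests.
#
# Background residues for proteins are drawn from the 15 amino acids that
# cannot instantiate a motif anchor (no C, F, L, V, I): planted blocks are
# then provably the only blocks, which is what the decoy and Class II
# guarantees require. Promoter background is uniform A/C/G/T.

.mutateProtein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA20, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

.buildLobProtein <- function(class, protein_len, grammar = motifGrammar()) {
  nterm <- randomResidues(sample(5:40, 1L), AA_SAFE)
  cblock <- paste0("C", randomResidues(2L, AA_SAFE),
                   "C", randomResidues(6L, AA_SAFE),
                   "C", randomResidues(3L, AA_SAFE), "C")
  gap1 <- randomResidues(sample(5:30, 1L), AA_SAFE)
  gas <- paste0("F", randomResidues(2L, AA_SAFE), sample(c("V", "A"), 1L), "H",
                randomResidues(sample(3:10, 1L), AA_SAFE),
                "DP", sample(c("V", "I"), 1L), "YG")
  gap2 <- randomResidues(sample(5:30, 1L), AA_SAFE)
  off <- .zipperOffsets(4L)
  zchars <- strsplit(randomResidues(off[4] + 1L, AA_SAFE), "", fixed = TRUE)[[1]]
  anchors <- sample(c("L", "V", "I"), 4L, replace = TRUE)
  if (class == "II") {
    # break the zipper: 1-2 anchors replaced by a non-hydrophobic residue
    broken <- sample(4L, sample(1:2, 1L))
    anchors[broken] <- sample(AA_SAFE, length(broken), replace = TRUE)
  }
  zchars[off + 1L] <- anchors
  zipper <- paste(zchars, collapse = "")
  core <- paste0(nterm, cblock, gap1, gas, gap2, zipper)
  target <- sample(protein_len[1]:protein_len[2], 1L)
  tail_len <- max(10L, target - nchar(core))
  paste0(core, randomResidues(tail_len, AA_SAFE))
}

#' Generate a labelled synthetic proteome
#'
#' Class I proteins carry, in order, a C-block, a GAS block and a complete
#' leucine-zipper-like block; Class II proteins carry the C-block and GAS
#' block but a broken zipper (1-2 anchors replaced by a non-hydrophobic
#' residue, at least 2 intact); decoys contain none of the three blocks by
#' construction.
#'
#' @param config a [SimConfig-class]; uses `n_class1`, `n_class2`,
#'   `n_decoys`, `protein_len`, `seed`.
#' @return list with `proteins` (`AAStringSet`, named) and `truth`
#'   (data.frame `id`, `class` in {"I", "II", "none"}).
#' @examples
#' sim <- generateProteome(simConfig(seed = 1, n_class1 = 5, n_class2 = 3,
#'                                   n_decoys = 10))
#' table(sim$truth$class)
#' @export
generateProteome <- function(config) {
  validObject(config)
  total <- config@n_class1 + config@n_class2 + config@n_decoys
  if (total == 0L) stop("zero total proteins requested")
  withSeed(subSeed(config@seed, 1L), {
    seqs <- c(
      vapply(seq_len(config@n_class1), function(i)
        .buildLobProtein("I", config@protein_len), character(1)),
      vapply(seq_len(config@n_class2), function(i)
        .buildLobProtein("II", config@protein_len), character(1)),
      vapply(seq_len(config@n_decoys), function(i)
        randomResidues(sample(config@protein_len[1]:config@protein_len[2], 1L),
                       AA_SAFE), character(1)))
    ids <- c(sprintf("classI_%03d", seq_len(config@n_class1)),
             sprintf("classII_%03d", seq_len(config@n_class2)),
             sprintf("decoy_%03d", seq_len(config@n_decoys)))
    truth <- data.frame(id = ids,
                        class = rep(c("I", "II", "none"),
                                    c(config@n_class1, config@n_class2,
                                      config@n_decoys)),
                        stringsAsFactors = FALSE)
    proteins <- Biostrings::AAStringSet(setNames(seqs, ids))
    list(proteins = proteins, truth = truth)
  })
}

.subclassPool <- list(array = c("f", "d", "g", "i", "c", "a"),
                      background = c("b", "e", "h"))

#' Generate a synthetic gene catalog with planted tandem arrays
#'
#' Places non-overlapping gene loci on `n_chromosomes` chromosomes.
#' Background genes are spaced 150-400 kb apart and drawn from subclasses
#' disjoint from the array subclasses, so planted arrays are exactly the
#' runs recoverable by [detectTandemArrays()] at the planted gap bound.
#' Each planted array is a run of same-subclass genes whose consecutive
#' start-to-start gaps respect `max_gap_bp`.
#'
#' @param config a [SimConfig-class]; uses `n_chromosomes`,
#'   `chromosome_length`, `n_background_genes`, `tandem_array_spec`, `seed`.
#' @return list with `catalog` (locus-table data.frame as from
#'   [parseLocusTable()]), `gff` (`GRanges` with gene/mRNA/exon/CDS
#'   features), and `truth` (list: `arrays` data.frame of locus_id/array,
#'   `structures` data.frame of locus_id/n_exons/n_noncoding_exons).
#' @export
generateGeneModels <- function(config) {
  validObject(config)
  withSeed(subSeed(config@seed, 2L), {
    counters <- new.env(parent = emptyenv())
    nextIndex <- function(class, sub) {
      key <- paste0(class, sub)
      i <- if (is.null(counters[[key]])) 1L else counters[[key]] + 1L
      counters[[key]] <- i
      i
    }
    rows <- list(); feats <- list(); truth_arr <- list(); truth_str <- list()
    locus_counter <- 0L
    arr_specs <- config@tandem_array_spec
    arr_chrom <- vapply(arr_specs, function(a) as.integer(a$chromosome),
                        integer(1))
    arr_sub <- rep(.subclassPool$array,
                   length.out = max(length(arr_specs), 1L))
    bg_per_chrom <- table(factor(
      sample(config@n_chromosomes, config@n_background_genes, replace = TRUE),
      levels = seq_len(config@n_chromosomes)))

    addGene <- function(chrom, start, class, sub, n_exons, noncoding_first) {
      locus_counter <<- locus_counter + 1L
      locus_id <- sprintf("Simvi%02dg%05d", chrom, locus_counter)
      idx <- nextIndex(class, sub)
      short <- paste0("LBD", class, sub, idx)
      exon_lens <- sample(150:400, n_exons, replace = TRUE)
      intron_lens <- if (n_exons > 1L) sample(80:200, n_exons - 1L,
                                              replace = TRUE) else integer(0)
      len <- sum(exon_lens) + sum(intron_lens)
      end <- start + len - 1L
      strand <- sample(c("+", "-"), 1L)
      ex_starts <- start + cumsum(c(0L, head(exon_lens, -1L) +
                                      intron_lens))
      ex_ends <- ex_starts + exon_lens - 1L
      cds_idx <- if (noncoding_first && n_exons > 1L) 2:n_exons else
        seq_len(n_exons)
      gid <- locus_id; mid <- paste0(locus_id, ".1")
      chrlab <- sprintf("chr%02d", chrom)
      feats[[length(feats) + 1L]] <<- data.frame(
        seqnames = chrlab,
        start = c(start, start, ex_starts, ex_starts[cds_idx]),
        end = c(end, end, ex_ends, ex_ends[cds_idx]),
        strand = strand,
        type = c("gene", "mRNA", rep("exon", n_exons),
                 rep("CDS", length(cds_idx))),
        ID = c(gid, mid, paste0(mid, ".exon", seq_len(n_exons)),
               paste0(mid, ".cds", seq_along(cds_idx))),
        Parent = c(NA, gid, rep(mid, n_exons + length(cds_idx))),
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <<- data.frame(
        locus_id = locus_id, short_name = short, legacy_names = "",
        chromosome = sprintf("%02d", chrom), strand = strand,
        start = start, end = end, class = class, subclass = sub, index = idx,
        stringsAsFactors = FALSE)
      truth_str[[length(truth_str) + 1L]] <<- data.frame(
        locus_id = locus_id, n_exons = n_exons,
        n_noncoding_exons = as.integer(noncoding_first && n_exons > 1L),
        stringsAsFactors = FALSE)
      list(locus_id = locus_id, end = end)
    }

    for (chrom in seq_len(config@n_chromosomes)) {
      pos <- sample(10000:50000, 1L)
      # background genes: widely spaced, non-array subclasses
      for (i in seq_len(bg_per_chrom[[chrom]])) {
        class <- sample(c("I", "II"), 1L, prob = c(0.8, 0.2))
        sub <- sample(.subclassPool$background, 1L)
        g <- addGene(chrom, pos, class, sub,
                     n_exons = sample(1:4, 1L, prob = c(.15, .55, .2, .1)),
                     noncoding_first = runif(1) < 0.2)
        pos <- g$end + sample(150000:400000, 1L)
      }
      # planted arrays on this chromosome
      for (ai in which(arr_chrom == chrom)) {
        spec <- arr_specs[[ai]]
        n <- as.integer(spec$n_genes)
        max_gap <- as.numeric(spec$max_gap_bp)
        pos <- pos + 200000L
        members <- character(n)
        for (k in seq_len(n)) {
          g <- addGene(chrom, pos, "I", arr_sub[ai],
                       n_exons = sample(2:3, 1L),
                       noncoding_first = FALSE)
          members[k] <- g$locus_id
          if (k < n) {
            gene_len <- g$end - pos + 1L
            lo <- gene_len + 200L
            if (lo > max_gap) {
              stop("infeasible packing: gene length exceeds max_gap_bp for ",
                   "array on chromosome ", chrom)
            }
            pos <- pos + sample(lo:max_gap, 1L)
          }
        }
        pos <- g$end + 200000L
        truth_arr[[length(truth_arr) + 1L]] <- data.frame(
          locus_id = members, array = paste0("array", ai),
          stringsAsFactors = FALSE)
      }
      if (pos > config@chromosome_length) {
        stop("infeasible packing: chromosome ", chrom,
             " cannot hold the requested genes")
      }
    }
    catalog <- do.call(rbind, rows)
    fdf <- do.call(rbind, feats)
    gff <- GenomicRanges::GRanges(
      seqnames = fdf$seqnames,
      ranges = IRanges::IRanges(fdf$start, fdf$end),
      strand = fdf$strand,
      type = fdf$type, ID = fdf$ID,
      Parent = ifelse(is.na(fdf$Parent), "", fdf$Parent))
    arrays <- if (length(truth_arr)) do.call(rbind, truth_arr) else
      data.frame(locus_id = character(0), array = character(0))
    list(catalog = catalog, gff = gff,
         truth = list(arrays = arrays,
                      structures = do.call(rbind, truth_str)))
  })
}

#' Generate multi-species protein families with a known ortholog map
#'
#' Each ancestral gene is copied into each species with i.i.d. point
#' substitutions at `mutation_rate`. With probability `loss_prob` the
#' species copy is dropped (true no-match). With probability `dup_prob` the
#' clean copy is replaced by a duplicated chimera pair (one third ancestral
#' sequence of the gene, two thirds of another retained gene): the query
#' still finds the chimera, but the chimera's best match is the partner
#' gene, so reciprocity is broken by construction (true homolog-only).
#'
#' @param config a [SimConfig-class]; uses `n_genes`, `n_species`,
#'   `loss_prob`, `dup_prob`, `mutation_rate`, `seed`.
#' @return list with `vitis` (query `AAStringSet`), `species` (named list
#'   of `AAStringSet`), and `truth` (data.frame `gene`, `species`,
#'   `category` in {"one_to_one", "homolog_only", "no_match"}).
#' @export
generateOrthologFamilies <- function(config) {
  validObject(config)
  withSeed(subSeed(config@seed, 3L), {
    len <- 200L
    anc <- vapply(seq_len(config@n_genes), function(i)
      randomResidues(len, AA20), character(1))
    gene_ids <- sprintf("Vvi_g%02d", seq_len(config@n_genes))
    vitis <- Biostrings::AAStringSet(setNames(anc, gene_ids))
    species <- list()
    truth <- list()
    for (s in seq_len(config@n_species)) {
      sp <- sprintf("species%d", s)
      lost <- runif(config@n_genes) < config@loss_prob
      dup <- !lost & runif(config@n_genes) < config@dup_prob
      # chimera partners must be clean (neither lost nor duplicated) genes:
      # the partner's full-length ortholog then outranks the chimera in both
      # directions, so only the duplicated gene's reciprocity breaks. With
      # no clean gene available the duplication degenerates to a clean copy
      # (recorded as such in the truth table).
      pool <- which(!lost & !dup)
      dup[dup & length(pool) == 0L] <- FALSE
      seqs <- character(0)
      for (g in seq_len(config@n_genes)) {
        if (lost[g]) next
        if (dup[g]) {
          partners <- pool
          h <- if (length(partners) == 1L) partners else sample(partners, 1L)
          b <- len %/% 3L
          chim <- paste0(substr(.mutateProtein(anc[g], config@mutation_rate),
                                1L, b),
                         substr(.mutateProtein(anc[h], config@mutation_rate),
                                b + 1L, len))
          seqs[sprintf("%s_g%02d_dupA", sp, g)] <- chim
          seqs[sprintf("%s_g%02d_dupB", sp, g)] <-
            .mutateProtein(chim, config@mutation_rate)
        } else {
          seqs[sprintf("%s_g%02d", sp, g)] <-
            .mutateProtein(anc[g], config@mutation_rate)
        }
      }
      species[[sp]] <- Biostrings::AAStringSet(seqs)
      truth[[sp]] <- data.frame(
        gene = gene_ids, species = sp,
        category = ifelse(lost, "no_match",
                          ifelse(dup, "homolog_only", "one_to_one")),
        stringsAsFactors = FALSE)
    }
    list(vitis = vitis, species = species, truth = do.call(rbind, truth))
  })
}

#' Generate target and background promoter sets with planted motifs
#'
#' Uniform random DNA with the configured motif planted per sequence with
#' probability `motif_freq_target` (targets) or `motif_freq_background`
#' (background), at a uniform random position; plant positions are
#' recorded.
#'
#' @param config a [SimConfig-class]; uses `motif_pattern`,
#'   `motif_freq_target`, `motif_freq_background`, `n_targets`,
#'   `n_background_promoters`, `promoter_len`, `seed`.
#' @return list with `targets`, `background` (`DNAStringSet`) and `plants`
#'   (data.frame `set`, `id`, `position`).
#' @export
generatePromoters <- function(config) {
  validObject(config)
  motif <- config@motif_pattern
  k <- nchar(motif)
  if (k > config@promoter_len) stop("motif longer than promoter")
  withSeed(subSeed(config@seed, 4L), {
    makeSet <- function(n, freq, prefix) {
      seqs <- character(n)
      plants <- list()
      for (i in seq_len(n)) {
        s <- randomDNA(config@promoter_len)
        if (runif(1) < freq) {
          pos <- sample(config@promoter_len - k + 1L, 1L)
          substr(s, pos, pos + k - 1L) <- motif
          plants[[length(plants) + 1L]] <- data.frame(
            set = prefix, id = sprintf("%s%02d", prefix, i), position = pos,
            stringsAsFactors = FALSE)
        }
        seqs[i] <- s
      }
      names(seqs) <- sprintf("%s%02d", prefix, seq_len(n))
      list(set = Biostrings::DNAStringSet(seqs),
           plants = if (length(plants)) do.call(rbind, plants) else
             data.frame(set = character(0), id = character(0),
                        position = integer(0)))
    }
    tg <- makeSet(config@n_targets, config@motif_freq_target, "target")
    bg <- makeSet(config@n_background_promoters,
                  config@motif_freq_background, "bg")
    list(targets = tg$set, background = bg$set,
         plants = rbind(tg$plants, bg$plants))
  })
}

#' Generate an expression atlas with planted modules and tissue-specific genes
#'
#' Co-expressed modules share a latent profile: gene = baseline + z +
#' independent noise with variance (1 - rho) / rho, so the expected
#' pairwise Pearson correlation inside a module equals `module_pcc`.
#' Tissue-specific genes sit near log2 intensity 10 (linear 1024, above the
#' 256 threshold) in their designated tissue and near 4 elsewhere.
#'
#' @param config a [SimConfig-class]; uses `n_modules`, `module_size`,
#'   `module_pcc`, `noise_sd`, `n_tissues`, `n_reps`, `n_tissue_specific`,
#'   `n_noise_genes`, `seed`.
#' @return list with `se` (a `SummarizedExperiment`, assay "log2", colData
#'   tissue/condition/platform) and `truth` (list: `modules` named list of
#'   gene vectors, `tissue` named character gene -> designated tissue).
#' @export
generateExpression <- function(config) {
  validObject(config)
  withSeed(subSeed(config@seed, 5L), {
    tissues <- sprintf("tissue%d", seq_len(config@n_tissues))
    samples <- as.vector(t(outer(tissues, seq_len(config@n_reps),
                                 function(t, r) paste0(t, "_r", r))))
    tissue_of <- rep(tissues, each = config@n_reps)
    ns <- length(samples)
    rows <- list(); modules <- list(); tissue_truth <- character(0)
    rho <- config@module_pcc
    sd_noise_mod <- if (rho > 0) sqrt((1 - rho) / rho) else Inf
    for (m in seq_len(config@n_modules)) {
      z <- rnorm(ns)
      base <- rnorm(1, 7, 0.5)
      gene_ids <- sprintf("mod%d_g%d", m, seq_len(config@module_size))
      for (g in gene_ids) {
        noise <- if (is.finite(sd_noise_mod)) rnorm(ns, 0, sd_noise_mod) else
          rnorm(ns)
        rows[[g]] <- base + if (is.finite(sd_noise_mod)) z + noise else noise
      }
      modules[[paste0("mod", m)]] <- gene_ids
    }
    for (tsi in seq_len(config@n_tissue_specific)) {
      g <- sprintf("ts%d", tsi)
      tis <- tissues[(tsi - 1L) %% config@n_tissues + 1L]
      v <- rnorm(ns, 4, 0.3)
      v[tissue_of == tis] <- rnorm(sum(tissue_of == tis), 10, 0.3)
      rows[[g]] <- v
      tissue_truth[g] <- tis
    }
    for (ni in seq_len(config@n_noise_genes)) {
      rows[[sprintf("noise%d", ni)]] <- rnorm(ns, 6, config@noise_sd)
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- samples
    meta <- data.frame(tissue = tissue_of, condition = tissue_of,
                       platform = "synthetic", row.names = samples,
                       stringsAsFactors = FALSE)
    se <- expressionMatrix(mat, meta)
    list(se = se, truth = list(modules = modules, tissue = tissue_truth))
  })
}
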