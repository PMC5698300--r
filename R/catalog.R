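# Gene catalog: locus table parsing, nomenclature grammar, census
# statistics, chromosome distribution, and tandem-duplication arrays.

#' Parse a family nomenclature gene symbol
#'
#' Gene symbols encode family, class (roman numeral), subclass (one letter)
#' and a distinctive index, e.g. "LBDIIa3" is family LBD, class II,
#' subclass a, index 3.
#'
#' @param short_name character vector of gene symbols.
#' @return data.frame with columns `family`, `class` ("I"/"II"), `subclass`
#'   (single lowercase letter) and `index` (integer). Errors on any
#'   non-conforming symbol, naming it.
#' @examples
#' parseFamilyName(c("LBDIIa3", "LBDIg1"))
#' @export
parseFamilyName <- function(short_name) {
  pat <- "^(LBD)(I{1,2})([a-z])([0-9]+)$"
  ok <- grepl(pat, short_name)
  if (any(!ok)) {
    stop("unparseable gene symbol(s): ",
         paste(short_name[!ok], collapse = ", "))
  }
  data.frame(
    family = sub(pat, "\\1", short_name),
    class = sub(pat, "\\2", short_name),
    subclass = sub(pat, "\\3", short_name),
    index = as.integer(sub(pat, "\\4", short_name)),
    stringsAsFactors = FALSE)
}

#' Format a family name back into a gene symbol
#'
#' Inverse of [parseFamilyName()]; `formatFamilyName(parseFamilyName(x))`
#' returns `x`.
#'
#' @param x data.frame with columns `family`, `class`, `subclass`, `index`.
#' @return character vector of gene symbols.
#' @export
formatFamilyName <- function(x) {
  paste0(x$family, x$class, x$subclass, x$index)
}

.chromFromLocusId <- function(locus_id) {
  pat <- "^[A-Za-z]+([0-9]{2})g[0-9]+$"
  ok <- grepl(pat, locus_id)
  if (any(!ok)) {
    stop("locus id(s) without a two-digit chromosome field: ",
         paste(locus_id[!ok], collapse = ", "))
  }
  sub(pat, "\\1", locus_id)
}

#' Parse a tab-delimited gene locus table
#'
#' Reads a catalog in the bundled Table-1 fixture schema: columns
#' `locus_id`, `short_name`, `legacy_names` (comma-separated, possibly
#' empty), `strand`, `start`, `end`. The chromosome is the two-digit field
#' of the locus id ("00" marks unplaced scaffolds); class/subclass/index
#' are parsed from the gene symbol.
#'
#' @param path path to the TSV file.
#' @return data.frame with one row per locus: `locus_id`, `short_name`,
#'   `legacy_names`, `chromosome` (two-digit label), `strand`, `start`,
#'   `end`, `class`, `subclass`, `index`. Input order is preserved.
#' @examples
#' tab <- parseLocusTable(system.file("extdata", "table1_vvilbd.tsv",
#'                                    package = "lbdfam"))
#' nrow(tab)  # 50
#' @export
parseLocusTable <- function(path) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("locus_id", "short_name", "legacy_names", "strand", "start", "end")
  if (!all(need %in% names(raw))) {
    stop("locus table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(data.frame(locus_id = character(0), short_name = character(0),
                      legacy_names = character(0), chromosome = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), class = character(0),
                      subclass = character(0), index = integer(0),
                      stringsAsFactors = FALSE))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("non-numeric coordinates in row(s): ", paste(bad, collapse = ", "),
         " (", paste(raw$locus_id[bad], collapse = ", "), ")")
  }
  bad <- which(start > end)
  if (length(bad)) {
    stop("start > end in row(s): ", paste(bad, collapse = ", "),
         " (", paste(raw$locus_id[bad], collapse = ", "), ")")
  }
  strand <- gsub("−", "-", raw$strand)  # tolerate typographic minus
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be + or - in every row")
  }
  fam <- tryCatch(parseFamilyName(raw$short_name), error = function(e) {
    stop("row with unparseable short_name: ", conditionMessage(e))
  })
  data.frame(locus_id = raw$locus_id,
             short_name = raw$short_name,
             legacy_names = raw$legacy_names,
             chromosome = .chromFromLocusId(raw$locus_id),
             strand = strand,
             start = start, end = end,
             class = fam$class, subclass = fam$subclass, index = fam$index,
             stringsAsFactors = FALSE)
}

#' Write a gene catalog back to the locus-table schema
#'
#' Writes the six schema columns; a write/read round-trip through
#' [parseLocusTable()] is lossless.
#'
#' @param catalog a catalog data.frame from [parseLocusTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLocusTable <- function(catalog, path) {
  out <- catalog[, c("locus_id", "short_name", "legacy_names",
                     "strand", "start", "end")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locus length under the end - start convention
#'
#' Returns `end - start` (not `end - start + 1`). This follows the
#' reference catalog's own convention: locus Vitvi13g00109 (LBDId4),
#' spanning 1022072-1022675, has a published length of 603 nucleotides,
#' which is `end - start`. This deviates from the usual 1-based inclusive
#' length; use `end - start + 1` externally if you need the inclusive span.
#'
#' @param locus a catalog data.frame (any number of rows) with `start`,
#'   `end` columns.
#' @return integer vector of lengths, named by `short_name` when present.
#' @examples
#' locusLength(data.frame(start = 1022072, end = 1022675))  # 603
#' @export
locusLength <- function(locus) {
  len <- locus$end - locus$start
  if (!is.null(locus$short_name)) names(len) <- locus$short_name
  len
}

#' Class and subclass census of a catalog
#'
#' @param catalog a catalog data.frame from [parseLocusTable()].
#' @return list with `total`, `by_class` (named counts), `by_subclass`
#'   (data.frame class/subclass/n) and `subclasses_per_class` (distinct
#'   subclass letters per class). Sums are conserved: subclass counts add
#'   up to class counts, class counts to the catalog size.
#' @examples
#' tab <- parseLocusTable(system.file("extdata", "table1_vvilbd.tsv",
#'                                    package = "lbdfam"))
#' familySummary(tab)$by_class  # I: 43, II: 7
#' @export
familySummary <- function(catalog) {
  if (nrow(catalog) == 0L) {
    return(list(total = 0L,
                by_class = setNames(integer(0), character(0)),
                by_subclass = data.frame(class = character(0),
                                         subclass = character(0),
                                         n = integer(0)),
                subclasses_per_class = setNames(integer(0), character(0))))
  }
  by_class <- table(catalog$class)
  by_sub <- as.data.frame(table(class = catalog$class,
                                subclass = catalog$subclass),
                          stringsAsFactors = FALSE)
  names(by_sub)[3] <- "n"
  by_sub <- by_sub[by_sub$n > 0L, ]
  by_sub <- by_sub[order(by_sub$class, by_sub$subclass), ]
  rownames(by_sub) <- NULL
  list(total = nrow(catalog),
       by_class = setNames(as.integer(by_class), names(by_class)),
       by_subclass = by_sub,
       subclasses_per_class = vapply(split(by_sub$subclass, by_sub$class),
                                     function(s) length(unique(s)),
                                     integer(1)))
}

#' Per-chromosome gene counts
#'
#' Counts catalog entries per chromosome; the "00" unplaced-scaffold label
#' is reported as "Unknown". Chromosome labels are stripped of leading
#' zeros ("08" -> "8").
#'
#' @param catalog a catalog data.frame.
#' @return named integer vector of counts; empty for an empty catalog.
#' @export
chromosomeDistribution <- function(catalog) {
  if (nrow(catalog) == 0L) return(setNames(integer(0), character(0)))
  lab <- ifelse(catalog$chromosome == "00", "Unknown",
                sub("^0", "", catalog$chromosome))
  tab <- table(lab)
  setNames(as.integer(tab), names(tab))
}

#' Detect tandem-duplication arrays
#'
#' A tandem array is a maximal run of same-subclass genes on one chromosome
#' in which consecutive start-to-start gaps do not exceed `max_gap`. The
#' reference catalog never defines "tandem" numerically; the defaults
#' (100 kb gap, minimum 2 members) enclose the dense subclass-If cluster on
#' chromosome 13 while excluding cross-arm pairs.
#'
#' @param catalog a catalog data.frame.
#' @param max_gap maximum start-to-start distance between consecutive
#'   members, bp (> 0).
#' @param min_size minimum members per reported array (>= 2).
#' @return data.frame with one row per array: `chromosome`, `class`,
#'   `subclass`, `n`, `span` (bp, first start to last end), and `members`
#'   (comma-separated short names ordered by start). Arrays are ordered by
#'   (chromosome, start). Reported arrays are maximal: they cannot be
#'   extended by an adjacent same-subclass gene within `max_gap`.
#' @examples
#' tab <- parseLocusTable(system.file("extdata", "table1_vvilbd.tsv",
#'                                    package = "lbdfam"))
#' detectTandemArrays(tab, max_gap = 100000, min_size = 3)
#' @export
detectTandemArrays <- function(catalog, max_gap = 100000, min_size = 2L) {
  stopifnot(max_gap > 0, min_size >= 2L)
  out <- list()
  if (nrow(catalog)) {
    grp <- interaction(catalog$chromosome, catalog$class, catalog$subclass,
                       drop = TRUE)
    for (g in split(catalog, grp)) {
      g <- g[order(g$start), ]
      if (nrow(g) < min_size) next
      gap_ok <- diff(g$start) <= max_gap
      run_id <- cumsum(c(0L, !gap_ok))
      for (run in split(g, run_id)) {
        if (nrow(run) < min_size) next
        out[[length(out) + 1L]] <- data.frame(
          chromosome = run$chromosome[1],
          class = run$class[1],
          subclass = run$subclass[1],
          n = nrow(run),
          start = run$start[1],
          span = run$end[nrow(run)] - run$start[1],
          members = paste(run$short_name, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(0), class = character(0),
                      subclass = character(0), n = integer(0),
                      start = integer(0), span = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start), ]
  rownames(res) <- NULL
  res
}

#' Exon/intron structure summary from a GFF3 file
#'
#' Counts exons of the primary (first) mRNA of every gene and classifies
#' exons without CDS overlap as non-coding. "Nonsense" exons are taken from
#' an input annotation flag (`nonsense_exon=true` exon attribute) rather
#' than computed, since no computable rule defines them.
#'
#' @param gff path to a GFF3 file, or a `GRanges` as returned by
#'   [rtracklayer::import()], with gene/mRNA/exon/CDS features linked by
#'   ID/Parent.
#' @return list with `structures` (data.frame: `locus_id`, `n_exons`,
#'   `n_noncoding_exons`, `n_nonsense_exons`) and `histogram` (table of
#'   exon counts across genes). Genes without an mRNA are skipped with a
#'   warning.
#' @export
exonStructureSummary <- function(gff) {
  gr <- if (methods::is(gff, "GRanges")) gff else rtracklayer::import(gff)
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  genes <- which(type == "gene")
  rows <- list()
  for (gi in genes) {
    gid <- ids[gi]
    mrnas <- which(type == "mRNA" & parents == gid)
    if (length(mrnas) == 0L) {
      warning("gene without mRNA skipped: ", gid)
      next
    }
    mid <- ids[mrnas[1]]
    ex <- which(type == "exon" & parents == mid)
    cds <- which(type == "CDS" & parents == mid)
    if (length(ex) == 0L) {
      warning("mRNA without exons skipped: ", mid)
      next
    }
    exr <- gr[ex]
    noncoding <- if (length(cds)) {
      ov <- GenomicRanges::countOverlaps(exr, gr[cds])
      sum(ov == 0L)
    } else length(ex)
    nonsense <- 0L
    if (!is.null(gr$nonsense_exon)) {
      flag <- tolower(as.character(gr$nonsense_exon[ex]))
      nonsense <- sum(!is.na(flag) & flag == "true")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = gid, n_exons = length(ex),
      n_noncoding_exons = noncoding, n_nonsense_exons = nonsense,
      stringsAsFactors = FALSE)
  }
  structures <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locus_id = character(0), n_exons = integer(0),
               n_noncoding_exons = integer(0), n_nonsense_exons = integer(0))
  list(structures = structures, histogram = table(structures$n_exons))
}
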