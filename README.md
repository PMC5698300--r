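# lbdfam

Genome-wide characterization of the LATERAL ORGAN BOUNDARIES Domain (LBD)
transcription-factor gene family, built around the grapevine
(*Vitis vinifera*) family of 50 `VviLBD` genes and reusable for any plant
genome with a comparable catalog.

LBD proteins are plant-specific transcription factors defined by an
N-terminal LOB domain made of three blocks:

* a **C-block** (zinc-finger-like domain) with invariant cysteine spacing
  `CX2CX6CX3C`, required for DNA binding;
* a **GAS block** with conserved anchors `FX2(V/A)H ... DP(V/I)YG`
  (the P and G are invariant);
* a **leucine-zipper-like motif** `LX6LX3LX6L`, whose hydrophobic anchor
  positions accept L, V or I.

Class I proteins carry a complete zipper; Class II proteins carry the
C-block but an incomplete, presumably non-functional zipper. The package
implements this motif grammar as a deterministic scanner, plus every
desk-scale analysis of a family characterization:

| Analysis | Functions |
|---|---|
| Catalog statistics, nomenclature, tandem arrays | `parseLocusTable`, `familySummary`, `chromosomeDistribution`, `detectTandemArrays`, `exonStructureSummary` |
| Domain scanning and Class I/II calls | `scanCBlock`, `scanGasBlock`, `scanZipper`, `classifyProtein`, `findConservedBlocks` |
| NJ phylogeny, bootstrap, subclass assignment | `filterColumns`, `proteinDistance`, `njTree`, `bootstrapTree`, `assignSubclasses` |
| RBH orthology and NG86 Ka/Ks | `allVsAllHits`, `retainHits`, `reciprocalBestHits`, `orthologPresenceMatrix`, `kaksNG86` |
| Promoter cis-element enrichment | `extractPromoters`, `scanMotif`, `motifEnrichment`, `kmerDiscovery` |
| Expression atlas and co-expression | `expressionMatrix`, `assignTissueOntology`, `coexpressionClusters`, `neighborsOf`, `conditionContrast` |
| Synthetic data with ground truth | `simConfig`, `generateProteome`, `generateGeneModels`, `generateOrthologFamilies`, `generatePromoters`, `generateExpression` |
| Orchestration | `runPipeline` |

The key statistical rules, as used throughout:

* orthologs are **reciprocal best hits** after retaining alignments with
  e-value < 1e-20 and identity > 40% (strict inequalities);
* Ka/Ks follows **Nei–Gojobori (1986)** with pathway averaging and the
  Jukes–Cantor correction d = −3/4 ln(1 − 4p/3);
* subclasses are assigned from clades with **bootstrap support ≥ 70**
  (100 replicates; branches < 30% collapsed; columns with < 95% site
  coverage removed beforehand);
* promoter motifs are tested by a one-sided **hypergeometric** test on
  presence/absence per promoter, called enriched at P < 0.01;
* tissue labels require mean log2 intensity ≥ 8 (linear 256); co-expressed
  genes are clustered by average linkage at Pearson distance
  1 − PCC < 0.2.

A transcription of the published 50-gene grapevine locus table ships as
`inst/extdata/table1_vvilbd.tsv` and anchors the catalog tests.

## Worked example

```r
library(lbdfam)

tab <- parseLocusTable(system.file("extdata", "table1_vvilbd.tsv",
                                   package = "lbdfam"))
familySummary(tab)$by_class
#>  I II
#> 43  7
chromosomeDistribution(tab)["13"]
#> 13
#> 15
detectTandemArrays(tab, max_gap = 100000, min_size = 3)[, c("chromosome", "subclass", "n", "span")]
#>   chromosome subclass  n   span
#> 1         07        c  3  22731
#> 2         13        f 11 225016
```

The family splits into 43 Class I and 7 Class II genes; chromosome 13
carries 15 of the 50 loci, driven by an 11-gene tandem array of
subclass-If genes spanning 225 kb (plus a 3-gene Ic array on
chromosome 7). The motif scanner closes the loop on simulated proteins
with known classes:

```r
sim <- generateProteome(simConfig(seed = 1, n_class1 = 3, n_class2 = 2,
                                  n_decoys = 3))
annotateProteome(sim$proteins)[, c("id", "c_block_start", "zipper_complete", "class")]
#>            id c_block_start zipper_complete class
#> 1  classI_001            28            TRUE     I
#> 2  classI_002            35            TRUE     I
#> 3  classI_003            21            TRUE     I
#> 4 classII_001             7           FALSE    II
#> 5 classII_002             6           FALSE    II
#> 6   decoy_001            NA           FALSE  none
#> 7   decoy_002            NA           FALSE  none
#> 8   decoy_003            NA           FALSE  none
```

Class I proteins are called from a located C-block plus a complete
downstream zipper; Class II from a C-block with a broken zipper; decoys
carry no C-block and are called `none`.

See the methods vignette (`vignettes/lbd-family-methods.Rmd`) for the
models, parameter defaults and design decisions.

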