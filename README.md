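# fpseg — forest-prairie chromatin domain segregation analysis

Mammalian genomes split, by CpG-island (CGI) density alone, into alternating
megabase-scale **forest** (F, CGI-rich) and **prairie** (P, CGI-poor)
domains. Because the partition is purely sequence-based it is fixed across
cell types, so the degree to which F and P domains segregate in 3D —
measured from Hi-C contact maps — is a clean, comparable readout of chromatin
organization across developmental stages, tissues, and conditions.

`fpseg` is an R package for researchers analyzing Hi-C, whole-genome
bisulfite, and RNA-seq data through this lens. It computes:

- **ORs** — overall segregation ratio, per domain type:
  `ORs(F) = Σ_{i,j∈F, i≠j} D_ij / Σ_{i∈F, j∈P} D_ij`, where
  `D_ij` is the contact sum between domains i and j divided by the product of
  their lengths (ICE-normalized input);
- **DRs** — the same ratio per individual domain, plus **Ror**
  (`ln(n_ij/n_ji)`, which of two samples is more segregated) and
  replicate-calibrated calls of significantly more segregated (`seg`) or
  mixed (`mix`) domains between stages;
- **Rs(d)** and **TC10(d)** — distance-resolved segregation and the F-F/F-P/
  P-P composition of the top 10% of contacts per distance, with the
  **critical genomic distance** (largest distance with a nonzero
  composition);
- **A/B compartments** — correlation-matrix PC1 with CpG sign orientation,
  the **C-index** `ln[(Σ C_ij δ_j/N_A)/(Σ C_ij(1−δ_j)/N_B)]`, strict
  compartments, Af/Bf/Ap/Bp composition, prairie compartment dynamics
  (stable Ap / stable Bp / switchable p), and A↔B transition composition;
- **MDI** — the open-sea methylation difference index
  `(q_i − (q_{i−1}+q_{i+1})/2) / ((q_{i−1}+q_i+q_{i+1})/3)` per domain, with
  per-sample |MDI| summaries, group tests and aging slopes;
- **lineage-specific genes** — Shannon-entropy selection (H < 1.7 bits,
  FPKM ≥ 1, relative expression > 1/7, above the reference stage) and
  expression-change grouping of prairie genes against host-domain mixing;
- a **synthetic-data generator** planting known domain structure, same-type
  contact affinity, methylation offsets and sample-specific genes, so every
  statistic is testable against ground truth.

Standard formats are used throughout: BED for domains/CGIs/LADs, sparse or
dense text for contact matrices, TSV/bedGraph for methylation and signal
tracks, gene × sample FPKM tables.

## Worked example

```r
library(fpseg)

spec <- synthetic_spec(affinity = 1)        # ~8 Mb genome, 20 F/P domains
g    <- generate_genome(spec, seed = 1)
m    <- ice_normalize(generate_hic(g$domains, spec, seed = 2))
dct  <- aggregate_domain_contacts(m, g$domains)

compute_ors(dct, "F")
#> [1] 1.086565
compute_ors(dct, "P")
#> [1] 1.111829

drs <- compute_drs(dct)
head(drs, 3)
#>      key chrom id label       drs
#> 1 chrS:1  chrS  1     F 1.2079838
#> 2 chrS:2  chrS  2     P 0.9059867
#> 3 chrS:3  chrS  3     F 1.1350562

track <- call_compartments(distance_normalize(m), g$bins$cpg_density)
mean((track$delta == 1) == (g$bins$label == "F"))
#> [1] 1
```

With the planted same-type affinity s = 1, forests and prairies each contact
their own type about 9–11% more than the other type once domain sizes and
genomic distance are accounted for (`ORs > 1`), individual domains show the
same preference (`DRs`, median 1.14 here), and compartment calls recover the
planted types on every bin. Raising `affinity` raises every one of these
numbers; at `affinity = 0` they drop below 1 because cross-type neighbors are
closer on the genome than same-type ones.

See `vignettes/forest-prairie-segregation.Rmd` for the statistical details
and design choices.

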