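---
title: "Quantifying forest-prairie chromatin domain segregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying forest-prairie chromatin domain segregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpseg)
```

## The model

Mammalian genomes carry a strongly uneven distribution of CpG islands (CGIs).
Merging runs of closely spaced CGIs splits each chromosome into alternating
megabase-scale **forest** (F, CGI-rich) and **prairie** (P, CGI-poor) domains.
Because the partition depends only on sequence, it is invariant across cell
types of a species, which makes it a convenient fixed frame for comparing
chromatin organization between developmental stages and tissues: in Hi-C
maps, domains of the same type contact each other more than chance would
predict, and the strength of that preference changes with differentiation
state.

`fpseg` quantifies this domain segregation and its epigenetic correlates.
All statistics operate on ICE-balanced intra-chromosomal contact matrices
(distance-normalized where stated) and on the domain-level contact table

$$D_{ij} = \frac{\sum_{a \in i, b \in j} C_{ab}}{n_i\, n_j},$$

the contact sum between domains $i$ and $j$ divided by the product of their
lengths. Lengths are counted in bins rather than base pairs, so $D_{ij}$ is
the mean contact per bin pair; the two conventions differ only by a global
constant, which cancels from every ratio below.

* **ORs** (overall segregation ratio), per type:
  $\mathrm{ORs}(F) = \sum_{i,j \in F, i \ne j} D_{ij} \big/ \sum_{i \in F, j \in P} D_{ij}$.
  The numerator ranges over ordered pairs (each unordered F-F pair counted
  twice) and the denominator over $F \times P$ (each cross pair once),
  following the defining index ranges literally. The factor of two is a fixed
  convention; comparisons of ORs across samples are unaffected.
* **DRs** (per-domain segregation ratio):
  $\mathrm{DRs}(i \in F) = \sum_{j \in F, j \ne i} D_{ij} \big/ \sum_{j \in P} D_{ij}$,
  undefined when a domain has no cross-type contact, zero when it has
  cross-type but no same-type contact.
* **Rs(d)**: the same ratio restricted to bin pairs exactly $d$ bins apart,
  revealing the length scale at which segregation acts.
* **TC10(d)**: the top 10% of contact entries at distance $d$ decomposed into
  F-F / F-P / P-P proportions. If any selected entry is zero the whole triple
  is set to (0, 0, 0); the largest distance with a nonzero triple is the
  **critical genomic distance**, a measure of how far reliable long-range
  contacts reach. Ties at the 10% cutoff are broken by ascending bin index so
  the output is deterministic.
* **Ror**: for two samples, $\ln(n_{ij}/n_{ji})$ where $n_{ij}$ counts shared
  domains with the higher DRs in sample $i$ (ties excluded). Positive means
  sample $i$ is the more segregated.
* **Seg/mix calls**: between two stages, domains whose DRs log-ratio
  $\ln(\mathrm{DRs}_{late}/\mathrm{DRs}_{early})$ exceeds a threshold $T$ are
  called significantly more segregated (`seg`), below $-T$ more mixed
  (`mix`). $T$ is calibrated from two replicates of a single stage as the
  larger magnitude of the 2.5% and 97.5% empirical quantiles (linear
  interpolation) of the replicate DRs log-ratios, so calls are anchored to
  measured technical variability rather than to a distributional assumption.
* **Compartments**: PC1 of the Pearson correlation matrix of the
  distance-normalized map, sign-oriented so PC1 increases with CpG density
  (the covariance form of "CpG-rich bins are compartment A"; the covariance
  is robust when one type holds the median, where an above-median rule
  degenerates). The **C-index** of bin $i$ is
  $\ln[(\sum_j C_{ij}\delta_j / N_A) / (\sum_j C_{ij}(1-\delta_j) / N_B)]$ on
  the 200-kb grid — the log-ratio of mean contact with A versus B bins.
  A bins with positive C-index are strict A, B bins with negative C-index
  strict B; crossing with F/P labels gives the sAf/sAp/sBf/sBp genome
  lengths and the Af/Bf/Ap/Bp composition.
* **MDI** (methylation difference index): with $q_i$ the mean open-sea
  methylation of domain $i$ (open sea = genome minus CGIs extended by 2 kb
  shores plus 2 kb shelves, the field's standard distances),
  $\mathrm{MDI}_i = (q_i - (q_{i-1}+q_{i+1})/2) \big/ ((q_{i-1}+q_i+q_{i+1})/3)$.
  Positive for domains more methylated than both flanks. Being a ratio it is
  invariant to global scaling of $q$.
* **Lineage-specific genes**: Shannon entropy of a gene's relative expression
  across samples, $H = -\sum_t p_t \log_2 p_t$; a gene is stage-specific when
  $H < 1.7$ bits, its FPKM in the target stage is at least 1, its relative
  expression exceeds 1/7 (strict), and it exceeds the reference stage
  (strict), matching the stated selection rules.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `gap_threshold_bp` | 50 kb | max inter-CGI gap inside a forest |
| `min_domain_bp` | 1 Mb | domains below this are absorbed into the longer neighbor |
| ICE `tol`, `max_iter` | 1e-5, 200 | row-sum convergence of matrix balancing |
| `top_frac` | 0.1 | diagonal fraction entering TC10 |
| calibration `tail` | 0.025 | per-side quantile of replicate log-ratios |
| `shore_bp`, `shelf_bp` | 2 kb each | open-sea exclusion around CGIs |
| `min_cov`, `min_cpg` | 3, 10 | CpG coverage filter and per-domain support for $q$ |
| `h_max`, `fpkm_min`, `rel_min` | 1.7, 1, 1/7 | lineage-specific gene filters |
| LAD `min_overlap` | 0.5 | covered-length fraction for calling a domain LAD |

The F/P calling constants are heuristics: the canonical partition comes from
dedicated prior analyses, and `read_domains_bed()` accepts such precomputed
domains as the authoritative input. `partition_forest_prairie()` exists so
the pipeline is self-contained on any genome with a CGI track; it is not
claimed to reproduce published mm9/hg19 domain coordinates.

## Design choices in ambiguous corners

* **Bins, not base pairs, in the $D_{ij}$ denominator** — $D$ becomes a mean
  of contact-matrix entries, and the choice cancels from all ratios.
* **Cis only, pooled across chromosomes.** All statistics are
  distance-oriented; tables from several chromosomes are row-bound and sums
  pool before ratios ("overall" semantics). ICE runs per chromosome.
* **Bin labelling**: a bin takes the label of the domain covering at least
  half of it; an exact 50/50 tie goes to the domain containing the bin start.
  Unassigned bins are excluded everywhere downstream.
* **Masking**: bins with zero raw marginal are masked before ICE (standard
  practice) and stay masked downstream.
* **Domain-level compartment per stage** = majority of member-bin A/B calls,
  ties to B — conservative toward the repressive default; the underlying
  per-bin calls are returned so other rules can be applied.
* **Undefined DRs** (no cross-type contact) domains are excluded from Ror
  counts, threshold calibration, and seg/mix fractions.
* **Degenerate inputs** fail loudly: all-equal density tracks (no median
  split), uniform matrices (no leading correlation structure), all-zero
  matrices, missing cross-type contact.
* **Sidedness**: Welch's, two-sample t and Fisher's exact tests are two-sided
  throughout; per-sample MDI is summarized as the mean |MDI| per domain label
  (signed means are also returned).

## What the synthetic generator emulates

`synthetic_spec()` + the `generate_*()` functions plant known structure:

* alternating F/P domains (lengths uniform over a bin range; defaults give
  ~200 bins at 40 kb, i.e. an 8-Mb chromosome, sized so a full analysis runs
  in seconds);
* CGIs every 20 kb in forests, every 500 kb in prairies; SINE density
  correlated with forest membership with tunable $\rho$;
* Hi-C counts that are negative binomial (dispersion 0.1 — Hi-C counts are
  overdispersed relative to Poisson) around
  $\mu_{ij} \propto (|i-j|+1)^{-\alpha}\,(1 + s\,[\text{same type}])$, a
  power-law decay with a multiplicative same-type affinity $s$: a monotone,
  scale-free control of segregation with no claim of biophysical realism;
* stage series with per-stage $s$ and per-domain effective-type flips (a
  prairie behaving as forest models a compartment-switching prairie);
* open-sea methylation Beta-distributed around $m_F = 0.75$ / $m_P = 0.55$
  (a typical somatic forest-prairie contrast), coverage Poisson(30);
* expression tables with 8 samples and 10% planted sample-specific genes,
  enriched `effect_multiplier`-fold in their target sample and depleted by
  the same factor elsewhere — tissue-restricted genes are low, not average,
  outside their tissue, and this is what makes specificity recoverable at
  moderate enrichment.

What it does **not** emulate: TADs and loops, trans contacts, coverage biases
that ICE corrects in real data, bisulfite non-conversion, mapping artifacts,
replicate batch structure. Passing the recovery tests therefore shows the
statistics measure what they claim on data with the assumed structure — not
that real embryo data meet those assumptions.

## A worked run

```{r example, eval = FALSE}
spec <- synthetic_spec(affinity = 1)
g <- generate_genome(spec, seed = 1)
m <- ice_normalize(generate_hic(g$domains, spec, seed = 2))
dct <- aggregate_domain_contacts(m, g$domains)
compute_ors(dct, "F")
drs <- compute_drs(dct)
track <- call_compartments(distance_normalize(m), g$bins$cpg_density)
```

The test suite (`tests/testthat/`) validates every statistic against naive
double-loop reference implementations to 1e-10, checks monotonicity of
ORs/DRs/C-index in the planted affinity, the replicate-calibrated threshold
against its Monte-Carlo sampling band, perfect compartment recovery on
two-block matrices, MDI sign and monotonicity under planted methylation
offsets, and entropy-based gene recovery. `scripts/acceptance.R` re-runs the
pipeline end to end and writes the resulting numbers as JSON.

## Limitations

* The inter-CGI-gap partition is a parameterized heuristic, not the published
  domain caller; use precomputed domain BEDs for cross-study comparability.
* Only intra-chromosomal analysis is supported; statistics sensitive to trans
  contacts are out of scope.
* The critical genomic distance takes the largest nonzero-composition offset;
  when zero and nonzero compositions interleave, the result carries a flag
  and deserves inspection.
* Group comparisons (germ layer, aging) are plain t-tests and least-squares
  slopes on per-sample summaries; no hierarchical modeling of domains within
  samples.
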