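---
title: "Denoising single-cell TCR-pMHC screens with itrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising single-cell TCR-pMHC screens with itrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell immune profiling screens capture T cells in droplets (GEMs,
gel beads-in-emulsion) together with a panel of DNA-barcoded peptide-MHC
multimers (dextramers). Each GEM yields TCR chain annotations and a vector
of pMHC capture counts in UMIs (unique molecular identifiers). In an ideal
GEM the cognate pMHC dominates the capture counts; in practice the raw data
is contaminated by ambient multimers sticking to droplets, incomplete chain
annotation (dropout), spurious extra chains (multiplets), and droplets that
are not cells at all. Left unfiltered, this noise produces TCR-pMHC pairs
that are simply wrong.

`itrap` implements a denoising cascade that exploits the one biological
constraint the platform gives us for free: **all GEMs of the same clonotype
came from clonal expansion of a single T cell, so they must share one true
specificity.** Any disagreement within a clonotype is evidence of noise,
and the clonotype's pooled UMI distributions let us decide which GEMs to
believe.

## Data model

The canonical object is a tibble with one row per GEM:

* `barcode_full` — `"<16nt core>-<well>-<donor>"`, globally unique across
  parallel donor runs,
* `is_cell` — the platform's cell call,
* `chains` — list-column of chain annotations (`chain_type`, `v_gene`,
  `j_gene`, `cdr3_aa`, `umi`, `productive`, `full_length`),
* `captures` — list-column of pMHC captures (`feature_id`, `peptide`,
  `hla_allele`, `umi`, `is_negative_control`).

After clonotyping the chains flatten to `v_a, j_a, cdr3_a, umi_a` /
`v_b, j_b, cdr3_b, umi_b` plus a `ct_id`, and filters add `assigned_pmhc`.
Every stage is a plain tibble; `write_gem_table()` /`read_gem_table()` give
an exact CSV round trip (list-columns as JSON).

## The method, stage by stage

### 1. Curation and amino-acid clonotypes

`curate_gems()` drops chains that are not productive, not full length, or
contain non-amino-acid CDR3 characters; a GEM is removed only when no chain
survives. `clonotype_gems()` then

1. resolves chain multiplets per GEM by keeping the highest-UMI alpha and
   beta (ties broken lexicographically so the result is order-invariant),
2. redefines clonotypes on the amino-acid six-tuple
   `(v_a, j_a, cdr3_a, v_b, j_b, cdr3_b)` — nucleotide-level clonotype
   calls fracture identical proteins into artificial singletons, which
   amino-acid identity repairs,
3. imputes a missing chain when the observed half-key
   `(v, j, cdr3)` of the present chain occurs in exactly one clonotype;
   imputed chains carry UMI 0 and an `imputed_*` flag.

### 2. Expected binders and threshold search

`annotate_expected_binders()` decides, per clonotype of at least `min_gems`
(default 10) GEMs, which pMHC is the clonotype's *expected binder*. The
candidate is the feature with the highest mean UMI across the clonotype's
GEMs; it is accepted only if a one-sided rank-sum (Wilcoxon/Mann-Whitney)
test rejects equality against **every** competitor feature at `alpha`
(default 0.05). For small samples (total n of 12 or less) the test
enumerates all label assignments exactly, with midranks for ties; larger
samples use the normal approximation with continuity correction.

UMI vectors are compared on the full clonotype: a feature absent from a GEM
contributes a zero. Without zero filling, a competitor detected in a single
GEM faces an exact permutation floor of `1/(n+1)`, which for clonotypes of
up to 19 GEMs can never fall below 0.05 — so one ambient molecule would
permanently veto the annotation of a clearly mono-specific clonotype.
Zero filling restores the power the clonotype's size should provide.

The annotated clonotypes become an internal golden standard for
`grid_search_thresholds()`: over a grid of threshold sets
(`umi_min_pmhc` 1–20, `ratio_min` 1.0–3.0 by 0.1, `umi_min_tcr` 0–5 by
default), it retains GEMs passing the cutoffs and scores the fraction whose
top capture equals their clonotype's expected binder. The maximizer is
returned; ties prefer more retained GEMs, then lexicographically smaller
thresholds. Boundary comparisons are inclusive, and the top/second ratio is
compared in integer arithmetic (`top*100 >= round(ratio*100)*second`) so a
grid value like 1.2 is exact rather than a floating-point neighbour. A GEM
whose top UMI is tied between two features has no unambiguous target and is
removed regardless of thresholds.

### 3–6. Specificity filters

`apply_itrap_filters()` chains, in order: the threshold filter (sets
`assigned_pmhc`), HLA haplotype matching (the assigned pMHC's restricting
allele must be carried by the GEM's donor, at two-field resolution),
paired-chain presence, removal of specificity singlets (a
`(clonotype, pMHC)` pair supported by one GEM only), and the platform
`is_cell` flag. The preset `"recommended"` applies thresholds + HLA;
`"full"` applies all five.

## Benchmark metrics

`metrics_report()` summarizes any filter state with four quantities:

* **retention** — percent of the curated GEMs that survive;
* **accuracy** — percent of GEMs (of annotated clonotypes) whose top
  capture equals the expected binder; per-GEM top ties count as misses;
* **binding concordance** — for each `(clonotype, assigned pMHC)` pair, the
  fraction of the clonotype's GEMs behind the pair; the dataset average is
  GEM-weighted; per-clonotype concordances sum to one by construction;
* **similarity AUC** — TCRs assigned the same specificity should look
  alike. Each clonotype's CDR3s are compared with a k-mer substitution
  string kernel (`kappa(a,b) = exp(beta * BLOSUM62[a,b])`,
  `beta = 0.11387`, k = 1–3, normalized so self-similarity is 1; alpha and
  beta chain scores add to a paired score in [0, 2]). Every clonotype on a
  specificity "plateau" of at least two contributes its maximal similarity
  to a plateau mate (intra) and to an equally sized random sample from
  other plateaus (inter); the tie-corrected Mann-Whitney AUC between the
  two score lists, scaled to 0–100, measures how much better than chance
  (50) the assignment groups similar receptors.

`classify_outliers()` inspects GEMs whose pair concordance falls below 0.5
and labels them `no_expected_binder`, `cross_reactivity_consistent`
(clonotype dominated by its expected binder, which the GEM detected at a
lower UMI than the assigned one), `dispersed_multiplet`, or `other`, with
an `hla_divergent` flag when assigned and expected pMHC are restricted by
different alleles.

## The simulator

`simulate_gem_dataset()` generates a fully ground-truthed dataset:
clonotype sizes follow a heavy-tailed power law (`P(k) ∝ k^-2`, k = 1–100);
each clonotype has one cognate pMHC whose restricting allele is carried by
its donor; cognate captures are negative-binomial (mean 15) against ambient
features at Poisson rate 3 with NB(mean 2) counts; chains drop out with
probability 0.1 and gain a spurious extra chain with probability 0.1;
5% of GEMs are flagged as non-cells. CDR3s embed a per-specificity motif
between the canonical `C…F` anchors, so the similarity AUC has signal to
detect. The whole dataset is a deterministic function of `sim_config()`,
whose defaults are the study conditions used by the test suite. The
simulator does **not** emulate doublet cells (two T cells in one GEM),
sequencing errors in barcodes, or batch effects between wells.

`evaluate_recovery()` and `evaluate_binder_recovery()` score any filtered
table against the truth (assignment precision/recall, per-corruption-type
confusion, and the fraction of expanded clonotypes annotated to their true
cognate).

## Limitations

* The rank-sum annotation needs clonal expansion; clonotypes below
  `min_gems` GEMs are never annotated and do not contribute to accuracy.
* The threshold search optimizes accuracy on the annotated subset only;
  its optimum is data-dependent and need not transfer between datasets.
* Kernel parameters (`beta`, k-mer lengths) are conventional defaults, not
  fitted quantities; AUC values are comparable within a dataset, not
  across kernels.
* HLA matching operates at two-field resolution and class I nomenclature;
  alleles that cannot be parsed to `LOCUS*NN:NN` are rejected outright.
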