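---
title: "Consensus references and reference bias: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus references and reference bias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusref)
```

## The problem

A conventional haploid reference genome is, allelically, close to a "type
specimen": it behaves like one sampled personal haplotype, not like a
population summary. Concretely, at a large fraction of polymorphic sites it
carries the *minor* allele, so variant calls made against it reflect the
reference's idiosyncrasies as much as the genome under study -- many
"variants" are simply the population's major allele disagreeing with a rare
reference allele, and a large share of homozygous calls have population
allele frequency above 0.5.

A *consensus* reference repairs this by construction: at every bi-allelic
SNV, carry the major allele. This package implements that construction and
the bookkeeping it forces (REF/ALT relabelling, genotype-dosage
re-projection, variant re-calling), together with a synthetic-cohort
generator so every claim is checkable end to end without any external
genotype download.

## The model

**Cohort.** A cohort is `n_sites` bi-allelic SNVs by `n_samples` diploid
genomes, represented as an ALT-dosage matrix (0/1/2, `NA` for missing).
Global ALT frequencies are drawn i.i.d. from a configurable site-frequency
spectrum (SFS): `uniform`, truncated `beta(a, b)`, or `neutral` (density
proportional to 1/p). Frequencies are truncated to `(eps, 1 - eps)` with
`eps = 1/(2 n_samples)` by default, so every simulated site is expected to
be polymorphic in a cohort of that size -- the analysis, like its real-data
counterpart, operates on called polymorphic sites.

**Population structure.** Subpopulation frequencies follow the
Balding-Nichols model: `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`, i.e. mean `p`
and variance `Fst * p * (1-p)`. `Fst = 0` forces `p_k = p` exactly. Within a
subpopulation, genotypes are Hardy-Weinberg: dosage `~ Binomial(2, p_k)`.
This is a modelling choice, not an empirical claim: the downstream analysis
needs only frequency structure and zygosity, so HWE + Balding-Nichols is the
minimal generative model that exercises it.

**The reference as a sampled haplotype.** In `ref_mode = "random-haplotype"`
the reference base at each site is the derived allele with probability `p`.
REF/ALT labels and every frequency in the emitted site list are then
re-expressed relative to that sequence (and genotype dosages flipped to
`2 - d` where the labels swapped), exactly as a VCF against that reference
would present them. This gives the reference the type-specimen property by
construction: its carried-allele spectrum is one more draw from the personal
haplotype distribution. `ref_mode = "all-ancestral"` is the degenerate
control in which the reference always carries the ancestral base.

**Haploid collapse.** A diploid personal genome is collapsed onto the
reference by keeping homozygous alleles and choosing one allele at each
heterozygous site with an independent fair coin. The coin stream is seeded
per sample (a child seed of the root seed), so samples are mutually
independent but each collapse is reproducible. Missing genotypes collapse to
REF -- a documented convention, since no imputation belongs in this
bookkeeping.

**Consensus rule.** The consensus carries ALT exactly where the scope's
ALT frequency is *strictly* above 0.5; at a tie the reference allele is
kept. The strict inequality makes results reproducible at ties and gives two
exact invariants: every allele the consensus carries has frequency >= 0.5,
and every variant called against it has called-allele frequency <= 0.5.

**Re-projection and calling.** Against any switched reference, dosage `d`
at a swapped site becomes `2 - d` (an involution; missing stays missing).
After re-projection, dosage 2 is a homozygous variant call, dosage 1
heterozygous, 0 or missing no call. The frequency recorded per call is that
of the carried non-reference allele -- the complement of the decision
frequency at swapped sites.

## Analytic anchors

Under HWE at a site with ALT frequency `p`, the per-site probability of a
homozygous variant call is

* `p^2` against a fixed all-REF reference,
* `p(1-p)` against a random-haplotype reference (the reference itself
  carries ALT with probability `p`),
* `min(p, 1-p)^2` against the consensus.

Averaged over a uniform SFS these give 1/3, 1/6 and 1/12: the consensus
halves the homozygous-variant rate relative to a type-specimen reference.
Two further uniform-SFS anchors: the reference carries the minor allele at
`2 * integral(p dp, 0..1/2) = 1/4` of sites, and among calls against it the
fraction whose called allele is the major allele is 11/16 for homozygous and
5/16 for heterozygous calls -- the familiar "about two-thirds / one-third"
reference-bias signature. `expected_hom_rate()` exposes the closed forms;
the test suite verifies each by Monte Carlo against the simulator.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `sfs_model` | shape of the global AF distribution | `uniform` | symmetric, maximises polymorphism; anchors have clean closed forms |
| `fst` | Balding-Nichols divergence | 0 | unstructured cohort unless structure is the question |
| `eps` | frequency truncation | `1/(2 n_samples)` | every site expected polymorphic at cohort size |
| `ref_mode` | reference construction | `random-haplotype` | the type-specimen property under study |
| `seed` | root RNG seed | 1 | child seeds per stage/sample: `(seed * 1009 + offset) mod 2^31 - 1` |
| consensus tie | AF exactly 0.5 | keep REF | the rule is strict `> 0.5`; ties are reproducible |

## Problem sizes used in the checks

The package's own verification runs at these sizes, chosen so every
stochastic check has its dominant noise term well below the asserted
tolerance while the whole suite stays interactive:

* hom-rate anchors and ratio: 50,000 sites x 200 samples, uniform SFS
  (site-level standard error of the ratio about 0.011; assertions at 3
  standard errors, with sites -- not samples -- as the independent
  replicates, since all samples share the site list and reference draw);
* type-specimen KS check: 3,000 sites x 30 samples, repeated over seeds;
  the reference and a collapsed genome share sites, so the two carried-AF
  samples are tied at identically-collapsed sites -- `ks.test` is run with
  `exact = FALSE` and the property asserted as a majority of p-values
  above 0.01 across seeds (a single p-value is uniform under the null);
* oracle equivalence: 100 random 30-site cohorts, genotype bookkeeping vs
  brute-force base-by-base comparison of reconstructed diploid sequences
  against the consensus FASTA;
* population gain: 6,000 sites x 300 samples, 3 subpopulations, Fst 0.1
  vs 0.

## Design choices where the design was open

* **AF source precedence**: frequencies are recomputed from GT whenever
  genotypes are present, with INFO `AF` as fallback; a disagreement beyond
  `af_tol` (default 0.01) is logged, or fatal with `strict = TRUE`.
* **Population consensuses include every site** in the global list, using
  that population's frequency -- including sites monomorphic within the
  population.
* **Per-sample population summaries**: `mode = "matched"` (each sample vs
  its own population's consensus, the default) and `mode = "mean"` (counts
  averaged over all population consensuses) are both implemented; outputs
  label which was used.
* **Sampling of report genomes** is simple random sampling without
  replacement, with stratified sampling available behind a flag.
* **Missing dosages** are excluded from AF denominators, collapse to REF,
  and never become calls under any reference.
* **Mode as headline statistic**: per-genome count distributions are
  summarised by mean, median, sd and the mode of a histogram with
  configurable bin width, since such distributions are typically read off
  their modal peaks.

## What the simulator does and does not emulate

It emulates: a polymorphic site list with population allele frequencies,
subpopulation divergence at a stated Fst, HWE diploid genotypes, and a
reference whose alleles behave like one sampled haplotype. It does **not**
emulate linkage disequilibrium (sites are independent; a major-allele
consensus does not preserve haplotype structure, and haplotype-block-scale
consensus construction is out of scope), indels, multi-allelic or structural
variants, genotyping error, or read-level effects -- in particular
alignment-level reference bias, which the site-level bookkeeping here cannot
see. Passing checks therefore demonstrate the *combinatorial and
population-genetic* correctness of consensus construction and re-calling,
not read-mapping behaviour on real data.

## A worked run

```{r example, eval = FALSE}
spec <- cohort_spec(n_sites = 20000, n_samples = 200,
                    n_subpops = 3, fst = 0.1, seed = 1)
res <- run_pipeline(spec, out_dir = tempfile("run"))
res$hom_distribution
```

The per-scope table shows the homozygous-count distribution shifting down
from the reference to the global consensus (about a factor of two in the
mean under a uniform SFS) and further under population-matched consensuses,
with a tighter spread -- the expected behaviour of a more refined null.

## Known limitations

Site-level analysis only (no re-alignment); single synthetic chromosome;
bi-allelic SNVs only; population labels must partition the cohort. The VCF
writer emits the subset of VCFv4.2 the analysis consumes (GT format, AF
INFO keys); symbolic alleles and breakends are out of scope.
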