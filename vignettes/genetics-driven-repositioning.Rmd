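---
title: "Genetics-driven drug repositioning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetics-driven drug repositioning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The procedure

`oxiscore` implements a genetics-first drug-repositioning funnel for a
disease phenotype defined by pathway membership — the worked case study is
multiple sclerosis (MS) with oxidative-stress (OS) pathways. The premise:
a gene whose expression or protein level is causally perturbed by disease
risk alleles is a better drug target than one nominated by annotation
alone, and the *sign* of that perturbation dictates whether a drug must
inhibit or activate the target.

The stages:

1. **Intake.** GWAS index variants ("top hits", one per locus) are read
   from a TSV and gated at p < 1e-5.
2. **Proxy expansion.** Each hit is expanded to the panel variants with
   r² > 0.7 (strict) within a 1 Mb window, using a two-locus EM haplotype
   estimator on the unphased genotype panel.
3. **Target mapping.** A gene becomes a target when a hit or proxy is a
   molecular QTL (eQTL, pQTL, sQTL, polyQTL, mQTL) for it, or carries a
   missense-or-worse consequence with CADD-Phred > 15. MHC genes are
   excluded (see below).
4. **Pathway overlap.** Targets are intersected with the union of the
   disease-phenotype pathway sets (GMT).
5. **Scoring and selection.** Each shared target receives the
   five-criterion score below; the top 25% are prioritized.
6. **Direction of effect.** For genes with a brain QTL of known sign, the
   risk allele is coupled through LD phase to the QTL effect allele: if the
   risk allele raises the molecular trait the therapeutic goal is
   inhibition, otherwise activation.
7. **Drug selection and ADME.** Candidate drugs are kept if they target a
   prioritized gene, are approved or in clinical trials (experimental
   compounds run as a separate track), have supported interactions
   (direct action, interaction score > 0.50, or published validation), and
   act in the direction the genetics requires. Survivors are gated by
   ADME-Tox descriptor rules for CNS penetration and oral bioavailability.

## The LD engine

For two biallelic loci with unphased genotypes, the four haplotype
frequencies are estimated by EM over the phase of double heterozygotes:
all other genotype cells contribute known gamete counts; the
double-heterozygote count is split between the two phasings in the ratio
of their current frequency products. From the estimated frequencies:
D = p(AB) − p(A)p(B), D′ = D/Dmax, r² = D²/(p(A)(1−p(A))p(B)(1−p(B))).
The *coupled allele* map follows the sign of D: each allele of the first
locus is paired with the allele of the second that co-occurs in excess on
haplotypes. Conventions:

* **Initialisation** is the linkage-equilibrium product of the allele
  frequencies, which are fixed by the data (phase cannot change allele
  counts). This makes the estimate deterministic — no seed dependence.
* **Convergence**: maximum frequency change < 1e-10 or 1000 iterations.
  The log-likelihood is non-decreasing by construction and is asserted in
  a property test.
* **Degenerate case**: a table dominated by double heterozygotes has a
  symmetric stationary point at D = 0 where the phase is genuinely
  undecidable; the estimator stays there by design and flags the pair
  `degenerate`, and no direction call is made through such a pair. The
  global likelihood maximum in this situation sits at either boundary
  phasing, so the EM-vs-exhaustive-search acceptance test treats exactly
  this case as the admissible disagreement.
* **Monomorphic loci** make LD undefined; this is signalled as a
  condition (`undefined = TRUE`), not an error.
* **Missing genotypes** are deleted pairwise and the effective sample
  size recorded in `n_eff`. This is the simplest defensible contract; no
  imputation is attempted.

## The five-criterion score

For each target, over all of its collected variants (hits plus their
QTL/consequence proxies), each criterion awards the maximum applicable
value — "met by at least one collected variant" is realized as a maximum:

| criterion | value |
|---|---|
| c1: top hit p < 5e-8 | 5 (2 if every such hit is in the MHC) |
| c2: top hit OR > 1.2, by LD to a gene-level QTL proxy | 4 / 3 / 2 / 1 for LD ≥ 0.99 / [0.95, 0.99) / [0.90, 0.95) / [0.80, 0.90) |
| c3: eQTL available | 10, +5 if a brain eQTL |
| c4: LD between top hit and eQTL | 5 / 3 / 2 / 1, same bins as c2 |
| c5: non-eQTL QTL with LD ≥ 0.99 to a top hit | 3 |

The maximum total is 32. Selection retains the top
`floor(0.25 × N)` totals and extends across boundary ties; the realized
boundary (20 in the case study) is reported alongside.

Design points a user should know:

* **Bin boundaries** are half-open `[lo, hi)` with the top bin closed at
  0.99; the source bands are quoted without boundary membership, so this
  is a convention, applied consistently and unit-tested at the edges.
* **OR is used as reported** on the risk-allele scale; protective ORs are
  not folded.
* **c2 vs c4 double counting**: c2 ranges over all QTL types and c4 over
  eQTLs only, so one eQTL proxy can earn both. This mirrors the criteria
  as stated; be aware of it when interpreting totals.
* Evidence with 0.7 < r² < 0.8 maps a gene (the proxy threshold) but
  contributes 0 to the LD-binned criteria (bins start at 0.80).
* **MHC handling** reconciles two statements — "excluding MHC genes" and
  scoring MHC hits at 2: genes on a configurable MHC-gene list are always
  excluded; genes whose *every* evidence variant lies in chr6:27–33 Mb
  (closed interval, GRCh37) are excluded by default
  (`exclude_all_mhc_evidence`); MHC variants remain usable evidence for
  other genes but down-score c1 to 2.

## Direction calls and drug matching

One call per gene and tissue, using the evidence with the highest LD to
its hit; ties prefer eQTL over other QTL types, then the smallest variant
id — deterministic, and biased toward the evidence class the scoring also
privileges. If equally-ranked top evidences disagree in sign, the call is
emitted with `conflict = TRUE` and imposes *no* constraint on drug
matching (the behaviour is explicit rather than silently picking a side).
QTL records may carry an unknown effect sign (empty `effect_sign`); they
support mapping and scoring but never a direction call — this is what
separates the case study's 18 brain-QTL genes from its 10 direction
calls.

Drugs matching a directed gene must have `mechanism` equal to the
required modulation; `other` mechanisms fail against a directed gene and
pass against an undirected one.

## ADME thresholds

The selection bands are qualitative ("medium–good", "high"); the numeric
defaults follow the descriptor tool's published conventions and are fully
configurable: CNS activity ≥ 0 (−2..2 scale); logBB in [−1.0, 1.2]
(medium cut of the −3..1.2 scale); MDCK and Caco2 apparent permeability
≥ 100 nm/sec (< 25 poor, > 500 great); human oral absorption class 3 of
3 and ≥ 80%. A missing descriptor fails its rule (reported as
`missing`), never passes silently. Tightening any threshold can only
shrink the pass set; this monotonicity is property-tested.

## The synthetic generator and what a green test establishes

`generate_bundle()` emits all seven inputs from a declarative plan (one
hit per planted gene, at most one QTL, optional consequence record,
pathway membership, drug plan) plus a ground-truth JSON computed by a
straight-line restatement of the rules, independent of the pipeline code.

Two constructions are worth explaining:

* **Exact LD.** Planted hit–proxy pairs use rational haplotype pools on
  the symmetric 0.5/0.5 allele-frequency grid, where r = 4f − 1 for pool
  fraction f of each coupled haplotype, paired into homozygotes. With no
  double heterozygotes the EM solution is closed-form and the realized r²
  equals the planted value exactly, so bin-sensitive ground truth (the
  0.95 and 0.99 edges) is well-defined. The general `simulate_panel()`
  instead pairs haplotypes at random — realistic double heterozygotes, a
  ±0.1 tolerance contract on realized r² at n ≥ 500.
* **Determinism.** Each bundle uses a single RNG stream from its seed,
  records the seed in every file header, restores the caller's RNG state,
  and is byte-identical across runs.

What the generator does *not* emulate: realistic allele-frequency
spectra or demography (all planted variants sit at frequency 0.5),
genotyping missingness, multi-QTL genes, overlapping LD blocks, or the
external-database scale of a real analysis (hundreds of hits, thousands
of targets). A green parameter-recovery test therefore establishes that
the pipeline's logic is faithful to the stated rules — not that it would
be robust to messy population-genetic structure.

## The case-study fixture

`ms_fixture()` encodes the name-level result lists of the MS/OS case
study: the 18 brain-QTL genes, the 7 up- / 3 down-regulated direction
calls, the 10 repurposable drugs over 5 targets (CARM1, MAPK1, CDK4,
STAT3, FOS), the 7 surviving experimental compounds, and the two MAPK1
inhibitors (MK8353, LY3214996) removed for direction inconsistency. The
underlying variants, panel, p-values and 58 of the 85 pathway-overlap
genes are synthetic stand-ins (named `SYNT..`) engineered so the funnel
arithmetic holds: 85 shared targets, top 25% = 21 selected, realized
threshold 20, with gene 21 placed exactly at 20 and the runner-up at 18.
The source accounting of "50 compounds" versus the enumerated 35+5+11 is
not resolvable from the published lists; the fixture encodes only the
named compounds (12 repurposable candidates including the two removed,
7 experimental) and documents the discrepancy rather than inventing the
unnamed remainder.

## Numerical and I/O conventions

* Coordinates are 1-based on a single build; every table carries a
  `# build=` header and the pipeline refuses to mix builds (no liftOver).
* Gene identity is the uppercased symbol; alias resolution is out of
  scope.
* Floats are written with 17 significant digits so write/read round-trips
  are lossless to 1e-12.
* All stage outputs are row-count audited against the report
  (`audit_ok`), and output ordering is deterministic (never dependent on
  input row order).

## Limitations

No colocalization testing backs the QTL links; direction calls rest on
the single best evidence rather than multi-tissue meta-analysis; the
intake gate (p < 1e-5) is applied uniformly although real catalogues mix
significance conventions across studies; consequence and CADD annotation
are consumed, never computed; and the ADME gate filters predicted
descriptors — it does not predict them from structure.
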