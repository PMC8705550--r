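# oxiscore

Genetics-driven drug repositioning for oxidative-stress targets.

`oxiscore` is for computational geneticists and drug-repositioning
analysts who want to go from a GWAS hit table to a short list of
existing drugs with the *right direction* of target modulation. It links
disease index variants to genes through molecular QTLs (eQTL, pQTL,
sQTL, polyQTL, mQTL) and linkage disequilibrium, intersects the genes
with a disease-phenotype pathway universe, ranks them with a
five-criterion genetic score, derives whether each target should be
inhibited or activated from the coupling of the risk allele to the QTL
effect allele in brain, and filters a drug–target table accordingly,
gated by ADME-Tox rules for CNS penetration and oral bioavailability.
The worked case study is multiple sclerosis (MS) against oxidative-stress
(OS) pathways.

## The core statistics

**Two-locus LD with allele coupling.** Haplotype frequencies are
estimated from unphased genotypes by EM over double-heterozygote phase;
then D = p(AB) − p(A)p(B), r² = D² / (p(A)(1−p(A)) p(B)(1−p(B))), and the
coupled-allele map follows sign(D). Proxies of a hit are the panel
variants with r² > 0.7 within 1 Mb.

**Five-criterion target score** (per target, maximum over its collected
variants; total ≤ 32):

- c1 — top hit p < 5×10⁻⁸: 5 points (2 if only inside the MHC,
  chr6:27–33 Mb);
- c2 — top hit OR > 1.2, binned by LD to a gene-level QTL proxy:
  4/3/2/1 for r² ≥ 0.99 / [0.95, 0.99) / [0.90, 0.95) / [0.80, 0.90);
- c3 — eQTL available: 10, plus 5 if it acts in brain;
- c4 — LD between top hit and eQTL: 5/3/2/1 over the same bins;
- c5 — non-eQTL QTL with r² ≥ 0.99 to a top hit: 3.

The top 25% of totals (ties extended) are prioritized. Direction of
effect: if the risk allele's coupled QTL allele raises the molecular
trait, the therapeutic goal is inhibition; if it lowers it, activation.
Drugs must be approved or in trials, have supported interactions
(direct action, interaction score > 0.50, or published validation), and
match that modulation; survivors must pass the ADME gate (CNS activity
≥ 0, logBB in [−1.0, 1.2], MDCK and Caco2 ≥ 100 nm/s, oral-absorption
class 3 and ≥ 80%).

## Worked example

The bundled case-study fixture generates all seven inputs (GWAS hits,
QTL catalogue, consequence annotations, genotype panel, pathway GMT,
drug table, ADME table) and the pipeline reproduces the funnel:

```r
library(oxiscore)

dir <- tempfile()
fx <- ms_fixture(dir = dir)   # writes the seven input files
cfg <- pipeline_config(
  gwas = fx$paths$gwas, qtl = fx$paths$qtl, panel = fx$paths$panel,
  pathways = fx$paths$pathways, consequences = fx$paths$consequences,
  drugs = fx$paths$drugs, adme = fx$paths$adme,
  out_dir = file.path(dir, "out"))
run_pipeline(cfg)
#> oxiscore run report
#>   GWAS hits retained:      88 (dropped 0 at p >= gate)
#>   hit-proxy pairs:         115
#>   gene targets:            88 (0 MHC-excluded)
#>   pathway-shared targets:  85
#>   prioritized (top 25%):   21 at threshold >= 20
#>   direction calls:         10 (0 conflict)
#>   repurposable survivors:  10 over 5 target(s)
#>   experimental survivors:  7
```

Reading the report: 85 genes sit in both the MS evidence and the OS
pathway universe; the top quartile (21 genes, realized score threshold
20) goes to drug matching; 10 genes have a brain direction call (7
requiring inhibition, e.g. CARM1, and 3 activation, e.g. MAPK1); 10
repurposable drugs over 5 targets survive drug selection plus the ADME
gate (the MAPK1 inhibitors MK8353 and LY3214996 are removed because the
genetics asks for activation), alongside 7 experimental compounds.
Per-stage TSVs and a JSON report land in `out_dir`.

For synthetic data with planted ground truth, see `?generator_config`
and `?generate_bundle`; a thin CLI lives at `inst/cli/oxiscore.R`
(subcommands `run`, `fixture`, `simulate`). The methods vignette
(`vignettes/genetics-driven-repositioning.Rmd`) documents estimator
conventions, parameter defaults and design decisions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the case-study bundle from scratch with the installed package,
runs the full pipeline on its files, and writes the recomputed headline
quantity (the count of repurposable drugs surviving the drug-selection
and ADME gates) as JSON.
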