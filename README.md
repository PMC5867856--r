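# adnasex

Biological sexing and authentication of ancient or severely degraded
shotgun sequencing data, in R.

DNA in ancient and badly degraded forensic specimens survives as fragments
mostly shorter than 100 bp, carrying characteristic chemical damage. This
package implements the analysis chain used to work with such data once
reads have been mapped: quality/duplicate/length filtering, terminal
deamination profiling, damage-based selection of authentic molecules, the
two chromosomal read-ratio sex statistics, and a mitochondrial
consensus-and-contamination workflow. A truth-tagged read simulator makes
every stage testable without access to controlled human data.

## The statistics

**R<sub>Y</sub>** — with n<sub>X</sub> and n<sub>Y</sub> unique reads mapped
to the sex chromosomes,

> R<sub>Y</sub> = n<sub>Y</sub> / (n<sub>X</sub> + n<sub>Y</sub>),   SE = √(R<sub>Y</sub>(1−R<sub>Y</sub>)/(n<sub>X</sub>+n<sub>Y</sub>)),

with a Wald 95% CI R<sub>Y</sub> ± 1.96·SE. Female when the CI upper bound
is < 0.016; male when the lower bound is > 0.075.

**R<sub>X</sub>** — mean over the 22 autosomes of the length-normalised
ratios r<sub>i</sub> = (n<sub>X</sub>/L<sub>X</sub>)/(n<sub>i</sub>/L<sub>i</sub>),
with CI mean ± 1.96·SD(r)/√22. Male when the CI upper bound is < 0.60;
female when the lower bound is > 0.80. Roughly 1 for XX and 0.5 for XY
individuals.

**Damage** — terminal C→T (5′) and G→A (3′) substitution frequencies are
modelled as D(z) = δ·φ<sup>z</sup> + ε at offset z from the molecule end.
The per-read PMD score is the log-likelihood ratio of this damage model
against a null in which every such substitution is background error; reads
scoring ≥ 3 are treated as authentic ancient molecules, and both sex
statistics are reported for all reads and for this damage-restricted set.

**Mitochondrial workflow** — circular pileup, consensus calling at minimum
depth 5 and majority frequency ≥ 80%, coverage summary, and a
maximum-likelihood mixture estimate of the modern contamination fraction
(endogenous component with damage-aware mismatch probabilities versus a
panel of candidate modern haplotypes, weights fitted by EM, bootstrap 95%
CI).

## Worked example

Simulate a male (XY) ancient library with no UDG treatment and 2% modern
contamination, run the whole pipeline, and print the report:

```r
library(adnasex)
report <- run_pipeline(list(
  seed = 3,
  simulate = list(karyotype = "XY", n_reads = 20000, contam_fraction = 0.02),
  mtdna = list(n_boot = 50)))
report
```

```
== adnasex pipeline report ==
seed 3, config 2789512961
reads: 20000 in, 14985 used (0 mapq / 2128 short / 2886 long / 1 dup removed)
damage: 5' C>T(0) = 0.279, 3' G>A(0) = 0.268; fitted D(z) = 0.277 * 0.48^z + 0.0014
Sex determination report

All reads:
  Mapped reads  14985
  Mapped to X   410
  Mapped to Y   137
  R_Y           0.2505  (95% CI 0.2141-0.2868)  male
  R_X           0.5323  (95% CI 0.5233-0.5412)  male

Damage-selected reads (PMD score >= 3):
  Mapped reads  3291
  Mapped to X   87
  Mapped to Y   26
  R_Y           0.2301  (95% CI 0.1525-0.3077)  male
  R_X           0.5129  (95% CI 0.4969-0.5288)  male

mtDNA: 94 reads, coverage 0-3 (mean 0.3), 16569 uncalled positions
```

Reading the output: ~25% of reads fall outside the retained 36–70 bp
window; the 5′ C→T frequency near 0.28 at the terminal base, decaying
geometrically, is the expected signature of unrepaired ancient DNA, and
the fitted damage curve recovers the library's amplitude. Both statistics
call the sample male — R<sub>Y</sub> ≈ 0.25 with a CI entirely above
0.075, R<sub>X</sub> ≈ 0.5 with a CI entirely below 0.60 — whether or not
the analysis is restricted to damaged molecules (simulated reads sit at
their true coordinates, so male R<sub>Y</sub> targets the idealized
L<sub>Y</sub>/(L<sub>X</sub>+L<sub>Y</sub>) ≈ 0.28 rather than the ~0.09
seen with real mapped data, where much of the Y is unmappable). The mtDNA
block shows why shotgun data alone cannot yield a mitochondrial profile:
at 0.3× coverage every position fails the depth-5 rule and stays uncalled —
consensus and contamination work needs capture-depth data, e.g. a
simulation restricted to chrM (`simulate_reads(cfg, ref, chroms = "chrM")`).

Individual stages are plain functions — `parse_alignments()`,
`filter_reads()`, `remove_duplicates()`, `damage_profile()`,
`fit_damage_params()`, `pmd_score()`, `compute_ry()`, `compute_rx()`,
`sex_report()`, `build_pileup()`, `call_consensus()`,
`estimate_contamination()` — and a thin CLI wrapper with `simulate`,
`filter`, `sex`, `damage`, `mtdna` and `run` subcommands is installed at
`inst/scripts/adnasex`. See the vignette in `vignettes/` for the methods
and their assumptions.

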