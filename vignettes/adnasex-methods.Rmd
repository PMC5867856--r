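---
title: "Methods: sexing and authenticating degraded shotgun sequencing data"
author: "adnasex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sexing and authenticating degraded shotgun sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnasex)
```

## The problem

DNA surviving in ancient or badly degraded forensic specimens is fragmented
to well under 100 bp and chemically damaged, so targeted PCR assays fail and
shotgun sequencing of whole libraries is used instead. Two questions then
dominate the analysis: *is the sequence data endogenous* (rather than modern
contamination), and *what can be said about the individual* — here,
biological sex. This package implements the standard desk-side answers:
read-level filtering, terminal-deamination profiling and damage-based read
selection, the R~Y~ and R~X~ chromosomal read-ratio statistics, and a
mitochondrial consensus-plus-contamination workflow. A truth-tagged
simulator generates data with the relevant properties so the whole chain is
testable without access to controlled human data.

## Read model and filtering

Reads enter as aligned records (SAM/BAM via Rsamtools, or a plain TSV with
the same fields) and are held internally with 0-based half-open coordinates;
SAM's 1-based positions are converted on input and output. A single
convention avoids off-by-one mistakes in terminal-offset arithmetic, which
is where damage lives.

The default filter retains reads with mapping quality at least 30 and
lengths in the 36–70 bp window: the lower cutoff guards against spurious
short alignments of microbial fragments, the upper against modern
contaminants, which tend to be longer. Both bounds are configurable
(`filter_config()`), and `max_len = Inf` disables the upper cutoff for
nuclear shotgun data where only the microbial guard is wanted — whether the
upper cutoff should apply outside the mitochondrial workflow is genuinely
ambiguous, so it is a switch rather than a hard rule.

Duplicate collapse (`remove_duplicates()`) treats reads as copies of one
molecule when they share chromosome, strand, fragment length and the
5′-most reference coordinate of the molecule (alignment start on the plus
strand, alignment end on the minus strand). The representative kept is the
highest-mapq read, ties broken by read identifier so the operation is
deterministic. This emulates standard duplicate marking at desk scale
without its optical/flag machinery. Merging datasets concatenates first and
deduplicates after, so a molecule sequenced in two libraries is counted
once.

## Damage model

Post-mortem cytosine deamination is read as C→T near the 5′ end of a
molecule and, in a double-stranded library, G→A near the 3′ end. The
package models the substitution probability at offset $z$ from the relevant
end as

$$D(z) = \delta\,\varphi^z + \varepsilon,$$

geometric decay from an amplitude $\delta$ at the terminal base to a
background $\varepsilon$ that absorbs sequencing error and polymorphism.
The geometric form is the standard single-parameter summary of observed
misincorporation curves; neither real damage-profiling tools nor this
package claim it is mechanistically exact, only that it tracks empirical
profiles well. Beyond `max_offset` (default 25 bp) the damage term is
treated as fully decayed. Defaults for $\delta$ follow commonly observed
operating points: 0.27 for a library without effective uracil removal,
0.084 under partial UDG treatment (about a three-fold reduction), 0.01 for
full UDG; $\varphi = 0.5$, and $\varepsilon = 0.001$ in the simulator
(0.01 as a conservative analysis default, since real data carry more noise
than the simulator).

`damage_profile()` counts substitutions per terminal offset over
reference-C (respectively -G) opportunities, after re-orienting
minus-strand alignments so offsets are measured on the original molecule.
Offsets with no opportunities are reported as undefined (`NA`), never as
zero. `fit_damage_params()` least-squares fits $D(z)$ to the 5′ profile
with parameters clipped to their valid ranges; starting values are
moment-style (tail mean for $\varepsilon$, terminal excess for $\delta$)
so the port-algorithm `nls()` converges on clean profiles to machine
precision, with a bounded `optim()` fallback for degenerate ones.

The PMD score of a read is the log-likelihood ratio (natural log) of the
damage model against a null in which every C→T/G→A is background error:
a C→T at offset $z$ contributes $\ln(D(z)/\varepsilon)$, an intact C
contributes $\ln((1-D(z))/(1-\varepsilon))$, all other columns 0. Base
qualities are deliberately ignored — the TSV interchange format carries
none, and $\varepsilon$ absorbs the error rate — which keeps scores
computable from every supported input. The damage-restricted analyses use
threshold 3 in nats, the conventional operating point; reads with indels
or without reference bases score 0 and thus drop out at any positive
threshold, a conservative choice.

## Sex statistics

With $n_X$ and $n_Y$ unique reads on the sex chromosomes,

$$R_Y = \frac{n_Y}{n_X + n_Y}, \qquad
  \mathrm{SE} = \sqrt{\frac{R_Y(1-R_Y)}{n_X+n_Y}},$$

with a Wald 95% CI $R_Y \pm 1.96\,\mathrm{SE}$ clipped to $[0,1]$. The
call is female when the CI upper bound is below 0.016 and male when the
lower bound exceeds 0.075; anything else is indeterminate.

$R_X$ compares X read density to each autosome:
$r_i = (n_X/L_X)/(n_i/L_i)$ for autosomes $i = 1..22$, and
$R_X = \bar r$ with CI $\bar r \pm 1.96\,\mathrm{SD}(r)/\sqrt{22}$. Male
when the upper bound is below 0.60, female when the lower bound exceeds
0.80. The CI form is a reconstruction of the method's published
per-autosome-ratio interval; note that all 22 ratios share the numerator
$n_X$, so the interval understates the sampling noise of $n_X$ itself —
a known property of the method, not a defect of this implementation, and
one reason the two statistics are always reported side by side. Autosomes
with zero reads are excluded with a warning; fewer than two usable
autosomes is an error. When both statistics are computed the report states
each call separately; no fusion rule is applied, and a combined verdict is
only implied when they agree.

Reported estimates are rounded half-away-from-zero at 4 decimals for
display; machine output always carries the raw values. Computing the CI
from raw counts can differ in the last printed digit from propagating a
rounded estimate, and the package always uses raw counts.

## Mitochondrial workflow

The mitochondrial reference is circular: pileup positions are taken modulo
the reference length, so fragments spanning the origin are handled without
edge artifacts (`build_pileup()` errors on overhanging reads only when the
reference is declared linear). Consensus calling uses the conservative
depth/frequency rule: a position is called to its majority base only with
depth ≥ 5 and majority frequency ≥ 0.80 (ties are never called; with any
`min_freq` above 0.5 a tie fails the frequency rule automatically).
Tightening either threshold can only convert calls into `N`s, never the
reverse.

Contamination is estimated with a likelihood mixture over reads. An
endogenous read matches the sample consensus up to damage: mismatch
probability $D(z)$ at consensus-C positions near the molecule 5′ end and
consensus-G positions near the 3′ end, $\varepsilon$ elsewhere. A
contaminant read is modelled as drawn from one of a user-supplied panel of
candidate modern haplotypes, with mismatch probability $\varepsilon$
everywhere; each panel haplotype is its own mixture component whose weight
is fitted, and the contamination proportion is the total weight off the
endogenous component. Likelihoods are computed on match/mismatch indicators
per column (no base qualities), positions where the consensus is `N` are
ignored, and the weights are fitted by EM to relative tolerance $10^{-8}$,
with the log-likelihood asserted non-decreasing at every iteration. The
95% CI is a non-parametric bootstrap over reads (default 200 replicates,
seedable); each replicate refits the endogenous-versus-contaminant split
from a cold start with the contaminant panel *composition* held at its
full-data estimate, which keeps replicates honestly dispersed while making
them cheap. If no read overlaps a site where the consensus differs from
the panel, the mixture is unidentifiable and the function says so rather
than returning a number.

Two design points deserve emphasis. First, the contaminant side is neither
each read's *best-matching* haplotype (maximising over panel members is
not a proper likelihood — in simulation it roughly doubled a true 10%
contaminant fraction) nor a fixed equal-weight average (which taxes reads
from the true contaminant by $\log K$ and biases the proportion low);
fitting the panel weights removes both defects, and in simulation the
estimator recovers a 10% admixture with sampling error at the
informative-read binomial bound. It also makes the estimate invariant to
duplicating a panel sequence, up to EM convergence tolerance. Second, this
is a maximum-likelihood EM with bootstrap CI, not the full Bayesian MCMC
of the established contamination tools; it estimates the same mixture
proportion at desk scale and is verifiable against simulation truth.

## The simulator

`sim_config()` fixes the study conditions: a miniature genome with nuclear
chromosomes at 1/1000 of hg19 lengths (large enough for stable
per-chromosome counts, small enough to regenerate in seconds) and a
full-size 16,569 bp circular mitochondrial genome, since mitochondrial
coverage and contamination behave realistically only at real length.
Fragment lengths are log-normal parameterised by their mode (47 bp default,
38 bp for a shorter-fragment protocol; `sdlog` 0.3 reproduces the observed
25–80 bp spread), truncated to 20–120 bp. Damage is applied per $D(z)$
at reference-C offsets from the 5′ end and reference-G offsets from the
3′ end of each molecule, with UDG mode selecting $\delta \in
\{0.27, 0.084, 0.01\}$. When a C→T occurs, the truth table attributes it
to deamination versus background in exact proportion
$\delta\varphi^z : \varepsilon$, so contaminant reads (simulated with
$\delta = 0$) never carry damage tags while still suffering background
error. Contaminant reads are drawn undamaged — from the first contaminant
mitochondrial haplotype for chrM, from an undamaged genome of configurable
karyotype for nuclear reads — mirroring the reasoning that damaged
molecules are unlikely to be modern. The endogenous mitochondrial
haplotype differs from the mapping reference at 10 sites by default and
each of the 5 panel haplotypes differs from it at exactly 30 sites, a
realistic between-lineage distance for human mitogenomes.

Reads are emitted *pre-aligned at their true coordinates*: no mapper runs,
so mappability artifacts are absent. Real male data show
$R_Y \approx 0.09$ because much of the Y is unmappable; simulated male
data instead target the idealized expectation
$L_Y/(L_X+L_Y) \approx 0.28$. Tests against simulation therefore validate
the statistics and thresholds, not mapper behaviour. Other features of
real data the simulator does not carry: GC structure (references are
i.i.d. uniform), indels, instrument error profiles and quality scores,
capture-enrichment bias, and UDG enzymology (treatment efficiency is a
free parameter, since fully treated real libraries have been observed with
undiminished damage when the reaction was inhibited).

## Problem sizes and numerical choices

The test suite exercises the statistics at 50,000-read simulations
(100,000 where the damage-restricted subset needs extra counts), which
gives the sex CIs several standard errors of margin to their thresholds;
mitochondrial runs use ~35× coverage for consensus recovery and ~200×
with 10% admixture and 200 bootstrap replicates for contamination
recovery. These sizes were chosen so each property is decided by the
statistics, not by luck, while a full run stays in minutes. Degenerate
inputs are defined rather than accidental: empty read sets flow through
filters and counts, zero-read simulations are valid, an all-`N` profile
refuses to fit, `nX + nY = 0` and an unidentifiable mixture are errors
with messages naming the cause. Ratios are never computed against
zero-count autosomes; EM runs in log space with a log-sum-exp guard.

## Limitations

No probabilistic karyotype inference (XXY and mosaicism are out of scope),
no Y-mappability correction, no haplogroup assignment or population
database comparison, no heteroplasmy beyond the `N` statuses, no indel
handling in damage analysis, and the contamination estimator trusts the
supplied panel to represent plausible contaminants. The package consumes
alignments; mapping itself, adapter trimming and demultiplexing are
upstream concerns.
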