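---
title: "Sigma scoring of pooled CRISPR suppressor screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sigma scoring of pooled CRISPR suppressor screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmascreen)
```

# The scientific problem

Pooled CRISPR knockout screens read out gene-level fitness by competition:
a library of sgRNAs (here, a Brunello-scale design of roughly 19,000 genes
with 4 guides each plus 1,000 non-targeting controls) is transduced into
cells at low multiplicity, the population is grown under a drug for about
two weeks with regular passaging, and guide abundances at harvest are
compared to the pre-treatment baseline (T0) by sequencing. In a suppressor
screen, knockouts that *restore* growth under a mitochondrial-translation
poison become enriched; knockouts that are synthetically sick with the drug
become depleted. `sigmascreen` implements this analysis — guide
quantification, sigma (Z) scoring, ΔZ hit calling, Fisher gene-set
enrichment — plus the growth bookkeeping and the [1,2-¹³C₂]-glucose
tracing arithmetic that accompany such a study, and a generative simulator
that makes every stage testable without any external data.

# The scoring model

For guide $g$ in sample $s$, relative abundance is
$a_{gs} = (c_{gs} + \epsilon)/\sum_{g'}(c_{g's} + \epsilon)$ with
pseudocount $\epsilon = 0.5$ by default. Per guide, condition and
replicate, the log fold-change against the replicate-matched baseline is

$$\mathrm{lfc}_{gcr} = \log_2 \frac{a_{g,\,(c,r,\mathrm{day15})}}{a_{g,\,(r,\,T0)}}.$$

Gene scores are the nested mean — each guide averaged over replicates,
then the gene over its guides — and are Z-transformed per condition using
the mean and *population* SD over gene-targeting genes (controls are
excluded from the standardization and kept as a null diagnostic):

$$z_{ic} = \frac{\bar{\mathrm{lfc}}_{ic} - \mu_c}{\sigma_c}.$$

The sigma-plot quantity is the Z difference between two conditions,
$\Delta Z_i = z_{ia} - z_{ib}$, with the drug arm first so suppressors are
positive. Hits are called at a fixed inclusive threshold,
$|\Delta Z| \ge 3$ by default, sorted by $|\Delta Z|$ with lexicographic
tie-breaks for byte-stable outputs. Suppressor lists are tested against
gene-set collections with a right-tailed Fisher exact test
($p = P(X \ge a)$ under the hypergeometric with the table's margins) and
Benjamini–Hochberg adjustment; the default universe is the set of scored
gene-targeting genes, since that is the population from which hits are
drawn.

Two aggregation orders are defensible: average guide fold-changes first
and Z-transform gene scores (the default), or z-score guide-level
fold-changes within a condition and then average per gene
(`z_before_average = TRUE`). We default to the former because it is the
procedural description; both are exposed because they weight noisy guides
differently, and the tests confirm both rank strong suppressors
identically at the top.

"Relative difference" of two Z columns is read as the simple difference
$z_a - z_b$: it is symmetric, yields one dot per gene, and is stable near
zero, where a ratio would explode.

# The screen simulator

The simulator is the package's ground-truth source, emulating the stated
design: four arms (solvent reference EtOH, ACT, CAP, ACT+CAP), three
replicates, 15 days with 72-h passages and a 4×10⁷-cell bottleneck,
multinomial sequencing at ~150 reads per guide. Where the underlying study
design leaves a quantity unstated, the generator fixes one realistic
choice:

* **Initial library skew** — lognormal relative abundances with
  $\sigma_{\log_2} = 0.5$, a typical plasmid-pool dispersion.
* **Guide efficacy** — Beta(8, 2) per guide (mean 0.8); the realized
  coefficient is $s_\mathrm{eff}(g,c) = \mathrm{efficacy}(g)\, s(\mathrm{gene}(g),c)$.
* **Growth** — deterministic exponential competition: per passage, guide
  $g$ multiplies by $2^{D_c (1 + s_\mathrm{eff})}$, where
  $D_c = \frac{\text{passage interval}}{\text{doubling time}}(1 - \text{inhibition}_c)$
  is the condition's doublings per passage; the bottleneck renormalizes.
  Optional per-passage lognormal jitter and multinomial bottleneck
  sampling (drift) are off by default.
* **Drug effect** — a global $(1 - \text{inhibition})$ multiplier on the
  doubling rate. All drug arms default to 0.40 inhibition because the arms
  were dose-matched to comparable growth inhibition; the reference is
  always 0. With 24-h untreated doubling this gives
  $15 \times 0.6 = 9$ cumulative doublings over the screen, inside the
  8–12 window the design requires.
* **T0** — sampled from the initial composition (the pre-treatment
  expansion is neutral growth, which leaves relative abundances
  unchanged).
* **Selection magnitudes** — the study reports hit classes, not effect
  sizes in natural units, so simulator `s` values are free parameters;
  the default planted classes (s = ±0.4) produce unambiguous separation
  at 150× coverage without saturating the Z scale.
* **Seeds** — one master seed; each stage hashes its own 31-bit child
  seed (`child_seed`), so outputs are bit-reproducible and stages are
  independently perturbable.

Sequencing is multinomial per sample (columns sum exactly to the read
budget), with optional Dirichlet overdispersion. FASTQ emission writes
`prefix + protospacer + suffix` reads with independent per-base errors
and a configurable fraction of low-quality reads, Phred+33. The anchor
prefix is a required configuration value with a synthetic default
(`"ACCG"`), as vector context is construct-specific.

What the simulator deliberately does **not** model: lentiviral
integration-site effects, cell-cycle structure, clonal lineage barcoding,
PCR jackpotting, and guide-specific off-target toxicity. Passing tests
therefore demonstrate correctness of the arithmetic and calibration of
the statistics under multinomial sampling noise — not robustness to every
artifact of real screens.

# Quantification choices

"Phred score > 20" is interpreted as *mean* read Phred strictly above 20
(a per-base variant is available via `min_base_fraction`). Guide matching
is exact by default — with 20-mers at 150× coverage, exact matching is the
conservative choice — with an optional unique-neighbour 1-mismatch rescue;
ambiguous rescues stay unmatched. Demultiplexing is assumed done upstream
(one FASTQ per sample). Every sample satisfies the accounting identity
`mapped + filtered + unmatched = total`, which the tests assert.

# Null calibration

Under the all-neutral simulator null the per-condition Z columns are
standardized to unit SD, and because both arms share the per-replicate T0
baseline their scores correlate at about 0.5, so
$\mathrm{Var}(\Delta Z) \approx 2(1 - \rho) \approx 1$. The observed null
SD is ~1.00 and the fraction of genes beyond $|\Delta Z| \ge 3$ is ~0.3%,
under the 1% calibration bound — a property of the 150×, 3-replicate
design, not of tuning.

# Growth kinetics and MOI

Population doublings are $(\log N_\mathrm{end} - \log N_\mathrm{start})/\log 2$
(the log base cancels; natural logs internally), cumulative curves sum
per-interval doublings over (seeded, harvested) pairs, and infection
efficiency is the puromycin survival ratio. MOI is reported by inverting
the single-hit Poisson model, $\mathrm{MOI} = -\ln(1 - \mathrm{eff})$, so
30–50% efficiency maps to [0.357, 0.693]; whether the conventional
"MOI > 0.3" figure derives from this model or vendor guidance is not
asserted — both numbers are reported.

# Isotope-tracing arithmetic

Measured mass isotopomer distributions (MIDs) are corrected for natural
¹³C abundance ($p_{13} = 0.0107$) and tracer impurity by inverting a
convolution matrix: column $j$ of $M$ is the distribution of observed mass
shifts for a molecule with $j$ tracer-derived labels — Binomial($j$,
purity) label retention convolved with Binomial($n-j$, $p_{13}$) natural
gains. Only carbon isotopes are modeled. Correction solves
$\mathrm{raw} \approx M t$ by non-negative least squares (plain inversion
can return negative fractions on noisy data), then renormalizes.
Defaults: purity 0.99 (typical vendor specification; configurable),
$p_{13}$ 0.0107.

The flux readout uses the classic single-pass [1,2-¹³C₂]-glucose logic:
intact glycolysis delivers both labels into one lactate (m+2) per glucose,
while oxidative-PPP transit decarboxylates the labeled C1 and yields m+1
lactate, so the labeled-lactate fractions satisfy
$m_1/(m_1 + m_2) = f_\mathrm{PPP}$ and the reported m+1/m+2 ratio equals
$f/(1-f)$. Non-oxidative PPP recycling and exchange fluxes are excluded —
a known limitation that biases $f$ slightly low in systems with heavy
recycling. Glucose uptake is summarized as the G6P/glucose total-pool
ratio. Replicate QC flags samples whose total intensity falls below a
configurable fraction (default 0.5) of the batch median; exclusions are
logged in the run manifest, never silent.

# Numerical and degenerate-input policy

Pseudocounts keep all fold-changes finite; zero-depth samples, zero-SD
screens (all gene scores equal), all-zero MIDs, zero m+2 lactate and
non-positive cell counts are errors, not NaNs. Ranking ties break
lexicographically. The correction matrix uses direct convolution of the
two binomials (exact to machine precision), and the Fisher tail uses the
hypergeometric CDF in log-stable form via `phyper`.

# Problem sizes

The test suite simulates at desk scale — null calibration uses 20 screens
of 1,000 genes × 4 guides at 150× coverage, hit recovery one screen of the
same size with 50 planted suppressors ($s = +0.4$, drug arm only) — sizes
at which the statistical properties of interest (null ΔZ calibration,
AUROC ≥ 0.95 recovery, enrichment ranking) are already stable across
seeds. Genome-scale runs use the same code paths with larger
configuration values.
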