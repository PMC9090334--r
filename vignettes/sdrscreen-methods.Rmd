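---
title: "Methods: forward genetics and chemoproteomics for SDR-activated ynone prodrugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward genetics and chemoproteomics for SDR-activated ynone prodrugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscreen)
```

# The problem

Secondary alkynylcarbinols are prodrugs: a short-chain
dehydrogenase/reductase (SDR) oxidizes the carbinol to the corresponding
alkynylketone (ynone), a potent Michael acceptor that covalently modifies
cysteine and lysine side chains of cellular proteins and kills the cell.
Which SDR performs the bioactivation can be identified by forward genetics:
chemically mutagenize a pseudo-haploid cell line, select clones resistant to
a lethal prodrug concentration, and look for a gene that is disrupted in
every resistant clone. `sdrscreen` implements the downstream analysis of
that strategy, together with the chemoproteomics and pharmacology
arithmetic that supports it:

* **variant screen** — filter clone-specific coding variants, rank genes by
  recurrence across independently derived clones, detect expression
  silencing, and nominate candidates that explain *every* clone;
* **chem mass** — exact-mass bookkeeping for ynone probes, their Michael
  adducts on proteins, and isotope-tagged (isoDTB) modification offsets;
* **pull-down enrichment** — fold change and Student's t statistics for
  label-free quantification (LFQ) of streptavidin pull-downs, plus
  sequence-context analysis of modified residues;
* **dose response** — SRB viability normalization, four-parameter logistic
  (4PL) fitting, IC50 and fold-resistance;
* **synthetic data** — seeded generators that emulate each input with a
  machine-readable ground truth, so every stage is testable without the
  original sequencing and proteomics archives.

# The screen model and its inference rule

Ethyl methanesulfonate (EMS) induces essentially only single-nucleotide
changes, mostly transitions. In a pseudo-haploid clone every fixed mutation
is hemizygous, so a true somatic call should show an allele fraction (AF)
near 1. The filter retains a clone variant iff

1. it has no parental match on (chromosome, position, ref, alt) — a
   parental variant at *any* AF masks the site;
2. AF ≥ 0.9 (inclusive);
3. depth > 10 reads (strict);
4. its consequence is frameshift, missense or nonsense
   (`missense_variant`, `stop_gained`, `stop_lost`, `start_lost`,
   `frameshift_variant` in SnpEff's Sequence Ontology vocabulary).

With ~9 coding-mutated genes per clone drawn from a ~20,000-gene universe,
the chance that the same passenger gene recurs in ≥ 3 of 4 clones is of
order 10⁻⁵ per run, so recurrence across independently mutagenized clones
is essentially noise-free — this is why clone intersection works, and the
test suite verifies the collision rate by Monte Carlo.

A resistant clone can also lose the causal gene by *silencing* rather than
mutation. The silencing channel compares CPM between parental and clone:

$$\mathrm{fold} = \frac{\mathrm{CPM}_{parental} + c}{\mathrm{CPM}_{clone} + c}$$

with pseudocount $c = 0.5$; a gene is flagged when fold ≥ 50 and the
parental CPM is at least 5. Both thresholds are pipeline defaults exposed in
`silencing_policy()`: the published screens applied this channel
qualitatively (a ~200-fold loss with no detectable cDNA), and 50-fold with
an expression floor is a conservative quantitative rendering. Note an
arithmetic consequence of the pseudocount: a 50-fold call requires parental
CPM ≳ 25 even when the clone count is zero, so the channel is only
sensitive for solidly expressed genes — which is also the only regime the
underlying RNA-seq assay can support.

The decisive pattern is **coverage**: the fraction of clones explained by
either channel. `nominate_candidates()` ranks genes by coverage, then by
number of mutated clones, then id; a gene explaining every clone is a
*full-coverage candidate*, the pattern that singles out the bioactivating
enzyme in a four-clone screen.

# What the simulators emulate — and what they do not

`simulate_resistance_screen()` plants, per clone, Poisson(9) passenger
genes (sampled proportionally to coding length), a transition fraction of
0.85, and one causal gene that is mutated in most clones and silenced
~200-fold in the rest. Specific choices, with reasons:

* **Passenger AF ~ Beta(50, 1.5)** — mode near 1 with occasional lower
  values, so the AF ≥ 0.9 filter is actually exercised (about 1.4% of
  passengers fall below it).
* **Causal AF ~ Beta(200, 1.5)** — tighter than passengers. Selection
  guarantees the causal mutation is present in every cell of a surviving
  clone; subclonal AF is a passenger phenomenon.
* **Depth ~ NB(mean 60, size 10)** — typical RNA-seq coverage at expressed
  genes; the >10-read filter then rarely removes a true call
  (P ≈ 1.6·10⁻⁴).
* **Counts ~ NB with dispersion 0.1**, library sizes log-normal; silencing
  is applied to the expected counts before sampling.
* **Causal gene baseline ≈ 400 CPM.** An RNA-seq-based screen can only see
  genes the cell expresses, and a 200-fold knockdown is only reliably
  callable against a solid baseline: at 400 CPM the 50-fold flag fires with
  probability ≈ 0.98 per silenced clone under the count noise above,
  matching the unambiguous silencing observed in the real screens; at low
  baselines the pseudocount floor swallows the signal.
* Non-qualifying "chaff" variants (synonymous, low-AF) and ~50
  germline-like variants shared with the parental line are included so that
  every filter rule does real work.

Not emulated: read-level errors, alignment or variant-calling artifacts,
annotation mistakes, linked passenger haplotypes, copy-number changes, and
clone-to-clone library-quality differences. Passing the recovery tests
therefore shows the *inference* is sound under the stated statistical
model, not that upstream calling is robust.

`simulate_pulldown()` plants 42 enriched proteins (3 above 60-fold) among
2,000, three replicates per condition, i.i.d. log2-normal replicate noise
(sd 0.4). Missingness defaults to 0 — the matrix emulates a complete-case
protein-group table; set `missingness > 0` to study dropout, which is
missing-at-random here (real LFQ dropout is intensity-dependent, a known
limitation).

`simulate_viability()` follows the SRB protocol: duplicate wells per
concentration, three independent experiments pooled into one table,
background and untreated wells included, multiplicative log-normal well
noise (cv 5%). The default dose grid spans 1 nM–316 µM in half-log steps so
that it brackets both the parental IC50 (62.4 nM) and clones up to ~62-fold
resistant; a grid that stops within a decade of a clone's IC50 leaves its
lower plateau unidentified and visibly inflates the IC50 variance. With the
pooled design the per-fit standard error of log IC50 is ≈ 4%, so recovered
fold-resistances scatter ≈ 5–6% around truth; a tolerance band of
[34, 68] around planted folds of [38, 62] is then roughly a 1.8σ statement
at the edges — comfortable for typical seeds but not a certainty, which is
worth remembering when re-running with new seeds.

# Enrichment statistics

Fold change is the ratio of mean *linear* intensities (S over R);
significance comes from an unpaired two-sided Student's t-test with pooled
variance on *log2* intensities (LFQ noise is multiplicative). Welch's
correction is available behind `var_equal = FALSE`. Proteins lacking two
finite values in either condition are flagged, not imputed — imputation
manufactures significance. Selection is strict (`fc > 2` and `p < 0.05`);
no multiple-testing correction is applied by default because the original
selection rule used raw p-values, and Benjamini–Hochberg is available via
`adjust = "BH"`.

The residue-context tools take ±10-residue windows around a modified
cysteine or lysine (pad character at sequence ends, excluded from all
counts). The PSSM is the per-position log2 ratio of observed to background
frequency, both with a pseudo-frequency (default 0.01) to keep empty cells
finite. Hydrophobicity enrichment uses the Kyte–Doolittle scale by default
and a one-sided permutation test resampling window sets from the background
(10,000 draws, seeded, with the +1 correction so p ∈ (0, 1]).

# Dose-response numerics

Normalization: response = (A − mean background) / (mean untreated − mean
background); duplicate wells stay separate points; zero-concentration wells
serve only normalization (log10 undefined). The 4PL

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + 10^{\,h\,(\log_{10} c - \log_{10}\mathrm{IC_{50}})}}$$

is fitted by Levenberg–Marquardt with a data-driven start (asymptotes from
response extrema, log IC50 from the concentration nearest half-maximum,
|h| = 1 with the sign taken from the data's direction) plus five jittered
restarts under a fixed seed, best residual sum of squares wins. Parameters
are unconstrained — bottom may go negative, and monotone-increasing data
simply fit with negative slope. A flat response is reported honestly as
`converged = FALSE` with an undefined IC50 rather than an arbitrary number.
Noise-free generator inversion recovers IC50 to machine precision, and the
multi-start fit has been checked to coincide with a truth-started fit, so
the restarts guard against pathological starts without influencing the
optimum.

# Exact-mass conventions

Monoisotopic atomic masses are frozen in the package (H 1.00782503207,
C 12 exactly, N 14.0030740048, O 15.9949146196, S 31.97207100,
Si 27.9769265325, plus the common halogens and alkali adduct metals), so
results do not depend on an external mass library. Reported m/z values are
plain atomic-mass sums over the ion formula as written (an [M+H]⁺ formula
already contains the extra hydrogen) divided by charge and rounded
half-away-from-zero to 4 decimals; **no electron-mass correction** is
applied, which is the convention under which the printed HRMS "calcd"
values of the probe syntheses reproduce bit-exactly. Michael addition adds
the entire neutral probe mass (no neutral loss). The isoDTB tag masses
default to light 481.2757 / heavy 487.2829 Da, back-derived from the
printed heavy/light modification offsets of the C10 clickable probe
(625.3332 / 631.3404 minus the probe's 144.0575 Da); the corresponding
printed light offset for the C17 probe differs from probe-mass + tag by
~2 mDa, and the C10-derived values are treated as authoritative. Adduct
stoichiometry on deconvoluted intact-protein masses assigns each peak to
the (base species, adduct count) lattice point minimizing the residual
within a tolerance (default 0.5 Da), ties broken toward fewer adducts
(parsimony), then base order.

# Problem sizes used by the tests

The suite runs 200 four-clone screens over a 20,000-gene universe for the
recovery property, 1,000 random tables for the filter oracle, a
10,000-protein null pull-down plus 100 seeded default pull-downs for
calibration, and 100 noise-free curve inversions plus a 10-clone viability
run for the 4PL properties; the whole suite completes in about a minute on
one core. These sizes were chosen to make the binomial/Monte-Carlo
tolerances meaningful at interactive runtimes.

# Known limitations

* The screen inference consumes annotated variant calls; it neither calls
  nor re-annotates, and inherits any upstream artifacts.
* The silencing channel needs a well-expressed gene (see the pseudocount
  arithmetic above) and a single parental reference sample; a noisy
  parental measurement propagates into every fold.
* LFQ missingness is modelled as missing-at-random only.
* The permutation test for hydrophobicity treats residues as exchangeable
  across positions; real flanks have positional composition biases.
* Fold-resistance tolerance bands are statistical statements, not
  guarantees, at the edges of the planted range (see above).
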