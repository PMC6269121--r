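---
title: "Pooled MHC-I minigene screens: design, deconvolution and clonal-fraction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled MHC-I minigene screens: design, deconvolution and clonal-fraction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presenteR)
```

## The experimental system

A minigene that encodes an ER signal sequence followed by a single defined
MHC class I peptide forces Tap-deficient cells to display exactly that
peptide. Because the epitope's coding DNA is unique per peptide, the peptide
is its own sequencing barcode: a pool of such cells can be injected into an
immunocompetent mouse, the tumor harvested, the minigene cassettes
amplified and sequenced, and each subclone's fate read off from the change
in its barcode's relative abundance. Depletion of a barcode between
injection and harvest is the screen's readout for an immunogenic peptide;
this is a drop-out screen, structurally the same analysis problem as a
pooled CRISPR viability screen.

This package implements the computational side of that experiment
end-to-end: library design from a proteome, oligo encoding, read counting,
abundance comparison, and the two-color mixture analysis that estimates the
clonal fraction below which immune depletion cannot be detected. Every
input can also be generated synthetically, with the statistical structure
the analysis assumes, so the whole pipeline is testable offline.

## Library design

Wild-type candidates are all unique 8-mers of the proteome
(`enumerate_kmers()`); non-canonical residues are excluded because affinity
matrices are defined only over the 20 canonical amino acids. Binders are
peptides with predicted IC50 strictly below 500 nM — the conventional
class-I binder cut, applied with a strict `<` — and the library is a
uniform without-replacement sample of `n_select = 5000` binders
(`select_wildtype_library()`), deterministic under a seed and invariant to
input order.

Each wild type receives one single-residue mutant
(`build_mutant_library()`). The mutant must

* differ from its partner at exactly one position (position and
  replacement residue drawn uniformly from the `8 × 19 = 152` candidate
  space),
* itself pass the same `IC50 < 500 nM` filter — "the substitution must not
  eliminate binding" is made operational with the only binding criterion
  the screen states, and
* not equal any proteome k-mer. The exclusion is deliberately the whole
  proteome rather than only the 5000-member library: a "mutant" matching a
  self peptide anywhere in the proteome would be a self antigen, not a
  neoantigen. `exclude_scope = "library"` gives the narrower reading.

Rejection sampling uses a budget of 200 draws (above the candidate-space
size); `method = "enumerate"` enumerates all admissible neighbours and
samples one uniformly, which cannot miss an admissible mutant and is what
the exhaustion tests use. Wild types with no admissible mutant are flagged
and excluded rather than silently dropped. Provenance uses 0-based
half-open starts; mutated positions are 1-based, matching how positions
are discussed in the field.

`characterize_library()` reports three statistics over the pairs: the
absolute affinity shift with a dedicated "within 100 nM" bin, the mutated
position histogram, and the substitution-class matrix. The
hydrophobic/polar/charged partition is a fixed documented convention
(hydrophobic A,C,F,I,L,M,P,V,W; polar G,H,N,Q,S,T,Y; charged D,E,K,R);
published figures of this kind rarely print their convention, so the only
defensible choice is to fix one and state it.

## Affinity scoring

External predictions enter as tables (`load_prediction_table()`, or
`read_netmhcpan()` for the long predictor format, columns located by
header name). Duplicate predictions keep the minimum IC50 — the most
optimistic binding call, conservative for binder filtering. The bundled
`toy_affinity_model()` is a seeded position-weight matrix with calibration
`ic50 = 50000·exp(−score)`; it is a *test double* with the right interface
(deterministic, strictly monotone calibration, canonical residues only),
not a scientific predictor, and with its default N(0.6, 0.5²) weights
roughly half of random 8-mers pass the 500 nM cut, which keeps the design
pipeline exercised at realistic sizes.

## Minigene encoding

`build_minigene()` assembles `adapter + SfiI site + signal + epitope +
stop + SfiI site + adapter`. Codon choice is the most frequent mouse codon
per residue, with seeded fallback to synonymous alternatives whenever the
degenerate SfiI pattern `GGCCNNNNNGGCC` would arise — checked across
junctions by including 12 nt of fixed flanking context, and re-verified on
the finished oligo, which must contain exactly its two intended sites.
(The pattern class is its own reverse complement, so one-strand matching
covers both strands.) In-silico digestion (`digest_sfii()`) cuts the top
strand after `GGCCNNNN`, so the released middle fragment is the insert
carrying the overhang remnants of both flanks; the tests verify this by
string surgery on a hand-worked example.

The shipped signal sequence is a synthetic, GGCC-free, ATG-initiated
placeholder and the default adapters are generic T3/T7 promoter primers:
the real construct's sequences are deposited with the plasmid rather than
printed, and inventing them would be worse than a documented placeholder.
Both are plain arguments.

`validate_pool()` reports duplicate encodings and stray SfiI sites (hard
violations) plus the minimum pairwise Hamming distance between encodings —
informational barcode confusability: distance 1 means one sequencing error
can convert one barcode into another, which the ambiguity-discarding
counter then refuses to resolve.

## Counting and screen comparison

`count_minigenes()` replaces a general-purpose aligner with anchored-window
matching: the epitope occupies a fixed position in the amplicon, encodings
are short and unique, so exact or ≤1-mismatch Hamming comparison of the
read's leading window is auditable and deterministic. A read tied between
two references at its best distance is discarded as ambiguous; mapped +
unmapped always equals total (conservation is a tested invariant), and the
implementation is checked against a brute-force all-pairs Hamming oracle.

Relative abundance is each minigene's count over total mapped reads.
`compare_screens()` averages replicate abundances arithmetically, computes
`log2((post + ε)/(pre + ε))`, and fits a LOESS trend (span 0.5, degree 1)
of log10 post on log10 pre for the classic pretumor-vs-tumor scatter. The
trend needs at least 10 distinct pretumor abundances, otherwise it is
reported NA rather than fitted degenerately. Numerical choices:

* **Pseudocount** `ε = 1/(2 · max total mapped reads)`: scale-aware, keeps
  drop-outs finite, and is below half the smallest observable abundance so
  it never reorders observed minigenes.
* **Drop-out floor** `1e-4`: minigenes rarer than 1/10,000 at injection
  are lost through the engraftment bottleneck by sampling alone (an
  inoculum of 5×10⁶ cells contains only a few hundred of them), so their
  disappearance is not evidence of immune selection and they are excluded
  from depletion calls.
* **Call threshold** `|log2 FC| ≥ 1`: the screen itself implies no formal
  call rule (its headline result is the *absence* of depletion), so the
  2-fold default is an exposed, reported parameter, never silently
  applied.

## Clonal-fraction analysis

For each tumor in a two-color mixture experiment, the eGFP/mCherry
percentages are renormalized to sum to 100 (non-fluorescent events are
host infiltrate and are ignored by construction), and the fold change is
normalized tumor percent over day-0 percent. Tumors with no recoverable
fluorescent cells are rejected: excluded from testing, but counted and
reported, since discarding fully rejected tumors biases the test *against*
detecting depletion and must be visible.

Each intended-fraction group is tested with a one-sample t-test of the
per-tumor log10 fold changes against mean 0. Two choices deserve
explanation:

* **Sidedness.** The default is one-sided in the depletion direction
  (`alternative = "less"`). Depletion is a directional hypothesis — the
  screen asks whether the subclone was lost, and enrichment, however
  extreme, is not depletion (a direction guard enforces this in both
  modes). The decisive argument is power: with 3–4 tumors per group the
  two-sided critical t at α = 0.001 is 12.9 (df 3), so even a 30-fold mean
  depletion at measurement SD 0.2 log10 units is detected in barely a
  third of experiments; the one-sided critical value of 10.2 makes the
  detection probabilities 0.90 (strong effect, −1.5 log10) and 0.59 (weak,
  −1.0). A depletion assay whose nominal procedure cannot detect 10-fold
  depletion at its own reporting threshold is mis-specified; the
  two-sided variant remains available for sensitivity analysis.
* **α = 0.001** mirrors the four-star reporting convention of such
  experiments and is configurable.

Groups with zero variance (possible with noiseless synthetic data) are
reported sign-based — significant only if the common value is negative —
with no t-statistic.

`detect_threshold()` returns the smallest fraction whose group is
significant *and* whose larger tested fractions are all significant (the
monotone frontier). The quantity of interest is a detection limit; an
isolated significant group below a non-significant one is more plausibly a
false positive than a genuine non-monotone dose response, though
`frontier = FALSE` gives the permissive reading. `tumor_volume()` is the
companion caliper utility (`L × W² × 0.52`).

## What the generators emulate — and what they do not

`simulate_screen()` is a chain of multinomial bottlenecks: injection
(multinomial draw of the inoculum from pretumor abundances — stochastic
drop-out of rare clones emerges here, with no explicit rule), selection
(survival multiplier `s_i`, applied only when the *realized* inoculum
fraction reaches minigene *i*'s clonal-fraction threshold), deterministic
growth, and multinomial sequencing at the chosen depth. Pretumor
abundances default to log-uniform on `[2×10⁻⁷, 5×10⁻³]`: the observed
span of such libraries is four-plus orders of magnitude, from one cell per
5×10⁶ to about half a percent, and log-uniform reproduces that spread
without claiming a particular shape. Defaults: inoculum 5×10⁶ cells, depth
10⁶ reads, 3 pretumor and 5 tumor replicates.

`simulate_two_color()` draws each mouse's measured log10 fold change from
`Normal(kill·1[fraction ≥ threshold], sd²)` and emits flow-style
percentages (scaled by a fluorescent fraction of 0.85, so the analysis
must really perform the renormalization) whose pipeline-recovered fold
change equals the generative one exactly. The hard threshold gating is the
minimal generative mechanism consistent with antigen-specific detection
limits — a modelling assumption, not biology. The default effect sizes
(−1.5 log10 strong, −1.0 weak, SD 0.2, 4 mice/group) are what a mixture
experiment of this design plausibly measures; no quantitative kill rates
exist to calibrate against. A tumor is emitted as rejected when its
surviving cells fall below 1% of the injected mixture, mirroring the
observation that the most immunogenic-rich mixtures are rejected outright.

Deliberately *not* modelled: T-cell dynamics, PCR amplification bias,
UMIs, indels, paired-end structure, quality degradation. A green test
therefore establishes that the analysis recovers the parameters of this
stated generative world — multinomial noise, threshold-gated depletion,
substitution errors — not that it is robust to every artefact of real
sequencing.

One known quantitative limit of the stated world: with 4 mice/group, SD
0.2 and α = 0.001, the per-group one-sided detection power is 0.90/0.59
for the strong/weak effect, so the full monotone frontier is recovered in
about 74% (strong) and 34% (weak) of replicate experiments — the *modal*
detected threshold over 100 replicates is the generative one, but no test
procedure at these group sizes recovers it in ≥90% of single experiments.
The acceptance suite asserts both facts honestly.

## Limitations

* The bundled affinity model carries no immunology; real designs should
  ingest genuine predictor output via the table readers.
* Counting assumes the epitope window starts the read (pre-trimmed,
  anchored amplicons); arbitrary-offset reads would need adapter trimming
  upstream.
* The depletion call threshold, floor and pseudocount are reported
  parameters with sensible defaults, not inferential statistics; the
  screen comparison deliberately stops short of a formal per-minigene
  test, which would require a variance model replicate counts here cannot
  support.
* 9–11-mer libraries are structurally supported (controls may differ in
  length; counting handles mixed-length references) but defaults and tests
  target 8-mers.
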