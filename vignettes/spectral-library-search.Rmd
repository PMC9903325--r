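---
title: "Scoring, decoys and FDR in speclib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, decoys and FDR in speclib}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speclib)
```

## The identification problem

In bottom-up proteomics, peptides are identified by matching each tandem
mass (MS/MS) spectrum to a reference. A spectral library search compares
the query spectrum against *previously observed* (or predicted) spectra of
known peptides, rather than against theoretical fragment patterns computed
from a sequence database. Because real libraries carry observed fragment
intensities, library search is typically more sensitive than database
search — at the price of needing a library and, for error control, a
credible way to build *decoy* spectra. speclib implements both halves: a
composite probabilistic/quantitative match score, and a
shuffle-and-reposition decoy generator driven by an iterative fragment-ion
annotation system.

## Preprocessing

Query and library spectra pass through the identical pipeline
(`preprocess_spectrum()`):

1. **Unspecific-ion removal.** Peaks below `low_mass_cutoff` (default
   145 Th) are dropped, as are peaks within `precursor_window` (default
   2 Th) of any precursor-derived species: the precursor at charges
   $z, z-1, \dots, 1$ and their $-\mathrm{H_2O}$/$-\mathrm{NH_3}$
   satellites. The cutoff at 145 Th sits below the smallest singly charged
   y1 ion of interest while excluding the immonium region; both values are
   explicit knobs because no universal convention exists.
2. **Peak picking.** Within each fixed 100 Th window $[100k, 100(k+1))$
   only the $m$ most intense peaks survive (`depth`, default 15).
   Fixed bins, not sliding windows, are used — the simplest reading of
   per-window thinning, and deterministic. Intensity ties keep the
   lower-m/z peak so the operation is seed-free.
3. **Normalization.** Intensities are scaled to a constant sum (default
   100). Only ratios matter downstream.

The composition is idempotent, which the test suite checks by direct
double application.

## The match score

For a preprocessed query $s_I$ ($N_I$ peaks) and library spectrum $s_L$
($N_L$ peaks), peaks are paired one-to-one within the fragment tolerance
(default 20 ppm), greedily by ascending absolute ppm error. With $n$
matched pairs, the score is

$$S(s_I, s_L) = P(s_I, s_L) \cdot Q(s_I, s_L)$$

**The probabilistic score** $P = -\log_{10} p_F$ combines three p-values
by Fisher's method, $X = -2(\ln p_B + \ln p_{KT} + \ln p_{HG})$, with
$p_F$ the upper tail of $\chi^2_6$ at $X$:

* $p_B$ — cumulative binomial: the probability of matching $n$ or more of
  the $N_I$ query peaks by chance, where the single-peak chance
  $p_{match}$ is the fraction of the query's m/z span (first to last
  peak) covered by the union of tolerance windows around the library
  peaks. Intensities play no role here.
* $p_{KT}$ — Kendall-Tau rank correlation: with $q$ the number of
  discordant pairs between the intensity ranks of the matched peaks
  (re-ranked within the matched subset), $p_{KT} = P(Q \le q)$ under the
  uniform permutation null. The inversion-count frequency distribution
  $f(q, n)$ is computed *exactly* for $n \le 170$ via the recurrence
  $f(q,n) = \sum_{j=0}^{\min(q,n-1)} f(q-j,\,n-1)$ in big-integer
  arithmetic (counts reach $170! \approx 7\times10^{306}$, beyond exact
  double range), cached per $n$. Fewer discordances mean better
  correlation, so the lower tail is the "as good or better" probability.
  Beyond $n = 170$ a continuity-corrected normal approximation with mean
  $q_{max}/2$ and variance $n(n-1)(2n+5)/72$ takes over.
* $p_{HG}$ — hypergeometric: the probability that $r$ or more of the $n$
  matched pairs share *exactly* the same intensity rank in their
  respective full spectra, an upper hypergeometric tail with population
  $N_{max} = \max(N_I, N_L)$, $n$ marked items and $n$ draws.

**The quantitative score** $Q = L_{scoring}/L_{total} \in [0,1]$ is the
fraction of the library spectrum's total intensity carried by *scoring
peaks*: peaks both matched to a query peak and annotated with a relevant
ion series — by default y-ions, b-ions and the internal fragments derived
from them.

The product form isolates two complementary monotonicities: $P$ grows
with the improbability of the mass/rank agreement, while $Q$ gates the
score on how much of the reference's explained fragment intensity the
query actually reproduces. The combination lives in one function
(`score_match()`), so alternative forms are one-line changes. All
subscores, counts and per-series matched intensities are exported in the
PSM table for downstream rescoring.

Numerical guards: p-values are clamped to $[10^{-300}, 1]$ before logs;
$p_{match}$ to $[10^{-9}, 1-10^{-9}]$; intensity-rank ties break by
ascending m/z so every ranking is a true permutation and the whole
computation is bit-reproducible.

## Annotation of library spectra

Decoy generation needs most library peaks annotated. The annotator is an
iterative expert system: a base list of b/y ions (charges up to
$\min(2, z)$) is matched to the spectrum; every matched ion spawns
*derived* ions — $-\mathrm{H_2O}$ variants when the spanned residues
include S/T/E/D, $-\mathrm{NH_3}$ for K/R/N/Q, and for matched b/y ions
the internal fragments (length $\ge 2$, singly charged, b-type chemistry)
created by a second cleavage inside their span. Derived ions are matched
against still-unannotated peaks and the loop repeats until a pass
annotates nothing new; termination is bounded by the peak count. When two
annotations land on one peak, a fixed priority table decides
(y < b < y-loss < b-loss < a < a-loss < internal), ties by smaller ppm
error. Keeping a-ions and losses out of the base list keeps first-pass
matching specific. The exact loss catalogue and gating residues of
published expert-system annotators are not fully standardized; the table
above is the package's documented default and is deliberately small.

The annotation-relevant parameters are fingerprinted
(`annotation_signature()`) and stored in the MSP Comment; a search run
whose fragment tolerance does not match the stored signature should
regenerate annotations and decoys rather than trust stale ones.

## Decoy generation

For each target entry the sequence interior is shuffled uniformly with
the two terminal residues fixed; positioned modifications move with their
residue instance, terminal modifications stay. A shuffle is accepted when
the Kendall-Tau correlation between original and shuffled residue
positions, $\tau = 1 - 4q/(L(L-1))$, is at most 0.5; otherwise it is
redrawn, up to $L^2$ trials (sequences whose interior is too short to
reach the threshold simply produce no decoy and are counted). Duplicate
residues are tracked as instances so $\tau$ is always defined on a true
permutation.

Every annotated peak then moves by
$\delta = m/z(\text{ion} \mid \text{decoy}) - m/z(\text{ion} \mid \text{target})$
at the annotation's charge — applied in m/z space so each peak keeps its
original calibration error — with its intensity unchanged. Internal
fragment annotations are recomputed from the same positional interval in
the decoy sequence (intervals, not residue identities, are conserved).
Peaks shifted outside the detectable range (default: the target
spectrum's own observed m/z range) are discarded; unannotated peaks are
copied verbatim. Because the shuffle permutes the full residue multiset,
the decoy precursor mass equals the target's, so decoys compete in
exactly the same precursor windows. Terminus-anchored ions (y1, b1, and
the full-length series) have $\delta = 0$ by construction. Per-entry RNG
streams derived from `(seed, entry index)` make the generator order-stable
and byte-reproducible.

## FDR estimation and validation

Rank-1 PSMs compete across the concatenated target+decoy library. At a
score threshold $t$, $\mathrm{FDR} = \#\text{decoy hits}/\#\text{target
hits}$ over PSMs with $S \ge t$ (non-strict, an isolated constant). The
q-value of a PSM is the minimum FDR over all thresholds that accept it.

For synthetic-peptide-pool validation the package computes a second,
library-independent error rate: a target hit is *correct* when its
stripped sequence equals a pool sequence or is a contiguous substring of
one (truncated synthesis products motivate the substring rule), and
$\text{synthetic FDR} = \#\text{incorrect}/(\#\text{incorrect} +
\#\text{correct})$. I and L are distinct by default, with an equivalence
flag; modified peptides compare by stripped sequence, since pool lists are
plain sequences.

## The synthetic data generator

`sim_config()` describes the simulated experiment: tryptic-style peptides
(ending K/R, no internal cleavage site, length 7–20, charges 2–3),
b/y fragments at theoretical m/z with Gaussian mass error (default
5 ppm spread), rank-exponential intensities
($I \propto e^{-\mathrm{rank}/10}$) whose rank order is a deterministic
property of the peptide — replicate spectra share their fragmentation
pattern, so the rank-correlation subscores carry signal — with about 30%
log-normal spectrum-to-spectrum variation, 20% fragment dropout and 20
uniform noise peaks per
spectrum whose intensities come from the lowest quartile of the fragment
intensities. Library spectra are simulated at consensus quality (1 ppm
jitter, no dropout, no noise) and annotated by the expert system.
Validation runs mix spectra of library ("pool") peptides with spectra of
off-pool peptides and keep a truth table, so both the target-decoy FDR
estimate and the true planted FDR are computable.

What the generator does *not* emulate: isotope envelopes, co-isolated
chimeric spectra, charge-state errors, intensity structure learned from
real HCD data, retention time, and modification-rich libraries. Passing
the recovery tests therefore demonstrates correctness of the machinery —
scoring, decoy competition, FDR arithmetic — under a clean generative
model, not sensitivity on real instrument data.

## Problem sizes and numerical choices

The validation workloads use 200-entry libraries with 200 noisy query
spectra (decoy invariants are additionally checked on 500 entries), sizes
at which a full simulate–annotate–decoy–search–FDR cycle completes in
well under a minute while leaving every code path exercised. Exactness
claims are tested against brute-force oracles at small $n$: term
enumeration for the binomial, full permutation enumeration ($n \le 7$)
for Kendall-Tau, draw enumeration for the hypergeometric, and quadrature
for the Fisher $\chi^2_6$ tail.

Known limitations: greedy peak pairing is not a globally optimal
assignment (it is oracle-tested where unambiguous); the hypergeometric
population parameterization and the exact combination form of $P$ and
$Q$ admit alternatives, and both are isolated behind single functions;
c/z/x ions (ETD) and isotope-aware annotation are out of scope.

## A minimal session

```{r example, eval = FALSE}
cfg <- sim_config(n_peptides = 50, seed = 1)
peps <- generate_peptides(cfg)
lib <- build_fixture_library(peps, cfg)
dec <- generate_decoy_library(lib, tol_ppm = 20, seed = 1)
run <- build_validation_run(peps, list(), cfg)
psms <- qvalues(search_run(run$spectra, c(lib, dec)))
head(psms[psms$rank == 1, c("spectrum_id", "peptide", "S", "Q", "q_value")])
```
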