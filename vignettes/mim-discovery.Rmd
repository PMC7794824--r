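---
title: "Discovering and evaluating MYC-interaction motifs with mimscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and evaluating MYC-interaction motifs with mimscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimscout)
```

## The problem

The MYC-interaction motif (MIM) is a short linear motif (SLiM) through
which a subgroup of plant MYB transcription factors binds MYC bHLH
transcription factors.  It is the six-residue element
`[L/F]LN[K/R][V/L]A`, of which only the core positions `xLNxxA` (L2,
N3, A6) are absolutely required for binding.  Six residues carry little
information — roughly 20–25 bits for the full degenerate pattern — so a
pattern scan of any realistic sequence collection yields both genuine
motifs and spurious matches.  Distinguishing the two requires the
sequence *context*: genuine MIMs sit inside large intrinsically
disordered regions (IDRs), locally form transient helices, and show a
characteristic compositional neighbourhood, whereas core-pattern
matches inside folded domains (as found in trihelix transcription
factors) do not bind.

`mimscout` packages that whole reasoning chain: pattern and profile
search, context evaluation, conservation contrast, and helicity
estimation from NMR chemical shifts, together with synthetic-data
generators that make every stage testable without external databases.

## Pattern scanning

A `motif_pattern` is an ordered list of allowed-residue sets with a
core mask.  Scanning reports *every* window whose residues all lie in
the allowed sets; overlapping hits are all kept, because proteins can
carry several motif instances.  Masked residues (`X`, from the `"mask"`
input policy) match no position, including "any" positions, so hits
never overlap corrupted sequence.  Coordinates are 1-based and
inclusive throughout, and `map_to_protein()` shifts peptide-local hits
into protein numbering.

```{r scan}
scan_motif("SSTSKLLNKVAARASS", "core")
map_to_protein(scan_motif("DSLVAVLNKLADAVAK", "core"), 294)
```

## Profile search with empirical significance

`build_seed()` extracts motif regions (motif plus `flank` residues each
side, `flank` between 0 and 20) from a set of hit-bearing sequences;
windows truncated at a terminus are padded with a neutral symbol that
contributes background frequencies to its columns and scores 0 bits.
`estimate_profile()` turns the seed into a log-odds matrix with column
probabilities

$$ p_j(a) = \frac{c_j(a) + \lambda\,q(a)}{n + \lambda}, $$

where $c_j$ counts residues in column $j$ (pad symbols contribute
$q(a)$ each), $q$ is the background, and $\lambda = 0.5$ is a
Jeffreys-style pseudocount.  Scores are $\sum_j \log_2 p_j(a_j)/q(a_j)$
in bits.  The background defaults to the database's own residue
frequencies (with an add-one floor); a uniform background is available.

Significance is empirical rather than analytic.  The null is built by
Fisher–Yates-shuffling each database sequence and scoring windows until
$M = 10^5$ null scores are collected; the E-value of a window score $s$
is $N \cdot \hat P(S \ge s)$ over the $N$ database windows.  Beyond the
observed null maximum the survival function is extrapolated with an
exponential (peaks-over-threshold) tail anchored at the maximum.  The
decay length is the mean exceedance over the null's 99.9th percentile:
mean-excess diagnostics on shuffled-window scores show the exponential
regime is typically reached only in the top ~0.1% (the mean excess
still shrinks between the 99th and 99.5th percentiles), and fitting a
wider slice overestimates the decay length severalfold, which inflates
far-tail E-values and starves the iterative refinement of hits.  For
null samples too small to populate that slice the threshold falls back
to the 99th percentile.

Searching is iterative in the manner of profile tools that readjust
their query from significant hits: hits at `evalue_cutoff` (default
1e-3) are appended to the seed, the profile re-estimated, and the
database rescanned until the hit set is stable or `max_iterations`
(default 5) is reached.  Hit sets need not grow monotonically — a
sharpened profile can drop marginal windows — but the loop always
terminates.  Records can be excluded by their order-level taxon tag
before searching, mirroring taxonomy-restricted discovery searches.

### The planted-recovery benchmark

The packaged benchmark plants one `strict` instance per positive record
(50 positives, 50 rejection-sampled negatives guaranteed free of core
matches) and asks the search, seeded at flank 5, to recover them at
E ≤ 1e-3 within 3 iterations.  The seed uses 24 motif-region members:
with a 0.5 pseudocount, flank columns estimated from only a handful of
members leave rarer flank residues at about −4 bits per occurrence,
which pushes a tail of genuine windows below the cutoff; two dozen
members stabilise the column estimates while remaining the kind of
confirmed-instance collection an iterative search would accumulate.
Under this design the benchmark recovers ≥ 95% of planted instances
with no hits in negatives.

## Context classification

`composition_track()` implements sliding-window residue-set fractions:
at each position, (count of plus-set − count of minus-set) divided by
the residues the window actually covers (truncated at termini), over a
15-residue window by default.  `disorder_proxy()` is the window mean
(21 residues) of the TOP-IDP disorder-propensity scale rescaled to
[0, 1].  It is a *compositional* stand-in for sequence-specific
disorder predictors: adequate for contrasting disorder- and
order-biased segments, blind to long-range contacts, and deliberately
simple so the package has no external prediction dependencies.

`classify_context()` evaluates the three-feature MIM signature for one
hit:

1. **order dip within an IDR** — the proxy averaged over the hit span
   lies at least `dip_depth = 0.05` below its average over the
   surrounding ±25 residues, and the span sits inside a maximal run of
   proxy ≥ 0.5 at least 30 residues long;
2. **positive net charge** — the mean `+RK-DE` track over the span ±5
   residues is positive;
3. **flank bias** — the mean `+PST-RK` track over the two 15-residue
   flanks is positive.

The thresholds are package defaults, exposed as arguments, because the
underlying observations are qualitative; they were fixed once against
the synthetic generator (below) and are not fitted to any particular
input.  Hits near a terminus are evaluated on the residues that exist
and flagged `truncated`.

## Conservation contrast

`column_conservation()` applies the strict >50% consensus rule per
column (gaps excluded from the denominator): a consensus residue exists
only when one residue occupies strictly more than half the non-gap
entries.  Because that rule already implies identity above one half, a
column with an identity consensus is classed `consensus-identical`; a
column where no single residue dominates but one physicochemical
similarity group covers more than half is classed `consensus-similar`;
otherwise `unconserved`, with all-gap columns `no-consensus`.  The
default similarity partition is {AVLIM, FWY, ST, KR, DE, NQ, C, G, P,
H} and is configurable.

`motif_flank_contrast()` compares mean per-column identity between
motif columns and flank columns.  A SLiM inside an otherwise weakly
constrained IDR should stand out (positive contrast); a core match
inside a conserved folded domain should not.  Identity, not similarity,
feeds the statistic, since the motif's core is defined by identity.
Significance comes from permuting the motif/flank labels over the
pooled columns with a seeded RNG:

$$ p = \frac{1 + \#\{\text{permuted contrast} \ge \text{observed}\}}{1 + B}, $$

which can never return zero and is super-uniform under an exchangeable
null (verified over hundreds of simulated alignments).  No phylogenetic
correction is attempted; columns are treated as exchangeable, which the
i.i.d. generator matches but real alignments only approximate.

## Helicity from chemical shifts

`random_coil_shifts()` predicts sequence-corrected random-coil Cα
shifts: a per-residue base table, additive neighbour corrections for
offsets −2..+2 (parameterised for proline neighbours, the dominant
effect: −1.85 ppm for a residue preceding proline, −0.30 ppm
following), a linear temperature term (−0.003 ppm/°C from a 25 °C
reference), and Henderson–Hasselbalch pH corrections for D, E and H
relative to a pH 6.5 reference.  The packaged coefficients are this
package's own edition of such a reference set; because the synthetic
shift generator uses the *same* model, secondary-chemical-shift
round-trips are exact by construction and do not depend on which
published table edition the values most resemble.  Analyses of
externally measured shifts inherit whatever systematic offset exists
between this edition and the one used for referencing.

`scs_profile()` subtracts the prediction from observed shifts (table
metadata supplies temperature and pH; defaults are 5 °C and pH 7.0) and
flags residues with SCS > 0.1 ppm as transiently helical.
`helicity()` converts the *peak* SCS to fractional helicity by dividing
by a full-helix shift difference of 3.0 ppm, clamped to [0, 1]; this
constant reproduces both anchor conversions exactly (0.75 ppm → 25%,
0.36 ppm → 12%).  A segment-mean alternative is available via
`method = "segment_mean"`.  Negative SCS (extended propensity) is
reported but never converted to a strand fraction.

```{r helicity}
st <- make_shift_table("DSLVAVLNKLADAVAK", rep(0.25, 16), noise_sd_ppm = 0)
helicity(scs_profile(st$shifts))
```

## The synthetic generators

`make_proteome()` emits records of an ordered segment (80 residues,
enriched L/V/I/F/W/A) followed by a disordered segment (120 residues,
enriched P/S/T/G/E/K/R).  Kinds:

* `r2r3_like` — one `strict` instance planted at a uniform position in
  the IDR, with 35 residues on each side rewritten from a
  proline-biased flank composition (P .70, S .10, T .05, K .10, R .05;
  `+PST-RK` bias 0.70, no D/E);
* `trihelix_like` — one `core` instance planted in the ordered segment;
* `negative` — no motif, rejection-sampled until free of any chance
  core match.

Two design choices deserve comment.  First, flanks are drawn as random
permutations of the exact residue multiset realising the composition
(largest-remainder rounding) rather than multinomially: the rewritten
flank then *meets* its compositional target instead of only averaging
to it, which keeps the context features sharp at the scale of a single
record.  Second, the rewrite width (35 = 25 + half the proxy window)
guarantees every window feeding the order-dip reference lies in
rewritten sequence, so the dip is a property of the construction, not
of lucky sampling.  The flank composition was chosen once so that the
disorder proxy separates ordered from disordered segments by at least
0.2 and the order-dip margin clears its 0.05 threshold with room to
spare; milder flank biases (e.g. `+PST-RK` around 0.15) leave the dip
ceiling — about 0.2 times the proxy gap between flank and motif — too
close to the threshold for reliable classification.  What passing tests
on these records shows is that the signature logic is implemented
correctly and separable contexts are separated; it does not show that
real proteomes, with their messier compositions, will separate as
cleanly.

`make_msa()` samples a uniform ancestral row and derives each row by
independent per-column substitution at a motif-column or flank-column
rate (uniform over the 19 other residues).  There is no phylogeny —
rows are i.i.d. given the ancestor — which suffices for exercising the
contrast statistic but underestimates the column dependence of real
alignments.  `make_shift_table()` adds `helicity × 3.0 ppm` plus
Gaussian noise (default σ = 0.02 ppm) to the random-coil prediction,
with an optional 0.8× dip at designated positions emulating the lower
helicity at the motif's core L–N residues.

All generators are deterministic given their seed; the pipeline fans a
single seed out to per-stage seeds at fixed offsets so stages can be
rerun in isolation.

## Numerical and edge-case conventions

* Window statistics truncate at termini and divide by the residues
  actually covered.
* The >50% consensus rule is strict: 3 of 6 is not a consensus.
* Permutation p-values use the +1 correction and a ≥ comparison with a
  1e-12 tie tolerance.
* E-values are non-increasing in score; scores at or below the null
  maximum use the empirical survival (never below 1/M before the N
  multiplier).
* Sequences shorter than a pattern or profile yield empty results, not
  errors; empty FASTA input to the pipeline is an error.
* Problem sizes in the packaged benchmarks — 50+50 records for planted
  recovery, 100+100 for context separation, 500 alignments of 12×40
  for null calibration, 50 replicates per helicity level — were chosen
  as the smallest sets at which the binomial noise of the measured
  rates is comfortably below the margins being asserted.

## Known limitations

* The disorder proxy is compositional only; it will misjudge sequences
  whose disorder is determined by context rather than composition.
* The empirical E-value rests on a composition-preserving shuffle null
  and an exponential tail extrapolated about three orders of magnitude
  beyond the sampled null at the default cutoff; it is honest about
  rank order but approximate in absolute calibration.
* The conservation contrast has no tree correction; closely related
  sequence sets overstate its significance.
* Helicity assumes a single residue-independent full-helix Cα shift
  difference (3.0 ppm); residue-specific references would shift
  estimates by a few percentage points.
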