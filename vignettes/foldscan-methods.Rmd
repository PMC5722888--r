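---
title: "Scanning genomes for unusually stable RNA structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning genomes for unusually stable RNA structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscan)
library(dplyr)
```

## The problem and the model

Functional RNA structures tend to be more thermodynamically stable than
the base composition of their sequence alone would predict: evolution
selects the *order* of nucleotides to form stable base pairs. foldscan
turns that principle into a genome-scale screen. A chromosome or
transcript is fragmented into overlapping windows (by default 120 nt
every 40 nt, on both strands), each window is folded under a
nearest-neighbor thermodynamic model, and five metrics are archived per
window:

* **MFE** (`mfe`): the minimum free energy $\Delta G$ (kcal/mol) over all
  pseudoknot-free secondary structures, with its dot-bracket structure;
* **thermodynamic z-score** (`zscore`):
  $z = (\Delta G_{native} - \overline{\Delta G_{random}})/\sigma$, where
  the null is a set of composition-preserving shuffles of the same
  window (30 by default) and $\sigma$ is their sample (n−1) standard
  deviation.  Negative $z$ means the native order folds more stably than
  composition-matched random sequence;
* **empirical p-value** (`pvalue`): the fraction of shuffles whose MFE is
  strictly lower than the native MFE — a quality check on $z$;
* **ensemble diversity** (`ed`): the Boltzmann-expected base-pair
  distance between two draws from the equilibrium ensemble,
  $ED = \sum_{i<j} 2 p_{ij}(1-p_{ij})$, computed from the pair
  probabilities $p_{ij}$ of a McCaskill-style partition function
  ($Z = \sum_S e^{-E(S)/RT}$, $G = -RT\ln Z$); low ED means one dominant
  fold;
* **MFE frequency** (`fmfe`): $e^{-E_{MFE}/RT}/Z$, the equilibrium
  probability of the reported MFE structure.

Windows whose z-scores fall below a regional threshold
(mean $- k\cdot$sd, default $k=1$) and that are *consecutive on the step
grid* are concatenated into candidate structured domains; isolated low-z
windows are reported separately.

### Why 120/40

Windows of 100–150 nt are long enough to hold typical structured RNA
elements (most curated RNA families are under 200 nt) while keeping the
$O(n^3)$ folding cost small and local predictions accurate; a 40-nt step
canvasses every position in three frames so elements are unlikely to be
split by every frame at once.  Both are ordinary parameters of
`scan_config()`.

## Energy models and engines

The folding engine is pluggable (`fold_engine()`):

* `builtin:bp_min` — every allowed pair (AU, UA, GC, CG, GU, UG)
  contributes −1.0 kcal/mol; loops are free.  The MFE is then minus the
  maximum number of admissible pairs, computed by an exact
  maximum-pairing dynamic program, and the partition function has an
  equally transparent form.  This model is deliberately simple: every
  number it produces can be checked by exhaustive enumeration
  (`enumerate_structures()`), and it is the default for scans and tests.
* `builtin:nn_lite` — a lightweight nearest-neighbor model: a 6×6
  stacking table, size-dependent hairpin/bulge/internal-loop penalties
  (log-extrapolated past 30 nt), and an affine multiloop penalty
  $a + b\cdot\text{branches} + c\cdot\text{unpaired}$ with defaults
  (3.4, 0.4, 0.0) kcal/mol — a standard simplification whose scoring the
  enumeration oracle reproduces exactly.  Parameters live in a
  plain-text file (`inst/extdata/nn_lite.par`) users can replace.
* `rnafold` — an adapter that shells out to an RNAfold executable for
  full Turner-parameter folding.  Reproducing published human-genome
  values requires this class of engine plus the reference genome; the
  built-in models are for transparent, self-contained analysis.  A
  missing executable is an immediate error, never a silent fallback.

Temperature defaults to 310.15 K (37 °C) with
$R = 0.0019872$ kcal/(mol·K); energies are reported to 2 decimals in
files and kept at full precision in memory.

## The shuffle null

`shuffle_sequence()` draws uniform permutations of the window's letters,
so the nucleotide multiset — including any N placeholders — is conserved
exactly; a dinucleotide-preserving variant (random Eulerian trail on the
transition graph) is available behind `scan_config(shuffle =
"dinucleotide")` for users who want the stricter null.  The default
matches the mononucleotide-composition null the z-score is defined
against.  With 30 shuffles the empirical p-value has resolution 1/30,
and `converge_randomizations()` can verify that 30 is enough for a given
sequence class by doubling the count until the z estimate moves by less
than a tolerance (0.1 by default).

Every window's shuffles are seeded by hashing the global seed with the
window's coordinates and strand (`derive_seed()`), so any window can be
recomputed in isolation and serial, partial and parallel runs agree
byte-for-byte.

## N placeholders and degenerate windows

Assembly gaps appear as runs of N.  N never pairs and contributes no
energy; windows keep their Ns as placeholders so coordinates stay
aligned.  A window more than half N (configurable) is skipped: its
metrics are `NA` and it is flagged `skipped`.  A window whose shuffles
all fold to the same energy (e.g. a homopolymer) has $\sigma = 0$; its
z-score is `NA` and it is flagged `degenerate` rather than given an
arbitrary value.  Degenerate and skipped windows break domain runs and
are omitted from tracks.

## Numerical choices

* **Tie-breaking.** Many sequences have several co-optimal structures.
  The traceback is fixed: the external loop prefers leaving the 3' base
  unpaired, then the smallest 5' partner; interior decompositions scan in
  a fixed order.  Output dot-brackets are therefore byte-reproducible.
* **Internal-loop cap.** The general dynamic programs cap bulge/internal
  loops at 30 unpaired nt (the conventional cap); the bp_min fast paths
  are exact without a cap.  At enumeration-oracle scale the cap never
  binds, which is how the two routes can be required to agree to 1e−6.
* **Overflow.** Partition functions are Boltzmann sums of up to
  astronomically many structures; for 200-nt windows they stay far below
  double-precision overflow, and the code fails loudly rather than
  returning a non-finite $Z$.
* **p-value ties.** Shuffles exactly matching the native MFE do not
  count as "more stable" (strict inequality).
* **Trailing remainders.** When $(L - w) \bmod s \neq 0$ the final
  sub-window-length tail is not emitted as a partial window (all windows
  stay the same length); an end-anchored final window can be requested
  with `scan_config(end_anchored = TRUE)`.
* **Minus-strand tracks.** Track intervals trim every window to its
  genomically leftmost `step` nucleotides on both strands, keeping the
  two strands' tracks on a common grid.

## The synthetic fixture generator

`fixture_spec()` / `simulate_chromosome()` build chromosome-like FASTA:
i.i.d. background at a chosen GC content, perfect inverted-repeat
hairpins (stem–loop–revcomp(stem)) at known coordinates, and runs of N —
with a truth table of what was embedded where.  The package's end-to-end
validation scans a 100-kb chromosome of this kind with twenty 25-bp-stem,
8-nt-loop hairpins at 50% GC and requires that windows containing a
complete hairpin sit well below the background z distribution and that
the reported domains cover the embedded elements.  (Windows that clip a
hairpin — holding one stem arm only — cannot fold it and behave like
background; they are not informative about recovery.)

What the generator does *not* emulate: real genomes are not i.i.d. —
they have repeats, skewed and autocorrelated composition, imperfect and
nested structural elements, and strand-asymmetric features.  Passing the
fixture tests shows the machinery is correct and sensitive to planted
signal under a clean null; it does not certify calibration of the
z-score on real chromatin-derived sequence, where the mononucleotide
null is known to be permissive (the dinucleotide option exists for
exactly that concern).

## Problem sizes used in the checks

The test-suite and the acceptance script keep deliberately modest
problem sizes: enumeration cross-checks use 200+ random sequences of
8–18 nt (where exhaustive enumeration is cheap and exact), calibration
uses 500 independent 120-nt windows, and the recovery study uses one
100-kb chromosome scanned forward-strand with 30 shuffles per window —
about 2,500 windows and 77,000 folds — which a single CPU completes in
about a minute with the default engine.

## Limitations

* Pseudoknots, coaxial stacking, dangling ends and SHAPE-directed
  folding are out of scope; the built-in models are not a substitute for
  full Turner-parameter engines when absolute energies matter.
* The z-score measures unusual stability given composition, not
  function; positive-z (structure-avoiding) regions and conserved but
  marginally stable structures need other tools.
* Published genome-wide values depend on the exact engine build and
  options used to produce them; with the adapter engine this package
  reproduces the procedure, while exact numeric reproduction requires
  matching those settings.

## A worked micro-example

```{r example}
fa <- tibble::tibble(name = "toy", sequence = strrep("GGGAAACCCAU", 20))
mets <- scan_sequences(fa, scan_config(window = 60, step = 20, seed = 7,
                                       strands = "forward"))
select(mets, start, end, mfe, zscore, pvalue, ed, fmfe)
```

The tandem GGGAAACCC repeats are an extreme of *ordered* complementarity:
every window pairs heavily (low MFE), shuffling destroys the G-run/C-run
register, and the z-scores are strongly negative — while the high ED
shows the many near-equivalent ways the repeats can pair with each
other.  A window can equally have a very low MFE with a mediocre z when
composition (e.g. GC content) rather than order drives the stability;
that distinction is exactly what the z-score adds over the raw MFE.

```{r domains}
report <- merge_domains(mets, sigma_multiplier = 0.5)
glance(report)
tidy(report)
```
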