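---
title: "Piecewise logistic primer scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise logistic primer scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrscore)
```

## The scoring model

Classical primer-design tools filter candidates against hard parameter
windows and fail outright when no candidate survives.  `pcrscore` instead
*scores* every feature on a continuous scale and always returns the
highest-scoring pairs.  Each feature $x$ is scored with a piecewise logistic
curve defined by six numbers $(MinO, MaxO, Min, Max, MinL, MaxL)$:

$$
f(x) = \begin{cases}
\dfrac{L}{1 + e^{-k (x - x_0)}} - y_0, & x \le MinO\\[4pt]
1, & MinO < x \le MaxO\\[4pt]
\dfrac{L'}{1 + e^{-k' (x - x_0')}} - y_0', & x > MaxO
\end{cases}
$$

with $k = 10/(MinO - MinL)$, $x_0 = (MinO + MinL)/2$,
$y_0 = e^{k(Min - x_0)}$, $L = 1 + y_0$, and the primed constants defined the
same way from $MaxO$, $Max$, $MaxL$.  The curve is 1 on the optimal range,
crosses 0 exactly at $Min$ and $Max$ (an algebraic identity:
$e^{-k(Min-x_0)} = 1/y_0$, so $f(Min) = (1+y_0)/(1+1/y_0) - y_0 = 0$), and
saturates towards $-y_0$ beyond the limits.  Scores are deliberately *not*
clamped below the limits: the logistic is already monotone and bounded, and a
negative score is how a disqualifying feature drags a candidate down without
ever producing a hard failure.

Three boundary conventions matter numerically:

* **Degenerate branches.**  Several parameter sets intentionally set
  $MinO = MinL$ (or $MaxO = MaxL$), e.g. self-complementarity
  $(-50, 45, -50, 50, -50, 55)$, where low values should carry no penalty.
  The slope $k$ would divide by zero there; the branch is treated as disabled
  and scores 1 on its whole side.
* **The value at $MinO$.**  As written, $x = MinO$ belongs to the left
  logistic, so for the GC model $(0.55, 0.6, 0.45, 0.65, 0.3, 0.7)$ we have
  $f(0.55) \approx 0.97511$, not 1.  The jump below the full score at
  $MinO$ is $(1+y_0)\,e^{-5}/(1+e^{-5})$, about 1.3% of the curve height.
* **Point optima.**  The 3'-adenine model $(1, 1, 0, 4, -1, 7)$ has
  $MinO = MaxO = 1$: its optimal "range" $(1, 1]$ is empty as written, which
  would make the full score unattainable for any primer and contradict the
  contract that an all-optimal primer scores exactly 100.  A point optimum
  therefore includes its single point: $x = MinO$ scores 1 when
  $MinO = MaxO$, while extended ranges keep the literal open-left behavior.

```{r}
gc <- model_params(0.55, 0.6, 0.45, 0.65, 0.3, 0.7)
piecewise_score(c(0.45, 0.55, 0.575, 0.65, 0.70), gc)
```

## Single-primer features

Seven features are evaluated per candidate (`extract_features()`), each with
its default model (`feature_models()`):

| feature | meaning | default $(MinO, MaxO, Min, Max, MinL, MaxL)$ |
|---|---|---|
| `tm` | nearest-neighbor melting temperature, °C | $(T, T{+}1, T{-}2, T{+}5, T{-}5, T{+}10)$, $T$ = user optimum |
| `gc` | GC fraction | $(0.55, 0.6, 0.45, 0.65, 0.3, 0.7)$ |
| `self` | best self-dimer/hairpin Tm, °C | $(-50, 45, -50, 50, -50, 55)$ |
| `end_a` | 3'-terminal adenine run length | $(1, 1, 0, 4, -1, 7)$ |
| `end_dg` | 3'-terminal 5-base stack ΔG, kcal/mol | $(-9, -7, -12, -6, -14, -5)$ |

SNPs and homopolymer runs ("polys") are not scored one curve each but through
a composite penalty over all sites a primer covers,

$$F(\vec p, \vec l) = 1 - \sum_j a\,[f(p_j) + b]\, f(l_j),$$

where $p_j$ is the distance of site $j$ from the 3' end and $l_j$ its
length; $a = 4, b = 0.2$ for SNPs and $a = 2, b = 2$ for polys.  The shared
position model $(0, 0, 0, 10, 0, 10)$ penalizes 3'-proximal sites most (a
SNP under the extending 3' end is the worst case, hence distance 0 is the
*maximum* of the positional factor), and the length models
$(15, 100, -15, 100, -15, 100)$ (SNP) and $(15, 100, 0, 100, 0, 100)$ (poly)
grow the penalty with site length.  The composite is unbounded below, so a
primer sitting on a long indel can score far below zero — intended behavior
for ranking.

SNP positions come from a degenerate-masked reference
(`mask_reference()`): substitution variants are rewritten as IUPAC ambiguity
codes (reference + alternate alleles merged, multi-allelic records unioned),
so walking candidates over the masked sequence recovers covered SNPs by
parsing the degenerate letters.  Indels cannot be expressed that way; they
are annotated in a side-channel interval table covering
$\max(\mathrm{len}(REF), \mathrm{len}(ALT)) - 1$ bases after the anchor.

The weighted sum of the seven feature scores is the primer score; weights sum
to 100, so an all-optimal primer scores exactly 100.  The individual weights
are a package choice (only their sum is fixed by the scoring convention):
Tm 30, GC 15, Self 15, EnddG 15, SNP 15, poly 7, EndA 3 — Tm and GC carry
the most weight because they dominate amplification behavior, EndA the least.
All weights are configurable and validated.

## Thermodynamics

Melting temperatures use the unified SantaLucia (1998) nearest-neighbor
parameters with the two-state formula
$T_m = \Delta H / (\Delta S + R \ln(C/4))$, the entropy salt correction
$\Delta S + 0.368\,(N{-}1)\ln[\mathrm{Mon}^+]$, and divalent cations folded
into the effective monovalent concentration as
$120\sqrt{[\mathrm{divalent}] - [\mathrm{dNTP}]}$ (the convention of the
widely used oligo-Tm implementations).  Defaults: 50 nM oligo, 50 mM
monovalent, 1.5 mM divalent, 0.6 mM dNTP, all configurable via
`thermo_conditions()`.

Mismatched duplexes (binding sites, dimers) are handled with the
perfect-match table plus a fixed destabilization for any stack containing a
mismatched pair ($\Delta H = -2.0$ kcal/mol, $\Delta S = -6.0$ e.u. for the
whole stack).  This is a deliberate simplification: the package's contracts
are that a perfect-match duplex reproduces the oligo Tm exactly and that
adding mismatches never increases the bound Tm (both property-tested), not
equivalence with any particular external engine.  When no stable duplex
exists at all (e.g. poly-A against itself) the reported Tm is the floor
−273.15 °C, which scores as fully unstructured.  Hairpins are unimolecular:
no concentration term, stems of at least three pairs, and a flat loop
penalty of +3.5 kcal/mol expressed as entropy.  IUPAC-degenerate bases are
resolved to the least-stable allele for Tm purposes only; the degenerate
letter itself is consumed by the SNP feature.

## Specificity: binding sites, products, oEff

Primer specificity is evaluated by in-silico PCR rather than by alignment
scores.  An exact 7-mer index over both strands of the reference
(`build_seed_index()`) seeds ungapped full-length extensions
(`find_binding_sites()`); each alignment gets a bound efficiency

$$E = f(btm)\,\prod_j f(m_j)$$

from its duplex Tm ($f(btm)$: $(60, 100, 45, 100, 45, 100)$, right side
open) and its mismatch positions counted 1-based from the 3' end ($f(m)$:
$(25, 100, 0.95, 100, 0.95, 100)$).  The $MinL = 0.95$ choice makes a
3'-terminal mismatch worth $\approx 1.4\times 10^{-4}$ — a trace of product
is still made — which sits just above the default efficiency cutoff of
$10^{-4}$; with the 0-based convention the factor would be negative, which
is how the 1-based convention was fixed.  Sites below the cutoff are
dropped.  Detection contract: any full-length site sharing at least one
exact word with the primer and passing the cutoff is found, so a 20-mer
site with up to 7 substitutions (35%) is detectable whenever one exact
7-mer survives — and whenever the mismatched duplex still clears the
bound-Tm floor, which is a property of the site, not of the search.  A
pluggable `hits` argument accepts (ref, strand, start) triples from an
external aligner.

Products are pairs of sites in a legal geometry with efficiency
$E_{prod} = E_1 E_2 f(bdis)$, where $bdis$ depends on the orientation:

* **face-to-face** (generic/genotyping/ARMS): converging sites on opposite
  strands; $bdis$ is the product size, the inclusive span between the two
  5' ends; $f(bdis)$ has $MinL = 30$ by default.
* **back-to-back** (inverse): diverging sites; $bdis$ is the gap between
  the 5' ends — the spacer that is *not* amplified on the circularized
  molecule.
* **unidirectional** (anchored): both sites on one strand; $bdis$ is the
  Primer2 5' start minus the Primer1 3' end along the strand, negative for
  nested overlap.

Non-target products are enumerated with the task's own orientation geometry
and distance model throughout (one uniform rule rather than a special case
per task).  The sum of all non-target product efficiencies, oEff, is the
pair's specificity value, scored with $(0, 0, 0, 0.02, 0, 0.1)$: perfect
specificity (oEff 0) scores 1, oEff 0.02 scores 0, and oEff 0.1 scores
$\approx -19.94$, enough to sink any pair.

## Pair scoring and selection

Five relation features — Tmdiff, Lendiff, Pos (Primer1 3' end to target),
Dis ($bdis$ of the designed product) and oEff — are scored and weighted
(defaults oEff 50, Dis 25, Pos 15, Tmdiff 6, Lendiff 4; for tasks without a
target spot the Pos weight is redistributed proportionally).  The final
score composes Primer1, Primer2 and the relation 25/25/50.

Since oEff can only lower a pair's score, pairs are ranked by an upper bound
(oEff feature at its best score 1) and the off-target search is evaluated
lazily best-first until the top `n_return` true scores provably dominate
every unevaluated bound — a branch-and-bound whose result is identical to
exhaustive evaluation (oracle-tested).  Ties break deterministically:
smaller oEff, then $|bdis - $ optimal midpoint$|$, then primer ids — the tie
order is a package choice.  The top three pairs per target are returned by
default, and a region yielding fewer legal pairs returns as many as exist
with a structured warning; the only empty result is a region with *no*
geometrically legal pair.

Task geometries follow the preset table (`apply_preset()`), whose
four-number ranges $(MinO, MaxO, Min, Max)$ are extended to limits by the
same margin the built-in defaults use (20 bases for Dis, 0 for Pos):

* *generic* — face-to-face, Dis (120, 160, 80, 200);
* *sanger_genotyping* — face-to-face, Dis (530, 570, 500, 600),
  Pos (100, 150, 70, 300); the product must cover the target;
* *arms* — Primer1's 3'-terminal base sits on the variant, one primer per
  allele, Pos fixed at 0 (the all-zero Pos model is fully degenerate and
  scores 1); deliberate secondary mismatches near the 3' end are not added;
* *inverse* — back-to-back around the target; the target is placed
  downstream of Primer1's 3' end (Pos = target − 3'-end), so it lies inside
  the circular product while the diverging 5' ends delimit the unamplified
  spacer;
* *anchored* — unidirectional on the target's strand, outer primer placed by
  Pos, nested primer overlapping by a negative Dis (−15, −10, −30, −5);
* *full_covered* — the template is partitioned into equal-width half-open
  windows (count given directly or derived from a spacing by ceiling
  division) and each window is designed as a generic region.

Cross-dimers among the selected panel (all primers of the top pairs of
every target, all-vs-all including self) are reported above a 45 °C duplex
threshold — mirroring the Self model's optimum ceiling — with a flag for
3'-anchored duplexes; reporting only, no automatic re-selection.

## The synthetic fixture generator

`generate_fixture()` builds the test worlds: a seeded random reference with
(optionally) duplicated segments at controlled divergence — the mechanism
that creates predictable off-target binding sites and products — embedded
substitution SNPs for masking, inserted homopolymer runs, target spots, and
planted copies of a probe site carrying 0–7 substitutions.  Substitutions in
planted sites are clustered at the probe's 5' end so the 3'-proximal
stretch (and at least one exact 7-mer) stays intact; that stretch is built
with a fixed high GC count so even the most mismatched copy stays above the
bound-Tm floor.  Everything is reproducible byte-for-byte from the seed.

What the generator does *not* emulate: real genomic repeat families and
low-complexity landscapes, sequencing error, chromatin/amplification biases,
and genome-scale references.  Passing tests therefore demonstrate the
*algorithmic* contracts (exhaustive enumeration, oracle equivalence,
monotonicity, no-failure selection) — not calibrated accuracy of efficiency
predictions on real genomes, which requires wet-lab data.

## Problem sizes and numerical tolerances

The test-suite and acceptance runs use desk-scale inputs chosen to exercise
every code path while staying comfortably reproducible: references of
1.5–10 kb, regions of 150–300 bases, candidate grids of one or a few
lengths, 20 oracle-equivalence fixtures and 100 hostile templates of 160
bases.  Oracle equivalence is exact for site sets and mismatch lists and
within $10^{-9}$ for efficiencies; the algebraic anchors $f(Min) = f(Max) =
0$ hold within $10^{-9}$ over 1000 random parameter sets.  Scores are plain
double arithmetic throughout; the only guarded operations are the disabled
logistic branches and the Tm floor.

## Known limitations

* Mismatch thermodynamics use a single fixed stack penalty, not the full
  mismatch nearest-neighbor tables; bound Tms of heavily mismatched hybrids
  are ranked correctly but not chemically accurate.
* Binding sites are full primer length and ungapped; partial dangling
  alignments and bulged duplexes are out of scope.
* The product-size endpoint convention (inclusive span between 5' ends) is
  the package's definition; tools with off-by-one conventions will differ by
  one base.
* Multi-tube panel distribution and compatible-set selection are not
  attempted; cross-dimers are reported for manual resolution.
* Degenerate-base masking covers substitutions; indels ride in a
  side-channel interval table rather than the sequence itself.
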