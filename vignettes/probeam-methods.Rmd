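---
title: "Decoding fluorosequencing reads with a beam search over (N, K, R) states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding fluorosequencing reads with a beam search over (N, K, R) states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement process

Fluorosequencing reads a surface-anchored peptide one Edman cycle at a time.
Fluorophores are attached to selected residue types (for example one dye for
D/E, one for C, one for Y), and after every cycle the per-color light
intensity is recorded.  Removing a labeled residue drops the corresponding
color's intensity by roughly one fluorophore unit, so the intensity
trajectory encodes which colors sat where in the peptide.  The chemistry is
imperfect, and the model carries four failure modes, each with a single rate:

| parameter | default | meaning |
|-----------|---------|---------|
| `e`       | 0.06    | an Edman cycle fails, removing nothing |
| `l`       | 0.05    | a fluorophore bleaches/detaches between cycles |
| `m`       | 0.07    | a fluorophore never attached in the first place |
| `p_d`     | 0.05    | the whole peptide detaches, permanently dark |
| `mu`      | 1       | mean intensity of one fluorophore |
| `sigma`   | 0.16    | intensity standard deviation per fluorophore |
| `sigma_b` | 0.0067  | background noise standard deviation |

A read is an `n_colors` by `n_cycles + 1` matrix: one observation before the
first cycle, one after each cycle.  Emissions are Gaussian: with `K_i` dyes
attached, color `i` fluoresces at `Normal(K_i * mu, sqrt(K_i * sigma^2 +
sigma_b^2))` — variances of independent fluorophores and background add,
which is how the effective deviation is implemented throughout.

Because only dye positions are observable, peptides are grouped by their
*dye sequence*: each residue replaced by its color digit or `.`, trailing
dots trimmed (`DAREICIKS` with C/E on dye 0, K on 1, D on 2 becomes
`2..0.0.1`).  The classifier still answers at the peptide level, with a
uniform prior over the database; the dye-sequence prior is the summed prior
of the peptides that share it.

## The state space

The decoder's state is the triple `(N, K, R)`:

* `N` — how many not-yet-removed residues attach to each color,
* `K` — how many fluorophores are actually still attached (`K <= N`),
* `R` — the removed dye-sequence prefix.

`(N, R)` determine which database dye sequences are still compatible (the
consistency set eta: sequences starting with `R` whose remaining suffix has
counts `N`), and the peptide posterior within a state is just the prior
renormalized over that set — independent of the observation history.  That
factorization is what makes per-state (rather than per-peptide) weights
sufficient, and it is verified against the exact decoder in the tests.
A state with `K = 0` is absorbing: whether the peptide detached or merely
went dark, nothing observable ever changes again.

One cycle factors into three independent phenomena, composed in a fixed
order: detachment (probability `p_d`, zeroing `K`), per-fluorophore dye loss
(binomial with rate `l`), and Edman removal (success `1 - e`; the removed
symbol is drawn from the marginal next-symbol distribution of eta, and a
removed residue of color `i` carries its dye away with probability
`K_i / N_i`, by exchangeability of dye placements).

## The beam recursion

The exact forward recursion over all states is intractable at proteome
scale, so the decoder keeps only the `n_beam` highest-weight states per
cycle: propagate each kept state through the one-cycle transitions, merge
duplicate successors across predecessors (log-sum-exp), weight by the
Gaussian observation likelihood, renormalize, truncate.  With `n_beam`
large enough to hold every reachable state the recursion is exactly the
forward algorithm, and the reported posterior equals the exact one — the
test suite asserts agreement to within 1e-6 relative error on thousands of
simulated reads.  The default beam width is 60.

**Initial states.**  Before the first cycle the state distribution is
known in closed form: ideal states (one per distinct dye-count vector, with
the summed dye-sequence prior) thinned by the binomial dye-miss
distribution.  The top-`n_beam` initial states under the first observation
are found without scoring the whole lattice: ideal states are ordered by
`||x_0/mu - N||`, and for each a breadth-first search expands deviations
from the bounded per-color density optimum `K^opt`.  Because the per-color
density is unimodal in `K_i`, the prior-times-observation bound (which
drops the dye-miss factor) can only decrease away from `K^opt`, so a node
whose bound falls below the current threshold is skipped together with
everything beyond it — a pure pruning of provably dominated nodes.  The
search provably returns the same set as exhaustive enumeration, and a
200-instance randomized test checks exactly that.  Optimizations beyond
this (tighter miss-aware bounds, discarding neighbors of skipped nodes,
smarter seeds) are deliberately not implemented.

**Pruning.**  Following the pruned-forward practice this decoder adopts, a
successor state is discarded when any color's observation deviates from
`K_i * mu` by more than `h = 5` effective standard deviations (boundary
inclusive).  The test is applied to the composed post-Edman successors —
the states about to be scored with `x_t` — not to the intermediate
post-dye-loss counts.  Applying it mid-composition would discard the
surviving path every time Edman removes a color's last dye
(`mu / sigma_eff(1) = 6.25 > 5` at the defaults), and in our measurements
that costs roughly half the achievable accuracy; scored-state pruning is
benign (a true state fails it with probability around `1e-6` per color).
Pruned mass is dropped, not renormalized; renormalization happens only at
the beam level.  A read whose successors are all pruned is flagged
undecodable rather than force-predicted.

**Numerics.**  All accumulation across cycles is in log space with
log-sum-exp merges (a density product over ten cells easily underflows);
within one transition step the linear products are safe.  Ties — equal beam
weights at the truncation boundary, equal initial scores, equal posterior
maxima — break on the canonical state key (`R|N|K` serialized) or the
smallest peptide id, so decoding is bit-reproducible run to run.

## The simulator and the exact oracle

`simulate_reads()` draws a peptide uniformly, applies dye miss once, then
per cycle detachment, dye loss and Edman removal in exactly the decoder's
event order, emitting Gaussian intensities after each stage.  Reads that
start with no attached dye are dropped and counted, not regenerated,
mirroring the dataset-filtering convention; detached or dark reads keep
emitting background noise.  The simulator is deliberately matched to the
decoder's model: passing tests demonstrate correctness of the inference
machinery, not robustness to model mismatch (real data adds effects —
non-Gaussian noise, position-dependent rates, partial quenching — that this
generator does not emulate).

`decode_map_exact()` is the verification oracle: for each dye sequence it
enumerates every hidden outcome (which dyes attached; per cycle detachment,
each dye-loss subset, Edman success or failure) tracking per-residue dye
presence exactly, collapses outcomes into distinct attached-count histories,
and sums probability-weighted Gaussian density products.  It shares no code
with the beam decoder — no (N, K, R) states, no compiled transitions — and
is exact but exponential, guarded by a trajectory cap that asks for a
smaller instance instead of silently approximating.

## Evaluation choices

Accuracy is reported with a standard error estimated from ten contiguous
equal splits of the read set.  The precision-recall sweep denominates recall
by all reads (not by predictions above threshold).  Calibration tables bin
predictions by posterior into equal-width bins and compare the mean
posterior against the empirical accuracy; on simulated data decoded by the
exact oracle the two agree within binomial noise, which is the desk-scale
analogue of posterior-calibration checks on proteome-scale runs.

## Problem sizes used in the tests

The test suite exercises desk-scale instances chosen so the exact oracle
stays cheap while every code path is hit: a 20-peptide two-color database
(random 6–12-mers labeled on D/E and C/Y, seed 1), 2,000 reads at 4 cycles
for the beam-vs-exact comparison, and 10,000 reads at 5 cycles for the
accuracy-vs-beam-width and calibration studies.  At this scale roughly a
fifth of reads lose their signal before the distinguishing cycle, leaving
structurally tied peptide pairs; that keeps absolute accuracies around
0.67–0.69 and makes tie handling an explicitly tested behavior.  Conclusions
about proteome-scale accuracy or runtime are out of scope here.

## Known limitations

* Rates are shared across colors; color-specific parameters would be a
  mechanical extension but are untested.
* The prior is uniform over peptides; abundance-weighted priors are a
  config hook only.
* Tryptic digestion uses the common convention (cleave after K/R, not
  before P, zero missed cleavages); other conventions require pre-digested
  peptide lists.
* No protein-level inference, no within-read parallelism, no transition
  caching.
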