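---
title: "Probabilistic screening of G-quadruplex motifs: models and methods"
author: "g4hmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic screening of G-quadruplex motifs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4hmm)
```

## The problem

A DNA G-quadruplex (G4) forms in guanine-rich sequence: four tracts of
consecutive guanines (*G-runs*) donate one strand each to a stack of
hydrogen-bonded G-quartets, and the three intervening stretches (*loops*)
connect them. At the sequence level the motif is the regular expression
`G+N*G+N*G+N*G+`. Regex scanning finds enormous numbers of such motifs in
mammalian genomes, but most matches are unlikely to fold: the pattern says
nothing about how probable a particular arrangement of run and loop lengths
is. `g4hmm` puts a probability model behind the pattern, so candidate motifs
can be *scored* and *screened* rather than merely matched.

## The four hidden Markov models

Each model is a left-to-right HMM over `{A,C,G,T}` with silent `begin` and
`end` states and four G-run blocks alternating with three loop blocks. The
models differ in how finely they resolve run and loop lengths:

| model | G-states per run | loop block | minimum emission |
|-------|------------------|------------|------------------|
| 1 | 2 | one self-looping state, bypass allowed | 8 |
| 2 | 4 | as model 1 | 16 |
| 3 | 2 | chain of 3/4/3 skippable states | 8 |
| 4 | 4 | chain of 3/4/3 skippable states | 16 |

Within a run block the G-states form a chain whose **last** state carries a
self-loop: "at least *r* Gs" semantics, where *r* is 2 (models 1, 3) or 4
(models 2, 4). Each loop block can be bypassed entirely (empty loops occur in
real G4 forms), entered at any of its states, and exited from any of them;
the last loop state self-loops so arbitrarily long loops remain reachable.

Two design points deserve emphasis, because the published figures the
topologies descend from are not textually specified:

* **Edge sets are a reconstruction.** The captions fix the state counts
  ("two hidden states per G-run", "increase to four", "three or four in
  turn") but not every arrow. We adopt chain-with-terminal-self-loop runs
  and skippable loop chains (3, 4, 3 states for loops 1–3, reading the
  alternation in order), and expose the alternatives: `rigid_runs = TRUE`
  removes run self-loops, and `loop_states =` changes the per-loop chain
  lengths.
* **Minimum run length is structural.** Under models 2 and 4 a sequence
  whose four longest G-runs are not all ≥ 4 admits *no* path and scores
  `-Inf`. This is deliberate and is handled as a flagged value everywhere
  (annotation returns an explicit unannotatable result; log-odds is `-Inf`;
  Z-scoring excludes such scores from the mean/SD and the lower screening
  cutoff always removes them). It also means the 4-G-state topologies are
  only meaningful for candidate sets whose runs reach length 4.

G-state emissions are initialized at `P(G) = 0.9` and are trainable, so the
data decide how strict a G-run is; `clamp_g = TRUE` pins `P(G) = 1` as a
structural zero. There are no flank states: training sequences are exact G4
forms.

## Algorithms

Decoding, likelihood and training are the three classical HMM dynamic
programs, all `O(m^2 n)` and all implemented in compiled code, in log space
with log-sum-exp — probability-space recursions underflow on genome-scale
inputs:

* `hmm_viterbi()` returns the most probable state path; ties are broken
  deterministically toward the lowest state index.
* `hmm_forward()` / `hmm_backward()` return `log P(x | θ)`; the two
  recursions agree to ~1e-15 and the identity is tested exhaustively
  against brute-force path enumeration on small random instances.
* `baum_welch()` re-estimates parameters by expectation-maximization.
  Defaults: convergence when the total log-likelihood improves by less than
  `1e-4`, at most 500 iterations, pseudocount `1e-3` added to every
  *allowed* expected count before normalization. Structural zeros are never
  touched, so the topology survives training. With a positive pseudocount
  the update is a lightly smoothed (MAP-style) M-step; the data
  log-likelihood is monotone up to a perturbation far below the `1e-8`
  slack the tests allow. Training sequences with no admissible path are
  excluded with a warning naming them (or are fatal with
  `on_no_path = "error"`).

Initialization is uniform over the allowed edges of the topology with
G-state emissions at 0.9 — enough asymmetry to break the run/loop symmetry
without biasing transitions.

## Scoring and screening

Raw log-likelihoods are strongly length-dependent, so sequences are scored
by log-odds against an i.i.d. background:

$$L(x) = \log \frac{P(x \mid \theta)}{\prod_i q_{x_i}}$$

with `q` the pooled base frequencies of the training sequences
(pseudocount 1). Scores are then standardized over an explicit collection —
validation sequences, all motifs of a database, all motifs of a genome scan,
never the training set:

$$Z_x = \frac{L(x) - \bar L}{s}.$$

**Standard-deviation convention.** Whether `s` uses the population (n) or
sample (n−1) denominator is an empirical question here: recomputing the
packaged 50-gene density table under both conventions and comparing with its
published reference Z-scores decides it. The sample convention reproduces
all 50 printed values to three decimals; the population convention misses by
up to 0.028. Sample SD is therefore the package default throughout
(`sd_type = "population"` remains available).

Screening uses exact normal quantiles, `qnorm(0.05) ≈ −1.645` and
`qnorm(0.95) ≈ +1.645` (displayed rounded to 3 decimals): `lower` mode cuts
the improbable left tail, `upper` mode retains only significantly
high-scoring candidates, `two-sided` cuts both tails.

## The regex prefilter

`scan_g4()` finds leftmost non-overlapping matches of
`G{3,5}[ACGT]{1,7}…G{3,5}` (run lengths 3–5, loop lengths 1–7 by default,
the convention of most pattern-matching G4 screens; `preset = "stegle"`
gives the fully generic `G+N*G+N*G+N*G+`). Choices the pattern alone does
not fix:

* **Non-overlap policy**: leftmost-first, resume after the match end —
  ordinary regex-engine semantics, and what the tests' independent
  backtracking oracle implements.
* **Run/loop ambiguity**: consecutive Gs can stretch over a run/loop
  border. Greedy quantifiers resolve this deterministically (runs absorb
  as many Gs as the bounds allow); `greedy_runs = FALSE` flips to lazy
  runs.
* **Strands**: forward only by default; `strands = "both"` also scans the
  reverse complement and reports minus-strand motifs in forward
  coordinates.
* **N and case**: `N` never matches a run, may sit in loops only with
  `allow_n = TRUE`; soft-masked lowercase is uppercased.

Coordinates are 0-based half-open everywhere internally and in BED output;
only human-readable logs are 1-based.

## Trinucleotide shuffling

Negative controls preserve overlapping 3-mer composition (and therefore GGG
content — the feature that stabilizes quadruplexes) while destroying the
four-run architecture. `trinucleotide_shuffle()` implements the
Altschul–Erickson doublet-shuffle generalized to order 2: vertices are
overlapping dinucleotides, trinucleotides are edges, and a random Eulerian
path from the first to the last dinucleotide is drawn by rejection-sampling
a uniform last-edge arborescence and permuting the remaining edges. Draws
are uniform over the shuffle space (verified by chi-square against an
exhaustively enumerated space), conserve the 3-mer multiset exactly, and fix
the terminal dinucleotides. A non-overlapping codon permutation
(`codon_shuffle()`) is provided only as a clearly non-default comparison.

## Evaluation

Per-base G-run prediction is scored by pooled (micro-averaged) counts over
all sequences — a G is a TP when both truth and prediction place it in a
run — giving `SEN = TP/(TP+FN)`, `PPV = TP/(TP+FP)` and the F-measure;
undefined ratios are `NaN` with a flag, never silently zero. Display
rounding is 3 decimals. `cross_validate()` does sequence-level k-fold splits
(default 10, unstratified, seeded), trains each fold by Baum-Welch and
Viterbi-annotates the held-out fold. `roc_auc()` sweeps thresholds over the
unique scores with ties grouped, so its trapezoidal AUC equals the
Mann–Whitney statistic; `-Inf` scores (structurally unscorable sequences)
are legitimate and rank below everything.

Per-gene screening uses G4 density `D(X) = G(X)/|X|` (motif count over gene
length in nt), standardized across all genes of a set; genes with
`Z(D) ≥ qnorm(0.95)` are flagged as significantly G4-dense — the symmetric
upper-tail analog of the −1.645 lower screening cutoff, since the original
tables bold their significant genes without printing the rule.

## Synthetic data: what it emulates and what it does not

The generator (`g4_spec()` / `make_g4_set()`) draws exact G4 forms with run
lengths 2–5 and loop lengths 0–7 (uniform weights), loop base composition
A/C/G/T = 0.3/0.3/0.1/0.3. Loops are G-depleted, and the first and last base
of every non-empty loop is non-G, so the generating segmentation is
unambiguous ground truth; `hard = TRUE` raises loop G content to stress the
run/loop boundary ambiguity instead. `make_genome()` plants such motifs in a
background whose G-runs are capped below the scan minimum, with non-G bases
flanking every insertion and G-free loops inside planted motifs — so the
planted BED truth is exact by construction rather than by re-scanning.

Synthetic data emulate the *form* of experimentally verified G4 sequences,
not their biology: there is no thermodynamic stability signal, no salt
dependence, no chromatin context, no length/GC structure of real genes, and
the loop composition is an idealization. Passing tests therefore demonstrate
algorithmic correctness and internal consistency, not predictive performance
on real genomes.

### Experiment design choices worth stating

* **Discrimination test (AUC > 0.9).** Positives for the model-2
  discrimination experiment are drawn with run lengths 4–5. Under the full
  default support 2–5 only ~6% of draws are even admissible under the
  4-G-state topology, and the AUC would measure admissibility rather than
  ranking. The generator defaults themselves are unchanged.
* **Parameter recovery (±0.05 on transitions at n = 200).** The known truth
  is chosen so every transition parameter is strongly identified: clamped G
  emissions, G-free loops, no empty loops (an empty loop merges two runs
  into one G-block whose split between blocks is inherently ambiguous), and
  self-loop probabilities of 0.8 so each free parameter sees ≥ 1000
  effective trials (±0.05 ≈ 4 SE). With a weakly identified truth the
  maximum-likelihood estimate itself — not the EM implementation — misses
  the band; with this design the EM fit coincides with the empirical
  generating-path frequencies to ~1e-6.
* **Why shuffles are hard for chain topologies.** A trinucleotide shuffle
  conserves dinucleotide counts, hence (almost) the number of G-blocks; and
  under a chain-with-self-loop run block, any shuffle that keeps four
  blocks above the minimum has *exactly* the same likelihood as the
  original (self-loop event counts depend only on totals). Discrimination
  by these models is therefore driven by shuffles pushing some block below
  the minimum run length — which is why the tight-run parameterizations
  separate well and diffuse ones do not, and why a 2-G-state topology (a
  probabilistic regex) discriminates poorly.

## Numerical choices and degenerate inputs

* All DP in log space; `-Inf` is a first-class value meaning "structurally
  impossible", distinguished from errors (bad alphabet, malformed input).
* Viterbi ties: lowest state index, documented and tested.
* Z-scoring requires ≥ 2 finite scores and positive variance; degenerate
  collections are errors naming the problem, and non-finite scores are
  excluded from the moments with a warning.
* Empty FASTA files are warnings with empty results; duplicate FASTA ids,
  inverted scan bounds, and unknown model ids are errors.
* Model JSON is written with 17 significant digits so parameters round-trip
  bit-exactly.
* Problem sizes in the test-suite simulations (200 enumeration instances,
  200 recovery sequences, 1000 shuffles, 1000 scanner strings, a 1 Mb
  planted genome, 10^5 screening draws) were chosen to make each check
  statistically decisive while keeping the whole suite comfortably fast on
  one CPU.

## Known limitations

* The figure-derived edge sets are a documented reconstruction, not the
  authors' graphs; alternative readings are configuration, not forks.
* Models 2/4 cannot score candidates whose runs never reach 4 Gs; combining
  the default 3–5 prefilter with model 2 therefore screens out all
  3-run-only motifs structurally (they are reported with `Z = -Inf`).
* Run-length distributions inside a block are shifted-geometric by
  construction; sharply peaked empirical length distributions can only be
  approximated.
* No bulged or imperfect quadruplexes, no RNA G4s, no two- vs
  three-quartet distinction, no thermodynamic scoring.
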