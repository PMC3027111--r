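---
title: "N-gram language models and composition signatures for whole proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{N-gram language models and composition signatures for whole proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteolm)
library(dplyr)
```

## The idea

Treat a whole proteome as a text and its amino-acid n-grams as words. Two
organisms that diverged recently still "write" similarly: they use the same
short peptide words at similar rates. `proteolm` turns that intuition into
three quantitative instruments:

1. **Comparative Zipf-like profiles.** Rank n-grams by their percentage
   frequency in a chosen reference organism and read every other organism's
   frequencies off in that fixed order. Organism-specific spikes and gaps —
   n-grams frequent in the reference but rare or absent elsewhere — are
   *proteome signatures*.
2. **Count-ratio language models and perplexity.** Train an order-`n` model
   on a reference proteome and score any test proteome by its
   cross-entropy,
   $$E = -\frac{1}{N}\sum_j C_{\text{test}}(g_j)\,
        \log_2 \frac{C_{\text{train}}(g_j)}{C_{\text{train}}(g_j^{(n-1)})},$$
   where $C(g)$ are raw counts, $g^{(n-1)}$ is the n-gram's length-$(n-1)$
   prefix, and $N$ is the test proteome's n-gram token count. Perplexity
   $B = 2^E$ is the model's average branching factor on that proteome:
   1 for a perfectly predictable text, $|A|$ for a random one, and — the
   headline property — increasing with evolutionary distance from the
   reference within a genus.
3. **Unigram taxonomy classifiers.** Single-predictor multinomial logistic
   regression of genus/class/phylum on one amino-acid frequency (or the
   first principal component of all twenty), cross-validated.

Every instrument is exercised end-to-end against a synthetic proteome
generator with a known taxonomy and known divergence structure, so the
package's claims are parameter-recovery statements, not anecdotes.

## Counting rules

- Windows slide within each protein independently; they never span protein
  boundaries (a junction bigram between two concatenated proteins is a
  bookkeeping artifact, not a peptide). A protein of length $L \ge n$
  contributes $L - n + 1$ windows.
- Sequences are uppercased at parse time; gaps (`-`, `.`) and stops (`*`)
  are removed. Non-canonical residue codes survive parsing and are handled
  at counting time by an `alphabet_policy()`: `drop_ngram` (default) skips
  any window touching a symbol outside the 20-letter alphabet, keeping the
  vocabulary at $|A|^n$; `map_to_nearest` rewrites B→D, Z→E, J→L, U→C,
  O→K first; `keep` counts verbatim. The skipped-window count is retained
  as a diagnostic.
- Frequencies are reported as percentages of the per-organism token total;
  raw counts are always kept because the language model needs counts, not
  percentages.

## The language model and its one free choice: smoothing

The count-ratio conditional $C_{\text{train}}(g)/C_{\text{train}}(g^{(n-1)})$
is undefined for n-grams absent from training — a certainty for 4-grams
across divergent proteomes ($20^4 = 160{,}000$ types against a few hundred
thousand tokens). Unseen events must receive probability, and the choice is
consequential:

- Default: **add-alpha** with $\alpha = 1$ pseudo-count per continuation,
  $q = (C_g + \alpha)/(C_{ctx} + \alpha|A|)$; a test n-gram whose context
  never occurs in training backs off to the add-alpha-smoothed unigram
  probability of its final residue.
- Alternative: a fixed probability floor (`floor_prob`).

Because published absolute perplexities from other implementations depend
on their (typically undocumented) unseen-event handling, absolute values
are not comparable across implementations. What is robust — and what the
acceptance suite tests — is *ordering*: self-perplexity below
cross-perplexity, and cross-perplexity increasing with divergence. One of
the acceptance checks demonstrates this directly by showing the absolute
value move materially between $\alpha = 1$ and $\alpha = 10^{-4}$ while
the orderings stay put.

Two boundary details are deliberate:

- $(n-1)$-gram counts are counted directly from the text rather than
  derived by marginalizing n-gram counts. A context that ends a protein
  therefore has one occurrence with no continuation, and smoothed
  conditionals for such contexts sum to slightly less than 1 (deficit at
  most one per protein per context). Boundary-free contexts normalize to
  1 within 1e-9; the tests check both.
- Entropy is normalized by the test n-gram *token* count, not the residue
  count, and logs are base 2 throughout, so $B = 2^E$.

`uniform_lm()` constructs the analytic limit: all counts zero under
add-alpha smoothing, so every conditional is exactly $1/|A|$ and any text
scores perplexity exactly $|A|$ — a useful calibration point (4 for
nucleotides, 20 for amino acids).

## The synthetic world

`generate_collection()` samples one proteome per species from a Markov
chain over the 20-letter alphabet, with a balanced
phylum → class → genus → species taxonomy. Its parameters and what they
emulate:

- **Root composition** (`reference_aa_freqs()`): database-wide amino-acid
  frequencies — L, A, G common; W, C rare — so unigram rank-frequency
  plots have the right shape.
- **Root heterogeneity** (`root_heterogeneity`, default 1.0): seeded
  lognormal noise applied once per collection to the root conditional
  table and shared by every taxon. This models the universal structure of
  protein sequences — some short peptides are intrinsically common and
  some rare in *all* organisms — and produces the steep shared top-40
  rank-frequency profile real proteomes show (roughly a factor 2–3 across
  the top 40 at order 3). Without it, a compositional chain is nearly
  i.i.d., its top-40 profile is flat, and top-40 correlations between any
  two organisms are pure counting noise — a world in which the
  correlation analysis would be meaningless. Set it to 0 when planted
  signatures must be the *only* taxon-specific n-gram structure.
- **Hierarchical divergence** (`sigma_phylum ≥ sigma_class ≥ sigma_genus ≥
  sigma_species`): moving one level down perturbs every conditional
  log-probability with Gaussian noise of the level's sigma, split evenly
  between a compositional component (one multiplier per residue, shared
  across contexts, so unigram marginals shift) and a context-specific
  component. Explicit per-species branch lengths are interpreted as
  Brownian-motion variances on the logit scale (perturbation sd
  $\sqrt{d}$), the standard evolutionary null model, making expected
  divergence of n-gram usage linear in branch length.
- **Topology** (`species_topology`): `"star"` makes congeners
  exchangeable perturbations of the genus model; `"chain"` places them on
  a single lineage. The distinction matters more than it looks: expected
  cross-entropy is *linear* in the test distribution, so perturbing test
  organisms symmetrically around the model's own distribution changes
  cross-entropy only at second order — a star around the reference shows
  almost no divergence signal. The signal the real data shows comes from
  *shared ancestry*: organisms closer to the reference share more of the
  reference lineage's accumulated quirks, which is what the model's
  probabilities encode. `ladder_spec()` therefore builds the divergence
  ladder as a chain ending at the reference, so a species at distance
  $d$ is the reference's ancestor state $d$ back along its own lineage.
  (Private terminal branches of the test species would add only the
  second-order term, so omitting them keeps distances exact and loses
  essentially nothing.)
- **Scale**: protein counts uniform in `protein_count_range` (default
  1,800–2,200) and lognormal lengths with mean ~300 residues — realistic
  microbial proteome shape. Tests and acceptance experiments use smaller
  explicit counts (300–2,000 proteins per species) to stay within a desk
  budget; each experiment states its size.

Ground-truth branch distance (recorded per species in the taxonomy table)
is the cumulative Brownian variance along the taxonomy path to the
designated reference — the quantity the divergence-recovery experiments
correlate against.

### What a green test does and does not establish

The generator instantiates exactly the statistical structure the analysis
assumes: taxon-specific n-gram usage diverging with distance on a shared
universal profile. Recovery on this world validates the pipeline's
machinery (counting, ranking, entropy arithmetic, correlation and
classification bookkeeping) and the *direction* of its inferences. It does
not certify behavior on real proteomes, which have domain structure,
repeats, horizontal transfer, and G+C-driven compositional trends the
generator deliberately omits.

## Experiment design choices (fixed a priori)

- **Signature planting** boosts the conditional probability of each
  planted 4-gram's final residue given its 3-residue context by the boost
  factor (renormalized). A conditional boost can only make an n-gram a
  top-40 signature if its context is common, so planted grams pair
  frequent contexts with rare final residues — mirroring how real
  signature 4-grams combine common and rare residues. The recovery world
  uses a single class whose internal sigmas all equal the genus sigma:
  with one phylum and one class, larger phylum/class sigmas would add
  only nuisance compositional drift that plays no comparative role.
- **Signature rule** (the original analysis is visual): an n-gram in the
  reference's top-k is flagged when the median of its frequency across
  comparison organisms falls below 10% of the reference frequency. Both
  knobs are arguments.
- **Correlation ceiling**: at desk-scale proteomes the top-40 frequency
  estimates carry 8–15% Poisson noise against a factor ~2 true spread, so
  within-genus correlations plateau near 0.85–0.9 even at negligible
  divergence; approaching 1.0 requires token counts growing with the
  inverse square of the tolerance. The acceptance check asserts the
  ordering and the rise toward 1 as species divergence shrinks, not an
  asymptote the finite world cannot reach.
- **Classifier worlds**: the separated-classes check uses an order-0
  (i.i.d. residue) generator with large class sigmas, so class membership
  is encoded in composition alone and a single well-chosen unigram should
  suffice; the null check shuffles labels and expects chance accuracy
  within three standard errors over 20 seeds.
- **Multinomial logistic regression** is fit by BFGS on the
  ridge-penalized multinomial likelihood (analytic gradient, predictors
  standardized internally, default ridge $10^{-6}$ as a
  perfect-separation guard — single-feature models on small genera
  separate easily, and unbounded coefficients break determinism). The
  two-category special case is cross-checked against `stats::glm` in the
  tests. Baseline category: the most frequent label (predictions are
  baseline-invariant; only coefficient reporting depends on it).
- **Fold assignment** is stratified by label and seeded; folds whose
  training set collapses to one category are skipped with a warning.
- **Tie-breaking** in all rankings: descending frequency, then
  lexicographic n-gram order, for bit-reproducible outputs.
- **Pipeline configuration** is JSON (`run_config()`), the one key-value
  format with a parser available everywhere this package runs; all
  outputs are TSV with a `# seed:` header line plus a JSON run manifest.

## Known limitations

- Absolute perplexities are smoothing-dependent (see above); compare
  orderings, not values, across implementations.
- The generator does not simulate codon-level effects, G+C content, gene
  gain/loss, or repeat expansion.
- Zipf-profile and correlation analyses condition on the reference's
  *observed* top-k, so selection noise at small proteome sizes biases
  comparison frequencies downward (regression to the mean); the tests use
  proteome sizes where this is second-order, but beware of very small
  collections.
- `n = 1` language models are context-free by construction; `n ≥ 5`
  works but needs token counts well beyond typical single microbial
  proteomes to be informative.

## A minimal session

```{r example, eval = FALSE}
coll <- generate_collection(
  ladder_spec(divergences = c(0.01, 0.05, 0.1, 0.2, 0.3), seed = 1),
  generator_model(order = 3, protein_count_range = c(400, 400)))

model <- ngram_lm(
  dplyr::filter(coll$proteins, organism_id == coll$reference_id), n = 4)
scan <- perplexity_scan(model, coll$proteins, coll$taxonomy)
divergence_report(scan)$correlations

freqs <- to_frequencies(count_ngrams(coll$proteins, 4))
profile <- build_rank_profile(freqs, coll$reference_id, k = 40)
extract_signatures(profile)
```
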