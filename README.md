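# proteolm

Alignment-free comparison of whole proteomes through amino-acid n-gram
statistics, for microbiologists and molecular evolution researchers who
want proteome-scale similarity measures without building alignments or
trees first.

A proteome is treated as a text over the 20-letter amino-acid alphabet.
The package provides:

- **n-gram counting** per proteome (windows never cross protein
  boundaries; configurable handling of non-canonical residues), with
  percentage-frequency tables;
- **comparative Zipf-like profiles**: n-grams ranked by a reference
  organism's frequencies, all other organisms projected onto that fixed
  order, and *signature* n-grams — frequent in the reference, rare
  elsewhere — extracted by an explicit rule;
- **count-ratio n-gram language models**: for a reference proteome, the
  conditional probability of each n-gram is the smoothed ratio of its
  training count to its (n−1)-gram prefix count. A test proteome's
  cross-entropy is

  ```
  E = -(1/N) * sum_j C_test(g_j) * log2( C_train(g_j) / C_train(g_j^(n-1)) )
  ```

  and its perplexity `B = 2^E` — the model's average branching factor on
  that proteome. Self-perplexity sits below cross-perplexity, and within
  a genus cross-perplexity tracks branch distance from the reference;
- **unigram taxonomy classifiers**: single-predictor multinomial logistic
  regression (one amino-acid frequency, or PC1 of all twenty) for
  genus/class/phylum, with stratified 10-fold cross-validation;
- a **synthetic proteome generator** with a known taxonomy and known
  branch distances (hierarchical logit-normal perturbations of a Markov
  chain), so every claim above is testable as parameter recovery;
- a **pipeline driver** (`run_pipeline()`) wiring all stages from a JSON
  config into a directory of TSVs plus a run manifest.

## Worked example: recovering a divergence ladder

Simulate one genus whose species lie on a single lineage at distances
0.01–0.3 from a reference species, train a 4-gram model on the reference,
and scan everyone:

```r
library(proteolm)
library(dplyr)

coll <- generate_collection(
  ladder_spec(divergences = c(0.01, 0.05, 0.1, 0.2, 0.3), seed = 1),
  generator_model(order = 3, protein_count_range = c(400, 400)))

model <- ngram_lm(
  filter(coll$proteins, organism_id == coll$reference_id), n = 4)
model
#> <ngram_lm> reference: s01.01.01.06 | n = 4 | |A| = 20 |
#>   distinct n-grams: 54139 | train tokens: 118,329

scan <- perplexity_scan(model, coll$proteins, coll$taxonomy)
scan
#>    organism_id perplexity unseen_fraction is_self branch_distance
#> 1 s01.01.01.06      11.64          0.0000    TRUE            0.00
#> 2 s01.01.01.04      15.96          0.2335   FALSE            0.05
#> 3 s01.01.01.05      16.19          0.2545   FALSE            0.01
#> 4 s01.01.01.03      16.45          0.2532   FALSE            0.10
#> 5 s01.01.01.02      18.19          0.3491   FALSE            0.20
#> 6 s01.01.01.01      18.99          0.3865   FALSE            0.30

divergence_report(scan)$correlations
#>             scope   method estimate n
#> 1         overall  pearson    0.809 6
#> 2         overall spearman    0.943 6
#> 3 reference_genus  pearson    0.809 6
#> 4 reference_genus spearman    0.943 6
```

Reading the output: the reference's self-perplexity (11.64) is the
minimum — a 4-gram model predicts its own proteome best. Cross-perplexity
rises from ~16 to ~19 as true branch distance grows from 0.01 to 0.3, with
a rank correlation of 0.94 in this single replicate (one local flip at the
two closest distances; averaged over seeds the ordering is strict — see
`tests/testthat/test-acceptance.R`). `unseen_fraction` is the share of
test 4-gram tokens never seen in training: substantial even within a
genus, which is why smoothing is mandatory and why absolute perplexities
are implementation-dependent (the methods vignette discusses this).

Zipf profiles and signatures from the same collection:

```r
freqs   <- to_frequencies(count_ngrams(coll$proteins, 4))
profile <- build_rank_profile(freqs, coll$reference_id, k = 40)
extract_signatures(profile)       # top-40 grams rare in the other species
autoplot(profile, coll$taxonomy)  # bold reference, thin comparisons
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference quantities from
scratch with the installed package — it trains a trigram model on a
periodic nucleotide sequence and reports its self-perplexity, and scores a
random nucleotide sequence under a uniform conditional model — and writes
them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

- `R/` — implementation (IO, counting, Zipf/signatures, language models,
  classifiers, simulator, pipeline)
- `tests/testthat/` — unit, property, and acceptance tests with
  brute-force oracles
- `vignettes/proteome-language-models.Rmd` — the model, its assumptions,
  the synthetic world, and design decisions
- `scripts/acceptance.R` — see above
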