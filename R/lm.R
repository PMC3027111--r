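#' Smoothing policy for n-gram language models
#'
#' A raw count-ratio model assigns probability `C_ngram / C_context`, which
#' is undefined (zero mass) for n-grams unseen in training — a certainty for
#' 4-grams across divergent proteomes, where the vocabulary holds
#' 20^4 = 160,000 types. Some probability floor for unseen events is
#' therefore mandatory.
#'
#' * `add_alpha` (default, `alpha = 1`): `q = (C_ngram + alpha) /
#'   (C_context + alpha * |A|)`, i.e. `alpha` pseudo-counts for each of the
#'   `|A|` possible continuations of a context. Test n-grams whose context
#'   was never seen in training fall back to the add-alpha-smoothed unigram
#'   probability of their final symbol.
#' * `floor_prob`: the raw ratio for seen n-grams, `floor` for unseen ones
#'   (no renormalization; cheap, but conditionals no longer sum to 1).
#'
#' @param kind `"add_alpha"` or `"floor_prob"`.
#' @param alpha Pseudo-count per continuation symbol (> 0).
#' @param floor Probability for unseen events under `floor_prob` (> 0).
#' @return An object of class `smoothing_policy`.
#' @export
smoothing_policy <- function(kind = c("add_alpha", "floor_prob"),
                             alpha = 1, floor = 1e-7) {
  kind <- match.arg(kind)
  if (kind == "add_alpha" && (!is.numeric(alpha) || alpha <= 0)) {
    plm_abort("`alpha` must be > 0 (unseen n-grams need mass).",
              "plm_param_error")
  }
  if (kind == "floor_prob" && (!is.numeric(floor) || floor <= 0)) {
    plm_abort("`floor` must be > 0 (unseen n-grams need mass).",
              "plm_param_error")
  }
  structure(list(kind = kind, alpha = alpha, floor = floor),
            class = "smoothing_policy")
}

#' Train a count-ratio n-gram language model on a reference proteome
#'
#' Stores raw training counts of n-grams and of (n-1)-grams, both counted
#' directly from the text with the same windowing rules as [count_ngrams()]
#' (per-protein windows, alphabet policy applied). Conditional
#' probabilities are count ratios `C_ngram / C_context`, smoothed per the
#' [smoothing_policy()]. Because (n-1)-grams are counted directly, a
#' context occurring at a protein end has one occurrence with no
#' continuation; the resulting deficit (at most one per protein per
#' context) is accepted as a boundary effect.
#'
#' @param proteins Protein tibble for a single organism (the reference).
#' @param n Model order (default 4, the headline whole-proteome setting);
#'   `n = 1` trains a context-free unigram model.
#' @param policy An [alphabet_policy()].
#' @param smoothing A [smoothing_policy()].
#'
#' @return An object of class `ngram_lm`.
#' @export
ngram_lm <- function(proteins, n = 4, policy = alphabet_policy(),
                     smoothing = smoothing_policy()) {
  n <- check_order(n)
  check_proteins(proteins)
  if (length(unique(proteins$organism_id)) != 1L) {
    plm_abort("`proteins` must contain a single organism.", "plm_param_error")
  }
  counts_n <- count_ngrams(proteins, n, policy)
  if (nrow(counts_n) == 0L || sum(counts_n$count) == 0) {
    plm_abort("Reference proteome yields no countable n-grams.",
              "plm_empty_input")
  }
  ngram_counts <- setNames(as.numeric(counts_n$count), counts_n$ngram)
  if (n > 1L) {
    counts_ctx <- count_ngrams(proteins, n - 1L, policy)
    context_counts <- setNames(as.numeric(counts_ctx$count), counts_ctx$ngram)
  } else {
    context_counts <- numeric(0)
  }
  counts_uni <- if (n == 1L) counts_n else count_ngrams(proteins, 1L, policy)
  unigram_counts <- setNames(as.numeric(counts_uni$count), counts_uni$ngram)
  structure(list(
    reference_id = proteins$organism_id[1],
    n = n,
    alphabet = policy$alphabet,
    policy = policy,
    smoothing = smoothing,
    ngram_counts = ngram_counts,
    context_counts = context_counts,
    unigram_counts = unigram_counts,
    unigram_total = sum(unigram_counts),
    train_tokens = sum(ngram_counts)
  ), class = "ngram_lm")
}

#' A uniform n-gram model (analytic limit)
#'
#' Every conditional distribution is uniform over the alphabet, so any test
#' text scores perplexity exactly `|A|` — the branching factor of a fully
#' random sequence. Implemented as a model with no training counts under
#' add-alpha smoothing, for which every smoothed ratio collapses to
#' `1 / |A|` exactly.
#'
#' @param policy An [alphabet_policy()].
#' @param n Model order.
#' @return An `ngram_lm` whose conditionals are uniform.
#' @export
uniform_lm <- function(policy = alphabet_policy(), n = 4) {
  n <- check_order(n)
  structure(list(
    reference_id = sprintf("uniform|A|=%d", length(policy$alphabet)),
    n = n, alphabet = policy$alphabet, policy = policy,
    smoothing = smoothing_policy("add_alpha", alpha = 1),
    ngram_counts = numeric(0), context_counts = numeric(0),
    unigram_counts = numeric(0), unigram_total = 0, train_tokens = 0
  ), class = "ngram_lm")
}

#' @export
print.ngram_lm <- function(x, ...) {
  cat("<ngram_lm> reference:", x$reference_id, "| n =", x$n,
      "| |A| =", length(x$alphabet),
      "| distinct n-grams:", length(x$ngram_counts),
      "| train tokens:", format(x$train_tokens, big.mark = ","), "\n")
  invisible(x)
}

# Smoothed conditional probability q(g) for a character vector of n-grams.
model_q <- function(model, grams) {
  A <- length(model$alphabet)
  cn <- unname(model$ngram_counts[grams])
  cn[is.na(cn)] <- 0
  if (model$n == 1L) {
    cc <- rep(model$train_tokens, length(grams))
  } else {
    ctx <- stringi::stri_sub(grams, 1L, model$n - 1L)
    cc <- unname(model$context_counts[ctx])
    cc[is.na(cc)] <- 0
  }
  sm <- model$smoothing
  if (sm$kind == "add_alpha") {
    q <- (cn + sm$alpha) / (cc + sm$alpha * A)
    # unseen context: back off to the smoothed unigram of the final symbol
    if (model$n > 1L && any(cc == 0)) {
      last <- stringi::stri_sub(grams[cc == 0], model$n, model$n)
      cu <- unname(model$unigram_counts[last])
      cu[is.na(cu)] <- 0
      q[cc == 0] <- (cu + sm$alpha) / (model$unigram_total + sm$alpha * A)
    }
  } else {
    q <- ifelse(cn > 0 & cc > 0, cn / cc, sm$floor)
  }
  q
}

#' Cross-entropy and perplexity of a test proteome under a model
#'
#' The entropy of the test proteome is the count-weighted average negative
#' log probability of its n-gram tokens:
#' `E = -(1/N) * sum_j C_test(g_j) * log2 q(g_j)` with `N` the test
#' proteome's total n-gram token count and `q` the model's smoothed
#' count-ratio conditional. Perplexity is `B = 2^E`, the model's effective
#' average branching factor on that proteome; self-perplexity (test ==
#' training organism) is the within-proteome baseline and cross-perplexity
#' tracks divergence from the reference.
#'
#' @param model An [ngram_lm()].
#' @param test Protein tibble for a single test organism (same alphabet
#'   policy as the model).
#'
#' @return A one-row tibble of class `perplexity_result`: `reference_id`,
#'   `test_id`, `n`, `cross_entropy` (bits per n-gram token), `perplexity`,
#'   `unseen_fraction` (fraction of test tokens absent from training),
#'   `is_self`.
#' @export
perplexity <- function(model, test) {
  if (!inherits(model, "ngram_lm")) {
    plm_abort("`model` must come from ngram_lm().", "plm_param_error")
  }
  check_proteins(test, "test")
  if (length(unique(test$organism_id)) != 1L) {
    plm_abort("`test` must contain a single organism.", "plm_param_error")
  }
  counts <- count_ngrams(test, model$n, model$policy)
  N <- sum(as.numeric(counts$count))
  if (N == 0) {
    plm_abort("Test proteome yields no countable n-grams.",
              "plm_degenerate_input")
  }
  q <- model_q(model, counts$ngram)
  E <- -sum(as.numeric(counts$count) * log2(q)) / N
  seen <- counts$ngram %in% names(model$ngram_counts)
  res <- tibble(
    reference_id = model$reference_id,
    test_id = test$organism_id[1],
    n = model$n,
    cross_entropy = E,
    perplexity = 2^E,
    unseen_fraction = sum(counts$count[!seen]) / N,
    is_self = test$organism_id[1] == model$reference_id
  )
  structure(res, class = c("perplexity_result", class(res)))
}

#' Score many proteomes against one model
#'
#' One [perplexity()] row per test organism, joined with taxonomy labels
#' and branch distances where available, sorted ascending by perplexity
#' (most model-like first).
#'
#' @param model An [ngram_lm()].
#' @param proteins Protein tibble covering >= 1 test organism.
#' @param taxonomy Optional taxonomy tibble; organisms missing from it are
#'   retained with `NA` labels and a warning.
#' @return A tibble of class `perplexity_scan` with columns `organism_id`,
#'   `perplexity`, `cross_entropy`, `unseen_fraction`, `is_self`, `genus`,
#'   `taxon_class`, `phylum`, `branch_distance`.
#' @export
perplexity_scan <- function(model, proteins, taxonomy = NULL) {
  check_proteins(proteins)
  rows <- purrr::map_dfr(split(proteins, proteins$organism_id),
                         function(p) perplexity(model, p))
  rows <- dplyr::rename(rows, organism_id = "test_id")
  if (!is.null(taxonomy)) {
    missing <- setdiff(rows$organism_id, taxonomy$organism_id)
    if (length(missing) > 0L) {
      plm_warn(paste0("No taxonomy for: ",
                      paste(head(missing, 5), collapse = ", ")),
               "plm_missing_taxonomy")
    }
    rows <- dplyr::left_join(
      rows,
      dplyr::select(taxonomy, "organism_id", "genus", "taxon_class",
                    "phylum", "branch_distance"),
      by = "organism_id")
  } else {
    rows$genus <- rows$taxon_class <- rows$phylum <- NA_character_
    rows$branch_distance <- NA_real_
  }
  rows <- dplyr::arrange(rows, .data$perplexity)
  out <- dplyr::select(rows, "organism_id", "perplexity", "cross_entropy",
                       "unseen_fraction", "is_self", "genus", "taxon_class",
                       "phylum", "branch_distance")
  structure(out, reference_id = model$reference_id, n = model$n,
            class = c("perplexity_scan", class(as_tibble(out))))
}

#' Perplexity versus branch distance
#'
#' Pairs each scanned organism's cross-perplexity with its branch distance
#' from the reference, and reports Pearson and Spearman correlations —
#' overall and restricted to the reference's genus (where the model is
#' expected to track evolutionary divergence).
#'
#' @param scan A `perplexity_scan` with >= 2 rows carrying branch distances.
#' @param reference_genus Genus of the reference organism; defaults to the
#'   genus of the `is_self` row if present.
#' @return A list of class `divergence_report`: `pairs` (tibble
#'   `organism_id`, `branch_distance`, `perplexity`, `genus`) and
#'   `correlations` (tibble `scope`, `method`, `estimate`, `n`); undefined
#'   correlations (zero variance) are reported as `NA`.
#' @export
divergence_report <- function(scan, reference_genus = NULL) {
  if (!inherits(scan, "perplexity_scan")) {
    plm_abort("`scan` must come from perplexity_scan().", "plm_param_error")
  }
  pairs <- dplyr::filter(scan, !is.na(.data$branch_distance))
  if (nrow(pairs) < 2L) {
    plm_abort("Need >= 2 scanned organisms with branch distances.",
              "plm_degenerate_input")
  }
  reference_genus <- reference_genus %||%
    (if (any(pairs$is_self)) pairs$genus[pairs$is_self][1] else NA_character_)
  corr_rows <- function(d, scope) {
    purrr::map_dfr(c("pearson", "spearman"), function(m) {
      est <- if (nrow(d) < 2L || sd(d$branch_distance) == 0 ||
                 sd(d$perplexity) == 0) NA_real_
             else cor(d$branch_distance, d$perplexity, method = m)
      tibble(scope = scope, method = m, estimate = est, n = nrow(d))
    })
  }
  correlations <- corr_rows(pairs, "overall")
  if (!is.na(reference_genus)) {
    correlations <- dplyr::bind_rows(
      correlations,
      corr_rows(dplyr::filter(pairs, .data$genus == reference_genus),
                "reference_genus"))
  }
  structure(list(
    reference_id = attr(scan, "reference_id"),
    reference_genus = reference_genus,
    pairs = dplyr::select(pairs, "organism_id", "branch_distance",
                          "perplexity", "genus"),
    correlations = correlations
  ), class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("<divergence_report> reference:", x$reference_id,
      "| pairs:", nrow(x$pairs), "\n")
  print(x$correlations)
  invisible(x)
}

#' Serialize / restore an n-gram model as plain text
#'
#' Writes `ngrams.tsv`, `contexts.tsv`, `unigrams.tsv` (columns `ngram`,
#' `count`) and `model.json` (order, alphabet, smoothing, reference id).
#'
#' @param model An `ngram_lm`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_ngram_lm <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dump <- function(counts, file) {
    readr::write_tsv(tibble(ngram = names(counts), count = unname(counts)),
                     file.path(dir, file), progress = FALSE)
  }
  dump(model$ngram_counts, "ngrams.tsv")
  dump(model$context_counts, "contexts.tsv")
  dump(model$unigram_counts, "unigrams.tsv")
  jsonlite::write_json(
    list(reference_id = model$reference_id, n = model$n,
         alphabet = paste(model$alphabet, collapse = ""),
         noncanonical = model$policy$noncanonical,
         smoothing = unclass(model$smoothing)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ngram_lm
#' @export
read_ngram_lm <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"))
  slurp <- function(file) {
    tab <- readr::read_tsv(file.path(dir, file), show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(ngram = "c", count = "d"))
    setNames(tab$count, tab$ngram)
  }
  policy <- alphabet_policy(strsplit(meta$alphabet, "")[[1]],
                            meta$noncanonical)
  ng <- slurp("ngrams.tsv")
  uni <- slurp("unigrams.tsv")
  structure(list(
    reference_id = meta$reference_id, n = as.integer(meta$n),
    alphabet = policy$alphabet, policy = policy,
    smoothing = smoothing_policy(meta$smoothing$kind,
                                 alpha = meta$smoothing$alpha,
                                 floor = meta$smoothing$floor),
    ngram_counts = ng, context_counts = slurp("contexts.tsv"),
    unigram_counts = uni, unigram_total = sum(uni),
    train_tokens = sum(ng)
  ), class = "ngram_lm")
}
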