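#' Build a comparative Zipf-like rank profile
#'
#' Modified Zipf-like analysis: n-grams are sorted in descending order of
#' their percentage frequency in a chosen reference organism (ties broken
#' lexicographically, for determinism), and every other organism's
#' frequencies are looked up at those same n-grams in that fixed order
#' (absent n-grams count as 0).
#'
#' @param freqs An `ngram_freqs` tibble from [to_frequencies()] covering the
#'   reference and the comparison organisms.
#' @param reference Organism id of the reference; must be present in `freqs`.
#' @param k Optional top-k cutoff on the reference ranking (e.g. 40 for the
#'   classic top-40 4-gram profile). `NULL` keeps all reference n-grams.
#'
#' @return An object of class `rank_profile`: a list with `reference_id`,
#'   `n`, `k`, `ranking` (tibble `rank`, `ngram`, `reference_freq`,
#'   non-increasing) and `comparisons` (long tibble `organism_id`, `rank`,
#'   `ngram`, `frequency`).
#' @export
build_rank_profile <- function(freqs, reference, k = NULL) {
  if (!inherits(freqs, "ngram_freqs")) {
    plm_abort("`freqs` must come from to_frequencies().", "plm_param_error")
  }
  if (!reference %in% freqs$organism_id) {
    plm_abort(paste0("Reference organism '", reference, "' not in `freqs`."),
              "plm_param_error")
  }
  ref <- dplyr::filter(freqs, .data$organism_id == reference)
  ref <- dplyr::arrange(ref, dplyr::desc(.data$frequency_percent), .data$ngram)
  if (!is.null(k)) {
    k <- check_order(k)
    ref <- head(ref, k)
  }
  ranking <- tibble(rank = seq_len(nrow(ref)), ngram = ref$ngram,
                    reference_freq = ref$frequency_percent)
  others <- dplyr::filter(freqs, .data$organism_id != reference)
  comparisons <- tidyr::crossing(organism_id = unique(others$organism_id),
                                 ranking[c("rank", "ngram")])
  comparisons <- dplyr::left_join(
    comparisons,
    dplyr::select(others, "organism_id", "ngram",
                  frequency = "frequency_percent"),
    by = c("organism_id", "ngram"))
  comparisons$frequency[is.na(comparisons$frequency)] <- 0
  comparisons <- dplyr::arrange(comparisons, .data$organism_id, .data$rank)
  structure(list(reference_id = reference, n = attr(freqs, "n"),
                 k = k, ranking = ranking, comparisons = comparisons),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat("<rank_profile> reference:", x$reference_id, "| n =", x$n,
      "| ranked n-grams:", nrow(x$ranking),
      "| comparison organisms:", length(unique(x$comparisons$organism_id)), "\n")
  print(head(x$ranking, 5))
  invisible(x)
}

#' Export a rank profile as a wide TSV
#'
#' Columns: `rank`, `ngram`, `reference_freq`, then one column per
#' comparison organism.
#'
#' @param profile A `rank_profile`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_rank_profile <- function(profile, path) {
  readr::write_tsv(rank_profile_wide(profile), path, progress = FALSE)
  invisible(path)
}

rank_profile_wide <- function(profile) {
  wide <- tidyr::pivot_wider(profile$comparisons, names_from = "organism_id",
                             values_from = "frequency")
  dplyr::left_join(profile$ranking, wide, by = c("rank", "ngram"))
}

#' Extract signature n-grams from a rank profile
#'
#' A proteome signature is an n-gram that is highly ranked in the reference
#' organism yet rare (or absent) across comparison organisms. The original
#' analysis identified these visually; here the rule is explicit: an n-gram
#' in the reference's top-k is flagged when the chosen quantile (default:
#' median) of its frequency across comparison organisms falls below
#' `rarity_threshold` times the reference frequency.
#'
#' @param profile A `rank_profile` (already truncated to the top-k of
#'   interest) with at least one comparison organism.
#' @param rarity_quantile Quantile of the comparison frequencies summarized
#'   per n-gram (default 0.5, the median).
#' @param rarity_threshold Multiplier on the reference frequency below which
#'   the comparison quantile must fall (default 0.1).
#'
#' @return A tibble of class `signature_report` with one row per flagged
#'   n-gram: `rank`, `ngram`, `reference_freq`, `comparison_stat`,
#'   `n_comparisons`. The full evaluated table is in attribute `evaluated`.
#' @export
extract_signatures <- function(profile, rarity_quantile = 0.5,
                               rarity_threshold = 0.1) {
  if (!inherits(profile, "rank_profile")) {
    plm_abort("`profile` must come from build_rank_profile().", "plm_param_error")
  }
  n_comp <- length(unique(profile$comparisons$organism_id))
  if (n_comp == 0L) {
    plm_abort("Signature extraction needs >= 1 comparison organism.",
              "plm_degenerate_input")
  }
  if (rarity_quantile <= 0 || rarity_quantile >= 1) {
    plm_abort("`rarity_quantile` must lie in (0, 1).", "plm_param_error")
  }
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(profile$comparisons, .data$rank, .data$ngram),
    comparison_stat = quantile(.data$frequency, rarity_quantile, names = FALSE),
    .groups = "drop")
  evaluated <- dplyr::mutate(
    dplyr::left_join(profile$ranking, stats_tbl, by = c("rank", "ngram")),
    n_comparisons = n_comp,
    flagged = .data$comparison_stat < rarity_threshold * .data$reference_freq)
  out <- dplyr::select(dplyr::filter(evaluated, .data$flagged), -"flagged")
  structure(as_tibble(out),
            reference_id = profile$reference_id, n = profile$n,
            k = nrow(profile$ranking),
            rarity_quantile = rarity_quantile,
            rarity_threshold = rarity_threshold,
            evaluated = evaluated,
            class = c("signature_report", class(as_tibble(out))))
}

#' Per-genus correlation of top-k n-gram frequencies
#'
#' For each genus with at least `min_species` members in the collection,
#' computes the correlation between the reference organism's top-k n-gram
#' frequency vector and each member species' frequencies at those same k
#' n-grams, then reports the per-genus mean and standard deviation, sorted
#' descending by mean. The reference organism itself is excluded from the
#' correlations (its self-correlation is trivially 1) but counts toward its
#' genus' size.
#'
#' @param freqs An `ngram_freqs` tibble covering reference and comparisons.
#' @param reference Reference organism id.
#' @param taxonomy Taxonomy tibble (see [read_taxonomy()]); every comparison
#'   organism must appear.
#' @param k Top-k cutoff (default 40, the classic 4-gram profile width).
#' @param min_species Minimum genus size to be reported (default 9).
#' @param method `"pearson"` (default) or `"spearman"`.
#'
#' @return A tibble of class `genus_correlations`: `genus`,
#'   `mean_correlation`, `sd_correlation`, `n_species`.
#' @export
genus_correlations <- function(freqs, reference, taxonomy, k = 40,
                               min_species = 9,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (k < 3) plm_abort("`k` must be >= 3.", "plm_param_error")
  profile <- build_rank_profile(freqs, reference, k = k)
  missing <- setdiff(unique(profile$comparisons$organism_id),
                     taxonomy$organism_id)
  if (length(missing) > 0L) {
    plm_abort(paste0("Organism(s) missing from taxonomy: ",
                     paste(head(missing, 5), collapse = ", ")),
              "plm_validation_error")
  }
  ref_vec <- profile$ranking$reference_freq
  per_org <- dplyr::summarise(
    dplyr::group_by(profile$comparisons, .data$organism_id),
    correlation = if (sd(.data$frequency) == 0 || sd(ref_vec) == 0)
      NA_real_ else cor(ref_vec, .data$frequency, method = method),
    .groups = "drop")
  if (anyNA(per_org$correlation)) {
    bad <- per_org$organism_id[is.na(per_org$correlation)]
    plm_warn(paste0("Constant frequency vector; correlation undefined, ",
                    "excluded: ", paste(head(bad, 5), collapse = ", ")),
             "plm_constant_vector")
    per_org <- dplyr::filter(per_org, !is.na(.data$correlation))
  }
  sizes <- dplyr::count(taxonomy, .data$genus, name = "n_species")
  per_org <- dplyr::left_join(
    per_org, dplyr::select(taxonomy, "organism_id", "genus"),
    by = "organism_id")
  out <- dplyr::summarise(
    dplyr::group_by(per_org, .data$genus),
    mean_correlation = mean(.data$correlation),
    sd_correlation = if (dplyr::n() > 1) sd(.data$correlation) else 0,
    .groups = "drop")
  out <- dplyr::left_join(out, sizes, by = "genus")
  out <- dplyr::filter(out, .data$n_species >= min_species)
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_correlation))
  structure(as_tibble(out),
            reference_id = reference, n = profile$n, k = k, method = method,
            per_organism = per_org,
            class = c("genus_correlations", class(as_tibble(out))))
}
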