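#' Pipeline run configuration
#'
#' Either a JSON file path or a named list. Recognized keys:
#' `input_dir` (directory of FASTA files; omit to simulate),
#' `taxonomy` (TSV path; omit when simulating),
#' `simulate` (list of [taxonomy_spec()] arguments, used when `input_dir`
#' is absent), `generator` (list of [generator_model()] arguments),
#' `n_orders` (n-gram orders to count; default `c(1, 4)`),
#' `reference` (reference organism id; required unless simulating, where it
#' defaults to the collection's reference), `top_k` (default 40),
#' `model_n` (language-model order, default 4), `alpha` (smoothing, default
#' 1), `min_species` (default 9), `folds` (default 10), `seed` (default 1),
#' `output_dir` (required).
#'
#' @param config Path to a JSON config or a named list.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      plm_abort(paste0("Config file not found: ", config), "plm_io_error")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(n_orders = c(1, 4), top_k = 40, model_n = 4, alpha = 1,
                   min_species = 9, folds = 10, seed = 1)
  config <- modifyList(defaults, config)
  if (is.null(config$output_dir)) {
    plm_abort("Config is missing required field `output_dir`.",
              "plm_validation_error")
  }
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir)) {
      plm_abort(paste0("`input_dir` does not exist: ", config$input_dir),
                "plm_validation_error")
    }
    if (is.null(config$taxonomy) || !file.exists(config$taxonomy)) {
      plm_abort("`taxonomy` must name an existing TSV when `input_dir` is set.",
                "plm_validation_error")
    }
    if (is.null(config$reference)) {
      plm_abort(paste0("Config is missing required field `reference` ",
                       "(needed for the perplexity scan)."),
                "plm_validation_error")
    }
  }
  structure(config, class = c("run_config", "list"))
}

#' Run the whole pipeline
#'
#' Stages: acquire proteomes (read `input_dir` or simulate), count n-grams
#' for each requested order, build the reference rank profile and extract
#' signatures, compute per-genus top-k correlations, train the reference
#' language model and scan all organisms, correlate perplexity with branch
#' distance, and cross-validate the unigram classifiers. All outputs are
#' TSV under `output_dir`, plus `manifest.json` recording the seed and the
#' config echo; every TSV carries a `# seed:` header line.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  emit <- function(tbl, name) {
    path <- file.path(out, name)
    writeLines(sprintf("# seed: %d", config$seed), path)
    suppressWarnings(readr::write_tsv(tbl, path, append = TRUE,
                                      col_names = TRUE, progress = FALSE))
    written[[name]] <<- path
    path
  }

  if (!is.null(config$input_dir)) {
    proteins <- read_proteome_dir(config$input_dir)
    taxonomy <- read_taxonomy(config$taxonomy)
    reference <- config$reference
  } else {
    spec <- do.call(taxonomy_spec,
                    modifyList(config$simulate %||% list(),
                               list(seed = config$seed)))
    gen <- do.call(generator_model, config$generator %||% list())
    coll <- generate_collection(spec, gen)
    proteins <- coll$proteins
    taxonomy <- coll$taxonomy
    reference <- config$reference %||% coll$reference_id
    emit(taxonomy, "taxonomy.tsv")
  }
  if (!reference %in% proteins$organism_id) {
    plm_abort(paste0("`reference` organism not in the collection: ",
                     reference), "plm_validation_error")
  }
  policy <- alphabet_policy()

  freqs_by_n <- list()
  for (n in config$n_orders) {
    freqs <- to_frequencies(count_ngrams(proteins, n, policy))
    freqs_by_n[[as.character(n)]] <- freqs
    emit(freqs, sprintf("ngram_frequencies_n%d.tsv", n))
  }

  prof_n <- as.character(max(config$n_orders))
  profile <- build_rank_profile(freqs_by_n[[prof_n]], reference,
                                k = config$top_k)
  emit(rank_profile_wide(profile), "rank_profile.tsv")
  emit(extract_signatures(profile), "signatures.tsv")
  emit(genus_correlations(freqs_by_n[[prof_n]], reference, taxonomy,
                          k = config$top_k,
                          min_species = config$min_species),
       "genus_correlations.tsv")

  model <- ngram_lm(dplyr::filter(proteins, .data$organism_id == reference),
                    n = config$model_n, policy = policy,
                    smoothing = smoothing_policy("add_alpha",
                                                 alpha = config$alpha))
  scan <- perplexity_scan(model, proteins, taxonomy)
  emit(scan, "perplexity_scan.tsv")
  if (sum(!is.na(scan$branch_distance)) >= 2) {
    rep <- divergence_report(scan)
    emit(rep$pairs, "divergence_pairs.tsv")
    emit(rep$correlations, "divergence_correlations.tsv")
  }

  if ("1" %in% names(freqs_by_n)) {
    cls <- tryCatch(
      classification_report(freqs_by_n[["1"]], taxonomy,
                            min_species = config$min_species,
                            folds = config$folds, seed = config$seed),
      plm_empty_selection = function(e) NULL)
    if (!is.null(cls)) emit(cls, "classification_report.tsv")
  }

  jsonlite::write_json(
    list(package = "proteolm",
         version = as.character(utils::packageVersion("proteolm")),
         seed = config$seed, reference = reference,
         config = unclass(config), outputs = names(written)),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  written[["manifest.json"]] <- file.path(out, "manifest.json")
  invisible(written)
}
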