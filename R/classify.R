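#' Restrict to well-populated genera
#'
#' Classification models are built only on organisms from genera with at
#' least `min_species` members (default 9), so that every category has
#' enough examples for cross-validation.
#'
#' @param taxonomy Taxonomy tibble.
#' @param min_species Minimum genus size (default 9).
#' @return Character vector of organism ids.
#' @export
select_training_subset <- function(taxonomy, min_species = 9) {
  if (nrow(taxonomy) == 0L) plm_abort("Empty taxonomy.", "plm_empty_input")
  keep <- dplyr::filter(dplyr::add_count(taxonomy, .data$genus),
                        .data$n >= min_species)
  if (nrow(keep) == 0L) {
    plm_abort(sprintf("No genus has >= %d species.", min_species),
              "plm_empty_selection")
  }
  keep$organism_id
}

#' Organism-by-unigram frequency matrix
#'
#' Wide feature table for classification: one row per organism, one column
#' per alphabet symbol holding its percentage frequency (absent symbols 0).
#'
#' @param freqs An `ngram_freqs` tibble with `n = 1`.
#' @return A tibble with `organism_id` plus one numeric column per symbol.
#' @export
unigram_features <- function(freqs) {
  if (!inherits(freqs, "ngram_freqs") || attr(freqs, "n") != 1L) {
    plm_abort("`freqs` must be unigram frequencies (n = 1).",
              "plm_param_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(freqs, "organism_id", "ngram", "frequency_percent"),
    names_from = "ngram", values_from = "frequency_percent",
    values_fill = 0)
  dplyr::select(wide, "organism_id", dplyr::all_of(sort(setdiff(names(wide), "organism_id"))))
}

#' First principal component of a feature matrix
#'
#' Column-centered (unscaled) PCA; returns each organism's score on the
#' leading component. Sign convention: the loading entry with the largest
#' magnitude is positive, so scores are deterministic.
#'
#' @param features Tibble with `organism_id` plus numeric feature columns,
#'   or a plain numeric matrix.
#' @return A tibble `organism_id`, `PC1` (or a numeric vector for matrix
#'   input).
#' @export
first_principal_component <- function(features) {
  if (is.data.frame(features)) {
    ids <- features$organism_id
    mat <- as.matrix(dplyr::select(features, dplyr::where(is.numeric)))
  } else {
    ids <- NULL
    mat <- as.matrix(features)
  }
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    plm_abort("PCA needs >= 2 organisms and >= 2 feature columns.",
              "plm_param_error")
  }
  if (all(apply(mat, 2, sd) == 0)) {
    plm_abort("Zero-variance feature matrix.", "plm_degenerate_input")
  }
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  load1 <- pc$rotation[, 1]
  if (load1[which.max(abs(load1))] < 0) load1 <- -load1
  scores <- as.numeric(scale(mat, center = TRUE, scale = FALSE) %*% load1)
  if (is.null(ids)) scores else tibble(organism_id = ids, PC1 = scores)
}

#' Fit a multinomial logistic regression
#'
#' Maximum-likelihood multinomial logit with a baseline category: for `q`
#' categories, `q - 1` logit equations
#' `log(Pr(category_j) / Pr(baseline)) = b0_j + sum_i b_ij x_i` are fit
#' jointly. A small ridge penalty on the coefficients (default `1e-6`)
#' guards against perfect separation, which single-predictor models on
#' small genera hit easily. Optimization is BFGS on the penalized
#' log-likelihood with analytic gradient; predictors are standardized
#' internally and coefficients reported on the original scale.
#'
#' @param data Data frame holding predictors and labels.
#' @param predictor Character vector of predictor column names (typically
#'   one unigram frequency, or `"PC1"`).
#' @param label Name of the category column.
#' @param baseline Baseline category; default: the most frequent label.
#' @param ridge Ridge penalty on slopes and non-baseline intercepts
#'   (default 1e-6).
#' @param maxit Maximum BFGS iterations.
#'
#' @return An object of class `mlr_fit` with `coefficients` (matrix,
#'   one row per non-baseline category: `(Intercept)` plus one column per
#'   predictor), `categories`, `baseline`, `logLik`, `converged`.
#' @export
fit_mlr <- function(data, predictor, label, baseline = NULL, ridge = 1e-6,
                    maxit = 500) {
  x <- as.matrix(data[predictor])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) plm_abort("Predictors must be finite.",
                                    "plm_param_error")
  y <- as.character(data[[label]])
  tab <- sort(table(y), decreasing = TRUE)
  if (length(tab) < 2L) {
    plm_abort("Need >= 2 categories to fit a multinomial model.",
              "plm_param_error")
  }
  baseline <- baseline %||% names(tab)[1]
  if (!baseline %in% names(tab)) {
    plm_abort("`baseline` is not an observed category.", "plm_param_error")
  }
  categories <- c(baseline, setdiff(names(sort(tab, decreasing = TRUE)), baseline))
  yi <- match(y, categories)

  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  q <- length(categories); p <- ncol(xs); nobs <- nrow(xs)
  Y <- matrix(0, nobs, q); Y[cbind(seq_len(nobs), yi)] <- 1

  # theta: (q-1) x (p+1), row-major flattened; eta for baseline fixed at 0
  nll <- function(theta) {
    B <- matrix(theta, q - 1L, p + 1L)
    eta <- cbind(0, sweep(xs %*% t(B[, -1L, drop = FALSE]), 2, -B[, 1L]))
    m <- apply(eta, 1, max)
    ll <- sum(eta[cbind(seq_len(nobs), yi)]) - sum(m + log(rowSums(exp(eta - m))))
    -ll + 0.5 * ridge * sum(theta^2)
  }
  grad <- function(theta) {
    B <- matrix(theta, q - 1L, p + 1L)
    eta <- cbind(0, sweep(xs %*% t(B[, -1L, drop = FALSE]), 2, -B[, 1L]))
    m <- apply(eta, 1, max)
    P <- exp(eta - m); P <- P / rowSums(P)
    R <- (P - Y)[, -1L, drop = FALSE]          # nobs x (q-1)
    g <- cbind(colSums(R), t(R) %*% xs)        # (q-1) x (p+1)
    as.numeric(g) + ridge * theta
  }
  fit <- optim(rep(0, (q - 1L) * (p + 1L)), nll, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  B <- matrix(fit$par, q - 1L, p + 1L)
  # undo standardization: slope_orig = slope_std / scl; b0 adjusts
  slopes <- sweep(B[, -1L, drop = FALSE], 2, scl, "/")
  b0 <- B[, 1L] - as.numeric(slopes %*% ctr)
  coef <- cbind(b0, slopes)
  dimnames(coef) <- list(categories[-1L], c("(Intercept)", predictor))
  structure(list(
    coefficients = coef, categories = categories, baseline = baseline,
    predictor = predictor, label = label, ridge = ridge,
    logLik = -fit$value, converged = fit$convergence == 0, n_obs = nobs
  ), class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat("<mlr_fit>", length(x$categories), "categories (baseline:",
      x$baseline, ") on", paste(x$predictor, collapse = " + "), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Predict from a multinomial logistic fit
#'
#' @param object An `mlr_fit`.
#' @param newdata Data frame containing the predictor columns.
#' @param type `"class"` (highest-probability category) or `"probs"`
#'   (matrix of per-category probabilities, columns in `object$categories`
#'   order, rows summing to 1).
#' @param ... Unused.
#' @export
predict.mlr_fit <- function(object, newdata, type = c("class", "probs"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[object$predictor])
  eta <- cbind(0, sweep(x %*% t(object$coefficients[, -1L, drop = FALSE]),
                        2, -object$coefficients[, 1L]))
  m <- apply(eta, 1, max)
  P <- exp(eta - m); P <- P / rowSums(P)
  colnames(P) <- object$categories
  if (type == "probs") return(P)
  object$categories[max.col(P, ties.method = "first")]
}

#' Stratified k-fold cross-validation of a single-predictor MLR
#'
#' Folds are assigned within each label (stratified) from the given seed,
#' so results are reproducible. Per-fold accuracy is the fraction of
#' held-out organisms whose highest-probability category matches the truth;
#' held-out organisms whose category never occurs in the training fold are
#' dropped from that fold's accuracy with a warning.
#'
#' @param data Data frame with predictors and labels.
#' @param predictor Predictor column name(s).
#' @param label Label column name.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param ridge Ridge penalty passed to [fit_mlr()].
#' @return An object of class `cv_result`: a list with `fold_accuracies`,
#'   `mean_accuracy`, `sd_accuracy`, `predictor`, `label`, `folds`, `seed`.
#' @export
cross_validate <- function(data, predictor, label, folds = 10, seed = 1,
                           ridge = 1e-6) {
  if (folds < 2) plm_abort("`folds` must be >= 2.", "plm_param_error")
  y <- as.character(data[[label]])
  fold_id <- integer(nrow(data))
  withr::with_seed(seed, {
    for (lv in unique(y)) {
      idx <- sample(which(y == lv))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  acc <- vapply(seq_len(folds), function(f) {
    train <- data[fold_id != f, , drop = FALSE]
    test <- data[fold_id == f, , drop = FALSE]
    if (nrow(test) == 0L) return(NA_real_)
    if (length(unique(train[[label]])) < 2L) {
      plm_warn(sprintf("Fold %d: training collapses to one category; skipped.",
                       f), "plm_unseen_category")
      return(NA_real_)
    }
    fit <- fit_mlr(train, predictor, label, ridge = ridge)
    truth <- as.character(test[[label]])
    known <- truth %in% fit$categories
    if (!all(known)) {
      plm_warn(sprintf("Fold %d: %d held-out organism(s) with a category %s",
                       f, sum(!known), "absent from training; dropped."),
               "plm_unseen_category")
    }
    if (!any(known)) return(NA_real_)
    mean(predict(fit, test[known, , drop = FALSE]) == truth[known])
  }, numeric(1))
  acc <- acc[!is.na(acc)]
  structure(list(
    fold_accuracies = acc, mean_accuracy = mean(acc),
    sd_accuracy = if (length(acc) > 1) sd(acc) else 0,
    predictor = predictor, label = label, folds = folds, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s ~ %s: mean accuracy %.3f (sd %.3f) over %d folds\n",
              x$label, paste(x$predictor, collapse = " + "),
              x$mean_accuracy, x$sd_accuracy, x$folds))
  invisible(x)
}

#' Single-variable classification report across taxonomy levels
#'
#' Builds one single-predictor multinomial model per alphabet symbol plus
#' one on the first principal component of all unigram frequencies, for
#' each requested taxonomic level, and cross-validates each — the content
#' of the classic per-unigram accuracy bar chart, as a table.
#'
#' @param freqs Unigram `ngram_freqs` for the collection.
#' @param taxonomy Taxonomy tibble.
#' @param levels Taxonomy levels to predict (default genus, class, phylum).
#' @param min_species Genus-size filter applied before fitting (default 9).
#' @param folds,seed,ridge Passed to [cross_validate()].
#' @return A tibble of class `classification_report`: `level`, `predictor`,
#'   `mean_accuracy`, `sd_accuracy`, `n_organisms`, `n_categories`.
#' @export
classification_report <- function(freqs, taxonomy,
                                  levels = c("genus", "taxon_class", "phylum"),
                                  min_species = 9, folds = 10, seed = 1,
                                  ridge = 1e-6) {
  ids <- select_training_subset(taxonomy, min_species)
  feats <- dplyr::filter(unigram_features(freqs), .data$organism_id %in% ids)
  feats <- dplyr::left_join(feats, taxonomy, by = "organism_id")
  unigrams <- intersect(sort(unique(freqs$ngram)), names(feats))
  feats$PC1 <- first_principal_component(feats[c("organism_id", unigrams)])$PC1
  single <- levels[vapply(levels, function(lv)
    dplyr::n_distinct(feats[[lv]]) < 2L, logical(1))]
  if (length(single) > 0L) {
    plm_warn(paste0("Level(s) with a single category skipped: ",
                    paste(single, collapse = ", ")), "plm_single_category")
    levels <- setdiff(levels, single)
  }
  if (length(levels) == 0L) {
    plm_abort("No taxonomy level has >= 2 categories.", "plm_empty_selection")
  }
  grid <- tidyr::crossing(level = levels, predictor = c(unigrams, "PC1"))
  out <- purrr::pmap_dfr(grid, function(level, predictor) {
    cv <- cross_validate(feats, predictor, level, folds = folds, seed = seed,
                         ridge = ridge)
    tibble(level = level, predictor = predictor,
           mean_accuracy = cv$mean_accuracy, sd_accuracy = cv$sd_accuracy,
           n_organisms = nrow(feats),
           n_categories = dplyr::n_distinct(feats[[level]]))
  })
  structure(out, min_species = min_species, folds = folds, seed = seed,
            class = c("classification_report", class(as_tibble(out))))
}
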