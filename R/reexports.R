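#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted objects
#'
#' Broom-style `tidy()` and `glance()` methods: `tidy()` returns one row
#' per estimated quantity, `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name proteolm-tidiers
NULL

#' @rdname proteolm-tidiers
#' @exportS3Method generics::tidy
tidy.ngram_lm <- function(x, ...) {
  tibble(ngram = names(x$ngram_counts),
         count = unname(x$ngram_counts),
         context = if (x$n > 1) stringi::stri_sub(names(x$ngram_counts),
                                                  1, x$n - 1)
                   else "",
         context_count = if (x$n > 1)
           unname(x$context_counts[stringi::stri_sub(names(x$ngram_counts),
                                                     1, x$n - 1)])
           else x$train_tokens)
}

#' @rdname proteolm-tidiers
#' @exportS3Method generics::glance
glance.ngram_lm <- function(x, ...) {
  tibble(reference_id = x$reference_id, n = x$n,
         alphabet_size = length(x$alphabet),
         vocabulary = length(x$alphabet)^x$n,
         distinct_ngrams = length(x$ngram_counts),
         train_tokens = x$train_tokens,
         smoothing = x$smoothing$kind,
         alpha = x$smoothing$alpha)
}

#' @rdname proteolm-tidiers
#' @exportS3Method generics::tidy
tidy.mlr_fit <- function(x, ...) {
  coef <- x$coefficients
  tibble(category = rep(rownames(coef), ncol(coef)),
         term = rep(colnames(coef), each = nrow(coef)),
         estimate = as.numeric(coef))
}

#' @rdname proteolm-tidiers
#' @exportS3Method generics::glance
glance.mlr_fit <- function(x, ...) {
  tibble(n_categories = length(x$categories), baseline = x$baseline,
         n_obs = x$n_obs, ridge = x$ridge, logLik = x$logLik,
         converged = x$converged)
}

#' @rdname proteolm-tidiers
#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) {
  tibble(fold = seq_along(x$fold_accuracies),
         accuracy = x$fold_accuracies)
}

#' @rdname proteolm-tidiers
#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) {
  tibble(label = x$label, predictor = paste(x$predictor, collapse = "+"),
         folds = x$folds, mean_accuracy = x$mean_accuracy,
         sd_accuracy = x$sd_accuracy, seed = x$seed)
}
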