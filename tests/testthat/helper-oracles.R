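# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no run splitting, no vectorized windows) so that agreement is
# meaningful.

# O(L * n) substring-extraction n-gram counter over one protein set
naive_count <- function(sequences, n, alphabet = proteolm::aa_alphabet(),
                        drop = TRUE) {
  counts <- new.env(parent = emptyenv())
  for (s in sequences) {
    L <- nchar(s)
    if (L < n) next
    for (i in seq_len(L - n + 1)) {
      g <- substr(s, i, i + n - 1)
      if (drop && !all(strsplit(g, "")[[1]] %in% alphabet)) next
      counts[[g]] <- (if (is.null(counts[[g]])) 0 else counts[[g]]) + 1
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) return(numeric(0))
  out[order(names(out))]
}

# Term-by-term evaluation of the count-ratio entropy: for each distinct
# test n-gram, q = (C_train_n + alpha) / (C_train_ctx + alpha * A), with
# the smoothed-unigram fallback for unseen contexts.
naive_cross_entropy <- function(train_seqs, test_seqs, n, alpha,
                                alphabet = proteolm::aa_alphabet()) {
  A <- length(alphabet)
  cn_train <- naive_count(train_seqs, n, alphabet)
  ctx_train <- if (n > 1) naive_count(train_seqs, n - 1, alphabet)
               else numeric(0)
  uni_train <- naive_count(train_seqs, 1, alphabet)
  uni_total <- sum(uni_train)
  cn_test <- naive_count(test_seqs, n, alphabet)
  N <- sum(cn_test)
  total <- 0
  for (g in names(cn_test)) {
    cn <- if (g %in% names(cn_train)) cn_train[[g]] else 0
    if (n == 1) {
      cc <- sum(cn_train)
    } else {
      ctx <- substr(g, 1, n - 1)
      cc <- if (ctx %in% names(ctx_train)) ctx_train[[ctx]] else 0
    }
    if (n > 1 && cc == 0) {
      last <- substr(g, n, n)
      cu <- if (last %in% names(uni_train)) uni_train[[last]] else 0
      q <- (cu + alpha) / (uni_total + alpha * A)
    } else {
      q <- (cn + alpha) / (cc + alpha * A)
    }
    total <- total + cn_test[[g]] * log2(q)
  }
  -total / N
}

# plain sum-based Pearson correlation (no stats::cor)
naive_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

random_proteome <- function(id, n_proteins, len_range = c(5, 40),
                            alphabet = proteolm::aa_alphabet()) {
  tibble::tibble(
    organism_id = id,
    protein_id = sprintf("%s_p%03d", id, seq_len(n_proteins)),
    sequence = vapply(seq_len(n_proteins), function(i) {
      L <- sample(seq(len_range[1], len_range[2]), 1)
      paste(sample(alphabet, L, replace = TRUE), collapse = "")
    }, character(1)))
}

one_protein <- function(id, seq) {
  tibble::tibble(organism_id = id, protein_id = paste0(id, "_p1"),
                 sequence = seq)
}

# ngram_freqs fixture straight from named count vectors (one per organism);
# frequencies fall out as count / total * 100
freqs_fixture <- function(count_list, n) {
  counts <- dplyr::bind_rows(lapply(names(count_list), function(org) {
    f <- count_list[[org]]
    tibble::tibble(organism_id = org, ngram = names(f),
                   count = as.integer(f))
  }))
  totals <- vapply(split(counts$count, counts$organism_id), sum, numeric(1))
  tbl <- structure(counts, n = n, policy = proteolm::alphabet_policy(),
                   totals = totals,
                   skipped_windows = setNames(rep(0, length(totals)),
                                              names(totals)),
                   class = c("ngram_counts", class(counts)))
  proteolm::to_frequencies(tbl)
}
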