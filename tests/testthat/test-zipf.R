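test_that("rank profiles sort by reference frequency and look up comparisons", {
  fr <- freqs_fixture(list(ref = c(A = 50, L = 30, C = 20),
                           cmp = c(A = 10, L = 80, C = 10)), n = 1)
  prof <- build_rank_profile(fr, "ref")
  expect_equal(prof$ranking$ngram, c("A", "L", "C"))
  expect_equal(prof$ranking$reference_freq, c(50, 30, 20))
  expect_equal(prof$comparisons$frequency, c(10, 80, 10))
  # reference frequencies are non-increasing along rank
  expect_true(all(diff(prof$ranking$reference_freq) <= 0))
})

test_that("a reference compared against its own copy matches itself", {
  fr <- freqs_fixture(list(ref = c(A = 5, L = 3, C = 2),
                           copy = c(A = 5, L = 3, C = 2)), n = 1)
  prof <- build_rank_profile(fr, "ref")
  expect_equal(prof$comparisons$frequency, prof$ranking$reference_freq)
})

test_that("profiles match a brute-force sort-then-lookup oracle", {
  withr::with_seed(21, {
    orgs <- paste0("o", 1:5)
    prots <- dplyr::bind_rows(lapply(orgs, function(o)
      random_proteome(o, 6, len_range = c(10, 40))))
  })
  fr <- to_frequencies(count_ngrams(prots, 2))
  prof <- build_rank_profile(fr, "o1", k = 10)
  # oracle: order o1's table by -freq then ngram, take 10, look up others
  ref_tab <- fr[fr$organism_id == "o1", ]
  ord <- order(-ref_tab$frequency_percent, ref_tab$ngram)
  want <- ref_tab$ngram[ord][1:10]
  expect_equal(prof$ranking$ngram, want)
  for (o in c("o3", "o5")) {
    tab <- fr[fr$organism_id == o, ]
    lookup <- vapply(want, function(g) {
      hit <- tab$frequency_percent[tab$ngram == g]
      if (length(hit)) hit else 0
    }, numeric(1))
    got <- prof$comparisons$frequency[prof$comparisons$organism_id == o]
    expect_equal(got, unname(lookup))
  }
  # ranking is a permutation: same multiset of frequencies
  full <- build_rank_profile(fr, "o1")
  expect_equal(sort(full$ranking$reference_freq),
               sort(ref_tab$frequency_percent))
})

test_that("signature extraction flags reference-specific n-grams only", {
  # o1 overuses two grams that are (nearly) absent in 6 comparisons
  base <- c(AA = 100, LL = 90, KK = 80, EE = 70, GG = 60)
  cmp <- lapply(1:6, function(i) base + i)
  names(cmp) <- paste0("c", 1:6)
  fr <- freqs_fixture(c(list(ref = c(base, WC = 50, MH = 40)), cmp), n = 2)
  prof <- build_rank_profile(fr, "ref", k = 7)
  sig <- extract_signatures(prof)
  expect_setequal(sig$ngram, c("WC", "MH"))          # absent elsewhere
  expect_true(all(sig$comparison_stat == 0))
  # identical frequencies everywhere are never signatures
  expect_false(any(c("AA", "LL") %in% sig$ngram))
})

test_that("signature extraction matches a brute-force quantile scan", {
  withr::with_seed(9, {
    grams <- replicate(30, paste(sample(aa_alphabet(), 2), collapse = ""))
    grams <- unique(grams)
    mk <- function() setNames(sample(0:40, length(grams), replace = TRUE),
                              grams)
    fr_list <- c(list(ref = mk()), setNames(lapply(1:8, function(i) mk()),
                                            paste0("c", 1:8)))
  })
  fr_list$ref <- fr_list$ref + 1  # reference total > 0 everywhere
  fr <- freqs_fixture(fr_list, n = 2)
  prof <- build_rank_profile(fr, "ref", k = 15)
  sig <- extract_signatures(prof, rarity_quantile = 0.5,
                            rarity_threshold = 0.25)
  # oracle: per ranked gram, median of the 8 comparison percentages
  totals <- vapply(fr_list, sum, numeric(1))
  flagged <- character(0)
  for (i in seq_len(nrow(prof$ranking))) {
    g <- prof$ranking$ngram[i]
    med <- median(vapply(paste0("c", 1:8), function(o) {
      f <- fr_list[[o]]
      100 * (if (g %in% names(f)) f[[g]] else 0) / totals[[o]]
    }, numeric(1)))
    if (med < 0.25 * prof$ranking$reference_freq[i]) flagged <- c(flagged, g)
  }
  expect_setequal(sig$ngram, flagged)
  # invariant to comparison organism order
  fr2 <- freqs_fixture(fr_list[c("ref", paste0("c", 8:1))], n = 2)
  sig2 <- extract_signatures(build_rank_profile(fr2, "ref", k = 15),
                             rarity_quantile = 0.5, rarity_threshold = 0.25)
  expect_equal(sig$ngram, sig2$ngram)
})

make_clade_freqs <- function() {
  # 3 genera x 4 species; genus A species are noisy copies of the reference
  withr::with_seed(31, {
    grams <- paste0(rep(aa_alphabet()[1:8], each = 5),
                    rep(aa_alphabet()[9:13], times = 8))
    base <- setNames(sample(50:500, length(grams)), grams)
    lst <- list(ref = base)
    for (g in 1:3) {
      for (s in 1:4) {
        noise <- round(base * exp(rnorm(length(base), 0, 0.05 * g)))
        lst[[sprintf("g%d_s%d", g, s)]] <- pmax(noise, 1)
      }
    }
    lst
  })
}

clade_taxonomy <- function(freq_list) {
  ids <- names(freq_list)
  tibble::tibble(
    organism_id = ids,
    genus = ifelse(ids == "ref", "g1", sub("_s\\d+", "", ids)),
    taxon_class = "c1", phylum = "p1", superkingdom = "Bacteria",
    host_label = "none", branch_distance = NA_real_)
}

test_that("per-genus correlation summaries behave like Pearson should", {
  lst <- make_clade_freqs()
  fr <- freqs_fixture(lst, n = 2)
  tax <- clade_taxonomy(lst)
  out <- genus_correlations(fr, "ref", tax, k = 20, min_species = 4)
  expect_true(all(out$mean_correlation >= -1 & out$mean_correlation <= 1))
  expect_true(all(out$sd_correlation >= 0))
  # least-perturbed genus (the reference's own) ranks first
  expect_equal(out$genus[1], "g1")
  expect_true(all(diff(out$mean_correlation) <= 0))

  # exact copies give mean 1, sd 0
  copies <- list(ref = lst$ref, a_s1 = lst$ref, a_s2 = lst$ref)
  fr2 <- freqs_fixture(copies, n = 2)
  tax2 <- clade_taxonomy(copies)
  tax2$genus <- c("a", "a", "a")
  out2 <- genus_correlations(fr2, "ref", tax2, k = 10, min_species = 2)
  expect_equal(out2$mean_correlation, 1, tolerance = 1e-12)
  expect_equal(out2$sd_correlation, 0, tolerance = 1e-12)
})

test_that("correlations are Pearson: affine-invariant and oracle-exact", {
  lst <- make_clade_freqs()
  # an affine positive transform of the reference counts correlates at 1
  aff <- list(ref = lst$ref, t_s1 = round(3 * lst$ref + 7))
  fr <- freqs_fixture(aff, n = 2)
  tax <- clade_taxonomy(aff); tax$genus[2] <- "t"
  out <- genus_correlations(fr, "ref", tax, k = 15, min_species = 1)
  expect_equal(out$mean_correlation[out$genus == "t"], 1, tolerance = 1e-9)

  # full-fixture agreement with a sum-formula Pearson oracle
  fr_all <- freqs_fixture(lst, n = 2)
  tax_all <- clade_taxonomy(lst)
  out_all <- genus_correlations(fr_all, "ref", tax_all, k = 20,
                                min_species = 4)
  prof <- build_rank_profile(fr_all, "ref", k = 20)
  per_org <- vapply(setdiff(names(lst), "ref"), function(o) {
    naive_pearson(prof$ranking$reference_freq,
                  prof$comparisons$frequency[prof$comparisons$organism_id == o])
  }, numeric(1))
  genus <- sub("_s\\d+", "", names(per_org))
  for (g in unique(genus)) {
    expect_equal(out_all$mean_correlation[out_all$genus == g],
                 mean(per_org[genus == g]), tolerance = 1e-12)
    expect_equal(out_all$sd_correlation[out_all$genus == g],
                 sd(per_org[genus == g]), tolerance = 1e-12)
  }
})

test_that("degenerate comparison vectors are excluded with a warning", {
  lst <- list(ref = c(AA = 10, LL = 5, KK = 2),
              flat = c(AA = 3, LL = 3, KK = 3),
              ok = c(AA = 8, LL = 6, KK = 1))
  fr <- freqs_fixture(lst, n = 2)
  tax <- clade_taxonomy(lst)
  tax$genus <- c("r", "f", "f")
  expect_warning(
    out <- genus_correlations(fr, "ref", tax, k = 3, min_species = 2),
    class = "plm_constant_vector")
  expect_equal(nrow(out), 1)   # genus f summarized from the one valid member
})
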