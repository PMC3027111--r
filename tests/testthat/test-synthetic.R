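small_spec <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_phyla = 1, classes_per_phylum = 1, genera_per_class = 2,
    species_per_genus = 3, sigma_phylum = 0.2, sigma_class = 0.15,
    sigma_genus = 0.1, sigma_species = 0.02, seed = seed), list(...))
  do.call(taxonomy_spec, args)
}

small_model <- function(...) {
  args <- modifyList(list(order = 1, protein_count_range = c(40, 50),
                          length_meanlog = log(120), length_sdlog = 0.3),
                     list(...))
  do.call(generator_model, args)
}

test_that("spec validation enforces counts, ordering, and chain rules", {
  expect_error(taxonomy_spec(n_phyla = 0), class = "plm_param_error")
  expect_error(taxonomy_spec(sigma_phylum = 0.1, sigma_class = 0.3),
               class = "plm_param_error")
  expect_error(taxonomy_spec(species_topology = "chain"),
               class = "plm_param_error")
  expect_error(taxonomy_spec(species_per_genus = 2,
                             species_branch_lengths = c(0.3, 0.1),
                             species_topology = "chain"),
               class = "plm_param_error")
  expect_error(generator_model(order = -1), class = "plm_param_error")
  expect_error(generator_model(root_freqs = c(0.5, 0.5)),
               class = "plm_param_error")
})

test_that("identical spec and seed reproduce the collection byte-for-byte", {
  c1 <- generate_collection(small_spec(3), small_model())
  c2 <- generate_collection(small_spec(3), small_model())
  expect_identical(c1$proteins, c2$proteins)
  expect_identical(c1$taxonomy, c2$taxonomy)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_collection(c1, d1); write_collection(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(
    unname(tools::md5sum(file.path(d1, f1))),
    unname(tools::md5sum(file.path(d2, f1))))
  # a different seed changes the sequences
  c3 <- generate_collection(small_spec(4), small_model())
  expect_false(identical(c1$proteins$sequence, c3$proteins$sequence))
})

test_that("generated collections round-trip through FASTA unchanged", {
  coll <- generate_collection(small_spec(5), small_model())
  dir <- withr::local_tempdir()
  write_collection(coll, dir)
  back <- read_proteome_dir(file.path(dir, "proteomes"))
  expect_identical(
    dplyr::arrange(back, organism_id, protein_id)$sequence,
    dplyr::arrange(coll$proteins, organism_id, protein_id)$sequence)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_equal(tax$organism_id, coll$taxonomy$organism_id)
  expect_equal(tax$branch_distance, coll$taxonomy$branch_distance)
})

test_that("taxonomy carries labels, hosts, and reference-relative distances", {
  spec <- small_spec(6)
  coll <- generate_collection(spec, small_model())
  tax <- coll$taxonomy
  expect_equal(nrow(tax), 6)
  expect_true(all(tax$host_label %in% c("animal", "plant")))
  expect_equal(tax$branch_distance[tax$organism_id == coll$reference_id], 0)
  same_genus <- tax$genus == tax$genus[tax$organism_id == coll$reference_id]
  expect_true(all(tax$branch_distance[same_genus] <
                  min(tax$branch_distance[!same_genus])))
  # star distances: sibling species sit at 2 * sigma_species^2
  sib <- tax$branch_distance[same_genus & tax$organism_id != coll$reference_id]
  expect_equal(sib, rep(2 * 0.02^2, 2), tolerance = 1e-12)
})

test_that("zero species divergence gives statistically identical proteomes", {
  # one genus, three species, sigma_species = 0: unigram tables should be
  # homogeneous; allow the occasional chance rejection at alpha = 0.01
  rejections <- 0
  for (s in 1:20) {
    coll <- generate_collection(
      small_spec(s, genera_per_class = 1, sigma_species = 0),
      small_model())
    fr <- count_ngrams(coll$proteins, 1)
    wide <- tidyr::pivot_wider(fr, names_from = "ngram",
                               values_from = "count", values_fill = 0)
    mat <- as.matrix(wide[, -1])
    pval <- suppressWarnings(stats::chisq.test(mat)$p.value)
    if (pval < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("between-genus divergence exceeds within-genus divergence", {
  tv <- function(f1, f2) sum(abs(f1 - f2)) / 2
  within <- c(); between <- c()
  for (s in 1:5) {
    coll <- generate_collection(
      small_spec(s, sigma_genus = 0.15, sigma_species = 0.02),
      small_model())
    fr <- to_frequencies(count_ngrams(coll$proteins, 1))
    wide <- tidyr::pivot_wider(
      dplyr::select(fr, "organism_id", "ngram", "frequency_percent"),
      names_from = "ngram", values_from = "frequency_percent",
      values_fill = 0)
    mat <- as.matrix(wide[, -1]) / 100
    rownames(mat) <- wide$organism_id
    tax <- coll$taxonomy
    for (i in 1:(nrow(tax) - 1)) for (j in (i + 1):nrow(tax)) {
      d <- tv(mat[tax$organism_id[i], ], mat[tax$organism_id[j], ])
      if (tax$genus[i] == tax$genus[j]) within <- c(within, d)
      else between <- c(between, d)
    }
  }
  expect_gt(mean(between), mean(within))
})

test_that("proteome sizes follow the requested count and length model", {
  coll <- generate_collection(small_spec(9), small_model())
  per_org <- dplyr::summarise(
    dplyr::group_by(coll$proteins, organism_id),
    n_prot = dplyr::n(), residues = sum(nchar(sequence)), .groups = "drop")
  expect_true(all(per_org$n_prot >= 40 & per_org$n_prot <= 50))
  # lognormal(meanlog = log 120, sdlog = 0.3): mean length ~125.5
  mu <- exp(log(120) + 0.3^2 / 2)
  sd_tot <- sqrt(per_org$n_prot) * sqrt((exp(0.3^2) - 1)) * mu
  expect_true(all(abs(per_org$residues - per_org$n_prot * mu) <=
                  3 * sd_tot + per_org$n_prot))  # + truncation slack
})

test_that("planting boosts the chosen taxon's n-gram usage and only that", {
  base <- small_model(order = 2)
  expect_identical(plant_signatures(base, "g01.01.01", "LAK", 1), base)
  expect_error(plant_signatures(base, "g01.01.01", "LAKE", 50),
               class = "plm_param_error")
  expect_error(plant_signatures(base, "g01.01.01", "LA1", 50),
               class = "plm_param_error")

  boosted <- plant_signatures(base, "g01.01.01", c("LAK", "EGW"), 40)
  spec <- small_spec(12, sigma_phylum = 0, sigma_class = 0, sigma_genus = 0,
                     sigma_species = 0)
  c_plain <- generate_collection(spec, base)
  c_boost <- generate_collection(spec, boosted)
  freq_of <- function(coll, org, gram) {
    fr <- to_frequencies(count_ngrams(
      dplyr::filter(coll$proteins, organism_id == org), 3))
    hit <- fr$frequency_percent[fr$ngram == gram]
    if (length(hit)) hit else 0
  }
  # boosted genus over-produces the planted grams...
  expect_gt(freq_of(c_boost, "s01.01.01.01", "LAK"),
            5 * max(freq_of(c_plain, "s01.01.01.01", "LAK"), 1e-4))
  # ...while the untouched genus is unaffected in distribution
  expect_lt(freq_of(c_boost, "s01.01.02.01", "LAK"),
            5 * max(freq_of(c_plain, "s01.01.02.01", "LAK"), 0.05))
})

test_that("degenerate and boundary generator settings behave", {
  # order 0 with a homogeneous root draws i.i.d. residues at the root
  # composition
  coll <- generate_collection(small_spec(15),
                              small_model(order = 0, root_heterogeneity = 0))
  fr <- to_frequencies(count_ngrams(coll$proteins, 1))
  top <- dplyr::slice_max(dplyr::filter(fr, organism_id == "s01.01.01.01"),
                          frequency_percent, n = 3)
  expect_true(all(top$ngram %in% names(sort(reference_aa_freqs(),
                                            decreasing = TRUE))[1:8]))
  # proteins are never shorter than order + 1
  coll3 <- generate_collection(
    small_spec(16), small_model(order = 3, length_meanlog = log(10),
                                length_sdlog = 0.1, min_length = 4))
  expect_gte(min(nchar(coll3$proteins$sequence)), 4)
})
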