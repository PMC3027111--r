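#' Hierarchical taxonomy specification for the simulator
#'
#' Describes a balanced phylum > class > genus > species taxonomy and the
#' divergence scale at each level. Divergence is modelled as Brownian
#' motion of the sequence-generating parameters on the logit scale: the
#' `sigma_*` values are per-edge standard deviations of the Gaussian
#' perturbation applied to every conditional log-probability when moving
#' one level down, and must be weakly ordered
#' `sigma_phylum >= sigma_class >= sigma_genus >= sigma_species` (deeper
#' splits diverge more). Explicit `species_branch_lengths` (one per species
#' within each genus) override `sigma_species`: a branch length `d` is a
#' Brownian variance, i.e. perturbation sd `sqrt(d)`, so expected
#' divergence of n-gram usage grows linearly in `d`.
#'
#' @param n_phyla,classes_per_phylum,genera_per_class,species_per_genus
#'   Balanced taxonomy counts (all >= 1).
#' @param sigma_phylum,sigma_class,sigma_genus,sigma_species Logit-scale
#'   perturbation standard deviations per level.
#' @param species_branch_lengths Optional numeric vector of length
#'   `species_per_genus`; branch lengths (variances) applied to each
#'   genus's species in order. `0` means the species equals its genus model.
#' @param species_topology `"star"` (default): each species perturbs the
#'   genus model independently, so congeners are exchangeable.
#'   `"chain"`: species form a serial lineage — each species perturbs the
#'   *previous* species' model by the increment of its branch length, so
#'   the first species' tree distance to species `i` is exactly
#'   `species_branch_lengths[i]` and earlier species share more ancestry
#'   with it. Cross-entropy against a reference tracks *shared lineage*,
#'   not perturbation magnitude per se, so divergence-recovery experiments
#'   need the chain; requires non-decreasing `species_branch_lengths`.
#' @param reference_species Index (in generation order) of the species
#'   used as the default branch-distance reference (default 1).
#' @param seed Integer seed; the whole collection is reproducible from it.
#' @return An object of class `taxonomy_spec`.
#' @export
taxonomy_spec <- function(n_phyla = 4, classes_per_phylum = 2,
                          genera_per_class = 3, species_per_genus = 4,
                          sigma_phylum = 0.3, sigma_class = 0.2,
                          sigma_genus = 0.1, sigma_species = 0.03,
                          species_branch_lengths = NULL,
                          species_topology = c("star", "chain"),
                          reference_species = 1, seed = 1) {
  species_topology <- match.arg(species_topology)
  counts <- c(n_phyla, classes_per_phylum, genera_per_class, species_per_genus)
  if (any(counts < 1) || any(counts != floor(counts))) {
    plm_abort("Taxonomy counts must be positive integers.", "plm_param_error")
  }
  sig <- c(sigma_phylum, sigma_class, sigma_genus, sigma_species)
  if (any(sig < 0) || any(diff(sig) > 1e-12)) {
    plm_abort(paste0("Divergence scales must satisfy sigma_phylum >= ",
                     "sigma_class >= sigma_genus >= sigma_species >= 0."),
              "plm_param_error")
  }
  if (!is.null(species_branch_lengths)) {
    if (length(species_branch_lengths) != species_per_genus ||
        any(species_branch_lengths < 0)) {
      plm_abort(paste0("`species_branch_lengths` must hold one non-negative ",
                       "value per species in a genus."), "plm_param_error")
    }
    if (species_topology == "chain" &&
        is.unsorted(species_branch_lengths)) {
      plm_abort("Chain topology needs non-decreasing `species_branch_lengths`.",
                "plm_param_error")
    }
  } else if (species_topology == "chain") {
    plm_abort("Chain topology needs explicit `species_branch_lengths`.",
              "plm_param_error")
  }
  if (reference_species < 1 ||
      reference_species > n_phyla * classes_per_phylum * genera_per_class *
        species_per_genus) {
    plm_abort("`reference_species` is out of range.", "plm_param_error")
  }
  structure(list(
    n_phyla = as.integer(n_phyla),
    classes_per_phylum = as.integer(classes_per_phylum),
    genera_per_class = as.integer(genera_per_class),
    species_per_genus = as.integer(species_per_genus),
    sigma_phylum = sigma_phylum, sigma_class = sigma_class,
    sigma_genus = sigma_genus, sigma_species = sigma_species,
    species_branch_lengths = species_branch_lengths,
    species_topology = species_topology,
    reference_species = as.integer(reference_species),
    seed = as.integer(seed)
  ), class = "taxonomy_spec")
}

#' Sequence-generating model for synthetic proteomes
#'
#' Proteins are sampled from a Markov chain over the amino-acid alphabet.
#' The root conditional table is i.i.d. at `root_freqs` (default: canonical
#' database-wide amino-acid composition); each taxon's table is obtained by
#' hierarchical logit-normal perturbation of its parent's (see
#' [taxonomy_spec()]). `order` is the chain's context length, so order 3
#' shapes 4-gram statistics — the headline analysis order. Protein counts
#' are uniform over `protein_count_range` and lengths are lognormal
#' (default mean ~300 residues, a realistic microbial protein length).
#' The default scale mimics a microbial proteome collection at desk size.
#'
#' @param root_freqs Named probability vector over the alphabet (any
#'   positive weights; normalized internally).
#' @param order Markov context length (>= 0; 0 means i.i.d. residues).
#' @param protein_count_range Integer range (min, max) of proteins per
#'   species.
#' @param length_meanlog,length_sdlog Lognormal parameters of protein
#'   length; defaults give mean ~300.
#' @param min_length,max_length Length truncation bounds.
#' @param root_heterogeneity Standard deviation of seeded lognormal noise
#'   applied once per collection to the root conditional table, shared by
#'   every taxon (default 0.6). This models the universal structure of
#'   protein sequences — some n-grams are intrinsically common and some
#'   rare in *all* organisms — and produces the steep shared rank-frequency
#'   profile real proteomes show; taxa then diverge around it. Set to 0
#'   for a purely compositional (independent-residue) root, e.g. when
#'   planted signatures must be the only taxon-specific n-gram structure.
#' @return An object of class `generator_model`.
#' @export
generator_model <- function(root_freqs = reference_aa_freqs(), order = 3,
                            protein_count_range = c(1800, 2200),
                            length_meanlog = log(300) - 0.5^2 / 2,
                            length_sdlog = 0.5,
                            min_length = 30, max_length = 3000,
                            root_heterogeneity = 0.6) {
  if (root_heterogeneity < 0) {
    plm_abort("`root_heterogeneity` must be >= 0.", "plm_param_error")
  }
  if (order < 0 || order != floor(order)) {
    plm_abort("`order` must be a non-negative integer.", "plm_param_error")
  }
  if (is.null(names(root_freqs)) || any(root_freqs <= 0)) {
    plm_abort("`root_freqs` must be a named vector of positive weights.",
              "plm_param_error")
  }
  alphabet <- sort(names(root_freqs))
  root <- root_freqs[alphabet] / sum(root_freqs)
  structure(list(
    alphabet = alphabet, root_freqs = root, order = as.integer(order),
    protein_count_range = as.integer(protein_count_range),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_length = as.integer(max(min_length, order + 1L)),
    max_length = as.integer(max_length),
    root_heterogeneity = root_heterogeneity,
    plantings = list()
  ), class = "generator_model")
}

#' Database-wide amino-acid composition used as the simulator root
#'
#' Long-run composition of well-curated protein databases (percent,
#' normalized to probabilities): an uneven distribution in which L, A, G
#' are common and W, C rare — the shape real rank-frequency plots show.
#'
#' @return Named probability vector over the 20 canonical amino acids.
#' @export
reference_aa_freqs <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.65, T = 5.36, W = 1.09,
         Y = 2.92, V = 6.86)
  f / sum(f)
}

#' Plant signature n-grams into a taxon's generating model
#'
#' Multiplies the conditional probability of each listed n-gram's final
#' symbol given its context by `boost` in the named taxon's table (then
#' renormalizes), so the taxon over-produces those n-grams — a known
#' ground truth for signature recovery. Each n-gram must have length
#' `order + 1`.
#'
#' @param model A [generator_model()].
#' @param taxon Taxon id the boost applies to (a phylum/class/genus/species
#'   id as produced by [generate_collection()], e.g. `"g01.02.01"`).
#' @param ngrams Character vector of n-grams over the model alphabet.
#' @param boost Multiplier > 0 (`1` leaves the model unchanged).
#' @return The model with the planting recorded.
#' @export
plant_signatures <- function(model, taxon, ngrams, boost) {
  if (!inherits(model, "generator_model")) {
    plm_abort("`model` must come from generator_model().", "plm_param_error")
  }
  if (!is.numeric(boost) || boost <= 0) {
    plm_abort("`boost` must be > 0.", "plm_param_error")
  }
  if (any(nchar(ngrams) != model$order + 1L)) {
    plm_abort(sprintf("Planted n-grams must have length order + 1 = %d.",
                      model$order + 1L), "plm_param_error")
  }
  bad <- setdiff(unique(strsplit(paste(ngrams, collapse = ""), "")[[1]]),
                 model$alphabet)
  if (length(bad) > 0L) {
    plm_abort(paste0("Planted n-grams use symbols outside the alphabet: ",
                     paste(bad, collapse = ", ")), "plm_param_error")
  }
  if (boost != 1) {
    model$plantings <- c(model$plantings,
                         list(list(taxon = taxon, ngrams = ngrams,
                                   boost = boost)))
  }
  model
}

# ---- internal table machinery -------------------------------------------

# conditional table: (A^order) x A matrix of row-stochastic probabilities
root_table <- function(model) {
  A <- length(model$alphabet)
  rows <- max(A^model$order, 1L)
  matrix(rep(model$root_freqs, each = rows), rows, A,
         dimnames = list(NULL, model$alphabet))
}

# Logit-normal perturbation with total variance sigma^2, split evenly
# between a compositional component (one multiplier per alphabet symbol,
# shared by all contexts, so the unigram marginal shifts too) and a
# context-specific component (independent per cell). Rows renormalized.
perturb_table <- function(tab, sigma) {
  if (sigma == 0) return(tab)
  s <- sigma / sqrt(2)
  z_col <- stats::rnorm(ncol(tab), 0, s)
  z_cell <- matrix(stats::rnorm(length(tab), 0, s), nrow(tab), ncol(tab))
  tab <- tab * exp(sweep(z_cell, 2, z_col, "+"))
  tab / rowSums(tab)
}

perturb_vector <- function(p, sigma) {
  if (sigma == 0) return(p)
  p <- p * exp(stats::rnorm(length(p), 0, sigma))
  p / sum(p)
}

apply_plantings <- function(tab, model, taxon) {
  A <- length(model$alphabet)
  for (pl in model$plantings) {
    if (pl$taxon != taxon) next
    for (g in pl$ngrams) {
      ctx <- substr(g, 1L, model$order)
      letter <- substr(g, model$order + 1L, model$order + 1L)
      row <- context_index(ctx, model$alphabet)
      col <- match(letter, model$alphabet)
      raw <- tab[row, col] * pl$boost
      if (raw > 1) {
        plm_warn(sprintf("Boost drives P(%s) to %.2f pre-normalization; %s",
                         g, raw, "rescaled."), "plm_boost_rescaled")
      }
      tab[row, col] <- raw
      tab[row, ] <- tab[row, ] / sum(tab[row, ])
    }
  }
  tab
}

# 1-based row index of a context string in the A^order table
context_index <- function(ctx, alphabet) {
  A <- length(alphabet)
  idx <- match(strsplit(ctx, "")[[1]], alphabet) - 1L
  sum(idx * A^(rev(seq_along(idx)) - 1L)) + 1L
}

# Vectorized Markov sampling of one species' proteome.
# cum_tab: row-wise cumulative probabilities; uni: initial-letter probs.
sample_proteome <- function(cum_tab, uni, lengths, order, alphabet) {
  A <- length(alphabet)
  np <- length(lengths)
  maxL <- max(lengths)
  letters_mat <- matrix(0L, np, maxL)
  init <- max(order, 1L)
  # initial context: i.i.d. from the taxon unigram distribution
  for (pos in seq_len(min(init, maxL))) {
    active <- lengths >= pos
    letters_mat[active, pos] <- sample.int(A, sum(active), replace = TRUE,
                                           prob = uni)
  }
  if (maxL > init) {
    # running context index, 0-based
    ctx <- integer(np)
    if (order > 0L) {
      for (k in seq_len(order)) {
        ctx <- ctx * A + (letters_mat[, k] - 1L)
      }
    }
    mod <- A^(max(order - 1L, 0L))
    for (pos in (init + 1L):maxL) {
      active <- which(lengths >= pos)
      if (length(active) == 0L) break
      rows <- if (order == 0L) rep(1L, length(active)) else ctx[active] + 1L
      u <- runif(length(active))
      nxt <- rowSums(cum_tab[rows, , drop = FALSE] < u) + 1L
      nxt[nxt > A] <- A
      letters_mat[active, pos] <- nxt
      if (order > 0L) {
        ctx[active] <- (ctx[active] %% mod) * A + (nxt - 1L)
      }
    }
  }
  vapply(seq_len(np), function(i) {
    stringi::stri_flatten(alphabet[letters_mat[i, seq_len(lengths[i])]])
  }, character(1))
}

#' Generate a synthetic proteome collection with known taxonomy
#'
#' Walks the balanced taxonomy of the spec, perturbing the generating
#' tables at each level (see [taxonomy_spec()]), samples one proteome per
#' species, and returns the proteins together with a taxonomy table that
#' carries the *true* labels and the true branch distance of every species
#' from the designated reference (the cumulative Brownian variance along
#' the taxonomy path connecting them). Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [taxonomy_spec()].
#' @param model A [generator_model()].
#' @param reference Organism id to measure branch distances from; default:
#'   the first species generated.
#' @return A list of class `proteome_collection` with `proteins` (tibble
#'   `organism_id`, `protein_id`, `sequence`) and `taxonomy` (tibble as in
#'   [read_taxonomy()], plus the true `branch_distance`).
#' @export
generate_collection <- function(spec, model, reference = NULL) {
  if (!inherits(spec, "taxonomy_spec")) {
    plm_abort("`spec` must come from taxonomy_spec().", "plm_param_error")
  }
  if (!inherits(model, "generator_model")) {
    plm_abort("`model` must come from generator_model().", "plm_param_error")
  }
  withr::with_seed(spec$seed, generate_collection_impl(spec, model, reference))
}

generate_collection_impl <- function(spec, model, reference) {
  alphabet <- model$alphabet
  sbl <- spec$species_branch_lengths
  proteins <- vector("list", 0)
  taxa <- vector("list", 0)
  root_tab <- root_table(model)
  if (model$root_heterogeneity > 0) {
    # universal n-gram structure: shared by all taxa in the collection
    root_tab <- root_tab * exp(matrix(
      stats::rnorm(length(root_tab), 0, model$root_heterogeneity),
      nrow(root_tab), ncol(root_tab)))
    root_tab <- root_tab / rowSums(root_tab)
  }
  for (ph in seq_len(spec$n_phyla)) {
    ph_id <- sprintf("p%02d", ph)
    ph_tab <- apply_plantings(perturb_table(root_tab, spec$sigma_phylum),
                              model, ph_id)
    ph_uni <- perturb_vector(model$root_freqs, spec$sigma_phylum)
    for (cl in seq_len(spec$classes_per_phylum)) {
      cl_id <- sprintf("c%02d.%02d", ph, cl)
      cl_tab <- apply_plantings(perturb_table(ph_tab, spec$sigma_class),
                                model, cl_id)
      cl_uni <- perturb_vector(ph_uni, spec$sigma_class)
      for (ge in seq_len(spec$genera_per_class)) {
        ge_id <- sprintf("g%02d.%02d.%02d", ph, cl, ge)
        ge_tab <- apply_plantings(perturb_table(cl_tab, spec$sigma_genus),
                                  model, ge_id)
        ge_uni <- perturb_vector(cl_uni, spec$sigma_genus)
        host <- sample(c("animal", "plant"), 1L)
        chain <- spec$species_topology == "chain"
        prev_tab <- ge_tab; prev_uni <- ge_uni; v_prev <- 0
        for (sp in seq_len(spec$species_per_genus)) {
          sp_id <- sprintf("s%02d.%02d.%02d.%02d", ph, cl, ge, sp)
          v_sp <- if (!is.null(sbl)) sbl[sp] else spec$sigma_species^2
          parent_tab <- if (chain) prev_tab else ge_tab
          parent_uni <- if (chain) prev_uni else ge_uni
          edge_sd <- sqrt(if (chain) v_sp - v_prev else v_sp)
          sp_tab <- apply_plantings(perturb_table(parent_tab, edge_sd),
                                    model, sp_id)
          sp_uni <- perturb_vector(parent_uni, edge_sd)
          if (chain) {
            prev_tab <- sp_tab; prev_uni <- sp_uni; v_prev <- v_sp
          }
          rng <- model$protein_count_range
          np <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
          lens <- pmin(pmax(round(rlnorm(np, model$length_meanlog,
                                         model$length_sdlog)),
                            model$min_length), model$max_length)
          cum_tab <- t(apply(sp_tab, 1, cumsum))
          seqs <- sample_proteome(cum_tab, sp_uni, lens, model$order,
                                  alphabet)
          proteins[[length(proteins) + 1L]] <- tibble(
            organism_id = sp_id,
            protein_id = sprintf("%s_prot%05d", sp_id, seq_len(np)),
            sequence = seqs)
          taxa[[length(taxa) + 1L]] <- tibble(
            organism_id = sp_id, genus = ge_id, taxon_class = cl_id,
            phylum = ph_id, superkingdom = "Bacteria", host_label = host,
            v_species = v_sp)
        }
      }
    }
  }
  taxonomy <- dplyr::bind_rows(taxa)
  reference <- reference %||% taxonomy$organism_id[spec$reference_species]
  if (!reference %in% taxonomy$organism_id) {
    plm_abort("`reference` is not a generated species id.", "plm_param_error")
  }
  taxonomy$branch_distance <- branch_distance_to(taxonomy, reference, spec)
  taxonomy$v_species <- NULL
  structure(list(proteins = dplyr::bind_rows(proteins), taxonomy = taxonomy,
                 reference_id = reference, seed = spec$seed),
            class = "proteome_collection")
}

# cumulative Brownian variance along the taxonomy path to the reference
branch_distance_to <- function(taxonomy, reference, spec) {
  ref <- taxonomy[taxonomy$organism_id == reference, ]
  v_lvl <- c(phylum = spec$sigma_phylum^2, class = spec$sigma_class^2,
             genus = spec$sigma_genus^2)
  chain <- spec$species_topology == "chain"
  vapply(seq_len(nrow(taxonomy)), function(i) {
    row <- taxonomy[i, ]
    if (row$organism_id == reference) return(0)
    d <- if (chain && row$genus == ref$genus) {
      abs(row$v_species - ref$v_species)   # same lineage: path distance
    } else {
      row$v_species + ref$v_species
    }
    if (row$genus != ref$genus) d <- d + 2 * v_lvl["genus"]
    if (row$taxon_class != ref$taxon_class) d <- d + 2 * v_lvl["class"]
    if (row$phylum != ref$phylum) d <- d + 2 * v_lvl["phylum"]
    unname(d)
  }, numeric(1))
}

#' @export
print.proteome_collection <- function(x, ...) {
  cat("<proteome_collection>", dplyr::n_distinct(x$taxonomy$organism_id),
      "species |", nrow(x$proteins), "proteins | reference:",
      x$reference_id, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Write a collection to disk (FASTA per species + taxonomy TSV)
#'
#' @param collection A `proteome_collection`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteome_fasta(collection$proteins, file.path(dir, "proteomes"))
  write_taxonomy(collection$taxonomy, file.path(dir, "taxonomy.tsv"))
  invisible(dir)
}

#' Single-genus divergence ladder
#'
#' Convenience spec for parameter-recovery experiments: one genus whose
#' species lie on a single lineage (chain topology) ending in the
#' reference, with one species at each supplied tree distance from it, all
#' other taxonomy levels collapsed. The reference sits at the lineage tip
#' so that more distant species share less of its ancestry — the structure
#' under which cross-perplexity is expected to track branch distance.
#'
#' @param divergences Tree distances of the non-reference species from the
#'   reference (default `c(0.01, 0.05, 0.1, 0.2, 0.3)`).
#' @param seed Seed.
#' @return A [taxonomy_spec()]; the reference is the *last* generated
#'   species (`reference_species` is set accordingly).
#' @export
ladder_spec <- function(divergences = c(0.01, 0.05, 0.1, 0.2, 0.3), seed = 1) {
  d <- sort(divergences)
  positions <- max(d) - rev(c(0, d))   # cumulative lineage positions
  taxonomy_spec(
    n_phyla = 1, classes_per_phylum = 1, genera_per_class = 1,
    species_per_genus = length(positions),
    sigma_phylum = 0, sigma_class = 0, sigma_genus = 0, sigma_species = 0,
    species_branch_lengths = positions,
    species_topology = "chain",
    reference_species = length(positions), seed = seed)
}
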