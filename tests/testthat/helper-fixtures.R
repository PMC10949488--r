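# Shared fixture builders: single feature rows, randomized feature tables for
# property tests, and tiny label tables. All randomness is seeded by callers.

# One feature-table row with explicit overrides; everything else absent.
ft_row <- function(seq_id = "s1", ...) {
  tab <- empty_feature_table(seq_id)
  overrides <- list(...)
  for (feat in names(overrides)) tab[[feat]] <- overrides[[feat]]
  tab
}

# Randomized feature table exercising presence/absence of every feature.
random_feature_table <- function(n, seed) {
  set.seed(seed)
  maybe <- function(v, p = 0.3) {
    v[runif(n) < p] <- NA
    v
  }
  tab <- empty_feature_table(sprintf("s%04d", seq_len(n)),
                             lengths = sample(3000:50000, n, replace = TRUE))
  tab$vs2_score <- maybe(round(runif(n), 3))
  tab$vs2_hallmark <- maybe(as.integer(rpois(n, 1)))
  tab$vb_quality <- sample(c("high", "medium", "low", "none"), n,
                           replace = TRUE, prob = c(.1, .1, .1, .7))
  tab$vb_vog_genes <- maybe(as.integer(rpois(n, 3)))
  tab$vb_total_genes <- tab$vb_vog_genes + as.integer(rpois(n, 5))
  tab$vs_category <- maybe(sample.int(6, n, replace = TRUE))
  tab$dvf_score <- maybe(round(runif(n), 3))
  tab$dvf_pvalue <- maybe(round(runif(n), 3))
  tab$cv_viral_genes <- maybe(as.integer(rpois(n, 2)))
  tab$cv_host_genes <- maybe(as.integer(rpois(n, 3)))
  tab$cv_completeness <- maybe(round(runif(n, 0, 100), 1))
  tab$cv_quality <- maybe(sample(c("complete", "high", "medium", "low",
                                   "not_determined"), n, replace = TRUE))
  tab$kj_classified <- runif(n) < 0.8
  path <- sample(c("Viruses; Caudoviricetes;", "Bacteria; Bacillota;"),
                 n, replace = TRUE)
  tab$kj_taxon_path <- ifelse(tab$kj_classified, path, NA_character_)
  tab$kj_is_viral <- ifelse(tab$kj_classified,
                            startsWith(path, "Viruses"), NA)
  tab
}

# Labels for n sequences, the first n_virus of which are viruses.
tiny_labels <- function(n, n_virus, prefix = "s") {
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  class <- c(rep("virus", n_virus),
             sample(c("bacteria", "archaea", "plasmid", "protist", "fungi"),
                    n - n_virus, replace = TRUE))
  tibble::tibble(seq_id = ids, class = class, is_virus = class == "virus")
}

# A small benchmark bundle in a temp dir; returns the bundle manifest list.
small_bundle <- function(dir, n = 200, replicates = 2, seed = 11,
                         profiles = default_profiles()) {
  make_benchmark_bundle(
    dir,
    composition_spec(total_sequences = n, n_replicates = replicates),
    profiles = profiles, seed = seed
  )
}
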