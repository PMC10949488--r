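# Simulated tool outputs: emit the six tools' file dialects for a labeled
# sequence set under configurable per-tool error profiles, so the scoring and
# evaluation stack is testable end to end without running any external tool.

#' Per-tool error profile for the output simulator
#'
#' @param sensitivity Probability a true virus receives a confident positive
#'   signal from the tool.
#' @param specificity Probability a non-virus receives no positive signal.
#' @param low_confidence_rate Probability a detected sequence is emitted at
#'   the low-confidence tier instead of the confident tier. Ignored for
#'   `checkv` and `kaiju`, whose tuning subrules have a single tier each.
#' @param dropout Probability the tool omits the sequence entirely.
#' @return A `tool_profile` object.
#' @export
tool_profile <- function(sensitivity, specificity, low_confidence_rate = 0.2,
                         dropout = 0.02) {
  vals <- c(sensitivity = sensitivity, specificity = specificity,
            low_confidence_rate = low_confidence_rate, dropout = dropout)
  if (any(vals < 0 | vals > 1)) {
    stop("tool_profile: all probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(as.list(vals), class = "tool_profile")
}

#' Default per-tool error profiles
#'
#' Marginal error rates chosen to emulate the tools' qualitative behaviour on
#' environmental-like contigs: VirSorter2 recall-heavy, VIBRANT
#' precision-heavy, VirSorter and DeepVirFinder noisy, CheckV and Kaiju
#' conservative.
#'
#' @param low_confidence_rate,dropout Shared tier/dropout rates.
#' @return Named list of [tool_profile()]s covering all six tools.
#' @export
default_profiles <- function(low_confidence_rate = 0.2, dropout = 0.02) {
  sens <- c(virsorter2 = 0.93, vibrant = 0.55, virsorter = 0.45,
            deepvirfinder = 0.70, checkv = 0.70, kaiju = 0.55)
  spec <- c(virsorter2 = 0.80, vibrant = 0.99, virsorter = 0.95,
            deepvirfinder = 0.75, checkv = 0.97, kaiju = 0.95)
  purrr::map2(sens, spec, tool_profile,
              low_confidence_rate = low_confidence_rate, dropout = dropout)
}

#' Noise-free profiles (perfect tools)
#'
#' @return Named list of [tool_profile()]s with sensitivity and specificity 1,
#'   no low-confidence calls, no dropout.
#' @export
noiseless_profiles <- function() {
  setNames(
    purrr::map(.TOOLS, ~ tool_profile(1, 1, low_confidence_rate = 0, dropout = 0)),
    .TOOLS
  )
}

# Kaiju lineage strings emitted for correctly classified non-viral sequences.
.CELLULAR_PATHS <- c(
  bacteria = "Bacteria; Pseudomonadota; Gammaproteobacteria;",
  archaea = "Archaea; Euryarchaeota;",
  plasmid = "Bacteria; Bacillota;",
  protist = "Eukaryota; Sar;",
  fungi = "Eukaryota; Fungi;"
)
.VIRAL_PATH <- "Viruses; Duplodnaviria; Caudoviricetes;"

# Draw per-sequence tool status: dropped / positive / low-confidence, with an
# optional shared latent detectability (Gaussian copula, exact marginals).
.draw_status <- function(is_virus, profile, latent, shared) {
  n <- length(is_virus)
  eps <- rnorm(n)
  u <- pnorm(sqrt(shared) * latent + sqrt(1 - shared) * eps)
  p_pos <- ifelse(is_virus, profile$sensitivity, 1 - profile$specificity)
  positive <- u < p_pos
  dropped <- runif(n) < profile$dropout
  lowconf <- positive & runif(n) < profile$low_confidence_rate
  list(positive = positive, lowconf = lowconf, dropped = dropped)
}

#' Simulate the six tools' output files
#'
#' Writes one file per dialect (two for VIBRANT) into `dir`. Positive signals
#' draw feature values uniformly from the region satisfying the default
#' confident subrule of that tool (e.g. a VirSorter2 score in `[0.9, 1]`);
#' low-confidence positives satisfy only the half-point subrule; negatives
#' satisfy none. CheckV gene counts and Kaiju taxon paths are generated
#' consistently with each sequence's sampled status and true class.
#' Deterministic for a fixed seed.
#'
#' @param labels Label table (`seq_id`, `class`, `is_virus`).
#' @param lengths Named integer vector or tibble (`seq_id`, `length_bp`).
#' @param profiles Named list of [tool_profile()]s covering all six tools.
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if needed).
#' @param shared_detectability In `[0, 1)`: correlation of detection events
#'   across tools through a shared per-sequence latent "detectability"
#'   (0 = independent tools; higher values make tools agree on easy viruses).
#' @param vog_frac_virus,vog_frac_other Expected fraction of VOG-annotated
#'   genes VIBRANT reports for viral and non-viral sequences it calls.
#' @return Named character vector of the written file paths.
#' @export
simulate_tool_outputs <- function(labels, lengths,
                                  profiles = default_profiles(), seed = 1,
                                  dir = tempfile("fixtures"),
                                  shared_detectability = 0,
                                  vog_frac_virus = 0.6,
                                  vog_frac_other = 0.1) {
  missing <- setdiff(.TOOLS, names(profiles))
  if (length(missing) > 0) {
    stop("profiles must cover all six tools; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot(shared_detectability >= 0, shared_detectability < 1)
  if (is.data.frame(lengths)) {
    lengths <- setNames(as.integer(lengths$length_bp), lengths$seq_id)
  }
  ids <- labels$seq_id
  len <- as.integer(lengths[ids])
  stopifnot(!anyNA(len))
  is_virus <- labels$is_virus
  n <- length(ids)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  latent <- rnorm(n)

  paths <- c(
    virsorter2 = file.path(dir, "virsorter2_final_viral_score.tsv"),
    vibrant_quality = file.path(dir, "vibrant_phage_quality.tsv"),
    vibrant_annotations = file.path(dir, "vibrant_annotations.tsv"),
    virsorter = file.path(dir, "virsorter_global_phage_signal.csv"),
    deepvirfinder = file.path(dir, "deepvirfinder_scores.tsv"),
    checkv = file.path(dir, "checkv_quality_summary.tsv"),
    kaiju = file.path(dir, "kaiju_taxonomy.tsv")
  )

  # VirSorter2: scores every (non-dropped) sequence.
  st <- .draw_status(is_virus, profiles$virsorter2, latent, shared_detectability)
  keep <- !st$dropped
  score <- runif(n, 0, 0.5)
  score[st$positive & st$lowconf] <- runif(sum(st$positive & st$lowconf), 0.5, 0.8999)
  score[st$positive & !st$lowconf] <- runif(sum(st$positive & !st$lowconf), 0.9, 1)
  hallmark <- integer(n)
  conf <- st$positive & !st$lowconf
  hallmark[conf] <- 1L + rbinom(sum(conf), 2, 0.5)
  readr::write_tsv(tibble::tibble(
    seqname = paste0(ids, "||full"), max_score = round(score, 4),
    max_score_group = ifelse(score >= 0.5, "dsDNAphage", "NA"),
    length = len, hallmark = hallmark
  )[keep, ], paths[["virsorter2"]])

  # VIBRANT: lists only the sequences it calls viral.
  st <- .draw_status(is_virus, profiles$vibrant, latent, shared_detectability)
  called <- st$positive & !st$dropped
  quality <- ifelse(st$lowconf[called], "low quality draft",
                    sample(c("high quality draft", "medium quality draft"),
                           sum(called), replace = TRUE))
  readr::write_tsv(tibble::tibble(
    scaffold = ids[called], Quality = quality
  ), paths[["vibrant_quality"]])
  ann <- NULL
  if (any(called)) {
    gene_n <- pmax(1L, as.integer(round(len[called] / 1000)))
    vog_p <- ifelse(is_virus[called], vog_frac_virus, vog_frac_other)
    ann <- purrr::pmap(list(ids[called], gene_n, vog_p), function(id, g, p) {
      has_vog <- runif(g) < p
      tibble::tibble(
        scaffold = id, protein = sprintf("%s_%d", id, seq_len(g)),
        VOG = ifelse(has_vog, sprintf("VOG%05d", sample.int(99999, g, replace = TRUE)), "")
      )
    }) |> dplyr::bind_rows()
  } else {
    ann <- tibble::tibble(scaffold = character(), protein = character(),
                          VOG = character())
  }
  readr::write_tsv(ann, paths[["vibrant_annotations"]])

  # VirSorter: lists only phage-signal sequences; categories 1-3.
  st <- .draw_status(is_virus, profiles$virsorter, latent, shared_detectability)
  called <- st$positive & !st$dropped
  category <- ifelse(st$lowconf[called], 3L,
                     sample(1:2, sum(called), replace = TRUE))
  readr::write_csv(tibble::tibble(
    contig_id = ids[called], category = category
  ), paths[["virsorter"]])

  # DeepVirFinder: scores every (non-dropped) sequence.
  st <- .draw_status(is_virus, profiles$deepvirfinder, latent, shared_detectability)
  keep <- !st$dropped
  score <- runif(n, 0, 0.6999)
  pval <- runif(n, 0.05, 1)
  lc <- st$positive & st$lowconf
  hc <- st$positive & !st$lowconf
  score[lc] <- runif(sum(lc), 0.7, 0.8999)
  score[hc] <- runif(sum(hc), 0.9, 1)
  pval[st$positive] <- runif(sum(st$positive), 0, 0.0499)
  readr::write_tsv(tibble::tibble(
    name = ids, len = len, score = round(score, 4), pvalue = signif(pval, 4)
  )[keep, ], paths[["deepvirfinder"]])

  # CheckV: reports every (non-dropped) sequence; positives look complete.
  st <- .draw_status(is_virus, profiles$checkv, latent, shared_detectability)
  keep <- !st$dropped
  pos <- st$positive
  completeness <- rep(NA_real_, n)
  quality <- rep("Not-determined", n)
  viral_genes <- integer(n)
  host_genes <- integer(n)
  completeness[pos] <- round(runif(sum(pos), 50, 100), 2)
  quality[pos] <- sample(c("Complete", "High-quality", "Medium-quality"),
                         sum(pos), replace = TRUE)
  viral_genes[pos] <- 2L + rpois(sum(pos), 4)
  host_genes[pos] <- rbinom(sum(pos), 1, 0.3)
  miss_v <- !pos & is_virus # viruses the tool failed to validate
  low <- runif(sum(miss_v)) < 0.5
  completeness[miss_v][low] <- round(runif(sum(low), 0, 49.9), 2)
  quality[miss_v][low] <- "Low-quality"
  viral_genes[miss_v] <- rbinom(sum(miss_v), 2, 0.5)
  host_genes[miss_v] <- rbinom(sum(miss_v), 1, 0.3)
  neg_c <- !pos & !is_virus # correctly unvalidated non-viruses
  host_genes[neg_c] <- 2L + rpois(sum(neg_c), 4)
  gene_count <- viral_genes + host_genes +
    pmax(0L, as.integer(round(len / 1000)) - viral_genes - host_genes)
  readr::write_tsv(tibble::tibble(
    contig_id = ids, contig_length = len, gene_count = gene_count,
    viral_genes = viral_genes, host_genes = host_genes,
    checkv_quality = quality, completeness = completeness
  )[keep, ], paths[["checkv"]])

  # Kaiju: reports every sequence; dropped/undetermined rows are unclassified.
  st <- .draw_status(is_virus, profiles$kaiju, latent, shared_detectability)
  status <- rep("C", n)
  taxon_id <- rep(2L, n)
  path <- unname(.CELLULAR_PATHS[labels$class])
  path[is.na(path)] <- .CELLULAR_PATHS[["bacteria"]]
  path[st$positive] <- .VIRAL_PATH
  taxon_id[st$positive] <- 10239L
  miss_v <- !st$positive & is_virus
  uncl <- miss_v & runif(n) < 0.5 # half the missed viruses go unclassified
  uncl <- uncl | st$dropped
  status[uncl] <- "U"
  taxon_id[uncl] <- 0L
  path[uncl] <- "NA"
  readr::write_delim(tibble::tibble(
    status = status, seq_id = ids, taxon_id = taxon_id, taxon_path = path
  ), paths[["kaiju"]], delim = "\t", col_names = FALSE)

  paths
}

#' Build a complete download-free benchmark bundle
#'
#' One call generates replicate mock metagenomes (FASTA + labels) and all six
#' simulated tool outputs for each, under one directory tree
#' (`rep1/`, `rep2/`, ...), plus a `manifest.json` recording the seed and
#' composition. The result parses end to end with [load_replicate()] and
#' [cmd_benchmark()].
#'
#' @param dir Output directory.
#' @param spec A [composition_spec()].
#' @param profiles Named list of [tool_profile()]s.
#' @param seed Integer RNG seed (drives pools, metagenomes and simulators).
#' @param pools Optional named list of class pools; random pools are generated
#'   when omitted.
#' @param ... Passed to [simulate_tool_outputs()] (e.g.
#'   `shared_detectability`).
#' @return List with `dir`, `replicates` (tibble of per-replicate paths) and
#'   `seed`, invisibly.
#' @export
make_benchmark_bundle <- function(dir, spec = composition_spec(),
                                  profiles = default_profiles(), seed = 1,
                                  pools = NULL, ...) {
  set.seed(seed)
  derived <- sample.int(.Machine$integer.max, 2 + spec$n_replicates)
  if (is.null(pools)) pools <- default_pools(seed = derived[1])
  mocks <- build_mock(pools, spec, seed = derived[2])
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reps <- purrr::map(seq_along(mocks), function(r) {
    rep_dir <- file.path(dir, sprintf("rep%d", r))
    mock_paths <- write_mock(mocks[[r]], rep_dir)
    lengths <- setNames(Biostrings::width(mocks[[r]]$sequences),
                        names(mocks[[r]]$sequences))
    tool_paths <- simulate_tool_outputs(
      mocks[[r]]$labels, lengths, profiles = profiles,
      seed = derived[2 + r], dir = rep_dir, ...
    )
    tibble::tibble(replicate = r, dir = rep_dir,
                   file = c(names(mock_paths), names(tool_paths)),
                   path = c(unname(mock_paths), unname(tool_paths)))
  }) |> dplyr::bind_rows()
  manifest <- list(
    seed = seed, n_replicates = spec$n_replicates,
    total_sequences = spec$total_sequences,
    fractions = as.list(spec$fractions),
    package_version = as.character(utils::packageVersion("viralscore"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = dir, replicates = reps, seed = seed))
}

#' Load one benchmark replicate directory
#'
#' Reads the six tool outputs, the label table and the FASTA written by
#' [make_benchmark_bundle()] (or by the real tools, given matching filenames)
#' and merges them into a feature table.
#'
#' @param dir Replicate directory.
#' @param normalizer Id normalizer, see [id_normalizer()].
#' @return List with `features` and `labels`.
#' @export
load_replicate <- function(dir, normalizer = id_normalizer()) {
  files <- c(
    virsorter2 = "virsorter2_final_viral_score.tsv",
    vibrant = "vibrant_phage_quality.tsv",
    virsorter = "virsorter_global_phage_signal.csv",
    deepvirfinder = "deepvirfinder_scores.tsv",
    checkv = "checkv_quality_summary.tsv",
    kaiju = "kaiju_taxonomy.tsv"
  )
  fragments <- list()
  for (tool in names(files)) {
    p <- file.path(dir, files[[tool]])
    if (file.exists(p)) {
      fragments <- c(fragments, list(read_tool_output(p, tool, normalizer)))
    }
  }
  ann <- file.path(dir, "vibrant_annotations.tsv")
  if (file.exists(ann)) {
    fragments <- c(fragments, list(read_vibrant_annotations(ann, normalizer)))
  }
  lengths <- NULL
  fasta <- file.path(dir, "sequences.fasta")
  if (file.exists(fasta)) lengths <- read_fasta_lengths(fasta)
  labels_path <- file.path(dir, "labels.tsv")
  labels <- if (file.exists(labels_path)) read_labels(labels_path) else NULL
  list(features = merge_features(fragments, lengths), labels = labels)
}
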