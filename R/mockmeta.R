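# Labeled mock metagenome construction: class-composition sampling with
# replacement from sequence pools, length trimming/filtering, and 3-5 kb
# fragment generation.

#' Composition specification for mock metagenomes
#'
#' Defaults mirror cellular-enriched environmental metagenomes: 68% bacteria,
#' 10% archaea, 10% virus, 5% plasmid, 5% protist, 2% fungi; 8,000 sequences
#' per replicate; 5 replicates.
#'
#' @param fractions Named numeric vector of class fractions (names drawn from
#'   `viral_classes()`); must sum to 1.
#' @param total_sequences Sequences per replicate.
#' @param n_replicates Number of replicate metagenomes.
#' @return A `composition_spec` object.
#' @export
composition_spec <- function(fractions = c(bacteria = 0.68, archaea = 0.10,
                                           virus = 0.10, plasmid = 0.05,
                                           protist = 0.05, fungi = 0.02),
                             total_sequences = 8000, n_replicates = 5) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  bad <- setdiff(names(fractions), .CLASSES)
  if (length(bad) > 0) {
    stop("composition_spec: unknown class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(fractions < 0)) stop("composition_spec: negative fraction", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("composition_spec: fractions must sum to 1 (got ", sum(fractions), ")",
         call. = FALSE)
  }
  stopifnot(total_sequences >= 1, n_replicates >= 1)
  structure(
    list(fractions = fractions,
         total_sequences = as.integer(total_sequences),
         n_replicates = as.integer(n_replicates)),
    class = "composition_spec"
  )
}

#' Per-class sequence counts under a composition
#'
#' `"largest_remainder"` (default) apportions `round(fraction * total)` counts
#' deterministically with largest-remainder correction so they sum exactly to
#' the total; `"multinomial"` draws the counts from a multinomial instead.
#'
#' @param spec A [composition_spec()].
#' @param mode Apportionment mode.
#' @return Named integer vector of class counts summing to
#'   `spec$total_sequences`.
#' @export
class_counts <- function(spec, mode = c("largest_remainder", "multinomial")) {
  mode <- match.arg(mode)
  fr <- spec$fractions
  total <- spec$total_sequences
  if (mode == "multinomial") {
    counts <- as.integer(rmultinom(1, total, fr))
    return(setNames(counts, names(fr)))
  }
  exact <- fr * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    # deterministic tie-break: larger fractional remainder first, then name
    ord <- order(-(exact - base), names(fr))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(base), names(fr))
}

#' Keep only sequences longer than a minimum length
#'
#' The inequality is strict: a sequence of exactly `min_length_bp` is dropped.
#'
#' @param sequences A [Biostrings::DNAStringSet].
#' @param min_length_bp Minimum length in bp (default 3,000).
#' @return The filtered `DNAStringSet`.
#' @export
length_filter <- function(sequences, min_length_bp = 3000) {
  sequences[Biostrings::width(sequences) > min_length_bp]
}

#' Trim sequences below a maximum length
#'
#' Sequences at or above the cap are truncated (keeping the prefix) to
#' `max_length_bp - 1`, so every output is strictly shorter than the cap —
#' the input-length ceiling DeepVirFinder imposes (2,100 kb).
#'
#' @param sequences A [Biostrings::DNAStringSet].
#' @param max_length_bp Length cap in bp (default 2,100,000).
#' @return The trimmed `DNAStringSet`.
#' @export
trim_sequence <- function(sequences, max_length_bp = 2100000) {
  w <- Biostrings::width(sequences)
  Biostrings::subseq(sequences, start = 1, width = pmin(w, max_length_bp - 1L))
}

#' Generate a random-sequence pool for one class
#'
#' Uniform-composition DNA with configurable GC content; a download-free
#' stand-in for reference-database pools when building test metagenomes.
#'
#' @param n Number of sequences.
#' @param class Class label used in sequence ids.
#' @param min_length,max_length Length range (uniform).
#' @param gc GC content in `[0, 1]`.
#' @param seed Optional RNG seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
random_pool <- function(n, class = "bacteria", min_length = 3200,
                        max_length = 12000, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, min_length >= 1, max_length >= min_length,
            gc >= 0, gc <= 1)
  lens <- min_length + floor(runif(n) * (max_length - min_length + 1))
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s_pool_%04d", class, seq_len(n))
  out
}

#' Random pools for all six classes
#'
#' @param seed RNG seed.
#' @param n_per_class Sequences per class pool.
#' @param ... Passed to [random_pool()].
#' @return Named list of `DNAStringSet`s, one per class.
#' @export
default_pools <- function(seed = 1, n_per_class = 60, ...) {
  set.seed(seed)
  pool_seeds <- sample.int(.Machine$integer.max, length(.CLASSES))
  out <- purrr::map2(.CLASSES, pool_seeds, function(cl, s) {
    random_pool(n_per_class, class = cl, seed = s, ...)
  })
  setNames(out, .CLASSES)
}

#' Build labeled mock metagenomes
#'
#' For each replicate, class counts are apportioned from the composition,
#' sequences are sampled with replacement from the class pools (pools are
#' length-filtered first), trimmed below the DeepVirFinder cap, re-filtered,
#' and given unique per-replicate ids. Identical seeds give byte-identical
#' outputs.
#'
#' @param pools Named list of `DNAStringSet`s (names = classes); every class
#'   with a positive fraction must have a pool with at least one sequence
#'   surviving the length filter.
#' @param spec A [composition_spec()].
#' @param seed Integer RNG seed.
#' @param mode Count apportionment mode, see [class_counts()].
#' @param min_length_bp,max_length_bp Length filter / trim parameters.
#' @return List of `mock_metagenome` objects (fields `sequences`, `labels`,
#'   `provenance`, `replicate`, `seed`), one per replicate.
#' @export
build_mock <- function(pools, spec = composition_spec(), seed = 1,
                       mode = c("largest_remainder", "multinomial"),
                       min_length_bp = 3000, max_length_bp = 2100000) {
  mode <- match.arg(mode)
  classes <- names(spec$fractions)[spec$fractions > 0]
  missing <- setdiff(classes, names(pools))
  if (length(missing) > 0) {
    stop("build_mock: no pool for class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  filtered <- purrr::map(pools[classes], length_filter,
                         min_length_bp = min_length_bp)
  empty <- classes[vapply(filtered, length, integer(1)) == 0]
  if (length(empty) > 0) {
    stop("build_mock: pool for class '", empty[1],
         "' has no sequences longer than ", min_length_bp, " bp",
         call. = FALSE)
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, spec$n_replicates)
  purrr::map(seq_len(spec$n_replicates), function(r) {
    set.seed(rep_seeds[r])
    counts <- class_counts(spec, mode)
    counts <- counts[classes]
    seqs_by_class <- purrr::map(classes, function(cl) {
      pool <- filtered[[cl]]
      idx <- sample.int(length(pool), counts[[cl]], replace = TRUE)
      s <- trim_sequence(pool[idx], max_length_bp)
      attr(s, "source_id") <- names(pool)[idx]
      s
    })
    sequences <- do.call(c, seqs_by_class)
    class_vec <- rep(classes, vapply(seqs_by_class, length, integer(1)))
    source_id <- unlist(purrr::map(seqs_by_class, attr, "source_id"))
    keep <- Biostrings::width(sequences) > min_length_bp
    sequences <- sequences[keep]
    class_vec <- class_vec[keep]
    source_id <- source_id[keep]
    ids <- sprintf("rep%d_seq%06d", r, seq_along(sequences))
    names(sequences) <- ids
    structure(
      list(
        sequences = sequences,
        labels = tibble::tibble(seq_id = ids, class = class_vec,
                                is_virus = class_vec == "virus"),
        provenance = tibble::tibble(seq_id = ids, source_id = source_id,
                                    class = class_vec, replicate = r,
                                    seed = rep_seeds[r]),
        replicate = r, seed = rep_seeds[r]
      ),
      class = "mock_metagenome"
    )
  })
}

#' @export
print.mock_metagenome <- function(x, ...) {
  cat("<mock_metagenome> replicate", x$replicate, "-",
      length(x$sequences), "sequences\n")
  print(table(x$labels$class))
  invisible(x)
}

#' Write a mock metagenome to disk
#'
#' Writes `sequences.fasta`, `labels.tsv` (seq_id, class) and
#' `provenance.tsv`.
#'
#' @param mock A `mock_metagenome`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_mock <- function(mock, dir) {
  stopifnot(inherits(mock, "mock_metagenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "sequences.fasta"),
    labels = file.path(dir, "labels.tsv"),
    provenance = file.path(dir, "provenance.tsv")
  )
  Biostrings::writeXStringSet(mock$sequences, paths[["fasta"]])
  readr::write_tsv(mock$labels[c("seq_id", "class")], paths[["labels"]])
  readr::write_tsv(mock$provenance, paths[["provenance"]])
  invisible(paths)
}

#' Draw one random fragment per sequence
#'
#' Fragment length is uniform on `[min_bp, min(max_bp, parent length)]` and
#' the start position uniform over valid positions; names (and therefore
#' labels) are inherited from the parents. Parents shorter than `min_bp` are
#' skipped with a warning.
#'
#' @param sequences A `DNAStringSet`.
#' @param min_bp,max_bp Fragment length range (defaults 3,000-5,000).
#' @param seed Optional RNG seed.
#' @return A `DNAStringSet` of fragments.
#' @export
fragment_sequences <- function(sequences, min_bp = 3000, max_bp = 5000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(min_bp >= 1, max_bp >= min_bp)
  w <- Biostrings::width(sequences)
  short <- w < min_bp
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than ", min_bp,
            " bp skipped during fragmentation", call. = FALSE)
    sequences <- sequences[!short]
    w <- w[!short]
  }
  if (length(sequences) == 0) return(sequences)
  cap <- pmin(max_bp, w)
  len <- min_bp + floor(runif(length(w)) * (cap - min_bp + 1))
  len <- pmin(len, cap)
  start <- 1 + floor(runif(length(w)) * (w - len + 1))
  Biostrings::subseq(sequences, start = start, width = len)
}
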