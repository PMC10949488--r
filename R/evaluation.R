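# Benchmarking rulesets against ground truth: confusion counts, precision /
# recall / Matthews correlation coefficient, statistically-equivalent top
# groups across replicates, and descriptive summaries.

#' Confusion counts for a set of viral predictions
#'
#' @param predictions Named logical vector (names = sequence ids) or a tibble
#'   with columns `seq_id` and `predicted_viral`.
#' @param labels Label table as from [read_labels()].
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(predictions, labels) {
  if (is.data.frame(predictions)) {
    predictions <- setNames(predictions$predicted_viral, predictions$seq_id)
  }
  stopifnot(is.logical(predictions), !is.null(names(predictions)))
  idx <- match(names(predictions), labels$seq_id)
  if (anyNA(idx)) {
    stop("unlabeled sequence id(s): ",
         paste(head(names(predictions)[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  }
  truth <- labels$is_virus[idx]
  pred <- unname(predictions)
  c(
    tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth)
  )
}

#' Precision, recall and Matthews correlation coefficient
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `mcc = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' Degenerate denominators follow the standard convention: a zero denominator
#' yields 0, keeping metrics finite for rulesets that call nothing viral.
#'
#' @param counts Named numeric vector with elements `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector `c(precision, recall, mcc)`.
#' @export
metrics <- function(counts) {
  tp <- as.numeric(counts[["tp"]])
  fp <- as.numeric(counts[["fp"]])
  tn <- as.numeric(counts[["tn"]])
  fn <- as.numeric(counts[["fn"]])
  stopifnot(tp + fp + tn + fn > 0, all(c(tp, fp, tn, fn) >= 0))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  c(precision = precision, recall = recall, mcc = mcc)
}

#' Benchmark rulesets across replicate metagenomes
#'
#' Scores every ruleset on every replicate and tabulates confusion counts and
#' metrics. Replicates with zero true viruses yield degenerate recall/MCC;
#' their rows are flagged (`degenerate = TRUE`) with a warning and are
#' excluded from [top_groups()].
#'
#' @param features_list List of feature tables, one per replicate.
#' @param labels_list List of label tables, parallel to `features_list`.
#' @param config A [score_config()].
#' @param rulesets Named list of rulesets (default: all 63).
#' @return Tibble with one row per (ruleset, replicate): confusion counts,
#'   `precision`, `recall`, `mcc`, `degenerate`.
#' @export
evaluate_all <- function(features_list, labels_list,
                         config = default_score_config(),
                         rulesets = enumerate_rulesets()) {
  stopifnot(length(features_list) >= 1,
            length(features_list) == length(labels_list))
  reps <- seq_along(features_list)
  rows <- purrr::map(reps, function(r) {
    features <- features_list[[r]]
    labels <- labels_list[[r]]
    degenerate <- sum(labels$is_virus[match(features$seq_id, labels$seq_id)],
                      na.rm = TRUE) == 0
    if (degenerate) {
      warning("replicate ", r, " contains no true viruses; ",
              "its rows are flagged degenerate and excluded from grouping",
              call. = FALSE)
    }
    preds <- predict_all_rulesets(features, config, rulesets)
    preds |>
      dplyr::group_by(.data$ruleset) |>
      dplyr::group_map(function(g, key) {
        cc <- confusion(setNames(g$predicted_viral, g$seq_id), labels)
        met <- metrics(cc)
        tibble::tibble(
          ruleset = key$ruleset, replicate = r,
          tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]], fn = cc[["fn"]],
          precision = met[["precision"]], recall = met[["recall"]],
          mcc = met[["mcc"]], degenerate = degenerate
        )
      }) |>
      dplyr::bind_rows()
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$ruleset, .data$replicate)
}

#' Per-ruleset mean metrics across replicates
#'
#' Unweighted means over non-degenerate replicates.
#'
#' @param rows Output of [evaluate_all()].
#' @return Tibble (`ruleset`, `n_replicates`, `precision`, `recall`, `mcc`).
#' @export
ruleset_means <- function(rows) {
  rows |>
    dplyr::filter(!.data$degenerate) |>
    dplyr::group_by(.data$ruleset) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      precision = mean(.data$precision),
      recall = mean(.data$recall),
      mcc = mean(.data$mcc),
      .groups = "drop"
    )
}

#' Statistically equivalent top rulesets per metric
#'
#' For each metric (MCC, precision, recall) rulesets are ranked by mean across
#' replicates; each ruleset is tested against the top one with a paired
#' one-sided test of decrease (Wilcoxon signed-rank by default, paired t-test
#' selectable), p-values are Benjamini-Hochberg adjusted across rulesets, and
#' the "high" group is the top ruleset plus every ruleset with
#' `p_adj >= alpha`. With a single replicate the grouping degrades to rank
#' only (the top ruleset alone forms the high group), with a warning.
#'
#' @param rows Output of [evaluate_all()].
#' @param alpha Significance level (default 0.05).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return List with `by_metric` (long tibble: `ruleset`, `metric`, `mean`,
#'   `p_value`, `p_adj`, `high`) and `assignment` (tibble `ruleset`, `group`
#'   with group in `high_mcc` > `high_precision` > `high_recall` > `other`,
#'   by that priority when a ruleset qualifies for several).
#' @export
top_groups <- function(rows, alpha = 0.05, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  rows <- dplyr::filter(rows, !.data$degenerate)
  stopifnot(nrow(rows) > 0)
  n_reps <- rows |>
    dplyr::count(.data$ruleset) |>
    dplyr::pull(.data$n) |>
    min()
  rank_only <- n_reps < 2
  if (rank_only) {
    warning("fewer than 2 replicates per ruleset; grouping by rank only",
            call. = FALSE)
  }
  by_metric <- purrr::map(c("mcc", "precision", "recall"), function(metric) {
    wide <- rows |>
      dplyr::select("ruleset", "replicate", dplyr::all_of(metric)) |>
      tidyr::pivot_wider(names_from = "replicate",
                         values_from = dplyr::all_of(metric))
    vals <- as.matrix(wide[-1])
    means <- rowMeans(vals, na.rm = TRUE)
    ord <- order(-means, wide$ruleset)
    top_i <- ord[1]
    p <- rep(NA_real_, nrow(wide))
    if (!rank_only) {
      for (i in seq_len(nrow(wide))) {
        if (i == top_i) next
        p[i] <- .paired_decrease_p(vals[i, ], vals[top_i, ], test)
      }
    }
    p_adj <- p
    p_adj[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
    high <- if (rank_only) {
      seq_len(nrow(wide)) == top_i
    } else {
      seq_len(nrow(wide)) == top_i | (!is.na(p_adj) & p_adj >= alpha)
    }
    tibble::tibble(
      ruleset = wide$ruleset, metric = metric, mean = means,
      p_value = p, p_adj = p_adj, high = high
    ) |>
      dplyr::arrange(dplyr::desc(.data$mean), .data$ruleset)
  }) |>
    dplyr::bind_rows()

  assignment <- by_metric |>
    dplyr::group_by(.data$ruleset) |>
    dplyr::summarise(
      group = if (any(.data$high[.data$metric == "mcc"])) "high_mcc"
      else if (any(.data$high[.data$metric == "precision"])) "high_precision"
      else if (any(.data$high[.data$metric == "recall"])) "high_recall"
      else "other",
      .groups = "drop"
    )
  list(by_metric = by_metric, assignment = assignment)
}

# One-sided paired test that x is smaller than the top ruleset's values.
.paired_decrease_p <- function(x, top, test) {
  ok <- !is.na(x) & !is.na(top)
  x <- x[ok]
  top <- top[ok]
  if (length(x) < 2 || all(x == top)) return(1)
  if (test == "wilcoxon") {
    suppressWarnings(
      wilcox.test(x, top, paired = TRUE, alternative = "less")$p.value
    )
  } else {
    t.test(x, top, paired = TRUE, alternative = "less")$p.value
  }
}

#' Proportion of sequences predicted viral
#'
#' @param predictions Logical vector, or a tibble with `predicted_viral`.
#' @return A number in `[0, 1]`.
#' @export
proportion_viral <- function(predictions) {
  if (is.data.frame(predictions)) predictions <- predictions$predicted_viral
  stopifnot(is.logical(predictions), length(predictions) > 0)
  mean(predictions)
}

#' Per-sequence VOG-annotated gene fraction by true class
#'
#' For sequences called viral (typically by VIBRANT, the only tool reporting
#' VOG annotations), reports the proportion of genes with a VOG annotation,
#' grouped by the sequence's true class — the diagnostic used to spot
#' database-mislabeled sequences (non-viral labels whose gene content looks
#' viral). Sequences with zero or absent total gene counts are skipped with a
#' warning.
#'
#' @param features A feature table.
#' @param labels A label table.
#' @param viral_calls Character vector of sequence ids called viral.
#' @return Tibble (`seq_id`, `class`, `vog_count`, `total_genes`,
#'   `vog_proportion`).
#' @export
vog_fraction <- function(features, labels, viral_calls) {
  sub <- dplyr::filter(features, .data$seq_id %in% viral_calls)
  skip <- is.na(sub$vb_total_genes) | sub$vb_total_genes == 0
  if (any(skip)) {
    warning(sum(skip), " sequence(s) skipped: zero or absent VIBRANT gene count",
            call. = FALSE)
    sub <- sub[!skip, ]
  }
  sub |>
    dplyr::left_join(dplyr::select(labels, "seq_id", "class"), by = "seq_id") |>
    dplyr::transmute(
      seq_id = .data$seq_id, class = .data$class,
      vog_count = .data$vb_vog_genes, total_genes = .data$vb_total_genes,
      vog_proportion = dplyr::coalesce(.data$vb_vog_genes, 0L) / .data$vb_total_genes
    )
}
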