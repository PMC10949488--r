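# Ruleset enumeration, per-ruleset prediction, and between-ruleset overlap.
# A ruleset is a non-empty subset of the six rules; 63 exist.

#' Canonical ruleset label
#'
#' Sorted rule ids joined by `"+"`.
#'
#' @param rule_ids Character vector of rule ids.
#' @return A single string.
#' @export
ruleset_label <- function(rule_ids) {
  paste(sort(unique(rule_ids)), collapse = "+")
}

#' Enumerate all non-empty rule combinations
#'
#' For `n` rules there are `2^n - 1` rulesets, returned in a deterministic
#' order: by size, then lexicographically by canonical label.
#'
#' @param rule_ids Rule ids to combine (default the six shipped rules).
#' @return Named list of character vectors; names are canonical labels.
#' @export
enumerate_rulesets <- function(rule_ids = viral_rule_ids()) {
  rule_ids <- unique(as.character(rule_ids))
  if (length(rule_ids) == 0) {
    stop("enumerate_rulesets: need at least one rule id", call. = FALSE)
  }
  if (length(rule_ids) > 16) {
    stop("enumerate_rulesets: more than 16 rules not supported", call. = FALSE)
  }
  rule_ids <- sort(rule_ids)
  out <- list()
  for (k in seq_along(rule_ids)) {
    sets <- utils::combn(rule_ids, k, simplify = FALSE)
    labels <- vapply(sets, ruleset_label, character(1))
    out <- c(out, setNames(sets, labels)[order(labels)])
  }
  out
}

#' Score every sequence under one ruleset
#'
#' Equivalent to [aggregate_score()] with exactly the ruleset's rules active.
#'
#' @param features A feature table.
#' @param config A [score_config()].
#' @param ruleset Character vector of rule ids (non-empty).
#' @return Tibble with `seq_id`, per-rule contributions, `viral_score`,
#'   `predicted_viral`.
#' @export
predict_ruleset <- function(features, config = default_score_config(),
                            ruleset = viral_rule_ids()) {
  stopifnot(nrow(features) > 0)
  aggregate_score(features, config, active_rules = ruleset)
}

#' Score every sequence under many rulesets at once
#'
#' Rule contributions are evaluated once per sequence and reused across
#' rulesets, so benchmarking all 63 combinations costs little more than
#' scoring each rule once.
#'
#' @inheritParams predict_ruleset
#' @param rulesets Named list of rulesets as from [enumerate_rulesets()].
#' @return Long tibble (`ruleset`, `seq_id`, `viral_score`, `predicted_viral`).
#' @export
predict_all_rulesets <- function(features, config = default_score_config(),
                                 rulesets = enumerate_rulesets()) {
  stopifnot(length(rulesets) > 0)
  contrib <- score_contributions(features, config)
  cm <- as.matrix(contrib[.RULE_IDS])
  purrr::imap(rulesets, function(rs, label) {
    score <- rowSums(cm[, rs, drop = FALSE])
    tibble::tibble(
      ruleset = label, seq_id = contrib$seq_id, viral_score = score,
      predicted_viral = score >= config$viral_threshold
    )
  }) |>
    dplyr::bind_rows()
}

#' Proportion of viral calls shared by two rulesets
#'
#' Intersection over union (Jaccard similarity) of the two sets of sequences
#' called viral. When both sets are empty the rulesets agree perfectly and the
#' overlap is defined as 1.
#'
#' @param viral_a,viral_b Character vectors of sequence ids called viral.
#' @return A number in `[0, 1]`; symmetric in its arguments.
#' @export
overlap <- function(viral_a, viral_b) {
  a <- unique(as.character(viral_a))
  b <- unique(as.character(viral_b))
  u <- length(union(a, b))
  if (u == 0) {
    message("overlap: both prediction sets empty; defined as 1")
    return(1)
  }
  length(intersect(a, b)) / u
}

#' Pairwise overlap matrix across rulesets
#'
#' @param predictions Named list (>= 2 entries) mapping ruleset label to the
#'   character vector of sequence ids it called viral.
#' @return List with `overlap` (symmetric matrix, unit diagonal) and
#'   `n_viral` (named integer vector of per-ruleset viral counts).
#' @export
overlap_matrix <- function(predictions) {
  stopifnot(is.list(predictions), length(predictions) >= 2,
            !is.null(names(predictions)))
  sets <- purrr::map(predictions, ~ unique(as.character(.x)))
  labels <- names(sets)
  n <- length(sets)
  m <- diag(1, n)
  dimnames(m) <- list(labels, labels)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- suppressMessages(overlap(sets[[i]], sets[[j]]))
    }
  }
  list(overlap = m, n_viral = setNames(lengths(sets), labels))
}

#' Summary counts over an overlap matrix
#'
#' Reports the fraction of between-ruleset comparisons (off-diagonal pairs)
#' exceeding `mid` and the number of rulesets with overlap of at least `high`
#' to at least one other ruleset.
#'
#' @param om Result of [overlap_matrix()].
#' @param mid,high Overlap thresholds (defaults 0.5 and 0.9).
#' @return List with `frac_above_mid` and `n_with_high_partner`.
#' @export
overlap_summary <- function(om, mid = 0.5, high = 0.9) {
  m <- om$overlap
  off <- m[upper.tri(m)]
  partner <- m
  diag(partner) <- NA
  list(
    frac_above_mid = mean(off > mid),
    n_with_high_partner = sum(apply(partner, 1, function(r) {
      any(r >= high, na.rm = TRUE)
    }))
  )
}
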