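# Rule-based viral scoring. Each of the six rules holds >= 2 subrules; a
# subrule is a condition over feature columns plus a score contribution
# (+/-0.5 low confidence, +/-1 confident, -3 highly confident not viral).
# Per-sequence viral score = sum of the active rules' contributions;
# score >= threshold (default 1, inclusive) => predicted viral.

.TIERS <- c("low_confidence", "confident", "high_confidence_negative")
.COMBINES <- c("max_positive", "sum")

# Functions a condition expression may call. Variables must be feature names.
.CONDITION_FUNS <- c(
  "&", "|", "!", "(", ">=", "<=", "==", "!=", ">", "<",
  "%in%", "c", "pmax", "pmin", "is.na", "abs", "+", "-", "*", "/"
)

#' Define a scoring subrule
#'
#' A subrule is a predicate over one feature-table row together with the score
#' it contributes when the predicate holds. Conditions are R expressions over
#' the feature schema (see [feature_schema()]), restricted to comparisons,
#' boolean combinators, `%in%`, `is.na`, `pmax`/`pmin` and arithmetic; they
#' are validated when the subrule is built, so a typo in a feature name fails
#' at config-load time, not during evaluation. Absent features are `NA`: a
#' condition only fires when it evaluates definitively `TRUE`, so any
#' comparison against an absent value fails (test for absence explicitly with
#' `is.na(...)`).
#'
#' @param name Subrule name.
#' @param condition Condition as a character string (or unevaluated
#'   expression).
#' @param score Score contributed when the condition holds. Defaults pair
#'   tiers with magnitudes 0.5 / 1 / 3; any real is permitted in a custom
#'   config.
#' @param tier One of `"low_confidence"`, `"confident"`,
#'   `"high_confidence_negative"`.
#' @return A `subrule_spec` object.
#' @export
subrule_spec <- function(name, condition, score, tier) {
  tier <- match.arg(tier, .TIERS)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  stopifnot(is.numeric(score), length(score) == 1, is.finite(score))
  expr <- if (is.character(condition)) {
    str2lang(condition)
  } else {
    condition
  }
  vars <- all.vars(expr)
  funs <- setdiff(all.names(expr), vars)
  bad_vars <- setdiff(vars, names(.FEATURE_TYPES))
  if (length(bad_vars) > 0) {
    stop("subrule '", name, "': condition references undefined feature(s): ",
         paste(bad_vars, collapse = ", "), call. = FALSE)
  }
  bad_funs <- setdiff(funs, .CONDITION_FUNS)
  if (length(bad_funs) > 0) {
    stop("subrule '", name, "': condition uses disallowed function(s): ",
         paste(bad_funs, collapse = ", "), call. = FALSE)
  }
  if (tier == "low_confidence" && abs(score) != 0.5) {
    warning("subrule '", name, "': low_confidence tier usually scores +/-0.5",
            call. = FALSE)
  }
  if (tier == "high_confidence_negative" && score >= 0) {
    stop("subrule '", name, "': high_confidence_negative requires a negative score",
         call. = FALSE)
  }
  structure(
    list(name = name, condition = deparse1(expr), expr = expr,
         score = as.numeric(score), tier = tier),
    class = "subrule_spec"
  )
}

#' Define a scoring rule
#'
#' @param rule_id One of `viral_rule_ids()`.
#' @param subrules List of at least two [subrule_spec()] objects.
#' @param combine `"max_positive"` (a tool contributes only its single best
#'   confidence level; the default for single-tool rules) or `"sum"` (evidence
#'   accumulates; the default for the tuning rules).
#' @return A `rule_spec` object.
#' @export
rule_spec <- function(rule_id, subrules, combine = c("max_positive", "sum")) {
  combine <- match.arg(combine)
  stopifnot(is.character(rule_id), length(rule_id) == 1)
  if (!all(vapply(subrules, inherits, logical(1), "subrule_spec"))) {
    stop("rule '", rule_id, "': subrules must be subrule_spec objects",
         call. = FALSE)
  }
  if (length(subrules) < 2) {
    stop("rule '", rule_id, "': each rule requires at least two subrules",
         call. = FALSE)
  }
  scores <- vapply(subrules, `[[`, numeric(1), "score")
  if (rule_id == "tna" && any(scores <= 0)) {
    stop("rule 'tna': tuning-addition subrules must have positive scores",
         call. = FALSE)
  }
  if (rule_id == "tnv" && any(scores >= 0)) {
    stop("rule 'tnv': tuning-removal subrules must have negative scores",
         call. = FALSE)
  }
  structure(list(rule_id = rule_id, subrules = subrules, combine = combine),
            class = "rule_spec")
}

#' Assemble a score configuration
#'
#' @param rules Named list of the six [rule_spec()] objects (names must equal
#'   `viral_rule_ids()`).
#' @param viral_threshold Score at and above which a sequence is predicted
#'   viral (inclusive; default 1).
#' @param include_low_confidence If `FALSE`, all `low_confidence`-tier
#'   subrules are removed before evaluation.
#' @return A `score_config` object.
#' @export
score_config <- function(rules, viral_threshold = 1,
                         include_low_confidence = TRUE) {
  stopifnot(is.list(rules), !is.null(names(rules)))
  if (!setequal(names(rules), .RULE_IDS)) {
    stop("score_config: rules must be named exactly ",
         paste(.RULE_IDS, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(viral_threshold), length(viral_threshold) == 1,
            is.finite(viral_threshold))
  stopifnot(is.logical(include_low_confidence), length(include_low_confidence) == 1)
  structure(
    list(rules = rules[.RULE_IDS],
         viral_threshold = as.numeric(viral_threshold),
         include_low_confidence = include_low_confidence),
    class = "score_config"
  )
}

#' The shipped default score configuration
#'
#' Six rules: four single-tool rules (`vs2`, `vb`, `vs`, `dvf`; combined by
#' `max_positive` so a tool contributes its single best confidence level) and
#' two tuning rules (`tna` adds score from distinctly viral CheckV / Kaiju /
#' VirSorter2 signals; `tnv` removes score from distinctly non-viral signals;
#' both combined by `sum` so independent evidence accumulates). Cutoffs follow
#' the tools' published recommendations and are fully overridable via
#' [read_score_config()].
#'
#' @return A `score_config` object.
#' @export
default_score_config <- function() {
  rules <- list(
    vs2 = rule_spec("vs2", list(
      subrule_spec("vs2_confident", "vs2_score >= 0.9", 1, "confident"),
      subrule_spec("vs2_low", "vs2_score >= 0.5 & vs2_score < 0.9", 0.5,
                   "low_confidence"),
      subrule_spec("vs2_hallmark", "vs2_hallmark >= 1 & vs2_score >= 0.5", 1,
                   "confident")
    ), combine = "max_positive"),
    vb = rule_spec("vb", list(
      subrule_spec("vb_confident", "vb_quality %in% c('high', 'medium')", 1,
                   "confident"),
      subrule_spec("vb_low", "vb_quality == 'low'", 0.5, "low_confidence")
    ), combine = "max_positive"),
    vs = rule_spec("vs", list(
      subrule_spec("vs_confident", "vs_category %in% c(1, 2)", 1, "confident"),
      subrule_spec("vs_low", "vs_category == 3", 0.5, "low_confidence")
    ), combine = "max_positive"),
    dvf = rule_spec("dvf", list(
      subrule_spec("dvf_confident", "dvf_score >= 0.9 & dvf_pvalue < 0.05", 1,
                   "confident"),
      subrule_spec("dvf_low",
                   "dvf_score >= 0.7 & dvf_score < 0.9 & dvf_pvalue < 0.05",
                   0.5, "low_confidence")
    ), combine = "max_positive"),
    tna = rule_spec("tna", list(
      subrule_spec("tna_checkv",
                   "cv_quality %in% c('complete', 'high', 'medium') | cv_completeness >= 50",
                   1, "confident"),
      subrule_spec("tna_kaiju", "kj_is_viral", 0.5, "low_confidence"),
      subrule_spec("tna_hallmark", "vs2_hallmark >= 2", 1, "confident")
    ), combine = "sum"),
    tnv = rule_spec("tnv", list(
      subrule_spec("tnv_cellular",
                   "kj_classified & !kj_is_viral & cv_viral_genes == 0",
                   -3, "high_confidence_negative"),
      subrule_spec("tnv_hostgenes",
                   "cv_host_genes >= 2 * pmax(cv_viral_genes, 1) & cv_viral_genes <= 1",
                   -1, "confident"),
      subrule_spec("tnv_nosignal",
                   "(is.na(vs2_score) | vs2_score < 0.5) & vb_quality == 'none' & is.na(vs_category)",
                   -0.5, "low_confidence")
    ), combine = "sum")
  )
  score_config(rules)
}

#' Evaluate one subrule on feature-table rows
#'
#' @param features A feature table (or a single row of one).
#' @param subrule A [subrule_spec()].
#' @return Numeric vector: `subrule$score` where the condition holds, else 0.
#'   A condition that evaluates to `NA` (an absent feature) contributes 0.
#' @export
evaluate_subrule <- function(features, subrule) {
  stopifnot(inherits(subrule, "subrule_spec"))
  hit <- .eval_condition(features, subrule$expr)
  ifelse(hit, subrule$score, 0)
}

.eval_condition <- function(features, expr) {
  hit <- rlang::eval_tidy(expr, data = features)
  if (length(hit) == 1) hit <- rep(hit, nrow(features))
  if (!is.logical(hit) || length(hit) != nrow(features)) {
    stop("condition did not evaluate to one logical per row: ",
         deparse1(expr), call. = FALSE)
  }
  hit & !is.na(hit)
}

.active_subrules <- function(rule, include_low_confidence) {
  if (include_low_confidence) return(rule$subrules)
  purrr::discard(rule$subrules, ~ .x$tier == "low_confidence")
}

#' Apply one rule to feature-table rows
#'
#' Under `max_positive` the rule contributes the maximum over matched subrule
#' scores (0 when none match); under `sum` it contributes the sum of all
#' matched subrule scores.
#'
#' @inheritParams evaluate_subrule
#' @param rule A [rule_spec()].
#' @param include_low_confidence Drop `low_confidence` subrules first?
#' @return Numeric vector of per-row rule contributions.
#' @export
apply_rule <- function(features, rule, include_low_confidence = TRUE) {
  stopifnot(inherits(rule, "rule_spec"))
  subs <- .active_subrules(rule, include_low_confidence)
  n <- nrow(features)
  if (length(subs) == 0) return(rep(0, n))
  hits <- vapply(subs, function(s) .eval_condition(features, s$expr),
                 logical(n))
  hits <- matrix(hits, nrow = n)
  scores <- vapply(subs, `[[`, numeric(1), "score")
  if (rule$combine == "sum") {
    as.numeric(hits %*% scores)
  } else {
    m <- sweep(ifelse(hits, 1, NA), 2, scores, `*`)
    out <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
    out[!is.finite(out)] <- 0
    out
  }
}

#' Per-rule score contributions for every sequence
#'
#' @inheritParams apply_rule
#' @param config A [score_config()].
#' @param rules Character vector of rule ids to evaluate (default all six).
#' @return Tibble with `seq_id` and one numeric column per rule.
#' @export
score_contributions <- function(features, config = default_score_config(),
                                rules = viral_rule_ids()) {
  stopifnot(inherits(config, "score_config"))
  rules <- match.arg(rules, .RULE_IDS, several.ok = TRUE)
  out <- tibble::tibble(seq_id = features$seq_id)
  for (rid in rules) {
    out[[rid]] <- apply_rule(features, config$rules[[rid]],
                             config$include_low_confidence)
  }
  out
}

#' Aggregate viral scores over a set of active rules
#'
#' The viral score of a sequence is the sum of the active rules'
#' contributions; sequences with score at or above `config$viral_threshold`
#' are predicted viral.
#'
#' @inheritParams score_contributions
#' @param active_rules Non-empty character vector of rule ids.
#' @return Tibble with `seq_id`, one contribution column per active rule,
#'   `viral_score` and `predicted_viral`.
#' @export
aggregate_score <- function(features, config = default_score_config(),
                            active_rules = viral_rule_ids()) {
  if (length(active_rules) == 0) {
    stop("active_rules must be a non-empty set of rule ids", call. = FALSE)
  }
  active_rules <- unique(match.arg(active_rules, .RULE_IDS, several.ok = TRUE))
  contrib <- score_contributions(features, config, active_rules)
  contrib$viral_score <- rowSums(as.matrix(contrib[active_rules]))
  contrib$predicted_viral <- contrib$viral_score >= config$viral_threshold
  contrib
}

#' @export
print.score_config <- function(x, ...) {
  cat("<score_config> threshold >=", x$viral_threshold,
      if (!x$include_low_confidence) "(low-confidence subrules disabled)",
      "\n")
  for (rule in x$rules) {
    cat(sprintf("  %-4s [%s]\n", rule$rule_id, rule$combine))
    for (s in rule$subrules) {
      cat(sprintf("    %+4.1f  %-18s %s\n", s$score, s$name, s$condition))
    }
  }
  invisible(x)
}
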