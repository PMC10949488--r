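# YAML serialization of score configurations, so every threshold, score and
# condition lives in one declarative file that the CLI can point at.

#' Read a score configuration from YAML
#'
#' The file holds `viral_threshold`, `include_low_confidence` and a `rules`
#' map; each rule has `combine` and a list of subrules with `name`, `tier`,
#' `score` and `condition` (an expression string over the feature schema).
#' Validation — unknown feature names, bad tiers, sign constraints on the
#' tuning rules — happens here, at load time.
#'
#' @param path YAML file path.
#' @return A `score_config` object.
#' @export
read_score_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$rules)) stop("config: missing 'rules' section", call. = FALSE)
  rules <- purrr::imap(raw$rules, function(r, rid) {
    subs <- purrr::map(r$subrules, function(s) {
      subrule_spec(s$name, s$condition, s$score, s$tier)
    })
    rule_spec(rid, subs, combine = r$combine %||% "max_positive")
  })
  score_config(
    rules,
    viral_threshold = raw$viral_threshold %||% 1,
    include_low_confidence = raw$include_low_confidence %||% TRUE
  )
}

#' Write a score configuration to YAML
#'
#' @param config A [score_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_config <- function(config, path) {
  stopifnot(inherits(config, "score_config"))
  out <- list(
    viral_threshold = config$viral_threshold,
    include_low_confidence = config$include_low_confidence,
    rules = purrr::map(config$rules, function(r) {
      list(
        combine = r$combine,
        subrules = purrr::map(r$subrules, function(s) {
          list(name = s$name, tier = s$tier, score = s$score,
               condition = s$condition)
        })
      )
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
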