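test_that("subrule evaluation matches an exhaustive truth-table oracle", {
  sub <- subrule_spec("dvf_confident", "dvf_score >= 0.9 & dvf_pvalue < 0.05",
                      1, "confident")
  scores <- c(NA, 0.95, 0.5)
  pvals <- c(NA, 0.01, 0.5)
  grid <- expand.grid(dvf_score = scores, dvf_pvalue = pvals)
  for (i in seq_len(nrow(grid))) {
    row <- ft_row("s1", dvf_score = grid$dvf_score[i],
                  dvf_pvalue = grid$dvf_pvalue[i])
    # oracle: brute-force three-valued logic, absent comparison fails
    expected <- isTRUE(grid$dvf_score[i] >= 0.9) &&
      isTRUE(grid$dvf_pvalue[i] < 0.05)
    expect_equal(evaluate_subrule(row, sub), if (expected) 1 else 0,
                 info = paste("case", i))
  }
})

test_that("default tiers score +/-0.5, +/-1 and -3, and absent features contribute 0", {
  cfg <- default_score_config()
  for (rule in cfg$rules) {
    for (s in rule$subrules) {
      expected_mag <- switch(s$tier, low_confidence = 0.5, confident = 1,
                             high_confidence_negative = 3)
      expect_equal(abs(s$score), expected_mag, info = s$name)
    }
  }
  # highly confident not viral: no viral genes, cellular taxonomy
  row <- ft_row("s1", cv_viral_genes = 0L, cv_host_genes = 8L,
                kj_classified = TRUE, kj_is_viral = FALSE)
  tnv_cellular <- cfg$rules$tnv$subrules[[1]]
  expect_equal(evaluate_subrule(row, tnv_cellular), -3)
  # absent dvf features: the confident dvf subrule contributes 0
  expect_equal(evaluate_subrule(ft_row("s1"), cfg$rules$dvf$subrules[[1]]), 0)
})

test_that("rule combination: max_positive keeps the best tier, sum accumulates", {
  cfg <- default_score_config()
  # both the +1 and +0.5 VirSorter2 subrules can't fire at once by
  # construction, but score+hallmark makes two +1/+0.5 candidates:
  row <- ft_row("s1", vs2_score = 0.7, vs2_hallmark = 3L)
  # matches vs2_low (+0.5) and vs2_hallmark (+1) -> max_positive gives +1
  expect_equal(apply_rule(row, cfg$rules$vs2), 1)
  expect_equal(apply_rule(ft_row("s1"), cfg$rules$vs2), 0)
  # tnv: -1 and -3 both match -> sum gives -4
  row <- ft_row("s1", cv_viral_genes = 0L, cv_host_genes = 5L,
                kj_classified = TRUE, kj_is_viral = FALSE,
                vs2_score = 0.9)
  expect_equal(apply_rule(row, cfg$rules$tnv), -4)
})

test_that("aggregate scores hit the inclusive >= 1 threshold", {
  cfg <- default_score_config()
  # one confident rule alone reaches exactly 1 -> viral
  row <- ft_row("s1", vs2_score = 0.95)
  res <- aggregate_score(row, cfg, active_rules = c("vs2", "tnv"))
  expect_equal(res$viral_score, 1)
  expect_true(res$predicted_viral)
  # two low-confidence half points reach 1.0 -> viral; one alone does not
  row <- ft_row("s1", dvf_score = 0.8, dvf_pvalue = 0.01, vs_category = 3L)
  expect_true(aggregate_score(row, cfg, c("dvf", "vs"))$predicted_viral)
  half <- aggregate_score(row, cfg, "dvf")
  expect_equal(half$viral_score, 0.5)
  expect_false(half$predicted_viral)
  # strong positives overruled by the -3 subrule: 1 + 1 - 3 = -1
  row <- ft_row("s1", vs2_score = 0.95, vb_quality = "high",
                cv_viral_genes = 0L, kj_classified = TRUE, kj_is_viral = FALSE)
  res <- aggregate_score(row, cfg, c("vs2", "vb", "tnv"))
  expect_equal(res$viral_score, -1)
  expect_false(res$predicted_viral)
  expect_error(aggregate_score(row, cfg, character()), "non-empty")
})

test_that("aggregation is additive and tuning rules are monotone", {
  cfg <- default_score_config()
  tab <- random_feature_table(120, seed = 42)
  contrib <- score_contributions(tab, cfg)
  set.seed(43)
  for (i in 1:10) {
    active <- sample(viral_rule_ids(), sample(1:6, 1))
    agg <- aggregate_score(tab, cfg, active)
    expect_equal(agg$viral_score,
                 rowSums(as.matrix(contrib[unique(active)])))
    base <- setdiff(active, c("tna", "tnv"))
    if (length(base) > 0) {
      s0 <- aggregate_score(tab, cfg, base)$viral_score
      expect_true(all(aggregate_score(tab, cfg, c(base, "tna"))$viral_score >= s0))
      expect_true(all(aggregate_score(tab, cfg, c(base, "tnv"))$viral_score <= s0))
    }
  }
  # predicted_viral is monotone in viral_score
  agg <- aggregate_score(tab, cfg)
  ord <- order(agg$viral_score)
  expect_true(!is.unsorted(agg$predicted_viral[ord]))
})

test_that("disabling low-confidence subrules changes scores by multiples of 0.5", {
  cfg <- default_score_config()
  cfg_hi <- cfg
  cfg_hi$include_low_confidence <- FALSE
  tab <- random_feature_table(150, seed = 7)
  full <- aggregate_score(tab, cfg)$viral_score
  strict <- aggregate_score(tab, cfg_hi)$viral_score
  delta <- full - strict
  expect_true(all(abs(delta - round(delta / 0.5) * 0.5) < 1e-12))
  # positive low-confidence contributions can only be removed, negative only added back
  for (rid in c("vs2", "vb", "vs", "dvf")) {
    expect_true(all(apply_rule(tab, cfg$rules[[rid]], FALSE) <=
                      apply_rule(tab, cfg$rules[[rid]], TRUE) + 1e-12))
  }
  expect_true(all(apply_rule(tab, cfg$rules$tnv, FALSE) >=
                    apply_rule(tab, cfg$rules$tnv, TRUE)))
})

test_that("config validation fails fast at load time", {
  expect_error(subrule_spec("bad", "no_such_feature >= 1", 1, "confident"),
               "no_such_feature")
  expect_error(subrule_spec("bad", "system('ls')", 1, "confident"),
               "disallowed")
  expect_error(rule_spec("vs2", list(subrule_spec("a", "vs2_score >= 0.9", 1,
                                                  "confident"))),
               "at least two")
  expect_error(
    rule_spec("tna", list(
      subrule_spec("a", "kj_is_viral", 0.5, "low_confidence"),
      subrule_spec("b", "cv_completeness >= 50", -1, "confident")
    )),
    "positive"
  )
  expect_error(
    rule_spec("tnv", list(
      subrule_spec("a", "kj_is_viral", -0.5, "low_confidence"),
      subrule_spec("b", "cv_completeness >= 50", 1, "confident")
    )),
    "negative"
  )
})

test_that("a YAML round-trip reproduces identical scores", {
  cfg <- default_score_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_score_config(cfg, path)
  cfg2 <- read_score_config(path)
  tab <- random_feature_table(80, seed = 3)
  expect_equal(aggregate_score(tab, cfg2), aggregate_score(tab, cfg))
  shipped <- system.file("extdata", "default_rules.yaml", package = "viralscore")
  expect_equal(aggregate_score(tab, read_score_config(shipped)),
               aggregate_score(tab, cfg))
})
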