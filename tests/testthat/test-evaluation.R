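# Independent metric oracles: confusion by per-sequence loop, MCC as the
# Pearson correlation of reconstructed 0/1 truth/prediction vectors.
confusion_oracle <- function(pred, truth) {
  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (i in seq_along(pred)) {
    cell <- if (pred[i] && truth[i]) "tp" else if (pred[i]) "fp"
    else if (truth[i]) "fn" else "tn"
    counts[cell] <- counts[cell] + 1L
  }
  counts
}

metrics_oracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp + fp), rep(0, tn + fn))
  prec <- if (tp + fp > 0) sum(pred & truth) / sum(pred) else 0
  rec <- if (tp + fn > 0) sum(pred & truth) / sum(truth) else 0
  mcc <- if (stats::sd(truth) == 0 || stats::sd(pred) == 0) 0
  else stats::cor(pred, truth)
  c(precision = prec, recall = rec, mcc = mcc)
}

test_that("confusion counts match a per-sequence tally", {
  labels <- tiny_labels(10, 3)
  all_correct <- stats::setNames(labels$is_virus, labels$seq_id)
  expect_equal(confusion(all_correct, labels), c(tp = 3L, fp = 0L, tn = 7L, fn = 0L))
  all_called <- stats::setNames(rep(TRUE, 10), labels$seq_id)
  expect_equal(confusion(all_called, labels), c(tp = 3L, fp = 7L, tn = 0L, fn = 0L))

  set.seed(14)
  labels <- tiny_labels(200, 60)
  pred <- stats::setNames(runif(200) < 0.4, labels$seq_id)
  expect_equal(confusion(pred, labels),
               confusion_oracle(unname(pred), labels$is_virus))
  expect_error(confusion(c(zzz = TRUE), labels), "unlabeled.*zzz")
})

test_that("precision/recall/MCC match the independent oracle on 1,000 random tables", {
  expect_equal(metrics(c(tp = 3, fp = 0, tn = 7, fn = 0)),
               c(precision = 1, recall = 1, mcc = 1))
  expect_equal(metrics(c(tp = 0, fp = 0, tn = 7, fn = 3)),
               c(precision = 0, recall = 0, mcc = 0))
  set.seed(99)
  for (i in seq_len(1000)) {
    counts <- c(tp = sample(0:40, 1), fp = sample(0:40, 1),
                tn = sample(0:40, 1), fn = sample(0:40, 1))
    if (sum(counts) == 0) counts["tn"] <- 1L
    got <- metrics(counts)
    want <- metrics_oracle(counts[["tp"]], counts[["fp"]],
                           counts[["tn"]], counts[["fn"]])
    expect_equal(got, want, tolerance = 1e-12, info = paste(counts, collapse = ","))
  }
})

test_that("MCC is 1 only for perfect two-class splits and is swap-symmetric", {
  set.seed(4)
  for (i in 1:100) {
    counts <- c(tp = sample(0:20, 1), fp = sample(0:20, 1),
                tn = sample(0:20, 1), fn = sample(0:20, 1))
    if (sum(counts) == 0) counts["tp"] <- 1L
    m <- metrics(counts)[["mcc"]]
    perfect <- counts[["fp"]] == 0 && counts[["fn"]] == 0 &&
      counts[["tp"]] > 0 && counts[["tn"]] > 0
    expect_equal(m == 1, perfect)
    swapped <- c(tp = counts[["tn"]], fp = counts[["fn"]],
                 tn = counts[["tp"]], fn = counts[["fp"]])
    expect_equal(metrics(swapped)[["mcc"]], m)
  }
})

test_that("evaluate_all rows are consistent with confusion + metrics", {
  cfg <- default_score_config()
  tab <- random_feature_table(120, seed = 31)
  labels <- tiny_labels(120, 30)
  rs <- list("dvf+vs2" = c("vs2", "dvf"))
  rows <- evaluate_all(list(tab), list(labels), cfg, rs)
  expect_equal(nrow(rows), 1)
  pred <- aggregate_score(tab, cfg, c("vs2", "dvf"))
  cc <- confusion(stats::setNames(pred$predicted_viral, pred$seq_id), labels)
  expect_equal(unlist(rows[c("tp", "fp", "tn", "fn")]),
               cc, ignore_attr = "names")
  expect_equal(rows$mcc, metrics(cc)[["mcc"]])
  expect_false(rows$degenerate)

  # a replicate without true viruses is flagged degenerate, with a warning
  no_virus <- tiny_labels(120, 0)
  expect_warning(
    rows2 <- evaluate_all(list(tab, tab), list(labels, no_virus), cfg, rs),
    "degenerate"
  )
  expect_equal(rows2$degenerate, c(FALSE, TRUE))
  expect_equal(nrow(ruleset_means(rows2)), 1)
  expect_equal(ruleset_means(rows2)$n_replicates, 1)
})

test_that("top groups isolate a clearly superior ruleset and keep ties together", {
  make_rows <- function(mcc_by_ruleset, n_rep = 20, noise = 0.002, seed = 5) {
    set.seed(seed)
    dplyr::bind_rows(lapply(names(mcc_by_ruleset), function(rs) {
      tibble::tibble(
        ruleset = rs, replicate = seq_len(n_rep),
        tp = 1L, fp = 0L, tn = 1L, fn = 0L,
        precision = pmin(1, pmax(0, 0.5 + rnorm(n_rep, 0, noise))),
        recall = pmin(1, pmax(0, 0.5 + rnorm(n_rep, 0, noise))),
        mcc = pmin(1, pmax(-1, mcc_by_ruleset[[rs]] + rnorm(n_rep, 0, noise))),
        degenerate = FALSE
      )
    }))
  }
  rows <- make_rows(c(best = 0.9, a = 0.1, b = 0.1, c = 0.1))
  groups <- top_groups(rows)
  mcc_high <- groups$by_metric |>
    dplyr::filter(metric == "mcc", high) |>
    dplyr::pull(ruleset)
  expect_equal(mcc_high, "best")
  expect_equal(groups$assignment$group[groups$assignment$ruleset == "best"],
               "high_mcc")

  # identical metrics across replicates -> everything in the high group
  ties <- make_rows(c(a = 0.5, b = 0.5, c = 0.5), noise = 0)
  groups_tied <- top_groups(ties)
  expect_true(all(groups_tied$by_metric$high))

  # grouping is invariant to input row order
  shuffled <- rows[sample(nrow(rows)), ]
  groups2 <- top_groups(shuffled)
  expect_equal(groups2$by_metric, groups$by_metric)

  # single replicate degrades to rank-only with a warning
  one <- make_rows(c(a = 0.9, b = 0.2), n_rep = 1)
  expect_warning(g1 <- top_groups(one), "rank only")
  expect_equal(sum(g1$by_metric$high[g1$by_metric$metric == "mcc"]), 1)

  # the t-test alternative behaves the same on well-separated data
  groups_t <- top_groups(rows, test = "t")
  mcc_high_t <- groups_t$by_metric |>
    dplyr::filter(metric == "mcc", high) |>
    dplyr::pull(ruleset)
  expect_equal(mcc_high_t, "best")
})

test_that("proportion_viral counts predictions", {
  expect_equal(proportion_viral(rep(TRUE, 5)), 1)
  expect_equal(proportion_viral(rep(FALSE, 5)), 0)
  expect_equal(proportion_viral(c(rep(TRUE, 44), rep(FALSE, 56))), 0.44)
  expect_equal(proportion_viral(tibble::tibble(predicted_viral = c(TRUE, FALSE))), 0.5)
})

test_that("VOG fractions divide annotated by total genes per true class", {
  tab <- dplyr::bind_rows(
    ft_row("v1", vb_vog_genes = 7L, vb_total_genes = 10L),
    ft_row("v2", vb_vog_genes = 0L, vb_total_genes = 5L),
    ft_row("b1", vb_vog_genes = 9L, vb_total_genes = 10L),
    ft_row("b2", vb_vog_genes = 8L, vb_total_genes = 10L),
    ft_row("b3", vb_vog_genes = 0L, vb_total_genes = 0L),
    ft_row("x1") # no VIBRANT annotation at all
  )
  labels <- tibble::tibble(
    seq_id = c("v1", "v2", "b1", "b2", "b3", "x1"),
    class = c("virus", "virus", "bacteria", "bacteria", "bacteria", "virus"),
    is_virus = class == "virus"
  )
  expect_warning(
    vf <- vog_fraction(tab, labels, viral_calls = labels$seq_id),
    "skipped"
  )
  expect_setequal(vf$seq_id, c("v1", "v2", "b1", "b2"))
  expect_equal(vf$vog_proportion[vf$seq_id == "v1"], 0.7)
  expect_equal(vf$vog_proportion[vf$seq_id == "v2"], 0)
  # planted signal: "bacteria" (mislabeled) show higher VOG fractions
  med <- tapply(vf$vog_proportion, vf$class, stats::median)
  expect_gt(med[["bacteria"]], med[["virus"]])
  # only sequences called viral are included
  vf2 <- vog_fraction(tab, labels, viral_calls = c("v1", "b1"))
  expect_setequal(vf2$seq_id, c("v1", "b1"))
})
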