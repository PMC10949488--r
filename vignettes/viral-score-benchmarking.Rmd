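---
title: "Rule-based viral scoring and ruleset benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based viral scoring and ruleset benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viralscore)
```

## The problem and the model

Identifying bacteriophage and other viral contigs in environmental
metagenomes is usually delegated to one of several *in silico* tools
(VirSorter2, VIBRANT, VirSorter, DeepVirFinder, CheckV, Kaiju, ...), and many
studies union the calls of several tools in the hope of recovering more
viruses. Whether such combinations actually help — or merely accumulate each
tool's false positives — is the question this package operationalizes.

The core construct is an additive per-contig **viral score**. Each of six
**rules** inspects the post-processed output of the tools and contributes a
value; the rule's internal **subrules** encode one condition each, scored by
prediction confidence:

* low confidence: ±0.5
* confident: ±1
* highly confident *not* viral: −3

Four rules are single-tool rules (`vs2`, `vb`, `vs`, `dvf`, one per
identification tool). Within a single-tool rule the subrules are alternative
confidence levels for the same signal, so the rule contributes the *maximum*
of its matched subrule scores — a tool never contributes twice. The two
tuning rules aggregate cross-tool evidence and therefore *sum* their matched
subrules: **tuning addition** (`tna`) adds score for distinctly viral
features (CheckV completeness/quality, a Kaiju viral lineage, ≥2 VirSorter2
hallmark genes) and **tuning removal** (`tnv`) subtracts score for distinctly
cellular features (a non-viral Kaiju classification with zero CheckV viral
genes, a host-gene excess, the absence of any positive signal). A contig with
final score ≥ 1 (inclusive) is predicted viral.

A **ruleset** is any non-empty subset of the six rules — 63 exist — and the
benchmarking layer scores each ruleset against labeled mock metagenomes with
precision, recall and the Matthews correlation coefficient (MCC), which uses
all four confusion-matrix cells and is robust to the strong class imbalance
(~10% viruses) typical of cellular metagenomes.

## Default subrule cutoffs

The shipped condition set (printable via `default_score_config()`, stored
declaratively in `inst/extdata/default_rules.yaml`) follows the tool
developers' published recommendations: VirSorter2 score ≥ 0.9 confident /
≥ 0.5 low confidence / hallmark-supported ≥ 0.5; VIBRANT medium-or-better
quality confident, low-quality draft half a point; VirSorter categories 1–2
confident, 3 low confidence (prophage categories 4–6 are excluded by default
because the positive class here is free viruses, not proviruses);
DeepVirFinder score ≥ 0.9 (≥ 0.7 for half a point) with p < 0.05. These
cutoffs are a reconstruction of standard practice, not a canonical constant:
every condition, score and the threshold itself can be replaced through the
YAML config, and the condition language (validated R expressions over the
feature schema) allows feature-to-feature comparisons such as the host-gene
ratio used by the default `tnv` rule.

Two deliberate semantics are worth calling out. First, *absence* — a tool not
reporting a contig — is distinct from any reported value, propagates as `NA`,
and makes every comparison fail; conditions that want to react to absence say
so explicitly (`is.na(vs2_score)`). Second, the classification threshold is
inclusive (`>=` 1), so a single confident subrule suffices, and two
independent low-confidence half-points also suffice — the
`include_low_confidence = FALSE` switch exists precisely to test whether such
stacked weak evidence helps (it removes all ±0.5 subrules before
evaluation, so scores change only by multiples of 0.5).

## Mock metagenomes

`build_mock()` assembles labeled test sets from class-labeled sequence pools
by sampling with replacement, mirroring cellular-enriched environmental
data: 68% bacteria, 10% archaea, 10% virus, 5% plasmid, 5% protist, 2% fungi,
8,000 contigs per replicate, 5 replicates. Counts are apportioned by largest
remainder, so the default composition is met exactly (5,440 bacteria / 800
viruses at n = 8,000); a multinomial mode reproduces sampling noise when
wanted. Sequences are trimmed to at most 2,099,999 bp (DeepVirFinder rejects
inputs of 2,100 kb and above; the prefix is kept, a choice that matters
little for random-composition pools and is configurable by replacing the
trimmer) and only contigs strictly longer than 3 kb are retained, because
tool accuracy degrades below that length. `fragment_sequences()` additionally
derives 3–5 kb fragments (one per parent, uniform length and start) to probe
short-contig behavior.

Pools can be real reference sequences, but `default_pools()` generates
uniform-ACGT random pools so the whole pipeline runs without downloads. That
choice defines what the bundled benchmarks can and cannot show: simulated
tool outputs are attached to the labels, not to the sequence content, so the
suite validates the *scoring, combination and evaluation machinery* (and the
statistical behavior of rulesets under controlled error rates) — it says
nothing about how the real tools behave on real genomes.

## Simulated tool outputs

`simulate_tool_outputs()` writes the six tools' file dialects for a labeled
contig set under per-tool error profiles (`sensitivity`, `specificity`,
`low_confidence_rate`, `dropout`). A positive draws its feature values
uniformly from the region satisfying that tool's confident default subrule
(e.g. a VirSorter2 score in [0.9, 1]); a low-confidence positive satisfies
only the ±0.5 subrule; a negative satisfies none. CheckV gene counts and
Kaiju lineages stay consistent with the contig's class and sampled status,
which makes the default `tnv` rule behave realistically: most non-viruses
hit the −3 or −1 subrules, and a small fraction of true viruses (missed by
both Kaiju and CheckV) are wrongly penalized. Because the values are drawn
inside the *default* cutoff regions, regenerate fixtures after tightening
thresholds in a custom config.

Default profiles (sensitivity/specificity) are fixed study conditions chosen
to mirror the tools' qualitative reputations: VirSorter2 0.93/0.80
(recall-heavy), VIBRANT 0.55/0.99 (precision-heavy), VirSorter 0.45/0.95,
DeepVirFinder 0.70/0.75 (noisy), CheckV 0.70/0.97 and Kaiju 0.55/0.95
(conservative); 20% of detections drop to the low-confidence tier and 2% of
rows drop out per tool. `low_confidence_rate` is ignored for CheckV and
Kaiju, whose tuning subrules have a single tier each. Tools err independently
by default; `shared_detectability` mixes in a per-contig latent variable
through a Gaussian copula (exact marginals), emulating the empirical fact
that tools overlap heavily on "easy" viruses. With profiles at
sensitivity = specificity = 1 (`noiseless_profiles()`), every ruleset
containing a positive rule attains MCC = 1 — the end-to-end identity the test
suite asserts.

## Benchmarking and grouping

`evaluate_all()` produces one row per (ruleset, replicate) with confusion
counts, precision, recall and MCC; zero-denominator cases return 0 (a ruleset
that calls nothing viral has precision, recall and MCC 0), and replicates
without true viruses are flagged degenerate and excluded from grouping.
`top_groups()` ranks rulesets by mean metric and tests each against the top
ruleset with a paired one-sided Wilcoxon signed-rank test of decrease,
Benjamini–Hochberg adjusted; the "high" group is the top ruleset plus
everything with adjusted p ≥ 0.05. The underlying test is a design choice,
not a reconstruction of prior art: with 5 replicates the Wilcoxon one-sided
floor is 1/32 ≈ 0.031, so after adjustment the grouping is permissive — a
paired t-test is selectable (`test = "t"`) when a sharper parametric
contrast is appropriate. Between-ruleset agreement is summarized by
`overlap_matrix()` as intersection-over-union of the viral call sets; two
rulesets that both call nothing are defined to agree perfectly (overlap 1,
logged when triggered).

## Numerical and design notes

* Determinism: every generator takes an integer seed; per-replicate and
  per-component seeds are derived by `sample.int()` from the master seed, so
  a bundle rerun is byte-identical.
* Ruleset order is deterministic (size, then lexicographic canonical label),
  making all outputs byte-stable.
* `max_positive` returns 0 when no subrule matches; under `sum`, matched
  scores simply add. Whether real single-tool rules cap or sum within a tool
  is undocumented upstream; capping was chosen so one tool cannot vote twice.
* Contig-id reconciliation across tools is performed by a configurable
  regex normalizer (VirSorter2 `||full`-style suffixes, VIBRANT fragment
  suffixes, VirSorter prefixes); a scoring run in which no id is shared by
  two tools aborts rather than silently producing per-tool scores.
* Problem sizes in the shipped tests are deliberately modest (hundreds of
  contigs, 1–3 replicates; the composition checks use the full n = 8,000
  deterministic apportionment), chosen to exercise every code path and the
  binomial/goodness-of-fit tolerances without large fixtures.

## Known limitations

Simulated outputs fake tool *outputs*, not biology: no gene calling, no
sequence-level signal, no taxon-specific difficulty, and per-tool errors are
exchangeable across contigs of a class. Conclusions about which real tool
combination is best for a real environment require running the real tools;
this package contributes the scoring, combination, benchmarking and
reporting layer, plus a fully controlled substrate on which that layer is
provably correct.

## A minimal session

```{r example, eval = FALSE}
bundle_dir <- tempfile("bundle")
make_benchmark_bundle(bundle_dir,
                      composition_spec(total_sequences = 500,
                                       n_replicates = 3),
                      seed = 1)
res <- cmd_benchmark(bundle_dir, out_dir = file.path(bundle_dir, "bench"))
head(dplyr::arrange(ruleset_means(res$metrics), dplyr::desc(mcc)))
subset(res$groups$assignment, group == "high_mcc")
```
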