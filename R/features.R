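#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||%
#' @importFrom stats rnorm runif rbinom rpois rmultinom pnorm wilcox.test
#'   t.test p.adjust setNames
#' @importFrom utils head
NULL

# The six ground-truth sequence classes used in labeled mock metagenomes.
.CLASSES <- c("virus", "bacteria", "archaea", "plasmid", "protist", "fungi")

# The six upstream tools whose output dialects are parsed.
.TOOLS <- c("virsorter2", "vibrant", "virsorter", "deepvirfinder", "checkv", "kaiju")

# The six score rules: four single-tool rules plus tuning addition/removal.
.RULE_IDS <- c("vs2", "vb", "vs", "dvf", "tna", "tnv")

# Per-sequence feature schema: every column of a feature table, with its
# storage type. Absence (the tool did not report the sequence) is NA and is
# distinct from zero throughout.
.FEATURE_TYPES <- c(
  length_bp      = "integer",
  vs2_score      = "double",
  vs2_hallmark   = "integer",
  vs2_group      = "character",
  vb_quality     = "character",
  vb_vog_genes   = "integer",
  vb_total_genes = "integer",
  vs_category    = "integer",
  dvf_score      = "double",
  dvf_pvalue     = "double",
  cv_viral_genes = "integer",
  cv_host_genes  = "integer",
  cv_completeness = "double",
  cv_quality     = "character",
  kj_classified  = "logical",
  kj_taxon_path  = "character",
  kj_is_viral    = "logical"
)

# Which feature columns each tool is allowed to populate.
.TOOL_FEATURES <- list(
  virsorter2    = c("vs2_score", "vs2_hallmark", "vs2_group"),
  vibrant       = c("vb_quality", "vb_vog_genes", "vb_total_genes"),
  virsorter     = c("vs_category"),
  deepvirfinder = c("dvf_score", "dvf_pvalue"),
  checkv        = c("cv_viral_genes", "cv_host_genes", "cv_completeness", "cv_quality"),
  kaiju         = c("kj_classified", "kj_taxon_path")
)

#' Sequence classes, tools and rule identifiers
#'
#' Accessors for the fixed vocabularies of the framework: the six ground-truth
#' sequence classes, the six supported tool-output dialects, and the six rule
#' identifiers (four single-tool rules, `tna` tuning addition, `tnv` tuning
#' removal).
#'
#' @return A character vector.
#' @export
viral_classes <- function() .CLASSES

#' @rdname viral_classes
#' @export
viral_tools <- function() .TOOLS

#' @rdname viral_classes
#' @export
viral_rule_ids <- function() .RULE_IDS

#' Names and types of the per-sequence feature schema
#'
#' @return Named character vector mapping feature name to storage type.
#' @export
feature_schema <- function() .FEATURE_TYPES

.na_of_type <- function(type) {
  switch(type,
    integer = NA_integer_,
    double = NA_real_,
    character = NA_character_,
    logical = NA
  )
}

#' Create an empty feature table for a set of sequence ids
#'
#' All tool features are absent (`NA`), except `vb_quality`, which defaults to
#' `"none"` (VIBRANT reports only sequences it calls viral), and
#' `kj_classified`, which defaults to `FALSE`.
#'
#' @param seq_ids Character vector of sequence identifiers.
#' @param lengths Optional integer vector of sequence lengths (recycled NA).
#' @return A tibble with one row per sequence and all schema columns.
#' @export
empty_feature_table <- function(seq_ids = character(), lengths = NULL) {
  tab <- tibble::tibble(seq_id = as.character(seq_ids))
  for (feat in names(.FEATURE_TYPES)) {
    tab[[feat]] <- rep(.na_of_type(.FEATURE_TYPES[[feat]]), nrow(tab))
  }
  if (!is.null(lengths)) tab$length_bp <- as.integer(lengths)
  tab$vb_quality <- rep("none", nrow(tab))
  tab$kj_classified <- rep(FALSE, nrow(tab))
  tab
}

# Coerce a column to the schema type without silent data loss.
.coerce_feature <- function(x, feat) {
  type <- .FEATURE_TYPES[[feat]]
  switch(type,
    integer = as.integer(x),
    double = as.double(x),
    character = as.character(x),
    logical = as.logical(x)
  )
}
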