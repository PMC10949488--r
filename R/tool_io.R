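# Parsers for the six tool-output dialects and the merge into one feature
# table. Dialect column layouts are pinned; unknown extra columns are ignored
# with a warning (tools add columns across versions).

#' Build a contig-id normalizer
#'
#' Several tools decorate contig names in their output (VirSorter2 appends
#' `||full` / `||lt2gene` / `||<i>_partial`, VIBRANT appends `_fragment_<i>`,
#' VirSorter prefixes `VIRSorter_` and appends `-circular` / `-cat_<i>`).
#' Cross-tool joins fail unless these decorations are stripped. The returned
#' function applies each regex in turn with [sub()].
#'
#' @param patterns Character vector of regexes removed from sequence ids.
#' @return A function mapping a character vector of raw ids to normalized ids.
#' @export
id_normalizer <- function(patterns = c(
                            "\\|\\|.*$",
                            "_fragment_\\d+$",
                            "^VIRSorter_",
                            "-circular$",
                            "-cat_\\d+$"
                          )) {
  force(patterns)
  function(x) {
    x <- trimws(as.character(x))
    for (p in patterns) x <- sub(p, "", x)
    x
  }
}

# Dialect registry: delimiter, pinned columns (name -> parser), and a mapper
# from the raw parsed tibble to schema feature columns.
.parse_int <- function(x) {
  out <- suppressWarnings(as.integer(round(as.numeric(x))))
  bad <- which(!is.na(x) & x != "" & toupper(x) != "NA" & is.na(out))
  attr(out, "bad_rows") <- bad
  out
}
.parse_dbl <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & toupper(x) != "NA" & is.na(out))
  attr(out, "bad_rows") <- bad
  out
}
.parse_chr <- function(x) {
  out <- as.character(x)
  out[!is.na(out) & out == ""] <- NA_character_
  attr(out, "bad_rows") <- integer()
  out
}

.DIALECTS <- list(
  virsorter2 = list(
    delim = "\t", header = TRUE,
    cols = list(seqname = .parse_chr, max_score = .parse_dbl,
                max_score_group = .parse_chr, length = .parse_int,
                hallmark = .parse_int),
    id_col = "seqname",
    map = function(df) tibble::tibble(
      length_bp = df$length, vs2_score = df$max_score,
      vs2_hallmark = df$hallmark, vs2_group = df$max_score_group
    )
  ),
  vibrant = list(
    delim = "\t", header = TRUE,
    cols = list(scaffold = .parse_chr, Quality = .parse_chr),
    id_col = "scaffold",
    map = function(df) tibble::tibble(vb_quality = .normalize_vb_quality(df$Quality))
  ),
  virsorter = list(
    delim = ",", header = TRUE,
    cols = list(contig_id = .parse_chr, category = .parse_int),
    id_col = "contig_id",
    map = function(df) tibble::tibble(vs_category = df$category)
  ),
  deepvirfinder = list(
    delim = "\t", header = TRUE,
    cols = list(name = .parse_chr, len = .parse_int, score = .parse_dbl,
                pvalue = .parse_dbl),
    id_col = "name",
    map = function(df) tibble::tibble(
      length_bp = df$len, dvf_score = df$score, dvf_pvalue = df$pvalue
    )
  ),
  checkv = list(
    delim = "\t", header = TRUE,
    cols = list(contig_id = .parse_chr, contig_length = .parse_int,
                gene_count = .parse_int, viral_genes = .parse_int,
                host_genes = .parse_int, checkv_quality = .parse_chr,
                completeness = .parse_dbl),
    id_col = "contig_id",
    map = function(df) tibble::tibble(
      length_bp = df$contig_length, cv_viral_genes = df$viral_genes,
      cv_host_genes = df$host_genes, cv_completeness = df$completeness,
      cv_quality = .normalize_cv_quality(df$checkv_quality)
    )
  ),
  kaiju = list(
    delim = "\t", header = FALSE,
    cols = list(status = .parse_chr, seq_id = .parse_chr, taxon_id = .parse_int,
                taxon_path = .parse_chr),
    id_col = "seq_id",
    map = function(df) tibble::tibble(
      kj_classified = toupper(df$status) == "C",
      kj_taxon_path = df$taxon_path
    )
  )
)

# VIBRANT writes "high quality draft" etc.; CheckV writes "High-quality" etc.
.normalize_vb_quality <- function(x) {
  y <- tolower(trimws(x))
  y <- sub(" quality draft$", "", y)
  bad <- !is.na(y) & !y %in% c("high", "medium", "low", "none")
  if (any(bad)) {
    stop("vibrant dialect: unknown Quality value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  y
}

.normalize_cv_quality <- function(x) {
  y <- tolower(trimws(x))
  y <- sub("-quality$", "", y)
  y <- sub("-determined$", "_determined", y)
  bad <- !is.na(y) & !y %in% c("complete", "high", "medium", "low", "not_determined")
  if (any(bad)) {
    stop("checkv dialect: unknown checkv_quality value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  y
}

#' Read one tool's output file into feature fragments
#'
#' Parses one of the six pinned tool-output dialects into a tibble of
#' per-sequence feature fragments (`seq_id`, `tool`, plus the feature columns
#' that tool reports). Numeric fields are parsed locale-independently; empty
#' or `NA` cells become absent values; a row whose required field cannot be
#' parsed is an error.
#'
#' @param path Path to the tool output file.
#' @param tool One of `viral_tools()`.
#' @param normalizer Id normalizer applied to contig names at parse time; see
#'   [id_normalizer()].
#' @return A tibble of fragments; zero rows for an empty file.
#' @export
read_tool_output <- function(path, tool, normalizer = id_normalizer()) {
  tool <- match.arg(tool, .TOOLS)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- .DIALECTS[[tool]]
  if (file.size(path) == 0) return(.fragment_skeleton(tool))

  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  header <- d$header
  if (tool == "kaiju" && length(lines) > 0 &&
      startsWith(tolower(lines[[1]]), "status")) {
    header <- TRUE # tolerate an optional header line
  }
  col_names <- if (header) TRUE else names(d$cols)
  raw <- suppressWarnings(readr::read_delim(
    I(lines),
    delim = d$delim, col_names = col_names,
    col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE,
    name_repair = "minimal"
  ))
  required <- names(d$cols)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop(tool, " dialect: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0) {
    warning(tool, " dialect: ignoring unknown column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(.fragment_skeleton(tool))

  parsed <- tibble::as_tibble(raw[required])
  for (col in required) {
    val <- d$cols[[col]](parsed[[col]])
    bad <- attr(val, "bad_rows")
    if (length(bad) > 0) {
      stop(tool, " dialect: unparseable value in column '", col, "' at data row(s) ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
    }
    attr(val, "bad_rows") <- NULL
    parsed[[col]] <- val
  }

  ids <- normalizer(parsed[[d$id_col]])
  if (any(is.na(ids) | ids == "")) {
    stop(tool, " dialect: empty sequence id at data row(s) ",
         paste(head(which(is.na(ids) | ids == ""), 10), collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(tool, " dialect: duplicate sequence id(s) within one file: ",
         paste(head(dup, 10), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_cols(tibble::tibble(seq_id = ids, tool = tool), d$map(parsed))
  for (feat in intersect(names(out), names(.FEATURE_TYPES))) {
    out[[feat]] <- .coerce_feature(out[[feat]], feat)
  }
  out
}

.fragment_skeleton <- function(tool) {
  out <- tibble::tibble(seq_id = character(), tool = character())
  feats <- .TOOL_FEATURES[[tool]]
  if (tool %in% c("virsorter2", "deepvirfinder", "checkv")) {
    feats <- c("length_bp", feats)
  }
  for (feat in feats) out[[feat]] <- .na_of_type(.FEATURE_TYPES[[feat]])[0]
  out
}

#' Read a VIBRANT annotation table and count VOG-annotated genes
#'
#' VIBRANT's per-protein annotation table (columns `scaffold`, `protein`,
#' `VOG`; one row per predicted protein, `VOG` empty when no VOG hit) is
#' reduced to per-scaffold gene counts: `vb_total_genes` = number of proteins,
#' `vb_vog_genes` = number with a VOG annotation.
#'
#' @inheritParams read_tool_output
#' @return A tibble of vibrant fragments with the two count features.
#' @export
read_vibrant_annotations <- function(path, normalizer = id_normalizer()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(tibble::tibble(seq_id = character(), tool = character(),
                          vb_vog_genes = integer(), vb_total_genes = integer()))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c("scaffold", "protein", "VOG"), names(raw))
  if (length(missing) > 0) {
    stop("vibrant annotation: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$seq_id <- normalizer(raw$scaffold)
  raw$has_vog <- !is.na(raw$VOG) & nzchar(trimws(raw$VOG))
  raw |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(vb_vog_genes = as.integer(sum(.data$has_vog)),
                     vb_total_genes = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(tool = "vibrant",
                  vb_total_genes = as.integer(.data$vb_total_genes)) |>
    dplyr::select("seq_id", "tool", "vb_vog_genes", "vb_total_genes")
}

#' Merge tool-output fragments into one per-sequence feature table
#'
#' Outer union of sequence ids across all fragments (and the optional length
#' map); features a tool did not report stay absent (`NA`). `kj_is_viral` is
#' derived from the Kaiju taxon path: `TRUE` iff the first-rank token equals
#' `"Viruses"` (case-insensitive); unclassified sequences leave it absent.
#' Conflicting values for the same (tool, sequence, feature) are an error.
#' Lengths reported by tools are used when no explicit length map is given;
#' an explicit map (e.g. from FASTA) wins, with a warning on disagreement.
#'
#' @param fragments List of fragment tibbles from [read_tool_output()] /
#'   [read_vibrant_annotations()] (may be empty).
#' @param lengths Optional named integer vector or tibble
#'   (`seq_id`, `length_bp`) giving authoritative sequence lengths.
#' @return A feature table: one row per `seq_id`, all schema columns, sorted
#'   by `seq_id`.
#' @export
merge_features <- function(fragments = list(), lengths = NULL) {
  stopifnot(is.list(fragments))
  if (!is.null(lengths) && !is.data.frame(lengths)) {
    lengths <- tibble::tibble(seq_id = names(lengths),
                              length_bp = as.integer(lengths))
  }
  frames <- purrr::keep(fragments, ~ nrow(.x) > 0)

  all_ids <- character()
  per_tool <- list()
  for (tool in .TOOLS) {
    tf <- purrr::keep(frames, ~ .x$tool[[1]] == tool)
    if (length(tf) == 0) next
    df <- dplyr::bind_rows(tf)
    df$tool <- NULL
    df <- .collapse_tool_rows(df, tool)
    all_ids <- union(all_ids, df$seq_id)
    per_tool[[tool]] <- df
  }
  if (!is.null(lengths)) all_ids <- union(all_ids, lengths$seq_id)

  out <- empty_feature_table(sort(all_ids))
  tool_lengths <- rep(NA_integer_, nrow(out))
  for (tool in names(per_tool)) {
    df <- per_tool[[tool]]
    idx <- match(df$seq_id, out$seq_id)
    for (feat in setdiff(names(df), c("seq_id", "length_bp"))) {
      vals <- .coerce_feature(df[[feat]], feat)
      keep <- !is.na(vals)
      out[[feat]][idx[keep]] <- vals[keep]
    }
    if ("length_bp" %in% names(df)) {
      lv <- as.integer(df$length_bp)
      keep <- !is.na(lv)
      conflict <- keep & !is.na(tool_lengths[idx]) & tool_lengths[idx] != lv
      if (any(conflict)) {
        warning("conflicting tool-reported lengths for ",
                paste(head(df$seq_id[conflict], 5), collapse = ", "),
                "; keeping the first value seen", call. = FALSE)
        keep <- keep & !conflict
      }
      tool_lengths[idx[keep]] <- lv[keep]
    }
  }
  out$length_bp <- tool_lengths
  if (!is.null(lengths)) {
    idx <- match(lengths$seq_id, out$seq_id)
    disagree <- !is.na(out$length_bp[idx]) &
      out$length_bp[idx] != as.integer(lengths$length_bp)
    if (any(disagree)) {
      warning("tool-reported lengths disagree with FASTA for ",
              paste(head(lengths$seq_id[disagree], 5), collapse = ", "),
              "; FASTA lengths kept", call. = FALSE)
    }
    out$length_bp[idx] <- as.integer(lengths$length_bp)
  }

  # Derived feature: viral superkingdom call from the Kaiju lineage string.
  first_rank <- tolower(trimws(sub(";.*$", "", out$kj_taxon_path)))
  out$kj_is_viral <- ifelse(out$kj_classified & !is.na(out$kj_taxon_path),
                            first_rank == "viruses", NA)
  out
}

# Collapse possibly-duplicated per-tool rows (e.g. VIBRANT quality +
# annotation fragments); identical values coalesce, conflicts are an error.
.collapse_tool_rows <- function(df, tool) {
  if (!anyDuplicated(df$seq_id)) return(df)
  feats <- setdiff(names(df), "seq_id")
  out <- df |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(feats), function(x) {
      v <- unique(x[!is.na(x)])
      if (length(v) > 1) {
        stop("conflicting values from tool '", tool, "' for one sequence",
             call. = FALSE)
      }
      if (length(v) == 0) x[1] else v
    }), .groups = "drop")
  out
}

#' Read a ground-truth label table
#'
#' Two-column delimited file (`seq_id`, class), tab or comma separated, with
#' an optional header. Classes outside the six known ones are an error naming
#' the token and line.
#'
#' @param path Path to the label file.
#' @return Tibble with columns `seq_id`, `class`, `is_virus`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(seq_id = character(), class = character(),
                          is_virus = logical()))
  }
  delim <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  lens <- lengths(fields)
  if (any(lens < 2)) {
    stop("label file: expected two delimited columns at line ",
         which(lens < 2)[1], call. = FALSE)
  }
  first_line <- 1L
  second <- tolower(trimws(fields[[1]][2]))
  if (second %in% c("class", "true_class", "label")) first_line <- 2L
  if (first_line > length(lines)) {
    return(tibble::tibble(seq_id = character(), class = character(),
                          is_virus = logical()))
  }
  rows <- fields[first_line:length(fields)]
  seq_id <- trimws(vapply(rows, `[`, character(1), 1))
  class <- tolower(trimws(vapply(rows, `[`, character(1), 2)))
  bad <- which(!class %in% .CLASSES)
  if (length(bad) > 0) {
    stop("label file: unknown class token '", class[bad[1]], "' at line ",
         bad[1] + first_line - 1L, call. = FALSE)
  }
  dup <- unique(seq_id[duplicated(seq_id)])
  if (length(dup) > 0) {
    stop("label file: duplicate sequence id(s): ",
         paste(head(dup, 10), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(seq_id = seq_id, class = class, is_virus = class == "virus")
}

#' Sequence lengths from a FASTA file
#'
#' @param path FASTA path.
#' @return Tibble (`seq_id`, `length_bp`).
#' @export
read_fasta_lengths <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  tibble::tibble(seq_id = ids, length_bp = Biostrings::width(seqs))
}
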