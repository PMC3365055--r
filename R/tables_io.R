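#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr across all_of any_of arrange bind_rows count distinct
#'   filter group_by inner_join left_join mutate n pull rename row_number
#'   select semi_join summarise ungroup
#' @importFrom tibble tibble as_tibble
NULL

# All interchange files are TAB-separated with "." as decimal point and no
# locale-dependent parsing; readr is configured accordingly throughout.
.tsv_locale <- function() readr::locale(decimal_mark = ".", grouping_mark = "")

.read_tsv <- function(path, col_types = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  readr::read_tsv(path, col_types = col_types, locale = .tsv_locale(),
                  progress = FALSE, comment = "", na = c("NA", ""),
                  show_col_types = FALSE)
}

#' Read a transcript-level count table with its annotation and sample groups
#'
#' Reads the three TSV files that define an RNA-seq experiment at the level
#' this pipeline starts from: a transcript-by-sample matrix of aligned read
#' counts, a transcript annotation (gene membership, symbol, transcript
#' length) and a sample-to-group assignment. All three are validated
#' strictly; malformed input fails with a message naming the offending
#' rows or columns.
#'
#' @param path TSV whose header is `transcript_id` followed by one column
#'   per sample; all count cells must be non-negative integers.
#' @param annotation_path TSV with columns `transcript_id`, `gene_id`,
#'   `gene_symbol`, `length_bp`. `gene_symbol` may be empty (such
#'   transcripts are quantified but excluded from symbol-level analyses);
#'   `length_bp` must be a positive integer.
#' @param groups_path TSV with columns `sample_id`, `group`, one row per
#'   sample in the count table.
#' @return A list with elements `counts` (tibble: `transcript_id` +
#'   one integer column per sample), `annotation` (tibble) and `groups`
#'   (tibble), each validated.
#' @export
read_count_table <- function(path, annotation_path, groups_path) {
  counts <- .read_tsv(path)
  if (names(counts)[1] != "transcript_id") {
    abort(paste0("malformed count header: first column must be 'transcript_id', got '",
                 names(counts)[1], "'"))
  }
  if (ncol(counts) < 2) abort("count table has no sample columns")
  annotation <- read_annotation(annotation_path)
  groups <- read_groups(groups_path)
  validate_counts(counts, groups)
  validate_annotation(annotation, counts)
  list(counts = counts, annotation = annotation, groups = groups)
}

#' Read a transcript annotation table
#'
#' @param path TSV with columns `transcript_id`, `gene_id`, `gene_symbol`,
#'   `length_bp`.
#' @return Validated tibble; `gene_symbol` is upper-cased at read time so
#'   fish (lower-case) and human (upper-case) symbol conventions compare
#'   equal downstream. Missing symbols become `NA`.
#' @export
read_annotation <- function(path) {
  ann <- .read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    gene_id = readr::col_character(),
    gene_symbol = readr::col_character(),
    length_bp = readr::col_double()
  ))
  need <- c("transcript_id", "gene_id", "gene_symbol", "length_bp")
  miss <- setdiff(need, names(ann))
  if (length(miss)) abort(paste0("annotation missing column(s): ",
                                 paste(miss, collapse = ", ")))
  dup <- ann$transcript_id[duplicated(ann$transcript_id)]
  if (length(dup)) abort(paste0("duplicate transcript_id in annotation: ",
                                paste(unique(dup), collapse = ", ")))
  bad <- ann$transcript_id[is.na(ann$length_bp) | ann$length_bp < 1 |
                             ann$length_bp != round(ann$length_bp)]
  if (length(bad)) abort(paste0("length_bp must be a positive integer; offending transcript(s): ",
                                paste(bad, collapse = ", ")))
  ann$gene_symbol <- toupper(trimws(ann$gene_symbol))
  ann$gene_symbol[!is.na(ann$gene_symbol) & ann$gene_symbol == ""] <- NA_character_
  ann
}

#' Read a sample-to-group assignment table
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return Validated tibble.
#' @export
read_groups <- function(path) {
  groups <- .read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character()))
  miss <- setdiff(c("sample_id", "group"), names(groups))
  if (length(miss)) abort(paste0("groups table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  dup <- groups$sample_id[duplicated(groups$sample_id)]
  if (length(dup)) abort(paste0("duplicate sample_id in groups: ",
                                paste(unique(dup), collapse = ", ")))
  if (any(is.na(groups$group) | groups$group == "")) {
    bad <- groups$sample_id[is.na(groups$group) | groups$group == ""]
    abort(paste0("missing group label for sample(s): ", paste(bad, collapse = ", ")))
  }
  groups
}

#' Validate a count tibble against a group table
#'
#' Checks the invariants of the raw-count container: unique transcript and
#' sample identifiers, integer counts that are non-negative and finite, and
#' a group label for every sample column.
#'
#' @param counts Tibble with `transcript_id` plus one numeric column per sample.
#' @param groups Optional tibble with `sample_id`, `group`; when supplied,
#'   every sample column must have a label.
#' @return `counts`, invisibly, on success; otherwise an error naming the
#'   offending row/column.
#' @export
validate_counts <- function(counts, groups = NULL) {
  if (names(counts)[1] != "transcript_id") abort("first column must be 'transcript_id'")
  ids <- counts$transcript_id
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) abort(paste0("duplicate transcript_id: ", paste(dup, collapse = ", ")))
  samples <- setdiff(names(counts), "transcript_id")
  if (anyDuplicated(samples)) abort("duplicate sample columns in count table")
  for (s in samples) {
    v <- counts[[s]]
    if (!is.numeric(v)) abort(paste0("non-numeric counts in column '", s, "'"))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad)) {
      abort(paste0("invalid count (must be integer >= 0) at transcript '",
                   ids[bad[1]], "', sample '", s, "'"))
    }
  }
  if (!is.null(groups)) {
    unlabelled <- setdiff(samples, groups$sample_id)
    if (length(unlabelled)) abort(paste0("sample(s) without group label: ",
                                         paste(unlabelled, collapse = ", ")))
  }
  invisible(counts)
}

#' Validate an annotation against a count table
#'
#' Every transcript present in the counts must be annotated.
#'
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param counts Count tibble.
#' @return `annotation`, invisibly.
#' @export
validate_annotation <- function(annotation, counts) {
  missing_ids <- setdiff(counts$transcript_id, annotation$transcript_id)
  if (length(missing_ids)) {
    abort(paste0("transcript(s) present in counts but absent from annotation: ",
                 paste(utils::head(missing_ids, 20), collapse = ", "),
                 if (length(missing_ids) > 20) sprintf(" (and %d more)", length(missing_ids) - 20) else ""))
  }
  invisible(annotation)
}

#' Read a fish-to-human ortholog mapping table
#'
#' One fish gene maps to at most one human symbol; one human symbol may map
#' to several fish genes (teleost paralog duplicates). Exact duplicate rows
#' are dropped; the number of human symbols hit by more than one fish gene
#' is reported with a message.
#'
#' @param path TSV with columns `fish_gene_id`, `fish_symbol`, `human_symbol`.
#' @return Tibble with the three columns, symbols upper-cased, deduplicated.
#' @export
read_ortholog_table <- function(path) {
  orth <- .read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("fish_gene_id", "fish_symbol", "human_symbol")
  miss <- setdiff(need, names(orth))
  if (length(miss)) abort(paste0("ortholog table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (nrow(orth) == 0) abort("ortholog table is empty")
  orth <- orth |>
    mutate(fish_symbol = toupper(trimws(.data$fish_symbol)),
           human_symbol = toupper(trimws(.data$human_symbol))) |>
    filter(!is.na(.data$human_symbol), .data$human_symbol != "") |>
    distinct()
  if (nrow(orth) == 0) abort("ortholog table has no rows with a human symbol")
  dup_pair <- orth |> count(.data$fish_gene_id, .data$human_symbol) |> filter(n > 1)
  if (nrow(dup_pair)) {
    abort(paste0("conflicting duplicate (fish_gene_id, human_symbol) pairs: ",
                 paste(dup_pair$fish_gene_id, collapse = ", ")))
  }
  multi <- orth |> count(.data$human_symbol) |> filter(n > 1)
  inform(sprintf("ortholog table: %d rows; %d human symbol(s) mapped by >1 fish gene",
                 nrow(orth), nrow(multi)))
  orth
}

#' Read a gene-signature file
#'
#' One symbol per line; lines starting with `#` are comments. Symbols are
#' upper-cased and deduplicated.
#'
#' @param path Plain-text signature file.
#' @param name Signature name (e.g. `"motif1"`).
#' @param direction One of `"up"`, `"down"`, `"unsigned"`.
#' @return An object of class `signature_set`: a list with `name`,
#'   `direction` and the character vector `symbols`.
#' @export
read_signature <- function(path, name, direction = c("unsigned", "up", "down")) {
  direction <- match.arg(direction)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  symbols <- unique(toupper(lines))
  if (length(symbols) == 0) abort(paste0("signature file yields an empty set: ", path))
  signature_set(symbols, name = name, direction = direction)
}

#' Construct a signature set in memory
#'
#' @param symbols Character vector of gene symbols (case-normalized here).
#' @param name Signature name.
#' @param direction `"up"`, `"down"` or `"unsigned"`.
#' @return A `signature_set` object.
#' @export
signature_set <- function(symbols, name, direction = c("unsigned", "up", "down")) {
  direction <- match.arg(direction)
  symbols <- unique(toupper(trimws(symbols)))
  symbols <- symbols[symbols != "" & !is.na(symbols)]
  if (length(symbols) == 0) abort("signature set must be non-empty")
  structure(list(name = name, direction = direction, symbols = symbols),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set '%s' (%s): %d symbols>\n", x$name, x$direction,
              length(x$symbols)))
  invisible(x)
}

#' Write a result table to TSV
#'
#' Fixed, documented column order (the tibble's own order), TAB separator,
#' "." decimal mark. Double columns are written with 17 significant digits,
#' so they round-trip bit-exactly through [read_result_table()].
#'
#' @param result Any result tibble (differential expression, splice,
#'   concordance, overlap, enrichment ...).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, path) {
  stopifnot(is.data.frame(result))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(paste0("unwritable path (directory does not exist): ", path))
  out <- as_tibble(result)
  # 17 significant digits restore the exact double bit pattern on re-read
  for (j in seq_along(out)) {
    if (is.double(out[[j]]) && !inherits(out[[j]], c("integer64", "Date", "POSIXt"))) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  readr::write_tsv(out, path, progress = FALSE, na = "NA")
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#'
#' Columns are read as text and converted with R's own (correctly rounded)
#' numeric parser, so doubles written by [write_result_table()] are
#' restored bit-exactly.
#'
#' @param path TSV path.
#' @return Tibble with column types inferred from the full column contents.
#' @export
read_result_table <- function(path) {
  out <- .read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  num_re <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$|^[+-]?(Inf|NaN)$"
  int_re <- "^[+-]?[0-9]{1,9}$"
  for (j in seq_along(out)) {
    v <- out[[j]]
    ok <- !is.na(v)
    if (!any(ok)) next
    if (all(grepl(int_re, v[ok]))) {
      out[[j]] <- as.integer(v)
    } else if (all(grepl(num_re, v[ok]))) {
      out[[j]] <- as.numeric(v)
    } else if (all(v[ok] %in% c("TRUE", "FALSE"))) {
      out[[j]] <- as.logical(v)
    }
  }
  out
}
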