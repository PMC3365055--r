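# Isoform-switch detection: for every multi-isoform gene, correlate each
# expressed transcript's per-group RPKM profile with the gene's mean profile
# and take the range (max - min) of those correlations (RC). A range above 1
# means at least two isoforms move in clearly different directions across
# the sample groups.

#' Genes annotated with more than one transcript
#'
#' @param annotation Annotation tibble.
#' @return Tibble `gene_id`, `n_isoforms` restricted to genes with >= 2
#'   annotated transcripts.
#' @export
multi_isoform_genes <- function(annotation) {
  annotation |>
    count(.data$gene_id, name = "n_isoforms") |>
    filter(.data$n_isoforms >= 2)
}

# per-transcript per-group mean RPKM for one gene; rows transcripts,
# columns groups in the requested order
.group_profiles <- function(expr, transcripts, groups, group_order) {
  m <- .count_matrix(expr)
  rows <- match(transcripts, rownames(m))
  if (anyNA(rows)) abort("transcript(s) missing from expression matrix")
  sub <- m[rows, , drop = FALSE]
  prof <- vapply(group_order, function(g) {
    cols <- intersect(groups$sample_id[groups$group == g], colnames(sub))
    if (!length(cols)) abort(paste0("no samples for group: ", g))
    rowMeans(sub[, cols, drop = FALSE])
  }, numeric(length(rows)))
  prof <- matrix(prof, nrow = length(rows),
                 dimnames = list(transcripts, group_order))
  prof
}

#' Per-group mean expression profile of a gene
#'
#' Averages each transcript's RPKM over the samples of each group, then
#' averages transcripts.
#'
#' @param expr An `rpkm_tbl`.
#' @param gene Gene id.
#' @param annotation Annotation tibble.
#' @param groups Tibble `sample_id`, `group`.
#' @param group_order Group labels in profile order (default
#'   `c("HP", "XE", "MM", "UM")` intersected with the available groups).
#' @return Named numeric vector, one value per group.
#' @export
gene_mean_profile <- function(expr, gene, annotation, groups,
                              group_order = NULL) {
  group_order <- .resolve_group_order(groups, group_order)
  tr <- annotation$transcript_id[annotation$gene_id == gene]
  if (!length(tr)) abort(paste0("gene absent from annotation: ", gene))
  prof <- .group_profiles(expr, tr, groups, group_order)
  colMeans(prof)
}

.resolve_group_order <- function(groups, group_order) {
  if (is.null(group_order)) {
    default <- c("HP", "XE", "MM", "UM")
    group_order <- if (all(unique(groups$group) %in% default)) {
      intersect(default, unique(groups$group))
    } else unique(groups$group)
  }
  group_order
}

# correlation range over the rows of a profile matrix; rows with undefined
# (zero-variance) profiles are dropped; needs >= 2 defined rows
.rc_from_profiles <- function(prof, method = "pearson") {
  gm <- colMeans(prof)
  ok <- apply(prof, 1, stats::sd) > 0 & stats::sd(gm) > 0
  cors <- rep(NA_real_, nrow(prof))
  if (stats::sd(gm) > 0) {
    cors[ok] <- apply(prof[ok, , drop = FALSE], 1, function(x)
      stats::cor(x, gm, method = method))
  }
  defined <- cors[!is.na(cors)]
  rc <- if (length(defined) >= 2) max(defined) - min(defined) else NA_real_
  list(correlations = cors, rc = rc)
}

#' RC statistic for one gene
#'
#' Pearson (or Spearman) correlation of each transcript's ordered per-group
#' profile with the gene-mean profile; RC is the max minus min of the
#' defined correlations, hence lies in [0, 2]. Transcripts with
#' zero-variance profiles have undefined correlation and are dropped; if
#' fewer than two defined correlations remain RC is `NA`.
#'
#' @inheritParams gene_mean_profile
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param gate Expression gate; transcripts below it in every group are
#'   excluded from both the correlation set and the gene mean.
#' @return One-row tibble: `gene_id`, `n_isoforms`, `n_expressed`,
#'   `rc_gene`, `correlations` (semicolon-joined, annotation order),
#'   `category`.
#' @export
rc_gene <- function(expr, gene, annotation, groups, group_order = NULL,
                    method = c("pearson", "spearman"),
                    gate = expression_gate(expr)) {
  method <- match.arg(method)
  group_order <- .resolve_group_order(groups, group_order)
  tr <- annotation$transcript_id[annotation$gene_id == gene]
  if (length(tr) < 2) abort(paste0("gene is not multi-isoform: ", gene))
  prof <- .group_profiles(expr, tr, groups, group_order)
  .classify_one(gene, prof, gate, method)
}

.classify_one <- function(gene, prof, gate, method) {
  expressed <- apply(prof, 1, function(x) any(x >= gate))
  n_expr <- sum(expressed)
  if (n_expr == 0) {
    return(tibble(gene_id = gene, n_isoforms = nrow(prof), n_expressed = 0L,
                  rc_gene = NA_real_, correlations = NA_character_,
                  category = "not_expressed"))
  }
  if (n_expr == 1) {
    return(tibble(gene_id = gene, n_isoforms = nrow(prof), n_expressed = 1L,
                  rc_gene = NA_real_, correlations = NA_character_,
                  category = "single_transcript"))
  }
  res <- .rc_from_profiles(prof[expressed, , drop = FALSE], method)
  category <- if (!is.na(res$rc) && res$rc > 1) "differential" else "same_direction"
  tibble(gene_id = gene, n_isoforms = nrow(prof), n_expressed = as.integer(n_expr),
         rc_gene = res$rc,
         correlations = paste(sprintf("%.6g", res$correlations), collapse = ";"),
         category = category)
}

#' Classify all multi-isoform genes by isoform behavior
#'
#' Four mutually exclusive categories partition the multi-isoform gene set:
#' `not_expressed` (no transcript passes the gate in any scoped group),
#' `single_transcript` (exactly one does), `differential` (RC > 1) and
#' `same_direction` (RC <= 1 or undefined).
#'
#' @inheritParams rc_gene
#' @param scope Which groups count for the expression gate:
#'   `"any_group"` (default: all groups, including the benign reference) or
#'   `"tumor_groups_only"`.
#' @param tumor_groups Labels treated as tumors when
#'   `scope = "tumor_groups_only"` (default: every group except the first in
#'   `group_order`).
#' @return Tibble of class `splice_result`, one row per multi-isoform gene:
#'   `gene_id`, `gene_symbol`, `n_isoforms`, `n_expressed`, `rc_gene`,
#'   `correlations`, `category`.
#' @export
splice_analysis <- function(expr, annotation, groups, group_order = NULL,
                            method = c("pearson", "spearman"),
                            gate = expression_gate(expr),
                            scope = c("any_group", "tumor_groups_only"),
                            tumor_groups = NULL) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  group_order <- .resolve_group_order(groups, group_order)
  gate_groups <- if (scope == "tumor_groups_only") {
    tumor_groups %||% group_order[-1]
  } else group_order
  multi <- multi_isoform_genes(annotation)
  m <- .count_matrix(expr)
  # per-group means for all transcripts at once
  gm_all <- vapply(group_order, function(g) {
    cols <- intersect(groups$sample_id[groups$group == g], colnames(m))
    if (!length(cols)) abort(paste0("no samples for group: ", g))
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(gm_all) <- rownames(m)
  ann <- annotation |> semi_join(multi, by = "gene_id")
  tr_by_gene <- split(ann$transcript_id, ann$gene_id)
  rows <- purrr::map(names(tr_by_gene), function(g) {
    prof <- gm_all[tr_by_gene[[g]], , drop = FALSE]
    # gate decision uses the scoped groups; correlations use the full profile
    gate_prof <- prof[, gate_groups, drop = FALSE]
    expressed <- apply(gate_prof, 1, function(x) any(x >= gate))
    n_expr <- sum(expressed)
    if (n_expr <= 1) {
      return(tibble(gene_id = g, n_isoforms = nrow(prof),
                    n_expressed = as.integer(n_expr),
                    rc_gene = NA_real_, correlations = NA_character_,
                    category = if (n_expr == 0) "not_expressed" else "single_transcript"))
    }
    res <- .rc_from_profiles(prof[expressed, , drop = FALSE], method)
    tibble(gene_id = g, n_isoforms = nrow(prof), n_expressed = as.integer(n_expr),
           rc_gene = res$rc,
           correlations = paste(sprintf("%.6g", res$correlations), collapse = ";"),
           category = if (!is.na(res$rc) && res$rc > 1) "differential" else "same_direction")
  })
  out <- bind_rows(rows)
  sym <- annotation |> distinct(.data$gene_id, .data$gene_symbol)
  out <- out |>
    left_join(sym, by = "gene_id") |>
    select("gene_id", "gene_symbol", dplyr::everything())
  class(out) <- c("splice_result", class(out))
  out
}

#' Bar chart of the isoform-behavior categories
#'
#' @param object A `splice_result` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.splice_result <- function(object, ...) {
  counts <- object |> count(.data$category)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Multi-isoform gene classification") +
    ggplot2::theme_minimal()
}
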