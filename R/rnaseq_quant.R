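# Quantification: RPKM, expression gating, size factors, base means and the
# transcript-level screens (presence/absence, fold filters, MA values).

.sample_cols <- function(tbl) setdiff(names(tbl), c("transcript_id", "id"))

.count_matrix <- function(counts) {
  m <- as.matrix(counts[.sample_cols(counts)])
  rownames(m) <- counts$transcript_id
  storage.mode(m) <- "double"
  m
}

.matrix_to_tbl <- function(m, id_col = "transcript_id") {
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  out[c(id_col, setdiff(names(out), id_col))]
}

#' Reads per kilobase of transcript per million aligned reads
#'
#' RPKM = 1e9 * C / (L * N) with C the transcript's read count, L its length
#' in bp and N the sample's total aligned reads. An inclusive expression
#' gate (RPKM >= `gate`) is recorded alongside; downstream presence calls
#' use it.
#'
#' @param counts Count tibble (`transcript_id` + one column per sample).
#' @param annotation Annotation tibble providing `length_bp` per transcript.
#' @param gate Expression threshold in RPKM units (default 2); a transcript
#'   is called expressed in a sample when its RPKM is >= `gate`.
#' @return Tibble of RPKM values, same shape as `counts`, with attributes
#'   `gate` (the threshold) and class `rpkm_tbl`.
#' @export
rpkm <- function(counts, annotation, gate = 2) {
  validate_counts(counts)
  validate_annotation(annotation, counts)
  m <- .count_matrix(counts)
  len <- annotation$length_bp[match(rownames(m), annotation$transcript_id)]
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  r <- 1e9 * sweep(m / len, 2, totals, "/")
  out <- .matrix_to_tbl(r)
  attr(out, "gate") <- gate
  class(out) <- c("rpkm_tbl", class(out))
  out
}

#' Expression gate of an RPKM table
#' @param x An `rpkm_tbl` (from [rpkm()]).
#' @return The gate threshold (numeric scalar).
#' @export
expression_gate <- function(x) attr(x, "gate") %||% 2

#' Logical expressed/not-expressed mask for an RPKM table
#' @inheritParams expression_gate
#' @param gate Override the stored gate.
#' @return Tibble of logicals, same shape as `x`.
#' @export
expressed_mask <- function(x, gate = expression_gate(x)) {
  m <- .count_matrix(x) >= gate
  .matrix_to_tbl(m)
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median of its count ratios to the
#' per-transcript geometric-mean pseudo-reference, computed over transcripts
#' with strictly positive counts in every sample. The factors define the
#' effective library sizes used to normalize counts.
#'
#' @param counts Count tibble.
#' @return Tibble with columns `sample_id`, `size_factor`.
#' @export
size_factors <- function(counts) {
  m <- .count_matrix(counts)
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) abort("no transcript with positive counts in all samples; size factors undefined")
  lm <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(lm)  # log geometric mean
  sf <- apply(lm, 2, function(col) exp(stats::median(col - ref)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

.sf_vector <- function(sf, samples) {
  if (is.data.frame(sf)) {
    v <- sf$size_factor[match(samples, sf$sample_id)]
    if (anyNA(v)) abort("size factors missing for some samples")
    v
  } else {
    v <- sf[samples]
    if (anyNA(v)) abort("size factors missing for some samples")
    unname(v)
  }
}

#' Base mean of size-factor-normalized counts
#'
#' The base mean of an id is the mean over samples of count/size_factor;
#' per-group base means are returned alongside when a group table is given.
#' The conventional expression gate on this scale is strict (`> 10`).
#'
#' @param counts Count tibble.
#' @param sf Size factors as returned by [size_factors()].
#' @param groups Optional tibble `sample_id`, `group`.
#' @return Tibble with `transcript_id`, `base_mean`, and one
#'   `base_mean_<group>` column per group when `groups` is supplied.
#' @export
base_mean <- function(counts, sf, groups = NULL) {
  m <- .count_matrix(counts)
  v <- .sf_vector(sf, colnames(m))
  norm <- sweep(m, 2, v, "/")
  out <- tibble(transcript_id = rownames(m), base_mean = unname(rowMeans(norm)))
  if (!is.null(groups)) {
    for (g in unique(groups$group)) {
      cols <- groups$sample_id[groups$group == g]
      cols <- intersect(cols, colnames(norm))
      out[[paste0("base_mean_", g)]] <- unname(rowMeans(norm[, cols, drop = FALSE]))
    }
  }
  out
}

#' Partition transcripts by presence in two samples
#'
#' Presence is the inclusive RPKM gate; the four categories are disjoint and
#' cover every transcript.
#'
#' @param expr An `rpkm_tbl`.
#' @param sample_a,sample_b Sample column names.
#' @param gate Gate override (default: stored gate).
#' @return Tibble `transcript_id`, `status` with status one of
#'   `only_a`, `only_b`, `both`, `neither`.
#' @export
presence_partition <- function(expr, sample_a, sample_b, gate = expression_gate(expr)) {
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(expr)) abort(paste0("unknown sample id: ", s))
  }
  a <- expr[[sample_a]] >= gate
  b <- expr[[sample_b]] >= gate
  status <- dplyr::case_when(a & b ~ "both", a & !b ~ "only_a",
                             !a & b ~ "only_b", TRUE ~ "neither")
  tibble(transcript_id = expr$transcript_id,
         status = factor(status, levels = c("only_a", "only_b", "both", "neither")))
}

#' Transcripts at least `min_fold`-fold higher in one sample than another
#'
#' Keeps transcripts expressed in `sample_a` whose pseudocounted RPKM ratio
#' `(a + epsilon) / (b + epsilon)` is `>= min_fold`. Presence calls use no
#' pseudocount; the fold value does, so on/off transcripts get a finite fold.
#'
#' @param expr An `rpkm_tbl`.
#' @param sample_a,sample_b Sample column names (fold is a over b).
#' @param min_fold Minimum fold (must be > 1); the comparison is inclusive.
#' @param epsilon Pseudocount in RPKM units added to both sides (default 1).
#' @param gate Expression gate for the `sample_a` presence requirement.
#' @return Tibble `transcript_id`, `rpkm_a`, `rpkm_b`, `fold`, sorted by
#'   decreasing fold.
#' @export
fold_filter <- function(expr, sample_a, sample_b, min_fold = 10, epsilon = 1,
                        gate = expression_gate(expr)) {
  stopifnot(min_fold > 1)
  for (s in c(sample_a, sample_b)) {
    if (!s %in% names(expr)) abort(paste0("unknown sample id: ", s))
  }
  a <- expr[[sample_a]]
  b <- expr[[sample_b]]
  fold <- (a + epsilon) / (b + epsilon)
  keep <- (a >= gate) & (fold >= min_fold)
  tibble(transcript_id = expr$transcript_id[keep],
         rpkm_a = a[keep], rpkm_b = b[keep], fold = fold[keep]) |>
    arrange(dplyr::desc(.data$fold))
}

#' Per-transcript MA values (mean log2 abundance, tumor-vs-reference log ratio)
#'
#' A is the mean over all groups of log2(group-mean RPKM + epsilon); M is the
#' mean over tumor groups of log2(group-mean RPKM + epsilon) minus the same
#' quantity for the reference group.
#'
#' @param expr An `rpkm_tbl`.
#' @param groups Tibble `sample_id`, `group`.
#' @param tumor_groups Character vector of tumor group labels.
#' @param reference_group Reference group label.
#' @param epsilon Pseudocount in RPKM units (default 1).
#' @return Tibble `transcript_id`, `A`, `M`.
#' @export
ma_values <- function(expr, groups, tumor_groups, reference_group, epsilon = 1) {
  all_groups <- unique(groups$group)
  if (!reference_group %in% all_groups) abort(paste0("unknown reference group: ", reference_group))
  if (!length(tumor_groups) || !all(tumor_groups %in% all_groups)) {
    abort("tumor_groups must name at least one known group")
  }
  m <- .count_matrix(expr)
  group_mean <- function(g) {
    cols <- intersect(groups$sample_id[groups$group == g], colnames(m))
    rowMeans(m[, cols, drop = FALSE])
  }
  gm <- vapply(all_groups, group_mean, numeric(nrow(m)))
  gm <- matrix(gm, nrow = nrow(m), dimnames = list(rownames(m), all_groups))
  lg <- log2(gm + epsilon)
  A <- rowMeans(lg)
  M <- rowMeans(lg[, tumor_groups, drop = FALSE]) - lg[, reference_group]
  tibble(transcript_id = rownames(m), A = unname(A), M = unname(M))
}

#' Merge several sample groups into one label
#'
#' Convenience for contrasts like "all tumors combined vs reference".
#'
#' @param groups Tibble `sample_id`, `group`.
#' @param new_label Label for the merged group.
#' @param old_labels Labels to merge.
#' @return Updated groups tibble.
#' @export
combine_groups <- function(groups, new_label, old_labels) {
  groups |>
    mutate(group = ifelse(.data$group %in% old_labels, new_label, .data$group))
}
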