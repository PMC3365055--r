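# Human-arm analysis: quantile normalization of intensity matrices, optional
# probe-to-gene collapsing, and an empirical-Bayes moderated t-test for a
# two-group (nevus vs melanoma) design.

.intensity_matrix <- function(tbl) {
  id_col <- intersect(c("probe_id", "gene_symbol", "id"), names(tbl))[1]
  if (is.na(id_col)) abort("intensity table needs a 'probe_id', 'gene_symbol' or 'id' column")
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

.intensity_tbl <- function(m, id_col) {
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  out[c(id_col, setdiff(names(out), id_col))]
}

#' Quantile normalization of an intensity matrix
#'
#' Forces every sample onto a common distribution: each sample's sorted
#' values are replaced by the across-sample mean of sorted values, with
#' within-sample ranks preserved. Ties within a sample receive the average
#' of the normalized values over the tied ranks, so the result is
#' deterministic.
#'
#' @param intensities Tibble with an id column (`probe_id` or
#'   `gene_symbol`) and one numeric column per sample.
#' @return Tibble of the same shape, normalized.
#' @export
quantile_normalize <- function(intensities) {
  id_col <- intersect(c("probe_id", "gene_symbol", "id"), names(intensities))[1]
  m <- .intensity_matrix(intensities)
  if (ncol(m) < 2) abort("quantile normalization needs at least 2 samples")
  if (any(!is.finite(m))) abort("intensity matrix contains non-finite values")
  target <- rowMeans(apply(m, 2, sort))
  n <- nrow(m)
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # fractional ranks (ties) -> average the target values of adjacent ranks
    lo <- target[floor(r)]
    hi <- target[ceiling(r)]
    (lo + hi) / 2
  })
  rownames(out) <- rownames(m)
  .intensity_tbl(out, id_col)
}

#' Collapse probe-level intensities to gene symbols
#'
#' @param intensities Probe-level tibble (`probe_id` + samples).
#' @param probe_map Tibble `probe_id`, `gene_symbol`.
#' @param method `"max_mean"` keeps, per symbol, the probe with the highest
#'   mean intensity; `"mean"` averages all probes of a symbol.
#' @return Gene-level tibble (`gene_symbol` + samples).
#' @export
collapse_probes <- function(intensities, probe_map, method = c("max_mean", "mean")) {
  method <- match.arg(method)
  samples <- setdiff(names(intensities), "probe_id")
  joined <- intensities |>
    inner_join(probe_map |> mutate(gene_symbol = toupper(.data$gene_symbol)),
               by = "probe_id") |>
    filter(!is.na(.data$gene_symbol), .data$gene_symbol != "")
  if (nrow(joined) == 0) abort("no probe maps to a gene symbol")
  if (method == "max_mean") {
    joined |>
      mutate(.mean = rowMeans(as.matrix(joined[samples]))) |>
      group_by(.data$gene_symbol) |>
      filter(.data$.mean == max(.data$.mean)) |>
      dplyr::slice(1) |>
      ungroup() |>
      select("gene_symbol", all_of(samples))
  } else {
    joined |>
      group_by(.data$gene_symbol) |>
      summarise(across(all_of(samples), mean), .groups = "drop")
  }
}

# Newton inversion of the trigamma function (for the prior df estimate).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated t-test for a two-group design
#'
#' Per-gene pooled residual variances s^2 (df d = n1 + n2 - 2) are shrunk
#' toward a common prior: s2_post = (d0 * s0^2 + d * s^2) / (d0 + d). The
#' prior (d0, s0^2) is estimated from the moments of log s^2 via
#' digamma/trigamma matching; when the trigamma equation has no positive
#' solution the prior is taken as exact (d0 = Inf, all posteriors equal
#' s0^2). The moderated statistic t = dmean / (s_post * sqrt(1/n1 + 1/n2))
#' is referred to a t distribution on d0 + d degrees of freedom.
#'
#' @param norm Normalized intensity tibble (id column + samples), log2 scale.
#'   Values whose maximum exceeds 50 trigger a message suggesting they are
#'   not yet log-transformed (override with `assume_log2 = TRUE`).
#' @param groups Tibble `sample_id`, `group` with exactly two group labels,
#'   each with at least 2 samples.
#' @param contrast Optional `c(group_a, group_b)`; log2FC is B minus A.
#'   Defaults to the two labels in sorted order.
#' @param assume_log2 Set `TRUE` to silence the scale heuristic.
#' @param prior Optional list `list(d0 =, s02 =)` overriding the estimated
#'   hyperparameters (useful for calibration studies).
#' @return Object of class `moderated_t_fit`: list with `table` (per-gene
#'   tibble), `d0`, `s02`, `contrast`, `n1`, `n2`.
#' @export
moderated_t <- function(norm, groups, contrast = NULL, assume_log2 = FALSE,
                        prior = NULL) {
  m <- .intensity_matrix(norm)
  if (!assume_log2 && max(m) > 50) {
    inform("intensity values exceed 50; input looks unlogged (expected log2 scale). Set assume_log2 = TRUE to silence.")
  }
  labs <- unique(groups$group)
  if (length(labs) != 2) abort("moderated_t needs exactly two groups")
  if (is.null(contrast)) contrast <- sort(labs)
  g1 <- intersect(groups$sample_id[groups$group == contrast[1]], colnames(m))
  g2 <- intersect(groups$sample_id[groups$group == contrast[2]], colnames(m))
  if (length(g1) < 2 || length(g2) < 2) abort("each group needs at least 2 samples")
  if (nrow(m) < 20) warn("fewer than 20 genes: hyperparameter estimates will be unstable")
  n1 <- length(g1); n2 <- length(g2)
  x1 <- m[, g1, drop = FALSE]; x2 <- m[, g2, drop = FALSE]
  mean1 <- rowMeans(x1); mean2 <- rowMeans(x2)
  ss <- rowSums((x1 - mean1)^2) + rowSums((x2 - mean2)^2)
  d <- n1 + n2 - 2
  s2 <- ss / d
  if (is.null(prior)) {
    ok <- s2 > 0
    e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
    ebar <- mean(e)
    excess <- mean((e - ebar)^2) * length(e) / (length(e) - 1) - trigamma(d / 2)
    if (is.finite(excess) && excess > 0) {
      d0 <- 2 * .trigamma_inverse(excess)
      s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # no excess spread in log s^2 beyond the chi-square noise: the prior
      # is exact and its scale is the plain mean of the variances
      d0 <- Inf
      s02 <- mean(s2[ok])
    }
  } else {
    d0 <- prior$d0; s02 <- prior$s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  delta <- mean2 - mean1
  tmod <- ifelse(delta == 0, 0, delta / se)
  # the prior cannot contribute more information than the pooled residual df
  df_total <- min(d0 + d, length(s2) * d)
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  tab <- tibble(id = rownames(m))
  tab[[paste0("mean_", contrast[1])]] <- unname(mean1)
  tab[[paste0("mean_", contrast[2])]] <- unname(mean2)
  tab$log2FC <- unname(delta)
  tab$s2 <- unname(s2)
  tab$s2_post <- unname(s2_post)
  tab$t <- unname(tmod)
  tab$df_total <- df_total
  tab$p_value <- unname(p)
  structure(list(table = tab, d0 = d0, s02 = s02, contrast = contrast,
                 n1 = n1, n2 = n2),
            class = "moderated_t_fit")
}

#' @export
print.moderated_t_fit <- function(x, ...) {
  cat(sprintf("<moderated_t_fit: %d genes, %s (n=%d) vs %s (n=%d), d0 = %.3g, s0^2 = %.3g>\n",
              nrow(x$table), x$contrast[1], x$n1, x$contrast[2], x$n2, x$d0, x$s02))
  invisible(x)
}

#' @export
tidy.moderated_t_fit <- function(x, ...) x$table

#' @export
glance.moderated_t_fit <- function(x, ...) {
  tibble(d0 = x$d0, s02 = x$s02, n_genes = nrow(x$table),
         n1 = x$n1, n2 = x$n2,
         contrast = paste(x$contrast, collapse = " vs "))
}

#' Fold-change / p-value calls for the microarray arm
#'
#' A gene is called when its linear fold change strictly exceeds `fold`
#' (equivalently |log2FC| > log2(fold)) and its p-value is strictly below
#' `p`.
#'
#' @param result A `moderated_t_fit` or its per-gene tibble.
#' @param fold Linear fold-change threshold (default 2).
#' @param p p-value threshold (default 0.05).
#' @return Per-gene tibble with added `fold` (linear, directional:
#'   2^log2FC) and `call` (`up`/`down`/`none`).
#' @export
call_array_de <- function(result, fold = 2, p = 0.05) {
  tab <- if (inherits(result, "moderated_t_fit")) result$table else as_tibble(result)
  lfc_min <- log2(fold)
  p_max <- p
  tab |>
    mutate(fold = 2^.data$log2FC,
           call = ifelse(abs(.data$log2FC) > lfc_min & .data$p_value < p_max,
                         ifelse(.data$log2FC > 0, "up", "down"), "none"))
}

#' Volcano plot for a moderated-t result
#'
#' @param object A `moderated_t_fit`.
#' @param fold,p Calling thresholds passed to [call_array_de()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moderated_t_fit <- function(object, fold = 2, p = 0.05, ...) {
  called <- call_array_de(object, fold = fold, p = p)
  ggplot2::ggplot(called, ggplot2::aes(x = .data$log2FC,
                                       y = -log10(.data$p_value),
                                       color = .data$call)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(up = "#c23b22", down = "#2c7fb8",
                                           none = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = paste(object$contrast, collapse = " vs ")) +
    ggplot2::theme_minimal()
}
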