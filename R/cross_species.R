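# Cross-species layer: join fish and human differential-expression results
# on harmonized gene symbols, extract conserved up/down signatures, count
# signature (motif) overlaps, and compute hypergeometric over-representation.

# collapse the fish paralogs mapping to one human symbol into a single
# call/log2FC according to the chosen policy
.collapse_paralogs <- function(fish_rows, policy) {
  pick <- switch(policy,
    any_call = {
      called <- fish_rows |> filter(.data$call != "none")
      if (nrow(called)) {
        called |> arrange(dplyr::desc(abs(.data$log2FC))) |> dplyr::slice(1)
      } else {
        fish_rows |> arrange(dplyr::desc(abs(.data$log2FC))) |> dplyr::slice(1)
      }
    },
    max_fold = fish_rows |> arrange(dplyr::desc(abs(.data$log2FC))) |> dplyr::slice(1),
    best_p = fish_rows |> arrange(.data$p_value) |> dplyr::slice(1)
  )
  pick
}

#' Join fish and human differential expression on gene symbols
#'
#' Fish genes are mapped to human symbols through the ortholog table; when
#' several fish paralogs hit one human symbol they are collapsed by
#' `paralog_policy`. Only symbols present in both result sets are kept; the
#' join size and the species-exclusive counts are reported with a message.
#'
#' @param fish_de `de_result` tibble from [call_de()] (needs `gene_id`,
#'   `log2FC`, `p_value`, `call`).
#' @param human_de Called human table from [call_array_de()] (needs an
#'   `id` or `gene_symbol` column plus `log2FC`, `p_value`, `call`).
#' @param orthologs Ortholog tibble from [read_ortholog_table()].
#' @param paralog_policy `"any_call"` (a human symbol is "up in fish" when
#'   any paralog is called up; ties broken by largest |log2FC|),
#'   `"max_fold"` or `"best_p"`.
#' @return Tibble of class `concordance_table`: `symbol`, `fish_gene_id`,
#'   `fish_log2FC`, `fish_p`, `fish_call`, `human_log2FC`, `human_p`,
#'   `human_call`, `n_paralogs`, `conserved_status` (one of `common_up`,
#'   `common_down`, `discordant`, `fish_only`, `human_only`, `neither`).
#' @export
join_on_symbols <- function(fish_de, human_de, orthologs,
                            paralog_policy = c("any_call", "max_fold", "best_p")) {
  paralog_policy <- match.arg(paralog_policy)
  human_tab <- as_tibble(human_de)
  id_col <- intersect(c("gene_symbol", "id", "symbol"), names(human_tab))[1]
  if (is.na(id_col)) abort("human result needs a symbol column ('gene_symbol', 'id' or 'symbol')")
  human_tab <- human_tab |>
    mutate(symbol = toupper(.data[[id_col]])) |>
    select("symbol", human_log2FC = "log2FC", human_p = "p_value", human_call = "call")
  fish_tab <- as_tibble(fish_de) |>
    inner_join(orthologs, by = c(gene_id = "fish_gene_id")) |>
    mutate(symbol = toupper(.data$human_symbol))
  if (nrow(fish_tab) == 0) abort("no fish gene maps through the ortholog table")
  fish_collapsed <- fish_tab |>
    group_by(.data$symbol) |>
    dplyr::group_modify(function(rows, key) {
      picked <- .collapse_paralogs(rows, paralog_policy)
      tibble(fish_gene_id = picked$gene_id, fish_log2FC = picked$log2FC,
             fish_p = picked$p_value, fish_call = picked$call,
             n_paralogs = nrow(rows))
    }) |>
    ungroup()
  joined <- inner_join(fish_collapsed, human_tab, by = "symbol")
  if (nrow(joined) == 0) abort("empty symbol intersection between fish and human results")
  n_fish_only <- length(setdiff(fish_collapsed$symbol, human_tab$symbol))
  n_human_only <- length(setdiff(human_tab$symbol, fish_collapsed$symbol))
  inform(sprintf("symbol join: %d common, %d fish-only, %d human-only",
                 nrow(joined), n_fish_only, n_human_only))
  out <- joined |>
    mutate(conserved_status = dplyr::case_when(
      fish_call == "up" & human_call == "up" ~ "common_up",
      fish_call == "down" & human_call == "down" ~ "common_down",
      fish_call != "none" & human_call != "none" ~ "discordant",
      fish_call != "none" ~ "fish_only",
      human_call != "none" ~ "human_only",
      TRUE ~ "neither"))
  class(out) <- c("concordance_table", class(out))
  out
}

#' Conserved up/down signatures from a concordance table
#'
#' @param table A `concordance_table`.
#' @return List with character vectors `common_up` and `common_down`
#'   (disjoint).
#' @export
conserved_signature <- function(table) {
  list(common_up = table$symbol[table$conserved_status == "common_up"],
       common_down = table$symbol[table$conserved_status == "common_down"])
}

# linear directional fold for one contrast result keyed by symbol
.fold_by_symbol <- function(de, orthologs = NULL) {
  tab <- as_tibble(de)
  if (!is.null(orthologs) && "gene_id" %in% names(tab)) {
    tab <- tab |>
      inner_join(orthologs, by = c(gene_id = "fish_gene_id")) |>
      mutate(symbol = toupper(.data$human_symbol))
  } else {
    sym_col <- intersect(c("gene_symbol", "symbol", "id"), names(tab))[1]
    tab <- tab |> mutate(symbol = toupper(.data[[sym_col]]))
  }
  tab |>
    filter(!is.na(.data$symbol)) |>
    group_by(.data$symbol) |>
    summarise(log2FC = .data$log2FC[which.max(abs(.data$log2FC))], .groups = "drop")
}

#' Count a signature's overlap with the fish dataset
#'
#' Shared symbols are those of the signature present in the fish result
#' (after symbol harmonization, optionally through the ortholog table);
#' meeting symbols additionally show a linear fold change strictly above
#' `fold` in the required direction in all (`quantifier = "all"`) or at
#' least one (`"any"`) of the supplied contrasts.
#'
#' @param fish_de_list A `de_result` or named list of them, one per
#'   tumor-vs-reference contrast.
#' @param signature A `signature_set`.
#' @param fold Linear fold threshold (> 1; strict comparison).
#' @param direction `"up"` or `"down"`; defaults to the signature's own
#'   direction, or `"up"` for unsigned signatures.
#' @param quantifier `"all"` contrasts must meet the rule, or `"any"`.
#' @param orthologs Optional ortholog table used to express fish genes as
#'   human symbols before matching.
#' @return One-row tibble: `signature`, `direction`, `quantifier`,
#'   `n_signature`, `n_shared`, `n_meeting`, `fold`.
#' @export
motif_overlap <- function(fish_de_list, signature, fold = 2, direction = NULL,
                          quantifier = c("all", "any"), orthologs = NULL) {
  quantifier <- match.arg(quantifier)
  stopifnot(inherits(signature, "signature_set"), fold > 1)
  direction <- direction %||%
    (if (signature$direction == "unsigned") "up" else signature$direction)
  if (inherits(fish_de_list, "de_result")) fish_de_list <- list(fish_de_list)
  folds <- purrr::map(fish_de_list, .fold_by_symbol, orthologs = orthologs)
  dataset_symbols <- unique(unlist(purrr::map(folds, "symbol")))
  shared <- intersect(signature$symbols, dataset_symbols)
  meets_one <- function(ftab) {
    lfc <- ftab$log2FC[match(shared, ftab$symbol)]
    lfc[is.na(lfc)] <- 0
    if (direction == "up") 2^lfc > fold else 2^(-lfc) > fold
  }
  if (length(shared)) {
    hit_mat <- vapply(folds, meets_one, logical(length(shared)))
    hit_mat <- matrix(hit_mat, nrow = length(shared))
    meeting <- if (quantifier == "all") rowSums(hit_mat) == ncol(hit_mat)
               else rowSums(hit_mat) > 0
  } else meeting <- logical(0)
  sig_name <- signature$name
  sig_size <- length(signature$symbols)
  tibble(signature = sig_name, direction = direction,
         quantifier = quantifier,
         n_signature = sig_size,
         n_shared = length(shared),
         n_meeting = sum(meeting), fold = fold)
}

#' Signed-signature comparison with an "at least one tumor type" rule
#'
#' Counts, for an up- and a down-signature, how many shared genes move in
#' the signature's direction by more than `fold` in at least one of the
#' supplied contrasts.
#'
#' @inheritParams motif_overlap
#' @param signature_up,signature_down `signature_set`s with directions up
#'   and down.
#' @return Two-row tibble (one per signature) as in [motif_overlap()].
#' @export
zebrafish_compare <- function(fish_de_list, signature_up, signature_down,
                              fold = 2, orthologs = NULL) {
  bind_rows(
    motif_overlap(fish_de_list, signature_up, fold = fold, direction = "up",
                  quantifier = "any", orthologs = orthologs),
    motif_overlap(fish_de_list, signature_down, fold = fold, direction = "down",
                  quantifier = "any", orthologs = orthologs))
}

#' Hypergeometric over-representation of a gene list in pathway sets
#'
#' For each pathway, compares the observed overlap k between the list
#' (size n) and the pathway (size K inside the universe of size N) with the
#' random expectation n*K/N, and computes the upper-tail hypergeometric
#' probability P(X >= k).
#'
#' @param gene_list Character vector of symbols (must lie in the universe).
#' @param pathways Named list of symbol vectors (intersected with the
#'   universe).
#' @param universe Character vector of all evaluable symbols.
#' @return Tibble: `pathway`, `N`, `K`, `n`, `k`, `expected`, `p_value`.
#' @export
over_representation <- function(gene_list, pathways, universe) {
  universe <- unique(toupper(universe))
  if (!length(universe)) abort("empty universe")
  gene_list <- unique(toupper(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) abort(paste0("gene list symbols outside the universe: ",
                                    paste(utils::head(outside, 5), collapse = ", ")))
  N <- length(universe); n <- length(gene_list)
  purrr::imap(pathways, function(syms, nm) {
    pw <- intersect(unique(toupper(syms)), universe)
    K <- length(pw)
    k <- length(intersect(gene_list, pw))
    tibble(pathway = nm, N = N, K = K, n = n, k = k,
           expected = n * K / N,
           p_value = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  }) |> bind_rows()
}

#' Fish-vs-human log fold change scatter
#'
#' @param object A `concordance_table`.
#' @param ... Unused.
#' @return A ggplot of fish vs human log2FC colored by conserved status.
#' @export
autoplot.concordance_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fish_log2FC,
                                       y = .data$human_log2FC,
                                       color = .data$conserved_status)) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::labs(x = "fish log2FC", y = "human log2FC") +
    ggplot2::theme_minimal()
}
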