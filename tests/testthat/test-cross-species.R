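fish_de_tbl <- function(gene_id, log2FC, call, p = 0.01) {
  tibble::tibble(gene_id = gene_id, gene_symbol = tolower(gene_id),
                 log2FC = log2FC, p_value = p, call = call)
}
human_de_tbl <- function(symbol, log2FC, call, p = 0.01) {
  tibble::tibble(id = symbol, log2FC = log2FC, p_value = p, call = call)
}
orth_tbl <- function(fish_gene_id, human_symbol) {
  tibble::tibble(fish_gene_id = fish_gene_id,
                 fish_symbol = tolower(human_symbol),
                 human_symbol = human_symbol)
}

test_that("symbol join classifies concordance and collapses paralogs", {
  fish <- fish_de_tbl(c("f1", "f2a", "f2b", "f3", "f4"),
                      c(3, 4, 0.1, -3, 2.5),
                      c("up", "up", "none", "down", "up"))
  human <- human_de_tbl(c("BCL2", "CDH2", "WNT5A", "MITF"),
                        c(2, 1.8, -2.5, -1.4),
                        c("up", "up", "down", "none"))
  orth <- orth_tbl(c("f1", "f2a", "f2b", "f3", "f4", "f5"),
                   c("BCL2", "CDH2", "CDH2", "WNT5A", "FISHONLY", "MITF"))
  conc <- suppressMessages(join_on_symbols(fish, human, orth))
  expect_setequal(conc$symbol, c("BCL2", "CDH2", "WNT5A"))  # only shared, measured genes
  st <- setNames(conc$conserved_status, conc$symbol)
  expect_equal(unname(st["BCL2"]), "common_up")
  expect_equal(unname(st["CDH2"]), "common_up")  # any_call: called paralog wins
  expect_equal(unname(st["WNT5A"]), "common_down")
  expect_equal(conc$n_paralogs[conc$symbol == "CDH2"], 2)
  expect_equal(conc$fish_gene_id[conc$symbol == "CDH2"], "f2a")

  # every row gets exactly one status
  expect_true(all(conc$conserved_status %in%
    c("common_up", "common_down", "discordant", "fish_only", "human_only", "neither")))

  # conserved sets are the two concordant classes
  sets <- conserved_signature(conc)
  expect_equal(sets$common_up, c("BCL2", "CDH2"))
  expect_equal(sets$common_down, "WNT5A")
  expect_length(intersect(sets$common_up, sets$common_down), 0)

  # swapping up/down labels in both species swaps the two sets
  flip <- function(x) c(up = "down", down = "up", none = "none")[x]
  conc2 <- suppressMessages(join_on_symbols(
    dplyr::mutate(fish, call = unname(flip(call)), log2FC = -log2FC),
    dplyr::mutate(human, call = unname(flip(call)), log2FC = -log2FC), orth))
  sets2 <- conserved_signature(conc2)
  expect_setequal(sets2$common_down, sets$common_up)
  expect_setequal(sets2$common_up, sets$common_down)

  expect_error(suppressMessages(join_on_symbols(
    fish, human_de_tbl("NOPE", 1, "none"), orth)), "empty symbol intersection")
})

test_that("paralog policies pick the intended representative", {
  fish <- fish_de_tbl(c("fa", "fb"), c(1.5, -4), c("none", "down"),
                      p = c(0.5, 0.001))
  human <- human_de_tbl("CDH2", 2, "up")
  orth <- orth_tbl(c("fa", "fb"), c("CDH2", "CDH2"))
  for (pol in c("any_call", "max_fold", "best_p")) {
    conc <- suppressMessages(join_on_symbols(fish, human, orth,
                                             paralog_policy = pol))
    expect_equal(conc$fish_gene_id, "fb")
  }
  # max_fold can differ from any_call when the called paralog is weaker
  fish2 <- fish_de_tbl(c("fa", "fb"), c(5, -4), c("none", "down"))
  conc_mf <- suppressMessages(join_on_symbols(fish2, human, orth, "max_fold"))
  expect_equal(conc_mf$fish_call, "none")
  conc_ac <- suppressMessages(join_on_symbols(fish2, human, orth, "any_call"))
  expect_equal(conc_ac$fish_call, "down")
})

test_that("motif overlap counts strict folds under all/any quantifiers", {
  sig <- signature_set(c("A", "B", "C"), name = "motif1")
  # two contrasts; A is >2-fold up in both, B exactly 2-fold, C absent
  de1 <- tibble::tibble(gene_symbol = c("A", "B"), log2FC = c(2, 1),
                        p_value = 0.01, call = "up")
  de2 <- tibble::tibble(gene_symbol = c("A", "B"), log2FC = c(1.5, 3),
                        p_value = 0.01, call = "up")
  rep_all <- motif_overlap(list(x = de1, y = de2), sig, fold = 2)
  expect_equal(rep_all$n_signature, 3)
  expect_equal(rep_all$n_shared, 2)
  expect_equal(rep_all$n_meeting, 1)  # B fails in contrast x (fold exactly 2)
  rep_any <- motif_overlap(list(x = de1, y = de2), sig, fold = 2,
                           quantifier = "any")
  expect_equal(rep_any$n_meeting, 2)
  # counts are monotone non-increasing in the fold threshold
  folds <- c(1.5, 2, 4, 8)
  ns <- vapply(folds, function(f)
    motif_overlap(list(de1, de2), sig, fold = f)$n_meeting, numeric(1))
  expect_true(all(diff(ns) <= 0))
  # empty intersection
  rep0 <- motif_overlap(list(de1), signature_set("ZZZ", "none_shared"), fold = 2)
  expect_equal(unlist(rep0[c("n_shared", "n_meeting")]), c(n_shared = 0, n_meeting = 0))
  expect_true(rep_all$n_meeting <= rep_all$n_shared &&
                rep_all$n_shared <= rep_all$n_signature)
})

test_that("signed comparison uses the at-least-one-tumor quantifier", {
  up <- signature_set(c("A", "B"), "zf_up", "up")
  down <- signature_set("C", "zf_down", "down")
  mk <- function(lfc) tibble::tibble(gene_symbol = c("A", "B", "C"),
                                     log2FC = lfc, p_value = 0.01, call = "none")
  contrasts <- list(XE = mk(c(2, 0, -0.5)), MM = mk(c(0.5, 0.2, -3)),
                    UM = mk(c(0.1, -1, 0)))
  res <- zebrafish_compare(contrasts, up, down)
  expect_equal(res$n_meeting, c(1, 1))  # A up in one contrast; B in none; C down once
  # report invariant under contrast order permutation
  res2 <- zebrafish_compare(rev(contrasts), up, down)
  expect_equal(res2$n_meeting, res$n_meeting)
})

test_that("over-representation matches the closed form and enumeration", {
  uni <- sprintf("G%03d", 1:100)
  pw <- list(p1 = uni[1:10])
  res <- over_representation(uni[11:20], pw, uni)
  expect_equal(res$expected, 10 * 10 / 100)  # = 1.0
  expect_equal(res$k, 0)
  expect_equal(res$p_value, 1)  # upper tail includes 0

  # small case against direct enumeration of the hypergeometric mass
  uni10 <- sprintf("g%02d", 1:10)
  lst <- uni10[c(1, 2, 5)]           # n = 3
  pw4 <- list(pw = uni10[1:4])       # K = 4, k = 2
  res2 <- over_representation(lst, pw4, uni10)
  enum <- sum(vapply(2:3, function(i)
    choose(4, i) * choose(6, 3 - i) / choose(10, 3), numeric(1)))
  expect_equal(res2$p_value, enum, tolerance = 1e-12)
  expect_equal(res2$expected, 3 * 4 / 10)

  expect_error(over_representation("X", pw4, uni10), "outside the universe")
  expect_error(over_representation(character(0), pw4, character(0)),
               "empty universe")
})
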