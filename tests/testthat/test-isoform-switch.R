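prof_expr <- function(profiles, groups = c("HP", "XE", "MM", "UM"), gate = 2) {
  # one sample per group; rows are transcripts
  m <- profiles
  colnames(m) <- groups
  make_expr(m, gate = gate)
}

four_groups <- function() tibble::tibble(sample_id = c("HP", "XE", "MM", "UM"),
                                         group = c("HP", "XE", "MM", "UM"))

test_that("multi-isoform selection partitions the annotated gene set", {
  ann <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
    gene_id = c("g1", "g2", "g2", "g3", "g3", "g3"),
    gene_symbol = c("A", "B", "B", "C", "C", "C"),
    length_bp = 1000L)
  multi <- multi_isoform_genes(ann)
  expect_setequal(multi$gene_id, c("g2", "g3"))
  expect_equal(sort(multi$n_isoforms), c(2, 3))
  n_single <- length(unique(ann$gene_id)) - nrow(multi)
  expect_equal(nrow(multi) + n_single, length(unique(ann$gene_id)))
})

test_that("gene mean profiles average transcripts after group means", {
  ann <- tibble::tibble(transcript_id = c("t1", "t2"),
                        gene_id = "g1", gene_symbol = "A", length_bp = 1000L)
  expr <- prof_expr(rbind(t1 = c(1, 2, 3, 4), t2 = c(3, 2, 1, 0)))
  prof <- gene_mean_profile(expr, "g1", ann, four_groups())
  expect_equal(unname(prof), c(2, 2, 2, 2))
  # single transcript: identity
  expr1 <- prof_expr(rbind(t1 = c(1, 2, 3, 4)))
  ann1 <- ann[1, ]
  expect_equal(unname(gene_mean_profile(expr1, "g1", ann1, four_groups())),
               c(1, 2, 3, 4))
  expect_error(gene_mean_profile(expr, "nope", ann, four_groups()),
               "absent from annotation")
})

test_that("RC equals the correlation range with hand-computed cases", {
  ann2 <- function(g = "g1") tibble::tibble(
    transcript_id = c("t1", "t2"), gene_id = g, gene_symbol = "A",
    length_bp = 1000L)
  # proportional isoforms: both correlations 1, RC = 0, same direction
  r1 <- rc_gene(prof_expr(rbind(t1 = c(1, 2, 3, 4), t2 = c(2, 4, 6, 8))),
                "g1", ann2(), four_groups())
  expect_equal(r1$rc_gene, 0)
  expect_equal(r1$category, "same_direction")
  # anti-correlated isoforms: correlations -1 and +1, RC = 2
  r2 <- rc_gene(prof_expr(rbind(t1 = c(1, 2, 3, 4), t2 = c(8, 6, 4, 2))),
                "g1", ann2(), four_groups())
  expect_equal(r2$rc_gene, 2)
  expect_equal(r2$category, "differential")
  cors <- as.numeric(strsplit(r2$correlations, ";")[[1]])
  expect_equal(sort(cors), c(-1, 1))
  # constant transcript: correlation undefined, dropped; < 2 remain -> RC NA
  r3 <- rc_gene(prof_expr(rbind(t1 = c(5, 5, 5, 5), t2 = c(1, 2, 3, 4))),
                "g1", ann2(), four_groups())
  expect_true(is.na(r3$rc_gene))
  expect_equal(r3$category, "same_direction")
})

test_that("RC matches a direct-summation Pearson oracle on random profiles", {
  set.seed(21)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    prof <- matrix(rlnorm(k * 4, log(10), 1), k, 4)
    gm <- colMeans(prof)
    oracle <- apply(prof, 1, pearson_brute, y = gm)
    rc_oracle <- max(oracle) - min(oracle)
    ann <- tibble::tibble(transcript_id = paste0("t", 1:k), gene_id = "g",
                          gene_symbol = "A", length_bp = 1000L)
    rownames(prof) <- ann$transcript_id
    r <- rc_gene(prof_expr(prof, gate = 0), "g", ann, four_groups())
    expect_equal(r$rc_gene, rc_oracle, tolerance = 1e-12)
    expect_gte(r$rc_gene, 0); expect_lte(r$rc_gene, 2)
    # relabeling (reordering) transcripts leaves RC unchanged
    perm <- sample(k)
    r2 <- rc_gene(prof_expr(prof[perm, , drop = FALSE], gate = 0), "g",
                  ann, four_groups())
    expect_equal(r2$rc_gene, r$rc_gene, tolerance = 1e-12)
  }
})

test_that("classification gates and partitions the multi-isoform genes", {
  ann <- tibble::tibble(
    transcript_id = c("a1", "a2", "b1", "b2", "c1", "c2", "d1", "d2"),
    gene_id = rep(c("gA", "gB", "gC", "gD"), each = 2),
    gene_symbol = rep(c("A", "B", "C", "D"), each = 2),
    length_bp = 1000L)
  prof <- rbind(
    a1 = c(1, 1, 0, 0), a2 = c(0.5, 1, 1, 0),      # below gate everywhere
    b1 = c(9, 4, 3, 8), b2 = c(1, 1.2, 0.4, 1),    # only b1 passes
    c1 = c(10, 20, 30, 40), c2 = c(80, 60, 40, 20),# anti-correlated
    d1 = c(10, 20, 30, 40), d2 = c(5, 10, 15, 20)) # proportional
  sp <- splice_analysis(prof_expr(prof), ann, four_groups())
  got <- setNames(sp$category, sp$gene_id)
  expect_equal(unname(got[c("gA", "gB", "gC", "gD")]),
               c("not_expressed", "single_transcript", "differential",
                 "same_direction"))
  expect_equal(nrow(sp), nrow(multi_isoform_genes(ann)))
  expect_true(all(table(sp$category) >= 0))
  # restricting the gate to tumor groups reclassifies a reference-only gene
  prof2 <- rbind(e1 = c(9, 0, 0, 0), e2 = c(4, 1, 1, 1))
  ann2 <- tibble::tibble(transcript_id = c("e1", "e2"), gene_id = "gE",
                         gene_symbol = "E", length_bp = 1000L)
  any_g <- splice_analysis(prof_expr(prof2), ann2, four_groups(),
                           scope = "any_group")
  tum_g <- splice_analysis(prof_expr(prof2), ann2, four_groups(),
                           scope = "tumor_groups_only")
  expect_false(any_g$category == "not_expressed")
  expect_equal(tum_g$category, "not_expressed")
})
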