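test_that("rpkm matches its closed form and scaling laws", {
  counts <- tibble::tibble(transcript_id = c("t1", "t2"),
                           S1 = c(1000L, 0L), S2 = c(999000L, 1000L))
  ann <- tibble::tibble(transcript_id = c("t1", "t2"),
                        gene_id = c("g1", "g2"), gene_symbol = c("A", "B"),
                        length_bp = c(1000L, 500L))
  # pad S1 so its total is exactly 1e6
  counts$S1[2] <- 999000L
  expr <- rpkm(counts, ann)
  expect_equal(expr$S1[1], 1e9 * 1000 / (1000 * 1e6))  # = 1000
  expect_equal(rpkm(dplyr::mutate(counts, S1 = c(0L, 1000L)), ann)$S1[1], 0)

  # doubling every count of a sample leaves its RPKM unchanged
  doubled <- dplyr::mutate(counts, S1 = S1 * 2L)
  expect_equal(rpkm(doubled, ann)$S1, expr$S1)

  # rpkm is homogeneous of degree -1 in transcript length
  ann2 <- dplyr::mutate(ann, length_bp = length_bp * 2L)
  expect_equal(rpkm(counts, ann2)$S1, expr$S1 / 2)

  zero <- dplyr::mutate(counts, S1 = c(0L, 0L))
  expect_error(rpkm(zero, ann), "zero total counts.*S1")
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("A", "B")))
  tb <- make_expr(m)[, 1:3]
  names(tb)[1] <- "transcript_id"
  sf <- size_factors(tb)
  expect_equal(sf$size_factor, c(1, 1))

  # B = 2 A on every row -> factors (1/sqrt(2), sqrt(2))
  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  tb2 <- make_expr(m2)[, 1:3]; names(tb2)[1] <- "transcript_id"
  expect_equal(size_factors(tb2)$size_factor, c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # permuting samples permutes the factors identically
  tb2r <- tb2[, c("transcript_id", "B", "A")]
  expect_equal(size_factors(tb2r)$size_factor,
               rev(size_factors(tb2)$size_factor), tolerance = 1e-12)

  # no row positive in all samples
  tb3 <- tibble::tibble(transcript_id = c("a", "b"), A = c(5L, 0L), B = c(0L, 5L))
  expect_error(size_factors(tb3), "no transcript with positive counts")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  m <- matrix(rpois(200 * 6, 50), 200, 6,
              dimnames = list(sprintf("t%03d", 1:200), paste0("s", 1:6)))
  m[, 2] <- m[, 2] * 3L
  tb <- tibble::as_tibble(m)
  tb <- tibble::add_column(tb, transcript_id = rownames(m), .before = 1)
  expect_equal(size_factors(tb)$size_factor,
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("base means normalize by size factor and support group summaries", {
  tb <- tibble::tibble(transcript_id = c("a", "b", "c"),
                       S1 = c(10L, 0L, 5L), S2 = c(10L, 0L, 20L))
  sf <- tibble::tibble(sample_id = c("S1", "S2"), size_factor = c(0.5, 2))
  bm <- base_mean(tb, sf)
  expect_equal(bm$base_mean[1], mean(c(10 / 0.5, 10 / 2)))
  expect_equal(bm$base_mean[2], 0)
  expect_equal(bm$base_mean[3], mean(c(10, 10)))  # (5/.5, 20/2) -> 10

  sf1 <- tibble::tibble(sample_id = c("S1", "S2"), size_factor = c(1, 1))
  grp <- tibble::tibble(sample_id = c("S1", "S2"), group = c("G1", "G2"))
  bmg <- base_mean(tb, sf1, grp)
  expect_equal(bmg$base_mean_G1[1], 10)
  # the conventional gate is strict: a base mean of exactly 10 fails "> 10"
  expect_false(bmg$base_mean[1] > 10)
})

test_that("presence partition is a true partition with an inclusive gate", {
  m <- matrix(c(3, 0, 2, 1,
                0, 4, 2, 1), ncol = 2,
              dimnames = list(c("a", "b", "c", "d"), c("X", "Y")))
  expr <- make_expr(m, gate = 2)
  pp <- presence_partition(expr, "X", "Y")
  expect_equal(as.character(pp$status), c("only_a", "only_b", "both", "neither"))
  expect_equal(sum(table(pp$status)), nrow(m))
  expect_error(presence_partition(expr, "X", "Z"), "unknown sample")
})

test_that("fold filter applies the pseudocount and inclusive threshold", {
  m <- matrix(c(40, 40, 9, 40, 4, 0, 1, 4.5), ncol = 2,
              dimnames = list(c("a", "b", "c", "d"), c("X", "Y")))
  expr <- make_expr(m, gate = 2)
  # epsilon 0: a/b = 10 exactly -> included (>=)
  ff0 <- fold_filter(expr, "X", "Y", min_fold = 10, epsilon = 0)
  expect_true("a" %in% ff0$transcript_id)
  expect_equal(ff0$fold[ff0$transcript_id == "a"], 10)
  expect_false("c" %in% ff0$transcript_id)  # 9-fold
  # epsilon 0.5: (40 + .5) / (0 + .5) = 81
  ff <- fold_filter(expr, "X", "Y", min_fold = 10, epsilon = 0.5)
  expect_equal(ff$fold[ff$transcript_id == "b"], 81)
})

test_that("MA values use group means of log2 pseudocounted rpkm", {
  m <- matrix(c(4, 0, 4, 0, 16, 0, 16, 0), ncol = 4,
              dimnames = list(c("a", "z"), c("HP", "XE", "MM", "UM")))
  expr <- make_expr(m)
  grp <- tiny_groups()
  ma <- ma_values(expr, grp, tumor_groups = c("MM", "UM"),
                  reference_group = "HP", epsilon = 0)
  expect_equal(ma$M[1], 2)  # tumors uniformly 4x the reference
  expect_equal(ma$A[1], mean(log2(c(4, 4, 16, 16))))
  # all-zero transcript with epsilon 1 sits at the origin
  ma1 <- ma_values(expr, grp, c("MM", "UM"), "HP", epsilon = 1)
  expect_equal(ma1$A[2], 0)
  expect_equal(ma1$M[2], 0)
  # equal groups give M = 0
  meq <- matrix(5, 1, 4, dimnames = list("e", c("HP", "XE", "MM", "UM")))
  expect_equal(ma_values(make_expr(meq), grp, c("XE", "MM", "UM"), "HP")$M, 0)
})
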