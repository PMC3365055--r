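make_int <- function(m) {
  out <- tibble::as_tibble(m)
  tibble::add_column(out, probe_id = rownames(m), .before = 1)
}

test_that("quantile normalization maps every sample to the mean distribution", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), ncol = 2,
              dimnames = list(c("p1", "p2", "p3"), c("A", "B")))
  qn <- quantile_normalize(make_int(m))
  expect_equal(qn$A, c(1.5, 3.5, 5.5))
  expect_equal(qn$B, c(1.5, 3.5, 5.5))

  # identical samples are a fixed point
  m2 <- matrix(c(2, 9, 4, 2, 9, 4), ncol = 2,
               dimnames = list(c("p1", "p2", "p3"), c("A", "B")))
  qn2 <- quantile_normalize(make_int(m2))
  expect_equal(qn2$A, unname(m2[, 1]))

  # within-sample ranks preserved; sorted columns identical (random case)
  set.seed(7)
  mr <- matrix(rnorm(300), 100, 3,
               dimnames = list(sprintf("p%03d", 1:100), c("A", "B", "C")))
  qr <- quantile_normalize(make_int(mr))
  qm <- as.matrix(qr[, -1])
  for (j in 1:3) expect_equal(rank(qm[, j]), unname(rank(mr[, j])))
  expect_identical(sort(qm[, 1]), sort(qm[, 2]))
  expect_identical(sort(qm[, 2]), sort(qm[, 3]))

  # ties receive the average of the tied normalized values
  mt <- matrix(c(1, 1, 5, 2, 4, 6), ncol = 2,
               dimnames = list(c("p1", "p2", "p3"), c("A", "B")))
  qt <- quantile_normalize(make_int(mt))
  expect_equal(qt$A[1], qt$A[2])
  expect_equal(qt$A[1], mean(c(1.5, 2.5)))

  mn <- m; mn[1, 1] <- NA
  expect_error(quantile_normalize(make_int(mn)), "non-finite")
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(6)
  m <- matrix(rnorm(500 * 5, 8, 2), 500, 5,
              dimnames = list(sprintf("p%03d", 1:500), paste0("s", 1:5)))
  qn <- as.matrix(quantile_normalize(make_int(m))[, -1])
  ref <- limma::normalizeQuantiles(m)
  dimnames(ref) <- dimnames(qn)
  expect_equal(qn, ref, tolerance = 1e-12)
})

test_that("probe collapsing keeps the brightest probe or averages", {
  ints <- tibble::tibble(probe_id = c("a1", "a2", "b1"),
                         s1 = c(1, 5, 2), s2 = c(3, 7, 4))
  pmap <- tibble::tibble(probe_id = c("a1", "a2", "b1"),
                         gene_symbol = c("G1", "G1", "G2"))
  mx <- collapse_probes(ints, pmap, "max_mean")
  expect_equal(mx$s1[mx$gene_symbol == "G1"], 5)
  av <- collapse_probes(ints, pmap, "mean")
  expect_equal(av$s1[av$gene_symbol == "G1"], 3)
})

test_that("moderated t shrinks variances and reduces to the pooled t at d0 = 0", {
  set.seed(8)
  m <- matrix(rnorm(50 * 8, 8, 1), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:8)))
  m[1, ] <- 8  # equal group means, zero variance
  grp <- tibble::tibble(sample_id = paste0("s", 1:8),
                        group = rep(c("n", "m"), each = 4))
  fit <- suppressWarnings(moderated_t(make_int(m), grp, contrast = c("n", "m")))
  expect_equal(fit$table$t[1], 0)
  expect_equal(fit$table$p_value[1], 1)

  # posterior variance lies between s2 and s02 and moves toward the prior
  tab <- fit$table[-1, ]
  above <- tab$s2 > fit$s02
  expect_true(all(tab$s2_post[above] < tab$s2[above]))
  expect_true(all(tab$s2_post[above] > fit$s02))
  expect_true(all(tab$s2_post[!above] > tab$s2[!above]))

  # d0 = 0 prior: ordinary pooled two-sample t
  fit0 <- suppressWarnings(moderated_t(make_int(m), grp, contrast = c("n", "m"),
                                       prior = list(d0 = 0, s02 = 1)))
  tt <- t.test(m[2, 5:8], m[2, 1:4], var.equal = TRUE)
  expect_equal(fit0$table$t[2], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(fit0$table$p_value[2], tt$p.value, tolerance = 1e-9)

  # shift invariance and group-swap equivariance
  fit_shift <- suppressWarnings(moderated_t(make_int(m + 3), grp,
                                            contrast = c("n", "m")))
  expect_equal(fit_shift$table$t, fit$table$t, tolerance = 1e-9)
  fit_swap <- suppressWarnings(moderated_t(make_int(m), grp,
                                           contrast = c("m", "n")))
  expect_equal(fit_swap$table$t, -fit$table$t, tolerance = 1e-12)

  grp_bad <- tibble::tibble(sample_id = paste0("s", 1:8),
                            group = c("n", rep("m", 7)))
  expect_error(moderated_t(make_int(m), grp_bad), "at least 2 samples")
})

test_that("moderated t agrees with the limma oracle on the full design", {
  skip_if_not_installed("limma")
  set.seed(9)
  n1 <- 18; n2 <- 19
  m <- matrix(rnorm(800 * (n1 + n2), 8, 0.7), 800, n1 + n2,
              dimnames = list(sprintf("g%03d", 1:800),
                              c(sprintf("nv%02d", 1:n1), sprintf("ml%02d", 1:n2))))
  m[1:40, (n1 + 1):(n1 + n2)] <- m[1:40, (n1 + 1):(n1 + n2)] + 2
  grp <- tibble::tibble(sample_id = colnames(m),
                        group = rep(c("nevus", "melanoma"), c(n1, n2)))
  fit <- moderated_t(make_int(m), grp, contrast = c("nevus", "melanoma"))
  design <- stats::model.matrix(~rep(c(0, 1), c(n1, n2)))
  ref <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(fit$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, ref$s2.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(ref$t[, 2]), tolerance = 1e-8)
  expect_equal(fit$table$p_value, unname(ref$p.value[, 2]), tolerance = 1e-8)
})

test_that("array calls need both a >2-fold change and p < 0.05", {
  tab <- tibble::tibble(id = c("a", "b", "c"),
                        log2FC = c(1.0, 1.6, -2),
                        p_value = c(0.01, 0.2, 0.001))
  called <- call_array_de(tab)
  expect_equal(called$call, c("none", "none", "down"))  # fold 2 exactly fails
  expect_equal(called$fold, 2^tab$log2FC)
})
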