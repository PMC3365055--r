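# Shared fixtures and independent oracle implementations.

tiny_counts <- function() {
  tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    HP = c(10L, 0L, 100L),
    XE = c(20L, 5L, 80L),
    MM = c(5L, 2L, 120L),
    UM = c(0L, 1L, 90L))
}

tiny_annotation <- function() {
  tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g1", "g2"),
    gene_symbol = c("ABC1", "ABC1", "XYZ2"),
    length_bp = c(1000L, 2000L, 1500L))
}

tiny_groups <- function() {
  tibble::tibble(sample_id = c("HP", "XE", "MM", "UM"),
                 group = c("HP", "XE", "MM", "UM"))
}

write_fish_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                               counts = tiny_counts(),
                               annotation = tiny_annotation(),
                               groups = tiny_groups()) {
  paths <- list(counts = file.path(dir, "counts.tsv"),
                annotation = file.path(dir, "annotation.tsv"),
                groups = file.path(dir, "groups.tsv"))
  readr::write_tsv(counts, paths$counts, progress = FALSE)
  readr::write_tsv(annotation, paths$annotation, progress = FALSE)
  readr::write_tsv(groups, paths$groups, progress = FALSE)
  paths
}

# build an rpkm-like expression table directly from a matrix of values
make_expr <- function(m, gate = 2) {
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, transcript_id = rownames(m), .before = 1)
  attr(out, "gate") <- gate
  class(out) <- c("rpkm_tbl", class(out))
  out
}

# direct-summation Pearson correlation (independent of stats::cor)
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# brute-force conditional NB p-value by explicit enumeration over all splits
oracle_nb_p <- function(ka, kb, sA, sB, alpha) {
  K <- ka + kb
  if (K == 0) return(1)
  q <- K / (sA + sB)
  muA <- q * sA; muB <- q * sB
  vA <- muA + alpha * muA^2; vB <- muB + alpha * muB^2
  lp <- function(k, mu, v) {
    if (v <= mu * (1 + 1e-12)) dpois(k, mu, log = TRUE)
    else dnbinom(k, mu = mu, size = mu^2 / (v - mu), log = TRUE)
  }
  lt <- vapply(0:K, function(a) lp(a, muA, vA) + lp(K - a, muB, vB), numeric(1))
  lobs <- lp(ka, muA, vA) + lp(kb, muB, vB)
  sum(exp(lt[lt <= lobs + 1e-7])) / sum(exp(lt))
}

# NB variance model with a fixed dispersion, for oracle comparisons
fixed_model <- function(alpha) {
  structure(list(alpha = alpha, n_genes = NA_integer_, n_samples = NA_integer_,
                 method = "fixed"), class = "nb_variance_model")
}

# gene-level count table straight from a matrix
make_gene_counts <- function(m, symbols = rownames(m)) {
  out <- tibble::as_tibble(m)
  tibble::add_column(out, gene_id = rownames(m), gene_symbol = symbols,
                     .before = 1)
}
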