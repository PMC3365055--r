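# Synthetic two-species study generator. Emulates the statistical structure
# the analysis assumes: a four-group fish RNA-seq design with one library
# per tumor type and a pooled benign reference, NB-distributed counts with
# multi-isoform genes and planted isoform switches, a human two-group
# microarray design (18 nevi vs 19 melanomas) with Gaussian log2
# intensities, an ortholog map with duplicated fish paralogs, and planted
# conserved up/down signatures — all with a per-gene truth table.

#' Simulation configuration
#'
#' Defaults reflect the study design this pipeline mirrors: fish groups HP
#' (pooled from 5 virtual siblings), XE, MM, UM with one library each;
#' human arm with 18 nevi and 19 melanomas; NB dispersion 0.1; planted
#' 8-fold expression effects.
#'
#' @param seed Master seed; fixes every random draw.
#' @param n_genes Number of fish genes.
#' @param isoform_fracs Fractions of genes with 1, 2, 3 annotated isoforms.
#' @param fish_groups Ordered fish group labels (benign reference first).
#' @param hp_pool Simulate the reference as a pool of `n_siblings` libraries
#'   whose counts are summed into one sample.
#' @param n_siblings Pool size for the reference group.
#' @param n_nevus,n_melanoma Human group sizes.
#' @param alpha NB dispersion (raw variance = mu + alpha mu^2).
#' @param group_cv Log-normal coefficient of variation of per-gene,
#'   per-group biological expression factors: real tumor types differ from
#'   each other beyond counting noise, and without this variation the
#'   gene-mean profile of a non-switch gene would be flat and its isoform
#'   correlations meaningless. Set 0 for pure noise-model simulations.
#' @param meanlog,sdlog Log-normal baseline of per-gene expression
#'   (concentration units, approximately RPKM).
#' @param depth_base Expected reads per concentration-unit-kilobase;
#'   scales library depth.
#' @param depth_sdlog Log-normal spread of per-sample depth factors.
#' @param n_up_fish,n_down_fish Planted tumor-up / tumor-down fish genes.
#' @param frac_conserved Fraction of planted fish genes also planted (same
#'   direction) in the human arm.
#' @param n_human_only Planted human-arm genes with no fish effect.
#' @param effect_fold Planted linear fold (both arms).
#' @param n_switch Planted isoform-switch genes (two anti-correlated
#'   isoforms each).
#' @param paralog_fraction Fraction of fish genes that are second copies of
#'   an existing human symbol.
#' @param array_sigma Human log2-intensity noise SD.
#' @param array_mean,array_sd Baseline log2 intensity distribution.
#' @param frac_two_probes Fraction of human genes measured by two probes.
#' @param frac_shared Fraction of fish symbols measured on the human array.
#' @param n_human_extra Human-only symbols on the array.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 8000,
                       isoform_fracs = c(0.80, 0.15, 0.05),
                       fish_groups = c("HP", "XE", "MM", "UM"),
                       hp_pool = TRUE, n_siblings = 5,
                       n_nevus = 18, n_melanoma = 19,
                       alpha = 0.1,
                       group_cv = 0.25,
                       meanlog = log(20), sdlog = 1.2,
                       depth_base = 3, depth_sdlog = 0.25,
                       n_up_fish = 150, n_down_fish = 150,
                       frac_conserved = 0.5,
                       n_human_only = 100,
                       effect_fold = 8,
                       n_switch = 100,
                       paralog_fraction = 0.10,
                       array_sigma = 0.5,
                       array_mean = 8, array_sd = 2,
                       frac_two_probes = 0.2,
                       frac_shared = 0.9,
                       n_human_extra = 300) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(isoform_fracs) - 1) < 1e-8,
            all(isoform_fracs >= 0),
            frac_conserved >= 0, frac_conserved <= 1,
            paralog_fraction >= 0, paralog_fraction < 1,
            frac_two_probes >= 0, frac_two_probes <= 1,
            frac_shared >= 0, frac_shared <= 1,
            alpha >= 0, effect_fold > 1)
  n_unique <- n_genes - floor(paralog_fraction * n_genes)
  if (n_up_fish + n_down_fish + n_switch + n_human_only > n_unique) {
    abort("infeasible config: planted sets exceed the number of available genes")
  }
  structure(cfg, class = "sim_config")
}

# profiles over the four ordered groups giving exact correlations +1/-1 to
# the gene mean before noise (correlation gap 2): the second isoform runs
# counter to the first with smaller amplitude, so the mean keeps a clean
# monotone trend
.switch_profiles <- function() {
  p1 <- c(0.1, 0.7, 1.3, 1.9)
  p2 <- c(1.3, 1.1, 0.9, 0.7)
  rbind(p1, p2)
}

.rnb <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate a full two-species study
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study` with elements `counts`, `annotation`,
#'   `groups` (fish arm); `intensities`, `probe_map`, `human_groups` (human
#'   arm); `orthologs`; `truth` (per-fish-gene tibble: `gene_id`, `symbol`,
#'   `fish_direction`, `human_direction`, `conserved`, `switch`,
#'   `paralog_group`); and `signatures` / `pathways` (named lists of symbol
#'   vectors derived from the planted truth: two unsigned overlap motifs,
#'   signed up/down signatures, one pathway enriched for planted
#'   conserved-down genes plus background pathways).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n <- cf$n_genes
  n_par <- floor(cf$paralog_fraction * n)
  n_unique <- n - n_par
  gene_id <- sprintf("FG%05d", seq_len(n))
  # paralog copies reuse the human symbol of an early unique gene
  base_sym_idx <- c(seq_len(n_unique), seq_len(n_par))
  human_symbol <- sprintf("GENE%05d", base_sym_idx)
  copy_tag <- c(rep("", n_unique), rep("b", n_par))
  fish_symbol <- toupper(paste0(tolower(human_symbol), ifelse(copy_tag == "b", "B",
                                                             ifelse(human_symbol %in% human_symbol[duplicated(human_symbol)], "A", ""))))

  # which unique genes are also measured on the human array (by symbol);
  # paralog copies inherit the status of their base gene
  shared_unique <- sort(sample(seq_len(n_unique), round(cf$frac_shared * n_unique)))
  is_shared <- base_sym_idx %in% shared_unique

  # planted sets live on unique (non-duplicated-copy) genes
  pool <- sample(seq_len(n_unique))
  idx_up <- pool[seq_len(cf$n_up_fish)]
  idx_down <- pool[cf$n_up_fish + seq_len(cf$n_down_fish)]
  idx_switch <- pool[cf$n_up_fish + cf$n_down_fish + seq_len(cf$n_switch)]
  fish_direction <- rep("none", n)
  fish_direction[idx_up] <- "up"
  fish_direction[idx_down] <- "down"
  is_switch <- seq_len(n) %in% idx_switch

  # human effects only make sense for genes on the array: conserved genes are
  # drawn from the planted-and-shared subset, human-only effects from shared
  # null genes
  n_cons_up <- round(cf$frac_conserved * cf$n_up_fish)
  n_cons_down <- round(cf$frac_conserved * cf$n_down_fish)
  up_shared <- idx_up[idx_up %in% shared_unique]
  down_shared <- idx_down[idx_down %in% shared_unique]
  if (length(up_shared) < n_cons_up || length(down_shared) < n_cons_down) {
    abort("infeasible config: not enough shared planted genes for the conserved set")
  }
  cons_idx <- c(up_shared[seq_len(n_cons_up)], down_shared[seq_len(n_cons_down)])
  null_shared <- setdiff(intersect(pool, shared_unique),
                         c(idx_up, idx_down, idx_switch))
  if (length(null_shared) < cf$n_human_only) {
    abort("infeasible config: not enough shared null genes for human-only effects")
  }
  idx_humanonly <- null_shared[seq_len(cf$n_human_only)]
  human_direction <- rep("none", n)
  human_direction[cons_idx] <- fish_direction[cons_idx]
  human_direction[idx_humanonly] <- rep(c("up", "down"), length.out = cf$n_human_only)

  truth <- tibble(
    gene_id = gene_id, symbol = human_symbol,
    fish_direction = fish_direction, human_direction = human_direction,
    conserved = seq_len(n) %in% cons_idx,
    switch = is_switch,
    paralog_group = ifelse(human_symbol %in% human_symbol[duplicated(human_symbol)],
                           human_symbol, NA_character_))

  # --- fish arm ------------------------------------------------------------
  n_iso <- sample(1:3, n, replace = TRUE, prob = cf$isoform_fracs)
  n_iso[is_switch] <- 2L
  q <- stats::rlnorm(n, cf$meanlog, cf$sdlog)
  groups_vec <- cf$fish_groups
  is_tumor <- groups_vec != groups_vec[1]
  de_mult <- matrix(1, n, length(groups_vec))
  de_mult[fish_direction == "up", is_tumor] <- cf$effect_fold
  de_mult[fish_direction == "down", is_tumor] <- 1 / cf$effect_fold
  if (cf$group_cv > 0) {
    sl <- sqrt(log(1 + cf$group_cv^2))
    gf <- matrix(stats::rlnorm(n * length(groups_vec), -sl^2 / 2, sl),
                 n, length(groups_vec))
    # switch genes keep their constructed group profiles (their correlation
    # gap is planted by design; counting noise alone sets the difficulty)
    gf[is_switch, ] <- 1
    de_mult <- de_mult * gf
  }

  ann_rows <- vector("list", n)
  conc_rows <- vector("list", n)
  sp <- .switch_profiles()
  for (g in seq_len(n)) {
    k <- n_iso[g]
    tid <- sprintf("%s.T%d", gene_id[g], seq_len(k))
    len <- sample(500:5000, k, replace = TRUE)
    if (is_switch[g]) {
      prop <- c(0.5, 0.5)
      conc <- (q[g] * prop) * sp   # 2 x 4, anti-correlated group profiles
      conc <- sweep(conc, 2, de_mult[g, ], "*")
    } else {
      w <- stats::rgamma(k, shape = 5)
      prop <- w / sum(w)
      conc <- outer(q[g] * prop, de_mult[g, ])
    }
    ann_rows[[g]] <- tibble(transcript_id = tid, gene_id = gene_id[g],
                            gene_symbol = fish_symbol[g], length_bp = len)
    conc_rows[[g]] <- conc
  }
  annotation <- bind_rows(ann_rows)
  conc_mat <- do.call(rbind, conc_rows)  # transcripts x groups

  depth <- cf$depth_base * stats::rlnorm(length(groups_vec), 0, cf$depth_sdlog)
  len_kb <- annotation$length_bp / 1000
  counts_mat <- matrix(0, nrow(annotation), length(groups_vec),
                       dimnames = list(annotation$transcript_id, groups_vec))
  for (j in seq_along(groups_vec)) {
    mu <- conc_mat[, j] * len_kb * depth[j]
    if (cf$hp_pool && j == 1) {
      k <- rowSums(vapply(seq_len(cf$n_siblings),
                          function(s) .rnb(length(mu), mu, cf$alpha),
                          numeric(length(mu))))
    } else {
      k <- .rnb(length(mu), mu, cf$alpha)
    }
    counts_mat[, j] <- k
  }
  counts <- .matrix_to_tbl(counts_mat)
  groups <- tibble(sample_id = groups_vec, group = groups_vec)

  # --- ortholog table ------------------------------------------------------
  orthologs <- tibble(fish_gene_id = gene_id, fish_symbol = fish_symbol,
                      human_symbol = human_symbol)

  # --- human arm -----------------------------------------------------------
  set.seed((cf$seed + 104729L) %% .Machine$integer.max)
  shared_syms <- sort(unique(human_symbol[is_shared]))
  extra_syms <- sprintf("HSONLY%04d", seq_len(cf$n_human_extra))
  h_syms <- c(shared_syms, extra_syms)
  h_dir <- truth$human_direction[match(h_syms, truth$symbol)]
  h_dir[is.na(h_dir)] <- "none"
  delta <- ifelse(h_dir == "up", log2(cf$effect_fold),
                  ifelse(h_dir == "down", -log2(cf$effect_fold), 0))
  n_probe <- 1L + (stats::runif(length(h_syms)) < cf$frac_two_probes)
  probe_map <- tibble(
    probe_id = unlist(purrr::map2(h_syms, n_probe,
                                  function(s, k) paste0(s, "_", seq_len(k), "_at"))),
    gene_symbol = rep(h_syms, n_probe))
  base_int <- stats::rnorm(length(h_syms), cf$array_mean, cf$array_sd)
  probe_base <- rep(base_int, n_probe) - (unlist(purrr::map(n_probe, seq_len)) - 1)
  probe_delta <- rep(delta, n_probe)
  samp_ids <- c(sprintf("nevus_%02d", seq_len(cf$n_nevus)),
                sprintf("mel_%02d", seq_len(cf$n_melanoma)))
  is_mel <- c(rep(0, cf$n_nevus), rep(1, cf$n_melanoma))
  im <- matrix(stats::rnorm(nrow(probe_map) * length(samp_ids), 0, cf$array_sigma),
               nrow(probe_map), length(samp_ids),
               dimnames = list(probe_map$probe_id, samp_ids))
  im <- im + probe_base + outer(probe_delta, is_mel)
  intensities <- .intensity_tbl(im, "probe_id")
  human_groups <- tibble(sample_id = samp_ids,
                         group = ifelse(is_mel == 1, "melanoma", "nevus"))

  # --- truth-derived signature and pathway sets ----------------------------
  set.seed((cf$seed + 224737L) %% .Machine$integer.max)
  up_syms <- truth$symbol[idx_up]
  down_syms <- truth$symbol[idx_down]
  null_syms <- setdiff(truth$symbol, c(up_syms, down_syms))
  pick <- function(x, k) sample(x, min(k, length(x)))
  signatures <- list(
    motif1 = c(pick(up_syms, 30), pick(null_syms, 10)),
    motif2 = c(pick(up_syms, 25), pick(null_syms, 15)),
    zf_up = c(pick(up_syms, 20), pick(null_syms, 5)),
    zf_down = c(pick(down_syms, 20), pick(null_syms, 5)))
  cons_down_syms <- truth$symbol[truth$conserved & truth$fish_direction == "down"]
  pathways <- c(
    list(adhesion_like = c(pick(cons_down_syms, 25), pick(null_syms, 15))),
    stats::setNames(purrr::map(1:4, function(i) pick(truth$symbol, 40)),
                    paste0("background_", 1:4)))

  structure(list(counts = counts, annotation = annotation, groups = groups,
                 intensities = intensities, probe_map = probe_map,
                 human_groups = human_groups, orthologs = orthologs,
                 truth = truth, signatures = signatures, pathways = pathways,
                 config = cf),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("<sim_study: %d fish genes (%d transcripts, %d samples), ",
                     "%d human probes (%d samples), seed %d>\n"),
              nrow(x$truth), nrow(x$counts), length(.sample_cols(x$counts)),
              nrow(x$intensities), nrow(x$human_groups), x$config$seed))
  invisible(x)
}

#' Write a simulated study to a directory in the pipeline's file formats
#'
#' Emits `counts.tsv`, `annotation.tsv`, `groups.tsv`, `intensities.tsv`,
#' `probe_map.tsv`, `human_groups.tsv`, `orthologs.tsv`, `truth.tsv`, and
#' `signatures/<name>.txt`, `pathways/<name>.txt`.
#'
#' @param sim A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f), progress = FALSE)
  w(sim$counts, "counts.tsv")
  w(sim$annotation, "annotation.tsv")
  w(sim$groups, "groups.tsv")
  w(sim$intensities, "intensities.tsv")
  w(sim$probe_map, "probe_map.tsv")
  w(sim$human_groups, "human_groups.tsv")
  w(sim$orthologs, "orthologs.tsv")
  w(sim$truth, "truth.tsv")
  dir.create(file.path(dir, "signatures"), showWarnings = FALSE)
  for (nm in names(sim$signatures)) {
    readr::write_lines(c(paste0("# ", nm), sim$signatures[[nm]]),
                       file.path(dir, "signatures", paste0(nm, ".txt")))
  }
  dir.create(file.path(dir, "pathways"), showWarnings = FALSE)
  for (nm in names(sim$pathways)) {
    readr::write_lines(c(paste0("# ", nm), sim$pathways[[nm]]),
                       file.path(dir, "pathways", paste0(nm, ".txt")))
  }
  invisible(dir)
}

#' Score pipeline results against the planted truth
#'
#' For each supplied result type, computes true/false positive counts,
#' sensitivity and false discovery rate against the simulation truth.
#' Conventions: an empty result has sensitivity 0 and FDR 0. A call counts
#' as a true positive only when its direction matches the planted one.
#'
#' @param truth Truth tibble from [simulate_study()].
#' @param fish_de Optional `de_result` (gene level, tumor-vs-reference).
#' @param human_de Optional called human table ([call_array_de()]) with
#'   symbols.
#' @param concordance Optional `concordance_table`.
#' @param splice Optional `splice_result`.
#' @return Tibble: `task`, `n_true`, `n_called`, `tp`, `fp`,
#'   `sensitivity`, `fdr`.
#' @export
score_recovery <- function(truth, fish_de = NULL, human_de = NULL,
                           concordance = NULL, splice = NULL) {
  out <- list()
  score <- function(task, called_ids, called_dir, true_ids, true_dir) {
    tp <- sum(called_ids %in% true_ids &
                called_dir == true_dir[match(called_ids, true_ids)], na.rm = TRUE)
    fp <- length(called_ids) - tp
    tibble(task = task, n_true = length(true_ids), n_called = length(called_ids),
           tp = tp, fp = fp,
           sensitivity = if (length(true_ids)) tp / length(true_ids) else NA_real_,
           fdr = if (length(called_ids)) fp / length(called_ids) else 0)
  }
  if (!is.null(fish_de)) {
    if (!all(fish_de$gene_id %in% truth$gene_id)) abort("fish result ids do not match the truth table")
    called <- fish_de |> filter(.data$call != "none")
    planted <- truth |> filter(.data$fish_direction != "none")
    out$fish <- score("fish_de", called$gene_id, called$call,
                      planted$gene_id, planted$fish_direction)
  }
  if (!is.null(human_de)) {
    tab <- as_tibble(human_de)
    sym_col <- intersect(c("gene_symbol", "id", "symbol"), names(tab))[1]
    tab$symbol <- toupper(tab[[sym_col]])
    called <- tab |> filter(.data$call != "none", .data$symbol %in% truth$symbol)
    planted <- truth |> filter(.data$human_direction != "none")
    out$human <- score("human_de", called$symbol, called$call,
                       planted$symbol, planted$human_direction)
  }
  if (!is.null(concordance)) {
    sets <- conserved_signature(concordance)
    planted_up <- truth$symbol[truth$conserved & truth$fish_direction == "up"]
    planted_down <- truth$symbol[truth$conserved & truth$fish_direction == "down"]
    out$cons <- score("conserved_sets",
                      c(sets$common_up, sets$common_down),
                      rep(c("up", "down"), c(length(sets$common_up), length(sets$common_down))),
                      c(planted_up, planted_down),
                      rep(c("up", "down"), c(length(planted_up), length(planted_down))))
  }
  if (!is.null(splice)) {
    if (!all(splice$gene_id %in% truth$gene_id)) abort("splice result ids do not match the truth table")
    called <- splice |> filter(.data$category == "differential")
    planted <- truth |> filter(.data$switch)
    out$splice <- score("switch_detection", called$gene_id,
                        rep("switch", nrow(called)),
                        planted$gene_id, rep("switch", nrow(planted)))
  }
  if (!length(out)) abort("no results supplied")
  bind_rows(out)
}
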