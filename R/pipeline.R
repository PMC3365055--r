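# Pipeline orchestration: a single structured config, file-based stages in
# dependency order, stderr logging and a machine-readable run manifest.

#' Build a pipeline configuration
#'
#' Thresholds default to the analysis conventions used throughout the
#' package: RPKM expression gate 2, logFC threshold 2 (log2), p 0.05, base
#' mean 10, linear overlap fold 2, RC threshold 1.
#'
#' @param outdir Output directory.
#' @param counts,annotation,groups,intensities,probe_map,human_groups,orthologs
#'   Input file paths (defaults point at a `sim/` subdirectory of `outdir`,
#'   where the `simulate` stage writes them).
#' @param signatures,pathways Directories of signature / pathway `.txt`
#'   files.
#' @param rpkm_gate,logfc,p,base_mean,fold,rc,epsilon Numeric thresholds.
#' @param de_mode `"fc_and_p"` or `"fc_only"` for the combined fish
#'   contrast.
#' @param paralog_policy Passed to [join_on_symbols()].
#' @param correlation `"pearson"` or `"spearman"` for the splice stage.
#' @param collapse `"max_mean"` or `"mean"` probe collapsing.
#' @param seed Seed for the simulate stage.
#' @param sim Optional [sim_config()] overriding the simulate-stage
#'   defaults (its seed is replaced by `seed`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "melacross_out",
                            counts = NULL, annotation = NULL, groups = NULL,
                            intensities = NULL, probe_map = NULL,
                            human_groups = NULL, orthologs = NULL,
                            signatures = NULL, pathways = NULL,
                            rpkm_gate = 2, logfc = 2, p = 0.05,
                            base_mean = 10, fold = 2, rc = 1, epsilon = 1,
                            de_mode = "fc_and_p",
                            paralog_policy = "any_call",
                            correlation = "pearson",
                            collapse = "max_mean",
                            seed = 1, sim = NULL) {
  simdir <- file.path(outdir, "sim")
  paths <- list(
    outdir = outdir,
    counts = counts %||% file.path(simdir, "counts.tsv"),
    annotation = annotation %||% file.path(simdir, "annotation.tsv"),
    groups = groups %||% file.path(simdir, "groups.tsv"),
    intensities = intensities %||% file.path(simdir, "intensities.tsv"),
    probe_map = probe_map %||% file.path(simdir, "probe_map.tsv"),
    human_groups = human_groups %||% file.path(simdir, "human_groups.tsv"),
    orthologs = orthologs %||% file.path(simdir, "orthologs.tsv"),
    signatures = signatures %||% file.path(simdir, "signatures"),
    pathways = pathways %||% file.path(simdir, "pathways"))
  thresholds <- list(rpkm_gate = rpkm_gate, logfc = logfc, p = p,
                     base_mean = base_mean, fold = fold, rc = rc,
                     epsilon = epsilon)
  modes <- list(de_mode = de_mode, paralog_policy = paralog_policy,
                correlation = correlation, collapse = collapse)
  structure(list(paths = paths, thresholds = thresholds, modes = modes,
                 seed = seed, sim = sim),
            class = "pipeline_config")
}

#' Write a config file populated with all defaults
#'
#' @param path YAML file to write.
#' @param config Config to serialize (default: all defaults).
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path, config = pipeline_config()) {
  cfg <- unclass(config)
  cfg$sim <- if (!is.null(cfg$sim)) unclass(cfg$sim) else NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a pipeline config from YAML
#'
#' Fields missing from the file fall back to defaults; unknown fields fail
#' with the offending field path.
#'
#' @param path YAML config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  for (section in names(raw)) {
    if (!section %in% names(base)) {
      abort(paste0("unknown config field: ", section))
    }
    if (section %in% c("paths", "thresholds", "modes")) {
      for (k in names(raw[[section]])) {
        if (!k %in% names(base[[section]])) {
          abort(paste0("unknown config field: ", section, ".", k))
        }
        base[[section]][[k]] <- raw[[section]][[k]]
      }
    } else if (section == "sim") {
      base$sim <- do.call(sim_config, raw$sim)
    } else {
      base[[section]] <- raw[[section]]
    }
  }
  base
}

.log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

.need_inputs <- function(paths) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing)) {
    abort(paste0("missing input file(s) for this stage: ",
                 paste(unlist(missing), collapse = ", ")))
  }
}

.stage_order <- c("simulate", "quantify", "de-fish", "de-human", "splice",
                  "concord", "enrich")

#' Run the pipeline
#'
#' Each stage reads its inputs from files and writes its outputs under
#' `outdir`, so every stage is a pure function of (inputs, config, seed);
#' `"all"` runs the full chain in dependency order. A JSON manifest with
#' the effective config, its hash, the seed and package/R versions is
#' written at the end of every run.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param stage One of `"simulate"`, `"quantify"`, `"de-fish"`,
#'   `"de-human"`, `"splice"`, `"concord"`, `"enrich"`, `"all"`.
#' @param seed Overrides the config seed.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), stage = "all", seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- seed
  stage <- match.arg(stage, c(.stage_order, "all"))
  stages <- if (stage == "all") .stage_order else stage
  out <- config$paths$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (s in stages) {
    .log_msg("INFO", "stage ", s)
    switch(s,
      "simulate" = .stage_simulate(config),
      "quantify" = .stage_quantify(config),
      "de-fish" = .stage_de_fish(config),
      "de-human" = .stage_de_human(config),
      "splice" = .stage_splice(config),
      "concord" = .stage_concord(config),
      "enrich" = .stage_enrich(config))
  }
  manifest <- list(
    stages = stages,
    seed = config$seed,
    config = list(paths = config$paths, thresholds = config$thresholds,
                  modes = config$modes),
    config_hash = rlang::hash(list(config$paths, config$thresholds,
                                   config$modes, config$seed)),
    package_version = as.character(utils::packageVersion("melacross")),
    r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.stage_simulate <- function(config) {
  sc <- config$sim %||% sim_config()
  sc$seed <- config$seed
  sim <- simulate_study(sc)
  write_study(sim, file.path(config$paths$outdir, "sim"))
}

.read_fish_inputs <- function(config) {
  p <- config$paths
  .need_inputs(p[c("counts", "annotation", "groups")])
  read_count_table(p$counts, p$annotation, p$groups)
}

.stage_quantify <- function(config) {
  fish <- .read_fish_inputs(config)
  expr <- rpkm(fish$counts, fish$annotation, gate = config$thresholds$rpkm_gate)
  sf <- size_factors(fish$counts)
  out <- config$paths$outdir
  write_result_table(expr, file.path(out, "rpkm.tsv"))
  write_result_table(sf, file.path(out, "size_factors.tsv"))
}

.fish_de_tables <- function(config) {
  fish <- .read_fish_inputs(config)
  th <- de_thresholds(log2fc = config$thresholds$logfc, p = config$thresholds$p,
                      base_mean = config$thresholds$base_mean,
                      epsilon = config$thresholds$epsilon)
  gc <- gene_counts(fish$counts, fish$annotation)
  sf <- size_factors(fish$counts)
  model <- fit_variance(gc, sf)
  ref <- fish$groups$group[1]
  tumor <- setdiff(unique(fish$groups$group), ref)
  per_tumor <- lapply(tumor, function(tg) {
    suppressMessages(call_de(gc, groups = fish$groups, contrast = c(ref, tg),
                             sf = sf, model = model, mode = "fc_only",
                             thresholds = th))
  })
  names(per_tumor) <- tumor
  cg <- combine_groups(fish$groups, "tumor", tumor)
  combined <- suppressMessages(
    call_de(gc, groups = cg, contrast = c(ref, "tumor"), sf = sf,
            model = model, mode = config$modes$de_mode, thresholds = th))
  list(per_tumor = per_tumor, combined = combined)
}

.stage_de_fish <- function(config) {
  de <- .fish_de_tables(config)
  out <- config$paths$outdir
  for (tg in names(de$per_tumor)) {
    write_result_table(de$per_tumor[[tg]], file.path(out, paste0("de_fish_", tg, ".tsv")))
  }
  write_result_table(de$combined, file.path(out, "de_fish_combined.tsv"))
}

.human_de_table <- function(config) {
  p <- config$paths
  .need_inputs(p[c("intensities", "probe_map", "human_groups")])
  ints <- read_result_table(p$intensities)
  pm <- read_result_table(p$probe_map)
  hg <- read_groups(p$human_groups)
  norm <- quantile_normalize(ints)
  coll <- collapse_probes(norm, pm, method = config$modes$collapse)
  fit <- moderated_t(coll, hg, contrast = c("nevus", "melanoma"),
                     assume_log2 = TRUE)
  call_array_de(fit, fold = config$thresholds$fold, p = config$thresholds$p)
}

.stage_de_human <- function(config) {
  called <- .human_de_table(config)
  write_result_table(called, file.path(config$paths$outdir, "de_human.tsv"))
}

.stage_splice <- function(config) {
  fish <- .read_fish_inputs(config)
  expr <- rpkm(fish$counts, fish$annotation, gate = config$thresholds$rpkm_gate)
  sp <- splice_analysis(expr, fish$annotation, fish$groups,
                        method = config$modes$correlation)
  write_result_table(sp, file.path(config$paths$outdir, "splice.tsv"))
}

.stage_concord <- function(config) {
  p <- config$paths
  .need_inputs(p["orthologs"])
  orth <- suppressMessages(read_ortholog_table(p$orthologs))
  # reuse tables already written by the de stages when available
  comb_path <- file.path(p$outdir, "de_fish_combined.tsv")
  human_path <- file.path(p$outdir, "de_human.tsv")
  de <- if (file.exists(comb_path)) {
    per <- list.files(p$outdir, pattern = "^de_fish_", full.names = TRUE)
    per <- per[!grepl("combined", per)]
    per_tabs <- lapply(per, read_result_table)
    names(per_tabs) <- sub("^de_fish_(.*)\\.tsv$", "\\1", basename(per))
    list(per_tumor = per_tabs, combined = read_result_table(comb_path))
  } else .fish_de_tables(config)
  human <- if (file.exists(human_path)) read_result_table(human_path)
           else .human_de_table(config)
  conc <- suppressMessages(
    join_on_symbols(de$combined, human, orth,
                    paralog_policy = config$modes$paralog_policy))
  out <- p$outdir
  write_result_table(conc, file.path(out, "concordance.tsv"))
  sets <- conserved_signature(conc)
  readr::write_lines(c("# conserved common_up", sets$common_up),
                     file.path(out, "conserved_up.txt"))
  readr::write_lines(c("# conserved common_down", sets$common_down),
                     file.path(out, "conserved_down.txt"))
  # signature overlap report (if signature files are configured)
  reports <- list()
  sig_dir <- p$signatures
  if (dir.exists(sig_dir)) {
    for (f in list.files(sig_dir, pattern = "\\.txt$", full.names = TRUE)) {
      nm <- sub("\\.txt$", "", basename(f))
      dirn <- if (grepl("down", nm)) "down" else "unsigned"
      sig <- read_signature(f, name = nm,
                            direction = if (dirn == "down") "down" else "unsigned")
      quant <- if (startsWith(nm, "zf")) "any" else "all"
      reports[[nm]] <- motif_overlap(de$per_tumor, sig,
                                     fold = config$thresholds$fold,
                                     quantifier = quant, orthologs = orth)
    }
  }
  if (length(reports)) {
    write_result_table(bind_rows(reports), file.path(out, "overlap_report.tsv"))
  }
}

.stage_enrich <- function(config) {
  p <- config$paths
  conc_path <- file.path(p$outdir, "concordance.tsv")
  .need_inputs(list(concordance = conc_path))
  conc <- read_result_table(conc_path)
  universe <- conc$symbol
  lists <- list(
    conserved_down = conc$symbol[conc$conserved_status == "common_down"],
    conserved_up = conc$symbol[conc$conserved_status == "common_up"])
  pathways <- list()
  if (dir.exists(p$pathways)) {
    for (f in list.files(p$pathways, pattern = "\\.txt$", full.names = TRUE)) {
      nm <- sub("\\.txt$", "", basename(f))
      pathways[[nm]] <- read_signature(f, name = nm)$symbols
    }
  }
  if (!length(pathways)) {
    .log_msg("WARN", "no pathway sets configured; skipping enrichment")
    return(invisible(NULL))
  }
  rows <- purrr::imap(lists, function(gl, nm) {
    gl <- intersect(gl, universe)
    if (!length(gl)) return(NULL)
    over_representation(gl, pathways, universe) |>
      mutate(gene_list = nm, .before = 1)
  })
  write_result_table(bind_rows(rows), file.path(p$outdir, "enrichment.tsv"))
}
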