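#' Configuration for an end-to-end pipeline run
#'
#' Bundles the seed, stage toggles, analysis thresholds and simulation
#' parameters for [run_pipeline()]. The default configuration simulates a
#' complete fixture set (expression with planted effects, annotation with
#' planted operons, a promoter with planted regulator boxes, a pair of
#' primer-extension traces and a reporter activity table) and runs every
#' stage on it. All values are plain so the configuration round-trips
#' through YAML.
#'
#' @param seed Integer seed used by every simulation stage.
#' @param stages Named list of logical toggles: simulate, diff, venn,
#'   operons, extend, scan, floe, reporter.
#' @param thresholds Named list: p, fc, fraction, fc_high, gap, named_gap,
#'   min_matches, spacer_min, spacer_max.
#' @param sim Named list of simulation parameters: n_genes, n_replicates,
#'   n_induced, induced_log2fc, n_regr_down, n_regr_up, regr_log2fc,
#'   noise_sd, dropout.
#' @param floe Named list: primer (name, five_prime, three_prime),
#'   tss_offsets, areas_reference, areas_test, n_replicates, jitter_sd.
#' @param reporter_table Path to an activity TSV; defaults to the packaged
#'   norC-lacZ table.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = list(),
                            thresholds = list(),
                            sim = list(),
                            floe = list(),
                            reporter_table = NULL) {
  defaults <- list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, diff = TRUE, venn = TRUE, operons = TRUE,
                  extend = TRUE, scan = TRUE, floe = TRUE, reporter = TRUE),
    thresholds = list(p = 0.025, fc = 2, fraction = 0.75, fc_high = 5,
                      gap = 32, named_gap = 100, min_matches = 5,
                      spacer_min = 2, spacer_max = 7),
    sim = list(n_genes = 200, n_replicates = 4, n_induced = 50,
               induced_log2fc = 3, n_regr_down = 40, n_regr_up = 10,
               regr_log2fc = 3, noise_sd = 0.25, dropout = 0.05),
    floe = list(primer = list(name = "NorC53", five_prime = 53, three_prime = 31),
                tss_offsets = c(-35, -21),
                areas_reference = c(100, 100), areas_test = c(100, 60),
                jitter_sd = 0),
    reporter_table = reporter_table
  )
  cfg <- defaults
  cfg$stages <- utils::modifyList(cfg$stages, stages)
  cfg$thresholds <- utils::modifyList(cfg$thresholds, thresholds)
  cfg$sim <- utils::modifyList(cfg$sim, sim)
  cfg$floe <- utils::modifyList(cfg$floe, floe)
  validate_thresholds(cfg$thresholds)
  structure(cfg, class = "pipeline_config")
}

validate_thresholds <- function(th) {
  ok <- th$p > 0 && th$p <= 1 && th$fc >= 1 && th$fraction >= 0 &&
    th$fraction <= 1 && th$fc_high >= th$fc && th$gap >= 0 &&
    th$named_gap >= th$gap && th$min_matches >= 0 && th$min_matches <= 5 &&
    th$spacer_min <= th$spacer_max
  if (!ok) abort("Thresholds outside documented ranges.",
                 class = "regulonkit_usage_error")
  invisible(th)
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    seed = raw$seed %||% 1L,
    stages = raw$stages %||% list(),
    thresholds = raw$thresholds %||% list(),
    sim = raw$sim %||% list(),
    floe = raw$floe %||% list(),
    reporter_table = raw$reporter_table
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

need_file <- function(path, stage, producer) {
  if (!file.exists(path)) {
    abort(sprintf("Stage '%s' needs '%s', produced by stage '%s' (disabled or failed).",
                  stage, basename(path), producer),
          class = "regulonkit_dependency_error")
  }
  path
}

#' Run the full regulon pipeline over a fixture set
#'
#' Executes, in order: simulate (fixture generation), diff (two
#' differential-expression contrasts), venn (regulon intersection report),
#' operons (operon reconstruction), extend (operon extension of the regulon),
#' scan (promoter box scan), floe (TSS calling and trace comparison) and
#' reporter (activity-table summaries). Stages hand data to each other only
#' through plain files in `out_dir`, so each stage can be rerun or replaced
#' independently; disabling a stage makes any dependent stage fail fast with
#' a dependency error.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return A manifest list (invisibly): seed, stage status, output files with
#'   md5 hashes. Also written to `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  stage_run <- character()
  outputs <- character()
  path <- function(...) file.path(out_dir, ...)

  group_wt_ref <- "wild_type:oxic"
  group_wt_trt <- "wild_type:anoxic_nitrate"
  group_mut_trt <- "regR:anoxic_nitrate"

  if (isTRUE(config$stages$simulate)) {
    sim <- default_fixture_sim(config)
    expr_paths <- write_expression(sim$expression, out_dir)
    readr::write_tsv(sim$truth, path("truth.tsv"))
    ann <- default_fixture_annotation()
    write_annotation_tsv(ann, path("annotation.tsv"))
    promoters <- default_fixture_promoters(config$seed)
    write_promoters_fasta(promoters, path("promoters.fasta"))
    traces <- default_fixture_traces(config)
    write_floe_trace(traces$reference, path("floe_reference.tsv"))
    write_floe_trace(traces$test, path("floe_test.tsv"))
    outputs <- c(outputs, expr_paths, path(c(
      "truth.tsv", "annotation.tsv", "promoters.fasta",
      "floe_reference.tsv", "floe_test.tsv")))
    stage_run <- c(stage_run, "simulate")
  }

  if (isTRUE(config$stages$diff)) {
    expr <- read_expression(
      need_file(path("expression_signals.csv"), "diff", "simulate"),
      need_file(path("expression_calls.csv"), "diff", "simulate"),
      need_file(path("expression_samples.tsv"), "diff", "simulate"))
    diff_wt <- differential_test(expr, group_wt_trt, group_wt_ref,
                                 p_threshold = th$p, fc_threshold = th$fc,
                                 fraction = th$fraction)
    diff_regr <- differential_test(expr, group_mut_trt, group_wt_trt,
                                   p_threshold = th$p, fc_threshold = th$fc,
                                   fraction = th$fraction)
    write_diff_results(diff_wt, path("diff_induced.tsv"))
    write_diff_results(diff_regr, path("diff_regr.tsv"))
    outputs <- c(outputs, path(c("diff_induced.tsv", "diff_regr.tsv")))
    stage_run <- c(stage_run, "diff")
  }

  if (isTRUE(config$stages$venn)) {
    diff_wt <- read_diff_results(need_file(path("diff_induced.tsv"), "venn", "diff"))
    diff_regr <- read_diff_results(need_file(path("diff_regr.tsv"), "venn", "diff"))
    report <- build_regulon_report(diff_wt, diff_regr, fc_high = th$fc_high)
    readr::write_tsv(tidy(report), path("regulon_report.tsv"))
    jsonlite::write_json(as.list(glance(report)), path("regulon_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path(c("regulon_report.tsv", "regulon_summary.json")))
    stage_run <- c(stage_run, "venn")
  }

  if (isTRUE(config$stages$operons)) {
    ann <- read_annotation_tsv(need_file(path("annotation.tsv"), "operons", "simulate"))
    ops <- build_operons(ann, gap_default = th$gap, gap_named = th$named_gap)
    write_operons(ops, path("operons.tsv"))
    outputs <- c(outputs, path("operons.tsv"))
    stage_run <- c(stage_run, "operons")
  }

  if (isTRUE(config$stages$extend)) {
    report_tbl <- readr::read_tsv(
      need_file(path("regulon_report.tsv"), "extend", "venn"),
      show_col_types = FALSE)
    ops <- read_operons(need_file(path("operons.tsv"), "extend", "operons"))
    down <- report_tbl$gene[report_tbl$overlap &
                              report_tbl$direction %in% "down_in_mutant"]
    extended <- extend_by_operon(down, ops)
    readr::write_tsv(tibble(gene = extended), path("regulon_extended.tsv"))
    outputs <- c(outputs, path("regulon_extended.tsv"))
    stage_run <- c(stage_run, "extend")
  }

  if (isTRUE(config$stages$scan)) {
    promoters <- read_promoters_fasta(
      need_file(path("promoters.fasta"), "scan", "simulate"))
    model <- regr_box_model(spacer_min = th$spacer_min,
                            spacer_max = th$spacer_max,
                            min_matches = th$min_matches)
    hits <- dplyr::bind_rows(lapply(promoters, scan_promoter, model = model))
    readr::write_tsv(hits, path("box_hits.tsv"))
    outputs <- c(outputs, path("box_hits.tsv"))
    stage_run <- c(stage_run, "scan")
  }

  if (isTRUE(config$stages$floe)) {
    pr <- config$floe$primer
    primer <- primer_spec(pr$name, pr$five_prime, pr$three_prime)
    ref <- read_floe_trace(need_file(path("floe_reference.tsv"), "floe", "simulate"))
    tst <- read_floe_trace(need_file(path("floe_test.tsv"), "floe", "simulate"))
    tss <- call_tss(ref, primer)
    readr::write_tsv(tss, path("tss_calls.tsv"))
    cmp <- compare_traces(ref, tst)
    readr::write_tsv(cmp, path("trace_comparison.tsv"))
    arch <- assemble_architecture(tss)
    jsonlite::write_json(
      list(elements = arch$elements, distances = arch$distances),
      path("architecture.json"), dataframe = "rows", auto_unbox = TRUE,
      digits = NA)
    outputs <- c(outputs, path(c("tss_calls.tsv", "trace_comparison.tsv",
                                 "architecture.json")))
    stage_run <- c(stage_run, "floe")
  }

  if (isTRUE(config$stages$reporter)) {
    tbl <- if (is.null(config$reporter_table)) {
      norc_lacz_activity()
    } else {
      readr::read_tsv(config$reporter_table, na = "nd", show_col_types = FALSE,
                      col_types = readr::cols(nitrate = readr::col_logical()))
    }
    summary <- dplyr::bind_rows(
      fold_induction(tbl, "wild_type", "anoxia") %>%
        dplyr::mutate(comparison = "nitrate_induction"),
      fold_induction(tbl, "wild_type", "2% O2") %>%
        dplyr::mutate(comparison = "nitrate_induction"),
      strain_ratio(tbl, "wild_type", "regR", "anoxia") %>%
        dplyr::rename(genotype = "genotype_a") %>%
        dplyr::mutate(comparison = paste0("vs_", .data$genotype_b)) %>%
        dplyr::select(-"genotype_b", -"nitrate")
    )
    readr::write_tsv(summary, path("reporter_summary.tsv"))
    outputs <- c(outputs, path("reporter_summary.tsv"))
    stage_run <- c(stage_run, "reporter")
  }

  manifest <- list(
    package = "regulonkit",
    version = as.character(utils::packageVersion("regulonkit")),
    seed = config$seed,
    stages = stage_run,
    files = as.list(tools::md5sum(sort(unique(outputs))))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

default_fixture_sim <- function(config) {
  s <- config$sim
  genes <- sprintf("gene%04d", seq_len(s$n_genes))
  induced_ids <- head(genes, s$n_induced)
  regr_ids <- head(genes, s$n_regr_down + s$n_regr_up)
  cfg <- simulation_config(
    seed = config$seed, n_genes = s$n_genes, n_replicates = s$n_replicates,
    induced = tibble(gene = induced_ids, log2fc = s$induced_log2fc),
    regr_dependent = tibble(
      gene = regr_ids,
      log2fc = c(rep(-s$regr_log2fc, s$n_regr_down),
                 rep(s$regr_log2fc, s$n_regr_up))),
    noise_sd = s$noise_sd, dropout = s$dropout
  )
  simulate_expression(cfg)
}

default_fixture_annotation <- function() {
  simulate_annotation(list(
    operon_run(names = c("nosR", "nosZ", "nosD"), gaps = c(20L, 20L), strand = "+"),
    operon_run(names = c("norC", "norB", "norQ"), gaps = c(90L, 10L), strand = "+"),
    operon_run(n = 2L, gaps = 10L, strand = "-"),
    operon_run(n = 2L, gaps = 50L, strand = "+"),
    operon_run(n = 1L, strand = "+")
  ))
}

default_fixture_promoters <- function(seed) {
  sites <- regr_box_sites()
  nosr <- dplyr::filter(sites, .data$gene == "nosR")
  list(simulate_promoter(
    "nosR", span = c(-195L, 46L),
    boxes = tibble(sequence = nosr$sequence, offset = nosr$offset),
    background = "inert", seed = seed))
}

default_fixture_traces <- function(config) {
  fl <- config$floe
  primer <- primer_spec(fl$primer$name, fl$primer$five_prime,
                        fl$primer$three_prime)
  list(
    reference = simulate_floe(fl$tss_offsets, fl$areas_reference, primer,
                              jitter_sd = fl$jitter_sd, seed = config$seed,
                              strain = "wild_type", condition = "anoxic_nitrate"),
    test = simulate_floe(fl$tss_offsets, fl$areas_test, primer,
                         jitter_sd = fl$jitter_sd, seed = config$seed + 1L,
                         strain = "regR", condition = "anoxic_nitrate")
  )
}
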