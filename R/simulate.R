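#' Configure a synthetic regulon experiment
#'
#' Builds the configuration for [simulate_expression()]. The defaults emulate
#' the design of an anoxic-denitrification transcriptome experiment: three
#' sample groups (wild type grown oxically, wild type grown anoxically with
#' nitrate, and a regulator deletion mutant grown anoxically with nitrate)
#' with four biological replicates each, log-normal signals, and
#' per-replicate detection calls.
#'
#' Planted effects are declared on the log2 scale. Genes in `induced` shift
#' their mean between the reference (oxic) condition and the treatment
#' (anoxic) condition in every strain; genes in `regr_dependent` shift
#' between the mutant strain and the wild type within the treatment
#' condition, with the sign giving the direction (negative = lower in the
#' mutant = positively controlled by the regulator).
#'
#' @param seed Integer seed; a fixed seed makes all outputs byte-identical.
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per group (at least 2; default 4).
#' @param groups Tibble with columns `strain` and `condition`; must contain
#'   the wild-type reference condition, the wild-type treatment condition and
#'   the mutant treatment condition.
#' @param induced Tibble with columns `gene` and `log2fc`: genes induced by
#'   the treatment condition, with their mean log2 shift.
#' @param regr_dependent Tibble with columns `gene` and `log2fc`: genes whose
#'   expression changes in the mutant, signed.
#' @param noise_sd Log2-scale standard deviation of replicate noise.
#' @param dropout Probability that a replicate measurement is called "absent".
#' @param marginal_rate Probability that a detected replicate is called
#'   "marginal" rather than "present".
#' @param baseline_range Range of per-gene baseline log2 means.
#' @param reference_condition,mutant_strain Labels that identify the oxic
#'   reference condition and the regulator-deletion strain within `groups`.
#' @return An object of class `sim_config`.
#' @seealso [simulate_expression()], [simulate_annotation()],
#'   [simulate_promoter()], [simulate_floe()]
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 200L,
                              n_replicates = 4L,
                              groups = default_groups(),
                              induced = NULL,
                              regr_dependent = NULL,
                              noise_sd = 0.25,
                              dropout = 0.05,
                              marginal_rate = 0.05,
                              baseline_range = c(6, 10),
                              reference_condition = "oxic",
                              mutant_strain = "regR") {
  if (n_replicates < 2L) {
    abort("At least 2 replicates per group are required.",
          class = "regulonkit_invalid_design")
  }
  stopifnot(is.data.frame(groups), all(c("strain", "condition") %in% names(groups)))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  empty_effect <- tibble(gene = character(), log2fc = numeric())
  induced <- if (is.null(induced)) empty_effect else as_tibble(induced)
  regr_dependent <- if (is.null(regr_dependent)) empty_effect else as_tibble(regr_dependent)
  for (eff in list(induced, regr_dependent)) {
    if (!all(eff$gene %in% genes)) {
      abort("Planted gene sets must be subsets of the simulated gene ids.")
    }
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates), groups = as_tibble(groups),
         induced = induced, regr_dependent = regr_dependent,
         noise_sd = noise_sd, dropout = dropout, marginal_rate = marginal_rate,
         baseline_range = baseline_range,
         reference_condition = reference_condition,
         mutant_strain = mutant_strain,
         genes = genes),
    class = "sim_config"
  )
}

#' @rdname simulation_config
#' @export
default_groups <- function() {
  tibble(
    strain = c("wild_type", "wild_type", "regR"),
    condition = c("oxic", "anoxic_nitrate", "anoxic_nitrate")
  )
}

#' Simulate a detection-called expression experiment with planted truth
#'
#' Draws linear-scale signals as 2^(baseline + planted effects + noise) and
#' per-replicate detection calls ("present", "marginal", "absent"), with the
#' "absent" call drawn independently of signal at the configured dropout
#' rate. A truth table listing every planted effect accompanies the data.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `expression_sim` with elements
#'   `expression` (long tibble: gene, sample, strain, condition, replicate,
#'   group, signal, call) and `truth` (tibble: gene, induced_log2fc,
#'   regr_log2fc).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  grp <- config$groups
  have_ref <- any(grp$condition == config$reference_condition & grp$strain != config$mutant_strain)
  have_trt <- any(grp$condition != config$reference_condition & grp$strain != config$mutant_strain)
  have_mut <- any(grp$strain == config$mutant_strain)
  if (!(have_ref && have_trt && have_mut)) {
    abort(paste("Groups must include a wild-type reference condition, a wild-type",
                "treatment condition and a mutant treatment condition."),
          class = "regulonkit_invalid_design")
  }
  set.seed(config$seed)
  genes <- config$genes
  n <- config$n_genes
  baseline <- runif(n, config$baseline_range[1], config$baseline_range[2])
  induced_fc <- setNames(numeric(n), genes)
  induced_fc[config$induced$gene] <- config$induced$log2fc
  regr_fc <- setNames(numeric(n), genes)
  regr_fc[config$regr_dependent$gene] <- config$regr_dependent$log2fc

  samples <- tidyr::crossing(grp, replicate = seq_len(config$n_replicates)) %>%
    dplyr::mutate(
      group = paste(.data$strain, .data$condition, sep = ":"),
      sample = paste(.data$group, .data$replicate, sep = "_")
    )

  long <- tidyr::crossing(gene = genes, samples) %>%
    dplyr::arrange(.data$gene, .data$group, .data$replicate)
  mu <- baseline[match(long$gene, genes)] +
    ifelse(long$condition != config$reference_condition, induced_fc[long$gene], 0) +
    ifelse(long$strain == config$mutant_strain, regr_fc[long$gene], 0)
  long$signal <- 2^(mu + rnorm(nrow(long), sd = config$noise_sd))
  u <- runif(nrow(long))
  long$call <- dplyr::case_when(
    u < config$dropout ~ "absent",
    u < config$dropout + (1 - config$dropout) * config$marginal_rate ~ "marginal",
    TRUE ~ "present"
  )

  truth <- tibble(
    gene = genes,
    induced_log2fc = unname(induced_fc),
    regr_log2fc = unname(regr_fc)
  )
  structure(
    list(expression = dplyr::select(
           long, "gene", "sample", "strain", "condition", "replicate",
           "group", "signal", "call"),
         truth = truth, config = config),
    class = "expression_sim"
  )
}

#' Describe one gene run for a synthetic annotation
#'
#' @param n Number of genes in the run (ignored when `names` is given).
#' @param names Optional character vector of mnemonic gene names; use `NA`
#'   for locus-tag-only genes.
#' @param gaps Intergenic gaps in bp between consecutive genes (recycled to
#'   length `n - 1`); each gap is the count of bases strictly between genes.
#' @param strand `"+"` or `"-"`.
#' @return A list describing the run, for [simulate_annotation()].
#' @export
operon_run <- function(n = NULL, names = NULL, gaps = 10L, strand = "+") {
  if (is.null(n)) n <- length(names)
  stopifnot(n >= 1L, strand %in% c("+", "-"))
  if (is.null(names)) names <- rep(NA_character_, n)
  stopifnot(length(names) == n)
  gaps <- rep_len(as.integer(gaps), max(n - 1L, 0L))
  if (any(gaps < 0L)) abort("Intergenic gaps must be >= 0.")
  list(n = as.integer(n), names = names, gaps = gaps, strand = strand)
}

#' Lay out a synthetic gene annotation on a linear replicon
#'
#' Places runs of genes ([operon_run()]) left to right with exactly the
#' requested intra-run gaps and a fixed spacer between runs, so that operon
#' reconstruction has a known truth. Genes never overlap. Locus tags follow
#' the B. japonicum style: `blr` numbers on the plus strand, `bll` on the
#' minus strand.
#'
#' @param plan List of runs created with [operon_run()].
#' @param gene_length Gene length in bp.
#' @param run_spacing Bases between consecutive runs (large enough that runs
#'   never merge).
#' @param origin Start coordinate of the first gene.
#' @param replicon_length Optional length limit; exceeding it is an error of
#'   class `regulonkit_layout_error`.
#' @return Tibble with columns locus_tag, name, strand, start, end.
#' @export
simulate_annotation <- function(plan, gene_length = 900L, run_spacing = 2000L,
                                origin = 1000L, replicon_length = NULL) {
  stopifnot(is.list(plan), length(plan) > 0L)
  rows <- list()
  cursor <- as.integer(origin)
  idx <- 0L
  for (run in plan) {
    for (i in seq_len(run$n)) {
      idx <- idx + 1L
      start <- cursor
      end <- start + as.integer(gene_length) - 1L
      rows[[idx]] <- tibble(
        locus_tag = sprintf("%s%04d", if (run$strand == "+") "blr" else "bll", idx),
        name = run$names[i], strand = run$strand, start = start, end = end
      )
      cursor <- if (i < run$n) end + run$gaps[i] + 1L else end + as.integer(run_spacing) + 1L
    }
  }
  ann <- dplyr::bind_rows(rows)
  if (!is.null(replicon_length) && max(ann$end) > replicon_length) {
    abort("Requested layout exceeds the replicon length.",
          class = "regulonkit_layout_error")
  }
  ann
}

#' Simulate a promoter fragment with embedded regulator boxes
#'
#' Generates the forward-strand sequence of a promoter fragment spanning
#' `span` on the no-zero promoter axis and writes box sequences at the stated
#' offsets. The `"inert"` background is AT-only, which guarantees zero
#' spurious hits for any G/C-anchored box model; `"random"` draws bases
#' uniformly.
#'
#' @param gene Gene id the fragment belongs to.
#' @param span Length-2 vector, offsets of the first and last base (e.g.
#'   `c(-195, 46)`); no position 0 exists.
#' @param boxes Optional tibble with columns `sequence` and `offset` (offset
#'   of the box's 5'-most base). Boxes must not overlap.
#' @param background `"inert"` or `"random"`.
#' @param seed Integer seed.
#' @return An object of class `promoter_seq`: list with `gene`, `sequence`
#'   (character string) and `anchor` (offset of the first base).
#' @export
simulate_promoter <- function(gene, span, boxes = NULL,
                              background = c("inert", "random"), seed = 1L) {
  background <- match.arg(background)
  stopifnot(length(span) == 2L, all(span != 0L))
  len <- span_length(span[1], span[2])
  set.seed(seed)
  alphabet <- if (background == "inert") c("A", "T") else c("A", "C", "G", "T")
  chars <- sample(alphabet, len, replace = TRUE)
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    starts <- offset_to_index(boxes$offset, anchor = span[1])
    widths <- nchar(boxes$sequence)
    ends <- starts + widths - 1L
    if (any(ends > len)) abort("A box extends beyond the fragment span.")
    ord <- order(starts)
    if (any(starts[ord][-1] <= ends[ord][-length(ord)])) {
      abort("Boxes overlap.", class = "regulonkit_placement_error")
    }
    for (i in seq_len(nrow(boxes))) {
      chars[starts[i]:ends[i]] <- strsplit(boxes$sequence[i], "")[[1]]
    }
  }
  structure(list(gene = gene, sequence = paste(chars, collapse = ""),
                 anchor = as.integer(span[1])),
            class = "promoter_seq")
}

#' @export
print.promoter_seq <- function(x, ...) {
  cat(sprintf("<promoter_seq> %s, %d nt, anchor %+d\n",
              x$gene, nchar(x$sequence), x$anchor))
  invisible(x)
}

#' Default internal size-marker ladder for simulated primer-extension traces
#'
#' Fragment sizes of the GeneScan-500 ROX ladder commonly co-run with
#' fluorescent primer-extension products.
#' @return Integer vector of marker sizes (nt).
#' @export
genescan500_markers <- function() {
  c(35L, 50L, 75L, 100L, 139L, 150L, 160L, 200L, 250L,
    300L, 340L, 350L, 400L, 450L, 490L, 500L)
}

#' Simulate a primer-extension (FLOE) trace from known transcript starts
#'
#' Computes the cDNA product length implied by each transcription start site
#' and the reverse primer (the product runs from the primer's 5' end back to
#' the TSS, both bases included), adds optional seeded size jitter, and
#' returns a calibrated peak list alongside the size-marker ladder.
#'
#' @param tss_offsets Integer vector of transcript 5'-end offsets relative to
#'   the translation start (no-zero axis). May be empty.
#' @param areas Peak areas (arbitrary units), one per TSS.
#' @param primer A [primer_spec()].
#' @param labels Optional peak labels; defaults to `P1`, `P2`, ... in input
#'   order.
#' @param markers Marker sizes to include; default [genescan500_markers()].
#' @param jitter_sd Standard deviation (nt) of Gaussian size jitter.
#' @param seed Integer seed.
#' @param strain,condition Sample metadata stored as attributes.
#' @return A tibble of class `floe_trace` with columns type ("peak" or
#'   "marker"), size, area, label.
#' @export
simulate_floe <- function(tss_offsets, areas, primer, labels = NULL,
                          markers = genescan500_markers(), jitter_sd = 0,
                          seed = 1L, strain = NA_character_,
                          condition = NA_character_) {
  stopifnot(inherits(primer, "primer_spec"), length(tss_offsets) == length(areas))
  set.seed(seed)
  if (length(tss_offsets) > 0L) {
    sizes <- implied_cdna_length(tss_offsets, primer) +
      rnorm(length(tss_offsets), sd = jitter_sd)
    if (is.null(labels)) labels <- paste0("P", seq_along(tss_offsets))
    peaks <- tibble(type = "peak", size = sizes, area = as.numeric(areas),
                    label = labels)
  } else {
    peaks <- tibble(type = character(), size = numeric(), area = numeric(),
                    label = character())
  }
  marker_rows <- tibble(type = "marker", size = as.numeric(markers),
                        area = NA_real_, label = paste0("M", markers))
  out <- dplyr::bind_rows(peaks, marker_rows)
  structure(out, class = c("floe_trace", class(out)),
            strain = strain, condition = condition, primer = primer$name)
}

#' Peaks of a FLOE trace
#' @param trace A `floe_trace` tibble (or any tibble with a `type` column).
#' @return The peak rows only.
#' @export
floe_peaks <- function(trace) {
  dplyr::filter(as_tibble(trace), .data$type == "peak")
}
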