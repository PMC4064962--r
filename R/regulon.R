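#' Intersect an induced gene set with a regulator-dependent gene set
#'
#' Reproduces the Venn logic used to define a regulator's regulon under
#' denitrifying conditions: genes induced in the wild type by the anoxic
#' treatment (up only in the wild-type contrast) are intersected with genes
#' differentially expressed in the regulator mutant (either direction, mutant
#' as numerator). The overlap is partitioned by direction - genes lower in
#' the mutant (negative fold change) are positively controlled by the
#' regulator - and a high-confidence subset of the mutant contrast is taken
#' at `|FC| >= fc_high`, over which the percentage under positive control is
#' reported.
#'
#' @param diff_induced [differential_test()] result for the wild-type
#'   treatment-vs-reference contrast (treatment as numerator).
#' @param diff_regr [differential_test()] result for the mutant-vs-wild-type
#'   contrast under treatment (mutant as numerator).
#' @param fc_high Fold-change magnitude defining the high-confidence subset
#'   (default 5).
#' @param operons Optional operon membership from [build_operons()]; when
#'   given, operon-extended versions of the sets are included.
#' @return Object of class `regulon_report` with gene-id sets `induced`,
#'   `regr_diff`, `overlap`, `overlap_down`, `overlap_up`, `high_conf`,
#'   scalar `percent_positive` (NA when `high_conf` is empty), and - when
#'   operons are supplied - `overlap_extended` and `high_conf_extended`.
#' @export
build_regulon_report <- function(diff_induced, diff_regr, fc_high = 5,
                                 operons = NULL) {
  if (!setequal(diff_induced$gene, diff_regr$gene)) {
    abort("The two contrasts were computed over different gene universes.",
          class = "regulonkit_universe_error")
  }
  induced <- sort(diff_induced$gene[diff_induced$de & diff_induced$fc > 0])
  regr_diff <- sort(diff_regr$gene[diff_regr$de])
  overlap <- intersect(induced, regr_diff)
  regr_fc <- setNames(diff_regr$fc, diff_regr$gene)
  overlap_down <- overlap[regr_fc[overlap] < 0]
  overlap_up <- overlap[regr_fc[overlap] > 0]
  high_conf <- regr_diff[abs(regr_fc[regr_diff]) >= fc_high]
  percent_positive <- if (length(high_conf) > 0) {
    100 * sum(regr_fc[high_conf] < 0) / length(high_conf)
  } else {
    NA_real_
  }
  report <- list(
    induced = induced, regr_diff = regr_diff, overlap = overlap,
    overlap_down = overlap_down, overlap_up = overlap_up,
    high_conf = high_conf, percent_positive = percent_positive,
    fc_high = fc_high, regr_fc = regr_fc
  )
  if (!is.null(operons)) {
    report$overlap_extended <- extend_by_operon(overlap, operons)
    report$high_conf_extended <- extend_by_operon(high_conf, operons)
  }
  structure(report, class = "regulon_report")
}

#' @export
print.regulon_report <- function(x, ...) {
  cat("<regulon_report>\n")
  cat(sprintf("  induced (wild type, up):        %d genes\n", length(x$induced)))
  cat(sprintf("  mutant-differential:            %d genes\n", length(x$regr_diff)))
  cat(sprintf("  overlap:                        %d (down %d / up %d)\n",
              length(x$overlap), length(x$overlap_down), length(x$overlap_up)))
  cat(sprintf("  high confidence (|FC| >= %g):   %d genes\n",
              x$fc_high, length(x$high_conf)))
  if (is.na(x$percent_positive)) {
    cat("  percent positively controlled:  not available\n")
  } else {
    cat(sprintf("  percent positively controlled:  %.1f%%\n", x$percent_positive))
  }
  invisible(x)
}

#' Tidy a regulon report into one row per gene
#'
#' @param x A `regulon_report`.
#' @param ... Unused.
#' @return Tibble: gene, induced, regr_diff, overlap, direction (in the
#'   mutant contrast), high_conf.
#' @exportS3Method generics::tidy
tidy.regulon_report <- function(x, ...) {
  genes <- sort(union(x$induced, x$regr_diff))
  tibble(
    gene = genes,
    induced = genes %in% x$induced,
    regr_diff = genes %in% x$regr_diff,
    overlap = genes %in% x$overlap,
    direction = dplyr::case_when(
      genes %in% x$overlap_down ~ "down_in_mutant",
      genes %in% x$overlap_up ~ "up_in_mutant",
      TRUE ~ NA_character_
    ),
    high_conf = genes %in% x$high_conf
  )
}

#' One-row summary of a regulon report
#'
#' @inheritParams tidy.regulon_report
#' @return Tibble with set sizes and `percent_positive`.
#' @exportS3Method generics::glance
glance.regulon_report <- function(x, ...) {
  tibble(
    n_induced = length(x$induced),
    n_regr_diff = length(x$regr_diff),
    n_overlap = length(x$overlap),
    n_overlap_down = length(x$overlap_down),
    n_overlap_up = length(x$overlap_up),
    n_high_conf = length(x$high_conf),
    percent_positive = x$percent_positive
  )
}

#' Bar-chart summary of a regulon report
#'
#' @param object A `regulon_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.regulon_report <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    set = factor(c("induced", "mutant-differential", "overlap",
                   "overlap down", "overlap up", "high confidence"),
                 levels = c("induced", "mutant-differential", "overlap",
                            "overlap down", "overlap up", "high confidence")),
    genes = c(g$n_induced, g$n_regr_diff, g$n_overlap,
              g$n_overlap_down, g$n_overlap_up, g$n_high_conf)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$genes)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Regulon set sizes",
                  subtitle = if (is.na(g$percent_positive)) NULL else
                    sprintf("%.0f%% of the high-confidence set under positive control",
                            g$percent_positive)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Volcano-style plot of a differential-expression contrast
#'
#' @param diff A [differential_test()] result.
#' @param p_threshold,fc_threshold Thresholds drawn as guides.
#' @return A ggplot.
#' @export
plot_differential <- function(diff, p_threshold = 0.025, fc_threshold = 2) {
  df <- dplyr::filter(diff, .data$pass_detection)
  ggplot2::ggplot(df, ggplot2::aes(
    x = sign(.data$fc) * log2(abs(.data$fc)),
    y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$de)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(p_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 name = "differential") +
    ggplot2::labs(x = "signed log2 fold change", y = "-log10 P") +
    ggplot2::theme_minimal()
}

#' Promoter architecture diagram
#'
#' @param object A `promoter_architecture`.
#' @param ... Unused.
#' @return A ggplot with boxes and transcription starts along the promoter
#'   axis.
#' @exportS3Method ggplot2::autoplot
autoplot.promoter_architecture <- function(object, ...) {
  el <- object$elements
  boxes <- dplyr::filter(el, .data$kind == "box")
  tss <- dplyr::filter(el, .data$kind == "tss")
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40")
  if (nrow(boxes) > 0L) {
    boxes$xmax <- vapply(seq_len(nrow(boxes)), function(i) {
      # end offset of a box of given length on the no-zero axis
      end <- boxes$offset[i] + boxes$length[i] - 1L
      if (boxes$offset[i] < 0 && end >= 0) end <- end + 1L
      as.numeric(end)
    }, numeric(1))
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$offset, xmax = .data$xmax,
                   ymin = -0.2, ymax = 0.2, fill = .data$element),
      alpha = 0.7)
  }
  if (nrow(tss) > 0L) {
    p <- p +
      ggplot2::geom_segment(
        data = tss,
        ggplot2::aes(x = .data$offset, xend = .data$offset, y = 0, yend = 0.6),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "black") +
      ggplot2::geom_text(
        data = tss,
        ggplot2::aes(x = .data$offset, y = 0.7, label = .data$element),
        size = 3)
  }
  p + ggplot2::labs(x = "offset relative to translation start (no position 0)",
                    y = NULL, fill = NULL) +
    ggplot2::scale_y_continuous(limits = c(-0.6, 1), breaks = NULL) +
    ggplot2::theme_minimal()
}
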