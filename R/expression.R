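#' Signed fold change between two positive means
#'
#' Ratios below 1 are reported as the negative reciprocal, so a value of -4
#' means four-fold lower in the numerator group; the magnitude is always
#' >= 1 and equal means give +1. In a mutant-versus-wild-type contrast the
#' mutant is the numerator, so genes positively controlled by the regulator
#' (lower in the mutant) carry negative fold changes.
#'
#' @param mean_numerator,mean_denominator Positive linear-scale group means
#'   (vectorized).
#' @return Signed fold change.
#' @examples
#' signed_fold_change(200, 100)  # +2
#' signed_fold_change(25, 100)   # -4
#' @export
signed_fold_change <- function(mean_numerator, mean_denominator) {
  if (any(mean_numerator <= 0) || any(mean_denominator <= 0)) {
    abort("Means must be positive.", class = "regulonkit_domain_error")
  }
  r <- mean_numerator / mean_denominator
  ifelse(r >= 1, r, -1 / r)
}

group_calls <- function(expr, group_label) {
  sub <- dplyr::filter(expr, .data$group == group_label)
  if (nrow(sub) == 0L) {
    abort(sprintf("Unknown group label '%s'.", group_label),
          class = "regulonkit_lookup_error")
  }
  sub
}

#' Detection-call presence filter
#'
#' A gene is retained when it is called "present" or "marginal" in at least
#' `fraction` of the replicates of at least one of the two compared groups
#' (>= comparison, so 3 of 4 replicates passes the default 0.75).
#'
#' @param expr Long expression tibble as produced by [simulate_expression()]
#'   (columns gene, group, replicate, call, signal).
#' @param group_a,group_b Group labels (`"strain:condition"`).
#' @param fraction Minimum detected fraction (default 0.75).
#' @return Character vector of retained gene ids.
#' @export
presence_filter <- function(expr, group_a, group_b, fraction = 0.75) {
  sub <- dplyr::bind_rows(group_calls(expr, group_a), group_calls(expr, group_b))
  keep <- sub %>%
    dplyr::group_by(.data$gene, .data$group) %>%
    dplyr::summarise(
      detected = mean(.data$call %in% c("present", "marginal")),
      .groups = "drop"
    ) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(pass = any(.data$detected >= fraction), .groups = "drop") %>%
    dplyr::filter(.data$pass)
  sort(keep$gene)
}

#' Median-scale expression signals across samples
#'
#' A deliberately simple between-sample normalization: each sample's signals
#' are scaled so that its median matches the global median. It stands in for
#' chip-level normalization, which is out of scope here.
#'
#' @param expr Long expression tibble.
#' @return The tibble with rescaled `signal`.
#' @export
median_normalize <- function(expr) {
  global <- median(expr$signal)
  expr %>%
    dplyr::group_by(.data$sample) %>%
    dplyr::mutate(signal = .data$signal * .env$global / median(.data$signal)) %>%
    dplyr::ungroup()
}

#' Replicate-filtered differential expression between two groups
#'
#' Implements the microarray criteria used to define the regulon: a gene is
#' differentially expressed when it (i) passes the detection-call
#' [presence_filter()], (ii) has a Welch two-sample t-test on log2 signals
#' with P <= `p_threshold`, and (iii) has a signed fold change of magnitude
#' >= `fc_threshold`, computed on linear-scale group means with `group_a` as
#' the numerator. No multiple-testing correction is applied (a raw P
#' threshold is the method's convention). When both groups have zero
#' within-group variance the p-value is defined as 0 if the means differ and
#' 1 otherwise.
#'
#' @inheritParams presence_filter
#' @param p_threshold Raw p-value threshold (default 0.025).
#' @param fc_threshold Minimum fold-change magnitude (default 2).
#' @param normalize If `TRUE`, apply [median_normalize()] first.
#' @return Tibble with one row per gene passing the presence filter over the
#'   full universe: gene, mean_a, mean_b, fc, p_value, pass_detection,
#'   pass_p, pass_fc, direction, de. Genes failing detection are kept with
#'   `pass_detection = FALSE` and NA statistics so contrasts share a gene
#'   universe.
#' @export
differential_test <- function(expr, group_a, group_b, p_threshold = 0.025,
                              fc_threshold = 2, fraction = 0.75,
                              normalize = FALSE) {
  if (normalize) expr <- median_normalize(expr)
  a <- group_calls(expr, group_a)
  b <- group_calls(expr, group_b)
  if (dplyr::n_distinct(a$replicate) < 2L || dplyr::n_distinct(b$replicate) < 2L) {
    abort("Each group needs at least 2 replicates.",
          class = "regulonkit_invalid_design")
  }
  detected <- presence_filter(expr, group_a, group_b, fraction = fraction)

  stats_tbl <- dplyr::bind_rows(a, b) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      mean_a = mean(.data$signal[.data$group == group_a]),
      mean_b = mean(.data$signal[.data$group == group_b]),
      p_value = welch_log2_p(.data$signal[.data$group == group_a],
                             .data$signal[.data$group == group_b]),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      fc = signed_fold_change(.data$mean_a, .data$mean_b),
      pass_detection = .data$gene %in% detected,
      pass_p = .data$p_value <= p_threshold,
      pass_fc = abs(.data$fc) >= fc_threshold,
      direction = ifelse(.data$fc >= 0, "up", "down"),
      de = .data$pass_detection & .data$pass_p & .data$pass_fc
    )
  undetected <- !stats_tbl$pass_detection
  stats_tbl[undetected, c("mean_a", "mean_b", "fc", "p_value")] <- NA_real_
  stats_tbl$direction[undetected] <- NA_character_
  stats_tbl$pass_p[undetected] <- FALSE
  stats_tbl$pass_fc[undetected] <- FALSE
  dplyr::arrange(stats_tbl, .data$gene)
}

welch_log2_p <- function(x, y) {
  lx <- log2(x); ly <- log2(y)
  if (sd(lx) == 0 && sd(ly) == 0) {
    return(if (mean(lx) != mean(ly)) 0 else 1)
  }
  tryCatch(t.test(lx, ly, var.equal = FALSE)$p.value,
           error = function(e) NA_real_)
}

#' Efficiency-corrected relative expression ratio (Pfaffl)
#'
#' ratio = E_target^dCt_target / E_ref^dCt_ref, with dCt oriented as
#' (control - treated) so that a ratio above 1 means higher expression in the
#' treated sample. The reference gene (e.g. the primary sigma factor gene
#' sigA) normalizes for template amounts.
#'
#' @param e_target,e_ref Amplification efficiencies in \[1, 2.2\] (2 = perfect
#'   doubling per cycle).
#' @param dct_target,dct_ref Ct differences (control - treated), in cycles.
#' @return Relative expression ratio.
#' @examples
#' pfaffl_ratio(2, 1, 2, 0)        # 2
#' pfaffl_ratio(1.9, 2, 2, 1)      # 1.805
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (any(c(e_target, e_ref) < 1) || any(c(e_target, e_ref) > 2.2)) {
    abort("Amplification efficiencies must lie in [1, 2.2].",
          class = "regulonkit_domain_error")
  }
  if (any(!is.finite(c(dct_target, dct_ref)))) {
    abort("Ct differences must be finite.", class = "regulonkit_domain_error")
  }
  e_target^dct_target / e_ref^dct_ref
}
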