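#' Beta-galactosidase specific activity in Miller units
#'
#' Standard Miller (1972) arithmetic:
#' 1000 * (A420 - 1.75 * A550) / (t * v * A600), where A550 corrects for
#' cell debris scattering and A600 normalizes to cell density. A negative
#' corrected A420 is reported as activity 0 with the `clamped` attribute set.
#'
#' @param a420,a550,a600 Absorbance readings (A600 > 0).
#' @param t Reaction time in minutes (> 0).
#' @param v Volume of culture assayed in ml (> 0).
#' @return Miller units (vectorized), with attribute `clamped`.
#' @examples
#' miller_units(0.5, 0, 0.5, t = 10, v = 0.1)  # 1000
#' @export
miller_units <- function(a420, a550, a600, t, v) {
  if (any(t <= 0) || any(v <= 0) || any(a600 <= 0)) {
    abort("t, v and A600 must be positive.", class = "regulonkit_domain_error")
  }
  raw <- 1000 * (a420 - 1.75 * a550) / (t * v * a600)
  clamped <- raw < 0
  if (any(clamped)) {
    warn("Negative corrected A420; activity clamped to 0.")
    raw[clamped] <- 0
  }
  attr(raw, "clamped") <- clamped
  raw
}

#' Example reporter-fusion activity table (norC-lacZ)
#'
#' Mean beta-galactosidase activities (Miller units, with standard errors)
#' of a norC-lacZ transcriptional fusion in B. japonicum wild-type,
#' regR-mutant and regS-mutant backgrounds, grown under anoxia or 2% initial
#' O2 with or without nitrate. Cells not determined are NA.
#'
#' @return Tibble: strain, genotype, oxygen, nitrate, activity, se.
#' @export
norc_lacz_activity <- function() {
  path <- system.file("extdata", "norc_lacz_activity.tsv", package = "regulonkit")
  readr::read_tsv(path, na = "nd", show_col_types = FALSE,
                  col_types = readr::cols(nitrate = readr::col_logical()))
}

reporter_cell <- function(table, genotype, oxygen, nitrate) {
  cell <- dplyr::filter(table, .data$genotype == .env$genotype,
                        .data$oxygen == .env$oxygen,
                        .data$nitrate == .env$nitrate)
  if (nrow(cell) != 1L || is.na(cell$activity)) {
    abort(sprintf("No activity value for %s / %s / nitrate=%s.",
                  genotype, oxygen, nitrate),
          class = "regulonkit_lookup_error")
  }
  cell$activity
}

#' Fold induction of reporter activity by nitrate
#'
#' mean(+nitrate) / mean(-nitrate) for one genotype under one oxygen
#' condition, reported raw and rounded to the nearest integer fold (the
#' rounding convention behind "about n-fold" statements).
#'
#' @param table Activity tibble as from [norc_lacz_activity()] (columns
#'   genotype, oxygen, nitrate, activity).
#' @param genotype,oxygen Which genotype and oxygen condition to compare.
#' @return Tibble: genotype, oxygen, ratio, fold (rounded).
#' @export
fold_induction <- function(table, genotype, oxygen) {
  num <- reporter_cell(table, genotype, oxygen, nitrate = TRUE)
  den <- reporter_cell(table, genotype, oxygen, nitrate = FALSE)
  if (den == 0) {
    abort("Zero denominator activity.", class = "regulonkit_domain_error")
  }
  tibble(genotype = genotype, oxygen = oxygen,
         ratio = num / den, fold = round(num / den))
}

#' Activity ratio between two strains under one condition
#'
#' mean(strain_a) / mean(strain_b) at the given oxygen/nitrate condition,
#' with the rounded companion value ("about n-fold lower" when strain_a is
#' the wild type and strain_b the mutant).
#'
#' @inheritParams fold_induction
#' @param genotype_a,genotype_b Numerator and denominator genotypes.
#' @param nitrate Logical, nitrate present.
#' @return Tibble: genotype_a, genotype_b, oxygen, nitrate, ratio, fold.
#' @export
strain_ratio <- function(table, genotype_a, genotype_b, oxygen, nitrate = TRUE) {
  num <- reporter_cell(table, genotype_a, oxygen, nitrate)
  den <- reporter_cell(table, genotype_b, oxygen, nitrate)
  if (den == 0) {
    abort("Zero denominator activity.", class = "regulonkit_domain_error")
  }
  tibble(genotype_a = genotype_a, genotype_b = genotype_b,
         oxygen = oxygen, nitrate = nitrate,
         ratio = num / den, fold = round(num / den))
}
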