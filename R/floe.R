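#' Specify a reverse primer by its offsets on the promoter axis
#'
#' @param name Primer name.
#' @param five_prime,three_prime Offsets of the primer's 5' and 3' ends
#'   relative to the translation start (no-zero axis). For a reverse primer
#'   annealing downstream of the start codon the 5' end is the larger offset
#'   (e.g. +53 to +31).
#' @param sequence Optional primer sequence.
#' @return Object of class `primer_spec`.
#' @examples
#' primer_spec("NorC53", 53, 31)
#' @export
primer_spec <- function(name, five_prime, three_prime, sequence = NULL) {
  if (five_prime <= three_prime) {
    abort("A reverse primer's 5' offset must exceed its 3' offset.")
  }
  structure(list(name = name, five_prime = as.integer(five_prime),
                 three_prime = as.integer(three_prime), sequence = sequence),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat(sprintf("<primer_spec> %s: %+d..%+d (reverse)\n",
              x$name, x$five_prime, x$three_prime))
  invisible(x)
}

primer_length <- function(primer) {
  promoter_distance(primer$five_prime, primer$three_prime) + 1L
}

#' Transcription start offset implied by a primer-extension product length
#'
#' The cDNA spans from the primer's 5'-end base back to the transcript's
#' first base, both included. On the no-zero promoter axis a product of
#' length L from a primer with 5' end at +p therefore starts at offset
#' -(L - p) when L > p (upstream of the start codon) and at p - L + 1
#' otherwise. `implied_cdna_length()` is the exact inverse.
#'
#' @param cdna_length Product length(s) in nt.
#' @param primer A [primer_spec()].
#' @param tss_offsets Nonzero TSS offsets (for the inverse).
#' @return Integer offsets (or lengths for the inverse).
#' @examples
#' p <- primer_spec("NorC53", 53, 31)
#' tss_offset(c(88, 74, 53), p)  # -35, -21, +1
#' @export
tss_offset <- function(cdna_length, primer) {
  stopifnot(inherits(primer, "primer_spec"))
  len <- as.integer(round(cdna_length))
  if (any(len < primer_length(primer))) {
    abort("cDNA product shorter than the primer itself.",
          class = "regulonkit_invalid_product")
  }
  ifelse(len > primer$five_prime,
         -(len - primer$five_prime),
         primer$five_prime - len + 1L)
}

#' @rdname tss_offset
#' @export
implied_cdna_length <- function(tss_offsets, primer) {
  stopifnot(inherits(primer, "primer_spec"), all(tss_offsets != 0L))
  len <- ifelse(tss_offsets < 0L,
                -tss_offsets + primer$five_prime,
                primer$five_prime - tss_offsets + 1L)
  if (any(len < primer_length(primer))) {
    abort("TSS offset lies within or downstream of the primer.",
          class = "regulonkit_invalid_product")
  }
  as.integer(len)
}

#' Calibrate raw peak positions to sizes using an internal marker ladder
#'
#' Assigns each peak a size (nt) by piecewise-linear interpolation between
#' the flanking size markers, rounded to the nearest integer. Peaks outside
#' the marker range are linearly extrapolated from the nearest marker segment
#' and flagged.
#'
#' @param peaks Tibble with a `position` column (raw migration units) and any
#'   other columns (e.g. area, label).
#' @param markers Tibble with columns `position` (raw units) and `size` (nt);
#'   at least two markers.
#' @return `peaks` with added columns `size` (integer nt) and `extrapolated`.
#' @examples
#' calibrate_sizes(tibble::tibble(position = 740, area = 1),
#'                 tibble::tibble(position = c(500, 1000), size = c(50, 100)))
#' @export
calibrate_sizes <- function(peaks, markers) {
  stopifnot(nrow(markers) >= 2L,
            all(c("position", "size") %in% names(markers)))
  markers <- dplyr::arrange(markers, .data$position)
  inside <- approx(markers$position, markers$size, xout = peaks$position,
                   rule = 1)$y
  out <- peaks
  out$extrapolated <- is.na(inside) & !is.na(peaks$position)
  # extrapolate from the terminal marker segments
  lo <- head(markers, 2); hi <- tail(markers, 2)
  slope_lo <- diff(lo$size) / diff(lo$position)
  slope_hi <- diff(hi$size) / diff(hi$position)
  ext <- ifelse(peaks$position < markers$position[1],
                lo$size[1] + (peaks$position - lo$position[1]) * slope_lo,
                hi$size[2] + (peaks$position - hi$position[2]) * slope_hi)
  out$size <- as.integer(round(ifelse(is.na(inside), ext, inside)))
  out
}

#' Percent reduction of a peak area relative to a reference
#'
#' 100 * (1 - area_test / area_reference): 40 means the test peak lost 40%
#' of the reference abundance (peak area is proportional to the number of
#' cDNA molecules).
#'
#' @param area_reference Reference area (> 0).
#' @param area_test Test area (>= 0).
#' @return Percent reduction (negative when the test peak is larger).
#' @export
peak_percent_reduction <- function(area_reference, area_test) {
  if (any(area_reference <= 0) || any(area_test < 0)) {
    abort("Areas must be positive (reference) and non-negative (test).",
          class = "regulonkit_domain_error")
  }
  100 * (1 - area_test / area_reference)
}

#' Call transcription start sites from a FLOE trace
#'
#' Converts every peak's size to a TSS offset with [tss_offset()]. Peaks are
#' labeled in order of decreasing size (most upstream start first) unless
#' they already carry labels.
#'
#' @param trace A `floe_trace` (or tibble with type/size/area/label columns).
#' @param primer A [primer_spec()].
#' @return Tibble: label, offset, size, area.
#' @export
call_tss <- function(trace, primer) {
  peaks <- floe_peaks(trace)
  if (nrow(peaks) == 0L) {
    return(tibble(label = character(), offset = integer(),
                  size = integer(), area = numeric()))
  }
  peaks <- dplyr::arrange(peaks, dplyr::desc(.data$size))
  if (all(is.na(peaks$label)) || all(peaks$label == "")) {
    peaks$label <- paste0("P", seq_len(nrow(peaks)))
  }
  tibble(label = peaks$label,
         offset = tss_offset(peaks$size, primer),
         size = as.integer(round(peaks$size)),
         area = peaks$area)
}

#' Match peaks across two traces and compare their abundances
#'
#' Peaks from the test trace are matched to reference peaks whose calibrated
#' sizes agree within `tol` nt (same transcript), and the percent reduction
#' of each matched peak is reported.
#'
#' @param reference,test `floe_trace` objects or peak tibbles.
#' @param tol Size tolerance in nt for calling two peaks the same transcript.
#' @return Tibble: label, size_reference, size_test, area_reference,
#'   area_test, percent_reduction.
#' @export
compare_traces <- function(reference, test, tol = 1) {
  ref <- floe_peaks(reference)
  tst <- floe_peaks(test)
  rows <- purrr::pmap(ref, function(size, area, label, ...) {
    d <- abs(tst$size - size)
    if (length(d) == 0L || min(d) > tol) return(NULL)
    j <- which.min(d)
    tibble(label = label, size_reference = size, size_test = tst$size[j],
           area_reference = area, area_test = tst$area[j],
           percent_reduction = peak_percent_reduction(area, tst$area[j]))
  })
  dplyr::bind_rows(rows)
}

#' Assemble a promoter architecture from TSS calls and regulatory boxes
#'
#' Collects transcription starts and regulatory-element positions on a common
#' translation-start anchor and computes all pairwise distances on the
#' no-zero axis. Element order in the input does not matter; duplicate
#' transcript labels are an error.
#'
#' @param tss Tibble with columns `label` and `offset` (e.g. from
#'   [call_tss()]).
#' @param boxes Optional tibble with columns `name`, `offset` and `length`
#'   (e.g. regulator boxes from [scan_promoter()], FixK2 boxes supplied by
#'   the user).
#' @return Object of class `promoter_architecture`: list with `elements`
#'   (tibble: element, kind, offset, length) and `distances` (tibble: from,
#'   to, distance), both sorted by offset.
#' @export
assemble_architecture <- function(tss, boxes = NULL) {
  tss <- as_tibble(tss)
  if (anyDuplicated(tss$label)) {
    abort("Duplicate transcript labels.", class = "regulonkit_label_error")
  }
  elements <- tibble(element = tss$label, kind = "tss",
                     offset = as.integer(tss$offset), length = 1L)
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    elements <- dplyr::bind_rows(elements, tibble(
      element = boxes$name, kind = "box",
      offset = as.integer(boxes$offset),
      length = as.integer(boxes$length)
    ))
  }
  elements <- dplyr::arrange(elements, .data$offset)
  pairs <- if (nrow(elements) > 1L) {
    idx <- utils::combn(nrow(elements), 2)
    tibble(
      from = elements$element[idx[1, ]],
      to = elements$element[idx[2, ]],
      distance = promoter_distance(elements$offset[idx[1, ]],
                                   elements$offset[idx[2, ]])
    )
  } else {
    tibble(from = character(), to = character(), distance = integer())
  }
  structure(list(elements = elements, distances = pairs),
            class = "promoter_architecture")
}

#' @export
print.promoter_architecture <- function(x, ...) {
  cat("<promoter_architecture>\n")
  print(x$elements)
  if (nrow(x$distances) > 0L) {
    cat("pairwise distances (bp):\n")
    print(x$distances)
  }
  invisible(x)
}
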