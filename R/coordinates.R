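#' Promoter coordinate arithmetic without a position zero
#'
#' Promoter positions are counted relative to the first base of the annotated
#' translation start codon, which is +1; the base immediately upstream is -1
#' and there is no position 0. These helpers convert between 1-based indices
#' into a promoter fragment and offsets on that axis, and measure distances
#' along it.
#'
#' @param offset,offset_a,offset_b Nonzero integer positions relative to the
#'   translation start (+1 = first base of the start codon).
#' @param index 1-based position within a fragment.
#' @param anchor Offset of the fragment's first base.
#' @return `fragment_index_to_offset()` and `offset_to_index()` return integer
#'   vectors; `promoter_distance()` returns the number of bases stepped
#'   between the two positions.
#' @examples
#' fragment_index_to_offset(123, anchor = -195)  # -73
#' fragment_index_to_offset(15, anchor = -10)    # +5 (the axis skips 0)
#' promoter_distance(-35, -21)                   # 14
#' promoter_distance(-1, 1)                      # 1
#' @name promoter-coordinates
NULL

#' @rdname promoter-coordinates
#' @export
fragment_index_to_offset <- function(index, anchor) {
  stopifnot(length(anchor) == 1L, anchor != 0)
  if (any(index < 1L)) abort("`index` must be >= 1.")
  pos <- anchor + as.integer(index) - 1L
  # crossing from negative to non-negative skips the non-existent position 0
  if (anchor < 0) pos <- ifelse(pos >= 0L, pos + 1L, pos)
  as.integer(pos)
}

#' @rdname promoter-coordinates
#' @export
offset_to_index <- function(offset, anchor) {
  stopifnot(length(anchor) == 1L, anchor != 0)
  if (any(offset == 0L)) abort("Position 0 does not exist on this axis.")
  idx <- as.integer(offset) - as.integer(anchor) + 1L
  if (anchor < 0) idx <- ifelse(offset > 0L, idx - 1L, idx)
  if (any(idx < 1L)) abort("Offset lies upstream of the fragment anchor.")
  as.integer(idx)
}

#' @rdname promoter-coordinates
#' @export
promoter_distance <- function(offset_a, offset_b) {
  if (any(offset_a == 0L) || any(offset_b == 0L)) {
    abort("Offsets of 0 are not valid: the axis has no position 0.")
  }
  as.integer(abs(offset_a - offset_b)) -
    as.integer(sign(offset_a) != sign(offset_b))
}

#' Length of a fragment given its span on the no-zero axis
#'
#' @param from,to Nonzero offsets of the first and last base (from <= to along
#'   the axis).
#' @return Integer number of bases in the span, inclusive.
#' @examples
#' span_length(-195, 46)  # 241
#' @export
span_length <- function(from, to) {
  promoter_distance(from, to) + 1L
}
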