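#' Intergenic gap between two genes
#'
#' The gap is the number of bases strictly between the upstream gene's end
#' and the downstream gene's start: `start - end - 1`. Adjacent genes
#' (start = end + 1) have a gap of 0. Overlapping genes return 0 with an
#' `overlap` attribute set.
#'
#' @param upstream_end End coordinate of the upstream gene.
#' @param downstream_start Start coordinate of the downstream gene
#'   (vectorized).
#' @return Integer gap(s) in bp, with attribute `overlap` (logical).
#' @examples
#' intergenic_gap(100, 101)  # 0, adjacent
#' intergenic_gap(100, 132)  # 31
#' @export
intergenic_gap <- function(upstream_end, downstream_start) {
  gap <- as.integer(downstream_start) - as.integer(upstream_end) - 1L
  overlap <- gap < 0L
  gap[overlap] <- 0L
  attr(gap, "overlap") <- overlap
  gap
}

#' Group annotated genes into operon-like units
#'
#' Two adjacent genes on the same strand are joined when the intergenic gap
#' is below `gap_default` (strictly, matching "separated by less than 32
#' bp"), or - if both carry mnemonic names whose first three letters match
#' case-insensitively (e.g. norC/norB) - when the gap is at most `gap_named`.
#' Transitive closure of the joining relation yields operons; genes left on
#' their own are omitted. Locus tags never count as names for the prefix
#' rule (they share prefixes vacuously), unless `use_names = FALSE` disables
#' the rule entirely.
#'
#' @param annotation Tibble with columns locus_tag, name (NA allowed),
#'   strand, start, end.
#' @param gap_default Joining threshold in bp (genes join when gap <
#'   `gap_default`).
#' @param gap_named Enlarged threshold for name-prefix pairs (join when gap
#'   <= `gap_named`).
#' @param use_names Apply the name-prefix rule (default TRUE).
#' @return Tibble with columns operon, locus_tag, name, strand, start, end,
#'   ordered genomically within each operon; singleton genes are absent.
#' @export
build_operons <- function(annotation, gap_default = 32L, gap_named = 100L,
                          use_names = TRUE) {
  ann <- as_tibble(annotation)
  stopifnot(all(c("locus_tag", "name", "strand", "start", "end") %in% names(ann)))
  if (is.unsorted(ann$start)) {
    warn("Annotation was not sorted by start coordinate; sorting.")
    ann <- dplyr::arrange(ann, .data$start)
  }
  n <- nrow(ann)
  if (n < 2L) {
    return(tibble(operon = character(), locus_tag = character(),
                  name = character(), strand = character(),
                  start = integer(), end = integer()))
  }
  join <- vapply(seq_len(n - 1L), function(i) {
    up <- ann[i, ]; dn <- ann[i + 1L, ]
    if (up$strand != dn$strand) return(FALSE)
    gap <- intergenic_gap(up$end, dn$start)
    if (gap < gap_default) return(TRUE)
    if (use_names && !is.na(up$name) && !is.na(dn$name) &&
        nchar(up$name) >= 3L && nchar(dn$name) >= 3L &&
        tolower(substr(up$name, 1, 3)) == tolower(substr(dn$name, 1, 3))) {
      return(gap <= gap_named)
    }
    FALSE
  }, logical(1))
  unit <- cumsum(c(TRUE, !join))
  ann$operon_unit <- unit
  multi <- ann %>%
    dplyr::count(.data$operon_unit) %>%
    dplyr::filter(.data$n >= 2L) %>%
    dplyr::pull(.data$operon_unit)
  out <- ann %>%
    dplyr::filter(.data$operon_unit %in% multi) %>%
    dplyr::mutate(operon = sprintf("operon%03d", match(.data$operon_unit, multi))) %>%
    dplyr::select("operon", "locus_tag", "name", "strand", "start", "end")
  out
}

#' Extend a gene set with all members of operons it touches
#'
#' For every operon containing at least one input gene, all members of that
#' operon are added to the set (used to report "putative operon members"
#' alongside a regulon). The operation is idempotent.
#'
#' @param genes Character vector of locus tags.
#' @param operons Operon membership tibble from [build_operons()].
#' @param annotation Optional annotation tibble; genes absent from it trigger
#'   a warning but are passed through.
#' @return Character vector: union of the input set with co-operonic genes,
#'   sorted.
#' @export
extend_by_operon <- function(genes, operons, annotation = NULL) {
  if (!is.null(annotation)) {
    missing <- setdiff(genes, annotation$locus_tag)
    if (length(missing) > 0L) {
      warn(sprintf("Genes not in annotation, passed through: %s",
                   paste(missing, collapse = ", ")))
    }
  }
  hit_ops <- unique(operons$operon[operons$locus_tag %in% genes])
  sort(union(genes, operons$locus_tag[operons$operon %in% hit_ops]))
}
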