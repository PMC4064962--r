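#' Write and read a detection-called expression set as plain files
#'
#' The on-disk representation is a wide signal matrix CSV (genes x samples),
#' a parallel detection-call CSV with identical dimensions, and a sample
#' sheet TSV (sample, strain, condition, replicate, group).
#'
#' @param expr Long expression tibble (gene, sample, strain, condition,
#'   replicate, group, signal, call).
#' @param dir Directory to write into (created if needed).
#' @param prefix File-name prefix.
#' @return `write_expression()` returns the three paths invisibly;
#'   `read_expression()` returns the long tibble.
#' @export
write_expression <- function(expr, dir, prefix = "expression") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  signals <- tidyr::pivot_wider(
    dplyr::select(expr, "gene", "sample", "signal"),
    names_from = "sample", values_from = "signal")
  calls <- tidyr::pivot_wider(
    dplyr::select(expr, "gene", "sample", "call"),
    names_from = "sample", values_from = "call")
  samples <- dplyr::distinct(
    dplyr::select(expr, "sample", "strain", "condition", "replicate", "group"))
  paths <- file.path(dir, paste0(prefix, c("_signals.csv", "_calls.csv",
                                           "_samples.tsv")))
  readr::write_csv(signals, paths[1])
  readr::write_csv(calls, paths[2])
  readr::write_tsv(samples, paths[3])
  invisible(paths)
}

#' @rdname write_expression
#' @param signals_path,calls_path,samples_path Paths written by
#'   `write_expression()`.
#' @export
read_expression <- function(signals_path, calls_path, samples_path) {
  signals <- readr::read_csv(signals_path, show_col_types = FALSE) %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "signal")
  calls <- readr::read_csv(calls_path, show_col_types = FALSE) %>%
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "call")
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  signals %>%
    dplyr::inner_join(calls, by = c("gene", "sample")) %>%
    dplyr::inner_join(samples, by = "sample") %>%
    dplyr::select("gene", "sample", "strain", "condition", "replicate",
                  "group", "signal", "call") %>%
    dplyr::arrange(.data$gene, .data$group, .data$replicate)
}

#' Gene annotation I/O (TSV and GFF3)
#'
#' The TSV form has columns locus_tag, name, strand, start, end. The GFF3
#' form writes one `gene` feature per row with `ID` = locus tag and `Name` =
#' mnemonic name (omitted when NA), via rtracklayer.
#'
#' @param annotation Annotation tibble.
#' @param path Output path.
#' @return Readers return the annotation tibble sorted by start.
#' @name annotation-io
NULL

#' @rdname annotation-io
#' @export
write_annotation_tsv <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname annotation-io
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(name = readr::col_character())) %>%
    dplyr::arrange(.data$start)
}

#' @rdname annotation-io
#' @param seqname Chromosome/replicon name used in the GFF3.
#' @export
write_annotation_gff3 <- function(annotation, path, seqname = "chr") {
  rlang::check_installed(c("rtracklayer", "GenomicRanges", "IRanges"))
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = annotation$start, end = annotation$end),
    strand = annotation$strand
  )
  gr$type <- "gene"
  gr$ID <- annotation$locus_tag
  gr$Name <- annotation$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname annotation-io
#' @export
read_annotation_gff3 <- function(path) {
  rlang::check_installed(c("rtracklayer", "GenomicRanges"))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  tibble(
    locus_tag = as.character(gr$ID),
    name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_,
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  ) %>%
    dplyr::arrange(.data$start)
}

#' Promoter FASTA I/O with anchor offsets
#'
#' Promoter fragments are stored as FASTA with the fragment's anchor (offset
#' of its first base relative to the translation start) declared in the
#' description line as `anchor=-195`.
#'
#' @param promoters A `promoter_seq` or list of them.
#' @param path FASTA path.
#' @return `read_promoters_fasta()` returns a named list of `promoter_seq`.
#' @export
write_promoters_fasta <- function(promoters, path) {
  rlang::check_installed("Biostrings")
  if (inherits(promoters, "promoter_seq")) promoters <- list(promoters)
  seqs <- Biostrings::DNAStringSet(vapply(promoters, `[[`, "", "sequence"))
  names(seqs) <- vapply(promoters, function(p) {
    sprintf("%s anchor=%d", p$gene, p$anchor)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  rlang::check_installed("Biostrings")
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    header <- names(seqs)[i]
    gene <- sub("\\s.*$", "", header)
    anchor <- stringr::str_match(header, "anchor=(-?\\d+)")[, 2]
    if (is.na(anchor)) {
      abort(sprintf("FASTA header '%s' lacks an anchor= field.", header))
    }
    structure(list(gene = gene, sequence = as.character(seqs[[i]]),
                   anchor = as.integer(anchor)),
              class = "promoter_seq")
  })
  names(out) <- vapply(out, `[[`, "", "gene")
  out
}

#' FLOE trace I/O
#'
#' Traces are TSVs with columns type (peak/marker), size, area, label, plus
#' strain and condition columns carrying the sample metadata.
#'
#' @param trace A `floe_trace`.
#' @param path TSV path.
#' @export
write_floe_trace <- function(trace, path) {
  out <- as_tibble(trace)
  out$strain <- attr(trace, "strain") %||% NA_character_
  out$condition <- attr(trace, "condition") %||% NA_character_
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_floe_trace
#' @export
read_floe_trace <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  strain <- if ("strain" %in% names(tbl)) tbl$strain[1] else NA_character_
  condition <- if ("condition" %in% names(tbl)) tbl$condition[1] else NA_character_
  tbl <- dplyr::select(tbl, -dplyr::any_of(c("strain", "condition")))
  structure(tbl, class = c("floe_trace", class(tbl)),
            strain = strain, condition = condition)
}

#' Differential-expression and operon table I/O
#'
#' @param x Tibble to write.
#' @param path TSV path.
#' @name table-io
NULL

#' @rdname table-io
#' @export
write_diff_results <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_diff_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(direction = readr::col_character()))
}

#' @rdname table-io
#' @export
write_operons <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_operons <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(name = readr::col_character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
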