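#' Spaced-dyad degenerate RegR box model
#'
#' The RegR binding site is modeled as two G/C-anchored half sites separated
#' by a variable spacer. The first half site is a 6-nt window whose positions
#' 2, 4 and 6 are G, G and C (the leading base is part of the reported box
#' but unconstrained); the second half site is a 3-nt window with G at
#' position 1 and C at position 3. A candidate window scores one point per
#' matching conserved position (5 in total) and is reported when the score
#' reaches `min_matches`.
#'
#' The default spacer range is 2..7 nt: scanning the published site
#' collection ([regr_box_sites()]) shows perfect sites with spacers from 3 to
#' 7, so the upper bound is 7 rather than the 6 that most sites would
#' suggest. [fit_box_model()] re-derives the spacer range and the match
#' requirement from any site collection.
#'
#' @param spacer_min,spacer_max Allowed spacer lengths (nt) between half
#'   sites.
#' @param min_matches Required number of matching conserved positions (of 5).
#' @return An object of class `regr_box_model`.
#' @export
regr_box_model <- function(spacer_min = 2L, spacer_max = 7L, min_matches = 5L) {
  stopifnot(spacer_min <= spacer_max, spacer_min >= 0L, min_matches <= 5L)
  structure(
    list(
      half1_len = 6L, half1_pos = c(2L, 4L, 6L), half1_base = c("G", "G", "C"),
      half2_len = 3L, half2_pos = c(1L, 3L), half2_base = c("G", "C"),
      spacer_min = as.integer(spacer_min), spacer_max = as.integer(spacer_max),
      min_matches = as.integer(min_matches)
    ),
    class = "regr_box_model"
  )
}

#' @export
print.regr_box_model <- function(x, ...) {
  cat(sprintf(
    "<regr_box_model> .G.G.C [spacer %d-%d] G.C, min %d/5 conserved matches\n",
    x$spacer_min, x$spacer_max, x$min_matches))
  invisible(x)
}

score_window <- function(chars, w, spacer, model) {
  h2_start <- w + model$half1_len + spacer
  sum(chars[w + model$half1_pos - 1L] == model$half1_base) +
    sum(chars[h2_start + model$half2_pos - 1L] == model$half2_base)
}

#' Scan a promoter fragment for regulator boxes
#'
#' Slides the spaced-dyad model over the forward strand for every spacer
#' length in the model's range, scores each window by its conserved-position
#' matches, and reports windows reaching `min_matches`. Overlapping hits are
#' deduplicated to the best-scoring one (ties broken by shorter spacer, then
#' leftmost start). Hit offsets are the box's 5'-most base relative to the
#' translation start, via [fragment_index_to_offset()]. Ambiguity codes
#' (non-ACGT characters) count as mismatches, with a warning.
#'
#' @param promoter A `promoter_seq` from [simulate_promoter()] or
#'   [read_promoters_fasta()].
#' @param model A [regr_box_model()].
#' @param revcomp Also scan the reverse complement and report mirrored hits
#'   with `strand = "-"` (default FALSE: published site collections are given
#'   on the displayed strand).
#' @param dedup Deduplicate overlapping hits (default TRUE).
#' @return Tibble: gene, offset, strand, match (the matched sequence,
#'   half1 + spacer + half2), score, spacer.
#' @export
scan_promoter <- function(promoter, model = regr_box_model(), revcomp = FALSE,
                          dedup = TRUE) {
  stopifnot(inherits(promoter, "promoter_seq"), inherits(model, "regr_box_model"))
  seq_fwd <- toupper(promoter$sequence)
  if (grepl("[^ACGT]", seq_fwd)) {
    warn("Sequence contains ambiguity codes; they are scored as mismatches.")
  }
  hits <- scan_strand(seq_fwd, model, strand = "+")
  if (revcomp) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq_fwd, "")[[1]]), collapse = ""))
    rhits <- scan_strand(rc, model, strand = "-")
    # map reverse-strand window starts back to forward coordinates of the
    # hit's 5'-most base on the forward strand
    if (nrow(rhits) > 0L) {
      rhits$index <- nchar(seq_fwd) - (rhits$index + rhits$width - 1L) + 1L
    }
    hits <- dplyr::bind_rows(hits, rhits)
  }
  if (dedup && nrow(hits) > 1L) hits <- dedup_hits(hits)
  hits$offset <- if (nrow(hits) > 0L) {
    fragment_index_to_offset(hits$index, promoter$anchor)
  } else integer()
  hits$gene <- rep(promoter$gene, nrow(hits))
  dplyr::select(hits, "gene", "offset", "strand", "match", "score", "spacer") %>%
    dplyr::arrange(.data$offset)
}

scan_strand <- function(seq, model, strand) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rows <- list()
  k <- 0L
  for (spacer in model$spacer_min:model$spacer_max) {
    width <- model$half1_len + spacer + model$half2_len
    if (width > n) next
    for (w in seq_len(n - width + 1L)) {
      sc <- score_window(chars, w, spacer, model)
      if (sc >= model$min_matches) {
        k <- k + 1L
        rows[[k]] <- tibble(
          index = w, width = width, strand = strand,
          match = substr(seq, w, w + width - 1L),
          score = sc, spacer = spacer
        )
      }
    }
  }
  if (k == 0L) {
    return(tibble(index = integer(), width = integer(), strand = character(),
                  match = character(), score = integer(), spacer = integer()))
  }
  dplyr::bind_rows(rows)
}

dedup_hits <- function(hits) {
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$spacer, .data$index)
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    overlaps <- nrow(kept) > 0L &&
      any(h$strand == kept$strand &
            h$index <= kept$index + kept$width - 1L &
            kept$index <= h$index + h$width - 1L)
    if (!overlaps) kept <- dplyr::bind_rows(kept, h)
  }
  dplyr::arrange(kept, .data$index)
}

#' Fit a spaced-dyad box model to a collection of binding sites
#'
#' For each site the best interpretation as half1 + spacer + half2 is found
#' by exhaustive enumeration of all (start, spacer) windows with spacers from
#' 0 to `max_spacer`, keeping the window with the highest conserved-position
#' score. When a site carries `conserved` annotations (1-based positions of
#' its conserved bases), windows agreeing most with the annotation are
#' preferred among equal scorers; remaining ties go to the shorter spacer,
#' then the leftmost start. The fitted model takes its spacer range from the
#' observed spacers and its `min_matches` from the worst site, so that every
#' input site rescans as a hit (closure).
#'
#' @param sites Tibble with column `sequence` and optionally `conserved`
#'   (character, comma-separated 1-based positions) as in [regr_box_sites()].
#' @param max_spacer Largest spacer considered during fitting.
#' @return A [regr_box_model()] with attribute `fit` (per-site tibble:
#'   sequence, start, spacer, score).
#' @export
fit_box_model <- function(sites, max_spacer = 10L) {
  sites <- as_tibble(sites)
  stopifnot("sequence" %in% names(sites), nrow(sites) >= 2L)
  probe <- regr_box_model(spacer_min = 0L, spacer_max = max_spacer,
                          min_matches = 0L)
  per_site <- purrr::pmap(sites, function(sequence, ...) {
    extra <- list(...)
    annotated <- if (!is.null(extra$conserved) && !is.na(extra$conserved)) {
      as.integer(strsplit(as.character(extra$conserved), ",")[[1]])
    } else integer()
    best_window(sequence, probe, annotated)
  })
  bad <- vapply(per_site, is.null, logical(1))
  if (any(bad)) {
    abort(paste("No half1/half2 frame found for site(s):",
                paste(sites$sequence[bad], collapse = ", ")),
          class = "regulonkit_fit_error")
  }
  fit <- dplyr::bind_rows(per_site)
  fit$sequence <- sites$sequence
  model <- regr_box_model(
    spacer_min = min(fit$spacer), spacer_max = max(fit$spacer),
    min_matches = min(fit$score)
  )
  attr(model, "fit") <- dplyr::select(fit, "sequence", "start", "spacer", "score")
  model
}

best_window <- function(sequence, probe, annotated) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  best <- NULL
  for (spacer in probe$spacer_min:probe$spacer_max) {
    width <- probe$half1_len + spacer + probe$half2_len
    if (width > n) next
    for (w in seq_len(n - width + 1L)) {
      slots <- c(w + probe$half1_pos - 1L,
                 w + probe$half1_len + spacer + probe$half2_pos - 1L)
      bases <- c(probe$half1_base, probe$half2_base)
      ok <- chars[slots] == bases
      sc <- sum(ok)
      # anchor requirement: both half-site leading Gs must be present
      if (!(ok[1] && ok[4])) next
      agree <- if (length(annotated) > 0L) sum(slots[ok] %in% annotated) else 0L
      cand <- tibble(start = w, spacer = spacer, score = sc, agree = agree)
      if (is.null(best) ||
          sc > best$score ||
          (sc == best$score && agree > best$agree) ||
          (sc == best$score && agree == best$agree && spacer < best$spacer)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) NULL else dplyr::select(best, "start", "spacer", "score")
}

#' Published RegR binding-site collection
#'
#' The ten putative RegR boxes identified upstream of anoxically induced,
#' RegR-controlled B. japonicum genes, with the 5' offset of each box
#' relative to the translation start of its gene and the 1-based positions of
#' the conserved (highlighted) nucleotides within each printed sequence. One
#' norC site carries only four conserved positions; it only reaches 4 of 5
#' model matches and is recovered by the fitted model rather than the strict
#' default.
#'
#' @return Tibble: gene, offset, sequence, conserved.
#' @export
regr_box_sites <- function() {
  path <- system.file("extdata", "regr_box_sites.tsv", package = "regulonkit")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(conserved = readr::col_character())) %>%
    dplyr::mutate(offset = as.integer(.data$offset))
}

#' EMSA promoter-fragment spans for the RegR site collection
#'
#' Genomic spans (relative to each gene's translation start, no-zero axis) of
#' the PCR fragments within which the [regr_box_sites()] were found, plus
#' whether a band shift was observed with phosphorylated RegR.
#'
#' @return Tibble: gene, span_from, span_to, shift.
#' @export
regr_emsa_fragments <- function() {
  path <- system.file("extdata", "regr_emsa_fragments.tsv", package = "regulonkit")
  readr::read_tsv(path, show_col_types = FALSE)
}
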