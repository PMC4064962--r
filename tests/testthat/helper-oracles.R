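# Independent brute-force oracles. These deliberately re-derive each result
# by enumeration, not by calling the implementation under test.

# positions on the promoter axis between lo and hi, which has no 0
nozero_axis <- function(lo, hi) setdiff(seq(lo, hi), 0L)

# stepwise distance between two axis positions
oracle_promoter_distance <- function(a, b) {
  axis <- nozero_axis(min(a, b), max(a, b))
  abs(match(a, axis) - match(b, axis))
}

# offset reached by walking (index - 1) steps downstream from anchor
oracle_index_to_offset <- function(index, anchor) {
  axis <- nozero_axis(anchor, anchor + index + 1L)
  axis[index]
}

# TSS offset implied by a cDNA of length L ending at the primer 5' base:
# count L axis positions backwards from the primer 5' offset
oracle_tss_offset <- function(len, five_prime) {
  axis <- nozero_axis(five_prime - len - 2L, five_prime)
  upto <- axis[axis <= five_prime]
  upto[length(upto) - len + 1L]
}

# per-gene recount of the detection filter from the raw call matrix
oracle_presence <- function(expr, group_a, group_b, fraction = 0.75) {
  genes <- sort(unique(expr$gene))
  keep <- vapply(genes, function(g) {
    ok <- vapply(c(group_a, group_b), function(grp) {
      calls <- expr$call[expr$gene == g & expr$group == grp]
      sum(calls %in% c("present", "marginal")) / length(calls) >= fraction
    }, logical(1))
    any(ok)
  }, logical(1))
  genes[keep]
}

# O(n^2) pairwise-closure operon oracle: join adjacent same-strand pairs by
# the distance/name rule, then take connected components by repeated merging
oracle_operons <- function(ann, gap_default = 32L, gap_named = 100L) {
  ann <- ann[order(ann$start), ]
  n <- nrow(ann)
  comp <- seq_len(n)
  for (i in seq_len(max(n - 1L, 0L))) {
    up <- ann[i, ]; dn <- ann[i + 1L, ]
    if (up$strand != dn$strand) next
    between <- if (dn$start > up$end) dn$start - up$end - 1L else 0L
    joined <- between < gap_default
    if (!joined && !is.na(up$name) && !is.na(dn$name)) {
      if (tolower(substr(up$name, 1, 3)) == tolower(substr(dn$name, 1, 3))) {
        joined <- between <= gap_named
      }
    }
    if (joined) comp[comp == comp[i + 1L]] <- comp[i]
  }
  groups <- split(ann$locus_tag, comp)
  unname(Filter(function(g) length(g) >= 2L, groups))
}

# exhaustive (start, spacer) motif enumeration; returns every window meeting
# min_matches, no deduplication
oracle_scan <- function(sequence, anchor, spacer_min, spacer_max, min_matches) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  hits <- list()
  k <- 0L
  for (w in seq_len(n)) {
    for (sp in spacer_min:spacer_max) {
      last <- w + 5L + sp + 3L
      if (last > n) next
      sc <- (chars[w + 1L] == "G") + (chars[w + 3L] == "G") +
        (chars[w + 5L] == "C") + (chars[w + 6L + sp] == "G") +
        (chars[w + 8L + sp] == "C")
      if (sc >= min_matches) {
        k <- k + 1L
        hits[[k]] <- data.frame(index = w, spacer = sp, score = sc)
      }
    }
  }
  if (k == 0L) return(data.frame(index = integer(), spacer = integer(),
                                 score = integer()))
  out <- do.call(rbind, hits)
  out$offset <- vapply(out$index, oracle_index_to_offset, integer(1),
                       anchor = anchor)
  out[order(out$offset, out$spacer), ]
}

random_annotation <- function(n_genes, seed) {
  set.seed(seed)
  pool <- c("nos", "nor", "nap", "cop", "fix")
  start <- 100L
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    len <- sample(300:1200, 1)
    strand <- sample(c("+", "-"), 1)
    named <- runif(1) < 0.4
    name <- if (named) paste0(sample(pool, 1), sample(LETTERS, 1)) else NA_character_
    rows[[i]] <- tibble::tibble(
      locus_tag = sprintf("g%04d", i), name = name, strand = strand,
      start = start, end = start + len
    )
    start <- start + len + sample(0:120, 1) + 1L
  }
  dplyr::bind_rows(rows)
}

operon_sets <- function(operon_tbl) {
  unname(lapply(split(operon_tbl$locus_tag, operon_tbl$operon), sort))
}

same_partition <- function(a, b) {
  norm <- function(x) sort(vapply(x, function(g) paste(sort(g), collapse = ","), ""))
  identical(norm(a), norm(b))
}
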