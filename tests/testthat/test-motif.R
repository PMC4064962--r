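nosr_promoter <- function(seed = 1) {
  sites <- regr_box_sites()
  nosr <- dplyr::filter(sites, gene == "nosR")
  simulate_promoter("nosR", c(-195L, 46L),
                    boxes = tibble::tibble(sequence = nosr$sequence,
                                           offset = nosr$offset),
                    background = "inert", seed = seed)
}

test_that("an AT-only fragment contains no boxes", {
  p <- simulate_promoter("empty", c(-100L, 20L), background = "inert", seed = 3)
  expect_identical(nrow(scan_promoter(p)), 0L)
})

test_that("the nosR promoter yields exactly its two planted boxes", {
  hits <- scan_promoter(nosr_promoter())
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$offset, c(-73L, -39L))
  expect_identical(hits$score, c(5L, 5L))
  expect_identical(hits$spacer, c(3L, 3L))
})

test_that("hit offsets shift with the fragment anchor, skipping zero", {
  sites <- regr_box_sites()
  nosr <- dplyr::filter(sites, gene == "nosR")
  base <- scan_promoter(nosr_promoter())
  for (shift in c(-8L, 13L)) {
    span <- c(-195L, 46L) + shift
    span[span == 0L] <- sign(shift)  # keep a legal no-zero span
    p <- simulate_promoter("nosR", span,
                           boxes = tibble::tibble(
                             sequence = nosr$sequence,
                             offset = nosr$offset),
                           background = "inert", seed = 1)
    hits <- scan_promoter(p)
    expect_identical(hits$offset, base$offset)
  }
})

test_that("nine published sites are perfect matches; the tenth needs one mismatch", {
  sites <- regr_box_sites()
  n_hits <- vapply(seq_len(nrow(sites)), function(i) {
    p <- structure(list(gene = sites$gene[i], sequence = sites$sequence[i],
                        anchor = sites$offset[i]),
                   class = "promoter_seq")
    nrow(scan_promoter(p, regr_box_model(min_matches = 5)))
  }, integer(1))
  expect_identical(sum(n_hits >= 1L), 9L)
  # the degenerate site still surfaces when one mismatch is allowed
  weak <- which(n_hits == 0L)
  expect_identical(sites$gene[weak], "norC")
  p <- structure(list(gene = "norC", sequence = sites$sequence[weak],
                      anchor = sites$offset[weak]), class = "promoter_seq")
  expect_gte(nrow(scan_promoter(p, regr_box_model(min_matches = 4))), 1L)
})

test_that("a model fitted to the published sites rescans all of them (closure)", {
  sites <- regr_box_sites()
  model <- fit_box_model(sites)
  expect_identical(model$spacer_min, 3L)
  expect_identical(model$spacer_max, 7L)
  expect_identical(model$min_matches, 4L)
  for (i in seq_len(nrow(sites))) {
    p <- structure(list(gene = sites$gene[i], sequence = sites$sequence[i],
                        anchor = sites$offset[i]), class = "promoter_seq")
    expect_gte(nrow(scan_promoter(p, model)), 1L)
  }
})

test_that("fitting the two nosR sites gives a fixed 3 nt spacer", {
  nosr <- dplyr::filter(regr_box_sites(), gene == "nosR")
  model <- fit_box_model(nosr)
  expect_identical(c(model$spacer_min, model$spacer_max), c(3L, 3L))
  expect_identical(model$min_matches, 5L)
})

test_that("a single site duplicated refits to a model matching that site exactly", {
  site <- regr_box_sites()[1, ]
  model <- fit_box_model(dplyr::bind_rows(site, site))
  p <- structure(list(gene = "x", sequence = site$sequence, anchor = -73L),
                 class = "promoter_seq")
  hits <- scan_promoter(p, model)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$offset, -73L)
})

test_that("sites with no half-site frame make the fit fail loudly", {
  bad <- tibble::tibble(sequence = c("ATATATATATATAT", "TTTTAAAATTTTAA"))
  expect_error(fit_box_model(bad), class = "regulonkit_fit_error")
})

test_that("scanning equals exhaustive (start, spacer) enumeration", {
  set.seed(73)
  for (i in 1:12) {
    len <- sample(60:300, 1)
    anchor <- -sample(30:(len - 10), 1)
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                    prob = c(0.2, 0.3, 0.3, 0.2))
    p <- structure(list(gene = "r", sequence = paste(chars, collapse = ""),
                        anchor = anchor), class = "promoter_seq")
    model <- regr_box_model(spacer_min = 2, spacer_max = 6, min_matches = 5)
    got <- scan_promoter(p, model, dedup = FALSE)
    want <- oracle_scan(p$sequence, anchor, 2, 6, 5)
    expect_identical(nrow(got), nrow(want), info = paste("case", i))
    got <- dplyr::arrange(got, offset, spacer)
    expect_identical(got$offset, as.integer(want$offset))
    expect_identical(got$spacer, as.integer(want$spacer))
    expect_identical(got$score, as.integer(want$score))
  }
})

test_that("overlapping hits collapse to the best-scoring, shortest-spacer one", {
  # GCGGC CCG GTC: a 5/5 box with spacer 3; a wider 4/5 window overlaps it
  p <- structure(list(gene = "d", sequence = "TGCGTCAACGGCGATT", anchor = -50L),
                 class = "promoter_seq")
  all_hits <- scan_promoter(p, regr_box_model(min_matches = 4), dedup = FALSE)
  deduped <- scan_promoter(p, regr_box_model(min_matches = 4), dedup = TRUE)
  expect_gt(nrow(all_hits), nrow(deduped))
  expect_identical(deduped$score, max(all_hits$score))
})

test_that("reverse-complement scanning finds the mirrored site", {
  site <- "TGCGTCAACGGCGA"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(site, "")[[1]]), collapse = ""))
  p <- simulate_promoter("rc", c(-60L, 20L),
                         boxes = tibble::tibble(sequence = rc, offset = -40L),
                         background = "inert", seed = 5)
  expect_identical(nrow(scan_promoter(p)), 0L)
  hits <- scan_promoter(p, revcomp = TRUE)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "-")
})

test_that("ambiguity codes are scored as mismatches with a warning", {
  p <- structure(list(gene = "n", sequence = "TGCGTCAACGGCGN", anchor = -50L),
                 class = "promoter_seq")
  expect_warning(hits <- scan_promoter(p), "ambiguity")
  expect_identical(nrow(hits), 1L)  # the N sits outside the conserved slots
})
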