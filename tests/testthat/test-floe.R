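norc_primer <- primer_spec("NorC53", 53, 31)

test_that("cDNA lengths map to transcript starts on the no-zero axis", {
  expect_identical(tss_offset(88, norc_primer), -35L)
  expect_identical(tss_offset(74, norc_primer), -21L)
  expect_identical(tss_offset(53, norc_primer), 1L)
  expect_error(tss_offset(10, norc_primer),
               class = "regulonkit_invalid_product")
  # against backwards enumeration along the axis
  for (len in c(23, 30, 53, 54, 60, 88, 120)) {
    expect_identical(tss_offset(len, norc_primer),
                     oracle_tss_offset(len, 53L))
  }
})

test_that("longer products imply strictly more upstream starts", {
  lens <- 23:130
  offs <- tss_offset(lens, norc_primer)
  expect_true(all(diff(offs) < 0))
  expect_true(all(offs != 0L))
})

test_that("implied_cdna_length inverts tss_offset", {
  offs <- setdiff(-60:31, 0L)
  lens <- implied_cdna_length(offs, norc_primer)
  expect_identical(tss_offset(lens, norc_primer), offs)
  expect_error(implied_cdna_length(45, norc_primer),
               class = "regulonkit_invalid_product")
})

test_that("marker interpolation assigns sizes piecewise-linearly", {
  markers <- tibble::tibble(position = c(500, 1000), size = c(50, 100))
  out <- calibrate_sizes(tibble::tibble(position = 740), markers)
  expect_identical(out$size, 74L)
  expect_false(out$extrapolated)
  on_marker <- calibrate_sizes(tibble::tibble(position = 1000), markers)
  expect_identical(on_marker$size, 100L)
  # three markers, nonuniform spacing: each segment has its own slope
  m3 <- tibble::tibble(position = c(100, 200, 500), size = c(35, 50, 139))
  peaks <- tibble::tibble(position = c(150, 350))
  got <- calibrate_sizes(peaks, m3)
  want <- c(35 + 50 * (50 - 35) / 100, 50 + 150 * (139 - 50) / 300)
  expect_identical(got$size, as.integer(round(want)))
  outside <- calibrate_sizes(tibble::tibble(position = 600), m3)
  expect_true(outside$extrapolated)
  expect_identical(outside$size, as.integer(round(139 + 100 * (139 - 50) / 300)))
})

test_that("peak reductions are percentages of the reference area", {
  expect_equal(peak_percent_reduction(100, 60), 40)
  expect_equal(peak_percent_reduction(55, 55), 0)
  expect_error(peak_percent_reduction(0, 10), class = "regulonkit_domain_error")
})

test_that("replicate-averaged reductions match the direct mean-ratio computation", {
  set.seed(79)
  ref_areas <- vector("list", 6); tst_areas <- vector("list", 6)
  for (r in 1:6) {
    ref <- simulate_floe(c(-35L, -21L), c(100, 100) * runif(2, 0.9, 1.1),
                         norc_primer, seed = 100 + r)
    tst <- simulate_floe(c(-35L, -21L), c(100, 60) * runif(2, 0.9, 1.1),
                         norc_primer, seed = 200 + r)
    ref_areas[[r]] <- floe_peaks(ref)$area
    tst_areas[[r]] <- floe_peaks(tst)$area
  }
  ref_p2 <- mean(vapply(ref_areas, `[`, 1, 2))
  tst_p2 <- mean(vapply(tst_areas, `[`, 1, 2))
  expect_equal(peak_percent_reduction(ref_p2, tst_p2),
               100 * (1 - tst_p2 / ref_p2))
})

test_that("simulated traces round-trip to the planted starts", {
  offsets <- c(-35L, -21L)
  clean <- simulate_floe(offsets, c(100, 60), norc_primer, jitter_sd = 0)
  calls <- call_tss(clean, norc_primer)
  expect_identical(sort(calls$offset), sort(offsets))
  expect_identical(calls$label, c("P1", "P2"))  # most upstream first
  set.seed(83)
  for (i in 1:10) {
    noisy <- simulate_floe(offsets, c(100, 60), norc_primer,
                           jitter_sd = 0.5, seed = i)
    got <- sort(call_tss(noisy, norc_primer)$offset)
    expect_true(all(abs(got - sort(offsets)) <= 1), info = paste("seed", i))
  }
})

test_that("trace comparison pairs peaks of matching size", {
  ref <- simulate_floe(c(-35L, -21L), c(100, 100), norc_primer)
  tst <- simulate_floe(c(-35L, -21L), c(100, 60), norc_primer, seed = 2)
  cmp <- compare_traces(ref, tst)
  expect_identical(nrow(cmp), 2L)
  expect_equal(cmp$percent_reduction, c(0, 40))
})

test_that("promoter architectures collect pairwise distances order-independently", {
  tss <- tibble::tibble(label = c("P1", "P2"), offset = c(-35L, -21L))
  arch <- assemble_architecture(tss)
  expect_identical(arch$distances$distance, 14L)
  arch2 <- assemble_architecture(tss[2:1, ])
  expect_identical(arch$elements, arch2$elements)
  expect_identical(arch$distances, arch2$distances)
  single <- assemble_architecture(tss[1, ])
  expect_identical(nrow(single$distances), 0L)
  expect_error(assemble_architecture(dplyr::bind_rows(tss, tss[1, ])),
               class = "regulonkit_label_error")
})

test_that("a supplied FixK2 box sits the stated distance upstream of P1", {
  # box of length 14 whose downstream edge is 45 bp upstream of P1 at -35
  edge <- -35L - 45L
  arch <- assemble_architecture(
    tibble::tibble(label = c("P1", "P2"), offset = c(-35L, -21L)),
    boxes = tibble::tibble(name = "FixK2", offset = edge - 13L, length = 14L))
  d <- arch$distances
  expect_identical(d$distance[d$from == "FixK2" & d$to == "P1"],
                   45L + 13L)  # measured from the box 5' end
})
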