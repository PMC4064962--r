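# hand-built two-group experiment: values on the linear scale
hand_expr <- function(sig_a, sig_b, calls_a = NULL, calls_b = NULL, gene = "g1") {
  n_a <- length(sig_a); n_b <- length(sig_b)
  if (is.null(calls_a)) calls_a <- rep("present", n_a)
  if (is.null(calls_b)) calls_b <- rep("present", n_b)
  tibble::tibble(
    gene = gene,
    sample = c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b))),
    strain = "s", condition = "c",
    replicate = c(seq_len(n_a), seq_len(n_b)),
    group = rep(c("A", "B"), c(n_a, n_b)),
    signal = c(sig_a, sig_b),
    call = c(calls_a, calls_b)
  )
}

test_that("the detection filter keeps genes detected in 75% of either group", {
  boundary <- hand_expr(rep(100, 4), rep(100, 4),
                        calls_a = c("present", "present", "marginal", "absent"),
                        calls_b = rep("absent", 4))
  expect_identical(presence_filter(boundary, "A", "B"), "g1")
  sparse <- hand_expr(rep(100, 4), rep(100, 4),
                      calls_a = c("present", "absent", "absent", "absent"),
                      calls_b = c("present", "absent", "absent", "absent"))
  expect_identical(presence_filter(sparse, "A", "B"), character(0))
  expect_error(presence_filter(boundary, "A", "nope"),
               class = "regulonkit_lookup_error")
})

test_that("the detection filter equals a brute-force recount under heavy dropout", {
  cfg <- simulation_config(seed = 21, n_genes = 200, dropout = 0.5)
  expr <- simulate_expression(cfg)$expression
  ga <- "wild_type:anoxic_nitrate"; gb <- "wild_type:oxic"
  expect_identical(presence_filter(expr, ga, gb),
                   oracle_presence(expr, ga, gb))
})

test_that("signed fold changes follow the negative-reciprocal convention", {
  expect_equal(signed_fold_change(100, 100), 1)
  expect_equal(signed_fold_change(25, 100), -4)
  expect_equal(signed_fold_change(200, 100), 2)
  expect_error(signed_fold_change(0, 10), class = "regulonkit_domain_error")
  set.seed(11)
  a <- runif(50, 1, 1000); b <- runif(50, 1, 1000)
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a))
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
})

test_that("a gene with identical values in both groups is never called", {
  expr <- hand_expr(rep(100, 4), rep(100, 4))
  res <- differential_test(expr, "A", "B")
  expect_equal(res$fc, 1)
  expect_equal(res$p_value, 1)  # zero variance, equal means
  expect_false(res$de)
  shifted <- hand_expr(rep(400, 4), rep(100, 4))
  res2 <- differential_test(shifted, "A", "B")
  expect_equal(res2$p_value, 0)  # zero variance, different means
  expect_true(res2$de)
})

test_that("differential calls ignore replicate order", {
  cfg <- simulation_config(seed = 13, n_genes = 40,
                           induced = tibble::tibble(gene = sprintf("gene%04d", 1:5),
                                                    log2fc = 3))
  expr <- simulate_expression(cfg)$expression
  ga <- "wild_type:anoxic_nitrate"; gb <- "wild_type:oxic"
  res1 <- differential_test(expr, ga, gb)
  shuffled <- dplyr::arrange(expr, dplyr::desc(replicate), gene)
  res2 <- differential_test(shuffled, ga, gb)
  expect_equal(res1, res2)
})

test_that("tightening either threshold never adds differential calls", {
  cfg <- simulation_config(seed = 17, n_genes = 150,
                           induced = tibble::tibble(gene = sprintf("gene%04d", 1:30),
                                                    log2fc = 1.5),
                           noise_sd = 0.5)
  expr <- simulate_expression(cfg)$expression
  ga <- "wild_type:anoxic_nitrate"; gb <- "wild_type:oxic"
  loose <- differential_test(expr, ga, gb, p_threshold = 0.05, fc_threshold = 1.5)
  tight_p <- differential_test(expr, ga, gb, p_threshold = 0.01, fc_threshold = 1.5)
  tight_fc <- differential_test(expr, ga, gb, p_threshold = 0.05, fc_threshold = 3)
  called <- function(r) r$gene[r$de]
  expect_true(all(called(tight_p) %in% called(loose)))
  expect_true(all(called(tight_fc) %in% called(loose)))
})

test_that("few genes are called under the null at the joint thresholds", {
  cfg <- simulation_config(seed = 19, n_genes = 300)
  expr <- simulate_expression(cfg)$expression
  res <- differential_test(expr, "wild_type:anoxic_nitrate", "wild_type:oxic")
  expect_lte(mean(res$de), 0.05)
})

test_that("strong planted effects are recovered with the right direction", {
  cfg <- simulation_config(
    seed = 23, n_genes = 200,
    induced = tibble::tibble(gene = sprintf("gene%04d", 1:50), log2fc = 3),
    noise_sd = 0.25)
  expr <- simulate_expression(cfg)$expression
  res <- differential_test(expr, "wild_type:anoxic_nitrate", "wild_type:oxic")
  planted <- sprintf("gene%04d", 1:50)
  called_up <- res$gene[res$de & res$direction == "up"]
  expect_gte(length(intersect(planted, called_up)) / 50, 0.9)
})

test_that("median normalization equalizes per-sample medians", {
  cfg <- simulation_config(seed = 29, n_genes = 60)
  expr <- simulate_expression(cfg)$expression
  expr$signal[expr$sample == expr$sample[1]] <-
    expr$signal[expr$sample == expr$sample[1]] * 3
  norm <- median_normalize(expr)
  med <- tapply(norm$signal, norm$sample, median)
  expect_true(diff(range(med)) < 1e-9)
})

test_that("the efficiency-corrected expression ratio follows the Pfaffl formula", {
  expect_equal(pfaffl_ratio(2, 1, 2, 0), 2)
  expect_equal(pfaffl_ratio(2, 3, 2, 3), 1)
  expect_equal(pfaffl_ratio(1.9, 2, 2, 1), 1.805)
  expect_error(pfaffl_ratio(2.5, 1, 2, 1), class = "regulonkit_domain_error")
  expect_error(pfaffl_ratio(2, Inf, 2, 1), class = "regulonkit_domain_error")
})
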