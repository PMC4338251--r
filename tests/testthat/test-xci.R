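test_that("per-patient X-promoter deltas recover the planted shift", {
  g <- small_genome()
  co <- generate_paired_cohort(g, cohort_spec(), seed = 51)
  d <- x_promoter_deltas(co)
  expect_true(all(d >= -1 & d <= 1))
  aff <- names(d) %in% co$truth$affected_patients
  expect_lt(abs(mean(d[aff]) - (-0.3)), 0.03)
  expect_lt(abs(mean(d[!aff])), 0.03)

  # tumour == normal -> all deltas zero
  co0 <- co
  co0$meth_tumor <- co0$meth_normal
  expect_true(all(abs(x_promoter_deltas(co0)) < 1e-12))
})

test_that("two-population classification recovers the planted patients", {
  g <- small_genome()
  co <- generate_paired_cohort(g, cohort_spec(), seed = 52)
  d <- x_promoter_deltas(co)
  calls <- classify_xci_status(d)
  truth_aff <- calls$patient %in% co$truth$affected_patients
  acc <- mean((calls$status == "xci_dysregulated") == truth_aff)
  expect_gte(acc, 0.95)
  expect_equal(sum(calls$status == "xci_dysregulated"), 36)

  # order invariance
  perm <- sample(length(d))
  calls_p <- classify_xci_status(d[perm])
  expect_equal(calls_p$status[match(calls$patient, calls_p$patient)],
               calls$status)

  # shift invariance of the two-component split
  calls_s <- classify_xci_status(d + 0.2)
  expect_equal(calls_s$status, calls$status)

  # null cohort: no dysregulated calls (separation floor)
  co0 <- generate_paired_cohort(g, cohort_spec(xci_loss_fraction = 0),
                                seed = 53)
  c0 <- classify_xci_status(x_promoter_deltas(co0))
  expect_equal(sum(c0$status == "xci_dysregulated"), 0)

  expect_error(classify_xci_status(c(a = 0.1, b = 0.2)), ">= 4")
})

test_that("XIST expression drops in the dysregulated group", {
  g <- small_genome()
  co <- generate_paired_cohort(g, cohort_spec(), seed = 54)
  calls <- classify_xci_status(x_promoter_deltas(co))
  xt <- xist_group_test(co, calls)
  expect_lt(xt$p, 0.01)
  expect_lt(xt$mean_dysregulated, xt$mean_normal)

  # identical groups: p near 1
  co_same <- co
  co_same$expr_tumor[co$xist_gene_id, ] <-
    rep(c(5, 5.1), length.out = length(co$patients))
  xt0 <- xist_group_test(co_same, calls)
  expect_gt(xt0$p, 0.5)
})

test_that("escapee-like calls respect the conjunction rule and recover truth", {
  g <- small_genome()
  co <- generate_paired_cohort(g, cohort_spec(), seed = 55)
  calls <- classify_xci_status(x_promoter_deltas(co))
  esc <- call_escapee_like(co, calls)
  called <- esc$gene[esc$called]
  recall <- mean(co$truth$affected_genes %in% called)
  expect_gte(recall, 0.9)
  unaffected <- setdiff(esc$gene, co$truth$affected_genes)
  false_rate <- mean(unaffected %in% called)
  expect_lte(false_rate, 0.05)
  # conjunction: every call is hypomethylated AND over-expressed with p < 0.01
  called_rows <- esc[esc$called, ]
  expect_true(all(called_rows$delta_meth < 0))
  expect_true(all(called_rows$delta_expr > 0))
  expect_true(all(called_rows$p_meth < 0.01 & called_rows$p_expr < 0.01))

  # hypomethylated but not over-expressed is never called
  co2 <- co
  co2$expr_tumor[, ] <- co2$expr_normal  # erase all expression effects
  esc2 <- call_escapee_like(co2, calls)
  expect_lte(sum(esc2$called), 2)
})

test_that("male-pattern scatter separates XCI-intact from male-like levels", {
  set.seed(6)
  n <- 50
  ids <- paste0("x", 1:n)
  female <- setNames(rnorm(n, 0.5, 0.04), ids)   # allelic ~50%
  male <- setNames(rnorm(n, 0.05, 0.03), ids)    # unmethylated
  r <- male_pattern_similarity(female, male)
  expect_gt(r$off_diagonal_fraction, 0.8)
  r2 <- male_pattern_similarity(female, female)
  expect_equal(r2$off_diagonal_fraction, 0)
  expect_equal(r2$diagonal_fraction, 1)
  expect_true(r$off_diagonal_fraction >= 0 && r$off_diagonal_fraction <= 1)
  expect_error(male_pattern_similarity(female[1:5], male[1:5]), ">= 20")
})
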