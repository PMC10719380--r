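make_contrast <- function(ids, sig, dpsi, categories = "SE",
                          label = "test") {
  n <- length(ids)
  spliceswitch:::new_splice_contrast(
    tibble::tibble(
      event_id = ids,
      gene_id = paste0("g_", ids),
      category = rep_len(categories, n),
      n_total_a = 100L, n_total_b = 100L,
      testable = TRUE,
      psi_a = 0.5, psi_b = 0.5 + dpsi,
      bf = ifelse(sig, 100, 1),
      delta_psi = dpsi,
      replicate_delta_psi = lapply(dpsi, function(d) rep(d, 3)),
      consistent = sig,
      significant = sig,
      direction = dplyr::case_when(sig & dpsi > 0 ~ "included",
                                   sig & dpsi < 0 ~ "excluded",
                                   .default = "none")
    ),
    contrast_label = label, conditions = c(a = "A", b = "B"),
    bf_threshold = 20, min_info = 10
  )
}

test_that("contrast intersection is a significant-set event-id join", {
  tr <- make_contrast(c("e1", "e2", "e3"), c(TRUE, TRUE, FALSE),
                      c(0.3, -0.2, 0.4))
  di <- make_contrast(c("e1", "e2", "e3"), c(FALSE, TRUE, TRUE),
                      c(0.5, 0.3, -0.1))
  shared <- intersect_contrasts(tr, di)
  expect_equal(shared$event_id, "e2")
  expect_equal(shared$treat_dpsi, -0.2)
  expect_equal(shared$disease_dpsi, 0.3)
  expect_s3_class(attr(shared, "overlap_enrichment"), "tbl_df")

  # identical significant sets intersect to themselves
  both <- intersect_contrasts(tr, tr)
  expect_setequal(both$event_id, c("e1", "e2"))

  # an empty disease set gives an empty intersection
  none <- make_contrast(c("e1", "e2", "e3"), rep(FALSE, 3), c(0.1, 0.2, 0.3))
  expect_equal(nrow(intersect_contrasts(tr, none)), 0)

  # disjoint event-id spaces warn
  other <- make_contrast(c("x1", "x2"), c(TRUE, TRUE), c(0.3, 0.4))
  expect_warning(intersect_contrasts(tr, other), "no event ids")
})

test_that("switch classification is exactly sign opposition", {
  expect_true(classify_switch(tibble::tibble(
    treat_dpsi = -0.3, disease_dpsi = 0.4))$switched)
  expect_false(classify_switch(tibble::tibble(
    treat_dpsi = 0.3, disease_dpsi = 0.4))$switched)

  # all four sign combinations: only the two opposed ones switch
  combos <- tidyr::expand_grid(st = c(-1, 1), sd = c(-1, 1)) |>
    dplyr::mutate(treat_dpsi = st * 0.3, disease_dpsi = sd * 0.4)
  got <- classify_switch(combos)$switched
  expect_equal(got, combos$st == -combos$sd)

  # zero delta in either contrast is never a switch
  zero <- classify_switch(tibble::tibble(treat_dpsi = c(0, 0.3),
                                         disease_dpsi = c(0.4, 0)))
  expect_false(any(zero$switched))

  # restore mode additionally demands comparable magnitudes
  far <- tibble::tibble(treat_dpsi = -0.05, disease_dpsi = 0.6)
  expect_true(classify_switch(far)$switched)
  expect_false(classify_switch(far, mode = "restore", restore_tol = 0.2)$switched)
})

test_that("switch set has the documented symmetries and partition", {
  set.seed(3)
  shared <- tibble::tibble(
    event_id = paste0("e", 1:50),
    category = sample(c("SE", "RI"), 50, TRUE),
    treat_dpsi = round(runif(50, -0.5, 0.5), 3),
    disease_dpsi = round(runif(50, -0.5, 0.5), 3)
  )
  base <- classify_switch(shared)
  # negating both contrasts leaves the switched set unchanged
  both_neg <- classify_switch(dplyr::mutate(
    shared, treat_dpsi = -treat_dpsi, disease_dpsi = -disease_dpsi))
  expect_equal(base$switched, both_neg$switched)
  # negating one contrast complements it (no zero deltas here)
  one_neg <- classify_switch(dplyr::mutate(shared, treat_dpsi = -treat_dpsi))
  nonzero <- shared$treat_dpsi != 0 & shared$disease_dpsi != 0
  expect_equal(one_neg$switched[nonzero], !base$switched[nonzero])
  # partition: switched + not-switched = shared
  expect_equal(sum(base$switched) + sum(!base$switched), nrow(shared))
})

test_that("switch summary reproduces published-style percentages", {
  # counts as printed in the source study: 2409 treatment-affected events,
  # 406 shared with the disease set, 254 switched
  s <- switch_summary(2409, 406, 254)
  expect_equal(s$pct_shared_of_treatment, 100 * 406 / 2409, tolerance = 1e-12)
  expect_equal(s$pct_switched_of_shared, 100 * 254 / 406, tolerance = 1e-12)
  expect_equal(round(s$pct_shared_of_treatment), 17)
  expect_equal(round(s$pct_switched_of_shared), 63)

  expect_equal(switch_summary(10, 5, 0)$pct_switched_of_shared, 0)
  expect_equal(switch_summary(10, 5, 5)$pct_switched_of_shared, 100)
  expect_true(is.na(switch_summary(10, 0, 0)$pct_switched_of_shared))
  expect_error(switch_summary(5, 10, 2), "<=")
})

test_that("switched-category enrichment flags a planted category excess", {
  # one category holds all switched events but a seventh of disease events
  sw <- tibble::tibble(
    category = rep("RI", 70),
    switched = TRUE
  )
  dis <- tibble::tibble(
    category = rep(SPLICE_CATEGORIES, each = 100),
    n_significant = 1L
  ) |>
    dplyr::count(category, name = "n_significant")
  res <- switched_category_enrichment(sw, dis)
  ri <- res[res$category == "RI", ]
  expect_lt(ri$p_adj, 0.05)
  # oracle: Fisher on the 2x2 (switched-in-RI vs disease-in-RI)
  fisher_p <- fisher.test(matrix(c(70, 0, 100, 600), 2))$p.value
  expect_lt(fisher_p, 0.05)

  # identical category distributions: all adjusted p ~ 1
  sw2 <- tibble::tibble(category = rep(SPLICE_CATEGORIES, each = 30),
                        switched = TRUE)
  dis2 <- tibble::tibble(category = SPLICE_CATEGORIES, n_significant = 300L)
  res2 <- switched_category_enrichment(sw2, dis2)
  expect_true(all(res2$p_adj > 0.99))

  # no switched events at all: untested marker
  res3 <- suppressMessages(switched_category_enrichment(
    tibble::tibble(category = "SE", switched = FALSE), dis2))
  expect_true(all(is.na(res3$p_value)))
})

test_that("overlap enrichment reuses the event-level hypergeometric test", {
  run <- shared_run()
  ov <- attr(run$shared, "overlap_enrichment")
  tt <- run$treatment
  dd <- run$disease
  uni <- intersect(tt$event_id[tt$testable], dd$event_id[dd$testable])
  k <- length(intersect(tt$event_id[tt$significant],
                        dd$event_id[dd$significant]))
  expect_equal(ov$k, k)
  expect_equal(ov$N, length(uni))
  expect_equal(ov$p_value,
               phyper(ov$k - 1, ov$K, ov$N - ov$K, ov$n, lower.tail = FALSE),
               tolerance = 1e-12)
})
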