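test_that("direction ratio covers both orientations and degenerate counts", {
  expect_equal(direction_ratio(327, 64), 327 / 64)
  expect_equal(direction_ratio(327, 64, "included_over_excluded"), 64 / 327)
  expect_equal(direction_ratio(12, 12), 1)
  expect_identical(direction_ratio(5, 0), Inf)
  expect_true(is.nan(direction_ratio(0, 0)))
  expect_error(direction_ratio(-1, 3), "non-negative")

  # the two orientations are reciprocal for nonzero counts
  a <- c(3, 17, 120)
  b <- c(9, 4, 60)
  expect_equal(direction_ratio(a, b) *
                 direction_ratio(a, b, "included_over_excluded"),
               rep(1, 3))
})

test_that("category proportion test flags excess rates and not null ones", {
  comp <- tibble::tibble(
    category = c("RI", "SE"),
    n_significant = c(50L, 50L),
    n_tested = c(100L, 1000L)
  )
  res <- category_proportion_test(comp)
  # cross-check the flagged category against Fisher's exact 2x2 computation
  fisher_p <- fisher.test(matrix(c(50, 50, 50, 950), 2))$p.value
  expect_lt(res$p_proportion_adj[1], 0.05 / 7)
  expect_lt(fisher_p, 0.05 / 7)

  # equal rates at large n: adjusted p ~ 1
  null_comp <- tibble::tibble(
    category = c("A3SS", "MXE"),
    n_significant = c(200L, 400L),
    n_tested = c(1000L, 2000L)
  )
  null_res <- category_proportion_test(null_comp)
  expect_true(all(null_res$p_proportion_adj > 0.9))

  # a single category has no complement: untested marker
  solo <- category_proportion_test(tibble::tibble(
    category = "SE", n_significant = 10L, n_tested = 50L
  ))
  expect_true(is.na(solo$p_proportion))
})

test_that("imbalance test matches binomial tails and is branch-consistent", {
  res <- inclusion_imbalance_test(tibble::tibble(
    category = c("RI", "SE"),
    n_included = c(64L, 30L),
    n_excluded = c(0L, 30L)
  ))
  # (64, 0): chi-square tail far below 1e-10 even after Bonferroni
  expect_lt(res$p_imbalance_adj[1], 1e-10)
  # 50:50 split: raw p = 1
  expect_equal(res$p_imbalance[2], 1)

  # exact binomial branch below the cutover
  small <- inclusion_imbalance_test(tibble::tibble(
    category = "MXE", n_included = 2L, n_excluded = 10L
  ))
  expect_equal(small$p_imbalance, binom.test(2, 12, 0.5)$p.value)

  # continuity-corrected chi-square tracks the exact binomial at n = 100
  for (a in c(60L, 65L)) {
    chi <- inclusion_imbalance_test(tibble::tibble(
      category = "SE", n_included = a, n_excluded = 100L - a
    ))$p_imbalance
    exact <- binom.test(a, 100, 0.5)$p.value
    expect_lt(abs(chi - exact) / exact, 0.10)
  }

  empty <- inclusion_imbalance_test(tibble::tibble(
    category = "AFE", n_included = 0L, n_excluded = 0L
  ))
  expect_true(is.na(empty$p_imbalance))
})

test_that("composition summary conserves counts across categories", {
  run <- shared_run()
  comp <- composition_summary(run$treatment)
  expect_equal(sum(comp$n_significant), sum(run$treatment$significant))
  expect_true(all(comp$n_included + comp$n_excluded == comp$n_significant))
  expect_true(all(comp$n_significant <= comp$n_tested))
})

test_that("a planted excluded-RI excess is flagged by both category tests", {
  # dense simulation: elevated differential rates give both tests power;
  # the default category skew doubles the RI rate and the direction bias
  # makes RI exclusion-heavy, while SE stays unremarkable
  catalog <- simulate_event_catalog(150, seed = 31)
  truth <- simulate_truth(
    catalog,
    frac_differential = c(treatment = 0.3, disease = 0.05),
    frac_disease_given_treatment = NULL,
    seed = 31
  )
  counts <- simulate_counts(truth, catalog, n_replicates = 3, seed = 31)
  calls <- call_contrast(counts, catalog, c("DMSO", "apigenin"))
  comp <- composition_summary(calls)

  ri <- comp[comp$category == "RI", ]
  se <- comp[comp$category == "SE", ]
  expect_gt(ri$ratio, 1)
  expect_lte(ri$p_proportion_adj, 0.05)
  expect_lte(ri$p_imbalance_adj, 0.05)
  expect_gt(se$p_proportion_adj, 0.05)
  expect_gt(se$p_imbalance_adj, 0.05)
})

test_that("concordance regression matches the normal-equations oracle", {
  d <- tibble::tibble(
    rtpcr = c(0.10, 0.35, 0.50, 0.72, 0.90),
    rnaseq = c(0.18, 0.30, 0.55, 0.70, 0.84)
  )
  fit <- psi_concordance(d, rtpcr, rnaseq)

  X <- cbind(1, d$rtpcr)
  beta <- solve(t(X) %*% X, t(X) %*% d$rnaseq)
  sxy <- sum((d$rtpcr - mean(d$rtpcr)) * (d$rnaseq - mean(d$rnaseq)))
  r2 <- sxy^2 / (sum((d$rtpcr - mean(d$rtpcr))^2) *
                   sum((d$rnaseq - mean(d$rnaseq))^2))
  expect_equal(fit$intercept, beta[1], tolerance = 1e-9)
  expect_equal(fit$slope, beta[2], tolerance = 1e-9)
  expect_equal(fit$r_squared, r2, tolerance = 1e-9)

  # y = x exactly
  perfect <- psi_concordance(tibble::tibble(a = c(.1, .5, .9),
                                            b = c(.1, .5, .9)), a, b)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)

  # degenerate and invalid inputs
  flat <- psi_concordance(tibble::tibble(a = c(.1, .5, .9),
                                         b = c(.4, .4, .4)), a, b)
  expect_true(flat$undefined)
  expect_true(is.na(flat$r_squared))
  expect_error(psi_concordance(tibble::tibble(a = c(.1, .2), b = c(.1, .2)),
                               a, b), "3 pairs")
  expect_error(psi_concordance(tibble::tibble(a = c(.1, .5, 1.2),
                                              b = c(.1, .5, .9)), a, b),
               "\\[0, 1\\]")

  g <- glance(fit)
  expect_equal(g$r_squared, fit$r_squared)
  expect_equal(tidy(fit)$estimate, c(fit$intercept, fit$slope))
})
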