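test_that("catalog has the right size, category set and determinism", {
  cat10 <- simulate_event_catalog(10, seed = 3)
  expect_equal(nrow(cat10), 70)
  expect_equal(unname(table(cat10$category)[SPLICE_CATEGORIES]),
               rep(10L, 7), ignore_attr = TRUE)

  cat1 <- simulate_event_catalog(1, seed = 3)
  expect_setequal(cat1$category, c("SE", "RI", "A5SS", "A3SS", "MXE",
                                   "AFE", "ALE"))

  expect_identical(simulate_event_catalog(25, seed = 9),
                   simulate_event_catalog(25, seed = 9))
  expect_false(identical(simulate_event_catalog(25, seed = 9),
                         simulate_event_catalog(25, seed = 10)))

  # some genes carry multiple events
  expect_gt(max(table(cat10$gene_id)), 1)
  expect_error(simulate_event_catalog(0), "positive integer")
})

test_that("simulated truth honours requested fractions and the switch invariant", {
  catalog <- simulate_event_catalog(715, seed = 5)  # 5005 events
  uniform <- list(
    treatment = setNames(rep(1, 7), SPLICE_CATEGORIES),
    disease = setNames(rep(1, 7), SPLICE_CATEGORIES)
  )
  truth <- simulate_truth(
    catalog,
    frac_differential = c(treatment = 0.2, disease = 0.2),
    frac_disease_given_treatment = NULL,
    rate_multiplier = uniform,
    seed = 5
  )
  n <- nrow(truth)
  tol <- 3 * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(mean(truth$is_differential_treatment) - 0.2), tol)
  expect_lt(abs(mean(truth$is_differential_disease) - 0.2), tol)

  # switch invariant over the full table: switched events are jointly
  # differential with opposed effect signs
  sw <- truth[truth$is_switch, ]
  expect_true(all(sw$is_differential_treatment & sw$is_differential_disease))
  expect_true(all(sign(sw$effect_treatment) == -sign(sw$effect_disease)))
  expect_true(all(sw$effect_treatment != 0 & sw$effect_disease != 0))

  psis <- as.matrix(truth[, c("psi_DMSO", "psi_apigenin", "psi_NBT",
                              "psi_TNBC")])
  expect_true(all(psis >= 0 & psis <= 1))
  expect_true(all(abs(truth$effect_treatment) <= 1))

  # planted |effects| respect the configured minimum
  eff <- truth$effect_treatment[truth$is_differential_treatment]
  expect_true(all(abs(eff) >= 0.25))
})

test_that("degenerate truth settings behave as documented", {
  catalog <- simulate_event_catalog(20, seed = 2)
  none <- simulate_truth(catalog,
                         frac_differential = c(treatment = 0, disease = 0),
                         seed = 2)
  expect_false(any(none$is_differential_treatment))
  expect_false(any(none$is_differential_disease))
  expect_false(any(none$is_switch))
  expect_equal(none$psi_DMSO, none$psi_apigenin)
  expect_equal(none$psi_NBT, none$psi_TNBC)

  uniform <- list(
    treatment = setNames(rep(1, 7), SPLICE_CATEGORIES),
    disease = setNames(rep(1, 7), SPLICE_CATEGORIES)
  )
  all_sw <- simulate_truth(catalog,
                           frac_differential = c(treatment = 1, disease = 1),
                           frac_switch = 1,
                           frac_disease_given_treatment = NULL,
                           rate_multiplier = uniform,
                           seed = 2)
  expect_true(all(all_sw$is_switch))

  expect_error(
    simulate_truth(catalog, effect_dist = list(min = 0.2, max = 1.2)),
    "delta-PSI"
  )
  expect_error(simulate_truth(catalog, frac_switch = 1.4), "fractions")
})

test_that("counts follow the length-corrected read-class probability", {
  catalog <- tiny_event(L_inc = 1L, L_exc = 1L)
  truth <- simulate_truth(catalog,
                          frac_differential = c(treatment = 0, disease = 0),
                          seed = 1)
  truth$psi_DMSO <- 0.5

  cov5 <- list(model = "poisson", mean = 1e5, dispersion = 0)
  counts <- simulate_counts(truth, catalog, coverage = cov5,
                            n_replicates = 1, seed = 1)
  one <- counts[counts$condition == "DMSO", ]
  expect_lt(abs(one$n_inc / (one$n_inc + one$n_exc) - 0.5), 0.01)

  # with unequal lengths the inclusion fraction converges to f(psi), not psi
  cat2 <- tiny_event(L_inc = 3L, L_exc = 1L)
  truth2 <- simulate_truth(cat2,
                           frac_differential = c(treatment = 0, disease = 0),
                           seed = 1)
  psi_t <- truth2$psi_DMSO
  f <- psi_t * 3 / (psi_t * 3 + (1 - psi_t))
  counts2 <- simulate_counts(truth2, cat2, coverage = cov5,
                             n_replicates = 1, seed = 1)
  one2 <- counts2[counts2$condition == "DMSO", ]
  expect_lt(abs(one2$n_inc / (one2$n_inc + one2$n_exc) - f), 0.01)
})

test_that("count edge cases: zero coverage and saturated PSI", {
  catalog <- tiny_event()
  truth <- simulate_truth(catalog,
                          frac_differential = c(treatment = 0, disease = 0),
                          seed = 1)
  zero <- simulate_counts(truth, catalog,
                          coverage = list(model = "nb", mean = 0,
                                          dispersion = 0.3),
                          n_replicates = 2, seed = 1)
  expect_true(all(zero$n_inc == 0 & zero$n_exc == 0))

  truth$psi_DMSO <- 1
  sat <- simulate_counts(truth, catalog,
                         coverage = list(model = "poisson", mean = 200),
                         n_replicates = 3, seed = 1)
  expect_true(all(sat$n_exc[sat$condition == "DMSO"] == 0))

  expect_identical(
    simulate_counts(truth, catalog, n_replicates = 2, seed = 8),
    simulate_counts(truth, catalog, n_replicates = 2, seed = 8)
  )
})

test_that("substrate labelling is gene-consistent and enriched as planted", {
  catalog <- simulate_event_catalog(300, seed = 6)
  truth <- simulate_truth(catalog,
                          frac_differential = c(treatment = 0.3,
                                                disease = 0.05),
                          frac_disease_given_treatment = NULL,
                          seed = 6)
  # substrate labels are a property of the gene, not the event
  per_gene <- tapply(truth$substrate_hnRNPA2, truth$gene_id,
                     function(v) length(unique(v)))
  expect_true(all(per_gene == 1))

  gene_tbl <- dplyr::distinct(truth, gene_id, .keep_all = FALSE)
  gene_diff <- tapply(truth$is_differential_treatment, truth$gene_id, any)
  gene_sub <- tapply(truth$substrate_hnRNPA2, truth$gene_id, any)
  rate_diff <- mean(gene_sub[gene_diff])
  rate_other <- mean(gene_sub[!gene_diff])
  expect_gt(rate_diff, rate_other)
})
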