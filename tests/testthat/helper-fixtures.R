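# Shared fixtures, built in code. The moderately sized pipeline run used by
# several recovery tests is computed once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

# one catalog row with chosen effective lengths
tiny_event <- function(event_id = "e1", gene_id = "g1", category = "SE",
                       L_inc = 1L, L_exc = 1L) {
  tibble::tibble(
    event_id = event_id, gene_id = gene_id, category = category,
    chrom = "chr1", strand = "+", segments = "100-200;300-400;500-600",
    L_inc = as.integer(L_inc), L_exc = as.integer(L_exc)
  )
}

# replicate-level counts for one event and two conditions; inc/exc are
# per-replicate matrices with replicates in rows and c(n_inc, n_exc) in cols
tiny_counts <- function(event_id, cond_a, cond_b, counts_a, counts_b) {
  make <- function(cond, m) {
    tibble::tibble(
      event_id = event_id,
      sample_id = sprintf("%s_R%d", cond, seq_len(nrow(m))),
      condition = cond,
      replicate = seq_len(nrow(m)),
      n_inc = as.integer(m[, 1]),
      n_exc = as.integer(m[, 2])
    )
  }
  dplyr::bind_rows(make(cond_a, counts_a), make(cond_b, counts_b))
}

# cached default-condition pipeline run, sized so gene-level enrichment
# properties have their intended universe (> 2000 genes)
shared_run <- function() {
  if (is.null(.fixture_env$run)) {
    cfg <- splice_config(seed = 42L, n_per_category = 560L)
    .fixture_env$run <- run_splice_pipeline(cfg, quiet = TRUE)
  }
  .fixture_env$run
}

# closed-form Bayes factor in the equal-effective-length case, where the
# marginal likelihoods reduce to Beta integrals
bf_closed_form <- function(ai, ae, bi, be) {
  exp(lbeta(ai + 1, ae + 1) + lbeta(bi + 1, be + 1) -
        lbeta(ai + bi + 1, ae + be + 1))
}

# brute-force two-sample KS statistic: maximal ECDF gap over all observed
# points (O(n^2) scan)
ks_d_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}
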