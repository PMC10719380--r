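#' Splice event categories
#'
#' The seven exon-centric mRNA processing event classes handled throughout
#' the package: skipped exon (SE), retained intron (RI), alternative 5'/3'
#' splice site (A5SS/A3SS), mutually exclusive exons (MXE), and alternative
#' first/last exons (AFE/ALE).
#' @export
SPLICE_CATEGORIES <- c("SE", "RI", "A5SS", "A3SS", "MXE", "AFE", "ALE")

# Condition labels of the two simulated contrasts. Treatment contrast:
# apigenin-treated tumor cells vs DMSO control; disease contrast: TNBC
# tumor tissue vs normal breast tissue. Delta-PSI is always condition B
# minus condition A (apigenin - DMSO; TNBC - NBT, i.e. tumor minus normal).
.SIM_CONTRASTS <- list(
  treatment = c(a = "DMSO", b = "apigenin"),
  disease = c(a = "NBT", b = "TNBC")
)

# Evaluate code under a temporary RNG state so simulators are deterministic
# given `seed` without disturbing the caller's RNG.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' Each simulation stage (catalog, truth, counts, ...) draws from its own
#' stream derived deterministically from one master seed, so that a stage
#' can be re-run reproducibly in isolation.
#'
#' @param seed Master seed (integer).
#' @param stage Stage name, e.g. `"catalog"`, `"truth"`, `"counts"`.
#' @return An integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  stage_num <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 69069 + stage_num * 1000003) %% 2147483562)
}

# segments-per-category used when sketching event coordinates
.N_SEGMENTS <- c(SE = 3L, RI = 2L, A5SS = 2L, A3SS = 2L, MXE = 4L,
                 AFE = 2L, ALE = 2L)

.format_segments <- function(starts, ends) {
  paste(sprintf("%d-%d", starts, ends), collapse = ";")
}

#' Simulate an annotated splice-event catalog
#'
#' Generates `n_per_category` events for each of the seven event classes,
#' with plausible genomic sketch coordinates, per-form effective lengths
#' drawn uniformly from the configured ranges, and gene assignments in which
#' some genes carry several events (as in real annotations, where one gene
#' can host multiple alternative events).
#'
#' @param n_per_category Events per category (>= 1).
#' @param length_config List with integer ranges `L_inc` and `L_exc`
#'   (c(min, max)) for the effective lengths of the inclusion and exclusion
#'   forms.
#' @param seed Integer seed; identical seeds give byte-identical catalogs.
#' @return A tibble with columns `event_id`, `gene_id`, `category`, `chrom`,
#'   `strand`, `segments` (semicolon-separated `start-end` pairs, 1-based
#'   inclusive), `L_inc`, `L_exc`.
#' @examples
#' cat7 <- simulate_event_catalog(1, seed = 1)
#' table(cat7$category)
#' @export
simulate_event_catalog <- function(n_per_category,
                                   length_config = list(L_inc = c(100L, 300L),
                                                        L_exc = c(50L, 150L)),
                                   seed = 1L) {
  if (length(n_per_category) != 1 || is.na(n_per_category) ||
      n_per_category < 1 || n_per_category != floor(n_per_category)) {
    stop("`n_per_category` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n_per_category) * length(SPLICE_CATEGORIES)
  .with_seed(derive_seed(seed, "catalog"), {
    category <- rep(SPLICE_CATEGORIES, each = n_per_category)
    # fewer genes than events so some genes carry multiple events
    n_genes <- max(1L, ceiling(0.75 * n))
    gene_id <- sprintf("G%05d", sample.int(n_genes, n, replace = TRUE))
    chrom <- sample(paste0("chr", c(1:22, "X")), n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    segments <- vapply(seq_len(n), function(i) {
      k <- .N_SEGMENTS[[category[i]]]
      start0 <- sample.int(1e8, 1)
      widths <- sample(80:300, k, replace = TRUE)
      gaps <- sample(100:5000, k, replace = TRUE)
      starts <- start0 + cumsum(c(0, (widths + gaps)[-k]))
      .format_segments(starts, starts + widths - 1L)
    }, character(1))
    L_inc <- sample(length_config$L_inc[1]:length_config$L_inc[2], n,
                    replace = TRUE)
    L_exc <- sample(length_config$L_exc[1]:length_config$L_exc[2], n,
                    replace = TRUE)
    tibble::tibble(
      event_id = sprintf("EV%06d", seq_len(n)),
      gene_id = gene_id,
      category = category,
      chrom = chrom,
      strand = strand,
      segments = segments,
      L_inc = as.integer(L_inc),
      L_exc = as.integer(L_exc)
    )
  })
}

.default_prob_positive <- list(
  # apigenin predominantly drives exclusion in retained introns
  # (exclusion-heavy direction bias), mild exclusion bias elsewhere
  treatment = c(SE = 0.45, RI = 0.16, A5SS = 0.45, A3SS = 0.45,
                MXE = 0.45, AFE = 0.45, ALE = 0.45),
  # tumors show the opposite: inclusion-heavy, strongest for RI
  disease = c(SE = 0.55, RI = 0.85, A5SS = 0.55, A3SS = 0.55,
              MXE = 0.55, AFE = 0.55, ALE = 0.55)
)

# category-level skew of the differential rate: retained introns and
# alternative last exons are over-represented among treatment-affected
# events, alternative 3' splice sites under-represented; the disease
# contrast is left uniform
.default_rate_multiplier <- list(
  treatment = c(SE = 1, RI = 2, A5SS = 1, A3SS = 0.5, MXE = 1, AFE = 1,
                ALE = 1.5),
  disease = c(SE = 1, RI = 1, A5SS = 1, A3SS = 1, MXE = 1, AFE = 1, ALE = 1)
)

.default_substrate_config <- list(
  rates = c(hnRNPA2 = 0.15, MSI2 = 0.10, CELF1 = 0.10),
  odds = c(hnRNPA2 = 4, MSI2 = 3, CELF1 = 3),
  hnRNPA2_shift = 0.1
)

#' Simulate per-event ground truth for the two contrasts
#'
#' Assigns every catalog event a true PSI in each of the four conditions
#' (DMSO/apigenin for the treatment contrast, NBT/TNBC for the disease
#' contrast), plants differential events with a signed delta-PSI effect,
#' plants switch events (jointly differential events whose treatment effect
#' sign opposes the disease effect sign, i.e. the treatment moves splicing
#' toward the non-tumor profile), and labels genes as substrates of the
#' RNA-binding proteins hnRNPA2, MSI2 and CELF1 with enrichment among
#' treatment-differential genes.
#'
#' The baseline PSI of each event is drawn from a Beta(2, 2)-shaped
#' distribution rescaled away from 0 and 1 by half the maximum effect size,
#' and effects are applied symmetrically (condition A gets baseline - effect/2,
#' condition B baseline + effect/2), so every planted effect is representable
#' within \[0, 1\].
#'
#' @param catalog Event catalog from [simulate_event_catalog()].
#' @param frac_differential Named fractions of differential events,
#'   `c(treatment = , disease = )`.
#' @param effect_dist List `list(min = , max = )`: |delta-PSI| of planted
#'   effects is uniform on this interval. `max` plus any substrate shift
#'   must stay <= 1.
#' @param frac_switch Among jointly differential events, the fraction whose
#'   disease-effect sign is forced opposite to the treatment sign.
#' @param frac_disease_given_treatment Probability that a
#'   treatment-differential event is also disease-differential; tumors and
#'   treatment perturb overlapping splicing programs, so this exceeds the
#'   marginal disease fraction. Set `NULL` for independent contrasts. The
#'   rate for the remaining events is adjusted so the marginal disease
#'   fraction is preserved when possible.
#' @param substrate_config List with per-RBP marginal membership `rates`,
#'   `odds` multipliers applied to membership odds of treatment-differential
#'   genes, and `hnRNPA2_shift`, an extra |delta-PSI| added to treatment
#'   effects in hnRNPA2-substrate genes (the RBP whose substrates shift in
#'   magnitude, not just in count).
#' @param prob_positive Per-category probability that a planted effect is
#'   positive (inclusion-promoting), one named vector per contrast.
#' @param rate_multiplier Per-category multipliers on the differential
#'   fraction, one named vector per contrast (resulting rates are capped at
#'   1). The default skews the treatment contrast toward retained introns
#'   and alternative last exons and away from alternative 3' splice sites.
#' @param seed Integer seed.
#' @return A tibble with one row per event: true PSI per condition
#'   (`psi_DMSO`, `psi_apigenin`, `psi_NBT`, `psi_TNBC`), differential and
#'   switch flags, signed effects, and logical substrate columns
#'   `substrate_hnRNPA2`, `substrate_MSI2`, `substrate_CELF1`.
#' @export
simulate_truth <- function(catalog,
                           frac_differential = c(treatment = 0.03,
                                                 disease = 0.0443),
                           effect_dist = list(min = 0.25, max = 0.45),
                           frac_switch = 0.63,
                           frac_disease_given_treatment = 0.17,
                           substrate_config = .default_substrate_config,
                           prob_positive = .default_prob_positive,
                           rate_multiplier = .default_rate_multiplier,
                           seed = 1L) {
  stopifnot(is.data.frame(catalog), nrow(catalog) >= 1)
  if (any(frac_differential < 0 | frac_differential > 1) ||
      frac_switch < 0 || frac_switch > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  shift <- substrate_config$hnRNPA2_shift %||% 0
  if (effect_dist$min < 0 || effect_dist$max > 1 ||
      effect_dist$min > effect_dist$max || effect_dist$max + shift > 1) {
    stop("`effect_dist` (plus substrate shift) must keep |delta-PSI| in [0, 1]",
         call. = FALSE)
  }
  ft <- unname(frac_differential[["treatment"]])
  fd <- unname(frac_differential[["disease"]])

  .with_seed(derive_seed(seed, "truth"), {
    n <- nrow(catalog)
    delta_max <- effect_dist$max + shift
    # baseline bounded away from 0/1 by half the max effect
    psi0 <- delta_max / 2 + (1 - delta_max) * stats::rbeta(n, 2, 2)

    mult_t <- rate_multiplier$treatment[catalog$category]
    mult_d <- rate_multiplier$disease[catalog$category]
    diff_t <- stats::runif(n) < pmin(1, ft * mult_t)
    if (is.null(frac_disease_given_treatment)) {
      diff_d <- stats::runif(n) < pmin(1, fd * mult_d)
    } else {
      p_dt <- frac_disease_given_treatment
      # keep the marginal disease fraction near fd when feasible
      p_rest <- if (ft < 1) max(0, (fd - ft * p_dt) / (1 - ft)) else 0
      diff_d <- stats::runif(n) <
        ifelse(diff_t, p_dt, pmin(1, p_rest * mult_d))
    }

    pp_t <- prob_positive$treatment[catalog$category]
    pp_d <- prob_positive$disease[catalog$category]
    sign_t <- ifelse(stats::runif(n) < pp_t, 1, -1)
    sign_d <- ifelse(stats::runif(n) < pp_d, 1, -1)
    joint <- diff_t & diff_d
    is_switch <- joint & stats::runif(n) < frac_switch
    sign_d[is_switch] <- -sign_t[is_switch]
    sign_d[joint & !is_switch] <- sign_t[joint & !is_switch]

    mag_t <- stats::runif(n, effect_dist$min, effect_dist$max)
    mag_d <- stats::runif(n, effect_dist$min, effect_dist$max)

    # substrate labels at gene level, enriched among
    # treatment-differential genes via an odds multiplier
    genes <- unique(catalog$gene_id)
    gene_diff_t <- tapply(diff_t, catalog$gene_id, any)[genes]
    substrate <- matrix(
      FALSE, n, length(substrate_config$rates),
      dimnames = list(NULL,
                      paste0("substrate_", names(substrate_config$rates)))
    )
    for (rbp in names(substrate_config$rates)) {
      p0 <- substrate_config$rates[[rbp]]
      odds <- substrate_config$odds[[rbp]]
      p1 <- odds * p0 / (1 - p0 + odds * p0)
      member <- stats::runif(length(genes)) < ifelse(gene_diff_t, p1, p0)
      substrate[, paste0("substrate_", rbp)] <-
        stats::setNames(member, genes)[catalog$gene_id]
    }

    if (shift > 0 && "substrate_hnRNPA2" %in% colnames(substrate)) {
      boost <- diff_t & substrate[, "substrate_hnRNPA2"]
      mag_t[boost] <- mag_t[boost] + shift
    }

    eff_t <- ifelse(diff_t, sign_t * mag_t, 0)
    eff_d <- ifelse(diff_d, sign_d * mag_d, 0)
    is_switch <- diff_t & diff_d & sign(eff_t) == -sign(eff_d) &
      eff_t != 0 & eff_d != 0

    clamp01 <- function(x) pmin(1, pmax(0, x))
    out <- tibble::tibble(
      event_id = catalog$event_id,
      gene_id = catalog$gene_id,
      category = catalog$category,
      psi_DMSO = clamp01(psi0 - eff_t / 2),
      psi_apigenin = clamp01(psi0 + eff_t / 2),
      psi_NBT = clamp01(psi0 - eff_d / 2),
      psi_TNBC = clamp01(psi0 + eff_d / 2),
      is_differential_treatment = diff_t,
      is_differential_disease = diff_d,
      effect_treatment = eff_t,
      effect_disease = eff_d,
      is_switch = is_switch
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(substrate))
    out
  })
}

#' Simulate replicate-level junction read counts
#'
#' For each event, condition and replicate, a total read depth is drawn from
#' the coverage model (negative binomial with the given mean and dispersion,
#' or Poisson) and split into inclusion- and exclusion-supporting reads by a
#' binomial draw with the length-corrected inclusion probability
#' \eqn{f(\psi) = \psi L_{inc} / (\psi L_{inc} + (1-\psi) L_{exc})}
#' evaluated at the event's true PSI for that condition.
#'
#' @param truth Ground-truth table from [simulate_truth()].
#' @param catalog Matching event catalog (provides effective lengths).
#' @param coverage List `list(model = "nb"|"poisson", mean = , dispersion = )`;
#'   for the negative binomial, variance = mean + dispersion * mean^2.
#' @param n_replicates Replicates per condition (>= 1).
#' @param seed Integer seed.
#' @return A tibble of per-sample counts: `event_id`, `sample_id`,
#'   `condition`, `replicate`, `n_inc`, `n_exc`.
#' @export
simulate_counts <- function(truth, catalog,
                            coverage = list(model = "nb", mean = 100,
                                            dispersion = 0.3),
                            n_replicates = 3L,
                            seed = 1L) {
  stopifnot(is.data.frame(truth), is.data.frame(catalog))
  if (coverage$mean < 0) stop("coverage mean must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  conditions <- c("DMSO", "apigenin", "NBT", "TNBC")
  psi_cols <- paste0("psi_", conditions)
  stopifnot(all(psi_cols %in% names(truth)))
  idx <- match(truth$event_id, catalog$event_id)
  if (anyNA(idx)) stop("truth contains events absent from the catalog",
                       call. = FALSE)
  L_inc <- catalog$L_inc[idx]
  L_exc <- catalog$L_exc[idx]
  n <- nrow(truth)

  .with_seed(derive_seed(seed, "counts"), {
    draws <- lapply(conditions, function(cond) {
      f <- .read_class_prob(truth[[paste0("psi_", cond)]], L_inc, L_exc)
      lapply(seq_len(n_replicates), function(rep_i) {
        total <- if (coverage$mean == 0) {
          integer(n)
        } else if (identical(coverage$model, "poisson")) {
          stats::rpois(n, coverage$mean)
        } else {
          stats::rnbinom(n, mu = coverage$mean,
                         size = 1 / coverage$dispersion)
        }
        n_inc <- stats::rbinom(n, total, f)
        tibble::tibble(
          event_id = truth$event_id,
          sample_id = sprintf("%s_R%d", cond, rep_i),
          condition = cond,
          replicate = rep_i,
          n_inc = as.integer(n_inc),
          n_exc = as.integer(total - n_inc)
        )
      })
    })
    dplyr::bind_rows(unlist(draws, recursive = FALSE))
  })
}

#' Extract RBP substrate gene sets from a simulated truth table
#'
#' Collects the genes labelled as substrates of each RNA-binding protein in
#' the ground truth into the named-list-of-gene-vectors form consumed by the
#' enrichment functions (the same shape [read_gene_sets()] returns).
#'
#' @param truth Tibble from [simulate_truth()].
#' @return Named list of character vectors of gene ids.
#' @export
truth_gene_sets <- function(truth) {
  cols <- grep("^substrate_", names(truth), value = TRUE)
  sets <- lapply(cols, function(cl) unique(truth$gene_id[truth[[cl]]]))
  names(sets) <- sub("^substrate_", "", cols)
  sets
}
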