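#' Generate a synthetic individual-level biomarker cohort
#'
#' Simulates per-individual urinary concentrations with the statistical
#' structure the tiered assessment assumes: each biomarker follows a
#' requested marginal distribution, and an optional Gaussian copula couples
#' the common metabolite 3-PBA with the other (component) biomarkers
#' through a shared latent rank, emulating the fact that individuals with
#' high overall pyrethroid exposure tend to be high on several markers at
#' once. The aggregated pipeline only consumes percentile tables, so the
#' generator does not enforce within-individual mass balance between 3-PBA
#' and the selective metabolites.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param biomarker_dists Named list of `dist_spec` objects, one per
#'   biomarker column.
#' @param correlation Latent Gaussian correlation in `[0, 1)` between 3-PBA
#'   and each component biomarker (ignored when 3-PBA is absent; 0 means
#'   independent columns).
#' @param seed Integer seed for reproducibility.
#' @param population_id Stored as metadata on the result.
#' @return A tibble with one row per individual and one concentration
#'   column (ug/L) per biomarker, plus `individual`.
#' @examples
#' generate_cohort(5, list("3-PBA" = dist_loglogistic(2, 1.7)), seed = 1)
#' @export
generate_cohort <- function(n_individuals, biomarker_dists, correlation = 0,
                            seed = NULL, population_id = "children") {
  if (n_individuals < 1) abort("`n_individuals` must be at least 1.",
                               class = "hbmtier_domain_error")
  if (!length(biomarker_dists) || is.null(names(biomarker_dists)) ||
      any(!nzchar(names(biomarker_dists)))) {
    abort("`biomarker_dists` must be a named list of dist_spec objects.",
          class = "hbmtier_domain_error")
  }
  ok <- vapply(biomarker_dists, inherits, logical(1), "dist_spec")
  if (any(!ok)) {
    abort(sprintf("Not a dist_spec: %s",
                  paste(names(biomarker_dists)[!ok], collapse = ", ")),
          class = "hbmtier_domain_error")
  }
  if (correlation < 0 || correlation >= 1) {
    abort("`correlation` must lie in [0, 1).", class = "hbmtier_domain_error")
  }
  ids <- names(biomarker_dists)
  cols <- with_seed(seed, {
    if (correlation > 0 && "3-PBA" %in% ids) {
      z0 <- rnorm(n_individuals)
      lapply(setNames(ids, ids), function(id) {
        z <- if (id == "3-PBA") z0 else {
          correlation * z0 + sqrt(1 - correlation^2) * rnorm(n_individuals)
        }
        dist_quantile(biomarker_dists[[id]], pnorm(z))
      })
    } else {
      lapply(biomarker_dists, dist_sample, n = n_individuals)
    }
  })
  out <- as_tibble(c(list(individual = seq_len(n_individuals)), cols))
  attr(out, "population") <- population_id
  out
}

#' Aggregate a cohort to a percentile table
#'
#' Collapses individual-level concentrations to the aggregated summary
#' format the assessment consumes: empirical percentiles (linear
#' interpolation of order statistics, the type-7 convention) with optional
#' percentile-bootstrap 95% confidence intervals on the 95th percentile.
#' Aggregation refuses cohorts below 20 individuals: high percentiles of
#' smaller samples are dominated by single observations and would feed
#' meaningless ratios downstream.
#'
#' @param cohort Tibble from [generate_cohort()] (or any tibble with an
#'   `individual` column and one numeric column per biomarker).
#' @param probs Percentile probabilities in (0, 1); must include 0.95 for
#'   downstream ratio computation (default `c(0.05, 0.5, 0.95)`).
#' @param bootstrap_reps Bootstrap replicates for the confidence interval;
#'   0 disables the interval.
#' @param seed Integer seed for the bootstrap.
#' @param study_id,country Metadata stamped on the output rows.
#' @return A tibble in the [read_exposure_table()] schema, one row per
#'   biomarker.
#' @export
aggregate_percentiles <- function(cohort, probs = c(0.05, 0.5, 0.95),
                                  bootstrap_reps = 0, seed = NULL,
                                  study_id = "synthetic",
                                  country = "synthetic") {
  n <- nrow(cohort)
  if (n < 20) {
    abort(sprintf("Refusing to aggregate %d individual(s): percentile summaries need at least 20.", n),
          class = "hbmtier_refusal_error")
  }
  if (any(probs <= 0 | probs >= 1)) {
    abort("Percentile probabilities must lie in (0, 1).",
          class = "hbmtier_domain_error")
  }
  population <- attr(cohort, "population") %||% "children"
  biomarkers <- setdiff(names(cohort), "individual")
  rows <- purrr::map(biomarkers, function(b) {
    x <- cohort[[b]]
    q <- quantile(x, probs, type = 7, names = FALSE)
    ci <- c(NA_real_, NA_real_)
    if (bootstrap_reps > 0) {
      boot <- with_seed(seed, {
        vapply(seq_len(bootstrap_reps), function(i) {
          quantile(sample(x, n, replace = TRUE), 0.95, type = 7, names = FALSE)
        }, numeric(1))
      })
      ci <- quantile(boot, c(0.025, 0.975), type = 7, names = FALSE)
    }
    grab <- function(p) if (p %in% probs) q[match(p, probs)] else NA_real_
    tibble(study_id = study_id, country = country, population = population,
           biomarker = b, n = n, p05 = grab(0.05), p50 = grab(0.5),
           p95 = grab(0.95), p95_lcl = ci[1], p95_ucl = ci[2],
           note = "synthetic cohort")
  })
  bind_rows(rows)
}
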