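#' Risk characterisation ratio
#'
#' The ratio between a conservative exposure estimate (the 95th percentile
#' of the urinary biomarker concentration) and the corresponding screening
#' or guidance value. Ratios above 1 flag a potential concern requiring
#' refinement.
#'
#' @param exposure_p95 Concentration, ug/L, strictly positive.
#' @param gv Screening or guidance value, ug/L, strictly positive.
#' @return The exact quotient (vectorised).
#' @examples
#' compute_rcr(7.05, 3.25) # ~2.17
#' @export
compute_rcr <- function(exposure_p95, gv) {
  assert_positive(exposure_p95, "exposure_p95")
  assert_positive(gv, "gv")
  exposure_p95 / gv
}

#' Tier-S screening against common metabolites
#'
#' Compares each study's 95th percentile for the common metabolites with the
#' conservative screening value for the matching biomarker and population.
#' Studies without an estimated 95th percentile are skipped with a message
#' (their exposure could not be quantified, which is not evidence of
#' absence).
#'
#' @param exposure Exposure tibble ([read_exposure_table()] schema).
#' @param screening_gvs Tibble from [screening_values()] (raw, unrounded
#'   values are used, per the full-precision ratio contract).
#' @return A tibble of results: `study_id`, `country`, `population`,
#'   `biomarker`, `exposure_p95`, `gv`, `rcr`, `tier = "S"`, `concern`.
#' @export
run_tier_s <- function(exposure, screening_gvs) {
  rows <- exposure[exposure$biomarker %in% screening_gvs$biomarker, ]
  skipped <- rows[is.na(rows$p95), ]
  if (nrow(skipped)) {
    inform(sprintf("Tier S: skipping %d row(s) without an estimated p95 (%s).",
                   nrow(skipped),
                   paste(unique(skipped$country), collapse = ", ")))
  }
  rows <- rows[!is.na(rows$p95), ]
  if (nrow(rows) == 0) {
    return(tibble(study_id = character(), country = character(),
                  population = character(), biomarker = character(),
                  exposure_p95 = numeric(), gv = numeric(), rcr = numeric(),
                  tier = character(), concern = logical()))
  }
  rows %>%
    inner_join(screening_gvs[, c("biomarker", "population", "raw_gv")],
               by = c("biomarker", "population")) %>%
    mutate(rcr = compute_rcr(.data$p95, .data$raw_gv),
           tier = "S", concern = .data$rcr > 1) %>%
    select(study_id = "study_id", country = "country",
           population = "population", biomarker = "biomarker",
           exposure_p95 = "p95", gv = "raw_gv", rcr = "rcr",
           tier = "tier", concern = "concern")
}

#' Biomarker-substance guidance map for Tier I
#'
#' The comparison values used in the substance-specific tier: the rounded
#' (or adopted) guidance value of each substance via its specific biomarker.
#' Cyfluthrin is compared against the 4-FPBA *screening* value (its adopted
#' guidance value rests on a single-volunteer excretion study, so the
#' conservative screening value is used for risk characterisation).
#' Tau-fluvalinate, which has no specific metabolite, is screened separately
#' via [required_contribution_fraction()] and is not part of this map.
#'
#' @param registry An `hbm_registry`.
#' @param population_id `"children"` or `"adults"`.
#' @return A tibble `substance`, `biomarker`, `population`, `gv`.
#' @export
tier_i_gvs <- function(registry, population_id) {
  gvs <- substance_specific_gvs(registry, population_id)
  gvs <- gvs[!(gvs$substance %in% c("tau-fluvalinate", "cyfluthrin")), ]
  screen <- derive_screening_value(registry, "4-FPBA", population_id)
  bind_rows(
    gvs[, c("substance", "biomarker", "population", "gv")],
    tibble(substance = "cyfluthrin", biomarker = "4-FPBA",
           population = population_id, gv = screen$raw_gv))
}

#' Tier-I substance-specific risk characterisation
#'
#' One ratio per study and biomarker-substance pair. Biomarkers shared by
#' several substances (DCCA, ClF3CA) yield one row per candidate substance:
#' each row answers "what if the whole measured level came from this
#' substance". Missing 95th percentiles produce rows marked `NR` (ratio
#' `NA`) rather than being dropped, so the published result matrix is
#' reproduced shape and all.
#'
#' @param exposure Exposure tibble.
#' @param gv_map Tibble from [tier_i_gvs()] (or a custom
#'   substance/biomarker/population/gv map).
#' @return A tibble with `study_id`, `country`, `population`, `biomarker`,
#'   `substance`, `exposure_p95`, `gv`, `rcr`, `tier = "I"`, `concern`,
#'   `status` (`ok`/`NR`).
#' @export
run_tier_i <- function(exposure, gv_map) {
  res <- exposure %>%
    inner_join(gv_map, by = c("biomarker", "population"),
               relationship = "many-to-many") %>%
    mutate(rcr = ifelse(is.na(.data$p95), NA_real_, .data$p95 / .data$gv),
           tier = "I",
           concern = !is.na(.data$rcr) & .data$rcr > 1,
           status = ifelse(is.na(.data$p95), "NR", "ok")) %>%
    select(study_id = "study_id", country = "country",
           population = "population", biomarker = "biomarker",
           substance = "substance", exposure_p95 = "p95", gv = "gv",
           rcr = "rcr", tier = "tier", concern = "concern",
           status = "status")
  arrange(res, .data$population, .data$country, .data$substance)
}

#' Sum of substance-specific ratios per study
#'
#' Integrates the Tier-I results into one combined indicator per study by
#' summing the ratios of the selected substances. Shared biomarkers must be
#' allocated to exactly one substance each (e.g. DCCA to cypermethrin and
#' ClF3CA to lambda-cyhalothrin, the more toxic candidate), otherwise the
#' same measured level would be double-counted. Missing (`NR`) terms are
#' omitted.
#'
#' @param tier_i_results Tibble from [run_tier_i()].
#' @param allocation Named character vector, biomarker -> substance.
#' @return A tibble `study_id`, `country`, `population`, `n_terms`,
#'   `sum_rcr`.
#' @examples
#' # Belgium children: 0.086 + 0.25 + 0.034 ~= 0.37
#' @export
sum_rcrs <- function(tier_i_results,
                     allocation = c("ClF3CA" = "lambda-cyhalothrin",
                                    "DCCA" = "cypermethrin",
                                    "DBCA" = "deltamethrin")) {
  sel <- tier_i_results %>%
    filter(.data$biomarker %in% names(allocation),
           .data$substance == allocation[.data$biomarker])
  missing_alloc <- setdiff(unname(allocation), unique(tier_i_results$substance))
  if (length(missing_alloc)) {
    abort(sprintf("Allocation names substance(s) without Tier-I results: %s",
                  paste(missing_alloc, collapse = ", ")),
          class = "hbmtier_lookup_error")
  }
  sel %>%
    filter(!is.na(.data$rcr)) %>%
    group_by(.data$study_id, .data$country, .data$population) %>%
    summarise(n_terms = dplyr::n(), sum_rcr = sum(.data$rcr),
              .groups = "drop")
}

#' Maximum possible contribution of one substance to the common metabolite
#'
#' From the substance's Tier-I ratio on its selective biomarker, the largest
#' amount of 3-PBA (ug/L) its exposure could explain: the substance's
#' 3-PBA-based guidance value (mass balance with the substance's own ADI and
#' molar mass, at the conservative 9% excretion fraction) multiplied by the
#' ratio. If exposure to the substance sits at fraction `rcr` of its ADI,
#' its 3-PBA output is at most that fraction of its 3-PBA guidance value.
#'
#' @param registry An `hbm_registry`.
#' @param substance_id Substance id.
#' @param tier_i_rcr The substance's Tier-I ratio (selective biomarker),
#'   non-negative.
#' @param population_id `"children"` or `"adults"`.
#' @param fue Molar excretion fraction for 3-PBA; the conservative 9%
#'   default matches the screening derivation.
#' @return ug 3-PBA per L urine.
#' @export
contribution_to_3pba <- function(registry, substance_id, tier_i_rcr,
                                 population_id, fue = 0.09) {
  if (!is.numeric(tier_i_rcr) || any(tier_i_rcr < 0)) {
    abort("`tier_i_rcr` must be non-negative.", class = "hbmtier_domain_error")
  }
  s <- assert_assessable(registry, substance_id)
  m <- registry_metabolite(registry, "3-PBA")
  gv3 <- derive_hbm_gv(s$adi_mg_per_kg_bw_day, s$mw_g_per_mol,
                       m$mw_g_per_mol, fue, urine_volume(registry, population_id))
  gv3 * tier_i_rcr
}

#' Combined-mixture refinement of the screening ratio
#'
#' Refines the worst-case screening ratio for the common metabolite by
#' apportioning the measured 3-PBA level among the substances whose
#' selective biomarkers bound their contribution, weighting each share by
#' its relative potency (the reference substance's ADI divided by the
#' substance's ADI; the reference is the most toxic candidate so potencies
#' are at most 1):
#'
#' \deqn{RCR_{refined} = RCR_{screen} \times \sum_i \frac{c_i}{C} \, P_i}
#'
#' where `c_i` are the attributed amounts (ug/L), `C` the measured level and
#' `P_i` the relative potencies. The unattributed remainder is assigned to a
#' residual substance (default tau-fluvalinate, the remaining 3-PBA parent
#' in the registry with no selective biomarker); attributing it instead to
#' the reference substance (potency 1) gives the conservative upper bound,
#' which is also reported.
#'
#' @param registry An `hbm_registry`.
#' @param screening_rcr The Tier-S ratio being refined (full precision).
#' @param measured_3pba Measured 95th-percentile 3-PBA level, ug/L.
#' @param contributions Named numeric vector, substance -> attributed ug/L
#'   (from [contribution_to_3pba()]). Their sum may not exceed the measured
#'   level (they are maximum-possible shares of it).
#' @param residual_substance_id Substance receiving the unattributed share.
#' @param population_id Population (metadata only).
#' @param reference_substance_id Potency reference; must carry the minimum
#'   ADI among the substances involved.
#' @return A `combined_rcr` object; see [tidy.combined_rcr()] and
#'   [glance.combined_rcr()].
#' @export
refined_combined_rcr <- function(registry, screening_rcr, measured_3pba,
                                 contributions,
                                 residual_substance_id = "tau-fluvalinate",
                                 population_id = "children",
                                 reference_substance_id = "lambda-cyhalothrin") {
  assert_positive(measured_3pba, "measured_3pba")
  if (!is.numeric(screening_rcr) || screening_rcr < 0) {
    abort("`screening_rcr` must be non-negative.", class = "hbmtier_domain_error")
  }
  if (is.null(names(contributions)) || any(!nzchar(names(contributions)))) {
    abort("`contributions` must be a named vector (substance -> ug/L).",
          class = "hbmtier_domain_error")
  }
  if (any(contributions < 0)) {
    abort("Contributions must be non-negative.", class = "hbmtier_domain_error")
  }
  total <- sum(contributions)
  if (total > measured_3pba * (1 + 1e-9)) {
    abort(sprintf(paste("Contributions (%.4g ug/L) exceed the measured level",
                        "(%.4g ug/L); they are maximum possible shares of it."),
                  total, measured_3pba),
          class = "hbmtier_consistency_error")
  }
  adi_ref <- registry_substance(registry, reference_substance_id)$adi_mg_per_kg_bw_day
  ids <- c(names(contributions), residual_substance_id)
  adis <- vapply(ids, function(id)
    registry_substance(registry, id)$adi_mg_per_kg_bw_day, numeric(1))
  if (adi_ref > min(adis)) {
    abort("Reference substance must carry the minimum ADI among those considered.",
          class = "hbmtier_domain_error")
  }
  amounts <- c(contributions, setNames(measured_3pba - total,
                                       residual_substance_id))
  potency <- adi_ref / adis
  shares <- amounts / measured_3pba
  refined <- screening_rcr * sum(shares * potency)
  # conservative bound: residual treated as the reference substance itself
  shares_wc <- shares
  potency_wc <- potency
  potency_wc[residual_substance_id] <- 1
  refined_wc <- screening_rcr * sum(shares_wc * potency_wc)
  structure(list(
    population = population_id,
    screening_rcr = screening_rcr,
    measured_3pba = measured_3pba,
    residual_substance = residual_substance_id,
    reference_substance = reference_substance_id,
    table = tibble(substance = ids, amount = unname(amounts),
                   share = unname(shares), potency = unname(potency),
                   role = c(rep("contributor", length(contributions)),
                            "residual")),
    refined_rcr = refined,
    refined_rcr_worst_case = refined_wc,
    concern = refined > 1),
    class = "combined_rcr")
}

#' @export
print.combined_rcr <- function(x, ...) {
  cat(sprintf("<combined_rcr (%s)>\n", x$population))
  cat(sprintf("  screening RCR %.4g on measured 3-PBA %.4g ug/L\n",
              x$screening_rcr, x$measured_3pba))
  print(x$table)
  cat(sprintf("  refined RCR %.4g (worst-case residual: %.4g)%s\n",
              x$refined_rcr, x$refined_rcr_worst_case,
              if (x$concern) " -- potential concern" else ""))
  invisible(x)
}

#' Tidy a combined-mixture refinement
#'
#' @param x A `combined_rcr` object.
#' @param ... Unused.
#' @return The attribution table: one row per substance with its attributed
#'   amount (ug/L), share of the measured level, relative potency and role.
#' @export
tidy.combined_rcr <- function(x, ...) {
  x$table
}

#' One-row summary of a combined-mixture refinement
#'
#' @param x A `combined_rcr` object.
#' @param ... Unused.
#' @return A one-row tibble with the screening and refined ratios.
#' @export
glance.combined_rcr <- function(x, ...) {
  tibble(population = x$population, screening_rcr = x$screening_rcr,
         measured_3pba = x$measured_3pba,
         residual_substance = x$residual_substance,
         refined_rcr = x$refined_rcr,
         refined_rcr_worst_case = x$refined_rcr_worst_case,
         concern = x$concern)
}

#' Biomarker fraction a substance would need to contribute to exceed its
#' guidance value
#'
#' For a substance assessed through a shared metabolite, the guidance value
#' divided by the measured level: the minimum fraction of the measured
#' biomarker that would have to originate from this substance for its
#' guidance value to be exceeded. Values above 1 mean exceedance is
#' impossible even if the substance explains the entire measurement.
#'
#' @param gv Guidance value, ug/L.
#' @param exposure Measured level, ug/L.
#' @return A positive fraction (vectorised).
#' @examples
#' required_contribution_fraction(6.4, 7.05) # ~0.91: over 90% required
#' @export
required_contribution_fraction <- function(gv, exposure) {
  assert_positive(gv, "gv")
  assert_positive(exposure, "exposure")
  gv / exposure
}

#' Run the combined (Tier-C) refinement for every eligible study
#'
#' For each study of the population with a measured 3-PBA 95th percentile
#' and Tier-I ratios for the three substances with selective biomarkers
#' (lambda-cyhalothrin via ClF3CA, cypermethrin via DCCA, deltamethrin via
#' DBCA), computes the maximum-possible contributions and the refined
#' combined ratio. DCCA is attributed to cypermethrin, not permethrin, by
#' default: the more potent candidate gives the conservative attribution.
#'
#' @param registry An `hbm_registry`.
#' @param tier_s_results Tibble from [run_tier_s()].
#' @param tier_i_results Tibble from [run_tier_i()].
#' @param population_id Population to refine.
#' @param allocation Biomarker -> substance map for the contributors.
#' @inheritParams refined_combined_rcr
#' @return A list of `combined_rcr` objects, named by study country.
#' @export
run_tier_c <- function(registry, tier_s_results, tier_i_results,
                       population_id = "children",
                       allocation = c("ClF3CA" = "lambda-cyhalothrin",
                                      "DCCA" = "cypermethrin",
                                      "DBCA" = "deltamethrin"),
                       residual_substance_id = "tau-fluvalinate",
                       reference_substance_id = "lambda-cyhalothrin") {
  s3pba <- tier_s_results %>%
    filter(.data$biomarker == "3-PBA", .data$population == population_id)
  out <- list()
  for (i in seq_len(nrow(s3pba))) {
    row <- s3pba[i, ]
    ti <- tier_i_results %>%
      filter(.data$study_id == row$study_id, .data$country == row$country,
             .data$population == population_id,
             .data$biomarker %in% names(allocation),
             .data$substance == allocation[.data$biomarker],
             !is.na(.data$rcr))
    if (nrow(ti) < length(allocation)) next  # incomplete selective coverage
    contrib <- setNames(
      map_dbl(seq_len(nrow(ti)), function(j) {
        contribution_to_3pba(registry, ti$substance[j], ti$rcr[j],
                             population_id)
      }),
      ti$substance)
    out[[row$country]] <- refined_combined_rcr(
      registry, row$rcr, row$exposure_p95, contrib,
      residual_substance_id = residual_substance_id,
      population_id = population_id,
      reference_substance_id = reference_substance_id)
  }
  out
}
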