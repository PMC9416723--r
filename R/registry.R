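#' Load a substance/metabolite registry
#'
#' The registry is the typed store behind every guidance-value derivation:
#' parent pyrethroid active substances (ADI in mg/kg bw/day and molar mass),
#' urinary metabolites (molar mass and the parent substances they trace back
#' to), molar urinary excretion fractions (Fue) linking a substance to a
#' biomarker, and the population urine-volume parameters (L/kg bw/day).
#'
#' All cross-references are checked at load time: every metabolite parent and
#' every excretion-fraction pair must resolve to a registered substance or
#' metabolite, ids must be unique, ADIs and molar masses strictly positive,
#' and Fue values in (0, 1]. Violations abort with the offending file, row
#' and field.
#'
#' @param substances Path to a CSV with columns
#'   `id,adi_mg_per_kg_bw_day,mw_g_per_mol,adi_source` and optionally
#'   `assessable` (logical; substances flagged `FALSE`, such as etofenprox,
#'   are stored but refuse guidance-value derivation).
#' @param metabolites Path to a CSV with columns
#'   `id,mw_g_per_mol,parents,isomer_note`; `parents` is semicolon-separated.
#' @param fues Path to a CSV with columns
#'   `substance_id,metabolite_id,fue,basis,source`; `basis` is one of
#'   `measured_human`, `inferred`, `worst_case`. The same substance-metabolite
#'   pair may appear once per basis (e.g. a measured and a worst-case entry).
#' @param populations Path to a YAML file mapping population ids to daily
#'   urine volumes adjusted to body weight (L/kg bw/day).
#' @return An object of class `hbm_registry`: a list of tibbles
#'   `substances`, `metabolites`, `fues`, `populations`.
#' @seealso [default_registry()] for the packaged values,
#'   [write_registry()] for the inverse operation.
#' @examples
#' reg <- default_registry()
#' reg$substances
#' @export
load_registry <- function(substances, metabolites, fues, populations) {
  sub <- read_registry_csv(substances, c("id", "adi_mg_per_kg_bw_day",
                                         "mw_g_per_mol", "adi_source"))
  if (!"assessable" %in% names(sub)) sub$assessable <- TRUE
  sub$assessable <- as.logical(sub$assessable)
  sub$adi_mg_per_kg_bw_day <- as.numeric(sub$adi_mg_per_kg_bw_day)
  sub$mw_g_per_mol <- as.numeric(sub$mw_g_per_mol)
  check_rows(sub, substances, "adi_mg_per_kg_bw_day", function(x) is.finite(x) & x > 0)
  check_rows(sub, substances, "mw_g_per_mol", function(x) is.finite(x) & x > 0)
  if (anyDuplicated(sub$id)) {
    abort(sprintf("Duplicate substance id(s) in %s: %s", substances,
                  paste(unique(sub$id[duplicated(sub$id)]), collapse = ", ")),
          class = "hbmtier_load_error")
  }

  met <- read_registry_csv(metabolites, c("id", "mw_g_per_mol", "parents",
                                          "isomer_note"))
  met$mw_g_per_mol <- as.numeric(met$mw_g_per_mol)
  check_rows(met, metabolites, "mw_g_per_mol", function(x) is.finite(x) & x > 0)
  if (anyDuplicated(met$id)) {
    abort(sprintf("Duplicate metabolite id(s) in %s", metabolites),
          class = "hbmtier_load_error")
  }
  met$parent_ids <- lapply(strsplit(met$parents, ";", fixed = TRUE), trimws)
  dangling <- setdiff(unlist(met$parent_ids), sub$id)
  if (length(dangling)) {
    abort(sprintf("Metabolite parent(s) not in substance registry: %s",
                  paste(dangling, collapse = ", ")),
          class = "hbmtier_integrity_error")
  }

  fue <- read_registry_csv(fues, c("substance_id", "metabolite_id", "fue",
                                   "basis", "source"), allow_empty = TRUE)
  if (nrow(fue)) {
    fue$fue <- as.numeric(fue$fue)
    check_rows(fue, fues, "fue", function(x) is.finite(x) & x > 0 & x <= 1)
    bad_basis <- setdiff(fue$basis, c("measured_human", "inferred", "worst_case"))
    if (length(bad_basis)) {
      abort(sprintf("Unknown fue basis in %s: %s", fues,
                    paste(bad_basis, collapse = ", ")),
            class = "hbmtier_load_error")
    }
    miss_s <- setdiff(fue$substance_id, sub$id)
    miss_m <- setdiff(fue$metabolite_id, met$id)
    if (length(miss_s) || length(miss_m)) {
      abort(sprintf("Excretion fraction references unknown id(s): %s",
                    paste(c(miss_s, miss_m), collapse = ", ")),
            class = "hbmtier_integrity_error")
    }
  }

  pop_raw <- yaml::read_yaml(populations)
  pop <- tibble(id = names(pop_raw),
                urine_volume_l_per_kg_bw_day = as.numeric(unlist(pop_raw)))
  if (any(!is.finite(pop$urine_volume_l_per_kg_bw_day)) ||
      any(pop$urine_volume_l_per_kg_bw_day <= 0)) {
    abort(sprintf("Urine volumes in %s must be positive numbers.", populations),
          class = "hbmtier_load_error")
  }

  structure(list(substances = as_tibble(sub),
                 metabolites = as_tibble(met),
                 fues = as_tibble(fue),
                 populations = pop),
            class = "hbm_registry")
}

read_registry_csv <- function(path, required, allow_empty = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("Registry file not found: %s", path),
          class = "hbmtier_load_error")
  }
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "hbmtier_load_error")
  }
  if (!allow_empty && nrow(x) == 0) {
    abort(sprintf("%s contains no rows.", path), class = "hbmtier_load_error")
  }
  x
}

check_rows <- function(df, path, field, ok) {
  bad <- which(!ok(df[[field]]))
  if (length(bad)) {
    abort(sprintf("%s: invalid `%s` in row(s) %s", path, field,
                  paste(bad, collapse = ", ")),
          class = "hbmtier_load_error")
  }
}

#' Packaged default registry
#'
#' Loads the registry shipped with the package: the eight pyrethroid active
#' substances under assessment (etofenprox stored but flagged non-assessable
#' because urinary 3-PBA is not a reliable marker for it), the five urinary
#' biomarkers (3-PBA, 4-FPBA, ClF3CA, DBCA, DCCA), the molar urinary
#' excretion fractions with their evidence basis, and the daily urine volumes
#' (0.03 L/kg bw/day for children, 0.02 for adults).
#'
#' Molecular masses are average (not monoisotopic) masses recomputed from the
#' molecular formulas with standard atomic weights; the source assessments do
#' not print them.
#'
#' @return An `hbm_registry`.
#' @export
default_registry <- function() {
  ext <- function(f) system.file("extdata", f, package = "hbmtier", mustWork = TRUE)
  load_registry(ext("substances.csv"), ext("metabolites.csv"),
                ext("fues.csv"), ext("populations.yaml"))
}

#' Write a registry back to files
#'
#' Inverse of [load_registry()]; writing and reloading reproduces the same
#' structured content.
#'
#' @param registry An `hbm_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "hbm_registry"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("substances.csv", "metabolites.csv", "fues.csv",
                            "populations.yaml"))
  readr::write_csv(registry$substances[, c("id", "adi_mg_per_kg_bw_day",
                                           "mw_g_per_mol", "adi_source",
                                           "assessable")], paths[1])
  readr::write_csv(registry$metabolites[, c("id", "mw_g_per_mol", "parents",
                                            "isomer_note")], paths[2])
  readr::write_csv(registry$fues, paths[3])
  yaml::write_yaml(as.list(setNames(registry$populations$urine_volume_l_per_kg_bw_day,
                                    registry$populations$id)), paths[4])
  invisible(paths)
}

#' @export
print.hbm_registry <- function(x, ...) {
  cat(sprintf("<hbm_registry: %d substances (%d assessable), %d metabolites, %d excretion fractions, %d populations>\n",
              nrow(x$substances), sum(x$substances$assessable),
              nrow(x$metabolites), nrow(x$fues), nrow(x$populations)))
  invisible(x)
}

# --- lookups -----------------------------------------------------------------

registry_substance <- function(registry, id) {
  i <- match(id, registry$substances$id)
  if (is.na(i)) {
    abort(sprintf("Unknown substance id: %s", id), class = "hbmtier_lookup_error")
  }
  registry$substances[i, ]
}

registry_metabolite <- function(registry, id) {
  i <- match(id, registry$metabolites$id)
  if (is.na(i)) {
    abort(sprintf("Unknown metabolite id: %s", id), class = "hbmtier_lookup_error")
  }
  registry$metabolites[i, ]
}

assert_assessable <- function(registry, id) {
  s <- registry_substance(registry, id)
  if (!isTRUE(s$assessable)) {
    abort(sprintf("Substance '%s' is registered but flagged non-assessable; no guidance value may be derived for it.", id),
          class = "hbmtier_policy_error")
  }
  invisible(s)
}

urine_volume <- function(registry, population) {
  i <- match(population, registry$populations$id)
  if (is.na(i)) {
    abort(sprintf("Unknown population id: %s", population),
          class = "hbmtier_lookup_error")
  }
  registry$populations$urine_volume_l_per_kg_bw_day[i]
}

#' Molecular-weight ratio between a metabolite and a parent substance
#'
#' The dimensionless factor `MW_metabolite / MW_parent` entering the
#' mass-balance translation of an external dose into a urinary concentration.
#'
#' @param registry An `hbm_registry`.
#' @param metabolite_id,substance_id Registry ids.
#' @return A positive scalar.
#' @examples
#' mw_ratio(default_registry(), "DCCA", "cypermethrin") # ~0.502
#' @export
mw_ratio <- function(registry, metabolite_id, substance_id) {
  m <- registry_metabolite(registry, metabolite_id)
  s <- registry_substance(registry, substance_id)
  m$mw_g_per_mol / s$mw_g_per_mol
}

#' Look up a molar urinary excretion fraction
#'
#' When a substance-metabolite pair carries several entries (e.g. a measured
#' and a deliberately conservative worst-case value), the most evidence-based
#' basis is preferred: `measured_human`, then `inferred`, then `worst_case`.
#' A specific basis can be requested instead.
#'
#' @param registry An `hbm_registry`.
#' @param substance_id,metabolite_id Registry ids.
#' @param basis Optional basis to select.
#' @return The Fue as a scalar in (0, 1].
#' @export
registry_fue <- function(registry, substance_id, metabolite_id, basis = NULL) {
  rows <- registry$fues[registry$fues$substance_id == substance_id &
                        registry$fues$metabolite_id == metabolite_id, ]
  if (!is.null(basis)) rows <- rows[rows$basis == basis, ]
  if (nrow(rows) == 0) {
    abort(sprintf("No excretion fraction registered for %s -> %s%s",
                  substance_id, metabolite_id,
                  if (is.null(basis)) "" else sprintf(" (basis %s)", basis)),
          class = "hbmtier_lookup_error")
  }
  pref <- c(measured_human = 1, inferred = 2, worst_case = 3)
  rows$fue[order(pref[rows$basis])][1]
}

#' Urinary excretion scenarios for the common metabolite 3-PBA
#'
#' The deterministic refinement ladder for the screening value: the
#' worst-case 9% (lowest reported molar excretion, observed for
#' deltamethrin), the 5th percentile (11%), the geometric mean of averaged
#' study values (21%), and the geometric mean accounting for cis/trans
#' isomer differences (31%).
#'
#' @return A tibble with columns `id`, `fue`, `conservatism`.
#' @export
fue_scenarios <- function() {
  tibble(id = c("worst_case", "p5", "geomean", "geomean_cis_trans"),
         fue = c(0.09, 0.11, 0.21, 0.31),
         conservatism = c("conservative", "realistic", "realistic", "realistic"))
}
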