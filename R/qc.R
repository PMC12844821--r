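#' Quality-control configuration
#'
#' Parameters of the plausibility screen applied to label-declared values
#' before aggregation. Energy is reconstructed from macronutrients with
#' Atwater-type factors (protein and carbohydrate 4 kcal/g, fat 9 kcal/g,
#' fiber 2 kcal/g, polyols 2.4 kcal/g) and compared with the on-pack
#' declaration; a relative difference above `energy_tolerance` (default 20%,
#' relative to the declared value) excludes the record. SFA:total-fat and
#' total-sugars:carbohydrate ratios strictly above `ratio_limit` (default 1)
#' also exclude. Range checks catch physically improbable declarations.
#'
#' @param kcal_per_g Named numeric: energy conversion factors per gram.
#' @param energy_tolerance Fraction in (0, 1).
#' @param ratio_limit Positive limit for the SFA:TF and TS:CHO ratios.
#' @param polyols_within_carbohydrate If TRUE (default, EU labeling
#'   convention) polyols are assumed included in the declared carbohydrate,
#'   so they are subtracted before the 4 kcal/g term and re-added at their
#'   own factor.
#' @param max_values Named numeric upper bounds per nutrient (per 100 g/mL)
#'   for the improbable-value check; gram nutrients default to 100 g,
#'   sodium to 40,000 mg, energy to 900 kcal.
#' @return A `qc_config` list.
#' @export
qc_config <- function(kcal_per_g = c(protein = 4, carbohydrate = 4, fat = 9,
                                     fiber = 2, polyols = 2.4),
                      energy_tolerance = 0.20,
                      ratio_limit = 1,
                      polyols_within_carbohydrate = TRUE,
                      max_values = NULL) {
  stopifnot(
    all(kcal_per_g > 0),
    energy_tolerance > 0, energy_tolerance < 1,
    ratio_limit > 0
  )
  defaults <- c(
    energy = 900, protein = 100, total_fat = 100, sfa = 100,
    carbohydrate = 100, total_sugars = 100, fiber = 100, polyols = 100,
    sodium = 40000
  )
  if (!is.null(max_values)) {
    defaults[names(max_values)] <- max_values
  }
  structure(
    list(
      kcal_per_g = kcal_per_g,
      energy_tolerance = energy_tolerance,
      ratio_limit = ratio_limit,
      polyols_within_carbohydrate = polyols_within_carbohydrate,
      max_values = defaults
    ),
    class = "qc_config"
  )
}

#' Reconstruct energy from declared macronutrients
#'
#' Computes `4*protein + 4*(carbohydrate - polyols) + 9*total_fat + 2*fiber +
#' 2.4*polyols` (factors and the polyol treatment configurable via
#' [qc_config()]). Absent fiber or polyols count as zero. When declared
#' polyols exceed the carbohydrate they are nominally part of, the
#' carbohydrate term is clamped at zero with a warning. Records missing any
#' of protein, carbohydrate or total fat are not computable and return `NA`.
#'
#' @param nutrients A data frame (or records tibble) with columns `protein`,
#'   `total_fat`, `carbohydrate` and optionally `fiber`, `polyols`.
#' @param config A [qc_config()].
#' @return Numeric vector of kcal per 100 g/mL (`NA` where not computable).
#' @export
compute_energy <- function(nutrients, config = qc_config()) {
  f <- config$kcal_per_g
  protein <- nutrients$protein
  fat <- nutrients$total_fat
  carb <- nutrients$carbohydrate
  n <- length(protein)
  fiber <- coalesce0(nutrients$fiber, n)
  polyols <- coalesce0(nutrients$polyols, n)
  if (config$polyols_within_carbohydrate) {
    avail_carb <- carb - polyols
    clamped <- !is.na(avail_carb) & avail_carb < 0
    if (any(clamped)) {
      warn(paste0(
        sum(clamped),
        " record(s) declare more polyols than carbohydrate; carbohydrate term clamped at 0"
      ))
      avail_carb[clamped] <- 0
    }
  } else {
    avail_carb <- carb
  }
  f[["protein"]] * protein + f[["carbohydrate"]] * avail_carb +
    f[["fat"]] * fat + f[["fiber"]] * fiber + f[["polyols"]] * polyols
}

coalesce0 <- function(x, n) {
  if (is.null(x)) {
    return(rep(0, n))
  }
  ifelse(is.na(x), 0, x)
}

#' Screen records for improbable declared values
#'
#' Applies the plausibility checks per record: energy reconciliation
#' (relative difference between declared and reconstructed energy strictly
#' above the tolerance), SFA:total-fat and total-sugars:carbohydrate ratios
#' strictly above the limit, per-nutrient range checks, and the pass-through
#' image-completeness curation flag if the description carries one. A check
#' whose inputs are unavailable (missing nutrient, zero denominator) is
#' skipped, never failed. Boundary cases (relative difference exactly at the
#' tolerance, ratio exactly at the limit) are included.
#'
#' @param records Records tibble.
#' @param config A [qc_config()].
#' @return Tibble with one row per record: `product_id`, `status`
#'   (`"included"`/`"excluded"`), `reasons` (list-column of reason codes;
#'   excluded iff non-empty), `energy_calculated` and `energy_rel_diff`
#'   (NA where not computable).
#' @export
qc_screen <- function(records, config = qc_config()) {
  n <- nrow(records)
  e_calc <- if (n > 0) compute_energy(records, config) else numeric()
  e_decl <- records$energy
  rel <- ifelse(
    !is.na(e_calc) & !is.na(e_decl) & e_decl > 0,
    abs(e_decl - e_calc) / e_decl,
    NA_real_
  )
  energy_bad <- !is.na(rel) & rel > config$energy_tolerance

  sfa_ratio_bad <- with_ratio(records$sfa, records$total_fat, config$ratio_limit)
  sugars_ratio_bad <- with_ratio(records$total_sugars, records$carbohydrate, config$ratio_limit)

  improbable <- rep(FALSE, n)
  for (nut in BFCD_NUTRIENTS) {
    x <- records[[nut]]
    improbable <- improbable |
      (!is.na(x) & (x < 0 | x > config$max_values[[nut]]))
  }

  image_bad <- if ("image_complete" %in% names(records)) {
    !is.na(records$image_complete) & !records$image_complete
  } else {
    rep(FALSE, n)
  }

  reasons <- lapply(seq_len(n), function(i) {
    c(
      if (energy_bad[i]) "energy_mismatch",
      if (sfa_ratio_bad[i]) "sfa_gt_fat",
      if (sugars_ratio_bad[i]) "sugars_gt_carb",
      if (improbable[i]) "improbable_value",
      if (image_bad[i]) "missing_image_proxy"
    ) %||% character()
  })
  tibble(
    product_id = records$product_id,
    status = ifelse(lengths(reasons) > 0, "excluded", "included"),
    reasons = reasons,
    energy_calculated = e_calc,
    energy_rel_diff = rel
  )
}

with_ratio <- function(num, den, limit) {
  !is.na(num) & !is.na(den) & den > 0 & (num / den) > limit
}

#' Filter a database on the QC screen
#'
#' @param records Records tibble.
#' @param config A [qc_config()].
#' @return List with `included` (records tibble, input order preserved),
#'   `results` (one [qc_screen()] row per input record) and `reason_counts`
#'   (tibble of reason code vs excluded-record count, for reporting).
#' @export
qc_filter <- function(records, config = qc_config()) {
  results <- qc_screen(records, config)
  keep <- results$status == "included"
  all_reasons <- unlist(results$reasons)
  reason_counts <- tibble(reason = QC_REASONS) |>
    mutate(n = map_int(reason, function(r) sum(all_reasons == r)))
  list(
    included = records[keep, , drop = FALSE],
    results = results,
    reason_counts = reason_counts
  )
}
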