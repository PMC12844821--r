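# Synthetic BFCD generator with planted ground truth. Every pipeline stage
# (QC screen, multipack exclusion, name-based grouping, latent-descriptor
# refinement) is validated against the truth table this module emits.

#' Simulation configuration
#'
#' Study conditions for the synthetic branded-food database. Defaults follow
#' the observed conditions of a national BFCD of ~4,700 curated products:
#' QC violation rates of 747/4738 (energy mismatch), 2/4738 (SFA:TF) and
#' 1/4738 (TS:CHO); a multipack share of about a third of eligible products
#' (1332/3988); and a group-size distribution whose 1 / 2 / >=3-product
#' shares match the published yield table (53% / 16% / 31%, mean about 3
#' products per generic name). Within-group CV targets and per-nutrient
#' missingness are not published and are set to values typical of
#' label-declared data (see the package vignette).
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output files.
#' @param templates Category/subgroup templates (see
#'   [default_sim_templates()]); each defines base nutrient means, descriptor
#'   dimensions with per-value effects, and an optional latent secondary
#'   descriptor.
#' @param n_groups_per_category Planted groups per category, distributed over
#'   the category's templates.
#' @param group_size_probs Named numeric: group size -> probability.
#' @param cv_targets Named numeric within-group CV targets per drawn nutrient.
#'   SFA and total sugars are drawn as fractions of total fat and
#'   carbohydrate, with fraction noise set so the product reaches the target.
#' @param omit_prob Probability that a sampled group omits a descriptor
#'   dimension entirely (its long names carry no token for it).
#' @param latent_split_fraction Fraction of groups of size >= 4 given a
#'   latent binary secondary descriptor (e.g. sweetener type) carried only in
#'   the ingredient list.
#' @param latent_shift_sd Size of the latent effect: the affected arm's mean
#'   for the latent nutrient is shifted down by this many within-group SDs.
#' @param qc_violation_rates Named rates for planted QC violations
#'   (`energy_mismatch`, `sfa_gt_fat`, `sugars_gt_carb`, `improbable_value`).
#' @param multipack_rate Multipack records added, as a fraction of base
#'   records.
#' @param missingness Named per-nutrient probabilities that a declared value
#'   is absent.
#' @param include_boundary_cases Add two hand-crafted records sitting exactly
#'   on the QC boundaries (energy relative difference exactly at the
#'   tolerance; ratios exactly 1) that must remain included.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       templates = default_sim_templates(),
                       n_groups_per_category = 8L,
                       group_size_probs = c(
                         "1" = 0.42, "2" = 0.16, "3" = 0.12, "4" = 0.09,
                         "5" = 0.07, "6" = 0.05, "8" = 0.04, "10" = 0.03,
                         "12" = 0.02
                       ),
                       cv_targets = c(
                         protein = 0.12, total_fat = 0.15, sfa = 0.18,
                         carbohydrate = 0.12, total_sugars = 0.18,
                         fiber = 0.15, polyols = 0.10, sodium = 0.12
                       ),
                       omit_prob = 0.15,
                       latent_split_fraction = 0.15,
                       latent_shift_sd = 3,
                       qc_violation_rates = c(
                         energy_mismatch = 747 / 4738, sfa_gt_fat = 2 / 4738,
                         sugars_gt_carb = 1 / 4738, improbable_value = 0
                       ),
                       multipack_rate = 1332 / 3988,
                       missingness = c(
                         energy = 0.02, protein = 0.03, total_fat = 0.02,
                         sfa = 0.04, carbohydrate = 0.03, total_sugars = 0.04,
                         sodium = 0.05, fiber = 0.50, polyols = 0.95
                       ),
                       include_boundary_cases = FALSE) {
  rates <- c(qc_violation_rates, multipack = multipack_rate,
             latent = latent_split_fraction, omit = omit_prob, missingness)
  if (any(rates < 0 | rates > 1)) {
    abort("all simulation rates must lie in [0, 1]")
  }
  if (any(cv_targets < 0)) {
    abort("within-group CV targets must be nonnegative")
  }
  if (latent_shift_sd * max(cv_targets) >= 1) {
    abort("latent_shift_sd too large: shifted means would cross zero")
  }
  if (is.null(names(group_size_probs)) ||
      any(is.na(suppressWarnings(as.integer(names(group_size_probs)))))) {
    abort("group_size_probs must be named by integer group sizes")
  }
  if (qc_violation_rates[["sfa_gt_fat"]] > 0 &&
      all(vapply(templates, function(t) t$base[["total_fat"]] <= 0, logical(1)))) {
    abort("sfa_gt_fat violations requested but no template declares total fat")
  }
  structure(
    list(
      seed = as.integer(seed), templates = templates,
      n_groups_per_category = as.integer(n_groups_per_category),
      group_size_probs = group_size_probs, cv_targets = cv_targets,
      omit_prob = omit_prob,
      latent_split_fraction = latent_split_fraction,
      latent_shift_sd = latent_shift_sd,
      qc_violation_rates = qc_violation_rates,
      multipack_rate = multipack_rate, missingness = missingness,
      include_boundary_cases = include_boundary_cases
    ),
    class = "sim_config"
  )
}

sim_template <- function(category, subcategory, group, subgroup, basis,
                         base, sfa_frac, sugars_frac, dim_values,
                         effects = list(), latent = NULL,
                         cv_overrides = NULL, ingredients_base = "") {
  list(
    category = category, subcategory = subcategory, group = group,
    subgroup = subgroup, basis = basis, base = base, sfa_frac = sfa_frac,
    sugars_frac = sugars_frac, dim_values = dim_values, effects = effects,
    latent = latent, cv_overrides = cv_overrides,
    ingredients_base = ingredients_base
  )
}

#' Default simulation templates
#'
#' Eight subgroup templates across the four categories of
#' [default_vocabulary()]: yogurts and milk drinks (with a latent sweetener
#' descriptor shifting total sugars), butters and margarines, breads and
#' biscuits (latent sweetener), and canned/frozen vegetables (latent
#' consumption-with-or-without-liquid descriptor shifting sodium). Base
#' nutrient means are typical label values per 100 g/mL.
#'
#' @return List of template objects consumed by [generate_db()].
#' @export
default_sim_templates <- function() {
  milk_cat <- "Milk, milk product or milk substitute"
  fat_cat <- "Fat or fat product"
  grain_cat <- "Grain or grain product"
  veg_cat <- "Vegetable or vegetable product"
  sweetener_latent <- list(
    dimension = "sweetener", nutrient = "total_sugars",
    arms = list(
      list(value = "with sweeteners", token = "sweeteners (stevia)"),
      list(value = "with sugar", token = "sugar")
    )
  )
  list(
    sim_template(
      milk_cat, "Dairy products", "Fermented milks", "Yogurt", "per_100g",
      base = c(protein = 9, total_fat = 3, carbohydrate = 5, fiber = 0,
               polyols = 0, sodium = 60),
      sfa_frac = 0.65, sugars_frac = 0.8,
      dim_values = list(
        animal_of_origin = c("cow", "sheep", "goat"),
        processing = c("strained", "fermented"),
        fat_content = c("0% fat", "2% fat", "full fat"),
        flavor = c("plain", "strawberry", "vanilla")
      ),
      effects = list(
        fat_content = list(
          "0% fat" = c(total_fat = 0.2), "2% fat" = c(total_fat = 2),
          "full fat" = c(total_fat = 5)
        ),
        flavor = list(
          strawberry = c(carbohydrate = 13), vanilla = c(carbohydrate = 12)
        )
      ),
      latent = sweetener_latent,
      ingredients_base = "milk, lactic cultures"
    ),
    sim_template(
      milk_cat, "Milks", "Liquid milks", "Milk", "per_100mL",
      base = c(protein = 3.3, total_fat = 3.5, carbohydrate = 4.8, fiber = 0,
               polyols = 0, sodium = 45),
      sfa_frac = 0.65, sugars_frac = 0.85,
      dim_values = list(
        animal_of_origin = c("cow", "goat"),
        processing = c("pasteurized", "UHT"),
        fat_content = c("0% fat", "2% fat", "full fat"),
        flavor = c("plain", "chocolate", "vanilla")
      ),
      effects = list(
        fat_content = list(
          "0% fat" = c(total_fat = 0.3), "2% fat" = c(total_fat = 1.8),
          "full fat" = c(total_fat = 3.6)
        ),
        flavor = list(chocolate = c(carbohydrate = 10))
      ),
      latent = sweetener_latent,
      ingredients_base = "milk"
    ),
    sim_template(
      fat_cat, "Animal fats", "Butters", "Butter", "per_100g",
      base = c(protein = 0.6, total_fat = 82, carbohydrate = 0.7, fiber = 0,
               polyols = 0, sodium = 15),
      sfa_frac = 0.65, sugars_frac = 0.6,
      dim_values = list(
        source = "cow",
        form = c("spreadable", "solid"),
        salting = c("salted", "unsalted")
      ),
      effects = list(
        salting = list(salted = c(sodium = 600), unsalted = c(sodium = 15))
      ),
      cv_overrides = c(total_fat = 0.03),
      ingredients_base = "cream"
    ),
    sim_template(
      fat_cat, "Vegetable fats", "Margarines", "Margarine", "per_100g",
      base = c(protein = 0.2, total_fat = 60, carbohydrate = 0.5, fiber = 0,
               polyols = 0, sodium = 300),
      sfa_frac = 0.25, sugars_frac = 0.5,
      dim_values = list(
        source = c("sunflower", "olive", "sunflower and olive oil mix"),
        form = c("spreadable", "solid"),
        salting = c("salted", "unsalted")
      ),
      effects = list(
        salting = list(salted = c(sodium = 700), unsalted = c(sodium = 30))
      ),
      cv_overrides = c(total_fat = 0.08),
      ingredients_base = "vegetable oils, water, emulsifier"
    ),
    sim_template(
      grain_cat, "Breads", "Leavened breads", "Bread", "per_100g",
      base = c(protein = 9, total_fat = 4, carbohydrate = 45, fiber = 4,
               polyols = 0, sodium = 450),
      sfa_frac = 0.3, sugars_frac = 0.08,
      dim_values = list(
        main_grain = c("wheat", "rye", "multigrain"),
        processing = c("wholegrain", "white"),
        form = c("sliced", "loaf")
      ),
      ingredients_base = "flour, water, yeast, salt"
    ),
    sim_template(
      grain_cat, "Fine bakery wares", "Biscuits", "Biscuits", "per_100g",
      base = c(protein = 7, total_fat = 18, carbohydrate = 62, fiber = 3,
               polyols = 0, sodium = 350),
      sfa_frac = 0.5, sugars_frac = 0.35,
      dim_values = list(
        main_grain = c("wheat", "oat", "corn"),
        coating_or_filling = c("plain", "chocolate coating", "fruit filling")
      ),
      latent = sweetener_latent,
      ingredients_base = "flour, vegetable fat, raising agents",
      cv_overrides = c(carbohydrate = 0.10)
    ),
    sim_template(
      veg_cat, "Canned vegetables", "Canned stem vegetables", "Asparagus",
      "per_100g",
      base = c(protein = 2, total_fat = 0.3, carbohydrate = 3.5, fiber = 1.5,
               polyols = 0, sodium = 350),
      sfa_frac = 0.3, sugars_frac = 0.5,
      dim_values = list(
        processing = "canned",
        liquid_matrix = c("in brine", "in water")
      ),
      latent = list(
        dimension = "consumption", nutrient = "sodium",
        arms = list(
          list(value = "strained", token = "drained weight declared"),
          list(value = "non-strained", token = "values refer to contents with liquid")
        )
      ),
      ingredients_base = "asparagus"
    ),
    sim_template(
      veg_cat, "Frozen vegetables", "Frozen leaf vegetables", "Spinach",
      "per_100g",
      base = c(protein = 2.9, total_fat = 0.4, carbohydrate = 1.8, fiber = 2.2,
               polyols = 0, sodium = 80),
      sfa_frac = 0.3, sugars_frac = 0.4,
      dim_values = list(
        processing = "frozen",
        seasoning = "with spices"
      ),
      ingredients_base = "spinach"
    )
  )
}

# Normal draw truncated at zero and at +/- 3.5 SD: label values do not stray
# arbitrarily far from the group's typical declaration, and clean synthetic
# records must never trip the improbable-value screen.
draw_tn <- function(n, mean, sd) {
  if (is.na(sd) || sd <= 0 || mean <= 0) {
    return(rep(max(mean, 0), n))
  }
  lo <- max(0, mean - 3.5 * sd)
  hi <- mean + 3.5 * sd
  x <- rnorm(n, mean, sd)
  for (k in seq_len(20)) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic branded-food database with planted ground truth
#'
#' Writes the four-file BFCD layout (description, nutrients, claims,
#' ingredients) plus `truth.csv` and `vocab.yaml` to `dir`. Nutrients are
#' drawn per planted group from truncated normals around template means;
#' declared energy is the Atwater-type reconstruction of the (rounded,
#' post-missingness) macronutrients times multiplicative noise — within the
#' QC tolerance for clean records, far outside it for planted energy
#' violations (which deflate the declaration, so they can never also trip the
#' improbable-value ceiling). SFA and sugars are drawn as fractions of total
#' fat and carbohydrate so clean records never violate the ratio rules even
#' after rounding.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with `records` (tibble equal to `read_bfcd()` on the written
#'   files), `truth` (tibble: product_id, category path, `true_group` step-1
#'   generic name, latent dimension/value, `qc_reason`, `multipack`,
#'   `boundary`), `paths` (named file paths) and `vocabulary`.
#' @export
generate_db <- function(config = sim_config(), dir = tempfile("simdb")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vocab <- default_vocabulary()
  sizes <- as.integer(names(config$group_size_probs))

  # --- plan groups: distinct descriptor combinations per template ----------
  cats <- unique(vapply(config$templates, function(t) t$category, character(1)))
  plans <- list()
  for (cat in cats) {
    tpls <- keep(config$templates, function(t) t$category == cat)
    quota <- diff(round(seq(0, config$n_groups_per_category, length.out = length(tpls) + 1)))
    for (j in seq_along(tpls)) {
      tpl <- tpls[[j]]
      combos <- enumerate_combos(tpl, config$omit_prob > 0)
      take <- min(quota[j], nrow(combos))
      if (take < quota[j]) {
        warn(paste0(
          "template '", tpl$subgroup, "' supports only ", nrow(combos),
          " distinct descriptor combinations; capping group count"
        ))
      }
      if (take == 0) next
      picked <- combos[sample.int(nrow(combos), take), , drop = FALSE]
      for (r in seq_len(take)) {
        assignment <- unlist(picked[r, , drop = TRUE])
        assignment <- assignment[!is.na(assignment)]
        size <- sizes[sample.int(length(sizes), 1, prob = config$group_size_probs)]
        latent <- !is.null(tpl$latent) && size >= 4 &&
          runif(1) < config$latent_split_fraction
        plans[[length(plans) + 1]] <- list(
          template = tpl, assignment = assignment, size = size, latent = latent
        )
      }
    }
  }

  # --- draw member records --------------------------------------------------
  rec_rows <- list()
  truth_rows <- list()
  pid <- 0
  for (plan in plans) {
    tpl <- plan$template
    size <- plan$size
    drawn <- draw_group_nutrients(tpl, plan$assignment, size, plan$latent, config)
    gname <- build_generic_name(
      c(tpl$category, tpl$subcategory, tpl$group, tpl$subgroup),
      plan$assignment, vocab
    )
    tokens <- paste(unname(plan$assignment), collapse = " ")
    ids <- sprintf("P%05d", pid + seq_len(size))
    arm_value <- arm_token <- rep(NA_character_, size)
    if (plan$latent) {
      arm_value <- vapply(drawn$arm, function(a) tpl$latent$arms[[a]]$value, character(1))
      arm_token <- vapply(drawn$arm, function(a) tpl$latent$arms[[a]]$token, character(1))
    }
    rec_rows[[length(rec_rows) + 1]] <- tibble(
      product_id = ids,
      long_name = stringi::stri_trim_both(paste(
        tpl$subgroup, tokens, "brand", pid + seq_len(size)
      )),
      category = tpl$category, subcategory = tpl$subcategory,
      group = tpl$group, subgroup = tpl$subgroup, basis = tpl$basis,
      protein = drawn$protein, total_fat = drawn$total_fat,
      sfa = drawn$sfa, carbohydrate = drawn$carbohydrate,
      total_sugars = drawn$total_sugars, fiber = drawn$fiber,
      polyols = drawn$polyols, sodium = drawn$sodium,
      ingredients_text = ifelse(
        is.na(arm_token), tpl$ingredients_base,
        paste0(tpl$ingredients_base, ", ", arm_token)
      )
    )
    truth_rows[[length(truth_rows) + 1]] <- tibble(
      product_id = ids, category = tpl$category, subgroup = tpl$subgroup,
      true_group = gname,
      latent_dimension = if (plan$latent) tpl$latent$dimension else NA_character_,
      latent_value = arm_value,
      qc_reason = NA_character_, multipack = FALSE, boundary = FALSE
    )
    pid <- pid + size
  }
  n_base <- pid

  # --- multipacks -----------------------------------------------------------
  n_multi <- round(config$multipack_rate * n_base)
  tpl_idx <- if (n_multi > 0) {
    sample.int(length(config$templates), n_multi, replace = TRUE)
  } else {
    integer()
  }
  for (ti in unique(tpl_idx)) {
    tpl <- config$templates[[ti]]
    size <- sum(tpl_idx == ti)
    drawn <- draw_group_nutrients(tpl, character(), size, FALSE, config)
    ids <- sprintf("P%05d", pid + seq_len(size))
    rec_rows[[length(rec_rows) + 1]] <- tibble(
      product_id = ids,
      long_name = paste(
        tpl$subgroup, "and crackers combo pack brand", pid + seq_len(size)
      ),
      category = tpl$category, subcategory = tpl$subcategory,
      group = tpl$group, subgroup = tpl$subgroup, basis = tpl$basis,
      protein = drawn$protein, total_fat = drawn$total_fat,
      sfa = drawn$sfa, carbohydrate = drawn$carbohydrate,
      total_sugars = drawn$total_sugars, fiber = drawn$fiber,
      polyols = drawn$polyols, sodium = drawn$sodium,
      ingredients_text = tpl$ingredients_base
    )
    truth_rows[[length(truth_rows) + 1]] <- tibble(
      product_id = ids, category = tpl$category, subgroup = tpl$subgroup,
      true_group = NA_character_, latent_dimension = NA_character_,
      latent_value = NA_character_, qc_reason = NA_character_,
      multipack = TRUE, boundary = FALSE
    )
    pid <- pid + size
  }

  records <- bind_rows(rec_rows)
  truth <- bind_rows(truth_rows)

  # --- missingness (before computing declared energy, so the declaration is
  # consistent with the values a QC audit can see) ---------------------------
  records_pre <- records
  for (nut in setdiff(BFCD_NUTRIENTS, "energy")) {
    rate <- if (nut %in% names(config$missingness)) config$missingness[[nut]] else 0
    if (rate > 0) {
      records[[nut]][runif(nrow(records)) < rate] <- NA_real_
    }
  }

  # --- planted QC violations ------------------------------------------------
  macros_ok <- !is.na(records$protein) & !is.na(records$total_fat) &
    !is.na(records$carbohydrate)
  # sfa/sugars plants multiply the denominator by 1.5/1.3; bound it so the
  # planted value stays under the improbable-value ceiling (single clean
  # reason per planted record, truth-table comparisons stay exact)
  eligible <- list(
    energy_mismatch = which(macros_ok & !truth$multipack),
    sfa_gt_fat = which(!truth$multipack & !is.na(records$total_fat) &
                         records$total_fat >= 1 & records$total_fat <= 66),
    sugars_gt_carb = which(!truth$multipack & !is.na(records$carbohydrate) &
                             records$carbohydrate >= 1 &
                             records$carbohydrate <= 75),
    improbable_value = which(macros_ok & !truth$multipack)
  )
  planted <- integer()
  for (reason in names(config$qc_violation_rates)) {
    want <- round(config$qc_violation_rates[[reason]] * n_base)
    pool <- setdiff(eligible[[reason]], planted)
    take <- head(pool[sample.int(length(pool))], want)
    planted <- c(planted, take)
    truth$qc_reason[take] <- reason
  }
  sfa_idx <- which(truth$qc_reason %in% "sfa_gt_fat")
  records$sfa[sfa_idx] <- round(records$total_fat[sfa_idx] * 1.5, 2)
  sug_idx <- which(truth$qc_reason %in% "sugars_gt_carb")
  records$total_sugars[sug_idx] <- round(records$carbohydrate[sug_idx] * 1.3, 2)
  imp_idx <- which(truth$qc_reason %in% "improbable_value")
  records$protein[imp_idx] <- 150

  # --- declared energy ------------------------------------------------------
  # Declared from the values the QC audit can see; when a macro is hidden the
  # energy check is skipped anyway, so fall back to the pre-missingness draw
  # (labels declare energy even when a macro is missing from curation).
  calc <- compute_energy(records, qc_config())
  calc_full <- compute_energy(records_pre, qc_config())
  calc <- ifelse(is.na(calc), calc_full, calc)
  u <- runif(nrow(records), -0.12, 0.12)
  energy <- round(calc * (1 + u))
  e_idx <- which(truth$qc_reason %in% "energy_mismatch")
  energy[e_idx] <- round(calc[e_idx] * (1 - runif(length(e_idx), 0.30, 0.45)))
  rate_e <- if ("energy" %in% names(config$missingness)) config$missingness[["energy"]] else 0
  if (rate_e > 0) {
    miss_e <- runif(nrow(records)) < rate_e
    miss_e[e_idx] <- FALSE # planted energy violations keep their declaration
    energy[miss_e] <- NA_real_
  }
  records$energy <- energy

  # --- boundary records sitting exactly on the QC cut-offs ------------------
  if (config$include_boundary_cases) {
    tpl <- config$templates[[1]]
    boundary <- tibble(
      product_id = sprintf("P%05d", pid + 1:2),
      long_name = paste("Reference specimen", c("alpha", "beta")),
      category = tpl$category, subcategory = tpl$subcategory,
      group = tpl$group, subgroup = tpl$subgroup, basis = tpl$basis,
      protein = c(20, 5), total_fat = c(0, 10), sfa = c(0, 10),
      carbohydrate = c(0, 20), total_sugars = c(0, 20),
      fiber = c(0, 0), polyols = c(0, 0), sodium = c(100, 50),
      ingredients_text = tpl$ingredients_base,
      energy = c(100, 190) # calc = 80 (rel diff exactly 0.20) and 190 (exact)
    )
    records <- bind_rows(records, boundary)
    truth <- bind_rows(truth, tibble(
      product_id = boundary$product_id, category = tpl$category,
      subgroup = tpl$subgroup,
      true_group = paste0(tpl$subgroup), # no descriptor tokens: subgroup alone
      latent_dimension = NA_character_, latent_value = NA_character_,
      qc_reason = NA_character_, multipack = FALSE, boundary = TRUE
    ))
    pid <- pid + 2
  }

  # --- claims (decorative; never match any descriptor pattern) --------------
  claim_pool <- c("new recipe", "family pack", "locally produced")
  has_claim <- runif(nrow(records)) < 0.15
  claims_tbl <- tibble(
    product_id = records$product_id[has_claim],
    claim_text = sample(claim_pool, sum(has_claim), replace = TRUE)
  )

  # --- write the BFCD layout ------------------------------------------------
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    description = file.path(dir, "description.csv"),
    nutrients = file.path(dir, "nutrients.csv"),
    claims = file.path(dir, "claims.csv"),
    ingredients = file.path(dir, "ingredients.csv"),
    truth = file.path(dir, "truth.csv"),
    vocab = file.path(dir, "vocab.yaml")
  )
  readr::write_csv(
    records[, c("product_id", "long_name", "category", "subcategory",
                "group", "subgroup", "basis")],
    paths[["description"]], na = ""
  )
  readr::write_csv(
    records[, c("product_id", BFCD_NUTRIENTS)], paths[["nutrients"]], na = ""
  )
  readr::write_csv(claims_tbl, paths[["claims"]], na = "")
  readr::write_csv(
    records[, c("product_id", "ingredients_text")], paths[["ingredients"]],
    na = ""
  )
  readr::write_csv(truth, paths[["truth"]], na = "")
  write_vocabulary(vocab, paths[["vocab"]])

  records_out <- records[, c(
    "product_id", "long_name", "category", "subcategory", "group", "subgroup",
    "basis", BFCD_NUTRIENTS
  )]
  records_out$claims <- rep(list(character()), nrow(records_out))
  pos <- match(claims_tbl$product_id, records_out$product_id)
  records_out$claims[pos] <- map(claims_tbl$claim_text, identity)
  records_out$ingredients_text <- records$ingredients_text
  list(records = records_out, truth = truth, paths = paths, vocabulary = vocab)
}

# All distinct descriptor-value combinations a template supports, optionally
# including omission of a dimension (NA slot).
enumerate_combos <- function(tpl, allow_omission) {
  opts <- lapply(tpl$dim_values, function(v) if (allow_omission) c(v, NA) else v)
  combos <- expand.grid(opts, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  # drop the all-omitted combination only if it collides with nothing: keep it,
  # it is the "subgroup alone" generic food
  tibble::as_tibble(combos)
}

draw_group_nutrients <- function(tpl, assignment, size, latent, config) {
  means <- tpl$base
  for (dname in names(assignment)) {
    eff <- tpl$effects[[dname]][[assignment[[dname]]]]
    if (!is.null(eff)) means[names(eff)] <- eff
  }
  cv <- config$cv_targets
  if (!is.null(tpl$cv_overrides)) cv[names(tpl$cv_overrides)] <- tpl$cv_overrides

  protein <- draw_tn(size, means[["protein"]], cv[["protein"]] * means[["protein"]])
  total_fat <- draw_tn(size, means[["total_fat"]], cv[["total_fat"]] * means[["total_fat"]])
  carbohydrate <- draw_tn(size, means[["carbohydrate"]], cv[["carbohydrate"]] * means[["carbohydrate"]])
  fiber <- draw_tn(size, means[["fiber"]], cv[["fiber"]] * means[["fiber"]])
  polyols <- draw_tn(size, means[["polyols"]], cv[["polyols"]] * means[["polyols"]])
  sodium <- draw_tn(size, means[["sodium"]], cv[["sodium"]] * means[["sodium"]])

  cv_sfa_frac <- sqrt(max(cv[["sfa"]]^2 - cv[["total_fat"]]^2, 0))
  sfa_frac <- pmin(draw_tn(size, tpl$sfa_frac, cv_sfa_frac * tpl$sfa_frac), 0.95)
  sfa <- total_fat * sfa_frac
  cv_sug_frac <- sqrt(max(cv[["total_sugars"]]^2 - cv[["carbohydrate"]]^2, 0))
  sug_frac <- pmin(draw_tn(size, tpl$sugars_frac, cv_sug_frac * tpl$sugars_frac), 0.95)
  total_sugars <- carbohydrate * sug_frac

  arm <- rep(2L, size)
  if (latent) {
    arm[sample.int(size, floor(size / 2))] <- 1L
    nut <- tpl$latent$nutrient
    factor_a <- 1 - config$latent_shift_sd * cv[[nut]]
    vals <- switch(nut,
      total_sugars = total_sugars, sodium = sodium, protein = protein,
      total_fat = total_fat, carbohydrate = carbohydrate,
      abort(paste0("unsupported latent nutrient: ", nut))
    )
    vals[arm == 1L] <- vals[arm == 1L] * factor_a
    if (nut == "total_sugars") total_sugars <- vals
    if (nut == "sodium") sodium <- vals
    if (nut == "protein") protein <- vals
    if (nut == "total_fat") total_fat <- vals
    if (nut == "carbohydrate") carbohydrate <- vals
  }

  list(
    protein = round(protein, 2), total_fat = round(total_fat, 2),
    sfa = round(pmin(sfa, total_fat), 2),
    carbohydrate = round(carbohydrate, 2),
    total_sugars = round(pmin(total_sugars, carbohydrate), 2),
    fiber = round(fiber, 2), polyols = round(pmin(polyols, carbohydrate), 2),
    sodium = round(sodium, 1), arm = arm
  )
}
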