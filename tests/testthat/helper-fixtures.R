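# Shared in-code fixtures: a two-dimension toy vocabulary and a records
# builder for the "Snacks" category it describes.

tiny_vocab <- function(multipack_patterns = "combo") {
  new_vocabulary(
    categories = list(
      Snacks = list(dimensions = list(
        list(
          name = "flavor", tier = "primary",
          values = list(
            list(value = "chocolate", patterns = c("chocolate", "choc")),
            list(value = "vanilla", patterns = "vanilla")
          )
        ),
        list(
          name = "salting", tier = "primary",
          values = list(list(value = "salted", patterns = "(?<!un)salted")),
          default = "unsalted"
        ),
        list(
          name = "sweetener", tier = "secondary",
          values = list(
            list(value = "with sweeteners", patterns = "stevia"),
            list(value = "with sugar", patterns = "sugar"),
            list(value = "with honey", patterns = "honey")
          )
        ),
        list(
          name = "farming", tier = "secondary",
          values = list(list(value = "organic", patterns = "organic"))
        )
      ))
    ),
    multipack_patterns = multipack_patterns
  )
}

# n Snack-category records with overridable columns.
snack_records <- function(n, long_name = "Bar", ingredients_text = NA_character_,
                          energy = 400, protein = 6, total_fat = 20, sfa = 8,
                          carbohydrate = 50, total_sugars = 25, fiber = 3,
                          polyols = 0, sodium = 300) {
  rep_n <- function(x) rep_len(x, n)
  tibble::tibble(
    product_id = sprintf("S%03d", seq_len(n)),
    long_name = rep_n(long_name),
    category = "Snacks", subcategory = "Sweet snacks", group = "Bars",
    subgroup = "Bar", basis = "per_100g",
    energy = rep_n(energy), protein = rep_n(protein),
    total_fat = rep_n(total_fat), sfa = rep_n(sfa),
    carbohydrate = rep_n(carbohydrate), total_sugars = rep_n(total_sugars),
    fiber = rep_n(fiber), polyols = rep_n(polyols), sodium = rep_n(sodium),
    claims = rep(list(character()), n),
    ingredients_text = rep_n(ingredients_text)
  )
}

# Wrap a set of records as a one-row groups tibble (all records one group).
as_single_group <- function(records, generic_name = "Bar") {
  tibble::tibble(
    generic_name = generic_name,
    category = records$category[1], subcategory = records$subcategory[1],
    group = records$group[1], subgroup = records$subgroup[1],
    basis = records$basis[1],
    descriptors = list(stats::setNames(character(0), character(0))),
    member_ids = list(records$product_id),
    n = nrow(records), provenance = "step1", inherent_heterogeneity = FALSE
  )
}

# Independent two-pass statistics used as oracles: never call package code.
naive_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}
naive_sd <- function(x) {
  if (length(x) < 2) {
    return(NA_real_)
  }
  m <- naive_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}
naive_cv <- function(x) {
  m <- naive_mean(x)
  s <- naive_sd(x)
  if (is.na(s)) {
    return(NA_real_)
  }
  if (m > 0) {
    return(s / m)
  }
  if (s == 0) {
    return(0)
  }
  NA_real_
}

# Largest trigger-nutrient CV of a member subset, by the naive route
# (Inf when undefined), mirroring the acceptance rule's quantity.
naive_max_cv <- function(members) {
  trig <- trigger_nutrients()
  complete <- rep(TRUE, nrow(members))
  for (nut in trig) complete <- complete & !is.na(members[[nut]])
  cm <- members[complete, , drop = FALSE]
  if (nrow(cm) < 2) {
    return(Inf)
  }
  worst <- 0
  for (nut in trig) {
    cv <- naive_cv(cm[[nut]])
    if (is.na(cv)) {
      return(Inf)
    }
    worst <- max(worst, cv)
  }
  worst
}

qc_reason_string <- function(results) {
  vapply(results$reasons, paste, character(1), collapse = ";")
}
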