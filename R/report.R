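#' Generic-name yield per food category
#'
#' For each category: number of products grouped, number of generic names,
#' and how many names are populated by 1, 2 or >= 3 products, plus a totals
#' row. Per row, `names_1 + names_2 + names_ge3 = n_generic_names`.
#'
#' @param groups Final groups tibble.
#' @param digits Optional decimal places for percentage columns (none here;
#'   kept for interface symmetry).
#' @return Tibble with one row per category and a `"Total"` row.
#' @export
yield_table <- function(groups, digits = NULL) {
  per_cat <- groups |>
    group_by(category) |>
    summarise(
      n_products = sum(n),
      n_generic_names = dplyr::n(),
      names_1 = sum(n == 1),
      names_2 = sum(n == 2),
      names_ge3 = sum(n >= 3),
      .groups = "drop"
    ) |>
    arrange(category)
  total <- per_cat |>
    summarise(
      category = "Total",
      n_products = sum(n_products),
      n_generic_names = sum(n_generic_names),
      names_1 = sum(names_1),
      names_2 = sum(names_2),
      names_ge3 = sum(names_ge3)
    )
  bind_rows(per_cat, total)
}

#' Aggregation capacity per food category
#'
#' Percentage of products per category (and overall) that fall under generic
#' names populated by at least three products, plus the category "reduction"
#' (how much the product list shrinks when replaced by generic names):
#' `100 * (1 - names/products)`.
#'
#' @param groups Final groups tibble.
#' @param min_n Group size counting as "aggregated" (default 3).
#' @param digits Optional decimal places for the percentage columns
#'   (default: full precision).
#' @return Tibble with one row per category and an `"Overall"` row:
#'   `n_products`, `n_in_ge3`, `capacity_pct`, `reduction_pct`.
#' @export
aggregation_capacity <- function(groups, min_n = 3, digits = NULL) {
  per_cat <- groups |>
    group_by(category) |>
    summarise(
      n_products = sum(n),
      n_generic_names = dplyr::n(),
      n_in_ge3 = sum(n[n >= min_n]),
      .groups = "drop"
    ) |>
    arrange(category)
  overall <- per_cat |>
    summarise(
      category = "Overall",
      n_products = sum(n_products),
      n_generic_names = sum(n_generic_names),
      n_in_ge3 = sum(n_in_ge3)
    )
  out <- bind_rows(per_cat, overall) |>
    mutate(
      capacity_pct = 100 * n_in_ge3 / n_products,
      reduction_pct = 100 * (1 - n_generic_names / n_products)
    )
  if (!is.null(digits)) {
    out <- mutate(out, across(c(capacity_pct, reduction_pct), ~ round(.x, digits)))
  }
  out
}

#' CV-grade distribution per nutrient
#'
#' For each graded nutrient, the percentage of aggregated values per CV grade
#' (`lt20`, `between20and40`, `ge40`, plus `undefined`), over the profiles
#' supplied (normally the value-emitting groups). Percentages sum to 100 per
#' nutrient; raw counts are included alongside.
#'
#' @param profiles Long profiles tibble (value-emitting groups).
#' @param digits Optional decimal places for the `pct` column.
#' @return Tibble: `nutrient`, `grade`, `count`, `pct`.
#' @export
cv_grade_distribution <- function(profiles, digits = NULL) {
  graded <- profiles[!is.na(profiles$grade), , drop = FALSE]
  if (nrow(graded) == 0) {
    return(tibble(
      nutrient = character(), grade = character(),
      count = integer(), pct = double()
    ))
  }
  out <- graded |>
    mutate(
      nutrient = factor(nutrient, levels = PROFILE_NUTRIENTS),
      grade = factor(grade, levels = CV_GRADES)
    ) |>
    count(nutrient, grade, name = "count", .drop = FALSE) |>
    group_by(nutrient) |>
    mutate(pct = 100 * count / sum(count)) |>
    ungroup() |>
    filter(as.character(nutrient) %in% unique(graded$nutrient)) |>
    mutate(nutrient = as.character(nutrient), grade = as.character(grade))
  if (!is.null(digits)) {
    out <- mutate(out, pct = round(pct, digits))
  }
  out
}

#' Highly heterogeneous values by nutrient and category
#'
#' Contingency counts of groups whose aggregated value is graded `ge40`
#' (CV >= 40%), by nutrient and food category. Row sums per nutrient equal
#' the `ge40` counts of [cv_grade_distribution()] on the same profiles.
#'
#' @param profiles Long profiles tibble (value-emitting groups).
#' @param groups Final groups tibble (to map generic names to categories).
#' @return Tibble: `nutrient`, `category`, `count` (zero rows included for
#'   every nutrient-by-category combination present in the inputs).
#' @export
heterogeneity_by_category <- function(profiles, groups) {
  cats <- sort(unique(groups$category))
  nuts <- intersect(PROFILE_NUTRIENTS, unique(profiles$nutrient[!is.na(profiles$grade)]))
  if (length(cats) == 0 || length(nuts) == 0) {
    return(tibble(nutrient = character(), category = character(), count = integer()))
  }
  hot <- profiles |>
    filter(!is.na(grade), grade == "ge40") |>
    left_join(
      distinct(groups, generic_name, category),
      by = "generic_name"
    )
  tidyr::expand_grid(nutrient = nuts, category = cats) |>
    left_join(
      count(hot, nutrient, category, name = "count"),
      by = c("nutrient", "category")
    ) |>
    mutate(count = ifelse(is.na(count), 0L, count))
}
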