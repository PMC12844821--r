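#' Read a branded food composition database from its multi-file layout
#'
#' The database layout mirrors common BFCD distributions: a description file
#' (one row per product: id, long name, 4-level category path, declaration
#' basis), a nutrients file (label-declared values per 100 g or 100 mL),
#' a claims file (one row per claim) and an ingredients file (free-text
#' ingredient list). An allergens file, if supplied, is accepted and ignored:
#' the aggregation framework never consults it. Auxiliary rows whose
#' product_id does not appear in the description file are dropped with a
#' warning. Missing nutrient cells stay missing — nothing is imputed at the
#' I/O layer.
#'
#' @param description_path CSV with columns `product_id`, `long_name`,
#'   `category`, `subcategory`, `group`, `subgroup`; optional `basis`
#'   (`per_100g`/`per_100mL`, defaults to `per_100g` with a warning when the
#'   column is absent) and optional `image_complete` (pass-through curation
#'   flag consumed by the QC step).
#' @param nutrients_path CSV with `product_id` plus the nine nutrient columns
#'   `energy` (kcal), `protein`, `total_fat`, `sfa`, `carbohydrate`,
#'   `total_sugars`, `fiber`, `polyols` (g) and `sodium` (mg), all per
#'   100 g/mL; empty cells mean "not declared".
#' @param claims_path Optional CSV with `product_id`, `claim_text`.
#' @param ingredients_path Optional CSV with `product_id`, `ingredients_text`.
#' @param allergens_path Optional; read for layout compatibility, ignored.
#' @param delim Field delimiter (default comma). Decimal points are required
#'   regardless of delimiter.
#' @return A records tibble, one row per description row in file order:
#'   identity and category columns, `basis`, nutrient columns, `claims`
#'   (list-column of character vectors) and `ingredients_text`.
#' @export
read_bfcd <- function(description_path, nutrients_path,
                      claims_path = NULL, ingredients_path = NULL,
                      allergens_path = NULL, delim = ",") {
  desc <- read_table_chr(description_path, delim)
  need <- c("product_id", "long_name", "category", "subcategory", "group", "subgroup")
  missing_cols <- setdiff(need, names(desc))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "description file is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(desc$product_id)) {
    abort(paste0(
      "duplicate product_id in description file: ",
      desc$product_id[duplicated(desc$product_id)][1]
    ))
  }
  if (any(is.na(desc$long_name) | !nzchar(desc$long_name))) {
    abort("description file has rows with an empty long_name")
  }
  check_category_path(desc)
  if (!"basis" %in% names(desc)) {
    warn("description file has no 'basis' column; assuming per_100g for all products")
    desc$basis <- "per_100g"
  } else {
    desc$basis[is.na(desc$basis) | !nzchar(desc$basis)] <- "per_100g"
    bad <- setdiff(unique(desc$basis), c("per_100g", "per_100mL"))
    if (length(bad) > 0) {
      abort(paste0("unknown basis value(s): ", paste(bad, collapse = ", ")))
    }
  }
  if ("image_complete" %in% names(desc)) {
    desc$image_complete <- parse_logical_col(desc$image_complete, "image_complete")
  }

  nut <- read_table_chr(nutrients_path, delim)
  if (!"product_id" %in% names(nut)) {
    abort("nutrients file is missing mandatory column: product_id")
  }
  missing_nut <- setdiff(BFCD_NUTRIENTS, names(nut))
  if (length(missing_nut) > 0) {
    abort(paste0(
      "nutrients file is missing mandatory column(s): ",
      paste(missing_nut, collapse = ", ")
    ))
  }
  nut <- drop_orphans(nut, desc$product_id, "nutrients")
  if (anyDuplicated(nut$product_id)) {
    abort(paste0(
      "duplicate product_id in nutrients file: ",
      nut$product_id[duplicated(nut$product_id)][1]
    ))
  }
  for (col in BFCD_NUTRIENTS) {
    nut[[col]] <- parse_nutrient_col(nut[[col]], col, nut$product_id)
  }

  out <- left_join(desc, nut[, c("product_id", BFCD_NUTRIENTS)], by = "product_id")

  claims_map <- rep(list(character()), nrow(out))
  if (!is.null(claims_path)) {
    cl <- read_table_chr(claims_path, delim)
    if (!all(c("product_id", "claim_text") %in% names(cl))) {
      abort("claims file must have columns product_id, claim_text")
    }
    cl <- drop_orphans(cl, desc$product_id, "claims")
    cl <- cl[!is.na(cl$claim_text) & nzchar(cl$claim_text), , drop = FALSE]
    by_id <- split(cl$claim_text, cl$product_id)
    pos <- match(names(by_id), out$product_id)
    claims_map[pos] <- unname(by_id)
  }
  out$claims <- claims_map

  out$ingredients_text <- NA_character_
  if (!is.null(ingredients_path)) {
    ing <- read_table_chr(ingredients_path, delim)
    if (!all(c("product_id", "ingredients_text") %in% names(ing))) {
      abort("ingredients file must have columns product_id, ingredients_text")
    }
    ing <- drop_orphans(ing, desc$product_id, "ingredients")
    pos <- match(ing$product_id, out$product_id)
    out$ingredients_text[pos] <- ing$ingredients_text
  }

  if (!is.null(allergens_path) && file.exists(allergens_path)) {
    invisible(read_table_chr(allergens_path, delim)) # layout compatibility only
  }
  out
}

read_table_chr <- function(path, delim) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path))
  }
  readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
}

check_category_path <- function(desc) {
  lvl <- cbind(desc$category, desc$subcategory, desc$group, desc$subgroup)
  filled <- !is.na(lvl) & nzchar(lvl)
  if (any(!filled[, 1])) {
    abort("description file has rows with an empty category")
  }
  # levels must be non-empty from the left: no gaps in the hierarchy
  gap <- (!filled[, 2] & (filled[, 3] | filled[, 4])) | (!filled[, 3] & filled[, 4])
  if (any(gap)) {
    abort(paste0(
      "category path has a gap (empty level above a filled one) for product ",
      desc$product_id[gap][1]
    ))
  }
  invisible(TRUE)
}

parse_nutrient_col <- function(x, col, ids) {
  x <- stringi::stri_trim_both(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  val <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(val)
  if (any(bad)) {
    abort(paste0(
      "non-numeric value '", x[bad][1], "' in nutrients column '", col,
      "' for product ", ids[bad][1]
    ))
  }
  if (any(val < 0, na.rm = TRUE)) {
    abort(paste0(
      "negative value in nutrients column '", col, "' for product ",
      ids[which(val < 0)][1]
    ))
  }
  val
}

parse_logical_col <- function(x, col) {
  val <- toupper(stringi::stri_trim_both(x)) %in% c("TRUE", "T", "1", "YES")
  val[is.na(x)] <- NA
  val
}

drop_orphans <- function(tbl, known_ids, what) {
  orphan <- !tbl$product_id %in% known_ids
  if (any(orphan)) {
    warn(paste0(
      sum(orphan), " row(s) in the ", what,
      " file reference unknown product_id(s) and were dropped (e.g. ",
      tbl$product_id[orphan][1], ")"
    ))
  }
  tbl[!orphan, , drop = FALSE]
}

#' Write the derived generic food composition database
#'
#' One row per generic food group: name, category path, membership counts and
#' per-nutrient mean/SD/CV/grade taken from the supplied profiles. Groups
#' without a profile (e.g. fewer complete members than the minimum group size
#' for value emission) keep their identity row but get the `NA` sentinel in
#' every statistic cell. The companion [read_generic_fcd()] restores an
#' equal structure.
#'
#' @param groups Groups tibble (see [group_step1()] / [aggregate_pipeline()]).
#' @param profiles Long profiles tibble (see [summarize_group()]); every
#'   `generic_name` in it must appear in `groups`, and generic names must be
#'   unique keys.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_generic_fcd <- function(groups, profiles, path) {
  if (anyDuplicated(groups$generic_name)) {
    abort(paste0(
      "generic_name collision: '",
      groups$generic_name[duplicated(groups$generic_name)][1],
      "' — generic names must be unique keys"
    ))
  }
  unknown <- setdiff(unique(profiles$generic_name), groups$generic_name)
  if (length(unknown) > 0) {
    abort(paste0(
      "profiles reference group(s) absent from `groups`: ", unknown[1]
    ))
  }
  flat <- groups |>
    mutate(
      member_ids = map_chr(member_ids, paste, collapse = ";"),
      descriptors = map_chr(descriptors, serialize_assignment)
    )
  if (nrow(profiles) > 0) {
    ncomp <- distinct(profiles, generic_name, n_complete)
    wide <- profiles |>
      select(generic_name, nutrient, mean, sd, cv, grade) |>
      tidyr::pivot_wider(
        names_from = nutrient,
        values_from = c(mean, sd, cv, grade),
        names_glue = "{nutrient}_{.value}"
      )
    flat <- flat |>
      left_join(ncomp, by = "generic_name") |>
      left_join(wide, by = "generic_name")
  } else {
    flat$n_complete <- NA_integer_
  }
  stat_cols <- as.vector(t(outer(
    PROFILE_NUTRIENTS, c("mean", "sd", "cv", "grade"), paste, sep = "_"
  )))
  for (col in stat_cols) {
    if (!col %in% names(flat)) {
      flat[[col]] <- if (grepl("_grade$", col)) NA_character_ else NA_real_
    }
  }
  flat <- flat[, c(
    "generic_name", "category", "subcategory", "group", "subgroup", "basis",
    "n", "n_complete", "provenance", "inherent_heterogeneity",
    "member_ids", "descriptors", stat_cols
  )]
  readr::write_csv(flat, path, na = "NA")
  invisible(path)
}

#' Read a generic food composition database written by [write_generic_fcd()]
#'
#' @param path CSV path.
#' @return List with `groups` (tibble as produced by the pipeline) and
#'   `profiles` (long tibble restricted to groups that carry emitted values).
#' @export
read_generic_fcd <- function(path) {
  flat <- readr::read_csv(
    path,
    col_types = readr::cols(
      n = readr::col_integer(), n_complete = readr::col_integer(),
      inherent_heterogeneity = readr::col_logical(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  stat_num <- as.vector(t(outer(
    PROFILE_NUTRIENTS, c("mean", "sd", "cv"), paste, sep = "_"
  )))
  for (col in stat_num) flat[[col]] <- as.numeric(flat[[col]])
  groups <- flat |>
    mutate(
      member_ids = map(member_ids, function(x) strsplit(x, ";", fixed = TRUE)[[1]]),
      descriptors = map(descriptors, deserialize_assignment)
    ) |>
    select(
      generic_name, category, subcategory, group, subgroup, basis,
      descriptors, member_ids, n, provenance, inherent_heterogeneity
    )
  emitted <- flat[!is.na(flat$n_complete), , drop = FALSE]
  profiles <- if (nrow(emitted) == 0) {
    empty_profiles_tbl()
  } else {
    bind_rows(lapply(seq_len(nrow(emitted)), function(i) {
      row <- emitted[i, ]
      tibble(
        generic_name = row$generic_name,
        n_complete = row$n_complete,
        nutrient = PROFILE_NUTRIENTS,
        mean = as.numeric(row[paste0(PROFILE_NUTRIENTS, "_mean")]),
        sd = as.numeric(row[paste0(PROFILE_NUTRIENTS, "_sd")]),
        cv = as.numeric(row[paste0(PROFILE_NUTRIENTS, "_cv")]),
        grade = as.character(row[paste0(PROFILE_NUTRIENTS, "_grade")])
      )
    }))
  }
  list(groups = groups, profiles = profiles)
}

empty_profiles_tbl <- function() {
  tibble(
    generic_name = character(), n_complete = integer(), nutrient = character(),
    mean = double(), sd = double(), cv = double(), grade = character()
  )
}
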