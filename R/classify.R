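#' Normalize free text for descriptor matching
#'
#' Lower-cases, folds accents/diacritics (Unicode NFD decomposition with
#' combining marks removed, so Greek and Latin accented characters match
#' unaccented patterns), and collapses punctuation to single spaces. The `%`
#' sign is kept because fat-content descriptors use it.
#'
#' @param x Character vector.
#' @return Normalized character vector (NA preserved).
#' @export
normalize_text <- function(x) {
  out <- stringi::stri_trans_general(x, "NFD")
  out <- stringi::stri_replace_all_regex(out, "\\p{Mn}+", "")
  out <- stringi::stri_trans_general(out, "NFC")
  out <- stringi::stri_trans_tolower(out)
  out <- stringi::stri_replace_all_regex(out, "[^\\p{L}\\p{N}%]+", " ")
  stringi::stri_trim_both(out)
}

# Match one dimension against normalized text. Returns list(value, matched):
# `matched` holds every descriptor value with at least one matching pattern
# (vocabulary order); `value` is the winner (first in vocabulary order) or the
# dimension default or NA. Within a value, longer patterns are tried first.
match_dimension <- function(dimension, text_norm) {
  if (is.na(text_norm) || !nzchar(text_norm)) {
    return(list(value = dimension$default %||% NA_character_, matched = character()))
  }
  matched <- character()
  for (v in dimension$values) {
    pats <- v$patterns[order(-nchar(v$patterns))]
    hit <- FALSE
    for (p in pats) {
      if (stringi::stri_detect_regex(text_norm, p)) {
        hit <- TRUE
        break
      }
    }
    if (hit) matched <- c(matched, v$value)
  }
  value <- if (length(matched) > 0) matched[1] else dimension$default %||% NA_character_
  list(value = value, matched = matched)
}

#' Parse descriptor values from a single product record
#'
#' Applies a category's dimensions of one tier to a record: primary-tier
#' dimensions are matched against the normalized long name, secondary-tier
#' dimensions against the normalized concatenation of the ingredient list and
#' claims. For each dimension the first descriptor value (in vocabulary
#' order) with a matching pattern wins; ties within a dimension (several
#' values matching) are recorded as conflicts. Unmatched dimensions take the
#' dimension's default value, or are omitted from the assignment.
#'
#' @param record A one-row tibble (or list) with at least `long_name` and
#'   `category`; `ingredients_text` and `claims` are used for the secondary
#'   tier.
#' @param vocabulary A `descriptor_vocabulary`.
#' @param tier `"primary"` (default) or `"secondary"`.
#' @return Named character vector mapping dimension name to descriptor value,
#'   with a `conflicts` attribute: a tibble of (dimension, values) for
#'   dimensions where several values matched.
#' @export
parse_descriptors <- function(record, vocabulary, tier = "primary") {
  record <- as.list(record)
  dims <- vocab_dimensions(vocabulary, record$category[[1]], tier = tier)
  text <- if (tier == "primary") {
    record$long_name[[1]]
  } else {
    secondary_text(record$ingredients_text[[1]] %||% NA_character_, record$claims[[1]])
  }
  text_norm <- normalize_text(text)
  assignment <- character()
  conflicts <- list()
  for (d in dims) {
    m <- match_dimension(d, text_norm)
    if (!is.na(m$value)) {
      assignment[[d$name]] <- m$value
    }
    if (length(m$matched) > 1) {
      conflicts[[length(conflicts) + 1]] <-
        tibble(dimension = d$name, values = paste(m$matched, collapse = "; "))
    }
  }
  structure(assignment, conflicts = bind_rows(conflicts))
}

secondary_text <- function(ingredients_text, claims) {
  claims <- unlist(claims %||% character())
  parts <- c(
    if (!is.na(ingredients_text)) ingredients_text else character(),
    claims
  )
  if (length(parts) == 0) NA_character_ else paste(parts, collapse = " ; ")
}

#' Flag multipack products
#'
#' Products whose long name indicates a multipack of different foods (combo
#' packs etc.) cannot be aggregated into a single generic food and are set
#' aside before grouping. Detection uses the vocabulary's
#' `multipack_patterns` on the normalized long name only.
#'
#' @param records A records tibble (see [read_bfcd()]).
#' @param vocabulary A `descriptor_vocabulary`.
#' @return List with `eligible` (records tibble, input order preserved) and
#'   `multipack_ids` (character vector of flagged product ids). The two
#'   partition the input.
#' @export
flag_multipacks <- function(records, vocabulary) {
  if (nrow(records) == 0 || length(vocabulary$multipack_patterns) == 0) {
    return(list(eligible = records, multipack_ids = character()))
  }
  names_norm <- normalize_text(records$long_name)
  flagged <- rep(FALSE, nrow(records))
  for (p in vocabulary$multipack_patterns) {
    flagged <- flagged | stringi::stri_detect_regex(names_norm, p)
  }
  list(
    eligible = records[!flagged, , drop = FALSE],
    multipack_ids = records$product_id[flagged]
  )
}

#' Build a canonical generic food name
#'
#' The generic name is the record's subgroup (the most specific hierarchy
#' level) followed by the assigned descriptor values in the vocabulary's
#' dimension order, comma-joined — e.g. `"Yogurt, cow, strained, 0% fat,
#' plain"`. Dimensions absent from the assignment (or assigned NA by an
#' unmatched secondary split) are skipped, so identical assignments always
#' produce identical strings regardless of insertion order.
#'
#' @param category_path Character vector `(category, subcategory, group,
#'   subgroup)`; the last non-empty level is the base term.
#' @param descriptor_assignment Named character vector (dimension -> value).
#' @param vocabulary A `descriptor_vocabulary`.
#' @return A single string.
#' @export
build_generic_name <- function(category_path, descriptor_assignment, vocabulary) {
  category_path <- as.character(category_path)
  nonempty <- category_path[!is.na(category_path) & nzchar(category_path)]
  base <- nonempty[length(nonempty)]
  dim_order <- vocab_dimension_names(vocabulary, category_path[1])
  ordered_dims <- c(intersect(dim_order, names(descriptor_assignment)),
                    setdiff(names(descriptor_assignment), dim_order))
  vals <- descriptor_assignment[ordered_dims]
  vals <- vals[!is.na(vals)]
  paste(c(base, unname(vals)), collapse = ", ")
}

# Serialize an assignment deterministically (used as part of group keys and
# in the generic FCD output). NA values serialize as "dim=".
serialize_assignment <- function(assignment) {
  if (length(assignment) == 0) {
    return("")
  }
  vals <- ifelse(is.na(assignment), "", assignment)
  paste(paste0(names(assignment), "=", vals), collapse = "; ")
}

deserialize_assignment <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(character(0))
  }
  parts <- strsplit(x, "; ", fixed = TRUE)[[1]]
  kv <- stringi::stri_split_fixed(parts, "=", n = 2L)
  vals <- vapply(kv, function(p) p[2], character(1))
  vals[!nzchar(vals)] <- NA_character_
  setNames(vals, vapply(kv, function(p) p[1], character(1)))
}

#' Step 1: partition records into candidate generic food groups
#'
#' Records are partitioned by category path, declaration basis and the
#' primary descriptor assignment parsed from their long names. Basis is part
#' of the key so per-100 g and per-100 mL declarations never aggregate
#' together. Every record lands in exactly one group; group membership
#' preserves input record order.
#'
#' @param records Records tibble (QC-included and multipack-eligible).
#' @param vocabulary A `descriptor_vocabulary`.
#' @return A groups tibble: `generic_name`, the four category-path columns,
#'   `basis`, `descriptors` (list of named character vectors), `member_ids`
#'   (list of character vectors), `n`, `provenance` (`"step1"`),
#'   `inherent_heterogeneity` (FALSE). Carries a `conflicts` attribute tibble
#'   (product_id, dimension, values) logging multi-value matches.
#' @export
group_step1 <- function(records, vocabulary) {
  if (nrow(records) == 0) {
    return(empty_groups_tbl())
  }
  conflicts <- list()
  assignments <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    a <- parse_descriptors(records[i, ], vocabulary, tier = "primary")
    cf <- attr(a, "conflicts")
    if (!is.null(cf) && nrow(cf) > 0) {
      conflicts[[length(conflicts) + 1]] <-
        mutate(cf, product_id = records$product_id[i], .before = 1)
    }
    attributes(a) <- list(names = names(a))
    assignments[[i]] <- a
  }
  key <- paste(
    records$category, records$subcategory, records$group, records$subgroup,
    records$basis, vapply(assignments, serialize_assignment, character(1)),
    sep = "\x1f"
  )
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(ii) {
    r1 <- records[ii[1], ]
    assignment <- assignments[[ii[1]]]
    tibble(
      generic_name = build_generic_name(
        c(r1$category, r1$subcategory, r1$group, r1$subgroup),
        assignment, vocabulary
      ),
      category = r1$category, subcategory = r1$subcategory,
      group = r1$group, subgroup = r1$subgroup, basis = r1$basis,
      descriptors = list(assignment),
      member_ids = list(records$product_id[ii]),
      n = length(ii),
      provenance = "step1",
      inherent_heterogeneity = FALSE
    )
  })
  out <- bind_rows(rows) |>
    arrange(category, subcategory, group, subgroup, basis, generic_name)
  attr(out, "conflicts") <- bind_rows(conflicts)
  out
}

empty_groups_tbl <- function() {
  tibble(
    generic_name = character(), category = character(),
    subcategory = character(), group = character(), subgroup = character(),
    basis = character(), descriptors = list(), member_ids = list(),
    n = integer(), provenance = character(), inherent_heterogeneity = logical()
  )
}
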