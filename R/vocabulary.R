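#' Descriptor vocabularies
#'
#' A descriptor vocabulary defines, per food category, the dimensions along
#' which product names are parsed into generic-food descriptors. Each
#' dimension has a tier: `"primary"` dimensions are matched against the
#' product long name (step 1 of the framework), `"secondary"` dimensions
#' against ingredient lists and on-pack claims (step 3 refinement). Each
#' dimension carries an ordered list of descriptor values with match patterns
#' (regular expressions applied to normalized text, see [normalize_text()]);
#' the first value with a matching pattern wins, and within a value longer
#' patterns are tried first. An optional `default` value is assigned when no
#' pattern matches.
#'
#' The on-disk format is YAML:
#' ```yaml
#' multipack_patterns: ["combo", "variety pack"]
#' categories:
#'   "Milk, milk product or milk substitute":
#'     dimensions:
#'       - name: animal_of_origin
#'         tier: primary
#'         values:
#'           - value: "cow"
#'             patterns: ["cow", "αγελαδ"]
#'         default: ~
#' ```
#'
#' @param path Path to a YAML vocabulary file.
#' @return A `descriptor_vocabulary` object: a list with elements
#'   `categories` (named list of category entries, each with a `dimensions`
#'   list) and `multipack_patterns` (character vector).
#' @seealso [default_vocabulary()] for the vocabulary shipped with the
#'   package's simulator and worked example.
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("vocabulary file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  new_vocabulary(
    categories = raw$categories %||% list(),
    multipack_patterns = as.character(unlist(raw$multipack_patterns %||% character()))
  )
}

#' Write a vocabulary back to YAML
#'
#' @param vocabulary A `descriptor_vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocabulary, path) {
  stopifnot(inherits(vocabulary, "descriptor_vocabulary"))
  yaml::write_yaml(
    list(
      multipack_patterns = vocabulary$multipack_patterns,
      categories = vocabulary$categories
    ),
    path
  )
  invisible(path)
}

#' Construct and validate a vocabulary from R lists
#'
#' @param categories Named list: category name -> list(dimensions = list of
#'   dimension entries). A dimension entry is a list with `name`, `tier`
#'   (`"primary"` or `"secondary"`), `values` (list of `list(value, patterns)`)
#'   and optional `default`.
#' @param multipack_patterns Character vector of regular expressions flagging
#'   multipack products in normalized long names.
#' @return A `descriptor_vocabulary`.
#' @export
new_vocabulary <- function(categories = list(), multipack_patterns = character()) {
  categories <- lapply(categories, validate_category_entry)
  for (cat in names(categories)) {
    dims <- categories[[cat]]$dimensions
    nms <- vapply(dims, function(d) d$name, character(1))
    if (anyDuplicated(nms)) {
      abort(paste0(
        "duplicate dimension name '", nms[duplicated(nms)][1],
        "' in category '", cat, "'"
      ))
    }
  }
  for (p in multipack_patterns) check_pattern(p, where = "multipack_patterns")
  structure(
    list(categories = categories, multipack_patterns = multipack_patterns),
    class = "descriptor_vocabulary"
  )
}

validate_category_entry <- function(entry) {
  dims <- entry$dimensions %||% list()
  entry$dimensions <- lapply(dims, validate_dimension)
  entry
}

validate_dimension <- function(dim) {
  if (is.null(dim$name) || !nzchar(dim$name)) {
    abort("vocabulary dimension without a name")
  }
  if (is.null(dim$tier) || !dim$tier %in% c("primary", "secondary")) {
    abort(paste0(
      "dimension '", dim$name, "': unknown tier '",
      dim$tier %||% "<missing>", "' (must be 'primary' or 'secondary')"
    ))
  }
  if (length(dim$values) < 1) {
    abort(paste0("dimension '", dim$name, "' has no descriptor values"))
  }
  dim$values <- lapply(dim$values, function(v) {
    if (is.null(v$value) || !nzchar(v$value)) {
      abort(paste0("dimension '", dim$name, "': descriptor value without a label"))
    }
    pats <- as.character(unlist(v$patterns %||% character()))
    if (length(pats) < 1) {
      abort(paste0(
        "dimension '", dim$name, "', value '", v$value, "': no match patterns"
      ))
    }
    for (p in pats) {
      check_pattern(p, where = paste0("dimension '", dim$name, "', value '", v$value, "'"))
    }
    list(value = as.character(v$value), patterns = pats)
  })
  vals <- vapply(dim$values, function(v) v$value, character(1))
  if (anyDuplicated(vals)) {
    abort(paste0(
      "dimension '", dim$name, "': duplicate descriptor value '",
      vals[duplicated(vals)][1], "'"
    ))
  }
  dim$default <- if (is.null(dim$default)) NULL else as.character(dim$default)
  dim[c("name", "tier", "values", "default")]
}

check_pattern <- function(pattern, where) {
  ok <- tryCatch(
    {
      suppressWarnings(grepl(pattern, "probe", perl = TRUE))
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) {
    abort(paste0("invalid match pattern '", pattern, "' in ", where))
  }
  invisible(TRUE)
}

#' @export
print.descriptor_vocabulary <- function(x, ...) {
  cat("<descriptor_vocabulary>\n")
  cat("  categories:", length(x$categories), "\n")
  for (cat_name in names(x$categories)) {
    dims <- x$categories[[cat_name]]$dimensions
    tiers <- vapply(dims, function(d) d$tier, character(1))
    cat(
      "   -", cat_name, ":", sum(tiers == "primary"), "primary /",
      sum(tiers == "secondary"), "secondary dimensions\n"
    )
  }
  cat("  multipack patterns:", length(x$multipack_patterns), "\n")
  invisible(x)
}

vocab_category <- function(vocabulary, category) {
  vocabulary$categories[[category]]
}

vocab_dimensions <- function(vocabulary, category, tier = NULL) {
  entry <- vocab_category(vocabulary, category)
  dims <- entry$dimensions %||% list()
  if (!is.null(tier)) {
    dims <- dims[vapply(dims, function(d) d$tier == tier, logical(1))]
  }
  dims
}

# Ordered dimension names for a category (name construction order).
vocab_dimension_names <- function(vocabulary, category) {
  vapply(vocab_dimensions(vocabulary, category), function(d) d$name, character(1))
}
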