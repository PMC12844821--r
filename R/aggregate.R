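#' Aggregation configuration
#'
#' @param cv_heterogeneity_threshold CV fraction above which (strictly) a
#'   trigger nutrient marks a group heterogeneous; default 0.20.
#' @param cv_grade_edges Two increasing edges for the CV grade bands
#'   `[0, e1)`, `[e1, e2)`, `[e2, Inf)`; default `c(0.20, 0.40)`.
#' @param min_group_size_for_values Minimum number of members with complete
#'   trigger-nutrient data for a group to receive aggregated values (and to
#'   be eligible for refinement); default 3. Two-product groups are still
#'   grouped and counted, they just carry no values forward.
#' @param trigger_nutrients Nutrients entering the heterogeneity trigger;
#'   defaults to energy, the macronutrients and sodium. Fiber and polyols are
#'   excluded by default: labels declare them too sparsely to grade.
#' @return An `agg_config` list.
#' @export
agg_config <- function(cv_heterogeneity_threshold = 0.20,
                       cv_grade_edges = c(0.20, 0.40),
                       min_group_size_for_values = 3,
                       trigger_nutrients = TRIGGER_NUTRIENTS) {
  stopifnot(
    cv_heterogeneity_threshold > 0, cv_heterogeneity_threshold < 1,
    length(cv_grade_edges) == 2, diff(cv_grade_edges) > 0,
    min_group_size_for_values >= 2,
    all(trigger_nutrients %in% TRIGGER_NUTRIENTS)
  )
  structure(
    list(
      cv_heterogeneity_threshold = cv_heterogeneity_threshold,
      cv_grade_edges = cv_grade_edges,
      min_group_size_for_values = as.integer(min_group_size_for_values),
      trigger_nutrients = trigger_nutrients
    ),
    class = "agg_config"
  )
}

#' Grade a coefficient of variation
#'
#' Bands are half-open on the left: `[0, 0.20)` is `lt20`, `[0.20, 0.40)` is
#' `between20and40`, `[0.40, Inf)` is `ge40` (edges configurable). `NA`
#' passes through as `"undefined"` (CV not computable: mean zero with
#' positive SD, or fewer than two complete members).
#'
#' @param cv Numeric vector of CV fractions (>= 0 or NA).
#' @param config An [agg_config()].
#' @return Character vector of grades.
#' @export
grade_cv <- function(cv, config = agg_config()) {
  if (any(!is.na(cv) & cv < 0)) {
    abort("negative CV is impossible for nonnegative nutrient values")
  }
  e <- config$cv_grade_edges
  dplyr::case_when(
    is.na(cv) ~ "undefined",
    cv < e[1] ~ "lt20",
    cv < e[2] ~ "between20and40",
    TRUE ~ "ge40"
  )
}

#' Descriptive statistics for one candidate generic food group
#'
#' Computes mean, sample SD (n-1 denominator) and CV = SD/mean per nutrient
#' over the group's *complete* members — those declaring every trigger
#' nutrient — mirroring how homogeneity is assessed on complete entries only.
#' Conventions: CV = 0 when SD = 0 (including the all-zero case 0/0); a zero
#' mean with positive SD, or fewer than two complete members, leaves the CV
#' undefined. Fiber and polyols are carried as means over the complete
#' members that declare them, without CV grades.
#'
#' @param group One-row groups tibble (or list with `member_ids`).
#' @param records Records tibble containing the members.
#' @param config An [agg_config()].
#' @return Long profile tibble: `generic_name`, `n_complete`, `nutrient`,
#'   `mean`, `sd`, `cv`, `grade`.
#' @export
summarize_group <- function(group, records, config = agg_config()) {
  ids <- if (is.data.frame(group)) group$member_ids[[1]] else group$member_ids
  gname <- if (is.data.frame(group)) group$generic_name[[1]] else group$generic_name %||% NA_character_
  members <- records[match(ids, records$product_id), , drop = FALSE]
  profile_from_members(members, gname, config)
}

profile_from_members <- function(members, generic_name, config) {
  trig <- config$trigger_nutrients
  complete <- rep(TRUE, nrow(members))
  for (nut in trig) complete <- complete & !is.na(members[[nut]])
  cm <- members[complete, , drop = FALSE]
  n_complete <- nrow(cm)
  k <- length(PROFILE_NUTRIENTS)
  mean_v <- sd_v <- cv_v <- rep(NA_real_, k)
  grade_v <- rep(NA_character_, k)
  for (j in seq_len(k)) {
    nut <- PROFILE_NUTRIENTS[j]
    graded <- nut %in% trig
    x <- cm[[nut]]
    if (!graded) x <- x[!is.na(x)]
    if (length(x) == 0) {
      if (graded) grade_v[j] <- "undefined"
      next
    }
    m <- mean(x)
    s <- if (length(x) >= 2) sd(x) else NA_real_
    cv <- if (is.na(s)) {
      NA_real_
    } else if (m > 0) {
      s / m
    } else if (s == 0) {
      0 # all members identically zero: homogeneous by convention
    } else {
      NA_real_ # zero mean, positive SD: undefined, treated as heterogeneous
    }
    mean_v[j] <- m
    sd_v[j] <- s
    cv_v[j] <- cv
    if (graded) grade_v[j] <- grade_cv(cv, config)
  }
  tibble(
    generic_name = generic_name, n_complete = n_complete,
    nutrient = PROFILE_NUTRIENTS, mean = mean_v, sd = sd_v, cv = cv_v,
    grade = grade_v
  )
}

#' Is a group's composition heterogeneous?
#'
#' TRUE iff any trigger nutrient has CV strictly above the threshold, or an
#' undefined grade (CV not computable).
#'
#' @param profile A profile tibble from [summarize_group()].
#' @param config An [agg_config()].
#' @return Logical scalar.
#' @export
is_heterogeneous <- function(profile, config = agg_config()) {
  p <- profile[profile$nutrient %in% config$trigger_nutrients, , drop = FALSE]
  any(
    p$grade == "undefined" |
      (!is.na(p$cv) & p$cv > config$cv_heterogeneity_threshold)
  )
}

# Largest CV over the trigger nutrients; Inf when any is undefined so that
# unsplittable/incomputable candidates never look like improvements.
group_max_cv <- function(profile, config) {
  p <- profile[profile$nutrient %in% config$trigger_nutrients, , drop = FALSE]
  if (any(p$grade == "undefined")) {
    return(Inf)
  }
  max(p$cv)
}

#' Step 3: refine a heterogeneous group on secondary descriptors
#'
#' Every secondary-tier dimension of the group's category not already used in
#' its descriptor assignment is evaluated as a candidate split: members are
#' partitioned by the descriptor value matched in their ingredient list and
#' claims (members matching no value form a bucket with value `NA`, omitted
#' from the child's generic name). A candidate is *accepted* when (a) every
#' subgroup has at least two members and (b) the member-weighted mean of the
#' subgroups' largest trigger-nutrient CV is strictly below the parent's
#' largest CV. Among accepted candidates the greatest improvement wins (ties
#' broken by vocabulary dimension order); each heterogeneous subgroup with
#' enough complete members is then refined recursively with the remaining
#' dimensions. If no candidate is accepted the group is returned intact with
#' `inherent_heterogeneity = TRUE` — the heterogeneity is inherent and
#' descriptor identification stops.
#'
#' @param group One-row groups tibble; must be heterogeneous (checked).
#' @param records Records tibble containing the members.
#' @param vocabulary A `descriptor_vocabulary`.
#' @param config An [agg_config()].
#' @return List with `groups` (tibble of final descendants, or the intact
#'   group), `inherent` (TRUE iff no split was applied at the top level) and
#'   `log` (tibble of applied splits: parent, dimension, children, max CV
#'   before/after).
#' @export
refine_group <- function(group, records, vocabulary, config = agg_config()) {
  profile <- summarize_group(group, records, config)
  if (!is_heterogeneous(profile, config)) {
    abort("refine_group() called on a homogeneous group (precondition violation)")
  }
  refine_rec(group, records, vocabulary, config, profile)
}

refine_rec <- function(group, records, vocabulary, config, profile = NULL) {
  if (is.null(profile)) {
    profile <- summarize_group(group, records, config)
  }
  parent_cv <- group_max_cv(profile, config)
  assignment <- group$descriptors[[1]]
  candidates <- vocab_dimensions(vocabulary, group$category, tier = "secondary")
  candidates <- candidates[
    !vapply(candidates, function(d) d$name %in% names(assignment), logical(1))
  ]
  members <- records[match(group$member_ids[[1]], records$product_id), , drop = FALSE]
  texts <- vapply(seq_len(nrow(members)), function(i) {
    normalize_text(secondary_text(members$ingredients_text[i], members$claims[[i]]))
  }, character(1))

  best <- NULL
  for (d in candidates) {
    vals <- vapply(texts, function(tx) match_dimension(d, tx)$value,
                   character(1), USE.NAMES = FALSE)
    if (length(unique(vals)) < 2) next # no split: all members in one bucket
    parts <- split(seq_len(nrow(members)), factor(vals, exclude = NULL))
    if (any(lengths(parts) < 2)) next # rule (a): every subgroup >= 2 members
    sub_cvs <- vapply(parts, function(ii) {
      group_max_cv(
        profile_from_members(members[ii, , drop = FALSE], NA_character_, config),
        config
      )
    }, numeric(1))
    weighted <- sum(sub_cvs * lengths(parts)) / nrow(members)
    improvement <- parent_cv - weighted
    if (!is.finite(improvement) || improvement <= 0) next # rule (b)
    if (is.null(best) || improvement > best$improvement) {
      best <- list(dimension = d, vals = vals, parts = parts,
                   improvement = improvement, weighted = weighted)
    }
  }

  if (is.null(best)) {
    out <- group
    out$inherent_heterogeneity <- TRUE
    return(list(groups = out, inherent = TRUE, log = empty_refinement_log()))
  }

  # value order: dimension's vocabulary order, unmatched bucket last
  value_order <- vapply(best$dimension$values, function(v) v$value, character(1))
  bucket_vals <- names(best$parts)
  bucket_vals[bucket_vals == "NA" & !"NA" %in% best$vals] <- NA_character_
  ord <- order(match(bucket_vals, value_order), na.last = TRUE)

  children <- list()
  logs <- list()
  for (k in ord) {
    ii <- best$parts[[k]]
    child_assignment <- assignment
    child_assignment[[best$dimension$name]] <- bucket_vals[k]
    child <- group
    child$descriptors <- list(child_assignment)
    child$member_ids <- list(members$product_id[ii])
    child$n <- length(ii)
    child$provenance <- "step3_refined"
    child$inherent_heterogeneity <- FALSE
    child$generic_name <- build_generic_name(
      c(group$category, group$subcategory, group$group, group$subgroup),
      child_assignment, vocabulary
    )
    child_profile <- summarize_group(child, records, config)
    if (is_heterogeneous(child_profile, config) &&
        child_profile$n_complete[1] >= config$min_group_size_for_values) {
      res <- refine_rec(child, records, vocabulary, config, child_profile)
      children[[length(children) + 1]] <- res$groups
      logs[[length(logs) + 1]] <- res$log
    } else {
      children[[length(children) + 1]] <- child
    }
  }
  split_log <- tibble(
    parent = group$generic_name,
    dimension = best$dimension$name,
    children = paste(
      vapply(children, function(g) paste(g$generic_name, collapse = " | "), character(1)),
      collapse = " | "
    ),
    max_cv_before = parent_cv,
    weighted_max_cv_after = best$weighted
  )
  list(
    groups = bind_rows(children),
    inherent = FALSE,
    log = bind_rows(c(list(split_log), logs))
  )
}

empty_refinement_log <- function() {
  tibble(
    parent = character(), dimension = character(), children = character(),
    max_cv_before = double(), weighted_max_cv_after = double()
  )
}

#' Run the full three-step aggregation pipeline
#'
#' QC screen -> multipack exclusion -> step-1 name-based grouping -> per-group
#' statistics -> step-3 refinement of heterogeneous groups -> final
#' statistics. Aggregated nutrient values are emitted only for groups whose
#' complete-member count reaches `min_group_size_for_values`; smaller groups
#' are still grouped and counted. Every input record is accounted for exactly
#' once: QC-excluded, multipack, or member of exactly one final group.
#'
#' @param records Records tibble from [read_bfcd()] or [generate_db()].
#' @param vocabulary A `descriptor_vocabulary`.
#' @param qc_config A [qc_config()].
#' @param config An [agg_config()].
#' @return List with `groups` (final groups tibble), `profiles` (long profile
#'   tibble for value-emitting groups) and `report_inputs`: QC results and
#'   reason counts, multipack ids, step-1 classification conflict log,
#'   refinement log, profiles of all final groups, and stage counts.
#' @export
aggregate_pipeline <- function(records, vocabulary,
                               qc_config = foodagg::qc_config(),
                               config = agg_config()) {
  qc <- qc_filter(records, qc_config)
  mp <- flag_multipacks(qc$included, vocabulary)
  step1 <- group_step1(mp$eligible, vocabulary)
  conflicts <- attr(step1, "conflicts") %||% tibble()

  final <- list()
  logs <- list()
  for (i in seq_len(nrow(step1))) {
    g <- step1[i, ]
    profile <- summarize_group(g, mp$eligible, config)
    if (is_heterogeneous(profile, config) &&
        profile$n_complete[1] >= config$min_group_size_for_values) {
      res <- refine_rec(g, mp$eligible, vocabulary, config, profile)
      final[[length(final) + 1]] <- res$groups
      logs[[length(logs) + 1]] <- res$log
    } else {
      final[[length(final) + 1]] <- g
    }
  }
  groups <- if (length(final) > 0) bind_rows(final) else empty_groups_tbl()
  groups <- arrange(
    groups, category, subcategory, group, subgroup, basis, generic_name
  )
  attr(groups, "conflicts") <- NULL # conflicts are reported via report_inputs
  profiles_all <- if (nrow(groups) > 0) {
    bind_rows(lapply(
      seq_len(nrow(groups)),
      function(i) summarize_group(groups[i, ], mp$eligible, config)
    ))
  } else {
    empty_profiles_tbl()
  }
  emit_names <- unique(
    profiles_all$generic_name[
      profiles_all$n_complete >= config$min_group_size_for_values
    ]
  )
  profiles <- profiles_all[profiles_all$generic_name %in% emit_names, , drop = FALSE]
  list(
    groups = groups,
    profiles = profiles,
    report_inputs = list(
      qc_results = qc$results,
      qc_reason_counts = qc$reason_counts,
      multipack_ids = mp$multipack_ids,
      conflict_log = conflicts,
      refinement_log = bind_rows(c(list(empty_refinement_log()), logs)),
      profiles_all = profiles_all,
      counts = list(
        n_input = nrow(records),
        n_qc_excluded = nrow(records) - nrow(qc$included),
        n_multipack = length(mp$multipack_ids),
        n_grouped = nrow(mp$eligible),
        n_groups_step1 = nrow(step1),
        n_groups_final = nrow(groups)
      )
    )
  )
}
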