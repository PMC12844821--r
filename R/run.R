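#' Run the full aggregation workflow on a BFCD directory
#'
#' Reads the multi-file database layout from `input_dir` (description.csv,
#' nutrients.csv and, when present, claims.csv / ingredients.csv /
#' allergens.csv), runs [aggregate_pipeline()] and writes every artifact to
#' `out_dir`:
#'
#' * `generic_fcd.csv` — the derived generic food composition database
#'   ([write_generic_fcd()]; values only for groups with at least
#'   `min_group_size_for_values` complete members),
#' * `groups.csv` / `profiles.csv` — final groups and their full profiles,
#' * `qc_report.csv`, `qc_reason_counts.csv`, `multipacks.csv`,
#' * `refinement_log.csv`, `conflict_log.csv`,
#' * report tables `yield_table.csv`, `aggregation_capacity.csv`,
#'   `cv_grade_distribution.csv`, `heterogeneity_by_category.csv`
#'   (percentages rounded to one decimal, raw counts alongside),
#' * `events.jsonl` — one JSON object per pipeline event (stage counts, every
#'   exclusion and split decision), the machine-readable audit trail.
#'
#' All outputs are deterministic functions of the inputs; nothing in
#' `input_dir` is modified.
#'
#' @param input_dir Directory with the BFCD files.
#' @param vocab_path Path to the YAML descriptor vocabulary.
#' @param out_dir Output directory (created if needed).
#' @param qc QC configuration ([qc_config()]).
#' @param agg Aggregation configuration ([agg_config()]).
#' @param delim Field delimiter of the input files.
#' @return Invisibly, the [aggregate_pipeline()] result.
#' @export
run_all <- function(input_dir, vocab_path, out_dir,
                    qc = qc_config(), agg = agg_config(), delim = ",") {
  p <- function(f) {
    fp <- file.path(input_dir, f)
    if (file.exists(fp)) fp else NULL
  }
  desc <- p("description.csv")
  nut <- p("nutrients.csv")
  if (is.null(desc) || is.null(nut)) {
    abort(paste0(
      "input directory must contain description.csv and nutrients.csv: ",
      input_dir
    ))
  }
  records <- read_bfcd(desc, nut, p("claims.csv"), p("ingredients.csv"),
                       p("allergens.csv"), delim = delim)
  vocabulary <- load_vocabulary(vocab_path)
  res <- aggregate_pipeline(records, vocabulary, qc_config = qc, config = agg)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ri <- res$report_inputs

  write_generic_fcd(res$groups, res$profiles, file.path(out_dir, "generic_fcd.csv"))

  groups_flat <- res$groups |>
    mutate(
      member_ids = map_chr(member_ids, paste, collapse = ";"),
      descriptors = map_chr(descriptors, serialize_assignment)
    )
  readr::write_csv(groups_flat, file.path(out_dir, "groups.csv"), na = "NA")
  readr::write_csv(ri$profiles_all, file.path(out_dir, "profiles.csv"), na = "NA")

  qc_flat <- ri$qc_results |>
    mutate(reasons = map_chr(reasons, paste, collapse = ";"))
  readr::write_csv(qc_flat, file.path(out_dir, "qc_report.csv"), na = "NA")
  readr::write_csv(ri$qc_reason_counts, file.path(out_dir, "qc_reason_counts.csv"))
  readr::write_csv(
    tibble(product_id = ri$multipack_ids),
    file.path(out_dir, "multipacks.csv")
  )
  readr::write_csv(ri$refinement_log, file.path(out_dir, "refinement_log.csv"))
  readr::write_csv(ri$conflict_log, file.path(out_dir, "conflict_log.csv"))

  readr::write_csv(yield_table(res$groups), file.path(out_dir, "yield_table.csv"))
  readr::write_csv(
    aggregation_capacity(res$groups, digits = 1),
    file.path(out_dir, "aggregation_capacity.csv")
  )
  readr::write_csv(
    cv_grade_distribution(res$profiles, digits = 1),
    file.path(out_dir, "cv_grade_distribution.csv")
  )
  readr::write_csv(
    heterogeneity_by_category(res$profiles, res$groups),
    file.path(out_dir, "heterogeneity_by_category.csv")
  )

  events <- c(
    list(list(event = "counts", counts = ri$counts)),
    map(
      ri$qc_results$product_id[ri$qc_results$status == "excluded"],
      function(id) {
        i <- match(id, ri$qc_results$product_id)
        list(
          event = "qc_exclusion", product_id = id,
          reasons = ri$qc_results$reasons[[i]]
        )
      }
    ),
    map(ri$multipack_ids, function(id) list(event = "multipack", product_id = id)),
    map(seq_len(nrow(ri$refinement_log)), function(i) {
      list(
        event = "split",
        parent = ri$refinement_log$parent[i],
        dimension = ri$refinement_log$dimension[i],
        max_cv_before = ri$refinement_log$max_cv_before[i],
        weighted_max_cv_after = ri$refinement_log$weighted_max_cv_after[i]
      )
    })
  )
  writeLines(
    vapply(events, function(e) {
      jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)
    }, character(1)),
    file.path(out_dir, "events.jsonl")
  )
  invisible(res)
}
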