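test_that("summarize_group computes mean, sample SD and CV with conventions", {
  rec <- snack_records(3, protein = c(8, 10, 12))
  prof <- summarize_group(as_single_group(rec), rec)
  p <- prof[prof$nutrient == "protein", ]
  expect_equal(p$mean, 10)
  expect_equal(p$sd, 2)
  expect_equal(p$cv, 0.2)
  expect_equal(p$grade, "between20and40")
  expect_equal(unique(prof$n_complete), 3L)

  # identical members: all CVs zero
  rec2 <- snack_records(4)
  prof2 <- summarize_group(as_single_group(rec2), rec2)
  expect_true(all(prof2$cv[prof2$nutrient %in% trigger_nutrients()] == 0))

  # all-zero sodium: CV 0 by the 0/0 convention, never NaN
  rec3 <- snack_records(3, sodium = 0)
  prof3 <- summarize_group(as_single_group(rec3), rec3)
  s <- prof3[prof3$nutrient == "sodium", ]
  expect_equal(s$cv, 0)
  expect_equal(s$grade, "lt20")

  # incomplete members are excluded from the statistics
  rec4 <- snack_records(4, protein = c(8, 10, 12, 1000))
  rec4$sodium[4] <- NA
  prof4 <- summarize_group(as_single_group(rec4), rec4)
  expect_equal(unique(prof4$n_complete), 3L)
  expect_equal(prof4$mean[prof4$nutrient == "protein"], 10)
  # fiber/polyols carry means but no grades
  expect_true(is.na(prof4$grade[prof4$nutrient == "fiber"]))

  # zero complete members: undefined grades throughout
  rec5 <- snack_records(2)
  rec5$energy <- NA
  prof5 <- summarize_group(as_single_group(rec5), rec5)
  expect_equal(unique(prof5$n_complete), 0L)
  expect_true(all(prof5$grade[prof5$nutrient %in% trigger_nutrients()] == "undefined"))
})

test_that("statistics agree with an independent two-pass oracle", {
  set.seed(99)
  for (rep in seq_len(50)) {
    n <- sample(2:12, 1)
    rec <- snack_records(n,
      protein = runif(n, 0, 30), total_fat = runif(n, 0, 40),
      sfa = runif(n, 0, 20), carbohydrate = runif(n, 0, 80),
      total_sugars = runif(n, 0, 50), sodium = runif(n, 0, 2000),
      energy = runif(n, 10, 800)
    )
    prof <- summarize_group(as_single_group(rec), rec)
    for (nut in trigger_nutrients()) {
      x <- rec[[nut]]
      row <- prof[prof$nutrient == nut, ]
      expect_equal(row$mean, naive_mean(x), tolerance = 1e-12)
      expect_equal(row$sd, naive_sd(x), tolerance = 1e-12)
      expect_equal(row$cv, naive_cv(x), tolerance = 1e-12)
    }
  }
})

test_that("CV grading uses half-open bands with strict boundaries", {
  expect_equal(grade_cv(c(0, 0.19, 0.20, 0.39, 0.40, 2)), c(
    "lt20", "lt20", "between20and40", "between20and40", "ge40", "ge40"
  ))
  expect_equal(grade_cv(NA_real_), "undefined")
  expect_error(grade_cv(-0.1), "negative CV")
})

test_that("the heterogeneity trigger is strict and matches a naive any-loop", {
  config <- agg_config()
  mk_prof <- function(cvs) {
    tibble(
      generic_name = "g", n_complete = 5L, nutrient = trigger_nutrients(),
      mean = 1, sd = cvs, cv = cvs, grade = grade_cv(cvs, config)
    )
  }
  # all CVs exactly at the threshold: NOT heterogeneous ("CV > 20%")
  expect_false(is_heterogeneous(mk_prof(rep(0.20, 7)), config))
  expect_true(is_heterogeneous(mk_prof(c(0.21, rep(0, 6))), config))
  expect_true(is_heterogeneous(mk_prof(c(NA, rep(0, 6))), config))
  set.seed(5)
  for (rep in seq_len(200)) {
    cvs <- runif(7, 0, 0.5)
    naive <- FALSE
    for (cv in cvs) if (cv > 0.2) naive <- TRUE
    expect_equal(is_heterogeneous(mk_prof(cvs), config), naive)
  }
})

test_that("refinement splits on the planted secondary descriptor", {
  vocab <- tiny_vocab()
  rec <- snack_records(
    6,
    total_sugars = c(30, 32, 28, 5, 5.5, 4.5),
    carbohydrate = c(50, 52, 48, 40, 41, 39),
    ingredients_text = c(rep("flour, sugar", 3), rep("flour, stevia", 3))
  )
  rec$energy <- compute_energy(rec)
  groups <- group_step1(rec, vocab)
  expect_equal(nrow(groups), 1)
  res <- refine_group(groups[1, ], rec, vocab)
  expect_false(res$inherent)
  expect_equal(nrow(res$groups), 2)
  expect_true(all(res$groups$provenance == "step3_refined"))
  expect_setequal(
    res$groups$generic_name,
    c("Bar, unsalted, with sugar", "Bar, unsalted, with sweeteners")
  )
  sweet <- res$groups[vapply(
    res$groups$descriptors,
    function(d) identical(unname(d["sweetener"]), "with sweeteners"), logical(1)
  ), ]
  expect_setequal(sweet$member_ids[[1]], rec$product_id[4:6])
  # each refined subgroup is now homogeneous in sugars
  for (i in 1:2) {
    prof <- summarize_group(res$groups[i, ], rec)
    expect_lt(prof$cv[prof$nutrient == "total_sugars"], 0.2)
  }
  # the log records the split and the CV improvement
  expect_equal(res$log$dimension, "sweetener")
  expect_lt(res$log$weighted_max_cv_after, res$log$max_cv_before)

  # descriptor assignments strictly extend the parent's
  parent_dims <- names(groups$descriptors[[1]])
  for (d in res$groups$descriptors) {
    expect_true(all(parent_dims %in% names(d)))
    expect_gt(length(d), length(parent_dims))
  }
})

test_that("refinement stops where no descriptor explains the heterogeneity", {
  vocab <- tiny_vocab()
  # wild sugars but no secondary tokens anywhere: inherent
  rec <- snack_records(4, total_sugars = c(2, 10, 30, 45),
                       ingredients_text = "flour")
  rec$energy <- compute_energy(rec)
  g <- group_step1(rec, vocab)
  res <- refine_group(g[1, ], rec, vocab)
  expect_true(res$inherent)
  expect_true(res$groups$inherent_heterogeneity)
  expect_equal(res$groups$member_ids[[1]], rec$product_id)
  expect_equal(nrow(res$log), 0)

  # a category without secondary dimensions: unchanged, inherent
  vocab2 <- new_vocabulary(list(Snacks = list(dimensions = list(
    list(name = "flavor", tier = "primary",
         values = list(list(value = "chocolate", patterns = "chocolate")))
  ))))
  res2 <- refine_group(g[1, ], rec, vocab2)
  expect_true(res2$inherent)

  # precondition: refining a homogeneous group is a contract violation
  rec3 <- snack_records(4)
  g3 <- group_step1(rec3, vocab)
  expect_error(refine_group(g3[1, ], rec3, vocab), "homogeneous")
})

test_that("splits must leave every subgroup with at least two members", {
  vocab <- tiny_vocab()
  rec <- snack_records(
    5,
    total_sugars = c(30, 32, 28, 31, 4),
    ingredients_text = c(rep("flour, sugar", 4), "flour, stevia")
  )
  rec$energy <- compute_energy(rec)
  g <- group_step1(rec, vocab)
  res <- refine_group(g[1, ], rec, vocab)
  expect_true(res$inherent) # the only candidate strands a singleton
})

test_that("the pipeline conserves records and is idempotent and scale-invariant", {
  cfg <- sim_config(
    seed = 77, n_groups_per_category = 5,
    qc_violation_rates = c(energy_mismatch = 0.08, sfa_gt_fat = 0.03,
                           sugars_gt_carb = 0.03, improbable_value = 0.02),
    multipack_rate = 0.15, latent_split_fraction = 0.5
  )
  db <- generate_db(cfg, withr::local_tempdir())
  res <- aggregate_pipeline(db$records, db$vocabulary)
  ri <- res$report_inputs
  expect_equal(
    sum(ri$qc_results$status == "excluded") + length(ri$multipack_ids) +
      sum(res$groups$n),
    nrow(db$records)
  )
  all_ids <- unlist(res$groups$member_ids)
  expect_false(any(duplicated(all_ids)))
  expect_equal(vapply(res$groups$member_ids, length, integer(1)), res$groups$n)

  # deterministic and idempotent: a second run reproduces the grouping
  res2 <- aggregate_pipeline(db$records, db$vocabulary)
  expect_identical(res2$groups, res$groups)
  expect_identical(res2$profiles, res$profiles)
  # no final group can be split further by its own rules
  for (i in seq_len(nrow(res$groups))) {
    prof <- summarize_group(res$groups[i, ], db$records)
    if (is_heterogeneous(prof) && prof$n_complete[1] >= 3 &&
        !res$groups$inherent_heterogeneity[i]) {
      again <- refine_group(res$groups[i, ], db$records, db$vocabulary)
      expect_true(again$inherent)
    }
  }

  # CV scale invariance: scaling every nutrient leaves CVs and grades alone
  scaled <- db$records
  for (nut in bfcd_nutrients()) scaled[[nut]] <- scaled[[nut]] * 3.7
  g <- res$groups[which(res$groups$n >= 3)[1], ]
  p1 <- summarize_group(g, db$records)
  p2 <- summarize_group(g, scaled)
  expect_equal(p2$cv, p1$cv, tolerance = 1e-12)
  expect_equal(p2$grade, p1$grade)

  # degenerate inputs
  empty <- aggregate_pipeline(db$records[0, ], db$vocabulary)
  expect_equal(nrow(empty$groups), 0)
  expect_equal(nrow(empty$profiles), 0)
})

test_that("two-product groups are counted but never receive values", {
  vocab <- tiny_vocab()
  rec <- snack_records(3, long_name = c("Bar vanilla", "Bar vanilla",
                                        "Bar chocolate"))
  rec$energy <- compute_energy(rec)
  res <- aggregate_pipeline(rec, vocab)
  expect_equal(sort(res$groups$n), c(1L, 2L))
  expect_equal(nrow(res$profiles), 0)
  yt <- yield_table(res$groups)
  expect_equal(yt$names_2[yt$category == "Snacks"], 1)
})
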