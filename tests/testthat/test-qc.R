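profile_row <- function(protein = NA, total_fat = NA, carbohydrate = NA,
                        fiber = NA, polyols = NA) {
  tibble(
    protein = protein, total_fat = total_fat, carbohydrate = carbohydrate,
    fiber = fiber, polyols = polyols
  )
}

test_that("compute_energy applies the Atwater-type factors", {
  expect_equal(
    compute_energy(profile_row(protein = 10, total_fat = 0, carbohydrate = 0)),
    40
  )
  # 5*4 + 2*9 + 20*4 + 3*2 = 124
  expect_equal(
    compute_energy(profile_row(
      protein = 5, total_fat = 2, carbohydrate = 20, fiber = 3, polyols = 0
    )),
    124
  )
  expect_equal(
    compute_energy(profile_row(protein = 0, total_fat = 0, carbohydrate = 0)),
    0
  )
  # polyols counted at 2.4 kcal/g after subtraction from carbohydrate
  expect_equal(
    compute_energy(profile_row(
      protein = 0, total_fat = 0, carbohydrate = 10, polyols = 4
    )),
    4 * 6 + 2.4 * 4
  )
  # toggled off: carbohydrate term not reduced
  expect_equal(
    compute_energy(
      profile_row(protein = 0, total_fat = 0, carbohydrate = 10, polyols = 4),
      qc_config(polyols_within_carbohydrate = FALSE)
    ),
    4 * 10 + 2.4 * 4
  )
  # clamping branch: polyols above carbohydrate
  expect_warning(
    e <- compute_energy(profile_row(
      protein = 0, total_fat = 0, carbohydrate = 2, polyols = 5
    )),
    "clamped"
  )
  expect_equal(e, 2.4 * 5)
  # not computable without the three macros
  expect_true(is.na(compute_energy(profile_row(protein = 10, total_fat = 2))))
})

test_that("qc_screen applies each rule with strict boundaries and skips", {
  # energy mismatch: declared 100 vs calculated 130 -> rel diff 0.30
  r <- snack_records(1, energy = 100, protein = 10, total_fat = 10,
                     carbohydrate = 0, total_sugars = 0, sfa = 5, fiber = 0)
  res <- qc_screen(r)
  expect_equal(res$energy_calculated, 130)
  expect_equal(res$energy_rel_diff, 0.3)
  expect_equal(res$status, "excluded")
  expect_equal(res$reasons[[1]], "energy_mismatch")

  # sfa 5 / fat 4 = 1.25 > 1
  r <- snack_records(1, energy = 81, protein = 2, total_fat = 4, sfa = 5,
                     carbohydrate = 9, total_sugars = 2, fiber = 0)
  expect_equal(qc_screen(r)$reasons[[1]], "sfa_gt_fat")

  # the 124-kcal profile declared exactly: included, reasons empty
  r <- snack_records(1, energy = 124, protein = 5, total_fat = 2, sfa = 1,
                     carbohydrate = 20, total_sugars = 10, fiber = 3,
                     polyols = 0)
  res <- qc_screen(r)
  expect_equal(res$status, "included")
  expect_length(res$reasons[[1]], 0)

  # strict boundaries: rel diff exactly 0.20 and ratios exactly 1 are kept
  r <- snack_records(2,
    energy = c(100, 190), protein = c(20, 5), total_fat = c(0, 10),
    sfa = c(0, 10), carbohydrate = c(0, 20), total_sugars = c(0, 20),
    fiber = 0, sodium = 100
  )
  res <- qc_screen(r)
  expect_equal(res$energy_rel_diff[1], 0.2)
  expect_equal(res$status, c("included", "included"))

  # incomputable checks are skipped, never failed
  r <- snack_records(1, energy = 500, protein = NA, total_fat = 0,
                     carbohydrate = 0, sfa = 0, total_sugars = 0)
  res <- qc_screen(r)
  expect_equal(res$status, "included")
  expect_true(is.na(res$energy_calculated))

  # improbable values (protein above 100 g/100 g, sodium above 40 g/100 g)
  r <- snack_records(2, protein = c(150, 6), sodium = c(300, 50000),
                     energy = c(986, 410))
  res <- qc_screen(r)
  expect_equal(res$reasons[[1]], "improbable_value")
  expect_equal(res$reasons[[2]], "improbable_value")
})

test_that("image-completeness curation flag passes through as a reason", {
  r <- snack_records(2)
  r$image_complete <- c(FALSE, TRUE)
  res <- qc_screen(r)
  expect_equal(res$reasons[[1]], "missing_image_proxy")
  expect_equal(res$status, c("excluded", "included"))
})

test_that("qc_filter is order-stable, deterministic and tolerance-monotone", {
  set.seed(42)
  n <- 60
  r <- snack_records(n,
    protein = runif(n, 2, 20), total_fat = runif(n, 1, 30),
    carbohydrate = runif(n, 5, 70), fiber = runif(n, 0, 6)
  )
  r$sfa <- r$total_fat * runif(n, 0.2, 1.3)
  r$total_sugars <- r$carbohydrate * runif(n, 0.1, 1.2)
  r$energy <- round(compute_energy(r) * runif(n, 0.7, 1.3))

  out <- qc_filter(r)
  expect_equal(
    out$included$product_id,
    r$product_id[r$product_id %in% out$included$product_id]
  )
  expect_equal(nrow(out$results), n)
  expect_equal(
    sum(out$reason_counts$n[out$reason_counts$reason == "energy_mismatch"]),
    sum(vapply(out$results$reasons, function(x) "energy_mismatch" %in% x, logical(1)))
  )

  # permutation invariance of the excluded id set
  perm <- sample(n)
  out_perm <- qc_filter(r[perm, ])
  excl <- function(o) sort(o$results$product_id[o$results$status == "excluded"])
  expect_equal(excl(out_perm), excl(out))

  # raising the tolerance never flips included -> excluded
  loose <- qc_filter(r, qc_config(energy_tolerance = 0.35))
  expect_true(all(excl(loose) %in% excl(out)))

  # degenerate inputs
  empty <- qc_filter(r[0, ])
  expect_equal(nrow(empty$included), 0)
  expect_equal(nrow(empty$results), 0)
  clean <- snack_records(4)
  clean$energy <- compute_energy(clean)
  expect_equal(qc_filter(clean)$included, clean)
})
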