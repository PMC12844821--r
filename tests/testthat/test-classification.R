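test_that("normalize_text lower-cases, folds accents and strips punctuation", {
  expect_equal(normalize_text("Γιαούρτι ΑΓΕΛΆΔΟΣ"), "γιαουρτι αγελαδος")
  expect_equal(normalize_text("Semi-skimmed, 1.5% Fat!"), "semi skimmed 1 5% fat")
  expect_equal(normalize_text("Crème fraîche"), "creme fraiche")
  expect_true(is.na(normalize_text(NA_character_)))
})

test_that("descriptors are parsed from Greek and English long names", {
  vocab <- default_vocabulary()
  milk_path <- c("Milk, milk product or milk substitute", "Dairy products",
                 "Fermented milks", "Yogurt")
  rec <- tibble(
    long_name = "Γιαούρτι αγελάδος στραγγιστό 0% πλαίν",
    category = milk_path[1]
  )
  a <- parse_descriptors(rec, vocab)
  expect_equal(
    a[c("animal_of_origin", "processing", "fat_content", "flavor")],
    c(animal_of_origin = "cow", processing = "strained",
      fat_content = "0% fat", flavor = "plain")
  )
  expect_equal(
    build_generic_name(milk_path, a, vocab),
    "Yogurt, cow, strained, 0% fat, plain"
  )
  # no match in any dimension: empty assignment, name falls back to subgroup
  rec2 <- tibble(long_name = "Mystery dairy item", category = milk_path[1])
  a2 <- parse_descriptors(rec2, vocab)
  expect_length(a2, 0)
  expect_equal(build_generic_name(milk_path, a2, vocab), "Yogurt")
  # semi-skimmed resolves to the 2% value, not to "skimmed"
  rec3 <- tibble(long_name = "Milk semi-skimmed fresh", category = milk_path[1])
  expect_equal(unname(parse_descriptors(rec3, vocab)["fat_content"]), "2% fat")
  rec4 <- tibble(long_name = "Milk skimmed fresh", category = milk_path[1])
  expect_equal(unname(parse_descriptors(rec4, vocab)["fat_content"]), "0% fat")
})

test_that("vocabulary-order tie-breaking matches a brute-force matcher", {
  vocab <- tiny_vocab()
  # "chocolate vanilla" matches both flavor values: earlier in vocabulary
  # order wins and the conflict is logged
  rec <- snack_records(1, long_name = "Bar chocolate vanilla salted")
  a <- parse_descriptors(rec[1, ], vocab)
  expect_equal(unname(a["flavor"]), "chocolate")
  conf <- attr(a, "conflicts")
  expect_equal(conf$dimension, "flavor")
  expect_match(conf$values, "chocolate; vanilla")

  # brute force: apply every pattern of every value by hand on small cases
  dims <- vocab$categories$Snacks$dimensions
  brute <- function(name) {
    text <- normalize_text(name)
    out <- character()
    for (d in dims[vapply(dims, function(d) d$tier == "primary", logical(1))]) {
      hit <- NA_character_
      for (v in d$values) {
        if (any(vapply(v$patterns, function(p) grepl(p, text, perl = TRUE), logical(1)))) {
          hit <- v$value
          break
        }
      }
      if (is.na(hit) && !is.null(d$default)) hit <- d$default
      if (!is.na(hit)) out[[d$name]] <- hit
    }
    out
  }
  for (name in c("Bar chocolate", "choc bar unsalted", "Vanilla salted bar",
                 "plain bar", "Bar vanilla chocolate salted")) {
    rec <- snack_records(1, long_name = name)
    a <- parse_descriptors(rec[1, ], vocab)
    expect_equal(a[order(names(a))], brute(name)[order(names(brute(name)))],
                 info = name)
  }
  # the default value fills unmatched dimensions
  a <- parse_descriptors(snack_records(1, long_name = "Bar vanilla")[1, ], vocab)
  expect_equal(unname(a["salting"]), "unsalted")
})

test_that("generic names are canonical regardless of assignment order", {
  vocab <- tiny_vocab()
  path <- c("Snacks", "Sweet snacks", "Bars", "Bar")
  a1 <- c(flavor = "chocolate", salting = "salted")
  a2 <- c(salting = "salted", flavor = "chocolate")
  expect_equal(build_generic_name(path, a1, vocab),
               build_generic_name(path, a2, vocab))
  expect_equal(build_generic_name(path, a1, vocab), "Bar, chocolate, salted")
  expect_equal(build_generic_name(path, character(), vocab), "Bar")
})

test_that("multipack flagging partitions on long names only", {
  vocab <- tiny_vocab()
  rec <- snack_records(3, long_name = c(
    "ham and cheese combo", "Bread, multigrain, wholegrain, sliced",
    "Bar chocolate"
  ))
  mp <- flag_multipacks(rec, vocab)
  expect_equal(mp$multipack_ids, rec$product_id[1])
  expect_equal(mp$eligible$product_id, rec$product_id[2:3])
  expect_equal(
    sort(c(mp$eligible$product_id, mp$multipack_ids)),
    sort(rec$product_id)
  )
  # empty pattern list: everything is eligible
  mp2 <- flag_multipacks(rec, tiny_vocab(multipack_patterns = character()))
  expect_equal(mp2$eligible, rec)
  expect_length(mp2$multipack_ids, 0)
})

test_that("step-1 grouping is an exact partition with a basis-aware key", {
  vocab <- tiny_vocab()
  rec <- snack_records(6, long_name = c(
    "Bar chocolate", "Bar chocolate", "Bar chocolate salted",
    "Bar vanilla", "Bar vanilla", "Bar chocolate"
  ))
  groups <- group_step1(rec, vocab)
  expect_equal(sum(groups$n), 6)
  expect_equal(nrow(groups), 3)
  all_ids <- unlist(groups$member_ids)
  expect_equal(sort(all_ids), sort(rec$product_id))
  expect_false(any(duplicated(all_ids)))

  # one record -> one singleton group
  single <- group_step1(rec[1, ], vocab)
  expect_equal(single$n, 1L)
  expect_equal(single$provenance, "step1")

  # per-100g and per-100mL never aggregate together
  rec2 <- snack_records(2, long_name = "Bar chocolate")
  rec2$basis <- c("per_100g", "per_100mL")
  expect_equal(nrow(group_step1(rec2, vocab)), 2)

  # determinism: identical inputs give identical names across runs
  expect_identical(group_step1(rec, vocab)$generic_name, groups$generic_name)
  expect_equal(nrow(group_step1(rec[0, ], vocab)), 0)
})

test_that("step-1 grouping recovers the planted structure of a clean database", {
  cfg <- sim_config(
    seed = 303, n_groups_per_category = 4,
    group_size_probs = c("5" = 1), latent_split_fraction = 0,
    qc_violation_rates = c(energy_mismatch = 0, sfa_gt_fat = 0,
                           sugars_gt_carb = 0, improbable_value = 0),
    multipack_rate = 0, missingness = c(energy = 0)
  )
  db <- generate_db(cfg, withr::local_tempdir())
  groups <- group_step1(db$records, db$vocabulary)
  expect_equal(nrow(groups), length(unique(db$truth$true_group)))
  expect_equal(sort(groups$generic_name), sort(unique(db$truth$true_group)))
  # memberships match the truth table exactly
  for (i in seq_len(nrow(groups))) {
    want <- db$truth$product_id[db$truth$true_group %in% groups$generic_name[i]]
    expect_setequal(groups$member_ids[[i]], want)
  }
})
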