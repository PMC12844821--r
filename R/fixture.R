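# Hand-written worked example: 34 branded products across the four built-in
# categories, constructed clean (declared energy equals the Atwater-type
# reconstruction exactly, ratios within limits) with known group structure:
# one latent sweetener split (flavored milk), one inherently heterogeneous
# biscuit group, and groups of size 1, 2 and >=3 in every category.

#' Write the worked-example database
#'
#' A small, fully hand-specified BFCD used in the package documentation and
#' regression tests. Its expected pipeline outputs are committed with the
#' package sources (`inst/extdata/worked_fixture/expected/`).
#'
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
generate_worked_fixture <- function(dir = tempfile("worked_fixture")) {
  milk <- c("Milk, milk product or milk substitute", "Dairy products",
            "Fermented milks", "Yogurt")
  milk2 <- c("Milk, milk product or milk substitute", "Milks",
             "Liquid milks", "Milk")
  grain <- c("Grain or grain product", "Breads", "Leavened breads", "Bread")
  grain2 <- c("Grain or grain product", "Fine bakery wares", "Biscuits",
              "Biscuits")
  fat <- c("Fat or fat product", "Vegetable fats", "Margarines", "Margarine")
  fat2 <- c("Fat or fat product", "Animal fats", "Butters", "Butter")
  veg <- c("Vegetable or vegetable product", "Frozen vegetables",
           "Frozen leaf vegetables", "Spinach")
  veg2 <- c("Vegetable or vegetable product", "Canned vegetables",
            "Canned stem vegetables", "Asparagus")

  g <- function(ids, name_stub, path, basis, protein, total_fat, sfa,
                carbohydrate, total_sugars, fiber, sodium, ingredients) {
    n <- length(ids)
    tibble(
      product_id = sprintf("WF%03d", ids),
      long_name = paste(name_stub, "brand", ids),
      category = path[1], subcategory = path[2], group = path[3],
      subgroup = path[4], basis = basis,
      protein = protein, total_fat = total_fat, sfa = sfa,
      carbohydrate = carbohydrate, total_sugars = total_sugars,
      fiber = fiber, polyols = rep(0, n), sodium = sodium,
      ingredients_text = ingredients
    )
  }

  records <- bind_rows(
    # G1: homogeneous strained yogurt, n = 4
    g(1:4, "Yogurt cow strained 0% fat plain", milk, "per_100g",
      protein = c(10, 10.2, 9.8, 10), total_fat = rep(0.2, 4),
      sfa = rep(0.1, 4), carbohydrate = c(4, 4.1, 3.9, 4),
      total_sugars = c(4, 4.1, 3.9, 4), fiber = rep(0, 4),
      sodium = c(50, 52, 48, 50), ingredients = "milk, lactic cultures"),
    # G2: flavored milk with a latent sweetener split, n = 3 + 3
    g(5:7, "Milk cow pasteurized full fat chocolate", milk2, "per_100mL",
      protein = c(3.3, 3.4, 3.2), total_fat = c(3.5, 3.6, 3.4),
      sfa = c(2.2, 2.3, 2.1), carbohydrate = c(13, 13.5, 12.5),
      total_sugars = c(12, 12.5, 11.5), fiber = rep(0, 3),
      sodium = c(45, 46, 44), ingredients = "milk, cocoa, sugar"),
    g(8:10, "Milk cow pasteurized full fat chocolate", milk2, "per_100mL",
      protein = c(3.3, 3.4, 3.2), total_fat = c(3.5, 3.6, 3.4),
      sfa = c(2.2, 2.3, 2.1), carbohydrate = c(5, 5.2, 4.8),
      total_sugars = c(4, 4.2, 3.8), fiber = rep(0, 3),
      sodium = c(45, 46, 44),
      ingredients = "milk, cocoa, sweeteners (stevia)"),
    # G3, G4: singleton and pair yogurts
    g(11, "Yogurt sheep plain", milk, "per_100g",
      protein = 5.5, total_fat = 6, sfa = 4, carbohydrate = 4.5,
      total_sugars = 4.5, fiber = 0, sodium = 55,
      ingredients = "milk, lactic cultures"),
    g(12:13, "Yogurt goat plain", milk, "per_100g",
      protein = c(4, 4.1), total_fat = c(4.5, 4.4), sfa = c(3, 2.9),
      carbohydrate = c(4.2, 4.3), total_sugars = c(4.2, 4.3),
      fiber = c(0, 0), sodium = c(50, 52),
      ingredients = "milk, lactic cultures"),
    # G5: homogeneous bread, n = 5
    g(14:18, "Bread multigrain wholegrain sliced", grain, "per_100g",
      protein = c(9, 9.2, 8.8, 9.1, 8.9), total_fat = c(4, 4.1, 3.9, 4, 4),
      sfa = rep(1.2, 5), carbohydrate = c(45, 46, 44, 45.5, 44.5),
      total_sugars = c(3.6, 3.7, 3.5, 3.6, 3.6), fiber = c(4, 4.1, 3.9, 4, 4),
      sodium = c(450, 455, 445, 450, 450),
      ingredients = "flour, water, yeast, salt"),
    # G6: inherently heterogeneous biscuits (wild sugar range, no secondary
    # tokens in the ingredient list), n = 3
    g(19:21, "Biscuits wheat plain", grain2, "per_100g",
      protein = rep(7, 3), total_fat = c(18, 18.2, 17.8), sfa = rep(9, 3),
      carbohydrate = c(62, 63, 61), total_sugars = c(10, 25, 40),
      fiber = rep(3, 3), sodium = rep(350, 3),
      ingredients = "flour, vegetable fat, raising agents"),
    # G7, G8: singleton and pair breads
    g(22, "Bread rye loaf", grain, "per_100g",
      protein = 8, total_fat = 2, sfa = 0.4, carbohydrate = 48,
      total_sugars = 3, fiber = 6, sodium = 430,
      ingredients = "rye flour, water, yeast, salt"),
    g(23:24, "Bread wheat wholegrain rusks", grain, "per_100g",
      protein = c(11, 11.2), total_fat = c(5, 5.1), sfa = c(1.5, 1.5),
      carbohydrate = c(60, 61), total_sugars = c(5, 5.2), fiber = c(5, 5),
      sodium = c(500, 505), ingredients = "flour, water, yeast, salt"),
    # G9, G10: margarine trio and butter singleton
    g(25:27, "Margarine sunflower spreadable unsalted", fat, "per_100g",
      protein = rep(0.2, 3), total_fat = c(60, 61, 59),
      sfa = c(15, 15.2, 14.8), carbohydrate = rep(0.5, 3),
      total_sugars = rep(0.2, 3), fiber = rep(0, 3), sodium = c(30, 31, 29),
      ingredients = "vegetable oils, water, emulsifier"),
    g(28, "Butter cow solid salted", fat2, "per_100g",
      protein = 0.6, total_fat = 82, sfa = 52, carbohydrate = 0.7,
      total_sugars = 0.7, fiber = 0, sodium = 600, ingredients = "cream"),
    # G11-G13: vegetables
    g(29:31, "Spinach frozen", veg, "per_100g",
      protein = c(2.9, 3, 2.8), total_fat = rep(0.4, 3), sfa = rep(0.1, 3),
      carbohydrate = c(1.8, 1.9, 1.7), total_sugars = c(0.7, 0.8, 0.6),
      fiber = rep(2.2, 3), sodium = c(80, 82, 78), ingredients = "spinach"),
    g(32:33, "Asparagus canned in brine", veg2, "per_100g",
      protein = c(2, 2.1), total_fat = rep(0.3, 2), sfa = rep(0.1, 2),
      carbohydrate = c(3.5, 3.6), total_sugars = c(1.8, 1.9),
      fiber = rep(1.5, 2), sodium = c(350, 355), ingredients = "asparagus"),
    g(34, "Asparagus canned in water", veg2, "per_100g",
      protein = 2, total_fat = 0.3, sfa = 0.1, carbohydrate = 3.4,
      total_sugars = 1.7, fiber = 1.4, sodium = 30,
      ingredients = "asparagus")
  )
  # declared energy equals the reconstruction exactly: the fixture is QC-clean
  records$energy <- compute_energy(records, qc_config())

  claims_tbl <- tibble(
    product_id = c("WF014", "WF025"),
    claim_text = c("family pack", "locally produced")
  )

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    description = file.path(dir, "description.csv"),
    nutrients = file.path(dir, "nutrients.csv"),
    claims = file.path(dir, "claims.csv"),
    ingredients = file.path(dir, "ingredients.csv"),
    vocab = file.path(dir, "vocab.yaml")
  )
  readr::write_csv(
    records[, c("product_id", "long_name", "category", "subcategory",
                "group", "subgroup", "basis")],
    paths[["description"]], na = ""
  )
  readr::write_csv(
    records[, c("product_id", BFCD_NUTRIENTS)], paths[["nutrients"]], na = ""
  )
  readr::write_csv(claims_tbl, paths[["claims"]], na = "")
  readr::write_csv(
    records[, c("product_id", "ingredients_text")], paths[["ingredients"]],
    na = ""
  )
  write_vocabulary(default_vocabulary(), paths[["vocab"]])
  invisible(paths)
}
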