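# Built-in vocabulary covering four common packaged-food categories
# (dairy, fats, grain products, vegetables). Used by the simulator and the
# worked example; real deployments supply their own YAML vocabulary tuned to
# their database's language and category tree.

dim_entry <- function(name, tier, values, default = NULL) {
  list(
    name = name, tier = tier,
    values = lapply(values, function(v) list(value = v$value, patterns = v$patterns)),
    default = default
  )
}

val <- function(value, patterns = NULL) {
  list(value = value, patterns = patterns %||% value)
}

#' The vocabulary shipped with the package
#'
#' Covers four categories (milk products, fats, grain products, vegetables)
#' with primary dimensions parsed from product long names (animal/plant of
#' origin, processing, fat content, flavor, form, liquid matrix, ...) and
#' secondary dimensions parsed from ingredient lists and claims (sweetener
#' type, protein/fiber fortification, bioactives, consumption with or without
#' the liquid matrix). Patterns are written against [normalize_text()] output:
#' lower-case, accent-folded, punctuation collapsed to spaces.
#'
#' @return A `descriptor_vocabulary`.
#' @export
default_vocabulary <- function() {
  sweetener_dim <- dim_entry(
    "sweetener", "secondary",
    list(
      val("with sweeteners", c("sweetener", "stevia", "steviol", "aspartame", "sucralose")),
      val("with honey", "honey"),
      val("with sugar", c("\\bsugar\\b", "sucrose", "glucose syrup"))
    )
  )
  milk <- list(dimensions = list(
    dim_entry(
      "animal_of_origin", "primary",
      list(
        val("cow", c("cow", "αγελαδ")),
        val("sheep", c("sheep", "προβει")),
        val("goat", c("goat", "κατσικ", "γιδ")),
        val("mixed milk", "mixed"),
        val("almond", "almond"),
        val("oat", "\\boat\\b")
      )
    ),
    dim_entry(
      "processing", "primary",
      list(
        val("pasteurized", c("pasteurized", "pasteurised", "fresh")),
        val("UHT", c("uht", "long life")),
        val("condensed", "condensed"),
        val("powder", "powder"),
        val("strained", c("strained", "στραγγιστ")),
        val("fermented", c("fermented", "kefir"))
      )
    ),
    dim_entry(
      "fat_content", "primary",
      list(
        val("2% fat", c("semi skimmed", "2% fat", "1 5% fat", "light")),
        val("0% fat", c("0% fat", "skimmed", "fat free", "0%")),
        val("full fat", c("full fat", "whole"))
      )
    ),
    dim_entry(
      "flavor", "primary",
      list(
        val("chocolate", c("chocolate", "cocoa", "σοκολατ")),
        val("strawberry", c("strawberry", "φραουλ")),
        val("vanilla", c("vanilla", "βανιλια")),
        val("plain", c("plain", "πλαιν"))
      )
    ),
    sweetener_dim,
    dim_entry(
      "protein_fortification", "secondary",
      list(
        val("protein fortified", c("whey protein", "pea protein", "milk protein", "added protein"))
      )
    )
  ))
  fat <- list(dimensions = list(
    dim_entry(
      "source", "primary",
      list(
        val("cow", "cow"),
        val("sunflower and olive oil mix", c("sunflower and olive", "oil mix")),
        val("sunflower", "sunflower"),
        val("olive", "olive")
      )
    ),
    dim_entry(
      "form", "primary",
      list(
        val("spreadable", c("spreadable", "spread")),
        val("solid", c("solid", "block")),
        val("liquid", "liquid")
      )
    ),
    dim_entry(
      "salting", "primary",
      list(
        val("unsalted", "unsalted"),
        val("salted", "(?<!un)salted")
      )
    ),
    dim_entry(
      "bioactives", "secondary",
      list(
        val("with plant sterols", c("plant sterol", "sterols", "stanols")),
        val("with yogurt", "yogurt")
      )
    )
  ))
  grain <- list(dimensions = list(
    dim_entry(
      "main_grain", "primary",
      list(
        val("multigrain", c("multigrain", "multi grain")),
        val("wheat", "wheat"),
        val("oat", "\\boat"),
        val("rye", "rye"),
        val("spelt", "spelt"),
        val("corn", c("\\bcorn\\b", "maize"))
      )
    ),
    dim_entry(
      "processing", "primary",
      list(
        val("wholegrain", c("wholegrain", "whole grain", "wholemeal")),
        val("white", "white"),
        val("dried", "dried"),
        val("baked", "baked")
      )
    ),
    dim_entry(
      "form", "primary",
      list(
        val("sliced", "sliced"),
        val("loaf", "loaf"),
        val("rusks", c("rusk", "παξιμαδ"))
      )
    ),
    dim_entry(
      "coating_or_filling", "primary",
      list(
        val("chocolate coating", c("chocolate coating", "chocolate coated")),
        val("fruit filling", c("fruit filling", "fruit filled")),
        val("plain", "plain")
      )
    ),
    sweetener_dim,
    dim_entry(
      "fiber_fortification", "secondary",
      list(
        val("fiber fortified", c("glucomannan", "added fiber", "fibre fortified", "inulin"))
      )
    )
  ))
  vegetable <- list(dimensions = list(
    dim_entry(
      "processing", "primary",
      list(
        val("canned", c("canned", "tinned")),
        val("frozen", "frozen"),
        val("dried", "dried"),
        val("roasted", "roasted")
      )
    ),
    dim_entry(
      "liquid_matrix", "primary",
      list(
        val("in brine", "brine"),
        val("in oil", "in oil"),
        val("in syrup", "syrup"),
        val("in water", "in water")
      )
    ),
    dim_entry(
      "seasoning", "primary",
      list(
        val("with spices", c("with spices", "spiced"))
      )
    ),
    dim_entry(
      "consumption", "secondary",
      list(
        val("strained", c("strained", "drained", "consume without liquid")),
        val("non-strained", c("non strained", "with liquid"))
      )
    )
  ))
  new_vocabulary(
    categories = list(
      "Milk, milk product or milk substitute" = milk,
      "Fat or fat product" = fat,
      "Grain or grain product" = grain,
      "Vegetable or vegetable product" = vegetable
    ),
    multipack_patterns = c("combo", "variety pack", "multipack", "assorted")
  )
}
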