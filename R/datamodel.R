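# Shared domain types: nutrient vectors, food-pattern-equivalent vectors,
# food items, person-days and sandwich profiles. All containers are plain
# named numeric vectors / lightweight S3 lists so they serialise to CSV
# without ceremony.

.NUTRIENTS <- c(
  "energy", "carbohydrate", "protein", "total_fat", "saturated_fat",
  "dietary_fiber", "iron", "calcium", "magnesium", "potassium", "sodium",
  "folate_dfe", "niacin", "riboflavin", "thiamin", "vitamin_a_rae",
  "vitamin_c", "vitamin_d", "vitamin_e_at", "added_sugar"
)

.NUTRIENT_UNITS <- c(
  energy = "kcal", carbohydrate = "g", protein = "g", total_fat = "g",
  saturated_fat = "g", dietary_fiber = "g", iron = "mg", calcium = "mg",
  magnesium = "mg", potassium = "mg", sodium = "mg", folate_dfe = "mcg",
  niacin = "mg", riboflavin = "mg", thiamin = "mg", vitamin_a_rae = "mcg",
  vitamin_c = "mg", vitamin_d = "mcg", vitamin_e_at = "mg",
  added_sugar = "tsp eq"
)

.FOOD_GROUPS <- c(
  "total_fruit", "whole_fruit", "total_veg", "greens_beans", "whole_grains",
  "refined_grains", "dairy", "total_protein", "seafood_plant_protein",
  "mufa", "pufa", "sfa", "added_sugar", "solid_fat_kcal", "alcohol"
)

#' Nutrient field dictionary
#'
#' The twenty reported energy/nutrient fields carried on every food item,
#' person-day total and sandwich profile. Units follow the source tables:
#' energy in kcal, minerals in mg, folate as dietary folate equivalents
#' (mcg), vitamin A as retinol activity equivalents (mcg), vitamin E as
#' alpha-tocopherol (mg), added sugar in teaspoon equivalents.
#'
#' @return Named character vector mapping field name to unit.
#' @export
#' @examples
#' nutrient_names()
nutrient_names <- function() .NUTRIENT_UNITS

#' Food-pattern-equivalent field dictionary
#'
#' MyPlate food-group equivalents (cup eq for fruit/vegetables/dairy, oz eq
#' for grains/protein) plus the fatty-acid grams, solid-fat energy, added
#' sugar and alcohol needed to score the Healthy Eating Index 2010.
#'
#' @return Character vector of field names.
#' @export
food_group_names <- function() .FOOD_GROUPS

.check_nonneg_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("%s: non-finite value in field(s) %s", what,
                 paste(names(x)[!is.finite(x)], collapse = ", ")),
         call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("%s: negative value in field(s) %s", what,
                 paste(names(x)[x < 0], collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Construct a nutrient vector
#'
#' Builds the canonical 20-field nutrient vector. Unspecified fields are
#' zero; all fields must be finite and non-negative.
#'
#' @param ... Named numeric values drawn from `names(nutrient_names())`,
#'   or a single named numeric vector.
#' @return Named numeric vector of length 20, class `nutrient_vector`.
#' @export
#' @examples
#' nutrient_vector(energy = 264, sodium = 681.8)
nutrient_vector <- function(...) {
  vals <- c(...)
  out <- stats::setNames(numeric(length(.NUTRIENTS)), .NUTRIENTS)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
      stop("all nutrient values must be named", call. = FALSE)
    }
    unknown <- setdiff(names(vals), .NUTRIENTS)
    if (length(unknown)) {
      stop("unknown nutrient field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[names(vals)] <- as.numeric(vals)
  }
  .check_nonneg_finite(out, "nutrient_vector")
  structure(out, class = c("nutrient_vector", "numeric"))
}

#' Construct a food-pattern-equivalent vector
#'
#' Builds the 15-field food-group vector. Beyond non-negativity, the
#' hierarchy constraints of the food-pattern scheme are enforced:
#' whole fruit cannot exceed total fruit, greens/beans cannot exceed total
#' vegetables, and seafood/plant protein cannot exceed total protein.
#'
#' @param ... Named numeric values drawn from `food_group_names()`,
#'   or a single named numeric vector.
#' @return Named numeric vector of length 15, class `foodgroup_vector`.
#' @export
foodgroup_vector <- function(...) {
  vals <- c(...)
  out <- stats::setNames(numeric(length(.FOOD_GROUPS)), .FOOD_GROUPS)
  if (length(vals)) {
    if (is.null(names(vals)) || any(!nzchar(names(vals)))) {
      stop("all food-group values must be named", call. = FALSE)
    }
    unknown <- setdiff(names(vals), .FOOD_GROUPS)
    if (length(unknown)) {
      stop("unknown food-group field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out[names(vals)] <- as.numeric(vals)
  }
  .check_nonneg_finite(out, "foodgroup_vector")
  tol <- 1e-9
  if (out["whole_fruit"] > out["total_fruit"] + tol) {
    stop("foodgroup_vector: whole_fruit exceeds total_fruit", call. = FALSE)
  }
  if (out["greens_beans"] > out["total_veg"] + tol) {
    stop("foodgroup_vector: greens_beans exceeds total_veg", call. = FALSE)
  }
  if (out["seafood_plant_protein"] > out["total_protein"] + tol) {
    stop("foodgroup_vector: seafood_plant_protein exceeds total_protein",
         call. = FALSE)
  }
  structure(out, class = c("foodgroup_vector", "numeric"))
}

#' Construct a single reported food item
#'
#' @param food_code Food code (8-digit USDA-style identifier).
#' @param amount Amount consumed, grams.
#' @param nutrients A [nutrient_vector()].
#' @param groups A [foodgroup_vector()]; zero when equivalents are unknown.
#' @param wweia_category Integer WWEIA food-category code, `NA` if absent.
#' @return Object of class `food_item`.
#' @export
food_item <- function(food_code, amount, nutrients,
                      groups = foodgroup_vector(),
                      wweia_category = NA_integer_) {
  if (!is.numeric(amount) || length(amount) != 1L || !is.finite(amount) ||
      amount < 0) {
    stop("food_item: amount must be a single finite value >= 0",
         call. = FALSE)
  }
  if (!inherits(nutrients, "nutrient_vector")) {
    nutrients <- nutrient_vector(nutrients)
  }
  if (!inherits(groups, "foodgroup_vector")) {
    groups <- foodgroup_vector(groups)
  }
  structure(list(food_code = as.character(food_code),
                 wweia_category = as.integer(wweia_category),
                 amount = as.numeric(amount),
                 nutrients = nutrients, groups = groups),
            class = "food_item")
}

#' Construct a person-day of dietary recall
#'
#' One participant's Day-1 24-hour recall: survey design labels, the
#' dietary day-1 weight, and the ordered list of reported items.
#' Dietary-supplement intake is outside the data model; only foods and
#' beverages are represented.
#'
#' @param participant_id Opaque participant identifier.
#' @param stratum,psu Survey design labels (non-empty).
#' @param weight Dietary day-1 survey weight, strictly positive.
#' @param items List of [food_item()] objects (may be empty).
#' @return Object of class `person_day`.
#' @export
person_day <- function(participant_id, stratum, psu, weight, items = list()) {
  stratum <- as.character(stratum); psu <- as.character(psu)
  if (!nzchar(stratum) || is.na(stratum)) stop("person_day: empty stratum",
                                               call. = FALSE)
  if (!nzchar(psu) || is.na(psu)) stop("person_day: empty psu", call. = FALSE)
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0) {
    stop("person_day: weight must be a single finite value > 0",
         call. = FALSE)
  }
  stopifnot(is.list(items))
  for (it in items) {
    if (!inherits(it, "food_item")) {
      stop("person_day: items must all be food_item objects", call. = FALSE)
    }
  }
  structure(list(participant_id = as.character(participant_id),
                 stratum = stratum, psu = psu, weight = as.numeric(weight),
                 items = items),
            class = "person_day")
}

#' Construct a sandwich profile
#'
#' A named composite sandwich: its nutrient vector and its food-pattern
#' equivalents. `groups_known = FALSE` marks profiles whose equivalents are
#' not established (the typical sandwich is reported with nutrients only).
#'
#' @param name Profile label, unique within a scenario set.
#' @param nutrients A [nutrient_vector()].
#' @param groups A [foodgroup_vector()].
#' @param groups_known Logical flag; `FALSE` when the group fields are
#'   placeholders rather than established values.
#' @return Object of class `sandwich_profile`.
#' @export
sandwich_profile <- function(name, nutrients, groups = foodgroup_vector(),
                             groups_known = TRUE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("sandwich_profile: name must be a non-empty string", call. = FALSE)
  }
  if (!inherits(nutrients, "nutrient_vector")) {
    nutrients <- nutrient_vector(nutrients)
  }
  if (!inherits(groups, "foodgroup_vector")) {
    groups <- foodgroup_vector(groups)
  }
  structure(list(name = name, nutrients = nutrients, groups = groups,
                 groups_known = isTRUE(groups_known)),
            class = "sandwich_profile")
}

#' @export
print.sandwich_profile <- function(x, ...) {
  cat("<sandwich_profile>", x$name, "\n")
  cat("  energy:", x$nutrients[["energy"]], "kcal;",
      "sodium:", x$nutrients[["sodium"]], "mg\n")
  if (!x$groups_known) cat("  food-group equivalents: unknown\n")
  invisible(x)
}

#' @export
print.person_day <- function(x, ...) {
  cat("<person_day>", x$participant_id,
      sprintf("[stratum %s, psu %s, weight %.4g]", x$stratum, x$psu,
              x$weight),
      length(x$items), "item(s)\n")
  invisible(x)
}
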