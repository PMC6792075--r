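# Composite construction: proportional-consumption weighting over the food
# codes that qualify for each targeted food group, then assembly of a
# sandwich profile whose group content matches the prespecified targets.

#' Define a composite specification
#'
#' @param name Composite label.
#' @param targets Named numeric vector, food group -> target amount in the
#'   group's equivalent unit (e.g. `c(whole_grains = 2)` for 2 oz eq).
#' @param qualifying_codes Named list, food group -> character vector of
#'   qualifying food codes; every targeted group needs a non-empty set.
#' @return Object of class `composite_spec`.
#' @export
#' @examples
#' composite_spec("wgb meat/cheese",
#'   targets = c(whole_grains = 2, total_protein = 2.5, dairy = 1,
#'               greens_beans = 0.1, total_veg = 0.2),
#'   qualifying_codes = list(whole_grains = "51000000",
#'     total_protein = "23000000", dairy = "14000000",
#'     greens_beans = "72000000", total_veg = c("72000000", "74000000")))
composite_spec <- function(name, targets, qualifying_codes) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(targets) || is.null(names(targets)) ||
      any(!nzchar(names(targets)))) {
    stop("targets must be a named numeric vector", call. = FALSE)
  }
  unknown <- setdiff(names(targets), .FOOD_GROUPS)
  if (length(unknown)) {
    stop("unknown food group(s) in targets: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(targets) | targets <= 0)) {
    stop("all target amounts must be finite and > 0", call. = FALSE)
  }
  for (g in names(targets)) {
    codes <- qualifying_codes[[g]]
    if (is.null(codes) || !length(codes)) {
      stop("no qualifying codes for targeted group: ", g, call. = FALSE)
    }
  }
  structure(list(name = name, targets = targets,
                 qualifying_codes = lapply(qualifying_codes, as.character)),
            class = "composite_spec")
}

#' Read a food database from CSV
#'
#' Layout: one row per food code, columns `food_code`, the 20 nutrient
#' columns (per 100 g) and `fg_`-prefixed food-group equivalent columns
#' (per 100 g). Codes must be unique; all entries non-negative.
#'
#' @param path CSV path.
#' @return Object of class `food_db` (a data frame).
#' @export
read_food_db <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(food_code = "character"))
  as_food_db(df)
}

#' Validate a food database data frame
#'
#' @param df Data frame with columns `food_code`, nutrient columns and
#'   `fg_`-prefixed group columns, all per 100 g.
#' @return The validated `food_db`.
#' @export
as_food_db <- function(df) {
  need <- c("food_code", .NUTRIENTS, .FG_COLS())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("food db missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$food_code <- as.character(df$food_code)
  if (anyDuplicated(df$food_code)) {
    stop("food db has duplicated food codes", call. = FALSE)
  }
  num <- as.matrix(df[, c(.NUTRIENTS, .FG_COLS())])
  if (!all(is.finite(num)) || any(num < 0)) {
    stop("food db entries must be finite and non-negative", call. = FALSE)
  }
  class(df) <- c("food_db", "data.frame")
  df
}

#' Survey-consumption weights for a set of food codes
#'
#' Weight of a code is its share of the survey-weighted gram total consumed
#' across person-days, over all codes in the set: codes are weighted so each
#' contributes to the composite in proportion to how much of it the
#' population actually eats. Codes never consumed get weight zero.
#'
#' @param dataset List of [person_day()] objects.
#' @param codes Character vector of qualifying food codes.
#' @return Named numeric vector over `codes`, summing to 1.
#' @export
consumption_weights <- function(dataset, codes) {
  stopifnot(length(dataset) > 0L, length(codes) > 0L)
  codes <- as.character(codes)
  tot <- stats::setNames(numeric(length(codes)), codes)
  for (d in dataset) {
    for (it in d$items) {
      if (it$food_code %in% codes) {
        tot[it$food_code] <- tot[it$food_code] + d$weight * it$amount
      }
    }
  }
  s <- sum(tot)
  if (s <= 0) stop("no consumption mass for the qualifying codes",
                   call. = FALSE)
  tot / s
}

#' Build a composite sandwich profile
#'
#' For every targeted group `g` with target `T_g`, each qualifying food `f`
#' contributes `T_g * w_f` equivalents of `g`; the grams of `f` needed are
#' that contribution divided by the food's per-gram equivalent density.
#' The profile's nutrients are the gram-weighted sum of the foods'
#' nutrients; its group vector accumulates everything the selected grams
#' carry, so targeted groups land exactly on their targets when foods carry
#' only their own group.
#'
#' @param spec A [composite_spec()].
#' @param db A `food_db` from [read_food_db()] / [as_food_db()].
#' @param weights Named list, food group -> consumption weights from
#'   [consumption_weights()] over that group's qualifying codes.
#' @return A [sandwich_profile()].
#' @export
build_composite <- function(spec, db, weights) {
  stopifnot(inherits(spec, "composite_spec"), inherits(db, "food_db"))
  nut <- stats::setNames(numeric(length(.NUTRIENTS)), .NUTRIENTS)
  grp <- stats::setNames(numeric(length(.FOOD_GROUPS)), .FOOD_GROUPS)
  for (g in names(spec$targets)) {
    T_g <- spec$targets[[g]]
    w <- weights[[g]]
    if (is.null(w)) stop("no weights supplied for group: ", g, call. = FALSE)
    if (abs(sum(w) - 1) > 1e-8) {
      stop("weights for group ", g, " are not normalized", call. = FALSE)
    }
    for (f in names(w)) {
      if (w[[f]] <= 0) next  # zero-consumption codes are dropped
      row <- db[db$food_code == f, , drop = FALSE]
      if (!nrow(row)) stop("food code not in db: ", f, call. = FALSE)
      eq_per_g <- row[[paste0("fg_", g)]] / 100
      if (eq_per_g <= 0) {
        stop(sprintf(
          "food %s has zero %s equivalent density; cannot realize target",
          f, g), call. = FALSE)
      }
      grams <- T_g * w[[f]] / eq_per_g
      nut <- nut + grams * unlist(row[, .NUTRIENTS]) / 100
      grp <- grp + grams * unlist(row[, .FG_COLS()]) / 100
    }
  }
  names(grp) <- .FOOD_GROUPS
  sandwich_profile(spec$name, nutrient_vector(nut), foodgroup_vector(grp))
}
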