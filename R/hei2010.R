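# Healthy Eating Index 2010: 12 components, 100 points. Nine adequacy
# components (density per 1000 kcal, plus the fatty-acid ratio) and three
# moderation components (refined grains, sodium, empty calories), each
# scored by linear interpolation between its zero-score and max-score
# standard, clipped to [0, max points]. Scoring here is person-level: each
# person-day is scored, then the totals are survey-averaged.

#' HEI-2010 component standards
#'
#' The fixed scoring standards: for adequacy components the value at which
#' the full points are awarded (zero intake scores zero, except the
#' fatty-acid ratio whose zero-score standard is 1.2); for moderation
#' components the value at or below which full points are awarded and the
#' value at or above which zero points are awarded. Densities are per
#' 1000 kcal (sodium in grams), the fatty-acid component is the ratio
#' (MUFA+PUFA)/SFA, and empty calories are percent of energy.
#'
#' @return Data frame with columns component, max_points, basis,
#'   value_at_zero, value_at_max, direction.
#' @export
hei_standards <- function() {
  if (is.null(.hei_cache$std)) {
    path <- system.file("extdata", "hei2010_standards.csv",
                        package = "dietshift", mustWork = TRUE)
    std <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(std$value_at_max != std$value_at_zero),
              sum(std$max_points) == 100)
    .hei_cache$std <- std
  }
  .hei_cache$std
}

.hei_cache <- new.env(parent = emptyenv())

#' HEI-2010 inputs from daily totals
#'
#' Converts a day's nutrient and food-group totals into the 12 values the
#' component standards are expressed in. Group densities are
#' `amount * 1000 / energy`; sodium uses grams per 1000 kcal; the
#' fatty-acid value is the ratio (MUFA+PUFA)/SFA (`Inf` when SFA is zero
#' but unsaturates are present, `NA` when all three are zero); empty
#' calories are the percent of energy from solid fats, added sugars
#' (16 kcal per teaspoon equivalent) and alcohol beyond 13 g per 1000 kcal
#' (7 kcal/g). A zero-energy day yields all-`NA` values, which score zero
#' downstream.
#'
#' @param nutrients A [nutrient_vector()] of daily totals.
#' @param groups A [foodgroup_vector()] of daily totals.
#' @return Named numeric vector over the 12 component names.
#' @export
hei_densities <- function(nutrients, groups) {
  comp <- hei_standards()$component
  energy <- nutrients[["energy"]]
  out <- stats::setNames(rep(NA_real_, length(comp)), comp)
  if (!is.finite(energy) || energy <= 0) return(out)
  dens <- function(x) x * 1000 / energy
  out["total_fruit"] <- dens(groups[["total_fruit"]])
  out["whole_fruit"] <- dens(groups[["whole_fruit"]])
  out["total_veg"] <- dens(groups[["total_veg"]])
  out["greens_beans"] <- dens(groups[["greens_beans"]])
  out["whole_grains"] <- dens(groups[["whole_grains"]])
  out["dairy"] <- dens(groups[["dairy"]])
  out["total_protein"] <- dens(groups[["total_protein"]])
  out["seafood_plant_protein"] <- dens(groups[["seafood_plant_protein"]])
  unsat <- groups[["mufa"]] + groups[["pufa"]]
  sfa <- groups[["sfa"]]
  out["fatty_acids"] <- if (sfa > 0) unsat / sfa else if (unsat > 0) Inf else NA_real_
  out["refined_grains"] <- dens(groups[["refined_grains"]])
  out["sodium"] <- dens(nutrients[["sodium"]] / 1000)  # mg -> g
  alcohol_excess <- max(0, groups[["alcohol"]] - 13 * energy / 1000)
  empty_kcal <- groups[["solid_fat_kcal"]] + 16 * groups[["added_sugar"]] +
    7 * alcohol_excess
  out["empty_calories"] <- 100 * empty_kcal / energy
  out
}

#' Score one HEI-2010 component
#'
#' Linear interpolation between the component's zero-score and max-score
#' standards, clipped to `[0, max_points]`. Undefined values (`NA`, from a
#' zero-energy day or an all-zero fatty-acid profile) score zero; an
#' infinite fatty-acid ratio scores the maximum.
#'
#' @param value The component's density / ratio / percent-of-energy value.
#' @param standard One row of [hei_standards()] (data frame or list).
#' @return Points awarded.
#' @export
component_score <- function(value, standard) {
  if (is.na(value)) return(0)
  frac <- (value - standard$value_at_zero) /
    (standard$value_at_max - standard$value_at_zero)
  if (is.nan(frac)) return(0)
  standard$max_points * min(max(frac, 0), 1)
}

#' HEI-2010 score of one person-day
#'
#' @param nutrients,groups Daily totals as a [nutrient_vector()] and
#'   [foodgroup_vector()].
#' @return List with `components` (named numeric, 12 entries) and `total`
#'   in `[0, 100]`; a zero-energy day scores 0 everywhere.
#' @export
#' @examples
#' # an "ideal" day: every adequacy standard met, every moderation
#' # standard at or under its full-credit cutoff
#' n <- nutrient_vector(energy = 2000, sodium = 2000)
#' g <- foodgroup_vector(total_fruit = 2, whole_fruit = 1, total_veg = 3,
#'   greens_beans = 0.5, whole_grains = 3.5, dairy = 3, total_protein = 6,
#'   seafood_plant_protein = 2, mufa = 30, pufa = 20, sfa = 10,
#'   refined_grains = 3)
#' hei_score(n, g)$total  # 100
hei_score <- function(nutrients, groups) {
  std <- hei_standards()
  vals <- hei_densities(nutrients, groups)
  pts <- vapply(seq_len(nrow(std)), function(i) {
    component_score(vals[[std$component[i]]], std[i, ])
  }, numeric(1))
  names(pts) <- std$component
  list(components = pts, total = sum(pts))
}

# Vectorized scoring over a totals data frame (apply_scenario layout);
# returns one total per row. Loads the standards once.
.hei_total_rows <- function(df) {
  std <- hei_standards()
  std_rows <- lapply(seq_len(nrow(std)), function(j) as.list(std[j, ]))
  n <- nrow(df)
  out <- numeric(n)
  nut_m <- as.matrix(df[, .NUTRIENTS])
  grp_m <- as.matrix(df[, .FG_COLS()])
  colnames(grp_m) <- .FOOD_GROUPS
  for (i in seq_len(n)) {
    vals <- hei_densities(nut_m[i, ], grp_m[i, ])
    out[i] <- sum(vapply(seq_along(std_rows), function(j) {
      component_score(vals[[std_rows[[j]]$component]], std_rows[[j]])
    }, numeric(1)))
  }
  out
}
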