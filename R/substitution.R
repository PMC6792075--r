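# Substitution engine: flag typical-sandwich items in each person-day,
# remove their energy/nutrient/food-group contributions from the daily
# totals, and inject one fixed-size modeled sandwich per flagged
# occurrence. Item lists are never rewritten; the analysis consumes totals.

#' Default substitution policy
#'
#' Flags items as "typical sandwiches" by WWEIA category code or by exact
#' food code. The shipped category defaults cover the sandwich families
#' that dominate US consumption (burgers, frankfurter/cold-cut, poultry and
#' egg sandwiches); the source survey does not publish its exact list, so
#' treat these as editable configuration, not a fidelity claim.
#' Replacement granularity is one fixed-size composite per flagged item,
#' never portion-scaled: the composites are defined as prespecified
#' amounts.
#'
#' @param sandwich_categories Integer WWEIA category codes to flag.
#' @param sandwich_codes Character food codes to flag (e.g. the taco codes
#'   `"58101450"`, `"58101610"`, `"58101615"`).
#' @return Object of class `substitution_policy`.
#' @export
substitution_policy <- function(
    sandwich_categories = c(3702L, 3703L, 3704L, 3706L, 3708L),
    sandwich_codes = character()) {
  sandwich_categories <- as.integer(sandwich_categories)
  sandwich_codes <- as.character(sandwich_codes)
  if (!length(sandwich_categories) && !length(sandwich_codes)) {
    stop("substitution_policy: category/code set must be non-empty",
         call. = FALSE)
  }
  structure(list(sandwich_categories = sandwich_categories,
                 sandwich_codes = sandwich_codes,
                 granularity = "per_item", portion_scaling = "none"),
            class = "substitution_policy")
}

#' Daily intake totals for one person-day
#'
#' @param day A [person_day()].
#' @return List with `nutrients` and `groups`: component-wise sums over the
#'   day's items (all-zero vectors for an empty day).
#' @export
daily_totals <- function(day) {
  stopifnot(inherits(day, "person_day"))
  if (!length(day$items)) {
    return(list(nutrients = nutrient_vector(), groups = foodgroup_vector()))
  }
  nut <- rowSums(vapply(day$items, function(it) as.numeric(it$nutrients),
                        numeric(length(.NUTRIENTS))))
  grp <- rowSums(vapply(day$items, function(it) as.numeric(it$groups),
                        numeric(length(.FOOD_GROUPS))))
  list(nutrients = nutrient_vector(stats::setNames(nut, .NUTRIENTS)),
       groups = foodgroup_vector(stats::setNames(grp, .FOOD_GROUPS)))
}

#' Indices of typical-sandwich items in a person-day
#'
#' @param day A [person_day()].
#' @param policy A [substitution_policy()].
#' @return Integer vector of item indices, in item order.
#' @export
identify_sandwiches <- function(day, policy) {
  stopifnot(inherits(day, "person_day"),
            inherits(policy, "substitution_policy"))
  if (!length(day$items)) return(integer())
  hit <- vapply(day$items, function(it) {
    (!is.na(it$wweia_category) &&
       it$wweia_category %in% policy$sandwich_categories) ||
      it$food_code %in% policy$sandwich_codes
  }, logical(1))
  which(hit)
}

#' Substitute a modeled sandwich into one person-day
#'
#' Modified totals are baseline minus the flagged items' vectors plus one
#' profile per flagged occurrence. `profile = NULL` is the pass-through
#' baseline (scenario 0): nothing is flagged, modified equals baseline.
#' Inconsistent inputs that would drive a field negative are clamped to 0
#' with a warning.
#'
#' @param day A [person_day()].
#' @param profile A [sandwich_profile()], or `NULL` for pass-through.
#' @param policy A [substitution_policy()].
#' @return List: `baseline` and `modified` (each `nutrients` + `groups`),
#'   and `n_replaced`.
#' @export
substitute_day <- function(day, profile, policy) {
  base <- daily_totals(day)
  if (is.null(profile)) {
    return(list(baseline = base, modified = base, n_replaced = 0L))
  }
  stopifnot(inherits(profile, "sandwich_profile"))
  idx <- identify_sandwiches(day, policy)
  k <- length(idx)
  if (!k) return(list(baseline = base, modified = base, n_replaced = 0L))
  rem_nut <- rowSums(vapply(day$items[idx],
                            function(it) as.numeric(it$nutrients),
                            numeric(length(.NUTRIENTS))))
  rem_grp <- rowSums(vapply(day$items[idx],
                            function(it) as.numeric(it$groups),
                            numeric(length(.FOOD_GROUPS))))
  nut <- as.numeric(base$nutrients) - rem_nut + k * as.numeric(profile$nutrients)
  grp <- as.numeric(base$groups) - rem_grp + k * as.numeric(profile$groups)
  if (any(nut < 0) || any(grp < 0)) {
    if (any(nut < -1e-9) || any(grp < -1e-9)) {
      warning("substitute_day: negative modified total clamped to 0 for ",
              day$participant_id, call. = FALSE)
    }
    nut <- pmax(nut, 0); grp <- pmax(grp, 0)
  }
  grp <- .repair_group_hierarchy(grp)
  list(baseline = base,
       modified = list(
         nutrients = nutrient_vector(stats::setNames(nut, .NUTRIENTS)),
         groups = foodgroup_vector(stats::setNames(grp, .FOOD_GROUPS))),
       n_replaced = k)
}

# Removing item groups and injecting a profile can break the subset
# constraints by floating-point slivers (e.g. whole_fruit a hair above
# total_fruit after clamping); nudge parents up to their children.
.repair_group_hierarchy <- function(grp) {
  names(grp) <- .FOOD_GROUPS
  grp["total_fruit"] <- max(grp[["total_fruit"]], grp[["whole_fruit"]])
  grp["total_veg"] <- max(grp[["total_veg"]], grp[["greens_beans"]])
  grp["total_protein"] <- max(grp[["total_protein"]],
                              grp[["seafood_plant_protein"]])
  grp
}

#' Apply one substitution scenario to a dataset
#'
#' Runs [substitute_day()] independently over every person-day and stacks
#' the per-participant baseline and modified daily totals.
#'
#' @param dataset Non-empty list of [person_day()] objects.
#' @param profile A [sandwich_profile()], or `NULL` for the pass-through
#'   baseline scenario.
#' @param policy A [substitution_policy()].
#' @return Object of class `scenario_result`: list with `baseline` and
#'   `modified` data frames (participant_id, stratum, psu, weight, the 20
#'   nutrient columns and the 15 `fg_` columns) and integer `n_replaced`
#'   per participant.
#' @export
apply_scenario <- function(dataset, profile, policy) {
  stopifnot(is.list(dataset), length(dataset) > 0L)
  n <- length(dataset)
  p_nut <- length(.NUTRIENTS); p_grp <- length(.FOOD_GROUPS)
  base_m <- matrix(0, n, p_nut + p_grp)
  mod_m <- matrix(0, n, p_nut + p_grp)
  n_rep <- integer(n)
  meta <- data.frame(
    participant_id = vapply(dataset, `[[`, "", "participant_id"),
    stratum = vapply(dataset, `[[`, "", "stratum"),
    psu = vapply(dataset, `[[`, "", "psu"),
    weight = vapply(dataset, `[[`, 0, "weight"),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- substitute_day(dataset[[i]], profile, policy)
    base_m[i, ] <- c(as.numeric(s$baseline$nutrients),
                     as.numeric(s$baseline$groups))
    mod_m[i, ] <- c(as.numeric(s$modified$nutrients),
                    as.numeric(s$modified$groups))
    n_rep[i] <- s$n_replaced
  }
  colnames(base_m) <- colnames(mod_m) <- c(.NUTRIENTS, .FG_COLS())
  structure(list(
    baseline = cbind(meta, as.data.frame(base_m)),
    modified = cbind(meta, as.data.frame(mod_m)),
    n_replaced = n_rep), class = "scenario_result")
}
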