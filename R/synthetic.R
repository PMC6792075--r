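# Synthetic NHANES-like populations with known ground truth. The generator
# emulates the structure the estimators assume — stratified sampling with
# two PSUs per stratum, unequal log-normal weights, person-days made of
# background items plus Poisson-occurring sandwich items whose vectors are
# a configured profile times multiplicative noise — so every pipeline stage
# can be checked against analytic expectations without any survey download.

.SANDWICH_WWEIA <- 3702L  # category the generator stamps on sandwich items

# Background daily-intake means: the population's non-sandwich intake,
# sized so that background + sandwich_rate * typical-sandwich lands at
# US-adult daily totals. Defaults assume the typical-sandwich profile and
# a 0.78 expected sandwiches per person-day.
.default_background_mean <- function() {
  nutrients <- c(
    energy = 1864, carbohydrate = 223, protein = 55, total_fat = 67,
    saturated_fat = 22, dietary_fiber = 14.6, iron = 12.4, calcium = 834,
    magnesium = 268, potassium = 2401, sodium = 2775, folate_dfe = 469,
    niacin = 21.5, riboflavin = 1.93, thiamin = 1.45, vitamin_a_rae = 549,
    vitamin_c = 78.4, vitamin_d = 4.31, vitamin_e_at = 7.38,
    added_sugar = 19.5)
  groups <- c(
    total_fruit = 0.95, whole_fruit = 0.45, total_veg = 1.45,
    greens_beans = 0.14, whole_grains = 0.75, refined_grains = 4.8,
    dairy = 1.2, total_protein = 4.5, seafood_plant_protein = 0.45,
    mufa = 24, pufa = 17, sfa = 20, added_sugar = 19.5,
    solid_fat_kcal = 330, alcohol = 10)
  list(nutrients = nutrients, groups = groups)
}

# Typical-sandwich food-pattern equivalents for the generator: the shipped
# control profile carries nutrients only, so sandwich items in synthetic
# days get these constructed equivalents (refined-grain bread, meat,
# cheese).
.default_typical_groups <- function() {
  foodgroup_vector(total_veg = 0.1, refined_grains = 2, dairy = 0.7,
                   total_protein = 2.5, mufa = 11, pufa = 6, sfa = 9.6,
                   added_sugar = 1, solid_fat_kcal = 220)
}

#' Configure a synthetic population
#'
#' Defaults describe the study conditions the pipeline is tested under:
#' a stratified two-PSU-per-stratum design with log-normal weights,
#' roughly ten background items per person-day sized so daily totals match
#' US-adult intake, and Poisson sandwich occurrences at 0.78 expected
#' sandwiches per person-day — the per-capita rate implied by daily totals
#' of roughly one typical sandwich's nutrients among near-half daily
#' consumers — built on the typical-sandwich profile.
#'
#' @param n_participants Number of person-days (one per participant).
#' @param n_strata Number of design strata.
#' @param psus_per_stratum PSUs per stratum (>= 2 for variance estimation).
#' @param weight_meanlog,weight_sdlog Log-normal survey-weight parameters.
#' @param mean_items_per_day Poisson mean of background items (min 1 kept).
#' @param sandwich_rate Expected sandwich items per person-day.
#' @param sandwich_profile [sandwich_profile()] the sandwich items follow;
#'   default is the built-in typical sandwich with constructed equivalents.
#' @param sandwich_noise_cv Coefficient of variation of the multiplicative
#'   log-normal (mean-1) noise on sandwich items.
#' @param background_mean,background_sd Named lists with `nutrients` and
#'   `groups` daily-total means / sds; sd defaults to 40% of the mean.
#' @param seed Integer seed; the generator is seed-deterministic.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_participants = 2000L, n_strata = 14L,
                              psus_per_stratum = 2L,
                              weight_meanlog = log(1e4), weight_sdlog = 0.6,
                              mean_items_per_day = 10,
                              sandwich_rate = 0.78,
                              sandwich_profile = NULL,
                              sandwich_noise_cv = 0.15,
                              background_mean = .default_background_mean(),
                              background_sd = NULL, seed = 1L) {
  if (is.null(sandwich_profile)) {
    p0 <- load_builtin_profiles()[["Sandwich 0"]]
    sandwich_profile <- sandwich_profile(p0$name, p0$nutrients,
                                         .default_typical_groups())
  }
  if (is.null(background_sd)) {
    background_sd <- lapply(background_mean, function(x) 0.4 * x)
  }
  stopifnot(n_participants >= 4L, n_strata >= 1L, psus_per_stratum >= 2L,
            sandwich_rate >= 0, sandwich_noise_cv >= 0,
            all(unlist(background_sd) >= 0),
            inherits(sandwich_profile, "sandwich_profile"))
  structure(list(
    n_participants = as.integer(n_participants),
    n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum),
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
    mean_items_per_day = mean_items_per_day,
    sandwich_rate = sandwich_rate, sandwich_profile = sandwich_profile,
    sandwich_noise_cv = sandwich_noise_cv,
    background_mean = background_mean, background_sd = background_sd,
    seed = as.integer(seed)), class = "population_config")
}

#' Generate a toy food database
#'
#' Reproducible random per-100 g nutrient and equivalent densities over
#' `n_foods` unique 8-digit codes. Foods are assigned a primary
#' food-pattern group by cycling through the HEI-relevant groups, so any
#' database with at least nine foods covers them all.
#'
#' @param seed Integer seed.
#' @param n_foods Number of foods (>= 1).
#' @return A `food_db` data frame (see [as_food_db()]).
#' @export
gen_food_db <- function(seed, n_foods) {
  stopifnot(n_foods >= 1L)
  set.seed(seed)
  primary <- c("whole_grains", "refined_grains", "dairy", "total_protein",
               "seafood_plant_protein", "total_fruit", "whole_fruit",
               "total_veg", "greens_beans")
  codes <- sprintf("5%07d", sample.int(9999999L, n_foods))
  nut <- matrix(0, n_foods, length(.NUTRIENTS),
                dimnames = list(NULL, .NUTRIENTS))
  grp <- matrix(0, n_foods, length(.FOOD_GROUPS),
                dimnames = list(NULL, paste0("fg_", .FOOD_GROUPS)))
  for (i in seq_len(n_foods)) {
    nut[i, "energy"] <- stats::runif(1, 50, 400)
    nut[i, "carbohydrate"] <- stats::runif(1, 0, 50)
    nut[i, "protein"] <- stats::runif(1, 0, 30)
    nut[i, "total_fat"] <- stats::runif(1, 0, 25)
    nut[i, "saturated_fat"] <- nut[i, "total_fat"] * stats::runif(1, 0.1, 0.5)
    others <- setdiff(.NUTRIENTS, c("energy", "carbohydrate", "protein",
                                    "total_fat", "saturated_fat"))
    nut[i, others] <- stats::rlnorm(length(others), meanlog = 0, sdlog = 1)
    g <- paste0("fg_", primary[(i - 1L) %% length(primary) + 1L])
    grp[i, g] <- stats::runif(1, 0.3, 3)
    # honour the hierarchy: child groups imply their parents
    if (g == "fg_whole_fruit") grp[i, "fg_total_fruit"] <- grp[i, g]
    if (g == "fg_greens_beans") grp[i, "fg_total_veg"] <- grp[i, g]
    if (g == "fg_seafood_plant_protein") grp[i, "fg_total_protein"] <- grp[i, g]
    grp[i, "fg_sfa"] <- nut[i, "saturated_fat"]
    rest <- nut[i, "total_fat"] - nut[i, "saturated_fat"]
    grp[i, "fg_mufa"] <- 0.65 * rest
    grp[i, "fg_pufa"] <- 0.35 * rest
  }
  as_food_db(data.frame(food_code = codes, nut, grp,
                        check.names = FALSE,
                        stringsAsFactors = FALSE))
}

# one truncated-normal draw per field
.rtruncnorm_vec <- function(mean, sd) pmax(0, stats::rnorm(length(mean), mean, sd))

#' Generate a synthetic population of person-days
#'
#' Participants are spread round-robin over strata, assigned one of the
#' stratum's PSUs and a log-normal weight. Each person-day draws its
#' background daily totals as truncated normals, splits them over a
#' Poisson number of background items, then appends `Poisson(rate)`
#' sandwich items equal to the configured profile times a mean-one
#' log-normal multiplier (stamped with the sandwich WWEIA category).
#'
#' @param config A [population_config()].
#' @return List of [person_day()] objects, seed-deterministic.
#' @export
gen_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  n <- config$n_participants
  cv <- config$sandwich_noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2  # mean-one multiplier
  prof_nut <- as.numeric(config$sandwich_profile$nutrients)
  prof_grp <- as.numeric(config$sandwich_profile$groups)
  bm_n <- config$background_mean$nutrients[.NUTRIENTS]
  bs_n <- config$background_sd$nutrients[.NUTRIENTS]
  bm_g <- config$background_mean$groups[.FOOD_GROUPS]
  bs_g <- config$background_sd$groups[.FOOD_GROUPS]
  out <- vector("list", n)
  psu_cycle <- integer(config$n_strata)  # next PSU per stratum
  for (i in seq_len(n)) {
    h <- (i - 1L) %% config$n_strata + 1L
    stratum <- sprintf("S%02d", h)
    psu_cycle[h] <- psu_cycle[h] %% config$psus_per_stratum + 1L
    psu <- sprintf("P%d", psu_cycle[h])
    w <- stats::rlnorm(1, config$weight_meanlog, config$weight_sdlog)
    day_nut <- .rtruncnorm_vec(bm_n, bs_n)
    day_grp <- .rtruncnorm_vec(bm_g, bs_g)
    day_grp <- .repair_group_hierarchy(day_grp)
    k <- max(1L, stats::rpois(1, config$mean_items_per_day))
    shares <- stats::rexp(k); shares <- shares / sum(shares)
    items <- vector("list", k)
    for (j in seq_len(k)) {
      nv <- stats::setNames(day_nut * shares[j], .NUTRIENTS)
      gv <- stats::setNames(day_grp * shares[j], .FOOD_GROUPS)
      items[[j]] <- food_item(sprintf("9%07d", j),
                              amount = nv[["energy"]] / 1.8,
                              nutrients = nutrient_vector(nv),
                              groups = foodgroup_vector(gv),
                              wweia_category = 9999L)
    }
    s <- stats::rpois(1, config$sandwich_rate)
    for (j in seq_len(s)) {
      m <- stats::rlnorm(1, meanlog, sdlog)
      nv <- stats::setNames(prof_nut * m, .NUTRIENTS)
      gv <- stats::setNames(prof_grp * m, .FOOD_GROUPS)
      items[[k + j]] <- food_item("58100100", amount = 250 * m,
                                  nutrients = nutrient_vector(nv),
                                  groups = foodgroup_vector(gv),
                                  wweia_category = .SANDWICH_WWEIA)
    }
    out[[i]] <- person_day(sprintf("ID%05d", i), stratum, psu, w, items)
  }
  out
}

#' Analytic expectation of a scenario's population mean shift
#'
#' Replacing every occurrence of `profile_in` by `profile_out` at rate
#' `r` expected occurrences per person-day shifts the expected mean daily
#' intake by `r * (profile_out - profile_in)`, field by field.
#'
#' @param config A [population_config()] (supplies the rate).
#' @param profile_in,profile_out [sandwich_profile()] objects.
#' @return List with `nutrients` and `groups` shift vectors (signed).
#' @export
expected_scenario_shift <- function(config, profile_in, profile_out) {
  stopifnot(inherits(config, "population_config"),
            inherits(profile_in, "sandwich_profile"),
            inherits(profile_out, "sandwich_profile"))
  r <- config$sandwich_rate
  list(nutrients = r * (as.numeric(profile_out$nutrients) -
                          as.numeric(profile_in$nutrients)) |>
         stats::setNames(.NUTRIENTS),
       groups = r * (as.numeric(profile_out$groups) -
                       as.numeric(profile_in$groups)) |>
         stats::setNames(.FOOD_GROUPS))
}
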