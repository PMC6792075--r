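# Independent oracles and small constructors shared across tests. The
# oracles deliberately use different code paths from the package: the
# variance oracle is an explicit loop transcription of the stratified
# with-replacement formula, and the HEI oracle evaluates the piecewise
# ramps with stats::approx.

# Brute-force Taylor-linearized SE of the weighted mean: loops, no tapply.
oracle_taylor_se <- function(y, stratum, psu, w) {
  m <- sum(w * y) / sum(w)
  z <- w * (y - m)
  total <- 0
  for (h in unique(stratum)) {
    sel <- stratum == h
    psus <- unique(psu[sel])
    nh <- length(psus)
    zh <- sapply(psus, function(p) sum(z[sel & psu[sel] == p]))
    zbar <- mean(zh)
    acc <- 0
    for (v in zh) acc <- acc + (v - zbar)^2
    total <- total + nh / (nh - 1) * acc
  }
  sqrt(total) / sum(w)
}

# Piecewise-linear HEI component oracle via stats::approx (rule = 2 clamps
# beyond the standards). Handles the conventions: NA -> 0, Inf -> max for
# adequacy.
oracle_component_score <- function(value, standard) {
  if (is.na(value)) return(0)
  if (is.infinite(value)) {
    return(if (standard$direction == "adequacy" && value > 0)
      standard$max_points else 0)
  }
  xs <- sort(c(standard$value_at_zero, standard$value_at_max))
  ys <- if (standard$value_at_max > standard$value_at_zero) {
    c(0, standard$max_points)
  } else {
    c(standard$max_points, 0)
  }
  stats::approx(xs, ys, xout = value, rule = 2)$y
}

# A one-item person-day holding a given profile's vectors.
profile_day <- function(profile, id = "P1", stratum = "S1", psu = "U1",
                        weight = 1, wweia = 3702L, code = "58100100") {
  person_day(id, stratum, psu, weight, list(
    food_item(code, amount = 250, nutrients = profile$nutrients,
              groups = profile$groups, wweia_category = wweia)))
}

# A minimal background (non-sandwich) item.
bg_item <- function(energy = 100, ...) {
  food_item("91000000", amount = 50,
            nutrients = nutrient_vector(energy = energy, ...),
            groups = foodgroup_vector(), wweia_category = 9999L)
}

# Item-level data frame for one small recall CSV (two participants, two
# items each) used by the io tests.
toy_recall_df <- function() {
  nut <- matrix(0, 4, length(names(nutrient_names())),
                dimnames = list(NULL, names(nutrient_names())))
  nut[, "energy"] <- c(100, 200, 300, 400)
  nut[, "sodium"] <- c(10, 20, 30, 40)
  data.frame(participant_id = c("A", "A", "B", "B"), day = 1L,
             stratum = "S1", psu = c("U1", "U1", "U2", "U2"),
             weight = c(2, 2, 3, 3),
             food_code = c("11111111", "22222222", "33333333", "44444444"),
             wweia_category = c(9999L, 3702L, 9999L, 9999L),
             amount = c(10, 20, 30, 40), nut, check.names = FALSE)
}
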