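# Composite builder: consumption weighting and target assembly.

# a db where each food carries exactly one group, with chosen densities
single_group_db <- function(codes, group, eq_per_100g, sodium_per_100g) {
  n <- length(codes)
  nut <- matrix(0, n, length(names(nutrient_names())),
                dimnames = list(NULL, names(nutrient_names())))
  nut[, "sodium"] <- sodium_per_100g
  nut[, "energy"] <- 100
  grp <- matrix(0, n, length(food_group_names()),
                dimnames = list(NULL, paste0("fg_", food_group_names())))
  grp[, paste0("fg_", group)] <- eq_per_100g
  as_food_db(data.frame(food_code = codes, nut, grp, check.names = FALSE,
                        stringsAsFactors = FALSE))
}

test_that("consumption weights are survey-weighted gram shares", {
  # codes A, B with survey-weighted gram totals 300 and 100 -> 0.75 / 0.25
  days <- list(
    person_day("P1", "S1", "U1", 3, list(
      food_item("A", amount = 100, nutrients = nutrient_vector()))),
    person_day("P2", "S1", "U2", 1, list(
      food_item("B", amount = 100, nutrients = nutrient_vector()))))
  w <- consumption_weights(days, c("A", "B"))
  expect_equal(unname(w), c(0.75, 0.25))
  expect_equal(sum(w), 1)

  # single consumed code takes all the mass
  expect_equal(unname(consumption_weights(days, "A")), 1)

  # equal-weight participants eating one of k codes in equal grams -> 1/k
  k <- 5L
  days_k <- lapply(seq_len(k), function(i) {
    person_day(paste0("Q", i), "S1", "U1", 2, list(
      food_item(paste0("C", i), amount = 40,
                nutrients = nutrient_vector())))
  })
  wk <- consumption_weights(days_k, paste0("C", seq_len(k)))
  expect_equal(unname(wk), rep(1 / k, k))

  # never-consumed codes get zero, the rest renormalize
  w2 <- consumption_weights(days, c("A", "B", "Z"))
  expect_equal(w2[["Z"]], 0)
  expect_equal(sum(w2), 1)

  expect_error(consumption_weights(days, "NOPE"), "no consumption mass")
})

test_that("a single-food composite scales grams to hit the target", {
  # 1 oz eq whole grain per 50 g -> 2 oz/100 g; target 2 oz eq -> 100 g
  db <- single_group_db("F1", "whole_grains", eq_per_100g = 2,
                        sodium_per_100g = 120)
  spec <- composite_spec("wg only", c(whole_grains = 2),
                         list(whole_grains = "F1"))
  prof <- build_composite(spec, db, list(whole_grains = c(F1 = 1)))
  expect_equal(prof$groups[["whole_grains"]], 2)
  expect_equal(prof$nutrients[["sodium"]], 120)  # 100 g at 120 mg/100 g
  expect_equal(prof$nutrients[["energy"]], 100)
})

test_that("two-food composite matches the hand-computed gram split", {
  # weights 0.75/0.25, per-gram sodium 2 and 4 mg, densities 0.02 and 0.04
  # oz eq/g, target 2 oz eq -> grams 75 and 12.5 -> sodium 200 mg
  db <- single_group_db(c("A", "B"), "whole_grains",
                        eq_per_100g = c(2, 4), sodium_per_100g = c(200, 400))
  spec <- composite_spec("two-food", c(whole_grains = 2),
                         list(whole_grains = c("A", "B")))
  prof <- build_composite(spec, db,
                          list(whole_grains = c(A = 0.75, B = 0.25)))
  expect_equal(prof$nutrients[["sodium"]], 200)
  expect_equal(prof$groups[["whole_grains"]], 2)
})

test_that("a multi-group composite reproduces the sandwich-1 targets", {
  targets <- c(whole_grains = 2, total_protein = 2.5, dairy = 1,
               greens_beans = 0.1)
  db <- rbind(
    single_group_db(c("G1", "G2"), "whole_grains", c(1.5, 3), c(100, 150)),
    single_group_db("M1", "total_protein", 2.2, 300),
    single_group_db("D1", "dairy", 0.8, 250),
    {
      d <- single_group_db("V1", "greens_beans", 0.5, 20)
      d$fg_total_veg <- d$fg_greens_beans  # greens imply vegetables
      d
    })
  db <- as_food_db(db)
  days <- list(person_day("P1", "S1", "U1", 1, list(
    food_item("G1", amount = 60, nutrients = nutrient_vector()),
    food_item("G2", amount = 20, nutrients = nutrient_vector()),
    food_item("M1", amount = 50, nutrients = nutrient_vector()),
    food_item("D1", amount = 30, nutrients = nutrient_vector()),
    food_item("V1", amount = 10, nutrients = nutrient_vector()))))
  spec <- composite_spec("sandwich 1 shape", targets, list(
    whole_grains = c("G1", "G2"), total_protein = "M1", dairy = "D1",
    greens_beans = "V1"))
  weights <- lapply(spec$qualifying_codes,
                    function(cc) consumption_weights(days, cc))
  prof <- build_composite(spec, db, weights)
  for (g in names(targets)) {
    expect_equal(prof$groups[[g]], unname(targets[g]), tolerance = 1e-9)
  }
})

test_that("built composites are linear in the targets", {
  db <- single_group_db(c("A", "B"), "dairy", c(1, 2), c(80, 160))
  w <- list(dairy = c(A = 0.4, B = 0.6))
  p1 <- build_composite(composite_spec("x", c(dairy = 1),
                                       list(dairy = c("A", "B"))), db, w)
  p2 <- build_composite(composite_spec("x2", c(dairy = 2),
                                       list(dairy = c("A", "B"))), db, w)
  expect_equal(2 * as.numeric(p1$nutrients), as.numeric(p2$nutrients))
  expect_equal(2 * as.numeric(p1$groups), as.numeric(p2$groups))
})

test_that("identical per-equivalent foods make the weights irrelevant", {
  # same nutrient content per equivalent -> composite independent of mix
  db <- single_group_db(c("A", "B"), "whole_grains",
                        eq_per_100g = c(1, 2), sodium_per_100g = c(50, 100))
  db$energy <- c(100, 200)  # keep energy per equivalent identical too
  db <- as_food_db(db)
  spec <- composite_spec("degenerate", c(whole_grains = 3),
                         list(whole_grains = c("A", "B")))
  pa <- build_composite(spec, db, list(whole_grains = c(A = 0.9, B = 0.1)))
  pb <- build_composite(spec, db, list(whole_grains = c(A = 0.2, B = 0.8)))
  expect_equal(as.numeric(pa$nutrients), as.numeric(pb$nutrients),
               tolerance = 1e-12)
})

test_that("zero equivalent density is rejected", {
  db <- single_group_db("A", "whole_grains", eq_per_100g = 0,
                        sodium_per_100g = 10)
  spec <- composite_spec("bad", c(whole_grains = 1),
                         list(whole_grains = "A"))
  expect_error(build_composite(spec, db, list(whole_grains = c(A = 1))),
               "zero whole_grains equivalent density")
})
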