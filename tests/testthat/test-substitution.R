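# Substitution engine: totals, flagging, per-occurrence replacement.

test_that("daily totals sum items component-wise", {
  empty <- person_day("E", "S1", "U1", 1)
  tot <- daily_totals(empty)
  expect_equal(sum(tot$nutrients), 0)
  expect_equal(sum(tot$groups), 0)

  d <- person_day("A", "S1", "U1", 1, list(bg_item(100), bg_item(100)))
  expect_equal(daily_totals(d)$nutrients[["energy"]], 200)

  p0 <- load_builtin_profiles()[["Sandwich 0"]]
  d0 <- profile_day(p0)
  tot0 <- daily_totals(d0)
  expect_equal(tot0$nutrients[["energy"]], 561)
  expect_equal(tot0$nutrients[["sodium"]], 1393)
})

test_that("sandwich items are flagged by category or food code, in order", {
  pol <- substitution_policy(sandwich_categories = 3702L,
                             sandwich_codes = "58101450")
  d <- person_day("A", "S1", "U1", 1, list(
    bg_item(), profile_day(load_builtin_profiles()[[1]])$items[[1]],
    bg_item(),
    food_item("58101450", amount = 100,
              nutrients = nutrient_vector(energy = 250),
              wweia_category = 9999L),
    bg_item()))
  expect_identical(identify_sandwiches(d, pol), c(2L, 4L))
  expect_identical(identify_sandwiches(person_day("B", "S1", "U1", 1,
                                                  list(bg_item())), pol),
                   integer())
})

test_that("substitution is the identity without sandwiches or with self-substitution", {
  pol <- substitution_policy()
  profs <- load_builtin_profiles()
  d_plain <- person_day("A", "S1", "U1", 1, list(bg_item(500)))
  s <- substitute_day(d_plain, profs[["Sandwich 5"]], pol)
  expect_identical(s$n_replaced, 0L)
  expect_equal(as.numeric(s$modified$nutrients),
               as.numeric(s$baseline$nutrients))

  # a day whose single sandwich equals the injected profile is unchanged
  p1 <- profs[["Sandwich 1"]]
  d_self <- profile_day(p1)
  s2 <- substitute_day(d_self, p1, pol)
  expect_identical(s2$n_replaced, 1L)
  expect_equal(as.numeric(s2$modified$nutrients),
               as.numeric(s2$baseline$nutrients), tolerance = 1e-12)
  expect_equal(as.numeric(s2$modified$groups),
               as.numeric(s2$baseline$groups), tolerance = 1e-12)
})

test_that("replacing the typical sandwich with the taco shifts the published deltas", {
  profs <- load_builtin_profiles()
  pol <- substitution_policy()
  d <- person_day("A", "S1", "U1", 1, list(
    bg_item(1500), profile_day(profs[["Sandwich 0"]])$items[[1]]))
  s <- substitute_day(d, profs[["Sandwich 5"]], pol)
  delta <- as.numeric(s$modified$nutrients) - as.numeric(s$baseline$nutrients)
  names(delta) <- names(nutrient_names())
  expect_equal(delta[["energy"]], -297)
  expect_equal(delta[["sodium"]], -711.2)
  expect_equal(delta[["saturated_fat"]], -5.8)
})

test_that("totals conservation holds exactly per nutrient", {
  # modified - baseline = count * profile - sum(flagged items)
  pol <- substitution_policy()
  profs <- load_builtin_profiles()
  q <- profs[["Sandwich 3"]]
  pop <- gen_population(population_config(n_participants = 150, seed = 42))
  for (d in pop[1:50]) {
    s <- substitute_day(d, q, pol)
    idx <- identify_sandwiches(d, pol)
    flagged <- if (length(idx)) {
      rowSums(vapply(d$items[idx], function(it) as.numeric(it$nutrients),
                     numeric(20)))
    } else numeric(20)
    lhs <- as.numeric(s$modified$nutrients) - as.numeric(s$baseline$nutrients)
    rhs <- s$n_replaced * as.numeric(q$nutrients) - flagged
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("component-wise larger profiles give component-wise larger totals", {
  pol <- substitution_policy()
  small <- sandwich_profile("small", nutrient_vector(energy = 100,
                                                     sodium = 50))
  big <- sandwich_profile("big", nutrient_vector(energy = 300, sodium = 80))
  pop <- gen_population(population_config(n_participants = 60, seed = 9))
  ra <- apply_scenario(pop, small, pol)
  rb <- apply_scenario(pop, big, pol)
  nut_cols <- names(nutrient_names())
  expect_true(all(as.matrix(ra$modified[nut_cols]) <=
                    as.matrix(rb$modified[nut_cols]) + 1e-12))
})

test_that("a uniform one-sandwich population shifts by the profile delta", {
  profs <- load_builtin_profiles()
  pol <- substitution_policy()
  pop <- lapply(1:10, function(i) {
    person_day(paste0("P", i), sprintf("S%d", (i - 1) %% 2 + 1),
               sprintf("U%d", i), 1 + i / 10,
               list(bg_item(1000 + 10 * i),
                    profile_day(profs[["Sandwich 0"]])$items[[1]]))
  })
  res <- apply_scenario(pop, profs[["Sandwich 5"]], pol)
  expect_identical(res$n_replaced, rep(1L, 10))
  shift <- res$modified$energy - res$baseline$energy
  expect_equal(shift, rep(264 - 561, 10))
})

test_that("pass-through baseline is idempotent and counts zero replacements", {
  pol <- substitution_policy()
  pop <- gen_population(population_config(n_participants = 30, seed = 5))
  r1 <- apply_scenario(pop, NULL, pol)
  expect_identical(r1$n_replaced, rep(0L, 30))
  expect_identical(r1$modified, r1$baseline)
  # re-applying the pass-through to its own totals changes nothing
  r2 <- apply_scenario(pop, NULL, pol)
  expect_identical(r2$modified, r1$modified)
})

test_that("removal never drives a total below zero; the boundary lands on zero", {
  pol <- substitution_policy()
  # the whole day is the flagged item: removal leaves exactly the profile
  weird <- person_day("W", "S1", "U1", 1, list(
    food_item("1", amount = 10,
              nutrients = nutrient_vector(energy = 700, sodium = 900),
              wweia_category = 3702L)))
  zero_sodium <- sandwich_profile("low", nutrient_vector(energy = 100))
  expect_silent(s <- substitute_day(weird, zero_sodium, pol))
  expect_equal(s$modified$nutrients[["sodium"]], 0)
  expect_equal(s$modified$nutrients[["energy"]], 100)
  expect_true(all(as.numeric(s$modified$nutrients) >= 0))
})
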