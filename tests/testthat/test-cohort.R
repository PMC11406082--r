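one_person_week <- function(foods = c("bread", "milk")) {
  grid <- expand.grid(day = 1:7, meal_moment = main_moments(),
                      food_id = foods, stringsAsFactors = FALSE)
  as_records(data.frame(person_id = "P1", day = grid$day,
                        meal_moment = grid$meal_moment,
                        food_id = grid$food_id, mass_g = 120))
}

test_that("one summary per person-day-main-moment group", {
  rec <- one_person_week()
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  s <- score_records(rec, persons, tiny_table())
  expect_equal(nrow(s), 21)
  expect_equal(sort(unique(s$day)), 1:7)
  expect_setequal(as.character(unique(s$meal_moment)), main_moments())
  # identical meals at every moment give identical row statistics
  m <- moment_summary(s)$stats
  expect_equal(length(unique(m$mean[m$adjustment == "with_digestibility"])), 1)
  expect_equal(length(unique(m$median[m$adjustment == "with_digestibility"])), 1)
})

test_that("missing body weights are reported by person", {
  rec <- one_person_week()
  expect_error(
    score_records(rec, data.frame(person_id = "P9", body_weight_kg = 70),
                  tiny_table()),
    "missing body weight.*P1")
})

test_that("plant categories partition [0,100] with a closed vegan edge", {
  x <- c(0, 26.99, 27, 64.9, 65, 99.99, 100, NA)
  expect_equal(as.character(plant_category(x)),
               c("0-27", "0-27", "27-65", "27-65", "65-99", "65-99", "100", NA))

  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  vegan <- score_records(one_person_week("bread"), persons, tiny_table())
  expect_true(all(vegan$category == "100"))
  expect_true(all(vegan$plant_pct_protein == 100))
  carni <- score_records(one_person_week("milk"), persons, tiny_table())
  expect_true(all(carni$category == "0-27"))
  expect_true(all(carni$plant_pct_protein == 0))
})

test_that("zero-protein meals are excluded from categorization with a count", {
  df <- tiny_foods_df()
  df$protein_g_per_100g[df$id == "mystery"] <- 0
  tab <- food_table(df)
  rec <- as_records(data.frame(person_id = "P1", day = 1,
                               meal_moment = c("BREAKFAST", "LUNCH"),
                               food_id = c("mystery", "bread"),
                               mass_g = c(200, 100)))
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  expect_message(s <- score_records(rec, persons, tab), "uncategorized")
  expect_equal(attr(s, "n_uncategorized"), 1L)
  expect_true(is.na(s$category[s$meal_moment == "BREAKFAST"]))
})

test_that("category assignment ignores portion order within the meal", {
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  base <- data.frame(person_id = "P1", day = 1, meal_moment = "DINNER",
                     food_id = c("bread", "milk", "bread"),
                     mass_g = c(50, 150, 90))
  s1 <- score_records(as_records(base), persons, tiny_table())
  s2 <- score_records(as_records(base[c(3, 1, 2), ]), persons, tiny_table())
  expect_equal(s1$category, s2$category)
  expect_equal(s1$mpqs, s2$mpqs)
  expect_equal(s1$plant_pct_protein, s2$plant_pct_protein)
})

test_that("digestibility impact is zero when all factors are one", {
  df <- tiny_foods_df()[1:2, ]
  df$digestibility_pct <- 100
  tab <- food_table(df)
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  s <- score_records(one_person_week(), persons, tab)
  expect_true(all(s$digestibility_impact_pct == 0))
  expect_equal(s$mpqs, s$mpqs_nodig)
})

test_that("batch scoring equals per-meal scoring on sampled groups", {
  st <- default_study()
  s <- st$summaries
  set.seed(77)
  for (i in sample(nrow(s), 25)) {
    row <- s[i, ]
    portions <- st$records[
      st$records$person_id == row$person_id &
      st$records$day == row$day &
      st$records$meal_moment == as.character(row$meal_moment),
      c("food_id", "mass_g")]
    w <- st$persons$body_weight_kg[st$persons$person_id == row$person_id]
    res <- score_meal(portions, st$table, meal_requirements(w))
    expect_equal(row$mpqs, res$mpqs, tolerance = 1e-12)
    expect_equal(row$limiting_eaa, res$limiting_eaa)
    expect_equal(row$total_protein_g, res$total_protein_g, tolerance = 1e-12)
  }
})

test_that("moment summaries order moments and handle single-meal cells", {
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  rec <- as_records(data.frame(person_id = "P1", day = 1,
                               meal_moment = "LUNCH",
                               food_id = "milk", mass_g = 300))
  s <- score_records(rec, persons, tiny_table())
  m <- moment_summary(s)
  expect_true(all(is.na(m$stats$sem)))
  expect_equal(m$stats$n, c(1, 1))
  expect_equal(m$paired$decrease, s$mpqs_nodig - s$mpqs)

  st <- default_study()
  stats <- moment_summary(st$summaries)$stats
  wd <- stats[stats$adjustment == "with_digestibility", ]
  expect_equal(as.character(wd$meal_moment),
               c("BREAKFAST", "LUNCH", "DINNER"))
  # the synthetic cohort loads animal protein at dinner
  expect_gt(wd$mean[wd$meal_moment == "DINNER"],
            wd$mean[wd$meal_moment == "BREAKFAST"])
})

test_that("limiting frequencies are percentages of limited meals", {
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  s <- score_records(one_person_week("bread"), persons, tiny_table())
  lf <- limiting_frequency(s, by = "moment")
  expect_true(all(lf$freq$limiting_eaa == "LYS"))
  expect_true(all(lf$freq$pct == 100))
  expect_true(all(lf$adequate$n_adequate == 0))

  st <- default_study()
  for (by in c("moment", "category")) {
    lf <- limiting_frequency(st$summaries, by = by)
    sums <- tapply(lf$freq$pct_rounded, lf$freq$group, sum)
    expect_true(all(abs(sums - 100) <= 1), info = by)
    # every categorized meal lands in exactly one group row
    grp <- if (by == "moment") st$summaries$meal_moment else st$summaries$category
    n_expected <- sum(!is.na(grp))
    expect_equal(sum(lf$freq$n) + sum(lf$adequate$n_adequate), n_expected)
  }
})

test_that("person summaries compute medians, adequacy rates, and missed protein", {
  tab <- tiny_table()
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  # a milk-only meal covers ~0.234% of requirement per gram (valine
  # limiting), so 300 g stays below 100 and 500 g exceeds it
  rec <- as_records(data.frame(
    person_id = "P1", day = c(1, 2, 2),
    meal_moment = c("LUNCH", "LUNCH", "SNACK"),
    food_id = "milk", mass_g = c(300, 500, 740)))
  s <- score_records(rec, persons, tab)
  expect_equal(sum(s$mpqs >= 100), 1)
  ps <- person_summary(s, rec, persons, tab)
  p <- ps$persons
  expect_equal(p$n_meals, 2L)
  expect_equal(p$pct_meals_ge_100, 50)
  expect_equal(p$median_mpqs, mean(sort(s$mpqs)), tolerance = 1e-12)
  # snack protein 740 g milk * 3.5% = 25.9 g on day 2 -> missed > 20 g
  expect_equal(p$n_days_missed_gt20, 1L)
  expect_equal(p$missed_protein_g_per_day, 740 * 3.5 / 100 / 2)
  expect_equal(p$protein_g_per_day, (300 + 500 + 740) * 3.5 / 100 / 2)

  # a person with every meal comfortably above 100
  rec2 <- as_records(data.frame(person_id = "P2", day = 1:3,
                                meal_moment = "DINNER",
                                food_id = "milk", mass_g = 1500))
  persons2 <- data.frame(person_id = "P2", body_weight_kg = 70)
  s2 <- score_records(rec2, persons2, tab)
  p2 <- person_summary(s2, rec2, persons2, tab)$persons
  expect_equal(p2$pct_meals_ge_100, 100)
  expect_equal(p2$group, factor(">=100", levels = c("<100", ">=100")))
})

test_that("the split report stratifies persons at median MPQS 100", {
  st <- default_study()
  ps <- person_summary(st$summaries, st$records, st$persons, st$table)
  p <- ps$persons
  expect_equal(nrow(p), nrow(st$persons))
  expect_true(all(p$pct_meals_ge_100 >= 0 & p$pct_meals_ge_100 <= 100))
  expect_equal(as.character(p$group),
               ifelse(p$median_mpqs >= 100, ">=100", "<100"))
  split <- ps$split
  n_tot <- split$n[split$group == "total"][1]
  n_lo <- split$n[split$group == "<100"][1]
  n_hi <- split$n[split$group == ">=100"][1]
  expect_equal(n_lo + n_hi, n_tot)
  med <- split[split$variable == "median_mpqs", ]
  expect_gt(med$median[med$group == ">=100"], 100)
  expect_lt(med$median[med$group == "<100"], 100)
})

test_that("before-breakfast entries merge into breakfast only on request", {
  tab <- tiny_table()
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  rec <- as_records(data.frame(
    person_id = "P1", day = 1,
    meal_moment = c("BEFORE_BREAKFAST", "BREAKFAST"),
    food_id = c("milk", "bread"), mass_g = c(200, 60)))
  s_off <- score_records(rec, persons, tab)
  expect_equal(nrow(s_off), 1)
  expect_equal(s_off$n_portions, 1L)  # the early milk is not scored
  s_on <- score_records(rec, persons, tab, merge_before_breakfast = TRUE)
  expect_equal(nrow(s_on), 1)
  expect_equal(s_on$n_portions, 2L)
  expect_gt(s_on$mpqs, s_off$mpqs)
})

test_that("snacks are scored as meals only when requested", {
  tab <- tiny_table()
  persons <- data.frame(person_id = "P1", body_weight_kg = 70)
  rec <- as_records(data.frame(
    person_id = "P1", day = 1, meal_moment = c("LUNCH", "SNACK"),
    food_id = "milk", mass_g = c(300, 100)))
  expect_equal(nrow(score_records(rec, persons, tab)), 1)
  withs <- score_records(rec, persons, tab, include_snacks = TRUE)
  expect_equal(nrow(withs), 2)
  expect_true("SNACK" %in% as.character(withs$meal_moment))
})
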