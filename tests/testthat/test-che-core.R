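test_that("equivalized size is the power scale with sane boundaries", {
  expect_equal(equivalized_size(1, 0.56), 1)
  expect_equal(equivalized_size(4, 1.0), 4)
  expect_equal(equivalized_size(4, 0.56), 4^0.56)
  expect_error(equivalized_size(3, 0), "in \\(0, 1\\]")
  expect_error(equivalized_size(3, 1.2), "in \\(0, 1\\]")
  expect_error(equivalized_size(0, 0.56), ">= 1")
  ## concavity for beta < 1: increments shrink with size
  inc <- diff(equivalized_size(1:10, 0.56))
  expect_true(all(diff(inc) < 0))
})

test_that("food share is food over total, undefined at zero total", {
  df <- make_records(the = c(4800, 100, 100), food = c(2400, 0, 100))
  expect_equal(food_share(df), c(0.5, 0, 1))
  df0 <- make_records(the = c(100, 0), food = c(50, 0))
  expect_warning(s <- food_share(df0), "undefined food share")
  expect_equal(s, c(0.5, NA))
})

test_that("poverty line picks the crafted mid-window households", {
  ## shares ascending: ranks 5 and 6 (0.40 and 0.50) are exactly the
  ## 45-55 nearest-rank window of n = 10; their per-equivalent-adult
  ## food spending is 1000 and 1400
  shares <- c(0.05, 0.10, 0.15, 0.20, 0.40, 0.50, 0.60, 0.65, 0.70, 0.75)
  food <- c(100, 210, 330, 460, 1000, 1400, 660, 715, 770, 825)
  the <- food / shares
  df <- make_records(the, food)  # all size 1: per-eq food = food
  pl <- poverty_line(df, beta = 0.56, window = c(45, 55))
  expect_equal(pl$value_per_eq_adult, 1200)
  expect_equal(pl$n_reference, 2)
})

test_that("poverty line degenerate and symmetric cases", {
  ## all households identical: line equals the common per-eq-adult food
  df <- make_records(rep(3000, 8), rep(1200, 8), size = rep(4L, 8))
  pl <- poverty_line(df, beta = 0.56)
  expect_equal(pl$value_per_eq_adult, 1200 / 4^0.56)
  expect_equal(pl$n_reference, 8)
  ## single household is its own window
  one <- make_records(2000, 900, size = 3L)
  pl1 <- poverty_line(one, beta = 0.56)
  expect_equal(pl1$value_per_eq_adult, 900 / 3^0.56)
  expect_equal(pl1$n_reference, 1)
  ## all food zero is a degenerate line
  z <- make_records(c(100, 200), c(0, 0))
  expect_error(poverty_line(z), "degenerate")
  expect_error(poverty_line(make_records(100, 50), window = c(55, 45)),
               "lo < hi")
})

test_that("subsistence expenditure composes the line and the scale", {
  pl <- structure(list(value_per_eq_adult = 1200, window_lo = 45,
                       window_hi = 55, n_reference = 2, beta = 0.56),
                  class = "poverty_line")
  expect_equal(subsistence_expenditure(1, pl), 1200)
  expect_equal(subsistence_expenditure(4, pl, beta = 1), 4800)
  expect_equal(subsistence_expenditure(4, pl), 1200 * 4^0.56)
})

test_that("capacity to pay applies the food-substitution rule", {
  r <- capacity_to_pay(5000, 600, 1200)
  expect_equal(r$pc_h, 3800)
  expect_false(r$substitution_applied)
  ## negative THE - SE: fall back to THE - food
  r2 <- capacity_to_pay(1000, 600, 1500)
  expect_equal(r2$pc_h, 400)
  expect_true(r2$substitution_applied)
  ## boundary: zero is not negative, no substitution
  r3 <- capacity_to_pay(1000, 600, 1000)
  expect_equal(r3$pc_h, 0)
  expect_false(r3$substitution_applied)
  expect_error(capacity_to_pay(500, 600, 100), "integrity")
})

test_that("the CHE flag uses a closed >= boundary", {
  expect_equal(che_flag(30, 100, 0.30), 1L)
  expect_equal(che_flag(29.999, 100, 0.30), 0L)
  expect_equal(che_flag(0, 100, 0.10), 0L)
  ## zero capacity: catastrophic iff any OOP at all
  expect_warning(f <- che_flag(c(5, 0), c(0, 0), 0.30), "zero capacity")
  expect_equal(f, c(1L, 0L))
})

test_that("incidence is the flagged share with a Wilson interval", {
  flags <- c(rep(1L, 135), rep(0L, 252))
  inc <- che_incidence(flags, threshold = 0.30)
  expect_equal(inc$incidence_pct, 100 * 135 / 387)
  expect_equal(inc$n_che, 135)
  expect_true(inc$ci_lo < inc$incidence_pct &
                inc$incidence_pct < inc$ci_hi)
  ## Wilson matches prop.test's score interval
  ref <- prop.test(135, 387, correct = FALSE)$conf.int * 100
  expect_equal(c(inc$ci_lo, inc$ci_hi), as.numeric(ref))
  expect_equal(che_incidence(rep(0L, 10))$incidence_pct, 0)
  expect_equal(che_incidence(rep(1L, 10))$incidence_pct, 100)
  expect_error(che_incidence(integer(0)), "empty")
})

test_that("decomposition refuses monthly data and respects thresholds", {
  df <- make_records(c(5000, 800), c(2000, 600))
  expect_error(che_decompose(monthly_survey(df)), "annualize")
  dec <- che_decompose(annual_survey(df))
  expect_s3_class(dec, "che_decomposition")
  expect_named(
    dec,
    c("household_id", "the_h", "food_h", "eq_size", "se_h", "pc_h",
      "substitution_applied", "oop_h", "ratio",
      "flag_10", "flag_20", "flag_30", "flag_40"))
  expect_error(che_decompose(annual_survey(df),
                             thresholds = c(0.3, 0.2)), "ascending")
})

test_that("sensitivity table is one incidence row per threshold", {
  set.seed(5)
  oop <- matrix(runif(150 * 5, 0, 1500), 150, 5)
  the <- runif(150, 3000, 50000)
  df <- make_records(the, the * runif(150, 0.2, 0.8),
                     size = sample(1:6, 150, TRUE), oop = oop)
  survey <- annual_survey(df)
  tab <- sensitivity_analysis(survey)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$threshold, c(0.10, 0.20, 0.30, 0.40))
  expect_true(all(diff(tab$incidence_pct) <= 0))
  ## single threshold agrees with che_incidence on the same flags
  dec <- che_decompose(survey, thresholds = 0.30)
  one <- sensitivity_analysis(decomposition = dec, thresholds = 0.30)
  expect_equal(one, che_incidence(dec$flag_30, 0.30))
  ## no OOP spending at all: zero incidence everywhere
  df0 <- make_records(the, the * 0.4, size = sample(1:6, 150, TRUE))
  expect_true(all(sensitivity_analysis(annual_survey(df0))$incidence_pct
                  == 0))
})

test_that("poverty line and flags match the brute-force oracle", {
  set.seed(99)
  for (i in 1:25) {
    df <- random_small_records()
    dec <- che_decompose(annual_survey(df))
    o <- oracle_chain(df$expenditure_total, df$expenditure_food,
                      df$household_size, oop_total(df))
    expect_equal(attr(dec, "poverty_line")$value_per_eq_adult, o$pl,
                 tolerance = 0)
    expect_equal(dec$se_h, o$se, tolerance = 0)
    expect_equal(dec$pc_h, o$pc, tolerance = 0)
    expect_equal(dec$substitution_applied, o$substituted)
    expect_identical(dec$flag_30, o$flags[["flag_30"]])
  }
})

test_that("money scale invariance: flags unchanged under rescaling", {
  set.seed(123)
  df <- random_small_records(40)
  dec <- che_decompose(annual_survey(df))
  for (c0 in c(1e-6, 0.5, 3, 1e6)) {
    df2 <- df
    for (col in c("income", "expenditure_total", "expenditure_food",
                  "oop_consultation", "oop_hospitalization",
                  "oop_medicines", "oop_diagnostics", "oop_transport")) {
      df2[[col]] <- df2[[col]] * c0
    }
    dec2 <- che_decompose(annual_survey(df2))
    expect_identical(dec2$flag_10, dec$flag_10)
    expect_identical(dec2$flag_30, dec$flag_30)
    expect_equal(dec2$ratio, dec$ratio, tolerance = 1e-12)
  }
})

test_that("after substitution, capacity is positive when THE > food", {
  set.seed(31)
  ## engineered so large households fall below their subsistence level
  the <- c(runif(30, 20000, 60000), runif(20, 1500, 2500))
  food <- the * c(runif(30, 0.2, 0.5), runif(20, 0.85, 0.95))
  size <- c(sample(1:3, 30, TRUE), rep(10L, 20))
  df <- make_records(the, food, size = size)
  dec <- che_decompose(annual_survey(df))
  expect_gt(mean(dec$substitution_applied), 0)  # rule exercised
  expect_true(all(dec$pc_h[dec$the_h > dec$food_h] > 0))
})
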