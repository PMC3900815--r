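test_that("wide CSV read yields arithmetic midpoints and normalized order", {
  set.seed(11)
  years <- 1950:2001
  labels <- paste0(seq(45, 80, 5), "-", seq(49, 84, 5))
  rates <- matrix(exp(rnorm(52 * 8, 4.5, 0.3)), 52, 8)
  path <- write_demo_csv(rates, years, labels)
  s <- read_surface(path, "wide_age_rows")
  expect_equal(s$age_midpoints, c(47, 52, 57, 62, 67, 72, 77, 82))
  expect_length(s$years, 52)
  expect_equal(s$rates[3, 5], rates[3, 5], tolerance = 1e-9)
})

test_that("shuffled long CSV reads identically to the wide read", {
  set.seed(12)
  years <- 1990:1999
  labels <- c("45-49", "50-54", "55-59", "60-64")
  rates <- matrix(exp(rnorm(40, 4, 0.2)), 10, 4)
  wide <- read_surface(write_demo_csv(rates, years, labels), "wide_age_rows")
  df <- expand.grid(year = years, age_group = labels,
                    stringsAsFactors = FALSE)
  df$rate <- as.vector(rates)
  df <- df[sample(nrow(df)), ]
  lp <- tempfile(fileext = ".csv")
  utils::write.csv(df, lp, row.names = FALSE)
  long <- read_surface(lp, "long")
  expect_equal(long$rates, wide$rates, tolerance = 1e-9)
  expect_equal(long$years, wide$years)
  expect_equal(long$age_midpoints, wide$age_midpoints)
})

test_that("zero rates become missing with a warning; negatives are rejected", {
  rates <- matrix(c(10, 0, 12, 14, 15, 16, 17, 18), 2, 4)
  expect_warning(s <- mortality_surface(rates, 2000:2001, c(47, 52, 57, 62)),
                 "zero rate")
  expect_true(s$missing[2, 1])
  expect_true(is.na(s$rates[2, 1]))
  bad <- rates; bad[1, 1] <- -1
  expect_error(mortality_surface(bad, 2000:2001, c(47, 52, 57, 62)),
               "negative")
})

test_that("malformed age labels and non-contiguous years are rejected by name", {
  expect_error(parse_age_label_err <- read_surface(
    write_demo_csv(matrix(1:4, 2, 2), 2000:2001, c("45-49", "banana")),
    "wide_age_rows"), "banana")
  rates <- matrix(exp(rnorm(8)), 2, 4)
  df <- data.frame(age_group = c("45-49", "50-54", "55-59", "60-64"),
                   `2000` = rates[1, ], `2005` = rates[2, ],
                   check.names = FALSE)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_surface(p, "wide_age_rows"), "contiguous")
})

test_that("log transform takes ln of rates and propagates missingness", {
  rates <- matrix(c(20, 1, NA, 5, 6, 7, 8, 9), 2, 4)
  s <- mortality_surface(rates, 2000:2001, c(47, 52, 57, 62))
  lm <- log_transform(s)
  expect_equal(round(lm$logrates[1, 1], 4), 2.9957)
  expect_equal(lm$logrates[2, 1], 0)
  expect_true(is.na(lm$logrates[1, 2]))
  # exp recovers the source rates to high relative accuracy
  ok <- !lm$missing
  expect_equal(exp(lm$logrates[ok]), s$rates[ok], tolerance = 1e-12)
})

test_that("an all-missing column survives the log transform without error", {
  rates <- cbind(matrix(exp(rnorm(20, 4, 0.1)), 5, 4), NA_real_)
  s <- mortality_surface(rates, 2000:2004, c(47, 52, 57, 62, 67))
  lm <- log_transform(s)
  expect_true(all(is.na(lm$logrates[, 5])))
})

test_that("read/write round-trips are idempotent in all three dialects", {
  set.seed(13)
  rates <- matrix(exp(rnorm(24, 4, 0.3)), 6, 4)
  rates[2, 3] <- NA
  s <- mortality_surface(rates, 1995:2000, c("45-49", "50-54", "55-59", "60-64"))
  for (d in c("wide_age_rows", "wide_year_rows", "long")) {
    p <- tempfile(fileext = ".csv")
    write_surface(s, p, d)
    s2 <- read_surface(p, d)
    expect_equal(s2$rates, s$rates, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(s2$years, s$years)
    expect_equal(s2$missing, s$missing, ignore_attr = TRUE)
    # second round trip is exact
    p3 <- tempfile(fileext = ".csv")
    write_surface(s2, p3, d)
    s3 <- read_surface(p3, d)
    expect_equal(s3$rates, s2$rates, ignore_attr = TRUE)
  }
})

test_that("forecast CSV has one row per (year, age), records the level, and round-trips", {
  sim <- simulate_surface(generator_config(seed = 301))
  sc <- smooth_surface(log_transform(sim$surface))
  fb <- fit_fpca(sc, 1)
  m <- suppressWarnings(fit_ets_damped(fb$scores[, 1]))
  f <- forecast_surface(fb, list(m), sc, h = 20, level = 0.80)
  p <- tempfile(fileext = ".csv")
  df <- write_forecast(p, f)
  expect_equal(nrow(df), 20 * 8)
  expect_true(all(df$level == 0.80))
  back <- read_forecast(p)
  for (cl in c("point_rate", "lower", "upper")) {
    expect_equal(back[[cl]], df[[cl]], tolerance = 1e-9)
  }
  expect_error(read_forecast(tempfile()), "not found")
})
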