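test_that("a well-formed detections file round-trips and validates", {
  eff <- tiny_effort()
  det <- tiny_detections(list(
    list("N", "2020-01-05", "a"),
    list("N", "2020-01-06", "a"),
    list("S", "2020-02-10", "b")))
  path <- write_tiny_csv(det)
  tab <- read_detections(path, tiny_catalogue(), eff)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$present))

  # canonical write -> read -> write is byte-stable
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "one.csv"); p2 <- file.path(dir, "two.csv")
  write_detections(tab, p1)
  tab2 <- read_detections(p1, tiny_catalogue(), eff)
  write_detections(tab2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("validation errors name the offending row", {
  eff <- tiny_effort()
  det <- tiny_detections(list(
    list("N", "2020-01-05", "a"),
    list("N", "2020-01-06", "narwhal")))
  path <- write_tiny_csv(det)
  expect_error(read_detections(path, tiny_catalogue(), eff),
               "narwhal.*row 2")

  det <- tiny_detections(list(list("Atlantis", "2020-01-05", "a")))
  expect_error(read_detections(write_tiny_csv(det), tiny_catalogue(), eff),
               "unknown site 'Atlantis'.*row 1")

  det <- tiny_detections(list(list("N", "2020-06-05", "a")))
  expect_error(read_detections(write_tiny_csv(det), tiny_catalogue(), eff),
               "outside the monitored effort")

  det <- tiny_detections(list(list("N", "2020-01-05", "a"),
                              list("N", "2020-01-05", "a")))
  expect_error(read_detections(write_tiny_csv(det), tiny_catalogue(), eff),
               "duplicated")
})

test_that("monthly binning counts, zero-fills and respects effort gaps", {
  # 15 detected of 31 monitored days in January
  jan_days <- seq(as.Date("2020-01-01"), as.Date("2020-01-31"), by = "day")
  eff <- data.frame(site = "N", date = jan_days)
  det <- data.frame(site = "N", date = jan_days[1:15], category = "a",
                    present = TRUE)
  ms <- bin_daily_to_monthly(det, eff, tiny_catalogue())
  row_a <- ms[ms$category == "a", ]
  expect_equal(row_a$days_detected, 15)
  expect_equal(row_a$days_monitored, 31)
  # never-detected categories appear zero-filled
  expect_equal(ms$days_detected[ms$category == "b"], 0)
  expect_equal(nrow(ms), 3)

  # gap month: 10 monitored days, all detected
  eff10 <- data.frame(site = "N", date = jan_days[10:19])
  det10 <- data.frame(site = "N", date = jan_days[10:19], category = "a",
                      present = TRUE)
  ms10 <- bin_daily_to_monthly(det10, eff10, tiny_catalogue())
  expect_equal(ms10$days_detected[ms10$category == "a"], 10)
  expect_equal(unique(ms10$days_monitored), 10)
})

test_that("binning conserves detections and ignores input row order", {
  sim <- generate_detections(mini_scenario(seed = 5))
  ms <- bin_daily_to_monthly(sim$detections, sim$effort,
                             default_categories())
  tot <- aggregate(days_detected ~ site + category, data = ms, FUN = sum)
  daily <- aggregate(present ~ site + category, data = sim$detections,
                     FUN = sum)
  m <- merge(tot, daily)
  expect_equal(m$days_detected, m$present)
  # months never merged across years; per-month detected <= monitored
  expect_true(all(ms$days_detected <= ms$days_monitored))
  expect_true(all(ms$days_monitored <= 31))

  shuf <- sim$detections[sample(nrow(sim$detections)), ]
  ms2 <- bin_daily_to_monthly(shuf, sim$effort, default_categories())
  expect_equal(ms2, ms)
})

test_that("site composition normalizes to 100 and handles edge cases", {
  jan <- seq(as.Date("2020-01-01"), as.Date("2020-01-31"), by = "day")
  feb <- seq(as.Date("2020-02-01"), as.Date("2020-02-29"), by = "day")
  eff <- data.frame(site = "N", date = c(jan, feb))

  # sole ever-present category scores 100%
  det <- data.frame(site = "N", date = c(jan, feb), category = "a",
                    present = TRUE)
  ms <- bin_daily_to_monthly(det, eff, tiny_catalogue())
  expect_equal(site_composition(ms, "N"), c(a = 100))

  # two categories with identical mean presence: 50/50
  det2 <- rbind(det, data.frame(site = "N", date = c(jan, feb),
                                category = "b", present = TRUE))
  ms2 <- bin_daily_to_monthly(det2, eff, tiny_catalogue())
  expect_equal(site_composition(ms2, "N"), c(a = 50, b = 50))

  # hand normalization: means 0.6 / 0.3 / 0.1 -> 60 / 30 / 10
  det3 <- rbind(
    data.frame(site = "N", date = jan[1:18], category = "a", present = TRUE),
    data.frame(site = "N", date = jan[1:9], category = "b", present = TRUE),
    data.frame(site = "N", date = jan[1:3], category = "c", present = TRUE))
  ms3 <- bin_daily_to_monthly(det3, data.frame(site = "N", date = jan[1:30]),
                              tiny_catalogue())
  expect_equal(site_composition(ms3, "N"), c(a = 60, b = 30, c = 10))

  # no detections at all: empty mapping
  ms0 <- bin_daily_to_monthly(det[0, ], eff, tiny_catalogue())
  expect_length(site_composition(ms0, "N"), 0)
  expect_error(site_composition(ms, "Atlantis"), "unknown site")
})

test_that("composition percentages sum to 100 at every site", {
  sim <- generate_detections(mini_scenario(seed = 2))
  ms <- bin_daily_to_monthly(sim$detections, sim$effort,
                             default_categories())
  comp <- composition_table(ms)
  sums <- tapply(comp$percent, comp$site, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
})
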