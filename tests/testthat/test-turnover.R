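test_that("effective number of species matches hand values and bounds", {
  expect_equal(ens(rep(0.25, 4)), 4)
  expect_equal(ens(1), 1)
  expect_equal(ens(c(0.5, 0.25, 0.25)), 1 / (0.25 + 0.0625 + 0.0625))
  expect_true(is.na(ens(numeric(0))))
  expect_error(ens(c(0.5, 0.2)), "sum to 1")

  # permutation-invariant, maximized at the uniform vector
  set.seed(1)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    p <- as.vector(stats::rmultinom(1, 50, runif(k))) / 50
    p <- p[p > 0]
    expect_equal(ens(sample(p)), ens(p))
    expect_lte(ens(p), length(p) + 1e-12)
    expect_gte(ens(p), 1 - 1e-12)
  }
  expect_equal(ens(rep(1 / 7, 7)), 7)
})

test_that("SERr takes its limit values and equals brute-force Jaccard", {
  expect_equal(serr(c("a", "b"), c("a", "b")), 0)
  expect_equal(serr(c("a", "b", "c"), c("d", "e")), 1)
  expect_equal(serr(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_true(is.na(serr(character(0), character(0))))
  expect_equal(serr(character(0), "a"), 1)

  # independent oracle: Jaccard dissimilarity from binary set algebra
  jaccard_oracle <- function(s1, s2) {
    u <- union(s1, s2)
    1 - length(intersect(s1, s2)) / length(u)
  }
  set.seed(42)
  pool <- letters[1:12]
  for (i in 1:300) {
    s1 <- sample(pool, sample(0:10, 1))
    s2 <- sample(pool, sample(1:10, 1))
    expect_equal(serr(s1, s2), jaccard_oracle(s1, s2), tolerance = 1e-15)
  }
})

test_that("SERr agrees with the vegan Jaccard implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  pool <- letters[1:10]
  for (i in 1:50) {
    s1 <- sample(pool, sample(1:9, 1))
    s2 <- sample(pool, sample(1:9, 1))
    m <- rbind(as.integer(pool %in% s1), as.integer(pool %in% s2))
    ref <- as.numeric(vegan::vegdist(m, method = "jaccard", binary = TRUE))
    expect_equal(serr(s1, s2), ref)
  }
})

test_that("SERa matches hand values, its limits, and stays in [0, 1]", {
  p <- c(a = 0.4, b = 0.3, c = 0.15, d = 0.1, e = 0.05)
  expect_equal(sera(p, p), 0)
  # disjoint supports: numerator equals denominator
  expect_equal(sera(c(a = 0.7, b = 0.3), c(c = 0.5, d = 0.5)), 1)
  # hand evaluation (2/9) / (4/9) for equal thirds with one species swapped
  expect_equal(sera(c(a = 1/3, b = 1/3, c = 1/3),
                    c(b = 1/3, c = 1/3, d = 1/3)), 0.5)
  expect_true(is.na(sera(setNames(numeric(0), character(0)), p)))

  set.seed(11)
  for (i in 1:200) {
    k1 <- sample(1:8, 1); k2 <- sample(1:8, 1)
    p1 <- setNames(as.vector(stats::rmultinom(1, 40, runif(k1))),
                   sample(letters[1:10], k1))
    p2 <- setNames(as.vector(stats::rmultinom(1, 40, runif(k2))),
                   sample(letters[1:10], k2))
    p1 <- p1[p1 > 0] / sum(p1); p2 <- p2[p2 > 0] / sum(p2)
    if (!length(p1) || !length(p2)) next
    v <- sera(p1, p2)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("SERa reduces to SERr for equi-proportional communities", {
  set.seed(23)
  for (i in 1:500) {
    pool <- letters[1:12]
    s1 <- sample(pool, sample(1:10, 1))
    s2 <- sample(pool, sample(1:10, 1))
    p1 <- setNames(rep(1 / length(s1), length(s1)), s1)
    p2 <- setNames(rep(1 / length(s2), length(s2)), s2)
    expect_equal(sera(p1, p2), serr(s1, s2), tolerance = 1e-12)
  }
})

test_that("turnover series pairs adjacent months and never bridges gaps", {
  jan <- seq(as.Date("2020-01-01"), as.Date("2020-01-31"), by = "day")
  feb <- seq(as.Date("2020-02-01"), as.Date("2020-02-29"), by = "day")
  mar <- seq(as.Date("2020-03-01"), as.Date("2020-03-31"), by = "day")

  # two identical fully-detected months: zero turnover
  eff <- data.frame(site = "N", date = c(jan, feb))
  det <- rbind(data.frame(site = "N", date = c(jan, feb), category = "a",
                          present = TRUE),
               data.frame(site = "N", date = c(jan, feb), category = "b",
                          present = TRUE))
  ms <- bin_daily_to_monthly(det, eff, tiny_catalogue())
  ts <- turnover_series(ms, "N")
  expect_equal(nrow(ts), 1)
  expect_equal(ts$delta_ens, 0)
  expect_equal(ts$serr, 0)
  expect_equal(ts$sera, 0)

  # unmonitored February: both pairs missing, never bridged
  eff2 <- data.frame(site = "N", date = c(jan, mar))
  det2 <- data.frame(site = "N", date = c(jan, mar), category = "a",
                     present = TRUE)
  ms2 <- bin_daily_to_monthly(det2, eff2, tiny_catalogue())
  ts2 <- turnover_series(ms2, "N")
  expect_equal(nrow(ts2), 2)  # jan-feb and feb-mar slots
  expect_true(all(is.na(ts2$serr)))
  expect_true(all(is.na(ts2$sera)))

  # 36 consecutive months -> 35 slots
  days36 <- seq(as.Date("2016-01-01"), as.Date("2018-12-31"), by = "day")
  eff3 <- data.frame(site = "N", date = days36)
  det3 <- data.frame(site = "N", date = days36, category = "a",
                     present = TRUE)
  ms3 <- bin_daily_to_monthly(det3, eff3, tiny_catalogue())
  expect_equal(nrow(turnover_series(ms3, "N")), 35)
})

test_that("per-category delta days reconcile with the monthly summary", {
  sim <- generate_detections(mini_scenario(seed = 4))
  ms <- bin_daily_to_monthly(sim$detections, sim$effort,
                             default_categories())
  dd <- delta_days_table(ms, "South A")
  sub <- ms[ms$site == "South A", ]
  for (i in sample(nrow(dd), 20)) {
    prev <- sub$days_detected[sub$month == dd$month_prev[i] &
                                sub$category == dd$category[i]]
    curr <- sub$days_detected[sub$month == dd$month_curr[i] &
                                sub$category == dd$category[i]]
    expect_equal(dd$delta_days[i], curr - prev)
  }
})

test_that("the LOESS trend reproduces constants and lines, and smooths noise", {
  x <- 1:40
  const <- smooth_trend(x, rep(2.5, 40))
  expect_equal(const$fitted, rep(2.5, 40), tolerance = 1e-8)

  lin <- smooth_trend(x, 0.3 * x - 1)
  expect_equal(lin$fitted, 0.3 * x - 1, tolerance = 1e-6)

  set.seed(3)
  noise <- rnorm(40, sd = 0.4)
  y <- sin(2 * pi * x / 20) + noise
  sm <- smooth_trend(x, y, span = 0.25)
  expect_lt(var(y - sm$fitted), var(noise))

  expect_warning(out <- smooth_trend(1:3, c(1, 2, 3)), "too few")
  expect_null(out)
})
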