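test_that("independence test degenerates correctly", {
  y <- factor(rep(c("A", "B"), each = 10))
  # constant covariate: no association possible
  r <- independence_test(rep(3, 20), y)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # constant response
  r2 <- independence_test(rnorm(20), factor(rep("A", 20)))
  expect_equal(r2$p.value, 1)
})

test_that("perfect separation at n = 60 is significant under permutation", {
  x <- rep(c(0, 5), each = 30)
  y <- factor(rep(c("A", "B"), each = 30))
  set.seed(1)
  r_mc <- independence_test(x, y, type = "monte_carlo", mc_reps = 10000)
  expect_lt(r_mc$p.value, 0.05)
  r_as <- independence_test(x, y)
  expect_lt(r_as$p.value, 0.05)
})

test_that("asymptotic p-values track the Monte-Carlo permutation oracle", {
  set.seed(5)
  for (i in 1:6) {
    n <- 100
    y <- factor(sample(rep(letters[1:4], n / 4)))
    x <- rpois(n, 4) + (i %% 2) * (y %in% c("a", "b")) * rpois(n, 1)
    pa <- independence_test(x, y)$p.value
    pm <- independence_test(x, y, type = "monte_carlo",
                            mc_reps = 10000)$p.value
    expect_lt(abs(pa - pm), 0.02)
  }
})

test_that("c_quad equals the squared standardized statistic for 2 levels", {
  set.seed(2)
  x <- rnorm(50)
  y <- factor(sample(rep(c("A", "B"), 25)))
  r <- independence_test(x, y)
  # closed form: z = (T_A - mu_A) / sd_A, c_quad = z^2, df = 1
  z <- (r$T[1] - r$mu[1]) / sqrt(r$Sigma[1, 1])
  expect_equal(r$statistic, z^2, tolerance = 1e-10)
  expect_equal(r$df, 1L)
})

test_that("observation assembly filters guilds and drops unmonitored months", {
  sim <- generate_detections(mini_scenario(seed = 6))
  ms <- bin_daily_to_monthly(sim$detections, sim$effort,
                             default_categories())
  obs <- assemble_observations(ms)
  # 3 sites x 8 fully monitored months, 14 covariates (mixed excluded)
  expect_equal(nrow(obs), 24)
  expect_length(attr(obs, "covariates"), 14)
  expect_false("bw_mixed" %in% attr(obs, "covariates"))
  obs_mix <- assemble_observations(ms, include_mixed = TRUE)
  expect_length(attr(obs_mix, "covariates"), 15)

  # mysticete-only covariate set
  obs_m <- assemble_observations(ms, include_guilds = "mysticete")
  expect_setequal(attr(obs_m, "covariates"),
                  c("blue", "fin", "humpback", "right", "sei"))

  # a site-month with zero effort contributes no row
  gaps <- list(`North A` = data.frame(start = as.Date("2016-06-01"),
                                      end = as.Date("2016-06-30")))
  sim2 <- generate_detections(mini_scenario(seed = 6, gaps = gaps))
  ms2 <- bin_daily_to_monthly(sim2$detections, sim2$effort,
                              default_categories())
  obs2 <- assemble_observations(ms2)
  expect_equal(nrow(obs2), 23)
  expect_false(any(obs2$site == "North A" & obs2$month == "2016-06"))

  expect_error(assemble_observations(ms[ms$site == "South A", ]),
               "at least 2 sites")
})

test_that("variable selection stops on constants and small nodes", {
  n <- 40
  X <- matrix(3, nrow = n, ncol = 2, dimnames = list(NULL, c("u", "v")))
  y <- factor(rep(c("A", "B"), each = n / 2))
  ctl <- citree_control(minsplit = 10, minbucket = 5)
  expect_null(pamdiv:::select_variable(X, y, rep(1, n), seq_len(n), ctl))

  # planted separator among noise covariates is selected
  set.seed(8)
  X2 <- matrix(rpois(60 * 8, 3), nrow = 60,
               dimnames = list(NULL, paste0("n", 1:8)))
  colnames(X2)[4] <- "planted"
  y2 <- factor(rep(c("A", "B"), each = 30))
  X2[, 4] <- rep(c(0, 6), each = 30) + rpois(60, 0.3)
  sel <- pamdiv:::select_variable(X2, y2, rep(1, 60), 1:60,
                                  citree_control(minsplit = 10, minbucket = 5))
  expect_equal(colnames(X2)[sel$var], "planted")
  expect_gte(sel$p_adjusted, sel$p_raw)

  # node weight below minsplit stops before testing
  fit <- citree(y ~ x, data = data.frame(
    y = factor(rep(c("A", "B"), each = 30)), x = rep(c(0, 5), each = 30)),
    control = citree_control(minsplit = 61, minbucket = 15))
  expect_length(fit$nodes, 1)
})

test_that("cutpoint search uses midpoints, minbucket and the tie rule", {
  # perfect 0/5 separation: midpoint 2.5
  x <- rep(c(0, 5), each = 10)
  y <- rep(c("A", "B"), each = 10)
  expect_equal(pamdiv:::find_split(x, y, rep(1, 20), minbucket = 5), 2.5)
  # minbucket too large: no admissible cutpoint
  expect_null(pamdiv:::find_split(x, y, rep(1, 20), minbucket = 11))
  # symmetric configuration: tie broken toward the smaller cutpoint
  xs <- c(1, 1, 2, 2, 3, 3)
  ys <- c("A", "A", "B", "B", "A", "A")
  expect_equal(pamdiv:::find_split(xs, ys, rep(1, 6), minbucket = 1), 1.5)
})

test_that("integer presence/absence splits render as '> 0'", {
  df <- data.frame(
    y = factor(rep(c("A", "B"), each = 40)),
    x = c(rep(0, 40), rep(c(1, 3, 5, 8), 10)))
  fit <- citree(y ~ x, data = df,
                control = citree_control(minsplit = 20, minbucket = 10))
  expect_equal(fit$nodes[[1]]$split$cutpoint, 0.5)
  txt <- capture.output(print(fit))
  expect_true(any(grepl("x > 0:", txt, fixed = TRUE)))
})

test_that("fitted trees are deterministic and permutation-equivariant", {
  sim <- generate_detections(mini_scenario(seed = 10))
  ms <- bin_daily_to_monthly(sim$detections, sim$effort,
                             default_categories())
  obs <- assemble_observations(ms)
  ctl <- citree_control(minsplit = 10, minbucket = 5)
  f1 <- citree(site ~ . - month, data = obs, control = ctl)
  f2 <- citree(site ~ . - month, data = obs, control = ctl)
  expect_identical(citree_nodes(f1), citree_nodes(f2))

  # relabelling sites permutes terminal distributions, preserves shape
  obs_r <- obs
  obs_r$site <- factor(as.character(obs_r$site),
                       levels = rev(levels(obs_r$site)))
  f3 <- citree(site ~ . - month, data = obs_r, control = ctl)
  n1 <- citree_nodes(f1); n3 <- citree_nodes(f3)
  expect_equal(n1$variable, n3$variable)
  expect_equal(n1$cutpoint, n3$cutpoint)
  for (lev in levels(obs$site))
    expect_equal(n1[[paste0("p_", lev)]], n3[[paste0("p_", lev)]])
})

test_that("tree invariants hold: partitions, minbucket, probability sums", {
  sim <- generate_detections(shelfbreak_scenario(seed = 2))
  ms <- bin_daily_to_monthly(sim$detections, sim$effort)
  obs <- assemble_observations(ms)
  fit <- citree(site ~ . - month, data = obs, control = tree_config("full"))
  nd <- citree_nodes(fit)
  term <- nd[nd$type == "terminal", ]
  expect_true(all(term$weight >= 15))
  # children partition the parent's weight
  for (i in which(nd$type == "split"))
    expect_equal(nd$weight[i],
                 nd$weight[nd$id == nd$kid_left[i]] +
                   nd$weight[nd$id == nd$kid_right[i]])
  # terminal distributions sum to 1
  pcols <- paste0("p_", fit$levels)
  expect_equal(rowSums(term[pcols]), rep(1, nrow(term)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # predict() reproduces the training partition
  nodes <- predict(fit, obs, type = "node")
  w <- table(factor(nodes, levels = term$id))
  expect_equal(as.numeric(w), term$weight)
  probs <- predict(fit, obs, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(obs)))
})

test_that("stump rendering prints three nodes and exports round-trip", {
  sim <- generate_detections(shelfbreak_scenario(seed = 2))
  ms <- bin_daily_to_monthly(sim$detections, sim$effort)
  obs <- assemble_observations(ms)
  fit <- citree(site ~ . - month, data = obs, control = tree_config("stump"))
  expect_length(fit$nodes, 3)
  txt <- capture.output(print(fit))
  expect_length(grep("\\[[0-9]+\\]", txt), 3)

  nd <- citree_nodes(fit)
  json <- jsonlite::toJSON(nd, dataframe = "rows", digits = NA)
  back <- jsonlite::fromJSON(json)
  expect_equal(back$variable[1], nd$variable[1])
  expect_equal(back$cutpoint[1], nd$cutpoint[1])
  pcols <- paste0("p_", fit$levels)
  expect_equal(back[back$type == "terminal", pcols],
               nd[nd$type == "terminal", pcols],
               tolerance = 1e-12, ignore_attr = TRUE)
})
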