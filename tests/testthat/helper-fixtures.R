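# Small in-code fixtures shared across tests.

# two sites, three categories, fully monitored January + February 2020
tiny_catalogue <- function() {
  data.frame(
    id = c("a", "b", "c"),
    label = c("Species A", "Species B", "Species C"),
    guild = c("mysticete", "beaked_whale", "other_odontocete"),
    kind = "species",
    stringsAsFactors = FALSE)
}

tiny_effort <- function(sites = c("N", "S"),
                        days = seq(as.Date("2020-01-01"),
                                   as.Date("2020-02-29"), by = "day")) {
  do.call(rbind, lapply(sites, function(s)
    data.frame(site = s, date = days, stringsAsFactors = FALSE)))
}

tiny_detections <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(site = r[[1]], date = as.Date(r[[2]]), category = r[[3]],
               present = TRUE, stringsAsFactors = FALSE)))
  df[order(df$site, df$date, df$category), , drop = FALSE]
}

write_tiny_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "detections.csv")
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a scenario small enough for fast end-to-end runs: 3 sites, 4 categories,
# 8 months, with the same planted south-only structure as the full scenario
mini_scenario <- function(seed = 1, gaps = list()) {
  sites <- data.frame(
    name = c("North A", "North B", "South A"),
    latitude = c(41, 39, 33),
    longitude = c(-66, -70, -76),
    depth = c(900, 950, 900))
  models <- list(
    occupancy_model("gervais", p_base = 0.6, lat_center = 37, lat_width = 1,
                    side = "south_of"),
    occupancy_model("fin", p_base = 0.6, season_amp = 0.95, season_phase = 15),
    occupancy_model("sperm", p_base = 0.7),
    occupancy_model("delphinid", p_base = 0.8))
  community_scenario(sites, models, start = as.Date("2016-04-01"),
                     end = as.Date("2016-11-30"), gaps = gaps, seed = seed)
}

north_sites <- function() c("Heezen Canyon", "Oceanographer Canyon",
                            "Nantucket Canyon", "Babylon Canyon",
                            "Wilmington Canyon")
south_sites <- function() c("Norfolk Canyon", "Hatteras", "Gulf Stream",
                            "Blake Plateau", "Blake Spur")

# dominant side (terminal node id) of each site under a fitted stump
stump_site_sides <- function(fit, obs) {
  nodes <- predict(fit, obs, type = "node")
  tapply(nodes, obs$site, function(v) names(which.max(table(v))))
}

# TRUE when a stump groups the five southern sites against the five northern
stump_splits_north_south <- function(fit, obs) {
  side <- stump_site_sides(fit, obs)
  all(side[south_sites()] == side[south_sites()][1]) &&
    all(side[north_sites()] == side[north_sites()][1]) &&
    side[south_sites()][1] != side[north_sites()][1]
}

# peak lag of the detrended autocorrelation over sub-annual lags 2..9
subannual_acf_peak <- function(y, lag.max = 9) {
  y <- y - mean(y, na.rm = TRUE)
  a <- stats::acf(y, lag.max = lag.max, na.action = stats::na.pass,
                  plot = FALSE)$acf[-1]
  which.max(a[2:lag.max]) + 1
}
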