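#' Category occupancy model
#'
#' Specifies the daily detection probability of one detection category in the
#' synthetic community. The realized probability on a given day at a given
#' site is
#' `clamp(p_base * seasonal(date) * range(latitude) * trend(date), 0, 1)`
#' where
#' `seasonal(d) = 1 - season_amp * (1 - cos(2*pi*(doy - season_phase)/365.25))/2`
#' (equal to 1 at the seasonal peak `season_phase`, and to `1 - season_amp` at
#' the trough), `range(lat)` is a logistic step of width `lat_width` centred
#' at `lat_center` on the stated `side` (identically 1 when `lat_center` is
#' `NULL`; a hard indicator when `lat_width = 0`), and
#' `trend(d) = trend^(years since the scenario origin)` is a per-year
#' multiplicative change.
#'
#' @param category Category id (must exist in the scenario catalogue).
#' @param p_base Daily detection probability inside the range at the seasonal
#'   peak, in \[0, 1\].
#' @param season_amp Seasonal amplitude in \[0, 1\]; 0 means no seasonality.
#' @param season_phase Day of year (1-366) of peak presence.
#' @param lat_center Latitudinal range boundary in degrees N, or `NULL` for no
#'   boundary.
#' @param lat_width Width (degrees) of the logistic transition at the
#'   boundary; `0` gives a hard boundary.
#' @param side `"south_of"` (present south of the boundary), `"north_of"`, or
#'   `"none"`.
#' @param trend Per-year multiplicative change in detection probability
#'   (1 = stationary).
#' @param persistence Day-to-day persistence in \[0, 1) of a 2-state Markov
#'   chain with the stated marginal probability; 0 (default) draws days
#'   independently. Real acoustic presence is bursty; this lets tests show
#'   monthly binning absorbing that burstiness.
#' @return An object of class `occupancy_model`.
#' @export
#' @examples
#' m <- occupancy_model("gervais", p_base = 0.65, lat_center = 38,
#'                      lat_width = 1, side = "south_of")
#' daily_probability(m, latitude = 33, date = as.Date("2017-06-01"))
occupancy_model <- function(category, p_base, season_amp = 0, season_phase = 1,
                            lat_center = NULL, lat_width = 1,
                            side = c("none", "south_of", "north_of"),
                            trend = 1, persistence = 0) {
  side <- match.arg(side)
  stopifnot(p_base >= 0, p_base <= 1, season_amp >= 0, season_amp <= 1,
            lat_width >= 0, trend > 0, persistence >= 0, persistence < 1)
  if (!is.null(lat_center) && side == "none")
    stop("lat_center given but side is 'none'")
  structure(list(category = category, p_base = p_base,
                 season_amp = season_amp, season_phase = season_phase,
                 lat_center = lat_center, lat_width = lat_width, side = side,
                 trend = trend, persistence = persistence),
            class = "occupancy_model")
}

#' Realized daily detection probability
#'
#' @param model An [occupancy_model()].
#' @param latitude Site latitude, decimal degrees N.
#' @param date Date vector.
#' @param origin Reference date for the per-year trend term.
#' @return Numeric vector of probabilities in \[0, 1\], one per date.
#' @export
daily_probability <- function(model, latitude, date,
                              origin = as.Date("2016-01-01")) {
  doy <- as.POSIXlt(date)$yday + 1
  seasonal <- 1 - model$season_amp *
    (1 - cos(2 * pi * (doy - model$season_phase) / 365.25)) / 2
  rng <- latitudinal_range(model, latitude)
  tr <- model$trend ^ (as.numeric(date - origin) / 365.25)
  pmin(pmax(model$p_base * seasonal * rng * tr, 0), 1)
}

latitudinal_range <- function(model, latitude) {
  if (is.null(model$lat_center) || model$side == "none") return(1)
  signed <- switch(model$side,
                   south_of = model$lat_center - latitude,
                   north_of = latitude - model$lat_center)
  if (model$lat_width == 0) return(as.numeric(signed > 0))
  # scale width/4: the transition from ~0.12 to ~0.88 spans about lat_width
  stats::plogis(signed / (model$lat_width / 4))
}

#' Synthetic community scenario
#'
#' Bundles everything needed to generate a reproducible daily detection table:
#' site metadata, per-category occupancy models, a date range, per-site
#' recording gaps and a seed. Identical scenario + seed always yields an
#' identical table.
#'
#' @param sites Site metadata data frame (`name`, `latitude`, `longitude`,
#'   optionally `depth`).
#' @param models List of [occupancy_model()] objects.
#' @param start,end First and last calendar day of monitoring (Dates).
#' @param gaps Named list (by site) of data frames with columns `start`,
#'   `end` (Dates): intervals with no monitoring effort.
#' @param catalogue Category catalogue; categories referenced by `models`
#'   must exist in it.
#' @param seed Integer seed for [generate_detections()].
#' @return An object of class `community_scenario`.
#' @export
community_scenario <- function(sites, models, start, end, gaps = list(),
                               catalogue = default_categories(), seed = 1L) {
  sites <- validate_sites(sites)
  ids <- vapply(models, function(m) m$category, character(1))
  unknown <- setdiff(ids, catalogue$id)
  if (length(unknown))
    stop("occupancy models reference categories not in the catalogue: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(ids))
    stop("more than one occupancy model for: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stopifnot(inherits(start, "Date"), inherits(end, "Date"), start <= end)
  structure(list(sites = sites, models = models, start = start, end = end,
                 gaps = gaps, catalogue = catalogue, seed = as.integer(seed)),
            class = "community_scenario")
}

#' @export
print.community_scenario <- function(x, ...) {
  cat("Synthetic community scenario\n")
  cat("  sites:      ", nrow(x$sites), " (",
      paste(range(x$sites$latitude), collapse = "-"), " deg N)\n", sep = "")
  cat("  categories: ", length(x$models), "\n", sep = "")
  cat("  period:     ", format(x$start), " to ", format(x$end), "\n", sep = "")
  cat("  seed:       ", x$seed, "\n", sep = "")
  invisible(x)
}

effort_days <- function(scenario, site) {
  days <- seq(scenario$start, scenario$end, by = "day")
  g <- scenario$gaps[[site]]
  if (!is.null(g) && nrow(g)) {
    drop <- rep(FALSE, length(days))
    for (i in seq_len(nrow(g)))
      drop <- drop | (days >= g$start[i] & days <= g$end[i])
    days <- days[!drop]
  }
  days
}

#' Generate a daily detection table from a scenario
#'
#' Draws each (site, monitored day, category) independently as
#' `Bernoulli(daily_probability)` (or from a 2-state Markov chain with the
#' same marginal probability when the model's `persistence` is positive).
#' Gap days carry no effort and no detections. The draw order is fixed, so
#' the output is fully determined by the scenario and its seed.
#'
#' @param scenario A [community_scenario()].
#' @return List with elements `detections` (positive records: `site`, `date`,
#'   `category`, `present`) and `effort` (`site`, `date`).
#' @export
generate_detections <- function(scenario) {
  set.seed(scenario$seed)
  det <- vector("list", nrow(scenario$sites) * length(scenario$models))
  eff <- vector("list", nrow(scenario$sites))
  k <- 0L
  for (i in seq_len(nrow(scenario$sites))) {
    site <- scenario$sites$name[i]
    lat <- scenario$sites$latitude[i]
    days <- effort_days(scenario, site)
    eff[[i]] <- data.frame(site = site, date = days, stringsAsFactors = FALSE)
    for (m in scenario$models) {
      p <- daily_probability(m, lat, days, origin = scenario$start)
      hit <- draw_presence(p, m$persistence)
      k <- k + 1L
      if (any(hit))
        det[[k]] <- data.frame(site = site, date = days[hit],
                               category = m$category, present = TRUE,
                               stringsAsFactors = FALSE)
    }
  }
  detections <- do.call(rbind, det[!vapply(det, is.null, logical(1))])
  if (is.null(detections))
    detections <- data.frame(site = character(0), date = as.Date(character(0)),
                             category = character(0), present = logical(0))
  detections <- detections[order(detections$site, detections$date,
                                 detections$category), , drop = FALSE]
  rownames(detections) <- NULL
  list(detections = detections, effort = do.call(rbind, eff))
}

draw_presence <- function(p, persistence) {
  n <- length(p)
  if (persistence == 0) return(runif(n) < p)
  # 2-state Markov chain with marginal p_t and lag-1 correlation `persistence`
  out <- logical(n)
  out[1] <- runif(1) < p[1]
  u <- runif(n - 1)
  for (t in seq_len(n - 1) + 1) {
    pt <- p[t]
    ptrans <- if (out[t - 1]) pt + persistence * (1 - pt)
              else pt * (1 - persistence)
    out[t] <- u[t - 1] < ptrans
  }
  out
}

#' Shelf-break study scenario
#'
#' The package's reference synthetic community: 10 shelf-break monitoring
#' sites spanning about 30.5-41°N monitored continuously from April 2016 to
#' June 2019 with short per-site redeployment gaps, and 15 detection
#' categories with the occupancy structure of a western North Atlantic
#' shelf-break cetacean community:
#' \itemize{
#'   \item Gervais'- and Blainville's-like beaked whales present year-round
#'     only at the five sites south of the ~38°N Wilmington/Norfolk divide
#'     (the planted latitudinal split);
#'   \item Sowerby's- and True's-like beaked whales only north of ~38°N, and
#'     a goose-beaked-whale-like category at all sites;
#'   \item five mysticete categories with strong staggered seasonal peaks in
#'     two cohorts about half a year apart (a rarely detected right-whale-like
#'     category among them), so seasonal dominance turns over twice a year;
#'   \item ubiquitous year-round sperm-whale-like and grouped-delphinid
#'     categories, plus Kogia-like (southern) and Risso's-like (northern)
#'     categories with wide, soft range preferences.
#' }
#'
#' @param seed Integer seed; fixes both the gap placement and the Bernoulli
#'   draws of [generate_detections()].
#' @param boundary `"logistic"` (default; 1° soft transition, so the planted
#'   38°N split is recoverable but not degenerate) or `"hard"` (strict
#'   indicator boundaries, useful for by-construction tests).
#' @return A [community_scenario()].
#' @export
#' @examples
#' sc <- shelfbreak_scenario(seed = 42)
#' sim <- generate_detections(sc)
#' nrow(sim$detections)
shelfbreak_scenario <- function(seed = 1L, boundary = c("logistic", "hard")) {
  boundary <- match.arg(boundary)
  w <- function(width) if (boundary == "hard") 0 else width
  sites <- shelfbreak_sites()
  start <- as.Date("2016-04-01")
  end <- as.Date("2019-06-30")

  models <- list(
    # mysticetes: strong staggered seasonality in two cohorts about half a
    # year apart, so seasonal dominance alternates twice per year, basin-wide
    occupancy_model("fin",      p_base = 0.70, season_amp = 0.95, season_phase = 15),
    occupancy_model("sei",      p_base = 0.50, season_amp = 0.95, season_phase = 45),
    occupancy_model("right",    p_base = 0.08, season_amp = 0.90, season_phase = 45),
    occupancy_model("humpback", p_base = 0.50, season_amp = 0.95, season_phase = 198),
    occupancy_model("blue",     p_base = 0.45, season_amp = 0.95, season_phase = 228),
    # beaked whales: narrow latitudinal ranges, mostly year-round; the
    # Gervais'/Blainville's boundary sits between the Wilmington and Norfolk
    # latitudes so northern leakage through the soft edge stays negligible
    occupancy_model("gervais",    p_base = 0.65, lat_center = 37.6,
                    lat_width = w(1), side = "south_of"),
    occupancy_model("blainville", p_base = 0.40, lat_center = 37.6,
                    lat_width = w(1), side = "south_of"),
    occupancy_model("sowerby", p_base = 0.35, season_amp = 0.30,
                    season_phase = 200, lat_center = 38.0, lat_width = w(1.5),
                    side = "north_of"),
    occupancy_model("true", p_base = 0.30, season_amp = 0.30,
                    season_phase = 150, lat_center = 38.5, lat_width = w(2),
                    side = "north_of"),
    occupancy_model("cuvier", p_base = 0.45, season_amp = 0.20, season_phase = 180),
    occupancy_model("bw_mixed", p_base = 0.20),
    # other odontocetes: ubiquitous or wide soft range preferences
    occupancy_model("sperm",     p_base = 0.75),
    occupancy_model("delphinid", p_base = 0.85),
    occupancy_model("kogia", p_base = 0.35, lat_center = 36.0,
                    lat_width = w(3), side = "south_of"),
    occupancy_model("risso", p_base = 0.50, lat_center = 35.0,
                    lat_width = w(3), side = "north_of")
  )

  # short redeployment gaps near the two service turnarounds, jittered by seed
  set.seed(seed)
  gaps <- setNames(lapply(seq_len(nrow(sites)), function(i) {
    anchor <- start + round(c(365, 730) + runif(2, -45, 45))
    len <- round(runif(2, 7, 21))
    data.frame(start = anchor, end = anchor + len)
  }), sites$name)

  community_scenario(sites, models, start, end, gaps = gaps, seed = seed)
}
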