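#' Read and validate tables from CSV
#'
#' Readers for the four plain-text interchange files used by the pipeline:
#' `categories.csv` (`id,label,guild,kind`), `sites.csv`
#' (`name,latitude,longitude,depth`), `effort.csv` (`site,date`, one row per
#' monitored calendar day) and `detections.csv` (`site,date,category,present`).
#' Dates are ISO-8601 (`YYYY-MM-DD`). Files are UTF-8, comma-delimited, with a
#' header row.
#'
#' @param path Path to a CSV file.
#' @return A validated data frame.
#' @name detection_io
NULL

#' @rdname detection_io
#' @export
read_categories <- function(path) {
  validate_categories(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname detection_io
#' @export
read_sites <- function(path) {
  validate_sites(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname detection_io
#' @export
read_effort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("site", "date"), names(df))
  if (length(miss))
    stop("effort table is missing columns: ", paste(miss, collapse = ", "))
  df$date <- parse_iso_date(df$date, "effort")
  if (anyDuplicated(df[c("site", "date")]))
    stop("duplicated (site, date) rows in effort calendar")
  df[order(df$site, df$date), c("site", "date"), drop = FALSE]
}

parse_iso_date <- function(x, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1]
    stop("unparseable ISO-8601 date in ", what, " row ", bad, ": '", x[bad], "'")
  }
  d
}

#' Read a daily detection table
#'
#' Reads `detections.csv` (columns `site,date,category,present`) and validates
#' it against a category catalogue and a monitoring-effort calendar. Rows are
#' daily binary detections; a (site, day, category) combination omitted from
#' the file counts as "not detected" on monitored days, so canonical files
#' carry positive records only. Validation is strict: an unknown site or
#' category, a date outside the site's monitored days, or a duplicated
#' (site, date, category) combination is a hard error naming the offending
#' data row.
#'
#' @param path Path to a detections CSV.
#' @param catalogue Category catalogue data frame (see [default_categories()]).
#' @param effort Effort calendar data frame with columns `site`, `date`.
#' @return A data frame of positive detection records with columns `site`,
#'   `date` (Date), `category`, `present` (all `TRUE`), sorted by site, date,
#'   category.
#' @seealso [write_detections()] for the canonical on-disk form.
#' @export
read_detections <- function(path, catalogue, effort) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("site", "date", "category", "present"), names(df))
  if (length(miss))
    stop("detections table is missing columns: ", paste(miss, collapse = ", "))
  df$present <- parse_present(df$present)
  df$date <- parse_iso_date(df$date, "detections")
  validate_detections(df, catalogue, effort)
}

parse_present <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- v %in% c("true", "t", "1", "yes")
  bad <- !(v %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
  if (any(bad))
    stop("unparseable 'present' value in detections row ", which(bad)[1],
         ": '", x[which(bad)[1]], "'")
  out
}

validate_detections <- function(df, catalogue, effort) {
  bad <- !(df$category %in% catalogue$id)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown category '", df$category[i], "' in detections row ", i)
  }
  bad <- !(df$site %in% unique(effort$site))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown site '", df$site[i], "' in detections row ", i)
  }
  key <- paste(df$site, df$date)
  ekey <- paste(effort$site, effort$date)
  bad <- !(key %in% ekey)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("detections row ", i, " (", df$site[i], ", ", df$date[i],
         ") is outside the monitored effort calendar")
  }
  dup <- duplicated(df[c("site", "date", "category")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("duplicated (site, date, category) in detections row ", i)
  }
  out <- df[df$present, c("site", "date", "category"), drop = FALSE]
  out$present <- TRUE
  out <- out[order(out$site, out$date, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a daily detection table in canonical form
#'
#' Writes positive records only, sorted by (site, date, category), with ISO
#' dates and `present = TRUE`. Reading a canonical file back and re-writing it
#' is byte-stable.
#'
#' @param detections Detection data frame (as returned by [read_detections()]
#'   or [generate_detections()]).
#' @param path Output CSV path.
#' @export
write_detections <- function(detections, path) {
  df <- detections[detections$present, c("site", "date", "category"), drop = FALSE]
  df <- df[order(df$site, df$date, df$category), , drop = FALSE]
  df$present <- TRUE
  df$date <- format(df$date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize daily detections into monthly counts
#'
#' Bins a validated daily detection table into the monthly record that feeds
#' all downstream statistics: for every site, every calendar month with at
#' least one monitored day, and every catalogue category, the number of days
#' the category was detected (`days_detected`) and the number of days the site
#' was monitored (`days_monitored`). Categories never detected in a month are
#' zero-filled, and calendar months are never merged across years. Detection
#' counts are conserved: summed over months they equal the number of positive
#' daily records per (site, category).
#'
#' @param detections Positive daily detection records (`site`, `date`,
#'   `category`).
#' @param effort Effort calendar (`site`, `date`).
#' @param catalogue Category catalogue; defaults to [default_categories()].
#' @return A data frame with columns `site`, `month` (`"YYYY-MM"`),
#'   `category`, `days_detected`, `days_monitored`.
#' @export
#' @examples
#' sc <- shelfbreak_scenario(seed = 1)
#' sim <- generate_detections(sc)
#' ms <- bin_daily_to_monthly(sim$detections, sim$effort)
#' head(ms)
bin_daily_to_monthly <- function(detections, effort, catalogue = default_categories()) {
  effm <- data.frame(site = effort$site, month = format(effort$date, "%Y-%m"))
  dm <- aggregate(list(days_monitored = rep(1L, nrow(effm))),
                  by = effm[c("site", "month")], FUN = sum)
  # one row per (site, monitored month) x category, zero-filled
  grid <- merge(dm, data.frame(category = catalogue$id), by = NULL)
  if (nrow(detections)) {
    det <- data.frame(site = detections$site,
                      month = format(detections$date, "%Y-%m"),
                      category = detections$category)
    dd <- aggregate(list(days_detected = rep(1L, nrow(det))),
                    by = det[c("site", "month", "category")], FUN = sum)
    grid <- merge(grid, dd, by = c("site", "month", "category"), all.x = TRUE)
    grid$days_detected[is.na(grid$days_detected)] <- 0L
  } else {
    grid$days_detected <- 0L
  }
  stopifnot(all(grid$days_detected <= grid$days_monitored))
  out <- grid[order(grid$site, grid$month, grid$category),
              c("site", "month", "category", "days_detected", "days_monitored")]
  rownames(out) <- NULL
  out
}

#' Relative acoustic presence composition of a site
#'
#' Computes the normalized 0-100% composition of detection categories at one
#' site over the whole monitored period: for each category the mean over
#' monitored months of its monthly presence proportion
#' (`days_detected / days_monitored`), rescaled so the categories at the site
#' sum to 100. Using `days_monitored` rather than calendar days keeps monthly
#' proportions in \[0, 1\] under recording gaps. A category detected on every
#' monitored day at a site where nothing else is ever detected scores 100%.
#'
#' @param summary Monthly summary from [bin_daily_to_monthly()].
#' @param site Site name.
#' @return Named numeric vector of percentages summing to 100, or an empty
#'   vector when the site has no detections at all.
#' @export
site_composition <- function(summary, site) {
  sub <- summary[summary$site == site, , drop = FALSE]
  if (!nrow(sub))
    stop("unknown site '", site, "' (no monitored months in summary)")
  prop <- sub$days_detected / sub$days_monitored
  means <- c(tapply(prop, sub$category, mean))
  means <- means[!is.na(means) & means > 0]
  if (!length(means)) return(setNames(numeric(0), character(0)))
  pct <- 100 * means / sum(means)
  pct[order(names(pct))]
}

#' Composition of every site as a long table
#'
#' @param summary Monthly summary from [bin_daily_to_monthly()].
#' @return Data frame `site`, `category`, `percent`.
#' @export
composition_table <- function(summary) {
  sites <- unique(summary$site)
  out <- do.call(rbind, lapply(sites, function(s) {
    pct <- site_composition(summary, s)
    if (!length(pct)) return(NULL)
    data.frame(site = s, category = names(pct), percent = as.numeric(pct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
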