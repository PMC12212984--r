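#' Calling-frequency band table
#'
#' The niche display shades each species' daily presence only in the
#' frequency band it is known to call in. `default_bands()` ships a
#' placeholder table of plausible band extents per category — every row is
#' flagged `placeholder = TRUE` and users analysing real data must replace
#' the values with literature-derived bands for their species
#' (`read_bands()` accepts the same CSV layout). Colours follow the display
#' convention: mysticetes in red-orange, beaked whales in greens, other
#' odontocetes in blue-purple.
#'
#' @param path CSV with columns `category,f_low_hz,f_high_hz,colour`
#'   (optional `placeholder`).
#' @return Data frame `category`, `f_low_hz`, `f_high_hz`, `colour`,
#'   `placeholder`.
#' @name bands
NULL

#' @rdname bands
#' @export
default_bands <- function() {
  read_bands(system.file("extdata", "bands.csv", package = "pamdiv",
                         mustWork = TRUE))
}

#' @rdname bands
#' @export
read_bands <- function(path) {
  if (!file.exists(path)) stop("band table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("category", "f_low_hz", "f_high_hz", "colour"), names(df))
  if (length(miss))
    stop("band table is missing columns: ", paste(miss, collapse = ", "))
  if (any(df$f_low_hz <= 0 | df$f_high_hz <= df$f_low_hz))
    stop("bands must satisfy 0 < f_low_hz < f_high_hz")
  if (anyDuplicated(df$category))
    stop("duplicated category in band table")
  if (is.null(df$placeholder)) df$placeholder <- FALSE
  df
}

#' Maximal consecutive-day presence runs
#'
#' Collapses a category's detected days at one site into maximal runs of
#' consecutive calendar days. Any break in the day sequence — including an
#' unmonitored gap day — ends a run, and total run length always equals the
#' category's total detected days.
#'
#' @param detections Positive daily detection records.
#' @param site Site name.
#' @param category Category id.
#' @return Data frame `start`, `end` (Dates), possibly empty.
#' @export
presence_runs <- function(detections, site, category) {
  days <- sort(unique(detections$date[detections$site == site &
                                        detections$category == category &
                                        detections$present]))
  if (!length(days))
    return(data.frame(start = as.Date(character(0)),
                      end = as.Date(character(0))))
  brk <- c(TRUE, diff(days) > 1)
  grp <- cumsum(brk)
  data.frame(start = as.Date(as.vector(tapply(days, grp, min)),
                             origin = "1970-01-01"),
             end = as.Date(as.vector(tapply(days, grp, max)),
                           origin = "1970-01-01"),
             row.names = NULL)
}

#' Unmonitored gap intervals at a site
#'
#' Maximal intervals of unmonitored days inside a site's overall monitoring
#' span (used for the grey full-axis shading of the niche display).
#'
#' @param effort Effort calendar (`site`, `date`).
#' @param site Site name.
#' @return Data frame `start`, `end` (Dates), possibly empty.
#' @export
gap_intervals <- function(effort, site) {
  days <- sort(unique(effort$date[effort$site == site]))
  if (length(days) < 2)
    return(data.frame(start = as.Date(character(0)),
                      end = as.Date(character(0))))
  all_days <- seq(min(days), max(days), by = "day")
  missing <- all_days[!(all_days %in% days)]
  if (!length(missing))
    return(data.frame(start = as.Date(character(0)),
                      end = as.Date(character(0))))
  grp <- cumsum(c(TRUE, diff(missing) > 1))
  data.frame(start = as.Date(as.vector(tapply(missing, grp, min)),
                             origin = "1970-01-01"),
             end = as.Date(as.vector(tapply(missing, grp, max)),
                           origin = "1970-01-01"),
             row.names = NULL)
}

#' Acoustic-niche box list
#'
#' The machine-readable content of the spectrographic box display: one box
#' per presence run per category per site, spanning the run's days on the
#' time axis and the category's calling-frequency band on the frequency
#' axis. Overlapping bands of species detected the same day visualize
#' potential frequency overlap of their vocalizations. The box list
#' losslessly determines the figure drawn by [plot_niche()].
#'
#' @param detections Positive daily detection records.
#' @param effort Effort calendar.
#' @param bands Band table (see [default_bands()]); must cover every
#'   category present in `detections`.
#' @return Data frame `site`, `category`, `start`, `end`, `f_low_hz`,
#'   `f_high_hz`, `colour`.
#' @export
niche_boxes <- function(detections, effort, bands = default_bands()) {
  cats <- unique(detections$category)
  missing <- setdiff(cats, bands$category)
  if (length(missing))
    stop("no frequency band for category(ies): ",
         paste(missing, collapse = ", "))
  sites <- unique(detections$site)
  out <- list()
  for (s in sites) for (cc in intersect(cats, unique(
    detections$category[detections$site == s]))) {
    runs <- presence_runs(detections, s, cc)
    if (!nrow(runs)) next
    b <- bands[bands$category == cc, ]
    out[[length(out) + 1L]] <- data.frame(
      site = s, category = cc, start = runs$start, end = runs$end,
      f_low_hz = b$f_low_hz, f_high_hz = b$f_high_hz, colour = b$colour,
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(site = character(0), category = character(0),
                      start = as.Date(character(0)),
                      end = as.Date(character(0)), f_low_hz = numeric(0),
                      f_high_hz = numeric(0), colour = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$site, res$category, res$start), ]
  rownames(res) <- NULL
  res
}

#' Draw the spectrographic box display
#'
#' One panel per site, ordered north to south: each presence run is a filled
#' box spanning its days by its category's calling band on a log frequency
#' axis (default 10 Hz - 150 kHz), and unmonitored gaps are shaded light
#' grey across the full frequency axis.
#'
#' @param boxes Box list from [niche_boxes()].
#' @param effort Effort calendar (for gap shading).
#' @param sites Site metadata (for the north-to-south panel order); `NULL`
#'   orders panels alphabetically.
#' @param flim Frequency axis limits in Hz.
#' @param main Overall title.
#' @export
plot_niche <- function(boxes, effort, sites = NULL,
                       flim = c(10, 150000), main = NULL) {
  panel_sites <- if (!is.null(sites)) {
    intersect(order_sites_north_south(validate_sites(sites)),
              unique(effort$site))
  } else sort(unique(effort$site))
  nf <- length(panel_sites)
  op <- par(mfrow = c(nf, 1), mar = c(1.2, 4, 1.1, 0.5),
            oma = c(2.5, 0, if (is.null(main)) 0 else 2, 0))
  on.exit(par(op))
  tlim <- range(effort$date)
  for (s in panel_sites) {
    plot(NA, xlim = as.numeric(tlim), ylim = log10(flim), axes = FALSE,
         xlab = "", ylab = "Frequency (Hz)", main = s, cex.main = 0.85)
    g <- gap_intervals(effort, s)
    if (nrow(g))
      rect(as.numeric(g$start) - 0.5, log10(flim[1]),
           as.numeric(g$end) + 0.5, log10(flim[2]),
           col = "grey85", border = NA)
    b <- boxes[boxes$site == s, , drop = FALSE]
    if (nrow(b))
      rect(as.numeric(b$start) - 0.5, log10(b$f_low_hz),
           as.numeric(b$end) + 0.5, log10(b$f_high_hz),
           col = adjustcolor(b$colour, alpha.f = 0.8), border = NA)
    ticks <- 10^seq(ceiling(log10(flim[1])), floor(log10(flim[2])), by = 2)
    axis(2, at = log10(ticks), labels = format(ticks, big.mark = ","),
         las = 1, cex.axis = 0.6)
    yrs <- seq(as.Date(format(tlim[1], "%Y-01-01")), tlim[2], by = "year")
    axis(1, at = as.numeric(yrs), labels = format(yrs, "%Y"), cex.axis = 0.7)
    box()
  }
  if (!is.null(main)) mtext(main, outer = TRUE, font = 2)
  invisible(boxes)
}
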