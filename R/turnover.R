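#' Effective number of species (inverse Simpson)
#'
#' The effective number of species (ENS) of a relative-presence composition:
#' `ENS = 1 / sum(p_i^2)`, the number of equally present species giving the
#' same dominance concentration as the observed community. It is bounded by
#' `1 <= ENS <= richness`, with equality to richness at the uniform
#' composition.
#'
#' @param p Numeric vector of relative presence proportions summing to 1
#'   (zeros allowed; they do not contribute).
#' @return ENS, or `NA` for an empty/all-zero composition.
#' @export
#' @examples
#' ens(rep(0.25, 4))        # 4: uniform community
#' ens(c(0.5, 0.25, 0.25))  # 2.667
ens <- function(p) {
  p <- p[!is.na(p) & p > 0]
  if (!length(p)) return(NA_real_)
  if (abs(sum(p) - 1) > 1e-8)
    stop("relative presence proportions must sum to 1 (got ", sum(p), ")")
  1 / sum(p^2)
}

#' Richness-based species exchange ratio (SERr)
#'
#' The identity-turnover ratio between two consecutive months: the number of
#' newly detected species (immigrations) plus the number of species no longer
#' detected (extinctions), as a fraction of the total number of species
#' detected in either month. SERr equals the Jaccard dissimilarity
#' `1 - |intersection| / |union|`: 0 when the detected sets are identical and
#' 1 when every species is replaced. The arithmetic is a ratio of small
#' integers, hence exact.
#'
#' @param set_prev,set_curr Character vectors of category ids detected in the
#'   previous and current month.
#' @return SERr in \[0, 1\], or `NA` when both sets are empty.
#' @export
#' @examples
#' serr(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
serr <- function(set_prev, set_curr) {
  set_prev <- unique(set_prev)
  set_curr <- unique(set_curr)
  u <- union(set_prev, set_curr)
  if (!length(u)) return(NA_real_)
  gains <- length(setdiff(set_curr, set_prev))
  losses <- length(setdiff(set_prev, set_curr))
  (gains + losses) / length(u)
}

#' Abundance-based species exchange ratio (SERa)
#'
#' Turnover in dominance structure between two consecutive months, the
#' Wishart dissimilarity on relative presence proportions:
#' \deqn{SERa = \frac{\sum_i (p_{i,1} - p_{i,2})^2}
#'   {\sum_i p_{i,1}^2 + \sum_i p_{i,2}^2 - \sum_i p_{i,1} p_{i,2}}}
#' with each month's proportions taken over the union of categories (an
#' absent category contributes 0). SERa is 0 when identity and dominance are
#' unchanged, 1 when the supports are disjoint, and reduces to SERr whenever
#' both months' detected species are equi-proportional.
#'
#' @param p_prev,p_curr Named numeric vectors of relative presence
#'   proportions, each summing to 1 over its detected categories.
#' @return SERa in \[0, 1\], or `NA` when either month has no detections.
#' @export
#' @examples
#' sera(c(a = 1/3, b = 1/3, c = 1/3), c(b = 1/3, c = 1/3, d = 1/3))  # 0.5
sera <- function(p_prev, p_curr) {
  p_prev <- p_prev[!is.na(p_prev) & p_prev > 0]
  p_curr <- p_curr[!is.na(p_curr) & p_curr > 0]
  if (!length(p_prev) || !length(p_curr)) return(NA_real_)
  for (p in list(p_prev, p_curr))
    if (abs(sum(p) - 1) > 1e-8)
      stop("each month's proportions must sum to 1 over its detected categories")
  cats <- union(names(p_prev), names(p_curr))
  if (is.null(names(p_prev)) || is.null(names(p_curr)))
    stop("proportion vectors must be named by category")
  a <- setNames(numeric(length(cats)), cats)
  b <- a
  a[names(p_prev)] <- p_prev
  b[names(p_curr)] <- p_curr
  num <- sum((a - b)^2)
  den <- sum(a^2) + sum(b^2) - sum(a * b)
  if (den == 0) return(0)
  min(max(num / den, 0), 1)  # guard one-ulp excursions past the bounds
}

#' Monthly community vectors for one site
#'
#' Relative presence proportions per month: within each monitored site-month,
#' `p_i = days_detected_i / sum_j days_detected_j` across categories. Months
#' with zero detections are flagged (`NULL` entry): ENS and SERa are
#' undefined there.
#'
#' @param summary Monthly summary from [bin_daily_to_monthly()].
#' @param site Site name.
#' @return Named list, one entry per monitored month (in calendar order):
#'   each a named proportion vector over detected categories, or `NULL` for
#'   a zero-detection month.
#' @keywords internal
monthly_communities <- function(summary, site) {
  sub <- summary[summary$site == site, , drop = FALSE]
  if (!nrow(sub)) stop("unknown site '", site, "'")
  months <- sort(unique(sub$month))
  out <- lapply(months, function(m) {
    d <- sub[sub$month == m & sub$days_detected > 0, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    setNames(d$days_detected / sum(d$days_detected), d$category)
  })
  names(out) <- months
  out
}

month_seq <- function(from, to) {
  d <- seq(as.Date(paste0(from, "-01")), as.Date(paste0(to, "-01")), by = "month")
  format(d, "%Y-%m")
}

#' Month-over-month turnover series for one site
#'
#' One row per adjacent calendar-month pair between the first and last
#' monitored month at the site: the current month's ENS, the change in ENS,
#' and the SERr and SERa exchange ratios. A pair whose months are separated
#' by (or fall in) an unmonitored or zero-detection month is emitted with
#' missing statistics — gaps are never bridged. The per-category change in
#' detection days is attached as attribute `"delta_days"` (long data frame)
#' and is also available via [delta_days_table()].
#'
#' @param summary Monthly summary from [bin_daily_to_monthly()].
#' @param site Site name.
#' @return Data frame `site`, `month_prev`, `month_curr`, `ens`,
#'   `delta_ens`, `serr`, `sera` (one row per consecutive-month slot; `ens`
#'   is the current month's value). Empty when fewer than 2 months span.
#' @export
#' @examples
#' sc <- shelfbreak_scenario(seed = 1)
#' sim <- generate_detections(sc)
#' ms <- bin_daily_to_monthly(sim$detections, sim$effort)
#' ts <- turnover_series(ms, "Hatteras")
#' head(ts)
turnover_series <- function(summary, site) {
  comm <- monthly_communities(summary, site)
  months <- month_seq(min(names(comm)), max(names(comm)))
  monitored <- months %in% names(comm)
  n <- length(months)
  empty <- data.frame(site = character(0), month_prev = character(0),
                      month_curr = character(0), ens = numeric(0),
                      delta_ens = numeric(0), serr = numeric(0),
                      sera = numeric(0))
  if (n < 2) return(empty)
  rows <- vector("list", n - 1)
  for (t in 2:n) {
    prev <- if (monitored[t - 1]) comm[[months[t - 1]]] else NULL
    curr <- if (monitored[t]) comm[[months[t]]] else NULL
    e_prev <- if (!is.null(prev)) ens(prev) else NA_real_
    e_curr <- if (!is.null(curr)) ens(curr) else NA_real_
    ok <- !is.null(prev) && !is.null(curr)
    rows[[t - 1]] <- data.frame(
      site = site, month_prev = months[t - 1], month_curr = months[t],
      ens = e_curr,
      delta_ens = if (ok) e_curr - e_prev else NA_real_,
      serr = if (ok) serr(names(prev), names(curr)) else NA_real_,
      sera = if (ok) sera(prev, curr) else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "delta_days") <- delta_days_table(summary, site)
  out
}

#' Per-category month-over-month change in detection days
#'
#' @param summary Monthly summary from [bin_daily_to_monthly()].
#' @param site Site name.
#' @return Long data frame `site`, `month_prev`, `month_curr`, `category`,
#'   `delta_days` (`days_detected[t] - days_detected[t-1]`; `NA` across
#'   unmonitored months).
#' @export
delta_days_table <- function(summary, site) {
  sub <- summary[summary$site == site, , drop = FALSE]
  if (!nrow(sub)) stop("unknown site '", site, "'")
  months <- month_seq(min(sub$month), max(sub$month))
  cats <- sort(unique(sub$category))
  wide <- matrix(NA_real_, nrow = length(months), ncol = length(cats),
                 dimnames = list(months, cats))
  idx <- cbind(match(sub$month, months), match(sub$category, cats))
  wide[idx] <- sub$days_detected
  n <- length(months)
  if (n < 2)
    return(data.frame(site = character(0), month_prev = character(0),
                      month_curr = character(0), category = character(0),
                      delta_days = numeric(0)))
  d <- wide[-1, , drop = FALSE] - wide[-n, , drop = FALSE]
  out <- data.frame(
    site = site,
    month_prev = rep(months[-n], times = length(cats)),
    month_curr = rep(months[-1], times = length(cats)),
    category = rep(cats, each = n - 1),
    delta_days = as.vector(d),
    stringsAsFactors = FALSE)
  out <- out[order(out$month_curr, out$category), ]
  rownames(out) <- NULL
  out
}

#' LOESS trend for a turnover series
#'
#' Display smoother for turnover panels: locally weighted polynomial
#' regression (tricube weights, degree 2) at the stated span, evaluated at
#' each observation time. Display-only — the smooth never feeds another
#' statistic.
#'
#' @param x Numeric time axis (e.g. month index).
#' @param y Series values; `NA`s are dropped before fitting.
#' @param span LOESS span (default 0.25).
#' @return Data frame `x`, `fitted` at the non-missing observation times, or
#'   `NULL` (with a warning) when fewer than `max(4, ceiling(span *
#'   n_nonmissing))` points remain.
#' @export
smooth_trend <- function(x, y, span = 0.25) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < max(4, ceiling(span * n))) {
    warning("too few non-missing points (", n, ") for a span-", span,
            " trend; curve omitted")
    return(NULL)
  }
  fit <- tryCatch(
    loess(y ~ x, span = span, degree = 2,
          control = stats::loess.control(surface = "direct")),
    error = function(e) {
      warning("trend smoother failed: ", conditionMessage(e))
      NULL
    })
  if (is.null(fit)) return(NULL)
  data.frame(x = x, fitted = as.numeric(predict(fit, newdata = data.frame(x = x))))
}
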