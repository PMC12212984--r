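#' Permutation test of independence between a covariate and the site label
#'
#' The split-selection engine of [citree()]: a conditional (permutation) test
#' of independence between a numeric covariate `x` and a categorical response
#' `y`, in the linear-statistic framework of Strasser & Weber. With case
#' weights `w` and the response-level indicator `h(y_i)`, the linear
#' statistic is `T = sum_i w_i x_i h(y_i)` (one entry per response level).
#' Its conditional expectation and covariance under all permutations of `y`
#' given the observed data are
#' \deqn{\mu = (\sum_i w_i x_i)\, E(h), \qquad
#'   \Sigma = \frac{w_\cdot \sum w_i x_i^2 - (\sum w_i x_i)^2}{w_\cdot - 1}
#'   \left(\mathrm{diag}(E(h)) - E(h)E(h)^\top\right)}
#' with `E(h)` the weighted response-level proportions. The quadratic test
#' statistic `c_quad = (T - mu)' Sigma^+ (T - mu)` uses the Moore-Penrose
#' pseudoinverse; its null distribution is chi-squared with
#' `df = rank(Sigma)` (asymptotic mode) or estimated from seeded Monte-Carlo
#' permutations of `y` (the exact-oracle mode).
#'
#' @param x Numeric covariate.
#' @param y Factor (or coercible) response with at least 2 levels among
#'   weighted rows.
#' @param weights Non-negative case weights; default 1 per row.
#' @param type `"asymptotic"` (chi-squared, default) or `"monte_carlo"`.
#' @param mc_reps Number of Monte-Carlo permutations.
#' @return An object of class `indep_test`: list with `statistic` (c_quad),
#'   `df`, `p.value`, `T`, `mu`, `Sigma`, `type`.
#' @references Strasser, H. & Weber, C. (1999) On the asymptotic theory of
#'   permutation statistics. Mathematical Methods of Statistics 8, 220-250.
#'   Hothorn, T., Hornik, K. & Zeileis, A. (2006) Unbiased recursive
#'   partitioning: a conditional inference framework. JCGS 15, 651-674.
#' @export
#' @examples
#' x <- c(rnorm(30), rnorm(30, 2))
#' y <- rep(c("A", "B"), each = 30)
#' independence_test(x, y)
independence_test <- function(x, y, weights = NULL,
                              type = c("asymptotic", "monte_carlo"),
                              mc_reps = 9999L) {
  type <- match.arg(type)
  y <- factor(y)
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(weights) == length(x),
            all(weights >= 0))
  keep <- weights > 0
  x <- x[keep]; y <- droplevels(y[keep]); w <- weights[keep]
  ws <- sum(w)
  if (ws < 2 || nlevels(y) < 2 || max(x) == min(x))
    return(indep_null(type))
  mom <- sw_moments(x, y, w)
  cq <- quad_form(mom$T - mom$mu, mom$Sigma)
  if (type == "asymptotic") {
    p <- pchisq(cq$stat, df = cq$rank, lower.tail = FALSE)
  } else {
    n <- length(x)
    exceed <- 0L
    for (r in seq_len(mc_reps)) {
      Tp <- as.numeric(rowsum(w * x, y[sample.int(n)], reorder = TRUE))
      cp <- sum(((Tp - mom$mu) %*% cq$half)^2)
      if (cp >= cq$stat - 1e-10) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (mc_reps + 1)
  }
  structure(list(statistic = cq$stat, df = cq$rank, p.value = p,
                 T = mom$T, mu = mom$mu, Sigma = mom$Sigma, type = type),
            class = "indep_test")
}

indep_null <- function(type) {
  structure(list(statistic = 0, df = 0L, p.value = 1,
                 T = NULL, mu = NULL, Sigma = NULL, type = type),
            class = "indep_test")
}

#' @export
print.indep_test <- function(x, ...) {
  cat("Permutation independence test (quadratic form, ", x$type, ")\n",
      sep = "")
  cat("  c_quad = ", format(x$statistic, digits = 5),
      ", df = ", x$df,
      ", p = ", format.pval(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

# Strasser-Weber conditional moments of T = sum_i w_i x_i h(y_i)
sw_moments <- function(x, y, w) {
  Tv <- as.numeric(rowsum(w * x, y, reorder = TRUE))
  wlev <- as.numeric(rowsum(w, y, reorder = TRUE))
  ws <- sum(w)
  Eh <- wlev / ws
  sg <- sum(w * x)
  ssg <- sum(w * x^2)
  cmult <- (ws * ssg - sg^2) / (ws - 1)
  Vh <- diag(Eh, nrow = length(Eh)) - tcrossprod(Eh)
  list(T = Tv, mu = sg * Eh, Sigma = cmult * Vh)
}

# (d' Sigma^+ d), rank, and a half-transform H with Sigma^+ = H H'
quad_form <- function(d, Sigma, tol = sqrt(.Machine$double.eps)) {
  e <- eigen(Sigma, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 0)
  rank <- sum(pos)
  if (rank == 0)
    return(list(stat = 0, rank = 0L, half = matrix(0, length(d), 1)))
  half <- e$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(e$values[pos]), nrow = rank)
  list(stat = sum((d %*% half)^2), rank = as.integer(rank), half = half)
}
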