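#' Control parameters for conditional inference trees
#'
#' @param mincriterion Split criterion: a node is split only when
#'   `1 - p_adjusted` of the best covariate exceeds this value (default 0.95,
#'   i.e. Bonferroni-adjusted p below 0.05).
#' @param minsplit Minimum node weight sum required to test a node for
#'   splitting (default 60, the full-model setting; the mysticete-only model
#'   uses 10).
#' @param minbucket Minimum terminal-node weight sum (default 15; the
#'   mysticete-only model uses 5).
#' @param maxdepth Maximum tree depth; `Inf` (default) for unrestricted, `1`
#'   for a stump.
#' @param test `"asymptotic"` chi-squared p-values (default) or
#'   `"monte_carlo"` permutation p-values.
#' @param mc_reps Permutations for Monte-Carlo mode.
#' @param seed Optional integer seed applied before fitting (only consulted
#'   in Monte-Carlo mode; asymptotic fits are deterministic).
#' @return A list of class `citree_control`.
#' @export
citree_control <- function(mincriterion = 0.95, minsplit = 60L,
                           minbucket = 15L, maxdepth = Inf,
                           test = c("asymptotic", "monte_carlo"),
                           mc_reps = 9999L, seed = NULL) {
  test <- match.arg(test)
  stopifnot(mincriterion > 0, mincriterion < 1, minbucket >= 1,
            minsplit >= 2, maxdepth >= 1)
  if (minbucket > minsplit / 2)
    stop("minbucket must not exceed minsplit/2")
  structure(list(mincriterion = mincriterion, minsplit = minsplit,
                 minbucket = minbucket, maxdepth = maxdepth, test = test,
                 mc_reps = mc_reps, seed = seed),
            class = "citree_control")
}

#' Assemble the site-month observation matrix for tree fitting
#'
#' One row per (site, monitored month); the response is the site label and
#' the covariates are the days each category was detected that month
#' (zero-filled). The covariate set can be restricted by guild — the
#' mysticete-only model excludes all odontocetes — and the mixed
#' Gervais'/True's category is excluded unless `include_mixed = TRUE`, so the
#' default full model has the 13 individual species plus the grouped
#' delphinid category as covariates.
#'
#' @param summary Monthly summary from [bin_daily_to_monthly()].
#' @param catalogue Category catalogue.
#' @param include_guilds Guilds whose categories enter as covariates.
#' @param include_mixed Include mixed categories (default `FALSE`).
#' @return Data frame with columns `site` (factor), `month`, and one numeric
#'   column per covariate category; attribute `"covariates"` holds the
#'   covariate ids.
#' @export
assemble_observations <- function(summary, catalogue = default_categories(),
                                  include_guilds = c("mysticete",
                                                     "beaked_whale",
                                                     "other_odontocete"),
                                  include_mixed = FALSE) {
  keep <- catalogue$guild %in% include_guilds
  if (!include_mixed) keep <- keep & catalogue$kind != "mixed"
  cats <- catalogue$id[keep]
  if (!length(cats)) stop("no covariate categories selected")
  sub <- summary[summary$category %in% cats, , drop = FALSE]
  sm <- unique(summary[c("site", "month")])
  if (length(unique(sm$site)) < 2)
    stop("need at least 2 sites to model site membership")
  wide <- matrix(0, nrow = nrow(sm), ncol = length(cats),
                 dimnames = list(NULL, cats))
  key <- paste(sm$site, sm$month)
  idx <- cbind(match(paste(sub$site, sub$month), key),
               match(sub$category, cats))
  wide[idx] <- sub$days_detected
  out <- data.frame(site = factor(sm$site), month = sm$month, wide,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$site, out$month), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "covariates") <- cats
  out
}

#' Fit a conditional inference tree
#'
#' Recursive partitioning of site-month observations by permutation-test
#' variable selection: at each node, every covariate is tested for
#' independence from the response with the quadratic-form statistic of
#' [independence_test()], raw p-values are Bonferroni-adjusted over the
#' covariates tested, and the node is split on the covariate with the
#' smallest adjusted p-value provided `1 - p_adjusted` exceeds
#' `mincriterion`. The cutpoint maximizes the standardized two-sample
#' statistic over midpoints between consecutive distinct covariate values,
#' subject to both children carrying at least `minbucket` weight (ties go to
#' the smaller cutpoint). Growth stops when a node's weight falls below
#' `minsplit`, no test passes the criterion, no admissible cutpoint exists,
#' or `maxdepth` is reached. Unbiased towards covariates with many split
#' points, because selection precedes cutpoint search.
#'
#' @param formula Model formula, e.g. `site ~ .` with covariate columns on
#'   the right (a `.` expands to all columns except the response and any
#'   `month` column).
#' @param data Observation data frame (see [assemble_observations()]).
#' @param weights Optional non-negative case weights (default 1 per row).
#' @param control A [citree_control()] list.
#' @return An object of class `citree` with `print`, `summary`, `predict`
#'   and `plot` methods. Nodes are stored in preorder; each node records
#'   either a split (covariate, cutpoint, statistic, raw and adjusted p) or
#'   a terminal weight and response distribution.
#' @export
#' @examples
#' sc <- shelfbreak_scenario(seed = 7)
#' sim <- generate_detections(sc)
#' ms <- bin_daily_to_monthly(sim$detections, sim$effort)
#' obs <- assemble_observations(ms)
#' fit <- citree(site ~ . - month, data = obs,
#'               control = citree_control(maxdepth = 1))
#' print(fit)
citree <- function(formula, data, weights = NULL,
                   control = citree_control()) {
  if (!is.null(control$seed)) set.seed(control$seed)
  mf <- model.frame(formula, data = data, na.action = stats::na.fail)
  y <- model.response(mf)
  if (!is.factor(y)) y <- factor(y)
  xvars <- attr(terms(mf), "term.labels")
  X <- data[xvars]
  notnum <- !vapply(X, is.numeric, logical(1))
  if (any(notnum))
    stop("non-numeric covariates: ", paste(xvars[notnum], collapse = ", "))
  X <- as.matrix(X)
  if (nlevels(droplevels(y)) < 2)
    stop("response has fewer than 2 levels")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  stopifnot(length(weights) == nrow(X), all(weights >= 0))

  nodes <- list()
  grow <- function(rows, depth) {
    id <- length(nodes) + 1L
    node <- list(id = id, weight = sum(weights[rows]),
                 dist = node_dist(y, weights, rows),
                 split = NULL, kids = NULL, depth = depth)
    nodes[[id]] <<- node  # reserve preorder slot
    sel <- if (node$weight >= control$minsplit && depth <= control$maxdepth)
      select_variable(X, y, weights, rows, control) else NULL
    if (!is.null(sel)) {
      cut <- find_split(X[rows, sel$var], y[rows], weights[rows],
                        control$minbucket)
      if (!is.null(cut)) {
        left <- rows[X[rows, sel$var] <= cut]
        right <- setdiff(rows, left)
        node$split <- list(variable = colnames(X)[sel$var], cutpoint = cut,
                           statistic = sel$statistic, p_raw = sel$p_raw,
                           p_adjusted = sel$p_adjusted)
        nodes[[id]] <<- node
        lid <- grow(left, depth + 1L)
        rid <- grow(right, depth + 1L)
        node$kids <- c(lid, rid)
      }
    }
    nodes[[id]] <<- node
    id
  }
  grow(which(weights > 0), 1L)

  structure(list(nodes = nodes, response = all.vars(formula)[1],
                 levels = levels(y), covariates = colnames(X),
                 control = control, nobs = sum(weights > 0),
                 call = match.call()),
            class = "citree")
}

node_dist <- function(y, weights, rows) {
  w <- vapply(levels(y), function(l) sum(weights[rows][y[rows] == l]),
              numeric(1))
  w / sum(w)
}

#' Select the split covariate at a node
#'
#' Tests each non-constant covariate against the response among the node's
#' rows, Bonferroni-adjusts the raw p-values over the `m` covariates tested
#' (`p_adj = min(1, m * p_raw)`), and returns the covariate with the
#' smallest adjusted p-value — or `NULL` (stop) when nothing passes
#' `1 - p_adj > mincriterion`, when all covariates are constant, or when the
#' node response is constant.
#'
#' @param X Covariate matrix, `y` response factor, `weights` case weights,
#'   `rows` node row indices, `control` a [citree_control()].
#' @return `NULL`, or list `var` (column index), `statistic`, `p_raw`,
#'   `p_adjusted`.
#' @keywords internal
select_variable <- function(X, y, weights, rows, control) {
  ysub <- droplevels(y[rows])
  if (nlevels(ysub) < 2) return(NULL)
  w <- weights[rows]
  testable <- which(apply(X[rows, , drop = FALSE], 2,
                          function(v) max(v) > min(v)))
  if (!length(testable)) return(NULL)
  res <- lapply(testable, function(j)
    independence_test(X[rows, j], ysub, w, type = control$test,
                      mc_reps = control$mc_reps))
  praw <- vapply(res, `[[`, numeric(1), "p.value")
  padj <- pmin(1, length(testable) * praw)
  best <- which.min(padj)
  if (1 - padj[best] <= control$mincriterion) return(NULL)
  list(var = testable[best], statistic = res[[best]]$statistic,
       p_raw = praw[best], p_adjusted = padj[best])
}

#' Find the cutpoint for a selected covariate
#'
#' Candidate cutpoints are midpoints between consecutive distinct sorted
#' covariate values. Each candidate's binary indicator `x <= c` is scored by
#' the quadratic-form two-sample statistic against the response; the
#' maximizer subject to both sides' weight sums being at least `minbucket`
#' is returned, ties broken toward the smaller cutpoint. On integer
#' detection-day covariates a presence/absence split therefore appears as
#' cutpoint 0.5, rendered "> 0".
#'
#' @param x Covariate values at the node, `y` response, `w` weights,
#'   `minbucket` minimum child weight.
#' @return The cutpoint, or `NULL` when no candidate is admissible.
#' @keywords internal
find_split <- function(x, y, w, minbucket) {
  y <- droplevels(factor(y))
  ux <- sort(unique(x))
  if (length(ux) < 2) return(NULL)
  cand <- (ux[-1] + ux[-length(ux)]) / 2
  best <- NULL
  best_stat <- -Inf
  for (cp in cand) {
    g <- as.numeric(x <= cp)
    wl <- sum(w[g == 1])
    if (min(wl, sum(w) - wl) < minbucket) next
    mom <- sw_moments(g, y, w)
    stat <- quad_form(mom$T - mom$mu, mom$Sigma)$stat
    if (stat > best_stat + 1e-10) {  # strict improvement: ties keep smaller c
      best_stat <- stat
      best <- cp
    }
  }
  best
}

#' @export
print.citree <- function(x, ...) {
  cat("Conditional inference tree: ", x$response, " ~ ",
      length(x$covariates), " covariates, n = ", x$nobs, "\n", sep = "")
  ctl <- x$control
  cat("Controls: mincriterion ", ctl$mincriterion, ", minsplit ",
      ctl$minsplit, ", minbucket ", ctl$minbucket,
      if (is.finite(ctl$maxdepth)) paste0(", maxdepth ", ctl$maxdepth) else "",
      ", ", ctl$test, " test\n\n", sep = "")
  print_node(x, 1L, prefix = "", edge = "")
  invisible(x)
}

print_node <- function(obj, id, prefix, edge) {
  nd <- obj$nodes[[id]]
  if (is.null(nd$split)) {
    top <- sort(nd$dist[nd$dist > 0], decreasing = TRUE)
    top <- top[seq_len(min(3, length(top)))]
    cat(prefix, edge, "[", id, "] terminal, weight ", nd$weight, ": ",
        paste0(names(top), " ", round(100 * top), "%", collapse = ", "),
        if (length(nd$dist[nd$dist > 0]) > 3) ", ..." else "",
        "\n", sep = "")
  } else {
    s <- nd$split
    cat(prefix, edge, "[", id, "] ", s$variable,
        " (p.adj = ", format.pval(s$p_adjusted, digits = 3), ")\n", sep = "")
    child_prefix <- paste0(prefix, if (nzchar(edge)) "|   " else "")
    print_node(obj, nd$kids[1], child_prefix,
               paste0(s$variable, " <= ", fmt_cut(s$cutpoint), ": "))
    print_node(obj, nd$kids[2], child_prefix,
               paste0(s$variable, " > ", fmt_cut(s$cutpoint), ": "))
  }
}

fmt_cut <- function(cp) {
  # integer detection-day covariates: "x > 0" reads better than "x > 0.5"
  if (isTRUE(all.equal(cp %% 1, 0.5))) format(cp - 0.5) else format(cp)
}

#' @export
summary.citree <- function(object, ...) {
  nd <- citree_nodes(object)
  cat("Conditional inference tree with",
      sum(nd$type == "terminal"), "terminal nodes\n\nSplits:\n")
  print(nd[nd$type == "split",
           c("id", "variable", "cutpoint", "statistic", "p_adjusted")],
        row.names = FALSE)
  cat("\nTerminal response distributions:\n")
  term <- object$nodes[vapply(object$nodes, function(n) is.null(n$split),
                              logical(1))]
  tab <- t(vapply(term, `[[`, numeric(length(object$levels)), "dist"))
  rownames(tab) <- paste0("node ", vapply(term, `[[`, integer(1), "id"),
                          " (w=", vapply(term, `[[`, numeric(1), "weight"), ")")
  print(round(tab, 3))
  invisible(nd)
}

#' Flat node table of a fitted tree
#'
#' Machine-readable export: one row per node with split records (covariate,
#' cutpoint, statistic, raw/adjusted p, child ids) for internal nodes and
#' weight plus the response distribution (as `p_<level>` columns) for every
#' node. Serializing this table (e.g. with `jsonlite`) losslessly captures
#' the tree's structure and labels.
#'
#' @param object A fitted [citree()].
#' @return A data frame.
#' @export
citree_nodes <- function(object) {
  rows <- lapply(object$nodes, function(nd) {
    base <- data.frame(
      id = nd$id, depth = nd$depth,
      type = if (is.null(nd$split)) "terminal" else "split",
      weight = nd$weight,
      variable = if (is.null(nd$split)) NA_character_ else nd$split$variable,
      cutpoint = if (is.null(nd$split)) NA_real_ else nd$split$cutpoint,
      statistic = if (is.null(nd$split)) NA_real_ else nd$split$statistic,
      p_raw = if (is.null(nd$split)) NA_real_ else nd$split$p_raw,
      p_adjusted = if (is.null(nd$split)) NA_real_ else nd$split$p_adjusted,
      kid_left = if (is.null(nd$kids)) NA_integer_ else nd$kids[1],
      kid_right = if (is.null(nd$kids)) NA_integer_ else nd$kids[2],
      stringsAsFactors = FALSE)
    dist <- as.data.frame(as.list(setNames(nd$dist,
                                           paste0("p_", names(nd$dist)))),
                          check.names = FALSE)
    cbind(base, dist)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
predict.citree <- function(object, newdata,
                           type = c("node", "prob", "response"), ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  node <- integer(n)
  for (i in seq_len(n)) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (is.null(nd$split)) break
      v <- newdata[[nd$split$variable]][i]
      id <- if (v <= nd$split$cutpoint) nd$kids[1] else nd$kids[2]
    }
    node[i] <- id
  }
  if (type == "node") return(node)
  probs <- t(vapply(node, function(id) object$nodes[[id]]$dist,
                    numeric(length(object$levels))))
  if (type == "prob") return(probs)
  factor(object$levels[max.col(probs, ties.method = "first")],
         levels = object$levels)
}

#' Plot a conditional inference tree
#'
#' Base-graphics rendering in the style of partitioned site-membership
#' trees: internal nodes carry the covariate name and adjusted p-value,
#' edges the split condition in days-per-month units, and terminal nodes a
#' pie of the site-membership distribution with its weight sum.
#'
#' @param x A fitted [citree()].
#' @param cols Optional named colours per response level; default a
#'   cool-to-warm spectrum over the response levels (sites ordered as in the
#'   factor, conventionally north to south).
#' @param main Plot title.
#' @param ... Ignored.
#' @export
plot.citree <- function(x, cols = NULL, main = NULL, ...) {
  if (is.null(cols))
    cols <- setNames(hcl.colors(length(x$levels), "Blue-Red"), x$levels)
  nodes <- x$nodes
  depth <- vapply(nodes, `[[`, integer(1), "depth")
  term <- vapply(nodes, function(n) is.null(n$split), logical(1))
  # terminal x-positions left-to-right in preorder, internals centred on kids
  xpos <- numeric(length(nodes))
  xpos[term] <- seq_len(sum(term))
  for (id in rev(seq_along(nodes)))
    if (!term[id]) xpos[id] <- mean(xpos[nodes[[id]]$kids])
  ypos <- max(depth) + 1 - depth
  op <- par(mar = c(0.5, 0.5, if (is.null(main)) 0.5 else 2.5, 0.5))
  on.exit(par(op))
  plot.new()
  plot.window(xlim = range(xpos) + c(-0.5, 0.5),
              ylim = c(min(ypos) - 0.7, max(ypos) + 0.4))
  if (!is.null(main)) title(main = main)
  for (id in seq_along(nodes)) {
    nd <- nodes[[id]]
    if (term[id]) next
    for (side in 1:2) {
      kid <- nd$kids[side]
      segments(xpos[id], ypos[id] - 0.12, xpos[kid], ypos[kid] + 0.28,
               col = "grey40")
      lab <- paste(if (side == 1) "<=" else ">", fmt_cut(nd$split$cutpoint))
      text((xpos[id] + xpos[kid]) / 2, (ypos[id] + ypos[kid]) / 2,
           lab, cex = 0.7, col = "grey25")
    }
    text(xpos[id], ypos[id], paste0("[", id, "] ", nd$split$variable),
         font = 2, cex = 0.8)
    text(xpos[id], ypos[id] - 0.22,
         paste0("p = ", format.pval(nd$split$p_adjusted, digits = 2)),
         cex = 0.65, col = "grey30")
  }
  for (id in which(term)) {
    draw_pie(xpos[id], ypos[id] - 0.1, r = 0.28, probs = nodes[[id]]$dist,
             cols = cols[names(nodes[[id]]$dist)])
    text(xpos[id], ypos[id] - 0.55,
         paste0("[", id, "] w=", nodes[[id]]$weight), cex = 0.65)
  }
  legend("topleft", legend = x$levels, fill = cols[x$levels],
         cex = 0.6, bty = "n")
  invisible(x)
}

draw_pie <- function(x0, y0, r, probs, cols) {
  probs <- probs[probs > 0]
  ang <- pi / 2 - 2 * pi * cumsum(c(0, probs))  # clockwise from 12 o'clock
  asp <- diff(par("usr")[3:4]) / diff(par("usr")[1:2]) *
    par("pin")[1] / par("pin")[2]
  for (i in seq_along(probs)) {
    th <- seq(ang[i], ang[i + 1], length.out = 32)
    polygon(c(x0, x0 + r * cos(th)), c(y0, y0 + r * asp * sin(th)),
            col = cols[names(probs)[i]], border = "white")
  }
}
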