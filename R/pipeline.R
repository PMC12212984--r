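#' Default pipeline configuration
#'
#' The configuration of the end-to-end reference run: generate the
#' shelf-break synthetic scenario, summarize to monthly presence, compute
#' per-site turnover series, fit the full / stump / mysticete-only
#' conditional inference trees, and emit the niche box display. Any part can
#' be overridden by a user config (a YAML file with the same structure, see
#' `system.file("extdata", "config-example.yaml", package = "pamdiv")`), and
#' file inputs can replace the simulated scenario.
#'
#' @param seed Global seed (drives the scenario and any Monte-Carlo tests).
#' @param out_dir Output directory.
#' @return A nested list.
#' @export
default_config <- function(seed = 1L, out_dir = "pamdiv-run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "summarize", "turnover", "ctree", "niche"),
    scenario = list(preset = "shelfbreak", boundary = "logistic"),
    inputs = NULL,
    turnover = list(span = 0.25),
    ctree = list(configs = c("full", "stump", "mysticete"),
                 include_mixed = FALSE),
    niche = list(bands = NULL, f_min_hz = 10, f_max_hz = 150000)
  )
}

#' Predefined tree control configurations
#'
#' The three model configurations of the analysis: `"full"` (all covariates;
#' minimum 60 weights to split, 15 per terminal, 0.95 criterion, unrestricted
#' depth), `"stump"` (as full but a single split), and `"mysticete"`
#' (mysticete covariates only; minimum weights relaxed to 10/5 to compensate
#' for the reduced data input).
#'
#' @param name One of `"full"`, `"stump"`, `"mysticete"`.
#' @return A [citree_control()].
#' @export
tree_config <- function(name = c("full", "stump", "mysticete")) {
  name <- match.arg(name)
  switch(name,
         full = citree_control(mincriterion = 0.95, minsplit = 60,
                               minbucket = 15),
         stump = citree_control(mincriterion = 0.95, minsplit = 60,
                                minbucket = 15, maxdepth = 1),
         mysticete = citree_control(mincriterion = 0.95, minsplit = 10,
                                    minbucket = 5))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages and writes every table, figure and a run
#' manifest under `config$out_dir`: the input tables (when simulated),
#' `monthly_summary.csv`, `composition.csv` (+ figure), `turnover.csv` and
#' `delta_days.csv` (+ figure), one text/JSON/figure bundle per tree
#' configuration, `niche_boxes.csv` (+ figure) and `manifest.json`. Identical
#' config and seed reproduce identical tables. A stage failure aborts the
#' run with an error naming the stage.
#'
#' @param config A config list (see [default_config()]) or the path to a
#'   YAML file with the same structure.
#' @return (Invisibly) a list of the in-memory artifacts.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(default_config(seed = 1, out_dir = tempfile()))
#' names(out)
#' }
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- load_config(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$out_dir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " INFO ", ...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  art <- list(config = cfg)

  if ("simulate" %in% cfg$stages || is.null(cfg$inputs)) {
    stage("simulate", {
      sc <- shelfbreak_scenario(seed = cfg$seed,
                                boundary = cfg$scenario$boundary)
      sim <- generate_detections(sc)
      art$scenario <- sc
      art$detections <- sim$detections
      art$effort <- sim$effort
      art$sites <- sc$sites
      art$catalogue <- sc$catalogue
      write_detections(art$detections, file.path(cfg$out_dir, "detections.csv"))
      eff <- art$effort
      eff$date <- format(eff$date, "%Y-%m-%d")
      write.csv(eff, file.path(cfg$out_dir, "effort.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(art$sites, file.path(cfg$out_dir, "sites.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(art$catalogue, file.path(cfg$out_dir, "categories.csv"),
                row.names = FALSE, quote = FALSE)
    })
  } else {
    stage("load", {
      art$catalogue <- read_categories(cfg$inputs$categories)
      art$sites <- read_sites(cfg$inputs$sites)
      art$effort <- read_effort(cfg$inputs$effort)
      art$detections <- read_detections(cfg$inputs$detections,
                                        art$catalogue, art$effort)
    })
  }

  if ("summarize" %in% cfg$stages) stage("summarize", {
    art$summary <- bin_daily_to_monthly(art$detections, art$effort,
                                        art$catalogue)
    write.csv(art$summary, file.path(cfg$out_dir, "monthly_summary.csv"),
              row.names = FALSE, quote = FALSE)
    art$composition <- composition_table(art$summary)
    write.csv(art$composition, file.path(cfg$out_dir, "composition.csv"),
              row.names = FALSE, quote = FALSE)
    pdf(file.path(cfg$out_dir, "composition.pdf"), width = 9, height = 5)
    plot_composition(art$composition, art$sites, art$catalogue)
    dev.off()
  })

  if ("turnover" %in% cfg$stages) stage("turnover", {
    sites_ns <- order_sites_north_south(art$sites)
    series <- lapply(sites_ns, function(s) turnover_series(art$summary, s))
    art$turnover <- do.call(rbind, series)
    art$delta_days <- do.call(rbind, lapply(series, attr, "delta_days"))
    write.csv(art$turnover, file.path(cfg$out_dir, "turnover.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(art$delta_days, file.path(cfg$out_dir, "delta_days.csv"),
              row.names = FALSE, quote = FALSE)
    pdf(file.path(cfg$out_dir, "turnover.pdf"), width = 9, height = 8)
    plot_turnover(art$turnover, span = cfg$turnover$span)
    dev.off()
  })

  if ("ctree" %in% cfg$stages) stage("ctree", {
    art$trees <- list()
    for (name in cfg$ctree$configs) {
      guilds <- if (name == "mysticete") "mysticete" else
        c("mysticete", "beaked_whale", "other_odontocete")
      obs <- assemble_observations(art$summary, art$catalogue,
                                   include_guilds = guilds,
                                   include_mixed = isTRUE(cfg$ctree$include_mixed))
      obs$site <- factor(obs$site, levels = order_sites_north_south(art$sites))
      fit <- citree(site ~ . - month, data = obs,
                    control = tree_config(name))
      art$trees[[name]] <- fit
      sink(file.path(cfg$out_dir, paste0("tree_", name, ".txt")))
      print(fit)
      sink()
      jsonlite::write_json(citree_nodes(fit),
                           file.path(cfg$out_dir, paste0("tree_", name, ".json")),
                           dataframe = "rows", digits = NA, pretty = TRUE)
      pdf(file.path(cfg$out_dir, paste0("tree_", name, ".pdf")),
          width = 10, height = 6)
      plot(fit, main = paste("Conditional inference tree:", name))
      dev.off()
    }
  })

  if ("niche" %in% cfg$stages) stage("niche", {
    bands <- if (is.null(cfg$niche$bands)) default_bands() else
      read_bands(cfg$niche$bands)
    art$boxes <- niche_boxes(art$detections, art$effort, bands)
    bx <- art$boxes
    bx$start <- format(bx$start, "%Y-%m-%d")
    bx$end <- format(bx$end, "%Y-%m-%d")
    write.csv(bx, file.path(cfg$out_dir, "niche_boxes.csv"),
              row.names = FALSE, quote = FALSE)
    pdf(file.path(cfg$out_dir, "niche.pdf"), width = 9, height = 13)
    plot_niche(art$boxes, art$effort, art$sites,
               flim = c(cfg$niche$f_min_hz, cfg$niche$f_max_hz))
    dev.off()
  })

  stage("manifest", {
    cfg_path <- file.path(cfg$out_dir, "config.yaml")
    yaml::write_yaml(cfg, cfg_path)
    manifest <- list(
      config_md5 = unname(tools::md5sum(cfg_path)),
      seed = cfg$seed,
      package = "pamdiv",
      version = as.character(packageVersion("pamdiv")),
      r_version = R.version.string,
      outputs = sort(setdiff(list.files(cfg$out_dir), "manifest.json")))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  say("done: ", cfg$out_dir)
  invisible(art)
}

load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Stacked relative-presence composition chart
#'
#' Per-site stacked bars of the 0-100% category composition, sites ordered
#' north to south, categories coloured by guild (mysticetes red-orange,
#' beaked whales green, other odontocetes blue-purple).
#'
#' @param composition Long table from [composition_table()].
#' @param sites Site metadata (for ordering); `NULL` for alphabetical.
#' @param catalogue Category catalogue (for colours and stacking order).
#' @export
plot_composition <- function(composition, sites = NULL,
                             catalogue = default_categories()) {
  site_order <- if (!is.null(sites))
    intersect(order_sites_north_south(validate_sites(sites)),
              unique(composition$site))
  else sort(unique(composition$site))
  cats <- catalogue$id[order(match(catalogue$guild,
                                   c("mysticete", "beaked_whale",
                                     "other_odontocete")))]
  cats <- intersect(cats, unique(composition$category))
  m <- matrix(0, nrow = length(cats), ncol = length(site_order),
              dimnames = list(cats, site_order))
  idx <- cbind(match(composition$category, cats),
               match(composition$site, site_order))
  ok <- complete.cases(idx)
  m[idx[ok, , drop = FALSE]] <- composition$percent[ok]
  cols <- guild_colours(catalogue)[cats]
  op <- par(mar = c(7, 4, 2, 9), xpd = TRUE)
  on.exit(par(op))
  barplot(m, col = cols, las = 2, cex.names = 0.7,
          ylab = "Relative acoustic presence (%)")
  legend("topright", inset = c(-0.32, 0),
         legend = catalogue$label[match(rev(cats), catalogue$id)],
         fill = rev(cols), cex = 0.55, bty = "n")
  invisible(m)
}

guild_colours <- function(catalogue) {
  pal <- list(
    mysticete = grDevices::colorRampPalette(c("#67000d", "#fb6a4a")),
    beaked_whale = grDevices::colorRampPalette(c("#00441b", "#a1d99b")),
    other_odontocete = grDevices::colorRampPalette(c("#3f007d", "#6baed6")))
  cols <- character(nrow(catalogue))
  for (g in names(pal)) {
    i <- which(catalogue$guild == g)
    cols[i] <- pal[[g]](length(i))
  }
  setNames(cols, catalogue$id)
}

#' Three-panel turnover chart
#'
#' ENS, SERr and SERa month-over-month series for every site, with a LOESS
#' trend curve (default span 0.25) overlaid per site where enough points are
#' available.
#'
#' @param turnover Combined turnover table (rows from [turnover_series()]).
#' @param span LOESS span.
#' @export
plot_turnover <- function(turnover, span = 0.25) {
  sites <- unique(turnover$site)
  cols <- setNames(hcl.colors(length(sites), "Blue-Red"), sites)
  op <- par(mfrow = c(3, 1), mar = c(2.5, 4, 2, 1))
  on.exit(par(op))
  panels <- c(ens = "ENS", serr = "SERr", sera = "SERa")
  for (metric in names(panels)) {
    ylim <- if (metric == "ens") range(turnover$ens, na.rm = TRUE) else c(0, 1)
    plot(NA, xlim = c(1, max(table(turnover$site)) + 1), ylim = ylim,
         xlab = "Month pair", ylab = panels[metric], main = panels[metric])
    for (s in sites) {
      sub <- turnover[turnover$site == s, , drop = FALSE]
      xi <- seq_len(nrow(sub))
      points(xi, sub[[metric]], col = adjustcolor(cols[s], 0.4), pch = 16,
             cex = 0.5)
      sm <- suppressWarnings(smooth_trend(xi, sub[[metric]], span = span))
      if (!is.null(sm)) lines(sm$x, sm$fitted, col = cols[s], lwd = 2)
    }
  }
  legend("bottomright", legend = sites, col = cols, lwd = 2, cex = 0.55,
         bty = "n", ncol = 2)
  invisible(NULL)
}
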