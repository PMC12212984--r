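#' Detection category catalogue
#'
#' A catalogue describes every detection category that may appear in a daily
#' detection table: a short unique id, a display label, the guild the category
#' belongs to (`"mysticete"`, `"beaked_whale"` or `"other_odontocete"`), and
#' whether it is an individual species, a mixed category (acoustically
#' inseparable species pair) or a grouped category (e.g. unidentified
#' delphinids).
#'
#' `default_categories()` returns the 15-category catalogue used throughout
#' the package: five mysticetes (blue, fin, humpback, North Atlantic right and
#' sei whales), five beaked whale species (Blainville's, goose-beaked,
#' Gervais', True's and Sowerby's), a mixed Gervais'/True's category, Kogia
#' spp., Risso's dolphin, sperm whale and grouped delphinids.
#'
#' @return A data frame with columns `id`, `label`, `guild`, `kind`.
#' @export
#' @examples
#' cat <- default_categories()
#' table(cat$guild)
default_categories <- function() {
  df <- data.frame(
    id = c("blue", "fin", "humpback", "right", "sei",
           "blainville", "cuvier", "gervais", "true", "sowerby", "bw_mixed",
           "kogia", "risso", "sperm", "delphinid"),
    label = c("Blue whale", "Fin whale", "Humpback whale",
              "North Atlantic right whale", "Sei whale",
              "Blainville's beaked whale", "Goose-beaked whale",
              "Gervais' beaked whale", "True's beaked whale",
              "Sowerby's beaked whale", "Gervais'/True's beaked whale",
              "Kogia spp.", "Risso's dolphin", "Sperm whale",
              "Delphinid spp."),
    guild = c(rep("mysticete", 5), rep("beaked_whale", 6),
              rep("other_odontocete", 4)),
    kind = c(rep("species", 5), rep("species", 5), "mixed",
             "species", "species", "species", "grouped"),
    stringsAsFactors = FALSE
  )
  validate_categories(df)
}

validate_categories <- function(df) {
  need <- c("id", "label", "guild", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("category catalogue is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("category ids must be unique; duplicated: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad <- setdiff(df$guild, c("mysticete", "beaked_whale", "other_odontocete"))
  if (length(bad))
    stop("unknown guild value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(df$kind, c("species", "mixed", "grouped"))
  if (length(bad))
    stop("unknown kind value(s): ", paste(bad, collapse = ", "))
  df
}

#' Shelf-break monitoring site metadata
#'
#' Returns metadata for the ten synthetic shelf-break monitoring sites used by
#' [shelfbreak_scenario()], ordered north to south between about 41°N and
#' 30.5°N. Latitude drives site ordering in all figures and the latitudinal
#' occupancy boundaries of the synthetic community.
#'
#' @return A data frame with columns `name`, `latitude` (decimal degrees N),
#'   `longitude` (decimal degrees E) and `depth` (metres).
#' @export
shelfbreak_sites <- function() {
  data.frame(
    name = c("Heezen Canyon", "Oceanographer Canyon", "Nantucket Canyon",
             "Babylon Canyon", "Wilmington Canyon", "Norfolk Canyon",
             "Hatteras", "Gulf Stream", "Blake Plateau", "Blake Spur"),
    latitude = c(41.10, 40.26, 39.83, 39.19, 38.37,
                 37.16, 35.30, 33.66, 31.95, 30.53),
    longitude = c(-66.35, -68.12, -69.98, -71.50, -73.37,
                  -74.47, -74.85, -75.90, -77.25, -77.39),
    depth = c(850, 900, 950, 1000, 950, 1050, 970, 950, 900, 850),
    stringsAsFactors = FALSE
  )
}

validate_sites <- function(df) {
  need <- c("name", "latitude", "longitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("site names must be unique")
  if (any(df$latitude < -90 | df$latitude > 90))
    stop("site latitude outside [-90, 90]")
  if (is.null(df$depth)) df$depth <- NA_real_
  df
}

# order site names north -> south by latitude
order_sites_north_south <- function(sites) {
  sites$name[order(-sites$latitude)]
}
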