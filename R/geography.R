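# Waypoint great-circle distances and the heterozygosity-distance regression.

#' Default waypoint routes
#'
#' Waypoint fixture for serial-founder distance computation: overland routes
#' from the East African origin through standard waypoints (Cairo, Istanbul,
#' Phnom Penh, Anadyr, Prince Rupert), as used in the serial-founder
#' literature. Each route is a matrix of (latitude, longitude) rows visited
#' in order before the target population.
#'
#' @return Named list of waypoint matrices (possibly empty for direct routes).
#' @export
defaultRoutes <- function() {
  cairo <- c(30.1, 31.2); istanbul <- c(41.1, 28.9)
  phnomPenh <- c(11.6, 104.9); anadyr <- c(64.7, 177.5)
  princeRupert <- c(54.3, -130.3)
  list(
    africa = NULL,
    western_eurasia = rbind(cairo, istanbul),
    east_asia = rbind(cairo, istanbul, phnomPenh),
    oceania = rbind(cairo, istanbul, phnomPenh),
    americas = rbind(cairo, istanbul, anadyr, princeRupert),
    direct = NULL
  )
}

#' Great-circle distance from an origin along a waypoint route
#'
#' Sum of haversine legs origin -> waypoint 1 -> ... -> target, on a sphere
#' of radius \code{radiusKm} (default 6371 km).
#'
#' @param lat,lon target coordinates in degrees (north/east positive).
#' @param route matrix of (lat, lon) waypoint rows, or NULL for the direct
#'   great-circle distance.
#' @param origin (lat, lon) of the origin; default Addis Ababa.
#' @param radiusKm sphere radius in km.
#' @return Distance in kilometres.
#' @export
waypointDistance <- function(lat, lon, route = NULL,
                             origin = c(9.03, 38.74), radiusKm = 6371) {
  pts <- rbind(origin, route, c(lat, lon))
  legs <- vapply(seq_len(nrow(pts) - 1L), function(i)
    geosphere::distHaversine(c(pts[i, 2], pts[i, 1]),
                             c(pts[i + 1, 2], pts[i + 1, 1]),
                             r = radiusKm), numeric(1))
  sum(legs)
}

#' Fill waypoint distances into a population table
#'
#' @param pops population table with \code{population}, \code{region},
#'   \code{latitude}, \code{longitude}.
#' @param routes named list of waypoint matrices, indexed by region; regions
#'   missing from the list raise an error.
#' @param origin,radiusKm passed to \code{\link{waypointDistance}}.
#' @return The table with a \code{distance_km} column appended.
#' @export
populationDistances <- function(pops, routes = defaultRoutes(),
                                origin = c(9.03, 38.74), radiusKm = 6371) {
  missingRoutes <- setdiff(unique(pops$region), names(routes))
  if (length(missingRoutes))
    stop(sprintf("no route defined for region(s): %s",
                 paste(missingRoutes, collapse = ", ")))
  pops$distance_km <- vapply(seq_len(nrow(pops)), function(i)
    waypointDistance(pops$latitude[i], pops$longitude[i],
                     routes[[pops$region[i]]], origin, radiusKm), numeric(1))
  pops
}

#' Regression of haplotype heterozygosity on geographic distance
#'
#' Ordinary least squares of genome-wide mean haplotype heterozygosity on
#' waypoint distance from the origin, the serial-founder test. Populations
#' flagged \code{exclude_from_regression} (e.g. recently admixed or
#' geographically ambiguous groups) are dropped first.
#'
#' @param het heterozygosity table (data.frame with \code{population},
#'   \code{mean_het}), e.g. \code{genomewideHeterozygosity(...)$table}.
#' @param pops population table with \code{population}, \code{distance_km}
#'   and optionally \code{exclude_from_regression}.
#' @return list with \code{slope} (per km), \code{intercept}, \code{r2},
#'   \code{p} (two-sided Pearson test), \code{n}.
#' @export
hetDistanceRegression <- function(het, pops) {
  tab <- merge(het, pops, by = "population")
  if ("exclude_from_regression" %in% names(tab))
    tab <- tab[!tab$exclude_from_regression, , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 populations after exclusions")
  if (stats::var(tab$distance_km) == 0) stop("no variance in distance")
  fit <- stats::lm(mean_het ~ distance_km, data = tab)
  ct <- stats::cor.test(tab$distance_km, tab$mean_het)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared,
       p = ct$p.value,
       n = nrow(tab))
}
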