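#' Great-circle distance (haversine)
#'
#' @param a,b numeric `c(lat, lon)` in decimal degrees, or two-column
#'   matrices for vectorised use.
#' @param radius_km Earth radius, km (6371.0).
#' @return distance(s) in km.
#' @export
great_circle_km <- function(a, b, radius_km = 6371.0) {
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  if (any(abs(a[, 1]) > 90 | abs(b[, 1]) > 90) ||
      any(abs(a[, 2]) > 180 | abs(b[, 2]) > 180))
    .stopf("invalid coordinates: latitude in [-90, 90], longitude in [-180, 180]")
  to_rad <- pi / 180
  dlat <- (b[, 1] - a[, 1]) * to_rad
  dlon <- (b[, 2] - a[, 2]) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a[, 1] * to_rad) * cos(b[, 1] * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(sqrt(h), 1))
}

#' ESU catalog: natural reference populations and regional status
#'
#' @param reference_populations data.frame with columns `esu`,
#'   `pop_id`, `lat`, `lon`; rows with missing `pop_id` declare an ESU
#'   present in the study without any natural in-region population.
#' @param autochthonous character vector of ESUs autochthonous to the
#'   study region; defaults to every ESU owning at least one natural
#'   reference population.
#' @param esus full ESU label set; defaults to the labels seen.
#' @return an `esu_catalog`.
#' @export
esu_catalog <- function(reference_populations,
                        autochthonous = NULL, esus = NULL) {
  rp <- as.data.frame(reference_populations)
  need <- c("esu", "pop_id", "lat", "lon")
  if (!all(need %in% names(rp)))
    .stopf("reference_populations needs columns %s", paste(need, collapse = ", "))
  rp$esu <- as.character(rp$esu)
  has_ref <- !is.na(rp$pop_id) & nzchar(rp$pop_id)
  esus <- esus %||% unique(rp$esu)
  autochthonous <- autochthonous %||% unique(rp$esu[has_ref])
  if (length(setdiff(autochthonous, esus)))
    .stopf("autochthonous set contains unknown ESU")
  structure(list(esus = esus,
                 reference_populations = rp[has_ref, , drop = FALSE],
                 autochthonous = autochthonous),
            class = "esu_catalog")
}

#' Allochthony test: the 100-km range rule
#'
#' An ESU observed at a site is allochthonous there when it is not
#' autochthonous to the study region, when it has no natural in-region
#' reference population at all, or when the nearest natural reference
#' population of that ESU lies strictly more than `threshold_km` away
#' (a conservative proxy for the range border beyond which natural
#' gene flow is unlikely); exactly `threshold_km` is autochthonous.
#'
#' @param pop_coords `c(lat, lon)` of the tested population.
#' @param esu ESU label.
#' @param catalog an [esu_catalog()].
#' @param threshold_km range-border proxy (default 100).
#' @return `"autochthonous"` or `"allochthonous"`.
#' @export
allochthony_test <- function(pop_coords, esu, catalog, threshold_km = 100) {
  if (!esu %in% catalog$esus) .stopf("unknown ESU %s", esu)
  if (!esu %in% catalog$autochthonous) return("allochthonous")
  refs <- catalog$reference_populations
  refs <- refs[refs$esu == esu, , drop = FALSE]
  if (!nrow(refs)) return("allochthonous")
  dmin <- min(great_circle_km(matrix(pop_coords, nrow(refs), 2, byrow = TRUE),
                              cbind(refs$lat, refs$lon)))
  if (dmin > threshold_km) "allochthonous" else "autochthonous"
}
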