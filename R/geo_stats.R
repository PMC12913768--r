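#' Regional centroids from sample coordinates
#'
#' Arithmetic mean latitude and longitude per region.
#'
#' @param samples Data frame with `region`, `lat`, `lon` (decimal degrees).
#' @return Tibble with `region`, `n`, `lat`, `lon`.
#' @export
region_centroids <- function(samples) {
  stopifnot(all(c("region", "lat", "lon") %in% names(samples)))
  if (nrow(samples) == 0) stop("no samples", call. = FALSE)
  if (any(abs(samples$lat) > 90) || any(abs(samples$lon) > 180)) {
    stop("coordinates out of range", call. = FALSE)
  }
  samples |>
    dplyr::group_by(region = .data$region) |>
    dplyr::summarise(n = dplyr::n(), lat = mean(.data$lat),
                     lon = mean(.data$lon))
}

#' Great-circle distance in kilometers
#'
#' Haversine distance with Earth radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @examples
#' haversine_km(0, 0, 0, 90)  # ~10007.5
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

#' Isolation-by-distance correlation
#'
#' Pearson correlation between pairwise great-circle distance (km, from
#' regional centroids) and pairwise F_ST, over region pairs in the
#' requested scope: within the western cluster, within the eastern
#' cluster, or between clusters. Listed regions are excluded first
#' (e.g. leading-edge outliers).
#'
#' @param fst_pairs Data frame with `region1`, `region2`, `fst`.
#' @param geo Data frame with `region`, `lat`, `lon`, `cluster` (values
#'   `"west"` / `"east"`; centroids, e.g. from [region_centroids()] joined
#'   with cluster labels).
#' @param scope `"within-west"`, `"within-east"` or `"between"`.
#' @param exclude Character vector of regions to drop.
#' @return One-row tibble with `scope`, `r`, `p_value`, `n_pairs`.
#' @export
ibd_correlation <- function(fst_pairs, geo,
                            scope = c("within-west", "within-east", "between"),
                            exclude = character(0)) {
  scope <- match.arg(scope)
  pairs <- fst_pairs[!(fst_pairs$region1 %in% exclude) &
                       !(fst_pairs$region2 %in% exclude), ]
  cl <- stats::setNames(geo$cluster, geo$region)
  c1 <- cl[pairs$region1]
  c2 <- cl[pairs$region2]
  keep <- switch(scope,
                 "within-west" = c1 == "west" & c2 == "west",
                 "within-east" = c1 == "east" & c2 == "east",
                 "between" = c1 != c2)
  pairs <- pairs[keep & !is.na(keep), ]
  if (nrow(pairs) < 3) stop("fewer than 3 region pairs in scope", call. = FALSE)
  lat <- stats::setNames(geo$lat, geo$region)
  lon <- stats::setNames(geo$lon, geo$region)
  d <- haversine_km(lat[pairs$region1], lon[pairs$region1],
                    lat[pairs$region2], lon[pairs$region2])
  if (stats::sd(d) == 0 || stats::sd(pairs$fst) == 0) {
    stop("zero variance in distances or F_ST", call. = FALSE)
  }
  ct <- stats::cor.test(d, pairs$fst)
  tibble::tibble(scope = scope, r = unname(ct$estimate),
                 p_value = ct$p.value, n_pairs = nrow(pairs))
}

#' Correlations of admixture proportion with bioclimatic variables
#'
#' Pearson correlation of the eastern admixture proportion with each
#' bioclimatic variable across samples with complete data, with Bonferroni
#' adjustment over the 19-variable family.
#'
#' @param table Data frame with an `admixture` column (eastern proportion,
#'   in \[0, 1\]) and the bioclimatic variable columns.
#' @param variables Variable column names (default: all `bio`-prefixed
#'   columns).
#' @param family_size Bonferroni family size (the 19 bioclim variables).
#' @return Tibble with `variable`, `r`, `p_value`, `p_adjusted`, `n`.
#' @export
climate_correlation <- function(table, variables = NULL, family_size = 19) {
  stopifnot("admixture" %in% names(table))
  if (any(table$admixture < 0 | table$admixture > 1, na.rm = TRUE)) {
    stop("admixture proportions must be in [0, 1]", call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- grep("^bio", names(table), value = TRUE)
  }
  purrr::map_dfr(variables, function(v) {
    ok <- stats::complete.cases(table$admixture, table[[v]])
    ct <- stats::cor.test(table$admixture[ok], table[[v]][ok])
    tibble::tibble(variable = v, r = unname(ct$estimate),
                   p_value = ct$p.value,
                   p_adjusted = pmin(1, ct$p.value * family_size),
                   n = sum(ok))
  })
}
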