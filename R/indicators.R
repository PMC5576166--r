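#' Demographic density of each region
#'
#' @param table A [region_table()].
#' @return Named numeric vector of persons per km2, in table order.
#' @examples
#' population_density(load_mongolia_2014())[["Ulaanbaatar"]] # ~306.5
#' @export
population_density <- function(table) {
  stopifnot(inherits(table, "region_table"))
  setNames(table$population / table$area_km2, table$region)
}

#' Classify a demographic density as urban, suburban or rural
#'
#' Urban means strictly more than 200 persons/km2, suburban strictly more
#' than 10, rural otherwise. Thresholds are strict, so a density of exactly
#' 10 or 200 falls in the lower category. The function is total on
#' `[0, Inf)`.
#'
#' @param density Non-negative numeric vector of persons per km2.
#' @return Factor with ordered levels `rural < suburban < urban`.
#' @examples
#' classify_region(c(306.5, 30.9, 0.4))
#' @export
classify_region <- function(density) {
  if (any(!is.finite(density) | density < 0)) {
    stop("population density must be non-negative and finite", call. = FALSE)
  }
  factor(ifelse(density > 200, "urban",
                ifelse(density > 10, "suburban", "rural")),
         levels = c("rural", "suburban", "urban"), ordered = TRUE)
}

#' Settlement category of every region in a table
#'
#' @param table A [region_table()].
#' @return Named factor (`rural < suburban < urban`) in table order.
#' @export
settlement_categories <- function(table) {
  setNames(classify_region(population_density(table)), table$region)
}

# bare per-region density values on a basis, full precision
indicator_values <- function(table, resource, basis) {
  resource <- match_resource(resource)
  basis <- match_basis(basis)
  denom <- if (basis == "population") table$population else table$area_km2
  setNames(table[[resource]] / denom * basis_scale[[basis]], table$region)
}

#' Density indicator of a resource on a chosen basis
#'
#' The two indicators of the analysis: resources per 10 000 persons
#' (`basis = "population"`) and resources per 1 000 km2 (`basis = "area"`).
#' Values are exact ratios at full precision; rounding happens only in
#' reports.
#'
#' @param table A [region_table()].
#' @param resource One of [resource_kinds].
#' @param basis `"population"` or `"area"`.
#' @return A tibble with columns `region`, `resource`, `basis`, `value`.
#' @examples
#' mn <- load_mongolia_2014()
#' density_indicator(mn, "physicians", "population")
#' @export
density_indicator <- function(table, resource, basis) {
  stopifnot(inherits(table, "region_table"))
  values <- indicator_values(table, resource, basis)
  tibble::tibble(region = table$region,
                 resource = match_resource(resource),
                 basis = match_basis(basis),
                 value = unname(values))
}

#' All density indicators of a table
#'
#' @param table A [region_table()].
#' @return A long tibble over every resource x basis combination, with the
#'   region's settlement category attached.
#' @export
indicator_table <- function(table) {
  cats <- settlement_categories(table)
  out <- do.call(rbind, lapply(resource_kinds, function(res) {
    do.call(rbind, lapply(basis_kinds, function(b) {
      density_indicator(table, res, b)
    }))
  }))
  out$category <- cats[out$region]
  tibble::as_tibble(out)
}

#' Per-category mean densities
#'
#' Groups regions into urban / suburban / rural by demographic density and
#' reports, for every resource and basis, the unweighted arithmetic mean of
#' the per-region indicator values (computed at full precision, not from
#' rounded cells). Unweighted means — not pooled ratios — are what the
#' reference summaries of the Mongolian table use.
#'
#' @param table A [region_table()].
#' @return A tibble with columns `category`, `n_regions`, `resource`,
#'   `basis`, `mean_value`, one row per category x resource x basis present.
#' @examples
#' summarize_groups(load_mongolia_2014())
#' @export
summarize_groups <- function(table) {
  ind <- indicator_table(table)
  out <- dplyr::summarise(
    dplyr::group_by(ind, .data$category, .data$resource, .data$basis),
    n_regions = dplyr::n(),
    mean_value = mean(.data$value),
    .groups = "drop"
  )
  out[order(out$category, out$resource, out$basis), ]
}

#' WHO health-workforce threshold constants
#'
#' `who_minimum_density` (22.8 physicians, nurses and midwives per 10 000
#' people) is the classic minimum for delivering essential health
#' interventions; `who_sdg_density` (44.5) is the updated benchmark tied to
#' universal health coverage and the Sustainable Development Goals.
#'
#' @format Numeric scalars, workers per 10 000 population.
#' @export
who_minimum_density <- 22.8

#' @rdname who_minimum_density
#' @export
who_sdg_density <- 44.5

#' Assess a workforce density against the WHO thresholds
#'
#' Applied here to physicians + nurses per 10 000 population (the table has
#' no separate midwife category). Boundaries are inclusive at the named
#' threshold: exactly 22.8 meets the minimum, exactly 44.5 meets the SDG
#' benchmark.
#'
#' @param density Non-negative workforce density per 10 000 population.
#' @return Factor with ordered levels
#'   `below_minimum < meets_minimum < meets_sdg`.
#' @examples
#' who_threshold_check(c(10, 22.8, 83.3))
#' @export
who_threshold_check <- function(density) {
  if (any(!is.finite(density) | density < 0)) {
    stop("workforce density must be non-negative and finite", call. = FALSE)
  }
  factor(ifelse(density >= who_sdg_density, "meets_sdg",
                ifelse(density >= who_minimum_density,
                       "meets_minimum", "below_minimum")),
         levels = c("below_minimum", "meets_minimum", "meets_sdg"),
         ordered = TRUE)
}

#' Workforce (physicians + nurses) density per 10 000 population
#'
#' @param table A [region_table()].
#' @return Named numeric vector per region.
#' @export
workforce_density <- function(table) {
  stopifnot(inherits(table, "region_table"))
  setNames((table$physicians + table$nurses) / table$population * 1e4,
           table$region)
}
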