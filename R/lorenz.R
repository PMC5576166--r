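#' Build a Lorenz curve for a resource on a weight basis
#'
#' Regions are sorted by ascending resource density on the chosen basis
#' (ties broken by region name, so the curve is deterministic; coefficients
#' are invariant to the tie order). Point k is the pair (cumulative weight
#' share, cumulative resource share) after the k-th region, with exact
#' endpoints (0,0) and (1,1). The weight is persons on the population basis
#' and km2 on the area basis.
#'
#' @param table A [region_table()] with at least two regions.
#' @param resource One of [resource_kinds].
#' @param basis `"population"` or `"area"`.
#' @return A `lorenz_curve`: a tibble with columns `region` (NA for the
#'   origin), `p` (cumulative weight share) and `q` (cumulative resource
#'   share), plus `resource` and `basis` attributes.
#' @examples
#' build_lorenz(load_mongolia_2014(), "physicians", "area")
#' @export
build_lorenz <- function(table, resource, basis) {
  stopifnot(inherits(table, "region_table"))
  resource <- match_resource(resource)
  basis <- match_basis(basis)
  if (nrow(table) < 2) {
    stop("a Lorenz curve needs at least 2 regions", call. = FALSE)
  }
  amounts <- table[[resource]]
  if (sum(amounts) <= 0) {
    stop("degenerate Lorenz curve: total ", resource, " is zero",
         call. = FALSE)
  }
  weights <- if (basis == "population") table$population else table$area_km2
  ord <- order(amounts / weights, table$region)
  w <- weights[ord]
  a <- amounts[ord]
  pts <- tibble::tibble(
    region = c(NA_character_, table$region[ord]),
    p = c(0, cumsum(w) / sum(w)),
    q = c(0, cumsum(a) / sum(a))
  )
  # guard against last-place floating drift: endpoints are exact by contract
  pts$p[nrow(pts)] <- 1
  pts$q[nrow(pts)] <- 1
  structure(pts, resource = resource, basis = basis,
            class = c("lorenz_curve", class(pts)))
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat(sprintf("<lorenz_curve> %s, %s basis, %d regions\n",
              attr(x, "resource"), attr(x, "basis"), nrow(x) - 1L))
  NextMethod()
  invisible(x)
}

#' Lorenz curves for all resources on one basis
#'
#' @param table A [region_table()].
#' @param basis `"population"` or `"area"`.
#' @return A list of `lorenz_curve` objects named by resource.
#' @export
lorenz_curves <- function(table, basis) {
  basis <- match_basis(basis)
  setNames(lapply(resource_kinds, function(res) {
    build_lorenz(table, res, basis)
  }), resource_kinds)
}

#' Flatten Lorenz curves into a plain point table
#'
#' @param curves A `lorenz_curve` or list of them.
#' @return A tibble with columns `resource`, `basis`, `region`, `p`, `q`,
#'   suitable for CSV export.
#' @export
lorenz_points <- function(curves) {
  if (inherits(curves, "lorenz_curve")) curves <- list(curves)
  out <- do.call(rbind, lapply(curves, function(cv) {
    tibble::tibble(resource = attr(cv, "resource"),
                   basis = attr(cv, "basis"),
                   region = cv$region, p = cv$p, q = cv$q)
  }))
  tibble::as_tibble(out)
}
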