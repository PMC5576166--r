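#' Gini concentration result
#'
#' Container for one concentration coefficient with its metadata. Created by
#' [gini_trapezoid()], [gini_grouped()], [gini_oracle()] and
#' [gini_coefficient()].
#'
#' @param coefficient Numeric in `[0, 1]`.
#' @param method One of `"trapezoid"`, `"grouped_formula"`, `"oracle"`.
#' @param n_groups Number of regions (groups) the coefficient was built from.
#' @param resource,basis Optional metadata (one of [resource_kinds],
#'   [basis_kinds]) when the coefficient came from a region table.
#' @return A `gini_result` object.
#' @export
gini_result <- function(coefficient, method, n_groups,
                        resource = NA_character_, basis = NA_character_) {
  structure(
    list(resource = resource, basis = basis,
         coefficient = coefficient, method = method,
         n_groups = as.integer(n_groups)),
    class = "gini_result"
  )
}

#' @export
print.gini_result <- function(x, ...) {
  meta <- if (!is.na(x$resource)) {
    sprintf(" [%s, %s basis]", x$resource, x$basis)
  } else ""
  cat(sprintf("Gini coefficient%s: %.4f (%s, %d groups)\n",
              meta, x$coefficient, x$method, x$n_groups))
  invisible(x)
}

#' Gini coefficient by trapezoidal integration of a Lorenz curve
#'
#' Twice the area between the Lorenz curve and the diagonal equality line,
#' computed as `1 - sum_k (p_k - p_{k-1}) (q_k + q_{k-1})`. This is the
#' package's primary estimator: it is basis-agnostic (weights may be
#' fractional) and needs no integerization.
#'
#' @param curve A `lorenz_curve` from [build_lorenz()].
#' @return A [gini_result()] with method `"trapezoid"`.
#' @examples
#' gini_trapezoid(build_lorenz(load_mongolia_2014(), "physicians", "area"))
#' @export
gini_trapezoid <- function(curve) {
  stopifnot(inherits(curve, "lorenz_curve"))
  p <- curve$p
  q <- curve$q
  g <- 1 - sum(diff(p) * (q[-1] + q[-length(q)]))
  gini_result(g, "trapezoid", nrow(curve) - 1L,
              resource = attr(curve, "resource"),
              basis = attr(curve, "basis"))
}

#' Gini coefficient by the grouped concentration-ratio formula
#'
#' Implements the classical grouped formula
#' `R = sum_l (i_{l-1} + i_l - 1) f_l x_l / ((n - 1) A_n) - 1`,
#' where groups (regions) are sorted by ascending density `x_l`, `f_l` is
#' the group weight (persons or km2), `i_l` the cumulative weight through
#' group l, `n` the total weight and `A_n = sum f_l x_l` the total resource.
#' The formula treats each region as `f_l` identical atomic units holding
#' `x_l` each; `i_l` is read as the cumulative count of those units — the
#' only reading under which equality gives 0 and perfect concentration gives
#' 1. Fractional weights are accepted (the reading extends continuously).
#'
#' Differs from [gini_trapezoid()] only through its `n - 1` denominator, so
#' the two agree to within `1/n`; with population weights in the millions
#' they agree to many decimals.
#'
#' @param weights Positive group weights `f_l` (persons or km2).
#' @param densities Non-negative group densities `x_l` (resource per weight
#'   unit; any common scaling of the densities cancels).
#' @param resource,basis Optional metadata passed to [gini_result()].
#' @return A [gini_result()] with method `"grouped_formula"`.
#' @examples
#' mn <- load_mongolia_2014()
#' gini_grouped(mn$population, mn$physicians / mn$population)
#' @export
gini_grouped <- function(weights, densities,
                         resource = NA_character_, basis = NA_character_) {
  stopifnot(length(weights) == length(densities))
  if (any(weights <= 0) || any(densities < 0)) {
    stop("weights must be positive and densities non-negative",
         call. = FALSE)
  }
  n <- sum(weights)
  if (n <= 1) {
    stop("total weight must exceed 1 for the grouped formula", call. = FALSE)
  }
  A_n <- sum(weights * densities)
  if (A_n == 0) {
    stop("undefined coefficient: total resource amount is zero",
         call. = FALSE)
  }
  ord <- order(densities)
  f <- weights[ord]
  x <- densities[ord]
  i_hi <- cumsum(f)
  i_lo <- c(0, i_hi[-length(i_hi)])
  g <- sum((i_lo + i_hi - 1) * f * x) / ((n - 1) * A_n) - 1
  gini_result(g, "grouped_formula", length(f),
              resource = resource, basis = basis)
}

#' Brute-force Gini oracle by mean absolute difference
#'
#' Expands each region into integer atomic units all holding the region's
#' density, then evaluates `sum_i sum_j |y_i - y_j| / (2 n^2 ybar)` by a
#' literal double loop. Exists purely as an independent check of the other
#' estimators (its `n` denominator matches [gini_trapezoid()]); it refuses
#' instances with more than `max_units` atomic units.
#'
#' @param weights Positive integer unit counts per region (rescale real
#'   weights to small integers first).
#' @param amounts Non-negative resource amounts per region.
#' @param max_units Refusal bound on `sum(weights)` (default 10^4).
#' @return A [gini_result()] with method `"oracle"`.
#' @examples
#' gini_oracle(c(1, 1, 1, 1), c(0, 0, 0, 5)) # 0.75
#' @export
gini_oracle <- function(weights, amounts, max_units = 1e4) {
  stopifnot(length(weights) == length(amounts))
  if (any(weights <= 0) || any(amounts < 0)) {
    stop("weights must be positive and amounts non-negative", call. = FALSE)
  }
  if (any(weights != floor(weights))) {
    stop("oracle needs integer weights; rescale to small integers first",
         call. = FALSE)
  }
  if (sum(weights) > max_units) {
    stop("instance too large for the brute-force oracle (",
         sum(weights), " units > ", max_units,
         "); rescale the weights first", call. = FALSE)
  }
  if (sum(amounts) == 0) {
    stop("undefined coefficient: total resource amount is zero",
         call. = FALSE)
  }
  y <- rep(amounts / weights, times = weights)
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) {
    total <- total + sum(abs(y[i] - y))
  }
  g <- total / (2 * n^2 * mean(y))
  gini_result(g, "oracle", length(weights))
}

#' Gini coefficient of a resource over a region table
#'
#' Front door joining [build_lorenz()] with an estimator. `"trapezoid"`
#' (default) integrates the Lorenz curve; `"grouped_formula"` applies the
#' classical grouped concentration-ratio formula; `"oracle"` runs the
#' brute-force mean-absolute-difference check (small instances only).
#'
#' @param table A [region_table()].
#' @param resource One of [resource_kinds].
#' @param basis `"population"` or `"area"`.
#' @param method Estimator to use.
#' @return A [gini_result()].
#' @examples
#' gini_coefficient(load_mongolia_2014(), "physicians", "population")
#' @export
gini_coefficient <- function(table, resource, basis,
                             method = c("trapezoid", "grouped_formula",
                                        "oracle")) {
  stopifnot(inherits(table, "region_table"))
  resource <- match_resource(resource)
  basis <- match_basis(basis)
  method <- match.arg(method)
  weights <- if (basis == "population") table$population else table$area_km2
  switch(method,
    trapezoid = gini_trapezoid(build_lorenz(table, resource, basis)),
    grouped_formula = gini_grouped(weights, table[[resource]] / weights,
                                   resource = resource, basis = basis),
    oracle = {
      res <- gini_oracle(round(weights), table[[resource]])
      res$resource <- resource
      res$basis <- basis
      res
    }
  )
}

#' All six Gini coefficients of a table
#'
#' @param table A [region_table()].
#' @param method Estimator, as in [gini_coefficient()].
#' @param digits Decimals for the rounded column (half-up; default 2, the
#'   reporting convention).
#' @return A tibble with columns `resource`, `basis`, `gini` (full
#'   precision), `gini_rounded`.
#' @examples
#' gini_table(load_mongolia_2014())
#' @export
gini_table <- function(table, method = "trapezoid", digits = 2) {
  grid <- expand.grid(resource = resource_kinds, basis = basis_kinds,
                      stringsAsFactors = FALSE)
  g <- mapply(function(res, b) {
    gini_coefficient(table, res, b, method = method)$coefficient
  }, grid$resource, grid$basis)
  tibble::tibble(resource = grid$resource, basis = grid$basis,
                 gini = unname(g),
                 gini_rounded = round_half_up(unname(g), digits))
}
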