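#' Supply-category labels for k classes
#'
#' Map classes run red (inadequate) through green (adequate); intermediate
#' colours are transition classes. For k outside 2..4 generic labels are
#' used.
#'
#' @param k Number of classes (>= 2).
#' @return Character vector of k labels, lowest class first.
#' @export
supply_labels <- function(k) {
  stopifnot(k >= 2)
  switch(as.character(k),
         "2" = c("red", "green"),
         "3" = c("red", "yellow", "green"),
         "4" = c("red", "orange", "yellow", "green"),
         paste0("class_", seq_len(k)))
}

#' Cut-off scheme for supply categories
#'
#' @param breakpoints Strictly increasing numeric vector (k - 1 values for
#'   k classes).
#' @param labels Category labels, lowest class first; defaults to
#'   [supply_labels()].
#' @param resource,basis Optional metadata.
#' @return A `cutoff_scheme` object.
#' @export
cutoff_scheme <- function(breakpoints, labels = NULL,
                          resource = NA_character_, basis = NA_character_) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 1 || is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be a non-empty strictly increasing vector",
         call. = FALSE)
  }
  k <- length(breakpoints) + 1L
  labels <- labels %||% supply_labels(k)
  if (length(labels) != k) {
    stop("need exactly ", k, " labels for ", k, " classes", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, labels = labels,
                 resource = resource, basis = basis),
            class = "cutoff_scheme")
}

#' @export
print.cutoff_scheme <- function(x, ...) {
  cat(sprintf("<cutoff_scheme> %d classes%s\n", length(x$labels),
              if (is.na(x$basis)) "" else
                sprintf(" (%s, %s basis)", x$resource, x$basis)))
  cat("  breaks:", paste(signif(x$breakpoints, 6), collapse = ", "), "\n")
  cat("  labels:", paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

# dynamic program: minimal within-class sum of squares over contiguous
# partitions of sorted x into k classes; returns indices of last element
# of classes 1..k-1
jenks_partition <- function(x_sorted, k) {
  n <- length(x_sorted)
  cs <- cumsum(x_sorted)
  cs2 <- cumsum(x_sorted^2)
  # ss(i, j): within-class SS of x[i..j]
  ss <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, nrow = k, ncol = n)
  back <- matrix(0L, nrow = k, ncol = n)
  for (j in seq_len(n)) cost[1, j] <- ss(1, j)
  if (k > 1) {
    for (cls in 2:k) {
      for (j in cls:n) {
        for (m in (cls - 1):(j - 1)) {
          cand <- cost[cls - 1, m] + ss(m + 1, j)
          if (cand < cost[cls, j] - 1e-12) {
            cost[cls, j] <- cand
            back[cls, j] <- m
          }
        }
      }
    }
  }
  ends <- integer(k)
  j <- n
  for (cls in k:1) {
    ends[cls] <- j
    j <- back[cls, j]
  }
  ends[-k]
}

#' Natural-breaks (Fisher–Jenks) cut-off values
#'
#' Finds the contiguous partition of the sorted values into `k` classes that
#' minimizes the total within-class sum of squared deviations (exact dynamic
#' program, deterministic — no seed sensitivity), then places each
#' breakpoint at the midpoint between the adjacent classes' boundary values.
#'
#' @param values Numeric vector with at least `k` distinct values.
#' @param k Number of classes (default 4, one per map colour).
#' @param resource,basis Optional metadata stored on the scheme.
#' @return A [cutoff_scheme()].
#' @examples
#' natural_breaks(c(1, 2, 3, 10, 11, 12, 30), k = 3)
#' @export
natural_breaks <- function(values, k = 4,
                           resource = NA_character_, basis = NA_character_) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  n_distinct <- length(unique(values))
  if (k < 2 || k > n_distinct) {
    stop("need 2 <= k <= number of distinct values (", n_distinct, ")",
         call. = FALSE)
  }
  x <- sort(values)
  ends <- jenks_partition(x, k)
  breakpoints <- (x[ends] + x[ends + 1]) / 2
  cutoff_scheme(breakpoints, resource = resource, basis = basis)
}

#' Assign supply categories from a cut-off scheme
#'
#' A value falls in the class whose interval contains it; a value exactly on
#' a breakpoint joins the higher class. On the area basis, any density of at
#' most 1 resource per 1 000 km2 is forced to the lowest (red) class
#' regardless of the clustering — the inadequate-supply rule of the map
#' legend.
#'
#' @param values Numeric densities.
#' @param scheme A [cutoff_scheme()].
#' @return Ordered factor of category labels (lowest class first).
#' @examples
#' sch <- natural_breaks(c(0.5, 2, 8, 40, 200), k = 4, basis = "area")
#' assign_category(c(0.9, 300), sch)
#' @export
assign_category <- function(values, scheme) {
  stopifnot(inherits(scheme, "cutoff_scheme"))
  idx <- findInterval(values, scheme$breakpoints) + 1L
  if (identical(scheme$basis, "area")) {
    idx[values <= 1] <- 1L
  }
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' Categorize every region of a table for one resource and basis
#'
#' Derives the per-region density indicator, fits [natural_breaks()] on it,
#' and assigns supply categories.
#'
#' @param table A [region_table()].
#' @param resource One of [resource_kinds].
#' @param basis `"population"` or `"area"`.
#' @param k Number of classes (default 4).
#' @return A tibble with columns `region`, `resource`, `basis`, `value`,
#'   `category`, joined to the fitted scheme via the `"scheme"` attribute.
#' @examples
#' categorize_table(load_mongolia_2014(), "physicians", "area")
#' @export
categorize_table <- function(table, resource, basis, k = 4) {
  stopifnot(inherits(table, "region_table"))
  values <- indicator_values(table, resource, basis)
  scheme <- natural_breaks(unname(values), k = k,
                           resource = match_resource(resource),
                           basis = match_basis(basis))
  out <- tibble::tibble(region = table$region,
                        resource = match_resource(resource),
                        basis = match_basis(basis),
                        value = unname(values),
                        category = assign_category(unname(values), scheme))
  attr(out, "scheme") <- scheme
  out
}
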