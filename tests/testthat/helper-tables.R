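# small constructors and independent brute-force oracles shared across tests

toy_table <- function(pop, area, phys, nurses = phys, beds = phys,
                      names = NULL, label = "toy") {
  n <- length(pop)
  region_table(data.frame(
    region = names %||% paste0("r", seq_len(n)),
    population = pop, area_km2 = area,
    physicians = phys, nurses = nurses, hospital_beds = beds
  ), label = label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive search over every contiguous partition of sorted values into
# k classes; independent of the package's dynamic program
exhaustive_breaks_ss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ss_of <- function(v) sum((v - mean(v))^2)
  best <- Inf
  best_ends <- NULL
  cuts <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(cuts))) {
    ends <- c(cuts[, j], n)
    starts <- c(1, head(ends, -1) + 1)
    total <- sum(mapply(function(s, e) ss_of(x[s:e]), starts, ends))
    if (total < best - 1e-12) {
      best <- total
      best_ends <- ends
    }
  }
  list(ss = best, ends = best_ends[-k], x = x)
}

# total within-class SS implied by a cutoff scheme applied to values
scheme_within_ss <- function(values, scheme) {
  cls <- findInterval(sort(values), scheme$breakpoints)
  sum(tapply(sort(values), cls, function(v) sum((v - mean(v))^2)))
}
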