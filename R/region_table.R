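#' Construct and validate a region table
#'
#' A region table is a tibble with one row per administrative region and the
#' six columns `region`, `population`, `area_km2`, `physicians`, `nurses`,
#' `hospital_beds`. Populations are positive integers, areas positive reals,
#' resource counts non-negative integers, and region names unique. Raw counts
#' are authoritative: derived densities are always recomputed from them, never
#' stored.
#'
#' A single-region table is a valid container (it can be written to CSV), but
#' every concentration or comparison computation requires at least two
#' regions and [read_region_csv()] enforces that minimum at read time.
#'
#' @param data A data frame with the six required columns.
#' @param label Optional free-text label (e.g. a country-year).
#' @return A validated `region_table` (a tibble subclass).
#' @examples
#' region_table(data.frame(
#'   region = c("A", "B"), population = c(1000, 2000),
#'   area_km2 = c(10, 20), physicians = c(5, 4),
#'   nurses = c(7, 9), hospital_beds = c(20, 30)
#' ), label = "toy")
#' @export
region_table <- function(data, label = NULL) {
  required <- c("region", "population", "area_km2",
                "physicians", "nurses", "hospital_beds")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("region table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::as_tibble(data)[required]
  tbl$region <- as.character(tbl$region)

  check_field <- function(values, field, ok, what) {
    bad <- which(!ok(values))
    if (length(bad) > 0) {
      stop(sprintf("invalid %s in row %d (region '%s'): %s must be %s",
                   field, bad[1], tbl$region[bad[1]], field, what),
           call. = FALSE)
    }
  }
  is_num <- function(x) is.numeric(x) & is.finite(x)
  is_whole <- function(x) is_num(x) & x == floor(x)
  check_field(tbl$population, "population",
              function(x) is_whole(x) & x > 0, "a positive integer")
  check_field(tbl$area_km2, "area_km2",
              function(x) is_num(x) & x > 0, "a positive number")
  for (res in resource_kinds) {
    check_field(tbl[[res]], res,
                function(x) is_whole(x) & x >= 0, "a non-negative integer")
  }
  if (anyDuplicated(tbl$region)) {
    dup <- tbl$region[duplicated(tbl$region)][1]
    stop("region names must be unique; duplicated: '", dup, "'",
         call. = FALSE)
  }
  if (nrow(tbl) < 1) {
    stop("a region table needs at least one region", call. = FALSE)
  }
  structure(tbl,
            label = label,
            class = c("region_table", class(tbl)))
}

#' @export
print.region_table <- function(x, ...) {
  label <- attr(x, "label")
  cat(sprintf("<region_table> %d regions%s\n", nrow(x),
              if (is.null(label)) "" else paste0(" — ", label)))
  NextMethod()
  invisible(x)
}

#' Label of a region table
#'
#' @param table A [region_table()].
#' @return The free-text label, or `NULL`.
#' @export
table_label <- function(table) attr(table, "label")

#' Read a region table from CSV
#'
#' The CSV dialect is fixed: UTF-8, comma separator, dot decimal, and a
#' header naming exactly the six required columns (`region`, `population`,
#' `area_km2`, `physicians`, `nurses`, `hospital_beds`). Thousands separators
#' are rejected. At least two region rows are required, since no
#' concentration or comparison measure is defined on fewer.
#'
#' @param path Path to a CSV file.
#' @param label Optional label; defaults to the file name.
#' @return A validated [region_table()], rows in file order.
#' @export
read_region_csv <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  required <- c("region", "population", "area_km2",
                "physicians", "nurses", "hospital_beds")
  header <- names(readr::spec_csv(path)$cols)
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    stop("CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # parse problems are re-raised as errors below, so silence readr's warning
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      region = readr::col_character(),
      population = readr::col_double(),
      area_km2 = readr::col_double(),
      physicians = readr::col_double(),
      nurses = readr::col_double(),
      hospital_beds = readr::col_double(),
      .default = readr::col_skip()
    ),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop(sprintf(
      "non-numeric value in row %d, column '%s' (got '%s'); %s",
      probs$row[1] - 1, header[probs$col[1]], probs$actual[1],
      "numbers must use dot decimals and no thousands separators"),
      call. = FALSE)
  }
  if (nrow(raw) < 2) {
    stop("a region table needs at least 2 regions; found ", nrow(raw),
         call. = FALSE)
  }
  region_table(raw, label = label %||% basename(path))
}

#' Write a region table to CSV
#'
#' Inverse of [read_region_csv()]: a written table re-reads identically
#' (raw counts only; no derived columns are emitted).
#'
#' @param table A [region_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_csv <- function(table, path) {
  stopifnot(inherits(table, "region_table"))
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' The 2014 Mongolian province-level table
#'
#' Raw 2014 counts for the 22 first-level administrative regions of Mongolia
#' (the capital Ulaanbaatar plus 21 aimags): population, land area, and the
#' numbers of physicians, nurses and hospital beds, as compiled by the
#' Ministry of Health and the National Statistical Information Service of
#' Mongolia. Only raw counts are stored; published per-10 000 density
#' columns for these data contain a few cells inconsistent with the raw
#' counts, so densities are always recomputed.
#'
#' @return A 22-row [region_table()] labelled `"Mongolia 2014"`.
#' @examples
#' mn <- load_mongolia_2014()
#' sum(mn$physicians) # 9364
#' @export
load_mongolia_2014 <- function() {
  path <- system.file("extdata", "mongolia_2014.csv", package = "hequity",
                      mustWork = TRUE)
  read_region_csv(path, label = "Mongolia 2014")
}
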