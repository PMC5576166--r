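#' Run the full equity analysis on a region table
#'
#' End-to-end pipeline: per-region density indicators with settlement
#' categories, per-category summaries, the six Gini coefficients (three
#' resources on two bases), the six urban+suburban vs. rural Mann–Whitney
#' tests, natural-breaks supply categories, Lorenz curve points, WHO
#' workforce assessment, and a provenance block. The report is
#' deterministic: the same table and options always produce byte-identical
#' CSV exports.
#'
#' @param table A [region_table()].
#' @param k_classes Number of supply classes for [categorize_table()].
#' @param gini_method Estimator for [gini_table()].
#' @param mw_method,continuity Passed to [compare_settlement_groups()].
#' @return An `analysis_report` list with elements `label`, `indicators`,
#'   `group_summaries`, `gini`, `utests`, `categories`, `lorenz`,
#'   `workforce`, `provenance`.
#' @examples
#' rep <- run_full_analysis(load_mongolia_2014())
#' rep$gini
#' @export
run_full_analysis <- function(table, k_classes = 4,
                              gini_method = "trapezoid",
                              mw_method = "asymptotic", continuity = TRUE) {
  stopifnot(inherits(table, "region_table"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) abort_stage(name, conditionMessage(e)))
  }
  indicators <- stage("indicators", indicator_table(table))
  summaries <- stage("indicators", summarize_groups(table))
  gini <- stage("lorenz_gini", gini_table(table, method = gini_method))
  utests <- stage("inference",
                  utest_table(table, method = mw_method,
                              continuity = continuity))
  categories <- stage("cutoffs", {
    grid <- expand.grid(resource = resource_kinds, basis = basis_kinds,
                        stringsAsFactors = FALSE)
    do.call(rbind, mapply(function(res, b) {
      out <- categorize_table(table, res, b, k = k_classes)
      attr(out, "scheme") <- NULL
      out
    }, grid$resource, grid$basis, SIMPLIFY = FALSE))
  })
  lorenz <- stage("lorenz_gini", rbind(
    lorenz_points(lorenz_curves(table, "population")),
    lorenz_points(lorenz_curves(table, "area"))
  ))
  wf <- workforce_density(table)
  workforce <- tibble::tibble(
    region = names(wf),
    physicians_nurses_per_10000 = unname(wf),
    who_assessment = who_threshold_check(unname(wf))
  )
  structure(
    list(label = table_label(table),
         indicators = indicators,
         group_summaries = summaries,
         gini = gini,
         utests = utests,
         categories = categories,
         lorenz = lorenz,
         workforce = workforce,
         provenance = report_provenance(table, k_classes, gini_method,
                                        mw_method, continuity)),
    class = "analysis_report"
  )
}

report_provenance <- function(table, k_classes, gini_method,
                              mw_method, continuity) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_region_csv(table, tmp)
  list(
    input_digest = unname(tools::md5sum(tmp)),
    n_regions = nrow(table),
    package_version = as.character(utils::packageVersion("hequity")),
    parameters = list(k_classes = k_classes, gini_method = gini_method,
                      mw_method = mw_method, continuity = continuity)
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report>%s — %d regions\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$provenance$n_regions))
  cat("\nGini coefficients:\n")
  print(x$gini)
  cat("\nUrban+suburban vs. rural (Mann-Whitney U):\n")
  print(x$utests)
  invisible(x)
}

#' Write an analysis report to a directory of CSV files
#'
#' Emits `indicators.csv`, `group_summaries.csv`, `gini.csv`, `utests.csv`,
#' `categories.csv`, `lorenz_points.csv`, `workforce.csv` and
#' `provenance.json`. Numeric columns are written at full precision, so
#' repeated runs on the same input are byte-identical. Optionally renders
#' the Lorenz and log-density figures next to them.
#'
#' @param report An `analysis_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @param table The source [region_table()]; required only when
#'   `save_plots = TRUE`.
#' @param save_plots Render `lorenz_<basis>.png` and
#'   `scatter_<resource>.png` alongside the CSVs (needs a working png
#'   device).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, table = NULL, save_plots = FALSE) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(dir, name)
  readr::write_csv(report$indicators, out("indicators.csv"), progress = FALSE)
  readr::write_csv(report$group_summaries, out("group_summaries.csv"),
                   progress = FALSE)
  readr::write_csv(report$gini, out("gini.csv"), progress = FALSE)
  readr::write_csv(report$utests, out("utests.csv"), progress = FALSE)
  readr::write_csv(report$categories, out("categories.csv"), progress = FALSE)
  readr::write_csv(report$lorenz, out("lorenz_points.csv"), progress = FALSE)
  readr::write_csv(report$workforce, out("workforce.csv"), progress = FALSE)
  jsonlite::write_json(report$provenance, out("provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (save_plots) {
    stopifnot(inherits(table, "region_table"))
    for (b in basis_kinds) {
      ggplot2::ggsave(out(paste0("lorenz_", b, ".png")),
                      plot_lorenz(table, b),
                      width = 6, height = 5, dpi = 150)
    }
    for (res in resource_kinds) {
      ggplot2::ggsave(out(paste0("scatter_", res, ".png")),
                      plot_density_scatter(table, res),
                      width = 6, height = 5, dpi = 150)
    }
  }
  invisible(dir)
}
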