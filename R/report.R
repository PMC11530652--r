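#' @export
print.abbrex_report <- function(x, ...) {
  cat(sprintf(
    "<abbrex_report> %d turns | strategy %s (%s) | %d options | context %s\n  mean KSR %.3f | single-call fraction %.3f\n",
    x$n_turns, x$config$strategy,
    if (is.na(x$config$ae_version)) "-" else x$config$ae_version,
    x$config$n_options, if (isTRUE(x$config$use_context)) "on" else "off",
    x$mean_ksr, x$single_call_fraction
  ))
  invisible(x)
}

#' Tidy a simulation report into per-turn rows
#'
#' @param x An `abbrex_report`.
#' @param ... Unused.
#' @return The per-turn outcome tibble (one row per simulated turn, with the
#'   full action ledger in columns).
#' @method tidy abbrex_report
#' @export
tidy.abbrex_report <- function(x, ...) {
  x$outcomes
}

#' One-row summary of a simulation report
#'
#' @param x An `abbrex_report`.
#' @param ... Unused.
#' @return A one-row tibble: `strategy`, `ae_version`, `n_options`,
#'   `use_context`, `mean_ksr`, `single_call_fraction`, `n_turns`.
#' @method glance abbrex_report
#' @export
glance.abbrex_report <- function(x, ...) {
  tibble::tibble(
    strategy = x$config$strategy,
    ae_version = x$config$ae_version,
    n_options = x$config$n_options,
    use_context = x$config$use_context,
    mean_ksr = x$mean_ksr,
    single_call_fraction = x$single_call_fraction,
    n_turns = x$n_turns
  )
}

#' Plot the per-turn KSR distribution of a report
#'
#' @param object An `abbrex_report`.
#' @param ... Unused.
#' @return A ggplot: KSR histogram filled by solve path.
#' @method autoplot abbrex_report
#' @export
autoplot.abbrex_report <- function(object, ...) {
  ggplot2::ggplot(object$outcomes,
                  ggplot2::aes(x = .data$ksr, fill = .data$solved_by)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$mean_ksr, linetype = "dashed") +
    ggplot2::labs(x = "keystroke-saving rate", y = "turns",
                  fill = "solved by",
                  title = sprintf("Strategy %s, %d options, mean KSR %.3f",
                                  object$config$strategy,
                                  object$config$n_options, object$mean_ksr)) +
    ggplot2::theme_minimal()
}

#' Plot a number-of-options sweep
#'
#' @param object An `abbrex_sweep` tibble from [sweep_n_options()].
#' @param ... Unused.
#' @return A ggplot of mean KSR against the number of prediction options.
#' @method autoplot abbrex_sweep
#' @export
autoplot.abbrex_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_options, y = .data$mean_ksr,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$n_options)) +
    ggplot2::labs(x = "number of prediction options", y = "mean KSR",
                  colour = "strategy") +
    ggplot2::theme_minimal()
}

#' Write a simulation report to disk
#'
#' Writes `report.json` (config, summary and full per-turn ledgers) and
#' `summary.tsv` (the [glance()] row) into `dir`.
#'
#' @param report An `abbrex_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      config = report$config[!vapply(report$config, is.null, logical(1))],
      summary = glance(report),
      outcomes = report$outcomes
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  utils::write.table(glance(report), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
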