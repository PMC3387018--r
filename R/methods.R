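# Methods on the mz_id result object: print, broom-style tidy()/glance(),
# and ggplot2 autoplot().

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.mz_id <- function(x, ...) {
  n_q <- nrow(x$queries)
  n_hit <- sum(x$queries$n_identifications > 0)
  cat("<mz_id> ", x$params$input, " run, ", x$params$polarity, " mode, ",
      x$params$tol_ppm, " ppm\n", sep = "")
  cat("  sources: ", paste(x$params$sources, collapse = ", "), "\n", sep = "")
  if (!is.null(x$groups)) {
    cat("  ", n_q, " peak(s) in ", nrow(x$groups), " annotation group(s)\n",
        sep = "")
  } else {
    cat("  ", n_q, " quer", if (n_q == 1) "y" else "ies", "\n", sep = "")
  }
  cat("  ", nrow(x$identifications), " merged identification(s); ", n_hit,
      "/", n_q, " with at least one hit\n", sep = "")
  invisible(x)
}

#' Tidy an identification result into flat rows
#'
#' @param x An `mz_id` result object.
#' @param ... Unused.
#' @return The [result_rows()] tibble: one row per (query, identification),
#'   queries without hits keeping an empty row.
#' @export
tidy.mz_id <- function(x, ...) {
  result_rows(x)
}

#' One-row summary of an identification run
#'
#' @param x An `mz_id` result object.
#' @param ... Unused.
#' @return A one-row tibble: query/identification counts, coverage, and the
#'   median |ppm error| of the best hit per identified query.
#' @export
glance.mz_id <- function(x, ...) {
  ids <- x$identifications
  tibble::tibble(
    n_queries = nrow(x$queries),
    n_groups = if (is.null(x$groups)) NA_integer_ else nrow(x$groups),
    n_identifications = nrow(ids),
    n_queries_identified = sum(x$queries$n_identifications > 0),
    identified_fraction = mean(x$queries$n_identifications > 0),
    median_abs_ppm = if (nrow(ids)) stats::median(abs(ids$best_ppm_error)) else NA_real_,
    tol_ppm = x$params$tol_ppm,
    polarity = x$params$polarity
  )
}

#' Plot an identification result
#'
#' Two-panel overview: merged identifications contributed per source, and
#' the distribution of signed ppm errors of the merged entries within the
#' search tolerance.
#'
#' @param object An `mz_id` result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mz_id <- function(object, ...) {
  ids <- object$identifications
  src <- tibble::tibble(
    source_db = unlist(strsplit(ids$source_dbs, ";", fixed = TRUE))
  )
  p1 <- ggplot2::ggplot(src, ggplot2::aes(x = .data$source_db)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "merged identifications",
                  title = "Identifications per contributing source") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(ids, ggplot2::aes(x = .data$best_ppm_error)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * object$params$tol_ppm, linetype = "dashed"
    ) +
    ggplot2::labs(x = "best ppm error", y = "entries",
                  title = "Mass-error distribution of merged entries") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p1, p2, ncol = 2)
  } else {
    p2
  }
}

#' Plot identification coverage with and without ion annotation
#'
#' Companion bar chart for comparing two runs of the same peaks (e.g. the
#' annotated CAMERA run against the bare m/z run): number of queries with at
#' least one identification in each.
#'
#' @param annotated,bare `mz_id` results over the same peaks.
#' @return A ggplot object.
#' @export
plot_annotation_benefit <- function(annotated, bare) {
  stopifnot(inherits(annotated, "mz_id"), inherits(bare, "mz_id"))
  df <- tibble::tibble(
    run = factor(c("annotated", "bare m/z"), levels = c("annotated", "bare m/z")),
    identified = c(sum(annotated$queries$n_identifications > 0),
                   sum(bare$queries$n_identifications > 0))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$identified)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::labs(x = NULL, y = "peaks with ≥ 1 identification",
                  title = "Effect of ion annotation on coverage") +
    ggplot2::theme_minimal()
}
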