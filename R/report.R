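#' Compare denoisers on one noisy image
#'
#' Runs each denoiser on the same noisy image and evaluates the averaged CNR
#' and COV over a set of ROI pairs, with the untouched noisy image as the
#' first (baseline) row.  Two ratio summaries relate each method to the
#' baseline: `cnr_gain_pct` \eqn{= 100 (CNR - CNR_0) / CNR_0} and
#' `cov_reduction_factor` \eqn{= COV_0 / COV}.  A method that throws is
#' recorded as a failed row (with a warning) and the report is still
#' produced; if every method fails, an error is raised.
#'
#' @param noisy the noisy [us_image()].
#' @param methods named list of denoiser functions, each mapping an image to
#'   an image (e.g. `list(nlm = function(x) nlm_denoise(x, cfg))`).
#' @param roi_pairs list of target/background ROI pairs (see
#'   [average_metric()]).
#' @param clean optional noise-free reference; when supplied, a
#'   root-mean-square error column `rmse_vs_clean` is added.
#' @param metadata optional list stored on the report (configs, seeds, ...).
#' @return A `quality_report`: a tibble with columns `method`, `cnr`, `cov`,
#'   `cnr_gain_pct`, `cov_reduction_factor`, optionally `rmse_vs_clean`, and
#'   `failed`; ROI geometry and `metadata` are kept in attributes.
#' @export
#' @examples
#' spec <- default_ats_grayscale_spec(c(96, 144))
#' noisy <- simulate_speckle(render_phantom(spec), seed = 3)
#' rep <- compare_denoisers(
#'   noisy,
#'   list(median = function(x) median_filter(x, 1)),
#'   ats_roi_pairs(spec)
#' )
#' tidy(rep)
compare_denoisers <- function(noisy, methods, roi_pairs, clean = NULL,
                              metadata = list()) {
  noisy <- as_us_image(noisy)
  if (length(methods) < 1L || is.null(names(methods)) ||
    any(!nzchar(names(methods)))) {
    usnlm_abort("`methods` must be a non-empty named list of functions.", "validation")
  }
  eval_one <- function(im) {
    list(
      cnr = as.numeric(average_metric(im, roi_pairs, "cnr")),
      cov = as.numeric(average_metric(im, roi_pairs, "cov")),
      rmse = if (is.null(clean)) {
        NA_real_
      } else {
        sqrt(mean((as_pixel_matrix(im) - as_pixel_matrix(clean))^2))
      }
    )
  }
  base <- eval_one(noisy)
  rows <- purrr::imap(methods, function(f, nm) {
    res <- tryCatch(
      {
        den <- as_us_image(f(noisy))
        c(eval_one(den), list(failed = FALSE))
      },
      error = function(e) {
        warning(
          sprintf("Method '%s' failed: %s", nm, conditionMessage(e)),
          call. = FALSE
        )
        list(cnr = NA_real_, cov = NA_real_, rmse = NA_real_, failed = TRUE)
      }
    )
    tibble::tibble(
      method = nm, cnr = res$cnr, cov = res$cov,
      rmse_vs_clean = res$rmse, failed = res$failed
    )
  })
  tbl <- dplyr::bind_rows(
    tibble::tibble(
      method = "noisy", cnr = base$cnr, cov = base$cov,
      rmse_vs_clean = base$rmse, failed = FALSE
    ),
    dplyr::bind_rows(rows)
  )
  if (all(tbl$failed[-1L])) {
    usnlm_abort("All denoising methods failed.", "validation")
  }
  tbl <- dplyr::mutate(
    tbl,
    cnr_gain_pct = 100 * (.data$cnr - base$cnr) / base$cnr,
    cov_reduction_factor = base$cov / .data$cov
  )
  tbl <- tbl[, c(
    "method", "cnr", "cov", "cnr_gain_pct", "cov_reduction_factor",
    if (!is.null(clean)) "rmse_vs_clean", "failed"
  )]
  new_quality_report(tbl, roi_pairs = roi_pairs, metadata = metadata)
}

new_quality_report <- function(tbl, roi_pairs = NULL, metadata = list()) {
  structure(
    tbl,
    roi_pairs = roi_pairs,
    metadata = metadata,
    class = c("quality_report", class(tibble::tibble()))
  )
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  NextMethod()
  invisible(x)
}

#' Tidy / summarize a quality report
#'
#' `tidy()` returns the per-method metric table as a plain tibble.
#' `glance()` returns a one-row summary: method count and the best method by
#' each metric with its ratio summary against the noisy baseline.
#'
#' @param x a `quality_report` from [compare_denoisers()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.quality_report <- function(x, ...) {
  tibble::as_tibble(unclass_report(x))
}

#' @rdname tidy.quality_report
#' @export
glance.quality_report <- function(x, ...) {
  tbl <- tidy(x)
  cand <- dplyr::filter(tbl, .data$method != "noisy", !.data$failed)
  best_cnr <- cand$method[which.max(cand$cnr)]
  best_cov <- cand$method[which.min(cand$cov)]
  tibble::tibble(
    n_methods = nrow(tbl) - 1L,
    n_failed = sum(tbl$failed),
    best_cnr_method = best_cnr,
    best_cnr_gain_pct = max(cand$cnr_gain_pct),
    best_cov_method = best_cov,
    best_cov_reduction_factor = max(cand$cov_reduction_factor)
  )
}

unclass_report <- function(x) {
  attr(x, "roi_pairs") <- NULL
  attr(x, "metadata") <- NULL
  class(x) <- setdiff(class(x), "quality_report")
  x
}

#' Plot a quality report
#'
#' Side-by-side bar panels of CNR (higher is better) and COV (lower is
#' better) per method, in report row order with the noisy baseline first.
#'
#' @param object a `quality_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.quality_report <- function(object, ...) {
  tbl <- tidy(object)
  long <- tidyr::pivot_longer(
    tbl[!tbl$failed, c("method", "cnr", "cov")],
    cols = c("cnr", "cov"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(
    long$metric,
    levels = c("cnr", "cov"),
    labels = c("CNR (higher is better)", "COV (lower is better)")
  )
  long$method <- factor(long$method, levels = tbl$method)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Write / read a quality report
#'
#' CSV holds the metric table (losslessly: doubles are written with
#' shortest-round-trip precision); JSON additionally carries the ROI
#' geometry and metadata.
#'
#' @param report a `quality_report`.
#' @param csv_path,json_path destinations (either may be `NULL`).
#' @param path a CSV written by `write_quality_report()`.
#' @return `write_quality_report()`: invisibly, a list of the paths written.
#'   `read_quality_report()`: a `quality_report`.
#' @export
write_quality_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "quality_report"))
  tbl <- tidy(report)
  if (!is.null(csv_path)) {
    out <- tbl
    for (col in names(out)) {
      # doubles as shortest-exact decimal strings so the round trip is exact
      if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
    }
    readr::write_csv(out, csv_path)
  }
  if (!is.null(json_path)) {
    rois <- attr(report, "roi_pairs")
    jsonlite::write_json(
      list(
        report = tbl,
        roi_pairs = purrr::map(rois %||% list(), function(p) {
          list(target = roi_to_list(p$target), background = roi_to_list(p$background))
        }),
        metadata = attr(report, "metadata")
      ),
      json_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' @rdname write_quality_report
#' @export
read_quality_report <- function(path) {
  # base R's strtod parses the 17-digit decimals back to the identical doubles
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_quality_report(tibble::as_tibble(tbl))
}
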