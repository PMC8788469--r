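#' Cook's-distance outliers of a simple linear regression
#'
#' Fits ordinary least squares `y ~ x` and returns the indices of points
#' whose Cook's distance exceeds `k` times the mean Cook's distance. A
#' single pass: the regression is not refit iteratively.
#'
#' @param x,y Numeric vectors of equal length (at least 4 points).
#' @param k Positive multiplier of the mean distance (default 3).
#' @return Integer vector of outlier indices (possibly empty).
#' @export
#' @examples
#' x <- 1:10; y <- 2 * x; y[4] <- 25
#' cooks_outliers(x, y)
cooks_outliers <- function(x, y, k = 3) {
  stopifnot(length(x) == length(y), length(x) >= 4, k > 0)
  if (stats::var(x) == 0) abort("`x` is degenerate (all values equal)")
  fit <- lm(y ~ x)
  # an (essentially) exact fit has no influential points; guard against
  # 0/0 Cook's distances built from float-noise residuals
  sst <- sum((y - mean(y))^2)
  if (sum(fit$residuals^2) <= 1e-12 * max(sst, 1e-300)) return(integer(0))
  d <- cooks.distance(fit)
  which(unname(d) > k * mean(d))
}

new_calibration <- function(fit, points, removed_accessions) {
  y <- fit$model[[1]]
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(
    list(
      slope = unname(coef(fit)[["lx"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      r2 = r2,
      removed_accessions = removed_accessions,
      n_points = sum(points$retained),
      space = "log10-log10",
      points = points
    ),
    class = "calibration"
  )
}

#' Fit a standard-of-reference calibration
#'
#' Regresses `log10(expected fmol)` on `log10(observed relative abundance)`
#' for the spiked standard proteins. Standards observed at zero or absent
#' are excluded before fitting (a message reports how many). Cook's-distance
#' outliers (distance greater than `k` times the mean) are removed in a
#' single pass and the line refit on the survivors.
#'
#' @param standards Tibble with one row per standard protein.
#' @param observed,expected,accession Columns of `standards` holding the
#'   observed relative abundance, the expected amount in fmol, and the
#'   protein accession (tidy-eval; defaults `abundance`, `expected_fmol`,
#'   `accession`).
#' @param k Cook's-distance multiplier passed to [cooks_outliers()].
#' @return An object of class `calibration` with elements `slope`,
#'   `intercept` (log10-fmol units), `r2` (computed on retained points),
#'   `removed_accessions`, `n_points`, `space` (`"log10-log10"`) and the
#'   point table `points`. Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_calibration <- function(standards, observed = abundance,
                            expected = expected_fmol,
                            accession = accession, k = 3) {
  stopifnot(is.data.frame(standards))
  dat <- tibble::tibble(
    accession = as.character(dplyr::pull(standards, {{ accession }})),
    observed = dplyr::pull(standards, {{ observed }}),
    expected = dplyr::pull(standards, {{ expected }})
  )
  unusable <- is.na(dat$observed) | dat$observed <= 0 |
    is.na(dat$expected) | dat$expected <= 0
  if (any(unusable)) {
    inform(sprintf(
      "excluding %d standard(s) with absent or non-positive observed/expected values",
      sum(unusable)
    ))
    dat <- dat[!unusable, , drop = FALSE]
  }
  if (nrow(dat) < 4L) {
    abort(sprintf(
      "only %d usable standard(s); at least 4 detected standards are required for regression",
      nrow(dat)
    ))
  }
  lx <- log10(dat$observed)
  ly <- log10(dat$expected)
  out_idx <- cooks_outliers(lx, ly, k = k)
  retained <- !seq_along(lx) %in% out_idx
  points <- tibble::tibble(
    accession = dat$accession,
    log10_observed = lx,
    log10_expected = ly,
    retained = retained
  )
  fit <- lm(ly ~ lx, subset = retained)
  new_calibration(fit, points, removed_accessions = dat$accession[out_idx])
}

#' Pool replicate calibrations into one standard of reference
#'
#' Fits a single regression on the union of the retained points of several
#' per-replicate calibration models (the bulk-replicate standard of
#' reference). No further outlier removal is performed.
#'
#' @param models List of `calibration` objects.
#' @return A `calibration` object; `removed_accessions` is the union of the
#'   per-replicate removals.
#' @export
pool_reference <- function(models) {
  if (length(models) == 0L) abort("`models` must contain at least one calibration")
  stopifnot(all(vapply(models, inherits, logical(1), "calibration")))
  spaces <- unique(vapply(models, `[[`, character(1), "space"))
  if (length(spaces) != 1L) abort("all models must share the same space")
  points <- purrr::map(models, \(m) m$points[m$points$retained, ]) |>
    purrr::list_rbind()
  fit <- lm(log10_expected ~ lx,
            data = dplyr::rename(points, lx = "log10_observed"))
  new_calibration(
    fit, points,
    removed_accessions = unique(unlist(purrr::map(models, "removed_accessions")))
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration (%s)>\n  log10(fmol) = %.4f * log10(observed) + %.4f\n  r2 = %.4f on %d points (%d outlier(s) removed%s)\n",
    x$space, x$slope, x$intercept, x$r2, x$n_points,
    length(x$removed_accessions),
    if (length(x$removed_accessions) > 0)
      paste0(": ", paste(x$removed_accessions, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.calibration <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "log10_observed"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname fit_calibration
#' @exportS3Method generics::glance
glance.calibration <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2,
    n_points = x$n_points,
    n_removed = length(x$removed_accessions)
  )
}

#' @rdname fit_calibration
#' @param object A `calibration` object.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$log10_observed, y = .data$log10_expected,
                 colour = .data$retained)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(
      x = "log10 observed relative abundance",
      y = "log10 expected amount (fmol)",
      colour = "retained",
      title = sprintf("Standard of reference (r² = %.3f)", object$r2)
    )
}

#' Convert relative abundances to fmol with a calibration model
#'
#' Reads each relative abundance off the fitted standard-of-reference line:
#' `fmol = 10^(slope * log10(abundance) + intercept)`. Zero or absent
#' abundances stay absent (`NA`).
#'
#' @param rel Long abundance tibble (`accession`, `sample_id`,
#'   `abundance`), e.g. from [quantify()].
#' @param model A `calibration` object.
#' @return Tibble `accession`, `sample_id`, `fmol`, with attributes
#'   `method` (carried over), `strategy = "UPS2"`, `unit = "fmol"`.
#' @export
apply_calibration <- function(rel, model) {
  stopifnot(inherits(model, "calibration"), is.data.frame(rel))
  out <- rel |>
    dplyr::mutate(
      fmol = ifelse(
        !is.na(.data$abundance) & .data$abundance > 0,
        10^(model$slope * log10(.data$abundance) + model$intercept),
        NA_real_
      )
    ) |>
    dplyr::select("accession", "sample_id", "fmol")
  attr(out, "method") <- attr(rel, "method") %||% "none"
  attr(out, "strategy") <- "UPS2"
  attr(out, "unit") <- "fmol"
  out
}

#' Serialize / restore a calibration model as JSON
#'
#' The JSON document records slope, intercept, r2, the removed accessions,
#' the point table and the regression space, so a model can be reused
#' across runs.
#'
#' @param model A `calibration` object.
#' @param path Output (input) file path.
#' @return `write_calibration()`: `path`, invisibly. `read_calibration()`:
#'   the restored `calibration` object.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration"))
  jsonlite::write_json(
    list(
      slope = model$slope, intercept = model$intercept, r2 = model$r2,
      removed_accessions = as.list(model$removed_accessions),
      n_points = model$n_points, space = model$space,
      points = model$points
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      slope = x$slope, intercept = x$intercept, r2 = x$r2,
      removed_accessions = as.character(unlist(x$removed_accessions)),
      n_points = x$n_points, space = x$space,
      points = tibble::as_tibble(x$points)
    ),
    class = "calibration"
  )
}
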