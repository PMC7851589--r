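new_ori_fit <- function(model, estimate, se, p, n, r_squared = NA_real_,
                        intercept = NA_real_, window = NA_real_,
                        response = NA_character_, separation = FALSE,
                        fit = NULL, meta = list()) {
  structure(list(model = model, estimate = estimate, se = se, p = p, n = n,
                 r_squared = r_squared, intercept = intercept,
                 window = window, response = response,
                 separation = separation, fit = fit, meta = meta),
            class = "ori_fit")
}

#' @export
print.ori_fit <- function(x, ...) {
  cat(sprintf(
    "<ori_fit> %s: slope %.4g per bp (SE %.3g, p %.3g, n %d)%s\n",
    x$model, x$estimate, x$se, x$p, x$n,
    if (isTRUE(x$separation)) " [separation]" else ""))
  invisible(x)
}

#' Tidy a spatial regression fit
#'
#' @param x An `ori_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `response`, `window`, `estimate`
#'   (distance slope per bp), `std_error`, `p_value`, `n`, `r_squared`,
#'   `separation`, plus any metadata columns.
#' @export
tidy.ori_fit <- function(x, ...) {
  out <- tibble::tibble(model = x$model, response = x$response,
                        window = x$window, estimate = x$estimate,
                        std_error = x$se, p_value = x$p, n = x$n,
                        r_squared = x$r_squared, separation = x$separation)
  if (length(x$meta)) out <- dplyr::bind_cols(out, tibble::as_tibble(x$meta))
  out
}

#' @export
#' @rdname tidy.ori_fit
glance.ori_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, r_squared = x$r_squared,
                 converged = !isTRUE(x$separation))
}

#' Generic tidiers
#'
#' Broom-style generics re-exported for fit objects in this package.
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Logistic regression of substitution occurrence on distance
#'
#' Fits `logit P(indicator = 1) = b0 + b1 * distance` by maximum likelihood
#' (iteratively reweighted least squares, [stats::glm()] with binomial
#' family) on the per-site table.  Rows flagged as outliers can be excluded
#' beforehand.  Complete or quasi-complete separation (a single response
#' class, or fitted probabilities collapsing to 0/1) is reported via the
#' `separation` flag rather than an error.
#'
#' @param site_table Output of [build_site_table()], optionally filtered.
#' @param exclude Optional logical mask of rows to drop (e.g. sites in
#'   outlier windows).
#' @param response Column to use as binary response (default `indicator`).
#' @return An `ori_fit` (slope per bp with Wald SE and p-value).
#' @export
fit_logistic <- function(site_table, exclude = NULL, response = "indicator") {
  tab <- site_table
  if (!is.null(exclude)) tab <- tab[!exclude, , drop = FALSE]
  y <- tab[[response]]
  n <- nrow(tab)
  if (n == 0L || length(unique(y)) < 2L ||
      length(unique(tab$distance)) < 2L) {
    return(new_ori_fit("logistic", NA_real_, NA_real_, NA_real_, n,
                       response = response, separation = TRUE))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ distance, data = tab, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  new_ori_fit("logistic", cf["distance", 1], cf["distance", 2],
              cf["distance", 4], n, intercept = cf["(Intercept)", 1],
              response = response, separation = sep, fit = fit)
}

#' Linear regression of windowed substitution totals on distance
#'
#' Ordinary least squares of each window's substitution total (or density)
#' on the window midpoint distance, after dropping outlier-flagged and
#' empty windows.
#'
#' @param windows Output of [window_aggregate()].
#' @param w Window width used (stored in the result).
#' @param response `"n_subs"` (default: windowed substitution totals) or
#'   `"density"`.
#' @param outlier Optional logical mask of windows to exclude.
#' @return An `ori_fit`, or `NULL` with a warning when fewer than 3 usable
#'   windows remain.
#' @export
fit_window_linear <- function(windows, w = NA_real_, response = "n_subs",
                              outlier = NULL) {
  tab <- windows
  if (!is.null(outlier)) tab <- tab[!outlier, , drop = FALSE]
  tab <- tab[is.finite(tab[[response]]) & tab$n_sites > 0, , drop = FALSE]
  if (nrow(tab) < 3L) {
    warning("fewer than 3 usable windows; linear fit skipped", call. = FALSE)
    return(NULL)
  }
  y <- tab[[response]]
  fit <- stats::lm(y ~ midpoint, data = tab)
  sm <- summary(fit)
  if (nrow(sm$coefficients) < 2L) {   # constant distance design
    warning("degenerate window design; linear fit skipped", call. = FALSE)
    return(NULL)
  }
  cf <- sm$coefficients
  new_ori_fit("linear", cf["midpoint", 1], cf["midpoint", 2],
              cf["midpoint", 4], nrow(tab), r_squared = sm$r.squared,
              intercept = cf["(Intercept)", 1], window = w,
              response = response, fit = fit)
}

#' Fit windowed linear trends at several window widths
#'
#' Convenience wrapper running [window_aggregate()], outlier flagging and
#' [fit_window_linear()] at each width (defaults: the six standard widths
#' 10, 25, 50, 100, 200 and 400 kb).
#'
#' @param site_table Output of [build_site_table()].
#' @param widths Window widths in bp.
#' @param response Passed to [fit_window_linear()].
#' @param outlier_mode Passed to [flag_outliers()].
#' @return Tibble of tidied fits, one row per width that could be fitted.
#' @export
fit_window_regressions <- function(site_table,
                                   widths = c(10, 25, 50, 100, 200, 400) * 1e3,
                                   response = "n_subs",
                                   outlier_mode = "tukey") {
  rows <- purrr::map(widths, function(w) {
    wins <- window_aggregate(site_table, w)
    out <- suppressWarnings(flag_outliers(wins$density, mode = outlier_mode))
    fit <- fit_window_linear(wins, w = w, response = response, outlier = out)
    if (is.null(fit)) NULL else tidy(fit)
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Origin-shift permutation test
#'
#' Moves the origin of replication in `step` increments out to `max_shift`
#' in both directions, re-transforms every site's ancestral position under
#' the shifted origin (terminus recomputed when it was assigned by the
#' midpoint rule) and refits the logistic regression, to check that the
#' sign and significance of the distance slope do not hinge on the exact
#' origin call.
#'
#' @param site_table Output of [build_site_table()] (must retain the raw
#'   `position` column).
#' @param rep The [replicon()] used for the base fit.
#' @param step Shift increment in bp (default 10000).
#' @param max_shift Maximum shift in bp (default 100000).
#' @param alpha Significance level for the stability summary.
#' @return Tibble of tidied logistic fits, one per shift (21 rows at the
#'   defaults), with a `shift` column; attributes `sign_stable` and
#'   `signif_stable` summarise constancy across shifts.
#' @export
origin_shift_permutation <- function(site_table, rep, step = 10000L,
                                     max_shift = 100000L, alpha = 0.05) {
  shifts <- seq(-max_shift, max_shift, by = step)
  rows <- purrr::map(shifts, function(delta) {
    res <- tryCatch({
      rep_s <- shift_origin(rep, delta, max_shift = max_shift)
      tab <- site_table
      tr <- transform_position(tab$position, rep_s)
      tab$distance <- tr$distance
      fit <- fit_logistic(tab)
      dplyr::mutate(tidy(fit), shift = delta, .before = 1L)
    }, error = function(e) {
      warning("shift ", delta, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    res
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  est <- out$estimate[is.finite(out$estimate)]
  attr(out, "sign_stable") <- length(est) > 0 &&
    (all(est > 0) || all(est < 0))
  attr(out, "signif_stable") <- all(out$p_value < alpha, na.rm = TRUE)
  out
}
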