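#' Build the per-site substitution table
#'
#' One row per analysed protein-coding alignment site, carrying the site's
#' ancestral genomic position (by default the root-node placement of its
#' block), the origin-relative transformed distance, the number of
#' substitution events inferred at the site summed over branches, and the
#' binary indicator (>= 1 event) used by the logistic regression.
#'
#' @param segments List of [gene_segment()] objects.
#' @param events Event tibble from [extract_substitutions()] (rows across
#'   all segments).
#' @param positions Named list: for each segment id, integer vector of the
#'   ancestral genomic position of every column.
#' @param rep A [replicon()].
#' @return Tibble with columns `segment`, `block`, `column`, `position`,
#'   `distance`, `replichore`, `signed`, `count`, `indicator`.
#' @export
build_site_table <- function(segments, events, positions, rep) {
  rows <- purrr::map(segments, function(s) {
    pos <- positions[[s$id]]
    if (is.null(pos)) stop("no positions for segment ", s$id, call. = FALSE)
    tibble::tibble(segment = s$id, block = s$block_id,
                   column = seq_len(s$width), position = pos)
  })
  tab <- dplyr::bind_rows(rows)
  if (any(tab$position < 1 | tab$position > rep$length, na.rm = TRUE)) {
    stop("ancestral position outside the replicon", call. = FALSE)
  }
  tr <- transform_position(tab$position, rep)
  tab$distance <- tr$distance
  tab$replichore <- tr$replichore
  tab$signed <- tr$signed
  counts <- events |>
    dplyr::count(.data$segment, .data$column, name = "count")
  tab <- tab |>
    dplyr::left_join(counts, by = c("segment", "column")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  indicator = as.integer(.data$count >= 1L))
  tab
}

#' Aggregate sites into fixed-width windows of transformed distance
#'
#' Sites are binned into half-open windows `[k*w, (k+1)*w)` of distance from
#' the origin (both replichores pooled).  Each window reports its
#' substitution total, coding-site total and density = substitutions per
#' coding site within the window; at the default `w` = 10000 this is the
#' "substitutions per 10 kb" scale.  Windows containing no coding sites get
#' `NA` density.
#'
#' @param site_table Output of [build_site_table()].
#' @param w Window width in bp (default 10000).
#' @param by_replichore Aggregate each replichore separately (diagnostic
#'   mode; default pools both).
#' @return Tibble with columns `window`, `start`, `end`, `midpoint`,
#'   `n_sites`, `n_subs`, `density` (and `replichore` when split).
#' @export
window_aggregate <- function(site_table, w = 10000, by_replichore = FALSE) {
  stopifnot(w > 0)
  grp <- if (by_replichore) c("replichore", "window") else "window"
  out <- site_table |>
    dplyr::mutate(window = floor(.data$distance / w)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     n_subs = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(start = .data$window * w, end = (.data$window + 1) * w,
                  midpoint = .data$start + w / 2,
                  density = ifelse(.data$n_sites > 0,
                                   .data$n_subs / .data$n_sites, NA_real_))
  dplyr::relocate(out, dplyr::all_of(grp), "start", "end", "midpoint")
}

#' Flag outlying values by Tukey fences
#'
#' The default interpretation of "points outside the interquartile range":
#' a value is an outlier iff it falls below `Q1 - 1.5 IQR` or above
#' `Q3 + 1.5 IQR`, with quartiles computed by linear interpolation
#' ([stats::quantile()] type 7).  `mode = "literal"` instead flags everything
#' strictly outside `[Q1, Q3]`.
#'
#' @param values Numeric vector (window densities, omega values, ...).
#' @param mode `"tukey"` (default) or `"literal"`.
#' @return Logical mask the length of `values`; `NA` values are never
#'   flagged.  With fewer than 4 finite values, an all-`FALSE` mask is
#'   returned with a warning.
#' @export
flag_outliers <- function(values, mode = c("tukey", "literal")) {
  mode <- match.arg(mode)
  finite <- is.finite(values)
  if (sum(finite) < 4L) {
    warning("fewer than 4 finite values; no outliers flagged", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values[finite], c(0.25, 0.75), names = FALSE)
  lims <- if (mode == "tukey") {
    iqr <- q[2] - q[1]
    c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  } else {
    q
  }
  out <- values < lims[1] | values > lims[2]
  out[!finite] <- FALSE
  out
}
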