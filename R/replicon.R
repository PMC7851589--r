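#' Describe the replication geometry of one replicon
#'
#' A replicon object records the facts needed to re-index genomic positions
#' around the origin of replication under bidirectional replication: total
#' length, topology, the origin position and the terminus.  For circular
#' replicons the origin and terminus split the molecule into two replichores,
#' each copied by one replication fork; for linear replicons replication runs
#' from the origin out to both chromosome ends, so the termini are fixed at
#' positions 1 and `length`.
#'
#' All coordinates are 1-based inclusive (GenBank/GFF convention).  Distances
#' reported by [transform_position()] are 0 at the origin; when a transformed
#' coordinate is displayed 1-based the origin carries the label 1
#' (`origin_label` attribute).
#'
#' @param name Replicon name (free text).
#' @param length Replicon length in bp (positive integer).
#' @param topology `"circular"` or `"linear"`.
#' @param origin Origin of replication, 1-based position in `[1, length]`.
#' @param terminus For circular replicons either a 1-based position, or
#'   `"midpoint"` to place the terminus antipodal to the origin (equal
#'   replichore lengths).  Ignored for linear replicons, whose termini are the
#'   two chromosome ends.
#' @return An object of class `replicon`.
#' @examples
#' rep <- replicon("toy", length = 100, topology = "circular",
#'                 origin = 20, terminus = 60)
#' transform_position(c(40, 80), rep)
#' @export
replicon <- function(name, length, topology = c("circular", "linear"),
                     origin, terminus = "midpoint") {
  topology <- match.arg(topology)
  length <- as.integer(length)
  origin <- as.integer(origin)
  if (is.na(length) || length <= 0L) {
    stop("replicon length must be a positive integer", call. = FALSE)
  }
  if (is.na(origin) || origin < 1L || origin > length) {
    stop("origin must lie in [1, length]", call. = FALSE)
  }
  rep <- structure(
    list(name = as.character(name), length = length, topology = topology,
         origin = origin, terminus = NA_integer_,
         terminus_rule = "unset", origin_label = 1L),
    class = "replicon"
  )
  if (topology == "linear") {
    rep$terminus <- c(1L, length)
    rep$terminus_rule <- "chromosome_ends"
  } else if (identical(terminus, "midpoint")) {
    rep <- assign_terminus(rep)
  } else if (!is.null(terminus) && !is.na(terminus)) {
    rep <- assign_terminus(rep, explicit = as.integer(terminus))
  }
  rep
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s, %d bp, origin %d, terminus %s (%s)\n",
              x$name, x$topology, x$length, x$origin,
              paste(x$terminus, collapse = "/"), x$terminus_rule))
  invisible(x)
}

#' Set the terminus of a circular replicon
#'
#' With an explicit position (e.g. a dif-site lookup) the terminus is placed
#' there.  Otherwise the terminus is placed at the antipodal midpoint
#' `((origin - 1 + floor(length/2)) mod length) + 1`, giving two replichores
#' of (near) equal length -- the natural reading of "midpoint between the
#' origin and the end of the replicon" for a replicon with no annotated
#' terminus.
#'
#' @param rep A [replicon()].
#' @param explicit Optional explicit terminus position (1-based).
#' @return The replicon with `terminus` and `terminus_rule` set.
#' @export
assign_terminus <- function(rep, explicit = NULL) {
  stopifnot(inherits(rep, "replicon"))
  if (rep$topology == "linear") {
    if (!is.null(explicit)) {
      stop("linear replicons terminate at the chromosome ends; ",
           "an explicit terminus cannot be assigned", call. = FALSE)
    }
    rep$terminus <- c(1L, rep$length)
    rep$terminus_rule <- "chromosome_ends"
    return(rep)
  }
  if (!is.null(explicit)) {
    explicit <- as.integer(explicit)
    if (is.na(explicit) || explicit < 1L || explicit > rep$length) {
      stop("explicit terminus must lie in [1, length]", call. = FALSE)
    }
    if (explicit == rep$origin) {
      stop("terminus must differ from the origin", call. = FALSE)
    }
    rep$terminus <- explicit
    rep$terminus_rule <- "explicit"
  } else {
    rep$terminus <-
      ((rep$origin - 1L + rep$length %/% 2L) %% rep$length) + 1L
    rep$terminus_rule <- "midpoint"
  }
  rep
}

#' Shift the origin of replication
#'
#' Moves the origin by `delta` bp (positive = increasing coordinates),
#' wrapping modularly on circular replicons.  A terminus assigned by the
#' midpoint rule is recomputed so it stays antipodal; an explicit terminus is
#' left untouched.  Used by [origin_shift_permutation()] to probe sensitivity
#' of spatial trends to the exact origin call.
#'
#' @param rep A [replicon()].
#' @param delta Signed shift in bp; `abs(delta)` must not exceed `max_shift`.
#' @param max_shift Guard against accidental huge shifts (default 100 kb).
#' @return The shifted replicon.
#' @export
shift_origin <- function(rep, delta, max_shift = 100000L) {
  stopifnot(inherits(rep, "replicon"))
  delta <- as.integer(delta)
  if (abs(delta) > max_shift) {
    stop("|delta| exceeds max_shift (", max_shift, " bp)", call. = FALSE)
  }
  if (rep$topology == "circular") {
    rep$origin <- ((rep$origin - 1L + delta) %% rep$length) + 1L
    if (identical(rep$terminus_rule, "midpoint")) rep <- assign_terminus(rep)
  } else {
    new_origin <- rep$origin + delta
    if (new_origin < 1L || new_origin > rep$length) {
      stop("origin shift runs past a chromosome end", call. = FALSE)
    }
    rep$origin <- new_origin
  }
  rep
}

#' Replichore lengths of a replicon
#'
#' For a circular replicon, the right replichore runs from the origin to the
#' terminus in increasing-coordinate direction and the left replichore covers
#' the rest.  For a linear replicon the two arms run from the origin to each
#' chromosome end.
#'
#' @param rep A [replicon()].
#' @return Named numeric vector: `right`/`left` (circular) or
#'   `right_arm`/`left_arm` (linear; right = increasing coordinates).
#' @export
replichore_lengths <- function(rep) {
  stopifnot(inherits(rep, "replicon"))
  if (rep$topology == "circular") {
    if (is.na(rep$terminus[1])) {
      stop("terminus is unset; call assign_terminus() first", call. = FALSE)
    }
    right <- (rep$terminus[1] - rep$origin) %% rep$length
    c(right = right, left = rep$length - right)
  } else {
    c(right_arm = rep$length - rep$origin, left_arm = rep$origin - 1L)
  }
}

#' Transform raw genomic positions to origin-relative coordinates
#'
#' Re-indexes positions as distance from the origin of replication measured
#' along the replichore that contains them, so that the two sequences copied
#' by the two forks are put on a common scale.  On a circular replicon a
#' position on the arc origin -> terminus (increasing coordinates, the
#' "right" replichore) gets `distance = (p - origin) mod length`; a position
#' on the complementary ("left") replichore gets
#' `distance = (origin - p) mod length`.  The origin itself maps to distance
#' 0.  On a linear replicon `signed = p - origin` and
#' `distance = abs(signed)`; the arm left of the origin carries negative
#' signed positions.
#'
#' The terminus of a circular replicon belongs to both replichores: it is
#' reported on the right replichore, where its distance equals the right
#' replichore length; measured along the left replichore its distance would
#' be the left replichore length (the two sum to the replicon length).  Use
#' [replichore_lengths()] for both values.
#'
#' @param p Vector of raw 1-based genomic positions.
#' @param rep A [replicon()] with origin and terminus set.
#' @return A tibble with columns `raw`, `distance`, `replichore`
#'   (`right`/`left` for circular, `long_arm`/`short_arm` for linear) and
#'   `signed` (`NA` for circular replicons).
#' @export
transform_position <- function(p, rep) {
  stopifnot(inherits(rep, "replicon"))
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 1 | p > rep$length)) {
    stop("positions must lie in [1, ", rep$length, "]", call. = FALSE)
  }
  if (rep$topology == "circular") {
    if (is.na(rep$terminus[1])) {
      stop("circular replicon has no terminus; call assign_terminus()",
           call. = FALSE)
    }
    L <- rep$length
    fwd <- (p - rep$origin) %% L          # arc length origin -> p, rightward
    right_len <- (rep$terminus[1] - rep$origin) %% L
    on_right <- fwd <= right_len
    tibble::tibble(
      raw = p,
      distance = ifelse(on_right, fwd, (rep$origin - p) %% L),
      replichore = ifelse(on_right, "right", "left"),
      signed = NA_real_
    )
  } else {
    signed <- p - rep$origin
    # convention: the arm left of the origin is the "short" arm and carries
    # negative signed positions; the arm right of the origin is the "long" arm
    tibble::tibble(
      raw = p,
      distance = abs(signed),
      replichore = ifelse(signed >= 0, "long_arm", "short_arm"),
      signed = signed
    )
  }
}
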