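# Standard genetic code keyed by codon; "*" marks stops.
genetic_code <- function() Biostrings::GENETIC_CODE

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Per-codon synonymous site counts (NG86): at each codon position the
# synonymous fraction of the three possible single-nucleotide changes.
# Changes creating a stop codon count as nonsynonymous; stop codons carry
# NA and are skipped by callers.
codon_site_table <- function() {
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  codons <- all_codons()
  syn <- stats::setNames(rep(NA_real_, length(codons)), codons)
  for (cd in codons) {
    aa <- gc[[cd]]
    if (aa == "*") next
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (gc[[alt]] == aa) s <- s + 1 / 3
      }
    }
    syn[[cd]] <- s
  }
  syn
}

# Count synonymous/nonsynonymous differences between two codons by
# averaging over all orderings of the single changes (mutation paths).
# Paths through stop codons are excluded unless every path is blocked.
codon_diff_counts <- function(c1, c2, gc = genetic_code()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- if (nd == 1L) {
    list(pos)
  } else if (nd == 2L) {
    list(pos, rev(pos))
  } else {
    p <- pos
    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
  }
  score_path <- function(order) {
    cur <- c1
    s <- 0; n <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && nxt != c2) return(NULL)  # blocked intermediate
      if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  scored <- purrr::compact(purrr::map(paths, score_path))
  if (!length(scored)) scored <- purrr::map(paths, function(order) {
    cur <- c1
    s <- 0; n <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  })
  avg <- Reduce(`+`, scored) / length(scored)
  c(syn = avg[1], nonsyn = avg[2])
}

# memoised pairwise codon difference table, built lazily
.oriscan_cache <- new.env(parent = emptyenv())

codon_pair_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  tab <- .oriscan_cache$pair
  if (is.null(tab)) {
    tab <- new.env(parent = emptyenv())
    .oriscan_cache$pair <- tab
  }
  hit <- tab[[key]]
  if (!is.null(hit)) return(hit)
  val <- codon_diff_counts(c1, c2)
  tab[[key]] <- val
  val
}

#' Jukes-Cantor distance correction
#'
#' `d = -3/4 log(1 - 4p/3)`; proportions `p >= 3/4` are saturated and
#' return `NA`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance (NA when saturated).
#' @export
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori dN/dS for one codon-complete alignment
#'
#' Counts synonymous and nonsynonymous sites (codon averages over the three
#' possible changes per position) and differences (averaged over mutation
#' paths) for every unordered pair of taxa, applies the Jukes-Cantor
#' correction to the per-pair proportions, and averages over pairs.  A pair
#' whose synonymous or nonsynonymous proportion reaches 3/4 is saturated and
#' excluded from the means; a record where all pairs are saturated is
#' flagged.  omega = dN/dS is reported only when dS > 0.
#'
#' Codons containing a stop in either sequence of a pair are skipped for
#' that pair.
#'
#' @param segment A [gene_segment()] or named character vector of gap-free,
#'   equal-length, codon-complete sequences (length divisible by 3).
#' @param distance Optional origin-relative distance of the segment midpoint
#'   (carried into the record).
#' @return One-row tibble (`selection record`): `segment`, `gene_id`,
#'   `length_bp`, `n_codons`, `n_pairs`, `n_saturated`, `dN`, `dS`, `omega`,
#'   `saturated`, `distance`.
#' @export
compute_dn_ds <- function(segment, distance = NA_real_) {
  if (inherits(segment, "gene_segment")) {
    seqs <- segment$seqs
    id <- segment$id
    gene <- segment$gene_id
  } else {
    seqs <- segment
    id <- NA_character_
    gene <- NA_character_
  }
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1L, len %% 3L == 0L, length(seqs) >= 2L)
  n_codons <- len %/% 3L
  gc <- genetic_code()
  site_tab <- .oriscan_cache$sites
  if (is.null(site_tab)) {
    site_tab <- codon_site_table()
    .oriscan_cache$sites <- site_tab
  }
  codons <- purrr::map(seqs, function(s) {
    substring(s, seq(1, len, 3), seq(3, len, 3))
  })
  taxa <- names(seqs)
  pairs <- utils::combn(taxa, 2L, simplify = FALSE)
  per_pair <- purrr::map(pairs, function(pr) {
    cd1 <- codons[[pr[1]]]; cd2 <- codons[[pr[2]]]
    ok <- gc[cd1] != "*" & gc[cd2] != "*"
    cd1 <- cd1[ok]; cd2 <- cd2[ok]
    if (!length(cd1)) return(NULL)
    S <- (sum(site_tab[cd1]) + sum(site_tab[cd2])) / 2
    N <- 3 * length(cd1) - S
    diffs <- which(cd1 != cd2)
    sd_ <- 0; nd_ <- 0
    for (i in diffs) {
      cnt <- codon_pair_counts(cd1[i], cd2[i])
      sd_ <- sd_ + cnt[["syn"]]
      nd_ <- nd_ + cnt[["nonsyn"]]
    }
    pS <- if (S > 0) sd_ / S else 0
    pN <- if (N > 0) nd_ / N else 0
    tibble::tibble(pS = pS, pN = pN,
                   dS = jc_correct(pS), dN = jc_correct(pN),
                   saturated = pS >= 0.75 | pN >= 0.75)
  })
  per_pair <- dplyr::bind_rows(purrr::compact(per_pair))
  usable <- per_pair[!per_pair$saturated, , drop = FALSE]
  tibble::tibble(
    segment = id, gene_id = gene, length_bp = len, n_codons = n_codons,
    n_pairs = nrow(per_pair), n_saturated = sum(per_pair$saturated),
    dN = if (nrow(usable)) mean(usable$dN) else NA_real_,
    dS = if (nrow(usable)) mean(usable$dS) else NA_real_,
    omega = if (nrow(usable) && mean(usable$dS) > 0) {
      mean(usable$dN) / mean(usable$dS)
    } else {
      NA_real_
    },
    saturated = nrow(usable) == 0L,
    distance = distance)
}

#' Flag selection outliers on omega and propagate to dN/dS
#'
#' Outliers are determined on the defined omega values only (Tukey fences by
#' default); the dN and dS of a flagged record are excluded from all
#' downstream summaries along with its omega.  Records with undefined omega
#' (dS = 0) are never flagged here -- they are handled by the zero rule in
#' [weighted_genome_average()].
#'
#' @param records Tibble of selection records ([compute_dn_ds()] rows, with
#'   a `distance` column).
#' @param mode Passed to [flag_outliers()].
#' @return The records with a logical `outlier` column.
#' @export
omega_outlier_filter <- function(records, mode = "tukey") {
  mask <- rep(FALSE, nrow(records))
  defined <- is.finite(records$omega)
  if (sum(defined) >= 4L) {
    mask[defined] <- flag_outliers(records$omega[defined], mode = mode)
  }
  dplyr::mutate(records, outlier = mask)
}

#' Length-weighted genome averages of dN, dS and omega
#'
#' Arithmetic averages weighted by segment length over non-outlier,
#' non-saturated records.  Records with dS = 0 (undefined omega) contribute
#' to the dN and dS averages but are removed from the weighted omega
#' average.
#'
#' @param records Output of [omega_outlier_filter()] (an `outlier` column is
#'   optional and treated as all-`FALSE` if absent).
#' @return One-row tibble: `dS_bar`, `dN_bar`, `omega_bar`, `n_segments`,
#'   `n_omega`.
#' @export
weighted_genome_average <- function(records) {
  if (is.null(records$outlier)) records$outlier <- FALSE
  use <- records[!records$outlier & !records$saturated &
                   is.finite(records$dN) & is.finite(records$dS), ,
                 drop = FALSE]
  if (!nrow(use)) {
    warning("no usable records after exclusions", call. = FALSE)
    return(tibble::tibble(dS_bar = NA_real_, dN_bar = NA_real_,
                          omega_bar = NA_real_, n_segments = 0L,
                          n_omega = 0L))
  }
  wmean <- function(x, w) sum(x * w) / sum(w)
  om <- use[use$dS > 0 & is.finite(use$omega), , drop = FALSE]
  tibble::tibble(
    dS_bar = wmean(use$dS, use$length_bp),
    dN_bar = wmean(use$dN, use$length_bp),
    omega_bar = if (nrow(om)) wmean(om$omega, om$length_bp) else NA_real_,
    n_segments = nrow(use), n_omega = nrow(om))
}

#' Linear regressions of dN, dS and omega on distance from the origin
#'
#' OLS of each response on the segment-midpoint transformed distance over
#' non-outlier records, plus windowed-average variants at the standard
#' window widths.
#'
#' @param records Output of [omega_outlier_filter()].
#' @param widths Window widths in bp for the windowed variants (default the
#'   six standard widths; `NULL` skips them).
#' @return Tibble of tidied fits with a `response` column (`dN`, `dS`,
#'   `omega`); per-record fits have `window = NA`.
#' @export
fit_selection_regressions <- function(records,
                                      widths = c(10, 25, 50, 100, 200,
                                                 400) * 1e3) {
  if (is.null(records$outlier)) records$outlier <- FALSE
  base <- records[!records$outlier & !records$saturated, , drop = FALSE]
  one <- function(resp, tab, w = NA_real_) {
    tab <- tab[is.finite(tab[[resp]]) & is.finite(tab$distance), ,
               drop = FALSE]
    if (nrow(tab) < 3L || length(unique(tab$distance)) < 2L) {
      warning("response ", resp, ": insufficient records; skipped",
              call. = FALSE)
      return(NULL)
    }
    y <- tab[[resp]]
    fit <- stats::lm(y ~ distance, data = tab)
    sm <- summary(fit)
    cf <- sm$coefficients
    dplyr::mutate(
      tidy(new_ori_fit("linear", cf["distance", 1], cf["distance", 2],
                       cf["distance", 4], nrow(tab),
                       r_squared = sm$r.squared,
                       intercept = cf["(Intercept)", 1], window = w,
                       response = resp)))
  }
  rows <- purrr::map(c("dN", "dS", "omega"), one, tab = base)
  win_rows <- list()
  for (w in widths %||% numeric()) {
    avg <- base |>
      dplyr::mutate(window = floor(.data$distance / w)) |>
      dplyr::group_by(.data$window) |>
      dplyr::summarise(distance = (.data$window[1] + 0.5) * w,
                       dN = mean(.data$dN, na.rm = TRUE),
                       dS = mean(.data$dS, na.rm = TRUE),
                       omega = mean(.data$omega, na.rm = TRUE),
                       .groups = "drop")
    win_rows <- c(win_rows,
                  purrr::map(c("dN", "dS", "omega"),
                             function(r) suppressWarnings(one(r, avg, w))))
  }
  dplyr::bind_rows(purrr::compact(c(rows, win_rows)))
}
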