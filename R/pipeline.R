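# Fit a single transition/transversion ratio on pooled segment data (capped
# column count keeps this cheap; kappa is shared across segments downstream).
fit_kappa <- function(segments, tree, max_cols = 20000L) {
  ord <- tree_postorder(tree)
  tips <- ord$tree$tip.label
  mats <- list(); total <- 0L
  for (s in segments) {
    if (total >= max_cols) break
    m <- segment_matrix(s)[tips, , drop = FALSE]
    take <- min(ncol(m), max_cols - total)
    mats[[length(mats) + 1L]] <- m[, seq_len(take), drop = FALSE]
    total <- total + take
  }
  if (!total) return(3)
  tipstates <- do.call(cbind, mats)
  counts <- table(factor(tipstates, levels = BASES))
  freqs <- (as.numeric(counts) + 1) / (sum(counts) + 4)
  stats::optimize(function(k) hky_loglik(tipstates, ord, k, freqs),
                  c(0.2, 100), maximum = TRUE, tol = 1e-2)$maximum
}

# remove one taxon's row from a block (no-op if absent); NULL when fewer
# than two rows would remain
drop_taxon_block <- function(block, taxon) {
  if (!taxon %in% block$taxa) return(block)
  keep <- setdiff(block$taxa, taxon)
  if (length(keep) < 2L) return(NULL)
  aligned_block(block$id, block$seqs[keep], block$start[keep],
                block$end[keep], block$strand[keep])
}

# block position label of one taxon: genomic start plus strand
block_label <- function(block, taxon) {
  paste0(block$start[[taxon]], block$strand[[taxon]])
}

# joint reconstruction over all segments: nucleotides per segment, positions
# per block, events with ancestral positions, root placement per segment
reconstruct_all <- function(segments, blocks, tree, kappa = NULL,
                            rho = NULL) {
  if (!length(segments)) {
    return(list(events = empty_events(), positions = list(),
                kappa = NA_real_, position_recs = list()))
  }
  if (is.null(kappa)) kappa <- fit_kappa(segments, tree)
  tips <- tree$tip.label
  block_ids <- unique(purrr::map_chr(segments, "block_id"))
  pos_recs <- purrr::map(block_ids, function(bid) {
    b <- blocks[[bid]]
    labels <- stats::setNames(purrr::map_chr(tips, ~ block_label(b, .x)),
                              tips)
    reconstruct_positions(tree, labels, rho = rho)
  })
  names(pos_recs) <- block_ids
  root_name <- function(pr) paste0("node", pr$ord$root)
  events <- list()
  positions <- list()
  for (s in segments) {
    pr <- pos_recs[[s$block_id]]
    label_maps <- purrr::map(
      stats::setNames(pr$alphabet, pr$alphabet),
      function(lab) {
        donor <- tips[purrr::map_chr(tips,
                                     ~ pr$labels[[.x]]) == lab][1L]
        s$pos_map[[donor]]
      })
    nuc <- reconstruct_nucleotides(s, tree, kappa = kappa)
    events[[s$id]] <- extract_substitutions(s, nuc, pr, label_maps)
    positions[[s$id]] <- label_maps[[pr$labels[[root_name(pr)]]]]
  }
  list(events = dplyr::bind_rows(events), positions = positions,
       kappa = kappa, position_recs = pos_recs)
}

#' Run the full origin-centred substitution analysis
#'
#' Orchestrates the stage sequence read -> filter -> reconstruct -> map ->
#' regress -> selection on a set of aligned blocks (or directly on a
#' [simulate_genomes()] result) and returns a run report whose tables are
#' all recomputable from its component tibbles: per-stage counts, the
#' average number of protein-coding substitutions per bp (outlier windows
#' excluded), the logistic regression of substitution occurrence on distance
#' from the origin, windowed substitution densities and linear trends, and
#' per-segment dN/dS/omega with genome averages and distance regressions.
#'
#' @param x List of [aligned_block()] objects, or a `genome_simulation`.
#' @param annotations Annotation tibble ([read_annotations()]).
#' @param tree Rooted `phylo` with branch lengths.
#' @param rep A [replicon()].
#' @param required_taxa Taxa every block must contain (default: the tree's
#'   tips).
#' @param max_gap_fraction,min_len,exclude_blocks Passed to
#'   [filter_blocks()].
#' @param kappa HKY kappa; `NULL` fits one shared value on pooled segments.
#' @param rho Rearrangement rate for position tie-breaking; `NULL` fits it
#'   per block from Fitch change counts.
#' @param window_w Window width for the headline density table (default
#'   10 kb).
#' @param widths Window widths for the windowed linear regressions.
#' @param outlier_mode Passed to [flag_outliers()].
#' @param reference_taxon Taxon anchoring per-segment midpoint distances for
#'   the selection analysis (default: first tree tip).
#' @param selection Run the dN/dS stage (default `TRUE`).
#' @param window_regressions Run the multi-width windowed linear fits
#'   (default `TRUE`).
#' @param ... Method-specific arguments.
#' @return An `ori_run` list; see Details in the package vignette.
#' @export
run_full_analysis <- function(x, ...) UseMethod("run_full_analysis")

#' @rdname run_full_analysis
#' @export
run_full_analysis.genome_simulation <- function(x, ...) {
  run_full_analysis(x$blocks, annotations = x$annotations, tree = x$tree,
                    rep = x$replicon, ...)
}

#' @rdname run_full_analysis
#' @export
run_full_analysis.default <- function(x, annotations, tree, rep,
                                      required_taxa = NULL,
                                      max_gap_fraction = 0.2,
                                      min_len = 100L,
                                      exclude_blocks = NULL,
                                      kappa = NULL, rho = NULL,
                                      window_w = 10000,
                                      widths = c(10, 25, 50, 100, 200,
                                                 400) * 1e3,
                                      outlier_mode = "tukey",
                                      reference_taxon = NULL,
                                      selection = TRUE,
                                      window_regressions = TRUE, ...) {
  required_taxa <- required_taxa %||% tree$tip.label
  reference_taxon <- reference_taxon %||% tree$tip.label[1L]
  filtered <- filter_blocks(x, annotations, required_taxa = required_taxa,
                            max_gap_fraction = max_gap_fraction,
                            min_len = min_len,
                            exclude_blocks = exclude_blocks)
  segments <- filtered$segments
  recon <- reconstruct_all(segments, x, tree, kappa = kappa, rho = rho)
  site_table <- if (length(segments)) {
    build_site_table(segments, recon$events, recon$positions, rep)
  } else {
    NULL
  }
  windows <- NULL; logistic <- NULL; subs_per_bp <- NA_real_
  window_fits <- NULL; site_excluded <- NULL
  if (!is.null(site_table) && nrow(site_table)) {
    windows <- window_aggregate(site_table, window_w)
    windows$outlier <- suppressWarnings(
      flag_outliers(windows$density, mode = outlier_mode))
    bad <- windows$window[windows$outlier]
    site_excluded <- floor(site_table$distance / window_w) %in% bad
    use <- site_table[!site_excluded, , drop = FALSE]
    subs_per_bp <- sum(use$count) / nrow(use)
    logistic <- fit_logistic(site_table, exclude = site_excluded)
    if (window_regressions) {
      window_fits <- fit_window_regressions(site_table, widths = widths,
                                            outlier_mode = outlier_mode)
    }
  }
  sel_records <- NULL; sel_summary <- NULL; sel_fits <- NULL
  if (selection && length(segments)) {
    sel_records <- dplyr::bind_rows(purrr::map(segments, function(s) {
      mid_raw <- s$pos_map[[reference_taxon]][ceiling(s$width / 2)]
      compute_dn_ds(s, distance = transform_position(mid_raw, rep)$distance)
    }))
    sel_records <- omega_outlier_filter(sel_records, mode = outlier_mode)
    sel_summary <- suppressWarnings(weighted_genome_average(sel_records))
    sel_fits <- suppressWarnings(
      fit_selection_regressions(sel_records, widths = widths))
  }
  structure(list(
    params = list(required_taxa = required_taxa,
                  max_gap_fraction = max_gap_fraction, min_len = min_len,
                  exclude_blocks = exclude_blocks, kappa = recon$kappa,
                  window_w = window_w, widths = widths,
                  outlier_mode = outlier_mode,
                  reference_taxon = reference_taxon),
    replicon = rep, tree = tree,
    stats = filtered$stats, segments = segments,
    events = recon$events, positions = recon$positions,
    position_recs = recon$position_recs,
    site_table = site_table, site_excluded = site_excluded,
    windows = windows,
    subs_per_bp = subs_per_bp,
    logistic = logistic,
    window_fits = window_fits,
    selection = sel_records, selection_summary = sel_summary,
    selection_fits = sel_fits),
    class = "ori_run")
}

#' @export
print.ori_run <- function(x, ...) {
  cat("<ori_run>\n")
  cat(sprintf("  replicon: %s (%d bp, %s)\n", x$replicon$name,
              x$replicon$length, x$replicon$topology))
  cat(sprintf("  blocks kept: %d; segments: %d; coding sites: %d\n",
              nrow(x$stats), length(x$segments),
              if (is.null(x$site_table)) 0L else nrow(x$site_table)))
  cat(sprintf("  substitution events: %d; subs/bp (outliers excluded): %.4g\n",
              nrow(x$events), x$subs_per_bp))
  if (!is.null(x$logistic)) {
    cat(sprintf("  logistic slope: %.4g per bp (p = %.3g)\n",
                x$logistic$estimate, x$logistic$p))
  }
  if (!is.null(x$selection_summary)) {
    cat(sprintf("  weighted dS = %.4g, dN = %.4g, omega = %.4g\n",
                x$selection_summary$dS_bar, x$selection_summary$dN_bar,
                x$selection_summary$omega_bar))
  }
  invisible(x)
}

#' Summary tibble for a full run
#'
#' @param x An `ori_run`.
#' @param ... Unused.
#' @return One-row tibble of the headline quantities.
#' @export
glance.ori_run <- function(x, ...) {
  tibble::tibble(
    n_blocks = nrow(x$stats), n_segments = length(x$segments),
    n_sites = if (is.null(x$site_table)) 0L else nrow(x$site_table),
    n_events = nrow(x$events), subs_per_bp = x$subs_per_bp,
    logistic_slope = if (is.null(x$logistic)) NA_real_ else
      x$logistic$estimate,
    logistic_p = if (is.null(x$logistic)) NA_real_ else x$logistic$p,
    dS_bar = if (is.null(x$selection_summary)) NA_real_ else
      x$selection_summary$dS_bar,
    dN_bar = if (is.null(x$selection_summary)) NA_real_ else
      x$selection_summary$dN_bar,
    omega_bar = if (is.null(x$selection_summary)) NA_real_ else
      x$selection_summary$omega_bar)
}

#' Taxon-removal (jackknife) sensitivity analysis
#'
#' Reruns block selection, reconstruction and the logistic regression with
#' each taxon removed in turn (its leaf pruned from the tree, adjacent
#' branch lengths merged), to check that no single genome drives the spatial
#' trend.  Each result row is flagged when the removed taxon was the
#' outgroup (a leaf attached directly at the root) or the modal donor of
#' ancestral block positions -- the two situations in which a sign flip is
#' expected rather than alarming.
#'
#' @param blocks List of [aligned_block()] objects.
#' @param annotations Annotation tibble.
#' @param tree Rooted `phylo`.
#' @param rep A [replicon()].
#' @param ... Passed to [run_full_analysis()] (selection and window fits are
#'   disabled here).
#' @return Tibble: one tidied logistic fit per removed taxon with
#'   `removed`, `was_outgroup`, `was_modal_donor` columns.
#' @export
taxon_jackknife <- function(blocks, annotations, tree, rep, ...) {
  tips <- tree$tip.label
  if (length(tips) <= 3L) {
    warning("3 or fewer taxa; jackknife skipped", call. = FALSE)
    return(tibble::tibble())
  }
  ord <- tree_postorder(tree)
  root_kids <- ord$edge[ord$edge[, 1L] == ord$root, 2L]
  outgroup <- tips[root_kids[root_kids <= length(tips)]]
  # modal ancestral-position donor over blocks, from the full-data run
  full <- reconstruct_all(
    filter_blocks(blocks, annotations, required_taxa = tips)$segments,
    blocks, tree)
  donor <- purrr::map_chr(full$position_recs, function(pr) {
    root_lab <- pr$labels[[paste0("node", pr$ord$root)]]
    hits <- tips[purrr::map_chr(tips, ~ pr$labels[[.x]]) == root_lab]
    if (length(hits)) hits[1L] else NA_character_
  })
  modal_donor <- if (length(donor)) {
    names(sort(table(donor), decreasing = TRUE))[1L]
  } else {
    NA_character_
  }
  rows <- purrr::map(tips, function(tx) {
    keep <- setdiff(tips, tx)
    if (length(keep) < 3L) {
      warning("removing ", tx, " leaves fewer than 3 taxa; skipped",
              call. = FALSE)
      return(NULL)
    }
    sub_tree <- ape::drop.tip(tree, tx)
    sub_blocks <- purrr::compact(
      purrr::map(blocks, drop_taxon_block, taxon = tx))
    run <- run_full_analysis(sub_blocks,
                             annotations =
                               annotations[annotations$taxon != tx, ,
                                           drop = FALSE],
                             tree = sub_tree, rep = rep,
                             selection = FALSE,
                             window_regressions = FALSE, ...)
    if (is.null(run$logistic)) return(NULL)
    dplyr::mutate(tidy(run$logistic),
                  removed = tx,
                  was_outgroup = tx %in% outgroup,
                  was_modal_donor = identical(tx, modal_donor),
                  .before = 1L)
  })
  dplyr::bind_rows(purrr::compact(rows))
}
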