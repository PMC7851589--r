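#' Construct a gene segment
#'
#' A gene segment is a codon-consistent, gap-free, unambiguous slice of a
#' coding alignment, stored in coding orientation, together with per-taxon
#' genomic position maps.  Downstream modules (ancestral reconstruction,
#' dN/dS) operate on segments only.
#'
#' @param id Segment identifier.
#' @param block_id Id of the parent aligned block.
#' @param seqs Named character vector of gap-free sequences (coding
#'   orientation, equal lengths).
#' @param pos_map Named list of integer vectors: genomic (forward-strand)
#'   position of every segment column per taxon.
#' @param codon_pos Integer vector of codon positions (1/2/3) per column.
#' @param gene_id Gene id in the reference (first) taxon.
#' @return Object of class `gene_segment`.
#' @export
gene_segment <- function(id, block_id, seqs, pos_map, codon_pos,
                         gene_id = NA_character_) {
  structure(
    list(id = as.character(id), block_id = as.character(block_id),
         taxa = names(seqs), seqs = seqs, pos_map = pos_map,
         codon_pos = as.integer(codon_pos),
         gene_id = gene_id, width = nchar(seqs[[1L]])),
    class = "gene_segment")
}

#' @export
print.gene_segment <- function(x, ...) {
  cat(sprintf("<gene_segment> %s (%s): %d taxa x %d bp\n",
              x$id, x$block_id, length(x$taxa), x$width))
  invisible(x)
}

segment_matrix <- function(segment) {
  m <- do.call(rbind, strsplit(segment$seqs, "", fixed = TRUE))
  rownames(m) <- segment$taxa
  m
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split a codon-filtered block into gene segments
#'
#' Columns kept by [codon_consistency_filter()] are scanned for maximal runs
#' that are contiguous in the alignment and free of gaps and ambiguous
#' bases in every taxon.  Each run is trimmed to complete codons
#' ([trim_to_codons()]); runs shorter than `min_len` bp after trimming are
#' discarded.  When the reference-taxon gene lies on the reverse strand the
#' segment is reverse-complemented into coding orientation (position maps
#' keep forward-genome coordinates).
#'
#' @param block An [aligned_block()].
#' @param kept_cols Output of [codon_consistency_filter()] for this block.
#' @param min_len Minimum segment length in bp (default 100).
#' @return List of [gene_segment()] objects.
#' @export
split_into_segments <- function(block, kept_cols, min_len = 100L) {
  if (!length(kept_cols)) return(list())
  codon_pos <- attr(kept_cols, "codon_pos")
  ref_gene <- attr(kept_cols, "ref_gene")
  ref_strand <- attr(kept_cols, "ref_strand")
  m <- block_matrix(block)
  clean <- colSums(matrix(m[, kept_cols, drop = FALSE] %in%
                            c("A", "C", "G", "T"),
                          nrow = nrow(m))) == nrow(m)
  keep <- kept_cols[clean]
  codon_pos <- codon_pos[clean]
  ref_gene <- ref_gene[clean]
  ref_strand <- ref_strand[clean]
  if (!length(keep)) return(list())
  run_id <- cumsum(c(1L, diff(keep) != 1L))
  ref <- block$taxa[1L]
  segs <- list()
  for (r in unique(run_id)) {
    idx <- which(run_id == r)
    cols <- keep[idx]
    cp <- codon_pos[idx]
    # orientation of the coding strand relative to the stored alignment rows:
    # reference row strand vs reference gene strand
    coding_forward <- block$strand[[ref]] == ref_strand[idx][1L]
    ord <- if (coding_forward) seq_along(cols) else rev(seq_along(cols))
    tc <- trim_to_codons_idx(cp[ord])       # trim in coding orientation
    if (length(tc) < max(min_len, 3L)) next
    sel <- sort(ord[tc])                    # back to alignment order
    cols_f <- cols[sel]; cp_f <- cp[sel]
    gid <- ref_gene[sel][1L]
    seqs <- apply(m[, cols_f, drop = FALSE], 1L, paste, collapse = "")
    seqs <- stats::setNames(seqs, block$taxa)
    pos_map <- purrr::map(block$pos_map, ~ .x[cols_f])
    if (!coding_forward) {
      seqs <- stats::setNames(revcomp_chr(seqs), block$taxa)
      pos_map <- purrr::map(pos_map, rev)
      cp_f <- rev(cp_f)
    }
    id <- sprintf("%s.seg%d", block$id, length(segs) + 1L)
    segs[[id]] <- gene_segment(id, block$id, seqs, pos_map, cp_f,
                               gene_id = gid)
  }
  segs
}

# indices of the maximal window of complete codons: drop leading columns
# until the first codon-position-1 column, trailing columns after the last
# codon-position-3 column; verify 1,2,3 cycling, falling back to scanning
# complete triplets if the interior is irregular (e.g. a gene junction).
trim_to_codons_idx <- function(codon_pos) {
  first1 <- which(codon_pos == 1L)
  last3 <- which(codon_pos == 3L)
  if (!length(first1) || !length(last3)) return(integer())
  lo <- first1[1L]; hi <- last3[length(last3)]
  if (hi < lo + 2L) return(integer())
  idx <- lo:hi
  if (length(idx) %% 3L == 0L &&
      all(codon_pos[idx] == rep_len(1:3, length(idx)))) {
    return(idx)
  }
  # irregular interior: keep all non-overlapping complete (1,2,3) triplets
  out <- integer()
  i <- 1L
  n <- length(codon_pos)
  while (i <= n - 2L) {
    if (codon_pos[i] == 1L && codon_pos[i + 1L] == 2L &&
        codon_pos[i + 2L] == 3L) {
      out <- c(out, i, i + 1L, i + 2L)
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Trim a segment to complete codons
#'
#' Removes leading columns before the first codon-position-1 column and
#' trailing columns after the last codon-position-3 column so the segment
#' starts and ends with complete codons.
#'
#' @param segment A [gene_segment()] whose columns carry codon-position
#'   labels.
#' @return The trimmed segment, or `NULL` when no complete codon remains.
#' @export
trim_to_codons <- function(segment) {
  idx <- trim_to_codons_idx(segment$codon_pos)
  if (!length(idx)) return(NULL)
  m <- segment_matrix(segment)[, idx, drop = FALSE]
  seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), segment$taxa)
  gene_segment(segment$id, segment$block_id, seqs,
               purrr::map(segment$pos_map, ~ .x[idx]),
               segment$codon_pos[idx], segment$gene_id)
}

#' Run the full alignment-hygiene filter chain on a set of blocks
#'
#' Universal-block selection, gap trimming, codon-consistency filtering and
#' run-splitting into codon-complete gene segments, with per-stage counts.
#'
#' @param blocks List of [aligned_block()] objects.
#' @param annotations Annotation tibble ([read_annotations()]).
#' @param required_taxa Taxa every block must contain (default: union of
#'   taxa seen across blocks).
#' @param max_gap_fraction Column gap-fraction threshold (default 0.2).
#' @param min_len Minimum segment length in bp (default 100).
#' @param exclude_blocks Optional character vector of block ids to drop
#'   before filtering (e.g. blocks whose topology failed an upstream
#'   congruence screen).
#' @return List with `segments` (list of [gene_segment()]) and `stats`
#'   (tibble of per-block column counts per filter stage).
#' @export
filter_blocks <- function(blocks, annotations, required_taxa = NULL,
                          max_gap_fraction = 0.2, min_len = 100L,
                          exclude_blocks = NULL) {
  if (!is.null(exclude_blocks)) {
    blocks <- blocks[setdiff(names(blocks), exclude_blocks)]
  }
  if (is.null(required_taxa)) {
    required_taxa <- sort(unique(unlist(purrr::map(blocks, "taxa"))))
  }
  blocks <- select_universal_blocks(blocks, required_taxa)
  segments <- list()
  stats <- purrr::map(blocks, function(b) {
    w0 <- b$width
    b <- gap_fraction_trim(b, max_gap_fraction)
    kept <- codon_consistency_filter(b, annotations)
    segs <- split_into_segments(b, kept, min_len = min_len)
    segments <<- c(segments, segs)
    tibble::tibble(block = b$id, columns = w0,
                   after_gap_trim = b$width,
                   codon_consistent = length(kept),
                   segments = length(segs),
                   segment_bp = sum(purrr::map_int(segs, "width")))
  })
  list(segments = segments, stats = dplyr::bind_rows(stats))
}

#' Write gene segments as FASTA plus a coordinate sidecar
#'
#' @param segments List of [gene_segment()] objects.
#' @param dir Output directory (created if needed).
#' @return Tibble sidecar (segment id, taxon, start, end, strand span of the
#'   mapped positions), invisibly; written as `segments.tsv` beside one
#'   FASTA per segment.
#' @export
write_segments <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  side <- purrr::map(segments, function(s) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(s$seqs),
      file.path(dir, paste0(s$id, ".fasta")))
    tibble::tibble(
      segment = s$id, taxon = s$taxa,
      start = purrr::map_int(s$pos_map, min),
      end = purrr::map_int(s$pos_map, max),
      strand = ifelse(purrr::map_lgl(s$pos_map,
                                     ~ .x[1] <= .x[length(.x)]), "+", "-"))
  })
  side <- dplyr::bind_rows(side)
  utils::write.table(side, file.path(dir, "segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(side)
}
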