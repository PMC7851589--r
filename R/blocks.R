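#' Construct an aligned homologous block
#'
#' An aligned block is one locally collinear block (LCB) of a multi-genome
#' alignment: equal-length aligned rows, one per taxon, each tagged with the
#' genomic span it came from and its strand.  Rows are stored in alignment
#' orientation; for a `-` strand row the per-column position map descends
#' from `end` to `start` (forward-genome coordinates), so reverse-complement
#' rows still map every column to its true genomic position.
#'
#' @param id Block identifier.
#' @param seqs Named character vector of aligned sequences (names = taxa),
#'   all the same length, alphabet `A C G T N -` (case-insensitive).
#' @param start,end Named integer vectors: 1-based inclusive genomic span of
#'   each row's ungapped sequence (forward-strand coordinates, start <= end).
#' @param strand Named character vector of `"+"`/`"-"`.
#' @return An object of class `aligned_block` with a `pos_map` component:
#'   per taxon, an integer vector giving the genomic position of every
#'   alignment column (`NA` at gaps).
#' @export
aligned_block <- function(id, seqs, start, end, strand) {
  taxa <- names(seqs)
  if (is.null(taxa) || any(taxa == "")) {
    stop("seqs must be a named vector (names = taxa)", call. = FALSE)
  }
  widths <- unique(nchar(seqs))
  if (length(widths) != 1L) {
    stop("block ", id, ": ragged rows (aligned lengths ",
         paste(widths, collapse = ", "), ")", call. = FALSE)
  }
  seqs <- toupper(seqs)
  start <- as.integer(start[taxa]); end <- as.integer(end[taxa])
  strand <- as.character(strand[taxa])
  pos_map <- purrr::map(taxa, function(tx) {
    chars <- strsplit(seqs[[tx]], "", fixed = TRUE)[[1]]
    ungapped <- chars != "-"
    n <- sum(ungapped)
    if (n != end[[match(tx, taxa)]] - start[[match(tx, taxa)]] + 1L) {
      stop("block ", id, ", taxon ", tx, ": ungapped length ", n,
           " does not match coordinates", call. = FALSE)
    }
    i <- match(tx, taxa)
    map <- rep(NA_integer_, length(chars))
    map[ungapped] <- if (strand[i] == "+") {
      seq.int(start[i], end[i])
    } else {
      seq.int(end[i], start[i])
    }
    map
  })
  names(pos_map) <- taxa
  structure(
    list(id = as.character(id), taxa = taxa, seqs = seqs,
         start = stats::setNames(start, taxa),
         end = stats::setNames(end, taxa),
         strand = stats::setNames(strand, taxa),
         pos_map = pos_map, width = widths),
    class = "aligned_block"
  )
}

#' @export
print.aligned_block <- function(x, ...) {
  cat(sprintf("<aligned_block> %s: %d taxa x %d columns\n",
              x$id, length(x$taxa), x$width))
  invisible(x)
}

block_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$seqs, "", fixed = TRUE))
  rownames(m) <- block$taxa
  m
}

subset_block_columns <- function(block, cols) {
  m <- block_matrix(block)[, cols, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  block$seqs <- stats::setNames(seqs, block$taxa)
  block$pos_map <- purrr::map(block$pos_map, ~ .x[cols])
  block$width <- length(cols)
  for (tx in block$taxa) {
    mapped <- block$pos_map[[tx]][!is.na(block$pos_map[[tx]])]
    if (length(mapped)) {
      block$start[tx] <- min(mapped)
      block$end[tx] <- max(mapped)
    } else {
      block$start[tx] <- NA_integer_
      block$end[tx] <- NA_integer_
    }
  }
  block
}

#' Read a block-partitioned alignment in XMFA format
#'
#' Parses the Mauve XMFA dialect: per-row headers
#' `> taxon:start-end strand [comment]`, sequence lines, blocks terminated by
#' `=`.  Leading comment lines (`#`) are skipped.
#'
#' @param path Path to an XMFA file.
#' @param replicon_lengths Optional named vector of replicon lengths per
#'   taxon; when given, coordinates are bounds-checked.
#' @return A list of [aligned_block()] objects (ids `block_1`, `block_2`, ...).
#' @export
read_xmfa <- function(path, replicon_lengths = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  blocks <- list()
  cur_names <- character(); cur_start <- integer(); cur_end <- integer()
  cur_strand <- character(); cur_seq <- character()
  pending <- NULL
  flush_row <- function() {
    if (!is.null(pending)) {
      cur_names[length(cur_names) + 1L] <<- pending$taxon
      cur_start[length(cur_start) + 1L] <<- pending$start
      cur_end[length(cur_end) + 1L] <<- pending$end
      cur_strand[length(cur_strand) + 1L] <<- pending$strand
      cur_seq[length(cur_seq) + 1L] <<- paste(pending$seq, collapse = "")
      pending <<- NULL
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush_row()
      m <- stringr::str_match(
        ln, "^>\\s*([^:\\s]+):(\\d+)-(\\d+)\\s+([+-])")
      if (any(is.na(m[1, ]))) {
        stop("unparseable XMFA header: ", ln, call. = FALSE)
      }
      pending <- list(taxon = m[1, 2], start = as.integer(m[1, 3]),
                      end = as.integer(m[1, 4]), strand = m[1, 5],
                      seq = character())
    } else if (startsWith(ln, "=")) {
      flush_row()
      if (length(cur_names)) {
        id <- paste0("block_", length(blocks) + 1L)
        if (!is.null(replicon_lengths)) {
          for (i in seq_along(cur_names)) {
            lim <- replicon_lengths[[cur_names[i]]]
            if (!is.null(lim) && cur_end[i] > lim) {
              stop("block ", id, ", taxon ", cur_names[i],
                   ": coordinates exceed replicon length ", lim,
                   call. = FALSE)
            }
          }
        }
        blocks[[id]] <- aligned_block(
          id, stats::setNames(cur_seq, cur_names),
          stats::setNames(cur_start, cur_names),
          stats::setNames(cur_end, cur_names),
          stats::setNames(cur_strand, cur_names))
      }
      cur_names <- character(); cur_start <- integer()
      cur_end <- integer(); cur_strand <- character(); cur_seq <- character()
    } else if (nzchar(trimws(ln))) {
      if (is.null(pending)) stop("sequence outside a block: ", ln,
                                 call. = FALSE)
      pending$seq <- c(pending$seq, trimws(ln))
    }
  }
  flush_row()
  if (length(cur_names)) {
    id <- paste0("block_", length(blocks) + 1L)
    blocks[[id]] <- aligned_block(
      id, stats::setNames(cur_seq, cur_names),
      stats::setNames(cur_start, cur_names),
      stats::setNames(cur_end, cur_names),
      stats::setNames(cur_strand, cur_names))
  }
  blocks
}

#' Write blocks to an XMFA file
#'
#' @param blocks List of [aligned_block()] objects.
#' @param path Output path.
#' @param comment Optional comment line(s) written as `#` header.
#' @return `path`, invisibly.
#' @export
write_xmfa <- function(blocks, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  for (b in blocks) {
    for (tx in b$taxa) {
      writeLines(sprintf("> %s:%d-%d %s %s", tx, b$start[[tx]], b$end[[tx]],
                         b$strand[[tx]], b$id), con)
      writeLines(b$seqs[[tx]], con)
    }
    writeLines("=", con)
  }
  invisible(path)
}

#' Keep only blocks present in every required taxon
#'
#' Restricting the analysis to universal blocks guarantees every alignment
#' column can be compared across all taxa and placed on the shared phylogeny.
#'
#' @param blocks List of [aligned_block()] objects.
#' @param required_taxa Character vector of taxa that must all be present.
#' @return The filtered list, original order preserved.  A warning is issued
#'   if nothing survives.
#' @export
select_universal_blocks <- function(blocks, required_taxa) {
  stopifnot(length(required_taxa) > 0L)
  keep <- purrr::map_lgl(blocks, ~ all(required_taxa %in% .x$taxa))
  out <- blocks[keep]
  if (!length(out)) {
    warning("no block contains all required taxa", call. = FALSE)
  }
  out
}

#' Remove excessively gapped alignment columns
#'
#' A light-weight stand-in for alignment-trimming tools: any column whose
#' gap fraction exceeds `max_gap_fraction` is dropped and position maps are
#' re-derived.
#'
#' @param block An [aligned_block()].
#' @param max_gap_fraction Columns with a gap fraction strictly greater than
#'   this are removed (default 0.2).
#' @return The trimmed block, with attribute `removed_columns`.
#' @export
gap_fraction_trim <- function(block, max_gap_fraction = 0.2) {
  m <- block_matrix(block)
  gap_frac <- colMeans(m == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  out <- subset_block_columns(block, keep)
  attr(out, "removed_columns") <- block$width - length(keep)
  out
}

#' Read a per-taxon gene annotation table
#'
#' Accepts a 6-column TSV (`taxon`, `gene_id`, `start`, `end`, `strand`,
#' `frame`; header required, `frame` optional) or an existing data frame with
#' those columns.  Coordinates are 1-based inclusive; `frame` is the offset
#' (0/1/2) of the first complete codon and defaults to 0.
#'
#' @param x Path to a TSV file, or a data frame.
#' @return A tibble with columns `taxon`, `gene_id`, `start`, `end`,
#'   `strand`, `frame`.
#' @export
read_annotations <- function(x) {
  ann <- if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE, comment.char = "#")
  } else {
    as.data.frame(x)
  }
  need <- c("taxon", "gene_id", "start", "end", "strand")
  if (!all(need %in% names(ann))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(ann$frame)) ann$frame <- 0L
  ann <- tibble::as_tibble(ann)
  ann$start <- as.integer(ann$start); ann$end <- as.integer(ann$end)
  ann$frame <- as.integer(ann$frame)
  if (any(ann$start > ann$end)) {
    stop("annotation rows with start > end", call. = FALSE)
  }
  ann
}

#' Read gene annotations from a GFF3 file
#'
#' Convenience wrapper around [ape::read.gff()] extracting CDS (or `type`)
#' features into the tabular annotation format used by the filters.
#'
#' @param path GFF3 file path.
#' @param taxon Taxon name to stamp on every row.
#' @param type Feature type to keep (default `"CDS"`).
#' @return Annotation tibble as in [read_annotations()].
#' @export
read_gff_annotations <- function(path, taxon, type = "CDS") {
  g <- ape::read.gff(path)
  g <- g[g$type == type, , drop = FALSE]
  id <- stringr::str_match(g$attributes, "ID=([^;]+)")[, 2]
  id[is.na(id)] <- paste0("feature_", seq_len(sum(is.na(id))))
  ph <- suppressWarnings(as.integer(as.character(g$phase)))
  ph[is.na(ph)] <- 0L
  read_annotations(tibble::tibble(
    taxon = taxon, gene_id = id, start = g$start, end = g$end,
    strand = as.character(g$strand), frame = ph))
}

# per-taxon codon position (1/2/3) and gene id for a vector of genomic
# positions; NA outside annotated genes.  Positions on a reverse-strand gene
# are counted from the gene's 3' genomic end (its coding 5' end).
codon_position_lookup <- function(positions, ann_taxon) {
  out_pos <- rep(NA_integer_, length(positions))
  out_gene <- rep(NA_character_, length(positions))
  out_strand <- rep(NA_character_, length(positions))
  if (!nrow(ann_taxon)) {
    return(list(codon_pos = out_pos, gene = out_gene, strand = out_strand))
  }
  ord <- order(ann_taxon$start)
  ann_taxon <- ann_taxon[ord, , drop = FALSE]
  idx <- findInterval(positions, ann_taxon$start)
  ok <- which(idx >= 1L & !is.na(positions))
  ok <- ok[positions[ok] <= ann_taxon$end[idx[ok]]]
  if (length(ok)) {
    g <- idx[ok]
    plus <- ann_taxon$strand[g] == "+"
    off <- ifelse(plus,
                  positions[ok] - ann_taxon$start[g] - ann_taxon$frame[g],
                  ann_taxon$end[g] - positions[ok] - ann_taxon$frame[g])
    inframe <- off >= 0L
    out_pos[ok[inframe]] <- (off[inframe] %% 3L) + 1L
    out_gene[ok[inframe]] <- ann_taxon$gene_id[g][inframe]
    out_strand[ok[inframe]] <- ann_taxon$strand[g][inframe]
  }
  list(codon_pos = out_pos, gene = out_gene, strand = out_strand)
}

#' Keep alignment columns with a consistent codon position in all taxa
#'
#' A column survives only if, in every taxon, its base falls inside an
#' annotated gene and all taxa report the identical codon position (1, 2 or
#' 3).  Columns that are intergenic in any taxon, gapped in any taxon, or
#' disagree on codon position are removed, restricting the analysis to
#' protein-coding sequence with a shared reading frame.
#'
#' @param block An [aligned_block()].
#' @param annotations Annotation tibble ([read_annotations()]) covering every
#'   taxon in the block.
#' @return Integer vector of kept column indices, with attributes
#'   `codon_pos` (codon position per kept column) and `ref_gene`/`ref_strand`
#'   (gene id and strand in the first taxon).
#' @export
codon_consistency_filter <- function(block, annotations) {
  missing <- setdiff(block$taxa, unique(annotations$taxon))
  if (length(missing)) {
    stop("no annotations for taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_taxon <- purrr::map(block$taxa, function(tx) {
    codon_position_lookup(block$pos_map[[tx]],
                          annotations[annotations$taxon == tx, , drop = FALSE])
  })
  names(per_taxon) <- block$taxa
  cp <- do.call(rbind, purrr::map(per_taxon, "codon_pos"))
  all_coding <- colSums(is.na(cp)) == 0L
  same <- colSums(cp == matrix(cp[1L, ], nrow(cp), ncol(cp),
                               byrow = TRUE)) == nrow(cp)
  kept <- which(all_coding & !is.na(same) & same)
  structure(kept,
            codon_pos = cp[1L, kept],
            ref_gene = per_taxon[[1L]]$gene[kept],
            ref_strand = per_taxon[[1L]]$strand[kept])
}
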