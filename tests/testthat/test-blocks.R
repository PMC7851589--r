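make_block <- function(id = "b1",
                       seqs = c(a = "ACGTAC", b = "ACGTAC", c = "ACGTAC"),
                       start = c(a = 1, b = 11, c = 21),
                       strand = c(a = "+", b = "+", c = "+")) {
  ungapped <- nchar(gsub("-", "", seqs))
  aligned_block(id, seqs, start, start + ungapped - 1L, strand)
}

test_that("XMFA files round-trip through write and read", {
  b1 <- make_block("b1")
  b2 <- make_block("b2", seqs = c(a = "GGCC", b = "GGCC", c = "GGCC"),
                   start = c(a = 101, b = 111, c = 121),
                   strand = c(a = "+", b = "-", c = "+"))
  path <- withr::local_tempfile(fileext = ".xmfa")
  write_xmfa(list(b1, b2), path, comment = "seed: 1")
  back <- read_xmfa(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$seqs, b1$seqs)
  expect_equal(back[[2]]$strand[["b"]], "-")
  # reverse-strand rows map columns in descending genomic order
  expect_equal(back[[2]]$pos_map$b, c(114, 113, 112, 111))
  expect_equal(back[[1]]$pos_map$a, 1:6)
})

test_that("malformed blocks are rejected with informative errors", {
  expect_error(aligned_block("x", c(a = "ACGT", b = "ACG"),
                             c(a = 1, b = 1), c(a = 4, b = 3),
                             c(a = "+", b = "+")),
               "ragged")
  expect_error(aligned_block("x", c(a = "AC-T", b = "ACGT"),
                             c(a = 1, b = 1), c(a = 4, b = 4),
                             c(a = "+", b = "+")),
               "does not match coordinates")
  path <- withr::local_tempfile(fileext = ".xmfa")
  writeLines(c("> a:5-8 + x", "ACGT", "="), path)
  expect_error(read_xmfa(path, replicon_lengths = c(a = 6)),
               "exceed replicon length")
  writeLines(c("> a 5 8", "ACGT", "="), path)
  expect_error(read_xmfa(path), "unparseable")
})

test_that("universal-block selection keeps exactly the fully shared blocks", {
  blocks <- list(
    b1 = make_block("b1"),
    b2 = aligned_block("b2", c(a = "AC", b = "AC"), c(a = 1, b = 1),
                       c(a = 2, b = 2), c(a = "+", b = "+")),
    b3 = make_block("b3"))
  expect_equal(names(select_universal_blocks(blocks, c("a", "b", "c"))),
               c("b1", "b3"))
  expect_length(select_universal_blocks(blocks, "a"), 3)
  expect_warning(out <- select_universal_blocks(blocks, c("a", "b", "c", "d")),
                 "no block")
  expect_length(out, 0)
})

test_that("gap-fraction trimming removes gappy columns and remaps", {
  b <- aligned_block("g", c(a = "A-CG", b = "A-CG", c = "AAC-", d = "AACG"),
                     start = c(a = 1, b = 1, c = 1, d = 1),
                     end = c(a = 3, b = 3, c = 3, d = 4),
                     strand = c(a = "+", b = "+", c = "+", d = "+"))
  tr <- gap_fraction_trim(b, 0.2)
  # column 2 (2/4 gaps) and column 4 (1/4 gaps) both exceed 0.2
  expect_equal(tr$width, 2)
  expect_equal(attr(tr, "removed_columns"), 2)
  expect_equal(tr$pos_map$a, c(1, 2))
  clean <- make_block()
  expect_equal(gap_fraction_trim(clean, 0.2)$seqs, clean$seqs)
  allgap <- aligned_block("ag", c(a = "A-", b = "A-"), c(a = 1, b = 1),
                          c(a = 1, b = 1), c(a = "+", b = "+"))
  expect_equal(gap_fraction_trim(allgap, 0.99)$width, 1)
})

test_that("codon consistency keeps agreeing columns and drops the rest", {
  # two taxa; in b the gene starts one base later, shifting codon position
  seqs <- c(a = "ATGAAACCC", b = "ATGAAACCC")
  blk <- aligned_block("cc", seqs, c(a = 1, b = 1), c(a = 9, b = 9),
                       c(a = "+", b = "+"))
  ann_agree <- read_annotations(tibble::tibble(
    taxon = c("a", "b"), gene_id = "g1", start = 1, end = 9,
    strand = "+", frame = 0))
  kept <- codon_consistency_filter(blk, ann_agree)
  expect_equal(as.integer(kept), 1:9)
  expect_equal(attr(kept, "codon_pos"), rep(1:3, 3))
  ann_shift <- read_annotations(tibble::tibble(
    taxon = c("a", "b"), gene_id = "g1", start = c(1, 2), end = c(9, 9),
    strand = "+", frame = 0))
  expect_length(codon_consistency_filter(blk, ann_shift), 0)
  # intergenic in one taxon -> dropped
  ann_part <- read_annotations(tibble::tibble(
    taxon = c("a", "b"), gene_id = "g1", start = c(1, 1), end = c(9, 6),
    strand = "+", frame = 0))
  expect_equal(as.integer(codon_consistency_filter(blk, ann_part)), 1:6)
  expect_error(codon_consistency_filter(blk, ann_agree[1, ]),
               "no annotations for taxa: b")
})

test_that("filters are invariant under taxon reordering", {
  seqs <- c(a = "ATGAAACCC", b = "ATGAAACCC", c = "ATGAAACCC")
  ann <- read_annotations(tibble::tibble(
    taxon = c("a", "b", "c"), gene_id = "g1", start = 1, end = 9,
    strand = "+", frame = 0))
  b1 <- aligned_block("o", seqs, c(a = 1, b = 1, c = 1),
                      c(a = 9, b = 9, c = 9), c(a = "+", b = "+", c = "+"))
  b2 <- aligned_block("o", seqs[c(3, 1, 2)], c(c = 1, a = 1, b = 1),
                      c(c = 9, a = 9, b = 9), c(c = "+", a = "+", b = "+"))
  expect_equal(length(codon_consistency_filter(b1, ann)),
               length(codon_consistency_filter(b2, ann)))
})

test_that("run splitting applies the minimum-length rule around gaps", {
  # one 249-bp gene in all taxa; taxon c lost one codon (columns 118-120)
  set.seed(1)
  gene <- paste(sample(c("GCT", "GAA", "TTC", "AAA", "CGT"), 83,
                       replace = TRUE), collapse = "")
  with_gap <- paste0(substr(gene, 1, 117), "---", substr(gene, 121, 249))
  blk <- aligned_block(
    "sp", c(a = gene, b = gene, c = with_gap),
    start = c(a = 1, b = 1, c = 1), end = c(a = 249, b = 249, c = 246),
    strand = c(a = "+", b = "+", c = "+"))
  ann <- read_annotations(tibble::tibble(
    taxon = c("a", "b", "c"), gene_id = "g1", start = 1,
    end = c(249, 249, 246), strand = "+", frame = 0))
  kept <- codon_consistency_filter(blk, ann)
  segs <- split_into_segments(blk, kept, min_len = 100)
  expect_length(segs, 2)
  expect_equal(purrr::map_int(segs, "width"), c(117, 129),
               ignore_attr = TRUE)
  # same gene but the gap at columns 58-60: the 57-bp run is discarded
  with_gap2 <- paste0(substr(gene, 1, 57), "---", substr(gene, 61, 249))
  blk2 <- aligned_block(
    "sp2", c(a = gene, b = gene, c = with_gap2),
    start = c(a = 1, b = 1, c = 1), end = c(a = 249, b = 249, c = 246),
    strand = c(a = "+", b = "+", c = "+"))
  segs2 <- split_into_segments(blk2, codon_consistency_filter(blk2, ann),
                               min_len = 100)
  expect_length(segs2, 1)
  expect_equal(segs2[[1]]$width, 189)
  # a 99-bp gene never reaches the threshold
  short <- substr(gene, 1, 99)
  blk3 <- aligned_block("sp3", c(a = short, b = short),
                        start = c(a = 1, b = 1), end = c(a = 99, b = 99),
                        strand = c(a = "+", b = "+"))
  ann3 <- read_annotations(tibble::tibble(
    taxon = c("a", "b"), gene_id = "g1", start = 1, end = 99,
    strand = "+", frame = 0))
  expect_length(split_into_segments(blk3,
                                    codon_consistency_filter(blk3, ann3),
                                    min_len = 100), 0)
})

test_that("codon trimming anchors segments on complete codons", {
  expect_equal(oriscan:::trim_to_codons_idx(c(2, 3, 1, 2, 3, 1, 2, 3)), 3:8)
  expect_equal(oriscan:::trim_to_codons_idx(c(1, 2, 3)), 1:3)
  expect_length(oriscan:::trim_to_codons_idx(c(2, 3)), 0)
  seg <- gene_segment("s", "b", c(a = "ACGTAC", b = "ACGTAC"),
                      list(a = 1:6, b = 1:6), c(2, 3, 1, 2, 3, 1))
  tr <- trim_to_codons(seg)
  expect_equal(tr$width, 3)
  expect_equal(tr$seqs[["a"]], "GTA")
  expect_equal(tr$pos_map$a, 3:5)
})

test_that("reverse-strand genes come out in coding orientation", {
  # gene on the minus strand of both taxa: ATG GAA TAA read on the
  # reverse complement; genomic forward sequence is TTATTCCAT
  fwd <- "TTATTCCAT"
  blk <- aligned_block("rv", c(a = fwd, b = fwd), c(a = 1, b = 1),
                       c(a = 9, b = 9), c(a = "+", b = "+"))
  ann <- read_annotations(tibble::tibble(
    taxon = c("a", "b"), gene_id = "g1", start = 1, end = 9,
    strand = "-", frame = 0))
  kept <- codon_consistency_filter(blk, ann)
  expect_length(kept, 9)
  segs <- split_into_segments(blk, kept, min_len = 9)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$seqs[["a"]], "ATGGAATAA")
  expect_equal(segs[[1]]$pos_map$a, 9:1)   # genomic coords preserved
  expect_equal(segs[[1]]$codon_pos, rep(1:3, 3))
})

test_that("position maps round-trip through column subsets", {
  b <- make_block()
  tr <- gap_fraction_trim(b, 0.5)
  for (tx in tr$taxa) {
    ungapped <- which(!is.na(tr$pos_map[[tx]]))
    gpos <- tr$pos_map[[tx]][ungapped]
    expect_equal(match(gpos, tr$pos_map[[tx]]), ungapped)
  }
})

test_that("segments write FASTA plus a coordinate sidecar", {
  sim <- small_sim()
  f <- filter_blocks(sim$blocks, sim$annotations)
  dir <- withr::local_tempdir()
  side <- write_segments(f$segments[1:3], dir)
  expect_true(file.exists(file.path(dir, "segments.tsv")))
  expect_equal(nrow(side), 3 * length(sim$tree$tip.label))
  expect_true(all(file.exists(
    file.path(dir, paste0(purrr::map_chr(f$segments[1:3], "id"), ".fasta")))))
})
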