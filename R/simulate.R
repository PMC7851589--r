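COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Configure a synthetic-genome simulation
#'
#' The simulator evolves a circular or linear replicon of protein-coding
#' genes along a clock-like tree.  On every branch it first draws block
#' rearrangements (a contiguous block is moved to a new locus and inverted
#' with probability `q`), then per-site substitutions whose rate follows a
#' log-linear gradient in distance from the origin,
#' `rate(d) = mu * exp(g * d)`, evaluated in the coordinates of the genome
#' as arranged on that branch -- so a rearranged block acquires the
#' substitution rate of its new neighbourhood, which is exactly the coupling
#' between rearrangement and spatial substitution trends the pipeline is
#' built to detect.  Proposed changes that are nonsynonymous are accepted
#' with probability `f` (purifying selection); the default base composition
#' is uniform, which keeps the mutation kernel strand-symmetric.
#'
#' Defaults describe the standard study condition: 5 taxa, a 500 kb circular
#' replicon with the origin at position 1 and an antipodal terminus, 400
#' genes in 20 rearrangeable blocks (about 72% coding), total tree length
#' 0.08 expected substitutions per site, a gradient that doubles the rate
#' across a replichore, and on average 0.5 rearrangements per branch.
#'
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param n_taxa Number of extant taxa (used when `tree` is `NULL`).
#' @param tree Optional rooted `phylo` with branch lengths; default is a
#'   coalescent (clock-like) tree rescaled to total length `tree_length`.
#' @param tree_length Total tree length in expected substitutions per site.
#' @param L Replicon length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @param origin Origin position (default 1).
#' @param terminus Terminus position or `"midpoint"`.
#' @param n_blocks Number of rearrangeable blocks (`L` must be divisible).
#' @param n_genes Number of genes (divisible by `n_blocks`).
#' @param gene_len_range Gene length range in bp; draws are rounded to
#'   multiples of 3.
#' @param mu Substitution rate scale at the origin (per site per unit branch
#'   length).
#' @param gradient Log-linear gradient g per bp of transformed distance;
#'   `NULL` means rate doubling across the longest replichore,
#'   `log(2) / max(replichore length)`.
#' @param kappa Transition/transversion rate ratio of the mutation kernel.
#' @param f Acceptance probability of nonsynonymous changes (1 = neutral).
#' @param rho Expected number of rearrangements per branch; counts on each
#'   branch are Poisson with intensity proportional to branch length, scaled
#'   so the tree-wide average per branch equals `rho`.
#' @param q Probability a rearranged block is also inverted.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_taxa = 5L, tree = NULL,
                       tree_length = 0.08, L = 500000L,
                       topology = "circular", origin = 1L,
                       terminus = "midpoint", n_blocks = 20L,
                       n_genes = 400L, gene_len_range = c(600L, 1200L),
                       mu = 1, gradient = NULL, kappa = 3, f = 0.2,
                       rho = 0.5, q = 0.5) {
  stopifnot(L %% n_blocks == 0L, n_genes %% n_blocks == 0L,
            mu >= 0, f > 0, f <= 1, rho >= 0, q >= 0, q <= 1)
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 tree = tree, tree_length = tree_length, L = as.integer(L),
                 topology = topology, origin = as.integer(origin),
                 terminus = terminus, n_blocks = as.integer(n_blocks),
                 n_genes = as.integer(n_genes),
                 gene_len_range = as.integer(gene_len_range), mu = mu,
                 gradient = gradient, kappa = kappa, f = f, rho = rho,
                 q = q),
            class = "sim_config")
}

# clade identifier of the child node of each edge: sorted tip labels joined
# with "|"; stable across tree serialisation round trips
node_clade_ids <- function(ord) {
  n_tip <- ord$n_tip
  tips <- ord$tree$tip.label
  sets <- vector("list", ord$n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tips[i]
  for (e in seq_len(nrow(ord$edge))) {   # postorder: children first
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  purrr::map_chr(sets, ~ paste(sort(.x), collapse = "|"))
}

# genome start of each arrangement slot, and (block, local offset, strand)
# lookups for genome positions, given block order/strand vectors
layout_starts <- function(arr_block, block_len) {
  c(0L, cumsum(rep(block_len, length(arr_block) - 1L))) + 1L
}

# genome position of block-local offsets under an arrangement
pos_of <- function(block, offset, arr_block, arr_strand, block_len) {
  slot <- match(block, arr_block)
  G <- (slot - 1L) * block_len + 1L
  ifelse(arr_strand[slot] == "+", G + offset - 1L, G + block_len - offset)
}

#' Simulate genomes, rearrangements and substitutions along a tree
#'
#' Generates a root genome, evolves it branch by branch (rearrangements,
#' then gradient-driven substitutions with purifying selection inside
#' genes), and returns the leaf genomes, per-taxon annotations, the exact
#' block alignment induced by the rearrangement history (gap-free, so no
#' upstream aligner is needed), and complete truth logs of every accepted
#' substitution and every rearrangement.
#'
#' @param config A [sim_config()].
#' @return A `genome_simulation` list: `config`, `tree`, `replicon`,
#'   `blocks` (list of [aligned_block()]), `annotations` (tibble),
#'   `leaf_genomes` (named character), `truth` (list with `substitutions`
#'   and `rearrangements` tibbles), `genes`, `root_blocks`, and per-node
#'   `arrangements`.
#' @export
simulate_genomes <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$L; n_blocks <- config$n_blocks
  block_len <- L %/% n_blocks
  genes_per_block <- config$n_genes %/% n_blocks

  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(config$n_taxa,
                       tip.label = paste0("t", seq_len(config$n_taxa)))
    tree$edge.length <- tree$edge.length *
      (config$tree_length / sum(tree$edge.length))
  }
  ord <- tree_postorder(tree)
  clades <- node_clade_ids(ord)

  rep <- replicon("sim", L, config$topology, config$origin,
                  config$terminus)
  g <- config$gradient %||% (log(2) / max(replichore_lengths(rep)))

  ## --- root genome: genes laid down block by block, all forward strand
  ## in block-local coordinates (inversions later create reverse genes)
  gene_rows <- list()
  root_blocks <- vector("list", n_blocks)
  gene_of <- vector("list", n_blocks)     # per local offset: gene index/NA
  gene_start_of <- vector("list", n_blocks)
  sense <- setdiff(all_codons(), names(which(genetic_code() == "*")))
  gid <- 0L
  for (b in seq_len(n_blocks)) {
    lens <- NULL
    for (try in 1:50) {
      cand <- sample(seq(config$gene_len_range[1], config$gene_len_range[2],
                         by = 3L), genes_per_block, replace = TRUE)
      if (block_len - sum(cand) >= genes_per_block + 1L) {
        lens <- cand
        break
      }
    }
    if (is.null(lens)) {
      stop("genes do not fit in blocks; reduce n_genes or lengths",
           call. = FALSE)
    }
    slack <- block_len - sum(lens)
    cuts <- sort(sample.int(slack - 1L, genes_per_block))
    gaps <- diff(c(0L, cuts))              # leading gap before each gene
    seq_local <- rep(NA_character_, block_len)
    gmap <- rep(NA_integer_, block_len)
    gsmap <- rep(NA_integer_, block_len)
    at <- 1L
    for (k in seq_len(genes_per_block)) {
      at <- at + gaps[k]
      gid <- gid + 1L
      span <- at:(at + lens[k] - 1L)
      seq_local[span] <- strsplit(
        paste(sample(sense, lens[k] / 3L, replace = TRUE), collapse = ""),
        "")[[1]]
      gmap[span] <- gid
      gsmap[span] <- at
      gene_rows[[gid]] <- tibble::tibble(
        gene = gid, block = b, local_start = at,
        local_end = at + lens[k] - 1L)
      at <- at + lens[k]
    }
    inter <- is.na(seq_local)
    seq_local[inter] <- sample(c("A", "C", "G", "T"), sum(inter),
                               replace = TRUE)
    root_blocks[[b]] <- seq_local
    gene_of[[b]] <- gmap
    gene_start_of[[b]] <- gsmap
  }
  genes <- dplyr::bind_rows(gene_rows)

  ## --- per-site substitution rate in genome coordinates (positions are
  ## always 1..L regardless of arrangement)
  base_rate <- config$mu *
    exp(g * transform_position(seq_len(L), rep)$distance)

  gc_tab <- genetic_code()
  kernel <- function(cur) {
    # HKY-like proposal among the three alternatives of `cur`
    alts <- setdiff(c("A", "C", "G", "T"), cur)
    w <- ifelse((cur %in% c("A", "G") & alts %in% c("A", "G")) |
                  (cur %in% c("C", "T") & alts %in% c("C", "T")),
                config$kappa, 1)
    alts[sample.int(3L, 1L, prob = w)]
  }

  ## --- evolve: preorder over edges
  states <- vector("list", ord$n_node)   # each: list(blocks, arr, strand)
  states[[ord$root]] <- list(blocks = root_blocks,
                             arr = seq_len(n_blocks),
                             strand = rep("+", n_blocks))
  sub_log <- list()
  re_log <- list()
  # rearrangement intensity per branch: Poisson in branch length, scaled so
  # the tree-wide average count per branch equals rho
  re_lambda <- if (sum(ord$lengths) > 0) {
    config$rho * ord$lengths * length(ord$lengths) / sum(ord$lengths)
  } else {
    rep(config$rho, length(ord$lengths))
  }
  for (e in rev(seq_len(nrow(ord$edge)))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    t_len <- ord$lengths[e]
    st <- states[[parent]]
    branch <- clades[child]
    parent_arr <- st$arr; parent_strand <- st$strand

    n_re <- stats::rpois(1L, re_lambda[e])
    if (n_re > 0L) {
      for (k in seq_len(n_re)) {
        i <- sample.int(n_blocks, 1L)
        moved <- st$arr[i]; moved_s <- st$strand[i]
        rest_a <- st$arr[-i]; rest_s <- st$strand[-i]
        j <- sample.int(n_blocks, 1L)      # insertion slot in the new order
        inv <- stats::runif(1L) < config$q
        if (inv) moved_s <- if (moved_s == "+") "-" else "+"
        st$arr <- append(rest_a, moved, after = j - 1L)
        st$strand <- append(rest_s, moved_s, after = j - 1L)
        re_log[[length(re_log) + 1L]] <- tibble::tibble(
          branch = branch, block = moved, dest_slot = j, inverted = inv)
      }
    }

    cnt <- stats::rpois(L, base_rate * t_len)
    hit <- which(cnt > 0L)
    if (length(hit)) {
      # map genome positions to (block, local offset)
      slot <- (hit - 1L) %/% block_len + 1L
      blk <- st$arr[slot]
      within <- hit - (slot - 1L) * block_len        # 1..block_len
      off <- ifelse(st$strand[slot] == "+", within,
                    block_len - within + 1L)
      n_ev <- sum(cnt[hit])
      ev_block <- integer(n_ev); ev_off <- integer(n_ev)
      ev_from <- character(n_ev); ev_to <- character(n_ev)
      ev_type <- character(n_ev); ev_child <- integer(n_ev)
      n_acc <- 0L
      for (ii in seq_along(hit)) {
        b <- blk[ii]; o <- off[ii]
        for (rep_i in seq_len(cnt[hit[ii]])) {
          cur <- st$blocks[[b]][o]
          prop <- kernel(cur)
          gidx <- gene_of[[b]][o]
          type <- "intergenic"
          if (!is.na(gidx)) {
            gs <- gene_start_of[[b]][o]
            cs <- gs + 3L * ((o - gs) %/% 3L)
            codon <- st$blocks[[b]][cs:(cs + 2L)]
            new_codon <- codon
            new_codon[o - cs + 1L] <- prop
            syn <- gc_tab[[paste(codon, collapse = "")]] ==
              gc_tab[[paste(new_codon, collapse = "")]]
            if (!syn && stats::runif(1L) >= config$f) next  # rejected
            type <- if (syn) "synonymous" else "nonsynonymous"
          }
          st$blocks[[b]][o] <- prop
          n_acc <- n_acc + 1L
          ev_block[n_acc] <- b; ev_off[n_acc] <- o
          ev_from[n_acc] <- cur; ev_to[n_acc] <- prop
          ev_type[n_acc] <- type; ev_child[n_acc] <- hit[ii]
        }
      }
      if (n_acc > 0L) {
        idx <- seq_len(n_acc)
        sub_log[[length(sub_log) + 1L]] <- tibble::tibble(
          branch = branch, block = ev_block[idx], offset = ev_off[idx],
          from = ev_from[idx], to = ev_to[idx], type = ev_type[idx],
          parent_pos = pos_of(ev_block[idx], ev_off[idx], parent_arr,
                              parent_strand, block_len),
          child_pos = ev_child[idx])
      }
    }
    states[[child]] <- st
  }

  ## --- outputs
  tips <- ord$tree$tip.label
  leaf_genomes <- stats::setNames(purrr::map_chr(seq_along(tips), function(i) {
    st <- states[[i]]
    paste(purrr::map_chr(seq_len(n_blocks), function(s) {
      b <- st$arr[s]
      chars <- st$blocks[[b]]
      if (st$strand[s] == "-") chars <- rev(unname(COMP[chars]))
      paste(chars, collapse = "")
    }), collapse = "")
  }), tips)

  blocks <- purrr::map(seq_len(n_blocks), function(b) {
    seqs <- character(); starts <- integer(); ends <- integer()
    strands <- character()
    for (i in seq_along(tips)) {
      st <- states[[i]]
      slot <- match(b, st$arr)
      G <- (slot - 1L) * block_len + 1L
      seqs[tips[i]] <- paste(st$blocks[[b]], collapse = "")
      starts[tips[i]] <- G
      ends[tips[i]] <- G + block_len - 1L
      strands[tips[i]] <- st$strand[slot]
    }
    aligned_block(paste0("block_", b), seqs, starts, ends, strands)
  })
  names(blocks) <- paste0("block_", seq_len(n_blocks))

  annotations <- dplyr::bind_rows(purrr::map(seq_along(tips), function(i) {
    st <- states[[i]]
    slot <- match(genes$block, st$arr)
    G <- (slot - 1L) * block_len + 1L
    plus <- st$strand[slot] == "+"
    tibble::tibble(
      taxon = tips[i],
      gene_id = paste0("g", genes$gene),
      start = ifelse(plus, G + genes$local_start - 1L,
                     G + block_len - genes$local_end),
      end = ifelse(plus, G + genes$local_end - 1L,
                   G + block_len - genes$local_start),
      strand = ifelse(plus, "+", "-"),
      frame = 0L)
  }))

  structure(list(
    config = config, tree = ord$tree, replicon = rep, gradient = g,
    blocks = blocks, annotations = annotations,
    leaf_genomes = leaf_genomes,
    truth = list(
      substitutions = if (length(sub_log)) dplyr::bind_rows(sub_log) else
        tibble::tibble(branch = character(), block = integer(),
                       offset = integer(), from = character(),
                       to = character(), type = character(),
                       parent_pos = integer(), child_pos = integer()),
      rearrangements = if (length(re_log)) dplyr::bind_rows(re_log) else
        tibble::tibble(branch = character(), block = integer(),
                       dest_slot = integer(), inverted = logical())),
    genes = genes, block_len = block_len, root_blocks = root_blocks,
    arrangements = purrr::map(states, ~ list(arr = .x$arr,
                                             strand = .x$strand)),
    clades = clades, ord = ord),
    class = "genome_simulation")
}

#' @export
print.genome_simulation <- function(x, ...) {
  cat(sprintf(paste0("<genome_simulation> seed %d: %d taxa, %d bp, ",
                     "%d blocks, %d substitutions, %d rearrangements\n"),
              x$config$seed, length(x$leaf_genomes), x$config$L,
              x$config$n_blocks, nrow(x$truth$substitutions),
              nrow(x$truth$rearrangements)))
  invisible(x)
}

#' Replay the truth log against the root genome
#'
#' Deterministically reapplies the logged rearrangements and substitutions
#' branch by branch to the root genome and checks that every leaf genome is
#' reproduced byte-exactly (and that every substitution's `from` base
#' matches the state it is applied to).  Any mismatch raises an integrity
#' error.
#'
#' @param sim A `genome_simulation`.
#' @return Named character vector of reconstructed leaf genomes, invisibly.
#' @export
replay_truth <- function(sim) {
  ord <- sim$ord
  n_blocks <- sim$config$n_blocks
  block_len <- sim$block_len
  states <- vector("list", ord$n_node)
  states[[ord$root]] <- list(blocks = sim$root_blocks,
                             arr = seq_len(n_blocks),
                             strand = rep("+", n_blocks))
  subs <- sim$truth$substitutions
  res <- sim$truth$rearrangements
  for (e in rev(seq_len(nrow(ord$edge)))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    st <- states[[parent]]
    branch <- sim$clades[child]
    rr <- res[res$branch == branch, , drop = FALSE]
    for (k in seq_len(nrow(rr))) {
      i <- match(rr$block[k], st$arr)
      moved <- st$arr[i]; moved_s <- st$strand[i]
      if (rr$inverted[k]) moved_s <- if (moved_s == "+") "-" else "+"
      st$arr <- append(st$arr[-i], moved, after = rr$dest_slot[k] - 1L)
      st$strand <- append(st$strand[-i], moved_s,
                          after = rr$dest_slot[k] - 1L)
    }
    ss <- subs[subs$branch == branch, , drop = FALSE]
    for (k in seq_len(nrow(ss))) {
      b <- ss$block[k]; o <- ss$offset[k]
      if (st$blocks[[b]][o] != ss$from[k]) {
        stop("truth log mismatch on branch ", branch, " at block ", b,
             " offset ", o, ": expected ", ss$from[k], ", found ",
             st$blocks[[b]][o], call. = FALSE)
      }
      st$blocks[[b]][o] <- ss$to[k]
    }
    states[[child]] <- st
  }
  tips <- ord$tree$tip.label
  out <- stats::setNames(purrr::map_chr(seq_along(tips), function(i) {
    st <- states[[i]]
    paste(purrr::map_chr(seq_len(n_blocks), function(s) {
      b <- st$arr[s]
      chars <- st$blocks[[b]]
      if (st$strand[s] == "-") chars <- rev(unname(COMP[chars]))
      paste(chars, collapse = "")
    }), collapse = "")
  }), tips)
  if (!identical(out, sim$leaf_genomes)) {
    stop("replayed leaf genomes differ from the simulated ones",
         call. = FALSE)
  }
  invisible(out)
}

#' Write a simulation to disk in standard formats
#'
#' Emits leaf genomes (multi-FASTA), annotations (TSV), the tree (Newick),
#' the block alignment (XMFA) and the truth logs (TSV).  Every file carries
#' the seed in a header comment where the format allows.
#'
#' @param sim A `genome_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- paste("seed:", sim$config$seed)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$leaf_genomes),
                              file.path(dir, "genomes.fasta"))
  tsv <- function(x, file) {
    con <- file(file.path(dir, file), "w")
    writeLines(paste("#", seed_line), con)
    utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  tsv(sim$annotations, "annotations.tsv")
  tsv(sim$truth$substitutions, "truth_substitutions.tsv")
  tsv(sim$truth$rearrangements, "truth_rearrangements.tsv")
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  write_xmfa(sim$blocks, file.path(dir, "blocks.xmfa"), comment = seed_line)
  invisible(dir)
}
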