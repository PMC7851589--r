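# Shared fixtures built in code.

# The 100-bp schematic replicon: origin at 20, terminus at 60.
toy_replicon <- function() {
  replicon("toy", length = 100, topology = "circular",
           origin = 20, terminus = 60)
}

# Three-taxon worked example: taxa a and b carry a 3-bp homologous segment
# at genomic positions 1-3 (ending in C), taxon c carries it at 7-9 ending
# in A; topology ((a,b),c).
three_taxon_fixture <- function() {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.2);")
  block <- aligned_block(
    "blk",
    seqs = c(a = "TTC", b = "TTC", c = "TTA"),
    start = c(a = 1, b = 1, c = 7),
    end = c(a = 3, b = 3, c = 9),
    strand = c(a = "+", b = "+", c = "+"))
  segment <- gene_segment("blk.seg1", "blk", block$seqs, block$pos_map,
                          codon_pos = 1:3, gene_id = "g1")
  list(tree = tree, block = block, segment = segment)
}

# brute-force distance-from-origin oracle: walk the circle step by step
# along the replichore containing p
walk_distance <- function(p, rep) {
  L <- rep$length
  step_right <- function(x) (x %% L) + 1L
  step_left <- function(x) ((x - 2L) %% L) + 1L
  # which replichore: walk right from origin to terminus, collecting arc
  x <- rep$origin
  right_arc <- x
  while (x != rep$terminus[1]) {
    x <- step_right(x)
    right_arc <- c(right_arc, x)
  }
  if (p %in% right_arc) {
    d <- 0L; x <- rep$origin
    while (x != p) {
      x <- step_right(x); d <- d + 1L
    }
    list(distance = d, replichore = "right")
  } else {
    d <- 0L; x <- rep$origin
    while (x != p) {
      x <- step_left(x); d <- d + 1L
    }
    list(distance = d, replichore = "left")
  }
}

# enumerate all rooted binary tree topologies (as phylo, branch lengths 1)
# on the given tip labels, by recursive leaf insertion into every edge
all_rooted_trees <- function(tips) {
  if (length(tips) == 1L) return(list(tips[1]))
  if (length(tips) == 2L) {
    return(list(sprintf("(%s,%s)", tips[1], tips[2])))
  }
  smaller <- all_rooted_trees(tips[-length(tips)])
  new <- tips[length(tips)]
  out <- list()
  insert_everywhere <- function(s, leaf) {
    # string-based: every subtree (leaf or parenthesised group) can be
    # paired with the new leaf; enumerate by recursive descent
    res <- c(sprintf("(%s,%s)", s, leaf))
    if (startsWith(s, "(")) {
      parts <- split_top_level(s)
      for (i in seq_along(parts)) {
        for (sub in insert_everywhere(parts[[i]], leaf)) {
          tmp <- parts
          tmp[[i]] <- sub
          res <- c(res, sprintf("(%s)", paste(unlist(tmp), collapse = ",")))
        }
      }
    }
    res
  }
  for (s in smaller) out <- c(out, insert_everywhere(s, new))
  unique(unlist(out))
}

# split "(
#   a,(b,c)
# )" style newick fragments at top-level commas
split_top_level <- function(s) {
  inner <- substr(s, 2L, nchar(s) - 1L)
  chars <- strsplit(inner, "", fixed = TRUE)[[1]]
  depth <- 0L; cuts <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(chars))
  purrr::map2_chr(starts, ends, ~ paste(chars[.x:.y], collapse = ""))
}

newick_to_tree <- function(s) {
  tr <- ape::read.tree(text = paste0(s, ";"))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# brute-force minimum label-change count over all internal assignments
brute_min_changes <- function(tree, labels) {
  ord <- oriscan:::tree_postorder(tree)
  tips <- ord$tree$tip.label
  alph <- sort(unique(as.character(labels[tips])))
  n_tip <- length(tips)
  internals <- (n_tip + 1L):ord$n_node
  grids <- expand.grid(rep(list(alph), length(internals)),
                       stringsAsFactors = FALSE)
  assign_state <- function(nd, row) {
    if (nd <= n_tip) labels[[tips[nd]]] else row[[nd - n_tip]]
  }
  best <- Inf
  for (r in seq_len(nrow(grids))) {
    row <- grids[r, , drop = FALSE]
    ch <- 0L
    for (e in seq_len(nrow(ord$edge))) {
      if (assign_state(ord$edge[e, 1], row) !=
          assign_state(ord$edge[e, 2], row)) {
        ch <- ch + 1L
      }
    }
    best <- min(best, ch)
  }
  best
}

# change count implied by a position_reconstruction
implied_changes <- function(pr) {
  ord <- pr$ord
  names_all <- names(pr$labels)
  sum(purrr::map_int(seq_len(nrow(ord$edge)), function(e) {
    as.integer(pr$labels[[names_all[ord$edge[e, 1]]]] !=
                 pr$labels[[names_all[ord$edge[e, 2]]]])
  }))
}

# small simulation used by several module tests (fast)
small_sim <- function(seed = 11, ...) {
  simulate_genomes(sim_config(seed = seed, L = 60000L, n_blocks = 6L,
                              n_genes = 60L, tree_length = 0.06, ...))
}

# recovery of event positions against the simulator's per-node arrangement
# snapshots, restricted to events whose block kept its placement (slot and
# strand) across the event's branch; returns the exact-agreement fraction
# for the parent-side and child-side mappings
position_recovery <- function(sim, run) {
  ev <- run$events
  ev$block_i <- as.integer(sub("block_", "", ev$block))
  tx1 <- sim$tree$tip.label[1]
  seg_by_id <- stats::setNames(run$segments,
                               purrr::map_chr(run$segments, "id"))
  ev$offset <- purrr::map2_int(ev$segment, ev$column, function(sid, col) {
    s <- seg_by_id[[sid]]
    b <- sim$blocks[[s$block_id]]
    pos <- s$pos_map[[tx1]][col]
    if (b$strand[[tx1]] == "+") {
      pos - b$start[[tx1]] + 1L
    } else {
      b$end[[tx1]] - pos + 1L
    }
  })
  ord <- sim$ord
  clades <- sim$clades
  bl <- sim$block_len
  placements <- dplyr::bind_rows(purrr::map(
    seq_len(nrow(ord$edge)), function(e) {
      pa <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
      pa_arr <- sim$arrangements[[pa]]; ch_arr <- sim$arrangements[[ch]]
      tibble::tibble(
        branch = clades[ch], block_i = pa_arr$arr,
        p_start = (seq_along(pa_arr$arr) - 1L) * bl + 1L,
        p_strand = pa_arr$strand,
        c_start = (match(pa_arr$arr, ch_arr$arr) - 1L) * bl + 1L,
        c_strand = ch_arr$strand[match(pa_arr$arr, ch_arr$arr)])
    }))
  ev <- dplyr::left_join(ev, placements, by = c("branch", "block_i"))
  un <- ev$p_start == ev$c_start & ev$p_strand == ev$c_strand
  true_parent <- ifelse(ev$p_strand == "+", ev$p_start + ev$offset - 1L,
                        ev$p_start + bl - ev$offset)
  true_child <- ifelse(ev$c_strand == "+", ev$c_start + ev$offset - 1L,
                       ev$c_start + bl - ev$offset)
  c(parent = mean(ev$parent_pos[un] == true_parent[un]),
    child = mean(ev$child_pos[un] == true_child[un]))
}
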