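# independent oracle: joint enumeration over all internal-node assignments
# under HKY gives the exact marginal posterior at any node
brute_marginal <- function(tree, tipstates, kappa, freqs) {
  ord <- oriscan:::tree_postorder(tree)
  Q <- oriscan:::hky_rate_matrix(kappa, freqs)
  P <- oriscan:::transition_probs(Q, ord$lengths)
  n_tip <- ord$n_tip
  internals <- (n_tip + 1L):ord$n_node
  grids <- expand.grid(rep(list(1:4), length(internals)))
  post <- matrix(0, length(internals), 4)
  for (r in seq_len(nrow(grids))) {
    states <- c(match(tipstates, oriscan:::BASES), as.integer(grids[r, ]))
    pr <- freqs[states[ord$root]]
    for (e in seq_len(nrow(ord$edge))) {
      pr <- pr * P[[e]][states[ord$edge[e, 1]], states[ord$edge[e, 2]]]
    }
    for (k in seq_along(internals)) {
      st <- states[internals[k]]
      post[k, st] <- post[k, st] + pr
    }
  }
  sweep(post, 1, rowSums(post), "/")
}

test_that("invariant columns reconstruct with posterior one", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.2);")
  seqs <- c(a = "CCCC", b = "CCCC", c = "CCCC")
  rec <- reconstruct_nucleotides(seqs, tree, kappa = 2)
  expect_true(all(rec$states == "C"))
  # empirical frequencies put most mass on C, so competing states retain a
  # little posterior; with uniform frequencies the call is near-certain
  expect_true(all(rec$posterior > 0.95))
  rec_u <- reconstruct_nucleotides(seqs, tree, kappa = 2,
                                   freqs = rep(0.25, 4))
  expect_true(all(rec_u$posterior > 0.99))
  expect_false(any(rec$tie))
})

test_that("the three-taxon worked example reconstructs C at the ancestor", {
  fx <- three_taxon_fixture()
  rec <- reconstruct_nucleotides(fx$segment, fx$tree, kappa = 2)
  ord <- rec$ord
  anc_ab <- which(purrr::map_lgl(
    (ord$n_tip + 1):ord$n_node,
    function(nd) {
      tips <- oriscan:::node_clade_ids(ord)[nd]
      tips == "a|b"
    })) + ord$n_tip
  expect_equal(unname(rec$states[paste0("node", anc_ab), 3]), "C")
  root <- ord$root
  expect_equal(unname(rec$states[paste0("node", root), 3]), "C")
})

test_that("marginal posteriors match joint enumeration on small trees", {
  tree <- ape::read.tree(text = "((a:0.15,b:0.2):0.1,(c:0.3,d:0.05):0.2);")
  freqs <- c(0.3, 0.2, 0.3, 0.2)
  set.seed(5)
  for (i in 1:4) {
    col <- sample(c("A", "C", "G", "T"), 4, replace = TRUE)
    seqs <- stats::setNames(col, c("a", "b", "c", "d"))
    rec <- reconstruct_nucleotides(
      stats::setNames(as.character(seqs), names(seqs)), tree,
      kappa = 3, freqs = freqs)
    tipstates <- as.character(seqs[rec$ord$tree$tip.label])
    oracle <- brute_marginal(tree, tipstates, 3, freqs)
    for (k in seq_len(nrow(rec$states))) {
      got <- unname(rec$posterior[k, 1])
      best <- oriscan:::BASES[which.max(oracle[k, ])]
      expect_equal(got, max(oracle[k, ]), tolerance = 1e-7)
      expect_equal(unname(rec$states[k, 1]), best)
    }
  }
})

test_that("balanced conflicts produce a flagged deterministic tie", {
  tree <- ape::read.tree(
    text = "((a:0.3,b:0.3):0.001,(c:0.3,d:0.3):0.001);")
  seqs <- c(a = "C", b = "C", c = "A", d = "A")
  rec <- reconstruct_nucleotides(seqs, tree, kappa = 1,
                                 freqs = rep(0.25, 4))
  root_row <- paste0("node", rec$ord$root)
  expect_true(rec$tie[root_row, 1])
  expect_lt(abs(rec$posterior[root_row, 1] - 0.5), 0.02)
  expect_equal(unname(rec$states[root_row, 1]), "A")  # A < C tie-break
})

test_that("position parsimony matches brute-force minimum change counts", {
  set.seed(9)
  trees <- all_rooted_trees(letters[1:5])
  sample_trees <- sample(trees, 12)
  for (nw in sample_trees) {
    tree <- newick_to_tree(nw)
    for (i in 1:4) {
      labels <- stats::setNames(
        as.character(sample(1:3, 5, replace = TRUE)), letters[1:5])
      pr <- reconstruct_positions(tree, labels)
      expect_equal(implied_changes(pr), brute_min_changes(tree, labels))
      expect_equal(pr$changes, implied_changes(pr))
    }
  }
})

test_that("shared positions and likelihood ties resolve as documented", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.2);")
  # all leaves at one position: zero changes everywhere
  pr0 <- reconstruct_positions(tree, c(a = "5+", b = "5+", c = "5+"))
  expect_equal(pr0$changes, 0)
  expect_true(all(pr0$labels == "5+"))
  # the worked example: the a/b ancestor takes the shared label, and the
  # root tie (1+ vs 7+) breaks toward the better-supported label
  pr <- reconstruct_positions(tree, c(a = "1+", b = "1+", c = "7+"))
  expect_equal(pr$changes, 1)
  expect_equal(unname(pr$labels[["node5"]]), "1+")
  expect_equal(unname(pr$labels[[paste0("node", pr$ord$root)]]), "1+")
})

test_that("the worked example yields exactly one located substitution", {
  fx <- three_taxon_fixture()
  rec <- reconstruct_nucleotides(fx$segment, fx$tree, kappa = 2)
  labels <- stats::setNames(
    purrr::map_chr(c("a", "b", "c"),
                   ~ oriscan:::block_label(fx$block, .x)),
    c("a", "b", "c"))
  pr <- reconstruct_positions(fx$tree, labels)
  label_maps <- list(`1+` = fx$segment$pos_map$a,
                     `7+` = fx$segment$pos_map$c)
  ev <- extract_substitutions(fx$segment, rec, pr, label_maps)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$branch, "c")
  expect_equal(ev$parent_base, "C")
  expect_equal(ev$child_base, "A")
  expect_equal(ev$parent_pos, 3)
  expect_equal(ev$child_pos, 9)
  # an invariant column yields no events
  expect_equal(sum(ev$column != 3), 0)
})

test_that("event tables are conserved under leaf relabelling", {
  sim <- small_sim(seed = 21)
  f <- filter_blocks(sim$blocks, sim$annotations)
  seg <- f$segments[[1]]
  tree <- sim$tree
  rec <- oriscan:::reconstruct_all(list(seg), sim$blocks, tree, kappa = 3)
  # relabel: swap two tips everywhere
  swap <- function(x) {
    x[x == "t1"] <- "zz"; x[x == "t2"] <- "t1"; x[x == "zz"] <- "t2"
    x
  }
  tree2 <- tree
  tree2$tip.label <- swap(tree2$tip.label)
  blk <- sim$blocks[[seg$block_id]]
  names(blk$seqs) <- swap(names(blk$seqs))
  names(blk$start) <- swap(names(blk$start))
  names(blk$end) <- swap(names(blk$end))
  names(blk$strand) <- swap(names(blk$strand))
  names(blk$pos_map) <- swap(names(blk$pos_map))
  blk$taxa <- swap(blk$taxa)
  seg2 <- seg
  names(seg2$seqs) <- swap(names(seg2$seqs))
  names(seg2$pos_map) <- swap(names(seg2$pos_map))
  seg2$taxa <- swap(seg2$taxa)
  blocks2 <- sim$blocks
  blocks2[[seg$block_id]] <- blk
  rec2 <- oriscan:::reconstruct_all(list(seg2), blocks2, tree2, kappa = 3)
  expect_equal(nrow(rec$events), nrow(rec2$events))
})
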