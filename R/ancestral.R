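BASES <- c("A", "C", "G", "T")

# HKY85 rate matrix, scaled to one expected substitution per site per unit
# branch length.  Transitions (A<->G, C<->T) are weighted by kappa.
hky_rate_matrix <- function(kappa, freqs) {
  stopifnot(length(freqs) == 4L, all(freqs > 0))
  freqs <- freqs / sum(freqs)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      ts <- (BASES[i] %in% c("A", "G") && BASES[j] %in% c("A", "G")) ||
        (BASES[i] %in% c("C", "T") && BASES[j] %in% c("C", "T"))
      Q[i, j] <- freqs[j] * if (ts) kappa else 1
    }
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(freqs * -diag(Q))
}

# transition probability matrices for a set of branch lengths (eigen
# decomposition done once; HKY is reversible so eigenvalues are real)
transition_probs <- function(Q, lengths) {
  eig <- eigen(Q)
  V <- eig$vectors; Vi <- solve(V)
  purrr::map(lengths, function(t) {
    P <- V %*% diag(exp(eig$values * t)) %*% Vi
    P[P < 0] <- 0
    P / rowSums(P)
    })
}

tree_postorder <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  list(tree = tree, n_tip = n_tip, n_node = n_tip + tree$Nnode,
       root = n_tip + 1L, edge = tree$edge,
       lengths = tree$edge.length)
}

# conditional ("inside") likelihood arrays for every node; tips are delta
# functions on their observed base
prune_likelihoods <- function(tipstates, ord, P_edge) {
  ncol_ <- ncol(tipstates)
  L <- vector("list", ord$n_node)
  for (i in seq_len(ord$n_tip)) {
    arr <- matrix(0, 4, ncol_, dimnames = list(BASES, NULL))
    arr[cbind(match(tipstates[i, ], BASES), seq_len(ncol_))] <- 1
    L[[i]] <- arr
  }
  for (nd in (ord$n_tip + 1L):ord$n_node) L[[nd]] <- matrix(1, 4, ncol_)
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    L[[parent]] <- L[[parent]] * (P_edge[[e]] %*% L[[child]])
  }
  L
}

hky_loglik <- function(tipstates, ord, kappa, freqs) {
  Q <- hky_rate_matrix(kappa, freqs)
  P_edge <- transition_probs(Q, ord$lengths)
  L <- prune_likelihoods(tipstates, ord, P_edge)
  site_lik <- as.numeric(freqs %*% L[[ord$root]])
  sum(log(pmax(site_lik, 1e-300)))
}

#' Reconstruct ancestral nucleotides by marginal maximum likelihood
#'
#' Runs Felsenstein pruning under the HKY85 substitution model on a gap-free
#' segment and reports, for every internal node and alignment column, the
#' marginal posterior distribution over bases and the maximum-posterior
#' state.  Base frequencies are taken from the segment; the
#' transition/transversion ratio kappa is fitted by one-dimensional
#' likelihood maximisation unless supplied.  Ties in the posterior are broken
#' deterministically in the fixed base order A < C < G < T and flagged.
#'
#' @param segment A [gene_segment()] (or any named character vector of equal
#'   length gap-free sequences).
#' @param tree Rooted `phylo` tree with branch lengths; tip labels must match
#'   the segment's taxa.
#' @param kappa Transition/transversion rate ratio; `NULL` (default) fits it
#'   in `[0.2, 100]` by [stats::optimize()].
#' @param freqs Base frequencies (A, C, G, T); default empirical with a
#'   pseudocount.
#' @return List of class `nuc_reconstruction`: `states` (matrix, internal
#'   nodes x columns), `posterior` (max posterior per state), `tie` (logical
#'   matrix), `kappa`, `loglik`, `tree` (postorder), plus the tip state
#'   matrix.
#' @export
reconstruct_nucleotides <- function(segment, tree, kappa = NULL,
                                    freqs = NULL) {
  seqs <- if (inherits(segment, "gene_segment")) segment$seqs else segment
  if (!all(tree$tip.label %in% names(seqs))) {
    stop("tree tips missing from segment: ",
         paste(setdiff(tree$tip.label, names(seqs)), collapse = ", "),
         call. = FALSE)
  }
  ord <- tree_postorder(tree)
  tipstates <- do.call(rbind, strsplit(seqs[ord$tree$tip.label], "",
                                       fixed = TRUE))
  if (ncol(tipstates) == 0L) {
    return(structure(list(states = NULL, posterior = NULL, tie = NULL,
                          kappa = NA_real_, loglik = NA_real_, ord = ord,
                          tipstates = tipstates),
                     class = "nuc_reconstruction"))
  }
  if (is.null(freqs)) {
    counts <- table(factor(tipstates, levels = BASES))
    freqs <- (as.numeric(counts) + 1) / (sum(counts) + 4)
  }
  if (is.null(kappa)) {
    kappa <- stats::optimize(function(k) hky_loglik(tipstates, ord, k, freqs),
                             c(0.2, 100), maximum = TRUE, tol = 1e-2)$maximum
  }
  Q <- hky_rate_matrix(kappa, freqs)
  P_edge <- transition_probs(Q, ord$lengths)
  L <- prune_likelihoods(tipstates, ord, P_edge)
  ncol_ <- ncol(tipstates)
  # outside pass: O[[v]] column c is the likelihood of everything except the
  # subtree of v, as a function of v's state (includes the root prior)
  O <- vector("list", ord$n_node)
  O[[ord$root]] <- matrix(freqs, 4, ncol_)
  for (e in rev(seq_len(nrow(ord$edge)))) {   # preorder
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    contrib <- O[[parent]]
    sibs <- ord$edge[ord$edge[, 1L] == parent, 2L]
    for (s in setdiff(sibs, child)) {
      es <- which(ord$edge[, 2L] == s)
      contrib <- contrib * (P_edge[[es]] %*% L[[s]])
    }
    O[[child]] <- crossprod(P_edge[[e]], contrib)
  }
  internals <- (ord$n_tip + 1L):ord$n_node
  states <- matrix(NA_character_, length(internals), ncol_,
                   dimnames = list(paste0("node", internals), NULL))
  postmax <- matrix(NA_real_, length(internals), ncol_,
                    dimnames = list(paste0("node", internals), NULL))
  tie <- matrix(FALSE, length(internals), ncol_,
                dimnames = list(paste0("node", internals), NULL))
  for (k in seq_along(internals)) {
    nd <- internals[k]
    post <- L[[nd]] * O[[nd]]
    tot <- colSums(post)
    post <- sweep(post, 2L, pmax(tot, 1e-300), "/")
    # argmax with A<C<G<T tie-break; posteriors equal to within 1e-9 are
    # treated as tied so floating-point noise cannot decide a state
    post <- round(post, 9L)
    best <- max.col(t(post), ties.method = "first")
    idx <- cbind(best, seq_len(ncol_))
    states[k, ] <- BASES[best]
    postmax[k, ] <- post[idx]
    post[idx] <- -Inf
    second <- post[cbind(max.col(t(post), ties.method = "first"), seq_len(ncol_))]
    tie[k, ] <- (postmax[k, ] - second) < 1e-9
  }
  site_lik <- as.numeric(freqs %*% L[[ord$root]])
  if (!all(is.finite(site_lik)) || any(site_lik <= 0)) {
    stop("non-finite likelihood in segment ",
         if (inherits(segment, "gene_segment")) segment$id else "",
         call. = FALSE)
  }
  structure(list(states = states, posterior = postmax, tie = tie,
                 kappa = kappa, loglik = sum(log(site_lik)), ord = ord,
                 tipstates = tipstates),
            class = "nuc_reconstruction")
}

#' Reconstruct ancestral genomic positions by parsimony with ML tie-breaking
#'
#' Treats each leaf's block position label (genomic start and strand) as a
#' categorical character and assigns internal-node labels with the minimum
#' number of label changes (Fitch small parsimony).  Where the parsimony
#' solution is ambiguous the tie is broken by marginal likelihood under a
#' simple rearrangement model in which a label change on a branch of length
#' `t` has probability `1 - exp(-rho * t)`, spread uniformly over the other
#' labels; any residual tie falls to the lexicographically smallest label.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param labels Named character vector: position label per tip.
#' @param rho Rearrangement rate for the tie-break model; default = number of
#'   Fitch changes divided by total tree length (floored at 1e-8).
#' @return List of class `position_reconstruction`: `labels` (character
#'   vector over all nodes, tips first in `tree$tip.label` order of the
#'   postorder tree), `changes` (minimum change count), `rho`, `ord`.
#' @export
reconstruct_positions <- function(tree, labels, rho = NULL) {
  ord <- tree_postorder(tree)
  tips <- ord$tree$tip.label
  if (!all(tips %in% names(labels))) {
    stop("labels missing for tips: ",
         paste(setdiff(tips, names(labels)), collapse = ", "), call. = FALSE)
  }
  alph <- sort(unique(as.character(labels[tips])))
  k <- length(alph)
  n_node <- ord$n_node
  sets <- matrix(FALSE, n_node, k, dimnames = list(NULL, alph))
  for (i in seq_along(tips)) sets[i, labels[[tips[i]]]] <- TRUE
  changes <- 0L
  # Fitch bottom-up over possibly multifurcating nodes: intersect children
  # sets pairwise, union on empty intersection (one change each time)
  kids <- split(ord$edge[, 2L], ord$edge[, 1L])
  node_order <- unique(ord$edge[, 1L])   # postorder guarantees children first
  for (nd in node_order) {
    cur <- NULL
    for (ch in kids[[as.character(nd)]]) {
      if (is.null(cur)) {
        cur <- sets[ch, ]
      } else {
        inter <- cur & sets[ch, ]
        if (any(inter)) cur <- inter
        else {
          cur <- cur | sets[ch, ]
          changes <- changes + 1L
        }
      }
    }
    sets[nd, ] <- cur
  }
  if (is.null(rho)) {
    total_len <- sum(ord$lengths)
    rho <- max(changes / max(total_len, 1e-12), 1e-8)
  }
  # marginal posteriors under the k-state rearrangement model, used only to
  # break ties among Fitch-optimal labels
  post <- position_posteriors(ord, sets[seq_along(tips), , drop = FALSE],
                              rho, k)
  assign <- character(n_node)
  assign[seq_along(tips)] <- as.character(labels[tips])
  pick <- function(nd, allowed) {
    cand <- which(allowed)
    if (length(cand) == 1L) return(alph[cand])
    alph[cand[which.max(post[nd, cand])]]   # which.max: first index on ties
  }
  root_set <- sets[ord$root, ]
  assign[ord$root] <- pick(ord$root, root_set)
  for (e in rev(seq_len(nrow(ord$edge)))) {  # preorder
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    if (child <= length(tips)) next
    if (sets[child, assign[parent]]) {
      assign[child] <- assign[parent]
    } else {
      assign[child] <- pick(child, sets[child, ])
    }
  }
  structure(list(labels = stats::setNames(
    assign, c(tips, paste0("node", (length(tips) + 1L):n_node))),
    changes = changes, rho = rho, ord = ord, alphabet = alph),
    class = "position_reconstruction")
}

# pruning + outside pass for the k-label rearrangement Markov model with
# uniform root prior; returns node x label posterior matrix
position_posteriors <- function(ord, tipsets, rho, k) {
  if (k == 1L) return(matrix(1, ord$n_node, 1L))
  P_edge <- purrr::map(ord$lengths, function(t) {
    stay <- exp(-rho * t)
    matrix((1 - stay) / (k - 1), k, k) + diag(stay - (1 - stay) / (k - 1), k)
  })
  L <- vector("list", ord$n_node)
  for (i in seq_len(nrow(tipsets))) L[[i]] <- as.numeric(tipsets[i, ])
  for (nd in (nrow(tipsets) + 1L):ord$n_node) L[[nd]] <- rep(1, k)
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    L[[parent]] <- L[[parent]] * as.numeric(P_edge[[e]] %*% L[[child]])
  }
  O <- vector("list", ord$n_node)
  O[[ord$root]] <- rep(1 / k, k)
  for (e in rev(seq_len(nrow(ord$edge)))) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    contrib <- O[[parent]]
    sibs <- ord$edge[ord$edge[, 1L] == parent, 2L]
    for (s in setdiff(sibs, child)) {
      es <- which(ord$edge[, 2L] == s)
      contrib <- contrib * as.numeric(P_edge[[es]] %*% L[[s]])
    }
    O[[child]] <- as.numeric(crossprod(P_edge[[e]], contrib))
  }
  post <- matrix(0, ord$n_node, k)
  for (nd in seq_len(ord$n_node)) {
    p <- L[[nd]] * O[[nd]]
    post[nd, ] <- p / max(sum(p), 1e-300)
  }
  post
}

#' Extract per-branch substitution events with ancestral genomic positions
#'
#' Compares reconstructed (or observed, at tips) states across every branch
#' of the tree and emits one event per (branch, column) where parent and
#' child states differ.  Each event carries the genomic position of the site
#' in the parent node's reconstructed block placement (the ancestral genomic
#' position, used for spatial mapping) and in the child's placement.
#' Multiple hits at one column on different branches yield multiple events.
#'
#' @param segment A [gene_segment()].
#' @param nuc A `nuc_reconstruction` for the segment.
#' @param pos A `position_reconstruction` for the segment's parent block.
#' @param label_maps Named list: for each position label, the integer vector
#'   of genomic positions for the segment's columns under that label
#'   (typically the position map of a leaf carrying the label).
#' @return Tibble with columns `branch` (child-node name; tip label for
#'   terminal branches), `segment`, `block`, `column`, `parent_base`,
#'   `child_base`, `parent_pos`, `child_pos`, `parent_tie`.
#' @export
extract_substitutions <- function(segment, nuc, pos, label_maps) {
  ord <- nuc$ord
  n_tip <- ord$n_tip
  tips <- ord$tree$tip.label
  ncol_ <- ncol(nuc$tipstates)
  if (is.null(ncol_) || ncol_ == 0L) return(empty_events())
  node_state <- function(nd) {
    if (nd <= n_tip) nuc$tipstates[nd, ] else nuc$states[nd - n_tip, ]
  }
  node_tie <- function(nd) {
    if (nd <= n_tip) rep(FALSE, ncol_) else nuc$tie[nd - n_tip, ]
  }
  node_name <- function(nd) if (nd <= n_tip) tips[nd] else paste0("node", nd)
  clades <- node_clade_ids(ord)
  seg_id <- segment$id
  blk_id <- segment$block_id
  out <- purrr::map(seq_len(nrow(ord$edge)), function(e) {
    parent <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    ps <- node_state(parent); cs <- node_state(child)
    diffc <- which(ps != cs)
    if (!length(diffc)) return(NULL)
    pmap <- label_maps[[pos$labels[[node_name(parent)]]]]
    cmap <- label_maps[[pos$labels[[node_name(child)]]]]
    tibble::tibble(
      branch = clades[child], segment = seg_id,
      block = blk_id, column = diffc,
      parent_base = ps[diffc], child_base = cs[diffc],
      parent_pos = pmap[diffc], child_pos = cmap[diffc],
      parent_tie = node_tie(parent)[diffc])
  })
  out <- dplyr::bind_rows(purrr::compact(out))
  if (!nrow(out)) empty_events() else out
}

empty_events <- function() {
  tibble::tibble(branch = character(), segment = character(),
                 block = character(), column = integer(),
                 parent_base = character(), child_base = character(),
                 parent_pos = integer(), child_pos = integer(),
                 parent_tie = logical())
}
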