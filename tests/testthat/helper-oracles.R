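# Independent oracles shared across test files.

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (tl in combinat_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], tl)
  }
  out
}

# exhaustive enumeration of all mutation paths between two codons,
# classifying each step with its own translation calls; paths through stop
# codons are excluded unless all are blocked
oracle_path_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  orders <- if (length(pos) == 1) list(pos) else combinat_perms(pos)
  score <- function(ord) {
    cur <- c1; s <- 0; n <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*" && nxt != c2) blocked <- TRUE
      if (gc[[cur]] == gc[[nxt]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    list(c(s, n), blocked)
  }
  scored <- lapply(orders, score)
  ok <- Filter(function(z) !z[[2]], scored)
  use <- if (length(ok)) ok else scored
  Reduce(`+`, lapply(use, `[[`, 1)) / length(use)
}

# oracle NG86 sites for one codon (synonymous fraction of all nine changes)
oracle_codon_sites <- function(cd) {
  gc <- Biostrings::GENETIC_CODE
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
      alt <- cd
      substr(alt, p, p) <- b
      if (gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
    }
  }
  s
}

# fully independent pairwise NG86 dN/dS on a two-sequence codon alignment
oracle_dn_ds_pair <- function(s1, s2) {
  gc <- Biostrings::GENETIC_CODE
  len <- nchar(s1)
  cd1 <- substring(s1, seq(1, len, 3), seq(3, len, 3))
  cd2 <- substring(s2, seq(1, len, 3), seq(3, len, 3))
  ok <- gc[cd1] != "*" & gc[cd2] != "*"
  cd1 <- cd1[ok]; cd2 <- cd2[ok]
  S <- (sum(vapply(cd1, oracle_codon_sites, 0)) +
          sum(vapply(cd2, oracle_codon_sites, 0))) / 2
  N <- 3 * length(cd1) - S
  sd_ <- 0; nd_ <- 0
  for (i in seq_along(cd1)) {
    cnt <- oracle_path_counts(cd1[i], cd2[i])
    sd_ <- sd_ + cnt[1]; nd_ <- nd_ + cnt[2]
  }
  pS <- sd_ / S; pN <- nd_ / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(dS = jc(pS), dN = jc(pN), pS = pS, pN = pN)
}

# vectorised brute-force minimum label-change count over every assignment
# of labels to internal nodes
brute_min_changes_vec <- function(tree, labels) {
  ord <- oriscan:::tree_postorder(tree)
  tips <- ord$tree$tip.label
  alph <- sort(unique(as.character(labels[tips])))
  n_tip <- length(tips)
  tip_int <- match(as.character(labels[tips]), alph)
  n_int <- ord$n_node - n_tip
  G <- as.matrix(expand.grid(rep(list(seq_along(alph)), n_int)))
  changes <- numeric(nrow(G))
  for (e in seq_len(nrow(ord$edge))) {
    u <- ord$edge[e, 1L]; v <- ord$edge[e, 2L]
    su <- if (u <= n_tip) tip_int[u] else G[, u - n_tip]
    sv <- if (v <= n_tip) tip_int[v] else G[, v - n_tip]
    changes <- changes + (su != sv)
  }
  min(changes)
}

# all set partitions of n items into at most kmax blocks, as restricted
# growth strings (rows = assignments)
rgs_partitions <- function(n, kmax) {
  out <- list()
  recurse <- function(prefix, m) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(min(m + 1L, kmax))) {
      recurse(c(prefix, v), max(m, v))
    }
  }
  recurse(integer(), 0L)
  do.call(rbind, out)
}
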