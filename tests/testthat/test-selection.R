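test_that("per-codon synonymous site counts match direct enumeration", {
  tab <- oriscan:::codon_site_table()
  gc <- Biostrings::GENETIC_CODE
  # spot checks against hand counts
  expect_equal(unname(tab["GCT"]), 1)      # 4-fold third position (Ala)
  expect_equal(unname(tab["AAA"]), 1 / 3)  # Lys: only AAG synonymous
  expect_equal(unname(tab["TGG"]), 0)      # Trp: nothing synonymous
  expect_true(is.na(tab["TAA"]))           # stop codons carry NA
  # full independent recount
  for (cd in sample(names(tab)[!is.na(tab)], 12)) {
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (gc[[alt]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
    expect_equal(unname(tab[cd]), s)
  }
})

test_that("codon difference counting agrees with path enumeration", {
  cases <- list(c("GCT", "GCC"), c("TTT", "TTA"), c("ATG", "ACG"),
                c("AAA", "AGC"), c("TTA", "CAT"), c("GGG", "CCC"),
                c("ATG", "CGT"))
  for (cs in cases) {
    got <- oriscan:::codon_diff_counts(cs[1], cs[2])
    want <- oracle_path_counts(cs[1], cs[2])
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 info = paste(cs, collapse = "->"))
  }
})

test_that("a single synonymous change gives dN = 0 and the JC-corrected dS", {
  rec <- compute_dn_ds(c(a = "AAAGCTTTT", b = "AAAGCCTTT"))
  expect_equal(rec$dN, 0)
  # S = 1/3 (AAA) + 1 (GCT/GCC) + 1/3 (TTT) = 5/3; pS = 1/(5/3) = 0.6
  expect_equal(rec$dS, -0.75 * log(1 - 4 * 0.6 / 3), tolerance = 1e-12)
  expect_equal(rec$omega, 0)
  # identical sequences: both rates zero, omega undefined
  rec0 <- compute_dn_ds(c(a = "AAAGCTTTT", b = "AAAGCTTTT"))
  expect_equal(rec0$dN, 0)
  expect_equal(rec0$dS, 0)
  expect_true(is.na(rec0$omega))
})

test_that("multi-taxon records average over all unordered pairs", {
  # a and b identical; c differs from both by one nonsynonymous change
  seqs <- c(a = "AAAGCTTTT", b = "AAAGCTTTT", c = "AAAACTTTT")
  rec <- compute_dn_ds(seqs)
  one <- compute_dn_ds(seqs[c("a", "c")])
  expect_equal(rec$n_pairs, 3)
  expect_equal(rec$dN, 2 * one$dN / 3, tolerance = 1e-12)
  expect_equal(rec$dS, 0)
})

test_that("saturated pairs are flagged and excluded", {
  # every codon differs at all three positions: proportions blow past 3/4
  rec <- compute_dn_ds(c(a = strrep("AAA", 10), b = strrep("CGT", 10)))
  expect_true(rec$saturated)
  expect_true(is.na(rec$dN))
})

test_that("omega outliers drag their dN and dS out of all summaries", {
  records <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    tibble::tibble(segment = paste0("s", i), gene_id = NA_character_,
                   length_bp = 300L, n_codons = 100L, n_pairs = 1L,
                   n_saturated = 0L, dN = 0.01, dS = 0.2,
                   omega = c(0.01, 0.02, 0.03, 0.04, 0.05, 9)[i],
                   saturated = FALSE, distance = i * 1000)
  }))
  flagged <- omega_outlier_filter(records)
  expect_equal(flagged$outlier, c(rep(FALSE, 5), TRUE))
  avg <- weighted_genome_average(flagged)
  expect_equal(avg$n_segments, 5)
  # undefined omega is never an outlier
  records$omega[2] <- NA_real_
  records$dS[2] <- 0
  flagged2 <- omega_outlier_filter(records)
  expect_false(flagged2$outlier[2])
  expect_false(any(omega_outlier_filter(
    dplyr::mutate(records, omega = 0.5))$outlier))
})

test_that("weighted averages follow the stated zero rules", {
  recs <- tibble::tibble(
    segment = c("s1", "s2", "s3"), gene_id = NA, length_bp = c(300, 100, 200),
    n_codons = c(100, 33, 66), n_pairs = 1, n_saturated = 0,
    dN = c(0.02, 0.06, 0.01), dS = c(0.1, 0.2, 0), omega = c(0.2, 0.3, NA),
    saturated = FALSE, distance = c(1, 2, 3) * 1e4, outlier = FALSE)
  avg <- weighted_genome_average(recs[1:2, ])
  expect_equal(avg$dN_bar, (0.02 * 300 + 0.06 * 100) / 400)
  # the dS = 0 record still feeds dN_bar/dS_bar but not omega_bar
  avg3 <- weighted_genome_average(recs)
  expect_equal(avg3$n_segments, 3)
  expect_equal(avg3$n_omega, 2)
  expect_equal(avg3$omega_bar, (0.2 * 300 + 0.3 * 100) / 400)
  one <- weighted_genome_average(recs[1, ])
  expect_equal(one$dN_bar, 0.02)
  expect_equal(one$omega_bar, 0.2)
  # doubling all lengths leaves the means unchanged
  doubled <- dplyr::mutate(recs, length_bp = length_bp * 2)
  expect_equal(weighted_genome_average(doubled)$dN_bar, avg3$dN_bar)
})

test_that("selection regressions recover a synthetic dS gradient", {
  set.seed(8)
  recs <- dplyr::bind_rows(purrr::map(1:40, function(i) {
    d <- i * 5000
    tibble::tibble(segment = paste0("s", i), gene_id = NA,
                   length_bp = 300L, n_codons = 100L, n_pairs = 1L,
                   n_saturated = 0L,
                   dN = 0.01 + stats::rnorm(1, 0, 0.001),
                   dS = 0.05 + 4e-7 * d + stats::rnorm(1, 0, 0.002),
                   omega = 0.2, saturated = FALSE, distance = d)
  }))
  recs <- omega_outlier_filter(recs)
  fits <- suppressWarnings(fit_selection_regressions(recs, widths = NULL))
  ds_fit <- fits[fits$response == "dS" & is.na(fits$window), ]
  expect_gt(ds_fit$estimate, 0)
  expect_lt(ds_fit$p_value, 0.01)
  expect_equal(ds_fit$estimate, 4e-7, tolerance = 0.25)
  # degenerate design: all records at one distance
  flat <- dplyr::mutate(recs, distance = 1000)
  w <- capture_warnings(out <- fit_selection_regressions(flat,
                                                         widths = NULL))
  expect_true(all(grepl("insufficient", w)))   # one per skipped response
  expect_equal(nrow(out), 0)
})
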