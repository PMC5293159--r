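test_that("Shannon evenness matches closed forms", {
  u <- shannon_evenness(c(2, 2, 2, 2))
  expect_equal(unname(u["H"]), log(4))
  expect_equal(unname(u["E"]), 1)

  d <- shannon_evenness(c(1, 1e-12))
  expect_lt(unname(d["E"]), 1e-10)

  h31 <- shannon_evenness(c(3, 1))
  expect_equal(unname(h31["H"]), 0.5623, tolerance = 1e-4)
  expect_equal(unname(h31["E"]), 0.8113, tolerance = 1e-4)

  expect_error(shannon_evenness(5), class = "cofrac_evenness_error")
})

test_that("evenness is invariant to rescaling the ratios", {
  withr::with_seed(3, {
    for (i in 1:20) {
      w <- runif(sample(2:8, 1), 0.1, 5)
      c0 <- shannon_evenness(w)
      c1 <- shannon_evenness(w * runif(1, 0.01, 100))
      expect_equal(c1, c0, tolerance = 1e-12)
    }
  })
})

test_that("fraction-level evenness requires 3 quantified peptides", {
  pep <- tibble::tibble(
    protein = c("P1", "P1", "P1", "P2", "P2"),
    peptide = c("a", "b", "c", "d", "e"),
    replicate = 1L, fraction = 1L,
    ratio = c(2, 2, 2, 1, 1)
  )
  ev <- peptide_evenness(pep)
  expect_equal(ev$fractions$protein, "P1")   # P2 has only 2 peptides
  expect_equal(ev$fractions$E, 1)
  expect_equal(ev$proteins$U, 0)
})

test_that("permutation p-values follow the (b + 1) / (m + 1) convention", {
  # the protein-level unevenness tracks the most extreme fraction, so the
  # planted profile must be unattainable by any within-fraction shuffle
  pep <- tidyr::crossing(protein = sprintf("N%03d", 1:12), pep_i = 1:7,
                         fraction = 1L) |>
    dplyr::mutate(peptide = sprintf("%s_p%d", protein, pep_i),
                  replicate = 1L, ratio = 1)
  # one dominant peptide while the protein's remaining peptides sit far
  # below the background: no permutation can reassemble this profile
  pep$ratio[pep$protein == "N001"] <- c(50, rep(0.1, 6))
  un <- call_uneven_proteins(pep, n_perm = 999, seed = 2)
  planted <- dplyr::filter(un, protein == "N001")
  expect_equal(planted$p, 1 / 1000)  # more extreme than every permutation
})

test_that("a protein with identical peptide ratios is never called uneven", {
  pep <- make_uneven_dataset(seed = 4, n_proteins = 20, n_peptides = 7,
                             planted = FALSE, noise_sd = 0)
  un <- call_uneven_proteins(pep, n_perm = 999, seed = 5)
  expect_false(any(un$uneven))
  expect_true(all(un$U < 1e-10))
})

test_that("hypergeometric overlap enrichment matches exact enumeration", {
  # disjoint sets: tail from k = 0 is 1
  expect_equal(overlap_enrichment(letters[1:5], letters[6:10],
                                  letters[1:20])$p, 1)
  # complete overlap of two 5-sets in a 20-universe: 1 / C(20, 5)
  p5 <- overlap_enrichment(letters[1:5], letters[1:5], letters[1:20])$p
  expect_equal(p5, 1 / choose(20, 5), tolerance = 1e-12)
  # brute-force enumeration oracle for a small case
  uni <- letters[1:8]
  a <- letters[1:3]
  b <- letters[c(1, 2, 5, 6)]
  k_obs <- length(intersect(a, b))
  combos <- combn(uni, length(b))
  exceed <- mean(apply(combos, 2, function(s) {
    length(intersect(a, s)) >= k_obs
  }))
  expect_equal(overlap_enrichment(a, b, uni)$p, exceed, tolerance = 1e-12)
  # saturation
  expect_equal(overlap_enrichment(letters[1:20], letters[1:4],
                                  letters[1:20])$p, 1)
  expect_error(overlap_enrichment("a", "a", character()),
               class = "cofrac_enrichment_error")
})

test_that("pooled feature t-test flags planted shifts and respects Bonferroni", {
  n_feat <- 100
  withr::with_seed(6, {
    base <- gauss_profile(1, 20, 2.5)
    chroms <- list()
    feats <- list()
    for (i in seq_len(n_feat)) {
      p <- sprintf("T%03d", i)
      shift <- if (i == 1) 2^-1.3 else 1
      for (r in 1:3) {
        tr <- base * shift * exp(rnorm(55, 0, 0.02))
        un <- base * exp(rnorm(55, 0, 0.02))
        chroms[[length(chroms) + 1]] <- make_chroms(un, tr, protein = p,
                                                    replicate = r)
        feats[[length(feats) + 1]] <- make_features(p, 20, sigma = 1,
                                                    replicate = r)
      }
    }
  })
  chroms <- dplyr::bind_rows(chroms)
  feats <- dplyr::bind_rows(feats) |>
    dplyr::mutate(center_aligned = center, sigma_aligned = sigma)
  res <- test_feature_changes(feats, chroms)
  hit <- dplyr::filter(res, protein == "T001")
  expect_true(hit$significant)
  expect_equal(hit$log2fc, -1.3, tolerance = 0.05)
  expect_gte(hit$n_replicates, 2)
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  # null features stay quiet after Bonferroni
  expect_equal(sum(res$significant[res$protein != "T001"]), 0)
})

test_that("constant zero measurements are untested and never significant", {
  base <- gauss_profile(1, 10, 2)
  chroms <- make_chroms(base, base)
  feats <- make_features("P1", 10, sigma = 2) |>
    dplyr::mutate(center_aligned = center, sigma_aligned = sigma)
  res <- test_feature_changes(feats, chroms)
  expect_false(res$significant)
  expect_false(res$tested)
})

test_that("compartment variance comparison reports the F-test", {
  withr::with_seed(8, {
    ra <- tibble::tibble(log2fc = rnorm(60, 0, 0.6), tested = TRUE,
                         sd_replicates = 0.3)
    rb <- tibble::tibble(log2fc = rnorm(60, 0, 0.3), tested = TRUE,
                         sd_replicates = 0.2)
  })
  cmp <- compare_compartment_variance(ra, rb)
  oracle <- var.test(ra$log2fc, rb$log2fc)
  expect_equal(cmp$f_statistic, unname(oracle$statistic))
  expect_equal(cmp$p, oracle$p.value)
  expect_lt(cmp$p, 0.05)
})

test_that("proteoform segmentation finds the planted change point", {
  withr::with_seed(9, {
    pep <- tibble::tibble(
      protein = "FLNB",
      peptide = sprintf("p%02d", 1:20),
      start = seq(1, 951, by = 50),
      end = seq(50, 1000, by = 50),
      log2fc = c(rnorm(10, 0, 0.2), rnorm(10, 2, 0.2))
    )
  })
  seg <- detect_proteoform_segments(pep)
  expect_true(seg$segmented)
  expect_equal(seg$changepoint, 10)
  expect_equal(seg$boundary_lo, 500L)
  expect_equal(seg$boundary_hi, 501L)

  # exhaustive oracle: the chosen split maximises |t| over all splits
  best_t <- max(vapply(2:18, function(i) {
    abs(t.test(pep$log2fc[1:i], pep$log2fc[(i + 1):20])$statistic)
  }, numeric(1)))
  expect_equal(abs(seg$t), best_t, tolerance = 1e-10)
})

test_that("segmentation declines flat proteins and short peptide sets", {
  pep <- tibble::tibble(protein = "X", peptide = sprintf("p%d", 1:10),
                        start = 1:10 * 50, end = 1:10 * 50 + 40,
                        log2fc = rep(1, 10))
  expect_false(detect_proteoform_segments(pep)$segmented)

  pep5 <- dplyr::slice(pep, 1:5)
  res5 <- detect_proteoform_segments(pep5)
  expect_false(res5$segmented)
  expect_true(is.na(res5$changepoint))
})

test_that("unevenness rises monotonically with fragment separation", {
  ladder <- c(1, 1.5, 2, 3, 4)
  u_at <- vapply(seq_along(ladder), function(i) {
    pep <- make_uneven_dataset(seed = 20 + i, n_proteins = 5,
                               n_peptides = 14, ratio = ladder[i],
                               noise_sd = 0.05)
    ev <- peptide_evenness(pep)
    ev$proteins$U[ev$proteins$protein == "N001"]
  }, numeric(1))
  expect_gte(cor(ladder, u_at, method = "spearman"), 0.9)
})

test_that("a planted fraction-local cleavage signature is reliably called", {
  hits <- vapply(1:15, function(run) {
    pep <- make_uneven_dataset(seed = 800 + run, n_proteins = 200,
                               n_peptides = 14, n_cleaved_peptides = 4,
                               ratio = 4, noise_sd = 0.1)
    un <- call_uneven_proteins(pep, n_perm = 4999, seed = 900 + run)
    isTRUE(un$uneven[un$protein == "N001"]) &&
      sum(un$uneven) == 1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
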