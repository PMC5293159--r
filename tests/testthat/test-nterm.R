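test_that("terminus classification follows the start/modification convention", {
  seqs <- c(P1 = paste(rep("ACDEFGHIKL", 20), collapse = ""))
  rec <- tibble::tibble(protein = "P1", start = c(1L, 2L, 120L),
                        modification = c("acetyl", "dimethyl", "dimethyl"))
  out <- classify_termini(rec, seqs)
  expect_equal(out$class, c("natural", "natural", "neo"))
  expect_true(is.na(out$p1[1]))
  expect_equal(out$p1[3], substr(seqs[["P1"]], 119, 119))
  # window is P5..P1 | P1'..P6' around the cut
  expect_equal(out$window[3], substr(seqs[["P1"]], 115, 125))
  # sequence-start padding
  expect_equal(substr(out$window[1], 1, 5), "-----")
})

test_that("records without sequences are dropped with a message", {
  seqs <- c(P1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  rec <- tibble::tibble(protein = c("P1", "P9"), start = c(10L, 5L),
                        modification = "dimethyl")
  expect_message(out <- classify_termini(rec, seqs), "dropped 1")
  expect_equal(out$protein, "P1")
  expect_error(
    classify_termini(tibble::tibble(protein = "P1", start = 99L,
                                    modification = "dimethyl"),
                     c(P1 = "SHORTSEQ")),
    class = "cofrac_nterm_error")
})

test_that("the mixture EM recovers the two planted ratio populations", {
  x <- withr::with_seed(7, c(rnorm(753, -0.9, 0.6), rnorm(411, 1.6, 0.8)))
  fit <- fit_ratio_mixture(x, k = 2, seed = 8)
  expect_equal(fit$means, c(-0.9, 1.6), tolerance = 0.1)
  expect_equal(fit$weights, c(753, 411) / 1164, tolerance = 0.08)
  expect_true(fit$converged)
  # EM monotonicity: the log-likelihood trace never decreases
  expect_true(all(diff(fit$ll_trace) > -1e-6))
  td <- tidy(fit)
  expect_equal(td$mean, fit$means)
  expect_equal(glance(fit)$k, 2)
})

test_that("EM handles degenerate and unimodal inputs", {
  fit <- fit_ratio_mixture(rep(1.5, 100), k = 2, seed = 1)
  expect_equal(fit$means, c(1.5, 1.5), tolerance = 1e-6)
  expect_equal(fit$sds, c(1e-3, 1e-3))   # floored: one effective component

  x <- withr::with_seed(2, rnorm(200, 0.7, 0.5))
  fit1 <- fit_ratio_mixture(x, k = 1, seed = 3)
  expect_equal(fit1$means, mean(x), tolerance = 1e-6)

  expect_error(fit_ratio_mixture(rnorm(10), k = 2),
               class = "cofrac_mixture_error")
})

test_that("population classification applies strict +/-1 log2 thresholds", {
  rec <- tibble::tibble(
    class = "neo", p1 = c("D", "D", "D", "R", "D", "D", "D", "D", "D", "R"),
    log2_fas = c(1.5, 0.99, -1.2, 2, rep(1.6, 4), -0.5, 1.1),
    log2_zvad = c(1.4, 0, -1.3, 1.8, rep(0.1, 4), -0.2, 1.2)
  )
  tab <- classify_populations(rec)
  fas <- dplyr::filter(tab, arm == "fas")
  expect_equal(dplyr::filter(fas, p1 == "D", direction == "increased")$n, 5)
  expect_equal(dplyr::filter(fas, p1 == "D", direction == "decreased")$n, 1)
  expect_equal(sum(dplyr::filter(fas, direction == "unchanged")$n), 2)
  # concordant: same non-unchanged direction in both arms
  conc <- dplyr::filter(tab, arm == "fas", p1 == "D",
                        direction == "increased")
  expect_equal(conc$n_concordant, 1)
})

test_that("inhibitor stabilisation needs both suppression and significance", {
  rec <- tibble::tibble(
    class = c("neo", "neo", "neo", "natural"),
    p1 = c("D", "D", "R", NA),
    log2_fas = c(2.0, 2.0, 0.2, 1.8),
    log2_zvad = c(0.1, 1.8, -1.5, 0.2),
    sig_fas = c(TRUE, TRUE, FALSE, TRUE)
  )
  st <- zvad_sensitivity(rec)
  expect_equal(nrow(st), 2)
  expect_setequal(st$subpopulation, c("asp_cleavage", "natural"))
  # 2.0 vs 1.8: suppression below 1 log2 unit -> not stabilised
  expect_false(any(st$log2_fas == 2.0 & st$log2_zvad == 1.8))
})

test_that("motif enrichment flags the canonical caspase pattern and skips small sets", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bg <- withr::with_seed(11, vapply(1:40, function(i) {
    paste(sample(aas, 250, replace = TRUE), collapse = "")
  }, ""))
  wins <- withr::with_seed(12, vapply(1:40, function(i) {
    w <- sample(aas, 11, replace = TRUE)
    w[2] <- "D"; w[3] <- "E"; w[5] <- "D"; w[6] <- "G"
    paste(w, collapse = "")
  }, ""))
  me <- motif_enrichment(wins, bg)
  expect_true(me$caspase_motif)
  enr <- dplyr::filter(me$cells, enriched)
  expect_true(all(c(2, 3, 5, 6) %in% enr$position))

  expect_message(out <- motif_enrichment(wins[1:9], bg), "skipped")
  expect_null(out)
})

test_that("null windows stay below the motif false-positive budget", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bg <- withr::with_seed(13, vapply(1:40, function(i) {
    paste(sample(aas, 250, replace = TRUE), collapse = "")
  }, ""))
  fp <- withr::with_seed(14, vapply(1:8, function(i) {
    wn <- vapply(1:40, function(j) {
      paste(sample(aas, 11, replace = TRUE), collapse = "")
    }, "")
    m <- motif_enrichment(wn, bg)
    mean(m$cells$q < 0.02, na.rm = TRUE)
  }, numeric(1)))
  expect_lte(mean(fp), 0.02)
})

test_that("terminome-interactome correlation reproduces rank identities", {
  rec <- tibble::tibble(protein = sprintf("P%02d", 1:20), class = "neo",
                        log2_fas = seq(-2, 2, length.out = 20))
  fe_pos <- tibble::tibble(protein = rec$protein, log2fc = rec$log2_fas)
  expect_equal(correlate_with_interactome(rec, fe_pos)$rho, 1)
  fe_neg <- dplyr::mutate(fe_pos, log2fc = -log2fc)
  expect_equal(correlate_with_interactome(rec, fe_neg)$rho, -1)
})

test_that("tied ranks agree with a brute-force Spearman computation", {
  rec <- tibble::tibble(protein = sprintf("P%02d", 1:12), class = "neo",
                        log2_fas = c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8, 9, 10))
  fe <- tibble::tibble(protein = rec$protein,
                       log2fc = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11))
  got <- correlate_with_interactome(rec, fe)$rho
  rx <- rank(rec$log2_fas)   # average-rank ties
  ry <- rank(fe$log2fc)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("correlation is undefined below 10 pairs", {
  rec <- tibble::tibble(protein = sprintf("P%d", 1:5), class = "neo",
                        log2_fas = 1:5)
  fe <- tibble::tibble(protein = rec$protein, log2fc = 1:5)
  expect_warning(out <- correlate_with_interactome(rec, fe), "undefined")
  expect_true(is.na(out$rho))
})

test_that("classification conserves records: natural + neo = mapped total", {
  truth <- simulate_truth(n_proteins = 80, n_complexes = 8, n_cleavages = 40,
                          seed = 15)
  seqs <- simulate_proteome(truth, seed = 16)
  tm <- simulate_ntermini(truth, seed = 17)
  out <- classify_termini(tm, seqs)
  expect_equal(sum(out$class == "natural") + sum(out$class == "neo"),
               nrow(tm))
  expect_equal(out$class, out$true_class)
  neo <- dplyr::filter(out, class == "neo")
  expect_equal(neo$p1, neo$true_p1)
})
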