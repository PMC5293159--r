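test_that("identical seeds give bit-identical simulations", {
  truth <- simulate_truth(n_proteins = 30, n_complexes = 4,
                          complex_size_range = c(2, 4), seed = 9)
  s1 <- simulate_profiles(truth, seed = 10, peptides = TRUE)
  s2 <- simulate_profiles(truth, seed = 10, peptides = TRUE)
  expect_identical(s1$chromatograms, s2$chromatograms)
  expect_identical(s1$peptides, s2$peptides)
  t1 <- simulate_ntermini(truth, seed = 11)
  t2 <- simulate_ntermini(truth, seed = 11)
  expect_identical(t1, t2)
  expect_identical(simulate_proteome(truth, seed = 12),
                   simulate_proteome(truth, seed = 12))
})

test_that("noiseless unshifted profiles equal the closed-form Gaussian sum", {
  truth <- simulate_truth(n_proteins = 25, n_complexes = 3,
                          prop_fold_change = 0, prop_disassembled = 0,
                          rep_slope_range = c(1, 1),
                          rep_offset_range = c(0, 0),
                          noise_sd = 0, missing_rate = 0,
                          n_replicates = 1, seed = 21)
  sim <- simulate_profiles(truth, seed = 22, peptides = FALSE)
  pk <- dplyr::filter(sim$planted, channel == "untreated")
  ch <- dplyr::filter(sim$chromatograms, channel == "untreated")
  for (p in unique(ch$protein)[1:10]) {
    pkp <- dplyr::filter(pk, protein == p)
    expected <- gauss_profile(pkp$amplitude, pkp$center, pkp$sigma, n = 55)
    got <- dplyr::filter(ch, protein == p) |>
      dplyr::arrange(fraction) |>
      dplyr::pull(ratio)
    got[is.na(got)] <- 0   # detection floor censors negligible tails
    expect_equal(got, expected, tolerance = 1e-4)
  }
})

test_that("disassembly moves the full assembly amplitude onto the monomer peak", {
  truth <- simulate_truth(n_proteins = 40, n_complexes = 6,
                          complex_size_range = c(2, 5),
                          prop_fold_change = 0, prop_disassembled = 1,
                          seed = 31)
  peaks <- planted_peaks(truth)
  by_channel <- peaks |>
    dplyr::group_by(protein, channel) |>
    dplyr::summarise(total = sum(amplitude), .groups = "drop") |>
    tidyr::pivot_wider(names_from = channel, values_from = total)
  # conservation: total planted amplitude identical across channels
  expect_equal(by_channel$treated, by_channel$untreated, tolerance = 1e-9)

  cpx_members <- unlist(truth$complexes$members)
  trt_cpx <- peaks |>
    dplyr::filter(channel == "treated", protein %in% cpx_members,
                  peak %in% c("complex", "complex_state2"))
  expect_equal(nrow(trt_cpx), 0)  # assembly peaks fully removed
  mono <- peaks |>
    dplyr::filter(peak == "monomer", protein %in% cpx_members) |>
    tidyr::pivot_wider(names_from = channel, values_from = amplitude,
                       id_cols = protein)
  expect_true(all(mono$treated > mono$untreated))
})

test_that("degenerate truth without complexes yields monomer-only data", {
  truth <- simulate_truth(n_proteins = 10, n_complexes = 0, n_cleavages = 0,
                          seed = 41)
  peaks <- planted_peaks(truth)
  expect_setequal(unique(peaks$peak), "monomer")
  sim <- simulate_profiles(truth, seed = 42, peptides = FALSE)
  expect_equal(nrow(sim$chromatograms), 10 * 3 * 2 * 55)
})

test_that("simulated termini follow the planted mixture and natural fraction", {
  truth <- simulate_truth(n_proteins = 400, n_complexes = 40,
                          n_cleavages = 1164, seed = 51)
  tm <- simulate_ntermini(truth, seed = 52)
  neo <- dplyr::filter(tm, true_class == "neo")
  expect_equal(nrow(neo), 1164)

  # analytic mixture mean of the per-replicate measurements
  np <- truth$params$nterm
  mix_mean <- sum(np$weights * np$centers)
  mix_var <- sum(np$weights * (np$sds^2 + np$centers^2)) - mix_mean^2 +
    np$replicate_sd^2
  se <- sqrt(mix_var / nrow(neo))
  expect_lt(abs(mean(neo$fas_1) - mix_mean), 3 * se)

  # natural-terminus fraction within the binomial interval around 0.86
  nat_frac <- mean(tm$true_class == "natural")
  ci <- stats::binom.test(sum(tm$true_class == "natural"), nrow(tm),
                          p = 0.86)$conf.int
  expect_true(0.86 >= ci[1] && 0.86 <= ci[2])
  expect_equal(nat_frac, 0.86, tolerance = 0.02)
})

test_that("degenerate mixture weights send all neo termini to one component", {
  truth <- simulate_truth(n_proteins = 60, n_complexes = 6, n_cleavages = 40,
                          nterm = list(centers = c(-0.9, 1.6),
                                       sds = c(0.6, 0.8), weights = c(1, 0),
                                       natural_fraction = 0.86,
                                       natural_sd = 0.3, replicate_sd = 0.4),
                          seed = 61)
  expect_true(all(truth$cleavages$component == 1))
  tm <- simulate_ntermini(truth, seed = 62)
  neo <- dplyr::filter(tm, true_class == "neo")
  expect_lt(mean(neo$fas_1), 0.2)   # all draws from the low component
})

test_that("proteome sequences embed the planted P1 residues and caspase context", {
  truth <- simulate_truth(n_proteins = 50, n_complexes = 5, n_cleavages = 30,
                          seed = 71)
  seqs <- simulate_proteome(truth, seed = 72)
  expect_equal(length(seqs), 50)
  for (i in seq_len(nrow(truth$cleavages))) {
    ev <- truth$cleavages[i, ]
    expect_equal(substr(seqs[[ev$protein]], ev$position - 1, ev$position - 1),
                 ev$p1)
    if (ev$p1 == "D" && ev$caspase_dependent) {
      expect_equal(substr(seqs[[ev$protein]], ev$position - 4, ev$position),
                   "DEVDG")
    }
  }
})

test_that("generator-pipeline consistency: planted peaks recovered without noise", {
  truth <- simulate_truth(n_proteins = 20, n_complexes = 3,
                          prop_fold_change = 0, prop_disassembled = 0,
                          two_state_prob = 0,
                          rep_slope_range = c(1, 1),
                          rep_offset_range = c(0, 0),
                          noise_sd = 0, missing_rate = 0,
                          n_replicates = 1, seed = 81)
  sim <- simulate_profiles(truth, seed = 82, peptides = FALSE)
  feats <- suppressMessages(fit_profiles(sim$chromatograms,
                                         channels = "untreated"))
  planted <- sim$planted |>
    dplyr::filter(channel == "untreated", center <= 52, center >= 3,
                  amplitude > 0.05)
  for (i in seq_len(nrow(planted))) {
    pl <- planted[i, ]
    match_f <- feats |>
      dplyr::filter(protein == pl$protein,
                    abs(center - pl$center_obs) < 0.5)
    # skip planted peaks overlapping another peak of the same protein
    others <- planted |>
      dplyr::filter(protein == pl$protein, center != pl$center)
    if (nrow(others) > 0 && min(abs(others$center - pl$center)) < 6) next
    expect_equal(nrow(match_f), 1)
    expect_equal(match_f$amplitude, pl$amplitude, tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(match_f$center, pl$center_obs, tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_equal(match_f$sigma, pl$sigma_obs, tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})
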