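#' Run the full dynamic-interactome pipeline on synthetic data
#'
#' End-to-end driver over one simulated study: generate ground truth and
#' profiles, deconvolve chromatograms into Gaussian features, align
#' replicates, test features for stimulation-induced changes, score and
#' calibrate the interaction network against the planted complexes as the
#' gold standard, Markov-cluster it into complexes, compute peptide-level
#' evenness, simulate and analyse the matched N-terminome, and correlate
#' cleavage with interactome change.
#'
#' @param truth Optional pre-built [simulate_truth()]; generated from
#'   `seed` when `NULL`.
#' @param seed Integer seed driving every stochastic stage.
#' @param target_precision Local precision target for calibration.
#' @param inflation MCL inflation.
#' @param fit_channel Channel whose profiles are deconvolved for
#'   interaction scoring (default `"untreated"`, the unperturbed state).
#' @param peptides Run the peptide-level evenness stage (slower).
#' @param ... Passed to [simulate_truth()] when `truth` is `NULL`.
#' @return A list with the truth, simulation, features, alignment,
#'   differential results, candidates, local and global networks,
#'   clusters, cluster precision, evenness, terminome results and the
#'   cleavage-interactome correlation.
#' @export
run_cofrac <- function(truth = NULL, seed = 1, target_precision = 0.70,
                       inflation = 3, fit_channel = "untreated",
                       peptides = TRUE, ...) {
  if (is.null(truth)) {
    truth <- simulate_truth(seed = child_seed(seed, 1), ...)
  }
  sim <- simulate_profiles(truth, seed = child_seed(seed, 2),
                           peptides = peptides)

  features <- fit_profiles(sim$chromatograms, channels = fit_channel)
  al <- align_features(features)
  feats <- feature_ratio(al$features, sim$chromatograms)

  # differential windows come from the channel-averaged profiles so that
  # neither condition's noise selects the tested fractions
  feats_diff <- fit_profiles(combine_channels(sim$chromatograms),
                             channels = "combined")
  al_diff <- align_features(feats_diff)
  fr_diff <- feature_ratio(al_diff$features, sim$chromatograms)
  diff <- test_feature_changes(fr_diff, sim$chromatograms)

  db <- truth_complex_db(truth)
  candidates <- score_candidate_pairs(feats, sim$chromatograms) |>
    label_pairs(db)
  local <- calibrate_threshold(candidates, target_precision)
  global <- global_report(local$edges, candidates)

  clusters <- cluster_network(global$edges, feats, inflation = inflation)
  cl_prec <- if (nrow(clusters) > 0) complex_precision(clusters, db) else NULL
  merged <- if (nrow(clusters) > 0 && "center" %in% names(clusters)) {
    merge_coeluting(clusters)
  } else {
    NULL
  }

  evenness <- uneven <- NULL
  if (peptides && !is.null(sim$peptides)) {
    evenness <- peptide_evenness(sim$peptides)
    uneven <- call_uneven_proteins(sim$peptides,
                                   seed = child_seed(seed, 3))
  }

  proteome <- simulate_proteome(truth, seed = child_seed(seed, 4))
  termini <- simulate_ntermini(truth, seed = child_seed(seed, 5)) |>
    classify_termini(proteome) |>
    flag_significant_termini()
  neo_ratios <- termini$log2_fas[termini$class == "neo"]
  mixture <- if (length(neo_ratios) >= 50) {
    fit_ratio_mixture(neo_ratios, seed = child_seed(seed, 6))
  } else {
    NULL
  }
  correlation <- correlate_with_interactome(
    termini, fr_diff,
    unevenness = if (!is.null(uneven)) rename(uneven, U = "U") else NULL
  )

  list(truth = truth, simulation = sim, features = feats,
       features_differential = fr_diff,
       alignment = al, differential = diff, candidates = candidates,
       local = local, global = global, clusters = clusters,
       cluster_precision = cl_prec, supercomplexes = merged,
       evenness = evenness, uneven = uneven, termini = termini,
       mixture = mixture, correlation = correlation)
}

#' Gold-standard complex database from a planted truth
#'
#' Recasts the generator's complex table into the [read_complex_db()]
#' layout, so the planted complexes serve as the CORUM-like gold standard
#' when analysing synthetic data.
#'
#' @param truth A [simulate_truth()] object.
#' @return Tibble with `complex_id`, `complex_name`, `members`,
#'   `n_members`.
#' @export
truth_complex_db <- function(truth) {
  truth$complexes |>
    transmute(complex_id = .data$complex_id,
              complex_name = .data$complex_id,
              members = .data$members,
              n_members = .data$n_members)
}

#' Cleavage-vs-interactome correlation under a planted regime
#'
#' Runs the measurement chain for the pipeline's central question: are
#' proteolytic cleavage and interactome rearrangement linked? Profiles are
#' simulated and deconvolved, feature fold changes measured, the matched
#' N-terminome simulated and classified, and
#' [correlate_with_interactome()] applied. With `coupled = FALSE`,
#' cleavage events and complex perturbations are planted independently
#' and the expected Spearman rho is 0; with `coupled = TRUE`, cleavage is
#' planted to drive complex fold changes, and a strong positive rho is
#' expected.
#'
#' @param seed Integer seed.
#' @param coupled Couple cleavage to interactome perturbation?
#' @return The [correlate_with_interactome()] result list (elements `rho`,
#'   `n_pairs`, `pairs`).
#' @export
cleavage_correlation_study <- function(seed = 1, coupled = FALSE) {
  truth <- if (coupled) {
    simulate_truth(n_proteins = 300, n_complexes = 40,
                   prop_fold_change = 0.7, prop_disassembled = 0,
                   fold_change_sd = 1.2, n_cleavages = 250,
                   couple_cleavage = TRUE, seed = child_seed(seed, 11))
  } else {
    simulate_truth(n_proteins = 400, n_complexes = 40, n_cleavages = 320,
                   seed = child_seed(seed, 12))
  }
  sim <- simulate_profiles(truth, seed = child_seed(seed, 13),
                           peptides = FALSE)
  feats <- fit_profiles(combine_channels(sim$chromatograms),
                        channels = "combined")
  al <- align_features(feats)
  fr <- feature_ratio(al$features, sim$chromatograms)
  proteome <- simulate_proteome(truth, seed = child_seed(seed, 14))
  termini <- simulate_ntermini(truth, seed = child_seed(seed, 15)) |>
    classify_termini(proteome) |>
    flag_significant_termini()
  correlate_with_interactome(termini, fr)
}
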