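#' Generate a ground-truthed synthetic study design
#'
#' Builds the hidden state behind a dynamic co-fractionation experiment:
#' a protein set with monomer masses, protein complexes with assembly
#' masses, a perturbation map describing how each complex responds to
#' stimulation (unchanged, abundance fold change, or complete disassembly),
#' proteolytic cleavage events with P1 residues and fragment fold changes,
#' per-replicate fractionation drift, and the noise/missingness model.
#' [simulate_profiles()], [simulate_peptides()], [simulate_proteome()] and
#' [simulate_ntermini()] consume this object to emit observable data, so
#' every downstream stage can be checked against known truth.
#'
#' The defaults emulate the study design this pipeline targets: 3-channel
#' SILAC over 55 fractions, 3 biological replicates, 500 proteins in 60
#' complexes of 2-10 members, a minority of complexes perturbed with
#' condensin-like log2 fold changes centred at -1.3, replicate fraction
#' drift with slope in \[0.97, 1.03\] and offset in \[-2, 2\] fractions,
#' and neo-N-termini drawn from a two-component normal mixture centred at
#' log2 -0.9 (degradation) and +1.6 (stable processing products) with
#' weights 753:411.
#'
#' @param n_proteins Number of protein groups.
#' @param n_complexes Number of planted complexes.
#' @param complex_size_range Inclusive member-count range per complex.
#' @param long_tail_sizes If `TRUE`, complex sizes are drawn from a
#'   geometric-tailed distribution (up to ~60 members) instead of uniform,
#'   emulating long-tailed real complex membership.
#' @param n_replicates Biological replicates.
#' @param n_fractions Fractions per separation (the calibrated 1..F axis).
#' @param prop_fold_change,prop_disassembled Proportions of complexes with
#'   an abundance fold change, and fully disassembled, on stimulation; the
#'   remainder are unchanged.
#' @param fold_change_mean,fold_change_sd Normal parameters for the log2
#'   fold change of perturbed complexes (clamped to |delta| <= 6).
#' @param monomer_meanlog,monomer_sdlog Lognormal parameters for monomer
#'   masses (Da).
#' @param complex_amplitude Proportion of a complexed member's signal in
#'   the assembly peak(s) (the rest elutes as monomer).
#' @param two_state_prob Probability that a complex elutes in two
#'   assembly states (a second peak at half or twice the assembly mass,
#'   shared by all members).
#' @param rep_slope_range,rep_offset_range Per-replicate fraction drift:
#'   observed signals are sampled through `f' = a_r * f + b_r`.
#' @param noise_sd Standard deviation of multiplicative lognormal noise.
#' @param missing_rate Baseline Bernoulli missingness (0 <= rate < 0.5);
#'   realised probability is intensity-dependent (higher at low signal).
#' @param n_cleavages Number of planted cleavage events (a protein may
#'   carry several).
#' @param p1_composition Named sampling weights for the P1 residue of
#'   cleavage events; the default is enriched for Asp and Arg.
#' @param caspase_prob Probability that an Asp(P1) event is
#'   caspase-dependent (attenuated by the pan-caspase inhibitor arm).
#' @param couple_cleavage If `TRUE`, cleavage events are planted on members
#'   of perturbed complexes and their terminus fold changes track the
#'   complex perturbation; if `FALSE` (default) cleavage and interactome
#'   perturbation are independent processes.
#' @param nterm List of N-terminome generative parameters: two-component
#'   `centers`, `sds`, `weights` (summing to 1), the `natural_fraction` of
#'   termini that are mature protein N-termini, measurement sd
#'   `replicate_sd`, and `natural_sd`.
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#'
#' @return An object of class `cofrac_truth`: a list with tibbles
#'   `proteins`, `complexes`, `cleavages`, `replicates` and the parameter
#'   list `params`.
#' @export
simulate_truth <- function(n_proteins = 500,
                           n_complexes = 60,
                           complex_size_range = c(2, 10),
                           long_tail_sizes = FALSE,
                           n_replicates = 3,
                           n_fractions = 55,
                           prop_fold_change = 0.15,
                           prop_disassembled = 0.10,
                           fold_change_mean = -1.3,
                           fold_change_sd = 0.6,
                           monomer_meanlog = log(7e4),
                           monomer_sdlog = 0.5,
                           complex_amplitude = 0.7,
                           two_state_prob = 0.5,
                           rep_slope_range = c(0.97, 1.03),
                           rep_offset_range = c(-2, 2),
                           noise_sd = 0.15,
                           missing_rate = 0.2,
                           n_cleavages = round(0.12 * n_proteins),
                           p1_composition = c(D = 0.35, R = 0.35, E = 0.06,
                                              A = 0.06, G = 0.06, S = 0.06,
                                              K = 0.06),
                           caspase_prob = 0.6,
                           couple_cleavage = FALSE,
                           nterm = list(centers = c(-0.9, 1.6),
                                        sds = c(0.6, 0.8),
                                        weights = c(753, 411) / 1164,
                                        natural_fraction = 0.86,
                                        natural_sd = 0.3,
                                        replicate_sd = 0.4),
                           seed = NULL) {
  stopifnot(missing_rate >= 0, missing_rate < 0.5,
            abs(sum(nterm$weights) - 1) < 1e-8)
  with_seed(seed, {
    protein <- sprintf("P%04d", seq_len(n_proteins))
    monomer_mass <- rlnorm(n_proteins, monomer_meanlog, monomer_sdlog)
    abundance <- rlnorm(n_proteins, 0, 0.3)

    stopifnot(complex_size_range[1] >= 2)
    sizes <- if (long_tail_sizes) {
      pmin(2 + stats::rgeom(n_complexes, prob = 0.25), 61L)
    } else {
      size_pool <- seq(complex_size_range[1], complex_size_range[2])
      if (length(size_pool) == 1) {
        rep(size_pool, n_complexes)
      } else {
        sample(size_pool, n_complexes, replace = TRUE)
      }
    }
    if (sum(sizes) > n_proteins) {
      stop_cofrac("complex membership exceeds the protein set; increase n_proteins",
                  "cofrac_truth_error")
    }
    member_pool <- sample(protein, sum(sizes))
    members <- split(member_pool, rep(seq_len(n_complexes), times = sizes))

    state <- sample(c("unchanged", "fold_change", "disassembled"),
                    n_complexes, replace = TRUE,
                    prob = c(1 - prop_fold_change - prop_disassembled,
                             prop_fold_change, prop_disassembled))
    delta <- ifelse(state == "fold_change",
                    pmax(-6, pmin(6, rnorm(n_complexes, fold_change_mean,
                                           fold_change_sd))),
                    0)
    # assembly mass: sum of member monomers times a supercomplex
    # stoichiometry factor, spreading complexes across the separation;
    # half the complexes elute in two assembly states (e.g. complex and
    # supercomplex/subcomplex), a fingerprint shared by all members
    assembly_factor <- sample(1:3, n_complexes, replace = TRUE,
                              prob = c(0.5, 0.3, 0.2))
    base_mass <- map_dbl(members, function(m) {
      sum(monomer_mass[match(m, protein)])
    }) * assembly_factor
    has_state2 <- runif(n_complexes) < two_state_prob
    state2_mass <- ifelse(has_state2,
                          base_mass * sample(c(0.5, 2), n_complexes,
                                             replace = TRUE),
                          NA_real_)
    complexes <- tibble(
      complex_id = sprintf("CPX%03d", seq_len(n_complexes)),
      members = unname(members),
      n_members = lengths(members),
      mass = base_mass,
      state2_mass = state2_mass,
      state2_share = ifelse(has_state2, 0.35, 0),
      width_factor = rlnorm(n_complexes, 0, 0.25),
      perturbation = state,
      log2_delta = delta
    )

    proteins <- tibble(
      protein = protein,
      monomer_mass = monomer_mass,
      length = pmax(60L, as.integer(round(monomer_mass / 110))),
      abundance = abundance,
      complex_id = NA_character_
    )
    for (i in seq_len(n_complexes)) {
      proteins$complex_id[match(complexes$members[[i]], proteins$protein)] <-
        complexes$complex_id[i]
    }

    # Cleavage events: independent of the perturbation map unless coupling
    # is requested, in which case targets are members of perturbed
    # complexes and the event's fold change tracks the complex delta.
    cleavages <- simulate_cleavage_events(
      proteins, complexes, n_cleavages, p1_composition, caspase_prob,
      couple_cleavage, nterm, n_fractions
    )

    replicates <- tibble(
      replicate = seq_len(n_replicates),
      slope = runif(n_replicates, rep_slope_range[1], rep_slope_range[2]),
      offset = runif(n_replicates, rep_offset_range[1], rep_offset_range[2])
    )

    structure(
      list(proteins = proteins, complexes = complexes,
           cleavages = cleavages, replicates = replicates,
           params = list(n_fractions = as.integer(n_fractions),
                         complex_amplitude = complex_amplitude,
                         noise_sd = noise_sd, missing_rate = missing_rate,
                         nterm = nterm, couple_cleavage = couple_cleavage,
                         caspase_prob = caspase_prob)),
      class = "cofrac_truth"
    )
  })
}

simulate_cleavage_events <- function(proteins, complexes, n_cleavages,
                                     p1_composition, caspase_prob,
                                     couple_cleavage, nterm, n_fractions) {
  if (n_cleavages == 0) {
    return(tibble(protein = character(), position = integer(),
                  p1 = character(), caspase_dependent = logical(),
                  component = integer(), true_log2 = numeric(),
                  frag_fraction = numeric()))
  }
  if (couple_cleavage) {
    perturbed <- complexes |> filter(.data$perturbation != "unchanged")
    pool <- proteins |> filter(.data$complex_id %in% perturbed$complex_id)
    if (nrow(pool) == 0) {
      stop_cofrac("couple_cleavage = TRUE requires perturbed complexes",
                  "cofrac_truth_error")
    }
  } else {
    pool <- proteins
  }
  target <- pool[sample.int(nrow(pool), n_cleavages, replace = TRUE), ]
  p1 <- sample(names(p1_composition), n_cleavages, replace = TRUE,
               prob = p1_composition)
  component <- sample.int(length(nterm$weights), n_cleavages, replace = TRUE,
                          prob = nterm$weights)
  true_log2 <- rnorm(n_cleavages, nterm$centers[component],
                     nterm$sds[component])
  if (couple_cleavage) {
    cpx <- complexes[match(target$complex_id, complexes$complex_id), ]
    base <- ifelse(cpx$perturbation == "disassembled", -2.5, cpx$log2_delta)
    true_log2 <- base + rnorm(n_cleavages, 0, 0.2)
  }
  # draw positions, then resolve collisions so that two events on the
  # same protein never share a P5..P1' context window
  position <- pmax(20L, pmin(target$length - 20L,
                             as.integer(round(runif(n_cleavages, 0.25, 0.75) *
                                                target$length))))
  taken <- split(integer(0), character(0))
  for (i in seq_len(n_cleavages)) {
    prot <- target$protein[i]
    used <- taken[[prot]]
    pos <- position[i]
    offset_try <- c(0L, as.integer(outer(c(7L, -7L), 1:20)))
    for (off in offset_try) {
      cand_pos <- pos + off
      if (cand_pos >= 20L && cand_pos <= target$length[i] - 20L &&
          (length(used) == 0 || min(abs(used - cand_pos)) >= 6)) {
        pos <- cand_pos
        break
      }
    }
    position[i] <- pos
    taken[[prot]] <- c(used, pos)
  }
  tibble(
    protein = target$protein,
    position = position,
    p1 = p1,
    caspase_dependent = p1 == "D" & runif(n_cleavages) < caspase_prob,
    component = component,
    true_log2 = true_log2,
    # stable fragments elute near (but not exactly at) the parent's own
    # elution position -- e.g. remaining loosely associated or joining a
    # co-eluting assembly -- so the peptide-level signal is localised to a
    # few fractions where the parent is also quantified
    frag_fraction = {
      cal <- mass_calibration(n_fractions)
      cpx_t <- complexes[match(target$complex_id, complexes$complex_id), ]
      m <- ifelse(is.na(cpx_t$mass), target$monomer_mass, cpx_t$mass)
      f0 <- fraction_for_mass(cal, pmin(pmax(m, cal$mw_last), cal$mw_first))
      pmin(pmax(f0 + runif(n_cleavages, -3, 3), 3), n_fractions - 1)
    }
  )
}

#' @export
print.cofrac_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "<cofrac_truth> %d proteins, %d complexes (%d perturbed), ",
    "%d cleavage events, %d replicates, %d fractions\n"),
    nrow(x$proteins), nrow(x$complexes),
    sum(x$complexes$perturbation != "unchanged"),
    nrow(x$cleavages), nrow(x$replicates), x$params$n_fractions))
  invisible(x)
}

#' Ground truth for a condensin-style disassembly study
#'
#' A focused study design for testing disassembly calls: three planted
#' complexes of three members each whose abundance drops by a common log2
#' fold change on stimulation (the condensin I pattern), against a
#' background of unperturbed complexes and monomeric proteins.
#' Single-assembly-state complexes are used so each member contributes one
#' clean elution feature.
#'
#' @param seed Integer seed.
#' @param n_proteins,n_complexes Background scale (includes the three
#'   planted complexes).
#' @param log2_delta Planted log2 fold change (default -1.3).
#' @param ... Further arguments to [simulate_truth()].
#' @return A `cofrac_truth` whose first three complexes carry the planted
#'   fold change.
#' @export
simulate_disassembly_truth <- function(seed = NULL, n_proteins = 150,
                                       n_complexes = 10, log2_delta = -1.3,
                                       ...) {
  truth <- simulate_truth(n_proteins = n_proteins, n_complexes = n_complexes,
                          complex_size_range = c(3, 3),
                          prop_fold_change = 0, prop_disassembled = 0,
                          two_state_prob = 0, seed = seed, ...)
  truth$complexes$perturbation[1:3] <- "fold_change"
  truth$complexes$log2_delta[1:3] <- log2_delta
  truth
}
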