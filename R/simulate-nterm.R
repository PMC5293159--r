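#' Simulate a proteome consistent with planted cleavage events
#'
#' Generates one amino-acid sequence per protein (length from the planted
#' monomer mass at ~110 Da/residue), drawn from near-uniform background
#' frequencies. At every planted cleavage position the required P1 residue
#' is embedded immediately before the cut; caspase-dependent Asp events
#' additionally carry the canonical executioner-caspase context (P4-P1 =
#' `DEVD`, P1' = `G`), and Arg events receive an acidic P1' residue with
#' probability one half, so that positional motif analysis has real signal
#' to find.
#'
#' @param truth A [simulate_truth()] object.
#' @param seed Integer seed.
#' @return Named character vector of sequences (one per protein).
#' @export
simulate_proteome <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "cofrac_truth"))
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    seqs <- map_chr(truth$proteins$length, function(len) {
      paste(sample(aas, len, replace = TRUE), collapse = "")
    })
    names(seqs) <- truth$proteins$protein
    for (i in seq_len(nrow(truth$cleavages))) {
      ev <- truth$cleavages[i, ]
      s <- strsplit(seqs[[ev$protein]], "")[[1]]
      pos <- ev$position           # cut between pos-1 and pos
      s[pos - 1] <- ev$p1
      if (ev$p1 == "D" && ev$caspase_dependent) {
        s[(pos - 4):(pos - 1)] <- c("D", "E", "V", "D")
        s[pos] <- "G"
      } else if (ev$p1 == "D") {
        if (runif(1) < 0.7) s[pos] <- "G"
      } else if (ev$p1 == "R") {
        if (runif(1) < 0.5) s[pos] <- sample(c("D", "E"), 1)
      }
      seqs[[ev$protein]] <- paste(s, collapse = "")
    }
    seqs
  })
}

#' Simulate a quantified N-terminome (TAILS) table
#'
#' Emits one record per planted cleavage event (a neo-N-terminus at the
#' cleavage position, dimethylated by the TAILS chemistry) plus mature
#' protein N-termini (start 1 or 2, acetylated or dimethylated) on a
#' random protein subset, sized so that natural termini make up
#' `natural_fraction` of all records (default 0.86).
#'
#' Neo-terminus log2 ratios follow the truth's two-component normal
#' mixture: a degradation population centred at log2 -0.9 and a stable
#' processing population centred at +1.6 (weights 753:411 by default), or
#' the complex perturbation delta when the truth was built with
#' `couple_cleavage = TRUE`. Natural termini scatter around 0. The
#' inhibitor arm attenuates caspase-dependent events towards 0 (factor
#' 0.15) and leaves the rest unchanged. Each arm is measured in
#' `n_replicates` noisy replicates (sd `replicate_sd`).
#'
#' @param truth A [simulate_truth()] object.
#' @param seed Integer seed.
#' @param n_replicates Measurement replicates per arm.
#' @return Tibble with one row per terminus: `terminus_id`, `protein`,
#'   `start`, `modification`, generator bookkeeping (`true_class`,
#'   `true_p1`, `true_component`), and per-replicate log2 ratio columns
#'   `fas_1..n` (stimulated vs untreated) and `zvad_1..n` (stimulated +
#'   pan-caspase inhibitor vs untreated).
#' @export
simulate_ntermini <- function(truth, seed = NULL, n_replicates = 3) {
  stopifnot(inherits(truth, "cofrac_truth"))
  np <- truth$params$nterm
  clv <- truth$cleavages
  with_seed(seed, {
    neo <- tibble(
      protein = clv$protein,
      start = clv$position,
      modification = "dimethyl",
      true_class = "neo",
      true_p1 = clv$p1,
      true_component = clv$component,
      mu_fas = clv$true_log2,
      mu_zvad = ifelse(clv$caspase_dependent, 0.15 * clv$true_log2,
                       clv$true_log2)
    )
    n_nat <- round(np$natural_fraction / (1 - np$natural_fraction) * nrow(neo))
    nat_prot <- sample(truth$proteins$protein, min(n_nat, nrow(truth$proteins)))
    if (n_nat > length(nat_prot)) {
      nat_prot <- c(nat_prot, sample(truth$proteins$protein,
                                     n_nat - length(nat_prot), replace = TRUE))
    }
    nat <- tibble(
      protein = nat_prot,
      start = sample(1:2, n_nat, replace = TRUE),
      modification = sample(c("acetyl", "dimethyl"), n_nat, replace = TRUE,
                            prob = c(0.7, 0.3)),
      true_class = "natural",
      true_p1 = NA_character_,
      true_component = NA_integer_,
      mu_fas = rnorm(n_nat, 0, np$natural_sd),
      mu_zvad = rnorm(n_nat, 0, np$natural_sd)
    )
    rec <- bind_rows(neo, nat)
    rec$terminus_id <- sprintf("NT%05d", seq_len(nrow(rec)))
    for (r in seq_len(n_replicates)) {
      rec[[sprintf("fas_%d", r)]] <- rec$mu_fas +
        rnorm(nrow(rec), 0, np$replicate_sd)
      rec[[sprintf("zvad_%d", r)]] <- rec$mu_zvad +
        rnorm(nrow(rec), 0, np$replicate_sd)
    }
    rec |>
      select("terminus_id", everything(), -"mu_fas", -"mu_zvad")
  })
}
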