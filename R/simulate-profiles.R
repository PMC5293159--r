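#' Planted elution peaks implied by a ground truth
#'
#' The generator's bookkeeping: every protein's noiseless elution profile
#' is a sum of Gaussians, one at its complex's calibrated fraction (if any)
#' plus a monomer peak, with peak widths broadening linearly along the
#' gradient (`sigma = 1.5 + 0.02 * f`). The treated channel applies the
#' perturbation map: an abundance fold change scales the assembly peak by
#' `2^delta`; disassembly moves the assembly peak's full amplitude onto the
#' monomer peak, conserving total planted amplitude.
#'
#' @param truth A [simulate_truth()] object.
#' @param cal A [mass_calibration()]; defaults to the truth's fraction count
#'   over 2 MDa..100 kDa.
#' @return Tibble with one row per (protein, channel, peak):
#'   `protein`, `channel`, `peak`, `amplitude`, `center`, `sigma`.
#' @export
planted_peaks <- function(truth, cal = mass_calibration(truth$params$n_fractions)) {
  stopifnot(inherits(truth, "cofrac_truth"))
  pro <- truth$proteins
  cpx <- truth$complexes[match(pro$complex_id, truth$complexes$complex_id), ]
  ca <- truth$params$complex_amplitude

  # monomers lighter than the calibrated floor elute beyond the analysed
  # window (extrapolated fraction > F) and are effectively invisible;
  # assemblies heavier than the exclusion limit pile up in the void (f = 1)
  f_mono <- fraction_for_mass(cal, pmin(pro$monomer_mass, cal$mw_first),
                              extrapolate = TRUE)
  clamp <- function(m) pmin(pmax(m, cal$mw_last), cal$mw_first)
  f_cpx <- fraction_for_mass(cal, clamp(ifelse(is.na(cpx$mass),
                                               cal$mw_first, cpx$mass)))
  f_cpx2 <- fraction_for_mass(cal, clamp(ifelse(is.na(cpx$state2_mass),
                                                cal$mw_first,
                                                cpx$state2_mass)))
  width_at <- function(f) 1.5 + 0.02 * f
  # peak width: chromatographic broadening along the gradient times a
  # per-complex heterogeneity factor shared by all members
  wf <- ifelse(is.na(cpx$width_factor), 1, cpx$width_factor)

  in_cpx <- !is.na(pro$complex_id)
  s2 <- ifelse(is.na(cpx$state2_share), 0, cpx$state2_share)
  amp_cpx_unt <- ifelse(in_cpx, ca * (1 - s2) * pro$abundance, 0)
  amp_cpx2_unt <- ifelse(in_cpx, ca * s2 * pro$abundance, 0)
  amp_mono_unt <- ifelse(in_cpx, (1 - ca) * pro$abundance, pro$abundance)

  scale <- ifelse(is.na(cpx$perturbation), 1,
                  ifelse(cpx$perturbation == "fold_change", 2^cpx$log2_delta,
                         ifelse(cpx$perturbation == "disassembled", 0, 1)))
  amp_cpx_trt <- amp_cpx_unt * scale
  amp_cpx2_trt <- amp_cpx2_unt * scale
  moved <- ifelse(!is.na(cpx$perturbation) & cpx$perturbation == "disassembled",
                  amp_cpx_unt + amp_cpx2_unt, 0)
  amp_mono_trt <- amp_mono_unt + moved

  peak_tbl <- function(channel, amp_cpx, amp_cpx2, amp_mono) {
    bind_rows(
      tibble(protein = pro$protein, channel = channel, peak = "complex",
             amplitude = amp_cpx, center = f_cpx,
             sigma = wf * width_at(f_cpx))[in_cpx & amp_cpx > 0, ],
      tibble(protein = pro$protein, channel = channel, peak = "complex_state2",
             amplitude = amp_cpx2, center = f_cpx2,
             sigma = wf * width_at(f_cpx2))[in_cpx & amp_cpx2 > 0, ],
      tibble(protein = pro$protein, channel = channel, peak = "monomer",
             amplitude = amp_mono, center = f_mono,
             sigma = width_at(f_mono))
    )
  }
  bind_rows(
    peak_tbl("untreated", amp_cpx_unt, amp_cpx2_unt, amp_mono_unt),
    peak_tbl("treated", amp_cpx_trt, amp_cpx2_trt, amp_mono_trt)
  ) |>
    arrange(.data$protein, .data$channel, .data$peak)
}

#' Simulate fraction-wise SILAC elution profiles
#'
#' Emits per-protein chromatograms for every replicate and channel from a
#' planted ground truth. Each replicate samples the common fraction axis
#' through its drift map `f' = a_r * f + b_r`, so an assembly at true
#' centre `mu` appears at `(mu - b_r) / a_r` on that replicate's grid.
#' Multiplicative lognormal noise and intensity-dependent Bernoulli
#' missingness are applied last; values below the detection floor (1e-4)
#' are censored to missing. Identical seeds give bit-identical output.
#'
#' @inheritParams planted_peaks
#' @param seed Integer seed.
#' @param peptides If `TRUE`, also simulate the peptide-level table (see
#'   [simulate_peptides()]).
#' @return An object of class `cofrac_simulation`: a list with
#'   `chromatograms` (tibble `protein`, `replicate`, `channel`, `fraction`,
#'   `ratio`; `NA` = missing), `planted` (per-replicate observed-grid
#'   coordinates of every planted peak), `peptides` (tibble or `NULL`) and
#'   `calibration`.
#' @export
simulate_profiles <- function(truth,
                              cal = mass_calibration(truth$params$n_fractions),
                              seed = NULL, peptides = TRUE) {
  stopifnot(inherits(truth, "cofrac_truth"))
  peaks <- planted_peaks(truth, cal)
  n_f <- truth$params$n_fractions
  noise_sd <- truth$params$noise_sd
  miss <- truth$params$missing_rate

  with_seed(seed, {
    chroms <- vector("list", nrow(truth$replicates) * 2L)
    planted <- vector("list", nrow(truth$replicates))
    idx <- 1L
    for (r in seq_len(nrow(truth$replicates))) {
      a <- truth$replicates$slope[r]
      b <- truth$replicates$offset[r]
      f_obs <- a * seq_len(n_f) + b
      planted[[r]] <- peaks |>
        mutate(replicate = r,
               center_obs = (.data$center - b) / a,
               sigma_obs = .data$sigma / a)
      for (ch in c("untreated", "treated")) {
        pk <- peaks[peaks$channel == ch, ]
        # peak contributions on the replicate's observed grid
        contrib <- pk$amplitude *
          exp(-(outer(pk$center, f_obs, `-`))^2 / (2 * pk$sigma^2))
        prof <- rowsum(contrib, pk$protein)
        y_true <- as.vector(t(prof))  # protein-major, fraction-minor
        prot <- rep(rownames(prof), each = n_f)
        y <- y_true
        if (noise_sd > 0) {
          y <- y * exp(rnorm(length(y), 0, noise_sd))
        }
        if (miss > 0) {
          # logistic in the log of the underlying signal: weak peaks drop
          # out more often; dropout depends on the signal, not the noisy
          # measurement, so observed values are not noise-selected
          thr <- rep(0.05 * apply(prof, 1, max), each = n_f)
          p_miss <- pmin(0.95, 2 * miss *
                           stats::plogis(-(log2(pmax(y_true, 1e-12)) -
                                             log2(pmax(thr, 1e-12)))))
          y[runif(length(y)) < p_miss] <- NA_real_
        }
        y[!is.na(y) & y_true < 1e-4] <- NA_real_
        chroms[[idx]] <- tibble(protein = prot, replicate = r, channel = ch,
                                fraction = rep(seq_len(n_f), times = nrow(prof)),
                                ratio = y)
        idx <- idx + 1L
      }
    }
    sim <- structure(
      list(chromatograms = list_rbind(chroms),
           planted = list_rbind(planted),
           peptides = NULL,
           calibration = cal,
           truth = truth),
      class = "cofrac_simulation"
    )
    if (peptides) {
      sim$peptides <- simulate_peptides(truth, sim$chromatograms,
                                        seed = NULL)
    }
    sim
  })
}

#' Simulate a peptide-level quantification table
#'
#' Tiles peptides along each protein and assigns every peptide, in every
#' fraction where the protein is quantified in both channels, a
#' treated/untreated SILAC ratio. Peptides of uncleaved proteins scatter
#' around the protein-level ratio; for planted cleavage events, peptides
#' on the N-terminal side of the cut follow the fragment's fold change
#' (`2^true_log2`) inside a Gaussian window around the fragment's own
#' elution fraction, while C-terminal peptides keep the protein-level
#' ratio -- the fraction-local uneven peptide populations that the Shannon
#' statistics are designed to detect.
#'
#' @param truth A [simulate_truth()] object.
#' @param chromatograms Chromatogram tibble from [simulate_profiles()].
#' @param seed Integer seed (`NULL` continues the current RNG stream).
#' @param peptide_spacing Approximate residues per tiled peptide.
#' @param peptide_noise_sd Lognormal sd of peptide-level ratio scatter.
#' @return Tibble: `protein`, `peptide`, `start`, `end`, `replicate`,
#'   `fraction`, `ratio` (linear treated/untreated).
#' @export
simulate_peptides <- function(truth, chromatograms, seed = NULL,
                              peptide_spacing = 60, peptide_noise_sd = 0.15) {
  stopifnot(inherits(truth, "cofrac_truth"))
  with_seed(seed, {
    wide <- chromatograms |>
      pivot_wider(names_from = "channel", values_from = "ratio") |>
      filter(!is.na(.data$treated), !is.na(.data$untreated)) |>
      mutate(protein_ratio = .data$treated / .data$untreated) |>
      select("protein", "replicate", "fraction", "protein_ratio")

    pro <- truth$proteins
    n_pep <- pmax(6L, pmin(14L, as.integer(round(pro$length / peptide_spacing))))
    bounds <- map2(pro$length, n_pep, function(len, k) {
      s <- as.integer(round(seq(1, len, length.out = k + 1)))
      tibble(start = head(s, -1) + c(0L, rep(1L, k - 1L)), end = s[-1])
    })
    peps <- tibble(protein = rep(pro$protein, n_pep)) |>
      bind_cols(list_rbind(bounds)) |>
      group_by(.data$protein) |>
      mutate(peptide = sprintf("%s_pep%02d", .data$protein, row_number())) |>
      ungroup()

    # first cleavage event per protein drives peptide routing: peptides on
    # the N-terminal side of the cut follow the fragment's fold change in
    # the fractions where the fragment elutes (Gaussian window, sd 2)
    clv <- truth$cleavages |>
      distinct(.data$protein, .keep_all = TRUE) |>
      select("protein", cut = "position", frag_log2 = "true_log2",
             "frag_fraction")
    peps <- peps |>
      left_join(clv, by = "protein") |>
      mutate(n_side = !is.na(.data$cut) & .data$end < .data$cut)

    out <- inner_join(peps, wide, by = "protein",
                      relationship = "many-to-many")
    frag_boost <- ifelse(
      out$n_side,
      1 + (2^out$frag_log2 - 1) *
        exp(-(out$fraction - out$frag_fraction)^2 / (2 * 2^2)),
      1
    )
    out$ratio <- out$protein_ratio * frag_boost *
      exp(rnorm(nrow(out), 0, peptide_noise_sd))
    out |>
      select("protein", "peptide", "start", "end", "replicate",
             "fraction", "ratio") |>
      arrange(.data$protein, .data$peptide, .data$replicate, .data$fraction)
  })
}

#' Write simulated chromatograms as a MaxQuant-style wide TSV
#'
#' Serialises a long chromatogram tibble into the wide channel-by-fraction
#' dialect that [read_quant_table()] reads, closing the round trip between
#' the generator and the readers.
#'
#' @param chromatograms Long tibble (`protein`, `channel`, `fraction`,
#'   `ratio`; a `replicate` column, if present, must be filtered to one
#'   replicate first).
#' @param path Output path.
#' @param dialect A [quant_dialect()]; channels are mapped back through its
#'   `channel_map`.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(chromatograms, path, dialect = quant_dialect()) {
  if ("replicate" %in% names(chromatograms) &&
      length(unique(chromatograms$replicate)) > 1) {
    stop_cofrac("filter to a single replicate before writing a quant table",
                "cofrac_format_error")
  }
  ch <- chromatograms$channel
  if (!is.null(dialect$channel_map)) {
    rev_map <- set_names(names(dialect$channel_map),
                         unname(dialect$channel_map))
    mapped <- rev_map[ch]
    ch <- ifelse(is.na(mapped), ch, unname(mapped))
  }
  wide <- chromatograms |>
    mutate(col = sprintf("Ratio %s/L %d", ch, .data$fraction)) |>
    select("protein", "col", "ratio") |>
    pivot_wider(names_from = "col", values_from = "ratio")
  names(wide)[1] <- dialect$id_col
  wide[[dialect$reverse_col]] <- ""
  wide[[dialect$contaminant_col]] <- ""
  readr::write_tsv(wide, path, na = "NaN")
  invisible(path)
}

#' @export
print.cofrac_simulation <- function(x, ...) {
  cat(sprintf("<cofrac_simulation> %d chromatogram rows, %d planted peaks%s\n",
              nrow(x$chromatograms), nrow(x$planted),
              if (is.null(x$peptides)) "" else
                sprintf(", %d peptide measurements", nrow(x$peptides))))
  invisible(x)
}
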