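#' Match aligned features across replicates
#'
#' Groups features of the same protein whose aligned centres lie within
#' `max_delta` fractions of one another (greedy single-linkage along the
#' sorted centres), yielding the cross-replicate feature groups that the
#' differential tests operate on.
#'
#' @param features Aligned feature tibble (needs `center_aligned`).
#' @param max_delta Maximum centre gap within a group (fractions).
#' @return `features` with an added `feature_group` id.
#' @export
match_features <- function(features, max_delta = 2) {
  features |>
    arrange(.data$protein, .data$center_aligned) |>
    group_by(.data$protein) |>
    mutate(.new = c(0, diff(.data$center_aligned)) > max_delta,
           .grp = cumsum(.data$.new)) |>
    ungroup() |>
    mutate(feature_group = sprintf("%s#%d", .data$protein, .data$.grp)) |>
    select(-".new", -".grp")
}

#' Test features for stimulation-induced fold changes
#'
#' For every cross-replicate feature group, pools the per-fraction
#' `log2(treated/untreated)` measurements from all member features (each
#' member contributes the fractions inside its own `mu +/- 2 sigma`
#' window in its replicate) and applies a one-sample t-test against 0.
#' Family-wise error is controlled by Bonferroni correction over the
#' number of tested groups; significance additionally requires support
#' from at least two replicates. Groups with fewer than `min_measurements`
#' pooled measurements are flagged untested and excluded from the
#' Bonferroni denominator.
#'
#' @param features Aligned feature tibble with `feature_group` (see
#'   [match_features()]; if absent it is added).
#' @param chromatograms Long chromatogram tibble with both channels.
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_measurements Minimum pooled fraction-level measurements.
#' @return Tibble with one row per feature group: mean `log2fc`,
#'   per-replicate fold changes (`replicate_log2fc`, list column),
#'   `sd_replicates` (cross-replicate sd), `n_measurements`,
#'   `n_replicates`, `t`, `p`, `p_adj`, `tested`, `significant`.
#' @export
test_feature_changes <- function(features, chromatograms, alpha = 0.05,
                                 min_measurements = 3) {
  if (!"feature_group" %in% names(features)) {
    features <- match_features(features)
  }
  meas <- feature_measurements(features, chromatograms) |>
    left_join(select(features, "feature_id", "feature_group"),
              by = "feature_id") |>
    # overlapping windows of co-grouped features must not double-count a
    # fraction's measurement
    distinct(.data$feature_group, .data$replicate, .data$fraction,
             .keep_all = TRUE)
  per_rep <- meas |>
    group_by(.data$feature_group, .data$replicate) |>
    summarise(rep_log2fc = mean(.data$log2_ratio), .groups = "drop")
  res <- meas |>
    group_by(.data$feature_group) |>
    summarise(
      protein = sub("#\\d+$", "", .data$feature_group[1]),
      log2fc = mean(.data$log2_ratio),
      n_measurements = n(),
      n_replicates = n_distinct(.data$replicate),
      t = tryCatch(t.test(.data$log2_ratio)$statistic,
                   error = function(e) NA_real_),
      p = tryCatch(t.test(.data$log2_ratio)$p.value,
                   error = function(e) NA_real_),
      .groups = "drop"
    ) |>
    left_join(
      per_rep |>
        group_by(.data$feature_group) |>
        summarise(replicate_log2fc = list(.data$rep_log2fc),
                  sd_replicates = sd(.data$rep_log2fc)),
      by = "feature_group"
    )
  # groups with no measurements at all still appear, untested
  all_groups <- distinct(features, .data$feature_group, .data$protein)
  res <- all_groups |>
    left_join(select(res, -"protein"), by = "feature_group") |>
    mutate(n_measurements = coalesce(.data$n_measurements, 0L),
           n_replicates = coalesce(.data$n_replicates, 0L),
           tested = .data$n_measurements >= min_measurements & !is.na(.data$p))
  res$p_adj <- NA_real_
  res$p_adj[res$tested] <- p.adjust(res$p[res$tested], method = "bonferroni")
  res |>
    mutate(significant = .data$tested & .data$p_adj < alpha &
             .data$n_replicates >= 2)
}

#' Compare fold-change variability between two compartments
#'
#' Reports each compartment's mean cross-replicate standard deviation of
#' feature fold changes and a two-sample F-test for equal variances of the
#' feature-level log2 fold changes between the two compartments.
#'
#' @param results_a,results_b Outputs of [test_feature_changes()] for the
#'   two compartments.
#' @return One-row tibble: `mean_sd_a`, `mean_sd_b`, `f_statistic`, `p`.
#' @export
compare_compartment_variance <- function(results_a, results_b) {
  xa <- results_a$log2fc[results_a$tested]
  xb <- results_b$log2fc[results_b$tested]
  ft <- var.test(xa, xb)
  tibble(
    mean_sd_a = mean(results_a$sd_replicates, na.rm = TRUE),
    mean_sd_b = mean(results_b$sd_replicates, na.rm = TRUE),
    f_statistic = unname(ft$statistic),
    p = ft$p.value
  )
}

#' Shannon diversity and Pielou evenness of peptide ratios
#'
#' Given the positive SILAC ratios of one protein's peptides in one
#' fraction, normalises them to proportions `p_i = r_i / sum(r)` and
#' computes the Shannon index `H = -sum(p_i ln p_i)` (natural log, with
#' `0 ln 0 := 0`) and the evenness `E = H / ln(n)`. Low evenness
#' ("unevenness") signals peptide populations behaving differently, e.g.
#' stable cleavage fragments.
#'
#' @param ratios Positive numeric weights, `n >= 2`.
#' @return Named numeric vector `c(H = , E = )`.
#' @examples
#' shannon_evenness(c(2, 2, 2, 2))  # H = ln 4, E = 1
#' shannon_evenness(c(3, 1))
#' @export
shannon_evenness <- function(ratios) {
  if (length(ratios) < 2 || any(ratios < 0) || sum(ratios) <= 0) {
    stop_cofrac("shannon_evenness needs >= 2 non-negative ratios with a positive sum",
                "cofrac_evenness_error")
  }
  p <- ratios / sum(ratios)
  terms <- ifelse(p > 0, p * log(p), 0)
  h <- -sum(terms)
  c(H = h, E = h / log(length(ratios)))
}

#' Fraction-level evenness for every protein
#'
#' Applies [shannon_evenness()] to each (protein, replicate, fraction)
#' peptide group with at least `min_peptides` quantified peptides, and
#' summarises each protein's unevenness as `U = 1 - min(E)` over its
#' fraction-level evenness values (the most extreme fraction).
#'
#' @param peptides Tibble with `protein`, `peptide`, `replicate`,
#'   `fraction`, `ratio` (positive linear ratios).
#' @param min_peptides Minimum peptides per fraction (default 3; the
#'   `ln(2)` normalisation is unstable).
#' @return List with `fractions` (per-group `n`, `H`, `E`) and `proteins`
#'   (per-protein `U`, `n_fractions`).
#' @export
peptide_evenness <- function(peptides, min_peptides = 3) {
  grp <- peptides |>
    filter(.data$ratio > 0) |>
    group_by(.data$protein, .data$replicate, .data$fraction) |>
    filter(n() >= min_peptides) |>
    summarise(n = n(),
              H = log(sum(.data$ratio)) -
                sum(.data$ratio * log(.data$ratio)) / sum(.data$ratio),
              .groups = "drop") |>
    mutate(E = .data$H / log(.data$n))
  prot <- grp |>
    group_by(.data$protein) |>
    summarise(U = 1 - min(.data$E), n_fractions = n())
  list(fractions = grp, proteins = prot)
}

#' Call uneven proteins by fraction-wise permutation
#'
#' Builds a null for the protein-level unevenness `U = 1 - min(E)` by
#' shuffling peptide ratios across proteins within each (replicate,
#' fraction) stratum, recomputing `U` for every protein in each
#' permutation. Per-protein p-values use the `(b + 1) / (m + 1)`
#' convention and are BH-adjusted; proteins with `q < q_threshold` are
#' called uneven.
#'
#' @inheritParams peptide_evenness
#' @param n_perm Number of permutations (>= 999).
#' @param q_threshold BH false-discovery threshold (default 0.05).
#' @param seed Integer seed.
#' @return Tibble per protein: `U`, `p`, `q`, `uneven`.
#' @export
call_uneven_proteins <- function(peptides, n_perm = 999, q_threshold = 0.05,
                                 min_peptides = 3, seed = NULL) {
  stopifnot(n_perm >= 999)
  dat <- peptides |>
    filter(.data$ratio > 0) |>
    group_by(.data$protein, .data$replicate, .data$fraction) |>
    filter(n() >= min_peptides) |>
    ungroup()
  if (nrow(dat) == 0) {
    return(tibble(protein = character(), U = numeric(), p = numeric(),
                  q = numeric(), uneven = logical()))
  }
  grp_id <- as.integer(interaction(dat$protein, dat$replicate, dat$fraction,
                                   drop = TRUE))
  strat_id <- interaction(dat$replicate, dat$fraction, drop = TRUE)
  n_grp <- max(grp_id)
  first <- match(seq_len(n_grp), grp_id)
  grp_protein <- dat$protein[first]
  prot_f <- factor(grp_protein)
  proteins <- levels(prot_f)
  prot_i <- as.integer(prot_f)
  nn <- tabulate(grp_id)
  log_nn <- log(nn)

  u_of <- function(r) {
    s <- rowsum(r, grp_id)[, 1]
    sl <- rowsum(r * log(r), grp_id)[, 1]
    e <- (log(s) - sl / s) / log_nn
    # per-protein minimum fraction-level evenness
    u <- vapply(split(e, prot_i), min, numeric(1))
    1 - u
  }
  obs <- u_of(dat$ratio)
  with_seed(seed, {
    exceed <- numeric(length(proteins))
    strata <- split(seq_len(nrow(dat)), strat_id)
    for (b in seq_len(n_perm)) {
      idx <- unlist(lapply(strata, function(ix) ix[sample.int(length(ix))]),
                    use.names = FALSE)
      r_perm <- dat$ratio
      r_perm[unlist(strata, use.names = FALSE)] <- dat$ratio[idx]
      exceed <- exceed + (u_of(r_perm) >= obs)
    }
    p <- (exceed + 1) / (n_perm + 1)
    q <- p.adjust(p, method = "BH")
    tibble(protein = proteins, U = unname(obs), p = unname(p),
           q = unname(q), uneven = unname(q < q_threshold))
  })
}

#' Hypergeometric over-enrichment of a set overlap
#'
#' Exact one-sided tail probability of observing at least the given
#' overlap between two sets drawn from a finite universe.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector, the sampling frame.
#' @return One-row tibble: `overlap`, `n_a`, `n_b`, `n_universe`, `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  if (length(universe) == 0) {
    stop_cofrac("empty universe", "cofrac_enrichment_error")
  }
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  stopifnot(all(set_a %in% universe), all(set_b %in% universe))
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), length(universe) - length(set_a),
              length(set_b), lower.tail = FALSE)
  tibble(overlap = k, n_a = length(set_a), n_b = length(set_b),
         n_universe = length(universe), p = p)
}

#' Detect discordant proteoform segments along a protein
#'
#' Orders a protein's peptides by start position and searches for a single
#' change point in their feature-window mean log2 fold changes (binary
#' segmentation: the split maximising the between-segment two-sample
#' t statistic). The change point is accepted if its t-test p-value falls
#' below `alpha`, and reported as the residue interval between the
#' flanking peptides. Proteins with fewer than `min_peptides` quantified
#' peptides are not segmented.
#'
#' @param peptide_fc Tibble with `protein`, `peptide`, `start`, `end`
#'   (optional), `log2fc` per peptide.
#' @param min_peptides Minimum quantified peptides (default 6).
#' @param alpha Change-point acceptance p-value (default 0.01).
#' @return Tibble per protein: `n_peptides`, `changepoint` (index of last
#'   left-segment peptide or `NA`), `boundary_lo`, `boundary_hi` (residue
#'   interval), `t`, `p`, `segmented`.
#' @export
detect_proteoform_segments <- function(peptide_fc, min_peptides = 6,
                                       alpha = 0.01) {
  peptide_fc |>
    filter(!is.na(.data$log2fc)) |>
    arrange(.data$protein, .data$start) |>
    group_by(.data$protein) |>
    group_modify(function(df, key) {
      n <- nrow(df)
      if (n < min_peptides) {
        return(tibble(n_peptides = n, changepoint = NA_integer_,
                      boundary_lo = NA_integer_, boundary_hi = NA_integer_,
                      t = NA_real_, p = NA_real_, segmented = FALSE))
      }
      best <- list(t = 0, p = 1, i = NA_integer_)
      for (i in 2:(n - 2)) {
        left <- df$log2fc[1:i]
        right <- df$log2fc[(i + 1):n]
        tt <- tryCatch(t.test(left, right), error = function(e) NULL)
        if (!is.null(tt) && is.finite(tt$statistic) &&
            abs(tt$statistic) > abs(best$t)) {
          best <- list(t = unname(tt$statistic), p = tt$p.value, i = i)
        }
      }
      accepted <- !is.na(best$i) && best$p < alpha
      lo <- if (accepted) {
        if ("end" %in% names(df)) df$end[best$i] else df$start[best$i]
      } else NA_integer_
      hi <- if (accepted) df$start[best$i + 1] else NA_integer_
      tibble(n_peptides = n,
             changepoint = if (accepted) best$i else NA_integer_,
             boundary_lo = as.integer(lo), boundary_hi = as.integer(hi),
             t = best$t, p = best$p, segmented = accepted)
    }) |>
    ungroup()
}
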