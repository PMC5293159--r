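#' Classify quantified N-termini against protein sequences
#'
#' A terminus is `natural` (the mature protein N-terminus, possibly after
#' initiator-Met removal) when it starts at position 1 or 2 and carries an
#' alpha-amine modification (acetylation in vivo or dimethylation from the
#' TAILS chemistry); any terminus starting at position 3 or later is a
#' `neo`-N-terminus created by proteolysis. For neo termini the P1 residue
#' (immediately preceding the cut) and the P5..P6' sequence window around
#' the cleavage site are extracted, padded with `-` at sequence ends.
#' Records whose accession is absent from the supplied proteome are
#' dropped with a message.
#'
#' @param records Terminus tibble with `protein`, `start`, `modification`.
#' @param sequences Named character vector of protein sequences (see
#'   [read_proteome_fasta()]).
#' @return `records` with added `class`, `p1`, `window` (11-character
#'   P5..P6' string).
#' @export
classify_termini <- function(records, sequences) {
  known <- records$protein %in% names(sequences)
  if (any(!known)) {
    inform(sprintf("classify_termini: dropped %d record(s) with no sequence",
                   sum(!known)))
    records <- records[known, ]
  }
  seqs <- sequences[records$protein]
  len <- nchar(seqs)
  bad <- records$start < 1 | records$start > len
  if (any(bad)) {
    stop_cofrac(sprintf("%d terminus position(s) outside the protein sequence",
                        sum(bad)), "cofrac_nterm_error")
  }
  natural <- records$start <= 2 & records$modification %in% c("acetyl", "dimethyl")
  p1 <- unname(ifelse(!natural & records$start >= 3,
                      substr(seqs, records$start - 1, records$start - 1),
                      NA_character_))
  window <- map2_chr(unname(seqs), records$start, function(s, st) {
    pos <- (st - 5):(st + 5)
    chars <- ifelse(pos >= 1 & pos <= nchar(s),
                    substring(s, pos, pos), "-")
    paste(chars, collapse = "")
  })
  records |>
    mutate(class = ifelse(natural, "natural", "neo"),
           p1 = p1, window = window)
}

#' Summarise replicate measurements and flag significant termini
#'
#' Averages per-replicate log2 ratios for each treatment arm, tests each
#' terminus's stimulated-arm ratios against 0 with a two-sided t-test, and
#' flags significance after Benjamini-Hochberg adjustment (threshold 0.2,
#' the convention for terminome fold-change analysis).
#'
#' @param records Terminus tibble with replicate columns `fas_*` and
#'   optionally `zvad_*`.
#' @param q_threshold BH threshold (default 0.2).
#' @return `records` with added `log2_fas`, `log2_zvad`, `p_fas`,
#'   `q_fas`, `sig_fas`.
#' @export
flag_significant_termini <- function(records, q_threshold = 0.2) {
  fas_cols <- grep("^fas_\\d+$", names(records), value = TRUE)
  zvad_cols <- grep("^zvad_\\d+$", names(records), value = TRUE)
  stopifnot(length(fas_cols) >= 1)
  fas <- as.matrix(records[fas_cols])
  records$log2_fas <- rowMeans(fas, na.rm = TRUE)
  records$log2_zvad <- if (length(zvad_cols) > 0) {
    rowMeans(as.matrix(records[zvad_cols]), na.rm = TRUE)
  } else {
    NA_real_
  }
  records$p_fas <- apply(fas, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || sd(x) == 0) return(NA_real_)
    t.test(x)$p.value
  })
  records$q_fas <- p.adjust(records$p_fas, method = "BH")
  records$sig_fas <- !is.na(records$q_fas) & records$q_fas < q_threshold
  records
}

# ---- Gaussian mixture EM ---------------------------------------------------

em_mixture_once <- function(x, k, means0, sd_floor = 1e-3, max_iter = 500,
                            tol = 1e-8) {
  n <- length(x)
  mu <- means0
  sg <- rep(max(sd(x), sd_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sg[j]),
                   numeric(n))
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    # EM guarantee: the observed-data log-likelihood never decreases
    if (!is.finite(ll) || ll < ll_old - 1e-6) {
      stop_cofrac("EM log-likelihood decreased or degenerated; numerical failure",
                  "cofrac_mixture_error")
    }
    resp <- dens / rowsum_d
    nk <- pmax(colSums(resp), 1e-10)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, `-`))^2) / nk)
    sg <- pmax(sg, sd_floor)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      return(list(mu = mu, sg = sg, w = w, loglik = ll, resp = resp,
                  converged = TRUE, n_iter = it, ll_trace = ll_trace))
    }
    ll_old <- ll
  }
  list(mu = mu, sg = sg, w = w, loglik = ll_old, resp = resp,
       converged = FALSE, n_iter = max_iter, ll_trace = ll_trace)
}

#' Fit a normal mixture to N-terminus log2 ratios
#'
#' Models the bimodal distribution of neo-N-terminus SILAC ratios -- a
#' degradation population and a stable-processing population -- as a
#' k-component normal mixture fitted by expectation-maximisation with
#' `n_restarts` seeded restarts (k-means initialisation); the best
#' log-likelihood is kept. Components are reported in ascending mean
#' order; standard deviations are floored at `1e-3`, so degenerate
#' (constant) input collapses to a single effective component.
#'
#' @param x Numeric log2 ratios (at least 50 values).
#' @param k Number of components (default 2).
#' @param seed Integer seed for the restarts.
#' @param n_restarts EM restarts (default 5).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return Object of class `cofrac_mixture`: `means`, `sds`, `weights`
#'   (ascending mean order), `loglik`, `converged`, `posteriors`,
#'   `n_iter`, `k`, `n`.
#' @export
fit_ratio_mixture <- function(x, k = 2, seed = NULL, n_restarts = 5,
                              max_iter = 500, tol = 1e-8) {
  x <- x[!is.na(x)]
  if (length(x) < 50) {
    stop_cofrac("mixture fitting requires >= 50 values",
                "cofrac_mixture_error")
  }
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      means0 <- if (length(unique(x)) >= k) {
        sort(kmeans(x, centers = k, nstart = 1)$centers[, 1])
      } else {
        # (near-)degenerate input: spread initial means by the sd floor
        mean(x) + max(sd(x), 1e-3) * seq(-1, 1, length.out = k)
      }
      fit <- tryCatch(
        em_mixture_once(x, k, means0, max_iter = max_iter, tol = tol),
        cofrac_mixture_error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    if (is.null(best)) {
      stop_cofrac("EM failed to converge in all restarts",
                  "cofrac_mixture_error")
    }
    ord <- order(best$mu)
    structure(
      list(means = best$mu[ord], sds = best$sg[ord], weights = best$w[ord],
           loglik = best$loglik, converged = best$converged,
           posteriors = best$resp[, ord, drop = FALSE],
           n_iter = best$n_iter, ll_trace = best$ll_trace,
           k = k, n = length(x), data = x),
      class = "cofrac_mixture"
    )
  })
}

#' @export
print.cofrac_mixture <- function(x, ...) {
  cat(sprintf("<cofrac_mixture> %d-component normal mixture (n = %d, logLik %.2f%s)\n",
              x$k, x$n, x$loglik, if (x$converged) "" else ", not converged"))
  for (j in seq_len(x$k)) {
    cat(sprintf("  component %d: mean %.3f, sd %.3f, weight %.3f\n",
                j, x$means[j], x$sds[j], x$weights[j]))
  }
  invisible(x)
}

#' Cross-tabulate neo-termini by P1 residue and response direction
#'
#' Direction calls use the +/-1 log2 thresholds: `increased` when the arm
#' mean exceeds +1, `decreased` below -1, `unchanged` otherwise (strict
#' inequalities). Counts are reported per treatment arm and P1 residue,
#' with the concordant subset (same non-unchanged direction in both arms)
#' counted separately.
#'
#' @param records Classified terminus tibble with `class`, `p1`,
#'   `log2_fas`, `log2_zvad`.
#' @param threshold Direction threshold on |log2 ratio| (default 1).
#' @return Tibble: `arm`, `p1`, `direction`, `n`, `n_concordant`.
#' @export
classify_populations <- function(records, threshold = 1) {
  neo <- filter(records, .data$class == "neo", !is.na(.data$p1))
  dir_of <- function(x) {
    case_when(x > threshold ~ "increased",
              x < -threshold ~ "decreased",
              TRUE ~ "unchanged")
  }
  neo <- neo |>
    mutate(dir_fas = dir_of(.data$log2_fas),
           dir_zvad = dir_of(.data$log2_zvad),
           concordant = .data$dir_fas == .data$dir_zvad &
             .data$dir_fas != "unchanged")
  bind_rows(
    neo |>
      count(.data$p1, direction = .data$dir_fas,
            wt = NULL, name = "n") |>
      mutate(arm = "fas"),
    neo |>
      count(.data$p1, direction = .data$dir_zvad, name = "n") |>
      mutate(arm = "fas_zvad")
  ) |>
    left_join(
      neo |>
        filter(.data$concordant) |>
        count(.data$p1, direction = .data$dir_fas, name = "n_concordant"),
      by = c("p1", "direction")
    ) |>
    mutate(n_concordant = coalesce(.data$n_concordant, 0L)) |>
    select("arm", "p1", "direction", "n", "n_concordant")
}

#' Termini stabilised by pan-caspase inhibition
#'
#' A terminus is called stabilised when pre-treatment with the pan-caspase
#' inhibitor suppresses its response: the stimulated-arm ratio exceeds the
#' inhibitor-arm ratio by at least `delta` log2 units and the
#' stimulated-arm change is BH-significant. Stabilised termini are grouped
#' into the three subpopulations seen in such data: Asp(P1) cleavage,
#' Arg(P1) cleavage, and natural termini.
#'
#' @param records Classified, flagged terminus tibble (needs `log2_fas`,
#'   `log2_zvad`, `sig_fas`, `class`, `p1`).
#' @param delta Minimum log2 suppression (default 1).
#' @return Tibble of stabilised termini with `subpopulation`.
#' @export
zvad_sensitivity <- function(records, delta = 1) {
  records |>
    filter(!is.na(.data$log2_fas), !is.na(.data$log2_zvad)) |>
    filter((.data$log2_fas - .data$log2_zvad) >= delta, .data$sig_fas) |>
    mutate(subpopulation = case_when(
      .data$class == "natural" ~ "natural",
      .data$p1 == "D" ~ "asp_cleavage",
      .data$p1 == "R" ~ "arg_cleavage",
      TRUE ~ "other"
    ))
}

#' Positional residue enrichment of aligned cleavage windows
#'
#' For each position of the P5..P6' alignment and each residue, compares
#' the observed count across windows to the residue's background frequency
#' in the supplied proteome by a binomial test, reporting a signed
#' log-odds matrix with BH-adjusted p-values (threshold 0.02). The
#' canonical executioner-caspase pattern is flagged when P4 = D, P3 = E,
#' P1 = D and P1' = G are all significantly enriched.
#'
#' @param windows Character vector of 11-character P5..P6' windows (gap
#'   `-` allowed), at least 10; fewer are skipped (`NULL` with message).
#' @param background Named character vector of proteome sequences for
#'   background residue frequencies.
#' @param q_threshold BH threshold over all (position, residue) cells.
#' @return List with `cells` (tibble: `position`, `residue`, `observed`,
#'   `expected`, `log_odds`, `p`, `q`, `enriched`) and `caspase_motif`
#'   (logical flag for the D-E-x-D|G pattern), or `NULL` if skipped.
#' @export
motif_enrichment <- function(windows, background, q_threshold = 0.02) {
  if (length(windows) < 10) {
    inform(sprintf("motif_enrichment: %d window(s) < 10; skipped",
                   length(windows)))
    return(NULL)
  }
  stopifnot(all(nchar(windows) == 11))
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bg_counts <- table(factor(strsplit(paste(background, collapse = ""), "")[[1]],
                            levels = aas))
  bg_freq <- as.numeric(bg_counts) / sum(bg_counts)
  names(bg_freq) <- aas
  pos_labels <- c(paste0("P", 5:1), paste0("P", 1:6, "'"))

  cells <- crossing(position = seq_len(11), residue = aas) |>
    mutate(pos_label = pos_labels[.data$position])
  wmat <- do.call(rbind, strsplit(windows, ""))
  cells <- cells |>
    mutate(
      n_windows = map_int(.data$position, ~ sum(wmat[, .x] != "-")),
      observed = map2_int(.data$position, .data$residue,
                          ~ sum(wmat[, .x] == .y)),
      expected = .data$n_windows * bg_freq[.data$residue],
      log_odds = log2((.data$observed + 0.5) / (.data$expected + 0.5))
    )
  cells$p <- pmap_dbl(cells, function(observed, n_windows, residue, ...) {
    if (n_windows == 0) return(NA_real_)
    binom.test(observed, n_windows, bg_freq[residue])$p.value
  })
  cells$q <- p.adjust(cells$p, method = "BH")
  cells$enriched <- !is.na(cells$q) & cells$q < q_threshold & cells$log_odds > 0

  enr <- function(pos, res) {
    any(cells$enriched[cells$position == pos & cells$residue == res])
  }
  caspase <- enr(2, "D") && enr(3, "E") && enr(5, "D") && enr(6, "G")
  list(cells = select(cells, "position", "pos_label", "residue", "observed",
                      "expected", "log_odds", "p", "q", "enriched"),
       caspase_motif = caspase)
}

#' Correlate N-terminome changes with interactome changes
#'
#' Forms all combinations of each shared protein's neo-terminus log2
#' ratios and its Gaussian-feature log2 fold changes, and reports the
#' Spearman rank correlation (average-rank ties) across all pairs. A weak
#' correlation indicates that proteolytic processing and interactome
#' rearrangement are not tightly linked. Optionally also summarises mean
#' protein unevenness by detected terminus count.
#'
#' @param records Terminus tibble with `protein`, `class`, `log2_fas`.
#' @param features Feature tibble with `protein`, `log2fc` (see
#'   [feature_ratio()]).
#' @param unevenness Optional per-protein unevenness tibble (`protein`,
#'   `U`) from [peptide_evenness()].
#' @param min_pairs Minimum (terminus, feature) combinations (default 10).
#' @return List with `rho`, `n_pairs`, `pairs` (the combination table),
#'   and `unevenness_by_count` (or `NULL`).
#' @export
correlate_with_interactome <- function(records, features, unevenness = NULL,
                                       min_pairs = 10) {
  nt <- records |>
    filter(.data$class == "neo", !is.na(.data$log2_fas)) |>
    select("protein", nterm_log2 = "log2_fas")
  fe <- features |>
    filter(!is.na(.data$log2fc)) |>
    select("protein", feature_log2 = "log2fc")
  pairs <- inner_join(nt, fe, by = "protein", relationship = "many-to-many")
  if (nrow(pairs) < min_pairs) {
    warn(sprintf("only %d (terminus, feature) pair(s); correlation undefined",
                 nrow(pairs)))
    rho <- NA_real_
  } else {
    rho <- cor(pairs$nterm_log2, pairs$feature_log2, method = "spearman")
  }
  ubc <- NULL
  if (!is.null(unevenness)) {
    ubc <- nt |>
      count(.data$protein, name = "n_termini") |>
      inner_join(unevenness, by = "protein") |>
      group_by(.data$n_termini) |>
      summarise(mean_unevenness = mean(abs(.data$U)), n_proteins = n())
  }
  list(rho = rho, n_pairs = nrow(pairs), pairs = pairs,
       unevenness_by_count = ubc)
}
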