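#' Score candidate protein pairs by co-elution
#'
#' Within each (replicate, channel), two proteins become a candidate pair
#' when each has a fitted feature and their (aligned) centres co-apex
#' within `w_coapex` fractions. Each candidate is scored by (i) the
#' co-apex distance `|delta mu|` (the smallest across the proteins'
#' feature combinations) and (ii) the Euclidean distance between the two
#' cleaned, unit-maximum-scaled profiles over their co-quantified
#' fractions; pairs sharing fewer than `min_shared` fractions are dropped.
#' The combined score is the sum of the two within-channel ranks (lower =
#' better co-elution), giving a single sweepable decision axis.
#'
#' @param features Feature tibble (aligned centres used when present).
#' @param chromatograms Long chromatogram tibble.
#' @param w_coapex Co-apex window in fractions (default 2).
#' @param min_shared Minimum co-quantified fractions (default 10).
#' @return Candidate tibble: `replicate`, `channel`, `protein_a`,
#'   `protein_b` (canonical order), `coapex`, `dist`, `n_shared`, `score`.
#' @export
score_candidate_pairs <- function(features, chromatograms, w_coapex = 2,
                                  min_shared = 10) {
  feats <- features
  if (!"center_aligned" %in% names(feats)) {
    feats <- mutate(feats, center_aligned = .data$center)
  }
  cleaned <- clean_profiles(chromatograms)
  n_f <- max(chromatograms$fraction)

  groups <- distinct(feats, .data$replicate, .data$channel)
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    fg <- filter(feats, .data$replicate == groups$replicate[g],
                 .data$channel == groups$channel[g])
    cg <- filter(cleaned, .data$replicate == groups$replicate[g],
                 .data$channel == groups$channel[g])
    # profile matrix, unit-max scaled, NA where not present
    mat <- matrix(NA_real_, nrow = n_distinct(cg$protein), ncol = n_f,
                  dimnames = list(sort(unique(cg$protein)), NULL))
    vals <- cg$clean
    vals[!cg$present] <- NA
    mat[cbind(match(cg$protein, rownames(mat)), cg$fraction)] <- vals
    rmax <- suppressWarnings(apply(mat, 1, max, na.rm = TRUE))
    rmax[!is.finite(rmax) | rmax <= 0] <- 1
    mat <- mat / rmax

    fg <- arrange(fg, .data$center_aligned)
    # all feature pairs with |delta mu| <= w_coapex via sorted sweep
    idx <- seq_len(nrow(fg))
    pairs <- list()
    hi <- 1L
    for (i in idx) {
      if (hi < i) hi <- i
      while (hi < nrow(fg) &&
             fg$center_aligned[hi + 1] - fg$center_aligned[i] <= w_coapex) {
        hi <- hi + 1L
      }
      if (hi > i) {
        pairs[[i]] <- tibble(i = i, j = seq(i + 1L, hi))
      }
    }
    pairs <- list_rbind(pairs)
    if (is.null(pairs) || nrow(pairs) == 0) {
      next
    }
    cand <- tibble(
      pa = fg$protein[pairs$i], pb = fg$protein[pairs$j],
      coapex = abs(fg$center_aligned[pairs$j] - fg$center_aligned[pairs$i])
    ) |>
      filter(.data$pa != .data$pb)
    if (nrow(cand) == 0) next
    cp <- canonical_pair(cand$pa, cand$pb)
    cand <- bind_cols(cp, coapex = cand$coapex) |>
      group_by(.data$protein_a, .data$protein_b) |>
      summarise(coapex = min(.data$coapex), .groups = "drop")

    ia <- match(cand$protein_a, rownames(mat))
    ib <- match(cand$protein_b, rownames(mat))
    keep <- !is.na(ia) & !is.na(ib)
    cand <- cand[keep, ]; ia <- ia[keep]; ib <- ib[keep]
    A <- mat[ia, , drop = FALSE]
    B <- mat[ib, , drop = FALSE]
    shared <- !is.na(A) & !is.na(B)
    d <- A - B
    d[!shared] <- 0
    cand$n_shared <- unname(rowSums(shared))
    cand$dist <- unname(sqrt(rowSums(d^2)))
    cand <- filter(cand, .data$n_shared >= min_shared)
    if (nrow(cand) == 0) next
    cand$score <- rank(cand$dist) + rank(cand$coapex)
    cand$replicate <- groups$replicate[g]
    cand$channel <- groups$channel[g]
    out[[g]] <- cand
  }
  res <- list_rbind(out)
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(replicate = integer(), channel = character(),
                  protein_a = character(), protein_b = character(),
                  coapex = numeric(), dist = numeric(),
                  n_shared = integer(), score = numeric()))
  }
  select(res, "replicate", "channel", "protein_a", "protein_b",
         "coapex", "dist", "n_shared", "score")
}

#' Label candidate pairs against the gold-standard complex database
#'
#' A pair is `positive` when both proteins co-occur in at least one gold
#' complex, `negative` when both occur in the database but never together,
#' and `unlabeled` otherwise.
#'
#' @param candidates Candidate tibble from [score_candidate_pairs()].
#' @param db Complex database from [read_complex_db()] (or any tibble with
#'   a `members` list column).
#' @return `candidates` with an added `label` column.
#' @export
label_pairs <- function(candidates, db) {
  pos <- db$members |>
    keep(~ length(.x) >= 2) |>
    map(function(m) {
      cmb <- combn(sort(m), 2)
      paste(cmb[1, ], cmb[2, ], sep = "\r")
    }) |>
    unlist() |>
    unique()
  covered <- unique(unlist(db$members))
  key <- paste(candidates$protein_a, candidates$protein_b, sep = "\r")
  label <- case_when(
    key %in% pos ~ "positive",
    candidates$protein_a %in% covered & candidates$protein_b %in% covered ~
      "negative",
    TRUE ~ "unlabeled"
  )
  counts <- table(label)
  inform(sprintf("label_pairs: %s",
                 paste(names(counts), counts, sep = "=", collapse = ", ")))
  mutate(candidates, label = label)
}

precision_report <- function(level, tp, fp, n_neg, n_pos, threshold = NA_real_) {
  tibble(level = level, tp = tp, fp = fp,
         precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
         fpr = ifelse(n_neg > 0, fp / n_neg, NA_real_),
         recall = ifelse(n_pos > 0, tp / n_pos, NA_real_),
         n_negative_space = n_neg, n_positive_space = n_pos,
         threshold = threshold)
}

#' Calibrate a score cutoff to a target precision (local network)
#'
#' Sweeps the combined-score cutoff from best to worst candidate and
#' accepts the largest prefix whose running precision over the labelled
#' members stays at or above the target. Unlabelled pairs inside the
#' cutoff are accepted as predictions. Applied per (replicate, channel)
#' when those columns are present, yielding one local network per channel.
#'
#' @param candidates Labelled candidate tibble ([label_pairs()]).
#' @param target_precision Desired precision (the study used 0.70, 0.60,
#'   0.50).
#' @param min_labeled Minimum labelled candidates per channel (default 50).
#' @return List with `edges` (accepted candidates) and `report` (one
#'   local [precision report][global_report] row per channel).
#' @export
calibrate_threshold <- function(candidates, target_precision = 0.70,
                                min_labeled = 50) {
  if (!"replicate" %in% names(candidates)) candidates$replicate <- 1L
  if (!"channel" %in% names(candidates)) candidates$channel <- "all"
  groups <- distinct(candidates, .data$replicate, .data$channel)
  edges <- list(); reports <- list()
  for (g in seq_len(nrow(groups))) {
    cand <- filter(candidates, .data$replicate == groups$replicate[g],
                   .data$channel == groups$channel[g]) |>
      arrange(.data$score, .data$dist, .data$coapex,
              .data$protein_a, .data$protein_b)
    n_labeled <- sum(cand$label != "unlabeled")
    if (n_labeled < min_labeled) {
      warn(sprintf("channel %s/r%s: only %d labeled candidates (< %d); skipped",
                   groups$channel[g], groups$replicate[g], n_labeled,
                   min_labeled))
      next
    }
    tp_run <- cumsum(cand$label == "positive")
    fp_run <- cumsum(cand$label == "negative")
    lab_run <- tp_run + fp_run
    prec_run <- ifelse(lab_run > 0, tp_run / lab_run, NA_real_)
    ok <- which(!is.na(prec_run) & prec_run >= target_precision)
    if (length(ok) == 0) {
      warn(sprintf("channel %s/r%s: target precision %.2f unreachable; empty network",
                   groups$channel[g], groups$replicate[g], target_precision))
      reports[[length(reports) + 1]] <- precision_report(
        "local", 0L, 0L, sum(cand$label == "negative"),
        sum(cand$label == "positive")) |>
        mutate(replicate = groups$replicate[g], channel = groups$channel[g])
      next
    }
    cut <- max(ok)
    acc <- cand[seq_len(cut), ]
    edges[[length(edges) + 1]] <- acc
    reports[[length(reports) + 1]] <- precision_report(
      "local", tp_run[cut], fp_run[cut], sum(cand$label == "negative"),
      sum(cand$label == "positive"), threshold = cand$score[cut]) |>
      mutate(replicate = groups$replicate[g], channel = groups$channel[g])
  }
  list(edges = list_rbind(edges), report = list_rbind(reports))
}

#' Combine local networks into a global, non-redundant network
#'
#' Unions accepted edges across channels and replicates (deduplicated,
#' with the supporting detections recorded), and reports global precision,
#' false-positive rate and recall over the labelled part of the union.
#' The FPR denominator is the full labelled negative candidate space that
#' was evaluated.
#'
#' @param local_edges Accepted edges from [calibrate_threshold()] (may
#'   span several channels/replicates).
#' @param candidates The labelled candidate space the networks were
#'   calibrated on.
#' @return List with `edges` (unique pairs with `support` list column,
#'   `n_support`, `label`, best `score`) and `report` (one global row).
#' @export
global_report <- function(local_edges, candidates) {
  if (is.null(local_edges) || nrow(local_edges) == 0) {
    return(list(edges = tibble(), report = precision_report("global", 0L, 0L,
      n_neg = n_distinct_labeled(candidates, "negative"),
      n_pos = n_distinct_labeled(candidates, "positive"))))
  }
  edges <- local_edges |>
    group_by(.data$protein_a, .data$protein_b) |>
    summarise(
      label = .data$label[1],
      score = min(.data$score),
      support = list(sprintf("%s:%s", .data$replicate, .data$channel)),
      n_support = n(),
      .groups = "drop"
    )
  tp <- sum(edges$label == "positive")
  fp <- sum(edges$label == "negative")
  rep <- precision_report("global", tp, fp,
                          n_neg = n_distinct_labeled(candidates, "negative"),
                          n_pos = n_distinct_labeled(candidates, "positive"))
  list(edges = edges, report = rep)
}

n_distinct_labeled <- function(candidates, lab) {
  candidates |>
    filter(.data$label == lab) |>
    distinct(.data$protein_a, .data$protein_b) |>
    nrow()
}

#' All-or-nothing (condition-specific) interactions
#'
#' An edge is condition-specific when it is detected in at least two
#' replicates of exactly one condition and in none of the other: `gained`
#' when only in the stimulated state, `lost` when only in the unstimulated
#' state.
#'
#' @param edges Edge tibble with `protein_a`, `protein_b`, `replicate` and
#'   a condition column (`channel` holding e.g. `treated`/`untreated`).
#' @param stimulated,unstimulated Channel values naming the two states.
#' @return Tibble of all-or-nothing pairs with `status` (`gained`/`lost`)
#'   and per-condition replicate counts.
#' @export
condition_specific_edges <- function(edges, stimulated = "treated",
                                     unstimulated = "untreated") {
  tab <- edges |>
    group_by(.data$protein_a, .data$protein_b) |>
    summarise(
      n_stim = n_distinct(.data$replicate[.data$channel == stimulated]),
      n_unstim = n_distinct(.data$replicate[.data$channel == unstimulated]),
      .groups = "drop"
    )
  tab |>
    filter((.data$n_stim >= 2 & .data$n_unstim == 0) |
             (.data$n_unstim >= 2 & .data$n_stim == 0)) |>
    mutate(status = ifelse(.data$n_stim > 0, "gained", "lost"))
}

#' Power-law fit of the vertex degree distribution
#'
#' Ordinary least squares of `log10(count)` against `log10(degree)` over
#' the degree histogram of a network (zero-count degrees excluded), the
#' standard scale-free diagnostic. Undefined (all-`NA` result with a
#' warning) when fewer than 5 distinct degrees are observed.
#'
#' @param edges Edge tibble with `protein_a`, `protein_b` (unique pairs).
#' @param degrees Optional pre-computed vertex degree vector; overrides
#'   `edges`.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`,
#'   `n_degrees`.
#' @export
degree_powerlaw <- function(edges, degrees = NULL) {
  deg <- degrees %||% table(c(edges$protein_a, edges$protein_b))
  hist <- table(as.integer(deg))
  if (length(hist) < 5) {
    warn("degree power-law fit undefined: fewer than 5 distinct degrees")
    return(tibble(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, n_degrees = length(hist)))
  }
  x <- log10(as.numeric(names(hist)))
  y <- log10(as.numeric(hist))
  fit <- lm(y ~ x)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n_degrees = length(hist))
}

#' Membrane GO-term overlap statistics of a network
#'
#' Computes the fraction of edges with at least one membrane-annotated
#' partner, and the fraction whose two proteins share the same
#' membrane-related cellular-component GO term.
#'
#' @param edges Edge tibble (unique pairs).
#' @param annotations GO annotation tibble from [read_go_annotations()].
#' @return One-row tibble with both fractions and their counts.
#' @export
go_overlap_stats <- function(edges, annotations) {
  memb <- filter(annotations, .data$is_membrane)
  if (nrow(memb) == 0) {
    warn("no membrane annotations supplied; overlap statistics are 0")
  }
  memb_terms <- memb |>
    group_by(.data$accession) |>
    summarise(terms = list(unique(.data$go_id)))
  get_terms <- function(p) {
    i <- match(p, memb_terms$accession)
    ifelse(is.na(i), list(character()), memb_terms$terms[i])
  }
  ta <- get_terms(edges$protein_a)
  tb <- get_terms(edges$protein_b)
  any_membrane <- lengths(ta) > 0 | lengths(tb) > 0
  shared <- map2_lgl(ta, tb, ~ length(intersect(.x, .y)) > 0)
  n <- nrow(edges)
  tibble(
    n_edges = n,
    n_any_membrane = sum(any_membrane),
    frac_any_membrane = ifelse(n > 0, sum(any_membrane) / n, 0),
    n_shared_term = sum(shared),
    frac_shared_term = ifelse(n > 0, sum(shared) / n, 0)
  )
}
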