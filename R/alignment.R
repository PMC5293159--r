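#' Fit an affine fraction map between two replicates
#'
#' Independent fractionation runs drift relative to one another, so feature
#' centres from different biological replicates live on slightly different
#' fraction axes. Anchors are proteins with exactly one well-fitted feature
#' (R-squared >= `r2_min`) in both replicates; the map
#' `mu_rep ~ a * mu_ref + b` is estimated by iteratively trimmed least
#' squares seeded with a robust Theil-Sen line: drop anchors with
#' residuals beyond 3 x MAD, refit by least squares, for at most five
#' rounds.
#'
#' @param features_ref,features_rep Feature tibbles (one replicate each)
#'   from [fit_profiles()].
#' @param r2_min Anchor acceptance threshold on feature R-squared.
#' @param min_anchors Minimum anchors required (default 10); fewer raises
#'   an alignment error, and the replicate should be excluded.
#' @param n_fractions Fraction count of the separation; anchor features
#'   must have centres in `[3, n_fractions - 3]`, since edge-truncated
#'   peaks carry unreliable centre estimates. A fitted map outside the
#'   valid drift range (`0.8 <= a <= 1.25`, `|b| <= 10`) also raises an
#'   alignment error.
#' @return Object of class `fraction_map`: replicate id, slope `a`,
#'   offset `b`, `n_anchors`, residual `mad`, rounds used.
#' @export
fit_fraction_map <- function(features_ref, features_rep, r2_min = 0.9,
                             min_anchors = 10, n_fractions = 55) {
  single <- function(fe) {
    fe |>
      filter(.data$r_squared >= r2_min,
             .data$center >= 3, .data$center <= n_fractions - 3) |>
      group_by(.data$protein) |>
      filter(n() == 1) |>
      ungroup() |>
      select("protein", "center")
  }
  anchors <- inner_join(single(features_ref), single(features_rep),
                        by = "protein", suffix = c("_ref", "_rep"))
  if (nrow(anchors) < min_anchors) {
    stop_cofrac(sprintf(
      "alignment failed: %d anchor protein(s), need >= %d; exclude replicate",
      nrow(anchors), min_anchors), "cofrac_alignment_error")
  }
  # robust initial line (Theil-Sen): median pairwise slope, so that the
  # first trimming round is not steered by noisy edge anchors
  x <- anchors$center_ref
  yv <- anchors$center_rep
  ij <- combn(seq_along(x), 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  sl <- (yv[ij[2, ]] - yv[ij[1, ]])[abs(dx) > 1e-6] / dx[abs(dx) > 1e-6]
  a <- median(sl)
  b <- median(yv - a * x)

  keep <- rep(TRUE, nrow(anchors))
  rounds <- 0
  for (round in 1:5) {
    res <- yv - (a * x + b)
    m <- mad(res[keep])
    drop_now <- keep & abs(res) > 3 * max(m, 1e-9)
    keep_new <- keep & !drop_now
    if (sum(keep_new) < min_anchors) break
    keep <- keep_new
    fit <- lm(center_rep ~ center_ref, data = anchors[keep, ])
    a <- unname(coef(fit)[2])
    b <- unname(coef(fit)[1])
    rounds <- round
    if (!any(drop_now)) break
  }
  if (a < 0.8 || a > 1.25 || abs(b) > 10) {
    stop_cofrac(sprintf(
      "alignment failed: fitted map (a = %.3f, b = %.2f) outside the valid drift range",
      a, b), "cofrac_alignment_error")
  }
  res <- anchors$center_rep - (a * anchors$center_ref + b)
  structure(
    list(replicate = features_rep$replicate[1], a = a, b = b,
         n_anchors = sum(keep), mad = mad(res[keep]), rounds = rounds),
    class = "fraction_map"
  )
}

#' @export
print.fraction_map <- function(x, ...) {
  cat(sprintf(
    "<fraction_map> replicate %s: mu_rep = %.4f * mu_ref + %.4f (%d anchors, MAD %.3f)\n",
    x$replicate, x$a, x$b, x$n_anchors, x$mad))
  invisible(x)
}

#' Map features onto the reference fraction axis
#'
#' Applies the inverse of a fitted [fit_fraction_map()]:
#' `mu' = (mu - b) / a`, `sigma' = sigma / a`; amplitudes are unchanged and
#' the original centres are retained for provenance.
#'
#' @param features Feature tibble for the map's replicate.
#' @param map A `fraction_map`.
#' @return `features` with added `center_aligned`, `sigma_aligned`.
#' @export
apply_fraction_map <- function(features, map) {
  stopifnot(inherits(map, "fraction_map"))
  features |>
    mutate(center_aligned = (.data$center - map$b) / map$a,
           sigma_aligned = .data$sigma / map$a)
}

#' Align features from all replicates to a common fraction axis
#'
#' Chooses the replicate with the most accepted features as the reference
#' (identity map) and fits a [fit_fraction_map()] for every other
#' replicate. Replicates whose alignment fails (too few anchors) are
#' dropped with a warning.
#'
#' @param features Combined feature tibble across replicates.
#' @param anchor_channel Optional channel whose features supply the
#'   anchors (e.g. `"untreated"`); the fitted map is applied to all of the
#'   replicate's features. With several channels per replicate, proteins
#'   rarely carry exactly one feature overall, so anchoring within one
#'   channel is required.
#' @inheritParams fit_fraction_map
#' @return List with `features` (aligned, including `center_aligned` and
#'   `sigma_aligned`), `maps` (list of `fraction_map`), and `reference`
#'   (the reference replicate id).
#' @export
align_features <- function(features, r2_min = 0.9, min_anchors = 10,
                           n_fractions = 55, anchor_channel = NULL) {
  anchor_pool <- features
  if (!is.null(anchor_channel) && "channel" %in% names(features)) {
    anchor_pool <- filter(features, .data$channel == anchor_channel)
    if (nrow(anchor_pool) == 0) anchor_pool <- features
  }
  reps <- anchor_pool |>
    count(.data$replicate, sort = TRUE)
  ref <- reps$replicate[1]
  a_ref <- filter(anchor_pool, .data$replicate == ref)
  maps <- list()
  aligned <- list(
    features |>
      filter(.data$replicate == ref) |>
      mutate(center_aligned = .data$center, sigma_aligned = .data$sigma)
  )
  for (r in setdiff(reps$replicate, ref)) {
    a_rep <- filter(anchor_pool, .data$replicate == r)
    map_r <- tryCatch(
      fit_fraction_map(a_ref, a_rep, r2_min = r2_min,
                       min_anchors = min_anchors, n_fractions = n_fractions),
      cofrac_alignment_error = function(e) {
        warn(sprintf("replicate %s excluded: %s", r, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(map_r)) next
    maps[[as.character(r)]] <- map_r
    aligned[[length(aligned) + 1]] <-
      apply_fraction_map(filter(features, .data$replicate == r), map_r)
  }
  list(features = list_rbind(aligned), maps = maps, reference = ref)
}

#' Alignment diagnostics as a tibble
#'
#' @param maps List of `fraction_map` objects (from [align_features()]).
#' @return Tibble with one row per replicate: `replicate`, `a`, `b`,
#'   `n_anchors`, `mad`.
#' @export
alignment_report <- function(maps) {
  map(maps, function(m) {
    tibble(replicate = m$replicate, a = m$a, b = m$b,
           n_anchors = m$n_anchors, mad = m$mad)
  }) |>
    list_rbind()
}
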