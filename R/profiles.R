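#' Clean a single elution chromatogram
#'
#' Prepares a raw fraction-wise ratio vector for Gaussian fitting:
#' isolated interior measurements (missing on both sides in the original
#' pattern) are removed as spikes; then single interior missing values
#' flanked by two measurements are imputed as the neighbour mean; the
#' remaining missing positions are set to 0 for fitting, with the
#' presence mask retained for distance computations.
#'
#' @param x Numeric vector of length F with `NA` for missing fractions.
#' @return List with `values` (length-F numeric, missing as 0) and
#'   `present` (logical mask after cleaning).
#' @examples
#' clean_chromatogram(c(1, NA, 3, 4, NA, NA, 2, NA))
#' @export
clean_chromatogram <- function(x) {
  n <- length(x)
  if (n >= 3) {
    # spikes first: a value isolated in the original missingness pattern
    # (both interior neighbours missing) is removed before gap bridging
    left_missing <- c(FALSE, is.na(x[-n]))
    right_missing <- c(is.na(x[-1]), FALSE)
    isolated <- !is.na(x) & left_missing & right_missing
    x[isolated] <- NA
    left <- c(NA, x[-n])
    right <- c(x[-1], NA)
    fill <- is.na(x) & !is.na(left) & !is.na(right)
    x[fill] <- (left[fill] + right[fill]) / 2
  }
  present <- !is.na(x)
  x[!present] <- 0
  list(values = x, present = present)
}

#' Clean every chromatogram in a long profile table
#'
#' Applies [clean_chromatogram()] per (protein, replicate, channel) group.
#' The input must carry a complete `1..F` fraction grid within each group
#' (missing fractions as `NA` rows), as produced by [simulate_profiles()]
#' or [read_quant_table()] after [tidyr::complete()].
#'
#' @param chromatograms Long tibble with `protein`, `replicate`, `channel`,
#'   `fraction`, `ratio`.
#' @return The input with added columns `clean` (0-filled) and `present`.
#' @export
clean_profiles <- function(chromatograms) {
  chromatograms |>
    arrange(.data$protein, .data$replicate, .data$channel, .data$fraction) |>
    group_by(.data$protein, .data$replicate, .data$channel) |>
    mutate(
      clean = {
        cl <- clean_chromatogram(.data$ratio)
        cl$values
      },
      present = {
        cl <- clean_chromatogram(.data$ratio)
        cl$present
      }
    ) |>
    ungroup()
}

# Sum-of-Gaussians model; par = c(A_1..A_k, mu_1..mu_k, sigma_1..sigma_k)
gauss_mix_value <- function(par, f) {
  k <- length(par) / 3
  A <- par[seq_len(k)]
  mu <- par[k + seq_len(k)]
  sg <- par[2 * k + seq_len(k)]
  y <- numeric(length(f))
  for (i in seq_len(k)) {
    y <- y + A[i] * exp(-(f - mu[i])^2 / (2 * sg[i]^2))
  }
  y
}

# Deterministic 1-D weighted k-means on fraction positions, signal-weighted.
weighted_centers <- function(f, w, k, jitter = 0) {
  cw <- cumsum(w) / sum(w)
  centers <- map_dbl(seq_len(k), function(i) {
    f[which(cw >= (i - 0.5) / k)[1]]
  })
  centers <- sort(centers + jitter * seq(-1, 1, length.out = k))
  for (it in 1:15) {
    assign <- apply(abs(outer(f, centers, `-`)), 1, which.min)
    new <- map_dbl(seq_len(k), function(i) {
      sel <- assign == i
      if (!any(sel) || sum(w[sel]) == 0) centers[i]
      else weighted.mean(f[sel], w[sel])
    })
    if (max(abs(new - centers)) < 1e-6) break
    centers <- sort(new)
  }
  centers
}

gauss_mix_jac <- function(par, f, sd_scale) {
  k <- length(par) / 3
  A <- par[seq_len(k)]
  mu <- par[k + seq_len(k)]
  sg <- par[2 * k + seq_len(k)]
  jac <- matrix(0, length(f), 3 * k)
  for (i in seq_len(k)) {
    d <- f - mu[i]
    e <- exp(-d^2 / (2 * sg[i]^2))
    jac[, i] <- -e / sd_scale
    jac[, k + i] <- -A[i] * e * d / (sg[i]^2 * sd_scale)
    jac[, 2 * k + i] <- -A[i] * e * d^2 / (sg[i]^3 * sd_scale)
  }
  jac
}

fit_k_gaussians <- function(y, f, k, lower, upper, sd_scale,
                            jitters = c(0, 2, -2)) {
  best <- NULL
  for (j in jitters) {
    centers <- weighted_centers(f, pmax(y, 0), k, jitter = j)
    A0 <- pmax(y[pmin(length(f), pmax(1, round(centers)))], 0.1 * max(y))
    s0 <- rep(2, k)
    par0 <- pmin(pmax(c(A0, centers, s0), lower), upper)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0,
                           fn = function(p) (y - gauss_mix_value(p, f)) / sd_scale,
                           jac = function(p) gauss_mix_jac(p, f, sd_scale),
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 120))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.finite(rss) && (is.null(best) || rss < best$rss)) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  best
}

#' Deconvolve a chromatogram into Gaussian features
#'
#' Fits sums of `k = 1..max_components` Gaussians
#' `y(f) = sum_i A_i exp(-(f - mu_i)^2 / (2 sigma_i^2))` to a cleaned
#' chromatogram by box-constrained nonlinear least squares
#' (Levenberg-Marquardt), and selects the component count by minimum AIC
#' (small-sample corrected, AICc). A model is selectable only when its
#' components are resolvable -- centres at least `min_separation`
#' fractions apart -- which keeps noise spikes riding on a real peak from
#' inflating the component count. Initial centres come from a
#' deterministic signal-weighted 1-D k-means with three jittered restarts
#' per `k`, so identical input always yields identical features.
#' Components below the amplitude floor (`0.05 * max(y)`) are discarded
#' after fitting; if the selected model's R-squared falls below `r2_min`
#' no features are returned.
#'
#' @param y Numeric profile of length F (raw, with `NA` for missing, or
#'   pre-cleaned; cleaning is applied internally).
#' @param max_components Maximum number of Gaussian components (default 5).
#' @param r2_min Minimum acceptable R-squared of the selected model.
#' @param min_points Minimum non-missing points required; profiles with
#'   fewer are skipped (empty result) with a message.
#' @param sigma_bounds,edge Width bounds in fractions and the allowed
#'   centre overhang beyond the fraction range (`mu` in
#'   `[1 - edge, F + edge]`).
#' @param min_separation Minimum centre distance (fractions) between
#'   components of a selectable model (default 2).
#' @param snr_min Minimum component amplitude in units of the fit's
#'   residual standard deviation (default 3).
#' @return Tibble with one row per retained feature: `component`,
#'   `amplitude`, `center`, `sigma`, `r_squared` (of the parent model),
#'   `n_components` (parent model size).
#' @export
fit_gaussians <- function(y, max_components = 5, r2_min = 0.5,
                          min_points = 5, sigma_bounds = c(0.5, 20),
                          edge = 5, min_separation = 2, snr_min = 3) {
  cl <- clean_chromatogram(y)
  n_present <- sum(cl$present)
  empty <- tibble(component = integer(), amplitude = numeric(),
                  center = numeric(), sigma = numeric(),
                  r_squared = numeric(), n_components = integer())
  if (n_present < min_points) {
    inform(sprintf("profile skipped: only %d non-missing point(s)", n_present))
    return(empty)
  }
  yv <- cl$values
  f <- seq_along(yv)
  ymax <- max(yv)
  if (ymax <= 0) {
    return(empty)
  }
  n <- length(yv)
  ss_tot <- sum((yv - mean(yv))^2)
  # SILAC ratio noise scales with signal: weight residuals by a
  # proportional-noise model, floored so baseline fractions still count.
  # Zero-filled missing fractions are censored, not measured zeros, and
  # get three times the baseline uncertainty.
  sd_scale <- pmax(yv, 0.1 * ymax)
  sd_scale[!cl$present] <- 0.3 * ymax

  # cap the searched component counts at (local maxima + 1) of the
  # lightly smoothed profile; chromatograms rarely hide more peaks than
  # they show apices
  ys <- stats::filter(yv, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- yv[is.na(ys)]
  is_peak <- ys > c(-Inf, ys[-n]) & ys >= c(ys[-1], -Inf) & ys > 0.05 * ymax
  k_cap <- min(max_components, sum(is_peak) + 1L)

  best <- NULL
  best_aic <- Inf
  n_bad <- 0
  for (k in seq_len(k_cap)) {
    if (3 * k >= n_present) break
    lower <- c(rep(1e-6, k), rep(1 - edge, k), rep(sigma_bounds[1], k))
    upper <- c(rep(2 * ymax, k), rep(n + edge, k), rep(sigma_bounds[2], k))
    fit <- fit_k_gaussians(yv, f, k, lower, upper, sd_scale)
    # a model is selectable only if its components are resolvable
    # (centres >= min_separation apart) and detectable (amplitudes above
    # snr_min raw residual standard deviations)
    raw_sd <- if (is.null(fit)) Inf else {
      sqrt(mean((yv - gauss_mix_value(fit$par, f))^2))
    }
    valid <- !is.null(fit) &&
      (k == 1 || min(diff(sort(fit$par[k + seq_len(k)]))) >= min_separation) &&
      all(fit$par[seq_len(k)] >= snr_min * raw_sd)
    if (!valid) {
      n_bad <- n_bad + 1
      if (n_bad >= 2) break
      next
    }
    p <- 3 * k + 1
    aic <- n * log(fit$rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
    if (aic < best_aic) {
      best_aic <- aic
      best <- c(fit, list(k = k))
      n_bad <- 0
    } else {
      break  # AICc got worse: larger models will not be selected
    }
  }
  if (is.null(best)) {
    return(empty)
  }
  rss_raw <- sum((yv - gauss_mix_value(best$par, f))^2)
  r2 <- if (ss_tot > 0) 1 - rss_raw / ss_tot else 0
  r2 <- max(0, min(1, r2))
  if (r2 < r2_min) {
    return(empty)
  }
  k <- best$k
  out <- tibble(
    component = seq_len(k),
    amplitude = best$par[seq_len(k)],
    center = best$par[k + seq_len(k)],
    sigma = best$par[2 * k + seq_len(k)],
    r_squared = r2,
    n_components = k
  )
  out |>
    filter(.data$amplitude >= 0.05 * ymax) |>
    arrange(.data$center)
}

#' Fit Gaussian features for every chromatogram in a profile table
#'
#' Maps [fit_gaussians()] over (protein, replicate, channel) groups and
#' assembles the feature table used by the alignment, differential and
#' interaction-scoring stages.
#'
#' @inheritParams clean_profiles
#' @param channels Channels to fit (default both).
#' @inheritParams fit_gaussians
#' @return Feature tibble: `protein`, `replicate`, `channel`,
#'   `feature_id`, `amplitude`, `center`, `sigma`, `r_squared`,
#'   `n_components`.
#' @export
fit_profiles <- function(chromatograms, channels = NULL, max_components = 5,
                         r2_min = 0.5, min_points = 5) {
  df <- chromatograms
  if (!is.null(channels)) {
    df <- filter(df, .data$channel %in% channels)
  }
  df <- arrange(df, .data$protein, .data$replicate, .data$channel,
                .data$fraction)
  keys <- distinct(df, .data$protein, .data$replicate, .data$channel)
  profs <- split(df$ratio,
                 interaction(df$protein, df$replicate, df$channel, drop = TRUE))
  # split() orders groups by factor level; realign to key order
  key_id <- interaction(keys$protein, keys$replicate, keys$channel, drop = TRUE)
  profs <- profs[as.character(key_id)]
  fits <- suppressMessages(
    map(profs, fit_gaussians, max_components = max_components,
        r2_min = r2_min, min_points = min_points)
  )
  n_feat <- map_int(fits, nrow)
  out <- keys[rep(seq_len(nrow(keys)), n_feat), ] |>
    bind_cols(list_rbind(fits))
  if (nrow(out) == 0) {
    return(mutate(out, feature_id = character()))
  }
  out |>
    mutate(feature_id = sprintf("%s|r%d|%s|%d", .data$protein,
                                .data$replicate, .data$channel,
                                .data$component)) |>
    select("protein", "replicate", "channel", "feature_id", "amplitude",
           "center", "sigma", "r_squared", "n_components")
}

#' Per-fraction fold-change measurements inside feature windows
#'
#' For each feature, collects `log2(treated / untreated)` at every fraction
#' within `mu +/- 2 sigma` (clipped to the fraction range) where both
#' channels are quantified in that feature's replicate. These per-fraction
#' measurements are the atoms pooled by [feature_ratio()] and
#' [test_feature_changes()].
#'
#' @param features Feature tibble from [fit_profiles()].
#' @param chromatograms Long chromatogram tibble covering both channels.
#' @param window_sd Half-window in units of sigma (default 2).
#' @return Tibble: `feature_id`, `protein`, `replicate`, `fraction`,
#'   `log2_ratio`.
#' @export
feature_measurements <- function(features, chromatograms, window_sd = 2) {
  n_f <- max(chromatograms$fraction)
  wide <- chromatograms |>
    select("protein", "replicate", "channel", "fraction", "ratio") |>
    pivot_wider(names_from = "channel", values_from = "ratio") |>
    filter(!is.na(.data$treated), !is.na(.data$untreated),
           .data$treated > 0, .data$untreated > 0)
  features |>
    mutate(lo = pmax(1, ceiling(.data$center - window_sd * .data$sigma)),
           hi = pmin(n_f, floor(.data$center + window_sd * .data$sigma))) |>
    select("feature_id", "protein", "replicate", "lo", "hi") |>
    inner_join(wide, by = c("protein", "replicate"),
               relationship = "many-to-many") |>
    filter(.data$fraction >= .data$lo, .data$fraction <= .data$hi) |>
    mutate(log2_ratio = log2(.data$treated / .data$untreated)) |>
    select("feature_id", "protein", "replicate", "fraction", "log2_ratio")
}

#' Feature-level log2 fold change between conditions
#'
#' Summarises the per-fraction measurements of [feature_measurements()]
#' into one log2 fold change per feature (their mean) with the number of
#' contributing fractions. Features with fewer than `min_fractions`
#' co-quantified fractions in the window get `NA` and are flagged.
#'
#' @inheritParams feature_measurements
#' @param min_fractions Minimum co-quantified fractions (default 3).
#' @return `features` with added `log2fc`, `n_fractions`, `fc_defined`.
#' @export
feature_ratio <- function(features, chromatograms, window_sd = 2,
                          min_fractions = 3) {
  meas <- feature_measurements(features, chromatograms, window_sd) |>
    group_by(.data$feature_id) |>
    summarise(log2fc = mean(.data$log2_ratio), n_fractions = n())
  features |>
    left_join(meas, by = "feature_id") |>
    mutate(n_fractions = coalesce(.data$n_fractions, 0L),
           fc_defined = .data$n_fractions >= min_fractions,
           log2fc = ifelse(.data$fc_defined, .data$log2fc, NA_real_))
}

#' Average the two condition channels into a window-definition channel
#'
#' Feature windows for fold-change testing must not be defined on one
#' condition's noisy profile alone: selecting fractions where the
#' reference channel happened to fluctuate upwards biases the
#' treated/untreated ratio inside the window downwards (regression to the
#' mean). Averaging the linear ratios of both channels (per protein,
#' replicate and fraction; missing values ignored, `NA` only when both
#' channels are missing) gives a symmetric profile on which features can
#' be fitted without favouring either condition.
#'
#' @inheritParams clean_profiles
#' @param channels The two channels to average.
#' @return Chromatogram tibble with `channel = "combined"`.
#' @export
combine_channels <- function(chromatograms,
                             channels = c("treated", "untreated")) {
  chromatograms |>
    filter(.data$channel %in% channels) |>
    group_by(.data$protein, .data$replicate, .data$fraction) |>
    summarise(ratio = ifelse(all(is.na(.data$ratio)), NA_real_,
                             mean(.data$ratio, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(channel = "combined") |>
    select("protein", "replicate", "channel", "fraction", "ratio")
}
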