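# Shared fixture builders and independent oracles, all generated in code.

# A complete-grid long chromatogram tibble from per-channel value vectors.
make_chroms <- function(untreated, treated = untreated, protein = "P1",
                        replicate = 1L) {
  stopifnot(length(untreated) == length(treated))
  dplyr::bind_rows(
    tibble::tibble(protein = protein, replicate = replicate,
                   channel = "untreated",
                   fraction = seq_along(untreated), ratio = untreated),
    tibble::tibble(protein = protein, replicate = replicate,
                   channel = "treated",
                   fraction = seq_along(treated), ratio = treated)
  )
}

gauss_profile <- function(a, mu, sigma, n = 55) {
  f <- seq_len(n)
  y <- numeric(n)
  for (i in seq_along(a)) {
    y <- y + a[i] * exp(-(f - mu[i])^2 / (2 * sigma[i]^2))
  }
  y
}

# Feature tibble row(s) for hand-constructed tests.
make_features <- function(protein, center, sigma = 2, amplitude = 1,
                          replicate = 1L, channel = "untreated",
                          r_squared = 0.99) {
  n <- max(length(protein), length(center))
  tibble::tibble(
    protein = rep_len(protein, n), replicate = rep_len(replicate, n),
    channel = rep_len(channel, n),
    amplitude = rep_len(amplitude, n), center = rep_len(center, n),
    sigma = rep_len(sigma, n), r_squared = rep_len(r_squared, n),
    n_components = 1L
  ) |>
    dplyr::mutate(feature_id = sprintf("%s|r%d|%s|%d", protein, replicate,
                                       channel, dplyr::row_number()))
}

# Single-fraction peptide table with one planted bimodal protein, the
# focused construction for the unevenness caller.
make_uneven_dataset <- function(seed, n_proteins = 200, n_peptides = 14,
                                n_cleaved_peptides = 4, ratio = 4,
                                noise_sd = 0.1, planted = TRUE) {
  withr::with_seed(seed, {
    pep <- tidyr::crossing(protein = sprintf("N%03d", seq_len(n_proteins)),
                           pep_i = seq_len(n_peptides)) |>
      dplyr::mutate(peptide = sprintf("%s_p%02d", protein, pep_i),
                    replicate = 1L, fraction = 1L,
                    ratio = exp(stats::rnorm(dplyr::n(), 0, noise_sd)))
    if (planted) {
      sel <- pep$protein == "N001" & pep$pep_i <= n_cleaved_peptides
      pep$ratio[sel] <- ratio * exp(stats::rnorm(sum(sel), 0, noise_sd))
    }
    pep
  })
}

# Independent reference implementation of Markov clustering, written
# directly from the algorithm definition with plain loops; used as the
# oracle for the package's mcl().
reference_mcl <- function(adj, inflation = 2, expansion = 2, prune = 1e-5,
                          tol = 1e-8, max_iter = 200) {
  m <- as.matrix(adj)
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- as.character(1:n)
  for (i in 1:n) {
    mx <- max(m[i, ])
    m[i, i] <- if (mx > 0) mx else 1
  }
  for (j in 1:n) m[, j] <- m[, j] / sum(m[, j])
  for (it in 1:max_iter) {
    prev <- m
    mm <- m
    for (e in seq_len(expansion - 1)) mm <- mm %*% m
    m <- mm
    m <- m^inflation
    m[m < prune] <- 0
    for (j in 1:n) {
      cs <- sum(m[, j])
      if (cs > 0) m[, j] <- m[, j] / cs
    }
    if (max(abs(m - prev)) < tol) break
  }
  clusters <- list()
  for (i in 1:n) {
    if (m[i, i] > prune) {
      clusters[[length(clusters) + 1]] <- rownames(m)[m[i, ] > prune]
    }
  }
  # merge overlapping attractor systems
  changed <- TRUE
  while (changed && length(clusters) > 1) {
    changed <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j && length(intersect(clusters[[i]], clusters[[j]])) > 0) {
          clusters[[i]] <- sort(unique(c(clusters[[i]], clusters[[j]])))
          clusters[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  clusters <- Filter(function(x) length(x) >= 2, lapply(clusters, sort))
  clusters[order(vapply(clusters, `[`, "", 1))]
}

# Canonical partition signature for comparing clusterings.
partition_signature <- function(members_list) {
  sig <- vapply(members_list, function(m) paste(sort(m), collapse = ","), "")
  paste(sort(sig), collapse = ";")
}

random_graph_adj <- function(n, p, seed) {
  withr::with_seed(seed, {
    m <- matrix(0, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                         sprintf("n%02d", 1:n)))
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (stats::runif(1) < p) {
          w <- stats::runif(1, 0.5, 1)
          m[i, j] <- w
          m[j, i] <- w
        }
      }
    }
    m
  })
}
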