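#' Markov clustering of a weighted interaction graph
#'
#' Partitions a graph by the Markov cluster algorithm: random-walk flow is
#' alternately expanded (matrix squaring) and inflated (elementwise power
#' followed by column renormalisation), which dissipates flow across
#' sparse boundaries and concentrates it within dense regions. Self-loops
#' (weight = the node's maximum incident weight) are added before column
#' normalisation; entries below `prune` are dropped each round; iteration
#' stops when the largest column change falls below `tol` or after
#' `max_iter` rounds. Clusters are read from the attractor rows of the
#' limit matrix; overlapping attractor systems are merged and singletons
#' discarded.
#'
#' @param adjacency Symmetric non-negative weighted adjacency matrix with
#'   dimnames.
#' @param inflation Inflation exponent (default 2; larger = finer
#'   clusters).
#' @param expansion Expansion power (default 2).
#' @param prune Entries below this are zeroed each iteration.
#' @param tol Convergence tolerance on the max absolute entry change.
#' @param max_iter Iteration cap.
#' @return Tibble: `cluster_id`, `members` (list column), `n_members`.
#' @export
mcl <- function(adjacency, inflation = 2, expansion = 2, prune = 1e-5,
                tol = 1e-8, max_iter = 200) {
  m <- as.matrix(adjacency)
  if (nrow(m) == 0) {
    return(tibble(cluster_id = character(), members = list(),
                  n_members = integer()))
  }
  if (any(m < 0) || !isSymmetric(unname(m), tol = 1e-12)) {
    stop_cofrac("adjacency must be symmetric with non-negative weights",
                "cofrac_mcl_error")
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- as.character(seq_len(nrow(m)))
  }
  loop <- apply(m, 1, max)
  loop[loop <= 0] <- 1
  diag(m) <- loop
  m <- sweep(m, 2, colSums(m), "/")

  for (it in seq_len(max_iter)) {
    prev <- m
    for (e in seq_len(expansion - 1)) {
      m <- m %*% m
    }
    m <- m^inflation
    m[m < prune] <- 0
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2, cs, "/")
    if (max(abs(m - prev)) < tol) break
  }

  attractors <- which(diag(m) > prune)
  if (length(attractors) == 0) {
    return(tibble(cluster_id = character(), members = list(),
                  n_members = integer()))
  }
  raw <- map(attractors, function(i) colnames(m)[m[i, ] > prune])
  # merge attractor systems sharing members (union-find over overlap)
  merged <- list()
  for (cl in raw) {
    hit <- which(map_lgl(merged, ~ length(intersect(.x, cl)) > 0))
    if (length(hit) == 0) {
      merged[[length(merged) + 1]] <- cl
    } else {
      merged[[hit[1]]] <- unique(c(unlist(merged[hit]), cl))
      if (length(hit) > 1) {
        merged <- merged[-hit[-1]]
      }
    }
  }
  merged <- keep(merged, ~ length(.x) >= 2)
  merged <- map(merged, sort)
  ord <- order(map_chr(merged, 1))
  merged <- merged[ord]
  tibble(
    cluster_id = sprintf("K%04d", seq_along(merged)),
    members = merged,
    n_members = lengths(merged)
  )
}

#' Build an MCL adjacency matrix from accepted edges
#'
#' Edge weight is `1 - score / max(score)` floored at 0.1, so accepted
#' interactions enter clustering near-binary while retaining rank
#' information.
#'
#' @param edges Edge tibble with `protein_a`, `protein_b`, `score`.
#' @param floor Minimum weight for an accepted edge.
#' @return Symmetric weighted adjacency matrix.
#' @export
network_adjacency <- function(edges, floor = 0.1) {
  prot <- sort(unique(c(edges$protein_a, edges$protein_b)))
  m <- matrix(0, length(prot), length(prot), dimnames = list(prot, prot))
  w <- if (!is.null(edges$score) && max(edges$score) > 0) {
    pmax(floor, 1 - edges$score / max(edges$score))
  } else {
    rep(1, nrow(edges))
  }
  ia <- match(edges$protein_a, prot)
  ib <- match(edges$protein_b, prot)
  m[cbind(ia, ib)] <- pmax(m[cbind(ia, ib)], w)
  m[cbind(ib, ia)] <- pmax(m[cbind(ib, ia)], w)
  m
}

#' Cluster an interaction network into complexes
#'
#' Convenience wrapper: [network_adjacency()] then [mcl()], then
#' [cluster_center()] when features are supplied.
#'
#' @param edges Accepted edge tibble.
#' @param features Optional aligned feature tibble for elution centres.
#' @param inflation MCL inflation; complex assembly defaults to 3, a
#'   finer operating point than the generic [mcl()] default, because the
#'   near-binary rank-weighted co-elution graph chains mass-coincident
#'   complexes together at lower inflation.
#' @return Cluster tibble (with `center` when features are given).
#' @export
cluster_network <- function(edges, features = NULL, inflation = 3) {
  if (is.null(edges) || nrow(edges) == 0) {
    return(tibble(cluster_id = character(), members = list(),
                  n_members = integer()))
  }
  clusters <- mcl(network_adjacency(edges), inflation = inflation)
  if (!is.null(features) && nrow(clusters) > 0) {
    clusters <- cluster_center(clusters, features)
  }
  clusters
}

#' Elution centre of a complex cluster
#'
#' For each cluster, takes every member's feature nearest the cluster's
#' median feature centre and reports the mean of those selected centres to
#' 0.1 fraction. Members without any fitted feature are excluded with a
#' warning.
#'
#' @param clusters Cluster tibble with `members` list column.
#' @param features Feature tibble (aligned centres used when present).
#' @return `clusters` with added `center`.
#' @export
cluster_center <- function(clusters, features) {
  feats <- features
  if (!"center_aligned" %in% names(feats)) {
    feats <- mutate(feats, center_aligned = .data$center)
  }
  missing_members <- 0L
  centers <- map_dbl(clusters$members, function(mem) {
    fm <- filter(feats, .data$protein %in% mem)
    missing_members <<- missing_members + sum(!mem %in% fm$protein)
    if (nrow(fm) == 0) {
      return(NA_real_)
    }
    med <- median(fm$center_aligned)
    sel <- fm |>
      group_by(.data$protein) |>
      slice_min(abs(.data$center_aligned - med), n = 1, with_ties = FALSE) |>
      ungroup()
    mean(sel$center_aligned)
  })
  if (missing_members > 0) {
    warn(sprintf("%d cluster member(s) without fitted features were excluded from centres",
                 missing_members))
  }
  mutate(clusters, center = round(centers, 1))
}

#' Merge co-eluting clusters into supercomplexes
#'
#' Large assemblies can be split into several clusters by Markov
#' clustering; the separation's spatial dimension allows their
#' reconstruction. Clusters are merged (union-find) when they share at
#' least one member and their elution centres lie within `max_gap`
#' fractions.
#'
#' @param clusters Cluster tibble with `members` and `center`.
#' @param max_gap Maximum centre distance for merging (default 1.0).
#' @return List with `clusters` (input plus `supercomplex_id`) and
#'   `supercomplexes` (merged member sets with their source clusters).
#' @export
merge_coeluting <- function(clusters, max_gap = 1.0) {
  n <- nrow(clusters)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (is.na(clusters$center[i]) || is.na(clusters$center[j])) next
        if (abs(clusters$center[i] - clusters$center[j]) <= max_gap &&
            length(intersect(clusters$members[[i]],
                             clusters$members[[j]])) > 0) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  root <- map_int(seq_len(n), find)
  sc_id <- match(root, unique(root))
  clusters$supercomplex_id <- sprintf("SC%04d", sc_id)
  supercomplexes <- clusters |>
    group_by(.data$supercomplex_id) |>
    summarise(
      members = list(sort(unique(unlist(.data$members)))),
      cluster_ids = list(.data$cluster_id),
      center = mean(.data$center),
      n_clusters = n()
    ) |>
    mutate(n_members = lengths(.data$members))
  list(clusters = clusters, supercomplexes = supercomplexes)
}

#' Precision of within-cluster pairs against the gold standard
#'
#' Enumerates all pairs inside each cluster, labels them against the
#' complex database, and reports `TP / (TP + FP)` over the labelled
#' pairs, together with each cluster's best gold-complex match by the
#' overlap score `O = |C intersect G|^2 / (|C| * |G|)`.
#'
#' @param clusters Cluster tibble with `members`.
#' @param db Gold-standard complex database.
#' @return List with `precision`, `tp`, `fp`, `n_unlabeled`, and
#'   `matches` (per-cluster best overlap score and matching complex).
#' @export
complex_precision <- function(clusters, db) {
  pairs <- clusters$members |>
    keep(~ length(.x) >= 2) |>
    map(function(m) {
      cmb <- combn(sort(m), 2)
      tibble(protein_a = cmb[1, ], protein_b = cmb[2, ])
    }) |>
    list_rbind()
  if (is.null(pairs) || nrow(pairs) == 0) {
    warn("no within-cluster pairs; precision undefined")
    return(list(precision = NA_real_, tp = 0L, fp = 0L, n_unlabeled = 0L,
                matches = tibble()))
  }
  pairs <- distinct(pairs)
  labeled <- label_pairs(pairs, db)
  tp <- sum(labeled$label == "positive")
  fp <- sum(labeled$label == "negative")
  if (tp + fp == 0) {
    warn("no labeled within-cluster pairs; precision undefined")
  }
  matches <- clusters |>
    mutate(best = map(.data$members, function(mem) {
      o <- map_dbl(db$members, function(g) {
        length(intersect(mem, g))^2 / (length(mem) * length(g))
      })
      i <- which.max(o)
      tibble(gold_complex = db$complex_id[i], overlap_score = o[i])
    })) |>
    select("cluster_id", "n_members", "best") |>
    unnest("best")
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, n_unlabeled = sum(labeled$label == "unlabeled"),
       matches = matches)
}
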