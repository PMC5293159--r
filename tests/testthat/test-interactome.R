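test_that("Euclidean distance is computed on unit-scaled shared fractions", {
  # identical profiles -> D = 0, co-apex 0, best possible rank
  base <- gauss_profile(1, 20, 2, n = 30)
  chroms <- dplyr::bind_rows(
    tibble::tibble(protein = "A", replicate = 1L, channel = "untreated",
                   fraction = 1:30, ratio = base),
    tibble::tibble(protein = "B", replicate = 1L, channel = "untreated",
                   fraction = 1:30, ratio = base)
  )
  feats <- make_features(c("A", "B"), c(20, 20), sigma = 2)
  cand <- score_candidate_pairs(feats, chroms)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$dist, 0, tolerance = 1e-12)
  expect_equal(cand$coapex, 0)

  # profiles peaking 10 fractions apart are not candidates
  feats2 <- make_features(c("A", "B"), c(10, 20), sigma = 2)
  cand2 <- score_candidate_pairs(feats2, chroms)
  expect_equal(nrow(cand2), 0)
})

test_that("hand-computed distance: orthogonal unit peaks give sqrt(2)", {
  ya <- c(1, 0, 0, rep(0.0, 12))
  yb <- c(0, 1, 0, rep(0.0, 12))
  chroms <- dplyr::bind_rows(
    tibble::tibble(protein = "A", replicate = 1L, channel = "untreated",
                   fraction = 1:15, ratio = ya),
    tibble::tibble(protein = "B", replicate = 1L, channel = "untreated",
                   fraction = 1:15, ratio = yb)
  )
  feats <- make_features(c("A", "B"), c(1, 2), sigma = 1)
  cand <- score_candidate_pairs(feats, chroms, min_shared = 10)
  expect_equal(cand$dist, sqrt(2), tolerance = 1e-6)
})

test_that("pairs sharing too few fractions are dropped", {
  ya <- c(rep(1, 5), rep(NA, 10))
  yb <- c(rep(1, 5), rep(NA, 10))
  chroms <- dplyr::bind_rows(
    tibble::tibble(protein = "A", replicate = 1L, channel = "untreated",
                   fraction = 1:15, ratio = ya),
    tibble::tibble(protein = "B", replicate = 1L, channel = "untreated",
                   fraction = 1:15, ratio = yb)
  )
  feats <- make_features(c("A", "B"), c(3, 3), sigma = 1)
  cand <- score_candidate_pairs(feats, chroms, min_shared = 10)
  expect_equal(nrow(cand), 0)
})

test_that("gold-standard labelling distinguishes positive, negative, unlabeled", {
  db <- tibble::tibble(complex_id = c("C1", "C2"),
                       complex_name = c("C1", "C2"),
                       members = list(c("A", "B", "C"), c("D", "E")))
  cand <- tibble::tibble(replicate = 1L, channel = "untreated",
                         protein_a = c("A", "A", "A"),
                         protein_b = c("B", "D", "Z"),
                         coapex = 0, dist = 0, n_shared = 20L,
                         score = c(1, 2, 3))
  lab <- suppressMessages(label_pairs(cand, db))
  expect_equal(lab$label, c("positive", "negative", "unlabeled"))
})

test_that("precision calibration accepts the largest prefix meeting the target", {
  stream <- tibble::tibble(
    replicate = 1L, channel = "untreated",
    protein_a = sprintf("a%d", 1:60), protein_b = sprintf("b%d", 1:60),
    coapex = seq(0.01, 0.6, length.out = 60),
    dist = seq(0.01, 0.6, length.out = 60),
    n_shared = 20L, score = 1:60,
    label = c("positive", "positive", "positive", "negative",
              rep(c("positive", "negative"), 28))
  )
  out <- calibrate_threshold(stream, target_precision = 0.70,
                             min_labeled = 50)
  # the P,P,P,N prefix has precision 0.75 >= 0.70; later the running
  # precision decays towards 0.5, so the cut lands where it last holds
  tp <- cumsum(stream$label == "positive")
  fp <- cumsum(stream$label == "negative")
  feasible <- which(tp / (tp + fp) >= 0.70)
  expect_equal(nrow(out$edges), max(feasible))
  expect_gte(out$report$precision, 0.70)

  # stream that starts with a negative and never recovers -> empty network
  bad <- dplyr::mutate(stream, label = c("negative", stream$label[-1]),
                       score = 1:60)
  bad$label[bad$label == "positive"] <- "negative"
  expect_warning(out_bad <- calibrate_threshold(bad, 0.70, min_labeled = 50),
                 "unreachable")
  expect_true(is.null(out_bad$edges) || nrow(out_bad$edges) == 0)

  # all positives -> full acceptance at precision 1
  allp <- dplyr::mutate(stream, label = "positive")
  out_all <- calibrate_threshold(allp, 0.70, min_labeled = 50)
  expect_equal(nrow(out_all$edges), 60)
  expect_equal(out_all$report$precision, 1)
})

test_that("global report unions local networks and recomputes precision", {
  cand <- tibble::tibble(
    replicate = c(rep(1L, 5), rep(2L, 4)),
    channel = "untreated",
    protein_a = c("a", "b", "c", "d", "x", "a", "e", "f", "y"),
    protein_b = c("A", "B", "C", "D", "X", "A", "E", "F", "Y"),
    score = 1, coapex = 0, dist = 0, n_shared = 20L,
    label = c("positive", "positive", "positive", "negative", "negative",
              "positive", "positive", "negative", "negative")
  )
  # net1 = {3 TP, 1 FP}; net2 = {2 TP, 1 FP}; shared TP pair a-A
  local_edges <- cand[c(1:4, 6:8), ]
  glob <- global_report(local_edges, cand)
  expect_equal(glob$report$tp, 4)
  expect_equal(glob$report$fp, 2)
  expect_equal(glob$report$precision, 2 / 3)
  expect_equal(nrow(glob$edges), 6)
  shared <- dplyr::filter(glob$edges, protein_a == "a")
  expect_equal(shared$n_support, 2)

  # idempotent union: two identical local networks change nothing
  glob2 <- global_report(dplyr::bind_rows(cand[1:4, ], cand[1:4, ]), cand)
  expect_equal(nrow(glob2$edges), 4)
  expect_equal(glob2$report$precision, 3 / 4)
})

test_that("false-positive rate is counted over the labelled negative space", {
  cand <- tibble::tibble(
    replicate = 1L, channel = "untreated",
    protein_a = sprintf("n%04d", 1:1001), protein_b = sprintf("m%04d", 1:1001),
    score = 1:1001, coapex = 0, dist = 0, n_shared = 20L,
    label = c("negative", rep("negative", 999), "positive")
  )
  glob <- global_report(cand[1, ], cand)
  expect_equal(glob$report$fpr, 1 / 1000)
})

test_that("all-or-nothing interactions need two replicates in exactly one state", {
  edges <- tibble::tibble(
    protein_a = c("a", "a", "b", "b", "b", "c"),
    protein_b = c("A", "A", "B", "B", "B", "C"),
    replicate = c(1L, 2L, 1L, 2L, 1L, 1L),
    channel = c("treated", "treated", "treated", "treated", "untreated",
                "untreated")
  )
  cs <- condition_specific_edges(edges)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$protein_a, "a")
  expect_equal(cs$status, "gained")
})

test_that("degree power law is exact on an exact power-law degree sample", {
  # degree counts exactly 1200 * k^-2 for k in 1..20 (rounded)
  degrees <- unlist(lapply(1:20, function(k) rep(k, round(1200 / k^2))))
  fit <- degree_powerlaw(degrees = degrees)
  expect_equal(fit$slope, -2, tolerance = 0.02)
  expect_gt(fit$r_squared, 0.999)
})

test_that("degree power law is undefined for a star graph", {
  star <- tibble::tibble(protein_a = "hub", protein_b = sprintf("s%d", 1:10))
  expect_warning(fit <- degree_powerlaw(star), "undefined")
  expect_true(is.na(fit$slope))
})

test_that("preferential-attachment networks show a heavy-tailed degree fit", {
  skip_if_not_installed("igraph")
  g <- withr::with_seed(13, igraph::sample_pa(1000, m = 2, directed = FALSE))
  el <- igraph::as_edgelist(g)
  edges <- tibble::tibble(protein_a = sprintf("v%04d", el[, 1]),
                          protein_b = sprintf("v%04d", el[, 2]))
  fit <- degree_powerlaw(edges)
  expect_lt(fit$slope, -1)
  expect_gt(fit$r_squared, 0.7)
})

test_that("membrane GO overlap statistics count edges correctly", {
  ann <- tibble::tibble(
    accession = c("A", "B", "C"),
    go_id = c("GO:0016020", "GO:0016020", "GO:0005634"),
    aspect = "C",
    is_membrane = c(TRUE, TRUE, FALSE)
  )
  edges <- tibble::tibble(protein_a = c("A", "A", "C", "X"),
                          protein_b = c("B", "C", "Z", "Y"))
  st <- go_overlap_stats(edges, ann)
  expect_equal(st$frac_any_membrane, 0.5)    # A-B and A-C touch membrane
  expect_equal(st$n_shared_term, 1)          # A-B share GO:0016020
  expect_equal(st$frac_shared_term, 0.25)

  expect_warning(st0 <- go_overlap_stats(edges, ann[ann$is_membrane == FALSE, ]),
                 "no membrane")
  expect_equal(st0$frac_any_membrane, 0)
})
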