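test_that("subject connectome applies Fisher z exactly", {
  # construct a pair with exact r = 0.5: y = 0.5 x + sqrt(0.75) e, x _|_ e
  x <- c(1, -1, 0, 0)
  e <- c(0, 0, 1, -1)
  y <- 0.5 * x + sqrt(0.75) * e
  conn <- subject_connectome(rbind(x, y))
  expect_equal(conn$z[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(conn$z[1, 2], 0.5493, tolerance = 1e-4)
  expect_equal(unname(diag(conn$z)), c(0, 0))  # self-edges zero by convention
  expect_error(subject_connectome(matrix(1:4, 2)), "at least 3 samples")
})

test_that("connectome matches the brute-force pairwise oracle", {
  set.seed(21)
  m <- matrix(rnorm(48 * 60), 48)
  conn <- subject_connectome(m)
  expect_lt(max(abs(conn$z - connectome_oracle(m))), 1e-12)
  expect_identical(conn$z, t(conn$z))
})

test_that("zero-variance regions yield zero edges with a warning", {
  set.seed(22)
  m <- rbind(matrix(rnorm(3 * 20), 3), rep(1, 20))
  expect_warning(conn <- subject_connectome(m), "zero-variance")
  expect_equal(conn$z[4, ], rep(0, 4))
  expect_equal(conn$z[, 4], rep(0, 4))
})

test_that("arctanh/tanh round trip holds on the clipped domain", {
  r <- seq(-1, 1, length.out = 1001)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  expect_lt(max(abs(tanh(atanh(r)) - r)), 1e-10)
})

test_that("group connectome averages and Bonferroni-masks edges", {
  set.seed(23)
  base <- abs(matrix(rnorm(6 * 6), 6)); base <- base + t(base); diag(base) <- 0
  conns <- lapply(1:8, function(s) {
    j <- matrix(rnorm(36, sd = 1e-3), 6); j <- (j + t(j)) / 2; diag(j) <- 0
    structure(list(z = base + j, region_positions = 1:6, subject_id = s,
                   window_min = NULL, modality = "PET"), class = "connectome")
  })
  gc <- group_connectome(conns)
  # mean is the elementwise average
  zmean <- Reduce(`+`, lapply(conns, `[[`, "z")) / 8
  expect_equal(gc$mean_z, zmean)
  # identical positive structure with tiny jitter: every edge survives FWE
  off <- !diag(6)
  expect_true(all(gc$fwe_mask[off]))
  expect_identical(gc$fwe_mask, t(gc$fwe_mask))
  # thresholded matrix has exact zeros where masked
  thr <- apply_fwe_mask(gc)
  expect_true(all(thr[!gc$fwe_mask] == 0))
  bad <- conns
  bad[[1]]$region_positions <- 2:7
  expect_error(group_connectome(bad), "mismatching region sets")
})

test_that("group statistics are equivariant under region relabeling", {
  set.seed(24)
  conns <- lapply(1:6, function(s) subject_connectome(matrix(rnorm(8 * 40), 8)))
  gc <- group_connectome(conns)
  perm <- sample(8)
  conns_p <- lapply(conns, function(cn) {
    cn$z <- cn$z[perm, perm]
    cn
  })
  gc_p <- group_connectome(conns_p)
  expect_equal(gc_p$mean_z, gc$mean_z[perm, perm])
  expect_equal(gc_p$edge_t, gc$edge_t[perm, perm])
  expect_equal(gc_p$fwe_mask, gc$fwe_mask[perm, perm])
})

test_that("edge similarity behaves as a correlation over unique edges", {
  set.seed(25)
  A <- subject_connectome(matrix(rnorm(10 * 50), 10))
  B <- subject_connectome(matrix(rnorm(10 * 50), 10))
  expect_equal(edge_similarity(A, A), 1)
  negA <- A; negA$z <- -A$z
  expect_equal(edge_similarity(A, negA), -1)
  # oracle on lower-triangle vectors
  lt <- lower.tri(A$z)
  expect_equal(edge_similarity(A, B), cor(A$z[lt], B$z[lt]))
  # symmetric in arguments, invariant to affine rescaling
  expect_equal(edge_similarity(A, B), edge_similarity(B, A))
  B2 <- B; B2$z <- 3.7 * B$z + 0.2
  expect_equal(edge_similarity(A, B2), edge_similarity(A, B))
  expect_error(edge_similarity(A, subject_connectome(matrix(rnorm(5 * 50), 5))),
               "dimension mismatch")
})

test_that("sliding windows tile the analysis span as specified", {
  set.seed(26)
  t <- seq(0.5, 79.5, by = 1)
  bp <- bp_series(matrix(rnorm(6 * 80), 6), 1:6, t)
  wins <- sliding_window_connectomes(bp)
  expect_equal(attr(wins, "window_starts"), seq(20, 60, by = 5))
  expect_length(wins, 9L)
  # each windowed matrix equals subject_connectome on the slice
  w3 <- subject_connectome(bp, window_min = c(30, 50))
  expect_equal(wins[[3]]$z, w3$z)
  expect_error(sliding_window_connectomes(bp, window_len_min = 100),
               "longer than the analysis span")
  short <- bp_series(matrix(rnorm(6 * 30), 6), 1:6, seq(0.5, 29.5, by = 1))
  expect_error(sliding_window_connectomes(short), "does not cover")
})

test_that("stationary cohorts give temporally stable window connectomes", {
  # planted stable covariance: group-level adjacent-window edge similarity
  # must stay high across the scan
  cfg <- sim_config(n_subjects = 12, challenge_min = NULL, seed = 31)
  co <- simulate_cohort(cfg)
  wins <- lapply(co$pet, function(ts) {
    sliding_window_connectomes(discard_and_detrend(framewise_bpnd(ts)))
  })
  n_win <- length(wins[[1]])
  groups <- lapply(seq_len(n_win), function(w) {
    group_connectome(lapply(wins, `[[`, w))
  })
  adj <- vapply(seq_len(n_win - 1), function(w) {
    edge_similarity(groups[[w]], groups[[w + 1]])
  }, numeric(1))
  expect_gt(mean(adj), 0.7)
})

test_that("network strength summarises within-network edges", {
  tab <- schiffer_region_table()
  nets <- network_definitions()
  z <- matrix(0, 48, 48)
  members <- resolve_network(nets$subcortical, tab)
  z[members, members] <- 0.8
  diag(z) <- 0
  conn <- structure(list(z = z, region_positions = 1:48, subject_id = NULL,
                         window_min = NULL, modality = "PET"),
                    class = "connectome")
  ns <- network_strength(conn, nets$subcortical, tab)
  expect_equal(ns$network_strength, 0.8)
  expect_equal(unname(ns$node_strength), rep(0.8, length(members)))
})

test_that("identical pre/post strengths give t = 0 and p = 1", {
  set.seed(27)
  tab <- schiffer_region_table()
  nets <- network_definitions()
  mk_win <- function() {
    w <- lapply(1:3, function(i) subject_connectome(matrix(rnorm(48 * 30), 48)))
    attr(w, "window_starts") <- c(20, 40, 60)
    w
  }
  subs <- lapply(1:5, function(s) mk_win())
  # make every window identical within subject
  subs <- lapply(subs, function(w) { w[[2]] <- w[[1]]; w[[3]] <- w[[1]]; w })
  tc <- network_strength_timecourse(subs, nets$salience, tab)
  expect_equal(tc$final_test$t, 0)
  expect_equal(tc$final_test$p, 1)
  expect_true(all(tc$p[-1] == 1))
  expect_false(any(tc$significant, na.rm = TRUE))
})
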