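test_that("reference TAC reaches a stable plateau and scales linearly", {
  cfg <- sim_config()
  tac <- simulate_reference_tac(cfg)
  act <- tac$activity
  plateau <- act[length(act)]
  late <- act[tac$time_min >= 40]
  # relative drift of the last 40 min < 5%; derivative < 1% of plateau/min
  expect_lt((max(late) - min(late)) / plateau, 0.05)
  expect_lt(max(abs(diff(late))), 0.01 * plateau)
  # doubling the infusion rate doubles the curve
  cfg2 <- sim_config(infusion_rate = 2)
  expect_equal(simulate_reference_tac(cfg2)$activity, 2 * act)
  # k_bol -> 0 is the pure-infusion limit: monotone rise, no overshoot
  cfg0 <- sim_config(k_bol_min = 0, clearance_min = 38.7)
  act0 <- simulate_reference_tac(cfg0)$activity
  expect_true(all(diff(act0) > 0))
  expect_true(all(act0 <= act0[length(act0)]))
  expect_error(sim_config(k_bol_min = -1), "non-negative")
})

test_that("default cohort matches the acquisition protocol", {
  co <- simulate_cohort(sim_config(n_subjects = 2, seed = 61))
  expect_length(co$pet, 2L)
  expect_equal(ncol(co$pet[[1]]$values), 80L)    # 1-min frames, 80 min
  expect_equal(ncol(co$bold[[1]]$values), 2400L) # TR 2 s, 80 min
  expect_equal(nrow(co$pet[[1]]$values), 49L)    # 48 regions + reference
  expect_equal(nrow(co$bold[[1]]$values), 48L)
  expect_true("Cer" %in% rownames(co$pet[[1]]$values))
})

test_that("same seed reproduces the cohort byte for byte", {
  cfg <- sim_config(n_subjects = 2, make_images = TRUE, seed = 62)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$pet, b$pet)
  expect_identical(a$bold, b$bold)
  expect_identical(a$pet_images[[1]]$data, b$pet_images[[1]]$data)
  c2 <- simulate_cohort(sim_config(n_subjects = 2, seed = 63))
  expect_false(identical(a$pet[[1]]$values, c2$pet[[1]]$values))
})

test_that("occupancy curves respect onset, monotonicity, and amplitude", {
  cfg <- sim_config(n_subjects = 1, seed = 64)
  co <- simulate_cohort(cfg)
  occ <- co$truth$occupancy
  t <- co$pet[[1]]$frame_mid_min
  amp <- co$truth$occupancy_amplitude
  for (i in seq_len(nrow(occ))) {
    expect_true(all(occ[i, t < 40] == 0))
    expect_true(all(diff(occ[i, ]) >= 0))
    expect_true(all(occ[i, ] <= amp[i] + 1e-12))
  }
  # salience onset delayed by 10 min relative to subcortical
  onset <- co$truth$occupancy_onset
  member <- co$truth$member_of
  expect_equal(unique(onset[member == "subcortical" & !is.na(member)]), 40)
  expect_equal(unique(onset[member == "salience" & !is.na(member)]), 50)
  # members sit at the configured plateau occupancies
  expect_equal(unique(amp[member == "subcortical" & !is.na(member)]), 0.4)
  expect_equal(unique(amp[member == "salience" & !is.na(member)]), 0.3)
})

test_that("no-challenge cohorts keep BP at baseline on average", {
  cfg <- sim_config(n_subjects = 6, challenge_min = NULL, seed = 65)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$occupancy == 0))
  bp_mean <- Reduce(`+`, lapply(co$pet, function(ts) {
    rowMeans(framewise_bpnd(ts)$values)
  })) / length(co$pet)
  expect_true(all(abs(bp_mean / cfg$baseline_bp - 1) < 0.02))
})

test_that("noise-free simulation round-trips through framewise_bpnd", {
  co <- simulate_cohort(sim_config(n_subjects = 2, noise_sd = 0, seed = 66))
  for (s in 1:2) {
    bp <- framewise_bpnd(co$pet[[s]])
    expect_lt(max(abs(bp$values - co$truth$bp_true[[s]])), 1e-10)
  }
})

test_that("planted network block structure is recoverable at group level", {
  tab <- schiffer_region_table()
  nets <- network_definitions()
  within_minus_between <- vapply(1:3, function(k) {
    co <- simulate_cohort(sim_config(n_subjects = 30, challenge_min = NULL,
                                     seed = 70 + k))
    conns <- lapply(co$pet, function(ts) {
      subject_connectome(discard_and_detrend(framewise_bpnd(ts)))
    })
    gz <- group_connectome(conns)$mean_z
    members <- lapply(nets, resolve_network, tab = tab)
    win <- unlist(lapply(members, function(m) {
      sub <- gz[m, m]; sub[upper.tri(sub)]
    }))
    btw <- gz[members[[1]], members[[2]]]
    mean(win) - mean(btw)
  }, numeric(1))
  expect_true(all(within_minus_between > 0.3))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(challenge_min = 100), "within the scan")
  expect_error(sim_config(occupancy_amplitude = c(subcortical = 1.2,
                                                  salience = 0.3)),
               "\\[0, 1\\)")
  expect_error(sim_config(occupancy_amplitude = c(bogus = 0.2)),
               "unknown network")
  tab <- schiffer_region_table()
  expect_error(sim_config(baseline_bp = rep(1, 10)), "one value per region")
})
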