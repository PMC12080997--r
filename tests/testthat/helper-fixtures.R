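# Shared fixtures: small images, planted-pattern generators, oracles.

# a tiny PET image on an arbitrary grid with 1-min frames
tiny_image <- function(data, frame_min = 1, modality = "PET") {
  n <- dim(data)[4]
  if (modality == "PET") {
    sched <- frame_schedule(seq(0, by = frame_min, length.out = n),
                            rep(frame_min, n))
    dynamic_image(data, timing = sched, modality = "PET")
  } else {
    dynamic_image(data, timing = 2, modality = "BOLD")
  }
}

# two-region single-voxel atlas (labels 1 and 2 in a 2x1x1 grid)
two_voxel_atlas <- function() {
  tab <- validate_region_table(data.frame(
    region = c("Region A", "Region B"),
    hemisphere = c("midline", "midline"),
    volume_mm3 = c(1, 1),
    position = 1:2,
    abbreviation = c("A", "B"),
    stringsAsFactors = FALSE))
  pet_atlas(array(c(1L, 2L), dim = c(2, 1, 1)), region_table = tab)
}

# independent voxel-loop extraction oracle
extract_oracle <- function(data4d, labels, region) {
  idx <- which(labels == region)
  n <- dim(data4d)[4]
  flat <- matrix(data4d, ncol = n)
  vapply(seq_len(n), function(t) mean(flat[idx, t]), numeric(1))
}

# brute-force pairwise Pearson + Fisher z oracle
connectome_oracle <- function(m) {
  R <- nrow(m)
  z <- matrix(0, R, R)
  for (i in seq_len(R)) for (j in seq_len(R)) {
    if (i == j) next
    x <- m[i, ]; y <- m[j, ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
    z[i, j] <- atanh(r)
  }
  z
}

# planted two-pattern voxel-by-time dataset for ICA recovery checks:
# two disjoint 60-voxel patterns in a 1200-voxel mask, amplitude 3 against
# unit voxel noise, four 120-frame subjects
ica_recovery_data <- function(seed, v = 1200, p = 60, amp = 3,
                              n_subj = 4, t_subj = 120) {
  set.seed(seed)
  s1 <- c(rep(1, p), rep(0, v - p))
  s2 <- c(rep(0, p), rep(1, p), rep(0, v - 2 * p))
  a <- matrix(rnorm(2 * n_subj * t_subj), 2)
  X <- amp * cbind(s1, s2) %*% a + matrix(rnorm(v * n_subj * t_subj), v)
  subjects <- lapply(seq_len(n_subj), function(k) {
    X[, ((k - 1) * t_subj + 1):(k * t_subj), drop = FALSE]
  })
  list(subjects = subjects, truth = cbind(s1, s2))
}

# regional time series with an explicit reference row
ts_with_reference <- function(act, ref, frame_min = 1) {
  n <- ncol(act)
  vals <- rbind(act, ref)
  abbrs <- c(rownames(act), "Cer")
  rownames(vals) <- abbrs
  regional_ts(vals, c(seq_len(nrow(act)), 49L),
              seq(0.5, by = frame_min, length.out = n),
              "PET", abbreviations = abbrs)
}
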