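#' Voxelwise two-sample t-map between groups of static uptake images
#'
#' Computes a voxelwise two-sample t statistic (group a minus group b) on
#' whole-brain-mean normalized static uptake images, with Bonferroni
#' familywise-error correction over in-mask voxels. The unpaired test is the
#' default; `paired = TRUE` computes the paired t over matched image pairs
#' (the within-subject design variant).
#'
#' @param group_a,group_b Lists of `static_image` objects on one grid; inputs
#'   must be normalized (`normalization != "none"`).
#' @param alpha FWE level (default 0.05).
#' @param paired Paired t-test over matched pairs (requires equal group
#'   sizes).
#' @param contrast Label stored with the map (e.g. `"early_vs_baseline"`).
#' @param mask Optional 3D logical array; defaults to the first image's mask.
#' @return An `effect_map`: `t_volume` (3D), `p_volume` (uncorrected),
#'   `fwe_mask`, `df`, `contrast`, `alpha`, `mask`.
#' @export
effect_tmap <- function(group_a, group_b, alpha = 0.05, paired = FALSE,
                        contrast = "a_vs_b", mask = NULL) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty")
  }
  all_imgs <- c(group_a, group_b)
  dims <- dim(group_a[[1]]$data)
  for (img in all_imgs) {
    if (!inherits(img, "static_image")) stop("inputs must be static_image objects")
    if (!identical(dim(img$data), dims)) stop("grid mismatch between images")
    if (identical(img$normalization, "none")) {
      stop("unnormalized input; normalize static images before t-mapping")
    }
  }
  A <- vapply(group_a, function(im) as.vector(im$data), numeric(prod(dims)))
  B <- vapply(group_b, function(im) as.vector(im$data), numeric(prod(dims)))
  na <- ncol(A); nb <- ncol(B)
  if (paired) {
    if (na != nb) stop("paired test requires equal group sizes")
    D <- A - B
    m <- rowMeans(D)
    s <- apply(D, 1, stats::sd)
    se <- s / sqrt(na)
    df <- na - 1
  } else {
    m <- rowMeans(A) - rowMeans(B)
    va <- apply(A, 1, stats::var)
    vb <- apply(B, 1, stats::var)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t_stat <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  if (is.null(mask)) mask <- group_a[[1]]$mask
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  n_vox <- sum(mask)
  p_fwe <- pmin(p * n_vox, 1)
  fwe <- array(p_fwe < alpha, dim = dims) & mask
  structure(list(t_volume = array(t_stat, dim = dims),
                 p_volume = array(p, dim = dims),
                 fwe_mask = fwe, df = df, contrast = contrast,
                 alpha = alpha, mask = mask, paired = paired),
            class = "effect_map")
}

#' @export
print.effect_map <- function(x, ...) {
  cat("<effect_map> contrast '", x$contrast, "', df = ", x$df,
      ", ", sum(x$fwe_mask), " FWE-surviving voxels (alpha ", x$alpha, ")\n",
      sep = "")
  invisible(x)
}

#' Regional quantification of an effect map
#'
#' Mean and standard deviation of voxel t-scores per atlas region, in
#' region-table position order (one row per region).
#'
#' @param map An `effect_map`.
#' @param atlas A `pet_atlas` on the same grid.
#' @return Data.frame with `position`, `abbreviation`, `hemisphere`,
#'   `mean_t`, `sd_t`.
#' @export
regional_effect_scores <- function(map, atlas) {
  stopifnot(inherits(map, "effect_map"), inherits(atlas, "pet_atlas"))
  if (!identical(dim(map$t_volume), dim(atlas$label_volume))) {
    stop("grid mismatch between effect map and atlas")
  }
  labs <- as.integer(atlas$label_volume)
  tvec <- as.vector(map$t_volume)
  tab <- atlas$region_table
  out <- do.call(rbind, lapply(tab$position, function(p) {
    v <- tvec[labs == p]
    if (length(v) == 0L) stop("region at position ", p, " has no voxels")
    data.frame(position = p,
               abbreviation = tab$abbreviation[tab$position == p],
               hemisphere = tab$hemisphere[tab$position == p],
               mean_t = mean(v),
               sd_t = if (length(v) > 1L) stats::sd(v) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-region paired t of global connectivity strength, post vs baseline
#'
#' For each region, its global molecular-connectivity strength is the mean
#' Fisher-z of its edges to all other regions. This is computed per subject
#' for a baseline-window and a post-challenge-window connectome, and the
#' paired t statistic (post minus baseline) is returned per region: planted
#' connectivity reductions yield negative t.
#'
#' @param baseline_conns,post_conns Lists of `connectome` objects, matched by
#'   subject, identical region sets.
#' @return Data.frame with `position`, `t`, `p`, `mean_diff`.
#' @export
regional_mc_strength_change <- function(baseline_conns, post_conns) {
  n <- length(baseline_conns)
  if (n != length(post_conns)) stop("subject lists differ in length")
  if (n < 2L) stop("need at least 2 subjects")
  pos <- baseline_conns[[1]]$region_positions
  R <- length(pos)
  gs <- function(conn) rowSums(conn$z) / (R - 1)   # global strength per region
  Base <- vapply(baseline_conns, gs, numeric(R))
  Post <- vapply(post_conns, gs, numeric(R))
  out <- do.call(rbind, lapply(seq_len(R), function(i) {
    res <- paired_t(Post[i, ], Base[i, ])
    data.frame(position = pos[i], t = res$t, p = res$p,
               mean_diff = res$mean_diff)
  }))
  rownames(out) <- NULL
  out
}

#' Compare regional BP_ND changes with molecular-connectivity changes
#'
#' Correlates the per-region t-scores of the drug-induced binding change
#' (from [regional_effect_scores()] of a post-vs-baseline t-map) with the
#' per-region paired-t of global MC strength change (from
#' [regional_mc_strength_change()]). With the post-minus-baseline sign
#' convention, planted reductions are negative in both vectors.
#'
#' @param bp_t Per-region BP_ND-change t-scores.
#' @param mc_t Per-region MC-strength-change t-scores, same region order.
#' @return List with `r`, `p`, `n`, and a `table` data.frame for plotting.
#' @export
bp_change_vs_mc_change <- function(bp_t, mc_t) {
  if (length(bp_t) != length(mc_t)) {
    stop("length mismatch: ", length(bp_t), " vs ", length(mc_t))
  }
  ct <- stats::cor.test(bp_t, mc_t, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(bp_t),
       table = data.frame(region = seq_along(bp_t), bp_t = bp_t,
                          mc_t = mc_t))
}

#' Half-drop onset time of a declining time course
#'
#' Estimates when a displacement effect begins by locating the first
#' crossing of the midpoint between the baseline level (mean over
#' `baseline_window_min`) and the final plateau (mean of the last
#' `tail_min`), with linear interpolation between samples. Used to compare
#' the immediate subcortical versus delayed salience response.
#'
#' @param values Numeric time course (e.g. network-mean BP_ND).
#' @param time_min Sample times, minutes.
#' @param baseline_window_min Length-2 window defining the pre-challenge
#'   level.
#' @param tail_min Minutes at the end of the series defining the plateau.
#' @return Crossing time in minutes (`NA` if the series never crosses).
#' @export
detect_onset <- function(values, time_min, baseline_window_min = c(20, 40),
                         tail_min = 10) {
  sel_b <- time_min >= baseline_window_min[1] & time_min < baseline_window_min[2]
  if (!any(sel_b)) stop("baseline window contains no samples")
  base <- mean(values[sel_b])
  plateau <- mean(values[time_min > max(time_min) - tail_min])
  if (plateau >= base) return(NA_real_)   # no drop to time
  half <- (base + plateau) / 2
  after <- which(time_min >= baseline_window_min[2] - 1e-9)
  below <- after[values[after] <= half]
  if (length(below) == 0L) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(time_min[1L])
  # linear interpolation between the bracketing samples
  t0 <- time_min[i - 1L]; t1 <- time_min[i]
  v0 <- values[i - 1L]; v1 <- values[i]
  if (v0 == v1) return(t1)
  t0 + (half - v0) / (v1 - v0) * (t1 - t0)
}
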