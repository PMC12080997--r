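#' Subject-level Fisher-z connectome
#'
#' Pairwise Pearson correlations between all regional time courses,
#' variance-stabilized with Fisher's transformation z = arctanh(r).
#' Correlations are clipped to +/-(1 - 1e-7) before arctanh so entries stay
#' finite; the diagonal is zero by convention. Regions with zero variance in
#' the window contribute zero edges (with a warning) rather than failing.
#'
#' @param x A `bp_series`, `regional_ts`, or plain region-by-sample matrix.
#' @param window_min Optional length-2 window (minutes, half-open
#'   `[start, end)`) applied to the object's time axis; ignored for plain
#'   matrices.
#' @param subject_id Optional subject identifier carried in the result.
#' @return A `connectome` object with fields `z`, `region_positions`,
#'   `subject_id`, `window_min`, `modality`.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(5 * 30), 5)
#' conn <- subject_connectome(m)
#' max(abs(conn$z - t(conn$z)))   # exactly symmetric
#' @export
subject_connectome <- function(x, window_min = NULL, subject_id = NULL) {
  info <- series_matrix(x)
  vals <- info$values
  if (!is.null(window_min) && !is.null(info$time)) {
    sel <- info$time >= window_min[1] & info$time < window_min[2]
    vals <- vals[, sel, drop = FALSE]
  } else if (is.null(window_min) && !is.null(info$time)) {
    window_min <- range(info$time)
  }
  if (ncol(vals) < 3L) stop("need at least 3 samples, got ", ncol(vals))
  sds <- apply(vals, 1, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate)) {
    warning("zero-variance region(s) at position(s) ",
            paste(info$positions[degenerate], collapse = ", "),
            "; their edges set to 0")
  }
  r <- suppressWarnings(stats::cor(t(vals)))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z <- (z + t(z)) / 2          # enforce exact symmetry
  diag(z) <- 0
  structure(list(z = z,
                 region_positions = info$positions,
                 subject_id = subject_id,
                 window_min = if (is.null(window_min)) NULL
                              else as.numeric(window_min),
                 modality = info$modality),
            class = "connectome")
}

# normalize the various time-series containers to (values, positions, time)
series_matrix <- function(x) {
  if (inherits(x, "bp_series") || inherits(x, "regional_ts")) {
    list(values = x$values, positions = x$region_positions,
         time = x$frame_mid_min,
         modality = if (identical(x$modality, "BOLD")) "BOLD" else "PET")
  } else if (is.matrix(x)) {
    list(values = x, positions = seq_len(nrow(x)), time = NULL,
         modality = "PET")
  } else {
    stop("unsupported input of class ", paste(class(x), collapse = "/"))
  }
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", nrow(x$z), " regions (", x$modality, ")",
      if (!is.null(x$window_min)) paste0(", window [",
        paste(round(x$window_min, 1), collapse = ", "), "] min"),
      "\n", sep = "")
  invisible(x)
}

#' Group connectome with familywise-error edge statistics
#'
#' Averages subject Fisher-z matrices elementwise and tests every unique edge
#' against zero with a one-sample t-test across subjects, Bonferroni-corrected
#' over the R(R-1)/2 unique edges. The FWE mask records which edges survive;
#' stored z values are never altered (masking is a display convention, see
#' [apply_fwe_mask()]).
#'
#' @param connectomes List of `connectome` objects with identical region sets.
#' @param alpha Familywise error level (default 0.05).
#' @return A `group_connectome` with `mean_z`, `edge_t`, `edge_p`
#'   (uncorrected), `fwe_mask`, `n_subjects`.
#' @export
group_connectome <- function(connectomes, alpha = 0.05) {
  if (length(connectomes) < 2L) stop("need at least 2 subjects")
  pos <- connectomes[[1]]$region_positions
  for (cn in connectomes) {
    if (!identical(cn$region_positions, pos)) {
      stop("subjects have mismatching region sets")
    }
  }
  R <- length(pos)
  n <- length(connectomes)
  Z <- vapply(connectomes, function(cn) cn$z, matrix(0, R, R))
  mean_z <- apply(Z, c(1, 2), mean)
  sd_z <- apply(Z, c(1, 2), stats::sd)
  edge_t <- ifelse(sd_z > 0, mean_z / (sd_z / sqrt(n)),
                   ifelse(mean_z == 0, 0, Inf))
  edge_p <- 2 * stats::pt(-abs(edge_t), df = n - 1)
  diag(edge_t) <- 0
  diag(edge_p) <- 1
  m_edges <- R * (R - 1) / 2
  p_fwe <- pmin(edge_p * m_edges, 1)
  fwe_mask <- p_fwe < alpha
  diag(fwe_mask) <- FALSE
  structure(list(mean_z = mean_z, edge_t = edge_t, edge_p = edge_p,
                 fwe_mask = fwe_mask, n_subjects = n,
                 region_positions = pos, alpha = alpha),
            class = "group_connectome")
}

#' Zero non-surviving edges of a group connectome
#'
#' Display convention used for group matrices: entries whose edges do not
#' survive the FWE threshold are set exactly to zero.
#'
#' @param gc A `group_connectome`.
#' @return The thresholded mean-z matrix.
#' @export
apply_fwe_mask <- function(gc) {
  stopifnot(inherits(gc, "group_connectome"))
  out <- gc$mean_z
  out[!gc$fwe_mask] <- 0
  out
}

#' Edge-level similarity between two connectomes
#'
#' Pearson correlation over the vectorized unique off-diagonal edges of two
#' matrices on the same region set (e.g. molecular vs hemodynamic, or early
#' vs late windows).
#'
#' @param a,b `connectome` or `group_connectome` objects (or plain symmetric
#'   matrices) with identical dimensions.
#' @return Pearson r (scalar).
#' @export
edge_similarity <- function(a, b) {
  za <- connectome_z(a)
  zb <- connectome_z(b)
  if (!identical(dim(za), dim(zb))) {
    stop("dimension mismatch: ", nrow(za), " vs ", nrow(zb), " regions")
  }
  lt <- lower.tri(za)
  stats::cor(za[lt], zb[lt])
}

connectome_z <- function(x) {
  if (inherits(x, "connectome")) x$z
  else if (inherits(x, "group_connectome")) x$mean_z
  else if (is.matrix(x)) x
  else stop("unsupported input of class ", paste(class(x), collapse = "/"))
}

#' Sliding-window connectomes
#'
#' Computes one connectome per 20-min (by default) window sliding across the
#' scan; window starts are `start_min, start_min + step_min, ...` up to the
#' latest start not exceeding `end_min - window_len_min`. Each entry equals
#' [subject_connectome()] applied to the corresponding half-open slice.
#'
#' @param x A `bp_series` or `regional_ts` (must carry a time axis covering
#'   `[start_min, end_min]`).
#' @param window_len_min Window length, minutes.
#' @param start_min,end_min Analysis span, minutes.
#' @param step_min Step between window starts, minutes.
#' @param subject_id Optional id attached to each window connectome.
#' @return List of `connectome` objects; window starts in
#'   `attr(, "window_starts")`.
#' @export
sliding_window_connectomes <- function(x, window_len_min = 20, start_min = 20,
                                       end_min = 80, step_min = 5,
                                       subject_id = NULL) {
  info <- series_matrix(x)
  if (is.null(info$time)) stop("input must carry a time axis")
  if (end_min - start_min < window_len_min) {
    stop("window (", window_len_min, " min) longer than the analysis span")
  }
  spacing <- stats::median(diff(info$time))
  if (min(info$time) - start_min > spacing ||
      end_min - max(info$time) > spacing) {
    stop("series does not cover [", start_min, ", ", end_min, "] min")
  }
  starts <- seq(start_min, end_min - window_len_min, by = step_min)
  out <- lapply(starts, function(s) {
    subject_connectome(x, window_min = c(s, s + window_len_min),
                       subject_id = subject_id)
  })
  attr(out, "window_starts") <- starts
  out
}

#' Within-network strength of a connectome
#'
#' Network strength is the mean Fisher-z over the unique within-network
#' edges; node strength is each member node's mean z to the other members.
#'
#' @param conn A `connectome` (or symmetric z matrix indexed by position).
#' @param net A `network_definition`.
#' @param region_table Region table used to resolve members.
#' @return List with `network_strength` (scalar) and `node_strength`
#'   (named numeric, one per member position).
#' @export
network_strength <- function(conn, net, region_table = schiffer_region_table()) {
  z <- connectome_z(conn)
  pos_all <- if (inherits(conn, "connectome")) conn$region_positions
             else seq_len(nrow(z))
  members <- resolve_network(net, region_table)
  idx <- match(members, pos_all)
  if (anyNA(idx)) {
    stop("network member position(s) absent from connectome: ",
         paste(members[is.na(idx)], collapse = ", "))
  }
  sub <- z[idx, idx, drop = FALSE]
  ut <- upper.tri(sub)
  node <- rowSums(sub) / (length(idx) - 1L)
  names(node) <- members
  list(network_strength = mean(sub[ut]), node_strength = node)
}

# paired / one-sample t that tolerates zero-variance differences
paired_t <- function(x, y = NULL, mu = 0, alternative = "two.sided") {
  d <- if (is.null(y)) x - mu else x - y
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired observations")
  s <- stats::sd(d)
  m <- mean(d)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t_stat <- m / (s / sqrt(n))
  }
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t_stat), df = n - 1),
              greater = stats::pt(t_stat, df = n - 1, lower.tail = FALSE),
              less = stats::pt(t_stat, df = n - 1))
  list(t = t_stat, p = p, df = n - 1, mean_diff = m)
}

#' Time-resolved network strength with paired tests against baseline
#'
#' For each subject and sliding window, computes the within-network strength;
#' each post-baseline window is then compared to the baseline window with a
#' paired t-test across subjects, and p-values are Benjamini-Hochberg
#' FDR-corrected over windows. A single baseline-vs-final-window paired test
#' is also reported.
#'
#' @param subject_windows List (one element per subject) of equal-length
#'   lists of `connectome` objects, as produced by
#'   [sliding_window_connectomes()] per subject.
#' @param net A `network_definition`.
#' @param region_table Region table used to resolve members.
#' @param baseline Index of the baseline window (default 1, i.e. the first
#'   window).
#' @param alpha Significance level for the FDR-corrected flags.
#' @return A `network_strength_tc` object: per-subject strength matrix
#'   (subjects x windows), per-window mean/sd, paired t and p per window,
#'   FDR-corrected p, significance flags, and the final-vs-baseline test.
#' @export
network_strength_timecourse <- function(subject_windows, net,
                                        region_table = schiffer_region_table(),
                                        baseline = 1L, alpha = 0.05) {
  n_sub <- length(subject_windows)
  if (n_sub < 2L) stop("need at least 2 subjects")
  n_win <- length(subject_windows[[1]])
  if (any(vapply(subject_windows, length, 0L) != n_win)) {
    stop("subjects have differing numbers of windows")
  }
  S <- matrix(NA_real_, n_sub, n_win)
  for (s in seq_len(n_sub)) {
    for (w in seq_len(n_win)) {
      S[s, w] <- network_strength(subject_windows[[s]][[w]], net,
                                  region_table)$network_strength
    }
  }
  t_vec <- p_vec <- rep(NA_real_, n_win)
  for (w in seq_len(n_win)) {
    if (w == baseline) next
    res <- paired_t(S[, w], S[, baseline])
    t_vec[w] <- res$t
    p_vec[w] <- res$p
  }
  p_fdr <- rep(NA_real_, n_win)
  tested <- which(!is.na(p_vec))
  p_fdr[tested] <- stats::p.adjust(p_vec[tested], method = "BH")
  final <- paired_t(S[, n_win], S[, baseline])
  starts <- attr(subject_windows[[1]], "window_starts")
  structure(list(strength = S,
                 window_starts = starts,
                 mean = colMeans(S),
                 sd = apply(S, 2, stats::sd),
                 t = t_vec, p = p_vec, p_fdr = p_fdr,
                 significant = !is.na(p_fdr) & p_fdr < alpha,
                 baseline = baseline,
                 final_test = final,
                 network = net$name, alpha = alpha),
            class = "network_strength_tc")
}

#' @export
print.network_strength_tc <- function(x, ...) {
  cat("<network_strength_tc> network '", x$network, "', ",
      nrow(x$strength), " subjects x ", ncol(x$strength), " windows\n",
      "  final vs baseline: t = ", round(x$final_test$t, 3),
      ", p = ", signif(x$final_test$p, 3), "\n", sep = "")
  invisible(x)
}
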