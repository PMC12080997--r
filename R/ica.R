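#' Spatial group independent component analysis
#'
#' Decomposes temporally concatenated multi-subject 4D series into spatially
#' independent maps. Per subject, in-mask voxel series restricted to the
#' analysis window are voxelwise standardized; subjects are concatenated
#' along time; dimensionality is reduced to `n_components` principal
#' components; and a symmetric fixed-point ICA (logcosh contrast) with
#' deterministic seeded initialization yields the spatial maps. Each map is
#' z-scored over in-mask voxels and sign-flipped to positive skewness.
#'
#' For PET, the intended input is the voxelwise framewise DVR-1 series
#' (reference-normalized, detrended), which makes the components
#' binding-driven; for BOLD, the preprocessed signal over the same window.
#'
#' @param images List of `dynamic_image` objects (one per subject), or list
#'   of voxel-by-time matrices (then `mask` indexing is skipped and all rows
#'   are used; a window is only applied when a time axis is available).
#' @param mask Optional 3D logical array selecting in-brain voxels (images
#'   input only). Defaults to all voxels.
#' @param n_components Number of independent components.
#' @param seed Integer seed for the deterministic random initialization.
#' @param analysis_window_min Length-2 half-open window in minutes (default
#'   `c(30, 80)`); `NULL` uses all frames.
#' @param tol Convergence tolerance of the fixed-point iteration.
#' @param max_iter Maximum iterations before failing with an error.
#' @return A `component_maps` object: `maps` (voxels x components, z-scored),
#'   `threshold_z` (1.96), `mask`, `dims`, `seed`, `n_iter`.
#' @export
group_spatial_ica <- function(images, mask = NULL, n_components = 2,
                              seed = 1L, analysis_window_min = c(30, 80),
                              tol = 1e-6, max_iter = 1000L) {
  if (length(images) < 1L) stop("need at least one subject")
  dims <- NULL
  blocks <- lapply(images, function(img) {
    if (inherits(img, "dynamic_image")) {
      d <- dim(img$data)
      if (is.null(mask)) mask <<- array(TRUE, dim = d[1:3])
      dims <<- d[1:3]
      mat <- matrix(img$data, nrow = prod(d[1:3]), ncol = d[4])[as.vector(mask), ,
                                                                drop = FALSE]
      tm <- frame_mid_min(img)
      if (!is.null(analysis_window_min)) {
        sel <- tm >= analysis_window_min[1] & tm < analysis_window_min[2]
        if (!any(sel)) stop("no frames inside the analysis window")
        mat <- mat[, sel, drop = FALSE]
      }
      mat
    } else if (is.matrix(img)) {
      img
    } else {
      stop("unsupported subject input of class ",
           paste(class(img), collapse = "/"))
    }
  })
  nv <- unique(vapply(blocks, nrow, 0L))
  if (length(nv) != 1L) stop("subjects have differing voxel counts")
  # voxelwise standardization per subject, then temporal concatenation
  blocks <- lapply(blocks, function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1, stats::sd)
    s[s == 0] <- 1
    (m - mu) / s
  })
  X <- do.call(cbind, blocks)
  n_total <- ncol(X)
  if (n_components >= n_total) {
    stop("n_components (", n_components,
         ") must be smaller than total concatenated time points (",
         n_total, ")")
  }
  X <- sweep(X, 2, colMeans(X))      # center each time point over voxels
  sv <- svd(X, nu = n_components, nv = 0)
  Z <- scale(sv$u, center = TRUE, scale = TRUE)   # whitened, unit variance
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  k <- n_components
  V <- nrow(Z)
  set.seed(seed)
  W <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    S <- Z %*% t(W)                  # V x k current source estimates
    G <- tanh(S)
    W_new <- crossprod(G, Z) / V - diag(colMeans(1 - G^2), k, k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("fixed-point ICA did not converge after ", max_iter,
         " iterations (tolerance ", tol, ")")
  }
  S <- Z %*% t(W)
  S <- apply(S, 2, function(s) {
    s <- (s - mean(s)) / stats::sd(s)
    if (mean(s^3) < 0) -s else s     # sign convention: positive skewness
  })
  structure(list(maps = S, n_components = k, threshold_z = 1.96,
                 mask = mask, dims = dims, seed = seed, n_iter = iter),
            class = "component_maps")
}

# symmetric decorrelation: W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' @export
print.component_maps <- function(x, ...) {
  cat("<component_maps> ", x$n_components, " components x ", nrow(x$maps),
      " voxels, threshold |z| >= ", x$threshold_z,
      ", converged in ", x$n_iter, " iterations\n", sep = "")
  invisible(x)
}

#' Threshold component maps
#'
#' Retains exactly the voxels with `|z| >= threshold`; all others are set to
#' zero. The default 1.96 corresponds to a two-sided p <= 0.05.
#'
#' @param maps A `component_maps` object.
#' @param threshold z threshold (default the object's `threshold_z`).
#' @return A `component_maps` object with thresholded maps.
#' @export
threshold_components <- function(maps, threshold = maps$threshold_z) {
  stopifnot(inherits(maps, "component_maps"))
  out <- maps
  out$maps[abs(out$maps) < threshold] <- 0
  out$threshold_z <- threshold
  out
}

#' Regional quantification of component maps
#'
#' Per component and region: mean and standard deviation of the
#' (unthresholded) voxel z-scores, in region-table position order.
#'
#' @param maps A `component_maps` produced from images on the atlas grid.
#' @param atlas A `pet_atlas` on the same grid as the maps.
#' @return A data.frame with columns `component`, `position`, `abbreviation`,
#'   `hemisphere`, `mean_z`, `sd_z`.
#' @export
regional_component_scores <- function(maps, atlas) {
  stopifnot(inherits(maps, "component_maps"), inherits(atlas, "pet_atlas"))
  if (is.null(maps$mask)) stop("maps carry no voxel grid information")
  if (!identical(dim(maps$mask), dim(atlas$label_volume))) {
    stop("grid mismatch between maps and atlas")
  }
  labs <- as.integer(atlas$label_volume)[as.vector(maps$mask)]
  tab <- atlas$region_table
  out <- do.call(rbind, lapply(seq_len(maps$n_components), function(ic) {
    do.call(rbind, lapply(tab$position, function(p) {
      v <- maps$maps[labs == p, ic]
      if (length(v) == 0L) stop("region at position ", p,
                                " has no in-mask voxels")
      data.frame(component = ic, position = p,
                 abbreviation = tab$abbreviation[tab$position == p],
                 hemisphere = tab$hemisphere[tab$position == p],
                 mean_z = mean(v),
                 sd_z = if (length(v) > 1L) stats::sd(v) else 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Correlate regional component scores with regional effect scores
#'
#' Pearson correlation (with two-sided p) between a component's regional
#' z-scores and the regional t-scores of a drug effect, across regions in
#' identical position order.
#'
#' @param ic_scores Numeric vector of per-region component z-scores.
#' @param effect_tscores Numeric vector of per-region effect t-scores, same
#'   order and length.
#' @return List with `r`, `p`, `n`.
#' @export
component_effect_correlation <- function(ic_scores, effect_tscores) {
  if (length(ic_scores) != length(effect_tscores)) {
    stop("length mismatch: ", length(ic_scores), " vs ",
         length(effect_tscores))
  }
  if (length(ic_scores) < 5L) stop("need at least 5 regions")
  ct <- stats::cor.test(ic_scores, effect_tscores, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ic_scores))
}

#' Greedy matching of estimated components to reference maps
#'
#' Assigns each reference map the estimated component with the largest
#' absolute spatial correlation, without replacement (used to score
#' recovery of planted patterns in simulations).
#'
#' @param estimated Voxels-by-k matrix (or `component_maps`).
#' @param reference Voxels-by-m matrix of reference maps.
#' @return Data.frame with `reference`, `component`, `abs_r`.
#' @export
match_components <- function(estimated, reference) {
  E <- if (inherits(estimated, "component_maps")) estimated$maps else estimated
  R <- as.matrix(reference)
  cors <- abs(stats::cor(R, E))          # m x k
  m <- nrow(cors)
  out <- data.frame(reference = seq_len(m), component = NA_integer_,
                    abs_r = NA_real_)
  avail <- rep(TRUE, ncol(cors))
  for (step in seq_len(m)) {
    cand <- cors
    cand[out$reference[!is.na(out$component)], ] <- -Inf
    cand[, !avail] <- -Inf
    idx <- arrayInd(which.max(cand), dim(cand))
    out$component[idx[1]] <- idx[2]
    out$abs_r[idx[1]] <- cors[idx[1], idx[2]]
    avail[idx[2]] <- FALSE
  }
  out
}
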