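#' Load the packaged Schiffer rat-brain region table
#'
#' Returns the 48-region parcellation metadata used throughout the package:
#' 23 bilateral regions (hemisphere-expanded into separate left/right rows)
#' plus the midline periaqueductal gray and septum. The `position` column
#' fixes the row/column ordering of every correlation matrix produced by the
#' connectivity functions.
#'
#' @param path Optional path to an alternative tab-separated region table with
#'   columns `region`, `hemisphere`, `volume_mm3`, `position`, `abbreviation`.
#'   Defaults to the table shipped with the package.
#' @return A `data.frame` of class `region_table` with one row per region
#'   (48 rows for the packaged table), ordered by `position`.
#' @examples
#' tab <- schiffer_region_table()
#' nrow(tab)                      # 48
#' region_lookup(tab, "NAc", "left")$volume_mm3
#' @export
schiffer_region_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "schiffer_region_table.tsv",
                        package = "molconn", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_region_table(tab)
}

#' Validate a region table
#'
#' Checks the invariants the rest of the package relies on: unique contiguous
#' positions `1..n`, positive volumes, a legal hemisphere code per row, and
#' consecutive left/right positions for bilateral regions.
#'
#' @param tab A data.frame with columns `region`, `hemisphere`, `volume_mm3`,
#'   `position`, `abbreviation`.
#' @return `tab`, ordered by position, with class `region_table` prepended.
#' @export
validate_region_table <- function(tab) {
  required <- c("region", "hemisphere", "volume_mm3", "position", "abbreviation")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("region table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  pos <- tab$position
  if (anyDuplicated(pos)) {
    dup <- pos[duplicated(pos)][1L]
    bad <- tab[tab$position == dup, , drop = FALSE]
    stop("duplicated matrix position ", dup, " (rows: ",
         paste(bad$region, bad$hemisphere, collapse = "; "), ")")
  }
  if (!setequal(pos, seq_len(nrow(tab)))) {
    stop("matrix positions must be contiguous 1..", nrow(tab),
         "; found range [", min(pos), ", ", max(pos), "]")
  }
  if (any(!is.finite(tab$volume_mm3) | tab$volume_mm3 <= 0)) {
    bad <- tab$region[!is.finite(tab$volume_mm3) | tab$volume_mm3 <= 0][1L]
    stop("non-positive volume for region '", bad, "'")
  }
  if (!all(tab$hemisphere %in% c("left", "right", "midline"))) {
    bad <- tab$hemisphere[!tab$hemisphere %in% c("left", "right", "midline")][1L]
    stop("invalid hemisphere code '", bad, "'")
  }
  # bilateral regions: exactly one left and one right row, consecutive positions
  for (ab in unique(tab$abbreviation)) {
    rows <- tab[tab$abbreviation == ab, , drop = FALSE]
    if (any(rows$hemisphere %in% c("left", "right"))) {
      if (nrow(rows) != 2L || !setequal(rows$hemisphere, c("left", "right"))) {
        stop("bilateral region '", ab, "' must appear exactly twice (left, right)")
      }
      if (abs(diff(sort(rows$position))) != 1L) {
        stop("bilateral region '", ab, "' has non-consecutive positions")
      }
    }
  }
  tab <- tab[order(tab$position), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- unique(c("region_table", class(tab)))
  tab
}

#' Look up rows of a region table
#'
#' @param tab A `region_table`.
#' @param abbreviation Region abbreviation, e.g. `"NAc"`.
#' @param hemisphere Optional hemisphere filter (`"left"`, `"right"`,
#'   `"midline"`).
#' @return The matching rows (data.frame); errors if nothing matches.
#' @export
region_lookup <- function(tab, abbreviation, hemisphere = NULL) {
  hit <- tab$abbreviation == abbreviation
  if (!is.null(hemisphere)) hit <- hit & tab$hemisphere == hemisphere
  if (!any(hit)) {
    stop("no region matching abbreviation '", abbreviation, "'",
         if (!is.null(hemisphere)) paste0(" (", hemisphere, ")"))
  }
  tab[hit, , drop = FALSE]
}

#' Serotonergic network definitions
#'
#' The two SERT networks used in the challenge analyses: the salience network
#' (NAc, Amyg, Str, Cg, Ins, mPFC) and the subcortical network
#' (VTA, Th, MB, PAG, Hyp). Members are abbreviations; bilateral members
#' resolve to both hemispheres.
#'
#' @return Named list of `network_definition` objects, each a list with
#'   `name` and `members`.
#' @export
network_definitions <- function() {
  defs <- list(
    salience = network_definition("salience",
                                  c("NAc", "Amyg", "Str", "Cg", "Ins", "mPFC")),
    subcortical = network_definition("subcortical",
                                     c("VTA", "Th", "MB", "PAG", "Hyp"))
  )
  defs
}

#' Construct a network definition
#'
#' @param name Network name.
#' @param members Character vector of region abbreviations (nonempty).
#' @return A `network_definition` object.
#' @export
network_definition <- function(name, members) {
  if (length(members) == 0L) stop("network '", name, "' has no members")
  structure(list(name = name, members = as.character(members)),
            class = "network_definition")
}

#' Resolve network members to matrix positions
#'
#' @param net A `network_definition`.
#' @param tab A `region_table`.
#' @return Integer vector of matrix positions (both hemispheres for bilateral
#'   members), sorted.
#' @export
resolve_network <- function(net, tab = schiffer_region_table()) {
  unmatched <- setdiff(net$members, tab$abbreviation)
  if (length(unmatched) > 0L) {
    stop("network '", net$name, "' has member(s) not in the region table: ",
         paste(unmatched, collapse = ", "))
  }
  sort(tab$position[tab$abbreviation %in% net$members])
}

#' Construct an atlas object
#'
#' An atlas couples an integer label volume with the region table. Labels
#' encode matrix positions directly (`0` = background); an optional extra
#' label marks the reference region (cerebellum), which is not part of the
#' correlation matrix.
#'
#' @param label_volume 3D integer array; `0` background, `k > 0` the matrix
#'   position of a region (or `reference_label`).
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm.
#' @param region_table A `region_table`.
#' @param reference_label Integer label of the reference region in
#'   `label_volume`, or `NA` if absent.
#' @param reference_abbreviation Abbreviation used for the reference region.
#' @return An object of class `pet_atlas`.
#' @export
pet_atlas <- function(label_volume, voxel_size_mm = c(1, 1, 1),
                      region_table = schiffer_region_table(),
                      reference_label = NA_integer_,
                      reference_abbreviation = "Cer") {
  if (length(dim(label_volume)) != 3L) stop("label_volume must be 3D")
  labs <- unique(as.integer(label_volume))
  labs <- labs[labs > 0L]
  known <- c(region_table$position,
             if (!is.na(reference_label)) as.integer(reference_label))
  orphan <- setdiff(labs, known)
  if (length(orphan) > 0L) {
    stop("label volume contains label(s) with no region record: ",
         paste(sort(orphan), collapse = ", "))
  }
  structure(list(label_volume = label_volume,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 region_table = region_table,
                 reference_label = if (is.na(reference_label)) NA_integer_
                                   else as.integer(reference_label),
                 reference_abbreviation = reference_abbreviation),
            class = "pet_atlas")
}

#' Toy block atlas for simulations and tests
#'
#' Builds a small synthetic label volume in which every region of the packaged
#' table occupies one rectangular block of voxels, plus one block for the
#' cerebellar reference region. This is a geometric stand-in used by the
#' simulator and the test-suite; it is not an anatomical atlas.
#'
#' @param block Integer length-3, voxels per region block.
#' @param margin Integer, background voxels separating blocks along each axis.
#' @param region_table A `region_table`.
#' @return A `pet_atlas` whose `reference_label` is `nrow(region_table) + 1`.
#' @export
toy_atlas <- function(block = c(3, 3, 2), margin = 1,
                      region_table = schiffer_region_table()) {
  n_regions <- nrow(region_table)
  n_labels <- n_regions + 1L   # + cerebellum reference block
  cell <- block + margin
  # lay cells on a grid just large enough for n_labels
  nx <- ceiling(n_labels^(1 / 3))
  ny <- nx
  nz <- ceiling(n_labels / (nx * ny))
  dims <- c(nx, ny, nz) * cell + margin
  vol <- array(0L, dim = dims)
  lab <- 1L
  for (iz in seq_len(nz)) for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (lab > n_labels) break
    x0 <- (ix - 1L) * cell[1] + margin + 1L
    y0 <- (iy - 1L) * cell[2] + margin + 1L
    z0 <- (iz - 1L) * cell[3] + margin + 1L
    vol[x0:(x0 + block[1] - 1L),
        y0:(y0 + block[2] - 1L),
        z0:(z0 + block[3] - 1L)] <- lab
    lab <- lab + 1L
  }
  pet_atlas(vol, voxel_size_mm = c(1, 1, 1), region_table = region_table,
            reference_label = n_regions + 1L)
}

#' Extract mean regional time series from a 4D image
#'
#' For every requested region, entry `(r, t)` of the result is the arithmetic
#' mean of frame `t` over all voxels carrying that region's label. The image
#' and atlas must live on identical voxel grids (analyses are performed in
#' voxel space on pre-aligned data; no resampling is done).
#'
#' @param image A `dynamic_image`.
#' @param atlas A `pet_atlas` on the same grid.
#' @param regions Which regions to extract: integer positions, or `NULL` for
#'   all table positions present plus the reference region (if labelled).
#' @param include_reference Include the reference-region row (default `TRUE`
#'   when the atlas has one and `regions` is `NULL`).
#' @return A `regional_ts` object (see [regional_ts()]).
#' @export
extract_regional_timeseries <- function(image, atlas, regions = NULL,
                                        include_reference = TRUE) {
  stopifnot(inherits(image, "dynamic_image"), inherits(atlas, "pet_atlas"))
  d <- dim(image$data)
  if (!identical(d[1:3], dim(atlas$label_volume))) {
    stop("grid mismatch: image grid ", paste(d[1:3], collapse = "x"),
         " vs atlas grid ", paste(dim(atlas$label_volume), collapse = "x"))
  }
  labs <- as.integer(atlas$label_volume)
  if (is.null(regions)) {
    regions <- atlas$region_table$position
    if (include_reference && !is.na(atlas$reference_label)) {
      regions <- c(regions, atlas$reference_label)
    }
  }
  regions <- as.integer(regions)
  n_frames <- d[4]
  mat <- matrix(image$data, nrow = prod(d[1:3]), ncol = n_frames)
  counts <- tabulate(labs, nbins = max(regions))
  empty <- regions[counts[regions] == 0L]
  if (length(empty) > 0L) {
    stop("region(s) with zero labelled voxels: ",
         paste(sort(empty), collapse = ", "))
  }
  sel <- labs %in% regions
  sums <- rowsum(mat[sel, , drop = FALSE], group = labs[sel])
  got <- as.integer(rownames(sums))
  values <- sums[match(regions, got), , drop = FALSE] / counts[regions]
  abbrs <- region_abbreviations(regions, atlas)
  rownames(values) <- abbrs
  regional_ts(values,
              region_positions = regions,
              frame_mid_min = frame_mid_min(image),
              modality = image$modality,
              abbreviations = abbrs)
}

region_abbreviations <- function(positions, atlas) {
  tab <- atlas$region_table
  vapply(positions, function(p) {
    if (!is.na(atlas$reference_label) && p == atlas$reference_label) {
      atlas$reference_abbreviation
    } else {
      tab$abbreviation[tab$position == p]
    }
  }, character(1))
}

#' Construct a regional time-series object
#'
#' @param values Region-by-frame numeric matrix.
#' @param region_positions Integer positions (row order of `values`).
#' @param frame_mid_min Frame midpoint times in minutes (strictly increasing).
#' @param modality `"PET"` or `"BOLD"`.
#' @param abbreviations Optional row abbreviations.
#' @return A `regional_ts` object.
#' @export
regional_ts <- function(values, region_positions, frame_mid_min,
                        modality = c("PET", "BOLD"), abbreviations = NULL) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (nrow(values) != length(region_positions)) {
    stop("values rows (", nrow(values), ") != region_positions length (",
         length(region_positions), ")")
  }
  if (ncol(values) != length(frame_mid_min)) {
    stop("values columns (", ncol(values), ") != frame_mid_min length (",
         length(frame_mid_min), ")")
  }
  if (any(diff(frame_mid_min) <= 0)) {
    stop("frame_mid_min must be strictly increasing")
  }
  if (any(!is.finite(values))) stop("time series contains non-finite values")
  if (!is.null(abbreviations)) rownames(values) <- abbreviations
  structure(list(values = values,
                 region_positions = as.integer(region_positions),
                 frame_mid_min = as.numeric(frame_mid_min),
                 modality = modality),
            class = "regional_ts")
}

#' @export
print.regional_ts <- function(x, ...) {
  cat("<regional_ts> ", nrow(x$values), " regions x ", ncol(x$values),
      " frames (", x$modality, "), t = [",
      round(min(x$frame_mid_min), 2), ", ", round(max(x$frame_mid_min), 2),
      "] min\n", sep = "")
  invisible(x)
}
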