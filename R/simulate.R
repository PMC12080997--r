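#' Simulation configuration for a synthetic simultaneous PET/BOLD cohort
#'
#' Defines the acquisition protocol and planted ground truth emulated by
#' [simulate_cohort()]: a bolus-plus-constant-infusion tracer protocol
#' (k_bol = 38.7 min) with 1-min PET frames over an 80-min scan, BOLD at
#' TR = 2 s (2400 volumes), two planted molecular networks (salience and
#' subcortical) with correlated BP_ND fluctuations, and an optional
#' displacement challenge at 40 min with immediate subcortical and
#' ~10-min-delayed salience occupancy.
#'
#' @param n_subjects Number of subjects (default 11, the challenge-cohort
#'   size).
#' @param scan_min Scan length, minutes.
#' @param pet_frame_min PET frame duration, minutes.
#' @param bold_tr_s BOLD repetition time, seconds.
#' @param k_bol_min Bolus-to-infusion ratio, minutes of infusion contained in
#'   the bolus.
#' @param clearance_min Plasma clearance time constant, minutes. Equal to
#'   `k_bol_min` by default, the tuning at which the bolus exactly offsets
#'   clearance and plasma is flat from the start.
#' @param challenge_min Challenge (displacement) time, minutes, or `NULL`
#'   for a baseline (no-challenge) cohort.
#' @param occupancy_amplitude Named per-network plateau occupancies in
#'   `[0, 1)`.
#' @param background_occupancy Plateau occupancy scale for regions outside
#'   the planted networks; each such region receives
#'   `background_occupancy * BP_r / max(BP)` (displacement strongest where
#'   baseline binding is highest).
#' @param salience_delay_min Delay of the salience-network occupancy onset
#'   after the challenge, minutes.
#' @param occupancy_rise_min Minutes from onset to 95% of plateau occupancy.
#' @param connectivity_reduction Named per-network fractional reduction of
#'   the shared-fluctuation coupling after the challenge (what reduces
#'   molecular connectivity; occupancy alone rescales BP and leaves
#'   correlations unchanged).
#' @param fc_reduction Same, for the BOLD (hemodynamic) networks.
#' @param baseline_bp Named per-position baseline BP_ND values; defaults to
#'   [default_baseline_bp()].
#' @param network_defs List of `network_definition`s (default
#'   [network_definitions()]).
#' @param network_coupling Baseline within-network correlation of BP_ND
#'   fluctuations (shared-variance fraction).
#' @param fluctuation_sd Marginal SD of the relative BP_ND fluctuation.
#' @param phi_pet,phi_bold AR(1) coefficients of the latent fluctuation
#'   series per PET frame / BOLD volume.
#' @param noise_sd PET measurement noise: Gaussian SD as a fraction of frame
#'   activity divided by the square root of the frame duration (counting-
#'   noise proxy).
#' @param voxel_noise_sd Extra voxel-level noise fraction used when painting
#'   images.
#' @param infusion_rate Infusion rate in arbitrary activity units per
#'   minute.
#' @param make_images Also paint regional activities into the toy atlas to
#'   produce 4D PET images.
#' @param region_table Region table (default the packaged one).
#' @param seed Top-level integer seed; all randomness flows from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_subjects = 11L,
                       scan_min = 80,
                       pet_frame_min = 1,
                       bold_tr_s = 2,
                       k_bol_min = 38.7,
                       clearance_min = k_bol_min,
                       challenge_min = 40,
                       occupancy_amplitude = c(subcortical = 0.4,
                                               salience = 0.3),
                       background_occupancy = 0.15,
                       salience_delay_min = 10,
                       occupancy_rise_min = 10,
                       connectivity_reduction = c(subcortical = 0.5,
                                                  salience = 0.15),
                       fc_reduction = c(subcortical = 0.05,
                                        salience = 0.2),
                       baseline_bp = NULL,
                       network_defs = network_definitions(),
                       network_coupling = 0.6,
                       fluctuation_sd = 0.1,
                       phi_pet = 0.5,
                       phi_bold = 0.4,
                       noise_sd = 0.02,
                       voxel_noise_sd = 0.05,
                       infusion_rate = 1,
                       make_images = FALSE,
                       region_table = schiffer_region_table(),
                       seed = 1L) {
  if (is.null(baseline_bp)) baseline_bp <- default_baseline_bp(region_table)
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), scan_min = scan_min,
    pet_frame_min = pet_frame_min, bold_tr_s = bold_tr_s,
    k_bol_min = k_bol_min, clearance_min = clearance_min,
    challenge_min = challenge_min,
    occupancy_amplitude = occupancy_amplitude,
    background_occupancy = background_occupancy,
    salience_delay_min = salience_delay_min,
    occupancy_rise_min = occupancy_rise_min,
    connectivity_reduction = connectivity_reduction,
    fc_reduction = fc_reduction,
    baseline_bp = baseline_bp, network_defs = network_defs,
    network_coupling = network_coupling,
    fluctuation_sd = fluctuation_sd,
    phi_pet = phi_pet, phi_bold = phi_bold,
    noise_sd = noise_sd, voxel_noise_sd = voxel_noise_sd,
    infusion_rate = infusion_rate, make_images = make_images,
    region_table = region_table, seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$k_bol_min < 0) stop("k_bol_min must be non-negative")
  if (cfg$clearance_min <= 0) stop("clearance_min must be positive")
  if (!is.null(cfg$challenge_min) &&
      (cfg$challenge_min <= 0 || cfg$challenge_min >= cfg$scan_min)) {
    stop("challenge_min must lie within the scan")
  }
  if (any(cfg$occupancy_amplitude < 0 | cfg$occupancy_amplitude >= 1)) {
    stop("occupancy amplitudes must lie in [0, 1)")
  }
  if (any(cfg$baseline_bp <= 0)) stop("baseline_bp must be positive")
  if (length(cfg$baseline_bp) != nrow(cfg$region_table)) {
    stop("baseline_bp must have one value per region")
  }
  for (nm in names(cfg$occupancy_amplitude)) {
    if (is.null(cfg$network_defs[[nm]])) {
      stop("occupancy_amplitude names an unknown network '", nm, "'")
    }
  }
  cfg
}

#' Default baseline BP_ND values per region
#'
#' High binding in the subcortical SERT network (midbrain, VTA, PAG,
#' thalamus, hypothalamus), moderate binding in the salience regions, low
#' cortical binding, with a mild 3% right-hemisphere asymmetry so every
#' region carries a distinct value. Values are illustrative configuration,
#' not empirical claims.
#'
#' @param region_table A `region_table`.
#' @return Named numeric vector indexed by matrix position.
#' @export
default_baseline_bp <- function(region_table = schiffer_region_table()) {
  levels <- c(MB = 3.0, VTA = 2.8, PAG = 2.6, Th = 2.4, Hyp = 2.2,
              Str = 1.8, NAc = 1.7, Amyg = 1.6, Ins = 1.4, Cg = 1.3,
              mPFC = 1.2)
  bp <- vapply(seq_len(nrow(region_table)), function(i) {
    ab <- region_table$abbreviation[i]
    base <- if (ab %in% names(levels)) levels[[ab]]
            else 0.5 + 0.015 * region_table$position[i]
    if (region_table$hemisphere[i] == "right") base * 1.03 else base
  }, numeric(1))
  names(bp) <- region_table$position
  bp
}

#' Reference-region time-activity curve under bolus plus constant infusion
#'
#' One-tissue-compartment reference tissue driven by a plasma input that
#' combines an instantaneous bolus of `k_bol_min` minutes' worth of infusion
#' with a constant infusion, cleared mono-exponentially:
#' `Cp(t) = R/lambda + R (k_bol - 1/lambda) exp(-lambda t)`. At the default
#' `k_bol = 1/lambda` the plasma level is flat from injection and the tissue
#' curve rises to a stable plateau; `k_bol = 0` is the pure-infusion limit
#' (no initial overshoot).
#'
#' @param config A `sim_config` (or arguments below).
#' @param time_min Evaluation times, minutes; defaults to the config's PET
#'   frame midpoints.
#' @param K1,k2 One-tissue rate constants (per minute); their ratio sets the
#'   reference distribution volume (1 by default).
#' @return List with `time_min` and `activity`.
#' @export
simulate_reference_tac <- function(config = sim_config(), time_min = NULL,
                                   K1 = 0.3, k2 = 0.3) {
  if (config$k_bol_min < 0) stop("k_bol_min must be non-negative")
  if (is.null(time_min)) {
    starts <- seq(0, config$scan_min - config$pet_frame_min,
                  by = config$pet_frame_min)
    time_min <- starts + config$pet_frame_min / 2
  }
  lambda <- 1 / config$clearance_min
  R <- config$infusion_rate
  a <- R / lambda
  b <- R * config$k_bol_min - a
  t <- time_min
  if (abs(k2 - lambda) < 1e-12) {
    trans <- b * t * exp(-k2 * t)
  } else {
    trans <- b * (exp(-lambda * t) - exp(-k2 * t)) / (k2 - lambda)
  }
  act <- K1 * (a * (1 - exp(-k2 * t)) / k2 + trans)
  list(time_min = time_min, activity = act)
}

# truncated-logistic occupancy profile: exactly 0 before onset, monotone,
# reaching 95% of `amplitude` within `rise_min` minutes of onset
occupancy_profile <- function(t, onset, amplitude, rise_min = 10) {
  if (amplitude == 0 || is.null(onset)) return(numeric(length(t)))
  s <- rise_min / 6
  p0 <- stats::plogis(-rise_min / 2 / s)
  f <- (stats::plogis((t - onset - rise_min / 2) / s) - p0) / (1 - p0)
  f[t < onset] <- 0
  amplitude * f
}

# per-region occupancy settings: list(amplitude, onset) resolved from config
region_occupancy_params <- function(cfg) {
  tab <- cfg$region_table
  n <- nrow(tab)
  amp <- numeric(n)
  onset <- rep(NA_real_, n)
  if (is.null(cfg$challenge_min)) {
    return(list(amplitude = amp, onset = onset))
  }
  member_of <- rep(NA_character_, n)
  for (nm in names(cfg$network_defs)) {
    pos <- resolve_network(cfg$network_defs[[nm]], tab)
    member_of[match(pos, tab$position)] <- nm
  }
  bp <- cfg$baseline_bp
  for (i in seq_len(n)) {
    nm <- member_of[i]
    if (!is.na(nm) && nm %in% names(cfg$occupancy_amplitude)) {
      amp[i] <- cfg$occupancy_amplitude[[nm]]
      onset[i] <- cfg$challenge_min +
        if (nm == "salience") cfg$salience_delay_min else 0
    } else {
      amp[i] <- cfg$background_occupancy * bp[i] / max(bp)
      onset[i] <- cfg$challenge_min
    }
  }
  list(amplitude = amp, onset = onset, member_of = member_of)
}

# unit-variance AR(1) series
ar1_series <- function(n, phi) {
  innov <- stats::rnorm(n) * sqrt(1 - phi^2)
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Simulate a synthetic simultaneous PET/BOLD cohort
#'
#' Generates, per subject, a dynamic PET regional time-activity table (48
#' regions plus the cerebellar reference) and a BOLD regional series, with
#' full ground truth. Regional PET activity is
#' `ref(t) * (1 + BP_r(t)) + noise` with
#' `BP_r(t) = baseline_bp_r * (1 - occupancy_r(t)) * (1 + fluctuation_r(t))`;
#' fluctuations mix a shared per-network latent AR(1) factor with a private
#' AR(1) term so that planted networks show correlated BP_ND dynamics. The
#' challenge (if configured) plants an immediate subcortical and a delayed
#' salience occupancy and scales down the shared-factor coupling
#' (`connectivity_reduction`), which is what reduces molecular connectivity.
#' BOLD series are built from the same latent-factor construction at TR
#' resolution. With `make_images = TRUE`, regional activities are painted
#' into the toy block atlas as 4D images (with voxel-level noise).
#'
#' Identical seeds yield identical cohorts.
#'
#' @param config A `sim_config`.
#' @return A `sim_cohort` object: `pet` and `bold` lists of `regional_ts`
#'   (one per subject), optional `pet_images`, the `atlas` used for
#'   painting, and `truth` (network membership, per-region occupancy curves,
#'   true BP series per subject, per-subject seeds, config).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- validate_sim_config(config)
  tab <- cfg$region_table
  n_reg <- nrow(tab)
  set.seed(cfg$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_subjects)

  starts <- seq(0, cfg$scan_min - cfg$pet_frame_min, by = cfg$pet_frame_min)
  sched <- frame_schedule(starts, rep(cfg$pet_frame_min, length(starts)))
  t_pet <- sched$mid_min
  n_pet <- length(t_pet)
  n_bold <- round(cfg$scan_min * 60 / cfg$bold_tr_s)
  t_bold <- (seq_len(n_bold) - 0.5) * cfg$bold_tr_s / 60

  ref <- simulate_reference_tac(cfg, time_min = t_pet)$activity
  occ_par <- region_occupancy_params(cfg)
  occ <- t(vapply(seq_len(n_reg), function(i) {
    occupancy_profile(t_pet, occ_par$onset[i], occ_par$amplitude[i],
                      cfg$occupancy_rise_min)
  }, numeric(n_pet)))

  # coupling time courses per network (shared-variance fraction over time)
  rho_course <- function(times, reduction) {
    lapply(names(cfg$network_defs), function(nm) {
      red <- if (nm %in% names(reduction)) reduction[[nm]] else 0
      onset <- if (is.null(cfg$challenge_min)) NULL
               else cfg$challenge_min +
                 (if (nm == "salience") cfg$salience_delay_min else 0)
      f <- occupancy_profile(times, onset, 1, cfg$occupancy_rise_min)
      cfg$network_coupling * (1 - red * f)
    }) -> out
    names(out) <- names(cfg$network_defs)
    out
  }
  rho_pet <- rho_course(t_pet, cfg$connectivity_reduction)
  rho_bold <- rho_course(t_bold, cfg$fc_reduction)
  member_of <- if (is.null(occ_par$member_of)) {
    mo <- rep(NA_character_, n_reg)
    for (nm in names(cfg$network_defs)) {
      pos <- resolve_network(cfg$network_defs[[nm]], tab)
      mo[match(pos, tab$position)] <- nm
    }
    mo
  } else occ_par$member_of

  abbrs <- c(tab$abbreviation, "Cer")
  positions <- c(tab$position, n_reg + 1L)
  atlas <- if (cfg$make_images) toy_atlas(region_table = tab) else NULL

  pet <- vector("list", cfg$n_subjects)
  bold <- vector("list", cfg$n_subjects)
  pet_images <- if (cfg$make_images) vector("list", cfg$n_subjects) else NULL
  bp_true <- vector("list", cfg$n_subjects)

  mix_series <- function(times, rho_list, phi) {
    u <- lapply(names(cfg$network_defs), function(nm) ar1_series(length(times), phi))
    names(u) <- names(cfg$network_defs)
    m <- matrix(0, n_reg, length(times))
    for (i in seq_len(n_reg)) {
      e <- ar1_series(length(times), phi)
      nm <- member_of[i]
      if (!is.na(nm)) {
        rho <- rho_list[[nm]]
        m[i, ] <- sqrt(rho) * u[[nm]] + sqrt(1 - rho) * e
      } else {
        m[i, ] <- e
      }
    }
    m
  }

  for (s in seq_len(cfg$n_subjects)) {
    set.seed(subject_seeds[s])
    fluct <- cfg$fluctuation_sd * mix_series(t_pet, rho_pet, cfg$phi_pet)
    bp_s <- cfg$baseline_bp * (1 - occ) * (1 + fluct)
    act <- sweep(1 + bp_s, 2, ref, "*")
    if (cfg$noise_sd > 0) {
      act <- act + stats::rnorm(length(act)) *
        (cfg$noise_sd * abs(act) / sqrt(cfg$pet_frame_min))
    }
    cer <- ref
    if (cfg$noise_sd > 0) {
      cer <- cer + stats::rnorm(n_pet) *
        (cfg$noise_sd * abs(ref) / sqrt(cfg$pet_frame_min))
    }
    vals <- rbind(act, cer)
    rownames(vals) <- abbrs
    pet[[s]] <- regional_ts(vals, positions, t_pet, "PET",
                            abbreviations = abbrs)
    bp_true[[s]] <- bp_s

    bold_vals <- mix_series(t_bold, rho_bold, cfg$phi_bold)
    rownames(bold_vals) <- tab$abbreviation
    bold[[s]] <- regional_ts(bold_vals, tab$position, t_bold, "BOLD",
                             abbreviations = tab$abbreviation)

    if (cfg$make_images) {
      labs <- as.integer(atlas$label_volume)
      vol4d <- array(0, dim = c(dim(atlas$label_volume), n_pet))
      flat <- matrix(vol4d, nrow = length(labs), ncol = n_pet)
      for (i in seq_len(n_reg + 1L)) {
        vox <- which(labs == positions[i])
        block <- matrix(rep(vals[i, ], each = length(vox)),
                        nrow = length(vox))
        if (cfg$voxel_noise_sd > 0) {
          block <- block * (1 + cfg$voxel_noise_sd *
                              stats::rnorm(length(block)))
        }
        flat[vox, ] <- block
      }
      pet_images[[s]] <- dynamic_image(array(flat,
                                             c(dim(atlas$label_volume), n_pet)),
                                       timing = sched, modality = "PET")
    }
  }

  structure(list(
    pet = pet, bold = bold, pet_images = pet_images, atlas = atlas,
    truth = list(member_of = member_of,
                 occupancy = occ,
                 occupancy_amplitude = occ_par$amplitude,
                 occupancy_onset = occ_par$onset,
                 bp_true = bp_true,
                 rho_pet = rho_pet, rho_bold = rho_bold,
                 reference_tac = ref,
                 subject_seeds = subject_seeds),
    config = cfg),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<sim_cohort> ", cfg$n_subjects, " subjects; PET ",
      ncol(x$pet[[1]]$values), " frames, BOLD ", ncol(x$bold[[1]]$values),
      " volumes; challenge at ",
      if (is.null(cfg$challenge_min)) "none" else paste0(cfg$challenge_min,
                                                         " min"),
      "; seed ", cfg$seed, "\n", sep = "")
  invisible(x)
}
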