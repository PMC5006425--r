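#' Configuration for the synthetic abdominal CT phantom
#'
#' The phantom emulates a mid-abdominal axial slice: an air background, an
#' optional CT bed slab, an elliptical body trunk whose outermost layer is a
#' subcutaneous fat (SFA) ring, a muscle wall, and a visceral cavity filled
#' with visceral fat (VFA), organ blobs and optional bowel-gas pockets. The
#' same 2D geometry is repeated on every slice, so analytic ellipse formulas
#' give exact expected areas. Default HU means follow standard CT anatomy:
#' fat in [-140, -40], soft tissue above -40, air/gas below -140.
#'
#' @param image_size pixels per slice axis (square slices).
#' @param n_slices number of slices.
#' @param pixel_spacing in-plane pixel size, mm (isotropic).
#' @param slice_thickness slice spacing, mm.
#' @param body_semiaxes ellipse semi-axes of the trunk, mm `(x, y)`.
#' @param sfa_thickness thickness of the subcutaneous fat ring, mm.
#' @param muscle_wall_thickness thickness of the muscle wall, mm.
#' @param hu_means named list of compartment mean HU (`air`, `bed`, `muscle`,
#'   `organ`, `sfa`, `vfa`, `gas`).
#' @param hu_noise_sd SD of additive Gaussian HU noise, truncated at +/- 3 SD
#'   so that for `hu_noise_sd <= 10` no compartment can cross the -140/-40 HU
#'   fat thresholds and the ground truth stays exact.
#' @param n_organ_blobs number of elliptical organ blobs in the cavity.
#' @param include_bed add a CT bed slab below the body.
#' @param include_gas_pockets add sub--140 HU gas pockets inside the cavity.
#' @param seed integer RNG seed; identical seeds give bit-identical phantoms.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(image_size = 256,
                           n_slices = 5,
                           pixel_spacing = 1.5,
                           slice_thickness = 5,
                           body_semiaxes = c(150, 110),
                           sfa_thickness = 25,
                           muscle_wall_thickness = 10,
                           hu_means = list(air = -1000, bed = 0, muscle = 40,
                                           organ = 50, sfa = -100, vfa = -90,
                                           gas = -600),
                           hu_noise_sd = 0,
                           n_organ_blobs = 3,
                           include_bed = TRUE,
                           include_gas_pockets = FALSE,
                           seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), n_slices = as.integer(n_slices),
              pixel_spacing = pixel_spacing, slice_thickness = slice_thickness,
              body_semiaxes = body_semiaxes, sfa_thickness = sfa_thickness,
              muscle_wall_thickness = muscle_wall_thickness,
              hu_means = hu_means, hu_noise_sd = hu_noise_sd,
              n_organ_blobs = as.integer(n_organ_blobs),
              include_bed = isTRUE(include_bed),
              include_gas_pockets = isTRUE(include_gas_pockets),
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$image_size < 16L) stop("invalid `image_size`: must be >= 16 pixels")
  if (cfg$n_slices < 1L) stop("invalid `n_slices`: must be >= 1")
  if (cfg$pixel_spacing <= 0) stop("invalid `pixel_spacing`: must be > 0")
  if (cfg$sfa_thickness < 0) stop("invalid `sfa_thickness`: must be >= 0")
  if (cfg$muscle_wall_thickness < 0) {
    stop("invalid `muscle_wall_thickness`: must be >= 0")
  }
  if (length(cfg$body_semiaxes) != 2L || any(cfg$body_semiaxes <= 0)) {
    stop("invalid `body_semiaxes`: must be two positive lengths in mm")
  }
  if (cfg$sfa_thickness + cfg$muscle_wall_thickness >= min(cfg$body_semiaxes)) {
    stop("invalid `body_semiaxes`: SFA ring plus muscle wall leaves no cavity")
  }
  half_extent <- cfg$image_size * cfg$pixel_spacing / 2
  # body (and bed, drawn below the body) must leave an air border at the edges
  margin <- if (cfg$include_bed) 30 else 5
  if (cfg$body_semiaxes[1L] >= half_extent - 5 ||
      cfg$body_semiaxes[2L] >= half_extent - margin) {
    stop("invalid `body_semiaxes`: body does not fit inside the image ",
         "with an air border")
  }
  hu <- cfg$hu_means
  needed <- c("air", "bed", "muscle", "organ", "sfa", "vfa", "gas")
  if (!all(needed %in% names(hu))) {
    stop("invalid `hu_means`: must name ", paste(needed, collapse = ", "))
  }
  for (comp in c("sfa", "vfa")) {
    if (hu[[comp]] < -140 || hu[[comp]] > -40) {
      stop("invalid `hu_means$", comp, "`: fat must lie in [-140, -40] HU")
    }
  }
  for (comp in c("muscle", "organ", "bed")) {
    if (hu[[comp]] <= -40) {
      stop("invalid `hu_means$", comp, "`: soft tissue must be > -40 HU")
    }
  }
  for (comp in c("air", "gas")) {
    if (hu[[comp]] >= -140) {
      stop("invalid `hu_means$", comp, "`: air/gas must be < -140 HU")
    }
  }
  if (cfg$hu_noise_sd < 0) stop("invalid `hu_noise_sd`: must be >= 0")
  if (cfg$n_organ_blobs < 0L) stop("invalid `n_organ_blobs`: must be >= 0")
  invisible(cfg)
}

# pixel-centre coordinate grids in mm, origin at the image centre
.phantom_grid <- function(image_size, pixel_spacing) {
  centre <- (image_size + 1) / 2
  coord <- (seq_len(image_size) - centre) * pixel_spacing
  list(x = matrix(coord, image_size, image_size, byrow = TRUE),
       y = matrix(coord, image_size, image_size))
}

.inside_ellipse <- function(grid, cx, cy, a, b) {
  ((grid$x - cx) / a)^2 + ((grid$y - cy) / b)^2 <= 1
}

#' Generate a synthetic abdominal CT phantom with ground truth
#'
#' Builds an `n_slices`-slice volume from the geometry in `config` and
#' returns it together with exact compartment masks and true per-slice areas.
#' Every trunk pixel belongs to exactly one of SFA, VFA, or non-fat
#' (muscle/organ/gas); organ blobs and gas pockets are placed strictly inside
#' the visceral cavity.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `volume` (a [ct_volume()]) and `truth`, the
#'   ground truth holding logical mask arrays (`trunk`, `sfa`, `vfa`,
#'   `nonfat`), per-slice true areas in cm^2 (`true_sfa_area`,
#'   `true_vfa_area`), and whole-volume `true_ratios` (SFA/trunk, VFA/trunk
#'   pixel fractions).
#' @export
generate_phantom <- function(config = phantom_config()) {
  validate_phantom_config(config)
  set.seed(config$seed)
  n <- config$image_size
  grid <- .phantom_grid(n, config$pixel_spacing)
  a <- config$body_semiaxes[1L]; b <- config$body_semiaxes[2L]
  t_sfa <- config$sfa_thickness; t_mus <- config$muscle_wall_thickness

  trunk <- .inside_ellipse(grid, 0, 0, a, b)
  inner <- if (t_sfa > 0) .inside_ellipse(grid, 0, 0, a - t_sfa, b - t_sfa) else trunk
  sfa <- trunk & !inner
  a_cav <- a - t_sfa - t_mus; b_cav <- b - t_sfa - t_mus
  cavity <- .inside_ellipse(grid, 0, 0, a_cav, b_cav)
  muscle <- inner & !cavity

  organ <- matrix(FALSE, n, n)
  if (config$n_organ_blobs > 0L) {
    for (i in seq_len(config$n_organ_blobs)) {
      ra <- stats::runif(1, 0.10, 0.25) * a_cav
      rb <- stats::runif(1, 0.10, 0.25) * b_cav
      # centre sampled so the blob's bounding box stays inside the cavity
      repeat {
        cx <- stats::runif(1, -1, 1) * (a_cav - ra)
        cy <- stats::runif(1, -1, 1) * (b_cav - rb)
        if ((cx / (a_cav - ra))^2 + (cy / (b_cav - rb))^2 <= 0.8) break
      }
      organ <- organ | (.inside_ellipse(grid, cx, cy, ra, rb) & cavity)
    }
  }
  gas <- matrix(FALSE, n, n)
  if (config$include_gas_pockets) {
    for (i in 1:2) {
      r <- stats::runif(1, 6, 12)
      repeat {
        cx <- stats::runif(1, -1, 1) * (a_cav - r)
        cy <- stats::runif(1, -1, 1) * (b_cav - r)
        if ((cx / (a_cav - r))^2 + (cy / (b_cav - r))^2 <= 0.8) break
      }
      gas <- gas | (.inside_ellipse(grid, cx, cy, r, r) & cavity)
    }
  }
  vfa <- cavity & !organ & !gas
  nonfat <- trunk & !sfa & !vfa

  hu <- config$hu_means
  slice_hu <- matrix(hu$air, n, n)
  if (config$include_bed) {
    # thin slab below the body, separated from it by an air gap
    bed_top <- b + 10
    bed_rows <- grid$y >= bed_top & grid$y <= bed_top + 12
    bed_cols <- abs(grid$x) <= n * config$pixel_spacing * 0.35
    slice_hu[bed_rows & bed_cols] <- hu$bed
  }
  slice_hu[sfa] <- hu$sfa
  slice_hu[vfa] <- hu$vfa
  slice_hu[muscle] <- hu$muscle
  slice_hu[organ & !gas] <- hu$organ
  slice_hu[gas] <- hu$gas

  voxels <- array(slice_hu, dim = c(n, n, config$n_slices))
  if (config$hu_noise_sd > 0) {
    noise <- stats::rnorm(length(voxels), 0, config$hu_noise_sd)
    lim <- 3 * config$hu_noise_sd
    voxels <- voxels + pmin(pmax(noise, -lim), lim)
  }

  px_cm2 <- config$pixel_spacing^2 / 100
  to3d <- function(m) array(m, dim = c(n, n, config$n_slices))
  truth <- list(
    trunk = to3d(trunk), sfa = to3d(sfa), vfa = to3d(vfa), nonfat = to3d(nonfat),
    true_sfa_area = rep(sum(sfa) * px_cm2, config$n_slices),
    true_vfa_area = rep(sum(vfa) * px_cm2, config$n_slices),
    true_ratios = c(sfa = sum(sfa) / sum(trunk), vfa = sum(vfa) / sum(trunk))
  )
  list(volume = ct_volume(voxels,
                          pixel_spacing = rep(config$pixel_spacing, 2L),
                          slice_thickness = config$slice_thickness),
       truth = truth)
}

#' Configuration for the simulated feature/outcome cohort
#'
#' Emulates the statistical structure of a chemotherapy-outcome cohort: a
#' balanced long/short survival split with `n_informative` features whose
#' class means differ by `effect_size` standard deviations, plus
#' class-independent noise features. Defaults mirror a 32-case cohort with a
#' 7-feature pool (one informative adiposity feature and six noise features)
#' and survival months whose overall median falls between the class medians.
#'
#' @param n_cases even number of cases, >= 4.
#' @param n_informative number of class-separated features.
#' @param effect_size standardized mean difference between classes.
#' @param n_noise number of pure-noise features.
#' @param outcome_medians months pair `c(long, short)`: target median survival
#'   of the long and short classes.
#' @param seed integer RNG seed.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 32, n_informative = 1, effect_size = 3,
                          n_noise = 6, outcome_medians = c(long = 40, short = 18),
                          seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_informative = as.integer(n_informative),
              effect_size = effect_size, n_noise = as.integer(n_noise),
              outcome_medians = outcome_medians, seed = as.integer(seed))
  if (cfg$n_cases < 4L) stop("invalid `n_cases`: must be >= 4")
  if (cfg$n_cases %% 2L != 0L) stop("invalid `n_cases`: must be even")
  if (cfg$effect_size < 0) stop("invalid `effect_size`: must be >= 0")
  if (cfg$n_informative + cfg$n_noise < 1L) {
    stop("at least one feature is required")
  }
  if (length(cfg$outcome_medians) != 2L ||
      cfg$outcome_medians[1L] <= cfg$outcome_medians[2L]) {
    stop("invalid `outcome_medians`: long median must exceed short median")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a feature/outcome cohort
#'
#' Half the cases are assigned to the long-survival class and half to the
#' short-survival class. Informative features are class-conditional
#' N(effect_size, 1) vs N(0, 1); noise features are N(0, 1) regardless of
#' class. Survival months are drawn uniformly on class-specific intervals
#' that meet at the midpoint of the class medians, so median dichotomization
#' recovers the true classes exactly.
#'
#' @param config a [cohort_config()].
#' @return A list with `features` (data.frame: `case_id`, `feat1..featK`,
#'   informative features first) and `outcomes` (data.frame: `case_id`,
#'   `months`, `true_class` with 1 = long).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_cases
  true_class <- sample(rep(c(1L, 0L), each = n %/% 2L))
  k <- config$n_informative + config$n_noise
  feat <- matrix(stats::rnorm(n * k), n, k)
  if (config$n_informative > 0L) {
    shift <- matrix(config$effect_size * true_class,
                    n, config$n_informative)
    feat[, seq_len(config$n_informative)] <- feat[, seq_len(config$n_informative),
                                                  drop = FALSE] + shift
  }
  colnames(feat) <- paste0("feat", seq_len(k))
  med_long <- config$outcome_medians[1L]; med_short <- config$outcome_medians[2L]
  mid <- (med_long + med_short) / 2
  months <- numeric(n)
  months[true_class == 1L] <- stats::runif(sum(true_class), mid,
                                           2 * med_long - mid)
  months[true_class == 0L] <- stats::runif(sum(true_class == 0L),
                                           max(0.5, 2 * med_short - mid), mid)
  case_id <- sprintf("case%03d", seq_len(n))
  list(features = data.frame(case_id = case_id, feat,
                             stringsAsFactors = FALSE),
       outcomes = data.frame(case_id = case_id, months = months,
                             true_class = true_class,
                             stringsAsFactors = FALSE))
}
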