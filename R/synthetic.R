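## Seeded synthetic data: (a) a geometric brain phantom with
## midsagittal-crossing homotopic bundles, heterotopic and stray fibers and
## optional partial agenesis; (b) cohorts drawn from the group-comparison
## linear models. All randomness flows from the single seed in the spec;
## the caller's RNG state is restored afterwards.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## anterior-offset fraction -> band label; a value exactly on a cut goes to
## the posterior band (same rule for ribbons, meshes and ground truth)
band_of <- function(s, fractions) {
  cuts <- cumsum(fractions)[1:(length(fractions) - 1L)]
  1L + vapply(s, function(x) sum(x >= cuts), integer(1))
}

#' Phantom specification
#'
#' The default phantom is a flat 1 mm strip, not an anatomical arch: areas,
#' densities and votes are geometry-agnostic, and a strip makes the ground
#' truth exact. The callosal strip spans `ap_extent` x `height` voxels
#' around the midsagittal plane; two lateral cortical ribbons carry the
#' seven labels in anterior-posterior bands of the given fractions.
#'
#' @param voxel_mm Native voxel size (default 1 mm).
#' @param ap_extent,height CC strip footprint in native voxels (default
#'   70 x 10, i.e. a 700 mm^2 section).
#' @param band_fractions Seven target AP band fractions (sum 1); defaults
#'   span ~10-20% each, anterior first.
#' @param n_per_bundle Streamlines per homotopic bundle; `NULL` (default)
#'   uses 1.2x the band's section voxel count so every section voxel is
#'   crossed at least once.
#' @param heterotopic_fraction Fraction of extra fibers connecting
#'   non-homologous parcels (default 0.10).
#' @param stray_fraction Fraction of extra fibers crossing the midplane
#'   outside the CC mask (default 0.05).
#' @param weight_meanlog,weight_sdlog Log-normal streamline weight
#'   distribution (SIFT2-like multipliers around 1).
#' @param agenesis Labels (names or indices) whose bundles are absent.
#' @param oversample Section oversampling factor the ground truth is stated
#'   for (default 2).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `cc_phantom_spec`.
#' @export
phantom_spec <- function(voxel_mm = 1, ap_extent = 70L, height = 10L,
                         band_fractions = c(0.13, 0.17, 0.20, 0.12, 0.10,
                                            0.13, 0.15),
                         n_per_bundle = NULL,
                         heterotopic_fraction = 0.10,
                         stray_fraction = 0.05,
                         weight_meanlog = 0, weight_sdlog = 0.5,
                         agenesis = integer(0),
                         oversample = 2L,
                         seed = 0L) {
  stopifnot(length(band_fractions) == 7L, all(band_fractions > 0),
            abs(sum(band_fractions) - 1) < 1e-8,
            heterotopic_fraction >= 0, stray_fraction >= 0,
            ap_extent >= 7L, height >= 1L)
  if (is.character(agenesis)) agenesis <- cc_parcels()[agenesis]
  agenesis <- as.integer(agenesis)
  stopifnot(all(agenesis %in% 1:7))
  structure(list(voxel_mm = voxel_mm, ap_extent = as.integer(ap_extent),
                 height = as.integer(height),
                 band_fractions = band_fractions,
                 n_per_bundle = n_per_bundle,
                 heterotopic_fraction = heterotopic_fraction,
                 stray_fraction = stray_fraction,
                 weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog,
                 agenesis = agenesis,
                 oversample = as.integer(oversample),
                 seed = as.integer(seed)),
            class = "cc_phantom_spec")
}

#' Generate a geometric phantom
#'
#' Builds, in memory, every input the parcellation pipeline consumes: a
#' white-matter mask holding the callosal strip, a seven-label cortical
#' ribbon volume and mesh, a weighted tractogram of homotopic streamlines
#' (plus heterotopic and stray fibers), the midsagittal plane, and the
#' ground truth needed to score every pipeline stage. Identical seeds give
#' identical output.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `cc_phantom`: `wm_mask`, `cortex_vol`,
#'   `cortex_mesh`, `tractogram`, `plane`, `spec`, and `ground_truth`
#'   (section in-plane coords and band label at the spec's oversampling,
#'   per-bundle streamline counts, WM voxel count, band fractions).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "cc_phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  vm <- spec$voxel_mm
  os <- spec$oversample
  ap <- spec$ap_extent
  ht <- spec$height
  ## native geometry (voxel indices, identity-scaled affine: world = vm * idx)
  affine <- diag(c(vm, vm, vm, 1))
  cc_x <- c(19L, 20L)                 # strip straddles the plane
  cc_y <- seq(8L, 8L + ap - 1L)
  cc_z <- seq(3L, 3L + ht - 1L)
  shape <- c(40L, 8L + ap + 8L, 3L + ht + 3L)
  plane <- plane_spec(x = vm * 19.5)
  y_ant_edge <- vm * (max(cc_y) + 0.5)
  extent <- vm * ap
  s_of_y <- function(y) (y_ant_edge - y) / extent  # 0 anterior .. 1 posterior

  wm <- array(0, shape)
  wm[cc_x + 1L, cc_y + 1L, cc_z + 1L] <- 1
  wm_mask <- cc_volume(wm, affine)

  ## cortical ribbons at x = 2 (left) and x = 37 (right)
  ribbon_x <- c(L = 2L, R = 37L)
  band_native <- band_of(s_of_y(vm * cc_y), spec$band_fractions)
  cortex <- array(0, shape)
  for (x in ribbon_x)
    cortex[x + 1L, cc_y + 1L, cc_z + 1L] <-
      matrix(band_native, length(cc_y), length(cc_z))
  cortex_vol <- cc_volume(cortex, affine)

  ## labelled ribbon mesh: one vertex lattice per hemisphere
  mesh_y <- vm * seq(min(cc_y) - 0.5, max(cc_y) + 0.5, by = vm)
  mesh_z <- vm * seq(min(cc_z) - 0.5, max(cc_z) + 0.5, by = vm)
  verts <- NULL; labs <- NULL; hemi <- NULL; tris <- NULL
  for (side in names(ribbon_x)) {
    g <- expand.grid(y = mesh_y, z = mesh_z)
    v0 <- if (is.null(verts)) 0L else nrow(verts)
    verts <- rbind(verts, cbind(vm * ribbon_x[[side]], g$y, g$z))
    labs <- c(labs, band_of(pmin(pmax(s_of_y(g$y), 0), 1),
                            spec$band_fractions))
    hemi <- c(hemi, rep(side, nrow(g)))
    ny <- length(mesh_y)
    for (j in seq_len(length(mesh_z) - 1L)) {
      for (i in seq_len(ny - 1L)) {
        a <- v0 + (j - 1L) * ny + i
        tris <- rbind(tris, c(a, a + 1L, a + ny), c(a + 1L, a + ny + 1L, a + ny))
      }
    }
  }
  cortex_mesh <- cc_mesh(verts, tris, labs, hemi)

  ## section ground truth at the spec's oversampling (x-normal plane: the
  ## in-plane axes are voxel axes 2 (y) and 3 (z))
  os_centre <- function(u) vm * ((u + 0.5) / os - 0.5)
  y_os <- which(os_centre(seq_len(shape[2] * os) - 1L) > (min(cc_y) - 0.5) * vm &
                os_centre(seq_len(shape[2] * os) - 1L) < (max(cc_y) + 0.5) * vm) - 1L
  z_os <- which(os_centre(seq_len(shape[3] * os) - 1L) > (min(cc_z) - 0.5) * vm &
                os_centre(seq_len(shape[3] * os) - 1L) < (max(cc_z) + 0.5) * vm) - 1L
  gt_coords <- as.matrix(expand.grid(y = y_os, z = z_os))
  gt_band <- band_of(s_of_y(os_centre(gt_coords[, 1])), spec$band_fractions)

  ## homotopic streamlines: per band, cover every section voxel once
  ## (shuffled), then extras at random; endpoints at ribbon voxel centres
  ## within the band
  active <- setdiff(1:7, spec$agenesis)
  sl <- list(); sl_band <- integer(0)
  counts <- integer(7)
  for (l in active) {
    vox_l <- which(gt_band == l)
    if (length(vox_l) == 0L)
      stop("band too small for requested streamline counts (label ", l, ")")
    n_l <- if (is.null(spec$n_per_bundle))
             as.integer(ceiling(1.2 * length(vox_l)))
           else as.integer(spec$n_per_bundle)
    if (n_l < 1L) next
    targets <- c(sample(vox_l),
                 if (n_l > length(vox_l))
                   sample(vox_l, n_l - length(vox_l), replace = TRUE))
    targets <- targets[seq_len(n_l)]
    ycols <- cc_y[band_native == l]
    for (v in targets) {
      pc <- c(os_centre(gt_coords[v, 1]), os_centre(gt_coords[v, 2]))
      eL <- c(vm * ribbon_x[["L"]], vm * sample(ycols, 1L),
              vm * sample(cc_z, 1L))
      eR <- c(vm * ribbon_x[["R"]], vm * sample(ycols, 1L),
              vm * sample(cc_z, 1L))
      sl[[length(sl) + 1L]] <- rbind(eL, c(vm * 19, pc), c(vm * 20, pc), eR,
                                     deparse.level = 0)
    }
    counts[l] <- n_l
    sl_band <- c(sl_band, rep(l, n_l))
  }
  n_hom <- length(sl)
  if (n_hom == 0L) stop("phantom has no homotopic streamlines")

  ## heterotopic fibers: endpoints in two different active bands
  n_het <- as.integer(round(spec$heterotopic_fraction * n_hom))
  if (n_het > 0L && length(active) >= 2L) {
    for (k in seq_len(n_het)) {
      pair <- sample(active, 2L)
      v <- sample(nrow(gt_coords), 1L)
      pc <- c(os_centre(gt_coords[v, 1]), os_centre(gt_coords[v, 2]))
      eL <- c(vm * ribbon_x[["L"]],
              vm * sample(cc_y[band_native == pair[1]], 1L),
              vm * sample(cc_z, 1L))
      eR <- c(vm * ribbon_x[["R"]],
              vm * sample(cc_y[band_native == pair[2]], 1L),
              vm * sample(cc_z, 1L))
      sl[[length(sl) + 1L]] <- rbind(eL, c(vm * 19, pc), c(vm * 20, pc), eR,
                                     deparse.level = 0)
      sl_band <- c(sl_band, NA_integer_)
    }
  } else n_het <- 0L

  ## stray fibers: cross the midplane well below the CC mask
  n_stray <- as.integer(round(spec$stray_fraction * n_hom))
  if (n_stray > 0L) {
    for (k in seq_len(n_stray)) {
      y <- vm * sample(cc_y, 1L)
      z <- -vm * (5 + stats::runif(1) * 5)
      sl[[length(sl) + 1L]] <- rbind(c(vm * 5, y, z), c(vm * 35, y, z),
                                     deparse.level = 0)
      sl_band <- c(sl_band, NA_integer_)
    }
  }

  weights <- stats::rlnorm(length(sl), spec$weight_meanlog, spec$weight_sdlog)
  tract <- cc_tractogram(sl, weights)

  structure(list(wm_mask = wm_mask,
                 cortex_vol = cortex_vol,
                 cortex_mesh = cortex_mesh,
                 tractogram = tract,
                 plane = plane,
                 spec = spec,
                 ground_truth = list(section_coords = gt_coords,
                                     band = gt_band,
                                     band_fractions = spec$band_fractions,
                                     bundle_counts = stats::setNames(counts,
                                                                     parcel_names()),
                                     n_heterotopic = n_het,
                                     n_stray = n_stray,
                                     streamline_band = sl_band,
                                     wm_voxel_count = as.integer(sum(wm)),
                                     plane_x = vm * 19.5,
                                     oversample = os)),
            class = "cc_phantom")
}

#' Write a phantom to disk
#'
#' Writes the same formats the pipeline reads: NIfTI masks and labels, a TCK
#' tractogram with an ASCII weights file, the ASCII mesh, and a
#' ground-truth JSON.
#'
#' @param phantom A `cc_phantom`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "cc_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(wm_mask = file.path(dir, "wm_mask.nii"),
                cortex = file.path(dir, "cortex_labels.nii"),
                mesh = file.path(dir, "cortex_mesh.txt"),
                tractogram = file.path(dir, "tracto.tck"),
                weights = file.path(dir, "weights.txt"),
                ground_truth = file.path(dir, "ground_truth.json"))
  write_nifti(phantom$wm_mask, paths$wm_mask, datatype = "uint8")
  write_nifti(phantom$cortex_vol, paths$cortex, datatype = "uint8")
  write_mesh(phantom$cortex_mesh, paths$mesh)
  write_tck(phantom$tractogram, paths$tractogram, weights_path = paths$weights)
  gt <- phantom$ground_truth
  gt$section_coords <- unname(apply(gt$section_coords, 1L, as.integer,
                                    simplify = FALSE))
  jsonlite::write_json(gt, paths$ground_truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Cohort specification
#'
#' The stated world of the simulated cohorts: group sizes and the 6-25 year
#' age range follow the study design; all distributional defaults are
#' arbitrary but realistic for a pediatric-to-young-adult cohort and are
#' configurable. Per-parcel callosal areas follow the linear model
#' `CcPS_l = b0_l + bSEX_l SEX + bAGE_l AGE + bTCxS_l TCxS + delta_l DIAG +
#' N(0, sigma_l)` truncated at 0; the total CC is the sum of the parcels.
#'
#' @param n_control,n_fas,n_nsfasd Group sizes (defaults 38 / 37 / 28).
#' @param sex_ratio Probability of male (default 0.5).
#' @param age_range Uniform age range in years (default 6-25).
#' @param tcxs_mean,tcxs_sd Total cortical surface, cm^2 (default 1900, 150).
#' @param parcel_fractions Baseline share of each parcel in the total CC.
#' @param b0_total,b_sex_total,b_age_total,b_tcxs_total Total-CC
#'   coefficients, distributed over parcels by `parcel_fractions` (mm^2,
#'   mm^2, mm^2/year, mm^2/cm^2).
#' @param delta Per-parcel group deficit in mm^2 (scalar or length-7; the
#'   DIAG coefficient of the generating model; default 0 = null).
#' @param sigma Per-parcel residual SD in mm^2 (scalar or length-7).
#' @param cxps_fractions Baseline cortical parcel shares of TCxS.
#' @param cxps_noise Relative jitter of cortical shares before
#'   renormalisation (default 0.03).
#' @param seed Integer seed.
#' @return A list of class `cc_cohort_spec`.
#' @export
cohort_spec <- function(n_control = 38L, n_fas = 37L, n_nsfasd = 28L,
                        sex_ratio = 0.5, age_range = c(6, 25),
                        tcxs_mean = 1900, tcxs_sd = 150,
                        parcel_fractions = c(0.13, 0.17, 0.20, 0.12, 0.10,
                                             0.13, 0.15),
                        b0_total = 250, b_sex_total = 20, b_age_total = 6,
                        b_tcxs_total = 0.15,
                        delta = 0, sigma = 12,
                        cxps_fractions = c(0.06, 0.17, 0.20, 0.11, 0.11,
                                           0.20, 0.15),
                        cxps_noise = 0.03,
                        seed = 1L) {
  stopifnot(length(parcel_fractions) == 7L,
            abs(sum(parcel_fractions) - 1) < 1e-8,
            length(cxps_fractions) == 7L,
            abs(sum(cxps_fractions) - 1) < 1e-8,
            all(c(n_control, n_fas, n_nsfasd) >= 0L),
            tcxs_sd > 0)
  delta <- rep_len(delta, 7L)
  sigma <- rep_len(sigma, 7L)
  stopifnot(all(sigma > 0))
  structure(list(n_control = as.integer(n_control),
                 n_fas = as.integer(n_fas),
                 n_nsfasd = as.integer(n_nsfasd),
                 sex_ratio = sex_ratio, age_range = age_range,
                 tcxs_mean = tcxs_mean, tcxs_sd = tcxs_sd,
                 parcel_fractions = parcel_fractions,
                 b0_total = b0_total, b_sex_total = b_sex_total,
                 b_age_total = b_age_total, b_tcxs_total = b_tcxs_total,
                 delta = delta, sigma = sigma,
                 cxps_fractions = cxps_fractions, cxps_noise = cxps_noise,
                 seed = as.integer(seed)),
            class = "cc_cohort_spec")
}

## generating coefficients per parcel (used by tests and power predictions)
cohort_true_coefficients <- function(spec) {
  f <- spec$parcel_fractions
  list(b0 = spec$b0_total * f, b_sex = spec$b_sex_total * f,
       b_age = spec$b_age_total * f, b_tcxs = spec$b_tcxs_total * f,
       delta = spec$delta, sigma = spec$sigma)
}

#' Simulate a cohort table
#'
#' Draws a cohort from the linear generating model of [cohort_spec()]:
#' `SEX ~ Bernoulli(sex_ratio)`, `AGE ~ Uniform(age_range)`,
#' `TCxS ~ Normal(tcxs_mean, tcxs_sd)`; per-parcel callosal areas from the
#' linear model truncated at 0; cortical parcel areas as jittered shares of
#' TCxS renormalised so they sum to TCxS exactly. Identical seeds give
#' identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param noise Set `FALSE` to generate noiseless (exact-model) areas,
#'   useful for exact-recovery checks.
#' @return A cohort `data.frame` in the canonical schema.
#' @export
simulate_cohort <- function(spec = cohort_spec(), noise = TRUE) {
  stopifnot(inherits(spec, "cc_cohort_spec"))
  with_seed(spec$seed, simulate_cohort_impl(spec, noise))
}

simulate_cohort_impl <- function(spec, noise) {
  n <- spec$n_control + spec$n_fas + spec$n_nsfasd
  group <- rep(c("control", "FAS", "NS-FASD"),
               c(spec$n_control, spec$n_fas, spec$n_nsfasd))
  diag_ <- as.integer(group != "control")
  sex <- stats::rbinom(n, 1L, spec$sex_ratio)
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  tcxs <- stats::rnorm(n, spec$tcxs_mean, spec$tcxs_sd)
  co <- cohort_true_coefficients(spec)
  ccps <- matrix(0, n, 7L)
  for (l in 1:7) {
    mu <- co$b0[l] + co$b_sex[l] * sex + co$b_age[l] * age +
      co$b_tcxs[l] * tcxs + co$delta[l] * diag_
    eps <- if (noise) stats::rnorm(n, 0, co$sigma[l]) else 0
    ccps[, l] <- pmax(mu + eps, 0)
  }
  raw <- matrix(0, n, 7L)
  for (l in 1:7) {
    jit <- if (noise) stats::rnorm(n, 0, spec$cxps_noise) else 0
    raw[, l] <- spec$cxps_fractions[l] * pmax(1 + jit, 0.01)
  }
  cxps <- raw / rowSums(raw) * tcxs
  df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   group = group, sex = sex, age_years = age,
                   tcxs_cm2 = tcxs)
  for (l in 1:7) df[[cxps_column(parcel_names()[l])]] <- cxps[, l]
  for (l in 1:7) df[[ccps_column(parcel_names()[l])]] <- ccps[, l]
  df$cc_total_mm2 <- rowSums(ccps)
  df
}
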