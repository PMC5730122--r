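#' pCASL acquisition and kinetic parameters
#'
#' Bundles the constants of the single-compartment quantification model and
#' of the simulated acquisition. Defaults follow the study protocol this
#' pipeline reproduces: labeling duration 1950 ms, initial post-labeling
#' delay 1200 ms with a 70 ms per-slice increment (2-D readout), labeling
#' efficiency 0.70 (background-suppression losses folded in), and 60
#' control/label pairs. Blood T1 (1650 ms) and the blood-brain partition
#' coefficient (0.9 ml/g) are the consensus-recommended values.
#'
#' @param ld labeling duration, ms.
#' @param pld0 initial post-labeling delay (slice 1), ms.
#' @param slice_dt per-slice delay increment, ms.
#' @param alpha labeling efficiency in (0, 1].
#' @param t1b longitudinal relaxation time of arterial blood, ms.
#' @param lambda blood-brain water partition coefficient, ml/g.
#' @param n_pairs number of control/label pairs.
#' @param noise_sd additive Gaussian noise SD, control-image units.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(ld = 1950, pld0 = 1200, slice_dt = 70,
                       alpha = 0.70, t1b = 1650, lambda = 0.9,
                       n_pairs = 60, noise_sd = 5) {
  if (ld <= 0 || pld0 <= 0 || t1b <= 0)
    stop("ld, pld0 and t1b must be positive (ms)")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (lambda <= 0) stop("lambda must be positive (ml/g)")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (slice_dt < 0) stop("slice_dt must be non-negative (ms)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(ld = ld, pld0 = pld0, slice_dt = slice_dt,
                 alpha = alpha, t1b = t1b, lambda = lambda,
                 n_pairs = as.integer(n_pairs), noise_sd = noise_sd),
            class = "acq_params")
}

#' Build smooth tissue posterior-probability maps
#'
#' A stand-in for structural segmentation output: a concentric head
#' geometry (white-matter core, gray-matter band, CSF rim, empty
#' background) whose tissue indicator maps are blurred by a Gaussian
#' kernel, producing pure-GM, pure-WM and mixed neighborhoods — so the
#' partial-volume regression is well-conditioned in some windows and
#' rank-deficient in others. A seeded smooth perturbation makes maps
#' differ across seeds while preserving per-voxel `sum(p) <= 1`.
#'
#' @param shape integer length-3 grid shape; in-plane extent must be at
#'   least 7 x 7 (the regression kernel footprint).
#' @param voxel_size (dx, dy, dz) in mm.
#' @param smoothness Gaussian blur SD in voxels; 0 gives piecewise-constant
#'   blocks.
#' @param seed integer RNG seed for the perturbation field.
#' @return A list of class `tissue_probmaps` with [volume_grid] elements
#'   `p_gm`, `p_wm`, `p_csf`.
#' @export
build_probmaps <- function(shape = c(32, 32, 12),
                           voxel_size = c(3.5, 3.5, 8.0),
                           smoothness = 1.2, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three positive integers")
  if (shape[1] < 7L || shape[2] < 7L)
    stop("in-plane shape must be at least 7 x 7 for the regression kernel")
  if (smoothness < 0) stop("smoothness must be non-negative")
  set.seed(as.integer(seed))

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  r <- sqrt(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+"))
  rmax <- min(cx, cy) - 1
  # concentric anatomy per slice: WM core, GM band, CSF rim
  ind_wm  <- array(0, shape); ind_gm <- array(0, shape); ind_csf <- array(0, shape)
  for (k in seq_len(nz)) {
    # head narrows slightly toward the first and last slices
    scale_k <- 0.85 + 0.15 * sin(pi * (k - 0.5) / nz)
    r_wm <- 0.45 * rmax * scale_k
    r_gm <- 0.75 * rmax * scale_k
    r_head <- 0.92 * rmax * scale_k
    ind_wm[, , k]  <- (r <= r_wm) * 1
    ind_gm[, , k]  <- (r > r_wm & r <= r_gm) * 1
    ind_csf[, , k] <- (r > r_gm & r <= r_head) * 1
  }
  if (smoothness > 0) {
    ind_gm  <- gauss_blur3(ind_gm, smoothness)
    ind_wm  <- gauss_blur3(ind_wm, smoothness)
    ind_csf <- gauss_blur3(ind_csf, smoothness)
  }
  # smooth seeded perturbation, redistributing GM/WM without changing sums
  pert <- array(stats::rnorm(prod(shape), sd = 0.15), shape)
  pert <- gauss_blur3(pert, max(smoothness, 1))
  shift <- pmin(pmin(ind_gm, ind_wm) * 0.5, abs(pert)) * sign(pert)
  ind_gm <- ind_gm + shift
  ind_wm <- ind_wm - shift
  ind_gm <- pmin(pmax(ind_gm, 0), 1)
  ind_wm <- pmin(pmax(ind_wm, 0), 1)
  tot <- ind_gm + ind_wm + ind_csf
  over <- tot > 1
  if (any(over)) {
    f <- ifelse(over, 1 / tot, 1)
    ind_gm <- ind_gm * f; ind_wm <- ind_wm * f; ind_csf <- ind_csf * f
  }
  structure(list(p_gm = volume_grid(ind_gm, voxel_size),
                 p_wm = volume_grid(ind_wm, voxel_size),
                 p_csf = volume_grid(ind_csf, voxel_size)),
            class = "tissue_probmaps")
}

# separable Gaussian blur; in-plane only when nz is small relative to kernel
gauss_blur3 <- function(a, sd) {
  if (sd <= 0) return(a)
  half <- max(1L, ceiling(3 * sd))
  g <- stats::dnorm(seq(-half, half), sd = sd)
  g <- g / sum(g)
  blur_axis <- function(x, axis) {
    n <- dim(x)[axis]
    out <- array(0, dim(x))
    for (off in seq(-half, half)) {
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
      sl <- switch(axis, x[idx, , , drop = FALSE],
                   x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
      out <- out + g[off + half + 1L] * sl
    }
    out
  }
  blur_axis(blur_axis(a, 1L), 2L)
}

#' Ground-truth perfusion maps for the phantom
#'
#' Constant gray- and white-matter flow fields with a multiplicative
#' GM-flow deficit in the designated occluded hemisphere (left half of the
#' first axis for `"L"`). CSF is not perfused. Defaults: textbook
#' f_GM = 60 and f_WM = 20 ml/100g/min with a 0.9 asymmetry factor, giving
#' a relative hemispheric deficit comparable to the ~8-9% seen in
#' unilateral carotid occlusive disease.
#'
#' @param probmaps a `tissue_probmaps` (defines the grid).
#' @param f_gm,f_wm tissue perfusion, ml/100g/min.
#' @param asymmetry_factor multiplier applied to GM flow on the occluded
#'   side; < 1 for a deficit.
#' @param occluded_side `"L"` or `"R"`.
#' @return A list of class `perfusion_truth` with [volume_grid] elements
#'   `f_gm`, `f_wm` and the scalar settings.
#' @export
perfusion_truth <- function(probmaps, f_gm = 60, f_wm = 20,
                            asymmetry_factor = 0.9, occluded_side = "L") {
  if (f_gm < 0 || f_wm < 0) stop("perfusion must be non-negative")
  if (asymmetry_factor < 0) stop("asymmetry_factor must be non-negative")
  occluded_side <- match.arg(occluded_side, c("L", "R"))
  shape <- dim(probmaps$p_gm$data)
  nx <- shape[1]
  fg <- array(f_gm, shape)
  left <- seq_len(floor(nx / 2))
  if (occluded_side == "L") fg[left, , ] <- fg[left, , ] * asymmetry_factor
  else fg[-left, , ] <- fg[-left, , ] * asymmetry_factor
  structure(list(f_gm = vg_like(probmaps$p_gm, fg),
                 f_wm = vg_like(probmaps$p_gm, array(f_wm, shape)),
                 asymmetry_factor = asymmetry_factor,
                 occluded_side = occluded_side),
            class = "perfusion_truth")
}

#' Forward single-compartment difference signal
#'
#' The inverse of the consensus quantification equation: the
#' perfusion-weighted (control - label) signal generated by flow `f` at a
#' tissue voxel with equilibrium magnetization `m0_tissue`,
#' \deqn{\Delta M = \frac{f \, m_0 \, 2\alpha T_{1b}
#'   (1 - e^{-LD/T_{1b}}) e^{-PLD/T_{1b}}}{6000\,\lambda}}
#' with times in seconds and `f` in ml/100g/min, so that
#' [cbf_from_ratio]`(forward_delta_m(f, m0, pld, acq) / m0, pld, acq)`
#' returns `f` exactly.
#'
#' @param f perfusion, ml/100g/min (vectorized; must be non-negative).
#' @param m0_tissue tissue magnetization, control-image units.
#' @param pld post-labeling delay, ms.
#' @param acq an [acq_params].
#' @return Difference signal in control-image units.
#' @export
forward_delta_m <- function(f, m0_tissue, pld, acq) {
  stopifnot(inherits(acq, "acq_params"))
  if (any(f < 0, na.rm = TRUE)) stop("perfusion f must be non-negative")
  t1b <- acq$t1b / 1000; ld <- acq$ld / 1000; plds <- pld / 1000
  f * m0_tissue * 2 * acq$alpha * t1b *
    (1 - exp(-ld / t1b)) * exp(-plds / t1b) / (6000 * acq$lambda)
}

#' Simulate a noisy pCASL control/label series
#'
#' Control frames carry the static mixture signal
#' `p_gm*m_gm + p_wm*m_wm + p_csf*m_csf`; label frames carry the static
#' signal minus the perfusion-weighted component
#' `p_gm*dM_gm + p_wm*dM_wm` (CSF contributes no perfusion signal).
#' Independent Gaussian noise of SD `acq$noise_sd` is added per voxel per
#' frame. The post-labeling delay entering the kinetic model is the
#' slice-adjusted delay of each voxel's slice.
#'
#' @param probmaps a `tissue_probmaps`.
#' @param truth a [perfusion_truth] on the same grid.
#' @param magnetizations named vector `c(gm=, wm=, csf=)`, control-image
#'   units.
#' @param acq an [acq_params] (frame count and noise SD are taken from it).
#' @param seed integer RNG seed.
#' @return A list with 4-D [volume_grid]s `control` and `label`
#'   (`acq$n_pairs` frames each), plus the noiseless `delta_m` 3-D field.
#' @export
simulate_series <- function(probmaps, truth,
                            magnetizations = c(gm = 100, wm = 70, csf = 120),
                            acq = acq_params(), seed = 1L) {
  stop_if_grid_mismatch(probmaps$p_gm, truth$f_gm, "probmaps and truth")
  set.seed(as.integer(seed))
  shape <- dim(probmaps$p_gm$data)
  nz <- shape[3]
  pld_slice <- adjusted_pld(seq_len(nz), acq)
  pld_vox <- array(rep(pld_slice, each = shape[1] * shape[2]), shape)
  dm_gm <- forward_delta_m(truth$f_gm$data, magnetizations[["gm"]], pld_vox, acq)
  dm_wm <- forward_delta_m(truth$f_wm$data, magnetizations[["wm"]], pld_vox, acq)
  static <- probmaps$p_gm$data * magnetizations[["gm"]] +
    probmaps$p_wm$data * magnetizations[["wm"]] +
    probmaps$p_csf$data * magnetizations[["csf"]]
  delta <- probmaps$p_gm$data * dm_gm + probmaps$p_wm$data * dm_wm
  nf <- acq$n_pairs
  control <- array(rep(static, nf), c(shape, nf))
  label <- array(rep(static - delta, nf), c(shape, nf))
  if (acq$noise_sd > 0) {
    control <- control + array(stats::rnorm(length(control), sd = acq$noise_sd),
                               dim(control))
    label <- label + array(stats::rnorm(length(label), sd = acq$noise_sd),
                           dim(label))
  }
  vs <- probmaps$p_gm$voxel_size
  list(control = volume_grid(control, vs),
       label = volume_grid(label, vs),
       delta_m = vg_like(probmaps$p_gm, delta))
}

#' Mirror-symmetric M1/V1 ROI atlas for the phantom
#'
#' Binary masks for left/right primary motor cortex (anterior GM band on
#' the upper slices, where the slice-adjusted delay averages ~1830 ms) and
#' left/right primary visual cortex (posterior GM band on lower slices).
#' Masks are disjoint, non-empty, and left/right pairs have equal voxel
#' counts by construction (each mask is intersected with its own mirror
#' image), mirroring the equal ROI volumes of the cohort this phantom
#' emulates.
#'
#' @param probmaps a `tissue_probmaps`.
#' @param gm_floor minimum GM probability for a voxel to enter an ROI.
#' @return A list of class `roi_atlas` with binary [volume_grid]s
#'   `m1_left`, `m1_right`, `v1_left`, `v1_right`.
#' @export
build_roi_atlas <- function(probmaps, gm_floor = 0.5) {
  shape <- dim(probmaps$p_gm$data)
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  if (nz < 4L) stop("phantom needs at least 4 slices for distinct M1/V1 ROIs")
  gm <- probmaps$p_gm$data
  left_cols <- seq_len(floor(nx / 2))
  mirror_x <- function(m) m[rev(seq_len(nx)), , , drop = FALSE]
  band <- function(slices, rows) {
    m <- array(0, shape)
    m[, rows, slices] <- 1
    m
  }
  m1_slices <- max(1L, min(10L, nz)):min(nz, max(1L, min(10L, nz)) + 1L)
  v1_slices <- max(1L, round(nz / 3)):max(1L, round(nz / 3) + 1L)
  m1_region <- band(m1_slices, seq_len(floor(ny / 3)))          # anterior
  v1_region <- band(v1_slices, (ny - floor(ny / 3) + 1L):ny)    # posterior
  side <- array(0, shape); side[left_cols, , ] <- 1
  mk <- function(region, left) {
    base <- (gm >= gm_floor) * region
    sym <- base * mirror_x(base)  # enforce equal left/right counts
    sym * (if (left) side else 1 - side)
  }
  m1l <- mk(m1_region, TRUE);  m1r <- mk(m1_region, FALSE)
  v1l <- mk(v1_region, TRUE);  v1r <- mk(v1_region, FALSE)
  for (m in list(m1l, m1r, v1l, v1r))
    if (sum(m) == 0) stop("empty ROI mask; enlarge the phantom or lower gm_floor")
  structure(list(m1_left = vg_like(probmaps$p_gm, m1l),
                 m1_right = vg_like(probmaps$p_gm, m1r),
                 v1_left = vg_like(probmaps$p_gm, v1l),
                 v1_right = vg_like(probmaps$p_gm, v1r)),
            class = "roi_atlas")
}
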