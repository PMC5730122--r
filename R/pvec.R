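#' Brain-tissue mask from summed tissue probabilities
#'
#' A voxel enters the brain mask iff its total tissue content
#' `p_gm + p_wm + p_csf` is at least `threshold` (default 30%, the
#' deskulling rule of the processing protocol this pipeline reproduces).
#'
#' @param probmaps a `tissue_probmaps`.
#' @param threshold total-tissue fraction in (0, 1].
#' @return A binary [volume_grid].
#' @export
brain_mask <- function(probmaps, threshold = 0.30) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  tot <- probmaps$p_gm$data + probmaps$p_wm$data + probmaps$p_csf$data
  vg_like(probmaps$p_gm, (tot >= threshold) * 1)
}

#' Voxelwise local linear regression on tissue probabilities
#'
#' At each masked voxel, the image values of the masked voxels inside a
#' kernel window centered there (truncated at volume edges) are regressed
#' by ordinary least squares, without intercept, on the corresponding
#' tissue-probability values — the signal model is a pure mixture
#' `sum_t p_t * m_t`, so an intercept would absorb tissue signal. The
#' normal-equation sums are accumulated with a moving-window box filter,
#' which is algebraically identical to assembling the per-voxel design
#' matrix; a brute-force per-voxel solve is kept as the test oracle.
#'
#' Where the window's design matrix is rank-deficient or ill-conditioned
#' (condition number > 1e6) or has fewer masked voxels than
#' `length(regressors) + 1`, the minimum-norm least-squares solution is
#' returned and the voxel is flagged `valid = 0`; downstream ROI
#' averaging uses valid voxels only, so pure-tissue neighborhoods cannot
#' poison ROI means.
#'
#' @param image a [volume_grid] (e.g. mean control or mean difference).
#' @param regressors list of probability [volume_grid]s (the design
#'   columns).
#' @param mask binary [volume_grid]; regression runs at and uses masked
#'   voxels only.
#' @param kernel odd integer length-3 window size, default `c(7, 7, 1)`.
#' @param cond_max condition-number threshold for the validity flag.
#' @return A list with `coef` (list of coefficient [volume_grid]s, one
#'   per regressor), `valid` and `n_neighbors` [volume_grid]s.
#' @export
local_regression <- function(image, regressors, mask,
                             kernel = c(7, 7, 1), cond_max = 1e6) {
  kernel <- as.integer(kernel)
  if (length(kernel) != 3L || any(kernel < 1L))
    stop("kernel must be three positive integers")
  if (any(kernel %% 2L == 0L))
    stop("kernel dimensions must be odd, got ",
         paste(kernel, collapse = "x"))
  for (r in regressors) stop_if_grid_mismatch(image, r, "image and regressors")
  stop_if_grid_mismatch(image, mask, "image and mask")
  m <- mask$data != 0
  if (!any(m)) stop("empty mask: no voxels to regress")
  p <- length(regressors)
  shape <- dim(image$data)

  # moving-window sums of masked products: entries of X'X and X'y per voxel
  bs <- function(a) box_sum3(a, kernel)
  reg <- lapply(regressors, function(r) r$data * m)
  y <- image$data * m
  sxx <- vector("list", p * p)
  for (i in seq_len(p)) for (j in i:p)
    sxx[[(i - 1) * p + j]] <- bs(reg[[i]] * regressors[[j]]$data * m)
  sxy <- lapply(seq_len(p), function(i) bs(reg[[i]] * y))
  nn <- bs(m * 1)

  coef <- lapply(seq_len(p), function(i) array(NA_real_, shape))
  valid <- array(0, shape)
  idx <- which(m)
  S <- matrix(0, p, p)
  b <- numeric(p)
  for (v in idx) {
    for (i in seq_len(p)) for (j in i:p) {
      S[i, j] <- sxx[[(i - 1) * p + j]][v]
      S[j, i] <- S[i, j]
    }
    for (i in seq_len(p)) b[i] <- sxy[[i]][v]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    tol <- max(ev) * 1e-12
    rank_ok <- min(ev) > tol
    cond_ok <- rank_ok && sqrt(max(ev) / min(ev)) <= cond_max
    if (cond_ok && nn[v] >= p + 1) {
      beta <- solve(S, b)
      valid[v] <- 1
    } else {
      es <- eigen(S, symmetric = TRUE)
      pos <- es$values > tol
      beta <- if (any(pos)) {
        es$vectors[, pos, drop = FALSE] %*%
          ((t(es$vectors[, pos, drop = FALSE]) %*% b) / es$values[pos])
      } else rep(0, p)
    }
    for (i in seq_len(p)) coef[[i]][v] <- beta[i]
  }
  list(coef = lapply(coef, function(cm) vg_like(image, cm)),
       valid = vg_like(image, valid),
       n_neighbors = vg_like(image, nn * m))
}

# sum of `a` over a kx*ky*kz window centered at each voxel, truncated at
# the volume edges, via cumulative sums along each axis
box_sum3 <- function(a, kernel) {
  half <- (kernel - 1L) %/% 2L
  axis_sum <- function(x, axis, h) {
    if (h == 0L) return(x)
    n <- dim(x)[axis]
    cs <- apply(x, setdiff(1:3, axis), cumsum)
    # apply() puts the cumsum axis first; restore original order
    perm <- order(c(axis, setdiff(1:3, axis)))
    cs <- aperm(cs, perm)
    hi <- pmin(seq_len(n) + h, n)
    lo <- seq_len(n) - h - 1L
    take <- function(i) switch(axis, cs[i, , , drop = FALSE],
                               cs[, i, , drop = FALSE],
                               cs[, , i, drop = FALSE])
    upper <- take(hi)
    lower <- array(0, dim(upper))
    pos <- lo >= 1L
    if (any(pos)) {
      lower_part <- take(lo[pos])
      switch(axis,
             lower[pos, , ] <- lower_part,
             lower[, pos, ] <- lower_part,
             lower[, , pos] <- lower_part)
    }
    out <- upper - lower
    array(out, dim(x))
  }
  out <- a
  for (ax in 1:3) out <- axis_sum(out, ax, half[ax])
  out
}

#' Partial-volume-effect correction of a control/label series
#'
#' Averages the control frames and the (control - label) pair differences,
#' then runs [local_regression] twice: the mean control image on the
#' GM/WM/CSF probabilities (yielding tissue magnetizations `m_gm`,
#' `m_wm`, `m_csf`) and the mean difference image on the GM/WM
#' probabilities only (yielding the perfusion-weighted components
#' `dm_gm`, `dm_wm`; CSF carries no perfusion signal). Outputs are
#' defined only inside the brain mask.
#'
#' @param control4d,label4d 4-D [volume_grid] series with equal frame
#'   counts.
#' @param probmaps a `tissue_probmaps` on the same grid.
#' @param kernel regression window, default `c(7, 7, 1)`.
#' @param mask_threshold total-tissue fraction for [brain_mask].
#' @param clip_negative if `TRUE`, negative coefficients are set to zero;
#'   default `FALSE` (retained, preserving unbiasedness of ROI means).
#' @return A list of class `pvec_result` with [volume_grid]s `m_gm`,
#'   `m_wm`, `m_csf`, `dm_gm`, `dm_wm`, `valid` (both regressions
#'   well-posed), `n_neighbors`, and the `mask` used.
#' @export
pvec_correct <- function(control4d, label4d, probmaps,
                         kernel = c(7, 7, 1), mask_threshold = 0.30,
                         clip_negative = FALSE) {
  dc <- dim(control4d$data); dl <- dim(label4d$data)
  if (length(dc) != 4L || length(dl) != 4L)
    stop("control4d and label4d must be 4-D series")
  if (dc[4] != dl[4])
    stop("frame-count mismatch: ", dc[4], " control vs ", dl[4], " label")
  if (!identical(dc[1:3], dl[1:3]))
    stop("shape mismatch between control and label series")
  mean_control <- vg_like(probmaps$p_gm, rowMeans(control4d$data, dims = 3))
  mean_diff <- vg_like(probmaps$p_gm,
                       rowMeans(control4d$data - label4d$data, dims = 3))
  mask <- brain_mask(probmaps, mask_threshold)
  fit_m <- local_regression(mean_control,
                            list(probmaps$p_gm, probmaps$p_wm, probmaps$p_csf),
                            mask, kernel)
  fit_dm <- local_regression(mean_diff,
                             list(probmaps$p_gm, probmaps$p_wm),
                             mask, kernel)
  clip <- function(v) {
    if (clip_negative) v$data <- pmax(v$data, 0)
    v
  }
  structure(list(
    m_gm = clip(fit_m$coef[[1]]), m_wm = clip(fit_m$coef[[2]]),
    m_csf = clip(fit_m$coef[[3]]),
    dm_gm = clip(fit_dm$coef[[1]]), dm_wm = clip(fit_dm$coef[[2]]),
    valid = vg_like(mask, fit_m$valid$data * fit_dm$valid$data),
    n_neighbors = fit_m$n_neighbors,
    mask = mask), class = "pvec_result")
}
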