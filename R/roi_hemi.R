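#' ROI-mean gray-matter CBF
#'
#' Unweighted mean of `cbf_gm` over the ROI voxels that are PVEc-valid,
#' defined, and have GM probability at least `gm_floor` (default 0.30,
#' mirroring the brain-mask threshold). PVEc already yields tissue-pure
#' values, so no probability weighting is applied by default; set
#' `weight_gm = TRUE` for a p_gm-weighted mean.
#'
#' @param cbf_map a `cbf_map`.
#' @param roi binary [volume_grid] mask, non-empty.
#' @param probmaps a `tissue_probmaps` (supplies p_gm for the floor).
#' @param gm_floor minimum GM probability for inclusion.
#' @param weight_gm weight voxels by p_gm instead of equally.
#' @return A list of class `roi_summary`: `mean_cbf`, `n_voxels_used`,
#'   and `defined` (FALSE when no usable voxel remained).
#' @export
roi_mean_cbf <- function(cbf_map, roi, probmaps, gm_floor = 0.30,
                         weight_gm = FALSE) {
  stop_if_grid_mismatch(cbf_map$cbf_gm, roi, "CBF map and ROI")
  if (sum(roi$data != 0) == 0) stop("ROI mask is empty")
  use <- roi$data != 0 & !is.na(cbf_map$cbf_gm$data) &
    cbf_map$valid$data != 0 & probmaps$p_gm$data >= gm_floor
  n <- sum(use)
  if (n == 0)
    return(structure(list(mean_cbf = NA_real_, n_voxels_used = 0L,
                          defined = FALSE), class = "roi_summary"))
  vals <- cbf_map$cbf_gm$data[use]
  mean_cbf <- if (weight_gm) {
    w <- probmaps$p_gm$data[use]
    sum(w * vals) / sum(w)
  } else mean(vals)
  structure(list(mean_cbf = mean_cbf, n_voxels_used = as.integer(n),
                 defined = TRUE), class = "roi_summary")
}

#' Paired t-test with Bonferroni control
#'
#' Classical paired t on per-subject occluded/unoccluded values, two-sided
#' p from Student's t with n - 1 df, and a Bonferroni significance flag at
#' `0.05 / bonferroni_m` (default m = 2 for the two regions tested,
#' i.e. significance requires two-sided p < 0.025).
#'
#' @param occluded,unoccluded numeric vectors, one value per subject;
#'   pairs with any NA are dropped.
#' @param bonferroni_m number of comparisons adjusted for.
#' @return A list of class `paired_test`: `mean_a` (occluded), `mean_b`
#'   (unoccluded), `mean_diff`, `t_statistic`, `df`, `p_two_sided`,
#'   `significant_after_bonferroni`, `n`.
#' @export
paired_t <- function(occluded, unoccluded, bonferroni_m = 2) {
  if (length(occluded) != length(unoccluded))
    stop("paired vectors must have equal length")
  keep <- stats::complete.cases(occluded, unoccluded)
  x <- occluded[keep]; y <- unoccluded[keep]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- x - y
  alpha <- 0.05 / bonferroni_m
  if (stats::sd(d) == 0) {
    # all differences identical: t is 0/0 (mean zero) or infinite
    if (mean(d) != 0)
      stop("degenerate input: zero-variance, non-zero paired differences")
    return(structure(list(mean_a = mean(x), mean_b = mean(y), mean_diff = 0,
                          t_statistic = 0, df = n - 1, p_two_sided = 1,
                          significant_after_bonferroni = FALSE,
                          alpha = alpha, n = n),
                     class = "paired_test"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  structure(list(mean_a = mean(x), mean_b = mean(y), mean_diff = mean(d),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_two_sided = tt$p.value,
                 significant_after_bonferroni = tt$p.value < alpha,
                 alpha = alpha, n = n),
            class = "paired_test")
}

#' Count subjects with CBF asymmetry in the expected direction
#'
#' Counts complete-case subjects whose regional CBF is strictly lower on
#' the occluded than the unoccluded side; ties count against the expected
#' direction (conservative). The percentage is rounded to the nearest
#' integer.
#'
#' @param table a `cohort_table`.
#' @param region `"m1"` or `"v1"`.
#' @return A list: `n_expected_direction`, `n_complete`, `percent`.
#' @export
asymmetry_count <- function(table, region = c("m1", "v1")) {
  region <- match.arg(region)
  occ <- table[[paste0(region, "_cbf_occ")]]
  unocc <- table[[paste0(region, "_cbf_unocc")]]
  keep <- stats::complete.cases(occ, unocc)
  if (!any(keep)) stop("no complete-case rows for region ", region)
  occ <- occ[keep]; unocc <- unocc[keep]
  n_exp <- sum(occ < unocc)
  list(n_expected_direction = n_exp, n_complete = length(occ),
       percent = round(100 * n_exp / length(occ)))
}

#' Extract per-subject ROI rows from a quantified phantom
#'
#' Maps the anatomical left/right atlas masks to occluded/unoccluded
#' labels using `side_occluded` (labels derive from the occlusion side,
#' not anatomy) and returns ROI-mean GM CBF for M1 and V1 on each side.
#'
#' @param cbf_map a `cbf_map`.
#' @param atlas a `roi_atlas`.
#' @param probmaps a `tissue_probmaps`.
#' @param side_occluded `"L"` or `"R"`.
#' @param gm_floor passed to [roi_mean_cbf].
#' @return A one-row data frame with columns `m1_cbf_occ`,
#'   `m1_cbf_unocc`, `v1_cbf_occ`, `v1_cbf_unocc` and voxel counts.
#' @export
extract_roi_cbf <- function(cbf_map, atlas, probmaps, side_occluded = "L",
                            gm_floor = 0.30) {
  side_occluded <- match.arg(side_occluded, c("L", "R"))
  pick <- function(region, occluded) {
    side <- if (xor(side_occluded == "L", !occluded)) "left" else "right"
    atlas[[paste(region, side, sep = "_")]]
  }
  s <- function(region, occluded)
    roi_mean_cbf(cbf_map, pick(region, occluded), probmaps, gm_floor)
  m1o <- s("m1", TRUE); m1u <- s("m1", FALSE)
  v1o <- s("v1", TRUE); v1u <- s("v1", FALSE)
  data.frame(m1_cbf_occ = m1o$mean_cbf, m1_cbf_unocc = m1u$mean_cbf,
             v1_cbf_occ = v1o$mean_cbf, v1_cbf_unocc = v1u$mean_cbf,
             m1_n_occ = m1o$n_voxels_used, m1_n_unocc = m1u$n_voxels_used,
             v1_n_occ = v1o$n_voxels_used, v1_n_unocc = v1u$n_voxels_used)
}
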