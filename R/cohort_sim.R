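#' Configuration for the synthetic cohort generator
#'
#' Encodes the effect structure the pipeline is designed to detect: motor
#' cortex (M1) thickness depends linearly on M1 gray-matter CBF and on
#' age; visual cortex (V1) thickness depends on neither; CBF on the
#' occluded side equals the unoccluded side minus a hemispheric deficit
#' plus per-subject noise. Defaults reproduce the cohort this pipeline
#' targets: n = 28; unoccluded M1 / V1 GM CBF 115.2 / 112.8 ml/100g/min
#' with deficits 9.7 / 6.4; covariate prevalences 21/28 hypertension,
#' 6/28 diabetes, 14/28 complete occlusion, and collateral status
#' 15 cross-filling / 6 none / 7 unknown. The thickness coefficients and
#' noise SD are set so the population CBF-thickness correlation per side
#' is ~0.45-0.50 and the age correlation ~ -0.35, and the side-noise SD
#' (9 ml/100g/min) puts the probability of occluded-lower CBF asymmetry
#' near 86%.
#'
#' @param n_subjects cohort size (>= 3).
#' @param beta_cbf_m1 mm of M1 thickness per ml/100g/min of M1 GM CBF.
#' @param beta_age_m1 mm of M1 thickness per year of age.
#' @param beta_cbf_v1,beta_age_v1 V1 analogues (default 0: no dependence).
#' @param mean_cbf_m1_unocc,mean_cbf_v1_unocc unoccluded-side population
#'   mean GM CBF, ml/100g/min.
#' @param cbf_offset_m1,cbf_offset_v1 hemispheric CBF deficit
#'   (unoccluded minus occluded), ml/100g/min.
#' @param cbf_subject_sd between-subject CBF SD, ml/100g/min.
#' @param cbf_side_sd SD of the per-subject hemispheric difference noise.
#' @param thick_mean_m1,thick_mean_v1 population mean thickness at the
#'   unoccluded-side mean CBF and mean age, mm.
#' @param thick_noise_sd residual thickness SD, mm.
#' @param age_range subject ages drawn uniformly on this interval, years.
#' @param prev_htn,prev_dm,prev_occlusion Bernoulli prevalences.
#' @param p_collateral probabilities for collateral status
#'   (cross-filling, none, unknown).
#' @param seed integer RNG seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 28,
                              beta_cbf_m1 = 0.0045,
                              beta_age_m1 = -0.0044,
                              beta_cbf_v1 = 0,
                              beta_age_v1 = 0,
                              mean_cbf_m1_unocc = 115.2,
                              mean_cbf_v1_unocc = 112.8,
                              cbf_offset_m1 = 9.7,
                              cbf_offset_v1 = 6.4,
                              cbf_subject_sd = 15,
                              cbf_side_sd = 9,
                              thick_mean_m1 = 2.15,
                              thick_mean_v1 = 1.79,
                              thick_noise_sd = 0.12,
                              age_range = c(50, 93),
                              prev_htn = 21 / 28,
                              prev_dm = 6 / 28,
                              prev_occlusion = 14 / 28,
                              p_collateral = c(15, 6, 7) / 28,
                              seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (thick_noise_sd < 0 || cbf_subject_sd < 0 || cbf_side_sd < 0)
    stop("noise SDs must be non-negative")
  if (abs(sum(p_collateral) - 1) > 1e-8)
    stop("p_collateral must sum to 1")
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Simulate a cohort table with known effect structure
#'
#' Per subject: age ~ U(age_range); unoccluded regional CBF ~
#' N(mean, cbf_subject_sd); occluded regional CBF = unoccluded - offset +
#' N(0, cbf_side_sd), floored at zero; per side, M1 thickness =
#' intercept + beta_cbf_m1 * CBF + beta_age_m1 * age + N(0,
#' thick_noise_sd) and V1 thickness likewise with the (default-zero) V1
#' coefficients, so any V1 association downstream is a false positive.
#' Hemispheral CBF is the M1/V1 mean per side plus noise; WMH volumes are
#' log-normal and independent of thickness. The intercept is chosen so
#' the unoccluded-side mean thickness equals `thick_mean_*` at the mean
#' CBF and mean age.
#'
#' @param config a [cohort_sim_config].
#' @return A `cohort_table` (see [read_cohort]) with `config$n_subjects`
#'   rows; bit-identical for a fixed `config$seed`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cf <- config
  set.seed(as.integer(cf$seed))
  n <- cf$n_subjects
  age <- round(stats::runif(n, cf$age_range[1], cf$age_range[2]), 1)
  mean_age <- mean(cf$age_range)

  draw_region <- function(mean_unocc, offset) {
    unocc <- stats::rnorm(n, mean_unocc, cf$cbf_subject_sd)
    occ <- unocc - offset + stats::rnorm(n, 0, cf$cbf_side_sd)
    list(unocc = pmax(unocc, 0), occ = pmax(occ, 0))
  }
  m1 <- draw_region(cf$mean_cbf_m1_unocc, cf$cbf_offset_m1)
  v1 <- draw_region(cf$mean_cbf_v1_unocc, cf$cbf_offset_v1)

  thick <- function(cbf, b_cbf, b_age, mu, mean_cbf) {
    intercept <- mu - b_cbf * mean_cbf - b_age * mean_age
    intercept + b_cbf * cbf + b_age * age +
      stats::rnorm(n, 0, cf$thick_noise_sd)
  }
  m1_thick_unocc <- thick(m1$unocc, cf$beta_cbf_m1, cf$beta_age_m1,
                          cf$thick_mean_m1, cf$mean_cbf_m1_unocc)
  m1_thick_occ <- thick(m1$occ, cf$beta_cbf_m1, cf$beta_age_m1,
                        cf$thick_mean_m1, cf$mean_cbf_m1_unocc)
  v1_thick_unocc <- thick(v1$unocc, cf$beta_cbf_v1, cf$beta_age_v1,
                          cf$thick_mean_v1, cf$mean_cbf_v1_unocc)
  v1_thick_occ <- thick(v1$occ, cf$beta_cbf_v1, cf$beta_age_v1,
                        cf$thick_mean_v1, cf$mean_cbf_v1_unocc)
  clamp_thick <- function(x) pmin(pmax(x, 0.5), 5.5)

  h_unocc <- (m1$unocc + v1$unocc) / 2 + stats::rnorm(n, 0, 5)
  h_occ <- (m1$occ + v1$occ) / 2 + stats::rnorm(n, 0, 5)

  df <- data.frame(
    subject_id = sprintf("sub%02d", seq_len(n)),
    age = age,
    htn = stats::rbinom(n, 1, cf$prev_htn),
    dm = stats::rbinom(n, 1, cf$prev_dm),
    side_occluded = ifelse(stats::rbinom(n, 1, 0.5) == 1, "L", "R"),
    occlusion_complete = stats::rbinom(n, 1, cf$prev_occlusion),
    collateral = sample(c("cross-filling", "none", "unknown"), n,
                        replace = TRUE, prob = cf$p_collateral),
    m1_cbf_occ = m1$occ, m1_cbf_unocc = m1$unocc,
    v1_cbf_occ = v1$occ, v1_cbf_unocc = v1$unocc,
    h_cbf_occ = pmax(h_occ, 0), h_cbf_unocc = pmax(h_unocc, 0),
    m1_thick_occ = clamp_thick(m1_thick_occ),
    m1_thick_unocc = clamp_thick(m1_thick_unocc),
    v1_thick_occ = clamp_thick(v1_thick_occ),
    v1_thick_unocc = clamp_thick(v1_thick_unocc),
    wmh_occ = stats::rlnorm(n, log(5), 0.8),
    wmh_unocc = stats::rlnorm(n, log(5), 0.8),
    stringsAsFactors = FALSE
  )
  as_cohort_table(df)
}
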