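#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation on complete pairs; the two-sided p-value
#' comes from `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 df.
#' Constant inputs are an error, never a silent NaN.
#'
#' @param x,y numeric vectors.
#' @return A list of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: constant vector has no defined correlation")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "correlation_result")
}

#' Standardized multiple linear regression
#'
#' OLS on the z-scored outcome and predictors (complete cases), so the
#' coefficients are standardized betas — invariant to affine rescaling of
#' any predictor — with classical t-test p-values. With a single
#' predictor the standardized beta equals the Pearson r.
#'
#' @param table data frame.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @return A list of class `regression_std`: `beta` and `p` (named per
#'   predictor), `n`, `outcome`.
#' @export
fit_ols_standardized <- function(table, outcome, predictors) {
  df <- as.data.frame(table)[, c(outcome, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < length(predictors) + 2)
    stop("need at least ", length(predictors) + 2, " complete cases")
  z <- as.data.frame(lapply(df, function(col) {
    s <- stats::sd(col)
    if (s == 0) return(col * NA_real_)
    (col - mean(col)) / s
  }))
  bad <- names(z)[vapply(z, function(c) all(is.na(c)), logical(1))]
  if (length(bad)) stop("constant column(s): ", paste(bad, collapse = ", "))
  X <- as.matrix(z[, predictors, drop = FALSE])
  if (kappa(crossprod(X), exact = TRUE) > 1e8)
    stop("collinear predictors (condition number > 1e8): ",
         paste(predictors, collapse = ", "))
  fit <- stats::lm(stats::reformulate(predictors, response = outcome),
                   data = z)
  sm <- summary(fit)$coefficients
  structure(list(beta = sm[predictors, "Estimate"],
                 p = sm[predictors, "Pr(>|t|)"],
                 n = n, outcome = outcome),
            class = "regression_std")
}

#' Univariate screen of candidate predictors
#'
#' Returns the candidates whose univariate Pearson p-value against the
#' outcome is at most `alpha` (the "p <= 0.05 enters the multivariable
#' model" rule; the boundary case p = alpha is selected).
#'
#' @param table data frame.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate column names.
#' @param alpha selection threshold.
#' @return Character vector of selected candidates (possibly empty), with
#'   the per-candidate `r` and `p` in attributes `"r"` and `"p"`.
#' @export
variable_screen <- function(table, outcome, candidates, alpha = 0.05) {
  rs <- ps <- stats::setNames(numeric(length(candidates)), candidates)
  for (cand in candidates) {
    res <- pearson(table[[cand]], table[[outcome]])
    rs[cand] <- res$r; ps[cand] <- res$p
  }
  sel <- candidates[ps <= alpha]
  attr(sel, "r") <- rs
  attr(sel, "p") <- ps
  sel
}

#' Reshape a cohort table to hemisphere-long format
#'
#' Two rows per subject (occluded / unoccluded side) with the regional
#' thickness as outcome and regional CBF, age, a side indicator
#' (1 = occluded), collateral status and occlusion-vs-stenosis as
#' covariates. Subjects with missing ASL data are dropped (complete-case).
#'
#' @param table a `cohort_table`.
#' @param region `"m1"` or `"v1"`.
#' @return A long data frame, `2 * n_subjects` rows.
#' @export
cohort_to_long <- function(table, region = c("m1", "v1")) {
  region <- match.arg(region)
  df <- as.data.frame(table)
  cols <- paste0(region, c("_thick_occ", "_thick_unocc",
                           "_cbf_occ", "_cbf_unocc"))
  keep <- stats::complete.cases(df[, c(cols, "age")])
  df <- df[keep, , drop = FALSE]
  one <- function(occ) data.frame(
    subject_id = df$subject_id,
    thickness = df[[paste0(region, if (occ) "_thick_occ" else "_thick_unocc")]],
    rcbf = df[[paste0(region, if (occ) "_cbf_occ" else "_cbf_unocc")]],
    age = df$age,
    side_occluded_row = as.integer(occ),
    collateral = df$collateral,
    occlusion_complete = df$occlusion_complete,
    stringsAsFactors = FALSE)
  long <- rbind(one(TRUE), one(FALSE))
  long[order(long$subject_id, -long$side_occluded_row), , drop = FALSE]
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Marginal linear model (identity link, Gaussian family) for clustered
#' observations, estimated by iterated generalized least squares: the
#' scale and the common within-cluster correlation are moment-estimated
#' from Pearson residuals, and the coefficient update solves
#' `sum_i X_i' V_i^-1 X_i beta = sum_i X_i' V_i^-1 y_i`. Inference uses
#' the robust (sandwich) covariance with z-based two-sided p-values.
#' With the independence working structure and no iteration the point
#' estimates reduce to OLS.
#'
#' @param formula model formula.
#' @param data data frame in long format.
#' @param id cluster identifier column name.
#' @param corstr `"exchangeable"` (default) or `"independence"`.
#' @param tol,max_iter convergence control on the coefficient change.
#' @return A list of class `gee_result`: `coefficients`, `robust_se`,
#'   `z`, `p`, `alpha_working` (estimated correlation), `corstr`,
#'   `n_clusters`, `n_rows`.
#' @export
fit_gee <- function(formula, data, id, corstr = c("exchangeable",
                                                  "independence"),
                    tol = 1e-10, max_iter = 50) {
  corstr <- match.arg(corstr)
  if (is.null(data[[id]])) stop("id column '", id, "' not found")
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  ids <- data[[id]]
  p <- ncol(X)
  groups <- split(seq_along(y), ids)
  beta <- stats::coef(stats::lm.fit(X, y))
  alpha_hat <- 0
  for (iter in seq_len(max_iter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (length(y) - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (g in groups) {
        if (length(g) < 2) next
        rg <- r[g]
        num <- num + (sum(rg)^2 - sum(rg^2)) / 2
        npairs <- npairs + length(g) * (length(g) - 1) / 2
      }
      alpha_hat <- num / (phi * max(npairs - p, 1))
      nmax <- max(lengths(groups))
      alpha_hat <- min(max(alpha_hat, -1 / (nmax - 1) + 1e-6), 1 - 1e-6)
    }
    A <- matrix(0, p, p); bvec <- numeric(p)
    for (g in groups) {
      Xg <- X[g, , drop = FALSE]
      ng <- length(g)
      Vinv <- solve_exch(ng, alpha_hat) / phi
      A <- A + crossprod(Xg, Vinv %*% Xg)
      bvec <- bvec + crossprod(Xg, Vinv %*% y[g])
    }
    beta_new <- solve(A, bvec)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (corstr == "independence" || delta < tol) break
  }
  # sandwich covariance
  r <- y - X %*% beta
  phi <- sum(r^2) / (length(y) - p)
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (g in groups) {
    Xg <- X[g, , drop = FALSE]
    Vinv <- solve_exch(length(g), alpha_hat) / phi
    B <- B + crossprod(Xg, Vinv %*% Xg)
    u <- crossprod(Xg, Vinv %*% r[g])
    M <- M + u %*% t(u)
  }
  Binv <- solve(B)
  vc <- Binv %*% M %*% Binv
  se <- sqrt(diag(vc))
  z <- as.numeric(beta) / se
  pv <- 2 * stats::pnorm(-abs(z))
  names(pv) <- names(se) <- names(z) <- colnames(X)
  structure(list(coefficients = stats::setNames(as.numeric(beta),
                                                colnames(X)),
                 robust_se = se, z = z, p = pv,
                 alpha_working = if (corstr == "exchangeable") alpha_hat
                                 else 0,
                 corstr = corstr,
                 n_clusters = length(groups), n_rows = length(y)),
            class = "gee_result")
}

# inverse of the n x n exchangeable correlation matrix (1-a)I + aJ
solve_exch <- function(n, a) {
  if (n == 1 || a == 0) return(diag(n))
  diag(n) / (1 - a) - matrix(a / ((1 - a) * (1 - a + n * a)), n, n)
}

#' GEE for cortical thickness with hemisphere clustering
#'
#' Fits the marginal model
#' `thickness ~ rcbf + age + side_occluded_row + collateral +
#' occlusion_complete` on a two-row-per-subject long table (see
#' [cohort_to_long]) with subject clusters, exchangeable working
#' correlation and sandwich standard errors. Unknown collateral status is
#' a third factor level, not dropped.
#'
#' @param long_table output of [cohort_to_long].
#' @param corstr working correlation, passed to [fit_gee].
#' @return A `gee_result` (see [fit_gee]); `n_rows = 2 * n_subjects`.
#' @export
fit_gee_thickness <- function(long_table, corstr = "exchangeable") {
  counts <- table(long_table$subject_id)
  if (any(counts != 2))
    stop("each subject must contribute exactly 2 rows; offending: ",
         paste(names(counts)[counts != 2], collapse = ", "))
  long_table$collateral <- factor(long_table$collateral,
                                  levels = c("cross-filling", "none",
                                             "unknown"))
  fit_gee(thickness ~ rcbf + age + side_occluded_row + collateral +
            occlusion_complete,
          data = long_table, id = "subject_id", corstr = corstr)
}

#' Full cohort statistics report
#'
#' Runs the complete tabular analysis on a cohort table: paired
#' occluded/unoccluded comparisons of regional CBF and thickness
#' (Bonferroni over the two regions per measure), the asymmetry-direction
#' count, the per-side univariate correlation screen of thickness against
#' age, hypertension, diabetes, hemispheral CBF, regional CBF and WMH
#' volume, standardized multiple regression on the screened predictors,
#' and the hemisphere-clustered GEE per region. Subjects flagged
#' `asl_missing` are excluded from all CBF-involving analyses
#' (complete-case per model). Deterministic: bit-identical for a fixed
#' input table.
#'
#' @param table a `cohort_table`.
#' @param screen_alpha univariate entry threshold for the regression.
#' @return A nested list report (JSON-serializable).
#' @export
stats_report <- function(table, screen_alpha = 0.05) {
  df <- as.data.frame(table)
  cc <- df[!df$asl_missing, , drop = FALSE]
  paired_block <- function(prefix)
    unclass(paired_t(cc[[paste0(prefix, "_occ")]],
                     cc[[paste0(prefix, "_unocc")]]))
  paired <- list(m1_cbf = paired_block("m1_cbf"),
                 v1_cbf = paired_block("v1_cbf"),
                 m1_thick = paired_block("m1_thick"),
                 v1_thick = paired_block("v1_thick"))
  asym <- list(m1 = asymmetry_count(cc, "m1"), v1 = asymmetry_count(cc, "v1"))

  sides <- c(occ = "occ", unocc = "unocc")
  regions <- c(m1 = "m1", v1 = "v1")
  correlations <- list(); regressions <- list()
  for (rg in names(regions)) {
    for (sd_ in names(sides)) {
      outcome <- paste0(rg, "_thick_", sd_)
      candidates <- c(age = "age", htn = "htn", dm = "dm",
                      hcbf = paste0("h_cbf_", sd_),
                      rcbf = paste0(rg, "_cbf_", sd_),
                      hwmh = paste0("wmh_", sd_))
      sel <- variable_screen(cc, outcome, unname(candidates),
                             alpha = screen_alpha)
      key <- paste(rg, sd_, sep = "_")
      correlations[[key]] <- list(
        r = as.list(stats::setNames(attr(sel, "r"), names(candidates))),
        p = as.list(stats::setNames(attr(sel, "p"), names(candidates))),
        selected = names(candidates)[match(sel, candidates)])
      if (length(sel) >= 1) {
        reg <- fit_ols_standardized(cc, outcome, sel)
        regressions[[key]] <- list(
          beta = as.list(stats::setNames(reg$beta,
                                         names(candidates)[match(sel, candidates)])),
          p = as.list(stats::setNames(reg$p,
                                      names(candidates)[match(sel, candidates)])),
          n = reg$n)
      } else regressions[[key]] <- list(beta = list(), p = list(),
                                        n = nrow(cc))
    }
  }
  gee <- lapply(regions, function(rg) {
    g <- fit_gee_thickness(cohort_to_long(table, rg))
    list(coefficients = as.list(g$coefficients),
         robust_se = as.list(g$robust_se), p = as.list(g$p),
         alpha_working = g$alpha_working, corstr = g$corstr,
         n_subjects = g$n_clusters, n_rows = g$n_rows)
  })
  list(n_total = nrow(df), n_analyzed = nrow(cc),
       n_asl_missing = sum(df$asl_missing),
       paired_tests = paired, asymmetry = asym,
       correlations = correlations, regressions = regressions,
       gee = gee)
}
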