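# Small fixtures shared across test files. Everything is generated in code;
# nothing is read from disk except files the tests themselves write.

# a small smooth probability fixture (in-plane >= 7 for the PVEc kernel)
small_probmaps <- function(shape = c(16, 16, 4), seed = 1L, smoothness = 1) {
  build_probmaps(shape, voxel_size = c(3.5, 3.5, 8.0),
                 smoothness = smoothness, seed = seed)
}

# random probability maps on a tiny grid (not anatomical; for OLS oracles)
random_probmaps <- function(shape = c(9, 9, 1), seed = 1L) {
  set.seed(seed)
  raw <- array(stats::runif(prod(shape) * 3), c(shape, 3))
  tot <- pmax(raw[, , , 1] + raw[, , , 2] + raw[, , , 3], 1)
  structure(list(
    p_gm = volume_grid(array(raw[, , , 1] / tot, shape)),
    p_wm = volume_grid(array(raw[, , , 2] / tot, shape)),
    p_csf = volume_grid(array(raw[, , , 3] / tot, shape))),
    class = "tissue_probmaps")
}

# brute-force per-voxel windowed OLS: the independent oracle for
# local_regression (explicit window gathering + qr solve per voxel)
brute_force_local_ols <- function(image, regressors, mask, kernel) {
  shape <- dim(image$data)
  half <- (as.integer(kernel) - 1L) %/% 2L
  p <- length(regressors)
  coef <- lapply(seq_len(p), function(i) array(NA_real_, shape))
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2]))
    for (k in seq_len(shape[3])) {
      if (mask$data[i, j, k] == 0) next
      ii <- max(1, i - half[1]):min(shape[1], i + half[1])
      jj <- max(1, j - half[2]):min(shape[2], j + half[2])
      kk <- max(1, k - half[3]):min(shape[3], k + half[3])
      inw <- mask$data[ii, jj, kk] != 0
      y <- image$data[ii, jj, kk][inw]
      X <- sapply(regressors, function(r) r$data[ii, jj, kk][inw])
      X <- matrix(X, ncol = p)
      if (qr(X)$rank < p) next  # oracle only covers well-posed voxels
      b <- qr.solve(X, y)
      for (q in seq_len(p)) coef[[q]][i, j, k] <- b[q]
    }
  coef
}

# synthetic cohort written to CSV and read back
roundtrip_cohort <- function(tab) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_cohort(tab, f)
  read_cohort(f, dialect = "csv")
}
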