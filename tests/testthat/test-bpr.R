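test_that("voxel standardization centres, scales and excludes constant voxels", {
  x <- cbind(c(1, 2, 3), c(5, 5, 5), c(2, 0, 4))
  sv <- standardize_voxels(x)
  expect_equal(sv$excluded, 2L)
  expect_equal(sv$z[, 1], c(-1, 0, 1))
  expect_equal(sv$voxel_means, c(2, 2))
  expect_equal(sv$voxel_sds, c(1, 2))

  r <- rmat(5, 8, seed = 2)
  svr <- standardize_voxels(r)
  expect_lt(max(abs(colMeans(svr$z))), 1e-10)
  expect_lt(max(abs(apply(svr$z, 2, sd) - 1)), 1e-8)

  expect_error(standardize_voxels(matrix(1, 1, 4)), "at least 2 subjects")
  expect_error(standardize_voxels(matrix(3, 4, 5)), "zero variance")
})

test_that("subject centring removes row means and is idempotent", {
  x <- rbind(c(1, 2, 3), c(0, 0, 0))
  cs <- center_subjects(x)
  expect_equal(cs$z[1, ], c(-1, 0, 1))
  expect_equal(cs$z[2, ], c(0, 0, 0))
  expect_equal(cs$row_means, c(2, 0))
  twice <- center_subjects(cs$z)
  expect_equal(twice$z, cs$z)
  expect_equal(twice$row_means, c(0, 0))
})

test_that("subject covariance matches the direct product oracle", {
  z <- matrix(c(1, -2, 0, 3,
                2, 1, -1, 0,
                0, 4, 1, -2), nrow = 3, byrow = TRUE)
  s <- subject_covariance(z)
  # brute-force oracle: entry-wise dot products / (p - 1)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) oracle[i, j] <- sum(z[i, ] * z[j, ]) / 3
  expect_equal(s, oracle)
  expect_lt(max(abs(s - t(s))), 1e-12)

  # orthogonal rows with squared norm (p-1)*c give diagonal S with entries c
  zo <- rbind(c(2, 0, 0, 0), c(0, 2, 0, 0)) * sqrt(3) / 2  # row norm^2 = (p-1)*1
  expect_equal(subject_covariance(zo), diag(1, 2))
  expect_error(subject_covariance(matrix(1:2, 2, 1)), "insufficient voxels")
})

test_that("rank-1 matrices are decomposed exactly", {
  set.seed(4)
  w <- rnorm(6)
  p <- rnorm(40); p <- p / sqrt(sum(p^2))
  z <- outer(w, p)
  dec <- bpr_decompose(z, k = 1)
  expect_equal(abs(sum(dec$patterns[, 1] * p)), 1, tolerance = 1e-10)
  expect_equal(dec$variance_fraction[1], 1, tolerance = 1e-10)
  expect_lt(dec$singular_values[2], 1e-7 * dec$singular_values[1])
  expect_equal(dec$rank, 1L)
  # weights reproduce the planted subject vector up to the common sign
  s <- sign(sum(dec$weights[, 1] * w))
  expect_equal(s * dec$weights[, 1], w, tolerance = 1e-10)
})

test_that("subject-space decomposition agrees with a direct SVD oracle", {
  z <- processed_matrix(rmat(6, 40, seed = 10))
  dec <- bpr_decompose(z, k = 4)
  sv <- svd(z)
  expect_equal(dec$singular_values[1:5], sv$d[1:5], tolerance = 1e-9)
  ang <- principal_angles(dec$patterns[, 1:3], sv$v[, 1:3])
  expect_lt(max(ang), 1e-6)
  # full reconstruction at the numerical rank
  full <- bpr_decompose(z, k = dec$rank)
  expect_lt(norm(z - tcrossprod(full$weights, full$patterns), "F") / norm(z, "F"),
            1e-6)
})

test_that("eigenbrains are orthonormal, weights orthogonal, variance accounted", {
  z <- processed_matrix(rmat(8, 60, seed = 12))
  dec <- bpr_decompose(z, k = 5)
  g <- crossprod(dec$patterns)
  expect_lt(max(abs(g - diag(5))), 1e-8)
  wg <- crossprod(dec$weights)
  expect_lt(max(abs(wg - diag(diag(wg)))) / max(diag(wg)), 1e-6)
  expect_equal(sum(dec$variance_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(dec$variance_fraction) <= 1e-12))
})

test_that("rank-k truncation is the optimal low-rank approximation", {
  z <- processed_matrix(rmat(9, 70, seed = 13))
  sv <- svd(z)
  for (k in c(1, 3, 5)) {
    dec <- bpr_decompose(z, k = k)
    err <- norm(z - tcrossprod(dec$weights, dec$patterns), "F")
    best <- sqrt(sum(sv$d[-(1:k)]^2))
    expect_equal(err, best, tolerance = 1e-9 * max(1, best))
  }
})

test_that("cumulative-variance selection stops at the threshold", {
  # plant an exact spectrum with variance fractions .30 .25 .20 .15 .10
  set.seed(14)
  u <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:5]
  v <- qr.Q(qr(matrix(rnorm(30 * 5), 30, 5)))
  lam <- c(.30, .25, .20, .15, .10) * 40
  z <- u %*% diag(sqrt(lam)) %*% t(v)
  dec <- bpr_decompose(z, var_threshold = 0.5)
  expect_equal(dec$k, 2L)
  expect_equal(dec$variance_fraction[1:5], c(.30, .25, .20, .15, .10),
               tolerance = 1e-10)
  dec8 <- bpr_decompose(z, var_threshold = 1)
  expect_equal(dec8$k, dec8$rank)
  expect_error(bpr_decompose(z, k = 6), "rank 5")
})

test_that("sign fixing is deterministic, idempotent and flip-invariant", {
  z <- processed_matrix(rmat(7, 30, seed = 15))
  dec <- bpr_decompose(z, k = 4)
  # largest-magnitude loading of every component is positive
  for (j in 1:4) {
    i <- which.max(abs(dec$patterns[, j]))
    expect_gt(dec$patterns[i, j], 0)
  }
  fs <- fix_signs(dec$patterns, dec$weights)
  expect_identical(fs$patterns, dec$patterns)
  expect_identical(fs$weights, dec$weights)
  for (seed in 1:5) {
    set.seed(seed)
    s <- sample(c(-1, 1), 4, replace = TRUE)
    flipped <- fix_signs(sweep(dec$patterns, 2, s, "*"),
                         sweep(dec$weights, 2, s, "*"))
    expect_identical(flipped$patterns, dec$patterns)
    expect_identical(flipped$weights, dec$weights)
  }
  # forced example: most-negative-dominant column gets flipped
  pat <- cbind(c(-0.9, 0.1, sqrt(1 - 0.81 - 0.01)))
  wt <- cbind(c(1, -2))
  out <- fix_signs(pat, wt)
  expect_equal(out$patterns[, 1], -pat[, 1])
  expect_equal(out$weights[, 1], -wt[, 1])
  # reconstruction unchanged
  expect_equal(tcrossprod(out$weights, out$patterns), tcrossprod(wt, pat))
})

test_that("projection reproduces training weights and is affine-consistent", {
  x <- rmat(12, 50, seed = 16)
  fit <- bpr(x, k = 4)
  pr <- predict(fit, x)
  expect_equal(unname(pr), unname(coef(fit)),
               tolerance = 1e-8 * max(abs(coef(fit))))
  # a scan equal to the stored voxel means projects to zero
  mu <- numeric(ncol(x))
  mu[setdiff(seq_len(ncol(x)), fit$excluded_voxels)] <- fit$voxel_means
  expect_equal(as.vector(predict(fit, mu)), rep(0, 4), tolerance = 1e-10)
  # affine combinations commute with projection
  a <- 0.35
  mix <- predict(fit, a * x[3, ] + (1 - a) * x[9, ])
  expect_equal(as.vector(mix), as.vector(a * pr[3, ] + (1 - a) * pr[9, ]),
               tolerance = 1e-8)
})

test_that("projection refuses scans extracted under a different mask", {
  mask <- array(FALSE, c(4, 4, 4)); mask[1:20] <- TRUE
  scans <- lapply(1:5, function(i) rvol(c(4L, 4L, 4L), seed = 30 + i))
  mat <- stack_cohort(scans, mask)
  fit <- bpr(mat, k = 2)
  other_mask <- array(FALSE, c(4, 4, 4)); other_mask[5:24] <- TRUE
  v <- masked_values(scans[[1]], other_mask)
  expect_error(predict(fit, v), "incompatible space")
  ok <- masked_values(scans[[1]], mask)
  expect_silent(predict(fit, ok))
})

test_that("the fitted object exposes the standard modelling interface", {
  x <- rmat(10, 40, seed = 17)
  fit <- bpr(x, k = 3)
  expect_s3_class(fit, "bpr")
  expect_equal(dim(coef(fit)), c(10L, 3L))
  expect_equal(colnames(coef(fit)), c("EB1", "EB2", "EB3"))
  expect_output(print(fit), "Eigenbrain decomposition")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.bpr")
  expect_output(print(sm), "singular_value")
  # residuals at full rank are numerically zero
  full <- bpr(x, k = fit$rank)
  expect_lt(max(abs(residuals(full))), 1e-8)
  expect_equal(fitted(fit) + residuals(fit), fit$Z)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("eigenbrains can be written back into template volumes", {
  mask <- array(FALSE, c(5, 5, 4)); mask[1:60] <- TRUE
  scans <- lapply(1:6, function(i) rvol(c(5L, 5L, 4L), seed = 40 + i))
  mat <- stack_cohort(scans, mask)
  fit <- bpr(mat, k = 2)
  dir <- tempfile("ebs")
  paths <- write_eigenbrains(fit, dir, voxel_mm = c(2, 2, 2))
  expect_length(paths, 2L)
  vol <- read_volume(paths[1])
  expect_equal(dim(vol), c(5L, 5L, 4L))
  keep <- which(mask)
  if (length(fit$excluded_voxels)) keep <- keep[-fit$excluded_voxels]
  expect_equal(as.numeric(vol[keep]), unname(fit$patterns[, 1]), tolerance = 1e-6)
  expect_true(all(vol[-keep] == 0))
})
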