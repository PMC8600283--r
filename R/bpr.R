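#' Voxel-wise standardization of a cohort matrix
#'
#' Centres and scales every voxel column to sample mean 0 and sample SD 1.
#' Columns whose SD falls below `tol * max(SD)` carry no between-subject
#' information (e.g. voxels outside any signal at zero noise) and are excluded
#' rather than rescaled; their indices are recorded.
#'
#' @param x Numeric matrix, subjects x voxels, at least 2 rows.
#' @param tol Relative SD tolerance below which a voxel is excluded.
#' @return List with `z` (standardized matrix over retained voxels),
#'   `voxel_means`, `voxel_sds` (retained columns), `excluded` (original
#'   column indices removed).
#' @export
standardize_voxels <- function(x, tol = 1e-10) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("voxel standardization needs at least 2 subjects")
  if (!all(is.finite(x))) stop("cohort matrix contains non-finite values")
  n <- nrow(x)
  m <- colMeans(x)
  xc <- sweep(x, 2L, m, "-")
  s <- sqrt(colSums(xc^2) / (n - 1))
  smax <- max(s)
  if (smax == 0) stop("all voxels have zero variance; nothing to decompose")
  keep <- s > tol * smax
  if (!any(keep)) stop("all voxels excluded as zero-variance")
  z <- sweep(xc[, keep, drop = FALSE], 2L, s[keep], "/")
  list(z = z, voxel_means = m[keep], voxel_sds = s[keep],
       excluded = which(!keep))
}

#' Subject-wise centring
#'
#' Subtracts each participant's own mean across (standardized) voxels, the
#' second processing step of BPR. Idempotent; the removed row means are kept
#' so new scans can be treated identically at projection time.
#'
#' @param x Numeric matrix, subjects x voxels.
#' @return List with `z` (row-centred matrix) and `row_means`.
#' @export
center_subjects <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("matrix contains non-finite values")
  rm <- rowMeans(x)
  list(z = x - rm, row_means = rm)
}

#' Participant-by-participant covariance
#'
#' The inter-individual covariance `Z Z' / (p - 1)` over the `p` retained
#' voxels. Its eigen-decomposition yields the subject-space route to the
#' voxel-space eigenbrains.
#'
#' @param z Doubly-processed matrix (see [standardize_voxels()],
#'   [center_subjects()]).
#' @return Symmetric n x n matrix.
#' @export
subject_covariance <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 subjects")
  p <- ncol(z)
  if (p < 2L) stop("insufficient voxels (", p, "); need at least 2")
  tcrossprod(z) / (p - 1)
}

#' Deterministic sign convention for eigenbrains
#'
#' An eigenvector and its weights can be jointly negated without changing the
#' decomposition, so signs are fixed by convention: for each component, if the
#' voxel loading of largest magnitude is negative, both the pattern and its
#' weight column are flipped. The result is invariant to any sign flips of the
#' input and leaves the reconstruction `W %*% t(patterns)` unchanged.
#'
#' @param patterns Voxels x k matrix of unit-norm patterns.
#' @param weights Subjects x k matrix of weights from the same decomposition.
#' @return List with sign-fixed `patterns` and `weights`.
#' @export
fix_signs <- function(patterns, weights) {
  patterns <- as.matrix(patterns)
  weights <- as.matrix(weights)
  if (ncol(patterns) != ncol(weights))
    stop("patterns and weights must have the same number of components")
  for (j in seq_len(ncol(patterns))) {
    i <- which.max(abs(patterns[, j]))
    if (patterns[i, j] < 0) {
      patterns[, j] <- -patterns[, j]
      weights[, j] <- -weights[, j]
    }
  }
  list(patterns = patterns, weights = weights)
}

#' Eigen-decompose a processed cohort matrix via the subject-space route
#'
#' Core decomposition on a doubly-processed matrix `Z` (voxel-standardized,
#' subject-centred): the n x n matrix `Z Z'` is eigen-decomposed, singular
#' values are `sigma_i = sqrt(lambda_i)`, voxel-space eigenbrains are
#' reconstructed as `v_i = Z' u_i / sigma_i` (the eigenfaces identity) and
#' weights as `W = U diag(sigma)`. Components with `sigma < 1e-7 *
#' sigma_max` are numerically null and cannot be retained. Signs are fixed
#' by [fix_signs()].
#'
#' @param z Processed numeric matrix, subjects x voxels.
#' @param k Number of components to retain; `NULL` selects the smallest k
#'   reaching `var_threshold` cumulative variance.
#' @param var_threshold Cumulative variance-fraction threshold in (0, 1].
#' @return List with `patterns` (p x k), `weights` (n x k),
#'   `singular_values` and `variance_fraction` (full spectrum), `k`, `rank`.
#' @export
bpr_decompose <- function(z, k = NULL, var_threshold = 0.5) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2L) stop("need at least 2 subjects")
  if (ncol(z) < 2L) stop("insufficient voxels (", ncol(z), "); need at least 2")
  e <- eigen(tcrossprod(z), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  sigma <- sqrt(lam)
  # eigenvalues of Z Z' carry ~eps relative noise, so singular values are
  # only resolved to ~sqrt(eps); 1e-7 sits safely above that floor
  r <- sum(sigma > 1e-7 * sigma[1L])
  varfrac <- lam / sum(lam)
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L) stop("'k' must be positive")
    if (k > r)
      stop(sprintf("requested k = %d exceeds the numerical rank %d", k, r))
  } else {
    if (!is.numeric(var_threshold) || var_threshold <= 0 || var_threshold > 1)
      stop("'var_threshold' must be in (0, 1]")
    k <- which(cumsum(varfrac) >= var_threshold - 1e-12)[1L]
    if (is.na(k) || k > r) k <- r
  }
  U <- e$vectors[, seq_len(k), drop = FALSE]
  V <- sweep(crossprod(z, U), 2L, sigma[seq_len(k)], "/")
  W <- sweep(U, 2L, sigma[seq_len(k)], "*")
  fs <- fix_signs(V, W)
  cn <- paste0("EB", seq_len(k))
  colnames(fs$weights) <- colnames(fs$patterns) <- cn
  list(patterns = fs$patterns, weights = fs$weights,
       singular_values = sigma, variance_fraction = varfrac,
       k = k, rank = r)
}

#' Between-subject variability projection and reduction (BPR)
#'
#' Fits the eigenbrain decomposition of a cohort of masked, reference-
#' normalized uptake vectors: voxel columns are standardized, rows (subjects)
#' are centred, and the n x n subject-space matrix `Z Z'` is
#' eigen-decomposed. Voxel-space eigenvectors ("eigenbrains") are recovered
#' through the eigenfaces identity `v_i = Z' u_i / sigma_i`, so only an
#' n x n problem is ever solved. Each participant's coordinates on the
#' eigenbrains (`W = U diag(sigma)`) are the latent weights used downstream
#' for clinical decoding.
#'
#' Components are retained either as a fixed number `k` or as the smallest k
#' whose cumulative variance fraction reaches `var_threshold` (default 0.50,
#' the conventional choice for this analysis). Components with singular value
#' below `1e-10 * sigma_max` are treated as numerically null.
#'
#' @param x Numeric matrix, subjects x voxels (e.g. from [stack_cohort()]).
#' @param k Fixed number of components; overrides `var_threshold`.
#' @param var_threshold Cumulative variance-fraction threshold in (0, 1].
#' @param sd_tol Relative voxel-SD tolerance passed to [standardize_voxels()].
#' @param ids Subject identifiers (default: rownames of `x`).
#' @param retx Keep the processed matrix `Z` in the fit (needed by
#'   [residuals.bpr()] and [fitted.bpr()]).
#' @return An object of class `"bpr"`: a list with `weights` (n x k),
#'   `patterns` (p x k, orthonormal columns), `singular_values` and
#'   `variance_fraction` over the full spectrum, `k`, `rank`, the stored
#'   standardization parameters (`voxel_means`, `voxel_sds`,
#'   `excluded_voxels`, `row_means`) and, when available, the voxel ordering
#'   record and mask fingerprint inherited from the cohort matrix.
#' @seealso [predict.bpr()], [eigenbrain_patterns()], [decode()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(20 * 50), 20, 50)
#' fit <- bpr(x, k = 3)
#' fit
#' head(coef(fit))
#' @export
bpr <- function(x, k = NULL, var_threshold = 0.5, sd_tol = 1e-10,
                ids = rownames(x), retx = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  if (length(ids) != n) stop("'ids' must have one entry per subject")
  sv <- standardize_voxels(x, tol = sd_tol)
  cs <- center_subjects(sv$z)
  Z <- cs$z
  p <- ncol(Z)
  if (p < 2L) stop("insufficient voxels retained (", p, ")")

  dec <- bpr_decompose(Z, k = k, var_threshold = var_threshold)
  rownames(dec$weights) <- ids
  dimnames(Z) <- list(ids, NULL)

  structure(list(
    weights = dec$weights,
    patterns = dec$patterns,
    singular_values = dec$singular_values,
    variance_fraction = dec$variance_fraction,
    k = dec$k, rank = dec$rank, n = n, p = p,
    voxel_means = sv$voxel_means,
    voxel_sds = sv$voxel_sds,
    excluded_voxels = sv$excluded,
    row_means = cs$row_means,
    ids = ids,
    n_voxels_input = ncol(x),
    voxel_order = attr(x, "voxel_order"),
    grid_dim = attr(x, "grid_dim"),
    mask_fingerprint = attr(x, "mask_fingerprint"),
    var_threshold = var_threshold,
    Z = if (retx) Z else NULL
  ), class = "bpr")
}

#' @export
print.bpr <- function(x, ...) {
  cat(sprintf("Eigenbrain decomposition (BPR): %d subjects, %d voxels (%d excluded)\n",
              x$n, x$p, length(x$excluded_voxels)))
  cat(sprintf("Retained k = %d of numerical rank %d; cumulative variance %.1f%%\n",
              x$k, x$rank, 100 * sum(x$variance_fraction[seq_len(x$k)])))
  vf <- x$variance_fraction[seq_len(x$k)]
  names(vf) <- colnames(x$weights)
  print(round(vf, 4))
  invisible(x)
}

#' @export
summary.bpr <- function(object, ...) {
  k <- object$k
  tab <- data.frame(
    component = paste0("EB", seq_len(k)),
    singular_value = object$singular_values[seq_len(k)],
    variance_fraction = object$variance_fraction[seq_len(k)],
    cumulative = cumsum(object$variance_fraction)[seq_len(k)]
  )
  structure(list(table = tab, n = object$n, p = object$p,
                 rank = object$rank, k = k,
                 excluded = length(object$excluded_voxels)),
            class = "summary.bpr")
}

#' @export
print.summary.bpr <- function(x, digits = 4, ...) {
  cat(sprintf("BPR decomposition: n = %d subjects, p = %d retained voxels (%d excluded), rank %d\n\n",
              x$n, x$p, x$excluded, x$rank))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.bpr <- function(object, ...) object$weights

#' Extract eigenbrain patterns
#'
#' Eigenbrains live in the doubly-processed (standardized) voxel space the
#' decomposition operates in. For comparison with spatial patterns expressed
#' in native uptake units, `space = "native"` rescales each pattern by the
#' stored per-voxel SDs (undoing the voxel-wise standardization as a linear
#' map on directions) and renormalizes to unit norm.
#'
#' @param object A `"bpr"` fit.
#' @param space `"standardized"` (as decomposed) or `"native"`.
#' @return Voxels x k matrix with unit-norm columns.
#' @export
eigenbrain_patterns <- function(object, space = c("standardized", "native")) {
  stopifnot(inherits(object, "bpr"))
  space <- match.arg(space)
  v <- object$patterns
  if (space == "native") {
    v <- v * object$voxel_sds
    v <- sweep(v, 2L, sqrt(colSums(v^2)), "/")
  }
  v
}

#' Project scans into an existing eigenbrain space
#'
#' Applies the stored voxel means and SDs (dropping voxels excluded at
#' training), subtracts the new participant's own mean, and returns dot
#' products with the eigenbrains. Projecting a training participant's raw
#' data reproduces that participant's stored weights.
#'
#' @param object A `"bpr"` fit.
#' @param newdata Numeric vector (one scan's within-mask values, in training
#'   voxel order) or a matrix with one such row per scan. If the data carry a
#'   `mask_fingerprint` attribute it must match the training mask.
#' @param ... Unused.
#' @return Matrix of weights, one row per scan, columns EB1..EBk.
#' @export
predict.bpr <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$weights)
  fp <- attr(newdata, "mask_fingerprint")
  if (!is.null(fp) && !is.null(object$mask_fingerprint) &&
      !identical(fp, object$mask_fingerprint))
    stop("incompatible space: mask fingerprint of 'newdata' differs from the training mask")
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_voxels_input)
    stop(sprintf("'newdata' has %d voxels; the training mask had %d",
                 ncol(newdata), object$n_voxels_input))
  if (length(object$excluded_voxels))
    newdata <- newdata[, -object$excluded_voxels, drop = FALSE]
  z <- sweep(sweep(newdata, 2L, object$voxel_means, "-"),
             2L, object$voxel_sds, "/")
  z <- z - rowMeans(z)
  w <- z %*% object$patterns
  colnames(w) <- colnames(object$weights)
  w
}

#' @export
fitted.bpr <- function(object, ...) {
  tcrossprod(object$weights, object$patterns)
}

#' @export
residuals.bpr <- function(object, ...) {
  if (is.null(object$Z))
    stop("fit was computed with retx = FALSE; refit to obtain residuals")
  object$Z - fitted(object)
}

#' Scree plot of an eigenbrain decomposition
#'
#' Bars show per-component variance fractions, the line their cumulative sum;
#' retained components are shaded.
#'
#' @param x A `"bpr"` fit.
#' @param n_components Number of leading components to display.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.bpr <- function(x, n_components = min(x$rank, 20L), ...) {
  vf <- x$variance_fraction[seq_len(n_components)]
  bp <- graphics::barplot(vf, names.arg = seq_len(n_components),
                          col = ifelse(seq_len(n_components) <= x$k,
                                       "steelblue", "grey80"),
                          xlab = "Eigenbrain", ylab = "Variance fraction",
                          ylim = c(0, 1), ...)
  graphics::lines(bp, cumsum(vf), type = "b", pch = 19)
  graphics::abline(h = x$var_threshold, lty = 2, col = "grey40")
  invisible(x)
}

#' Write eigenbrains as NIfTI volumes
#'
#' Places each pattern's loadings back into the template grid using the voxel
#' ordering recorded at stacking time (out-of-mask and excluded voxels zero)
#' and writes one volume per component, suitable for surface rendering.
#'
#' @param object A `"bpr"` fit produced from a [stack_cohort()] matrix.
#' @param dir Output directory (created if needed).
#' @param space Pattern space, see [eigenbrain_patterns()].
#' @param voxel_mm Voxel sizes for the NIfTI header.
#' @param prefix File name prefix.
#' @return Invisibly, the vector of file paths.
#' @export
write_eigenbrains <- function(object, dir, space = "standardized",
                              voxel_mm = c(1, 1, 1), prefix = "EB") {
  stopifnot(inherits(object, "bpr"))
  if (is.null(object$voxel_order) || is.null(object$grid_dim))
    stop("fit carries no voxel ordering record; refit from a stack_cohort() matrix")
  v <- eigenbrain_patterns(object, space)
  keep <- object$voxel_order
  if (length(object$excluded_voxels))
    keep <- keep[-object$excluded_voxels]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(object$k)
  for (j in seq_len(object$k)) {
    vol <- array(0, object$grid_dim)
    vol[keep] <- v[, j]
    paths[j] <- file.path(dir, sprintf("%s%d.nii.gz", prefix, j))
    write_volume(vol, paths[j], voxel_mm = voxel_mm)
  }
  invisible(paths)
}
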