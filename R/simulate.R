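#' Configuration for a synthetic FDG-PET-like cohort
#'
#' Defines the phantom geometry and generative model used by
#' [make_patterns()] and [simulate_cohort()]: a template grid with an
#' ellipsoidal brain mask and a small constant-uptake reference region
#' (disjoint from the brain mask, mimicking the pons), a set of smooth
#' localized hypometabolism patterns with per-subject weights, additive
#' voxel noise, and clinical variables linked to the latent weights.
#'
#' Patterns are subtracted multiplicatively from baseline uptake
#' (`baseline * (1 - sum_j w_ij P_j)`), so images stay positive and
#' reference scaling behaves like real uptake ratios. Weight SDs must be
#' strictly decreasing and the default pattern extents decrease in the same
#' order: after the pipeline's voxel-wise standardization, component
#' separation in the eigen-spectrum is driven by spatial extent, so aligned,
#' well-separated extents are what make the planted order identifiable.
#'
#' @param n Cohort size.
#' @param dim Grid dimensions (3 integers).
#' @param voxel_mm Voxel edge lengths in mm.
#' @param n_patterns Number of planted patterns (up to 6 built-in shapes:
#'   left occipito-parieto-temporal, its right mirror, medial-temporal/limbic,
#'   medial-occipital, medial-frontal, superior-parietal).
#' @param weight_sd Per-pattern weight SDs, strictly decreasing.
#' @param baseline Baseline uptake level (arbitrary tracer units).
#' @param noise_sd Additive voxel noise SD in uptake units; default
#'   `NULL` means 10% of the RMS pattern signal over the brain mask.
#' @param pattern_fwhm FWHM (mm) of the smoothing applied to the planted
#'   blobs (pattern smoothness, not the preprocessing kernel).
#' @param blob_radius_mm Per-pattern blob radii in mm (recycled/truncated to
#'   `n_patterns`). Defaults decrease with component order; pass equal radii
#'   to obtain an exactly mirrored left/right pair.
#' @param links List of clinical link definitions (see [link_clinical()]);
#'   default: age of onset rising with the limbic pattern and falling with
#'   the medial-occipital pattern, plus aphasia odds rising with the
#'   left-lateralized pattern.
#' @param missing_rate Fraction of clinical cells set missing at random.
#' @param seed Integer seed; the whole cohort is bit-reproducible given it.
#' @return A list of class `"bpr_sim_config"`.
#' @export
sim_config <- function(n = 91, dim = c(32L, 38L, 32L), voxel_mm = c(4, 4, 4),
                       n_patterns = 4L,
                       weight_sd = c(3, 2.5, 2, 1.5),
                       baseline = 100, noise_sd = NULL,
                       pattern_fwhm = 8,
                       blob_radius_mm = c(28, 21, 14.5, 10, 8, 6.5),
                       links = NULL, missing_rate = 0, seed = 1L) {
  dim <- as.integer(rep_len(dim, 3L))
  if (any(dim < 8L)) stop("grid too small for the phantom geometry")
  n_patterns <- as.integer(n_patterns)
  if (n_patterns < 1L || n_patterns > 6L)
    stop("'n_patterns' must be between 1 and 6")
  weight_sd <- as.numeric(weight_sd)[seq_len(n_patterns)]
  if (anyNA(weight_sd) || any(weight_sd <= 0))
    stop("'weight_sd' must supply a positive SD per pattern")
  if (n_patterns > 1L && any(diff(weight_sd) >= 0))
    stop("'weight_sd' must be strictly decreasing (identifiable component order)")
  if (!is.null(noise_sd) && noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  blob_radius_mm <- rep_len(as.numeric(blob_radius_mm), max(6L, n_patterns))
  if (is.null(links)) links <- default_links(n_patterns)
  structure(list(n = as.integer(n), dim = dim,
                 voxel_mm = rep_len(as.numeric(voxel_mm), 3L),
                 n_patterns = n_patterns, weight_sd = weight_sd,
                 baseline = baseline, noise_sd = noise_sd,
                 pattern_fwhm = pattern_fwhm,
                 blob_radius_mm = blob_radius_mm[seq_len(n_patterns)],
                 links = links, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "bpr_sim_config")
}

# Default clinical links: age of onset tied (+/-) to the third and fourth
# patterns when available, aphasia odds to the first (left-lateralized) one.
default_links <- function(n_patterns) {
  links <- list()
  if (n_patterns >= 4L) {
    links$age_of_onset <- list(name = "age_of_onset", kind = "continuous",
                               patterns = c(3L, 4L), effects = c(3, -3),
                               intercept = 60, noise_sd = 2)
  } else {
    links$age_of_onset <- list(name = "age_of_onset", kind = "continuous",
                               patterns = 1L, effects = 3,
                               intercept = 60, noise_sd = 2)
  }
  links$aphasia <- list(name = "aphasia", kind = "binary",
                        patterns = 1L, effects = 0.9, intercept = 0)
  links
}

#' Brain and reference masks of the synthetic template
#'
#' The brain mask is a centred ellipsoid (semi-axes 40% of each grid
#' dimension); the reference region is a small inferior box, carved out of
#' the brain mask so the two are disjoint.
#'
#' @param config A [sim_config()].
#' @return List with logical arrays `brain` and `ref` (voxel sizes attached).
#' @export
sim_masks <- function(config) {
  d <- config$dim
  ctr <- (d + 1) / 2
  semi <- 0.40 * d
  g <- expand.grid(x = seq_len(d[1L]), y = seq_len(d[2L]), z = seq_len(d[3L]))
  r2 <- ((g$x - ctr[1L]) / semi[1L])^2 + ((g$y - ctr[2L]) / semi[2L])^2 +
    ((g$z - ctr[3L]) / semi[3L])^2
  brain <- array(r2 <= 1, dim = d)
  ref <- array(FALSE, dim = d)
  xr <- pmax(1L, pmin(d[1L], round(ctr[1L]) + (-1L:1L)))
  yr <- pmax(1L, pmin(d[2L], round(0.40 * d[2L]) + (-1L:1L)))
  zr <- pmax(1L, pmin(d[3L], 2:4))
  ref[xr, yr, zr] <- TRUE
  brain[ref] <- FALSE
  attr(brain, "voxel_mm") <- config$voxel_mm
  attr(ref, "voxel_mm") <- config$voxel_mm
  list(brain = brain, ref = ref)
}

# Built-in blob centres as fractions of the grid; pattern 2 mirrors pattern 1
# across the x (left-right) axis exactly.
blob_centers <- function(d) {
  frac <- rbind(
    c(0.35, 0.35, 0.55),   # left occipito-parieto-temporal
    c(NA,   0.35, 0.55),   # right mirror (x set below)
    c(0.50, 0.57, 0.30),   # medial-temporal / limbic
    c(0.50, 0.24, 0.58),   # medial occipital
    c(0.50, 0.75, 0.55),   # medial frontal
    c(0.50, 0.45, 0.80))   # superior parietal
  ctr <- sweep(frac, 2L, d, "*")
  ctr[2L, 1L] <- d[1L] + 1 - ctr[1L, 1L]  # exact mirror of pattern 1
  ctr
}

#' Planted spatial patterns of the synthetic cohort
#'
#' Each pattern is a smooth center-surround blob: a hard ball of the
#' configured radius minus a co-centred surround ball (1.4x the radius)
#' scaled so the pattern sums to zero within the brain mask, both smoothed
#' with `pattern_fwhm`. The zero-sum, compact shape mirrors what the
#' analysis pipeline can represent -- eigenbrains code *relative* metabolic
#' preservation versus reduction and live in the subject-centred subspace --
#' so planted and recoverable patterns coincide. Patterns are restricted to
#' the brain mask and orthonormalized sequentially by Gram-Schmidt.
#' Deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return List with `patterns` (within-mask voxels x k, orthonormal,
#'   zero-sum columns), `masks` (as [sim_masks()]) and `centers` (voxel
#'   coordinates).
#' @export
make_patterns <- function(config) {
  masks <- sim_masks(config)
  d <- config$dim
  idx <- which(masks$brain)
  p <- length(idx)
  if (config$n_patterns > p) stop("mask too small for the requested patterns")
  ctr <- blob_centers(d)
  g <- expand.grid(x = seq_len(d[1L]), y = seq_len(d[2L]), z = seq_len(d[3L]))
  surround <- 1.4
  P <- matrix(0, p, config$n_patterns)
  for (j in seq_len(config$n_patterns)) {
    dist2 <- ((g$x - ctr[j, 1L]) * config$voxel_mm[1L])^2 +
      ((g$y - ctr[j, 2L]) * config$voxel_mm[2L])^2 +
      ((g$z - ctr[j, 3L]) * config$voxel_mm[3L])^2
    core <- gaussian_smooth(array(as.numeric(dist2 <= config$blob_radius_mm[j]^2), dim = d),
                            config$pattern_fwhm, voxel_mm = config$voxel_mm)[idx]
    ring <- gaussian_smooth(array(as.numeric(dist2 <= (surround * config$blob_radius_mm[j])^2), dim = d),
                            config$pattern_fwhm, voxel_mm = config$voxel_mm)[idx]
    P[, j] <- core - (sum(core) / sum(ring)) * ring
  }
  # sequential Gram-Schmidt, then re-orthogonalize once for 1e-10 accuracy
  for (pass in 1:2) {
    for (j in seq_len(ncol(P))) {
      if (j > 1L)
        P[, j] <- P[, j] - P[, seq_len(j - 1L), drop = FALSE] %*%
          crossprod(P[, seq_len(j - 1L), drop = FALSE], P[, j])
      nrm <- sqrt(sum(P[, j]^2))
      if (nrm < 1e-12) stop("pattern ", j, " degenerate after orthogonalization")
      P[, j] <- P[, j] / nrm
    }
  }
  colnames(P) <- paste0("P", seq_len(ncol(P)))
  list(patterns = P, masks = masks, centers = ctr[seq_len(config$n_patterns), , drop = FALSE])
}

#' Clinical variables generated from latent weights
#'
#' Continuous variables are `intercept + sum(effect * standardized weight) +
#' Gaussian noise`; binary variables are drawn from a logistic link with the
#' configured per-SD log-odds (levels `"absent"`/`"present"`, the modelled
#' level being `"present"`). Missingness is injected completely at random at
#' `missing_rate`.
#'
#' @param weights Subjects x k latent weight matrix.
#' @param links List of link definitions: each a list with `name`, `kind`
#'   (`"continuous"` or `"binary"`), `patterns` (column indices), `effects`,
#'   `intercept` and, for continuous links, `noise_sd`.
#' @param seed Optional seed (`NULL`: use the current RNG stream).
#' @param missing_rate Fraction of cells set to `NA` per variable.
#' @return Data frame with an `id` column and one column per link.
#' @export
link_clinical <- function(weights, links, seed = NULL, missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  ids <- rownames(weights)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (lk in links) {
    if (any(lk$patterns < 1L | lk$patterns > ncol(weights)))
      stop("link '", lk$name, "' references a pattern index out of range")
    ws <- scale(weights[, lk$patterns, drop = FALSE])
    eta <- as.numeric(lk$intercept + ws %*% lk$effects)
    if (identical(lk$kind, "continuous")) {
      val <- eta + stats::rnorm(n, 0, lk$noise_sd)
    } else if (identical(lk$kind, "binary")) {
      val <- factor(ifelse(stats::runif(n) < stats::plogis(eta),
                           "present", "absent"),
                    levels = c("absent", "present"))
    } else stop("unknown link kind: ", lk$kind)
    if (missing_rate > 0)
      val[stats::runif(n) < missing_rate] <- NA
    out[[lk$name]] <- val
  }
  out
}

#' Simulate a synthetic FDG-PET cohort with known ground truth
#'
#' Each subject's image is `baseline * (1 - sum_j w_ij P_j)` plus independent
#' Gaussian voxel noise inside the brain mask; the reference region has
#' constant, noiseless uptake equal to `baseline`, so reference normalization
#' is exact; voxels outside both masks are zero. Weights are drawn
#' independently per pattern with the configured SDs, and clinical variables
#' are generated from them via [link_clinical()]. The output is
#' bit-reproducible given the configuration seed.
#'
#' @param config A [sim_config()].
#' @param format `"matrix"` returns the subjects x within-mask-voxels raw
#'   uptake matrix directly (fast path used by simulation studies);
#'   `"volumes"` additionally materializes full 3D images per subject.
#' @param write_dir Optional directory: writes per-subject NIfTI volumes,
#'   both masks, the clinical table and ground-truth weights.
#' @return List with `config`, `matrix` (raw within-mask uptake, one row per
#'   subject; `NULL` unless requested), `images` (list of 3D arrays or
#'   `NULL`), `brain_mask`, `ref_mask`, `ref_mean` (per-subject reference
#'   mean), `clinical`, `ids`, `noise_sd` and `truth` (planted `patterns`,
#'   `weights`, `links`).
#' @export
simulate_cohort <- function(config, format = c("matrix", "volumes"),
                            write_dir = NULL) {
  stopifnot(inherits(config, "bpr_sim_config"))
  format <- match.arg(format)
  set.seed(config$seed)
  mp <- make_patterns(config)
  P <- mp$patterns
  p <- nrow(P)
  n <- config$n
  k <- config$n_patterns
  W <- matrix(stats::rnorm(n * k), n, k) %*% diag(config$weight_sd, k)
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(W) <- list(ids, colnames(P))

  noise_sd <- config$noise_sd
  if (is.null(noise_sd))
    noise_sd <- 0.1 * config$baseline * sqrt(sum(config$weight_sd^2) / p)

  vals <- config$baseline * (1 - tcrossprod(W, P))
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  n_neg <- sum(vals < 0)
  if (n_neg > 0) {
    warning(sprintf("%d voxel values clipped at zero (weights drove uptake negative)",
                    n_neg))
    vals[vals < 0] <- 0
  }
  rownames(vals) <- ids

  clinical <- link_clinical(W, config$links, seed = NULL,
                            missing_rate = config$missing_rate)

  images <- NULL
  if (format == "volumes" || !is.null(write_dir)) {
    bidx <- which(mp$masks$brain)
    ridx <- which(mp$masks$ref)
    images <- lapply(seq_len(n), function(i) {
      vol <- array(0, config$dim)
      vol[ridx] <- config$baseline
      vol[bidx] <- vals[i, ]
      attr(vol, "voxel_mm") <- config$voxel_mm
      vol
    })
    names(images) <- ids
  }

  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n))
      write_volume(images[[i]], file.path(write_dir, paste0(ids[i], ".nii.gz")),
                   voxel_mm = config$voxel_mm)
    write_volume(array(as.numeric(mp$masks$brain), config$dim),
                 file.path(write_dir, "brain_mask.nii.gz"), config$voxel_mm)
    write_volume(array(as.numeric(mp$masks$ref), config$dim),
                 file.path(write_dir, "reference_mask.nii.gz"), config$voxel_mm)
    utils::write.csv(clinical, file.path(write_dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(id = ids, W, check.names = FALSE),
                     file.path(write_dir, "true_weights.csv"), row.names = FALSE)
  }

  list(config = config,
       matrix = if (format == "matrix") vals else NULL,
       images = images,
       brain_mask = mp$masks$brain, ref_mask = mp$masks$ref,
       ref_mean = rep(config$baseline, n),
       clinical = clinical, ids = ids, noise_sd = noise_sd,
       truth = list(patterns = P, weights = W, links = config$links,
                    centers = mp$centers))
}
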