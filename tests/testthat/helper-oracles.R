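# Independent oracles and small fixture builders used across the suite.

# Literal Benjamini-Hochberg step-up, written from the definition: sort
# ascending, q_i = min_{j >= i} p_(j) * m / j, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Principal angles (radians) between the column spans of A and B.
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  acos(pmin(1, svd(crossprod(qa, qb))$d))
}

# Seeded random matrix.
rmat <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# A small random volume with voxel sizes attached.
rvol <- function(dim = c(7L, 6L, 5L), voxel_mm = c(2, 2, 2), seed = 1) {
  set.seed(seed)
  v <- array(rexp(prod(dim)) + 0.5, dim = dim)
  attr(v, "voxel_mm") <- voxel_mm
  v
}

# Doubly-processed matrix (voxel-standardized then subject-centred).
processed_matrix <- function(x) {
  center_subjects(standardize_voxels(x)$z)$z
}
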