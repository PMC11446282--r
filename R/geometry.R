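# Internal vector geometry used by the helix builder, dihedral assignment and
# superposition. Coordinates are plain numeric length-3 vectors or n x 3
# matrices in Angstrom.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
# Dihedral angle (degrees, in (-180, 180]) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural extension reference frame: place a new atom at the given bond
# length, bond angle (deg) and torsion (deg) relative to atoms a-b-c.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  c(m %*% d) + c
}

# Kabsch algorithm: optimal proper rotation + translation of `mobile` onto
# `reference` (both n x 3). Reflections are rejected by flipping the sign of
# the smallest singular vector when det < 0.
kabsch <- function(reference, mobile) {
  stopifnot(nrow(reference) == nrow(mobile), ncol(reference) == 3)
  mu_r <- colMeans(reference)
  mu_m <- colMeans(mobile)
  P <- sweep(mobile, 2, mu_m)
  Q <- sweep(reference, 2, mu_r)
  H <- t(P) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, translation = mu_r - c(R %*% mu_m),
       center_mobile = mu_m, center_reference = mu_r)
}

apply_rigid <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, `+`)
}

# Random rigid transform (uniform rotation via QR of a Gaussian matrix).
random_rigid <- function(max_shift = 20) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = stats::runif(3, -max_shift, max_shift))
}

# Apply a rigid transform to a structure tibble.

#' Rigidly transform all coordinates of a structure
#'
#' Applies a proper rotation followed by a translation to every atom. Used to
#' test invariance of interface maps, register assignment and RMSD to the
#' arbitrary frame of a predicted model.
#'
#' @param model structure tibble (see [read_structure()]).
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric length-3 shift in Angstrom.
#' @return the transformed structure tibble.
#' @export
transform_structure <- function(model, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")])
  xyz <- apply_rigid(xyz, rotation, translation)
  model$x <- xyz[, 1]
  model$y <- xyz[, 2]
  model$z <- xyz[, 3]
  model
}
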