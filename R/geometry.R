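# Small 3D geometry kernel shared by the rotamer builder, ligand placement
# and RMSD code. Coordinates are plain numeric length-3 vectors or n x 3
# matrices, in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into the (-180, 180] convention
#'
#' @param x angles in degrees.
#' @return angles wrapped into `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[which(y > 180)] <- y[which(y > 180)] - 360
  # map -180 to +180 so the interval is half-open as documented
  y[which(y <= -180)] <- y[which(y <= -180)] + 360
  y
}

#' Bond angle at b formed by atoms a-b-c, in degrees
#' @param a,b,c length-3 coordinate vectors.
#' @export
bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle a-b-c-d (IUPAC sign convention), degrees in (-180, 180]
#' @param a,b,c,d length-3 coordinate vectors.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(rad2deg(atan2(y, x)))
}

# NERF atom placement: put atom D given positions A, B, C, the C-D bond
# length, the B-C-D angle (deg) and the A-B-C-D torsion (deg).
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- -deg2rad(torsion)  # sign flip matches the IUPAC dihedral convention
  d_local <- c(-length * cos(ang),
               length * sin(ang) * cos(tor),
               length * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d_local + c)
}

# Rotation matrices about the coordinate axes, angle in degrees.
rot_x <- function(t) {
  t <- deg2rad(t)
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
}
rot_y <- function(t) {
  t <- deg2rad(t)
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}
rot_z <- function(t) {
  t <- deg2rad(t)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Kabsch: optimal rotation (and translation) superposing mobile onto target.
# Both are n x 3 matrices with paired rows. Returns list(R, t) such that
# mobile %*% R + t approximates target in the least-squares sense.
kabsch <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  p <- sweep(mobile, 2, cm)
  q <- sweep(target, 2, ct)
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  r <- t(r)
  list(R = r, t = ct - as.numeric(cm %*% r))
}

apply_transform <- function(coords, tr) {
  sweep(coords %*% tr$R, 2, tr$t, "+")
}

coord_rmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}
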