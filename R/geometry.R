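# Internal-coordinate geometry helpers. Coordinates are plain numeric
# 3-vectors / n x 3 matrices in nm unless a function says otherwise.

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

deg2rad <- function(x) x * pi / 180

#' Distance between two points
#' @noRd
dist3 <- function(a, b) vec_norm(a - b)

# Angle a-b-c in degrees.
angle3 <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

# Dihedral a-b-c-d in degrees, IUPAC sign convention.
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# NeRF atom placement: put a new atom D at distance `bond` from C, with
# angle D-C-B equal to `ang` (deg) and dihedral A-B-C-D equal to `tor` (deg).
place_atom <- function(a, b, c, bond, ang, tor) {
  ang <- deg2rad(ang)
  tor <- deg2rad(tor)
  d2 <- c(
    -bond * cos(ang),
    bond * cos(tor) * sin(ang),
    -bond * sin(tor) * sin(ang)
  )
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Kabsch superposition: rotate/translate `mobile` (n x 3) onto `fixed`.
# Returns the transformed coordinates.
kabsch_fit <- function(mobile, fixed, apply_to = mobile) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  p <- sweep(mobile, 2, cm)
  q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(p, q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(apply_to, 2, cm) %*% t(rot), 2, cf, "+")
}

# Rotation matrix for angle theta (rad) about unit axis u (Rodrigues).
rotation_about_axis <- function(u, theta) {
  u <- unit(u)
  k <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * k + (1 - cos(theta)) * (k %*% k)
}
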