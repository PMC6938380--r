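## Shared ideal-geometry constants and internal-coordinate atom placement.
## The same constants drive the synthetic structure builder and the
## stereochemical (bond/angle) terms of the objective, so a generated
## structure sits at the minimum of its own physical terms.

IDEAL_BONDS <- list(
  "N-CA"  = 1.458, "CA-C" = 1.525, "C-O" = 1.231, "C-N" = 1.329,
  "CA-CB" = 1.530, "CB-CG" = 1.520)

IDEAL_ANGLES_DEG <- list(
  "N-CA-C" = 111.2, "CA-C-O" = 120.8, "CA-C-N" = 116.2,
  "C-N-CA" = 121.7, "N-CA-CB" = 110.5, "CA-CB-CG" = 114.0)

## Place atom d given positions of a, b, c and the internal coordinates
## |c-d| = bond, angle b-c-d, torsion a-b-c-d (degrees). Standard NeRF.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- pracma_cross(ab, bc)
  nn <- vnorm(n)
  if (nn < 1e-10) {  # collinear reference: pick any perpendicular
    n <- pracma_cross(bc, c(1, 0, 0))
    if (vnorm(n) < 1e-10) n <- pracma_cross(bc, c(0, 1, 0))
    nn <- vnorm(n)
  }
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

## interior angle a-b-c in radians
bond_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang)))
}
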