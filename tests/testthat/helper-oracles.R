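# Closed-form annular Poiseuille flow between radii R1 < R2 (SI units):
#   u(r) = G/(4 mu) * (R2^2 - r^2 + (R2^2 - R1^2) ln(r/R2) / ln(R2/R1))
# with G = -dp/dz. The oracle returns the profile normalized to a given
# volumetric flow, plus the analytic wall shear at R2; the flow integral is
# evaluated by brute-force quadrature so the oracle stays independent of the
# solver discretization.
annular_poiseuille <- function(r, q_m3_s, R1, R2, mu) {
  shape <- function(rr) {
    R2^2 - rr^2 + (R2^2 - R1^2) * log(rr / R2) / log(R2 / R1)
  }
  rr <- seq(R1, R2, length.out = 4001)
  q_unit <- sum(2 * pi * rr * shape(rr)) * (rr[2] - rr[1]) # G/(4 mu) = 1
  scale <- q_m3_s / q_unit
  dshape <- function(rr) -2 * rr + (R2^2 - R1^2) / (log(R2 / R1) * rr)
  list(
    u = scale * shape(r),
    wall_shear = mu * abs(scale * dshape(R2)) # = mu * |du/dr| at R2
  )
}
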