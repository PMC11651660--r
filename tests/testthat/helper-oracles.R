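# Independent oracles used across tests.

# Single-ligand binding quadratic: bound complex for totals Pt, Lt and
# dissociation constant Kd.
bound_quadratic <- function(Pt, Lt, Kd) {
  b <- Pt + Lt + Kd
  (b - sqrt(b^2 - 4 * Pt * Lt)) / 2
}

# Competitive equilibrium as the real root in [0, Pt] of the cubic in
# free P (independent closed-form route, vs the package's bisection):
# P (KdA+P)(KdB+P) + At P (KdB+P) + Bt P (KdA+P)
#   - Pt (KdA+P)(KdB+P) = 0
competition_cubic_freeP <- function(Pt, Bt, KdB, At, KdA) {
  # rescale by Pt so polyroot sees O(1) coefficients
  s <- Pt
  pt <- 1; bt <- Bt / s; kb <- KdB / s; at <- At / s; ka <- KdA / s
  a3 <- 1
  a2 <- ka + kb + at + bt - pt
  a1 <- ka * kb + at * kb + bt * ka - pt * (ka + kb)
  a0 <- -pt * ka * kb
  r <- polyroot(c(a0, a1, a2, a3))
  r <- Re(r[abs(Im(r)) < 1e-8 * pmax(1, Mod(r))])
  r <- r[r >= -1e-9 & r <= pt * (1 + 1e-9)]
  stopifnot(length(r) == 1)
  max(r, 0) * s
}

# Default study-condition parameters reused across tests
default_stability <- function() stability_params(332.15, 6e5)
table3_setup <- function() competition_setup(Pt = 5e-9, Bt = 10e-9,
                                             KdB = 150e-12)
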