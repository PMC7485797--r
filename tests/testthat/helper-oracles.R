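# Independent oracles for the elimination math.  These never call the
# package's solver internals: the two-cause oracle bisects the joint
# survival / risk-proportionality system directly, and the simultaneous
# oracle solves the all-causes proportional-risk system with uniroot.

# bisection solve of {q1/q2 = D1/D2, (1 - q1)(1 - q2) = 1 - D1 - D2}
bisect_two_cause <- function(D1, D2, tol = 1e-12, iter = 200) {
  D1 <- unname(D1); D2 <- unname(D2)
  stopifnot(D1 > 0, D2 > 0, D1 + D2 < 1)
  S <- 1 - D1 - D2
  f <- function(q2) (1 - (D1 / D2) * q2) * (1 - q2) - S
  lo <- 0
  hi <- min(1, D2 / D1) - 1e-15
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  q2 <- (lo + hi) / 2
  c(q1 = (D1 / D2) * q2, q2 = q2)
}

# simultaneous proportional-risk solution for all causes at once:
# q_i = t * D_i with prod(1 - t * D_i) = 1 - sum(D)
simultaneous_net <- function(D) {
  stopifnot(all(D >= 0), sum(D) < 1)
  pos <- D > 0
  if (!any(pos)) return(D * 0)
  f <- function(t) prod(1 - t * D[pos]) - (1 - sum(D))
  if (abs(f(1)) < 1e-14) return(stats::setNames(D, names(D)))  # single cause
  upper <- 1 / max(D[pos]) - 1e-12
  t <- stats::uniroot(f, c(1, upper), tol = 1e-14)$root
  q <- t * D
  names(q) <- names(D)
  q
}
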