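#' Exact 1-D total variation denoising by the taut-string construction
#'
#' Computes the exact minimizer of
#' `1/2 * sum((y - x)^2) + lambda * sum(|diff(x)|)` via the taut-string
#' equivalence: the solution is the sample-wise derivative of the shortest
#' (taut) path through the tube of half-width `lambda` around the running
#' sum of `y`, pinned at both ends.
#'
#' The taut path is constructed by divide and conquer: over the chord
#' between two pinned points, the ceiling or floor point that violates the
#' chord the most is a contact point of the taut string; it becomes a knot
#' and the two halves are solved recursively (chord feasible -> straight
#' segment).  This is direct and exact to floating point, which is why it
#' serves as the reference implementation for [tvdDenoise()]; optimality
#' of its output is certified in the test suite by the dual (KKT)
#' conditions.  Worst-case cost O(n^2); intended for oracle-scale signals.
#'
#' @param y numeric signal.
#' @param lambda TV regularization weight (>= 0).
#' @return Numeric vector, the exact TV-denoised signal.
#' @examples
#' y <- c(0, 0, 5, 5, 0)
#' tvTautString(y, 0.5)
#' @export
tvTautString <- function(y, lambda) {
  n <- length(y)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (n <= 1L || lambda == 0) return(y)
  r <- c(0, cumsum(y))                    # ordinates at abscissa 0..n
  up <- r + lambda; up[1L] <- 0; up[n + 1L] <- r[n + 1L]
  lo <- r - lambda; lo[1L] <- 0; lo[n + 1L] <- r[n + 1L]
  s <- numeric(n + 1L)                    # taut path ordinates
  s[1L] <- 0; s[n + 1L] <- r[n + 1L]
  # segment stack: pinned (ai, av) -- (bi, bv), abscissae 0-based
  stack <- list(c(0, 0, n, r[n + 1L]))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ai <- seg[1L]; av <- seg[2L]; bi <- seg[3L]; bv <- seg[4L]
    if (bi - ai <= 1L) next
    ii <- (ai + 1L):(bi - 1L)
    chord <- av + (bv - av) * (ii - ai) / (bi - ai)
    vU <- chord - up[ii + 1L]             # > 0: chord above the ceiling
    vL <- lo[ii + 1L] - chord             # > 0: chord below the floor
    mU <- which.max(vU); mL <- which.max(vL)
    if (vU[mU] <= 0 && vL[mL] <= 0) {     # chord feasible: straight segment
      s[ii + 1L] <- chord
      next
    }
    if (vU[mU] >= vL[mL]) { ki <- ii[mU]; kv <- up[ki + 1L] }
    else { ki <- ii[mL]; kv <- lo[ki + 1L] }
    s[ki + 1L] <- kv
    stack[[length(stack) + 1L]] <- c(ai, av, ki, kv)
    stack[[length(stack) + 1L]] <- c(ki, kv, bi, bv)
  }
  diff(s)
}
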