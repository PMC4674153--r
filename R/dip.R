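#' Hartigan's dip statistic
#'
#' Departure of a sample from unimodality: the minimum over all unimodal
#' distribution functions G (convex to the left of the mode, concave to the
#' right, with an atom permitted at the mode itself) of the sup-norm distance
#' between G and the empirical CDF. The result is floored at `1/(2n)`, the
#' value attained by perfectly unimodal configurations, so that
#' `1/(2n) <= D <= 1/4` always; a constant sample (point mass, itself
#' unimodal) returns exactly `1/(2n)`.
#'
#' The search is exact and runs over every admissible mode placement: the
#' mode lying strictly between two adjacent observed values, or at an
#' observed value where the fitted CDF may jump. For a fixed placement the
#' minimal band half-width is determined by three certificate families on
#' the ECDF band: (i) convexity of the left flank against the band (greatest
#' convex minorant of the upper bound vs the lower bound), (ii) the mirrored
#' concavity condition on the right flank, and (iii) a junction condition --
#' the smallest value the convex flank can reach at its last support point
#' must not exceed the largest value the concave flank can take at its
#' first. Ties contribute ECDF jumps of `k/n`; no jittering is applied.
#'
#' @param x numeric vector, `n >= 2`, finite; need not be sorted.
#' @return the dip statistic D (dimensionless).
#' @examples
#' dip_statistic(c(0, 1))        # 0.25, the maximal value
#' dip_statistic(c(0, 0.5, 1))   # 1/6
#' dip_statistic(rep(3, 10))     # 1/(2n) = 0.05
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  .assert(n >= 2L, "need at least 2 observations")
  .assert(all(is.finite(x)), "non-finite values in x")
  if (n <= 3L) return(0.5 / n)     # closed form: any 2- or 3-point sample
  tt <- sort(unique(x))
  K <- length(tt)
  if (K == 1L) return(0.5 / n)
  cnt <- tabulate(match(x, tt), K)
  u <- cumsum(cnt) / n             # F_n at the points
  l <- c(0, u[-K])                 # left limits
  jump <- u - l

  cvx <- .dip_flank_profile(tt, l, u)                          # left flanks
  rvx <- rev(.dip_flank_profile(rev(-tt), rev(1 - u), rev(1 - l)))  # right
  cviol <- pmax(cvx, jump)
  dviol <- pmax(rvx, jump)

  # flank-only half-widths per mode placement
  epsA <- numeric(K + 1L)          # mode in gap k (between t_k and t_{k+1})
  for (k in 0:K)
    epsA[k + 1L] <- max(if (k >= 1L) cviol[k] else -Inf,
                        if (k < K) dviol[k + 1L] else -Inf) / 2
  epsB <- pmax(cvx, rvx) / 2       # mode at point j, atom allowed

  minG <- function(k, eps, relax_last) {
    A <- u[1:k] - eps; B <- l[1:k] + eps
    if (relax_last) A[k] <- l[k] - eps
    .min_end_convex(tt[1:k], A, B)
  }
  maxH <- function(k, eps, relax_first) {
    A <- rev(1 - l[k:K]) - eps; B <- rev(1 - u[k:K]) + eps
    if (relax_first) A[length(A)] <- rev(1 - u[k:K])[length(A)] - eps
    1 - .min_end_convex(rev(-tt[k:K]), A, B)
  }
  jun_gap <- function(type, id, e) {
    if (type == 1L) return(minG(id, e, FALSE) - maxH(id + 1L, e, FALSE))
    a <- if (id == 1L) l[1] - e else minG(id, e, TRUE)
    b <- if (id == K) u[K] + e else maxH(id, e, TRUE)
    a - b
  }

  type <- c(rep(1L, K + 1L), rep(2L, K))
  idx <- c(0:K, 1:K)
  eps0 <- c(epsA, epsB)
  ord <- order(eps0)
  best <- Inf
  for (ci in ord) {
    e0 <- max(eps0[ci], 0)
    if (e0 >= best) break
    ty <- type[ci]; id <- idx[ci]
    if (ty == 1L && (id == 0L || id == K)) { best <- e0; next }
    if (jun_gap(ty, id, e0) <= 1e-13) { best <- e0; next }
    lo <- e0; hi <- min(best, 0.76)
    if (jun_gap(ty, id, hi) > 0) next    # cannot beat the current best
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (jun_gap(ty, id, mid) <= 0) hi <- mid else lo <- mid
    }
    best <- hi
  }
  max(0.5 / n, best)
}

# For each k, the largest violation max_{m<k} (u_m - env_{1..k}(t_m)) where
# env is the lower convex envelope of the points (tt, l) on window 1..k
# (the point's own jump term m = k is excluded; callers add it when needed).
# Incremental convex-hull maintenance; envelopes only move down as the
# window grows, so a running maximum over re-evaluated segments is exact.
.dip_flank_profile <- function(tt, l, u) {
  K <- length(tt)
  violx <- numeric(K)
  viol_m <- u - l
  hull <- integer(K); hp <- 0L
  runmax <- -Inf
  for (k in 1:K) {
    while (hp >= 2L) {
      a <- hull[hp - 1L]; b <- hull[hp]
      if ((l[b] - l[a]) * (tt[k] - tt[b]) > (l[k] - l[b]) * (tt[b] - tt[a]))
        hp <- hp - 1L
      else break
    }
    if (k > 1L) {
      a <- hull[hp]
      if (k - a > 1L) {
        m <- (a + 1L):(k - 1L)
        line <- l[a] + (l[k] - l[a]) * (tt[m] - tt[a]) / (tt[k] - tt[a])
        viol_m[m] <- pmax(viol_m[m], u[m] - line)
        runmax <- max(runmax, viol_m[m])
      }
      runmax <- max(runmax, viol_m[k - 1L])
    }
    violx[k] <- if (k == 1L) -Inf else runmax
    hp <- hp + 1L; hull[hp] <- k
  }
  violx
}

# Minimal feasible value at the last support point of a convex nondecreasing
# function bounded by A (below) and B (above): certificates chain one upper
# bound B_i with a later lower bound A_m' (forcing a slope) and a still later
# lower bound A_m'' from which that slope propagates to the end.
.min_end_convex <- function(tt, A, B) {
  k <- length(A)
  v <- A[k]
  if (k >= 3L) {
    S <- rep(-Inf, k - 1L)
    for (mp in 2:(k - 1L))
      S[mp] <- max((A[mp] - B[1:(mp - 1L)]) / (tt[mp] - tt[1:(mp - 1L)]))
    S <- cummax(S)
    m <- 2:(k - 1L)
    cand <- A[m] + S[m] * (tt[k] - tt[m])
    cand <- cand[is.finite(cand)]
    if (length(cand)) v <- max(v, cand)
  }
  v
}

#' Monte-Carlo null configuration for the dip test
#'
#' The dip statistic's null distribution is simulated from samples of the
#' standard uniform -- the classical least-favourable unimodal reference --
#' of the same size as the data. `B` replicates with the `+1` correction
#' give p-values in `(0, 1]`. Tables are cached per `(n, B, seed)` within a
#' session.
#'
#' @param B number of Monte-Carlo replicates (>= 1).
#' @param seed integer seed making the null table reproducible.
#' @param alpha significance level used by the multimodality flag.
#' @return list of class `dip_null_config`.
#' @export
dip_null_config <- function(B = 10000, seed = 17, alpha = 0.05) {
  .assert(B >= 1, "B must be >= 1")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(B = as.integer(B), seed = as.integer(seed), alpha = alpha),
            class = "dip_null_config")
}

.dip_cache <- new.env(parent = emptyenv())

#' Simulated null dip values for a given sample size
#'
#' @param n sample size (>= 2).
#' @param cfg [dip_null_config()]
#' @return sorted numeric vector of `B` dip statistics of uniform samples.
#' @export
dip_null_table <- function(n, cfg = dip_null_config()) {
  .assert(n >= 2L, "n must be >= 2")
  key <- sprintf("n%d_B%d_s%d", n, cfg$B, cfg$seed)
  tab <- .dip_cache[[key]]
  if (is.null(tab)) {
    tab <- with_seed(cfg$seed + n, {
      sort(vapply(seq_len(cfg$B),
                  function(b) dip_statistic(stats::runif(n)), numeric(1)))
    })
    .dip_cache[[key]] <- tab
  }
  tab
}

#' Monte-Carlo p-value for an observed dip
#'
#' `p = (1 + #\{D_b >= D\}) / (B + 1)` against the uniform null of the same
#' sample size; always in `(0, 1]`, equal to 1 when `D = 0`, and
#' non-increasing in `D` for a fixed table.
#'
#' @param D observed dip statistic (>= 0).
#' @param n sample size the statistic was computed from.
#' @param cfg [dip_null_config()]
#' @return p-value.
#' @export
dip_pvalue <- function(D, n, cfg = dip_null_config()) {
  .assert(is.numeric(D) && D >= 0, "D must be >= 0")
  tab <- dip_null_table(n, cfg)
  exceed <- length(tab) - findInterval(D, tab, left.open = TRUE)
  (1 + exceed) / (cfg$B + 1)
}
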