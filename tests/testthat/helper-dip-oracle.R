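# Brute-force oracle for the dip statistic, independent of the production
# search in R/dip.R: envelopes are evaluated by enumerating every chord,
# junction feasibility by explicit certificate enumeration plus bisection.
# Agrees with an exact linear-programming formulation (see
# data-raw/make_dip_reference.R) to < 1e-13 on thousands of dev samples.
dip_oracle <- function(x) {
  n <- length(x)
  tt <- sort(unique(x))
  K <- length(tt)
  cnt <- tabulate(match(x, tt), K)
  u <- cumsum(cnt) / n
  l <- c(0, u[-K])
  if (K == 1L) return(0.5 / n)

  env_at <- function(w, m) {            # lower convex envelope of (tt, l)
    lo <- w[w <= m]; hi <- w[w >= m]
    best <- l[m]
    for (i in lo) for (j in hi) {
      if (i == j) next
      v <- l[i] + (l[j] - l[i]) * (tt[m] - tt[i]) / (tt[j] - tt[i])
      if (v < best) best <- v
    }
    best
  }
  cap_at <- function(w, m) {            # upper concave envelope of (tt, u)
    lo <- w[w <= m]; hi <- w[w >= m]
    best <- u[m]
    for (i in lo) for (j in hi) {
      if (i == j) next
      v <- u[i] + (u[j] - u[i]) * (tt[m] - tt[i]) / (tt[j] - tt[i])
      if (v > best) best <- v
    }
    best
  }
  cviol  <- function(k) if (k < 1) -Inf else
    max(vapply(1:k, function(m) u[m] - env_at(1:k, m), 0))
  dviol  <- function(k) if (k > K) -Inf else
    max(vapply(k:K, function(m) cap_at(k:K, m) - l[m], 0))
  cviolx <- function(j) if (j <= 1) -Inf else
    max(vapply(1:(j - 1), function(m) u[m] - env_at(1:j, m), 0))
  dviolx <- function(j) if (j >= K) -Inf else
    max(vapply((j + 1):K, function(m) cap_at(j:K, m) - l[m], 0))

  min_end <- function(ss, A, B) {
    k <- length(A)
    v <- A[k]
    if (k >= 3) {
      for (i in 1:(k - 2)) for (mp in (i + 1):(k - 1)) {
        s <- (A[mp] - B[i]) / (ss[mp] - ss[i])
        for (mpp in mp:(k - 1)) {
          cand <- A[mpp] + s * (ss[k] - ss[mpp])
          if (cand > v) v <- cand
        }
      }
    }
    v
  }
  minG <- function(k, eps, relax_last = FALSE) {
    A <- u[1:k] - eps; B <- l[1:k] + eps
    if (relax_last) A[k] <- l[k] - eps
    min_end(tt[1:k], A, B)
  }
  maxH <- function(k, eps, relax_first = FALSE) {
    A <- rev(1 - l[k:K]) - eps; B <- rev(1 - u[k:K]) + eps
    if (relax_first) A[length(A)] <- rev(1 - u[k:K])[length(A)] - eps
    1 - min_end(rev(-tt[k:K]), A, B)
  }
  case_eps <- function(sides, jun) {
    eps <- max(0, sides / 2)
    f <- jun(eps)
    if (f[1] <= f[2] + 1e-13) return(eps)
    lo <- eps; hi <- 0.76
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      f <- jun(mid)
      if (f[1] <= f[2]) hi <- mid else lo <- mid
    }
    hi
  }

  best <- Inf
  for (k in 0:K) {
    sides <- max(cviol(k), dviol(k + 1))
    eps <- if (k == 0 || k == K) max(0, sides / 2)
    else case_eps(sides, function(e) c(minG(k, e), maxH(k + 1, e)))
    best <- min(best, eps)
  }
  for (j in 1:K) {
    sides <- max(cviolx(j), dviolx(j))
    jun <- if (j == 1) function(e) c(l[1] - e, maxH(1, e, relax_first = TRUE))
    else if (j == K) function(e) c(minG(K, e, relax_last = TRUE), u[K] + e)
    else function(e) c(minG(j, e, relax_last = TRUE),
                       maxH(j, e, relax_first = TRUE))
    best <- min(best, case_eps(sides, jun))
  }
  max(0.5 / n, best)
}

# all multisets of size n drawn from `values`, as a matrix with n rows
multisets <- function(values, n) {
  cmb <- utils::combn(length(values) + n - 1L, n)
  apply(cmb, 2L, function(ix) values[ix - seq_len(n) + 1L])
}
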