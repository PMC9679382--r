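## Independent reference implementations used as oracles.  Each solves the
## same problem as a package routine by a different route (linear
## programming, exhaustive enumeration, greedy transport) and is kept
## deliberately naive.

## Exact 1-D optimal transport between histograms on shared bin centers by
## the north-west-corner rule; with both marginals sorted on the same 1-D
## axis the greedy matching is the optimal transport plan.
transportEmdOracle <- function(h1, h2) {
  p <- h1$mass; q <- h2$mass; centers <- h1$centers
  i <- 1L; j <- 1L
  cost <- 0
  p <- p + 0; q <- q + 0
  while (i <= length(p) && j <= length(q)) {
    m <- min(p[i], q[j])
    cost <- cost + m * abs(centers[i] - centers[j])
    p[i] <- p[i] - m; q[j] <- q[j] - m
    if (p[i] <= 1e-15) i <- i + 1L
    if (j <= length(q) && q[j] <= 1e-15) j <- j + 1L
  }
  cost
}

## Transportation linear program via boot::simplex (flow variables f[i,j]);
## empty bins are dropped so the equality system stays nondegenerate.
lpEmdOracle <- function(h1, h2) {
  keepP <- which(h1$mass > 0)
  keepQ <- which(h2$mass > 0)
  p <- h1$mass[keepP]; q <- h2$mass[keepQ]
  cp <- h1$centers[keepP]; cq <- h2$centers[keepQ]
  np <- length(p); nq <- length(q)
  cost <- as.vector(outer(cp, cq, function(a, b) abs(a - b)))
  A3 <- matrix(0, np + nq, np * nq)
  for (i in 1:np) A3[i, ((1:nq) - 1) * np + i] <- 1      # row sums = p
  for (j in 1:nq) A3[np + j, (j - 1) * np + (1:np)] <- 1 # col sums = q
  ## one equality is redundant (both marginals sum to 1): drop it, or the
  ## simplex tableau is rank-deficient
  A3 <- A3[-(np + nq), , drop = FALSE]
  s <- boot::simplex(a = cost, A3 = A3, b3 = c(p, q[-nq]), maxi = FALSE)
  unname(s$value)
}

## Weighted clustering coefficient by exhaustive triple enumeration.
clusteringOracle <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  if (n < 3 || max(A) == 0) return(out)
  W <- A / max(A)
  for (i in 1:n) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      s <- s + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    out[i] <- s / (k * (k - 1) / 2)
  }
  out
}

## Hartigan dip by linear programming: for each candidate mode point p,
## minimize the band halfwidth d subject to gate, monotonicity, convexity-
## through-p and concavity-from-p constraints.  Curvature rows are scaled
## and solutions verified (boot::simplex can return invalid vertices on
## ill-conditioned bases); the sample is standardized first (the dip is
## invariant under increasing affine maps of the data).
dipLpOracle <- function(x, tol = 1e-8) {
  x <- (x - mean(x)) / stats::sd(x)
  n <- length(x)
  xs <- sort(x)
  ux <- unique(xs)
  cnt <- cumsum(tabulate(match(xs, ux), nbins = length(ux)))
  m <- length(ux)
  nv <- m + 1
  row <- function(idx, val) { r <- numeric(nv); r[idx] <- val; r }
  A1 <- NULL; b1 <- NULL; A2b <- NULL; b2b <- NULL
  for (j in 1:m) {
    A2b <- rbind(A2b, row(c(j, nv), c(1, 1))); b2b <- c(b2b, cnt[j] / n)
    prev <- if (j == 1) 0 else cnt[j - 1] / n
    A1 <- rbind(A1, row(c(j, nv), c(1, -1))); b1 <- c(b1, prev)
    A1 <- rbind(A1, row(j, 1)); b1 <- c(b1, 1)
  }
  if (m > 1) for (j in 1:(m - 1)) {
    A2b <- rbind(A2b, row(c(j + 1, j), c(1, -1))); b2b <- c(b2b, 0)
  }
  curvRow <- function(k, sgn) {
    d1 <- ux[k + 1] - ux[k]; d2 <- ux[k + 2] - ux[k + 1]
    r <- numeric(nv)
    r[k] <- sgn / d1; r[k + 1] <- -sgn * (1 / d1 + 1 / d2); r[k + 2] <- sgn / d2
    r / max(abs(r))
  }
  best <- Inf
  obj <- numeric(nv); obj[nv] <- 1
  for (p in 0:m) {
    A2 <- A2b; b2 <- b2b
    if (p >= 3) for (k in 1:(p - 2)) {
      A2 <- rbind(A2, curvRow(k, 1)); b2 <- c(b2, 0)
    }
    if (p <= m - 2) for (k in max(1, p):(m - 2)) {
      A2 <- rbind(A2, curvRow(k, -1)); b2 <- c(b2, 0)
    }
    s <- tryCatch(
      boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                    maxi = FALSE),
      error = function(e) NULL)
    if (is.null(s) || s$solved != 1) next
    sol <- c(s$soln[1:m], s$value)
    if (all(A1 %*% sol <= b1 + tol) && all(A2 %*% sol >= b2 - tol))
      best <- min(best, s$value)
  }
  best
}

## Exact two-sided rank-sum p-value by exhaustive enumeration of all
## assignments of the pooled sample to the two groups.
ranksumEnumOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  ws <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  pLess <- mean(ws <= wObs)
  pGreater <- mean(ws >= wObs)
  min(1, 2 * min(pLess, pGreater))
}

## Window count by brute-force enumeration of candidate starts.
windowCountOracle <- function(nSamples, w, stride) {
  starts <- 0
  count <- 0
  s <- 0
  while (s + w <= nSamples) {
    count <- count + 1
    s <- s + stride
  }
  count
}
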