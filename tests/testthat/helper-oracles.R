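# Independent oracles: deliberately written on different code paths than
# the package (scalar loops, Floyd-Warshall, exhaustive partition
# enumeration, alternative integral representations) so that agreement is
# evidence, not tautology.

# --- Welch cross-spectra: plain segment-by-segment loop, per-channel fft --
oracleCrossSpectra <- function(X, fs, windowS = 2, overlap = 0.5) {
  wl <- round(windowS * fs)
  step <- round(wl * (1 - overlap))
  K <- floor((nrow(X) - wl) / step) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(wl) / wl)
  nf <- wl / 2 + 1
  nch <- ncol(X)
  S <- array(0 + 0i, c(nch, nch, nf))
  for (k in seq_len(K)) {
    idx <- ((k - 1) * step + 1):((k - 1) * step + wl)
    Fk <- matrix(0 + 0i, nf, nch)
    for (ch in seq_len(nch)) {
      seg <- X[idx, ch]
      seg <- (seg - mean(seg)) * w
      Fk[, ch] <- stats::fft(seg)[1:nf]
    }
    for (i in seq_len(nch)) for (j in seq_len(nch))
      S[i, j, ] <- S[i, j, ] + Fk[, i] * Conj(Fk[, j])
  }
  S / (fs * sum(w^2) * K)
}

# --- global efficiency: Floyd-Warshall over 1/w lengths ------------------
oracleEfficiency <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1 / A[A > 0]
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# --- Onnela clustering: explicit triangle enumeration --------------------
oracleOnnela <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      s <- s + (A[i, j] * A[i, h] * A[j, h])^(1 / 3)
    }
    out[i] <- 2 * s / (k * (k - 1))
  }
  out
}

# --- modularity ----------------------------------------------------------
oracleModularityQ <- function(A, membership) {
  m2 <- sum(A)                 # 2m for an undirected graph stored symmetric
  k <- colSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (membership[i] == membership[j])
      q <- q + A[i, j] - k[i] * k[j] / m2
  unname(q / m2)
}

# all partitions of n items (restricted growth strings); n <= 7 only
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxUsed) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(maxUsed + 1))
      rec(c(prefix, v), max(maxUsed, v))
  }
  rec(integer(0), 0L)
  out
}

oracleBestModularity <- function(A) {
  best <- -Inf
  for (p in allPartitions(nrow(A))) {
    q <- oracleModularityQ(A, p)
    if (q > best) best <- q
  }
  best
}

# --- JZS Bayes factor: g-prior representation (two-sided), and a
#     Monte-Carlo prior-sampling estimate ---------------------------------
oracleJzsG <- function(t, n1, n2, width) {
  df <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)
  num <- stats::integrate(function(g)
    (1 + N * g)^(-1 / 2) * (1 + t^2 / ((1 + N * g) * df))^(-(df + 1) / 2) *
      stats::dgamma(1 / g, 1 / 2, rate = width^2 / 2) / g^2,
    0, Inf, rel.tol = 1e-11)$value
  num / (1 + t^2 / df)^(-(df + 1) / 2)
}

oracleJzsMC <- function(t, n1, n2, width, side = "two_sided", nMC = 2e5,
                        seed = 99) {
  set.seed(seed)
  df <- n1 + n2 - 2
  neff <- sqrt(n1 * n2 / (n1 + n2))
  d <- stats::rcauchy(nMC, 0, width)
  if (side == "greater") d <- abs(d)
  lik <- suppressWarnings(stats::dt(t, df, ncp = d * neff))
  list(bf = mean(lik) / stats::dt(t, df),
       se = stats::sd(lik) / sqrt(nMC) / stats::dt(t, df))
}

# --- small graph fixtures -------------------------------------------------
unitTriangleGraph <- function(w3 = 1) {
  A <- symmetricFromUpperTri(c(1, 1, w3), c("a", "b", "c"), diag = 0)
  new("WeightedGraph", adjacency = A,
      meta = list(retainedFraction = 1, normalized = TRUE, nRetained = 3L,
                  ties = FALSE))
}

pathGraph3 <- function() {
  A <- symmetricFromUpperTri(c(1, 0, 1), c("a", "b", "c"), diag = 0)
  new("WeightedGraph", adjacency = A,
      meta = list(retainedFraction = 1, normalized = TRUE, nRetained = 2L,
                  ties = FALSE))
}

twoTrianglesGraph <- function() {
  A <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  A[1, 2] <- A[1, 3] <- A[2, 3] <- 1
  A[4, 5] <- A[4, 6] <- A[5, 6] <- 1
  A <- A + t(A)
  new("WeightedGraph", adjacency = A,
      meta = list(retainedFraction = 1, normalized = TRUE, nRetained = 6L,
                  ties = FALSE))
}

completeUnitGraph <- function(n) {
  A <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(A) <- 0
  new("WeightedGraph", adjacency = A,
      meta = list(retainedFraction = 1, normalized = TRUE,
                  nRetained = as.integer(n * (n - 1) / 2), ties = FALSE))
}

randomNormalizedGraph <- function(n, seed, density = 0.6) {
  set.seed(seed)
  v <- stats::runif(n * (n - 1) / 2)
  v[stats::runif(length(v)) > density] <- 0
  if (all(v == 0)) v[1] <- 0.5
  A <- symmetricFromUpperTri(v / max(v), letters[1:n], diag = 0)
  new("WeightedGraph", adjacency = A,
      meta = list(retainedFraction = 1, normalized = TRUE,
                  nRetained = sum(v > 0), ties = FALSE))
}

# --- tiny connectivity-matrix fixture ------------------------------------
fakeConnectivity <- function(v, labels, band = bandSpec("beta", 13, 29)) {
  new("ConnectivityMatrix", band = band,
      values = symmetricFromUpperTri(v, labels, diag = 1))
}

# shared-source coupled pair built from the package's band-pass primitive,
# mixed by hand (the analytic route the generator is supposed to follow)
coupledPairRecording <- function(a, band, fs = 256, durationS = 240, seed = 1) {
  set.seed(seed)
  n <- round(durationS * fs)
  bl <- function(b, x) {
    y <- zerophaseBandpass(x, b@fLo, b@fHi, fs)
    y / stats::sd(y)
  }
  s <- bl(band, stats::rnorm(n))
  x1 <- a * s + sqrt(1 - a^2) * bl(band, stats::rnorm(n))
  x2 <- a * s + sqrt(1 - a^2) * bl(band, stats::rnorm(n))
  # independent background in the remaining bands, as in the generator
  for (b2 in defaultBands()) {
    if (b2@name == band@name) next
    x1 <- x1 + bl(b2, stats::rnorm(n))
    x2 <- x2 + bl(b2, stats::rnorm(n))
  }
  m <- cbind(x1 = x1, x2 = x2)
  new("SubjectRecording", subjectID = "pair", group = "TD", series = m,
      fs = fs)
}
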