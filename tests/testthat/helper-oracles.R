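# Independent brute-force oracles; deliberately naive so they share no
# code path with the implementation.

# Exact two-sided rank-sum p by exhaustive enumeration of all C(N, n1)
# equally likely assignments of pooled ranks to the first sample.
bruteRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  wObs <- sum(r[seq_len(n1)])
  ws <- utils::combn(length(pooled), n1,
                     FUN = function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= wObs), mean(ws >= wObs)))
}

# Sort-and-scan per-sample statistics, quantiles computed from first
# principles with the type-7 interpolation formula.
naiveQuantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  j <- floor(h)
  g <- h - j
  if (j >= n) v[n] else (1 - g) * v[j] + g * v[j + 1]
}

naiveStats <- function(v, quantiles = c(10, 25, 75, 90)) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0) {
    out <- rep(NA_real_, 5 + length(quantiles))
  } else {
    s <- sum(v)
    m <- s / n
    vr <- if (n < 2) NA_real_ else sum((v - m)^2) / (n - 1)
    sv <- sort(v)
    med <- if (n %% 2 == 1) sv[(n + 1) / 2]
           else (sv[n / 2] + sv[n / 2 + 1]) / 2
    out <- c(m, med, vr, sv[1], sv[n],
             vapply(quantiles / 100, function(p) naiveQuantile(v, p),
                    numeric(1)))
  }
  names(out) <- c("mean", "median", "var", "min", "max",
                  paste0("q", quantiles))
  out
}

# Two-pass Pearson correlation from raw sums.
naivePearson <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# A small deterministic plate built by hand, no generator involved.
handPlate <- function() {
  newRawPlate(
    well = c("A1", "A1", "A1", "B2", "B2", "H12"),
    tof = c(10, 20, 30, 5, 0, 100),
    ext = c(1, 2, 3, 0.5, 7, 50),
    green = c(0.1, 0.2, 0.3, NA, 0.5, 1),
    yellow = 1, red = 2, status = 0L, source = "hand")
}

trainingScenario <- function(seed = 7L) {
  plateScenario(
    organism = list(
      tof = list(dist = "normal", mean = 300, sd = 30),
      ext = list(dist = "normal", mean = 150, sd = 20),
      green = list(dist = "gamma", shape = 4, scale = 10),
      yellow = list(dist = "gamma", shape = 4, scale = 8),
      red = list(dist = "gamma", shape = 4, scale = 6)),
    seed = seed)
}
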