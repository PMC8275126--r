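# Independent oracles: naive reference implementations used to check the
# package's optimized paths. They deliberately share no code with R/.

# naive double-loop time-averaged MSD
oracle_msd <- function(p, max_lag) {
  vapply(seq_len(max_lag), function(l) {
    s <- 0; k <- 0
    for (t in seq_len(nrow(p) - l)) {
      s <- s + sum((p[t + l, ] - p[t, ])^2)
      k <- k + 1
    }
    s / k
  }, numeric(1))
}

# exhaustive valley search of the Minimum method: smooth the 256-bin
# histogram until exactly two strict local maxima remain, then scan every
# bin between them for the smallest count (first on ties)
oracle_minimum_bin <- function(x, nbins = 256L) {
  rng <- range(x)
  b <- pmin(floor((x - rng[1]) / diff(rng) * nbins) + 1L, nbins)
  h <- as.numeric(tabulate(b, nbins))
  # plateau-aware peak scan, written longhand: walk the bins and record
  # each run of equal values that is higher than both neighbouring runs
  peaks_of <- function(h) {
    pk <- integer(0)
    i <- 1L
    prev <- -Inf
    while (i <= nbins) {
      j <- i
      while (j < nbins && h[j + 1L] == h[i]) j <- j + 1L
      nxt <- if (j < nbins) h[j + 1L] else -Inf
      if (h[i] > prev && h[i] > nxt)
        pk <- c(pk, as.integer(floor((i + j) / 2)))
      prev <- h[i]
      i <- j + 1L
    }
    pk
  }
  it <- 0L
  while (length(peaks_of(h)) != 2L) {
    if (it > 10000L || length(peaks_of(h)) < 2L) return(NA_integer_)
    h <- (c(h[1], h[-nbins]) + h + c(h[-1], h[nbins])) / 3
    it <- it + 1L
  }
  pk <- peaks_of(h)
  best <- pk[1]; bestv <- h[pk[1]]
  for (i in pk[1]:pk[2]) if (h[i] < bestv) { best <- i; bestv <- h[i] }
  best
}

# reference greedy matcher: literal distance-sorted acceptance loop
oracle_greedy <- function(A, B, gate) {
  m <- rep(NA_integer_, nrow(A))
  if (!nrow(A) || !nrow(B)) return(m)
  d <- as.matrix(dist(rbind(A, B)))[seq_len(nrow(A)), nrow(A) + seq_len(nrow(B)), drop = FALSE]
  cand <- which(d <= gate, arr.ind = TRUE)
  if (!nrow(cand)) return(m)
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used_j <- logical(nrow(B))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (is.na(m[i]) && !used_j[j]) { m[i] <- j; used_j[j] <- TRUE }
  }
  m
}

# brute-force optimal full assignment (minimum total distance over all
# permutations, links within the gate); valid when nA == nB <= 8 and a
# complete matching exists
oracle_optimal_match <- function(A, B, gate) {
  n <- nrow(A)
  stopifnot(n == nrow(B), n <= 8L)
  d <- as.matrix(dist(rbind(A, B)))[seq_len(n), n + seq_len(n), drop = FALSE]
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    dd <- d[cbind(seq_len(n), p)]
    if (all(dd <= gate) && sum(dd) < best_cost) { best_cost <- sum(dd); best <- p }
  }
  best
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
oracle_mwu_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_min <- min(u_obs, n1 * n2 - u_obs)
  idx <- combn(n1 + n2, n1)
  us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(pmin(us, n1 * n2 - us) <= u_min)
}
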