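# Independent oracles used across the suite: deliberately naive
# implementations (double loops, direct sums) kept separate from the code
# paths they check.

# random proper rotation matrix (uses the current RNG state)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

bruteRg <- function(frame, w = rep(1, nrow(frame))) {
  com <- c(sum(w * frame[, 1]), sum(w * frame[, 2]), sum(w * frame[, 3])) / sum(w)
  s <- 0
  for (i in seq_len(nrow(frame)))
    s <- s + w[i] * sum((frame[i, ] - com)^2)
  sqrt(s / sum(w))
}

bruteSwitch <- function(r, r0, n, m) {
  x <- r / r0
  if (abs(x - 1) < 1e-12) return(n / m)
  (1 - x^n) / (1 - x^m)
}

bruteContact <- function(frame, r0, n, m, excl) {
  total <- 0
  nb <- nrow(frame)
  for (i in seq_len(nb))
    for (j in seq_len(nb))
      if (j > i && j - i >= excl)
        total <- total + bruteSwitch(sqrt(sum((frame[i, ] - frame[j, ])^2)),
                                     r0, n, m)
  total
}

bruteBiasEnergy <- function(state, s, t = Inf) {
  V <- 0
  for (k in seq_len(nHills(state))) {
    if (state@times[k] > t) next
    V <- V + state@heights[k] *
      exp(-sum((s - state@centers[k, ])^2 / (2 * state@widths[k, ]^2)))
  }
  V
}

# leader clustering oracle on a precomputed distance matrix, with the same
# tie rule (lowest index wins)
bruteLeader <- function(D, w, cutoff) {
  n <- nrow(D)
  active <- seq_len(n)
  assign <- integer(n)
  pops <- numeric(0)
  cl <- 0L
  while (length(active)) {
    counts <- vapply(active, function(i) sum(D[i, active] <= cutoff), 0)
    centre <- active[which.max(counts)]
    members <- active[D[centre, active] <= cutoff]
    members <- union(centre, members)
    cl <- cl + 1L
    assign[members] <- cl
    pops <- c(pops, sum(w[members]))
    active <- setdiff(active, members)
  }
  list(assignment = assign, weights = pops)
}

bruteKabschRMSD <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  sv <- svd(t(P) %*% Q)
  d <- sign(det(sv$v %*% t(sv$u)))
  tr <- sv$d[1] + sv$d[2] + d * sv$d[3]
  sqrt(max(0, (sum(P^2) + sum(Q^2) - 2 * tr) / nrow(P)))
}

randomPeptideString <- function(n, phosphoProb = 0) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  res <- sample(aa, n, replace = TRUE)
  out <- res
  can <- which(res %in% c("S", "T", "Y"))
  if (phosphoProb > 0 && length(can)) {
    hit <- can[runif(length(can)) < phosphoProb]
    out[hit] <- paste0("{p", res[hit], "}")
  }
  paste(out, collapse = "")
}

segmentText <- "APNSTPIVSTAATGLQHKGKGTQAKII"
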