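# Independent oracles and small fixture builders used across the suite.

# All permutations of 1..n (n <= 7)
permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))))
}

# Brute-force square assignment: minimal total cost over all permutations
bruteAssignmentCost <- function(cost) {
  n <- nrow(cost)
  perms <- permutationsOf(n)
  min(apply(perms, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
}

# Brute-force frame-pair linking objective: over all partial matchings of
# n1 source to n2 target spots (only admissible pairs), total cost =
# sum(link costs) + alt * (#unmatched sources + #unmatched targets).
bruteLinkCost <- function(d2, maxDist, alt) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  adm <- d2 <= maxDist^2
  best <- Inf
  rec <- function(i, usedCols, acc) {
    if (acc >= best) return()
    if (i > n1) {
      best <<- min(best, acc + alt * sum(!usedCols))
      return()
    }
    rec(i + 1L, usedCols, acc + alt)           # source i dies
    for (j in which(!usedCols & adm[i, ])) {
      usedCols[j] <- TRUE
      rec(i + 1L, usedCols, acc + d2[i, j])
      usedCols[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, n2), 0)
  best
}

# Achieved objective of .linkFramePair's solution under the same cost rule
achievedLinkCost <- function(d2, link, alt) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  linked <- !is.na(link)
  sum(d2[cbind(which(linked), link[linked])]) +
    alt * (sum(!linked) + (n2 - sum(linked)))
}

# Closed-form Gompertz through three equally spaced noiseless points
gompertz3pt <- function(t, y) {
  stopifnot(length(t) == 3L, abs(diff(diff(t))) < 1e-12)
  z <- log(y)
  dt <- t[2] - t[1]
  q <- (z[2] - z[3]) / (z[1] - z[2])     # = exp(-c dt)
  cc <- -log(q) / dt
  b <- (z[1] - z[2]) / (exp(-cc * t[1]) * (q - 1))
  a <- exp(z[1] + b * exp(-cc * t[1]))
  c(a = a, b = b, c = cc)
}

# Brute-force ANCOVA oracle: explicit design matrices and the
# extra-sum-of-squares F for the group factor.
bruteAncova <- function(y, group, x) {
  g <- factor(group)
  G <- model.matrix(~ g)
  Xfull <- cbind(G, x)
  Xred <- cbind(1, x)
  rssOf <- function(X) {
    beta <- qr.solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  rssF <- rssOf(Xfull); rssR <- rssOf(Xred)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - ncol(Xfull)
  F <- ((rssR - rssF) / df1) / (rssF / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE),
       beta = qr.solve(crossprod(Xfull), crossprod(Xfull, y))[ncol(Xfull)])
}

# Paint hard-edged disks onto a constant background (no noise, no
# anti-aliasing) -- an independent fixture builder for segmentation and
# detection tests.
paintDisks <- function(fieldPx, centers, radii, fg = 100, bg = 2) {
  img <- matrix(bg, fieldPx, fieldPx)
  for (i in seq_len(nrow(centers))) {
    rr <- seq_len(fieldPx)
    d2 <- outer((rr - centers[i, 1])^2, (rr - centers[i, 2])^2, `+`)
    img[d2 <= radii[i]^2] <- fg
  }
  img
}

# Synthetic spot tables (one data.frame per frame) from per-frame centers
spotsFromCenters <- function(centerList) {
  lapply(centerList, function(m) {
    if (is.null(m) || !nrow(m))
      data.frame(row = numeric(0), col = numeric(0), response = numeric(0))
    else
      data.frame(row = m[, 1], col = m[, 2], response = 1)
  })
}
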