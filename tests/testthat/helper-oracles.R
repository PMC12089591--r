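## Independent brute-force reimplementations of the statistical primitives,
## written from their textbook definitions. The package routes the same
## operations through stats::p.adjust / closed-form vector algebra; these
## oracles deliberately use naive loops so agreement is a genuine dual route.

bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  ## step-up: enforce monotonicity from the largest p downwards
  for (k in (m - 1):1) if (m > 1) ranked[k] <- min(ranked[k], ranked[k + 1])
  adj <- numeric(m)
  adj[o] <- pmin(ranked, 1)
  adj
}

bruteHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- (m - seq_len(m) + 1) * p[o]
  ## step-down: enforce monotonicity from the smallest p upwards
  for (k in seq_len(m)[-1]) ranked[k] <- max(ranked[k], ranked[k - 1])
  adj <- numeric(m)
  adj[o] <- pmin(ranked, 1)
  adj
}

brutePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  r <- sxy / sqrt(sxx * syy)
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(tt, n - 2, lower.tail = FALSE))
}

bruteConfusion <- function(predicted, actual, med) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(actual)) {
    a <- actual[i] > med
    p <- predicted[i] > med
    if (p && a) tp <- tp + 1
    if (p && !a) fp <- fp + 1
    if (!p && !a) tn <- tn + 1
    if (!p && a) fn <- fn + 1
  }
  acc <- (tp + tn) / length(actual)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

bruteMse <- function(predicted, actual) {
  s <- 0
  for (i in seq_along(actual)) s <- s + (predicted[i] - actual[i])^2
  s / length(actual)
}

bruteDilate <- function(mask, connectivity = 6) {
  d <- dim(mask)
  out <- mask
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] != 1) next
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      dist <- abs(dx) + abs(dy) + abs(dz)
      keep <- switch(as.character(connectivity),
                     "6" = dist == 1,
                     "18" = dist >= 1 && dist <= 2,
                     "26" = dist >= 1)
      if (!keep) next
      nx <- x + dx; ny <- y + dy; nz <- z + dz
      if (nx >= 1 && nx <= d[1] && ny >= 1 && ny <= d[2] &&
          nz >= 1 && nz <= d[3]) out[nx, ny, nz] <- 1
    }
  }
  out
}
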