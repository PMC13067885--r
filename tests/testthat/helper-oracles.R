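# Independent brute-force oracles, deliberately separate from the package's
# metric engine: plain-R BFS distances, direct-formula efficiencies,
# triangle-count clustering, and classical contrast/adjustment formulas.

oracleDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (src in seq_len(n)) {
    d[src, src] <- 0
    frontier <- src
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (!is.finite(d[src, v])) {
            d[src, v] <- depth
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

oracleGlobalEff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracleDistances(adj)
  tot <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) tot <- tot + 1 / d[i, j]
    }
  }
  tot / (n * (n - 1))
}

oracleNodalEff <- function(adj) {
  n <- nrow(adj)
  d <- oracleDistances(adj)
  sapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(d[i, j])) s <- s + 1 / d[i, j]
    s / (n - 1)
  })
}

oracleLocalEff <- function(adj) {
  n <- nrow(adj)
  vals <- sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracleGlobalEff(adj[nb, nb, drop = FALSE])
  })
  mean(vals)
}

oracleClusteringVec <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) if (adj[nb[u], nb[v]] > 0) tri <- tri + 1
    }
    2 * tri / (k * (k - 1))
  })
}

oraclePathLength <- function(adj) {
  d <- oracleDistances(adj)
  vals <- d[row(d) != col(d)]
  mean(vals[is.finite(vals)])
}

randomConnectedGraph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    a <- matrix(0L, n, n)
    up <- which(upper.tri(a))
    a[up] <- as.integer(runif(length(up)) < p)
    a <- a + t(a)
    d <- oracleDistances(a)
    if (all(is.finite(d))) return(a)
  }
}

# Benjamini-Hochberg by explicit step-up
oracleFdrBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[ord[k]] * m / k)
    adj[ord[k]] <- val
    prev <- val
  }
  adj
}

# vectors with an exact prescribed sample correlation
vectorsWithSampleR <- function(n, r, seed) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  xs <- (x - mean(x)) / sd(x)
  es <- (e - mean(e)) / sd(e)
  list(x = xs, y = r * xs + sqrt(1 - r^2) * es)
}

# mixed 2x2 ANOVA oracle for balanced designs via equivalent t statistics:
# interaction = pooled two-sample t^2 on within-subject difference scores,
# group = pooled two-sample t^2 on subject means, condition = paired t^2
oracleMixedF <- function(data) {
  data$participant <- factor(data$participant)
  wide <- reshape(data[, c("participant", "group", "condition", "value")],
    idvar = c("participant", "group"), timevar = "condition",
    direction = "wide"
  )
  v <- as.matrix(wide[, 3:4])
  diffs <- v[, 1] - v[, 2]
  means <- rowMeans(v)
  g <- factor(wide$group)
  tInt <- t.test(diffs ~ g, var.equal = TRUE)$statistic
  tGrp <- t.test(means ~ g, var.equal = TRUE)$statistic
  # condition F from the difference scores with group-centred error:
  # SS_cond = N dbar^2 / 2 against the condition-by-subject error
  nTot <- length(diffs)
  dbar <- mean(diffs)
  dg <- ave(diffs, g)
  fCond <- nTot * dbar^2 * (nTot - 2) / sum((diffs - dg)^2)
  c(
    interaction = unname(tInt)^2, group = unname(tGrp)^2,
    condition = unname(fCond)
  )
}

smallCopTrial <- function(ml, ap, fs = 100) {
  copTrial(ml, ap, samplingRate = fs)
}
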