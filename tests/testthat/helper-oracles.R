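# Independent oracles used to pin expected values. These deliberately use
# different algorithms from the package implementation.

# Exhaustive search over every CHO composition within the element bounds
# (C 1..90, H 0..190, O 0..90): the ground truth for formula enumeration.
.ORACLE_MASSES <- local({
  grid <- expand.grid(H = 0:190, O = 0:90)
  grid_mass <- grid$H * 1.0078250319 + grid$O * 15.9949146221
  list(grid = grid, grid_mass = grid_mass)
})

oracleEnumerate <- function(query_mass, tol_ppm = 5, rdbe_bounds = c(0, 40)) {
  lo <- query_mass * (1 - tol_ppm * 1e-6)
  hi <- query_mass * (1 + tol_ppm * 1e-6)
  out <- list()
  for (nc in 1:90) {
    m <- 12 * nc + .ORACLE_MASSES$grid_mass
    hit <- which(m >= lo & m <= hi)
    if (!length(hit)) next
    h <- .ORACLE_MASSES$grid$H[hit]
    o <- .ORACLE_MASSES$grid$O[hit]
    r <- nc - h / 2 + 1
    ok <- r >= rdbe_bounds[1] & r <= rdbe_bounds[2]
    if (any(ok))
      out[[length(out) + 1]] <- data.frame(n_C = nc, n_H = h[ok], n_O = o[ok])
  }
  if (!length(out)) return(data.frame(n_C = integer(), n_H = integer(),
                                      n_O = integer()))
  do.call(rbind, out)
}

# Textbook pooled-variance two-sample t-test, written out by hand.
pooledTP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), df = n1 + n2 - 2)
}

# Monte-Carlo permutation test on the absolute mean difference (equivalent
# to permuting the pooled-t statistic, which is monotone in it). Group-1
# subsets are drawn by vectorised sequential sampling so B can be large.
permP <- function(x, y, B = 1e5) {
  z <- c(x, y)
  n <- length(z); n1 <- length(x)
  d_obs <- abs(mean(x) - mean(y))
  s1 <- numeric(B)
  need <- rep(n1, B)
  remaining <- n
  for (i in seq_len(n)) {
    p_take <- need / remaining
    take <- runif(B) < p_take
    s1 <- s1 + z[i] * take
    need <- need - take
    remaining <- remaining - 1
  }
  d_perm <- abs(s1 / n1 - (sum(z) - s1) / (n - n1))
  mean(d_perm >= d_obs - 1e-12)
}

# Exact permutation p over all group-1 subsets (small n only).
exactPermP <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  d_obs <- abs(mean(x) - mean(y))
  combos <- combn(length(z), n1)
  d <- apply(combos, 2, function(ix)
    abs(mean(z[ix]) - mean(z[-ix])))
  mean(d >= d_obs - 1e-12)
}
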