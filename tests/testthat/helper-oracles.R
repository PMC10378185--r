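# Independent oracles used to cross-check the package implementations.
# These deliberately use naive, direct formulations.

# fixed-step classical RK4 integrator
rk4_fixed <- function(f, y0, t_end, dt) {
  t <- 0
  y <- y0
  n_steps <- ceiling(t_end / dt)
  dt <- t_end / n_steps
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  y
}

# brute-force recovery-curve area for one cell: enumerate x = 1..n_top,
# count gene-set members among the top x genes, sum, normalize by the
# ideal staircase
auc_oracle <- function(values, members, top_fraction) {
  G <- length(values)
  n_top <- ceiling(top_fraction * G)
  ranking <- names(sort(values, decreasing = TRUE))  # assumes no ties
  hits <- 0
  area <- 0
  for (x in seq_len(n_top)) {
    if (ranking[x] %in% members) hits <- hits + 1
    area <- area + hits
  }
  m <- sum(members %in% names(values))
  ideal <- sum(pmin(seq_len(n_top), m))
  area / ideal
}

# ordinary least squares via explicit normal equations (X'X)^-1 X'y
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# pooled-variance two-sample Student t-test, two-sided
ttest_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Benjamini-Hochberg step-up by direct min-over-tail computation
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # rank of p[i] among sorted values
    tail_vals <- vapply(rank_i:m, function(j) p[ord[j]] * m / j, 0)
    adj[i] <- min(1, min(tail_vals))
  }
  adj
}

# median by explicit sort-and-middle
median_oracle <- function(x) {
  s <- unname(sort(x))
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# serial-passage loop driven by the fixed-step RK4 oracle
passage_oracle <- function(r, K, density, interval, n_passages, freqs,
                           area = 25, dt = 1e-3) {
  seed_total <- density * area
  state <- seed_total * freqs
  sizes <- matrix(NA_real_, n_passages, length(r))
  fmat <- sizes
  rhs <- function(t, y) y * r * (1 - sum(y / K))
  for (p in seq_len(n_passages)) {
    state <- rk4_fixed(rhs, state, interval, dt)
    sizes[p, ] <- state
    fmat[p, ] <- state / sum(state)
    state <- seed_total * fmat[p, ]
  }
  list(sizes = sizes, frequencies = fmat)
}

# quick constructor for a biomarker_fit-shaped object (tie-rule tests)
fake_biomarker <- function(pathway, adj_r2, p_value, target = "r",
                           grouping = "all") {
  structure(list(pathway = pathway, target = target, grouping = grouping,
                 slope = 1, intercept = 0, pearson = sqrt(max(adj_r2, 0)),
                 r2 = adj_r2, adj_r2 = adj_r2, p_value = p_value,
                 fdr = NA_real_, n = 5, degenerate = FALSE),
            class = "biomarker_fit")
}
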