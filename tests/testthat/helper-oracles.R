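# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: the effect oracle solves the saturated linear
# system with explicit constraint rows, ANOVA oracles go through stats::aov,
# and group means through a plain split/apply.

# Constrained least-squares fit of x_ij = u + g_i + g_j + s_ij on a symmetric
# entry-mean table, with constraints sum_i g_i = 0 and, for each i,
# sum_j s_ij + s_ii = 0. The model is saturated (66 equations, 78 unknowns,
# 12 constraints), so the combined square system has a unique exact solution.
oracle_constrained_ls <- function(x) {
  p <- nrow(x)
  idx <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- nrow(idx)
  npar <- 1L + p + n                    # u, g_1..g_p, s_(i<=j)
  scol <- function(i, j) 1L + p + which(idx[, 1] == min(i, j) &
                                          idx[, 2] == max(i, j))
  A <- matrix(0, n + 1L + p, npar)
  b <- numeric(n + 1L + p)
  for (k in seq_len(n)) {
    i <- idx[k, 1]; j <- idx[k, 2]
    A[k, 1L] <- 1
    A[k, 1L + i] <- A[k, 1L + i] + 1
    A[k, 1L + j] <- A[k, 1L + j] + 1
    A[k, scol(i, j)] <- 1
    b[k] <- x[i, j]
  }
  A[n + 1L, 2:(p + 1L)] <- 1            # sum g = 0
  for (i in seq_len(p)) {               # sum_j s_ij + s_ii = 0
    row <- n + 1L + i
    for (j in seq_len(p)) A[row, scol(i, j)] <- A[row, scol(i, j)] + 1
    A[row, scol(i, i)] <- A[row, scol(i, i)] + 1
  }
  theta <- qr.solve(A, b)
  s <- matrix(0, p, p)
  for (k in seq_len(n)) {
    s[idx[k, 1], idx[k, 2]] <- s[idx[k, 2], idx[k, 1]] <- theta[1L + p + k]
  }
  list(mu = theta[1L], gca = theta[2:(p + 1L)], sca = s)
}

# brute-force per-entry group means of one env/trait subset
oracle_group_means <- function(plots, environment, trait) {
  sub <- plots[plots$environment == environment & plots$trait == trait, ]
  key <- paste(sub$parent_a, sub$parent_b)
  vapply(split(sub$value, key), mean, numeric(1))
}

# RCBD SS via stats::aov
oracle_rcbd_ss <- function(plots, environment, trait) {
  sub <- plots[plots$environment == environment & plots$trait == trait, ]
  sub$entry <- factor(paste(sub$parent_a, sub$parent_b))
  sub$rep <- factor(sub$replicate)
  a <- stats::anova(stats::aov(value ~ rep + entry, data = sub))
  stats::setNames(a[["Sum Sq"]], rownames(a))
}

# combined ANOVA SS via stats::aov
oracle_combined_ss <- function(plots, trait) {
  sub <- plots[plots$trait == trait, ]
  sub$entry <- factor(paste(sub$parent_a, sub$parent_b))
  sub$env <- factor(sub$environment)
  sub$rep <- factor(sub$replicate)
  a <- stats::anova(stats::aov(value ~ env + env:rep + entry + entry:env,
                               data = sub))
  stats::setNames(a[["Sum Sq"]], trimws(rownames(a)))
}

# random symmetric entry-mean table
random_diallel_table <- function(p, seed) {
  set.seed(seed)
  m <- matrix(0, p, p)
  ut <- upper.tri(m, diag = TRUE)
  m[ut] <- rnorm(sum(ut), 10, 3)
  m <- m + t(m) - diag(diag(m))
  diallel_table(m, trait = "T", environment = "e1", r = 2L)
}

# reference-shaped long data frame for IO tests (p parents, values arbitrary)
make_plot_df <- function(p = 3, envs = "e1", reps = c("r1", "r2"),
                         trait = "FY",
                         value_fun = function(n) as.numeric(seq_len(n))) {
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  grid <- expand.grid(k = seq_len(nrow(idx)), rep = reps, env = envs,
                      stringsAsFactors = FALSE)
  data.frame(environment = grid$env, replicate = grid$rep,
             parent_a = paste0("P", idx[grid$k, 1]),
             parent_b = paste0("P", idx[grid$k, 2]),
             trait = trait, value = value_fun(nrow(grid)),
             stringsAsFactors = FALSE)
}
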