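test_that("estimate_effects recovers additive and constant toy tables", {
  # additive: x_ij = 10 + a_i + a_j with a = (1, 0, -1)
  a <- c(1, 0, -1)
  x <- 10 + outer(a, a, "+")
  eff <- estimate_effects(diallel_table(x))
  expect_equal(eff$mu_hat, 10)
  expect_equal(eff$gca, a)
  expect_equal(eff$sca, matrix(0, 3, 3))

  # constant table
  effc <- estimate_effects(diallel_table(matrix(7, 4, 4)))
  expect_equal(effc$mu_hat, 7)
  expect_equal(effc$gca, rep(0, 4))
  expect_equal(effc$sca, matrix(0, 4, 4))
})

test_that("effects equal the constrained least-squares oracle", {
  for (case in list(c(p = 3, seed = 11), c(p = 4, seed = 12),
                    c(p = 5, seed = 13), c(p = 6, seed = 14))) {
    tab <- random_diallel_table(case["p"], case["seed"])
    eff <- estimate_effects(tab)
    ora <- oracle_constrained_ls(unclass(tab))
    expect_equal(eff$mu_hat, ora$mu, tolerance = 1e-9)
    expect_equal(eff$gca, ora$gca, tolerance = 1e-9)
    expect_equal(eff$sca, ora$sca, tolerance = 1e-9)
  }
})

test_that("Griffing invariants: sum-zero GCA, exact reconstruction, permutation equivariance", {
  for (seed in 1:5) {
    p <- sample(3:8, 1)
    tab <- random_diallel_table(p, seed + 100)
    eff <- estimate_effects(tab)
    expect_lt(abs(sum(eff$gca)), 1e-10)
    recon <- eff$mu_hat + outer(eff$gca, eff$gca, "+") + eff$sca
    expect_equal(recon, matrix(as.numeric(tab), p), tolerance = 1e-10)

    # permutation equivariance
    perm <- sample(p)
    xp <- unclass(tab)[perm, perm]
    effp <- estimate_effects(diallel_table(xp))
    expect_equal(effp$gca, eff$gca[perm], tolerance = 1e-10)
    expect_equal(effp$sca, eff$sca[perm, perm], tolerance = 1e-10)
  }
  expect_error(estimate_effects(matrix(1, 2, 2)), "p >= 3")
  m <- matrix(rnorm(16), 4, 4)
  expect_error(estimate_effects(m), "symmetric")
})

test_that("genotype SS partition is additive and matches the aov oracle", {
  # additive, noise-free data -> SS_SCA = 0
  a <- c(2, 1, 0, -1, -2)
  x <- 30 + outer(a, a, "+")
  df <- make_plot_df(p = 5, value_fun = function(n) NA_real_)
  for (k in seq_len(nrow(df))) {
    i <- as.integer(sub("P", "", df$parent_a[k]))
    j <- as.integer(sub("P", "", df$parent_b[k]))
    df$value[k] <- x[i, j]
  }
  part <- partition_genotype_ss(plot_table(df), "e1", "FY")
  expect_equal(part$ss_sca, 0, tolerance = 1e-10)
  expect_equal(part$df_gca, 4L)
  expect_equal(part$df_sca, 10L)

  # constant data -> both zero
  dfc <- make_plot_df(p = 4, value_fun = function(n) rep(5, n))
  pc <- partition_genotype_ss(plot_table(dfc), "e1", "FY")
  expect_equal(pc$ss_gca + pc$ss_sca, 0, tolerance = 1e-12)

  # random data -> SS_GCA + SS_SCA = genotype SS from an independent
  # decomposition, both non-negative
  set.seed(99)
  dfr <- make_plot_df(p = 5, value_fun = function(n) rnorm(n, 20, 4))
  pt <- plot_table(dfr)
  part <- partition_genotype_ss(pt, "e1", "FY")
  ss <- oracle_rcbd_ss(pt, "e1", "FY")
  expect_gte(part$ss_gca, 0)
  expect_gte(part$ss_sca, 0)
  expect_equal(part$ss_gca + part$ss_sca, unname(ss["entry"]),
               tolerance = 1e-8)
})

test_that("effect-contrast LSDs reproduce the printed reference values", {
  # 11-parent trial, FY non-saline: MS_error 19.54, r = 2, df = 65
  gca <- lsd_effect_contrast("gca_pair", 19.54, r = 2, p = 11,
                             df_error = 65, alpha = 0.05)
  hs <- lsd_effect_contrast("sca_halfsib", 19.54, 2, 11, 65, 0.05)
  dj <- lsd_effect_contrast("sca_disjoint", 19.54, 2, 11, 65, 0.05)
  expect_equal(round(gca$value, 2), 2.45)
  expect_equal(round(hs$value, 2), 8.48)
  expect_equal(round(dj$value, 2), 8.12)
  expect_error(lsd_effect_contrast("gca_pair", -1, 2, 11, 65), "domain")
})

test_that("contrast variances agree with numeric coefficient-vector variances", {
  # Var(g_i - g_j), Var(s_ij - s_ik), Var(s_ij - s_kl) derived numerically
  # from the estimator's linear map must match the closed forms used in
  # lsd_effect_contrast (in units of sigma2_e').
  for (p in c(4, 6, 11)) {
    idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    n <- nrow(idx)
    # effect of a unit bump in entry k on g_i and s_ij
    unit_fit <- function(k) {
      x <- matrix(0, p, p)
      x[idx[k, 1], idx[k, 2]] <- x[idx[k, 2], idx[k, 1]] <- 1
      estimate_effects(diallel_table(x))
    }
    fits <- lapply(seq_len(n), unit_fit)
    var_of <- function(extract) {
      sum(vapply(fits, extract, numeric(1))^2)
    }
    v_g <- var_of(function(f) f$gca[1] - f$gca[2])
    v_hs <- var_of(function(f) f$sca[1, 2] - f$sca[1, 3])
    v_dj <- var_of(function(f) f$sca[1, 2] - f$sca[3, 4])
    expect_equal(v_g, 2 / (p + 2), tolerance = 1e-10)
    expect_equal(v_hs, 2 * (p + 1) / (p + 2), tolerance = 1e-10)
    expect_equal(v_dj, 2 * p / (p + 2), tolerance = 1e-10)
  }
})

test_that("effect stars use Method-2 effect variances and flag large effects", {
  # additive table with one big GCA effect and tiny error
  a <- c(5, 0, 0, 0, -5)
  x <- 50 + outer(a, a, "+")
  eff <- estimate_effects(diallel_table(x), ms_error = 0.01, r = 2,
                          df_error = 20)
  expect_equal(eff$star_gca[1], "**")
  expect_equal(eff$star_gca[3], "ns")
  expect_true(all(eff$star_sca == "ns"))
  expect_equal(length(eff$se_gca), 1L)      # equal SE across parents
  expect_true(eff$se_sca_hybrid > eff$se_gca)
})
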