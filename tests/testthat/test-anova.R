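test_that("rcbd_anova has design df and matches the aov oracle", {
  set.seed(7)
  df <- make_plot_df(p = 4, reps = c("r1", "r2", "r3"),
                     value_fun = function(n) rnorm(n, 25, 4))
  pt <- plot_table(df)
  an <- rcbd_anova(pt, "e1", "FY")
  expect_equal(an$df, c(2L, 9L, 18L))
  ss <- oracle_rcbd_ss(pt, "e1", "FY")
  expect_equal(an$SS[an$source == "Replicate"], unname(ss["rep"]),
               tolerance = 1e-8)
  expect_equal(an$SS[an$source == "Genotype"], unname(ss["entry"]),
               tolerance = 1e-8)
  expect_equal(an$SS[an$source == "Error"], unname(ss["Residuals"]),
               tolerance = 1e-8)
  expect_equal(an$MS, an$SS / an$df)
  expect_equal(attr(an, "r_squared"),
               1 - an$SS[3] / sum(an$SS), tolerance = 1e-10)

  # reference 11-parent design df
  df11 <- make_plot_df(p = 11, value_fun = function(n) rnorm(n))
  an11 <- rcbd_anova(plot_table(df11), "e1", "FY")
  expect_equal(an11$df, c(1L, 65L, 65L))

  # identical replicates -> zero error SS and CV
  dfi <- make_plot_df(p = 3, value_fun = function(n) rep(rnorm(n / 2, 10), 2))
  dfi$value <- ave(dfi$value, paste(dfi$parent_a, dfi$parent_b),
                   FUN = function(v) v[1])
  ani <- rcbd_anova(plot_table(dfi), "e1", "FY")
  expect_equal(ani$SS[ani$source == "Error"], 0, tolerance = 1e-18)
  expect_equal(attr(ani, "cv_percent"), 0, tolerance = 1e-9)
})

test_that("combined_anova reproduces the reference-design df vector and aov SS", {
  cfg <- sim_config(p = 11, r = 2, environments = c("ns", "sa"),
                    grand_mean = 40, var_gca = 20, var_sca = 60,
                    var_env = 30, var_gca_env = 2, var_sca_env = 5,
                    var_rep = 1, var_error = 19, seed = 21, trait = "FY")
  pt <- simulate_diallel(cfg)$plots
  ca <- combined_anova(pt, "FY")
  expect_equal(ca$source,
               c("Environment", "Rep(Environment)", "Genotype", "GCA", "SCA",
                 "Genotype x Env", "GCA x Env", "SCA x Env", "Residual"))
  expect_equal(ca$df, c(1L, 2L, 65L, 10L, 55L, 65L, 10L, 55L, 130L))
  ss <- oracle_combined_ss(pt, "FY")
  expect_equal(ca$SS[ca$source == "Environment"], unname(ss["env"]),
               tolerance = 1e-8)
  expect_equal(ca$SS[ca$source == "Genotype"], unname(ss["entry"]),
               tolerance = 1e-8)
  expect_equal(ca$SS[ca$source == "Rep(Environment)"], unname(ss["env:rep"]),
               tolerance = 1e-8)
  expect_equal(ca$SS[ca$source == "Genotype x Env"], unname(ss["env:entry"]),
               tolerance = 1e-8)
  expect_equal(ca$SS[ca$source == "Residual"], unname(ss["Residuals"]),
               tolerance = 1e-8)
  expect_error(combined_anova(pt[pt$environment == "ns", ], "FY"),
               "rcbd_anova")
})

test_that("combined partitions are additive and pooling-consistent", {
  cfg <- sim_config(p = 6, r = 3, environments = c("e1", "e2", "e3"),
                    grand_mean = 15, var_gca = 4, var_sca = 2, var_env = 3,
                    var_gca_env = 1, var_sca_env = 1, var_rep = 0.5,
                    var_error = 2, seed = 31, trait = "T")
  pt <- simulate_diallel(cfg)$plots
  ca <- combined_anova(pt, "T")
  pick <- function(s) ca$SS[ca$source == s]
  expect_equal(pick("Genotype"), pick("GCA") + pick("SCA"), tolerance = 1e-8)
  expect_equal(pick("Genotype x Env"), pick("GCA x Env") + pick("SCA x Env"),
               tolerance = 1e-8)
  base_rows <- c("Environment", "Rep(Environment)", "Genotype",
                 "Genotype x Env", "Residual")
  expect_equal(sum(vapply(base_rows, pick, numeric(1))),
               sum((pt$value[pt$trait == "T"] -
                      mean(pt$value[pt$trait == "T"]))^2),
               tolerance = 1e-8)
  # pooled residual = sum of per-env error SS
  per_env <- vapply(cfg$environments, function(e) {
    an <- rcbd_anova(pt, e, "T")
    an$SS[an$source == "Error"]
  }, numeric(1))
  expect_equal(pick("Residual"), sum(per_env), tolerance = 1e-8)
})

test_that("ANOVA is scale-equivariant", {
  cfg <- sim_config(p = 5, r = 2, environments = c("e1", "e2"),
                    grand_mean = 10, var_gca = 2, var_sca = 1, var_env = 1,
                    var_error = 1, seed = 41, trait = "T")
  pt <- simulate_diallel(cfg)$plots
  ca1 <- combined_anova(pt, "T")
  pt2 <- pt
  pt2$value <- pt$value * 3
  ca2 <- combined_anova(pt2, "T")
  expect_equal(ca2$SS, 9 * ca1$SS, tolerance = 1e-10)
  expect_equal(ca2$F, ca1$F, tolerance = 1e-10)
  expect_equal(ca2$p_value, ca1$p_value, tolerance = 1e-10)
  expect_equal(attr(ca2, "cv_percent"), attr(ca1, "cv_percent"),
               tolerance = 1e-10)
  expect_equal(attr(ca2, "r_squared"), attr(ca1, "r_squared"),
               tolerance = 1e-10)
})

test_that("significance_stars applies the quoted thresholds", {
  expect_equal(significance_stars(c(0.049, 0.009, 0.2, 0.05, 0.01)),
               c("*", "**", "ns", "ns", "*"))
  expect_error(significance_stars(1.2))
})
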