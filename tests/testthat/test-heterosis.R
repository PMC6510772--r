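test_that("heterosis percentages: boundary cases and scale invariance", {
  expect_equal(heterosis(10, 8, 12)$heterosis_pct, 0)       # f1 = MP
  expect_equal(heterosis(12, 8, 12)$heterobeltiosis_pct, 0) # f1 = BP
  h <- heterosis(12, 10, 10)
  expect_equal(h$heterosis_pct, 20)
  expect_equal(h$heterobeltiosis_pct, 20)
  # zero reference -> NA
  expect_true(is.na(heterosis(5, 2, -2)$heterosis_pct))
  # scale invariance
  for (seed in 1:10) {
    set.seed(seed)
    v <- runif(3, 1, 50)
    h1 <- heterosis(v[1], v[2], v[3])
    h2 <- heterosis(7 * v[1], 7 * v[2], 7 * v[3])
    expect_equal(h1$heterosis_pct, h2$heterosis_pct, tolerance = 1e-12)
    expect_equal(h1$heterobeltiosis_pct, h2$heterobeltiosis_pct,
                 tolerance = 1e-12)
  }
  # heterosis >= heterobeltiosis always (BP >= MP)
  set.seed(2)
  f1 <- runif(50, 1, 40); p1 <- runif(50, 1, 40); p2 <- runif(50, 1, 40)
  h <- heterosis(f1, p1, p2)
  expect_true(all(h$heterosis_pct >= h$heterobeltiosis_pct))
})

test_that("heterosis LSDs match the frozen t-quantile oracle values", {
  # Me = 19.54, r = 2, df = 65: values frozen from two independent
  # t-quantile implementations (R qt and scipy t.ppf agree to 1e-12)
  l <- heterosis_lsd(19.54, r = 2, df_error = 65, alpha = 0.05)
  expect_equal(l$lsd_mp, 7.6454, tolerance = 1e-4)
  expect_equal(l$lsd_bp, 8.8282, tolerance = 1e-4)
  # alpha = 0.01 strictly larger
  l01 <- heterosis_lsd(19.54, 2, 65, 0.01)
  expect_gt(l01$lsd_mp, l$lsd_mp)
  expect_gt(l01$lsd_bp, l$lsd_bp)
  expect_error(heterosis_lsd(0, 2, 65), "domain")
})

test_that("lsd_bp / lsd_mp = sqrt(4/3) for any input", {
  for (seed in 1:10) {
    set.seed(seed)
    me <- runif(1, 0.01, 100); r <- sample(1:5, 1); df <- sample(5:200, 1)
    a <- runif(1, 0.001, 0.2)
    l <- heterosis_lsd(me, r, df, a)
    expect_equal(l$lsd_bp / l$lsd_mp, sqrt(4 / 3), tolerance = 1e-12)
  }
})

test_that("favorability respects trait direction with zero unfavorable", {
  expect_true(favorability(-5, higher_is_better = FALSE))   # smaller cavity
  expect_true(favorability(10.2, higher_is_better = TRUE))  # yield gain
  expect_false(favorability(0, higher_is_better = TRUE))
  expect_false(favorability(0, higher_is_better = FALSE))
  expect_false(favorability(-3, higher_is_better = TRUE))
})

test_that("null simulation: |F1 - MP| exceeds lsd_mp at about alpha", {
  # no genetic effects at all: every exceedance is a false positive
  reject <- 0L; total <- 0L
  for (seed in 1:120) {
    cfg <- sim_config(p = 6, r = 2, environments = "e1", grand_mean = 20,
                      var_gca = 0, var_sca = 0, var_error = 4,
                      seed = seed, trait = "T")
    pt <- simulate_diallel(cfg)$plots
    an <- rcbd_anova(pt, "e1", "T")
    me <- an$MS[an$source == "Error"]
    dfe <- an$df[an$source == "Error"]
    tab <- entry_means(pt, "e1", "T")
    het <- heterosis_table(tab, me, df_error = dfe)
    reject <- reject + sum(het$sig_mp != "ns")
    total <- total + nrow(het)
  }
  rate <- reject / total
  # 1800 hybrid tests; correlated within trial, so allow a generous band
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("fisher_lsd_means matches an exhaustive pairwise oracle", {
  # all means equal -> single group "a"
  eq <- fisher_lsd_means(rep(3, 5), ms_error = 1, r = 2, df_error = 10)
  expect_true(all(eq$groups$letters == "a"))
  expect_false(any(eq$different))

  # difference exactly at the LSD -> not significant (strict inequality)
  l <- fisher_lsd_means(c(a = 0, b = 0.5), ms_error = 2, r = 2,
                        df_error = 10)
  m2 <- c(a = 0, b = l$lsd)
  l2 <- fisher_lsd_means(m2, 2, 2, 10)
  expect_false(l2$different["a", "b"])

  # known grouping: (10, 10.1, 20) with a small LSD
  m <- c(x = 10, y = 10.1, z = 20)
  # pick error so that lsd ~ 1
  me <- (1 / (qt(0.975, 10) * sqrt(2 / 2)))^2
  res <- fisher_lsd_means(m, me, 2, 10)
  expect_equal(round(res$lsd, 6), 1)
  expect_false(res$different["x", "y"])
  expect_true(res$different["x", "z"])
  expect_true(res$different["y", "z"])
  expect_equal(res$groups$letters[res$groups$entry == "z"], "a")
  expect_equal(res$groups$letters[res$groups$entry == "x"], "b")
  expect_equal(res$groups$letters[res$groups$entry == "y"], "b")

  # random means: letter display consistent with the pairwise matrix
  for (seed in 1:5) {
    set.seed(seed)
    m <- setNames(rnorm(12, 20, 3), paste0("e", 1:12))
    res <- fisher_lsd_means(m, ms_error = 4, r = 2, df_error = 22)
    g <- res$groups
    share <- function(i, j) {
      any(strsplit(g$letters[i], "")[[1]] %in% strsplit(g$letters[j], "")[[1]])
    }
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
      if (i == j) next
      differ <- res$different[g$entry[i], g$entry[j]]
      expect_equal(!share(i, j), unname(differ),
                   info = sprintf("seed %d pair %s-%s", seed,
                                  g$entry[i], g$entry[j]))
    }
  }
})
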