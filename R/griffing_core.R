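#' @title Griffing Method 2 / Model 1 combining-ability estimation
#'
#' @description
#' Closed-form estimation for a half diallel that includes the parents and one
#' set of F1 crosses but no reciprocals (Griffing's Method 2), with fixed
#' genetic effects (Model 1). On the entry-mean table \eqn{x_{ij}} the model is
#' \deqn{x_{ij} = u + g_i + g_j + s_{ij}}
#' under the identifiability constraints \eqn{\sum_i g_i = 0} and, for every
#' i, \eqn{\sum_j s_{ij} + s_{ii} = 0}. The model is saturated, so the fit
#' reconstructs every cell exactly: \eqn{\hat u + \hat g_i + \hat g_j +
#' \hat s_{ij} = x_{ij}}.
#'
#' @name griffing_method2
NULL

# Effect estimator variances in units of the entry-mean error variance
# sigma2_e' = MS_error / r, computed exactly from the coefficient vector of
# the linear map entry means -> effect (entry means are independent with
# equal variance under balance). Avoids transcribing the classical closed
# forms; the contrast variances in lsd_effect_contrast() are property-tested
# against this.
.m2_var_numeric <- function(p) {
  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  n <- nrow(idx)
  # coefficient vector of g_i over the n distinct entries
  coef_g <- function(i) {
    cf <- rep(-2 / (p * (p + 2)), n)
    row_i <- idx[, 1] == i | idx[, 2] == i
    diag_i <- idx[, 1] == i & idx[, 2] == i
    cf[row_i] <- cf[row_i] + 1 / (p + 2)
    cf[diag_i] <- cf[diag_i] + 1 / (p + 2)
    cf
  }
  coef_s <- function(i, j) {
    cf <- rep(2 / ((p + 1) * (p + 2)), n)
    for (k in unique(c(i, j))) {
      row_k <- idx[, 1] == k | idx[, 2] == k
      diag_k <- idx[, 1] == k & idx[, 2] == k
      cf[row_k] <- cf[row_k] - 1 / (p + 2)
      cf[diag_k] <- cf[diag_k] - 1 / (p + 2)
    }
    tgt <- (pmin(i, j) == idx[, 1]) & (pmax(i, j) == idx[, 2])
    cf[tgt] <- cf[tgt] + 1
    cf
  }
  list(g = sum(coef_g(1L)^2),
       s_offd = if (p >= 2) sum(coef_s(1L, 2L)^2) else NA_real_,
       s_diag = sum(coef_s(1L, 1L)^2))
}

#' Estimate Griffing Method-2 combining-ability effects
#'
#' Returns the closed-form fixed-effect (Model 1) estimates of the grand mean,
#' GCA effects \eqn{\hat g_i} and SCA effects \eqn{\hat s_{ij}} from a
#' symmetric entry-mean table. If plot-basis error information is supplied,
#' standard errors and two-sided t-test significance codes are attached
#' (effect variances use \eqn{\hat\sigma^2_{e'} = MS_{error}/r}).
#'
#' @param table a [diallel_table] (or symmetric p x p matrix) of entry means.
#' @param ms_error plot-basis error mean square from the per-environment RCBD
#'   ANOVA (optional; enables SEs and stars).
#' @param r number of replicates behind each entry mean; defaults to the
#'   table's `r` attribute.
#' @param df_error error degrees of freedom for the t tests
#'   (per environment: `(n_entries - 1) * (r - 1)`).
#' @return a `griffing_effects` list: `p`, `mu_hat`, `gca` (length p),
#'   `sca` (symmetric p x p), and when error information is given `se_gca`,
#'   `se_sca_hybrid`, `se_sca_parent`, `star_gca`, `star_sca`.
#' @export
estimate_effects <- function(table, ms_error = NULL, r = NULL,
                             df_error = NULL) {
  if (inherits(table, "diallel_table") && is.null(r)) r <- attr(table, "r")
  x <- as.matrix(table)
  x <- matrix(as.numeric(x), nrow(x))   # drop class and table attributes
  p <- nrow(x)
  if (p < 3L) stop("design too small: Method 2 needs p >= 3", call. = FALSE)
  if (!isSymmetric(unname(x), tol = 1e-10)) {
    stop("contract violation: entry-mean table must be symmetric",
         call. = FALSE)
  }
  row_tot <- rowSums(x)                  # x_i. (diagonal counted once)
  Y <- row_tot + diag(x)                 # x_i. + x_ii
  tot <- sum(x[upper.tri(x, diag = TRUE)])  # x_.. over distinct entries
  mu_hat <- 2 * tot / (p * (p + 1))
  gca <- (Y - 2 * tot / p) / (p + 2)
  sca <- x - outer(Y, Y, "+") / (p + 2) + 2 * tot / ((p + 1) * (p + 2))
  dimnames(sca) <- NULL
  out <- list(p = p, mu_hat = mu_hat, gca = unname(gca), sca = sca)
  if (!is.null(ms_error)) {
    if (ms_error <= 0) stop("domain error: ms_error must be positive",
                            call. = FALSE)
    if (is.null(r) || is.null(df_error)) {
      stop("r and df_error are required alongside ms_error", call. = FALSE)
    }
    s2e <- ms_error / r
    v <- .m2_var_numeric(p)
    out$se_gca <- sqrt(v$g * s2e)
    out$se_sca_hybrid <- sqrt(v$s_offd * s2e)
    out$se_sca_parent <- sqrt(v$s_diag * s2e)
    pval <- function(est, se) 2 * stats::pt(abs(est) / se, df_error,
                                            lower.tail = FALSE)
    out$star_gca <- significance_stars(pval(out$gca, out$se_gca))
    se_mat <- matrix(out$se_sca_hybrid, p, p)
    diag(se_mat) <- out$se_sca_parent
    p_mat <- matrix(pval(out$sca, se_mat), p, p)
    out$star_sca <- matrix(significance_stars(p_mat), p, p)
    out$df_error <- df_error
  }
  class(out) <- "griffing_effects"
  out
}

#' @export
print.griffing_effects <- function(x, digits = 3, ...) {
  cat(sprintf("Griffing Method 2 effects (p = %d)\n", x$p))
  cat("  grand mean:", round(x$mu_hat, digits), "\n")
  g <- round(x$gca, digits)
  names(g) <- paste0("P", seq_len(x$p))
  cat("  GCA effects:\n")
  print(g)
  cat("  SCA effects (upper triangle = hybrids, diagonal = parents)\n")
  invisible(x)
}

#' Partition the genotype sum of squares into GCA and SCA
#'
#' Computes the Method-2 sums of squares on the plot basis for one
#' environment and trait. With entry totals over the r replicates entering
#' the classical formulas, the partition is additive:
#' `SS_GCA + SS_SCA = SS_genotype` from the RCBD ANOVA on the same subset.
#'
#' @param plots a `plot_table`.
#' @param environment,trait labels selecting the balanced subset.
#' @return list with `ss_gca`, `ss_sca`, `df_gca = p - 1`,
#'   `df_sca = p(p-1)/2`, `ms_gca`, `ms_sca`, and `p`, `r`.
#' @export
partition_genotype_ss <- function(plots, environment, trait) {
  tab <- entry_means(plots, environment, trait)
  r <- attr(tab, "r")
  ss <- .m2_partition_entry(unclass(tab))
  df_gca <- ss$p - 1L
  df_sca <- ss$p * (ss$p - 1L) / 2L
  list(ss_gca = r * ss$ss_gca, ss_sca = r * ss$ss_sca,
       df_gca = df_gca, df_sca = as.integer(df_sca),
       ms_gca = r * ss$ss_gca / df_gca, ms_sca = r * ss$ss_sca / df_sca,
       p = ss$p, r = r)
}

# entry-mean-basis Method-2 SS; multiply by r (and by number of environments
# when pooling) for the plot basis
.m2_partition_entry <- function(x) {
  p <- nrow(x)
  Y <- rowSums(x) + diag(x)
  tot <- sum(x[upper.tri(x, diag = TRUE)])
  ss_gca <- (sum(Y^2) - 4 * tot^2 / p) / (p + 2)
  ss_gen <- sum(x[upper.tri(x, diag = TRUE)]^2) - 2 * tot^2 / (p * (p + 1))
  list(p = p, ss_gca = max(ss_gca, 0), ss_sca = max(ss_gen - ss_gca, 0),
       ss_gen = ss_gen)
}

#' Least significant difference for combining-ability contrasts
#'
#' LSDs for comparing two GCA effects (`gca_pair`), two SCA effects sharing a
#' parent (`sca_halfsib`, \eqn{s_{ij} - s_{ik}}), or two SCA effects with no
#' common parent (`sca_disjoint`, \eqn{s_{ij} - s_{kl}}). With
#' \eqn{\hat\sigma^2_{e'} = MS_{error}/r}, the contrast variances are the
#' Method-2 closed forms
#' \eqn{2\sigma^2_{e'}/(p+2)}, \eqn{2(p+1)\sigma^2_{e'}/(p+2)} and
#' \eqn{2p\,\sigma^2_{e'}/(p+2)} respectively, and
#' LSD = \eqn{t_{1-\alpha/2,\,df} \sqrt{V}}.
#'
#' @param kind one of `"gca_pair"`, `"sca_halfsib"`, `"sca_disjoint"`.
#' @param ms_error plot-basis error mean square.
#' @param r replicates per entry mean.
#' @param p number of parents.
#' @param df_error error degrees of freedom.
#' @param alpha significance level (default 0.05).
#' @return an `effect_contrast_lsd` list with `kind`, `alpha`, `df_error`,
#'   `value`.
#' @export
lsd_effect_contrast <- function(kind = c("gca_pair", "sca_halfsib",
                                         "sca_disjoint"),
                                ms_error, r, p, df_error, alpha = 0.05) {
  kind <- match.arg(kind)
  if (ms_error <= 0) stop("domain error: ms_error must be positive",
                          call. = FALSE)
  stopifnot(r >= 1, p >= 3, df_error >= 1, alpha > 0, alpha < 1)
  s2e <- ms_error / r
  V <- switch(kind,
              gca_pair = 2 * s2e / (p + 2),
              sca_halfsib = 2 * (p + 1) * s2e / (p + 2),
              sca_disjoint = 2 * p * s2e / (p + 2))
  value <- stats::qt(1 - alpha / 2, df_error) * sqrt(V)
  structure(list(kind = kind, alpha = alpha, df_error = df_error,
                 value = value),
            class = "effect_contrast_lsd")
}

#' @export
print.effect_contrast_lsd <- function(x, ...) {
  cat(sprintf("LSD(%s, alpha = %g, df = %d) = %.4g\n",
              x$kind, x$alpha, x$df_error, x$value))
  invisible(x)
}
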