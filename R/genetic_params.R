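#' @title Variance components, Baker's ratio and heritabilities
#'
#' @description
#' Random-model interpretation of the Method-2 mean squares, following the
#' DIALLEL-SAS conventions: with r replicates and p parents,
#' \deqn{\sigma^2_{GCA} = (MS_{GCA} - MS_{SCA}) / (r (p + 2)),\quad
#'       \sigma^2_{SCA} = (MS_{SCA} - MS_{error}) / r,}
#' \eqn{\sigma^2_A = 2\sigma^2_{GCA}}, \eqn{\sigma^2_D = \sigma^2_{SCA}}.
#' Heritabilities are on the entry-mean error basis:
#' \deqn{h^2_b = \frac{\sigma^2_A + \sigma^2_D}
#'   {\sigma^2_A + \sigma^2_D + \sigma^2_E / r},\qquad
#'       h^2_n = \frac{\sigma^2_A}
#'   {\sigma^2_A + \sigma^2_D + \sigma^2_E / r},}
#' with \eqn{\sigma^2_E} the plot-basis residual mean square. Baker's ratio
#' \eqn{2\sigma^2_{GCA} / (2\sigma^2_{GCA} + \sigma^2_{SCA})} measures the
#' relative weight of additive over dominance variation.
#'
#' @name genetic_parameters
NULL

#' Variance components from Method-2 mean squares
#'
#' Negative estimates are returned as computed with a `truncated` flag
#' marking values a user might wish to treat as zero; downstream ratio and
#' heritability computations use the raw values (with a warning), which
#' preserves the estimator's sampling distribution in simulations.
#'
#' @param ms_gca,ms_sca,ms_error plot-basis mean squares.
#' @param r number of replicates.
#' @param p number of parents.
#' @return list with `sigma2_gca`, `sigma2_sca`, `sigma2_a`, `sigma2_d`,
#'   and logical `truncated` (named, one flag per component).
#' @export
variance_components <- function(ms_gca, ms_sca, ms_error, r, p) {
  stopifnot(r >= 1, p >= 3)
  s2_gca <- (ms_gca - ms_sca) / (r * (p + 2))
  s2_sca <- (ms_sca - ms_error) / r
  list(sigma2_gca = s2_gca, sigma2_sca = s2_sca,
       sigma2_a = 2 * s2_gca, sigma2_d = s2_sca,
       truncated = c(sigma2_gca = s2_gca < 0, sigma2_sca = s2_sca < 0))
}

#' Baker's GCA/SCA ratio
#'
#' \eqn{2\sigma^2_{GCA} / (2\sigma^2_{GCA} + \sigma^2_{SCA})}; values near 1
#' indicate predominantly additive genetic control.
#'
#' @param sigma2_gca,sigma2_sca variance components.
#' @return the ratio, or `NA` when both components are zero.
#' @export
baker_ratio <- function(sigma2_gca, sigma2_sca) {
  if (sigma2_gca < 0 || sigma2_sca < 0) {
    warning("negative variance component used in Baker's ratio")
  }
  den <- 2 * sigma2_gca + sigma2_sca
  if (den == 0) return(NA_real_)
  2 * sigma2_gca / den
}

#' Broad- and narrow-sense heritability
#'
#' Entry-mean-basis heritabilities: the phenotypic denominator is
#' \eqn{\sigma^2_A + \sigma^2_D + \sigma^2_E / r} with \eqn{\sigma^2_E}
#' the plot-basis residual mean square of the same environment.
#'
#' @param sigma2_a additive variance.
#' @param sigma2_d dominance variance.
#' @param sigma2_e plot-basis residual mean square.
#' @param r number of replicates.
#' @return list with `h2_broad` and `h2_narrow`.
#' @export
heritability <- function(sigma2_a, sigma2_d, sigma2_e, r) {
  stopifnot(r >= 1)
  if (sigma2_a < 0 || sigma2_d < 0) {
    warning("negative variance component used in heritability")
  }
  den <- sigma2_a + sigma2_d + sigma2_e / r
  if (den <= 0) {
    stop("undefined heritability: non-positive phenotypic variance",
         call. = FALSE)
  }
  list(h2_broad = (sigma2_a + sigma2_d) / den, h2_narrow = sigma2_a / den)
}

#' Significance flags for variance components
#'
#' The GCA component is tested with `F = MS_GCA / MS_SCA` on
#' `(df_gca, df_sca)` degrees of freedom and the SCA component with
#' `F = MS_SCA / MS_error` on `(df_sca, df_error)`; flags are the usual
#' `ns` / `*` / `**` codes.
#'
#' @param ms_gca,ms_sca,ms_error plot-basis mean squares.
#' @param df_gca,df_sca,df_error degrees of freedom.
#' @return named character vector with elements `sigma2_gca`, `sigma2_sca`.
#' @export
component_significance <- function(ms_gca, ms_sca, ms_error,
                                   df_gca, df_sca, df_error) {
  stopifnot(df_gca > 0, df_sca > 0, df_error > 0)
  p_gca <- stats::pf(ms_gca / ms_sca, df_gca, df_sca, lower.tail = FALSE)
  p_sca <- stats::pf(ms_sca / ms_error, df_sca, df_error, lower.tail = FALSE)
  c(sigma2_gca = significance_stars(p_gca),
    sigma2_sca = significance_stars(p_sca))
}

#' Per-environment genetic parameters for one trait
#'
#' Convenience wrapper running the RCBD ANOVA and the Method-2 partition on
#' one environment, then assembling mean squares, variance components,
#' Baker's ratio, heritabilities, CV and R-squared.
#'
#' @param plots a `plot_table`.
#' @param environment,trait labels.
#' @return a `genetic_params` list with fields `ms_gca`, `ms_sca`,
#'   `ms_error`, `cv_percent`, `r_squared`, `sigma2_gca`, `sigma2_sca`,
#'   `sigma2_a`, `sigma2_d`, `sigma2_e`, `ratio`, `h2_broad`, `h2_narrow`,
#'   `flags`, `truncated`, `df` (named df vector).
#' @export
genetic_parameters <- function(plots, environment, trait) {
  an <- rcbd_anova(plots, environment, trait)
  part <- partition_genotype_ss(plots, environment, trait)
  err <- an[an$source == "Error", ]
  ms_error <- err$MS
  vc <- variance_components(part$ms_gca, part$ms_sca, ms_error,
                            part$r, part$p)
  if (any(vc$truncated)) {
    warning("negative variance component estimate(s): ",
            paste(names(vc$truncated)[vc$truncated], collapse = ", "),
            " (reported as computed)")
  }
  h2 <- suppressWarnings(
    heritability(vc$sigma2_a, vc$sigma2_d, ms_error, part$r))
  ratio <- suppressWarnings(baker_ratio(vc$sigma2_gca, vc$sigma2_sca))
  flags <- component_significance(part$ms_gca, part$ms_sca, ms_error,
                                  part$df_gca, part$df_sca, err$df)
  structure(list(
    environment = environment, trait = trait, p = part$p, r = part$r,
    ms_gca = part$ms_gca, ms_sca = part$ms_sca, ms_error = ms_error,
    df = c(gca = part$df_gca, sca = part$df_sca, error = err$df),
    cv_percent = attr(an, "cv_percent"), r_squared = attr(an, "r_squared"),
    sigma2_gca = vc$sigma2_gca, sigma2_sca = vc$sigma2_sca,
    sigma2_a = vc$sigma2_a, sigma2_d = vc$sigma2_d, sigma2_e = ms_error,
    ratio = ratio, h2_broad = h2$h2_broad, h2_narrow = h2$h2_narrow,
    flags = flags, truncated = vc$truncated),
    class = "genetic_params")
}

#' @export
print.genetic_params <- function(x, digits = 2, ...) {
  cat(sprintf("Genetic parameters: trait %s, environment %s (p = %d, r = %d)\n",
              x$trait, x$environment, x$p, x$r))
  v <- c(`MS GCA` = x$ms_gca, `MS SCA` = x$ms_sca, `MS error` = x$ms_error,
         `sigma2 GCA` = x$sigma2_gca, `sigma2 SCA` = x$sigma2_sca,
         `sigma2 A` = x$sigma2_a, `sigma2 D` = x$sigma2_d,
         `GCA/SCA` = x$ratio, `h2 broad` = x$h2_broad,
         `h2 narrow` = x$h2_narrow)
  print(round(v, digits))
  cat("flags:", paste(names(x$flags), x$flags, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
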