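#' @title Balanced RCBD and combined multi-environment ANOVA
#'
#' @description
#' Closed-form sums of squares for the balanced randomized complete block
#' design within one environment, and the combined analysis across
#' environments with the genotype and genotype-by-environment terms
#' partitioned into GCA, SCA, GCA x environment and SCA x environment.
#' All F tests use the pooled residual (fixed-effects Model 1).
#'
#' @name diallel_anova
NULL

.anova_table <- function(rows, cv_percent, r_squared) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r$source, df = r$df, SS = r$ss,
               MS = if (r$df > 0) r$ss / r$df else NA_real_,
               F = if (is.null(r$f)) NA_real_ else r$f,
               p_value = if (is.null(r$p)) NA_real_ else r$p,
               stars = if (is.null(r$p)) "" else significance_stars(r$p),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  structure(df, cv_percent = cv_percent, r_squared = r_squared,
            class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  for (cl in c("SS", "MS", "F", "p_value")) y[[cl]] <- signif(y[[cl]], digits)
  print(y)
  cat(sprintf("CV = %.2f%%, R-squared = %.3f\n",
              attr(x, "cv_percent"), attr(x, "r_squared")))
  invisible(x)
}

.f_row <- function(source, df, ss, ms_res, df_res) {
  ms <- ss / df
  if (is.na(ms_res) || ms_res <= 0) {
    list(source = source, df = df, ss = ss, f = NULL, p = NULL)
  } else {
    f <- ms / ms_res
    list(source = source, df = df, ss = ss, f = f,
         p = stats::pf(f, df, df_res, lower.tail = FALSE))
  }
}

#' Per-environment RCBD analysis of variance
#'
#' Sources: replicate (df r-1), genotype (df g-1, g = p(p+1)/2 entries),
#' error (df (g-1)(r-1)). `CV = 100 sqrt(MS_error) / grand mean`,
#' `R^2 = 1 - SS_error / SS_total`.
#'
#' @param plots a `plot_table`.
#' @param environment,trait labels selecting the balanced subset.
#' @return an `anova_table` (data.frame with attributes `cv_percent`,
#'   `r_squared`).
#' @export
rcbd_anova <- function(plots, environment, trait) {
  sub <- plots[plots$environment == environment & plots$trait == trait, ,
               drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("lookup error: no rows for environment='%s', trait='%s'",
                 environment, trait), call. = FALSE)
  }
  entry <- paste(sub$parent_a, sub$parent_b)
  g <- length(unique(entry))
  r <- length(unique(sub$replicate))
  if (nrow(sub) != g * r) stop("imbalance error: RCBD subset is not balanced",
                               call. = FALSE)
  y <- sub$value
  gm <- mean(y)
  ss_tot <- sum((y - gm)^2)
  rep_means <- tapply(y, sub$replicate, mean)
  entry_mean <- tapply(y, entry, mean)
  ss_rep <- g * sum((rep_means - gm)^2)
  ss_gen <- r * sum((entry_mean - gm)^2)
  ss_err <- ss_tot - ss_rep - ss_gen
  df_err <- (g - 1L) * (r - 1L)
  ms_err <- if (df_err > 0) ss_err / df_err else NA_real_
  rows <- list(
    .f_row("Replicate", r - 1L, ss_rep, ms_err, df_err),
    .f_row("Genotype", g - 1L, ss_gen, ms_err, df_err),
    list(source = "Error", df = df_err, ss = ss_err, f = NULL, p = NULL))
  cv <- if (is.na(ms_err)) NA_real_ else 100 * sqrt(max(ms_err, 0)) / gm
  r2 <- if (ss_tot > 0) 1 - ss_err / ss_tot else NA_real_
  .anova_table(rows, cv, r2)
}

#' Combined multi-environment diallel ANOVA
#'
#' Fits the combined model
#' \deqn{X_{ijkl} = u + e_i + r_{j(i)} + g_k + g_l + s_{kl} + eg_{ik} +
#'   eg_{il} + es_{ikl} + \varepsilon_{ijkl}}
#' with sources Environment, Rep(Environment), Genotype, Genotype x
#' Environment, the Method-2 partitions GCA / SCA of the genotype SS (on
#' pooled entry means) and GCA x Env / SCA x Env of the interaction SS
#' (`SS_GCAxE = sum over environments of per-environment SS_GCA - pooled
#' SS_GCA`, analogously for SCA), and the pooled Residual. Every F test is
#' against the residual (Model 1, fixed effects).
#'
#' @param plots a `plot_table` with at least two environments.
#' @param trait trait label.
#' @return an `anova_table` with rows Environment, Rep(Environment),
#'   Genotype, GCA, SCA, Genotype x Env, GCA x Env, SCA x Env, Residual.
#' @export
combined_anova <- function(plots, trait) {
  sub <- plots[plots$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("lookup error: unknown trait '", trait, "'",
                            call. = FALSE)
  envs <- unique(sub$environment)
  nE <- length(envs)
  if (nE < 2L) {
    stop("single environment: use rcbd_anova() for per-environment analysis",
         call. = FALSE)
  }
  entry <- paste(sub$parent_a, sub$parent_b)
  g <- length(unique(entry))
  r <- length(unique(sub$replicate))
  if (nrow(sub) != g * r * nE) stop("imbalance error: combined subset is not balanced",
                                    call. = FALSE)
  p <- max(sub$parent_b)
  y <- sub$value
  gm <- mean(y)
  ss_tot <- sum((y - gm)^2)
  env_mean <- tapply(y, sub$environment, mean)
  ss_env <- g * r * sum((env_mean - gm)^2)
  # rep-within-environment deviations from their environment mean
  er_mean <- tapply(y, list(sub$environment, sub$replicate), mean)
  ss_rep <- g * sum(sweep(er_mean, 1L,
                          as.vector(env_mean[rownames(er_mean)]))^2,
                    na.rm = TRUE)
  entry_mean <- tapply(y, entry, mean)          # pooled over envs and reps
  ss_gen <- nE * r * sum((entry_mean - gm)^2)
  cell_mean <- tapply(y, list(sub$environment, entry), mean)
  dev <- sweep(cell_mean, 1L, as.vector(env_mean[rownames(cell_mean)])) -
    matrix(entry_mean[colnames(cell_mean)], nrow(cell_mean),
           ncol(cell_mean), byrow = TRUE) + gm
  ss_ge <- r * sum(dev^2, na.rm = TRUE)
  ss_res <- ss_tot - ss_env - ss_rep - ss_gen - ss_ge
  df_res <- nE * (g - 1L) * (r - 1L)
  ms_res <- ss_res / df_res

  # Method-2 partition of genotype SS on pooled entry means (plot basis:
  # x nE x r), and of the interaction SS via the per-environment identity
  pooled <- matrix(NA_real_, p, p)
  am <- tapply(sub$value, list(sub$parent_a, sub$parent_b), mean)
  for (i in seq_len(p)) for (j in i:p) {
    pooled[i, j] <- pooled[j, i] <- am[as.character(i), as.character(j)]
  }
  part_pool <- .m2_partition_entry(pooled)
  ss_gca <- nE * r * part_pool$ss_gca
  ss_sca <- nE * r * part_pool$ss_sca
  per_env <- lapply(envs, function(e) partition_genotype_ss(plots, e, trait))
  ss_gca_e <- sum(vapply(per_env, `[[`, 0, "ss_gca")) - ss_gca
  ss_sca_e <- sum(vapply(per_env, `[[`, 0, "ss_sca")) - ss_sca
  ss_gca_e <- max(ss_gca_e, 0)
  ss_sca_e <- max(ss_sca_e, 0)

  df_gca <- p - 1L
  df_sca <- as.integer(p * (p - 1L) / 2L)
  rows <- list(
    .f_row("Environment", nE - 1L, ss_env, ms_res, df_res),
    .f_row("Rep(Environment)", nE * (r - 1L), ss_rep, ms_res, df_res),
    .f_row("Genotype", g - 1L, ss_gen, ms_res, df_res),
    .f_row("GCA", df_gca, ss_gca, ms_res, df_res),
    .f_row("SCA", df_sca, ss_sca, ms_res, df_res),
    .f_row("Genotype x Env", (g - 1L) * (nE - 1L), ss_ge, ms_res, df_res),
    .f_row("GCA x Env", df_gca * (nE - 1L), ss_gca_e, ms_res, df_res),
    .f_row("SCA x Env", df_sca * (nE - 1L), ss_sca_e, ms_res, df_res),
    list(source = "Residual", df = df_res, ss = ss_res, f = NULL, p = NULL))
  cv <- 100 * sqrt(max(ms_res, 0)) / gm
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  .anova_table(rows, cv, r2)
}

#' Significance star codes from p-values
#'
#' `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p_value numeric vector of p-values in `[0, 1]`.
#' @return character vector of codes.
#' @export
significance_stars <- function(p_value) {
  stopifnot(all(is.na(p_value) | (p_value >= 0 & p_value <= 1)))
  ifelse(is.na(p_value), "ns",
         ifelse(p_value < 0.01, "**", ifelse(p_value < 0.05, "*", "ns")))
}
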