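#' @title Synthetic multi-environment half-diallel trials
#'
#' @description
#' Generates balanced half-diallel RCBD trials under the additive-dominance
#' model the analysis assumes,
#' \deqn{X = u + e + r_{(e)} + g_i + g_j + s_{ij} + eg_i + eg_j + es_{ij}
#'   + \varepsilon,}
#' with every effect Gaussian at user-chosen variances and the drawn truth
#' returned alongside the data for parameter-recovery and calibration tests.
#' GCA effects are centered to sum exactly to zero (matching the estimator's
#' identifiability constraint); interaction GCA effects are centered within
#' each environment. SCA effects are symmetric, drawn once per unordered
#' pair including the parental diagonal \eqn{s_{ii}}.
#'
#' Randomness uses one global seed with fixed per-component substreams, so
#' changing the number of replicates does not reshuffle the genetic effects.
#'
#' @name synthetic_diallel
NULL

#' Simulation configuration
#'
#' @param p number of parents (>= 3).
#' @param r replicates per environment (>= 1).
#' @param environments character vector of environment labels.
#' @param grand_mean trait grand mean, trait units.
#' @param var_gca,var_sca GCA and SCA variances (trait units squared).
#' @param var_env environment main-effect variance.
#' @param var_gca_env,var_sca_env interaction variances.
#' @param var_rep replicate-within-environment variance.
#' @param var_error plot error variance.
#' @param seed integer seed.
#' @param trait trait label.
#' @return a `sim_config` list.
#' @export
sim_config <- function(p = 11, r = 2, environments = c("non-saline", "saline"),
                       grand_mean = 0, var_gca = 1, var_sca = 1,
                       var_env = 0, var_gca_env = 0, var_sca_env = 0,
                       var_rep = 0, var_error = 1, seed = 1L,
                       trait = "trait") {
  vars <- c(var_gca = var_gca, var_sca = var_sca, var_env = var_env,
            var_gca_env = var_gca_env, var_sca_env = var_sca_env,
            var_rep = var_rep, var_error = var_error)
  if (any(!is.finite(vars)) || any(vars < 0)) {
    stop("config error: variances must be finite and non-negative",
         call. = FALSE)
  }
  if (p < 3) stop("config error: p must be >= 3", call. = FALSE)
  if (r < 1) stop("config error: r must be >= 1", call. = FALSE)
  structure(list(p = as.integer(p), r = as.integer(r),
                 environments = as.character(environments),
                 grand_mean = grand_mean, var_gca = var_gca,
                 var_sca = var_sca, var_env = var_env,
                 var_gca_env = var_gca_env, var_sca_env = var_sca_env,
                 var_rep = var_rep, var_error = var_error,
                 seed = as.integer(seed), trait = trait),
            class = "sim_config")
}

# deterministic substream seeds from the global seed; offsets are fixed so
# e.g. changing r only affects the error/rep substreams it uses
.substream <- function(seed, component) {
  offsets <- c(gca = 1L, sca = 2L, env = 3L, gca_env = 4L, sca_env = 5L,
               rep = 6L, error = 7L)
  (as.integer(seed) * 8191L + offsets[[component]] * 127L) %% 2147483647L
}

.draw <- function(seed, component, n, sd) {
  set.seed(.substream(seed, component))
  stats::rnorm(n, 0, sd)
}

#' Simulate a balanced half-diallel RCBD trial
#'
#' @param config a [sim_config()].
#' @return list with `plots` (a `plot_table` of
#'   `p(p+1)/2 * r * n_env` rows) and `truth` (a `sim_truth` list holding
#'   the drawn `gca`, `sca` matrix, `env`, per-environment `gca_env` and
#'   `sca_env`, and `rep_effects`).
#' @examples
#' sim <- simulate_diallel(sim_config(p = 4, r = 2, seed = 42))
#' validate_design(sim$plots)
#' @export
simulate_diallel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p; r <- config$r; envs <- config$environments
  nE <- length(envs)
  g <- .draw(config$seed, "gca", p, sqrt(config$var_gca))
  g <- g - mean(g)                      # estimator's constraint: sum zero
  s <- matrix(0, p, p)
  ut <- upper.tri(s, diag = TRUE)
  s[ut] <- .draw(config$seed, "sca", sum(ut), sqrt(config$var_sca))
  s <- s + t(s) - diag(diag(s))
  e_env <- .draw(config$seed, "env", nE, sqrt(config$var_env))
  ge <- matrix(.draw(config$seed, "gca_env", p * nE,
                     sqrt(config$var_gca_env)), p, nE)
  ge <- sweep(ge, 2L, colMeans(ge))     # centered within environment
  se <- array(0, c(p, p, nE))
  draws <- .draw(config$seed, "sca_env", sum(ut) * nE,
                 sqrt(config$var_sca_env))
  for (k in seq_len(nE)) {
    m <- matrix(0, p, p)
    m[ut] <- draws[((k - 1) * sum(ut) + 1):(k * sum(ut))]
    se[, , k] <- m + t(m) - diag(diag(m))
  }
  rep_eff <- matrix(.draw(config$seed, "rep", nE * r,
                          sqrt(config$var_rep)), nE, r)
  idx <- which(ut, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n_entries <- nrow(idx)
  grid <- expand.grid(k = seq_len(n_entries), rep = seq_len(r),
                      env = seq_len(nE))
  eps <- .draw(config$seed, "error", nrow(grid), sqrt(config$var_error))
  i <- idx[grid$k, 1]; j <- idx[grid$k, 2]
  value <- config$grand_mean + e_env[grid$env] + rep_eff[cbind(grid$env, grid$rep)] +
    g[i] + g[j] + s[cbind(i, j)] +
    ge[cbind(i, grid$env)] + ge[cbind(j, grid$env)] +
    se[cbind(i, j, grid$env)] + eps
  plots <- plot_table(data.frame(
    environment = envs[grid$env],
    replicate = paste0("r", grid$rep),
    parent_a = paste0("P", i), parent_b = paste0("P", j),
    trait = config$trait, value = value,
    stringsAsFactors = FALSE),
    parent_levels = paste0("P", seq_len(p)))
  truth <- structure(list(gca = g, sca = s, env = stats::setNames(e_env, envs),
                          gca_env = ge, sca_env = se, rep_effects = rep_eff,
                          config = config),
                     class = "sim_truth")
  list(plots = plots, truth = truth)
}
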