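#' @title Run orchestration and report rendering
#'
#' @description
#' End-to-end analysis of a plot-level phenotype file: per-trait combined
#' ANOVA, per-environment genetic parameters, GCA effects of the parents,
#' SCA effects of the hybrids per environment with LSD footers, heterosis
#' tables, and Fisher LSD mean comparisons. Every rendered number is the
#' rounding of the corresponding full-precision value in the machine-readable
#' `summary.json`; rendering never recomputes.
#'
#' @name cli_report
NULL

#' Run configuration
#'
#' @param traits named logical vector: names are the traits to analyze,
#'   values their direction (`TRUE` = higher is better). `NULL` analyzes
#'   every trait in the input with `higher_is_better = TRUE`.
#' @param alpha two significance levels for `*` and `**` codes.
#' @param digits rounding used in rendered tables (full precision is kept in
#'   the JSON summary).
#' @param seed seed for the simulate subcommand.
#' @return a `run_config` list.
#' @export
run_config <- function(traits = NULL, alpha = c(0.05, 0.01), digits = 2,
                       seed = 1L) {
  stopifnot(all(alpha > 0), all(alpha < 1), length(alpha) == 2L)
  if (!is.null(traits)) {
    stopifnot(is.logical(traits), length(traits) > 0L,
              !is.null(names(traits)))
  }
  structure(list(traits = traits, alpha = sort(alpha, decreasing = TRUE),
                 digits = digits, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Recognized fields: `traits` (object mapping trait name to
#' `higher_is_better` boolean), `alpha` (array of two levels), `digits`,
#' `seed`, and for the simulate subcommand any [sim_config()] field.
#'
#' @param path JSON file path.
#' @return list with `run` (a `run_config`) and `sim` (named list of
#'   sim_config overrides, possibly empty).
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  traits <- NULL
  if (!is.null(raw$traits)) {
    if (length(raw$traits) == 0L) {
      stop("config error: empty trait list", call. = FALSE)
    }
    traits <- vapply(raw$traits, isTRUE, logical(1))
  }
  run <- run_config(
    traits = traits,
    alpha = if (is.null(raw$alpha)) c(0.05, 0.01) else as.numeric(raw$alpha),
    digits = if (is.null(raw$digits)) 2 else raw$digits,
    seed = if (is.null(raw$seed)) 1L else raw$seed)
  sim_fields <- intersect(names(raw),
                          c("p", "r", "environments", "grand_mean", "var_gca",
                            "var_sca", "var_env", "var_gca_env", "var_sca_env",
                            "var_rep", "var_error", "trait"))
  list(run = run, sim = raw[sim_fields])
}

.write_tsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  path
}

.anova_df <- function(an) {
  cbind(as.data.frame(an),
        data.frame(cv_percent = attr(an, "cv_percent"),
                   r_squared = attr(an, "r_squared"))[rep(1, nrow(an)), ])
}

#' Analyze a phenotype file end to end
#'
#' @param input path to a delimited plot-level phenotype file
#'   (see [read_phenotypes()]).
#' @param out_dir output directory (created if missing).
#' @param config a [run_config()].
#' @return invisibly, the full-precision summary list (also written as
#'   `summary.json`); rendered TSV tables and `run_log.txt` are written to
#'   `out_dir`.
#' @export
run_analyze <- function(input, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  plots <- read_phenotypes(input)
  design <- validate_design(plots)
  traits <- config$traits
  if (is.null(traits)) {
    traits <- stats::setNames(rep(TRUE, length(design$traits)), design$traits)
  }
  if (length(traits) == 0L) stop("config error: empty trait list",
                                 call. = FALSE)
  unknown <- setdiff(names(traits), design$traits)
  if (length(unknown) > 0L) {
    stop("config error: trait(s) not in input: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- config$alpha
  summary <- list(design = list(p = design$p,
                                environments = design$environments,
                                replicates = design$replicates_per_env,
                                n_entries = design$n_entries),
                  traits = list())
  multi_env <- length(design$environments) >= 2L
  gca_rows <- list()
  for (tr in names(traits)) {
    s <- list(direction_higher_is_better = unname(traits[[tr]]))
    if (multi_env) {
      ca <- combined_anova(plots, tr)
      s$combined_anova <- .anova_df(ca)
      .write_tsv(.anova_df(ca), file.path(out_dir,
                                          paste0("anova_combined_", tr, ".tsv")),
                 digits = config$digits)
    }
    s$environments <- list()
    for (env in design$environments) {
      gp <- genetic_parameters(plots, env, tr)
      tab <- entry_means(plots, env, tr)
      eff <- estimate_effects(tab, ms_error = gp$ms_error, r = gp$r,
                              df_error = gp$df["error"])
      lsd_g <- lsd_effect_contrast("gca_pair", gp$ms_error, gp$r, gp$p,
                                   gp$df["error"], alpha[1])
      lsd_hs <- lsd_effect_contrast("sca_halfsib", gp$ms_error, gp$r, gp$p,
                                    gp$df["error"], alpha[1])
      lsd_dj <- lsd_effect_contrast("sca_disjoint", gp$ms_error, gp$r, gp$p,
                                    gp$df["error"], alpha[1])
      het <- heterosis_table(tab, gp$ms_error, gp$r, gp$df["error"],
                             alpha = alpha,
                             higher_is_better = traits[[tr]])
      ut <- upper.tri(tab, diag = TRUE)
      entry_names <- {
        idx <- which(ut, arr.ind = TRUE)
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
        ifelse(idx[, 1] == idx[, 2], paste0("P", idx[, 1]),
               paste0("H", idx[, 1], "x", idx[, 2]))
      }
      mvec <- {
        idx <- which(ut, arr.ind = TRUE)
        idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
        stats::setNames(unclass(tab)[idx], entry_names)
      }
      cmp <- fisher_lsd_means(mvec, gp$ms_error, gp$r, gp$df["error"],
                              alpha[1])
      s$environments[[env]] <- list(
        genetic_params = gp[c("ms_gca", "ms_sca", "ms_error", "cv_percent",
                              "r_squared", "sigma2_gca", "sigma2_sca",
                              "sigma2_a", "sigma2_d", "ratio", "h2_broad",
                              "h2_narrow")],
        flags = as.list(gp$flags),
        gca = eff$gca, star_gca = eff$star_gca,
        sca = eff$sca[upper.tri(eff$sca)],
        lsd = list(gca_pair = lsd_g$value, sca_halfsib = lsd_hs$value,
                   sca_disjoint = lsd_dj$value),
        heterosis = het,
        mean_groups = cmp$groups, mean_lsd = cmp$lsd)
      gca_rows[[paste(tr, env)]] <- data.frame(
        trait = tr, environment = env, parent = paste0("P", seq_len(gp$p)),
        gca = eff$gca, stars = eff$star_gca, stringsAsFactors = FALSE)
      hyb <- which(upper.tri(eff$sca), arr.ind = TRUE)
      hyb <- hyb[order(hyb[, 1], hyb[, 2]), , drop = FALSE]
      sca_df <- data.frame(
        hybrid = paste0("H", hyb[, 1], "x", hyb[, 2]),
        sca = eff$sca[hyb], stars = eff$star_sca[hyb],
        stringsAsFactors = FALSE)
      sca_df <- rbind(sca_df,
                      data.frame(hybrid = c("LSD(Sij-Sik)", "LSD(Sij-Skl)"),
                                 sca = c(lsd_hs$value, lsd_dj$value),
                                 stars = "", stringsAsFactors = FALSE))
      .write_tsv(sca_df, file.path(out_dir, paste0("sca_", tr, "_", env,
                                                   ".tsv")),
                 digits = config$digits)
      .write_tsv(het, file.path(out_dir, paste0("heterosis_", tr, "_", env,
                                                ".tsv")),
                 digits = config$digits)
      .write_tsv(cmp$groups, file.path(out_dir, paste0("means_", tr, "_",
                                                       env, ".tsv")),
                 digits = config$digits)
    }
    summary$traits[[tr]] <- s
  }
  # GCA table across traits and environments, with the LSD footer per env
  gca_all <- do.call(rbind, gca_rows)
  .write_tsv(gca_all, file.path(out_dir, "gca_effects.tsv"),
             digits = config$digits)
  # Table-4-shaped genetic parameter overview
  gp_rows <- do.call(rbind, lapply(names(summary$traits), function(tr) {
    do.call(rbind, lapply(design$environments, function(env) {
      g <- summary$traits[[tr]]$environments[[env]]$genetic_params
      cbind(data.frame(trait = tr, environment = env,
                       stringsAsFactors = FALSE),
            as.data.frame(g))
    }))
  }))
  .write_tsv(gp_rows, file.path(out_dir, "genetic_params.tsv"),
             digits = config$digits)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log <- c(paste("package_version:",
                 as.character(utils::packageVersion("griffing"))),
           paste("input:", normalizePath(input)),
           paste("input_md5:", unname(tools::md5sum(input))),
           paste("alpha:", paste(alpha, collapse = ", ")),
           paste("digits:", config$digits),
           paste("seed:", config$seed),
           "decisions: Model 1 fixed-effect F tests vs pooled residual;",
           "  per-environment error df for all effect and heterosis LSDs;",
           "  BP = numerically larger parent; strict inequality at LSD;",
           "  negative variance components reported as computed.")
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}

#' Simulate a trial and write it to disk
#'
#' @param out_dir output directory.
#' @param config a [sim_config()].
#' @return invisibly, list with paths `data` (long-format phenotype file
#'   readable by [read_phenotypes()]) and `truth` (JSON sidecar with the
#'   drawn effects).
#' @export
run_simulate <- function(out_dir, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_diallel(config)
  data_path <- file.path(out_dir, paste0("simulated_", config$trait, ".csv"))
  write_phenotypes(sim$plots, data_path)
  truth_path <- file.path(out_dir, paste0("truth_", config$trait, ".json"))
  tr <- sim$truth
  jsonlite::write_json(
    list(config = unclass(config), gca = tr$gca, sca = tr$sca,
         env = as.list(tr$env), gca_env = tr$gca_env,
         rep_effects = tr$rep_effects),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(data = data_path, truth = truth_path))
}

#' Command-line entry point
#'
#' Usage (see `inst/cli/griffing-cli.R` for the installed wrapper):
#' \preformatted{
#'   griffing-cli analyze  --input FILE [--config FILE] --out DIR
#'   griffing-cli simulate [--config FILE] --out DIR [--seed N]
#' }
#'
#' @param args character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage:",
    "  analyze  --input FILE [--config FILE] --out DIR",
    "  simulate [--config FILE] --out DIR [--seed N]", sep = "\n")
  if (length(args) < 1L) stop(usage, call. = FALSE)
  cmd <- args[1L]
  opt <- list()
  rest <- args[-1L]
  while (length(rest) > 0L) {
    if (!startsWith(rest[1L], "--") || length(rest) < 2L) {
      stop("bad argument: ", rest[1L], "\n", usage, call. = FALSE)
    }
    opt[[sub("^--", "", rest[1L])]] <- rest[2L]
    rest <- rest[-(1:2)]
  }
  if (is.null(opt$out)) stop("--out is required\n", usage, call. = FALSE)
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else
    list(run = run_config(), sim = list())
  if (cmd == "analyze") {
    if (is.null(opt$input)) stop("--input is required\n", usage,
                                 call. = FALSE)
    run_analyze(opt$input, opt$out, cfg$run)
  } else if (cmd == "simulate") {
    seed <- if (!is.null(opt$seed)) as.integer(opt$seed) else cfg$run$seed
    sc <- do.call(sim_config, c(cfg$sim, list(seed = seed)))
    run_simulate(opt$out, sc)
  } else {
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
  }
  invisible(0L)
}
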