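#' @title Built-in variance-magnitude presets
#'
#' @description
#' Single-environment simulation presets at the variance magnitudes of a
#' published 11-parent melon half-diallel salinity trial (10 fruit traits
#' grown under non-saline and saline irrigation, 2 replicates): `var_gca`
#' and `var_sca` are the reported GCA and SCA variance components and
#' `var_error` the residual mean square for that trait and environment.
#' The preset grand mean is back-calculated from the reported coefficient
#' of variation, `mean = 100 sqrt(MS_error) / CV`. Interaction variances
#' default to zero because each preset describes one environment.
#'
#' @name diallel_presets
NULL

# trait x environment -> (sigma2_gca, sigma2_sca, error MS, CV %)
.preset_table <- local({
  tr <- c("FWT", "NF", "FY", "FL", "FW", "SCL", "SCW", "FT", "PT", "TSS")
  nonsal <- data.frame(
    trait = tr, environment = "non-saline",
    var_gca = c(0.11, 0.03, 21.39, 0.74, 1.5, 0.54, 0.71, 0.11, 0.001, 0.25),
    var_sca = c(0.07, 0.09, 62.51, 1.98, 0.51, 1.74, 0.18, 0.02, 0.06, 0.34),
    var_error = c(0.05, 0.12, 19.54, 0.82, 1.03, 0.57, 0.62, 0.08, 0.05, 0.28),
    cv = c(11.5, 15.4, 11, 6.1, 6.3, 7.6, 8.6, 8, 11.3, 5),
    stringsAsFactors = FALSE)
  sal <- data.frame(
    trait = tr, environment = "saline",
    var_gca = c(0.03, 0.01, 1.8, 0.28, 0.88, 0.28, 0.44, 0.05, 0.002, 0.32),
    var_sca = c(0.07, 0.06, 22.01, 2.07, 0.68, 1.42, 0.22, 0.05, 0.09, 0.74),
    var_error = c(0.04, 0.08, 11.16, 0.71, 0.8, 0.48, 0.29, 0.06, 0.04, 0.2),
    cv = c(15, 18.3, 14.2, 6.6, 6.3, 8.7, 6.7, 8, 8, 3.8),
    stringsAsFactors = FALSE)
  rbind(nonsal, sal)
})

#' Reference simulation preset for one trait and environment
#'
#' @param trait one of `"FWT"` (fruit weight, kg), `"NF"` (fruits per
#'   plant), `"FY"` (fruit yield, t/ha), `"FL"`/`"FW"` (fruit length/width,
#'   cm), `"SCL"`/`"SCW"` (seed cavity length/width, cm), `"FT"` (flesh
#'   thickness, cm), `"PT"` (peel thickness, cm), `"TSS"` (total soluble
#'   solids, degrees Brix).
#' @param environment `"non-saline"` or `"saline"`.
#' @param seed seed stored in the returned config.
#' @return a [sim_config()] with `p = 11`, `r = 2`, the single requested
#'   environment, the preset variance magnitudes, and a grand mean derived
#'   from the reported CV.
#' @examples
#' diallel_preset("FY", "non-saline")$var_gca  # 21.39
#' @export
diallel_preset <- function(trait, environment = c("non-saline", "saline"),
                           seed = 1L) {
  environment <- match.arg(environment)
  row <- .preset_table[.preset_table$trait == trait &
                         .preset_table$environment == environment, ]
  if (nrow(row) != 1L) {
    stop("lookup error: no preset for trait '", trait, "'", call. = FALSE)
  }
  sim_config(p = 11, r = 2, environments = environment,
             grand_mean = 100 * sqrt(row$var_error) / row$cv,
             var_gca = row$var_gca, var_sca = row$var_sca,
             var_error = row$var_error, seed = seed, trait = trait)
}

#' Names of the traits with built-in presets
#' @return character vector of trait codes.
#' @export
preset_traits <- function() unique(.preset_table$trait)
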