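#' @title Heterosis, heterobeltiosis and Fisher LSD mean comparisons
#'
#' @description
#' Mid-parent heterosis and best-parent heterobeltiosis of F1 hybrids,
#' \deqn{Heterosis = 100\,(\bar F_1 - MP)/MP, \qquad
#'       Heterobeltiosis = 100\,(\bar F_1 - BP)/BP,}
#' with MP the mid-parent mean and BP the numerically larger parent mean,
#' their least-significant-difference tests
#' \eqn{LSD_{MP} = t\sqrt{3 M_e / (2r)}} and
#' \eqn{LSD_{BP} = t\sqrt{2 M_e / r}} (applied to the absolute trait-unit
#' deviations, not to the percentages), and Fisher LSD comparisons of entry
#' means with a compact letter display.
#'
#' @name heterosis_stats
NULL

#' Mid-parent heterosis and heterobeltiosis percentages
#'
#' @param f1 F1 hybrid mean.
#' @param p1,p2 parent means.
#' @return list with `heterosis_pct` (vs mid-parent `MP = (p1 + p2)/2`) and
#'   `heterobeltiosis_pct` (vs best parent `BP = max(p1, p2)`); a percentage
#'   is `NA` when its reference value is zero.
#' @export
heterosis <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  bp <- pmax(p1, p2)
  list(heterosis_pct = ifelse(mp == 0, NA_real_, 100 * (f1 - mp) / mp),
       heterobeltiosis_pct = ifelse(bp == 0, NA_real_, 100 * (f1 - bp) / bp))
}

#' LSDs for heterosis and heterobeltiosis
#'
#' @param ms_error plot-basis residual mean square `Me`.
#' @param r number of replicates.
#' @param df_error error degrees of freedom for the t quantile.
#' @param alpha significance level.
#' @return list with `lsd_mp` \eqn{= t\sqrt{3Me/(2r)}} and `lsd_bp`
#'   \eqn{= t\sqrt{2Me/r}}, in trait units; compare against
#'   \eqn{|\bar F_1 - MP|} and \eqn{|\bar F_1 - BP|} respectively.
#' @export
heterosis_lsd <- function(ms_error, r, df_error, alpha = 0.05) {
  if (ms_error <= 0) stop("domain error: ms_error must be positive",
                          call. = FALSE)
  stopifnot(r >= 1, df_error >= 1, alpha > 0, alpha < 1)
  tq <- stats::qt(1 - alpha / 2, df_error)
  list(lsd_mp = tq * sqrt(3 * ms_error / (2 * r)),
       lsd_bp = tq * sqrt(2 * ms_error / r))
}

#' Favorability of a heterosis percentage given the trait direction
#'
#' A percentage is favorable when it moves the trait in the desired
#' direction: positive for "higher is better" traits, negative for traits
#' such as seed cavity size where smaller values are beneficial. Zero is
#' never favorable.
#'
#' @param pct heterosis or heterobeltiosis percentage.
#' @param higher_is_better logical trait direction.
#' @return logical.
#' @export
favorability <- function(pct, higher_is_better) {
  stopifnot(is.logical(higher_is_better))
  ifelse(is.na(pct), NA,
         ifelse(higher_is_better, pct > 0, pct < 0))
}

#' Heterosis table for all hybrids of one environment
#'
#' @param table a [diallel_table] of entry means (diagonal = parents).
#' @param ms_error,r,df_error error information for the LSD tests;
#'   `r` defaults to the table's replicate count.
#' @param alpha two significance levels `c(star, double_star)` for the
#'   `*` and `**` codes.
#' @param higher_is_better trait direction for the favorability calls.
#' @return data.frame with one row per hybrid: `parent_a`, `parent_b`,
#'   `f1_mean`, `mp`, `bp`, `heterosis_pct`, `heterobeltiosis_pct`,
#'   significance codes `sig_mp`, `sig_bp` (`ns`/`*`/`**`, strict
#'   inequality at the LSD boundary) and logical `favorable_mp`,
#'   `favorable_bp`.
#' @export
heterosis_table <- function(table, ms_error, r = NULL, df_error,
                            alpha = c(0.05, 0.01), higher_is_better = TRUE) {
  x <- unclass(as.matrix(table))
  p <- nrow(x)
  if (is.null(r)) r <- attr(table, "r")
  alpha <- sort(alpha, decreasing = TRUE)
  lsd05 <- heterosis_lsd(ms_error, r, df_error, alpha[1])
  lsd01 <- heterosis_lsd(ms_error, r, df_error, alpha[2])
  idx <- which(upper.tri(x), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  f1 <- x[idx]
  p1 <- diag(x)[idx[, 1]]
  p2 <- diag(x)[idx[, 2]]
  h <- heterosis(f1, p1, p2)
  mp <- (p1 + p2) / 2
  bp <- pmax(p1, p2)
  code <- function(dev, l05, l01) {
    ifelse(abs(dev) > l01, "**", ifelse(abs(dev) > l05, "*", "ns"))
  }
  data.frame(
    parent_a = idx[, 1], parent_b = idx[, 2],
    f1_mean = f1, mp = mp, bp = bp,
    heterosis_pct = h$heterosis_pct,
    heterobeltiosis_pct = h$heterobeltiosis_pct,
    sig_mp = code(f1 - mp, lsd05$lsd_mp, lsd01$lsd_mp),
    sig_bp = code(f1 - bp, lsd05$lsd_bp, lsd01$lsd_bp),
    favorable_mp = favorability(h$heterosis_pct, higher_is_better),
    favorable_bp = favorability(h$heterobeltiosis_pct, higher_is_better),
    stringsAsFactors = FALSE)
}

#' Fisher LSD comparison of entry means with compact letter display
#'
#' Two entries differ when their absolute mean difference strictly exceeds
#' `LSD = t * sqrt(2 MS_error / r)`. Because all entries share the same
#' standard error, non-significance groups are intervals of the means sorted
#' in decreasing order; letters label the maximal such intervals
#' (insert-and-absorb).
#'
#' @param means named numeric vector of entry means.
#' @param ms_error plot-basis error mean square.
#' @param r replicates per mean.
#' @param df_error error degrees of freedom.
#' @param alpha significance level.
#' @return list with `lsd` (trait units), `different` (logical matrix of
#'   pairwise significant differences, entry order as input) and `groups`
#'   (data.frame `entry`, `mean`, `letters`, sorted by decreasing mean).
#' @export
fisher_lsd_means <- function(means, ms_error, r, df_error, alpha = 0.05) {
  if (ms_error < 0) stop("domain error: negative ms_error", call. = FALSE)
  stopifnot(r >= 1, df_error >= 1, alpha > 0, alpha < 1)
  if (is.null(names(means))) names(means) <- seq_along(means)
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / r)
  diff_mat <- abs(outer(means, means, "-")) > lsd
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  n <- length(m)
  # maximal intervals [i..j] with m[i] - m[j] <= lsd
  intervals <- list()
  j_prev <- 0L
  for (i in seq_len(n)) {
    j <- i
    while (j < n && m[i] - m[j + 1L] <= lsd) j <- j + 1L
    if (j > j_prev) {                       # maximal (not nested in previous)
      intervals[[length(intervals) + 1L]] <- c(i, j)
      j_prev <- j
    }
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lab <- character(n)
  for (k in seq_along(intervals)) {
    rng <- intervals[[k]][1]:intervals[[k]][2]
    lab[rng] <- paste0(lab[rng], letters_pool[k])
  }
  list(lsd = lsd, different = diff_mat,
       groups = data.frame(entry = names(m), mean = unname(m), letters = lab,
                           stringsAsFactors = FALSE))
}
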