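#' @title Plot-level phenotype tables for half-diallel trials
#'
#' @description
#' A `plot_table` is a long-format data frame of plot-level observations from
#' a balanced half-diallel trial grown as a randomized complete block design
#' (RCBD) in one or more environments. Each row is one plot of one entry
#' (a parent, coded `parent_a == parent_b`, or an F1 cross) for one trait.
#' Crosses are canonicalized so that `parent_a <= parent_b`; cross (i, j) and
#' (j, i) denote the same entry (no reciprocals in a half diallel).
#'
#' @name plot_table
NULL

.required_cols <- c("environment", "replicate", "parent_a", "parent_b",
                    "trait", "value")

#' Construct a plot table from raw columns
#'
#' Canonicalizes crosses (`parent_a <= parent_b`), checks values are finite
#' and rejects duplicate (environment, replicate, entry, trait) rows.
#'
#' @param df data frame with columns `environment`, `replicate`, `parent_a`,
#'   `parent_b` (integer parent indices in `1..p` or labels mappable to them),
#'   `trait`, `value`.
#' @param parent_levels optional character vector of parent labels whose order
#'   defines the 1-based parent indexing; default: sorted unique labels, with
#'   labels of the form `P<number>` ordered numerically.
#' @return a `plot_table` (data.frame) with integer `parent_a <= parent_b`.
#' @export
plot_table <- function(df, parent_levels = NULL) {
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  missing <- setdiff(.required_cols, names(df))
  if (length(missing) > 0L) {
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[.required_cols]
  if (!is.numeric(df$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$value)))))
    if (length(bad) > 0L) {
      stop("parse error: non-numeric value in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    df$value <- as.numeric(as.character(df$value))
  }
  if (any(!is.finite(df$value))) {
    stop("parse error: non-finite value in row(s) ",
         paste(utils::head(which(!is.finite(df$value)), 5L), collapse = ", "),
         call. = FALSE)
  }
  labs <- unique(c(as.character(df$parent_a), as.character(df$parent_b)))
  if (is.null(parent_levels)) {
    num <- suppressWarnings(as.numeric(sub("^[Pp]", "", labs)))
    parent_levels <- if (all(is.finite(num))) labs[order(num)] else sort(labs)
  }
  a <- match(as.character(df$parent_a), parent_levels)
  b <- match(as.character(df$parent_b), parent_levels)
  if (any(is.na(a)) || any(is.na(b))) {
    unknown <- setdiff(labs, parent_levels)
    stop("mapping error: unknown parent label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  df$parent_a <- pmin(a, b)
  df$parent_b <- pmax(a, b)
  df$environment <- as.character(df$environment)
  df$replicate <- as.character(df$replicate)
  df$trait <- as.character(df$trait)
  key <- paste(df$environment, df$replicate, df$parent_a, df$parent_b,
               df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate entry after canonicalization: env=%s rep=%s entry=(%d,%d) trait=%s",
      d$environment, d$replicate, d$parent_a, d$parent_b, d$trait),
      call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, parent_levels = parent_levels,
            class = c("plot_table", "data.frame"))
}

#' Read plot-level phenotypes from a delimited file
#'
#' Reads a comma- or tab-delimited UTF-8 file with header row
#' `environment, replicate, parent_a, parent_b, trait, value` (case
#' insensitive), one row per plot per trait, and returns a canonicalized
#' [plot_table].
#'
#' @param path path to the file.
#' @param sep field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param parent_levels passed to [plot_table()].
#' @return a `plot_table`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("environment,replicate,parent_a,parent_b,trait,value",
#'              "e1,r1,P1,P2,FY,40", "e1,r1,P1,P1,FY,35"), tf)
#' read_phenotypes(tf)
#' @export
read_phenotypes <- function(path, sep = NULL, parent_levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = "character")
  plot_table(df, parent_levels = parent_levels)
}

#' Write a plot table back to a delimited file
#'
#' Inverse of [read_phenotypes()]; parent indices are written as `P<i>`
#' labels. Reading the result back yields identical observations
#' (canonicalization is idempotent).
#'
#' @param table a `plot_table`.
#' @param path output path.
#' @param sep delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "plot_table"))
  out <- as.data.frame(table)
  out$parent_a <- paste0("P", out$parent_a)
  out$parent_b <- paste0("P", out$parent_b)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate the diallel design of a plot table
#'
#' Infers the number of parents p, environments and replicates, and confirms
#' the table is a fully balanced half diallel: all p(p+1)/2 entries (p parents
#' + p(p-1)/2 crosses) present exactly once in every (environment, replicate)
#' for every trait.
#'
#' @param table a `plot_table`.
#' @return a `diallel_design` list with fields `p`, `environments`,
#'   `replicates_per_env`, `n_entries`, `traits`, `parent_names`.
#' @export
validate_design <- function(table) {
  stopifnot(inherits(table, "plot_table"))
  if (nrow(table) == 0L) stop("empty plot table", call. = FALSE)
  p <- max(table$parent_b)
  envs <- unique(table$environment)
  reps <- sort(unique(table$replicate))
  traits <- unique(table$trait)
  n_entries <- p * (p + 1L) / 2L
  entries <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  want <- expand.grid(environment = envs, replicate = reps,
                      i = seq_len(p), trait = traits,
                      stringsAsFactors = FALSE)
  # every entry (i <= j), every env x rep x trait, exactly once
  grid <- expand.grid(e = seq_along(envs), r = seq_along(reps),
                      k = seq_len(nrow(entries)), t = seq_along(traits))
  want_key <- paste(envs[grid$e], reps[grid$r],
                    entries[grid$k, "row"], entries[grid$k, "col"],
                    traits[grid$t], sep = "\r")
  have_key <- paste(table$environment, table$replicate,
                    table$parent_a, table$parent_b, table$trait, sep = "\r")
  absent <- setdiff(want_key, have_key)
  extra <- setdiff(have_key, want_key)
  if (length(absent) > 0L || length(extra) > 0L) {
    fmt <- function(k) {
      f <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      sprintf("env=%s rep=%s entry=(%s,%s) trait=%s", f[1], f[2], f[3], f[4], f[5])
    }
    msg <- c(if (length(absent)) paste(" missing:",
                                       vapply(utils::head(absent, 5L), fmt, "")),
             if (length(extra)) paste(" unexpected:",
                                      vapply(utils::head(extra, 5L), fmt, "")))
    stop("imbalance error (balanced half diallel required):\n",
         paste(msg, collapse = "\n"), call. = FALSE)
  }
  pl <- attr(table, "parent_levels")
  structure(list(p = as.integer(p), environments = envs,
                 replicates_per_env = length(reps), replicates = reps,
                 n_entries = as.integer(n_entries), traits = traits,
                 parent_names = if (is.null(pl)) paste0("P", seq_len(p)) else pl),
            class = "diallel_design")
}

#' @export
print.diallel_design <- function(x, ...) {
  cat(sprintf(
    "Half-diallel design: p = %d parents, %d entries, %d environment(s), r = %d\n",
    x$p, x$n_entries, length(x$environments), x$replicates_per_env))
  invisible(x)
}

#' Symmetric table of entry means for one environment and trait
#'
#' Averages the r plot values of every entry; cell (i, j) holds the entry
#' mean of cross i x j (diagonal: parents).
#'
#' @param table a `plot_table`.
#' @param environment environment label to subset.
#' @param trait trait label to subset.
#' @return a `diallel_table`: symmetric p x p matrix with attributes
#'   `trait`, `environment`, `r` (replicates averaged over).
#' @export
entry_means <- function(table, environment, trait) {
  stopifnot(inherits(table, "plot_table"))
  sub <- table[table$environment == environment & table$trait == trait, ,
               drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("lookup error: no rows for environment='%s', trait='%s'",
                 environment, trait), call. = FALSE)
  }
  p <- max(sub$parent_b)
  r <- length(unique(sub$replicate))
  n_entries <- p * (p + 1) / 2
  if (nrow(sub) != n_entries * r) {
    stop("imbalance error: expected ", n_entries * r, " plots, got ",
         nrow(sub), call. = FALSE)
  }
  m <- matrix(NA_real_, p, p)
  agg <- tapply(sub$value, list(sub$parent_a, sub$parent_b), mean)
  for (i in seq_len(p)) for (j in i:p) {
    v <- agg[as.character(i), as.character(j)]
    if (is.na(v)) stop("imbalance error: entry (", i, ",", j, ") absent",
                       call. = FALSE)
    m[i, j] <- m[j, i] <- v
  }
  diallel_table(m, trait = trait, environment = environment, r = r)
}

#' Construct a diallel entry-mean table
#'
#' @param means symmetric p x p numeric matrix of entry means.
#' @param trait,environment labels.
#' @param r number of replicates each cell averages over.
#' @return a `diallel_table`.
#' @export
diallel_table <- function(means, trait = "trait", environment = "env", r = 1L) {
  means <- as.matrix(means)
  p <- nrow(means)
  stopifnot(p == ncol(means), p >= 2)
  if (!isSymmetric(unname(means), tol = 1e-10)) {
    stop("contract violation: entry-mean table must be symmetric",
         call. = FALSE)
  }
  structure(means, trait = trait, environment = environment, r = as.integer(r),
            class = c("diallel_table", class(means)))
}

#' @export
print.diallel_table <- function(x, digits = 3, ...) {
  cat(sprintf("Diallel entry means: p = %d, trait = %s, environment = %s\n",
              nrow(x), attr(x, "trait"), attr(x, "environment")))
  print(round(unclass(x), digits))
  invisible(x)
}

# internal: subset one environment (all traits intact)
.env_subset <- function(table, environment) {
  sub <- table[table$environment == environment, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("lookup error: unknown environment '", environment, "'",
         call. = FALSE)
  }
  sub
}
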