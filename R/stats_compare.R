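# Two-group statistical protocol: sample-size-gated normality
# assessment, the two-tailed Mann-Whitney U test, descriptive tables,
# shape-type proportions and the full West/East comparison report.

#' Sample-size-gated normality assessment
#'
#' Shapiro-Wilk for small samples (`n <= 50`), one-sample
#' Kolmogorov-Smirnov against a normal with the sample's own mean and SD
#' for large samples (`n > 50`).  The decision is "non-normal" iff
#' p < 0.05.
#'
#' @param values numeric sample, n >= 3.
#' @return A list with `test` ("shapiro" or "ks"), `statistic`, `p_value`
#'   and `decision` ("normal"/"non-normal").
#' @export
normality_gate <- function(values) {
  stopifnot(is.numeric(values), all(is.finite(values)))
  n <- length(values)
  if (n < 3L) stop("normality assessment needs at least 3 values")
  if (n <= 50L) {
    ht <- stats::shapiro.test(values)
    test <- "shapiro"
  } else {
    ht <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
    test <- "ks"
  }
  list(test = test, statistic = unname(ht$statistic),
       p_value = ht$p.value,
       decision = if (ht$p.value < 0.05) "non-normal" else "normal")
}

# U statistic for the first group from joint midranks.
u_statistic <- function(west, east) {
  n1 <- length(west)
  r <- rank(c(west, east))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

# Exact two-tailed p by enumeration of all C(n1 + n2, n1) group labelings
# of the joint midranks (valid with ties).
mwu_exact_p <- function(west, east) {
  n1 <- length(west)
  n2 <- length(east)
  r <- rank(c(west, east))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  u_obs <- u_statistic(west, east)
  eps <- 1e-9
  p_lo <- mean(u_all <= u_obs + eps)
  p_hi <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed for the first (west) group from joint midranks.  For
#' `min(n) <= 8` the two-tailed p-value comes from exact enumeration of
#' all group labelings (valid under ties); otherwise from the normal
#' approximation with tie-corrected variance (no continuity correction).
#'
#' @param west,east numeric samples.
#' @return An object of class `mwu_result`: `u_west`, `u_east`,
#'   `p_value`, `method`, `n_west`, `n_east`, `degenerate`.
#' @export
mann_whitney_u <- function(west, east) {
  stopifnot(length(west) > 0L, length(east) > 0L,
            all(is.finite(west)), all(is.finite(east)))
  n1 <- length(west)
  n2 <- length(east)
  u1 <- u_statistic(west, east)
  degenerate <- length(unique(c(west, east))) == 1L
  if (degenerate) {
    p <- 1
    method <- "degenerate"
  } else if (min(n1, n2) <= 8L) {
    p <- mwu_exact_p(west, east)
    method <- "exact"
  } else {
    nt <- n1 + n2
    ties <- table(c(west, east))
    tie_term <- sum(ties^3 - ties) / (nt * (nt - 1))
    v <- n1 * n2 / 12 * ((nt + 1) - tie_term)
    z <- (u1 - n1 * n2 / 2) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(u_west = u1, u_east = n1 * n2 - u1, p_value = p,
                 method = method, n_west = n1, n_east = n2,
                 degenerate = degenerate,
                 convention = "U reported for the first (west) group"),
            class = "mwu_result")
}

#' Descriptive statistics of one parameter
#'
#' @param values numeric sample (n >= 1).
#' @return A list with `n`, `mean`, `sd` (n-1 denominator; 0 with
#'   `sd_defined = FALSE` for a single value), `min`, `max`.
#' @export
describe_values <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(is.finite(values)))
  list(n = length(values), mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else 0,
       sd_defined = length(values) > 1L,
       min = min(values), max = max(values))
}

#' Counts and percentages of whistle shape types
#'
#' @param labels character vector of shape labels drawn from the six
#'   contour types.
#' @return A data frame with `type`, `count`, `percent` (rounded to two
#'   decimals); percentages sum to 100 within rounding.
#' @export
type_proportions <- function(labels) {
  types <- c("constant", "upsweep", "downsweep", "concave", "convex",
             "sinusoidal")
  if (length(labels) == 0L) stop("no shape labels supplied")
  bad <- setdiff(unique(labels), types)
  if (length(bad) > 0L) {
    stop("unknown shape labels: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(labels, levels = types))
  keep <- counts > 0
  data.frame(type = names(counts)[keep],
             count = as.integer(counts[keep]),
             percent = round(100 * as.integer(counts[keep]) /
                               length(labels), 2L),
             stringsAsFactors = FALSE)
}

#' Grouped samples of one acoustic parameter
#'
#' @param parameter parameter name.
#' @param west,east numeric samples for the two sub-regions.
#' @param units unit string for reports.
#' @return An object of class `grouped_samples`.
#' @export
grouped_samples <- function(parameter, west, east, units = "") {
  stopifnot(is.character(parameter), length(west) > 0L, length(east) > 0L,
            all(is.finite(west)), all(is.finite(east)))
  structure(list(parameter = parameter, west = west, east = east,
                 units = units), class = "grouped_samples")
}

#' Two-group comparison report
#'
#' For each parameter: per-group normality decisions (sample-size-gated),
#' the two-tailed Mann-Whitney U test, and group descriptive statistics.
#' Per-parameter p-values are reported without multiplicity correction at
#' a two-tailed alpha of 0.05, matching the conventional reporting of
#' such surveys; Holm correction is available behind a flag.
#'
#' @param grouped list of [grouped_samples()] objects.
#' @param alpha significance threshold (default 0.05).
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return An object of class `compare_report`: a list with `table` (data
#'   frame) and `details`.
#' @export
compare_report <- function(grouped, alpha = 0.05, p_adjust = "none") {
  if (length(grouped) == 0L) stop("no parameters to compare")
  stopifnot(all(vapply(grouped, inherits, TRUE, "grouped_samples")))
  details <- lapply(grouped, function(g) {
    nw <- normality_gate(g$west)
    ne <- normality_gate(g$east)
    mw <- mann_whitney_u(g$west, g$east)
    list(parameter = g$parameter, units = g$units,
         normality_west = nw, normality_east = ne, test = mw,
         west = describe_values(g$west), east = describe_values(g$east))
  })
  p_raw <- vapply(details, function(d) d$test$p_value, 0)
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  tab <- do.call(rbind, lapply(seq_along(details), function(i) {
    d <- details[[i]]
    data.frame(parameter = d$parameter, units = d$units,
               n_west = d$test$n_west, n_east = d$test$n_east,
               mean_west = d$west$mean, sd_west = d$west$sd,
               mean_east = d$east$mean, sd_east = d$east$sd,
               normality_west = d$normality_west$decision,
               normality_east = d$normality_east$decision,
               u_west = d$test$u_west, p_value = p_adj[i],
               significant = p_adj[i] < alpha,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, details = details, alpha = alpha,
                 p_adjust = p_adjust,
                 convention = "U reported for the first (west) group"),
            class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  cat("Two-group comparison (two-tailed Mann-Whitney U, alpha =",
      x$alpha, ")\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s %s: West %.1f ± %.1f vs East %.1f ± %.1f, U = %g, p = %.3g%s\n",
                tab$parameter[i], tab$units[i], tab$mean_west[i],
                tab$sd_west[i], tab$mean_east[i], tab$sd_east[i],
                tab$u_west[i], tab$p_value[i],
                if (tab$significant[i]) " *" else ""))
  }
  invisible(x)
}

#' Write a comparison report as JSON and a Markdown table
#'
#' @param report a [compare_report()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_compare_report <- function(report, dir) {
  stopifnot(inherits(report, "compare_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report$table, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  tab <- report$table
  lines <- c(
    "| Parameter | Units | West (mean ± SD) | East (mean ± SD) | U | p | Significant |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %.1f ± %.1f | %.1f ± %.1f | %g | %.3g | %s |",
            tab$parameter, tab$units, tab$mean_west, tab$sd_west,
            tab$mean_east, tab$sd_east, tab$u_west, tab$p_value,
            ifelse(tab$significant, "yes", "no")))
  writeLines(lines, file.path(dir, "comparison.md"))
  invisible(dir)
}

#' Read a monthly vessel-density table
#'
#' Expects a CSV with columns `month`, `region` (`West`/`East`) and
#' `hours_per_km2` (monthly vessel hours per square kilometre), the
#' format consumed by the traffic comparison.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_vessel_density <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("month", "region", "hours_per_km2")
  if (!all(need %in% names(df))) {
    stop("vessel-density CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Compare monthly vessel density between sub-regions
#'
#' Treats monthly values as sampling units and applies the same
#' normality-gated two-tailed Mann-Whitney U protocol used for the
#' acoustic parameters.
#'
#' @param density data frame from [read_vessel_density()].
#' @return A [compare_report()] with one row.
#' @export
compare_vessel_density <- function(density) {
  w <- density$hours_per_km2[density$region == "West"]
  e <- density$hours_per_km2[density$region == "East"]
  compare_report(list(grouped_samples("vessel_density", w, e,
                                      "h/km^2/month")))
}
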