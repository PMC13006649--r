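#' Construct an orthogonal experimental design with responses
#'
#' Wraps a run table (one row per experimental run) for Taguchi-style range
#' analysis. The design must be balanced: every level of every factor must
#' appear in the same number of runs. Unassigned array columns are simply
#' omitted from `factors`.
#'
#' @param runs a `data.frame` holding the factor columns and the response.
#' @param factors character vector of factor column names; defaults to all
#'   columns except `response`.
#' @param response name of the numeric response column.
#' @return an object of class `orthogonal_design`.
#' @export
orthogonal_design <- function(runs,
                              factors = setdiff(names(runs), response),
                              response = "response") {
  stopifnot(is.data.frame(runs))
  if (!response %in% names(runs))
    stop("response column '", response, "' not found", call. = FALSE)
  missing_f <- setdiff(factors, names(runs))
  if (length(missing_f) > 0)
    stop("factor column(s) not found: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  y <- runs[[response]]
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("responses must be finite numbers", call. = FALSE)
  for (f in factors) {
    counts <- table(runs[[f]])
    if (length(unique(counts)) != 1L)
      stop("design is unbalanced in factor '", f, "': level counts ",
           paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
           call. = FALSE)
  }
  structure(list(runs = runs, factors = factors, response = response),
            class = "orthogonal_design")
}

#' Per-level mean responses (the k table)
#'
#' For each factor j and level i, `k_ij` is the mean of the responses over
#' the runs where factor j is at level i.
#'
#' @param design an [orthogonal_design()].
#' @return a long-format `data.frame` with columns `factor`, `level`, `k`.
#' @export
level_means <- function(design) {
  stopifnot(inherits(design, "orthogonal_design"))
  y <- design$runs[[design$response]]
  out <- do.call(rbind, lapply(design$factors, function(f) {
    lev <- design$runs[[f]]
    means <- tapply(y, lev, mean)
    data.frame(factor = f, level = names(means), k = as.numeric(means),
               row.names = NULL)
  }))
  out
}

#' Ranges of the level means (the R statistic)
#'
#' `R_j = max_i k_ij - min_i k_ij`: how far the mean response moves across
#' the levels of factor j. Larger R means a more influential factor.
#'
#' @param k_table a [level_means()] table.
#' @return a named numeric vector of ranges, one per factor.
#' @export
doe_ranges <- function(k_table) {
  stopifnot(is.data.frame(k_table),
            all(c("factor", "level", "k") %in% names(k_table)))
  r <- tapply(k_table$k, k_table$factor, function(v) max(v) - min(v))
  # preserve the original factor order
  r[unique(k_table$factor)]
}

#' Rank factors and pick the optimal level combination
#'
#' Factors are ranked by R descending; the optimal level of each factor is
#' the one with the maximal level mean (response assumed
#' larger-is-better). Ties on the maximal mean are broken toward the
#' first-listed level, with a warning.
#'
#' @param k_table a [level_means()] table.
#' @return list with `ranking` (factor names, most influential first),
#'   `ranges` (named numeric) and `optimal_levels` (named character).
#' @export
rank_and_optimize <- function(k_table) {
  r <- doe_ranges(k_table)
  ranking <- names(sort(r, decreasing = TRUE))
  optimal <- vapply(unique(k_table$factor), function(f) {
    sub <- k_table[k_table$factor == f, ]
    best <- which(sub$k == max(sub$k))
    if (length(best) > 1L)
      warning("factor '", f, "': tie between levels ",
              paste(sub$level[best], collapse = ", "),
              "; taking the first", call. = FALSE)
    sub$level[best[1L]]
  }, character(1))
  list(ranking = ranking, ranges = r, optimal_levels = optimal)
}

#' Full range analysis of an orthogonal experiment
#'
#' Convenience wrapper computing level means, ranges, factor ranking and
#' optimal levels in one call.
#'
#' @param design an [orthogonal_design()].
#' @return an object of class `range_analysis`: list with `level_means`,
#'   `ranges`, `ranking`, `optimal_levels`.
#' @export
range_analysis <- function(design) {
  k <- level_means(design)
  opt <- rank_and_optimize(k)
  structure(list(level_means = k, ranges = opt$ranges,
                 ranking = opt$ranking, optimal_levels = opt$optimal_levels),
            class = "range_analysis")
}

#' @export
print.range_analysis <- function(x, ...) {
  cat("<range_analysis>\n")
  for (f in unique(x$level_means$factor)) {
    sub <- x$level_means[x$level_means$factor == f, ]
    cat(sprintf("  %-6s R = %.3g | ", f, x$ranges[[f]]))
    cat(paste(sprintf("k[%s] = %.3g", sub$level, sub$k), collapse = "  "),
        "\n")
  }
  cat("  ranking:", paste(x$ranking, collapse = " > "), "\n")
  cat("  optimal:",
      paste(sprintf("%s = %s", names(x$optimal_levels), x$optimal_levels),
            collapse = ", "), "\n")
  invisible(x)
}

#' Specific fluorescence intensity
#'
#' Cellular fluorescence normalized to biomass: the sfGFP expression
#' capacity per unit of OD600.
#'
#' @param cellular_flu cellular fluorescence intensity (au).
#' @param od600 optical density at 600 nm (> 0).
#' @return specific fluorescence intensity (au), vectorized.
#' @export
specific_fluorescence <- function(cellular_flu, od600) {
  if (any(!is.finite(od600)) || any(od600 <= 0))
    stop("'od600' must be > 0", call. = FALSE)
  cellular_flu / od600
}

#' Percent change of a against reference b
#'
#' @param a new value.
#' @param b reference value (> 0).
#' @return `(a - b) / b * 100`, vectorized.
#' @export
percent_change <- function(a, b) {
  if (any(!is.finite(b)) || any(b <= 0))
    stop("reference 'b' must be > 0", call. = FALSE)
  (a - b) / b * 100
}

#' Bundled L9(3^4) induction-optimization experiment
#'
#' Loads the packaged nine-run orthogonal experiment on sfGFP induction
#' conditions: induction start time (`IT`, h), IPTG addition amount (`IA`,
#' mmol/L) and the DO-stat feed start/stop threshold pair (`SSH`,
#' \%/\%), with the measured specific fluorescence intensity (au) as the
#' response. The fourth column of the L9 array was left unassigned.
#'
#' @return an [orthogonal_design()] with factors `IT`, `IA`, `SSH` and
#'   response `specific_flu`; the run table also carries the `batch` label.
#' @export
induction_l9 <- function() {
  path <- system.file("extdata", "induction_l9.csv", package = "neurostat",
                      mustWork = TRUE)
  runs <- utils::read.csv(path, colClasses = c(batch = "character",
                                               IT = "character",
                                               IA = "character",
                                               SSH = "character",
                                               specific_flu = "numeric"))
  orthogonal_design(runs, factors = c("IT", "IA", "SSH"),
                    response = "specific_flu")
}
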