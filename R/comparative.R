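#' Empirical survivor curve of a trait
#'
#' For a trait across species, the survivor curve gives the fraction of
#' species whose trait value strictly exceeds the abscissa value. Missing
#' values are excluded and their count reported.
#'
#' @param values numeric trait values (missing allowed, all-missing is an
#'   error).
#' @param group optional label for the group of species.
#' @return An object of class `"deb_survivor"`: a list with the sorted
#'   `values`, group label, `n`, `n_missing`, and `S`, the survivor function
#'   (a function of a vector of abscissa values).
#' @examples
#' sc <- survivor_curve(c(1, 2, 3, 4))
#' sc$S(2.5)  # 0.5
#' @export
survivor_curve <- function(values, group = NA_character_) {
  n_missing <- sum(!is.finite(values))
  v <- sort(values[is.finite(values)])
  if (length(v) == 0L)
    stop("survivor_curve: no non-missing values", call. = FALSE)
  S <- function(x) vapply(x, function(xi) mean(v > xi), numeric(1))
  structure(list(values = v, group = group, n = length(v),
                 n_missing = n_missing, S = S),
            class = "deb_survivor")
}

#' @export
print.deb_survivor <- function(x, ...) {
  cat("Survivor curve", if (!is.na(x$group)) paste0("(", x$group, ")"),
      ": n =", x$n, ", missing =", x$n_missing,
      ", range [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "]\n")
  invisible(x)
}

#' Log-log scaling fit
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`: the standard
#' cross-species allometric regression. Both variables must be strictly
#' positive; offending rows are reported.
#'
#' @param x,y paired positive values (at least 3 complete pairs).
#' @return An object of class `"scaling_fit"`: `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `r_squared`, `n`, and the underlying `lm`
#'   fit.
#' @export
loglog_slope <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  bad <- which(keep & (x <= 0 | y <= 0))
  if (length(bad))
    stop("loglog_slope: non-positive values in rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("loglog_slope: need at least 3 complete pairs", call. = FALSE)
  fit <- stats::lm(ly ~ lx, data = data.frame(lx = log10(x), ly = log10(y)))
  # summary.lm warns on noiseless power laws ("essentially perfect fit");
  # zero standard errors are the correct answer there, not a problem
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- sm$coefficients
  structure(list(slope = cf["lx", "Estimate"],
                 intercept = cf["(Intercept)", "Estimate"],
                 se_slope = cf["lx", "Std. Error"],
                 se_intercept = cf["(Intercept)", "Std. Error"],
                 r_squared = sm$r.squared,
                 n = length(x), fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "log10-log10 OLS fit (n = %d): slope %.4f (SE %.4f), intercept %.4f, R^2 %.4f\n",
    x$n, x$slope, x$se_slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Per-taxon medians of a trait
#'
#' Median trait value per taxonomic group, over non-missing values, with
#' group sizes. Medians of even-sized groups are the mean of the central
#' pair.
#'
#' @param table a [build_trait_table()] data frame.
#' @param trait trait (column) name.
#' @param by grouping column, default `"taxon"`.
#' @return Data frame with columns `group`, `median`, `n`, `n_missing`.
#' @export
group_medians <- function(table, trait, by = "taxon") {
  if (!trait %in% names(table))
    stop("unknown trait name: '", trait, "'", call. = FALSE)
  if (!by %in% names(table))
    stop("unknown grouping column: '", by, "'", call. = FALSE)
  groups <- split(table[[trait]], table[[by]])
  out <- data.frame(
    group = names(groups),
    median = vapply(groups, function(v) stats::median(v, na.rm = TRUE),
                    numeric(1)),
    n = vapply(groups, function(v) sum(is.finite(v)), integer(1)),
    n_missing = vapply(groups, function(v) sum(!is.finite(v)), integer(1)),
    row.names = NULL)
  out[order(out$group), , drop = FALSE]
}

#' Lifetime neonate mass vs ultimate weight equality diagnostic
#'
#' Across many taxa the lifetime cumulated neonate mass production roughly
#' equals the ultimate wet weight. This diagnostic reports, per species, the
#' ratio `N_mass_life / Ww_i`, plus the geometric-mean ratio and the log-log
#' scaling fit of `N_mass_life` against `Ww_i` (slope 1 and ratio 1 indicate
#' equality). It is descriptive: no reference line is fitted.
#'
#' @param table a [build_trait_table()] data frame.
#' @return List with `ratios` (named per species), `geometric_mean_ratio`,
#'   and `fit` (a [loglog_slope()] object), plus `n_missing`.
#' @export
equality_diagnostic <- function(table) {
  ok <- is.finite(table$N_mass_life) & is.finite(table$Ww_i) &
    table$N_mass_life > 0 & table$Ww_i > 0
  ratios <- stats::setNames(table$N_mass_life / table$Ww_i,
                            table$species_id)
  list(ratios = ratios,
       geometric_mean_ratio = exp(mean(log(ratios[ok]))),
       fit = loglog_slope(table$Ww_i[ok], table$N_mass_life[ok]),
       n_missing = sum(!ok))
}
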