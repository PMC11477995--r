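# Embedded experimental pKa dataset (para-substituted aniline radical
# cations and anilinium ions, literature values) and the evaluation
# statistics: delta pKa, RMSE, RMSE aggregation, calculated-vs-experimental
# regression.

# One row per substituent x system; multiple literature values kept as-is.
.exp_rows <- list(
  list("H",     "radical_cation", c(7.05),             c("B35")),
  list("C4H9",  "radical_cation", c(8.2),              c("B7")),
  list("CF3",   "radical_cation", c(4.8),              c("B7")),
  list("CH3",   "radical_cation", c(8.5),              c("B36")),
  list("OCH3",  "radical_cation", c(9.6),              c("B7")),
  list("CN",    "radical_cation", c(4),                c("B7")),
  list("COCH3", "radical_cation", c(6.1),              c("B7")),
  list("I",     "radical_cation", c(7.1),              c("B7")),
  list("NH2",   "radical_cation", c(12),               c("B7")),
  list("SO3-",  "radical_cation", c(5.8),              c("B7")),
  list("H",     "anilinium",      c(4.62, 4.58),       c("B37", "B38")),
  list("C4H9",  "anilinium",      c(4.95),             c("B34")),
  list("CF3",   "anilinium",      c(2.92, 2.75, 2.57), c("B39", "B40", "B41")),
  list("CH3",   "anilinium",      c(5.12),             c("B37")),
  list("OCH3",  "anilinium",      c(5.29),             c("B37")),
  list("CN",    "anilinium",      c(1.75, 1.82),       c("B42", "B43")),
  list("COCH3", "anilinium",      c(2.19, 2.26),       c("B42", "B43")),
  list("I",     "anilinium",      c(3.78),             c("B44")),
  list("NH2",   "anilinium",      c(5.94, 6.2),        c("B45", "B42")),
  list("SO3-",  "anilinium",      c(3.25, 2.93, 3.32), c("B46", "B47", "B48"))
)

#' Average literature pKa values for one compound
#'
#' Arithmetic mean; applied whenever two or more literature values exist
#' (a single value is returned unchanged).
#'
#' @param values non-empty numeric vector of literature pKa values.
#' @return mean pKa.
#' @export
average_experimental_pka <- function(values) {
  if (length(values) == 0) {
    stop("cannot average an empty value list", call. = FALSE)
  }
  mean(values)
}

#' The embedded experimental pKa dataset
#'
#' Literature aqueous pKa values for ten para-substituted aniline radical
#' cations (R-PhNH2·+, one value each) and the corresponding anilinium
#' ions (R-PhNH3+, one to three values each, 18 values in total).
#' `pka_exp` is the per-compound arithmetic mean of the literature values.
#'
#' @param system optional filter: `"radical_cation"` or `"anilinium"`.
#' @return data.frame with columns `substituent`, `system`, `n_values`,
#'   `pka_exp`, and list-columns `values` and `references`.
#' @export
#' @examples
#' experimental_pka_table("radical_cation")
experimental_pka_table <- function(system = NULL) {
  tab <- data.frame(
    substituent = vapply(.exp_rows, `[[`, character(1), 1),
    system = vapply(.exp_rows, `[[`, character(1), 2),
    n_values = vapply(.exp_rows, function(r) length(r[[3]]), integer(1)),
    pka_exp = vapply(.exp_rows, function(r) average_experimental_pka(r[[3]]),
                     numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$values <- I(lapply(.exp_rows, `[[`, 3))
  tab$references <- I(lapply(.exp_rows, `[[`, 4))
  if (!is.null(system)) {
    system <- match.arg(system, c("radical_cation", "anilinium"))
    tab <- tab[tab$system == system, , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

#' Root-mean-square error of calculated vs experimental pKa
#'
#' `sqrt( sum((calc_i - exp_i)^2) / n )` over paired vectors.
#'
#' @param calc calculated pKa values.
#' @param exp experimental pKa values, same length.
#' @return RMSE (dimensionless).
#' @export
pka_rmse <- function(calc, exp) {
  if (length(calc) != length(exp) || length(calc) == 0) {
    stop("calc and exp must be non-empty vectors of equal length",
         call. = FALSE)
  }
  sqrt(mean((calc - exp)^2))
}

#' Aggregate RMSE values across method combinations
#'
#' Mean and standard deviation of a set of RMSE values (one per
#' model/method combination). The standard deviation uses the sample
#' (n-1) denominator by default; `type = "population"` divides by n.
#'
#' @param rmse_values numeric vector of RMSE values (>= 1; >= 2 for a
#'   finite standard deviation).
#' @param type `"sample"` or `"population"`.
#' @return named list with `rmse_aver`, `rmse_std` and the `type` used.
#' @export
rmse_aggregate <- function(rmse_values, type = c("sample", "population")) {
  type <- match.arg(type)
  if (length(rmse_values) == 0) {
    stop("need at least one RMSE value", call. = FALSE)
  }
  m <- mean(rmse_values)
  s <- if (type == "sample") stats::sd(rmse_values)
       else sqrt(mean((rmse_values - m)^2))
  list(rmse_aver = m, rmse_std = s, type = type)
}

#' Regression of calculated on experimental pKa
#'
#' Ordinary least squares with the calculated pKa as response and the
#' experimental pKa as predictor (calculated values on the y-axis), the
#' orientation used to judge a method by its slope (ideal 1), intercept
#' (ideal 0) and squared Pearson correlation.
#'
#' @param calc calculated pKa values (>= 3 points).
#' @param exp experimental pKa values, same length, non-degenerate
#'   variance.
#' @return named list with `slope`, `intercept`, `r_squared`.
#' @export
regression_calc_vs_exp <- function(calc, exp) {
  if (length(calc) != length(exp) || length(calc) < 3) {
    stop("need >= 3 paired points", call. = FALSE)
  }
  if (stats::var(exp) == 0) {
    stop("experimental values have zero variance", call. = FALSE)
  }
  fit <- stats::lm(calc ~ exp)
  r2 <- if (stats::var(calc) == 0) 1 else stats::cor(calc, exp)^2
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

.calc_frame <- function(results) {
  if (is.data.frame(results)) {
    need <- c("substituent", "system", "pka_calc")
    if (!all(need %in% names(results))) {
      stop("results data.frame needs columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    return(results[, need])
  }
  stop("results must be a data.frame(substituent, system, pka_calc)",
       call. = FALSE)
}

#' Benchmark a set of calculated pKa values
#'
#' Matches each calculated value to exactly one experimental entry by
#' substituent and system, then reports the per-compound absolute error
#' `delta = |calc - exp|`, the RMSE over the matched set, delta summary
#' statistics and the calculated-vs-experimental regression, together
#' with grouping metadata (approach, correction, protocol, water model)
#' so combination matrices can be compared.
#'
#' @param results data.frame with columns `substituent`, `system`,
#'   `pka_calc` (one row per compound).
#' @param table experimental reference table; defaults to the embedded
#'   dataset of [experimental_pka_table()].
#' @param approach,correction,protocol,water_model optional grouping
#'   metadata echoed into the report.
#' @return object of class `benchmark_report`.
#' @export
benchmark_run <- function(results, table = experimental_pka_table(),
                          approach = NULL, correction = NULL,
                          protocol = NULL, water_model = NULL) {
  calc <- .calc_frame(results)
  key <- paste(calc$substituent, calc$system, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate results for: ",
         paste(unique(key[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  }
  tkey <- paste(table$substituent, table$system, sep = "/")
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    stop("no experimental entry for: ",
         paste(key[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  per <- data.frame(
    substituent = calc$substituent,
    system = calc$system,
    pka_calc = calc$pka_calc,
    pka_exp = table$pka_exp[idx],
    stringsAsFactors = FALSE
  )
  per$delta <- abs(per$pka_calc - per$pka_exp)
  reg <- if (nrow(per) >= 3 && stats::var(per$pka_exp) > 0) {
    regression_calc_vs_exp(per$pka_calc, per$pka_exp)
  } else {
    list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_)
  }
  structure(list(
    per_compound = per,
    rmse = pka_rmse(per$pka_calc, per$pka_exp),
    delta_mean = mean(per$delta),
    delta_min = min(per$delta),
    delta_max = max(per$delta),
    regression = reg,
    metadata = list(approach = approach, correction = correction,
                    protocol = protocol, water_model = water_model,
                    n = nrow(per))
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, digits = 3, ...) {
  md <- x$metadata
  tag <- paste(Filter(Negate(is.null),
                      md[c("approach", "correction", "protocol",
                           "water_model")]), collapse = "/")
  cat(sprintf("<benchmark_report> %d compounds%s\n", md$n,
              if (nzchar(tag)) paste0("  [", tag, "]") else ""))
  per <- x$per_compound
  per$pka_calc <- round(per$pka_calc, digits)
  per$pka_exp <- round(per$pka_exp, digits)
  per$delta <- round(per$delta, digits)
  print(per, row.names = FALSE)
  cat(sprintf("  RMSE = %.*f;  delta mean/min/max = %.*f / %.*f / %.*f\n",
              digits, x$rmse, digits, x$delta_mean, digits, x$delta_min,
              digits, x$delta_max))
  if (!is.na(x$regression$slope)) {
    cat(sprintf("  regression: S = %.*f, I = %.*f, r^2 = %.*f\n",
                digits, x$regression$slope, digits, x$regression$intercept,
                digits, x$regression$r_squared))
  }
  invisible(x)
}
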