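#' Orthogonality diagnostics of a choice design
#'
#' Computes pairwise Pearson correlations between the effect-coded design
#' columns over all profile rows. Between-attribute correlations near zero
#' indicate an (approximately) orthogonal design; within-attribute columns
#' of a 3+ level attribute are correlated by construction of effect coding
#' and are reported separately. Constant columns have undefined
#' correlation and are flagged rather than given a number.
#'
#' @param design a `dce_design`, or an effect-coded matrix.
#' @param warn_threshold warn when the maximum absolute between-attribute
#'   correlation exceeds this (default 0.3); inspection aid, never a hard
#'   failure.
#' @return a list with `correlation` (p x p matrix, `NA` where undefined),
#'   `max_abs_offdiag`, `max_abs_between_attributes`, and
#'   `constant_columns` (labels of zero-variance columns).
#' @export
orthogonality_report <- function(design, warn_threshold = 0.3) {
  if (inherits(design, "dce_design")) {
    X <- design$model_matrix
    groups <- effect_column_groups(design$space)
  } else {
    X <- as.matrix(design)
    groups <- NULL
  }
  if (ncol(X) < 2L) stop("need at least 2 design columns", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  const <- sds == 0
  R <- matrix(NA_real_, ncol(X), ncol(X),
              dimnames = list(colnames(X), colnames(X)))
  ok <- which(!const)
  if (length(ok) >= 2L)
    R[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  diag(R) <- 1
  off <- abs(R[upper.tri(R)])
  max_off <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  max_between <- NA_real_
  if (!is.null(groups)) {
    between <- outer(groups, groups, "!=") & upper.tri(R)
    vals <- abs(R[between])
    if (any(!is.na(vals))) max_between <- max(vals, na.rm = TRUE)
    if (is.finite(max_between) && max_between > warn_threshold)
      warning("maximum between-attribute |r| = ",
              format(max_between, digits = 3), " exceeds ",
              warn_threshold, call. = FALSE)
  }
  list(correlation = R,
       max_abs_offdiag = max_off,
       max_abs_between_attributes = max_between,
       constant_columns = colnames(X)[const])
}

# attribute index of each effect-coded column
effect_column_groups <- function(space) {
  rep(seq_len(space$n_attributes), space$levels_per_attribute - 1L)
}

#' Level-balance diagnostics of a choice design
#'
#' Tallies how often each attribute level appears across all `S * J`
#' profile rows. Perfect balance means every level of an L-level attribute
#' appears `S * J / L` times, attainable when `S` is divisible by `L`.
#'
#' @param design a `dce_design`.
#' @param tolerance maximum allowed deviation (profiles) from the ideal
#'   count before a level is flagged as imbalanced (default 1).
#' @return a data frame with columns `attribute`, `level`, `count`,
#'   `proportion`, `ideal`, `deviation`, `balanced`.
#' @export
level_balance_report <- function(design, tolerance = 1) {
  stopifnot(inherits(design, "dce_design"))
  space <- design$space
  n <- nrow(design$profiles)
  out <- do.call(rbind, lapply(seq_len(space$n_attributes), function(i) {
    a <- space$attributes[[i]]
    L <- length(a$levels)
    cnt <- tabulate(design$profiles[, i], nbins = L)
    data.frame(attribute = names(space$attributes)[i],
               level = a$levels,
               count = cnt,
               proportion = cnt / n,
               ideal = n / L,
               deviation = abs(cnt - n / L),
               stringsAsFactors = FALSE)
  }))
  out$balanced <- out$deviation <= tolerance
  rownames(out) <- NULL
  out
}

#' Full diagnostic report for a choice design
#'
#' Aggregates the checks applied to a finished design: pairwise
#' correlations of the effect-coded columns (orthogonality), level
#' frequencies and proportions (balance), per-set utility-balance score
#' gaps, and per-set dominant-alternative flags.
#'
#' @param design a `dce_design`.
#' @param balance_tolerance level-count tolerance for
#'   [level_balance_report()].
#' @param correlation_warn threshold for [orthogonality_report()].
#' @return an object of class `dce_diagnostics`; convert to a plain list
#'   for JSON export with [diagnostics_to_list()].
#' @export
design_report <- function(design, balance_tolerance = 1,
                          correlation_warn = 0.3) {
  stopifnot(inherits(design, "dce_design"))
  orth <- orthogonality_report(design, warn_threshold = correlation_warn)
  structure(list(
    d_error = as.numeric(design$d_error),
    orthogonality = orth,
    level_balance = level_balance_report(design, tolerance = balance_tolerance),
    balance_gaps = set_score_gaps(design),
    dominance_flags = set_dominance_flags(design),
    balance_threshold = design$config$balance_threshold,
    seed = design$seed
  ), class = "dce_diagnostics")
}

#' @export
print.dce_diagnostics <- function(x, ...) {
  cat("Design diagnostics\n")
  cat("  D-error: ", format(x$d_error, digits = 6), "\n", sep = "")
  cat("  max |r| between attributes: ",
      format(x$orthogonality$max_abs_between_attributes, digits = 3),
      "   (overall off-diagonal: ",
      format(x$orthogonality$max_abs_offdiag, digits = 3), ")\n", sep = "")
  lb <- x$level_balance
  cat("  level balance: ", sum(lb$balanced), "/", nrow(lb),
      " levels within tolerance; max deviation ",
      format(max(lb$deviation), digits = 3), " profiles\n", sep = "")
  cat("  within-set score gaps: max ", format(max(x$balance_gaps), digits = 3),
      " (threshold ", x$balance_threshold, ")\n", sep = "")
  cat("  sets with a dominant alternative: ",
      sum(!is.na(x$dominance_flags)), "\n", sep = "")
  invisible(x)
}

#' Convert diagnostics to a JSON-ready list
#'
#' Plain-list representation of a [design_report()] suitable for
#' `jsonlite::write_json()`; reading it back reconstructs every number.
#'
#' @param report a `dce_diagnostics`.
#' @return a named list of scalars, vectors and data frames.
#' @export
diagnostics_to_list <- function(report) {
  stopifnot(inherits(report, "dce_diagnostics"))
  list(
    schema_version = 1L,
    d_error = report$d_error,
    max_abs_between_attribute_correlation =
      report$orthogonality$max_abs_between_attributes,
    max_abs_offdiag_correlation = report$orthogonality$max_abs_offdiag,
    constant_columns = report$orthogonality$constant_columns,
    correlation = report$orthogonality$correlation,
    level_balance = report$level_balance,
    balance_gaps = unname(report$balance_gaps),
    dominance_flags = unname(report$dominance_flags),
    balance_threshold = report$balance_threshold,
    seed = report$seed
  )
}
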