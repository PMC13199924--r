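#' Write a design (and companions) to CSV + JSON
#'
#' The CSV is the wide human-readable design: one row per alternative
#' with `set`, `alternative` and one column of level text per attribute.
#' The JSON carries everything needed to reconstruct the run: per-profile
#' scores, D-error, seed, the search configuration echo, and (when
#' given) the block assignment and the consistency set.
#'
#' @param design a `dce_design`.
#' @param csv_path,json_path output paths.
#' @param blocks optional `dce_blocks` to embed.
#' @param consistency optional `dce_consistency_set` to embed.
#' @return invisibly, the JSON list that was written.
#' @export
write_design <- function(design, csv_path, json_path = NULL,
                         blocks = NULL, consistency = NULL) {
  stopifnot(inherits(design, "dce_design"))
  utils::write.csv(as.data.frame(design), csv_path, row.names = FALSE)
  meta <- list(
    schema_version = 1L,
    d_error = as.numeric(design$d_error),
    seed = design$seed,
    config = design$config[c("J", "S", "balance_threshold",
                             "enforce_dominance", "n_random_starts",
                             "max_outer_iterations")],
    priors = design$priors,
    profile_scores = unname(score_profiles(design$profiles, design$space)),
    set_gaps = unname(set_score_gaps(design)),
    feasible = design$feasible
  )
  if (!is.null(blocks))
    meta$block_assignment <- blocks$assignment
  if (!is.null(consistency))
    meta$consistency_profiles <- unname(consistency$profiles)
  if (!is.null(json_path))
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(meta)
}

#' Read a design back from its CSV export
#'
#' Reconstructs a `dce_design` from the wide CSV written by
#' [write_design()], matching level text back to level indices; the
#' D-error is recomputed from the profiles. When the JSON companion is
#' given, the embedded block assignment and consistency set are restored
#' too.
#'
#' @param csv_path path to the design CSV.
#' @param space the [dce_space()] the design was built on.
#' @param json_path optional path to the JSON companion.
#' @return a `dce_design`, or (with `json_path`) a list with elements
#'   `design`, `blocks`, `consistency`.
#' @export
read_design <- function(csv_path, space, json_path = NULL) {
  stopifnot(inherits(space, "dce_space"))
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- c("set", "alternative", names(space$attributes))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$set, df$alternative), , drop = FALSE]
  J <- length(unique(df$alternative))
  profiles <- matrix(NA_integer_, nrow(df), space$n_attributes,
                     dimnames = list(NULL, names(space$attributes)))
  for (i in seq_len(space$n_attributes)) {
    nm <- names(space$attributes)[i]
    m <- match(df[[nm]], space$attributes[[i]]$levels)
    if (anyNA(m))
      stop("unknown level text in column '", nm, "': ",
           paste(unique(df[[nm]][is.na(m)]), collapse = ", "),
           call. = FALSE)
    profiles[, i] <- m
  }
  cfg <- list(J = J, S = nrow(df) %/% J, priors = numeric(space$n_params),
              balance_threshold = NA_real_, enforce_dominance = NA,
              n_random_starts = NA_integer_, max_outer_iterations = NA_integer_,
              seed = NULL)
  meta <- NULL
  if (!is.null(json_path)) {
    meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    cfg$balance_threshold <- meta$config$balance_threshold
    cfg$enforce_dominance <- meta$config$enforce_dominance
    cfg$seed <- meta$seed
  }
  derr <- d_error(effect_code(profiles, space), J = J)
  design <- new_dce_design(profiles, space, d_error = derr,
                           priors = numeric(space$n_params),
                           seed = cfg$seed, config = cfg,
                           provenance = list(source = csv_path),
                           feasible = TRUE)
  if (is.null(json_path)) return(design)
  blocks <- NULL
  if (!is.null(meta$block_assignment)) {
    assignment <- as.integer(meta$block_assignment)
    dev <- block_level_deviation(design, assignment, max(assignment))
    blocks <- new_dce_blocks(design, assignment, max(assignment), dev,
                             tolerance = NA_real_, feasible = TRUE,
                             seed = NULL)
  }
  consistency <- NULL
  if (!is.null(meta$consistency_profiles)) {
    m <- meta$consistency_profiles
    if (is.list(m)) m <- do.call(rbind, lapply(m, as.integer))
    m <- matrix(as.integer(m), ncol = space$n_attributes)
    dimnames(m) <- list(NULL, names(space$attributes))
    consistency <- structure(list(profiles = m,
                                  dominant = find_dominant(m, space)),
                             class = "dce_consistency_set")
  }
  list(design = design, blocks = blocks, consistency = consistency)
}

#' Write a response panel to CSV
#'
#' Long format, one row per answered choice set: `respondent`, `block`,
#' `set` (0 = consistency task) and `choice` written as a 0-based
#' alternative index, matching [read_responses()] bit-for-bit.
#'
#' @param panel a `dce_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(respondent = panel$respondent, block = panel$block,
                    set = panel$set, choice = panel$choice - 1L)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate survey responses
#'
#' Reads a long-format response export (`respondent`, `block`, `set`,
#' `choice` with a header row). Choices may be 0-based integers or the
#' letters A/B/C...; both map to 1-based indices internally. Validation
#' errors (unknown set ids, out-of-range choices, duplicated
#' respondent-set rows) stop with the offending rows named. Respondents
#' missing any choice set assigned to their block (or the consistency
#' task, when one is expected) are incomplete: they are dropped with a
#' message and counted in the `"n_incomplete"` attribute.
#'
#' @param path path to the CSV.
#' @param design the `dce_design` the responses refer to.
#' @param blocks optional `dce_blocks`; enables the completeness check
#'   per block.
#' @param expect_consistency whether every respondent must have answered
#'   the consistency task, set id 0 (default `TRUE` when any set-0 row is
#'   present).
#' @return a `dce_panel` data.frame.
#' @export
read_responses <- function(path, design, blocks = NULL,
                           expect_consistency = NULL) {
  stopifnot(inherits(design, "dce_design"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("respondent", "block", "set", "choice")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("response file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ch <- as.character(df$choice)
  num <- suppressWarnings(as.integer(ch))
  lett <- match(toupper(trimws(ch)), LETTERS)
  choice <- ifelse(!is.na(num), num + 1L, lett)
  bad <- which(is.na(choice) | choice < 1L | choice > design$J)
  if (length(bad))
    stop("unparseable or out-of-range choice value(s) '",
         paste(unique(ch[bad]), collapse = "', '"), "' at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  df$choice <- as.integer(choice)
  bad_set <- !(df$set %in% c(0L, seq_len(design$S)))
  if (any(bad_set))
    stop("unknown choice-set id(s): ",
         paste(unique(df$set[bad_set]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[, c("respondent", "set")]))
    stop("duplicated (respondent, set) rows in response file", call. = FALSE)
  if (is.null(expect_consistency)) expect_consistency <- any(df$set == 0L)

  # completeness: every respondent must cover their assigned sets
  incomplete <- character(0)
  for (r in unique(df$respondent)) {
    rows <- df[df$respondent == r, , drop = FALSE]
    b <- rows$block[1L]
    expected <- if (!is.null(blocks)) {
      if (!b %in% seq_len(blocks$n_blocks))
        stop("respondent ", r, " has unknown block id ", b, call. = FALSE)
      blocks$block_sets[[b]]
    } else sort(unique(df$set[df$set > 0L]))
    if (expect_consistency) expected <- c(0L, expected)
    if (!all(expected %in% rows$set)) incomplete <- c(incomplete, r)
  }
  if (length(incomplete)) {
    message(length(incomplete), " excluded: incomplete")
    df <- df[!(df$respondent %in% incomplete), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "n_incomplete") <- length(incomplete)
  class(df) <- c("dce_panel", "data.frame")
  df
}

#' Write a tidy estimation-results CSV
#'
#' One row per non-reference attribute level:
#' `term, attribute, level, beta, se, or, ci_low, ci_high`.
#'
#' @param fit a `dce_clogit`.
#' @param path output path.
#' @param json_path optional JSON companion with fit metadata
#'   (log-likelihood, counts, convergence).
#' @export
write_estimation <- function(fit, path, json_path = NULL) {
  tab <- odds_summary(fit)
  out <- tab[, c("term", "attribute", "level", "estimate", "se",
                 "or", "ci_low", "ci_high")]
  names(out)[names(out) == "estimate"] <- "beta"
  utils::write.csv(out, path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      loglik = fit$loglik, null_loglik = fit$null_loglik,
      n_respondents = fit$n_respondents, n_choices = fit$n_choices,
      converged = fit$converged, iterations = fit$iterations,
      level = fit$level
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Run the full design pipeline from an instrument file
#'
#' Loads the instrument, runs the constrained D-efficient search, builds
#' diagnostics, blocks the design, constructs the consistency set, and
#' writes every artifact (design CSV/JSON, diagnostics JSON, one survey
#' CSV per block) into `out_dir`. Counts are logged at each stage.
#'
#' @param instrument_path YAML instrument file (see [read_instrument()]).
#' @param out_dir output directory, created if needed.
#' @param seed integer seed for the search and the blocking.
#' @param n_blocks number of blocks (default from the instrument file's
#'   design block, else 2).
#' @param balance_threshold within-set score-gap limit (default from the
#'   instrument file, else 4.5).
#' @param ... further arguments to [search_design()].
#' @return invisibly, a list with `space`, `design`, `report`, `blocks`,
#'   `consistency`, `surveys` and the written `paths`.
#' @export
run_design_pipeline <- function(instrument_path, out_dir, seed = NULL,
                                n_blocks = NULL, balance_threshold = NULL,
                                ...) {
  space <- read_instrument(instrument_path)
  des_cfg <- attr(space, "design")
  if (is.null(n_blocks))
    n_blocks <- if (!is.null(des_cfg$n_blocks)) des_cfg$n_blocks else 2L
  if (is.null(balance_threshold))
    balance_threshold <- if (!is.null(des_cfg$balance_threshold))
      des_cfg$balance_threshold else 4.5
  if (is.null(seed) && !is.null(des_cfg$seed)) seed <- des_cfg$seed
  message("instrument: ", space$n_attributes, " attributes, ",
          space$n_profiles, " full-factorial profiles, p = ",
          space$n_params)
  design <- search_design(space, balance_threshold = balance_threshold,
                          seed = seed, ...)
  message("design: ", design$S, " sets x ", design$J,
          " alternatives, D-error ", format(design$d_error, digits = 5))
  report <- design_report(design)
  blocks <- block_design(design, n_blocks = n_blocks,
                         seed = if (is.null(seed)) NULL else seed + 1L)
  cons <- consistency_set(space)
  surveys <- render_block_survey(design, blocks, cons)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    design_csv = file.path(out_dir, "design.csv"),
    design_json = file.path(out_dir, "design.json"),
    diagnostics_json = file.path(out_dir, "diagnostics.json"),
    surveys = file.path(out_dir, sprintf("survey_block%d.csv",
                                         seq_len(n_blocks))))
  write_design(design, paths$design_csv, paths$design_json,
               blocks = blocks, consistency = cons)
  jsonlite::write_json(diagnostics_to_list(report), paths$diagnostics_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  for (b in seq_len(n_blocks))
    utils::write.csv(surveys[[b]], paths$surveys[b], row.names = FALSE)
  message("blocks: ", paste(lengths(blocks$block_sets), collapse = "/"),
          " sets; surveys written to ", out_dir)
  invisible(list(space = space, design = design, report = report,
                 blocks = blocks, consistency = cons, surveys = surveys,
                 paths = paths))
}

#' Run the analysis pipeline on a response export
#'
#' Reads responses, applies the consistency filter, fits the conditional
#' logit, and writes the tidy results CSV and a JSON metadata file.
#' Respondent counts before and after filtering are logged.
#'
#' @param responses_path long-format response CSV (see
#'   [read_responses()]).
#' @param design_csv,design_json design artifacts written by
#'   [run_design_pipeline()].
#' @param instrument_path the instrument YAML the design was built on.
#' @param out_dir output directory.
#' @return invisibly, a list with `panel`, `fit`, `odds` and `paths`.
#' @export
run_analysis_pipeline <- function(responses_path, design_csv, design_json,
                                  instrument_path, out_dir) {
  space <- read_instrument(instrument_path)
  bundle <- read_design(design_csv, space, design_json)
  design <- bundle$design
  panel <- read_responses(responses_path, design, bundle$blocks)
  n0 <- length(unique(panel$respondent))
  dom <- if (!is.null(bundle$consistency)) bundle$consistency$dominant else NULL
  filtered <- filter_consistent(panel, dominant_index = dom)
  n1 <- length(unique(filtered$respondent))
  message("respondents: ", n0, " read, ",
          attr(filtered, "n_removed"), " failed consistency, ",
          n1, " analyzable")
  if (nrow(filtered) == 0L)
    stop("no analyzable respondents after the consistency filter",
         call. = FALSE)
  fit <- fit_conditional_logit(filtered, design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(results_csv = file.path(out_dir, "estimates.csv"),
                results_json = file.path(out_dir, "estimates.json"))
  write_estimation(fit, paths$results_csv, paths$results_json)
  message("fit: loglik ", format(fit$loglik, digits = 6),
          ", converged = ", fit$converged)
  invisible(list(panel = filtered, fit = fit, odds = odds_summary(fit),
                 paths = paths))
}
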