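#' Split a design into level-balanced blocks
#'
#' Partitions the choice sets of a design into `n_blocks` sub-designs of
#' (near-)equal size so each respondent answers fewer tasks. Following the
#' "randomly selected while maintaining level balance" recipe, candidate
#' partitions are drawn at random and accepted once every block's
#' per-level profile counts deviate from the block ideal
#' `S * J / (n_blocks * L)` by at most `tolerance` profiles.
#'
#' @param design a `dce_design`.
#' @param n_blocks number of blocks (default 2); a warning is issued when
#'   `S` is not divisible by it.
#' @param tolerance per-level count tolerance in profiles (default 1).
#' @param max_tries rejection-sampling cap (default 10000).
#' @param seed integer seed; the partition is reproducible from it.
#' @return an object of class `dce_blocks`: list with `n_blocks`,
#'   `assignment` (block id per choice set), `block_sets` (list of set
#'   ids per block), `level_counts` (per block, per attribute) and
#'   `max_deviation`.
#' @section Infeasibility:
#' If no qualifying partition appears within `max_tries` draws, a warning
#' of class `"dce_infeasible"` is raised and the best partition found
#' (smallest worst-case deviation) is returned with `feasible = FALSE`.
#' @export
block_design <- function(design, n_blocks = 2L, tolerance = 1,
                         max_tries = 10000L, seed = NULL) {
  stopifnot(inherits(design, "dce_design"))
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  S <- design$S
  if (n_blocks > S) stop("more blocks than choice sets", call. = FALSE)
  if (S %% n_blocks != 0L)
    warning("S = ", S, " is not divisible by n_blocks = ", n_blocks,
            "; block sizes will differ by one", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  sizes <- rep(S %/% n_blocks, n_blocks)
  extra <- S %% n_blocks
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  base_assign <- rep(seq_len(n_blocks), times = sizes)

  if (n_blocks == 1L) {
    assignment <- rep(1L, S)
    dev <- block_level_deviation(design, assignment, n_blocks)
    return(new_dce_blocks(design, assignment, n_blocks, dev, tolerance,
                          feasible = TRUE, seed = seed))
  }

  best <- NULL
  for (t in seq_len(max_tries)) {
    assignment <- base_assign[sample.int(S)]
    dev <- block_level_deviation(design, assignment, n_blocks)
    if (is.null(best) || dev$max < best$dev$max)
      best <- list(assignment = assignment, dev = dev)
    if (dev$max <= tolerance)
      return(new_dce_blocks(design, assignment, n_blocks, dev, tolerance,
                            feasible = TRUE, seed = seed))
  }
  warning(structure(class = c("dce_infeasible", "warning", "condition"),
                    list(message = paste0(
                      "no partition met the level-balance tolerance of ",
                      tolerance, " within ", max_tries,
                      " draws; returning best found (max deviation ",
                      format(best$dev$max, digits = 3), ")"),
                      call = sys.call())))
  new_dce_blocks(design, best$assignment, n_blocks, best$dev, tolerance,
                 feasible = FALSE, seed = seed)
}

# per-block level counts and worst-case deviation from the block ideal
block_level_deviation <- function(design, assignment, n_blocks) {
  space <- design$space
  J <- design$J
  counts <- vector("list", n_blocks)
  max_dev <- 0
  for (b in seq_len(n_blocks)) {
    sets <- which(assignment == b)
    rows <- design$set %in% sets
    prof <- design$profiles[rows, , drop = FALSE]
    cb <- lapply(seq_len(space$n_attributes), function(i) {
      L <- space$levels_per_attribute[i]
      cnt <- tabulate(prof[, i], nbins = L)
      ideal <- length(sets) * J / L
      max_dev <<- max(max_dev, max(abs(cnt - ideal)))
      stats::setNames(cnt, space$attributes[[i]]$levels)
    })
    names(cb) <- names(space$attributes)
    counts[[b]] <- cb
  }
  list(counts = counts, max = max_dev)
}

new_dce_blocks <- function(design, assignment, n_blocks, dev, tolerance,
                           feasible, seed) {
  structure(list(
    n_blocks = n_blocks,
    assignment = as.integer(assignment),
    block_sets = split(seq_len(design$S), assignment),
    level_counts = dev$counts,
    max_deviation = dev$max,
    tolerance = tolerance,
    feasible = feasible,
    seed = seed
  ), class = "dce_blocks")
}

#' @export
print.dce_blocks <- function(x, ...) {
  sizes <- lengths(x$block_sets)
  cat("Block assignment: ", x$n_blocks, " blocks of ",
      paste(sizes, collapse = "/"), " choice sets\n", sep = "")
  cat("Max per-level count deviation from block ideal: ",
      format(x$max_deviation, digits = 3),
      " (tolerance ", x$tolerance, ")",
      if (!x$feasible) "  [tolerance NOT met]", "\n", sep = "")
  invisible(x)
}

#' Render respondent-facing block surveys
#'
#' Builds one survey specification per block: the consistency test as the
#' first choice set (identical for all respondents, set id 0), followed by
#' the block's choice sets. Alternatives are labelled "Job A", "Job B",
#' ... and the format is forced choice (no opt-out).
#'
#' @param design a `dce_design`.
#' @param blocks a `dce_blocks` from [block_design()].
#' @param consistency a `dce_consistency_set` from [consistency_set()],
#'   or `NULL` to omit the screening task.
#' @return a list of data frames, one per block, with columns `block`,
#'   `position`, `set` (0 for the consistency task), `alternative`
#'   (Job A/B/C label) and one column of level text per attribute.
#' @export
render_block_survey <- function(design, blocks, consistency = NULL) {
  stopifnot(inherits(design, "dce_design"), inherits(blocks, "dce_blocks"))
  if (length(blocks$assignment) != design$S)
    stop("block assignment does not match the design", call. = FALSE)
  space <- design$space
  alt_labels <- paste("Job", LETTERS[seq_len(design$J)])
  lapply(seq_len(blocks$n_blocks), function(b) {
    sets <- blocks$block_sets[[b]]
    pieces <- list()
    if (!is.null(consistency)) {
      stopifnot(inherits(consistency, "dce_consistency_set"))
      labs <- profile_labels(consistency$profiles, space)
      pieces[[1L]] <- data.frame(
        block = b, position = 1L, set = 0L,
        alternative = paste("Job", LETTERS[seq_len(nrow(labs))]),
        as.data.frame(labs, stringsAsFactors = FALSE), check.names = FALSE)
    }
    for (k in seq_along(sets)) {
      rows <- which(design$set == sets[k])
      labs <- profile_labels(design$profiles[rows, , drop = FALSE], space)
      pieces[[length(pieces) + 1L]] <- data.frame(
        block = b, position = k + as.integer(!is.null(consistency)),
        set = sets[k], alternative = alt_labels,
        as.data.frame(labs, stringsAsFactors = FALSE), check.names = FALSE)
    }
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    out
  })
}
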