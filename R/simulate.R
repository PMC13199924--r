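#' Specify true preferences for a simulated respondent panel
#'
#' Bundles the data-generating preferences used by [simulate_panel()]:
#' utility coefficients on the effect-coded scale, a utility scale factor,
#' and a mixture of response behaviours. Utility-maximizing respondents
#' draw i.i.d. Gumbel-noise utilities `scale * (x' beta) + e`, the
#' generator matching the conditional logit model fitted downstream;
#' random responders pick uniformly; lexicographic responders always pick
#' the alternative with the best level of one focal attribute, breaking
#' ties uniformly.
#'
#' @param beta coefficient vector of length `p` (effect-coded scale).
#' @param noise_scale positive scale multiplying systematic utility
#'   (default 1); large values approach deterministic choice.
#' @param behavior_mix named proportions for `maximizer`, `random`,
#'   `lexicographic`; must sum to 1.
#' @param focal_attribute attribute index for lexicographic respondents;
#'   `NULL` draws one uniformly per respondent.
#' @return an object of class `dce_prefs`.
#' @export
true_preferences <- function(beta,
                             noise_scale = 1,
                             behavior_mix = c(maximizer = 1, random = 0,
                                              lexicographic = 0),
                             focal_attribute = NULL) {
  beta <- as.numeric(beta)
  if (noise_scale <= 0) stop("noise_scale must be positive", call. = FALSE)
  mix <- behavior_mix[c("maximizer", "random", "lexicographic")]
  mix[is.na(mix)] <- 0
  names(mix) <- c("maximizer", "random", "lexicographic")
  if (abs(sum(mix) - 1) > 1e-8)
    stop("behavior_mix proportions must sum to 1", call. = FALSE)
  structure(list(beta = beta, noise_scale = noise_scale,
                 behavior_mix = mix, focal_attribute = focal_attribute),
            class = "dce_prefs")
}

#' Simulate a respondent panel for a blocked DCE survey
#'
#' Generates long-format choices for `n_respondents` synthetic
#' respondents. Respondents are allocated to blocks by alternation
#' (respondent 1 to block 1, 2 to block 2, ...), a balanced, reproducible
#' stand-in for uniform randomisation. Every respondent first answers the
#' consistency set (recorded with set id 0), then the choice sets of
#' their block in design order. An optional dropout rate lets a fraction
#' of respondents abandon the survey partway, producing the incomplete
#' records that [read_responses()] excludes.
#'
#' @param design a `dce_design`.
#' @param blocks a `dce_blocks`, or `NULL` to give every respondent the
#'   whole design.
#' @param consistency a `dce_consistency_set`, or `NULL` to skip the
#'   screening task.
#' @param prefs a [true_preferences()] object; `beta` must have length
#'   `design$space$n_params`.
#' @param n_respondents number of synthetic respondents (>= 1).
#' @param seed integer seed; the panel is reproducible from it.
#' @param dropout_rate probability that a respondent stops answering
#'   after a uniformly drawn position (default 0).
#' @return a data.frame of class `dce_panel` with columns `respondent`,
#'   `block`, `set` (0 = consistency task), `choice` (1..J) and, when a
#'   consistency set was shown, a per-respondent `consistency_pass` flag.
#' @export
simulate_panel <- function(design, blocks = NULL, consistency = NULL,
                           prefs, n_respondents, seed = NULL,
                           dropout_rate = 0) {
  stopifnot(inherits(design, "dce_design"), inherits(prefs, "dce_prefs"))
  n_respondents <- as.integer(n_respondents)
  if (n_respondents < 1L) stop("need at least one respondent", call. = FALSE)
  space <- design$space
  p <- space$n_params
  if (length(prefs$beta) != p)
    stop("beta has length ", length(prefs$beta), "; expected ", p,
         call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_blocks <- if (is.null(blocks)) 1L else blocks$n_blocks

  # per-set utility ingredients, indexed by set id (0 = consistency)
  set_rows <- split(seq_len(nrow(design$profiles)), design$set)
  cons_X <- cons_pts <- NULL
  if (!is.null(consistency)) {
    stopifnot(inherits(consistency, "dce_consistency_set"))
    cons_X <- effect_code(consistency$profiles, space)
    cons_pts <- profile_points(consistency$profiles, space)
  }
  pts_all <- profile_points(design$profiles, space)

  behaviors <- sample(names(prefs$behavior_mix), n_respondents,
                      replace = TRUE, prob = prefs$behavior_mix)
  rows <- vector("list", n_respondents)
  for (r in seq_len(n_respondents)) {
    b <- ((r - 1L) %% n_blocks) + 1L
    sets <- if (is.null(blocks)) seq_len(design$S) else blocks$block_sets[[b]]
    schedule <- c(if (!is.null(consistency)) 0L, sets)
    n_ans <- length(schedule)
    if (dropout_rate > 0 && length(schedule) > 1L &&
        stats::runif(1) < dropout_rate)
      n_ans <- sample.int(length(schedule) - 1L, 1L)
    focal <- prefs$focal_attribute
    if (is.null(focal) && behaviors[r] == "lexicographic")
      focal <- sample.int(space$n_attributes, 1L)
    choices <- integer(n_ans)
    for (k in seq_len(n_ans)) {
      s <- schedule[k]
      if (s == 0L) { X <- cons_X; pts <- cons_pts }
      else {
        X <- design$model_matrix[set_rows[[as.character(s)]], , drop = FALSE]
        pts <- pts_all[set_rows[[as.character(s)]], , drop = FALSE]
      }
      choices[k] <- draw_choice(behaviors[r], X, pts, prefs, focal)
    }
    rows[[r]] <- data.frame(respondent = r, block = b,
                            set = schedule[seq_len(n_ans)],
                            choice = choices)
  }
  panel <- do.call(rbind, rows)
  if (!is.null(consistency)) {
    pass_by_resp <- tapply(
      panel$choice[panel$set == 0L] == consistency$dominant,
      panel$respondent[panel$set == 0L], identity)
    panel$consistency_pass <-
      as.logical(pass_by_resp[as.character(panel$respondent)])
    attr(panel, "dominant") <- consistency$dominant
  }
  attr(panel, "behaviors") <- behaviors
  class(panel) <- c("dce_panel", "data.frame")
  panel
}

# one choice under a behaviour type
draw_choice <- function(behavior, X, pts, prefs, focal) {
  J <- nrow(X)
  switch(behavior,
    maximizer = {
      u <- prefs$noise_scale * drop(X %*% prefs$beta) + rgumbel(J)
      which.max(u)
    },
    random = sample.int(J, 1L),
    lexicographic = {
      v <- pts[, focal]
      best <- which(v == max(v))
      if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    })
}

# standard Gumbel draws (the MNL-consistent error distribution)
rgumbel <- function(n) -log(-log(stats::runif(n)))

#' Filter a panel on the internal consistency test
#'
#' Removes every respondent who failed the screening task (did not pick
#' the dominant alternative of the consistency set) and strips the
#' consistency-set rows from the surviving respondents, leaving only
#' analysis rows. Applying the filter to an already-filtered panel is a
#' no-op.
#'
#' @param panel a `dce_panel` or data.frame with columns `respondent`,
#'   `set`, `choice`.
#' @param dominant_index 1-based index of the dominant alternative
#'   (default: the `"dominant"` attribute recorded by [simulate_panel()]).
#' @return the filtered panel; the number of removed respondents is
#'   attached as attribute `"n_removed"`.
#' @export
filter_consistent <- function(panel, dominant_index = attr(panel, "dominant")) {
  cons <- panel$set == 0L
  if (!any(cons)) {
    attr(panel, "n_removed") <- 0L
    return(panel)
  }
  if (is.null(dominant_index))
    stop("dominant_index is required when the panel carries no ",
         "\"dominant\" attribute", call. = FALSE)
  failed <- unique(panel$respondent[cons & panel$choice != dominant_index])
  keep <- !(panel$respondent %in% failed) & !cons
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- length(failed)
  attr(out, "dominant") <- NULL
  class(out) <- class(panel)
  out
}
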