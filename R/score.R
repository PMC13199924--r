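#' Per-level attractiveness points of an attribute space
#'
#' The scoring matrix behind the utility-balance rule: each attribute level
#' carries points from 0 (least attractive) to 1 (most attractive within the
#' same attribute). A profile's total score is the sum over attributes of the
#' points of its chosen levels; the ceiling equals the number of attributes
#' when every attribute anchors at 1.
#'
#' @param space a [dce_space()].
#' @return a list of numeric point vectors, one per attribute, with the
#'   maximum attainable total score as attribute `"max_score"`.
#' @export
score_table <- function(space) {
  stopifnot(inherits(space, "dce_space"))
  pts <- lapply(space$attributes, `[[`, "points")
  attr(pts, "max_score") <- sum(vapply(pts, max, numeric(1)))
  pts
}

#' Total attractiveness score of profiles
#'
#' @param profiles integer profile matrix (1-based level indices).
#' @param space a [dce_space()].
#' @return numeric vector of total scores, one per profile row.
#' @examples
#' sp <- dce_space(list(a = list(levels = c("l", "h"), points = c(0, 1)),
#'                      b = list(levels = c("l", "m", "h"), points = c(0, .5, 1))),
#'                 J = 2, S = 6)
#' score_profiles(rbind(c(2, 3), c(1, 2)), sp)  # 2.0, 0.5
#' @export
score_profiles <- function(profiles, space) {
  profiles <- as_profile_matrix(profiles, space)
  rowSums(profile_points(profiles, space))
}

#' Utility-balance check for one choice set
#'
#' A choice set is utility-balanced when the difference in total
#' attractiveness scores between its best and worst alternative does not
#' exceed `threshold` points. With scores, the maximum pairwise gap and
#' the max-minus-min gap coincide, so either reading of "no alternative
#' exceeds another by more than the threshold" gives the same rule.
#'
#' @param profiles integer matrix, one row per alternative (J >= 2 rows).
#' @param space a [dce_space()].
#' @param threshold maximum allowed score gap in points (default 4.5, half
#'   the 9-point ceiling of the packaged nurse instrument). A value in
#'   `(0, 1]` given with `relative = TRUE` is interpreted as a fraction of
#'   the space's maximum score.
#' @param relative interpret `threshold` as a fraction of the maximum
#'   attainable score (default `FALSE`).
#' @return a list with `pass` (logical), `gap` (max - min score) and
#'   `scores`.
#' @export
check_balance <- function(profiles, space, threshold = 4.5, relative = FALSE) {
  profiles <- as_profile_matrix(profiles, space)
  if (nrow(profiles) < 2L)
    stop("a choice set needs at least 2 alternatives", call. = FALSE)
  if (relative)
    threshold <- threshold * attr(score_table(space), "max_score")
  s <- score_profiles(profiles, space)
  gap <- max(s) - min(s)
  list(pass = gap <= threshold, gap = gap, scores = s)
}

#' Detect a dominant alternative in a choice set
#'
#' An alternative dominates when its level points are greater than or equal
#' to every competitor's on all attributes, with a strict advantage on at
#' least one attribute, against each competitor. Dominant alternatives are
#' uninformative about trade-offs, so the design search excludes choice
#' sets containing one (and the consistency test deliberately includes one).
#'
#' @param profiles integer matrix, one row per alternative (J >= 2 rows).
#' @param space a [dce_space()].
#' @return the 1-based row index of the first dominant alternative, or
#'   `NA_integer_` if none dominates.
#' @export
find_dominant <- function(profiles, space) {
  profiles <- as_profile_matrix(profiles, space)
  if (nrow(profiles) < 2L)
    stop("a choice set needs at least 2 alternatives", call. = FALSE)
  pts <- profile_points(profiles, space)
  J <- nrow(pts)
  for (d in seq_len(J)) {
    dom <- TRUE
    for (j in seq_len(J)) {
      if (j == d) next
      diff <- pts[d, ] - pts[j, ]
      if (any(diff < 0) || !any(diff > 0)) { dom <- FALSE; break }
    }
    if (dom) return(d)
  }
  NA_integer_
}

# matrix of per-attribute points for each profile row
profile_points <- function(profiles, space) {
  pts <- score_table(space)
  m <- matrix(0, nrow(profiles), space$n_attributes)
  for (i in seq_len(space$n_attributes)) m[, i] <- pts[[i]][profiles[, i]]
  m
}
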