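#' Define a DCE attribute space
#'
#' An attribute space is the instrument definition of a discrete choice
#' experiment: an ordered list of attributes, each with ordered levels and
#' per-level attractiveness points, plus the choice-set geometry (number of
#' alternatives per set `J` and number of choice sets `S`).
#'
#' Levels must be ordered from least to most attractive, and the point
#' vector must anchor that ordering: exactly one level carries 0 points
#' (least attractive), exactly one carries 1 point (most attractive), and
#' points increase strictly with the level order. The points feed the
#' utility-balance rule used during design search (see
#' [score_profiles()] and [search_design()]).
#'
#' @param attributes a named list; each element is a list with components
#'   `levels` (character vector, length >= 2, ordered least to most
#'   attractive) and `points` (numeric vector of the same length, in
#'   `[0, 1]`, strictly increasing, containing exactly one 0 and one 1).
#' @param J alternatives per choice set (default 3).
#' @param S number of choice sets (default 18). A warning is issued when
#'   `S` is not divisible by every level count, since divisibility is what
#'   makes perfect level balance attainable.
#'
#' @return an object of class `dce_space` with components `attributes`,
#'   `J`, `S`, and derived counts: `n_attributes`, `levels_per_attribute`,
#'   `n_profiles` (full-factorial size, the product of level counts) and
#'   `n_params` (effect-coded parameter count, sum of level counts minus
#'   one per attribute).
#' @examples
#' sp <- dce_space(list(
#'   salary  = list(levels = c("low", "mid", "high"), points = c(0, 0.5, 1)),
#'   commute = list(levels = c("60 min", "30 min"),   points = c(0, 1))
#' ), J = 2, S = 6)
#' sp$n_profiles  # 6
#' sp$n_params    # 3
#' @seealso [read_instrument()] to load a space from a YAML file,
#'   [full_factorial()], [effect_code()].
#' @export
dce_space <- function(attributes, J = 3L, S = 18L) {
  if (!is.list(attributes) || length(attributes) < 1L)
    stop("`attributes` must be a non-empty named list", call. = FALSE)
  nm <- names(attributes)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every attribute must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate attribute names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  attributes <- lapply(seq_along(attributes), function(i) {
    validate_attribute(attributes[[i]], nm[i])
  })
  names(attributes) <- nm

  J <- as.integer(J); S <- as.integer(S)
  if (length(J) != 1L || is.na(J) || J < 2L)
    stop("`J` must be a single integer >= 2", call. = FALSE)
  if (length(S) != 1L || is.na(S) || S < 1L)
    stop("`S` must be a single integer >= 1", call. = FALSE)

  L <- vapply(attributes, function(a) length(a$levels), integer(1))
  if (any(S %% L != 0L))
    warning("S = ", S, " is not divisible by every level count (",
            paste(sort(unique(L)), collapse = ", "),
            "); perfect level balance is unattainable", call. = FALSE)

  structure(list(
    attributes = attributes,
    J = J, S = S,
    n_attributes = length(attributes),
    levels_per_attribute = L,
    n_profiles = prod(L),
    n_params = sum(L - 1L)
  ), class = "dce_space")
}

validate_attribute <- function(a, name) {
  if (!is.list(a) || is.null(a$levels) || is.null(a$points))
    stop("attribute '", name, "' needs `levels` and `points`", call. = FALSE)
  levels <- as.character(a$levels)
  points <- as.numeric(a$points)
  L <- length(levels)
  if (L < 2L)
    stop("attribute '", name, "' must have at least 2 levels", call. = FALSE)
  if (length(points) != L)
    stop("attribute '", name, "': points and levels differ in length",
         call. = FALSE)
  if (anyDuplicated(levels))
    stop("attribute '", name, "' has duplicate level labels", call. = FALSE)
  if (any(points < 0 | points > 1))
    stop("attribute '", name, "': points must lie in [0, 1]", call. = FALSE)
  if (sum(points == 0) != 1L || sum(points == 1) != 1L)
    stop("attribute '", name,
         "': points must contain exactly one 0 and exactly one 1 anchor",
         call. = FALSE)
  if (any(diff(points) <= 0))
    stop("attribute '", name, "': points must increase strictly with the ",
         "level order (least to most attractive)", call. = FALSE)
  list(levels = levels, points = points)
}

#' Load an attribute space from a YAML instrument file
#'
#' Reads an instrument configuration with one entry per attribute
#' (`name`, `levels`, `points`) and an optional `design` block
#' (`J`, `S`, `n_blocks`, `balance_threshold`, `seed`). The packaged nurse
#' job-preference instrument can be loaded with
#' `read_instrument(system.file("extdata", "nurse_jobs.yaml", package = "dcekit"))`.
#'
#' @param path path to a YAML file.
#' @return a [dce_space()]; design-block extras (`n_blocks`,
#'   `balance_threshold`, `seed`) are attached as the `"design"` attribute.
#' @export
read_instrument <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$attributes))
    stop("instrument file must contain an `attributes` list", call. = FALSE)
  attrs <- list()
  for (a in cfg$attributes) {
    if (is.null(a$name)) stop("every attribute entry needs a `name`", call. = FALSE)
    attrs[[a$name]] <- list(levels = a$levels, points = a$points)
  }
  des <- cfg$design
  sp <- dce_space(attrs,
                  J = if (!is.null(des$J)) des$J else 3L,
                  S = if (!is.null(des$S)) des$S else 18L)
  attr(sp, "design") <- des
  sp
}

#' @export
print.dce_space <- function(x, ...) {
  cat("DCE attribute space: ", x$n_attributes, " attributes, ",
      x$n_profiles, " full-factorial profiles, ",
      x$n_params, " effect-coded parameters\n", sep = "")
  cat("Choice-set geometry: J = ", x$J, " alternatives, S = ", x$S,
      " sets\n", sep = "")
  for (nm in names(x$attributes)) {
    a <- x$attributes[[nm]]
    cat("  ", nm, ": ",
        paste0(a$levels, " (", a$points, ")", collapse = " | "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Enumerate the full factorial of an attribute space
#'
#' Returns every possible profile (one level per attribute) exactly once,
#' in lexicographic order with the last attribute varying fastest. For a
#' space with level counts `L_1, ..., L_A` the result has `prod(L)` rows.
#'
#' @param space a [dce_space()].
#' @param max_profiles safety cap on the enumeration size (default `1e6`);
#'   enumeration is refused above it.
#' @return an integer matrix with one row per profile and one column per
#'   attribute; entries are 1-based level indices (1 = least attractive).
#' @examples
#' sp <- dce_space(list(a = list(levels = c("l", "h"), points = c(0, 1)),
#'                      b = list(levels = c("l", "m", "h"), points = c(0, .5, 1))),
#'                 J = 2, S = 6)
#' nrow(full_factorial(sp))  # 6
#' @export
full_factorial <- function(space, max_profiles = 1e6) {
  stopifnot(inherits(space, "dce_space"))
  if (space$n_profiles > max_profiles)
    stop("full factorial has ", space$n_profiles,
         " profiles, above the cap of ", max_profiles, call. = FALSE)
  L <- space$levels_per_attribute
  grid <- expand.grid(rev(lapply(L, seq_len)), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid[, rev(seq_along(L)), drop = FALSE])
  dimnames(m) <- list(NULL, names(space$attributes))
  storage.mode(m) <- "integer"
  m
}

#' Effect-code profiles
#'
#' Builds the effect-coded model matrix for a set of profiles. Each
#' attribute with `L` levels contributes `L - 1` columns, one per
#' non-reference level; the reference is the least attractive level
#' (1 point-wise lowest). A profile at non-reference level `k` carries +1
#' in the column for level `k` and 0 in the attribute's other columns; a
#' profile at the reference level carries -1 in all of the attribute's
#' columns. Columns are labelled `attribute:level`.
#'
#' Choosing the least attractive level as reference makes the expected
#' sign of every main-effect coefficient positive for attractive levels,
#' which keeps odds-scale summaries readable.
#'
#' @param profiles integer matrix of 1-based level indices (rows =
#'   profiles, columns = attributes), e.g. from [full_factorial()].
#' @param space a [dce_space()].
#' @return a numeric matrix with `space$n_params` columns and entries in
#'   \{-1, 0, 1\}.
#' @export
effect_code <- function(profiles, space) {
  stopifnot(inherits(space, "dce_space"))
  profiles <- as_profile_matrix(profiles, space)
  L <- space$levels_per_attribute
  n <- nrow(profiles)
  out <- matrix(0, n, space$n_params)
  labs <- character(space$n_params)
  col0 <- 0L
  for (i in seq_len(space$n_attributes)) {
    a <- space$attributes[[i]]
    li <- profiles[, i]
    for (k in 2:L[i]) {
      col <- col0 + k - 1L
      out[, col] <- (li == k) - (li == 1L)
      labs[col] <- paste0(names(space$attributes)[i], ":", a$levels[k])
    }
    col0 <- col0 + L[i] - 1L
  }
  colnames(out) <- labs
  out
}

#' Recover level indices from an effect-coded matrix
#'
#' Inverse of [effect_code()]: maps each row of an effect-coded matrix
#' back to 1-based level indices.
#'
#' @param X effect-coded matrix with `space$n_params` columns.
#' @param space a [dce_space()].
#' @return integer profile matrix.
#' @export
decode_profiles <- function(X, space) {
  stopifnot(inherits(space, "dce_space"))
  X <- as.matrix(X)
  if (ncol(X) != space$n_params)
    stop("expected ", space$n_params, " columns, got ", ncol(X), call. = FALSE)
  L <- space$levels_per_attribute
  out <- matrix(NA_integer_, nrow(X), space$n_attributes,
                dimnames = list(NULL, names(space$attributes)))
  col0 <- 0L
  for (i in seq_len(space$n_attributes)) {
    cols <- col0 + seq_len(L[i] - 1L)
    block <- X[, cols, drop = FALSE]
    for (r in seq_len(nrow(X))) {
      v <- block[r, ]
      if (all(v == -1)) out[r, i] <- 1L
      else {
        k <- which(v == 1)
        if (length(k) != 1L || any(v[-k] != 0))
          stop("row ", r, " is not a valid effect coding for attribute '",
               names(space$attributes)[i], "'", call. = FALSE)
        out[r, i] <- k + 1L
      }
    }
    col0 <- col0 + L[i] - 1L
  }
  out
}

# coerce + validate a profile matrix against the space
as_profile_matrix <- function(profiles, space) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "integer"
  if (ncol(profiles) != space$n_attributes)
    stop("profiles have ", ncol(profiles), " columns; space has ",
         space$n_attributes, " attributes", call. = FALSE)
  L <- space$levels_per_attribute
  for (i in seq_len(ncol(profiles))) {
    bad <- profiles[, i] < 1L | profiles[, i] > L[i] | is.na(profiles[, i])
    if (any(bad))
      stop("level index out of range for attribute '",
           names(space$attributes)[i], "'", call. = FALSE)
  }
  profiles
}

#' Translate level indices to level labels
#'
#' @param profiles integer profile matrix.
#' @param space a [dce_space()].
#' @return character matrix of level labels, same shape as `profiles`.
#' @export
profile_labels <- function(profiles, space) {
  profiles <- as_profile_matrix(profiles, space)
  out <- matrix(NA_character_, nrow(profiles), ncol(profiles),
                dimnames = list(NULL, names(space$attributes)))
  for (i in seq_len(ncol(profiles)))
    out[, i] <- space$attributes[[i]]$levels[profiles[, i]]
  out
}
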