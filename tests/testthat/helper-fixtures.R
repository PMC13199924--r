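# Shared fixtures and independent oracles for the test suite.

# tiny space: two binary attributes, paired choice sets
toy_space <- function(J = 2L, S = 2L) {
  suppressWarnings(dce_space(list(
    a = list(levels = c("a0", "a1"), points = c(0, 1)),
    b = list(levels = c("b0", "b1"), points = c(0, 1))
  ), J = J, S = S))
}

# mixed space: one binary, one ternary attribute
mixed_space <- function(J = 2L, S = 6L) {
  dce_space(list(
    x = list(levels = c("x0", "x1"), points = c(0, 1)),
    y = list(levels = c("y0", "y1", "y2"), points = c(0, 0.5, 1))
  ), J = J, S = S)
}

nurse_space <- function() {
  read_instrument(system.file("extdata", "nurse_jobs.yaml",
                              package = "dcekit"))
}

# the shared default-search design is expensive; build it once per run
.fixture_cache <- new.env(parent = emptyenv())
default_nurse_design <- function() {
  if (is.null(.fixture_cache$design))
    .fixture_cache$design <- search_design(nurse_space(), seed = 20240917)
  .fixture_cache$design
}

# a cheap (lightly optimised) nurse design for simulation-heavy tests
quick_nurse_design <- function() {
  if (is.null(.fixture_cache$quick))
    .fixture_cache$quick <- search_design(
      nurse_space(), seed = 1105, n_random_starts = 1L,
      max_passes = 2L, exchange_candidates = 120L)
  .fixture_cache$quick
}

# ---- independent oracles ------------------------------------------------

# zero-prior D-error from the closed form, no shared code with d_error()
oracle_d_error0 <- function(X, J) {
  p <- ncol(X)
  S <- nrow(X) / J
  M <- matrix(0, p, p)
  for (s in seq_len(S)) {
    Xs <- X[((s - 1) * J + 1):(s * J), , drop = FALSE]
    ones <- rep(1, J)
    M <- M + (t(Xs) %*% Xs - (t(Xs) %*% ones %*% t(ones) %*% Xs) / J) / J
  }
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev))) return(Inf)
  prod(ev)^(-1 / p)
}

# exhaustive minimum zero-prior D-error over enumerated designs
oracle_min_d_error <- function(space, J, S, keep_set = NULL) {
  pool <- full_factorial(space)
  X <- effect_code(pool, space)
  sets <- utils::combn(nrow(pool), J, simplify = FALSE)
  if (!is.null(keep_set)) sets <- Filter(keep_set, sets)
  best <- Inf
  for (ids in utils::combn(length(sets), S, simplify = FALSE)) {
    rows <- unlist(sets[ids])
    best <- min(best, oracle_d_error0(X[rows, , drop = FALSE], J))
  }
  best
}

# brute-force dominance oracle over raw point comparisons
oracle_dominant <- function(profiles, space) {
  pts <- sapply(seq_len(space$n_attributes), function(i)
    space$attributes[[i]]$points[profiles[, i]])
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = nrow(profiles))
  for (d in seq_len(nrow(pts))) {
    others <- setdiff(seq_len(nrow(pts)), d)
    ok <- TRUE
    for (j in others) {
      if (!(all(pts[d, ] >= pts[j, ]) && any(pts[d, ] > pts[j, ]))) {
        ok <- FALSE; break
      }
    }
    if (ok) return(d)
  }
  NA_integer_
}

# naive two-pass Pearson correlation
oracle_cor <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random valid attribute list for property tests
random_attr_list <- function(n_attr, max_levels = 4L) {
  out <- list()
  for (i in seq_len(n_attr)) {
    L <- sample(2:max_levels, 1L)
    pts <- if (L == 2L) c(0, 1) else c(0, sort(runif(L - 2L)), 1)
    out[[paste0("attr", i)]] <- list(
      levels = paste0("v", seq_len(L), "_", i), points = pts)
  }
  out
}
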