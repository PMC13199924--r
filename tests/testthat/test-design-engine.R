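test_that("single-set binary design under zero priors has unit information", {
  sp <- suppressWarnings(dce_space(
    list(a = list(levels = c("lo", "hi"), points = c(0, 1))), J = 2, S = 1))
  X <- effect_code(rbind(1L, 2L), sp)     # coded -1 / +1
  M <- information_matrix(X, J = 2)
  expect_equal(dim(M), c(1L, 1L))
  expect_equal(M[1, 1], 1)                # 1*(1/2) + 1*(1/2) - 0^2
  expect_equal(as.numeric(d_error(X, J = 2)), 1)
})

test_that("a set of identical profiles contributes no information", {
  sp <- toy_space()
  X <- effect_code(rbind(c(1L, 2L), c(1L, 2L)), sp)
  M <- information_matrix(X, J = 2)
  expect_equal(M, matrix(0, 2, 2), ignore_attr = TRUE)
  de <- d_error(X, J = 2)
  expect_true(is.infinite(de))
  expect_true(isTRUE(attr(de, "singular")))
})

test_that("zero-prior information matches the closed-form simplification", {
  sp <- nurse_space()
  set.seed(11)
  ff <- full_factorial(sp)
  rows <- sample(nrow(ff), 4 * sp$J)
  X <- effect_code(ff[rows, , drop = FALSE], sp)
  M <- information_matrix(X, J = sp$J)
  J <- sp$J
  Mc <- matrix(0, ncol(X), ncol(X))
  for (s in 1:4) {
    Xs <- X[((s - 1) * J + 1):(s * J), , drop = FALSE]
    Mc <- Mc + (crossprod(Xs) - tcrossprod(colSums(Xs)) / J) / J
  }
  expect_equal(M, Mc, tolerance = 1e-12)
})

test_that("information matrix matches a finite-difference Hessian under nonzero priors", {
  sp <- suppressWarnings(mixed_space(J = 3L, S = 2L))
  set.seed(13)
  ff <- full_factorial(sp)
  rows <- c(sample(6, 3), sample(6, 3))
  X <- effect_code(ff[rows, , drop = FALSE], sp)
  beta <- c(0.4, -0.3, 0.6)
  M <- information_matrix(X, J = 3, priors = beta)
  # MNL log-likelihood Hessian is outcome-free: -I equals the numeric
  # Hessian of the chosen-alternative log-probability summed over sets
  ll <- function(b) {
    out <- 0
    for (s in 1:2) {
      Xs <- X[((s - 1) * 3 + 1):(s * 3), ]
      u <- Xs %*% b
      out <- out + u[1] - log(sum(exp(u)))
    }
    out
  }
  h <- 1e-4
  H <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    e1 <- e2 <- numeric(3); e1[i] <- h; e2[j] <- h
    H[i, j] <- (ll(beta + e1 + e2) - ll(beta + e1) -
                ll(beta + e2) + ll(beta)) / h^2
  }
  expect_equal(M, -H, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("symmetric PSD structure holds for random designs and priors", {
  sp <- nurse_space()
  set.seed(17)
  ff <- full_factorial(sp)
  for (rep in 1:5) {
    X <- effect_code(ff[sample(nrow(ff), 6 * sp$J), , drop = FALSE], sp)
    beta <- rnorm(sp$n_params, sd = 0.3)
    M <- information_matrix(X, J = sp$J, priors = beta)
    expect_equal(M, t(M), tolerance = 1e-12)
    expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("search on the enumerable toy space attains the exhaustive optimum", {
  sp <- toy_space(J = 2L, S = 2L)
  oracle <- oracle_min_d_error(sp, J = 2L, S = 2L)
  d <- search_design(sp, balance_threshold = Inf, enforce_dominance = FALSE,
                     n_random_starts = 4L, seed = 101)
  expect_equal(as.numeric(d$d_error), oracle, tolerance = 1e-10)
})

test_that("more alternatives identify more: J=3 beats J=2 on a saturated toy", {
  # three binary attributes, two sets: J=2 contributes rank <= 1 per set,
  # so p = 3 is unidentifiable; J=3 identifies it with finite D-error
  mk <- function(J) suppressWarnings(dce_space(list(
    a = list(levels = c("a0", "a1"), points = c(0, 1)),
    b = list(levels = c("b0", "b1"), points = c(0, 1)),
    c = list(levels = c("c0", "c1"), points = c(0, 1))), J = J, S = 2L))
  best2 <- oracle_min_d_error(mk(2L), J = 2L, S = 2L)
  best3 <- oracle_min_d_error(mk(3L), J = 3L, S = 2L)
  expect_true(is.infinite(best2))
  expect_lt(best3, best2)
  d3 <- search_design(mk(3L), balance_threshold = Inf,
                      enforce_dominance = FALSE,
                      n_random_starts = 4L, seed = 7)
  expect_equal(as.numeric(d3$d_error), best3, tolerance = 1e-10)
})

test_that("incumbent D-error is non-increasing within a search run", {
  d <- quick_nurse_design()
  for (traj in d$provenance) {
    finite <- traj[is.finite(traj)]
    expect_true(all(diff(finite) <= 1e-9))
  }
})

test_that("emitted designs satisfy both constraints under independent re-checks", {
  d <- quick_nurse_design()
  sp <- d$space
  expect_equal(d$S, 18L)
  expect_equal(nrow(d$profiles), 54L)
  for (s in seq_len(d$S)) {
    set <- d$profiles[d$set == s, , drop = FALSE]
    expect_lte(check_balance(set, sp, 4.5)$gap, 4.5)
    expect_true(is.na(oracle_dominant(set, sp)))
    expect_equal(anyDuplicated(set), 0L)
  }
  # no duplicated choice sets design-wide
  keys <- vapply(seq_len(d$S), function(s)
    paste(sort(apply(d$profiles[d$set == s, ], 1, paste, collapse = ",")),
          collapse = ";"), character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("identical configuration and seed reproduce the identical design", {
  sp <- suppressWarnings(mixed_space(J = 2L, S = 3L))
  d1 <- search_design(sp, seed = 55, n_random_starts = 1L, max_passes = 3L)
  d2 <- search_design(sp, seed = 55, n_random_starts = 1L, max_passes = 3L)
  expect_identical(d1$profiles, d2$profiles)
  expect_equal(d1$d_error, d2$d_error)
})

test_that("an unattainable balance threshold raises an infeasibility signal", {
  sp <- mixed_space(J = 2L, S = 6L)
  expect_error(
    search_design(sp, balance_threshold = 0, seed = 3,
                  n_random_starts = 1L),
    class = "dce_infeasible")
})

test_that("the consistency set has the intended dominant first alternative", {
  sp <- nurse_space()
  cs <- consistency_set(sp)
  expect_identical(find_dominant(cs$profiles, sp), 1L)
  expect_identical(cs$dominant, 1L)
  expect_equal(unname(cs$profiles[1, ]), unname(sp$levels_per_attribute))
  # maximal score gap: exempt from (and failing) the balance rule
  expect_equal(check_balance(cs$profiles, sp, 4.5)$gap, 9.0)
  expect_false(check_balance(cs$profiles, sp, 4.5)$pass)
  # J = 2 on one binary attribute: best vs worst
  sp1 <- suppressWarnings(dce_space(
    list(a = list(levels = c("lo", "hi"), points = c(0, 1))), J = 2, S = 1))
  cs1 <- consistency_set(sp1)
  expect_equal(unname(cs1$profiles[, 1]), c(2L, 1L))
})
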