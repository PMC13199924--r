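make_design_from_rows <- function(space, rows) {
  pool <- full_factorial(space)
  profiles <- pool[rows, , drop = FALSE]
  dcekit:::new_dce_design(
    profiles, space,
    d_error = d_error(effect_code(profiles, space), J = space$J),
    priors = numeric(space$n_params), seed = NULL,
    config = list(J = space$J, balance_threshold = Inf),
    provenance = list(), feasible = TRUE)
}

test_that("full-factorial design has zero between-attribute correlations", {
  sp <- suppressWarnings(mixed_space(J = 2L, S = 3L))
  d <- make_design_from_rows(sp, 1:6)
  rep <- orthogonality_report(d)
  expect_equal(rep$max_abs_between_attributes, 0, tolerance = 1e-12)
  expect_equal(diag(rep$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rep$correlation, t(rep$correlation))
})

test_that("perfectly aligned attributes are flagged with |r| = 1", {
  sp <- dce_space(list(
    a = list(levels = c("a0", "a1"), points = c(0, 1)),
    b = list(levels = c("b0", "b1"), points = c(0, 1))), J = 2, S = 2)
  # b always equals a -> columns identical
  d <- make_design_from_rows(sp, c(1, 4, 1, 4))
  expect_warning(rep <- orthogonality_report(d), "exceeds")
  expect_equal(rep$max_abs_between_attributes, 1, tolerance = 1e-12)
})

test_that("constant columns are reported as undefined, not numbers", {
  X <- cbind(c1 = c(1, 1, 1, 1), c2 = c(-1, 1, -1, 1))
  rep <- orthogonality_report(X)
  expect_equal(rep$constant_columns, "c1")
  expect_true(all(is.na(rep$correlation["c1", "c2"])))
})

test_that("correlations match a naive two-pass computation on a searched design", {
  d <- quick_nurse_design()
  rep <- orthogonality_report(d)
  X <- d$model_matrix
  for (k in 1:25) {
    ij <- sample(ncol(X), 2L)
    expect_equal(rep$correlation[ij[1], ij[2]],
                 oracle_cor(X[, ij[1]], X[, ij[2]]), tolerance = 1e-12)
  }
})

test_that("level-balance counts reconcile with a brute-force tally", {
  d <- quick_nurse_design()
  lb <- level_balance_report(d)
  sp <- d$space
  for (i in seq_len(sp$n_attributes)) {
    nm <- names(sp$attributes)[i]
    rows <- lb[lb$attribute == nm, ]
    expect_equal(sum(rows$count), 54L)
    expect_equal(sum(rows$proportion), 1, tolerance = 1e-12)
    for (k in seq_along(sp$attributes[[i]]$levels))
      expect_equal(rows$count[k], sum(d$profiles[, i] == k))
  }
})

test_that("single-set imbalance is reported, not an error", {
  sp <- suppressWarnings(mixed_space(J = 3L, S = 1L))
  d <- make_design_from_rows(sp, c(1, 2, 4))
  lb <- level_balance_report(d, tolerance = 0.4)
  x <- lb[lb$attribute == "x", ]
  expect_equal(sort(x$count), c(1L, 2L))
  expect_false(all(x$balanced))  # deviation 0.5 from the 1.5 ideal
})

test_that("the aggregate report flags hand-built dominated sets and round-trips via JSON", {
  sp <- suppressWarnings(mixed_space(J = 2L, S = 3L))
  # sets 1 and 3: trade-offs; set 2: (2,3) dominates (1,1)
  pool <- full_factorial(sp)
  profiles <- pool[c(4, 3, 6, 1, 2, 4), , drop = FALSE]
  d <- dcekit:::new_dce_design(
    profiles, sp, d_error = d_error(effect_code(profiles, sp), J = 2),
    priors = numeric(3), seed = NULL,
    config = list(J = 2L, balance_threshold = 4.5),
    provenance = list(), feasible = FALSE)
  # this deliberately poor 3-set design also trips the correlation warning
  rep <- suppressWarnings(design_report(d))
  expect_true(is.na(rep$dominance_flags[1]))
  expect_identical(unname(rep$dominance_flags[2]), 1L)
  expect_true(is.na(rep$dominance_flags[3]))
  expect_true(is.finite(rep$d_error))
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(diagnostics_to_list(rep), tmp, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$d_error, rep$d_error, tolerance = 1e-12)
  expect_equal(back$balance_gaps, unname(rep$balance_gaps), tolerance = 1e-12)
  expect_equal(as.numeric(unlist(back$level_balance$count)),
               as.numeric(rep$level_balance$count))
})

test_that("diagnostics never mutate the design", {
  d <- quick_nurse_design()
  snap <- unserialize(serialize(d, NULL))
  invisible(design_report(d))
  expect_identical(d, snap)
})
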