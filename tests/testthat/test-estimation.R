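est_fixture <- function(n = 150, beta = NULL, seed = 301, scale = 1) {
  d <- quick_nurse_design()
  b <- block_design(d, 2L, seed = 62)
  cs <- consistency_set(d$space)
  p <- d$space$n_params
  if (is.null(beta)) beta <- seq(0.15, 0.6, length.out = p)
  prefs <- true_preferences(beta, noise_scale = scale)
  pan <- simulate_panel(d, b, cs, prefs, n_respondents = n, seed = seed)
  list(d = d, b = b, cs = cs, beta = beta,
       panel = filter_consistent(pan))
}

test_that("optimizer objective and the direct-summation oracle agree", {
  f <- est_fixture(n = 20)
  p <- length(f$beta)
  n <- nrow(f$panel)
  set.seed(99)
  for (k in 1:100) {
    beta <- rnorm(p, sd = 0.7)
    a <- clogit_loglik(beta, f$panel, f$d)
    b <- loglik_direct(beta, f$panel, f$d)
    expect_equal(a, b, tolerance = 1e-10)
  }
  expect_equal(clogit_loglik(numeric(p), f$panel, f$d), n * log(1 / 3),
               tolerance = 1e-12)
  expect_equal(loglik_direct(numeric(p), f$panel, f$d), n * log(1 / 3),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to per-set additive utility shifts", {
  f <- est_fixture(n = 15)
  beta <- rnorm(length(f$beta), sd = 0.5)
  base <- loglik_direct(beta, f$panel, f$d)
  shifted <- f$d
  # shift every alternative of each set by the same arbitrary row vector:
  # utilities move by a per-set constant, probabilities are unchanged
  set.seed(5)
  for (s in seq_len(shifted$S)) {
    delta <- rnorm(ncol(shifted$model_matrix))
    rows <- which(shifted$set == s)
    shifted$model_matrix[rows, ] <-
      sweep(shifted$model_matrix[rows, , drop = FALSE], 2L, -delta)
  }
  expect_equal(loglik_direct(beta, f$panel, shifted), base,
               tolerance = 1e-9)
})

test_that("the fitter recovers simulated preferences and matches survival::clogit", {
  skip_if_not_installed("survival")
  library(survival)  # clogit() builds a coxph() call in the caller's env
  f <- est_fixture(n = 250, seed = 303)
  fit <- fit_conditional_logit(f$panel, f$d)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - f$beta)), 0.35)
  # independent route: Cox-trick conditional logistic regression
  dat <- dcekit:::build_choice_data(f$panel, f$d)
  X <- dat$X
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  long <- data.frame(X)
  long$stratum <- dat$choice_id
  long$chosen <- 0
  long$chosen[dat$chosen] <- 1
  fml <- stats::as.formula(paste(
    "chosen ~", paste(colnames(X), collapse = " + "),
    "+ strata(stratum)"))
  cox <- survival::clogit(fml, data = long)
  expect_equal(unname(coef(fit)), unname(coef(cox)), tolerance = 1e-5)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(cox)))), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(cox)), tolerance = 1e-6)
})

test_that("a symmetric panel yields zero coefficients and the uniform log-likelihood", {
  # every alternative of every set chosen exactly once
  d <- quick_nurse_design()
  panel <- do.call(rbind, lapply(1:3, function(ch)
    data.frame(respondent = ch, block = 1L, set = 1:18, choice = ch)))
  fit <- fit_conditional_logit(panel, d)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), rep(0, 12), tolerance = 1e-6)
  expect_equal(fit$loglik, 54 * log(1 / 3), tolerance = 1e-8)
})

test_that("distinct starting points converge to the same maximum (concavity)", {
  f <- est_fixture(n = 120, seed = 305)
  fit0 <- fit_conditional_logit(f$panel, f$d)
  set.seed(12)
  fit1 <- fit_conditional_logit(f$panel, f$d,
                                start = rnorm(length(f$beta), sd = 1))
  expect_lt(max(abs(coef(fit0) - coef(fit1))), 1e-6)
  expect_equal(fit0$loglik, fit1$loglik, tolerance = 1e-10)
})

test_that("estimation refuses panels that still contain the consistency set", {
  f <- est_fixture(n = 10)
  poisoned <- f$panel
  poisoned$set[1] <- 0L
  expect_error(fit_conditional_logit(poisoned, f$d), "consistency set")
  expect_error(fit_conditional_logit(f$panel[0, ], f$d), "empty panel")
})

test_that("panel validation catches bad ids, ranges and duplicates", {
  f <- est_fixture(n = 10)
  bad_set <- f$panel; bad_set$set[1] <- 99L
  expect_error(fit_conditional_logit(bad_set, f$d), "unknown choice-set")
  bad_ch <- f$panel; bad_ch$choice[1] <- 4L
  expect_error(fit_conditional_logit(bad_ch, f$d), "out of range")
  dup <- rbind(f$panel, f$panel[1, ])
  expect_error(fit_conditional_logit(dup, f$d), "duplicated")
})

test_that("odds summaries expose twelve non-reference rows with coherent CIs", {
  f <- est_fixture(n = 200, seed = 307)
  fit <- fit_conditional_logit(f$panel, f$d)
  tab <- odds_summary(fit)
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$or > 0))
  expect_true(all(tab$ci_low < tab$or & tab$or < tab$ci_high))
  expect_equal(tab$or, exp(tab$estimate), tolerance = 1e-12)
  # grouped by attribute, sorted by point estimate within attribute
  expect_equal(unique(tab$attribute), names(f$d$space$attributes))
  for (a in unique(tab$attribute)) {
    ors <- tab$or[tab$attribute == a]
    expect_true(all(diff(ors) <= 0))
  }
  full <- odds_summary(fit, include_reference = TRUE)
  expect_equal(nrow(full), 12L + 9L)
  expect_true(all(full$or[full$reference] == 1))
})

test_that("zero coefficients map to unit odds", {
  d <- quick_nurse_design()
  panel <- do.call(rbind, lapply(1:3, function(ch)
    data.frame(respondent = ch, block = 1L, set = 1:18, choice = ch)))
  fit <- fit_conditional_logit(panel, d)
  tab <- odds_summary(fit)
  expect_equal(tab$or, rep(1, 12), tolerance = 1e-5)
})

test_that("model methods behave like standard R fits", {
  f <- est_fixture(n = 100, seed = 309)
  fit <- fit_conditional_logit(f$panel, f$d)
  expect_equal(unname(diag(vcov(fit))), unname(fit$se^2), tolerance = 1e-12)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(attr(ll, "df"), 12L)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  pr <- predict(fit)
  expect_equal(dim(pr), c(18L, 3L))
  expect_equal(unname(rowSums(pr)), rep(1, 18), tolerance = 1e-12)
  res <- residuals(fit, panel = f$panel)
  expect_equal(unname(rowSums(res)), rep(0, nrow(f$panel)),
               tolerance = 1e-12)
})
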