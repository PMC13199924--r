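sim_fixture <- function() {
  d <- quick_nurse_design()
  b <- block_design(d, 2L, seed = 61)
  cs <- consistency_set(d$space)
  list(d = d, b = b, cs = cs, p = d$space$n_params)
}

test_that("zero preferences give near-uniform choice frequencies", {
  f <- sim_fixture()
  prefs <- true_preferences(numeric(f$p))
  pan <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 300,
                        seed = 71)
  tab <- table(pan$choice[pan$set > 0])
  freq <- as.numeric(tab) / sum(tab)
  # 300 * 9 = 2700 draws; binomial 4-sigma band around 1/3
  expect_true(all(abs(freq - 1 / 3) < 4 * sqrt((1 / 3) * (2 / 3) / 2700)))
})

test_that("empirical frequencies approach analytic MNL probabilities as n grows", {
  f <- sim_fixture()
  beta <- seq(-0.4, 0.6, length.out = f$p)
  prefs <- true_preferences(beta)
  err <- sapply(c(100, 400, 1600), function(n) {
    pan <- simulate_panel(f$d, NULL, NULL, prefs, n_respondents = n,
                          seed = 73)
    mx <- 0
    for (s in seq_len(f$d$S)) {
      X <- f$d$model_matrix[f$d$set == s, , drop = FALSE]
      pr <- exp(X %*% beta); pr <- pr / sum(pr)
      ch <- pan$choice[pan$set == s]
      emp <- tabulate(ch, 3) / length(ch)
      mx <- max(mx, max(abs(emp - as.numeric(pr))))
    }
    mx
  })
  expect_true(all(err < 6 * sqrt(0.25 / c(100, 400, 1600))))
})

test_that("strong utility maximizers pick the dominant consistency alternative", {
  f <- sim_fixture()
  prefs <- true_preferences(rep(0.5, f$p), noise_scale = 50)
  pan <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 300,
                        seed = 77)
  expect_gt(mean(pan$choice[pan$set == 0] == f$cs$dominant), 0.99)
})

test_that("pure random responders pass the consistency test at about 1/3", {
  f <- sim_fixture()
  prefs <- true_preferences(numeric(f$p),
                            behavior_mix = c(maximizer = 0, random = 1,
                                             lexicographic = 0))
  pan <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 900,
                        seed = 79)
  rate <- mean(pan$choice[pan$set == 0] == f$cs$dominant)
  expect_lt(abs(rate - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / 900))
})

test_that("lexicographic responders always take the best focal level", {
  f <- sim_fixture()
  prefs <- true_preferences(numeric(f$p),
                            behavior_mix = c(maximizer = 0, random = 0,
                                             lexicographic = 1),
                            focal_attribute = 1L)
  pan <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 40,
                        seed = 81)
  pts <- f$d$space$attributes[[1]]$points
  for (i in which(pan$set > 0)) {
    rows <- f$d$profiles[f$d$set == pan$set[i], 1]
    expect_equal(pts[rows[pan$choice[i]]], max(pts[rows]))
  }
})

test_that("the consistency filter removes exactly the failures and is idempotent", {
  f <- sim_fixture()
  prefs <- true_preferences(rep(0.3, f$p),
                            behavior_mix = c(maximizer = 0.5, random = 0.5,
                                             lexicographic = 0))
  pan <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 60, seed = 83)
  failures <- unique(pan$respondent[pan$set == 0 &
                                    pan$choice != f$cs$dominant])
  flt <- filter_consistent(pan)
  expect_equal(attr(flt, "n_removed"), length(failures))
  expect_false(any(flt$respondent %in% failures))
  expect_false(any(flt$set == 0))
  # survivors keep all their analysis rows
  keep <- setdiff(unique(pan$respondent), failures)
  expect_equal(nrow(flt), sum(pan$respondent %in% keep & pan$set > 0))
  # idempotent
  again <- filter_consistent(flt, dominant_index = f$cs$dominant)
  expect_equal(again[c("respondent", "set", "choice")],
               flt[c("respondent", "set", "choice")], ignore_attr = TRUE)
})

test_that("an all-passing panel only loses its consistency rows", {
  f <- sim_fixture()
  prefs <- true_preferences(rep(0.5, f$p), noise_scale = 60)
  pan <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 25, seed = 85)
  if (all(pan$choice[pan$set == 0] == f$cs$dominant)) {
    flt <- filter_consistent(pan)
    expect_equal(attr(flt, "n_removed"), 0L)
    expect_equal(nrow(flt), sum(pan$set > 0))
  } else succeed("seeded panel contained a failure; covered elsewhere")
})

test_that("panels are reproducible from the seed and respect block alternation", {
  f <- sim_fixture()
  prefs <- true_preferences(numeric(f$p))
  p1 <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 20, seed = 87)
  p2 <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 20, seed = 87)
  expect_identical(p1$choice, p2$choice)
  expect_equal(unique(p1$block[p1$respondent %% 2 == 1]), 1L)
  expect_equal(unique(p1$block[p1$respondent %% 2 == 0]), 2L)
  # each respondent answers consistency + their block's nine sets
  for (r in 1:4) {
    rows <- p1[p1$respondent == r, ]
    expect_setequal(rows$set, c(0L, f$b$block_sets[[rows$block[1]]]))
  }
})

test_that("dropout produces incomplete respondents at roughly the requested rate", {
  f <- sim_fixture()
  prefs <- true_preferences(numeric(f$p))
  pan <- simulate_panel(f$d, f$b, f$cs, prefs, n_respondents = 200,
                        seed = 89, dropout_rate = 0.3)
  n_sets <- table(pan$respondent)
  frac <- mean(n_sets < 10L)
  expect_gt(frac, 0.15); expect_lt(frac, 0.45)
})

test_that("beta length mismatches are rejected", {
  f <- sim_fixture()
  expect_error(simulate_panel(f$d, f$b, f$cs,
                              true_preferences(numeric(3)), 5),
               "expected 12")
})
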