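#' Fit a conditional logit model to choice-panel data
#'
#' Maximum-likelihood estimation of the conditional (multinomial) logit
#' for forced choices among the `J` alternatives of each choice set. The
#' log-likelihood
#' \deqn{\ell(\beta) = \sum_i \left[ x_{c_i}'\beta -
#'   \log \sum_{j} \exp(x_{ij}'\beta) \right]}
#' (one stratum per respondent-set pair, `x` the effect-coded attribute
#' rows of that set) is maximised by Newton-Raphson with step halving from
#' `beta = 0`; the log-likelihood is globally concave, so the optimum is
#' unique whenever it exists. Standard errors come from the inverse
#' observed information at the maximum.
#'
#' The panel must not contain the consistency screening task (set id 0):
#' that set has a dominant alternative by construction and would bias the
#' fit, so its presence is an error — run [filter_consistent()] first.
#'
#' @param panel a `dce_panel` or data.frame with columns `respondent`,
#'   `set`, `choice` (1..J).
#' @param design the `dce_design` the choices refer to.
#' @param level confidence level for Wald intervals on the log-odds scale
#'   (default 0.95).
#' @param max_iter Newton iteration cap (default 50).
#' @param tol convergence tolerance on the gradient norm (default 1e-8).
#' @param start optional starting coefficients (default: all zero); the
#'   concave likelihood makes the solution independent of the start.
#' @return an object of class `dce_clogit` with components
#'   `coefficients`, `se`, `vcov`, `loglik`, `null_loglik`, `or`
#'   (exp(coef)), `or_ci`, `level`, `n_respondents`, `n_choices`,
#'   `iterations`, `converged`, `space`, `design`.
#' @section Non-convergence:
#' Complete or quasi-complete separation (some contrast never chosen
#' against) makes the MLE diverge; the fit then returns with
#' `converged = FALSE` and a warning carrying the gradient norm and the
#' largest coefficient magnitude, never a silently wrong answer.
#' @export
fit_conditional_logit <- function(panel, design, level = 0.95,
                                  max_iter = 50L, tol = 1e-8,
                                  start = NULL) {
  stopifnot(inherits(design, "dce_design"))
  dat <- build_choice_data(panel, design)
  beta <- if (is.null(start)) numeric(ncol(dat$X)) else as.numeric(start)
  if (length(beta) != ncol(dat$X))
    stop("start must have length ", ncol(dat$X), call. = FALSE)
  ll <- clogit_core(beta, dat)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    H <- ll$hessian
    step <- tryCatch(solve(H, -ll$gradient), error = function(e) NULL)
    if (is.null(step)) break
    # step halving keeps the ascent monotone far from the optimum
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      llc <- clogit_core(cand, dat)
      if (llc$loglik >= ll$loglik - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    beta <- beta + alpha * step
    ll <- llc
    if (sqrt(sum(ll$gradient^2)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("conditional logit did not converge (gradient norm ",
            format(sqrt(sum(ll$gradient^2)), digits = 3),
            ", max |coef| ", format(max(abs(beta)), digits = 3),
            "); possible separation", call. = FALSE)
  vc <- tryCatch(solve(-ll$hessian), error = function(e)
    matrix(NA_real_, length(beta), length(beta)))
  se <- sqrt(diag(vc))
  names(beta) <- names(se) <- colnames(dat$X)
  dimnames(vc) <- list(colnames(dat$X), colnames(dat$X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(
    coefficients = beta,
    se = se,
    vcov = vc,
    loglik = ll$loglik,
    null_loglik = dat$n_choices * log(1 / design$J),
    or = exp(beta),
    or_ci = cbind(lower = exp(beta - z * se), upper = exp(beta + z * se)),
    level = level,
    n_respondents = dat$n_respondents,
    n_choices = dat$n_choices,
    iterations = iter,
    converged = converged,
    space = design$space,
    design = design
  ), class = "dce_clogit")
}

# expand a panel into stacked per-alternative rows; validates ids
build_choice_data <- function(panel, design) {
  req <- c("respondent", "set", "choice")
  if (!all(req %in% names(panel)))
    stop("panel needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(panel) == 0L) stop("empty panel", call. = FALSE)
  if (any(panel$set == 0L))
    stop("panel still contains the consistency set (set id 0); ",
         "apply filter_consistent() before estimation", call. = FALSE)
  bad <- !(panel$set %in% seq_len(design$S))
  if (any(bad))
    stop("unknown choice-set ids: ",
         paste(unique(panel$set[bad]), collapse = ", "), call. = FALSE)
  if (any(panel$choice < 1L | panel$choice > design$J))
    stop("choice index out of range 1..", design$J, call. = FALSE)
  if (anyDuplicated(panel[, c("respondent", "set")]))
    stop("duplicated (respondent, set) rows", call. = FALSE)
  J <- design$J
  set_rows <- split(seq_len(nrow(design$profiles)), design$set)
  rows <- unlist(set_rows[as.character(panel$set)], use.names = FALSE)
  X <- design$model_matrix[rows, , drop = FALSE]
  n <- nrow(panel)
  list(X = X, J = J,
       choice_id = rep(seq_len(n), each = J),
       chosen = (seq_len(n) - 1L) * J + panel$choice,
       n_choices = n,
       n_respondents = length(unique(panel$respondent)))
}

# log-likelihood, gradient and Hessian of the conditional logit
clogit_core <- function(beta, dat) {
  eta <- drop(dat$X %*% beta)
  m <- matrix(eta, nrow = dat$J)
  mx <- apply(m, 2L, max)
  w <- exp(sweep(m, 2L, mx))
  denom <- colSums(w)
  pr <- as.vector(sweep(w, 2L, denom, "/"))
  loglik <- sum(eta[dat$chosen]) - sum(mx + log(denom))
  y <- numeric(length(eta)); y[dat$chosen] <- 1
  gradient <- drop(crossprod(dat$X, y - pr))
  Xw <- dat$X * pr
  Mm <- rowsum(Xw, dat$choice_id)
  hessian <- -(crossprod(dat$X, Xw) - crossprod(Mm))
  list(loglik = loglik, gradient = gradient, hessian = hessian)
}

#' Conditional logit log-likelihood (optimizer objective)
#'
#' Evaluates the exact objective the fitter maximises, at an arbitrary
#' coefficient vector. Useful for profiling and for cross-checking
#' against [loglik_direct()].
#'
#' @param beta coefficient vector of length `p`.
#' @param panel a filtered choice panel.
#' @param design the `dce_design` the choices refer to.
#' @return the log-likelihood (a non-positive number).
#' @export
clogit_loglik <- function(beta, panel, design) {
  dat <- build_choice_data(panel, design)
  clogit_core(beta, dat)$loglik
}

#' Direct-summation log-likelihood evaluator
#'
#' An independent implementation of the conditional logit log-likelihood
#' that loops over choices and sums terms explicitly, sharing no code
#' with the optimizer's vectorised objective. Intended as a numerical
#' oracle: `clogit_loglik()` and `loglik_direct()` must agree to
#' near-machine precision at any `beta`.
#'
#' @inheritParams clogit_loglik
#' @return the log-likelihood.
#' @export
loglik_direct <- function(beta, panel, design) {
  if (any(panel$set == 0L))
    stop("panel still contains the consistency set (set id 0)", call. = FALSE)
  total <- 0
  for (i in seq_len(nrow(panel))) {
    rows <- which(design$set == panel$set[i])
    u <- numeric(length(rows))
    for (j in seq_along(rows))
      u[j] <- sum(design$model_matrix[rows[j], ] * beta)
    total <- total + u[panel$choice[i]] - log(sum(exp(u)))
  }
  total
}

#' @export
print.dce_clogit <- function(x, ...) {
  cat("Conditional logit fit: ", x$n_choices, " choices from ",
      x$n_respondents, " respondents\n", sep = "")
  cat("log-likelihood ", format(x$loglik, digits = 6),
      " (null ", format(x$null_loglik, digits = 6), "), ",
      x$iterations, " iterations",
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.dce_clogit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(estimate = object$coefficients,
               se = object$se,
               z = z,
               p = 2 * stats::pnorm(-abs(z)),
               or = object$or,
               or_low = object$or_ci[, "lower"],
               or_high = object$or_ci[, "upper"])
  out <- list(fit = object, table = tab)
  class(out) <- "summary.dce_clogit"
  out
}

#' @export
print.summary.dce_clogit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (odds scale with ",
      format(100 * x$fit$level), "% CI):\n", sep = "")
  stats::printCoefmat(x$table[, c("estimate", "se", "z", "p")],
                      P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.dce_clogit <- function(object, ...) object$coefficients

#' @export
vcov.dce_clogit <- function(object, ...) object$vcov

#' @export
logLik.dce_clogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_choices, class = "logLik")
}

#' @export
confint.dce_clogit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste0(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.dce_clogit <- function(object, design = object$design, ...) {
  stopifnot(inherits(design, "dce_design"))
  X <- design$model_matrix
  pr <- matrix(NA_real_, design$S, design$J,
               dimnames = list(paste0("set", seq_len(design$S)),
                               paste0("alt", seq_len(design$J))))
  for (s in seq_len(design$S)) {
    rows <- which(design$set == s)
    pr[s, ] <- mnl_probs(X[rows, , drop = FALSE], object$coefficients)
  }
  pr
}

#' @export
residuals.dce_clogit <- function(object, panel = NULL, ...) {
  if (is.null(panel))
    stop("supply the fitted panel to compute choice residuals", call. = FALSE)
  dat <- build_choice_data(panel, object$design)
  eta <- drop(dat$X %*% object$coefficients)
  m <- matrix(eta, nrow = dat$J)
  w <- exp(sweep(m, 2L, apply(m, 2L, max)))
  pr <- as.vector(sweep(w, 2L, colSums(w), "/"))
  y <- numeric(length(eta)); y[dat$chosen] <- 1
  matrix(y - pr, ncol = dat$J, byrow = TRUE,
         dimnames = list(NULL, paste0("alt", seq_len(dat$J))))
}

#' Odds-scale summary table per attribute level
#'
#' Tabulates `exp(beta)` with confidence intervals for every
#' non-reference attribute level, grouped by attribute and sorted by
#' point estimate within attribute (largest odds first). Reference
#' levels sit at odds 1 by the effect-coding convention and can be
#' included as explicit rows.
#'
#' @param fit a converged `dce_clogit`.
#' @param space the attribute space (default: stored in the fit).
#' @param include_reference also emit the reference level of each
#'   attribute at odds 1 (default `FALSE`).
#' @return a data.frame with columns `attribute`, `level`, `term`,
#'   `estimate`, `se`, `or`, `ci_low`, `ci_high`, `reference`.
#' @export
odds_summary <- function(fit, space = fit$space, include_reference = FALSE) {
  stopifnot(inherits(fit, "dce_clogit"))
  if (!fit$converged)
    warning("fit did not converge; odds are unreliable", call. = FALSE)
  rows <- list()
  col0 <- 0L
  for (i in seq_len(space$n_attributes)) {
    a <- space$attributes[[i]]
    nm <- names(space$attributes)[i]
    L <- length(a$levels)
    idx <- col0 + seq_len(L - 1L)
    block <- data.frame(
      attribute = nm,
      level = a$levels[-1L],
      term = names(fit$coefficients)[idx],
      estimate = unname(fit$coefficients[idx]),
      se = unname(fit$se[idx]),
      or = unname(fit$or[idx]),
      ci_low = unname(fit$or_ci[idx, "lower"]),
      ci_high = unname(fit$or_ci[idx, "upper"]),
      reference = FALSE,
      stringsAsFactors = FALSE)
    block <- block[order(-block$or), , drop = FALSE]
    if (include_reference)
      block <- rbind(block, data.frame(
        attribute = nm, level = a$levels[1L],
        term = paste0(nm, ":", a$levels[1L], " (ref)"),
        estimate = 0, se = NA_real_, or = 1,
        ci_low = NA_real_, ci_high = NA_real_, reference = TRUE,
        stringsAsFactors = FALSE))
    rows[[i]] <- block
    col0 <- col0 + L - 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Forest plot of odds-scale attribute effects
#'
#' Draws the per-level odds ratios and confidence intervals of a fitted
#' conditional logit, one row per non-reference level, grouped by
#' attribute, with a reference line at odds 1.
#'
#' @param x a `dce_clogit`.
#' @param ... passed to [odds_summary()].
#' @return invisibly, the odds table that was plotted.
#' @export
plot.dce_clogit <- function(x, ...) {
  tab <- odds_summary(x, ...)
  n <- nrow(tab)
  ypos <- rev(seq_len(n))
  xlim <- range(c(tab$ci_low, tab$ci_high, 1), na.rm = TRUE)
  op <- graphics::par(mar = c(4, 14, 2, 2))
  on.exit(graphics::par(op))
  graphics::plot(tab$or, ypos, log = "x", xlim = xlim, pch = 16,
                 yaxt = "n", xlab = "Odds ratio (log scale)", ylab = "",
                 main = "Attribute effects, odds scale")
  graphics::segments(tab$ci_low, ypos, tab$ci_high, ypos)
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::axis(2, at = ypos, las = 1, cex.axis = 0.7,
                 labels = paste(tab$attribute, tab$level, sep = ": "))
  invisible(tab)
}
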