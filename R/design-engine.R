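#' Multinomial logit information matrix of a choice design
#'
#' Computes the Fisher information of a choice design under the
#' multinomial logit model,
#' \deqn{I(\beta) = \sum_s X_s' (\mathrm{diag}(\pi_s) - \pi_s \pi_s') X_s,}
#' where `X_s` is the effect-coded matrix of the J alternatives in set `s`
#' and `pi_s` their MNL choice probabilities under the prior coefficients.
#' With zero priors every alternative has probability `1/J`, which is the
#' standard assumption when no prior estimates are available.
#'
#' @param X effect-coded model matrix with `S * J` rows, stacked set by
#'   set, or a `dce_design`.
#' @param J alternatives per choice set (taken from the design when `X`
#'   is a `dce_design`).
#' @param priors coefficient vector of length `ncol(X)`; `NULL` means all
#'   zeros.
#' @return a symmetric positive semidefinite `p x p` matrix.
#' @export
information_matrix <- function(X, J = NULL, priors = NULL) {
  if (inherits(X, "dce_design")) {
    if (is.null(J)) J <- X$J
    X <- X$model_matrix
  }
  X <- as.matrix(X)
  if (is.null(J)) stop("`J` must be supplied with a plain matrix", call. = FALSE)
  J <- as.integer(J)
  if (nrow(X) %% J != 0L)
    stop("nrow(X) = ", nrow(X), " is not a multiple of J = ", J, call. = FALSE)
  p <- ncol(X)
  if (is.null(priors)) priors <- numeric(p)
  if (length(priors) != p)
    stop("priors must have length ", p, call. = FALSE)
  S <- nrow(X) %/% J
  M <- matrix(0, p, p)
  for (s in seq_len(S)) {
    rows <- ((s - 1L) * J + 1L):(s * J)
    M <- M + set_information(X[rows, , drop = FALSE], priors)
  }
  M
}

# information contribution of one choice set
set_information <- function(Xs, beta) {
  pr <- mnl_probs(Xs, beta)
  m <- drop(crossprod(Xs, pr))
  crossprod(Xs, Xs * pr) - tcrossprod(m)
}

# MNL choice probabilities of the alternatives in one set
mnl_probs <- function(Xs, beta) {
  u <- drop(Xs %*% beta)
  u <- u - max(u)
  w <- exp(u)
  w / sum(w)
}

#' D-error of a choice design
#'
#' The D-error is `det(I(beta))^(-1/p)`: the geometric mean of the inverse
#' information per parameter. Lower is better; a D-efficient design
#' minimises it. A singular information matrix (condition number above
#' `1e12`) yields `Inf` with attribute `"singular"` set, signalling that
#' some parameter is not identified by the design.
#'
#' @param x a `dce_design`, or an effect-coded model matrix (then give `J`).
#' @param priors coefficient vector (`NULL` = zeros).
#' @param J alternatives per set when `x` is a matrix.
#' @return a positive number, or `Inf` with `attr(., "singular") = TRUE`.
#' @export
d_error <- function(x, priors = NULL, J = NULL) {
  M <- information_matrix(x, J = J, priors = priors)
  ld <- logdet_psd(M)
  if (!is.finite(ld)) return(structure(Inf, singular = TRUE))
  exp(-ld / ncol(M))
}

# log-determinant of a symmetric PSD matrix; -Inf when numerically singular
# (singularity proxy: squared Cholesky diagonal ratio, a cheap bound on the
# condition number suitable for the exchange hot path)
logdet_psd <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  d <- diag(ch)
  if (min(d)^2 / max(d)^2 < 1e-12) return(-Inf)
  2 * sum(log(d))
}

#' Build the dominant-alternative consistency choice set
#'
#' Constructs the comprehension-screening task shown to every respondent
#' as the first choice set: one alternative (the first) holds the most
#' attractive level of every attribute and attribute-wise dominates all
#' others, so any respondent who understands the task should pick it.
#' The set intentionally violates the utility-balance rule (for the
#' packaged nurse instrument its score gap is the maximal 9.0); it is
#' exempt from the balance constraint, never enters the D-efficiency
#' search, and must be stripped before estimation (see
#' [filter_consistent()]).
#'
#' @param space a [dce_space()].
#' @param J alternatives in the set (default `space$J`).
#' @return a list of class `dce_consistency_set` with `profiles`
#'   (`J x A` integer matrix) and `dominant` (always 1).
#' @export
consistency_set <- function(space, J = space$J) {
  stopifnot(inherits(space, "dce_space"))
  J <- as.integer(J)
  if (J < 2L) stop("need at least 2 alternatives", call. = FALSE)
  L <- space$levels_per_attribute
  best <- L
  alts <- vector("list", J)
  alts[[1L]] <- best
  for (j in 2:J) alts[[j]] <- pmax(L - (j - 1L), 1L)
  m <- do.call(rbind, alts)
  if (anyDuplicated(m)) {
    # not enough level depth: degrade one extra attribute per alternative
    if (length(L) < J - 1L)
      stop("space too small to build ", J,
           " distinct alternatives for the consistency set", call. = FALSE)
    for (j in 2:J) {
      v <- best
      v[seq_len(j - 1L)] <- 1L
      alts[[j]] <- v
    }
    m <- do.call(rbind, alts)
  }
  dimnames(m) <- list(NULL, names(space$attributes))
  storage.mode(m) <- "integer"
  stopifnot(identical(find_dominant(m, space), 1L))
  structure(list(profiles = m, dominant = 1L), class = "dce_consistency_set")
}

#' Search for a balanced D-efficient choice design
#'
#' Runs a two-loop constrained search for a fractional factorial choice
#' design. The inner loop seeks D-efficiency: each choice set is
#' initialised with randomly drawn constraint-satisfying profiles from the
#' candidate pool, then improved by coordinate exchange (swapping one
#' alternative at a time against pool candidates, accepting only swaps
#' that lower the D-error while keeping the set feasible). The outer loop
#' independently re-verifies the two constraints on the finished candidate
#' — the utility-balance rule (within-set score gap at most
#' `balance_threshold` points) and the absence of dominant alternatives —
#' and discards and regenerates the design if either fails. The best
#' feasible design over `n_random_starts` restarts is returned.
#'
#' @param space a [dce_space()].
#' @param priors prior coefficients for the MNL information (default all
#'   zero, i.e. equal choice probabilities).
#' @param balance_threshold maximum within-set score gap in points
#'   (default 4.5, half the packaged instrument's 9-point ceiling); `Inf`
#'   disables the balance constraint.
#' @param relative interpret `balance_threshold` as a fraction of the
#'   maximum attainable score.
#' @param enforce_dominance exclude choice sets containing a dominant
#'   alternative (default `TRUE`).
#' @param level_balance_cap attribute-level balance constraint: every
#'   level of every attribute must appear within this many profiles of
#'   its ideal count `S*J/L` across the design (default 1; `Inf`
#'   disables). Initial designs are repaired towards balance and the
#'   exchange only considers swaps that keep counts within the cap,
#'   reflecting the choice of `S` divisible by every level count.
#' @param n_random_starts number of independent restarts (default 2).
#' @param max_outer_iterations cap on outer-loop regenerations per start
#'   (default 25).
#' @param max_passes cap on coordinate-exchange sweeps per start.
#' @param exchange_candidates number of pool candidates examined per swap
#'   position (the full pool when it is smaller).
#' @param candidate_pool optional integer profile matrix to draw from
#'   (default: the full factorial).
#' @param seed integer seed; the run is reproducible from it.
#' @return an object of class `dce_design`: a list with `profiles`
#'   (`S*J x A` level-index matrix), `set` (set id per row), `J`, `S`,
#'   `space`, `model_matrix`, `d_error`, `priors`, `seed` and
#'   `provenance` (per-start D-error trajectories).
#' @section Infeasibility:
#' When no constraint-satisfying choice set can be assembled (e.g. a zero
#' threshold on an instrument without score ties) the search stops with an
#' error of class `"dce_infeasible"`; when the outer iteration cap is
#' exhausted, a warning of the same class is raised and the best design
#' found so far is returned with `feasible = FALSE`.
#' @examples
#' sp <- dce_space(list(a = list(levels = c("l", "h"), points = c(0, 1)),
#'                      b = list(levels = c("l", "h"), points = c(0, 1))),
#'                 J = 2, S = 2)
#' d <- search_design(sp, enforce_dominance = FALSE, seed = 1)
#' d$d_error
#' @export
search_design <- function(space,
                          priors = NULL,
                          balance_threshold = 4.5,
                          relative = FALSE,
                          enforce_dominance = TRUE,
                          level_balance_cap = 1,
                          n_random_starts = 2L,
                          max_outer_iterations = 25L,
                          max_passes = 12L,
                          exchange_candidates = 600L,
                          candidate_pool = NULL,
                          seed = NULL) {
  stopifnot(inherits(space, "dce_space"))
  J <- space$J; S <- space$S
  p <- space$n_params
  if (is.null(priors)) priors <- numeric(p)
  if (length(priors) != p)
    stop("priors must have length ", p, call. = FALSE)
  if (relative)
    balance_threshold <- balance_threshold * attr(score_table(space), "max_score")
  if (balance_threshold < 0)
    stop("balance_threshold must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  pool <- if (is.null(candidate_pool)) full_factorial(space)
          else as_profile_matrix(candidate_pool, space)
  N <- nrow(pool)
  if (N < J) stop("candidate pool smaller than J", call. = FALSE)
  Xpool <- effect_code(pool, space)
  spool <- score_profiles(pool, space)
  ppool <- profile_points(pool, space)
  zero_priors <- all(priors == 0)

  cfg <- list(J = J, S = S, priors = priors,
              balance_threshold = balance_threshold,
              enforce_dominance = enforce_dominance,
              level_balance_cap = level_balance_cap,
              n_random_starts = n_random_starts,
              max_outer_iterations = max_outer_iterations,
              seed = seed)

  # per-attribute admissible count windows around the ideal S*J/L
  lv <- pool_levels_info(pool, space, level_balance_cap, S * J)

  best <- NULL
  provenance <- list()
  for (start in seq_len(n_random_starts)) {
    res <- one_search_run(space, pool, Xpool, spool, ppool, lv, priors,
                          balance_threshold, enforce_dominance,
                          max_outer_iterations, max_passes,
                          exchange_candidates)
    provenance[[start]] <- res$trajectory
    if (is.null(best) || res$logdet > best$logdet) best <- res
  }

  derr <- if (is.finite(best$logdet)) exp(-best$logdet / p)
          else structure(Inf, singular = TRUE)
  design <- new_dce_design(pool[as.vector(t(best$idx)), , drop = FALSE],
                           space, d_error = derr, priors = priors,
                           seed = seed, config = cfg,
                           provenance = provenance,
                           feasible = best$feasible)
  if (!best$feasible)
    warning(structure(class = c("dce_infeasible", "warning", "condition"),
                      list(message = paste0(
                        "outer-loop iteration cap reached without a fully ",
                        "constraint-satisfying design; returning best found"),
                        call = sys.call())))
  design
}

# level metadata for the candidate pool: level index matrix, count
# bounds per attribute, or NULL bounds when the cap is infinite
pool_levels_info <- function(pool, space, cap, n_rows) {
  L <- space$levels_per_attribute
  list(levels = pool,
       L = L,
       bounds = if (is.infinite(cap)) NULL else
         lapply(L, function(l) {
           ideal <- n_rows / l
           c(lo = ideal - cap, hi = ideal + cap)
         }))
}

# one restart of the two-loop search; idx is S x J matrix of pool rows
one_search_run <- function(space, pool, Xpool, spool, ppool, lv, priors,
                           threshold, enforce_dominance,
                           max_outer, max_passes, n_cand) {
  J <- space$J; S <- space$S
  trajectory <- numeric(0)
  for (outer in seq_len(max_outer)) {
    idx <- init_feasible_design(S, J, spool, ppool, threshold,
                                enforce_dominance)
    idx <- balance_repair(idx, spool, ppool, lv, threshold,
                          enforce_dominance)
    st <- exchange_improve(idx, Xpool, spool, ppool, lv, priors, J,
                           threshold, enforce_dominance,
                           max_passes, n_cand)
    trajectory <- c(trajectory, st$trajectory)
    # outer loop: independent post hoc verification of both constraints
    ok <- verify_design_constraints(pool[as.vector(t(st$idx)), , drop = FALSE],
                                    space, J, threshold, enforce_dominance)
    if (ok) return(list(idx = st$idx, logdet = st$logdet,
                        feasible = TRUE, trajectory = trajectory))
  }
  list(idx = st$idx, logdet = st$logdet, feasible = FALSE,
       trajectory = trajectory)
}

# design-wide per-attribute level counts of an index matrix
design_level_counts <- function(idx, lv) {
  rows <- as.vector(idx)
  lapply(seq_along(lv$L), function(i)
    tabulate(lv$levels[rows, i], nbins = lv$L[i]))
}

# total excess of counts over the admissible windows
balance_excess <- function(counts, lv) {
  if (is.null(lv$bounds)) return(0)
  tot <- 0
  for (i in seq_along(counts)) {
    b <- lv$bounds[[i]]
    tot <- tot + sum(pmax(0, b["lo"] - counts[[i]]) +
                     pmax(0, counts[[i]] - b["hi"]))
  }
  tot
}

# greedy repair pass: swap profiles to pull level counts inside the
# admissible windows, keeping every set feasible; stops at zero excess
balance_repair <- function(idx, spool, ppool, lv, threshold,
                           enforce_dominance, max_sweeps = 8L) {
  if (is.null(lv$bounds)) return(idx)
  S <- nrow(idx); J <- ncol(idx); N <- length(spool)
  counts <- design_level_counts(idx, lv)
  excess <- balance_excess(counts, lv)
  if (excess == 0) return(idx)
  set_keys <- apply(idx, 1L, function(r) paste(sort(r), collapse = ","))
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (s in seq_len(S)) {
      for (j in seq_len(J)) {
        if (excess == 0) return(idx)
        others <- idx[s, -j]
        cand <- feasible_candidates(others, spool, ppool, threshold,
                                    enforce_dominance, N, N,
                                    exclude = idx[s, j])
        if (!length(cand)) next
        old <- idx[s, j]
        best_c <- 0L; best_ex <- excess
        for (cc in cand) {
          if (cc == old) next
          ex <- excess
          for (i in seq_along(counts)) {
            lo <- lv$levels[old, i]; ln <- lv$levels[cc, i]
            if (lo == ln) next
            b <- lv$bounds[[i]]
            ci <- counts[[i]]
            ex <- ex -
              (max(0, b["lo"] - ci[lo]) + max(0, ci[lo] - b["hi"])) -
              (max(0, b["lo"] - ci[ln]) + max(0, ci[ln] - b["hi"])) +
              (max(0, b["lo"] - (ci[lo] - 1)) + max(0, (ci[lo] - 1) - b["hi"])) +
              (max(0, b["lo"] - (ci[ln] + 1)) + max(0, (ci[ln] + 1) - b["hi"]))
          }
          if (ex < best_ex) { best_ex <- ex; best_c <- cc }
        }
        if (best_c > 0L) {
          key <- paste(sort(c(others, best_c)), collapse = ",")
          if (key %in% set_keys[-s]) next
          for (i in seq_along(counts)) {
            counts[[i]][lv$levels[old, i]] <- counts[[i]][lv$levels[old, i]] - 1L
            counts[[i]][lv$levels[best_c, i]] <-
              counts[[i]][lv$levels[best_c, i]] + 1L
          }
          idx[s, j] <- best_c
          set_keys[s] <- key
          excess <- best_ex
          improved <- TRUE
        }
      }
    }
    if (!improved || excess == 0) break
  }
  idx
}

# re-check balance, dominance, and duplicate rules on a finished candidate
verify_design_constraints <- function(profiles, space, J, threshold,
                                      enforce_dominance) {
  S <- nrow(profiles) %/% J
  keys <- character(S)
  for (s in seq_len(S)) {
    rows <- ((s - 1L) * J + 1L):(s * J)
    m <- profiles[rows, , drop = FALSE]
    if (anyDuplicated(m)) return(FALSE)
    if (is.finite(threshold) &&
        !check_balance(m, space, threshold)$pass) return(FALSE)
    if (enforce_dominance && !is.na(find_dominant(m, space))) return(FALSE)
    keys[s] <- paste(sort(apply(m, 1L, paste, collapse = ",")), collapse = ";")
  }
  !anyDuplicated(keys)
}

# rejection-sample S distinct feasible sets of J distinct pool rows
init_feasible_design <- function(S, J, spool, ppool, threshold,
                                 enforce_dominance, tries_per_set = 5000L) {
  N <- length(spool)
  idx <- matrix(0L, S, J)
  keys <- character(S)
  for (s in seq_len(S)) {
    ok <- FALSE
    for (t in seq_len(tries_per_set)) {
      cand <- sample.int(N, J)
      if (!set_feasible(cand, spool, ppool, threshold, enforce_dominance))
        next
      key <- paste(sort(cand), collapse = ",")
      if (key %in% keys[seq_len(s - 1L)]) next
      idx[s, ] <- cand; keys[s] <- key; ok <- TRUE
      break
    }
    if (!ok)
      stop(structure(class = c("dce_infeasible", "error", "condition"),
                     list(message = paste0(
                       "could not assemble a constraint-satisfying choice set (",
                       "balance threshold ", threshold, "); the constraint ",
                       "appears infeasible for this instrument"),
                       call = sys.call())))
  }
  idx
}

# feasibility of one candidate set of pool-row indices
set_feasible <- function(cand, spool, ppool, threshold, enforce_dominance) {
  if (anyDuplicated(cand)) return(FALSE)
  s <- spool[cand]
  if (is.finite(threshold) && max(s) - min(s) > threshold) return(FALSE)
  if (enforce_dominance && dominant_in_points(ppool[cand, , drop = FALSE]))
    return(FALSE)
  TRUE
}

# TRUE when some row attribute-wise dominates every other row
dominant_in_points <- function(pts) {
  J <- nrow(pts)
  for (d in seq_len(J)) {
    dom <- TRUE
    for (j in seq_len(J)) {
      if (j == d) next
      dd <- pts[d, ] - pts[j, ]
      if (any(dd < 0) || !any(dd > 0)) { dom <- FALSE; break }
    }
    if (dom) return(TRUE)
  }
  FALSE
}

# coordinate-exchange improvement of a feasible design (inner loop)
exchange_improve <- function(idx, Xpool, spool, ppool, lv, priors, J,
                             threshold, enforce_dominance,
                             max_passes, n_cand) {
  S <- nrow(idx); p <- ncol(Xpool); N <- nrow(Xpool)
  set_C <- vector("list", S)
  M <- matrix(0, p, p)
  for (s in seq_len(S)) {
    set_C[[s]] <- set_information(Xpool[idx[s, ], , drop = FALSE], priors)
    M <- M + set_C[[s]]
  }
  logdet <- logdet_psd(M)
  trajectory <- if (is.finite(logdet)) exp(-logdet / p) else Inf
  set_keys <- apply(idx, 1L, function(r) paste(sort(r), collapse = ","))
  counts <- design_level_counts(idx, lv)

  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    for (s in seq_len(S)) {
      for (j in seq_len(J)) {
        others <- idx[s, -j]
        cand <- feasible_candidates(others, spool, ppool, threshold,
                                    enforce_dominance, N, n_cand,
                                    exclude = idx[s, j],
                                    lv = lv, counts = counts,
                                    old = idx[s, j])
        if (!length(cand)) next
        M_wo <- M - set_C[[s]]
        best_c <- 0L; best_ld <- logdet; best_C <- NULL
        Xo <- Xpool[others, , drop = FALSE]
        zero_pr <- all(priors == 0)
        if (zero_pr) {
          # zero priors: C = (1/J)[X'X - (1/J) s s'] admits rank-1 updates
          G0 <- crossprod(Xo)
          s0 <- colSums(Xo)
        }
        for (cc in cand) {
          if (zero_pr) {
            xc <- Xpool[cc, ]
            sv <- s0 + xc
            Cn <- (G0 + tcrossprod(xc) - tcrossprod(sv) / J) / J
          } else {
            Cn <- set_information(rbind(Xo, Xpool[cc, ]), priors)
          }
          ld <- logdet_psd(M_wo + Cn)
          if (ld > best_ld + 1e-9) { best_ld <- ld; best_c <- cc; best_C <- Cn }
        }
        if (best_c > 0L) {
          # never let a swap duplicate an existing choice set
          key <- paste(sort(c(others, best_c)), collapse = ",")
          if (key %in% set_keys[-s]) next
          old <- idx[s, j]
          for (i in seq_along(counts)) {
            counts[[i]][lv$levels[old, i]] <- counts[[i]][lv$levels[old, i]] - 1L
            counts[[i]][lv$levels[best_c, i]] <-
              counts[[i]][lv$levels[best_c, i]] + 1L
          }
          idx[s, j] <- best_c
          set_C[[s]] <- best_C
          M <- M_wo + best_C
          logdet <- best_ld
          set_keys[s] <- paste(sort(idx[s, ]), collapse = ",")
          trajectory <- c(trajectory, exp(-logdet / p))
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(idx = idx, logdet = logdet, trajectory = trajectory)
}

# pool rows that keep the set feasible when substituted into one slot;
# when lv/counts/old are given, also keep design-wide level counts
# inside their admissible windows
feasible_candidates <- function(others, spool, ppool, threshold,
                                enforce_dominance, N, n_cand, exclude,
                                lv = NULL, counts = NULL, old = NULL) {
  keep <- rep(TRUE, N)
  keep[others] <- FALSE
  if (!is.null(lv) && !is.null(lv$bounds)) {
    for (i in seq_along(counts)) {
      b <- lv$bounds[[i]]
      cl <- lv$levels[, i]
      old_l <- lv$levels[old, i]
      removal_ok <- counts[[i]][old_l] - 1L >= b["lo"]
      keep <- keep & (cl == old_l |
                      (removal_ok & counts[[i]][cl] + 1L <= b["hi"]))
    }
  }
  if (is.finite(threshold)) {
    so <- spool[others]
    keep <- keep & spool >= (max(so) - threshold) & spool <= (min(so) + threshold)
  }
  if (enforce_dominance) {
    A <- ncol(ppool)
    # candidate dominates all others, or some other dominates candidate
    # and every remaining other
    cand_dom_all <- rep(TRUE, N)
    other_dom_cand <- rep(FALSE, N)
    for (oi in seq_along(others)) {
      po <- ppool[others[oi], ]
      ge <- ppool >= matrix(po, N, A, byrow = TRUE)
      gt <- ppool >  matrix(po, N, A, byrow = TRUE)
      c_dom_o <- rowSums(ge) == A & rowSums(gt) > 0L
      cand_dom_all <- cand_dom_all & c_dom_o
      # does other oi dominate the remaining others?
      o_dom_rest <- TRUE
      for (ok in seq_along(others)) {
        if (ok == oi) next
        dd <- po - ppool[others[ok], ]
        if (any(dd < 0) || !any(dd > 0)) { o_dom_rest <- FALSE; break }
      }
      if (o_dom_rest) {
        le <- ppool <= matrix(po, N, A, byrow = TRUE)
        lt <- ppool <  matrix(po, N, A, byrow = TRUE)
        o_dom_c <- rowSums(le) == A & rowSums(lt) > 0L
        other_dom_cand <- other_dom_cand | o_dom_c
      }
    }
    keep <- keep & !cand_dom_all & !other_dom_cand
  }
  cand <- which(keep)
  if (length(cand) > n_cand) cand <- sample(cand, n_cand)
  cand
}

new_dce_design <- function(profiles, space, d_error, priors, seed, config,
                           provenance, feasible = TRUE) {
  J <- config$J; S <- nrow(profiles) %/% J
  structure(list(
    profiles = profiles,
    set = rep(seq_len(S), each = J),
    alternative = rep(seq_len(J), times = S),
    J = J, S = S,
    space = space,
    model_matrix = effect_code(profiles, space),
    d_error = d_error,
    priors = priors,
    seed = seed,
    config = config,
    provenance = provenance,
    feasible = feasible
  ), class = "dce_design")
}

#' @export
print.dce_design <- function(x, ...) {
  cat("DCE design: ", x$S, " choice sets x ", x$J, " alternatives (",
      nrow(x$profiles), " profile rows)\n", sep = "")
  cat("D-error: ", format(x$d_error, digits = 6),
      if (!x$feasible) "  [constraints NOT satisfied]", "\n", sep = "")
  if (!is.null(x$seed)) cat("Seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.dce_design <- function(object, ...) {
  gaps <- set_score_gaps(object)
  doms <- set_dominance_flags(object)
  out <- list(design = object, gaps = gaps, dominant = doms,
              d_error = object$d_error)
  class(out) <- "summary.dce_design"
  out
}

#' @export
print.summary.dce_design <- function(x, ...) {
  print(x$design)
  cat("Within-set score gaps: min ", format(min(x$gaps), digits = 3),
      ", max ", format(max(x$gaps), digits = 3), "\n", sep = "")
  nd <- sum(!is.na(x$dominant))
  cat("Sets with a dominant alternative: ", nd, "\n", sep = "")
  invisible(x)
}

#' Within-set score gaps of a design
#'
#' @param design a `dce_design`.
#' @return numeric vector of max-minus-min total scores, one per set.
#' @export
set_score_gaps <- function(design) {
  stopifnot(inherits(design, "dce_design"))
  s <- score_profiles(design$profiles, design$space)
  vapply(split(s, design$set), function(v) max(v) - min(v), numeric(1))
}

#' Per-set dominant-alternative flags of a design
#'
#' @param design a `dce_design`.
#' @return integer vector, one per set: index of the dominant alternative
#'   or `NA` when none.
#' @export
set_dominance_flags <- function(design) {
  stopifnot(inherits(design, "dce_design"))
  vapply(seq_len(design$S), function(s) {
    rows <- which(design$set == s)
    find_dominant(design$profiles[rows, , drop = FALSE], design$space)
  }, integer(1))
}

#' @export
as.data.frame.dce_design <- function(x, ...) {
  labs <- profile_labels(x$profiles, x$space)
  data.frame(set = x$set, alternative = x$alternative,
             as.data.frame(labs, stringsAsFactors = FALSE),
             check.names = FALSE)
}
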