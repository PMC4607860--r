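# Multi-start bounded optimizer portfolio for the exponential SAT model.
#
# The portfolio runs several distinct algorithm families from seeded random
# starts drawn uniformly within the box constraints and keeps the best run
# (smallest SSE; ties broken by fewer iterations, then run order). A final
# derivative-based polish from the best run tightens the optimum. The
# portfolio is a contract -- any adequate set of bounded optimizers
# satisfies the best-of-all-runs selection rule -- not a clone of any
# specific solver set.

#' Fitting configuration
#'
#' @param lambda_bounds,beta_bounds,delta_bounds box constraints per
#'   parameter kind. Defaults: asymptote in 0..6 d-prime, rate in
#'   0.05..6 1/s, intercept in 0..3 s. An optional asymptote floor of
#'   0.4 can be set via `lambda_bounds = c(0.4, 6)`.
#' @param restarts random restarts per algorithm (>= 1).
#' @param algorithms portfolio; at least two of `"neldermead"`
#'   (derivative-free simplex with box penalty), `"lbfgsb"` (quasi-Newton
#'   with box constraints), `"port"` (bounded PORT/trust-region via
#'   [stats::nlminb()]), `"newton"` (Newton-type [stats::nlm()] with box
#'   penalty).
#' @param seed integer seed controlling all start values.
#' @param rel_tol relative convergence tolerance on the objective.
#' @param polish run a tight bounded polish from the best run (default TRUE).
#' @param fit_lags lags entering the objective; default lags 2..n_tones (the
#'   post-onset response points).
#' @param asymptote_margin d-prime margin above the empirical asymptote
#'   beyond which a fitted asymptote counts as overestimated.
#' @param bound_tol tolerance for the at-bound validity flag.
#' @return an object of class `sat_fit_config`.
#' @export
fit_config <- function(lambda_bounds = c(0, 6), beta_bounds = c(0.05, 6),
                       delta_bounds = c(0, 3), restarts = 10L,
                       algorithms = c("neldermead", "lbfgsb", "port", "newton"),
                       seed = 1L, rel_tol = 1e-10, polish = TRUE,
                       fit_lags = NULL, asymptote_margin = 1.0,
                       bound_tol = 1e-3) {
  known <- c("neldermead", "lbfgsb", "port", "newton")
  algorithms <- match.arg(algorithms, known, several.ok = TRUE)
  for (b in list(lambda_bounds, beta_bounds, delta_bounds)) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop_config("each bound must be c(lower, upper) with lower < upper")
    }
  }
  if (restarts < 1L) stop_config("restarts must be >= 1")
  structure(list(
    lambda_bounds = lambda_bounds, beta_bounds = beta_bounds,
    delta_bounds = delta_bounds, restarts = as.integer(restarts),
    algorithms = algorithms, seed = as.integer(seed), rel_tol = rel_tol,
    polish = polish, fit_lags = fit_lags,
    asymptote_margin = asymptote_margin, bound_tol = bound_tol
  ), class = "sat_fit_config")
}

spec_bounds <- function(spec, cfg) {
  list(
    lower = c(rep(cfg$lambda_bounds[1], spec$n_lambda),
              rep(cfg$beta_bounds[1], spec$n_beta),
              rep(cfg$delta_bounds[1], spec$n_delta)),
    upper = c(rep(cfg$lambda_bounds[2], spec$n_lambda),
              rep(cfg$beta_bounds[2], spec$n_beta),
              rep(cfg$delta_bounds[2], spec$n_delta))
  )
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Fit a model specification to one d-prime curve set
#'
#' Runs every portfolio algorithm from `restarts` seeded uniform-in-bounds
#' starting points, minimizing the least-squares objective
#' ([objective_sse()]), and returns the best run (optionally polished).
#' Deterministic given (data, spec, config, seed). Validity flags
#' (overestimated asymptotes, parameters at bounds) are attached via
#' [check_asymptotes()].
#'
#' @param curves curve data frame for a single data unit (one participant or
#'   the averaged data): columns `construction`, `lag`, `lag_time`,
#'   `dprime`.
#' @param spec a [model_spec()] or model name.
#' @param cfg a [fit_config()].
#' @param unit identifier of the data unit (defaults to the `participant`
#'   value in `curves`); mixed into the start-value seed.
#' @param extra_starts optional list of additional starting vectors (e.g.
#'   solutions of nested models embedded into this spec's parameter space);
#'   each is recorded as a run of its own and also refined with the bounded
#'   PORT optimizer, which guarantees the best objective can only improve
#'   on them.
#' @return an object of class `sat_fit`: fitted `theta`, `sse`, `adj_r2`,
#'   per-run log, validity `flags`.
#' @export
fit_model <- function(curves, spec, cfg = fit_config(), unit = NULL,
                      extra_starts = list()) {
  spec <- model_spec(spec)
  stopifnot(inherits(cfg, "sat_fit_config"))
  units <- unique(curves$participant)
  if (is.null(unit)) {
    if (length(units) > 1L) {
      stop_data("curves contain several units (", paste(units, collapse = ", "),
                "); fit one at a time or use fit_ladder()")
    }
    unit <- if (length(units) == 1L) units else "unit"
  }
  fit_lags <- cfg$fit_lags %||% setdiff(sort(unique(curves$lag)), 1L)
  sub <- curves[curves$lag %in% fit_lags, , drop = FALSE]
  if (!all(spec$conditions %in% sub$construction)) {
    stop_data("curves are missing condition(s): ",
              paste(setdiff(spec$conditions, sub$construction), collapse = ", "))
  }
  b <- spec_bounds(spec, cfg)
  k <- spec$k
  nl <- spec$n_lambda; nb <- spec$n_beta
  li <- spec$lambda_map[match(sub$construction, spec$conditions)]
  bi <- nl + spec$beta_map[match(sub$construction, spec$conditions)]
  di <- nl + nb + spec$delta_map[match(sub$construction, spec$conditions)]
  obs <- sub$dprime
  tt <- sub$lag_time
  fn <- function(theta) {
    del <- theta[di]
    r <- obs - ifelse(tt > del, theta[li] * (1 - exp(-theta[bi] * (tt - del))), 0)
    sum(r * r)
  }
  # box penalty for the unconstrained algorithm families
  fn_pen <- function(theta) {
    ex <- pmax(b$lower - theta, 0) + pmax(theta - b$upper, 0)
    fn(clamp(theta, b$lower, b$upper)) + 1e4 * sum(ex * ex)
  }

  runs <- list()
  thetas <- list()
  for (alg in cfg$algorithms) {
    for (r in seq_len(cfg$restarts)) {
      # one substream per restart, so a run with more restarts evaluates a
      # strict superset of the starting points of a run with fewer
      start <- with_seed(hash_mix(cfg$seed, "starts", spec$name, unit, alg, r),
                         stats::runif(k, b$lower, b$upper))
      res <- tryCatch(switch(alg,
        neldermead = {
          o <- stats::optim(start, fn_pen, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = cfg$rel_tol))
          list(par = o$par, conv = o$convergence == 0, iter = o$counts[1])
        },
        lbfgsb = {
          o <- stats::optim(start, fn, method = "L-BFGS-B",
                            lower = b$lower, upper = b$upper,
                            control = list(
                              maxit = 500,
                              factr = max(cfg$rel_tol / .Machine$double.eps, 10)))
          list(par = o$par, conv = o$convergence == 0, iter = o$counts[1])
        },
        port = {
          o <- stats::nlminb(start, fn, lower = b$lower, upper = b$upper,
                             control = list(rel.tol = max(cfg$rel_tol, 1e-14),
                                            iter.max = 500, eval.max = 1000))
          list(par = o$par, conv = o$convergence == 0, iter = o$iterations)
        },
        newton = {
          o <- suppressWarnings(stats::nlm(fn_pen, start, iterlim = 500))
          list(par = o$estimate, conv = o$code %in% c(1, 2), iter = o$iterations)
        }
      ), error = function(e) NULL)
      if (is.null(res)) {
        runs[[length(runs) + 1L]] <- data.frame(
          algorithm = alg, restart = r, objective = NA_real_,
          converged = FALSE, iterations = NA_integer_,
          stringsAsFactors = FALSE)
        thetas[[length(thetas) + 1L]] <- rep(NA_real_, k)
      } else {
        par <- clamp(res$par, b$lower, b$upper)
        runs[[length(runs) + 1L]] <- data.frame(
          algorithm = alg, restart = r, objective = fn(par),
          converged = isTRUE(res$conv), iterations = as.integer(res$iter),
          stringsAsFactors = FALSE)
        thetas[[length(thetas) + 1L]] <- par
      }
    }
  }
  for (i in seq_along(extra_starts)) {
    start <- clamp(extra_starts[[i]], b$lower, b$upper)
    runs[[length(runs) + 1L]] <- data.frame(
      algorithm = "warmstart", restart = i, objective = fn(start),
      converged = TRUE, iterations = 0L, stringsAsFactors = FALSE)
    thetas[[length(thetas) + 1L]] <- start
    o <- tryCatch(
      stats::nlminb(start, fn, lower = b$lower, upper = b$upper,
                    control = list(rel.tol = max(cfg$rel_tol, 1e-14),
                                   iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(o)) {
      par <- clamp(o$par, b$lower, b$upper)
      runs[[length(runs) + 1L]] <- data.frame(
        algorithm = "warmstart+port", restart = i, objective = fn(par),
        converged = o$convergence == 0, iterations = as.integer(o$iterations),
        stringsAsFactors = FALSE)
      thetas[[length(thetas) + 1L]] <- par
    }
  }
  log <- do.call(rbind, runs)
  ok <- which(is.finite(log$objective))
  if (length(ok) == 0) {
    err <- simpleError("fit-failure error: no portfolio run produced a finite objective")
    err$run_log <- log
    stop(err)
  }
  best <- ok[order(log$objective[ok], log$iterations[ok], ok)][1]
  theta <- thetas[[best]]
  sse <- log$objective[best]
  provenance <- sprintf("%s[%d]", log$algorithm[best], log$restart[best])
  if (isTRUE(cfg$polish)) {
    po <- tryCatch(
      stats::nlminb(theta, fn, lower = b$lower, upper = b$upper,
                    control = list(rel.tol = 1e-15, x.tol = 1e-12,
                                   iter.max = 1000, eval.max = 2000)),
      error = function(e) NULL)
    if (!is.null(po) && is.finite(po$objective) && po$objective <= sse) {
      theta <- clamp(po$par, b$lower, b$upper)
      sse <- po$objective
      provenance <- paste0(provenance, "+polish")
    }
  }
  names(theta) <- theta_names(spec)
  pred <- predict_sat(theta, spec, sub$construction, sub$lag_time)
  adj <- tryCatch(adjusted_r2(obs, pred, k), error = function(e) NA_real_)
  fit <- structure(list(
    spec = spec, unit = unit, theta = theta, sse = sse, adj_r2 = adj,
    k = k, n_points = nrow(sub), fit_lags = fit_lags, runs = log,
    provenance = provenance, converged = any(log$converged[ok]),
    flags = NULL
  ), class = "sat_fit")
  fit$flags <- check_asymptotes(fit, curves, cfg = cfg)
  fit
}

#' @export
print.sat_fit <- function(x, ...) {
  cat(sprintf("SAT fit: model %s on unit '%s'\n", x$spec$name, x$unit))
  cat(sprintf("  SSE = %.6g, adjusted R^2 = %.4f (%d points, k = %d; %s)\n",
              x$sse, x$adj_r2, x$n_points, x$k, x$provenance))
  print(round(x$theta, 4))
  if (isTRUE(x$flags$asymptote_overestimated)) {
    cat("  flag: asymptote overestimated\n")
  }
  if (isTRUE(x$flags$at_bound)) cat("  flag: parameter(s) at bound\n")
  invisible(x)
}

#' Validity flags for a fitted model
#'
#' Flags a fit whose asymptote estimates exceed the empirical asymptote
#' (mean of the last four d-prime values) of their condition by more than
#' `asymptote_margin`, or that sit at the asymptote upper bound; also flags
#' any parameter lying within `bound_tol` of a box constraint.
#'
#' @param fit a `sat_fit`.
#' @param curves the full curve data frame of the fitted unit (all lags).
#' @param margin,bound_tol override the thresholds; default from `cfg`.
#' @param cfg optional [fit_config()] supplying defaults.
#' @return list with `asymptote_overestimated`, `at_bound`, and a `detail`
#'   data frame of per-condition asymptote comparisons.
#' @export
check_asymptotes <- function(fit, curves, margin = NULL, bound_tol = NULL,
                             cfg = fit_config()) {
  margin <- margin %||% cfg$asymptote_margin
  bound_tol <- bound_tol %||% cfg$bound_tol
  spec <- fit$spec
  p <- theta_by_condition(fit$theta, spec)
  emp <- vapply(spec$conditions, function(cn) {
    d <- curves[curves$construction == cn, , drop = FALSE]
    if (nrow(d) == 0) return(NA_real_)
    empirical_asymptote(d$dprime[order(d$lag)], m = min(4L, nrow(d)))
  }, numeric(1))
  # a shared asymptote group legitimately compromises across its conditions,
  # so each fitted asymptote is judged against the best empirical asymptote
  # among the conditions sharing that group
  emp_group <- vapply(seq_along(spec$conditions), function(i) {
    grp <- spec$lambda_map == spec$lambda_map[i]
    if (all(is.na(emp[grp]))) NA_real_ else max(emp[grp], na.rm = TRUE)
  }, numeric(1))
  b <- spec_bounds(spec, cfg)
  lam_upper <- cfg$lambda_bounds[2]
  over <- (!is.na(emp_group) & p$lambda > emp_group + margin) |
    p$lambda >= lam_upper - bound_tol
  at_bound <- any(fit$theta <= b$lower + bound_tol |
                    fit$theta >= b$upper - bound_tol)
  list(
    asymptote_overestimated = any(over),
    at_bound = at_bound,
    detail = data.frame(construction = spec$conditions,
                        lambda_hat = as.numeric(p$lambda),
                        empirical = as.numeric(emp),
                        overestimated = as.logical(over),
                        stringsAsFactors = FALSE)
  )
}

# TRUE when `small` is nested in `large`: wherever `large` shares a
# parameter group between two conditions, `small` must share it too.
spec_nested_in <- function(small, large) {
  if (!identical(small$conditions, large$conditions)) return(FALSE)
  coarser <- function(ms, ml) {
    for (i in seq_along(ms)) for (j in seq_along(ms)) {
      if (ml[i] == ml[j] && ms[i] != ms[j]) return(FALSE)
    }
    TRUE
  }
  coarser(small$lambda_map, large$lambda_map) &&
    coarser(small$beta_map, large$beta_map) &&
    coarser(small$delta_map, large$delta_map) &&
    small$k < large$k
}

# Express a nested model's solution in the larger model's parameter space
# (each group of the larger model takes the value of the nested group that
# covers its conditions).
embed_theta <- function(theta_small, small, large) {
  pick <- function(map_s, map_l, off_s, off_l, n_groups) {
    vapply(seq_len(n_groups), function(g) {
      cond <- which(map_l == g)[1]
      theta_small[off_s + map_s[cond]]
    }, numeric(1))
  }
  c(pick(small$lambda_map, large$lambda_map, 0L, 0L, large$n_lambda),
    pick(small$beta_map, large$beta_map, small$n_lambda, large$n_lambda,
         large$n_beta),
    pick(small$delta_map, large$delta_map, small$n_lambda + small$n_beta,
         large$n_lambda + large$n_beta, large$n_delta))
}

#' Fit a ladder of nested model specifications
#'
#' Fits every specification to every participant's curves and to the
#' averaged-data curves, with a shared seed discipline so ladders are
#' reproducible. Each model is additionally warm-started from the embedded
#' solutions of every nested model already fitted for that unit, which
#' guarantees that a larger model's best SSE never exceeds a nested
#' model's. A unit that fails to fit under some specification (error, or
#' overestimated asymptotes) is recorded and excluded from that model's
#' summaries without aborting the ladder.
#'
#' @param curves a `sat_curves` data frame covering one or more participants
#'   (and optionally an `"average"` unit).
#' @param specs character vector of model names or list of [model_spec()]s,
#'   typically ordered from the null model upward.
#' @param cfg a [fit_config()].
#' @return an object of class `sat_ladder`: per model, the averaged-data
#'   fit, per-participant fits, and failure records.
#' @export
fit_ladder <- function(curves, specs, cfg = fit_config()) {
  specs <- lapply(specs, model_spec)
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  units <- unique(curves$participant)
  participants <- setdiff(units, "average")
  done <- list()  # per unit: list of successful fits of earlier specs
  models <- lapply(specs, function(spec) {
    fit_unit <- function(u) {
      # warm-start from the closest nested model already fitted; the SSE
      # guarantee propagates down the chain by induction
      nested <- Filter(function(f) spec_nested_in(f$spec, spec), done[[u]])
      warm <- list()
      if (length(nested) > 0) {
        ks <- vapply(nested, function(f) f$spec$k, numeric(1))
        warm <- lapply(nested[ks == max(ks)], function(f) {
          embed_theta(f$theta, f$spec, spec)
        })
      }
      f <- tryCatch(fit_model(curves[curves$participant == u, , drop = FALSE],
                              spec, cfg, unit = u, extra_starts = warm),
                    error = function(e) structure(
                      list(message = conditionMessage(e)),
                      class = "sat_fit_failure"))
      if (inherits(f, "sat_fit")) {
        done[[u]] <<- c(done[[u]], list(f))
      }
      f
    }
    list(
      average = if ("average" %in% units) fit_unit("average") else NULL,
      participants = stats::setNames(lapply(participants, fit_unit),
                                     participants)
    )
  })
  structure(list(specs = specs, models = models,
                 participants = participants),
            class = "sat_ladder")
}

# A participant fit is usable for model comparison when it succeeded and did
# not overestimate the asymptotes (mirroring exclusion of unfittable
# participants from a model's summaries).
fit_usable <- function(fit) {
  inherits(fit, "sat_fit") && !isTRUE(fit$flags$asymptote_overestimated)
}

#' @export
print.sat_ladder <- function(x, ...) {
  cat("SAT model ladder\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    avg <- if (inherits(m$average, "sat_fit")) {
      sprintf("avg adjR2 = %.3f", m$average$adj_r2)
    } else "avg fit failed"
    n_ok <- sum(vapply(m$participants, fit_usable, logical(1)))
    cat(sprintf("  %-9s %s; %d/%d participants usable\n", nm, avg, n_ok,
                length(m$participants)))
  }
  invisible(x)
}
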