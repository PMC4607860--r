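# The exponential SAT model, parameter-sharing model specifications,
# the least-squares objective, and the parameter-adjusted R^2.

#' Exponential approach-to-limit SAT function
#'
#' The speed-accuracy tradeoff model
#' `d'(t) = lambda * (1 - exp(-beta * (t - delta)))` for `t > delta`, else 0.
#' `lambda` is the asymptote (d-prime units, representation quality),
#' `beta` the rate (1/s) and `delta` the intercept (s), the time at which
#' accuracy first departs from chance. The function is continuous at
#' `t = delta`, nondecreasing in `t` and in `lambda`; larger `beta` steepens
#' the approach without changing the asymptote.
#'
#' @param lambda asymptote (>= 0).
#' @param beta rate (> 0).
#' @param delta intercept (>= 0).
#' @param t time(s) in seconds relative to critical-word onset; vectorized.
#' @return predicted d-prime value(s).
#' @examples
#' evaluate_sat(2, 1, 1, 2)  # 2 * (1 - exp(-1))
#' @export
evaluate_sat <- function(lambda, beta, delta, t) {
  # the pmax clamp makes the pre-intercept branch exactly 0 and recycles
  # cleanly over any mix of vector arguments
  lambda * (1 - exp(-beta * pmax(t - delta, 0)))
}

default_groups <- function(count, conditions) {
  n <- length(conditions)
  if (count == 1L) return(rep(1L, n))
  if (count == n) return(seq_len(n))
  if (count == 2L && n == 3L) return(c(1L, 2L, 2L))  # {NoInterp} vs interpolated
  stop_config("no default grouping for ", count, " groups over ", n,
              " conditions; supply an explicit grouping")
}

check_groups <- function(groups, count, conditions, what) {
  if (length(groups) != length(conditions)) {
    stop_config(what, " grouping must map every condition")
  }
  g <- sort(unique(as.integer(groups)))
  if (!identical(g, seq_len(count))) {
    stop_config(what, " grouping must use contiguous group indices 1..", count,
                " and be surjective")
  }
  stats::setNames(as.integer(groups), conditions)
}

#' Parse a parameter-sharing model specification
#'
#' Model names follow the `<a>l-<b>b-<c>d` convention (equivalently with the
#' Greek letters lambda/beta/delta), giving the number of asymptote, rate and
#' intercept parameter groups. `"1l-1b-1d"` is the null model (all conditions
#' share everything); `"3l-3b-3d"` is fully saturated. When a count is 2 the
#' default preset groups the no-interpolation condition against the two
#' interpolated-material conditions, unless an explicit grouping overrides
#' it.
#'
#' @param name model name, e.g. `"3l-1b-2d"`.
#' @param conditions construction condition labels, in order.
#' @param lambda_groups,beta_groups,delta_groups optional explicit
#'   condition-to-group index vectors (contiguous from 1).
#' @return an object of class `sat_model_spec` with fields `name`,
#'   `conditions`, `lambda_map`, `beta_map`, `delta_map`, counts and the free
#'   parameter count `k`.
#' @examples
#' model_spec("3l-1b-2d")
#' @export
model_spec <- function(name, conditions = sat_conditions(),
                       lambda_groups = NULL, beta_groups = NULL,
                       delta_groups = NULL) {
  if (inherits(name, "sat_model_spec")) return(name)
  pat <- paste0("^([0-9]+)(?:\u03bb|[lL])-([0-9]+)(?:\u03b2|[bB])-",
                "([0-9]+)(?:\u03b4|[dD])$")
  m <- regmatches(name, regexec(pat, name))[[1]]
  if (length(m) != 4L) {
    stop_config("cannot parse model name '", name,
                "'; expected the form '<a>l-<b>b-<c>d'")
  }
  counts <- as.integer(m[2:4])
  n <- length(conditions)
  if (any(counts < 1L) || any(counts > n)) {
    stop_config("parameter group counts must lie in 1..", n,
                " (number of conditions)")
  }
  lmap <- check_groups(lambda_groups %||% default_groups(counts[1], conditions),
                       counts[1], conditions, "lambda")
  bmap <- check_groups(beta_groups %||% default_groups(counts[2], conditions),
                       counts[2], conditions, "beta")
  dmap <- check_groups(delta_groups %||% default_groups(counts[3], conditions),
                       counts[3], conditions, "delta")
  structure(list(
    name = sprintf("%dl-%db-%dd", counts[1], counts[2], counts[3]),
    conditions = conditions,
    lambda_map = lmap, beta_map = bmap, delta_map = dmap,
    n_lambda = counts[1], n_beta = counts[2], n_delta = counts[3],
    k = sum(counts)
  ), class = "sat_model_spec")
}

#' @export
print.sat_model_spec <- function(x, ...) {
  cat(sprintf("SAT model %s (k = %d)\n", x$name, x$k))
  for (i in seq_along(x$conditions)) {
    cat(sprintf("  %-9s lambda%-2d beta%-2d delta%d\n", x$conditions[i],
                x$lambda_map[i], x$beta_map[i], x$delta_map[i]))
  }
  invisible(x)
}

theta_names <- function(spec) {
  c(paste0("lambda", seq_len(spec$n_lambda)),
    paste0("beta", seq_len(spec$n_beta)),
    paste0("delta", seq_len(spec$n_delta)))
}

# Per-condition (lambda, beta, delta) resolved through the spec's group maps.
theta_by_condition <- function(theta, spec) {
  lam <- theta[spec$lambda_map]
  bet <- theta[spec$n_lambda + spec$beta_map]
  del <- theta[spec$n_lambda + spec$n_beta + spec$delta_map]
  list(lambda = stats::setNames(lam, spec$conditions),
       beta = stats::setNames(bet, spec$conditions),
       delta = stats::setNames(del, spec$conditions))
}

#' Predict SAT model values for a curve layout
#'
#' @param theta free-parameter vector (lambda groups, then beta groups, then
#'   delta groups).
#' @param spec a [model_spec()].
#' @param construction condition label per observation.
#' @param time lag time per observation (s).
#' @return predicted d-prime per observation.
#' @export
predict_sat <- function(theta, spec, construction, time) {
  p <- theta_by_condition(theta, spec)
  ci <- match(construction, spec$conditions)
  if (anyNA(ci)) {
    stop_data("condition(s) not in model spec: ",
              paste(unique(construction[is.na(ci)]), collapse = ", "))
  }
  evaluate_sat(p$lambda[ci], p$beta[ci], p$delta[ci], time)
}

#' Least-squares objective for a model specification
#'
#' Sum over conditions and included lags of squared deviations between the
#' observed d-prime curve and the model prediction, parameters resolved
#' through the spec's condition-to-group maps.
#'
#' @param theta free-parameter vector for `spec`.
#' @param spec a [model_spec()].
#' @param curves d-prime curve data frame for a single data unit with
#'   columns `construction`, `lag`, `lag_time`, `dprime`.
#' @param fit_lags optional integer vector of lags to include (default: all
#'   rows of `curves`).
#' @return nonnegative sum of squared errors.
#' @export
objective_sse <- function(theta, spec, curves, fit_lags = NULL) {
  spec <- model_spec(spec)
  if (!all(spec$conditions %in% curves$construction)) {
    stop_data("curves are missing condition(s): ",
              paste(setdiff(spec$conditions, curves$construction), collapse = ", "))
  }
  if (!is.null(fit_lags)) curves <- curves[curves$lag %in% fit_lags, , drop = FALSE]
  r <- curves$dprime - predict_sat(theta, spec, curves$construction, curves$lag_time)
  sum(r * r)
}

#' Parameter-adjusted R-squared
#'
#' Proportion of variance accounted for, penalized by the number of free
#' model parameters: `1 - (SS_res / (n - k)) / (SS_tot / (n - 1))`, with
#' `SS_tot` taken about the mean of the observations. Invariant to affine
#' rescaling applied jointly to `obs` and `pred`.
#'
#' @param obs observed values.
#' @param pred model predictions (same length).
#' @param k number of free model parameters.
#' @return adjusted R-squared (<= 1).
#' @export
adjusted_r2 <- function(obs, pred, k) {
  n <- length(obs)
  if (length(pred) != n) stop_data("obs and pred lengths differ")
  if (n <= k) {
    stop("degrees-of-freedom error: need more points (", n,
         ") than parameters (", k, ")", call. = FALSE)
  }
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    stop("undefined-statistic error: observations have zero variance",
         call. = FALSE)
  }
  ss_res <- sum((obs - pred)^2)
  1 - (ss_res / (n - k)) / (ss_tot / (n - 1))
}

#' Generate a noiseless d-prime curve set from known parameters
#'
#' Evaluates a parameter set (per-construction lambda/beta/delta, as in the
#' elements of [reference_params()]) at the given lags of a design, producing
#' a curve table in the layout that [fit_model()] consumes. Used for
#' round-trip validation of the fitting portfolio.
#'
#' @param params list with named `lambda`, `beta`, `delta` vectors per
#'   construction.
#' @param spec a [design_spec()].
#' @param lags integer lags at which to evaluate (default: all post-onset
#'   lags, i.e. dropping the pre-onset first tone).
#' @return data frame `participant`, `construction`, `lag`, `lag_time`,
#'   `dprime`.
#' @export
noiseless_curves <- function(params, spec = design_spec(),
                             lags = seq_len(spec$n_tones)[-1]) {
  tt <- lag_times(spec)[lags]
  conds <- names(params$lambda)
  out <- do.call(rbind, lapply(conds, function(cn) {
    data.frame(participant = "average", construction = cn, lag = lags,
               lag_time = tt,
               dprime = evaluate_sat(params$lambda[[cn]], params$beta[[cn]],
                                     params$delta[[cn]], tt),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
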