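# Hierarchical model comparison: adjusted-R^2 deltas across nested model
# pairs, per-participant consistency summaries, and the preferred-model
# verdict.

#' Adjusted-R-squared difference between two nested fits
#'
#' @param fit_small,fit_large `sat_fit` objects on the same data unit, with
#'   `fit_small` the more constrained model.
#' @return `adj_r2(large) - adj_r2(small)`.
#' @export
compare_nested <- function(fit_small, fit_large) {
  stopifnot(inherits(fit_small, "sat_fit"), inherits(fit_large, "sat_fit"))
  if (!identical(fit_small$unit, fit_large$unit)) {
    stop("comparison error: fits are for different data units ('",
         fit_small$unit, "' vs '", fit_large$unit, "')", call. = FALSE)
  }
  if (fit_small$k >= fit_large$k) {
    stop("comparison error: fit_small must have fewer parameters than fit_large",
         call. = FALSE)
  }
  fit_large$adj_r2 - fit_small$adj_r2
}

# Names of the models in `candidates` nested directly below `name`
# (one parameter-group count lower on exactly one of lambda/beta/delta).
parent_names <- function(name, candidates) {
  s <- model_spec(name)
  counts <- c(s$n_lambda, s$n_beta, s$n_delta)
  out <- character(0)
  for (i in 1:3) {
    if (counts[i] > 1L) {
      cc <- counts; cc[i] <- cc[i] - 1L
      out <- c(out, sprintf("%dl-%db-%dd", cc[1], cc[2], cc[3]))
    }
  }
  intersect(out, setdiff(candidates, name))
}

#' Per-participant consistency of nested model improvements
#'
#' For every nested pair in a fitted ladder (each model against the
#' model(s) one parameter-group below it that are present in the ladder),
#' reports the per-participant adjusted-R^2 increases with mean/min/max
#' summaries, the count of improved participants, the averaged-data delta,
#' and the participants excluded because either fit failed or overestimated
#' its asymptotes.
#'
#' @param ladder a `sat_ladder` from [fit_ladder()].
#' @return an object of class `sat_consistency`: list of per-pair reports
#'   and a `summary` data frame (`model_pair`, `mean_delta`, `min_delta`,
#'   `max_delta`, `n_improved`, `n`, `avg_delta`).
#' @export
consistency_report <- function(ladder) {
  stopifnot(inherits(ladder, "sat_ladder"))
  cand <- names(ladder$models)
  pairs <- list()
  for (nm in cand) {
    for (pn in parent_names(nm, cand)) {
      pairs[[length(pairs) + 1L]] <- c(small = pn, large = nm)
    }
  }
  reports <- lapply(pairs, function(pr) {
    small <- ladder$models[[pr["small"]]]
    large <- ladder$models[[pr["large"]]]
    deltas <- c(); excluded <- character(0)
    for (p in ladder$participants) {
      fs <- small$participants[[p]]; fl <- large$participants[[p]]
      if (fit_usable(fs) && fit_usable(fl)) {
        deltas[p] <- compare_nested(fs, fl)
      } else {
        excluded <- c(excluded, p)
      }
    }
    avg_delta <- if (inherits(small$average, "sat_fit") &&
                     inherits(large$average, "sat_fit")) {
      compare_nested(small$average, large$average)
    } else NA_real_
    list(
      pair = sprintf("%s vs %s", pr["small"], pr["large"]),
      small = unname(pr["small"]), large = unname(pr["large"]),
      deltas = deltas,
      mean = if (length(deltas)) mean(deltas) else NA_real_,
      min = if (length(deltas)) min(deltas) else NA_real_,
      max = if (length(deltas)) max(deltas) else NA_real_,
      n_improved = sum(deltas > 0),
      n = length(deltas),
      avg_delta = avg_delta,
      excluded = excluded
    )
  })
  summary <- data.frame(
    model_pair = vapply(reports, `[[`, character(1), "pair"),
    mean_delta = vapply(reports, `[[`, numeric(1), "mean"),
    min_delta = vapply(reports, `[[`, numeric(1), "min"),
    max_delta = vapply(reports, `[[`, numeric(1), "max"),
    n_improved = vapply(reports, `[[`, numeric(1), "n_improved"),
    n = vapply(reports, `[[`, numeric(1), "n"),
    avg_delta = vapply(reports, `[[`, numeric(1), "avg_delta"),
    stringsAsFactors = FALSE
  )
  structure(list(reports = reports, summary = summary),
            class = "sat_consistency")
}

#' @export
print.sat_consistency <- function(x, ...) {
  cat("Nested-model consistency report\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-22s avg-data delta = %+.3f; participants mean %+.3f [%+.3f, %+.3f], %d/%d improved\n",
                s$model_pair[i], s$avg_delta[i], s$mean_delta[i],
                s$min_delta[i], s$max_delta[i], s$n_improved[i], s$n[i]))
  }
  invisible(x)
}

#' Preferred-model verdict over a fitted ladder
#'
#' An added parameter group is accepted when the averaged-data adjusted-R^2
#' increase over the nested parent exceeds `threshold` AND a majority of
#' (non-excluded) participants improve. A model is justified when every
#' parent present in the candidate set is justified and its addition is
#' accepted. Among justified models with no justified extension, the one
#' with fewest parameters wins; ties go to the model placing more groups on
#' the intercept (delta) rather than the rate (beta), the conservative
#' reading when rate and intercept trade off.
#'
#' @param ladder a `sat_ladder`, or a precomputed [consistency_report()]
#'   together with `ladder`.
#' @param threshold minimal averaged-data adjusted-R^2 gain.
#' @param majority fraction of participants that must improve (strictly
#'   more than this fraction).
#' @param reports optional precomputed `sat_consistency`.
#' @return list with `preferred` (model name), `justified`, `survivors`,
#'   and the consistency `reports`; class `sat_selection`.
#' @export
select_preferred <- function(ladder, threshold = 0.005, majority = 0.5,
                             reports = NULL) {
  stopifnot(inherits(ladder, "sat_ladder"))
  cand <- names(ladder$models)
  if (length(cand) == 0) stop_data("empty candidate set")
  reports <- reports %||% consistency_report(ladder)
  pair_pass <- function(small, large) {
    for (r in reports$reports) {
      if (r$small == small && r$large == large) {
        maj <- r$n > 0 && r$n_improved > majority * r$n
        return(is.finite(r$avg_delta) && r$avg_delta > threshold && maj)
      }
    }
    FALSE
  }
  justified <- stats::setNames(logical(length(cand)), cand)
  is_justified <- function(nm) {
    parents <- parent_names(nm, cand)
    if (length(parents) == 0) return(TRUE)
    all(vapply(parents, function(pn) is_justified(pn) && pair_pass(pn, nm),
               logical(1)))
  }
  for (nm in cand) justified[nm] <- is_justified(nm)
  # survivors: justified models with no justified accepted extension
  survivors <- names(which(justified))
  has_better_child <- vapply(survivors, function(nm) {
    kids <- cand[vapply(cand, function(c2) nm %in% parent_names(c2, cand),
                        logical(1))]
    any(vapply(kids, function(k2) justified[k2] && pair_pass(nm, k2),
               logical(1)))
  }, logical(1))
  survivors <- survivors[!has_better_child]
  if (length(survivors) == 0) survivors <- cand[1]
  ks <- vapply(survivors, function(nm) model_spec(nm)$k, numeric(1))
  nd <- vapply(survivors, function(nm) model_spec(nm)$n_delta, numeric(1))
  ord <- order(ks, -nd, match(survivors, cand))
  structure(list(preferred = survivors[ord[1]],
                 survivors = survivors[ord],
                 justified = justified, reports = reports,
                 threshold = threshold, majority = majority),
            class = "sat_selection")
}

#' @export
print.sat_selection <- function(x, ...) {
  cat(sprintf("Preferred model: %s\n", x$preferred))
  cat("  justified:", paste(names(which(x$justified)), collapse = ", "), "\n")
  invisible(x)
}
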