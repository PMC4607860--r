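# Group-level inference on empirical asymptotes and fitted SAT parameters:
# construction effects, reading-ability effects, and pairwise contrasts.

group_label <- function(map) {
  conds <- names(map)
  vapply(seq_len(max(map)), function(g) {
    paste(conds[map == g], collapse = "+")
  }, character(1))
}

#' Assemble a parameter table from per-participant fits
#'
#' One row per participant x quantity x parameter group. For a quantity
#' with one group per construction (e.g. the asymptotes of a 3-asymptote
#' model) the group labels are the construction names; shared parameters
#' (e.g. the single rate of a 3l-1b-2d model) contribute one row per
#' participant, labelled with the conditions they span. Expanding shared
#' parameters to duplicated per-construction rows would make the
#' random-intercept model degenerate, so rows are per estimated parameter.
#'
#' @param fits named list (participant -> `sat_fit`) for a single model
#'   specification; failed fits may be present and are skipped.
#' @param curves optional full curve table; adds `empirical_asymptote`
#'   rows (mean of the last `m` d-prime values per construction).
#' @param abilities optional data frame `participant`, `ability`.
#' @param m lags entering the empirical asymptote.
#' @param usable_only drop fits whose validity flags report overestimated
#'   asymptotes (default TRUE), mirroring the exclusion of participants who
#'   cannot be fit by a model without asymptote overshoot.
#' @return data frame `participant`, `quantity`, `level`, `value`,
#'   `ability`.
#' @export
parameter_table <- function(fits, curves = NULL, abilities = NULL, m = 4L,
                            usable_only = TRUE) {
  rows <- list()
  for (p in names(fits)) {
    fit <- fits[[p]]
    if (!inherits(fit, "sat_fit")) next
    if (usable_only && !fit_usable(fit)) next
    spec <- fit$spec
    maps <- list(lambda = spec$lambda_map, beta = spec$beta_map,
                 delta = spec$delta_map)
    off <- c(lambda = 0L, beta = spec$n_lambda,
             delta = spec$n_lambda + spec$n_beta)
    for (q in names(maps)) {
      labs <- group_label(maps[[q]])
      for (g in seq_along(labs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = p, quantity = q, level = labs[g],
          value = unname(fit$theta[off[[q]] + g]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_data("no usable fits to tabulate")
  if (!is.null(curves)) {
    emp <- empirical_asymptote(curves[curves$participant %in% out$participant, ],
                               m = m)
    out <- rbind(out, data.frame(
      participant = emp$participant, quantity = "empirical_asymptote",
      level = emp$construction, value = emp$empirical_asymptote,
      stringsAsFactors = FALSE))
  }
  if (!is.null(abilities)) {
    out$ability <- abilities$ability[match(out$participant,
                                           abilities$participant)]
  } else {
    out$ability <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Mixed-model analysis of a SAT quantity
#'
#' Fits a linear mixed model with participant random intercepts to the
#' per-participant values of one quantity, with a fixed effect of the
#' parameter grouping (construction, for per-construction quantities) and
#' optionally standardized reading ability plus its interaction. F tests
#' use Satterthwaite-approximated denominator degrees of freedom; factors
#' are sum-coded so the ability main effect is evaluated at the average
#' condition. When the quantity has a single shared parameter group (one
#' value per participant) the random intercept is unidentifiable and an
#' ordinary least-squares regression on ability is reported instead.
#'
#' @param table a [parameter_table()].
#' @param quantity one of `"lambda"`, `"beta"`, `"delta"`,
#'   `"empirical_asymptote"`.
#' @param with_ability include standardized ability and its interaction
#'   with the grouping factor.
#' @return an object of class `sat_anova`: `anova` data frame (`effect`,
#'   `F`, `df_num`, `df_den`, `p`), the fitted `model`, and the analyzed
#'   data.
#' @export
mixed_anova <- function(table, quantity, with_ability = FALSE) {
  d <- table[table$quantity == quantity, , drop = FALSE]
  if (nrow(d) == 0) stop_data("no rows for quantity '", quantity, "'")
  if (length(unique(d$participant)) < 2L) {
    stop("estimation error: need at least 2 participants", call. = FALSE)
  }
  if (with_ability) {
    if (!any(is.finite(d$ability))) {
      stop_data("ability scores required for with_ability = TRUE")
    }
    d$ability_z <- as.numeric(scale(d$ability))
  }
  n_levels <- length(unique(d$level))
  if (n_levels >= 2L) {
    d$level <- factor(d$level)
    stats::contrasts(d$level) <- stats::contr.sum(n_levels)
    form <- if (with_ability) {
      value ~ level * ability_z + (1 | participant)
    } else {
      value ~ level + (1 | participant)
    }
    model <- tryCatch(
      suppressMessages(lmerTest::lmer(
        form, data = d,
        control = lme4::lmerControl(check.conv.singular = "ignore",
                                    calc.derivs = FALSE))),
      error = function(e) stop("estimation error: ", conditionMessage(e),
                               call. = FALSE))
    a <- suppressWarnings(stats::anova(model, ddf = "Satterthwaite"))
    res <- data.frame(effect = rownames(a), F = a[["F value"]],
                      df_num = a$NumDF, df_den = a$DenDF,
                      p = a[["Pr(>F)"]], stringsAsFactors = FALSE)
  } else {
    if (!with_ability) {
      stop_data("quantity '", quantity, "' has a single shared group and no ",
                "covariate; nothing to test")
    }
    model <- stats::lm(value ~ ability_z, data = d)
    a <- stats::anova(model)
    res <- data.frame(effect = "ability_z", F = a[["F value"]][1],
                      df_num = a$Df[1], df_den = a$Df[2],
                      p = a[["Pr(>F)"]][1], stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  structure(list(anova = res, model = model, quantity = quantity,
                 data = d), class = "sat_anova")
}

#' @export
print.sat_anova <- function(x, ...) {
  cat(sprintf("Mixed-model analysis of %s\n", x$quantity))
  a <- x$anova
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-16s F(%g, %.1f) = %.2f, p = %.4g\n", a$effect[i],
                a$df_num[i], a$df_den[i], a$F[i], a$p[i]))
  }
  invisible(x)
}

#' Pairwise contrasts between parameter-group levels
#'
#' Paired t tests on per-participant values for every pair of levels of a
#' quantity, using the convention that |t| > 2 marks significance. A pair
#' with zero variance of the differences but a nonzero mean difference is
#' degenerate and reported with an infinite-t sentinel.
#'
#' @param table a [parameter_table()].
#' @param quantity quantity to contrast.
#' @return data frame `quantity`, `pair`, `mean_diff`, `t`, `df`,
#'   `significant`, `degenerate`.
#' @export
pairwise_contrasts <- function(table, quantity) {
  d <- table[table$quantity == quantity, , drop = FALSE]
  levels <- unique(d$level)
  if (length(levels) < 2L) {
    stop("estimation error: need at least 2 levels to contrast", call. = FALSE)
  }
  if (length(unique(d$participant)) < 2L) {
    stop("estimation error: need at least 2 participants", call. = FALSE)
  }
  combs <- utils::combn(levels, 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1, i]; b2 <- combs[2, i]
    da <- d[d$level == a, c("participant", "value")]
    db <- d[d$level == b2, c("participant", "value")]
    common <- intersect(da$participant, db$participant)
    diffs <- da$value[match(common, da$participant)] -
      db$value[match(common, db$participant)]
    n <- length(diffs)
    s <- stats::sd(diffs)
    degenerate <- is.na(s) || s == 0
    tval <- if (degenerate) {
      if (mean(diffs) == 0) 0 else Inf * sign(mean(diffs))
    } else {
      mean(diffs) / (s / sqrt(n))
    }
    data.frame(quantity = quantity, pair = paste(a, "-", b2),
               mean_diff = mean(diffs), t = tval, df = n - 1L,
               significant = abs(tval) > 2, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
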