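# File schemas, configuration, and the end-to-end pipeline runner.
#
# Two input dialects exist because MR-SAT hardware exports differ: lag-code
# trial tables (one row per trial with design labels and lag_1..lag_n codes;
# the canonical internal form) and raw key-press event streams (participant,
# trial, time_s, key, action) accompanied by a design table. All tables are
# comma-separated with a header and floating point values printed at 6
# significant digits, so pipeline outputs are byte-stable.

write_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a lag-code trial table
#'
#' Columns: `participant`, `list`, `trial`, `item`, `sentence_type`,
#' `construction`, `acceptable`, `control_anomaly`, `lag_1` .. `lag_n`.
#'
#' @param trials trial table data frame.
#' @param path file path.
#' @export
write_trials <- function(trials, path) write_table(trials, path)

#' @rdname write_trials
#' @param spec a [design_spec()] used to validate the schema.
#' @return `read_trials()`: the validated trial table.
#' @export
read_trials <- function(path, spec) {
  stopifnot(inherits(spec, "sat_design"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lagcols <- grep("^lag_", names(df), value = TRUE)
  if (length(lagcols) != spec$n_tones) {
    stop_data("schema error in ", path, ": expected ", spec$n_tones,
              " lag columns, found ", length(lagcols))
  }
  need <- c("participant", "trial", "sentence_type", "construction",
            "acceptable", "control_anomaly")
  if (!all(need %in% names(df))) {
    stop_data("schema error in ", path, ": missing column(s) ",
              paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad_type <- !df$sentence_type %in% spec$type_map$sentence_type
  if (any(bad_type)) {
    stop_data("unknown sentence type '", df$sentence_type[which(bad_type)[1]],
              "' at row ", which(bad_type)[1], " of ", path)
  }
  codes <- as.matrix(df[lagcols])
  bad <- !codes %in% CODE_LEVELS
  if (any(bad)) {
    stop_data("invalid lag code at row ", ((which(bad)[1] - 1) %% nrow(df)) + 1,
              " of ", path)
  }
  df
}

#' Write / read a key-press event stream table
#'
#' Columns: `participant`, `trial`, `time_s`, `key`, `action`.
#' @param events event data frame.
#' @param path file path.
#' @export
write_events <- function(events, path) write_table(events, path)

#' @rdname write_events
#' @return `read_events()`: the validated event table.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "time_s", "key", "action")
  if (!all(need %in% names(df))) {
    stop_data("schema error in ", path, ": missing column(s) ",
              paste(setdiff(need, names(df)), collapse = ", "))
  }
  ord <- order(df$participant, df$trial, df$time_s)
  reordered <- df[ord, , drop = FALSE]
  mono <- tapply(reordered$time_s,
                 paste(reordered$participant, reordered$trial), is.unsorted)
  if (any(unlist(mono))) {
    stop_data("non-monotone event times in ", path)
  }
  reordered
}

#' Convert an event-stream table to lag codes
#'
#' Parses each (participant, trial) stream with [parse_stream()] and joins
#' the codes onto the design rows of the matching trials, yielding the
#' canonical lag-code trial table. Downstream scoring of the two dialects is
#' identical.
#'
#' @param events event table (see [read_events()]).
#' @param design_trials trial design table without lag columns (same schema
#'   as the lag-code table minus `lag_*`).
#' @param spec a [design_spec()].
#' @return lag-code trial table.
#' @export
events_to_trials <- function(events, design_trials, spec) {
  lagcols <- paste0("lag_", seq_len(spec$n_tones))
  codes <- matrix("NONE", nrow(design_trials), spec$n_tones,
                  dimnames = list(NULL, lagcols))
  key <- paste(design_trials$participant, design_trials$trial)
  ev_key <- paste(events$participant, events$trial)
  for (i in seq_len(nrow(design_trials))) {
    stream <- events[ev_key == key[i], , drop = FALSE]
    codes[i, ] <- parse_stream(stream, spec)
  }
  cbind(design_trials, as.data.frame(codes, stringsAsFactors = FALSE))
}

#' Write a d-prime curve table
#' @param curves a `sat_curves` data frame.
#' @param path file path.
#' @export
write_curves <- function(curves, path) write_table(as.data.frame(curves), path)

#' @rdname write_curves
#' @return `read_curves()`: the curve table.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("sat_curves", class(df))
  df
}

#' Default pipeline configuration
#'
#' Nested list mirroring the analysis stages: `design`, `generative`,
#' `cohort`, `scoring`, `models`, `fit`, `selection`, `inference`, `seed`.
#' Any subset can be overridden by a YAML file via [read_config()].
#'
#' @return configuration list.
#' @export
default_config <- function() {
  ref <- reference_params()$comm_3l1b2d
  list(
    seed = 1L,
    design = list(n_types = 8L, items_per_type = 48L, n_lists = 4L,
                  n_tones = 15L, tone_interval = 0.350, tone_lead = 0.200,
                  response_period = 5.000),
    generative = list(lambda = as.list(ref$lambda), beta = as.list(ref$beta),
                      delta = as.list(ref$delta), criterion = 0,
                      ability_slope_lambda = 0.3, switch_prob = 0,
                      control_lambda_scale = 0.8, trials_per_cell = 48L),
    cohort = list(n_participants = 22L, sd_lambda = 0.2, sd_log_beta = 0.2,
                  sd_delta = 0.1),
    scoring = list(clip = TRUE, average = "pooled", asymptote_m = 4L),
    models = list("1l-1b-1d", "2l-1b-1d", "3l-1b-1d", "3l-1b-2d",
                  "3l-1b-3d", "3l-2b-1d"),
    fit = list(restarts = 3L, algorithms = c("port", "lbfgsb"),
               lambda_bounds = c(0, 6), beta_bounds = c(0.05, 6),
               delta_bounds = c(0, 3)),
    selection = list(threshold = 0.005, majority = 0.5),
    inference = list(quantities = c("empirical_asymptote", "lambda", "beta",
                                    "delta"),
                     with_ability = TRUE)
  )
}

#' Read a YAML pipeline configuration
#'
#' Values in the file override the defaults of [default_config()];
#' unspecified blocks keep their defaults.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

config_design <- function(cfg) do.call(design_spec, cfg$design)

config_generative <- function(cfg) {
  g <- cfg$generative
  generative_params(
    lambda = unlist(g$lambda), beta = unlist(g$beta), delta = unlist(g$delta),
    criterion = g$criterion %||% 0,
    ability_slope_lambda = g$ability_slope_lambda %||% 0,
    switch_prob = g$switch_prob %||% 0,
    control_lambda_scale = g$control_lambda_scale %||% 0.8,
    trials_per_cell = g$trials_per_cell %||% 48L
  )
}

#' Run the full MR-SAT analysis pipeline
#'
#' simulate (or load) -> score -> fit ladder -> consistency/selection ->
#' inference. All artifacts are written to `out_dir` as comma-separated
#' tables plus a JSON run manifest (seed, config, file checksums); rerunning
#' with the same configuration and seed reproduces the outputs
#' byte-identically. Each stage failure aborts with the stage named,
#' preserving the artifacts already written.
#'
#' @param config configuration list ([default_config()]) or path to a YAML
#'   file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of `config$seed`.
#' @param trials optional preexisting lag-code trial table; skips
#'   simulation.
#' @param abilities optional `participant`/`ability` table accompanying
#'   `trials`.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "satdyn-run",
                         seed = NULL, trials = NULL, abilities = NULL,
                         quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else config
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[satdyn] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table(df, path)
    files <<- c(files, path)
  }

  spec <- stage("design", config_design(cfg))
  if (is.null(trials)) {
    say("simulating cohort")
    cohort <- stage("simulate", {
      base <- config_generative(cfg)
      cp <- cohort_params(n_participants = cfg$cohort$n_participants,
                          base = base, sd_lambda = cfg$cohort$sd_lambda,
                          sd_log_beta = cfg$cohort$sd_log_beta,
                          sd_delta = cfg$cohort$sd_delta,
                          seed = hash_mix(seed, "cohort"))
      simulate_cohort(spec, cp, seed = hash_mix(seed, "simulate"))
    })
    trials <- cohort$trials
    abilities <- cohort$abilities
  } else {
    if (is.null(cfg$generative) && is.null(trials)) {
      stop_config("either a generative block or an input trial table is required")
    }
  }
  put(trials, "trials.csv")
  if (!is.null(abilities)) put(abilities, "abilities.csv")

  say("scoring d-prime curves")
  curves <- stage("score", dprime_curves(trials, spec,
                                         clip = cfg$scoring$clip %||% TRUE,
                                         average = cfg$scoring$average %||% "pooled"))
  put(as.data.frame(curves), "curves.csv")
  crp <- stage("score", cr_profile(trials, spec))
  put(crp, "cr_profile.csv")

  say("fitting model ladder")
  fcfg <- stage("fit", do.call(fit_config, c(cfg$fit, list(seed = hash_mix(seed, "fit")))))
  ladder <- stage("fit", fit_ladder(curves, cfg$models, fcfg))
  fit_rows <- list()
  for (nm in names(ladder$models)) {
    m <- ladder$models[[nm]]
    all_fits <- c(list(average = m$average), m$participants)
    for (u in names(all_fits)) {
      f <- all_fits[[u]]
      if (!inherits(f, "sat_fit")) next
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        unit = u, model = nm,
        parameter = c(names(f$theta), "sse", "adj_r2"),
        value = c(unname(f$theta), f$sse, f$adj_r2),
        stringsAsFactors = FALSE)
    }
  }
  put(do.call(rbind, fit_rows), "fits.csv")

  say("model selection")
  sel <- stage("selection", select_preferred(
    ladder, threshold = cfg$selection$threshold %||% 0.005,
    majority = cfg$selection$majority %||% 0.5))
  put(sel$reports$summary, "consistency.csv")
  put(data.frame(preferred = sel$preferred,
                 survivors = paste(sel$survivors, collapse = ";"),
                 stringsAsFactors = FALSE), "selection.csv")

  say("inference on ", sel$preferred)
  pref_fits <- ladder$models[[sel$preferred]]$participants
  ptab <- stage("inference",
                parameter_table(pref_fits, curves = curves,
                                abilities = abilities,
                                m = cfg$scoring$asymptote_m %||% 4L))
  put(ptab, "parameters.csv")
  with_ability <- isTRUE(cfg$inference$with_ability) &&
    !is.null(abilities) && any(is.finite(ptab$ability))
  anova_rows <- list(); contrast_rows <- list()
  for (q in cfg$inference$quantities) {
    if (!q %in% ptab$quantity) next
    an <- tryCatch(mixed_anova(ptab, q, with_ability = with_ability),
                   error = function(e) NULL)
    if (!is.null(an)) {
      a <- an$anova; a$quantity <- q
      anova_rows[[length(anova_rows) + 1L]] <- a
    }
    ct <- tryCatch(pairwise_contrasts(ptab, q), error = function(e) NULL)
    if (!is.null(ct)) contrast_rows[[length(contrast_rows) + 1L]] <- ct
  }
  if (length(anova_rows)) put(do.call(rbind, anova_rows), "anova.csv")
  if (length(contrast_rows)) put(do.call(rbind, contrast_rows), "contrasts.csv")

  manifest <- list(
    seed = seed,
    config = cfg,
    package = "satdyn",
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  invisible(list(spec = spec, trials = trials, curves = curves,
                 ladder = ladder, selection = sel, parameters = ptab,
                 anova = if (length(anova_rows)) do.call(rbind, anova_rows),
                 contrasts = if (length(contrast_rows)) do.call(rbind, contrast_rows),
                 manifest = manifest))
}
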