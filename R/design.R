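# Experimental design: sentence types, lists, and the tone/response schedule.

#' Construction condition labels
#'
#' The three construction conditions of the subject-verb dependency design:
#' no interpolated material, an interpolated object relative clause, and
#' interpolated object + subject relative clauses.
#' @export
sat_conditions <- function() c("NoInterp", "OR", "OR+SR")

default_type_map <- function(n_types = 8L) {
  m <- data.frame(
    sentence_type   = paste0("T", 1:8),
    construction    = c("NoInterp", "NoInterp", "OR", "OR", "OR",
                        "OR+SR", "OR+SR", "OR+SR"),
    acceptable      = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    control_anomaly = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  if (n_types > nrow(m)) {
    stop_config("no default type map for n_types > 8; supply `type_map`")
  }
  m[seq_len(n_types), , drop = FALSE]
}

#' Specify an MR-SAT experimental design
#'
#' Describes the stimulus design and the tone-paced response schedule of an
#' auditory multiple-response speed-accuracy tradeoff experiment. The default
#' is the eight-sentence-type subject-verb dependency design: 48 instances of
#' each type split over 4 lists of 96 sentences (12 per type per list), with
#' 15 response tones every 350 ms beginning 200 ms before the onset of the
#' sentence-final critical word, spanning a 5000 ms response period.
#'
#' Sentence types map onto three construction conditions (see
#' [sat_conditions()]); types T5 and T8 are control items whose grammatical
#' anomaly sits inside the interpolated clause rather than at the
#' sentence-final verb.
#'
#' @param n_types number of sentence types.
#' @param items_per_type stimulus instances per sentence type.
#' @param n_lists number of experimental lists the items are dealt into.
#' @param n_tones number of response tones per trial.
#' @param tone_interval seconds between tone onsets.
#' @param tone_lead seconds by which the first tone precedes critical-word
#'   onset (lag times are reported relative to that onset).
#' @param response_period total response window in seconds, measured from the
#'   first tone.
#' @param type_map optional data frame with columns `sentence_type`,
#'   `construction`, `acceptable`, `control_anomaly`; defaults to the
#'   standard eight-type map.
#' @return an object of class `sat_design` (a validated list).
#' @examples
#' spec <- design_spec()
#' lag_times(spec)
#' @export
design_spec <- function(n_types = 8L, items_per_type = 48L, n_lists = 4L,
                        n_tones = 15L, tone_interval = 0.350,
                        tone_lead = 0.200, response_period = 5.000,
                        type_map = NULL) {
  n_types <- as.integer(n_types)
  items_per_type <- as.integer(items_per_type)
  n_lists <- as.integer(n_lists)
  n_tones <- as.integer(n_tones)
  if (n_types < 1L || items_per_type < 1L || n_lists < 1L || n_tones < 0L) {
    stop_config("n_types, items_per_type and n_lists must be positive counts")
  }
  if ((n_types * items_per_type) %% n_lists != 0L) {
    stop_config("n_types * items_per_type must equal n_lists * sentences_per_list ",
                "(total items not divisible by n_lists)")
  }
  sentences_per_list <- (n_types * items_per_type) %/% n_lists
  if (sentences_per_list %% n_types != 0L) {
    stop_config("sentences_per_list must equal n_types * instances_per_type_per_list ",
                "(items_per_type not divisible by n_lists)")
  }
  instances_per_type_per_list <- sentences_per_list %/% n_types
  if (tone_interval <= 0 || tone_lead < 0 || response_period <= 0) {
    stop_config("tone_interval and response_period must be positive; tone_lead non-negative")
  }
  if (n_tones > 0L && !(tone_lead < tone_interval * n_tones)) {
    stop_config("tone_lead must be smaller than tone_interval * n_tones")
  }
  type_map <- type_map %||% default_type_map(n_types)
  req <- c("sentence_type", "construction", "acceptable", "control_anomaly")
  if (!all(req %in% names(type_map)) || nrow(type_map) != n_types) {
    stop_config("type_map must have one row per sentence type with columns ",
                paste(req, collapse = ", "))
  }
  structure(list(
    n_types = n_types,
    items_per_type = items_per_type,
    n_lists = n_lists,
    sentences_per_list = sentences_per_list,
    instances_per_type_per_list = instances_per_type_per_list,
    n_tones = n_tones,
    tone_interval = tone_interval,
    tone_lead = tone_lead,
    response_period = response_period,
    conditions = unique(type_map$construction),
    type_map = type_map
  ), class = "sat_design")
}

#' @export
print.sat_design <- function(x, ...) {
  cat(sprintf(
    "MR-SAT design: %d types x %d items = %d items; %d lists of %d (%d/type/list)\n",
    x$n_types, x$items_per_type, x$n_types * x$items_per_type,
    x$n_lists, x$sentences_per_list, x$instances_per_type_per_list))
  cat(sprintf("  %d tones every %.0f ms from %.0f ms pre-onset; %.0f ms response period\n",
              x$n_tones, x$tone_interval * 1000, x$tone_lead * 1000,
              x$response_period * 1000))
  invisible(x)
}

#' Response-lag times
#'
#' Times of the response tones relative to critical-word onset:
#' `t_k = -tone_lead + (k - 1) * tone_interval` for `k = 1..n_tones`.
#'
#' @param spec a [design_spec()].
#' @return numeric vector of lag times in seconds.
#' @export
lag_times <- function(spec) {
  stopifnot(inherits(spec, "sat_design"))
  if (spec$n_tones == 0L) return(numeric(0))
  -spec$tone_lead + (seq_len(spec$n_tones) - 1L) * spec$tone_interval
}

#' Build the stimulus lists
#'
#' Deals the stimulus instances of each sentence type into the experimental
#' lists, so that every list contains exactly
#' `instances_per_type_per_list` items of each type. Assignment is
#' seed-reproducible.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed for the item-to-list shuffle.
#' @return a data frame with one row per item: `item`, `sentence_type`,
#'   `construction`, `acceptable`, `control_anomaly`, `list`.
#' @export
build_design <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sat_design"))
  tm <- spec$type_map
  out <- do.call(rbind, lapply(seq_len(spec$n_types), function(i) {
    idx <- with_seed(hash_mix(seed, "build_design", i),
                     sample.int(spec$items_per_type))
    data.frame(
      item = sprintf("%s_%03d", tm$sentence_type[i], seq_len(spec$items_per_type)),
      sentence_type = tm$sentence_type[i],
      construction = tm$construction[i],
      acceptable = tm$acceptable[i],
      control_anomaly = tm$control_anomaly[i],
      list = rep(seq_len(spec$n_lists),
                 each = spec$instances_per_type_per_list)[order(idx)],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  attr(out, "design") <- spec
  out
}
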