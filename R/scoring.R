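# Scoring: response streams -> per-lag judgments -> d-prime time courses
# and control-condition correct-rejection profiles.
#
# Conventions (all switchable where noted): tone windows are half-open
# [t_k, t_{k+1}); key state is sampled at window start, so a key released
# exactly at a tone time is not held at that tone. BOTH (undecided) earns
# 0.5 yes-credit; NONE (no key held) is treated as missing, not as a guess.

#' Parse a key-press event stream into per-lag codes
#'
#' For each tone time the code reflects which keys are held at that instant:
#' both keys -> `BOTH`, one key -> that key, none -> `NONE`. A key counts as
#' held at `t` if a `down` event at time <= `t` has no matching `up` at
#' time <= `t` (so presses at a tone time count, releases at a tone time do
#' not).
#'
#' @param stream data frame `participant`, `trial`, `time_s`, `key`,
#'   `action` for a single trial, time-sorted or sortable.
#' @param spec a [design_spec()].
#' @return character vector of length `spec$n_tones`.
#' @export
parse_stream <- function(stream, spec) {
  stopifnot(inherits(spec, "sat_design"))
  tt <- lag_times(spec)
  if (nrow(stream) == 0) return(rep("NONE", spec$n_tones))
  bad <- !stream$key %in% c("YES", "NO") | !stream$action %in% c("down", "up")
  if (any(bad)) {
    stop_data("malformed events (trial ", stream$trial[1], "): unknown key/action")
  }
  held_at <- function(key) {
    ev <- stream[stream$key == key, , drop = FALSE]
    ev <- ev[order(ev$time_s, ev$action != "up"), , drop = FALSE]
    # validate pairing: state must alternate down/up
    state <- FALSE
    for (i in seq_len(nrow(ev))) {
      is_down <- ev$action[i] == "down"
      if (is_down == state) {
        stop_data("malformed event pairing for key ", key, " (participant ",
                  ev$participant[1], ", trial ", ev$trial[1], ", time ",
                  ev$time_s[i], ")")
      }
      state <- is_down
    }
    downs <- ev$time_s[ev$action == "down"]
    ups <- ev$time_s[ev$action == "up"]
    eps <- 1e-9  # events logged at a tone's nominal time count at that tone
    vapply(tt, function(t) {
      sum(downs <= t + eps) - sum(ups <= t + eps) > 0
    }, logical(1))
  }
  yes_held <- held_at("YES")
  no_held <- held_at("NO")
  codes <- rep("NONE", spec$n_tones)
  codes[yes_held & no_held] <- "BOTH"
  codes[yes_held & !no_held] <- "YES"
  codes[!yes_held & no_held] <- "NO"
  codes
}

# yes-credit per code: YES 1, NO 0, BOTH 0.5, NONE missing.
code_credit <- function(codes) {
  cr <- matrix(NA_real_, nrow(codes), ncol(codes))
  cr[codes == "YES"] <- 1
  cr[codes == "NO"] <- 0
  cr[codes == "BOTH"] <- 0.5
  cr
}

lag_code_matrix <- function(trials, spec) {
  lagcols <- paste0("lag_", seq_len(spec$n_tones))
  missing_cols <- setdiff(lagcols, names(trials))
  if (length(missing_cols) > 0) {
    stop_data("trial table lacks lag columns: ",
              paste(missing_cols, collapse = ", "))
  }
  as.matrix(trials[lagcols])
}

# Rate of a cell at every lag with the 1/(2N) edge clip, where N is the
# per-lag count of scorable (non-NONE) trials.
cell_rate <- function(credit_sum, n_eff, clip = TRUE) {
  r <- credit_sum / n_eff
  if (clip) pmin(pmax(r, 1 / (2 * n_eff)), 1 - 1 / (2 * n_eff)) else r
}

#' Compute d-prime time courses per participant and construction
#'
#' Per lag, the hit rate is the mean yes-credit over acceptable trials and
#' the false-alarm rate the mean over matched unacceptable trials (control
#' anomaly trials are excluded); rates are clipped to
#' `[1/(2N), 1 - 1/(2N)]` so `d' = z(hit) - z(fa)` is always finite. An
#' `"average"` curve is emitted as well, by default pooling trial counts
#' across participants before the z-transform (count pooling); set
#' `average = "mean"` for the mean of per-participant d-primes instead.
#'
#' @param trials lag-code trial table (as produced by [simulate_cohort()] or
#'   [read_trials()]).
#' @param spec a [design_spec()].
#' @param clip apply the 1/(2N) edge correction (default TRUE).
#' @param average `"pooled"` (default) or `"mean"`.
#' @param include_average emit the averaged curve (default TRUE).
#' @return data frame `participant`, `construction`, `lag`, `lag_time`,
#'   `dprime`, `n_acc`, `n_unacc`, of class `sat_curves`.
#' @export
dprime_curves <- function(trials, spec, clip = TRUE,
                          average = c("pooled", "mean"),
                          include_average = TRUE) {
  stopifnot(inherits(spec, "sat_design"))
  average <- match.arg(average)
  trials <- trials[!trials$control_anomaly, , drop = FALSE]
  if (nrow(trials) == 0) stop_data("no experimental (non-control) trials")
  credit <- code_credit(lag_code_matrix(trials, spec))
  tt <- lag_times(spec)
  conds <- unique(trials$construction)
  participants <- unique(trials$participant)

  cell_sums <- function(rows) {
    # returns list(sum, n) per lag for a set of trial rows
    cr <- credit[rows, , drop = FALSE]
    list(s = colSums(cr, na.rm = TRUE), n = colSums(!is.na(cr)))
  }
  one_curve <- function(acc_rows, unacc_rows, pid, cn) {
    a <- cell_sums(acc_rows); u <- cell_sums(unacc_rows)
    if (any(a$n == 0)) {
      stop_data("no scorable acceptable trials for participant ", pid,
                ", construction ", cn, " at lag ", which(a$n == 0)[1])
    }
    if (any(u$n == 0)) {
      stop_data("no scorable unacceptable trials for participant ", pid,
                ", construction ", cn, " at lag ", which(u$n == 0)[1])
    }
    hit <- cell_rate(a$s, a$n, clip)
    fa <- cell_rate(u$s, u$n, clip)
    data.frame(participant = pid, construction = cn,
               lag = seq_len(spec$n_tones), lag_time = tt,
               dprime = stats::qnorm(hit) - stats::qnorm(fa),
               n_acc = a$n, n_unacc = u$n, stringsAsFactors = FALSE)
  }

  out <- list()
  for (cn in conds) {
    acc_all <- trials$construction == cn & trials$acceptable
    unacc_all <- trials$construction == cn & !trials$acceptable
    if (!any(acc_all) || !any(unacc_all)) {
      stop_data("construction ", cn, " lacks ",
                if (!any(acc_all)) "acceptable" else "unacceptable", " trials")
    }
    for (pid in participants) {
      pr <- trials$participant == pid
      out[[length(out) + 1L]] <- one_curve(which(acc_all & pr),
                                           which(unacc_all & pr), pid, cn)
    }
    if (include_average) {
      if (average == "pooled") {
        out[[length(out) + 1L]] <- one_curve(which(acc_all), which(unacc_all),
                                             "average", cn)
      } else {
        pc <- do.call(rbind, lapply(participants, function(pid) {
          pr <- trials$participant == pid
          one_curve(which(acc_all & pr), which(unacc_all & pr), pid, cn)
        }))
        agg <- stats::aggregate(dprime ~ lag, data = pc, FUN = mean)
        out[[length(out) + 1L]] <- data.frame(
          participant = "average", construction = cn, lag = agg$lag,
          lag_time = tt[agg$lag], dprime = agg$dprime,
          n_acc = as.integer(tapply(pc$n_acc, pc$lag, sum)),
          n_unacc = as.integer(tapply(pc$n_unacc, pc$lag, sum)),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("sat_curves", class(res))
  res
}

#' Empirical asymptote of a d-prime curve
#'
#' Arithmetic mean of the final `m` d-prime values (default 4), the
#' model-free estimate of asymptotic accuracy.
#'
#' @param curve numeric d-prime vector (time-ordered), or a curve data frame
#'   (possibly covering several participants/constructions).
#' @param m number of final values to average.
#' @return a single value for a vector input; a data frame
#'   (`participant`, `construction`, `empirical_asymptote`) for a curve
#'   table.
#' @export
empirical_asymptote <- function(curve, m = 4L) {
  if (is.numeric(curve)) {
    if (m > length(curve)) {
      stop("argument error: m (", m, ") exceeds number of lags (",
           length(curve), ")", call. = FALSE)
    }
    return(mean(utils::tail(curve, m)))
  }
  stopifnot(is.data.frame(curve))
  groups <- unique(curve[c("participant", "construction")])
  groups$empirical_asymptote <- mapply(function(p, cn) {
    sub <- curve[curve$participant == p & curve$construction == cn, ]
    empirical_asymptote(sub$dprime[order(sub$lag)], m)
  }, groups$participant, groups$construction)
  rownames(groups) <- NULL
  groups
}

#' Correct-rejection profiles for unacceptable conditions
#'
#' Per-lag proportion of NO responses (BOTH credited 0.5, NONE excluded)
#' among unacceptable trials, reported separately for the
#' interpolated-anomaly control group (anomaly inside the embedded clause)
#' and the sentence-final-anomaly group of the interpolated constructions.
#' The pre-onset first lag is dropped by default.
#'
#' @param trials lag-code trial table.
#' @param spec a [design_spec()].
#' @param drop_first_lag drop the pre-onset tone from the profile
#'   (default TRUE).
#' @return data frame `group`, `lag`, `lag_time`, `cr`, `n`.
#' @export
cr_profile <- function(trials, spec, drop_first_lag = TRUE) {
  stopifnot(inherits(spec, "sat_design"))
  interp <- trials$control_anomaly
  final <- !trials$acceptable & !trials$control_anomaly &
    trials$construction != "NoInterp"
  if (!any(interp)) stop_data("no interpolated-anomaly (control) trials")
  if (!any(final)) stop_data("no sentence-final-anomaly trials")
  credit <- code_credit(lag_code_matrix(trials, spec))
  no_credit <- 1 - credit  # NO -> 1, YES -> 0, BOTH -> 0.5
  tt <- lag_times(spec)
  lags <- seq_len(spec$n_tones)
  if (drop_first_lag) lags <- lags[-1]
  one <- function(rows, label) {
    cr <- no_credit[rows, lags, drop = FALSE]
    n <- colSums(!is.na(cr))
    if (any(n == 0)) {
      stop_data("no scorable trials in group ", label, " at lag ",
                lags[which(n == 0)[1]])
    }
    data.frame(group = label, lag = lags, lag_time = tt[lags],
               cr = colSums(cr, na.rm = TRUE) / n, n = n,
               stringsAsFactors = FALSE)
  }
  res <- rbind(one(which(interp), "interpolated_anomaly"),
               one(which(final), "final_anomaly"))
  rownames(res) <- NULL
  res
}
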