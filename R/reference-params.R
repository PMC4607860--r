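# Bundled averaged-data parameter sets for the exponential SAT model.

#' Reference averaged-data SAT parameter sets
#'
#' Averaged-data parameter estimates for the exponential approach-to-limit
#' model from two auditory MR-SAT grammaticality-judgment experiments on
#' subject-verb dependency resolution: a university cohort (high-accuracy
#' listeners) and an age-matched community cohort with a wide range of
#' reading ability. These sets serve two purposes: they are the default
#' generating parameters of the cohort simulator, and they anchor the
#' noiseless round-trip validation of the fitting portfolio (generate a
#' curve set from a row, refit the matching model specification, and recover
#' every parameter).
#'
#' Each element contains the model name, the per-construction asymptotes
#' (`lambda`, d-prime units), rates (`beta`, 1/s) and intercepts
#' (`delta`, s) in the condition order of [sat_conditions()].
#'
#' @return a named list of parameter sets:
#' \describe{
#'   \item{univ_3l1b2d}{university cohort, three asymptotes, one rate, two
#'     intercepts.}
#'   \item{univ_3l2b1d}{university cohort, three asymptotes, two rates, one
#'     intercept.}
#'   \item{comm_3l1b2d}{community cohort, three asymptotes, one rate, two
#'     intercepts.}
#' }
#' @export
reference_params <- function() {
  cond <- sat_conditions()
  nm <- function(x) stats::setNames(x, cond)
  list(
    univ_3l1b2d = list(
      model  = "3l-1b-2d",
      lambda = nm(c(3.897, 2.690, 1.489)),
      beta   = nm(c(0.826, 0.826, 0.826)),
      delta  = nm(c(0.831, 1.223, 1.223))
    ),
    univ_3l2b1d = list(
      model  = "3l-2b-1d",
      lambda = nm(c(3.666, 3.256, 1.685)),
      beta   = nm(c(1.156, 0.439, 0.439)),
      delta  = nm(c(0.886, 0.886, 0.886))
    ),
    comm_3l1b2d = list(
      model  = "3l-1b-2d",
      lambda = nm(c(2.690, 1.482, 0.834)),
      beta   = nm(c(0.779, 0.779, 0.779)),
      delta  = nm(c(1.266, 1.579, 1.579))
    )
  )
}

#' Receptive-vocabulary ability prior
#'
#' Scaled receptive-vocabulary scores of the community cohort: mean 96.41,
#' SD 13.60, observed range 74-128. The simulator draws abilities from a
#' normal distribution with these moments truncated to the observed range,
#' and standardizes scores with the same mean/SD before applying the
#' ability-on-asymptote slope.
#'
#' @return list with `mean`, `sd`, `lower`, `upper`.
#' @export
ability_prior <- function() {
  list(mean = 96.41, sd = 13.60, lower = 74, upper = 128)
}
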