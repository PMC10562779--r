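# Shared helpers: seed fan-out, age bands, critical values.

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed and an integer offset to a new seed
#' below 2^31, so that every stochastic stage of the pipeline draws from its
#' own reproducible stream.
#'
#' @param master Integer master seed.
#' @param offset Integer stage offset.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(offset), length(offset) == 1L)
  # 2147483629 is prime and < 2^31; 104729 spreads consecutive offsets apart
  as.integer((abs(as.numeric(master)) + 104729 * abs(as.numeric(offset))) %% 2147483629)
}

#' Age band labels used for stratified networks
#'
#' The six bands: `<40`, `40-49`, `50-59`, `60-69`, `70-79`, `>=80`.
#'
#' @return Character vector of band labels, in increasing age order.
#' @export
age_band_labels <- function() {
  c("<40", "40-49", "50-59", "60-69", "70-79", ">=80")
}

#' Assign ages to age bands
#'
#' Bands are left-closed: an age of exactly 40 falls in `40-49`, 39.99 in
#' `<40`.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels [age_band_labels()].
#' @export
assign_age_band <- function(age) {
  cut(age, breaks = c(-Inf, 40, 50, 60, 70, 80, Inf),
      labels = age_band_labels(), right = FALSE)
}

#' Two-sided normal critical value for the pair-significance screen
#'
#' The screen on the t statistic of a disease pair uses the two-sided
#' standard-normal critical value at level `p` (2.5758... at p = 0.01,
#' conventionally quoted as 2.58).
#'
#' @param p Two-sided significance level (default 0.01).
#' @return The critical value, a positive scalar.
#' @export
t_critical_value <- function(p = 0.01) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1)
  stats::qnorm(1 - p / 2)
}

# Three-character stem of an ICD-10 code ("E11.3" -> "E11")
icd_stem <- function(code) {
  sub("\\..*$", "", code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
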