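# The three clock outcome transformations and their exact inverses.
#
# All transforms are strictly increasing in age, vectorized, and use natural
# logarithms throughout.

#' Clock transformation constants
#'
#' @param clock1_offset years added to age before the log of the basic clock
#'   so that prenatal (negative) ages stay in the log domain; default 2.
#' @param c2 scale constant of the log-linear change point, default 5.0.
#'   (`c2 = c1 * exp(2.92)`, so the implied proportionality constant
#'   `c1` is about 0.2694; only `c2` is ever used.)
#' @param allometric_exponent exponent of the gestation/ASM ratio in the
#'   change-point surrogate, default 0.38.
#' @param relative_age_clamp_epsilon half-width of the clamp applied to
#'   relative age before the double-log transform, keeping observed encodings
#'   finite for animals at or beyond the recorded maximum lifespan. Must lie
#'   in (0, 0.01); default 1e-6.
#' @return List of class `clock_constants`.
#' @export
clock_constants <- function(clock1_offset = 2, c2 = 5.0,
                            allometric_exponent = 0.38,
                            relative_age_clamp_epsilon = 1e-6) {
  stopifnot(clock1_offset > 0, c2 > 0,
            relative_age_clamp_epsilon > 0,
            relative_age_clamp_epsilon < 0.01)
  structure(list(clock1_offset = clock1_offset, c2 = c2,
                 allometric_exponent = allometric_exponent,
                 relative_age_clamp_epsilon = relative_age_clamp_epsilon),
            class = "clock_constants")
}

# Recycle a trait table against an age vector; returns list of numeric
# vectors of length n. `traits` may have 1 row (recycled) or n rows.
.trait_vectors <- function(traits, n) {
  stopifnot(is.data.frame(traits))
  if (nrow(traits) != 1L && nrow(traits) != n) {
    stop("traits must have 1 row or one row per age value", call. = FALSE)
  }
  idx <- if (nrow(traits) == 1L) rep(1L, n) else seq_len(n)
  list(L = traits$max_lifespan[idx],
       G = traits$gestation_time[idx],
       A = traits$asm[idx])
}

.require_adjusted <- function(traits) {
  if (!isTRUE(attr(traits, "lifespan_adjusted"))) {
    stop("relative-age transforms require a lifespan-adjusted trait table; ",
         "call adjust_max_lifespan() first", call. = FALSE)
  }
}

#' Basic clock transform: log of offset age
#'
#' `y = log(age + offset)`; the offset (2 years by default) keeps prenatal
#' ages inside the log domain.
#'
#' @param age chronological age in years (vectorized).
#' @param constants a [clock_constants()] list.
#' @return Transformed age.
#' @export
clock1_forward <- function(age, constants = clock_constants()) {
  shifted <- age + constants$clock1_offset
  if (any(shifted <= 0, na.rm = TRUE)) {
    stop("age + offset must be positive for the basic clock", call. = FALSE)
  }
  log(shifted)
}

#' Inverse of the basic clock transform
#'
#' @param y transformed age.
#' @inheritParams clock1_forward
#' @return Age in years: `exp(y) - offset`.
#' @export
clock1_inverse <- function(y, constants = clock_constants()) {
  exp(y) - constants$clock1_offset
}

#' Relative age
#'
#' `(age + GestationT) / (MaxLifespan + GestationT)`, in \[0, 1\]. Gestation
#' time shifts the origin to conception so the numerator is never negative;
#' for relative-age clocks the trait table must carry adjusted lifespans.
#'
#' @param age chronological age in years (0 = birth; conception is
#'   `-gestation_time`).
#' @param traits a [trait_table()] row set (1 row recycled, or one per age).
#' @return Relative age values.
#' @export
relative_age <- function(age, traits) {
  tv <- .trait_vectors(traits, length(age))
  if (any(age < -tv$G, na.rm = TRUE)) {
    stop("age below -gestation_time (before conception)", call. = FALSE)
  }
  (age + tv$G) / (tv$L + tv$G)
}

#' Relative-age clock transform (double logarithm)
#'
#' `-log(-log(RelativeAge))`, after clamping relative age into
#' `[eps, 1 - eps]` so animals at or beyond the recorded maximum lifespan map
#' to a finite value. Strictly increasing in age inside the clamp.
#'
#' @inheritParams relative_age
#' @param constants a [clock_constants()] list.
#' @return Double-log transformed relative age (the clock-2 outcome).
#' @export
clock2_forward <- function(age, traits, constants = clock_constants()) {
  .require_adjusted(traits)
  r <- relative_age(age, traits)
  eps <- constants$relative_age_clamp_epsilon
  r <- pmin(pmax(r, eps), 1 - eps)
  -log(-log(r))
}

#' Inverse of the relative-age clock transform
#'
#' `DNAmAge = exp(-exp(-y)) * (MaxLifespan + GestationT) - GestationT`.
#' Output is bounded in `(-GestationT, MaxLifespan)` for all finite `y`.
#'
#' @param y transformed age (unbounded; model predictions may exceed the
#'   range of observed encodings).
#' @inheritParams clock2_forward
#' @return DNAm age in years.
#' @export
clock2_inverse <- function(y, traits, constants = clock_constants()) {
  .require_adjusted(traits)
  tv <- .trait_vectors(traits, length(y))
  exp(-exp(-y)) * (tv$L + tv$G) - tv$G
}

#' Relative adult age
#'
#' `(age + GestationT) / (ASM + GestationT)`: age measured from conception in
#' units of the age at sexual maturity (also from conception). Always
#' positive for ages after conception.
#'
#' @inheritParams relative_age
#' @return Relative adult age values.
#' @export
relative_adult_age <- function(age, traits) {
  tv <- .trait_vectors(traits, length(age))
  x <- (age + tv$G) / (tv$A + tv$G)
  if (any(x <= 0, na.rm = TRUE)) {
    stop("relative adult age must be positive (age at or before conception)",
         call. = FALSE)
  }
  x
}

#' Log-linear transformation with change point m
#'
#' Logarithmic below the change point, linear above it:
#' `y = x/m - 1` when `x >= m`, `y = log(x/m)` when `x < m`. The two branches
#' meet at `x = m` with equal value (0) and equal derivative (`1/m`), so the
#' transform is continuously differentiable; it encodes the faster tick rate
#' of epigenetic clocks during development.
#'
#' @param x positive ratio (relative adult age).
#' @param m positive change point.
#' @return Transformed value(s).
#' @export
loglinear <- function(x, m) {
  if (any(x <= 0, na.rm = TRUE) || any(m <= 0, na.rm = TRUE)) {
    stop("loglinear requires positive x and m", call. = FALSE)
  }
  r <- x / m
  ifelse(r >= 1, r - 1, log(r))
}

#' Exact inverse of the log-linear transformation
#'
#' `x = m * (y + 1)` when `y >= 0`, `x = m * exp(y)` when `y < 0`.
#'
#' @param y transformed value.
#' @param m positive change point.
#' @return Positive ratio(s).
#' @export
loglinear_inverse <- function(y, m) {
  if (any(m <= 0, na.rm = TRUE)) {
    stop("loglinear_inverse requires positive m", call. = FALSE)
  }
  ifelse(y >= 0, m * (y + 1), m * exp(y))
}

#' Log-linear clock transform
#'
#' Applies [loglinear()] to [relative_adult_age()] with the species change
#' point `m_hat` from [estimate_m_hat()]; the clock-3 outcome. Uses only ASM
#' and gestation time, never maximum lifespan.
#'
#' @inheritParams relative_age
#' @param constants a [clock_constants()] list supplying `c2` and the
#'   allometric exponent.
#' @return Log-linear transformed age.
#' @export
clock3_forward <- function(age, traits, constants = clock_constants()) {
  n <- length(age)
  tv <- .trait_vectors(traits, n)
  m <- constants$c2 * (tv$G / tv$A)^constants$allometric_exponent
  loglinear(relative_adult_age(age, traits), m)
}

#' Inverse of the log-linear clock transform
#'
#' `DNAmAge = m_hat * (ASM + GestationT) * (y + 1) - GestationT` for
#' `y >= 0`, and `m_hat * (ASM + GestationT) * exp(y) - GestationT` for
#' `y < 0`.
#'
#' @param y transformed age.
#' @inheritParams clock3_forward
#' @return DNAm age in years.
#' @export
clock3_inverse <- function(y, traits, constants = clock_constants()) {
  n <- length(y)
  tv <- .trait_vectors(traits, n)
  m <- constants$c2 * (tv$G / tv$A)^constants$allometric_exponent
  loglinear_inverse(y, m) * (tv$A + tv$G) - tv$G
}

# Dispatch helpers used by the clock trainer/predictor.
.clock_forward <- function(kind, age, traits, constants) {
  switch(kind,
         clock1 = clock1_forward(age, constants),
         clock2 = clock2_forward(age, traits, constants),
         clock3 = clock3_forward(age, traits, constants),
         stop("unknown clock kind: ", kind, call. = FALSE))
}

.clock_inverse <- function(kind, y, traits, constants) {
  switch(kind,
         clock1 = clock1_inverse(y, constants),
         clock2 = clock2_inverse(y, traits, constants),
         clock3 = clock3_inverse(y, traits, constants),
         stop("unknown clock kind: ", kind, call. = FALSE))
}
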