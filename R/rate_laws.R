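#' Michaelis-Menten saturation term
#'
#' Single-substrate saturation fraction `S / (S + Km)`. Reaction rates in the
#' model are products of such terms, one per substrate, times a maximal rate
#' and any regulation factors.
#'
#' @param S Substrate concentration (mM extracellular, mmol per 1e6 cells
#'   intracellular). Negative values are clamped to zero: transient solver
#'   overshoot below zero must not produce negative rates.
#' @param Km Half-saturation constant, same units as `S`; must be positive.
#' @return Dimensionless fraction in `[0, 1)`.
#' @export
mm_term <- function(S, Km) {
  if (!is.numeric(Km) || any(Km <= 0)) {
    stop("mm_term: Km must be strictly positive", call. = FALSE)
  }
  S <- pmax(S, 0)
  S / (S + Km)
}

#' Non-competitive inhibition rate law
#'
#' `Vmax * S / (S + Km * (1 + I/KI))`: the inhibitor scales the apparent
#' Michaelis constant, so the rate at saturating substrate is reduced by the
#' factor `1/(1 + I/KI)` while substrate affinity in the low-S limit is
#' unchanged. Reduces to plain Michaelis-Menten at `I = 0`.
#'
#' @param Vmax Maximal rate (mmol per 1e6 cells per h).
#' @param S Substrate concentration (clamped at 0 if negative).
#' @param Km Half-saturation constant (> 0).
#' @param I Inhibitor concentration (clamped at 0 if negative).
#' @param KI Inhibition constant (> 0).
#' @return Flux, same units as `Vmax`.
#' @export
noncompetitive_inhibition_rate <- function(Vmax, S, Km, I, KI) {
  if (any(Km <= 0) || any(KI <= 0)) {
    stop("noncompetitive_inhibition_rate: Km and KI must be strictly positive",
         call. = FALSE)
  }
  S <- pmax(S, 0)
  I <- pmax(I, 0)
  Vmax * S / (S + Km * (1 + I / KI))
}

#' Non-competitive inhibition factor
#'
#' The multiplicative factor `1 / (1 + I/K)` applied to growth by lactate and
#' ammonia, and reported as the "inhibition term" time courses in the flux
#' analysis. Equals 1 with no inhibitor and 1/2 at `I = K`.
#'
#' @param I Inhibitor concentration (clamped at 0 if negative).
#' @param K Inhibition constant (> 0).
#' @return Factor in `(0, 1]`.
#' @export
inhibition_factor <- function(I, K) {
  if (any(K <= 0)) stop("inhibition_factor: K must be strictly positive", call. = FALSE)
  1 / (1 + pmax(I, 0) / K)
}

#' Non-essential activation rate law
#'
#' `Vmax * S * (1 + beta*A/(alpha*KA)) / (KS*(1 + A/KA) + S*(1 + A/(alpha*KA)))`.
#' The reaction proceeds without the activator (reducing to Michaelis-Menten at
#' `A = 0`) and is accelerated when `beta > 1`. `alpha = beta = 1` is the
#' neutral identity: the law collapses to plain Michaelis-Menten for any `A`.
#'
#' @param Vmax Maximal rate.
#' @param S Substrate concentration (clamped at 0).
#' @param KS Substrate half-saturation constant (> 0).
#' @param A Activator concentration or ratio (clamped at 0).
#' @param KA Activation constant (> 0).
#' @param alpha Dissociation modifier, must be non-zero (> 0 in practice).
#' @param beta Catalytic modifier, >= 0.
#' @return Flux, same units as `Vmax`.
#' @export
nonessential_activation_rate <- function(Vmax, S, KS, A, KA, alpha, beta) {
  if (any(KS <= 0) || any(KA <= 0)) {
    stop("nonessential_activation_rate: KS and KA must be strictly positive",
         call. = FALSE)
  }
  if (any(alpha == 0)) {
    stop("nonessential_activation_rate: alpha must be non-zero", call. = FALSE)
  }
  S <- pmax(S, 0)
  A <- pmax(A, 0)
  Vmax * S * (1 + beta * A / (alpha * KA)) /
    (KS * (1 + A / KA) + S * (1 + A / (alpha * KA)))
}

#' Saturation term on a nucleotide ratio
#'
#' Energetic cofactors enter rate laws through pool ratios (AMP/ATP, ATP/ADP,
#' NADH/NAD, NADP/NADPH and their inverses) rather than absolute amounts:
#' `r / (r + K)` with `r = numerator/denominator`. An empty denominator pool is
#' treated as ratio infinity only when the numerator is positive; if both pools
#' are empty the term is 0 and a warning attribute is set by the caller's
#' bookkeeping.
#'
#' @param num Numerator pool (clamped at 0).
#' @param den Denominator pool.
#' @param K Half-saturation constant on the ratio (> 0).
#' @return Fraction in `[0, 1]`.
#' @export
ratio_term <- function(num, den, K) {
  if (any(K <= 0)) stop("ratio_term: K must be strictly positive", call. = FALSE)
  num <- pmax(num, 0)
  out <- numeric(length(num))
  ok <- den > 0
  out[ok] <- {
    r <- num[ok] / den[ok]
    r / (r + K)
  }
  # denominator pool exhausted: ratio -> Inf when numerator remains, term -> 1
  out[!ok & num > 0] <- 1
  out
}
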