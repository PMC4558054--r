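# Flux evaluation. Every reaction rate is the product of a maximal rate, one
# saturation term per substrate (on a concentration or a nucleotide-pool
# ratio), and multiplicative regulation factors: 1/(1 + I/Kd) for
# non-competitive inhibition, and the non-essential activation form applied to
# the reaction's leading substrate term. Negative concentrations (stiff-solver
# overshoot) are clamped to zero inside every term.

state_value <- function(x, i1, i2) {
  if (i2 > 0L) {  # pool ratio
    den <- x[i2]
    num <- max(x[i1], 0)
    if (den <= 0) return(if (num > 0) Inf else 0)
    num / den
  } else {
    max(x[i1], 0)
  }
}

eval_one_rate <- function(k, x, p) {
  rate <- p[k$vmax]
  if (rate == 0) return(0)
  subs <- k$subs
  ns <- length(subs)
  terms <- numeric(ns)
  for (ti in seq_len(ns)) {
    s <- subs[[ti]]
    if (s$type == 1L) {
      sv <- max(x[s$i1], 0)
      terms[ti] <- sv / (sv + p[s$k])
    } else {
      den <- x[s$i2]
      num <- max(x[s$i1], 0)
      terms[ti] <- if (den <= 0) {
        if (num > 0) 1 else 0
      } else {
        r <- num / den
        r / (r + p[s$k])
      }
    }
  }
  for (g in k$regs) {
    if (g$kind == 1L) {  # non-competitive inhibition factor
      I <- state_value(x, g$eff[1], g$eff[2])
      rate <- if (is.infinite(I)) 0 else rate / (1 + I / p[g$k])
    } else {             # non-essential activation on leading substrate term
      A <- state_value(x, g$eff[1], g$eff[2])
      if (is.infinite(A)) A <- .Machine$double.xmax^0.25
      s1 <- subs[[1]]
      sv <- max(x[s1$i1], 0)
      KS <- p[s1$k]; KA <- p[g$k]; al <- p[g$alpha]; be <- p[g$beta]
      terms[1] <- sv * (1 + be * A / (al * KA)) /
        (KS * (1 + A / KA) + sv * (1 + A / (al * KA)))
    }
  }
  rate * prod(terms)
}

eval_fluxes <- function(comp, x, p) {
  kin <- comp$kin
  v <- numeric(length(kin))
  for (j in seq_along(kin)) v[j] <- eval_one_rate(kin[[j]], x, p)
  v
}

# evaluate fluxes at every row of a state matrix (columns in species order)
flux_matrix_along <- function(comp, states, pv) {
  nR <- length(comp$reaction_ids)
  fl <- vapply(seq_len(nrow(states)),
               function(i) eval_fluxes_fast(comp, unname(states[i, ]), pv),
               numeric(nR))
  m <- if (is.matrix(fl)) t(fl) else matrix(fl, ncol = 1L)
  colnames(m) <- comp$reaction_ids
  m
}

as_compiled <- function(network, params) {
  if (is.list(network) && !is.null(network$kin)) network
  else compile_network(network, params)
}

state_vector <- function(comp, state) {
  if (is.null(names(state))) {
    stopifnot(length(state) == length(comp$species))
    return(unname(state))
  }
  miss <- setdiff(comp$species, names(state))
  if (length(miss)) {
    stop("state is missing species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unname(state[comp$species])
}

#' Evaluate the per-cell flux vector at a state
#'
#' @param network A `MetabolicNetwork` or a compiled network.
#' @param state Named numeric state (one entry per declared species) or an
#'   unnamed vector in the network's species order.
#' @param params `ParameterSet` or named numeric vector.
#' @return Named numeric vector, one flux per reaction
#'   (mmol per 1e6 cells per h; `V_growth` in 1/h, `V_mAb` in mg per 1e6
#'   cells per h).
#' @export
flux_vector <- function(network, state, params) {
  comp <- as_compiled(network, params)
  pv <- param_values(params)[comp$param_names]
  x <- state_vector(comp, state)
  stats::setNames(eval_fluxes(comp, x, unname(pv)), comp$reaction_ids)
}

#' Evaluate a single reaction rate
#'
#' @inheritParams flux_vector
#' @param reaction Reaction id (e.g. `"V_HK"`).
#' @return Scalar flux.
#' @export
reaction_rate <- function(network, reaction, state, params) {
  comp <- as_compiled(network, params)
  j <- match(reaction, comp$reaction_ids)
  if (is.na(j)) stop("unknown reaction: ", reaction, call. = FALSE)
  pv <- param_values(params)[comp$param_names]
  x <- state_vector(comp, state)
  eval_one_rate(comp$kin[[j]], x, unname(pv))
}

#' Specific growth rate at a state
#'
#' Multiplicative Michaelis-Menten over the growth precursors (all modelled
#' extracellular amino acids plus intracellular glucose-6-phosphate, citrate
#' and ribulose-5-phosphate), times non-competitive inhibition factors for
#' lactate and ammonia.
#'
#' @inheritParams flux_vector
#' @return mu in 1/h.
#' @export
growth_rate <- function(network, state, params) {
  reaction_rate(network, "V_growth", state, params)
}

#' Specific mAb production rate at a state
#'
#' Same multiplicative structure as [growth_rate()] over the antibody's
#' amino-acid precursors with its own affinity constants.
#'
#' @inheritParams flux_vector
#' @return q_mAb in mg per 1e6 cells per h.
#' @export
mab_rate <- function(network, state, params) {
  reaction_rate(network, "V_mAb", state, params)
}
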