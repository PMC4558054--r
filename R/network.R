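#' Load a metabolic network definition
#'
#' Reads a YAML model file declaring metabolites (with compartments),
#' reactions (stoichiometry maps plus rate-law specs in the multiplicative
#' Michaelis-Menten grammar) and the biomass/mAb composition block. Rate laws
#' are data, not code: a reaction's kinetics are fully described by its
#' substrate saturation terms (on concentrations or nucleotide-pool ratios),
#' optional non-competitive inhibition and non-essential activation factors,
#' and a named maximal-rate parameter.
#'
#' @param path Path to the YAML model file.
#' @return A `MetabolicNetwork` object (list with `metabolites`, `reactions`,
#'   `biomass`, `name`).
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  mets <- do.call(rbind, lapply(raw$metabolites, function(m) {
    data.frame(id = m$id, compartment = m$compartment, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(mets$id[duplicated(mets$id)], collapse = ", "), call. = FALSE)
  }
  mets$units <- compartment_units(mets$compartment)
  rxns <- lapply(raw$reactions, normalize_reaction)
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  if (anyDuplicated(names(rxns))) stop("duplicate reaction ids", call. = FALSE)
  structure(
    list(name = raw$name %||% basename(path),
         metabolites = mets, reactions = rxns, biomass = raw$biomass),
    class = "MetabolicNetwork")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a metabolic network in code
#'
#' Programmatic equivalent of [load_network()]: takes the same structures the
#' YAML file declares (metabolite list with compartments, reactions with
#' stoichiometry maps and rate-law specs) and returns a validated
#' `MetabolicNetwork`. Mainly useful for small test models and for building
#' model variants without editing files.
#'
#' @param metabolites List of `list(id =, compartment =)` entries.
#' @param reactions List of reaction specs (`id`, `stoichiometry`,
#'   `rate_law`, optional `reversible_pair`, `reconstructed`).
#' @param biomass Optional biomass composition block.
#' @param name Network name.
#' @return `MetabolicNetwork`.
#' @export
metabolic_network <- function(metabolites, reactions, biomass = NULL,
                              name = "network") {
  mets <- do.call(rbind, lapply(metabolites, function(m) {
    data.frame(id = m$id, compartment = m$compartment, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids", call. = FALSE)
  mets$units <- compartment_units(mets$compartment)
  rxns <- lapply(reactions, normalize_reaction)
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  if (anyDuplicated(names(rxns))) stop("duplicate reaction ids", call. = FALSE)
  structure(list(name = name, metabolites = mets, reactions = rxns,
                 biomass = biomass),
            class = "MetabolicNetwork")
}

compartment_units <- function(compartment) {
  unname(c(extracellular = "mM",
           intracellular = "mmol/1e6cells",
           cells = "1e6cells/mL",
           product = "mg/L",
           volume = "L")[compartment])
}

normalize_reaction <- function(r) {
  stopifnot(!is.null(r$id), !is.null(r$stoichiometry), !is.null(r$rate_law))
  stoich <- unlist(r$stoichiometry)
  if (!any(stoich < 0)) {
    stop("reaction ", r$id, " has no substrate (negative) coefficient",
         call. = FALSE)
  }
  if (any(!is.finite(stoich))) {
    stop("reaction ", r$id, " has non-finite stoichiometry", call. = FALSE)
  }
  rl <- r$rate_law
  rl$substrates <- lapply(rl$substrates %||% list(), function(s) {
    if (!is.null(s$ratio)) list(ratio = unlist(s$ratio), Km = s$Km)
    else list(species = s$species, Km = s$Km)
  })
  rl$regulation <- lapply(rl$regulation %||% list(), function(g) {
    kind <- g$kind
    if (!kind %in% c("noncompetitive_inhibition", "nonessential_activation")) {
      stop("reaction ", r$id, ": unknown regulation kind ", kind, call. = FALSE)
    }
    g$ratio <- if (!is.null(g$ratio)) unlist(g$ratio)
    g
  })
  list(id = r$id, stoichiometry = stoich, rate_law = rl,
       reversible_pair = r$reversible_pair %||% NULL,
       reconstructed = isTRUE(r$reconstructed))
}

#' Load a kinetic parameter table
#'
#' CSV with columns `name`, `value`, `magnitude_exponent`, `lower_bound`,
#' `upper_bound`, `sensitive_flag`. The magnitude exponent `n` is the
#' order-of-magnitude used to normalize each parameter to unit scale
#' (`value / 10^n`) during optimization.
#'
#' @param path CSV path.
#' @return Data frame of class `ParameterSet` with those columns.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "value", "magnitude_exponent", "lower_bound",
            "upper_bound", "sensitive_flag")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("parameter table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$name)) stop("duplicate parameter names", call. = FALSE)
  class(tab) <- c("ParameterSet", "data.frame")
  tab
}

#' Parameter table to named vector
#' @param params A `ParameterSet` data frame or an already-named numeric vector.
#' @return Named numeric vector of parameter values.
#' @export
param_values <- function(params) {
  if (is.numeric(params)) return(params)
  stats::setNames(params$value, params$name)
}

#' Validate a network against a parameter set
#'
#' Reports (rather than errors on) structural problems: metabolites never used
#' by any reaction, rate-law references to undeclared species or missing
#' parameters, reversible pairs that are not mutual, and inconsistency between
#' the biomass conversion factor and the dry weight / protein molar mass pair
#' (they must agree within 1%). An empty `issues` table means the model is
#' valid. Also reports the parameter count used by the model.
#'
#' @param network A `MetabolicNetwork`.
#' @param params A `ParameterSet` or named numeric vector.
#' @return List with `issues` (data frame: type, where, detail),
#'   `n_parameters`, `n_reactions`, `n_metabolites`, and `valid` (logical).
#' @export
validate_network <- function(network, params = NULL) {
  mets <- network$metabolites$id
  pv <- if (!is.null(params)) param_values(params)
  issues <- list()
  add <- function(type, where, detail) {
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, where = where, detail = detail, stringsAsFactors = FALSE)
  }
  used <- character()
  pnames <- character()
  for (r in network$reactions) {
    used <- c(used, names(r$stoichiometry))
    for (sp in names(r$stoichiometry)) {
      if (!sp %in% mets) add("unresolved_species", r$id, sp)
    }
    rl <- r$rate_law
    pnames <- c(pnames, rl$Vmax)
    for (s in rl$substrates) {
      pnames <- c(pnames, s$Km)
      ref <- if (!is.null(s$ratio)) s$ratio else s$species
      for (sp in ref) if (!sp %in% mets) add("unresolved_species", r$id, sp)
    }
    for (g in rl$regulation) {
      ref <- if (!is.null(g$ratio)) g$ratio else g$effector
      for (sp in ref) if (!sp %in% mets) add("unresolved_species", r$id, sp)
      pnames <- c(pnames,
                  if (g$kind == "noncompetitive_inhibition") g$K
                  else c(g$Ka, g$alpha, g$beta))
    }
    if (!is.null(r$reversible_pair)) {
      mate <- network$reactions[[r$reversible_pair]]
      if (is.null(mate) || !identical(mate$reversible_pair, r$id)) {
        add("non_mutual_reversible_pair", r$id, r$reversible_pair %||% "<none>")
      }
    }
  }
  pnames <- unique(pnames)
  if (!is.null(pv)) {
    for (pn in setdiff(pnames, names(pv))) add("unresolved_parameter", "<model>", pn)
  }
  for (m in setdiff(mets, unique(used))) {
    comp <- network$metabolites$compartment[network$metabolites$id == m]
    if (!comp %in% c("volume", "cells", "product")) add("orphan_metabolite", m, comp)
  }
  bm <- network$biomass
  if (!is.null(bm)) {
    implied <- bm$dry_weight_g_per_1e6 / bm$protein_mw * 1000  # mmol per 1e6 cells
    if (abs(implied - bm$biomass_mmol_per_1e6) / bm$biomass_mmol_per_1e6 > 0.01) {
      add("biomass_factor_mismatch", "biomass",
          sprintf("dry weight / molar mass implies %.4g, stated %.4g",
                  implied, bm$biomass_mmol_per_1e6))
    }
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(type = character(), where = character(), detail = character())
  list(issues = issues, valid = nrow(issues) == 0L,
       n_parameters = length(pnames),
       n_reactions = length(network$reactions),
       n_metabolites = length(mets))
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  cat("MetabolicNetwork:", x$name, "\n",
      " ", nrow(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  invisible(x)
}

# ---- compiled form -----------------------------------------------------------
# Index-based representation used by the flux evaluator and the ODE right-hand
# side: all name lookups are resolved once, so each evaluation is loops over
# small integer vectors.

compile_network <- function(network, params) {
  pv <- param_values(params)
  pidx <- stats::setNames(seq_along(pv), names(pv))
  mets <- network$metabolites
  sidx <- stats::setNames(seq_len(nrow(mets)), mets$id)
  need_p <- function(nm, rid) {
    i <- pidx[nm]
    if (is.na(i)) stop("reaction ", rid, ": parameter '", nm,
                       "' not in parameter set", call. = FALSE)
    unname(i)
  }
  need_s <- function(nm, rid) {
    i <- sidx[nm]
    if (is.na(i)) stop("reaction ", rid, ": species '", nm,
                       "' not declared", call. = FALSE)
    unname(i)
  }
  rids <- names(network$reactions)
  nS <- nrow(mets); nR <- length(rids)
  stoich <- matrix(0, nS, nR, dimnames = list(mets$id, rids))
  compiled <- vector("list", nR)
  for (j in seq_len(nR)) {
    r <- network$reactions[[j]]
    for (sp in names(r$stoichiometry)) {
      stoich[need_s(sp, r$id), j] <- r$stoichiometry[[sp]]
    }
    rl <- r$rate_law
    subs <- lapply(rl$substrates, function(s) {
      if (!is.null(s$ratio)) {
        list(type = 2L, i1 = need_s(s$ratio[1], r$id),
             i2 = need_s(s$ratio[2], r$id), k = need_p(s$Km, r$id))
      } else {
        list(type = 1L, i1 = need_s(s$species, r$id), i2 = 0L,
             k = need_p(s$Km, r$id))
      }
    })
    regs <- lapply(rl$regulation, function(g) {
      if (!is.null(g$ratio)) {
        eff <- c(need_s(g$ratio[1], r$id), need_s(g$ratio[2], r$id))
      } else {
        eff <- c(need_s(g$effector, r$id), 0L)
      }
      if (g$kind == "noncompetitive_inhibition") {
        list(kind = 1L, eff = eff, k = need_p(g$K, r$id),
             alpha = 0L, beta = 0L)
      } else {
        list(kind = 2L, eff = eff, k = need_p(g$Ka, r$id),
             alpha = need_p(g$alpha, r$id), beta = need_p(g$beta, r$id))
      }
    })
    if (any(vapply(regs, function(g) g$kind == 2L, TRUE)) &&
        (length(subs) == 0L || subs[[1]]$type != 1L)) {
      stop("reaction ", r$id, ": non-essential activation requires a leading ",
           "concentration substrate term", call. = FALSE)
    }
    compiled[[j]] <- list(vmax = need_p(rl$Vmax, r$id), subs = subs, regs = regs)
  }
  comp <- mets$compartment
  out <- list(network = network,
              species = mets$id, compartment = comp,
              i_ext = which(comp %in% c("extracellular", "product")),
              i_int = which(comp == "intracellular"),
              i_cells = which(comp == "cells"),
              i_vol = which(comp == "volume"),
              reaction_ids = rids, stoich = stoich, kin = compiled,
              param_names = names(pv),
              i_growth = match("V_growth", rids), i_mab = match("V_mAb", rids))
  out$flat <- build_flat(out)
  out
}

# 0-based flat arrays consumed by the C++ evaluator (src/flux_eval.cpp)
build_flat <- function(comp) {
  sub_rows <- list(); reg_rows <- list()
  sub_off <- integer(length(comp$kin) + 1L)
  reg_off <- integer(length(comp$kin) + 1L)
  for (j in seq_along(comp$kin)) {
    k <- comp$kin[[j]]
    for (s in k$subs) {
      sub_rows[[length(sub_rows) + 1L]] <-
        c(s$type, s$i1 - 1L, if (s$i2 > 0L) s$i2 - 1L else -1L, s$k - 1L)
    }
    for (g in k$regs) {
      reg_rows[[length(reg_rows) + 1L]] <-
        c(g$kind, g$eff[1] - 1L, if (g$eff[2] > 0L) g$eff[2] - 1L else -1L,
          g$k - 1L, max(g$alpha - 1L, 0L), max(g$beta - 1L, 0L))
    }
    sub_off[j + 1L] <- length(sub_rows)
    reg_off[j + 1L] <- length(reg_rows)
  }
  sm <- if (length(sub_rows)) do.call(rbind, sub_rows) else
    matrix(integer(), 0, 4)
  rm_ <- if (length(reg_rows)) do.call(rbind, reg_rows) else
    matrix(integer(), 0, 6)
  code <- c(extracellular = 1L, product = 1L, intracellular = 2L,
            cells = 3L, volume = 4L)[comp$compartment]
  list(vmax_idx = vapply(comp$kin, function(k) k$vmax - 1L, 1L),
       sub_off = as.integer(sub_off), sub_type = as.integer(sm[, 1]),
       sub_i1 = as.integer(sm[, 2]), sub_i2 = as.integer(sm[, 3]),
       sub_k = as.integer(sm[, 4]),
       reg_off = as.integer(reg_off), reg_kind = as.integer(rm_[, 1]),
       reg_e1 = as.integer(rm_[, 2]), reg_e2 = as.integer(rm_[, 3]),
       reg_k = as.integer(rm_[, 4]), reg_alpha = as.integer(rm_[, 5]),
       reg_beta = as.integer(rm_[, 6]),
       comp_code = unname(code),
       i_cells0 = comp$i_cells[1] - 1L,
       i_growth0 = if (is.na(comp$i_growth)) -1L else comp$i_growth - 1L)
}

# fast flux evaluation through the compiled C++ kernel
eval_fluxes_fast <- function(comp, x, p) {
  f <- comp$flat
  .flux_eval_cpp(x, p, f$vmax_idx, f$sub_off, f$sub_type, f$sub_i1, f$sub_i2,
                 f$sub_k, f$reg_off, f$reg_kind, f$reg_e1, f$reg_e2, f$reg_k,
                 f$reg_alpha, f$reg_beta)
}
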