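# Gas constants selected by the energy unit tag of EnergyParameters.
.GAS_CONSTANTS <- c(
  "kcal/mol" = 1.98720425864083e-3,
  "J/mol"    = 8.31446261815324
)

#' Relative dose of one transcription factor
#'
#' An activator dose is the dimensionless relative concentration
#' \eqn{x_i = c_i / K_i} of a transcription factor, i.e. its free concentration
#' divided by the dissociation constant of its binding site. Either the
#' relative concentration is given directly, or it is derived from an absolute
#' concentration and a dissociation constant (both in the same molar units).
#'
#' @param name Short identifier of the transcription factor (e.g. `"A"`).
#' @param relative_concentration Non-negative dimensionless dose. May be
#'   omitted when both `concentration` and `kd` are supplied.
#' @param concentration Optional absolute concentration (molar units).
#' @param kd Optional dissociation constant (same units as `concentration`).
#' @return An object of class `activator_dose` with fields `name`,
#'   `relative_concentration` and, when supplied, `concentration` and `kd`.
#' @examples
#' activator_dose("A", 0.5)
#' activator_dose("CRP", concentration = 2e-6, kd = 1e-6)
#' @export
activator_dose <- function(name, relative_concentration = NULL,
                           concentration = NULL, kd = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  x <- .resolve_relative(relative_concentration, concentration, kd)
  structure(
    list(name = name, relative_concentration = x,
         concentration = concentration, kd = kd),
    class = "activator_dose"
  )
}

#' Relative dose of RNA polymerase
#'
#' The relative RNA polymerase concentration \eqn{x_P = [\mathrm{RNAP}]/K_P},
#' where \eqn{K_P} is the dissociation constant of polymerase at the core
#' promoter.
#'
#' @inheritParams activator_dose
#' @return An object of class `polymerase_dose`.
#' @examples
#' polymerase_dose(0.5)
#' @export
polymerase_dose <- function(relative_concentration = NULL,
                            concentration = NULL, kd = NULL) {
  x <- .resolve_relative(relative_concentration, concentration, kd)
  structure(
    list(relative_concentration = x, concentration = concentration, kd = kd),
    class = "polymerase_dose"
  )
}

.resolve_relative <- function(relative, concentration, kd) {
  if (!is.null(concentration) || !is.null(kd)) {
    if (is.null(concentration) || is.null(kd))
      stop("'concentration' and 'kd' must be supplied together")
    if (!is.numeric(kd) || kd <= 0) stop("'kd' must be positive")
    if (!is.numeric(concentration) || concentration < 0)
      stop("'concentration' must be non-negative")
    ratio <- concentration / kd
    if (!is.null(relative)) {
      if (abs(relative - ratio) > 1e-12 * max(1, abs(ratio)))
        stop("'relative_concentration' disagrees with concentration/kd")
    }
    relative <- ratio
  }
  if (is.null(relative))
    stop("either 'relative_concentration' or 'concentration' + 'kd' required")
  if (!is.numeric(relative) || length(relative) != 1L || is.na(relative) ||
      relative < 0)
    stop("'relative_concentration' must be a non-negative number")
  as.numeric(relative)
}

#' Free-energy shift parameters of a promoter
#'
#' Collects the free-energy shifts that transcription factors impose on the
#' promoter, in explicit energy units: per-factor shifts of the polymerase
#' binding energy (`delta_e`, one per transcription factor; negative for an
#' activator, which lowers the binding energy), pairwise factor-factor
#' interaction energies that do not involve polymerase (`delta_e_pair`), and
#' three-body shifts active only when both factors of a pair and polymerase
#' are bound simultaneously (`delta_e3`).
#'
#' Pairwise entries are named `"A:B"` with the two factor identifiers in the
#' order of `delta_e`'s names (i.e. i < j); duplicated or reversed pairs are
#' rejected.
#'
#' @param delta_e Named numeric vector of per-factor polymerase-coupling
#'   shifts.
#' @param delta_e_pair Optional named numeric vector of pairwise factor-factor
#'   shifts (names `"A:B"`).
#' @param delta_e3 Optional named numeric vector of pairwise three-body
#'   (factor, factor, polymerase) shifts (names `"A:B"`).
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @param units Energy unit tag, `"kcal/mol"` or `"J/mol"`; picks the matching
#'   gas constant.
#' @return An object of class `energy_parameters`.
#' @seealso [factors_from_energies()]
#' @examples
#' energy_parameters(c(A = -0.8, B = -0.4), temperature = 298.15)
#' @export
energy_parameters <- function(delta_e, delta_e_pair = NULL, delta_e3 = NULL,
                              temperature = 298.15,
                              units = c("kcal/mol", "J/mol")) {
  units <- match.arg(units)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("'temperature' must be positive")
  if (length(delta_e) && is.null(names(delta_e)))
    names(delta_e) <- LETTERS[seq_along(delta_e)]
  tf_names <- names(delta_e)
  .check_pairs(delta_e_pair, tf_names, "delta_e_pair")
  .check_pairs(delta_e3, tf_names, "delta_e3")
  structure(
    list(delta_e = delta_e, delta_e_pair = delta_e_pair, delta_e3 = delta_e3,
         temperature = temperature, units = units,
         gas_constant = .GAS_CONSTANTS[[units]]),
    class = "energy_parameters"
  )
}

.check_pairs <- function(x, tf_names, what) {
  if (is.null(x) || !length(x)) return(invisible(NULL))
  if (is.null(names(x))) stop("'", what, "' entries must be named 'i:j'")
  parts <- strsplit(names(x), ":", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("'", what, "' names must have the form 'i:j'")
  for (p in parts) {
    idx <- match(p, tf_names)
    if (anyNA(idx)) stop("'", what, "' refers to unknown factor: ",
                         paste(p, collapse = ":"))
    if (idx[1] >= idx[2])
      stop("'", what, "' pair '", paste(p, collapse = ":"),
           "' must be ordered i < j")
  }
  if (anyDuplicated(names(x))) stop("duplicate pair in '", what, "'")
  invisible(NULL)
}

#' Cooperativity factors of a promoter
#'
#' The multiplicative statistical-weight factors of the model: `w` couples one
#' bound transcription factor to bound polymerase (an activator has
#' \eqn{w > 1}), `omega_tf` couples a pair of bound factors independently of
#' polymerase, and `omega3` is the three-body factor that acts only when the
#' pair of factors and polymerase are all bound (e.g. DNA looping or assembly
#' of an activation complex). Missing pairs default to 1 (no interaction).
#'
#' @param w Named positive numeric vector, one entry per transcription factor.
#' @param omega_tf Optional named positive numeric vector of factor-factor
#'   couplings, names `"A:B"` with i < j.
#' @param omega3 Optional named positive numeric vector of three-body
#'   couplings, same naming rule.
#' @return An object of class `cooperativity_parameters` with fully populated
#'   `omega_tf` and `omega3` vectors over all factor pairs.
#' @examples
#' cooperativity_parameters(c(A = 5, B = 10), omega3 = c("A:B" = 2))
#' @export
cooperativity_parameters <- function(w, omega_tf = NULL, omega3 = NULL) {
  if (length(w) && is.null(names(w))) names(w) <- LETTERS[seq_along(w)]
  if (!is.numeric(w) || any(w <= 0) || anyNA(w))
    stop("all 'w' factors must be positive")
  tf_names <- names(w)
  .check_pairs(omega_tf, tf_names, "omega_tf")
  .check_pairs(omega3, tf_names, "omega3")
  if (any(unlist(omega_tf) <= 0) || any(unlist(omega3) <= 0))
    stop("all cooperativity factors must be positive")
  pairs <- .pair_names(tf_names)
  full <- function(x) {
    out <- stats::setNames(rep(1, length(pairs)), pairs)
    if (!is.null(x)) out[names(x)] <- as.numeric(x)
    out
  }
  structure(
    list(w = stats::setNames(as.numeric(w), tf_names),
         omega_tf = full(omega_tf), omega3 = full(omega3)),
    class = "cooperativity_parameters"
  )
}

.pair_names <- function(tf_names) {
  n <- length(tf_names)
  if (n < 2L) return(character(0))
  idx <- utils::combn(n, 2L)
  paste(tf_names[idx[1L, ]], tf_names[idx[2L, ]], sep = ":")
}

#' @export
print.cooperativity_parameters <- function(x, ...) {
  cat("Cooperativity factors\n")
  cat("  w (TF-polymerase):   ",
      paste(sprintf("%s=%.6g", names(x$w), x$w), collapse = ", "), "\n")
  if (length(x$omega_tf)) {
    cat("  omega_tf (TF-TF):    ",
        paste(sprintf("%s=%.6g", names(x$omega_tf), x$omega_tf),
              collapse = ", "), "\n")
    cat("  omega3 (TF-TF-P):    ",
        paste(sprintf("%s=%.6g", names(x$omega3), x$omega3),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert free-energy shifts to cooperativity factors
#'
#' Applies the Boltzmann map \eqn{f = \exp(-\Delta E / (R T))} to every energy
#' shift. The sign convention is that an activating shift (which lowers the
#' polymerase binding energy) is negative and therefore maps to a factor
#' greater than 1.
#'
#' @param energies An [energy_parameters()] object.
#' @return A [cooperativity_parameters()] object.
#' @seealso [energies_from_factors()] for the inverse map.
#' @examples
#' rt <- 1.98720425864083e-3 * 298.15
#' factors_from_energies(energy_parameters(c(A = -rt * log(2))))$w  # w_A = 2
#' @export
factors_from_energies <- function(energies) {
  if (!inherits(energies, "energy_parameters"))
    stop("'energies' must be an energy_parameters object")
  rt <- energies$gas_constant * energies$temperature
  f <- function(e) if (is.null(e)) NULL else
    stats::setNames(exp(-as.numeric(e) / rt), names(e))
  cooperativity_parameters(
    w = f(energies$delta_e),
    omega_tf = f(energies$delta_e_pair),
    omega3 = f(energies$delta_e3)
  )
}

#' Convert cooperativity factors back to free-energy shifts
#'
#' Inverse of [factors_from_energies()] at a given temperature:
#' \eqn{\Delta E = -R T \log f}.
#'
#' @param factors A [cooperativity_parameters()] object.
#' @param temperature Absolute temperature in kelvin.
#' @param units Energy unit tag, `"kcal/mol"` or `"J/mol"`.
#' @return An [energy_parameters()] object.
#' @export
energies_from_factors <- function(factors, temperature = 298.15,
                                  units = c("kcal/mol", "J/mol")) {
  units <- match.arg(units)
  if (!inherits(factors, "cooperativity_parameters"))
    stop("'factors' must be a cooperativity_parameters object")
  rt <- .GAS_CONSTANTS[[units]] * temperature
  g <- function(f) if (is.null(f) || !length(f)) NULL else
    stats::setNames(-rt * log(as.numeric(f)), names(f))
  energy_parameters(
    delta_e = g(factors$w),
    delta_e_pair = g(factors$omega_tf),
    delta_e3 = g(factors$omega3),
    temperature = temperature, units = units
  )
}

#' Enumerate promoter occupancy states
#'
#' Lists the \eqn{2^{(n+1)}} mutually exclusive occupancy states of a promoter
#' regulated by `n_tf` transcription factors plus RNA polymerase. Each state is
#' a unique combination of the polymerase flag and a subset of bound factors.
#'
#' The ordering is deterministic: all polymerase-free states first, then all
#' polymerase-bound states; within each block the bound-factor subsets are in
#' binary counting order (factor i toggles bit i). For two factors the
#' conventional textbook display interleaves the two blocks
#' (empty, P, A, B, PA, PB, AB, PAB); that permutation is attached as the
#' `"display_order"` attribute.
#'
#' @param n_tf Number of transcription factors (non-negative integer).
#' @param tf_names Identifiers of the factors; defaults to `LETTERS`.
#' @return A data frame with columns `state_index`, `rnap_bound` (logical) and
#'   `bound_tfs` (comma-joined identifiers, `""` for none), with attributes
#'   `n_tf`, `tf_names` and (for `n_tf = 2`) `display_order`.
#' @examples
#' enumerate_states(2)
#' @export
enumerate_states <- function(n_tf, tf_names = NULL) {
  if (!is.numeric(n_tf) || length(n_tf) != 1L || is.na(n_tf) || n_tf < 0 ||
      n_tf != round(n_tf))
    stop("'n_tf' must be a non-negative integer")
  n_tf <- as.integer(n_tf)
  if (is.null(tf_names)) tf_names <- if (n_tf) LETTERS[seq_len(n_tf)] else character(0)
  if (length(tf_names) != n_tf || anyDuplicated(tf_names))
    stop("'tf_names' must supply ", n_tf, " distinct identifiers")
  masks <- seq_len(2^n_tf) - 1L
  subsets <- vapply(masks, function(m) {
    paste(tf_names[bitwAnd(m, bitwShiftL(1L, seq_len(n_tf) - 1L)) > 0L],
          collapse = ",")
  }, character(1))
  states <- data.frame(
    state_index = seq_len(2^(n_tf + 1)),
    rnap_bound = rep(c(FALSE, TRUE), each = 2^n_tf),
    bound_tfs = rep(subsets, 2L),
    stringsAsFactors = FALSE
  )
  attr(states, "n_tf") <- n_tf
  attr(states, "tf_names") <- tf_names
  if (n_tf == 2L)
    attr(states, "display_order") <- c(1L, 5L, 2L, 3L, 6L, 7L, 4L, 8L)
  states
}

# Extract named dose vector from a list of activator_dose objects (or a
# plain named numeric vector).
.dose_vector <- function(doses) {
  if (is.numeric(doses)) {
    if (length(doses) && is.null(names(doses)))
      names(doses) <- LETTERS[seq_along(doses)]
    return(doses)
  }
  if (inherits(doses, "activator_dose")) doses <- list(doses)
  vals <- vapply(doses, function(d) {
    if (!inherits(d, "activator_dose")) stop("invalid activator dose")
    d$relative_concentration
  }, numeric(1))
  stats::setNames(vals, vapply(doses, `[[`, character(1), "name"))
}

.pol_value <- function(pol) {
  if (inherits(pol, "polymerase_dose")) return(pol$relative_concentration)
  if (is.numeric(pol) && length(pol) == 1L && pol >= 0) return(as.numeric(pol))
  stop("'pol' must be a polymerase_dose or a non-negative number")
}

# Log statistical weight of each state in a state table. log(0) = -Inf is a
# legitimate value here (zero dose annihilates every state containing that
# factor); all accumulation happens in log space.
.log_weights <- function(states, x, x_p, params) {
  tf_names <- attr(states, "tf_names")
  if (!all(tf_names %in% names(x)))
    stop("missing dose for factor(s): ",
         paste(setdiff(tf_names, names(x)), collapse = ", "))
  if (!all(tf_names %in% names(params$w)))
    stop("missing cooperativity factor for: ",
         paste(setdiff(tf_names, names(params$w)), collapse = ", "))
  lx <- log(x[tf_names])
  lw <- log(params$w[tf_names])
  lo_tf <- log(params$omega_tf)
  lo_3 <- log(params$omega3)
  vapply(seq_len(nrow(states)), function(j) {
    s <- states$bound_tfs[j]
    members <- if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1]] else character(0)
    pol <- states$rnap_bound[j]
    out <- if (pol) log(x_p) else 0
    if (length(members)) {
      out <- out + sum(lx[members])
      if (length(members) >= 2L) {
        idx <- utils::combn(members, 2L)
        pr <- paste(idx[1L, ], idx[2L, ], sep = ":")
        out <- out + sum(lo_tf[pr])
        if (pol) out <- out + sum(lo_3[pr])
      }
      if (pol) out <- out + sum(lw[members])
    }
    out
  }, numeric(1))
}

#' Statistical weight of a single promoter state
#'
#' The unnormalized Boltzmann weight of one occupancy state:
#' \deqn{x_P^{\sigma} \prod_{i \in S} x_i \prod_{i<j \in S} \omega_{ij}
#'       \left(\prod_{i \in S} w_i \prod_{i<j \in S} \omega^{(3)}_{ij}\right)^{\sigma}}
#' where \eqn{S} is the set of bound factors and \eqn{\sigma} the polymerase
#' flag. The product is accumulated in log space and exponentiated once, so
#' saturating doses do not overflow.
#'
#' @param state A list (or one-row data frame) with elements `rnap_bound`
#'   (logical) and `bound_tfs` (comma-joined identifiers or character vector).
#' @param doses List of [activator_dose()] objects (or a named numeric vector
#'   of relative concentrations).
#' @param pol A [polymerase_dose()] object (or a non-negative number).
#' @param params A [cooperativity_parameters()] object.
#' @return The positive statistical weight (1 for the empty state).
#' @examples
#' params <- cooperativity_parameters(c(A = 2, B = 3))
#' state_weight(list(rnap_bound = TRUE, bound_tfs = "A"),
#'              c(A = 0.5, B = 1), 0.1, params)  # 0.1 * 0.5 * 2
#' @export
state_weight <- function(state, doses, pol, params) {
  x <- .dose_vector(doses)
  x_p <- .pol_value(pol)
  tfs <- state$bound_tfs
  if (length(tfs) > 1L) tfs <- paste(tfs, collapse = ",")
  members <- if (nzchar(tfs)) strsplit(tfs, ",", fixed = TRUE)[[1]] else character(0)
  if (!all(members %in% names(x)))
    stop("unknown TF identifier in state: ",
         paste(setdiff(members, names(x)), collapse = ", "))
  tab <- data.frame(state_index = 1L, rnap_bound = isTRUE(state$rnap_bound),
                    bound_tfs = tfs, stringsAsFactors = FALSE)
  attr(tab, "tf_names") <- members
  exp(.log_weights(tab, x, x_p, params))
}

#' Promoter state probabilities
#'
#' Enumerates all occupancy states, assigns Boltzmann statistical weights, and
#' normalizes them by the partition sum to obtain the probability of each
#' state. Weights are handled in log space throughout, so doses and factors up
#' to at least 1e12 remain numerically finite.
#'
#' @inheritParams state_weight
#' @param temperature Temperature (K) used only to report per-state
#'   free-energy shifts in `units`.
#' @param units Energy unit for the reported free-energy shifts.
#' @return An object of class `promoter_state_space`: a list with `n_tf`,
#'   `states` (data frame with `state_index`, `rnap_bound`, `bound_tfs`,
#'   `weight`, `free_energy_shift`, `probability`), `v_on`, `v_off`, and
#'   `probabilities` (named by state index).
#' @examples
#' params <- cooperativity_parameters(c(A = 5, B = 5), omega3 = c("A:B" = 2))
#' ss <- state_probabilities(c(A = 1, B = 1), 0.1, params)
#' sum(ss$states$probability)  # 1
#' @export
state_probabilities <- function(doses, pol, params, temperature = 298.15,
                                units = c("kcal/mol", "J/mol")) {
  units <- match.arg(units)
  x <- .dose_vector(doses)
  x_p <- .pol_value(pol)
  states <- enumerate_states(length(x), names(x))
  lw <- .log_weights(states, x, x_p, params)
  m <- max(lw)
  pr <- exp(lw - m)
  pr <- pr / sum(pr)
  rt <- .GAS_CONSTANTS[[units]] * temperature
  # free-energy shift excludes the concentration-degeneracy part of the weight
  ldeg <- .log_weights(states, x, x_p,
                       cooperativity_parameters(
                         stats::setNames(rep(1, length(x)), names(x))))
  states$weight <- exp(lw)
  states$free_energy_shift <- -rt * (lw - ldeg)
  states$probability <- pr
  on <- states$rnap_bound
  structure(
    list(n_tf = length(x), states = states,
         v_on = sum(exp(lw[on])), v_off = sum(exp(lw[!on])),
         probabilities = stats::setNames(pr, states$state_index),
         temperature = temperature, units = units),
    class = "promoter_state_space"
  )
}

#' @export
print.promoter_state_space <- function(x, ...) {
  cat(sprintf("Promoter state space: %d TF(s), %d states\n",
              x$n_tf, nrow(x$states)))
  cat(sprintf("  v_on = %.6g, v_off = %.6g, P(RNAP bound) = %.6g\n",
              x$v_on, x$v_off, x$v_on / (x$v_on + x$v_off)))
  print(x$states[, c("state_index", "rnap_bound", "bound_tfs", "weight",
                     "probability")], row.names = FALSE)
  invisible(x)
}

#' Total weights of polymerase-bound and polymerase-free states
#'
#' Splits the partition sum into the total relative concentration of 'on'
#' states (polymerase bound, transcription initiated) and 'off' states.
#' The empty state contributes 1 to `v_off`, so `v_off >= 1` always.
#'
#' @inheritParams state_weight
#' @return Named numeric vector `c(v_on = , v_off = )`.
#' @examples
#' on_off_sums(numeric(0), 0.5, cooperativity_parameters(numeric(0)))
#' @export
on_off_sums <- function(doses, pol, params) {
  ss <- state_probabilities(doses, pol, params)
  c(v_on = ss$v_on, v_off = ss$v_off)
}

#' Probability that RNA polymerase occupies the promoter
#'
#' The equilibrium binding probability \eqn{p = V_{on}/(V_{on} + V_{off})},
#' equal to the summed probability of all polymerase-bound states. Computed as
#' a log-space difference, so it stays finite at extreme doses.
#'
#' @inheritParams state_weight
#' @return A probability in \[0, 1\].
#' @examples
#' # basal occupancy at half the polymerase dissociation constant: 1/3
#' occupancy_probability(numeric(0), 0.5, cooperativity_parameters(numeric(0)))
#' @export
occupancy_probability <- function(doses, pol, params) {
  x <- .dose_vector(doses)
  x_p <- .pol_value(pol)
  if (x_p == 0) return(0)
  states <- enumerate_states(length(x), names(x))
  lw <- .log_weights(states, x, x_p, params)
  on <- states$rnap_bound
  l_on <- .logsumexp(lw[on])
  l_off <- .logsumexp(lw[!on])
  1 / (1 + exp(l_off - l_on))
}

.logsumexp <- function(l) {
  m <- max(l)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(l - m)))
}

#' Transcription rate from promoter occupancy
#'
#' The standard linear assumption: the transcription rate is proportional to
#' the polymerase binding probability. The proportionality constant is an
#' arbitrary scale carried by the user.
#'
#' @param p Occupancy probability (or vector of probabilities).
#' @param rate_scale Positive proportionality constant (arbitrary units).
#' @return `rate_scale * p`.
#' @export
transcription_rate <- function(p, rate_scale) {
  if (!is.numeric(rate_scale) || length(rate_scale) != 1L || rate_scale <= 0)
    stop("'rate_scale' must be a positive number")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("'p' must lie in [0, 1]")
  rate_scale * p
}
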