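# Vectorized log-sum-exp over the columns of a matrix of log terms.
# Handles -Inf rows (all-zero weights never occur: the empty state is 1).
.lse_rows <- function(...) {
  mat <- cbind(...)
  m <- do.call(pmax, c(as.data.frame(mat), na.rm = FALSE))
  s <- rowSums(exp(mat - m))
  out <- m + log(s)
  out[!is.finite(m)] <- -Inf
  out
}

# Closed-form two-activator occupancy, fully vectorized, in log space:
#   v_on  = x_P (1 + x_A w_A + x_B w_B + x_A x_B w_A w_B omega_AB omega3)
#   v_off = 1 + x_A + x_B + x_A x_B omega_AB
#   p     = v_on / (v_on + v_off)
.p_two <- function(x_p, x_a, x_b, w_a, w_b, omega_ab = 1, omega3 = 1) {
  la <- log(x_a); lb <- log(x_b)
  lwa <- log(w_a); lwb <- log(w_b)
  lo <- log(omega_ab); l3 <- log(omega3)
  l_on <- .lse_rows(0, la + lwa, lb + lwb, la + lb + lwa + lwb + lo + l3)
  l_off <- .lse_rows(0, la, lb, la + lb + lo)
  p <- 1 / (1 + exp(l_off + (-log(x_p)) - l_on))
  p[x_p == 0] <- 0
  p
}

# Difference measure underlying the synergy classification:
#   D = p(x_A, x_B) - p(x_A, 0) - p(0, x_B)
# (raw occupancies; optionally the basal occupancy p(0,0) is added back).
.d_two <- function(x_p, x_a, x_b, w_a, w_b, omega_ab = 1, omega3 = 1,
                   include_basal = FALSE) {
  d <- .p_two(x_p, x_a, x_b, w_a, w_b, omega_ab, omega3) -
    .p_two(x_p, x_a, 0, w_a, w_b, omega_ab, omega3) -
    .p_two(x_p, 0, x_b, w_a, w_b, omega_ab, omega3)
  if (include_basal) d <- d + x_p / (1 + x_p)
  d
}

#' Promoter regulated by two activators
#'
#' The seven-parameter system describing a promoter with binding sites for two
#' activators A and B: relative doses `x_A`, `x_B`, relative polymerase dose
#' `x_P`, two-body activator-polymerase factors `w_A`, `w_B`, the
#' activator-activator factor `omega_AB`, and the three-body factor `omega3`.
#'
#' @param x_P Relative RNA polymerase concentration (>= 0), or a
#'   [polymerase_dose()].
#' @param x_A,x_B Relative activator concentrations (>= 0), or
#'   [activator_dose()] objects.
#' @param w_A,w_B Positive two-body cooperativity factors.
#' @param omega_AB Positive activator-activator factor (default 1).
#' @param omega3 Positive three-body factor (default 1).
#' @return An object of class `two_activator_system`.
#' @examples
#' two_activator_system(x_P = 0.1, x_A = 1, x_B = 1, w_A = 5, w_B = 5)
#' @export
two_activator_system <- function(x_P, x_A, x_B, w_A = 1, w_B = 1,
                                 omega_AB = 1, omega3 = 1) {
  if (inherits(x_A, "activator_dose")) x_A <- x_A$relative_concentration
  if (inherits(x_B, "activator_dose")) x_B <- x_B$relative_concentration
  x_P <- .pol_value(x_P)
  for (nm in c("x_A", "x_B")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("'", nm, "' must be a non-negative number")
  }
  for (nm in c("w_A", "w_B", "omega_AB", "omega3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("'", nm, "' must be a positive number")
  }
  structure(
    list(x_P = x_P, x_A = as.numeric(x_A), x_B = as.numeric(x_B),
         w_A = as.numeric(w_A), w_B = as.numeric(w_B),
         omega_AB = as.numeric(omega_AB), omega3 = as.numeric(omega3)),
    class = "two_activator_system"
  )
}

#' @export
print.two_activator_system <- function(x, ...) {
  cat("Two-activator promoter system\n")
  cat(sprintf("  x_P = %.6g, x_A = %.6g, x_B = %.6g\n", x$x_P, x$x_A, x$x_B))
  cat(sprintf("  w_A = %.6g, w_B = %.6g, omega_AB = %.6g, omega3 = %.6g\n",
              x$w_A, x$w_B, x$omega_AB, x$omega3))
  cat(sprintf("  occupancy = %.6g\n", occupancy_two(x)))
  invisible(x)
}

.check_system <- function(system) {
  if (!inherits(system, "two_activator_system"))
    stop("'system' must be a two_activator_system object")
  system
}

#' Polymerase occupancy for two activators (closed form)
#'
#' Closed-form binding probability of RNA polymerase for the two-activator
#' promoter,
#' \deqn{p = \frac{x_P (1 + x_A w_A + x_B w_B +
#'         x_A x_B w_A w_B \omega_{AB} \omega_3)}{
#'         x_P (\cdot) + 1 + x_A + x_B + x_A x_B \omega_{AB}},}
#' identical to the full state-space enumeration.
#'
#' @param system A [two_activator_system()].
#' @param x_A,x_B Optional dose overrides (vectors allowed; recycled).
#' @return Occupancy probability (vectorized over the overrides).
#' @examples
#' occupancy_two(two_activator_system(0.5, 0, 0))  # basal: 1/3
#' @export
occupancy_two <- function(system, x_A = NULL, x_B = NULL) {
  s <- .check_system(system)
  if (is.null(x_A)) x_A <- s$x_A
  if (is.null(x_B)) x_B <- s$x_B
  .p_two(s$x_P, x_A, x_B, s$w_A, s$w_B, s$omega_AB, s$omega3)
}

#' Synergy difference measure for two activators
#'
#' The greater-than-additive / less-than-additive difference
#' \deqn{D = p(x_A, x_B) - p(x_A, 0) - p(0, x_B):}
#' dual-stimulation occupancy minus the sum of the two single-stimulation
#' occupancies, without basal subtraction. `D > 0` is a greater-than-additive
#' (synergistic) response, `D < 0` less-than-additive; `|D|` below `tolerance`
#' is reported as additive. `D` is symmetric under exchanging the (dose,
#' factor) pairs of A and B and always lies in (-2, 1).
#'
#' Setting `include_basal = TRUE` adds the basal occupancy `p(0, 0)` back,
#' i.e. compares baseline-subtracted responses; this alternative convention is
#' not the default.
#'
#' @inheritParams occupancy_two
#' @param tolerance Half-width of the additive band (absolute, probability
#'   units).
#' @param include_basal Add `p(0,0)` to the difference (default `FALSE`).
#' @return An object of class `synergy_assessment`: list with `D`,
#'   `classification` (one of `"greater_than_additive"`,
#'   `"less_than_additive"`, `"additive"`) and `tolerance`.
#' @examples
#' s <- two_activator_system(0.01, 1e3, 1e3, w_A = 10, w_B = 10)
#' synergy_difference(s)
#' @export
synergy_difference <- function(system, tolerance = 1e-9,
                               include_basal = FALSE) {
  s <- .check_system(system)
  d <- .d_two(s$x_P, s$x_A, s$x_B, s$w_A, s$w_B, s$omega_AB, s$omega3,
              include_basal)
  cls <- if (d > tolerance) "greater_than_additive"
         else if (d < -tolerance) "less_than_additive"
         else "additive"
  structure(list(D = d, classification = cls, tolerance = tolerance),
            class = "synergy_assessment")
}

#' @export
print.synergy_assessment <- function(x, ...) {
  cat(sprintf("D = %.6g (%s; additive band +/- %g)\n",
              x$D, x$classification, x$tolerance))
  invisible(x)
}

#' Saturation occupancies
#'
#' Analytic limits of the occupancy as the activator doses tend to infinity,
#' one at a time and jointly:
#' \deqn{p^{sat}_A = \frac{x_P w_A}{1 + x_P w_A}, \qquad
#'       p^{sat}_{AB} = \frac{x_P w_A w_B \omega_3}{1 + x_P w_A w_B \omega_3}.}
#' The activator-activator factor \eqn{\omega_{AB}} cancels in the joint limit
#' (it multiplies the leading term of both the on- and off-sums).
#'
#' @inheritParams occupancy_two
#' @return Named vector `c(p_sat_A =, p_sat_B =, p_sat_AB =)`.
#' @export
saturation_occupancies <- function(system) {
  s <- .check_system(system)
  sat <- function(z) z / (1 + z)
  c(p_sat_A = sat(s$x_P * s$w_A),
    p_sat_B = sat(s$x_P * s$w_B),
    p_sat_AB = sat(s$x_P * s$w_A * s$w_B * s$omega3))
}

#' Saturation fold changes
#'
#' Ratios of saturated stimulated occupancy to basal occupancy
#' \eqn{p_{basal} = x_P/(1+x_P)} for single stimulation by A, by B, and dual
#' stimulation. In the low-polymerase limit \eqn{x_P \to 0} these converge to
#' \eqn{F_A \to w_A}, \eqn{F_B \to w_B}, \eqn{F_{AB} \to w_A w_B \omega_3},
#' the relations used for parameter estimation from reporter-assay data.
#'
#' @inheritParams occupancy_two
#' @return Named vector `c(F_A =, F_B =, F_AB =)`.
#' @export
fold_change <- function(system) {
  s <- .check_system(system)
  if (s$x_P <= 0) stop("fold changes are undefined at x_P = 0 (no basal occupancy)")
  basal <- s$x_P / (1 + s$x_P)
  p <- saturation_occupancies(s)
  stats::setNames(as.numeric(p) / basal, c("F_A", "F_B", "F_AB"))
}
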