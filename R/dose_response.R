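# Double-binding-site promoter: one activator species, two identical sites.
# Specialization x_A = x_B = x, w_A = w_B = w of the two-activator model.

#' Promoter with two identical binding sites for one activator
#'
#' @param x_P Relative RNA polymerase concentration (>= 0).
#' @param x Relative activator concentration shared by both sites (>= 0;
#'   scalar default dose, operations accept dose vectors).
#' @param w Positive per-site activator-polymerase factor.
#' @param omega_tf Positive site-site activator-activator factor.
#' @param omega3 Positive three-body factor.
#' @return An object of class `double_site_system`.
#' @examples
#' double_site_system(x_P = 0.05, x = 1, w = 30)
#' @export
double_site_system <- function(x_P, x = 0, w = 1, omega_tf = 1, omega3 = 1) {
  x_P <- .pol_value(x_P)
  if (!is.numeric(x) || any(x < 0) || anyNA(x)) stop("'x' must be non-negative")
  for (nm in c("w", "omega_tf", "omega3")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("'", nm, "' must be a positive number")
  }
  structure(list(x_P = x_P, x = as.numeric(x), w = as.numeric(w),
                 omega_tf = as.numeric(omega_tf), omega3 = as.numeric(omega3)),
            class = "double_site_system")
}

.check_ds <- function(sys) {
  if (!inherits(sys, "double_site_system"))
    stop("'sys' must be a double_site_system object")
  sys
}

#' Occupancy of the double-binding-site promoter
#'
#' Polymerase binding probability of the two-site promoter, the
#' specialization \eqn{x_A = x_B = x}, \eqn{w_A = w_B = w} of the general
#' two-activator occupancy.
#'
#' @param sys A [double_site_system()].
#' @param x Optional dose vector overriding `sys$x`.
#' @return Occupancy probability, vectorized over `x`.
#' @export
double_site_occupancy <- function(sys, x = NULL) {
  s <- .check_ds(sys)
  if (is.null(x)) x <- s$x
  .p_two(s$x_P, x, x, s$w, s$w, s$omega_tf, s$omega3)
}

#' Occupancy of the single-binding-site reference promoter
#'
#' Binding probability of a promoter with one site for the activator,
#' \deqn{p_{SS} = \frac{x_P (1 + x w)}{x_P (1 + x w) + 1 + x},}
#' monotone non-decreasing in the dose for \eqn{w \ge 1}, saturating at
#' \eqn{x_P w / (1 + x_P w)}. The reference promoter shares `x_P` and `w`
#' with one site of the double-site promoter.
#'
#' @param x_P Relative polymerase concentration (>= 0).
#' @param x Dose (vectorized, >= 0).
#' @param w Positive activator-polymerase factor.
#' @return Occupancy probability.
#' @export
single_site_occupancy <- function(x_P, x, w) {
  if (any(x_P < 0) || any(x < 0) || any(w <= 0)) stop("invalid inputs")
  # exp(...) diverges at x_P = 0, giving p = 0 without a special case
  1 / (1 + exp(log1p(x) - log(x_P) - log1p(x * w)))
}

#' Dose-resolved synergy of the double-site promoter
#'
#' The difference between the double-site occupancy and twice the single-site
#' occupancy at the same dose,
#' \eqn{D(x) = p_{DS}(x) - 2 p_{SS}(x)}. Its sign classifies the response at
#' that dose as greater-than-additive (positive) or less-than-additive
#' (negative).
#'
#' @inheritParams double_site_occupancy
#' @return D, vectorized over `x`.
#' @export
dose_synergy <- function(sys, x = NULL) {
  s <- .check_ds(sys)
  if (is.null(x)) x <- s$x
  double_site_occupancy(s, x) - 2 * single_site_occupancy(s$x_P, x, s$w)
}

#' Ratio measure of synergy (double site over twice single site)
#'
#' The synergy ratio \eqn{p_{DS}(x) / (2 p_{SS}(x))}, the measure used in
#' reporter experiments comparing a multi-site promoter against a single-site
#' construct. The ratio exceeds 1 exactly where [dose_synergy()] is positive.
#' In the re-entrant regime it rises above 1, reaches a single interior peak,
#' then decays monotonically below 1 at saturating doses.
#'
#' @inheritParams double_site_occupancy
#' @return The ratio (1/2 at zero dose), vectorized over `x`.
#' @export
synergy_ratio <- function(sys, x = NULL) {
  s <- .check_ds(sys)
  if (s$x_P <= 0) stop("synergy ratio undefined at x_P = 0")
  if (is.null(x)) x <- s$x
  double_site_occupancy(s, x) / (2 * single_site_occupancy(s$x_P, x, s$w))
}

# Sign-change bracketing + bisection for roots of a smooth f over a
# log-spaced dose grid. Bisection refines each bracket to `tol` in log-dose.
.bracket_roots <- function(f, lo = 1e-6, hi = 1e6, n = 400, tol = 1e-12) {
  lx <- seq(log(lo), log(hi), length.out = n)
  fx <- f(exp(lx))
  roots <- numeric(0)
  for (i in seq_len(n - 1L)) {
    f1 <- fx[i]; f2 <- fx[i + 1L]
    if (is.na(f1) || is.na(f2)) next
    if (f1 == 0) { roots <- c(roots, exp(lx[i])); next }
    if (f1 * f2 < 0) {
      a <- lx[i]; b <- lx[i + 1L]; fa <- f1
      while (b - a > tol) {
        m <- (a + b) / 2
        fm <- f(exp(m))
        if (fm == 0) { a <- m; b <- m; break }
        if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
      }
      roots <- c(roots, exp((a + b) / 2))
    }
  }
  if (length(fx) && fx[n] == 0) roots <- c(roots, exp(lx[n]))
  sort(unique(roots))
}

#' Critical crossover dose driven by the three-body interaction
#'
#' For the double-site promoter with neutral per-site factors
#' (\eqn{w = 1}, \eqn{\omega_{tf} = 1}) and a three-body factor
#' \eqn{\omega_3}, the single-site reference occupancy is dose-independent
#' and the synergy difference has at most one positive root, in closed form
#' the positive solution of
#' \deqn{\left[(1 - x_P)\,\omega_3 - 2\right] x^2 - 2 (1 + x_P)\, x -
#'       (1 + x_P) = 0,}
#' \deqn{x^* = \frac{c + \sqrt{c^2 + c\,a}}{a}, \quad c = 1 + x_P,\;
#'       a = (1 - x_P)\,\omega_3 - 2.}
#' The crossover exists only when \eqn{\omega_3 (1 - x_P) > 2}; in particular
#' never for \eqn{x_P \ge 1}, however strong the three-body interaction.
#'
#' @param x_P Relative polymerase concentration in (0, 1) (vectorized).
#' @param omega3 Positive three-body factor (vectorized).
#' @return The critical dose, or `NA` where no crossover exists.
#' @examples
#' critical_dose_three_body(0.2, 4)  # 1 + sqrt(2)
#' @export
critical_dose_three_body <- function(x_P, omega3) {
  if (any(x_P <= 0)) stop("'x_P' must be positive")
  if (any(omega3 <= 0)) stop("'omega3' must be positive")
  n <- max(length(x_P), length(omega3))
  x_P <- rep_len(x_P, n); omega3 <- rep_len(omega3, n)
  cc <- 1 + x_P
  a <- (1 - x_P) * omega3 - 2
  out <- rep(NA_real_, n)
  ok <- a > 0
  out[ok] <- (cc[ok] + sqrt(cc[ok]^2 + cc[ok] * a[ok])) / a[ok]
  out
}

#' Critical polymerase line for three-body-driven crossovers
#'
#' The polymerase concentration below which a three-body crossover dose
#' exists: from the existence condition \eqn{\omega_3 (1 - x_P) > 2},
#' \deqn{x_P^{crit}(\omega_3) = 1 - 2/\omega_3,}
#' defined for \eqn{\omega_3 > 2} and approaching the asymptote
#' \eqn{x_P = 1} as \eqn{\omega_3 \to \infty}.
#'
#' @param omega3 Positive three-body factor (vectorized).
#' @return Critical \eqn{x_P}, `NA` where no crossover is possible
#'   (`omega3 <= 2`).
#' @export
critical_xp_line_three_body <- function(omega3) {
  if (any(omega3 <= 0)) stop("'omega3' must be positive")
  out <- 1 - 2 / omega3
  out[omega3 <= 2] <- NA_real_
  out
}

#' Crossover doses driven by the nonlinearity of the machinery
#'
#' For the double-site promoter with neutral interaction factors
#' (\eqn{\omega_{tf} = \omega_3 = 1}) and per-site factor `w`, returns all
#' positive roots of the dose-resolved synergy difference, found by
#' sign-change bracketing on a log-spaced dose grid refined by bisection.
#' There are 0, 1 or 2 roots, corresponding to the three response patterns
#' (pure less-than-additive, single crossover, re-entrant).
#'
#' Equivalently, the roots are the doses at which the activation ratio
#' \eqn{r(x) = (1 + x w)/(1 + x)} crosses the solutions of
#' \eqn{x_P r^2 - r + 2 = 0}; the numeric solver and that closed form agree
#' to high precision and both are exercised by the test suite.
#'
#' @param x_P Relative polymerase concentration (> 0).
#' @param w Per-site factor (>= 1).
#' @param dose_range Search interval for doses (default `c(1e-6, 1e6)`).
#' @param n Grid points for bracketing (default 400).
#' @return Increasing numeric vector of 0, 1 or 2 critical doses.
#' @export
critical_doses_nonlinearity <- function(x_P, w, dose_range = c(1e-6, 1e6),
                                        n = 400) {
  if (!is.numeric(x_P) || x_P <= 0) stop("'x_P' must be positive")
  if (!is.numeric(w) || w < 1) stop("'w' must be >= 1")
  sys <- double_site_system(x_P, 0, w)
  .bracket_roots(function(x) dose_synergy(sys, x),
                 dose_range[1], dose_range[2], n)
}

# Closed-form counterpart of critical_doses_nonlinearity (internal; used as
# an independent cross-check): roots of x_P r^2 - r + 2 = 0 mapped back
# through r = (1 + x w)/(1 + x).
.critical_doses_closed <- function(x_P, w) {
  disc <- 1 - 8 * x_P
  if (disc < 0) return(numeric(0))
  r <- sort(c((1 - sqrt(disc)) / (2 * x_P), (1 + sqrt(disc)) / (2 * x_P)))
  r <- r[r > 1 & r < w]
  sort((r - 1) / (w - r))
}

#' Classify the dose-response pattern of a double-site promoter
#'
#' Counts the crossover doses of the synergy difference over a wide dose range
#' and maps the count to the response pattern: 0 roots mean the response is
#' less-than-additive at every dose, 1 root a single crossover to a
#' greater-than-additive response, and 2 roots the re-entrant sequence
#' less-than-additive, greater-than-additive, less-than-additive.
#'
#' @param x_P Relative polymerase concentration (> 0).
#' @param w Per-site factor (>= 1).
#' @param omega_tf Site-site factor (>= 1).
#' @param omega3 Three-body factor (>= 1).
#' @param dose_range,n Search grid, as in [critical_doses_nonlinearity()].
#' @return One of `"less_than_additive"`, `"single_crossover"`,
#'   `"re_entrant"`.
#' @export
classify_dose_pattern <- function(x_P, w, omega_tf = 1, omega3 = 1,
                                  dose_range = c(1e-6, 1e6), n = 400) {
  if (!is.numeric(x_P) || x_P <= 0) stop("'x_P' must be positive")
  if (w < 1 || omega_tf < 1 || omega3 < 1)
    stop("activator domain requires w, omega_tf, omega3 >= 1")
  sys <- double_site_system(x_P, 0, w, omega_tf, omega3)
  roots <- .bracket_roots(function(x) dose_synergy(sys, x),
                          dose_range[1], dose_range[2], n)
  switch(as.character(length(roots)),
         "0" = "less_than_additive",
         "1" = "single_crossover",
         "2" = "re_entrant",
         stop("unexpected number of sign changes: ", length(roots)))
}

#' Dose-response curve of a double-site promoter
#'
#' Tabulates the double-site occupancy, the single-site reference occupancy,
#' the synergy difference D and the synergy ratio over a dose grid, and
#' annotates the critical crossover doses and the response pattern.
#'
#' @param sys A [double_site_system()].
#' @param doses Dose grid (default 200 log-spaced points in `[1e-3, 1e3]`).
#' @param dose_range,n Root-search grid for the critical-dose annotation.
#' @return An object of class `dose_response_curve`: a data frame with
#'   columns `x`, `p_double`, `p_single`, `D`, `ratio` and attributes
#'   `critical_doses` (increasing numeric vector) and `pattern`.
#' @examples
#' curve <- dose_response_curve(double_site_system(0.05, 0, 30))
#' attr(curve, "pattern")
#' @export
dose_response_curve <- function(sys,
                                doses = exp(seq(log(1e-3), log(1e3),
                                                length.out = 200)),
                                dose_range = c(1e-6, 1e6), n = 400) {
  s <- .check_ds(sys)
  rows <- data.frame(
    x = doses,
    p_double = double_site_occupancy(s, doses),
    p_single = single_site_occupancy(s$x_P, doses, s$w),
    D = dose_synergy(s, doses)
  )
  rows$ratio <- if (s$x_P > 0) synergy_ratio(s, doses) else NA_real_
  roots <- .bracket_roots(function(x) dose_synergy(s, x),
                          dose_range[1], dose_range[2], n)
  pattern <- switch(as.character(length(roots)),
                    "0" = "less_than_additive",
                    "1" = "single_crossover",
                    "2" = "re_entrant",
                    "multiple_crossovers")
  structure(rows, critical_doses = roots, pattern = pattern,
            class = c("dose_response_curve", "data.frame"))
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve (%d doses): pattern %s\n",
              nrow(x), attr(x, "pattern")))
  cd <- attr(x, "critical_doses")
  if (length(cd))
    cat("  critical doses:", paste(sprintf("%.6g", cd), collapse = ", "), "\n")
  NextMethod()
}
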