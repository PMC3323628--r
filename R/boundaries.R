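# Closed-form critical boundaries between greater-than-additive and
# less-than-additive regimes, and the regime classification table.

#' Limiting synergy statistic (strong activation, low polymerase)
#'
#' In the strong-activation (\eqn{x_A w_A \gg 1}, \eqn{x_B w_B \gg 1}) and
#' low-polymerase (\eqn{x_P \ll 1}) limit the sign of the synergy difference
#' D is governed by
#' \deqn{w_A w_B \omega_3 - w_A - w_B.}
#' The activator-activator factor \eqn{\omega_{AB}} cancels in this limit.
#' Vectorized over all arguments.
#'
#' @param w_A,w_B Positive two-body factors.
#' @param omega3 Positive three-body factor (default 1).
#' @return The statistic; its sign equals the sign of D in the limit.
#' @export
limiting_synergy_statistic <- function(w_A, w_B, omega3 = 1) {
  if (any(w_A <= 0) || any(w_B <= 0) || any(omega3 <= 0))
    stop("factors must be positive")
  w_A * w_B * omega3 - w_A - w_B
}

#' Sign statistic for nonlinearity-induced synergy
#'
#' For a system with neutral interaction factors
#' (\eqn{\omega_{AB} = \omega_3 = 1}) the sign of the synergy difference D at
#' finite doses equals the sign of the quadratic form
#' \deqn{(uv - u - v) - 2uv\, x_P - (uv)^2 x_P^2,}
#' where \eqn{u = (1 + x_A w_A)/(1 + x_A)} and
#' \eqn{v = (1 + x_B w_B)/(1 + x_B)} are the effective activation ratios.
#' Both non-constant coefficients are negative, so for each (u, v) the
#' synergistic window in \eqn{x_P} is an interval anchored at 0.
#'
#' @param system A [two_activator_system()] with `omega_AB = omega3 = 1`.
#' @return The statistic (same sign as D).
#' @export
synergy_sign_statistic <- function(system) {
  s <- .check_system(system)
  if (s$omega_AB != 1 || s$omega3 != 1)
    stop("synergy_sign_statistic requires omega_AB = omega3 = 1")
  if (!is.finite(s$x_A) || !is.finite(s$x_B)) stop("doses must be finite")
  u <- (1 + s$x_A * s$w_A) / (1 + s$x_A)
  v <- (1 + s$x_B * s$w_B) / (1 + s$x_B)
  uv <- u * v
  (uv - u - v) - 2 * uv * s$x_P - uv^2 * s$x_P^2
}

#' Critical polymerase concentration for equal activators at saturation
#'
#' With neutral interaction factors, equal two-body factors
#' \eqn{w_A = w_B = w} and saturating doses, the synergy difference changes
#' sign at
#' \deqn{x_P^{crit}(w) = \frac{w - 2}{w^2},}
#' defined for \eqn{w \ge 2} (for weaker activators the saturated response is
#' less-than-additive at every polymerase concentration). The curve rises from
#' 0 at \eqn{w = 2}, peaks at \eqn{w = 4} with value 1/8, and decays towards 0
#' as \eqn{w \to \infty}; below the curve the saturated response is
#' greater-than-additive, above it less-than-additive.
#'
#' @param w Positive two-body factor (vectorized).
#' @return Critical \eqn{x_P}, or `NA` where no positive boundary exists
#'   (`w < 2`).
#' @examples
#' critical_xp_equal_activators(c(2, 4, 10))  # 0, 1/8, 0.08
#' @export
critical_xp_equal_activators <- function(w) {
  if (any(w <= 0)) stop("'w' must be positive")
  out <- (w - 2) / w^2
  out[w < 2] <- NA_real_
  out
}

#' Critical polymerase concentration versus energy shift
#'
#' Re-parametrizes [critical_xp_equal_activators()] by the magnitude `g` of
#' the activating energy shift in units of RT (so \eqn{w = e^g}):
#' \deqn{x_P^{crit}(g) = \frac{e^g - 2}{e^{2g}}.}
#'
#' @param g Energy shift in units of RT (vectorized).
#' @return Critical \eqn{x_P}, `NA` where no boundary exists (`g < log 2`).
#' @export
critical_xp_vs_energy <- function(g) {
  critical_xp_equal_activators(exp(g))
}

#' Two-body synergy hyperbola
#'
#' With neutral interaction factors, in the strong-activation low-polymerase
#' limit the boundary between less-than-additive and greater-than-additive
#' responses in the \eqn{(w_A, w_B)} plane is the hyperbola
#' \deqn{w_B^{crit}(w_A) = \frac{w_A}{w_A - 1},}
#' i.e. \eqn{(w_A - 1)(w_B - 1) = 1}. Above the curve the limiting response is
#' greater-than-additive. The diagonal crosses it at \eqn{w_A = w_B = 2}; the
#' horizontal asymptote is \eqn{w_B = 1}.
#'
#' @param w_A Two-body factor of activator A (vectorized).
#' @return Critical \eqn{w_B}; `Inf` where unbounded (`w_A <= 1`).
#' @export
two_body_hyperbola <- function(w_A) {
  if (any(w_A <= 0)) stop("'w_A' must be positive")
  out <- rep(Inf, length(w_A))
  ok <- w_A > 1
  out[ok] <- w_A[ok] / (w_A[ok] - 1)
  out
}

#' Three-body synergy hyperbola
#'
#' With no direct activator-activator interaction (\eqn{\omega_{AB} = 1}), in
#' the strong-activation low-polymerase limit the critical curve separating
#' less-than-additive (below) from greater-than-additive (above) responses is
#' \deqn{w_B^{crit}(w_A; \omega_3) = \frac{w_A}{\omega_3 w_A - 1},}
#' with asymptotes at \eqn{w_A = 1/\omega_3} and \eqn{w_B = 1/\omega_3} that
#' move towards the axes as \eqn{\omega_3} grows. At \eqn{\omega_3 = 1} this
#' reduces to [two_body_hyperbola()]. For \eqn{\omega_3 \ge 2} the whole
#' activator domain \eqn{w_A, w_B > 1} lies above the curve.
#'
#' @param w_A Two-body factor of activator A (vectorized).
#' @param omega3 Positive three-body factor.
#' @return Critical \eqn{w_B}; `Inf` where unbounded
#'   (`w_A <= 1/omega3`, at or below the vertical asymptote).
#' @export
three_body_hyperbola <- function(w_A, omega3) {
  if (any(w_A <= 0)) stop("'w_A' must be positive")
  if (any(omega3 <= 0)) stop("'omega3' must be positive")
  denom <- omega3 * w_A - 1
  out <- rep(Inf, length(denom))
  ok <- denom > 0
  out[ok] <- (w_A / denom)[ok]
  out
}

#' Universal three-body cooperativity threshold
#'
#' The smallest three-body factor \eqn{\omega_3} for which the
#' strong-activation, low-polymerase synergy statistic is positive for every
#' pair of activator factors \eqn{w_A, w_B > 1} (with
#' \eqn{\omega_{AB} = 1}). Found by bisection of the everywhere-positive
#' predicate evaluated with [limiting_synergy_statistic()] on a log grid of
#' factor pairs; the worst case sits at \eqn{w_A = w_B \to 1^+}, where the
#' threshold approaches 2.
#'
#' @param n_grid Number of grid points per axis (default 200).
#' @param w_min,w_max Grid limits; `w_min` must exceed 1 (the grid covers the
#'   open interval just above 1 up to `w_max`).
#' @param tol Bisection tolerance on the returned factor.
#' @return The infimum three-body factor (about 2).
#' @examples
#' minimal_universal_three_body_factor(n_grid = 50)
#' @export
minimal_universal_three_body_factor <- function(n_grid = 200,
                                                w_min = 1 + 1e-4,
                                                w_max = 100,
                                                tol = 1e-4) {
  if (w_min <= 1) stop("'w_min' must exceed 1 (activator domain is open at 1)")
  w <- exp(seq(log(w_min), log(w_max), length.out = n_grid))
  wa <- rep(w, times = n_grid)
  wb <- rep(w, each = n_grid)
  positive_everywhere <- function(o3)
    all(limiting_synergy_statistic(wa, wb, o3) > 0)
  lo <- tol
  hi <- 4
  if (!positive_everywhere(hi)) stop("bisection bracket failure")
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (positive_everywhere(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Brute-force sign scan of the synergy difference
#'
#' Evaluates the synergy difference D on a deterministic grid over one or more
#' free coordinates of a template system and records its sign. This is the
#' reference oracle against which every closed-form boundary is validated.
#'
#' @param system Template [two_activator_system()]; coordinates named in
#'   `free` are overridden by the grid.
#' @param free Character vector of coordinate names, a subset of
#'   `c("x_P", "x_A", "x_B", "w_A", "w_B", "omega_AB", "omega3")`.
#' @param ranges Named list of length-2 numeric ranges `c(lo, hi)`, one per
#'   free coordinate.
#' @param n Grid points per coordinate.
#' @param log_spacing Use log-spaced grids (default `TRUE`; requires positive
#'   range limits).
#' @return Data frame with one column per free coordinate plus `D` and `sign`.
#' @examples
#' tmpl <- two_activator_system(0.05, 1e6, 1e6, w_A = 5, w_B = 5)
#' scan <- sign_scan_oracle(tmpl, "x_P", list(x_P = c(1e-3, 1)), n = 20)
#' @export
sign_scan_oracle <- function(system, free, ranges, n = 25,
                             log_spacing = TRUE) {
  s <- .check_system(system)
  coords <- c("x_P", "x_A", "x_B", "w_A", "w_B", "omega_AB", "omega3")
  if (!all(free %in% coords))
    stop("unknown coordinate(s): ", paste(setdiff(free, coords), collapse = ", "))
  if (!all(free %in% names(ranges))) stop("'ranges' must cover every free coordinate")
  if (n^length(free) > 1e6) stop("grid too large (over 1e6 points)")
  grids <- lapply(free, function(f) {
    r <- ranges[[f]]
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid range for '", f, "'")
    if (log_spacing) {
      if (any(r <= 0)) stop("log-spaced range for '", f, "' must be positive")
      exp(seq(log(r[1]), log(r[2]), length.out = n))
    } else seq(r[1], r[2], length.out = n)
  })
  names(grids) <- free
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  args <- list(x_P = s$x_P, x_A = s$x_A, x_B = s$x_B, w_A = s$w_A,
               w_B = s$w_B, omega_AB = s$omega_AB, omega3 = s$omega3)
  for (f in free) args[[f]] <- grid[[f]]
  grid$D <- .d_two(args$x_P, args$x_A, args$x_B, args$w_A, args$w_B,
                   args$omega_AB, args$omega3)
  grid$sign <- sign(grid$D)
  grid
}

#' Classify the synergy regime of a two-activator promoter
#'
#' Matches a system against the catalogue of analytically characterized
#' regimes and reports the predicted sign of the synergy difference D.
#' Classification is defined for activators only (`w_A, w_B >= 1`).
#'
#' The cases, matched in the fixed priority order 1, 2, 3, 4, 7b, 7a, 6, 5b,
#' 5a so that overlapping preconditions resolve deterministically:
#' \describe{
#'   \item{1}{Low activator concentrations: only less-than-additive.}
#'   \item{2}{Weak activators (all polymerase-coupling factors near 1), even
#'     with strong activator-activator interaction: less-than-additive.}
#'   \item{3}{Neutral interaction factors and polymerase at or above half its
#'     dissociation constant (`x_P >= 1/2`): less-than-additive.}
#'   \item{4}{Neutral interaction factors and weak activation
#'     (`x*w` small for both): less-than-additive.}
#'   \item{5a/5b}{Neutral interaction factors, saturating stimulation: sign of
#'     the saturated difference; 5b is the equal-activator slice governed by
#'     [critical_xp_equal_activators()].}
#'   \item{6}{Strong activation at low polymerase with `omega3 = 1`
#'     (`omega_AB` free, it cancels): sign from [two_body_hyperbola()].}
#'   \item{7a}{Three-body interaction (`omega_AB = 1`, `omega3 > 1`), strong
#'     activation, low polymerase: sign from [three_body_hyperbola()].}
#'   \item{7b}{Strong three-body interaction (`omega3 >= 2`): always
#'     greater-than-additive in that limit.}
#' }
#'
#' @param system A [two_activator_system()] with `w_A, w_B >= 1`.
#' @param thresholds Named list of the documented numeric cutoffs used to
#'   translate the asymptotic conditions into checkable inequalities:
#'   `low_tf` (doses below this are "low", default 0.01), `low_xp` (default
#'   0.01), `strong` (activation products `x*w` at or above this are
#'   "strong"/saturating, default 100), `weak` (factors within `1 + weak` are
#'   "weak activators", default 0.05), `factor_tol` (tolerance for treating an
#'   interaction factor as exactly 1), `equal_tol` (relative tolerance for
#'   `w_A = w_B`).
#' @return An object of class `regime_label`: list with `case_id` (one of
#'   `"1"`, `"2"`, `"3"`, `"4"`, `"5a"`, `"5b"`, `"6"`, `"7a"`, `"7b"`,
#'   `"unclassified"`), `predicted_sign` (`"negative"`, `"positive"`,
#'   `"either"`) and `conditions_met` (character).
#' @examples
#' classify_regime(two_activator_system(0.1, 1e-4, 1e-4, 5, 5))  # case 1
#' @export
classify_regime <- function(system,
                            thresholds = list()) {
  s <- .check_system(system)
  th <- utils::modifyList(
    list(low_tf = 0.01, low_xp = 0.01, strong = 100, weak = 0.05,
         factor_tol = 1e-9, equal_tol = 1e-6),
    thresholds
  )
  if (s$w_A < 1 || s$w_B < 1)
    stop("classification is defined for activators only (w >= 1)")
  near1 <- function(v) abs(v - 1) <= th$factor_tol
  neutral <- near1(s$omega_AB) && near1(s$omega3)
  strong <- s$x_A * s$w_A >= th$strong && s$x_B * s$w_B >= th$strong
  low_xp <- s$x_P <= th$low_xp

  label <- function(case, sign, conds)
    structure(list(case_id = case, predicted_sign = sign,
                   conditions_met = conds),
              class = "regime_label")

  if (s$x_A <= th$low_tf && s$x_B <= th$low_tf)
    return(label("1", "negative", "low activator concentrations"))
  if (max(s$w_A, s$w_B, s$omega3) <= 1 + th$weak)
    return(label("2", "negative", "weak activators (all polymerase-coupling factors near 1)"))
  if (neutral && s$x_P >= 0.5)
    return(label("3", "negative",
                 "neutral interaction factors, x_P >= 1/2"))
  if (neutral && s$x_A * s$w_A <= th$low_tf && s$x_B * s$w_B <= th$low_tf)
    return(label("4", "negative", "neutral interaction factors, weak activation"))
  if (near1(s$omega_AB) && s$omega3 >= 2 && strong && low_xp)
    return(label("7b", "positive",
                 "strong three-body interaction (omega3 >= 2), strong activation, low x_P"))
  if (near1(s$omega_AB) && s$omega3 > 1 && strong && low_xp) {
    crit <- three_body_hyperbola(s$w_A, s$omega3)
    sign <- if (s$w_B > crit) "positive"
            else if (s$w_B < crit) "negative" else "either"
    return(label("7a", sign,
                 "three-body interaction, strong activation, low x_P; sign from hyperbola"))
  }
  if (near1(s$omega3) && strong && low_xp) {
    crit <- two_body_hyperbola(s$w_A)
    sign <- if (s$w_B > crit) "positive"
            else if (s$w_B < crit) "negative" else "either"
    return(label("6", sign,
                 "strong activation, low x_P, omega3 = 1; sign from two-body hyperbola"))
  }
  if (neutral && strong) {
    if (abs(s$w_A - s$w_B) <= th$equal_tol * max(s$w_A, s$w_B)) {
      crit <- critical_xp_equal_activators(s$w_A)
      sign <- if (is.na(crit) || s$x_P > crit) "negative"
              else if (s$x_P < crit) "positive" else "either"
      return(label("5b", sign,
                   "nonlinearity-induced, equal activators at saturation; sign from critical x_P curve"))
    }
    stat <- synergy_sign_statistic(s)
    sign <- if (stat > 0) "positive" else if (stat < 0) "negative" else "either"
    return(label("5a", sign,
                 "nonlinearity-induced, saturating stimulation; sign from quadratic statistic"))
  }
  label("unclassified", "either", "no analytic case matches")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime case %s: predicted sign %s\n  (%s)\n",
              x$case_id, x$predicted_sign, x$conditions_met))
  invisible(x)
}
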