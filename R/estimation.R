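# Estimation of cooperativity factors from saturation fold changes, and the
# predicted synergy-domain contour in dose space.

#' Estimate cooperativity factors from saturation fold changes
#'
#' Inverts the saturation fold-change relations to recover the two-body
#' factors and the joint three-body factor from three reporter readouts:
#' single stimulation by A, single stimulation by B, and dual stimulation,
#' each expressed as a fold change over basal activity at saturation.
#'
#' In the default low-polymerase mode (no `x_P` supplied) the limits
#' \eqn{F_A \to w_A}, \eqn{F_B \to w_B},
#' \eqn{F_{AB} \to w_A w_B \omega_3} give
#' \deqn{\hat w_A = F_A, \quad \hat w_B = F_B, \quad
#'       \hat \omega_3 = F_{AB} / (F_A F_B).}
#' In exact mode (`x_P` given) the finite-polymerase relation
#' \eqn{F = w (1 + x_P)/(1 + x_P w)} is inverted per condition,
#' \eqn{\hat w = F / (1 + x_P (1 - F))}, which requires every fold change to
#' stay below the invertibility bound \eqn{(1 + x_P)/x_P}; the joint estimate
#' \eqn{\widehat{w_A w_B \omega_3}} is inverted the same way from
#' \eqn{F_{AB}}.
#'
#' The activator-activator factor \eqn{\omega_{AB}} cancels at joint
#' saturation, so the three saturation readouts identify only the product
#' reported as `omega3`; `omega3` and \eqn{\omega_{AB}} are not separately
#' identifiable from these data, which is recorded in the output.
#'
#' @param records Data frame with columns `condition` (exactly one each of
#'   `"A_only"`, `"B_only"`, `"dual"`) and `fold_change` (non-negative);
#'   an optional `noise_sd` column is carried through untouched.
#' @param x_P Optional relative polymerase concentration for exact-mode
#'   inversion.
#' @return An object of class `estimated_parameters`: list with `w_A`, `w_B`,
#'   `omega3`, and `assumptions` (list with `low_polymerase`, `saturation`,
#'   `x_P_used`, `omega_identifiability`).
#' @examples
#' fc <- data.frame(condition = c("A_only", "B_only", "dual"),
#'                  fold_change = c(5, 10, 100))
#' estimate_from_fold_changes(fc)  # w_A = 5, w_B = 10, omega3 = 2
#' @export
estimate_from_fold_changes <- function(records, x_P = NULL) {
  if (!is.data.frame(records) ||
      !all(c("condition", "fold_change") %in% names(records)))
    stop("'records' must have columns 'condition' and 'fold_change'")
  need <- c("A_only", "B_only", "dual")
  if (!setequal(records$condition, need) || nrow(records) != 3L)
    stop("'records' must contain exactly one record per condition: ",
         paste(need, collapse = ", "))
  fc <- stats::setNames(records$fold_change, records$condition)[need]
  if (any(!is.finite(fc)) || any(fc < 0))
    stop("fold changes must be finite and non-negative")
  if (any(fc < 1))
    warning("fold change below 1: inconsistent with activation (w >= 1)")
  if (is.null(x_P)) {
    w_a <- fc[["A_only"]]
    w_b <- fc[["B_only"]]
    joint <- fc[["dual"]]
  } else {
    if (!is.numeric(x_P) || length(x_P) != 1L || x_P <= 0)
      stop("'x_P' must be a positive number")
    bound <- (1 + x_P) / x_P
    if (any(fc >= bound))
      stop(sprintf(
        "fold change >= invertibility bound (1 + x_P)/x_P = %.6g", bound))
    invert <- function(f) f / (1 + x_P * (1 - f))
    w_a <- invert(fc[["A_only"]])
    w_b <- invert(fc[["B_only"]])
    joint <- invert(fc[["dual"]])
  }
  omega3 <- joint / (w_a * w_b)
  if (any(c(w_a, w_b, omega3) <= 0)) stop("estimates must be positive")
  structure(
    list(w_A = w_a, w_B = w_b, omega3 = omega3,
         assumptions = list(
           low_polymerase = is.null(x_P),
           saturation = TRUE,
           x_P_used = if (is.null(x_P)) NA_real_ else x_P,
           omega_identifiability = paste(
             "omega3 is the joint factor w_A*w_B*omega3/(w_A*w_B);",
             "omega_AB cancels at joint saturation and is not separately",
             "identifiable from three saturation fold changes"))),
    class = "estimated_parameters"
  )
}

#' @export
print.estimated_parameters <- function(x, ...) {
  cat(sprintf("Estimated cooperativity factors: w_A = %.6g, w_B = %.6g, omega3 = %.6g\n",
              x$w_A, x$w_B, x$omega3))
  cat(sprintf("  mode: %s (x_P used: %s); saturation assumed\n",
              if (x$assumptions$low_polymerase) "low-polymerase limit" else "exact",
              format(x$assumptions$x_P_used)))
  invisible(x)
}

#' Read a fold-change table
#'
#' Reads a TSV with columns `condition` (`A_only`, `B_only`, `dual`) and
#' `fold_change`.
#'
#' @param path File path.
#' @return Data frame suitable for [estimate_from_fold_changes()].
#' @export
read_fold_changes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("condition", "fold_change") %in% names(df)))
    stop("fold-change table must have columns 'condition' and 'fold_change'")
  df
}

#' Dose inducing a given fraction of saturation activity
#'
#' The unique dose at which the single-site occupancy reaches
#' `fraction` of its saturation value \eqn{x_P w/(1 + x_P w)}, found by
#' bisection in log dose. Used to express dose axes in experiment-anchored
#' units (e.g. the dose inducing 80% of the saturation response).
#'
#' @param fraction Target fraction in (0, 1).
#' @param x_P Relative polymerase concentration (> 0).
#' @param w Activator-polymerase factor (> 1; at `w = 1` occupancy is
#'   dose-independent and no such dose exists).
#' @param tol Absolute tolerance on the achieved activity.
#' @return The dose `x*` with `single_site_occupancy(x_P, x*, w)` within
#'   `tol` of `fraction` times the saturation occupancy.
#' @export
dose_for_saturation_fraction <- function(fraction, x_P, w, tol = 1e-12) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("'fraction' must lie strictly between 0 and 1")
  if (!is.numeric(x_P) || x_P <= 0) stop("'x_P' must be positive")
  if (!is.numeric(w) || w <= 1)
    stop("'w' must exceed 1 (no dose dependence otherwise)")
  sat <- x_P * w / (1 + x_P * w)
  basal_share <- (x_P / (1 + x_P)) / sat
  if (fraction <= basal_share)
    stop(sprintf(paste0(
      "no dose induces %.3g of the saturation activity: basal occupancy ",
      "already amounts to fraction %.3g"), fraction, basal_share))
  target <- fraction * sat
  f <- function(lx) single_site_occupancy(x_P, exp(lx), w) - target
  lo <- log(1e-12); hi <- log(1e12)
  while (f(hi) < 0) {
    hi <- hi + log(1e3)
    if (hi > log(1e300)) stop("target fraction not reached within bracket")
  }
  while (hi - lo > 1e-15 * max(1, abs(hi))) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(1, abs(hi))) break
  }
  x_star <- exp((lo + hi) / 2)
  if (abs(single_site_occupancy(x_P, x_star, w) - target) > tol)
    warning("bisection did not reach the requested activity tolerance")
  x_star
}

#' Synergy-domain contour in the dose plane
#'
#' Traces the locus \eqn{D(x_A, x_B) = 0} separating the less-than-additive
#' domain (around the origin, where D < 0 always) from the
#' greater-than-additive domain, for a promoter with estimated (or specified)
#' factors. The contour is found by 1-D root bracketing along rays from the
#' origin through a fan of directions, each root refined until
#' \eqn{|D| < } `d_tol`.
#'
#' Optionally the dose axes are rescaled to experiment-anchored units: the
#' dose that induces `rescale_fraction` of the single-stimulation saturation
#' occupancy of the corresponding activator (occupancy, not
#' baseline-subtracted activity, defines the anchor).
#'
#' @param params An `estimated_parameters` object (or a list with `w_A`,
#'   `w_B`, `omega3`).
#' @param x_P Relative polymerase concentration (> 0).
#' @param omega_AB Activator-activator factor assumed for the forward model
#'   (default 1; unidentifiable from saturation fold changes).
#' @param n_rays Number of ray directions across the positive quadrant.
#' @param dose_limit Largest dose searched along each ray.
#' @param rescale_fraction Optional fraction in (0, 1) anchoring the axis
#'   rescaling (e.g. 0.8); requires `w_A, w_B > 1`.
#' @param d_tol Refinement tolerance on |D| at the reported contour points.
#' @return An object of class `boundary_curve`: data frame with columns
#'   `x_A`, `x_B`, `D` (and `x_A_rescaled`, `x_B_rescaled` when rescaling is
#'   requested), with attributes `parameterization = "ray_angle"`,
#'   `validity_domain`, and `empty` (TRUE when D < 0 everywhere searched).
#' @export
synergy_domain_contour <- function(params, x_P, omega_AB = 1, n_rays = 50,
                                   dose_limit = 1e6,
                                   rescale_fraction = NULL, d_tol = 1e-9) {
  w_a <- params$w_A; w_b <- params$w_B; o3 <- params$omega3
  if (is.null(w_a) || is.null(w_b) || is.null(o3))
    stop("'params' must provide w_A, w_B and omega3")
  if (!is.numeric(x_P) || x_P <= 0) stop("'x_P' must be positive")
  if (w_a < 1 || w_b < 1) stop("activator domain requires w_A, w_B >= 1")
  dfun <- function(xa, xb) .d_two(x_P, xa, xb, w_a, w_b, omega_AB, o3)
  angles <- seq(0, pi / 2, length.out = n_rays + 2L)[-c(1L, n_rays + 2L)]
  pts <- lapply(angles, function(th) {
    da <- cos(th); db <- sin(th)
    f <- function(t) dfun(t * da, t * db)
    roots <- .bracket_roots(f, 1e-9, dose_limit, n = 300, tol = 1e-13)
    if (!length(roots)) return(NULL)
    t0 <- roots[1]
    if (abs(f(t0)) < d_tol) return(c(t0 * da, t0 * db, f(t0)))
    # polish in linear t until the defect is inside d_tol
    span <- 1e-9
    repeat {
      lo <- t0 * (1 - span); hi <- t0 * (1 + span)
      if (sign(f(lo)) != sign(f(hi)) || span > 0.5) break
      span <- span * 4
    }
    flo <- f(lo)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      if (abs(fm) < d_tol) return(c(mid * da, mid * db, fm))
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    c(t0 * da, t0 * db, f(t0))
  })
  pts <- do.call(rbind, pts)
  empty <- is.null(pts)
  out <- if (empty)
    data.frame(x_A = numeric(0), x_B = numeric(0), D = numeric(0))
  else
    data.frame(x_A = pts[, 1], x_B = pts[, 2], D = pts[, 3])
  if (!is.null(rescale_fraction) && !empty) {
    sa <- dose_for_saturation_fraction(rescale_fraction, x_P, w_a)
    sb <- dose_for_saturation_fraction(rescale_fraction, x_P, w_b)
    out$x_A_rescaled <- out$x_A / sa
    out$x_B_rescaled <- out$x_B / sb
  }
  structure(out, parameterization = "ray_angle",
            validity_domain = c(0, dose_limit), empty = empty,
            class = c("boundary_curve", "data.frame"))
}

#' @export
print.boundary_curve <- function(x, ...) {
  if (isTRUE(attr(x, "empty"))) {
    cat("Synergy-domain contour: empty (D < 0 over the searched domain)\n")
  } else {
    cat(sprintf("Synergy-domain contour: %d points (|D| at points <= %.3g)\n",
                nrow(x), max(abs(x$D))))
  }
  NextMethod()
}
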