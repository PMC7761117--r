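# analysis: sign analysis of whole-minus-sum integrated information --
# f(s), g(s1), the exact threshold s1min, weak-correlation asymptotics and
# positivity conditions.

#' Effective information as a function of the bipartition, f(s)
#'
#' Under spatially independent spiking, the effective information of a
#' bipartition depends on the bipartition only through the subsystem spike
#' probability `sA = s` (with `sB = s1 / s`):
#' `f(s) = I0((1-s1)ps, eps) - I0((1-s)ps, eps) - I0((1-s1/s)ps, eps)`,
#' defined on `s1 < s < 1`. It vanishes at both ends and is symmetric under
#' `s -> s1 / s`; its value at the symmetric point `s = sqrt(s1)` is
#' [g_fn()].
#'
#' @param s subsystem spike probability; vectorized; must satisfy
#'   `s1 < s < 1`.
#' @param s1 system-wide spontaneous spike probability, in (0, 1).
#' @param ps,eps dichotomous component parameters.
#' @return effective information in bits.
#' @export
f_curve <- function(s, s1, ps, eps) {
  stopifnot(s1 > 0, s1 < 1)
  if (any(s <= s1) || any(s >= 1)) {
    stop(sprintf("f(s) is defined on s1 < s < 1 (s1 = %g)", s1), call. = FALSE)
  }
  i0_safe((1 - s1) * ps, eps) - i0_safe((1 - s) * ps, eps) -
    i0_safe((1 - s1 / s) * ps, eps)
}

#' Symmetric-bipartition effective information g(s1)
#'
#' `g(s1) = I0((1-s1)ps, eps) - 2 I0((1-sqrt(s1))ps, eps)` -- the effective
#' information of the (possibly hypothetical) symmetric bipartition with
#' `sA = sB = sqrt(s1)`. `g(0) = -I0(ps, eps) < 0` and `g(s1 -> 1-) -> +0`,
#' so `g` changes sign on (0, 1); its unique root is the positivity
#' threshold [s1min_exact()]. For an N-node model with equal independent
#' nodes and even N, `g(s1)` equals [effective_information()] of the
#' symmetric N/2 | N/2 bipartition.
#'
#' @param s1 system-wide spontaneous spike probability, in `[0, 1)`;
#'   vectorized.
#' @param ps,eps dichotomous component parameters.
#' @return effective information in bits.
#' @export
g_fn <- function(s1, ps, eps) {
  stopifnot(all(s1 >= 0), all(s1 < 1))
  i0_safe((1 - s1) * ps, eps) - 2 * i0_safe((1 - sqrt(s1)) * ps, eps)
}

# Standard scan grid for the sign of g: 1e-3 steps across (0, 1), refined
# logarithmically near 0 because the root falls below 1e-3 when ps -> 1
# (s1min decreases monotonically in ps).
g_scan_grid <- function(step = 1e-3) {
  unique(sort(c(10^seq(-12, log10(step), length.out = 46),
                seq(step, 1 - step, by = step))))
}

#' Number of sign changes of g(s1) on the scan grid
#'
#' Scans `g(s1)` on a 1e-3-step grid (log-refined near 0) and counts sign
#' changes. Uniqueness of the sign change (value 1) underlies the
#' definition of the threshold [s1min_exact()]; it holds numerically across
#' the whole valid parameter region but is not proven.
#'
#' @param ps,eps dichotomous component parameters (`eps > 0`).
#' @param step scan step (default 1e-3).
#' @return integer count of sign changes.
#' @export
g_sign_changes <- function(ps, eps, step = 1e-3) {
  gv <- g_fn(g_scan_grid(step), ps, eps)
  sg <- sign(gv)
  sg <- sg[sg != 0]
  sum(diff(sg) != 0)
}

#' Exact positivity threshold s1min by root finding
#'
#' The unique root of `g(s1)` on (0, 1): spontaneous activity above
#' `s1min(ps, eps)` makes the symmetric-bipartition effective information
#' positive (a sufficient condition for positive whole-minus-sum integrated
#' information; also necessary when a symmetric bipartition exists).
#' A 1e-3-step scan first verifies that `g` changes sign exactly once
#' (uniqueness holds numerically over the whole parameter region but is not
#' proven); the root is then bracketed and solved to absolute tolerance
#' 1e-12.
#'
#' @param ps probability of the spiking state, in (0, 1).
#' @param eps time-correlation parameter, `> 0` (and `<= (1-ps)/ps`).
#' @param tol absolute tolerance of the root (default 1e-12).
#' @return the threshold `s1min` in (0, 1).
#' @export
#' @examples
#' s1min_exact(0.6, 0.1)
s1min_exact <- function(ps, eps, tol = 1e-12) {
  dichotomous_params(ps, eps)  # validates the pair
  if (eps <= 0) stop("s1min requires eps > 0 (eps = 0 is degenerate)", call. = FALSE)
  s1 <- g_scan_grid()
  gv <- g_fn(s1, ps, eps)
  sg <- sign(gv)
  idx <- which(sg != 0)
  changes <- which(diff(sg[idx]) != 0)
  if (length(changes) != 1L) {
    stop(sprintf("anomaly: g(s1) has %d sign changes on (0, 1) at ps = %g, eps = %g (expected exactly 1)",
                 length(changes), ps, eps), call. = FALSE)
  }
  lo <- s1[idx[changes]]
  hi <- s1[idx[changes + 1L]]
  stats::uniroot(function(x) g_fn(x, ps, eps), c(lo, hi), tol = tol)$root
}

#' Weak-correlation approximation of I0
#'
#' Leading-order expansion of `I0(ps, eps)` in the time-correlation
#' parameter: `I0 ~ eps^2 / (2 ln 2) * (ps / (1 - ps))^2`. The approximation
#' is applicable for weak correlations (`|eps| << 1`) within the bound
#' `ps < 1 / (1 + |eps|)`; the returned `valid` flag marks the hard
#' boundaries (strict inequalities `|eps| < 1` and `ps < 1/(1+|eps|)`) --
#' how much smaller than the bound "much less" must be is left to the user.
#'
#' @param ps first argument of `I0`, in (0, 1); vectorized.
#' @param eps time-correlation parameter; vectorized.
#' @return list with numeric `value` (bits) and logical `valid`.
#' @export
i0_approx <- function(ps, eps) {
  n <- max(length(ps), length(eps))
  ps <- rep_len(ps, n); eps <- rep_len(eps, n)
  stopifnot(all(ps > 0), all(ps < 1))
  list(value = eps^2 / (2 * log(2)) * (ps / (1 - ps))^2,
       valid = abs(eps) < 1 & ps < 1 / (1 + abs(eps)))
}

#' Asymptotic positivity threshold for weak time correlations
#'
#' In the weak-correlation limit the threshold depends on `ps` alone:
#' substituting the leading-order `I0` into `g(s1) = 0` gives the quadratic
#' `(sqrt(2)-1) ps u^2 - u + (sqrt(2)-1)(1 - ps) = 0` in `u = sqrt(s1)`,
#' whose unique root in (0, 1) yields
#' `s1min = [2 (1-ps)(sqrt(2)-1) / (1 + sqrt(1 - 4 ps (1-ps) (sqrt(2)-1)^2))]^2`
#' (written in cancellation-stable form). As `ps -> 0` the threshold tends
#' to its supremum `3 - 2 sqrt(2) ~ 0.17`, and it decreases monotonically
#' to 0 as `ps -> 1`.
#'
#' @param ps probability of the spiking state, in (0, 1); vectorized.
#' @return the asymptotic threshold `s1min` in (0, 1).
#' @export
#' @examples
#' s1min_asymptotic(c(1e-6, 0.5, 0.9))
s1min_asymptotic <- function(ps) {
  stopifnot(all(ps > 0), all(ps < 1))
  k <- sqrt(2) - 1
  disc <- 1 - 4 * ps * (1 - ps) * k^2
  u <- 2 * (1 - ps) * k / (1 + sqrt(disc))
  u^2
}

#' Threshold curve over a parameter grid
#'
#' Evaluates the positivity threshold on the product grid of `ps` and `eps`
#' values, tagging each row with the method used. Grid points violating the
#' validity constraint `eps <= (1 - ps) / ps` are dropped.
#'
#' @param ps_grid,eps_grid numeric vectors of parameter values.
#' @param method `"exact"` (root of g, default) or `"asymptotic"`
#'   (weak-correlation formula, independent of eps).
#' @param path optional CSV output path.
#' @return data frame with columns `ps`, `eps`, `s1min`, `method`.
#' @export
threshold_curve <- function(ps_grid, eps_grid, method = c("exact", "asymptotic"),
                            path = NULL) {
  method <- match.arg(method)
  grid <- expand.grid(ps = ps_grid, eps = eps_grid)
  grid <- grid[grid$eps <= (1 - grid$ps) / grid$ps + PROB_TOL & grid$eps > 0, ]
  s1min <- if (method == "exact") {
    mapply(s1min_exact, grid$ps, grid$eps)
  } else {
    s1min_asymptotic(grid$ps)
  }
  out <- data.frame(ps = grid$ps, eps = grid$eps, s1min = s1min, method = method)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}

#' Positivity verdict for whole-minus-sum integrated information
#'
#' Reports the sign analysis for a model. In *exact* mode (spatially
#' independent spiking) it enumerates the subsystem spike probabilities
#' `{sA}` over all bipartitions and reports: the necessary-and-sufficient
#' verdict `min f(sA) > 0`; the sufficient verdict `g(s1) > 0`; and whether
#' a symmetric bipartition (`sA = sqrt(s1)`) exists, which makes the two
#' equivalent. In *directional* mode (spatially correlated spiking) only
#' one-sided logic survives: with positive spatial correlation
#' (`s1 > sA sB`) a failed necessary condition still rules positivity out;
#' with negative correlation (`s1 < sA sB`) a passed sufficient condition
#' still rules it in.
#'
#' @param model an `"sb_model"`.
#' @param mode `"auto"` (detect independence of the spike table),
#'   `"exact"`, or `"directional"`.
#' @return an object of class `"sb_positivity"`: list with `mode`, `s1`,
#'   `g_value`, `min_f`, logical verdicts `necessary_sufficient` and
#'   `sufficient` (NA where the logic does not apply), `symmetric_exists`,
#'   `correlation` (`"none"`, `"positive"`, `"negative"`, `"mixed"`), and
#'   `degenerate`.
#' @export
positivity_conditions <- function(model, mode = c("auto", "exact", "directional")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "sb_model"))
  n <- model$spikes$n_nodes
  s1 <- model$spikes$s1
  ps <- model$dichotomous$ps; eps <- model$dichotomous$eps
  if (model$dichotomous$degenerate || s1 >= 1) {
    return(structure(list(mode = mode, s1 = s1, g_value = 0, min_f = 0,
                          necessary_sufficient = NA, sufficient = NA,
                          symmetric_exists = NA, correlation = "none",
                          degenerate = TRUE), class = "sb_positivity"))
  }
  bps <- bipartitions(n)
  sa <- vapply(bps, function(bp) subsystem_spike_table(model$spikes, bp$a)$s1, 0)
  sb <- vapply(bps, function(bp) subsystem_spike_table(model$spikes, bp$b)$s1, 0)
  prod_gap <- s1 - sa * sb
  indep <- all(abs(prod_gap) <= 1e-9)
  if (mode == "auto") mode <- if (indep) "exact" else "directional"
  g_val <- g_fn(s1, ps, eps)
  # effective information per bipartition (exact for any table)
  f_val <- vapply(seq_along(bps), function(i) {
    i0_safe((1 - s1) * ps, eps) - i0_safe((1 - sa[i]) * ps, eps) -
      i0_safe((1 - sb[i]) * ps, eps)
  }, 0)
  min_f <- min(f_val)
  sym <- any(abs(sa - sqrt(s1)) <= 1e-12 | abs(sb - sqrt(s1)) <= 1e-12)
  if (mode == "exact") {
    if (!indep) stop("exact mode requires spatially independent spiking", call. = FALSE)
    res <- list(necessary_sufficient = min_f > 0, sufficient = g_val > 0,
                correlation = "none")
  } else {
    corr <- if (all(prod_gap >= -1e-12)) "positive"
            else if (all(prod_gap <= 1e-12)) "negative" else "mixed"
    res <- list(
      # positive spatial correlation: phi_eff < f(sA), so only the
      # necessary side survives; negative: phi_eff > f(sA), only sufficient
      necessary_sufficient = if (corr == "positive" && min_f <= 0) FALSE else NA,
      sufficient = if (corr == "negative" && g_val > 0) TRUE else NA,
      correlation = corr)
  }
  structure(c(list(mode = mode, s1 = s1, g_value = g_val, min_f = min_f),
              res[c("necessary_sufficient", "sufficient")],
              list(symmetric_exists = sym, correlation = res$correlation,
                   degenerate = FALSE)),
            class = "sb_positivity")
}

#' @export
print.sb_positivity <- function(x, ...) {
  cat(sprintf("Positivity analysis (%s mode): s1 = %.4g\n", x$mode, x$s1))
  if (x$degenerate) {
    cat("  degenerate model (no time correlation): integrated information is 0\n")
    return(invisible(x))
  }
  cat(sprintf("  g(s1) = %.6g bits, min over bipartitions of phi_eff = %.6g bits\n",
              x$g_value, x$min_f))
  cat(sprintf("  necessary & sufficient (min phi_eff > 0): %s\n",
              format(x$necessary_sufficient)))
  cat(sprintf("  sufficient (g(s1) > 0): %s\n", format(x$sufficient)))
  cat(sprintf("  symmetric bipartition exists: %s; spatial correlation: %s\n",
              format(x$symmetric_exists), x$correlation))
  invisible(x)
}
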