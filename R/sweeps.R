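# cli_sweeps: figure-level parameter sweeps producing tidy CSV curve data.

default_s1_grid <- function() {
  # logarithmic near 0 to resolve the sign transition, linear near 1
  unique(sort(c(10^seq(-3, log10(0.2), length.out = 18),
                seq(0.25, 0.95, by = 0.05), 0.99)))
}

#' Run a figure-level parameter sweep
#'
#' Produces the curve data behind the standard views of the model:
#' \describe{
#'   \item{`"i0-vs-ps"`}{`I0(ps, eps)` and its weak-correlation
#'     approximation (with validity flag) versus `ps` from near 0 to
#'     `ps_max = 1/(1+eps)`, one curve per `eps`.}
#'   \item{`"f-vs-s"`}{`f(s)` on `s1 < s < 1`, one curve per `s1`, with the
#'     symmetric point `s = sqrt(s1)` marked.}
#'   \item{`"s1min-vs-ps"`}{exact threshold versus `ps` per `eps`, plus the
#'     asymptotic (eps-independent) curve.}
#'   \item{`"s1min-vs-eps"`}{exact threshold versus `eps` (up to
#'     `eps_max`) per `ps`, plus the asymptotic constant.}
#'   \item{`"phi-vs-s1"`}{whole-minus-sum and decoder-based effective
#'     information of the symmetric bipartition of an N-node equal-node
#'     model (`P = s1^(1/N)`), raw and divided by `eps^2`, one curve per
#'     `eps`, with the asymptotic threshold attached.}
#' }
#' Grid points outside the validity region are skipped with a message.
#'
#' @param kind sweep kind; see above.
#' @param ps,eps,s1 fixed parameters or parameter sets (vectors allowed
#'   where the sweep draws one curve per value).
#' @param grid grid of the abscissa variable; a sensible default is chosen
#'   per kind.
#' @param n_nodes system size for `"phi-vs-s1"` (even, default 6).
#' @param path optional CSV output path.
#' @return a data frame of curve data (one row per grid point), invisibly
#'   written to `path` if given.
#' @export
#' @examples
#' head(run_sweep("i0-vs-ps", eps = c(0.1, 0.5), grid = seq(0.05, 0.6, 0.05)))
run_sweep <- function(kind = c("i0-vs-ps", "f-vs-s", "s1min-vs-ps",
                               "s1min-vs-eps", "phi-vs-s1"),
                      ps = 0.6, eps = 0.1, s1 = NULL, grid = NULL,
                      n_nodes = 6L, path = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    "i0-vs-ps" = {
      rows <- lapply(eps, function(e) {
        g <- if (is.null(grid)) seq(0.01, 0.99, by = 0.01) else grid
        g <- g[g < 1 / (1 + e) - 1e-12 & g > 0]
        if (length(g) < 2) {
          message(sprintf("skipping eps = %g: fewer than 2 valid grid points", e))
          return(NULL)
        }
        ap <- i0_approx(g, e)
        data.frame(eps = e, ps = g, i0 = i0(g, e), i0_approx = ap$value,
                   approx_valid = ap$valid, ps_max = 1 / (1 + e))
      })
      do.call(rbind, rows)
    },
    "f-vs-s" = {
      s1v <- if (is.null(s1)) c(0.05, 0.02, 0.0131, 0.005) else s1
      rows <- lapply(s1v, function(s1i) {
        g <- if (is.null(grid)) {
          exp(seq(log(s1i) * 0.999, log(1 - 1e-4) , length.out = 200))
        } else grid
        g <- g[g > s1i & g < 1]
        if (length(g) < 2) {
          message(sprintf("skipping s1 = %g: fewer than 2 valid grid points", s1i))
          return(NULL)
        }
        g <- unique(sort(c(g, sqrt(s1i))))
        data.frame(ps = ps[1], eps = eps[1], s1 = s1i, s = g,
                   f = f_curve(g, s1i, ps[1], eps[1]),
                   symmetric_point = abs(g - sqrt(s1i)) < 1e-15)
      })
      do.call(rbind, rows)
    },
    "s1min-vs-ps" = {
      g <- if (is.null(grid)) seq(0.01, 0.99, by = 0.01) else grid
      rows <- lapply(eps, function(e) {
        gv <- g[g < 1 / (1 + e) + 1e-12]
        if (length(gv) < 2) {
          message(sprintf("skipping eps = %g: fewer than 2 valid grid points", e))
          return(NULL)
        }
        data.frame(eps = e, ps = gv,
                   s1min_exact = vapply(gv, s1min_exact, 0, eps = e),
                   s1min_asymptotic = s1min_asymptotic(gv))
      })
      do.call(rbind, rows)
    },
    "s1min-vs-eps" = {
      rows <- lapply(ps, function(p) {
        emax <- (1 - p) / p
        g <- if (is.null(grid)) seq(0.01, emax, length.out = 50) else grid
        g <- g[g > 0 & g <= emax + 1e-12]
        if (length(g) < 2) {
          message(sprintf("skipping ps = %g: fewer than 2 valid grid points", p))
          return(NULL)
        }
        data.frame(ps = p, eps = g,
                   s1min_exact = vapply(g, s1min_exact, 0, ps = p),
                   s1min_asymptotic = s1min_asymptotic(p))
      })
      do.call(rbind, rows)
    },
    "phi-vs-s1" = {
      stopifnot(n_nodes %% 2 == 0)
      g <- if (is.null(grid)) default_s1_grid() else grid
      g <- g[g > 0 & g < 1]
      half <- seq_len(n_nodes / 2)
      rows <- lapply(eps, function(e) {
        if (e > (1 - ps[1]) / ps[1] + 1e-12) {
          message(sprintf("skipping eps = %g: exceeds eps_max for ps = %g", e, ps[1]))
          return(NULL)
        }
        per_point <- lapply(g, function(s1i) {
          m <- spiking_bursting_model(
            independent_spike_table(rep(s1i^(1 / n_nodes), n_nodes)), ps[1], e)
          bp <- bipartition(half, n_nodes)
          pe <- effective_information(m, bp)
          st <- phi_star(m, bp)
          data.frame(eps = e, s1 = s1i, phi_eff = pe, phi_star = st$phi_star,
                     beta_opt = st$beta_opt,
                     phi_eff_per_eps2 = pe / e^2,
                     phi_star_per_eps2 = st$phi_star / e^2)
        })
        do.call(rbind, per_point)
      })
      out <- do.call(rbind, rows)
      out$ps <- ps[1]
      out$s1min_asymptotic <- s1min_asymptotic(ps[1])
      out
    })
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  out
}
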