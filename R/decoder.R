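# decoder_phi: decoder-based integrated information phi-star via mismatched
# decoding with scalar beta maximization.

#' Mismatched (factorized) decoding conditional
#'
#' The hypothetical decoder's conditional for a bipartition AB assumes the
#' two subsystems evolve independently:
#' `q(y | x) = p(yA | xA) * p(yB | xB)`.
#'
#' @param joint `2^N x 2^N` two-time joint probability matrix (rows = x).
#' @param bp an `"sb_bipartition"`.
#' @return `2^N x 2^N` matrix `q[x, y]`; every row sums to 1.
#' @export
mismatched_conditional <- function(joint, bp) {
  stopifnot(inherits(bp, "sb_bipartition"))
  n <- bp$n_nodes
  stopifnot(nrow(joint) == 2^n, ncol(joint) == 2^n)
  cond_side <- function(nodes) {
    idx <- word_project(nodes, n)
    m <- joint_marginal(joint, nodes, n)
    marg <- rowSums(m)
    zero <- marg <= 0
    if (any(zero)) {
      # a conditioning state that never occurs: only an error if some full
      # word mapping to it has positive probability (it cannot, since the
      # subsystem marginal dominates), so flag it explicitly
      stop(sprintf("zero-probability conditioning state for nodes {%s}: subsystem word(s) %s",
                   paste(nodes, collapse = ","),
                   paste(which(zero) - 1L, collapse = ", ")), call. = FALSE)
    }
    list(idx = idx + 1L, cond = m / marg)
  }
  a <- cond_side(bp$a)
  b <- cond_side(bp$b)
  q <- a$cond[a$idx, a$idx] * b$cond[b$idx, b$idx]
  dimnames(q) <- NULL
  q
}

# Mismatched-decoding objective at a single beta (log2 scale, in bits).
# Evaluated in the log domain: q(y|x)^beta underflows to 0 at moderate beta
# already for N = 6, so sum_x p(x) q(y|x)^beta is computed by a column-wise
# log-sum-exp over log p(x) + beta log q(y|x).
istar_objective <- function(beta, logq, logpx, py, s2) {
  if (beta == 0) return(0)  # q^0 = 1: both terms vanish identically
  m <- logpx + beta * logq
  mx <- apply(m, 2L, max)
  finite <- is.finite(mx)
  pos <- py > 0
  if (any(pos & !finite)) return(-Inf)
  logdenom <- mx
  logdenom[finite] <- mx[finite] +
    log(colSums(exp(sweep(m[, finite, drop = FALSE], 2L, mx[finite]))))
  -sum(py[pos] * logdenom[pos]) / log(2) + beta * s2
}

#' Mismatched-decoding information I* with beta maximization
#'
#' Maximizes over the scalar decoding exponent `beta >= 0` the objective
#' `- sum_y p(y) log2 sum_x p(x) q(y|x)^beta + beta sum_xy p(x,y) log2 q(y|x)`,
#' where `q` is the factorized conditional of the bipartition. The objective
#' is exactly 0 at `beta = 0`, so the maximum is non-negative. The search
#' evaluates a coarse grid (a log-spaced plus linear set of 64 points on
#' `[0, beta_max]`), refines the best bracket with `stats::optimize()`
#' (golden-section/Brent) to `tol`, and keeps the larger of the grid and
#' refined values.
#'
#' @param joint `2^N x 2^N` two-time joint probability matrix.
#' @param bp an `"sb_bipartition"`.
#' @param beta_max upper end of the search domain (default 100).
#' @param tol absolute tolerance on beta for the refinement (default 1e-8).
#' @return list with `i_star` (bits) and `beta_opt`.
#' @export
i_star <- function(joint, bp, beta_max = 100, tol = 1e-8) {
  q <- mismatched_conditional(joint, bp)
  joint <- unclass(joint)
  px <- rowSums(joint); py <- colSums(joint)
  supp <- joint > 0
  if (any(q[supp] <= 0)) {
    stop("structural mismatch: q(y|x) = 0 on a word pair with p(x, y) > 0; the objective diverges for beta > 0",
         call. = FALSE)
  }
  s2 <- sum(joint[supp] * log2(q[supp]))
  logq <- suppressWarnings(log(q))  # -Inf where q = 0 (off the support)
  logpx <- ifelse(px > 0, log(px), -Inf)
  grid <- unique(sort(c(0, 10^seq(-3, log10(beta_max), length.out = 40),
                        seq(0, beta_max, length.out = 24))))
  vals <- vapply(grid, istar_objective, numeric(1),
                 logq = logq, logpx = logpx, py = py, s2 = s2)
  k <- which.max(vals)
  lo <- grid[max(k - 1L, 1L)]
  hi <- grid[min(k + 1L, length(grid))]
  best <- list(maximum = grid[k], objective = vals[k])
  if (hi > lo) {
    opt <- stats::optimize(istar_objective, c(lo, hi), maximum = TRUE, tol = tol,
                           logq = logq, logpx = logpx, py = py, s2 = s2)
    if (opt$objective > best$objective) {
      best <- list(maximum = opt$maximum, objective = opt$objective)
    }
  }
  list(i_star = max(best$objective, 0), beta_opt = best$maximum)
}

#' Decoder-based integrated information phi-star
#'
#' `phi_star(AB) = Ixy - I*(AB)`: the loss of extractable information when
#' decoding is constrained to the bipartition's factorized conditional,
#' maximized over the decoding exponent beta. Non-negative by construction.
#'
#' @param model an `"sb_model"` (or a `2^N x 2^N` joint matrix).
#' @param bp an `"sb_bipartition"`.
#' @param ... passed to [i_star()] (`beta_max`, `tol`).
#' @return an object of class `"sb_phistar"`: list with `i_xy`, `i_star`,
#'   `beta_opt`, `phi_star` (all informations in bits) and `bipartition`.
#' @export
#' @examples
#' m <- spiking_bursting_model(independent_spike_table(rep(0.1^(1/2), 2)),
#'                             ps = 0.6, eps = 0.2)
#' phi_star(m, bipartition(1, 2))
phi_star <- function(model, bp, ...) {
  joint <- if (inherits(model, "sb_model")) two_time_joint(model) else model
  ixy <- mutual_information(joint)
  st <- i_star(joint, bp, ...)
  structure(list(i_xy = ixy, i_star = st$i_star, beta_opt = st$beta_opt,
                 phi_star = max(ixy - st$i_star, 0), bipartition = bp),
            class = "sb_phistar")
}

#' @export
print.sb_phistar <- function(x, ...) {
  cat(sprintf("Decoder-based information: Ixy = %.6g, I* = %.6g (beta = %.4g), phi* = %.6g bits\n",
              x$i_xy, x$i_star, x$beta_opt, x$phi_star))
  print(x$bipartition)
  invisible(x)
}
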