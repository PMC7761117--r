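# simulator: seeded realizations of the spiking-bursting process and
# plug-in (empirical) estimation of its probability tables and integrated
# information.
#
# The model constrains only the pair distribution at the analysis lag; the
# simulator realizes the minimal first-order Markov completion of the
# hidden spiking/bursting state whose one-step joint equals the model's
# 2x2 table. Empirical analysis therefore defaults to lag tau = 1; at
# larger lags the chain's effective correlation decays geometrically and
# does not reproduce the single-lag table.

#' Simulate a realization of the spiking-bursting process
#'
#' The hidden state V is a stationary two-state Markov chain started from
#' `(ps, pb)` with stay probabilities `pss / ps` (spiking) and `pbb / pb`
#' (bursting), so its one-step joint equals the model's two-time table.
#' While bursting the observed row is all-ones; while spiking it is drawn
#' from the spike table (per-node draws when the table is independent,
#' inverse-CDF over the `2^N` words otherwise). Identical
#' `(model, n_steps, seed)` give identical output.
#'
#' @param model an `"sb_model"`.
#' @param n_steps number of time bins T (`>= 2`).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return a `T x N` integer 0/1 matrix of class `"sb_realization"` with
#'   attributes `seed` and `burst` (the logical hidden bursting state,
#'   useful for diagnostics).
#' @export
#' @examples
#' m <- spiking_bursting_model(independent_spike_table(rep(0.3, 4)),
#'                             ps = 0.7, eps = 0.5)
#' x <- simulate_sb(m, 50, seed = 1)
simulate_sb <- function(model, n_steps, seed = NULL) {
  stopifnot(inherits(model, "sb_model"), n_steps >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_steps <- as.integer(n_steps)
  d <- dichotomous_joint(model$dichotomous)
  ps <- model$dichotomous$ps; pb <- model$dichotomous$pb
  stay_s <- d["s", "s"] / ps
  stay_b <- if (pb > 0) d["b", "b"] / pb else 0
  u <- stats::runif(n_steps)
  v <- logical(n_steps)  # TRUE = bursting
  v[1] <- u[1] < pb
  for (t in 2:n_steps) {
    v[t] <- if (v[t - 1]) u[t] < stay_b else u[t] >= stay_s
  }
  n <- model$spikes$n_nodes
  pv <- attr(model$spikes, "p_vec")
  if (!is.null(pv)) {
    x <- matrix(as.integer(stats::runif(n_steps * n) < rep(pv, each = n_steps)),
                n_steps, n)
  } else {
    w <- sample.int(2^n, n_steps, replace = TRUE, prob = model$spikes$probs) - 1L
    x <- word_bits(n)[w + 1L, , drop = FALSE]
  }
  x[v, ] <- 1L
  structure(x, seed = seed, burst = v, class = "sb_realization")
}

#' @export
print.sb_realization <- function(x, ...) {
  cat(sprintf("Spiking-bursting realization: %d time bins x %d nodes (%.1f%% bursting)\n",
              nrow(x), ncol(x), 100 * mean(attr(x, "burst"))))
  invisible(x)
}

#' Write / read a realization as delimited text
#'
#' The matrix is stored headerless (rows = time bins, columns = nodes,
#' values 0/1, space-delimited) with a JSON sidecar `<path>.json` recording
#' the seed, the analysis lag and the generating model configuration.
#'
#' @param x an `"sb_realization"` (or plain 0/1 matrix).
#' @param path output file path.
#' @param model optional `"sb_model"` to record in the sidecar.
#' @param tau analysis lag recorded in the sidecar (default 1).
#' @return `write_realization()`: `path`, invisibly. `read_realization()`:
#'   the integer matrix, with the sidecar (if present) in attribute `meta`.
#' @export
write_realization <- function(x, path, model = NULL, tau = 1L) {
  utils::write.table(unclass(x), path, row.names = FALSE, col.names = FALSE)
  meta <- list(seed = attr(x, "seed"), tau = tau, n_nodes = ncol(x),
               markov_completion = TRUE)
  if (!is.null(model)) {
    meta$model <- list(
      n_nodes = model$spikes$n_nodes,
      spike = if (!is.null(attr(model$spikes, "p_vec"))) {
        list(mode = "independent", p = attr(model$spikes, "p_vec"))
      } else {
        list(mode = "table", probs = model$spikes$probs)
      },
      dichotomous = list(ps = model$dichotomous$ps, eps = model$dichotomous$eps))
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_realization
#' @export
read_realization <- function(path) {
  x <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(x) <- NULL
  storage.mode(x) <- "integer"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) attr(x, "meta") <- jsonlite::fromJSON(sidecar)
  x
}

#' Plug-in estimates of the probability tables
#'
#' Empirical one-time word distribution over all T bins and the symmetrized
#' two-time word-pair distribution at lag `tau` (frequencies of
#' `(x_t, x_{t+tau})` over `t = 1 .. T - tau`, averaged with their
#' transposes so the estimate shares the exact table's exchange symmetry).
#'
#' @param x a `T x N` 0/1 matrix.
#' @param tau analysis lag (positive integer `< T`).
#' @return list with `one_time` (an `"sb_onetime"` vector) and `two_time`
#'   (an `"sb_twotime"` matrix).
#' @export
estimate_tables <- function(x, tau = 1L) {
  x <- unclass(x)
  n <- ncol(x); t_len <- nrow(x)
  stopifnot(t_len > tau, tau >= 1)
  k <- 2L^n
  w <- as.integer(x %*% 2^(seq_len(n) - 1L))
  one <- tabulate(w + 1L, nbins = k) / t_len
  w1 <- w[seq_len(t_len - tau)]
  w2 <- w[(tau + 1L):t_len]
  cnt <- matrix(0, k, k)
  pair_idx <- w1 * k + w2 + 1L  # flatten (row-major on w1)
  tab <- tabulate(pair_idx, nbins = k * k)
  cnt <- matrix(tab, k, k, byrow = TRUE)
  joint <- (cnt + t(cnt)) / (2 * (t_len - tau))
  list(one_time = structure(one, n_nodes = n, p1 = one[k], class = "sb_onetime"),
       two_time = structure(joint, n_nodes = n, p11 = joint[k, k],
                            class = "sb_twotime"))
}

#' Empirical integrated information by plug-in
#'
#' Feeds the plug-in two-time table into the definitional (table-based)
#' whole-minus-sum MIB search and decoder-based phi-star. As the series
#' length grows the results converge to the analytic values of the
#' generating model (at lag 1; see the note on the Markov completion).
#'
#' @param x a `T x N` 0/1 matrix.
#' @param tau analysis lag.
#' @param bp bipartition for phi-star; default is the estimated MIB.
#' @param ... passed to [i_star()].
#' @return list with `ii` (an `"sb_ii"`) and `phi_star` (an
#'   `"sb_phistar"`).
#' @export
empirical_ii <- function(x, tau = 1L, bp = NULL, ...) {
  tabs <- estimate_tables(x, tau)
  ii <- mib_phi_table(tabs$two_time)
  if (is.null(bp)) bp <- ii$mib
  ps <- phi_star(tabs$two_time, bp, ...)
  list(ii = ii, phi_star = ps)
}
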