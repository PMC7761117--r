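# model_core: parameterization of the spiking-bursting model and its exact
# probability tables.
#
# The model combines a system-wide two-state ("dichotomous") component V --
# "spiking" (spontaneous activity) with probability ps, "bursting" with
# probability pb = 1 - ps -- with a time-uncorrelated spiking distribution
# sx over N-bit words. While bursting, the observed word is all-ones; while
# spiking, it is drawn from sx. Time correlations of V at the analysis lag
# are parameterized by the scaling-invariant parameter eps via
# pss = ps^2 (1 + eps).

PROB_TOL <- 1e-12

#' Dichotomous (bursting) component parameters
#'
#' Validates and stores the two independent parameters of the system-wide
#' two-state component: the probability `ps` of the spontaneous ("spiking")
#' state and the scaling-invariant time-correlation parameter `eps`.
#' Derived quantities: `pb = 1 - ps`, the Pearson time-delayed correlation
#' `rho = eps * ps / pb`, and the admissible bounds `eps_max = pb / ps` and
#' `ps_max = 1 / (1 + eps)`.
#'
#' Only non-negative time correlations are supported (`eps >= 0`). The
#' non-negativity of the two-time probability table requires
#' `ps <= 1 / (1 + eps)` (equivalently `eps <= pb / ps`); parameter pairs on
#' the boundary are admitted (they give a perfectly persistent component).
#'
#' @param ps probability of the spiking state, strictly inside (0, 1).
#' @param eps scaling-invariant time-correlation parameter, `>= 0`.
#' @return an object of class `"sb_dichotomous"`: a list with elements
#'   `ps`, `pb`, `eps`, `rho`, `eps_max`, `ps_max` and a logical
#'   `degenerate` flag (`TRUE` when `eps == 0`, i.e. no time correlation).
#' @export
#' @examples
#' dichotomous_params(0.6, 0.5)
dichotomous_params <- function(ps, eps) {
  stopifnot(is.numeric(ps), length(ps) == 1L, is.numeric(eps), length(eps) == 1L)
  if (!(ps > 0 && ps < 1)) {
    stop("`ps` must lie strictly in (0, 1); the boundary cases are degenerate (always-spiking or always-bursting)",
         call. = FALSE)
  }
  if (eps < 0) {
    stop("constraint violated: eps >= 0 (negative time correlations are not supported)",
         call. = FALSE)
  }
  pb <- 1 - ps
  ps_max <- 1 / (1 + eps)
  eps_max <- pb / ps
  if (ps > ps_max + PROB_TOL) {
    stop(sprintf(paste0("constraint violated: ps <= 1/(1+eps) ",
                        "(equivalently eps <= pb/ps): ps = %g > ps_max = %g"),
                 ps, ps_max), call. = FALSE)
  }
  structure(
    list(ps = ps, pb = pb, eps = min(eps, eps_max), rho = eps * ps / pb,
         eps_max = eps_max, ps_max = ps_max, degenerate = (eps == 0)),
    class = "sb_dichotomous"
  )
}

#' @export
print.sb_dichotomous <- function(x, ...) {
  cat(sprintf("Dichotomous component: ps = %g, pb = %g, eps = %g (rho = %g, eps_max = %g)\n",
              x$ps, x$pb, x$eps, x$rho, x$eps_max))
  if (x$degenerate) cat("  [degenerate: eps = 0, no time correlation]\n")
  invisible(x)
}

#' Two-time joint table of the dichotomous component
#'
#' The 2x2 stationary joint probability table of the spiking/bursting state
#' observed at two times separated by the analysis lag:
#' `pss = ps^2 (1 + eps)`, `psb = pbs = ps pb - eps ps^2`,
#' `pbb = pb^2 + eps ps^2`.
#'
#' @param params an `"sb_dichotomous"` object (or `ps` if `eps` given too).
#' @param eps optional; when supplied, `params` is interpreted as `ps`.
#' @return a 2x2 numeric matrix with dimnames `c("s", "b")`, rows = earlier
#'   time, columns = later time. Cells sum to 1; row sums are `(ps, pb)`.
#' @export
#' @examples
#' dichotomous_joint(dichotomous_params(0.5, 1))  # diag(0.5, 0.5)
dichotomous_joint <- function(params, eps = NULL) {
  if (!inherits(params, "sb_dichotomous")) params <- dichotomous_params(params, eps)
  ps <- params$ps; pb <- params$pb; e <- params$eps
  psb <- clamp_prob(ps * pb - e * ps^2, what = "psb")
  m <- matrix(c(ps^2 * (1 + e), psb, psb, pb^2 + e * ps^2), 2L, 2L,
              dimnames = list(c("s", "b"), c("s", "b")))
  m
}

#' Convert between the Pearson correlation rho and the effective parameter eps
#'
#' The time-delayed Pearson correlation coefficient `rho` of the dichotomous
#' component and the scaling-invariant parameter `eps` are proportional:
#' `eps = rho * pb / ps = rho * eps_max`.
#'
#' @param ps probability of the spiking state, in (0, 1).
#' @param rho,eps the value to convert.
#' @return the converted parameter (numeric).
#' @export
#' @examples
#' rho_to_eps(0.6, 1)        # eps_max = 2/3
#' eps_to_rho(0.6, rho_to_eps(0.6, 0.25))
rho_to_eps <- function(ps, rho) {
  stopifnot(ps > 0, ps < 1)
  rho * (1 - ps) / ps
}

#' @rdname rho_to_eps
#' @export
eps_to_rho <- function(ps, eps) {
  stopifnot(ps > 0, ps < 1)
  eps * ps / (1 - ps)
}

#' Spontaneous spiking distribution over N-bit words
#'
#' Constructs the one-time probability table `sx` of the time-uncorrelated
#' spiking component from a full vector of `2^N` word probabilities.
#' The table is validated (non-negative, sums to 1) and renormalized exactly.
#'
#' @param probs numeric vector of length `2^n_nodes`, indexed by word + 1
#'   (see [word_bits()] for the encoding).
#' @param n_nodes number of nodes; defaults to `log2(length(probs))`.
#' @return an object of class `"sb_spike_table"`: a list with `n_nodes`,
#'   `probs`, and `s1` (probability of the all-ones word, i.e. of a
#'   system-wide simultaneous spike).
#' @export
spike_table <- function(probs, n_nodes = round(log2(length(probs)))) {
  stopifnot(is.numeric(probs), length(probs) == 2^n_nodes, n_nodes >= 1)
  probs <- clamp_prob(unname(probs), tol = 1e-9, what = "spike table")
  s <- sum(probs)
  if (abs(s - 1) > 1e-8) {
    stop(sprintf("spike table must sum to 1 (got %.10g)", s), call. = FALSE)
  }
  probs <- probs / s
  structure(list(n_nodes = as.integer(n_nodes), probs = probs,
                 s1 = probs[length(probs)]),
            class = "sb_spike_table")
}

#' @export
print.sb_spike_table <- function(x, ...) {
  cat(sprintf("Spike table over %d nodes (%d words), s1 = %g\n",
              x$n_nodes, length(x$probs), x$s1))
  if (!is.null(attr(x, "p_vec"))) {
    cat("  independent per-node spike probabilities:",
        paste(signif(attr(x, "p_vec"), 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Spike table for independent node activity
#'
#' Builds the word distribution when nodes spike independently:
#' `sx = prod_i (Pi if node i active in x else 1 - Pi)`. For equal
#' probabilities `P` this is `P^m(x) (1 - P)^(N - m(x))` with `m(x)` the
#' number of ones, and `s1 = prod_i Pi`; to hit a target system-wide spike
#' probability `s1` with `N` equal nodes use `P = s1^(1/N)`.
#'
#' @param p_vec per-node spike probabilities, each in `[0, 1]`.
#' @return an `"sb_spike_table"` with attribute `p_vec` recording the
#'   independent parameterization.
#' @export
#' @examples
#' independent_spike_table(rep(0.5, 2))        # uniform over 4 words
#' independent_spike_table(rep(0.1^(1/6), 6))  # N = 6, s1 = 0.1
independent_spike_table <- function(p_vec) {
  stopifnot(is.numeric(p_vec), length(p_vec) >= 1, all(p_vec >= 0), all(p_vec <= 1))
  v <- 1
  for (p in p_vec) v <- as.vector(outer(v, c(1 - p, p)))
  st <- spike_table(v, length(p_vec))
  attr(st, "p_vec") <- as.numeric(p_vec)
  st
}

#' Marginal spike table of a subsystem
#'
#' Sums the word distribution over the excluded nodes, giving the spiking
#' distribution of the subsystem. For independent spiking the subsystem
#' all-ones probabilities of a bipartition (A, B) satisfy `sA * sB = s1`.
#'
#' @param table an `"sb_spike_table"`.
#' @param nodes non-empty integer vector of node indices (1-based) to keep.
#' @return an `"sb_spike_table"` over `length(nodes)` nodes.
#' @export
subsystem_spike_table <- function(table, nodes) {
  stopifnot(inherits(table, "sb_spike_table"))
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) == 0L) stop("`nodes` must be a non-empty subset", call. = FALSE)
  if (any(nodes < 1L) || any(nodes > table$n_nodes)) {
    stop("`nodes` out of range", call. = FALSE)
  }
  if (length(nodes) == table$n_nodes) return(table)
  idx <- word_project(nodes, table$n_nodes)
  probs <- as.vector(rowsum(table$probs, idx))
  st <- spike_table(probs, length(nodes))
  pv <- attr(table, "p_vec")
  if (!is.null(pv)) attr(st, "p_vec") <- pv[nodes]
  st
}

#' Spiking-bursting model
#'
#' Combines a spontaneous spiking distribution with a dichotomous bursting
#' component into the full model M = {V, S}.
#'
#' @param spikes an `"sb_spike_table"`.
#' @param ps probability of the spiking state, or an `"sb_dichotomous"`
#'   object (in which case `eps` is ignored).
#' @param eps time-correlation parameter.
#' @return an object of class `"sb_model"`: list with `spikes` and
#'   `dichotomous`.
#' @export
#' @examples
#' m <- spiking_bursting_model(independent_spike_table(rep(0.3, 3)), ps = 0.7, eps = 0.1)
#' m
spiking_bursting_model <- function(spikes, ps, eps = NULL) {
  stopifnot(inherits(spikes, "sb_spike_table"))
  dich <- if (inherits(ps, "sb_dichotomous")) ps else dichotomous_params(ps, eps)
  structure(list(spikes = spikes, dichotomous = dich), class = "sb_model")
}

#' @export
print.sb_model <- function(x, ...) {
  cat("Spiking-bursting model\n")
  print(x$spikes)
  print(x$dichotomous)
  invisible(x)
}

#' One-time state distribution of the model
#'
#' The stationary distribution over the `2^N` observed words:
#' `p(x != 1) = ps * sx` and `p(x = 1) = p1 = ps * s1 + pb` (the all-ones
#' word arises from a burst or a system-wide simultaneous spike).
#'
#' @param model an `"sb_model"`.
#' @return numeric vector of length `2^N` of class `"sb_onetime"`, with
#'   attributes `n_nodes` and `p1`.
#' @export
one_time_dist <- function(model) {
  stopifnot(inherits(model, "sb_model"))
  ps <- model$dichotomous$ps
  p <- ps * model$spikes$probs
  k <- length(p)
  p[k] <- ps * model$spikes$s1 + model$dichotomous$pb
  structure(p, n_nodes = model$spikes$n_nodes, p1 = p[k], class = "sb_onetime")
}

#' Two-time joint distribution of the model
#'
#' The stationary joint distribution of the word pair (x, y) observed at the
#' two analysis times: `p(x != 1, y != 1) = pss sx sy`,
#' `p(x != 1, y = 1) = pi sx` (and symmetrically), `p(1, 1) = p11`, with
#' `pi = pss s1 + psb` and `p11 = pss s1^2 + 2 psb s1 + pbb`.
#'
#' @param model an `"sb_model"`.
#' @return a `2^N x 2^N` numeric matrix of class `"sb_twotime"` (rows = x,
#'   columns = y) with attributes `n_nodes`, `pi` and `p11`. The matrix is
#'   symmetric and both marginals equal [one_time_dist()].
#' @export
two_time_joint <- function(model) {
  stopifnot(inherits(model, "sb_model"))
  d <- dichotomous_joint(model$dichotomous)
  pss <- d["s", "s"]; psb <- d["s", "b"]; pbb <- d["b", "b"]
  s <- model$spikes$probs
  s1 <- model$spikes$s1
  k <- length(s)
  pi_ <- pss * s1 + psb
  p11 <- pss * s1^2 + 2 * psb * s1 + pbb
  j <- pss * outer(s, s)
  j[k, ] <- pi_ * s
  j[, k] <- pi_ * s
  j[k, k] <- p11
  structure(j, n_nodes = model$spikes$n_nodes, pi = pi_, p11 = p11,
            class = "sb_twotime")
}

#' Admissible scaling range of the model
#'
#' The model is redundant: bursts and system-wide simultaneous spikes are
#' indistinguishable in realizations, so a one-parameter family of models
#' generates the same stochastic process. [scaling_transform()] with scaling
#' parameter `alpha` relabels a fraction of all-ones words between the two
#' components; this function returns the interval of `alpha` for which all
#' transformed probabilities remain valid.
#'
#' @param model an `"sb_model"`.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
admissible_alpha <- function(model) {
  stopifnot(inherits(model, "sb_model"))
  s <- model$spikes$probs
  k <- length(s)
  s_other <- if (k > 1L) s[-k] else numeric(0)
  lower <- max(1 - model$spikes$s1, if (length(s_other)) max(s_other) else 0)
  upper <- model$dichotomous$ps_max / model$dichotomous$ps
  c(lower = max(lower, .Machine$double.eps), upper = upper)
}

#' Invariance scaling of the model parameters
#'
#' Applies the one-parameter transformation that relabels system-wide
#' simultaneous spikes as (time-uncorrelated) bursts without changing the
#' observable process: `sx' = sx / alpha` for non-all-ones words,
#' `1 - s1' = (1 - s1) / alpha`, `ps' = alpha * ps`, `pss' = alpha^2 * pss`.
#' The effective correlation parameter `eps` is invariant, and the one- and
#' two-time distributions of the transformed model coincide with the
#' original's.
#'
#' @param model an `"sb_model"`.
#' @param alpha positive scaling parameter within [admissible_alpha()].
#' @return the transformed `"sb_model"`.
#' @export
scaling_transform <- function(model, alpha) {
  stopifnot(inherits(model, "sb_model"), is.numeric(alpha), length(alpha) == 1L,
            alpha > 0)
  rng <- admissible_alpha(model)
  if (alpha < rng[1] - PROB_TOL || alpha > rng[2] + PROB_TOL) {
    stop(sprintf("alpha = %g outside the admissible interval [%.6g, %.6g]",
                 alpha, rng[1], rng[2]), call. = FALSE)
  }
  s <- model$spikes$probs
  k <- length(s)
  s_new <- s / alpha
  s_new[k] <- 1 - (1 - model$spikes$s1) / alpha
  s_new <- clamp_prob(s_new, what = "scaled spike table")
  st <- spike_table(s_new, model$spikes$n_nodes)
  spiking_bursting_model(st, alpha * model$dichotomous$ps, model$dichotomous$eps)
}

#' Read a model from a JSON or YAML config file
#'
#' Config layout:
#' \preformatted{
#' {"n_nodes": 3,
#'  "spike": {"mode": "independent", "p": [0.3, 0.3, 0.3]},
#'  "dichotomous": {"ps": 0.7, "eps": 0.1}}
#' }
#' `spike$mode` may also be `"table"` with `probs` a vector of `2^N` word
#' probabilities (word order as in [word_bits()]). The dichotomous block
#' accepts either `{ps, eps}` or `{pb, rho}`.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return an `"sb_model"`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$spike) || is.null(cfg$dichotomous)) {
    stop("config must contain `spike` and `dichotomous` blocks", call. = FALSE)
  }
  st <- switch(tolower(cfg$spike$mode %||% "independent"),
    independent = independent_spike_table(as.numeric(cfg$spike$p)),
    table = spike_table(as.numeric(cfg$spike$probs),
                        cfg$n_nodes %||% round(log2(length(cfg$spike$probs)))),
    stop("spike$mode must be 'independent' or 'table'", call. = FALSE)
  )
  d <- cfg$dichotomous
  if (!is.null(d$ps)) {
    ps <- as.numeric(d$ps)
  } else if (!is.null(d$pb)) {
    ps <- 1 - as.numeric(d$pb)
  } else stop("dichotomous block needs `ps` or `pb`", call. = FALSE)
  eps <- if (!is.null(d$eps)) as.numeric(d$eps) else rho_to_eps(ps, as.numeric(d$rho))
  spiking_bursting_model(st, ps, eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a probability table as CSV
#'
#' Writes a two-column CSV (`word`, `probability`) where `word` is the
#' binary string label of each state (node 1 leftmost).
#'
#' @param x an `"sb_spike_table"`, `"sb_onetime"` vector, or plain numeric
#'   vector of length `2^N`.
#' @param path output file path.
#' @return the data frame written, invisibly.
#' @export
write_prob_csv <- function(x, path) {
  p <- if (inherits(x, "sb_spike_table")) x$probs else as.numeric(x)
  n <- round(log2(length(p)))
  df <- data.frame(word = word_labels(n), probability = p)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
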