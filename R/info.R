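# info_measures: entropy, mutual information, closed-form I0 and Ixy,
# effective information over bipartitions, MIB search and whole-minus-sum
# integrated information.

# {q} = -q log2 q with {0} = 0 (elementwise).
qfun <- function(q) {
  out <- numeric(length(q))
  pos <- q > 0
  out[pos] <- -q[pos] * log2(q[pos])
  out
}

#' Shannon entropy of a discrete distribution (bits)
#'
#' Base-2 entropy with the convention `0 * log2(0) = 0`.
#'
#' @param p numeric vector (or matrix) of probabilities summing to 1.
#' @return entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # 1 bit
shannon_entropy <- function(p) sum(qfun(as.numeric(p)))

#' Mutual information of a two-variable joint table (bits)
#'
#' `I = H(x) + H(y) - H(x, y)` from the row/column marginals of the joint
#' matrix. Tiny negative round-off is clamped to 0.
#'
#' @param joint numeric matrix `p(x, y)`.
#' @return mutual information in bits (`>= 0`).
#' @export
#' @examples
#' mutual_information(diag(2) / 2)  # 1 bit
mutual_information <- function(joint) {
  joint <- unclass(joint)
  mi <- shannon_entropy(rowSums(joint)) + shannon_entropy(colSums(joint)) -
    shannon_entropy(joint)
  max(mi, 0)
}

#' Closed-form mutual information of the dichotomous component
#'
#' `I0(ps, eps)` is the time-delayed mutual information of the two-state
#' spiking/bursting component alone:
#' `I0 = 2({ps} + {pb}) - ({pss} + 2 {psb} + {pbb})` with `{q} = -q log2 q`
#' and the two-time cells expressed through `ps` and `eps`. It is the
#' universal function through which the whole model's time-delayed mutual
#' information and effective information are expressed (their first argument
#' being a rescaled `ps`).
#'
#' @param ps first argument; must lie strictly in (0, 1). Vectorized.
#' @param eps time-correlation parameter; the pair must satisfy
#'   `eps <= (1 - ps) / ps`. Vectorized (recycled against `ps`).
#' @return mutual information in bits.
#' @export
#' @examples
#' i0(0.5, 1)    # 1 bit: perfectly persistent symmetric component
#' i0(0.7, 0)    # 0: no time correlation
i0 <- function(ps, eps) {
  n <- max(length(ps), length(eps))
  ps <- rep_len(ps, n); eps <- rep_len(eps, n)
  if (any(ps <= 0 | ps >= 1)) {
    stop("i0 is defined only for first argument strictly in (0, 1)", call. = FALSE)
  }
  if (any(eps < 0)) stop("i0 requires eps >= 0", call. = FALSE)
  pb <- 1 - ps
  r <- eps * ps / pb
  if (any(r > 1 + PROB_TOL)) {
    stop("invalid (ps, eps): eps exceeds (1 - ps)/ps, psb would be negative",
         call. = FALSE)
  }
  r <- pmin(r, 1)
  # Rearranged as sum_ij p_ij log2(p_ij / (p_i p_j)): algebraically equal to
  # the entropy-difference form but free of the catastrophic cancellation
  # that form suffers when the first argument is tiny (I0 = O(eps^2 ps^2)
  # while the individual entropies are O(ps log ps)).
  mid <- ifelse(r < 1, (1 - r) * log1p(-r), 0)  # psb = 0 contributes 0 bits
  (ps^2 * (1 + eps) * log1p(eps) +
     2 * ps * pb * mid +
     (pb^2 + eps * ps^2) * log1p(eps * (ps / pb)^2)) / log(2)
}

# I0 extended by continuity to the degenerate boundary: 0 when the first
# argument hits 0 or 1 or when eps = 0. Used by all closed forms so that
# degenerate submodels contribute 0 bits without 0*log(0) evaluations.
i0_safe <- function(p, eps) {
  n <- max(length(p), length(eps))
  p <- rep_len(p, n); eps <- rep_len(eps, n)
  out <- numeric(n)
  ok <- p > 0 & p < 1 & eps > 0
  if (any(ok)) out[ok] <- i0(p[ok], eps[ok])
  out
}

#' Time-delayed mutual information of the whole system (closed form)
#'
#' Mutual information between the system words at the two analysis times.
#' Two algebraically equivalent routes are provided: `"scaled"` evaluates
#' `I0((1 - s1) ps, eps)` (the invariance scaling absorbs s1 into ps);
#' `"expanded"` evaluates the five-term expression
#' `2 (1 - s1) {ps} + 2 {p1} - (1 - s1)^2 {pss} - 2 (1 - s1) {pi} - {p11}`.
#' Both equal the generic mutual information of [two_time_joint()] for any
#' spike table with the given `s1`. Degenerate parameter settings
#' (`s1 = 1` or `eps = 0`) give 0.
#'
#' @param s1 probability of a system-wide simultaneous spike, in `[0, 1]`.
#' @param ps,eps dichotomous component parameters.
#' @param method `"scaled"` (default) or `"expanded"`.
#' @return mutual information in bits.
#' @export
i_xy <- function(s1, ps, eps, method = c("scaled", "expanded")) {
  method <- match.arg(method)
  stopifnot(all(s1 >= 0), all(s1 <= 1))
  if (method == "scaled") {
    return(i0_safe((1 - s1) * ps, eps))
  }
  n <- max(length(s1), length(ps), length(eps))
  s1 <- rep_len(s1, n); ps <- rep_len(ps, n); eps <- rep_len(eps, n)
  pb <- 1 - ps
  pss <- ps^2 * (1 + eps)
  psb <- pmax(ps * pb - eps * ps^2, 0)
  pbb <- pb^2 + eps * ps^2
  p1 <- ps * s1 + pb
  pi_ <- pss * s1 + psb
  p11 <- pss * s1^2 + 2 * psb * s1 + pbb
  out <- 2 * (1 - s1) * qfun(ps) + 2 * qfun(p1) -
    (1 - s1)^2 * qfun(pss) - 2 * (1 - s1) * qfun(pi_) - qfun(p11)
  out[s1 == 1 | eps == 0] <- 0
  pmax(out, 0)
}

#' Bipartition of the system nodes
#'
#' A split of the N nodes into two disjoint non-empty subsystems A and B.
#' The canonical form keeps node 1 in A; constructing with node 1 in the
#' second argument swaps the sides.
#'
#' @param a integer vector of node indices forming subsystem A.
#' @param n_nodes total number of nodes.
#' @return an object of class `"sb_bipartition"`: list with sorted integer
#'   vectors `a`, `b` and `n_nodes`.
#' @export
#' @examples
#' bipartition(c(1, 3), 4)
bipartition <- function(a, n_nodes) {
  a <- sort(unique(as.integer(a)))
  stopifnot(length(a) >= 1L, all(a >= 1L), all(a <= n_nodes))
  b <- setdiff(seq_len(n_nodes), a)
  if (length(b) == 0L) stop("subsystem B must be non-empty", call. = FALSE)
  if (!(1L %in% a)) { tmp <- a; a <- b; b <- tmp }
  structure(list(a = a, b = b, n_nodes = as.integer(n_nodes)),
            class = "sb_bipartition")
}

#' @export
print.sb_bipartition <- function(x, ...) {
  cat(sprintf("Bipartition of %d nodes: A = {%s} | B = {%s}\n", x$n_nodes,
              paste(x$a, collapse = ","), paste(x$b, collapse = ",")))
  invisible(x)
}

#' Enumerate all canonical bipartitions
#'
#' All `2^(N-1) - 1` bipartitions with node 1 in A, in increasing order of
#' the A bit-mask (used as the deterministic tie-break order of the MIB
#' search).
#'
#' @param n_nodes number of nodes (`>= 2`).
#' @return a list of `"sb_bipartition"` objects.
#' @export
bipartitions <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  masks <- seq(1L, 2L^n_nodes - 2L, by = 2L)  # node 1 (bit 0) always set
  lapply(masks, function(m) {
    bipartition(which(bitwAnd(m, 2L^(seq_len(n_nodes) - 1L)) > 0L), n_nodes)
  })
}

# Marginal joint table of a subsystem from a full two-time joint.
joint_marginal <- function(joint, nodes, n_nodes) {
  idx <- word_project(nodes, n_nodes)
  m <- rowsum(unclass(joint), idx, reorder = TRUE)
  t(rowsum(t(m), idx, reorder = TRUE))
}

#' Effective information of a bipartition (closed form)
#'
#' Whole-minus-sum effective information
#' `phi_eff(AB) = Ixy - I(xA; yA) - I(xB; yB)`, evaluated through the closed
#' form `I0((1 - s1) ps, eps) - I0((1 - sA) ps, eps) - I0((1 - sB) ps, eps)`
#' where `sA`, `sB` are the subsystem-wide simultaneous-spike probabilities
#' of the marginal spike tables. Valid for arbitrary (not necessarily
#' independent) spiking tables.
#'
#' @param model an `"sb_model"`.
#' @param bp an `"sb_bipartition"`.
#' @return effective information in bits (may be negative).
#' @export
effective_information <- function(model, bp) {
  stopifnot(inherits(model, "sb_model"), inherits(bp, "sb_bipartition"))
  ps <- model$dichotomous$ps; eps <- model$dichotomous$eps
  s1 <- model$spikes$s1
  sa <- subsystem_spike_table(model$spikes, bp$a)$s1
  sb <- subsystem_spike_table(model$spikes, bp$b)$s1
  i0_safe((1 - s1) * ps, eps) - i0_safe((1 - sa) * ps, eps) -
    i0_safe((1 - sb) * ps, eps)
}

#' Effective information from a generic two-time joint table
#'
#' Definitional route: generic mutual information of the full joint minus
#' the mutual informations of the two subsystem marginal joints. Used for
#' empirical (plug-in) tables and as the independent cross-check of
#' [effective_information()].
#'
#' @param joint `2^N x 2^N` joint probability matrix (rows = x, cols = y).
#' @param bp an `"sb_bipartition"`.
#' @return effective information in bits.
#' @export
effective_information_table <- function(joint, bp) {
  n <- bp$n_nodes
  stopifnot(nrow(joint) == 2^n)
  # subsystem MIs are non-negative; do not clamp the difference
  mutual_information(joint) -
    mutual_information(joint_marginal(joint, bp$a, n)) -
    mutual_information(joint_marginal(joint, bp$b, n))
}

ii_result <- function(i_xy, tab, bps, degenerate) {
  finite <- is.finite(tab$normalized)
  if (!any(finite)) {
    mib_idx <- NA_integer_
    phi <- 0
    degenerate <- TRUE
  } else {
    mib_idx <- which(finite)[which.min(tab$normalized[finite])]
    phi <- tab$phi_eff[mib_idx]
  }
  structure(list(i_xy = i_xy, table = tab,
                 mib = if (is.na(mib_idx)) NULL else bps[[mib_idx]],
                 mib_index = mib_idx, phi = phi, degenerate = degenerate),
            class = "sb_ii")
}

#' Whole-minus-sum integrated information via exhaustive MIB search
#'
#' Enumerates all canonical bipartitions, computes per-bipartition effective
#' information and subsystem entropies, selects the minimum information
#' bipartition (MIB) minimizing `phi_eff / min(H(xA), H(xB))`, and reports
#' `Phi = phi_eff(MIB)`. Bipartitions whose normalizing entropy is zero are
#' excluded from the argmin (a zero-entropy subsystem carries no
#' information); ties are broken by the smallest canonical A mask. If every
#' bipartition is excluded, or the model has no time correlation, `Phi = 0`
#' with `degenerate = TRUE`.
#'
#' @param model an `"sb_model"` with `N >= 2` nodes.
#' @param cap maximum N for exhaustive enumeration (default 12).
#' @return an object of class `"sb_ii"`: list with `i_xy`, a per-bipartition
#'   data frame `table` (`mask_a`, `nodes_a`, `size_a`, `phi_eff`, `h_a`,
#'   `h_b`, `normalized`), the `mib` bipartition, `phi` (bits) and a
#'   `degenerate` flag. `as.data.frame()` extracts the table.
#' @export
mib_phi <- function(model, cap = 12L) {
  stopifnot(inherits(model, "sb_model"))
  n <- model$spikes$n_nodes
  if (n < 2) stop("MIB search needs at least 2 nodes", call. = FALSE)
  if (n > cap) {
    stop(sprintf("N = %d exceeds the exhaustive-enumeration cap (%d)", n, cap),
         call. = FALSE)
  }
  bps <- bipartitions(n)
  dich <- model$dichotomous
  rows <- lapply(bps, function(bp) {
    sub_a <- spiking_bursting_model(subsystem_spike_table(model$spikes, bp$a), dich)
    sub_b <- spiking_bursting_model(subsystem_spike_table(model$spikes, bp$b), dich)
    h_a <- shannon_entropy(one_time_dist(sub_a))
    h_b <- shannon_entropy(one_time_dist(sub_b))
    phi_eff <- effective_information(model, bp)
    data.frame(mask_a = sum(2^(bp$a - 1L)),
               nodes_a = paste(bp$a, collapse = "+"),
               size_a = length(bp$a), phi_eff = phi_eff, h_a = h_a, h_b = h_b,
               normalized = if (min(h_a, h_b) > 0) phi_eff / min(h_a, h_b) else Inf)
  })
  tab <- do.call(rbind, rows)
  ii_result(i_xy(model$spikes$s1, dich$ps, dich$eps), tab, bps, dich$degenerate)
}

#' Whole-minus-sum integrated information from a generic joint table
#'
#' Same search as [mib_phi()] but computed definitionally from an arbitrary
#' two-time joint table (e.g. a plug-in estimate from data), with subsystem
#' entropies taken from the marginals of the table's row marginal.
#'
#' @param joint `2^N x 2^N` joint probability matrix.
#' @param cap maximum N for exhaustive enumeration.
#' @return an `"sb_ii"` object (see [mib_phi()]).
#' @export
mib_phi_table <- function(joint, cap = 12L) {
  n <- round(log2(nrow(joint)))
  if (n < 2) stop("MIB search needs at least 2 nodes", call. = FALSE)
  if (n > cap) stop("N exceeds the exhaustive-enumeration cap", call. = FALSE)
  bps <- bipartitions(n)
  px <- rowSums(unclass(joint))
  rows <- lapply(bps, function(bp) {
    h_a <- shannon_entropy(rowsum(px, word_project(bp$a, n)))
    h_b <- shannon_entropy(rowsum(px, word_project(bp$b, n)))
    phi_eff <- effective_information_table(joint, bp)
    data.frame(mask_a = sum(2^(bp$a - 1L)),
               nodes_a = paste(bp$a, collapse = "+"),
               size_a = length(bp$a), phi_eff = phi_eff, h_a = h_a, h_b = h_b,
               normalized = if (min(h_a, h_b) > 0) phi_eff / min(h_a, h_b) else Inf)
  })
  tab <- do.call(rbind, rows)
  ii_result(mutual_information(joint), tab, bps, degenerate = FALSE)
}

#' @export
print.sb_ii <- function(x, ...) {
  cat(sprintf("Whole-minus-sum integrated information over %d bipartitions\n",
              nrow(x$table)))
  cat(sprintf("  Ixy = %.6g bits, Phi = %.6g bits%s\n", x$i_xy, x$phi,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$mib)) {
    cat(sprintf("  MIB: A = {%s}\n", paste(x$mib$a, collapse = ",")))
  }
  invisible(x)
}

#' @export
as.data.frame.sb_ii <- function(x, ...) x$table

#' Serialize an integrated-information result
#'
#' `write_ii_csv()` writes the per-bipartition table as CSV;
#' `ii_to_json()` returns (or writes) a JSON document with the summary and
#' the per-bipartition records.
#'
#' @param x an `"sb_ii"` object.
#' @param path output file path (optional for JSON).
#' @return `write_ii_csv()`: the data frame, invisibly. `ii_to_json()`: the
#'   JSON string, invisibly if written to a file.
#' @export
write_ii_csv <- function(x, path) {
  stopifnot(inherits(x, "sb_ii"))
  utils::write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  invisible(x$table)
}

#' @rdname write_ii_csv
#' @export
ii_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "sb_ii"))
  doc <- list(i_xy = x$i_xy, phi = x$phi, degenerate = x$degenerate,
              mib = if (!is.null(x$mib)) list(a = x$mib$a, b = x$mib$b),
              bipartitions = x$table)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
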