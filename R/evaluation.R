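#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same node set,
#' under the permutation (hypergeometric) null model. Symmetric and
#' invariant to relabelling either argument; 1 for identical partitions,
#' approximately 0 for independent ones. Degenerate pairs where the
#' correction term equals the maximum (e.g. both partitions trivial) return
#' 1 when the two set partitions coincide and 0 otherwise.
#'
#' @param z_a,z_b label vectors of equal length.
#' @return a scalar in [-1, 1].
#' @export
ari <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) stop("partitions must have equal length")
  za <- compress_labels(as.integer(factor(z_a)))
  zb <- compress_labels(as.integer(factor(z_b)))
  v <- mclust::adjustedRandIndex(za, zb)
  if (is.nan(v)) return(as.numeric(identical(za, zb)))
  v
}

#' BIC of a DCHSBM affinity family at a fixed labelling
#'
#' Fits the affinity in closed form at \code{z}, evaluates the approximate
#' DCHSBM log-likelihood at (z, omega_hat, theta_hat = d), and returns
#' \code{BIC = kappa * log(m) - 2 * L_hat}, where kappa counts the affinity
#' parameters (the n degree parameters are identical across families and
#' excluded) and m is the number of observations: the total weighted
#' hyperedge count by default, or the node count with
#' \code{sample_size = "nodes"}.
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector (metadata labels or an inferred partition).
#' @param family affinity family.
#' @param kmax maximum edge size modelled (default: largest observed).
#' @param smoothing pseudocount for \code{\link{estimate_omega}}.
#' @param sample_size observation count convention for the penalty.
#' @return scalar BIC with attributes \code{loglik} and \code{kappa}.
#' @export
dchsbm_bic <- function(H, z, family, kmax = NULL, smoothing = 1e-10,
                       sample_size = c("edges", "nodes")) {
  sample_size <- match.arg(sample_size)
  if (is.null(kmax)) kmax <- max(2L, max_edge_size(H))
  z <- check_labels(z, H$n)
  om <- estimate_omega(H, z, family, kmax = kmax, smoothing = smoothing)
  ll <- dchsbm_loglik(H, z, om)$L
  kappa <- count_parameters(family, kmax, lbar = length(unique(z)))
  m <- if (sample_size == "edges") sum(H$weights) else H$n
  structure(kappa * log(m) - 2 * ll, loglik = ll, kappa = kappa)
}

#' Compare affinity families by BIC
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector used for all families.
#' @param families affinity families to compare.
#' @param ... further arguments to \code{\link{dchsbm_bic}}.
#' @return data frame with one row per family (\code{family}, \code{loglik},
#'   \code{kappa}, \code{bic}), ranked by ascending BIC (lower is the more
#'   plausible model).
#' @export
compare_affinities <- function(H, z, families = c("aon", "gn", "rp", "pairwise"),
                               ...) {
  rows <- lapply(families, function(f) {
    b <- dchsbm_bic(H, z, f, ...)
    data.frame(family = f, loglik = attr(b, "loglik"),
               kappa = attr(b, "kappa"), bic = as.numeric(b))
  })
  out <- do.call(rbind, rows)
  out[order(out$bic), , drop = FALSE]
}

#' Detectability sweep on the two-block generator
#'
#' For each (p2, p3) cell, generates \code{n_seeds} two-block hypergraphs
#' and records the mean ARI of the highest-likelihood partition returned by
#' each method (AON coordinate ascent on the hypergraph; GMLL on a clique
#' projection), both run with the cluster-count regularizer. The implied
#' dyadic detectability signals \code{(c_i - c_o)^2 / (2 (c_i + c_o))} for
#' 2-edges and (projected) 3-edges are attached per cell; values below 1
#' mark cells where no dyadic algorithm can succeed on that edge size alone.
#'
#' @param p2_values,p3_values grid of within-community fractions.
#' @param n_seeds independent replicates per cell.
#' @param n,c2,c3 generator configuration (see
#'   \code{\link{sample_two_block}}).
#' @param alternations alternations per fit.
#' @param methods subset of \code{c("aon_hmll", "gmll")}.
#' @param projection clique projection variant used by GMLL.
#' @param seed base seed; cell/replicate seeds are derived from it.
#' @return data frame: p2, p3, method, mean_ari, signal2, signal3.
#' @export
run_detectability_sweep <- function(p2_values, p3_values, n_seeds = 20L,
                                    n = 500L, c2 = 5, c3 = 5,
                                    alternations = 20L,
                                    methods = c("aon_hmll", "gmll"),
                                    projection = c("unnormalized", "normalized"),
                                    seed = 1L) {
  projection <- match.arg(projection)
  methods <- match.arg(methods, several.ok = TRUE)
  out <- NULL
  cell <- 0L
  for (p2 in p2_values) for (p3 in p3_values) {
    cell <- cell + 1L
    aris <- matrix(NA_real_, n_seeds, length(methods),
                   dimnames = list(NULL, methods))
    for (s in seq_len(n_seeds)) {
      sd <- (seed + 104729L * cell + 31L * s) %% .Machine$integer.max
      samp <- sample_two_block(n = n, p2 = p2, p3 = p3, c2 = c2, c3 = c3,
                               seed = sd)
      if ("aon_hmll" %in% methods) {
        fit <- fit_dchsbm(samp$H, "aon", alternations = alternations,
                          regularize = TRUE, seed = sd + 1L)
        aris[s, "aon_hmll"] <- ari(fit$labels, samp$z)
      }
      if ("gmll" %in% methods) {
        G <- clique_project(samp$H, normalized = (projection == "normalized"))
        fit <- gmll(G, alternations = alternations, regularize = TRUE,
                    seed = sd + 2L)
        aris[s, "gmll"] <- ari(fit$labels, samp$z)
      }
    }
    out <- rbind(out, data.frame(
      p2 = p2, p3 = p3, method = methods,
      mean_ari = colMeans(aris)[methods],
      signal2 = detectability_threshold(c2 * p2, c2 * (1 - p2)),
      signal3 = detectability_threshold(c3 * p3, c3 * (1 - p3)),
      row.names = NULL))
  }
  out
}

#' Runtime benchmark on the synthetic testbed
#'
#' Reproduces the scalability design: hypergraphs from
#' \code{\link{sample_runtime_testbed}} in the sparse-large-edge regime,
#' with AON parameters (and the GMLL resolution) estimated from the ground
#' truth labels, comparing AON HMLL, GMLL on a normalized projection, and
#' GMLL refined by HMLL. Runtimes are reported, never asserted.
#'
#' @param n_values node counts (multiples of 200).
#' @param n_seeds replicates per size.
#' @param seed base seed.
#' @return data frame: n, seed, method, seconds, ari, n_clusters.
#' @export
run_runtime_benchmark <- function(n_values, n_seeds = 5L, seed = 1L) {
  out <- NULL
  for (n in n_values) for (s in seq_len(n_seeds)) {
    sd <- (seed + 7907L * n + s) %% .Machine$integer.max
    samp <- sample_runtime_testbed(n, fig1 = TRUE, seed = sd)
    params <- aon_params(estimate_omega(samp$H, samp$z, "aon"))
    t0 <- proc.time()[["elapsed"]]
    ph <- aon_hmll(samp$H, params, seed = sd + 1L)
    th <- proc.time()[["elapsed"]] - t0
    G <- clique_project(samp$H, normalized = TRUE)
    params2 <- aon_params(estimate_omega(G, samp$z, "aon", kmax = 2L))
    t0 <- proc.time()[["elapsed"]]
    pg <- aon_hmll(G, params2, seed = sd + 2L)
    tg <- proc.time()[["elapsed"]] - t0
    t0 <- proc.time()[["elapsed"]]
    pr <- aon_hmll(samp$H, params, z0 = pg$labels, seed = sd + 3L)
    tr <- proc.time()[["elapsed"]] - t0 + tg
    out <- rbind(out, data.frame(
      n = n, seed = s,
      method = c("aon_hmll", "gmll", "gmll_refined"),
      seconds = c(th, tg, tr),
      ari = c(ari(ph$labels, samp$z), ari(pg$labels, samp$z),
              ari(pr$labels, samp$z)),
      n_clusters = c(ph$n_clusters, pg$n_clusters, pr$n_clusters)))
  }
  out
}
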