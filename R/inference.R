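## ---- shared Louvain machinery --------------------------------------------

## cluster-count penalty change when the source cluster is emptied by a move
reg_gain <- function(n_reg, lbar) n_reg * log(lbar / (lbar - 1))

#' Cluster-count regularized objective
#'
#' Adds the Bayesian uniform-label prior term to a modularity-type
#' objective: \code{Q - n * log(lbar)}. Greedy moves that empty a cluster
#' then gain \code{n * log(lbar / (lbar - 1))}.
#'
#' @param Q objective value.
#' @param n number of nodes.
#' @param lbar number of distinct clusters (at least 1).
#' @export
regularized_objective <- function(Q, n, lbar) {
  stopifnot(lbar >= 1)
  Q - n * log(lbar)
}

ACCEPT_TOL <- 1e-12

## ---- AON fast path -------------------------------------------------------

## One stabilized sweep phase of single-(super)node moves on a working
## structure. Mutates and returns z/vols/counts.
aon_sweep <- function(edges, inc, d, z, vols, counts, bw, sizes, bg,
                      n_reg, visit_order) {
  N <- length(d)
  accepted_any <- FALSE
  repeat {
    accepted <- FALSE
    for (u in visit_order()) {
      a <- z[u]
      eids <- inc[[u]]
      if (!length(eids)) next
      base_loss <- 0
      gains <- numeric(0)
      cands <- integer(0)
      for (ei in eids) {
        e <- edges[[ei]]
        others <- e[e != u]
        if (!length(others)) next
        labs <- z[others]
        u1 <- labs[1L]
        mono <- all(labs == u1)
        cands <- c(cands, labs)
        if (mono) {
          if (u1 == a) base_loss <- base_loss + bw[ei]
          else gains[as.character(u1)] <-
              (if (is.na(gains[as.character(u1)])) 0
               else gains[as.character(u1)]) + bw[ei]
        }
      }
      cands <- unique(cands)
      cands <- cands[cands != a]
      if (!length(cands)) next
      du <- d[u]
      va <- vols[a]
      dvol_a <- sum(bg * ((va - du)^sizes - va^sizes))
      rg <- if (!is.null(n_reg) && counts[a] == 1L) {
        lbar <- sum(counts > 0L)
        if (lbar > 1L) reg_gain(n_reg, lbar) else 0
      } else 0
      best <- ACCEPT_TOL
      best_b <- 0L
      for (b in sort(cands)) {
        vb <- vols[b]
        dq <- -dvol_a - sum(bg * ((vb + du)^sizes - vb^sizes)) - base_loss + rg
        g <- gains[as.character(b)]
        if (!is.na(g)) dq <- dq + g
        if (dq > best) {
          best <- dq
          best_b <- b
        }
      }
      if (best_b != 0L) {
        accepted <- TRUE
        accepted_any <- TRUE
        vols[a] <- vols[a] - du
        vols[best_b] <- vols[best_b] + du
        counts[a] <- counts[a] - 1L
        counts[best_b] <- counts[best_b] + 1L
        z[u] <- best_b
      }
    }
    if (!accepted) break
  }
  list(z = z, vols = vols, counts = counts, accepted = accepted_any)
}

## collapse a working structure under labels z (values 1..L, possibly with
## gaps); returns the new structure whose nodes are the non-empty clusters
aon_collapse <- function(edges, esize, eweight, members, d, z) {
  z <- compress_labels(z)
  L <- max(z)
  new_members <- lapply(split(seq_along(z), z),
                        function(ix) unlist(members[ix], use.names = FALSE))
  new_d <- as.numeric(rowsum(d, z)[, 1L])
  keys <- character(length(edges))
  newe <- vector("list", length(edges))
  keep <- logical(length(edges))
  for (i in seq_along(edges)) {
    ids <- unique(z[edges[[i]]])
    if (length(ids) > 1L) {
      keep[i] <- TRUE
      ids <- sort(ids)
      newe[[i]] <- ids
      keys[i] <- paste(esize[i], paste(ids, collapse = ","), sep = "@")
    }
  }
  newe <- newe[keep]
  keys <- keys[keep]
  w <- eweight[keep]
  k <- esize[keep]
  if (length(newe)) {
    first <- !duplicated(keys)
    wsum <- rowsum(w, keys)
    ord <- match(keys[first], rownames(wsum))
    newe <- newe[first]
    k <- k[first]
    w <- as.numeric(wsum[ord, 1L])
  }
  list(edges = newe, esize = k, eweight = w,
       members = unname(new_members), d = new_d, N = L)
}

build_incidence <- function(edges, N) {
  inc <- rep(list(integer(0)), N)
  if (!length(edges)) return(inc)
  eid <- rep.int(seq_along(edges), vapply(edges, length, 1L))
  node <- unlist(edges, use.names = FALSE)
  sp <- split(eid, factor(node, levels = seq_len(N)))
  unname(sp)
}

#' All-or-nothing hypergraph maximum-likelihood Louvain
#'
#' Greedy agglomerative maximization of the AON hypergraph modularity
#' \code{-sum_k beta_k [cut_k + gamma_k sum_l vol(l)^k]}. The first round
#' moves single nodes starting from singletons (or \code{z0}); between
#' rounds clusters are collapsed into consolidated supernodes and only
#' hyperedges spanning several supernodes are retained (with their original
#' sizes), so later rounds move whole clusters cheaply. Every accepted move
#' strictly increases the (optionally regularized) objective; the algorithm
#' terminates at a partition where no single supernode move improves it.
#'
#' @param H a \code{hypergraph}.
#' @param params an \code{aon_params} (or list with \code{sizes},
#'   \code{beta}, \code{gamma}) covering all observed edge sizes.
#' @param z0 optional initial labelling (default: singletons).
#' @param regularize add the cluster-count penalty \code{- n log(lbar)} to
#'   the objective during optimization.
#' @param seed optional integer seed controlling visit order.
#' @param visit \code{"random"} (a fresh permutation per pass) or
#'   \code{"sequential"} (deterministic unit order).
#' @param max_rounds safety cap on collapse rounds.
#' @return object of class \code{"hg_partition"}: list with \code{labels}
#'   (contiguous 1-based), \code{n_clusters}, \code{objective} (regularized
#'   if requested), and the per-round objective \code{trace}.
#' @export
aon_hmll <- function(H, params, z0 = NULL, regularize = FALSE, seed = NULL,
                     visit = c("random", "sequential"), max_rounds = 100L) {
  stopifnot(inherits(H, "hypergraph"))
  visit <- match.arg(visit)
  obs <- as.integer(names(size_counts(H)))
  if (length(setdiff(obs, params$sizes)))
    stop("params missing beta/gamma for some observed edge size")
  sizes <- as.integer(params$sizes)
  beta_of <- stats::setNames(as.numeric(params$beta), sizes)
  bg <- as.numeric(params$beta) * as.numeric(params$gamma)
  n_reg <- if (regularize) H$n else NULL
  z_init <- if (is.null(z0)) seq_len(H$n) else compress_labels(check_labels(z0, H$n))

  with_rng(seed, {
    W <- list(edges = H$edges, esize = H$sizes, eweight = H$weights,
              members = as.list(seq_len(H$n)), d = degrees(H), N = H$n)
    z <- z_init
    trace <- numeric(0)
    round <- 0L
    repeat {
      round <- round + 1L
      if (round > max_rounds) break
      inc <- build_incidence(W$edges, W$N)
      bw <- if (length(W$edges)) beta_of[as.character(W$esize)] * W$eweight
            else numeric(0)
      vols <- numeric(max(z, W$N))
      agg <- rowsum(W$d, z)
      vols[as.integer(rownames(agg))] <- agg[, 1L]
      counts <- tabulate(z, nbins = length(vols))
      vo <- if (visit == "random") function() sample.int(W$N)
            else function() seq_len(W$N)
      res <- aon_sweep(W$edges, inc, W$d, z, vols, counts, bw, sizes, bg,
                       n_reg, vo)
      z <- res$z
      z_full <- integer(H$n)
      for (u in seq_len(W$N)) z_full[W$members[[u]]] <- z[u]
      z_full <- compress_labels(z_full)
      q <- aon_modularity(H, z_full, params, n_reg = n_reg)
      trace <- c(trace, q)
      if (round > 1L && !res$accepted) break
      if (round == 1L && !res$accepted && max(compress_labels(z)) == W$N)
        break # nothing moved and collapsing would be the identity
      W <- aon_collapse(W$edges, W$esize, W$eweight, W$members, W$d, z)
      z <- seq_len(W$N)
    }
    z_full <- integer(H$n)
    for (u in seq_len(W$N)) z_full[W$members[[u]]] <- z[u]
    z_full <- compress_labels(z_full)
    structure(list(labels = z_full, n_clusters = max(z_full),
                   objective = trace[length(trace)], trace = trace,
                   method = "aon_hmll", seed = seed),
              class = "hg_partition")
  })
}

#' @export
print.hg_partition <- function(x, ...) {
  cat(sprintf("Partition from %s: %d clusters, objective %.6g (%d rounds)\n",
              x$method, x$n_clusters, x$objective, length(x$trace)))
  invisible(x)
}

## ---- symmetric path ------------------------------------------------------

## precompute (partition vector, omega, log omega) for all sizes <= kmax
aff_pattern_table <- function(aff) {
  pats <- list()
  for (k in 2:aff$kmax) {
    for (p in integer_partitions(k)) {
      w <- omega_value(aff, p)
      pats[[length(pats) + 1L]] <- list(p = p, key = p_key(p), w = w,
                                        lw = if (w > 0) log(w) else -Inf)
    }
  }
  pats
}

## expected edge mass from power sums using a pattern table
edge_mass_S <- function(S, pats) {
  acc <- 0
  for (pt in pats) if (pt$w > 0) acc <- acc + pt$w * vol_p_from_powersums(S, pt$p)
  acc
}

## log Omega lookup by pattern key
log_omega_fun <- function(aff, pats) {
  tab <- stats::setNames(vapply(pats, `[[`, 0, "lw"),
                         vapply(pats, `[[`, "", "key"))
  function(p) {
    v <- tab[p_key(p)]
    if (is.na(v)) -Inf else unname(v)
  }
}

#' Symmetric hypergraph maximum-likelihood Louvain
#'
#' Greedy maximization of the symmetric hypergraph modularity
#' \code{sum_p [cut_p log Omega(p) - vol_p Omega(p)]} for an arbitrary
#' symmetric affinity function. The first round moves single nodes from
#' singletons (or \code{z0}); later rounds move the clusters formed
#' previously as units over the full adjacency data (hyperedges are never
#' collapsed, since general affinities require the full partition vector of
#' every edge). Volume changes are evaluated through power-sum updates.
#'
#' @inheritParams aon_hmll
#' @param aff an \code{hg_affinity} with \code{kmax >= max_edge_size(H)}.
#' @return an \code{hg_partition} (see \code{\link{aon_hmll}}).
#' @export
symmetric_hmll <- function(H, aff, z0 = NULL, regularize = FALSE, seed = NULL,
                           visit = c("random", "sequential"),
                           max_rounds = 100L) {
  stopifnot(inherits(H, "hypergraph"), inherits(aff, "hg_affinity"))
  visit <- match.arg(visit)
  if (max_edge_size(H) > aff$kmax) stop("edges larger than aff$kmax")
  n <- H$n
  pats <- aff_pattern_table(aff)
  lomega <- log_omega_fun(aff, pats)
  n_reg <- if (regularize) n else NULL
  inc <- incidence_lists(H)
  d <- degrees(H)
  z <- if (is.null(z0)) seq_len(n) else compress_labels(check_labels(z0, n))

  sweep_units <- function(z, unit_id) {
    units <- sort(unique(unit_id))
    nlab <- max(z, n)
    vols <- numeric(nlab)
    agg <- rowsum(d, z)
    vols[as.integer(rownames(agg))] <- agg[, 1L]
    counts <- tabulate(z, nbins = nlab)
    S <- power_sums(vols, aff$kmax)
    Emass <- edge_mass_S(S, pats)
    accepted_any <- FALSE
    repeat {
      accepted <- FALSE
      ord <- if (visit == "random") sample(units) else units
      for (u in ord) {
        U <- which(unit_id == u)
        a <- z[U[1L]]
        D <- sum(d[U])
        eids <- unique(unlist(inc[U], use.names = FALSE))
        if (!length(eids)) next
        in_u <- logical(n)
        in_u[U] <- TRUE
        cands <- integer(0)
        epat <- vector("list", length(eids))
        for (j in seq_along(eids)) {
          e <- H$edges[[eids[j]]]
          zl <- z[e]
          epat[[j]] <- list(e = e, zl = zl, mv = in_u[e],
                            lw = lomega(partition_vector(zl)),
                            w = H$weights[eids[j]])
          cands <- c(cands, zl[!in_u[e]])
        }
        cands <- setdiff(unique(cands), a)
        if (!length(cands)) next
        q <- seq_len(aff$kmax)
        Sa <- S - vols[a]^q + (vols[a] - D)^q
        rg <- if (!is.null(n_reg) && counts[a] == length(U)) {
          lbar <- sum(counts > 0L)
          if (lbar > 1L) reg_gain(n_reg, lbar) else 0
        } else 0
        best <- ACCEPT_TOL
        best_b <- 0L
        for (b in sort(cands)) {
          Sb <- Sa - vols[b]^q + (vols[b] + D)^q
          dq <- Emass - edge_mass_S(Sb, pats) + rg
          for (ep in epat) {
            zl2 <- ep$zl
            zl2[ep$mv] <- b
            lw2 <- lomega(partition_vector(zl2))
            dterm <- if (is.infinite(ep$lw) && is.infinite(lw2)) 0
                     else ep$w * (lw2 - ep$lw)
            dq <- dq + dterm
          }
          if (dq > best) {
            best <- dq
            best_b <- b
          }
        }
        if (best_b != 0L) {
          accepted <- TRUE
          accepted_any <- TRUE
          b <- best_b
          S <- Sa - vols[b]^q + (vols[b] + D)^q
          vols[a] <- vols[a] - D
          vols[b] <- vols[b] + D
          counts[a] <- counts[a] - length(U)
          counts[b] <- counts[b] + length(U)
          z[U] <- b
          Emass <- edge_mass_S(S, pats)
        }
      }
      if (!accepted) break
    }
    list(z = z, accepted = accepted_any)
  }

  with_rng(seed, {
    trace <- numeric(0)
    round <- 0L
    repeat {
      round <- round + 1L
      if (round > max_rounds) break
      unit_id <- if (round == 1L) seq_len(n) else z
      res <- sweep_units(z, unit_id)
      z <- compress_labels(res$z)
      q <- symmetric_modularity(H, z, aff)
      if (!is.null(n_reg)) q <- regularized_objective(q, n_reg, max(z))
      trace <- c(trace, q)
      if (round > 1L && !res$accepted) break
      if (round == 1L && !res$accepted && max(z) == n) break
    }
    structure(list(labels = z, n_clusters = max(z),
                   objective = trace[length(trace)], trace = trace,
                   method = "symmetric_hmll", seed = seed),
              class = "hg_partition")
  })
}

## ---- coordinate ascent ---------------------------------------------------

## density-calibrated assortative starting affinity for symmetric families
default_start_affinity <- function(H, kmax) {
  mk <- size_counts(H)
  volH <- hg_volume(H)
  vals <- numeric(0)
  for (k in 2:kmax) {
    m <- mk[as.character(k)]
    if (is.na(m)) m <- 1
    for (p in integer_partitions(k)) {
      vals[p_key(p)] <- m / volH^k * exp(1 - length(p))
    }
  }
  affinity("custom", vals, kmax)
}

#' Fit a DCHSBM by coordinate-ascent maximum likelihood
#'
#' Alternates between (i) updating the node labelling z with the matching
#' Louvain optimizer (the fast supernode-collapse path for the AON family,
#' the general symmetric path otherwise) and (ii) re-estimating the degree
#' and affinity parameters in closed form from the current labelling.
#' Returns the alternation attaining the highest DCHSBM log-likelihood
#' (penalized by \code{- n log lbar} when \code{regularize = TRUE}).
#'
#' @param H a \code{hypergraph}.
#' @param family affinity family: \code{"aon"}, \code{"gn"}, \code{"rp"} or
#'   \code{"pairwise"}.
#' @param alternations number of partition/estimation alternations.
#' @param z0 optional initial labelling; also used to estimate the starting
#'   parameters.
#' @param dyadic_init when no \code{z0} is given and the hypergraph has
#'   edges beyond size 2, bootstrap the ascent from a short dyadic run on
#'   the normalized clique projection, so that the first affinity estimate
#'   carries the signs of the per-size signals (an a-priori assortative
#'   start cannot discover sizes whose edges run between clusters). With
#'   \code{dyadic_init = FALSE} (or when projection is not possible) the AON
#'   path starts from strict-modularity parameters and symmetric families
#'   from a density-calibrated assortative affinity.
#' @param regularize use the cluster-count penalty in both the move
#'   objective and the model selection across alternations.
#' @param seed integer seed; alternation i uses a seed derived from it.
#' @param kmax maximum edge size modelled (default: largest observed).
#' @param smoothing pseudocount forwarded to \code{\link{estimate_omega}}.
#' @param cold_start restart each alternation's Louvain from singletons
#'   instead of warm-starting from the previous labelling.
#' @param visit node visit order policy, see \code{\link{aon_hmll}}.
#' @param keep_partitions also return the labelling of every alternation
#'   (list column \code{partitions}).
#' @return object of class \code{"dchsbm_fit"}: best \code{labels},
#'   fitted \code{affinity} (and \code{aon} parameters for the AON family),
#'   \code{theta}, \code{loglik}, the per-alternation \code{trace}
#'   data frame, \code{best_alternation}, and the settings used.
#' @export
fit_dchsbm <- function(H, family = c("aon", "gn", "rp", "pairwise"),
                       alternations = 20L, z0 = NULL, regularize = FALSE,
                       seed = NULL, kmax = NULL, smoothing = 1e-10,
                       cold_start = FALSE, visit = c("random", "sequential"),
                       keep_partitions = FALSE, dyadic_init = TRUE) {
  family <- match.arg(family)
  visit <- match.arg(visit)
  stopifnot(inherits(H, "hypergraph"), alternations >= 1)
  if (is.null(kmax)) kmax <- max(2L, max_edge_size(H))
  n <- H$n
  theta <- degrees(H)

  if (is.null(z0) && dyadic_init && max_edge_size(H) > 2L) {
    ## bootstrap from short unregularized dyadic runs on both projection
    ## variants; keep the candidate whose induced affinity estimate scores
    ## the highest hypergraph likelihood
    cand <- list()
    for (nrm in c(TRUE, FALSE)) {
      zc <- tryCatch({
        G <- clique_project(H, normalized = nrm)
        gseed <- if (is.null(seed)) NULL
                 else (seed + 17L + as.integer(nrm)) %% .Machine$integer.max
        gfit <- fit_dchsbm(G, "aon", alternations = 5L,
                           regularize = regularize, seed = gseed, kmax = 2L,
                           smoothing = smoothing)
        if (max(gfit$labels) < 2L && regularize) {
          ## regularized dyadic run collapsed; retry without the penalty
          gfit <- fit_dchsbm(G, "aon", alternations = 5L, regularize = FALSE,
                             seed = gseed, kmax = 2L, smoothing = smoothing)
        }
        if (max(gfit$labels) >= 2L) gfit$labels else NULL
      }, error = function(e) NULL)
      if (!is.null(zc)) cand[[length(cand) + 1L]] <- zc
    }
    if (length(cand)) {
      ## cluster-count-penalized likelihood: plain L systematically favours
      ## fragmented candidates
      scores <- vapply(cand, function(zc)
        regularized_objective(
          dchsbm_loglik(H, zc, estimate_omega(H, zc, family, kmax = kmax,
                                              smoothing = smoothing))$L,
          n, max(zc)), 0)
      z0 <- cand[[which.max(scores)]]
    }
  }
  params <- NULL      # aon_params for the fast path
  aff_cur <- NULL     # hg_affinity for the symmetric path
  if (!is.null(z0)) {
    om0 <- estimate_omega(H, z0, family, kmax = kmax, smoothing = smoothing)
    if (family == "aon") params <- tryCatch(aon_params(om0), error = function(e) NULL)
    aff_cur <- om0
  }
  if (family == "aon" && is.null(params))
    params <- strict_modularity_params(H, sizes = 2:kmax)
  if (family != "aon" && is.null(aff_cur))
    aff_cur <- default_start_affinity(H, kmax)

  z_cur <- z0
  partitions <- if (keep_partitions) vector("list", alternations)
  z_prev <- NULL
  om_prev <- NULL
  best <- list(score = -Inf)
  trace <- data.frame(alternation = integer(0), loglik = numeric(0),
                      score = numeric(0), n_clusters = integer(0),
                      moves_objective = numeric(0))
  for (it in seq_len(alternations)) {
    seed_i <- if (is.null(seed)) NULL else (seed + 7919L * it) %% .Machine$integer.max
    init <- if (cold_start) NULL else z_cur
    part <- if (family == "aon")
      aon_hmll(H, params, z0 = init, regularize = regularize, seed = seed_i,
               visit = visit)
    else
      symmetric_hmll(H, aff_cur, z0 = init, regularize = regularize,
                     seed = seed_i, visit = visit)
    z_cur <- part$labels
    lbar <- max(z_cur)
    om <- estimate_omega(H, z_cur, family, kmax = kmax, smoothing = smoothing)
    ll <- unname(dchsbm_loglik(H, z_cur, om, theta)$L)
    score <- if (regularize) regularized_objective(ll, n, lbar) else ll
    if (lbar >= 2L) {
      aff_cur <- om
      if (family == "aon") {
        params <- tryCatch(aon_params(om), error = function(e) params)
      }
    }
    if (keep_partitions) partitions[[it]] <- z_cur
    trace <- rbind(trace, data.frame(alternation = it, loglik = ll,
                                     score = score, n_clusters = lbar,
                                     moves_objective = part$objective))
    if (score > best$score)
      best <- list(score = score, labels = z_cur, affinity = om, loglik = ll,
                   alternation = it,
                   aon = if (family == "aon") tryCatch(aon_params(om),
                                                       error = function(e) NULL))
    ## fixed point: with a warm start, an unchanged (z, omega) pair makes
    ## every remaining alternation provably identical (no move improves
    ## under the same move values, whatever the visit order)
    if (!cold_start && identical(z_cur, z_prev) &&
        isTRUE(all.equal(om$values, om_prev$values)) && it < alternations) {
      extra <- (it + 1L):alternations
      if (keep_partitions) for (j in extra) partitions[[j]] <- z_cur
      trace <- rbind(trace, data.frame(alternation = extra, loglik = ll,
                                       score = score, n_clusters = lbar,
                                       moves_objective = part$objective))
      break
    }
    z_prev <- z_cur
    om_prev <- om
  }
  structure(list(labels = best$labels, affinity = best$affinity,
                 aon = best$aon, theta = theta, loglik = best$loglik,
                 score = best$score, trace = trace,
                 partitions = if (keep_partitions) partitions,
                 best_alternation = best$alternation,
                 settings = list(family = family, alternations = alternations,
                                 regularize = regularize, seed = seed,
                                 kmax = kmax, smoothing = smoothing,
                                 cold_start = cold_start, visit = visit)),
            class = "dchsbm_fit")
}

#' @export
print.dchsbm_fit <- function(x, ...) {
  cat(sprintf(
    "DCHSBM fit (%s): %d clusters, log-likelihood %.6g (best of %d alternations)\n",
    x$settings$family, max(x$labels), x$loglik, nrow(x$trace)))
  invisible(x)
}

#' Refine a partition by coordinate ascent
#'
#' Runs \code{\link{fit_dchsbm}} warm-started at \code{z_init} (the
#' parameters are first estimated from \code{z_init}); used e.g. to refine
#' the output of a dyadic-projection method with the hypergraph objective.
#' The returned objective is at least that of \code{z_init} under the fitted
#' parameters.
#'
#' @param H a \code{hypergraph}.
#' @param z_init initial labelling.
#' @param family affinity family.
#' @param alternations number of alternations.
#' @param ... further arguments to \code{\link{fit_dchsbm}}.
#' @export
refine_partition <- function(H, z_init, family = "aon", alternations = 20L, ...) {
  fit_dchsbm(H, family = family, alternations = alternations,
             z0 = compress_labels(check_labels(z_init, H$n)), ...)
}
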