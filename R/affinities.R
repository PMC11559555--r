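#' Partition vector of a label tuple
#'
#' The partition vector p = phi(z) of a tuple of cluster labels is the
#' non-increasing sequence of label multiplicities: p_j is the size of the
#' j-th largest group within the tuple (ties broken by sorting). Symmetric
#' affinity functions depend on the labels of an edge only through p.
#'
#' @param labels vector of cluster labels (any atomic type).
#' @return integer vector, sorted non-increasing, summing to
#'   \code{length(labels)}.
#' @examples
#' partition_vector(c(1, 1, 4, 1, 2, 3, 2)) # (3, 2, 1, 1)
#' @export
partition_vector <- function(labels) {
  if (!length(labels)) stop("empty label tuple")
  sort(tabulate(match(labels, unique(labels))), decreasing = TRUE)
}

## string key for a partition vector, e.g. "3|2|1|1"
p_key <- function(p) paste(p, collapse = "|")
p_unkey <- function(key) as.integer(strsplit(key, "|", fixed = TRUE)[[1]])

## all integer partitions of k (non-increasing), memoised
.partition_cache <- new.env(parent = emptyenv())
integer_partitions <- function(k) {
  key <- as.character(k)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  rec <- function(k, maxpart) {
    if (k == 0L) return(list(integer(0)))
    out <- list()
    for (first in seq.int(min(k, maxpart), 1L)) {
      for (rest in rec(k - first, first)) out[[length(out) + 1L]] <- c(first, rest)
    }
    out
  }
  res <- rec(as.integer(k), as.integer(k))
  .partition_cache[[key]] <- res
  res
}

#' Affinity class of a partition vector
#'
#' Maps a partition vector to the identifier of the equivalence class on
#' which the affinity family is constant. Classes are:
#' \describe{
#'   \item{aon}{\code{(k, 1)} if the edge lies in a single cluster
#'     (\code{length(p) == 1}), else \code{(k, 0)}.}
#'   \item{gn}{\code{(k, t)} with \code{t} the number of distinct groups in
#'     the edge.}
#'   \item{rp}{\code{(k, 1)} if the gap between the largest and second
#'     largest group, \code{p[1] - p[2]}, is below \code{k/4}, else
#'     \code{(k, 0)}.}
#'   \item{pairwise}{\code{(k, 1)} if the number of ordered node pairs in
#'     differing groups, \code{k^2 - sum(p^2)}, is below \code{k*(k-1)/4},
#'     else \code{(k, 0)}.}
#' }
#'
#' @param family one of \code{"aon"}, \code{"gn"}, \code{"rp"},
#'   \code{"pairwise"}, \code{"custom"}.
#' @param p a partition vector.
#' @param kmax optional maximum supported edge size; an error is raised when
#'   \code{sum(p) > kmax}.
#' @return character class id, \code{"k:c"}.
#' @export
affinity_class <- function(family, p, kmax = NULL) {
  family <- match.arg(family, c("aon", "gn", "rp", "pairwise", "custom"))
  p <- as.integer(p)
  k <- sum(p)
  if (!is.null(kmax) && k > kmax) stop("edge size exceeds kmax of affinity")
  cls <- switch(family,
    aon = as.integer(length(p) == 1L),
    gn = length(p),
    rp = {
      p2 <- if (length(p) >= 2L) p[2] else 0L
      as.integer(p[1] - p2 < k / 4)
    },
    pairwise = as.integer(k^2 - sum(p^2) < k * (k - 1) / 4),
    custom = return(p_key(p)))
  paste0(k, ":", cls)
}

#' Construct an affinity function
#'
#' An affinity function Omega assigns a non-negative Poisson rate factor to
#' every partition vector with edge size between 2 and \code{kmax},
#' constant on the classes of the chosen family (see
#' \code{\link{affinity_class}}).
#'
#' @param family affinity family.
#' @param values named numeric vector of per-class values; names are class
#'   ids (\code{"k:c"} for the named families, partition keys like
#'   \code{"2|1"} for \code{family = "custom"}). Classes absent from
#'   \code{values} evaluate to 0.
#' @param kmax maximum edge size covered.
#' @return object of class \code{"hg_affinity"}.
#' @export
affinity <- function(family, values, kmax) {
  family <- match.arg(family, c("aon", "gn", "rp", "pairwise", "custom"))
  stopifnot(is.numeric(values), !is.null(names(values)), kmax >= 2)
  if (any(values < 0)) stop("affinity values must be non-negative")
  structure(list(family = family, values = values, kmax = as.integer(kmax)),
            class = "hg_affinity")
}

#' @export
print.hg_affinity <- function(x, ...) {
  cat(sprintf("Affinity function: family=%s, kmax=%d\n", x$family, x$kmax))
  print(x$values)
  invisible(x)
}

#' Evaluate an affinity function on a partition vector
#'
#' @param aff an \code{hg_affinity}.
#' @param p a partition vector (edge size \code{sum(p)} must not exceed
#'   \code{aff$kmax}).
#' @return non-negative scalar; classes with no stored value give 0.
#' @export
omega_value <- function(aff, p) {
  stopifnot(inherits(aff, "hg_affinity"))
  key <- affinity_class(aff$family, p, aff$kmax)
  v <- aff$values[key]
  if (is.na(v)) 0 else unname(v)
}

#' Degree parameter estimate
#'
#' Under the joint normalization tying theta to cluster volumes, the
#' conditional maximum-likelihood estimate of the degree parameters is the
#' observed degree vector itself, for every labelling z.
#'
#' @param H a \code{hypergraph}.
#' @return numeric vector \code{theta_hat = degrees(H)}.
#' @export
estimate_theta <- function(H) degrees(H)

#' Conditional maximum-likelihood affinity estimate
#'
#' For a fixed labelling z, the ML estimate of the affinity value on a class
#' Y is the weighted count of observed hyperedges whose partition vector
#' falls in Y, divided by the total (ordered-tuple) volume
#' \code{sum over p in Y of vol_p}. Classes with zero volume get value 0.
#' By default a pseudocount \code{smoothing} is added to every numerator
#' with positive denominator so that log-affinities stay finite.
#'
#' @param H a \code{hypergraph}.
#' @param z integer label vector.
#' @param family affinity family.
#' @param kmax maximum edge size to cover (default: largest observed size).
#' @param smoothing pseudocount added to class numerators (0 disables).
#' @return an \code{hg_affinity} with one value per class realised by some
#'   partition vector of size 2..kmax with at most \code{max(z)} parts.
#' @export
estimate_omega <- function(H, z, family = c("aon", "gn", "rp", "pairwise", "custom"),
                           kmax = NULL, smoothing = 1e-10) {
  family <- match.arg(family)
  z <- check_labels(z, H$n)
  if (is.null(kmax)) kmax <- max(2L, max_edge_size(H))
  vols <- cluster_volumes(H, z)
  ## numerators: observed weighted edge count per class
  num <- new.env(parent = emptyenv())
  for (i in seq_along(H$edges)) {
    key <- affinity_class(family, partition_vector(z[H$edges[[i]]]), kmax)
    num[[key]] <- (if (is.null(num[[key]])) 0 else num[[key]]) + H$weights[i]
  }
  ## denominators: sum of vol_p over the class's partition vectors
  den <- new.env(parent = emptyenv())
  for (k in 2:kmax) {
    for (p in integer_partitions(k)) {
      key <- affinity_class(family, p, kmax)
      den[[key]] <- (if (is.null(den[[key]])) 0 else den[[key]]) + vol_p(vols, p)
    }
  }
  keys <- ls(den)
  vals <- vapply(keys, function(key) {
    dn <- den[[key]]
    if (dn <= 0) return(0)
    nm <- if (is.null(num[[key]])) 0 else num[[key]]
    (nm + smoothing) / dn
  }, 0)
  affinity(family, stats::setNames(vals, keys), kmax)
}

#' Size-resolved AON modularity parameters
#'
#' Converts the per-size AON affinity pair (omega_k1 within, omega_k0
#' between) into the parameters of the AON modularity objective:
#' \code{beta_k = log(omega_k1) - log(omega_k0)} (importance of size-k
#' edges) and \code{gamma_k = (omega_k1 - omega_k0) / beta_k} (size-resolved
#' resolution). When the two values coincide, beta_k = 0 and gamma_k is
#' taken as the continuity limit omega_k1 (with a warning).
#'
#' @param omega either an \code{hg_affinity} of family \code{"aon"} or a
#'   2-column matrix/data.frame with rows indexed by size k and columns
#'   \code{omega0, omega1}.
#' @return object of class \code{"aon_params"}: list with numeric vectors
#'   \code{beta}, \code{gamma}, \code{omega0}, \code{omega1}, named by size.
#' @export
aon_params <- function(omega) {
  if (inherits(omega, "hg_affinity")) {
    stopifnot(omega$family == "aon")
    keys <- names(omega$values)
    ks <- as.integer(sub(":.*", "", keys))
    cls <- sub(".*:", "", keys)
    sizes <- sort(unique(ks))
    o1 <- vapply(sizes, function(k) {
      v <- omega$values[paste0(k, ":1")]; if (is.na(v)) 0 else v }, 0)
    o0 <- vapply(sizes, function(k) {
      v <- omega$values[paste0(k, ":0")]; if (is.na(v)) 0 else v }, 0)
  } else {
    omega <- as.matrix(omega)
    sizes <- as.integer(rownames(omega))
    if (!length(sizes) || anyNA(sizes)) sizes <- seq_len(nrow(omega)) + 1L
    o0 <- omega[, "omega0"]; o1 <- omega[, "omega1"]
  }
  if (any(o0 <= 0) || any(o1 <= 0))
    stop("AON parameters require strictly positive omega_k0 and omega_k1 (apply smoothing)")
  beta <- log(o1) - log(o0)
  gamma <- ifelse(beta == 0, o1, (o1 - o0) / ifelse(beta == 0, 1, beta))
  if (any(beta == 0))
    warning("omega_k1 == omega_k0 for some size; gamma_k set to the limit value omega_k")
  structure(list(sizes = sizes,
                 beta = stats::setNames(as.numeric(beta), sizes),
                 gamma = stats::setNames(as.numeric(gamma), sizes),
                 omega0 = stats::setNames(as.numeric(o0), sizes),
                 omega1 = stats::setNames(as.numeric(o1), sizes)),
            class = "aon_params")
}

#' @export
print.aon_params <- function(x, ...) {
  print(data.frame(k = x$sizes, beta = x$beta, gamma = x$gamma,
                   omega0 = x$omega0, omega1 = x$omega1, row.names = NULL))
  invisible(x)
}

#' Strict-modularity AON parameters
#'
#' The strict hypergraph modularity objective is the special case of AON
#' modularity with \code{beta_k = 1} and \code{gamma_k = m_k / vol(H)^k}.
#'
#' @param H a \code{hypergraph}.
#' @param sizes edge sizes to cover (default: 2 to the largest observed).
#' @return an \code{aon_params} object.
#' @export
strict_modularity_params <- function(H, sizes = NULL) {
  if (is.null(sizes)) sizes <- 2:max(2L, max_edge_size(H))
  mk <- size_counts(H)
  volH <- hg_volume(H)
  gamma <- vapply(sizes, function(k) {
    m <- mk[as.character(k)]
    if (is.na(m)) 0 else m / volH^k
  }, 0)
  structure(list(sizes = as.integer(sizes),
                 beta = stats::setNames(rep(1, length(sizes)), sizes),
                 gamma = stats::setNames(as.numeric(gamma), sizes),
                 omega0 = NULL, omega1 = NULL),
            class = "aon_params")
}

#' Build an AON affinity from beta/gamma parameters
#'
#' Inverts the parameterisation of \code{\link{aon_params}}:
#' omega_k0 = gamma_k * beta_k / (exp(beta_k) - 1),
#' omega_k1 = exp(beta_k) * omega_k0.
#'
#' @param params an \code{aon_params} (beta and gamma must be set; beta != 0).
#' @param kmax maximum edge size (default: largest size in \code{params}).
#' @return an \code{hg_affinity} of family \code{"aon"}.
#' @export
aon_affinity <- function(params, kmax = NULL) {
  stopifnot(inherits(params, "aon_params"))
  if (!is.null(params$omega0)) {
    sizes <- params$sizes
    vals <- c(stats::setNames(params$omega1, paste0(sizes, ":1")),
              stats::setNames(params$omega0, paste0(sizes, ":0")))
  } else {
    b <- params$beta; g <- params$gamma; sizes <- params$sizes
    if (any(b == 0)) stop("beta = 0 is not invertible to (omega0, omega1)")
    o0 <- g * b / (exp(b) - 1)
    o1 <- exp(b) * o0
    vals <- c(stats::setNames(o1, paste0(sizes, ":1")),
              stats::setNames(o0, paste0(sizes, ":0")))
  }
  if (is.null(kmax)) kmax <- max(sizes)
  affinity("aon", vals, kmax)
}

#' Number of free affinity parameters
#'
#' AON, RP and Pairwise affinities have \code{2 * kmax} parameters. The GN
#' affinity has one parameter per (size, group count) combination with the
#' group count capped at the number of distinct labels present:
#' \code{sum over k = 2..kmax of min(k, lbar)}. Setting
#' \code{restrict_groups = FALSE} removes the cap (then \code{k} parameters
#' for each size).
#'
#' @param family affinity family.
#' @param kmax maximum edge size.
#' @param lbar number of distinct cluster labels (required for GN with the
#'   default restriction).
#' @param restrict_groups cap GN group counts at \code{lbar}.
#' @return integer parameter count kappa.
#' @export
count_parameters <- function(family, kmax, lbar = NULL, restrict_groups = TRUE) {
  family <- match.arg(family, c("aon", "gn", "rp", "pairwise"))
  stopifnot(kmax >= 2)
  if (family != "gn") return(2L * as.integer(kmax))
  ks <- 2:kmax
  if (!restrict_groups) return(sum(ks))
  stopifnot(!is.null(lbar), lbar >= 1)
  sum(pmin(ks, lbar))
}

#' Serialize an affinity function to JSON
#' @param aff an \code{hg_affinity}.
#' @return a JSON string \code{{family, kmax, values}}.
#' @export
affinity_to_json <- function(aff) {
  stopifnot(inherits(aff, "hg_affinity"))
  jsonlite::toJSON(list(family = aff$family, kmax = aff$kmax,
                        values = as.list(aff$values)),
                   auto_unbox = TRUE, digits = NA)
}

#' Deserialize an affinity function from JSON
#' @param json a JSON string produced by \code{\link{affinity_to_json}}.
#' @return an \code{hg_affinity}.
#' @export
affinity_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  affinity(x$family, unlist(x$values), x$kmax)
}
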