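#' Fit the First/Second-Subtree radius threshold
#'
#' Branch mean radii are modelled as a two-component Gaussian mixture
#' (expectation-maximisation): the taller small-radius component N(mu2,
#' sigma2) describes the abundant distal branches, the large-radius
#' component N(mu1, sigma1) the few trunk vessels. With mu = mu2, the
#' Second-Subtree radius range is \[Min, 2*mu - Min\], so the separation
#' threshold is \code{theta = 2*mu - Min} (clamped to the observed radius
#' range). When the fit is degenerate (components closer than 1e-3, a
#' component weight below 0.05, fewer than 4 radii, all radii identical, or
#' EM failure) the
#' default \code{theta = 0.5 * Max} is used instead (again clamped to the
#' observed radius range).
#'
#' @param radii numeric vector of branch mean radii (mm).
#' @param seed integer seed for the EM initialisation.
#' @return A [RadiusModel-class].
#' @importFrom mclust Mclust mclustBIC
#' @export
fitRadiusThreshold <- function(radii, seed = 0L) {
  radii <- as.numeric(radii)
  stopifnot(all(is.finite(radii)), all(radii >= 0))
  rMin <- min(radii); rMax <- max(radii)
  fallbackModel <- function() {
    new("RadiusModel", mu1 = NA_real_, sigma1 = NA_real_, mu2 = NA_real_,
        sigma2 = NA_real_, rMin = rMin, rMax = rMax,
        theta = min(max(0.5 * rMax, rMin), rMax), fallback = TRUE)
  }
  if (length(radii) < 4) {
    warning("fewer than 4 radii; using the default threshold 0.5 * Max")
    return(fallbackModel())
  }
  if (rMax - rMin < 1e-8) return(fallbackModel())  # EM stalls on constant data
  fit <- withr::with_seed(seed, tryCatch({
    bic <- mclust::mclustBIC(radii, G = 2, modelNames = "V", verbose = FALSE)
    mclust::Mclust(radii, G = 2, modelNames = "V", x = bic, verbose = FALSE)
  }, error = function(e) NULL))
  if (is.null(fit)) return(fallbackModel())
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- as.numeric(fit$parameters$pro)
  lo <- which.min(mu); hi <- which.max(mu)
  if (abs(mu[hi] - mu[lo]) < 1e-3 || min(w) < 0.05) return(fallbackModel())
  theta <- min(max(2 * mu[lo] - rMin, rMin), rMax)
  new("RadiusModel", mu1 = mu[hi], sigma1 = sig[hi], mu2 = mu[lo],
      sigma2 = sig[lo], rMin = rMin, rMax = rMax, theta = theta,
      fallback = FALSE)
}

#' Split a vessel tree into First and Second Subtrees
#'
#' Edges with mean radius above \code{theta} form the First Subtree (main
#' portal trunks); edges with mean radius in \[Min, theta\] form the Second
#' Subtree and are grouped into maximal connected directed subtrees. Each
#' subtree's root is its vertex closest (in tree depth) to the main root,
#' which is unique because the input is a tree.
#'
#' @param t a [VesselTree-class].
#' @param theta radius threshold in mm (see [fitRadiusThreshold()]).
#' @return list with \code{first} (edge ids of the First Subtree) and
#'   \code{second} (list of subtrees: each has \code{root}, \code{vertices},
#'   \code{edges}).
#' @export
splitSubtrees <- function(t, theta) {
  e <- t@edges
  firstIds <- e$id[e$meanRadius > theta]
  secondRows <- which(e$meanRadius <= theta)
  if (!length(secondRows))
    return(list(first = firstIds, second = list()))
  depth <- .vertexDepths(t)
  # connected components of the second-subtree edge set (undirected sense)
  sub <- e[secondRows, , drop = FALSE]
  comp <- .edgeComponents(sub)
  second <- lapply(split(seq_len(nrow(sub)), comp), function(rows) {
    vs <- sort(unique(c(sub$from[rows], sub$to[rows])))
    list(root = vs[which.min(depth[as.character(vs)])],
         vertices = vs,
         edges = sub$id[rows])
  })
  names(second) <- NULL
  list(first = firstIds, second = second)
}

.vertexDepths <- function(t) {
  depth <- setNames(rep(NA_real_, nrow(t@vertices)), as.character(t@vertices$id))
  depth[as.character(t@root)] <- 0
  queue <- t@root
  e <- t@edges
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    kids <- e$to[e$from == cur]
    for (k in kids) {
      if (is.na(depth[as.character(k)])) {
        depth[as.character(k)] <- depth[as.character(cur)] + 1
        queue <- c(queue, k)
      }
    }
  }
  depth
}

# union-find over the vertices touched by an edge subset; returns a component
# id per edge row
.edgeComponents <- function(sub) {
  vs <- sort(unique(c(sub$from, sub$to)))
  parent <- setNames(seq_along(vs), as.character(vs))
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  for (r in seq_len(nrow(sub))) {
    a <- find(match(sub$from[r], vs)); b <- find(match(sub$to[r], vs))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(vs), function(i) find(i), 0L)
  comp <- match(roots, unique(roots))
  comp[match(sub$from, vs)]
}

#' Prune Micro Subtrees
#'
#' A Second Subtree with at most five vertices is a Micro Subtree (trivial
#' vascular structure) and is removed.
#'
#' @param subtrees list of subtrees from [splitSubtrees()].
#' @return the preserved subtrees.
#' @export
pruneMicro <- function(subtrees) {
  if (!length(subtrees)) return(subtrees)
  keep <- vapply(subtrees, function(s) length(s$vertices) > 5, TRUE)
  out <- subtrees[keep]
  if (!length(out))
    stop("all subtrees are Micro Subtrees; lower the radius threshold theta")
  out
}

# k-means++ initial centres: first centre uniform, subsequent centres drawn
# with probability proportional to the squared distance to the nearest
# chosen centre.
.kmeansppInit <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ], `-`)^2)
  for (j in seq_len(k - 1) + 1) {
    if (sum(d2) == 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ], `-`)^2))
  }
  centers
}

#' Cluster Second-Subtree roots into blood-supply branch groups
#'
#' k-means (Lloyd iterations) with k-means++ initialisation on the physical
#' 3D coordinates of the preserved subtree roots; 10 restarts, best
#' within-cluster sum of squares kept, fixed seed for reproducibility. All
#' vertices and skeleton voxels of a subtree inherit its cluster label
#' (vessels of one subtree supply one functional segment). Clusters are
#' relabelled by ascending first-subtree index so labels are deterministic.
#'
#' @param t the [VesselTree-class] the subtrees came from.
#' @param subtrees preserved subtrees (see [pruneMicro()]).
#' @param K number of branch groups; 8 for the Couinaud segments. Lowered
#'   with a warning when fewer subtrees are available.
#' @param seed integer RNG seed (default 0).
#' @param nstart number of k-means++ restarts.
#' @return A [BranchDivision-class].
#' @export
clusterBranches <- function(t, subtrees, K = 8L, seed = 0L, nstart = 10L) {
  stopifnot(length(subtrees) >= 1)
  if (length(subtrees) < K) {
    warning(sprintf("only %d subtrees; lowering K from %d", length(subtrees), K))
    K <- length(subtrees)
  }
  v <- t@vertices
  roots <- vapply(subtrees, function(s) s$root, 0L)
  X <- as.matrix(v[match(roots, v$id), c("x", "y", "z")])
  res <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- .kmeansppInit(X, K)
      km <- suppressWarnings(
        kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) best <- km
    }
    best
  })
  labels <- as.integer(res$cluster)
  # deterministic label order: clusters numbered by first occurrence
  uniq <- unique(labels)
  labels2 <- match(labels, uniq)
  centers <- res$centers[uniq, , drop = FALSE]
  new("BranchDivision", tree = t, subtrees = subtrees,
      labels = as.integer(labels2), K = as.integer(K), centers = centers)
}
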