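#' Select the root of the vascular graph
#'
#' The root is the end-voxel maximising \code{radius(v) +
#' meanRadius(incident edge)}: the main portal trunk enters the liver as the
#' thickest terminal branch. Ties resolve to the smallest linear voxel
#' index.
#'
#' @param g a [TopoGraph-class] with at least one end-voxel.
#' @return integer vertex id.
#' @export
selectRoot <- function(g) {
  v <- g@vertices; e <- g@edges
  ends <- v[v$kind == "end", , drop = FALSE]
  if (nrow(ends) == 0)
    stop("graph has no end-voxel (pure loop); prune cyclic branches first or supply a root manually")
  score <- vapply(ends$id, function(id) {
    inc <- e[e$from == id | e$to == id, , drop = FALSE]
    mr <- if (nrow(inc)) max(inc$meanRadius) else 0
    ends$radius[ends$id == id] + mr
  }, 0)
  best <- which(score == max(score))
  if (length(best) > 1) {
    lin <- .coordToLin(as.matrix(ends[best, c("vx", "vy", "vz")]), g@dim)
    best <- best[which.min(lin)]
  }
  as.integer(ends$id[best])
}

#' Orient a topological graph from a root by breadth-first search
#'
#' Every edge reached along the BFS tree is directed parent-to-child;
#' neighbours are expanded in ascending vertex-id order so orientation is
#' deterministic. Edges that connect two already-discovered vertices close a
#' cycle and are flagged \code{cyclic} (directed from the earlier-discovered
#' endpoint); self-loops are flagged cyclic as well.
#'
#' @param g a connected [TopoGraph-class].
#' @param root integer vertex id (see [selectRoot()]).
#' @return A [VesselGraph-class].
#' @export
orientGraph <- function(g, root) {
  v <- g@vertices; e <- g@edges
  stopifnot(root %in% v$id)
  n <- nrow(v)
  # adjacency: vertex -> incident edge rows
  inc <- lapply(v$id, function(id) which(e$from == id | e$to == id))
  names(inc) <- as.character(v$id)
  order_ <- rep(NA_integer_, n); names(order_) <- as.character(v$id)
  order_[as.character(root)] <- 1L
  cnt <- 1L
  queue <- root
  usedEdge <- rep(FALSE, nrow(e))
  newFrom <- e$from; newTo <- e$to
  cyclic <- rep(FALSE, nrow(e))
  flipped <- rep(FALSE, nrow(e))
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ei <- inc[[as.character(cur)]]
    if (!length(ei)) next
    # deterministic: sort by the opposite vertex id, then edge id
    opp <- ifelse(e$from[ei] == cur, e$to[ei], e$from[ei])
    o <- order(opp, ei)
    for (k in o) {
      edgeRow <- ei[k]
      if (usedEdge[edgeRow]) next
      other <- opp[k]
      if (other == cur) {                       # self-loop
        usedEdge[edgeRow] <- TRUE
        cyclic[edgeRow] <- TRUE
        next
      }
      if (is.na(order_[as.character(other)])) { # tree edge
        usedEdge[edgeRow] <- TRUE
        cnt <- cnt + 1L
        order_[as.character(other)] <- cnt
        if (e$from[edgeRow] != cur) {
          newFrom[edgeRow] <- cur; newTo[edgeRow] <- other; flipped[edgeRow] <- TRUE
        }
        queue <- c(queue, other)
      } else {                                  # closes a cycle
        usedEdge[edgeRow] <- TRUE
        cyclic[edgeRow] <- TRUE
        a <- e$from[edgeRow]; b <- e$to[edgeRow]
        if (order_[as.character(a)] > order_[as.character(b)]) {
          newFrom[edgeRow] <- b; newTo[edgeRow] <- a; flipped[edgeRow] <- TRUE
        }
      }
    }
  }
  if (any(is.na(order_)))
    stop("graph is disconnected; select a component before orienting")
  e$from <- newFrom; e$to <- newTo; e$cyclic <- cyclic
  paths <- g@paths
  for (k in which(flipped)) paths[[k]] <- paths[[k]][rev(seq_len(nrow(paths[[k]]))), , drop = FALSE]
  new("VesselGraph", vertices = v, edges = e, paths = paths,
      spacing = g@spacing, dim = g@dim, root = as.integer(root))
}

#' Remove redundant branches
#'
#' Deletes self-loop edges and spur (leaf) branches whose every interior
#' path voxel shares one nearest topological vertex (nearest in physical
#' distance over all graph vertices, ties to the lower vertex id; vacuously
#' true for spurs with no interior voxel). Such branches duplicate structure
#' already represented by a junction. The root's incident edges are never
#' removed, and vertices left isolated are dropped.
#'
#' @param g a [VesselGraph-class].
#' @return A pruned [VesselGraph-class].
#' @export
removeRedundant <- function(g) {
  v <- g@vertices; e <- g@edges; paths <- g@paths
  if (!nrow(e)) return(g)
  drop <- e$from == e$to                        # self-loops
  deg <- table(factor(c(e$from, e$to), levels = v$id))
  vpos <- as.matrix(v[, c("x", "y", "z")])
  nearestVertex <- function(coords) {
    # coords: voxel coordinate matrix
    pp <- .physical(coords, g@spacing)
    vapply(seq_len(nrow(pp)), function(r) {
      d2 <- rowSums(sweep(vpos, 2, pp[r, ], `-`)^2)
      v$id[which.min(d2)]                       # which.min: lowest id on ties
    }, 0L)
  }
  for (k in seq_len(nrow(e))) {
    if (drop[k]) next
    a <- e$from[k]; b <- e$to[k]
    if (a == g@root || b == g@root) next
    leaf <- (deg[as.character(a)] == 1) || (deg[as.character(b)] == 1)
    if (!leaf) next
    p <- paths[[k]]
    interior <- p[-c(1, nrow(p)), , drop = FALSE]
    if (nrow(interior) == 0) { drop[k] <- TRUE; next }
    nv <- nearestVertex(interior)
    if (length(unique(nv)) == 1) drop[k] <- TRUE
  }
  e2 <- e[!drop, , drop = FALSE]
  paths2 <- paths[!drop]
  keepV <- v$id %in% c(e2$from, e2$to, g@root)
  new("VesselGraph", vertices = v[keepV, , drop = FALSE], edges = e2,
      paths = paths2, spacing = g@spacing, dim = g@dim, root = g@root)
}

# Minimum-|Diff| subset of cyclic outflow radii at one ramification:
# Diff = rIn^2 - sum(rOutNoncyclic^2) - sum(rComb^2). Exhaustive over 2^m
# subsets for m <= cap, greedy largest-first beyond. Ties: smaller |Diff|,
# then fewer edges, then lexicographically smallest index set.
.bestCyclicSubset <- function(rIn, rOutNoncyclic, rCyclic, cap = 16L) {
  m <- length(rCyclic)
  target <- rIn^2 - sum(rOutNoncyclic^2)
  if (m == 0) return(integer(0))
  if (m > cap) {
    warning(sprintf("%d cyclic candidates exceed the enumeration cap; using greedy matching", m))
    ord <- order(-rCyclic, seq_along(rCyclic))
    pick <- logical(m); acc <- 0
    for (i in ord) {
      if (abs(target - (acc + rCyclic[i]^2)) < abs(target - acc)) {
        pick[i] <- TRUE; acc <- acc + rCyclic[i]^2
      }
    }
    return(which(pick))
  }
  best <- NULL; bestDiff <- Inf; bestSize <- Inf
  for (s in 0:(2^m - 1)) {
    sel <- which(bitwAnd(s, bitwShiftL(1L, seq_len(m) - 1L)) > 0)
    d <- abs(target - sum(rCyclic[sel]^2))
    better <- d < bestDiff - 1e-12 ||
      (abs(d - bestDiff) <= 1e-12 && length(sel) < bestSize)
    if (better) { best <- sel; bestDiff <- d; bestSize <- length(sel) }
  }
  best
}

#' Remove irrelevant cyclic branches by inflow-outflow matching
#'
#' At each ramification vertex (processed in BFS order from the root) the
#' blood inflow must match the outflow; flow is approximated by the squared
#' mean radius (cross-sectional area). Among the cyclic-flagged outflow
#' candidates at the vertex, the subset minimising \code{|rIn^2 -
#' sum(rOutNoncyclic^2) - sum(rComb^2)|} is kept (exhaustive enumeration up
#' to \code{cap} candidates, greedy beyond, with a warning) and the rest are
#' deleted as irrelevant. Kept cyclic edges may still close a cycle across
#' junctions; any residual cycle is broken at its smallest-mean-radius edge.
#' The result is re-oriented from the root and returned as a strict tree.
#'
#' @param g a [VesselGraph-class] with cyclic edges flagged (see
#'   [orientGraph()]).
#' @param cap maximum number of cyclic candidates enumerated exhaustively
#'   per ramification (default 16).
#' @return A [VesselTree-class].
#' @export
removeIrrelevant <- function(g, cap = 16L) {
  v <- g@vertices; e <- g@edges; paths <- g@paths
  keep <- rep(TRUE, nrow(e))
  if (nrow(e)) {
    # BFS order of vertices over tree (non-cyclic) edges
    bfsOrder <- .bfsVertexOrder(v$id, e[!e$cyclic, c("from", "to")], g@root)
    for (cur in bfsOrder) {
      incCyc <- which(keep & e$cyclic & (e$from == cur | e$to == cur) & e$from != e$to)
      if (!length(incCyc)) next
      eIn <- which(keep & !e$cyclic & e$to == cur)
      rIn <- if (length(eIn)) max(e$meanRadius[eIn]) else {
        vrow <- v[v$id == cur, ]
        vrow$radius[1]                      # root ramification: vertex radius
      }
      eOutN <- which(keep & !e$cyclic & e$from == cur)
      sel <- .bestCyclicSubset(rIn, e$meanRadius[eOutN], e$meanRadius[incCyc], cap)
      dropIdx <- setdiff(seq_along(incCyc), sel)
      keep[incCyc[dropIdx]] <- FALSE
      # kept cyclic edges at this vertex become ordinary outflow branches
      e$cyclic[incCyc[sel]] <- FALSE
      flip <- incCyc[sel][e$to[incCyc[sel]] == cur]
      if (length(flip)) {
        tmp <- e$from[flip]; e$from[flip] <- e$to[flip]; e$to[flip] <- tmp
        for (k in flip) paths[[k]] <- paths[[k]][rev(seq_len(nrow(paths[[k]]))), , drop = FALSE]
      }
    }
  }
  keep[e$from == e$to] <- FALSE            # any remaining self-loops
  e2 <- e[keep, , drop = FALSE]; paths2 <- paths[keep]

  # break residual cycles at the smallest-mean-radius edge: BFS from the
  # root builds a spanning tree; each non-tree edge closes exactly one
  # fundamental cycle (the edge plus the tree paths of its endpoints to
  # their common ancestor), and the weakest edge on that cycle is dropped.
  repeat {
    if (!nrow(e2)) break
    bt <- .bfsTree(v$id, e2, g@root)
    if (!length(bt$nonTree)) break
    k <- bt$nonTree[1]
    if (e2$from[k] == e2$to[k]) {
      cycleEdges <- k
    } else {
      pathUp <- function(vid) {
        eds <- integer(0)
        while (!is.na(bt$parentEdge[[as.character(vid)]])) {
          pe <- bt$parentEdge[[as.character(vid)]]
          eds <- c(eds, pe)
          vid <- if (e2$from[pe] == vid) e2$to[pe] else e2$from[pe]
        }
        eds
      }
      ua <- pathUp(e2$from[k]); ub <- pathUp(e2$to[k])
      cycleEdges <- c(k, setdiff(union(ua, ub), intersect(ua, ub)))
    }
    kdrop <- cycleEdges[which.min(e2$meanRadius[cycleEdges])]
    e2 <- e2[-kdrop, , drop = FALSE]
    paths2 <- paths2[-kdrop]
  }

  # keep the component containing the root, re-orient
  keepV <- .reachableVertices(v$id, e2[, c("from", "to")], g@root)
  selE <- e2$from %in% keepV & e2$to %in% keepV
  g2 <- new("TopoGraph",
            vertices = v[v$id %in% keepV, , drop = FALSE],
            edges = {
              e3 <- e2[selE, , drop = FALSE]
              e3$cyclic <- FALSE
              e3
            },
            paths = paths2[selE], spacing = g@spacing, dim = g@dim)
  oriented <- orientGraph(g2, g@root)
  tree <- new("VesselTree", vertices = oriented@vertices, edges = oriented@edges,
              paths = oriented@paths, spacing = oriented@spacing,
              dim = oriented@dim, root = oriented@root)
  validObject(tree)
  computeAngles(tree)
}

# BFS spanning tree over undirected edge rows: per-vertex parent edge row
# index (NA at the root / unreached) and the row indices of non-tree edges.
.bfsTree <- function(ids, e2, root) {
  parentEdge <- as.list(rep(NA_integer_, length(ids)))
  names(parentEdge) <- as.character(ids)
  seen <- setNames(rep(FALSE, length(ids)), as.character(ids))
  usedEdge <- rep(FALSE, nrow(e2))
  nonTree <- integer(0)
  seen[as.character(root)] <- TRUE
  queue <- root
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    ei <- which(e2$from == cur | e2$to == cur)
    opp <- ifelse(e2$from[ei] == cur, e2$to[ei], e2$from[ei])
    for (k in order(opp, ei)) {
      row <- ei[k]
      if (usedEdge[row]) next
      usedEdge[row] <- TRUE
      other <- opp[k]
      if (other == cur || seen[as.character(other)]) {
        nonTree <- c(nonTree, row)
      } else {
        seen[as.character(other)] <- TRUE
        parentEdge[[as.character(other)]] <- row
        queue <- c(queue, other)
      }
    }
  }
  list(parentEdge = parentEdge, nonTree = sort(nonTree))
}

.bfsVertexOrder <- function(ids, ft, root) {
  seen <- root; queue <- root
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nxt <- sort(unique(c(ft$to[ft$from == cur], ft$from[ft$to == cur])))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt); queue <- c(queue, nxt)
  }
  seen
}

.reachableVertices <- function(ids, ft, root) {
  .bfsVertexOrder(ids, ft, root)
}

#' Annotate edges with branching angles
#'
#' For every non-root edge, the angle (degrees, in \[0, 180\]) between its
#' chord (straight line from its parent vertex to its child vertex) and the
#' chord of its parent edge at the shared vertex. Edges leaving the root
#' have no parent edge and keep \code{NA}; zero-length chords give \code{NA}
#' as well.
#'
#' @param t a [VesselTree-class].
#' @return the tree with the \code{angle} edge column filled.
#' @export
computeAngles <- function(t) {
  v <- t@vertices; e <- t@edges
  if (!nrow(e)) return(t)
  pos <- as.matrix(v[, c("x", "y", "z")])
  rownames(pos) <- as.character(v$id)
  chord <- pos[as.character(e$to), , drop = FALSE] - pos[as.character(e$from), , drop = FALSE]
  parentEdge <- match(e$from, e$to)        # incoming edge of the from-vertex
  ang <- rep(NA_real_, nrow(e))
  for (k in seq_len(nrow(e))) {
    pk <- parentEdge[k]
    if (is.na(pk)) next
    a <- chord[pk, ]; b <- chord[k, ]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) next
    ang[k] <- acos(pmin(pmax(sum(a * b) / (na * nb), -1), 1)) * 180 / pi
  }
  e$angle <- ang
  t@edges <- e
  t
}
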