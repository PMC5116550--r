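# Phantom builders local to the test-suite.

# a random vessel-tree spec on a small grid; geometry is drawn from a local
# deterministic RNG so specs are reproducible by seed without touching the
# session RNG state
randomTreeSpec <- function(seed, nNodes = 6, shape = c(36, 36, 36)) {
  state <- as.double((seed %% 2147483646) + 1)
  unif <- function() {
    state <<- (16807 * state) %% 2147483647
    state / 2147483647
  }
  lo <- 5; hi <- shape - 6
  nodes <- data.frame(id = 1L,
                      x = lo + unif() * (hi[1] - lo),
                      y = lo + unif() * (hi[2] - lo),
                      z = lo + unif() * (hi[3] - lo))
  edges <- NULL
  for (k in 2:nNodes) {
    parent <- floor(unif() * (k - 1)) + 1
    ang <- unif() * 2 * pi; elev <- (unif() - 0.5) * pi
    len <- 6 + unif() * 8
    p <- as.numeric(nodes[parent, c("x", "y", "z")])
    q <- p + len * c(cos(ang) * cos(elev), sin(ang) * cos(elev), sin(elev))
    q <- pmin(pmax(q, lo), hi)
    nodes <- rbind(nodes, data.frame(id = k, x = q[1], y = q[2], z = q[3]))
    edges <- rbind(edges, data.frame(parent = parent, child = k,
                                     radius = 1.2 + unif() * 1.3))
  }
  TreeSpec(nodes, edges, spacing = c(1, 1, 1), shape = shape,
           seed = as.integer(seed))
}

# a tiny fixed Y-shaped spec with well-separated limbs
ySpec <- function(shape = c(48, 48, 48)) {
  TreeSpec(
    nodes = data.frame(id = 1:4,
                       x = c(24, 24, 10, 38),
                       y = c(24, 24, 24, 24),
                       z = c(5, 21, 39, 39)),
    edges = data.frame(parent = c(1, 2, 2), child = c(2, 3, 4),
                       radius = c(2.5, 2, 2)),
    spacing = c(1, 1, 1), shape = shape, seed = 0L)
}
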