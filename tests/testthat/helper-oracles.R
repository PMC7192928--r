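# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops, parent-pointer climbs and hand quantiles.

# WE per cell: per-taxon 1/R tally
oracle_we <- function(comm) {
  p <- comm$presence
  R <- colSums(p)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    v <- 0
    for (j in seq_len(ncol(p))) if (p[i, j]) v <- v + 1 / R[j]
    out[i] <- v
  }
  names(out) <- rownames(p)
  out
}

# tips under one edge's child, by recursive descent on the raw edge matrix
oracle_edge_tips <- function(tree, child) {
  ntip <- length(tree$tip.label)
  if (child <= ntip) return(tree$tip.label[child])
  kids <- tree$edge[tree$edge[, 1] == child, 2]
  unlist(lapply(kids, oracle_edge_tips, tree = tree))
}

# PE per cell: enumerate each resident's path to the root, union the edges,
# sum L_i / R_i with R_i from an independent per-edge tip union
oracle_pe <- function(comm, tree, normalized = TRUE) {
  p <- comm$presence
  ntip <- length(tree$tip.label)
  L <- tree$edge.length
  if (normalized) L <- L / sum(L)
  # R_i per edge
  Re <- integer(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    tips <- oracle_edge_tips(tree, tree$edge[e, 2])
    tips <- intersect(tips, colnames(p))
    occ_cells <- character(0)
    for (tp in tips) occ_cells <- union(occ_cells, rownames(p)[p[, tp]])
    Re[e] <- length(occ_cells)
  }
  # parent edge of each node
  edge_above <- function(node) which(tree$edge[, 2] == node)
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    edges <- integer(0)
    for (tp in intersect(colnames(p)[p[i, ]], tree$tip.label)) {
      node <- match(tp, tree$tip.label)
      repeat {
        e <- edge_above(node)
        if (!length(e)) break
        edges <- union(edges, e)
        node <- tree$edge[e, 1]
      }
    }
    out[i] <- sum(L[edges] / Re[edges])
  }
  names(out) <- rownames(p)
  out
}

# sort-and-cut hotspot oracle with a hand-rolled type-7 quantile and the
# ties-at-threshold-included rule
oracle_hotspots <- function(values, occupied, prob) {
  v <- sort(values[occupied])
  n <- length(v)
  h <- (n - 1) * (1 - prob / 100) + 1
  lo <- floor(h)
  thr <- v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  names(values)[occupied & values >= thr]
}

# brute-force autocovariate: all-pairs Manhattan neighbourhood scan
oracle_autocov <- function(values, grid, order, weighting) {
  ids <- as.integer(names(values))
  r <- ids %/% grid$n_cols
  c <- ids %% grid$n_cols
  out <- numeric(length(values))
  for (i in seq_along(values)) {
    s <- 0; sw <- 0
    for (j in seq_along(values)) {
      d <- abs(r[j] - r[i]) + abs(c[j] - c[i])
      if (d == 0 || d > order) next
      w <- if (weighting == "equal") 1
           else 1 / (sqrt((r[j] - r[i])^2 + (c[j] - c[i])^2) * grid$grain)
      s <- s + w * values[j]; sw <- sw + w
    }
    out[i] <- if (sw > 0) s / sw else 0
  }
  names(out) <- names(values)
  out
}

# BFS connectivity of a cell set on rook adjacency (contiguity oracle)
oracle_connected <- function(cells, n_rows, n_cols) {
  if (length(cells) <= 1) return(TRUE)
  cells <- sort(as.integer(cells))
  seen <- cells[1]
  queue <- cells[1]
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    r <- cur %/% n_cols; c <- cur %% n_cols
    nb <- c(if (r > 0) cur - n_cols, if (r < n_rows - 1) cur + n_cols,
            if (c > 0) cur - 1, if (c < n_cols - 1) cur + 1)
    nxt <- setdiff(intersect(nb, cells), seen)
    seen <- c(seen, nxt)
    queue <- c(queue, nxt)
  }
  length(seen) == length(cells)
}

# random community on an nr x nc grid: each taxon gets a random non-empty
# cell set (not necessarily contiguous; contiguity is irrelevant to metrics)
random_comm <- function(nr, nc, n_taxa, taxa = sprintf("t%03d", seq_len(n_taxa))) {
  g <- endem_grid(nr, nc)
  n <- nr * nc
  ranges <- lapply(seq_len(n_taxa), function(i) {
    size <- sample.int(n, 1)
    sample.int(n, size) - 1L
  })
  names(ranges) <- taxa
  list(comm = ranges_to_community(ranges, g), grid = g)
}
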