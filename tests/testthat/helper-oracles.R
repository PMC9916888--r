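# Independent brute-force oracles used to validate the segmentation and
# merging implementations, plus small fixture builders.

# Flood-fill connected-component labeling by explicit BFS.
bf_label <- function(fg, connectivity = 8) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  k <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (!fg[rr, cc] || lab[rr, cc] > 0L) next
    k <- k + 1L
    queue <- list(c(rr, cc))
    lab[rr, cc] <- k
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in seq_len(nrow(nbr))) {
        r2 <- p[1] + nbr[d, 1]; c2 <- p[2] + nbr[d, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            fg[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- k
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# Canonicalize a label matrix to first-occurrence (raster) order so two
# labelings of the same partition compare equal.
canon_labels <- function(lab) {
  u <- unique(lab[lab > 0L])
  map <- integer(max(c(u, 1L)))
  map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# All-pairs transitive-closure clustering at strict distance <_ min_d.
bf_cluster <- function(pts, min_d) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  adj <- as.matrix(stats::dist(pts)) < min_d
  diag(adj) <- TRUE
  grp <- rep(0L, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (grp[i] > 0L) next
    k <- k + 1L
    frontier <- i
    grp[i] <- k
    while (length(frontier) > 0) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & grp == 0L)
      grp[nxt] <- k
      frontier <- nxt
    }
  }
  grp
}

# Partition induced by merge_min_distance, as group ids per input point.
merge_partition <- function(pts, min_d) {
  det <- merge_min_distance(pts, min_d)
  grp <- integer(nrow(pts))
  for (k in seq_len(nrow(det))) grp[det$segment_ids[[k]]] <- k
  grp
}

# Same partition up to relabeling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(match(a, unique(a)), match(b, unique(b)))
}

# A filled disk mask of radius r centred in a (2r+margin) square.
disk_mask <- function(r, margin = 6) {
  n <- 2 * r + margin
  ctr <- (n + 1) / 2
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
  m
}

# A one-pixel-wide cross with arm half-length L, centred.
cross_mask <- function(L, margin = 6) {
  n <- 2 * L + margin
  ctr <- as.integer((n + 1) / 2)
  m <- matrix(FALSE, n, n)
  m[ctr, (ctr - L):(ctr + L)] <- TRUE
  m[(ctr - L):(ctr + L), ctr] <- TRUE
  m
}

# Small fast field spec for simulation-heavy tests.
tiny_nuclei_spec <- function(seed, n_cells = 100, shape = c(360, 360))
  field_spec(image_shape = shape, n_cells = n_cells, min_spacing_px = 20,
             soma_radius_px = 3, seed = seed)
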