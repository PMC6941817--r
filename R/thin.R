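# Binary thinning and skeleton path extraction.
# No installed R package provides morphological thinning, and the ordered
# one-pixel center line is the backbone of the whole coordinate system, so it
# is implemented here: Zhang-Suen two-subiteration thinning followed by
# longest-geodesic path tracing over the 8-connected skeleton graph.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Zhang-Suen binary thinning
#'
#' Reduces a binary mask to a one-pixel-wide 8-connected skeleton.
#' @param mask logical or 0/1 matrix
#' @return logical matrix of the same shape
#' @export
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  # neighbour order P2..P9: N, NE, E, SE, S, SW, W, NW (row 1 = top)
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- lapply(offs, function(o) shift_mat(m, -o[1], -o[2]))
      B <- Reduce(`+`, nb)
      seqn <- c(nb, nb[1])
      A <- Reduce(`+`, lapply(1:8, function(i) {
        (seqn[[i]] == 0L) * (seqn[[i + 1]] == 1L)
      }))
      if (sub == 1) {
        c1 <- nb[[1]] * nb[[3]] * nb[[5]] == 0L
        c2 <- nb[[3]] * nb[[5]] * nb[[7]] == 0L
      } else {
        c1 <- nb[[1]] * nb[[3]] * nb[[7]] == 0L
        c2 <- nb[[1]] * nb[[5]] * nb[[7]] == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Longest geodesic path over the skeleton pixel graph. Returns an n x 2
# matrix of (row, col) 1-based pixel indices ordered along the path, or NULL
# for degenerate skeletons.
skeleton_path <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(NULL)
  if (n == 1) return(idx)
  nr <- nrow(skel)
  key <- (idx[, 2] - 1L) * nr + idx[, 1]
  pos <- integer(nrow(skel) * ncol(skel))
  pos[key] <- seq_len(n)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  # adjacency lists (guard against column wrap by checking row difference)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- key[i] + offs
    ok <- cand >= 1 & cand <= length(pos)
    cand <- cand[ok]
    hit <- pos[cand]
    hit <- hit[hit > 0]
    # reject wrapped neighbours (row distance must be <= 1)
    hit <- hit[abs(idx[hit, 1] - idx[i, 1]) <= 1 & abs(idx[hit, 2] - idx[i, 2]) <= 1]
    nbrs[[i]] <- hit
  }
  deg <- lengths(nbrs)
  ends <- which(deg == 1L)
  if (length(ends) == 0) ends <- which.min(deg)  # loop fallback
  bfs <- function(start) {
    dist <- rep(NA_integer_, n); par <- integer(n)
    dist[start] <- 0L
    queue <- start; qi <- 1L
    while (qi <= length(queue)) {
      u <- queue[qi]; qi <- qi + 1L
      for (v in nbrs[[u]]) {
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + 1L
          par[v] <- u
          queue <- c(queue, v)
        }
      }
    }
    list(dist = dist, par = par)
  }
  best <- NULL; bestlen <- -1L
  for (e in ends) {
    b <- bfs(e)
    far <- which.max(b$dist)
    if (b$dist[far] > bestlen) {
      bestlen <- b$dist[far]
      best <- list(from = e, to = far, par = b$par)
    }
  }
  path <- integer(0)
  v <- best$to
  while (v != best$from) {
    path <- c(v, path)
    v <- best$par[v]
  }
  path <- c(best$from, path)
  idx[path, , drop = FALSE]
}
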