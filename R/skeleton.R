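# Topology-preserving thinning (Zhang-Suen) and branch-graph decomposition.
# Everything operates on logical matrices indexed [row, col], 0-based
# coordinates reported to the user, 8-connectivity throughout.

shift_mat <- function(m, dr, dc) {
  # neighbor view: out[r, c] = m[r + dr, c + dc], FALSE outside the grid
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# 8-neighbourhood in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
.zs_offsets <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                     dc = c(0, 1, 1, 1, 0, -1, -1, -1))

thin_zhang_suen <- function(m, max_iter = 10000L) {
  m <- m != 0
  repeat_count <- 0L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P <- lapply(seq_len(8L), function(k)
        shift_mat(m, .zs_offsets[k, 1], .zs_offsets[k, 2]))
      B <- Reduce(`+`, P)
      # A = number of 0->1 transitions around the ring P2..P9..P2
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in seq_len(8L)) {
        nxt <- if (k == 8L) 1L else k + 1L
        A <- A + (!P[[k]] & P[[nxt]])
      }
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (sub == 1L) {
        cond <- cond & !(P[[1]] & P[[3]] & P[[5]]) &
                       !(P[[3]] & P[[5]] & P[[7]])
      } else {
        cond <- cond & !(P[[1]] & P[[3]] & P[[7]]) &
                       !(P[[1]] & P[[5]] & P[[7]])
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    repeat_count <- repeat_count + 1L
    if (!changed || repeat_count >= max_iter) break
  }
  m
}

prune_redundant <- function(m) {
  # Reduce the thinned set to a minimal 8-connected curve: a pixel whose
  # foreground neighbours form a single mutually 8-connected component in
  # the punctured 3x3 neighbourhood is redundant (Zhang-Suen's crossing
  # number misses these diagonal staircase pixels, which would otherwise
  # masquerade as junctions). Endpoints are kept.
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (i in which(m)) {
      r <- ((i - 1L) %% nr) + 1L
      c <- ((i - 1L) %/% nr) + 1L
      rr <- r + .zs_offsets[, 1]; cc <- c + .zs_offsets[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nb <- which(ok)[m[cbind(rr[ok], cc[ok])]]
      k <- length(nb)
      if (k < 2L) next
      # single-linkage components of the neighbours under 8-adjacency
      pr <- .zs_offsets[nb, 1, drop = FALSE]
      pc <- .zs_offsets[nb, 2, drop = FALSE]
      comp <- seq_len(k)
      for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
        if (max(abs(pr[a] - pr[b]), abs(pc[a] - pc[b])) <= 1L) {
          old <- comp[b]; comp[comp == old] <- comp[a]
        }
      if (length(unique(comp)) == 1L) {
        m[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

neighbor_count <- function(m) {
  m <- m != 0
  acc <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_len(8L))
    acc <- acc + shift_mat(m, .zs_offsets[k, 1], .zs_offsets[k, 2])
  acc
}

#' Skeletonize a binary vessel mask into a branch graph
#'
#' Thins the mask to a one-pixel-wide, 8-connected centerline with
#' Zhang-Suen topology-preserving thinning, then decomposes the skeleton
#' into branches between nodes. Nodes are endpoint pixels (exactly one
#' skeleton neighbour) and junction clusters (8-connected groups of pixels
#' with three or more neighbours). Each branch records its ordered pixel
#' path, its path length (sum of unit/sqrt(2) steps, in pixels) and its
#' chord length (Euclidean distance between the branch's two terminal
#' pixel centres). Isolated cycles are returned as branches with chord 0.
#'
#' @param mask a [binary_mask()] or logical matrix with at least one TRUE.
#' @return object of class `skeleton_graph`: list with `skeleton_mask`
#'   (logical matrix), `branches` (list of `path` n x 2 matrix of 0-based
#'   (row, col), `path_length`, `chord_length`, `is_loop`), `nodes`
#'   (data.frame of 0-based `row`, `col`, `type` in endpoint/junction), and
#'   `pixel_size` when the input carried one.
#' @export
skeletonize <- function(mask) {
  pixel_size <- NULL
  if (inherits(mask, "binary_mask")) {
    pixel_size <- mask$pixel_size
    mask <- mask$mask
  }
  mask <- as_logical_mask(mask, "mask")
  if (!any(mask)) stop("empty mask: nothing to skeletonize", call. = FALSE)
  skel <- prune_redundant(thin_zhang_suen(mask))
  g <- decompose_skeleton(skel)
  structure(list(skeleton_mask = skel, branches = g$branches,
                 nodes = g$nodes, pixel_size = pixel_size),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d skeleton px, %d branches, %d nodes\n",
              sum(x$skeleton_mask), length(x$branches), nrow(x$nodes)))
  invisible(x)
}

#' Count junction clusters of a skeleton graph
#'
#' Adjacent junction pixels (8-connectivity) belong to one anatomical
#' junction; this counts the clusters, which is what "number of junction
#' nodes" means for structures wider than one pixel.
#'
#' @param skeleton a [skeletonize()] result.
#' @return integer count of junction clusters.
#' @export
n_junctions <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  j <- skeleton$nodes[skeleton$nodes$type == "junction", , drop = FALSE]
  if (nrow(j) == 0L) return(0L)
  # single-linkage clustering under Chebyshev distance <= 1
  n <- nrow(j)
  comp <- seq_len(n)
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (max(abs(j$row[a] - j$row[b]), abs(j$col[a] - j$col[b])) <= 1L) {
      old <- comp[b]; new <- comp[a]
      comp[comp == old] <- new
    }
  }
  length(unique(comp))
}

smoothed_path_length <- function(r, c, window = 5L) {
  # Raw chain-code length overestimates smooth curves by the staircase
  # effect (up to ~8%). A short moving average of the interior vertices,
  # endpoints fixed, removes most of the bias while leaving straight
  # digital lines exact.
  n <- length(r)
  if (n > window) {
    half <- window %/% 2L
    sm <- function(v) {
      cs <- cumsum(c(0, v))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      out[1L] <- v[1L]; out[n] <- v[n]
      out
    }
    r <- sm(r); c <- sm(c)
  }
  sum(sqrt(diff(r)^2 + diff(c)^2))
}

decompose_skeleton <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  idx <- which(skel)
  n <- length(idx)
  id_of <- matrix(0L, nr, nc)
  id_of[idx] <- seq_len(n)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L

  # adjacency lists over the 8-neighbourhood
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    rr <- rows[i] + .zs_offsets[, 1]
    cc <- cols[i] + .zs_offsets[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    ids <- id_of[cbind(rr[ok], cc[ok])]
    nbrs[[i]] <- ids[ids > 0L]
  }
  deg <- lengths(nbrs)
  is_node <- deg != 2L           # endpoints (1), junctions (>=3), isolated (0)

  node_type <- ifelse(deg[is_node] >= 3L, "junction",
                      ifelse(deg[is_node] == 1L, "endpoint", "isolated"))
  nodes <- data.frame(row = rows[is_node] - 1L, col = cols[is_node] - 1L,
                      type = node_type, stringsAsFactors = FALSE)

  step_len <- function(a, b)
    sqrt((rows[a] - rows[b])^2 + (cols[a] - cols[b])^2)

  branches <- list()
  # visited marks traversal of degree-2 corridor pixels and node-node edges
  visited_px <- rep(FALSE, n)
  edge_seen <- new.env(hash = TRUE, parent = emptyenv())
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))

  add_branch <- function(path_ids, is_loop = FALSE) {
    path <- cbind(row = rows[path_ids] - 1L, col = cols[path_ids] - 1L)
    plen <- if (length(path_ids) < 2L) 0 else
      smoothed_path_length(rows[path_ids], cols[path_ids])
    chord <- if (is_loop) 0 else
      step_len(path_ids[1L], path_ids[length(path_ids)])
    branches[[length(branches) + 1L]] <<-
      list(path = path, path_length = plen, chord_length = chord,
           is_loop = is_loop)
  }

  node_ids <- which(is_node)
  for (s in node_ids) {
    for (nb in nbrs[[s]]) {
      if (is_node[nb]) {
        # direct node-node adjacency: a minimal branch, except between two
        # junction pixels, which belong to one junction cluster
        if (deg[s] >= 3L && deg[nb] >= 3L) next
        key <- edge_key(s, nb)
        if (!exists(key, envir = edge_seen)) {
          assign(key, TRUE, envir = edge_seen)
          add_branch(c(s, nb))
        }
      } else if (!visited_px[nb]) {
        # walk the degree-2 corridor until the next node
        path <- c(s, nb)
        visited_px[nb] <- TRUE
        prev <- s; cur <- nb
        repeat {
          nxt <- setdiff(nbrs[[cur]], prev)
          if (length(nxt) == 0L) break            # dangling (shouldn't occur)
          nxt <- nxt[1L]
          path <- c(path, nxt)
          if (is_node[nxt]) break
          if (visited_px[nxt]) break               # loop back into the path
          visited_px[nxt] <- TRUE
          prev <- cur; cur <- nxt
        }
        last <- path[length(path)]
        add_branch(path, is_loop = !is_node[last] || last == s)
      }
    }
  }
  # pure cycles: degree-2 pixels never reached from any node
  for (i in seq_len(n)) {
    if (deg[i] == 2L && !visited_px[i]) {
      path <- c(i)
      visited_px[i] <- TRUE
      prev <- i; cur <- nbrs[[i]][1L]
      while (cur != i && !visited_px[cur]) {
        visited_px[cur] <- TRUE
        path <- c(path, cur)
        nxt <- setdiff(nbrs[[cur]], prev)[1L]
        prev <- cur; cur <- nxt
      }
      path <- c(path, i)  # close the ring
      add_branch(path, is_loop = TRUE)
    }
  }
  list(branches = branches, nodes = nodes)
}
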