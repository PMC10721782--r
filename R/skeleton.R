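# Topological skeletonization (Zhang-Suen thinning) and decomposition of
# the skeleton into ordered branches: the "profile curve" of the vessel
# diameter pipeline.

shift_mat <- function(M, dr, dc) {
  # out[r, c] = M[r + dr, c + dc], FALSE outside
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) && length(cs)) out[rs, cs] <- M[rs + dr, cs + dc]
  out
}

# neighbor order P2..P9: N, NE, E, SE, S, SW, W, NW (row index grows down)
zs_offsets <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                    c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))

#' Thin a binary mask to its topological skeleton
#'
#' Zhang-Suen two-subiteration thinning; iterates to convergence. The
#' result is an 8-connected curve one pixel wide (up to the algorithm's
#' standard staircase artifacts).
#'
#' @param mask `binary_mask`, logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  m <- as_mask_array(mask) != 0
  if (!is.matrix(m)) stop("mask must be 2D", call. = FALSE)
  img <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  img[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      P <- lapply(seq_len(8L), function(i)
        shift_mat(img, zs_offsets[i, 1L], zs_offsets[i, 2L]))
      B <- Reduce(`+`, P)
      A <- Reduce(`+`, lapply(seq_len(8L), function(i) {
        j <- if (i == 8L) 1L else i + 1L
        (!P[[i]]) & P[[j]]
      }))
      if (step == 1L) {
        c3 <- !(P[[1L]] & P[[3L]] & P[[5L]])   # P2*P4*P6 == 0
        c4 <- !(P[[3L]] & P[[5L]] & P[[7L]])   # P4*P6*P8 == 0
      } else {
        c3 <- !(P[[1L]] & P[[3L]] & P[[7L]])   # P2*P4*P8 == 0
        c4 <- !(P[[1L]] & P[[5L]] & P[[7L]])   # P2*P6*P8 == 0
      }
      del <- img & B >= 2 & B <= 6 & A == 1 & c3 & c4
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE]
}

# Adjacency list over skeleton pixels. Redundant diagonal links (a diagonal
# pair that also shares an orthogonal skeleton neighbor) are dropped so that
# staircase pixels do not masquerade as junctions.
skeleton_adjacency <- function(skel) {
  idx <- which(skel)
  n <- length(idx)
  pos <- integer(length(skel)); pos[idx] <- seq_len(n)
  rc <- arrayInd(idx, dim(skel))
  nr <- nrow(skel); ncl <- ncol(skel)
  at <- function(r, c) {
    ok <- r >= 1L & r <= nr & c >= 1L & c <= ncl
    out <- integer(length(r))
    out[ok] <- pos[(c[ok] - 1L) * nr + r[ok]]
    out
  }
  adj <- vector("list", n)
  for (k in seq_len(8L)) {
    o <- zs_offsets[k, ]
    nb <- at(rc[, 1L] + o[1L], rc[, 2L] + o[2L])
    hit <- nb > 0L
    if (!any(hit)) next
    if (all(o != 0L)) {
      # diagonal: skip if the two shared orthogonal cells contain skeleton
      a1 <- at(rc[, 1L] + o[1L], rc[, 2L])
      a2 <- at(rc[, 1L], rc[, 2L] + o[2L])
      hit <- hit & a1 == 0L & a2 == 0L
    }
    for (i in which(hit)) adj[[i]] <- c(adj[[i]], nb[i])
  }
  list(adj = adj, coords = rc, index = idx)
}

# Decompose a skeleton into ordered branches between terminals (pixels of
# degree != 2). Returns list of integer vectors of node ids plus node info.
trace_branch_paths <- function(adjinfo) {
  adj <- adjinfo$adj
  n <- length(adj)
  deg <- lengths(adj)
  terminal <- deg != 2L
  edge_seen <- new.env(hash = TRUE, parent = emptyenv())
  mark <- function(a, b) assign(paste(min(a, b), max(a, b)), TRUE, envir = edge_seen)
  is_marked <- function(a, b) !is.null(edge_seen[[paste(min(a, b), max(a, b))]])

  paths <- list()
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    mark(start, nxt)
    prev <- start; cur <- nxt
    while (!terminal[cur]) {
      nbrs <- adj[[cur]]
      nxt2 <- nbrs[nbrs != prev]
      if (length(nxt2) == 0L) break          # isolated loop end
      nxt2 <- nxt2[1L]
      if (is_marked(cur, nxt2)) break
      mark(cur, nxt2)
      path <- c(path, nxt2)
      prev <- cur; cur <- nxt2
      if (cur == start) break                # closed cycle
    }
    path
  }
  for (v in which(terminal)) {
    for (nb in adj[[v]]) {
      if (!is_marked(v, nb)) paths[[length(paths) + 1L]] <- walk(v, nb)
    }
  }
  # pure cycles with no terminal
  for (v in seq_len(n)) {
    if (deg[v] == 2L) {
      for (nb in adj[[v]]) {
        if (!is_marked(v, nb)) paths[[length(paths) + 1L]] <- walk(v, nb)
      }
    }
  }
  list(paths = paths, degree = deg, terminal = terminal)
}

path_arclength <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

# Remove skeleton spurs: branches shorter than prune_px with at least one
# free end (degree-1 terminal). Iterates until stable.
prune_spurs <- function(skel, prune_px) {
  repeat {
    adjinfo <- skeleton_adjacency(skel)
    if (length(adjinfo$adj) <= 1L) return(skel)
    tb <- trace_branch_paths(adjinfo)
    if (!length(tb$paths)) return(skel)
    removed <- FALSE
    for (p in tb$paths) {
      coords <- adjinfo$coords[p, , drop = FALSE]
      len <- path_arclength(coords)
      d1 <- tb$degree[p[1L]]; d2 <- tb$degree[p[length(p)]]
      if (len < prune_px && (d1 == 1L || d2 == 1L) && !(d1 == 1L && d2 == 1L)) {
        # drop all pixels except the junction-side end
        keep_end <- if (d1 == 1L) length(p) else 1L
        drop <- p[-keep_end]
        skel[adjinfo$index[drop]] <- FALSE
        removed <- TRUE
        break  # topology changed; recompute
      }
    }
    if (!removed) return(skel)
  }
}

#' Ordered vessel centerline
#'
#' A set of ordered branches of subpixel (y, x) points (0-based pixel
#' coordinates) with per-point cumulative arclength, optional unit tangents,
#' and the junction coordinates where branches meet.
#'
#' @param branches List of n-by-2 numeric matrices (columns y, x), each with
#'   at least 2 points and consecutive point spacing at most 2 px.
#' @param junctions Optional m-by-2 matrix of junction coordinates.
#' @return Object of class `centerline`.
#' @export
centerline <- function(branches, junctions = NULL) {
  stopifnot(is.list(branches), length(branches) >= 1L)
  br <- lapply(branches, function(b) {
    b <- as.matrix(b)
    if (nrow(b) < 2L) stop("every branch needs >= 2 points", call. = FALSE)
    steps <- sqrt(rowSums(diff(b)^2))
    if (any(steps > 2 + 1e-9))
      stop("consecutive centerline points more than 2 px apart", call. = FALSE)
    list(points = b, arclength = c(0, cumsum(steps)), tangents = NULL)
  })
  structure(list(branches = br, junctions = junctions), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  lens <- vapply(x$branches, function(b) max(b$arclength), 0)
  cat(sprintf("<centerline> %d branch(es), arclengths %s px\n",
              length(x$branches), paste(signif(lens, 4), collapse = ", ")))
  invisible(x)
}

# moving-average smoothing of branch points (one-sided at the ends);
# suppresses the staircase of the pixel chain so arclengths approach the
# Euclidean length and tangents stabilize. End points are kept fixed.
smooth_branch <- function(pts, window) {
  n <- nrow(pts)
  if (window < 2L || n < 3L) return(pts)
  half <- floor(window / 2)
  out <- pts
  for (i in seq_len(n)) {
    w <- max(1L, i - half):min(n, i + half)
    out[i, ] <- colMeans(pts[w, , drop = FALSE])
  }
  out
}

#' Extract the centerline of a vessel mask
#'
#' Thins the mask to its topological skeleton, prunes spurs shorter than
#' `prune_px`, decomposes the remaining skeleton into ordered branches
#' between endpoints/junctions, and smooths each branch with a short moving
#' average so the subpixel arclength is not inflated by the pixel-chain
#' staircase.
#'
#' @param mask `binary_mask` or 0/1 matrix.
#' @param prune_px Spur-pruning length in pixels.
#' @param smooth_window Moving-average window in points (0 or 1 disables).
#' @return A [centerline()].
#' @export
extract_centerline <- function(mask, prune_px = 5, smooth_window = 5) {
  m <- as_mask_array(mask)
  if (sum(m) == 0L) stop("empty mask", call. = FALSE)
  skel <- thin_mask(m)
  if (sum(skel) <= 1L) stop("vessel too small", call. = FALSE)
  skel <- prune_spurs(skel, prune_px)
  if (sum(skel) <= 1L) stop("vessel too small", call. = FALSE)
  adjinfo <- skeleton_adjacency(skel)
  tb <- trace_branch_paths(adjinfo)
  if (!length(tb$paths)) stop("vessel too small", call. = FALSE)
  branches <- lapply(tb$paths, function(p)
    smooth_branch(adjinfo$coords[p, , drop = FALSE] - 1, smooth_window))
  branches <- Filter(function(b) nrow(b) >= 2L, branches)
  if (!length(branches)) stop("vessel too small", call. = FALSE)
  junc <- adjinfo$coords[tb$degree >= 3L, , drop = FALSE] - 1
  centerline(branches, junctions = if (nrow(junc)) junc else NULL)
}

#' Estimate unit tangents along a centerline
#'
#' The tangent at each point is the principal direction (first principal
#' component) of the centered points inside a window of +/- `window_px`
#' arclength around it; endpoints use the one-sided window that remains.
#' Tangents are unit-norm and sign-oriented along increasing arclength.
#'
#' @param cl A [centerline()].
#' @param window_px Half-window in pixels of arclength.
#' @return The centerline with a `tangents` matrix (columns dy, dx) per
#'   branch.
#' @export
estimate_tangents <- function(cl, window_px = 5) {
  stopifnot(inherits(cl, "centerline"))
  cl$branches <- lapply(cl$branches, function(b) {
    pts <- b$points; s <- b$arclength
    n <- nrow(pts)
    tang <- matrix(0, n, 2L)
    for (i in seq_len(n)) {
      w <- which(abs(s - s[i]) <= window_px)
      if (length(w) < 2L) {
        w <- unique(pmin(pmax(c(i - 1L, i, i + 1L), 1L), n))
      }
      X <- sweep(pts[w, , drop = FALSE], 2L, colMeans(pts[w, , drop = FALSE]))
      ev <- eigen(crossprod(X), symmetric = TRUE)
      v <- ev$vectors[, 1L]
      chord <- pts[w[length(w)], ] - pts[w[1L], ]
      if (sum(v * chord) < 0) v <- -v
      tang[i, ] <- v / sqrt(sum(v^2))
    }
    b$tangents <- tang
    b
  })
  cl
}
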