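# Connected-component labeling for 2D (8-connectivity) and 3D
# (26-connectivity) binary grids, built on the voxel adjacency graph.

#' Label connected components of a binary grid
#'
#' Foreground pixels/voxels (nonzero) are grouped into connected components
#' under full connectivity: 8-connectivity in 2D, 26-connectivity in 3D.
#' Labels are assigned in scan order of each component's first element.
#'
#' @param arr Logical/0-1 matrix or 3D array.
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(arr) {
  dims <- dim(arr)
  if (is.null(dims) || !length(dims) %in% c(2L, 3L))
    stop("arr must be a matrix or 3D array", call. = FALSE)
  out <- array(0L, dims)
  fg <- which(arr != 0)
  if (!length(fg)) return(out)

  # half set of neighbor offsets (lexicographically positive) so each
  # adjacent pair is generated once
  offs <- as.matrix(expand.grid(rep(list(-1:1), length(dims))))
  keep <- apply(offs, 1L, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1L]] > 0
  })
  offs <- offs[keep, , drop = FALSE]

  pos <- integer(prod(dims))       # foreground index lookup
  pos[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dims)
  strides <- cumprod(c(1L, dims[-length(dims)]))

  from <- integer(0); to <- integer(0)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- coords + matrix(o, nrow(coords), length(dims), byrow = TRUE)
    ok <- rep(TRUE, nrow(nb))
    for (d in seq_along(dims)) ok <- ok & nb[, d] >= 1L & nb[, d] <= dims[d]
    if (!any(ok)) next
    lin <- as.integer((nb[ok, , drop = FALSE] - 1L) %*% strides) + 1L
    hit <- pos[lin] > 0L
    if (!any(hit)) next
    from <- c(from, which(ok)[hit])
    to <- c(to, pos[lin[hit]])
  }

  if (length(from)) {
    g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  # renumber in scan order of first occurrence
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  out[fg] <- relab[memb]
  out
}

#' Sizes of labeled components
#'
#' @param lab Integer label array from [label_components()].
#' @return Integer vector of component sizes, indexed by label.
#' @export
component_sizes <- function(lab) {
  tabulate(lab[lab > 0L])
}
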