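#' Connection matrix from filtered fibers
#'
#' \eqn{M(i, j)} counts the fibers whose endpoint labels are \{i, j\} with
#' \eqn{i \ne j}; fibers linking an ROI to itself are discarded and the
#' diagonal is zero. The matrix is symmetric by construction.
#'
#' @param fibers a `streamline_set` with `endpoint_labels` filled (i.e.
#'   after [filter_fibers()]).
#' @param roi_ids integer vector of ROI labels defining the matrix order.
#' @return An object of class `connection_matrix`: an N x N integer matrix
#'   with `roi_ids` as dimnames and attributes `n_fibers` (fibers counted
#'   into the upper triangle) and `n_self` (discarded self-pairs).
#' @export
build_connection_matrix <- function(fibers, roi_ids) {
  labs <- fibers$endpoint_labels
  if (is.null(labs)) stop("fiber set has no endpoint labels; filter first")
  roi_ids <- as.integer(roi_ids)
  n <- length(roi_ids)
  M <- matrix(0L, n, n, dimnames = list(roi_ids, roi_ids))
  n_self <- 0L
  if (nrow(labs)) {
    unknown <- setdiff(unique(as.vector(labs)), roi_ids)
    if (length(unknown))
      stop("endpoint label not in roi_ids: ", paste(unknown, collapse = ", "))
    i <- match(labs[, 1], roi_ids)
    j <- match(labs[, 2], roi_ids)
    self <- i == j
    n_self <- sum(self)
    if (any(!self)) {
      lo <- pmin(i[!self], j[!self])
      hi <- pmax(i[!self], j[!self])
      tab <- table(factor(paste(lo, hi), levels = unique(paste(lo, hi))))
      key <- strsplit(names(tab), " ")
      for (k in seq_along(tab)) {
        a <- as.integer(key[[k]][1]); b <- as.integer(key[[k]][2])
        M[a, b] <- M[a, b] + as.integer(tab[k])
        M[b, a] <- M[a, b]
      }
    }
  }
  structure(M, class = c("connection_matrix", class(M)),
            n_fibers = sum(M[upper.tri(M)]), n_self = n_self)
}

#' @export
print.connection_matrix <- function(x, ...) {
  cat(sprintf("<connection_matrix: %d ROIs, %d fibers, %d connections>\n",
              nrow(x), attr(x, "n_fibers"), count_connections(x)))
  invisible(x)
}

#' Geodesic connection-distance matrix
#'
#' \eqn{d(i, j)} is the shortest path between ROIs i and j confined to the
#' white-matter volume: a graph is built over WM voxel centers with
#' 26-neighborhood edges weighted by the physical center-to-center distance,
#' each ROI attaches through the WM voxels 6-adjacent to any of its labeled
#' voxels, and multi-source shortest paths give the ROI-to-ROI distances
#' (`Inf` where no white-matter path exists).
#'
#' @param wm_mask logical 3-D array.
#' @param roi_labels integer 3-D array.
#' @param voxel_size mm 3-vector.
#' @return An N x N `distance_matrix` (mm) with ROI labels as dimnames.
#' @export
geodesic_distance_matrix <- function(wm_mask, roi_labels, voxel_size) {
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  dm <- dim(wm_mask)
  wm_idx <- which(wm_mask)
  nwm <- length(wm_idx)
  node_of <- integer(prod(dm))
  node_of[wm_idx] <- seq_len(nwm)
  ijk <- arrayInd(wm_idx, dm)
  # 26-neighborhood edges (13 forward offsets to avoid duplicates)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  ei <- ej <- ew <- list()
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dm[1] + (nb[ok, 3] - 1) * dm[1] * dm[2]
    tgt <- node_of[lin]
    src <- which(ok)[tgt > 0]
    tgt <- tgt[tgt > 0]
    ei[[k]] <- src; ej[[k]] <- tgt
    ew[[k]] <- rep(sqrt(sum((offs[k, ] * voxel_size)^2)), length(src))
  }
  g <- igraph::graph_from_edgelist(cbind(unlist(ei), unlist(ej)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nwm - igraph::vcount(g)))
  igraph::E(g)$weight <- unlist(ew)

  roi_ids <- sort(setdiff(unique(as.vector(roi_labels)), 0L))
  n <- length(roi_ids)
  # source set per ROI: WM voxels 6-adjacent to any voxel with that label
  offs6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  sources <- lapply(roi_ids, function(lab) {
    rv <- arrayInd(which(roi_labels == lab), dm)
    hits <- integer(0)
    for (k in 1:6) {
      nb <- sweep(rv, 2, offs6[k, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 &
        nb[, 2] <= dm[2] & nb[, 3] >= 1 & nb[, 3] <= dm[3]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dm[1] +
        (nb[ok, 3] - 1) * dm[1] * dm[2]
      hits <- c(hits, node_of[lin])
    }
    sort(unique(hits[hits > 0]))
  })
  D <- matrix(Inf, n, n, dimnames = list(roi_ids, roi_ids))
  diag(D) <- 0
  empty <- lengths(sources) == 0
  if (any(empty))
    warning("ROI(s) without WM-adjacent voxels: ",
            paste(roi_ids[empty], collapse = ", "))
  for (a in seq_len(n - 1)) {
    if (empty[a]) next
    dist_a <- igraph::distances(g, v = sources[[a]], algorithm = "dijkstra")
    mins <- apply(dist_a, 2, min)
    for (b in seq(a + 1, n)) {
      if (empty[b]) next
      D[a, b] <- D[b, a] <- min(mins[sources[[b]]])
    }
  }
  structure(D, class = c("distance_matrix", class(D)))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix: %d ROIs, finite range %.1f-%.1f mm>\n",
              nrow(x), min(x[upper.tri(x) & is.finite(x)]),
              max(x[upper.tri(x) & is.finite(x)])))
  invisible(x)
}

#' Number of connections above a fiber threshold
#'
#' A connection is an unordered ROI pair linked by at least `n_f` fibers
#' (default 1).
#'
#' @param M a `connection_matrix`.
#' @param n_f minimum fiber count per connection.
#' @return integer count of pairs i < j with `M[i, j] >= n_f`.
#' @export
count_connections <- function(M, n_f = 1L) {
  if (n_f < 1) stop("n_f must be >= 1")
  sum(M[upper.tri(M)] >= n_f)
}

#' Distance-binned connection counts
#'
#' Accumulates each connection (pair with `M >= n_f`) into the bin of its
#' geodesic distance. Bins are half-open `[lo, hi)`; the last bin is closed.
#' Pairs with infinite distance are reported separately.
#'
#' @param M a `connection_matrix`.
#' @param D a `distance_matrix` over the same ROIs.
#' @param bin_edges increasing numeric vector of bin edges in mm
#'   (default the 0-50/50-100/100-200 mm categories).
#' @param n_f minimum fiber count per connection.
#' @return list with `counts` (named per bin), `unreachable` and `outside`
#'   (finite distances falling outside the binned range).
#' @export
distance_distribution <- function(M, D, bin_edges = c(0, 50, 100, 200),
                                  n_f = 1L) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  if (!identical(dim(M), dim(D)))
    stop("M and D must share ROI ids")
  up <- upper.tri(M)
  sel <- up & M >= n_f
  d <- D[sel]
  nb <- length(bin_edges) - 1
  counts <- integer(nb)
  names(counts) <- paste0(bin_edges[-length(bin_edges)], "-",
                          bin_edges[-1], "mm")
  fin <- is.finite(d)
  b <- findInterval(d[fin], bin_edges, rightmost.closed = TRUE)
  inside <- b >= 1 & b <= nb
  tb <- table(factor(b[inside], levels = seq_len(nb)))
  counts[] <- as.integer(tb)
  list(counts = counts, unreachable = sum(!fin),
       outside = sum(fin) - sum(inside))
}

#' Write/read a matrix as headered CSV (ROI ids as header row and column)
#' @param M matrix with ROI-id dimnames.
#' @param path CSV path.
#' @return `write_matrix_csv`: invisibly the path; `read_matrix_csv`: the
#'   matrix.
#' @export
write_matrix_csv <- function(M, path) {
  df <- data.frame(roi = rownames(M), as.data.frame(unclass(M)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  M
}
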