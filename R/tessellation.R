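#' Sphere tessellation for ODF discretization
#'
#' Builds an antipodally complete unit-sphere tessellation by repeated
#' midpoint subdivision of the regular icosahedron (whose vertex set is
#' centrally symmetric, a property subdivision preserves). The default
#' subdivision order 3 gives 642 vertices (1280 triangular faces) with a
#' typical edge of about 8 degrees.
#'
#' @param subdiv non-negative integer subdivision order.
#' @return An object of class `sphere_tess` with components `vertices`
#'   (n x 3 unit vectors), `faces` (m x 3 vertex indices), `neighbors`
#'   (list of integer neighbor indices per vertex), `antipode` (index of
#'   each vertex's antipode) and `edge_deg` (maximum edge arc in degrees).
#' @export
sphere_tessellation <- function(subdiv = 3L) {
  stopifnot(subdiv >= 0, subdiv == round(subdiv))
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  p, 0), c(1,  p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1,  p), c(0, 1,  p), c(0, -1, -p), c(0, 1, -p),
    c( p, 0, -1), c(p, 0,  1), c(-p, 0, -1), c(-p, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2])
    uniq <- !duplicated(key)
    ue <- edges[uniq, , drop = FALSE]
    mid <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    midx <- stats::setNames(nv + seq_len(nrow(ue)), key[uniq])
    v <- rbind(v, mid)
    m12 <- midx[paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2]))]
    m23 <- midx[paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3]))]
    m13 <- midx[paste(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3]))]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(m12, f[, 2], m23),
               cbind(m13, m23, f[, 3]),
               cbind(m12, m23, m13))
    dimnames(f) <- NULL
  }
  n <- nrow(v)
  nb <- vector("list", n)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    nb[[a]] <- c(nb[[a]], b, cc)
    nb[[b]] <- c(nb[[b]], a, cc)
    nb[[cc]] <- c(nb[[cc]], a, b)
  }
  nb <- lapply(nb, function(x) sort(unique(x)))
  # antipode lookup: centrally symmetric vertex set, match -v to v
  ant <- integer(n)
  keyv <- apply(round(v, 9), 1, paste, collapse = ",")
  lookup <- stats::setNames(seq_len(n), keyv)
  ant <- unname(lookup[apply(round(-v, 9), 1, paste, collapse = ",")])
  if (anyNA(ant)) stop("tessellation not antipodally complete")
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  edge_deg <- max(acos(pmin(1, rowSums(v[e[, 1], ] * v[e[, 2], ]))) * 180 / pi)
  structure(list(vertices = v, faces = f, neighbors = nb,
                 antipode = ant, edge_deg = edge_deg),
            class = "sphere_tess")
}

#' @export
print.sphere_tess <- function(x, ...) {
  cat(sprintf("<sphere_tess: %d vertices, %d faces, max edge %.1f deg>\n",
              nrow(x$vertices), nrow(x$faces), x$edge_deg))
  invisible(x)
}

#' Export a tessellation as plain-text vertex and face lists
#' @param tess a `sphere_tess`.
#' @param vertices_path,faces_path output paths (whitespace-separated text).
#' @return invisibly, the two paths.
#' @export
write_tessellation <- function(tess, vertices_path, faces_path) {
  utils::write.table(tess$vertices, vertices_path, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(tess$faces, faces_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(vertices_path, faces_path))
}
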