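#' Symmetric sphere tessellation with quadrature weights
#'
#' Icosahedron subdivided `subdiv` times and projected to the unit sphere.
#' The mesh is centrally symmetric: every vertex has an exact antipodal
#' partner. Per-vertex quadrature weights are one third of the spherical
#' area of the adjacent triangles (L'Huilier), summing to 4*pi.
#'
#' @param subdiv subdivision level (2 gives 162 vertices, 3 gives 642).
#' @return List of class `sphere_mesh` with `vertices` (n x 3),
#'   `triangles` (m x 3, 1-based), `neighbors` (n x max-degree, 0-based,
#'   -1 padded), `weights`, and 0-based `antipode` indices.
#' @export
sphere_mesh <- function(subdiv = 3L) {
  key <- paste0("mesh", subdiv)
  cached <- .tractfd_cache[[key]]
  if (!is.null(cached)) return(cached)

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newf <- matrix(0L, 0, 3)
    vlist <- list(v)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- edge_mid[[k]]
      if (!is.null(id)) return(id)
      m <- v[a, ] + v[b, ]
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1]] <<- matrix(m, 1)
      nv <<- nv + 1L
      edge_mid[[k]] <- nv
      nv
    }
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }

  n <- nrow(v)
  # antipodal partner (exact by construction, matched numerically)
  ant <- integer(n)
  for (i in seq_len(n)) {
    d <- rowSums(sweep(v, 2, -v[i, ], "-")^2)
    ant[i] <- which.min(d) - 1L
  }
  # adjacency
  nbl <- vector("list", n)
  for (t in seq_len(nrow(f))) {
    tr <- f[t, ]
    for (j in 1:3) {
      nbl[[tr[j]]] <- c(nbl[[tr[j]]], tr[-j])
    }
  }
  nbl <- lapply(nbl, function(x) sort(unique(x)) - 1L)
  deg <- max(lengths(nbl))
  nb <- matrix(-1L, n, deg)
  for (i in seq_len(n)) nb[i, seq_along(nbl[[i]])] <- nbl[[i]]

  # spherical triangle areas by L'Huilier, 1/3 to each corner vertex
  w <- numeric(n)
  for (t in seq_len(nrow(f))) {
    tr <- f[t, ]
    a <- acos(pmin(1, pmax(-1, sum(v[tr[2], ] * v[tr[3], ]))))
    b <- acos(pmin(1, pmax(-1, sum(v[tr[1], ] * v[tr[3], ]))))
    cc <- acos(pmin(1, pmax(-1, sum(v[tr[1], ] * v[tr[2], ]))))
    s <- (a + b + cc) / 2
    ex <- 4 * atan(sqrt(pmax(0, tan(s / 2) * tan((s - a) / 2) *
                               tan((s - b) / 2) * tan((s - cc) / 2))))
    w[tr] <- w[tr] + ex / 3
  }

  mesh <- structure(list(vertices = v, triangles = f, neighbors = nb,
                         weights = w, antipode = ant, subdiv = subdiv),
                    class = "sphere_mesh")
  assign(key, mesh, envir = .tractfd_cache)
  mesh
}

.tractfd_cache <- new.env(parent = emptyenv())

#' @export
print.sphere_mesh <- function(x, ...) {
  cat("sphere_mesh:", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles (subdiv", x$subdiv, ")\n")
  invisible(x)
}

#' Hemisphere representatives of a symmetric mesh
#'
#' One vertex per antipodal pair (z > 0, ties by y then x), used as the
#' constraint direction set for deconvolution.
#'
#' @param mesh a [sphere_mesh()].
#' @return Integer (1-based) vertex indices, about half the vertex count.
#' @export
mesh_hemisphere <- function(mesh) {
  v <- mesh$vertices
  keep <- v[, 3] > 1e-9 |
    (abs(v[, 3]) <= 1e-9 & (v[, 2] > 1e-9 |
                              (abs(v[, 2]) <= 1e-9 & v[, 1] > 0)))
  which(keep)
}
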