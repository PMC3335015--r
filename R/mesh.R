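#' Build a toy two-hemisphere surface mesh
#'
#' Constructs a closed, connected, sphere-like triangulation with
#' `nVertices` vertices per hemisphere, as a small stand-in for a cortical
#' surface. Each hemisphere is a stacked-ring (antiprism) triangulation of
#' the sphere: two poles plus rings of equal size, with the ring size chosen
#' as the divisor of `nVertices - 2` closest to its square root. With
#' `nVertices = 12` this reproduces the icosahedron combinatorics (every
#' vertex of degree 5). Any closed triangulation satisfies V - E + F = 2 and
#' has mean degree 6 - 12/V, i.e. approximately 6.
#'
#' The topology is fully determined by `nVertices`; the seed only applies a
#' small deterministic random rotation and radial jitter to the coordinates
#' so that repeated calls with the same seed are bit-identical.
#'
#' @param nVertices vertices per hemisphere, at least 12.
#' @param seed integer seed for the coordinate jitter.
#' @return A [SurfaceMesh-class] with `2 * nVertices` vertices.
#' @examples
#' mesh <- buildToyMesh(150, seed = 1)
#' nVertices(mesh)
#' @export
buildToyMesh <- function(nVertices = 150L, seed = 1L) {
  nVertices <- as.integer(nVertices)
  if (is.na(nVertices) || nVertices < 12L)
    stop("nVertices must be an integer >= 12")

  hemi <- .hemisphereTriangulation(nVertices)
  nv <- nVertices

  coords <- .withSeed(as.integer(seed), {
    # deterministic random rotation + tiny radial jitter; topology untouched
    rot <- qr.Q(qr(matrix(rnorm(9L), 3L, 3L)))
    if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
    radii <- 1 + runif(nv, -0.02, 0.02)
    (hemi$coords * radii) %*% rot
  })

  left <- coords
  left[, 1L] <- left[, 1L] - 2
  right <- coords
  right[, 1L] <- right[, 1L] + 2

  new("SurfaceMesh",
      coordinates = rbind(left, right),
      faces = rbind(hemi$faces, hemi$faces + nv),
      hemisphere = factor(rep(c("left", "right"), each = nv),
                          levels = c("left", "right")))
}

# ring-stacked closed triangulation of the sphere with exactly n vertices:
# 2 poles + r rings of m vertices, m * r == n - 2
.hemisphereTriangulation <- function(n) {
  m <- .ringSize(n - 2L)
  r <- (n - 2L) %/% m

  theta <- pi * seq_len(r) / (r + 1)              # polar angle per ring
  coords <- matrix(0, nrow = n, ncol = 3L)
  coords[1L, ] <- c(0, 0, 1)                       # north pole
  coords[n, ] <- c(0, 0, -1)                       # south pole
  idx <- function(ring, j) 1L + (ring - 1L) * m + ((j - 1L) %% m) + 1L
  for (ring in seq_len(r)) {
    phi <- 2 * pi * (seq_len(m) - 1L) / m + (ring - 1L) * pi / m
    coords[idx(ring, seq_len(m)), ] <- cbind(sin(theta[ring]) * cos(phi),
                                             sin(theta[ring]) * sin(phi),
                                             cos(theta[ring]))
  }

  faces <- matrix(0L, nrow = 0L, ncol = 3L)
  # north cap
  faces <- rbind(faces, cbind(1L, idx(1L, seq_len(m)), idx(1L, seq_len(m) + 1L)))
  # ring bands, antiprism split of each quad
  if (r > 1L) {
    for (ring in seq_len(r - 1L)) {
      a <- idx(ring, seq_len(m)); b <- idx(ring, seq_len(m) + 1L)
      c_ <- idx(ring + 1L, seq_len(m)); d <- idx(ring + 1L, seq_len(m) + 1L)
      faces <- rbind(faces, cbind(a, c_, b), cbind(b, c_, d))
    }
  }
  # south cap
  faces <- rbind(faces,
                 cbind(n, idx(r, seq_len(m) + 1L), idx(r, seq_len(m))))
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  list(coords = coords, faces = faces)
}

# divisor of k closest to sqrt(k), at least 3; falls back to k itself
# (bipyramid) when k has no divisor in [3, k)
.ringSize <- function(k) {
  divs <- which(k %% seq_len(k) == 0L)
  divs <- divs[divs >= 3L]
  if (!length(divs)) stop("cannot triangulate this vertex count")
  divs[which.min(abs(divs - sqrt(k)))]
}

#' @describeIn buildToyMesh edge list of a mesh (unique unordered vertex
#'   pairs appearing in faces), as a two-column integer matrix.
#' @param mesh a [SurfaceMesh-class].
#' @export
meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

.meshGraph <- function(mesh) {
  e <- meshEdges(mesh)
  len <- sqrt(rowSums((mesh@coordinates[e[, 1L], , drop = FALSE] -
                       mesh@coordinates[e[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- len
  g
}

#' Geodesic (graph) distances between mesh vertices
#'
#' Shortest-path distances along mesh edges, weighted by Euclidean edge
#' length. Vertices in different hemispheres are at infinite distance.
#'
#' @param mesh a [SurfaceMesh-class].
#' @return A dense numeric matrix of distances.
#' @export
meshDistances <- function(mesh) {
  igraph::distances(.meshGraph(mesh))
}

#' Smooth per-vertex values on the mesh surface
#'
#' Convolves per-vertex values with a Gaussian kernel in graph geodesic
#' distance, the surface analogue of volumetric Gaussian blurring. The
#' kernel weight for vertex pair (i, j) is proportional to
#' `exp(-d_ij^2 / (2 * sigma^2))` with `sigma = fwhm / (2 * sqrt(2 * log 2))`,
#' and each vertex's weights are normalized to sum to one, so constant maps
#' are reproduced exactly. The impulse response therefore falls to half its
#' maximum at geodesic distance `fwhm / 2`. `fwhm = 0` returns the input
#' unchanged.
#'
#' @param values numeric vector of length `nVertices(mesh)`, or a matrix
#'   with that many rows (each column smoothed independently).
#' @param mesh a [SurfaceMesh-class].
#' @param fwhm kernel full width at half maximum, in mesh distance units.
#' @return Smoothed values, same shape as the input.
#' @examples
#' mesh <- buildToyMesh(52, seed = 1)
#' smoothOnMesh(rep(3.3, nVertices(mesh)), mesh, fwhm = 0.5)[1:3]
#' @export
smoothOnMesh <- function(values, mesh, fwhm) {
  K <- smoothingOperator(mesh, fwhm)
  if (is.matrix(values)) {
    stopifnot(nrow(values) == nrow(K))
    K %*% values
  } else {
    stopifnot(length(values) == nrow(K))
    drop(K %*% values)
  }
}

#' @describeIn smoothOnMesh the row-normalized smoothing operator itself
#'   (vertices x vertices). `fwhm = NA` resolves to twice the mesh's mean
#'   edge length (the configuration default).
#' @export
smoothingOperator <- function(mesh, fwhm) {
  if (length(fwhm) != 1L || (!is.na(fwhm) && (!is.numeric(fwhm) || fwhm < 0)))
    stop("fwhm must be a single number >= 0 (or NA for the default)")
  if (is.na(fwhm)) {
    e <- meshEdges(mesh)
    len <- sqrt(rowSums((mesh@coordinates[e[, 1L], , drop = FALSE] -
                         mesh@coordinates[e[, 2L], , drop = FALSE])^2))
    fwhm <- 2 * mean(len)
  }
  nv <- nVertices(mesh)
  if (fwhm == 0) return(diag(nv))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- meshDistances(mesh)
  W <- exp(-(d^2) / (2 * sigma^2))
  W[is.infinite(d)] <- 0       # never smooth across hemispheres
  W / rowSums(W)
}

#' Contiguous vertex cluster around a seed vertex
#'
#' Grows a cluster of `size` vertices by geodesic distance from a seed
#' vertex, staying within its hemisphere. Used to place the "affected"
#' region of the trajectory model.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param vertex seed vertex id.
#' @param size cluster size in vertices (including the seed).
#' @return Sorted integer vertex ids.
#' @export
clusterAroundVertex <- function(mesh, vertex, size) {
  vertex <- as.integer(vertex)
  size <- as.integer(size)
  nv <- nVertices(mesh)
  if (vertex < 1L || vertex > nv) stop("vertex outside the mesh")
  d <- meshDistances(mesh)[vertex, ]
  ok <- which(is.finite(d))
  if (size > length(ok)) stop("cluster size exceeds the hemisphere")
  sort(ok[order(d[ok], ok)][seq_len(size)])
}

#' @rdname cortdev-accessors
#' @export
setMethod("meshCoordinates", "SurfaceMesh", function(x) x@coordinates)

#' @rdname cortdev-accessors
#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

#' @rdname cortdev-accessors
#' @export
setMethod("hemisphere", "SurfaceMesh", function(x) x@hemisphere)

#' @rdname cortdev-accessors
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@coordinates))

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh with", nVertices(object), "vertices,",
      nrow(object@faces), "faces\n")
  cat("  per hemisphere:", paste(table(object@hemisphere), collapse = " / "),
      "(left / right)\n")
})
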