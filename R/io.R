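#' Read and write the pipeline's file dialects
#'
#' Plain-text formats: `phenotypes.csv` (columns exactly
#' `id,diagnosis,age,sex,hand,iq,slice_dummy,med_months`), `volumes.csv`
#' (`id` plus one snake_case column per measure), `thickness.tsv` (rows =
#' subjects in phenotype order, columns = vertices, tab-separated with a
#' header), and `mesh.off` (standard OFF vertex/face format; hemispheres
#' are recovered as the connected components, ordered by mean x
#' coordinate).
#'
#' @param phenotypes,volumetrics data.frames as produced by the generator.
#' @param thickness subjects x vertices matrix.
#' @param mesh a [SurfaceMesh-class].
#' @param path file path.
#' @name cortdev-io
NULL

#' @rdname cortdev-io
#' @export
writePhenotypes <- function(phenotypes, path) {
  cols <- c("id", "diagnosis", "age", "sex", "hand", "iq", "slice_dummy",
            "med_months")
  write.csv(phenotypes[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cortdev-io
#' @export
readPhenotypes <- function(path) {
  ph <- read.csv(path, stringsAsFactors = FALSE)
  ph$diagnosis <- factor(ph$diagnosis, levels = c("control", "adhd"))
  ph$sex <- factor(ph$sex, levels = c("male", "female"))
  ph$hand <- factor(ph$hand, levels = c("R", "L", "A"))
  ph
}

#' @rdname cortdev-io
#' @export
writeVolumetrics <- function(volumetrics, path) {
  write.csv(volumetrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cortdev-io
#' @export
readVolumetrics <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' @rdname cortdev-io
#' @export
writeThickness <- function(thickness, path) {
  write.table(thickness, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname cortdev-io
#' @export
readThickness <- function(path) {
  as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                       check.names = FALSE))
}

#' @rdname cortdev-io
#' @export
writeMeshOFF <- function(mesh, path) {
  nv <- nVertices(mesh)
  nf <- nrow(meshFaces(mesh))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nv, nf, nrow(meshEdges(mesh))), con)
  coords <- meshCoordinates(mesh)
  writeLines(sprintf("%.10g %.10g %.10g",
                     coords[, 1L], coords[, 2L], coords[, 3L]), con)
  f0 <- meshFaces(mesh) - 1L   # OFF faces are 0-based
  writeLines(sprintf("3 %d %d %d", f0[, 1L], f0[, 2L], f0[, 3L]), con)
  invisible(path)
}

#' @rdname cortdev-io
#' @export
readMeshOFF <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1L])) != "OFF") stop("not an OFF file")
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  coords <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                        quiet = TRUE), ncol = 3L, byrow = TRUE)
  fl <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)],
                                 collapse = "\n"), quiet = TRUE),
               ncol = 4L, byrow = TRUE)
  if (any(fl[, 1L] != 3L)) stop("only triangular faces are supported")
  faces <- matrix(as.integer(fl[, 2:4] + 1L), ncol = 3L)

  g <- igraph::graph_from_edgelist(
    rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)]),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  comps <- sort(unique(comp))
  mx <- vapply(comps, function(cc) mean(coords[comp == cc, 1L]), numeric(1))
  ord <- comps[order(mx)]
  labNames <- if (length(ord) == 2L) c("left", "right")
              else paste0("component", seq_along(ord))
  lab <- labNames[match(comp, ord)]
  new("SurfaceMesh", coordinates = coords, faces = faces,
      hemisphere = factor(lab, levels = labNames))
}
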