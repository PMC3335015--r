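#' Read a plain-text key = value run configuration
#'
#' Parses a flat `key = value` file into a named list, coercing numeric
#' values. Recognised keys mirror the [simConfig()] and analysis arguments
#' (`n_per_cell`, `age_min`, `age_max`, `n_vertices`, `fwhm`, `seed`,
#' `max_age`, `fdr_level`, `alpha`, `df_max`, `peak_shift`,
#' `intercept_offset`, `noise_sd`, `affected_cluster_size`). Unknown keys
#' are kept verbatim. Lines starting with `#` are comments.
#'
#' @param path configuration file path.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop("cannot parse config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

#' @describeIn readRunConfig write a named list back to the key = value
#'   format (round-trips losslessly for flat configurations).
#' @param config named list.
#' @export
writeRunConfig <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, character(1))), path)
  invisible(path)
}

.configValue <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Run the full simulate-analyze-report pipeline
#'
#' Orchestrates the three analysis stages end to end: (1) simulate a
#' cohort (phenotypes, volumetric table, thickness maps, toy mesh) and
#' write the plain-text artifacts; (2) the volumetric GLM battery
#' ([volumetricSummaryTable()] plus within-group IQ correlations);
#' (3) the vertexwise trajectory analysis ([vertexwiseAnalysis()]).
#' Every artifact, a run manifest (configuration echo, package version,
#' seed, per-stage status, file checksums) and a human-readable summary
#' are written under `outDir`. Re-running with the same configuration
#' reproduces all outputs bit-identically.
#'
#' @param config named list (see [readRunConfig()]) or a path to a
#'   configuration file.
#' @param outDir output directory (created if missing).
#' @param stages character subset of `c("simulate", "volumetrics",
#'   "vertexwise")`, in pipeline order. Later stages read the files written
#'   by earlier ones, so a partial run requires the earlier artifacts to
#'   exist in `outDir`.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = list(), outDir,
                        stages = c("simulate", "volumetrics",
                                   "vertexwise")) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  seed <- as.integer(.configValue(config, "seed", 1))
  manifest <- list(package = "cortdev",
                   version = as.character(packageVersion("cortdev")),
                   seed = seed, config = config, stages = list())
  paths <- list(phenotypes = file.path(outDir, "phenotypes.csv"),
                volumes = file.path(outDir, "volumes.csv"),
                thickness = file.path(outDir, "thickness.tsv"),
                mesh = file.path(outDir, "mesh.off"),
                table2 = file.path(outDir, "table2_like.tsv"),
                correlations = file.path(outDir, "iq_correlations.tsv"),
                vertexStats = file.path(outDir, "vertex_stats.tsv"),
                runSummary = file.path(outDir, "run_summary.json"),
                manifest = file.path(outDir, "manifest.json"),
                summary = file.path(outDir, "summary.txt"))

  if ("simulate" %in% stages) {
    cfg <- simConfig(
      nPerCell = .configValue(config, "n_per_cell", 25),
      ageRange = c(.configValue(config, "age_min", 6),
                   .configValue(config, "age_max", 15)),
      nVertices = .configValue(config, "n_vertices", 150),
      fwhm = .configValue(config, "fwhm", NA_real_),
      seed = seed)
    mesh <- buildToyMesh(cfg@nVertices, seed = .stageSeed(seed, "mesh"))
    clusterSize <- .configValue(config, "affected_cluster_size", 0)
    affected <- if (clusterSize > 0)
      clusterAroundVertex(mesh, 1L, clusterSize) else integer(0)
    model <- trajectoryModel(
      peakShift = .configValue(config, "peak_shift", 0),
      interceptOffset = .configValue(config, "intercept_offset", 0),
      noiseSd = .configValue(config, "noise_sd", 0.10),
      affectedVertices = affected)
    ph <- generateCohort(cfg)
    vol <- generateVolumetrics(ph, cfg)
    Y <- generateThicknessMaps(ph, mesh, model, cfg)
    writePhenotypes(ph, paths$phenotypes)
    writeVolumetrics(vol, paths$volumes)
    writeThickness(Y, paths$thickness)
    writeMeshOFF(mesh, paths$mesh)
    manifest$stages$simulate <- list(status = "ok", n = nrow(ph),
                                     vertices = nVertices(mesh))
  }

  ph <- readPhenotypes(paths$phenotypes)

  if ("volumetrics" %in% stages) {
    vol <- readVolumetrics(paths$volumes)
    joined <- merge(ph, vol, by = "id", sort = FALSE)
    tab <- volumetricSummaryTable(joined)
    write.table(tab, paths$table2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cors <- do.call(rbind, lapply(
      c("cerebral_gray_matter", "cerebral_fa", "mean_cortical_thickness"),
      function(ms) cbind(measure = ms,
                         groupCorrelation(excludeIqOutliers(joined)$phenotypes,
                                          ms))))
    write.table(cors, paths$correlations, sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$stages$volumetrics <- list(status = "ok",
                                        measures = nrow(tab))
  }

  if ("vertexwise" %in% stages) {
    Y <- readThickness(paths$thickness)
    mesh <- readMeshOFF(paths$mesh)
    map <- vertexwiseAnalysis(
      Y, ph, hemisphereLabels = hemisphere(mesh),
      maxAge = .configValue(config, "max_age", 14),
      alpha = .configValue(config, "alpha", 0.05),
      fdrLevel = .configValue(config, "fdr_level", 0.05),
      ladder = dfLadder(.configValue(config, "df_max", 5)))
    st <- vertexStats(map)
    write.table(st, paths$vertexStats, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed,
           nRejected = sum(st$rejected),
           critical = as.list(criticalStatistic(map)),
           params = map@params[c("nPerGroup", "maxAge", "alpha",
                                 "fdrLevel")]),
      paths$runSummary, auto_unbox = TRUE, digits = NA, na = "null")
    manifest$stages$vertexwise <- list(status = "ok",
                                       rejected = sum(st$rejected))
  }

  files <- unlist(paths[c("phenotypes", "volumes", "thickness", "mesh",
                          "table2", "correlations", "vertexStats")])
  files <- files[file.exists(files)]
  manifest$checksums <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  .writeTextSummary(manifest, paths, paths$summary)
  invisible(manifest)
}

.writeTextSummary <- function(manifest, paths, path) {
  lines <- c(sprintf("cortdev %s run (seed %d)", manifest$version,
                     manifest$seed),
             sprintf("stages run: %s",
                     paste(names(manifest$stages), collapse = ", ")))
  if (file.exists(paths$table2)) {
    tab <- read.table(paths$table2, sep = "\t", header = TRUE)
    lines <- c(lines, sprintf("volumetric measures analyzed: %d",
                              nrow(tab)))
  } else lines <- c(lines, "volumetric section: absent")
  if (file.exists(paths$vertexStats)) {
    st <- read.table(paths$vertexStats, sep = "\t", header = TRUE)
    lines <- c(lines,
               sprintf("vertexwise: %d vertices, %d rejected at FDR",
                       nrow(st), sum(st$rejected)))
  } else lines <- c(lines, "vertexwise section: absent")
  writeLines(lines, path)
  invisible(path)
}
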