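# evaluate expr with a local RNG state seeded at `seed`, restoring the
# caller's RNG afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sub-seeds for the pipeline stages, fanned out from one master seed by
# fixed offsets so stages are independently reproducible
.stageSeed <- function(seed, stage) {
  offsets <- c(mesh = 101L, cohort = 211L, volumetrics = 307L,
               thickness = 401L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
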