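## Two-axis parameter sweeps: one independent simulation per grid cell,
## reduced to scalar metrics. Cells are pure functions of (cell, seed), so
## the grid is embarrassingly parallel; this driver simply loops.

#' Parameter sweep result
#'
#' @slot axis1,axis2 named lists `(name, values)`.
#' @slot metrics named list of value matrices, `length(values1)` x
#'   `length(values2)`.
#' @slot seeds integer seeds used per cell (recycled over the grid).
#' @export
setClass("SweepResult",
  representation(axis1 = "list", axis2 = "list", metrics = "list",
                 seeds = "integer"))

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult: %s (%d values) x %s (%d values); metrics: %s\n",
              object@axis1$name, length(object@axis1$values),
              object@axis2$name, length(object@axis2$values),
              paste(names(object@metrics), collapse = ", ")))
})

## set one swept parameter on a configuration; returns the new config
.applySweepParam <- function(config, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("sweep parameter '", name, "' must look like 'component.field'")
  comp <- parts[1]; field <- parts[2]
  switch(comp,
    model = {
      if (!field %in% names(config$model@params))
        stop("model has no parameter '", field, "'")
      config$model@params[[field]] <- value
    },
    coupling = {
      if (!field %in% slotNames("CouplingSpec"))
        stop("coupling has no field '", field, "'")
      slot(config$coupling, field) <- value
    },
    connectome = {
      if (field != "speed")
        stop("only connectome.speed can be swept")
      config$connectome@speed <- value
    },
    noise = {
      if (!config$integrator@stochastic)
        stop("integrator has no noise process to sweep")
      if (!field %in% c("intensity", "tau"))
        stop("noise field must be intensity or tau")
      slot(config$integrator@noise, field) <- value
    },
    integrator = {
      if (field != "dt") stop("only integrator.dt can be swept")
      config$integrator@dt <- value
    },
    stop("unknown component '", comp,
         "'; use model.*, coupling.*, connectome.speed, noise.*"))
  config
}

.builtinMetrics <- list(
  global_variance = function(r) globalVariance(r),
  node_variance = function(r) varianceOfNodeVariances(r))

#' Explore a two-parameter space
#'
#' Runs one simulation per cell of the outer product of the two axis value
#' grids — e.g. global coupling strength (`coupling.a`) against transmission
#' speed (`connectome.speed`) — and reduces each monitor output to scalar
#' metrics such as the global variance and the variance of node variances.
#'
#' @param config base [simulationConfig()]; everything but the swept
#'   parameters is identical across cells.
#' @param axis1,axis2 lists `list(name = "coupling.a", values = c(...))`.
#' @param metrics named list of functions of a [TimeSeriesResult-class], or
#'   names among `"global_variance"`, `"node_variance"`.
#' @param length simulated ms per cell (default: the configured length).
#' @param transient initial ms discarded before computing metrics.
#' @param seeds integer vector of seeds, recycled over cells (default: the
#'   config seed for every cell).
#' @param monitor name or index of the monitor to reduce (default: first).
#' @return a [SweepResult-class].
#' @export
parameterSweep <- function(config, axis1, axis2,
                           metrics = c("global_variance", "node_variance"),
                           length = NULL, transient = 0, seeds = NULL,
                           monitor = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.character(metrics)) {
    bad <- setdiff(metrics, names(.builtinMetrics))
    if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
    metrics <- .builtinMetrics[metrics]
  }
  if (is.null(names(metrics)))
    names(metrics) <- paste0("metric", seq_along(metrics))
  n1 <- base::length(axis1$values)
  n2 <- base::length(axis2$values)
  seeds <- as.integer(seeds %||% config$seed)
  grids <- lapply(metrics, function(f) matrix(NA_real_, n1, n2))
  cell <- 0L
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      cell <- cell + 1L
      cfg <- .applySweepParam(config, axis1$name, axis1$values[i])
      cfg <- .applySweepParam(cfg, axis2$name, axis2$values[j])
      cfg$seed <- seeds[(cell - 1L) %% base::length(seeds) + 1L]
      res <- simulateNetwork(cfg, length)[[monitor]]
      if (transient > 0) {
        drop <- sum(tsTime(res) <= res@startTime + transient)
        if (drop >= dim(res@data)[1] - 1)
          stop("transient leaves too few samples")
        res@data <- res@data[-seq_len(drop), , , , drop = FALSE]
        res@startTime <- res@startTime + drop * res@samplePeriod
      }
      for (mname in names(metrics))
        grids[[mname]][i, j] <- metrics[[mname]](res)
    }
  }
  new("SweepResult", axis1 = axis1, axis2 = axis2, metrics = grids,
      seeds = seeds)
}

#' Write sweep grids as delimited matrices with axis headers
#'
#' @param sweep a [SweepResult-class].
#' @param dir output directory (one TSV per metric).
#' @return the written paths, invisibly.
#' @export
writeSweepResult <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (mname in names(sweep@metrics)) {
    p <- file.path(dir, paste0(mname, ".tsv"))
    m <- sweep@metrics[[mname]]
    rownames(m) <- sweep@axis1$values
    colnames(m) <- sweep@axis2$values
    con <- file(p, "w")
    writeLines(sprintf("# rows: %s; columns: %s", sweep@axis1$name,
                       sweep@axis2$name), con)
    utils::write.table(m, con, sep = "\t", quote = FALSE,
                       col.names = NA)
    close(con)
    paths <- c(paths, p)
  }
  invisible(paths)
}
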