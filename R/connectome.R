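## Connectome container, ZIP import/export, synthetic connectomes, and the
## conversion of tract lengths + transmission speed into integer delay steps.

#' Connectome: the structural network of a brain network model
#'
#' Holds the weighted connectivity (`weights`, dimensionless strengths),
#' white-matter tract lengths in mm, region centres/areas/orientations and a
#' transmission speed in mm/ms. `weights[i, j]` is the strength of the
#' connection *into* region `i` *from* region `j` (row = target), so the
#' delayed network input is a plain matrix-vector product. Neither matrix is
#' required to be symmetric.
#'
#' @slot regionLabels character vector of region names.
#' @slot centres n x 3 matrix of region centres (mm).
#' @slot areas numeric vector of region areas (mm^2).
#' @slot orientations n x 3 matrix of average surface orientations.
#' @slot weights n x n non-negative connection strength matrix.
#' @slot tractLengths n x n non-negative tract length matrix (mm), zero
#'   diagonal.
#' @slot speed transmission speed, mm/ms; a positive scalar or an n x n
#'   matrix of per-edge speeds.
#' @slot hemisphere character vector (`"L"`/`"R"`) or empty when unknown.
#' @export
setClass("Connectome",
  representation(regionLabels = "character", centres = "matrix",
                 areas = "numeric", orientations = "matrix",
                 weights = "matrix", tractLengths = "matrix",
                 speed = "numeric", hemisphere = "character"))

setValidity("Connectome", function(object) {
  w <- object@weights; tl <- object@tractLengths
  n <- nrow(w)
  msgs <- character(0)
  if (ncol(w) != n) msgs <- c(msgs, "weights must be square")
  if (!all(dim(tl) == c(n, n)))
    msgs <- c(msgs, "tract lengths must be square and match weights")
  if (any(w < 0)) msgs <- c(msgs, "negative weights")
  if (any(tl < 0)) msgs <- c(msgs, "negative tract lengths")
  if (n > 0 && any(diag(tl) != 0))
    msgs <- c(msgs, "tract length diagonal must be 0")
  if (length(object@regionLabels) != n)
    msgs <- c(msgs, "regionLabels length must equal n")
  if (!all(dim(object@centres) == c(n, 3)))
    msgs <- c(msgs, "centres must be n x 3")
  if (!(length(object@speed) %in% c(1L, n * n)) || any(object@speed <= 0))
    msgs <- c(msgs, "speed must be a positive scalar or n x n matrix")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Connectome number of regions.
#' @param x,object a `Connectome`.
#' @export
nRegions <- function(x) nrow(x@weights)

#' @describeIn Connectome connection strength matrix.
#' @export
weightsMatrix <- function(x) x@weights

#' @describeIn Connectome tract length matrix (mm).
#' @export
tractLengths <- function(x) x@tractLengths

#' @describeIn Connectome region labels.
#' @export
regionLabels <- function(x) x@regionLabels

#' @describeIn Connectome transmission speed (mm/ms).
#' @export
transmissionSpeed <- function(x) x@speed

setMethod("show", "Connectome", function(object) {
  n <- nRegions(object)
  cat("Connectome with", n, "regions\n")
  cat("  weights: [", paste(range(object@weights), collapse = ", "), "],",
      sum(object@weights > 0), "non-zero connections\n")
  cat("  tract lengths (mm): max", max(object@tractLengths), "\n")
  cat("  speed (mm/ms):", if (length(object@speed) == 1) object@speed
      else "per-edge matrix", "\n")
})

#' Construct a Connectome
#'
#' Missing descriptive pieces get documented defaults: labels `region_k`,
#' centres placed on a unit sphere, unit areas, radial orientations.
#'
#' @param weights n x n non-negative matrix; `weights[i, j]` couples activity
#'   from region `j` into region `i`.
#' @param tractLengths n x n non-negative matrix of tract lengths (mm), zero
#'   diagonal.
#' @param speed transmission speed in mm/ms (positive scalar or n x n matrix).
#' @param regionLabels,centres,areas,orientations,hemisphere optional
#'   descriptive data; see slots.
#' @return a validated [Connectome-class] object.
#' @export
connectome <- function(weights, tractLengths, speed = 4,
                       regionLabels = NULL, centres = NULL, areas = NULL,
                       orientations = NULL, hemisphere = character(0)) {
  weights <- as.matrix(weights)
  tractLengths <- as.matrix(tractLengths)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop("weights matrix must be square, got ", n, " x ", ncol(weights))
  if (!all(dim(tractLengths) == c(n, n)))
    stop("tract length matrix (", nrow(tractLengths), " x ",
         ncol(tractLengths), ") does not match weights (", n, " x ", n, ")")
  if (is.null(regionLabels))
    regionLabels <- paste0("region_", seq_len(n))
  if (is.null(centres)) {
    ## default: points spread on a unit sphere (Fibonacci lattice)
    k <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * k / n)
    theta <- pi * (1 + sqrt(5)) * k
    centres <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  centres <- as.matrix(centres)
  if (is.null(areas)) areas <- rep(1, n)
  if (is.null(orientations)) {
    nrm <- sqrt(rowSums(centres^2))
    nrm[nrm == 0] <- 1
    orientations <- centres / nrm
  }
  new("Connectome", regionLabels = as.character(regionLabels),
      centres = centres, areas = as.numeric(areas),
      orientations = as.matrix(orientations), weights = weights,
      tractLengths = tractLengths, speed = as.numeric(speed),
      hemisphere = as.character(hemisphere))
}

## candidate file names inside a connectome archive; "weigths.txt" is a
## widely circulated misspelling in existing datasets and is accepted
.connectomeFileAliases <- list(
  weights = c("weights.txt", "weigths.txt"),
  tract_lengths = c("tract_lengths.txt", "tract_lengths_data.txt"),
  positions = c("positions.txt", "centres.txt"),
  areas = c("areas.txt"),
  orientations = c("average_orientations.txt", "orientations.txt"),
  info = c("info.txt")
)

#' Read a connectome from a ZIP archive of ASCII matrices
#'
#' The archive must contain at least a weights file (`weights.txt`, alias
#' `weigths.txt`) and a tract-lengths file (`tract_lengths.txt`), each a
#' whitespace/tab/comma-delimited numeric matrix. Optional files
#' `positions.txt` (3 numeric columns, optionally preceded by a label
#' column), `areas.txt` and `average_orientations.txt` populate the
#' corresponding slots; missing ones fall back to the defaults of
#' [connectome()].
#'
#' @param path path to the ZIP archive.
#' @param speed transmission speed (mm/ms) to attach; the archive format does
#'   not carry one.
#' @return a [Connectome-class].
#' @export
readConnectomeZip <- function(path, speed = 4) {
  if (!file.exists(path)) stop("no such file: ", path)
  exdir <- tempfile("connzip")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  have <- basename(files)
  find <- function(key) {
    hit <- intersect(.connectomeFileAliases[[key]], have)
    if (length(hit)) files[match(hit[1], have)] else NULL
  }
  wfile <- find("weights")
  lfile <- find("tract_lengths")
  if (is.null(wfile))
    stop("archive is missing a weights file (weights.txt / weigths.txt)")
  if (is.null(lfile))
    stop("archive is missing a tract lengths file (tract_lengths.txt)")
  weights <- .readDelimMatrix(wfile)
  lengths <- .readDelimMatrix(lfile)
  if (any(weights < 0)) stop("negative entries in weights file")
  if (any(lengths < 0)) stop("negative entries in tract lengths file")

  labels <- NULL; centres <- NULL
  pfile <- find("positions")
  if (!is.null(pfile)) {
    tab <- utils::read.table(pfile, header = FALSE,
                             stringsAsFactors = FALSE)
    numcols <- vapply(tab, is.numeric, logical(1))
    if (!numcols[1]) labels <- as.character(tab[[1]])
    centres <- as.matrix(tab[, numcols, drop = FALSE])
    if (ncol(centres) != 3) stop("positions file must have 3 numeric columns")
    dimnames(centres) <- NULL
  }
  afile <- find("areas")
  areas <- if (!is.null(afile)) as.numeric(.readDelimMatrix(afile)) else NULL
  ofile <- find("orientations")
  orient <- if (!is.null(ofile)) .readDelimMatrix(ofile) else NULL
  connectome(weights, lengths, speed = speed, regionLabels = labels,
             centres = centres, areas = areas, orientations = orient)
}

#' Write a connectome to a ZIP archive of ASCII matrices
#'
#' Inverse of [readConnectomeZip()]; writes `weights.txt`,
#' `tract_lengths.txt`, `positions.txt`, `areas.txt`,
#' `average_orientations.txt` and a one-line `info.txt` as stored entries.
#'
#' @param x a [Connectome-class].
#' @param zipfile output ZIP path.
#' @return `zipfile`, invisibly.
#' @export
writeConnectomeZip <- function(x, zipfile) {
  stopifnot(is(x, "Connectome"))
  d <- tempfile("connout")
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  wm <- function(m, f) {
    ## %.17g keeps doubles bit-exact through a write/read cycle
    m <- as.matrix(m)
    lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " "))
    writeLines(lines, file.path(d, f))
    file.path(d, f)
  }
  fs <- c(wm(x@weights, "weights.txt"),
          wm(x@tractLengths, "tract_lengths.txt"),
          { p <- file.path(d, "positions.txt")
            utils::write.table(data.frame(x@regionLabels, x@centres), p,
                               row.names = FALSE, col.names = FALSE,
                               quote = FALSE)
            p },
          wm(x@areas, "areas.txt"),
          wm(x@orientations, "average_orientations.txt"),
          { p <- file.path(d, "info.txt")
            writeLines(paste("n_regions", nRegions(x)), p)
            p })
  writeStoredZip(zipfile, fs)
}

#' Generate a synthetic two-hemisphere connectome
#'
#' Emulates the structure of typical parcellation-level demonstration
#' datasets: an even number of regions split into two hemispheres, symmetric
#' integer weights drawn uniformly from `0 .. weightLevels - 1` with a zero
#' diagonal, centres on two hemispheric shells of ~70 mm radius, and
#' symmetric tract lengths equal to the Euclidean inter-centre distances.
#'
#' @param nRegions number of regions (>= 2; even when hemispheres are
#'   tagged).
#' @param weightLevels number of integer weight levels (default 4, i.e.
#'   weights in 0..3).
#' @param seed integer seed; the same seed always yields the same connectome.
#' @param speed transmission speed (mm/ms).
#' @return a [Connectome-class].
#' @export
generateSyntheticConnectome <- function(nRegions = 74, weightLevels = 4,
                                        seed = 42, speed = 4) {
  if (nRegions < 2) stop("nRegions must be at least 2")
  stream <- makeStream(seed)
  n <- as.integer(nRegions)
  nl <- ceiling(n / 2)
  ## centres: Fibonacci points on a 70 mm sphere, mirrored into hemispheres
  k <- seq_len(nl) - 0.5
  phi <- acos(1 - 2 * k / nl)
  theta <- pi * (1 + sqrt(5)) * k
  left <- 70 * cbind(-abs(sin(phi) * cos(theta)), sin(phi) * sin(theta),
                     cos(phi))
  right <- left * matrix(c(-1, 1, 1), nrow(left), 3, byrow = TRUE)
  centres <- rbind(left, right)[seq_len(n), , drop = FALSE]
  ## jitter so no two centres coincide exactly
  centres <- centres + matrix(streamUnif(stream, 3 * n, -1, 1), n, 3)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  w[up] <- floor(streamUnif(stream, sum(up), 0, weightLevels))
  w[w == weightLevels] <- weightLevels - 1  # guard the open interval edge
  w <- w + t(w)
  tl <- as.matrix(dist(centres))
  dimnames(tl) <- NULL
  hemi <- c(rep("L", nl), rep("R", n - nl))[seq_len(n)]
  labels <- paste0(ifelse(hemi == "L", "lh_", "rh_"), "region_",
                   c(seq_len(nl), seq_len(n - nl)))
  connectome(w, tl, speed = speed, regionLabels = labels, centres = centres,
             hemisphere = hemi)
}

#' Conduction delays in integration steps
#'
#' @slot delaysMs n x n matrix of delays in ms.
#' @slot delaySteps n x n integer matrix of delays in integration steps.
#' @slot horizon depth of the history buffer: `max(delaySteps) + 1`.
#' @export
setClass("DelayTable",
  representation(delaysMs = "matrix", delaySteps = "matrix",
                 horizon = "integer"))

setValidity("DelayTable", function(object) {
  if (any(object@delaySteps < 0)) return("negative delay steps")
  if (object@horizon < max(object@delaySteps) + 1L)
    return("horizon must exceed the maximum delay")
  if (any(diag(object@delaySteps) != 0))
    return("diagonal delay steps must be 0")
  TRUE
})

setMethod("show", "DelayTable", function(object) {
  cat("DelayTable:", nrow(object@delaySteps), "nodes, max delay",
      max(object@delaySteps), "steps, horizon", object@horizon, "\n")
})

## round half away from zero (inputs are non-negative here)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Convert tract lengths and speed into integer step delays
#'
#' `delaySteps[i, j] = round(tractLengths[i, j] / speed / dt)`, rounding half
#' away from zero; sub-step delays round to 0 (instantaneous). The horizon is
#' the maximum delay plus one slot for the current state.
#'
#' @param x a [Connectome-class].
#' @param dt integration step size (ms, > 0).
#' @return a [DelayTable-class].
#' @export
computeDelayTable <- function(x, dt) {
  .assertScalarNumeric(dt, "dt", positive = TRUE)
  if (any(x@speed <= 0)) stop("speed must be positive")
  sp <- if (length(x@speed) == 1L) x@speed
        else matrix(x@speed, nRegions(x), nRegions(x))
  delaysMs <- x@tractLengths / sp
  steps <- .roundHalfUp(delaysMs / dt)
  storage.mode(steps) <- "integer"
  new("DelayTable", delaysMs = delaysMs, delaySteps = steps,
      horizon = max(steps) + 1L)
}

#' @describeIn DelayTable history depth in steps.
#' @param x a `DelayTable`.
#' @export
horizon <- function(x) x@horizon

#' @describeIn DelayTable delays as an integer matrix of steps.
#' @export
delaySteps <- function(x) x@delaySteps
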