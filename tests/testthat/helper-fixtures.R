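## Shared fixtures: tiny connectomes, meshes, and configuration shortcuts.

## a single disconnected node
oneNodeConnectome <- function() {
  connectome(matrix(0, 1, 1), matrix(0, 1, 1))
}

## n-node connectome with explicit weight/length matrices
fixtureConnectome <- function(weights, lengths, speed = 4) {
  connectome(as.matrix(weights), as.matrix(lengths), speed = speed)
}

## small dense random connectome (reproducible)
randomConnectome <- function(n, seed = 1, maxLength = 20, speed = 4) {
  st <- makeStream(seed)
  w <- matrix(streamUnif(st, n * n), n, n)
  diag(w) <- 0
  l <- matrix(streamUnif(st, n * n, 1, maxLength), n, n)
  l <- (l + t(l)) / 2
  diag(l) <- 0
  connectome(w, l, speed = speed)
}

## the oscillatory plane-oscillator configuration used for network demos:
## FitzHugh-Nagumo special case driven into its limit cycle, with the rate
## scale set so an isolated node oscillates near 40 Hz
demoOscillator <- function(...) genericOscillator2d(Iext = 0.5, d = 0.42, ...)

## toy two-cluster mesh with a simple triangulation
toyMesh <- function(nPerSide = 10, seed = 5) {
  st <- makeStream(seed)
  v <- rbind(
    cbind(streamUnif(st, nPerSide, -35, -25), streamUnif(st, nPerSide, -5, 5),
          streamUnif(st, nPerSide, -5, 5)),
    cbind(streamUnif(st, nPerSide, 25, 35), streamUnif(st, nPerSide, -5, 5),
          streamUnif(st, nPerSide, -5, 5)))
  n <- nrow(v)
  tri <- cbind(seq_len(n - 2), seq_len(n - 2) + 1L, seq_len(n - 2) + 2L)
  triangularMesh(v, tri)
}

## write a connectome fixture ZIP with known matrices; returns path
fixtureZip <- function(weights, lengths, dir = tempfile("zipfix"),
                       weightsName = "weights.txt") {
  dir.create(dir)
  wf <- file.path(dir, weightsName)
  lf <- file.path(dir, "tract_lengths.txt")
  writeLines(apply(as.matrix(weights), 1, paste, collapse = " "), wf)
  writeLines(apply(as.matrix(lengths), 1, paste, collapse = " "), lf)
  z <- file.path(dir, "connectome.zip")
  writeStoredZip(z, c(wf, lf))
  z
}
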