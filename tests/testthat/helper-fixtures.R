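# Shared fixtures: tiny simulation configs and hand-built model graphs.

tinyConfig <- function(n = 10L, seed = 7L, effect = 4, noise = 0.3,
                       lengths = c(200L, 400L), depth = 2000L) {
  simulationConfig(nRegionsPerClass = n, regionLengthRange = lengths,
                   cofactorEffect = effect, rpkmNoiseSd = noise,
                   readDepth = depth, seed = seed)
}

# fully position-specific linear scoring graph f_c(x) = <W_c, vec(x)> + b_c
# built from the engine's own layers (squeeze + dense): the closed-form
# oracle for the attribution methods
makeLinearModel <- function(W, b = NULL, classes = NULL) {
  ns <- asNamespace("deepCobind")
  C <- nrow(W)
  if (is.null(b)) b <- numeric(C)
  if (is.null(classes)) classes <- paste0("c", seq_len(C))
  L <- ncol(W) / 4L
  dn <- ns$layerDense(ncol(W), C)
  dn$W <- W
  dn$b <- b
  m <- ns$newModel("linear", NULL, list(ns$layerSqueeze()),
                   list(classificationHead(classes)), L)
  m@graph$heads[["class"]]$layers <- list(dn)
  m
}

# weight of class ci at (base b, position l) on the 4 x L input
linW <- function(W, ci, L) matrix(W[ci, ], 4L, L)

randomOneHot <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, 4L, L)
  m[cbind(sample.int(4L, L, replace = TRUE), seq_len(L))] <- 1
  m
}

# small deep classifier spec whose receptive field fits a 300 nt input
smallDeepSpec <- function(inputLength = 300L, channels = c(24L, 32L, 32L, 32L))
  deepModelSpec(nPoolBlocks = 2L, nDilBlocks = 2L, channels = channels,
                kernelWidths = c(16L, 16L, 8L, 8L),
                inputLength = as.integer(inputLength))

# labelled examples with a single planted consensus motif separating two
# classes; the simplest learnable task for sanity checks
motifToyExamples <- function(n = 200L, L = 200L, motif = "ATCAATC",
                             seed = 1L) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), "")
  y <- rep(c("pos", "neg"), length.out = n)
  for (i in which(y == "pos")) {
    p <- sample.int(L - nchar(motif), 1L)
    substr(seqs[i], p, p + nchar(motif) - 1L) <- motif
  }
  tg <- matrix(ifelse(y == "pos", 2, 0), n, 2,
               dimnames = list(NULL, c("g1", "g2")))
  new("LabelledExamples", X = encodeSequences(seqs, L), labels = factor(y),
      targets = tg, ids = as.character(seq_len(n)))
}
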