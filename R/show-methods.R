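#' @describeIn MotifModel-class compact display
#' @param object a `MotifModel`
#' @export
setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel '%s': width %d, consensus %s\n",
              object@name, ncol(object@pwm), object@consensus))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d regions/class, lengths [%d, %d] nt, %d tissues (%s)\n",
              object@nRegionsPerClass, object@regionLengthRange[1L],
              object@regionLengthRange[2L], length(object@tissueNames),
              paste(object@tissueNames, collapse = ", ")))
  cat(sprintf("  replicates %s; cofactor effect x%.1f, RPKM noise sd %.2f\n",
              paste(object@replicatesPerTissue, collapse = ","),
              object@cofactorEffect, object@rpkmNoiseSd))
  cat(sprintf("  read depth %d/replicate, positional sd %.0f nt, seed %d\n",
              object@readDepth, object@readPositionalSd, object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d regions on %d contig(s), %d replicates\n",
              length(object@regions), length(object@genome),
              ncol(object@rpkm)))
  print(table(object@labels))
  cat(sprintf("  %d planted co-factor sites; validation reads: %d + %d\n",
              length(object@trueSites),
              length(object@validationReads[[1L]]),
              length(object@validationReads[[2L]])))
})

setMethod("show", "ShallowCNNSpec", function(object) {
  cat(sprintf(
    "ShallowCNNSpec: %d filters x %d nt, fc [%s], dropout %.2f, input %d nt\n",
    object@nFilters, object@filterWidth,
    paste(object@fcSizes, collapse = ","), object@dropout,
    object@inputLength))
})

setMethod("show", "DeepModelSpec", function(object) {
  cat(sprintf(
    "DeepModelSpec: %d pool + %d dilation blocks, bottleneck %s (ratio %.2f)\n",
    object@nPoolBlocks, object@nDilBlocks, object@bottleneck,
    object@bottleneckRatio))
  cat(sprintf(
    "  %d conv layers, receptive field %d nt, input %d nt\n",
    countConvLayers(object), receptiveField(object), object@inputLength))
})

setMethod("show", "CNNModel", function(object) {
  g <- object@graph
  heads <- vapply(g$heads, function(h)
    sprintf("%s(%s:%d)", h$name, h$kind, h$size), character(1))
  cat(sprintf("CNNModel (%s): input %d nt, %d parameters\n  heads: %s\n",
              g$kind, g$inputLength, numParams(object),
              paste(heads, collapse = ", ")))
})

setMethod("show", "MutationMap", function(object) {
  cat(sprintf(
    "MutationMap: %d positions, class '%s', reference logit %.4f\n",
    nrow(object@effects), object@classLabel, object@referenceOutput))
})

setMethod("show", "AttributionTrack", function(object) {
  cat(sprintf("AttributionTrack (%s, class '%s'): %d nt, score range [%.3g, %.3g]\n",
              object@method, object@classLabel, length(object@scores),
              min(object@scores), max(object@scores)))
})

setMethod("show", "PoissonTest", function(object) {
  n <- nrow(object@results)
  cat(sprintf(
    "PoissonTest: %d features, %d nt window, alpha %.2f; %d/%d passed both replicates\n",
    n, object@window, object@alpha, sum(object@results$passed), n))
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf(
    "StabilityResult: Phi = %.4f (%d models x %d regions, mask %d nt, %d excluded)\n",
    object@phi, object@nModels, object@nRegions,
    as.integer(object@maskWidth), object@excluded))
})

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport\n  PR-AUC:\n")
  print(round(object@prAUC, 4))
  cat(sprintf("  macro F1: %.4f\n", object@macroF1))
})

setMethod("show", "RegressionReport", function(object) {
  cat("RegressionReport (per replicate)\n")
  print(round(rbind(R = object@pearson, Rho = object@spearman), 4))
})

setMethod("show", "LabelledExamples", function(object) {
  d <- dim(object@X)
  cat(sprintf(
    "LabelledExamples: %d examples, %d nt, %d regression targets\n",
    d[3L], d[2L], ncol(object@targets)))
  print(table(object@labels))
})

#' Subset labelled examples
#'
#' @param x a [LabelledExamples-class]
#' @param i integer or logical index over examples
#' @param j,...,drop ignored
#' @export
setMethod("[", "LabelledExamples", function(x, i, j, ..., drop = FALSE) {
  new("LabelledExamples",
      X = x@X[, , i, drop = FALSE],
      labels = droplevels0(x@labels[i]),
      targets = x@targets[i, , drop = FALSE],
      ids = x@ids[i])
})

# keep the full class set: metrics and heads rely on stable levels
droplevels0 <- function(f) f

#' Number of examples
#' @param x a [LabelledExamples-class]
#' @export
setMethod("length", "LabelledExamples", function(x) dim(x@X)[3L])
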