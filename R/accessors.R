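# Accessor functions for the package's S4 containers.

#' @rdname SyntheticDataset-class
#' @param ds a [SyntheticDataset-class]
#' @export
datasetRegions <- function(ds) ds@regions

#' @rdname SyntheticDataset-class
#' @export
datasetLabels <- function(ds) ds@labels

#' @rdname SyntheticDataset-class
#' @export
datasetRpkm <- function(ds) ds@rpkm

#' @rdname SyntheticDataset-class
#' @export
trueSites <- function(ds) ds@trueSites

#' @rdname SyntheticDataset-class
#' @export
validationReads <- function(ds) ds@validationReads

#' @rdname SyntheticDataset-class
#' @export
datasetGenome <- function(ds) ds@genome

#' @rdname AttributionTrack-class
#' @param track an [AttributionTrack-class]
#' @export
trackScores <- function(track) track@scores

#' @rdname MutationMap-class
#' @param map a [MutationMap-class]
#' @export
mapEffects <- function(map) map@effects

#' @rdname StabilityResult-class
#' @param x a [StabilityResult-class]
#' @export
stabilityPhi <- function(x) x@phi

#' @rdname PoissonTest-class
#' @param x a [PoissonTest-class]
#' @export
testResults <- function(x) x@results

#' @rdname PoissonTest-class
#' @export
passCurve <- function(x) x@curve

#' @rdname ClassificationReport-class
#' @param x a [ClassificationReport-class]
#' @export
prAUC <- function(x) x@prAUC

#' @rdname ClassificationReport-class
#' @export
macroF1 <- function(x) x@macroF1

#' @rdname ClassificationReport-class
#' @export
confusionMatrix <- function(x) x@confusion

#' @rdname RegressionReport-class
#' @param x a [RegressionReport-class]
#' @export
pearsonR <- function(x) x@pearson

#' @rdname RegressionReport-class
#' @export
spearmanRho <- function(x) x@spearman

#' @rdname LabelledExamples-class
#' @param ex a [LabelledExamples-class]
#' @export
exampleLabels <- function(ex) ex@labels

#' @rdname LabelledExamples-class
#' @export
exampleTargets <- function(ex) ex@targets

#' @rdname LabelledExamples-class
#' @export
exampleIds <- function(ex) ex@ids

#' @rdname LabelledExamples-class
#' @export
exampleTensor <- function(ex) ex@X

#' @rdname CNNModel-class
#' @param model a [CNNModel-class]
#' @export
modelSpec <- function(model) model@graph$spec

#' @rdname CNNModel-class
#' @export
modelKind <- function(model) model@graph$kind

#' @rdname CNNModel-class
#' @export
modelInputLength <- function(model) model@graph$inputLength

#' @rdname CNNModel-class
#' @param head head name
#' @export
headClasses <- function(model, head = "class") model@graph$heads[[head]]$classes
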