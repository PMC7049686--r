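#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet subseq
#' @importFrom rtracklayer import export
#' @importFrom stats ppois rnorm runif rlnorm rmultinom cor sd setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

BASE_ORDER <- c("A", "C", "G", "T")

#' Position weight matrix model of a transcription-factor binding site
#'
#' A `MotifModel` holds a 4 x W matrix of per-position base probabilities
#' (rows in fixed A,C,G,T order), a name, and the consensus sequence (the
#' per-column argmax).  Motifs stand in for anchor-TF and co-factor binding
#' sites in the synthetic data generator.
#'
#' @slot name single character identifier.
#' @slot pwm 4 x W numeric matrix; columns sum to 1.
#' @slot consensus length-W DNA string, per-column argmax of `pwm`.
#' @export
setClass("MotifModel",
         representation(name = "character", pwm = "matrix",
                        consensus = "character"))

setValidity("MotifModel", function(object) {
  p <- object@pwm
  if (nrow(p) != 4L) return("pwm must have 4 rows (A,C,G,T)")
  W <- ncol(p)
  if (W < 6L || W > 12L) return("motif width must be in [6, 12]")
  if (any(abs(colSums(p) - 1) > 1e-9)) return("pwm columns must sum to 1")
  cons <- paste(BASE_ORDER[apply(p, 2L, which.max)], collapse = "")
  if (!identical(cons, object@consensus))
    return("consensus must be the per-column argmax of pwm")
  TRUE
})

#' Configuration of the synthetic differential-binding simulator
#'
#' Defines the study conditions under which labelled multi-tissue datasets
#' with known ground-truth co-factor sites are generated.  See
#' [simulationConfig()] for defaults and the meaning of each parameter.
#'
#' @export
setClass("SimulationConfig",
         representation(nRegionsPerClass = "integer",
                        regionLengthRange = "integer",
                        tissueNames = "character",
                        replicatesPerTissue = "integer",
                        anchorMotif = "MotifModel",
                        cofactorMotifs = "list",
                        cofactorEffect = "numeric",
                        rpkmNoiseSd = "numeric",
                        labelFoldThreshold = "numeric",
                        readDepth = "integer",
                        readPositionalSd = "numeric",
                        backgroundReadFraction = "numeric",
                        spacerLength = "integer",
                        baseRpkm = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  rl <- object@regionLengthRange
  if (length(rl) != 2L || rl[1L] > rl[2L])
    return("regionLengthRange must be an ordered pair")
  if (rl[1L] < 200L || rl[2L] > 2000L)
    return("region lengths must lie within [200, 2000]")
  if (object@nRegionsPerClass < 1L) return("nRegionsPerClass must be positive")
  if (length(object@replicatesPerTissue) != length(object@tissueNames))
    return("one replicate count per tissue required")
  if (any(object@replicatesPerTissue < 1L))
    return("replicate counts must be positive")
  if (object@cofactorEffect <= 1) return("cofactorEffect must exceed 1")
  if (object@labelFoldThreshold <= 1) return("labelFoldThreshold must exceed 1")
  minlen <- ncol(object@anchorMotif@pwm) +
    max(vapply(object@cofactorMotifs, function(m) ncol(m@pwm), integer(1)))
  if (rl[1L] < minlen)
    return("regions too short to hold both anchor and co-factor motifs")
  TRUE
})

#' Synthetic multi-tissue differential-binding dataset
#'
#' Regions with planted anchor (and class-dependent co-factor) motif
#' instances laid out on a single synthetic contig, per-replicate RPKM
#' values, differential class labels, ground-truth co-factor sites and two
#' replicates of validation read positions concentrated at those sites.
#'
#' @slot genome `DNAStringSet` with the synthetic contig.
#' @slot regions `GRanges` of region intervals (names are region
#'   identifiers; `mcols` carry the intended design class).
#' @slot trueSites `GRanges` of planted co-factor sites (genome
#'   coordinates; `mcols$region` holds the parent region identifier).
#' @slot rpkm numeric matrix, regions x replicates.
#' @slot labels factor of differential classes assigned by the
#'   fold-change threshold rule (what an upstream differential analysis
#'   would hand over).
#' @slot validationReads list of two `GRanges` of width-1 read anchors.
#' @slot config the generating [SimulationConfig-class].
#' @export
setClass("SyntheticDataset",
         representation(genome = "DNAStringSet", regions = "GRanges",
                        trueSites = "GRanges", rpkm = "matrix",
                        labels = "factor", validationReads = "list",
                        config = "SimulationConfig"))

setValidity("SyntheticDataset", function(object) {
  n <- length(object@regions)
  if (nrow(object@rpkm) != n) return("rpkm rows must match regions")
  if (length(object@labels) != n) return("one label per region required")
  if (length(object@validationReads) != 2L)
    return("two validation read replicates required")
  TRUE
})

#' Shallow (DeepBind-like) CNN architecture specification
#'
#' One convolution with ReLU, concatenated global max- and average-pooling
#' (2 x nFilters features) and fully connected layers to the output
#' head(s).
#'
#' @export
setClass("ShallowCNNSpec",
         representation(nFilters = "integer", filterWidth = "integer",
                        fcSizes = "integer", dropout = "numeric",
                        inputLength = "integer"))

setValidity("ShallowCNNSpec", function(object) {
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@filterWidth > object@inputLength)
    return("filterWidth must not exceed inputLength")
  if (object@inputLength < 200L || object@inputLength > 2000L)
    return("inputLength must lie within [200, 2000]")
  TRUE
})

#' Deep (Basenji-like) CNN architecture specification
#'
#' Pooling blocks (conv, batch-norm, 1x bottleneck conv, dropout,
#' max-pool) followed by dilated-convolution blocks whose outputs are
#' concatenated channel-wise onto the running representation
#' (hyper-residual), then a linear 1x convolution and global average
#' pooling into the head(s).
#'
#' @export
setClass("DeepModelSpec",
         representation(nPoolBlocks = "integer", nDilBlocks = "integer",
                        channels = "integer", kernelWidths = "integer",
                        poolWidth = "integer", bottleneck = "character",
                        bottleneckRatio = "numeric", dropout = "numeric",
                        dilationBase = "integer", dilationGrowth = "numeric",
                        maxDilation = "integer", inputLength = "integer"))

setValidity("DeepModelSpec", function(object) {
  nb <- object@nPoolBlocks + object@nDilBlocks
  if (length(object@channels) != nb || length(object@kernelWidths) != nb)
    return("channels and kernelWidths need one entry per block")
  if (!object@bottleneck %in% c("off", "linear", "relu"))
    return("bottleneck must be one of off, linear, relu")
  if (object@bottleneckRatio <= 0 || object@bottleneckRatio > 1)
    return("bottleneckRatio must be in (0, 1]")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@dilationBase < 1L) return("dilationBase must be >= 1")
  rf <- receptiveField(object)
  clip <- function(v) min(2000L, max(200L, v))
  lo <- clip(rf)
  hi <- clip(2L * rf)
  if (object@inputLength < lo || object@inputLength > hi)
    return(sprintf(
      "inputLength %d outside [receptive field, 2 x receptive field] clipped to [200, 2000] = [%d, %d]",
      object@inputLength, lo, hi))
  TRUE
})

#' Trained or trainable CNN model graph
#'
#' Wraps the computation graph (an environment of layers) together with
#' its metadata: the architecture spec, class order per classification
#' head and replicate order for the regression head.  Classification
#' heads expose pre-softmax logits via [predictLogits()] independently of
#' probabilities.
#'
#' @slot graph environment holding trunk and head layers plus metadata.
#' @export
setClass("CNNModel", representation(graph = "environment"))

#' Single-base substitution effect map of one region
#'
#' Entry (i, b) is the change in the chosen pre-softmax class logit when
#' position i is substituted to base b; entries at the reference base and
#' at padded (all-zero) columns are exactly 0.
#'
#' @export
setClass("MutationMap",
         representation(effects = "matrix", referenceOutput = "numeric",
                        classLabel = "character"))

#' Per-nucleotide importance track for one region and class
#'
#' @slot scores length-L numeric importance per position.
#' @slot classLabel attributed class label.
#' @slot method one of `mutagenesis`, `integrated_gradients`,
#'   `gradient_x_input`.
#' @slot metadata list (integration steps, reference description, region
#'   identifier).
#' @export
setClass("AttributionTrack",
         representation(scores = "numeric", classLabel = "character",
                        method = "character", metadata = "list"))

setValidity("AttributionTrack", function(object) {
  if (!all(is.finite(object@scores))) return("scores must be finite")
  if (!object@method %in% c("mutagenesis", "integrated_gradients",
                            "gradient_x_input", "ensemble"))
    return("unknown attribution method")
  TRUE
})

#' Motif-centre Poisson test results
#'
#' Per-feature read counts, expected counts (lambda) and upper-tail
#' Poisson P values in two validation replicates, the joint pass flag
#' (P < alpha in both), and the pass-proportion curve over the ranked
#' feature list together with a random-position baseline.
#'
#' @export
setClass("PoissonTest",
         representation(results = "DFrame", curve = "data.frame",
                        window = "integer", alpha = "numeric"))

#' Cross-model feature-selection stability result
#'
#' The per-feature-variance stability estimator over binary feature masks
#' from repeated model instances: 1 for identical selections, 0 in
#' expectation for random ones.
#'
#' @export
setClass("StabilityResult",
         representation(phi = "numeric", perRegion = "numeric",
                        nModels = "integer", nRegions = "integer",
                        maskWidth = "numeric", excluded = "integer"))

#' Multi-class classification evaluation report
#' @export
setClass("ClassificationReport",
         representation(prCurves = "list", prAUC = "numeric",
                        confusion = "table", recall = "numeric",
                        f1 = "numeric", macroF1 = "numeric"))

#' Per-replicate regression evaluation report
#' @export
setClass("RegressionReport",
         representation(pearson = "numeric", spearman = "numeric",
                        crossReplicate = "matrix"))

#' Labelled, encoded examples ready for training
#'
#' One-hot encoded regions with their differential class label and
#' per-replicate log-RPKM regression targets.
#'
#' @slot X array 4 x L x n of one-hot columns (A,C,G,T order).
#' @slot labels factor of length n.
#' @slot targets n x N matrix of log-RPKM regression targets.
#' @slot ids region identifiers.
#' @export
setClass("LabelledExamples",
         representation(X = "array", labels = "factor", targets = "matrix",
                        ids = "character"))

setValidity("LabelledExamples", function(object) {
  n <- dim(object@X)[3L]
  if (length(object@labels) != n || nrow(object@targets) != n ||
      length(object@ids) != n)
    return("labels, targets and ids must match the number of examples")
  if (!all(is.finite(object@targets)))
    return("regression targets must be finite")
  TRUE
})
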