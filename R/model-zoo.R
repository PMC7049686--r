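# Architecture construction and structural calculators.

#' Specify a shallow (DeepBind-like) CNN
#'
#' @param nFilters number of convolutional filters.
#' @param filterWidth filter width in nt.
#' @param fcSizes sizes of the fully connected hidden layers.
#' @param dropout dropout probability in \[0, 1).
#' @param inputLength encoded input length in nt (200-2000).
#' @return a [ShallowCNNSpec-class].
#' @export
shallowCNNSpec <- function(nFilters = 32L, filterWidth = 12L,
                           fcSizes = c(64L), dropout = 0.1,
                           inputLength = 300L) {
  new("ShallowCNNSpec", nFilters = as.integer(nFilters),
      filterWidth = as.integer(filterWidth), fcSizes = as.integer(fcSizes),
      dropout = dropout, inputLength = as.integer(inputLength))
}

#' Specify a deep (Basenji-like) CNN
#'
#' @param nPoolBlocks number of pooling blocks (conv, batch-norm, 1x
#'   bottleneck conv, dropout, max-pool).
#' @param nDilBlocks number of dilated hyper-residual blocks.
#' @param channels main-conv output channels per block (length
#'   `nPoolBlocks + nDilBlocks`; recycled if scalar).
#' @param kernelWidths kernel width per block (recycled if scalar).
#' @param poolWidth max-pool window = stride of each pooling block.
#' @param bottleneck `"off"`, `"linear"` or `"relu"`; when not off, each
#'   block appends a 1x convolution with
#'   `round(bottleneckRatio x channels)` output channels.
#' @param bottleneckRatio fraction of the preceding channels kept.
#' @param dropout dropout probability.
#' @param dilationBase dilation rate of the first dilation block.
#' @param dilationGrowth multiplier applied per dilation block.
#' @param maxDilation cap on the dilation rate.
#' @param inputLength encoded input length; must lie in
#'   \[receptive field, 2 x receptive field\] intersected with
#'   \[200, 2000\].
#' @return a [DeepModelSpec-class].
#' @export
deepModelSpec <- function(nPoolBlocks = 3L, nDilBlocks = 7L,
                          channels = 32L, kernelWidths = 8L,
                          poolWidth = 2L, bottleneck = "relu",
                          bottleneckRatio = 0.5, dropout = 0.1,
                          dilationBase = 2L, dilationGrowth = 2,
                          maxDilation = 4L, inputLength = NULL) {
  nb <- nPoolBlocks + nDilBlocks
  channels <- as.integer(rep_len(channels, nb))
  kernelWidths <- as.integer(rep_len(kernelWidths, nb))
  if (is.null(inputLength)) {
    rf <- rfFromParams(as.integer(nPoolBlocks), as.integer(nDilBlocks),
                       kernelWidths, as.integer(poolWidth),
                       as.integer(dilationBase), dilationGrowth,
                       as.integer(maxDilation))
    inputLength <- min(2000L, max(200L, rf))
  }
  new("DeepModelSpec", nPoolBlocks = as.integer(nPoolBlocks),
      nDilBlocks = as.integer(nDilBlocks), channels = channels,
      kernelWidths = kernelWidths, poolWidth = as.integer(poolWidth),
      bottleneck = bottleneck, bottleneckRatio = bottleneckRatio,
      dropout = dropout, dilationBase = as.integer(dilationBase),
      dilationGrowth = dilationGrowth,
      maxDilation = as.integer(maxDilation),
      inputLength = as.integer(inputLength))
}

dilationSchedule <- function(spec) {
  if (spec@nDilBlocks == 0L) return(integer(0))
  d <- spec@dilationBase * spec@dilationGrowth^(seq_len(spec@nDilBlocks) - 1L)
  as.integer(pmin(round(d), spec@maxDilation))
}

#' Count convolutional layers of a deep architecture
#'
#' Counts every block's main convolution, each 1x bottleneck convolution
#' when the bottleneck is enabled, and the final linear 1x output
#' convolution.
#'
#' @param spec a [DeepModelSpec-class].
#' @return integer layer count: `2*nPool + 2*nDil + 1` with bottlenecks,
#'   `nPool + nDil + 1` without.
#' @examples
#' countConvLayers(deepModelSpec(3, 7))   # 21
#' @export
countConvLayers <- function(spec) {
  stopifnot(is(spec, "DeepModelSpec"))
  nb <- spec@nPoolBlocks + spec@nDilBlocks
  if (spec@bottleneck == "off") nb + 1L else 2L * nb + 1L
}

#' Receptive field of an architecture
#'
#' The maximum span in the input that can affect one activation prior to
#' the global pooling layer:
#' `RF = 1 + sum_i (k_i - 1) * d_i * prod_{j<i} s_j` over all
#' convolution and pooling layers in order (kernel `k`, dilation `d`,
#' stride `s`).  For the shallow CNN this is simply the filter width.
#'
#' @param spec a [DeepModelSpec-class] or [ShallowCNNSpec-class].
#' @return receptive field in nt.
#' @export
receptiveField <- function(spec) {
  if (is(spec, "ShallowCNNSpec")) return(spec@filterWidth)
  stopifnot(is(spec, "DeepModelSpec"))
  rfFromParams(spec@nPoolBlocks, spec@nDilBlocks, spec@kernelWidths,
               spec@poolWidth, spec@dilationBase, spec@dilationGrowth,
               spec@maxDilation)
}

rfFromParams <- function(nPool, nDil, kernels, poolWidth, dilBase,
                         dilGrowth, maxDil) {
  rf <- 1L
  stride <- 1L
  for (i in seq_len(nPool)) {
    rf <- rf + (kernels[i] - 1L) * stride          # conv, d = 1
    rf <- rf + (poolWidth - 1L) * stride           # max-pool
    stride <- stride * poolWidth
  }
  if (nDil > 0L) {
    dil <- as.integer(pmin(round(dilBase * dilGrowth^(seq_len(nDil) - 1L)),
                           maxDil))
    for (j in seq_len(nDil))
      rf <- rf + (kernels[nPool + j] - 1L) * dil[j] * stride
  }
  as.integer(rf)
}

#' Sample an input length from a receptive field
#'
#' Uniform integer in `[rf, 2*rf]`, clipped to the encodable range
#' \[200, 2000\].
#'
#' @param rf receptive field in nt (must be <= 2000).
#' @return sampled input length.
#' @export
sampleInputLength <- function(rf) {
  if (rf > 2000L) stop("receptive field exceeds the 2000 nt input bound")
  L <- sample(rf:(2L * rf), 1L)
  as.integer(min(2000L, max(200L, L)))
}

headDescription <- function(name, kind, size, classes = NULL)
  list(name = name, kind = kind, size = as.integer(size), classes = classes)

#' Head descriptions for model construction
#'
#' `classificationHead()` ends in softmax over its class set (pre-softmax
#' logits remain accessible); `regressionHead()` is linear with one
#' output per replicate target.
#'
#' @param classes class labels, in output order.
#' @param name head name.
#' @export
classificationHead <- function(classes, name = "class")
  headDescription(name, "classification", length(classes), as.character(classes))

#' @rdname classificationHead
#' @param targets replicate target names.
#' @export
regressionHead <- function(targets, name = "rpkm")
  headDescription(name, "regression", length(targets), as.character(targets))

newModel <- function(kind, spec, trunk, heads, inputLength) {
  g <- new.env(parent = emptyenv())
  g$kind <- kind
  g$spec <- spec
  g$trunk <- trunk
  g$inputLength <- as.integer(inputLength)
  g$heads <- list()
  for (h in heads) g$heads[[h$name]] <- h
  new("CNNModel", graph = g)
}

buildHeadLayersConv <- function(cin, size) list(layerConv1d(cin, size, 1L),
                                                layerGAP())

#' Build a shallow CNN model graph
#'
#' One convolution with ReLU, concatenated global max- and
#' average-pooling (2 x nFilters features), fully connected layers, and
#' a dense layer per head; classification heads emit pre-softmax logits.
#'
#' @param spec a [ShallowCNNSpec-class].
#' @param heads list of head descriptions ([classificationHead()] /
#'   [regressionHead()]).
#' @return a [CNNModel-class].
#' @export
buildShallowCNN <- function(spec, heads) {
  validObject(spec)
  checkHeads(heads)
  trunk <- list(layerConv1d(4L, spec@nFilters, spec@filterWidth),
                layerReLU(), layerPoolConcat())
  fin <- 2L * spec@nFilters
  for (sz in spec@fcSizes) {
    trunk <- c(trunk, list(layerDense(fin, sz), layerReLU(),
                           layerDropout(spec@dropout)))
    fin <- sz
  }
  m <- newModel("shallow", spec, trunk, heads, spec@inputLength)
  for (h in names(m@graph$heads))
    m@graph$heads[[h]]$layers <- list(layerDense(fin, m@graph$heads[[h]]$size))
  m
}

checkHeads <- function(heads) {
  if (length(heads) == 0L) stop("at least one head required")
  ok <- vapply(heads, function(h)
    is.list(h) && h$kind %in% c("classification", "regression"), logical(1))
  if (!all(ok)) stop("invalid head description")
  invisible(TRUE)
}

#' Build a deep CNN model graph
#'
#' `nPoolBlocks` blocks of convolution, batch normalization, ReLU, a 1x
#' bottleneck convolution (activation per spec; omitted when
#' `bottleneck = "off"`), dropout and max-pooling; then `nDilBlocks`
#' dilated blocks of the same composition (without pooling) whose
#' outputs are concatenated channel-wise onto the running representation
#' (hyper-residual); finally, per head, a linear 1x convolution and
#' global average pooling.
#'
#' @param spec a [DeepModelSpec-class].
#' @param heads list of head descriptions.
#' @return a [CNNModel-class].
#' @export
buildDeepCNN <- function(spec, heads) {
  validObject(spec)
  checkHeads(heads)
  # dilated windows must fit in the pooled length
  Lp <- spec@inputLength %/% (spec@poolWidth^spec@nPoolBlocks)
  dil <- dilationSchedule(spec)
  if (spec@nDilBlocks > 0L) {
    ke <- (spec@kernelWidths[spec@nPoolBlocks + seq_len(spec@nDilBlocks)] - 1L) *
      dil + 1L
    if (any(ke > Lp))
      stop("dilation window exceeds the pooled length")
  }
  if (Lp < 1L) stop("pooled length < 1")

  bneck <- function(cin) {
    if (spec@bottleneck == "off") return(list(layers = list(), cout = cin))
    cb <- max(1L, as.integer(round(spec@bottleneckRatio * cin)))
    ls <- list(layerConv1d(cin, cb, 1L))
    if (spec@bottleneck == "relu") ls <- c(ls, list(layerReLU()))
    list(layers = ls, cout = cb)
  }

  trunk <- list()
  cin <- 4L
  for (i in seq_len(spec@nPoolBlocks)) {
    co <- spec@channels[i]
    bn <- bneck(co)
    trunk <- c(trunk,
               list(layerConv1d(cin, co, spec@kernelWidths[i]),
                    layerBatchNorm(co), layerReLU()),
               bn$layers,
               list(layerDropout(spec@dropout),
                    layerMaxPool(spec@poolWidth)))
    cin <- bn$cout
  }
  for (j in seq_len(spec@nDilBlocks)) {
    co <- spec@channels[spec@nPoolBlocks + j]
    bn <- bneck(co)
    sub <- c(list(layerConv1d(cin, co,
                              spec@kernelWidths[spec@nPoolBlocks + j],
                              dilation = dil[j]),
                  layerBatchNorm(co), layerReLU()),
             bn$layers,
             list(layerDropout(spec@dropout)))
    trunk <- c(trunk, list(layerDilBlock(sub)))
    cin <- cin + bn$cout
  }
  m <- newModel("deep", spec, trunk, heads, spec@inputLength)
  for (h in names(m@graph$heads))
    m@graph$heads[[h]]$layers <-
      buildHeadLayersConv(cin, m@graph$heads[[h]]$size)
  m
}

#' Number of trainable parameters of a model
#' @param model a [CNNModel-class].
#' @export
numParams <- function(model) {
  g <- model@graph
  layers <- c(flattenLayers(g$trunk),
              unlist(lapply(g$heads, function(h) flattenLayers(h$layers)),
                     recursive = FALSE))
  sum(vapply(layers, function(ly)
    sum(vapply(ly$params, function(p) length(get(p, envir = ly)),
               integer(1)), 0L), integer(1)))
}

allModelLayers <- function(model, heads = NULL) {
  g <- model@graph
  hn <- if (is.null(heads)) names(g$heads) else heads
  c(g$trunk, unlist(lapply(g$heads[hn], function(h) h$layers),
                    recursive = FALSE, use.names = FALSE))
}

# forward pass to one head; x is (4, L, B)
modelForwardHead <- function(model, x, head, train = FALSE) {
  g <- model@graph
  h <- g$heads[[head]]
  if (is.null(h)) stop("unknown head: ", head)
  feat <- netForward(g$trunk, x, train)
  out <- netForward(h$layers, feat, train)
  out
}

# backward from a head-output gradient to the input gradient
modelBackwardHead <- function(model, dOut, head) {
  g <- model@graph
  dFeat <- netBackward(g$heads[[head]]$layers, dOut)
  netBackward(g$trunk, dFeat)
}

#' Pre-softmax logits of a classification head
#'
#' @param model a [CNNModel-class].
#' @param x input array `(4, L, B)` or a single `(4, L)` matrix.
#' @param head head name (default `"class"`).
#' @return matrix classes x B of raw logits.
#' @export
predictLogits <- function(model, x, head = "class") {
  x <- as3d(x)
  out <- modelForwardHead(model, x, head, train = FALSE)
  rownames(out) <- model@graph$heads[[head]]$classes
  out
}

#' Softmax probabilities of a classification head
#' @rdname predictLogits
#' @export
predictProbs <- function(model, x, head = "class") {
  lg <- predictLogits(model, x, head)
  p <- softmaxProbs(lg)
  rownames(p) <- rownames(lg)
  p
}

#' Regression-head predictions
#' @rdname predictLogits
#' @export
predictRegression <- function(model, x, head = "rpkm") {
  x <- as3d(x)
  out <- modelForwardHead(model, x, head, train = FALSE)
  rownames(out) <- model@graph$heads[[head]]$classes
  out
}

as3d <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

#' Write or read an architecture spec as a DCF key-value file
#'
#' Serializes a [ShallowCNNSpec-class] or [DeepModelSpec-class] to a
#' structured key-value (DCF) file and back.
#'
#' @param spec the spec to write.
#' @param file path.
#' @return `readSpec` returns the reconstructed spec (validated).
#' @export
writeSpec <- function(spec, file) {
  if (is(spec, "ShallowCNNSpec")) {
    df <- data.frame(family = "shallow",
                     nFilters = spec@nFilters,
                     filterWidth = spec@filterWidth,
                     fcSizes = paste(spec@fcSizes, collapse = ","),
                     dropout = spec@dropout,
                     inputLength = spec@inputLength)
  } else {
    stopifnot(is(spec, "DeepModelSpec"))
    df <- data.frame(family = "deep",
                     nPoolBlocks = spec@nPoolBlocks,
                     nDilBlocks = spec@nDilBlocks,
                     channels = paste(spec@channels, collapse = ","),
                     kernelWidths = paste(spec@kernelWidths, collapse = ","),
                     poolWidth = spec@poolWidth,
                     bottleneck = spec@bottleneck,
                     bottleneckRatio = spec@bottleneckRatio,
                     dropout = spec@dropout,
                     dilationBase = spec@dilationBase,
                     dilationGrowth = spec@dilationGrowth,
                     maxDilation = spec@maxDilation,
                     inputLength = spec@inputLength)
  }
  write.dcf(df, file)
  invisible(file)
}

#' @rdname writeSpec
#' @export
readSpec <- function(file) {
  kv <- as.list(read.dcf(file)[1L, ])
  ints <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
  if (kv$family == "shallow")
    shallowCNNSpec(nFilters = as.integer(kv$nFilters),
                   filterWidth = as.integer(kv$filterWidth),
                   fcSizes = ints(kv$fcSizes),
                   dropout = as.numeric(kv$dropout),
                   inputLength = as.integer(kv$inputLength))
  else
    deepModelSpec(nPoolBlocks = as.integer(kv$nPoolBlocks),
                  nDilBlocks = as.integer(kv$nDilBlocks),
                  channels = ints(kv$channels),
                  kernelWidths = ints(kv$kernelWidths),
                  poolWidth = as.integer(kv$poolWidth),
                  bottleneck = kv$bottleneck,
                  bottleneckRatio = as.numeric(kv$bottleneckRatio),
                  dropout = as.numeric(kv$dropout),
                  dilationBase = as.integer(kv$dilationBase),
                  dilationGrowth = as.numeric(kv$dilationGrowth),
                  maxDilation = as.integer(kv$maxDilation),
                  inputLength = as.integer(kv$inputLength))
}
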