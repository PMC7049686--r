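# Dataset assembly with reverse-complement augmentation, cross-validated
# model selection with two-stage early stopping, and the regularization
# modes (direct, transfer, serial, parallel multitask).

#' Training configuration
#'
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param patience epochs without validation improvement before stopping.
#' @param maxEpochs epoch cap.
#' @param seed seed for shuffling, initialization and dropout.
#' @param folds cross-validation folds (default 3).
#' @param testFraction held-out test fraction (default 0.2).
#' @export
trainingConfig <- function(learningRate = 1e-3, batchSize = 32L,
                           patience = 3L, maxEpochs = 30L, seed = 1L,
                           folds = 3L, testFraction = 0.2) {
  stopifnot(patience >= 1L, folds >= 2L, testFraction > 0, testFraction < 1)
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs),
                 seed = as.integer(seed),
                 folds = as.integer(folds),
                 testFraction = testFraction),
            class = "trainingConfig")
}

#' @export
print.trainingConfig <- function(x, ...) {
  cat(sprintf(
    "trainingConfig: lr %g, batch %d, patience %d, max %d epochs, %d folds, test %.0f%%\n",
    x$learningRate, x$batchSize, x$patience, x$maxEpochs, x$folds,
    100 * x$testFraction))
  invisible(x)
}

#' Encode a synthetic dataset into labelled examples
#'
#' One-hot encodes all region sequences to a common input length
#' (centred crop/pad) and log-transforms RPKM into regression targets.
#'
#' @param ds a [SyntheticDataset-class].
#' @param inputLength encoded length in nt.
#' @param pseudocount added to RPKM before the log.
#' @return a [LabelledExamples-class].
#' @export
encodeExamples <- function(ds, inputLength, pseudocount = 1) {
  seqs <- as.character(regionSequences(ds))
  X <- encodeSequences(seqs, inputLength)
  new("LabelledExamples", X = X, labels = ds@labels,
      targets = log(ds@rpkm + pseudocount), ids = names(ds@regions))
}

#' One-hot encode a character vector of sequences into a tensor
#'
#' @param seqs character vector.
#' @param inputLength common encoded length.
#' @return array `(4, inputLength, length(seqs))`.
#' @export
encodeSequences <- function(seqs, inputLength) {
  X <- array(0, c(4L, inputLength, length(seqs)))
  for (i in seq_along(seqs))
    X[, , i] <- oneHotEncode(seqs[i], inputLength, strict = FALSE)
  X
}

rcTensor <- function(X) X[4:1, dim(X)[2L]:1, , drop = FALSE]

#' Reverse-complement augmentation of the minority classes
#'
#' Duplicates every example of `targetClass` as its reverse complement
#' (same label and regression targets).  With `m` the resulting target
#' count, every other class whose count is below `m` is likewise fully
#' duplicated.  Apply to training/validation data only, never to the
#' test split.
#'
#' @param ex a [LabelledExamples-class].
#' @param targetClass the class driving the augmentation.
#' @return augmented [LabelledExamples-class].
#' @export
augmentReverseComplement <- function(ex, targetClass) {
  if (!targetClass %in% levels(ex@labels)) stop("unknown class: ", targetClass)
  cnt <- table(ex@labels)
  idx <- which(ex@labels == targetClass)
  if (length(idx) == 0L) return(ex)
  m <- 2L * length(idx)
  for (cl in setdiff(names(cnt)[cnt > 0], targetClass))
    if (cnt[[cl]] < m) idx <- c(idx, which(ex@labels == cl))
  new("LabelledExamples",
      X = abind3(ex@X, rcTensor(ex@X[, , idx, drop = FALSE])),
      labels = factor(c(as.character(ex@labels),
                        as.character(ex@labels[idx])),
                      levels = levels(ex@labels)),
      targets = rbind(ex@targets, ex@targets[idx, , drop = FALSE]),
      ids = c(ex@ids, paste0(ex@ids[idx], "_rc")))
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
  out[, , seq_len(da[3L])] <- a
  out[, , da[3L] + seq_len(db[3L])] <- b
  out
}

#' Stratified test split and cross-validation folds
#'
#' Holds out `testFraction` of the examples (stratified by class) and
#' partitions the remainder into `folds` disjoint stratified folds.
#' Deterministic under `config$seed`.
#'
#' @param ex a [LabelledExamples-class].
#' @param config a [trainingConfig()].
#' @return list with integer index vectors `test` and `folds` (a list).
#' @export
splitFolds <- function(ex, config) {
  set.seed(config$seed)
  lab <- ex@labels
  test <- integer(0)
  folds <- replicate(config$folds, integer(0), simplify = FALSE)
  for (cl in levels(lab)) {
    idx <- which(lab == cl)
    if (length(idx) == 0L) next
    if (length(idx) < config$folds)
      stop("class too small to stratify: ", cl)
    idx <- idx[sample.int(length(idx))]
    nTest <- round(config$testFraction * length(idx))
    test <- c(test, idx[seq_len(nTest)])
    rest <- idx[setdiff(seq_along(idx), seq_len(nTest))]
    f <- rep_len(seq_len(config$folds), length(rest))
    for (k in seq_len(config$folds))
      folds[[k]] <- c(folds[[k]], rest[f == k])
  }
  list(test = sort(test), folds = lapply(folds, sort))
}

# ---- task plumbing -------------------------------------------------------

taskData <- function(ex, model, head) {
  h <- model@graph$heads[[head]]
  if (is.null(h)) stop("unknown head: ", head)
  if (h$kind == "classification") {
    keep <- which(as.character(ex@labels) %in% h$classes)
    list(X = ex@X[, , keep, drop = FALSE],
         y = match(as.character(ex@labels)[keep], h$classes),
         n = length(keep))
  } else {
    list(X = ex@X, y = t(ex@targets), n = length(ex))
  }
}

batchLoss <- function(model, head, x, y, train) {
  h <- model@graph$heads[[head]]
  out <- modelForwardHead(model, x, head, train = train)
  if (h$kind == "classification") softmaxXent(out, y)
  else mseLoss(out, y)
}

evalTaskLoss <- function(model, head, td, batchSize = 128L) {
  if (td$n == 0L) return(NA_real_)
  tot <- 0
  i <- 1L
  while (i <= td$n) {
    j <- min(td$n, i + batchSize - 1L)
    x <- td$X[, , i:j, drop = FALSE]
    y <- if (is.matrix(td$y)) td$y[, i:j, drop = FALSE] else td$y[i:j]
    r <- batchLoss(model, head, x, y, train = FALSE)
    tot <- tot + r$loss * (j - i + 1L)
    i <- j + 1L
  }
  tot / td$n
}

trainOneBatch <- function(model, head, x, y, layers, lr, t) {
  r <- batchLoss(model, head, x, y, train = TRUE)
  if (!is.finite(r$loss)) stop("divergent loss (non-finite); trial aborted")
  h <- model@graph$heads[[head]]
  first <- model@graph$trunk[[1L]]
  first$skipDx <- TRUE        # input gradients are only needed by attribution
  on.exit(first$skipDx <- FALSE)
  dFeat <- netBackward(h$layers, r$grad)
  netBackward(model@graph$trunk, dFeat)
  adamStep(layers, lr, t)
  r$loss
}

#' Train one head with patience-based early stopping
#'
#' Runs minibatch Adam, evaluating the validation loss each epoch; stops
#' after `patience` epochs without improvement, restores the
#' best-validation weights and reports the training loss at the best
#' epoch (the quantity later used as the stopping criterion of the final
#' fit).
#'
#' @param model a [CNNModel-class] (modified in place).
#' @param trainEx,valEx [LabelledExamples-class] splits.
#' @param config a [trainingConfig()].
#' @param head head to train (default `"class"`).
#' @return list: `stopEpoch`, `trainLossAtBest`, `valLoss`, `epochsRun`,
#'   `log` (per-epoch data frame).
#' @export
trainWithEarlyStopping <- function(model, trainEx, valEx, config,
                                   head = "class") {
  set.seed(config$seed)
  td <- taskData(trainEx, model, head)
  vd <- taskData(valEx, model, head)
  layers <- allModelLayers(model, head)
  adamInit(layers)
  best <- list(val = Inf, train = NA_real_, epoch = 0L, snap = NULL)
  bad <- 0L
  t <- 0L
  log <- NULL
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(td$n)
    i <- 1L
    trLoss <- 0
    while (i <= td$n) {
      j <- min(td$n, i + config$batchSize - 1L)
      sel <- ord[i:j]
      x <- td$X[, , sel, drop = FALSE]
      y <- if (is.matrix(td$y)) td$y[, sel, drop = FALSE] else td$y[sel]
      t <- t + 1L
      trLoss <- trLoss + trainOneBatch(model, head, x, y, layers,
                                       config$learningRate, t) * length(sel)
      i <- j + 1L
    }
    trLoss <- trLoss / td$n
    bnRecalibrate(model@graph$trunk, td$X)
    valLoss <- evalTaskLoss(model, head, vd)
    log <- rbind(log, data.frame(epoch = epoch, train = trLoss,
                                 validation = valLoss))
    if (valLoss < best$val - 1e-9) {
      best <- list(val = valLoss, train = trLoss, epoch = epoch,
                   snap = collectParams(layers))
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  if (!is.null(best$snap)) {
    restoreParams(layers, best$snap)
    bnRecalibrate(model@graph$trunk, td$X)
  }
  list(stopEpoch = best$epoch, trainLossAtBest = best$train,
       valLoss = best$val, epochsRun = nrow(log), log = log)
}

#' Final training on all cross-validation data
#'
#' Trains without a validation set until the running epoch training loss
#' reaches `criterion` (the mean of the cross-validation stoppage
#' training losses) or `maxEpochs`, whichever comes first.
#'
#' @param model a [CNNModel-class] (modified in place).
#' @param ex all cross-validation examples.
#' @param criterion target training loss.
#' @param config a [trainingConfig()].
#' @param head head to train.
#' @return list: `epochs`, `finalTrainLoss`, `reached`.
#' @export
trainFinalOnAll <- function(model, ex, criterion, config, head = "class") {
  stopifnot(!is.na(criterion))
  set.seed(config$seed + 1L)
  td <- taskData(ex, model, head)
  layers <- allModelLayers(model, head)
  adamInit(layers)
  t <- 0L
  trLoss <- Inf
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(td$n)
    i <- 1L
    trLoss <- 0
    while (i <= td$n) {
      j <- min(td$n, i + config$batchSize - 1L)
      sel <- ord[i:j]
      x <- td$X[, , sel, drop = FALSE]
      y <- if (is.matrix(td$y)) td$y[, sel, drop = FALSE] else td$y[sel]
      t <- t + 1L
      trLoss <- trLoss + trainOneBatch(model, head, x, y, layers,
                                       config$learningRate, t) * length(sel)
      i <- j + 1L
    }
    trLoss <- trLoss / td$n
    if (trLoss <= criterion) {
      bnRecalibrate(model@graph$trunk, td$X)
      return(list(epochs = epoch, finalTrainLoss = trLoss, reached = TRUE))
    }
  }
  bnRecalibrate(model@graph$trunk, td$X)
  warning("stopping criterion not reached within maxEpochs")
  list(epochs = config$maxEpochs, finalTrainLoss = trLoss, reached = FALSE)
}

# ---- model selection -----------------------------------------------------

#' Random hyper-parameter search space
#'
#' `sampler` is a zero-argument function returning a list with elements
#' `spec` (a [ShallowCNNSpec-class] or [DeepModelSpec-class]) and
#' optionally `learningRate`.  Helpers [shallowSearchSpace()] and
#' [deepSearchSpace()] build common spaces; input length is sampled
#' uniformly for shallow models and derived from the receptive field
#' ([sampleInputLength()]) for deep ones.
#'
#' @param nTrials number of i.i.d. draws.
#' @param sampler the sampling function.
#' @export
searchSpace <- function(nTrials, sampler) {
  stopifnot(nTrials >= 1L, is.function(sampler))
  structure(list(nTrials = as.integer(nTrials), sampler = sampler),
            class = "searchSpace")
}

pick <- function(v) v[sample.int(length(v), 1L)]

#' @rdname searchSpace
#' @param nFilters,filterWidth,fcSizes,dropout,inputLengths,learningRates
#'   candidate values sampled uniformly.
#' @export
shallowSearchSpace <- function(nTrials = 5L, nFilters = c(8L, 16L, 32L),
                               filterWidth = c(8L, 12L, 16L),
                               fcSizes = list(16L, 32L, 64L),
                               dropout = c(0, 0.1, 0.2),
                               inputLengths = 200L:600L,
                               learningRates = c(1e-3, 3e-3)) {
  searchSpace(nTrials, function() {
    list(spec = shallowCNNSpec(
           nFilters = pick(nFilters),
           filterWidth = pick(filterWidth),
           fcSizes = fcSizes[[sample.int(length(fcSizes), 1L)]],
           dropout = pick(dropout),
           inputLength = pick(inputLengths)),
         learningRate = pick(learningRates))
  })
}

#' @rdname searchSpace
#' @param nPoolBlocks,nDilBlocks,channels,kernelWidths,poolWidth,
#'   bottleneck,bottleneckRatio candidate architecture values.
#' @export
deepSearchSpace <- function(nTrials = 5L, nPoolBlocks = 2L:3L,
                            nDilBlocks = 1L:3L, channels = c(16L, 32L),
                            kernelWidths = c(4L, 8L), poolWidth = 2L,
                            bottleneck = "relu",
                            bottleneckRatio = c(0.25, 0.5),
                            dropout = c(0, 0.1),
                            learningRates = c(1e-3, 3e-3)) {
  searchSpace(nTrials, function() {
    sp <- deepModelSpec(
      nPoolBlocks = pick(nPoolBlocks),
      nDilBlocks = pick(nDilBlocks),
      channels = pick(channels),
      kernelWidths = pick(kernelWidths),
      poolWidth = poolWidth,
      bottleneck = bottleneck,
      bottleneckRatio = pick(bottleneckRatio),
      dropout = pick(dropout))
    sp@inputLength <- sampleInputLength(receptiveField(sp))
    validObject(sp)
    list(spec = sp, learningRate = pick(learningRates))
  })
}

buildFromSpec <- function(spec, heads) {
  if (is(spec, "ShallowCNNSpec")) buildShallowCNN(spec, heads)
  else buildDeepCNN(spec, heads)
}

#' Random search with cross-validated early stopping
#'
#' Samples `nTrials` hyper-parameter draws, evaluates each by k-fold
#' cross-validation (mean best validation loss; ties broken by earlier
#' trial), then retrains the winner on all the data with
#' [trainFinalOnAll()] using the mean stoppage training loss as the
#' criterion.
#'
#' @param space a [searchSpace()].
#' @param ex cross-validation examples (test split already removed).
#' @param heads head description list for every candidate model.
#' @param config a [trainingConfig()].
#' @param head head to train and monitor.
#' @return list: `model` (final trained [CNNModel-class]), `best` (trial
#'   record), `trials` (data frame of all trials).
#' @export
randomSearch <- function(space, ex, heads, config, head = "class") {
  trials <- NULL
  best <- NULL
  for (tr in seq_len(space$nTrials)) {
    set.seed(config$seed + 1000L * tr)
    draw <- tryCatch(space$sampler(), error = function(e) NULL)
    cfg <- config
    if (is.null(draw)) {
      trials <- rbind(trials, data.frame(
        trial = tr, meanValLoss = NA_real_,
        meanStoppageTrainLoss = NA_real_, inputLength = NA_integer_,
        learningRate = cfg$learningRate, diverged = TRUE))
      next
    }
    if (!is.null(draw$learningRate)) cfg$learningRate <- draw$learningRate
    res <- tryCatch({
      ex2 <- reencodeExamples(ex, draw$spec@inputLength)
      folds <- splitCV(ex2, cfg)
      vals <- numeric(0)
      trs <- numeric(0)
      for (k in seq_len(cfg$folds)) {
        set.seed(cfg$seed + 1000L * tr + k)
        m <- buildFromSpec(draw$spec, heads)
        fit <- trainWithEarlyStopping(
          m, ex2[unlist(folds[-k])], ex2[folds[[k]]], cfg, head)
        vals <- c(vals, fit$valLoss)
        trs <- c(trs, fit$trainLossAtBest)
      }
      list(val = mean(vals), train = mean(trs))
    }, error = function(e) NULL)
    diverged <- is.null(res) || !is.finite(res$val)
    trials <- rbind(trials, data.frame(
      trial = tr, meanValLoss = if (diverged) NA_real_ else res$val,
      meanStoppageTrainLoss = if (diverged) NA_real_ else res$train,
      inputLength = draw$spec@inputLength,
      learningRate = cfg$learningRate, diverged = diverged))
    if (!diverged && (is.null(best) || res$val < best$val))
      best <- list(val = res$val, train = res$train, trial = tr,
                   draw = draw, cfg = cfg)
  }
  if (is.null(best)) stop("all trials diverged")
  ex2 <- reencodeExamples(ex, best$draw$spec@inputLength)
  set.seed(best$cfg$seed + 1000L * best$trial)
  model <- buildFromSpec(best$draw$spec, heads)
  trainFinalOnAll(model, ex2, best$train, best$cfg, head)
  list(model = model, best = best, trials = trials)
}

splitCV <- function(ex, config) {
  set.seed(config$seed)
  lab <- ex@labels
  folds <- replicate(config$folds, integer(0), simplify = FALSE)
  for (cl in levels(lab)) {
    idx <- which(lab == cl)
    if (length(idx) == 0L) next
    idx <- idx[sample.int(length(idx))]
    f <- rep_len(seq_len(config$folds), length(idx))
    for (k in seq_len(config$folds)) folds[[k]] <- c(folds[[k]], idx[f == k])
  }
  lapply(folds, sort)
}

# re-encode by centred crop/pad when a trial's input length differs
reencodeExamples <- function(ex, inputLength) {
  L <- dim(ex@X)[2L]
  if (L == inputLength) return(ex)
  n <- length(ex)
  X <- array(0, c(4L, inputLength, n))
  if (L > inputLength) {
    off <- (L - inputLength) %/% 2L
    X[, , ] <- ex@X[, off + seq_len(inputLength), , drop = FALSE]
  } else {
    off <- (inputLength - L) %/% 2L
    X[, off + seq_len(L), ] <- ex@X
  }
  new("LabelledExamples", X = X, labels = ex@labels, targets = ex@targets,
      ids = ex@ids)
}

# ---- regularization modes ------------------------------------------------

cloneLayers <- function(layers) lapply(layers, function(ly) {
  e <- new.env(parent = emptyenv())
  for (nm in setdiff(ls(ly), c("cache", "adam", "sub", "colbuf", "ybuf", "argbuf", "dxbuf")))
    assign(nm, get(nm, envir = ly), envir = e)
  if (ly$type == "dilblock") e$sub <- cloneLayers(ly$sub)
  e
})

#' Transfer-regularized shallow classifier
#'
#' Copies the convolutional layer of a trained shallow regression model,
#' freezes it, and selects/trains only the classifier that follows; the
#' input length is inherited from the regression model.  Because the
#' frozen stage never changes, its pooled features are computed once and
#' the classifier candidates train on the cached features.
#'
#' @param regressionModel trained shallow [CNNModel-class] with a
#'   regression head.
#' @param ex labelled examples encoded at any length (re-encoded to the
#'   regression model's input length).
#' @param classes classification class set, in output order.
#' @param config a [trainingConfig()].
#' @param fcOptions list of candidate fully-connected size vectors for
#'   the classifier search.
#' @return list: `model`, `best`, `trials` as in [randomSearch()].
#' @export
buildTransferModel <- function(regressionModel, ex, classes, config,
                               fcOptions = list(16L, 32L)) {
  g <- regressionModel@graph
  if (g$kind != "shallow") stop("transfer expects a trained shallow CNN")
  frozen <- cloneLayers(g$trunk[1:3])   # conv, relu, poolconcat
  freezeLayers(frozen)
  assembleFrozenClassifier(frozen, "transfer", g$spec, g$inputLength, ex,
                           classes, config, fcOptions)
}

#' Serial-regularized deep classifier
#'
#' Freezes a trained deep regression model and stacks a small fully
#' connected classifier on its per-replicate log-RPKM output vector; the
#' composite graph stays end-to-end differentiable so attribution can
#' flow to the input, but only classifier weights train.  The frozen
#' trunk's outputs are computed once and cached for the classifier
#' search.
#'
#' @param regressionModel trained deep [CNNModel-class] with head
#'   `"rpkm"`.
#' @inheritParams buildTransferModel
#' @return list: `model`, `best`, `trials`.
#' @export
buildSerialModel <- function(regressionModel, ex, classes, config,
                             fcOptions = list(16L, c(32L, 16L))) {
  g <- regressionModel@graph
  if (is.null(g$heads[["rpkm"]])) stop("regression head 'rpkm' required")
  frozen <- c(cloneLayers(g$trunk), cloneLayers(g$heads[["rpkm"]]$layers))
  freezeLayers(frozen)
  assembleFrozenClassifier(frozen, "serial", g$spec, g$inputLength, ex,
                           classes, config, fcOptions)
}

# shared machinery: cache the frozen stage's features, model-select the
# dense classifier on them, then assemble the end-to-end composite graph
assembleFrozenClassifier <- function(frozen, kind, spec, inputLength, ex,
                                     classes, config, fcOptions) {
  ex2 <- reencodeExamples(ex, inputLength)
  feat <- frozenFeatures(frozen, ex2@X)
  fex <- new("LabelledExamples",
             X = array(feat, c(nrow(feat), 1L, ncol(feat))),
             labels = ex2@labels, targets = ex2@targets, ids = ex2@ids)
  fin0 <- nrow(feat)
  buildCandidate <- function(fc) {
    trunk <- list(layerSqueeze())
    fin <- fin0
    for (sz in fc) {
      trunk <- c(trunk, list(layerDense(fin, sz), layerReLU()))
      fin <- sz
    }
    m <- newModel(kind, spec, trunk, list(classificationHead(classes)),
                  inputLength)
    m@graph$heads[["class"]]$layers <- list(layerDense(fin, length(classes)))
    m
  }
  sel <- classifierSelect(buildCandidate, fcOptions, fex, config)
  inner <- sel$model@graph
  final <- newModel(kind, spec,
                    c(frozen, inner$trunk),
                    list(classificationHead(classes)), inputLength)
  final@graph$heads[["class"]]$layers <- inner$heads[["class"]]$layers
  list(model = final, best = sel$best, trials = sel$trials)
}

# forward a frozen layer stack over a dataset in batches; returns a
# features x examples matrix
frozenFeatures <- function(layers, X, batchSize = 128L) {
  n <- dim(X)[3L]
  out <- NULL
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batchSize - 1L)
    f <- netForward(layers, X[, , i:j, drop = FALSE], train = FALSE)
    if (is.null(out)) out <- matrix(0, nrow(f), n)
    out[, i:j] <- f
    i <- j + 1L
  }
  out
}

# small deterministic model selection over classifier architectures:
# k-fold CV per candidate, winner refit on everything via the two-stage
# stopping criterion
classifierSelect <- function(buildCandidate, fcOptions, ex, config) {
  trials <- NULL
  best <- NULL
  for (tr in seq_along(fcOptions)) {
    fc <- fcOptions[[tr]]
    folds <- splitCV(ex, config)
    vals <- numeric(0); trs <- numeric(0)
    for (k in seq_len(config$folds)) {
      set.seed(config$seed + 1000L * tr + k)
      m <- buildCandidate(fc)
      fit <- trainWithEarlyStopping(m, ex[unlist(folds[-k])],
                                    ex[folds[[k]]], config)
      vals <- c(vals, fit$valLoss)
      trs <- c(trs, fit$trainLossAtBest)
    }
    trials <- rbind(trials, data.frame(trial = tr,
                                       fc = paste(fc, collapse = "-"),
                                       meanValLoss = mean(vals),
                                       meanStoppageTrainLoss = mean(trs)))
    if (is.null(best) || mean(vals) < best$val)
      best <- list(val = mean(vals), train = mean(trs), trial = tr, fc = fc)
  }
  set.seed(config$seed + 1000L * best$trial)
  model <- buildCandidate(best$fc)
  trainFinalOnAll(model, ex, best$train, config)
  list(model = model, best = best, trials = trials)
}

#' Parallel multitask training of a deep model
#'
#' Builds a deep model whose shared trunk feeds a regression head over
#' all replicate targets plus one (`tasks = "2task"`: down-binding) or
#' two (`"3task"`: down- and up-binding, sharing the non-differential
#' class) classification heads.  Minibatches alternate cyclically across
#' the task heads (regression, down, up), each batch updating the trunk
#' and that head; early stopping monitors the summed classification
#' validation loss only.
#'
#' @param spec a [DeepModelSpec-class].
#' @param trainEx,valEx [LabelledExamples-class] splits (regression
#'   targets required for all examples).
#' @param config a [trainingConfig()].
#' @param tasks `"2task"` or `"3task"`.
#' @param tissueNames tissues defining the up_/down_ class sets.
#' @return list: `model`, `fit` (early-stopping record).
#' @export
trainParallelMultitask <- function(spec, trainEx, valEx, config,
                                   tasks = c("2task", "3task"),
                                   tissueNames = NULL) {
  tasks <- match.arg(tasks)
  if (is.null(tissueNames)) {
    lv <- levels(trainEx@labels)
    tissueNames <- sub("^down_", "", grep("^down_", lv, value = TRUE))
  }
  downClasses <- c(paste0("down_", tissueNames), "non_differential")
  upClasses <- c(paste0("up_", tissueNames), "non_differential")
  heads <- list(regressionHead(colnames(trainEx@targets)),
                classificationHead(downClasses, name = "down"))
  if (tasks == "3task")
    heads <- c(heads, list(classificationHead(upClasses, name = "up")))
  set.seed(config$seed)
  model <- buildDeepCNN(spec, heads)
  ex2 <- reencodeExamples(trainEx, spec@inputLength)
  val2 <- reencodeExamples(valEx, spec@inputLength)

  clsHeads <- setdiff(names(model@graph$heads), "rpkm")
  tds <- lapply(names(model@graph$heads), function(h) taskData(ex2, model, h))
  names(tds) <- names(model@graph$heads)
  vds <- lapply(clsHeads, function(h) taskData(val2, model, h))
  names(vds) <- clsHeads
  if (all(vapply(tds[clsHeads], function(d) d$n, integer(1)) == 0L))
    stop("no classification examples supplied")

  layers <- allModelLayers(model)
  adamInit(layers)
  order <- c("rpkm", "down", if (tasks == "3task") "up")
  best <- list(val = Inf, epoch = 0L, snap = NULL)
  bad <- 0L
  t <- 0L
  log <- NULL
  for (epoch in seq_len(config$maxEpochs)) {
    queues <- lapply(order, function(h) {
      n <- tds[[h]]$n
      split(sample.int(n), ceiling(seq_len(n) / config$batchSize))
    })
    names(queues) <- order
    ptr <- stats::setNames(rep(1L, length(order)), order)
    repeat {
      progressed <- FALSE
      for (h in order) {             # fixed cyclic alternation
        q <- queues[[h]]
        if (ptr[[h]] > length(q)) next
        sel <- q[[ptr[[h]]]]
        ptr[[h]] <- ptr[[h]] + 1L
        progressed <- TRUE
        td <- tds[[h]]
        x <- td$X[, , sel, drop = FALSE]
        y <- if (is.matrix(td$y)) td$y[, sel, drop = FALSE] else td$y[sel]
        t <- t + 1L
        hl <- allModelLayers(model, h)
        trainOneBatch(model, h, x, y, hl, config$learningRate, t)
      }
      if (!progressed) break
    }
    # early stopping: classification validation loss only
    bnRecalibrate(model@graph$trunk, tds[["rpkm"]]$X)
    valLoss <- sum(vapply(clsHeads, function(h)
      evalTaskLoss(model, h, vds[[h]]), numeric(1)))
    log <- rbind(log, data.frame(epoch = epoch, clsValLoss = valLoss))
    if (valLoss < best$val - 1e-9) {
      best <- list(val = valLoss, epoch = epoch,
                   snap = collectParams(layers))
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= config$patience) break
    }
  }
  if (!is.null(best$snap)) {
    restoreParams(layers, best$snap)
    bnRecalibrate(model@graph$trunk, tds[["rpkm"]]$X)
  }
  list(model = model,
       fit = list(stopEpoch = best$epoch, valLoss = best$val, log = log))
}
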