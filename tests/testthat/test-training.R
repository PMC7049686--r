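test_that("reverse-complement augmentation follows the minority rule", {
  mk <- function(counts) {
    n <- sum(counts)
    lab <- factor(rep(names(counts), counts),
                  levels = c("down", "up", "non"))
    new("LabelledExamples",
        X = array(as.numeric(runif(4 * 20 * n) > 0.75), c(4, 20, n)),
        labels = lab,
        targets = matrix(0, n, 1, dimnames = list(NULL, "t")),
        ids = as.character(seq_len(n)))
  }
  ex <- mk(c(down = 100L, up = 300L, non = 250L))
  a <- augmentReverseComplement(ex, "down")
  expect_equal(unname(table(exampleLabels(a))[c("down", "up", "non")]),
               c(200L, 300L, 250L), ignore_attr = TRUE)
  ex2 <- mk(c(down = 100L, up = 150L, non = 250L))
  a2 <- augmentReverseComplement(ex2, "down")
  expect_equal(unname(table(exampleLabels(a2))[c("down", "up", "non")]),
               c(200L, 300L, 250L), ignore_attr = TRUE)
  # duplicated examples are true reverse complements
  rc <- exampleTensor(a)[, , 651]
  orig <- exampleTensor(a)[, , which(exampleIds(a) ==
            sub("_rc", "", exampleIds(a)[651]))[1]]
  expect_equal(rc, orig[4:1, 20:1])
  # empty target class: unchanged
  ex3 <- mk(c(down = 0L, up = 10L, non = 10L))
  expect_equal(length(augmentReverseComplement(ex3, "down")), 20L)
  expect_error(augmentReverseComplement(ex, "bogus"), "unknown class")
})

test_that("stratified splitting partitions the data deterministically", {
  ds <- generateDataset(tinyConfig(n = 100L))
  ex <- encodeExamples(ds, 200L)
  tc <- trainingConfig(seed = 3L)
  sp <- splitFolds(ex, tc)
  expect_equal(length(sp$test), 140L)
  sizes <- lengths(sp$folds)
  expect_true(all(abs(sizes - 560 / 3) <= 4))
  all <- c(sp$test, unlist(sp$folds))
  expect_equal(sort(all), seq_len(700L))       # disjoint union
  sp2 <- splitFolds(ex, tc)
  expect_identical(sp, sp2)
  expect_error(splitFolds(ex[1:2], tc), "too small")
})

test_that("early stopping obeys patience and restores the best epoch", {
  # training targets +5, validation targets -5: every step towards the
  # training optimum increases validation loss from epoch 1 on
  set.seed(1)
  n <- 60L
  X <- array(as.numeric(runif(4 * 200 * n) > 0.75), c(4, 200, n))
  mk <- function(t) new("LabelledExamples", X = X,
                        labels = factor(rep("a", n)),
                        targets = matrix(t, n, 1,
                                         dimnames = list(NULL, "t")),
                        ids = as.character(1:n))
  m <- buildShallowCNN(shallowCNNSpec(nFilters = 4L, filterWidth = 6L,
                                      fcSizes = 4L, dropout = 0,
                                      inputLength = 200L),
                       list(regressionHead("t")))
  tc <- trainingConfig(patience = 2L, maxEpochs = 20L, seed = 2L,
                       learningRate = 0.05)
  fit <- trainWithEarlyStopping(m, mk(5), mk(-5), tc, head = "rpkm")
  expect_equal(fit$epochsRun, 3L)   # epochs 2 and 3 fail to improve
  expect_equal(fit$stopEpoch, 1L)
  # monotone improvement runs to maxEpochs
  set.seed(3)
  m2 <- buildShallowCNN(shallowCNNSpec(nFilters = 4L, filterWidth = 6L,
                                       fcSizes = 4L, dropout = 0,
                                       inputLength = 200L),
                        list(regressionHead("t")))
  tc2 <- trainingConfig(patience = 3L, maxEpochs = 6L, seed = 2L,
                        learningRate = 1e-3)
  fit2 <- trainWithEarlyStopping(m2, mk(5), mk(5), tc2, head = "rpkm")
  expect_equal(fit2$epochsRun, 6L)
  # training reduced the loss against initialization
  expect_lt(fit2$log$train[6], fit2$log$train[1])
})

test_that("final training stops at the cross-validation criterion", {
  set.seed(1)
  ex <- motifToyExamples(n = 60L)
  mkm <- function() buildShallowCNN(
    shallowCNNSpec(nFilters = 4L, filterWidth = 6L, fcSizes = 4L,
                   dropout = 0, inputLength = 200L),
    list(regressionHead(c("g1", "g2"))))
  tc <- trainingConfig(maxEpochs = 5L, seed = 2L)
  r1 <- trainFinalOnAll(mkm(), ex, Inf, tc, head = "rpkm")
  expect_equal(r1$epochs, 1L)       # immediately satisfied
  expect_true(r1$reached)
  expect_warning(r2 <- trainFinalOnAll(mkm(), ex, -1, tc, head = "rpkm"),
                 "not reached")
  expect_equal(r2$epochs, 5L)
  expect_false(r2$reached)
  # a criterion from a prior CV run is reachable by the stopping rule
  m <- mkm()
  fit <- trainWithEarlyStopping(m, ex[1:40], ex[41:60],
                                trainingConfig(maxEpochs = 8L, seed = 2L),
                                head = "rpkm")
  r3 <- trainFinalOnAll(mkm(), ex, fit$trainLossAtBest * 1.5, tc,
                        head = "rpkm")
  expect_true(r3$finalTrainLoss <= fit$trainLossAtBest * 1.5 ||
                !r3$reached)
})

test_that("random search selects the usable spec and is reproducible", {
  ex <- motifToyExamples(n = 90L)
  tc <- trainingConfig(maxEpochs = 2L, patience = 1L, seed = 4L,
                       folds = 3L)
  # one healthy candidate and one whose dilation window cannot fit
  good <- shallowCNNSpec(nFilters = 4L, filterWidth = 6L, fcSizes = 4L,
                         dropout = 0, inputLength = 200L)
  i <- 0
  space <- searchSpace(2L, function() {
    i <<- i + 1
    if (i %% 2 == 0) list(spec = good)
    else list(spec = deepModelSpec(2L, 1L, channels = 8L,
                                   kernelWidths = c(16L, 16L, 60L),
                                   dilationBase = 4L,
                                   inputLength = 280L))   # unusable
  })
  res <- randomSearch(space, ex, list(classificationHead(c("pos", "neg"))),
                      tc)
  expect_equal(res$best$trial, 2L)
  expect_true(res$trials$diverged[1])
  # single-trial search trivially selects that trial
  sp1 <- searchSpace(1L, function() list(spec = good))
  r1 <- randomSearch(sp1, ex, list(classificationHead(c("pos", "neg"))), tc)
  expect_equal(r1$best$trial, 1L)
  r1b <- randomSearch(sp1, ex, list(classificationHead(c("pos", "neg"))), tc)
  expect_identical(r1$best$val, r1b$best$val)
  expect_identical(predictLogits(r1$model, exampleTensor(ex[1:3])),
                   predictLogits(r1b$model, exampleTensor(ex[1:3])))
})

test_that("transfer models freeze the copied convolution bit-for-bit", {
  ex <- motifToyExamples(n = 120L)
  tc <- trainingConfig(maxEpochs = 6L, patience = 2L, seed = 5L)
  set.seed(6)
  reg <- buildShallowCNN(shallowCNNSpec(nFilters = 8L, filterWidth = 8L,
                                        fcSizes = 8L, dropout = 0,
                                        inputLength = 200L),
                         list(regressionHead(c("g1", "g2"))))
  trainWithEarlyStopping(reg, ex[1:80], ex[81:120], tc, head = "rpkm")
  Wconv <- reg@graph$trunk[[1L]]$W
  res <- buildTransferModel(reg, ex, classes = c("pos", "neg"),
                            config = tc, fcOptions = list(4L))
  tm <- res$model
  expect_identical(tm@graph$trunk[[1L]]$W, Wconv)   # frozen, bit-identical
  expect_true(tm@graph$trunk[[1L]]$frozen)
  expect_equal(modelInputLength(tm), modelInputLength(reg))
  expect_equal(modelKind(tm), "transfer")
})

test_that("an informative frozen convolution beats a random one", {
  ex <- motifToyExamples(n = 240L, seed = 8L)
  tc <- trainingConfig(maxEpochs = 12L, patience = 4L, seed = 5L,
                       learningRate = 3e-3)
  set.seed(6)
  reg <- buildShallowCNN(shallowCNNSpec(nFilters = 8L, filterWidth = 8L,
                                        fcSizes = 8L, dropout = 0,
                                        inputLength = 200L),
                         list(regressionHead(c("g1", "g2"))))
  # the regression targets encode motif presence, so this conv learns it
  trainWithEarlyStopping(reg, ex[1:160], ex[161:200], tc, head = "rpkm")
  set.seed(6)
  rnd <- buildShallowCNN(shallowCNNSpec(nFilters = 8L, filterWidth = 8L,
                                        fcSizes = 8L, dropout = 0,
                                        inputLength = 200L),
                         list(regressionHead(c("g1", "g2"))))
  f1 <- function(regModel) {
    res <- buildTransferModel(regModel, ex[1:200],
                              classes = c("pos", "neg"), config = tc,
                              fcOptions = list(4L))
    te <- ex[201:240]
    pr <- t(predictProbs(res$model, exampleTensor(te)))
    colnames(pr) <- c("pos", "neg")
    macroF1(classificationReport(exampleLabels(te), pr))
  }
  expect_gt(f1(reg), f1(rnd) - 0.05)   # informative conv at least as good
})

test_that("serial models keep the trunk frozen and compose functionally", {
  ex <- motifToyExamples(n = 120L)
  tc <- trainingConfig(maxEpochs = 4L, patience = 2L, seed = 5L)
  sp <- deepModelSpec(2L, 1L, channels = 8L,
                      kernelWidths = c(16L, 16L, 8L),
                      inputLength = 200L)
  set.seed(7)
  reg <- buildDeepCNN(sp, list(regressionHead(c("g1", "g2"))))
  trainWithEarlyStopping(reg, ex[1:80], ex[81:120], tc, head = "rpkm")
  ns0 <- asNamespace("deepCobind")
  snap <- ns0$collectParams(reg@graph$trunk)
  res <- buildSerialModel(reg, ex, classes = c("pos", "neg"), config = tc,
                          fcOptions = list(4L))
  sm <- res$model
  ns <- asNamespace("deepCobind")
  frozenConvs <- Filter(function(l) l$type == "conv",
                        ns$flattenLayers(sm@graph$trunk))
  expect_true(all(vapply(frozenConvs, function(l) l$frozen, logical(1))))
  # composition: class logits are a function of the trunk's N-vector only
  x1 <- exampleTensor(ex)[, , 1]
  nTrunk <- length(reg@graph$trunk) + length(reg@graph$heads[["rpkm"]]$layers)
  z <- ns$netForward(sm@graph$trunk[seq_len(nTrunk)],
                     array(x1, c(4, 200, 1)), FALSE)
  full <- predictLogits(sm, x1)
  clf <- ns$netForward(sm@graph$trunk[-seq_len(nTrunk)], z, FALSE)
  manual <- ns$netForward(sm@graph$heads[["class"]]$layers, clf, FALSE)
  expect_equal(full, manual, tolerance = 1e-12, ignore_attr = TRUE)
  # trunk weights unchanged by classifier training
  snap2 <- ns$collectParams(sm@graph$trunk[seq_len(length(reg@graph$trunk))])
  expect_identical(snap2, snap)
})

test_that("a serial classifier separates classes defined by its trunk output", {
  # regression targets: group means differ exactly with the class, so a
  # trunk that predicts them makes the classes linearly separable
  ex <- motifToyExamples(n = 240L, seed = 9L)
  tc <- trainingConfig(maxEpochs = 15L, patience = 5L, seed = 5L,
                       learningRate = 3e-3)
  sp <- deepModelSpec(2L, 1L, channels = 12L,
                      kernelWidths = c(16L, 16L, 8L),
                      inputLength = 200L)
  set.seed(8)
  reg <- buildDeepCNN(sp, list(regressionHead(c("g1", "g2"))))
  trainWithEarlyStopping(reg, ex[1:160], ex[161:200], tc, head = "rpkm")
  res <- buildSerialModel(reg, ex[1:200], classes = c("pos", "neg"),
                          config = tc, fcOptions = list(8L))
  te <- ex[201:240]
  pred <- c("pos", "neg")[max.col(t(predictLogits(res$model,
                                                  exampleTensor(te))),
                                  ties.method = "first")]
  recallPos <- mean(pred[exampleLabels(te) == "pos"] == "pos")
  expect_gte(recallPos, 0.6)
})

test_that("parallel multitask builds the shared-class head structure", {
  ds <- generateDataset(tinyConfig(n = 15L, lengths = c(200L, 300L)))
  ex <- encodeExamples(ds, 250L)
  tc <- trainingConfig(maxEpochs = 2L, patience = 1L, seed = 6L)
  sp <- deepModelSpec(2L, 1L, channels = 8L,
                      kernelWidths = c(16L, 16L, 8L),
                      inputLength = 205L)
  r2 <- trainParallelMultitask(sp, ex[1:84], ex[85:105], tc,
                               tasks = "2task")
  expect_setequal(names(r2$model@graph$heads), c("rpkm", "down"))
  expect_equal(length(headClasses(r2$model, "down")), 4L)  # 3 down + non
  r3 <- trainParallelMultitask(sp, ex[1:84], ex[85:105], tc,
                               tasks = "3task")
  expect_setequal(names(r3$model@graph$heads), c("rpkm", "down", "up"))
  expect_equal(sort(headClasses(r3$model, "up")),
               sort(c(paste0("up_", c("tissueA", "tissueB", "tissueC")),
                      "non_differential")))
  # the early-stopping log tracks classification loss only
  expect_named(r2$fit$log, c("epoch", "clsValLoss"))
})
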