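test_that("convolutional layer counts follow the block structure", {
  expect_equal(countConvLayers(deepModelSpec(3L, 7L)), 21L)
  expect_equal(countConvLayers(
    deepModelSpec(0L, 0L, channels = integer(0),
                  kernelWidths = integer(0))), 1L)
  expect_equal(countConvLayers(deepModelSpec(1L, 1L)), 5L)
  expect_equal(countConvLayers(deepModelSpec(3L, 7L, bottleneck = "off")),
               11L)
  expect_equal(countConvLayers(deepModelSpec(2L, 3L, bottleneck = "off")),
               6L)
})

test_that("analytic receptive field matches hand-computed layer stacks", {
  # single convolution: RF is the filter width
  expect_equal(receptiveField(shallowCNNSpec(filterWidth = 25L)), 25L)
  # conv k=3 -> pool w=2,s=2 -> conv k=3 (d=1): 1 + 2 + 1 + 2*2 = 8
  sp <- deepModelSpec(1L, 1L, channels = 8L, kernelWidths = c(3L, 3L),
                      poolWidth = 2L, dilationBase = 1L, maxDilation = 1L)
  expect_equal(receptiveField(sp), 8L)
})

test_that("analytic receptive field equals the perturbation oracle", {
  ns <- asNamespace("deepCobind")
  set.seed(42)
  for (rep in 1:8) {
    np <- sample(1:2, 1); nd <- sample(0:2, 1)
    ks <- sample(3:9, np + nd, replace = TRUE)
    pw <- sample(2:3, 1); db <- sample(1:2, 1)
    rf <- asNamespace("deepCobind")$rfFromParams(np, nd, ks, pw, db, 2, 4L)
    if (rf >= 170L) next   # keep the probed unit clear of the borders
    sp <- deepModelSpec(
      nPoolBlocks = np, nDilBlocks = nd, channels = 4L, kernelWidths = ks,
      poolWidth = pw, bottleneck = "relu", bottleneckRatio = 0.5,
      dropout = 0, dilationBase = db, maxDilation = 4L,
      inputLength = max(200L, rf))
    m <- buildDeepCNN(sp, list(classificationHead(c("a", "b"))))
    # all-positive weights + positive input: every path stays active, so
    # a large perturbation provably reaches every unit in range
    for (ly in ns$flattenLayers(m@graph$trunk))
      for (p in ly$params) assign(p, abs(get(p, ly)) + 0.01, envir = ly)
    L <- sp@inputLength
    set.seed(rep)
    x <- array(stats::runif(4 * L) + 0.5, c(4, L, 1))
    base <- ns$netForward(m@graph$trunk, x, train = FALSE)
    len <- dim(base)[2L]
    mid <- (len + 1L) %/% 2L
    # batch of single-position perturbations
    Xp <- array(rep(x, L), c(4, L, L))
    for (p in seq_len(L)) Xp[, p, p] <- Xp[, p, p] + 100
    out <- ns$netForward(m@graph$trunk, Xp, train = FALSE)
    affected <- which(vapply(seq_len(L), function(p)
      any(abs(out[, mid, p] - base[, mid, 1]) > 1e-8), logical(1)))
    expect_equal(max(affected) - min(affected) + 1L, rf,
                 label = sprintf("perturbation span (trial %d)", rep))
  }
})

test_that("input length sampling expands the receptive field up to twice", {
  set.seed(1)
  v <- replicate(50, sampleInputLength(600L))
  expect_true(all(v >= 600 & v <= 1200))
  v2 <- replicate(50, sampleInputLength(1500L))
  expect_true(all(v2 >= 1500 & v2 <= 2000))
  set.seed(9); a <- sampleInputLength(700L)
  set.seed(9); b <- sampleInputLength(700L)
  expect_identical(a, b)
  expect_error(sampleInputLength(2001L), "2000")
})

test_that("deep spec validity constrains the input window", {
  expect_error(deepModelSpec(2L, 2L, channels = 8L,
                             kernelWidths = c(16L, 16L, 8L, 8L),
                             inputLength = 2000L),
               "inputLength")
  expect_error(deepModelSpec(1L, 1L, bottleneckRatio = 1.5), "bottleneckRatio")
})

test_that("shallow models pool max and average per filter", {
  set.seed(2)
  sp <- shallowCNNSpec(nFilters = 16L, filterWidth = 8L, fcSizes = 8L,
                       dropout = 0, inputLength = 200L)
  m <- buildShallowCNN(sp, list(classificationHead(c("a", "b"))))
  ns <- asNamespace("deepCobind")
  x <- array(randomOneHot(200, seed = 3), c(4, 200, 1))
  pooled <- ns$netForward(m@graph$trunk[1:3], x, FALSE)
  expect_equal(nrow(pooled), 32L)   # 2 x nFilters
  # constant input: per-filter max equals average (width-1 filters keep
  # every position identical; wider same-padded filters differ at the
  # borders, so the translation-invariance claim is exact only there)
  sp1 <- shallowCNNSpec(nFilters = 16L, filterWidth = 1L, fcSizes = 8L,
                        dropout = 0, inputLength = 200L)
  m1 <- buildShallowCNN(sp1, list(classificationHead(c("a", "b"))))
  xc <- array(0.25, c(4, 200, 1))
  pc <- ns$netForward(m1@graph$trunk[1:3], xc, FALSE)
  expect_equal(pc[1:16, 1], pc[17:32, 1], tolerance = 1e-12)
})

test_that("a PWM-matched filter scores motif regions highest", {
  ns <- asNamespace("deepCobind")
  motif <- motifFromConsensus("m", "TGACTCA", 0.9)
  lodds <- log(motif@pwm / 0.25)
  set.seed(4)
  sp <- shallowCNNSpec(nFilters = 1L, filterWidth = 7L, fcSizes = 4L,
                       dropout = 0, inputLength = 200L)
  m <- buildShallowCNN(sp, list(classificationHead(c("a", "b"))))
  conv <- m@graph$trunk[[1L]]
  conv$W <- matrix(as.vector(lodds), 1L)   # taps ordered (base, position)
  conv$b <- 0
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""), "")
  withMotif <- seq(1, 30, by = 3)
  for (i in withMotif) {
    p <- sample(60:120, 1)
    substr(seqs[i], p, p + 6) <- "TGACTCA"
  }
  X <- encodeSequences(seqs, 200L)
  pooled <- ns$netForward(m@graph$trunk[1:3], X, FALSE)
  mx <- pooled[1, ]
  # sliding dot-product oracle emulating the same-padded convolution
  oracle <- vapply(seq_len(30), function(i) {
    xp <- cbind(matrix(0, 4, 3), X[, , i], matrix(0, 4, 3))
    best <- -Inf
    for (s in seq_len(200)) {
      v <- sum(lodds * xp[, s:(s + 6)])
      if (v > best) best <- v
    }
    best
  }, numeric(1))
  expect_gt(min(rank(mx)[withMotif]), 20)
  # the convolution applies ReLU before pooling, clamping negative maxima
  expect_equal(mx, pmax(0, oracle), tolerance = 1e-8)
})

test_that("deep graph shapes and bottleneck widths follow the spec", {
  ns <- asNamespace("deepCobind")
  sp <- smallDeepSpec()
  m <- buildDeepCNN(sp, list(classificationHead(c("a", "b", "c"))))
  x <- array(randomOneHot(300, seed = 5), c(4, 300, 2))
  feat <- ns$netForward(m@graph$trunk, x, FALSE)
  expect_equal(dim(feat)[2L], 300L %/% 4L)   # floor(L / pool^nPool)
  # bottleneck channel counts: round(ratio x channels), >= 1
  convs <- Filter(function(l) l$type == "conv",
                  ns$flattenLayers(m@graph$trunk))
  ks <- vapply(convs, function(l) l$k, integer(1))
  couts <- vapply(convs, function(l) l$cout, integer(1))
  expect_equal(couts[ks == 1L], c(12L, 16L, 16L, 16L))
  # bottleneck off: only main convs remain
  sp2 <- deepModelSpec(2L, 1L, channels = 8L,
                       kernelWidths = c(16L, 16L, 8L),
                       bottleneck = "off", inputLength = 205L)
  m2 <- buildDeepCNN(sp2, list(classificationHead(c("a", "b"))))
  convs2 <- Filter(function(l) l$type == "conv",
                   ns$flattenLayers(m2@graph$trunk))
  expect_length(convs2, 3L)
})

test_that("logits and probabilities differ by exactly a softmax", {
  set.seed(6)
  m <- buildShallowCNN(shallowCNNSpec(nFilters = 4L, filterWidth = 6L,
                                      fcSizes = 4L, dropout = 0,
                                      inputLength = 200L),
                       list(classificationHead(c("a", "b", "c"))))
  X <- array(randomOneHot(200, seed = 7), c(4, 200, 1))
  lg <- predictLogits(m, X)
  pr <- predictProbs(m, X)
  expect_equal(pr, exp(lg) / sum(exp(lg)), tolerance = 1e-12)
  expect_equal(sum(pr), 1)
})

test_that("specs whose dilation window cannot fit are rejected", {
  # the receptive field of such a stack always exceeds the input bound,
  # so the spec is refused at construction
  expect_error(deepModelSpec(2L, 1L, channels = 8L,
                             kernelWidths = c(16L, 16L, 60L),
                             dilationBase = 4L, inputLength = 280L),
               "inputLength")
})

test_that("specs round-trip through DCF serialization", {
  dir <- withr::local_tempdir()
  sp <- deepModelSpec(2L, 2L, channels = c(24L, 32L, 32L, 32L),
                      kernelWidths = c(16L, 16L, 8L, 8L),
                      inputLength = 300L)
  f <- file.path(dir, "spec.dcf")
  writeSpec(sp, f)
  sp2 <- readSpec(f)
  expect_equal(sp2, sp)
  ssp <- shallowCNNSpec(nFilters = 8L, filterWidth = 10L,
                        fcSizes = c(32L, 16L), dropout = 0.2,
                        inputLength = 400L)
  writeSpec(ssp, f)
  expect_equal(readSpec(f), ssp)
})

test_that("trained models survive serialization round-trips", {
  set.seed(30)
  m <- buildShallowCNN(shallowCNNSpec(nFilters = 4L, filterWidth = 6L,
                                      fcSizes = 4L, dropout = 0,
                                      inputLength = 200L),
                       list(classificationHead(c("a", "b"))))
  x <- randomOneHot(200L, seed = 31)
  before <- predictLogits(m, x)
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m, f)
  m2 <- readRDS(f)
  expect_equal(predictLogits(m2, x), before, tolerance = 1e-15)
  expect_equal(headClasses(m2), c("a", "b"))
})
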