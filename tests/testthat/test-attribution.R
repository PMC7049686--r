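# Closed-form oracles on a hand-built linear scoring graph, plus the
# exact equivalences between the attribution methods.

test_that("mutagenesis maps match the linear closed form", {
  set.seed(1)
  L <- 40L
  W <- matrix(rnorm(2 * 4 * L), 2, 4 * L)
  m <- makeLinearModel(W, b = c(0.3, -0.1))
  x <- randomOneHot(L, seed = 2)
  mm <- mutationMap(m, x, "c1")
  w <- linW(W, 1L, L)
  ref <- apply(x, 2, which.max)
  for (i in seq_len(L)) for (b in 1:4)
    expect_equal(unname(mm@effects[i, b]), w[b, i] - w[ref[i], i],
                 tolerance = 1e-10)
  # reference-base entries are exactly zero
  expect_true(all(mm@effects[cbind(seq_len(L), ref)] == 0))
  # exactly 3 substitutions per retained position are evaluated
  expect_lte(sum(mm@effects != 0), 3L * L)
  expect_equal(rowSums(mm@effects != 0), rep(3L, L), ignore_attr = TRUE)
})

test_that("padded positions get zero mutagenesis effect", {
  set.seed(3)
  L <- 30L
  W <- matrix(rnorm(2 * 4 * L), 2, 4 * L)
  m <- makeLinearModel(W)
  x <- oneHotEncode("ACGTACGTAC", L, strict = FALSE)   # centred, padded
  mm <- mutationMap(m, x, "c1")
  padded <- colSums(x) == 0
  expect_true(all(mm@effects[padded, ] == 0))
})

test_that("importance summation follows the sign convention", {
  eff <- matrix(0, 1, 4)
  eff[1, 2:4] <- c(-2, -3, -1)      # reference base A
  mm <- new("MutationMap", effects = eff, referenceOutput = 0,
            classLabel = "c1")
  tr <- importanceFromMap(mm)
  expect_equal(tr@scores, 6)
  # all-zero map gives an all-zero track
  mm0 <- new("MutationMap", effects = matrix(0, 5, 4),
             referenceOutput = 0, classLabel = "c1")
  expect_equal(importanceFromMap(mm0)@scores, rep(0, 5))
  # linear closed form: 3 w(i, ref) - sum_{b != ref} w(i, b)
  set.seed(4)
  L <- 20L
  W <- matrix(rnorm(2 * 4 * L), 2, 4 * L)
  m <- makeLinearModel(W)
  x <- randomOneHot(L, seed = 5)
  sc <- importanceFromMap(mutationMap(m, x, "c2"))@scores
  w <- linW(W, 2L, L)
  ref <- apply(x, 2, which.max)
  exp_sc <- vapply(seq_len(L), function(i)
    3 * w[ref[i], i] - sum(w[-ref[i], i]), numeric(1))
  expect_equal(sc, exp_sc, tolerance = 1e-10)
})

test_that("integrated gradients are exact for affine models at any steps", {
  set.seed(6)
  L <- 25L
  W <- matrix(rnorm(3 * 4 * L), 3, 4 * L)
  m <- makeLinearModel(W, b = c(1, -2, 0.5))
  x <- randomOneHot(L, seed = 7)
  refs <- list(matrix(0, 4, L), randomOneHot(L, seed = 8))
  for (steps in c(1L, 7L, 64L)) {
    tr <- integratedGradients(m, x, "c2", steps = steps,
                              references = refs)
    w <- linW(W, 2L, L)
    expected <- (colSums(w * (x - refs[[1]])) +
                   colSums(w * (x - refs[[2]]))) / 2
    expect_equal(tr@scores, expected, tolerance = 1e-10)
    dev <- completenessCheck(m, x, "c2", steps = steps, references = refs)
    expect_lt(dev, 1e-10)
  }
  expect_error(integratedGradients(m, x, "c2",
                                   references = list(matrix(0, 4, L + 1))),
               "mismatch")
})

test_that("gradient x input equals one-step integrated gradients exactly", {
  set.seed(9)
  sp <- deepModelSpec(2L, 1L, channels = 8L, kernelWidths = c(16L, 16L, 8L),
                      inputLength = 200L)
  m <- buildDeepCNN(sp, list(classificationHead(c("a", "b"))))
  x <- randomOneHot(200L, seed = 10)
  g1 <- gradientTimesInput(m, x, "a")
  g2 <- integratedGradients(m, x, "a", steps = 1L)
  expect_equal(g1@scores, g2@scores, tolerance = 1e-12)
  # zero input gives a zero track
  g0 <- gradientTimesInput(m, matrix(0, 4, 200), "a")
  expect_equal(g0@scores, rep(0, 200))
  # linear model: gxi picks out the reference-base weight
  W <- matrix(rnorm(2 * 4 * 30), 2, 4 * 30)
  lm <- makeLinearModel(W)
  xs <- randomOneHot(30L, seed = 11)
  sc <- gradientTimesInput(lm, xs, "c1")@scores
  w <- linW(W, 1L, 30L)
  ref <- apply(xs, 2, which.max)
  expect_equal(sc, w[cbind(ref, seq_len(30))], tolerance = 1e-12)
})

test_that("completeness deviation shrinks with more integration steps", {
  set.seed(12)
  sp <- deepModelSpec(2L, 1L, channels = 8L, kernelWidths = c(16L, 16L, 8L),
                      inputLength = 200L)
  m <- buildDeepCNN(sp, list(classificationHead(c("a", "b"))))
  # freshly initialised nets are positively homogeneous (zero biases), so
  # integrated gradients would be exact at any step count; perturb the
  # biases the way training would
  ns <- asNamespace("deepCobind")
  for (ly in ns$flattenLayers(ns$allModelLayers(m))) {
    if (ly$type == "conv") ly$b <- rnorm(length(ly$b), sd = 0.5)
    if (ly$type == "bn") { ly$beta <- rnorm(length(ly$beta), sd = 0.5)
                           ly$rmean <- rnorm(length(ly$rmean), sd = 0.2) }
  }
  devs <- sapply(1:15, function(i) {
    x <- randomOneHot(200L, seed = 100 + i)
    c(completenessCheck(m, x, "a", steps = 8L),
      completenessCheck(m, x, "a", steps = 128L))
  })
  expect_lt(mean(devs[2, ], na.rm = TRUE), mean(devs[1, ], na.rm = TRUE))
  Xs <- array(vapply(1:5, function(i) randomOneHot(200L, seed = 200 + i),
                     matrix(0, 4, 200)), c(4, 200, 5))
  rp <- completenessReport(m, Xs, "a", steps = c(16L, 128L))
  expect_named(rp, c("steps", "meanDeviation", "maxDeviation", "excluded"))
})

test_that("strongest windows maximise the sliding sum with leftmost ties", {
  sc <- numeric(200)
  sc[51:59] <- 1            # 0-based positions 50..58
  call <- strongestWindow(sc, W = 25L, regionId = "r")
  expect_equal(call$start, 34L)
  expect_equal(call$end, 59L)
  expect_equal(call$score, 9)
  # uniform track: leftmost window wins the tie
  u <- strongestWindow(rep(1, 60), W = 25L)
  expect_equal(u$start, 0L)
  expect_error(strongestWindow(rep(1, 10), W = 25L), "shorter")
  # brute-force oracle over random tracks
  set.seed(13)
  for (i in 1:500) {
    L <- sample(30:120, 1)
    tr <- rnorm(L)
    Wd <- sample(c(5L, 25L), 1)
    if (L < Wd) next
    call <- strongestWindow(tr, W = Wd)
    sums <- vapply(seq_len(L - Wd + 1L), function(s)
      sum(tr[s:(s + Wd - 1L)]), numeric(1))
    expect_equal(call$score, max(sums), tolerance = 1e-9)
    expect_equal(call$start, which.max(sums) - 1L)
  }
})

test_that("feature ranking is deterministic and order-invariant", {
  mkTrack <- function(s, id) new("AttributionTrack", scores = s,
                                 classLabel = "c", method = "gradient_x_input",
                                 metadata = list(region = id))
  t1 <- rep(3 / 30, 30); t2 <- rep(1 / 30, 30); t3 <- rep(2 / 30, 30)
  tracks <- list(region1 = mkTrack(t1, "region1"),
                 region2 = mkTrack(t2, "region2"),
                 region3 = mkTrack(t3, "region3"))
  r <- rankFeatures(tracks, W = 25L)
  expect_equal(r$region, c("region1", "region3", "region2"))
  expect_equal(r$rank, 1:3)
  r2 <- rankFeatures(rev(tracks), W = 25L)
  expect_equal(r2$region, r$region)
})

test_that("ensemble attribution averages tracks across models", {
  set.seed(14)
  L <- 30L
  W <- matrix(rnorm(2 * 4 * L), 2, 4 * L)
  m1 <- makeLinearModel(W)
  m2 <- makeLinearModel(-W)
  x <- randomOneHot(L, seed = 15)
  single <- gradientTimesInput(m1, x, "c1")@scores
  same <- ensembleAttribution(list(m1, m1), x, "c1",
                              method = "gradient_x_input")
  expect_equal(same@scores, single, tolerance = 1e-12)
  opp <- ensembleAttribution(list(m1, m2), x, "c1",
                             method = "gradient_x_input")
  expect_equal(opp@scores, rep(0, L), tolerance = 1e-12)
  held <- ensembleAttribution(list(m1, m2), x, "c1",
                              method = "gradient_x_input",
                              mode = "heldout", holdoutOf = 2L)
  expect_equal(held@scores, -single, tolerance = 1e-12)
  all1 <- ensembleAttribution(list(m1, m2), x, "c1",
                              method = "gradient_x_input", mode = "alldata")
  expect_equal(all1@scores, single, tolerance = 1e-12)
})

test_that("tracks and feature calls export to standard formats", {
  dir <- withr::local_tempdir()
  tr <- new("AttributionTrack", scores = c(0.5, -1, 2), classLabel = "c",
            method = "gradient_x_input", metadata = list(region = "r1"))
  f1 <- file.path(dir, "track.bedGraph")
  exportTrackBedGraph(tr, f1)
  bg <- read.table(f1)
  expect_equal(bg$V4, c(0.5, -1, 2))
  expect_equal(bg$V2, 0:2)          # 0-based starts
  calls <- S4Vectors::DataFrame(region = c("a", "b"), start = c(5L, 0L),
                                end = c(30L, 25L), score = c(2, 1),
                                rank = 1:2)
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(101, 501),
                                                     width = 60))
  names(regions) <- c("a", "b")
  f2 <- file.path(dir, "calls.bed")
  exportFeatureBed(calls, regions, f2)
  bed <- read.table(f2)
  expect_equal(bed$V2, c(105L, 500L))   # region start0 + relative start
  expect_equal(bed$V3 - bed$V2, c(25L, 25L))
})
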