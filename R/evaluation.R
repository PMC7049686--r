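# Predictive metrics, the motif-centre Poisson test, and the
# cross-model feature-selection stability estimator.

#' Precision-recall curve for one class (one-vs-rest)
#'
#' Step-wise curve over decreasing score thresholds; the area is
#' accumulated as `sum (R_i - R_{i-1}) * P_i`, so an uninformative
#' constant score yields the class prevalence.
#'
#' @param truth logical vector (TRUE = positive class).
#' @param score numeric score for the positive class.
#' @return list with `recall`, `precision` vectors and `auc`.
#' @export
prCurve <- function(truth, score) {
  P <- sum(truth)
  if (P == 0L) return(list(recall = numeric(0), precision = numeric(0),
                           auc = NA_real_))
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  score <- score[ord]
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  keep <- c(score[-1] != score[-length(score)], TRUE)  # threshold boundaries
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / P
  precision <- tp / (tp + fp)
  auc <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision, auc = auc)
}

#' Classification evaluation report
#'
#' One-vs-rest precision-recall curves and PR-AUC per class, confusion
#' matrix from the argmax prediction, per-class recall and macro F1.
#'
#' @param truth factor of true labels.
#' @param scores numeric matrix examples x classes (colnames = classes);
#'   logits are converted to probabilities internally.
#' @param logits set TRUE when `scores` are pre-softmax logits.
#' @return a [ClassificationReport-class]; classes absent from `truth`
#'   get `NA` PR-AUC and are excluded from the macro F1.
#' @export
classificationReport <- function(truth, scores, logits = FALSE) {
  classes <- colnames(scores)
  stopifnot(!is.null(classes))
  truth <- factor(as.character(truth), levels = classes)
  if (logits) scores <- t(softmaxProbs(t(scores)))
  curves <- lapply(classes, function(cl)
    prCurve(truth == cl, scores[, cl]))
  names(curves) <- classes
  auc <- vapply(curves, function(cv) cv$auc, numeric(1))
  pred <- factor(classes[max.col(scores, ties.method = "first")],
                 levels = classes)
  conf <- table(truth = truth, predicted = pred)
  support <- rowSums(conf)
  recall <- ifelse(support > 0, diag(conf) / support, NA_real_)
  predTot <- colSums(conf)
  precision <- ifelse(predTot > 0, diag(conf) / predTot, 0)
  f1 <- ifelse(is.na(recall), NA_real_,
               ifelse(precision + recall > 0,
                      2 * precision * recall / (precision + recall), 0))
  new("ClassificationReport", prCurves = curves, prAUC = auc,
      confusion = conf, recall = recall, f1 = f1,
      macroF1 = mean(f1, na.rm = TRUE))
}

#' Regression evaluation report
#'
#' Per-replicate Pearson R and Spearman Rho between prediction and
#' truth; optionally the cross-replicate same-tissue correlations of the
#' true values, the expected upper bound of model performance.
#'
#' @param truth,pred aligned numeric matrices examples x replicates.
#' @param replicateTissues optional character vector assigning each
#'   column to a tissue; enables the cross-replicate bound.
#' @return a [RegressionReport-class]; zero-variance columns yield `NA`.
#' @export
regressionReport <- function(truth, pred, replicateTissues = NULL) {
  stopifnot(all(dim(truth) == dim(pred)))
  safeCor <- function(a, b, method) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = method)
  }
  nrep <- ncol(truth)
  r <- vapply(seq_len(nrep), function(j)
    safeCor(truth[, j], pred[, j], "pearson"), numeric(1))
  rho <- vapply(seq_len(nrep), function(j)
    safeCor(truth[, j], pred[, j], "spearman"), numeric(1))
  names(r) <- names(rho) <- colnames(truth)
  cross <- matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("R", "Rho")))
  if (!is.null(replicateTissues)) {
    for (t in unique(replicateTissues)) {
      js <- which(replicateTissues == t)
      if (length(js) < 2L) next
      for (a in seq_along(js)) for (b in seq_along(js)) if (a < b) {
        cross <- rbind(cross, c(
          safeCor(truth[, js[a]], truth[, js[b]], "pearson"),
          safeCor(truth[, js[a]], truth[, js[b]], "spearman")))
        rownames(cross)[nrow(cross)] <-
          paste0(colnames(truth)[js[a]], ":", colnames(truth)[js[b]])
      }
    }
  }
  new("RegressionReport", pearson = r, spearman = rho,
      crossReplicate = cross)
}

#' Upper-tail Poisson probability P(X >= k)
#'
#' @param k observed count.
#' @param lambda expected count.
#' @return `P(X >= k | lambda)`; 1 at `k = 0`.
#' @export
poissonUpperTail <- function(k, lambda)
  stats::ppois(k - 1, lambda, lower.tail = FALSE)

#' Motif-centre Poisson test of ranked features against read profiles
#'
#' For each feature, counts validation reads in a `window`-nt interval
#' centred on the feature midpoint in each of two replicates, compares
#' against the expected Poisson count, and requires `P < alpha` in both
#' replicates to pass.  The pass-proportion curve reports, for each n,
#' the fraction of the top-n ranked features passing; a random baseline
#' re-draws each feature position uniformly within its parent region.
#'
#' @param features `GRanges` of ranked feature windows (from
#'   [featureGenomicRanges()]; must be in rank order).
#' @param reads1,reads2 `readIndex` objects of the two validation
#'   replicates.
#' @param genomeSpan effective genome span in nt (for the background
#'   rate).
#' @param window test window in nt (default 500).
#' @param alpha per-replicate significance level (default 0.05).
#' @param lambdaMode `"global"` (dataset-wide average rate) or
#'   `"local"` (MACS2-style maximum of the global rate and the rates in
#'   1 kb / 5 kb / 10 kb windows around the feature).
#' @param regions optional named `GRanges` of parent regions; enables
#'   the random baseline.
#' @param baselineSeed seed for the baseline redraw.
#' @return a [PoissonTest-class].
#' @export
poissonMotifTest <- function(features, reads1, reads2, genomeSpan,
                             window = 500L, alpha = 0.05,
                             lambdaMode = c("global", "local"),
                             regions = NULL, baselineSeed = 1L) {
  lambdaMode <- match.arg(lambdaMode)
  half <- window / 2
  chrom <- as.character(GenomicRanges::seqnames(features))
  mid <- (GenomicRanges::start(features) - 1 +
            GenomicRanges::end(features)) / 2

  testAt <- function(reads, chr, mids) {
    k <- mapply(function(ch, m)
      countReads(reads, ch, floor(m - half), floor(m + half)), chr, mids)
    lam <- rep(reads$total / genomeSpan * window, length(mids))
    if (lambdaMode == "local") {
      for (w in c(1000L, 5000L, 10000L)) {
        kw <- mapply(function(ch, m)
          countReads(reads, ch, floor(m - w / 2), floor(m + w / 2)),
          chr, mids)
        lam <- pmax(lam, kw / w * window)
      }
    }
    list(k = as.integer(k), lambda = lam,
         p = poissonUpperTail(k, lam))
  }

  t1 <- testAt(reads1, chrom, mid)
  t2 <- testAt(reads2, chrom, mid)
  passed <- t1$p < alpha & t2$p < alpha
  n <- length(features)
  curve <- data.frame(n = seq_len(n),
                      proportion = cumsum(passed) / seq_len(n))
  if (!is.null(regions)) {
    set.seed(baselineSeed)
    rid <- S4Vectors::mcols(features)$region
    r <- regions[rid]
    rmid <- GenomicRanges::start(r) - 1 +
      floor(stats::runif(n) * GenomicRanges::width(r))
    b1 <- testAt(reads1, as.character(GenomicRanges::seqnames(r)), rmid)
    b2 <- testAt(reads2, as.character(GenomicRanges::seqnames(r)), rmid)
    bpass <- b1$p < alpha & b2$p < alpha
    curve$random <- cumsum(bpass) / seq_len(n)
  }
  res <- S4Vectors::DataFrame(
    region = if (!is.null(S4Vectors::mcols(features)$region))
      S4Vectors::mcols(features)$region else NA_character_,
    mid = mid, k1 = t1$k, k2 = t2$k,
    lambda1 = t1$lambda, lambda2 = t2$lambda,
    p1 = t1$p, p2 = t2$p, passed = passed)
  new("PoissonTest", results = res, curve = curve,
      window = as.integer(window), alpha = alpha)
}

#' Feature-selection stability over repeated model instances
#'
#' Treats each position of a region as a candidate feature and each
#' model's binary mask as a selection of ~k of d positions.  Per region,
#' `Phi = 1 - mean_f s_f^2 / (kbar/d * (1 - kbar/d))` with `s_f^2` the
#' unbiased sample variance of the selection indicator of position f
#' across models and `kbar` the mean number of selected positions.
#' `Phi = 1` iff all models select identically in every region; for
#' independent uniform-random selections its expectation is 0.  The
#' score is averaged over regions; regions with a degenerate
#' denominator (all or no positions selected) are excluded and counted.
#'
#' @param masks list over regions of binary matrices (models x region
#'   length).
#' @return a [StabilityResult-class].
#' @export
stabilityEstimator <- function(masks) {
  stopifnot(length(masks) >= 1L)
  M <- nrow(masks[[1L]])
  if (M < 2L) stop("at least 2 models required")
  phi <- vapply(masks, function(m) {
    d <- ncol(m)
    p <- mean(m)
    denom <- p * (1 - p)
    if (denom == 0) return(NA_real_)
    cm <- colMeans(m)
    v <- (colSums(m) - M * cm^2) / (M - 1)   # binary: m^2 = m
    1 - mean(v) / denom
  }, numeric(1))
  excluded <- sum(is.na(phi))
  new("StabilityResult", phi = mean(phi, na.rm = TRUE),
      perRegion = phi, nModels = as.integer(M),
      nRegions = length(masks),
      maskWidth = mean(vapply(masks, function(m) mean(rowSums(m)),
                              numeric(1))),
      excluded = as.integer(excluded))
}

#' Binary mask of the strongest attribution window
#'
#' @param track an [AttributionTrack-class] or numeric score vector.
#' @param W mask width in nt (default 25).
#' @return binary vector of the track length with `W` ones.
#' @export
featureMask <- function(track, W = 25L) {
  sc <- if (is(track, "AttributionTrack")) track@scores else track
  call <- strongestWindow(sc, W)
  m <- integer(length(sc))
  m[(call$start + 1L):call$end] <- 1L
  m
}

#' Attribution stability experiment across model initializations
#'
#' Trains `nModels` models with identical data and hyper-parameters but
#' different initialization seeds, attributes a fixed region sample with
#' each, converts each region's strongest window into a `width`-nt
#' binary mask, and evaluates the stability estimator.
#'
#' @param trainFun function(seed) returning a trained
#'   [CNNModel-class]; called with seeds `1..nModels`.
#' @param X array `(4, L, n)` of regions to attribute.
#' @param class class to attribute.
#' @param nModels number of model instances (default 10).
#' @param width mask width in nt (default 25).
#' @param method attribution method.
#' @param head head name.
#' @param ... passed to the attribution function.
#' @return a [StabilityResult-class].
#' @export
stabilityExperiment <- function(trainFun, X, class, nModels = 10L,
                                width = 25L,
                                method = c("gradient_x_input",
                                           "integrated_gradients",
                                           "mutagenesis"),
                                head = "class", ...) {
  method <- match.arg(method)
  n <- dim(X)[3L]
  L <- dim(X)[2L]
  masks <- lapply(seq_len(n), function(i) matrix(0L, nModels, L))
  for (mIdx in seq_len(nModels)) {
    model <- trainFun(mIdx)
    if (!is(model, "CNNModel")) stop("model ", mIdx, " failed to train")
    for (i in seq_len(n)) {
      tr <- attributeOne(model, X[, , i], class, method, head = head, ...)
      masks[[i]][mIdx, ] <- featureMask(tr, width)
    }
  }
  stabilityEstimator(masks)
}
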