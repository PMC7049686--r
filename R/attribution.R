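# Nucleotide-level attribution: in silico mutagenesis, integrated
# gradients and gradient-times-input, all evaluated on the raw
# pre-softmax logit of the chosen class; plus sliding-window feature
# ranking and fold-ensemble attribution.

classIndex <- function(model, head, class) {
  cls <- model@graph$heads[[head]]$classes
  i <- match(class, cls)
  if (is.na(i)) stop("unknown class '", class, "' for head '", head, "'")
  i
}

# logits for a batch, returning only the chosen class row
classLogit <- function(model, X, head, ci) {
  out <- modelForwardHead(model, as3d(X), head, train = FALSE)
  out[ci, ]
}

# gradient of the summed class logit w.r.t. a batch of inputs
inputGradient <- function(model, X, head, ci) {
  X <- as3d(X)
  out <- modelForwardHead(model, X, head, train = FALSE)
  dOut <- matrix(0, nrow(out), ncol(out))
  dOut[ci, ] <- 1
  modelBackwardHead(model, dOut, head)
}

#' In silico mutagenesis map of one region
#'
#' Evaluates the change in the chosen class's pre-softmax logit for all
#' single-base substitutions, in batched forward passes.  Entries at the
#' reference base and at padded (all-zero) columns are exactly 0.
#'
#' @param model a [CNNModel-class].
#' @param x one-hot matrix `(4, L)` of the region.
#' @param class class label to attribute.
#' @param head classification head name.
#' @param batchSize substitutions evaluated per forward pass.
#' @return a [MutationMap-class] with an L x 4 `effects` matrix.
#' @export
mutationMap <- function(model, x, class, head = "class", batchSize = 256L) {
  ci <- classIndex(model, head, class)
  L <- ncol(x)
  refOut <- classLogit(model, x, head, ci)
  refBase <- apply(x, 2L, which.max)
  present <- colSums(x) > 0
  subs <- NULL   # (position, base) pairs to evaluate
  for (b in 1:4) {
    pos <- which(present & refBase != b)
    if (length(pos)) subs <- rbind(subs, cbind(pos, b))
  }
  effects <- matrix(0, L, 4L, dimnames = list(NULL, BASE_ORDER))
  i <- 1L
  while (i <= nrow(subs)) {
    j <- min(nrow(subs), i + batchSize - 1L)
    n <- j - i + 1L
    Xb <- array(x, c(4L, L, n))
    for (k in seq_len(n)) {
      p <- subs[i + k - 1L, 1L]
      Xb[, p, k] <- 0
      Xb[subs[i + k - 1L, 2L], p, k] <- 1
    }
    out <- classLogit(model, Xb, head, ci)
    effects[subs[i:j, , drop = FALSE]] <- out - refOut
    i <- j + 1L
  }
  new("MutationMap", effects = effects, referenceOutput = refOut,
      classLabel = class)
}

#' Per-nucleotide importance from a mutation map
#'
#' `score(i) = -sum_b effects(i, b)`: positive scores mean mutating the
#' position lowers the class logit, i.e. the reference base supports the
#' class.
#'
#' @param map a [MutationMap-class].
#' @param regionId optional identifier stored in the track metadata.
#' @return an [AttributionTrack-class].
#' @export
importanceFromMap <- function(map, regionId = NULL) {
  new("AttributionTrack", scores = -rowSums(map@effects),
      classLabel = map@classLabel, method = "mutagenesis",
      metadata = list(region = regionId))
}

zeroReference <- function(L) matrix(0, 4L, L)

#' Integrated gradients attribution
#'
#' For each reference x', averages the input gradient of the chosen
#' pre-softmax class logit along the straight path from x' to x
#' (right-endpoint rule, `s/steps` for `s = 1..steps`), multiplies by
#' `(x - x')`, sums the 4 base channels per position, and finally
#' averages the per-reference tracks.  Interpolation proceeds in
#' continuous input space: interior points are not one-hot.
#'
#' @param model a [CNNModel-class].
#' @param x one-hot matrix `(4, L)`.
#' @param class class label to attribute.
#' @param steps number of integration steps (>= 1).
#' @param references list of `(4, L)` reference matrices; `NULL` means a
#'   single all-zero reference.
#' @param head classification head name.
#' @param batchSize steps evaluated per forward/backward pass.
#' @return an [AttributionTrack-class].
#' @export
integratedGradients <- function(model, x, class, steps = 512L,
                                references = NULL, head = "class",
                                batchSize = 128L, regionId = NULL) {
  stopifnot(steps >= 1L)
  ci <- classIndex(model, head, class)
  L <- ncol(x)
  if (is.null(references)) references <- list(zeroReference(L))
  bad <- vapply(references, function(r) !all(dim(r) == c(4L, L)), logical(1))
  if (any(bad)) stop("reference length mismatch")
  tracks <- vapply(references, function(ref) {
    delta <- x - ref
    gsum <- matrix(0, 4L, L)
    s <- 1L
    while (s <= steps) {
      e <- min(steps, s + batchSize - 1L)
      alphas <- (s:e) / steps
      n <- length(alphas)
      Xb <- array(0, c(4L, L, n))
      for (k in seq_len(n)) Xb[, , k] <- ref + alphas[k] * delta
      g <- inputGradient(model, Xb, head, ci)
      gsum <- gsum + rowSums(g, dims = 2L)
      s <- e + 1L
    }
    colSums(delta * (gsum / steps))
  }, numeric(L))
  sc <- if (is.matrix(tracks)) rowMeans(tracks) else mean(tracks)
  new("AttributionTrack", scores = as.numeric(sc), classLabel = class,
      method = "integrated_gradients",
      metadata = list(steps = steps, region = regionId,
                      reference = if (length(references) == 1L &&
                                      all(references[[1L]] == 0))
                        "zeros" else sprintf("%d references",
                                             length(references))))
}

#' @param regionId optional identifier stored in the track metadata.
#' @rdname integratedGradients
#' @export
gradientTimesInput <- function(model, x, class, head = "class",
                               regionId = NULL) {
  ci <- classIndex(model, head, class)
  g <- inputGradient(model, x, head, ci)
  dim(g) <- dim(x)
  new("AttributionTrack", scores = colSums(x * g), classLabel = class,
      method = "gradient_x_input", metadata = list(region = regionId))
}

#' Summation-to-delta (completeness) deviation of integrated gradients
#'
#' Computes `|sum(track) - (f(x) - mean_ref f(x'))| / |f(x) - mean_ref
#' f(x')|` at a given step count.
#'
#' @inheritParams integratedGradients
#' @return relative deviation (scalar); `NA` with a warning when the
#'   denominator is degenerate.
#' @export
completenessCheck <- function(model, x, class, steps = 512L,
                              references = NULL, head = "class",
                              batchSize = 128L) {
  ci <- classIndex(model, head, class)
  L <- ncol(x)
  if (is.null(references)) references <- list(zeroReference(L))
  fx <- classLogit(model, x, head, ci)
  fref <- mean(vapply(references, function(r)
    classLogit(model, r, head, ci), numeric(1)))
  denom <- fx - fref
  if (abs(denom) < 1e-12) {
    warning("degenerate completeness denominator; region flagged")
    return(NA_real_)
  }
  tr <- integratedGradients(model, x, class, steps, references, head,
                            batchSize)
  abs(sum(tr@scores) - denom) / abs(denom)
}

#' Completeness report over a region sample and step schedule
#'
#' @param model a [CNNModel-class].
#' @param X array `(4, L, n)` of regions to check.
#' @param class class label.
#' @param steps step counts to profile.
#' @param references reference set (`NULL` = zeros).
#' @param head head name.
#' @return data frame with per-step mean and max relative deviation and
#'   the number of degenerate (excluded) regions.
#' @export
completenessReport <- function(model, X, class,
                               steps = c(16L, 64L, 128L, 256L, 512L),
                               references = NULL, head = "class") {
  n <- dim(X)[3L]
  out <- NULL
  for (st in steps) {
    dev <- vapply(seq_len(n), function(i)
      suppressWarnings(
        completenessCheck(model, X[, , i], class, st, references, head)),
      numeric(1))
    out <- rbind(out, data.frame(
      steps = st, meanDeviation = mean(dev, na.rm = TRUE),
      maxDeviation = max(dev, na.rm = TRUE), excluded = sum(is.na(dev))))
  }
  out
}

#' Strongest sliding-window feature of an attribution track
#'
#' Maximizes the attribution sum over all length-`W` windows (stride 1);
#' ties break to the leftmost start.
#'
#' @param track an [AttributionTrack-class] (or numeric vector).
#' @param W window width in nt (default 25).
#' @param regionId identifier used in the output (defaults to the track
#'   metadata).
#' @return `DataFrame` with one row: `region`, `start` (0-based,
#'   region-relative), `end`, `score`.
#' @export
strongestWindow <- function(track, W = 25L, regionId = NULL) {
  sc <- if (is(track, "AttributionTrack")) track@scores else track
  if (is.null(regionId) && is(track, "AttributionTrack"))
    regionId <- track@metadata$region
  L <- length(sc)
  if (L < W) stop("track shorter than the window")
  cs <- cumsum(c(0, sc))
  win <- cs[(W + 1L):(L + 1L)] - cs[seq_len(L - W + 1L)]
  i <- which.max(win)   # first maximum = leftmost tie-break
  S4Vectors::DataFrame(region = if (is.null(regionId)) NA_character_
                       else regionId,
                       start = i - 1L, end = i - 1L + W,
                       score = win[i])
}

#' Rank strongest-window features across a dataset
#'
#' One feature call per region (via [strongestWindow()]), sorted by
#' descending score with deterministic tie-break by region identifier.
#'
#' @param tracks named list of [AttributionTrack-class] (names = region
#'   identifiers).
#' @param W window width in nt.
#' @return `DataFrame` of ranked feature calls with a `rank` column.
#' @export
rankFeatures <- function(tracks, W = 25L) {
  calls <- do.call(rbind, lapply(names(tracks), function(id)
    strongestWindow(tracks[[id]], W, regionId = id)))
  ord <- order(-calls$score, calls$region)
  calls <- calls[ord, ]
  calls$rank <- seq_len(nrow(calls))
  calls
}

#' Map region-relative feature calls to genome coordinates
#'
#' @param calls `DataFrame` from [rankFeatures()].
#' @param regions named `GRanges` of the parent regions.
#' @return `GRanges` of the feature windows with the call scores.
#' @export
featureGenomicRanges <- function(calls, regions) {
  r <- regions[calls$region]
  gr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(r),
    IRanges::IRanges(GenomicRanges::start(r) + calls$start,
                     width = calls$end - calls$start))
  S4Vectors::mcols(gr)$region <- calls$region
  S4Vectors::mcols(gr)$score <- calls$score
  S4Vectors::mcols(gr)$rank <- calls$rank
  gr
}

#' Ensemble attribution over several models
#'
#' `mode = "ensemble"`: arithmetic mean of the per-model tracks.
#' `mode = "heldout"`: each region attributed only by the model that
#' held it out during training (`holdoutOf` gives that model's index).
#' `mode = "alldata"`: a single model attributes everything.
#'
#' @param models list of [CNNModel-class] sharing the input length.
#' @param x one-hot matrix `(4, L)`.
#' @param class class to attribute.
#' @param method `"mutagenesis"`, `"integrated_gradients"` or
#'   `"gradient_x_input"`.
#' @param mode attribution mode.
#' @param holdoutOf model index owning this region (heldout mode).
#' @param ... passed to the underlying attribution function.
#' @return an [AttributionTrack-class].
#' @export
ensembleAttribution <- function(models, x, class,
                                method = c("gradient_x_input",
                                           "integrated_gradients",
                                           "mutagenesis"),
                                mode = c("ensemble", "heldout", "alldata"),
                                holdoutOf = NULL, ...) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (length(models) == 0L) stop("no models supplied")
  Ls <- vapply(models, modelInputLength, integer(1))
  if (length(unique(Ls)) != 1L) stop("incompatible graphs: input lengths differ")
  one <- function(m) attributeOne(m, x, class, method, ...)
  tr <- switch(mode,
    ensemble = {
      ts <- lapply(models, one)
      Reduce(`+`, lapply(ts, function(t) t@scores)) / length(ts)
    },
    heldout = {
      if (is.null(holdoutOf)) stop("holdoutOf required for heldout mode")
      one(models[[holdoutOf]])@scores
    },
    alldata = one(models[[1L]])@scores)
  new("AttributionTrack", scores = tr, classLabel = class, method = method,
      metadata = list(mode = mode, nModels = length(models)))
}

attributeOne <- function(model, x, class, method, ...) {
  switch(method,
    mutagenesis = importanceFromMap(mutationMap(model, x, class, ...)),
    integrated_gradients = integratedGradients(model, x, class, ...),
    gradient_x_input = gradientTimesInput(model, x, class, ...))
}

#' Export an attribution track as bedGraph
#'
#' Writes per-nucleotide attribution scores as a bedGraph interval track,
#' either region-relative (positions 0..L-1 on the region identifier) or
#' in genome coordinates when the parent region is supplied.
#'
#' @param track an [AttributionTrack-class].
#' @param file output path.
#' @param region optional `GRanges` of length 1 locating the region; when
#'   given, scores are written at genome coordinates on its contig.
#' @return invisibly, the path.
#' @export
exportTrackBedGraph <- function(track, file, region = NULL) {
  sc <- track@scores
  L <- length(sc)
  if (is.null(region)) {
    chrom <- if (!is.null(track@metadata$region)) track@metadata$region
             else "region"
    start0 <- 0L
  } else {
    stopifnot(length(region) == 1L)
    chrom <- as.character(GenomicRanges::seqnames(region))
    start0 <- GenomicRanges::start(region) - 1L
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + seq_len(L),
                                                width = 1L),
                               score = sc)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Export ranked feature calls as BED
#'
#' @param calls ranked calls from [rankFeatures()].
#' @param regions named `GRanges` of the parent regions.
#' @param file output path.
#' @return invisibly, the path.
#' @export
exportFeatureBed <- function(calls, regions, file) {
  gr <- featureGenomicRanges(calls, regions)
  names(gr) <- sprintf("%s_rank%d", S4Vectors::mcols(gr)$region,
                       S4Vectors::mcols(gr)$rank)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
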