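# Synthetic multi-tissue differential-binding data with known ground truth.
#
# Every region carries one anchor-TF motif instance; differential classes
# additionally carry a co-factor motif whose tissue-specific activity
# drives the RPKM differences, the labels, and the validation read
# profiles.  The generator is the test bed for the whole pipeline: the
# planted co-factor sites are the ground truth that attribution is later
# asked to rediscover.

#' Construct a MotifModel
#'
#' @param name motif identifier.
#' @param pwm 4 x W matrix of per-position base probabilities (rows
#'   A,C,G,T; columns sum to 1; 6 <= W <= 12).
#' @return a [MotifModel-class]; the consensus is the per-column argmax.
#' @export
motifModel <- function(name, pwm) {
  rownames(pwm) <- BASE_ORDER
  cons <- paste(BASE_ORDER[apply(pwm, 2L, which.max)], collapse = "")
  new("MotifModel", name = name, pwm = pwm, consensus = cons)
}

#' MotifModel from a consensus string
#'
#' Builds a PWM placing probability `concentration` on the consensus base
#' at each position and the remainder uniformly on the alternatives.
#'
#' @param name motif identifier.
#' @param consensus DNA string over A,C,G,T, length 6-12.
#' @param concentration probability of the consensus base per position.
#' @export
motifFromConsensus <- function(name, consensus, concentration = 0.95) {
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  stopifnot(all(ch %in% BASE_ORDER))
  pwm <- matrix((1 - concentration) / 3, 4L, length(ch))
  pwm[cbind(match(ch, BASE_ORDER), seq_along(ch))] <- concentration
  motifModel(name, pwm)
}

#' Sample a motif instance from its PWM
#'
#' @param motif a [MotifModel-class].
#' @return character string of the motif width drawn column-wise.
#' @export
sampleMotif <- function(motif) {
  p <- motif@pwm
  paste(vapply(seq_len(ncol(p)),
               function(j) sample(BASE_ORDER, 1L, prob = p[, j]),
               character(1)), collapse = "")
}

activityKey <- function(tissues) paste(sort(tissues), collapse = ",")

defaultCofactorMotifs <- function(tissueNames) {
  consensi <- c("ATCAATC", "AGATAAG", "TGACTCA",
                "CACGTGT", "TTCCGGT", "CCGGAAG")
  out <- list()
  ci <- 1L
  for (t in tissueNames) {          # co-factor absent in t: drives down_t
    key <- activityKey(setdiff(tissueNames, t))
    out[[key]] <- motifFromConsensus(paste0("cof_down_", t),
                                     consensi[(ci - 1L) %% 6L + 1L])
    ci <- ci + 1L
  }
  for (t in tissueNames) {          # co-factor exclusive to t: drives up_t
    out[[activityKey(t)]] <- motifFromConsensus(paste0("cof_up_", t),
                                                consensi[(ci - 1L) %% 6L + 1L])
    ci <- ci + 1L
  }
  out
}

#' Configure the synthetic differential-binding simulator
#'
#' Defaults mirror the structure of a three-tissue differential ChIP-seq
#' study with 2, 2 and 4 replicates: regions of 200-2000 nt, one anchor
#' motif everywhere, a tissue-pattern-specific co-factor motif in each
#' differential class whose presence multiplies the RPKM of the tissues
#' it is active in, log-normal replicate noise, labels from a
#' fold-change threshold rule, and validation reads concentrated at the
#' planted co-factor sites.
#'
#' @param nRegionsPerClass regions per class (2 x tissues + 1 classes).
#' @param regionLengthRange inclusive nt bounds, within \[200, 2000\].
#' @param tissueNames tissue identifiers.
#' @param replicatesPerTissue integer vector, one count per tissue.
#' @param anchorMotif [MotifModel-class] planted once in every region.
#' @param cofactorMotifs named list of [MotifModel-class]; names are
#'   comma-joined sorted tissue subsets in which that co-factor is
#'   active.
#' @param cofactorEffect multiplicative RPKM boost (> 1) in active
#'   tissues of regions carrying the co-factor site.
#' @param rpkmNoiseSd log-normal sigma of per-replicate noise.
#' @param labelFoldThreshold fold change against the other tissues'
#'   means required for a differential label.
#' @param readDepth validation reads per replicate.
#' @param readPositionalSd sd (nt) of read positions around site centres.
#' @param backgroundReadFraction fraction of reads placed uniformly on
#'   the genome instead of at sites.
#' @param spacerLength random spacer between regions on the synthetic
#'   contig.
#' @param baseRpkm median baseline occupancy.
#' @param seed integer governing all randomness of the generator.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nRegionsPerClass = 100L,
                             regionLengthRange = c(200L, 2000L),
                             tissueNames = c("tissueA", "tissueB", "tissueC"),
                             replicatesPerTissue = c(2L, 2L, 4L),
                             anchorMotif = motifFromConsensus("anchor", "CTGTCAG"),
                             cofactorMotifs = defaultCofactorMotifs(tissueNames),
                             cofactorEffect = 4,
                             rpkmNoiseSd = 0.3,
                             labelFoldThreshold = 2,
                             readDepth = 20000L,
                             readPositionalSd = 50,
                             backgroundReadFraction = 0.3,
                             spacerLength = 1000L,
                             baseRpkm = 10,
                             seed = 1L) {
  new("SimulationConfig",
      nRegionsPerClass = as.integer(nRegionsPerClass),
      regionLengthRange = as.integer(regionLengthRange),
      tissueNames = tissueNames,
      replicatesPerTissue = as.integer(replicatesPerTissue),
      anchorMotif = anchorMotif,
      cofactorMotifs = cofactorMotifs,
      cofactorEffect = cofactorEffect,
      rpkmNoiseSd = rpkmNoiseSd,
      labelFoldThreshold = labelFoldThreshold,
      readDepth = as.integer(readDepth),
      readPositionalSd = readPositionalSd,
      backgroundReadFraction = backgroundReadFraction,
      spacerLength = as.integer(spacerLength),
      baseRpkm = baseRpkm,
      seed = as.integer(seed))
}

classNames <- function(tissueNames)
  c(paste0("up_", tissueNames), paste0("down_", tissueNames),
    "non_differential")

cofactorForClass <- function(config, cls) {
  tn <- config@tissueNames
  if (cls == "non_differential") return(NULL)
  t <- sub("^(up|down)_", "", cls)
  key <- if (startsWith(cls, "up_")) activityKey(t)
         else activityKey(setdiff(tn, t))
  m <- config@cofactorMotifs[[key]]
  if (is.null(m))
    stop("no co-factor motif configured for tissue pattern ", key)
  list(motif = m, active = strsplit(key, ",", fixed = TRUE)[[1L]])
}

randomSeq <- function(n) paste(sample(BASE_ORDER, n, replace = TRUE),
                               collapse = "")

plantAt <- function(seq, instance, offset0) {
  # offset0 is 0-based
  paste0(substr(seq, 1L, offset0),
         instance,
         substr(seq, offset0 + nchar(instance) + 1L, nchar(seq)))
}

#' Generate a synthetic labelled differential-binding dataset
#'
#' Draws background sequences i.i.d. uniform over A,C,G,T, plants one
#' anchor motif instance at a uniform-random position in every region and
#' a co-factor motif instance (non-overlapping the anchor) in regions
#' designed for a differential class, lays all regions on a single
#' synthetic contig separated by random spacers, simulates per-replicate
#' RPKM as baseline x co-factor boost x log-normal noise, assigns labels
#' by comparing each tissue's mean RPKM against the other tissues with
#' the fold threshold (a simplified stand-in for an edgeR-style
#' analysis), and draws two replicates of validation reads: Normal(site
#' centre, readPositionalSd) positions at every planted co-factor site
#' plus a uniform background component.  Fully reproducible from
#' `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SyntheticDataset-class].
#' @export
generateDataset <- function(config) {
  validObject(config)
  set.seed(config@seed)
  tn <- config@tissueNames
  classes <- classNames(tn)
  n <- config@nRegionsPerClass
  design <- factor(rep(classes, each = n), levels = classes)
  nreg <- length(design)
  ids <- sprintf("region_%04d", seq_len(nreg))
  WA <- ncol(config@anchorMotif@pwm)

  seqs <- character(nreg)
  rl <- config@regionLengthRange
  lens <- rl[1L] + sample.int(rl[2L] - rl[1L] + 1L, nreg,
                              replace = TRUE) - 1L
  siteRegion <- character(0)
  siteOffset <- integer(0)   # 0-based region-relative
  siteWidth <- integer(0)
  siteMotif <- character(0)
  hasCof <- logical(nreg)
  activeOf <- vector("list", nreg)

  for (i in seq_len(nreg)) {
    s <- randomSeq(lens[i])
    offA <- sample.int(lens[i] - WA + 1L, 1L) - 1L
    s <- plantAt(s, sampleMotif(config@anchorMotif), offA)
    cof <- cofactorForClass(config, as.character(design[i]))
    if (!is.null(cof)) {
      WC <- ncol(cof$motif@pwm)
      cand <- 0:(lens[i] - WC)
      ok <- cand + WC <= offA | cand >= offA + WA   # avoid the anchor
      cand <- cand[ok]
      if (length(cand) == 0L) stop("region too short to hold both motifs")
      offC <- cand[sample.int(length(cand), 1L)]
      s <- plantAt(s, sampleMotif(cof$motif), offC)
      siteRegion <- c(siteRegion, ids[i])
      siteOffset <- c(siteOffset, offC)
      siteWidth <- c(siteWidth, WC)
      siteMotif <- c(siteMotif, cof$motif@name)
      hasCof[i] <- TRUE
      activeOf[[i]] <- cof$active
    }
    seqs[i] <- s
  }

  # genome: spacer + region + spacer + ... + spacer, one contig
  sp <- config@spacerLength
  spacers <- vapply(seq_len(nreg + 1L), function(i) randomSeq(sp),
                    character(1))
  starts0 <- sp + cumsum(c(0L, lens[-nreg] + sp))   # 0-based region starts
  genomeSeq <- paste0(paste0(spacers[seq_len(nreg)], seqs, collapse = ""),
                      spacers[nreg + 1L])
  genome <- Biostrings::DNAStringSet(genomeSeq)
  names(genome) <- "synth1"

  regions <- GenomicRanges::GRanges("synth1",
                                    IRanges::IRanges(starts0 + 1L,
                                                     width = lens))
  names(regions) <- ids
  S4Vectors::mcols(regions)$intended <- as.character(design)

  sidx <- match(siteRegion, ids)
  trueSites <- GenomicRanges::GRanges(
    "synth1",
    IRanges::IRanges(starts0[sidx] + siteOffset + 1L, width = siteWidth))
  S4Vectors::mcols(trueSites)$region <- siteRegion
  S4Vectors::mcols(trueSites)$motif <- siteMotif

  # RPKM: baseline x co-factor boost (in active tissues) x log-normal noise
  reps <- config@replicatesPerTissue
  repTissue <- rep(tn, reps)
  repNames <- unlist(lapply(seq_along(tn), function(k)
    paste0(tn[k], "_rep", seq_len(reps[k]))))
  base <- stats::rlnorm(nreg, log(config@baseRpkm), 0.5)
  rpkm <- matrix(0, nreg, length(repTissue),
                 dimnames = list(ids, repNames))
  for (j in seq_along(repTissue)) {
    boost <- ifelse(hasCof & vapply(activeOf, function(a)
      repTissue[j] %in% a, logical(1)), config@cofactorEffect, 1)
    rpkm[, j] <- base * boost * stats::rlnorm(nreg, 0, config@rpkmNoiseSd)
  }

  labels <- assignLabels(rpkm, repTissue, tn, config@labelFoldThreshold)

  glen <- nchar(genomeSeq)
  centres0 <- starts0[sidx] + siteOffset + siteWidth / 2
  validationReads <- lapply(1:2, function(r)
    drawReads(centres0, glen, config))

  new("SyntheticDataset", genome = genome, regions = regions,
      trueSites = trueSites, rpkm = rpkm, labels = labels,
      validationReads = validationReads, config = config)
}

# fold-change threshold rule emulating the label semantics of an
# edgeR-style differential analysis
assignLabels <- function(rpkm, repTissue, tissueNames, thr) {
  means <- sapply(tissueNames, function(t)
    rowMeans(rpkm[, repTissue == t, drop = FALSE]))
  classes <- classNames(tissueNames)
  lab <- rep("non_differential", nrow(rpkm))
  score <- rep(0, nrow(rpkm))
  for (k in seq_along(tissueNames)) {
    others <- means[, -k, drop = FALSE]
    up <- means[, k] >= thr * apply(others, 1L, max)
    dn <- thr * means[, k] <= apply(others, 1L, min)
    fold <- abs(log(means[, k] / exp(rowMeans(log(others)))))
    take <- up & fold > score
    lab[take] <- paste0("up_", tissueNames[k])
    score[take] <- fold[take]
    take <- dn & fold > score
    lab[take] <- paste0("down_", tissueNames[k])
    score[take] <- fold[take]
  }
  factor(lab, levels = classes)
}

drawReads <- function(centres0, genomeLength, config) {
  depth <- config@readDepth
  nSites <- length(centres0)
  nSite <- round((1 - config@backgroundReadFraction) * depth)
  pos0 <- integer(0)
  if (nSites > 0L && nSite > 0L) {
    cnt <- stats::rmultinom(1L, nSite, rep(1, nSites))[, 1L]
    pos0 <- round(stats::rnorm(nSite, rep(centres0, cnt),
                               config@readPositionalSd))
  }
  bg <- sample.int(genomeLength, depth - length(pos0), replace = TRUE) - 1L
  pos0 <- pmin(pmax(c(pos0, bg), 0), genomeLength - 1L)
  GenomicRanges::GRanges("synth1", IRanges::IRanges(pos0 + 1L, width = 1L))
}

#' Write a synthetic dataset to standard genomic formats
#'
#' Emits the genome FASTA, region and true-site BED files (0-based
#' half-open), RPKM and label TSV tables, two BED files of validation
#' read positions, and the scalar generator settings as a DCF key-value
#' file.
#'
#' @param ds a [SyntheticDataset-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
writeDataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             regions = file.path(dir, "regions.bed"),
             sites = file.path(dir, "true_sites.bed"),
             rpkm = file.path(dir, "rpkm.tsv"),
             labels = file.path(dir, "labels.tsv"),
             reads1 = file.path(dir, "reads_rep1.bed"),
             reads2 = file.path(dir, "reads_rep2.bed"),
             config = file.path(dir, "config.dcf"))
  Biostrings::writeXStringSet(ds@genome, paths["genome"])
  reg <- ds@regions
  S4Vectors::mcols(reg)$score <- 0
  rtracklayer::export(reg, paths["regions"], format = "BED")
  st <- ds@trueSites
  names(st) <- S4Vectors::mcols(st)$region
  S4Vectors::mcols(st)$score <- 0
  rtracklayer::export(st, paths["sites"], format = "BED")
  utils::write.table(data.frame(region = rownames(ds@rpkm), ds@rpkm,
                                check.names = FALSE),
                     paths["rpkm"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(region = names(ds@regions),
                                label = as.character(ds@labels),
                                intended = S4Vectors::mcols(ds@regions)$intended),
                     paths["labels"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (r in 1:2) {
    rd <- ds@validationReads[[r]]
    names(rd) <- sprintf("read_%06d", seq_along(rd))
    S4Vectors::mcols(rd)$score <- 0
    rtracklayer::export(rd, paths[paste0("reads", r)], format = "BED")
  }
  cfg <- ds@config
  dcf <- data.frame(nRegionsPerClass = cfg@nRegionsPerClass,
                    regionLengthMin = cfg@regionLengthRange[1L],
                    regionLengthMax = cfg@regionLengthRange[2L],
                    tissues = paste(cfg@tissueNames, collapse = ","),
                    replicatesPerTissue = paste(cfg@replicatesPerTissue,
                                                collapse = ","),
                    cofactorEffect = cfg@cofactorEffect,
                    rpkmNoiseSd = cfg@rpkmNoiseSd,
                    labelFoldThreshold = cfg@labelFoldThreshold,
                    readDepth = cfg@readDepth,
                    readPositionalSd = cfg@readPositionalSd,
                    seed = cfg@seed)
  write.dcf(dcf, paths["config"])
  invisible(paths)
}

#' Extract region sequences of a synthetic dataset
#'
#' @param ds a [SyntheticDataset-class].
#' @return named `DNAStringSet` of region sequences (plus strand).
#' @export
regionSequences <- function(ds) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(ds@regions), function(i)
    as.character(Biostrings::subseq(ds@genome[[1L]],
                                    GenomicRanges::start(ds@regions)[i],
                                    GenomicRanges::end(ds@regions)[i])),
    character(1)))
  names(seqs) <- names(ds@regions)
  seqs
}
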