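#' Two-class Gaussian feature clusters
#'
#' Generates a labeled feature matrix of two isotropic unit-variance
#' Gaussian clusters whose means are \code{classSeparation} within-class
#' standard deviations apart along a random unit direction — a fast
#' stand-in for extracted image features when exercising the classifier
#' alone.
#'
#' @param nSamples total sample count (>= 4).
#' @param nFeatures feature dimension.
#' @param classSeparation distance between the class means in units of
#'   the within-class standard deviation (0 = indistinguishable classes).
#' @param classBalance fraction of samples in the positive class, in
#'   (0, 1).
#' @param seed integer seed; the output is bit-reproducible.
#' @return A list with \code{inputs} (n x d matrix), \code{labels}
#'   (0/1 integer vector), and \code{direction} (the unit separation
#'   axis, useful for oracle classifiers in tests).
#' @examples
#' ds <- generateFeatureDataset(100, 5, classSeparation = 4, seed = 1)
#' table(ds$labels)
#' @export
generateFeatureDataset <- function(nSamples = 200, nFeatures = 5,
                                   classSeparation = 3, classBalance = 0.5,
                                   seed = 1L) {
  if (nSamples < 4L) stop("nSamples must be at least 4")
  if (nFeatures < 1L) stop("nFeatures must be at least 1")
  if (classSeparation < 0) stop("classSeparation must be nonnegative")
  if (classBalance <= 0 || classBalance >= 1)
    stop("classBalance must lie strictly inside (0, 1)")
  set.seed(seed)
  nPos <- max(1L, min(nSamples - 1L, round(nSamples * classBalance)))
  labels <- c(rep(0L, nSamples - nPos), rep(1L, nPos))
  u <- stats::rnorm(nFeatures)
  u <- u / sqrt(sum(u^2))
  shift <- classSeparation / 2
  x <- matrix(stats::rnorm(nSamples * nFeatures), nSamples, nFeatures)
  x <- x + outer(ifelse(labels == 1L, shift, -shift), u)
  list(inputs = x, labels = labels, direction = u)
}

# pixel-center coordinate grids for a square image
.pixelGrid <- function(size) {
  g <- seq_len(size) - 0.5
  list(x = matrix(g, size, size), y = matrix(g, size, size, byrow = TRUE))
}

#' Synthetic two-class toy brain images
#'
#' Writes PNG images emulating a two-class tumor/no-tumor task: every
#' image is a dark background with a mid-gray head ellipse plus Gaussian
#' pixel noise; the positive class additionally contains one bright
#' ellipsoidal blob placed uniformly within the inner 60% of the head so
#' that later resizing never clips it. A CSV manifest (columns
#' \code{filepath}, \code{label}) and a YAML sidecar recording the
#' generator settings are written next to the images.
#'
#' @param dir output directory (created if needed).
#' @param nImages number of images.
#' @param imageSize image side length in pixels (default 227).
#' @param tumorFraction fraction of positive (blob-bearing) images, in
#'   (0, 1).
#' @param blobRadiusRange 2-vector of minimum and maximum blob semi-axis
#'   lengths in pixels.
#' @param blobIntensityLift additive intensity of the blob above the head
#'   gray level.
#' @param noiseSd standard deviation of the additive Gaussian pixel
#'   noise (0 gives noiseless images).
#' @param seed integer seed; images and manifest are bit-reproducible.
#' @return Invisibly, a list with \code{manifest} (data.frame) and
#'   \code{details} (per-image blob geometry: center, semi-axes; NA for
#'   negatives), for downstream analytic checks.
#' @export
generateSyntheticImages <- function(dir, nImages = 200, imageSize = 227L,
                                    tumorFraction = 0.5,
                                    blobRadiusRange = c(12, 30),
                                    blobIntensityLift = 0.35,
                                    noiseSd = 0.05, seed = 1L) {
  if (tumorFraction <= 0 || tumorFraction >= 1)
    stop("tumorFraction must lie strictly inside (0, 1)")
  if (length(blobRadiusRange) != 2L || any(blobRadiusRange <= 0) ||
      blobRadiusRange[1] > blobRadiusRange[2])
    stop("blobRadiusRange must be an increasing pair of positive lengths")
  if (blobRadiusRange[2] > 0.3 * imageSize)
    stop("blob radii must fit inside the head ellipse")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  set.seed(seed)
  s <- as.integer(imageSize)
  nPos <- max(1L, min(nImages - 1L, round(nImages * tumorFraction)))
  labels <- rep(c(0L, 1L), c(nImages - nPos, nPos))
  labels <- labels[sample.int(nImages)]  # shuffle file order
  grid <- .pixelGrid(s)
  cx <- s / 2; cy <- s / 2
  headA <- 0.38 * s; headB <- 0.46 * s  # head ellipse semi-axes
  headMask <- ((grid$x - cx) / headA)^2 + ((grid$y - cy) / headB)^2 <= 1
  background <- 0.05; headGray <- 0.45
  details <- data.frame(filepath = character(nImages), label = labels,
                        blobX = NA_real_, blobY = NA_real_,
                        blobRx = NA_real_, blobRy = NA_real_)
  for (i in seq_len(nImages)) {
    img <- matrix(background, s, s)
    img[headMask] <- headGray
    if (labels[i] == 1L) {
      rx <- stats::runif(1, blobRadiusRange[1], blobRadiusRange[2])
      ry <- stats::runif(1, blobRadiusRange[1], blobRadiusRange[2])
      # uniform placement within the inner 60% of the head ellipse
      repeat {
        px <- cx + stats::runif(1, -0.6, 0.6) * headA
        py <- cy + stats::runif(1, -0.6, 0.6) * headB
        if (((px - cx) / (0.6 * headA))^2 +
            ((py - cy) / (0.6 * headB))^2 <= 1) break
      }
      blobMask <- ((grid$x - px) / rx)^2 + ((grid$y - py) / ry)^2 <= 1
      img[blobMask] <- img[blobMask] + blobIntensityLift
      details$blobX[i] <- px; details$blobY[i] <- py
      details$blobRx[i] <- rx; details$blobRy[i] <- ry
    }
    if (noiseSd > 0)
      img <- img + matrix(stats::rnorm(s * s, sd = noiseSd), s, s)
    img <- pmin(pmax(img, 0), 1)
    fname <- sprintf("img_%04d.png", i)
    EBImage::writeImage(EBImage::Image(img, colormode = "Grayscale"),
                        file.path(dir, fname))
    details$filepath[i] <- fname
  }
  manifest <- details[, c("filepath", "label")]
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(nImages = nImages, imageSize = s,
                        tumorFraction = tumorFraction,
                        blobRadiusRange = as.numeric(blobRadiusRange),
                        blobIntensityLift = blobIntensityLift,
                        noiseSd = noiseSd, seed = as.integer(seed)),
                   file.path(dir, "spec.yaml"))
  invisible(list(manifest = manifest, details = details))
}

#' Stratified train/test split of a labeled manifest
#'
#' Randomly splits the rows of a labeled table into train and test sets,
#' stratified by label so that each class contributes its proportional
#' share to both sides; the default 0.8 matches the ~80/20 protocol of
#' the motivating study. The two parts are disjoint and exhaustive.
#'
#' @param manifest data.frame with a \code{label} column (e.g. an image
#'   manifest or feature table).
#' @param trainFraction fraction of each class assigned to training, in
#'   (0, 1).
#' @param seed integer seed.
#' @return A list with \code{train} and \code{test} data.frames.
#' @examples
#' m <- data.frame(filepath = sprintf("i%d.png", 1:10),
#'                 label = rep(0:1, 5))
#' sp <- splitManifest(m, 0.8, seed = 1)
#' nrow(sp$train); nrow(sp$test)
#' @export
splitManifest <- function(manifest, trainFraction = 0.8, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly inside (0, 1)")
  if (!("label" %in% names(manifest)))
    stop("manifest needs a 'label' column")
  set.seed(seed)
  trainIdx <- integer(0)
  for (lv in sort(unique(manifest$label))) {
    idx <- which(manifest$label == lv)
    if (length(idx) < 2L)
      stop("class '", lv, "' has fewer than 2 members; cannot split")
    nTrain <- round(trainFraction * length(idx))
    nTrain <- max(1L, min(length(idx) - 1L, nTrain))
    trainIdx <- c(trainIdx, sample(idx, nTrain))
  }
  trainIdx <- sort(trainIdx)
  list(train = manifest[trainIdx, , drop = FALSE],
       test = manifest[setdiff(seq_len(nrow(manifest)), trainIdx), ,
                       drop = FALSE])
}
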