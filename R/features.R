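#' Mini-batch mean and variance
#'
#' The per-batch statistics used by the batch-normalization transform:
#' \eqn{\bar z = \frac{1}{N}\sum_i z_i} and the biased variance
#' \eqn{S^2 = \frac{1}{N}\sum_i (z_i - \bar z)^2} (divisor N, not N-1).
#'
#' @param values numeric vector (or array, treated elementwise) of
#'   mini-batch activations; must be non-empty.
#' @return A list with \code{mean} and \code{variance}.
#' @examples
#' batchStatistics(c(1, 2, 3))  # mean 2, variance 2/3
#' @export
batchStatistics <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) stop("values must be non-empty")
  m <- sum(values) / n
  list(mean = m, variance = sum((values - m)^2) / n)
}

#' Batch-normalization transform
#'
#' Standardizes the values by their own batch statistics,
#' \eqn{\hat z_i = (z_i - \bar z) / \sqrt{S^2 + \epsilon}}, then applies
#' the affine map \eqn{y_i = a + b\,\hat z_i} with shift \code{a} and
#' scale \code{b}. \code{epsilon} guards the constant-input case (all
#' outputs then equal \code{a}).
#'
#' @param values numeric vector or array of activations.
#' @param shift affine shift a (default 0).
#' @param scale affine scale b (default 1).
#' @param epsilon small positive stabilizer (default 1e-8).
#' @return Normalized values with the shape of the input.
#' @examples
#' y <- batchNormalize(rnorm(1000))
#' c(mean(y), var(y))  # ~0 and ~1
#' @export
batchNormalize <- function(values, shift = 0, scale = 1, epsilon = 1e-8) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (length(values) < 1L) stop("values must be non-empty")
  st <- batchStatistics(values)
  out <- shift + scale * (values - st$mean) / sqrt(st$variance + epsilon)
  out
}

#' Load and standardize an image for the feature stack
#'
#' Reads a PNG/JPEG (or accepts an in-memory matrix/array), resizes to
#' \code{size} x \code{size} with bilinear interpolation, replicates
#' grayscale to 3 channels, and clamps intensities to [0, 1] — the input
#' contract of the 227 x 227 x 3 feature extractor.
#'
#' @param image a file path, a 2-D matrix (grayscale), or an H x W x C
#'   array with values in [0, 1].
#' @param size output side length (default 227).
#' @return A \code{size} x \code{size} x 3 numeric array in [0, 1].
#' @export
preprocessImage <- function(image, size = 227L) {
  if (is.character(image)) {
    if (!file.exists(image))
      stop("cannot read image file: ", image)
    img <- EBImage::readImage(image)
    arr <- as.array(img)
  } else {
    arr <- as.array(image)
  }
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("image must be 2-D grayscale or H x W x C")
  if (dim(arr)[1] != size || dim(arr)[2] != size) {
    arr <- as.array(EBImage::resize(EBImage::Image(arr, colormode = "Grayscale"),
                                    w = size, h = size))
    if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  }
  nc <- dim(arr)[3]
  out <- if (nc == 1L) array(arr[, , 1L], c(size, size, 3L))
         else if (nc >= 3L) arr[, , 1:3, drop = FALSE]
         else array(arr[, , 1L], c(size, size, 3L))
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- c(size, size, 3L)
  out
}

convOutputSide <- function(side, kernel, stride, pad) {
  num <- side - kernel + 2L * pad
  if (num %% stride != 0L)
    stop(sprintf("layer geometry is inconsistent: (%d - %d + 2*%d) is not divisible by stride %d",
                 side, kernel, pad, stride))
  num %/% stride + 1L
}

#' The AlexNet-shaped convolutional feature stack
#'
#' Builds the fixed five-convolution feature extractor:
#' conv 96@11x11 stride 4 (+BN+ReLU), 3x3/2 max-pool,
#' conv 256@5x5 pad 2 (+BN+ReLU), pool, conv 384@3x3 pad 1 (+BN+ReLU),
#' conv 384@3x3 pad 1 (+BN+ReLU), conv 256@3x3 pad 1 (+BN+ReLU), pool,
#' flatten. For a 227 x 227 x 3 input the shape chain is
#' 55x55x96 -> 27x27x96 -> 27x27x256 -> 13x13x256 -> 13x13x384 ->
#' 13x13x384 -> 13x13x256 -> 6x6x256, flattening to 9216 features. The
#' whole chain is shape-checked at construction; an inconsistent geometry
#' errors here, never at extraction time.
#'
#' @param inputSize input side length (default 227).
#' @return A \linkS4class{ConvStack}.
#' @examples
#' stack <- convStackConfig()
#' stack  # prints the shape chain ending in 9216
#' @export
convStackConfig <- function(inputSize = 227L) {
  layers <- list(
    list(type = "conv", filters = 96L,  kernel = 11L, stride = 4L, pad = 0L),
    list(type = "pool", kernel = 3L, stride = 2L),
    list(type = "conv", filters = 256L, kernel = 5L,  stride = 1L, pad = 2L),
    list(type = "pool", kernel = 3L, stride = 2L),
    list(type = "conv", filters = 384L, kernel = 3L,  stride = 1L, pad = 1L),
    list(type = "conv", filters = 384L, kernel = 3L,  stride = 1L, pad = 1L),
    list(type = "conv", filters = 256L, kernel = 3L,  stride = 1L, pad = 1L),
    list(type = "pool", kernel = 3L, stride = 2L))
  shape <- c(as.integer(inputSize), as.integer(inputSize), 3L)
  shapes <- list(shape)
  for (ly in layers) {
    side <- if (ly$type == "conv")
      convOutputSide(shape[1], ly$kernel, ly$stride, ly$pad)
    else
      convOutputSide(shape[1], ly$kernel, ly$stride, 0L)
    depth <- if (ly$type == "conv") ly$filters else shape[3]
    shape <- c(side, side, depth)
    shapes <- c(shapes, list(shape))
  }
  new("ConvStack", layers = layers, shapes = shapes,
      outputLength = as.integer(prod(shape)))
}

#' Seeded random filters for the feature stack
#'
#' Generates one filter matrix per convolution layer — each of shape
#' (kernel^2 * inChannels) x filters with unit-norm columns — from a
#' dedicated seeded generator, leaving the caller's RNG state untouched.
#' Unit-norm random filters make the stack a fixed random-projection
#' feature extractor; externally supplied filters of the same shapes can
#' be plugged in instead wherever a \code{weights} argument is accepted.
#'
#' @param stack a \linkS4class{ConvStack}.
#' @param seed integer seed for the filter draw.
#' @return A list of filter matrices, one per convolution layer.
#' @export
convStackWeights <- function(stack, seed = 1L) {
  stopifnot(is(stack, "ConvStack"))
  oldseed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(oldseed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldseed, envir = globalenv())
  })
  set.seed(seed)
  weights <- list()
  for (k in seq_along(stack@layers)) {
    ly <- stack@layers[[k]]
    if (ly$type != "conv") next
    inDepth <- stack@shapes[[k]][3]
    nr <- ly$kernel^2 * inDepth
    W <- matrix(stats::rnorm(nr * ly$filters), nr, ly$filters)
    W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
    weights[[length(weights) + 1L]] <- W
  }
  weights
}

# strided convolution via im2col + one matrix product; x is H x W x C,
# wmat is (k^2*C) x F with column blocks ordered (kj, ki) outer, channel inner
convForward <- function(x, wmat, kernel, stride, pad) {
  dm <- dim(x)
  if (pad > 0L) {
    padded <- array(0, dm + c(2L * pad, 2L * pad, 0L))
    padded[pad + seq_len(dm[1]), pad + seq_len(dm[2]), ] <- x
    x <- padded
    dm <- dim(x)
  }
  oh <- (dm[1] - kernel) %/% stride + 1L
  ow <- (dm[2] - kernel) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = oh)
  ci <- seq(1L, by = stride, length.out = ow)
  C <- dm[3]
  patches <- matrix(0, oh * ow, kernel * kernel * C)
  col <- 0L
  for (kj in seq_len(kernel)) {
    for (ki in seq_len(kernel)) {
      block <- x[ri + ki - 1L, ci + kj - 1L, , drop = FALSE]
      patches[, col + seq_len(C)] <- matrix(block, oh * ow, C)
      col <- col + C
    }
  }
  out <- patches %*% wmat
  array(out, c(oh, ow, ncol(wmat)))
}

maxPoolForward <- function(x, kernel, stride) {
  dm <- dim(x)
  oh <- (dm[1] - kernel) %/% stride + 1L
  ow <- (dm[2] - kernel) %/% stride + 1L
  ri <- seq(1L, by = stride, length.out = oh)
  ci <- seq(1L, by = stride, length.out = ow)
  out <- array(-Inf, c(oh, ow, dm[3]))
  for (kj in seq_len(kernel)) {
    for (ki in seq_len(kernel)) {
      slab <- x[ri + ki - 1L, ci + kj - 1L, , drop = FALSE]
      out <- pmax(out, slab)
    }
  }
  dim(out) <- c(oh, ow, dm[3])
  out
}

# per-channel batch normalization (a = 0, b = 1) followed by ReLU
bnRelu <- function(x, epsilon = 1e-8) {
  for (ch in seq_len(dim(x)[3])) {
    x[, , ch] <- batchNormalize(x[, , ch], epsilon = epsilon)
  }
  pmax(x, 0)
}

#' Extract the 9216-length convolutional feature vector
#'
#' Pushes one preprocessed image through the feature stack: each
#' convolution is followed by per-channel batch normalization and ReLU,
#' max-pooling layers downsample 3x3 at stride 2, and the final 6x6x256
#' tensor is flattened. With the same seed (or the same supplied filters)
#' the mapping is deterministic.
#'
#' @param image a 227 x 227 x 3 array (see \code{\link{preprocessImage}}),
#'   or anything that function accepts.
#' @param stack a \linkS4class{ConvStack} (default \code{convStackConfig()}).
#' @param weights filter list from \code{\link{convStackWeights}} (or
#'   externally supplied matrices of the same shapes); generated from
#'   \code{seed} when \code{NULL}.
#' @param seed filter seed used when \code{weights} is \code{NULL}.
#' @return Numeric feature vector of length \code{stack@outputLength}
#'   (9216 for the default stack).
#' @export
extractFeatures <- function(image, stack = convStackConfig(),
                            weights = NULL, seed = 1L) {
  stopifnot(is(stack, "ConvStack"))
  x <- preprocessImage(image, size = stack@shapes[[1]][1])
  if (is.null(weights)) weights <- convStackWeights(stack, seed = seed)
  wi <- 0L
  for (k in seq_along(stack@layers)) {
    ly <- stack@layers[[k]]
    if (ly$type == "conv") {
      wi <- wi + 1L
      W <- weights[[wi]]
      expected <- ly$kernel^2 * stack@shapes[[k]][3]
      if (nrow(W) != expected || ncol(W) != ly$filters)
        stop(sprintf("filter matrix %d has shape %dx%d, expected %dx%d",
                     wi, nrow(W), ncol(W), expected, ly$filters))
      x <- convForward(x, W, ly$kernel, ly$stride, ly$pad)
      x <- bnRelu(x)
    } else {
      x <- maxPoolForward(x, ly$kernel, ly$stride)
    }
    if (!identical(dim(x), stack@shapes[[k + 1L]]))
      stop("internal shape-chain violation at layer ", k)
  }
  as.numeric(x)
}

#' Feature matrix for a labeled image manifest
#'
#' Applies \code{\link{extractFeatures}} to every image listed in a
#' manifest (columns \code{filepath}, \code{label}) and returns the
#' feature matrix with its labels. Relative file paths are resolved
#' against \code{baseDir}.
#'
#' @param manifest data.frame with columns \code{filepath} and
#'   \code{label}, or the path of such a CSV.
#' @param baseDir directory against which relative paths resolve
#'   (defaults to the manifest's directory when a path is given, else
#'   \code{"."}).
#' @param stack,weights,seed passed to \code{\link{extractFeatures}};
#'   filters are generated once and shared across images.
#' @return A list with \code{features} (n x 9216 matrix) and \code{labels}.
#' @export
extractFeatureMatrix <- function(manifest, baseDir = NULL,
                                 stack = convStackConfig(), weights = NULL,
                                 seed = 1L) {
  if (is.character(manifest)) {
    if (is.null(baseDir)) baseDir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(baseDir)) baseDir <- "."
  if (!all(c("filepath", "label") %in% names(manifest)))
    stop("manifest needs 'filepath' and 'label' columns")
  if (is.null(weights)) weights <- convStackWeights(stack, seed = seed)
  paths <- ifelse(file.exists(manifest$filepath), manifest$filepath,
                  file.path(baseDir, manifest$filepath))
  feats <- matrix(0, nrow(manifest), stack@outputLength)
  for (i in seq_len(nrow(manifest))) {
    feats[i, ] <- extractFeatures(paths[i], stack = stack, weights = weights)
  }
  list(features = feats, labels = manifest$label)
}

#' Write a feature matrix as CSV
#'
#' One row per image, feature columns \code{f1..fD}, and a final
#' \code{label} column — the interchange format between the extractor and
#' the classifier.
#'
#' @param features n x D feature matrix.
#' @param labels length-n labels.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureCSV <- function(features, labels, path) {
  df <- as.data.frame(features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @return For \code{readFeatureCSV}: a list with \code{features} and
#'   \code{labels}.
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("label" %in% names(df))) stop("feature CSV must have a 'label' column")
  list(features = as.matrix(df[, setdiff(names(df), "label"), drop = FALSE]),
       labels = df$label)
}
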