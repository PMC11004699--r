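.elmActivations <- list(
  sigmoid = function(z) 1 / (1 + exp(-z)),
  tanh    = function(z) tanh(z),
  relu    = function(z) pmax(z, 0),
  linear  = function(z) z)

elmActivation <- function(name) {
  f <- .elmActivations[[name]]
  if (is.null(f))
    stop("unknown activation '", name, "'; use one of: ",
         paste(names(.elmActivations), collapse = ", "))
  f
}

#' Hidden-layer output matrix of an ELM
#'
#' Computes \eqn{H_{ij} = f(w_j \cdot x_i + b_j)} for every sample i and
#' hidden node j.
#'
#' @param inputs n x d matrix of samples in rows.
#' @param weights L_h x d matrix of hidden input weights (one node per row).
#' @param biases length-L_h bias vector.
#' @param activation activation name (default \code{"sigmoid"}).
#' @return The n x L_h hidden output matrix H.
#' @examples
#' elmHiddenMatrix(matrix(0, 1, 2), matrix(1, 3, 2), rep(0, 3))  # all 0.5
#' @export
elmHiddenMatrix <- function(inputs, weights, biases,
                            activation = "sigmoid") {
  inputs <- as.matrix(inputs)
  weights <- as.matrix(weights)
  if (ncol(inputs) != ncol(weights))
    stop("input width does not match the hidden weight width")
  if (length(biases) != nrow(weights))
    stop("bias length does not match the hidden node count")
  f <- elmActivation(activation)
  z <- tcrossprod(inputs, weights)
  z <- sweep(z, 2L, biases, "+")
  f(z)
}

#' Minimum-norm least-squares output weights
#'
#' Solves \eqn{H \beta = T} for the output weights as
#' \eqn{\beta = H^\dagger T}, the Moore-Penrose (minimum-norm
#' least-squares) solution, via a thin SVD with the usual
#' machine-precision rank cutoff. Rank-deficient H is handled; among all
#' least-squares solutions the returned one has the smallest Frobenius
#' norm.
#'
#' @param H n x L_h hidden output matrix.
#' @param targets n x k target matrix (one-hot class indicators, or any
#'   regression targets).
#' @return The L_h x k output weight matrix.
#' @export
solveOutputWeights <- function(H, targets) {
  H <- as.matrix(H)
  targets <- as.matrix(targets)
  if (nrow(H) != nrow(targets))
    stop("H and targets must have the same number of rows")
  if (any(!is.finite(H)) || any(!is.finite(targets)))
    stop("H and targets must be finite")
  sv <- svd(H)
  tol <- max(dim(H)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(H), ncol(targets)))
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], targets)) / sv$d[pos])
}

oneHot <- function(labels, levels = NULL) {
  f <- factor(labels, levels = levels %||% sort(unique(labels)))
  if (anyNA(f)) stop("labels outside the declared class levels")
  tmat <- matrix(0, length(f), nlevels(f),
                 dimnames = list(NULL, levels(f)))
  tmat[cbind(seq_along(f), as.integer(f))] <- 1
  tmat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an ELM with random hidden weights
#'
#' Draws hidden input weights and biases uniformly from
#' \code{[-weightRange, weightRange]}, then solves the output weights in
#' closed form. This is the plain (non-optimized) ELM baseline.
#'
#' @param inputs n x d matrix of samples.
#' @param labels length-n class labels (any atomic type; at least 2
#'   classes).
#' @param hiddenCount number of hidden nodes L_h (default 50).
#' @param activation hidden activation name.
#' @param weightRange half-width of the uniform weight/bias box.
#' @param seed integer seed for the weight draw.
#' @return An \linkS4class{ELMModel}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2); y <- rep(0:1, each = 10)
#' m <- elmTrain(x, y, hiddenCount = 10, seed = 3)
#' mean(elmPredict(m, x)$class == y)
#' @export
elmTrain <- function(inputs, labels, hiddenCount = 50,
                     activation = "sigmoid", weightRange = 1, seed = 1L) {
  inputs <- as.matrix(inputs)
  if (length(labels) != nrow(inputs))
    stop("labels length must match the number of samples")
  if (length(unique(labels)) < 2L)
    stop("training data must contain at least 2 classes")
  set.seed(seed)
  d <- ncol(inputs)
  W <- matrix(stats::runif(hiddenCount * d, -weightRange, weightRange),
              hiddenCount, d)
  b <- stats::runif(hiddenCount, -weightRange, weightRange)
  tmat <- oneHot(labels)
  H <- elmHiddenMatrix(inputs, W, b, activation)
  beta <- solveOutputWeights(H, tmat)
  new("ELMModel", inputWeights = W, biases = b, activation = activation,
      outputWeights = beta, classLevels = colnames(tmat))
}

#' Predict with an ELM model
#'
#' Scores are \eqn{H \beta} (linear output layer); the predicted class is
#' the argmax over score columns, with exact ties resolved to the
#' lowest class index.
#'
#' @param model an \linkS4class{ELMModel}.
#' @param inputs n x d matrix of samples.
#' @return A list with \code{scores} (n x k matrix) and \code{class}
#'   (length-n vector of class labels).
#' @export
elmPredict <- function(model, inputs) {
  stopifnot(is(model, "ELMModel"))
  H <- elmHiddenMatrix(inputs, model@inputWeights, model@biases,
                       model@activation)
  scores <- H %*% model@outputWeights
  colnames(scores) <- model@classLevels
  idx <- apply(scores, 1L, which.max)  # which.max takes the first maximum
  list(scores = scores, class = model@classLevels[idx])
}

#' Flatten ELM hidden parameters into an agent vector
#'
#' Encodes the hidden input weights (row-major: node 1's weights, then
#' node 2's, ...) followed by the biases into a single flat vector — the
#' decision-variable layout the optimizer searches over.
#'
#' @param weights L_h x d weight matrix.
#' @param biases length-L_h bias vector.
#' @return Numeric vector of length \code{L_h * d + L_h}.
#' @export
agentEncode <- function(weights, biases) {
  weights <- as.matrix(weights)
  if (length(biases) != nrow(weights))
    stop("bias length must equal the number of hidden nodes")
  c(as.numeric(t(weights)), as.numeric(biases))
}

#' @rdname agentEncode
#' @param agent flat vector of length \code{hiddenCount * inputDim +
#'   hiddenCount}.
#' @param hiddenCount,inputDim layout of the encoded parameters.
#' @return For \code{agentDecode}: a list with \code{weights} and
#'   \code{biases}.
#' @export
agentDecode <- function(agent, hiddenCount, inputDim) {
  expected <- hiddenCount * inputDim + hiddenCount
  if (length(agent) != expected)
    stop(sprintf("agent vector has length %d, expected %d", length(agent),
                 expected))
  W <- matrix(agent[seq_len(hiddenCount * inputDim)], hiddenCount, inputDim,
              byrow = TRUE)
  list(weights = W, biases = agent[hiddenCount * inputDim + seq_len(hiddenCount)])
}

#' Sum-of-squares training fitness of an encoded ELM
#'
#' The objective the optimizer minimizes when tuning the hidden layer:
#' decode the agent into (W, b), solve the output weights in closed form
#' on the training samples, and return the residual sum of squares
#' \eqn{\sum_k (D_k - H_k)^2} between targets and network outputs. A
#' non-finite result is reported as +Inf.
#'
#' @param agent flat parameter vector (see \code{\link{agentEncode}}).
#' @param inputs n x d training matrix.
#' @param targets n x k target matrix (one-hot).
#' @param hiddenCount number of hidden nodes.
#' @param activation hidden activation name.
#' @return Nonnegative scalar fitness.
#' @export
elmFitness <- function(agent, inputs, targets, hiddenCount,
                       activation = "sigmoid") {
  inputs <- as.matrix(inputs)
  dec <- agentDecode(agent, hiddenCount, ncol(inputs))
  H <- elmHiddenMatrix(inputs, dec$weights, dec$biases, activation)
  beta <- solveOutputWeights(H, targets)
  sse <- sum((targets - H %*% beta)^2)
  if (!is.finite(sse)) Inf else sse
}

#' Tune an ELM's hidden layer with the amended grasshopper optimizer
#'
#' Runs the optimizer over flat (W, b) agent vectors in the box
#' \code{[-weightRange, weightRange]} per component, minimizing the
#' closed-form training SSE (\code{\link{elmFitness}}), then returns the
#' model decoded from the best agent with its closed-form output weights.
#'
#' @param inputs n x d training matrix.
#' @param labels length-n class labels (at least 2 classes).
#' @param hiddenCount number of hidden nodes L_h (default 50).
#' @param control a \linkS4class{GoaControl}; default \code{agoaControl()}
#'   settings scaled to the problem are recommended.
#' @param activation hidden activation name.
#' @param weightRange half-width of the search box (default 1).
#' @return A list with \code{model} (\linkS4class{ELMModel}) and
#'   \code{result} (\linkS4class{GoaResult}).
#' @examples
#' set.seed(2)
#' x <- rbind(matrix(rnorm(50, -1), 25, 2), matrix(rnorm(50, 1), 25, 2))
#' y <- rep(0:1, each = 25)
#' fit <- trainElmAgoa(x, y, hiddenCount = 5,
#'                     control = agoaControl(populationSize = 8,
#'                                           maxIterations = 10, seed = 1))
#' bestFitness(fit$result)
#' @export
trainElmAgoa <- function(inputs, labels, hiddenCount = 50,
                         control = agoaControl(), activation = "sigmoid",
                         weightRange = 1) {
  inputs <- as.matrix(inputs)
  if (length(unique(labels)) < 2L)
    stop("training data must contain at least 2 classes")
  tmat <- oneHot(labels)
  d <- ncol(inputs)
  dim <- hiddenCount * d + hiddenCount
  bounds <- boxBounds(-weightRange, weightRange, dimension = dim)
  objective <- function(agent)
    elmFitness(agent, inputs, tmat, hiddenCount, activation)
  result <- goaOptimize(objective, bounds, control)
  dec <- agentDecode(bestPosition(result), hiddenCount, d)
  H <- elmHiddenMatrix(inputs, dec$weights, dec$biases, activation)
  beta <- solveOutputWeights(H, tmat)
  model <- new("ELMModel", inputWeights = dec$weights, biases = dec$biases,
               activation = activation, outputWeights = beta,
               classLevels = colnames(tmat))
  list(model = model, result = result)
}

#' Serialize an ELM model to JSON
#'
#' Writes/reads the full model (weights, biases, activation, output
#' weights, class levels) as a single portable JSON file at full double
#' precision.
#'
#' @param model an \linkS4class{ELMModel}.
#' @param path file path ending in \code{.json}.
#' @return \code{writeELMModel}: the path, invisibly. \code{readELMModel}:
#'   the restored \linkS4class{ELMModel}.
#' @export
writeELMModel <- function(model, path) {
  stopifnot(is(model, "ELMModel"))
  payload <- list(
    inputWeights = unname(model@inputWeights),
    biases = model@biases,
    activation = model@activation,
    outputWeights = unname(model@outputWeights),
    classLevels = model@classLevels)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeELMModel
#' @export
readELMModel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ELMModel",
      inputWeights = as.matrix(payload$inputWeights),
      biases = as.numeric(payload$biases),
      activation = payload$activation,
      outputWeights = as.matrix(payload$outputWeights),
      classLevels = as.character(payload$classLevels))
}
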