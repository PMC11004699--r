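#' Social-force kernel of the grasshopper optimizer
#'
#' The attraction/repulsion force a grasshopper exerts on another at distance
#' \code{d}: \eqn{s(d) = f e^{-d/l} - e^{-d}}, negative (repulsive) at short
#' range, positive (attractive) at intermediate range, vanishing as
#' \eqn{d \to \infty}.
#'
#' @param distance nonnegative distance(s); vectorized.
#' @param attractionIntensity attraction intensity f (default 0.5).
#' @param attractionLengthScale attraction length scale l (default 1.5).
#' @return Numeric vector of forces, same length as \code{distance}.
#' @examples
#' socialForce(0)           # -0.5: pure repulsion at zero distance
#' socialForce(c(1, 5, 50))
#' @export
socialForce <- function(distance, attractionIntensity = 0.5,
                        attractionLengthScale = 1.5) {
  if (any(distance < 0)) stop("distance must be nonnegative")
  if (attractionLengthScale <= 0) stop("attractionLengthScale must be positive")
  attractionIntensity * exp(-distance / attractionLengthScale) - exp(-distance)
}

#' Comfort-zone coefficient schedule
#'
#' Linearly decreasing coefficient
#' \eqn{c = c_{max} - l (c_{max} - c_{min}) / L} that shrinks the
#' grasshoppers' comfort/attraction/repulsion zones across iterations,
#' shifting the swarm from exploration to exploitation.
#'
#' @param iteration current iteration l, between 0 and \code{maxIterations};
#'   vectorized.
#' @param maxIterations total iterations L.
#' @param cMax,cMin schedule endpoints (defaults 1 and 0.01).
#' @return The coefficient value(s).
#' @examples
#' comfortCoefficient(0, 100)    # cMax
#' comfortCoefficient(100, 100)  # cMin
#' @export
comfortCoefficient <- function(iteration, maxIterations, cMax = 1,
                               cMin = 0.01) {
  if (any(iteration < 0) || any(iteration > maxIterations))
    stop("iteration must lie in [0, maxIterations]")
  cMax - iteration * (cMax - cMin) / maxIterations
}

#' One step of the singer chaotic map
#'
#' Advances a chaotic state in (0,1) by the quartic singer map
#' \eqn{r \mapsto 1.07\,(7.9 r - 23.3 r^2 + 28.7 r^3 - 13.3 r^4)}.
#' The raw quartic can leave (0,1) (its maximum on the unit interval is
#' about 1.0093, near r = 0.328), and once outside, iteration diverges; a
#' safeguard therefore reflects any excursion back via
#' \eqn{r \leftarrow |r| \bmod 1}, with an exact 0 remapped to 1e-6, so the
#' stream stays strictly inside (0,1) forever.
#'
#' @param r current state(s) in the open interval (0,1); vectorized.
#' @return Next state(s), strictly inside (0,1).
#' @examples
#' singerStep(0.5)   # 0.9429375, the raw quartic value
#' r <- 0.1
#' for (i in 1:5) r <- singerStep(r)
#' @export
singerStep <- function(r) {
  if (any(r <= 0) || any(r >= 1)) stop("r must lie strictly inside (0, 1)")
  v <- 1.07 * (7.9 * r - 23.3 * r^2 + 28.7 * r^3 - 13.3 * r^4)
  bad <- v <= 0 | v >= 1
  if (any(bad)) {
    v[bad] <- abs(v[bad]) %% 1
    v[v == 0] <- 1e-6
  }
  v
}

#' Opposite point within a box
#'
#' Reflects a point through the center of the search box:
#' \eqn{\breve{x}_d = Lb_d + Ub_d - x_d}. Applying it twice returns the
#' original point.
#'
#' @param x point inside \code{bounds}.
#' @param bounds a \linkS4class{BoxBounds}.
#' @return The reflected point.
#' @examples
#' oppositePoint(c(1, 4), boxBounds(0, 10, dimension = 2))  # c(9, 6)
#' @export
oppositePoint <- function(x, bounds) {
  stopifnot(is(bounds, "BoxBounds"))
  if (length(x) != length(bounds@lower))
    stop("x and bounds dimensions differ")
  if (any(x < bounds@lower) || any(x > bounds@upper))
    stop("x lies outside the bounds")
  bounds@lower + bounds@upper - x
}

#' Quasi-opposite point within a box
#'
#' Draws each component uniformly between the box center
#' \eqn{m_d = (Lb_d + Ub_d)/2} and the opposite point component
#' \eqn{Lb_d + Ub_d - x_d}. This is the candidate generator of
#' quasi-opposition-based learning; the result always lies inside the box.
#'
#' @param x point inside \code{bounds}.
#' @param bounds a \linkS4class{BoxBounds}.
#' @param u optional uniform draw(s) in [0,1] (scalar, or one per
#'   dimension) giving the interpolation fraction from the center towards
#'   the opposite point; when \code{NULL}, drawn from the current RNG. The
#'   amended optimizer passes its chaotic r3 stream value here.
#' @return The quasi-opposite point.
#' @examples
#' set.seed(1)
#' quasiOppositePoint(2, boxBounds(-5, 5))  # somewhere in [-2, 0]
#' @export
quasiOppositePoint <- function(x, bounds, u = NULL) {
  stopifnot(is(bounds, "BoxBounds"))
  if (length(x) != length(bounds@lower))
    stop("x and bounds dimensions differ")
  if (any(x < bounds@lower) || any(x > bounds@upper))
    stop("x lies outside the bounds")
  center <- (bounds@lower + bounds@upper) / 2
  opposite <- bounds@lower + bounds@upper - x
  if (is.null(u)) u <- stats::runif(length(x))
  center + u * (opposite - center)
}

#' Greedy selection between a candidate and its quasi-opposite
#'
#' Keeps whichever of the two has the lower objective value (minimization);
#' on an exact tie the original candidate is retained.
#'
#' @param candidate,candidateFitness the original candidate and its fitness.
#' @param opposite,oppositeFitness the quasi-opposite candidate and its
#'   fitness, evaluated on the same objective.
#' @return A list with elements \code{position}, \code{fitness} and
#'   \code{tookOpposite}.
#' @export
qoblSelect <- function(candidate, candidateFitness, opposite,
                       oppositeFitness) {
  if (oppositeFitness < candidateFitness) {
    list(position = opposite, fitness = oppositeFitness, tookOpposite = TRUE)
  } else {
    list(position = candidate, fitness = candidateFitness,
         tookOpposite = FALSE)
  }
}

#' Grasshopper swarm position update
#'
#' Computes the next positions of all agents from the pairwise social
#' forces and the attraction towards the best-known target:
#' \deqn{x_i^d \leftarrow c \sum_{j \ne i} c \frac{ub_d - lb_d}{2}
#'   s(|x_j^d - x_i^d|) \frac{x_j^d - x_i^d}{d_{ij}} + \hat{T}_d,}
#' with \eqn{d_{ij}} the Euclidean distance between agents i and j. A
#' coincident pair (\eqn{d_{ij} = 0}) contributes nothing. When chaotic
#' streams are supplied (the amended variant), r1 scales the whole social
#' summation and r2 scales the target term. All coordinates are clamped
#' into the bounds afterwards.
#'
#' @param positions N x D matrix of current agent positions.
#' @param target length-D best-known position.
#' @param bounds a \linkS4class{BoxBounds}.
#' @param comfort current comfort coefficient c.
#' @param control a \linkS4class{GoaControl} (social-force parameters and
#'   the optional gravity/wind drifts are read from it).
#' @param streams optional named list or vector with chaotic values
#'   \code{r1}, \code{r2}; \code{NULL} for the baseline update.
#' @return N x D matrix of new positions, all inside the bounds.
#' @export
goaPositionUpdate <- function(positions, target, bounds, comfort, control,
                              streams = NULL) {
  stopifnot(is.matrix(positions), is(bounds, "BoxBounds"),
            is(control, "GoaControl"))
  n <- nrow(positions)
  if (n < 2L) stop("the swarm needs at least 2 agents")
  if (comfort <= 0) stop("comfort coefficient must be positive")
  d <- ncol(positions)
  halfspan <- comfort * (bounds@upper - bounds@lower) / 2
  r1 <- if (is.null(streams)) 1 else streams[["r1"]]
  r2 <- if (is.null(streams)) 1 else streams[["r2"]]
  drift <- numeric(d)
  if (control@gravityConstant != 0)
    drift <- drift - control@gravityConstant / sqrt(d)
  if (control@windStrength != 0)
    drift <- drift + control@windStrength / sqrt(d)
  newpos <- matrix(0, n, d)
  for (i in seq_len(n)) {
    diff <- positions - matrix(positions[i, ], n, d, byrow = TRUE)
    dij <- sqrt(rowSums(diff * diff))
    ok <- dij > 0
    social <- numeric(d)
    if (any(ok)) {
      s <- socialForce(abs(diff[ok, , drop = FALSE]),
                       control@attractionIntensity,
                       control@attractionLengthScale)
      # rows j scaled by 1/d_ij, columns by the inner c*(ub_d-lb_d)/2
      contrib <- s * diff[ok, , drop = FALSE] / dij[ok]
      social <- colSums(contrib) * halfspan
    }
    newpos[i, ] <- r1 * comfort * social + r2 * target + drift
  }
  newpos <- pmin(pmax(newpos,
                      matrix(bounds@lower, n, d, byrow = TRUE)),
                 matrix(bounds@upper, n, d, byrow = TRUE))
  newpos
}

#' Run the grasshopper optimizer
#'
#' Minimizes \code{objective} over a box with the grasshopper optimization
#' algorithm. With \code{useChaos} and \code{useQobl} both off (the default
#' \code{goaControl}) this is the baseline GOA; with both on
#' (\code{agoaControl}) it is the amended variant, in which the singer-map
#' streams r1/r2 modulate the position update, r3 supplies the
#' quasi-opposition draw, and each agent's update is compared against its
#' quasi-opposite candidate, keeping the better of the two. Streams advance
#' once per iteration. Non-finite objective values are treated as +Inf and
#' the run continues.
#'
#' @param objective function taking a length-D numeric vector, returning a
#'   scalar to minimize.
#' @param bounds a \linkS4class{BoxBounds} defining the search box.
#' @param control a \linkS4class{GoaControl}.
#' @param verbose logical; print per-iteration progress lines (iteration,
#'   best fitness, comfort coefficient, chaotic stream values).
#' @return A \linkS4class{GoaResult}.
#' @examples
#' res <- goaOptimize(function(x) sum(x^2), boxBounds(-100, 100, dimension = 2),
#'                    goaControl(populationSize = 20, maxIterations = 30,
#'                               seed = 42))
#' bestFitness(res)
#' @export
goaOptimize <- function(objective, bounds, control = goaControl(),
                        verbose = FALSE) {
  stopifnot(is.function(objective), is(bounds, "BoxBounds"),
            is(control, "GoaControl"))
  set.seed(control@seed)
  n <- control@populationSize
  d <- length(bounds@lower)
  L <- control@maxIterations
  evalSafe <- function(x) {
    v <- objective(x)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else as.numeric(v)
  }
  positions <- matrix(stats::runif(n * d), n, d)
  positions <- positions *
    matrix(bounds@upper - bounds@lower, n, d, byrow = TRUE) +
    matrix(bounds@lower, n, d, byrow = TRUE)
  fitness <- apply(positions, 1L, evalSafe)
  evals <- n
  bestIdx <- which.min(fitness)
  target <- positions[bestIdx, ]
  targetFit <- fitness[bestIdx]
  history <- numeric(L + 1L)
  history[1L] <- targetFit
  streams <- NULL
  if (control@useChaos) {
    r0 <- stats::runif(3)
    r0 <- pmin(pmax(r0, 1e-6), 1 - 1e-6)
    streams <- list(r1 = r0[1], r2 = r0[2], r3 = r0[3])
  }
  for (l in seq_len(L)) {
    cc <- comfortCoefficient(l, L, control@cMax, control@cMin)
    if (control@useChaos) {
      streams$r1 <- singerStep(streams$r1)
      streams$r2 <- singerStep(streams$r2)
      streams$r3 <- singerStep(streams$r3)
    }
    newpos <- goaPositionUpdate(positions, target, bounds, cc, control,
                                streams = streams)
    newfit <- apply(newpos, 1L, evalSafe)
    evals <- evals + n
    if (control@useQobl) {
      for (i in seq_len(n)) {
        u <- if (control@useChaos) streams$r3 else stats::runif(d)
        q <- quasiOppositePoint(newpos[i, ], bounds, u = u)
        qfit <- evalSafe(q)
        evals <- evals + 1L
        pick <- qoblSelect(newpos[i, ], newfit[i], q, qfit)
        newpos[i, ] <- pick$position
        newfit[i] <- pick$fitness
      }
    }
    positions <- newpos
    fitness <- newfit
    it <- which.min(fitness)
    if (fitness[it] < targetFit) {  # strict improvement replaces the target
      targetFit <- fitness[it]
      target <- positions[it, ]
    }
    history[l + 1L] <- targetFit
    if (verbose)
      message(sprintf(
        "iter %d/%d best %.6g c %.4g%s", l, L, targetFit, cc,
        if (control@useChaos)
          sprintf(" r1 %.3f r2 %.3f r3 %.3f", streams$r1, streams$r2,
                  streams$r3) else ""))
  }
  label <- if (control@useChaos && control@useQobl) "agoa"
           else if (!control@useChaos && !control@useQobl) "goa"
           else if (control@useChaos) "goa+chaos" else "goa+qobl"
  new("GoaResult", bestPosition = as.numeric(target),
      bestFitness = targetFit, convergenceHistory = history,
      evaluationsUsed = as.integer(evals), optimizer = label)
}

#' Export a convergence history as CSV
#'
#' Writes the best-so-far fitness trace of a run to a two-column CSV
#' (\code{iteration}, \code{best_fitness}); iteration 0 is the initial
#' population's best.
#'
#' @param result a \linkS4class{GoaResult}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeConvergenceCSV <- function(result, path) {
  stopifnot(is(result, "GoaResult"))
  h <- convergenceHistory(result)
  utils::write.csv(
    data.frame(iteration = seq_along(h) - 1L, best_fitness = h),
    path, row.names = FALSE)
  invisible(path)
}
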