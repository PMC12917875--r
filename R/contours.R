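# Monotone contour machinery: enumeration of candidate maximum-tolerated-contour
# (MTC) partitions of a dose-combination grid, beta posterior tail probabilities,
# the posterior distribution over contours, the insertion trigger and the
# contour-averaged overdose measure.

.contour_cache <- new.env(parent = emptyenv())

#' Enumerate all monotone binary contours of an I x J dose grid
#'
#' A contour is a binary I x J matrix whose entries mark combinations above (1)
#' or below (0) a candidate maximum tolerated contour. Toxicity is assumed
#' monotone in the dose of each agent, so eligible contours are exactly the
#' binary matrices that are nondecreasing along every row and every column.
#' There are \code{choose(I + J, I)} such matrices.
#'
#' Results are cached per shape, and returned in a fixed canonical order
#' (lexicographic on the row-major flattened matrices) so that indices into the
#' contour distribution are stable across calls.
#'
#' @param I,J Number of dose levels of Agent A (rows) and Agent B (columns);
#'   both at least 1. Grids beyond roughly 6 x 6 are refused: the contour count
#'   grows combinatorially and such grids are outside the intended use.
#' @return An object of class \code{contour_set}: a list with elements
#'   \code{shape}, \code{matrices} (list of binary matrices) and \code{flat}
#'   (S x (I*J) 0/1 matrix, one row-major flattened contour per row).
#' @examples
#' cs <- enumerate_contours(3, 3)
#' length(cs$matrices)  # 20
#' @export
enumerate_contours <- function(I, J) {
  if (length(I) != 1L || length(J) != 1L || is.na(I) || is.na(J) ||
      I < 1 || J < 1 || I != round(I) || J != round(J)) {
    stop("grid dimensions must be positive integers")
  }
  I <- as.integer(I); J <- as.integer(J)
  if (choose(I + J, I) > 1e4) {
    stop("grid of shape ", I, "x", J, " has too many contours; ",
         "only grids up to about 6x6 are supported")
  }
  key <- paste0(I, "x", J)
  cached <- .contour_cache[[key]]
  if (!is.null(cached)) return(cached)

  # A monotone contour is determined by the number of leading zeros z_i in each
  # row; column monotonicity makes z nonincreasing in i. Enumerate all
  # nonincreasing sequences of length I over 0..J.
  zs <- list()
  gen <- function(prefix, last) {
    if (length(prefix) == I) {
      zs[[length(zs) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (z in seq.int(last, 0L)) gen(c(prefix, z), z)
  }
  gen(integer(0), J)

  mats <- lapply(zs, function(z) {
    m <- matrix(0L, I, J)
    for (i in seq_len(I)) if (z[i] < J) m[i, (z[i] + 1L):J] <- 1L
    m
  })
  flat <- matrix(unlist(lapply(mats, function(m) as.integer(t(m)))),
                 ncol = I * J, byrow = TRUE)
  ord <- do.call(order, lapply(seq_len(ncol(flat)), function(k) flat[, k]))
  out <- structure(
    list(shape = c(I, J), matrices = mats[ord], flat = flat[ord, , drop = FALSE]),
    class = "contour_set"
  )
  .contour_cache[[key]] <- out
  out
}

#' @export
print.contour_set <- function(x, ...) {
  cat("Set of", nrow(x$flat), "monotone contours on a",
      paste(x$shape, collapse = " x "), "grid\n")
  invisible(x)
}

#' @export
length.contour_set <- function(x) nrow(x$flat)

#' Posterior probability that a combination's toxicity is at or below target
#'
#' Conjugate beta-binomial update: with prior Beta(a, b) and y toxicities in n
#' patients, the posterior is Beta(a + y, b + n - y) and the below-target
#' probability is its CDF at \code{theta}.
#'
#' @param n,y Patients treated and toxicities observed (vectorised; 0 <= y <= n).
#' @param a,b Beta prior hyperparameters, both positive.
#' @param theta Target toxicity probability in (0, 1).
#' @return Probability (or vector/matrix of probabilities) in [0, 1].
#' @examples
#' below_target_prob(0, 0, 1, 1, 0.3)   # uniform prior: 0.3
#' below_target_prob(12, 0, 1, 1, 0.3)  # 1 - 0.7^13
#' @export
below_target_prob <- function(n, y, a, b, theta) {
  if (any(y > n)) stop("y cannot exceed n")
  if (any(y < 0) || any(n < 0)) stop("n and y must be nonnegative")
  if (any(a <= 0) || any(b <= 0)) stop("beta hyperparameters must be positive")
  if (any(theta <= 0) || any(theta >= 1)) stop("theta must lie in (0, 1)")
  stats::pbeta(theta, a + y, b + n - y)
}

#' Posterior distribution over monotone contours
#'
#' Given the matrix p of per-combination posterior probabilities of lying at or
#' below the target toxicity, each contour C receives unnormalised weight
#' \deqn{\prod_{i,j} (1 - p_{ij})^{C[i,j]} p_{ij}^{1 - C[i,j]},}
#' and the weights are normalised over the full contour set. The modal contour
#' is the current estimate of the maximum tolerated contour.
#'
#' @param p Matrix of below-target probabilities (entries in [0, 1]).
#' @param contours Optional \code{contour_set} matching \code{dim(p)}
#'   (enumerated on the fly if omitted).
#' @return An object of class \code{mtc_estimate}: list with the modal
#'   \code{contour}, its canonical \code{index}, its posterior
#'   \code{probability}, the \code{full_distribution} over contours in
#'   canonical order, and the \code{contours} set itself. Ties for the mode are
#'   broken by canonical order.
#' @export
contour_distribution <- function(p, contours = NULL) {
  p <- as.matrix(p)
  if (is.null(contours)) contours <- enumerate_contours(nrow(p), ncol(p))
  if (!all(dim(p) == contours$shape)) {
    stop("p does not match the contour set's grid shape")
  }
  if (any(p < 0) || any(p > 1) || anyNA(p)) {
    stop("p must contain probabilities in [0, 1]")
  }
  pv <- as.vector(t(p))  # row-major, matching contours$flat
  if (all(pv > 0 & pv < 1)) {
    lw <- as.vector(contours$flat %*% (log1p(-pv) - log(pv))) + sum(log(pv))
    w <- exp(lw - max(lw))
  } else {
    # boundary probabilities: evaluate weights directly with 0^0 = 1
    w <- apply(contours$flat, 1L, function(C) prod(ifelse(C == 1L, 1 - pv, pv)))
    if (all(w == 0)) {
      stop("degenerate contour distribution: every contour has zero weight")
    }
  }
  dist <- w / sum(w)
  idx <- which.max(dist)  # first maximum = canonical-order tie-break
  structure(
    list(contour = contours$matrices[[idx]], index = idx,
         probability = dist[idx], full_distribution = dist,
         contours = contours),
    class = "mtc_estimate"
  )
}

#' @export
print.mtc_estimate <- function(x, ...) {
  cat("MTC estimate on a", paste(x$contours$shape, collapse = " x "),
      "grid\nModal contour (posterior probability",
      sprintf("%.3f", x$probability), "):\n")
  print(x$contour)
  invisible(x)
}

#' Does the contour estimate trigger a dose insertion?
#'
#' An insertion is triggered when the modal contour's posterior probability
#' strictly exceeds the MTC threshold lambda; lambda = 1 therefore disables
#' insertions entirely.
#'
#' @param estimate An \code{mtc_estimate}.
#' @param lambda MTC threshold in [0, 1].
#' @return Logical scalar.
#' @export
insertion_triggered <- function(estimate, lambda) {
  stopifnot(inherits(estimate, "mtc_estimate"),
            length(lambda) == 1L, lambda >= 0, lambda <= 1)
  estimate$probability > lambda
}

#' Contour-averaged overdose measure
#'
#' The probability that each combination lies above the maximum tolerated
#' contour, averaged over the posterior contour distribution:
#' \eqn{q_{ij} = \sum_s C_s[i,j] P(MTC = C_s | data)}. Used by the PIPE design
#' to bar overly toxic combinations (inadmissible when \eqn{q_{ij} \ge
#' \epsilon}) and to terminate the trial when the lowest combination itself
#' fails the rule.
#'
#' @param estimate An \code{mtc_estimate}.
#' @return Matrix of probabilities, monotone nondecreasing in each dose.
#' @export
overdose_measure <- function(estimate) {
  stopifnot(inherits(estimate, "mtc_estimate"))
  sh <- estimate$contours$shape
  q <- crossprod(estimate$contours$flat, estimate$full_distribution)
  matrix(as.vector(q), sh[1], sh[2], byrow = TRUE)
}
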