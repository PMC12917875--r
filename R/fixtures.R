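# Built-in fixtures: true-toxicity scenarios, the calibrated PIPE prior, and
# the neratinib/temsirolimus case-study data with its response generator.

#' Construct a true-toxicity scenario
#'
#' @param truth Matrix of true toxicity probabilities, monotone nondecreasing
#'   along rows and columns, entries in [0, 1].
#' @param name Label.
#' @param pos_a,pos_b Numeric level positions (original levels at integers,
#'   inserted ones at midpoints); default 1..I and 1..J.
#' @return A list of class \code{scenario}.
#' @export
scenario <- function(truth, name = "custom", pos_a = NULL, pos_b = NULL) {
  truth <- as.matrix(truth)
  if (any(truth < 0) || any(truth > 1)) stop("toxicities must lie in [0, 1]")
  if (!is_monotone_matrix(truth)) {
    stop("truth matrix must be monotone nondecreasing in both doses")
  }
  if (is.null(pos_a)) pos_a <- as.numeric(seq_len(nrow(truth)))
  if (is.null(pos_b)) pos_b <- as.numeric(seq_len(ncol(truth)))
  stopifnot(length(pos_a) == nrow(truth), length(pos_b) == ncol(truth))
  structure(list(truth = truth, name = name, pos_a = pos_a, pos_b = pos_b),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", x$name, "(rows = Agent A, cols = Agent B):\n")
  print(x$truth)
  invisible(x)
}

.scenario_table <- list(
  # Scenarios with no acceptable combination anywhere in the starting grid:
  # the target sits strictly between the lowest safe cells and the rest.
  A1 = matrix(c(0.10, 0.45, 0.50,
                0.45, 0.50, 0.60,
                0.50, 0.60, 0.65), 3, 3, byrow = TRUE),
  A2 = matrix(c(0.05, 0.10, 0.45,
                0.10, 0.45, 0.50,
                0.45, 0.50, 0.60), 3, 3, byrow = TRUE),
  A3 = matrix(c(0.05, 0.05, 0.10,
                0.05, 0.10, 0.45,
                0.10, 0.45, 0.50), 3, 3, byrow = TRUE),
  # Calibration scenarios for the logistic-model design: a hardest case with
  # the target at the lowest combination, and a simple graded landscape.
  Z1 = matrix(c(0.30, 0.40, 0.50,
                0.40, 0.50, 0.65,
                0.50, 0.60, 0.70), 3, 3, byrow = TRUE),
  Z2 = matrix(c(0.10, 0.20, 0.25,
                0.20, 0.25, 0.30,
                0.40, 0.50, 0.60), 3, 3, byrow = TRUE)
)

#' Load a built-in toxicity scenario
#'
#' @param name One of \code{"A1"}, \code{"A2"}, \code{"A3"}, \code{"Z1"},
#'   \code{"Z2"}.
#' @return A \code{scenario}.
#' @export
load_scenario <- function(name) {
  if (!name %in% names(.scenario_table)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(.scenario_table), collapse = ", "))
  }
  scenario(.scenario_table[[name]], name = name)
}

#' Calibrated beta prior for the PIPE design
#'
#' Prior medians rise linearly from 0.05 at the lowest combination in steps
#' of 0.025 per dose level of either agent; the shared prior sample size is
#' 1/(I*J) so total prior weight per combination shrinks when the grid grows
#' after an insertion; the overdose threshold is 0.5. Hyperparameters are
#' derived from the medians by \code{\link{beta_from_median}}.
#'
#' @param shape Grid dimensions c(I, J).
#' @return List with \code{median} matrix, \code{ss} scalar and
#'   \code{epsilon}.
#' @export
pipe_prior <- function(shape = c(3, 3)) {
  I <- shape[1]; J <- shape[2]
  med <- outer(seq_len(I), seq_len(J),
               function(i, j) 0.05 + 0.025 * (i - 1 + j - 1))
  list(median = med, ss = 1 / (I * J), epsilon = 0.5)
}

#' Case-study DLT data (neratinib x temsirolimus)
#'
#' Observed DLTs/patients from a published phase I combination trial of
#' neratinib (rows: 120/160/200/240 mg) and temsirolimus (columns:
#' 15/25/50/75 mg); 52 evaluable patients, 10 DLTs. The reduced 3 x 3 grid
#' used by the replay drops the lowest temsirolimus and highest neratinib
#' dose.
#'
#' @return List with full \code{n}, \code{y} (4 x 4), reduced \code{n3},
#'   \code{y3} (3 x 3) and dose labels.
#' @export
case_study_data <- function() {
  nera <- c(120, 160, 200, 240)
  tems <- c(15, 25, 50, 75)
  n <- matrix(c(2, 4, 5, 4,
                4, 4, 5, 6,
                4, 8, 2, 0,
                4, 0, 0, 0), 4, 4, byrow = TRUE,
              dimnames = list(paste0(nera, "mg"), paste0(tems, "mg")))
  y <- matrix(c(0, 0, 1, 0,
                1, 1, 0, 3,
                0, 1, 1, 0,
                2, 0, 0, 0), 4, 4, byrow = TRUE, dimnames = dimnames(n))
  list(n = n, y = y,
       n3 = n[1:3, 2:4], y3 = y[1:3, 2:4],
       neratinib = nera, temsirolimus = tems)
}

#' Fixed per-combination response streams for the case-study replay
#'
#' For each combination of the reduced 3 x 3 grid, builds an ordered list of
#' \code{max_n} binary DLT responses. The first n_ij entries are a random
#' permutation of the observed outcomes; each remaining patient gets an
#' individual DLT probability drawn from Beta(1 + y_ij, 1 + n_ij - y_ij)
#' (Beta(3, 3) at combinations never tested in the original study, flagging
#' them as likely unsafe) and then a Bernoulli response. Generate once under a
#' fixed seed and reuse the object across designs so both replay identical
#' patient outcomes.
#'
#' @param max_n Stream length per combination.
#' @param data Case-study data as from \code{\link{case_study_data}}.
#' @return A 3 x 3 list-matrix of integer vectors, with the observed
#'   \code{n}, \code{y} attached as attributes.
#' @export
case_study_responses <- function(max_n = 48, data = case_study_data()) {
  n <- data$n3; y <- data$y3
  out <- matrix(vector("list", length(n)), nrow(n), ncol(n),
                dimnames = dimnames(n))
  for (i in seq_len(nrow(n))) for (j in seq_len(ncol(n))) {
    obs <- c(rep(1L, y[i, j]), rep(0L, n[i, j] - y[i, j]))
    head <- if (length(obs) > 1) sample(obs) else obs
    tail_len <- max_n - n[i, j]
    tail <- integer(tail_len)
    for (t in seq_len(tail_len)) {
      p <- if (n[i, j] > 0) {
        stats::rbeta(1, 1 + y[i, j], 1 + n[i, j] - y[i, j])
      } else {
        stats::rbeta(1, 3, 3)
      }
      tail[t] <- stats::rbinom(1, 1, p)
    }
    out[[i, j]] <- c(head, tail)
  }
  attr(out, "n_obs") <- n
  attr(out, "y_obs") <- y
  out
}
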