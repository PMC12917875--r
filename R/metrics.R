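# Operating-characteristic metrics: selection classification, accuracy and
# utility indices, and aggregation of replicated trials.

#' Classify a true toxicity probability
#'
#' Partitions [0, 1] into subtherapeutic [0, 0.16), acceptable-but-not-correct
#' ([0.16, 0.275) or (0.325, 0.33]), correct [0.275, 0.325] and toxic
#' (0.33, 1]; the correct band is a subset of the acceptable band
#' [0.16, 0.33], and all boundaries are closed exactly as stated.
#'
#' @param pi_true True toxicity probability (vectorised).
#' @return Character vector with values \code{"subtherapeutic"},
#'   \code{"acceptable"}, \code{"correct"} or \code{"toxic"}.
#' @export
classify_combo <- function(pi_true) {
  if (any(pi_true < 0 | pi_true > 1, na.rm = TRUE)) {
    stop("toxicity probabilities must lie in [0, 1]")
  }
  ifelse(pi_true < 0.16, "subtherapeutic",
         ifelse(pi_true > 0.33, "toxic",
                ifelse(pi_true >= 0.275 & pi_true <= 0.325,
                       "correct", "acceptable")))
}

# correct + acceptable = the acceptable band [0.16, 0.33]
is_acceptable_class <- function(cls) cls %in% c("correct", "acceptable")

#' Accuracy index of a selection distribution
#'
#' \deqn{AI = 100 - 100 \cdot N \cdot
#'   \frac{\sum_{ij} (\pi_{ij} - \theta)^2 \rho_{ij}}
#'        {\sum_{ij \in original} (\pi_{ij} - \theta)^2}}
#' where \eqn{\rho_{ij}} is the proportion of trials selecting combination
#' (i, j) (trials with no selection leave \eqn{\sum \rho < 1}) and N is the
#' number of original combinations. Selections of inserted combinations
#' contribute their interpolated true toxicity in the numerator while the
#' normalising sum and N stay on the original grid, keeping runs with and
#' without insertions comparable; set \code{original = NULL} to normalise
#' over the full grid instead.
#'
#' @param rho Matrix of selection proportions.
#' @param truth Matrix of true toxicities, same shape.
#' @param theta Target toxicity.
#' @param original Logical matrix marking original-grid cells (default: all).
#' @return Accuracy index on the percent scale (100 = every selection at
#'   target; returns 100 when all true toxicities equal the target).
#' @export
accuracy_index <- function(rho, truth, theta = 0.30, original = NULL) {
  rho <- as.matrix(rho); truth <- as.matrix(truth)
  stopifnot(all(dim(rho) == dim(truth)), all(rho >= 0), sum(rho) <= 1 + 1e-9)
  if (is.null(original)) original <- matrix(TRUE, nrow(rho), ncol(rho))
  w <- (truth - theta)^2
  denom <- sum(w[original])
  if (denom == 0) return(100)
  100 - 100 * sum(original) * sum(w * rho) / denom
}

#' Utility index
#'
#' Rewards correct and acceptable selections and doubly penalises toxic
#' ones: \code{PCS + PAS - 2 * PTS}, all on the percent scale.
#'
#' @param pcs,pas,pts Selection percentages in [0, 100].
#' @return Utility index (percent scale; can be negative).
#' @export
utility_index <- function(pcs, pas, pts) pcs + pas - 2 * pts

#' Aggregate replicated trial results into operating characteristics
#'
#' Computes selection proportions (correct / acceptable / subtherapeutic /
#' toxic / none, all with the full trial count as denominator), the insertion
#' rate, mean patient exposure on truly acceptable and truly toxic
#' combinations, the selection-frequency matrix over the maximal (fully
#' expanded) grid, and the accuracy and utility indices.
#'
#' @param results List of \code{trial_result} objects from
#'   \code{\link{run_trial}}.
#' @param scen The \code{scenario} the trials were run under (original grid).
#' @param theta Target toxicity.
#' @return A list of class \code{oc_summary}.
#' @export
summarize_trials <- function(results, scen, theta = 0.30) {
  stopifnot(length(results) > 0, inherits(scen, "scenario"))
  n_trials <- length(results)
  cls <- vapply(results, function(r) r$classification, character(1))
  pcs <- 100 * mean(cls == "correct")
  pas <- 100 * mean(is_acceptable_class(cls))
  pss <- 100 * mean(cls == "subtherapeutic")
  pts <- 100 * mean(cls == "toxic")
  none <- 100 * mean(cls == "none")
  insertion_rate <- 100 * mean(vapply(results, function(r) r$inserted,
                                      logical(1)))

  # maximal grid: every midpoint inserted
  I0 <- nrow(scen$truth); J0 <- ncol(scen$truth)
  full <- interp_expand(scen$truth, seq_len(I0 - 1), seq_len(J0 - 1))
  pos_a <- seq(1, I0, by = 0.5); pos_b <- seq(1, J0, by = 0.5)
  rho <- matrix(0, length(pos_a), length(pos_b))
  for (r in results) {
    if (is.null(r$selection)) next
    ia <- match(r$selection_pos[1], pos_a)
    jb <- match(r$selection_pos[2], pos_b)
    rho[ia, jb] <- rho[ia, jb] + 1
  }
  rho <- rho / n_trials
  original <- outer(!full$new_rows, !full$new_cols)
  ai <- accuracy_index(rho, full$mat, theta, original)

  mean_n_acceptable <- mean(vapply(results, function(r) r$n_acceptable,
                                   numeric(1)))
  mean_n_toxic <- mean(vapply(results, function(r) r$n_toxic, numeric(1)))

  structure(list(
    scenario = scen$name, n_trials = n_trials,
    pcs = pcs, pas = pas, pss = pss, pts = pts, none = none,
    insertion_rate = insertion_rate,
    accuracy_index = ai, utility_index = utility_index(pcs, pas, pts),
    mean_n_acceptable = mean_n_acceptable, mean_n_toxic = mean_n_toxic,
    selection_freq = rho, pos_a = pos_a, pos_b = pos_b,
    truth_full = full$mat
  ), class = "oc_summary")
}

#' @export
print.oc_summary <- function(x, ...) {
  cat("Operating characteristics, scenario ", x$scenario,
      " (", x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  PCS %.1f%%  PAS %.1f%%  PSS %.1f%%  PTS %.1f%%  none %.1f%%\n",
              x$pcs, x$pas, x$pss, x$pts, x$none))
  cat(sprintf("  insertions %.1f%%  accuracy index %.1f  utility index %.1f\n",
              x$insertion_rate, x$accuracy_index, x$utility_index))
  cat(sprintf("  mean patients on acceptable %.1f, on toxic %.1f\n",
              x$mean_n_acceptable, x$mean_n_toxic))
  invisible(x)
}

#' @export
as.data.frame.oc_summary <- function(x, ...) {
  data.frame(scenario = x$scenario, n_trials = x$n_trials,
             pcs = x$pcs, pas = x$pas, pss = x$pss, pts = x$pts,
             none = x$none, insertion_rate = x$insertion_rate,
             accuracy_index = x$accuracy_index,
             utility_index = x$utility_index,
             mean_n_acceptable = x$mean_n_acceptable,
             mean_n_toxic = x$mean_n_toxic)
}
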