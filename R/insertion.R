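# Insertion mechanics: deciding where new levels go, expanding the trial state
# and the true-toxicity scenario, and the insertion window.

#' Insertion plan derived from an estimated contour
#'
#' A new level of Agent A is proposed between existing levels i and i+1
#' whenever the contour crosses there, i.e. some column has entry 0 in row i
#' and 1 in row i+1; analogously for Agent B over columns. The all-zeros and
#' all-ones contours yield an empty plan: the contour then lies outside the
#' grid and extrapolation beyond the original dose range is forbidden.
#'
#' @param contour Binary monotone matrix (the modal contour of an
#'   \code{mtc_estimate}).
#' @param state Optional \code{trial_state}; when supplied, gaps that are not
#'   midpoints of two original levels (i.e. already bridged by a previous
#'   insertion) are dropped from the plan.
#' @return A list of class \code{insertion_plan} with integer vectors
#'   \code{a_gaps} and \code{b_gaps} (gap i = between levels i and i+1).
#' @export
insertion_candidates <- function(contour, state = NULL) {
  contour <- as.matrix(contour)
  I <- nrow(contour); J <- ncol(contour)
  a_gaps <- which(vapply(seq_len(max(I - 1L, 0L)), function(i) {
    any(contour[i, ] == 0L & contour[i + 1L, ] == 1L)
  }, logical(1)))
  b_gaps <- which(vapply(seq_len(max(J - 1L, 0L)), function(j) {
    any(contour[, j] == 0L & contour[, j + 1L] == 1L)
  }, logical(1)))
  plan <- structure(list(a_gaps = as.integer(a_gaps),
                         b_gaps = as.integer(b_gaps)),
                    class = "insertion_plan")
  if (!is.null(plan) && !is.null(state)) plan <- filter_plan(plan, state)
  plan
}

# Drop gaps whose flanking levels are not one original dose apart: only
# midpoints of original levels are available, so a gap next to an inserted
# level cannot be subdivided further.
filter_plan <- function(plan, state) {
  keep_a <- plan$a_gaps[abs(diff(state$levels_a)[plan$a_gaps] - 1) < 1e-12]
  keep_b <- plan$b_gaps[abs(diff(state$levels_b)[plan$b_gaps] - 1) < 1e-12]
  structure(list(a_gaps = as.integer(keep_a), b_gaps = as.integer(keep_b)),
            class = "insertion_plan")
}

#' @export
print.insertion_plan <- function(x, ...) {
  cat("Insertion plan: Agent A gaps {", paste(x$a_gaps, collapse = ", "),
      "}, Agent B gaps {", paste(x$b_gaps, collapse = ", "), "}\n")
  invisible(x)
}

plan_size <- function(plan) length(plan$a_gaps) + length(plan$b_gaps)

# Expand a matrix by midpoint interpolation at the given row/column gaps.
# New-row x old-column cells take the mean of the two flanking rows, then new
# columns take the mean of the flanking columns; a new-row x new-column cell
# therefore equals the mean of its four diagonal original neighbours.
interp_expand <- function(mat, a_gaps, b_gaps) {
  new_rows <- rep(FALSE, nrow(mat))
  if (length(a_gaps)) {
    out <- matrix(NA_real_, nrow(mat) + length(a_gaps), ncol(mat))
    new_rows <- rep(FALSE, nrow(out))
    r <- 1L
    for (i in seq_len(nrow(mat))) {
      out[r, ] <- mat[i, ]; r <- r + 1L
      if (i %in% a_gaps) {
        out[r, ] <- (mat[i, ] + mat[i + 1L, ]) / 2
        new_rows[r] <- TRUE; r <- r + 1L
      }
    }
    mat <- out
  }
  new_cols <- rep(FALSE, ncol(mat))
  if (length(b_gaps)) {
    out <- matrix(NA_real_, nrow(mat), ncol(mat) + length(b_gaps))
    new_cols <- rep(FALSE, ncol(out))
    cc <- 1L
    for (j in seq_len(ncol(mat))) {
      out[, cc] <- mat[, j]; cc <- cc + 1L
      if (j %in% b_gaps) {
        out[, cc] <- (mat[, j] + mat[, j + 1L]) / 2
        new_cols[cc] <- TRUE; cc <- cc + 1L
      }
    }
    mat <- out
  }
  list(mat = mat, new_rows = new_rows, new_cols = new_cols)
}

# Insert values at gap midpoints of an ordered level vector.
expand_levels <- function(levels, inserted, gaps) {
  if (!length(gaps)) return(list(levels = levels, inserted = inserted))
  newl <- numeric(0); newf <- logical(0)
  for (i in seq_along(levels)) {
    newl <- c(newl, levels[i]); newf <- c(newf, inserted[i])
    if (i %in% gaps) {
      newl <- c(newl, (levels[i] + levels[i + 1L]) / 2)
      newf <- c(newf, TRUE)
    }
  }
  list(levels = newl, inserted = newf)
}

#' Expand the trial state after an insertion
#'
#' Inserts one new level per planned gap. Observed counts carry over to their
#' (re-indexed) combinations and new combinations start with no data. Prior
#' centres for new combinations are midpoint-interpolated from their
#' neighbours (four-diagonal mean for new-row x new-column cells), the shared
#' prior sample size is reset to 1/(I' * J') on the enlarged grid so the
#' total prior weight per combination shrinks as the grid grows, and the
#' beta hyperparameters are rederived from the new centres and sample size.
#'
#' @param state A \code{trial_state}.
#' @param plan A nonempty \code{insertion_plan} whose gaps are midpoints of
#'   original levels.
#' @return The expanded \code{trial_state}, flagged so that (by default) no
#'   further insertion occurs.
#' @export
expand_state <- function(state, plan) {
  stopifnot(inherits(state, "trial_state"), inherits(plan, "insertion_plan"))
  I <- length(state$levels_a); J <- length(state$levels_b)
  if (any(plan$a_gaps < 1 | plan$a_gaps >= I) ||
      any(plan$b_gaps < 1 | plan$b_gaps >= J)) {
    stop("insertion plan references a nonexistent gap")
  }
  if (plan_size(plan) == 0L) stop("insertion plan is empty")

  la <- expand_levels(state$levels_a, state$inserted_a, plan$a_gaps)
  lb <- expand_levels(state$levels_b, state$inserted_b, plan$b_gaps)
  pm <- interp_expand(state$prior_centre, plan$a_gaps, plan$b_gaps)

  Inew <- length(la$levels); Jnew <- length(lb$levels)
  old_i <- which(!pm$new_rows); old_j <- which(!pm$new_cols)
  n <- matrix(0L, Inew, Jnew); y <- matrix(0L, Inew, Jnew)
  n[old_i, old_j] <- state$n
  y[old_i, old_j] <- state$y

  state$levels_a <- la$levels; state$inserted_a <- la$inserted
  state$levels_b <- lb$levels; state$inserted_b <- lb$inserted
  state$n <- n; state$y <- y
  state$prior_centre <- pm$mat
  state$prior_ss <- 1 / (Inew * Jnew)
  ab <- beta_from_median(state$prior_centre, state$prior_ss, state$prior_param)
  state$prior_a <- ab$a; state$prior_b <- ab$b
  state$insertion_done <- TRUE
  attr(state, "new_rows") <- pm$new_rows
  attr(state, "new_cols") <- pm$new_cols
  state
}

#' Mask of combinations involving a just-inserted level
#'
#' The cohort treated directly after an insertion must receive a combination
#' containing at least one of the new dose levels; this returns that mask for
#' a state just returned by \code{\link{expand_state}}.
#'
#' @param state A \code{trial_state} returned by \code{expand_state}.
#' @return Logical matrix over the expanded grid.
#' @export
new_combination_mask <- function(state) {
  nr <- attr(state, "new_rows"); nc <- attr(state, "new_cols")
  if (is.null(nr) || is.null(nc)) {
    stop("state carries no record of a just-performed insertion")
  }
  outer(nr, rep(TRUE, length(nc))) | outer(rep(TRUE, length(nr)), nc)
}

#' Expand a true-toxicity scenario to match an insertion plan
#'
#' New levels receive midpoint-interpolated true toxicities (four-diagonal
#' means at new-row x new-column cells), which preserves monotonicity.
#'
#' @param scenario A \code{scenario} object (see \code{\link{scenario}}).
#' @param plan An \code{insertion_plan}; an empty plan returns the scenario
#'   unchanged.
#' @return The expanded \code{scenario}.
#' @export
expand_truth <- function(scenario, plan) {
  stopifnot(inherits(scenario, "scenario"))
  if (plan_size(plan) == 0L) return(scenario)
  ex <- interp_expand(scenario$truth, plan$a_gaps, plan$b_gaps)
  pa <- expand_levels(scenario$pos_a, rep(FALSE, length(scenario$pos_a)),
                      plan$a_gaps)
  pb <- expand_levels(scenario$pos_b, rep(FALSE, length(scenario$pos_b)),
                      plan$b_gaps)
  out <- scenario(ex$mat, name = scenario$name,
                  pos_a = pa$levels, pos_b = pb$levels)
  stopifnot(is_monotone_matrix(out$truth))  # midpoints of a monotone matrix
  out
}

#' Is the insertion window open?
#'
#' Insertions are only permitted once enough patients have been treated to
#' support the decision, and not so late that a new combination could not be
#' adequately explored before the sample size runs out.
#'
#' @param n_treated Total patients treated so far.
#' @param config A \code{design_config} (bounds in \code{insertion_window}).
#' @param insertion_done Has an insertion already happened? (With the default
#'   single-timepoint policy this closes the window for good.)
#' @return Logical scalar.
#' @export
window_open <- function(n_treated, config = design_config(),
                        insertion_done = FALSE) {
  if (insertion_done && !config$allow_multiple_insertions) return(FALSE)
  n_treated >= config$insertion_window[1] &&
    n_treated <= config$insertion_window[2]
}

is_monotone_matrix <- function(m, tol = 1e-9) {
  ok_rows <- nrow(m) < 2 || all(diff(m) >= -tol)
  ok_cols <- ncol(m) < 2 || all(diff(t(m)) >= -tol)
  ok_rows && ok_cols
}
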