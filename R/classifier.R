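#' Fit the one-dimensional max-margin I_h-slope classifier
#'
#' Fits a linear soft-margin support-vector classifier to a single
#' feature (the I_h slope), solved exactly rather than by a generic QP:
#' the decision function is `f(x) = w (x - t)` and the objective
#' `J(w, t) = w^2/2 + C * sum_i u_i * max(0, 1 - y_i w (x_i - t))`, with
#' per-class weights `u_i = 0.5 / n_class(i)` implementing a uniform class
#' prior (each class contributes equally regardless of its size). For each
#' candidate boundary `t` — all data points, all midpoints of adjacent
#' sorted points, and the extremes — the optimum over `w` is piecewise
#' quadratic and solved in closed form; the best candidate is then refined
#' by local continuous minimization. For linearly separable data and large
#' `C` the solution is the hard-margin one: the midpoint of the innermost
#' opposite-class pair.
#'
#' The class with the larger training mean lies above the boundary; a
#' point exactly on the boundary is assigned to that upper class (a
#' documented, deterministic tie rule).
#'
#' @param data A data frame with the slope and label columns.
#' @param slope,label Column names (tidy-eval) holding the I_h slope
#'   (pA/s) and the two-level class label.
#' @param C Soft-margin cost (the conventional default 1).
#'
#' @return An object of class `ih_svm`: boundary, margin, orientation,
#'   per-class training counts, objective value, and a `degenerate` flag
#'   (set when the classes cannot be separated at all, e.g. identical
#'   values with mixed labels).
#'
#' @examples
#' d <- tibble::tibble(slope = c(-5, 0, 3, 60, 80, 100),
#'                     type = rep(c("LP", "ORBvl"), each = 3))
#' fit <- fit_ih_classifier(d, slope, type, C = 1e6)
#' fit$boundary # midpoint of 3 and 60
#' predict(fit, c(10, 90))
#' @export
fit_ih_classifier <- function(data, slope, label, C = 1) {
  x <- dplyr::pull(data, {{ slope }})
  lab <- as.character(dplyr::pull(data, {{ label }}))
  check_number(C, "C", min = 0, strict_min = TRUE)
  if (length(x) != length(lab) || anyNA(x) || anyNA(lab)) {
    abort("Slope and label columns must be complete and equal length.")
  }
  classes <- sort(unique(lab))
  if (length(classes) != 2L) abort("Exactly two classes are required.")
  n_by <- table(lab)
  if (any(n_by < 2L)) abort("Each class needs at least two examples.")

  upper <- classes[which.max(c(mean(x[lab == classes[1]]),
                               mean(x[lab == classes[2]])))]
  lower <- setdiff(classes, upper)
  y <- ifelse(lab == upper, 1, -1)
  u <- 0.5 / as.numeric(n_by[lab]) # uniform prior: classes weighted equally

  sx <- sort(unique(x))
  cand <- unique(c(sx, (head(sx, -1) + tail(sx, -1)) / 2,
                   sx[1] - 1, sx[length(sx)] + 1))
  scan <- cpp_scan_fit(x, y, u, C, cand)
  t_best <- scan$t

  # Local continuous refinement between the neighboring candidates (the
  # soft-margin optimum need not sit exactly on a midpoint).
  srt <- sort(cand)
  p <- which(srt == t_best)[1]
  lo <- if (p > 1) srt[p - 1] else t_best - 1
  hi <- if (p < length(srt)) srt[p + 1] else t_best + 1
  ref <- stats::optimize(function(t) solve_w_given_t(x, y, u, C, t)$objective,
                         interval = c(lo, hi))
  if (ref$objective < scan$objective - 1e-12) t_best <- ref$minimum
  sol <- solve_w_given_t(x, y, u, C, t_best)

  structure(
    list(
      boundary = t_best,
      w = sol$w,
      margin = if (sol$w > 0) 1 / sol$w else Inf,
      upper_class = upper,
      lower_class = lower,
      C = C,
      objective = sol$objective,
      training_counts = stats::setNames(as.integer(n_by), names(n_by)),
      degenerate = sol$w <= 0
    ),
    class = "ih_svm"
  )
}

# Exact minimization of J(w) = w^2/2 + C sum u_i max(0, 1 - w g_i) over
# w >= 0, where g_i = y_i (x_i - t). J is convex piecewise quadratic in w
# with kinks at w = 1/g_i for positive g_i; on the interval where the k
# largest-g points are inactive the stationary point is w = C * S_k with
# S_k the weighted sum of g over the active set. Evaluating J exactly at
# every kink and every clamped stationary point covers the optimum.
solve_w_given_t <- function(x, y, u, C, t) {
  g <- y * (x - t)
  ord <- order(g, decreasing = TRUE)
  gs <- g[ord]
  us <- u[ord]
  npos <- sum(gs > 0)

  cum_u <- cumsum(us)
  cum_s <- cumsum(us * gs)
  act_u <- sum(us) - c(0, cum_u[seq_len(npos)])
  act_s <- sum(us * gs) - c(0, cum_s[seq_len(npos)])
  w_lo <- c(0, 1 / gs[seq_len(npos)])
  w_hi <- c(w_lo[-1], Inf)
  w_star <- pmin(pmax(C * act_s, w_lo), w_hi)
  w_star[!is.finite(w_star)] <- C * pmax(act_s[!is.finite(w_star)], 0)

  # Closed-form J within each interval: active points all have positive
  # hinge there, so the hinge sum is act_u - w * act_s.
  jv <- w_star^2 / 2 + C * (act_u - w_star * act_s)
  best <- which.min(jv)
  w <- max(w_star[best], 0)
  list(w = w, objective = w^2 / 2 + C * sum(u * pmax(0, 1 - w * g)))
}

#' @export
print.ih_svm <- function(x, ...) {
  cat(sprintf(
    "<ih_svm> boundary %.3g pA/s, margin %.3g; '%s' above, '%s' below (C = %g)%s\n",
    x$boundary, x$margin, x$upper_class, x$lower_class, x$C,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Predict neuron types from I_h slopes
#'
#' @param object A fitted [fit_ih_classifier()] model.
#' @param new_slopes Numeric vector of I_h slopes (pA/s).
#' @param ... Unused.
#' @return Character vector of predicted class labels. A slope equal to
#'   the boundary goes to the upper class.
#' @export
predict.ih_svm <- function(object, new_slopes, ...) {
  if (object$degenerate) {
    warn("Degenerate model: predictions default to the upper class.")
  }
  ifelse(new_slopes >= object$boundary, object$upper_class, object$lower_class)
}

#' @export
tidy.ih_svm <- function(x, ...) {
  tibble(
    term = c("boundary", "margin", "w"),
    estimate = c(x$boundary, x$margin, x$w)
  )
}

#' @export
glance.ih_svm <- function(x, ...) {
  tibble(
    boundary = x$boundary, margin = x$margin, C = x$C,
    n_upper = x$training_counts[[x$upper_class]],
    n_lower = x$training_counts[[x$lower_class]],
    degenerate = x$degenerate
  )
}

#' Cross-validate the I_h-slope classifier
#'
#' Stratified k-fold cross-validation, the whole k-fold process repeated
#' with fresh random divisions; per-fold held-out accuracy is averaged
#' over folds within a repeat, then over repeats. Stratification keeps
#' both classes in every training split; in the rare event a split still
#' loses a class the partition is redrawn (and counted).
#'
#' @inheritParams fit_ih_classifier
#' @param k Folds (10 in the standard protocol).
#' @param repeats Repeats of the whole k-fold process (20).
#' @param seed Integer seed for the fold draws.
#'
#' @return An `ih_cv` object: `mean_accuracy`, `per_repeat` tibble,
#'   `per_fold` tibble, and the protocol settings. `tidy()` returns the
#'   per-repeat accuracies, `glance()` the one-row summary.
#' @examples
#' d <- tibble::tibble(slope = c(rnorm(20), rnorm(20, 8)),
#'                     type = rep(c("a", "b"), each = 20))
#' cv <- cross_validate_ih(d, slope, type, k = 5, repeats = 2, seed = 1)
#' glance(cv)
#' @export
cross_validate_ih <- function(data, slope, label, k = 10, repeats = 20,
                              C = 1, seed = 1) {
  x <- dplyr::pull(data, {{ slope }})
  lab <- as.character(dplyr::pull(data, {{ label }}))
  n <- length(x)
  if (n < k) abort("Need at least `k` observations.")
  if (length(unique(lab)) != 2L) abort("Exactly two classes are required.")

  with_local_seed(seed, {
    redraws <- 0L
    rows <- list()
    for (r in seq_len(repeats)) {
      folds <- draw_stratified_folds(lab, k)
      while (!folds_trainable(folds, lab, k)) {
        redraws <- redraws + 1L
        folds <- draw_stratified_folds(lab, k)
      }
      for (f in seq_len(k)) {
        test <- folds == f
        d_train <- tibble(s = x[!test], l = lab[!test])
        fit <- fit_ih_classifier(d_train, s, l, C = C)
        acc <- prediction_accuracy(predict(fit, x[test]), lab[test])
        rows[[length(rows) + 1L]] <- tibble(repeat_ = r, fold = f,
                                            n_test = sum(test), accuracy = acc)
      }
    }
    per_fold <- dplyr::bind_rows(rows)
    per_repeat <- per_fold |>
      dplyr::group_by(.data$repeat_) |>
      dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
    if (redraws > 0L) {
      inform(sprintf("Redrew %d partition(s) that lost a class.", redraws))
    }
    structure(
      list(
        mean_accuracy = mean(per_repeat$accuracy),
        per_repeat = per_repeat,
        per_fold = per_fold,
        k = k, repeats = repeats, C = C, seed = seed,
        n = n, redraws = redraws
      ),
      class = "ih_cv"
    )
  })
}

draw_stratified_folds <- function(lab, k) {
  folds <- integer(length(lab))
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

folds_trainable <- function(folds, lab, k) {
  all(vapply(seq_len(k), function(f) {
    length(unique(lab[folds != f])) == 2L && all(table(lab[folds != f]) >= 2L)
  }, logical(1)))
}

#' @export
print.ih_cv <- function(x, ...) {
  cat(sprintf("<ih_cv> %d-fold x %d repeats on n = %d: mean accuracy %.3f\n",
              x$k, x$repeats, x$n, x$mean_accuracy))
  invisible(x)
}

#' @export
tidy.ih_cv <- function(x, ...) x$per_repeat

#' @export
glance.ih_cv <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, k = x$k, repeats = x$repeats,
         n = x$n, C = x$C, seed = x$seed)
}

#' Shuffled-label null distribution of classifier accuracy
#'
#' Permutes the class labels and re-runs the cross-validation for each of
#' `n_shuffles` instances, yielding the empirical null distribution of
#' accuracy and its central 95% interval (2.5 and 97.5 percentiles). A
#' real effect shows as the true-label accuracy exceeding the interval's
#' upper bound.
#'
#' @inheritParams cross_validate_ih
#' @param n_shuffles Number of label permutations (1000 in the standard
#'   protocol).
#' @param repeats CV repeats per shuffle (1: a single k-fold pass per
#'   permutation).
#'
#' @return An `ih_null` object: `null_accuracies`, `interval_95`
#'   (length-2), and the settings. `tidy()` returns the accuracies.
#' @export
shuffled_null_ih <- function(data, slope, label, n_shuffles = 1000,
                             k = 10, repeats = 1, C = 1, seed = 1) {
  x <- dplyr::pull(data, {{ slope }})
  lab <- as.character(dplyr::pull(data, {{ label }}))
  with_local_seed(seed, {
    accs <- vapply(seq_len(n_shuffles), function(s) {
      d <- tibble(s = x, l = sample(lab))
      cv <- cross_validate_ih(d, s, l, k = k, repeats = repeats, C = C,
                              seed = sample.int(.Machine$integer.max, 1))
      cv$mean_accuracy
    }, numeric(1))
    structure(
      list(
        null_accuracies = accs,
        interval_95 = unname(quantile(accs, c(0.025, 0.975))),
        n_shuffles = n_shuffles, k = k, repeats = repeats, C = C, seed = seed
      ),
      class = "ih_null"
    )
  })
}

#' @export
print.ih_null <- function(x, ...) {
  cat(sprintf("<ih_null> %d shuffles: 95%% interval [%.3f, %.3f]\n",
              x$n_shuffles, x$interval_95[1], x$interval_95[2]))
  invisible(x)
}

#' @export
tidy.ih_null <- function(x, ...) tibble(accuracy = x$null_accuracies)

#' Prediction accuracy
#'
#' The number of correct predictions divided by the total number of
#' predictions.
#'
#' @param pred,truth Equal-length label vectors.
#' @return Fraction in \[0, 1\].
#' @examples
#' prediction_accuracy(c("a", "a", "b"), c("a", "b", "b"))
#' @export
prediction_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    abort("`pred` and `truth` must be nonempty and equal length.")
  }
  mean(pred == truth)
}
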