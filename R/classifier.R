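#' Configuration of the forward-selection SVM search
#'
#' @param c_grid Soft-margin C values to try, default
#'   `c(0.1, 1, 10, 100, 1000)`.
#' @param n_folds Cross-validation folds, default 10.
#' @param seed Fold-assignment seed.
#' @param max_features Cap on selected features; `NULL` allows all
#'   candidates.
#' @param stall_patience Number of consecutive non-improving greedy
#'   rounds tolerated before the search stops (default 1).
#' @return A `selection_config` object.
#' @export
selection_config <- function(c_grid = c(0.1, 1, 10, 100, 1000),
                             n_folds = 10, seed = 1,
                             max_features = NULL, stall_patience = 1) {
  if (!length(c_grid) || any(c_grid <= 0))
    stop("c_grid must be a non-empty vector of positive values")
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (stall_patience < 1) stop("stall_patience must be at least 1")
  structure(list(c_grid = c_grid, n_folds = n_folds, seed = seed,
                 max_features = max_features, stall_patience = stall_patience),
            class = "selection_config")
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each subject to one of `n_folds` folds so that (a) per-class
#' counts across folds differ by at most one and (b) overall fold sizes
#' differ by at most one. Within each class members are shuffled and
#' dealt round-robin; the classes' surplus members are then placed on
#' distinct folds chosen to keep the overall sizes balanced.
#' Deterministic for a given seed.
#'
#' @param labels Factor (or character) of class labels.
#' @param n_folds Number of folds, default 10.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds), one per subject.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n_folds > n) stop("more folds than subjects")
  fold <- integer(n)
  extra_load <- integer(n_folds)  # how many surplus members each fold holds
  # classes processed in first-occurrence order with a per-class seeded
  # stream, so the assignment is invariant to renaming the classes
  classes <- unique(labels)
  for (ci in seq_along(classes)) {
    set.seed(seed %% 1000000L + 7919L * ci)
    idx <- sample(which(labels == classes[ci]))
    m <- length(idx)
    base <- m %/% n_folds
    extra <- m %% n_folds
    # folds receiving one surplus member of this class: least-loaded first
    ord <- order(extra_load, stats::runif(n_folds))
    extra_folds <- ord[seq_len(extra)]
    extra_load[extra_folds] <- extra_load[extra_folds] + 1L
    counts <- rep(base, n_folds)
    counts[extra_folds] <- counts[extra_folds] + 1L
    fold[idx] <- rep(seq_len(n_folds), times = counts)
  }
  fold
}

#' Pooled cross-validated confusion matrix of a linear SVM
#'
#' Trains a linear-kernel soft-margin SVM on each training split and
#' pools the holdout predictions of all folds into a single confusion
#' matrix over all n subjects. A training split that contains a single
#' class cannot fit an SVM; its holdout is predicted as that (majority)
#' class and the result is flagged.
#'
#' @param features Numeric matrix (subjects x features), at least one
#'   column.
#' @param positive Logical vector: membership of the positive class.
#' @param c_value Soft-margin parameter C.
#' @param folds Fold assignment from [stratified_folds()].
#' @return A [confusion_matrix()] with attribute
#'   `degenerate_folds` (integer vector of single-class training folds).
#' @export
cv_evaluate <- function(features, positive, c_value, folds) {
  features <- as.matrix(features)
  if (ncol(features) == 0) stop("feature subset is empty")
  y <- factor(ifelse(positive, "pos", "neg"), levels = c("neg", "pos"))
  pred <- factor(rep(NA_character_, length(y)), levels = c("neg", "pos"))
  degenerate <- integer()
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- folds == f
    if (length(unique(y[tr])) < 2) {
      maj <- names(which.max(table(y[tr])))
      pred[te] <- maj
      degenerate <- c(degenerate, f)
      next
    }
    # libsvm's internal per-training-fold feature scaling: candidate
    # features span orders of magnitude (leading vs trailing PC scores)
    # and the solver converges poorly without it
    fit <- e1071::svm(x = features[tr, , drop = FALSE], y = y[tr],
                      kernel = "linear", cost = c_value, scale = TRUE)
    pred[te] <- stats::predict(fit, features[te, , drop = FALSE])
  }
  cm <- confusion_matrix(tp = sum(pred == "pos" & y == "pos"),
                         fp = sum(pred == "pos" & y == "neg"),
                         fn = sum(pred == "neg" & y == "pos"),
                         tn = sum(pred == "neg" & y == "neg"))
  attr(cm, "degenerate_folds") <- degenerate
  cm
}

# greedy forward selection for one C value; returns the best prefix
forward_pass <- function(features, positive, c_value, folds, config) {
  cand <- colnames(features)
  max_feat <- min(if (is.null(config$max_features)) ncol(features)
                  else config$max_features, ncol(features))
  selected <- character()
  trace <- list()
  best_mcc <- -Inf; best_len <- 0; best_cm <- NULL
  stall <- 0
  d_cache <- vapply(cand, function(f)
    cohens_d(features[positive, f], features[!positive, f]), numeric(1))
  while (length(selected) < max_feat) {
    remaining <- setdiff(cand, selected)
    stats_m <- vapply(remaining, function(f) {
      cm <- cv_evaluate(features[, c(selected, f), drop = FALSE],
                        positive, c_value, folds)
      c(mcc = mcc(cm), acc = prf1(cm)$accuracy)
    }, numeric(2))
    mccs <- stats_m["mcc", ]; accs <- stats_m["acc", ]
    if (all(is.na(mccs))) {
      # MCC undefined for every candidate (a zero confusion-matrix
      # marginal): fall back to the largest univariate effect size,
      # ties broken by CV accuracy, then candidate order
      ord <- order(-d_cache[remaining], -accs, seq_along(remaining))
      pick <- remaining[ord[1]]
      crit <- NA_real_
    } else {
      ord <- order(-mccs, -accs, seq_along(remaining))
      pick <- remaining[ord[1]]
      crit <- mccs[[pick]]
    }
    selected <- c(selected, pick)
    trace[[length(trace) + 1]] <- list(feature = pick, criterion = crit,
                                       accuracy = accs[[pick]])
    improved <- !is.na(crit) && crit > best_mcc
    if (improved) {
      best_mcc <- crit; best_len <- length(selected)
      best_cm <- cv_evaluate(features[, selected, drop = FALSE],
                             positive, c_value, folds)
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= config$stall_patience) break
    }
  }
  if (best_len == 0) {
    # MCC never became defined; keep the full fallback path
    best_len <- length(selected)
    best_cm <- cv_evaluate(features[, selected, drop = FALSE],
                           positive, c_value, folds)
    best_mcc <- mcc(best_cm)
  }
  list(selected = selected[seq_len(best_len)],
       mcc = best_mcc, cm = best_cm,
       trace = trace[seq_len(best_len)])
}

#' One-vs-all forward-selection SVM for a single experience class
#'
#' For each C on the grid, runs a greedy sequential forward selection:
#' at every step the candidate feature whose addition maximizes the
#' pooled cross-validated MCC is added; when the MCC is undefined for
#' all candidates (no predicted case in one class), the candidate with
#' the largest univariate Cohen's d between the positive class and the
#' rest is added instead (ties broken by CV accuracy, then candidate
#' order). The search stops at `max_features` or after
#' `stall_patience` non-improving rounds and returns the best-scoring
#' prefix; across the C grid the model with the highest final MCC wins,
#' ties resolved toward smaller C.
#'
#' @param candidates A `candidate_set` from [build_candidates()].
#' @param positive_class One of [experience_levels()].
#' @param config A [selection_config()].
#' @param folds Optional precomputed fold assignment (shared across
#'   classes); computed from `config` when `NULL`.
#' @return A `one_vs_all_report`: list with `positive_class`,
#'   `selected_features`, `c_value`, `confusion` ([confusion_matrix()]),
#'   `metrics` (mcc/accuracy/precision/recall/f1),
#'   `min_significant_accuracy`, `selection_trace`, `folds`, `seed`.
#' @export
forward_select <- function(candidates, positive_class, config = selection_config(),
                           folds = NULL) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (!positive_class %in% levels(candidates$labels))
    stop("unknown positive class: ", positive_class)
  if (ncol(candidates$features) == 0) stop("empty candidate set")
  if (length(unique(candidates$labels)) < 2)
    stop("need at least 2 classes present")
  positive <- candidates$labels == positive_class
  if (is.null(folds))
    folds <- stratified_folds(candidates$labels, config$n_folds, config$seed)
  passes <- lapply(config$c_grid, function(cc)
    forward_pass(candidates$features, positive, cc, folds, config))
  final_mcc <- vapply(passes, function(p) ifelse(is.na(p$mcc), -Inf, p$mcc),
                      numeric(1))
  # ties toward smaller C: order over (-mcc, C)
  best <- order(-final_mcc, config$c_grid)[1]
  pass <- passes[[best]]
  n <- length(positive)
  p0 <- max(mean(positive), 1 - mean(positive))  # no-information rate
  met <- c(list(mcc = mcc(pass$cm)), prf1(pass$cm))
  structure(list(positive_class = positive_class,
                 selected_features = pass$selected,
                 c_value = config$c_grid[best],
                 confusion = pass$cm,
                 metrics = met,
                 min_significant_accuracy = min_significant_accuracy(n, p0),
                 selection_trace = pass$trace,
                 folds = folds, seed = config$seed,
                 degenerate_folds = attr(pass$cm, "degenerate_folds")),
            class = "one_vs_all_report")
}

#' @export
print.one_vs_all_report <- function(x, ...) {
  cat(sprintf("One-vs-all SVM report: %s vs all (C = %g)\n",
              x$positive_class, x$c_value))
  cat(sprintf("  features selected: %d (first: %s)\n",
              length(x$selected_features),
              paste(utils::head(x$selected_features, 3), collapse = ", ")))
  m <- x$metrics
  cat(sprintf("  MCC %.2f | accuracy %.1f%% | precision %.1f%% | recall %.1f%% | F1 %.2f\n",
              m$mcc, 100 * m$accuracy, 100 * m$precision, 100 * m$recall, m$f1))
  cat(sprintf("  minimum significant accuracy %.1f%%\n",
              100 * x$min_significant_accuracy))
  invisible(x)
}

#' Fit one-vs-all models for all three experience classes
#'
#' Runs an independent [forward_select()] per class on a shared fold
#' assignment; the chosen C may differ between classes.
#'
#' @inheritParams forward_select
#' @return Named list of three `one_vs_all_report`s.
#' @export
fit_all_classes <- function(candidates, config = selection_config()) {
  present <- levels(droplevels(candidates$labels))
  if (length(present) < 3) stop("all three experience classes must be present")
  folds <- stratified_folds(candidates$labels, config$n_folds, config$seed)
  reports <- lapply(experience_levels(), function(cl)
    forward_select(candidates, cl, config, folds = folds))
  names(reports) <- experience_levels()
  reports
}

#' Serialize one-vs-all reports to JSON
#' @param reports List of `one_vs_all_report`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  out <- lapply(reports, function(r) {
    list(positive_class = r$positive_class,
         selected_features = r$selected_features,
         c_value = r$c_value,
         confusion = r$confusion[c("tp", "fp", "fn", "tn")],
         metrics = r$metrics,
         min_significant_accuracy = r$min_significant_accuracy,
         seed = r$seed,
         selection_trace = lapply(r$selection_trace, function(s)
           list(feature = s$feature, criterion = s$criterion)))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
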