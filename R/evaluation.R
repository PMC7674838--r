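# Nested cross-validation and AUC. The outer loop estimates generalization;
# the inner loop (when a hyperparameter grid is given) selects
# hyperparameters by inner AUC. Every fitting call is instrumented: the
# harness records which subjects each call saw, so leakage of test-fold
# subjects into any fitting step is a hard, testable assertion.

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, ties counted 1/2 (mid-rank
#' convention).
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels (or two-level factor), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)                    # mid-ranks implement the 1/2-tie rule
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation folds
#'
#' @param y 0/1 labels.
#' @param k Fold count.
#' @param seed Seed for the within-class shuffles (deterministic folds).
#' @param as_foldid If `TRUE` return an integer fold id per subject instead
#'   of a list of test-index vectors.
#' @return List of k test-index vectors (default), or a fold-id vector.
#' @export
make_folds <- function(y, k, seed = 1L, as_foldid = FALSE) {
  y <- as.integer(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (min(table(y)) < k)
    stop("a class has fewer subjects (", min(table(y)),
         ") than folds (", k, ")")
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- with_seed(seed + cls, idx[sample.int(length(idx))])
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (as_foldid) return(foldid)
  lapply(seq_len(k), function(f) which(foldid == f))
}

#' Nested cross-validation plan
#'
#' @param k_out Outer folds (default 10).
#' @param k_in Inner folds for hyperparameter selection (default 5).
#' @param grid Named list of hyperparameter value vectors (e.g.
#'   `list(C = c(0.01, 0.1, 1, 10))`); empty list disables the inner loop.
#' @param seed Seed from which all fold assignments and per-fold training
#'   seeds are derived.
#' @return A `cv_plan`.
#' @export
cv_plan <- function(k_out = 10L, k_in = 5L, grid = list(), seed = 1L) {
  stopifnot(k_out >= 2L, k_in >= 2L)
  structure(list(k_out = as.integer(k_out), k_in = as.integer(k_in),
                 grid = grid, seed = as.integer(seed), stratified = TRUE),
            class = "cv_plan")
}

.grid_rows <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  df <- expand.grid(grid, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Run nested cross-validation
#'
#' `builder(cohort_train, hyper, seed)` must return a model whose
#' `predict(model, cohort)` yields named scores in `[0,1]`. Feature
#' reduction, hyperparameter choice and training all happen inside each
#' outer training fold: the harness only ever passes training subjects to
#' `builder`, and logs the subject ids of every fitting call in `fit_log`
#' so tests can assert the absence of leakage.
#'
#' @param cohort A cohort list (see [read_cohort()] / [make_cohort()]).
#' @param builder Model builder, `function(cohort, hyper, seed) -> model`.
#' @param plan A [cv_plan()].
#' @return A `cv_result`: out-of-fold `scores` (named by subject), `labels`,
#'   `auc`, per-fold `fold_aucs`, `folds` (test indices), `chosen` hyper per
#'   fold, and `fit_log`.
#' @export
run_nested_cv <- function(cohort, builder, plan = cv_plan()) {
  y <- cohort$labels
  n <- length(y)
  folds <- make_folds(y, plan$k_out, seed = plan$seed)
  fold_seeds <- derive_seeds(plan$seed, plan$k_out * 2L + 1L)
  grid_rows <- .grid_rows(plan$grid)
  fit_log <- list()
  scores <- stats::setNames(rep(NA_real_, n), cohort$subject_ids)
  chosen <- vector("list", plan$k_out)
  fold_aucs <- numeric(plan$k_out)
  logged_builder <- function(ch, hyper, seed, context) {
    fit_log[[length(fit_log) + 1L]] <<- list(context = context,
                                             subjects = ch$subject_ids)
    builder(ch, hyper, seed)
  }
  for (f in seq_len(plan$k_out)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n), test_idx)
    ch_train <- cohort_subset(cohort, train_idx)
    best <- grid_rows[[1]]
    if (length(grid_rows) > 1L) {
      in_folds <- make_folds(ch_train$labels, plan$k_in,
                             seed = fold_seeds[plan$k_out + f])
      mean_aucs <- vapply(grid_rows, function(hy) {
        a <- vapply(seq_along(in_folds), function(g) {
          it <- in_folds[[g]]
          ch_in <- cohort_subset(ch_train, setdiff(seq_along(ch_train$labels), it))
          m <- logged_builder(ch_in, hy, fold_seeds[plan$k_out * 2L + 1L],
                              context = sprintf("outer%d_inner%d", f, g))
          s <- stats::predict(m, cohort_subset(ch_train, it))
          auc(s, ch_train$labels[it])
        }, numeric(1))
        mean(a)
      }, numeric(1))
      best <- grid_rows[[which.max(mean_aucs)]]
    }
    chosen[[f]] <- best
    model <- logged_builder(ch_train, best, fold_seeds[f],
                            context = sprintf("outer%d_final", f))
    s <- stats::predict(model, cohort_subset(cohort, test_idx))
    scores[test_idx] <- s[cohort$subject_ids[test_idx]]
    fold_aucs[f] <- if (length(unique(y[test_idx])) == 2L)
      auc(scores[test_idx], y[test_idx]) else NA_real_
  }
  structure(list(scores = scores, labels = y,
                 auc = auc(scores, y), fold_aucs = fold_aucs,
                 folds = folds, chosen = chosen, fit_log = fit_log,
                 plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> AUC = %.3f over %d folds (n = %d)\n",
              x$auc, length(x$folds), length(x$labels)))
  invisible(x)
}

#' Whole-volume versus inner-structure comparison
#'
#' Runs the same nested CV twice -- once on the entire volumes and once on
#' the inner central crop -- under identical fold assignments (paired
#' design), and reports both AUCs and their difference.
#'
#' @param cohort Cohort list.
#' @param builder_factory `function(crop_k) -> builder`; called with `NULL`
#'   for the whole-volume run and with `crop_k` for the cropped run.
#' @param plan A [cv_plan()].
#' @param crop_k Central-slice count for the inner run.
#' @return List with `whole`, `inner` (both `cv_result`) and `auc_diff`
#'   (inner minus whole).
#' @export
compare_regions <- function(cohort, builder_factory, plan = cv_plan(),
                            crop_k) {
  whole <- run_nested_cv(cohort, builder_factory(NULL), plan)
  inner <- run_nested_cv(cohort, builder_factory(crop_k), plan)
  stopifnot(identical(whole$folds, inner$folds))   # paired by construction
  list(whole = whole, inner = inner, auc_diff = inner$auc - whole$auc)
}

#' Serialize a CV result
#'
#' Writes the full result (fold map, out-of-fold scores, AUCs, chosen
#' hyperparameters) as JSON plus a flat CSV of scores.
#'
#' @param res A `cv_result`.
#' @param path_json JSON output path.
#' @param path_csv Optional CSV output path for the flat score table.
#' @return `path_json`, invisibly.
#' @export
write_cv_result <- function(res, path_json, path_csv = NULL) {
  obj <- list(auc = res$auc, fold_aucs = res$fold_aucs,
              scores = as.list(res$scores), labels = res$labels,
              folds = res$folds, chosen = res$chosen,
              plan = unclass(res$plan)[c("k_out", "k_in", "seed")])
  jsonlite::write_json(obj, path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_csv))
    utils::write.csv(data.frame(subject_id = names(res$scores),
                                score = unname(res$scores),
                                label = res$labels),
                     path_csv, row.names = FALSE)
  invisible(path_json)
}

#' Canonical builders for the two headline methods
#'
#' Convenience factories producing `builder(cohort, hyper, seed)` functions
#' for [run_nested_cv()]: `method1_builder` wires Aggregate-Selection + SVM
#' and kernel-PLS + SVM fused by the sum rule (hyper `C` selected on the
#' inner grid); `method2_builder` wires the per-slice decomposition ensemble;
#' `cnn3d_builder` the patch-based 3D CNN.
#'
#' @param as_k,kpls_h,kernel See [build_method1()].
#' @param crop_k Central-slice crop (`NULL` for whole volumes).
#' @return A builder function.
#' @export
method1_builder <- function(as_k = 200L, kpls_h = 10L, kernel = "gaussian",
                            crop_k = NULL) {
  cache <- new.env(parent = emptyenv())   # reductions reused across C values
  function(cohort, hyper, seed) {
    C <- if (!is.null(hyper$C)) hyper$C else 1
    key <- paste(c(cohort$subject_ids, seed), collapse = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- method1_reductions(cohort, as_k = as_k,
                                         kpls_h = kpls_h, kernel = kernel,
                                         crop_k = crop_k, seed = seed)
    build_method1(cohort, as_k = as_k, kpls_h = kpls_h, kernel = kernel,
                  C = C, crop_k = crop_k, seed = seed,
                  reductions = cache[[key]])
  }
}

#' @rdname method1_builder
#' @param approaches,gaps,backends,stride See [build_method2()].
#' @export
method2_builder <- function(approaches = c("A", "B", "C", "D"), gaps = 0:2,
                            backends = list(slice_backend("lin")),
                            stride = NULL, crop_k = NULL) {
  function(cohort, hyper, seed)
    build_method2(cohort, approaches = approaches, gaps = gaps,
                  backends = backends, stride = stride, crop_k = crop_k,
                  seed = seed)
}

#' @rdname method1_builder
#' @param spec A [patch3d_spec()].
#' @export
cnn3d_builder <- function(spec = patch3d_spec(), crop_k = NULL) {
  function(cohort, hyper, seed) {
    vols <- cohort$volumes
    if (!is.null(crop_k)) vols <- lapply(vols, crop_inner, k = crop_k)
    model <- train_patch_cnn(vols, cohort$labels, spec = spec, seed = seed)
    structure(list(model = model, crop_k = crop_k), class = "cnn3d_wrapper")
  }
}

#' @export
predict.cnn3d_wrapper <- function(object, cohort, ...) {
  vols <- cohort$volumes
  if (!is.null(object$crop_k))
    vols <- lapply(vols, crop_inner, k = object$crop_k)
  s <- predict_cnn3d(object$model, vols)
  stats::setNames(s, cohort$subject_ids)
}
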