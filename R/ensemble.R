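# Sum-rule classifier fusion. The sum rule is realized as the unweighted
# mean of member scores -- AUC-equivalent to the plain sum while keeping
# fused scores in [0,1] at every level of the tree. Fusion is applied
# bottom-up: slices first, then (approach, gap) configurations, then
# backends (Method #2); or across the two SVM pipelines (Method #1).

#' Fuse member score vectors by the sum rule
#'
#' @param score_sets List of named numeric vectors, one per ensemble member,
#'   all over the same subjects with scores in `[0,1]`.
#' @return Named fused score vector (member mean, order-invariant).
#' @export
sum_rule <- function(score_sets) {
  if (length(score_sets) < 1L) stop("need at least one member")
  ref <- names(score_sets[[1]])
  if (is.null(ref)) stop("member scores must be named by subject")
  for (s in score_sets) {
    if (!setequal(names(s), ref))
      stop("ensemble members score different subject sets")
    if (any(s < -1e-9 | s > 1 + 1e-9))
      stop("member scores must lie in [0,1]")
  }
  mat <- vapply(score_sets, function(s) s[ref], numeric(length(ref)))
  if (length(ref) == 1L) mat <- matrix(mat, nrow = 1)
  stats::setNames(rowMeans(mat), ref)
}

#' Restrict a cohort to a subset of subjects
#'
#' @param cohort A cohort list.
#' @param idx Integer (or logical) subject index.
#' @return A cohort list over the selected subjects.
#' @export
cohort_subset <- function(cohort, idx) {
  list(volumes = cohort$volumes[idx], labels = cohort$labels[idx],
       classes = cohort$classes, subject_ids = cohort$subject_ids[idx])
}

#' Build Method #1: fusion of two conventional-ML SVM pipelines
#'
#' Trains two members on flattened voxel features -- Aggregate Selection +
#' SVM and kernel PLS + SVM -- and fuses their probability outputs by the sum
#' rule.
#'
#' @param cohort Training cohort (see [read_cohort()] / [make_cohort()]).
#' @param as_k Features kept by Aggregate Selection (default 200).
#' @param kpls_h Kernel-PLS components (default 10, capped at N-2).
#' @param kernel Kernel for the kPLS member (default `"gaussian"`).
#' @param C SVM cost (one value; the nested-CV harness owns any grid).
#' @param crop_k Optional central-slice crop applied before flattening.
#' @param members Subset of `c("as", "kpls")` to include.
#' @param seed Integer seed.
#' @return A `method1_model` with `predict(cohort) -> named scores` plus the
#'   per-member models; `predict_members()` exposes member-level scores.
#' @export
build_method1 <- function(cohort, as_k = 200L, kpls_h = 10L,
                          kernel = "gaussian", C = 1, crop_k = NULL,
                          members = c("as", "kpls"), seed = 1L,
                          reductions = NULL) {
  members <- match.arg(members, several.ok = TRUE)
  if (is.null(reductions))
    reductions <- method1_reductions(cohort, as_k = as_k, kpls_h = kpls_h,
                                     kernel = kernel, crop_k = crop_k,
                                     members = members, seed = seed)
  fm <- reductions$fm
  seeds <- derive_seeds(seed, 4L)
  mods <- list()
  if ("as" %in% members) {
    sel <- reductions$sel
    svm_as <- train_svm(fm$X[, sel$index, drop = FALSE], y = fm$y, C = C,
                        seed = seeds[2])
    mods$as <- list(sel = sel, svm = svm_as)
  }
  if ("kpls" %in% members) {
    svm_kp <- train_svm(reductions$kpls$T, y = fm$y, C = C, seed = seeds[3])
    mods$kpls <- list(kpls = reductions$kpls, svm = svm_kp)
  }
  structure(list(members = mods, crop_k = crop_k, C = C, seed = seed),
            class = "method1_model")
}

#' Precompute the feature-reduction stage of Method #1
#'
#' The reductions (Aggregate Selection, kernel PLS) depend only on the
#' training cohort and seed, never on the SVM cost, so inner-CV grids can
#' reuse them across `C` values. [build_method1()] accepts the result via
#' its `reductions` argument.
#'
#' @inheritParams build_method1
#' @return List with `fm`, `sel` (when `"as"` requested) and `kpls` (when
#'   `"kpls"` requested).
#' @export
method1_reductions <- function(cohort, as_k = 200L, kpls_h = 10L,
                               kernel = "gaussian", crop_k = NULL,
                               members = c("as", "kpls"), seed = 1L) {
  members <- match.arg(members, several.ok = TRUE)
  fm <- cohort_features(cohort, crop_k = crop_k)
  seeds <- derive_seeds(seed, 4L)
  out <- list(fm = fm)
  if ("as" %in% members)
    out$sel <- aggregate_select(fm, k = min(as_k, ncol(fm$X)),
                                seed = seeds[1])
  if ("kpls" %in% members) {
    h <- min(kpls_h, nrow(fm$X) - 2L)
    out$kpls <- suppressWarnings(kpls_fit(fm, h = h, kernel = kernel))
  }
  out
}

#' Member-level scores of a Method #1 model
#' @param model A `method1_model`.
#' @param cohort Cohort to score.
#' @return Named list of named score vectors, one per member.
#' @export
predict_members_method1 <- function(model, cohort) {
  fm <- cohort_features(cohort, crop_k = model$crop_k)
  out <- list()
  if (!is.null(model$members$as))
    out$as <- stats::setNames(
      predict_svm(model$members$as$svm,
                  fm$X[, model$members$as$sel$index, drop = FALSE]),
      fm$subject_ids)
  if (!is.null(model$members$kpls))
    out$kpls <- stats::setNames(
      predict_svm(model$members$kpls$svm,
                  kpls_transform(model$members$kpls$kpls, fm$X)),
      fm$subject_ids)
  out
}

#' @export
predict.method1_model <- function(object, cohort, ...) {
  sum_rule(predict_members_method1(object, cohort))
}

#' Build Method #2: per-slice ensemble over approaches, gaps and backends
#'
#' For every backend and every (approach, gap) configuration, one per-slice
#' model is trained per anchor slice; scores are fused bottom-up by the sum
#' rule: slices -> configuration -> backend -> final.
#'
#' @param cohort Training cohort.
#' @param approaches Decomposition approaches (default `c("A","B","C","D")`).
#' @param gaps Gap values (default `0:2`).
#' @param backends List of [slice_backend()]s (default the desk `"lin"`).
#' @param stride Anchor stride override (default: gap-dependent,
#'   non-overlapping; see [decomp_config()]).
#' @param crop_k Optional central-slice crop before decomposition.
#' @param seed Integer seed.
#' @return A `method2_model` with a fusion tree of slice models.
#' @export
build_method2 <- function(cohort, approaches = c("A", "B", "C", "D"),
                          gaps = 0:2, backends = list(slice_backend("lin")),
                          stride = NULL, crop_k = NULL, seed = 1L) {
  if (!is.null(crop_k)) {
    cohort <- cohort_subset(cohort, seq_along(cohort$volumes))
    cohort$volumes <- lapply(cohort$volumes, crop_inner, k = crop_k)
  }
  labels <- stats::setNames(cohort$labels, cohort$subject_ids)
  if (is.null(names(backends)))
    names(backends) <- vapply(backends, function(b) b$name, character(1))
  tree <- list()
  seeds <- derive_seeds(seed, length(backends) * length(approaches) *
                          length(gaps) * 10000L)
  si <- 0L
  for (bk in names(backends)) {
    tree[[bk]] <- list()
    for (ap in approaches) for (gp in gaps) {
      cfgname <- sprintf("%s|g%d", ap, gp)
      cfg <- decomp_config(approach = ap, gap = gp, stride = stride)
      groups <- decompose_cohort(cohort, cfg)
      tree[[bk]][[cfgname]] <- lapply(groups, function(g) {
        si <<- si + 1L
        train_slice_model(g, labels, backend = backends[[bk]],
                          seed = seeds[si])
      })
    }
  }
  structure(list(tree = tree, approaches = approaches, gaps = gaps,
                 stride = stride, crop_k = crop_k,
                 backends = backends, seed = seed),
            class = "method2_model")
}

#' Score a cohort with a Method #2 ensemble, level by level
#'
#' @param model A `method2_model`.
#' @param cohort Cohort to score (same volume shape as training).
#' @return List: `final` (named fused scores), `by_backend`, `by_config`
#'   (nested lists of fused scores at intermediate levels).
#' @export
predict_method2_tree <- function(model, cohort) {
  if (!is.null(model$crop_k))
    cohort$volumes <- lapply(cohort$volumes, crop_inner, k = model$crop_k)
  by_backend <- list(); by_config <- list()
  for (bk in names(model$tree)) {
    cfg_scores <- list()
    for (cfgname in names(model$tree[[bk]])) {
      parts <- strsplit(cfgname, "|g", fixed = TRUE)[[1]]
      cfg <- decomp_config(approach = parts[1], gap = as.integer(parts[2]),
                           stride = model$stride)
      groups <- decompose_cohort(cohort, cfg)
      slice_models <- model$tree[[bk]][[cfgname]]
      slice_scores <- lapply(names(slice_models), function(key) {
        if (is.null(groups[[key]]))
          stop("cohort lacks slice group ", key,
               " (shape mismatch with training?)")
        predict_slice_model(slice_models[[key]], groups[[key]])
      })
      cfg_scores[[cfgname]] <- sum_rule(slice_scores)
    }
    by_config[[bk]] <- cfg_scores
    by_backend[[bk]] <- sum_rule(cfg_scores)
  }
  list(final = sum_rule(by_backend), by_backend = by_backend,
       by_config = by_config)
}

#' @export
predict.method2_model <- function(object, cohort, ...) {
  predict_method2_tree(object, cohort)$final
}
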