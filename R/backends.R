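# Pluggable 2D slice-classifier backends. Every backend implements the same
# contract -- train(X, y, seed) returning an object whose score(X) maps
# flattened RGB-like band matrices to [0,1] -- so deep fine-tuned networks
# and the lightweight desk backends are interchangeable behind the per-slice
# ensemble machinery. Resizing to a native input size (e.g. 227 x 227 for
# pretrained nets) is a backend's own responsibility.

#' Define a slice-classifier backend
#'
#' Built-in backends:
#' \describe{
#'   \item{`"lin"`}{Regularized linear discriminant scorer on flattened
#'     bands: features standardized by training statistics, direction =
#'     class-mean difference, Platt-scaled decision value. Deterministic,
#'     fast enough for hundreds of per-slice models.}
#'   \item{`"svm"`}{Linear SVM ([train_svm()]) on flattened bands.}
#'   \item{`"ridge"`}{Ridge-penalized logistic regression (glmnet).}
#' }
#' Custom backends supply `train` directly.
#'
#' @param name Backend name.
#' @param train Optional custom `function(X, y, seed)` returning a list with
#'   a `score(X)` function mapping rows to `[0,1]`.
#' @param epochs,learning_rate,minibatch Training hyperparameters recorded in
#'   the spec (used by iterative backends; the paper-style defaults are a
#'   learning rate of 1e-4 and mini-batches of 30 observations, with
#'   convergence within a 20-epoch cap).
#' @param input_size Optional native input size contract (height, width).
#' @return A `slice_backend` object.
#' @export
slice_backend <- function(name = c("lin", "svm", "ridge"), train = NULL,
                          epochs = 20L, learning_rate = 1e-4,
                          minibatch = 30L, input_size = NULL) {
  if (is.null(train)) {
    name <- match.arg(name)
    train <- switch(name,
      lin = .backend_train_lin,
      svm = function(X, y, seed) {
        m <- train_svm(X, y = y, C = 1, seed = seed)
        list(score = function(Xn) predict_svm(m, Xn))
      },
      ridge = .backend_train_ridge)
  } else name <- as.character(name)
  structure(list(name = name, train = train, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 minibatch = as.integer(minibatch), input_size = input_size),
            class = "slice_backend")
}

.backend_train_lin <- function(X, y, seed = 1L) {
  mu <- colMeans(X)
  sdv <- col_sds(X)
  sdv[sdv < 1e-8] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  w <- colMeans(Z[y == 1L, , drop = FALSE]) -
       colMeans(Z[y == 0L, , drop = FALSE])
  nw <- sqrt(sum(w^2))
  if (nw > 1e-12) w <- w / nw
  proj <- function(Xn)
    as.numeric(sweep(sweep(Xn, 2, mu), 2, sdv, "/") %*% w)
  f <- proj(X)
  if (stats::sd(f) < 1e-12) {
    p0 <- mean(y)                     # uninformative input: prevalence score
    return(list(score = function(Xn) rep(p0, nrow(Xn))))
  }
  platt <- .platt_fit(f, y)
  list(score = function(Xn) {
    z <- platt["A"] * proj(Xn) + platt["B"]
    unname(.sigmoid(-z))
  })
}

.backend_train_ridge <- function(X, y, seed = 1L) {
  # suppressWarnings: glmnet flags small class counts at desk scale
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                   lambda = c(10, 1, 0.1), standardize = TRUE))
  list(score = function(Xn)
    as.numeric(stats::predict(fit, Xn, s = 1, type = "response")))
}

.flatten_images <- function(group) {
  t(vapply(group, function(im) as.numeric(im$bands),
           numeric(length(group[[1]]$bands))))
}

#' Train one per-slice model
#'
#' Trains a backend on the RGB-like images of one slice group -- images of
#' different subjects sharing the same `(approach, gap, n)` key, hence (by
#' co-registration) the same anatomical content. A model never sees images
#' from other slice keys.
#'
#' @param group List of `rgb_like` images, one per subject, single key.
#' @param labels Named 0/1 vector (names = subject ids) or vector aligned
#'   with `group`.
#' @param backend A [slice_backend()].
#' @param seed Integer seed forwarded to the backend.
#' @return A `slice_model` with the key, backend name and a
#'   `score(images)` function returning named scores in `[0,1]`.
#' @export
train_slice_model <- function(group, labels, backend = slice_backend("lin"),
                              seed = 1L) {
  keys <- unique(vapply(group, function(im) im$key, character(1)))
  if (length(keys) != 1L)
    stop("mixed slice keys in one training group: ",
         paste(keys, collapse = ", "))
  subj <- vapply(group, function(im) im$subject_id, character(1))
  if (anyDuplicated(subj)) stop("duplicate subject in slice group")
  y <- if (!is.null(names(labels))) labels[subj] else labels
  if (anyNA(y) || length(y) != length(group))
    stop("labels do not cover the group's subjects")
  X <- .flatten_images(group)
  fitted <- backend$train(X, as.integer(y), seed)
  structure(list(key = keys, backend = backend$name, fitted = fitted,
                 n_features = ncol(X)),
            class = "slice_model")
}

#' Score RGB-like images with a per-slice model
#'
#' @param model A `slice_model`.
#' @param images List of `rgb_like` images with the model's key.
#' @return Named numeric vector of scores in `[0,1]`.
#' @export
predict_slice_model <- function(model, images) {
  keys <- vapply(images, function(im) im$key, character(1))
  if (any(keys != model$key))
    stop("images do not match model key ", model$key)
  X <- .flatten_images(images)
  s <- model$fitted$score(X)
  s <- pmin(pmax(s, 0), 1)
  stats::setNames(s, vapply(images, function(im) im$subject_id, character(1)))
}
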