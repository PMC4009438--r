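#' Fit a two-class Fisher linear discriminant
#'
#' From-scratch LDA with pooled within-class covariance:
#' `w = Sigma_pooled^-1 (mu_1 - mu_0)` and bias placing the boundary at the
#' midpoint of the projected class means, shifted by the log prior ratio.
#' Decisions are `sign(w . x + b)`: positive scores go to the second class
#' level, zero scores (ties) to the first. By convention the first level is
#' the rest/"Stop" class, so ambiguity produces no movement; factor labels
#' are used as given, otherwise `"rest"`/`"Stop"` is forced to be first when
#' present.
#'
#' If the pooled covariance is numerically singular a ridge
#' `1e-6 * trace(Sigma)/p` is added to its diagonal.
#'
#' @param data A data frame / tibble of numeric features, or a matrix.
#' @param labels A vector with exactly two distinct values, length
#'   `nrow(data)`.
#' @return An object of class `bci_lda`: list with `w`, `b`, `means`,
#'   `cov_pooled`, `levels`, `priors`, `features`.
#' @examples
#' d <- data.frame(x = c(rnorm(20), rnorm(20, 3)), y = c(rnorm(20), rnorm(20, 3)))
#' fit <- fit_lda(d, rep(c("rest", "left"), each = 20))
#' predict(fit, d)
#' @export
fit_lda <- function(data, labels) {
  x <- as.matrix(data)
  if (!is.numeric(x) || ncol(x) < 1) {
    stop("`data` must contain at least one numeric feature.", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("Features must be finite.", call. = FALSE)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("Exactly two classes are required.", call. = FALSE)
  rest_like <- lev[tolower(lev) %in% c("rest", "stop")]
  lev <- if (length(rest_like) == 1) c(rest_like, setdiff(lev, rest_like))
         else sort(lev)
  y <- match(labels, lev) - 1L           # 0 = rest-like class
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 < 2 || n1 < 2) {
    stop("Each class needs at least 2 samples (got ", n0, " and ", n1, ").",
         call. = FALSE)
  }
  p <- ncol(x)
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  c0 <- stats::cov(x[y == 0L, , drop = FALSE])
  c1 <- stats::cov(x[y == 1L, , drop = FALSE])
  S <- ((n0 - 1) * c0 + (n1 - 1) * c1) / (n0 + n1 - 2)
  if (sum(diag(S)) <= 0) {
    stop("Degenerate model: all features are identical within classes.",
         call. = FALSE)
  }
  ridge <- 1e-6 * sum(diag(S)) / p
  w <- tryCatch(solve(S, mu1 - mu0),
                error = function(e) solve(S + diag(ridge, p), mu1 - mu0))
  if (!all(is.finite(w)) || sqrt(sum(w^2)) < .Machine$double.eps) {
    stop("Degenerate model: class means coincide.", call. = FALSE)
  }
  priors <- c(n0, n1) / (n0 + n1)
  b <- -sum(w * (mu0 + mu1)) / 2 + log(priors[2] / priors[1])
  structure(list(w = w, b = b,
                 means = rbind(mu0, mu1),
                 cov_pooled = S,
                 levels = lev, priors = priors,
                 features = colnames(x) %||% paste0("x", seq_len(p))),
            class = "bci_lda")
}

#' Predict with a fitted linear discriminant
#'
#' @param object A `bci_lda` fit.
#' @param newdata Data frame or matrix with the model's features.
#' @param ... Unused.
#' @return A tibble with `.class` (predicted label) and `.score`
#'   (discriminant value `w . x + b`; positive means the second class, and
#'   exact zeros resolve to the first, rest-like class).
#' @export
predict.bci_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$w)) {
    stop("Feature dimension mismatch: model has ", length(object$w),
         ", data has ", ncol(x), ".", call. = FALSE)
  }
  score <- as.numeric(x %*% object$w) + object$b
  tibble::tibble(.class = object$levels[ifelse(score > 0, 2L, 1L)],
                 .score = score)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a linear discriminant fit
#'
#' @param x A `bci_lda` object.
#' @param ... Unused.
#' @return A tibble with one row per term (`(bias)` plus one per feature) and
#'   its `estimate`.
#' @method tidy bci_lda
#' @export
tidy.bci_lda <- function(x, ...) {
  tibble::tibble(term = c("(bias)", x$features),
                 estimate = c(x$b, unname(x$w)))
}

#' @rdname tidy.bci_lda
#' @return `glance()` returns a one-row tibble with the model dimensions,
#'   class labels and priors.
#' @method glance bci_lda
#' @export
glance.bci_lda <- function(x, ...) {
  tibble::tibble(n_features = length(x$w),
                 class_rest = x$levels[1], class_active = x$levels[2],
                 prior_rest = x$priors[1], prior_active = x$priors[2])
}

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class and assigned by a seeded shuffle, so results
#' are deterministic given `seed`. Accuracy is the pooled percentage of
#' correct test predictions across folds.
#'
#' @param data Feature data frame / matrix.
#' @param labels Two-class label vector.
#' @param k Number of folds (>= 2, <= n).
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `bci_cv`: `accuracy` (percent), `folds` (tibble
#'   with per-fold `n_test` and `accuracy`), `k`, `seed`.
#' @export
cross_validate <- function(data, labels, k = 5, seed = 1) {
  x <- as.matrix(data)
  n <- nrow(x)
  if (k < 2 || k > n) stop("Need 2 <= k <= n.", call. = FALSE)
  labels <- as.character(labels)
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  res <- purrr::map_dfr(seq_len(k), function(f) {
    te <- fold == f
    if (!any(te) || length(unique(labels[!te])) < 2) {
      return(tibble::tibble(fold = f, n_test = 0L, accuracy = NA_real_))
    }
    fit <- fit_lda(x[!te, , drop = FALSE], labels[!te])
    pred <- predict(fit, x[te, , drop = FALSE])$.class
    tibble::tibble(fold = f, n_test = sum(te),
                   accuracy = 100 * mean(pred == labels[te]))
  })
  ok <- !is.na(res$accuracy)
  acc <- 100 * sum(res$accuracy[ok] / 100 * res$n_test[ok]) / sum(res$n_test[ok])
  structure(list(accuracy = acc, folds = res, k = k, seed = seed),
            class = "bci_cv")
}

#' @method glance bci_cv
#' @export
glance.bci_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, k = x$k,
                 n = sum(x$folds$n_test), seed = x$seed)
}

#' @export
print.bci_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated accuracy: %.1f%% (n = %d)\n",
              x$k, x$accuracy, sum(x$folds$n_test)))
  invisible(x)
}

#' Serialize / restore a linear discriminant as JSON
#'
#' @param model A `bci_lda` fit (or named list of fits for `write_models()`).
#' @param path JSON file path.
#' @return `read_models()` returns the model (or named list) with classes
#'   restored.
#' @export
write_models <- function(model, path) {
  strip <- function(m) {
    if (inherits(m, "bci_lda")) {
      list(type = "bci_lda", w = unname(m$w), b = m$b,
           means = unname(m$means), cov_pooled = unname(m$cov_pooled),
           levels = m$levels, priors = m$priors, features = m$features)
    } else if (is.list(m)) lapply(m, strip) else m
  }
  jsonlite::write_json(strip(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  if (!file.exists(path)) stop("Model file not found: ", path, call. = FALSE)
  restore <- function(m) {
    if (is.list(m) && identical(m$type, "bci_lda")) {
      w <- unlist(m$w); names(w) <- unlist(m$features)
      structure(list(w = w, b = m$b,
                     means = do.call(rbind, lapply(m$means, unlist)),
                     cov_pooled = do.call(rbind, lapply(m$cov_pooled, unlist)),
                     levels = unlist(m$levels), priors = unlist(m$priors),
                     features = unlist(m$features)),
                class = "bci_lda")
    } else if (is.list(m)) lapply(m, restore) else m
  }
  restore(jsonlite::read_json(path, simplifyVector = FALSE))
}
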