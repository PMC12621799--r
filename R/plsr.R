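#' Column z-scoring of an observations-by-variables block
#'
#' Centres and scales each variable (column) across the condition rows to
#' mean 0 and unit sample variance (n - 1 denominator). Variables with zero
#' variance carry no cross-condition information and are dropped with a
#' warning.
#'
#' @param m numeric matrix, conditions in rows, variables in columns.
#' @return Matrix of the same orientation with zero-variance columns
#'   removed.
#' @export
zscore_block <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2L) {
    stop("z-scoring needs a matrix with at least 2 condition rows",
         call. = FALSE)
  }
  sds <- apply(m, 2L, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance column(s): ",
            paste(utils::head(colnames(m)[drop], 5L), collapse = ", "),
            call. = FALSE)
    m <- m[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Fit a partial least squares regression by SIMPLS
#'
#' Finds latent components that maximize the covariance between the
#' predictor block X (protein responses) and the response block Y
#' (phenotypic outputs), using the SIMPLS formulation: each component's
#' weight vector is the dominant left singular vector of the running
#' cross-product matrix, which is then deflated against an orthonormal
#' basis of the X-loadings. Score columns come out orthonormal, and the
#' per-component explained variances for X and Y are exact partitions of
#' each block's total sum of squares.
#'
#' @param X conditions x predictors matrix (z-score beforehand; columns are
#'   centred internally in any case).
#' @param Y conditions x responses matrix.
#' @param n_components number of latent components, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return A `plsr_model`: `x_weights` (R), `x_loadings` (P), `y_loadings`
#'   (Q), `scores` (orthonormal T), `coefficients` (for centred data),
#'   `r2x`/`r2y` per-component and `r2x_cum`/`r2y_cum` cumulative explained
#'   variance, plus centring means.
#' @export
fit_plsr <- function(X, Y, n_components = 2L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y need matching rows", call. = FALSE)
  if (n < 2L) stop("need at least 2 condition rows", call. = FALSE)
  a_max <- min(n - 1L, ncol(X))
  if (n_components > a_max) {
    stop("n_components must be <= min(rows - 1, predictors) = ", a_max,
         call. = FALSE)
  }
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  Xc <- sweep(X, 2L, x_mean)
  Yc <- sweep(Y, 2L, y_mean)
  ssx <- sum(Xc^2)
  ssy <- sum(Yc^2)
  if (ssx == 0) stop("degenerate input: X has no variance", call. = FALSE)

  A <- n_components
  R <- matrix(0, ncol(X), A) # X weights (applied to centred X)
  P <- matrix(0, ncol(X), A) # X loadings
  Q <- matrix(0, ncol(Y), A) # Y loadings
  TT <- matrix(0, n, A)      # orthonormal scores
  V <- matrix(0, ncol(X), A) # orthonormal basis for deflation
  S <- crossprod(Xc, Yc)
  s_ref <- NA_real_
  used <- A
  for (a in seq_len(A)) {
    sv <- svd(S, nu = 1L, nv = 0L)
    if (a == 1L) s_ref <- max(sv$d[1L], .Machine$double.eps)
    if (sv$d[1L] < 1e-10 * s_ref) { used <- a - 1L; break }
    r <- sv$u[, 1L]
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < .Machine$double.eps^0.5) { used <- a - 1L; break }
    t <- t / nt
    r <- r / nt
    p <- crossprod(Xc, t)
    q <- crossprod(Yc, t)
    v <- p
    if (a > 1L) {
      v <- v - V[, 1:(a - 1L), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1L), drop = FALSE], p)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- p; Q[, a] <- q; TT[, a] <- t; V[, a] <- v
  }
  if (used < A) {
    warning("cross-covariance exhausted after ", used,
            " component(s); truncating", call. = FALSE)
    keep <- seq_len(used)
    R <- R[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    Q <- Q[, keep, drop = FALSE]; TT <- TT[, keep, drop = FALSE]
  }
  r2x <- colSums(P^2) / ssx
  r2y <- colSums(Q^2) / ssy
  dimnames(R) <- dimnames(P) <- list(colnames(X), NULL)
  dimnames(Q) <- list(colnames(Y), NULL)
  rownames(TT) <- rownames(X)
  structure(
    list(
      n_components = ncol(TT),
      x_weights = R, x_loadings = P, y_loadings = Q, scores = TT,
      coefficients = R %*% t(Q),
      x_mean = x_mean, y_mean = y_mean,
      r2x = r2x, r2y = r2y,
      r2x_cum = cumsum(r2x), r2y_cum = cumsum(r2y),
      q2 = NULL
    ),
    class = "plsr_model"
  )
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d component(s), %d predictors -> %d responses\n",
              x$n_components, nrow(x$x_loadings), nrow(x$y_loadings)))
  cat("  cumulative R2Y:", paste(sprintf("%.3f", x$r2y_cum), collapse = " "),
      "\n")
  if (!is.null(x$q2)) {
    cat("  cumulative Q2: ", paste(sprintf("%.3f", x$q2$q2), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Predict responses from a fitted model
#'
#' @param object a `plsr_model`.
#' @param newdata predictor matrix on the training scale.
#' @param n_components number of components to use (default: all fitted).
#' @param ... unused.
#' @return Predicted response matrix.
#' @export
predict.plsr_model <- function(object, newdata,
                               n_components = object$n_components, ...) {
  stopifnot(n_components >= 1L, n_components <= object$n_components)
  k <- seq_len(n_components)
  B <- object$x_weights[, k, drop = FALSE] %*%
    t(object$y_loadings[, k, drop = FALSE])
  Xc <- sweep(as.matrix(newdata), 2L, object$x_mean)
  sweep(Xc %*% B, 2L, object$y_mean, "+")
}

#' Leave-one-out cross-validated predictive ability (Q2)
#'
#' Each condition row is left out in turn; the model refit on the remaining
#' rows predicts it. Q2 = 1 - PRESS / TSS, with TSS accumulated against the
#' training-fold response means, reported cumulatively per component count.
#' To keep the inner fits well-posed the component count is capped at
#' `nrow - 2`.
#'
#' @param X,Y data blocks as in [fit_plsr()] (>= 3 rows).
#' @param n_components maximum components to evaluate.
#' @return data.frame with columns `n_components`, `press`, `q2`.
#' @export
loo_q2 <- function(X, Y, n_components = 2L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out Q2 needs at least 3 rows", call. = FALSE)
  a_max <- min(n_components, n - 2L, ncol(X))
  press <- numeric(a_max)
  tss <- 0
  for (i in seq_len(n)) {
    fit <- fit_plsr(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                    n_components = a_max)
    tss <- tss + sum((Y[i, ] - colMeans(Y[-i, , drop = FALSE]))^2)
    for (a in seq_len(a_max)) {
      a_use <- min(a, fit$n_components)
      pred <- predict(fit, X[i, , drop = FALSE], n_components = a_use)
      press[a] <- press[a] + sum((Y[i, ] - pred)^2)
    }
  }
  data.frame(n_components = seq_len(a_max), press = press,
             q2 = 1 - press / tss)
}

#' k-means clustering of protein loadings in the latent plane
#'
#' Clusters each predictor's loading vector restricted to the first two
#' latent components (the plotted biplot plane), using k-means++ seeding
#' followed by Lloyd iteration. Deterministic given `seed`.
#'
#' @param model a fitted `plsr_model` with >= 2 components.
#' @param k number of clusters (<= number of predictors).
#' @param seed RNG seed for centroid seeding.
#' @return List: `k`, `assignment` (named integer vector, labels 1..k),
#'   `centroids` (k x 2), `seed`.
#' @export
kmeans_loadings <- function(model, k, seed = 1L) {
  stopifnot(inherits(model, "plsr_model"))
  if (model$n_components < 2L) {
    stop("need at least 2 fitted components for the loading plane",
         call. = FALSE)
  }
  L <- model$x_loadings[, 1:2, drop = FALSE]
  if (k > nrow(L)) stop("k exceeds the number of predictors", call. = FALSE)
  set.seed(seed)
  centers <- kmeanspp_centers(L, k)
  km <- stats::kmeans(L, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd")
  list(
    k = k,
    assignment = stats::setNames(km$cluster, rownames(L)),
    centroids = km$centers,
    seed = as.integer(seed)
  )
}

# k-means++ seeding: first centre uniform, then points picked with
# probability proportional to squared distance from the nearest centre.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
  }
  # duplicate centres break stats::kmeans; nudge any collisions apart
  dup <- duplicated(centers)
  if (any(dup)) {
    spread <- max(apply(X, 2L, function(col) diff(range(col))), 1e-8)
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      matrix(stats::rnorm(sum(dup) * ncol(X), 0, 1e-6 * spread),
             ncol = ncol(X))
  }
  centers
}

#' Alignment of each predictor with a phenotype in the latent plane
#'
#' The alignment score of a predictor with a phenotype is the cosine
#' similarity between the predictor's loading vector and the phenotype's
#' response-block loading vector, both restricted to the first two latent
#' components: +1 for loadings pointing the same way in the biplot, -1 for
#' opposite, 0 for orthogonal.
#'
#' @param model a fitted `plsr_model` with >= 2 components.
#' @param phenotype response column name present in the Y loadings.
#' @return Named numeric vector of scores in `[-1, 1]`; predictors with a
#'   zero-length loading vector get NA with a warning.
#' @export
alignment_scores <- function(model, phenotype) {
  stopifnot(inherits(model, "plsr_model"))
  if (model$n_components < 2L) {
    stop("need at least 2 fitted components", call. = FALSE)
  }
  if (!phenotype %in% rownames(model$y_loadings)) {
    stop("unknown phenotype '", phenotype, "'", call. = FALSE)
  }
  L <- model$x_loadings[, 1:2, drop = FALSE]
  v <- model$y_loadings[phenotype, 1:2]
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("phenotype '", phenotype, "' has a zero loading vector",
                    call. = FALSE)
  nl <- sqrt(rowSums(L^2))
  score <- as.numeric(L %*% v) / (nl * nv)
  if (any(nl == 0)) {
    warning(sum(nl == 0), " predictor(s) with zero loading; score set NA",
            call. = FALSE)
    score[nl == 0] <- NA_real_
  }
  stats::setNames(score, rownames(L))
}

#' Per-output agreement between observed and fitted responses
#'
#' Squared Pearson correlation between the observed and fitted values of
#' one (or every) response column.
#'
#' @param model a fitted `plsr_model`.
#' @param X,Y the data blocks the model was fit on.
#' @param output response column name, or NULL for all.
#' @return Named numeric vector of per-output R^2; NA (with a warning) for
#'   constant observed columns.
#' @export
observed_vs_fitted <- function(model, X, Y, output = NULL) {
  Y <- as.matrix(Y)
  fitted <- predict(model, X)
  outs <- if (is.null(output)) colnames(Y) else output
  if (!all(outs %in% colnames(Y))) {
    stop("unknown output(s): ",
         paste(setdiff(outs, colnames(Y)), collapse = ", "), call. = FALSE)
  }
  r2 <- vapply(outs, function(o) {
    obs <- Y[, o]
    if (stats::sd(obs) == 0 || stats::sd(fitted[, o]) == 0) {
      return(NA_real_)
    }
    stats::cor(obs, fitted[, o])^2
  }, numeric(1L))
  if (anyNA(r2)) {
    warning("constant observed or fitted values for: ",
            paste(outs[is.na(r2)], collapse = ", "), call. = FALSE)
  }
  r2
}
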