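#' PCA of a dosage matrix
#'
#' Missing dosages are mean-imputed per locus, columns are centered, and
#' the matrix is decomposed by SVD. Scores are left singular vectors scaled
#' by the singular values. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param g a [dosage_matrix] or a plain numeric matrix (rows = accessions).
#' @param n_components number of components to retain.
#' @return object of class `pca_basis`: list with `scores`, `loadings`,
#'   `explained` (variance fractions for all components), `center`,
#'   `n_retained`.
#' @export
pca_dosage <- function(g, n_components) {
  X <- if (inherits(g, "dosage_matrix")) g$dosage else as.matrix(g)
  mode(X) <- "double"
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- cm[j]
  stop_if(n_components > min(dim(X)),
          "n_components exceeds min(n_accessions, n_loci)")
  Xc <- sweep(X, 2, colMeans(X), `-`)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  # deterministic sign: largest-|loading| positive per component
  for (k in seq_len(n_components)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores, loadings = sv$v,
                 explained = sv$d^2 / sum(sv$d^2),
                 center = colMeans(X), n_retained = n_components),
            class = "pca_basis")
}

#' K-means clustering with BIC model selection
#'
#' For K = 1..k_max, runs best-of-`n_restarts` K-means on the score matrix
#' and evaluates `BIC(K) = n ln(WSS_K / n) + K ln(n)`. The full BIC curve
#' is returned along with the argmin; local-valley inspection is left to
#' the caller. Reproducible under a fixed seed.
#'
#' @param scores numeric matrix (e.g. retained PC scores).
#' @param k_max largest K to evaluate (K > n is skipped).
#' @param n_restarts random restarts per K.
#' @param seed integer seed.
#' @return list with `bic` (data.frame K/WSS/BIC), `best_k`, and
#'   `assignments` (list of cluster vectors per K).
#' @export
kmeans_bic <- function(scores, k_max = 10, n_restarts = 10, seed = 1) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  ks <- seq_len(min(k_max, n))
  wss <- numeric(length(ks))
  assignments <- vector("list", length(ks))
  local_seed(seed, {
    for (i in seq_along(ks)) {
      K <- ks[i]
      if (K == 1) {
        wss[i] <- sum(scale(scores, scale = FALSE)^2)
        assignments[[i]] <- rep(1L, n)
      } else if (K == n) {
        wss[i] <- 0
        assignments[[i]] <- seq_len(n)
      } else {
        km <- suppressWarnings(
          kmeans(scores, centers = K, nstart = n_restarts, iter.max = 100))
        wss[i] <- km$tot.withinss
        assignments[[i]] <- km$cluster
      }
    }
  })
  bic <- ifelse(wss > 0, n * log(wss / n), -Inf) + ks * log(n)
  names(assignments) <- ks
  list(bic = data.frame(K = ks, WSS = wss, BIC = bic),
       best_k = ks[which.min(bic)],
       assignments = assignments)
}

# linear discriminant solver with shared within-class covariance and an
# automatic ridge for singular scatter; returns axes, class means, and the
# pieces needed for Gaussian posteriors
fit_lda <- function(X, labels) {
  X <- as.matrix(X)
  f <- factor(labels)
  k <- nlevels(f)
  n <- nrow(X); p <- ncol(X)
  stop_if(any(table(f) < 2), "every cluster needs >= 2 members")
  means <- do.call(rbind, lapply(levels(f), function(l)
    colMeans(X[f == l, , drop = FALSE])))
  rownames(means) <- levels(f)
  W <- matrix(0, p, p)
  for (l in levels(f)) {
    Xl <- sweep(X[f == l, , drop = FALSE], 2, means[l, ], `-`)
    W <- W + crossprod(Xl)
  }
  W <- W / (n - k)
  if (rcond(W) < 1e-10) {
    W <- W + diag(1e-8 * sum(diag(W)), p)
    message("singular within-class scatter; ridge added")
  }
  gm <- colMeans(X)
  B <- matrix(0, p, p)
  for (l in levels(f)) {
    dm <- means[l, ] - gm
    B <- B + sum(f == l) * tcrossprod(dm)
  }
  B <- B / (n - 1)
  R <- chol(W)
  A <- backsolve(R, t(backsolve(R, t(B), transpose = TRUE)), transpose = TRUE)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  n_axes <- min(k - 1, p, sum(e$values > 1e-10))
  axes <- backsolve(R, e$vectors[, seq_len(n_axes), drop = FALSE])
  colnames(axes) <- paste0("LD", seq_len(n_axes))
  list(means = means, W = W, axes = axes, priors = as.vector(table(f)) / n,
       levels = levels(f), eigenvalues = e$values[seq_len(n_axes)])
}

# Gaussian posteriors under the shared-covariance class model
lda_posterior <- function(fit, X) {
  X <- as.matrix(X)
  R <- chol(fit$W)
  logd <- vapply(seq_along(fit$levels), function(l) {
    Z <- backsolve(R, t(sweep(X, 2, fit$means[l, ], `-`)), transpose = TRUE)
    -0.5 * colSums(Z^2) + log(fit$priors[l])
  }, numeric(nrow(X)))
  logd <- matrix(logd, nrow = nrow(X))
  mx <- apply(logd, 1, max)
  Q <- exp(logd - mx)
  Q <- Q / rowSums(Q)
  colnames(Q) <- fit$levels
  rownames(Q) <- rownames(X)
  Q
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant analysis on the first `n_pc` PC scores with the
#' given cluster labels: discriminant axes (at most K - 1), accession
#' coordinates, and a posterior membership matrix Q from the Gaussian
#' class model with shared within-class covariance. Singular within-class
#' scatter is handled by a small logged ridge.
#'
#' @param pca a `pca_basis` (or a plain score matrix).
#' @param labels cluster labels, one per accession (each level >= 2 members).
#' @param n_pc number of leading PCs to use.
#' @return object of class `dapc_model`: list with `coords`, `Q`,
#'   `loadings` (axes in PC space), `labels`, `n_pc`, `fit`.
#' @export
dapc_fit <- function(pca, labels, n_pc) {
  scores <- if (inherits(pca, "pca_basis")) pca$scores else as.matrix(pca)
  stop_if(n_pc > ncol(scores), "n_pc exceeds available PCs")
  X <- scores[, seq_len(n_pc), drop = FALSE]
  fit <- fit_lda(X, labels)
  coords <- sweep(X, 2, colMeans(X), `-`) %*% fit$axes
  rownames(coords) <- rownames(X)
  Q <- lda_posterior(fit, X)
  structure(list(coords = coords, Q = Q, loadings = fit$axes,
                 labels = factor(labels), n_pc = n_pc, fit = fit),
            class = "dapc_model")
}

#' Predict DAPC posteriors for new score rows
#' @param object a `dapc_model`.
#' @param newdata matrix of PC scores (same basis, >= n_pc columns).
#' @param ... unused.
#' @return posterior membership matrix Q (rows sum to 1).
#' @export
predict.dapc_model <- function(object, newdata, ...) {
  lda_posterior(object$fit, newdata[, seq_len(object$n_pc), drop = FALSE])
}

#' Cross-validated choice of the number of retained PCs for DAPC
#'
#' Stratified repeated holdout: for each candidate `n_pc`, the model is
#' refit on a training split and evaluated on the held-out accessions.
#' Mean success is the fraction of held-out accessions assigned (argmax Q)
#' to their true cluster; MSE is the mean of `(1 - Q_true)^2`. The chosen
#' `n_pc` maximizes mean success, with ties broken by lowest MSE, then by
#' the smaller `n_pc`.
#'
#' @param pca a `pca_basis` or score matrix.
#' @param labels cluster labels.
#' @param grid candidate values of n_pc (values exceeding the available
#'   PCs are dropped with a warning).
#' @param n_rep number of holdout repetitions (> 0).
#' @param holdout held-out fraction per class.
#' @param seed integer seed.
#' @return list with `chosen`, and `summary` (per-n_pc mean success / MSE).
#' @export
dapc_select_npc <- function(pca, labels, grid, n_rep = 30, holdout = 0.1,
                            seed = 1) {
  stop_if(n_rep < 1, "n_rep must be >= 1")
  scores <- if (inherits(pca, "pca_basis")) pca$scores else as.matrix(pca)
  f <- factor(labels)
  drop <- grid > ncol(scores)
  if (any(drop)) {
    warning(sum(drop), " grid value(s) exceed available PCs; dropped")
    grid <- grid[!drop]
  }
  stop_if(length(grid) == 0, "empty n_pc grid")
  succ <- mse <- matrix(NA_real_, n_rep, length(grid))
  local_seed(seed, {
    for (r in seq_len(n_rep)) {
      test_idx <- unlist(lapply(levels(f), function(l) {
        idx <- which(f == l)
        n_out <- max(1L, floor(holdout * length(idx)))
        n_out <- min(n_out, length(idx) - 2L)  # keep >= 2 in training
        if (n_out < 1L) return(integer(0))
        sample(idx, n_out)
      }))
      if (length(test_idx) == 0) next
      train <- setdiff(seq_len(nrow(scores)), test_idx)
      for (gi in seq_along(grid)) {
        fit <- dapc_fit(scores[train, , drop = FALSE], f[train], grid[gi])
        Q <- predict(fit, scores[test_idx, , drop = FALSE])
        pred <- colnames(Q)[max.col(Q, ties.method = "first")]
        truth <- as.character(f[test_idx])
        succ[r, gi] <- mean(pred == truth)
        qt <- Q[cbind(seq_along(test_idx), match(truth, colnames(Q)))]
        mse[r, gi] <- mean((1 - qt)^2)
      }
    }
  })
  summ <- data.frame(n_pc = grid,
                     mean_success = colMeans(succ, na.rm = TRUE),
                     mean_mse = colMeans(mse, na.rm = TRUE))
  o <- order(-summ$mean_success, summ$mean_mse, summ$n_pc)
  list(chosen = summ$n_pc[o[1]], summary = summ)
}

#' Threshold posterior memberships into assignments
#'
#' An accession is assigned to its argmax cluster when the maximum
#' posterior reaches the threshold, and is called `"admixed"` otherwise.
#'
#' @param Q posterior membership matrix (rows sum to 1).
#' @param threshold assignment q-value threshold (default 0.65).
#' @return list with `assignment` (character vector), `fraction_assigned`.
#' @export
assign_by_q <- function(Q, threshold = 0.65) {
  Q <- as.matrix(Q)
  top <- max.col(Q, ties.method = "first")
  qmax <- Q[cbind(seq_len(nrow(Q)), top)]
  lab <- colnames(Q) %||% as.character(seq_len(ncol(Q)))
  assignment <- ifelse(qmax >= threshold, lab[top], "admixed")
  names(assignment) <- rownames(Q)
  list(assignment = assignment,
       fraction_assigned = mean(qmax >= threshold))
}
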