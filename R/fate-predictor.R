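#' Library-size normalization
#'
#' Counts per cell scaled to a common library size, then \code{log1p} — the
#' standard single-cell normalization assumed throughout the classifier.
#'
#' @param counts genes x cells matrix (dense or sparse).
#' @param scale_factor target library size (default 1e4).
#' @return matrix of the same shape.
#' @export
normalize_log1p <- function(counts, scale_factor = 1e4) {
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  x <- counts %*% Matrix::Diagonal(x = scale_factor / lib)
  x@x <- log1p(x@x)
  colnames(x) <- colnames(counts)
  x
}

#' Most variable genes
#'
#' Ranks genes by the variance of their log1p-normalized expression and
#' returns the top \code{n} (default 3,000), with deterministic ties broken
#' by gene id.
#'
#' @param counts genes x cells count matrix with gene rownames.
#' @param n number of genes to keep.
#' @return character vector of gene ids, most variable first.
#' @export
select_variable_genes <- function(counts, n = 3000) {
  stopifnot(n <= nrow(counts))
  x <- normalize_log1p(counts)
  nc <- ncol(x)
  mu <- Matrix::rowSums(x) / nc
  v <- (Matrix::rowSums(x^2) - nc * mu^2) / (nc - 1)
  ord <- order(-v, rownames(counts))
  rownames(counts)[ord][seq_len(n)]
}

#' Fit a balanced IN-vs-PN fate classifier
#'
#' L1-regularized logistic regression of cell class on scaled log-normalized
#' expression: classes are balanced by seeded downsampling of the majority
#' class, two-thirds of the balanced cells train the model (stratified, so
#' the training classes stay exactly equal) and the held-out third measures
#' validation accuracy. The penalty is chosen by cross-validation on the
#' training cells (\code{glmnet::cv.glmnet}, binomial family). The class
#' encoding is IN = 0, PN = 1, so positive coefficients mark PN-predictive
#' genes.
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell class labels, values in \code{class_levels}.
#' @param train_frac training fraction of the balanced cells (default 2/3).
#' @param seed integer seed controlling the subsample, the split and the CV
#'   folds.
#' @param genes optional gene subset (e.g. from
#'   \code{\link{select_variable_genes}}).
#' @param alpha elastic-net mixing parameter (1 = lasso, default).
#' @param class_levels length-2 character, the 0-class then the 1-class
#'   (default \code{c("IN", "PN")}).
#' @param nfolds cross-validation folds.
#' @return object of class \code{fate_model}.
#' @export
fit_fate_classifier <- function(counts, labels, train_frac = 2 / 3, seed = 1,
                                genes = NULL, alpha = 1,
                                class_levels = c("IN", "PN"), nfolds = 10) {
  stopifnot(length(labels) == ncol(counts))
  if (!all(labels %in% class_levels))
    stop("labels must be in {", paste(class_levels, collapse = ", "), "}")
  n_by_class <- table(factor(labels, levels = class_levels))
  if (any(n_by_class < 10))
    stop("each class needs at least 10 cells (got ",
         paste(n_by_class, collapse = ", "), ")")
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]

  # balance by downsampling the majority class
  set.seed(derive_seed(seed, 5L))
  n_min <- min(n_by_class)
  keep <- unlist(lapply(class_levels, function(cl) {
    idx <- which(labels == cl)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  y <- as.integer(labels[keep] == class_levels[2])

  x <- Matrix::t(normalize_log1p(counts[, keep, drop = FALSE]))
  centers <- Matrix::colMeans(x)
  xc <- as.matrix(x) - rep(centers, each = nrow(x))
  scales <- apply(xc, 2L, sd)
  scales[scales == 0] <- 1
  xs <- xc / rep(scales, each = nrow(x))

  # stratified 2/3-1/3 split keeps the training classes exactly balanced
  set.seed(derive_seed(seed, 6L))
  n_train_per_class <- floor(train_frac * n_min)
  train <- unlist(lapply(0:1, function(k) {
    idx <- which(y == k)
    sort(sample(idx, n_train_per_class))
  }))
  valid <- setdiff(seq_along(y), train)

  set.seed(derive_seed(seed, 7L))
  foldid <- unlist(lapply(0:1, function(k)
    sample(rep_len(seq_len(nfolds), n_train_per_class))))
  cv <- glmnet::cv.glmnet(xs[train, , drop = FALSE], y[train],
                          family = "binomial", alpha = alpha,
                          foldid = foldid, standardize = FALSE)
  pred <- as.integer(predict(cv, xs[valid, , drop = FALSE],
                             s = "lambda.min", type = "class"))
  accuracy <- mean(pred == y[valid])
  beta <- coef(cv, s = "lambda.min")
  structure(list(genes = rownames(counts),
                 coefficients = setNames(as.numeric(beta)[-1],
                                         rownames(counts)),
                 intercept = as.numeric(beta)[1],
                 lambda = cv$lambda.min,
                 accuracy = accuracy,
                 class_levels = class_levels,
                 centers = centers, scales = scales,
                 n_per_class = n_min,
                 n_train = length(train), n_valid = length(valid),
                 train_frac = train_frac, alpha = alpha, seed = seed,
                 fit = cv),
            class = "fate_model")
}

#' Per-gene fate scores on the unit interval
#'
#' The logistic transform of each gene's coefficient: 0.5 for a
#' zero-coefficient gene, above 0.5 for genes predictive of the 1-class
#' (PN), below 0.5 for genes predictive of the 0-class (IN).
#'
#' @param model a \code{fate_model}.
#' @return named numeric vector of scores in (0, 1).
#' @export
gene_fate_scores <- function(model) {
  stopifnot(inherits(model, "fate_model"))
  plogis(model$coefficients)
}

#' @export
print.fate_model <- function(x, ...) {
  cat("Balanced logistic fate classifier (", x$class_levels[1], " = 0, ",
      x$class_levels[2], " = 1)\n", sep = "")
  cat(sprintf("  %d genes, %d cells/class after balancing; train %d / validate %d\n",
              length(x$genes), x$n_per_class, x$n_train, x$n_valid))
  cat(sprintf("  lambda (CV) = %.4g, alpha = %g\n", x$lambda, x$alpha))
  cat(sprintf("  validation accuracy = %.2f%%\n", 100 * x$accuracy))
  nz <- sum(x$coefficients != 0)
  cat(sprintf("  %d genes with nonzero coefficients\n", nz))
  invisible(x)
}

#' @export
coef.fate_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
summary.fate_model <- function(object, ...) {
  sc <- gene_fate_scores(object)
  out <- data.frame(gene = object$genes,
                    coefficient = unname(object$coefficients),
                    score = unname(sc), stringsAsFactors = FALSE)
  out[order(-abs(out$coefficient), out$gene), ]
}

#' Predict fate classes for new cells
#'
#' @param object a \code{fate_model}.
#' @param newdata genes x cells count matrix covering the model's genes.
#' @param type \code{"class"} for labels, \code{"prob"} for the probability
#'   of the 1-class (PN).
#' @param ... unused.
#' @export
predict.fate_model <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- Matrix::t(normalize_log1p(newdata[object$genes, , drop = FALSE]))
  xs <- (as.matrix(x) - rep(object$centers, each = nrow(x))) /
    rep(object$scales, each = nrow(x))
  eta <- as.numeric(xs %*% object$coefficients) + object$intercept
  if (type == "prob") return(plogis(eta))
  object$class_levels[(eta > 0) + 1L]
}
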