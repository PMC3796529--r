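# Multinomial log-linear (maximum-entropy) classifier over sparse binary
# indicator features, fit by L2-regularized maximum likelihood with L-BFGS.
# Shared by the base sequence tagger and the maximum-entropy resolver.

# feats: list of character vectors (feature names per instance)
# y: character/factor labels
fit_maxent <- function(feats, y, lambda = 0.01, maxit = 500) {
  y <- as.character(y)
  labels <- sort_c(unique(y))
  k <- length(labels)
  feat_names <- sort_c(unique(unlist(feats, use.names = FALSE)))
  d <- length(feat_names)
  model <- structure(list(labels = labels, feat_index = NULL, W = NULL,
                          lambda = lambda),
                     class = "pheno_maxent")
  if (k == 1L) return(model)           # degenerate: always predict the label
  feat_index <- stats::setNames(seq_len(d), feat_names)
  idx <- lapply(feats, function(f) unname(feat_index[unique(f)]))
  nI <- length(feats)
  X <- Matrix::sparseMatrix(i = rep.int(seq_len(nI), lengths(idx)),
                            j = unlist(idx), x = 1, dims = c(nI, d))
  yi <- match(y, labels)
  Y <- Matrix::sparseMatrix(i = seq_len(nI), j = yi, x = 1, dims = c(nI, k))
  obj <- function(par) {
    W <- matrix(par, d, k)
    S <- as.matrix(X %*% W)
    mx <- apply(S, 1, max)
    lse <- mx + log(rowSums(exp(S - mx)))
    -sum(S[cbind(seq_len(nI), yi)] - lse) + 0.5 * lambda * sum(par^2)
  }
  grad <- function(par) {
    W <- matrix(par, d, k)
    S <- as.matrix(X %*% W)
    mx <- apply(S, 1, max)
    P <- exp(S - mx)
    P <- P / rowSums(P)
    as.vector(as.matrix(Matrix::crossprod(X, P - Y))) + lambda * par
  }
  fit <- stats::optim(rep(0, d * k), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  model$feat_index <- feat_index
  model$W <- matrix(fit$par, d, k, dimnames = list(feat_names, labels))
  model
}

# log-probabilities over the model's labels for one feature set; features
# unseen at training time are ignored (sparse contract)
maxent_logprob <- function(model, feats) {
  k <- length(model$labels)
  if (is.null(model$W)) {
    return(stats::setNames(rep(0, k), model$labels))   # k == 1: log 1
  }
  idx <- model$feat_index[unique(feats)]
  idx <- idx[!is.na(idx)]
  s <- if (length(idx)) colSums(model$W[idx, , drop = FALSE]) else rep(0, k)
  mx <- max(s)
  stats::setNames(s - mx - log(sum(exp(s - mx))), model$labels)
}
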