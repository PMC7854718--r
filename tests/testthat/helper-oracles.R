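# Independent brute-force oracles. These deliberately share no code with the
# package: naive loops, explicit Kronecker products, explicit pair
# enumeration. They exist to pin the package's linear-algebra and counting
# paths against a second, slower derivation.

oracle_encode <- function(x, encoding, rescale = 1) {
  x <- x * rescale
  if (encoding == "stereographic") {
    a <- c(2 * x, sum(x^2) - 1) / (sum(x^2) + 1)
  } else {
    a <- c(x, 1) / sqrt(sum(x^2) + 1)
  }
  a %o% a
}

oracle_kron <- function(A, B) {
  m <- nrow(A); p <- nrow(B)
  out <- matrix(0, m * p, m * p)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    out[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p)] <- A[i, j] * B
  }
  out
}

oracle_copies <- function(rho, m) {
  out <- rho
  if (m > 1) for (k in seq_len(m - 1)) out <- oracle_kron(out, rho)
  out
}

# Naive Helstrom classifier: encodes every sample as a full density matrix,
# averages per class, eigendecomposes the weighted difference, scores by
# explicit trace of a matrix product.
oracle_hqc <- function(X, y, rescale, encoding, copies, weighting) {
  X <- as.matrix(X)
  pats <- lapply(seq_len(nrow(X)), function(i) {
    oracle_copies(oracle_encode(X[i, ], encoding, rescale), copies)
  })
  pos <- which(y == 1); neg <- which(y == 0)
  Cp <- Reduce(`+`, pats[pos]) / length(pos)
  Cn <- Reduce(`+`, pats[neg]) / length(neg)
  wp <- if (weighting == "equiprobable") 0.5 else length(pos) / length(y)
  wn <- 1 - wp
  L <- wp * Cp - wn * Cn
  es <- eigen((L + t(L)) / 2, symmetric = TRUE)
  P <- matrix(0, nrow(L), ncol(L))
  for (k in seq_along(es$values)) {
    if (es$values[k] > 1e-12) P <- P + es$vectors[, k] %o% es$vectors[, k]
  }
  I <- diag(nrow(L))
  bound <- wp * sum(diag(P %*% Cp)) + wn * sum(diag((I - P) %*% Cn))
  score <- function(xnew) {
    rho <- oracle_copies(oracle_encode(xnew, encoding, rescale), copies)
    sum(diag(P %*% rho))
  }
  list(projector_pos = P, helstrom_bound = bound, score = score)
}

# Brute-force GLCM descriptors of one window: enumerate every pixel pair at
# the offset with explicit loops, build the L x L count matrix, evaluate the
# four descriptor formulas by a double loop over levels.
oracle_glcm_descriptors <- function(win, dr, dc, levels) {
  H <- nrow(win); W <- ncol(win)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
      counts[win[r, c] + 1, win[r2, c2] + 1] <-
        counts[win[r, c] + 1, win[r2, c2] + 1] + 1
    }
  }
  tot <- sum(counts)
  if (tot == 0) return(c(contrast = 0, correlation = 0, energy = 0,
                         homogeneity = 0))
  p <- counts / tot
  mi <- 0; mj <- 0
  for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
    mi <- mi + i * p[i + 1, j + 1]; mj <- mj + j * p[i + 1, j + 1]
  }
  vi <- 0; vj <- 0; con <- 0; en <- 0; hom <- 0; cov <- 0
  for (i in 0:(levels - 1)) for (j in 0:(levels - 1)) {
    pij <- p[i + 1, j + 1]
    vi <- vi + (i - mi)^2 * pij; vj <- vj + (j - mj)^2 * pij
    cov <- cov + (i - mi) * (j - mj) * pij
    con <- con + (i - j)^2 * pij
    en <- en + pij^2
    hom <- hom + pij / (1 + abs(i - j))
  }
  corr <- if (vi <= 0 || vj <= 0) 0 else cov / sqrt(vi * vj)
  c(contrast = con, correlation = corr, energy = en, homogeneity = hom)
}

oracle_entropy <- function(win) {
  p <- table(as.vector(win)) / length(win)
  -sum(p * log2(p))
}

# Trapezoidal integration of the empirical ROC curve.
oracle_auc_trapezoid <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
}

# Small linearly separable pixel table for grid-search tests.
make_separable_table <- function(n = 60, n_features = 1, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * n_features, -gap / 2), n / 2),
             matrix(rnorm(n / 2 * n_features, gap / 2), n / 2))
  tab <- data.frame(x = seq_len(n) - 1L, y = 0L)
  for (k in seq_len(n_features)) tab[[paste0("f", k)]] <- X[, k]
  tab$label <- rep(c(0L, 1L), each = n / 2)
  tab
}

random_density_pattern <- function(side, rank = 3) {
  A <- matrix(rnorm(side * rank), side, rank)
  ps <- lapply(seq_len(rank), function(k) {
    a <- A[, k] / sqrt(sum(A[, k]^2)); a %o% a
  })
  w <- runif(rank); w <- w / sum(w)
  Reduce(`+`, Map(`*`, ps, w))
}
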