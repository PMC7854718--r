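test_that("rescaling multiplies features and rejects bad factors", {
  expect_equal(rescale_features(c(1, 2), 1), c(1, 2))
  expect_equal(rescale_features(c(1, 2), 0.5), c(0.5, 1))
  for (f in c(0.5, 1, 1.5, 2)) {
    expect_length(rescale_features(c(1, 2, 3), f), 3L)
  }
  expect_error(rescale_features(1, 0), "positive")
  expect_error(rescale_features(1, -1), "positive")
  expect_error(rescale_features(1, Inf), "positive")
})

test_that("stereographic encoding lands on the unit hypersphere", {
  expect_equal(encode_stereographic(0), matrix(c(0, 0, 0, 1), 2, 2))
  expected <- tcrossprod(c(2, 2, 1) / 3)
  expect_equal(encode_stereographic(c(1, 1)), expected, tolerance = 1e-12)
  expect_equal(sum(diag(encode_stereographic(c(1, 1)))), 1, tolerance = 1e-12)

  set.seed(42)
  for (i in 1:200) {
    x <- rnorm(sample(1:4, 1), sd = 3)
    rho <- encode_stereographic(x)
    expect_equal(sum(diag(rho)), 1, tolerance = 1e-12)
    s <- sum(x^2)
    a <- c(2 * x, s - 1) / (s + 1)
    expect_equal(sum(a^2), 1, tolerance = 1e-12)
  }
})

test_that("amplitude encoding keeps norm information and is rank one", {
  expect_equal(encode_amplitude(c(0, 0)), diag(c(0, 0, 1)))
  expect_equal(encode_amplitude(c(1, 1)), matrix(1 / 3, 3, 3),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(3, sd = 2)
    rho <- encode_amplitude(x)
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(ev), c(0, 0, 0, 1), tolerance = 1e-10)
  }
})

test_that("encodings are invertible up to the stated convention", {
  set.seed(3)
  for (i in 1:20) {
    # amplitude: leading eigenvector is (x, 1)/norm, any n
    x <- rnorm(sample(1:3, 1), sd = 2)
    es <- eigen(encode_amplitude(x), symmetric = TRUE)
    a <- es$vectors[, 1]
    a <- a / a[length(a)]                   # fix sign/scale by the constant
    expect_equal(a[-length(a)], x, tolerance = 1e-8)
    # stereographic, n = 1: invert the projection
    x1 <- rnorm(1, sd = 2)
    es1 <- eigen(encode_stereographic(x1), symmetric = TRUE)
    b <- es1$vectors[, 1] * sign(sum(es1$vectors[, 1] *
                                       c(2 * x1, x1^2 - 1) / (x1^2 + 1)))
    expect_equal(b[1] / (1 - b[2]), x1, tolerance = 1e-8)
  }
})

test_that("tensor copies produce the Kronecker power within the cap", {
  rho <- encode_amplitude(c(0.3, -1.2))
  expect_equal(tensor_copies(rho, 1), rho)
  expect_equal(tensor_copies(diag(c(1, 0)), 2), diag(c(1, 0, 0, 0)))
  r3 <- tensor_copies(rho, 3)
  expect_equal(dim(r3), c(27, 27))
  expect_equal(sum(diag(r3)), 1, tolerance = 1e-12)
  expect_equal(min(eigen(r3, symmetric = TRUE, only.values = TRUE)$values),
               0, tolerance = 1e-10)
  expect_error(tensor_copies(rho, 0), "positive integer")
  expect_error(tensor_copies(diag(4) / 4, 7, side_cap = 4096), "4096")
  expect_error(tensor_copies(diag(4) / 4, 7, side_cap = 4096), "16384")
})

test_that("quantum centroid is the entrywise mean and stays a state", {
  p <- encode_amplitude(1.5)
  expect_equal(quantum_centroid(list(p)), p)
  expect_equal(quantum_centroid(list(diag(c(1, 0)), diag(c(0, 1)))),
               diag(c(0.5, 0.5)))
  set.seed(11)
  pats <- lapply(1:50, function(i) encode_stereographic(rnorm(2)))
  cen <- quantum_centroid(pats)
  expect_equal(sum(diag(cen)), 1, tolerance = 1e-10)
  expect_equal(cen, t(cen), tolerance = 1e-12)
  expect_gte(min(eigen(cen, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(quantum_centroid(list()), "non-empty")
  expect_error(quantum_centroid(list(diag(2) / 2, diag(3) / 3)), "same side")
})

test_that("Helstrom projectors resolve identity and give the right bound", {
  # identical centroids: indistinguishable
  C <- encode_amplitude(c(1, 2))
  hp <- helstrom_projectors(C, C, 0.5, 0.5)
  expect_equal(hp$projector_pos, matrix(0, 3, 3))
  expect_equal(hp$helstrom_bound, 0.5, tolerance = 1e-12)
  # orthogonal pure states: perfect discrimination
  hp2 <- helstrom_projectors(diag(c(1, 0)), diag(c(0, 1)), 0.5, 0.5)
  expect_equal(hp2$projector_pos, diag(c(1, 0)))
  expect_equal(hp2$helstrom_bound, 1, tolerance = 1e-12)

  set.seed(5)
  for (i in 1:50) {
    Cp <- random_density_pattern(4); Cn <- random_density_pattern(4)
    w <- runif(1)
    hp <- helstrom_projectors(Cp, Cn, w, 1 - w)
    P <- hp$projector_pos; Q <- hp$projector_neg
    expect_equal(P + Q, diag(4), tolerance = 1e-10)
    expect_equal(P %*% P, P, tolerance = 1e-8)
    expect_equal(Q %*% Q, Q, tolerance = 1e-8)
    expect_equal(max(abs(P %*% Q)), 0, tolerance = 1e-8)
    expect_equal(P, t(P), tolerance = 1e-10)
    # closed-form identity via independent eigenvalue summation
    lam <- eigen((w * Cp - (1 - w) * Cn + t(w * Cp - (1 - w) * Cn)) / 2,
                 symmetric = TRUE, only.values = TRUE)$values
    expect_equal(hp$helstrom_bound, (1 + sum(abs(lam))) / 2,
                 tolerance = 1e-10)
  }
  expect_error(helstrom_projectors(matrix(c(1, 2, 0, 0), 2, 2),
                                   diag(2) / 2, 0.5, 0.5), "symmetric")
  expect_error(helstrom_projectors(diag(2) / 2, diag(2) / 2, 0.7, 0.7),
               "sum to 1")
})

test_that("fit separates a separable 1-D dataset and honors weighting", {
  X <- matrix(c(-1.1, -0.9, 0.9, 1.1), ncol = 1)
  y <- c(0, 0, 1, 1)
  fit <- hqc(X, y, encoding = "amplitude", copies = 1,
             weighting = "equiprobable", standardize = FALSE)
  expect_equal(predict(fit, X), c("0", "0", "1", "1"))

  set.seed(2)
  Xw <- matrix(rnorm(100), ncol = 1)
  yw <- rep(c(1, 0), times = c(30, 70))
  fw <- hqc(Xw, yw, weighting = "weighted")
  expect_equal(fw$weight_pos, 0.3)
  expect_equal(fw$weight_neg, 0.7)

  expect_error(hqc(X, rep(1, 4)), "negative class")
  expect_error(hqc(X, rep(0, 4)), "positive class")
})

test_that("fit is invariant to training-row permutation", {
  set.seed(9)
  X <- matrix(rnorm(60), ncol = 2)
  y <- rep(c(0, 1), 15)
  f1 <- hqc(X, y, copies = 2, rescale = 1.5)
  perm <- sample(nrow(X))
  f2 <- hqc(X[perm, ], y[perm], copies = 2, rescale = 1.5)
  expect_equal(f1$centroid_pos, f2$centroid_pos, tolerance = 1e-10)
  expect_equal(f1$projector_pos, f2$projector_pos, tolerance = 1e-10)
  expect_equal(f1$helstrom_bound, f2$helstrom_bound, tolerance = 1e-12)
})

test_that("decision scores live in [0,1] and sum with complements to 1", {
  set.seed(4)
  X <- matrix(rnorm(80), ncol = 2)
  y <- rep(c(0, 1), 20)
  fit <- hqc(X, y, copies = 2, encoding = "stereographic")
  Xnew <- matrix(rnorm(200), ncol = 2)
  s <- decision_scores(fit, Xnew)
  expect_true(all(s >= 0 & s <= 1))
  # complement score via the negative projector
  st <- fit$standardization
  Xs <- sweep(sweep(Xnew, 2, st$center), 2, st$scale, "/")
  V <- hqcolony:::encode_amplitudes(Xs, "stereographic", 1, 2L)
  s_neg <- colSums(V * (fit$projector_neg %*% V))
  expect_equal(s + s_neg, rep(1, 100), tolerance = 1e-10)
  expect_error(decision_scores(fit, matrix(rnorm(9), ncol = 3)), "features")
})

test_that("zero positive projector gives all-zero scores and the orthogonal model scores its centroid at 1", {
  fit <- hqc(matrix(c(-1, 1), ncol = 1), c(0, 1), standardize = FALSE)
  fit$projector_pos <- matrix(0, fit$side, fit$side)
  expect_equal(decision_scores(fit, matrix(rnorm(10), ncol = 1)),
               rep(0, 10))
  # orthogonal pure training states: stereographic encodings of x = 0 and
  # x = 1 are the orthogonal unit vectors (0, -1) and (1, 0), so each
  # training point is an eigenstate of its own projector
  X <- matrix(c(0, 1), ncol = 1)
  f <- hqc(X, c(0, 1), encoding = "stereographic", standardize = FALSE)
  expect_equal(decision_scores(f, X)[2], 1, tolerance = 1e-10)
  expect_equal(decision_scores(f, X)[1], 0, tolerance = 1e-10)
})

test_that("every produced density pattern satisfies the state invariants", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(1:3, 1)
    x <- rnorm(n, sd = 5)
    for (enc in c(encode_stereographic, encode_amplitude)) {
      rho <- enc(x)
      expect_equal(sum(diag(rho)), 1, tolerance = 1e-10)
      expect_equal(rho, t(rho), tolerance = 1e-10)
      expect_gte(min(eigen(rho, symmetric = TRUE,
                           only.values = TRUE)$values), -1e-10)
    }
  }
})

test_that("fit and scores match the brute-force oracle", {
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(1:2, 1)
    N <- sample(c(10, 20, 40), 1)
    copies <- sample(1:3, 1)
    enc <- sample(c("amplitude", "stereographic"), 1)
    wt <- sample(c("equiprobable", "weighted"), 1)
    rs <- sample(c(0.5, 1, 2), 1)
    mu <- rnorm(n)
    X <- rbind(matrix(rnorm(N / 2 * n, mu), N / 2, n, byrow = TRUE),
               matrix(rnorm(N / 2 * n, -mu), N / 2, n, byrow = TRUE))
    y <- rep(c(1, 0), each = N / 2)
    fit <- hqc(X, y, rescale = rs, encoding = enc, copies = copies,
               weighting = wt, standardize = FALSE)
    orc <- oracle_hqc(X, y, rs, enc, copies, wt)
    expect_equal(fit$helstrom_bound, orc$helstrom_bound, tolerance = 1e-8)
    Xtest <- matrix(rnorm(6 * n), ncol = n)
    s_pkg <- decision_scores(fit, Xtest)
    s_orc <- vapply(seq_len(6), function(i) orc$score(Xtest[i, ]),
                    numeric(1))
    expect_equal(s_pkg, pmin(pmax(s_orc, 0), 1), tolerance = 1e-8)
    expect_identical(s_pkg > 0.5, s_orc > 0.5)
  }
})

test_that("the Helstrom bound is non-decreasing in the number of copies", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(1:2, 1)
    mu <- rnorm(n)
    X <- rbind(matrix(rnorm(20 * n, mu), 20, n, byrow = TRUE),
               matrix(rnorm(20 * n, -mu), 20, n, byrow = TRUE))
    y <- rep(c(1, 0), each = 20)
    b <- vapply(1:3, function(m) hqc(X, y, copies = m)$helstrom_bound,
                numeric(1))
    expect_gte(b[2] - b[1], -1e-9)
    expect_gte(b[3] - b[2], -1e-9)
    expect_gte(b[1], 0.5 - 1e-10)
    expect_lte(b[3], 1 + 1e-10)
  }
})

test_that("formula interface and JSON round trip preserve predictions", {
  set.seed(13)
  df <- data.frame(a = rnorm(40), b = rnorm(40),
                   colony = factor(rep(c("bg", "col"), 20)))
  df$a <- df$a + 2 * (df$colony == "col")
  fit <- hqc(colony ~ a + b, data = df, copies = 2)
  expect_s3_class(fit, "hqc")
  expect_identical(fit$levels, c("bg", "col"))
  path <- tempfile(fileext = ".json")
  write_hqc(fit, path)
  back <- read_hqc(path)
  newx <- as.matrix(df[1:10, c("a", "b")])
  expect_equal(decision_scores(back, newx), decision_scores(fit, newx),
               tolerance = 1e-12)
  expect_identical(predict(back, newx), predict(fit, newx))
  expect_identical(hqc_params(back)$copies, 2L)
  # printing is informative, not an error
  expect_output(print(fit), "Helstrom")
  expect_output(print(summary(fit)), "trace norm")
})
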