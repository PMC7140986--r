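test_that("gaussian kernel matches hand-computed values", {
  expect_equal(gaussian_kernel(c(1, 2), c(1, 2), 10), 1)
  u <- c(0, 0); v <- c(1, 0)
  expect_equal(gaussian_kernel(u, v, 1), exp(-1))
  expect_equal(gaussian_kernel(c(0, 0), c(3, 4), 50), exp(-25 / 50))
  expect_equal(gaussian_kernel(u, v, 2), gaussian_kernel(v, u, 2))
  expect_error(gaussian_kernel(u, v, 0), "positive")
  expect_error(gaussian_kernel(u, c(1, 2, 3), 1), "equal length")
})

test_that("kernel matrix equals the double-loop brute force", {
  expect_equal(kernel_matrix(matrix(5), 3), matrix(1))
  expect_equal(kernel_matrix(rbind(c(1, 2), c(1, 2)), 3),
               matrix(1, 2, 2))
  set.seed(21)
  X <- matrix(rnorm(20), 4, 5)
  K <- kernel_matrix(X, 7)
  brute <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    brute[i, j] <- gaussian_kernel(X[i, ], X[j, ], 7)
  }
  expect_equal(K, brute, tolerance = 1e-12)
  expect_identical(K, t(K))
  expect_equal(diag(K), rep(1, 4))
  # independent kernel implementation (different distance code path)
  Kk <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = 1 / 7), X)@.Data
  expect_equal(K, unname(Kk), tolerance = 1e-10)
})

test_that("kernel system is positive definite with eigenvalues >= 1/C", {
  for (s in 1:5) {
    set.seed(30 + s)
    X <- matrix(rnorm(60), 10, 6)
    K <- kernel_matrix(X, 60)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    C <- runif(1, 0.1, 5)
    evA <- eigen(K + diag(1 / C, 10), symmetric = TRUE,
                 only.values = TRUE)$values
    expect_gte(min(evA), 1 / C - 1e-8)
  }
})

test_that("two-point training reproduces the symbolic 2x2 solution", {
  x <- rbind(c(0, 0), c(1, 1))
  gamma <- 5; C <- 1
  m <- kelm(x, c("AD", "NC"), C = C, gamma = gamma,
            class_order = c("AD", "NC"))
  k <- exp(-2 / gamma)
  # (Omega + I/C) = [[2, k], [k, 2]]; hand inverse times Y
  Ainv <- matrix(c(2, -k, -k, 2), 2, 2) / (4 - k^2)
  Y <- rbind(c(1, -1), c(-1, 1))
  expect_equal(unname(m$coef), unname(Ainv %*% Y), tolerance = 1e-12)
})

test_that("predictions match an explicit linear-algebra oracle", {
  set.seed(22)
  X <- matrix(rnorm(12), 3, 4)
  y <- c("AD", "NC", "AD")
  gamma <- 11; C <- 0.7
  m <- kelm(X, y, C = C, gamma = gamma, class_order = c("AD", "NC"))
  K <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) K[i, j] <- gaussian_kernel(X[i, ], X[j, ], gamma)
  Y <- cbind(ifelse(y == "AD", 1, -1), ifelse(y == "NC", 1, -1))
  xstar <- rnorm(4)
  krow <- vapply(1:3, function(i) gaussian_kernel(xstar, X[i, ], gamma),
                 numeric(1))
  expected <- krow %*% solve(K + diag(1 / C, 3)) %*% Y
  expect_equal(unname(predict(m, xstar, type = "score")), expected,
               tolerance = 1e-12)
})

test_that("training is deterministic and permutation invariant", {
  d <- random_labelled(12, 3, seed = 23)
  m1 <- kelm(d$x, d$y, class_order = c("pos", "neg"))
  m2 <- kelm(d$x, d$y, class_order = c("pos", "neg"))
  expect_identical(m1$coef, m2$coef)
  perm <- sample(12)
  m3 <- kelm(d$x[perm, ], d$y[perm], class_order = c("pos", "neg"))
  xs <- matrix(rnorm(15), 5, 3)
  expect_equal(predict(m1, xs, type = "score"),
               predict(m3, xs, type = "score"), tolerance = 1e-10)
})

test_that("weak regularisation interpolates, strong kills the scores", {
  d <- random_labelled(10, 2, seed = 24)
  m <- kelm(d$x, d$y, C = 1e8, class_order = c("pos", "neg"))
  sc <- predict(m, d$x, type = "score")
  Y <- cbind(ifelse(d$y == "pos", 1, -1), ifelse(d$y == "neg", 1, -1))
  expect_equal(unname(sc), Y, tolerance = 1e-3)

  m0 <- kelm(d$x, d$y, C = 1e-8, class_order = c("pos", "neg"))
  expect_lt(max(abs(predict(m0, d$x, type = "score"))), 1e-6)

  # a point far outside the kernel's reach scores ~(0, 0)
  far <- predict(m, matrix(1e4, 1, 2), type = "score")
  expect_lt(max(abs(far)), 1e-10)
})

test_that("duplicated consistent training rows leave predictions unchanged", {
  d <- random_labelled(8, 3, seed = 25)
  m <- kelm(d$x, d$y, C = 1e8, class_order = c("pos", "neg"))
  mdup <- kelm(rbind(d$x, d$x[1:3, ]), c(d$y, d$y[1:3]), C = 1e8,
               class_order = c("pos", "neg"))
  xs <- matrix(rnorm(12), 4, 3)
  expect_equal(predict(m, xs, type = "score"),
               predict(mdup, xs, type = "score"), tolerance = 1e-4)
})

test_that("grade is the channel difference and classify its sign", {
  d <- random_labelled(14, 3, seed = 26)
  m <- kelm(d$x, d$y, class_order = c("pos", "neg"))
  xs <- matrix(rnorm(300), 100, 3)
  sc <- predict(m, xs, type = "score")
  g <- predict(m, xs, type = "grade")
  expect_equal(unname(g), unname(sc[, 1] - sc[, 2]))
  cls <- predict(m, xs, type = "class")
  expect_identical(as.character(cls),
                   ifelse(g > 0, "pos", "neg"))  # tie -> negative class
  # symmetric two-point model grades the midpoint exactly 0 -> negative
  msym <- kelm(rbind(-1, 1), c("pos", "neg"), gamma = 10,
               class_order = c("pos", "neg"))
  expect_equal(unname(predict(msym, 0, type = "grade")), 0)
  expect_identical(as.character(predict(msym, 0, type = "class")), "neg")
})

test_that("per-channel output equals kernel ridge regression", {
  set.seed(27)
  X <- matrix(rnorm(48), 12, 4)
  y <- rep(c("AD", "NC"), 6)
  C <- 2; gamma <- 30
  m <- kelm(X, y, C = C, gamma = gamma, class_order = c("AD", "NC"))
  Xs <- matrix(rnorm(20), 5, 4)
  # independent route: kernlab kernels + dense solve, one ridge fit per channel
  rbf <- kernlab::rbfdot(sigma = 1 / gamma)
  K <- unname(kernlab::kernelMatrix(rbf, X)@.Data)
  Kt <- unname(kernlab::kernelMatrix(rbf, Xs, X)@.Data)
  for (ch in 1:2) {
    ycol <- if (ch == 1) ifelse(y == "AD", 1, -1) else ifelse(y == "NC", 1, -1)
    ridge <- Kt %*% solve(K + diag(1 / C, 12), ycol)
    expect_equal(unname(predict(m, Xs, type = "score"))[, ch],
                 as.numeric(ridge), tolerance = 1e-8)
  }
})

test_that("model round-trips through serialisation", {
  d <- random_labelled(9, 2, seed = 28)
  m <- kelm(d$x, d$y)
  path <- withr::local_tempfile(fileext = ".rds")
  write_kelm(m, path)
  expect_identical(read_kelm(path), m)
})

test_that("degenerate inputs are rejected", {
  d <- random_labelled(6, 2, seed = 29)
  expect_error(kelm(d$x, rep("one", 6)), "2 classes")
  expect_error(kelm(d$x, d$y, C = 0), "positive")
  m <- kelm(d$x, d$y)
  expect_error(predict(m, matrix(0, 1, 5)), "features")
})
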