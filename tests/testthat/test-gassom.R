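# Patch encoding, subspace responses, and the online subspace update.

test_that("a 55x55 window yields 100 patch vectors with normalized halves", {
  set.seed(1)
  L <- matrix(runif(55 * 55), 55, 55)
  R <- matrix(runif(55 * 55), 55, 55)
  pt <- patchify(L, R, stride = 5L)
  expect_equal(ncol(pt$x), 100L)
  expect_equal(nrow(pt$x), 200L)
  expect_equal(pt$ny, 10L)
  for (j in c(1, 37, 100)) {
    for (half in list(1:100, 101:200)) {
      expect_lt(abs(mean(pt$x[half, j])), 1e-9)
      expect_lt(abs(var(pt$x[half, j]) - 1), 1e-9)
    }
  }
})

test_that("constant windows produce zero vectors flagged low-contrast", {
  pt <- patchify(matrix(0.4, 35, 35), matrix(0.7, 35, 35), stride = 5L)
  expect_true(all(pt$low_contrast))
  expect_true(all(pt$x == 0))
})

test_that("patch extraction content matches a direct double loop", {
  set.seed(2)
  L <- matrix(runif(35 * 35), 35, 35); R <- L + 0.1
  pt <- patchify(L, R, stride = 5L)
  # patch grid is scanned column-major: j = (gx-1)*ny + gy
  for (probe in list(c(1L, 1L), c(3L, 2L), c(6L, 6L))) {
    gy <- probe[1]; gx <- probe[2]
    j <- (gx - 1L) * pt$ny + gy
    raw <- as.vector(L[(gy - 1L) * 5L + 1:10, (gx - 1L) * 5L + 1:10])
    expect_equal(pt$x[1:100, j], (raw - mean(raw)) / sd(raw))
  }
})

test_that("subspace responses equal the brute-force projection energy", {
  set.seed(3)
  bank <- small_bank(n = 12L, d = 20L)
  for (rep in 1:25) {
    x <- rnorm(20)
    r <- subspace_responses(bank, x)
    oracle <- vapply(bank$phi, function(phi) {
      sum(phi[, 1] * x)^2 + sum(phi[, 2] * x)^2
    }, numeric(1))
    expect_equal(drop(r), oracle, tolerance = 1e-12)
  }
  # in-subspace and orthogonal inputs
  phi1 <- bank$phi[[1]]
  expect_equal(drop(subspace_responses(bank, phi1[, 1]))[1], 1)
  x_perp <- rnorm(20)
  x_perp <- x_perp - phi1 %*% crossprod(phi1, x_perp)
  expect_lt(drop(subspace_responses(bank, x_perp))[1], 1e-20)
})

test_that("winner selection and residual error satisfy Pythagoras and match
           an exhaustive scan", {
  set.seed(4)
  bank <- small_bank(n = 15L, d = 30L)
  X <- matrix(rnorm(30 * 40), 30, 40)
  be <- best_subspace_and_error(bank, X)
  r <- subspace_responses(bank, X)
  for (j in 1:40) {
    expect_equal(be$m[j], which.max(r[, j]))
    expect_equal(be$e[j] + max(r[, j]), sum(X[, j]^2), tolerance = 1e-10)
  }
  # exact in-subspace input
  x_in <- bank$phi[[7]] %*% c(0.3, -1.2)
  be1 <- best_subspace_and_error(bank, x_in)
  expect_equal(be1$m, 7L)
  expect_lt(be1$e, 1e-12)
})

test_that("scale errors average correctly and reject empty input", {
  set.seed(5)
  bank <- small_bank(n = 6L, d = 10L)
  X <- matrix(rnorm(10 * 8), 10, 8)
  expect_equal(scale_error(bank, X), mean(best_subspace_and_error(bank, X)$e))
  expect_error(scale_error(bank, matrix(0, 10, 0)), "empty")
  expect_equal(average_error(2, 2, 2), 2)
  expect_equal(average_error(1, 2, 3), 2)
  expect_equal(vergence_reward(0), 0)
})

test_that("responsibilities are a sticky softmax over responses", {
  bank <- small_bank(n = 10L, d = 20L, sigma_e = 0.5, omega = 0.4)
  # equal responses, no previous winner -> uniform
  H <- responsibilities(bank, matrix(1, 10, 1))
  expect_equal(drop(H), rep(0.1, 10))
  # sigma_e -> 0: one-hot on the argmax
  bank_hard <- small_bank(n = 10L, d = 20L, sigma_e = 1e-4)
  r <- matrix(runif(10), 10, 1)
  Hh <- responsibilities(bank_hard, r)
  expect_equal(drop(Hh)[which.max(r)], 1, tolerance = 1e-9)
  # matches a direct evaluation of the documented formula
  set.seed(6)
  r2 <- matrix(runif(20), 10, 2)
  prev <- c(3L, NA)
  H2 <- responsibilities(bank, r2, prev)
  prior1 <- rep((1 - 0.4) / 9, 10); prior1[3] <- 0.4
  o1 <- exp(r2[, 1] / (2 * 0.5^2)) * prior1
  expect_equal(H2[, 1], o1 / sum(o1), tolerance = 1e-12)
  o2 <- exp(r2[, 2] / (2 * 0.5^2))
  expect_equal(H2[, 2], o2 / sum(o2), tolerance = 1e-12)
  expect_equal(colSums(H2), c(1, 1))
  # hard mode is winner-take-all
  bw <- small_bank(n = 10L, d = 20L, mode = "hard")
  Hw <- responsibilities(bw, r2)
  expect_equal(colSums(Hw > 0), c(1L, 1L))
})

test_that("the subspace update leaves represented patches fixed, reduces the
           residual otherwise, and preserves orthonormality", {
  set.seed(7)
  bank <- small_bank(n = 5L, d = 20L)
  # patches exactly inside the subspaces responsible for them (one-hot
  # assignment) -> residuals are zero and the bank does not move
  X_in <- do.call(cbind, lapply(bank$phi, function(p) p %*% rnorm(2)))
  H <- diag(5)
  upd <- update_gassom_bank(bank, X_in, H, lambda = 0.05)
  for (i in 1:5) {
    expect_lt(max(abs(upd$phi[[i]] - bank$phi[[i]])), 1e-10)
  }
  # single patch, one-hot responsibility -> residual strictly decreases
  x <- rnorm(20)
  H1 <- matrix(0, 5, 1); H1[2, 1] <- 1
  before <- sum((x - bank$phi[[2]] %*% crossprod(bank$phi[[2]], x))^2)
  upd2 <- update_gassom_bank(bank, matrix(x), H1, lambda = 0.01)
  after <- sum((x - upd2$phi[[2]] %*% crossprod(upd2$phi[[2]], x))^2)
  expect_lt(after, before)
  # orthonormality after arbitrary updates
  set.seed(8)
  X <- matrix(rnorm(20 * 30), 20, 30)
  H3 <- responsibilities(bank, subspace_responses(bank, X))
  upd3 <- update_gassom_bank(bank, X, H3, lambda = 0.1)
  for (i in 1:5) {
    expect_lt(max(abs(crossprod(upd3$phi[[i]]) - diag(2))), 1e-8)
  }
  # zero-norm patches contribute nothing
  upd4 <- update_gassom_bank(bank, matrix(0, 20, 1), matrix(0.2, 5, 1),
                             lambda = 0.1)
  for (i in 1:5) expect_equal(upd4$phi[[i]], bank$phi[[i]])
})

test_that("bank initialization is deterministic, orthonormal and sized", {
  b1 <- init_gassom_bank(n = 324L, seed = 42)
  b2 <- init_gassom_bank(n = 324L, seed = 42)
  expect_identical(b1$phi, b2$phi)
  expect_equal(b1$n, 324L)
  for (i in c(1L, 100L, 324L)) {
    expect_lt(max(abs(crossprod(b1$phi[[i]]) - diag(2))), 1e-10)
  }
})

test_that("training on planted subspaces recovers them (error drops >= 80%)", {
  set.seed(9)
  bases <- replicate(20, random_basis(50), simplify = FALSE)
  bank <- init_gassom_bank(n = 20L, dim = 50L, seed = 1, sigma_e = 0.5)
  err <- function(b) {
    set.seed(99)
    mean(best_subspace_and_error(b, planted_patches(bases, 30L))$e)
  }
  e0 <- err(bank)
  set.seed(10)
  for (it in 1:150) {
    X <- planted_patches(bases, 2L)
    st <- gassom_step(bank, list(x = X, low_contrast = rep(FALSE, ncol(X))),
                      lambda = 0.1)
    bank <- st$bank
  }
  expect_lt(err(bank), 0.2 * e0)
})

test_that("identical seed and input stream give a bit-identical bank
           trajectory", {
  run <- function() {
    bank <- small_bank(n = 6L, d = 20L, seed = 5)
    set.seed(11)
    for (i in 1:10) {
      X <- matrix(rnorm(20 * 5), 20, 5)
      bank <- gassom_step(bank, list(x = X,
                                     low_contrast = rep(FALSE, 5L)))$bank
    }
    bank
  }
  expect_identical(run(), run())
})
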