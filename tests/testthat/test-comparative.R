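test_that("phylogenetic covariance reads shared path lengths", {
  C1 <- phylo_covariance(read_newick("(A:1.5,B:2.5);"))
  expect_equal(unname(C1), matrix(c(1.5, 0, 0, 2.5), 2))

  C2 <- phylo_covariance(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(C2["A", "B"], 1)
  expect_equal(C2["A", "C"], 0)
  expect_equal(C2["A", "A"], 2)

  tr <- simulate_tree(15, 1, seed = 3)
  C <- phylo_covariance(tr)
  expect_true(isSymmetric(C))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("contrasts follow the Felsenstein recursion", {
  tr <- read_newick("(A:1,B:1);")
  cs <- compute_contrasts(tr, c(A = 3, B = 1))
  expect_equal(abs(cs$contrast), 2 / sqrt(2), tolerance = 1e-12)

  tr2 <- simulate_tree(10, 1, seed = 6)
  cs2 <- compute_contrasts(tr2, stats::setNames(rep(4.2, 10), tr2$tip.label))
  expect_equal(cs2$contrast, rep(0, 9), tolerance = 1e-12)
  expect_equal(nrow(cs2), 10 - 1)
})

test_that("contrasts match ape and the GLS slope oracle", {
  set.seed(11)
  for (r in 1:10) {
    n <- sample(5:40, 1)
    tr <- simulate_tree(n, 1, seed = 100 + r)
    tr$edge.length <- tr$edge.length * stats::runif(nrow(tr$edge), 0.3, 2)
    x <- stats::setNames(
      simulate_brownian_traits(tr, matrix(1), 0, seed = 200 + r)$trait1,
      tr$tip.label)
    y <- stats::setNames(
      simulate_brownian_traits(tr, matrix(1), 0, seed = 300 + r)$trait1,
      tr$tip.label)
    cx <- compute_contrasts(tr, x)
    cy <- compute_contrasts(tr, y)
    expect_equal(sort(abs(cx$contrast)), unname(sort(abs(ape::pic(x, tr)))),
                 tolerance = 1e-10)
    C <- phylo_covariance(tr); Ci <- solve(C)
    X <- cbind(1, x[tr$tip.label])
    beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y[tr$tip.label])
    slope <- pic_regression(cx, cy)$slope
    expect_equal(slope, beta[2, 1], tolerance = 1e-8)
  }
})

test_that("contrast signs are arbitrary but the slope is not", {
  tr <- read_newick("((A:1,B:1):0.5,(C:0.7,D:1.3):0.5);")
  x <- c(A = 1, B = 4, C = 2, D = 9)
  y <- c(A = 2, B = 5, C = 1, D = 6)
  rot <- ape::rotate(tr, node = 6)
  s1 <- pic_regression(compute_contrasts(tr, x), compute_contrasts(tr, y))
  s2 <- pic_regression(compute_contrasts(rot, x), compute_contrasts(rot, y))
  expect_equal(s1$slope, s2$slope, tolerance = 1e-12)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
})

test_that("through-origin regression handles exact and orthogonal cases", {
  cx <- c(1, -2, 3, 0.5)
  r <- suppressWarnings(pic_regression(cx, 2 * cx))  # perfect fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$adj_r_squared, 1, tolerance = 1e-12)

  cy <- c(2, 1, 0, 0)   # cx . cy = 2 - 2 = 0
  expect_equal(pic_regression(cx, cy)$slope, 0, tolerance = 1e-12)
  expect_error(pic_regression(rep(0, 4), cy), "zero variance")
})

test_that("OLS regression matches the normal equations and log invariance", {
  x <- c(1, 2, 3, 4, 5); y <- 2 * x
  r <- suppressWarnings(ols_regression(x, y))  # perfect fit
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$adj_r_squared, 1, tolerance = 1e-10)

  set.seed(4)
  x <- stats::runif(30, 1, 100); y <- x^0.7 * exp(stats::rnorm(30, 0, 0.2))
  r_ln <- ols_regression(x, y, log_x = TRUE, log_y = TRUE)
  fit10 <- stats::lm(log10(y) ~ log10(x))
  expect_equal(r_ln$slope, unname(stats::coef(fit10)[2]), tolerance = 1e-10)

  loss <- function(b) sum((log(y) - b[1] - b[2] * log(x))^2)
  num <- stats::optim(c(0, 1), loss, control = list(reltol = 1e-15))
  expect_equal(r_ln$slope, num$par[2], tolerance = 1e-5)
  expect_error(ols_regression(c(-1, 2, 3), c(1, 2, 3), log_x = TRUE),
               "non-positive")
})

test_that("Brownian REML matches closed forms and the contrast identity", {
  tr <- read_newick("(A:1,B:1);")
  f <- fit_brownian_multivariate(tr, matrix(c(0, 2),
                                            dimnames = list(c("A", "B"), "t")))
  expect_equal(unname(f$R[1, 1]), 2, tolerance = 1e-12)

  tr2 <- simulate_tree(25, 1, seed = 14)
  tt <- simulate_brownian_traits(tr2, matrix(c(1, 0.6, 0.6, 1), 2),
                                 c(0, 0), seed = 8)
  f2 <- fit_brownian_multivariate(tr2, as.matrix(tt[, c("trait1", "trait2")]))
  c1 <- compute_contrasts(tr2, stats::setNames(tt$trait1, tt$species))
  c2 <- compute_contrasts(tr2, stats::setNames(tt$trait2, tt$species))
  n <- 25
  R_or <- matrix(c(sum(c1$contrast^2), sum(c1$contrast * c2$contrast),
                   sum(c1$contrast * c2$contrast), sum(c2$contrast^2)),
                 2) / (n - 1)
  expect_equal(unname(f2$R), R_or, tolerance = 1e-8)
  expect_true(all(abs(f2$correlation) <= 1 + 1e-12))
})

test_that("bootstrap support is deterministic and saturates when collinear", {
  tr <- simulate_tree(20, 1, seed = 2)
  tt <- simulate_brownian_traits(tr, matrix(c(1, 0.5, 0.5, 1), 2), c(0, 0),
                                 seed = 3)
  Y <- as.matrix(tt[, c("trait1", "trait2")])
  f <- fit_brownian_multivariate(tr, Y)
  s1 <- bootstrap_support(f, n_reps = 120, seed = 7)
  s2 <- bootstrap_support(f, n_reps = 120, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$support >= 0 & s1$support <= 1))

  Y2 <- cbind(a = tt$trait1, b = 2 * tt$trait1)
  rownames(Y2) <- tt$species
  f2 <- fit_brownian_multivariate(tr, Y2)
  s3 <- suppressWarnings(bootstrap_support(f2, n_reps = 100, seed = 1))
  expect_equal(s3$support, 1)
})

test_that("duplication screen excludes only strictly high scores", {
  tab <- small_trait_table()  # scores 5, 35, 30, 10
  out <- duplication_screen(tab)
  expect_setequal(out$excluded, "b")           # 35 > 30
  expect_true("c" %in% out$reduced$species)    # exactly 30 retained
  expect_identical(out$full, tab)

  tab$busco_duplicated <- c(1, 2, 3, 4)
  out2 <- duplication_screen(tab)
  expect_equal(nrow(out2$reduced), nrow(tab))
})
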