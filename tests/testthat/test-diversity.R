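comm <- function(m) {
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

test_that("richness counts positive features per sample", {
  m <- matrix(c(0, 0, 5, 1,
                0, 0, 0, 0,
                2, 3, 1, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), paste0("f", 1:4)))
  out <- richness(comm(m))
  expect_identical(out$richness, c(2L, 0L, 4L))

  withr::with_seed(3, {
    r <- matrix(rpois(50, 0.8), 5, 10,
                dimnames = list(paste0("s", 1:5), paste0("f", 1:10)))
    expect_identical(richness(comm(r))$richness,
                     unname(apply(r, 1, function(v) sum(v > 0))))
  })
})

test_that("richness regression matches the closed-form OLS", {
  s1 <- c(1, 2, 3, 4, 5)
  out <- compare_richness(s1, -2 * s1 + 7)
  expect_equal(out$slope, -2)
  expect_equal(out$r, -1)

  out2 <- compare_richness(s1, rep(4, 5))
  expect_equal(out2$slope, 0)
  expect_true(is.na(out2$r))

  withr::with_seed(10, {
    x <- stats::rnorm(11)
    y <- stats::rnorm(11)
  })
  out3 <- compare_richness(x, y)
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(out3$slope, bhat)
  expect_equal(out3$intercept, mean(y) - bhat * mean(x))
  expect_equal(out3$r, stats::cor(x, y))
})

test_that("relative-frequency standardisation conserves composition", {
  m <- matrix(c(2, 2, 4,
                1, 0, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("f", 1:3)))
  out <- standardize_relfreq(comm(m))
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(0.25, 0.25, 0.5))
  expect_equal(unlist(out[2, -1], use.names = FALSE), c(1, 0, 0))

  withr::with_seed(4, {
    r <- matrix(stats::runif(40), 4, 10,
                dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
    sums <- rowSums(as.matrix(standardize_relfreq(comm(r))[-1]))
    expect_equal(unname(sums), rep(1, 4))
  })

  z <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(standardize_relfreq(comm(z)), "all-zero")
})

test_that("Bray-Curtis and Jaccard match their formulas", {
  m <- matrix(c(1, 2, 3,
                2, 2, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("f", 1:3)))
  expect_equal(as.numeric(bray_curtis(comm(m))), 0.4)  # 4/10

  ident <- matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE,
                  dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(as.numeric(bray_curtis(comm(ident))), 0)

  disj <- matrix(c(3, 0, 0, 5), 2, 2,
                 dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(as.numeric(bray_curtis(comm(disj))), 1)
  expect_equal(as.numeric(jaccard(comm(disj))), 1)

  jm <- matrix(c(1, 0, 1,
                 1, 1, 0), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), paste0("f", 1:3)))
  expect_equal(as.numeric(jaccard(comm(jm))), 2 / 3)
  expect_equal(as.numeric(jaccard(comm(ident))), 0)

  # symmetry, zero diagonal, [0, 1] range on random data
  withr::with_seed(6, {
    r <- matrix(stats::runif(60), 6, 10,
                dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  })
  d <- as.matrix(bray_curtis(comm(r)))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("ordination recovers an exactly embeddable configuration", {
  withr::with_seed(8, {
    pts <- matrix(stats::rnorm(22), 11, 2,
                  dimnames = list(sprintf("s%02d", 1:11), NULL))
  })
  d <- stats::dist(pts)
  mds <- ordinate(d, method = "mds")
  expect_s3_class(mds, "sedacomp_ordination")
  # PCoA of Euclidean distances recovers the configuration up to rotation
  pro <- procrustes_test(comm(pts), mds, n_perm = 99, seed = 1)
  expect_lt(pro$m12_squared, 1e-6)
  expect_lt(mds$stress, 1e-6)

  nmds <- ordinate(d, method = "nmds", seed = 2)
  expect_lt(nmds$stress, 0.01)
  expect_identical(nmds$points$sample_id, sprintf("s%02d", 1:11))

  expect_error(ordinate(stats::dist(pts[1:2, ]), k = 2), "more samples")
})

test_that("procrustes test sees through rotation, scale and translation", {
  withr::with_seed(9, {
    x <- matrix(stats::rnorm(20), 10, 2,
                dimnames = list(paste0("s", 1:10), NULL))
  })
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  y <- 3 * x %*% rot
  rownames(y) <- rownames(x)
  out <- procrustes_test(x, y, n_perm = 199, seed = 3)
  expect_lt(out$m12_squared, 1e-8)
  expect_equal(out$p_value, 1 / 200)  # add-one estimator at its floor

  # translation invariance
  y2 <- sweep(y, 2, c(5, -2), "+")
  out2 <- procrustes_test(x, y2, n_perm = 199, seed = 3)
  expect_equal(out$m12_squared, out2$m12_squared, tolerance = 1e-10)
})

test_that("mantel statistic and exact enumeration agree on small cases", {
  withr::with_seed(13, {
    a <- matrix(stats::runif(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
    b <- matrix(stats::runif(8), 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  })
  d1 <- stats::dist(a)
  d2 <- stats::dist(b)
  exact <- oracle_mantel_exact(d1, d2)
  out <- mantel_test(d1, d2, n_perm = 5000, seed = 2)
  expect_equal(out$r, exact$r, tolerance = 1e-10)
  expect_lt(abs(out$p_value - exact$p), 0.05)

  # identical matrices: r = 1
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1)

  # invariant under identical relabeling of both matrices
  perm <- c(3, 1, 4, 2)
  m1 <- as.matrix(d1)[perm, perm]
  m2 <- as.matrix(d2)[perm, perm]
  out_perm <- mantel_test(stats::as.dist(m1), stats::as.dist(m2),
                          n_perm = 99, seed = 2)
  expect_equal(out_perm$r, out$r, tolerance = 1e-10)

  expect_error(mantel_test(d1, stats::dist(a[1:3, ])), "size")
})
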