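# minimal feature-table wrapper around one numeric descriptor for tukey tests
one_desc_table <- function(values, groups) {
  dn <- descriptor_names()
  tab <- as.data.frame(matrix(1, length(values), 30,
                              dimnames = list(NULL, dn)))
  tab$length <- values
  tab$taxon <- groups
  tab$modality <- "BF"
  tab$grain_id <- seq_along(values)
  tab
}

test_that("Tukey letters separate distant groups and merge identical ones", {
  y <- with_seed_test(1, c(rnorm(50, 0), rnorm(50, 10)))
  g <- rep(c("A", "B"), each = 50)
  tk <- tukey_letters(one_desc_table(y, g), "length")
  lt <- setNames(tk$summary$letters, tk$summary$taxon)
  expect_false(grepl(lt[["A"]], lt[["B"]], fixed = TRUE))
  expect_equal(nchar(lt[["A"]]), 1L)

  y2 <- with_seed_test(2, rep(rnorm(40, 5), 2))
  tk2 <- tukey_letters(one_desc_table(y2, g[1:80]), "length")
  expect_equal(unique(tk2$summary$letters), "a")
})

test_that("letter patterns agree with direct studentized-range decisions", {
  for (rep in 1:5) {
    y <- with_seed_test(rep + 10,
                        c(rnorm(10, 0), rnorm(10, 1.2), rnorm(10, 2.4)))
    g <- rep(c("g1", "g2", "g3"), each = 10)
    tk <- tukey_letters(one_desc_table(y, g), "length")
    # independent oracle: q statistics straight from the definitions
    ni <- tapply(y, g, length); mi <- tapply(y, g, mean)
    mse <- sum((y - ave(y, g))^2) / (length(y) - 3)
    sig <- matrix(FALSE, 3, 3, dimnames = list(names(mi), names(mi)))
    for (a in 1:2) for (b in (a + 1):3) {
      se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
      q <- abs(mi[a] - mi[b]) / se
      p <- stats::ptukey(q, 3, length(y) - 3, lower.tail = FALSE)
      sig[a, b] <- sig[b, a] <- p < 0.05
    }
    lt <- setNames(tk$summary$letters, tk$summary$taxon)
    for (a in 1:2) for (b in (a + 1):3) {
      shares <- any(strsplit(lt[a], "")[[1]] %in% strsplit(lt[b], "")[[1]])
      expect_equal(!shares, unname(sig[a, b]),
                   label = sprintf("rep %d pair %d-%d", rep, a, b))
    }
  }
})

test_that("same-distribution groups rarely receive disjoint letters", {
  # type-I letter separation over repeated null draws stays near alpha
  n_rep <- 1000
  hits <- 0
  for (r in seq_len(n_rep)) {
    y <- with_seed_test(r, rnorm(30))
    g <- rep(c("u", "v"), each = 15)
    tk <- tukey_letters(one_desc_table(y, g), "length")
    lt <- tk$summary$letters
    if (!any(strsplit(lt[1], "")[[1]] %in% strsplit(lt[2], "")[[1]]))
      hits <- hits + 1
  }
  rate <- hits / n_rep
  mc <- 2 * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(rate, 0.05 + 2 * mc)
})

test_that("degenerate Tukey inputs raise explicit errors", {
  expect_error(tukey_letters(one_desc_table(rep(1, 20),
                                            rep(c("a", "b"), 10)), "length"),
               "zero within-group variance")
  expect_error(tukey_letters(one_desc_table(rnorm(10), rep("a", 10)),
                             "length"), ">= 2 groups")
  expect_error(tukey_letters(one_desc_table(rnorm(3),
                                            c("a", "a", "b")), "length"),
               "n >= 2")
})

test_that("factor model matches the two-variable closed form and its invariants", {
  n <- 20000
  r <- 0.8
  x <- with_seed_test(5, {
    z1 <- rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
    cbind(a = z1, b = z2)
  })
  fm <- fit_factor_model(x)
  expect_equal(fm$eigenvalues, c(1 + r, 1 - r), tolerance = 0.02)
  expect_equal(retain_factors(fm), 1L)   # both variables load max on factor 1

  # exactly uncorrelated variables (2^3 factorial design): unit eigenvalues,
  # every factor is some variable's max, so all are retained
  xi <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1)))
  fmi <- fit_factor_model(xi)
  expect_equal(fmi$eigenvalues, rep(1, 3), tolerance = 1e-12)
  expect_equal(retain_factors(fmi), 1:3)

  expect_error(fit_factor_model(cbind(a = rnorm(10), b = rep(2, 10))), "b")
})

test_that("loadings, eigenvalue sum and score covariance satisfy the model algebra", {
  tab <- sample_feature_table(60, "BF", seed = 44)
  x <- as.matrix(tab[descriptor_names()])
  fm <- fit_factor_model(tab)
  p <- ncol(x)
  expect_equal(sum(fm$eigenvalues), p, tolerance = 1e-8)
  # column sums of squared loadings reproduce the eigenvalues, checked against
  # direct matrix arithmetic on the correlation matrix
  expect_equal(unname(colSums(fm$loadings^2)), fm$eigenvalues,
               tolerance = 1e-8)
  expect_equal(max(abs(fm$correlation - stats::cor(x))), 0, tolerance = 1e-12)
  sc <- fm$scores
  expect_lt(max(abs(colMeans(sc))), 1e-10)
  cv <- stats::cov(sc) * (nrow(sc) - 1) / nrow(sc) * nrow(sc) / (nrow(sc) - 1)
  expect_equal(unname(diag(stats::cov(sc))), fm$eigenvalues, tolerance = 1e-8)
  off <- stats::cov(sc); diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
})

test_that("LDA recovers 1-D separation and matches a generalized-eigen oracle", {
  y <- with_seed_test(7, c(rnorm(60, -5), rnorm(60, 5)))
  g <- rep(c("lo", "hi"), each = 60)
  m <- fit_lda(matrix(y, ncol = 1), g)
  expect_equal(ncol(m$axes), 1L)
  expect_equal(sum(m$centroids), 0, tolerance = 0.5)
  expect_equal(unname(classify_lda(m, matrix(c(-5, 5), ncol = 1))),
               c("lo", "hi"))

  # 3-class 2-D data against a symmetric generalized-eigenproblem oracle
  x <- with_seed_test(8, rbind(
    cbind(rnorm(40, 0), rnorm(40, 0)),
    cbind(rnorm(40, 3), rnorm(40, 1)),
    cbind(rnorm(40, 1), rnorm(40, 4))))
  g3 <- rep(c("a", "b", "c"), each = 40)
  m3 <- fit_lda(x, g3)
  mu <- colMeans(x); W <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  for (lv in unique(g3)) {
    xi <- x[g3 == lv, ]; ci <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, ci))
    B <- B + nrow(xi) * tcrossprod(ci - mu)
  }
  Sw <- W / (nrow(x) - 3); Sb <- B / (nrow(x) - 3)
  Ws <- chol(Sw)
  M <- t(solve(Ws)) %*% Sb %*% solve(Ws)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  expect_equal(m3$eigenvalues, ev$values[1:2], tolerance = 1e-8)
  # axes agree up to sign/scale: compare absolute cosine similarity
  oracle_axes <- solve(Ws) %*% ev$vectors[, 1:2]
  for (j in 1:2) {
    cosang <- abs(sum(m3$axes[, j] * oracle_axes[, j])) /
      sqrt(sum(m3$axes[, j]^2) * sum(oracle_axes[, j]^2))
    expect_equal(cosang, 1, tolerance = 1e-8)
  }
})

test_that("shuffled labels destroy discriminant structure", {
  x <- with_seed_test(9, rbind(cbind(rnorm(100, 0), rnorm(100, 0)),
                               cbind(rnorm(100, 6), rnorm(100, 6))))
  g <- with_seed_test(10, sample(rep(c("a", "b"), each = 100)))
  m <- fit_lda(x, g)
  expect_lt(m$eigenvalues[1], 0.1)
  pred <- classify_lda(m, x)
  ccr <- confusion_and_ccr(g, pred)$overall_ccr
  expect_lt(abs(ccr - 50), 15)
})

test_that("classification agrees with an established LDA on shared assumptions", {
  skip_if_not_installed("MASS")
  tab <- sample_feature_table(80, "BF", taxa = c("Brassica", "Salix",
                                                 "Phacelia"), seed = 13)
  x <- scale(as.matrix(tab[descriptor_names()]))
  m <- fit_lda(x, tab$taxon)
  ours <- classify_lda(m, x)
  ref <- as.character(stats::predict(MASS::lda(x, grouping = tab$taxon))$class)
  expect_gte(mean(ours == ref), 0.99)
})

test_that("nearest-centroid assignment honours distances and tie-breaking", {
  cent <- matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE)
  m <- structure(list(axes = diag(2), eigenvalues = c(1, 1),
                      centroids = cent, labels = c("first", "second"),
                      centre = c(0, 0)), class = "lda_model")
  expect_equal(classify_lda(m, matrix(c(0, 0), 1)), "first")
  expect_equal(classify_lda(m, matrix(c(10, 0), 1)), "second")
  expect_equal(classify_lda(m, matrix(c(5, 0), 1)), "first")  # midpoint tie
  expect_error(classify_lda(m, matrix(1, 1, 3)), "columns")

  # far-separated clouds classify essentially perfectly
  x <- with_seed_test(11, rbind(cbind(rnorm(200, -20), rnorm(200)),
                                cbind(rnorm(200, 20), rnorm(200))))
  g <- rep(c("a", "b"), each = 200)
  fit <- fit_lda(x, g)
  expect_gte(confusion_and_ccr(g, classify_lda(fit, x))$overall_ccr, 99)
})

test_that("confusion matrices count and rate as defined", {
  g <- rep(letters[1:7], each = 10)
  cm <- confusion_and_ccr(g, g)
  expect_equal(cm$overall_ccr, 100)
  expect_equal(unname(rowSums(cm$counts)), rep(10L, 7))

  allb <- rep("a", 70)
  cm2 <- confusion_and_ccr(g, allb)
  expect_equal(cm2$overall_ccr, 100 / 7, tolerance = 1e-9)

  expect_error(confusion_and_ccr(g, rep("zz", 70)), "outside")
})

test_that("the CCR of the full chain is invariant to affine descriptor rescaling", {
  tab <- sample_feature_table(60, "Ph", seed = 19)
  base <- classify_taxa(tab)$ccr
  tab2 <- tab
  shift <- with_seed_test(20, runif(30, -5, 5))
  scale_f <- with_seed_test(21, runif(30, 0.1, 10))
  for (j in seq_along(descriptor_names())) {
    d <- descriptor_names()[j]
    tab2[[d]] <- tab2[[d]] * scale_f[j] + shift[j]
  }
  expect_equal(classify_taxa(tab2)$ccr, base, tolerance = 1e-8)
})

test_that("classification accuracy rises with class separation", {
  tight <- taxon_book("BF"); tight$sd <- tight$sd * 0.5
  wide <- taxon_book("BF"); wide$sd <- wide$sd * 3
  ccr_tight <- classify_taxa(sample_feature_table(80, "BF", book = tight,
                                                  seed = 23))$ccr
  ccr_wide <- classify_taxa(sample_feature_table(80, "BF", book = wide,
                                                 seed = 23))$ccr
  expect_gt(ccr_tight, ccr_wide)
})
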