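#' All-pairs Tukey HSD with compact letter display
#'
#' One-way ANOVA on a single descriptor across taxa followed by all-pairs
#' Tukey HSD (Tukey-Kramer for unequal group sizes), summarised as a compact
#' letter display: two taxa share no letter exactly when their adjusted
#' p-value is below \code{alpha}. Letters are assigned by the insert-and-absorb
#' algorithm, ordered by decreasing group mean.
#'
#' @param table feature-table data.frame.
#' @param descriptor one of \code{\link{descriptor_names}()}.
#' @param alpha significance level (default 0.05).
#' @param group_col grouping column (default \code{"taxon"}).
#' @return object of class \code{"tukey_grouping"}: data.frame \code{summary}
#'   (taxon, n, mean, sd, letters), matrix \code{p_values}, \code{alpha}.
#' @export
tukey_letters <- function(table, descriptor, alpha = 0.05,
                          group_col = "taxon") {
  if (!descriptor %in% names(table))
    stop_pollen("no descriptor column '%s'", descriptor)
  y <- table[[descriptor]]
  g <- factor(table[[group_col]])
  if (nlevels(g) < 2L) stop_pollen("tukey_letters: need >= 2 groups")
  if (any(tabulate(g) < 2L)) stop_pollen("tukey_letters: every group needs n >= 2")
  if (all(tapply(y, g, stats::var) == 0))
    stop_pollen("tukey_letters: zero within-group variance everywhere")
  fit <- stats::aov(y ~ g)
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  lev <- levels(g)
  k <- length(lev)
  P <- matrix(1, k, k, dimnames = list(lev, lev))
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    P[a, b] <- P[b, a] <- hsd[i, "p adj"]
  }
  means <- tapply(y, g, mean)
  ord <- order(means, decreasing = TRUE)
  letters_list <- cld_insert_absorb(P[ord, ord, drop = FALSE] < alpha)
  letters <- stats::setNames(letters_list[match(lev, lev[ord])], lev)
  structure(list(
    summary = data.frame(taxon = lev, n = as.integer(tabulate(g)),
                         mean = as.numeric(means),
                         sd = as.numeric(tapply(y, g, stats::sd)),
                         letters = unname(letters),
                         stringsAsFactors = FALSE),
    p_values = P, alpha = alpha, descriptor = descriptor
  ), class = "tukey_grouping")
}

# insert-and-absorb compact letter display.
# signif: k x k logical matrix (TRUE = significantly different), groups ordered
# as they should receive letters. Returns a character vector of letter strings.
cld_insert_absorb <- function(signif) {
  k <- nrow(signif)
  cols <- list(rep(TRUE, k))            # start: one letter containing all
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!signif[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        c1 <- col; c1[j] <- FALSE
        c2 <- col; c2[i] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    # absorb: drop any column whose membership is a subset of another's
    drop <- rep(FALSE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && !drop[a] && !drop[b] &&
          all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
        drop[a] <- TRUE
      if (a != b && !drop[a] && !drop[b] && identical(cols[[a]], cols[[b]]) &&
          a > b)
        drop[a] <- TRUE
    }
    cols <- cols[!drop]
  }
  # order columns by first member, assign letters
  first <- vapply(cols, function(cc) which(cc)[1], 1L)
  cols <- cols[order(first)]
  out <- character(k)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters[ci])
  out
}

#' @export
print.tukey_grouping <- function(x, ...) {
  cat(sprintf("Tukey HSD grouping for '%s' (alpha = %g)\n", x$descriptor,
              x$alpha))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Factor analysis of a descriptor table
#'
#' Principal-axis extraction from the correlation matrix of the standardized
#' descriptors (no rotation): eigenvalues in decreasing order, eigenvectors,
#' loadings (sqrt(eigenvalue) times eigenvector component, i.e. the
#' factor-variable correlations), and factor scores (standardized data times
#' eigenvectors, so score covariance is diag(eigenvalues)).
#'
#' @param x numeric matrix or data.frame of descriptor columns (a feature
#'   table's metadata columns are dropped automatically).
#' @return object of class \code{"factor_model"}.
#' @export
fit_factor_model <- function(x) {
  if (is.data.frame(x)) x <- x[, setdiff(names(x), feature_meta_cols())]
  x <- as.matrix(x)
  stopifnot(is.numeric(x), nrow(x) >= 3)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_pollen("constant column(s): %s",
                paste(colnames(x)[sds == 0], collapse = ", "))
  R <- stats::cor(x)
  e <- eigen(R, symmetric = TRUE)
  vecs <- e$vectors
  colnames(vecs) <- paste0("F", seq_len(ncol(vecs)))
  rownames(vecs) <- colnames(x)
  loadings <- sweep(vecs, 2, sqrt(pmax(e$values, 0)), `*`)
  z <- scale(x)
  scores <- z %*% vecs
  structure(list(correlation = R, eigenvalues = e$values,
                 eigenvectors = vecs, loadings = loadings, scores = scores,
                 centre = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale")),
            class = "factor_model")
}

#' Factor retention rule
#'
#' Retains every factor with eigenvalue above 1 plus every factor that carries
#' the maximum squared factor-variable correlation for at least one original
#' variable; returned in ascending index order.
#'
#' @param model a \code{\link{fit_factor_model}} result.
#' @return integer vector of retained factor indices.
#' @export
retain_factors <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  kaiser <- which(model$eigenvalues > 1)
  l2 <- model$loadings^2
  maxload <- apply(l2, 1, which.max)
  sort(unique(c(kaiser, maxload)))
}

#' Standardized scores of retained factors
#'
#' @param model a \code{factor_model}.
#' @param retained factor indices (default \code{\link{retain_factors}}).
#' @return n x q matrix of unit-variance factor scores.
#' @export
factor_scores <- function(model, retained = NULL) {
  if (is.null(retained)) retained <- retain_factors(model)
  sweep(model$scores[, retained, drop = FALSE], 2,
        sqrt(model$eigenvalues[retained]), `/`)
}

#' Linear discriminant axes from within/between scatter
#'
#' Solves the eigenproblem of (within-group scatter)^-1 (between-group
#' scatter). Axes with eigenvalue above 1e-10 are kept (at most
#' min(p, k - 1)), and each axis is normalized so the pooled within-class
#' variance along it is 1, which makes nearest-centroid assignment by
#' Euclidean distance the standard rule.
#'
#' @param scores n x p numeric matrix.
#' @param labels group labels, every class with n >= 2.
#' @param ridge relative ridge added when the within scatter is singular.
#' @return object of class \code{"lda_model"}: \code{axes} (p x q),
#'   \code{eigenvalues}, \code{centroids} (k x q, in discriminant space),
#'   \code{labels}.
#' @export
fit_lda <- function(scores, labels, ridge = 1e-8) {
  x <- as.matrix(scores)
  g <- factor(labels)
  stopifnot(nrow(x) == length(g), nlevels(g) >= 2)
  if (any(tabulate(g) < 2L)) stop_pollen("fit_lda: every class needs n >= 2")
  p <- ncol(x); n <- nrow(x); k <- nlevels(g)
  mu <- colMeans(x)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lv in levels(g)) {
    xi <- x[g == lv, , drop = FALSE]
    ci <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, ci))
    B <- B + nrow(xi) * tcrossprod(ci - mu)
  }
  Sw <- W / (n - k)
  ok <- FALSE
  Swr <- Sw
  for (try in 1:2) {
    ev <- tryCatch(eigen(solve(Swr, B / (n - k))), error = function(e) NULL)
    if (!is.null(ev)) { ok <- TRUE; break }
    Swr <- Sw + ridge * mean(diag(Sw)) * diag(p)
  }
  if (!ok) stop_pollen("fit_lda: within-group scatter is singular even after ridging")
  vals <- Re(ev$values); vecs <- Re(ev$vectors)
  ord <- order(vals, decreasing = TRUE)
  vals <- vals[ord]; vecs <- vecs[, ord, drop = FALSE]
  q <- min(sum(vals > 1e-10), p, k - 1L)
  if (q < 1L) stop_pollen("fit_lda: no discriminant structure (all eigenvalues null)")
  vecs <- vecs[, seq_len(q), drop = FALSE]
  vals <- vals[seq_len(q)]
  # scale axes to unit pooled within-class variance
  for (j in seq_len(q)) {
    wv <- drop(t(vecs[, j]) %*% Swr %*% vecs[, j])
    vecs[, j] <- vecs[, j] / sqrt(wv)
  }
  cent <- t(vapply(levels(g),
                   function(lv) colMeans(x[g == lv, , drop = FALSE] %*% vecs),
                   numeric(q)))
  if (q == 1L) cent <- matrix(cent, ncol = 1L,
                              dimnames = list(levels(g), NULL))
  structure(list(axes = vecs, eigenvalues = vals, centroids = cent,
                 labels = levels(g), centre = mu),
            class = "lda_model")
}

#' Nearest-centroid classification in discriminant space
#'
#' Projects rows onto the discriminant axes and assigns each to the class with
#' the nearest centroid (Euclidean; ties go to the lexicographically first
#' label).
#'
#' @param model an \code{\link{fit_lda}} result.
#' @param scores n x p matrix in the space the model was fitted on.
#' @return character vector of class labels.
#' @export
classify_lda <- function(model, scores) {
  stopifnot(inherits(model, "lda_model"))
  x <- as.matrix(scores)
  if (ncol(x) != nrow(model$axes))
    stop_pollen("classify_lda: expected %d columns, got %d",
                nrow(model$axes), ncol(x))
  proj <- x %*% model$axes
  d2 <- outer(rowSums(proj^2), rep(1, nrow(model$centroids))) -
    2 * proj %*% t(model$centroids) +
    outer(rep(1, nrow(proj)), rowSums(model$centroids^2))
  # centroids are ordered by sorted label, so which.min ties pick the first
  model$labels[apply(d2, 1, which.min)]
}

#' Confusion matrix and correct classification rate
#'
#' Rows are the true taxa, columns the assigned taxa; per-class CCR is the
#' diagonal over the row sum, overall CCR the trace over the total, both in
#' percent.
#'
#' @param true_labels,predicted_labels equal-length label vectors; predictions
#'   outside the true label set (plus \code{labels}) are an error.
#' @param labels optional fixed label order.
#' @return object of class \code{"confusion_matrix"}: \code{counts},
#'   \code{per_class_ccr}, \code{overall_ccr}.
#' @export
confusion_and_ccr <- function(true_labels, predicted_labels, labels = NULL) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (is.null(labels)) labels <- sort(unique(as.character(true_labels)))
  bad <- setdiff(unique(as.character(predicted_labels)), labels)
  if (length(bad))
    stop_pollen("predicted label(s) outside the class set: %s",
                paste(bad, collapse = ", "))
  tt <- table(factor(true_labels, levels = labels),
              factor(predicted_labels, levels = labels))
  counts <- matrix(as.integer(tt), nrow(tt), ncol(tt),
                   dimnames = dimnames(tt))
  per <- 100 * diag(counts) / pmax(rowSums(counts), 1)
  structure(list(counts = counts, per_class_ccr = per,
                 overall_ccr = 100 * sum(diag(counts)) / sum(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix (overall CCR %.2f%%)\n", x$overall_ccr))
  print(x$counts)
  invisible(x)
}

#' Factor-retention + discriminant classification of a feature table
#'
#' The multivariate chain of the study: standardize descriptors, factor
#' analysis, retain factors by the eigenvalue/max-correlation rule, linear
#' discriminant analysis on the standardized retained factor scores, and
#' resubstitution classification (optionally k-fold cross-validated).
#'
#' @param table feature-table data.frame with a \code{taxon} column.
#' @param cv_folds 0 for resubstitution CCR (the default, matching the study's
#'   single reported rate); > 1 for k-fold cross-validated CCR.
#' @param seed fold-assignment seed when cross-validating.
#' @return list: \code{factor_model}, \code{retained}, \code{lda},
#'   \code{confusion} (resubstitution), \code{ccr} (percent), and
#'   \code{ccr_cv} when cross-validated.
#' @export
classify_taxa <- function(table, cv_folds = 0L, seed = 1L) {
  validate_feature_table(table)
  fm <- fit_factor_model(table)
  retained <- retain_factors(fm)
  sc <- factor_scores(fm, retained)
  lda <- fit_lda(sc, table$taxon)
  pred <- classify_lda(lda, sc)
  conf <- confusion_and_ccr(table$taxon, pred)
  out <- list(factor_model = fm, retained = retained, lda = lda,
              confusion = conf, ccr = conf$overall_ccr)
  if (cv_folds > 1L) {
    n <- nrow(table)
    fold <- with_seed(derive_seed(seed, "cvfolds"),
                      sample(rep_len(seq_len(cv_folds), n)))
    pred_cv <- character(n)
    for (f in seq_len(cv_folds)) {
      tr <- table[fold != f, , drop = FALSE]
      fm_f <- fit_factor_model(tr)
      ret_f <- retain_factors(fm_f)
      lda_f <- fit_lda(factor_scores(fm_f, ret_f), tr$taxon)
      te <- as.matrix(table[fold == f, setdiff(names(table),
                                               feature_meta_cols())])
      z <- sweep(sweep(te, 2, fm_f$centre), 2, fm_f$scale, `/`)
      sc_te <- sweep((z %*% fm_f$eigenvectors)[, ret_f, drop = FALSE], 2,
                     sqrt(fm_f$eigenvalues[ret_f]), `/`)
      pred_cv[fold == f] <- classify_lda(lda_f, sc_te)
    }
    out$confusion_cv <- confusion_and_ccr(table$taxon, pred_cv)
    out$ccr_cv <- out$confusion_cv$overall_ccr
  }
  out
}
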