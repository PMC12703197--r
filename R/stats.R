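#' Spearman rank correlation
#'
#' Computes the rank correlation as the product-moment correlation of the
#' mid-ranks (ties averaged): with ranks x', y' and rank means m_x', m_y',
#' rho = sum((x'-m_x')(y'-m_y')) / sqrt(sum((x'-m_x')^2) sum((y'-m_y')^2)).
#' The p-value uses the large-sample t approximation with n - 2 degrees of
#' freedom (the behaviour of `cor.test(..., method = "spearman")` on tied
#' data of this size).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return an object of class `spearman_result`: list with `rho`, `p_value`,
#'   `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  rho <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d, p = %.3g)\n", x$rho, x$n,
              x$p_value))
  invisible(x)
}

#' Ordinary least squares fit with studentized residuals
#'
#' Fits `y ~ x` by [stats::lm()] and packages the quantities the downstream
#' outlier test needs: slope, intercept, adjusted R^2 (with n - 2 residual
#' degrees of freedom), raw residuals, and externally studentized residuals.
#'
#' @param x,y numeric vectors of equal length >= 3; `x` must not be constant.
#' @return an object of class `regression_fit`: list with `slope`,
#'   `intercept`, `r2`, `adjusted_r2`, `residuals`, `studentized_residuals`,
#'   `n`, `lm` (the underlying fit).
#' @export
fit_linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L) stop("constant x: singular design")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r2 = s$r.squared, adjusted_r2 = s$adj.r.squared,
                 residuals = unname(stats::residuals(fit)),
                 studentized_residuals = unname(stats::rstudent(fit)),
                 n = length(x), lm = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: y = %.4g + %.4g x (n = %d, adj. R^2 = %.4f)\n",
              x$intercept, x$slope, x$n, x$adjusted_r2))
  invisible(x)
}

#' Bonferroni outlier test on a regression fit
#'
#' For each observation, a two-sided p-value is computed from its externally
#' studentized residual against a t distribution with n - 3 degrees of
#' freedom, then Bonferroni-adjusted by the number of observations (capped at
#' 1). Up to `n_max` observations with adjusted p below `alpha` are reported,
#' largest absolute studentized residual first — the behaviour of the
#' standard regression-deletion outlier test.
#'
#' @param fit a `regression_fit` (or an `lm` on one predictor) with >= 4
#'   observations.
#' @param n_max maximum number of outliers reported (default 3).
#' @param alpha significance cutoff on the adjusted p (default 0.05).
#' @return an object of class `outlier_report`: list with `indices`,
#'   `studentized`, `p_raw`, `p_bonferroni`, `n`, `n_max`, `alpha`.
#' @export
bonferroni_outlier_test <- function(fit, n_max = 3L, alpha = 0.05) {
  if (inherits(fit, "lm")) {
    rs <- unname(stats::rstudent(fit))
    res <- unname(stats::residuals(fit))
    fv <- unname(stats::fitted(fit))
    n <- length(rs)
  } else {
    stopifnot(inherits(fit, "regression_fit"))
    rs <- fit$studentized_residuals
    res <- fit$residuals
    fv <- unname(stats::fitted(fit$lm))
    n <- fit$n
  }
  if (n <= 3L) stop("need more than 3 observations for the outlier test")
  # an (essentially) exact fit has only numerical-noise residuals, whose
  # studentized values are meaningless ratios: nothing to report
  if (max(abs(res)) <= sqrt(.Machine$double.eps) * max(1, abs(fv)))
    rs[] <- 0
  # a deletion fit with zero residual variance yields NaN: infinitely
  # discrepant if the point itself misfits beyond numerical noise,
  # irrelevant if the whole fit is exact
  bad <- !is.finite(rs)
  tol <- sqrt(.Machine$double.eps) * max(1, abs(res))
  rs[bad] <- ifelse(abs(res[bad]) > tol, sign(res[bad]) * Inf, 0)
  df <- n - 3L
  p_raw <- 2 * stats::pt(-abs(rs), df = df)
  p_bonf <- pmin(1, n * p_raw)
  ord <- order(-abs(rs))
  sig <- ord[p_bonf[ord] < alpha]
  sig <- utils::head(sig, n_max)
  structure(list(indices = sig, studentized = rs[sig], p_raw = p_raw[sig],
                 p_bonferroni = p_bonf[sig], n = n, n_max = n_max,
                 alpha = alpha),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  if (!length(x$indices)) {
    cat("No outliers at adjusted p <", x$alpha, "\n")
  } else {
    cat("Bonferroni outliers (largest |studentized residual| first):\n")
    for (i in seq_along(x$indices))
      cat(sprintf("  obs %d: t = %.3f, adj. p = %.3g\n",
                  x$indices[i], x$studentized[i], x$p_bonferroni[i]))
  }
  invisible(x)
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail probability of observing at least `overlap` shared genes
#' between two sets drawn from a common universe: P(X >= overlap) with X ~
#' Hypergeometric(universe, set_a_size, set_b_size).
#'
#' @param set_a_size,set_b_size sizes of the two gene sets.
#' @param overlap observed overlap (0 <= overlap <= min of sizes).
#' @param universe universe size (>= both set sizes).
#' @return an object of class `enrichment_result`: list with `overlap`,
#'   `set_a_size`, `set_b_size`, `universe`, `p_value`.
#' @export
hypergeometric_overlap <- function(set_a_size, set_b_size, overlap, universe) {
  if (overlap > min(set_a_size, set_b_size) || overlap < 0)
    stop("overlap must lie in [0, min(set sizes)]")
  if (set_a_size > universe || set_b_size > universe)
    stop("set sizes cannot exceed the universe")
  p <- stats::phyper(overlap - 1, set_a_size, universe - set_a_size,
                     set_b_size, lower.tail = FALSE)
  structure(list(overlap = overlap, set_a_size = set_a_size,
                 set_b_size = set_b_size, universe = universe, p_value = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric overlap: %d of (%d, %d) in universe %d, p = %.4g\n",
              x$overlap, x$set_a_size, x$set_b_size, x$universe, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Substitution-score principal component analysis of an alignment
#'
#' Builds the symmetric species-by-species matrix of pairwise similarity
#' scores obtained by summing BLOSUM62 substitution scores over the chosen
#' sites, then eigendecomposes it. By default the matrix is double-centered
#' first (the classical multidimensional-scaling convention, which removes
#' the dominant overall-similarity component); `center = FALSE`
#' decomposes the raw score matrix. Coordinates are eigenvector times the
#' square root of the (non-negative) eigenvalue.
#'
#' Gap scoring: a pair involving `-` scores the minimum of the substitution
#' matrix (default -4); a pair involving `X` scores 0. Both are configurable.
#'
#' @param aln an amino-acid `multiple_alignment` with >= 3 species.
#' @param sites 1-based site indices to score (default: all).
#' @param center double-center the score matrix before decomposition.
#' @param gap_score,ambiguous_score scores for pairs involving `-` / `X`.
#' @return an object of class `pca_result`: list with `scores` (the species
#'   matrix), `eigenvalues` (descending), `coordinates` (species x PCs for
#'   non-negative eigenvalues), `center`.
#' @export
blosum62_pca <- function(aln, sites = NULL, center = TRUE,
                         gap_score = NULL, ambiguous_score = 0) {
  stopifnot(inherits(aln, "multiple_alignment"),
            alignment_level(aln) == "amino_acid")
  if (nrow(aln) < 3L) stop("need at least 3 species")
  sites <- sites %||% seq_len(ncol(aln))
  if (any(sites < 1L | sites > ncol(aln))) stop("site index out of range")
  blosum <- get_blosum62()
  if (is.null(gap_score)) gap_score <- min(blosum)
  sp <- rownames(aln)
  n <- nrow(aln)
  S <- matrix(0, n, n, dimnames = list(sp, sp))
  sub <- unclass(aln)[, sites, drop = FALSE]
  for (i in seq_len(n)) for (j in i:n) {
    a <- sub[i, ]; b <- sub[j, ]
    sc <- numeric(length(a))
    gap <- a == "-" | b == "-"
    amb <- !gap & (a == "X" | b == "X")
    ok <- !gap & !amb
    sc[gap] <- gap_score
    sc[amb] <- ambiguous_score
    if (any(ok)) sc[ok] <- blosum[cbind(a[ok], b[ok])]
    S[i, j] <- S[j, i] <- sum(sc)
  }
  M <- if (center) {
    H <- diag(n) - matrix(1 / n, n, n)
    H %*% S %*% H
  } else S
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  pos <- eig$values > max(abs(eig$values)) * 1e-12
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  rownames(coords) <- sp
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(scores = S, eigenvalues = eig$values,
                 coordinates = coords, center = center),
            class = "pca_result")
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d species, %d retained component(s)\n",
              nrow(x$scores), ncol(x$coordinates)))
  ev <- utils::head(x$eigenvalues, 5L)
  cat("  leading eigenvalues:", paste(signif(ev, 4), collapse = ", "), "\n")
  invisible(x)
}
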