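# Phylogenetic generalized least squares with maximum-likelihood Pagel's
# lambda, plus the supporting transforms: body-mass residualization of drum
# speed, the collinearity screen, and log10 variable transforms.

#' Read a rooted phylogeny from a Newick file
#'
#' @param path Path to a Newick tree file.
#' @return An \pkg{ape} `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("cannot read tree file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse Newick tree: ", path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("tip labels must be unique")
  tr
}

#' Phylogenetic covariance matrix in a given species order
#'
#' `C[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of species `i` and `j`; the diagonal holds root-to-tip
#' depths. Tips absent from `species` are pruned; species absent from the
#' tree raise an error naming them. Names are normalised case-insensitively
#' with underscores treated as spaces.
#'
#' @param tree A `phylo` tree.
#' @param species Character vector of species names fixing the row order.
#' @return Covariance matrix with `species` as dimnames.
#' @export
phylo_covariance <- function(tree, species) {
  key <- .normalize_species(species)
  tipkey <- .normalize_species(tree$tip.label)
  if (anyDuplicated(tipkey)) stop("tree tips not unique after normalization")
  hit <- match(key, tipkey)
  if (anyNA(hit))
    stop("species missing from tree: ",
         paste(species[is.na(hit)], collapse = ", "))
  drop <- tree$tip.label[-hit]
  if (length(drop) > 0) tree <- ape::drop.tip(tree, drop)
  C <- ape::vcv.phylo(tree)
  ord <- match(key, .normalize_species(rownames(C)))
  C <- C[ord, ord, drop = FALSE]
  dimnames(C) <- list(species, species)
  C
}

.normalize_species <- function(x) tolower(gsub("_", " ", trimws(x)))

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged: `lambda = 1` is the full Brownian covariance, `lambda = 0` a
#' star phylogeny.
#'
#' @param C Covariance matrix.
#' @param lambda Signal strength in `[0, 1]`.
#' @return The transformed matrix `C(lambda)`.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  out <- lambda * C
  diag(out) <- diag(C)
  out
}

#' Generalized least squares with a fixed error covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma^2 V)`, by Cholesky whitening.
#' `sigma^2` is reported as the ML estimate `e' V^-1 e / n`; standard
#' errors use the unbiased `n/(n - p)` correction, with two-sided t tests
#' on `n - p` degrees of freedom. With `V = I` this reduces exactly to
#' ordinary least squares.
#'
#' @param X Design matrix (including the intercept column).
#' @param y Response vector.
#' @param V Positive-definite error covariance (up to scale).
#' @return List with `coefficients` (term, estimate, se, t, p),
#'   `sigma2_ml`, `logLik`, `rss_w` (whitened residual sum of squares),
#'   `residuals` (original scale), `fitted`, `n`, `p`.
#' @export
gls_fit <- function(X, y, V) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("dimensions of X, y and V must agree")
  U <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite: ", conditionMessage(e)))
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qrx <- qr(Xw)
  if (qrx$rank < ncol(X))
    stop("design matrix is rank deficient (rank ", qrx$rank, " < ",
         ncol(X), ")")
  beta <- qr.coef(qrx, yw)
  ew <- yw - Xw %*% beta
  rss_w <- sum(ew^2)
  p <- ncol(X)
  sigma2_ml <- rss_w / n
  s2 <- rss_w / (n - p)
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(s2 * diag(XtX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  ldetV <- 2 * sum(log(diag(U)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + ldetV + n)
  terms <- colnames(X)
  if (is.null(terms)) terms <- paste0("x", seq_len(p))
  list(
    coefficients = data.frame(
      term = terms, estimate = as.numeric(beta), se = se,
      t = as.numeric(tval), p = as.numeric(pval), row.names = NULL
    ),
    sigma2_ml = sigma2_ml, logLik = ll, rss_w = rss_w,
    residuals = as.numeric(y - X %*% beta),
    fitted = as.numeric(X %*% beta), n = n, p = p
  )
}

#' Phylogenetic GLS with maximum-likelihood Pagel's lambda
#'
#' Profiles the GLS log-likelihood over `lambda` in `[0, 1]` (bounded 1-D
#' optimization, tolerance 1e-6, endpoints included) and reports the fit at
#' the maximizing value. The model F statistic compares the fit against the
#' intercept-only GLS under the same `V(lambda_hat)`, computed in the
#' whitened space: `F = [(TSS_w - RSS_w)/(p - 1)] / [RSS_w/(n - p)]`.
#'
#' @param X Design matrix including an intercept column.
#' @param y Response vector.
#' @param C Phylogenetic covariance matrix in the row order of `X`.
#' @param lambda `"ml"` (default) or a fixed value in `[0, 1]`.
#' @return An object of class `pgls_fit`.
#' @export
pgls_ml <- function(X, y, C, lambda = "ml") {
  X <- as.matrix(X)
  if (length(y) < 4) stop("at least 4 species are required")
  prof <- function(lam) gls_fit(X, y, lambda_transform(C, lam))$logLik
  if (identical(lambda, "ml")) {
    opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-6)
    cand <- c(0, opt$maximum, 1)
    ll <- c(prof(0), opt$objective, prof(1))
    if (diff(range(ll)) < 1e-10) {
      warning("profile likelihood is flat in lambda; using lambda = 1")
      lam_hat <- 1
    } else {
      lam_hat <- cand[which.max(ll)]
    }
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be \"ml\" or a value in [0, 1]")
    lam_hat <- lambda
  }
  V <- lambda_transform(C, lam_hat)
  fit <- gls_fit(X, y, V)
  n <- fit$n; p <- fit$p
  # intercept-only baseline under the same covariance
  null_fit <- gls_fit(matrix(1, n, 1), y, V)
  tss_w <- null_fit$rss_w
  df1 <- p - 1
  df2 <- n - p
  if (df1 > 0) {
    Fstat <- ((tss_w - fit$rss_w) / df1) / (fit$rss_w / df2)
    model_p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  } else {
    Fstat <- NA_real_
    model_p <- NA_real_
  }
  structure(list(
    coefficients = fit$coefficients,
    lambda = lam_hat,
    F = Fstat, df = c(df1, df2), model_p = model_p,
    sigma2_ml = fit$sigma2_ml, logLik = fit$logLik,
    residuals = fit$residuals, fitted = fit$fitted, n = n
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "PGLS fit (n = %d)\nLambda: %.3f, F-statistic: %.3f, %d and %d d.f., p-value: %.4g\n",
    x$n, x$lambda, x$F, x$df[1], x$df[2], x$model_p))
  tab <- x$coefficients
  tab[, -1] <- round(tab[, -1], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Residualize drum speed on body mass
#'
#' Ordinary (non-phylogenetic) simple linear regression of (log) drum speed
#' on (log) body mass; the residuals serve as mass-corrected relative
#' speed. A phylogenetic variant is available by supplying a covariance
#' matrix `C`.
#'
#' @param speed,mass Numeric vectors (already log-transformed).
#' @param C Optional phylogenetic covariance; if given, a GLS regression is
#'   used instead of OLS.
#' @return Residual speeds (same order as input).
#' @export
mass_correct <- function(speed, mass, C = NULL) {
  if (stats::var(mass) == 0) stop("body mass has zero variance")
  X <- cbind(intercept = 1, mass = mass)
  if (is.null(C)) {
    as.numeric(stats::lm.fit(X, speed)$residuals)
  } else {
    gls_fit(X, speed, C)$residuals
  }
}

#' Collinearity screen of model predictors
#'
#' Pearson correlations among the (transformed) predictors, flagging any
#' pair at or above the conventional `|r| >= 0.7` concern threshold.
#'
#' @param predictors Data frame or matrix of numeric predictors (>= 2).
#' @param threshold Absolute correlation flag threshold.
#' @return List with `correlations` (symmetric, unit diagonal), `flagged`
#'   (data frame of flagged pairs) and `ok` (`TRUE` when nothing flagged).
#' @export
collinearity_screen <- function(predictors, threshold = 0.7) {
  m <- as.matrix(predictors)
  if (ncol(m) < 2) stop("at least two predictors are required")
  r <- stats::cor(m)
  idx <- which(abs(r) >= threshold & upper.tri(r), arr.ind = TRUE)
  flagged <- data.frame(
    var1 = colnames(r)[idx[, 1]],
    var2 = colnames(r)[idx[, 2]],
    r = r[idx]
  )
  list(correlations = r, flagged = flagged, ok = nrow(flagged) == 0)
}

#' Log10-transform modelled variables
#'
#' Applies `log10(x)` to each named continuous column; columns containing
#' zeros get `log10(x + offset)` (recorded in the `offsets` attribute).
#' Negative values are an error. A `habitat` column, if present, is
#' dummy-coded `closed = 0`, `open = 1` and is not logged.
#'
#' @param table Data frame of species traits.
#' @param columns Character vector of columns to transform (default: all
#'   numeric columns except `habitat`).
#' @param offset Offset added to columns containing zeros (default 0.01).
#' @return The transformed data frame, with an `offsets` attribute naming
#'   the columns that received the offset.
#' @export
transform_variables <- function(table, columns = NULL, offset = 0.01) {
  if (is.null(columns))
    columns <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                       "habitat")
  offs <- character(0)
  for (cl in columns) {
    x <- table[[cl]]
    if (any(x < 0)) stop("column '", cl, "' has negative values; cannot log")
    if (any(x == 0)) {
      x <- x + offset
      offs <- c(offs, cl)
    }
    table[[cl]] <- log10(x)
  }
  if ("habitat" %in% names(table) && !is.numeric(table[["habitat"]])) {
    hab <- as.character(table[["habitat"]])
    if (!all(hab %in% c("closed", "open")))
      stop("habitat must be 'closed' or 'open'")
    table[["habitat"]] <- as.numeric(hab == "open")
  }
  attr(table, "offsets") <- offs
  table
}
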