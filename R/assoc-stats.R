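#' Latent expression factors by residualised SVD
#'
#' Residualises each gene's expression on the known covariates,
#' standardises genes, and returns the top left singular directions over
#' individuals. These act as surrogate variables for unwanted technical
#' and biological variation in the cis-eQTL model.
#'
#' @param expression numeric matrix, genes x individuals.
#' @param covariates optional data.frame of known covariates
#'   (individuals in rows).
#' @param n_factors number of factors (`< n_individuals`); 0 gives an
#'   empty factor matrix.
#' @return orthonormal matrix individuals x `n_factors`.
#' @export
estimate_latent_factors <- function(expression, covariates = NULL,
                                    n_factors) {
  E <- as.matrix(expression)
  n <- ncol(E)
  if (n_factors >= n) stop("n_factors must be smaller than n_individuals")
  if (n_factors == 0L) {
    return(matrix(0, n, 0, dimnames = list(colnames(E), NULL)))
  }
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  Rres <- t(stats::lm.fit(X, t(E))$residuals)  # genes x individuals
  sds <- apply(Rres, 1L, stats::sd)
  keep <- sds > 0
  Z <- Rres[keep, , drop = FALSE] / sds[keep]
  if (n_factors >= qr(Z)$rank) {
    stop("n_factors is not below the rank of the residual matrix")
  }
  sv <- svd(t(Z), nu = n_factors, nv = 0)
  f <- sv$u
  dimnames(f) <- list(colnames(E), paste0("factor", seq_len(n_factors)))
  f
}

#' Benjamini-Hochberg q-values
#'
#' @param p_values vector of p-values in `(0, 1]`.
#' @return step-up q-values (monotone in p).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# residualize columns of M on design X; returns a matrix with M's
# column names (lm.fit drops dimensions for single-column responses)
residualize <- function(M, X) {
  M <- as.matrix(M)
  r <- as.matrix(stats::lm.fit(X, M)$residuals)
  colnames(r) <- colnames(M)
  r
}

#' Additive-model cis-eQTL scan
#'
#' Tests every variant-gene pair whose variant lies within `window` bp of
#' the gene's TSS with ordinary least squares of expression on allele
#' dosage, adjusting for covariates (and latent factors, passed in as
#' covariate columns). Variants below the minor-allele-frequency threshold
#' are excluded (attribute `"excluded"`). All tested pairs form a single
#' BH family.
#'
#' @param dosages numeric matrix individuals x variants with entries in
#'   `[0, 2]` (column names = variant ids).
#' @param variant_pos named bp positions of the variants.
#' @param expression numeric matrix genes x individuals.
#' @param tss named bp TSS positions per gene.
#' @param covariates optional data.frame (individuals in rows).
#' @param window cis window around the TSS in bp (default 500000).
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @return data.frame of association records: `variant`, `gene`, `beta`,
#'   `se`, `stat`, `p`, `q`, `n`.
#' @export
cis_eqtl_scan <- function(dosages, variant_pos, expression, tss,
                          covariates = NULL, window = 5e5, maf_min = 0.05) {
  D <- as.matrix(dosages)
  if (any(D < 0 | D > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  E <- as.matrix(expression)
  n <- nrow(D)
  if (ncol(E) != n) stop("individuals misaligned between inputs")
  maf <- pmin(colMeans(D) / 2, 1 - colMeans(D) / 2)
  excl <- colnames(D)[maf < maf_min]
  D <- D[, maf >= maf_min, drop = FALSE]
  if (ncol(D) == 0L) stop("no variant passes the MAF filter")
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  k <- qr(X)$rank
  Dr <- residualize(D, X)
  Er <- residualize(t(E), X)            # individuals x genes
  df <- n - k - 1L
  recs <- list()
  for (v in colnames(D)) {
    genes <- names(tss)[abs(variant_pos[[v]] - tss) <= window]
    genes <- intersect(genes, rownames(E))
    if (length(genes) == 0L) next
    x <- Dr[, v]
    ssx <- sum(x^2)
    if (ssx < 1e-12) next
    for (g in genes) {
      y <- Er[, g]
      beta <- sum(x * y) / ssx
      rss <- sum((y - beta * x)^2)
      se <- sqrt(rss / df / ssx)
      tval <- beta / se
      recs[[length(recs) + 1L]] <- data.frame(
        variant = v, gene = g, beta = beta, se = se, stat = tval,
        p = 2 * stats::pt(-abs(tval), df), n = n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0L) stop("no variant-gene pair within the cis window")
  out <- do.call(rbind, recs)
  out$q <- bh_fdr(out$p)
  out <- out[, c("variant", "gene", "beta", "se", "stat", "p", "q", "n")]
  attr(out, "excluded") <- excl
  out
}

#' Conditional effect of a variant given other variants
#'
#' Re-estimates the target variant's effect with the conditioning dosages
#' appended to the covariates.
#'
#' @param target numeric dosage vector of the variant of interest.
#' @param conditioning numeric matrix (or vector) of conditioning dosages.
#' @param y response vector (e.g. expression).
#' @param covariates optional data.frame.
#' @return one-row data.frame: `beta`, `se`, `stat`, `p`, `n`.
#' @export
conditional_effect <- function(target, conditioning, y, covariates = NULL) {
  Z <- as.matrix(conditioning)
  for (j in seq_len(ncol(Z))) {
    if (isTRUE(all.equal(as.numeric(target), as.numeric(Z[, j])))) {
      stop("conditioning set contains the target variant itself")
    }
  }
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  Xfull <- cbind(X, Z)
  res_t <- stats::lm.fit(Xfull, target)$residuals
  if (sum(res_t^2) < 1e-10 * sum(target^2)) {
    stop("target is collinear with the conditioning set")
  }
  fit <- stats::lm.fit(cbind(Xfull, target = target), y)
  k <- fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - k)
  ssx <- sum(res_t^2)
  beta <- fit$coefficients[["target"]]
  se <- sqrt(sigma2 / ssx)
  tval <- beta / se
  data.frame(beta = beta, se = se, stat = tval,
             p = 2 * stats::pt(-abs(tval), n - k), n = n)
}

#' Kinship mixed-model association test
#'
#' Fits `y = X b + dosage * beta + g + e` with `g ~ N(0, sigma_g^2 K)` by
#' single-component restricted maximum likelihood on the eigenbasis of the
#' kinship matrix, and reports a Wald test for the dosage term. With
#' `K = I` the fit collapses to ordinary least squares.
#'
#' @param y trait vector.
#' @param dosage genotype dosage vector.
#' @param covariates optional data.frame.
#' @param kinship symmetric positive semi-definite kinship matrix.
#' @return object of class `kinship_lmm_fit`: list with `beta`, `se`, `p`
#'   (dosage term), `fixed` (all fixed effects), `sigma_g2`, `sigma_e2`,
#'   `lambda` (variance ratio), `n`.
#' @export
lmm_test <- function(y, dosage, covariates = NULL, kinship) {
  n <- length(y)
  K <- as.matrix(kinship)
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kinship must be symmetric")
  ek <- eigen(K, symmetric = TRUE)
  if (min(ek$values) < -1e-8) stop("kinship must be positive semi-definite")
  X <- if (is.null(covariates)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")) else
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  X <- cbind(X, dosage = dosage)
  U <- ek$vectors; d <- pmax(ek$values, 0)
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  reml <- function(loglam) {
    lam <- exp(loglam)           # sigma_g^2 / sigma_e^2
    w <- 1 / (lam * d + 1)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    b <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% b
    rss <- sum(w * r^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(s2) - sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(reml, interval = c(-12, 12), maximum = TRUE)
  lam <- exp(opt$maximum)
  w <- 1 / (lam * d + 1)
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  b <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% b
  s2e <- sum(w * r^2) / (n - p)
  V <- solve(XtWX) * s2e
  se <- sqrt(diag(V))
  z <- b[p] / se[p]
  structure(list(beta = b[p], se = se[p],
                 p = 2 * stats::pnorm(-abs(z)),
                 fixed = stats::setNames(drop(b), colnames(X)),
                 sigma_g2 = lam * s2e, sigma_e2 = s2e, lambda = lam,
                 n = n),
            class = "kinship_lmm_fit")
}

#' Proportional-odds ordinal regression of severity
#'
#' Fits a proportional-odds model of an ordered outcome on a predictor
#' plus covariates by maximum likelihood (two-category outcomes reduce to
#' binary logistic regression).
#'
#' @param severity ordered factor (or coercible) outcome.
#' @param predictor numeric predictor (e.g. haplotype dosage).
#' @param covariates optional data.frame.
#' @return one-row data.frame: `beta`, `se`, `ci_lo`, `ci_hi`, `p`, `n`,
#'   with threshold estimates in attribute `"thresholds"` (when `> 2`
#'   categories).
#' @export
ordinal_logistic <- function(severity, predictor, covariates = NULL) {
  yv <- if (is.ordered(severity)) severity else
    ordered(severity, levels = unique(severity))
  yv <- droplevels(yv)
  if (nlevels(yv) < 2L) stop("outcome has a single category")
  dat <- data.frame(.y = yv, .x = predictor)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  rhs <- paste(setdiff(names(dat), ".y"), collapse = " + ")
  if (nlevels(yv) == 2L) {
    dat$.y <- as.integer(dat$.y) - 1L
    fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)), data = dat,
                      family = stats::binomial())
    co <- summary(fit)$coefficients
    beta <- co[".x", 1]; se <- co[".x", 2]
    th <- NULL
  } else {
    fit <- tryCatch(
      MASS::polr(stats::as.formula(paste(".y ~", rhs)), data = dat,
                 Hess = TRUE),
      error = function(e) stop("proportional-odds fit failed: ",
                               conditionMessage(e)))
    beta <- fit$coefficients[[".x"]]
    se <- sqrt(diag(stats::vcov(fit))[".x"])
    th <- fit$zeta
  }
  out <- data.frame(beta = beta, se = se,
                    ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                    p = 2 * stats::pnorm(-abs(beta / se)),
                    n = nrow(dat), row.names = NULL)
  attr(out, "thresholds") <- th
  out
}

#' Additive modifier test within genotype strata
#'
#' Within each homozygous stratum of a background genotype, fits a
#' logistic regression of case status on the modifier dosage (plus
#' covariates) and reports the per-stratum odds ratio with its CI. Strata
#' without modifier variation get an explicit no-variation record.
#'
#' @param status binary 0/1 outcome.
#' @param modifier numeric modifier dosage.
#' @param stratum factor (or vector) of stratum membership; `NA` rows are
#'   dropped.
#' @param covariates optional data.frame.
#' @return data.frame with one row per stratum: `stratum`, `n`, `beta`,
#'   `se`, `or`, `ci_lo`, `ci_hi`, `p`, `note`.
#' @export
stratified_additive_test <- function(status, modifier, stratum,
                                     covariates = NULL) {
  st <- factor(stratum)
  rows <- list()
  for (lv in levels(st)) {
    sel <- which(st == lv)
    if (length(sel) == 0L) next
    if (stats::var(modifier[sel]) == 0) {
      rows[[lv]] <- data.frame(stratum = lv, n = length(sel),
                               beta = NA_real_, se = NA_real_, or = NA_real_,
                               ci_lo = NA_real_, ci_hi = NA_real_,
                               p = NA_real_, note = "no modifier variation",
                               stringsAsFactors = FALSE)
      next
    }
    dat <- data.frame(.y = status[sel], .x = modifier[sel])
    if (!is.null(covariates)) {
      dat <- cbind(dat, as.data.frame(covariates)[sel, , drop = FALSE])
    }
    rhs <- paste(setdiff(names(dat), ".y"), collapse = " + ")
    fit <- suppressWarnings(
      stats::glm(stats::as.formula(paste(".y ~", rhs)), data = dat,
                 family = stats::binomial()))
    co <- summary(fit)$coefficients
    beta <- co[".x", 1]; se <- co[".x", 2]
    rows[[lv]] <- data.frame(stratum = lv, n = length(sel), beta = beta,
                             se = se, or = exp(beta),
                             ci_lo = exp(beta - 1.96 * se),
                             ci_hi = exp(beta + 1.96 * se),
                             p = 2 * stats::pnorm(-abs(beta / se)),
                             note = if (se > 10) "possible separation" else "",
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Monte Carlo global-null test over correlated traits
#'
#' Computes the probability, under a correlated multivariate-normal null,
#' of observing at least `k` of `m` two-sided tests with `p < alpha`.
#' Draws `z ~ MVN(0, R)` and counts draws whose exceedance count reaches
#' `k`.
#'
#' @param p_values observed per-trait p-values (used to default `k`), or
#'   `NULL` if `k` is given.
#' @param R trait correlation matrix (unit diagonal, positive
#'   semi-definite).
#' @param alpha per-test level (default 0.05).
#' @param k exceedance count tested (default: observed `sum(p < alpha)`).
#' @param n_draws Monte Carlo draws (default 1e6; `< 1e4` warns).
#' @param seed integer seed.
#' @return object of class `global_null_result`: list with `m`, `alpha`,
#'   `k`, `p` (Monte Carlo tail probability), `se` (binomial standard
#'   error), `n_draws`, `seed`, `R`.
#' @export
global_null_test <- function(p_values = NULL, R, alpha = 0.05, k = NULL,
                             n_draws = 1e6, seed = NULL) {
  R <- as.matrix(R)
  m <- nrow(R)
  if (!isSymmetric(unname(R), tol = 1e-8) ||
      any(abs(diag(R) - 1) > 1e-8)) {
    stop("R must be a symmetric unit-diagonal correlation matrix")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("R must be positive semi-definite")
  if (is.null(k)) {
    if (is.null(p_values)) stop("supply p_values or k")
    k <- sum(p_values < alpha)
  }
  if (k > m) stop("k cannot exceed the number of traits")
  if (n_draws < 1e4) warning("fewer than 1e4 Monte Carlo draws")
  if (!is.null(seed)) set.seed(seed)
  if (k == 0L) {
    return(structure(list(m = m, alpha = alpha, k = 0L, p = 1, se = 0,
                          n_draws = as.integer(n_draws), seed = seed, R = R),
                     class = "global_null_result"))
  }
  Rh <- tryCatch(chol(R), error = function(e) {
    e2 <- eigen(R, symmetric = TRUE)
    t(e2$vectors %*% (sqrt(pmax(e2$values, 0)) * t(e2$vectors)))
  })
  zcrit <- stats::qnorm(1 - alpha / 2)
  hits <- 0
  block <- 1e5
  done <- 0
  while (done < n_draws) {
    b <- min(block, n_draws - done)
    Z <- matrix(stats::rnorm(b * m), b, m) %*% Rh
    hits <- hits + sum(rowSums(abs(Z) > zcrit) >= k)
    done <- done + b
  }
  p <- hits / n_draws
  structure(list(m = m, alpha = alpha, k = as.integer(k), p = p,
                 se = sqrt(p * (1 - p) / n_draws),
                 n_draws = as.integer(n_draws), seed = seed, R = R),
            class = "global_null_result")
}

#' @export
print.global_null_result <- function(x, ...) {
  cat(sprintf(
    "global null: P(>= %d of %d tests with p < %.3g) = %.5f (MC se %.2g, %d draws)\n",
    x$k, x$m, x$alpha, x$p, x$se, x$n_draws))
  invisible(x)
}
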