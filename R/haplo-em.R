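# Haplotype codes are bit-encoded integers: site l contributes
# allele_l * 2^(l-1). Strings like "01011" are the user-facing form.

hap_code <- function(alleles) {
  as.integer(drop(alleles %*% 2^(seq_along(alleles) - 1L)))
}

hap_string <- function(code, L) {
  vapply(code, function(cd) {
    paste(bitwAnd(bitwShiftR(cd, seq_len(L) - 1L), 1L), collapse = "")
  }, character(1))
}

hap_code_from_string <- function(s) {
  vapply(strsplit(s, ""), function(a) hap_code(as.integer(a)), integer(1))
}

#' Enumerate haplotype pairs compatible with an unphased genotype
#'
#' Returns every unordered haplotype pair whose site-wise allele sums equal
#' the genotype; missing sites are expanded over both alleles on both
#' haplotypes.
#'
#' @param genotype integer vector with entries 0/1/2/`NA` (alternate-allele
#'   counts at each site).
#' @param max_het cap on ambiguity: the number of heterozygous sites plus
#'   twice the number of missing sites must not exceed this (default 20).
#' @return data.frame with columns `hap1`, `hap2` (allele strings,
#'   `hap1 <= hap2`), and `mult` (2 for heterozygous pairs, 1 for
#'   homozygous pairs).
#' @export
enumerate_compatible_pairs <- function(genotype, max_het = 20) {
  g <- as.integer(genotype)
  L <- length(g)
  if (any(!is.na(g) & (g < 0L | g > 2L))) stop("genotype codes must be 0/1/2/NA")
  n_het <- sum(g == 1L, na.rm = TRUE)
  n_mis <- sum(is.na(g))
  if (n_mis == L) stop("individual with all genotypes missing")
  if (n_het + 2L * n_mis > max_het) {
    stop(sprintf("genotype ambiguity (%d het + %d missing sites) exceeds cap %d",
                 n_het, n_mis, max_het))
  }
  # per-site ordered allele options (a on hap1, b on hap2)
  opts <- lapply(g, function(x) {
    if (is.na(x)) cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 0L, 1L))
    else if (x == 0L) cbind(a = 0L, b = 0L)
    else if (x == 2L) cbind(a = 1L, b = 1L)
    else cbind(a = c(0L, 1L), b = c(1L, 0L))
  })
  a <- matrix(0L, 1, 0); b <- matrix(0L, 1, 0)
  for (l in seq_len(L)) {
    k <- nrow(opts[[l]])
    n0 <- nrow(a)
    a <- cbind(a[rep(seq_len(n0), times = k), , drop = FALSE],
               rep(opts[[l]][, "a"], each = n0))
    b <- cbind(b[rep(seq_len(n0), times = k), , drop = FALSE],
               rep(opts[[l]][, "b"], each = n0))
  }
  code_a <- as.integer(a %*% 2^(seq_len(L) - 1L))
  code_b <- as.integer(b %*% 2^(seq_len(L) - 1L))
  lo <- pmin(code_a, code_b); hi <- pmax(code_a, code_b)
  key <- paste(lo, hi)
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]
  data.frame(hap1 = hap_string(lo, L), hap2 = hap_string(hi, L),
             mult = ifelse(lo == hi, 1L, 2L), stringsAsFactors = FALSE)
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Maximises the multinomial likelihood of unphased multi-site genotypes
#' over haplotype frequencies by expectation-maximisation, starting from
#' uniform frequencies over all haplotypes compatible with the sample.
#' Optionally restarts from Dirichlet-perturbed initialisations to escape
#' symmetric stationary points, keeping the best likelihood.
#'
#' @param genotypes integer matrix individuals x sites with entries
#'   0/1/2/`NA`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param max_het per-individual ambiguity cap (see
#'   [enumerate_compatible_pairs()]).
#' @param n_restarts extra perturbed restarts (default 0: pure uniform
#'   initialisation).
#' @param seed seed for the restarts.
#' @return object of class `haplo_em_fit`: a list with `haplotypes`
#'   (data.frame `haplotype`, `freq`), `posterior` (per-individual
#'   data.frames `hap1`, `hap2`, `prob`), `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `genotypes`.
#' @export
em_haplotype_frequencies <- function(genotypes, tol = 1e-8, max_iter = 5000,
                                     max_het = 20, n_restarts = 0,
                                     seed = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes); L <- ncol(genotypes)
  if (n < 1L) stop("need at least one individual")
  if (tol <= 0) stop("tol must be positive")
  key <- apply(genotypes, 1L, paste, collapse = ",")
  u <- !duplicated(key)
  patt_rows <- which(u)
  patt_of <- match(key, key[u])
  counts <- as.vector(table(factor(patt_of, levels = seq_along(patt_rows))))
  pairs <- lapply(patt_rows, function(i)
    enumerate_compatible_pairs(genotypes[i, ], max_het = max_het))
  # flatten
  pat_id <- rep(seq_along(pairs), vapply(pairs, nrow, integer(1)))
  all_pairs <- do.call(rbind, pairs)
  universe <- sort(unique(c(all_pairs$hap1, all_pairs$hap2)))
  ia <- match(all_pairs$hap1, universe)
  ib <- match(all_pairs$hap2, universe)
  mult <- all_pairs$mult
  H <- length(universe)
  run_em <- function(p) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    repeat {
      it <- it + 1L
      num <- mult * p[ia] * p[ib]
      tot <- as.vector(rowsum(num, pat_id))
      ll <- sum(counts * log(tot))
      if (length(trace) && ll < trace[length(trace)] - 1e-9) {
        stop("EM log-likelihood decreased")  # guarded invariant
      }
      trace <- c(trace, ll)
      w <- num / tot[pat_id] * counts[pat_id]
      p_new <- numeric(H)
      tmp <- rowsum(w, ia)
      p_new[as.integer(rownames(tmp))] <- tmp
      tmp <- rowsum(w, ib)
      p_new[as.integer(rownames(tmp))] <-
        p_new[as.integer(rownames(tmp))] + tmp
      p_new <- p_new / (2 * n)
      if (is.finite(ll) && is.finite(ll_old) &&
          abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
        converged <- TRUE
        p <- p_new
        break
      }
      if (it >= max_iter) { p <- p_new; break }
      ll_old <- ll
      p <- p_new
    }
    list(p = p, loglik = trace[length(trace)], trace = trace,
         n_iter = it, converged = converged)
  }
  starts <- list(rep(1 / H, H))
  if (n_restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(n_restarts)) {
      x <- rgamma(H, shape = 2)
      starts[[r + 1L]] <- x / sum(x)
    }
  }
  best <- NULL
  for (p0 in starts) {
    res <- run_em(p0)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  p <- best$p
  # final posteriors at the converged frequencies
  num <- mult * p[ia] * p[ib]
  tot <- as.vector(rowsum(num, pat_id))
  post_by_pattern <- lapply(seq_along(pairs), function(k) {
    sel <- pat_id == k
    pr <- num[sel] / tot[k]
    keep <- pr > 1e-12
    data.frame(hap1 = all_pairs$hap1[sel][keep],
               hap2 = all_pairs$hap2[sel][keep],
               prob = pr[keep] / sum(pr[keep]),
               stringsAsFactors = FALSE)
  })
  posterior <- post_by_pattern[patt_of]
  names(posterior) <- rownames(genotypes)
  ord <- order(p, decreasing = TRUE)
  structure(list(
    haplotypes = data.frame(haplotype = universe[ord], freq = p[ord],
                            stringsAsFactors = FALSE),
    posterior = posterior,
    loglik = best$loglik, loglik_trace = best$trace,
    n_iter = best$n_iter, converged = best$converged,
    genotypes = genotypes
  ), class = "haplo_em_fit")
}

#' @export
print.haplo_em_fit <- function(x, ...) {
  cat(sprintf("haplo_em_fit: %d haplotypes, logLik %.4f, %d iterations%s\n",
              nrow(x$haplotypes), x$loglik, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  print(utils::head(x$haplotypes, 10))
  invisible(x)
}

#' Summaries of per-individual phase certainty
#'
#' For each individual, takes the maximum posterior probability over its
#' compatible haplotype pairs and summarises these maxima across the
#' cohort.
#'
#' @param fit a `haplo_em_fit` (or a bare list of per-individual posterior
#'   data.frames with a `prob` column).
#' @return list with `median`, `iqr` (`c(q25, q75)`), `min`, and the
#'   per-individual vector `max_posterior`.
#' @export
posterior_quality_summary <- function(fit) {
  post <- if (inherits(fit, "haplo_em_fit")) fit$posterior else fit
  if (length(post) == 0L) stop("empty posterior set")
  mx <- vapply(post, function(d) max(d$prob), numeric(1))
  list(median = stats::median(mx),
       iqr = unname(stats::quantile(mx, c(0.25, 0.75))),
       min = min(mx), max_posterior = mx)
}

#' Posterior-weighted haplotype logistic regression
#'
#' Tests additive haplotype effects on a binary outcome. Each individual is
#' expanded into pseudo-observations, one per compatible haplotype pair,
#' weighted by the pair's posterior probability; a weighted logistic model
#' of the outcome on per-haplotype dosages (relative to a stated reference
#' haplotype) plus covariates is fitted, and the weights and haplotype
#' frequencies are re-computed from the current fit each outer iteration
#' until the coefficients stabilise. Haplotypes below `min_freq` are pooled
#' into a single `rare` class.
#'
#' @param fit a [em_haplotype_frequencies()] result for the cohort.
#' @param outcome binary 0/1 vector, one per individual.
#' @param covariates optional data.frame of covariates.
#' @param reference reference haplotype string (frequency must be
#'   `>= min_freq`).
#' @param min_freq pooling/reporting frequency threshold (default 0.05).
#' @param tol outer-iteration convergence tolerance on coefficients.
#' @param max_iter maximum outer iterations.
#' @return object of class `haplo_glm_fit`: data.frame `effects` with one
#'   row per non-reference haplotype class (`haplotype`, `freq`, `beta`,
#'   `se`, `or`, `ci_lo`, `ci_hi`, `p`, `pooled_rare`), covariate
#'   coefficients in `covariate_effects`, `reference`, `converged`,
#'   `failed` (+`failure_reason`), `n_iter`.
#' @export
haplotype_glm <- function(fit, outcome, covariates = NULL, reference,
                          min_freq = 0.05, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(fit, "haplo_em_fit"))
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  n <- length(fit$posterior)
  if (length(y) != n) stop("outcome length must match individuals")
  freq <- stats::setNames(fit$haplotypes$freq, fit$haplotypes$haplotype)
  if (!reference %in% names(freq)) stop("reference haplotype not observed")
  if (freq[reference] < min_freq) {
    stop(sprintf("reference haplotype frequency %.3f below min_freq %.3f",
                 freq[reference], min_freq))
  }
  common <- names(freq)[freq >= min_freq]
  rare <- setdiff(names(freq), common)
  classes <- c(setdiff(common, reference),
               if (length(rare)) "rare")
  class_of <- stats::setNames(names(freq), names(freq))
  class_of[rare] <- "rare"
  # expanded design: one pseudo-observation per (individual, pair)
  ind_id <- integer(0); h1 <- character(0); h2 <- character(0)
  w0 <- numeric(0)
  for (i in seq_len(n)) {
    d <- fit$posterior[[i]]
    ind_id <- c(ind_id, rep(i, nrow(d)))
    h1 <- c(h1, d$hap1); h2 <- c(h2, d$hap2)
    w0 <- c(w0, d$prob)
  }
  dose <- matrix(0, length(ind_id), length(classes),
                 dimnames = list(NULL, classes))
  for (j in seq_along(classes)) {
    dose[, j] <- (class_of[h1] == classes[j]) + (class_of[h2] == classes[j])
  }
  # drop classes carried by (in posterior expectation) less than one
  # chromosome -- e.g. a pooled-rare class made of phantom haplotypes
  # whose pairs have essentially zero posterior weight
  eff_count <- colSums(dose * w0)
  dropped <- classes[eff_count < 1]
  if (length(dropped)) {
    classes <- setdiff(classes, dropped)
    dose <- dose[, classes, drop = FALSE]
  }
  Xcov <- if (is.null(covariates)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  X <- cbind(Xcov[ind_id, , drop = FALSE], dose)
  yy <- y[ind_id]
  p_cur <- freq
  w <- w0
  beta <- rep(0, ncol(X))
  converged <- FALSE; failed <- FALSE; reason <- NA_character_
  it <- 0L
  pair_prior <- function(p) {
    pr <- p[h1] * p[h2] * ifelse(h1 == h2, 1, 2)
    pr[is.na(pr)] <- 0
    pr
  }
  repeat {
    it <- it + 1L
    g <- suppressWarnings(
      stats::glm.fit(X, yy, weights = w,
                     family = stats::quasibinomial("logit"),
                     control = list(maxit = 50)))
    beta_new <- g$coefficients
    if (anyNA(beta_new)) {
      failed <- TRUE; reason <- "collinear design (aliased coefficient)"
      break
    }
    if (any(abs(beta_new[classes]) > 15)) {
      failed <- TRUE; reason <- "separation (unbounded coefficient)"
      break
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    # E-step: joint posterior of each pair given frequencies and outcome
    mu <- plogis(drop(X %*% beta))
    lik <- ifelse(yy == 1, mu, 1 - mu)
    num <- pair_prior(p_cur) * lik
    tot <- as.vector(rowsum(num, ind_id))
    w <- num / tot[ind_id]
    # frequency update from the posterior
    cnt <- rowsum(c(w, w), c(h1, h2))
    p_cur[] <- 0
    p_cur[rownames(cnt)] <- cnt / (2 * n)
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  eff <- NULL; cov_eff <- NULL
  if (!failed) {
    mu <- plogis(drop(X %*% beta))
    info <- crossprod(X, X * (w * mu * (1 - mu)))
    V <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(V)) {
      failed <- TRUE; reason <- "singular information matrix"
    } else {
      se <- sqrt(diag(V))
      class_freq <- vapply(classes, function(cl)
        sum(p_cur[names(class_of)[class_of == cl]]), numeric(1))
      bj <- beta[classes]; sj <- se[match(classes, colnames(X))]
      eff <- data.frame(
        haplotype = classes, freq = class_freq, beta = bj, se = sj,
        or = exp(bj), ci_lo = bj - 1.96 * sj, ci_hi = bj + 1.96 * sj,
        p = 2 * stats::pnorm(-abs(bj / sj)),
        pooled_rare = classes == "rare",
        row.names = NULL, stringsAsFactors = FALSE)
      covn <- colnames(Xcov)
      cov_eff <- data.frame(term = covn, beta = beta[covn],
                            se = se[match(covn, colnames(X))],
                            row.names = NULL)
    }
  }
  structure(list(effects = eff, covariate_effects = cov_eff,
                 reference = reference, frequencies = p_cur,
                 dropped_classes = dropped,
                 converged = converged, failed = failed,
                 failure_reason = reason, n_iter = it),
            class = "haplo_glm_fit")
}

#' @export
print.haplo_glm_fit <- function(x, ...) {
  if (x$failed) {
    cat("haplo_glm_fit: FAILED -", x$failure_reason, "\n")
  } else {
    cat(sprintf("haplo_glm_fit (reference %s, %d iterations):\n",
                x$reference, x$n_iter))
    print(transform(x$effects,
                    or = sprintf("%.2f [%.2f, %.2f]", or,
                                 exp(ci_lo), exp(ci_hi))))
  }
  invisible(x)
}
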