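# Independent brute-force oracles. These deliberately avoid the package's
# own recursions: HMM quantities come from exhaustive path enumeration,
# EM likelihoods from a grid search over the frequency simplex, and pair
# enumeration from checking all ordered haplotype pairs.

# all donor paths of length L over D states, as a matrix (D^L rows)
all_paths <- function(D, L) {
  as.matrix(expand.grid(rep(list(seq_len(D)), L)))
}

# joint probability of one path under the copying model
path_prob <- function(path, target, donors, distances, rho, theta) {
  D <- nrow(donors); L <- length(target)
  s <- 1 - exp(-rho * distances)
  em <- ifelse(donors[cbind(path, seq_len(L))] == target, 1 - theta, theta)
  pr <- (1 / D) * em[1L]
  if (L > 1L) for (l in 2L:L) {
    tr <- if (path[l] == path[l - 1L]) (1 - s[l - 1L]) + s[l - 1L] / D
          else s[l - 1L] / D
    pr <- pr * tr * em[l]
  }
  pr
}

# exhaustive forward-backward: per-site posterior, total likelihood,
# and the maximum-probability path value
brute_hmm <- function(target, donors, distances, rho, theta) {
  donors <- as.matrix(donors)
  D <- nrow(donors); L <- length(target)
  paths <- all_paths(D, L)
  pr <- apply(paths, 1L, path_prob, target, donors, distances, rho, theta)
  lik <- sum(pr)
  post <- matrix(0, L, D)
  for (l in seq_len(L)) {
    for (d in seq_len(D)) post[l, d] <- sum(pr[paths[, l] == d])
  }
  best <- which.max(pr)
  list(posterior = post / lik, lik = lik, max_path = paths[best, ],
       max_path_prob = pr[best])
}

# all haplotype pairs compatible with genotype g, by checking every
# ordered pair of the full 2^L haplotype universe (L small)
brute_pairs <- function(g) {
  L <- length(g)
  haps <- as.matrix(expand.grid(rep(list(0:1), L)))
  out <- list()
  for (i in seq_len(nrow(haps))) for (j in i:nrow(haps)) {
    sums <- haps[i, ] + haps[j, ]
    ok <- all(is.na(g) | sums == g)
    if (ok) out[[length(out) + 1L]] <- c(
      paste(haps[i, ], collapse = ""), paste(haps[j, ], collapse = ""))
  }
  do.call(rbind, out)
}

# multinomial log-likelihood of unphased genotypes at frequencies p
geno_loglik <- function(genotypes, p) {
  ll <- 0
  for (i in seq_len(nrow(genotypes))) {
    prs <- brute_pairs(genotypes[i, ])
    tot <- 0
    for (r in seq_len(nrow(prs))) {
      mult <- if (prs[r, 1] == prs[r, 2]) 1 else 2
      tot <- tot + mult * p[[prs[r, 1]]] * p[[prs[r, 2]]]
    }
    ll <- ll + log(tot)
  }
  ll
}

# maximum of the genotype log-likelihood over the frequency simplex of
# the given haplotypes, at grid step `step`
grid_loglik_max <- function(genotypes, haplotypes, step = 0.01) {
  H <- length(haplotypes)
  n_units <- round(1 / step)
  if (H == 1L) return(geno_loglik(genotypes, stats::setNames(1, haplotypes)))
  # compositions of n_units into H parts: free H-1 coordinates + remainder
  free <- as.matrix(expand.grid(rep(list(0:n_units), H - 1L)))
  free <- free[rowSums(free) <= n_units, , drop = FALSE]
  comp <- cbind(free, n_units - rowSums(free)) * step
  # vectorised likelihood over the grid
  pair_list <- lapply(seq_len(nrow(genotypes)), function(i)
    brute_pairs(genotypes[i, ]))
  idx <- stats::setNames(seq_len(H), haplotypes)
  ll <- numeric(nrow(comp))
  for (i in seq_along(pair_list)) {
    prs <- pair_list[[i]]
    keep <- prs[, 1] %in% haplotypes & prs[, 2] %in% haplotypes
    prs <- prs[keep, , drop = FALSE]
    tot <- numeric(nrow(comp))
    for (r in seq_len(nrow(prs))) {
      mult <- if (prs[r, 1] == prs[r, 2]) 1 else 2
      tot <- tot + mult * comp[, idx[[prs[r, 1]]]] * comp[, idx[[prs[r, 2]]]]
    }
    ll <- ll + log(tot)
  }
  max(ll[is.finite(ll)])
}
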