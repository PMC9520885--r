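# Li-Stephens copying model: a target chromosome is an imperfect mosaic of
# donor chromosomes. Hidden state at site l = donor being copied; switch
# probability over interval j is s_j = 1 - exp(-rho * d_j) (then a uniform
# donor is chosen), and emissions mismatch the donor allele with
# probability theta. All recursions use per-site rescaling, so locus sizes
# of 1e5 sites do not underflow.

check_painting_inputs <- function(target, donors, distances, rho, theta) {
  donors <- as.matrix(donors)
  if (ncol(donors) != length(target)) stop("site grids of target and donors differ")
  if (nrow(donors) < 1L) stop("need at least one donor")
  if (length(distances) != length(target) - 1L) {
    stop("distances must have length n_sites - 1")
  }
  if (any(distances < 0)) stop("distances must be non-negative")
  if (rho <= 0) stop("switch scale rho must be positive")
  if (theta <= 0 || theta >= 0.5) stop("theta must lie in (0, 0.5)")
  donors
}

#' Copying-model posteriors by scaled forward-backward
#'
#' Computes, for every site, the posterior probability that the target
#' chromosome is copying each donor, under the Li-Stephens HMM with a
#' uniform donor prior. Transition over interval `j`: stay with probability
#' `(1 - s_j) + s_j / D`, move to each other donor with `s_j / D`, where
#' `s_j = 1 - exp(-rho * d_j)` and `D` is the donor count.
#'
#' @param target 0/1 allele vector of the chromosome to paint.
#' @param donors 0/1 matrix, donors x sites (the target must not be
#'   included).
#' @param distances inter-site genetic distances in Morgans.
#' @param rho switch scale (`> 0`).
#' @param theta emission mismatch probability in `(0, 0.5)`.
#' @return object of class `painting`: list with `posterior` (sites x
#'   donors, rows sum to 1), `loglik`, `log_scale` (per-site log scale
#'   factors), `donor_ids`.
#' @export
copying_forward_backward <- function(target, donors, distances, rho, theta) {
  donors <- check_painting_inputs(target, donors, distances, rho, theta)
  D <- nrow(donors); L <- length(target)
  em <- theta + (1 - 2 * theta) * (donors == rep(target, each = D))
  s <- 1 - exp(-rho * distances)
  A <- matrix(0, L, D)
  logc <- numeric(L)
  a <- em[, 1L] / D
  logc[1L] <- log(sum(a)); a <- a / sum(a)
  A[1L, ] <- a
  if (L > 1L) for (l in 2L:L) {
    pred <- (1 - s[l - 1L]) * a + s[l - 1L] / D
    a <- pred * em[, l]
    logc[l] <- log(sum(a)); a <- a / sum(a)
    A[l, ] <- a
  }
  B <- matrix(0, L, D)
  b <- rep(1, D)
  B[L, ] <- b
  if (L > 1L) for (l in (L - 1L):1L) {
    bb <- em[, l + 1L] * b
    b <- (1 - s[l]) * bb + s[l] * mean(bb)
    b <- b / exp(logc[l + 1L])
    B[l, ] <- b
  }
  post <- A * B
  post <- post / rowSums(post)
  donor_ids <- rownames(donors)
  if (is.null(donor_ids)) donor_ids <- paste0("donor", seq_len(D))
  colnames(post) <- donor_ids
  structure(list(posterior = post, loglik = sum(logc), log_scale = logc,
                 donor_ids = donor_ids),
            class = "painting")
}

#' Most probable donor path (Viterbi) under the copying model
#'
#' @inheritParams copying_forward_backward
#' @return list with `path` (donor index per site), `donor_ids`, and
#'   `log_prob` of the best path. Ties are broken toward the lower donor
#'   index.
#' @export
viterbi_copying <- function(target, donors, distances, rho, theta) {
  donors <- check_painting_inputs(target, donors, distances, rho, theta)
  D <- nrow(donors); L <- length(target)
  lem <- log(theta + (1 - 2 * theta) * (donors == rep(target, each = D)))
  s <- 1 - exp(-rho * distances)
  lstay <- log((1 - s) + s / D)
  lmove <- ifelse(s > 0, log(s / D), -Inf)
  delta <- lem[, 1L] - log(D)
  back <- matrix(0L, L, D)
  if (L > 1L) for (l in 2L:L) {
    best_prev <- which.max(delta)  # first max: lowest index on ties
    second <- if (D > 1L) which.max(replace(delta, best_prev, -Inf)) else best_prev
    # best move-source for state d must differ from d
    move_src <- ifelse(seq_len(D) == best_prev, second, best_prev)
    cand_move <- delta[move_src] + lmove[l - 1L]
    stay <- delta + lstay[l - 1L]
    take_stay <- stay >= cand_move  # ties prefer continuity
    back[l, ] <- ifelse(take_stay, seq_len(D), move_src)
    delta <- ifelse(take_stay, stay, cand_move) + lem[, l]
  }
  path <- integer(L)
  path[L] <- which.max(delta)
  if (L > 1L) for (l in L:2L) path[l - 1L] <- back[l, path[l]]
  donor_ids <- rownames(donors)
  if (is.null(donor_ids)) donor_ids <- paste0("donor", seq_len(D))
  list(path = path, donor_ids = donor_ids, log_prob = max(delta))
}

#' Collapse donor posteriors to tag-haplotype labels
#'
#' The posterior of a label at a site is the sum of the posteriors of all
#' donors carrying that label; the per-site call is the maximum-posterior
#' label (ties broken toward the lexicographically smaller label).
#'
#' @param painting a [copying_forward_backward()] result.
#' @param donor_labels character vector of tag-haplotype labels, one per
#'   donor (no `NA`s).
#' @return object of class `label_path`: list with `labels` (per-site
#'   call), `label_posterior` (sites x labels), `switches`
#'   (see [detect_switch_points()] run lazily by callers).
#' @export
label_sites_by_tag_haplotype <- function(painting, donor_labels) {
  stopifnot(inherits(painting, "painting"))
  if (length(donor_labels) != ncol(painting$posterior)) {
    stop("need one label per donor")
  }
  if (anyNA(donor_labels)) stop("unlabeled donor")
  labs <- sort(unique(donor_labels))
  lp <- sapply(labs, function(lb)
    rowSums(painting$posterior[, donor_labels == lb, drop = FALSE]))
  lp <- matrix(lp, ncol = length(labs), dimnames = list(NULL, labs))
  # columns already in lexicographic order, so "first" tie-break is the
  # lexicographically smaller label
  call <- labs[max.col(lp, ties.method = "first")]
  structure(list(labels = call, label_posterior = lp),
            class = "label_path")
}

#' Switch points along a label path
#'
#' @param labels per-site label calls (or a `label_path`).
#' @param positions per-site bp positions (optional).
#' @return data.frame with one row per change of consecutive labels:
#'   `left_site`, `right_site` (1-based site indices flanking the switch
#'   interval), `left_pos`, `right_pos`, `from`, `to`.
#' @export
detect_switch_points <- function(labels, positions = NULL) {
  if (inherits(labels, "label_path")) labels <- labels$labels
  L <- length(labels)
  if (L == 0L) stop("empty label path")
  idx <- which(labels[-1L] != labels[-L])
  if (is.null(positions)) positions <- rep(NA_real_, L)
  data.frame(left_site = idx, right_site = idx + 1L,
             left_pos = positions[idx], right_pos = positions[idx + 1L],
             from = labels[idx], to = labels[idx + 1L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Individuals homozygous for a tag haplotype
#'
#' Works on a phased [haplotype_panel()] (both chromosomes must carry the
#' allele string at the tag sites) or an unphased genotype matrix (the
#' genotype must be homozygous for the string's alleles at every tag
#' site).
#'
#' @param x a [haplotype_panel()] or genotype matrix (individuals x tag
#'   sites, 0/1/2, rownames = ids).
#' @param haplotype tag-haplotype allele string, e.g. `"11100"`.
#' @param tag_sites tag-site indices (panels default to their own).
#' @return character vector of individual ids.
#' @export
select_homozygotes <- function(x, haplotype, tag_sites = NULL) {
  alle <- as.integer(strsplit(haplotype, "")[[1L]])
  if (inherits(x, "haplotype_panel")) {
    lab <- tag_labels(x, tag_sites)
    ids <- unique(x$sample_id)
    ok <- vapply(ids, function(id)
      all(lab[x$sample_id == id] == haplotype), logical(1))
    return(ids[ok])
  }
  g <- as.matrix(x)
  if (!is.null(tag_sites)) g <- g[, tag_sites, drop = FALSE]
  if (ncol(g) != length(alle)) stop("tag sites absent from genotype matrix")
  want <- 2L * alle
  ok <- apply(g, 1L, function(r) all(!is.na(r)) && all(r == want))
  ids <- rownames(g)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(g)))
  ids[ok]
}

#' Painting quality: per-chromosome median of maximum posteriors
#'
#' @param paintings a single `painting` or list of them.
#' @return list with `per_chromosome` (median of per-site maximum
#'   posterior, one per chromosome), `median` and `range` across
#'   chromosomes.
#' @export
painting_quality <- function(paintings) {
  if (inherits(paintings, "painting")) paintings <- list(paintings)
  if (length(paintings) == 0L) stop("need at least one painted chromosome")
  per <- vapply(paintings, function(p)
    stats::median(apply(p$posterior, 1L, max)), numeric(1))
  list(per_chromosome = per, median = stats::median(per), range = range(per))
}

#' Default copying-model parameters for a donor panel
#'
#' `rho` is set so the expected number of switch events across the painted
#' region is about `log(D)` (the coalescent-scale growth of distinct
#' ancestors with donor count `D`); `theta` is half the Watterson-style
#' mutation estimate `1 / sum_{i<D} 1/i`. Both are heuristics meant to be
#' overridden when better values are known.
#'
#' @param n_donors donor count.
#' @param total_distance total genetic length in Morgans.
#' @return list with `rho` and `theta`.
#' @export
default_copying_params <- function(n_donors, total_distance) {
  if (total_distance <= 0) total_distance <- 1e-6
  rho <- max(log(n_donors + 1), 1) / total_distance
  theta <- 0.5 / sum(1 / seq_len(max(1L, n_donors - 1L)))
  theta <- min(max(theta, 1e-6), 0.49)
  list(rho = rho, theta = theta)
}

#' Paint every chromosome of a panel against the others
#'
#' Leave-one-out painting: each target chromosome is painted against all
#' other chromosomes in the donor set (its own row removed). Donor labels
#' are the donors' tag-haplotype strings, so the returned label paths are
#' on the tag-haplotype alphabet.
#'
#' @param panel a [haplotype_panel()] with tag sites and distances.
#' @param targets chromosome row indices to paint (default all).
#' @param donors_rows chromosome rows to use as donors (default all).
#' @param rho,theta copying parameters (default
#'   [default_copying_params()]).
#' @return list with `paintings`, `label_paths` (list of `label_path`),
#'   `labels_matrix` (targets x sites label calls), `quality`, `rho`,
#'   `theta`.
#' @export
paint_panel <- function(panel, targets = NULL, donors_rows = NULL,
                        rho = NULL, theta = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.null(panel$distances)) stop("panel has no genetic distances")
  if (is.null(targets)) targets <- seq_len(nrow(panel$alleles))
  if (is.null(donors_rows)) donors_rows <- seq_len(nrow(panel$alleles))
  defaults <- default_copying_params(length(donors_rows) - 1L,
                                     sum(panel$distances))
  if (is.null(rho)) rho <- defaults$rho
  if (is.null(theta)) theta <- defaults$theta
  lab <- tag_labels(panel)
  paintings <- vector("list", length(targets))
  lpaths <- vector("list", length(targets))
  L <- ncol(panel$alleles)
  labmat <- matrix(NA_character_, length(targets), L)
  for (k in seq_along(targets)) {
    tgt <- targets[k]
    dset <- setdiff(donors_rows, tgt)
    pt <- copying_forward_backward(panel$alleles[tgt, ],
                                   panel$alleles[dset, , drop = FALSE],
                                   panel$distances, rho, theta)
    lp <- label_sites_by_tag_haplotype(pt, lab[dset])
    paintings[[k]] <- pt
    lpaths[[k]] <- lp
    labmat[k, ] <- lp$labels
  }
  rownames(labmat) <- paste0(panel$sample_id[targets], "_",
                             ave(targets, panel$sample_id[targets],
                                 FUN = seq_along))
  list(paintings = paintings, label_paths = lpaths, labels_matrix = labmat,
       quality = painting_quality(paintings), rho = rho, theta = theta)
}
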