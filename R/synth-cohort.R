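#' Simulate a founder haplotype pool
#'
#' Draws independent binary alleles per founder and site. `allele_freq` may
#' be a scalar frequency, a per-site vector, or a function `f(n_sites)`
#' returning per-site frequencies.
#'
#' @param n_founders number of founder chromosomes (`>= 2`).
#' @param n_sites number of sites (`>= 5`).
#' @param allele_freq scalar, vector, or sampler function (default 0.5).
#' @param seed optional integer seed.
#' @return integer 0/1 matrix, founders x sites.
#' @export
simulate_founders <- function(n_founders, n_sites, allele_freq = 0.5,
                              seed = NULL) {
  if (n_founders < 2L) stop("n_founders must be >= 2")
  if (n_sites < 5L) stop("n_sites must be >= 5")
  if (!is.null(seed)) set.seed(seed)
  freq <- if (is.function(allele_freq)) allele_freq(n_sites) else allele_freq
  freq <- rep_len(freq, n_sites)
  if (any(freq < 0 | freq > 1)) stop("allele frequencies must lie in [0, 1]")
  matrix(rbinom(n_founders * n_sites, 1L, rep(freq, each = n_founders)),
         n_founders, n_sites)
}

#' Simulate chromosomes as founder mosaics
#'
#' Each chromosome starts on a uniformly drawn founder; in the interval
#' before site `j + 1` it jumps, with probability `1 - exp(-switch_scale *
#' d_j)`, to a uniformly chosen *different* founder. Observed alleles are
#' the donor's alleles flipped independently with probability
#' `mutation_rate`. The donor path of every chromosome is recorded as the
#' ground truth.
#'
#' @param founders founder pool matrix (rows = founder chromosomes).
#' @param distances inter-site genetic distances in Morgans
#'   (length `ncol(founders) - 1`, all `>= 0`).
#' @param n_chrom number of chromosomes to emit.
#' @param switch_scale recombination scale `rho >= 0`.
#' @param mutation_rate per-site flip probability in `[0, 0.5]`.
#' @param seed optional integer seed.
#' @param positions optional bp positions (default `1..L` spaced 1 kb).
#' @param chrom chromosome name.
#' @return list with `panel` ([haplotype_panel()]) and `truth` (list with
#'   `paths`, a chromosomes x sites matrix of founder indices).
#' @export
simulate_mosaic_panel <- function(founders, distances, n_chrom,
                                  switch_scale = 1, mutation_rate = 0,
                                  seed = NULL, positions = NULL,
                                  chrom = "chr1") {
  founders <- as.matrix(founders)
  K <- nrow(founders); L <- ncol(founders)
  if (length(distances) != L - 1L) stop("distances must have length L - 1")
  if (any(distances < 0)) stop("distances must be non-negative")
  if (switch_scale < 0) stop("switch_scale must be non-negative")
  if (mutation_rate < 0 || mutation_rate > 0.5) {
    stop("mutation_rate must lie in [0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- seq_len(L) * 1000
  s <- 1 - exp(-switch_scale * distances)
  paths <- matrix(0L, n_chrom, L)
  alleles <- matrix(0L, n_chrom, L)
  for (i in seq_len(n_chrom)) {
    path <- integer(L)
    path[1L] <- sample.int(K, 1L)
    if (L > 1L) {
      jumps <- runif(L - 1L) < s
      for (j in seq_len(L - 1L)) {
        path[j + 1L] <- if (jumps[j] && K > 1L) {
          sample(seq_len(K)[-path[j]], 1L)
        } else path[j]
      }
    }
    paths[i, ] <- path
    obs <- founders[cbind(path, seq_len(L))]
    if (mutation_rate > 0) {
      flip <- runif(L) < mutation_rate
      obs <- ifelse(flip, 1L - obs, obs)
    }
    alleles[i, ] <- obs
  }
  panel <- haplotype_panel(alleles, positions, distances = distances,
                           chrom = chrom)
  list(panel = panel, truth = list(paths = paths))
}

#' Inject haplotype-specific variants into a panel
#'
#' Picks `k_variants` monomorphic-reference sites inside `region` and sets
#' the alternate allele with probability `on_freq` on chromosomes whose
#' tag-haplotype label equals `target_label` and `off_freq` on all others.
#' This emulates population-specific variation enriched on one haplotype
#' background, for which the discovery pipeline is then tested.
#'
#' @param panel a [haplotype_panel()] with tag sites.
#' @param target_label tag-haplotype allele string of the carrier haplotype.
#' @param k_variants number of variants to inject.
#' @param on_freq carrier frequency on target-labelled chromosomes.
#' @param off_freq carrier frequency elsewhere (`<= on_freq`).
#' @param region site-index range `c(first, last)` to inject into
#'   (default: between the outermost tag sites).
#' @param seed optional integer seed.
#' @return list with the modified `panel` and `truth` (injected `sites`,
#'   `positions`, `target_label`, and the true critical-segment interval).
#' @export
inject_specific_variants <- function(panel, target_label, k_variants,
                                     on_freq, off_freq = 0, region = NULL,
                                     seed = NULL) {
  if (on_freq < 0 || on_freq > 1 || off_freq < 0 || off_freq > 1) {
    stop("frequencies must lie in [0, 1]")
  }
  if (off_freq > on_freq) stop("on_freq must be >= off_freq")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(region)) region <- range(panel$tag_sites)
  cand <- seq(region[1L], region[2L])
  cand <- cand[colSums(panel$alleles[, cand, drop = FALSE]) == 0L]
  cand <- setdiff(cand, panel$tag_sites)
  if (length(cand) < k_variants) {
    stop(sprintf("region holds only %d monomorphic candidate sites (< %d)",
                 length(cand), k_variants))
  }
  sites <- sort(sample(cand, k_variants))
  lab <- tag_labels(panel)
  on <- lab == target_label
  for (s in sites) {
    pr <- ifelse(on, on_freq, off_freq)
    panel$alleles[, s] <- rbinom(length(pr), 1L, pr)
  }
  list(panel = panel,
       truth = list(sites = sites, positions = panel$positions[sites],
                    target_label = target_label,
                    segment = c(panel$positions[region[1L]],
                                panel$positions[region[2L]])))
}

#' Effect specification for phenotype simulation
#'
#' @param target_hap tag-haplotype label carrying the phenotype effects.
#' @param hap_log_or named per-haplotype log odds ratios on case status
#'   (unnamed haplotypes have effect 0).
#' @param baseline_prev baseline case prevalence on the reference
#'   background.
#' @param eqtl_beta additive dosage effect on the cis-regulated expression
#'   trait (per-allele, in expression SD units).
#' @param trait_beta length-7 vector of dosage effects on the quantitative
#'   traits.
#' @param trait_cor 7 x 7 correlation matrix of the trait noise
#'   (symmetric positive definite, unit diagonal).
#' @param ordinal_beta dosage effect on the latent severity scale.
#' @param ordinal_thresholds two increasing proportional-odds thresholds.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(target_hap,
                        hap_log_or = stats::setNames(log(1.67), target_hap),
                        baseline_prev = 0.3,
                        eqtl_beta = 0.5,
                        trait_beta = c(-0.3, -0.15, 0, 0, -0.25, 0, -0.2),
                        trait_cor = default_trait_cor(),
                        ordinal_beta = 1.58,
                        ordinal_thresholds = qlogis(c(19, 37) / 63)) {
  trait_cor <- as.matrix(trait_cor)
  if (!isSymmetric(unname(trait_cor)) ||
      any(abs(diag(trait_cor) - 1) > 1e-12)) {
    stop("trait_cor must be symmetric with unit diagonal")
  }
  if (min(eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values)
      <= 1e-10) {
    stop("trait_cor must be positive definite")
  }
  if (length(trait_beta) != nrow(trait_cor)) {
    stop("trait_beta length must match trait_cor dimension")
  }
  if (is.unsorted(ordinal_thresholds, strictly = TRUE)) {
    stop("ordinal thresholds must be increasing")
  }
  structure(list(target_hap = target_hap, hap_log_or = hap_log_or,
                 baseline_prev = baseline_prev, eqtl_beta = eqtl_beta,
                 trait_beta = trait_beta, trait_cor = trait_cor,
                 ordinal_beta = ordinal_beta,
                 ordinal_thresholds = ordinal_thresholds),
            class = "effect_spec")
}

#' Default correlation structure of the seven quantitative traits
#'
#' A modest positive-definite structure: the two lung-function traits
#' correlate strongly, inflammation/allergy/immune traits weakly.
#'
#' @return 7 x 7 correlation matrix.
#' @export
default_trait_cor <- function() {
  R <- diag(7)
  R[1, 2] <- R[2, 1] <- 0.6   # FEV1-like vs FEV1/FVC-like
  R[1, 3] <- R[3, 1] <- 0.25
  R[2, 3] <- R[3, 2] <- 0.2
  R[4, 5] <- R[5, 4] <- 0.3   # inflammation vs allergy
  R[5, 6] <- R[6, 5] <- 0.35  # IgE-like vs eosinophils-like
  R[6, 7] <- R[7, 6] <- 0.2
  R
}

#' Simulate phenotypes and covariates for a panel
#'
#' Forward model: case status is Bernoulli with additive haplotype
#' log-odds; one cis-regulated expression trait is linear in target-hap
#' dosage with Gaussian noise; seven quantitative traits are linear in
#' dosage with correlated multivariate normal noise (plus an optional
#' shared polygenic component under a kinship matrix); a 3-level ordinal
#' severity arises from a proportional-odds latent model. Covariates are a
#' binary sex analogue, a 3-level site analogue, and three continuous
#' ancestry-PC analogues, each with small effects on status.
#'
#' @param panel a [haplotype_panel()] with tag sites.
#' @param spec an [effect_spec()].
#' @param seed optional integer seed.
#' @param kinship optional kinship matrix (individuals x individuals)
#'   inducing a polygenic trait component with variance `h2_poly`.
#' @param h2_poly polygenic variance added to each trait when `kinship`
#'   is supplied.
#' @return data.frame with id, status, expression, trait1..7, severity,
#'   covariates, and per-haplotype dosage columns (`dose_<label>`); the
#'   dosage matrix is attached as attribute `"dosages"`.
#' @export
simulate_phenotypes <- function(panel, spec, seed = NULL, kinship = NULL,
                                h2_poly = 0.3) {
  if (!inherits(spec, "effect_spec")) stop("spec must be an effect_spec")
  if (!is.null(seed)) set.seed(seed)
  dos <- haplotype_dosages(panel)
  n <- nrow(dos)
  m <- length(spec$trait_beta)
  sex <- rbinom(n, 1L, 0.5)
  site <- factor(sample(c("A", "B", "C"), n, replace = TRUE))
  pcs <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, paste0("pc", 1:3)))
  beta <- stats::setNames(numeric(ncol(dos)), colnames(dos))
  keep <- intersect(names(spec$hap_log_or), names(beta))
  beta[keep] <- spec$hap_log_or[keep]
  eta <- qlogis(spec$baseline_prev) + drop(dos %*% beta) +
    0.1 * sex + 0.1 * (site == "B") - 0.1 * (site == "C") + 0.05 * pcs[, 1]
  status <- rbinom(n, 1L, plogis(eta))
  d_t <- if (spec$target_hap %in% colnames(dos)) {
    dos[, spec$target_hap]
  } else rep(0L, n)  # target haplotype absent from this population
  expression <- spec$eqtl_beta * d_t + rnorm(n)
  Rc <- chol(spec$trait_cor)
  noise <- matrix(rnorm(n * m), n, m) %*% Rc
  traits <- outer(d_t, spec$trait_beta) + noise
  if (!is.null(kinship)) {
    ek <- eigen(kinship, symmetric = TRUE)
    half <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
    g <- half %*% matrix(rnorm(n * m), n, m) * sqrt(h2_poly)
    traits <- traits + g
  }
  colnames(traits) <- paste0("trait", seq_len(m))
  th <- spec$ordinal_thresholds
  lat <- spec$ordinal_beta * d_t + rlogis(n)
  severity <- ordered(cut(lat, c(-Inf, th, Inf),
                          labels = c("mild", "moderate", "severe")))
  out <- data.frame(id = rownames(dos), status = status,
                    expression = expression, traits, severity = severity,
                    sex = sex, site = site, pcs,
                    stats::setNames(as.data.frame(dos),
                                    paste0("dose_", colnames(dos))),
                    check.names = FALSE)
  attr(out, "dosages") <- dos
  out
}

#' Block-family kinship matrix
#'
#' Builds a block-diagonal kinship matrix with unit diagonal and a constant
#' relatedness coefficient within each family block (0.5 = full sibs).
#'
#' @param block_sizes integer vector of family sizes (`>= 1`).
#' @param relatedness within-block off-diagonal coefficient in `[0, 1)`.
#' @return symmetric positive semi-definite matrix of dimension
#'   `sum(block_sizes)`.
#' @export
simulate_kinship <- function(block_sizes, relatedness = 0.5) {
  if (any(block_sizes < 1L)) stop("block sizes must be >= 1")
  if (relatedness < 0 || relatedness >= 1) {
    stop("relatedness must lie in [0, 1)")
  }
  n <- sum(block_sizes)
  K <- matrix(0, n, n)
  at <- 0L
  for (b in block_sizes) {
    idx <- at + seq_len(b)
    K[idx, idx] <- relatedness
    at <- at + b
  }
  diag(K) <- 1
  K
}

#' Full synthetic-cohort configuration
#'
#' Defaults emulate the study's data structure: a ~300-kb locus, five tag
#' SNPs defining six common core haplotypes, a long-LD population (two
#' haplotypes, few switches per chromosome) and a short-LD population
#' (six haplotypes, frequent switching), nine specific variants injected on
#' the target haplotype at within-carrier frequency 0.85 and 0 elsewhere,
#' a target-haplotype odds ratio of 1.67 on case status, one cis-regulated
#' expression trait plus null genes, seven correlated quantitative traits,
#' and a 3-level ordinal severity with baseline proportions ~(0.30, 0.29,
#' 0.41).
#'
#' @param n_sites number of sites on the locus grid.
#' @param locus_span locus length in bp.
#' @param n_founders_per_hap founder chromosomes carried per tag haplotype.
#' @param pop_long,pop_short per-population settings: lists with
#'   `n_individuals`, `switch_scale`, `mutation_rate`, `hap_freq`
#'   (named tag-haplotype frequencies).
#' @param target_hap the high-risk tag haplotype label.
#' @param k_variants,on_freq,off_freq specific-variant injection settings.
#' @param effects an [effect_spec()] (built with `target_hap` by default).
#' @param n_null_genes number of unregulated expression traits added for
#'   the cis scan.
#' @param family_blocks optional family-block sizes for the kinship matrix
#'   of the short-LD population (`NULL` = unrelated).
#' @param seed global integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 200, locus_span = 3e5,
                       n_founders_per_hap = 2,
                       pop_long = list(n_individuals = 100,
                                       switch_scale = 150,
                                       mutation_rate = 0.001,
                                       hap_freq = c("00000" = 0.55,
                                                    "11111" = 0.45)),
                       pop_short = list(n_individuals = 300,
                                        switch_scale = 600,
                                        mutation_rate = 0.001,
                                        hap_freq = c("00000" = 0.12,
                                                     "11111" = 0.37,
                                                     "10110" = 0.18,
                                                     "11100" = 0.20,
                                                     "11101" = 0.07,
                                                     "11110" = 0.06)),
                       target_hap = "11100",
                       k_variants = 9, on_freq = 0.85, off_freq = 0,
                       effects = effect_spec(target_hap),
                       n_null_genes = 30,
                       family_blocks = NULL,
                       seed = 1) {
  for (p in list(pop_long, pop_short)) {
    if (abs(sum(p$hap_freq) - 1) > 1e-8) {
      stop("population haplotype frequencies must sum to 1")
    }
  }
  if (off_freq > on_freq) stop("on_freq must be >= off_freq")
  tag_sites <- round(seq(0.35, 0.65, length.out = 5) * n_sites)
  structure(list(n_sites = n_sites, locus_span = locus_span,
                 n_founders_per_hap = n_founders_per_hap,
                 tag_sites = tag_sites,
                 pops = list(long = pop_long, short = pop_short),
                 target_hap = target_hap, k_variants = k_variants,
                 on_freq = on_freq, off_freq = off_freq, effects = effects,
                 n_null_genes = n_null_genes,
                 family_blocks = family_blocks, seed = seed),
            class = "sim_config")
}

#' Simulate a complete cohort from a configuration
#'
#' Builds founder pools per tag haplotype, emits mosaic chromosomes for the
#' long-LD and short-LD populations, injects specific variants on the
#' target haplotype in the short-LD population, and simulates phenotypes,
#' covariates and (optionally) kinship. Every stage draws its seed
#' deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (combined [haplotype_panel()]), `phenotypes`
#'   (short-LD population), `phenotypes_long`, `expression` (genes x
#'   individuals, short-LD), `tss`, `kinship` (or `NULL`), `truth`, and
#'   `map` (the recombination map used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$n_sites
  positions <- round(seq(1, config$locus_span, length.out = L))
  # recombination is suppressed inside the core block (the tag-site span
  # plus a 5-kb margin) and elevated in the flanking hotspot regions --
  # the structure that makes the core an LD block in the first place
  core <- c(positions[config$tag_sites[1L]] - 5000,
            positions[config$tag_sites[length(config$tag_sites)]] + 5000)
  rate <- ifelse(positions >= core[1L] & positions <= core[2L], 0.3, 3)
  seg_cM <- c(0, diff(positions)) * rate / 1e6
  map <- data.frame(position_bp = positions,
                    rate_cM_per_Mb = rate,
                    map_cM = cumsum(seg_cM))
  distances <- diff(map$map_cM) / 100
  haps <- unique(c(names(config$pops$long$hap_freq),
                   names(config$pops$short$hap_freq)))
  set.seed(stage_seed(config$seed, "founders"))
  # reserve invariant positions (monomorphic reference, no mutational
  # flips) as candidates for specific-variant injection; denser inside
  # the core span where injection happens
  span <- seq(min(config$tag_sites), max(config$tag_sites))
  in_span <- setdiff(span, config$tag_sites)
  out_span <- setdiff(seq_len(L), c(span, config$tag_sites))
  reserved <- sort(c(sample(in_span, round(0.5 * length(in_span))),
                     sample(out_span, round(0.2 * length(out_span)))))
  founder_list <- list()
  founder_hap <- character(0)
  for (h in haps) {
    f <- simulate_founders(max(2L, config$n_founders_per_hap), L,
                           allele_freq = function(n) runif(n, 0.05, 0.5))
    alle <- as.integer(strsplit(h, "")[[1L]])
    f[, config$tag_sites] <- matrix(alle, nrow(f), 5, byrow = TRUE)
    f[, reserved] <- 0L
    founder_list[[h]] <- f
    founder_hap <- c(founder_hap, rep(h, nrow(f)))
  }
  founders <- do.call(rbind, founder_list)

  # founder choice is uniform in the mosaic model, so the population's
  # tag-haplotype frequencies are realised by replicating founder rows in
  # proportion to the target frequency (50 pool slots per population)
  expand_founders <- function(hap_freq, pool_slots = 50L) {
    idx <- integer(0)
    for (h in names(hap_freq)) {
      slots <- round(hap_freq[[h]] * pool_slots)
      if (slots > 0L) {
        idx <- c(idx, rep_len(which(founder_hap == h), slots))
      }
    }
    idx
  }
  pops <- list()
  for (popname in names(config$pops)) {
    p <- config$pops[[popname]]
    idx <- expand_founders(p$hap_freq)
    sim <- simulate_mosaic_panel(
      founders[idx, , drop = FALSE], distances, 2L * p$n_individuals,
      switch_scale = p$switch_scale, mutation_rate = p$mutation_rate,
      seed = stage_seed(config$seed, paste0("mosaic_", popname)),
      positions = positions)
    sim$panel$alleles[, reserved] <- 0L  # invariant positions stay invariant
    sim$panel$population <- rep(popname, 2L * p$n_individuals)
    sim$panel$sample_id <- rep(sprintf("%s_%03d", toupper(popname),
                                       seq_len(p$n_individuals)), each = 2)
    sim$panel$tag_sites <- config$tag_sites
    pops[[popname]] <- sim
  }
  short <- pops$short$panel
  # truth donor labels per chromosome/site: the tag haplotype of the
  # copied founder
  short_pool_hap <- founder_hap[expand_founders(config$pops$short$hap_freq)]
  truth_labels <- matrix(short_pool_hap[pops$short$truth$paths],
                         nrow(pops$short$truth$paths))
  # inject inside the segment of the locus that target-haplotype
  # homozygote chromosomes truly share (so the injected variants lie in
  # the recoverable critical segment); fall back to the tag span
  lab_short <- tag_labels(short)
  hom_rows <- which(short$sample_id %in%
                      select_homozygotes(short, config$target_hap))
  region <- range(config$tag_sites)
  if (length(hom_rows) >= 2L) {
    shared <- apply(truth_labels[hom_rows, , drop = FALSE] ==
                      config$target_hap, 2L, all)
    mid <- config$tag_sites[ceiling(length(config$tag_sites) / 2)]
    if (shared[mid]) {
      r <- rle(shared)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      hit <- which(r$values & starts <= mid & ends >= mid)
      cand_region <- c(starts[hit], ends[hit])
      n_cand <- sum(colSums(short$alleles[, seq(cand_region[1L],
                                                cand_region[2L]),
                                          drop = FALSE]) == 0L)
      if (n_cand >= config$k_variants) region <- cand_region
    }
  }
  inj <- inject_specific_variants(
    short, config$target_hap, config$k_variants,
    config$on_freq, config$off_freq, region = region,
    seed = stage_seed(config$seed, "inject"))
  short <- inj$panel
  kin <- NULL
  if (!is.null(config$family_blocks)) {
    kin <- simulate_kinship(config$family_blocks)
  }
  phen_short <- simulate_phenotypes(
    short, config$effects, seed = stage_seed(config$seed, "phen_short"),
    kinship = kin)
  phen_long <- simulate_phenotypes(
    pops$long$panel, config$effects,
    seed = stage_seed(config$seed, "phen_long"))
  # expression matrix: cis gene + null genes, TSS spread around the
  # locus; a hidden batch shifts half the genes (the unwanted variation
  # the latent factors are meant to absorb)
  set.seed(stage_seed(config$seed, "expression"))
  n_ind <- length(unique(short$sample_id))
  genes <- c("cis_gene", sprintf("null_gene%02d", seq_len(config$n_null_genes)))
  expr <- rbind(phen_short$expression,
                matrix(rnorm(config$n_null_genes * n_ind),
                       config$n_null_genes, n_ind))
  batch <- rbinom(n_ind, 1L, 0.5)
  affected <- seq_along(genes) %% 2L == 1L
  expr[affected, ] <- expr[affected, ] +
    matrix(0.8 * batch, sum(affected), n_ind, byrow = TRUE)
  dimnames(expr) <- list(genes, unique(short$sample_id))
  tss <- stats::setNames(
    round(seq(positions[1L] - 2e5, positions[L] + 2e5,
              length.out = length(genes))), genes)
  # combined panel for cross-population views
  combined <- haplotype_panel(
    rbind(pops$long$panel$alleles, short$alleles), positions,
    distances = distances,
    sample_id = c(pops$long$panel$sample_id, short$sample_id),
    population = c(pops$long$panel$population, short$population),
    tag_sites = config$tag_sites, chrom = "chrSim")
  list(panel = combined, panel_long = pops$long$panel, panel_short = short,
       phenotypes = phen_short, phenotypes_long = phen_long,
       expression = expr, tss = tss, kinship = kin,
       truth = list(variants = inj$truth,
                    paths_long = pops$long$truth$paths,
                    paths_short = pops$short$truth$paths,
                    truth_labels_short = truth_labels,
                    expression_batch = batch),
       map = map)
}

#' Panel of tag-haplotype homozygote groups over a shared background
#'
#' Builds, for each tag haplotype, `2 * n_homozygotes` chromosomes that
#' share one random background sequence (plus independent per-site noise)
#' and carry the group's alleles at the tag sites. A fraction of sites is
#' kept invariant (reference allele, no noise) to serve as injection
#' candidates. This is the controlled setting for testing consensus
#' building and specific-variant discovery: outside the injected sites
#' the groups differ only at the tag sites.
#'
#' @param group_labels character vector of tag-haplotype strings (equal
#'   length).
#' @param n_homozygotes diploid homozygote count per group (recycled).
#' @param n_sites total sites on the grid.
#' @param noise per-site flip probability at non-invariant, non-tag
#'   sites (default 0.02).
#' @param invariant_frac fraction of sites kept invariant (default 0.3).
#' @param seed optional integer seed.
#' @return a [haplotype_panel()]; chromosome group labels equal
#'   `tag_labels(panel)`.
#' @export
simulate_group_panel <- function(group_labels, n_homozygotes = 18,
                                 n_sites = 120, noise = 0.02,
                                 invariant_frac = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Lt <- nchar(group_labels[1L])
  stopifnot(all(nchar(group_labels) == Lt))
  tag_sites <- round(seq(0.35, 0.65, length.out = Lt) * n_sites)
  n_homozygotes <- rep_len(n_homozygotes, length(group_labels))
  invariant <- sort(sample(setdiff(seq_len(n_sites), tag_sites),
                           round(invariant_frac * n_sites)))
  base <- rbinom(n_sites, 1L, 0.5)
  base[invariant] <- 0L
  rows <- list(); ids <- character(0)
  for (gi in seq_along(group_labels)) {
    g <- group_labels[gi]
    alle <- as.integer(strsplit(g, "")[[1L]])
    for (ch in seq_len(2L * n_homozygotes[gi])) {
      h <- base
      flip <- runif(n_sites) < noise
      flip[c(tag_sites, invariant)] <- FALSE
      h[flip] <- 1L - h[flip]
      h[tag_sites] <- alle
      rows[[length(rows) + 1L]] <- h
    }
    ids <- c(ids, rep(sprintf("G%d_%02d", gi, seq_len(n_homozygotes[gi])),
                      each = 2))
  }
  haplotype_panel(do.call(rbind, rows), positions = seq_len(n_sites) * 1000,
                  distances = rep(1e-5, n_sites - 1L), sample_id = ids,
                  tag_sites = tag_sites, chrom = "chrSim")
}

#' Deterministic per-stage seed derived from a global seed
#'
#' @param global_seed integer global seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483629)
}
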