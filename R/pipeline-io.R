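#' Read a phased panel from a VCF file
#'
#' Accepts biallelic SNP records with phased GT (`a|b`); an unphased
#' genotype or multi-allelic record raises an error naming the offending
#' record.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param region optional `c(start, end)` bp filter.
#' @return a [haplotype_panel()] with two chromosome rows per sample.
#' @export
read_phased_panel <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stop("no records in VCF")
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    i <- which(multi)[1L]
    stop(sprintf("multi-allelic record at %s:%s", fix[i, "CHROM"],
                 fix[i, "POS"]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  unph <- matrix(grepl("/", gt), nrow(gt))
  if (any(unph)) {
    i <- which(unph, arr.ind = TRUE)[1L, ]
    stop(sprintf("unphased genotype '%s' at %s:%s (sample %s)",
                 gt[i[1L], i[2L]], fix[i[1L], "CHROM"], fix[i[1L], "POS"],
                 colnames(gt)[i[2L]]))
  }
  pos <- as.numeric(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) keep <- pos >= region[1L] & pos <= region[2L]
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]
  h1 <- apply(gt, 2L, function(col)
    as.integer(vapply(strsplit(col, "\\|"), `[[`, character(1), 1L)))
  h2 <- apply(gt, 2L, function(col)
    as.integer(vapply(strsplit(col, "\\|"), `[[`, character(1), 2L)))
  n_samp <- ncol(gt)
  alleles <- matrix(0L, 2L * n_samp, length(pos))
  alleles[seq(1L, 2L * n_samp, 2L), ] <- t(h1)
  alleles[seq(2L, 2L * n_samp, 2L), ] <- t(h2)
  haplotype_panel(alleles, pos,
                  sample_id = rep(colnames(gt), each = 2),
                  chrom = fix[keep, "CHROM"][1L],
                  ref = fix[keep, "REF"], alt = alt[keep])
}

#' Write a panel as a phased VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (plain-text VCF).
#' @return `path`, invisibly.
#' @export
write_phased_panel <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  ids <- unique(panel$sample_id)
  L <- ncol(panel$alleles)
  gt_cols <- vapply(ids, function(id) {
    rows <- which(panel$sample_id == id)
    paste0(panel$alleles[rows[1L], ], "|", panel$alleles[rows[2L], ])
  }, character(L))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", panel$chrom),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(panel$chrom, format(panel$positions, scientific = FALSE,
                                    trim = TRUE),
                paste0("site", seq_len(L)), panel$ref, panel$alt,
                ".", "PASS", ".", "GT",
                apply(matrix(gt_cols, nrow = L), 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a 3-column recombination map
#'
#' Whitespace-delimited columns: `position_bp`, `rate_cM_per_Mb`,
#' `map_cM`, positions strictly increasing, rates non-negative. A header
#' line is detected and skipped automatically.
#'
#' @param path file path.
#' @return data.frame of class `recomb_map`.
#' @export
read_recomb_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[0-9]", first)
  m <- utils::read.table(path, header = has_header,
                         col.names = c("position_bp", "rate_cM_per_Mb",
                                       "map_cM"))
  if (is.unsorted(m$position_bp, strictly = TRUE)) {
    stop("map positions must be strictly increasing")
  }
  if (any(m$rate_cM_per_Mb < 0)) stop("negative recombination rate")
  class(m) <- c("recomb_map", class(m))
  m
}

#' Write a recombination map
#' @param map data.frame with `position_bp`, `rate_cM_per_Mb`, `map_cM`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recomb_map <- function(map, path) {
  utils::write.table(map[, c("position_bp", "rate_cM_per_Mb", "map_cM")],
                     path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate a recombination map at site positions
#'
#' Linear interpolation of cumulative cM; positions outside the map range
#' are clamped to the ends with a warning.
#'
#' @param map a [read_recomb_map()] data.frame.
#' @param positions query bp positions.
#' @return list with `cM` (cumulative map at each position) and
#'   `distances` (inter-site distances in Morgans, length `n - 1`).
#' @export
interpolate_map <- function(map, positions) {
  rng <- range(map$position_bp)
  if (any(positions < rng[1L] | positions > rng[2L])) {
    warning("positions outside map range clamped to map ends")
  }
  cm <- stats::approx(map$position_bp, map$map_cM, xout = positions,
                      rule = 2)$y
  list(cM = cm, distances = pmax(diff(cm), 0) / 100)
}

#' Site quality control
#'
#' Removes sites in this order of precedence: duplicated position,
#' non-SNP alleles, invalid alleles (not A/C/G/T), monomorphic genotypes,
#' and call rate below `min_call_rate`. Each removed site is counted
#' under the first rule it violates, so removed + retained equals the
#' input count.
#'
#' @param genotypes matrix individuals x sites with entries 0/1/2/`NA`.
#' @param sites data.frame with per-site `pos`, `ref`, `alt`.
#' @param min_call_rate minimum per-site call rate (default 0.90).
#' @return list with `genotypes`, `sites` (retained), and `report`
#'   (class `qc_report`): counts per removal reason plus `retained` and
#'   `input`.
#' @export
apply_site_qc <- function(genotypes, sites, min_call_rate = 0.90) {
  g <- as.matrix(genotypes)
  stopifnot(nrow(sites) == ncol(g))
  reason <- rep(NA_character_, ncol(g))
  dup <- duplicated(sites$pos)
  nonsnp <- nchar(as.character(sites$ref)) != 1L |
    nchar(as.character(sites$alt)) != 1L
  valid <- c("A", "C", "G", "T")
  invalid <- !(toupper(sites$ref) %in% valid & toupper(sites$alt) %in% valid)
  invalid <- invalid & !nonsnp
  call_rate <- colMeans(!is.na(g))
  mono <- apply(g, 2L, function(x) length(unique(x[!is.na(x)])) <= 1L)
  reason[mono] <- "monomorphic"
  reason[call_rate < min_call_rate] <- "low_call_rate"
  reason[mono & is.na(reason)] <- "monomorphic"
  # precedence: duplicated > non-SNP > invalid > monomorphic > call rate
  reason <- ifelse(dup, "duplicated",
            ifelse(nonsnp, "non_snp",
            ifelse(invalid, "invalid_allele",
            ifelse(mono, "monomorphic",
            ifelse(call_rate < min_call_rate, "low_call_rate",
                   NA_character_)))))
  keep <- is.na(reason)
  counts <- table(factor(reason, levels = c("duplicated", "non_snp",
                                            "invalid_allele", "monomorphic",
                                            "low_call_rate")))
  report <- structure(list(removed = as.list(counts),
                           retained = sum(keep), input = ncol(g)),
                      class = "qc_report")
  list(genotypes = g[, keep, drop = FALSE],
       sites = sites[keep, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("site QC: %d input, %d retained\n", x$input, x$retained))
  for (r in names(x$removed)) {
    if (x$removed[[r]] > 0) cat(sprintf("  removed (%s): %d\n", r,
                                        x$removed[[r]]))
  }
  invisible(x)
}

#' Write an interval as a BED record (0-based half-open)
#' @param interval a `genomic_interval`.
#' @param path output path.
#' @param name feature name.
#' @return `path`, invisibly.
#' @export
write_interval_bed <- function(interval, path, name = "critical_region") {
  writeLines(sprintf("%s\t%d\t%d\t%s", interval$chrom,
                     as.integer(interval$start) - 1L,
                     as.integer(interval$end), name), path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' The file may override any [sim_config()] argument except `effects`
#' (effect-model overrides are taken from an `effects:` block of scalar
#' fields). Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  eff_args <- list()
  if (!is.null(y$effects)) {
    eff_args <- y$effects
    y$effects <- NULL
  }
  for (p in c("pop_long", "pop_short")) {
    if (!is.null(y[[p]]$hap_freq)) {
      y[[p]]$hap_freq <- unlist(y[[p]]$hap_freq)
    }
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (length(eff_args)) {
    if (is.null(eff_args$target_hap)) {
      eff_args$target_hap <- if (!is.null(y$target_hap)) y$target_hap
        else formals(sim_config)$target_hap
    }
    for (nm in c("hap_log_or", "trait_beta", "ordinal_thresholds")) {
      if (!is.null(eff_args[[nm]])) eff_args[[nm]] <- unlist(eff_args[[nm]])
    }
    y$effects <- do.call(effect_spec, eff_args)
  }
  do.call(sim_config, y)
}

# FNV-1a hash of a config for provenance stamping
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 2166136261
  for (ch in s) h <- ((bitwXor(as.integer(h %% 2^31), ch)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full fine-mapping pipeline on a synthetic cohort
#'
#' Chains the stages end-to-end: cohort simulation, haplotype EM and
#' posterior-weighted haplotype regression in each population, copying-
#' model painting of target-haplotype homozygote chromosomes, critical-
#' region delineation and 5% extension, per-group consensus building and
#' specific-variant calling with a per-group frequency table, the
#' cis-eQTL scan with latent factors and BH FDR, quantitative-trait
#' mixed-model tests with the correlated global-null summary, ordinal
#' severity regression, and the stratified additive modifier test. All
#' artifacts are written under `out_dir` and stamped with the config hash
#' and seed.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param n_factors latent factors for the eQTL stage (default 5).
#' @return (invisibly) list of stage results; files are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, n_factors = 5) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(config), seed = config$seed,
                version = as.character(utils::packageVersion("haplofine")))
  log_lines <- character(0)
  logmsg <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste(format(Sys.time(), "%H:%M:%S"), msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  logmsg("simulating cohort (seed %d)", config$seed)
  sim <- stage("simulate", simulate_cohort(config))
  write_phased_panel(sim$panel_short, file.path(out_dir, "panel_short.vcf"))
  write_recomb_map(sim$map, file.path(out_dir, "recomb_map.txt"))
  utils::write.table(sim$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth$variants,
                       file.path(out_dir, "truth.json"), auto_unbox = TRUE)

  # haplotype EM + GLM per population
  em_stage <- function(panel, phen) {
    g <- panel_genotypes(panel)
    em <- em_haplotype_frequencies(g)
    glm_fit <- haplotype_glm(
      em, phen$status,
      covariates = phen[, c("sex", "site")],
      reference = "00000")
    list(em = em, glm = glm_fit,
         quality = posterior_quality_summary(em))
  }
  logmsg("haplotype EM / GLM")
  hap_short <- stage("em-haplo", em_stage(sim$panel_short, sim$phenotypes))
  hap_long <- stage("em-haplo", em_stage(sim$panel_long,
                                         sim$phenotypes_long))
  utils::write.table(hap_short$glm$effects,
                     file.path(out_dir, "haplotype_glm_short.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # painting of homozygote chromosomes, all groups
  logmsg("painting homozygote chromosomes")
  paint <- stage("paint", {
    panel <- sim$panel_short
    lab <- tag_labels(panel)
    ids <- unique(panel$sample_id)
    hom_ids <- list()
    for (h in names(config$pops$short$hap_freq)) {
      hom_ids[[h]] <- select_homozygotes(panel, h)
    }
    targets <- which(panel$sample_id %in% unlist(hom_ids))
    pp <- paint_panel(panel, targets = targets)
    list(pp = pp, targets = targets, hom_ids = hom_ids,
         target_rows = which(panel$sample_id %in%
                               hom_ids[[config$target_hap]]))
  })

  logmsg("critical region")
  crit <- stage("critical-region", {
    rows_in_targets <- match(paint$target_rows, paint$targets)
    labm <- paint$pp$labels_matrix[rows_in_targets, , drop = FALSE]
    # drop recombinant chromosomes: homozygous at the tag SNPs but not
    # painted as the target haplotype across all tag sites
    intact <- apply(labm[, config$tag_sites, drop = FALSE] ==
                      config$target_hap, 1L, all)
    if (sum(intact) >= 2L && any(!intact)) {
      logmsg("dropping %d recombinant target chromosome(s) before segment search",
             sum(!intact))
      labm <- labm[intact, , drop = FALSE]
    }
    seg <- find_shared_segment(labm, config$target_hap,
                               sim$panel_short$positions,
                               chrom = sim$panel_short$chrom)
    if (seg$empty) {
      # no site shared by every homozygote chromosome (possible with
      # small homozygote groups): fall back to examining the tag span
      logmsg("no all-shared segment; falling back to the tag-site span")
      span <- range(config$tag_sites)
      seg <- structure(list(
        chrom = sim$panel_short$chrom,
        start = sim$panel_short$positions[span[1L]],
        end = sim$panel_short$positions[span[2L]],
        width = sim$panel_short$positions[span[2L]] -
          sim$panel_short$positions[span[1L]] + 1,
        start_site = span[1L], end_site = span[2L],
        boundary_evidence = c(left = 0L, right = 0L),
        below_threshold = TRUE, empty = FALSE,
        fallback = "tag_span"), class = "genomic_interval")
    }
    ext <- extend_interval(seg, 0.05,
                           bounds = range(sim$panel_short$positions))
    list(segment = seg, extended = ext)
  })
  write_interval_bed(crit$extended, file.path(out_dir, "critical_region.bed"))

  logmsg("consensus / specific variants")
  calls <- stage("call-variants", {
    panel <- sim$panel_short
    in_region <- which(panel$positions >= crit$extended$start &
                         panel$positions <= crit$extended$end)
    groups <- names(paint$hom_ids)
    cons <- list()
    for (h in groups) {
      rows <- which(panel$sample_id %in% paint$hom_ids[[h]])
      if (length(rows) >= 2L) {
        cons[[h]] <- build_consensus(
          panel$alleles[rows, in_region, drop = FALSE], group = h)
      }
    }
    target_cons <- cons[[config$target_hap]]
    other_cons <- cons[setdiff(names(cons), config$target_hap)]
    sv <- call_specific_variants(target_cons, other_cons,
                                 positions = panel$positions[in_region])
    called_sites <- in_region[sv$specific]
    ft <- frequency_table(panel, tag_labels(panel),
                          sites = if (length(called_sites)) called_sites
                          else in_region[1L])
    truth_sites <- sim$truth$variants$sites
    recall <- if (length(truth_sites))
      mean(truth_sites %in% called_sites) else NA_real_
    precision <- if (length(called_sites))
      mean(called_sites %in% truth_sites) else NA_real_
    # overlap of the examined region with the true injected segment
    tseg <- sim$truth$variants$segment
    ov <- max(0, min(crit$extended$end, tseg[2]) -
                max(crit$extended$start, tseg[1]))
    seg_overlap <- ov / (tseg[2] - tseg[1])
    list(calls = sv, called_sites = called_sites, freq = ft,
         recall = recall, precision = precision,
         segment_overlap = seg_overlap)
  })
  utils::write.table(calls$calls[calls$calls$specific, ],
                     file.path(out_dir, "specific_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant = rownames(calls$freq$freq),
               position = calls$freq$positions,
               calls$freq$freq, check.names = FALSE),
    file.path(out_dir, "frequency_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  logmsg("cis-eQTL scan")
  eqtl <- stage("eqtl", {
    panel <- sim$panel_short
    sites <- if (length(calls$called_sites)) calls$called_sites else
      sim$truth$variants$sites
    dos <- rowsum(panel$alleles[, sites, drop = FALSE] + 0,
                  panel$sample_id)  # individuals x variants
    dos <- dos[sim$phenotypes$id, , drop = FALSE]
    colnames(dos) <- paste0("var_", sites)
    vp <- stats::setNames(panel$positions[sites], colnames(dos))
    covs <- sim$phenotypes[, c("sex", "site", "pc1", "pc2", "pc3")]
    fac <- estimate_latent_factors(sim$expression, covs, n_factors)
    covs2 <- cbind(covs, as.data.frame(fac))
    cis_eqtl_scan(dos, vp, sim$expression, sim$tss, covariates = covs2)
  })
  utils::write.table(eqtl, file.path(out_dir, "eqtl.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  logmsg("trait associations + global null")
  traits <- stage("assoc", {
    phen <- sim$phenotypes
    dvar <- if (length(calls$called_sites)) {
      rowsum(sim$panel_short$alleles[, calls$called_sites[1L]] + 0,
             sim$panel_short$sample_id)[phen$id, 1L]
    } else phen[[paste0("dose_", config$target_hap)]]
    covs <- phen[, c("sex", "site", "pc1", "pc2", "pc3")]
    K <- if (is.null(sim$kinship)) diag(nrow(phen)) else sim$kinship
    tn <- paste0("trait", 1:7)
    recs <- do.call(rbind, lapply(tn, function(tr) {
      f <- lmm_test(phen[[tr]], dvar, covs, K)
      data.frame(trait = tr, beta = f$beta, se = f$se,
                 z = f$beta / f$se, p = f$p)
    }))
    X <- stats::model.matrix(~ ., covs)
    res <- stats::lm.fit(X, as.matrix(phen[, tn]))$residuals
    Rhat <- stats::cor(res)
    gn <- global_null_test(recs$p, Rhat,
                           seed = stage_seed(config$seed, "globalnull"))
    list(records = recs, global_null = gn)
  })
  utils::write.table(traits$records, file.path(out_dir, "trait_assoc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(m = traits$global_null$m, alpha = traits$global_null$alpha,
         k = traits$global_null$k, p = traits$global_null$p,
         se = traits$global_null$se, n_draws = traits$global_null$n_draws,
         seed = traits$global_null$seed),
    file.path(out_dir, "global_null.json"), auto_unbox = TRUE)

  logmsg("severity + stratified tests")
  phen <- sim$phenotypes
  sev <- stage("severity", ordinal_logistic(
    phen$severity, phen[[paste0("dose_", config$target_hap)]],
    phen[, c("sex", "pc1", "pc2", "pc3")]))
  strat <- stage("stratified", {
    g_tag <- panel_genotypes(sim$panel_short)[, 2L]  # background genotype
    modifier <- if (length(calls$called_sites)) {
      rowsum(sim$panel_short$alleles[, calls$called_sites[1L]] + 0,
             sim$panel_short$sample_id)[phen$id, 1L]
    } else phen[[paste0("dose_", config$target_hap)]]
    stratum <- ifelse(g_tag == 0L, "background_00",
                      ifelse(g_tag == 2L, "background_11", NA))
    stratified_additive_test(phen$status, modifier, stratum,
                             phen[, c("sex", "site")])
  })

  summary <- list(
    stamp = stamp,
    haplotype_or_short = as.list(stats::setNames(
      hap_short$glm$effects$or, hap_short$glm$effects$haplotype)),
    posterior_quality = hap_short$quality[c("median", "min")],
    painting_quality = paint$pp$quality[c("median", "range")],
    critical_region = list(
      start = crit$segment$start, end = crit$segment$end,
      width_kb = crit$segment$width / 1000,
      extended_width_kb = crit$extended$width / 1000,
      boundary_evidence = as.list(crit$segment$boundary_evidence)),
    specific_variants = list(n_called = length(calls$called_sites),
                             recall = calls$recall,
                             precision = calls$precision,
                             segment_overlap = calls$segment_overlap),
    eqtl_top = eqtl[which.min(eqtl$p),
                    c("variant", "gene", "beta", "p", "q")],
    global_null_p = traits$global_null$p,
    severity_beta = sev$beta)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(sim = sim, haplotypes = list(short = hap_short,
                                              long = hap_long),
                 painting = paint$pp, critical_region = crit,
                 variant_calls = calls, eqtl = eqtl, traits = traits,
                 severity = sev, stratified = strat, summary = summary))
}
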