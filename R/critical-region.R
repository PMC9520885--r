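#' Maximal segment shared by all target-haplotype chromosomes
#'
#' Scans the per-site label calls of the painted chromosomes of
#' target-haplotype homozygotes for the maximal run of consecutive sites
#' at which *every* chromosome is called the target label. Boundary
#' evidence on each side is the number of distinct chromosomes whose call
#' at the first flanking non-shared site differs from the target label
#' (i.e. observed switch events delimiting the segment). Candidate runs
#' are considered widest-first (ties broken to the left); the first run
#' with both evidence counts `>= min_boundary_events` is returned,
#' otherwise the widest run is returned flagged `below_threshold`.
#'
#' @param labels_matrix character matrix, chromosomes x sites, of per-site
#'   label calls (e.g. `paint_panel()$labels_matrix`).
#' @param target_label the shared label looked for.
#' @param positions per-site bp positions.
#' @param min_boundary_events required switch events per flank (default 2).
#' @param chrom chromosome name for the reported interval.
#' @return object of class `genomic_interval`: list with `chrom`, `start`,
#'   `end` (1-based inclusive bp), `width`, `start_site`, `end_site`,
#'   `boundary_evidence` (`c(left, right)`), `below_threshold`, `empty`.
#' @export
find_shared_segment <- function(labels_matrix, target_label, positions,
                                min_boundary_events = 2, chrom = "chr1") {
  m <- as.matrix(labels_matrix)
  if (nrow(m) < 2L) stop("need at least two chromosomes")
  if (ncol(m) != length(positions)) stop("positions must match site grid")
  shared <- apply(m == target_label, 2L, all)
  if (!any(shared)) {
    return(structure(list(chrom = chrom, start = NA_real_, end = NA_real_,
                          width = 0, start_site = NA_integer_,
                          end_site = NA_integer_,
                          boundary_evidence = c(left = 0L, right = 0L),
                          below_threshold = TRUE, empty = TRUE),
                     class = "genomic_interval"))
  }
  r <- rle(shared)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     len = r$lengths[r$values])
  runs <- runs[order(-runs$len, runs$start), , drop = FALSE]
  evidence <- function(run) {
    left <- if (run$start > 1L) {
      sum(m[, run$start - 1L] != target_label)
    } else 0L
    right <- if (run$end < ncol(m)) {
      sum(m[, run$end + 1L] != target_label)
    } else 0L
    c(left = left, right = right)
  }
  chosen <- NULL; ev <- NULL; below <- TRUE
  for (i in seq_len(nrow(runs))) {
    e <- evidence(runs[i, ])
    if (all(e >= min_boundary_events)) {
      chosen <- runs[i, ]; ev <- e; below <- FALSE
      break
    }
  }
  if (is.null(chosen)) {   # no run meets the threshold: report the widest
    chosen <- runs[1L, ]; ev <- evidence(chosen)
  }
  structure(list(chrom = chrom,
                 start = positions[chosen$start], end = positions[chosen$end],
                 width = positions[chosen$end] - positions[chosen$start] + 1,
                 start_site = chosen$start, end_site = chosen$end,
                 boundary_evidence = ev, below_threshold = below,
                 empty = FALSE),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("genomic_interval: empty (no shared site)\n")
  } else {
    cat(sprintf("genomic_interval: %s:%.0f-%.0f (%.1f kb), evidence L=%d R=%d%s\n",
                x$chrom, x$start, x$end, x$width / 1000,
                x$boundary_evidence[1L], x$boundary_evidence[2L],
                if (isTRUE(x$below_threshold)) " [below evidence threshold]" else ""))
  }
  invisible(x)
}

#' Extend an interval by a fraction of its width per side
#'
#' The per-side extension is `frac * width`, rounded to
#' `per_side_rounding` bp (default 100 bp = 0.1 kb, so a 23.9-kb segment
#' gains 1.2 kb per side and totals 26.3 kb); set `per_side_rounding = 0`
#' for exact arithmetic.
#'
#' @param interval a `genomic_interval` (from [find_shared_segment()]).
#' @param frac per-side extension fraction (`>= 0`, default 0.05).
#' @param per_side_rounding rounding quantum in bp for the per-side
#'   extension.
#' @param bounds optional `c(min, max)` chromosome bounds; extensions are
#'   clipped with a warning.
#' @return the extended `genomic_interval`, with the applied per-side
#'   extension in `$extension`.
#' @export
extend_interval <- function(interval, frac = 0.05, per_side_rounding = 100,
                            bounds = NULL) {
  stopifnot(inherits(interval, "genomic_interval"))
  if (isTRUE(interval$empty)) stop("cannot extend an empty interval")
  if (frac < 0) stop("frac must be non-negative")
  ext <- frac * interval$width
  if (per_side_rounding > 0) {
    ext <- round(ext / per_side_rounding) * per_side_rounding
  }
  out <- interval
  out$start <- interval$start - ext
  out$end <- interval$end + ext
  if (!is.null(bounds)) {
    if (out$start < bounds[1L] || out$end > bounds[2L]) {
      warning("extension clipped at chromosome bounds")
      out$start <- max(out$start, bounds[1L])
      out$end <- min(out$end, bounds[2L])
    }
  }
  out$width <- out$end - out$start + 1  # 1-based inclusive
  out$extension <- ext
  out
}

#' Consensus sequence of one homozygote group
#'
#' Per-site majority allele over the group's chromosomes with its support
#' fraction; exact ties yield the ambiguity code `NA` with support 0.5.
#'
#' @param alleles 0/1 matrix, chromosomes x sites, of the group's phased
#'   alleles over the region of interest.
#' @param group label of the group (carried through for reporting).
#' @return object of class `consensus_sequence`: list with `group`,
#'   `consensus` (integer 0/1 or `NA` per site), `support` (majority
#'   fraction), `ambiguous` (logical), `n_chromosomes`.
#' @export
build_consensus <- function(alleles, group = "group") {
  m <- as.matrix(alleles)
  if (nrow(m) < 2L) stop("need at least two chromosomes in the group")
  n1 <- colSums(m == 1L)
  n0 <- colSums(m == 0L)
  cons <- ifelse(n1 > n0, 1L, ifelse(n0 > n1, 0L, NA_integer_))
  support <- pmax(n0, n1) / (n0 + n1)
  structure(list(group = group, consensus = cons, support = support,
                 ambiguous = is.na(cons), n_chromosomes = nrow(m)),
            class = "consensus_sequence")
}

#' Call variants specific to the target consensus
#'
#' A site is called specific when the target group's consensus allele is
#' unambiguous and differs from the unambiguous consensus allele of
#' *every* other group. Sites ambiguous in any consensus are excluded from
#' calling and reported.
#'
#' @param target a [build_consensus()] result for the target group.
#' @param others list of [build_consensus()] results for the comparison
#'   groups (same site grid).
#' @param positions per-site bp positions (optional).
#' @return data.frame with one row per site: `site`, `position`,
#'   `target_allele`, one `allele_<group>` column per other group,
#'   `ambiguous_any`, `specific`.
#' @export
call_specific_variants <- function(target, others, positions = NULL) {
  stopifnot(inherits(target, "consensus_sequence"))
  L <- length(target$consensus)
  for (o in others) {
    if (length(o$consensus) != L) stop("consensus site grids differ")
  }
  omat <- vapply(others, function(o) o$consensus, integer(L))
  omat <- matrix(omat, nrow = L)
  colnames(omat) <- vapply(others, function(o) o$group, character(1))
  amb <- is.na(target$consensus) | apply(is.na(omat), 1L, any)
  differs <- omat != target$consensus
  specific <- !amb & apply(differs, 1L, all)
  out <- data.frame(site = seq_len(L),
                    position = if (is.null(positions)) NA_real_ else positions,
                    target_allele = target$consensus,
                    stats::setNames(as.data.frame(omat),
                                    paste0("allele_", colnames(omat))),
                    ambiguous_any = amb, specific = specific,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Per-group allele frequency table
#'
#' @param panel a [haplotype_panel()].
#' @param groups character vector assigning each chromosome to a group
#'   (`NA` = unassigned, dropped).
#' @param sites site indices of the variants to tabulate.
#' @param effect_allele allele counted as the effect allele (default 1).
#' @return object of class `frequency_table`: list with `freq` (variants x
#'   groups matrix), `group_sizes` (chromosome counts, i.e. `2n`),
#'   `positions`.
#' @export
frequency_table <- function(panel, groups, sites, effect_allele = 1L) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (length(groups) != nrow(panel$alleles)) {
    stop("need one group per chromosome")
  }
  keep <- !is.na(groups)
  if (!any(keep)) stop("empty group")
  g <- factor(groups[keep])
  if (any(table(g) == 0L)) stop("empty group")
  a <- panel$alleles[keep, sites, drop = FALSE] == effect_allele
  freq <- t(rowsum(a + 0, g) / as.vector(table(g)))
  rownames(freq) <- paste0("var_", sites)
  structure(list(freq = freq,
                 group_sizes = stats::setNames(as.vector(table(g)),
                                               levels(g)),
                 positions = panel$positions[sites]),
            class = "frequency_table")
}

#' Pairwise linkage disequilibrium r-squared from phased haplotypes
#'
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))` computed
#' from phased chromosome counts. Monomorphic sites give `NA`.
#'
#' @param alleles 0/1 matrix, chromosomes x sites (or a
#'   [haplotype_panel()]).
#' @param sites site indices to include (default all columns).
#' @return symmetric matrix of r-squared values with unit diagonal for
#'   polymorphic sites.
#' @export
pairwise_r2 <- function(alleles, sites = NULL) {
  if (inherits(alleles, "haplotype_panel")) alleles <- alleles$alleles
  m <- as.matrix(alleles)
  if (!is.null(sites)) m <- m[, sites, drop = FALSE]
  p <- colMeans(m)
  v <- p * (1 - p)
  k <- ncol(m)
  r2 <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  poly <- v > 0
  if (any(poly)) {
    mm <- m[, poly, drop = FALSE]
    co <- crossprod(mm) / nrow(mm) - outer(colMeans(mm), colMeans(mm))
    r2[poly, poly] <- co^2 / outer(v[poly], v[poly])
  }
  r2
}

#' Link variants to promoters through scored chromatin loops
#'
#' A variant links to a promoter when it lies within `flank` bp of one
#' anchor of a loop whose score is `>= min_score` and whose other anchor
#' overlaps the promoter interval. Intervals are 1-based inclusive.
#'
#' @param variant_pos named numeric vector of variant positions.
#' @param loops data.frame with columns `a1_start`, `a1_end`, `a2_start`,
#'   `a2_end`, `score`.
#' @param promoters data.frame with columns `gene`, `start`, `end`.
#' @param min_score minimum loop score (default 5).
#' @param flank bp added around anchors for variant overlap (default
#'   1000, inclusive).
#' @return data.frame of links: `variant`, `position`, `gene`, `loop`,
#'   `score`.
#' @export
annotate_variants_with_loops <- function(variant_pos, loops, promoters,
                                         min_score = 5, flank = 1000) {
  if (any(loops$a1_start > loops$a1_end | loops$a2_start > loops$a2_end)) {
    stop("malformed loop anchor (start > end)")
  }
  if (is.null(names(variant_pos))) {
    names(variant_pos) <- paste0("var", seq_along(variant_pos))
  }
  hits <- list()
  keep <- which(loops$score >= min_score)
  ov <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
  for (li in keep) {
    lp <- loops[li, ]
    for (side in 1:2) {
      a_s <- lp[[paste0("a", side, "_start")]]
      a_e <- lp[[paste0("a", side, "_end")]]
      o_s <- lp[[paste0("a", 3 - side, "_start")]]
      o_e <- lp[[paste0("a", 3 - side, "_end")]]
      near <- variant_pos >= a_s - flank & variant_pos <= a_e + flank
      if (!any(near)) next
      pg <- promoters[ov(promoters$start, promoters$end, o_s, o_e), ,
                      drop = FALSE]
      if (nrow(pg) == 0L) next
      for (v in which(near)) for (gi in seq_len(nrow(pg))) {
        hits[[length(hits) + 1L]] <- data.frame(
          variant = names(variant_pos)[v], position = variant_pos[[v]],
          gene = pg$gene[gi], loop = li, score = lp$score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(variant = character(0), position = numeric(0),
                      gene = character(0), loop = integer(0),
                      score = numeric(0)))
  }
  unique(do.call(rbind, hits))
}
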