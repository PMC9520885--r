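#' Phased haplotype panel
#'
#' Container for a set of phased chromosomes over a common site grid.
#' Rows of `alleles` are chromosomes (two consecutive rows per diploid
#' individual when `sample_id` repeats), columns are biallelic sites coded
#' 0 (reference) / 1 (alternate).
#'
#' @param alleles integer matrix, chromosomes x sites, entries in `{0, 1}`.
#' @param positions 1-based bp positions, strictly increasing, one per site.
#' @param distances inter-site genetic distances in Morgans
#'   (length `ncol(alleles) - 1`, all `>= 0`); may be `NULL`.
#' @param sample_id character vector, one entry per chromosome; diploid
#'   individuals contribute two chromosomes with the same id.
#' @param population optional population label per chromosome.
#' @param tag_sites indices of the tag SNPs that define the core-region
#'   haplotype labels (strictly increasing), or `NULL`.
#' @param chrom chromosome name used in coordinates and VCF output.
#' @param ref,alt optional per-site allele characters (defaults `A`/`G`).
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, positions, distances = NULL,
                            sample_id = NULL, population = NULL,
                            tag_sites = NULL, chrom = "chr1",
                            ref = NULL, alt = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L))) {
    stop("panel alleles must be coded 0/1")
  }
  L <- ncol(alleles)
  if (length(positions) != L) stop("positions must have one entry per site")
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (!is.null(distances)) {
    if (length(distances) != L - 1L) {
      stop("distances must have length n_sites - 1")
    }
    if (any(distances < 0)) stop("distances must be non-negative")
  }
  if (is.null(sample_id)) {
    sample_id <- rep(paste0("S", seq_len(nrow(alleles) %/% 2)), each = 2)[
      seq_len(nrow(alleles))]
  }
  if (length(sample_id) != nrow(alleles)) {
    stop("sample_id must have one entry per chromosome")
  }
  if (!is.null(tag_sites)) {
    tag_sites <- as.integer(tag_sites)
    if (any(tag_sites < 1L | tag_sites > L)) stop("tag_sites out of range")
    if (is.unsorted(tag_sites, strictly = TRUE)) {
      stop("tag_sites must be strictly increasing")
    }
  }
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("G", L)
  structure(list(
    alleles = alleles, positions = as.numeric(positions),
    distances = distances, sample_id = as.character(sample_id),
    population = population, tag_sites = tag_sites, chrom = chrom,
    ref = ref, alt = alt
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d chromosomes (%d individuals), %d sites, %s:%d-%d\n",
    nrow(x$alleles), length(unique(x$sample_id)), ncol(x$alleles),
    x$chrom, min(x$positions), max(x$positions)))
  if (!is.null(x$tag_sites)) {
    cat(sprintf("tag sites: %s\n", paste(x$tag_sites, collapse = ", ")))
  }
  invisible(x)
}

#' Number of chromosomes in a panel
#' @param panel a [haplotype_panel()].
#' @return integer chromosome count (2 per diploid individual).
#' @export
n_chromosomes <- function(panel) nrow(panel$alleles)

#' Tag-haplotype label of every chromosome
#'
#' The label of a chromosome is its allele string restricted to the panel's
#' tag sites, e.g. `"11100"`.
#'
#' @param panel a [haplotype_panel()] with `tag_sites` set.
#' @param tag_sites optional override of the panel's tag sites.
#' @return character vector of length `n_chromosomes(panel)`.
#' @export
tag_labels <- function(panel, tag_sites = NULL) {
  sites <- if (is.null(tag_sites)) panel$tag_sites else tag_sites
  if (is.null(sites)) stop("panel has no tag sites")
  apply(panel$alleles[, sites, drop = FALSE], 1L, paste, collapse = "")
}

#' Per-individual diploid genotype codes at selected sites
#'
#' @param panel a [haplotype_panel()].
#' @param sites site indices (default: the panel's tag sites).
#' @return integer matrix, individuals x sites, entries 0/1/2 (alternate
#'   allele counts), rownames = sample ids.
#' @export
panel_genotypes <- function(panel, sites = NULL) {
  if (is.null(sites)) sites <- panel$tag_sites
  if (is.null(sites)) sites <- seq_len(ncol(panel$alleles))
  ids <- unique(panel$sample_id)
  g <- matrix(0L, length(ids), length(sites),
              dimnames = list(ids, colnames(panel$alleles)[sites]))
  for (i in seq_along(ids)) {
    rows <- which(panel$sample_id == ids[i])
    g[i, ] <- as.integer(colSums(panel$alleles[rows, sites, drop = FALSE]))
  }
  g
}

#' Per-individual dosage of each tag haplotype
#'
#' @param panel a [haplotype_panel()] with tag sites.
#' @return integer matrix individuals x haplotype labels; each row sums to 2.
#' @export
haplotype_dosages <- function(panel) {
  lab <- tag_labels(panel)
  ids <- unique(panel$sample_id)
  haps <- sort(unique(lab))
  d <- matrix(0L, length(ids), length(haps), dimnames = list(ids, haps))
  for (i in seq_along(ids)) {
    for (h in lab[panel$sample_id == ids[i]]) d[i, h] <- d[i, h] + 1L
  }
  d
}
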