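#' Annotate DMRs with the genomic feature at their midpoint
#'
#' Each DMR is assigned one label by midpoint overlap with fixed
#' precedence promoter > exon > intron > downstream > distal_intergenic.
#' The promoter is the strand-aware `promoter_span` bp upstream of the
#' TSS; downstream is `downstream_span` bp past the gene end. When no
#' exon table is supplied, whole gene bodies are labelled `"genic"` in
#' place of the exon/intron split.
#'
#' @param dmrs DMR table from [call_dmrs()] (0-based half-open
#'   `start`/`end`).
#' @param genes Gene annotation (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, 0-based half-open).
#' @param exons Optional exon table (`gene_id`, `chrom`, `start`, `end`,
#'   0-based half-open).
#' @param promoter_span,downstream_span Extents in bp.
#' @return List with `annotated` (the DMR table plus `feature` and
#'   `gene_id` columns) and the per-direction gene sets `hyper_genes`
#'   and `hypo_genes` (genes hosting at least one DMR of that direction
#'   in a non-distal feature).
#' @export
annotate_dmrs <- function(dmrs, genes, exons = NULL,
                          promoter_span = 2000, downstream_span = 2000) {
  n <- nrow(dmrs)
  mid <- (dmrs$start + dmrs$end) %/% 2L  # 0-based midpoint
  mid1 <- mid + 1L                        # 1-based for interval queries
  feature <- rep("distal_intergenic", n)
  gene_id <- rep(NA_character_, n)

  hit_in <- function(tab) {
    # first containing interval per DMR midpoint, NA when none
    if (is.null(tab) || nrow(tab) == 0) return(rep(NA_integer_, n))
    q <- GenomicRanges::GRanges(dmrs$chrom, IRanges::IRanges(mid1, mid1))
    s <- GenomicRanges::GRanges(tab$chrom,
                                IRanges::IRanges(tab$start + 1L, tab$end))
    h <- GenomicRanges::findOverlaps(q, s, select = "first",
                                     ignore.strand = TRUE)
    as.integer(h)
  }

  plus <- genes$strand != "-"
  promoters <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, pmax(genes$start - promoter_span, 0), genes$end),
    end = ifelse(plus, genes$start, genes$end + promoter_span),
    gene_id = genes$gene_id, stringsAsFactors = FALSE
  )
  downstream <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$end, pmax(genes$start - downstream_span, 0)),
    end = ifelse(plus, genes$end + downstream_span, genes$start),
    gene_id = genes$gene_id, stringsAsFactors = FALSE
  )

  # precedence applied from lowest to highest so later labels overwrite
  i_down <- hit_in(downstream)
  ok <- !is.na(i_down)
  feature[ok] <- "downstream"; gene_id[ok] <- downstream$gene_id[i_down[ok]]

  i_gene <- hit_in(genes)
  ok <- !is.na(i_gene)
  if (is.null(exons)) {
    feature[ok] <- "genic"; gene_id[ok] <- genes$gene_id[i_gene[ok]]
  } else {
    feature[ok] <- "intron"; gene_id[ok] <- genes$gene_id[i_gene[ok]]
    i_ex <- hit_in(exons)
    ok2 <- !is.na(i_ex)
    feature[ok2] <- "exon"; gene_id[ok2] <- exons$gene_id[i_ex[ok2]]
  }

  i_prom <- hit_in(promoters)
  ok <- !is.na(i_prom)
  feature[ok] <- "promoter"; gene_id[ok] <- promoters$gene_id[i_prom[ok]]

  annotated <- dmrs
  annotated$feature <- feature
  annotated$gene_id <- gene_id
  genic <- !is.na(gene_id) & feature != "distal_intergenic"
  list(
    annotated = annotated,
    hyper_genes = sort(unique(gene_id[genic & dmrs$direction == "hyper"])),
    hypo_genes = sort(unique(gene_id[genic & dmrs$direction == "hypo"]))
  )
}

#' Average methylation profile around DMR centers
#'
#' Bins the `flank` bp on each side of every DMR center into `bin`-bp
#' bins (80 bins with the defaults) and averages site methylation levels
#' per bin per group over all DMRs. Bins containing no covered site are
#' `NA`.
#'
#' @param dmrs DMR table.
#' @param x_sites,y_sites Site tables or replicate lists (pooled).
#' @param flank,bin Flank width and bin size in bp; `2 * flank / bin`
#'   must be an integer.
#' @return Data frame with `bin` (1-based index), `offset` (bp of the
#'   bin start relative to the DMR center), `level_x`, `level_y`.
#' @export
dmr_meta_profile <- function(dmrs, x_sites, y_sites, flank = 2000, bin = 50) {
  stopifnot(nrow(dmrs) >= 1, (2 * flank) %% bin == 0)
  n_bins <- as.integer(2 * flank / bin)
  x <- .pool_sites(x_sites); y <- .pool_sites(y_sites)
  if ("context" %in% names(x)) x <- x[x$context == "CpG", ]
  if ("context" %in% names(y)) y <- y[y$context == "CpG", ]

  bin_means <- function(sites) {
    level <- sites$count_methylated /
      (sites$count_methylated + sites$count_unmethylated)
    ok <- is.finite(level)
    sites <- sites[ok, ]; level <- level[ok]
    acc <- rep(0, n_bins); cnt <- rep(0L, n_bins)
    centers <- (dmrs$start + dmrs$end) %/% 2L
    for (i in seq_len(nrow(dmrs))) {
      sel <- sites$chrom == dmrs$chrom[i] &
        sites$pos > centers[i] - flank & sites$pos <= centers[i] + flank
      if (!any(sel)) next
      off <- sites$pos[sel] - (centers[i] - flank) - 1L  # 0 .. 2*flank-1
      b <- off %/% bin + 1L
      acc2 <- tapply(level[sel], b, sum)
      idx <- as.integer(names(acc2))
      acc[idx] <- acc[idx] + as.vector(acc2)
      cnt2 <- tapply(level[sel], b, length)
      cnt[idx] <- cnt[idx] + as.vector(cnt2)
    }
    ifelse(cnt > 0, acc / ifelse(cnt > 0, cnt, 1L), NA_real_)
  }

  data.frame(
    bin = seq_len(n_bins),
    offset = seq(-flank, flank - bin, by = bin),
    level_x = bin_means(x),
    level_y = bin_means(y)
  )
}

#' Integrate differential methylation with sperm expression
#'
#' Filters the hyper- and hypomethylated gene sets to genes expressed
#' (FPKM > 0 in any sample), clusters their row-standardized expression
#' by k-means (fixed seed, multiple restarts), labels each cluster by
#' the sign of its centroid's Y-minus-X mean, and intersects the
#' theory-concordant sets (hypermethylated genes in down-trending
#' clusters, hypomethylated genes in up-trending clusters) with the
#' differential expression calls. Genes whose DMR annotation is a
#' promoter are tabulated separately.
#'
#' @param hyper_genes,hypo_genes Gene sets from [annotate_dmrs()].
#' @param fpkm Gene-by-sample FPKM matrix.
#' @param groups Group label (`"X"`/`"Y"`) per column of `fpkm`.
#' @param de [de_test()] result for Y versus X.
#' @param annotated Annotated DMR table (for the promoter focus).
#' @param k Number of k-means clusters.
#' @param seed,nstart k-means seed and restart count.
#' @return List with `clusters` (named cluster id per gene, per
#'   direction), `concordant` (`hyper_down`, `hypo_up` gene sets),
#'   `concordant_degs` (their intersections with down-/up-DEGs) and
#'   `promoter_table` (annotated promoter DMRs of concordant genes).
#' @export
integrate_with_expression <- function(hyper_genes, hypo_genes, fpkm, groups,
                                      de, annotated = NULL, k = 3,
                                      seed = 42, nstart = 20) {
  stopifnot(length(groups) == ncol(fpkm))
  expressed <- rownames(fpkm)[rowSums(fpkm > 0) > 0]

  cluster_dir <- function(genes_in) {
    genes_in <- intersect(genes_in, expressed)
    if (length(genes_in) == 0)
      return(list(assign = integer(0), trend = character(0)))
    if (k > length(genes_in))
      stop("k exceeds the number of expressed genes", call. = FALSE)
    m <- fpkm[genes_in, , drop = FALSE]
    sdv <- apply(m, 1, stats::sd)
    z <- (m - rowMeans(m)) / ifelse(sdv > 0, sdv, 1)
    km <- withr::with_seed(seed, stats::kmeans(z, centers = k,
                                               nstart = nstart))
    cent_diff <- apply(km$centers, 1, function(ctr)
      mean(ctr[groups == "Y"]) - mean(ctr[groups == "X"]))
    trend <- ifelse(cent_diff < 0, "down", "up")
    list(assign = km$cluster, trend = trend, centers = km$centers)
  }

  hyper_cl <- cluster_dir(hyper_genes)
  hypo_cl <- cluster_dir(hypo_genes)
  hyper_down <- names(hyper_cl$assign)[
    hyper_cl$trend[hyper_cl$assign] == "down"]
  hypo_up <- names(hypo_cl$assign)[hypo_cl$trend[hypo_cl$assign] == "up"]

  degs <- call_degs(de)
  concordant_degs <- list(hyper_down_deg = intersect(hyper_down, degs$down),
                          hypo_up_deg = intersect(hypo_up, degs$up))
  promoter_table <- NULL
  if (!is.null(annotated)) {
    conc <- c(hyper_down, hypo_up)
    promoter_table <- annotated[annotated$feature == "promoter" &
                                  !is.na(annotated$gene_id) &
                                  annotated$gene_id %in% conc, ]
  }
  list(clusters = list(hyper = hyper_cl, hypo = hypo_cl),
       concordant = list(hyper_down = hyper_down, hypo_up = hypo_up),
       concordant_degs = concordant_degs,
       promoter_table = promoter_table)
}
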