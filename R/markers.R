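#' Select informative SNP markers from two parental genotype sets
#'
#' An informative marker is a site at which both parents are confidently
#' homozygous with different alleles, so that any embryo read at the site
#' can be assigned a parental origin. Sites are rejected when either
#' parent is heterozygous, the homozygous genotypes agree, a genotype is
#' missing, the record is multi-allelic, or depth/quality falls below the
#' thresholds in either parent.
#'
#' @param maternal,paternal Genotype data frames with columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `gt` (`"0/0"`, `"0/1"`, `"1/1"`,
#'   `"./."`, phased separators accepted), `dp`, `gq`.
#' @param min_depth Minimum read depth required in each parent.
#' @param min_qual Minimum genotype quality required in each parent.
#'
#' @return Data frame with one row per retained site: `chrom`, `pos`,
#'   `maternal_allele`, `paternal_allele`.
#' @examples
#' m <- data.frame(chrom = "chr1", pos = 10, ref = "A", alt = "T",
#'                 gt = "0/0", dp = 20, gq = 60)
#' f <- transform(m, gt = "1/1")
#' select_informative_markers(m, f)
#' @export
select_informative_markers <- function(maternal, paternal,
                                       min_depth = 10, min_qual = 30) {
  if (!any(unique(maternal$chrom) %in% unique(paternal$chrom)))
    stop("parental genotype tables share no contigs; mismatched assemblies?",
         call. = FALSE)
  key_m <- paste(maternal$chrom, maternal$pos)
  key_f <- paste(paternal$chrom, paternal$pos)
  idx <- match(key_m, key_f)
  ok <- !is.na(idx)
  m <- maternal[ok, ]
  f <- paternal[idx[ok], ]

  hom_allele <- function(gt, ref, alt) {
    gt <- gsub("|", "/", gt, fixed = TRUE)
    out <- rep(NA_character_, length(gt))
    out[gt == "0/0"] <- ref[gt == "0/0"]
    out[gt == "1/1"] <- alt[gt == "1/1"]
    out
  }
  biallelic <- !grepl(",", m$alt, fixed = TRUE) & m$ref == f$ref & m$alt == f$alt
  am <- hom_allele(m$gt, m$ref, m$alt)
  af <- hom_allele(f$gt, f$ref, f$alt)
  keep <- biallelic & !is.na(am) & !is.na(af) & am != af &
    !is.na(m$dp) & !is.na(f$dp) & m$dp >= min_depth & f$dp >= min_depth &
    !is.na(m$gq) & !is.na(f$gq) & m$gq >= min_qual & f$gq >= min_qual
  out <- data.frame(chrom = m$chrom[keep], pos = m$pos[keep],
                    maternal_allele = am[keep], paternal_allele = af[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Assign markers to the genes whose intervals contain them
#'
#' A marker at 1-based position p belongs to every gene whose stored
#' 0-based half-open interval satisfies start < p <= end, so the last
#' base of a gene is included and the base immediately after is not.
#' Markers falling outside all genes are dropped.
#'
#' @param markers Marker table (`chrom`, `pos`).
#' @param genes Gene annotation (`gene_id`, `chrom`, `start`, `end`,
#'   0-based half-open).
#' @return Data frame with one row per (gene, marker) containment pair:
#'   `gene_id`, `chrom`, `pos`.
#' @export
assign_markers_to_genes <- function(markers, genes) {
  if (nrow(markers) == 0 || nrow(genes) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  mk <- GenomicRanges::GRanges(markers$chrom,
                               IRanges::IRanges(markers$pos, markers$pos))
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(mk, gn, ignore.strand = TRUE)
  out <- data.frame(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    chrom = markers$chrom[S4Vectors::queryHits(hits)],
    pos = markers$pos[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id, out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}
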