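#' Simulate parental genotypes, gene annotation and informative markers
#'
#' Generates a non-overlapping gene annotation and two parental genotype
#' tables. Informative marker sites (homozygous in each parent, different
#' allele between them, adequately covered) are planted inside genes and
#' recorded as ground truth. Decoy sites of every kind the marker filter
#' must reject are planted alongside: shared-homozygous, heterozygous in
#' either parent, missing genotypes, low-depth and low-quality calls, and
#' multi-allelic records.
#'
#' @param config A [sim_config()] object.
#' @param decoy_only If `TRUE`, no informative sites are planted and the
#'   marker truth set is empty (the two parents carry no usable
#'   divergence).
#'
#' @return A list of class `"mzt_parents"` with elements
#'   \describe{
#'     \item{maternal, paternal}{genotype data frames with columns
#'       `chrom`, `pos` (1-based), `ref`, `alt`, `gt`, `dp`, `gq`.}
#'     \item{genes}{gene annotation with `gene_id`, `chrom`, `start`,
#'       `end` (0-based half-open) and `strand`.}
#'     \item{markers}{truth table of planted informative sites with
#'       `chrom`, `pos`, `maternal_allele`, `paternal_allele`, `gene_id`.}
#'   }
#' @examples
#' p <- simulate_parents(sim_config(n_genes = 20, seed = 1))
#' nrow(p$markers)  # 20 * 3 planted sites
#' @export
simulate_parents <- function(config, decoy_only = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genes <- .place_genes(config, chroms)

  n_inf <- if (decoy_only) 0L else as.integer(round(config$n_genes * config$n_snps_per_gene))
  # distribute the planted informative sites over genes at random
  host <- if (n_inf > 0) sample(seq_len(nrow(genes)), n_inf, replace = TRUE) else integer(0)

  inf_pos <- .sample_positions_in_genes(genes, host)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_inf, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  mother_ref <- sample(c(TRUE, FALSE), n_inf, replace = TRUE)

  inf <- data.frame(
    chrom = genes$chrom[host], pos = inf_pos,
    ref = ref, alt = alt,
    gt_m = ifelse(mother_ref, "0/0", "1/1"),
    gt_f = ifelse(mother_ref, "1/1", "0/0"),
    dp_m = 20L + stats::rpois(n_inf, 20), dp_f = 20L + stats::rpois(n_inf, 20),
    gq_m = 60L + stats::rpois(n_inf, 20), gq_f = 60L + stats::rpois(n_inf, 20),
    stringsAsFactors = FALSE
  )
  inf$gene_id <- genes$gene_id[host]

  decoys <- .plant_decoys(config, genes, chroms)

  # drop any accidental position collisions, decoys give way to markers
  key_inf <- paste(inf$chrom, inf$pos)
  decoys <- decoys[!paste(decoys$chrom, decoys$pos) %in% key_inf, ]
  decoys <- decoys[!duplicated(paste(decoys$chrom, decoys$pos)), ]
  dup_inf <- duplicated(key_inf)
  inf <- inf[!dup_inf, ]

  all_sites <- rbind(inf[setdiff(names(inf), "gene_id")], decoys)
  ord <- order(all_sites$chrom, all_sites$pos)
  all_sites <- all_sites[ord, ]

  maternal <- data.frame(
    chrom = all_sites$chrom, pos = all_sites$pos, ref = all_sites$ref,
    alt = all_sites$alt, gt = all_sites$gt_m, dp = all_sites$dp_m,
    gq = all_sites$gq_m, stringsAsFactors = FALSE
  )
  paternal <- data.frame(
    chrom = all_sites$chrom, pos = all_sites$pos, ref = all_sites$ref,
    alt = all_sites$alt, gt = all_sites$gt_f, dp = all_sites$dp_f,
    gq = all_sites$gq_f, stringsAsFactors = FALSE
  )

  markers <- data.frame(
    chrom = inf$chrom, pos = inf$pos,
    maternal_allele = ifelse(inf$gt_m == "0/0", inf$ref, inf$alt),
    paternal_allele = ifelse(inf$gt_f == "0/0", inf$ref, inf$alt),
    gene_id = inf$gene_id, stringsAsFactors = FALSE
  )
  markers <- markers[order(markers$chrom, markers$pos), ]
  rownames(maternal) <- rownames(paternal) <- rownames(markers) <- NULL

  structure(
    list(maternal = maternal, paternal = paternal, genes = genes,
         markers = markers, config = config),
    class = "mzt_parents"
  )
}

# evenly spaced, non-overlapping gene intervals (0-based half-open)
.place_genes <- function(config, chroms) {
  per_chrom <- diff(floor(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    n <- per_chrom[i]
    if (n == 0) next
    slot <- config$chrom_length %/% n
    if (slot < config$gene_length + 10)
      stop("chromosome too short to host the requested genes", call. = FALSE)
    offset <- sample.int(slot - config$gene_length, n, replace = TRUE) - 1L
    start <- (seq_len(n) - 1L) * slot + offset
    out[[i]] <- data.frame(
      chrom = chroms[i], start = start, end = start + config$gene_length,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, out)
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes[c("gene_id", "chrom", "start", "end", "strand")]
}

# 1-based positions uniformly inside the hosting gene, unique per gene
.sample_positions_in_genes <- function(genes, host) {
  if (length(host) == 0) return(integer(0))
  pos <- integer(length(host))
  for (g in unique(host)) {
    idx <- which(host == g)
    pos[idx] <- sample((genes$start[g] + 1L):genes$end[g], length(idx))
  }
  pos
}

.plant_decoys <- function(config, genes, chroms) {
  n <- max(1L, config$n_genes)
  types <- c("shared_hom", "het_mother", "het_father", "missing",
             "low_depth", "low_qual", "multi_allelic")
  type <- sample(types, 2L * n, replace = TRUE)
  m <- length(type)
  chrom <- sample(chroms, m, replace = TRUE)
  pos <- sapply(chrom, function(ch) sample.int(config$chrom_length, 1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  gt_m <- gt_f <- character(m)
  dp_m <- dp_f <- 20L + stats::rpois(m, 20)
  gq_m <- gq_f <- 60L + stats::rpois(m, 20)
  for (i in seq_len(m)) {
    gt_m[i] <- "0/0"; gt_f[i] <- "1/1"
    switch(type[i],
      shared_hom = { gt_f[i] <- "0/0" },
      het_mother = { gt_m[i] <- "0/1" },
      het_father = { gt_f[i] <- "0/1" },
      missing    = { gt_m[i] <- "./." },
      low_depth  = { dp_m[i] <- sample(0:9, 1) },
      low_qual   = { gq_f[i] <- sample(0:29, 1) },
      multi_allelic = { alt[i] <- paste(alt[i], sample(setdiff(bases, c(ref[i], alt[i])), 1), sep = ",") }
    )
  }
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gt_m = gt_m, gt_f = gt_f, dp_m = dp_m, dp_f = dp_f,
             gq_m = gq_m, gq_f = gq_f, stringsAsFactors = FALSE)
}
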