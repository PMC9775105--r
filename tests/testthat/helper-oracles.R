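# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (per-row loops, full enumeration) so they share no
# code path with the vectorized implementations they check.

# brute-force informative-marker filter: explicit per-site predicate
# applied one site at a time (column vectors, not data-frame rows, so the
# loop stays affordable at acceptance scale)
oracle_select_markers <- function(maternal, paternal,
                                  min_depth = 10, min_qual = 30) {
  j_of <- match(paste(maternal$chrom, maternal$pos),
                paste(paternal$chrom, paternal$pos))
  allele <- function(gt, ref, alt) {
    gt <- gsub("|", "/", gt, fixed = TRUE)
    if (gt == "0/0") ref else if (gt == "1/1") alt else NA_character_
  }
  keep <- logical(nrow(maternal))
  am_all <- af_all <- character(nrow(maternal))
  for (i in seq_len(nrow(maternal))) {
    j <- j_of[i]
    if (is.na(j)) next
    if (grepl(",", maternal$alt[i], fixed = TRUE)) next
    if (maternal$ref[i] != paternal$ref[j] ||
        maternal$alt[i] != paternal$alt[j]) next
    am <- allele(maternal$gt[i], maternal$ref[i], maternal$alt[i])
    af <- allele(paternal$gt[j], paternal$ref[j], paternal$alt[j])
    if (is.na(am) || is.na(af) || am == af) next
    if (is.na(maternal$dp[i]) || is.na(paternal$dp[j]) ||
        maternal$dp[i] < min_depth || paternal$dp[j] < min_depth) next
    if (is.na(maternal$gq[i]) || is.na(paternal$gq[j]) ||
        maternal$gq[i] < min_qual || paternal$gq[j] < min_qual) next
    keep[i] <- TRUE
    am_all[i] <- am; af_all[i] <- af
  }
  out <- data.frame(chrom = maternal$chrom[keep], pos = maternal$pos[keep],
                    maternal_allele = am_all[keep],
                    paternal_allele = af_all[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

# random parental genotype tables mixing all the decoy flavours
random_genotype_tables <- function(n_sites, seed) {
  set.seed(seed)
  chrom <- sample(paste0("chr", 1:3), n_sites, replace = TRUE)
  pos <- sample.int(1e6, n_sites)
  key <- !duplicated(paste(chrom, pos))
  chrom <- chrom[key]; pos <- pos[key]
  n <- length(pos)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  alt[sample.int(n, n %/% 20)] <- paste0(alt[sample.int(n, n %/% 20)], ",T")
  gts <- c("0/0", "0/1", "1/1", "./.")
  mk <- function() data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    gt = sample(gts, n, replace = TRUE, prob = c(0.4, 0.15, 0.4, 0.05)),
    dp = sample(0:60, n, replace = TRUE),
    gq = sample(0:99, n, replace = TRUE),
    stringsAsFactors = FALSE)
  list(maternal = mk(), paternal = mk())
}

# full-enumeration Spearman oracle; r via cor(method = "spearman"),
# permutations built as an explicit list
oracle_spearman <- function(x, y) {
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_list(v[-i]))
        out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  r_obs <- cor(x, y, method = "spearman")
  rs <- vapply(perm_list(y), function(py) cor(x, py, method = "spearman"),
               numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# small embryo study used by several classification tests
small_embryo_study <- function(seed = 5, ...) {
  cfg <- sim_config(n_genes = 80, seed = seed, ...)
  parents <- simulate_parents(cfg)
  markers <- select_informative_markers(parents$maternal, parents$paternal)
  gene_map <- assign_markers_to_genes(markers, parents$genes)
  embryos <- simulate_embryo_series(parents, config = cfg)
  list(cfg = cfg, parents = parents, markers = markers,
       gene_map = gene_map, embryos = embryos)
}

# truth-agreement of a classification run, covered genes only
classification_agreement <- function(study, cross = "XX") {
  obs <- study$embryos$allele_counts[
    study$embryos$allele_counts$cross == cross, ]
  cl <- classify_stage(obs, study$gene_map, study$cfg$stages)
  tr <- study$embryos$truth$categories[
    study$embryos$truth$categories$cross == cross, ]
  idx <- match(paste(cl$classification$gene_id, cl$classification$stage),
               paste(tr$gene_id, tr$stage))
  cov <- cl$classification$n_markers_covered > 0
  list(agreement = mean(cl$classification$category[cov] ==
                          tr$category[idx][cov]),
       result = cl)
}
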