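#' Fragments per kilobase per million mapped fragments
#'
#' FPKM = 1e9 * c / (L * N) for count c, gene length L (bp) and library
#' size N.
#'
#' @param counts Gene-by-sample count matrix.
#' @param lengths Gene lengths in bp, recycled/matched by name when named.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return FPKM matrix with the dimensions of `counts`.
#' @export
compute_fpkm <- function(counts, lengths, lib_sizes = colSums(counts)) {
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  stopifnot(all(lengths > 0), all(lib_sizes > 0),
            length(lengths) == nrow(counts),
            length(lib_sizes) == ncol(counts))
  1e9 * sweep(counts / lengths, 2, lib_sizes, "/")
}

#' Retain genes expressed in at least one group
#'
#' A gene passes when its replicate-mean FPKM is strictly above
#' `threshold` in at least one group.
#'
#' @param fpkm FPKM matrix.
#' @param groups Group label per column of `fpkm`.
#' @param threshold Mean-FPKM cutoff (default 1.0).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(fpkm, groups, threshold = 1.0) {
  stopifnot(length(groups) == ncol(fpkm))
  means <- sapply(unique(groups), function(g)
    rowMeans(fpkm[, groups == g, drop = FALSE]))
  keep <- apply(as.matrix(means), 1, function(x) any(x > threshold))
  rownames(fpkm)[keep]
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A compact DESeq-style test: median-of-ratios size factors,
#' method-of-moments gene-wise dispersions moderated toward the median
#' dispersion (prior degrees of freedom `prior_df`), and a Wald test on
#' the log2 fold change (group B over group A) referred to a
#' t-distribution with residual-plus-prior degrees of freedom. The
#' moderation and the heavy-tailed reference keep the test calibrated
#' with as few as three replicates per group, where raw gene-wise
#' dispersion estimates are too noisy to support a normal reference.
#' P-values are Benjamini-Hochberg adjusted.
#'
#' @param counts Gene-by-sample raw count matrix.
#' @param group_a,group_b Column names (or indices) of the two groups,
#'   each with >= 2 replicates.
#' @param prior_df Prior degrees of freedom for dispersion moderation.
#' @return Data frame with one row per gene: `gene_id`, `base_mean`,
#'   `log2fc`, `se`, `stat`, `p`, `padj`, `direction` (at the default
#'   padj < 0.05, fold change > 2 thresholds). All-zero genes get
#'   `log2fc = 0`, `p = 1`.
#' @export
de_test <- function(counts, group_a, group_b, prior_df = 10) {
  A <- counts[, group_a, drop = FALSE]
  B <- counts[, group_b, drop = FALSE]
  n1 <- ncol(A); n2 <- ncol(B)
  if (n1 < 2 || n2 < 2)
    stop("need at least 2 replicates per group to estimate dispersion",
         call. = FALSE)
  K <- cbind(A, B)
  dg <- n1 + n2 - 2

  # median-of-ratios size factors over genes positive in every sample
  logg <- rowMeans(log(K))
  ok <- is.finite(logg)
  if (!any(ok)) {
    sf <- rep(1, ncol(K))
  } else {
    sf <- apply(K, 2, function(col) exp(stats::median((log(col) - logg)[ok])))
  }
  Kn <- sweep(K, 2, sf, "/")
  An <- Kn[, seq_len(n1), drop = FALSE]
  Bn <- Kn[, n1 + seq_len(n2), drop = FALSE]
  muA <- rowMeans(An); muB <- rowMeans(Bn)

  vA <- apply(An, 1, stats::var); vB <- apply(Bn, 1, stats::var)
  v <- ((n1 - 1) * vA + (n2 - 1) * vB) / dg
  m <- (muA + muB) / 2
  disp_g <- ifelse(m > 0, pmax((v - m) / m^2, 0), 0)
  disp_c <- stats::median(disp_g[m > 0])
  if (!is.finite(disp_c)) disp_c <- 0.1
  disp <- pmax((prior_df * disp_c + dg * disp_g) / (prior_df + dg), 1e-8)

  # half-a-normalized-count floor keeps fold changes finite for on/off genes
  muA_s <- pmax(muA, 0.5); muB_s <- pmax(muB, 0.5)
  sfA <- sf[seq_len(n1)]; sfB <- sf[n1 + seq_len(n2)]
  mA <- muA_s %o% sfA; mB <- muB_s %o% sfB
  varA <- rowSums(sweep(mA + disp * mA^2, 2, sfA^2, "/")) / n1^2
  varB <- rowSums(sweep(mB + disp * mB^2, 2, sfB^2, "/")) / n2^2
  se <- sqrt(varA / muA_s^2 + varB / muB_s^2) / log(2)
  log2fc <- log2(muB_s) - log2(muA_s)
  stat <- log2fc / se
  p <- 2 * stats::pt(-abs(stat), df = dg + prior_df)

  zero <- rowSums(K) == 0
  log2fc[zero] <- 0; stat[zero] <- 0; p[zero] <- 1
  padj <- stats::p.adjust(p, method = "BH")

  res <- data.frame(
    gene_id = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts))) else rownames(counts),
    base_mean = m, log2fc = log2fc, se = se, stat = stat, p = p, padj = padj,
    stringsAsFactors = FALSE
  )
  res$direction <- ifelse(res$padj < 0.05 & res$log2fc >= 1, "up",
                          ifelse(res$padj < 0.05 & res$log2fc <= -1, "down",
                                 "ns"))
  rownames(res) <- NULL
  res
}

#' Call differentially expressed genes from a test result
#'
#' @param de Result of [de_test()].
#' @param padj_thresh Adjusted p-value cutoff (default 0.05).
#' @param fc_thresh Linear fold-change cutoff (default 2.0, i.e.
#'   |log2FC| >= 1).
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(de, padj_thresh = 0.05, fc_thresh = 2.0) {
  lfc <- log2(fc_thresh)
  ok <- !is.na(de$padj) & de$padj < padj_thresh
  list(up = de$gene_id[ok & de$log2fc >= lfc],
       down = de$gene_id[ok & de$log2fc <= -lfc])
}

#' Call maternal-degradation and zygotic-activation gene sets
#'
#' Crosses the stage classification with the differential test between
#' the two blastocyst stages: maternal-degradation genes are classified
#' maternal at the earlier (high-blastocyst) stage and significantly down
#' from high to low blastocyst; zygotic-activation genes are classified
#' zygotic at the later (low-blastocyst) stage and significantly up.
#'
#' @param classification Classification table from [classify_stage()].
#' @param de Result of [de_test()] with group A = high-blastocyst and
#'   group B = low-blastocyst samples.
#' @param high_stage,low_stage Stage labels of the compared pair.
#' @param padj_thresh,fc_thresh DEG thresholds, see [call_degs()].
#' @return List with character vectors `maternal_degradation` and
#'   `zygotic_activation`.
#' @export
call_mzt_genes <- function(classification, de,
                           high_stage = "high-blastocyst",
                           low_stage = "low-blastocyst",
                           padj_thresh = 0.05, fc_thresh = 2.0) {
  for (st in c(high_stage, low_stage))
    if (!st %in% classification$stage)
      stop("stage missing from classification: ", st, call. = FALSE)
  degs <- call_degs(de, padj_thresh, fc_thresh)
  mat_high <- classification$gene_id[classification$stage == high_stage &
                                       classification$category == "maternal"]
  zyg_low <- classification$gene_id[classification$stage == low_stage &
                                      classification$category == "zygotic"]
  list(maternal_degradation = intersect(mat_high, degs$down),
       zygotic_activation = intersect(zyg_low, degs$up))
}

#' Empirical cumulative distribution of expression levels
#'
#' Non-positive values are dropped before the optional log10 transform,
#' then an ECDF and a type-7 quantile function are returned.
#'
#' @param fpkm Numeric vector of expression values.
#' @param log10 Transform to log10 scale after dropping zeros.
#' @return List with `ecdf` (a function), `quantile` (function of q),
#'   `values` (the transformed sample) and `n_dropped`.
#' @export
cumulative_distribution <- function(fpkm, log10 = TRUE) {
  x <- fpkm[fpkm > 0]
  n_dropped <- length(fpkm) - length(x)
  if (length(x) == 0)
    stop("no positive expression values", call. = FALSE)
  if (log10) x <- log10(x)
  list(ecdf = stats::ecdf(x),
       quantile = function(q) unname(stats::quantile(x, q, type = 7)),
       values = x, n_dropped = n_dropped)
}

#' Partition two gene sets into shared and specific components
#'
#' @param a,b Character vectors of ids (duplicates ignored).
#' @return List with `shared`, `a_specific`, `b_specific` and a named
#'   `counts` vector.
#' @export
overlap_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- intersect(a, b)
  list(shared = shared,
       a_specific = setdiff(a, b),
       b_specific = setdiff(b, a),
       counts = c(shared = length(shared),
                  a_specific = length(a) - length(shared),
                  b_specific = length(b) - length(shared)))
}
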