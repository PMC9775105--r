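#' Build replicate-averaged stage profiles from an expression matrix
#'
#' @param expr Gene-by-sample matrix (counts or FPKM).
#' @param stage_map Data frame mapping `sample` to `stage`; every column
#'   of `expr` must appear.
#' @param stages Declared ordered stage series; every stage must have at
#'   least one sample.
#' @return Gene-by-stage matrix of replicate means, columns in the order
#'   of `stages`.
#' @export
build_profiles <- function(expr, stage_map, stages) {
  stopifnot(all(colnames(expr) %in% stage_map$sample))
  st <- stage_map$stage[match(colnames(expr), stage_map$sample)]
  missing <- setdiff(stages, st)
  if (length(missing))
    stop("stage with zero samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  prof <- vapply(stages, function(s)
    rowMeans(expr[, st == s, drop = FALSE]), numeric(nrow(expr)))
  matrix(prof, nrow = nrow(expr),
         dimnames = list(rownames(expr), stages))
}

#' Spearman rank correlation with an exact permutation p-value
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' average ranks. For n <= `exact_max` the one-sided p-value
#' P(R >= r_obs) is computed by full enumeration of the n! permutations
#' of one profile (the observed tie pattern is treated as fixed); for
#' larger n the usual t-approximation with n - 2 degrees of freedom is
#' used. The positive one-sided tail matches a screen for genes tracking
#' a marker profile.
#'
#' @param x,y Numeric profiles of equal length n >= 3.
#' @param exact_max Largest n for which the exact enumeration is used.
#' @return List with `r`, `p` and `method` (`"exact"` or
#'   `"t-approximation"`). A constant profile gives `r = NA` with a
#'   warning.
#' @examples
#' spearman_exact(1:5, c(2, 4, 5, 7, 9))  # r = 1, p = 1/120
#' @export
spearman_exact <- function(x, y, exact_max = 8) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant profile; Spearman correlation undefined")
    return(list(r = NA_real_, p = NA_real_, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- .permutations(n)
    # rows of ry_perm are permuted copies of ry; correlations with the
    # centered rx come from a single matrix product
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    num <- ry_perm %*% (rx - mean(rx))
    denom <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    rs <- as.vector(num) / denom
    p <- mean(rs >= r - 1e-12)
    method <- "exact"
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- stats::pt(t, df = n - 2, lower.tail = FALSE)
    method <- "t-approximation"
  }
  list(r = r, p = p, method = method)
}

# all permutations of 1..n as rows (n <= 8 keeps this small)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Screen genes for PGC-relatedness against marker stage profiles
#'
#' A gene is PGC-related when its stage profile tracks at least one PGC
#' marker-gene profile: the best (maximum-r) marker must exceed
#' `r_thresh` with its exact one-sided p below `p_thresh`. With
#' `composite = TRUE` genes are instead compared against the mean marker
#' profile.
#'
#' @param profiles Candidate gene-by-stage profile matrix.
#' @param marker_profiles Marker-by-stage profile matrix.
#' @param r_thresh,p_thresh Inclusion thresholds (defaults 0.9 / 0.05).
#' @param composite Compare against the mean marker profile instead of
#'   each marker separately.
#' @return List with `genes` (character vector) and `results` (data frame
#'   `gene_id`, `best_marker`, `r`, `p`, `pgc_related`).
#' @export
screen_pgc <- function(profiles, marker_profiles, r_thresh = 0.9,
                       p_thresh = 0.05, composite = FALSE) {
  stopifnot(nrow(marker_profiles) >= 1,
            ncol(profiles) == ncol(marker_profiles))
  if (composite) {
    marker_profiles <- matrix(colMeans(marker_profiles), nrow = 1,
                              dimnames = list("composite",
                                              colnames(marker_profiles)))
  }
  res <- lapply(seq_len(nrow(profiles)), function(i) {
    x <- profiles[i, ]
    if (stats::sd(x) == 0)
      return(data.frame(best_marker = NA_character_, r = NA_real_,
                        p = NA_real_))
    fits <- lapply(seq_len(nrow(marker_profiles)), function(j)
      suppressWarnings(spearman_exact(x, marker_profiles[j, ])))
    rs <- vapply(fits, `[[`, numeric(1), "r")
    if (all(is.na(rs)))
      return(data.frame(best_marker = NA_character_, r = NA_real_,
                        p = NA_real_))
    best <- which.max(rs)
    data.frame(best_marker = rownames(marker_profiles)[best],
               r = rs[best], p = fits[[best]]$p, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  results <- data.frame(gene_id = rownames(profiles), results,
                        stringsAsFactors = FALSE)
  results$pgc_related <- !is.na(results$r) & results$r > r_thresh &
    results$p < p_thresh
  list(genes = results$gene_id[results$pgc_related], results = results)
}

#' Proportion of PGC-related genes in each category gene set
#'
#' @param pgc_genes Character vector of PGC-related gene ids.
#' @param sets Named list of category gene sets.
#' @return Data frame with `category`, `size`, `n_pgc`, `proportion`
#'   (`NA` with a warning for an empty set).
#' @export
category_proportions <- function(pgc_genes, sets) {
  out <- do.call(rbind, lapply(names(sets), function(nm) {
    s <- unique(sets[[nm]])
    if (length(s) == 0) {
      warning("empty category set: ", nm)
      return(data.frame(category = nm, size = 0L, n_pgc = 0L,
                        proportion = NA_real_))
    }
    n <- sum(s %in% pgc_genes)
    data.frame(category = nm, size = length(s), n_pgc = n,
               proportion = n / length(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of highly variable genes per group
#'
#' A gene is highly variable between two stages when its |log2FC| meets
#' the threshold (default 1.0, i.e. a two-fold change).
#'
#' @param log2fc Named numeric vector of per-gene log2 fold changes.
#' @param groups Named list of gene-id sets.
#' @param threshold |log2FC| cutoff.
#' @return Data frame per group: `group`, `n`, `frac_high`, `frac_low`
#'   (the two fractions sum to 1). Genes without a fold change are
#'   excluded with a warning.
#' @export
variable_gene_fractions <- function(log2fc, groups, threshold = 1.0) {
  out <- do.call(rbind, lapply(names(groups), function(nm) {
    ids <- unique(groups[[nm]])
    miss <- setdiff(ids, names(log2fc))
    if (length(miss)) {
      warning(length(miss), " gene(s) in group ", nm,
              " lack a log2FC; excluded")
      ids <- setdiff(ids, miss)
    }
    v <- abs(log2fc[ids])
    data.frame(group = nm, n = length(v),
               frac_high = if (length(v)) mean(v >= threshold) else NA_real_,
               frac_low = if (length(v)) mean(v < threshold) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
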