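#' Read a per-cytosine methylation report
#'
#' Parses a tab-separated CpG report (header line, then one row per
#' cytosine: chromosome, 1-based position, strand, context,
#' methylated count, unmethylated count). Malformed rows raise an error
#' naming the offending line.
#'
#' @param path Report file path.
#' @return Site data frame (`chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_unmethylated`).
#' @export
read_cpg_report <- function(path) {
  lines <- readLines(path)
  empty_tab <- data.frame(chrom = character(0), pos = integer(0),
                          strand = character(0), context = character(0),
                          count_methylated = integer(0),
                          count_unmethylated = integer(0),
                          stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty_tab)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6)
  if (length(bad))
    stop("malformed CpG report line ", bad[1], " in ", path, call. = FALSE)
  if (length(lines) == 1) return(empty_tab)
  body <- fields[-1]
  mat <- matrix(unlist(body), ncol = 6, byrow = TRUE)
  num <- suppressWarnings(cbind(as.integer(mat[, 2]), as.integer(mat[, 5]),
                                as.integer(mat[, 6])))
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad))
    stop("malformed CpG report line ", bad[1] + 1L, " in ", path,
         call. = FALSE)
  data.frame(chrom = mat[, 1], pos = num[, 1], strand = mat[, 3],
             context = mat[, 4], count_methylated = num[, 2],
             count_unmethylated = num[, 3], stringsAsFactors = FALSE)
}

# pool replicate site tables: sum counts over (chrom, pos, strand, context)
.pool_sites <- function(reps) {
  if (is.data.frame(reps)) return(reps)
  all <- do.call(rbind, reps)
  by <- list(chrom = all$chrom, pos = all$pos, strand = all$strand)
  if ("context" %in% names(all)) by$context <- all$context
  agg <- stats::aggregate(
    all[c("count_methylated", "count_unmethylated")], by = by, FUN = sum)
  agg[order(agg$chrom, agg$pos), ]
}

#' Fraction of methylated cytosines per sequence context
#'
#' A covered cytosine is called methylated when its methylated read
#' count is larger than expected from bisulfite non-conversion alone
#' (one-sided binomial test against `error_rate` at level `alpha`).
#'
#' @param sites Site table (or list of replicate tables, pooled).
#' @param min_cov Minimum coverage for a site to be considered.
#' @param error_rate Assumed non-conversion error rate.
#' @param alpha Test level of the per-site binomial call.
#' @return Data frame per context: `context`, `n_sites`,
#'   `frac_methylated`.
#' @export
context_summary <- function(sites, min_cov = 5, error_rate = 0.005,
                            alpha = 0.05) {
  stopifnot(min_cov >= 1)
  sites <- .pool_sites(sites)
  cov <- sites$count_methylated + sites$count_unmethylated
  sites <- sites[cov >= min_cov, ]
  cov <- cov[cov >= min_cov]
  # P(X >= m | cov, error_rate) < alpha -> methylated
  pup <- stats::pbinom(sites$count_methylated - 1L, cov, error_rate,
                       lower.tail = FALSE)
  called <- pup < alpha & sites$count_methylated > 0
  out <- do.call(rbind, lapply(sort(unique(sites$context)), function(cx) {
    sel <- sites$context == cx
    data.frame(context = cx, n_sites = sum(sel),
               frac_methylated = mean(called[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bisulfite conversion efficiency from an unmethylated spike-in
#'
#' @param sites Site table (or replicate list) including spike-in rows.
#' @param spikein Contig name of the unmethylated spike-in genome.
#' @return Efficiency fraction: 1 - sum(methylated) / sum(total) over
#'   spike-in cytosines.
#' @export
conversion_efficiency <- function(sites, spikein = "lambda") {
  sites <- .pool_sites(sites)
  s <- sites[sites$chrom == spikein, ]
  if (nrow(s) == 0)
    stop("no spike-in sites on contig ", spikein, call. = FALSE)
  tot <- sum(s$count_methylated) + sum(s$count_unmethylated)
  1 - sum(s$count_methylated) / tot
}

#' Genome-wide site-level comparison of two methylomes
#'
#' Matches CpG sites between the pooled X and pooled Y tables on
#' (chrom, pos, strand), keeps sites covered at `min_cov` in both, and
#' reports the fractions of sites where Y is higher, X is higher, and
#' the levels tie.
#'
#' @param x_sites,y_sites Site tables or lists of replicate tables.
#' @param min_cov Minimum pooled coverage per group.
#' @return Named numeric vector `c(y_higher, x_higher, tied)` summing
#'   to 1, with the matched site count as attribute `n_sites`.
#' @export
global_site_comparison <- function(x_sites, y_sites, min_cov = 5) {
  x <- .pool_sites(x_sites); y <- .pool_sites(y_sites)
  if ("context" %in% names(x)) x <- x[x$context == "CpG", ]
  if ("context" %in% names(y)) y <- y[y$context == "CpG", ]
  key_x <- paste(x$chrom, x$pos, x$strand)
  key_y <- paste(y$chrom, y$pos, y$strand)
  idx <- match(key_x, key_y)
  ok <- !is.na(idx)
  x <- x[ok, ]; y <- y[idx[ok], ]
  cov_x <- x$count_methylated + x$count_unmethylated
  cov_y <- y$count_methylated + y$count_unmethylated
  keep <- cov_x >= min_cov & cov_y >= min_cov
  if (!any(keep)) stop("no matched covered sites", call. = FALSE)
  lx <- x$count_methylated[keep] / cov_x[keep]
  ly <- y$count_methylated[keep] / cov_y[keep]
  out <- c(y_higher = mean(ly > lx), x_higher = mean(lx > ly),
           tied = mean(lx == ly))
  attr(out, "n_sites") <- sum(keep)
  out
}

#' Call differentially methylated regions between two replicate groups
#'
#' Tiles each chromosome into fixed windows, pools replicate counts per
#' group within each window, and tests the group difference in
#' methylation proportion. The default test is a binomial
#' likelihood-ratio test (equivalent to a logistic-regression LRT with a
#' group term, since the group-wise MLE pools replicate counts); with a
#' single replicate in either group, or on request, Fisher's exact test
#' on the pooled 2x2 table is used. P-values are Benjamini-Hochberg
#' adjusted across all tested windows, and windows passing both the
#' q-value and the absolute methylation-difference thresholds are
#' reported with their direction (Y versus X).
#'
#' @param x_reps,y_reps Lists of replicate site tables (CpG context
#'   rows are selected automatically when a `context` column exists).
#' @param window,step Window width and step in bp (equal by default:
#'   non-overlapping tiles). Windows below 50 bp are a configuration
#'   error.
#' @param min_cpg Minimum number of CpG sites covered in both groups for
#'   a window to be tested.
#' @param diff_thresh Minimum |methylation difference| in percentage
#'   points.
#' @param q_thresh Maximum BH-adjusted p-value.
#' @param test `"lrt"`, `"fisher"`, or `"auto"` (Fisher when a group has
#'   one replicate).
#' @return Data frame of DMRs: `chrom`, `start`, `end` (0-based
#'   half-open), `n_cpg`, `mean_x`, `mean_y`, `meth_diff` (percentage
#'   points, Y - X), `p`, `q`, `direction`. The full tested-window table
#'   is attached as attribute `"windows"`.
#' @export
call_dmrs <- function(x_reps, y_reps, window = 1000, step = window,
                      min_cpg = 10, diff_thresh = 25, q_thresh = 0.01,
                      test = c("auto", "lrt", "fisher")) {
  test <- match.arg(test)
  if (window < 50) stop("window smaller than 50 bp", call. = FALSE)
  if (is.data.frame(x_reps)) x_reps <- list(x_reps)
  if (is.data.frame(y_reps)) y_reps <- list(y_reps)
  if (test == "auto")
    test <- if (length(x_reps) == 1 || length(y_reps) == 1) "fisher" else "lrt"
  x <- .pool_sites(x_reps); y <- .pool_sites(y_reps)
  if ("context" %in% names(x)) x <- x[x$context == "CpG", ]
  if ("context" %in% names(y)) y <- y[y$context == "CpG", ]

  key_x <- paste(x$chrom, x$pos, x$strand)
  key_y <- paste(y$chrom, y$pos, y$strand)
  idx <- match(key_x, key_y)
  ok <- !is.na(idx) &
    (x$count_methylated + x$count_unmethylated) > 0
  x <- x[ok, ]; y <- y[idx[ok], ]
  ok2 <- (y$count_methylated + y$count_unmethylated) > 0
  x <- x[ok2, ]; y <- y[ok2, ]

  if (step > window) stop("step larger than window", call. = FALSE)
  step <- as.integer(step); window <- as.integer(window)
  # a site at 0-based offset p0 falls in every window start = k*step
  # with start <= p0 < start + window
  p0 <- x$pos - 1L
  k_hi <- p0 %/% step
  k_lo <- pmax(0L, (p0 - window) %/% step + 1L)
  reps <- k_hi - k_lo + 1L
  site_idx <- rep(seq_len(nrow(x)), reps)
  win <- unlist(mapply(seq.int, k_lo, k_hi, SIMPLIFY = FALSE)) * step
  wid <- paste(x$chrom[site_idx], win)
  uw <- sort(unique(wid))
  ord <- match(uw, wid)  # representative row per window for coordinates
  mx <- as.vector(tapply(x$count_methylated[site_idx], wid, sum)[uw])
  ux <- as.vector(tapply(x$count_unmethylated[site_idx], wid, sum)[uw])
  my <- as.vector(tapply(y$count_methylated[site_idx], wid, sum)[uw])
  uy <- as.vector(tapply(y$count_unmethylated[site_idx], wid, sum)[uw])
  ncpg <- as.vector(tapply(site_idx, wid, length)[uw])
  chrom <- x$chrom[site_idx][ord]
  start <- win[ord]

  keep <- ncpg >= min_cpg
  tab <- data.frame(chrom = chrom[keep], start = start[keep],
                    end = start[keep] + as.integer(window),
                    n_cpg = ncpg[keep],
                    mx = mx[keep], ux = ux[keep], my = my[keep],
                    uy = uy[keep], stringsAsFactors = FALSE)
  if (nrow(tab) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_cpg = integer(0),
                      mean_x = numeric(0), mean_y = numeric(0),
                      meth_diff = numeric(0), p = numeric(0),
                      q = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "windows") <- tab
    return(out)
  }
  tab$mean_x <- tab$mx / (tab$mx + tab$ux)
  tab$mean_y <- tab$my / (tab$my + tab$uy)
  tab$meth_diff <- 100 * (tab$mean_y - tab$mean_x)

  tab$p <- if (test == "fisher") {
    fisher_window_p(tab$mx, tab$ux, tab$my, tab$uy)
  } else {
    .binom_lrt_p(tab$mx, tab$ux, tab$my, tab$uy)
  }
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$direction <- ifelse(tab$meth_diff > 0, "hyper", "hypo")

  dmr <- tab[tab$q < q_thresh & abs(tab$meth_diff) >= diff_thresh,
             c("chrom", "start", "end", "n_cpg", "mean_x", "mean_y",
               "meth_diff", "p", "q", "direction")]
  rownames(dmr) <- NULL
  attr(dmr, "windows") <- tab[c("chrom", "start", "end", "n_cpg", "mean_x",
                                "mean_y", "meth_diff", "p", "q",
                                "direction")]
  dmr
}

# two-proportion binomial likelihood-ratio test, chi-square with 1 df
.binom_lrt_p <- function(mx, ux, my, uy) {
  ll <- function(m, u, p) {
    out <- numeric(length(m))
    pos <- m > 0
    out[pos] <- m[pos] * log(p[pos])
    pos <- u > 0
    out[pos] <- out[pos] + u[pos] * log(1 - p[pos])
    out
  }
  px <- mx / (mx + ux); py <- my / (my + uy)
  p0 <- (mx + my) / (mx + ux + my + uy)
  g <- 2 * (ll(mx, ux, px) + ll(my, uy, py) -
              ll(mx, ux, p0) - ll(my, uy, p0))
  stats::pchisq(pmax(g, 0), df = 1, lower.tail = FALSE)
}

#' Exact (Fisher/hypergeometric) p-value for pooled 2x2 window tables
#'
#' Two-sided Fisher's exact test probability for the table
#' \code{rbind(c(mx, ux), c(my, uy))}, computed by summing hypergeometric
#' point probabilities no larger than the observed one. Vectorized over
#' windows.
#'
#' @param mx,ux Methylated / unmethylated pooled counts in group X.
#' @param my,uy Methylated / unmethylated pooled counts in group Y.
#' @return Numeric vector of p-values.
#' @export
fisher_window_p <- function(mx, ux, my, uy) {
  n <- length(mx)
  stopifnot(length(ux) == n, length(my) == n, length(uy) == n)
  vapply(seq_len(n), function(i) {
    m1 <- mx[i] + ux[i]   # row total X
    m2 <- my[i] + uy[i]   # row total Y
    k <- mx[i] + my[i]    # methylated column total
    support <- max(0, k - m2):min(k, m1)
    dens <- stats::dhyper(support, m1, m2, k)
    obs <- stats::dhyper(mx[i], m1, m2, k)
    sum(dens[dens <= obs * (1 + 1e-7)])
  }, numeric(1))
}
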