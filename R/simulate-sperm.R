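#' Simulate replicate X and Y sperm methylomes with planted DMRs
#'
#' Lays CpG sites at a regular spacing along the simulated chromosomes
#' (plus small CHG/CHH complements and an unmethylated spike-in contig)
#' and draws per-site methylated counts from a binomial at the configured
#' coverage. The X background sits at `baseline`; the Y background may
#' carry a global offset, and windows listed in `dmr_spec` are shifted in
#' Y by the requested delta and direction, giving a recorded DMR truth.
#'
#' @param annotation Gene annotation (used only to carry the chromosome
#'   set; sites are laid independently of genes).
#' @param dmr_spec Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `direction` (`"hyper"`/`"hypo"`, Y versus X) and
#'   `delta` (shift in methylation proportion, in \[0, 1\]). May be `NULL`
#'   or empty for no planted regions.
#' @param config A [sim_config()]; supplies chromosome sizes and the seed.
#' @param baseline Background CpG methylation level.
#' @param coverage Mean per-site read coverage.
#' @param y_offset Additive global shift of the Y background level.
#' @param cpg_spacing Distance between consecutive CpG sites in bp; the
#'   default of 100 gives ten CpGs per kilobase window.
#' @param n_chh Number of CHH (and CHG) decoy sites per chromosome.
#' @param spikein_name,spikein_sites,non_conversion Name, site count and
#'   residual (non-converted) level of the unmethylated spike-in contig
#'   used to estimate bisulfite conversion efficiency.
#'
#' @return A list of class `"sperm_methylome_sim"`: `X` and `Y` are lists
#'   of `n_replicates` site tables (`chrom`, `pos`, `strand`, `context`,
#'   `count_methylated`, `count_unmethylated`), `truth` is the realized
#'   DMR spec (rows with `delta > 0` only).
#' @export
simulate_sperm_methylomes <- function(annotation, dmr_spec = NULL, config,
                                      baseline = 0.95, coverage = 30,
                                      y_offset = 0, cpg_spacing = 100,
                                      n_chh = 200, spikein_name = "lambda",
                                      spikein_sites = 500,
                                      non_conversion = 0.004) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2000L)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))

  if (is.null(dmr_spec)) {
    dmr_spec <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), direction = character(0),
                           delta = numeric(0), stringsAsFactors = FALSE)
  }
  if (nrow(dmr_spec)) {
    stopifnot(all(dmr_spec$direction %in% c("hyper", "hypo")),
              all(dmr_spec$delta >= 0), all(dmr_spec$delta <= 1))
    if (!all(dmr_spec$chrom %in% chroms) ||
        any(dmr_spec$start < 0) || any(dmr_spec$end > config$chrom_length))
      stop("dmr_spec intervals must lie on simulated chromosomes", call. = FALSE)
  }
  truth <- dmr_spec[dmr_spec$delta > 0, , drop = FALSE]
  rownames(truth) <- NULL

  pos_list <- lapply(chroms, function(ch)
    seq.int(cpg_spacing %/% 2, config$chrom_length, by = cpg_spacing))
  site_chrom <- rep(chroms, lengths(pos_list))
  site_pos <- unlist(pos_list)
  n_cpg <- length(site_pos)

  level_x <- rep(baseline, n_cpg)
  level_y <- rep(baseline + y_offset, n_cpg)
  for (i in seq_len(nrow(truth))) {
    hit <- site_chrom == truth$chrom[i] &
      site_pos > truth$start[i] & site_pos <= truth$end[i]
    shift <- if (truth$direction[i] == "hyper") truth$delta[i] else -truth$delta[i]
    level_y[hit] <- level_y[hit] + shift
  }
  if (any(level_y < 0 | level_y > 1) || any(level_x < 0 | level_x > 1)) {
    warning("methylation levels clipped to [0, 1]")
    level_x <- pmin(pmax(level_x, 0), 1)
    level_y <- pmin(pmax(level_y, 0), 1)
  }

  # non-CpG complement: a small fraction of CHG/CHH sites is genuinely
  # methylated (0.5% and 1.4%), the rest sit at the non-conversion floor
  n_other <- 2L * n_chh * length(chroms)
  other_context <- rep(rep(c("CHG", "CHH"), each = n_chh), length(chroms))
  meth_frac <- ifelse(other_context == "CHG", 0.005, 0.014)
  other <- data.frame(
    chrom = rep(chroms, each = 2 * n_chh),
    pos = as.vector(replicate(length(chroms),
                              sample.int(config$chrom_length, 2 * n_chh))),
    context = other_context,
    level = ifelse(stats::runif(n_other) < meth_frac, 0.8, non_conversion),
    stringsAsFactors = FALSE
  )
  spike <- data.frame(
    chrom = spikein_name,
    pos = seq.int(10, by = 50, length.out = spikein_sites),
    context = "CpG", level = non_conversion, stringsAsFactors = FALSE
  )

  draw_rep <- function(levels) {
    chrom <- c(site_chrom, other$chrom, spike$chrom)
    pos <- c(site_pos, other$pos, spike$pos)
    context <- c(rep("CpG", n_cpg), other$context, spike$context)
    lev <- c(levels, other$level, spike$level)
    cov <- stats::rpois(length(lev), coverage)
    m <- stats::rbinom(length(lev), cov, lev)
    out <- data.frame(chrom = chrom, pos = as.integer(pos), strand = "+",
                      context = context, count_methylated = m,
                      count_unmethylated = cov - m, stringsAsFactors = FALSE)
    out[order(out$chrom, out$pos), ]
  }
  X <- lapply(seq_len(config$n_replicates), function(i) draw_rep(level_x))
  Y <- lapply(seq_len(config$n_replicates), function(i) draw_rep(level_y))

  structure(list(X = X, Y = Y, truth = truth, baseline = baseline,
                 coverage = coverage, spikein = spikein_name,
                 non_conversion = non_conversion, config = config),
            class = "sperm_methylome_sim")
}

#' Simulate X and Y sperm expression counts with planted fold changes
#'
#' Negative-binomial counts for three X and three Y replicates over the
#' annotated genes. Genes listed in `de_spec` have their Y mean multiplied
#' by the given fold change, so an asymmetric up/down spec reproduces the
#' up-skewed differential expression seen when comparing Y to X sperm.
#'
#' @param annotation Gene annotation providing the gene set.
#' @param de_spec Data frame with columns `gene_id` and `fold_change`
#'   (Y over X, > 0); `NULL` or empty plants no differential genes.
#' @param config A [sim_config()] (seed, replicate count).
#' @param mean_expr Median baseline expression count.
#' @param dispersion Negative-binomial dispersion.
#'
#' @return List of class `"sperm_expression_sim"` with `counts` (genes x
#'   6 samples), `groups` (named group factor), and `truth` (the spec with
#'   a derived `direction` column).
#' @export
simulate_sperm_expression <- function(annotation, de_spec = NULL, config,
                                      mean_expr = 100, dispersion = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3000L)
  if (is.null(de_spec)) {
    de_spec <- data.frame(gene_id = character(0), fold_change = numeric(0),
                          stringsAsFactors = FALSE)
  }
  if (nrow(de_spec)) {
    stopifnot(all(de_spec$fold_change > 0),
              all(de_spec$gene_id %in% annotation$gene_id))
  }
  ids <- annotation$gene_id
  base <- stats::rlnorm(length(ids), log(mean_expr), 0.4)
  fc <- rep(1, length(ids))
  fc[match(de_spec$gene_id, ids)] <- de_spec$fold_change
  nr <- config$n_replicates
  samples <- c(paste0("X_r", seq_len(nr)), paste0("Y_r", seq_len(nr)))
  mu <- cbind(matrix(base, length(ids), nr),
              matrix(base * fc, length(ids), nr))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = length(ids), dimnames = list(ids, samples))
  truth <- de_spec
  truth$direction <- ifelse(truth$fold_change > 1, "up",
                            ifelse(truth$fold_change < 1, "down", "ns"))
  groups <- stats::setNames(rep(c("X", "Y"), each = nr), samples)
  structure(list(counts = counts, groups = groups, truth = truth,
                 config = config),
            class = "sperm_expression_sim")
}
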