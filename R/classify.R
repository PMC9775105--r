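#' Call the genotype observed at one marker site in one sample
#'
#' Vectorized evidence call from allele-specific read counts. A site shows
#' `both` alleles when each parental allele reaches `min_allele_reads`;
#' it is `maternal_only` (or `paternal_only`) when only that allele
#' reaches the per-allele threshold and the site's total read count
#' reaches `min_total_reads`; anything weaker is `uncovered`.
#'
#' @param maternal_reads,paternal_reads,other_reads Non-negative read
#'   counts (recycled to common length).
#' @param min_allele_reads Reads required to accept an allele as seen.
#' @param min_total_reads Total reads required for a single-allele call.
#' @return Character vector in
#'   `c("maternal_only", "paternal_only", "both", "uncovered")`.
#' @export
call_marker_genotype <- function(maternal_reads, paternal_reads,
                                 other_reads = 0L,
                                 min_allele_reads = 2, min_total_reads = 5) {
  stopifnot(min_allele_reads >= 1, min_total_reads >= 1)
  n <- max(length(maternal_reads), length(paternal_reads), length(other_reads))
  m <- rep_len(maternal_reads, n)
  p <- rep_len(paternal_reads, n)
  o <- rep_len(other_reads, n)
  total <- m + p + o
  out <- rep("uncovered", n)
  out[m >= min_allele_reads & p < min_allele_reads & total >= min_total_reads] <- "maternal_only"
  out[p >= min_allele_reads & m < min_allele_reads & total >= min_total_reads] <- "paternal_only"
  out[m >= min_allele_reads & p >= min_allele_reads] <- "both"
  out
}

#' Classify one gene from its per-site calls
#'
#' A gene harboring at least one biparental (heterozygous-evidence) site
#' is zygotic; otherwise one harboring a maternal-only site is maternal;
#' otherwise one harboring a paternal-only site is paternal; a gene with
#' no covered site is unobserved. The priority order zygotic > maternal >
#' paternal means biparental evidence anywhere dominates.
#'
#' @param calls Character vector of site calls from
#'   [call_marker_genotype()].
#' @return One of `"maternal"`, `"zygotic"`, `"paternal"`, `"unobserved"`.
#' @export
classify_gene <- function(calls) {
  if (any(calls == "both")) return("zygotic")
  if (any(calls == "maternal_only")) return("maternal")
  if (any(calls == "paternal_only")) return("paternal")
  "unobserved"
}

#' Classify every gene at every stage of one cross
#'
#' Merges replicate evidence per marker site (by pooling allele counts
#' under the default `"union"` rule, or by per-replicate majority vote
#' under `"majority"`), calls each site, and classifies each gene per
#' stage by the zygotic > maternal > paternal priority. Genes listed in
#' `gene_map` but covered by no site at a stage are `unobserved`.
#'
#' @param observations Allele-count table for one cross (columns `stage`,
#'   `replicate`, `chrom`, `pos`, `maternal_reads`, `paternal_reads`,
#'   `other_reads`).
#' @param gene_map Gene-to-marker map from [assign_markers_to_genes()].
#' @param stages Declared ordered stage series; an observation at a stage
#'   outside this series is an error.
#' @param replicate_rule `"union"` (pool counts across replicates before
#'   calling) or `"majority"` (call each replicate, then take the
#'   majority non-uncovered call per site, ties resolved by the
#'   both > maternal_only > paternal_only priority).
#' @param min_allele_reads,min_total_reads Thresholds passed to
#'   [call_marker_genotype()].
#'
#' @return List with
#'   \describe{
#'     \item{classification}{data frame `gene_id`, `stage`, `category`,
#'       `n_markers_covered`, one row per gene x stage.}
#'     \item{counts}{per-stage category counts (`stage`, `maternal`,
#'       `zygotic`, `paternal`, `unobserved`).}
#'     \item{site_calls}{per-site calls (`stage`, `chrom`, `pos`,
#'       `call`), covered sites only.}
#'   }
#' @export
classify_stage <- function(observations, gene_map, stages,
                           replicate_rule = c("union", "majority"),
                           min_allele_reads = 2, min_total_reads = 5) {
  replicate_rule <- match.arg(replicate_rule)
  bad <- setdiff(unique(observations$stage), stages)
  if (length(bad))
    stop("observations contain stages outside the declared series: ",
         paste(bad, collapse = ", "), call. = FALSE)

  genes <- sort(unique(gene_map$gene_id))
  site_key <- function(d) paste(d$chrom, d$pos)

  per_stage <- lapply(stages, function(st) {
    obs <- observations[observations$stage == st, , drop = FALSE]
    if (nrow(obs) == 0) {
      calls <- character(0); keys <- character(0); agg_tab <- NULL
    } else if (replicate_rule == "union") {
      agg <- stats::aggregate(
        obs[c("maternal_reads", "paternal_reads", "other_reads")],
        by = list(chrom = obs$chrom, pos = obs$pos), FUN = sum)
      calls <- call_marker_genotype(agg$maternal_reads, agg$paternal_reads,
                                    agg$other_reads,
                                    min_allele_reads, min_total_reads)
      keys <- site_key(agg)
      agg_tab <- agg
    } else {
      obs$call <- call_marker_genotype(obs$maternal_reads, obs$paternal_reads,
                                       obs$other_reads,
                                       min_allele_reads, min_total_reads)
      obs <- obs[obs$call != "uncovered", , drop = FALSE]
      keys_all <- site_key(obs)
      calls <- vapply(split(obs$call, keys_all), .majority_call, character(1))
      keys <- names(calls)
      agg_tab <- NULL
    }
    covered <- calls != "uncovered"
    calls <- calls[covered]; keys <- keys[covered]
    if (replicate_rule == "union" && !is.null(agg_tab)) {
      site_df <- data.frame(stage = st,
                            chrom = agg_tab$chrom[covered],
                            pos = agg_tab$pos[covered],
                            call = unname(calls), stringsAsFactors = FALSE)
    } else if (length(keys)) {
      parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
      site_df <- data.frame(stage = st, chrom = parts[, 1],
                            pos = as.integer(parts[, 2]),
                            call = unname(calls), stringsAsFactors = FALSE)
    } else {
      site_df <- data.frame(stage = character(0), chrom = character(0),
                            pos = integer(0), call = character(0),
                            stringsAsFactors = FALSE)
    }

    map_call <- calls[match(site_key(gene_map), keys)]
    cat_by_gene <- tapply(map_call, gene_map$gene_id, function(cl) {
      cl <- cl[!is.na(cl)]
      c(classify_gene(cl), length(cl))
    })
    cls <- vapply(cat_by_gene[genes], `[`, character(1), 1)
    ncov <- as.integer(vapply(cat_by_gene[genes], `[`, character(1), 2))
    list(
      classification = data.frame(gene_id = genes, stage = st,
                                  category = unname(cls),
                                  n_markers_covered = ncov,
                                  stringsAsFactors = FALSE),
      site_calls = site_df
    )
  })

  classification <- do.call(rbind, lapply(per_stage, `[[`, "classification"))
  site_calls <- do.call(rbind, lapply(per_stage, `[[`, "site_calls"))
  rownames(classification) <- rownames(site_calls) <- NULL

  counts <- do.call(rbind, lapply(stages, function(st) {
    cl <- classification[classification$stage == st, "category"]
    data.frame(stage = st,
               maternal = sum(cl == "maternal"),
               zygotic = sum(cl == "zygotic"),
               paternal = sum(cl == "paternal"),
               unobserved = sum(cl == "unobserved"),
               stringsAsFactors = FALSE)
  }))
  list(classification = classification, counts = counts,
       site_calls = site_calls)
}

.majority_call <- function(cl) {
  tab <- table(cl)
  top <- names(tab)[tab == max(tab)]
  for (pref in c("both", "maternal_only", "paternal_only"))
    if (pref %in% top) return(pref)
  top[1]
}

#' Per-stage composition of maternal, zygotic and paternal SNP calls
#'
#' @param site_calls Covered site-call table from [classify_stage()].
#' @return Data frame per stage with `pct_maternal`, `pct_zygotic`
#'   (biparental sites), `pct_paternal`, summing to 100 over covered
#'   sites; stages without covered sites get `NA` with a warning.
#' @export
snp_composition <- function(site_calls) {
  stages <- unique(site_calls$stage)
  out <- do.call(rbind, lapply(stages, function(st) {
    cl <- site_calls$call[site_calls$stage == st]
    n <- length(cl)
    if (n == 0) {
      warning("stage ", st, " has no covered sites; composition undefined")
      return(data.frame(stage = st, n_sites = 0L, pct_maternal = NA_real_,
                        pct_zygotic = NA_real_, pct_paternal = NA_real_))
    }
    data.frame(stage = st, n_sites = n,
               pct_maternal = 100 * sum(cl == "maternal_only") / n,
               pct_zygotic = 100 * sum(cl == "both") / n,
               pct_paternal = 100 * sum(cl == "paternal_only") / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Locate the zygotic-activation transition in a stage series
#'
#' Finds the consecutive stage pair with the largest increase in zygotic
#' gene count (ties broken toward the earlier pair) and, symmetrically,
#' the pair with the largest decrease in maternal gene count. When no
#' strictly positive increase (resp. decrease) exists the corresponding
#' element is `NULL`.
#'
#' @param stages Ordered stage labels (length >= 2).
#' @param zygotic_counts,maternal_counts Per-stage gene counts.
#' @return List with `zygotic_up` and `maternal_down`, each either
#'   `c(from, to)` stage labels or `NULL`.
#' @export
detect_transition <- function(stages, zygotic_counts, maternal_counts = NULL) {
  stopifnot(length(stages) >= 2, length(zygotic_counts) == length(stages))
  pick <- function(delta) {
    if (all(delta <= 0)) return(NULL)
    i <- which.max(delta)  # which.max takes the earliest tie
    c(from = stages[i], to = stages[i + 1])
  }
  res <- list(zygotic_up = pick(diff(zygotic_counts)))
  res$maternal_down <- if (is.null(maternal_counts)) NULL else {
    stopifnot(length(maternal_counts) == length(stages))
    pick(-diff(maternal_counts))
  }
  res
}

#' Correlation between paternal and zygotic activation across stages
#'
#' @param paternal_counts,zygotic_counts Per-stage gene (or SNP) counts,
#'   length >= 3.
#' @return Pearson correlation coefficient; `NA` with a warning when
#'   either series has zero variance.
#' @export
paternal_zygotic_coupling <- function(paternal_counts, zygotic_counts) {
  stopifnot(length(paternal_counts) == length(zygotic_counts),
            length(paternal_counts) >= 3)
  if (stats::sd(paternal_counts) == 0 || stats::sd(zygotic_counts) == 0) {
    warning("zero variance in a count series; correlation undefined")
    return(NA_real_)
  }
  stats::cor(paternal_counts, zygotic_counts)
}

#' Compare a per-replicate statistic between XX and XY embryos
#'
#' Equal-variance two-sample two-tailed t-test, with the conventional
#' significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param xx,xy Numeric vectors of per-replicate values (>= 2 each).
#' @return List with `t`, `df`, `p` and `stars`.
#' @export
compare_sexes <- function(xx, xy) {
  if (length(xx) < 2 || length(xy) < 2)
    stop("need at least 2 replicates per group", call. = FALSE)
  df <- length(xx) + length(xy) - 2
  sp2 <- ((length(xx) - 1) * stats::var(xx) +
          (length(xy) - 1) * stats::var(xy)) / df
  if (sp2 == 0) {
    t <- if (mean(xx) == mean(xy)) 0 else sign(mean(xx) - mean(xy)) * Inf
  } else {
    res <- stats::t.test(xx, xy, var.equal = TRUE)
    t <- unname(res$statistic)
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(t = t, df = df, p = p, stars = stars)
}
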