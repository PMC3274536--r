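# Per-gene "local" statistics whose ranks feed the set-level WRS test.
# Only the rank order of a local statistic matters downstream, so the choice
# among t, fold change and count-based statistics has limited impact on the
# enrichment results; all are provided because they are what practitioners
# compute from microarray and RNA-seq inputs.

split_groups <- function(data, group) {
  stopifnot(is.data.frame(data), "gene" %in% names(data))
  if (anyDuplicated(data$gene)) stop("gene ids must be unique", call. = FALSE)
  sample_cols <- setdiff(names(data), "gene")
  if (length(group) != length(sample_cols)) {
    stop("`group` must have one label per sample column", call. = FALSE)
  }
  # stable level order: factor levels if given, else sorted -- so relabelling
  # the samples (a label swap) flips the sign convention, as it should
  lev <- if (is.factor(group)) levels(group) else sort(unique(as.character(group)))
  if (length(lev) != 2L) stop("exactly two groups are required", call. = FALSE)
  group <- as.character(group)
  mat <- as.matrix(data[sample_cols])
  list(g1 = mat[, group == lev[1], drop = FALSE],
       g2 = mat[, group == lev[2], drop = FALSE],
       genes = data$gene, levels = lev)
}

#' Per-gene two-sample t statistics
#'
#' Classical pooled-variance two-sample t per gene, sign convention
#' group1 - group2 (first level of `group` minus the second).  Genes with
#' zero pooled variance get statistic 0 with a warning.
#'
#' @param data a data frame with a `gene` column and one numeric column per
#'   sample (log2-scale expression for arrays).
#' @param group character/factor vector of group labels, one per sample
#'   column, with exactly two levels; at least two samples per group.
#' @return a tibble with columns `gene`, `stat`.
#' @export
local_t <- function(data, group) {
  sp <- split_groups(data, group)
  n1 <- ncol(sp$g1); n2 <- ncol(sp$g2)
  if (n1 < 2 || n2 < 2) {
    stop("need at least two samples per group for a t statistic",
         call. = FALSE)
  }
  m1 <- rowMeans(sp$g1); m2 <- rowMeans(sp$g2)
  v1 <- apply(sp$g1, 1, stats::var); v2 <- apply(sp$g2, 1, stats::var)
  pooled <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  if (any(se == 0)) {
    warning(sum(se == 0), " gene(s) with zero pooled variance; t set to 0")
    t[se == 0] <- 0
  }
  tibble::tibble(gene = sp$genes, stat = t)
}

#' Per-gene log2 fold change
#'
#' Difference of group means on the log2 scale (values are assumed already
#' log2-transformed), sign convention group1 - group2.
#'
#' @inheritParams local_t
#' @return a tibble with columns `gene`, `stat`.
#' @export
local_log2fc <- function(data, group) {
  sp <- split_groups(data, group)
  tibble::tibble(gene = sp$genes, stat = rowMeans(sp$g1) - rowMeans(sp$g2))
}

check_count_pair <- function(x, y, T1, T2) {
  stopifnot(length(x) == length(y), length(T1) == 1L, length(T2) == 1L,
            T1 > 0, T2 > 0)
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(x + y == 0)) {
    stop("genes with zero total count must be filtered out first",
         call. = FALSE)
  }
}

#' Wald-type statistic for two-group count data
#'
#' For summed counts `x`, `y` of a gene in two tissues with per-group library
#' sizes `T1`, `T2`, and `t_hat = T1 / T2`, the statistic
#' `z = (x - t_hat * y) / sqrt(t_hat * (x + y))` is approximately standard
#' normal when the gene's Poisson rates are equal after library-size scaling.
#'
#' @param x,y non-negative integer count vectors (one element per gene);
#'   `x + y > 0` for every gene.
#' @param T1,T2 positive totals of mapped reads in the two groups.
#' @return numeric vector of z statistics.
#' @examples
#' poisson_wald(30, 10, T1 = 2e6, T2 = 1e6)   # (30 - 20)/sqrt(2*40)
#' @export
poisson_wald <- function(x, y, T1, T2) {
  check_count_pair(x, y, T1, T2)
  t_hat <- T1 / T2
  (x - t_hat * y) / sqrt(t_hat * (x + y))
}

#' Poisson likelihood-ratio statistic for two-group count data
#'
#' Closed-form likelihood ratio for H0: equal Poisson rates after library-size
#' scaling: `2 [x log(x/x0) + y log(y/y0)]` with null fitted means
#' `x0 = (x+y) T1/(T1+T2)`, `y0 = (x+y) T2/(T1+T2)` and `0 log 0 = 0`.
#' The signed variant multiplies by `sign(x - t_hat y)` so direction is
#' preserved for one-sided set-level tests.
#'
#' @inheritParams poisson_wald
#' @param signed if `TRUE`, attach the sign of the rate difference.
#' @return numeric vector of LR statistics (nonnegative unless `signed`).
#' @export
poisson_lr <- function(x, y, T1, T2, signed = FALSE) {
  check_count_pair(x, y, T1, T2)
  x0 <- (x + y) * T1 / (T1 + T2)
  y0 <- (x + y) * T2 / (T1 + T2)
  xlogr <- function(a, a0) ifelse(a == 0, 0, a * log(a / a0))
  lr <- 2 * (xlogr(x, x0) + xlogr(y, y0))
  lr <- pmax(lr, 0)   # guard tiny negative rounding at the null
  if (signed) lr * sign(x - (T1 / T2) * y) else lr
}

#' Read a gene-level statistic table
#'
#' Reads a TSV with columns `gene` and `stat` (additional columns are kept),
#' the interchange format for externally computed local statistics such as a
#' negative-binomial likelihood ratio.
#'
#' @param path file path.
#' @return a tibble with at least columns `gene` (character), `stat` (double).
#' @export
read_gene_stats <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "stat") %in% names(out))) {
    stop("stats table must have columns `gene` and `stat`", call. = FALSE)
  }
  out$gene <- as.character(out$gene)
  out
}

#' Write a gene-level statistic table
#'
#' @param stats a data frame with columns `gene`, `stat`.
#' @param path destination TSV path (written atomically).
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(stats, path) {
  stopifnot(all(c("gene", "stat") %in% names(stats)))
  write_atomic_tsv(stats, path)
}
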