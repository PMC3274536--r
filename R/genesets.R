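# Competitive gene set enrichment: each set's local statistics are WRS-tested
# against those of all scored genes outside the set.  Genes without a
# statistic are excluded from both sides, so the universe is the scored-gene
# set; overlapping sets are tested independently.

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `term`, `description`,
#' member gene ids.  Duplicate genes within a term are deduplicated;
#' duplicate term ids are an error.
#'
#' @param path file path.
#' @return a named list of character vectors (term id -> gene ids), with a
#'   `names` attribute-like tibble in `attr(, "terms")` holding descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty gene-set file: ", path)
    out <- list()
    attr(out, "terms") <- tibble::tibble(term = character(),
                                         name = character())
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  attr(sets, "terms") <- tibble::tibble(
    term = ids, name = vapply(fields, `[[`, character(1), 2L))
  sets
}

#' Read a two-column gene-to-term mapping
#'
#' TSV with columns `gene`, `term` (header required), the shape produced by
#' annotation exports; many-to-many mappings are allowed, as with GO.
#'
#' @param path file path.
#' @return a named list of character vectors (term id -> gene ids).
#' @export
read_gene_mapping <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "term") %in% names(tab))) {
    stop("mapping must have columns `gene` and `term`", call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    warning("empty mapping file: ", path)
    out <- list()
    attr(out, "terms") <- tibble::tibble(term = character(),
                                         name = character())
    return(out)
  }
  sets <- lapply(split(as.character(tab$gene), as.character(tab$term)), unique)
  attr(sets, "terms") <- tibble::tibble(term = names(sets),
                                        name = names(sets))
  sets
}

#' Competitive gene set enrichment by the WRS test
#'
#' For every gene set, the local statistics of its member genes are compared
#' against those of all other scored genes with the Wilcoxon rank-sum test.
#' Sets are intersected with the scored universe before size filtering.  Both
#' the uniform (Irwin-Hall) and the normal p-value are always reported;
#' `p_used` follows `method` (`"auto"`: uniform when the set has fewer than
#' 30 scored genes, normal otherwise) and feeds the multiple-testing
#' adjustment.
#'
#' @param stats a data frame with columns `gene`, `stat` (one scored gene per
#'   row; genes must be unique and statistics finite).
#' @param gene_sets a named list of character vectors (term -> gene ids), as
#'   returned by [read_gmt()] or [read_gene_mapping()].
#' @param min_size,max_size retain sets with `min_size <= m <= max_size`
#'   scored genes (defaults 2 and 30, the small-set window where the choice
#'   of approximation matters).
#' @param method `"auto"` (default), `"uniform"` or `"normal"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param adjust multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`).
#' @param absolute rank `abs(stat)` instead of the signed statistic.
#' @return a tibble with one row per surviving set, columns `term`, `name`,
#'   `size`, `W`, `U`, `direction`, `p_uniform`, `p_normal`, `p_used`,
#'   `p_adjusted`, ordered by `p_used`.
#' @export
wrs_enrich <- function(stats, gene_sets,
                       min_size = 2L, max_size = 30L,
                       method = c("auto", "uniform", "normal"),
                       alternative = c("two.sided", "greater", "less"),
                       adjust = "bonferroni",
                       absolute = FALSE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(stats), all(c("gene", "stat") %in% names(stats)))
  if (nrow(stats) == 0L) stop("`stats` is empty", call. = FALSE)
  if (anyDuplicated(stats$gene)) {
    stop("duplicate gene ids in `stats`", call. = FALSE)
  }
  values <- stats$stat
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`stat` must be finite; drop unscored genes first", call. = FALSE)
  }
  if (absolute) values <- abs(values)

  N <- length(values)
  r <- midranks(values)
  names(r) <- as.character(stats$gene)
  tf <- tie_factor(as.integer(table(values)), N)

  term_info <- attr(gene_sets, "terms")
  n_unscored <- sum(vapply(gene_sets, function(g) {
    !any(g %in% names(r))
  }, logical(1)))
  if (n_unscored > 0) {
    message(n_unscored,
            " gene set(s) dropped: no member gene has a statistic")
  }
  rows <- purrr::imap(gene_sets, function(genes, term) {
    members <- intersect(unique(genes), names(r))
    m <- length(members)
    if (m < min_size || m > max_size || m >= N) return(NULL)
    W <- sum(r[members])
    n <- N - m
    used <- if (method == "auto") {
      if (m < 30) "uniform" else "normal"
    } else method
    pu <- wrs_p_components(W, m, n, tf, "uniform")
    pn <- wrs_p_components(W, m, n, tf, "normal")
    pick <- function(pl_pg) switch(alternative,
      "two.sided" = two_sided(pl_pg[1], pl_pg[2]),
      "greater" = pl_pg[2], "less" = pl_pg[1])
    tibble::tibble(
      term = term, size = m, W = W, U = W - m * (m + 1) / 2,
      direction = if (W / m >= (N + 1) / 2) "up" else "down",
      p_uniform = pick(pu), p_normal = pick(pn),
      p_used = if (used == "uniform") pick(pu) else pick(pn))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    warning("no gene sets survive the size filters")
    return(tibble::tibble(term = character(), name = character(),
                          size = integer(), W = double(), U = double(),
                          direction = character(), p_uniform = double(),
                          p_normal = double(), p_used = double(),
                          p_adjusted = double()))
  }
  out$p_adjusted <- stats::p.adjust(out$p_used, method = adjust)
  if (!is.null(term_info) && nrow(term_info) > 0) {
    out <- dplyr::left_join(out, term_info, by = "term")
  }
  if (!"name" %in% names(out)) out$name <- out$term
  out$name[is.na(out$name)] <- out$term[is.na(out$name)]
  dplyr::arrange(
    dplyr::select(out, "term", "name", "size", "W", "U", "direction",
                  "p_uniform", "p_normal", "p_used", "p_adjusted"),
    .data$p_used, .data$term)
}

#' Write an enrichment table
#'
#' @param enrichment a tibble from [wrs_enrich()].
#' @param path destination TSV path (written atomically).
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  write_atomic_tsv(enrichment, path)
}
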