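# Simulation machinery comparing the uniform and normal approximations:
# false-positive-rate calibration on a null gene universe, power against a
# location-shifted gene set, and synthetic enrichment fixtures.  Local
# statistics are drawn directly per gene (no sample-level expression is
# simulated); under the null they come from N(3, 1) -- the location is
# arbitrary since only ranks enter the test.

# deterministic per-cell substream: reproducible and order-independent
cell_seed <- function(root, idx) {
  as.integer((as.double(root) * 1009 + 7919 * idx) %% 2147483629)
}

sim_result <- function(rates, type) {
  structure(rates, class = c("wrs_sim", class(rates)), sim_type = type)
}

#' False-positive-rate simulation for the WRS approximations
#'
#' Per round, `G` null local statistics are drawn from N(3, 1); `reps` times a
#' random `m`-subset is taken as the gene set and the two-sided WRS p-value is
#' computed under both approximations; the per-round false positive rate at
#' each significance level is the fraction of rejections.  Uniform-method
#' rates should sit at the nominal level for every set size, while the normal
#' approximation becomes conservative for small sets at stringent levels.
#'
#' @param G total number of genes (default 15000).
#' @param set_sizes gene-set sizes to simulate (default `c(5, 10, 15, 20,
#'   25)`).
#' @param alpha_levels significance levels (default `c(0.05, 0.01, 0.001)`).
#' @param rounds outer repeats (default 50).
#' @param reps inner repetitions per round (default 100).
#' @param seed root seed; per-(size, round) substreams are derived from it
#'   deterministically.
#' @return a `wrs_sim` tibble with one row per (method, m, alpha, round) and
#'   the per-round rejection `rate`; `tidy()` aggregates to means with
#'   Monte-Carlo standard errors.
#' @export
simulate_fpr <- function(G = 15000L, set_sizes = c(5L, 10L, 15L, 20L, 25L),
                         alpha_levels = c(0.05, 0.01, 0.001),
                         rounds = 50L, reps = 100L, seed = 1L) {
  stopifnot(all(set_sizes < G), rounds >= 1, reps >= 1,
            all(alpha_levels > 0), all(alpha_levels <= 1))
  grid <- tidyr::expand_grid(m = as.integer(set_sizes),
                             round = seq_len(rounds))
  rows <- purrr::pmap(grid, function(m, round) {
    idx <- match(m, set_sizes) * 100000L + round
    set.seed(cell_seed(seed, idx))
    pool <- stats::rnorm(G, mean = 3, sd = 1)
    r <- rank(pool)           # continuous draws: ties have probability zero
    n <- G - m
    p2 <- matrix(0, nrow = reps, ncol = 2)  # uniform, normal
    for (i in seq_len(reps)) {
      W <- sum(r[sample.int(G, m)])
      pu <- wrs_p_components(W, m, n, 0, "uniform")
      pn <- wrs_p_components(W, m, n, 0, "normal")
      p2[i, ] <- c(two_sided(pu[1], pu[2]), two_sided(pn[1], pn[2]))
    }
    tidyr::expand_grid(method = c("uniform", "normal"),
                       alpha = alpha_levels) |>
      dplyr::mutate(m = m, round = round,
                    rate = purrr::map2_dbl(.data$method, .data$alpha,
                      \(me, a) mean(p2[, if (me == "uniform") 1 else 2] < a)))
  })
  sim_result(dplyr::bind_rows(rows), "fpr")
}

#' Power simulation for the WRS approximations
#'
#' Per repetition a fresh universe is drawn: the `m` gene-set statistics from
#' N(3 + delta, 1) and the `G - m` complement statistics from N(3, 1); power
#' is the fraction of repetitions with two-sided p below `threshold`
#' (default 0.0005, i.e. 0.05 with a Bonferroni correction for ~100 sets).
#'
#' @inheritParams simulate_fpr
#' @param deltas effect sizes added to the gene-set mean (default
#'   `seq(0, 2, by = 0.2)`).
#' @param threshold rejection threshold on the two-sided p-value.
#' @param rounds outer repeats (default 30).
#' @return a `wrs_sim` tibble with one row per (method, m, delta, round).
#' @export
simulate_power <- function(G = 15000L, set_sizes = c(5L, 10L, 15L, 20L, 25L),
                           deltas = seq(0, 2, by = 0.2),
                           threshold = 0.0005,
                           rounds = 30L, reps = 100L, seed = 1L) {
  stopifnot(all(set_sizes < G), rounds >= 1, reps >= 1,
            threshold > 0, threshold < 1)
  grid <- tidyr::expand_grid(m = as.integer(set_sizes), delta = deltas,
                             round = seq_len(rounds))
  rows <- purrr::pmap(grid, function(m, delta, round) {
    idx <- match(m, set_sizes) * 10000000L +
      match(delta, deltas) * 100000L + round
    set.seed(cell_seed(seed, idx))
    n <- G - m
    hits <- matrix(FALSE, nrow = reps, ncol = 2)
    for (i in seq_len(reps)) {
      x <- stats::rnorm(m, mean = 3 + delta)
      y_sorted <- sort(stats::rnorm(n, mean = 3))
      # rank of each set value in the pooled sample, without a full pooled sort
      W <- sum(findInterval(x, y_sorted)) + sum(rank(x))
      pu <- wrs_p_components(W, m, n, 0, "uniform")
      pn <- wrs_p_components(W, m, n, 0, "normal")
      hits[i, ] <- c(two_sided(pu[1], pu[2]), two_sided(pn[1], pn[2])) <
        threshold
    }
    tibble::tibble(method = c("uniform", "normal"), m = m, delta = delta,
                   round = round, rate = colMeans(hits))
  })
  sim_result(dplyr::bind_rows(rows), "power")
}

#' Synthetic enrichment fixture
#'
#' Emulates a scored gene universe with spiked-in enriched sets so the
#' enrichment driver can be exercised end to end without any external data:
#' `n_genes` genes get N(0, 1) statistics, `n_sets` random sets are drawn,
#' and a `spike_fraction` of them have `effect` added to their member genes'
#' statistics.
#'
#' @param n_genes universe size.
#' @param set_sizes set size(s), recycled over sets.
#' @param n_sets number of gene sets.
#' @param spike_fraction fraction of sets that are truly enriched, in
#'   `[0, 1]`.
#' @param effect shift added to spiked members' statistics.
#' @param seed RNG seed.
#' @param dir directory the fixture files are written to (default a fresh
#'   temporary directory); set `NULL` to skip writing.
#' @return a list with tibbles `stats` and `truth`, the gene-set list `sets`,
#'   and (if written) paths `stats_path`, `gmt_path`, `truth_path`.
#' @export
make_fixture <- function(n_genes = 10000L, set_sizes = 5L, n_sets = 50L,
                         spike_fraction = 0.2, effect = 3, seed = 1L,
                         dir = tempfile("fixture")) {
  stopifnot(spike_fraction >= 0, spike_fraction <= 1,
            all(set_sizes <= n_genes))
  set.seed(cell_seed(seed, 424243L))
  genes <- sprintf("g%05d", seq_len(n_genes))
  stat <- stats::rnorm(n_genes)
  sizes <- rep_len(as.integer(set_sizes), n_sets)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("SET:%04d", seq_len(n_sets))
  n_spiked <- round(spike_fraction * n_sets)
  spiked <- names(sets)[seq_len(n_spiked)]
  if (n_spiked > 0) {
    members <- unique(unlist(sets[spiked], use.names = FALSE))
    stat[match(members, genes)] <- stat[match(members, genes)] + effect
  }
  stats_tbl <- tibble::tibble(gene = genes, stat = stat)
  truth <- tibble::tibble(term = spiked)
  attr(sets, "terms") <- tibble::tibble(term = names(sets),
                                        name = names(sets))
  out <- list(stats = stats_tbl, sets = sets, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$stats_path <- file.path(dir, "stats.tsv")
    write_gene_stats(stats_tbl, out$stats_path)
    out$gmt_path <- file.path(dir, "sets.gmt")
    gmt_lines <- vapply(names(sets), function(id) {
      paste(c(id, id, sets[[id]]), collapse = "\t")
    }, character(1))
    writeLines(gmt_lines, out$gmt_path)
    out$truth_path <- file.path(dir, "truth.tsv")
    write_atomic_tsv(truth, out$truth_path)
  }
  out
}
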