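# GMT/mapping parsing and the competitive enrichment driver.

write_tmp_lines <- function(lines, ext = ".gmt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("read_gmt dedups genes, keeps descriptions, rejects bad input", {
  path <- write_tmp_lines(c("GO:1\tdesc one\tg1\tg2\tg2",
                            "GO:2\tdesc two\tg3\tg1"))
  sets <- read_gmt(path)
  expect_equal(sets$`GO:1`, c("g1", "g2"))
  expect_equal(sets$`GO:2`, c("g3", "g1"))
  expect_equal(attr(sets, "terms")$name, c("desc one", "desc two"))

  expect_warning(empty <- read_gmt(write_tmp_lines(character())), "empty")
  expect_length(empty, 0)
  expect_error(read_gmt(write_tmp_lines("GO:1\tonly-two-fields")),
               "line 1")
  expect_error(read_gmt(write_tmp_lines(c("GO:1\td\tg1", "GO:1\td\tg2"))),
               "duplicate term")
})

test_that("read_gene_mapping builds many-to-many collections", {
  path <- write_tmp_lines(c("gene\tterm", "g1\tGO:1", "g2\tGO:1",
                            "g1\tGO:2", "g2\tGO:1"), ext = ".tsv")
  sets <- read_gene_mapping(path)
  expect_equal(sort(names(sets)), c("GO:1", "GO:2"))
  expect_equal(sort(sets$`GO:1`), c("g1", "g2"))  # duplicate row deduped
  expect_equal(sets$`GO:2`, "g1")
  expect_error(read_gene_mapping(write_tmp_lines(c("a\tb", "1\t2"),
                                                 ext = ".tsv")),
               "gene")
})

test_that("enrichment of a top-ranked spike reproduces the extreme-case p", {
  N <- 10000
  stats <- tibble::tibble(gene = sprintf("g%05d", 1:N), stat = 1:N / N)
  sets <- list(TOP = sprintf("g%05d", (N - 2):N),
               RAND = sprintf("g%05d", c(17, 4012, 9000, 22, 731)))
  res <- wrs_enrich(stats, sets, method = "uniform")
  top <- res[res$term == "TOP", ]
  expect_equal(top$size, 3)
  expect_equal(top$direction, "up")
  expect_equal(top$p_uniform, 2 * 7.15e-12, tolerance = 5e-3)
  expect_equal(top$p_normal, 2 * 1.35e-3, tolerance = 5e-3)
  expect_equal(top$p_used, top$p_uniform)
  expect_equal(top$p_adjusted, pmin(1, top$p_used * nrow(res)))
})

test_that("universe intersection, size filters and missing genes behave", {
  stats <- tibble::tibble(gene = sprintf("g%03d", 1:100), stat = rnorm(100))
  sets <- list(ABSENT = c("x1", "x2", "x3"),          # dropped: no overlap
               TINY = "g001",                          # dropped: m < 2
               PARTIAL = c("g001", "g002", "x9"),      # m = 2 survives
               BIG = sprintf("g%03d", 1:40))           # dropped: m > 30
  expect_message(res <- wrs_enrich(stats, sets), "dropped")
  expect_equal(res$term, "PARTIAL")
  expect_equal(res$size, 2)
  # widening the window admits the big set
  res2 <- suppressMessages(wrs_enrich(stats, sets, max_size = 50))
  expect_setequal(res2$term, c("PARTIAL", "BIG"))
  # no survivors -> empty tibble with a warning
  expect_warning(res3 <- suppressMessages(wrs_enrich(stats, sets["ABSENT"])),
                 "survive")
  expect_equal(nrow(res3), 0)
})

test_that("auto method switches to normal at 30 scored genes", {
  set.seed(12)
  stats <- tibble::tibble(gene = sprintf("g%03d", 1:200), stat = rnorm(200))
  sets <- list(SMALL = sprintf("g%03d", 1:29),
               LARGE = sprintf("g%03d", 100:130))
  res <- wrs_enrich(stats, sets, max_size = 40, method = "auto")
  expect_equal(res$p_used[res$term == "SMALL"],
               res$p_uniform[res$term == "SMALL"])
  expect_equal(res$p_used[res$term == "LARGE"],
               res$p_normal[res$term == "LARGE"])
})

test_that("enrichment output is deterministic and round-trips", {
  fx <- make_fixture(n_genes = 2000, set_sizes = 5, n_sets = 20,
                     spike_fraction = 0.2, effect = 3, seed = 5, dir = NULL)
  a <- wrs_enrich(fx$stats, fx$sets)
  b <- wrs_enrich(fx$stats, fx$sets)
  expect_identical(a, b)
  path <- tempfile(fileext = ".tsv")
  write_enrichment(a, path)
  expect_true(file.exists(path))
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$term, a$term)
  expect_equal(back$p_used, a$p_used, tolerance = 1e-12)
})

test_that("null-fixture p-values are calibrated and KS-uniform", {
  fx <- make_fixture(n_genes = 4000, set_sizes = 6, n_sets = 1000,
                     spike_fraction = 0, effect = 0, seed = 31, dir = NULL)
  res <- wrs_enrich(fx$stats, fx$sets, method = "uniform")
  expect_equal(nrow(res), 1000)
  expect_lt(abs(mean(res$p_uniform < 0.05) - 0.05), 0.02)
  expect_gt(suppressWarnings(ks.test(res$p_uniform, "punif"))$p.value, 0.01)
})

test_that("bonferroni adjustment clamps at one and is identity for k = 1", {
  stats <- tibble::tibble(gene = sprintf("g%03d", 1:50), stat = rnorm(50))
  sets <- list(A = sprintf("g%03d", 1:5))
  res <- wrs_enrich(stats, sets)
  expect_equal(res$p_adjusted, res$p_used)   # single test: identity
  expect_true(all(res$p_adjusted <= 1))
  expect_true(all(res$p_adjusted >= res$p_used))
})
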