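features_df <- function(genes, products = NULL, locus_tags = NULL) {
  n <- length(genes)
  data.frame(
    locus_tag = locus_tags %||% sprintf("F_RS%05d", seq_len(n) * 5L),
    gene = genes,
    product = products %||% rep("hypothetical protein", n),
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 600L,
    strand = "+", translation = NA_character_,
    protein_id = NA_character_, ordinal = seq_len(n) - 1L,
    stringsAsFactors = FALSE)
}

test_that("gene-name matching is case-insensitive and exact", {
  def <- cai_definition()
  f <- features_df(c("caiB", "caib", "caiBX", "yfgA"))
  m <- match_genes(f, def)
  expect_equal(m$matched_label, c("caiB", "caiB"))
  expect_equal(m$method, rep("gene-exact", 2L))
  expect_equal(m$ordinal, 0:1)
})

test_that("product fallback uses word-boundary tokens, only without /gene", {
  def <- cai_definition()
  f <- features_df(
    genes = c(NA, NA, "yfgA"),
    products = c("crotonobetainyl-CoA:carnitine CoA-transferase CaiB",
                 "caiBase-like protein",   # caiB embedded in a word: no match
                 "carnitine CoA-transferase CaiB"))  # has /gene: no fallback
  m <- match_genes(f, def, allow_product_fallback = TRUE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$matched_label, "caiB")
  expect_equal(m$method, "product-substring")
  expect_equal(nrow(match_genes(f, def, allow_product_fallback = FALSE)), 0L)
})

test_that("a CDS matching several labels takes the first in definition order", {
  def <- cluster_definition("multi", c("alpha", "beta"))
  f <- features_df(NA, products = "alpha beta fusion protein")
  m <- match_genes(f, def)
  expect_equal(m$matched_label, "alpha")
})

test_that("proximity chaining follows the worked examples", {
  one <- chain_by_proximity(matches_at(10:15), g = 4L)
  expect_length(one, 1L)
  expect_equal(one[[1L]]$max_gap, 0L)
  expect_equal(nrow(one[[1L]]$matches), 6L)

  two <- chain_by_proximity(matches_at(c(0L, 12L)), g = 10L)
  expect_length(two, 2L)
  expect_true(all(vapply(two, function(ch) nrow(ch$matches), 0L) == 1L))

  expect_equal(chain_by_proximity(matches_at(integer()), g = 10L), list())
})

test_that("chain gap bookkeeping satisfies its invariants", {
  set.seed(101)
  for (i in 1:50) {
    ords <- sort(sample(0:40, sample(1:10, 1L)))
    g <- sample(0:6, 1L)
    for (ch in chain_by_proximity(matches_at(ords), g)) {
      m <- ch$matches
      expect_length(ch$gaps, nrow(m) - 1L)
      if (nrow(m) > 1L) {
        expect_equal(ch$gaps, diff(m$ordinal) - 1L)
        expect_true(all(ch$gaps >= 0L & ch$gaps <= g))
        expect_equal(ch$max_gap, max(ch$gaps))
      } else {
        expect_equal(ch$max_gap, 0L)
      }
    }
  }
})

test_that("chaining agrees with the exhaustive oracle on small records", {
  set.seed(7)
  for (i in 1:200) {
    n_cds <- sample(0:12, 1L)
    ords <- sort(sample(seq_len(n_cds) - 1L, sample(0:n_cds, 1L)))
    for (g in 0:6) {
      got <- lapply(chain_by_proximity(matches_at(ords), g),
                    function(ch) ch$matches$ordinal)
      expect_identical(got, brute_force_chain_ordinals(ords, g))
    }
  }
})

test_that("classification separates intact, candidate and rejected", {
  def <- cai_definition()
  full <- matches_at(0:5)
  full$matched_label <- def$gene_labels
  expect_equal(classify_chain(chain_by_proximity(full, 10L)[[1L]], def), "intact")

  # duplicated label copies do not break intactness (set semantics)
  dup <- matches_at(0:6)
  dup$matched_label <- c(def$gene_labels, "caiB")
  expect_equal(classify_chain(chain_by_proximity(dup, 10L)[[1L]], def), "intact")

  partial <- matches_at(0:1)
  partial$matched_label <- c("caiT", "caiA")
  expect_equal(classify_chain(chain_by_proximity(partial, 10L)[[1L]], def,
                              min_genes = 2L), "candidate")

  single <- matches_at(0L)
  single$matched_label <- "caiT"
  expect_equal(classify_chain(chain_by_proximity(single, 10L)[[1L]], def,
                              min_genes = 2L), "rejected")
})

test_that("intact-hit sets grow monotonically with the gap budget", {
  suite <- withr::local_tempdir()
  make_suite(suite, 12, mix = c("intact", "scattered", "partial"), seed = 31)
  key <- function(res) {
    ht <- hits_table(res$hits)
    sort(paste(ht$genome_name, ht$cluster_name, ht$locus_tags)[
      ht$status == "intact"])
  }
  gs <- c(0L, 4L, 10L, 20L)
  sets <- lapply(gs, function(g)
    key(run_extraction(suite, "caiTABCDE", extraction_config(g = g))))
  for (i in seq_len(length(gs) - 1L)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
  }
})

test_that("sequence extraction slices span and genes, strand-oriented", {
  suite <- withr::local_tempdir()
  make_suite(suite, 1, seed = 21)
  # plant on mixed strands to exercise reverse complementation
  def <- cai_definition()
  gen <- make_genome(plant_spec(def, strand_pattern = c("+", "-")),
                     seed = 22L, genome_name = "mixed_strand")
  gdir <- file.path(suite, "results_mixed_strand")
  dir.create(gdir)
  writeLines(gen$gbk, file.path(gdir, "mixed_strand.gbk"))
  write_region_table(gen$regions, file.path(gdir, "regions.tsv"))
  # the ad-hoc genome has no species entry; that warning is expected
  res <- suppressWarnings(run_extraction(suite, "caiTABCDE"))
  hit <- Filter(function(h) h$genome_name == "mixed_strand", res$hits)[[1L]]
  expect_equal(hit$status, "intact")
  expect_false(hit$strand_homogeneous)
  expect_equal(nchar(hit$cluster_nt), hit$span[2L] - hit$span[1L])
  expect_equal(nrow(hit$per_gene), 6L)
  rec <- read_genbank(file.path(gdir, "mixed_strand.gbk"))[[1L]]
  minus <- which(hit$per_gene$strand == "-")[1L]
  raw <- substr(rec$sequence, hit$per_gene$start[minus] + 1L,
                hit$per_gene$end[minus])
  expect_equal(hit$per_gene$nt[minus],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(raw))))
  # every member protein starts with the planted initiator methionine
  expect_true(all(startsWith(hit$per_gene$aa, "M")))
})

test_that("run_extraction recovers planted clusters and reports edge genomes", {
  suite <- withr::local_tempdir()
  make_suite(suite, 5, mix = "intact", seed = 13)
  dir.create(file.path(suite, "results_empty_genome"))  # no GBK inside
  res <- run_extraction(suite, "caiTABCDE", out_dir = file.path(suite, "out"))
  ht <- hits_table(res$hits)
  expect_equal(sum(ht$status == "intact"), 5L)
  expect_equal(length(unique(ht$genome_name[ht$status == "intact"])), 5L)
  expect_equal(res$report$note[res$report$genome_name == "empty_genome"],
               "no data")
  expect_true(file.exists(file.path(suite, "out", "hits.tsv")))
  expect_true(file.exists(file.path(suite, "out", "report.tsv")))
  expect_equal(length(list.files(file.path(suite, "out"), pattern = "\\.faa$")),
               5L)

  # unknown MGC type: valid empty outcome, not an error
  none <- run_extraction(suite, "no_such_type")
  expect_length(none$hits, 0L)
  expect_equal(nrow(none$report), 6L)
})

test_that("scattered plantings are never intact at the default budget", {
  suite <- withr::local_tempdir()
  make_suite(suite, 3, mix = "scattered", seed = 17)
  res <- run_extraction(suite, "caiTABCDE")
  ht <- hits_table(res$hits)
  expect_equal(sum(ht$status == "intact"), 0L)
})

test_that("an empty input directory yields an empty report", {
  dir <- withr::local_tempdir()
  res <- run_extraction(dir, "caiTABCDE",
                        definitions = list(caiTABCDE = cai_definition()))
  expect_length(res$hits, 0L)
  expect_equal(nrow(res$report), 0L)
})

test_that("the strict preset sets the gap budget to four", {
  expect_equal(extraction_config(strict = TRUE)$g, 4L)
  expect_equal(extraction_config()$g, 10L)
  expect_equal(extraction_config()$min_genes, 2L)
})

test_that("determinism: identical inputs give byte-identical FASTA", {
  suite <- withr::local_tempdir()
  make_suite(suite, 2, seed = 47)
  out1 <- file.path(suite, "o1"); out2 <- file.path(suite, "o2")
  run_extraction(suite, "caiTABCDE", out_dir = out1)
  run_extraction(suite, "caiTABCDE", out_dir = out2)
  f1 <- sort(list.files(out1, pattern = "\\.(faa|fna)$"))
  expect_gt(length(f1), 0L)
  for (f in f1) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})
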