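test_that("GenBank CDS coordinates convert to 0-based half-open spans", {
  path <- write_hand_gbk()
  recs <- read_genbank(path)
  expect_length(recs, 1L)
  f <- recs[[1L]]$features
  expect_equal(f$start, c(0L, 400L, 800L))
  expect_equal(f$end, c(300L, 700L, 1100L))
  expect_equal(f$ordinal, 0:2)
  expect_equal(f$strand, c("+", "-", "+"))
  expect_equal(nchar(recs[[1L]]$sequence), 1200L)
  # uppercased on read
  expect_match(recs[[1L]]$sequence, "^[ACGT]+$")
})

test_that("a record with zero CDS yields an empty feature table", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "empty.gbk")
  writeLines(c(
    "LOCUS       EMPTYREC             60 bp    DNA     linear   BCT 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "ORIGIN",
    sprintf("%9d %s", 1L, paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), path)
  recs <- read_genbank(path)
  expect_equal(nrow(recs[[1L]]$features), 0L)
  expect_equal(recs[[1L]]$record_id, "EMPTYREC")
})

test_that("annotator-style locus tags parse verbatim", {
  tags <- sprintf("HVZ69_RS%05d", seq(3925L, 3950L, by = 5L))[1:3]
  path <- write_hand_gbk(locus_tags = tags)
  recs <- read_genbank(path)
  expect_equal(recs[[1L]]$features$locus_tag, tags)
})

test_that("multi-record files, join collapse and tag synthesis behave", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "multi.gbk")
  writeLines(c(
    hand_gbk_lines(record_id = "RECA"),
    "LOCUS       RECB                 120 bp    DNA     linear   BCT 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             join(1..30,61..90)",
    '                     /product="split protein"',
    "ORIGIN",
    sprintf("%9d %s", 1L, paste(rep("atgaaaaccg", 6), collapse = " ")),
    sprintf("%9d %s", 61L, paste(rep("atgaaaaccg", 6), collapse = " ")),
    "//"), path)
  expect_warning(expect_warning(recs <- read_genbank(path),
                                "compound location"),
                 "synthesized locus_tag")
  expect_length(recs, 2L)
  f <- recs[[2L]]$features
  expect_equal(f$start, 0L)       # outer span of the join
  expect_equal(f$end, 90L)
  expect_equal(f$locus_tag, "RECB_cds0")
})

test_that("a garbled file raises a parse error naming the record", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad.gbk")
  writeLines(c("LOCUS       BADREC 100 bp",
               "FEATURES             Location/Qualifiers",
               "     CDS             nonsense-location",
               "//"), path)
  expect_error(read_genbank(path), "BADREC")
  writeLines("just some text", file.path(dir, "notgbk.txt"))
  expect_error(read_genbank(file.path(dir, "notgbk.txt")), "LOCUS")
})

test_that("translate_cds honours the qualifier and table 11 on both strands", {
  rec <- list(record_id = "R", genome_name = "g",
              sequence = paste0("ATGAAAACCTAA",
                                as.character(Biostrings::reverseComplement(
                                  Biostrings::DNAString("ATGAAAACCTAA")))),
              features = NULL)
  f_qual <- list(locus_tag = "a", translation = "MKT", start = 0L, end = 12L,
                 strand = "+")
  expect_equal(translate_cds(f_qual, rec), "MKT")
  f_plus <- list(locus_tag = "b", translation = NA_character_, start = 0L,
                 end = 12L, strand = "+")
  expect_equal(translate_cds(f_plus, rec), "MKT")
  f_minus <- list(locus_tag = "c", translation = NA_character_, start = 12L,
                  end = 24L, strand = "-")
  expect_equal(translate_cds(f_minus, rec), "MKT")
  f_bad <- list(locus_tag = "d", translation = NA_character_, start = 0L,
                end = 10L, strand = "+")
  expect_error(translate_cds(f_bad, rec), "divisible by 3")
})

test_that("coordinate conversion is an involution", {
  for (i in 1:20) {
    s <- sample.int(10000L, 1L); e <- s + sample.int(5000L, 1L)
    gb <- to_genbank_coords(s, e)
    back <- to_internal_coords(gb$start, gb$end)
    expect_identical(c(back$start, back$end), c(s, e))
  }
})

test_that("written nucleotide FASTA round-trips against the genome slices", {
  suite <- withr::local_tempdir()
  make_suite(suite, 1, seed = 11)
  res <- run_extraction(suite, "caiTABCDE")
  hit <- res$hits[[1L]]
  gd <- list.files(suite, pattern = "^results_", full.names = TRUE)[1L]
  rec <- read_genbank(list.files(gd, pattern = "gbk$", full.names = TRUE))[[1L]]
  out <- file.path(suite, "hit.fna")
  write_cluster_fasta(hit, "nucleotide", out)
  ss <- Biostrings::readDNAStringSet(out)
  # one record per gene plus the full span
  expect_length(ss, nrow(hit$per_gene) + 1L)
  expect_equal(as.character(ss[[length(ss)]]),
               substr(rec$sequence, hit$span[1L] + 1L, hit$span[2L]))
  for (i in seq_len(nrow(hit$per_gene))) {
    slice <- substr(rec$sequence, hit$per_gene$start[i] + 1L,
                    hit$per_gene$end[i])
    if (hit$per_gene$strand[i] == "-") {
      slice <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(slice)))
    }
    expect_equal(as.character(ss[[i]]), slice)
  }
})

test_that("protein FASTA has one record per member gene with species headers", {
  suite <- withr::local_tempdir()
  make_suite(suite, 1, seed = 5)
  res <- run_extraction(suite, "caiTABCDE")
  hit <- res$hits[[1L]]
  expect_equal(hit$status, "intact")
  out <- file.path(suite, "hit.faa")
  write_cluster_fasta(hit, "protein", out)
  aa <- Biostrings::readAAStringSet(out)
  expect_length(aa, 6L)
  expect_true(all(grepl(hit$species, names(aa), fixed = TRUE)))
  # pipe-separated header with 1-based inclusive coordinates
  parts <- strsplit(names(aa)[1L], "|", fixed = TRUE)[[1L]]
  expect_length(parts, 8L)
  expect_match(parts[6L], "^[0-9]+\\.\\.[0-9]+$")
})

test_that("a gene with no obtainable protein is skipped with a warning", {
  suite <- withr::local_tempdir()
  make_suite(suite, 1, seed = 3)
  res <- run_extraction(suite, "caiTABCDE")
  hit <- res$hits[[1L]]
  hit$per_gene$aa[2L] <- NA_character_
  out <- file.path(suite, "partial.faa")
  expect_warning(write_cluster_fasta(hit, "protein", out), "skipping 1")
  expect_length(Biostrings::readAAStringSet(out), 5L)
  hit$status <- "rejected"
  expect_error(write_cluster_fasta(hit, "protein", out), "rejected")
})

test_that("generated GenBank fixtures parse identically under Biopython", {
  dir <- withr::local_tempdir()
  gen <- make_genome(plant_spec(cai_definition()), n_decoy_genes = 4L,
                     seed = 99L, genome_name = "oracle_check")
  path <- file.path(dir, "oracle.gbk")
  writeLines(gen$gbk, path)
  script <- paste(
    "import sys",
    "from Bio import SeqIO",
    "recs = list(SeqIO.parse(sys.argv[1], 'genbank'))",
    "cds = [f for f in recs[0].features if f.type == 'CDS']",
    "first = cds[0]",
    "print(len(recs), len(cds), len(recs[0].seq),",
    "      int(first.location.start), int(first.location.end),",
    "      first.qualifiers['locus_tag'][0])",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(path)),
                 stdout = TRUE)
  ours <- read_genbank(path)[[1L]]
  fields <- strsplit(trimws(out[length(out)]), " +")[[1L]]
  expect_equal(as.integer(fields[1L]), 1L)
  expect_equal(as.integer(fields[2L]), nrow(ours$features))
  expect_equal(as.integer(fields[3L]), nchar(ours$sequence))
  expect_equal(as.integer(fields[4L]), ours$features$start[1L])
  expect_equal(as.integer(fields[5L]), ours$features$end[1L])
  expect_equal(fields[6L], ours$features$locus_tag[1L])
})
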