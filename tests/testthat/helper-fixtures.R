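# shared fixtures: hand-written GenBank text, tiny definitions, fake hits,
# and the brute-force chaining oracle

cai_definition <- function() {
  load_definitions(system.file("extdata", "gene_label2",
                               package = "coremgc"))[["caiTABCDE"]]
}

two_gene_definition <- function(name = "pairAB") {
  cluster_definition(name, c("pairA", "pairB"))
}

# minimal hand-written GenBank record: genes at 1..300, 401..700, 801..1100
# (1-based inclusive), the second on the minus strand
hand_gbk_lines <- function(record_id = "TESTREC1",
                           locus_tags = c("T_RS00005", "T_RS00010",
                                          "T_RS00015"),
                           genes = c("abcA", "abcB", "abcC"),
                           seq_len = 1200L) {
  set.seed(42)
  s <- paste(sample(c("a", "c", "g", "t"), seq_len, replace = TRUE),
             collapse = "")
  locs <- c("1..300", "complement(401..700)", "801..1100")
  lines <- c(
    sprintf("LOCUS       %s             %d bp    DNA     linear   BCT 01-JAN-2026",
            record_id, seq_len),
    "DEFINITION  hand-written parser fixture.",
    sprintf("ACCESSION   %s", record_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", seq_len))
  for (i in 1:3) {
    lines <- c(lines,
      sprintf("     CDS             %s", locs[i]),
      sprintf('                     /locus_tag="%s"', locus_tags[i]),
      sprintf('                     /gene="%s"', genes[i]),
      sprintf('                     /product="%s protein"', genes[i]))
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1L, seq_len, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, seq_len))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

write_hand_gbk <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                           ...) {
  path <- file.path(dir, "fixture.gbk")
  writeLines(hand_gbk_lines(...), path)
  path
}

# a match table as match_genes() would produce, from bare ordinals
matches_at <- function(ordinals, label = "x") {
  n <- length(ordinals)
  if (n == 0L) {
    return(data.frame(ordinal = integer(), locus_tag = character(),
                      matched_label = character(), method = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  data.frame(ordinal = as.integer(ordinals),
             locus_tag = sprintf("T_RS%05d", ordinals * 5L),
             matched_label = rep_len(label, n),
             method = "gene-exact",
             start = as.integer(ordinals * 1000L),
             end = as.integer(ordinals * 1000L + 500L),
             strand = "+", stringsAsFactors = FALSE)
}

# exhaustive oracle: every maximal contiguous run of matches whose
# consecutive ordinal gaps are all <= g (enumerates all candidate runs and
# keeps those that cannot be extended)
brute_force_chain_ordinals <- function(ordinals, g) {
  n <- length(ordinals)
  if (n == 0L) return(list())
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      idx <- i:j
      if (length(idx) > 1L && any(diff(ordinals[idx]) - 1L > g)) next
      left_max <- i == 1L || (ordinals[i] - ordinals[i - 1L] - 1L) > g
      right_max <- j == n || (ordinals[j + 1L] - ordinals[j] - 1L) > g
      if (left_max && right_max) out[[length(out) + 1L]] <- ordinals[idx]
    }
  }
  out
}

fake_hit <- function(genome, mgc_type, status = "intact",
                     species = NA_character_, taxonomy = NULL) {
  structure(list(genome_name = genome, record_id = paste0("CTG_", genome),
                 mgc_type = mgc_type, status = status, species = species,
                 taxonomy = taxonomy),
            class = "cluster_hit")
}

# seven-rank taxonomy vector for fake hits
ranks7 <- function(Domain = "Bacteria", Phylum = NA, Class = NA, Order = NA,
                   Family = NA, Genus = NA, Species = NA) {
  c(Domain = Domain, Phylum = Phylum, Class = Class, Order = Order,
    Family = Family, Genus = Genus, Species = Species)
}
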