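#' Describe a cluster planting for the fixture generator
#'
#' A plant places the member genes of a cluster definition onto a synthetic
#' genome. `internal_gaps` gives the number of decoy CDS inserted between
#' consecutive members; a `scattered` plant instead separates every pair of
#' members by 12-18 decoys, so its keyword matches fail the proximity rule
#' at the default gap budget and mimic false-positive scattered homologs.
#' `members` may name a subset of the definition's labels to plant a
#' partial (candidate-grade) cluster.
#'
#' @param definition a `cluster_definition`.
#' @param internal_gaps integer vector of length `length(members) - 1`
#'   (ignored when `scattered`); defaults to all zeros.
#' @param scattered logical.
#' @param strand_pattern `"+"`/`"-"` vector recycled over members.
#' @param members labels to plant; default all definition labels.
#' @param tag_step locus-tag numbering step (annotators typically use 5).
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(definition, internal_gaps = NULL, scattered = FALSE,
                       strand_pattern = "+", members = NULL, tag_step = 5L) {
  stopifnot(inherits(definition, "cluster_definition"))
  members <- members %||% definition$gene_labels
  stopifnot(all(tolower(members) %in% tolower(definition$gene_labels)))
  if (!scattered) {
    internal_gaps <- internal_gaps %||% rep(0L, length(members) - 1L)
    if (length(internal_gaps) != length(members) - 1L) {
      stop_data("internal_gaps must have length(members) - 1 entries")
    }
    stopifnot(all(internal_gaps >= 0L))
  }
  structure(list(definition = definition,
                 internal_gaps = as.integer(internal_gaps),
                 scattered = isTRUE(scattered),
                 strand_pattern = strand_pattern, members = members,
                 tag_step = as.integer(tag_step)),
            class = "plant_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    paste0), c("A", "C", "G", "T"), paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

random_gene_nt <- function(aa_len) {
  paste0("ATG", paste(sample(SENSE_CODONS, aa_len - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

random_spacer <- function() {
  paste(sample(c("A", "C", "G", "T"), sample(50:200, 1L), replace = TRUE),
        collapse = "")
}

# decoy gene symbols that cannot collide with any definition label
random_decoy_label <- function(forbidden) {
  for (i in 1:100) {
    lab <- paste0(paste(sample(letters, 3L, replace = TRUE), collapse = ""),
                  sample(LETTERS, 1L))
    if (!tolower(lab) %in% forbidden) return(lab)
  }
  stop("could not draw a non-colliding decoy gene label")
}

#' Generate one synthetic annotated genome
#'
#' Builds a single-contig genome with the requested cluster plantings
#' surrounded by decoy genes, emitting annotator-style GenBank text, a
#' canonical region table and a ground-truth entry. Genes are laid out left
#' to right with 50-200 nt random intergenic spacers; locus tags are
#' assigned sequentially in steps of `tag_step`, so an uninterrupted
#' planting yields the arithmetic locus-tag run characteristic of genuine
#' operons in annotator output. Member genes carry `/gene`, `/product` and
#' a computed `/translation`; decoys carry unrelated gene symbols and
#' "hypothetical protein" products. Output is deterministic given `seed`.
#'
#' @param plants list of [plant_spec()] (a single spec is accepted).
#' @param n_decoy_genes decoys flanking the plantings (additional decoys
#'   are inserted inside gapped/scattered plantings as specified).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param genome_name genome label (also used in the region table).
#' @param record_id contig identifier; default derived from `genome_name`.
#' @param truth_g,truth_min_genes parameters at which the truth entry's
#'   `expected_status` is stated.
#' @return list with `gbk` (character vector of GenBank lines), `regions`
#'   (canonical region annotation data.frame, internal coordinates) and
#'   `truth` (list: genome_name and one entry per plant with cluster name,
#'   member locus tags, kind and expected status at `truth_g`).
#' @export
make_genome <- function(plants, n_decoy_genes = 10L, seed = 1L,
                        genome_name = "synthetic_genome", record_id = NULL,
                        truth_g = 10L, truth_min_genes = 2L) {
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  stopifnot(all(vapply(plants, inherits, logical(1), "plant_spec")))
  record_id <- record_id %||%
    paste0("CTG_", gsub("[^A-Za-z0-9]", "", genome_name))
  set.seed(seed)
  forbidden <- tolower(unlist(lapply(plants, function(p)
    p$definition$gene_labels)))

  # ordered gene plan: flanking decoys, plants with internal decoys,
  # 12+ decoys between consecutive plants so they can never co-chain
  plan <- list()
  add_decoys <- function(plan, n) {
    for (i in seq_len(n)) {
      plan[[length(plan) + 1L]] <- list(
        label = random_decoy_label(forbidden), member = FALSE, plant = NA_integer_,
        strand = sample(c("+", "-"), 1L), aa_len = sample(80:200, 1L))
    }
    plan
  }
  plan <- add_decoys(plan, ceiling(n_decoy_genes / 2))
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    if (pi > 1L) plan <- add_decoys(plan, 12L)
    gaps <- if (p$scattered) {
      sample(12:18, length(p$members) - 1L, replace = TRUE)
    } else {
      p$internal_gaps
    }
    strands <- rep(p$strand_pattern, length.out = length(p$members))
    rl <- p$definition$ref_lengths
    for (mi in seq_along(p$members)) {
      lab <- p$members[mi]
      aa_len <- NA_integer_
      if (!is.null(rl)) {
        j <- match(tolower(lab), tolower(rl$gene_label))
        if (!is.na(j)) aa_len <- as.integer(rl$length[j])
      }
      if (is.na(aa_len)) aa_len <- sample(150:350, 1L)
      plan[[length(plan) + 1L]] <- list(
        label = lab, member = TRUE, plant = pi, strand = strands[mi],
        aa_len = aa_len)
      if (mi < length(p$members)) plan <- add_decoys(plan, gaps[mi])
    }
  }
  plan <- add_decoys(plan, floor(n_decoy_genes / 2))

  # lay out sequence and features
  prefix <- paste0(paste(sample(LETTERS, 3L), collapse = ""),
                   sample(10:99, 1L))
  tag_step <- if (length(plants)) plants[[1L]]$tag_step else 5L
  seq_parts <- character()
  pos <- 0L
  feats <- list()
  for (i in seq_along(plan)) {
    gp <- plan[[i]]
    spacer <- random_spacer()
    coding <- random_gene_nt(gp$aa_len)
    placed <- if (gp$strand == "-") revcomp(coding) else coding
    start0 <- pos + nchar(spacer)
    end0 <- start0 + nchar(placed)
    seq_parts <- c(seq_parts, spacer, placed)
    pos <- end0
    aa <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(coding),
      genetic.code = Biostrings::getGeneticCode("11"))))
    feats[[i]] <- list(
      locus_tag = sprintf("%s_RS%05d", prefix, i * tag_step),
      gene = gp$label,
      product = if (gp$member) paste(gp$label, "family protein")
                else "hypothetical protein",
      start = start0, end = end0, strand = gp$strand,
      translation = if (gp$member) aa else NA_character_,
      protein_id = sprintf("WP_%09d.1", (seed %% 99999L) * 10000L + i),
      member = gp$member, plant = gp$plant)
  }
  seq_parts <- c(seq_parts, random_spacer())
  genome_seq <- paste(seq_parts, collapse = "")

  fdf <- do.call(rbind, lapply(feats, function(f)
    as.data.frame(f, stringsAsFactors = FALSE)))

  regions <- empty_regions()
  truth_plants <- list()
  for (pi in seq_along(plants)) {
    p <- plants[[pi]]
    mf <- fdf[fdf$member & fdf$plant == pi, , drop = FALSE]
    regions <- rbind(regions, data.frame(
      genome_name = genome_name, record_id = record_id,
      region_label = paste("region", pi),
      mgc_type = p$definition$cluster_name,
      start = min(mf$start), end = max(mf$end),
      source_dialect = "canonical-tsv", stringsAsFactors = FALSE))
    gaps <- (diff(which(fdf$member & !is.na(fdf$plant) & fdf$plant == pi)) - 1L)
    truth_plants[[pi]] <- list(
      cluster_name = p$definition$cluster_name,
      member_locus_tags = mf$locus_tag,
      kind = if (p$scattered) "scattered"
             else if (setequal(tolower(p$members),
                               tolower(p$definition$gene_labels))) "intact"
             else "partial",
      expected_status = expected_plant_status(p, gaps, truth_g,
                                              truth_min_genes))
  }

  gbk <- format_gbk(record_id, genome_name, genome_seq, fdf)
  list(gbk = gbk, regions = regions,
       truth = list(genome_name = genome_name, record_id = record_id,
                    plants = truth_plants))
}

# status the extractor should assign at gap budget g: split members at
# gaps > g, classify the best resulting chain
expected_plant_status <- function(p, gaps, g, min_genes) {
  grp <- cumsum(c(FALSE, gaps > g))
  runs <- split(seq_along(p$members), grp)
  all_labels <- tolower(p$definition$gene_labels)
  statuses <- vapply(runs, function(idx) {
    have <- unique(tolower(p$members[idx]))
    if (setequal(have, all_labels)) "intact"
    else if (length(idx) >= min_genes) "candidate"
    else "rejected"
  }, character(1))
  rank <- c(rejected = 1L, candidate = 2L, intact = 3L)
  names(rank)[max(rank[statuses])]
}

format_gbk <- function(record_id, genome_name, genome_seq, fdf) {
  lines <- c(
    sprintf("LOCUS       %-23s %d bp    DNA     linear   BCT 01-JAN-2026",
            record_id, nchar(genome_seq)),
    sprintf("DEFINITION  synthetic genome %s, annotator-style fixture.",
            genome_name),
    sprintf("ACCESSION   %s", record_id),
    sprintf("VERSION     %s", record_id),
    "KEYWORDS    .",
    sprintf("SOURCE      synthetic construct (%s)", genome_name),
    "  ORGANISM  synthetic construct",
    "            Bacteria.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome_seq)),
    qual_line("organism", "synthetic construct"),
    qual_line("mol_type", "genomic DNA"))
  for (i in seq_len(nrow(fdf))) {
    f <- fdf[i, ]
    loc <- sprintf("%d..%d", f$start + 1L, f$end)
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               qual_line("locus_tag", f$locus_tag),
               qual_line("gene", f$gene),
               qual_line("product", f$product),
               qual_line("protein_id", f$protein_id),
               "                     /codon_start=1",
               "                     /transl_table=11")
    if (!is.na(f$translation)) {
      lines <- c(lines, wrap_qualifier("translation", f$translation))
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- tolower(genome_seq)
  starts <- seq.int(1L, nchar(s), by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", st, paste(groups, collapse = " ")))
  }
  c(lines, "//")
}

qual_line <- function(name, value) {
  sprintf('                     /%s="%s"', name, value)
}

wrap_qualifier <- function(name, value, width = 58L) {
  text <- paste0('/', name, '="', value, '"')
  starts <- seq.int(1L, nchar(text), by = width)
  vapply(starts, function(st) {
    paste0(strrep(" ", 21L), substr(text, st, min(st + width - 1L, nchar(text))))
  }, character(1))
}

#' Generate a complete synthetic suite with ground truth
#'
#' Emits the full on-disk layout the extractor consumes: one
#' `results_<genome>/` directory per genome holding a GenBank file and a
#' canonical region table, a `species/` directory with both taxonomy
#' dialects (assembly-summary and seven-rank lineage), a `gene_label2/`
#' definitions directory, and a machine-readable `truth.json` manifest.
#' Per-genome content is seeded from the suite seed, so the whole tree is
#' deterministic.
#'
#' @param out_dir output directory (must be empty unless `force`).
#' @param n_genomes number of genomes.
#' @param mix character vector over `"intact"`, `"scattered"`, `"partial"`,
#'   recycled across genomes in order (a deterministic composition, not a
#'   random draw).
#' @param seed integer suite seed.
#' @param definitions named list of `cluster_definition`; defaults to the
#'   definitions shipped under `extdata/gene_label2` (the six-gene
#'   carnitine degradation operon caiTABCDE).
#' @param g,min_genes parameters at which the manifest's expected statuses
#'   are stated (defaults: the extractor defaults).
#' @param max_intact_gap intact plants draw each internal gap uniformly
#'   from `0:max_intact_gap`; must be `<= g`.
#' @param n_decoy_genes flanking decoys per genome.
#' @param force overwrite a non-empty `out_dir`.
#' @return `out_dir`, invisibly; side effect is the directory tree.
#' @export
make_suite <- function(out_dir, n_genomes, mix = "intact", seed = 1L,
                       definitions = NULL, g = 10L, min_genes = 2L,
                       max_intact_gap = 3L, n_decoy_genes = 10L,
                       force = FALSE) {
  stopifnot(max_intact_gap <= g)
  if (dir.exists(out_dir) && length(list.files(out_dir, all.files = TRUE,
                                               no.. = TRUE)) > 0L) {
    if (!force) stop_data("output directory not empty: ", out_dir,
                          " (use force = TRUE to overwrite)")
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(definitions)) {
    definitions <- load_definitions(
      system.file("extdata", "gene_label2", package = "coremgc"))
  }
  dir.create(file.path(out_dir, "gene_label2"))
  for (def in definitions) {
    write_definition(def, file.path(out_dir, "gene_label2",
                                    def$cluster_name))
  }

  kinds <- if (n_genomes > 0L) rep(mix, length.out = n_genomes) else character()
  stopifnot(all(kinds %in% c("intact", "scattered", "partial")))
  set.seed(seed)
  genome_seeds <- sample.int(.Machine$integer.max - 1L, max(n_genomes, 1L))
  truth <- list()
  species_rows <- list()
  for (i in seq_len(n_genomes)) {
    gname <- sprintf("GCF_9%05d.1", i)
    def <- definitions[[1L + (i - 1L) %% length(definitions)]]
    set.seed(genome_seeds[i])
    p <- switch(kinds[i],
      intact = plant_spec(def, internal_gaps = sample(
        0:max_intact_gap, length(def$gene_labels) - 1L, replace = TRUE)),
      scattered = plant_spec(def, scattered = TRUE),
      partial = plant_spec(def,
        members = utils::head(def$gene_labels,
                              max(min_genes, length(def$gene_labels) %/% 3L)),
        internal_gaps = sample(0:max_intact_gap,
          max(min_genes, length(def$gene_labels) %/% 3L) - 1L,
          replace = TRUE)))
    gen <- make_genome(p, n_decoy_genes = n_decoy_genes,
                       seed = genome_seeds[i], genome_name = gname,
                       truth_g = g, truth_min_genes = min_genes)
    gdir <- file.path(out_dir, paste0("results_", gname))
    dir.create(gdir)
    writeLines(gen$gbk, file.path(gdir, paste0(gname, ".gbk")))
    write_region_table(gen$regions, file.path(gdir, "regions.tsv"))
    sp <- SPECIES_POOL[1L + (i - 1L) %% nrow(SPECIES_POOL), ]
    species_rows[[i]] <- data.frame(key = gname, sp,
                                    stringsAsFactors = FALSE)
    gen$truth$species <- sp$Species
    gen$truth$kind <- kinds[i]
    truth[[i]] <- gen$truth
  }
  write_species_dir(file.path(out_dir, "species"),
                    if (length(species_rows)) do.call(rbind, species_rows)
                    else NULL)
  jsonlite::write_json(
    list(g = g, min_genes = min_genes, seed = seed, genomes = truth),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Write a cluster definition file in the `gene_label2/` grammar
#'
#' First line the cluster name; one gene label per subsequent line, with a
#' tab-separated `KO:length` reference annotation where known.
#'
#' @param definition a `cluster_definition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_definition <- function(definition, path) {
  lines <- definition$cluster_name
  rl <- definition$ref_lengths
  for (lab in definition$gene_labels) {
    j <- if (!is.null(rl)) match(tolower(lab), tolower(rl$gene_label)) else NA
    lines <- c(lines, if (!is.na(j)) {
      sprintf("%s\t%s:%d", lab, rl$ko_id[j], as.integer(rl$length[j]))
    } else {
      lab
    })
  }
  writeLines(lines, path)
  invisible(path)
}

SPECIES_POOL <- data.frame(
  Domain = "Bacteria",
  Phylum = c("Pseudomonadota", "Pseudomonadota", "Pseudomonadota",
             "Bacillota", "Bacteroidota", "Bacillota"),
  Class = c("Gammaproteobacteria", "Gammaproteobacteria",
            "Gammaproteobacteria", "Bacilli", "Bacteroidia", "Clostridia"),
  Order = c("Enterobacterales", "Enterobacterales", "Enterobacterales",
            "Lactobacillales", "Bacteroidales", "Eubacteriales"),
  Family = c("Enterobacteriaceae", "Enterobacteriaceae",
             "Enterobacteriaceae", "Enterococcaceae", "Bacteroidaceae",
             "Clostridiaceae"),
  Genus = c("Escherichia", "Escherichia", "Salmonella", "Enterococcus",
            "Bacteroides", "Clostridium"),
  Species = c("Escherichia fergusonii", "Escherichia coli",
              "Salmonella enterica", "Enterococcus faecalis",
              "Bacteroides fragilis", "Clostridium sporogenes"),
  stringsAsFactors = FALSE)

write_species_dir <- function(sp_dir, rows) {
  dir.create(sp_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(rows) || nrow(rows) == 0L) {
    writeLines(c("# assembly summary (synthetic)",
                 "# assembly_accession\ttaxid\torganism_name"),
               file.path(sp_dir, "assembly_summary.txt"))
    return(invisible(sp_dir))
  }
  strain <- sprintf("strain SYN-%02d", seq_len(nrow(rows)))
  asm <- c("# assembly summary (synthetic)",
           "# assembly_accession\ttaxid\torganism_name",
           sprintf("%s\t%d\t%s %s", rows$key, 1000L + seq_len(nrow(rows)),
                   rows$Species, strain))
  writeLines(asm, file.path(sp_dir, "assembly_summary.txt"))
  lin <- sprintf("%s\td__%s;p__%s;c__%s;o__%s;f__%s;g__%s;s__%s",
                 rows$key, rows$Domain, rows$Phylum, rows$Class, rows$Order,
                 rows$Family, rows$Genus, rows$Species)
  writeLines(lin, file.path(sp_dir, "lineage.tsv"))
  invisible(sp_dir)
}
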