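#' Read taxonomy from a `species/` directory
#'
#' Each file in the directory is parsed with per-file dialect detection:
#'
#' * **assembly-summary dialect** — NCBI `assembly_summary.txt` style:
#'   comment lines start with `#`, tab-separated, with
#'   `assembly_accession` and `organism_name` columns. Species is taken as
#'   the first two words of the organism name (strain suffixes dropped),
#'   Genus as the first word; ranks above Genus are unavailable in this
#'   dialect.
#' * **lineage dialect** — two tab-separated columns: a key and a
#'   seven-rank GTDB-style lineage string
#'   `d__...;p__...;c__...;o__...;f__...;g__...;s__...`; empty segments mean
#'   the rank is absent.
#'
#' Unparseable lines are skipped with a warning naming the line number. A
#' key seen twice with a conflicting species keeps the last occurrence, with
#' a warning. Files are read in sorted name order.
#'
#' @param species_dir directory path.
#' @return a `taxonomy_table` data.frame with columns `key` and the seven
#'   ranks Domain..Species (`NA` where absent).
#' @export
read_taxonomy <- function(species_dir) {
  if (!dir.exists(species_dir)) {
    stop_data("species directory not found: ", species_dir)
  }
  files <- sort(list.files(species_dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  rows <- list()
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    content <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (length(content) == 0L) next
    dialect <- if (any(grepl("d__", content, fixed = TRUE))) {
      "lineage"
    } else {
      "assembly"
    }
    if (dialect == "assembly") {
      rows <- c(rows, parse_assembly_summary(lines, f))
    } else {
      rows <- c(rows, parse_lineage_file(lines, f))
    }
  }
  out <- empty_taxonomy()
  for (r in rows) {
    i <- match(r$key, out$key)
    if (!is.na(i)) {
      if (!identical(out$Species[i], r$Species)) {
        warning("duplicate taxonomy key '", r$key,
                "' with conflicting lineage; last occurrence wins",
                call. = FALSE)
      }
      out[i, ] <- as.data.frame(r, stringsAsFactors = FALSE)
    } else {
      out <- rbind(out, as.data.frame(r, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

empty_taxonomy <- function() {
  cols <- c("key", TAX_RANKS)
  out <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

parse_assembly_summary <- function(lines, path) {
  header_at <- grep("^#?\\s*assembly_accession", lines)[1L]
  if (is.na(header_at)) {
    warning("no assembly_accession header in ", path, "; file skipped",
            call. = FALSE)
    return(list())
  }
  header <- strsplit(sub("^#\\s*", "", lines[header_at]), "\t")[[1L]]
  i_acc <- match("assembly_accession", header)
  i_org <- match("organism_name", header)
  if (is.na(i_org)) {
    warning("no organism_name column in ", path, "; file skipped",
            call. = FALSE)
    return(list())
  }
  out <- list()
  for (ln in seq.int(header_at + 1L, length(lines))) {
    if (ln > length(lines)) break
    raw <- lines[ln]
    if (grepl("^#", raw) || !nzchar(trimws(raw))) next
    parts <- strsplit(raw, "\t")[[1L]]
    if (length(parts) < max(i_acc, i_org) || !nzchar(parts[i_acc])) {
      warning("skipping unparseable line ", ln, " in ", path, call. = FALSE)
      next
    }
    words <- strsplit(trimws(parts[i_org]), "[[:space:]]+")[[1L]]
    if (length(words) == 0L) {
      warning("skipping unparseable line ", ln, " in ", path, call. = FALSE)
      next
    }
    species <- paste(utils::head(words, 2L), collapse = " ")
    out[[length(out) + 1L]] <- list(
      key = parts[i_acc], Domain = NA_character_, Phylum = NA_character_,
      Class = NA_character_, Order = NA_character_, Family = NA_character_,
      Genus = words[1L], Species = species)
  }
  out
}

RANK_PREFIX <- c(Domain = "d", Phylum = "p", Class = "c", Order = "o",
                 Family = "f", Genus = "g", Species = "s")

parse_lineage_file <- function(lines, path) {
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    if (grepl("^#", raw) || !nzchar(trimws(raw))) next
    parts <- strsplit(raw, "\t")[[1L]]
    if (length(parts) < 2L || !grepl("__", parts[2L], fixed = TRUE)) {
      warning("skipping unparseable line ", ln, " in ", path, call. = FALSE)
      next
    }
    segs <- strsplit(trimws(parts[2L]), ";", fixed = TRUE)[[1L]]
    ranks <- setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
    for (seg in segs) {
      m <- regmatches(seg, regexec("^\\s*([a-z])__(.*)$", seg))[[1L]]
      if (length(m) < 3L) next
      rank <- names(RANK_PREFIX)[RANK_PREFIX == m[2L]]
      if (length(rank) == 1L && nzchar(trimws(m[3L]))) {
        ranks[[rank]] <- trimws(m[3L])
      }
    }
    out[[length(out) + 1L]] <- c(list(key = trimws(parts[1L])),
                                 as.list(ranks))
  }
  out
}

#' Attach taxonomy to cluster hits
#'
#' Each hit is looked up in the taxonomy table by, in order of precedence:
#' its genome name, its record id, then the longest taxonomy key occurring
#' as a substring of the genome name (which resolves
#' `results_GCF_013813205.1`-style directory names to the embedded assembly
#' accession). Unmatched hits get species `NA` with a warning.
#'
#' @param hits list of `cluster_hit`.
#' @param taxmap a `taxonomy_table` from [read_taxonomy()].
#' @return the hits with `species` and `taxonomy` filled in.
#' @export
annotate_hits <- function(hits, taxmap) {
  if (length(hits) == 0L) return(hits)
  keys_by_len <- taxmap$key[order(-nchar(taxmap$key))]
  unmatched <- character()
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    row <- NA_integer_
    if (h$genome_name %in% taxmap$key) {
      row <- match(h$genome_name, taxmap$key)
    } else if (h$record_id %in% taxmap$key) {
      row <- match(h$record_id, taxmap$key)
    } else {
      for (k in keys_by_len) {
        if (grepl(k, h$genome_name, fixed = TRUE)) {
          row <- match(k, taxmap$key); break
        }
      }
    }
    if (!is.na(row)) {
      hits[[i]]$taxonomy <- setNames(
        as.character(taxmap[row, TAX_RANKS]), TAX_RANKS)
      hits[[i]]$species <- taxmap$Species[row]
    } else {
      unmatched <- c(unmatched, h$genome_name)
    }
  }
  if (length(unmatched)) {
    warning("no taxonomy entry for genome(s): ",
            paste(unique(unmatched), collapse = ", "),
            "; species set to NA", call. = FALSE)
  }
  hits
}

#' Summarise intact hits at a taxonomic rank
#'
#' Groups intact hits by (taxon at `tax_level`, MGC type), counting distinct
#' genomes and hits; `proportion` is each row's share of all intact hits and
#' sums to one over the table. Hits whose taxonomy lacks the requested rank
#' are grouped under `"Unclassified"` (with a warning above Genus, where the
#' assembly-summary dialect cannot supply the rank), so no hit is ever
#' dropped and totals are conserved across ranks. Rows are ordered by taxon
#' then MGC type.
#'
#' @param hits annotated list of `cluster_hit`.
#' @param tax_level one of Domain, Phylum, Class, Order, Family, Genus,
#'   Species.
#' @return data.frame with columns `taxon`, `rank`, `mgc_type`,
#'   `n_genomes_with_intact`, `n_hits`, `proportion`.
#' @export
aggregate_hits <- function(hits, tax_level = "Species") {
  stopifnot(tax_level %in% TAX_RANKS)
  intact <- Filter(function(h) h$status == "intact", hits)
  empty <- data.frame(taxon = character(), rank = character(),
                      mgc_type = character(),
                      n_genomes_with_intact = integer(), n_hits = integer(),
                      proportion = numeric(), stringsAsFactors = FALSE)
  if (length(intact) == 0L) return(empty)
  taxon <- vapply(intact, function(h) {
    tx <- h$taxonomy
    val <- if (!is.null(tx)) tx[[tax_level]] else NA_character_
    if (is.na(val) || !nzchar(val)) "Unclassified" else val
  }, character(1))
  if (tax_level %in% c("Domain", "Phylum", "Class", "Order", "Family") &&
      any(taxon == "Unclassified")) {
    warning("some hits lack rank ", tax_level,
            " (assembly-summary taxonomy only provides Genus and Species); ",
            "grouped under 'Unclassified'", call. = FALSE)
  }
  df <- data.frame(
    taxon = taxon,
    mgc_type = vapply(intact, `[[`, "", "mgc_type"),
    genome = vapply(intact, `[[`, "", "genome_name"),
    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(
    split(df, list(df$taxon, df$mgc_type), drop = TRUE),
    function(gp) data.frame(
      taxon = gp$taxon[1L], rank = tax_level, mgc_type = gp$mgc_type[1L],
      n_genomes_with_intact = length(unique(gp$genome)),
      n_hits = nrow(gp), stringsAsFactors = FALSE)))
  agg$proportion <- agg$n_hits / length(intact)
  agg <- agg[order(agg$taxon, agg$mgc_type), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
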