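#' Read a GenBank flat file into genome records
#'
#' Parses one or more LOCUS entries from an annotator-produced GenBank flat
#' file. Only CDS features are retained; coordinates are converted from the
#' GenBank 1-based inclusive convention to the internal 0-based half-open
#' convention. Compound (`join(...)`) locations are collapsed to their outer
#' span with a warning, which is adequate for bacterial CDS. Features are
#' sorted by start, then end, then locus tag, and given consecutive ordinals
#' `0..n-1`; a CDS without a `/locus_tag` gets a synthesized
#' `<record_id>_cds<ordinal>` tag and a warning. Sequence letters are
#' uppercased on read.
#'
#' @param path path to a GenBank flat file (may contain multiple records).
#' @param genome_name genome label attached to each record; defaults to the
#'   `results_<genome_name>` directory name convention when `path` sits in
#'   such a directory, otherwise the file stem.
#' @return a list of `genome_record` objects, each a list with elements
#'   `record_id`, `genome_name`, `sequence` (character scalar), `features`
#'   (data.frame with columns `locus_tag`, `gene`, `product`, `start`, `end`,
#'   `strand`, `translation`, `protein_id`, `ordinal`) and `source_path`.
#' @export
read_genbank <- function(path, genome_name = NULL) {
  if (!file.exists(path)) stop_data("GenBank file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(genome_name)) {
    dir_base <- basename(dirname(normalizePath(path, mustWork = FALSE)))
    genome_name <- if (grepl("^results_", dir_base)) {
      sub("^results_", "", dir_base)
    } else {
      sub("\\.(gbk|gb|gbff)$", "", basename(path), ignore.case = TRUE)
    }
  }

  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0L) {
    stop_data("not a GenBank flat file (no LOCUS line): ", path)
  }
  ends <- c(locus_at[-1L] - 1L, length(lines))
  records <- vector("list", length(locus_at))
  for (i in seq_along(locus_at)) {
    block <- lines[locus_at[i]:ends[i]]
    rec <- tryCatch(
      parse_gbk_record(block, genome_name, path),
      error = function(e) {
        tok <- strsplit(block[1L], "[[:space:]]+")[[1L]]
        stop_data("failed to parse GenBank record '",
                  if (length(tok) >= 2) tok[2L] else "?", "' in ", path, ": ",
                  conditionMessage(e))
      })
    records[[i]] <- rec
  }
  records
}

parse_gbk_record <- function(block, genome_name, path) {
  tok <- strsplit(block[1L], "[[:space:]]+")[[1L]]
  if (length(tok) < 2L) stop("malformed LOCUS line")
  record_id <- tok[2L]

  feat_start <- grep("^FEATURES", block)[1L]
  origin_at <- grep("^ORIGIN", block)[1L]
  end_at <- grep("^//", block)[1L]
  if (is.na(end_at)) end_at <- length(block) + 1L

  sequence <- ""
  if (!is.na(origin_at)) {
    seq_lines <- block[seq.int(origin_at + 1L, max(origin_at, end_at - 1L))]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  feats <- list()
  if (!is.na(feat_start)) {
    stop_feat <- if (!is.na(origin_at)) origin_at - 1L else end_at - 1L
    if (stop_feat > feat_start) {
      flines <- block[seq.int(feat_start + 1L, stop_feat)]
      feats <- parse_gbk_features(flines, record_id)
    }
  }

  features <- if (length(feats)) {
    do.call(rbind, lapply(feats, as.data.frame, stringsAsFactors = FALSE))
  } else {
    data.frame(locus_tag = character(), gene = character(),
               product = character(), start = integer(), end = integer(),
               strand = character(), translation = character(),
               protein_id = character(), stringsAsFactors = FALSE)
  }
  if (nrow(features)) {
    ord <- order(features$start, features$end, features$locus_tag)
    features <- features[ord, , drop = FALSE]
    bad <- features$end > nchar(sequence) & nchar(sequence) > 0L
    if (any(bad)) {
      stop("CDS feature extends beyond sequence in record ", record_id)
    }
  }
  features$ordinal <- seq_len(nrow(features)) - 1L
  missing_tag <- is.na(features$locus_tag) | !nzchar(features$locus_tag)
  if (any(missing_tag)) {
    features$locus_tag[missing_tag] <-
      paste0(record_id, "_cds", features$ordinal[missing_tag])
    warning("synthesized locus_tag for ", sum(missing_tag),
            " CDS feature(s) in record ", record_id, call. = FALSE)
  }
  rownames(features) <- NULL
  structure(list(record_id = record_id, genome_name = genome_name,
                 sequence = sequence, features = features,
                 source_path = path),
            class = "genome_record")
}

# split the FEATURES block into per-feature (key, location, qualifiers)
parse_gbk_features <- function(flines, record_id) {
  key_at <- grep("^ {5}\\S", flines)
  if (length(key_at) == 0L) return(list())
  fends <- c(key_at[-1L] - 1L, length(flines))
  out <- list()
  for (k in seq_along(key_at)) {
    fl <- flines[key_at[k]:fends[k]]
    key <- sub("^ {5}(\\S+).*$", "\\1", fl[1L])
    if (key != "CDS") next
    # the location may continue over lines until the first qualifier ('/')
    body <- sub("^ {5}\\S+\\s*", "", fl[1L])
    rest <- if (length(fl) > 1L) trimws(fl[-1L]) else character()
    qual_start <- which(startsWith(rest, "/"))[1L]
    loc_extra <- if (is.na(qual_start)) rest else utils::head(rest, qual_start - 1L)
    loc <- paste0(body, paste(loc_extra, collapse = ""))
    quals <- if (!is.na(qual_start)) rest[qual_start:length(rest)] else character()
    parsed_loc <- parse_gbk_location(loc, record_id)
    q <- parse_gbk_qualifiers(quals)
    out[[length(out) + 1L]] <- list(
      locus_tag = q[["locus_tag"]] %||% NA_character_,
      gene = q[["gene"]] %||% NA_character_,
      product = q[["product"]] %||% NA_character_,
      start = parsed_loc$start, end = parsed_loc$end,
      strand = parsed_loc$strand,
      translation = q[["translation"]] %||% NA_character_,
      protein_id = q[["protein_id"]] %||% NA_character_)
  }
  out
}

# GenBank location string -> 0-based half-open span + strand.
# join()/order() compound locations collapse to the outer span.
parse_gbk_location <- function(loc, record_id) {
  loc <- gsub("[[:space:]]", "", loc)
  strand <- "+"
  if (grepl("complement\\(", loc)) strand <- "-"
  if (grepl("join\\(|order\\(", loc)) {
    warning("compound location collapsed to outer span in record ",
            record_id, ": ", loc, call. = FALSE)
  }
  nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
  if (length(nums) == 0L) stop("unparseable location: ", loc)
  nums <- as.numeric(nums)
  start1 <- min(nums); end1 <- max(nums)
  if (start1 > end1 || start1 < 1) stop("unparseable location: ", loc)
  list(start = as.integer(start1 - 1), end = as.integer(end1), strand = strand)
}

parse_gbk_qualifiers <- function(qlines) {
  if (length(qlines) == 0L) return(list())
  # re-join continuation lines onto their qualifier
  idx <- cumsum(startsWith(qlines, "/"))
  joined <- vapply(split(qlines, idx), function(parts) {
    # translations are wrapped without spaces; products with spaces
    first <- parts[1L]
    if (length(parts) == 1L) return(first)
    sep <- if (grepl("^/translation=", first)) "" else " "
    paste(parts, collapse = sep)
  }, character(1))
  out <- list()
  for (q in joined) {
    m <- regmatches(q, regexec('^/([A-Za-z_]+)=?(.*)$', q))[[1L]]
    if (length(m) < 2L) next
    name <- m[2L]
    val <- gsub('^"|"$', "", m[3L])
    out[[name]] <- val
  }
  out
}

#' Convert internal coordinates to GenBank display coordinates
#'
#' Internal spans are 0-based half-open; user-facing output is 1-based
#' inclusive. The conversion is an involution with [to_internal_coords()].
#'
#' @param start,end integer vectors of internal coordinates.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
to_genbank_coords <- function(start, end) {
  data.frame(start = as.integer(start) + 1L, end = as.integer(end))
}

#' @rdname to_genbank_coords
#' @export
to_internal_coords <- function(start, end) {
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}

#' Translate a CDS feature to protein
#'
#' Returns the annotator's `/translation` qualifier verbatim when present;
#' otherwise slices the span from the genome, reverse-complements
#' minus-strand features, and translates with the bacterial genetic code
#' (translation table 11), removing a trailing stop.
#'
#' @param feature one row of a `genome_record` features data.frame (or a
#'   list with the same fields).
#' @param record the `genome_record` the feature belongs to.
#' @return amino-acid string.
#' @export
translate_cds <- function(feature, record) {
  tr <- feature$translation
  if (length(tr) == 1L && !is.na(tr) && nzchar(tr)) return(tr)
  nt <- substr(record$sequence, feature$start + 1L, feature$end)
  if (feature$strand == "-") nt <- revcomp(nt)
  if (nchar(nt) %% 3L != 0L) {
    stop_data("translation unavailable for ", feature$locus_tag,
              ": span length ", nchar(nt), " not divisible by 3 and no ",
              "/translation qualifier")
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Write an extracted cluster hit as FASTA
#'
#' In `protein` mode one record is written per member gene; in `nucleotide`
#' mode one record per member gene plus one record covering the full cluster
#' span. Headers are pipe-separated:
#' `genome_name|record_id|locus_tag|gene_label|cluster_name|start..end|strand|species`
#' with 1-based inclusive coordinates and `NA` for a missing species.
#' Sequences wrap at 70 columns.
#'
#' @param hit a `cluster_hit` with status `intact` or `candidate` whose
#'   sequences have been filled in by [extract_cluster()] (as done by
#'   [run_extraction()]).
#' @param mode `"nucleotide"` or `"protein"`.
#' @param out_path output file path.
#' @return `out_path`, invisibly.
#' @export
write_cluster_fasta <- function(hit, mode = c("nucleotide", "protein"),
                                out_path) {
  mode <- match.arg(mode)
  if (!hit$status %in% c("intact", "candidate")) {
    stop_data("refusing to write a '", hit$status, "' hit")
  }
  pg <- hit$per_gene
  if (is.null(pg)) stop_data("hit has no extracted sequences; run extract_cluster() first")
  species <- hit$species %||% NA_character_
  hdr <- function(locus_tag, gene_label, start, end) {
    paste(hit$genome_name, hit$record_id, locus_tag,
          ifelse(is.na(gene_label), "NA", gene_label),
          hit$definition$cluster_name,
          sprintf("%d..%d", start + 1L, end),
          hit_strand(pg, locus_tag),
          ifelse(is.na(species), "NA", species), sep = "|")
  }
  if (mode == "protein") {
    keep <- !is.na(pg$aa) & nzchar(pg$aa)
    if (any(!keep)) {
      warning("skipping ", sum(!keep), " gene(s) without obtainable protein ",
              "sequence in ", hit$definition$cluster_name, " hit of ",
              hit$genome_name, call. = FALSE)
    }
    pg2 <- pg[keep, , drop = FALSE]
    seqs <- Biostrings::AAStringSet(pg2$aa)
    names(seqs) <- mapply(hdr, pg2$locus_tag, pg2$gene_label, pg2$start, pg2$end)
  } else {
    seqs <- Biostrings::DNAStringSet(c(pg$nt, hit$cluster_nt))
    span_hdr <- paste(hit$genome_name, hit$record_id,
                      paste0(hit$definition$cluster_name, "_span"), "NA",
                      hit$definition$cluster_name,
                      sprintf("%d..%d", hit$span[1L] + 1L, hit$span[2L]),
                      "+",
                      ifelse(is.na(species), "NA", species), sep = "|")
    names(seqs) <- c(mapply(hdr, pg$locus_tag, pg$gene_label, pg$start, pg$end),
                     span_hdr)
  }
  Biostrings::writeXStringSet(seqs, out_path, width = 70L)
  invisible(out_path)
}

hit_strand <- function(pg, locus_tag) {
  s <- pg$strand[match(locus_tag, pg$locus_tag)]
  ifelse(is.na(s), "+", s)
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$record_id, " (genome ", x$genome_name, ")\n",
      "  ", nchar(x$sequence), " bp, ", nrow(x$features), " CDS\n", sep = "")
  invisible(x)
}
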