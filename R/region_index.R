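#' Read a canonical region table
#'
#' The canonical per-genome region table is a TSV with header columns
#' `genome_name`, `record_id`, `region_label`, `mgc_type`, `start`, `end`,
#' coordinates 1-based inclusive in the file. This table is the contract
#' between the annotator and the extractor; [scrape_regions_html()] is a
#' best-effort convenience that produces the same structure from annotator
#' index pages. Duplicate rows are collapsed.
#'
#' @param path path to the TSV.
#' @return data.frame of region annotations with internal 0-based half-open
#'   coordinates and a `source_dialect` column (`"canonical-tsv"`).
#' @export
read_region_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("genome_name", "record_id", "region_label", "mgc_type",
                "start", "end")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_data("region table ", path, " lacks required column(s): ",
              paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(empty_regions())
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop_data("non-numeric ", col, " in region table ", path,
                " at data line ", which(is.na(v))[1L])
    }
    df[[col]] <- v
  }
  df <- unique(df[required])
  data.frame(genome_name = df$genome_name, record_id = df$record_id,
             region_label = df$region_label, mgc_type = df$mgc_type,
             start = as.integer(df$start - 1), end = as.integer(df$end),
             source_dialect = "canonical-tsv", stringsAsFactors = FALSE)
}

empty_regions <- function() {
  data.frame(genome_name = character(), record_id = character(),
             region_label = character(), mgc_type = character(),
             start = integer(), end = integer(),
             source_dialect = character(), stringsAsFactors = FALSE)
}

#' Write region annotations back to the canonical TSV
#'
#' Inverse of [read_region_table()]: coordinates go out 1-based inclusive.
#'
#' @param regions data.frame as returned by [read_region_table()] or
#'   [scrape_regions_html()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  out <- regions[c("genome_name", "record_id", "region_label", "mgc_type",
                   "start", "end")]
  out$start <- out$start + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scrape region annotations from an annotator index page
#'
#' Best-effort extraction of (record, region, type, coordinates) rows from
#' the overview tables of an antiSMASH- or gutSMASH-style `index.html`.
#' Each overview table is attributed to the record named by the nearest
#' preceding heading. The `auto` dialect tries both column layouts and keeps
#' whichever yields more rows. The result can be written back to the
#' canonical TSV with [write_region_table()]. This never crashes on
#' unrecognized pages: it returns an empty annotation set with a prominent
#' warning, and skips individual rows whose coordinates do not parse.
#'
#' @param path path to the HTML file.
#' @param dialect `"gutsmash-html"`, `"antismash-html"` or `"auto"`.
#' @param genome_name genome label for the emitted rows; defaults to the
#'   `results_<genome_name>` directory convention.
#' @return data.frame in the same shape as [read_region_table()].
#' @export
scrape_regions_html <- function(path,
                                dialect = c("auto", "gutsmash-html",
                                            "antismash-html"),
                                genome_name = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(genome_name)) {
    dir_base <- basename(dirname(normalizePath(path, mustWork = FALSE)))
    genome_name <- sub("^results_", "", dir_base)
  }
  doc <- tryCatch(xml2::read_html(path), error = function(e) NULL)
  if (is.null(doc)) {
    warning("could not parse HTML at ", path, "; no regions scraped",
            call. = FALSE)
    return(empty_regions())
  }
  if (dialect == "auto") {
    a <- scrape_dialect(doc, "antismash-html", genome_name)
    g <- scrape_dialect(doc, "gutsmash-html", genome_name)
    out <- if (nrow(g) > nrow(a)) g else a
  } else {
    out <- scrape_dialect(doc, dialect, genome_name)
  }
  if (nrow(out) == 0L) {
    warning("no recognizable region table in ", path, call. = FALSE)
  }
  out
}

# column headers the two annotator page layouts use for the span
DIALECT_COLS <- list(
  "antismash-html" = c(from = "from", to = "to"),
  "gutsmash-html" = c(from = "start", to = "end"))

scrape_dialect <- function(doc, dialect, genome_name) {
  cols <- DIALECT_COLS[[dialect]]
  tables <- xml2::xml_find_all(doc, ".//table")
  rows_out <- list()
  for (tab in tables) {
    header <- tolower(xml2::xml_text(xml2::xml_find_all(tab, ".//th")))
    header <- trimws(header)
    i_region <- match("region", header)
    i_type <- match("type", header)
    i_from <- match(unname(cols["from"]), header)
    i_to <- match(unname(cols["to"]), header)
    if (anyNA(c(i_region, i_type, i_from, i_to))) next
    record_id <- nearest_heading(tab) %||% genome_name
    trs <- xml2::xml_find_all(tab, ".//tr[td]")
    for (tr in trs) {
      tds <- trimws(xml2::xml_text(xml2::xml_find_all(tr, ".//td")))
      if (length(tds) < max(i_region, i_type, i_from, i_to)) next
      from <- suppressWarnings(as.numeric(gsub("[,[:space:]]", "", tds[i_from])))
      to <- suppressWarnings(as.numeric(gsub("[,[:space:]]", "", tds[i_to])))
      if (is.na(from) || is.na(to) || from < 1 || to < from ||
          !nzchar(tds[i_type])) {
        warning("skipping malformed region row in record ", record_id,
                call. = FALSE)
        next
      }
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        genome_name = genome_name, record_id = record_id,
        region_label = tds[i_region], mgc_type = tds[i_type],
        start = as.integer(from - 1), end = as.integer(to),
        source_dialect = dialect, stringsAsFactors = FALSE)
    }
  }
  if (length(rows_out) == 0L) return(empty_regions())
  do.call(rbind, rows_out)
}

nearest_heading <- function(tab) {
  h <- xml2::xml_find_first(
    tab, "preceding::*[self::h1 or self::h2 or self::h3 or self::h4 or self::h5][1]")
  if (inherits(h, "xml_missing")) return(NULL)
  txt <- trimws(xml2::xml_text(h))
  if (nzchar(txt)) txt else NULL
}

#' Select regions of a queried MGC type
#'
#' Keeps the regions whose `mgc_type` equals the query after
#' [normalize_type()] normalization — exact normalized equality, not
#' substring, so `"NRPS"` never matches `"NRPS-like"`. Order-preserving and
#' idempotent; an empty result is valid (the genome simply has no region of
#' that type).
#'
#' @param regions region annotation data.frame.
#' @param mgc_type_query the MGC type to keep.
#' @return the matching subset, original order preserved.
#' @export
select_regions <- function(regions, mgc_type_query) {
  if (nrow(regions) == 0L) return(regions)
  keep <- normalize_type(regions$mgc_type) == normalize_type(mgc_type_query)
  regions[keep, , drop = FALSE]
}
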