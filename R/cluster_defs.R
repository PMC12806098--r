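#' Construct a gene-cluster definition
#'
#' A definition names an MGC and lists its member gene labels in order,
#' optionally with reference protein lengths (KEGG-ortholog id and length in
#' amino acids) used later by [coverage_filter()].
#'
#' @param cluster_name name of the MGC, e.g. `"caiTABCDE"`.
#' @param gene_labels ordered character vector of member gene labels.
#' @param ref_lengths optional data.frame with columns `gene_label`,
#'   `ko_id`, `length`; its labels must be a subset of `gene_labels`.
#' @return a `cluster_definition` object.
#' @export
cluster_definition <- function(cluster_name, gene_labels, ref_lengths = NULL) {
  stopifnot(is.character(cluster_name), length(cluster_name) == 1L,
            nzchar(cluster_name))
  gene_labels <- as.character(gene_labels)
  if (length(gene_labels) < 1L) stop_data("definition needs >= 1 gene label")
  if (anyDuplicated(tolower(gene_labels))) {
    stop_data("duplicate gene labels in definition ", cluster_name)
  }
  if (!is.null(ref_lengths)) {
    stopifnot(all(c("gene_label", "ko_id", "length") %in% names(ref_lengths)))
    extra <- setdiff(tolower(ref_lengths$gene_label), tolower(gene_labels))
    if (length(extra)) {
      stop_data("ref_lengths for labels not in definition ", cluster_name,
                ": ", paste(extra, collapse = ", "))
    }
    ref_lengths$length <- as.numeric(ref_lengths$length)
    if (any(ref_lengths$length <= 0)) stop_data("reference lengths must be > 0")
  }
  structure(list(cluster_name = cluster_name, gene_labels = gene_labels,
                 ref_lengths = ref_lengths),
            class = "cluster_definition")
}

#' Load MGC definitions from a `gene_label2/` directory
#'
#' Each file defines one MGC: the first line is the cluster name, each
#' subsequent non-empty line one member gene label, optionally followed by a
#' tab and `KO:length` giving the reference protein length for that gene
#' (e.g. `caiB<TAB>K08298:405`). File order defines label order. Files are
#' visited in sorted name order so loading is deterministic regardless of
#' filesystem listing order. Empty files are skipped with a warning; two
#' files defining the same cluster name is an error.
#'
#' @param dir path to the definitions directory.
#' @return named list of `cluster_definition`, keyed by cluster name.
#' @export
load_definitions <- function(dir) {
  if (!dir.exists(dir)) stop_data("definitions directory not found: ", dir)
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  defs <- list()
  sources <- character()
  for (f in files) {
    lines <- trimws(readLines(f, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L) {
      warning("skipping definition file with no gene labels: ", f,
              call. = FALSE)
      next
    }
    cluster_name <- lines[1L]
    labels <- character()
    refs <- list()
    for (ln in lines[-1L]) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      label <- trimws(parts[1L])
      labels <- c(labels, label)
      if (length(parts) >= 2L && nzchar(trimws(parts[2L]))) {
        kv <- strsplit(trimws(parts[2L]), ":", fixed = TRUE)[[1L]]
        if (length(kv) != 2L || is.na(suppressWarnings(as.numeric(kv[2L])))) {
          stop_data("malformed KO:length annotation '", parts[2L],
                    "' in ", f)
        }
        refs[[length(refs) + 1L]] <- data.frame(
          gene_label = label, ko_id = kv[1L],
          length = as.numeric(kv[2L]), stringsAsFactors = FALSE)
      }
    }
    ref_lengths <- if (length(refs)) do.call(rbind, refs) else NULL
    if (cluster_name %in% names(defs)) {
      stop_data("cluster '", cluster_name, "' defined in both ",
                sources[[cluster_name]], " and ", f)
    }
    defs[[cluster_name]] <- cluster_definition(cluster_name, labels,
                                               ref_lengths)
    sources[[cluster_name]] <- f
  }
  defs
}

#' @export
print.cluster_definition <- function(x, ...) {
  cat("<cluster_definition> ", x$cluster_name, ": ",
      paste(x$gene_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}
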