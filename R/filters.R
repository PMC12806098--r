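#' Define a reference-length coverage rule
#'
#' Ties a gene label's KEGG-ortholog reference protein length to a minimum
#' coverage fraction. The canonical example is l-carnitine CoA-transferase
#' (K08298) with a 405-amino-acid reference and 80% minimum coverage.
#'
#' @param ko_id KEGG ortholog id, e.g. `"K08298"`.
#' @param ref_length reference protein length in amino acids (> 0).
#' @param min_coverage minimum kept coverage fraction in (0, 1]; default 0.8.
#' @return a `coverage_rule` list.
#' @export
coverage_rule <- function(ko_id, ref_length, min_coverage = 0.8) {
  ref_length <- as.numeric(ref_length)
  min_coverage <- as.numeric(min_coverage)
  stopifnot(ref_length > 0, min_coverage > 0, min_coverage <= 1)
  structure(list(ko_id = ko_id, ref_length = ref_length,
                 min_coverage = min_coverage), class = "coverage_rule")
}

#' Build coverage rules from a cluster definition's reference lengths
#'
#' @param definition a `cluster_definition` whose `ref_lengths` is set.
#' @param min_coverage minimum kept coverage fraction; default 0.8.
#' @return named list of `coverage_rule`, keyed by gene label.
#' @export
rules_from_definition <- function(definition, min_coverage = 0.8) {
  rl <- definition$ref_lengths
  if (is.null(rl)) return(list())
  setNames(
    lapply(seq_len(nrow(rl)), function(i) {
      coverage_rule(rl$ko_id[i], rl$length[i], min_coverage)
    }),
    rl$gene_label)
}

#' Filter protein sequences by reference-length coverage
#'
#' Coverage is the pure length ratio `nchar(seq) / ref_length` (no alignment
#' is performed). A sequence is removed when its coverage is strictly below
#' the rule's minimum — a sequence at exactly the minimum (e.g. 324/405 =
#' 0.8) is kept. Sequences whose gene label has no rule pass through
#' untouched. The result partitions the input: `kept` and `removed` are
#' disjoint and together contain every input row.
#'
#' @param seqs data.frame with columns `id`, `seq` (amino-acid strings) and
#'   `gene_label`.
#' @param rules named list of `coverage_rule`, keyed by gene label
#'   (case-insensitive); see [rules_from_definition()].
#' @return list with data.frames `kept` and `removed`; both carry a
#'   `coverage` column (`NA` where no rule applied).
#' @export
coverage_filter <- function(seqs, rules) {
  stopifnot(all(c("id", "seq", "gene_label") %in% names(seqs)))
  n <- nrow(seqs)
  coverage <- rep(NA_real_, n)
  drop <- rep(FALSE, n)
  rule_keys <- tolower(names(rules))
  for (i in seq_len(n)) {
    j <- match(tolower(seqs$gene_label[i]), rule_keys)
    if (is.na(j)) next
    rule <- rules[[j]]
    coverage[i] <- nchar(seqs$seq[i]) / rule$ref_length
    drop[i] <- coverage[i] < rule$min_coverage
  }
  seqs$coverage <- coverage
  list(kept = seqs[!drop, , drop = FALSE],
       removed = seqs[drop, , drop = FALSE])
}

#' Dereplicate sequences at 100% identity
#'
#' `exact` mode collapses character-for-character identical sequences to
#' one representative (the first seen). `containment` mode additionally
#' collapses any sequence that occurs as a substring of a longer kept
#' sequence, reproducing the behaviour of greedy 100%-identity clustering
#' as configured in CD-HIT with `-c 1` (the word size `-n 5`, memory
#' `-M 1600` and threads `-t 8` knobs affect speed only, not the resulting
#' nonredundant set, and are therefore not modelled). Representative order
#' is first-seen order; the operation is idempotent.
#'
#' @param seqs data.frame with columns `id` and `seq`.
#' @param mode `"exact"` or `"containment"`.
#' @return list with `representatives` (data.frame `id`, `seq`) and
#'   `clusters` (data.frame `representative_id`, `member_id`).
#' @export
dereplicate <- function(seqs, mode = c("exact", "containment")) {
  mode <- match.arg(mode)
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  empty <- list(
    representatives = data.frame(id = character(), seq = character(),
                                 stringsAsFactors = FALSE),
    clusters = data.frame(representative_id = character(),
                          member_id = character(), stringsAsFactors = FALSE))
  if (nrow(seqs) == 0L) return(empty)

  # exact collapse first: first-seen id represents each distinct string
  first <- !duplicated(seqs$seq)
  rep_of_string <- setNames(seqs$id[first], seqs$seq[first])
  member_rep <- rep_of_string[seqs$seq]

  if (mode == "containment") {
    # greedy longest-first containment over the distinct strings, as a
    # 100%-identity clusterer does; representatives keep first-seen order
    uniq <- data.frame(id = seqs$id[first], seq = seqs$seq[first],
                       stringsAsFactors = FALSE)
    ord <- order(-nchar(uniq$seq), seq_len(nrow(uniq)))
    kept_idx <- integer()
    parent <- setNames(uniq$id, uniq$id)
    for (i in ord) {
      contained <- FALSE
      for (k in kept_idx) {
        if (grepl(uniq$seq[i], uniq$seq[k], fixed = TRUE)) {
          parent[[uniq$id[i]]] <- uniq$id[k]
          contained <- TRUE
          break
        }
      }
      if (!contained) kept_idx <- c(kept_idx, i)
    }
    member_rep <- unname(parent[member_rep])
    keep <- seqs$id %in% uniq$id[kept_idx] & first
  } else {
    keep <- first
  }
  reps <- data.frame(id = seqs$id[keep], seq = seqs$seq[keep],
                     stringsAsFactors = FALSE)
  clusters <- data.frame(representative_id = unname(member_rep),
                         member_id = seqs$id, stringsAsFactors = FALSE)
  rownames(reps) <- NULL
  list(representatives = reps, clusters = clusters)
}
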