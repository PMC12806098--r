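#' Prevalence of MGC types across a genome batch
#'
#' For each MGC type, counts the distinct genomes carrying at least one
#' intact hit and the share of genomes (`pct_of_genomes`), plus each type's
#' share of all intact hit instances (`pct_of_all_intact_hits`, summing to
#' 100 when any intact hit exists). Both denominators are reported because
#' "proportion of an MGC type" is read either way in batch surveys. Rows
#' are sorted by instance share descending, ties broken lexicographically.
#'
#' @param hits list of `cluster_hit`.
#' @param n_genomes number of genomes screened (>= distinct genomes in
#'   `hits`).
#' @return data.frame with columns `mgc_type`, `n_genomes_with_intact`,
#'   `n_hits`, `pct_of_genomes`, `pct_of_all_intact_hits`.
#' @export
mgc_prevalence <- function(hits, n_genomes) {
  intact <- Filter(function(h) h$status == "intact", hits)
  if (n_genomes == 0L && length(intact) > 0L) {
    stop_data("n_genomes is 0 but hits are present")
  }
  empty <- data.frame(mgc_type = character(),
                      n_genomes_with_intact = integer(), n_hits = integer(),
                      pct_of_genomes = numeric(),
                      pct_of_all_intact_hits = numeric(),
                      stringsAsFactors = FALSE)
  if (length(intact) == 0L) return(empty)
  n_distinct <- length(unique(vapply(intact, `[[`, "", "genome_name")))
  if (n_genomes < n_distinct) {
    stop_data("n_genomes (", n_genomes, ") is below the number of distinct ",
              "genomes among hits (", n_distinct, ")")
  }
  df <- data.frame(
    mgc_type = vapply(intact, `[[`, "", "mgc_type"),
    genome = vapply(intact, `[[`, "", "genome_name"),
    stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$mgc_type), function(gp) {
    data.frame(mgc_type = gp$mgc_type[1L],
               n_genomes_with_intact = length(unique(gp$genome)),
               n_hits = nrow(gp), stringsAsFactors = FALSE)
  }))
  agg$pct_of_genomes <- 100 * agg$n_genomes_with_intact / n_genomes
  agg$pct_of_all_intact_hits <- 100 * agg$n_hits / nrow(df)
  agg <- agg[order(-agg$pct_of_all_intact_hits, agg$mgc_type), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Coexistence of MGC types within genomes
#'
#' Counts, for every unordered pair of MGC types, the genomes in which
#' intact hits of both types occur. Each genome contributes at most once
#' per pair; the diagonal (a type with itself) is excluded.
#'
#' @param hits list of `cluster_hit`.
#' @return data.frame with columns `mgc_type_a`, `mgc_type_b`,
#'   `n_genomes_with_both`, pairs ordered lexicographically.
#' @export
coexistence <- function(hits) {
  intact <- Filter(function(h) h$status == "intact", hits)
  empty <- data.frame(mgc_type_a = character(), mgc_type_b = character(),
                      n_genomes_with_both = integer(),
                      stringsAsFactors = FALSE)
  if (length(intact) == 0L) return(empty)
  df <- unique(data.frame(
    genome = vapply(intact, `[[`, "", "genome_name"),
    mgc_type = vapply(intact, `[[`, "", "mgc_type"),
    stringsAsFactors = FALSE))
  pair_counts <- list()
  for (gp in split(df$mgc_type, df$genome)) {
    types <- sort(unique(gp))
    if (length(types) < 2L) next
    cmb <- utils::combn(types, 2L)
    for (j in seq_len(ncol(cmb))) {
      key <- paste(cmb[1L, j], cmb[2L, j], sep = "\r")
      pair_counts[[key]] <- (pair_counts[[key]] %||% 0L) + 1L
    }
  }
  if (length(pair_counts) == 0L) return(empty)
  keys <- sort(names(pair_counts))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(mgc_type_a = vapply(parts, `[[`, "", 1L),
             mgc_type_b = vapply(parts, `[[`, "", 2L),
             n_genomes_with_both = unlist(pair_counts[keys], use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Genomes with at least one intact MGC
#'
#' @param hits list of `cluster_hit`.
#' @param n_genomes number of genomes screened.
#' @return list with `count` (distinct genomes owning >= 1 intact hit) and
#'   `fraction` (`count / n_genomes`; 0 when `n_genomes` is 0).
#' @export
genomes_with_any_intact <- function(hits, n_genomes) {
  intact <- Filter(function(h) h$status == "intact", hits)
  if (n_genomes == 0L && length(intact) > 0L) {
    stop_data("n_genomes is 0 but hits are present")
  }
  count <- length(unique(vapply(intact, `[[`, "", "genome_name")))
  list(count = count,
       fraction = if (n_genomes > 0L) count / n_genomes else 0)
}
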