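`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a

#' Normalize an MGC type or cluster name for comparison
#'
#' Lower-cases and collapses runs of spaces, hyphens and underscores to a
#' single space, so that e.g. `"Carnitine_degradation_I"` and
#' `"carnitine degradation-I"` compare equal. Matching elsewhere in the
#' package is exact on the normalized form, never substring.
#'
#' @param x character vector.
#' @return normalized character vector of the same length.
#' @export
normalize_type <- function(x) {
  x <- trimws(as.character(x))
  tolower(gsub("[[:space:]_-]+", " ", x))
}

# case-insensitive equality of gene labels
label_eq <- function(a, b) tolower(a) == tolower(b)

# word-boundary token search of `label` inside `text` (case-insensitive):
# the label must not be flanked by letters or digits.
product_contains_label <- function(text, label) {
  if (is.na(text) || !nzchar(text)) return(FALSE)
  pat <- paste0("(?<![A-Za-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", label),
                "(?![A-Za-z0-9])")
  grepl(pat, text, perl = TRUE, ignore.case = TRUE)
}

# seven canonical ranks, most to least inclusive
TAX_RANKS <- c("Domain", "Phylum", "Class", "Order", "Family", "Genus", "Species")

stop_data <- function(...) {
  stop(structure(class = c("coremgc_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
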