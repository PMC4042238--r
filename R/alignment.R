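#' Multiple alignment container
#'
#' A minimal container for a gap-aware multiple sequence alignment: a
#' named character vector of equal-length upper-case rows, one per
#' species. Construction validates row lengths and label uniqueness;
#' input is normalized to upper case.
#'
#' @param rows Named character vector (or named list of single strings)
#'   of aligned sequences. IUPAC DNA plus `-` for gaps.
#' @return A `mult_aln` object.
#' @examples
#' multiple_alignment(c(mouse = "ACGT", rat = "ACGA"))
#' @export
multiple_alignment <- function(rows) {
  rows <- unlist(rows)
  if (is.null(names(rows)) || any(names(rows) == "") || anyNA(names(rows))) {
    abort("every row must be named with a species label",
          class = "rateshift_error_alignment")
  }
  if (anyDuplicated(names(rows))) {
    abort("duplicate species labels in alignment",
          class = "rateshift_error_alignment")
  }
  if (length(unique(nchar(rows))) > 1) {
    abort("ragged alignment: rows differ in length",
          class = "rateshift_error_alignment")
  }
  structure(toupper(rows), class = "mult_aln")
}

#' @export
print.mult_aln <- function(x, ...) {
  cat(sprintf("Multiple alignment: %d species x %d columns\n",
              length(x), aln_width(x)))
  shown <- substr(unclass(x), 1, 60)
  for (i in seq_along(x)) {
    cat(sprintf(
      "  %-8s %s%s\n", names(x)[i], shown[i],
      if (aln_width(x) > 60) "..." else ""
    ))
  }
  invisible(x)
}

#' @rdname multiple_alignment
#' @param x A `mult_aln` object.
#' @export
aln_width <- function(x) if (length(x) == 0) 0L else nchar(x[[1]])

#' @exportS3Method tibble::as_tibble
as_tibble.mult_aln <- function(x, ...) {
  tibble(species = names(x), sequence = as.character(unclass(x)))
}

# alignment as a species x column character matrix
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(as.character(unclass(aln)), ""))
}

matrix_aln <- function(m, species) {
  multiple_alignment(setNames(apply(m, 1, paste0, collapse = ""), species))
}

#' Read and write multi-FASTA alignments
#'
#' Thin wrappers over Biostrings FASTA I/O that return/accept the
#' package's `mult_aln` container. Sequences are upper-cased on read;
#' ragged or duplicate-label inputs are rejected.
#'
#' @param path File path.
#' @return `read_fasta()` returns a `mult_aln`; `write_fasta()` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  multiple_alignment(setNames(as.character(ss), names(ss)))
}

#' @rdname read_fasta
#' @param aln A `mult_aln`.
#' @export
write_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(as.character(unclass(aln)), names(aln)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Column filtering policy
#'
#' A deterministic stand-in for manual alignment curation: drop gapped
#' columns, then drop columns lying in low-identity windows. Window
#' identity is the mean pairwise identity over all species pairs,
#' averaged across the window's columns (gap-containing pairs at a
#' column do not count as matches).
#'
#' @param drop_gap_columns Drop any column containing a gap? Default TRUE.
#' @param window_len Window size in columns (>= 1). Windows tile the
#'   alignment; a window longer than the alignment collapses to one
#'   whole-alignment window.
#' @param min_window_identity Minimum mean pairwise identity a window
#'   must reach for its columns to be kept, in `[0, 1]`.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(drop_gap_columns = TRUE, window_len = 10,
                          min_window_identity = 0.5) {
  if (window_len < 1) {
    abort("window_len must be >= 1", class = "rateshift_error_param")
  }
  if (min_window_identity < 0 || min_window_identity > 1) {
    abort("min_window_identity must lie in [0, 1]",
          class = "rateshift_error_param")
  }
  structure(
    list(
      drop_gap_columns = isTRUE(drop_gap_columns),
      window_len = as.integer(window_len),
      min_window_identity = min_window_identity
    ),
    class = "filter_policy"
  )
}

# mean pairwise identity per column: fraction of species pairs agreeing,
# counting pairs where either member is a gap as non-matching
column_identity <- function(m) {
  n <- nrow(m)
  pairs <- utils::combn(n, 2)
  agree <- matrix(0, nrow = ncol(pairs), ncol = ncol(m))
  for (j in seq_len(ncol(pairs))) {
    a <- m[pairs[1, j], ]
    b <- m[pairs[2, j], ]
    agree[j, ] <- as.numeric(a == b & a != "-" & b != "-")
  }
  colMeans(agree)
}

#' Filter alignment columns by gap content and window identity
#'
#' Filtering is two-staged: gap-containing columns are removed first
#' (when the policy asks for it), then the remaining columns are tiled
#' into consecutive windows of `window_len` and each window is kept or
#' dropped as a whole according to its mean pairwise identity. Because
#' windows are all-or-nothing and evaluated on the gap-free alignment,
#' the operation is idempotent under a fixed policy.
#'
#' @param aln A `mult_aln`.
#' @param policy A [filter_policy()].
#' @return The filtered `mult_aln`, with the per-column logical keep
#'   mask (relative to the input) attached as attribute `"keep_mask"`
#'   for audit.
#' @examples
#' aln <- multiple_alignment(c(a = "ACG-T", b = "ACGTT"))
#' filter_columns(aln, filter_policy())
#' @export
filter_columns <- function(aln, policy = filter_policy()) {
  if (aln_width(aln) == 0) {
    abort("cannot filter an empty alignment",
          class = "rateshift_error_alignment")
  }
  m <- aln_matrix(aln)
  nc <- ncol(m)
  keep <- rep(TRUE, nc)
  if (policy$drop_gap_columns) {
    keep <- colSums(m == "-") == 0
  }
  kept_idx <- which(keep)
  if (length(kept_idx) > 0) {
    m2 <- m[, kept_idx, drop = FALSE]
    w <- min(policy$window_len, ncol(m2))
    ident <- column_identity(m2)
    for (s in seq(1, ncol(m2), by = w)) {
      idx <- s:min(s + w - 1, ncol(m2))
      if (mean(ident[idx]) < policy$min_window_identity) {
        keep[kept_idx[idx]] <- FALSE
      }
    }
  }
  out <- matrix_aln(m[, keep, drop = FALSE], names(aln))
  attr(out, "keep_mask") <- keep
  out
}

#' Concatenate alignments over a shared species set
#'
#' Columns are concatenated in list order; per-source offsets (0-based
#' half-open, on the concatenated alignment) are attached as attribute
#' `"offsets"` so the originals can be recovered by slicing.
#'
#' @param alns A list of `mult_aln` objects over identical species sets.
#' @return A `mult_aln`.
#' @export
concat_alignments <- function(alns) {
  if (length(alns) == 0) {
    abort("need at least one alignment", class = "rateshift_error_alignment")
  }
  species <- sort(names(alns[[1]]))
  for (a in alns) {
    if (!identical(sort(names(a)), species)) {
      abort("alignments do not share the same species set",
            class = "rateshift_error_alignment")
    }
  }
  lens <- map_dbl(alns, aln_width)
  rows <- map_chr(species, function(sp) {
    paste0(map_chr(alns, ~ unclass(.x)[[sp]]), collapse = "")
  })
  out <- multiple_alignment(setNames(rows, species))
  ends <- cumsum(lens)
  attr(out, "offsets") <- tibble(
    source = seq_along(alns), start = c(0, ends[-length(ends)]), end = ends
  )
  out
}

#' Extract a column range from an alignment
#'
#' @param aln A `mult_aln`.
#' @param start,end 0-based half-open column range.
#' @return A `mult_aln` over the same species.
#' @export
slice_alignment <- function(aln, start, end) {
  if (start < 0 || end > aln_width(aln) || end <= start) {
    abort("invalid column range", class = "rateshift_error_alignment")
  }
  multiple_alignment(setNames(
    substr(as.character(unclass(aln)), start + 1, end), names(aln)
  ))
}
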