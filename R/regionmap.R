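# Alignment-block and annotation analysis: MAF-style block I/O,
# inversion detection from strand-flipped blocks, per-species feature
# coverage, RepeatMasker parsing, TE/feature composition, ORF scanning.
#
# All coordinates are 0-based half-open on the forward strand; MAF
# minus-strand source coordinates are converted on read.

#' Read and write MAF-style alignment blocks
#'
#' Parses the block-based Multiple Alignment Format: each block is an
#' `a` line followed by `s` lines `src start size strand srcSize text`,
#' where `src` is `species.chromosome`. Minus-strand source coordinates
#' (which MAF gives on the reverse strand) are converted to
#' forward-strand 0-based half-open intervals; the original strand is
#' kept in the `strand` column. The first `s` line of each block is the
#' reference species (always `+` strand).
#'
#' @param path MAF file path.
#' @return A block tibble: `block`, `species`, `chrom`, `start`, `end`,
#'   `strand`, `src_size`, `text`.
#' @examples
#' blocks <- make_block_fixture(3, inverted = 2)
#' f <- tempfile(fileext = ".maf")
#' write_maf(blocks, f)
#' read_maf(f)
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  rows <- list()
  block <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, "a")) {
      block <- block + 1L
      next
    }
    if (startsWith(line, "s ")) {
      if (block == 0L) {
        abort(sprintf("line %d: 's' line before any 'a' line", i),
              class = "rateshift_error_maf")
      }
      # fields: s src start size strand srcSize text
      f <- strsplit(line, "\\s+")[[1]]
      if (length(f) != 7 || !f[5] %in% c("+", "-")) {
        abort(sprintf("line %d: malformed 's' line", i),
              class = "rateshift_error_maf")
      }
      src <- strsplit(f[2], ".", fixed = TRUE)[[1]]
      start <- suppressWarnings(as.numeric(f[3]))
      size <- suppressWarnings(as.numeric(f[4]))
      src_size <- suppressWarnings(as.numeric(f[6]))
      if (anyNA(c(start, size, src_size))) {
        abort(sprintf("line %d: non-numeric coordinates", i),
              class = "rateshift_error_maf")
      }
      strand <- f[5]
      fwd_start <- if (strand == "-") src_size - start - size else start
      rows[[length(rows) + 1]] <- tibble(
        block = block,
        species = src[1],
        chrom = if (length(src) > 1) paste(src[-1], collapse = ".") else NA_character_,
        start = fwd_start, end = fwd_start + size,
        strand = strand, src_size = src_size, text = f[7]
      )
      next
    }
    # other MAF line types (i, e, q) are ignored
  }
  if (length(rows) == 0) {
    return(tibble(
      block = integer(), species = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character(),
      src_size = numeric(), text = character()
    ))
  }
  list_rbind(rows)
}

#' @rdname read_maf
#' @param blocks A block tibble.
#' @return `write_maf()` returns `path` invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in unique(blocks$block)) {
    rows <- blocks[blocks$block == b, ]
    writeLines("a score=0", con)
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      size <- r$end - r$start
      maf_start <- if (r$strand == "-") r$src_size - r$end else r$start
      writeLines(sprintf(
        "s %s.%s %d %d %s %d %s",
        r$species, r$chrom, as.integer(maf_start), as.integer(size),
        r$strand, as.integer(r$src_size), r$text
      ), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# per-block query rows joined with the reference interval of each block
query_block_table <- function(blocks, query_species, ref_species) {
  ref_species <- ref_species %||% blocks$species[1]
  ref_rows <- blocks |>
    filter(.data$species == ref_species) |>
    select("block", ref_chrom = "chrom", ref_start = "start",
           ref_end = "end")
  q <- blocks |>
    filter(.data$species == query_species) |>
    select("block", "strand") |>
    dplyr::inner_join(ref_rows, by = "block") |>
    arrange(.data$ref_start)
  if (nrow(q) == 0) {
    abort(sprintf("query species '%s' absent from all blocks", query_species),
          class = "rateshift_error_blocks")
  }
  # minority orientation relative to the length-weighted majority strand
  w <- q$ref_end - q$ref_start
  plus_w <- sum(w[q$strand == "+"])
  majority <- if (plus_w >= sum(w) / 2) "+" else "-"
  mutate(q, flipped = .data$strand != majority)
}

#' Detect inversions from strand-flipped alignment blocks
#'
#' An inversion shows up as a run of blocks whose query strand opposes
#' the majority orientation of the query's chained blocks (majority is
#' block-length weighted; ties resolve to `+`). Consecutive flipped
#' blocks are merged into one interval when their reference gap is at
#' most `max_gap` (alignment pipelines fragment single events into
#' adjacent blocks).
#'
#' @param blocks A block tibble (see [read_maf()]); row order is
#'   irrelevant, blocks are sorted internally by reference coordinate.
#' @param query_species Species whose orientation is tested.
#' @param ref_species Reference species; defaults to the species of the
#'   first row (MAF convention: first `s` line).
#' @param max_gap Maximum reference gap (bp) across which adjacent
#'   flipped blocks merge. Default 1000.
#' @return A tibble of merged reference intervals: `chrom`, `start`,
#'   `end`, `n_blocks`.
#' @examples
#' detect_inversions(make_block_fixture(8, inverted = c(2, 3, 7)), "human")
#' @export
detect_inversions <- function(blocks, query_species, ref_species = NULL,
                              max_gap = 1000) {
  q <- query_block_table(blocks, query_species, ref_species)
  flip <- q[q$flipped, , drop = FALSE]
  if (nrow(flip) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_blocks = integer()))
  }
  # runs must be consecutive in the full sorted chain, not just nearby
  chain_pos <- match(flip$block, q$block)
  new_run <- c(TRUE, diff(chain_pos) > 1 |
                 (flip$ref_start[-1] - flip$ref_end[-nrow(flip)]) > max_gap)
  flip$run <- cumsum(new_run)
  flip |>
    group_by(.data$run) |>
    summarise(
      chrom = .data$ref_chrom[1],
      start = min(.data$ref_start),
      end = max(.data$ref_end),
      n_blocks = dplyr::n(),
      .groups = "drop"
    ) |>
    select("chrom", "start", "end", "n_blocks")
}

# union length of intervals clipped to [fs, fe)
overlap_union <- function(starts, ends, fs, fe) {
  s <- pmax(starts, fs); e <- pmin(ends, fe)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  if (length(s) == 0) return(0)
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ce) ce <- max(ce, e[i])
    else { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
  }
  tot + (ce - cs)
}

#' Per-species coverage of reference features by alignment blocks
#'
#' For each feature interval on the reference species and each query
#' species, reports the fraction of the feature covered by blocks in
#' which that species is present, a status (`absent` if nothing aligns,
#' `covered` if the fraction reaches `threshold`, otherwise `partial`),
#' and whether any covering block is inversion-flagged for that species.
#'
#' @inheritParams detect_inversions
#' @param features Feature tibble: `id`, `chrom`, `start`, `end` (on the
#'   reference species).
#' @param species_list Query species to report; default all non-reference
#'   species present in `blocks`.
#' @param threshold Covered-fraction cutoff for status `covered`
#'   (default 0.5).
#' @return A tibble: `feature`, `species`, `fraction`, `status`,
#'   `inverted`.
#' @export
feature_coverage <- function(blocks, features, species_list = NULL,
                             ref_species = NULL, threshold = 0.5,
                             max_gap = 1000) {
  ref_species <- ref_species %||% blocks$species[1]
  species_list <- species_list %||%
    setdiff(unique(blocks$species), ref_species)
  out <- purrr::map(species_list, function(sp) {
    q <- query_block_table(blocks, sp, ref_species)
    purrr::map(seq_len(nrow(features)), function(i) {
      f <- features[i, ]
      hit <- q[q$ref_start < f$end & q$ref_end > f$start, , drop = FALSE]
      frac <- overlap_union(hit$ref_start, hit$ref_end, f$start, f$end) /
        (f$end - f$start)
      tibble(
        feature = f$id, species = sp, fraction = frac,
        status = if (frac == 0) "absent"
                 else if (frac >= threshold) "covered" else "partial",
        inverted = any(hit$flipped)
      )
    }) |> list_rbind()
  })
  list_rbind(out)
}

#' @export
#' @rdname feature_coverage
#' @param object A coverage tibble from `feature_coverage()` (for
#'   `plot_coverage`).
plot_coverage <- function(object) {
  ggplot(object, aes(x = .data$species, y = .data$feature,
                     fill = .data$fraction)) +
    geom_tile(colour = "white") +
    geom_point(data = dplyr::filter(object, .data$inverted),
               aes(x = .data$species, y = .data$feature),
               shape = 4, size = 3, inherit.aes = FALSE) +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(fill = "covered fraction",
         title = "Feature coverage by species (x = inverted)") +
    theme_minimal()
}

collapse_repeat_class <- function(raw) {
  base <- sub("/.*$", "", raw)
  dplyr::case_when(
    base %in% c("SINE", "SINE?") ~ "SINE",
    base %in% c("LINE", "LINE?") ~ "LINE",
    base %in% c("DNA", "DNA?", "RC") ~ "DNA",
    base %in% c("LTR", "LTR?", "Retroposon") ~ "LTR",
    TRUE ~ "Other"
  )
}

#' Read a RepeatMasker `.out` annotation table
#'
#' Parses the standard RepeatMasker output layout (three header lines,
#' then whitespace-delimited records) and collapses repeat classes into
#' the five groups SINE, LINE, DNA, LTR, Other. With `ancient_only =
#' TRUE`, simple repeats and low-complexity annotations are excluded
#' (they carry no phylogenetic signal about ancestral insertions).
#'
#' @param path `.out` file path.
#' @param species Species label to attach to every record.
#' @param ancient_only Drop `Simple_repeat` / `Low_complexity` records?
#'   Default `FALSE`.
#' @return A TE annotation tibble: `name`, `repeat_class`, `raw_class`,
#'   `species`, `chrom`, `start`, `end`, `strand` (0-based half-open).
#' @export
read_repeatmasker_out <- function(path, species, ancient_only = FALSE) {
  lines <- readLines(path)
  body <- lines[-seq_len(min(3, length(lines)))]
  body <- body[trimws(body) != ""]
  if (length(body) == 0) {
    return(tibble(
      name = character(), repeat_class = character(),
      raw_class = character(), species = character(), chrom = character(),
      start = numeric(), end = numeric(), strand = character()
    ))
  }
  rows <- purrr::imap(body, function(line, i) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 11 || is.na(suppressWarnings(as.numeric(f[6]))) ||
        is.na(suppressWarnings(as.numeric(f[7])))) {
      abort(sprintf("malformed RepeatMasker record at body line %d", i),
            class = "rateshift_error_repeatmasker")
    }
    tibble(
      name = f[10],
      raw_class = f[11],
      chrom = f[5],
      start = as.numeric(f[6]) - 1,  # .out is 1-based inclusive
      end = as.numeric(f[7]),
      strand = if (f[9] == "C") "-" else "+"
    )
  })
  out <- list_rbind(rows) |>
    mutate(
      repeat_class = collapse_repeat_class(.data$raw_class),
      species = species
    ) |>
    select("name", "repeat_class", "raw_class", "species", "chrom",
           "start", "end", "strand")
  if (ancient_only) {
    out <- filter(out, !.data$raw_class %in% c("Simple_repeat",
                                               "Low_complexity"))
  }
  out
}

#' Write a TE annotation tibble in RepeatMasker `.out` layout
#'
#' @param tes TE tibble with at least `name`, `chrom`, `start`, `end`
#'   (0-based half-open), optional `raw_class`/`repeat_class`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(tes, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)  repeat    class/family   begin end  (left) ID",
    ""
  )
  raw <- tes$raw_class %||% tes$repeat_class %||% rep("Unknown", nrow(tes))
  strand <- tes$strand %||% rep("+", nrow(tes))
  recs <- sprintf(
    "  225   10.0  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
    tes$chrom, as.integer(tes$start) + 1L, as.integer(tes$end),
    ifelse(strand == "-", "C", "+"), tes$name, raw,
    as.integer(tes$end - tes$start), seq_len(nrow(tes))
  )
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Filter TEs shared across species
#'
#' Groups per-species TE annotations by element (the `symbol` column if
#' present, otherwise repeat name plus locus interval) and keeps groups
#' observed in at least `min_species` species, with `required_species`
#' among them.
#'
#' @param annotations TE annotation tibble (one row per element x
#'   species).
#' @param min_species Minimum number of distinct carrier species.
#' @param required_species Species that must be among the carriers.
#' @return One row per retained group: grouping columns, `species`
#'   (list column), `n_species`.
#' @examples
#' shared_te_filter(make_te_fixture())
#' @export
shared_te_filter <- function(annotations, min_species = 2,
                             required_species = "mouse") {
  key <- if ("symbol" %in% names(annotations)) "symbol"
         else c("name", "chrom", "start", "end")
  meta <- annotations |>
    distinct(across(all_of(key)), .keep_all = TRUE) |>
    select(all_of(key), dplyr::any_of(c("name", "repeat_class")))
  annotations |>
    group_by(across(all_of(key))) |>
    summarise(
      n_species = n_distinct(.data$species),
      species = list(sort(unique(.data$species))),
      .groups = "drop"
    ) |>
    left_join(meta, by = key) |>
    filter(
      .data$n_species >= min_species,
      purrr::map_lgl(.data$species, ~ all(required_species %in% .x))
    )
}

#' TE / feature composition table
#'
#' Lists, for every feature interval, the TE copies overlapping it by at
#' least 1 bp (half-open interval intersection on a shared coordinate
#' system). TE copies are deduplicated by symbol/name and interval, so a
#' per-species table can be passed directly.
#'
#' @param tes TE tibble with `chrom`, `start`, `end` and `symbol` (or
#'   `name`).
#' @param features Feature tibble: `id`, `chrom`, `start`, `end`.
#' @return A tibble: `feature`, `n_te`, `te_symbols` (comma-separated,
#'   position-sorted), `symbols` (list column).
#' @examples
#' te_feature_overlap(make_te_fixture(), locus_features())
#' @export
te_feature_overlap <- function(tes, features) {
  lab <- if ("symbol" %in% names(tes)) "symbol" else "name"
  copies <- distinct(tes, across(all_of(c(lab, "chrom", "start", "end"))))
  purrr::map(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    hit <- copies |>
      filter(.data$chrom == f$chrom, .data$start < f$end,
             .data$end > f$start) |>
      arrange(.data[[lab]], .data$start)
    tibble(
      feature = f$id,
      n_te = nrow(hit),
      te_symbols = paste(hit[[lab]], collapse = ", "),
      symbols = list(hit[[lab]])
    )
  }) |> list_rbind()
}

GENETIC_STOPS <- c("TAA", "TAG", "TGA")

scan_frames <- function(seq_chars, min_aa, require_stop) {
  L <- length(seq_chars)
  out <- list()
  for (off in 0:2) {
    n_codon <- (L - off) %/% 3
    if (n_codon < 2) next
    idx <- off + seq_len(n_codon * 3)
    codons <- apply(matrix(seq_chars[idx], nrow = 3), 2, paste0,
                    collapse = "")
    starts <- which(codons == "ATG")
    stops <- which(codons %in% GENETIC_STOPS)
    if (length(starts) == 0) next
    nxt <- stops[findInterval(starts, stops) + 1]
    for (s_i in seq_along(starts)) {
      st <- starts[s_i]; sp <- nxt[s_i]
      if (is.na(sp)) {
        if (!require_stop) {
          out[[length(out) + 1]] <- tibble(
            frame_off = off, start = off + (st - 1) * 3,
            end = off + n_codon * 3, length_aa = n_codon - st + 1,
            open = TRUE
          )
        }
        next
      }
      aa <- sp - st
      out[[length(out) + 1]] <- tibble(
        frame_off = off, start = off + (st - 1) * 3, end = off + sp * 3,
        length_aa = aa, open = FALSE
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(frame_off = integer(), start = numeric(), end = numeric(),
                  length_aa = numeric(), open = logical()))
  }
  list_rbind(out)
}

#' Scan a transcript for AUG-initiated open reading frames
#'
#' Finds every ATG-initiated, stop-terminated reading frame (standard
#' genetic code) of at least `min_aa` amino acids, on the sense strand
#' or in all six frames. `length_aa` counts codons from the initiator
#' methionine up to (excluding) the stop; coordinates are 0-based
#' half-open on the input sequence and include the stop codon. The
#' number of ATG codons occurring (in any frame, sense strand) upstream
#' of the longest sense ORF's start is attached as attribute
#' `"n_upstream_aug"`.
#'
#' @param transcript A DNA string (A/C/G/T, case-insensitive).
#' @param min_aa Minimum peptide length in amino acids (default 30).
#' @param frames `"sense"` (default) or `"six"`.
#' @param require_stop Only report stop-terminated frames (default
#'   TRUE); if FALSE, frames running off the 3' end are reported too and
#'   flagged in the `open` column.
#' @return A tibble sorted by decreasing length: `frame` (+1..+3,
#'   -1..-3), `start`, `end`, `length_aa`, `open`.
#' @examples
#' find_orfs("ATGAAATGA", min_aa = 1)
#' @export
find_orfs <- function(transcript, min_aa = 30,
                      frames = c("sense", "six"), require_stop = TRUE) {
  frames <- match.arg(frames)
  chars <- strsplit(toupper(transcript), "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    abort("transcript contains non-DNA characters",
          class = "rateshift_error_sequence")
  }
  L <- length(chars)
  sense <- scan_frames(chars, min_aa, require_stop) |>
    mutate(frame = .data$frame_off + 1)
  res <- sense
  if (frames == "six") {
    rc <- rev(chartr("ACGT", "TGCA", chars))
    anti <- scan_frames(rc, min_aa, require_stop) |>
      mutate(
        frame = -(.data$frame_off + 1),
        new_start = L - .data$end, new_end = L - .data$start,
        start = .data$new_start, end = .data$new_end
      ) |>
      select(-"new_start", -"new_end")
    res <- bind_rows(sense, anti)
  }
  res <- res |>
    filter(.data$length_aa >= min_aa) |>
    arrange(dplyr::desc(.data$length_aa), .data$start) |>
    select("frame", "start", "end", "length_aa", "open")
  n_up <- NA_integer_
  sense_kept <- res[res$frame > 0, , drop = FALSE]
  if (nrow(sense_kept) > 0) {
    main_start <- sense_kept$start[1]
    if (main_start >= 3) {
      head_seq <- paste0(chars[seq_len(main_start)], collapse = "")
      hits <- gregexpr("ATG", head_seq, fixed = TRUE)[[1]]
      n_up <- if (hits[1] == -1) 0L else length(hits)
    } else n_up <- 0L
  }
  attr(res, "n_upstream_aug") <- n_up
  res
}

#' Read features from a BED file
#'
#' Uses `rtracklayer` when installed, otherwise a minimal BED parser
#' (tab-separated, 0-based half-open; columns chrom, start, end, name,
#' score, strand).
#'
#' @param path BED file path.
#' @return A feature tibble: `id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_features <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    return(tibble(
      id = if (!is.null(gr$name)) gr$name else paste0("feature", seq_along(gr)),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    ))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  tibble(
    id = if (ncol(df) >= 4) df[[4]] else paste0("feature", seq_len(nrow(df))),
    chrom = df[[1]], start = df[[2]], end = df[[3]],
    strand = if (ncol(df) >= 6) df[[6]] else "*"
  )
}

#' @rdname read_features
#' @param features A feature tibble.
#' @export
write_features <- function(features, path) {
  df <- data.frame(
    chrom = features$chrom, start = features$start, end = features$end,
    name = features$id, score = 0,
    strand = features$strand %||% "*"
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
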