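# Pairwise distance estimation and neighbor joining.
#
# Gaps and ambiguity codes are handled by pairwise deletion: for each
# sequence pair, only columns where both sequences carry an unambiguous
# A/C/G/T are used.

VALID_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

usable_sites <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv)) {
    abort("sequences differ in length", class = "rateshift_error_distance")
  }
  ok <- av %in% VALID_BASES & bv %in% VALID_BASES
  list(a = av[ok], b = bv[ok])
}

dist_estimate <- function(value, model, sites_used) {
  tibble(value = value, model = model, sites_used = as.integer(sites_used))
}

#' Pairwise genetic distances between two aligned sequences
#'
#' `p_distance()` is the raw mismatch proportion; `jc69_distance()`
#' applies the Jukes-Cantor correction
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}; `k80_distance()` applies
#' the Kimura two-parameter correction
#' \eqn{d = \frac{1}{2}\ln\frac{1}{1-2P-Q} + \frac{1}{4}\ln\frac{1}{1-2Q}}
#' with \eqn{P} the transition and \eqn{Q} the transversion proportion.
#' Sites where either sequence has a gap or ambiguity are excluded
#' (pairwise deletion).
#'
#' @param a,b Equal-length aligned DNA sequences (single strings).
#' @return A one-row tibble with columns `value` (substitutions per
#'   site), `model`, and `sites_used`.
#' @examples
#' jc69_distance("ACGTACGT", "ACGAACGT")
#' @export
p_distance <- function(a, b) {
  s <- usable_sites(a, b)
  n <- length(s$a)
  if (n < 1) {
    abort("no usable sites shared by the two sequences",
          class = "rateshift_error_distance")
  }
  dist_estimate(mean(s$a != s$b), "p", n)
}

#' @rdname p_distance
#' @export
jc69_distance <- function(a, b) {
  pd <- p_distance(a, b)
  p <- pd$value
  if (p >= 0.75) {
    abort(
      sprintf("saturated pair (p = %.4f >= 3/4): JC69 distance undefined", p),
      class = "rateshift_error_saturation"
    )
  }
  dist_estimate(-0.75 * log(1 - 4 * p / 3), "JC69", pd$sites_used)
}

#' @rdname p_distance
#' @export
k80_distance <- function(a, b) {
  s <- usable_sites(a, b)
  n <- length(s$a)
  if (n < 1) {
    abort("no usable sites shared by the two sequences",
          class = "rateshift_error_distance")
  }
  diff <- s$a != s$b
  transition <- diff & ((s$a %in% PURINES) == (s$b %in% PURINES))
  P <- mean(transition)
  Q <- mean(diff & !transition)
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    abort(
      sprintf("saturated pair (P = %.4f, Q = %.4f): K80 distance undefined",
              P, Q),
      class = "rateshift_error_saturation"
    )
  }
  d <- 0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
  dist_estimate(d, "K80", n)
}

#' Pairwise distance matrix for a multiple alignment
#'
#' @param aln A `mult_aln` with at least two species.
#' @param model `"p"`, `"jc69"`, or `"k80"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by
#'   species. Saturated pairs raise an error naming the pair.
#' @examples
#' aln <- multiple_alignment(c(a = "ACGTACGT", b = "ACGAACGT"))
#' distance_matrix(aln, model = "jc69")
#' @export
distance_matrix <- function(aln, model = c("k80", "jc69", "p")) {
  model <- match.arg(model)
  fn <- switch(model, p = p_distance, jc69 = jc69_distance,
               k80 = k80_distance)
  sp <- names(aln)
  if (length(sp) < 2) {
    abort("need at least two species", class = "rateshift_error_distance")
  }
  dm <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)[-length(sp)]) {
    for (j in (i + 1):length(sp)) {
      d <- tryCatch(
        fn(unclass(aln)[[i]], unclass(aln)[[j]]),
        rateshift_error_saturation = function(e) {
          abort(
            sprintf("pair (%s, %s): %s", sp[i], sp[j], conditionMessage(e)),
            class = "rateshift_error_saturation"
          )
        }
      )
      dm[i, j] <- dm[j, i] <- d$value
    }
  }
  dm
}

#' Tidy a distance matrix into pair rows
#'
#' @param dm A symmetric labelled distance matrix.
#' @return A tibble with one row per unordered pair: `sp1`, `sp2`,
#'   `distance`.
#' @export
tidy_distances <- function(dm) {
  sp <- rownames(dm)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  tibble(
    sp1 = sp[idx[, 1]], sp2 = sp[idx[, 2]],
    distance = dm[idx]
  )
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion. Ties in Q
#' are broken deterministically by the lexicographically smallest pair
#' of subtree labels. The result is returned as a Newick string (also
#' convertible via [ape::read.tree] for plotting).
#'
#' @param dm A symmetric labelled distance matrix over >= 3 taxa.
#' @return A Newick string (unrooted tree, with branch lengths).
#' @examples
#' aln <- multiple_alignment(c(
#'   a = "ACGTACGTAC", b = "ACGTACGTAT", c = "TCGAACGTAC", d = "TCGAACGTAT"
#' ))
#' nj_tree(distance_matrix(aln, "p"))
#' @export
nj_tree <- function(dm) {
  n <- nrow(dm)
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  }
  if (n < 3) {
    abort("neighbor joining needs at least 3 taxa",
          class = "rateshift_error_tree"
    )
  }
  d <- dm
  nodes <- rownames(dm)        # newick fragment per active node
  labels <- rownames(dm)       # tie-break label (smallest leaf label inside)
  while (length(nodes) > 3) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    key <- paste(pmin(labels[best[, 1]], labels[best[, 2]]),
                 pmax(labels[best[, 1]], labels[best[, 2]]))
    pick <- best[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_node <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    new_lab <- min(labels[i], labels[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    labels <- c(labels[keep], new_lab)
  }
  # final three-node star: three-point formulas
  li <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lj <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lk <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
          nodes[1], li, nodes[2], lj, nodes[3], lk)
}

#' Read and write square PHYLIP distance matrices
#'
#' @param dm A symmetric labelled distance matrix.
#' @param path File path.
#' @return `write_phylip_dm()` returns `path` invisibly;
#'   `read_phylip_dm()` returns the matrix.
#' @export
write_phylip_dm <- function(dm, path) {
  lines <- c(
    sprintf("%5d", nrow(dm)),
    map_chr(seq_len(nrow(dm)), function(i) {
      paste0(formatC(rownames(dm)[i], width = -10),
             paste(sprintf("%.8f", dm[i, ]), collapse = "  "))
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_dm
#' @export
read_phylip_dm <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labels <- map_chr(rows, 1)
  dm <- do.call(rbind, map(rows, ~ as.numeric(.x[-1])))
  dimnames(dm) <- list(labels, labels)
  dm
}
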