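# Independent oracles used across tests. These deliberately re-derive
# results by brute force or closed form, separately from the package
# implementation paths they check.

# exhaustive ORF scan: walk every position on both strands
orf_oracle <- function(seq, min_aa, six_frame = TRUE) {
  revcomp_chr <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  scan_one <- function(s) {
    L <- nchar(s)
    out <- list()
    for (i in seq_len(max(L - 5, 0))) {
      if (substr(s, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= L) {
        cod <- substr(s, j, j + 2)
        if (cod %in% stops) {
          aa <- (j - i) / 3
          if (aa >= min_aa) {
            out[[length(out) + 1]] <-
              data.frame(start = i - 1, end = j + 2, length_aa = aa,
                         frame_off = (i - 1) %% 3)
          }
          break
        }
        j <- j + 3
      }
    }
    if (length(out) == 0) {
      return(data.frame(start = numeric(), end = numeric(),
                        length_aa = numeric(), frame_off = numeric()))
    }
    do.call(rbind, out)
  }
  s <- toupper(seq)
  L <- nchar(s)
  fwd <- scan_one(s)
  fwd$frame <- fwd$frame_off + 1
  res <- fwd
  if (six_frame) {
    rc <- scan_one(revcomp_chr(s))
    if (nrow(rc) > 0) {
      rc$frame <- -(rc$frame_off + 1)
      new_start <- L - rc$end
      rc$end <- L - rc$start
      rc$start <- new_start
    } else rc$frame <- numeric()
    res <- rbind(fwd, rc)
  }
  res <- res[order(-res$length_aa, res$start), c("frame", "start", "end",
                                                 "length_aa")]
  rownames(res) <- NULL
  res
}

# least-squares topology fit over the three unrooted 4-taxon topologies;
# returns the sister pair of taxon 1 in the best-fitting topology
ls_topology_oracle <- function(dm) {
  stopifnot(nrow(dm) == 4)
  pairs <- utils::combn(4, 2)
  d <- dm[t(pairs)]
  rss_for <- function(partner) {
    others <- setdiff(2:4, partner)
    # branches: e1..e4 external, e5 internal; row per pair (i,j)
    X <- matrix(0, 6, 5)
    for (p in seq_len(6)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      X[p, i] <- 1; X[p, j] <- 1
      same_side <- (j == partner && i == 1) ||
        (i == partner && j == 1) || all(c(i, j) %in% others)
      if (!same_side) X[p, 5] <- 1
    }
    fit <- stats::lm.fit(X, d)
    sum(fit$residuals^2)
  }
  rss <- vapply(2:4, rss_for, 0)
  c(2L, 3L, 4L)[which.min(rss)]
}

# random additive (tree-metric) 4x4 distance matrix with known split;
# returns list(dm, partner_of_1)
random_additive_matrix <- function(labels = c("mouse", "rat", "human", "dog")) {
  partner <- sample(2:4, 1)
  ext <- stats::runif(4, 0.05, 1)
  internal <- stats::runif(1, 0.05, 1)
  dm <- matrix(0, 4, 4, dimnames = list(labels, labels))
  for (i in 1:3) for (j in (i + 1):4) {
    same <- (i == 1 && j == partner) || (i != 1 && j != 1 && i != partner &&
                                           j != partner)
    dm[i, j] <- dm[j, i] <- ext[i] + ext[j] + if (same) 0 else internal
  }
  list(dm = dm, partner = partner)
}

# sister pair of taxon `label` in an unrooted 4-taxon newick string
newick_sister_of <- function(nwk, label) {
  tr <- ape::read.tree(text = nwk)
  tr <- ape::unroot(tr)
  # the unique internal edge splits the 4 tips 2|2
  parts <- ape::prop.part(tr)
  # find a bipartition of size 2 containing the label
  tips <- tr$tip.label
  for (i in 1:3) {
    for (j in (i + 1):4) {
      cand <- c(tips[i], tips[j])
      if (!(label %in% cand)) next
      rest <- setdiff(tips, cand)
      d_split <- ape::dist.topo(
        tr,
        ape::unroot(ape::read.tree(text = sprintf(
          "((%s,%s),(%s,%s));", cand[1], cand[2], rest[1], rest[2]
        )))
      )
      if (d_split == 0) return(setdiff(cand, label))
    }
  }
  NA_character_
}

# sequence pair with exact substitution composition (for distance
# closed-form checks): n sites, n_ts transitions (A->G), n_tv
# transversions (A->C)
pair_with_counts <- function(n, n_ts, n_tv) {
  a <- rep("A", n)
  b <- rep("A", n)
  if (n_ts > 0) b[seq_len(n_ts)] <- "G"
  if (n_tv > 0) b[n_ts + seq_len(n_tv)] <- "C"
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

random_aln <- function(n_species = 4, width = 60, gap_prob = 0,
                       labels = NULL) {
  labels <- labels %||% paste0("sp", seq_len(n_species))
  rows <- vapply(seq_len(n_species), function(i) {
    chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    if (gap_prob > 0) {
      g <- stats::runif(width) < gap_prob
      chars[g] <- "-"
    }
    paste(chars, collapse = "")
  }, "")
  multiple_alignment(stats::setNames(rows, labels))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
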