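#' Read an aligned FASTA file
#'
#' Sequences must already be aligned (equal length); gap characters `-` and
#' `.` are preserved and letters are upper-cased. Labels are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path FASTA file.
#' @return named character vector of equal-length sequences.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the 'Biostrings' package", call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop("duplicate sequence label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences have unequal lengths; align them first ",
         "(lengths: ", paste(sort(unique(nchar(seqs))), collapse = ", "), ")",
         call. = FALSE)
  seqs
}

#' Pairwise p-distances from an alignment
#'
#' The p-distance between two aligned sequences is the fraction of mismatched
#' positions among the positions where neither sequence carries a gap
#' (`-` or `.`), i.e. pairwise deletion of gapped columns. This is the
#' standard uncorrected distance used when clustering 16S sequences at
#' similarity thresholds (distance = 1 - similarity).
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (at least two).
#' @return symmetric matrix of distances in `[0, 1]` with zero diagonal.
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences have unequal lengths", call. = FALSE)
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    stop("sequences must be named", call. = FALSE)
  chars <- t(vapply(strsplit(toupper(seqs), ""), identity,
                    character(nchar(seqs[[1L]]))))
  gap <- chars == "-" | chars == "."
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !(gap[i, ] | gap[j, ])
      if (!any(ok))
        stop("no comparable (gap-free) positions between '", names(seqs)[i],
             "' and '", names(seqs)[j], "'", call. = FALSE)
      d[i, j] <- d[j, i] <- mean(chars[i, ok] != chars[j, ok])
    }
  }
  d
}

#' Read / write a labelled square distance matrix (TSV)
#'
#' @param path TSV with a header row and first column of labels.
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  validate_distance(m)
  m
}

#' @rdname read_distance_matrix
#' @param dist symmetric matrix to write.
#' @export
write_distance_matrix <- function(dist, path) {
  df <- data.frame(id = rownames(dist), dist, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_distance <- function(d, tol = 1e-9) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (nrow(d) < 2L) stop("need at least 2 items", call. = FALSE)
  if (is.null(rownames(d))) stop("distance matrix must be labelled",
                                 call. = FALSE)
  if (anyNA(d)) stop("distance matrix contains missing values", call. = FALSE)
  if (any(d < 0)) stop("negative distance(s)", call. = FALSE)
  if (max(abs(d - t(d))) > tol)
    stop("distance matrix is asymmetric beyond tolerance ", tol,
         call. = FALSE)
  if (any(abs(diag(d)) > tol))
    stop("distance matrix has a nonzero diagonal", call. = FALSE)
  invisible(TRUE)
}

#' Agglomerative ladder dendrogram over a distance matrix
#'
#' Builds the full agglomeration ladder (average/UPGMA or complete linkage)
#' and returns it as a rooted [ape::phylo] tree whose node heights equal the
#' merge distances, so that cutting the tree at any threshold `t` reproduces
#' the flat clustering obtained by agglomerating up to distance `t`. The
#' continuous range of similarity clustering thresholds is thereby embodied
#' in a single tree that can be fed directly to [find_pcgs()].
#'
#' Merging is deterministic: ties are broken by the smallest pair of original
#' item indices (clusters are identified by their smallest member index).
#'
#' @param dist symmetric labelled distance matrix, zero diagonal.
#' @param linkage `"average"` (default; UPGMA, ultrametric heights) or
#'   `"complete"`.
#' @return an [ape::phylo] tree with an attached `"ladder"` attribute (merge
#'   table and merge heights, \code{\link[stats]{hclust}}-style) used by
#'   [cut_dendrogram()].
#' @export
ladder_dendrogram <- function(dist, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  validate_distance(dist)
  n <- nrow(dist)
  labels <- rownames(dist)
  d <- dist
  # active[k]: smallest original index in cluster k (cluster id); size[k]
  active <- seq_len(n)
  cl_id <- -seq_len(n)            # hclust convention: negatives = singletons
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(Inf, Inf, Inf)  # (distance, small index, large index)
    bi <- bj <- 0L
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        key <- c(d[i, j], min(active[i], active[j]), max(active[i], active[j]))
        if (key[1] < best[1] - 1e-15 ||
            (abs(key[1] - best[1]) <= 1e-15 &&
             (key[2] < best[2] || (key[2] == best[2] && key[3] < best[3])))) {
          best <- key; bi <- i; bj <- j
        }
      }
    }
    height[step] <- d[bi, bj]
    merge[step, ] <- sort(c(cl_id[bi], cl_id[bj]))
    # linkage update against every other cluster
    others <- setdiff(seq_len(m), c(bi, bj))
    newd <- numeric(m)
    for (k in others) {
      newd[k] <- switch(linkage,
        average  = (size[bi] * d[bi, k] + size[bj] * d[bj, k]) /
                   (size[bi] + size[bj]),
        complete = max(d[bi, k], d[bj, k]))
    }
    keep <- others
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    d <- d2
    active <- c(active[keep], min(active[bi], active[bj]))
    size <- c(size[keep], size[bi] + size[bj])
    cl_id <- c(cl_id[keep], step)
  }
  phy <- ladder_to_phylo(merge, height, labels)
  attr(phy, "ladder") <- list(merge = merge, height = height, labels = labels,
                              linkage = linkage)
  phy
}

# Convert an hclust-style merge table into a phylo tree with node heights
# equal to the merge heights.
ladder_to_phylo <- function(merge, height, labels) {
  n <- length(labels)
  if (n == 1L) stop("cannot build a tree from one item", call. = FALSE)
  nmerge <- nrow(merge)
  # ape numbering: tips 1..n; merge k becomes internal node; the LAST merge is
  # the root. Internal node number for merge k: n + (nmerge - k + 1) so the
  # root (last merge) gets n+1.
  node_of <- function(x) if (x < 0) -x else n + (nmerge - x + 1L)
  h_node <- c(rep(0, n), rev(height))  # height of each node number
  edge <- matrix(0L, 0L, 2L); elen <- numeric(0)
  for (k in seq_len(nmerge)) {
    p <- node_of(k)
    for (ch in merge[k, ]) {
      cnode <- node_of(ch)
      edge <- rbind(edge, c(p, cnode))
      elen <- c(elen, height[k] - h_node[cnode])
    }
  }
  phy <- list(edge = edge, edge.length = pmax(elen, 0), tip.label = labels,
              Nnode = nmerge)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' Cut a ladder dendrogram at a distance threshold
#'
#' Applies every merge whose height is at most `t` (within a 1e-12 tolerance)
#' and returns the resulting flat clustering, i.e. the OTUs produced at
#' similarity threshold `1 - t`.
#'
#' @param dend result of [ladder_dendrogram()].
#' @param t distance threshold.
#' @return integer cluster membership vector named by item label; cluster ids
#'   are consecutive integers in order of first appearance.
#' @export
cut_dendrogram <- function(dend, t) {
  lad <- attr(dend, "ladder")
  if (is.null(lad))
    stop("not a ladder dendrogram (missing ladder attribute)", call. = FALSE)
  n <- length(lad$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  cl_root <- integer(nrow(lad$merge))  # representative tip of each merge
  for (k in seq_len(nrow(lad$merge))) {
    a <- lad$merge[k, 1L]; b <- lad$merge[k, 2L]
    ra <- if (a < 0) -a else cl_root[a]
    rb <- if (b < 0) -b else cl_root[b]
    ra <- find(ra); rb <- find(rb)
    if (lad$height[k] <= t + 1e-12) parent[rb] <- ra
    cl_root[k] <- ra
  }
  rep_tip <- vapply(seq_len(n), find, integer(1))
  ids <- match(rep_tip, unique(rep_tip))
  setNames(ids, lad$labels)
}
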