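# Distance-based phylogenetics for the synthase family: pairwise nucleotide
# distances (p-distance, JC69, TN93) with pairwise deletion of ambiguous
# sites, neighbor-joining tree construction, bootstrap support with
# collapsing of weakly supported edges, and Newick I/O. Distance and NJ
# machinery is delegated to ape; distances are computed pair by pair so the
# TN93 base frequencies are those of each pair's retained sites.

records_to_dnabin <- function(records) {
  m <- seq_matrix(records)
  # ape's DNA alphabet: anything non-ACGT is carried through and ignored by
  # dist.dna under pairwise deletion
  ape::as.DNAbin(tolower(m))
}

model_key <- function(model) {
  model <- match.arg(tolower(model), c("p-distance", "p", "raw", "jc69", "tn93"))
  switch(model, "p-distance" = , "p" = , "raw" = "raw",
         "jc69" = "JC69", "tn93" = "TN93")
}

#' Pairwise nucleotide distance matrix
#'
#' Distances are computed independently for every pair; alignment columns
#' holding a gap or an IUPAC ambiguity code in either member of the pair are
#' excluded (pairwise deletion). Under TN93 the base frequencies are empirical
#' frequencies of the pair's retained sites.
#'
#' @param records List of >= 3 equal-length [seq_record] (pre-aligned,
#'   co-linear cds).
#' @param model One of `"p-distance"`, `"JC69"`, `"TN93"` (case-insensitive).
#' @return Object of class `dist_matrix`: list with `ids`, `d` (symmetric
#'   numeric matrix, zero diagonal), `sites_used` (pairwise retained-site
#'   counts), `model`.
#' @export
pairwise_distance <- function(records, model = c("TN93", "JC69", "p-distance")) {
  model <- model_key(model[1])
  if (length(records) < 3L) stop("need at least 3 sequences", call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "id")
  m <- seq_matrix(records)
  n <- length(records)
  clean <- m %in% c("A", "C", "G", "T")
  dim(clean) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(ncol(m), n, n, dimnames = list(ids, ids))
  bin <- records_to_dnabin(records)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- clean[i, ] & clean[j, ]
    sites[i, j] <- sites[j, i] <- sum(keep)
    if (!sum(keep))
      stop("no retained sites for pair ", ids[i], " / ", ids[j], call. = FALSE)
    dij <- as.numeric(ape::dist.dna(bin[c(i, j), ], model = model,
                                    pairwise.deletion = TRUE))
    if (!is.finite(dij))
      stop("saturated or undefined ", model, " distance for pair ",
           ids[i], " / ", ids[j], call. = FALSE)
    d[i, j] <- d[j, i] <- dij
  }
  structure(list(ids = ids, d = d, sites_used = sites, model = model),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d taxa, model %s\n", length(x$ids), x$model))
  print(round(x$d, 6))
  invisible(x)
}

as_dist_matrix <- function(d, ids = rownames(d), model = "supplied") {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(d)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d,
                 sites_used = matrix(NA_integer_, nrow(d), ncol(d)),
                 model = model), class = "dist_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (exact on additive matrices). Negative branch
#' length estimates, which NJ can produce on noisy matrices, are clamped to
#' zero with a warning.
#'
#' @param D A `dist_matrix` from [pairwise_distance()], or a plain symmetric
#'   numeric matrix with dimnames.
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(D) {
  if (is.matrix(D)) D <- as_dist_matrix(D)
  stopifnot(inherits(D, "dist_matrix"))
  if (length(D$ids) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(D$d)
  if (any(tr$edge.length < 0)) {
    warning(sum(tr$edge.length < 0),
            " negative NJ branch length(s) clamped to zero")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

resample_records <- function(records, cols) {
  lapply(records, function(r) {
    chars <- strsplit(r$seq, "")[[1]]
    seq_record(r$id, paste(chars[cols], collapse = ""), r$description, r$role)
  })
}

#' Collapse weakly supported internal edges into polytomies
#'
#' @param tree An [ape::phylo] with bootstrap percentages in `node.label`.
#' @param collapse_below Support threshold; internal edges with support
#'   strictly below it are removed (their subtended clades become polytomies).
#' @return The collapsed [ape::phylo].
#' @export
collapse_low_support <- function(tree, collapse_below = 50) {
  if (is.null(tree$node.label)) return(tree)
  ntip <- length(tree$tip.label)
  support <- suppressWarnings(as.numeric(tree$node.label))
  child <- tree$edge[, 2]
  weak <- rep(FALSE, nrow(tree$edge))
  internal <- which(child > ntip)
  sup <- support[child[internal] - ntip]
  weak[internal] <- !is.na(sup) & sup < collapse_below
  if (!any(weak)) return(tree)
  # mark weak edges with a negative sentinel length, then contract exactly
  # those (legitimate zero-length edges are preserved)
  tr <- tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  tr$edge.length[weak] <- -1
  out <- ape::di2multi(tr, tol = -0.5)
  # di2multi collapses edges with length < tol: our sentinel edges qualify,
  # anything >= 0 does not
  out
}

#' Neighbor-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for each
#' replicate, scores the bipartitions of the original tree, and collapses
#' edges supported by fewer than `collapse_below` percent of replicates.
#' Zero-length internal edges of the point-estimate tree carry no distance
#' signal and are treated as unresolved before scoring (an alignment of
#' identical sequences therefore returns a star tree).
#'
#' @param records List of equal-length [seq_record].
#' @param model Distance model, see [pairwise_distance()].
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param collapse_below Collapse threshold in percent (default 50); set to 0
#'   to keep all edges.
#' @param seed Integer seed; required for reproducibility.
#' @return An [ape::phylo] whose `node.label` holds bootstrap percentages,
#'   collapsed below the threshold.
#' @export
bootstrap_support <- function(records, model = "TN93", n_reps = 1000L,
                              collapse_below = 50, seed = 1L) {
  if (n_reps < 1L) stop("'n_reps' must be >= 1", call. = FALSE)
  set.seed(seed)
  len <- nchar(records[[1]]$seq)
  tree0 <- suppressWarnings(nj_tree(pairwise_distance(records, model)))
  # zero-length internal edges carry no signal: treat as unresolved before
  # scoring bipartitions
  tree0 <- ape::di2multi(tree0, tol = 1e-10)
  if (tree0$Nnode == 1L) return(tree0)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(len, len, replace = TRUE)
    reps[[b]] <- tryCatch(
      suppressWarnings(
        nj_tree(pairwise_distance(resample_records(records, cols), model))),
      error = function(e) NULL)
  }
  reps <- Filter(Negate(is.null), reps)
  counts <- ape::prop.clades(tree0, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(reps)
  tree0$node.label <- formatC(support, format = "f", digits = 1)
  # the root "node" of an unrooted phylo carries no bipartition: blank it
  tree0$node.label[1] <- ""
  collapse_low_support(tree0, collapse_below)
}

#' Write a tree as a Newick string (and optionally to file)
#'
#' Branch lengths are written with 6 significant digits; bootstrap supports
#' (if present) appear as internal node labels. Round-trips through
#' [read_newick()].
#'
#' @param tree An [ape::phylo].
#' @param path Optional output file.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 6)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Parse a Newick string or file
#'
#' @param x Newick string, or a path to a file holding one.
#' @return An [ape::phylo].
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}

#' Write a distance matrix as a PHYLIP-style square TSV
#'
#' @param D A `dist_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_tsv <- function(D, path) {
  stopifnot(inherits(D, "dist_matrix"))
  df <- data.frame(id = D$ids, as.data.frame(D$d), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check that a set of records stacks gap-free into an alignment
#'
#' The package treats synthase cds as co-linear and does not build multiple
#' alignments; this verifies the assumption (equal lengths, no gap
#' characters).
#'
#' @param records List of [seq_record].
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_colinear <- function(records) {
  lens <- vapply(records, function(r) nchar(r$seq), integer(1))
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths: ", paste(unique(lens), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
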