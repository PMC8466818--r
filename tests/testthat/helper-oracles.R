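# Independent brute-force oracles and small generators used across the test
# files. These deliberately avoid the package's own code paths.

BASES4 <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

# random complete cds of n nt (n divisible by 3): ATG + non-stop codons + stop
random_cds <- function(n) {
  stopifnot(n %% 3 == 0, n >= 9)
  stops <- c("TAA", "TAG", "TGA")
  body <- character(n / 3 - 2)
  for (i in seq_along(body)) {
    repeat {
      cd <- paste(sample(BASES4, 3, replace = TRUE), collapse = "")
      if (!cd %in% stops) { body[i] <- cd; break }
    }
  }
  paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
}

mutate_at <- function(seq, pos, alt) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- alt[i]
  seq
}

# positional identity oracle (equal lengths, no rounding subtleties hidden)
naive_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  100 * sum(ca == cb) / length(ca)
}

rc_oracle <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# all-offsets primer site scan, both strands, exact-base templates only
naive_sites <- function(primer, template, max_mm, clamp) {
  p <- strsplit(primer, "")[[1]]
  L <- length(p)
  tc <- strsplit(template, "")[[1]]
  n <- length(tc)
  hits <- list()
  for (s in seq_len(n - L + 1)) {
    win <- tc[s:(s + L - 1)]
    mm <- sum(win != p)
    if (mm <= max_mm && sum(win[(L - clamp + 1):L] != p[(L - clamp + 1):L]) == 0)
      hits[[length(hits) + 1]] <- c(strand = "+", pos5 = s, mm = mm)
    rp <- strsplit(rc_oracle(primer), "")[[1]]
    mm2 <- sum(win != rp)
    if (mm2 <= max_mm && sum(win[1:clamp] != rp[1:clamp]) == 0)
      hits[[length(hits) + 1]] <- c(strand = "-", pos5 = s + L - 1, mm = mm2)
  }
  if (!length(hits))
    return(data.frame(strand = character(0), pos5 = integer(0), mm = integer(0)))
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  df$pos5 <- as.integer(df$pos5); df$mm <- as.integer(df$mm)
  df[order(df$strand, df$pos5), ]
}

# substitution-effect oracle: translate whole mutated cds and diff proteins
naive_effect <- function(pos, alt, cds) {
  aa_of <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  mut <- mutate_at(cds, pos, alt)
  a0 <- aa_of(cds); a1 <- aa_of(mut)
  ci <- (pos - 1) %/% 3 + 1
  from <- substr(a0, ci, ci); to <- substr(a1, ci, ci)
  eff <- if (from == to) "synonymous" else if (to == "*") "nonsense" else "missense"
  list(effect = eff, aa_from = from, aa_to = to)
}

# random unrooted binary tree with positive branch lengths -> additive matrix
random_additive <- function(ntaxa) {
  tr <- ape::unroot(ape::rtree(ntaxa, br = NULL))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# every unrooted binary 5-taxon tree is two cherries plus a central leaf:
# enumerate all 15 labelled topologies as newick strings
all_5taxon_topologies <- function(tips) {
  stopifnot(length(tips) == 5)
  out <- list()
  for (single in 1:5) {
    rest <- tips[-single]
    for (mate in 2:4) {
      pair1 <- c(rest[1], rest[mate])
      pair2 <- setdiff(rest, pair1)
      nwk <- sprintf("((%s,%s),(%s,%s),%s);", pair1[1], pair1[2],
                     pair2[1], pair2[2], tips[single])
      out[[length(out) + 1]] <- ape::read.tree(text = nwk)
    }
  }
  out
}

# exhaustive 5-taxon topology search with least-squares branch fitting
best_ls_topology <- function(D) {
  tips <- rownames(D)
  tops <- all_5taxon_topologies(tips)
  pair_idx <- t(combn(5, 2))
  best <- NULL; best_rss <- Inf
  for (tp in tops) {
    ne <- nrow(tp$edge)
    A <- matrix(0, nrow(pair_idx), ne)
    for (r in seq_len(nrow(pair_idx))) {
      t1 <- which(tp$tip.label == tips[pair_idx[r, 1]])
      t2 <- which(tp$tip.label == tips[pair_idx[r, 2]])
      path_nodes <- ape::nodepath(tp, t1, t2)
      for (k in seq_len(length(path_nodes) - 1)) {
        e <- which((tp$edge[, 1] == path_nodes[k] & tp$edge[, 2] == path_nodes[k + 1]) |
                   (tp$edge[, 2] == path_nodes[k] & tp$edge[, 1] == path_nodes[k + 1]))
        A[r, e] <- 1
      }
    }
    y <- D[cbind(tips[pair_idx[, 1]], tips[pair_idx[, 2]])]
    fit <- lm.fit(A, y)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- tp }
  }
  list(tree = best, rss = best_rss)
}

# build a tiny manual qPCR plate data.frame from a vector spec
plate_rows <- function(genotype, gene, cq, bio = 1L, tech = 1L,
                       std = FALSE, lq = NA_real_) {
  data.frame(sample = paste(genotype, gene, bio, tech, sep = "_"),
             genotype = genotype, gene = gene, bio_rep = bio, tech_rep = tech,
             cq = cq, is_standard = std, log10_quantity = lq,
             stringsAsFactors = FALSE)
}

# noise-only stability panel: one Cq per sample x gene, gene g with SD sds[g]
stability_plate <- function(n_samples, sds) {
  genes <- paste0("g", LETTERS[seq_along(sds)])
  cq <- vapply(sds, function(s) rnorm(n_samples, 20, s), numeric(n_samples))
  data.frame(sample = rep(paste0("s", seq_len(n_samples)), times = length(sds)),
             genotype = rep(paste0("s", seq_len(n_samples)), times = length(sds)),
             gene = rep(genes, each = n_samples),
             bio_rep = 1L, tech_rep = 1L, cq = as.vector(cq),
             is_standard = FALSE, log10_quantity = NA_real_,
             stringsAsFactors = FALSE)
}

# dilution standards for one gene on an ideal curve
std_rows <- function(gene, intercept = 20, slope = -3.3219, noise = 0) {
  lq <- -(0:4) * log10(4)
  plate_rows("standard", gene, intercept + slope * lq + rnorm(5, 0, noise),
             std = TRUE, lq = lq)
}

# simulate a minimal two-genotype recovery plate and return estimated ratio
recover_ratio <- function(true_ratio, noise_sd = 0.15, seed = 1) {
  design <- rbind(
    data.frame(genotype = c("hi", "lo"), gene = "target",
               expression = c(true_ratio, 1)),
    data.frame(genotype = c("hi", "lo"), gene = "ref1", expression = 1),
    data.frame(genotype = c("hi", "lo"), gene = "ref2", expression = 1))
  sp <- simulate_qpcr_plate(design, noise_sd = noise_sd, seed = seed)
  rq <- compute_rq(sp$plate, "target", c("ref1", "ref2"))
  rq$rq[rq$genotype == "hi"] / rq$rq[rq$genotype == "lo"]
}
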