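# Discovery of clade-diagnostic SNP positions among labelled paralog sets and
# classification of unknown cds into gene classes (CBCAS / THCAS / CBDAS).
# The THCAS-like synthases are discriminated by a handful of positions fixed
# within each clade and different between clades; classification requires a
# full diagnostic-allele match plus a minimum identity to the clade reference.

#' Create a clade profile
#'
#' @param name Gene-class name (e.g. `"CBCAS"`).
#' @param reference A [seq_record] holding the clade reference cds.
#' @param diagnostic data.frame with columns `pos_nt`, `allele`: positions
#'   (1-based from ATG) whose allele is fixed in this clade and discriminates
#'   it from the others.
#' @param critical_residues Optional data.frame from [critical_residue_set()].
#' @return Object of class `clade_profile`.
#' @export
clade_profile <- function(name, reference, diagnostic, critical_residues = NULL) {
  stopifnot(is_seq_record(reference), is.data.frame(diagnostic),
            all(c("pos_nt", "allele") %in% names(diagnostic)))
  if (anyDuplicated(diagnostic$pos_nt))
    stop("duplicate diagnostic positions", call. = FALSE)
  if (any(diagnostic$pos_nt < 1 | diagnostic$pos_nt > nchar(reference$seq)))
    stop("diagnostic position outside the reference sequence", call. = FALSE)
  diagnostic$allele <- toupper(diagnostic$allele)
  ref_alleles <- substring(reference$seq, diagnostic$pos_nt, diagnostic$pos_nt)
  if (any(ref_alleles != diagnostic$allele))
    stop("reference sequence of '", name,
         "' does not carry its own diagnostic alleles at position(s) ",
         paste(diagnostic$pos_nt[ref_alleles != diagnostic$allele], collapse = ", "),
         call. = FALSE)
  structure(list(name = name, reference = reference,
                 diagnostic = diagnostic[order(diagnostic$pos_nt), , drop = FALSE],
                 critical_residues = critical_residues),
            class = "clade_profile")
}

#' @export
print.clade_profile <- function(x, ...) {
  cat(sprintf("<clade_profile> %s: reference %s, %d diagnostic position(s): %s\n",
              x$name, x$reference$id, nrow(x$diagnostic),
              paste(x$diagnostic$pos_nt, collapse = ", ")))
  invisible(x)
}

#' Discover clade-diagnostic positions between two labelled sequence sets
#'
#' Returns exactly the alignment columns where every clade-A sequence carries
#' one unambiguous allele and every clade-B sequence carries a different
#' unambiguous allele (strict fixation). A column polymorphic within either
#' clade is excluded unless its minor-allele frequency is at most
#' `max_minor_freq` (default 0: no relaxation).
#'
#' @param clade_a,clade_b Lists of equal-length [seq_record] (>= 2 each is
#'   recommended; singleton clades are accepted but every private SNP then
#'   looks "fixed").
#' @param max_minor_freq Tolerated within-clade minor-allele frequency.
#' @return data.frame with columns `pos_nt`, `allele_a`, `allele_b`, sorted by
#'   position.
#' @export
discover_diagnostic_positions <- function(clade_a, clade_b, max_minor_freq = 0) {
  lens <- vapply(c(clade_a, clade_b), function(r) nchar(r$seq), integer(1))
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths; align them first", call. = FALSE)
  ma <- seq_matrix(clade_a)
  mb <- seq_matrix(clade_b)
  fixed_allele <- function(col) {
    tab <- table(col)
    major <- names(tab)[which.max(tab)]
    minor_freq <- 1 - max(tab) / length(col)
    if (minor_freq <= max_minor_freq && major %in% c("A", "C", "G", "T"))
      major else NA_character_
  }
  fa <- apply(ma, 2, fixed_allele)
  fb <- apply(mb, 2, fixed_allele)
  keep <- which(!is.na(fa) & !is.na(fb) & fa != fb)
  data.frame(pos_nt = keep, allele_a = unname(fa[keep]),
             allele_b = unname(fb[keep]), stringsAsFactors = FALSE)
}

#' Classify a sequence into a gene class by diagnostic SNPs
#'
#' A clade is assigned iff all its diagnostic alleles match the query exactly
#' (IUPAC ambiguity in the query counts as non-matching) and the identity to
#' its reference is at least `identity_threshold`. Ties are broken by highest
#' identity, then by profile registration order.
#'
#' @param query A [seq_record] (complete cds, co-linear with the references).
#' @param profiles List of [clade_profile] objects.
#' @param identity_threshold Minimum percent identity to the assigned clade's
#'   reference (default 97: within-clade identities in this family exceed 99
#'   percent while between-clade identities stay below about 96).
#' @return Object of class `clade_call`: list with `query_id`, `assigned`
#'   (clade name or `"unknown"`), `identity_to_each`, `diagnostic_matches`
#'   (fraction per clade), `rationale`.
#' @export
classify_sequence <- function(query, profiles, identity_threshold = 97.0) {
  stopifnot(is_seq_record(query), length(profiles) >= 1L)
  names_ <- vapply(profiles, `[[`, character(1), "name")
  idents <- vapply(profiles, function(p) percent_identity(query, p$reference),
                   numeric(1))
  fracs <- vapply(profiles, function(p) {
    obs <- substring(query$seq, p$diagnostic$pos_nt, p$diagnostic$pos_nt)
    mean(obs == p$diagnostic$allele)
  }, numeric(1))
  names(idents) <- names(fracs) <- names_
  eligible <- which(fracs == 1 & idents >= identity_threshold)
  if (!length(eligible)) {
    assigned <- "unknown"
    rationale <- "no profile with full diagnostic match and identity above threshold"
  } else {
    best <- eligible[order(-idents[eligible], eligible)][1]
    assigned <- names_[best]
    rationale <- sprintf(
      "all %d diagnostic alleles of %s match; identity %.2f%% >= %.2f%%%s",
      nrow(profiles[[best]]$diagnostic), assigned, idents[best],
      identity_threshold,
      if (length(eligible) > 1) " (tie broken by identity, then order)" else "")
  }
  structure(list(query_id = query$id, assigned = assigned,
                 identity_to_each = idents, diagnostic_matches = fracs,
                 rationale = rationale),
            class = "clade_call")
}

#' @export
print.clade_call <- function(x, ...) {
  cat(sprintf("<clade_call> %s -> %s (%s)\n", x$query_id, x$assigned,
              x$rationale))
  invisible(x)
}

#' Tabulate clade calls for a set of records
#'
#' @param records List of [seq_record].
#' @param profiles List of [clade_profile].
#' @param identity_threshold Passed to [classify_sequence()].
#' @return data.frame: `id`, `assigned`, one identity column per clade,
#'   one `diag_` fraction column per clade.
#' @export
classify_all <- function(records, profiles, identity_threshold = 97.0) {
  calls <- lapply(records, classify_sequence, profiles = profiles,
                  identity_threshold = identity_threshold)
  nm <- vapply(profiles, `[[`, character(1), "name")
  out <- data.frame(id = vapply(calls, `[[`, character(1), "query_id"),
                    assigned = vapply(calls, `[[`, character(1), "assigned"),
                    stringsAsFactors = FALSE)
  for (cl in nm) {
    out[[paste0("identity_", cl)]] <-
      vapply(calls, function(x) x$identity_to_each[[cl]], numeric(1))
    out[[paste0("diag_", cl)]] <-
      vapply(calls, function(x) x$diagnostic_matches[[cl]], numeric(1))
  }
  out
}

#' Deduplicate cds and tabulate per-genotype occurrence
#'
#' Mirrors the clone-library bookkeeping of a resequencing survey: clones are
#' deduplicated by exact sequence, and the table reports how many unique cds
#' exist, how often each recurs, and in which genotypes.
#'
#' @param records List of [seq_record] (clones).
#' @param genotype_labels Named character vector mapping record id to
#'   genotype. Records without a label are grouped under `"unknown"`.
#' @return List with `n_unique`, `inventory` (data.frame: `unique_id` =
#'   first-seen record id, `n_clones`, `n_genotypes`, `genotypes`
#'   comma-collapsed), and `per_genotype` (data.frame: `genotype`, `n_clones`,
#'   `n_unique`).
#' @export
unique_cds_inventory <- function(records, genotype_labels = NULL) {
  ids <- vapply(records, `[[`, character(1), "id")
  seqs <- vapply(records, `[[`, character(1), "seq")
  geno <- if (is.null(genotype_labels)) rep("unknown", length(ids))
          else unname(ifelse(ids %in% names(genotype_labels),
                             genotype_labels[ids], "unknown"))
  key <- match(seqs, unique(seqs))
  inv <- do.call(rbind, lapply(seq_along(unique(seqs)), function(k) {
    sel <- key == k
    g <- sort(unique(geno[sel]))
    data.frame(unique_id = ids[which(sel)[1]], n_clones = sum(sel),
               n_genotypes = length(g), genotypes = paste(g, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  per_g <- do.call(rbind, lapply(sort(unique(geno)), function(g) {
    sel <- geno == g
    data.frame(genotype = g, n_clones = sum(sel),
               n_unique = length(unique(key[sel])), stringsAsFactors = FALSE)
  }))
  list(n_unique = length(unique(seqs)), inventory = inv, per_genotype = per_g)
}
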