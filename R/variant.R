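# SNP calling, identity arithmetic, codon mapping and substitution-effect
# classification against a reference cds. Positions are 1-based from the A of
# ATG throughout, matching the usual cds coordinate convention for this gene
# family ("position 13, 18 and 1628 from the starting codon").

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Percent identity between two nucleotide sequences
#'
#' Equal-length sequences are compared positionally (the synthase cds are
#' co-linear, so no alignment is needed); unequal-length sequences are first
#' globally aligned (match +1, mismatch -1, gap -2, end gaps penalized) and
#' identity is matches over alignment columns. Values are rounded half-up to
#' two decimals, the precision at which such identities are conventionally
#' reported.
#'
#' @param a,b [seq_record] objects or nucleotide strings.
#' @return Percentage in \[0, 100\], rounded half-up to 2 decimals. Symmetric.
#' @examples
#' percent_identity("ACGTACGT", "ACGTACGA")  # 87.5
#' @export
percent_identity <- function(a, b) {
  sa <- if (is_seq_record(a)) a$seq else toupper(as.character(a))
  sb <- if (is_seq_record(b)) b$seq else toupper(as.character(b))
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  if (nchar(sa) == nchar(sb)) {
    ca <- strsplit(sa, "")[[1]]
    cb <- strsplit(sb, "")[[1]]
    return(round_half_up(100 * sum(ca == cb) / length(ca)))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sa), Biostrings::DNAString(sb),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  round_half_up(100 * Biostrings::nmatch(aln) / cols)
}

#' Map a cds nucleotide position to its codon (residue) index
#'
#' @param pos_nt 1-based position from the A of ATG.
#' @return Codon index `floor((pos_nt - 1)/3) + 1`.
#' @examples
#' codon_index(1426)  # 476
#' @export
codon_index <- function(pos_nt) {
  if (any(pos_nt < 1)) stop("'pos_nt' must be >= 1", call. = FALSE)
  (as.integer(pos_nt) - 1L) %/% 3L + 1L
}

#' Classify the protein-level effect of a single-nucleotide substitution
#'
#' Mutates the codon containing `snp_pos` in the reference cds, translates the
#' original and mutated codon, and classifies the change as synonymous,
#' missense, or nonsense.
#'
#' @param snp_pos 1-based cds position of the substitution.
#' @param alt Alternative base (A/C/G/T), must differ from the reference base.
#' @param reference_cds Reference coding sequence ([seq_record] or string).
#' @return List with `effect` (`"synonymous"`, `"missense"`, `"nonsense"`),
#'   `codon_index`, `aa_from`, `aa_to`.
#' @export
classify_substitution <- function(snp_pos, alt, reference_cds) {
  seq <- if (is_seq_record(reference_cds)) reference_cds$seq
         else toupper(as.character(reference_cds))
  alt <- toupper(alt)
  if (snp_pos < 1 || snp_pos > nchar(seq))
    stop("'snp_pos' outside the cds", call. = FALSE)
  if (!alt %in% c("A", "C", "G", "T"))
    stop("'alt' must be one of A/C/G/T", call. = FALSE)
  ref_base <- substr(seq, snp_pos, snp_pos)
  if (ref_base == alt)
    stop("'alt' equals the reference base at position ", snp_pos, call. = FALSE)
  ci <- codon_index(snp_pos)
  cstart <- (ci - 1L) * 3L + 1L
  codon <- substr(seq, cstart, cstart + 2L)
  if (grepl("[^ACGT]", codon))
    stop("reference codon ", ci, " is ambiguous", call. = FALSE)
  mutated <- codon
  substr(mutated, snp_pos - cstart + 1L, snp_pos - cstart + 1L) <- alt
  aa_from <- unname(Biostrings::GENETIC_CODE[codon])
  aa_to <- unname(Biostrings::GENETIC_CODE[mutated])
  effect <- if (aa_from == aa_to) "synonymous"
            else if (aa_to == "*") "nonsense"
            else "missense"
  list(effect = effect, codon_index = ci, aa_from = aa_from, aa_to = aa_to)
}

#' Call SNPs of a query cds against a reference cds
#'
#' Equal-length sequences are compared position by position; only unambiguous
#' base-to-base differences are reported as SNPs (sites involving IUPAC
#' ambiguity are counted as mismatches for identity but listed separately).
#' Unequal lengths require `align = TRUE`, in which case a global alignment is
#' built first and indels are reported separately from the SNP list.
#'
#' @param query,reference [seq_record] objects (reference should be a complete
#'   cds so effects can be annotated).
#' @param align Allow alignment of unequal-length sequences.
#' @return Object of class `snp_table`: list with `query_id`, `reference_id`,
#'   `snps` (data.frame: `pos_nt`, `ref_allele`, `alt_allele`, `codon_index`,
#'   `effect`, `aa_from`, `aa_to`), `indels`, `ambiguous_sites`,
#'   `aligned_length_nt`, `identity_pct`.
#' @export
call_snps <- function(query, reference, align = FALSE) {
  stopifnot(is_seq_record(query), is_seq_record(reference))
  if (nchar(query$seq) != nchar(reference$seq) && !align)
    stop("sequences have unequal length (", nchar(query$seq), " vs ",
         nchar(reference$seq), "); set align = TRUE", call. = FALSE)
  if (nchar(query$seq) == nchar(reference$seq)) {
    qc <- strsplit(query$seq, "")[[1]]
    rc <- strsplit(reference$seq, "")[[1]]
    ref_pos <- seq_along(rc)
    indels <- data.frame(ref_pos = integer(0), type = character(0),
                         length = integer(0), stringsAsFactors = FALSE)
    cols <- length(rc)
    gap_cols <- 0L
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query$seq), Biostrings::DNAString(reference$seq),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    qc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    rc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ref_pos <- cumsum(rc != "-")
    cols <- length(rc)
    gap_cols <- sum(qc == "-" | rc == "-")
    gap_runs <- rle(qc == "-" | rc == "-")
    ends <- cumsum(gap_runs$lengths)
    starts <- ends - gap_runs$lengths + 1L
    gi <- which(gap_runs$values)
    indels <- do.call(rbind, lapply(gi, function(k) {
      data.frame(ref_pos = ref_pos[starts[k]],
                 type = if (rc[starts[k]] == "-") "insertion" else "deletion",
                 length = gap_runs$lengths[k], stringsAsFactors = FALSE)
    }))
    if (is.null(indels))
      indels <- data.frame(ref_pos = integer(0), type = character(0),
                           length = integer(0), stringsAsFactors = FALSE)
  }
  diff_i <- which(qc != rc & qc != "-" & rc != "-")
  clean <- diff_i[qc[diff_i] %in% c("A", "C", "G", "T") &
                  rc[diff_i] %in% c("A", "C", "G", "T")]
  ambiguous <- setdiff(diff_i, clean)
  snps <- do.call(rbind, lapply(clean, function(i) {
    eff <- classify_substitution(ref_pos[i], qc[i], reference$seq)
    data.frame(pos_nt = ref_pos[i], ref_allele = rc[i], alt_allele = qc[i],
               codon_index = eff$codon_index, effect = eff$effect,
               aa_from = eff$aa_from, aa_to = eff$aa_to,
               stringsAsFactors = FALSE)
  }))
  if (is.null(snps))
    snps <- data.frame(pos_nt = integer(0), ref_allele = character(0),
                       alt_allele = character(0), codon_index = integer(0),
                       effect = character(0), aa_from = character(0),
                       aa_to = character(0), stringsAsFactors = FALSE)
  snps <- snps[order(snps$pos_nt), , drop = FALSE]
  rownames(snps) <- NULL
  matches <- sum(qc == rc)
  structure(list(
    query_id = query$id, reference_id = reference$id,
    snps = snps, indels = indels,
    ambiguous_sites = ref_pos[ambiguous],
    aligned_length_nt = cols,
    identity_pct = round_half_up(100 * matches / cols)
  ), class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("<snp_table> %s vs %s: %d SNPs, identity %.2f%%\n",
              x$query_id, x$reference_id, nrow(x$snps), x$identity_pct))
  if (nrow(x$snps)) print(x$snps)
  invisible(x)
}

#' Write a set of SNP tables as TSV
#'
#' @param tables List of `snp_table` objects (or a single one).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_tsv <- function(tables, path) {
  if (inherits(tables, "snp_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(t) {
    if (!nrow(t$snps))
      return(NULL)
    cbind(data.frame(query_id = t$query_id, reference_id = t$reference_id,
                     stringsAsFactors = FALSE), t$snps)
  }))
  if (is.null(rows))
    rows <- data.frame(query_id = character(0), reference_id = character(0),
                       pos_nt = integer(0), ref_allele = character(0),
                       alt_allele = character(0), codon_index = integer(0),
                       effect = character(0), aa_from = character(0),
                       aa_to = character(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a critical-residue profile
#'
#' The catalytically required residues of the THCAS/CBCAS protein family span
#' Arg110 to His114 plus Cys176. The profile fixes Arg at 110, His at 114 and
#' Cys at 176; residues 111-113 are taken from the supplied reference protein.
#'
#' @param reference_protein A `protein` object (or amino-acid string) used for
#'   positions without a canonical expectation.
#' @param positions Residue positions to check (default 110:114 and 176).
#' @return data.frame with columns `position`, `expected`.
#' @export
critical_residue_set <- function(reference_protein,
                                 positions = c(110:114, 176L)) {
  aa <- if (inherits(reference_protein, "protein")) reference_protein$aa
        else toupper(as.character(reference_protein))
  if (nchar(aa) < max(positions))
    stop("reference protein shorter than the checked positions", call. = FALSE)
  canonical <- c(`110` = "R", `114` = "H", `176` = "C")
  expected <- vapply(positions, function(p) {
    key <- as.character(p)
    if (key %in% names(canonical)) {
      obs <- substr(aa, p, p)
      if (obs != canonical[[key]])
        warning("reference protein has ", obs, " (not ", canonical[[key]],
                ") at canonical position ", p)
      canonical[[key]]
    } else substr(aa, p, p)
  }, character(1))
  data.frame(position = as.integer(positions), expected = expected,
             stringsAsFactors = FALSE)
}

#' Check a protein against a critical-residue profile
#'
#' @param p A `protein` object (or amino-acid string).
#' @param profile data.frame from [critical_residue_set()].
#' @return List with `residues_checked`, `all_intact` (logical), `deviations`
#'   (data.frame `position`, `expected`, `observed`).
#' @export
check_critical_residues <- function(p, profile) {
  aa <- if (inherits(p, "protein")) p$aa else toupper(as.character(p))
  if (nchar(aa) < max(profile$position))
    stop("protein shorter than the checked positions", call. = FALSE)
  observed <- vapply(profile$position, function(pos) substr(aa, pos, pos),
                     character(1))
  dev <- profile[observed != profile$expected, , drop = FALSE]
  dev$observed <- observed[observed != profile$expected]
  rownames(dev) <- NULL
  list(residues_checked = profile, all_intact = nrow(dev) == 0L,
       deviations = dev)
}

#' Pairwise identity matrix for a set of records
#'
#' @param records List of [seq_record].
#' @return Symmetric numeric matrix of percent identities.
#' @export
identity_matrix <- function(records) {
  ids <- vapply(records, `[[`, character(1), "id")
  n <- length(records)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- percent_identity(records[[i]], records[[j]])
  }
  m
}
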