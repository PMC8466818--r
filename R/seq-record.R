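#' @importFrom stats lm coef sd pt runif rnorm aggregate
#' @importFrom utils write.table read.csv write.csv
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Create a sequence record
#'
#' A `seq_record` is the basic unit handled by the package: an identified
#' nucleotide sequence with an optional description and a role tag saying how
#' it is used downstream (clade reference, query clone, PCR template, or
#' predicted amplicon).
#'
#' @param id Sequence identifier (non-empty string).
#' @param seq Nucleotide sequence over the IUPAC alphabet; case-insensitive,
#'   stored upper-case.
#' @param description Free-text description (defaults to empty).
#' @param role One of `"query"`, `"reference"`, `"template"`, `"amplicon"`.
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `seq` and `role`.
#' @examples
#' seq_record("clone1", "atgGCTtaa")
#' @export
seq_record <- function(id, seq, description = "",
                       role = c("query", "reference", "template", "amplicon")) {
  role <- match.arg(role)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("'id' must be a non-empty string", call. = FALSE)
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a non-empty string", call. = FALSE)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), IUPAC_CHARS)
  if (length(bad))
    stop("sequence for '", id, "' contains non-IUPAC characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(id = id, description = description, seq = seq, role = role),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s] %d nt\n", x$id, x$role, nchar(x$seq)))
  invisible(x)
}

is_seq_record <- function(x) inherits(x, "seq_record")

#' Coerce a named character vector to a list of sequence records
#'
#' @param x Named character vector of sequences.
#' @param role Role assigned to every record.
#' @return List of [seq_record] objects.
#' @export
as_seq_records <- function(x, role = "query") {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("'x' must be a fully named character vector", call. = FALSE)
  lapply(seq_along(x), function(i) seq_record(names(x)[i], x[[i]], role = role))
}

#' Stack equal-length records into a character matrix
#'
#' Rows are sequences, columns alignment positions. Errors if lengths differ:
#' the package treats the synthase cds family as co-linear and does not build
#' multiple alignments itself.
#'
#' @param records List of [seq_record].
#' @return Character matrix with row names set to record ids.
#' @export
seq_matrix <- function(records) {
  stopifnot(length(records) >= 1L)
  lens <- vapply(records, function(r) nchar(r$seq), integer(1))
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths (", paste(unique(lens), collapse = ", "),
         "); align them first", call. = FALSE)
  m <- t(vapply(records, function(r) strsplit(r$seq, "")[[1]],
                character(lens[1])))
  rownames(m) <- vapply(records, `[[`, character(1), "id")
  m
}

#' Read a multi-record FASTA file
#'
#' @param path Path to a FASTA file.
#' @param role Role assigned to the records read.
#' @return List of [seq_record], in file order, sequences upper-cased.
#'   Duplicate ids are accepted with a warning.
#' @export
read_fasta <- function(path, role = "query") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop("FASTA format error in ", path, ": file is empty", call. = FALSE)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("FASTA format error in ", path, ": line ", first,
         " does not start with '>'", call. = FALSE)
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">") && !nzchar(sub("^>\\s*", "", ln)))
      stop("FASTA format error in ", path, ": empty header at line ", i,
           call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set))
    stop("FASTA format error in ", path, ": no records", call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  descs <- ifelse(grepl("\\s", names(set)), sub("^\\S+\\s+", "", names(set)), "")
  if (anyDuplicated(ids))
    warning("duplicate sequence ids in ", path, ": ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(seq_along(set), function(i)
    seq_record(ids[i], as.character(set[[i]]), descs[i], role = role))
}

#' Write sequence records to FASTA
#'
#' @param records List of [seq_record].
#' @param path Output path.
#' @param width Line-wrap width (default 70 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "seq"))
  nm <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, character(1))
  names(seqs) <- nm
  Biostrings::writeXStringSet(seqs, path, width = as.integer(width))
  invisible(path)
}

#' Classify a sequence as complete cds, pseudogene, or fragment
#'
#' A complete cds starts with ATG, ends with an in-frame stop (TAA/TAG/TGA),
#' has length divisible by 3, and carries no internal stop codon. A sequence
#' with start and terminal stop but an internal stop and/or a frameshift
#' length is a pseudogene; one lacking start or terminal stop is a fragment.
#'
#' @param rec A [seq_record] (or nucleotide string).
#' @return An object of class `cds_status`: list with `status` (one of
#'   `"complete"`, `"pseudogene"`, `"fragment"`), `length_nt`, `reason`.
#' @examples
#' validate_cds(seq_record("x", "ATGGCTGGGTAA"))
#' @export
validate_cds <- function(rec) {
  seq <- if (is_seq_record(rec)) rec$seq else toupper(as.character(rec))
  n <- nchar(seq)
  if (n < 6L) stop("sequence shorter than 6 nt", call. = FALSE)
  first3 <- substr(seq, 1L, 3L)
  last3 <- substr(seq, n - 2L, n)
  if (grepl("[^ACGT]", first3) || grepl("[^ACGT]", last3))
    stop("ambiguity codes in the first or last codon; resolve before cds validation",
         call. = FALSE)
  has_start <- first3 == "ATG"
  has_stop <- last3 %in% STOP_CODONS
  mk <- function(status, reason)
    structure(list(status = status, length_nt = n, reason = reason),
              class = "cds_status")
  if (!has_start || !has_stop) {
    return(mk("fragment", paste0(
      if (!has_start) "no ATG start" else "",
      if (!has_start && !has_stop) "; " else "",
      if (!has_stop) "no terminal stop codon" else "")))
  }
  if (n %% 3L != 0L)
    return(mk("pseudogene", sprintf("frameshift-length (%d nt not divisible by 3)", n)))
  codons <- substring(seq, seq(1L, n - 3L, by = 3L), seq(3L, n - 3L, by = 3L))
  internal <- which(codons %in% STOP_CODONS)
  if (length(internal))
    return(mk("pseudogene", sprintf("internal stop at codon %d", internal[1])))
  mk("complete", "")
}

#' @export
print.cds_status <- function(x, ...) {
  cat(sprintf("<cds_status> %s (%d nt)%s\n", x$status, x$length_nt,
              if (nzchar(x$reason)) paste0(": ", x$reason) else ""))
  invisible(x)
}

#' Tabulate cds status for a set of records
#'
#' @param records List of [seq_record].
#' @return data.frame with columns `id`, `status`, `length_nt`, `reason`.
#' @export
cds_status_table <- function(records) {
  rows <- lapply(records, function(r) {
    st <- validate_cds(r)
    data.frame(id = r$id, status = st$status, length_nt = st$length_nt,
               reason = st$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

orfs_one_strand <- function(seq, min_len_nt) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  out <- list()
  for (frame in 0:2) {
    starts_at <- seq(1L + frame, n - 2L, by = 3L)
    if (!length(starts_at)) next
    codons <- paste0(chars[starts_at], chars[starts_at + 1L], chars[starts_at + 2L])
    is_start <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    stop_idx <- which(is_stop)
    for (si in which(is_start)) {
      nxt <- stop_idx[stop_idx > si]
      if (!length(nxt)) next
      s <- starts_at[si]
      e <- starts_at[nxt[1]] + 2L
      if (e - s + 1L >= min_len_nt)
        out[[length(out) + 1L]] <- c(start = s, end = e)
    }
  }
  out
}

#' Find open reading frames on both strands
#'
#' Reports every ATG-to-first-in-frame-stop span of at least `min_len_nt`
#' nucleotides, on both strands. Coordinates are 1-based and end-inclusive on
#' the plus strand of the supplied template; the start column always holds the
#' smaller coordinate, with `strand` giving the reading orientation.
#'
#' @param rec A [seq_record] (or nucleotide string).
#' @param min_len_nt Minimum ORF length in nt; must be >= 6 and divisible by 3.
#' @return data.frame with columns `start`, `end`, `strand` ("+" or "-"),
#'   sorted by start then strand; zero rows when no ORF qualifies.
#' @export
find_orfs <- function(rec, min_len_nt = 300L) {
  if (min_len_nt < 6L || min_len_nt %% 3L != 0L)
    stop("'min_len_nt' must be >= 6 and divisible by 3", call. = FALSE)
  seq <- if (is_seq_record(rec)) rec$seq else toupper(as.character(rec))
  n <- nchar(seq)
  plus <- orfs_one_strand(seq, min_len_nt)
  minus_raw <- orfs_one_strand(revcomp(seq), min_len_nt)
  rows <- c(
    lapply(plus, function(p) data.frame(start = p[["start"]], end = p[["end"]],
                                        strand = "+", stringsAsFactors = FALSE)),
    lapply(minus_raw, function(p) data.frame(start = n - p[["end"]] + 1L,
                                             end = n - p[["start"]] + 1L,
                                             strand = "-", stringsAsFactors = FALSE))
  )
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate a complete coding sequence
#'
#' Standard genetic code; the terminal stop is dropped. Codons containing
#' ambiguity codes translate to `X` with a warning. An internal stop codon is
#' an error carrying the offending codon index.
#'
#' @param cds A [seq_record] or nucleotide string holding a complete cds.
#' @param id Identifier for the resulting protein (defaults to the record id).
#' @return An object of class `protein`: list with `id` and `aa` (one-letter
#'   amino-acid string without the terminal stop).
#' @examples
#' translate_cds("ATGGCTTAA")$aa  # "MA"
#' @export
translate_cds <- function(cds, id = NULL) {
  seq <- if (is_seq_record(cds)) cds$seq else toupper(as.character(cds))
  if (is.null(id)) id <- if (is_seq_record(cds)) cds$id else "cds"
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("cds length not divisible by 3", call. = FALSE)
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- vapply(codons, function(cd) {
    if (grepl("[^ACGT]", cd)) "X" else unname(Biostrings::GENETIC_CODE[cd])
  }, character(1), USE.NAMES = FALSE)
  if (any(aa == "X"))
    warning("ambiguous codon(s) translated to X at position(s) ",
            paste(which(aa == "X"), collapse = ", "))
  internal <- which(aa == "*")
  internal <- internal[internal < length(aa)]
  if (length(internal))
    stop("internal stop at codon ", internal[1], call. = FALSE)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  structure(list(id = id, aa = paste(aa, collapse = "")), class = "protein")
}

#' @export
print.protein <- function(x, ...) {
  cat(sprintf("<protein> %s (%d aa)\n", x$id, nchar(x$aa)))
  invisible(x)
}
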