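# In-silico PCR: primer binding-site search under a mismatch budget with a
# 3'-clamp rule, multiplex product prediction, B-locus marker interpretation,
# and an executable version of the wet-lab primer-specificity screen
# (positive/negative template panels). The mismatch model (<= 2 total
# mismatches, none in the 3'-terminal bases) is the standard in-silico proxy
# for primer extension competence; both knobs are exposed.

# base-compatibility lookup: compat iff the IUPAC expansions intersect
# (built lazily at first use and cached)
compat_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    map <- Biostrings::IUPAC_CODE_MAP[IUPAC_CHARS]
    m <- matrix(FALSE, length(IUPAC_CHARS), length(IUPAC_CHARS),
                dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
    for (a in IUPAC_CHARS) for (b in IUPAC_CHARS) {
      ea <- strsplit(map[[a]], "")[[1]]
      eb <- strsplit(map[[b]], "")[[1]]
      m[a, b] <- length(intersect(ea, eb)) > 0
    }
    cache <<- m
    m
  }
})

#' Create a primer pair
#'
#' @param name Pair name.
#' @param fw Forward primer, 5'->3', plus strand.
#' @param rv Reverse primer, 5'->3' (anneals to the plus strand, i.e. its
#'   reverse complement appears on the plus strand).
#' @param expected_len_bp Expected amplicon length (optional).
#' @param ta_celsius Annealing temperature (optional, reporting only).
#' @param conc_um Usage concentration in micromolar (optional, reporting only).
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, fw, rv, expected_len_bp = NULL,
                        ta_celsius = NULL, conc_um = NULL) {
  fw <- toupper(fw); rv <- toupper(rv)
  if (nchar(fw) < 15L || nchar(rv) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  if (!is.null(expected_len_bp) && expected_len_bp <= nchar(fw) + nchar(rv))
    stop("'expected_len_bp' must exceed the combined primer lengths",
         call. = FALSE)
  structure(list(name = name, fw = fw, rv = rv,
                 expected_len_bp = expected_len_bp,
                 ta_celsius = ta_celsius, conc_um = conc_um),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s: fw %s / rv %s%s\n", x$name, x$fw, x$rv,
              if (!is.null(x$expected_len_bp))
                sprintf(" (expected %d bp)", x$expected_len_bp) else ""))
  invisible(x)
}

# mismatch counts of `pchars` against every offset of `tchars`; returns a
# matrix with one row per offset: total and clamp-window mismatches
scan_offsets <- function(pchars, tchars, clamp_idx) {
  L <- length(pchars)
  noff <- length(tchars) - L + 1L
  if (noff < 1L) return(NULL)
  cm <- compat_matrix()
  mm <- integer(noff)
  cl <- integer(noff)
  for (i in seq_len(L)) {
    ok <- cm[pchars[i], tchars[i:(i + noff - 1L)]]
    mm <- mm + !ok
    if (i %in% clamp_idx) cl <- cl + !ok
  }
  cbind(total = mm, clamp = cl)
}

#' Find primer binding sites on both strands of a template
#'
#' A site qualifies if it has at most `max_mismatch` mismatches in total and
#' none within the `clamp_3prime` bases at the primer's 3' end (a mismatched
#' 3' terminus blocks extension). IUPAC ambiguity codes in the template match
#' any compatible base.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param template A [seq_record] or nucleotide string.
#' @param max_mismatch Mismatch budget outside the clamp (default 2).
#' @param clamp_3prime Number of 3'-terminal bases that must match exactly
#'   (default 3).
#' @return data.frame with columns `strand` ("+" if the primer anneals so its
#'   3' end points right on the plus strand), `start`, `end` (plus-strand
#'   footprint), `pos5` (plus-strand coordinate of the primer's 5' base),
#'   `mismatches`.
#' @export
find_binding_sites <- function(primer, template, max_mismatch = 2L,
                               clamp_3prime = 3L) {
  primer <- toupper(as.character(primer))
  tseq <- if (is_seq_record(template)) template$seq
          else toupper(as.character(template))
  if (nchar(primer) > nchar(tseq))
    stop("primer longer than template", call. = FALSE)
  L <- nchar(primer)
  pchars <- strsplit(primer, "")[[1]]
  tchars <- strsplit(tseq, "")[[1]]
  res <- list()
  # plus strand: primer as-is, 3' end = last clamp bases
  sc <- scan_offsets(pchars, tchars, clamp_idx = (L - clamp_3prime + 1L):L)
  if (!is.null(sc)) {
    hit <- which(sc[, "total"] <= max_mismatch & sc[, "clamp"] == 0L)
    if (length(hit))
      res[[1]] <- data.frame(strand = "+", start = hit, end = hit + L - 1L,
                             pos5 = hit, mismatches = sc[hit, "total"],
                             stringsAsFactors = FALSE)
  }
  # minus strand: the plus-strand footprint matches revcomp(primer); the
  # primer's 3' end maps to the leftmost footprint base
  rc <- strsplit(revcomp(primer), "")[[1]]
  sc <- scan_offsets(rc, tchars, clamp_idx = 1L:clamp_3prime)
  if (!is.null(sc)) {
    hit <- which(sc[, "total"] <= max_mismatch & sc[, "clamp"] == 0L)
    if (length(hit))
      res[[2]] <- data.frame(strand = "-", start = hit, end = hit + L - 1L,
                             pos5 = hit + L - 1L, mismatches = sc[hit, "total"],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(strand = character(0), start = integer(0),
                      end = integer(0), pos5 = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predict PCR products of a primer pair on a set of templates
#'
#' Every combination of a forward-oriented site and a downstream
#' reverse-oriented site on the opposite strand yields a product, measured
#' from 5' end of one primer footprint to 5' end of the other, inclusive
#' (so a product whose primers sit exactly at start and stop of a cds has the
#' cds length). Both template orientations are considered.
#'
#' @param pair A [primer_pair].
#' @param templates List of [seq_record] (a single record is accepted).
#' @param max_len_bp Longest product reported (default 5000).
#' @param max_mismatch,clamp_3prime Passed to [find_binding_sites()].
#' @return data.frame with columns `template_id`, `start`, `end`, `length_bp`,
#'   `fw_mismatches`, `rv_mismatches`.
#' @export
predict_products <- function(pair, templates, max_len_bp = 5000L,
                             max_mismatch = 2L, clamp_3prime = 3L) {
  stopifnot(inherits(pair, "primer_pair"))
  if (is_seq_record(templates)) templates <- list(templates)
  min_len <- nchar(pair$fw) + nchar(pair$rv)
  rows <- lapply(templates, function(tmpl) {
    fw_sites <- find_binding_sites(pair$fw, tmpl, max_mismatch, clamp_3prime)
    rv_sites <- find_binding_sites(pair$rv, tmpl, max_mismatch, clamp_3prime)
    combos <- rbind(
      merge(fw_sites[fw_sites$strand == "+", ],
            rv_sites[rv_sites$strand == "-", ],
            by = NULL, suffixes = c("_f", "_r")),
      merge(rv_sites[rv_sites$strand == "+", ],
            fw_sites[fw_sites$strand == "-", ],
            by = NULL, suffixes = c("_f", "_r"))
    )
    if (!nrow(combos)) return(NULL)
    combos$length_bp <- combos$pos5_r - combos$pos5_f + 1L
    combos <- combos[combos$length_bp >= min_len &
                     combos$length_bp <= max_len_bp, , drop = FALSE]
    if (!nrow(combos)) return(NULL)
    data.frame(template_id = tmpl$id, start = combos$pos5_f,
               end = combos$pos5_r, length_bp = combos$length_bp,
               fw_mismatches = combos$mismatches_f,
               rv_mismatches = combos$mismatches_r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length_bp = integer(0),
                      fw_mismatches = integer(0), rv_mismatches = integer(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$template_id, out$start, out$length_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interpret a B-locus multiplex band pattern
#'
#' The three-primer B1080/B1192 marker produces a band of about 1080/1081 bp
#' in the presence of a functional CBDAS and about 1192 bp in the presence of
#' a functional THCAS. A THCAS-only pattern indicates a chemotype-I plant, a
#' two-band pattern chemotype II, and a CBDAS-only pattern the CBDA-dominant
#' classes (III, IV and V are indistinguishable at this marker).
#'
#' @param bands Integer vector of observed band lengths (may be empty).
#' @param tol Band-size tolerance in bp (default 5; the CBDAS band is reported
#'   as both 1080 and 1081 in practice and is treated as one class).
#' @return Object of class `marker_call`: list with `bands`, `b_locus` (one of
#'   `"BD/BD"`, `"BT/BT"`, `"BT/BD"`, `"no-call"`), `chemotype_class` (one of
#'   `"I"`, `"II"`, `"III-IV-V"`, `"undetermined"`), `reason`.
#' @export
interpret_b_locus <- function(bands, tol = 5L) {
  bands <- sort(unique(as.integer(bands)))
  near <- function(b, target) abs(b - target) <= tol
  is_d <- vapply(bands, near, logical(1), target = 1080L) |
          vapply(bands, near, logical(1), target = 1081L)
  is_t <- vapply(bands, near, logical(1), target = 1192L)
  mk <- function(b_locus, chem, reason = "")
    structure(list(bands = bands, b_locus = b_locus, chemotype_class = chem,
                   reason = reason), class = "marker_call")
  if (length(bands) && any(!is_d & !is_t))
    return(mk("no-call", "undetermined",
              paste0("band(s) ", paste(bands[!is_d & !is_t], collapse = ", "),
                     " match neither 1080/1081 nor 1192 within ", tol, " bp")))
  has_d <- any(is_d); has_t <- any(is_t)
  if (has_d && has_t) return(mk("BT/BD", "II"))
  if (has_t) return(mk("BT/BT", "I"))
  if (has_d) return(mk("BD/BD", "III-IV-V"))
  mk("no-call", "undetermined", "no band")
}

#' @export
print.marker_call <- function(x, ...) {
  cat(sprintf("<marker_call> bands {%s} -> %s, chemotype %s%s\n",
              paste(x$bands, collapse = ", "), x$b_locus, x$chemotype_class,
              if (nzchar(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Run a three-primer multiplex marker on a template set and call the B locus
#'
#' @param templates List of [seq_record] (e.g. the two haplotype templates of
#'   one genotype).
#' @param fw Shared forward primer.
#' @param rv_d Reverse primer yielding the CBDAS-associated (~1080 bp) band.
#' @param rv_t Reverse primer yielding the THCAS-associated (~1192 bp) band.
#' @param tol,max_mismatch,clamp_3prime,max_len_bp Tuning knobs, see
#'   [interpret_b_locus()] and [find_binding_sites()].
#' @return A `marker_call`.
#' @export
call_b_marker <- function(templates, fw, rv_d, rv_t, tol = 5L,
                          max_mismatch = 2L, clamp_3prime = 3L,
                          max_len_bp = 5000L) {
  if (is_seq_record(templates)) templates <- list(templates)
  bands <- integer(0)
  for (rv in c(rv_d, rv_t)) {
    pp <- primer_pair("marker", fw, rv)
    prod <- predict_products(pp, templates, max_len_bp = max_len_bp,
                             max_mismatch = max_mismatch,
                             clamp_3prime = clamp_3prime)
    bands <- c(bands, prod$length_bp)
  }
  interpret_b_locus(bands, tol = tol)
}

#' Validate primer-pair specificity on positive and negative template panels
#'
#' Executable analogue of a wet-lab specificity screen: the pair passes iff it
#' predicts at least one product on every positive template and none on any
#' negative template under the configured mismatch model. Melting behaviour is
#' summarized as a report-only note on the estimated Tm of both primers.
#'
#' @param pair A [primer_pair].
#' @param positive_templates,negative_templates Lists of [seq_record].
#' @param max_mismatch,clamp_3prime,max_len_bp See [predict_products()].
#' @return List with `pass` (logical), `per_template` (data.frame:
#'   `template_id`, `panel`, `n_products`, `lengths`), `failures` (character),
#'   `tm_note`.
#' @export
validate_primer_specificity <- function(pair, positive_templates,
                                        negative_templates,
                                        max_mismatch = 2L, clamp_3prime = 3L,
                                        max_len_bp = 5000L) {
  stopifnot(length(positive_templates) >= 1L, length(negative_templates) >= 1L)
  audit <- function(tmpls, panel) {
    do.call(rbind, lapply(tmpls, function(tmpl) {
      prod <- predict_products(pair, list(tmpl), max_len_bp, max_mismatch,
                               clamp_3prime)
      data.frame(template_id = tmpl$id, panel = panel,
                 n_products = nrow(prod),
                 lengths = paste(prod$length_bp, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  tab <- rbind(audit(positive_templates, "positive"),
               audit(negative_templates, "negative"))
  fail_pos <- tab$template_id[tab$panel == "positive" & tab$n_products == 0L]
  fail_neg <- tab$template_id[tab$panel == "negative" & tab$n_products > 0L]
  failures <- c(
    if (length(fail_pos)) paste0("no product on positive template ", fail_pos),
    if (length(fail_neg)) paste0("product on negative template ", fail_neg))
  tms <- c(fw = primer_tm(pair$fw), rv = primer_tm(pair$rv))
  list(pass = length(failures) == 0L, per_template = tab,
       failures = if (length(failures)) failures else character(0),
       tm_note = sprintf("estimated Tm fw %.1f C / rv %.1f C (reporting only)",
                         tms[["fw"]], tms[["rv"]]))
}

#' Rough primer melting temperature (reporting only)
#'
#' Wallace rule `2(A+T) + 4(G+C)` below 14 nt, otherwise
#' `64.9 + 41 (GC - 16.4)/N`. Not a thermodynamic model; never used as a
#' filter anywhere in the package.
#'
#' @param primer Primer sequence.
#' @return Estimated Tm in degrees Celsius.
#' @export
primer_tm <- function(primer) {
  p <- strsplit(toupper(primer), "")[[1]]
  n <- length(p)
  gc <- sum(p %in% c("G", "C"))
  at <- sum(p %in% c("A", "T"))
  if (n < 14L) 2 * at + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
}
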