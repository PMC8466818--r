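# RT-qPCR relative quantification by the standard-curve method: dilution-series
# curve fitting with amplification efficiency E = 10^(-1/slope) - 1,
# interpolation of unknowns, reference-gene stability ranking (geNorm-style M
# plus comparative delta-Ct SD, combined by geometric mean of ranks),
# normalization to the geometric mean of the reference-gene quantities, and
# genotype-vs-baseline significance by Student's t-test on log-transformed RQ.

PLATE_COLS <- c("sample", "genotype", "gene", "bio_rep", "tech_rep", "cq",
                "is_standard", "log10_quantity")

#' Read a long-format qPCR plate CSV
#'
#' Expected columns: `sample`, `genotype`, `gene`, `bio_rep`, `tech_rep`,
#' `cq` (empty/NA = undetermined), `is_standard` (logical), `log10_quantity`
#' (set for standards only).
#'
#' @param path CSV path.
#' @return Validated plate data.frame.
#' @export
read_qpcr_plate <- function(path) {
  plate <- read.csv(path, stringsAsFactors = FALSE)
  validate_plate(plate)
}

#' Validate a qPCR plate data.frame
#'
#' @param plate data.frame in the long plate layout (see [read_qpcr_plate()]).
#' @return The plate, with types normalized.
#' @export
validate_plate <- function(plate) {
  missing_cols <- setdiff(PLATE_COLS, names(plate))
  if (length(missing_cols))
    stop("plate is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  plate$cq <- suppressWarnings(as.numeric(plate$cq))
  plate$is_standard <- as.logical(plate$is_standard)
  plate$log10_quantity <- suppressWarnings(as.numeric(plate$log10_quantity))
  if (any(plate$is_standard & is.na(plate$log10_quantity)))
    stop("standard wells must carry 'log10_quantity'", call. = FALSE)
  plate
}

#' Write a plate to CSV
#'
#' @param plate Plate data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qpcr_plate <- function(plate, path) {
  write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

geomean <- function(x) exp(mean(log(x)))

#' Fit a standard curve (Cq vs log10 quantity)
#'
#' Ordinary least squares of Cq on log10 input quantity over a dilution
#' series. The amplification efficiency is `E = 10^(-1/slope) - 1`; a
#' perfectly doubling assay has slope about -3.3219 and E = 1.
#'
#' @param log10_quantity Numeric vector (or a 2-column data.frame/matrix of
#'   `log10_quantity`, `cq`).
#' @param cq Numeric vector of quantification cycles.
#' @param gene Optional gene name carried in the result.
#' @return Object of class `standard_curve`: `gene`, `slope`, `intercept`,
#'   `r_squared`, `efficiency`, `n_points`.
#' @examples
#' fit_standard_curve(0:-4, 30 + 3.3219 * (0:4))
#' @export
fit_standard_curve <- function(log10_quantity, cq = NULL, gene = NA_character_) {
  if (is.null(cq)) {
    stopifnot(ncol(log10_quantity) >= 2)
    cq <- log10_quantity[[2]]
    log10_quantity <- log10_quantity[[1]]
  }
  ok <- is.finite(log10_quantity) & is.finite(cq)
  log10_quantity <- log10_quantity[ok]; cq <- cq[ok]
  if (length(cq) < 3L) stop("need at least 3 standard points", call. = FALSE)
  if (length(unique(log10_quantity)) < 2L)
    stop("standard quantities are all equal; cannot fit a curve", call. = FALSE)
  fit <- lm(cq ~ log10_quantity)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= 0)
    warning("standard-curve slope is non-negative; Cq should decrease with input")
  # R2 computed directly (summary.lm warns on exactly collinear points)
  tss <- sum((cq - mean(cq))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  structure(list(gene = gene, slope = slope, intercept = intercept,
                 r_squared = r2,
                 efficiency = efficiency_from_slope(slope),
                 n_points = length(cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s: slope %.4f, intercept %.3f, R2 %.4f, E %.3f (n=%d)\n",
    if (is.na(x$gene)) "(unnamed)" else x$gene, x$slope, x$intercept,
    x$r_squared, x$efficiency, x$n_points))
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' @param slope Slope of Cq on log10 quantity (negative for a valid assay).
#' @return `10^(-1/slope) - 1`.
#' @export
efficiency_from_slope <- function(slope) 10^(-1 / slope) - 1

#' Fit standard curves for every gene on a plate
#'
#' @param plate Validated plate data.frame.
#' @param genes Genes to fit (default: all genes having standard wells).
#' @return Named list of `standard_curve` objects.
#' @export
curves_from_plate <- function(plate, genes = NULL) {
  std <- plate[plate$is_standard & !is.na(plate$cq), , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(std$gene))
  missing_g <- setdiff(genes, unique(std$gene))
  if (length(missing_g))
    stop("no standard wells for gene(s): ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  out <- lapply(genes, function(g) {
    s <- std[std$gene == g, ]
    fit_standard_curve(s$log10_quantity, s$cq, gene = g)
  })
  names(out) <- genes
  out
}

#' Interpolate input quantity from a Cq value
#'
#' @param cq Quantification cycle (NA propagates as NA: undetermined).
#' @param curve A `standard_curve`.
#' @return Quantity in the arbitrary units of the dilution series,
#'   `10^((cq - intercept)/slope)`.
#' @export
interpolate_quantity <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

# tech-replicate-averaged Cq per genotype x gene x biological replicate;
# wells with all-NA Cq average to NA (undetermined)
mean_cq_by_bio <- function(plate) {
  unk <- plate[!plate$is_standard, , drop = FALSE]
  agg <- aggregate(cq ~ genotype + gene + bio_rep, data = unk,
                   FUN = function(x) mean(x, na.rm = TRUE),
                   na.action = stats::na.pass)
  agg$cq[is.nan(agg$cq)] <- NA_real_
  agg
}

#' Rank candidate reference genes by expression stability
#'
#' A documented stand-in for multi-tool consensus rankers: computes (a) a
#' geNorm-style M value (mean SD, across samples, of pairwise log2 expression
#' ratios with every other candidate) and (b) a comparative delta-Ct SD (SD
#' across samples of the gene's Cq minus the mean Cq of the other
#' candidates), then ranks by the geometric mean of the two ranks. Lower is
#' more stable. Ties break by delta-Ct SD, then by gene name.
#'
#' @param plate Validated plate data.frame (unknown wells are used).
#' @param candidate_genes Character vector of >= 2 candidates.
#' @param min_coverage Candidates with Cq in fewer than this fraction of
#'   samples are excluded with a warning (default 0.5).
#' @return data.frame sorted by rank: `gene`, `m_value`, `dct_sd`, `rank`.
#' @export
rank_reference_stability <- function(plate, candidate_genes,
                                     min_coverage = 0.5) {
  if (length(candidate_genes) < 2L)
    stop("need at least 2 candidate genes", call. = FALSE)
  cqs <- mean_cq_by_bio(plate)
  cqs <- cqs[cqs$gene %in% candidate_genes, , drop = FALSE]
  wide <- stats::reshape(cqs, idvar = c("genotype", "bio_rep"),
                         timevar = "gene", direction = "wide")
  mat <- as.matrix(wide[, paste0("cq.", candidate_genes), drop = FALSE])
  colnames(mat) <- candidate_genes
  coverage <- colMeans(!is.na(mat))
  drop_g <- candidate_genes[coverage < min_coverage]
  if (length(drop_g)) {
    warning("excluding gene(s) detected in under ",
            round(100 * min_coverage), "% of samples: ",
            paste(drop_g, collapse = ", "))
    candidate_genes <- setdiff(candidate_genes, drop_g)
    mat <- mat[, candidate_genes, drop = FALSE]
    if (length(candidate_genes) < 2L)
      stop("fewer than 2 candidates remain after coverage filtering",
           call. = FALSE)
  }
  if (nrow(mat) < 3L) stop("need at least 3 samples", call. = FALSE)
  # expression on the log2 scale is -Cq (ideal doubling); ratio SDs are
  # therefore SDs of Cq differences
  m_value <- vapply(candidate_genes, function(g) {
    others <- setdiff(candidate_genes, g)
    mean(vapply(others, function(h)
      sd(mat[, g] - mat[, h], na.rm = TRUE), numeric(1)))
  }, numeric(1))
  dct_sd <- vapply(candidate_genes, function(g) {
    others <- setdiff(candidate_genes, g)
    sd(mat[, g] - rowMeans(mat[, others, drop = FALSE], na.rm = TRUE),
       na.rm = TRUE)
  }, numeric(1))
  r1 <- rank(m_value, ties.method = "average")
  r2 <- rank(dct_sd, ties.method = "average")
  score <- sqrt(r1 * r2)
  ord <- order(score, dct_sd, candidate_genes)
  out <- data.frame(gene = candidate_genes, m_value = m_value,
                    dct_sd = dct_sd, score = score,
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Relative quantification of a target gene
#'
#' Technical replicates are averaged on the Cq scale, quantities are
#' interpolated on each gene's standard curve, and per biological replicate
#' the target quantity is divided by the geometric mean of the reference-gene
#' quantities. Per genotype the RQ is the mean over biological replicates
#' with SEM = SD/sqrt(n). A genotype whose target Cq is undetermined in every
#' replicate is reported `detected = FALSE`; a replicate with an undetermined
#' reference is dropped with a warning.
#'
#' @param plate Validated plate data.frame.
#' @param target_gene Target gene name.
#' @param reference_genes Character vector of reference genes (>= 1).
#' @param curves Named list of `standard_curve` for target and references
#'   (default: fitted from the plate's standard wells).
#' @return Object of class `rq_table`: data.frame `genotype`, `gene`, `rq`,
#'   `sem`, `n`, `detected`; per-replicate RQs kept in
#'   `attr(, "replicates")` for downstream testing.
#' @export
compute_rq <- function(plate, target_gene, reference_genes, curves = NULL) {
  stopifnot(length(reference_genes) >= 1L)
  genes <- c(target_gene, reference_genes)
  if (is.null(curves)) curves <- curves_from_plate(plate, genes)
  missing_c <- setdiff(genes, names(curves))
  if (length(missing_c))
    stop("missing standard curve for: ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  cqs <- mean_cq_by_bio(plate)
  cqs <- cqs[cqs$gene %in% genes, , drop = FALSE]
  cqs$quantity <- NA_real_
  for (g in genes) {
    sel <- cqs$gene == g
    cqs$quantity[sel] <- interpolate_quantity(cqs$cq[sel], curves[[g]])
  }
  genotypes <- unique(cqs$genotype)
  reps <- list(); rows <- list()
  for (gt in genotypes) {
    sub <- cqs[cqs$genotype == gt, ]
    bio <- sort(unique(sub$bio_rep))
    rq_rep <- c()
    dropped <- 0L
    target_seen <- FALSE
    for (b in bio) {
      qt <- sub$quantity[sub$gene == target_gene & sub$bio_rep == b]
      qr <- vapply(reference_genes, function(g) {
        v <- sub$quantity[sub$gene == g & sub$bio_rep == b]
        if (length(v)) v[1] else NA_real_
      }, numeric(1))
      if (any(is.na(qr))) { dropped <- dropped + 1L; next }
      if (length(qt) && is.finite(qt[1])) {
        target_seen <- TRUE
        rq_rep <- c(rq_rep, qt[1] / geomean(qr))
      }
    }
    if (dropped)
      warning("genotype ", gt, ": ", dropped,
              " replicate(s) dropped (undetermined reference gene)")
    detected <- target_seen && length(rq_rep) > 0
    rows[[gt]] <- data.frame(
      genotype = gt, gene = target_gene,
      rq = if (detected) mean(rq_rep) else NA_real_,
      sem = if (detected && length(rq_rep) > 1)
              sd(rq_rep) / sqrt(length(rq_rep)) else NA_real_,
      n = length(rq_rep), detected = detected, stringsAsFactors = FALSE)
    if (detected)
      reps[[gt]] <- data.frame(genotype = gt, bio_rep = seq_along(rq_rep),
                               rq = rq_rep, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("rq_table", "data.frame"),
            replicates = do.call(rbind, reps))
}

#' Compare genotype RQs against a baseline genotype
#'
#' Two-sided Student's t-test (pooled variance) on natural-log-transformed
#' per-replicate RQ values of each genotype against the baseline. Stars
#' follow the conventional thresholds: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `ns` otherwise. Undetected genotypes are reported without a
#' test (`n.d.`).
#'
#' @param rq An `rq_table` from [compute_rq()].
#' @param baseline_genotype Genotype used as the comparison baseline.
#' @return The `rq_table` with added columns `p_vs_baseline`, `stars`.
#' @export
compare_to_baseline <- function(rq, baseline_genotype) {
  stopifnot(inherits(rq, "rq_table"))
  reps <- attr(rq, "replicates")
  if (is.null(reps) || !baseline_genotype %in% reps$genotype)
    stop("baseline genotype '", baseline_genotype,
         "' absent or undetected", call. = FALSE)
  base <- reps$rq[reps$genotype == baseline_genotype]
  if (sum(base > 0) < 2L)
    stop("baseline needs at least 2 positive replicates", call. = FALSE)
  if (any(base <= 0)) {
    warning("baseline replicate(s) with non-positive RQ dropped before log transform")
    base <- base[base > 0]
  }
  lbase <- log(base)
  rq$p_vs_baseline <- NA_real_
  rq$stars <- NA_character_
  for (i in seq_len(nrow(rq))) {
    gt <- rq$genotype[i]
    if (!rq$detected[i]) next
    if (gt == baseline_genotype) {
      rq$p_vs_baseline[i] <- 1; rq$stars[i] <- "ns"; next
    }
    x <- reps$rq[reps$genotype == gt]
    if (any(x <= 0)) {
      warning("genotype ", gt,
              ": non-positive RQ replicate(s) dropped before log transform")
      x <- x[x > 0]
    }
    if (length(x) < 2L) next
    p <- pooled_t_test(log(x), lbase)
    rq$p_vs_baseline[i] <- p
    rq$stars[i] <- stars_for_p(p)
  }
  rq
}

# two-sided pooled-variance two-sample t-test p-value
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), df)
}

stars_for_p <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Format an RQ table for reporting
#'
#' @param rq An `rq_table` (possibly with baseline comparison columns).
#' @return data.frame where undetected entries show `"n.d."`.
#' @export
format_rq <- function(rq) {
  out <- as.data.frame(rq)
  out$rq <- ifelse(out$detected, formatC(out$rq, format = "g", digits = 4), "n.d.")
  out
}
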