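# Seeded generators emulating the study system: a synthase-like gene family
# with clade-fixed diagnostic substitutions, per-sequence private SNPs and
# optional pseudogenes with internal stops; qPCR plates with dilution-series
# standards and Cq values drawn from per-genotype expression levels under the
# exponential-phase idealization Cq = intercept - log10(q)/log10(1+E).
# Every generator returns its ground truth so downstream calls can be scored.

BASES <- c("A", "C", "G", "T")

#' Specification of one clade in a simulated gene family
#'
#' @param name Clade name.
#' @param n_sequences Number of sequences to draw for this clade.
#' @param diagnostic data.frame `pos_nt`, `allele`: clade-fixed alleles.
#' @param private_snps_range Length-2 integer range; each sequence gets
#'   `k ~ Uniform(min, max)` private substitutions (default 3 to 8, the
#'   observed per-clone range in resequenced synthase families).
#' @return List of class `clade_spec`.
#' @export
clade_spec <- function(name, n_sequences, diagnostic,
                       private_snps_range = c(3L, 8L)) {
  stopifnot(is.data.frame(diagnostic),
            all(c("pos_nt", "allele") %in% names(diagnostic)),
            length(private_snps_range) == 2L,
            private_snps_range[1] <= private_snps_range[2])
  diagnostic$allele <- toupper(diagnostic$allele)
  structure(list(name = name, n_sequences = as.integer(n_sequences),
                 diagnostic = diagnostic,
                 private_snps_range = as.integer(private_snps_range)),
            class = "clade_spec")
}

default_clades <- function(n_per_clade = 10L) {
  list(
    clade_spec("CBCAS", n_per_clade,
               data.frame(pos_nt = c(13L, 18L, 1628L),
                          allele = c("T", "G", "A"))),
    clade_spec("THCAS", n_per_clade,
               data.frame(pos_nt = c(13L, 18L, 1628L),
                          allele = c("G", "C", "G")))
  )
}

#' Configuration for a simulated synthase gene family
#'
#' Defaults mirror the structure of the real family: a 1638-nt cds (545
#' codons plus stop), two clades fixed apart at positions 13, 18 and 1628
#' from the starting codon, 3 to 8 private SNPs per sequence, and protected
#' codons covering the catalytic residues 110-114 and 176 (which the
#' generator sets to the canonical Arg110...His114 / Cys176).
#'
#' @param ancestor_length_nt Total cds length, divisible by 3 (default 1638).
#' @param clades List of [clade_spec] (default: two 10-sequence clades named
#'   CBCAS and THCAS, fixed apart at 13/18/1628).
#' @param pseudogene_fraction Fraction of sequences given one internal stop.
#' @param protected_codons Codon indices never touched by private SNPs.
#' @param seed Integer seed.
#' @return List of class `family_config`.
#' @export
family_config <- function(ancestor_length_nt = 1638L,
                          clades = default_clades(),
                          pseudogene_fraction = 0,
                          protected_codons = c(110:114, 176L),
                          seed = 1L) {
  if (ancestor_length_nt %% 3L != 0L || ancestor_length_nt < 30L)
    stop("'ancestor_length_nt' must be divisible by 3 and at least 30",
         call. = FALSE)
  all_pos <- unlist(lapply(clades, function(cl) cl$diagnostic$pos_nt))
  if (any(all_pos > ancestor_length_nt - 3L) || any(all_pos <= 3L))
    stop("diagnostic position outside the mutable cds body", call. = FALSE)
  if (pseudogene_fraction < 0 || pseudogene_fraction > 1)
    stop("'pseudogene_fraction' must be in [0, 1]", call. = FALSE)
  structure(list(ancestor_length_nt = as.integer(ancestor_length_nt),
                 clades = clades,
                 pseudogene_fraction = pseudogene_fraction,
                 protected_codons = as.integer(protected_codons),
                 seed = as.integer(seed)),
            class = "family_config")
}

random_codon <- function() {
  repeat {
    cd <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
    if (!cd %in% STOP_CODONS) return(cd)
  }
}

# resample the non-fixed bases of a codon until every candidate allele at the
# fixed within-codon offset yields a non-stop codon
safe_codon_for <- function(offset_in_codon, alleles) {
  for (attempt in 1:200) {
    cd <- sample(BASES, 3L, replace = TRUE)
    ok <- all(vapply(alleles, function(a) {
      cd2 <- cd; cd2[offset_in_codon] <- a
      !paste(cd2, collapse = "") %in% STOP_CODONS
    }, logical(1)))
    if (ok) return(cd)
  }
  stop("could not place diagnostic alleles without creating a stop codon",
       call. = FALSE)
}

#' Simulate a gene family with clade-diagnostic and private SNPs
#'
#' Draws a random ancestor cds (ATG start, in-frame terminal stop, no internal
#' stop, canonical critical residues), derives each clade reference by applying
#' its diagnostic alleles, then derives each sequence by adding private
#' substitutions that avoid diagnostic positions, protected codons, the start
#' and stop codons, and never create an in-frame stop. A configured fraction
#' of sequences is designated pseudogene and receives one internal stop codon.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [family_config].
#' @return List with `records` (list of [seq_record]; clade references first
#'   as `<clade>_ref`, then clones `<clade>_<i>`), `truth` (data.frame: `id`,
#'   `clade`, `n_private`, `private_positions`, `is_pseudogene`, `status`),
#'   `diagnostics` (per-clade data.frame of `pos_nt`, `allele`),
#'   `references` (named list of clade reference [seq_record]), `ancestor`.
#' @export
simulate_gene_family <- function(cfg = family_config()) {
  stopifnot(inherits(cfg, "family_config"))
  set.seed(cfg$seed)
  len <- cfg$ancestor_length_nt
  n_codons <- len %/% 3L
  codons <- vapply(seq_len(n_codons - 1L), function(i) random_codon(),
                   character(1))
  codons[1] <- "ATG"
  canonical <- c(`110` = "CGT", `114` = "CAT", `176` = "TGT")
  for (k in names(canonical))
    if (as.integer(k) <= n_codons - 1L) codons[as.integer(k)] <- canonical[[k]]
  terminal <- sample(STOP_CODONS, 1L)

  # diagnostic positions: make the containing codons safe for every allele any
  # clade (or the ancestor) may carry there
  diag_pos <- sort(unique(unlist(lapply(cfg$clades,
                                        function(cl) cl$diagnostic$pos_nt))))
  anc <- strsplit(paste(c(codons, terminal), collapse = ""), "")[[1]]
  for (pos in diag_pos) {
    ci <- codon_index(pos)
    off <- pos - (ci - 1L) * 3L
    alleles <- unique(unlist(lapply(cfg$clades, function(cl) {
      cl$diagnostic$allele[cl$diagnostic$pos_nt == pos]
    })))
    # ancestor allele must differ from every clade allele so that a clade not
    # listing the position is still fixed apart from one that does
    anc_allele <- sample(setdiff(BASES, alleles), 1L)
    cd <- safe_codon_for(off, c(alleles, anc_allele))
    cd[off] <- anc_allele
    anc[(ci - 1L) * 3L + 1:3] <- cd
  }
  ancestor <- paste(anc, collapse = "")

  # forbidden zone for private SNPs
  protected_nt <- unlist(lapply(cfg$protected_codons,
                                function(ci) (ci - 1L) * 3L + 1:3))
  forbidden <- unique(c(1:3, (len - 2L):len, diag_pos, protected_nt))
  allowed <- setdiff(seq_len(len), forbidden)

  mutate_no_stop <- function(chars, pos, alt = NULL) {
    ci <- codon_index(pos)
    off <- pos - (ci - 1L) * 3L
    cands <- if (is.null(alt)) sample(setdiff(BASES, chars[pos])) else alt
    for (a in cands) {
      cd <- chars[(ci - 1L) * 3L + 1:3]
      cd[off] <- a
      if (!paste(cd, collapse = "") %in% STOP_CODONS) {
        chars[pos] <- a
        return(list(chars = chars, alt = a))
      }
    }
    NULL
  }

  records <- list(); truth_rows <- list()
  references <- list(); diagnostics <- list()
  for (cl in cfg$clades) {
    ref_chars <- strsplit(ancestor, "")[[1]]
    for (r in seq_len(nrow(cl$diagnostic)))
      ref_chars[cl$diagnostic$pos_nt[r]] <- cl$diagnostic$allele[r]
    ref_seq <- paste(ref_chars, collapse = "")
    ref_rec <- seq_record(paste0(cl$name, "_ref"), ref_seq, role = "reference")
    references[[cl$name]] <- ref_rec
    diagnostics[[cl$name]] <- cl$diagnostic
    records[[length(records) + 1L]] <- ref_rec
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      id = ref_rec$id, clade = cl$name, n_private = 0L,
      private_positions = "", private_alleles = "",
      is_pseudogene = FALSE, status = "complete",
      stringsAsFactors = FALSE)
    for (i in seq_len(cl$n_sequences)) {
      k <- sample(cl$private_snps_range[1]:cl$private_snps_range[2], 1L)
      chars <- ref_chars
      placed <- integer(0)
      alts <- character(0)
      pool <- sample(allowed)
      for (pos in pool) {
        if (length(placed) == k) break
        res <- mutate_no_stop(chars, pos)
        if (!is.null(res)) {
          chars <- res$chars
          placed <- c(placed, pos)
          alts <- c(alts, res$alt)
        }
      }
      ord <- order(placed)
      id <- sprintf("%s_%02d", cl$name, i)
      records[[length(records) + 1L]] <-
        seq_record(id, paste(chars, collapse = ""), role = "query")
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = id, clade = cl$name, n_private = length(placed),
        private_positions = paste(placed[ord], collapse = ","),
        private_alleles = paste(alts[ord], collapse = ","),
        is_pseudogene = FALSE, status = "complete", stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth_rows)

  # designate pseudogenes among the clones (never the clade references)
  clone_idx <- which(!grepl("_ref$", truth$id))
  n_pseudo <- round(cfg$pseudogene_fraction * length(clone_idx))
  if (n_pseudo > 0L) {
    pick <- sample(clone_idx, n_pseudo)
    stop_ok_codons <- setdiff(2:(n_codons - 1L),
                              c(cfg$protected_codons,
                                unique(codon_index(diag_pos))))
    for (i in pick) {
      chars <- strsplit(records[[i]]$seq, "")[[1]]
      ci <- sample(stop_ok_codons, 1L)
      chars[(ci - 1L) * 3L + 1:3] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
      records[[i]] <- seq_record(records[[i]]$id, paste(chars, collapse = ""),
                                 role = records[[i]]$role)
      truth$is_pseudogene[i] <- TRUE
      truth$status[i] <- "pseudogene"
    }
  }
  list(records = records, truth = truth, diagnostics = diagnostics,
       references = references, ancestor = ancestor)
}

#' Default RT-qPCR plate design emulating the study panel
#'
#' Thirteen genotypes by three target genes plus two reference genes. Where
#' the published figure prints an RQ, that value is used as the true
#' expression level (17.80 and 1.32 for THCAS in the two medical genotypes,
#' 4.90 and 0.02 for the CBDAS extremes, 0.05/0.06 for CBCAS in the medical
#' genotypes); unprinted hemp levels are fixed plausible values inside the
#' printed 0.28-1.81 CBDAS range and a low CBCAS band. `NA` marks true
#' absence (THCAS in hemp, CBDAS in the THCA-predominant genotype), which the
#' simulator converts to undetermined Cq.
#'
#' @return data.frame `genotype`, `gene`, `expression`.
#' @export
default_qpcr_design <- function() {
  g <- cannabis_genotypes()$genotype
  hemp <- setdiff(g, c("CINBOL", "CINRO"))
  thcas <- ifelse(g == "CINBOL", 17.80, ifelse(g == "CINRO", 1.32, NA_real_))
  cbdas_hemp <- c(`Santhica 27` = 0.02, Carmagnola = 0.45, Bernabeo = 0.70,
                  Carmaleonte = 0.52, CS = 1.10, Ermo = 1.44, Fibrante = 0.95,
                  Fibranova = 0.60, `Eletta Campana` = 1.20, Codimono = 1.30,
                  `Futura 75` = 0.75)
  cbdas <- ifelse(g == "CINRO", 4.90, ifelse(g == "CINBOL", NA_real_,
                                             cbdas_hemp[g]))
  cbcas_lvl <- c(`Santhica 27` = 0.07, Carmagnola = 0.22, Bernabeo = 0.19,
                 Carmaleonte = 0.09, CS = 0.25, Ermo = 0.08, Fibrante = 0.20,
                 Fibranova = 0.12, `Eletta Campana` = 0.11, Codimono = 0.21,
                 `Futura 75` = 0.10, CINBOL = 0.06, CINRO = 0.05)
  cbcas <- cbcas_lvl[g]
  rbind(
    data.frame(genotype = g, gene = "THCAS", expression = unname(thcas)),
    data.frame(genotype = g, gene = "CBDAS", expression = unname(cbdas)),
    data.frame(genotype = g, gene = "CBCAS", expression = unname(cbcas)),
    data.frame(genotype = g, gene = "CsClathrin", expression = 1),
    data.frame(genotype = g, gene = "CsRAN", expression = 1),
    data.frame(genotype = g, gene = "CsActin", expression = 1)
  )
}

#' Simulate an RT-qPCR plate with standards and known truth
#'
#' Standards per gene are a 5-point series of four 1:4 serial dilutions (top
#' point = 1 arbitrary unit). Every well's Cq is drawn as
#' `intercept - log10(q)/log10(1+E) + Normal(0, noise_sd)`; gene-by-genotype
#' combinations with `NA` expression produce undetermined (NA) Cq.
#'
#' @param design data.frame `genotype`, `gene`, `expression` (see
#'   [default_qpcr_design()]).
#' @param efficiencies Named per-gene amplification efficiencies in (0, 1.2]
#'   (default 1 for every gene).
#' @param intercepts Named per-gene curve intercepts (default 20).
#' @param noise_sd Cq noise standard deviation (default 0.15, a typical
#'   technical-replicate scatter).
#' @param n_bio,n_tech Biological and technical replicates (default 3 x 3).
#' @param seed Integer seed.
#' @return List with `plate` (long-format data.frame accepted by the
#'   quantification functions) and `truth` (design, efficiencies, intercepts,
#'   noise_sd).
#' @export
simulate_qpcr_plate <- function(design = default_qpcr_design(),
                                efficiencies = NULL, intercepts = NULL,
                                noise_sd = 0.15, n_bio = 3L, n_tech = 3L,
                                seed = 1L) {
  stopifnot(all(c("genotype", "gene", "expression") %in% names(design)))
  genes <- unique(design$gene)
  if (is.null(efficiencies)) efficiencies <- stats::setNames(rep(1, length(genes)), genes)
  if (is.null(intercepts)) intercepts <- stats::setNames(rep(20, length(genes)), genes)
  if (any(!genes %in% names(efficiencies)))
    stop("missing efficiency for some gene(s)", call. = FALSE)
  if (any(efficiencies <= 0 | efficiencies > 1.2))
    stop("efficiencies must lie in (0, 1.2]", call. = FALSE)
  if (any(design$expression[!is.na(design$expression)] <= 0))
    stop("expression levels must be positive or NA (absent)", call. = FALSE)
  set.seed(seed)
  cq_of <- function(gene, q) {
    intercepts[[gene]] - log10(q) / log10(1 + efficiencies[[gene]]) +
      rnorm(length(q), 0, noise_sd)
  }
  rows <- list()
  for (g in genes) {
    lq <- log10(0.25^(0:4))
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sprintf("std_%s_%d", g, 1:5), genotype = "standard", gene = g,
      bio_rep = NA_integer_, tech_rep = NA_integer_,
      cq = cq_of(g, 10^lq), is_standard = TRUE, log10_quantity = lq,
      stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(design))) {
    gt <- design$genotype[r]; g <- design$gene[r]; ex <- design$expression[r]
    for (b in seq_len(n_bio)) for (t in seq_len(n_tech)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("%s_b%d_t%d", gt, b, t), genotype = gt, gene = g,
        bio_rep = b, tech_rep = t,
        cq = if (is.na(ex)) NA_real_ else cq_of(g, ex),
        is_standard = FALSE, log10_quantity = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  list(plate = plate,
       truth = list(design = design, efficiencies = efficiencies,
                    intercepts = intercepts, noise_sd = noise_sd))
}

extdata <- function(file) {
  path <- system.file("extdata", file, package = "cansynth")
  if (!nzchar(path)) stop("fixture not found: ", file, call. = FALSE)
  path
}

#' Genotype metadata fixture
#'
#' The 13-genotype study panel: chemotype class, B-locus marker phenotype,
#' sampling time and cannabinoid content (metadata only; the chemistry is out
#' of scope for this package).
#'
#' @return data.frame with one row per genotype.
#' @export
cannabis_genotypes <- function() {
  read.delim(extdata("genotype_metadata.tsv"), stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Full-length cds primer fixture
#'
#' @return data.frame: `gene`, `fw`, `rv`, `amplicon_bp`, `note`.
#' @export
cds_primer_table <- function() {
  read.delim(extdata("cds_primers.tsv"), stringsAsFactors = FALSE)
}

#' RT-qPCR primer fixture
#'
#' @return data.frame: `gene`, `fw`, `rv`, `amplicon_bp`, `r_squared`,
#'   `efficiency`, `ta_celsius`, `conc_um`.
#' @export
qpcr_primer_table <- function() {
  read.delim(extdata("qpcr_primers.tsv"), stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Synthetic three-primer B-locus marker panel
#'
#' The real multiplex marker's primer sequences are not part of the packaged
#' data; this synthetic stand-in reproduces its logic: one shared forward
#' primer and two reverse primers whose templates yield a 1080-bp band
#' (functional-CBDAS haplotype) or a 1192-bp band (functional-THCAS
#' haplotype). Templates for a genotype are built from its marker phenotype.
#'
#' @param seed Seed fixing the synthetic primer/template sequences.
#' @return List with `fw`, `rv_d`, `rv_t` (primer strings) and
#'   `templates` (named list of [seq_record]: `BD`, `BT`).
#' @export
synthetic_b_marker_panel <- function(seed = 101L) {
  set.seed(seed)
  fw <- random_seq(20L)
  rv_d <- random_seq(20L)
  rv_t <- random_seq(20L)
  build <- function(band_len, rv, id) {
    pad <- 50L
    total <- pad + band_len + pad
    chars <- strsplit(random_seq(total), "")[[1]]
    chars[(pad + 1L):(pad + 20L)] <- strsplit(fw, "")[[1]]
    rv_start <- pad + band_len - 19L
    chars[rv_start:(rv_start + 19L)] <- strsplit(revcomp(rv), "")[[1]]
    seq_record(id, paste(chars, collapse = ""), role = "template")
  }
  list(fw = fw, rv_d = rv_d, rv_t = rv_t,
       templates = list(BD = build(1080L, rv_d, "hap_BD"),
                        BT = build(1192L, rv_t, "hap_BT")))
}

#' Templates carried by a genotype of a given marker phenotype
#'
#' @param marker_phenotype `"BD/BD"`, `"BT/BT"` or `"BT/BD"`.
#' @param panel A [synthetic_b_marker_panel()].
#' @return List of [seq_record] haplotype templates.
#' @export
marker_templates_for <- function(marker_phenotype, panel) {
  switch(marker_phenotype,
         "BD/BD" = panel$templates["BD"],
         "BT/BT" = panel$templates["BT"],
         "BT/BD" = , "BD/BT" = panel$templates[c("BD", "BT")],
         stop("unknown marker phenotype: ", marker_phenotype, call. = FALSE))
}

#' Write the bundled fixture set to a directory
#'
#' Emits the genotype metadata, both primer tables, a default family
#' configuration summary and a manifest.
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
make_paper_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("genotype_metadata.tsv", "cds_primers.tsv", "qpcr_primers.tsv"))
    file.copy(extdata(f), file.path(dir, f), overwrite = TRUE)
  cfg <- family_config()
  cfg_lines <- c(
    sprintf("ancestor_length_nt\t%d", cfg$ancestor_length_nt),
    sprintf("pseudogene_fraction\t%g", cfg$pseudogene_fraction),
    sprintf("protected_codons\t%s", paste(cfg$protected_codons, collapse = ",")),
    vapply(cfg$clades, function(cl)
      sprintf("clade\t%s\tn=%d\tdiag=%s", cl$name, cl$n_sequences,
              paste(sprintf("%d:%s", cl$diagnostic$pos_nt,
                            cl$diagnostic$allele), collapse = ",")),
      character(1)))
  writeLines(cfg_lines, file.path(dir, "family_config.tsv"))
  writeLines(c("file\tdescription",
               "genotype_metadata.tsv\t13-genotype study panel metadata",
               "cds_primers.tsv\tfull-length cds primer pairs",
               "qpcr_primers.tsv\tRT-qPCR primer pairs with assay settings",
               "family_config.tsv\tdefault synthetic gene-family configuration"),
             file.path(dir, "MANIFEST.tsv"))
  invisible(dir)
}
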