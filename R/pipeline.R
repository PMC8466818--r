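# Orchestration of the two study workflows: (1) sequence typing — cds
# validation, clade classification, SNP and critical-residue annotation,
# unique-cds inventory; (2) transcription quantification — standard curves,
# reference-gene ranking, RQ and baseline statistics. Each run can write its
# TSV/CSV reports plus a manifest of inputs, thresholds and seeds. A thin
# command-line front-end over these functions ships in inst/scripts.

write_manifest <- function(dir, params) {
  lines <- c("key\tvalue",
             vapply(names(params), function(k)
               paste(k, paste(format(params[[k]]), collapse = ","), sep = "\t"),
               character(1)),
             paste("cansynth_version",
                   as.character(utils::packageVersion("cansynth")), sep = "\t"))
  writeLines(lines, file.path(dir, "manifest.tsv"))
}

#' Type a set of cds against clade profiles
#'
#' Runs the full sequence-typing workflow: cds completeness classification,
#' clade assignment of the complete cds by diagnostic SNPs, SNP calling
#' against the assigned clade's reference, critical-residue checks on the
#' translated proteins, and the unique-cds inventory.
#'
#' @param x Path to a FASTA file or a list of [seq_record].
#' @param profiles List of [clade_profile].
#' @param genotype_labels Optional named vector mapping record id to genotype
#'   (for the inventory).
#' @param identity_threshold Passed to [classify_sequence()].
#' @param out_dir Optional output directory for TSV reports and a manifest.
#' @return List with `status` (cds status table), `calls`, `snp_tables`,
#'   `critical`, `inventory`, `summary`.
#' @export
run_type_seqs <- function(x, profiles, genotype_labels = NULL,
                          identity_threshold = 97.0, out_dir = NULL) {
  records <- if (is.character(x)) read_fasta(x) else x
  status <- cds_status_table(records)
  complete <- records[status$status == "complete"]
  if (!length(complete))
    stop("no complete cds in input (", nrow(status), " records: ",
         sum(status$status == "pseudogene"), " pseudogene, ",
         sum(status$status == "fragment"), " fragment)", call. = FALSE)
  calls <- classify_all(complete, profiles, identity_threshold)
  refs <- lapply(profiles, `[[`, "reference")
  names(refs) <- vapply(profiles, `[[`, character(1), "name")
  snp_tables <- lapply(seq_along(complete), function(i) {
    cl <- calls$assigned[i]
    if (cl == "unknown") return(NULL)
    call_snps(complete[[i]], refs[[cl]])
  })
  snp_tables <- Filter(Negate(is.null), snp_tables)
  critical <- do.call(rbind, lapply(seq_along(complete), function(i) {
    cl <- calls$assigned[i]
    if (cl == "unknown") return(NULL)
    prof <- profiles[[which(names(refs) == cl)]]
    crs <- prof$critical_residues
    if (is.null(crs))
      crs <- critical_residue_set(translate_cds(refs[[cl]]))
    rep_ <- check_critical_residues(translate_cds(complete[[i]]), crs)
    data.frame(id = complete[[i]]$id, clade = cl,
               all_intact = rep_$all_intact,
               deviations = if (nrow(rep_$deviations))
                 paste(sprintf("%d:%s>%s", rep_$deviations$position,
                               rep_$deviations$expected,
                               rep_$deviations$observed), collapse = ",")
               else "", stringsAsFactors = FALSE)
  }))
  inventory <- unique_cds_inventory(complete, genotype_labels)
  summary <- data.frame(
    n_input = nrow(status),
    n_complete = sum(status$status == "complete"),
    n_pseudogene = sum(status$status == "pseudogene"),
    n_fragment = sum(status$status == "fragment"),
    n_unique_complete = inventory$n_unique,
    n_unknown_clade = sum(calls$assigned == "unknown"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(status, file.path(out_dir, "cds_status.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(out_dir, "clade_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_snp_tsv(snp_tables, file.path(out_dir, "snps.tsv"))
    if (!is.null(critical))
      write.table(critical, file.path(out_dir, "critical_residues.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(inventory$inventory, file.path(out_dir, "unique_cds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, list(workflow = "type-seqs",
                                 identity_threshold = identity_threshold,
                                 n_profiles = length(profiles)))
  }
  list(status = status, calls = calls, snp_tables = snp_tables,
       critical = critical, inventory = inventory, summary = summary)
}

#' Genotype a panel at the B locus with a three-primer marker
#'
#' @param genotype_templates Named list: per genotype, a list of
#'   [seq_record] haplotype templates.
#' @param fw,rv_d,rv_t Marker primers, see [call_b_marker()].
#' @param out Optional TSV output path.
#' @param ... Tuning knobs passed to [call_b_marker()].
#' @return data.frame: `genotype`, `bands`, `b_locus`, `chemotype_class`.
#' @export
run_genotype <- function(genotype_templates, fw, rv_d, rv_t, out = NULL, ...) {
  rows <- lapply(names(genotype_templates), function(gt) {
    call <- call_b_marker(genotype_templates[[gt]], fw, rv_d, rv_t, ...)
    data.frame(genotype = gt, bands = paste(call$bands, collapse = ","),
               b_locus = call$b_locus, chemotype_class = call$chemotype_class,
               stringsAsFactors = FALSE)
  })
  out_df <- do.call(rbind, rows)
  if (!is.null(out))
    write.table(out_df, out, sep = "\t", quote = FALSE, row.names = FALSE)
  out_df
}

#' Run the full qPCR quantification workflow on a plate
#'
#' Fits standard curves for all involved genes, ranks the candidate reference
#' genes by stability, quantifies each target relative to the geometric mean
#' of the chosen references, and compares every genotype against the baseline.
#'
#' @param plate Plate data.frame or CSV path.
#' @param target_genes Character vector of target genes.
#' @param candidate_references Candidate reference genes (>= 2); the top
#'   `n_references` by stability are used.
#' @param n_references Number of reference genes to keep (default 2).
#' @param baseline_genotype Baseline for the t-tests (default `"CINRO"`).
#' @param out_dir Optional output directory.
#' @return List with `curves`, `stability`, `references_used`, `rq` (named
#'   list of `rq_table` with baseline stats), `summary`.
#' @export
run_qpcr <- function(plate, target_genes, candidate_references,
                     n_references = 2L, baseline_genotype = "CINRO",
                     out_dir = NULL) {
  if (is.character(plate)) plate <- read_qpcr_plate(plate) else
    plate <- validate_plate(plate)
  if (!baseline_genotype %in% plate$genotype)
    stop("baseline genotype '", baseline_genotype, "' not on the plate",
         call. = FALSE)
  genes <- c(target_genes, candidate_references)
  curves <- curves_from_plate(plate, genes)
  stability <- rank_reference_stability(plate, candidate_references)
  refs_used <- stability$gene[seq_len(min(n_references, nrow(stability)))]
  rq <- lapply(target_genes, function(g) {
    r <- compute_rq(plate, g, refs_used, curves)
    tryCatch(compare_to_baseline(r, baseline_genotype),
             error = function(e) r)
  })
  names(rq) <- target_genes
  summary <- do.call(rbind, lapply(target_genes, function(g) {
    cbind(gene_target = g, format_rq(rq[[g]]))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    curve_df <- do.call(rbind, lapply(curves, function(cv)
      data.frame(gene = cv$gene, slope = cv$slope, intercept = cv$intercept,
                 r_squared = cv$r_squared, efficiency = cv$efficiency,
                 n_points = cv$n_points)))
    write.csv(curve_df, file.path(out_dir, "standard_curves.csv"),
              row.names = FALSE)
    write.csv(stability, file.path(out_dir, "reference_stability.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "rq_results.csv"), row.names = FALSE)
    write_manifest(out_dir, list(workflow = "qpcr",
                                 targets = target_genes,
                                 references_used = refs_used,
                                 baseline = baseline_genotype))
  }
  list(curves = curves, stability = stability, references_used = refs_used,
       rq = rq, summary = summary)
}

#' Build clade profiles from a simulated family
#'
#' Convenience for tests and examples: turns the output of
#' [simulate_gene_family()] into registered [clade_profile] objects.
#'
#' @param sim Output of [simulate_gene_family()].
#' @return List of [clade_profile].
#' @export
profiles_from_simulation <- function(sim) {
  lapply(names(sim$references), function(nm)
    clade_profile(nm, sim$references[[nm]], sim$diagnostics[[nm]]))
}
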