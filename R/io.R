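#' Write / read allele-count pileup TSV
#'
#' The interchange format for per-position allele counts: columns
#' exactly `sample_id, gene_id, pos, nA, nC, nG, nT` with `pos` 0-based
#' within gene. On read, duplicate `(sample, gene, pos)` rows are
#' summed with a warning; negative counts or malformed positions raise
#' a parse error naming the offending line.
#'
#' @param x a `pileup_set` or allele-count data.table.
#' @param path file path.
#' @return `read_pileup_tsv` returns a data.table.
#' @export
write_pileup_tsv <- function(x, path) {
  counts <- if (inherits(x, "pileup_set")) x$counts else x
  data.table::fwrite(counts, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pileup_tsv
#' @export
read_pileup_tsv <- function(path) {
  expected <- c("sample_id", "gene_id", "pos", "nA", "nC", "nG", "nT")
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("sample_id", "gene_id")))
  if (!identical(names(dt), expected)) {
    sf_stop(paste0("pileup header must be exactly: ",
                   paste(expected, collapse = ", ")),
            class = "strainflow_parse_error")
  }
  num <- c("pos", "nA", "nC", "nG", "nT")
  for (cn in num) {
    v <- dt[[cn]]
    if (!is.numeric(v) || anyNA(v) || any(v != round(v))) {
      bad <- which(!grepl("^-?[0-9]+$", as.character(v)) | is.na(v))[1]
      sf_stop(sprintf("malformed integer in column '%s' at data line %d",
                      cn, bad),
              class = "strainflow_parse_error")
    }
  }
  if (any(dt$pos < 0)) {
    sf_stop(sprintf("negative position at data line %d",
                    which(dt$pos < 0)[1]),
            class = "strainflow_parse_error")
  }
  cnt <- as.matrix(dt[, c("nA", "nC", "nG", "nT")])
  if (any(cnt < 0)) {
    sf_stop(sprintf("negative count at data line %d",
                    which(rowSums(cnt < 0) > 0)[1]),
            class = "strainflow_parse_error")
  }
  if (anyDuplicated(dt, by = c("sample_id", "gene_id", "pos"))) {
    warning("duplicate (sample, gene, pos) rows summed")
    dt <- dt[, lapply(.SD, sum), by = c("sample_id", "gene_id", "pos"),
             .SDcols = c("nA", "nC", "nG", "nT")]
  }
  dt
}

#' Write one strain's gene sequences as FASTA (gene per record)
#'
#' @param seq integer base vector over the concatenated catalog (or a
#'   name into `genomes$seqs`).
#' @param catalog the catalog defining record boundaries and IDs.
#' @param path output path.
#' @export
write_fasta_refs <- function(seq, catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  chars <- BASES[seq]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(catalog$genes))) {
    g <- catalog$genes[i, ]
    writeLines(paste0(">", g$gene_id), con)
    s <- chars[(g$offset + 1):(g$offset + g$length)]
    writeLines(paste(s, collapse = ""), con)
  }
  invisible(path)
}

#' Read gene-per-record FASTA into a concatenated call vector
#'
#' Record IDs must match the catalog's gene IDs exactly; offenders are
#' listed in the error. Accepts CRLF line endings and lowercase bases.
#'
#' @param path FASTA path.
#' @param catalog the catalog to align against.
#' @return integer base vector over the concatenated catalog.
#' @export
read_fasta_refs <- function(path, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  dna <- ape::read.FASTA(path)
  ids <- names(dna)
  missing_genes <- setdiff(catalog$genes$gene_id, ids)
  extra <- setdiff(ids, catalog$genes$gene_id)
  if (length(missing_genes) || length(extra)) {
    sf_stop(paste0("FASTA/catalog ID mismatch; missing: ",
                   paste(missing_genes, collapse = ", "),
                   "; unexpected: ", paste(extra, collapse = ", ")),
            class = "strainflow_parse_error")
  }
  chars <- as.character(dna)
  out <- integer(catalog$total_length)
  for (i in seq_len(nrow(catalog$genes))) {
    g <- catalog$genes[i, ]
    s <- toupper(chars[[g$gene_id]])
    if (length(s) != g$length) {
      sf_stop(sprintf("gene %s length %d does not match catalog (%d)",
                      g$gene_id, length(s), g$length),
              class = "strainflow_parse_error")
    }
    out[(g$offset + 1):(g$offset + g$length)] <- match(s, BASES)
  }
  out
}

#' Write / read a strain tree in newick format
#'
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Pipeline run configuration
#'
#' Aggregates every tunable of the pipeline (typing thresholds, DMM
#' settings, permutation counts, non-inferiority margin, seeds) so that
#' a run is fully described by one object; the resolved configuration
#' is serialized into the output manifest for provenance.
#'
#' @param cohort a [cohort_config()].
#' @param typing a [typing_params()].
#' @param kmax,n_restarts DMM model scan settings.
#' @param n_perm permutations for PERMANOVA/Procrustes.
#' @param margin non-inferiority margin (g/day).
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), typing = typing_params(),
                       kmax = 15, n_restarts = 10, n_perm = 1000,
                       margin = -3.6, seed = 1L) {
  structure(list(cohort = cohort, typing = typing, kmax = kmax,
                 n_restarts = n_restarts, n_perm = n_perm,
                 margin = margin, seed = seed),
            class = "run_config")
}

#' Write the synthetic cohort's interchange files
#'
#' Emits the pileup TSV, read-count TSV, genus count TSV, metadata CSV,
#' biomarker CSV, per-strain reference FASTAs and the machine-readable
#' truth JSON.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(outdir, f)
  if (!is.null(cohort$pileups)) {
    write_pileup_tsv(cohort$pileups, p("pileups.tsv"))
    data.table::fwrite(cohort$pileups$read_counts, p("read_counts.tsv"),
                       sep = "\t")
    files <- c(files, p("pileups.tsv"), p("read_counts.tsv"))
  }
  gc_ <- data.table::as.data.table(cohort$genus_counts,
                                   keep.rownames = "sample_id")
  data.table::fwrite(gc_, p("genus_counts.tsv"), sep = "\t")
  meta <- cohort$truth$samples
  write.csv(meta, p("metadata.csv"), row.names = FALSE)
  write.csv(cohort$biomarkers, p("biomarkers.csv"), row.names = FALSE)
  write.csv(cohort$limits, p("biomarker_limits.csv"), row.names = FALSE)
  write.csv(cohort$growth, p("growth.csv"), row.names = FALSE)
  for (nm in names(cohort$genomes$seqs)) {
    write_fasta_refs(cohort$genomes$seqs[[nm]], cohort$catalog,
                     p(sprintf("ref_%s.fasta", nm)))
  }
  truth <- list(
    fct_labels = as.list(cohort$fct_truth),
    strain = setNames(as.list(cohort$truth$samples$strain),
                      cohort$truth$samples$sample_id),
    seed = cohort$seed
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       null = "null")
  files <- c(files, p("genus_counts.tsv"), p("metadata.csv"),
             p("biomarkers.csv"), p("growth.csv"), p("truth.json"))
  invisible(files)
}

#' Run the full analysis pipeline
#'
#' Chains all stages over one configuration: simulate (optional) ->
#' strain typing -> longitudinal tracking -> community typing ->
#' ecology statistics -> trial statistics, writing each stage's outputs
#' plus a manifest (resolved configuration, seeds, file checksums)
#' under `outdir`. Any stage failure aborts with the stage name;
#' partial outputs are preserved.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param cohort optionally, a pre-simulated [simulate_cohort()] object.
#' @param verbose log stage progress.
#' @return invisibly, a list with each stage's in-memory results.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("sfrun"),
                         cohort = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) if (verbose) message("[strainflow] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      sf_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              class = "strainflow_stage_error")
    })
  }
  results <- list()

  log_("stage simulate")
  cohort <- cohort %||%
    stage("simulate", simulate_cohort(config$cohort, seed = config$seed))
  stage("simulate", write_cohort(cohort, file.path(outdir, "cohort")))
  results$cohort <- cohort
  present <- cohort$truth$samples[!cohort$truth$samples$missing, ]

  log_("stage type-strains")
  classes <- stage("type-strains", type_strains(
    cohort$pileups,
    present[, c("sample_id", "abundance")],
    cohort$genomes, cohort$catalog, config$typing))
  write.csv(classes, file.path(outdir, "classifications.csv"),
            row.names = FALSE)
  results$classes <- classes

  log_("stage track")
  traj <- stage("track", track_trajectories(classes, present,
                                            config$cohort$visits))
  summ <- stage("track", tracking_summary(traj))
  write.csv(as.data.frame(traj), file.path(outdir, "trajectories.csv"),
            row.names = FALSE)
  jsonlite::write_json(summ, file.path(outdir, "tracking_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  results$trajectories <- traj
  results$tracking <- summ

  log_("stage fct (K up to %d)", config$kmax)
  sel <- stage("fct", select_k(cohort$genus_counts, k_max = config$kmax,
                               n_restarts = config$n_restarts,
                               seed = child_seed(config$seed, 101)))
  kbest <- sel$best$laplace
  labels <- fct_assign(sel$models[[kbest]])
  ord <- stage("fct", order_chronologically(
    labels, present[, c("sample_id", "visit_index")], K = kbest))
  write.csv(sel$criteria, file.path(outdir, "dmm_criteria.csv"),
            row.names = FALSE)
  write.csv(data.frame(sample_id = names(ord$labels), fct = ord$labels),
            file.path(outdir, "fct_assignments.csv"), row.names = FALSE)
  results$fct <- list(selection = sel, labels = ord$labels)

  log_("stage ecology")
  props <- cohort$genus_counts / rowSums(cohort$genus_counts)
  bc <- stage("ecology", bray_curtis(props))
  meta_m <- present[match(rownames(props), present$sample_id), ]
  perma <- stage("ecology", permanova(
    bc, meta_m, c("arm", "visit"), n_perm = config$n_perm,
    seed = child_seed(config$seed, 102)))
  write.csv(perma, file.path(outdir, "permanova.csv"), row.names = FALSE)
  results$ecology <- list(permanova = perma)

  log_("stage trial")
  ni <- stage("trial", growth_noninferiority(cohort$growth,
                                             margin = config$margin))
  write.csv(ni$decisions, file.path(outdir, "noninferiority.csv"),
            row.names = FALSE)
  results$trial <- ni

  manifest <- list(
    package_version = as.character(utils::packageVersion("strainflow")),
    seed = config$seed,
    config = list(
      typing = unclass(config$typing),
      kmax = config$kmax, n_restarts = config$n_restarts,
      n_perm = config$n_perm, margin = config$margin,
      cohort = lapply(unclass(config$cohort), function(x)
        if (is.function(x)) NULL else x)
    ),
    files = as.list(tools::md5sum(list.files(outdir, recursive = TRUE,
                                             full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_("done: %s", outdir)
  invisible(results)
}
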