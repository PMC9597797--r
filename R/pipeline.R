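#' Pipeline configuration
#'
#' Collects the inputs and parameters of a full run. Inputs are in-memory
#' objects (use [read_fasta()], [read_breed_table()], [parse_newick()] to load
#' them from files).
#'
#' @param alignment Named character vector of aligned sequences.
#' @param breed_table Breed table resolving every id.
#' @param tree Optional externally built rooted `phylo` (e.g., an ML tree).
#'   When supplied it takes precedence and the internal NJ builder is skipped.
#' @param haplogroup_refs Optional named vector or data.frame of reference
#'   haplogroup labels (`id -> A..E`); haplogroup stages run only if given.
#' @param grouping Optional named vector `breed -> group` for profiles.
#' @param outgroup_ids Optional outgroup tips used to root the NJ tree.
#' @param dedup Collapse identical sequences within breeds first (default TRUE).
#' @param max_missing_frac Missing-data locus threshold before Phi-ST.
#' @param min_individuals Minimum population size kept for Phi-ST.
#' @param retention_fraction Fraction of links covered in breed profiles.
#' @param kinship_types Integer subset of `c(1, 2)`.
#' @param nmds_restarts NMDS restarts.
#' @param seed Top-level seed; per-stage seeds are derived from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment, breed_table, tree = NULL,
                            haplogroup_refs = NULL, grouping = NULL,
                            outgroup_ids = NULL, dedup = TRUE,
                            max_missing_frac = 0.05, min_individuals = 3L,
                            retention_fraction = 0.77,
                            kinship_types = c(1L, 2L), nmds_restarts = 20L,
                            seed = 1L) {
  breed_table <- validate_breed_table(breed_table)
  stopifnot(is.character(alignment), !is.null(names(alignment)),
            max_missing_frac >= 0, max_missing_frac <= 1,
            min_individuals >= 1L,
            retention_fraction > 0, retention_fraction <= 1,
            all(kinship_types %in% c(1L, 2L)))
  breed_of(names(alignment), breed_table)  # every id must resolve
  if (!is.null(tree)) stopifnot(inherits(tree, "phylo"))
  structure(list(alignment = alignment, breed_table = breed_table, tree = tree,
                 haplogroup_refs = haplogroup_refs, grouping = grouping,
                 outgroup_ids = outgroup_ids, dedup = dedup,
                 max_missing_frac = max_missing_frac,
                 min_individuals = as.integer(min_individuals),
                 retention_fraction = retention_fraction,
                 kinship_types = as.integer(kinship_types),
                 nmds_restarts = as.integer(nmds_restarts),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, log, expr) {
  log(paste0("stage ", name, ": start"))
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline and write its artifacts
#'
#' Executes IO (optional within-breed dedup), column QC, tree construction
#' (or adoption of a supplied tree), haplogroup assignment and regional
#' summary, type-1/type-2 connection matrices and per-breed profiles,
#' pairwise Phi-ST with its population/locus filters, and NMDS plus UPGMA
#' clustering — writing every intermediate artifact, a machine-readable
#' summary and a log into `out_dir`.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of the in-memory results (`alignment`, `tree`,
#'   `connections`, `phist`, `nmds`, ...); artifact files are in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  log(paste0("dloopkin ", as.character(utils::packageVersion("dloopkin")),
             " | R ", getRversion()))
  log(paste0("seed: ", config$seed,
             " | dedup: ", config$dedup,
             " | max_missing_frac: ", config$max_missing_frac,
             " | min_individuals: ", config$min_individuals,
             " | retention_fraction: ", config$retention_fraction))
  res <- list()

  aln <- config$alignment
  bt <- config$breed_table
  res$dedup_report <- NULL
  if (config$dedup) {
    dd <- stage("io", log, dedup_identical_within_breed(aln, bt))
    aln <- dd$kept
    res$dedup_report <- dd$report
    log(paste0("stage io: ", nrow(dd$report), " identical within-breed sequence(s) removed, ",
               length(aln), " kept"))
    utils::write.table(dd$report, file.path(out_dir, "dedup_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bt <- bt[bt$id %in% names(aln), , drop = FALSE]
  res$alignment <- aln
  write_fasta(aln, file.path(out_dir, "alignment.fasta"))
  write_breed_table(bt, file.path(out_dir, "breed_table.tsv"))

  mask <- stage("qc", log, conserved_block_mask(aln))
  aln_tree <- apply_column_mask(aln, mask)
  log(paste0("stage qc: conserved-block mask retained ", sum(mask), " of ",
             length(mask), " columns"))
  res$column_mask <- mask

  if (!is.null(config$tree)) {
    tree <- config$tree
    log("stage tree: external tree supplied, NJ builder skipped")
  } else {
    tree <- stage("tree", log, nj_tree(k2p_matrix(aln_tree)))
    if (!is.null(config$outgroup_ids))
      tree <- stage("tree", log, root_with_outgroup(tree, config$outgroup_ids))
    log("stage tree: internal NJ tree built from K2P distances (desk-scale surrogate for an external ML tree)")
  }
  res$tree <- tree
  write_newick(tree, file.path(out_dir, "tree.nwk"))

  if (!is.null(config$haplogroup_refs)) {
    hg <- stage("haplogroups", log, assign_haplogroups(tree, config$haplogroup_refs))
    res$haplogroups <- hg
    utils::write.table(hg, file.path(out_dir, "haplogroups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$haplogroup_summary <- summarize_haplogroups(hg, bt)
    utils::write.table(res$haplogroup_summary,
                       file.path(out_dir, "haplogroup_summary.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    log("stage haplogroups: assignment and regional summary written")
  }

  res$connections <- list()
  res$profiles <- list()
  for (kt in config$kinship_types) {
    cm <- stage("connections", log,
                suppressMessages(connection_matrix(tree, bt, kinship_type = kt)))
    res$connections[[paste0("type", kt)]] <- cm
    write_connection_matrix(cm, file.path(out_dir,
                                          paste0("connections_type", kt, ".tsv")))
    prof <- lapply(cm$breeds, function(b)
      breed_profile(cm, b, grouping = config$grouping,
                    retention_fraction = config$retention_fraction))
    names(prof) <- cm$breeds
    res$profiles[[paste0("type", kt)]] <- prof
    ptab <- do.call(rbind, lapply(prof, function(p)
      if (nrow(p$table)) cbind(focal = p$focal, p$table) else NULL))
    utils::write.table(ptab, file.path(out_dir, paste0("profiles_type", kt, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log(paste0("stage connections: type-", kt, " matrix (", cm$n_links, " links)"))
  }

  filt <- stage("fst", log,
                apply_population_filters(aln, bt,
                                         min_individuals = config$min_individuals,
                                         max_missing_frac = config$max_missing_frac))
  log(paste0("stage fst: dropped population(s): ",
             if (length(filt$dropped_populations))
               paste(filt$dropped_populations, collapse = ", ") else "none"))
  res$phist <- stage("fst", log, phi_st_matrix(filt$aln, filt$breed_table))
  write_phist_matrix(res$phist, file.path(out_dir, "phist.tsv"))

  phist_d <- pmax(res$phist$values, 0)  # ordination needs nonnegative input
  res$nmds <- stage("ordination", log,
                    nmds(phist_d, n_restarts = config$nmds_restarts,
                         seed = config$seed + 1L))
  utils::write.table(res$nmds$coordinates,
                     file.path(out_dir, "nmds_coordinates.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  log(paste0("stage ordination: NMDS stress-1 = ", signif(res$nmds$stress, 6)))
  res$dendrogram_phist <- upgma_dendrogram(phist_d)
  write_newick(res$dendrogram_phist, file.path(out_dir, "dendrogram_phist.nwk"))
  if ("type2" %in% names(res$connections) &&
      length(res$connections$type2$breeds) >= 3L) {
    pd <- suppressWarnings(profile_distance_matrix(res$connections$type2,
                                                   method = "correlation"))
    res$dendrogram_profiles <- upgma_dendrogram(pd)
    write_newick(res$dendrogram_profiles,
                 file.path(out_dir, "dendrogram_profiles.nwk"))
  }

  summary <- list(
    n_sequences = length(aln),
    n_breeds = length(unique(bt$breed)),
    columns_retained_qc = sum(mask),
    phist_populations = length(res$phist$populations),
    nmds_stress = res$nmds$stress,
    connection_links = lapply(res$connections, function(x) x$n_links),
    seed = config$seed
  )
  if (!is.null(res$haplogroup_summary))
    summary$haplogroup_summary <- as.data.frame.matrix(res$haplogroup_summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(res)
}

#' Cross-tabulate haplogroup assignments by region
#'
#' @param assignment A [assign_haplogroups()] result (or data.frame with `id`
#'   and `haplogroup`).
#' @param breed_table Breed table with `id` and `region`.
#' @return A region x haplogroup contingency table; each row sums to the
#'   number of assigned sequences sampled in that region.
#' @export
summarize_haplogroups <- function(assignment, breed_table) {
  idx <- match(assignment$id, breed_table$id)
  if (anyNA(idx))
    stop("assigned id(s) missing from breed table: ",
         paste(utils::head(assignment$id[is.na(idx)], 5L), collapse = ", "))
  region <- breed_table$region[idx]
  table(region = region, haplogroup = assignment$haplogroup)
}
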