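## End-to-end orchestration: profiles -> classification -> tree -> dating ->
## consensus -> routes, with a serialized config and deterministic outputs.

#' Build a validated run configuration
#'
#' @param fasta path to the sample FASTA (aligned to the reference length or
#'   alignable).
#' @param sample_sheet path to the sample-sheet TSV (`sample_id`,
#'   `region_label`, `name`).
#' @param reference path to the reference FASTA (single record).
#' @param out_dir output directory.
#' @param mask `"default"`, `"none"`, or a path to a mask TSV.
#' @param haplogroup_tree optional path to a reference haplogroup-tree TSV.
#' @param route_table optional path to a route-table TSV.
#' @param route_overrides optional path to a region-override TSV.
#' @param methods dating methods, subset of `c("rho", "ml")`.
#' @param z normal multiplier for rho CIs, default 1.96.
#' @param years_per_substitution clock rate, default 3624.
#' @param correction optional path to a correction-curve TSV.
#' @param seed integer seed recorded and used for any stochastic step.
#' @return object of class `run_config`.
#' @export
run_config <- function(fasta, sample_sheet, reference, out_dir,
                       mask = "default", haplogroup_tree = NULL,
                       route_table = NULL, route_overrides = NULL,
                       methods = c("rho", "ml"), z = 1.96,
                       years_per_substitution = 3624, correction = NULL,
                       seed = 1L) {
  for (p in c(fasta, sample_sheet, reference))
    if (!file.exists(p)) stop("input file not found: ", p)
  methods <- match.arg(methods, c("rho", "ml"), several.ok = TRUE)
  structure(list(fasta = fasta, sample_sheet = sample_sheet,
                 reference = reference, out_dir = out_dir, mask = mask,
                 haplogroup_tree = haplogroup_tree,
                 route_table = route_table,
                 route_overrides = route_overrides, methods = methods,
                 z = z, years_per_substitution = years_per_substitution,
                 correction = correction, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the founder-analysis pipeline
#'
#' Stages, in order: read inputs, call variants against the reference, apply
#' the site mask, classify haplogroups (when a reference tree is given),
#' build the maximum-parsimony tree, date the root clade by the configured
#' methods, intersect the method CIs into a consensus interval, and
#' attribute routes (when a route table is given). Each stage writes a TSV
#' (or Newick) into the output directory; a log records the package version,
#' seed and per-stage counts, and the configuration is serialized so a rerun
#' with the same inputs and seed is byte-identical. Any stage error aborts
#' with the stage name.
#'
#' @param config a `run_config`.
#' @return list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- c(paste0("mitofounder ",
                        as.character(utils::packageVersion("mitofounder"))),
                 paste0("seed\t", config$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ref <- stage("reference", load_reference(config$reference))
  sheet <- stage("sample-sheet", read_sample_sheet(config$sample_sheet))
  if (!nrow(sheet)) stop("pipeline stage 'sample-sheet' failed: empty input ",
                         config$sample_sheet)
  seqs <- stage("fasta", {
    s <- Biostrings::readBStringSet(config$fasta)
    if (!length(s)) stop("empty input ", config$fasta)
    stats::setNames(as.character(s),
                    vapply(strsplit(names(s), "\\s+"), `[`, "", 1L))
  })
  missing <- setdiff(sheet$name, names(seqs))
  if (length(missing))
    stop("pipeline stage 'fasta' failed: sample sheet names absent from FASTA: ",
         paste(missing, collapse = ", "))
  log_lines <- c(log_lines, paste0("inputs_read\t", nrow(sheet)))

  mask <- switch(config$mask,
                 default = default_site_mask(),
                 none = site_mask(),
                 read_site_mask(config$mask))
  profiles <- stage("call-variants", lapply(seq_len(nrow(sheet)), function(i)
    apply_mask(call_variants(seqs[[sheet$name[i]]], ref,
                             sample_id = sheet$sample_id[i],
                             region_label = sheet$region_label[i]),
               mask)))
  n_masked <- sum(vapply(profiles, function(p) p$masked_removed, 1L))
  log_lines <- c(log_lines, paste0("variants_masked\t", n_masked))
  write_variant_profiles(profiles, file.path(config$out_dir, "profiles.tsv"))

  calls <- NULL
  if (!is.null(config$haplogroup_tree)) {
    rt <- stage("classify", read_haplogroup_tree(config$haplogroup_tree))
    calls <- stage("classify", lapply(profiles, classify, ref_tree = rt))
    ctab <- data.frame(
      sample_id = vapply(calls, function(x) x$sample_id, ""),
      haplogroup = vapply(calls, function(x) x$best_label, ""),
      score = vapply(calls, function(x) x$score, 0),
      depth = vapply(calls, function(x) x$path_depth, 0L))
    utils::write.table(ctab, file.path(config$out_dir, "haplogroups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tree <- stage("tree", build_mp_tree(profiles))
  log_lines <- c(log_lines,
                 paste0("haplotypes_collapsed\t", sum(tree$is_tip)),
                 paste0("parsimony_score\t", tree$score))
  mp_write_newick(tree, file.path(config$out_dir, "tree.nwk"))
  mp_write_edge_table(tree, file.path(config$out_dir, "tree_edges.tsv"))

  clock <- if (is.null(config$correction))
    clock_model(config$years_per_substitution)
  else read_correction_curve(config$correction)
  estimates <- list(); rhos <- list()
  if ("rho" %in% config$methods) {
    r <- stage("date-rho", rho_sigma(tree, clade_id = "all"))
    rhos[["all"]] <- r
    estimates$rho <- rho_age(r, clock, z = config$z)
  }
  if ("ml" %in% config$methods && sum(tree$is_tip) >= 2L) {
    estimates$ml <- stage("date-ml", {
      aln <- do.call(rbind, lapply(profiles, function(p)
        strsplit(apply_variants(p, ref), "")[[1L]]))
      rownames(aln) <- vapply(profiles, function(p) p$sample_id, "")
      ## the ML tree has one tip per collapsed haplotype
      phy <- mp_as_phylo(tree)
      rep_ids <- vapply(strsplit(phy$tip.label, "|", fixed = TRUE),
                        `[`, "", 1L)
      aln <- aln[rep_ids, , drop = FALSE]
      rownames(aln) <- phy$tip.label
      fit <- fit_clock_heights(aln, phy,
                               substitution_model("TN93",
                                 transition_rate_purines = 20,
                                 transition_rate_pyrimidines = 20),
                               parts = partition_scheme(),
                               positions = seq_len(ncol(aln)),
                               seed = config$seed)
      ml_age(fit, clock = clock, genome_length = ref$length,
             clade_id = "all")
    })
  }
  write_age_table(estimates, file.path(config$out_dir, "ages.tsv"),
                  rhos = rhos)

  cons <- NULL
  if (length(estimates) >= 1L) {
    cons <- consensus_interval(unname(estimates))
    utils::write.table(
      data.frame(clade_id = "all", low = cons$low, high = cons$high,
                 empty = cons$empty),
      file.path(config$out_dir, "consensus.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  routes <- NULL
  if (!is.null(config$route_table)) {
    routes <- stage("routes", {
      rtab <- read_route_table(config$route_table)
      ov <- if (!is.null(config$route_overrides))
        read_route_overrides(config$route_overrides) else NULL
      hg <- if (!is.null(calls))
        vapply(calls, function(x) x$best_label, "")
      else if ("haplogroup" %in% names(sheet)) sheet$haplogroup
      else stop("route attribution needs haplogroup calls or a ",
                "'haplogroup' sample-sheet column")
      attribute_routes(
        data.frame(sample_id = sheet$sample_id,
                   region_label = sheet$region_label, haplogroup = hg),
        rtab, region_overrides = ov)
    })
    write_region_summary(routes, file.path(config$out_dir, "routes.tsv"))
  }

  cfg_out <- config; cfg_out$out_dir <- NULL
  yaml::write_yaml(unclass(cfg_out), file.path(config$out_dir, "config.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(profiles = profiles, calls = calls, tree = tree,
                 estimates = estimates, consensus = cons, routes = routes,
                 out_dir = config$out_dir))
}
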