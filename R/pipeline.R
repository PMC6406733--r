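#' Run the full workflow from a configuration
#'
#' Executes the stages in order — load expression, discretize, build the
#' requested trees, bootstrap, split the major clades, test differential
#' genes, run gene-set enrichment, and score a drug screen when one is given
#' — writing every artifact plus a JSON run manifest to an output directory.
#' A failure in any stage is re-raised with the stage name prefixed.
#'
#' @param config a named list, or path to a JSON file, with entries:
#'   `expression` (path to a TSV expression table), `sample_meta` (path to a
#'   metadata TSV), `methods` (subset of nj/parsimony/ml; default all),
#'   `metric`, `tau` (`"auto"` or number), `n_boot`, `seed`, and optionally
#'   `gmt` (gene-set file), `screen` (plate CSV), `alpha`, `n_perm`.
#' @param out_dir output directory (created if absent).
#' @return the manifest list, invisibly; artifacts are written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) abort("`config` must be a list or a JSON file path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("stage %s: %s", name, conditionMessage(e)))
  }
  methods <- config$methods %||% c("nj", "parsimony", "ml")
  seed <- config$seed %||% 1L
  n_boot <- config$n_boot %||% 100L
  outputs <- character(0)
  emit <- function(file) outputs <<- c(outputs, file)

  expr <- stage("load", read_expression_table(
    config$expression, dialect = config$dialect %||% "tsv",
    sample_meta = config$sample_meta,
    log2_scale = config$log2_scale %||% TRUE))

  fits <- list()
  for (m in methods) {
    fits[[m]] <- stage(m, expr_phylo(expr, method = m,
                                     metric = config$metric %||% "euclidean",
                                     tau = config$tau %||% "auto",
                                     n_boot = n_boot, seed = seed))
    f <- file.path(out_dir, sprintf("tree_%s.nwk", m))
    write_newick(fits[[m]]$tree, f); emit(f)
    if (!is.null(fits[[m]]$char)) {
      f <- file.path(out_dir, sprintf("characters_%s.nex", m))
      write_character_matrix(fits[[m]]$char, f, "nexus"); emit(f)
    }
    if (!is.null(fits[[m]]$threshold_search)) {
      f <- file.path(out_dir, sprintf("threshold_%s.json", m))
      ts <- fits[[m]]$threshold_search
      jsonlite::write_json(ts[c("grid", "informative", "tau")], f,
                           auto_unbox = TRUE, digits = NA); emit(f)
    }
  }

  compare <- stage("compare", {
    cmp <- list()
    for (m in methods)
      if (!is.null(fits[[m]]$temporal_score))
        cmp[[paste0("temporal_score_", m)]] <- fits[[m]]$temporal_score
    if (length(methods) >= 2L)
      for (pr in utils::combn(methods, 2, simplify = FALSE)) {
        t1 <- fits[[pr[1]]]$tree
        t2 <- fits[[pr[2]]]$tree
        # character-based trees carry one collapsed outgroup taxon, the NJ
        # tree all its replicates: compare on the shared leaves
        shared <- intersect(t1$tip.label, t2$tip.label)
        cmp[[sprintf("rf_%s_vs_%s", pr[1], pr[2])]] <-
          rf_distance(ape::keep.tip(t1, shared), ape::keep.tip(t2, shared))
      }
    dm <- compute_distance(expr, config$metric %||% "euclidean")
    for (lk in c("single", "complete")) {
      hc <- hierarchical_cluster(dm, lk)
      f <- file.path(out_dir, sprintf("hclust_%s.nwk", lk))
      write_newick(hc, f); emit(f)
    }
    cmp
  })
  f <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(compare, f, auto_unbox = TRUE, digits = NA); emit(f)

  first_fit <- fits[[methods[1L]]]
  clades <- stage("clades", split_major_clades(
    first_fit$tree, exclude_outgroup = TRUE, outgroup = outgroup_samples(expr)))
  dg <- stage("differential", differential_genes(
    expr, clades, mode = config$diff_mode %||% "welch_bh",
    alpha = config$alpha %||% 0.05, cm = first_fit$char))
  f <- file.path(out_dir, "differential_genes.tsv")
  utils::write.table(dg, f, sep = "\t", quote = FALSE, row.names = FALSE); emit(f)

  if (!is.null(config$gmt)) {
    enr <- stage("enrichment", {
      coll <- read_gmt(config$gmt)
      enrichment(dg$gene[dg$significant %in% TRUE], coll,
                 universe = rownames(expr$values),
                 n_perm = config$n_perm %||% 1000L, seed = seed)
    })
    f <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enr, f, sep = "\t", quote = FALSE, row.names = FALSE); emit(f)
  }

  if (!is.null(config$screen)) {
    scr <- stage("screen", {
      sd_ <- read_plate_table(config$screen)
      ctrl <- fold_change_table(sd_, "ctrl")
      calls <- resistance_calls(ctrl, config$resist_threshold %||% 1)
      out <- list(fraction_resistant = calls$fraction_resistant,
                  n_resistant = calls$n_resistant, n_drugs = calls$n_drugs)
      f1 <- file.path(out_dir, "resistance_ctrl.tsv")
      utils::write.table(calls$calls, f1, sep = "\t", quote = FALSE, row.names = FALSE)
      emit(f1)
      if (any(sd_$arm == "siATG16L1")) {
        kd <- fold_change_table(sd_, "kd")
        rs <- resensitization(ctrl, kd, config$resens_rule %||% "below_one")
        out$n_resensitized <- rs$n_resensitized
        out$resensitized_fraction <- rs$fraction
      }
      qc <- plate_position_qc(sd_)
      out$qc_r_squared <- qc$r_squared
      out$density_correlation <- as.list(density_replicate_correlation(sd_, "ctrl"))
      out
    })
    f <- file.path(out_dir, "screen_summary.json")
    jsonlite::write_json(scr, f, auto_unbox = TRUE, digits = NA); emit(f)
  }

  inputs <- Filter(Negate(is.null),
                   config[c("expression", "sample_meta", "gmt", "screen")])
  manifest <- list(
    subcommand = "run",
    parameters = config,
    input_hashes = as.list(vapply(unlist(inputs), function(p)
      unname(tools::md5sum(p)), character(1))),
    seed = seed,
    tool_version = as.character(utils::packageVersion("exprphylo")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
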