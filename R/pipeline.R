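# End-to-end orchestration: simulate -> connectivity -> CBPT -> seed ->
# association -> moderation, with every artifact written to a run directory
# and checksummed into a manifest. Reruns with the same configuration
# reproduce identical checksums.

#' Validate a pipeline configuration
#'
#' A pipeline config is a named list (or a YAML/JSON file) with a `sim`
#' block of [sim_config()] arguments and a `cbpt` block with `n_perm`,
#' `seed`, `alpha_node`, `alpha_cluster` and `covariates`; optional
#' `moderation` block with `covariates`. Every stochastic stage must carry
#' an explicit seed and all alpha levels must lie in (0, 1).
#'
#' @param config named list, or path to a YAML or JSON file.
#' @return The validated config, class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    sim = list(n_nodes = 64, n_regions = 8, group_sizes = c(CI = 40, MCI = 20),
               n_epochs = 1, noise_sd = 3,
               recall_intercepts = c(CI = 50, MCI = 45), seed = 11),
    cbpt = list(n_perm = 500, seed = 7, alpha_node = 0.001,
                alpha_cluster = 0.05, covariates = "age"),
    moderation = list(covariates = c("age", "education"))
  )
  for (blk in names(defaults)) {
    user <- config[[blk]]
    merged <- defaults[[blk]]
    for (nm in names(user)) merged[[nm]] <- user[[nm]]
    config[[blk]] <- merged
  }
  if (!is.null(config$sim$group_sizes)) {
    gs <- unlist(config$sim$group_sizes)
    if (is.null(names(gs))) names(gs) <- c("CI", "MCI")  # YAML drops names
    config$sim$group_sizes <- gs
  }
  for (a in c("alpha_node", "alpha_cluster")) {
    v <- config$cbpt[[a]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(sprintf("%s must lie strictly in (0, 1)", a))
  }
  if (!is.numeric(config$cbpt$seed) || !is.numeric(config$sim$seed))
    stop("every stochastic stage needs an explicit numeric seed")
  if (config$cbpt$n_perm < 100) stop("n_perm must be >= 100")
  structure(config, class = "pipeline_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

cluster_as_json <- function(clusters) {
  lapply(clusters, function(cl) list(
    nodes = cl$nodes, sign = if (cl$sign > 0) "+" else "-",
    size = length(cl$nodes), mass = cl$mass, p_perm = cl$p_perm,
    significant = cl$significant
  ))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, connectivity (strength maps and per-subject PLV),
#' strength CBPT, seed-based CBPT (if a significant primary cluster
#' exists), marker-structure associations with group contrast, and the
#' moderated regression with its Johnson-Neyman region. All stage outputs
#' are written under `out_dir` and listed, with MD5 checksums, in
#' `manifest.json`; the manifest also records the package version and a
#' hash of the configuration, so a rerun with the same config yields an
#' identical manifest.
#'
#' @param config a `pipeline_config`, or anything [pipeline_config()]
#'   accepts.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results (`cohort_sim`,
#'   `cbpt`, `seed`, `associations`, `group_contrast`, `moderation`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("plvnet_run_")) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", file = log, append = TRUE)
  cat(sprintf("plvnet pipeline started %s\n", format(Sys.time())), file = log)

  # 1. simulate
  cfg <- do.call(sim_config, config$sim)
  sim <- simulate_cohort(cfg, return_plv = TRUE)
  files <- c(files,
    write_tsv(sim$grid$nodes, file.path(out_dir, "grid.tsv")))
  utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(out_dir, "cohort.csv"))
  logline("simulate: %d subjects x %d nodes", nrow(sim$cohort),
          ncol(sim$strength))

  # 2. connectivity artifacts
  st <- as.data.frame(sim$strength)
  names(st) <- sprintf("node%04d", seq_len(ncol(sim$strength)))
  files <- c(files,
    write_tsv(cbind(subject_id = sim$cohort$subject_id, st),
              file.path(out_dir, "strength.tsv")))
  saveRDS(sim$plv, file.path(out_dir, "plv.rds"), version = 3)
  files <- c(files, file.path(out_dir, "plv.rds"))

  # 3. strength CBPT
  adjacency <- build_adjacency(sim$grid)
  covs <- sim$cohort[, config$cbpt$covariates, drop = FALSE]
  cb <- cbpt_run(sim$strength, sim$cohort$delayed_recall, covariates = covs,
                 adjacency = adjacency, n_perm = config$cbpt$n_perm,
                 seed = config$cbpt$seed,
                 alpha_node = config$cbpt$alpha_node,
                 alpha_cluster = config$cbpt$alpha_cluster)
  jsonlite::write_json(cluster_as_json(cb$clusters),
                       file.path(out_dir, "clusters_strength.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "clusters_strength.json"))
  files <- c(files, write_tsv(
    data.frame(node = seq_along(cb$node_rho), rho = cb$node_rho,
               p = cb$node_p),
    file.path(out_dir, "node_map_strength.tsv")))
  logline("cbpt: %d candidate clusters, %d significant",
          length(cb$clusters), length(significant_clusters(cb)))

  sig <- significant_clusters(cb)
  markers <- data.frame(subject_id = sim$cohort$subject_id)
  sd_res <- NULL
  if (length(sig)) {
    primary <- sig[[1L]]
    markers$strength_marker <- primary$marker

    # 4. seed-based CBPT
    sd_res <- seed_cbpt(sim$plv, primary$nodes, sim$cohort$delayed_recall,
                        covariates = covs, adjacency = adjacency,
                        n_perm = config$cbpt$n_perm,
                        seed = config$cbpt$seed + 1,
                        alpha_node = config$cbpt$alpha_node,
                        alpha_cluster = config$cbpt$alpha_cluster)
    jsonlite::write_json(cluster_as_json(sd_res$clusters),
                         file.path(out_dir, "clusters_seed.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, file.path(out_dir, "clusters_seed.json"))
    sig2 <- significant_clusters(sd_res)
    if (length(sig2)) markers$seed_link_marker <- sig2[[1L]]$marker
    logline("seed: %d candidate clusters, %d significant",
            length(sd_res$clusters), length(sig2))
  } else {
    logline("seed: skipped, no significant primary cluster")
  }
  utils::write.csv(markers, file.path(out_dir, "markers.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(out_dir, "markers.csv"))

  assoc <- NULL
  contrast <- NULL
  moder <- NULL
  if (length(sig)) {
    # 5. associations + group contrast
    meas <- sim$cohort[, c("total_gm", "total_wm", "hippocampus",
                           "fa_cingulum_left", "fa_cingulum_right",
                           "fa_forceps_major", "fa_forceps_minor")]
    assoc <- marker_associations(
      stats::setNames(
        lapply(names(markers)[-1L], function(m) markers[[m]]),
        names(markers)[-1L]
      ),
      meas, group = sim$cohort$group
    )
    files <- c(files,
      write_tsv(as.data.frame(assoc), file.path(out_dir, "associations.tsv")))
    contrast <- group_compare(markers[[2L]], sim$cohort$group,
                              sim$cohort[, config$moderation$covariates])
    jsonlite::write_json(
      list(F = contrast$F, p = contrast$p,
           adjusted_means = as.list(contrast$adjusted_means)),
      file.path(out_dir, "group_contrast.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
    files <- c(files, file.path(out_dir, "group_contrast.json"))

    # 6. moderation
    mcol <- names(markers)[[length(names(markers))]]
    moder <- tryCatch({
      fit <- fit_moderation(
        sim$cohort$delayed_recall, markers[[mcol]],
        sim$cohort$apoe_e4 == "carrier",
        covariates = sim$cohort[, config$moderation$covariates])
      jn <- johnson_neyman(fit)
      jsonlite::write_json(
        list(coefficients = as.list(coef(fit)), delta_R2 = fit$delta_R2,
             R2_full = fit$R2_full, df = fit$df,
             jn_thresholds = jn$thresholds, jn_direction = jn$direction),
        file.path(out_dir, "moderation.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      list(fit = fit, jn = jn)
    }, error = function(e) {
      logline("moderation: skipped (%s)", conditionMessage(e))
      NULL
    })
    if (!is.null(moder)) files <- c(files, file.path(out_dir, "moderation.json"))
  }

  manifest <- list(
    package = "plvnet",
    version = as.character(utils::packageVersion("plvnet")),
    config_hash = config_hash(config),
    files = lapply(stats::setNames(nm = basename(files)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logline("pipeline finished; %d artifacts", length(files))
  invisible(list(
    out_dir = out_dir, cohort_sim = sim, cbpt = cb, seed = sd_res,
    associations = assoc, group_contrast = contrast, moderation = moder,
    manifest = manifest
  ))
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(as.character(s), f, eos = NULL)
  unname(tools::md5sum(f))
}
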