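#' Build a pipeline run configuration
#'
#' Collects every stage's parameters into one serializable list.  Either
#' `simulate = TRUE` with a [sim_config()] (possibly supplied as a plain
#' list of its arguments), or input paths for genotypes, marker map and
#' pedigree.
#'
#' @param simulate simulate inputs instead of loading them.
#' @param sim a [sim_config()] or argument list for one.
#' @param genotypes,map,pedigree input paths when `simulate = FALSE`.
#' @param qtls,genes optional feature TSV paths for the overlap and
#'   cluster stages.
#' @param detector a [detector_params()] or argument list.
#' @param scan_window,scan_step sliding-scan geometry in loci.
#' @param convention quadrant convention, see [classify_selection()].
#' @param ld_max_distance_bp maximum marker separation for LD pairs.
#' @param cluster_gap_mb gene-cluster gap; `NULL` uses the fitted LD
#'   decay distance.
#' @param seed global seed; per-stage seeds are derived from it and the
#'   stage name, so adding a stage never perturbs earlier randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(),
                       genotypes = NULL, map = NULL, pedigree = NULL,
                       qtls = NULL, genes = NULL,
                       detector = detector_params(),
                       scan_window = 15L, scan_step = 1L,
                       convention = "main_text",
                       ld_max_distance_bp = 10e6,
                       cluster_gap_mb = NULL,
                       seed = 1L) {
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  if (!inherits(detector, "detector_params")) {
    detector <- do.call(detector_params, detector)
  }
  if (!simulate) {
    for (f in c("genotypes", "map", "pedigree")) {
      v <- get(f)
      if (is.null(v)) stop("run_config: '", f, "' path required when simulate = FALSE")
      if (!file.exists(v)) stop("run_config: ", f, " file not found: ", v)
    }
  }
  structure(list(simulate = simulate, sim = sim, genotypes = genotypes,
                 map = map, pedigree = pedigree, qtls = qtls, genes = genes,
                 detector = detector, scan_window = as.integer(scan_window),
                 scan_step = as.integer(scan_step), convention = convention,
                 ld_max_distance_bp = ld_max_distance_bp,
                 cluster_gap_mb = cluster_gap_mb, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML path; top-level keys are [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$detector)) y$detector <- do.call(detector_params, y$detector)
  do.call(run_config, y)
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(serialize_config(config), tmp)
  unname(tools::md5sum(tmp))
}

serialize_config <- function(config) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$selection_targets <- if (is.null(x$sim$selection_targets)) NULL else
    as.list(x$sim$selection_targets)
  x$detector <- unclass(x$detector)
  x
}

#' Run the full pedigree-dissection pipeline
#'
#' Executes simulate/load -> IBD detection -> transfer aggregation ->
#' selection scans -> LD decay -> gene clusters -> QTL overlap, writing
#' each stage's output as TSV/BED into `out_dir` together with a YAML
#' manifest recording the seed, a config fingerprint and per-stage
#' status.  Stages communicate only through their files, so each is
#' independently re-runnable; reruns with the same config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config_md5 = config_fingerprint(config),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   stages = list())
  path <- function(...) file.path(out_dir, ...)
  done <- function(stage, files) {
    manifest$stages[[stage]] <<- list(status = "ok", files = files)
  }

  tryCatch({
    # --- inputs -----------------------------------------------------------
    if (config$simulate) {
      simcfg <- config$sim
      simcfg$seed <- stage_seed(config$seed, "simulate")
      ped <- tapidor_ningyou_pedigree()
      sim <- simulate_pedigree(ped, simcfg)
      calls <- sim$calls
      map <- sim$map
      write_genotypes(calls, path("genotypes.tsv"))
      write_marker_map(map, path("map.tsv"))
      write_pedigree(ped, path("pedigree.csv"))
      truth <- do.call(rbind, lapply(final_cultivars(ped), function(d) {
        do.call(rbind, lapply(ancestors(ped, d), function(a) {
          true_ibd_segments(sim, a, d, mode = "lineage")
        }))
      }))
      write_segments_bed(truth, path("truth_segments.bed"))
      done("simulate", c("genotypes.tsv", "map.tsv", "pedigree.csv",
                         "truth_segments.bed"))
    } else {
      map <- read_marker_map(config$map)
      calls <- read_genotypes(config$genotypes, map)$calls
      ped <- read_pedigree(config$pedigree)
      done("load", c(config$genotypes, config$map, config$pedigree))
    }

    panels <- pedigree_panels(ped)
    panels <- lapply(panels, intersect, y = rownames(calls))

    # --- IBD --------------------------------------------------------------
    pairs <- do.call(rbind, lapply(names(panels), function(lbl) {
      d <- lbl
      anc <- setdiff(panels[[lbl]], d)
      data.frame(a = anc, b = d, stringsAsFactors = FALSE)
    }))
    segs <- all_pairs_ibd(calls, map, pairs, config$detector)
    write_segments_bed(segs, path("ibd.bed"))
    summ <- ibd_summary(segs)
    utils::write.table(summ$per_pair, path("ibd_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    done("ibd", c("ibd.bed", "ibd_summary.tsv"))

    # --- transfer ---------------------------------------------------------
    records <- data.frame(ancestor = summ$per_pair$sample_a,
                          descendant = summ$per_pair$sample_b,
                          n_ibd = summ$per_pair$count_total,
                          total_size_mb = summ$per_pair$length_total_mb,
                          stringsAsFactors = FALSE)
    tt <- aggregate_transfer(records, ped)
    utils::write.table(as.data.frame(tt), path("transfer.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    done("transfer", "transfer.tsv")

    # --- selection scan ---------------------------------------------------
    scan_files <- character(0)
    scans <- list()
    for (lbl in names(panels)) {
      if (length(panels[[lbl]]) < 3) next
      sc <- sliding_scan(calls, map, panels[[lbl]],
                         window = config$scan_window, step = config$scan_step)
      cls <- classify_selection(sc$D, sc$Hs, config$convention)
      sc$quadrant <- cls$quadrant
      f <- paste0("scan_", lbl, ".tsv")
      utils::write.table(sc, path(f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      scans[[lbl]] <- sc
      scan_files <- c(scan_files, f)
    }
    done("scan", scan_files)

    # --- LD ---------------------------------------------------------------
    ld <- pairwise_r2(calls, map, rownames(calls),
                      max_distance_bp = config$ld_max_distance_bp)
    utils::write.table(ld, path("ld.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    decay <- fit_decay(ld)
    yaml::write_yaml(list(beta = decay$beta,
                          decay_distance_mb = decay$decay_distance_mb,
                          mean_r2 = decay$mean_r2,
                          n_pairs = decay$n_pairs),
                     path("ld_decay.yaml"))
    done("ld", c("ld.tsv", "ld_decay.yaml"))

    # --- clusters ---------------------------------------------------------
    if (!is.null(config$genes)) {
      genes <- read_features(config$genes)
      gap <- if (is.null(config$cluster_gap_mb)) {
        if (is.finite(decay$decay_distance_mb)) decay$decay_distance_mb else 0.7
      } else config$cluster_gap_mb
      cl <- call_clusters(genes, gap_mb = gap)
      utils::write.table(cl, path("clusters.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      done("clusters", "clusters.tsv")
    }

    # --- overlap ----------------------------------------------------------
    if (!is.null(config$qtls) && !is.null(config$genes)) {
      qtls <- read_features(config$qtls)
      genes <- read_features(config$genes)
      ov <- intersect_qtl_ibd(qtls, segs)
      cand <- candidate_genes(ov$overlaps, genes, ped)
      if (length(scans)) {
        ann <- selection_annotate(cand, scans[[1]],
                                  convention = config$convention)
        cand <- ann$genes
      }
      utils::write.table(ov$overlaps, path("qtl_ibd_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cand, path("candidate_genes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      done("overlap", c("qtl_ibd_overlap.tsv", "candidate_genes.tsv"))
    }
  }, error = function(e) {
    manifest$stages[["failed"]] <<- list(status = "error",
                                         message = conditionMessage(e))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    stop(e)
  })

  yaml::write_yaml(manifest, path("manifest.yaml"))
  invisible(manifest)
}
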