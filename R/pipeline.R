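PIPELINE_STAGES <- c("synthesize", "segment", "assign", "morphometry",
                     "profiles", "compare")

#' Default pipeline configuration
#'
#' Two-group (control vs mutant) run of the full stage list with the
#' generator defaults; see [validate_config()] for the schema.
#'
#' @param outdir output directory
#' @return a `run_config` list
#' @export
default_run_config <- function(outdir = tempfile("hearttube_run")) {
  list(
    stages = PIPELINE_STAGES,
    seed = 1L,
    io = list(outdir = outdir, write_images = TRUE),
    groups = list(
      list(name = "control", n_hearts = 1L, nucleus_volume_factor = 1),
      list(name = "mutant", n_hearts = 1L, nucleus_volume_factor = 1.25)),
    synthetic = list(),
    segmentation = list(sigmas = c(2.2, 2.8, 3.4, 4.0), rel_threshold = 0.15,
                        min_separation = 6),
    assignment = list(cutoff = 20),
    morphometry = list(target_edge = 2),
    profiles = list(n_lines = 8, half_length = 3, step = 0.25,
                    regions = c("AVC", "atrium")),
    compare = list(test = "mann_whitney", reference_group = "control",
                   compartment = "AVC"))
}

#' Validate a pipeline configuration (file or list)
#'
#' Fills defaults, rejects unknown top-level keys and unknown stage names,
#' and checks numeric ranges. All problems are reported together in one
#' error.
#'
#' @param config path to a JSON config file, or a config list
#' @return a validated `run_config`
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.data.frame(config$groups))
      config$groups <- lapply(seq_len(nrow(config$groups)),
                              function(i) as.list(config$groups[i, ]))
  }
  def <- default_run_config()
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    add(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])
  bad_stage <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad_stage))
    add(sprintf("unknown stage(s) %s; valid stages: %s",
                paste(bad_stage, collapse = ", "),
                paste(PIPELINE_STAGES, collapse = ", ")))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || cfg$seed != round(cfg$seed))
    add("seed must be a single integer")
  for (g in cfg$groups) {
    if (is.null(g$name)) add("every group needs a name")
    if (!is.null(g$n_hearts) && g$n_hearts < 1) add("group n_hearts must be >= 1")
    if (!is.null(g$nucleus_volume_factor) && g$nucleus_volume_factor <= 0)
      add(sprintf("group '%s': nucleus_volume_factor must be positive",
                  g$name %||% "?"))
  }
  if (!is.null(cfg$synthetic$tube_radius_by_compartment) &&
      any(cfg$synthetic$tube_radius_by_compartment <= 0))
    add("synthetic.tube_radius_by_compartment must be strictly positive")
  if (!is.null(cfg$synthetic$spacing) && any(cfg$synthetic$spacing <= 0))
    add("synthetic.spacing must be strictly positive")
  if (cfg$segmentation$rel_threshold <= 0)
    add("segmentation.rel_threshold must be positive")
  if (cfg$assignment$cutoff <= 0) add("assignment.cutoff must be positive")
  if (cfg$morphometry$target_edge <= 0)
    add("morphometry.target_edge must be positive")
  if (cfg$profiles$n_lines < 1) add("profiles.n_lines must be >= 1")
  if (cfg$profiles$half_length < cfg$profiles$step || cfg$profiles$step <= 0)
    add("profiles: need half_length >= step > 0")
  if (!cfg$compare$test %in% c("mann_whitney", "t_test", "kruskal_wallis"))
    add(sprintf("compare.test '%s' unsupported (mann_whitney, t_test, kruskal_wallis)",
                cfg$compare$test))
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-heart quantification pipeline
#'
#' Executes the requested stages per heart (generator, nucleus segmentation
#' and measurement, compartment assignment, lumen morphometry, membrane line
#' profiles) and pools the per-group comparison. Each heart gets a derived
#' seed (`seed + 1000 * group_index + heart_index`) that is logged in the
#' report, so any heart can be replayed in isolation; a failure in one heart
#' is recorded and does not abort the batch. The run is bit-identical under
#' identical config + seed.
#'
#' @param config a `run_config`, config list, or JSON path
#' @return the run report (list), invisibly; also written as
#'   `report.json` + `nuclei.csv` in the output directory
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  outdir <- cfg$io$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  # provenance hash covers the scientific configuration, not output paths
  hash_src <- unclass(cfg)
  hash_src$io <- NULL
  hash_file <- tempfile(fileext = ".json")
  jsonlite::write_json(hash_src, hash_file, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  nuclei_all <- list()
  morpho <- list()
  profile_summ <- list()
  errors <- list()
  seeds_used <- list()

  for (gi in seq_along(cfg$groups)) {
    grp <- cfg$groups[[gi]]
    n_hearts <- as.integer(grp$n_hearts %||% 1L)
    for (hi in seq_len(n_hearts)) {
      heart_id <- sprintf("%s_%02d", grp$name, hi)
      heart_seed <- as.integer(cfg$seed + 1000L * gi + hi)
      seeds_used[[heart_id]] <- heart_seed
      res <- tryCatch(
        run_one_heart(cfg, grp, heart_id, heart_seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[heart_id]] <- conditionMessage(res)
        next
      }
      if (!is.null(res$nuclei)) nuclei_all[[heart_id]] <- res$nuclei
      if (!is.null(res$morphometry)) morpho[[heart_id]] <- res$morphometry
      if (!is.null(res$profiles)) profile_summ[[heart_id]] <- res$profiles
    }
  }

  nuclei <- if (length(nuclei_all)) do.call(rbind, c(nuclei_all, make.row.names = FALSE)) else NULL
  comparisons <- list()
  group_summaries <- list()
  if (!is.null(nuclei) && "compare" %in% cfg$stages && length(cfg$groups) >= 2) tryCatch({
    comp <- cfg$compare$compartment
    sub <- nuclei[nuclei$compartment == comp, , drop = FALSE]
    if (nrow(sub)) {
      sub <- normalize_volumes(sub, cfg$compare$reference_group, comp)
      by_group <- split(sub$volume_um3, sub$group)
      group_summaries <- lapply(names(by_group), function(g) list(
        group = g, compartment = comp, n = length(by_group[[g]]),
        mean_volume_um3 = mean(by_group[[g]]),
        normalized_mean = mean(sub$volume_norm[sub$group == g])))
      names(group_summaries) <- names(by_group)
      if (length(by_group) >= 2 && all(lengths(by_group) >= 2)) {
        tst <- run_group_test(
          if (cfg$compare$test == "kruskal_wallis") by_group else by_group[1:2],
          cfg$compare$test)
        comparisons[[paste(names(by_group)[1:2], collapse = "_vs_")]] <- unclass(tst)
      }
      nuclei <- sub_merge_norm(nuclei, sub)
    }
  }, error = function(e) {
    errors[["comparison"]] <<- conditionMessage(e)
  })

  report <- list(
    provenance = list(config_hash = cfg_hash, seed = cfg$seed,
                      package_version = as.character(packageVersion("hearttube")),
                      heart_seeds = seeds_used),
    groups = group_summaries,
    morphometry = morpho,
    profiles = profile_summ,
    comparisons = comparisons,
    errors = errors)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(nuclei))
    write.csv(nuclei, file.path(outdir, "nuclei.csv"), row.names = FALSE)
  invisible(report)
}

sub_merge_norm <- function(nuclei, sub) {
  nuclei$volume_norm <- NA_real_
  key_all <- paste(nuclei$heart_id, nuclei$id)
  key_sub <- paste(sub$heart_id, sub$id)
  nuclei$volume_norm[match(key_sub, key_all)] <- sub$volume_norm
  nuclei
}

run_one_heart <- function(cfg, grp, heart_id, heart_seed) {
  syn_args <- cfg$synthetic
  syn_args$seed <- heart_seed
  syn_args$group <- grp$name
  if (!is.null(grp$nucleus_volume_factor))
    syn_args$nucleus_volume_factor <- grp$nucleus_volume_factor
  heart <- do.call(synthetic_config, syn_args)
  heart <- synthesize_heart(heart)
  out <- list()
  heart_dir <- file.path(cfg$io$outdir, heart_id)
  if (isTRUE(cfg$io$write_images) && "synthesize" %in% cfg$stages)
    write_synthetic_heart(heart, heart_dir)
  if (!"segment" %in% cfg$stages && !"assign" %in% cfg$stages &&
      !"morphometry" %in% cfg$stages && !"profiles" %in% cfg$stages)
    return(out)

  with_local_seed(heart_seed + 500000L, {
    if ("segment" %in% cfg$stages) {
      seg <- segment_heart_nuclei(
        heart$nuclear, sigmas = cfg$segmentation$sigmas,
        rel_threshold = cfg$segmentation$rel_threshold,
        min_separation = cfg$segmentation$min_separation)
      nuc <- seg$nuclei
      if ("assign" %in% cfg$stages && nrow(nuc)) {
        nuc <- assign_compartment(
          nuc, heart$truth, cutoff = cfg$assignment$cutoff,
          tube_radius = heart$config$tube_radius_by_compartment)
      }
      if (nrow(nuc)) {
        nuc$group <- grp$name
        nuc$heart_id <- heart_id
      }
      out$nuclei <- nuc
      if (isTRUE(cfg$io$write_images))
        write.csv(nuc, file.path(heart_dir, "nuclei.csv"), row.names = FALSE)
    }
    if ("morphometry" %in% cfg$stages) {
      m <- heart_morphometry(heart$compartments,
                             target_edge = cfg$morphometry$target_edge)
      out$morphometry <- list(
        heart_id = heart_id, avc_length = m$avc_length,
        straight_distance = m$straight_distance,
        central_line_length = m$central_line_length,
        convolutedness = m$convolutedness)
      if (isTRUE(cfg$io$write_images)) {
        jsonlite::write_json(out$morphometry,
                             file.path(heart_dir, "morphometry.json"),
                             auto_unbox = TRUE, digits = NA)
        write.csv(data.frame(z_um = m$central_line[, 1],
                             y_um = m$central_line[, 2],
                             x_um = m$central_line[, 3]),
                  file.path(heart_dir, "central_line.csv"), row.names = FALSE)
      }
    }
    if ("profiles" %in% cfg$stages) {
      pr <- lapply(cfg$profiles$regions, function(rg) {
        # oversample anchors: the planar normal fit rejects some of them
        anchors <- membrane_anchors(heart$membrane_regions,
                                    4L * cfg$profiles$n_lines, rg)
        nr <- suppressWarnings(estimate_normals(heart$membrane_regions, anchors))
        keep <- seq_len(min(cfg$profiles$n_lines, nrow(nr$anchors)))
        if (!length(keep))
          return(list(region = rg, n_lines = 0L, mean_max_intensity = NA_real_))
        lp <- sample_line_profiles(
          heart$membrane, nr$anchors[keep, , drop = FALSE],
          nr$normals[keep, , drop = FALSE],
          half_length = cfg$profiles$half_length, step = cfg$profiles$step,
          region_labels = heart$membrane_regions)
        list(region = rg, n_lines = nrow(lp$lines),
             mean_max_intensity = mean(lp$lines$max_intensity))
      })
      names(pr) <- cfg$profiles$regions
      out$profiles <- pr
    }
  })
  out
}
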