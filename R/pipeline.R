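# Pipeline orchestration: a single YAML config names the input trajectory,
# named atom selections, the stages to run and their parameters; stages
# execute in dependency order (superpose -> pca -> domains, then the
# independent contact and energy stages), every table is written as
# tab-separated text, and a run report echoes parameters and outputs.
# Deterministic numerics and the fixed eigenvector sign convention make
# two runs on the same inputs byte-identical.

.stage_names <- c("superpose", "pca", "domains", "hbonds", "hydration",
                  "coord", "channel", "energy")

.stage_defaults <- list(
  superpose = list(selection = "all", equilibration_drop = NULL,
                   ref_frame = 1),
  pca = list(selection = "all", equilibration_drop = NULL, modes = 2,
             interpolants = 0),
  domains = list(window = 5, min_domain = 20, cluster_radius = 5,
                 linkage = "complete", mode = 1, extreme_average = 1),
  hbonds = list(donors = NULL, acceptors = NULL, mode = "distance-only",
                d_cut = 3.5, angle_cut = 120),
  hydration = list(region_center = NULL, region_radius = 8, grid = 1.0,
                   occ_threshold = 0.40, merge_radius = 1.5,
                   gap_tolerance = 2),
  coord = list(center = NULL, partners = NULL, cutoff = 3.0),
  channel = list(set_a = NULL, set_b = NULL, entrance = NULL,
                 frame = 1, axis = "auto"),
  energy = list(receptor = NULL, ligand = NULL, snapshot_stride = 1,
                entropy_stride = 5, temperature = 300,
                entropy = "quasiharmonic", sasa_points = 240,
                parameter_table = NULL, decompose = FALSE,
                threshold_fraction = 1.4))

#' Validate a pipeline configuration file
#'
#' Reads the YAML config, rejects unknown keys, fills every documented
#' default, resolves relative paths against the config file's directory
#' and checks that stage selections refer to entries of the `selections`
#' map.
#'
#' @param path YAML config path.
#' @return validated config list of class `analysis_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("validate_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  known_top <- c("input", "dialect", "output_dir", "seed", "selections",
                 "stages")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown) > 0)
    stop("validate_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(raw$input)) stop("validate_config: 'input' is required")
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)
  cfg <- list(
    input = resolve(raw$input),
    dialect = if (is.null(raw$dialect)) "frame-dump" else raw$dialect,
    output_dir = resolve(if (is.null(raw$output_dir)) "trajscope_out"
                         else raw$output_dir),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    selections = if (is.null(raw$selections)) list(all = "resid 1-999999")
                 else raw$selections,
    stages = list())
  if (!("all" %in% names(cfg$selections)))
    cfg$selections$all <- "resid 1-999999"
  if (!file.exists(cfg$input))
    stop("validate_config: input file not found: ", cfg$input)
  if (!(cfg$dialect %in% c("pdb-multimodel", "frame-dump")))
    stop("validate_config: unknown dialect '", cfg$dialect, "'")
  stages <- raw$stages
  if (is.null(stages)) stages <- list(superpose = list(), pca = list())
  unknown_st <- setdiff(names(stages), .stage_names)
  if (length(unknown_st) > 0)
    stop("validate_config: unknown stage(s): ",
         paste(unknown_st, collapse = ", "))
  for (st in names(stages)) {
    given <- stages[[st]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), names(.stage_defaults[[st]]))
    if (length(bad) > 0)
      stop("validate_config: stage '", st, "' has unknown parameter(s): ",
           paste(bad, collapse = ", "))
    merged <- .stage_defaults[[st]]
    merged[names(given)] <- given
    # every selection-valued parameter must resolve in the selections map
    sel_params <- c("selection", "donors", "acceptors", "partners",
                    "set_a", "set_b", "entrance", "receptor", "ligand",
                    "region_center", "center")
    for (pkey in intersect(sel_params, names(merged))) {
      v <- merged[[pkey]]
      if (is.character(v) && length(v) == 1 &&
          !(v %in% names(cfg$selections)))
        stop("validate_config: stage '", st, "' references unknown ",
             "selection '", v, "'")
    }
    cfg$stages[[st]] <- merged
  }
  structure(cfg, class = "analysis_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order.  The PCA extreme
#' conformers feed the domain stage automatically; a failure in one
#' independent stage is recorded in the report without aborting the
#' others.
#'
#' @param config an [validate_config()] result (or a path to a config).
#' @return run report of class `run_report`: per-stage `status`,
#'   parameter echo, `outputs` file inventory and wall time.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "analysis_config"))
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  traj <- read_structure(config$input, config$dialect)
  sel_of <- function(name) select(traj$top, config$selections[[name]],
                                  label = name)
  report <- list()
  outputs <- character(0)
  note <- function(st, status, files = character(0), detail = "") {
    report[[st]] <<- list(status = status,
                          parameters = config$stages[[st]],
                          outputs = files, detail = detail)
    outputs <<- c(outputs, files)
  }
  run_stage <- function(st, fun) {
    if (!(st %in% names(config$stages))) return(invisible(NULL))
    tryCatch(fun(config$stages[[st]]),
             error = function(e) note(st, "failed",
                                      detail = conditionMessage(e)))
  }

  run_stage("superpose", function(p) {
    sel <- sel_of(p$selection)
    rs <- rmsd_series(traj, p$ref_frame, sel)
    f1 <- file.path(config$output_dir, "rmsd.tsv")
    write.table(data.frame(time_ps = traj$times, rmsd_A = format(rs,
                digits = 8)), f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    prof <- rmsf(traj, sel, p$equilibration_drop)
    f2 <- file.path(config$output_dir, "fluctuations.tsv")
    write_fluctuation_profile(prof, f2)
    note("superpose", "ok", c(f1, f2))
  })

  pca_state <- NULL
  run_stage("pca", function(p) {
    sel <- sel_of(p$selection)
    model <- build_covariance(traj, sel, p$equilibration_drop)
    modes <- seq_len(p$modes)
    series <- project(traj, model, modes)
    files <- write_pca_tables(model, series, config$output_dir)
    pca_state <<- list(model = model, series = series)
    note("pca", "ok", files)
  })

  run_stage("domains", function(p) {
    if (is.null(pca_state))
      stop("domains stage needs the pca stage")
    ext <- extreme_conformers(pca_state$series, traj, pca_state$model,
                              p$mode, average = p$extreme_average)
    sel <- pca_state$model$selection
    confA <- ext$min_structure
    confB <- ext$max_structure
    resid <- traj$top$atoms$resid[sel$indices]
    field <- local_rotation_field(confA, confB, resid, p$window)
    part <- partition_domains(field, p$min_domain, p$cluster_radius,
                              p$linkage)
    hinges <- lapply(seq_along(part$moving_domains), function(k)
      hinge_parameters(confA, confB, part, k, resid))
    f1 <- file.path(config$output_dir, "hinges.tsv")
    write_hinge_table(hinges, f1, pc = p$mode)
    note("domains", "ok", f1)
  })

  run_stage("hbonds", function(p) {
    hb <- hbond_scan(traj, sel_of(p$donors), sel_of(p$acceptors),
                     p$mode, p$d_cut, p$angle_cut)
    f1 <- file.path(config$output_dir, "hbonds.tsv")
    df <- do.call(rbind, lapply(hb, function(s)
      data.frame(donor = s$donor_label, acceptor = s$acceptor_label,
                 occupancy = s$occupancy,
                 mean_distance_A = mean(s$distance))))
    if (is.null(df)) df <- data.frame(donor = character(0))
    write.table(format(df, digits = 6), f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("hbonds", "ok", f1)
  })

  run_stage("hydration", function(p) {
    ctr <- if (is.character(p$region_center)) sel_of(p$region_center)
           else as.numeric(p$region_center)
    sites <- hydration_sites(traj, ctr, p$region_radius, p$grid,
                             p$occ_threshold, p$merge_radius,
                             p$gap_tolerance)
    f1 <- file.path(config$output_dir, "hydration_sites.tsv")
    df <- do.call(rbind, lapply(seq_along(sites), function(k)
      data.frame(site = k, x = sites[[k]]$centroid[1],
                 y = sites[[k]]$centroid[2], z = sites[[k]]$centroid[3],
                 occupancy = sites[[k]]$occupancy,
                 longest_residence_ns = sites[[k]]$longest_residence_ns)))
    if (is.null(df)) df <- data.frame(site = integer(0))
    write.table(format(df, digits = 6), f1, sep = "\t", quote = FALSE,
                row.names = FALSE)
    note("hydration", "ok", f1)
  })

  run_stage("coord", function(p) {
    ctr_sel <- sel_of(p$center)
    rep_c <- coordination_geometry(traj, ctr_sel$indices[1],
                                   sel_of(p$partners), p$cutoff)
    f1 <- file.path(config$output_dir, "coordination.tsv")
    write.table(format(rep_c$pairs, digits = 6), f1, sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("coord", "ok", f1)
  })

  run_stage("channel", function(p) {
    cm <- channel_metrics(traj, p$frame, sel_of(p$set_a), sel_of(p$set_b),
                          sel_of(p$entrance), p$axis)
    f1 <- file.path(config$output_dir, "channel.tsv")
    write.table(data.frame(centroid_distance_A =
                             sprintf("%.4f", cm$centroid_distance),
                           entrance_area_A2 =
                             sprintf("%.4f", cm$entrance_area)),
                f1, sep = "\t", quote = FALSE, row.names = FALSE)
    note("channel", "ok", f1)
  })

  run_stage("energy", function(p) {
    top <- traj$top
    if (!is.null(p$parameter_table)) {
      tab <- read_parameter_table(p$parameter_table)
      top <- assign_parameters(top, tab, strict = TRUE)
      traj <- trajectory(top, traj$xyz, traj$times)
    }
    rec <- sel_of(p$receptor)
    lig <- sel_of(p$ligand)
    rep_e <- mmgbsa_binding(traj, rec, lig, p$snapshot_stride,
                            p$entropy_stride, p$temperature, p$entropy,
                            p$sasa_points)
    f1 <- file.path(config$output_dir, "binding_report.tsv")
    write_binding_report(rep_e, f1)
    files <- f1
    if (isTRUE(p$decompose)) {
      dec <- decompose_per_residue(traj, rec, lig, "receptor",
                                   p$threshold_fraction,
                                   p$snapshot_stride)
      f2 <- file.path(config$output_dir, "per_residue.tsv")
      write.table(format(as.data.frame(dec), digits = 6), f2, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      files <- c(files, f2)
    }
    note("energy", "ok", files)
  })

  structure(list(stages = report, outputs = outputs,
                 config = config,
                 wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs"))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run:", length(x$stages), "stage(s),",
      sprintf("%.2f s\n", x$wall_time_s))
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    cat(sprintf("  %-10s %s %s\n", st, s$status,
                if (s$status == "failed") paste0("(", s$detail, ")")
                else paste(basename(s$outputs), collapse = ", ")))
  }
  invisible(x)
}
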