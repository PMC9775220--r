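# End-to-end orchestration: one subcommand per analysis stage, a YAML (or
# in-memory list) configuration, and a JSON run manifest that suffices to
# re-run the identical computation.

.stop_input <- function(msg) {
  stop(structure(class = c("loopdyn_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.stop_validation <- function(msg) {
  stop(structure(class = c("loopdyn_validation_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}

# Allowed keys per subcommand (TRUE = required).
.pipeline_schemas <- list(
  "simulate" = c(subcommand = TRUE, output_dir = TRUE, seed = TRUE,
                 n_models = TRUE, f_closed = TRUE, n_core_residues = FALSE,
                 loop_residue_count = FALSE, closed_distance = FALSE,
                 open_distance = FALSE, jitter_sd = FALSE, s_min = FALSE,
                 s_max = FALSE, n_s = FALSE, relative_sd = FALSE,
                 floor = FALSE),
  "saxs-curve" = c(subcommand = TRUE, output_dir = TRUE, pool_pdb = TRUE,
                   s_min = FALSE, s_max = FALSE, n_s = FALSE,
                   form_factor = FALSE),
  "saxs-fit" = c(subcommand = TRUE, output_dir = TRUE, seed = TRUE,
                 pool_pdb = TRUE, profile = TRUE, n_se = FALSE,
                 pop_size = FALSE, generations = FALSE,
                 mutation_rate = FALSE, s_unit = FALSE),
  "classify" = c(subcommand = TRUE, output_dir = TRUE, pool_pdb = TRUE,
                 loop_first = TRUE, loop_last = TRUE, site_chain = TRUE,
                 site_resno = TRUE, site_elety = TRUE, threshold = FALSE),
  "popscan" = c(subcommand = TRUE, output_dir = TRUE, pool_pdb = TRUE,
                profile = TRUE, loop_first = TRUE, loop_last = TRUE,
                site_chain = TRUE, site_resno = TRUE, site_elety = TRUE,
                f_step = FALSE, s_unit = FALSE),
  "rmsf" = c(subcommand = TRUE, output_dir = TRUE, traj_pdb = TRUE,
             align = FALSE),
  "dcc" = c(subcommand = TRUE, output_dir = TRUE, traj_pdb = TRUE,
            stride = FALSE),
  "network" = c(subcommand = TRUE, output_dir = TRUE, traj_pdb = TRUE,
                cutoff = FALSE, weighting = FALSE, stride = FALSE),
  "paths" = c(subcommand = TRUE, output_dir = TRUE, traj_pdb = TRUE,
              source = TRUE, target = TRUE, k = FALSE, cutoff = FALSE,
              weighting = FALSE, stride = FALSE),
  "pathdelta" = c(subcommand = TRUE, output_dir = TRUE, traj_pdb_a = TRUE,
                  traj_pdb_b = TRUE, pairs_csv = TRUE, cutoff = FALSE,
                  weighting = FALSE, stride = FALSE),
  "dockhist" = c(subcommand = TRUE, output_dir = TRUE, pose_dir = TRUE,
                 score_csv = TRUE, site_x = TRUE, site_y = TRUE,
                 site_z = TRUE, metric = FALSE, bin_width = FALSE,
                 range_lo = FALSE, range_hi = FALSE),
  "struct-compare" = c(subcommand = TRUE, output_dir = TRUE, pdb_a = TRUE,
                       pdb_b = TRUE, chain = FALSE, cell_volume = FALSE,
                       molecules_per_cell = FALSE, molecular_mass = FALSE,
                       res_a = FALSE, res_b = FALSE)
)

.validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stop_input(paste("config not found:",
                                                config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .stop_validation("config must be a list/YAML map")
  if (is.null(config$subcommand)) .stop_validation("missing key: subcommand")
  schema <- .pipeline_schemas[[config$subcommand]]
  if (is.null(schema)) {
    .stop_validation(paste("unknown subcommand:", config$subcommand))
  }
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0L) {
    .stop_validation(paste("unknown config key(s):",
                           paste(unknown, collapse = ", ")))
  }
  missing_req <- setdiff(names(schema)[schema], names(config))
  if (length(missing_req) > 0L) {
    .stop_validation(paste("missing required key(s):",
                           paste(missing_req, collapse = ", ")))
  }
  config
}

.require_file <- function(path, what) {
  if (!file.exists(path)) .stop_input(sprintf("%s not found: %s", what,
                                              path))
  path
}

.default_s_grid <- function(cfg) {
  seq(if (is.null(cfg$s_min)) 0.01 else cfg$s_min,
      if (is.null(cfg$s_max)) 0.30 else cfg$s_max,
      length.out = if (is.null(cfg$n_s)) 100L else cfg$n_s)
}

.cfg_site <- function(cfg) {
  list(chain = cfg$site_chain, resno = cfg$site_resno,
       elety = cfg$site_elety)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.classify_pool <- function(cfg) {
  ens <- read_pdb_models(.require_file(cfg$pool_pdb, "pool PDB"))
  d <- loop_site_distance(ens, c(cfg$loop_first, cfg$loop_last),
                          .cfg_site(cfg))
  st <- if (is.null(cfg$threshold)) classify_states(d) else
    classify_states(d, method = "threshold", threshold = cfg$threshold)
  list(ens = ens, states = st)
}

.pipeline_handlers <- list(
  "simulate" = function(cfg, out) {
    spec_args <- cfg[intersect(names(cfg),
                               c("n_core_residues", "loop_residue_count",
                                 "closed_distance", "open_distance",
                                 "jitter_sd"))]
    spec <- do.call(toy_protein_spec, spec_args)
    gen <- make_two_state_ensemble(cfg$n_models, cfg$f_closed, spec,
                                   seed = cfg$seed)
    s_grid <- .default_s_grid(cfg)
    nm <- noise_model(
      relative_sd = if (is.null(cfg$relative_sd)) 0.02 else cfg$relative_sd,
      floor = if (is.null(cfg$floor)) 0 else cfg$floor)
    prof <- simulate_saxs_profile(gen$ensemble, s_grid, noise = nm,
                                  seed = cfg$seed + 1L)
    write_pdb_models(gen$ensemble, file.path(out, "pool.pdb"))
    write_saxs_profile(prof, file.path(out, "profile.dat"))
    jsonlite::write_json(list(labels = gen$labels,
                              distances = gen$distances,
                              f_closed = cfg$f_closed),
                         file.path(out, "truth.json"), digits = NA)
    list(outputs = c("pool.pdb", "profile.dat", "truth.json"),
         results = list(n_closed = sum(gen$labels == "closed")))
  },
  "saxs-curve" = function(cfg, out) {
    ens <- read_pdb_models(.require_file(cfg$pool_pdb, "pool PDB"))
    ff <- if (is.null(cfg$form_factor)) "uniform" else cfg$form_factor
    curves <- pool_debye_curves(ens, .default_s_grid(cfg), form_factor = ff)
    avg <- ensemble_average_curve(curves)
    write_saxs_profile(avg, file.path(out, "curve.dat"))
    list(outputs = "curve.dat", results = list(i0 = avg$intensity[1]))
  },
  "saxs-fit" = function(cfg, out) {
    ens <- read_pdb_models(.require_file(cfg$pool_pdb, "pool PDB"))
    prof <- read_saxs_profile(.require_file(cfg$profile, "SAXS profile"),
                              s_unit = if (is.null(cfg$s_unit)) "invA"
                                       else cfg$s_unit)
    curves <- pool_debye_curves(ens, prof$s)
    sel <- select_subensemble(
      curves, prof,
      n_se = if (is.null(cfg$n_se)) 20L else cfg$n_se, seed = cfg$seed,
      pop_size = if (is.null(cfg$pop_size)) 100L else cfg$pop_size,
      generations = if (is.null(cfg$generations)) 200L else
        cfg$generations,
      mutation_rate = if (is.null(cfg$mutation_rate)) 0.1 else
        cfg$mutation_rate)
    .write_tsv(data.frame(member = sel$member_indices),
               file.path(out, "selection.tsv"))
    list(outputs = "selection.tsv",
         results = list(chi2 = sel$chi2, scale = sel$scale,
                        pool_chi2 = sel$pool_chi2, n_se = sel$size))
  },
  "classify" = function(cfg, out) {
    cl <- .classify_pool(cfg)
    .write_tsv(data.frame(model = seq_along(cl$states$labels),
                          d_loop_site = cl$states$d_loop_site,
                          label = cl$states$labels),
               file.path(out, "states.tsv"))
    list(outputs = "states.tsv",
         results = list(boundary = cl$states$boundary,
                        n_closed = sum(cl$states$labels == "closed")))
  },
  "popscan" = function(cfg, out) {
    cl <- .classify_pool(cfg)
    prof <- read_saxs_profile(.require_file(cfg$profile, "SAXS profile"),
                              s_unit = if (is.null(cfg$s_unit)) "invA"
                                       else cfg$s_unit)
    curves <- pool_debye_curves(cl$ens, prof$s)
    closed <- which(cl$states$labels == "closed")
    open <- which(cl$states$labels == "open")
    if (length(closed) == 0L || length(open) == 0L) {
      .stop_input("population scan needs both closed and open conformers")
    }
    fit <- population_scan(ensemble_average_curve(curves[closed]),
                           ensemble_average_curve(curves[open]), prof,
                           f_step = if (is.null(cfg$f_step)) 0.01 else
                             cfg$f_step)
    .write_tsv(data.frame(f_closed = fit$f_grid, chi2 = fit$chi2_of_f),
               file.path(out, "scan.tsv"))
    list(outputs = "scan.tsv",
         results = list(best_f = fit$best_f, best_chi2 = fit$best_chi2))
  },
  "rmsf" = function(cfg, out) {
    traj <- read_pdb_models(.require_file(cfg$traj_pdb, "trajectory PDB"))
    v <- rmsf(traj, align = if (is.null(cfg$align)) TRUE else cfg$align)
    .write_tsv(data.frame(residue = names(v), rmsf = unname(v)),
               file.path(out, "rmsf.tsv"))
    list(outputs = "rmsf.tsv", results = list(mean_rmsf = mean(v)))
  },
  "dcc" = function(cfg, out) {
    traj <- read_pdb_models(.require_file(cfg$traj_pdb, "trajectory PDB"))
    dcc <- dcc_matrix(traj, stride = if (is.null(cfg$stride)) 1L else
      cfg$stride)
    utils::write.table(dcc$values, file.path(out, "dcc.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    list(outputs = "dcc.tsv",
         results = list(mean_abs_offdiag =
                          mean(abs(dcc$values[upper.tri(dcc$values)]))))
  },
  "network" = function(cfg, out) {
    net <- .traj_network(cfg)
    write_network(net, file.path(out, "edges.tsv"))
    list(outputs = "edges.tsv",
         results = list(n_edges = igraph::ecount(net$graph)))
  },
  "paths" = function(cfg, out) {
    net <- .traj_network(cfg)
    ps <- shortest_paths_k(net, cfg$source, cfg$target,
                           k = if (is.null(cfg$k)) 15L else cfg$k)
    df <- data.frame(
      rank = seq_along(ps$lengths), length = ps$lengths,
      path = vapply(ps$paths, paste, character(1), collapse = ">"))
    .write_tsv(df, file.path(out, "paths.tsv"))
    list(outputs = "paths.tsv",
         results = list(reachable = ps$reachable,
                        optimal_length = if (ps$reachable) ps$lengths[1]
                                         else NA))
  },
  "pathdelta" = function(cfg, out) {
    neta <- .traj_network(cfg, key = "traj_pdb_a")
    netb <- .traj_network(cfg, key = "traj_pdb_b")
    pairs <- utils::read.csv(.require_file(cfg$pairs_csv, "pairs CSV"),
                             stringsAsFactors = FALSE)
    tab <- path_delta_ranking(neta, netb, pairs)
    .write_tsv(tab, file.path(out, "path_delta.tsv"))
    .write_tsv(attr(tab, "participation"),
               file.path(out, "participation.tsv"))
    list(outputs = c("path_delta.tsv", "participation.tsv"),
         results = list(most_shortened = tab$delta[1]))
  },
  "dockhist" = function(cfg, out) {
    ps <- read_pose_set(.require_file(cfg$pose_dir, "pose directory"),
                        .require_file(cfg$score_csv, "score CSV"))
    d <- pose_site_distances(ps, c(cfg$site_x, cfg$site_y, cfg$site_z),
                             metric = if (is.null(cfg$metric)) "min-atom"
                                      else cfg$metric)
    h <- distance_histogram(
      d, bin_width = if (is.null(cfg$bin_width)) 0.5 else cfg$bin_width,
      range = c(if (is.null(cfg$range_lo)) 2 else cfg$range_lo,
                if (is.null(cfg$range_hi)) 20 else cfg$range_hi),
      scores = ps$scores$score_kcal_mol)
    .write_tsv(h$score_summary, file.path(out, "histogram.tsv"))
    list(outputs = "histogram.tsv",
         results = list(n_poses = length(d), overflow = h$overflow,
                        mode_bin_lo =
                          h$score_summary$bin_lo[which.max(h$counts)]))
  },
  "struct-compare" = function(cfg, out) {
    ch <- if (is.null(cfg$chain)) "A" else cfg$chain
    ea <- read_pdb_models(.require_file(cfg$pdb_a, "PDB A"))
    eb <- read_pdb_models(.require_file(cfg$pdb_b, "PDB B"))
    ca_a <- select_subset(ea, chain = ch, atom_names = "CA")
    ca_b <- select_subset(eb, chain = ch, atom_names = "CA")
    common <- intersect(atom_keys(ca_a$atoms), atom_keys(ca_b$atoms))
    ia <- match(common, atom_keys(ca_a$atoms))
    ib <- match(common, atom_keys(ca_b$atoms))
    sup <- kabsch_superpose_rmsd(conf_coords(ca_a)[ia, , drop = FALSE],
                                 conf_coords(ca_b)[ib, , drop = FALSE])
    results <- list(ca_rmsd = sup$rmsd, n_paired = length(common))
    if (!is.null(cfg$res_a) && !is.null(cfg$res_b)) {
      results$min_distance_a <- min_residue_distance(
        ea, list(chain = ch, resno = cfg$res_a),
        list(chain = ch, resno = cfg$res_b))
      results$min_distance_b <- min_residue_distance(
        eb, list(chain = ch, resno = cfg$res_a),
        list(chain = ch, resno = cfg$res_b))
    }
    if (!is.null(cfg$cell_volume)) {
      mt <- matthews_solvent(cfg$cell_volume, cfg$molecules_per_cell,
                             cfg$molecular_mass)
      results$vm <- mt$vm
      results$solvent_pct <- mt$solvent_pct
    }
    asa <- shrake_rupley_asa(ea)
    .write_tsv(asa, file.path(out, "asa_a.tsv"))
    jsonlite::write_json(results, file.path(out, "compare.json"),
                         auto_unbox = TRUE, digits = NA)
    list(outputs = c("asa_a.tsv", "compare.json"), results = results)
  }
)

.traj_network <- function(cfg, key = "traj_pdb") {
  traj <- read_pdb_models(.require_file(cfg[[key]], "trajectory PDB"))
  dcc <- dcc_matrix(traj, stride = if (is.null(cfg$stride)) 1L else
    cfg$stride)
  mean_xyz <- matrix(colMeans(traj$xyz), 1L)
  mean_structure <- new_confens(traj$atoms, mean_xyz)
  build_network(mean_structure, dcc,
                cutoff = if (is.null(cfg$cutoff)) 4.5 else cfg$cutoff,
                weighting = if (is.null(cfg$weighting)) "neglog" else
                  cfg$weighting)
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches on `config$subcommand` (one verb per analysis stage:
#' `simulate`, `saxs-curve`, `saxs-fit`, `classify`, `popscan`, `rmsf`,
#' `dcc`, `network`, `paths`, `pathdelta`, `dockhist`, `struct-compare`),
#' validates the configuration against the subcommand's schema (unknown
#' keys are rejected; a seed is mandatory for every stochastic stage),
#' writes the stage outputs plus a JSON manifest recording input hashes,
#' parameters, seed and package version, and returns the manifest.  Runs
#' are idempotent given identical configuration and seed.
#'
#' @param config a named list, or the path of a YAML file with the same
#'   keys
#' @return invisibly, a list with `status` (0 on success) and `manifest`
#' @export
run_pipeline <- function(config) {
  cfg <- .validate_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- .pipeline_handlers[[cfg$subcommand]](cfg, out)
  input_keys <- intersect(names(cfg),
                          c("pool_pdb", "profile", "traj_pdb", "traj_pdb_a",
                            "traj_pdb_b", "pairs_csv", "score_csv",
                            "pdb_a", "pdb_b"))
  hashes <- lapply(cfg[input_keys], function(p) unname(tools::md5sum(p)))
  manifest <- list(
    subcommand = cfg$subcommand,
    parameters = cfg[setdiff(names(cfg), c("subcommand", "output_dir"))],
    seed = cfg$seed,
    input_md5 = hashes,
    outputs = res$outputs,
    results = res$results,
    package_version = as.character(utils::packageVersion("loopdyn")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(status = 0L, manifest = manifest))
}
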