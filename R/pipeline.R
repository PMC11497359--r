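#' Read a pipeline run configuration
#'
#' The run configuration is a YAML file with any of the blocks:
#' \describe{
#'   \item{domains}{list of `{domain, chain, start, end}` intervals.}
#'   \item{systems}{list of `{focal, co, structure, trajectory}` entries; the
#'     structure is a PDB file whose `HETATM` records are the ligand copies
#'     (species = residue name), the trajectory a frame-table CSV.}
#'   \item{tracks}{list of `{condition, path}` track-table CSVs.}
#'   \item{params}{analysis parameters: `cutoff_nm` (0.7), `interval_ps`
#'     (100), `equilibration_ps` (3000), `atom_selection` ("calpha"),
#'     `hotspot_k` (1).}
#'   \item{output_dir}{where [run_pipeline()] writes its report.}
#' }
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path Path to the YAML configuration.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  for (i in seq_along(cfg$systems)) {
    cfg$systems[[i]]$structure <- fix(cfg$systems[[i]]$structure)
    cfg$systems[[i]]$trajectory <- fix(cfg$systems[[i]]$trajectory)
  }
  for (i in seq_along(cfg$tracks)) {
    cfg$tracks[[i]]$path <- fix(cfg$tracks[[i]]$path)
  }
  if (!is.null(cfg$output_dir)) cfg$output_dir <- fix(cfg$output_dir)
  new_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A list in the layout above.
#' @export
new_run_config <- function(cfg) {
  defaults <- list(cutoff_nm = 0.7, interval_ps = 100,
                   equilibration_ps = 3000, atom_selection = "calpha",
                   hotspot_k = 1)
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  with(cfg$params, stopifnot(cutoff_nm > 0, interval_ps > 0,
                             equilibration_ps >= 0, hotspot_k >= 0))
  for (s in cfg$systems) {
    for (p in c(s$structure, s$trajectory)) {
      if (!file.exists(p)) stop("Missing input file: ", p, call. = FALSE)
    }
  }
  for (t in cfg$tracks) {
    if (!file.exists(t$path)) stop("Missing input file: ", t$path, call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

.param_header <- function(params) {
  paste0("# ", names(params), " = ",
         vapply(params, function(x) paste(format(x), collapse = " "), ""))
}

.write_report_csv <- function(df, path, params) {
  cat(paste0(paste(.param_header(params), collapse = "\n"), "\n",
             readr::format_csv(df)),
      file = path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, for every configured system, the domain RMSD series, the
#' per-residue RMSF with domain box statistics, and the contact analysis
#' (per-residue averages, domain contact numbers, per-domain competition
#' matrices, hotspots, and a B-factor-annotated PDB per system); and, for
#' every configured track table, the per-cell kinematics with per-condition
#' summaries and pairwise Mann-Whitney comparisons. Stages without inputs
#' are skipped. All tables are written as tidy CSV with a `#`-comment header
#' recording the parameters, plus a manifest with an MD5 checksum per output
#' file; a rerun on unchanged inputs reproduces identical bytes.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param output_dir Output directory (default from the config); created if
#'   needed.
#' @return A `pipeline_report` list of the result tables and output paths.
#' @export
run_pipeline <- function(config, output_dir = config$output_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(output_dir)) stop("No output directory given.", call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  map <- if (!is.null(config$domains)) {
    build_domain_map(dplyr::bind_rows(lapply(config$domains, tibble::as_tibble)))
  }
  report <- list(params = p, files = character(0))
  add_file <- function(path) report$files <<- c(report$files, path)

  if (length(config$systems) > 0L) {
    if (is.null(map)) stop("Systems given but no domain spec.", call. = FALSE)
    sys_tbl <- purrr::map_dfr(config$systems, function(s) {
      tibble::tibble(focal = s$focal,
                     co = s$co %||% s$focal,
                     structure_path = s$structure,
                     trajectory_path = s$trajectory)
    })
    rmsd_all <- list(); rmsf_all <- list(); box_all <- list()
    avg_all <- list(); dom_all <- list(); hot_all <- list()
    contact_objs <- vector("list", nrow(sys_tbl))
    for (i in seq_len(nrow(sys_tbl))) {
      st <- parse_structure(sys_tbl$structure_path[i])
      tr <- as_trajectory(sys_tbl$trajectory_path[i])
      lab <- tibble::tibble(focal = sys_tbl$focal[i], co = sys_tbl$co[i])
      rmsd_all[[i]] <- purrr::map_dfr(unique(map$domain), function(d) {
        dplyr::bind_cols(lab, domain_rmsd_series(
          tr, st, map, d, atom_selection = p$atom_selection,
          equilibration_ps = p$equilibration_ps
        ))
      })
      prof <- residue_rmsf(tr, st, atom_selection = p$atom_selection,
                           equilibration_ps = p$equilibration_ps)
      rmsf_all[[i]] <- dplyr::bind_cols(lab, tibble::as_tibble(prof))
      box_all[[i]] <- dplyr::bind_cols(
        lab, tibble::as_tibble(domain_rmsf_distribution(prof, map))[
          , c("domain", "n", "median", "q1", "q3", "whisker_low", "whisker_high")
        ]
      )
      lig <- ligands_from_structure(st)
      cs <- contact_series(tr, st, lig, interval_ps = p$interval_ps,
                           equilibration_ps = p$equilibration_ps,
                           cutoff_nm = p$cutoff_nm)
      contact_objs[[i]] <- cs
      avg_all[[i]] <- dplyr::bind_cols(lab, cs$averages)
      dom_all[[i]] <- dplyr::bind_cols(lab, domain_contact_number(cs, map))
      hot_all[[i]] <- dplyr::bind_cols(lab, hotspot_residues(cs, k = p$hotspot_k))
      pdb_path <- file.path(output_dir, sprintf(
        "bfactor_%s_in_%s.pdb", sys_tbl$focal[i], sys_tbl$co[i]
      ))
      write_bfactor_pdb(st, cs, sys_tbl$focal[i], path = pdb_path)
      add_file(pdb_path)
    }
    report$rmsd_series <- dplyr::bind_rows(rmsd_all)
    report$rmsf <- dplyr::bind_rows(rmsf_all)
    report$box_stats <- dplyr::bind_rows(box_all)
    report$contact_averages <- dplyr::bind_rows(avg_all)
    report$domain_contacts <- dplyr::bind_rows(dom_all)
    report$hotspots <- dplyr::bind_rows(hot_all)
    report$competition <- purrr::map(
      rlang::set_names(unique(map$domain)),
      function(d) {
        competition_matrix(
          dplyr::mutate(sys_tbl[, c("focal", "co")], series = contact_objs),
          map, d
        )
      }
    )
    for (nm in c("rmsd_series", "rmsf", "box_stats", "contact_averages",
                 "domain_contacts", "hotspots")) {
      path <- file.path(output_dir, paste0(nm, ".csv"))
      .write_report_csv(report[[nm]], path, p)
      add_file(path)
    }
    for (d in names(report$competition)) {
      path <- file.path(output_dir, sprintf("competition_%s.csv", d))
      .write_report_csv(tibble::as_tibble(report$competition[[d]]), path, p)
      add_file(path)
    }
  }

  if (length(config$tracks) > 0L) {
    tracks <- purrr::map_dfr(config$tracks, function(t) {
      tr <- read_tracks(t$path)
      tr$condition <- t$condition %||% tr$condition %||% basename(t$path)
      tr
    })
    report$track_stats <- track_stats(tracks)
    report$condition_summary <- summarise_conditions(report$track_stats)
    for (nm in c("track_stats", "condition_summary")) {
      path <- file.path(output_dir, paste0(nm, ".csv"))
      .write_report_csv(report[[nm]], path, p)
      add_file(path)
    }
    if (dplyr::n_distinct(report$track_stats$condition) >= 2L) {
      report$comparisons <- compare_conditions(report$track_stats)
      path <- file.path(output_dir, "comparisons.csv")
      .write_report_csv(report$comparisons, path, p)
      add_file(path)
    }
  }

  manifest <- tibble::tibble(
    file = basename(report$files),
    md5 = unname(tools::md5sum(report$files)),
    package_version = as.character(utils::packageVersion("trajmetrics"))
  )
  manifest_path <- file.path(output_dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  report$manifest <- manifest
  report$output_dir <- output_dir
  structure(report, class = "pipeline_report")
}

#' Render human-readable summary tables from a pipeline report
#'
#' Prints the per-domain competition tables (diagonal flagged, off-diagonal
#' cells annotated as increase/decrease relative to the single-species
#' value) and the domain box statistics.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @return The report, invisibly.
#' @export
render_tables <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  for (d in names(report$competition)) {
    cat("\n== Domain contact competition:", d, "==\n")
    print(tidyr::pivot_wider(
      dplyr::mutate(
        tibble::as_tibble(report$competition[[d]]),
        cell = sprintf("%.2f%s", .data$c_domain, dplyr::case_when(
          .data$diagonal ~ " [diag]",
          .data$annotation == "increase" ~ " (+)",
          .data$annotation == "decrease" ~ " (-)",
          TRUE ~ ""
        ))
      )[, c("focal", "co", "cell")],
      names_from = "co", values_from = "cell"
    ))
  }
  if (!is.null(report$box_stats)) {
    cat("\n== Domain RMSF box statistics (A) ==\n")
    print(report$box_stats)
  }
  if (!is.null(report$condition_summary)) {
    cat("\n== Track condition summary ==\n")
    print(report$condition_summary)
  }
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> ", length(x$files) + 1L, " files in ", x$output_dir,
      "\n", sep = "")
  invisible(x)
}
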