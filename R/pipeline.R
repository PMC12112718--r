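# End-to-end orchestration: trajectory file I/O, YAML run configs, the
# density -> hotspot -> label stage, and the predict/rank stage. Stage
# artifacts are files (DX grids, CSV tables) so runs are resumable and
# inspectable; every output directory carries a provenance log with the
# config hash.

#' Write a trajectory bundle as a multi-model PDB
#'
#' Protein heavy atoms as ATOM records, probe heavy atoms as HETATM records
#' (residue number = molecule id), one MODEL per frame. The same format is
#' read back by [read_trajectory_bundle()], so synthetic fixtures and real
#' trajectories are interchangeable.
#'
#' @param bundle a [trajectory_bundle()].
#' @param path output path.
#' @param probe_resname HETATM residue name used for probe atoms.
#' @export
write_trajectory_pdb <- function(bundle, path, probe_resname = "PRB") {
  ref <- bundle$reference
  pa <- ref$atoms[ref$atoms$is_heavy, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- "%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  pad_name <- function(nm) ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), nm)
  model <- 0L
  for (run in bundle$runs) {
    for (f in seq_len(dim(run$probe_xyz)[1])) {
      model <- model + 1L
      writeLines(sprintf("MODEL     %4d", model), con)
      prot <- if (!is.null(run$protein_xyz)) {
        m <- run$protein_xyz[f, , , drop = TRUE]
        if (is.null(dim(m))) matrix(m, ncol = 3) else m
      } else as.matrix(pa[, c("x", "y", "z")])
      lines <- sprintf(fmt, "ATOM", seq_len(nrow(prot)),
                       pad_name(pa$atom_name), pa$resname,
                       pa$chain, as.integer(gsub("[^0-9-]", "", pa$resno)),
                       prot[, 1], prot[, 2], prot[, 3], 1, 0, pa$element)
      writeLines(lines, con)
      pxyz <- run$probe_xyz[f, , , drop = TRUE]
      if (is.null(dim(pxyz))) pxyz <- matrix(pxyz, ncol = 3)
      n0 <- nrow(prot)
      lines <- sprintf(fmt, "HETATM", n0 + seq_len(nrow(pxyz)),
                       pad_name("C"), probe_resname, "P",
                       run$molecule_id, pxyz[, 1], pxyz[, 2], pxyz[, 3],
                       1, 0, "C")
      writeLines(lines, con)
      writeLines("ENDMDL", con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Read probe trajectory files into a bundle
#'
#' Each file is a multi-model PDB whose ATOM records are the protein and
#' whose HETATM records with `probe_resname` are probe heavy atoms; the
#' HETATM residue number is the probe molecule id.
#'
#' @param paths character vector of trajectory files (one run each).
#' @param probe a [probe_spec()].
#' @param reference [structure3d] defining the protein-fixed frame.
#' @param probe_resname probe HETATM residue name.
#' @return A [trajectory_bundle()].
#' @export
read_trajectory_bundle <- function(paths, probe, reference,
                                   probe_resname = "PRB") {
  runs <- lapply(paths, function(p) {
    pdb <- suppressWarnings(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE))
    at <- pdb$atom
    is_probe <- at$type == "HETATM" & at$resid == probe_resname
    is_prot <- at$type == "ATOM"
    nf <- nrow(pdb$xyz)
    idx3 <- function(sel) as.vector(rbind(3 * (which(sel) - 1) + 1,
                                          3 * (which(sel) - 1) + 2,
                                          3 * (which(sel) - 1) + 3))
    probe_xyz <- array(NA_real_, dim = c(nf, sum(is_probe), 3))
    protein_xyz <- array(NA_real_, dim = c(nf, sum(is_prot), 3))
    for (f in seq_len(nf)) {
      m <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
      probe_xyz[f, , ] <- m[is_probe, , drop = FALSE]
      protein_xyz[f, , ] <- m[is_prot, , drop = FALSE]
    }
    list(probe_xyz = probe_xyz, molecule_id = at$resno[is_probe],
         protein_xyz = protein_xyz)
  })
  trajectory_bundle(probe, runs, reference)
}

#' Read a YAML run manifest / config
#'
#' @param path YAML file.
#' @return named list with a `config_hash` attribute (FNV-1a of the text).
#' @export
read_run_config <- function(path) {
  txt <- readLines(path)
  cfg <- yaml::yaml.load(paste(txt, collapse = "\n"))
  attr(cfg, "config_hash") <- fnv1a_hash(paste(txt, collapse = "\n"))
  cfg
}

config_hash_of <- function(config) {
  attr(config, "config_hash") %||%
    fnv1a_hash(paste(deparse(config), collapse = ""))
}

write_runlog <- function(out_dir, config_hash, stage, notes = character(0)) {
  log <- file.path(out_dir, "runlog.txt")
  cat(sprintf("[%s] stage=%s config_hash=%s\n%s",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, config_hash,
              if (length(notes)) paste0(paste(notes, collapse = "\n"), "\n") else ""),
      file = log, append = TRUE)
}

#' Density-to-hotspot detection stage
#'
#' For each probe bundle: build a grid over the reference, accumulate and
#' normalize occupancy, threshold and cluster voxels; then merge clusters
#' across probes into hotspots and (if a cryptic-site definition is given)
#' label them. When `out_dir` is set, per-probe DX grids, the hotspot CSV
#' table, a voxel pseudo-atom PDB and a provenance log are written.
#'
#' @param bundles named list of [trajectory_bundle()]s (name = probe name).
#' @param reference apo [structure3d] defining the grid frame.
#' @param params [detection_params()].
#' @param site optional `cryptic_site` for labeling.
#' @param lparams [label_params()].
#' @param align superpose each frame's protein onto the reference before
#'   binning.
#' @param padding,spacing grid geometry (see [build_grid()]).
#' @param out_dir optional artifact directory.
#' @param config_hash provenance hash recorded in outputs.
#' @return list with `hotspots`, per-probe `grids`, and the hotspot `table`.
#' @export
run_detect <- function(bundles, reference, params = detection_params(),
                       site = NULL, lparams = label_params(), align = FALSE,
                       padding = 8, spacing = 1, out_dir = NULL,
                       config_hash = "unhashed") {
  stopifnot(length(bundles) >= 1L)
  grids <- list()
  clusters <- list()
  for (nm in names(bundles)) {
    bundle <- bundles[[nm]]
    g <- build_grid(reference, padding = padding, spacing = spacing,
                    probe = bundle$probe)
    g <- accumulate_occupancy(bundle, g, align = align)
    g <- normalize_occupancy(g)
    grids[[nm]] <- g
    sel <- select_voxels(g, params)
    cl <- cluster_voxels(sel, params, probe = bundle$probe,
                         lattice = grid_lattice_signature(g))
    clusters <- c(clusters, cl)
  }
  hotspots <- merge_clusters(clusters, params)
  if (!is.null(site))
    hotspots <- lapply(hotspots, label_cryptic, site = site, apo = reference,
                       params = lparams)
  tab <- hotspot_table(hotspots)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(grids))
      write_dx(grids[[nm]], file.path(out_dir, paste0("occupancy_", nm, ".dx")))
    tab_out <- tab
    tab_out$config_hash <- config_hash
    utils::write.csv(tab_out, file.path(out_dir, "hotspots.csv"),
                     row.names = FALSE)
    if (length(hotspots))
      write_hotspot_pdb(hotspots, file.path(out_dir, "hotspot_voxels.pdb"))
    write_runlog(out_dir, config_hash, "detect",
                 sprintf("%d hotspot(s) from %d probe(s)", length(hotspots),
                         length(bundles)))
  }
  list(hotspots = hotspots, grids = grids, table = tab)
}

#' Prediction and ranking stage
#'
#' Validates the feature table against the model sidecar hash, predicts
#' cryptic probabilities, ranks hotspots per protein and produces the top-N
#' report (labels permitting).
#'
#' @param model a `cryptohot_model` from [train_model()].
#' @param features feature table with `protein_id`, `hotspot_id` and the
#'   model's feature columns (optionally `label`).
#' @param Ns top-N thresholds.
#' @param n_proteins denominator for the top-N percentages.
#' @param out_dir optional artifact directory.
#' @param config_hash provenance hash recorded in outputs.
#' @return list with `ranking` and (if labels present) `topn`.
#' @export
run_predict <- function(model, features, Ns = c(1L, 3L, 5L),
                        n_proteins = NULL, out_dir = NULL,
                        config_hash = "unhashed") {
  check_feature_hash(model, features)
  features$probability <- predict_prob(model, features)
  ranking <- rank_hotspots(features)
  topn <- NULL
  if ("label" %in% names(features))
    topn <- topn_report(ranking, Ns = Ns, n_proteins = n_proteins)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rk <- ranking
    rk$config_hash <- config_hash
    utils::write.csv(rk, file.path(out_dir, "ranking.csv"), row.names = FALSE)
    if (!is.null(topn)) {
      tn <- topn; tn$config_hash <- config_hash
      utils::write.csv(tn, file.path(out_dir, "topn.csv"), row.names = FALSE)
    }
    write_runlog(out_dir, config_hash, "predict",
                 sprintf("%d row(s) ranked", nrow(ranking)))
  }
  list(ranking = ranking, topn = topn)
}
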