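# End-to-end analysis pipeline: chains every analysis stage on a
# trajectory and emits the full figure-data set as TSV tables with
# provenance headers.

provenanceHeader <- function(cfg, inputHash, seed) {
  c(sprintf("# oligolens %s", as.character(utils::packageVersion("oligolens"))),
    sprintf("# config_hash %s", digestConfig(cfg)),
    sprintf("# input_hash %s", inputHash),
    sprintf("# seed %d", as.integer(seed)))
}

digestConfig <- function(cfg) {
  s <- paste(vapply(names(cfg), function(k)
    paste0(k, "=", paste(format(cfg[[k]], digits = 12), collapse = ",")), ""),
    collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251 + 1)) %%
            .Machine$integer.max)
}

writeTsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pdfToDf <- function(p) data.frame(mid = p$mids, density = p$density)

contactMapToDf <- function(cm) {
  L <- length(cm@labels)
  idx <- which(upper.tri(matrix(0, L, L), diag = TRUE), arr.ind = TRUE)
  data.frame(res_i = cm@labels[idx[, 1]], res_j = cm@labels[idx[, 2]],
             class = cm@contactClass,
             probability = cm@probabilities[idx])
}

pmfToDf <- function(s) {
  xc <- (s@xEdges[-1] + s@xEdges[-length(s@xEdges)]) / 2
  yc <- (s@yEdges[-1] + s@yEdges[-length(s@yEdges)]) / 2
  grid <- expand.grid(x = seq_along(xc), y = seq_along(yc))
  data.frame(x_center = xc[grid$x], y_center = yc[grid$y],
             free_energy = s@freeEnergy[cbind(grid$x, grid$y)])
}

#' Run the full analysis pipeline
#'
#' Produces, as TSV tables with provenance headers: secondary-structure
#' populations overall and per residue; PDFs of C-alpha RMSD (to frame
#' 1), end-to-end distance and main-/side-chain hydrogen-bond counts;
#' the SASA--RG free-energy surface with the top-cluster projection;
#' MC-MC and SC-SC inter-peptide contact maps; and, when ligand chains
#' are present, ligand binding and hydrogen-bond profiles, the
#' ring-stacking angle/distance table, and CH-pi / F23-F23 ring distance
#' series. A convergence report is added when both windows are
#' configured. Ligand stages are skipped with a notice when no ligand is
#' present.
#'
#' @param traj a [Trajectory-class] or a path to a multi-model PDB file.
#' @param config a configuration from [validateConfig()] (or \code{NULL}
#'   for defaults).
#' @param outDir output directory (created if needed).
#' @return invisibly, a named list of the tables written (as data
#'   frames), plus \code{files} with their paths.
#' @export
runFullPipeline <- function(traj, config = NULL, outDir = "oligolens-out") {
  cfg <- if (is.list(config) && is.null(names(config)) == FALSE &&
             all(names(analysisDefaults()) %in% names(config))) config
         else validateConfig(config)
  inputHash <- "in-memory"
  if (is.character(traj)) {
    inputHash <- sprintf("%s:%d", basename(traj), file.size(traj))
    traj <- readMultiModelPDB(traj)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenanceHeader(cfg, inputHash, cfg$seed)
  top <- traj@topology
  hasLigand <- any(top@chains$kind == "ligand")
  out <- list(); files <- character(0)
  emit <- function(df, name) {
    p <- file.path(outDir, paste0(name, ".tsv"))
    writeTsv(df, p, hdr)
    out[[name]] <<- df
    files <<- c(files, p)
  }

  ## secondary structure (populations overall and per residue)
  ss <- assignSecondaryStructure(traj)
  emit(ssPopulation(ss), "ss_population")
  emit(ssPopulation(ss, perResidue = TRUE), "ss_per_residue")

  ## PDFs: RMSD to the initial structure, end-to-end, H-bond counts
  caSel <- atomSelect(top, "peptide and name CA")
  rmsd <- rmsdToReference(traj, caSel)
  emit(data.frame(frame = seq_along(rmsd), rmsd = rmsd), "rmsd_series")
  if (nFrames(traj) >= 2) emit(pdfToDf(pdf1d(rmsd[-1])), "rmsd_pdf")
  pepChains <- top@chains$id[top@chains$kind == "peptide"]
  e2e <- unlist(lapply(pepChains, function(cid) endToEndDistance(traj, cid)))
  emit(pdfToDf(pdf1d(e2e)), "end_to_end_pdf")
  hb <- detectHBonds(traj, scope = "peptide",
                     distanceCutoff = cfg$hbond_distance,
                     angleCutoff = cfg$hbond_angle)
  emit(hbondCountPdf(traj, "MC", hb), "hbond_mc_pdf")
  emit(hbondCountPdf(traj, "SC", hb), "hbond_sc_pdf")

  ## SASA-RG free-energy surface and clustering
  pepHeavy <- atomSelect(top, "peptide and heavy")
  sasa <- sasaTimeSeries(traj, pepHeavy, probe = cfg$sasa_probe,
                         nPoints = cfg$sasa_points)
  masses <- top@atoms$mass[pepHeavy]
  rg <- vapply(seq_len(nFrames(traj)), function(f)
    radiusOfGyration(traj@coords[[f]][pepHeavy, , drop = FALSE], masses), 0)
  emit(data.frame(frame = seq_along(sasa), sasa = sasa, rg = rg), "sasa_rg_series")
  surface <- pmf2d(sasa, rg, temperature = cfg$temperature, bins = cfg$pmf_bins)
  emit(pmfToDf(surface), "sasa_rg_pmf")
  clFrames <- seq_len(nFrames(traj))
  if (length(clFrames) > cfg$cluster_max_frames)
    clFrames <- clFrames[seq(1, length(clFrames),
                             length.out = cfg$cluster_max_frames)]
  sub <- traj
  sub@coords <- traj@coords[clFrames]
  sub@box <- traj@box[clFrames]
  sub@time <- traj@time[clFrames]
  cl <- dauraCluster(sub, atomSelect(top, "peptide and name CA"),
                     cutoff = cfg$cluster_cutoff)
  asg <- data.frame(frame = clFrames[unlist(cl@members)],
                    cluster = rep(seq_along(cl@members),
                                  vapply(cl@members, length, 1L)))
  asg$is_medoid <- asg$frame %in% clFrames[cl@medoids]
  emit(asg[order(asg$frame), ], "clusters")
  emit(projectClusters(cl, sasa[clFrames], rg[clFrames]), "cluster_projection")

  ## inter-peptide contact maps
  if (length(pepChains) >= 2) {
    emit(contactMapToDf(interpeptideContactMap(traj, "MC-MC",
                                               cfg$contact_cutoff)),
         "contact_map_mc")
    emit(contactMapToDf(interpeptideContactMap(traj, "SC-SC",
                                               cfg$contact_cutoff)),
         "contact_map_sc")
  }

  ## F23-F23 ring stacking (peptide-peptide), present with or without ligand
  pheRings <- ringSelection(top, "peptide and resname PHE")
  if (length(pheRings) >= 2) {
    ff <- stackingEvents(traj, pheRings, pheRings,
                         parallelMax = cfg$stacking_parallel_max,
                         herringboneMin = cfg$stacking_herringbone_min)
    if (nrow(ff)) emit(ff, "phe_phe_stacking")
  }

  ## ligand stages
  if (hasLigand) {
    emit(ligandBindingProbability(traj, cfg$contact_cutoff), "ligand_binding")
    emit(ligandHbondProfile(traj), "ligand_hbond_profile")
    ligRings <- ringSelection(top, "ligand")
    if (length(pheRings) && length(ligRings)) {
      st <- stackingEvents(traj, pheRings, ligRings,
                           parallelMax = cfg$stacking_parallel_max,
                           herringboneMin = cfg$stacking_herringbone_min)
      emit(st, "ligand_stacking")
      if (nrow(st) >= 2) {
        stPmf <- pmf2d(st$angle, st$distance, temperature = cfg$temperature,
                       bins = c(18L, 20L))
        emit(pmfToDf(stPmf), "stacking_pmf")
      }
      for (resn in c("ILE", "LEU")) {
        expr <- sprintf("peptide and resname %s", resn)
        if (length(atomSelect(top, expr))) {
          d <- chpiMinDistance(traj, expr, ligRings, mode = cfg$chpi_mode)
          emit(data.frame(frame = seq_along(d), distance = d),
               paste0("chpi_", tolower(resn)))
        }
      }
    }
  } else {
    message("runFullPipeline: no ligand chains; ligand stages skipped")
  }

  ## convergence report
  if (!is.null(cfg$window_a) && !is.null(cfg$window_b)) {
    cv <- convergenceCheck(traj, unlist(cfg$window_a), unlist(cfg$window_b),
                           threshold = cfg$convergence_threshold)
    emit(data.frame(observable = names(cv$divergences),
                    jsd_bits = as.numeric(cv$divergences),
                    threshold = cv$threshold, pass = cv$pass), "convergence")
  }
  out$files <- files
  invisible(out)
}
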