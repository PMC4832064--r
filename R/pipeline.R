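# Pipeline orchestration: a single structured configuration drives every
# stage; each stage writes its declared text outputs plus a JSON run
# manifest with file digests, so any output can be regenerated from the
# manifest's config and seed.

#' Default pipeline configuration
#'
#' Stage parameters for the full phospho-vs-unphospho workflow. The
#' sequence block defaults to the 27-residue Sac6 loop segment anchored at
#' residue 99 with the phospho site on T103.
#'
#' @return nested named list; see the entries themselves for units.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    output_dir = "pepmetad_run",
    sequence = list(text = "APNSTPIVSTAATGLQHKGKGTQAKII",
                    start_number = 99L, phospho_site = 103L),
    surrogate = list(mass = 110, bond_length = 0.38,
                     bond_stiffness = 1000, radius = 0.25,
                     dielectric = 80, screening_length = 1.0,
                     repulsion_stiffness = 500, phospho_charge = -2),
    cvs = list(r0 = 0.65, n = 6L, m = 12L, exclusion = 3L),
    metadynamics = list(well_tempered = TRUE, bias_factor = 10,
                        base_height = 1.0, sigma_rg = 0.05,
                        sigma_contact = 0.5, deposition_stride = 500L,
                        temperature = 298, friction = 1, timestep = 0.005,
                        n_steps = 200000L, save_stride = 500L),
    analysis = list(cluster_metric = "rmsd", cluster_cutoff = 0.2,
                    contact_cutoff = 0.45, contact_exclusion = 2L,
                    fes_bins = 100L))
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (at any level) are rejected; missing keys are filled from
#' [defaultRunConfig()].
#'
#' @param config nested list (possibly partial).
#' @return the completed configuration list.
#' @export
validateRunConfig <- function(config) {
  defaults <- defaultRunConfig()
  check <- function(user, def, path) {
    extra <- setdiff(names(user), names(def))
    if (length(extra))
      stop("unknown configuration key(s): ",
           paste(paste0(path, extra), collapse = ", "))
    for (k in names(user))
      if (is.list(def[[k]]))
        check(user[[k]], def[[k]], paste0(path, k, "."))
  }
  check(config, defaults, "")
  merge <- function(def, user) {
    for (k in names(user))
      def[[k]] <- if (is.list(def[[k]]))
        merge(def[[k]], user[[k]]) else user[[k]]
    def
  }
  merge(defaults, config)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; keys as in [defaultRunConfig()].
#' @return validated, completed configuration list.
#' @export
readRunConfig <- function(path) {
  validateRunConfig(yaml::read_yaml(path))
}

#' Write a JSON run manifest
#'
#' Records the tool version, the full configuration, the seed, MD5 digests
#' of the stage's input and output files, and a timestamp. The
#' reproducibility contract: re-running the stage with the manifest's
#' config and seed regenerates byte-identical numeric outputs.
#'
#' @param dir directory the manifest is written into (as
#'   `run_manifest.json`).
#' @param config the configuration list driving the stage.
#' @param inputs,outputs character vectors of file paths.
#' @param stage stage name recorded in the manifest.
#' @return manifest path, invisibly.
#' @export
writeRunManifest <- function(dir, config, inputs = character(0),
                             outputs = character(0), stage = "run") {
  digest <- function(paths) {
    if (!length(paths)) return(stats::setNames(list(), character(0)))
    md5 <- tools::md5sum(paths)
    as.list(stats::setNames(unname(md5), basename(paths)))
  }
  manifest <- list(tool = "pepmetad",
                   version = as.character(packageVersion("pepmetad")),
                   stage = stage,
                   seed = config$seed,
                   config = config,
                   inputs = digest(inputs),
                   outputs = digest(outputs),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.configSeq <- function(config, phospho) {
  s <- config$sequence
  seq <- parsePeptide(s$text, s$start_number)
  if (phospho) {
    i <- s$phospho_site - s$start_number + 1L
    if (i < 1L || i > length(seq))
      stop("phospho_site falls outside the sequence")
    if (!seq@residues[i] %in% c("S", "T", "Y"))
      stop("phospho_site is not an S/T/Y residue")
    seq@phospho[i] <- TRUE
    validObject(seq)
  }
  seq
}

.configChain <- function(config, phospho) {
  s <- config$surrogate
  buildBeadChain(.configSeq(config, phospho), mass = s$mass,
                 bondLength = s$bond_length,
                 bondStiffness = s$bond_stiffness, radius = s$radius,
                 dielectric = s$dielectric,
                 screeningLength = s$screening_length,
                 repulsionStiffness = s$repulsion_stiffness,
                 phosphoCharge = s$phospho_charge)
}

#' Write sequence fixtures for a pipeline run
#'
#' Emits an annotated FASTA with the configured segment in both
#' conditions (unphospho, phospho) plus a manifest.
#'
#' @param config configuration list (completed by [validateRunConfig()]).
#' @param dir output directory (created if missing).
#' @return named vector of written file paths, invisibly.
#' @export
pipelineFixtures <- function(config = defaultRunConfig(), dir = config$output_dir) {
  config <- validateRunConfig(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "segment.fasta")
  writePeptideFasta(list(segment_unphospho = .configSeq(config, FALSE),
                         segment_phospho = .configSeq(config, TRUE)),
                    fasta)
  writeRunManifest(dir, config, outputs = fasta, stage = "fixtures")
  invisible(c(fasta = fasta))
}

#' Run biased sampling for one condition and write its records
#'
#' Builds the bead chain for the configured segment, runs well-tempered
#' (or standard) metadynamics over (Rg, contact number) from the linear
#' conformation, and writes trajectory (XYZ and frame-PDB), COLVAR and
#' HILLS files plus a manifest.
#'
#' @param config configuration list.
#' @param dir output directory.
#' @param phospho logical condition flag.
#' @return list with the in-memory `trajectory`, `cv`, `bias` and the
#'   written `files`.
#' @export
pipelineSimulate <- function(config = defaultRunConfig(),
                             dir = config$output_dir, phospho = FALSE) {
  config <- validateRunConfig(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- if (phospho) "phospho" else "unphospho"
  message("simulate [", tag, "]: seed ", config$seed)
  m <- config$metadynamics
  chain <- .configChain(config, phospho)
  cvdefs <- chainCVDefinitions(length(chain@masses), r0 = config$cvs$r0,
                               n = config$cvs$n, m = config$cvs$m,
                               exclusion = config$cvs$exclusion)
  bias <- biasState(c("rg", "contact_number"),
                    temperature = m$temperature,
                    wellTempered = m$well_tempered,
                    biasFactor = m$bias_factor,
                    baseHeight = m$base_height,
                    sigma = c(m$sigma_rg, m$sigma_contact),
                    depositionStride = m$deposition_stride)
  cfg <- simulationConfig(temperature = m$temperature,
                          friction = m$friction, timestep = m$timestep,
                          nSteps = m$n_steps, seed = config$seed,
                          saveStride = m$save_stride)
  run <- runMetadynamics(chain, cfg, bias, cvdefs = cvdefs)
  files <- c(xyz = file.path(dir, paste0("traj_", tag, ".xyz")),
             pdb = file.path(dir, paste0("traj_", tag, ".pdb")),
             colvar = file.path(dir, paste0("COLVAR_", tag)),
             hills = file.path(dir, paste0("HILLS_", tag)))
  writeXYZ(run$trajectory, files["xyz"])
  writePDBFrames(run$trajectory, files["pdb"], seq = chain@sourceSeq)
  writeColvar(run$cv, files["colvar"])
  writeHills(run$bias, files["hills"])
  writeRunManifest(dir, config, outputs = unname(files),
                   stage = paste0("simulate_", tag))
  c(run, list(files = files, chain = chain))
}

#' Reconstruct and write a free-energy surface from a HILLS file
#'
#' @param hillsPath HILLS file.
#' @param outPath output FES table.
#' @param bins grid nodes per CV.
#' @return the [FESGrid-class], invisibly.
#' @export
pipelineFes <- function(hillsPath, outPath, bins = 100L) {
  state <- readHills(hillsPath)
  fes <- reconstructFES(state, bins = bins)
  writeFESTable(fes, outPath)
  invisible(fes)
}

#' Reweight a COLVAR series against its HILLS bias and write weights
#'
#' @param colvarPath COLVAR file of the biased run.
#' @param hillsPath HILLS file.
#' @param fesPath FES table (from [pipelineFes()]).
#' @param outPath output two-column weights file.
#' @return the [FrameWeights-class], invisibly.
#' @export
pipelineReweight <- function(colvarPath, hillsPath, fesPath, outPath) {
  cv <- readColvar(colvarPath)
  state <- readHills(hillsPath)
  fes <- readFESTable(fesPath)
  w <- reweightFrames(cv, state, fes)
  writeWeights(w, cv@times, outPath)
  invisible(w)
}

#' Cluster a trajectory with frame weights and write the cluster table
#'
#' @param trajPath XYZ trajectory.
#' @param weightsPath two-column weights file (optional; uniform if NULL).
#' @param outPath output TSV.
#' @param metric,cutoff as in [clusterConformations()].
#' @param temperature K for the cluster free energies.
#' @return the [ClusterSet-class], invisibly.
#' @export
pipelineCluster <- function(trajPath, weightsPath = NULL, outPath,
                            metric = "rmsd", cutoff = 0.2,
                            temperature = 298) {
  traj <- readXYZ(trajPath)
  w <- if (is.null(weightsPath)) NULL else readWeights(weightsPath)$weights
  cl <- clusterConformations(traj, w, metric = metric, cutoff = cutoff)
  cl <- clusterFreeEnergies(cl, temperature)
  writeClusterTsv(cl, outPath)
  invisible(cl)
}

#' Compute and write a weighted contact-probability map
#'
#' @param trajPath XYZ trajectory.
#' @param weightsPath weights file (optional).
#' @param outPath output TSV.
#' @param seq optional [PeptideSeq-class] for residue labels.
#' @param cutoff,exclusion,condition as in [contactProbabilityMap()].
#' @return the [ContactMap-class], invisibly.
#' @export
pipelineContactMap <- function(trajPath, weightsPath = NULL, outPath,
                               seq = NULL, cutoff = 0.45, exclusion = 2L,
                               condition = "unspecified") {
  traj <- readXYZ(trajPath)
  w <- if (is.null(weightsPath)) NULL else readWeights(weightsPath)$weights
  map <- contactProbabilityMap(traj, w, seq = seq, cutoff = cutoff,
                               exclusion = exclusion,
                               condition = condition)
  writeContactTsv(map, outPath)
  invisible(map)
}

#' Scan a FASTA file for Cdk1 consensus motifs and write hits as TSV
#'
#' @param fastaPath FASTA (plain or `{pX}`-annotated sequence lines).
#' @param outPath output TSV.
#' @param motifKind `"minimal"` or `"full_consensus"`.
#' @param startNumber numbering anchor for every record.
#' @return the hit table, invisibly.
#' @export
pipelineScanMotifs <- function(fastaPath, outPath,
                               motifKind = "minimal", startNumber = 1L) {
  records <- readPeptideFasta(fastaPath, startNumber)
  hits <- lapply(records, scanCdk1Sites, motifKind = motifKind)
  writeMotifTsv(hits, outPath)
  invisible(do.call(rbind, hits))
}

#' End-to-end phospho-vs-unphospho demonstration pipeline
#'
#' Chains, for both conditions: metadynamics sampling of the bead-chain
#' surrogate, FES reconstruction, time-dependent reweighting, weighted
#' clustering with Boltzmann free energies, contact-probability maps, the
#' combined dual-condition contact matrix, and salt-bridge /
#' hydrogen-bond surrogate detection. All numeric outputs are
#' deterministic given the configured seed.
#'
#' @param config configuration list.
#' @param dir output directory.
#' @return list with per-condition results (`phospho`, `unphospho`: each
#'   fes, weights, clusters, contacts, interactions) and the combined
#'   `dual_map`, invisibly.
#' @export
pipelineDemo <- function(config = defaultRunConfig(),
                         dir = config$output_dir) {
  config <- validateRunConfig(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pipelineFixtures(config, dir)
  out <- list()
  maps <- list()
  for (phospho in c(FALSE, TRUE)) {
    tag <- if (phospho) "phospho" else "unphospho"
    sim <- pipelineSimulate(config, dir, phospho)
    fes <- reconstructFES(sim$bias, bins = config$analysis$fes_bins)
    writeFESTable(fes, file.path(dir, paste0("fes_", tag, ".dat")))
    w <- reweightFrames(sim$cv, sim$bias, fes)
    writeWeights(w, sim$cv@times, file.path(dir, paste0("weights_", tag, ".dat")))
    cl <- clusterConformations(sim$trajectory, w,
                               metric = config$analysis$cluster_metric,
                               cutoff = config$analysis$cluster_cutoff)
    cl <- clusterFreeEnergies(cl, config$metadynamics$temperature)
    writeClusterTsv(cl, file.path(dir, paste0("clusters_", tag, ".tsv")))
    map <- contactProbabilityMap(sim$trajectory, w, seq = sim$chain@sourceSeq,
                                 cutoff = config$analysis$contact_cutoff,
                                 exclusion = config$analysis$contact_exclusion,
                                 condition = tag)
    writeContactTsv(map, file.path(dir, paste0("contacts_", tag, ".tsv")))
    inter <- detectInteractions(sim$trajectory, w, sim$chain@sourceSeq)
    write.table(inter, file.path(dir, paste0("interactions_", tag, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    maps[[tag]] <- map
    out[[tag]] <- list(fes = fes, weights = w, clusters = cl,
                       contacts = map, interactions = inter)
  }
  dual <- dualConditionMap(maps$phospho, maps$unphospho)
  writeContactTsv(dual, file.path(dir, "contacts_dual.tsv"))
  out$dual_map <- dual
  writeRunManifest(dir, config,
                   outputs = list.files(dir, full.names = TRUE,
                                        pattern = "\\.(tsv|dat|fasta)$"),
                   stage = "demo")
  invisible(out)
}
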