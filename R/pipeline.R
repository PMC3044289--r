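# One-shot pipeline orchestration: site extraction -> energy decomposition
# -> profiles -> mining -> scoring -> consensus (if actives known) ->
# clustering, with every intermediate written as TSV so stages can also be
# run independently (see the `pharmint` command-line script in inst/cli).

#' Pipeline configuration
#'
#' Collects paths, thresholds and algorithm choices with the standard
#' defaults: E/H profile cutoff -2.5 kcal/mol, V cutoff -4 kcal/mol,
#' preference call threshold 0.4, hot-spot ratio 0.5, site radius 8
#' Angstrom, RMSD success 2 Angstrom, 1000 shuffles, average linkage.
#'
#' Inputs may be given as file paths or as already-parsed objects
#' (`protein_structure`, list of `ligand_pose`, character vector of active
#' ids), which makes the pipeline usable both from the command line and
#' programmatically.
#'
#' @param protein PDB path or `protein_structure`.
#' @param poses SDF/MOL2 path or list of `ligand_pose`.
#' @param reference pose path / `ligand_pose` used to derive the site, or a
#'   HETATM residue name to look up in the protein.
#' @param actives optional path to a one-id-per-line file, or character
#'   vector of active compound ids.
#' @param out_dir output directory for the TSV report files (created).
#' @param site_radius,thresholds,call_threshold,hotspot_threshold,
#'   rmsd_threshold,n_shuffles,seed,pose_policy,linkage,distance,n_clusters,
#'   params tunables; see Details in the package vignette.
#' @return a `run_config` list.
#' @export
run_config <- function(protein, poses, reference, actives = NULL,
                       out_dir = tempfile("pharmint_run_"),
                       site_radius = 8.0,
                       thresholds = profile_thresholds(),
                       call_threshold = 0.4, hotspot_threshold = 0.5,
                       rmsd_threshold = 2.0, n_shuffles = 1000, seed = 33,
                       pose_policy = "best", linkage = "average",
                       distance = "euclidean", n_clusters = NULL,
                       params = potential_params()) {
  num <- c(site_radius, unlist(thresholds), call_threshold,
           hotspot_threshold, rmsd_threshold, n_shuffles, seed)
  if (any(!is.finite(num))) abort("all thresholds must be finite")
  structure(list(protein = protein, poses = poses, reference = reference,
                 actives = actives, out_dir = out_dir,
                 site_radius = site_radius, thresholds = thresholds,
                 call_threshold = call_threshold,
                 hotspot_threshold = hotspot_threshold,
                 rmsd_threshold = rmsd_threshold,
                 n_shuffles = n_shuffles, seed = seed,
                 pose_policy = pose_policy, linkage = linkage,
                 distance = distance, n_clusters = n_clusters,
                 params = params),
            class = "run_config")
}

resolve_protein <- function(x) {
  if (inherits(x, "protein_structure")) x else read_protein(x)
}

resolve_poses <- function(x) {
  if (is.character(x)) read_poses(x) else x
}

resolve_reference <- function(x, protein) {
  if (inherits(x, "ligand_pose")) return(x)
  if (is.character(x) && !file.exists(x)) return(het_as_pose(protein, x))
  resolve_poses(x)[[1]]
}

resolve_actives <- function(x) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1 && file.exists(x)) {
    readLines(x, warn = FALSE) |> trimws() |> Filter(f = nzchar)
  } else as.character(x)
}

#' Run the full post-screening pipeline
#'
#' Executes site extraction, per-pose energy decomposition, E/H/V profile
#' construction, pharmacological mining, re-scoring and ranking, consensus
#' hot-spot comparison (when actives are given), and hierarchical
#' clustering by interaction profile and atomic composition.  All tables
#' are written as TSV under `config$out_dir`; the run is deterministic for
#' a fixed config and seed, so two runs produce byte-identical files.
#'
#' @param config a [run_config()].
#' @return a `run_report` list: `site`, `decomp`, `profiles`, `preferences`
#'   (called), `scores` (ranked), `consensus` + `comparison` (or NULL),
#'   `clusters`, `trees`, `files`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(tibble::as_tibble(x), p)
    files[[name]] <<- p
  }

  protein <- stage("read_protein", resolve_protein(config$protein))
  poses <- stage("read_poses", resolve_poses(config$poses))
  reference <- stage("reference", resolve_reference(config$reference, protein))
  actives <- resolve_actives(config$actives)

  site <- stage("site", extract_binding_site(protein, reference,
                                             radius = config$site_radius))
  write_site(site, file.path(config$out_dir, "site.tsv"))
  files[["site.tsv"]] <- file.path(config$out_dir, "site.tsv")

  decomp <- stage("energies", batch_decompose(
    poses, site, params = config$params, pose_policy = config$pose_policy))
  emit(decomp, "energies.tsv")

  profiles <- stage("profiles", purrr::map(
    c(E = "E", H = "H", V = "V"),
    function(ch) build_profile(decomp, site, ch,
                               thresholds = config$thresholds)))
  for (ch in names(profiles)) {
    p <- file.path(config$out_dir, paste0("profile_", ch, ".tsv"))
    write_profile(profiles[[ch]], p)
    files[[basename(p)]] <- p
  }

  preferences <- stage("mine", dplyr::bind_rows(purrr::map(
    profiles, function(pr) {
      suppressWarnings(mine_profile(pr, n_shuffles = config$n_shuffles,
                                    seed = config$seed,
                                    threshold = config$call_threshold))
    })))
  emit(preferences, "preferences.tsv")

  scores <- stage("score", rank_compounds(score_compounds(decomp,
                                                          preferences)))
  emit(scores, "scores.tsv")

  consensus <- NULL; comparison <- NULL
  if (!is.null(actives) && length(actives) > 0) {
    consensus <- stage("consensus", dplyr::bind_rows(purrr::map(
      profiles, function(pr) {
        present <- intersect(actives, rownames(pr$matrix))
        if (length(present) == 0) return(NULL)
        consensus_ratio(subset_profile(pr, present),
                        threshold = config$hotspot_threshold)
      })))
    if (nrow(consensus) > 0) {
      emit(consensus, "consensus.tsv")
      comparison <- compare_pharma_to_hotspots(preferences, consensus)
      emit(comparison$summary, "hotspot_summary.tsv")
    }
  }

  clusters <- NULL; trees <- NULL
  if (length(poses) >= 2) {
    trees <- stage("cluster", {
      pd <- profile_distance(unname(profiles),
                             method = config$distance)
      cd <- composition_distance(atomic_compositions(poses))
      list(profile = hierarchical_cluster(pd, linkage = config$linkage),
           composition = hierarchical_cluster(cd, linkage = config$linkage))
    })
    k <- config$n_clusters %||% min(10L, length(trees$profile$labels))
    clusters <- select_representatives(cut_tree(trees$profile, k = k),
                                       scores)
    emit(clusters, "clusters.tsv")
    export_dendrogram(trees$profile,
                      file.path(config$out_dir, "profile_tree.nwk"))
    export_dendrogram(trees$composition,
                      file.path(config$out_dir, "composition_tree.nwk"))
    files[["profile_tree.nwk"]] <- file.path(config$out_dir,
                                             "profile_tree.nwk")
    files[["composition_tree.nwk"]] <- file.path(config$out_dir,
                                                 "composition_tree.nwk")
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("pharmint")),
    seed = config$seed,
    n_shuffles = config$n_shuffles,
    config_hash = rlang::hash(config[setdiff(names(config),
                                             c("out_dir"))]),
    timestamp = NA_character_  # deliberately unset: outputs stay byte-stable
  )
  structure(list(site = site, decomp = decomp, profiles = profiles,
                 preferences = preferences, scores = scores,
                 consensus = consensus, comparison = comparison,
                 clusters = clusters, trees = trees, files = files,
                 provenance = provenance),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  site: ", nrow(x$site$groups), " residue groups\n", sep = "")
  cat("  compounds scored: ", nrow(x$scores), "\n", sep = "")
  cat("  pharmacological calls: ", sum(x$preferences$call), "\n", sep = "")
  if (!is.null(x$comparison)) {
    ov <- dplyr::filter(x$comparison$summary, .data$type == "all")
    cat("  calls agreeing with hot spots: ", ov$n_hotspot, "/",
        ov$n_called, "\n", sep = "")
  }
  cat("  outputs: ", length(x$files), " file(s) in ",
      dirname(x$files[[1]]), "\n", sep = "")
  invisible(x)
}
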