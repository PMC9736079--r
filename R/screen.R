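# End-to-end screen: read -> charges -> one ligand-free PB solve ->
# per-ligand energy/shape/descriptor terms -> replacement energies ->
# normalization -> Z-score -> ranking -> optional evaluation.

#' Run an electrostatics-driven rescoring screen
#'
#' Scores a library of pre-placed ligand poses against a protein target and
#' its cognate (co-crystallized reference) pose. The ligand-free protein
#' potential is solved once and reused for every ligand; each ligand
#' contributes three replacement energies, two shape similarities, eight
#' descriptor similarities, and an atom-pair similarity, combined into a
#' weighted Z-score.
#'
#' @param protein A `protein_structure` or a PDB path.
#' @param cognate A `ligand_pose` or a ligand-file path (first record used).
#' @param library List of `ligand_pose` or a ligand-file path.
#' @param weights [es_weights()].
#' @param params [es_defaults()]-shaped parameter list.
#' @param labels Optional data.frame (name, active) enabling evaluation.
#' @param ligand_charges `"auto"` uses charges carried by the input file when
#'   every pose has them, otherwise computes Gasteiger charges; `"file"` and
#'   `"gasteiger"` force the respective source.
#' @param charge_table Protein charge table (path or
#'   [load_charge_table()] output).
#' @param metal_charges Named metal formal charges.
#' @param include_cognate Also score the cognate against itself as a row.
#' @param verbose Emit per-stage progress messages.
#' @return Object of class `es_screen`: `ranking` data.frame (name, raw
#'   energies, normalized terms, Z, rank), `cognate_energies`, `grid_id`,
#'   `evaluation` (if labels given), `weights`, `params`, `log`.
#' @export
es_screen <- function(protein, cognate, library, weights = es_weights(),
                      params = es_defaults(), labels = NULL,
                      ligand_charges = c("auto", "file", "gasteiger"),
                      charge_table = NULL, metal_charges = NULL,
                      include_cognate = FALSE, verbose = FALSE) {
  ligand_charges <- match.arg(ligand_charges)
  t0 <- Sys.time()
  stages <- list()
  tick <- function(stage) {
    stages[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (verbose) message(sprintf("[%6.1fs] %s", stages[[stage]], stage))
  }
  radii <- load_radius_set()

  if (is.character(protein)) protein <- read_protein(protein)
  protein <- assign_radii(protein, radii)
  if (all(is.na(protein$atoms$charge))) {
    ct <- if (is.null(charge_table)) load_charge_table()
          else if (is.character(charge_table)) load_charge_table(charge_table)
          else charge_table
    args <- list(protein = protein, charge_table = ct)
    if (!is.null(metal_charges)) args$metal_charges <- metal_charges
    protein <- suppressMessages(do.call(protein_charge_assignment, args))
  }
  if (is.character(cognate)) cognate <- read_ligand_poses(cognate)[[1]]
  if (is.character(library)) library <- read_ligand_poses(library)
  if (inherits(library, "ligand_pose")) library <- list(library)
  tick("read inputs")

  prep_pose <- function(p) {
    p <- assign_radii(p, radii)
    has_q <- !any(is.na(p$atoms$charge))
    use_file <- switch(ligand_charges,
                       file = TRUE, gasteiger = FALSE, auto = has_q)
    if (use_file && !has_q)
      stop("pose ", p$name, " carries no charges but ligand_charges='file'")
    if (!use_file) p <- gasteiger_charges(p)
    p
  }
  cognate <- prep_pose(cognate)
  library <- lapply(library, prep_pose)
  nms <- vapply(library, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate ligand names in library: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  tick("ligand preparation")

  pb <- params$pb
  grid <- build_grid(protein, spacing = pb$spacing,
                     fill_fraction = pb$fill, min_edge = pb$min_edge)
  dmap <- map_dielectric(protein, grid, eps_in = pb$eps_in,
                         eps_out = pb$eps_out,
                         ionic_strength = pb$ionic_strength,
                         ion_radius = pb$ion_radius, probe = pb$probe,
                         temperature = pb$temperature)
  pot <- solve_lpbe(dmap, omega = pb$omega, tol = pb$tol, maxit = pb$maxit)
  tick("PB solve (ligand-free, solved once)")

  np <- params$nonpolar
  pose_energies <- function(p) {
    phi <- interpolate_esp(pot, as.matrix(p$atoms[, c("x", "y", "z")]))
    energy_components(
      electrostatic_interaction_energy(phi, p$atoms$charge),
      hydrophobic_energy(protein, p, gamma = np$gamma, probe = np$probe,
                         n_sphere_points = np$sphere_points),
      vdw_energy(protein, p, cutoff = np$cutoff),
      grid_id = pot$grid_id)
  }
  cog_e <- pose_energies(cognate)
  tick("cognate energies")

  sh <- params$shape
  pm <- generate_protomol(protein, cognate,
                          pocket_radius = sh$pocket_radius,
                          grid_step = sh$grid_step, reach = sh$reach)
  pocket_desc <- shape_descriptor(pm$atoms, l_max = sh$l_max,
                                  n_theta = sh$n_theta, n_phi = sh$n_phi)
  cog_desc_shape <- shape_descriptor(cognate, l_max = sh$l_max,
                                     n_theta = sh$n_theta,
                                     n_phi = sh$n_phi)
  cog_desc <- compute_descriptors(cognate, probe = np$probe)
  cog_fp <- atom_pair_fingerprint(cognate)
  tick("reference shape and descriptors")

  score_pose <- function(p) {
    e <- pose_energies(p)
    de <- replacement_energy(e, cog_e)
    shp <- shape_descriptor(p, l_max = sh$l_max, n_theta = sh$n_theta,
                            n_phi = sh$n_phi)
    d_pocket <- shape_distance(pocket_desc, shp)
    d_ref <- shape_distance(cog_desc_shape, shp)
    dsc <- compute_descriptors(p, probe = np$probe)
    terms <- list(
      elec = normalize_term(de$d_electrostatic, weights$alpha_small),
      hyd = normalize_term(de$d_hydrophobic, weights$alpha_large),
      vdw = normalize_term(de$d_vdw, weights$alpha_large),
      pocket_shape = normalize_term(d_pocket, weights$alpha_small,
                                    favorable_low = TRUE),
      ref_shape = normalize_term(d_ref, weights$alpha_small,
                                 favorable_low = TRUE),
      desc = descriptor_similarity(cog_desc, dsc),
      ap = tanimoto(cog_fp, atom_pair_fingerprint(p)))
    data.frame(name = p$name,
               e_elec = e$e_electrostatic, e_hyd = e$e_hydrophobic,
               e_vdw = e$e_vdw,
               d_elec = de$d_electrostatic, d_hyd = de$d_hydrophobic,
               d_vdw = de$d_vdw,
               n_elec = terms$elec, n_hyd = terms$hyd, n_vdw = terms$vdw,
               n_pocket_shape = terms$pocket_shape,
               n_ref_shape = terms$ref_shape,
               t(setNames(terms$desc, paste0("x_", names(terms$desc)))),
               n_ap = terms$ap,
               Z = z_score(terms, weights),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(library, score_pose)
  if (include_cognate) rows <- c(list(score_pose(cognate)), rows)
  ranking <- rank_ligands(do.call(rbind, rows))
  tick("per-ligand scoring")

  evaluation <- NULL
  if (!is.null(labels)) {
    lab <- labels$active[match(ranking$name, labels$name)]
    if (any(is.na(lab)))
      stop("labels missing for: ",
           paste(ranking$name[is.na(lab)], collapse = ", "))
    lr <- labeled_ranking(ranking$name, ranking$Z, lab)
    evaluation <- list(auc = roc_auc(lr),
                       ef1 = relative_ef(lr, 1),
                       ef5 = relative_ef(lr, 5),
                       n_actives = sum(lab), n_total = length(lab))
    ranking$active <- lab
    tick("evaluation")
  }
  structure(list(ranking = ranking, cognate_energies = cog_e,
                 grid_id = pot$grid_id, solver = list(
                   iterations = pot$iterations,
                   final_residual = pot$final_residual),
                 evaluation = evaluation, weights = weights,
                 params = params, log = stages),
            class = "es_screen")
}

#' @export
print.es_screen <- function(x, ...) {
  cat("es_screen:", nrow(x$ranking), "ligands ranked (grid", x$grid_id,
      ")\n")
  top <- utils::head(x$ranking[, c("rank", "name", "Z", "n_elec")], 5)
  print(top, row.names = FALSE)
  if (!is.null(x$evaluation))
    cat(sprintf("AUC %.3f | EF1%% %.1f | EF5%% %.1f (%d actives / %d)\n",
                x$evaluation$auc, x$evaluation$ef1, x$evaluation$ef5,
                x$evaluation$n_actives, x$evaluation$n_total))
  invisible(x)
}

#' @export
summary.es_screen <- function(object, ...) {
  cat("Ranking of", nrow(object$ranking), "ligands\n")
  cat("Cognate energies: elec", signif(object$cognate_energies$e_electrostatic, 4),
      "kcal/mol | hyd", signif(object$cognate_energies$e_hydrophobic, 4),
      "kJ/mol | vdw", signif(object$cognate_energies$e_vdw, 4), "kJ/mol\n")
  cat("Z range:", signif(min(object$ranking$Z), 4), "to",
      signif(max(object$ranking$Z), 4), "of max",
      with(object$weights, w_elec + w_hyd + w_vdw + w_pocket + w_ref +
                           sum(w_desc) + w_ap), "\n")
  if (!is.null(object$evaluation)) {
    cat(sprintf("AUC %.3f | EF1%% %.1f | EF5%% %.1f\n",
                object$evaluation$auc, object$evaluation$ef1,
                object$evaluation$ef5))
  }
  invisible(object)
}

#' @export
plot.es_screen <- function(x, ...) {
  if (!is.null(x$evaluation) && "active" %in% names(x$ranking)) {
    act <- x$ranking$active
    n1 <- sum(act); n0 <- sum(!act)
    tpr <- cumsum(act) / n1
    fpr <- cumsum(!act) / n0
    plot(c(0, fpr), c(0, tpr), type = "l", xlab = "False positive rate",
         ylab = "True positive rate",
         main = sprintf("ROC (AUC = %.3f)", x$evaluation$auc), ...)
    graphics::abline(0, 1, lty = 3)
  } else {
    graphics::hist(x$ranking$Z, breaks = 20, xlab = "Z-score",
                   main = "Z-score distribution", ...)
  }
  invisible(x)
}

#' Run a screen from a configuration file or list
#'
#' Thin orchestration layer over [es_screen()]: reads a YAML (or list)
#' configuration with input paths and parameter overrides, runs the screen,
#' and writes the ranked TSV, an evaluation/provenance report (JSON), and a
#' verbatim copy of the configuration into the output directory.
#'
#' @param config YAML path or list. Recognized keys: `protein`, `cognate`,
#'   `library`, `labels` (TSV with name/active), `charge_table`, `out_dir`,
#'   `ligand_charges`, `max_mw` (optional molecular-weight filter, g/mol,
#'   off by default), plus nested `pb`, `nonpolar`, `shape`, `weights`
#'   overrides of [es_defaults()].
#' @return The `es_screen` object, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_screen <- function(config) {
  cfg_raw <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- cfg_raw
  for (k in c("protein", "cognate", "library"))
    if (is.null(cfg[[k]])) stop("config missing required key: ", k)
  params <- es_defaults()
  for (blk in c("pb", "nonpolar", "shape"))
    if (!is.null(cfg[[blk]]))
      params[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
  weights <- if (is.null(cfg$weights)) es_weights()
             else do.call(es_weights, cfg$weights)
  labels <- NULL
  if (!is.null(cfg$labels)) {
    labels <- read.delim(cfg$labels, stringsAsFactors = FALSE)
    labels$active <- as.logical(labels$active)
  }
  lib <- cfg$library
  if (!is.null(cfg$max_mw)) {
    lib <- read_ligand_poses(lib)
    keep <- vapply(lib, molecular_weight, 0) < cfg$max_mw
    message(sum(!keep), " ligand(s) removed by the molecular-weight filter")
    lib <- lib[keep]
    if (!length(lib)) stop("no ligands remain after the MW filter")
    if (!is.null(labels)) labels <- labels[labels$name %in%
                                             vapply(lib, `[[`, "", "name"), ]
  }
  scr <- es_screen(cfg$protein, cfg$cognate, lib,
                   weights = weights, params = params, labels = labels,
                   ligand_charges = if (is.null(cfg$ligand_charges)) "auto"
                                    else cfg$ligand_charges,
                   charge_table = cfg$charge_table,
                   verbose = isTRUE(cfg$verbose))
  out_dir <- if (is.null(cfg$out_dir)) "es_screen_out" else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(scr$ranking, file.path(out_dir, "ranking.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  report <- list(grid_id = scr$grid_id, solver = scr$solver,
                 evaluation = scr$evaluation, stage_seconds = scr$log)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(cfg_raw, file.path(out_dir, "config_used.yaml"))
  invisible(scr)
}
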