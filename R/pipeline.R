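pkg_version <- function() {
  as.character(utils::packageVersion("hemelock"))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

provenance_lines <- function(config) {
  c(paste("hemelock version", pkg_version()),
    paste("config md5", config_hash(config)))
}

#' Run the scan-aggregate-score pipeline on structure ensembles
#'
#' For each named input (a PDB path or an in-memory trajectory/structure):
#' read, census interactions, aggregate per residue, collapse the contact
#' residue's summary, and compute its HemeLock index and predicted Tm.
#' Deterministic given inputs and config; output files carry a provenance
#' header (package version, config hash).
#'
#' @param inputs named list (or character vector of PDB paths); names label
#'   the variants.
#' @param aa181 residue identity at the contact position per input
#'   (recycled when length 1).
#' @param contact_resseq residue number whose summary is scored.
#' @param config list with optional `criteria`, `donors`, `acceptors`,
#'   `frequency_mode`, `model` (a `hemelock_model`), `salt_bridge_mode`.
#' @param out_dir optional directory for TSV outputs (created if needed);
#'   the config is echoed there as `config.yaml`.
#' @return list per variant with `summary` (aggregate table),
#'   `breakdown` (a `score_breakdown`), plus a combined `scores`
#'   data.frame (`variant`, `aa181`, `index`, `predicted_tm`).
#' @export
run_scan_score <- function(inputs, aa181, contact_resseq = 181L,
                           config = list(), out_dir = NULL) {
  if (length(inputs) == 0L) stop("no inputs given")
  if (is.character(inputs)) inputs <- as.list(inputs)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    stop("inputs must be named by variant")
  }
  aa181 <- rep_len(canonical_aa(aa181), length(inputs))
  criteria <- do.call(geometric_criteria, config$criteria %||% list())
  donors <- config$donors %||% default_donor_rules()
  acceptors <- config$acceptors %||% default_acceptors()
  mode <- config$frequency_mode %||% "frame_fraction"
  sb_mode <- config$salt_bridge_mode %||% "both"
  model <- config$model %||% published_model()

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(list(criteria = unclass(criteria),
                          frequency_mode = mode,
                          salt_bridge_mode = sb_mode,
                          contact_resseq = contact_resseq,
                          model = list(a = model$a, b = model$b,
                                       weights = unclass(model$weights))),
                     file.path(out_dir, "config.yaml"))
  }
  prov <- provenance_lines(list(criteria = unclass(criteria), mode = mode,
                                sb_mode = sb_mode))

  results <- list()
  scores <- list()
  for (v in names(inputs)) {
    obj <- inputs[[v]]
    if (is.character(obj)) obj <- read_pdb(obj)
    traj <- if (inherits(obj, "pdb_structure")) as_trajectory(list(obj))
            else obj
    ev <- tryCatch(
      scan_trajectory(traj, donors, acceptors, criteria, sb_mode),
      error = function(e) stop("stage scan failed for variant '", v, "': ",
                               conditionMessage(e)))
    agg <- aggregate_events(ev, mode = mode)
    summ <- summary_for_residue(agg, contact_resseq)
    aa <- aa181[match(v, names(inputs))]
    breakdown <- hemelock_index(summ, aa, model$weights)
    results[[v]] <- list(summary = agg, breakdown = breakdown)
    scores[[v]] <- data.frame(variant = v, aa181 = aa,
                              index = breakdown$hemelock_index,
                              predicted_tm = predict_tm(breakdown, model))
    if (!is.null(out_dir)) {
      write_interactions_tsv(ev, file.path(out_dir, paste0(v, "_events.tsv")),
                             comment = prov)
      write_interactions_tsv(agg, file.path(out_dir,
                                            paste0(v, "_summary.tsv")),
                             comment = prov)
    }
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  if (!is.null(out_dir)) {
    write_interactions_tsv(scores, file.path(out_dir, "scores.tsv"),
                           comment = prov)
  }
  c(results, list(scores = scores))
}

#' Predict Tm for a panel and tabulate residuals
#'
#' @param panel variant panel (with or without observed `Tm_obs`).
#' @param model a `hemelock_model` or a fitted [hemelock()] object.
#' @param volumes named volume table.
#' @return data.frame `variant`, `index`, `predicted`, and - when
#'   observations are present - `observed` and `difference`
#'   (predicted - observed).
#' @export
run_predict <- function(panel, model = published_model(),
                        volumes = aa_volumes()) {
  if (inherits(model, "hemelock")) model <- model$model
  idx <- panel_index(panel, model$weights, volumes)
  out <- data.frame(variant = panel$variant %||% seq_len(nrow(panel)),
                    index = idx,
                    predicted = model$a * idx + model$b)
  if ("Tm_obs" %in% names(panel)) {
    out$observed <- panel$Tm_obs
    out$difference <- out$predicted - out$observed
  }
  out
}
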