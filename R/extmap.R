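# Mapping residue-level scores from external cryptic-site predictors onto
# hotspots, for head-to-head comparison with hotspot-level ranking.

#' Residue-level score table from an external predictor
#'
#' @param scores data.frame with columns `chain`, `resno`, `score`.
#' @param method method name; `"cryptosite"` and `"pocketminer"` carry their
#'   recommended classification thresholds (10.0 and 0.7).
#' @param threshold override of the method default.
#' @return A `residue_score_table`.
#' @export
residue_score_table <- function(scores, method = "external", threshold = NULL) {
  stopifnot(all(c("chain", "resno", "score") %in% names(scores)))
  scores$resno <- as.character(scores$resno)
  key <- paste(scores$chain, scores$resno)
  if (anyDuplicated(key))
    stop_cryptohot("duplicate residue rows in score table",
                   "cryptohot_format_error")
  if (is.null(threshold))
    threshold <- switch(tolower(method), cryptosite = 10.0, pocketminer = 0.7,
                        stop_cryptohot("no default threshold for this method; supply one",
                                       "cryptohot_argument_error"))
  structure(list(scores = scores, method = method, threshold = threshold),
            class = "residue_score_table")
}

#' Read a residue score table from CSV
#'
#' @param path CSV with columns chain, resno, score.
#' @inheritParams residue_score_table
#' @export
read_residue_scores <- function(path, method = "external", threshold = NULL) {
  residue_score_table(utils::read.csv(path, stringsAsFactors = FALSE),
                      method = method, threshold = threshold)
}

#' Score-mapping parameters
#'
#' @param contact_cutoff residue-to-voxel distance in Angstrom (default 5.0).
#' @param contact_fraction strict fraction of voxels that must contact the
#'   protein for a hotspot to count as surface-contacting (default 0.80).
#' @return A `mapping_params` list.
#' @export
mapping_params <- function(contact_cutoff = 5.0, contact_fraction = 0.80) {
  stopifnot(contact_cutoff > 0, contact_fraction > 0, contact_fraction <= 1)
  structure(list(contact_cutoff = contact_cutoff,
                 contact_fraction = contact_fraction),
            class = "mapping_params")
}

#' Is a hotspot in contact with the protein surface?
#'
#' TRUE iff strictly more than `contact_fraction` of the hotspot voxel
#' centers lie within `contact_cutoff` of any protein heavy atom.
#'
#' @param h a `hotspot`.
#' @param s the protein [structure3d].
#' @param params [mapping_params()].
#' @return logical flag.
#' @export
surface_contact <- function(h, s, params = mapping_params()) {
  centers <- as.matrix(h$voxels[, c("x", "y", "z")])
  prot <- xyz_of(s, record = "ATOM")
  frac <- mean(cross_mindist(centers, prot) <= params$contact_cutoff)
  frac > params$contact_fraction
}

#' Map residue-level scores onto a hotspot
#'
#' For a surface-contacting hotspot, the scores of all residues with a heavy
#' atom within `contact_cutoff` of any hotspot voxel center are averaged.
#' Non-contacting hotspots get a missing score.
#'
#' @param h a `hotspot`.
#' @param s the protein [structure3d].
#' @param table a [residue_score_table()].
#' @param params [mapping_params()].
#' @return mean score, or `NA` for non-contacting hotspots / no scored
#'   residues in range (with a warning in the latter case).
#' @export
map_scores <- function(h, s, table, params = mapping_params()) {
  if (!surface_contact(h, s, params)) return(NA_real_)
  centers <- as.matrix(h$voxels[, c("x", "y", "z")])
  a <- s$atoms[s$atoms$record == "ATOM" & s$atoms$is_heavy, , drop = FALSE]
  dmin <- cross_mindist(cbind(a$x, a$y, a$z), centers)
  res <- unique(a[dmin <= params$contact_cutoff, c("chain", "resno")])
  key <- paste(res$chain, res$resno)
  tab_key <- paste(table$scores$chain, table$scores$resno)
  hit <- tab_key %in% key
  if (!any(hit)) {
    warning(sprintf("hotspot %s: no scored residues within %.1f A",
                    h$id, params$contact_cutoff))
    return(NA_real_)
  }
  mean(table$scores$score[hit])
}

#' Classify an external hotspot score against the method threshold
#'
#' @param score mapped hotspot score.
#' @param threshold method threshold (positive iff score >= threshold).
#' @return 1L (positive), 0L (negative), or NA for missing scores.
#' @export
classify_external <- function(score, threshold) {
  ifelse(is.na(score), NA_integer_, as.integer(score >= threshold))
}

#' Compare an external predictor against hotspot labels
#'
#' Maps residue scores onto every hotspot, classifies at the method
#' threshold, and computes the classification metrics over hotspots with a
#' score (non-contacting hotspots are excluded from metrics but kept in the
#' ranking at -Inf).
#'
#' @param hotspots list of labelled `hotspot`s.
#' @param s the protein [structure3d].
#' @param table a [residue_score_table()].
#' @param params [mapping_params()].
#' @param protein_id id used in the ranking output.
#' @return list with the per-hotspot `table` (score, prediction, label) and
#'   `metrics` (NULL if only one class has scores).
#' @export
compare_external <- function(hotspots, s, table, params = mapping_params(),
                             protein_id = s$id) {
  rows <- do.call(rbind, lapply(hotspots, function(h) {
    sc <- map_scores(h, s, table, params)
    data.frame(protein_id = protein_id, hotspot_id = h$id, score = sc,
               prediction = classify_external(sc, table$threshold),
               label = h$label, stringsAsFactors = FALSE)
  }))
  scored <- !is.na(rows$score)
  y <- as.integer(rows$label == "cryptic")
  metrics <- NULL
  if (any(scored) && length(unique(y[scored])) == 2L)
    metrics <- compute_metrics(y[scored], rows$score[scored], table$threshold)
  ranking <- rows
  ranking$probability <- ifelse(is.na(ranking$score), -Inf, ranking$score)
  ranking <- rank_hotspots(ranking)
  list(table = rows, metrics = metrics, ranking = ranking,
       method = table$method)
}
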