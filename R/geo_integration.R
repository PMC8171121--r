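# Integration entry point for the deposited study data (GEO accession
# GSE163943). Network retrieval is out of scope: the user downloads the
# processed matrix themselves and converts it to the package's expression
# schema (see read_expression); this function then reruns the canonical
# chain and reports the up/down DE counts per biotype and the CNC panel
# edge counts.

#' Re-analyze a locally deposited expression matrix
#'
#' Runs flag filter, quantile normalization and the DE call with the
#' canonical thresholds on a user-supplied copy of a deposited dataset,
#' then builds the up- and down-panel CNC networks from the validation
#' candidates.
#'
#' @param expression_path Expression matrix in [read_expression()] schema.
#' @param design_path Design TSV (`sample_id`, `group`).
#' @param annotation_path Feature annotation TSV.
#' @param config Thresholds, see [default_config()].
#' @return List with `de_counts` (biotype x direction table),
#'   `cnc_edges_up`, `cnc_edges_down`.
#' @export
analyze_deposited_study <- function(expression_path, design_path,
                                    annotation_path,
                                    config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  bundle <- read_expression(expression_path)
  design <- read_design(design_path)
  anno <- read_annotation(annotation_path)
  norm <- preprocess(bundle, min_detected = cfg$flag_min_detected)$bundle
  de <- call_de(norm, design, anno, fc_min = cfg$de_fc_min,
                p_max = cfg$de_p_max)
  cand <- suppressWarnings(select_validation_candidates(
    de, fc_min = cfg$val_fc_min, p_max = cfg$val_p_max,
    intensity_min = cfg$val_intensity_min, n_each = cfg$val_n_each))
  logb <- log2_transform(norm)
  mrna_de <- de$feature_id[de$de & de$biotype == "mRNA"]
  panel <- function(dirn) {
    lncs <- cand$feature_id[cand$biotype == "lncRNA" & cand$direction == dirn]
    if (!length(lncs)) return(0L)
    build_cnc(logb, lncs, mrna_de, r_min = cfg$cnc_r_min,
              p_max = cfg$cnc_p_max)$summary$n_edges
  }
  list(de_counts = de_counts(de),
       cnc_edges_up = panel("up"),
       cnc_edges_down = panel("down"))
}
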