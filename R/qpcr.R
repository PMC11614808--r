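#' Collapse technical qPCR replicates
#'
#' Per (sample, gene): the mean Ct over detected replicates. Non-detect
#' replicates are dropped from the mean and flagged; when every replicate is
#' non-detect the Ct is imputed at the amplification cycle limit
#' (`policy = "impute_limit"`, the default — the assay ran 40 cycles, so 40
#' is the censoring bound, not an invented value) or excluded
#' (`policy = "drop"`). Nothing is ever silently discarded: both situations
#' carry flags.
#'
#' @param table a `ct_table` (replicate level).
#' @param policy `"impute_limit"` or `"drop"` for all-non-detect samples.
#' @param ct_limit cycle limit used for imputation (default 40).
#' @return data.frame with one row per (sample, gene): group labels, `ct`,
#'   `n_detected`, `nondetect_dropped`, `all_nondetect`.
#' @export
collapse_technical <- function(table, policy = c("impute_limit", "drop"),
                               ct_limit = 40) {
  policy <- match.arg(policy)
  key <- interaction(table$sample_id, table$gene, drop = TRUE)
  pieces <- lapply(split(seq_len(nrow(table)), key), function(i) {
    sub <- table[i, ]
    det <- !sub$nondetect & !is.na(sub$ct)
    all_nd <- !any(det)
    ct <- if (all_nd) {
      if (policy == "impute_limit") ct_limit else NA_real_
    } else mean(sub$ct[det])
    data.frame(sample_id = sub$sample_id[1], line = sub$line[1],
               treatment = sub$treatment[1], dpi = sub$dpi[1],
               gene = sub$gene[1], ct = ct, n_detected = sum(det),
               nondetect_dropped = any(!det) && !all_nd,
               all_nondetect = all_nd)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (policy == "drop") out <- out[!out$all_nondetect, ]
  out
}

#' Screen candidate reference genes for stability
#'
#' For each candidate, the range of sample-mean Cts (max - min) is converted
#' to a fold scale `2^range`; a gene is `unsuitable` when that scale exceeds
#' `threshold_fold` (default 2, mirroring the published screen in which 18s
#' with inter-sample ranges within ~1-1.4 on the fold scale was retained and
#' genes varying by more than 2 were rejected).
#'
#' @param table replicate-level `ct_table`.
#' @param candidate_genes character vector; each must be measured in every
#'   sample.
#' @param threshold_fold suitability cutoff on the `2^range` scale.
#' @return data.frame per gene: `inter_sample_ct_range`, `fold_scale_range`,
#'   `verdict`. Attribute `chosen` holds the most stable suitable gene.
#' @export
screen_reference <- function(table, candidate_genes, threshold_fold = 2) {
  coll <- collapse_technical(table)
  samples <- unique(coll$sample_id)
  res <- lapply(candidate_genes, function(g) {
    sub <- coll[coll$gene == g, ]
    if (!all(samples %in% sub$sample_id))
      stop_retinaquant(paste0("candidate '", g,
                              "' not measured in every sample"),
                       "qpcr_config_error")
    rng <- max(sub$ct) - min(sub$ct)
    fold <- 2^rng
    data.frame(gene = g, inter_sample_ct_range = rng,
               fold_scale_range = fold,
               verdict = if (fold > threshold_fold) "unsuitable"
                         else "suitable")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  suitable <- out[out$verdict == "suitable", ]
  if (nrow(suitable) == 0)
    stop_retinaquant("no suitable reference gene among candidates",
                     "qpcr_reference_error")
  attr(out, "chosen") <-
    suitable$gene[which.min(suitable$fold_scale_range)]
  out
}

#' Delta-delta-Ct relative quantification
#'
#' Per sample: `dCt = Ct_target - Ct_reference`; `ddCt = dCt - mean(dCt)`
#' over the sample's calibrator group; `fold = 2^-ddCt` (Livak method,
#' amplification efficiency fixed at 2). One record per biological sample
#' (one retina). The calibrator statistic is the arithmetic mean of
#' calibrator delta-Cts, i.e. the geometric mean on the fold scale, so the
#' calibrator group's folds have geometric mean 1 by construction.
#'
#' @param table replicate-level `ct_table`.
#' @param target_gene gene to quantify.
#' @param reference_gene reference gene (must be measured in every sample;
#'   screen it first with [screen_reference()]).
#' @param calibrator named list selecting the calibrator condition, e.g.
#'   `list(treatment = "saline")`.
#' @param match_on columns on which a sample must agree with its calibrator
#'   samples (default `"dpi"`: saline samples of the same timepoint; add
#'   `"line"` to also match the transgenic line).
#' @param policy non-detect collapse policy, see [collapse_technical()].
#' @return `fold_change_result` data.frame: one row per sample with
#'   `delta_ct`, `delta_delta_ct`, `fold_change` and non-detect flags.
#' @export
delta_delta_ct <- function(table, target_gene, reference_gene,
                           calibrator = list(treatment = "saline"),
                           match_on = "dpi",
                           policy = c("impute_limit", "drop")) {
  policy <- match.arg(policy)
  coll <- collapse_technical(table, policy = policy)
  tg <- coll[coll$gene == target_gene, ]
  rf <- coll[coll$gene == reference_gene, ]
  if (nrow(tg) == 0)
    stop_retinaquant(paste0("target gene not in table: ", target_gene),
                     "qpcr_config_error")
  if (nrow(rf) == 0 || !all(tg$sample_id %in% rf$sample_id))
    stop_retinaquant(paste0("reference gene '", reference_gene,
                            "' must be measured in every sample"),
                     "qpcr_config_error")
  m <- merge(tg, rf[, c("sample_id", "ct")], by = "sample_id",
             suffixes = c("", "_ref"))
  m$delta_ct <- m$ct - m$ct_ref

  in_calibrator <- rep(TRUE, nrow(m))
  for (nm in names(calibrator))
    in_calibrator <- in_calibrator & m[[nm]] == calibrator[[nm]]
  if (!any(in_calibrator))
    stop_retinaquant(sprintf(
      "empty calibrator group for gene %s (%s)", target_gene,
      paste(names(calibrator), unlist(calibrator), sep = "=",
            collapse = ", ")), "qpcr_calibrator_error")

  m$delta_delta_ct <- NA_real_
  for (i in seq_len(nrow(m))) {
    match_cal <- in_calibrator
    for (nm in match_on) match_cal <- match_cal & m[[nm]] == m[[nm]][i]
    cal_dct <- m$delta_ct[match_cal & !is.na(m$delta_ct)]
    if (length(cal_dct) == 0)
      stop_retinaquant(sprintf(
        "calibrator group for gene %s is empty or all non-detect (%s)",
        target_gene,
        paste(match_on, sapply(match_on, function(nm) m[[nm]][i]),
              sep = "=", collapse = ", ")), "qpcr_calibrator_error")
    m$delta_delta_ct[i] <- m$delta_ct[i] - mean(cal_dct)
  }
  m$fold_change <- 2^(-m$delta_delta_ct)
  out <- m[, c("sample_id", "line", "treatment", "dpi", "delta_ct",
               "delta_delta_ct", "fold_change", "nondetect_dropped",
               "all_nondetect")]
  out$gene <- target_gene
  attr(out, "reference_gene") <- reference_gene
  attr(out, "calibrator") <- calibrator
  class(out) <- c("fold_change_result", "data.frame")
  out
}
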